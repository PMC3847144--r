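## Type-I functional divergence between two protein subfamilies: per-site
## minimum substitution counts by Fitch parsimony on each cluster's
## subtree, maximum-likelihood estimation of the divergence coefficient
## theta under a two-state Poisson-gamma mixture, the likelihood-ratio
## test against theta = 0 (chi-square, df 1), and per-site posterior
## probabilities Q_k of belonging to the diverged class.
##
## Model: site rates lambda ~ Gamma(shape a, rate b).  With probability
## (1 - theta) the two clusters share one rate (state S0); with
## probability theta they draw independent rates (state S1, altered
## selective constraints).  Substitution counts are Poisson with mean
## lambda * d_k, where d_k is the cluster's evolutionary depth.
## Marginally the counts are negative binomial; under S0 the pair is a
## bivariate Poisson-gamma with joint kernel
## Gamma(x1+x2+a) / (x1! x2! Gamma(a)) * d1^x1 d2^x2 b^a /
## (d1+d2+b)^(x1+x2+a).

MISSING_STATES <- c("-", "X", "?", ".", "*")

#' Construct per-site substitution counts for two clusters
#'
#' @param x1,x2 Non-negative integer vectors of equal length (minimum
#'   substitution counts per site in clusters 1 and 2).
#' @param d1,d2 Positive cluster evolutionary depths (default 1; the
#'   overall rate scale is then absorbed into the model's `b`).
#' @param masked Optional logical vector marking sites excluded from
#'   fitting.
#' @return An object of class `site_change_counts`.
#' @export
site_change_counts <- function(x1, x2, d1 = 1, d2 = 1, masked = NULL) {
  stopifnot(length(x1) == length(x2), all(x1 >= 0), all(x2 >= 0),
            d1 > 0, d2 > 0)
  if (is.null(masked)) masked <- rep(FALSE, length(x1))
  stopifnot(length(masked) == length(x1))
  structure(list(x1 = as.integer(x1), x2 = as.integer(x2),
                 d1 = d1, d2 = d2, masked = masked,
                 n_sites = length(x1)),
            class = "site_change_counts")
}

## Fitch small parsimony over one rooted (possibly multifurcating)
## subtree for every alignment column.  Missing leaves carry the full
## state set, so they never force a change.
fitch_counts_tree <- function(tree, states_matrix) {
  n_tip <- length(tree$tip.label)
  if (n_tip == 1L) return(rep(0L, nrow(states_matrix)))
  tree <- ape::reorder.phylo(tree, "postorder")
  edge <- tree$edge
  n_edge <- nrow(edge)
  n_node <- n_tip + tree$Nnode
  L <- nrow(states_matrix)
  counts <- integer(L)
  for (s in seq_len(L)) {
    st <- states_matrix[s, tree$tip.label]
    miss <- st %in% MISSING_STATES | is.na(st)
    alpha <- unique(st[!miss])
    if (length(alpha) <= 1L) { counts[s] <- 0L; next }
    bit <- setNames(bitwShiftL(1L, seq_along(alpha) - 1L), alpha)
    full <- sum(bit)
    sets <- integer(n_node)
    sets[seq_len(n_tip)] <- ifelse(miss, full, bit[st])
    nch <- 0L
    ## postorder guarantees a child's set is complete before the edge to
    ## its parent is visited; parents accumulate children pairwise
    for (e in seq_len(n_edge)) {
      p <- edge[e, 1]; ch <- edge[e, 2]
      s_ch <- sets[ch]
      if (sets[p] == 0L) sets[p] <- s_ch
      else {
        inter <- bitwAnd(sets[p], s_ch)
        if (inter != 0L) sets[p] <- inter
        else { sets[p] <- bitwOr(sets[p], s_ch); nch <- nch + 1L }
      }
    }
    counts[s] <- nch
  }
  counts
}

#' Per-site substitution counts by Fitch parsimony
#'
#' For each alignment column and each cluster, the minimum number of
#' state changes on that cluster's induced subtree.  Gaps and unknown
#' residues are treated as missing: the leaf contributes the universal
#' state set, so the site's count reflects only the observed leaves.
#' Columns missing in more than `max_missing` of either cluster's leaves
#' are masked and excluded from model fitting.
#'
#' @param ca A [clustered_alignment()].
#' @param max_missing Masking threshold as a fraction of a cluster's
#'   leaves (default 0.5).
#' @return A [site_change_counts()] with `d1 = d2 = 1`.
#' @export
fitch_site_changes <- function(ca, max_missing = 0.5) {
  stopifnot(inherits(ca, "clustered_alignment"))
  counts <- masked <- vector("list", 2)
  for (cl in 1:2) {
    leaves <- names(ca$clusters)[ca$clusters == cl]
    sub <- if (length(leaves) == length(ca$tree$tip.label)) ca$tree
           else if (length(leaves) == 1L) NULL
           else ape::keep.tip(ca$tree, leaves)
    mat <- ca$aln[, leaves, drop = FALSE]
    miss_frac <- rowMeans(mat %in% MISSING_STATES | is.na(mat))
    dim(miss_frac) <- NULL
    masked[[cl]] <- miss_frac > max_missing
    counts[[cl]] <- if (is.null(sub)) rep(0L, nrow(mat))
                    else fitch_counts_tree(sub, mat)
  }
  mk <- masked[[1]] | masked[[2]]
  if (any(mk))
    message(sum(mk), " site(s) masked (> ", 100 * max_missing,
            "% missing in a cluster)")
  site_change_counts(counts[[1]], counts[[2]], masked = mk)
}

## closed-form log marginals
log_p1 <- function(x, d, a, b) {
  lgamma(x + a) - lgamma(x + 1) - lgamma(a) +
    x * log(d / (d + b)) + a * log(b / (d + b))
}

log_p0 <- function(x1, x2, d1, d2, a, b) {
  lgamma(x1 + x2 + a) - lgamma(x1 + 1) - lgamma(x2 + 1) - lgamma(a) +
    x1 * log(d1) + x2 * log(d2) + a * log(b) -
    (x1 + x2 + a) * log(d1 + d2 + b)
}

#' Log-likelihood of the two-state functional-divergence model
#'
#' `lnL = sum_k log[(1 - theta) P0(x1k, x2k) + theta P1(x1k) P1(x2k)]`
#' over unmasked sites, with the closed-form Poisson-gamma marginals
#' described in the package vignette.
#'
#' @param counts A [site_change_counts()].
#' @param theta Mixture weight of the diverged class, in `[0, 1]`.
#' @param a,b Gamma shape and rate of the site-rate distribution.
#' @return Log-likelihood (numeric scalar).
#' @export
type1_loglik <- function(counts, theta, a, b) {
  stopifnot(theta >= 0, theta <= 1, a > 0, b > 0,
            is.finite(a), is.finite(b))
  use <- !counts$masked
  x1 <- counts$x1[use]; x2 <- counts$x2[use]
  lp0 <- log_p0(x1, x2, counts$d1, counts$d2, a, b)
  if (theta == 0) return(sum(lp0))
  lp1 <- log_p1(x1, counts$d1, a, b) + log_p1(x2, counts$d2, a, b)
  if (theta == 1) return(sum(lp1))
  hi <- pmax(lp0 + log1p(-theta), lp1 + log(theta))
  lo <- pmin(lp0 + log1p(-theta), lp1 + log(theta))
  sum(hi + log1p(exp(lo - hi)))
}

## fit (a, b) under theta = 0 (null) by multi-start quasi-Newton on the
## log scale; returns list(a, b, lnL)
fit_null <- function(counts, a_starts = c(0.5, 1, 2)) {
  use <- !counts$masked
  mean_tot <- mean(counts$x1[use] + counts$x2[use])
  dsum <- counts$d1 + counts$d2
  nll <- function(p) -type1_loglik(counts, 0, exp(p[1]), exp(p[2]))
  best <- NULL
  for (a0 in a_starts) {
    b0 <- max(a0 * dsum / max(mean_tot, 0.05), 1e-3)
    fit <- tryCatch(optim(c(log(a0), log(b0)), nll, method = "L-BFGS-B",
                          lower = c(-12, -12), upper = c(12, 12),
                          control = list(factr = 1e4)),
                    error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value))
      best <- fit
  }
  if (is.null(best)) stop("null-model optimization failed")
  list(a = exp(best$par[1]), b = exp(best$par[2]), lnL = -best$value)
}

#' Maximum-likelihood estimation of type-I functional divergence
#'
#' Maximizes the mixture log-likelihood over `(theta, a, b)` with theta
#' bounded in `[0, 1]` (multi-start bounded quasi-Newton), fits the null
#' model with theta fixed at 0, and reports the likelihood-ratio test
#' `LRT = 2 * (lnL_alt - lnL_null)` (clipped at 0) against a chi-square
#' distribution with one degree of freedom, the curvature-based standard
#' error of theta, and the per-site posteriors
#' `Q_k = theta P1 P1 / ((1 - theta) P0 + theta P1 P1)`.
#'
#' @param counts A [site_change_counts()]; at least 20 unmasked sites are
#'   recommended (a warning is issued below that).
#' @param theta_starts,a_starts Multi-start grids.
#' @param boundary_mix If TRUE, use the 50:50 chi-square(0)/chi-square(1)
#'   boundary mixture for the p-value instead of the plain df-1
#'   chi-square (off by default).
#' @return An object of class `funcdiv_result` with elements `theta`,
#'   `a`, `b`, `lnL`, `lnL_null`, `theta_se`, `lrt`, `p`, `qk`,
#'   `critical_sites_070`, `critical_sites_095`, `convergence`.
#' @export
estimate_type1 <- function(counts, theta_starts = c(0.1, 0.5, 0.9),
                           a_starts = c(0.5, 1, 2),
                           boundary_mix = FALSE) {
  use <- !counts$masked
  if (sum(use) < 20)
    warning("only ", sum(use), " unmasked sites; estimates may be unstable")
  if (all(counts$x1[use] == 0) && all(counts$x2[use] == 0))
    stop("degenerate input: all site counts are zero")
  null_fit <- fit_null(counts, a_starts)
  eps <- 1e-9
  nll <- function(p) -type1_loglik(counts, p[1], exp(p[2]), exp(p[3]))
  mean_tot <- mean(counts$x1[use] + counts$x2[use])
  dsum <- counts$d1 + counts$d2
  best <- NULL
  for (t0 in theta_starts) for (a0 in a_starts) {
    b0 <- max(a0 * dsum / max(mean_tot, 0.05), 1e-3)
    fit <- tryCatch(optim(c(t0, log(a0), log(b0)), nll,
                          method = "L-BFGS-B",
                          lower = c(eps, -12, -12),
                          upper = c(1 - eps, 12, 12),
                          control = list(factr = 1e4)),
                    error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value))
      best <- fit
  }
  if (is.null(best)) stop("optimizer failed to converge from any start")
  theta_hat <- best$par[1]
  a_hat <- exp(best$par[2]); b_hat <- exp(best$par[3])
  lnL_alt <- -best$value
  ## the null is nested: never report an alternative fit below it
  if (lnL_alt < null_fit$lnL) {
    lnL_alt <- null_fit$lnL
    theta_hat <- 0
    a_hat <- null_fit$a; b_hat <- null_fit$b
  }
  at_zero <- theta_hat < 1e-6
  lrt <- if (at_zero) 0 else max(0, 2 * (lnL_alt - null_fit$lnL))
  p <- if (at_zero) 1
       else if (boundary_mix) 0.5 * pchisq(lrt, 1, lower.tail = FALSE)
       else pchisq(lrt, 1, lower.tail = FALSE)
  theta_se <- NA_real_
  if (!at_zero && theta_hat < 1 - 1e-6) {
    hess <- tryCatch(
      optimHess(c(theta_hat, a_hat, b_hat),
                function(p) -type1_loglik(counts, p[1], p[2], p[3])),
      error = function(e) NULL)
    if (!is.null(hess)) {
      vc <- tryCatch(solve(hess), error = function(e) NULL)
      if (!is.null(vc) && vc[1, 1] > 0) theta_se <- sqrt(vc[1, 1])
    }
  }
  qk <- rep(NA_real_, counts$n_sites)
  if (theta_hat > 0) {
    lp0 <- log_p0(counts$x1, counts$x2, counts$d1, counts$d2, a_hat, b_hat)
    lp1 <- log_p1(counts$x1, counts$d1, a_hat, b_hat) +
           log_p1(counts$x2, counts$d2, a_hat, b_hat)
    num <- log(theta_hat) + lp1
    den_hi <- pmax(lp0 + log1p(-theta_hat), num)
    den_lo <- pmin(lp0 + log1p(-theta_hat), num)
    qk <- exp(num - (den_hi + log1p(exp(den_lo - den_hi))))
  } else qk <- rep(0, counts$n_sites)
  qk[counts$masked] <- NA_real_
  res <- structure(list(theta = theta_hat, a = a_hat, b = b_hat,
                        lnL = lnL_alt, lnL_null = null_fit$lnL,
                        theta_se = theta_se, lrt = lrt, p = p, qk = qk,
                        convergence = best$convergence),
                   class = "funcdiv_result")
  cs <- site_posteriors(res)
  res$critical_sites_070 <- cs$q070
  res$critical_sites_095 <- cs$q095
  res
}

#' Critical sites from fitted per-site posteriors
#'
#' Returns the 1-based alignment columns whose posterior probability of
#' belonging to the diverged class is strictly above each threshold
#' (default 0.7 and 0.95; the stricter list is nested in the looser one).
#'
#' @param result A `funcdiv_result` (or any list with a `qk` element).
#' @param thresholds Two increasing thresholds (default `c(0.7, 0.95)`).
#' @return A list with components `q070` and `q095` (site index vectors).
#' @export
site_posteriors <- function(result, thresholds = c(0.7, 0.95)) {
  qk <- result$qk
  list(q070 = which(!is.na(qk) & qk > thresholds[1]),
       q095 = which(!is.na(qk) & qk > thresholds[2]))
}

#' @export
print.funcdiv_result <- function(x, ...) {
  cat("<funcdiv_result> type-I functional divergence\n",
      "  theta = ", format(x$theta, digits = 4),
      if (!is.na(x$theta_se)) paste0(" +/- ", format(x$theta_se, digits = 3)),
      "\n  LRT = ", format(x$lrt, digits = 5), " (df 1), p = ",
      format(x$p, digits = 4), "\n",
      "  critical sites: ", length(x$critical_sites_070), " at Q>0.7, ",
      length(x$critical_sites_095), " at Q>0.95\n", sep = "")
  invisible(x)
}
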