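## 3:1 codon-junction dinucleotide relative abundances (the genomic
## signature restricted to the least constrained dinucleotide context),
## the sigma difference between two signatures, and rank-covariation
## tests between a gene and its genome.

## junction (third base of codon i, first base of codon i+1) counts for
## one sequence; junctions touching a codon with ambiguous bases are
## dropped, as are the positional base counts of such codons
junction_counts_one <- function(nt_seq) {
  cod <- split_codons(nt_seq)
  ok <- grepl("^[ACGT]{3}$", cod)
  b3 <- substr(cod, 3L, 3L)
  b1 <- substr(cod, 1L, 1L)
  nc <- length(cod)
  jc <- setNames(integer(16), DINUCS)
  if (nc >= 2L) {
    i <- seq_len(nc - 1L)
    use <- ok[i] & ok[i + 1L]
    if (any(use)) {
      tb <- table(paste0(b3[i][use], b1[i + 1L][use]))
      jc[names(tb)] <- as.integer(tb)
    }
  }
  f3 <- setNames(integer(4), BASES)
  f1 <- setNames(integer(4), BASES)
  t3 <- table(b3[ok]); t1 <- table(b1[ok])
  f3[names(t3)] <- as.integer(t3)
  f1[names(t1)] <- as.integer(t1)
  list(junction = jc, third = f3, first = f1)
}

#' 3:1 dinucleotide relative-abundance profile
#'
#' Junctions are the pairs (third base of codon i, first base of codon
#' i+1) within each gene — never across gene boundaries.  The relative
#' abundance of dinucleotide XY is `rho*_XY = f_XY / (f_X * f_Y)` where
#' `f_XY` is the junction dinucleotide frequency, `f_X` the frequency of
#' X among third-codon-position bases and `f_Y` the frequency of Y among
#' first-codon-position bases (position-specific mononucleotide
#' frequencies, consistent with the 3:1 restriction).  For a gene set the
#' counts are pooled over all genes before frequencies are formed.
#'
#' @param x A nucleotide sequence string or a [cds_set()].
#' @return An object of class `dinuc31_profile` with `rho` (16 values),
#'   `f_junction`, `f3`, `f1` and `junction_count`.
#' @export
dinuc31_profile <- function(x) {
  seqs <- if (is.data.frame(x)) x$nt_seq else x
  parts <- lapply(seqs, junction_counts_one)
  jc <- Reduce(`+`, lapply(parts, `[[`, "junction"))
  f3c <- Reduce(`+`, lapply(parts, `[[`, "third"))
  f1c <- Reduce(`+`, lapply(parts, `[[`, "first"))
  n_j <- sum(jc)
  if (n_j == 0L) stop("no valid 3:1 junctions (need >= 2 codons)")
  f_xy <- jc / n_j
  f3 <- f3c / sum(f3c)
  f1 <- f1c / sum(f1c)
  rho <- setNames(numeric(16), DINUCS)
  for (d in DINUCS) {
    fx <- f3[substr(d, 1, 1)]; fy <- f1[substr(d, 2, 2)]
    rho[d] <- if (fx > 0 && fy > 0) f_xy[d] / (fx * fy) else NA_real_
  }
  structure(list(rho = rho, f_junction = f_xy, f3 = f3, f1 = f1,
                 junction_count = n_j),
            class = "dinuc31_profile")
}

#' Sigma difference between two dinucleotide signatures
#'
#' The mean absolute difference of the two relative-abundance vectors,
#' averaged over exactly the 16 dinucleotides:
#' `sigma(f, g) = (1/16) * sum_XY |rho*_XY(f) - rho*_XY(g)|`.
#'
#' @param a,b Two [dinuc31_profile()] objects.
#' @return Non-negative numeric scalar (NA, with a warning, if either
#'   profile has undefined entries).
#' @export
sigma_difference <- function(a, b) {
  ra <- a$rho[DINUCS]; rb <- b$rho[DINUCS]
  if (anyNA(ra) || anyNA(rb)) {
    warning("undefined relative abundance in a profile; sigma is NA")
    return(NA_real_)
  }
  mean(abs(ra - rb))
}

#' Rank covariation between two dinucleotide signatures
#'
#' Spearman's rho and Kendall's tau on the 16 paired relative-abundance
#' values, with average ranks for ties and two-sided p-values.  The
#' default p-values use the standard large-sample approximations; a
#' seeded Monte-Carlo permutation alternative is available.
#'
#' @param a,b Two [dinuc31_profile()] objects.
#' @param p_method `"asymptotic"` (default) or `"montecarlo"`.
#' @param n_perm Number of permutations for the Monte-Carlo option.
#' @param seed Seed for the Monte-Carlo option.
#' @return A list with `spearman_rho`, `spearman_p`, `kendall_tau`,
#'   `kendall_p` (all NA, with a warning, when either profile is
#'   constant).
#' @export
rank_covariation <- function(a, b, p_method = c("asymptotic", "montecarlo"),
                             n_perm = 9999, seed = 1L) {
  p_method <- match.arg(p_method)
  x <- unname(a$rho[DINUCS]); y <- unname(b$rho[DINUCS])
  if (anyNA(x) || anyNA(y) || sd(x) == 0 || sd(y) == 0) {
    warning("constant or undefined profile; rank covariation is NA")
    return(list(spearman_rho = NA_real_, spearman_p = NA_real_,
                kendall_tau = NA_real_, kendall_p = NA_real_))
  }
  sp <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
  kd <- suppressWarnings(cor.test(x, y, method = "kendall", exact = FALSE))
  out <- list(spearman_rho = unname(sp$estimate), spearman_p = sp$p.value,
              kendall_tau = unname(kd$estimate), kendall_p = kd$p.value)
  if (p_method == "montecarlo") {
    out$spearman_p <- mc_cor_p(x, y, "spearman", n_perm, seed)
    out$kendall_p <- mc_cor_p(x, y, "kendall", n_perm, seed + 1L)
  }
  out
}

mc_cor_p <- function(x, y, method, n_perm, seed) {
  obs <- abs(suppressWarnings(stats::cor(x, y, method = method)))
  with_seed(seed, {
    hits <- 0L
    for (i in seq_len(n_perm)) {
      r <- abs(suppressWarnings(stats::cor(x, sample(y), method = method)))
      if (r >= obs - 1e-12) hits <- hits + 1L
    }
    (hits + 1L) / (n_perm + 1L)
  })
}
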