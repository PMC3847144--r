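## Phenotype enrichment between family-containing and non-containing
## strains: per-category two-sided Fisher exact tests (one-vs-rest 2x2
## tables) and pooled-variance Student t-tests for quantitative traits.

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Rows are in-family / not-in-family, columns has-category /
#' lacks-category.  The two-sided p-value is the sum of hypergeometric
#' probabilities of all tables with the same margins whose probability
#' does not exceed that of the observed table (within relative tolerance
#' 1e-7).  A zero margin gives p = 1 with a warning.
#'
#' @param a,b,c,d Cell counts, or a 2x2 matrix as `a`.
#' @return Two-sided p-value.
#' @export
fisher_exact_2x2 <- function(a, b = NULL, c = NULL, d = NULL) {
  if (is.matrix(a)) {
    m <- a
  } else {
    m <- matrix(c(a, c, b, d), nrow = 2)
  }
  stopifnot(all(dim(m) == 2), all(m >= 0))
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    warning("degenerate margin; p = 1")
    return(1)
  }
  fisher.test(m)$p.value
}

#' Pooled-variance two-sample Student t-test
#'
#' The classic equal-variance t statistic with
#' `df = n_a + n_b - 2` and a two-sided p-value.
#'
#' @param group_a,group_b Numeric vectors (NA values dropped); each needs
#'   at least 2 observations.
#' @return A list with `t`, `df`, `p`, `mean_a`, `mean_b`.
#' @export
student_t_test <- function(group_a, group_b) {
  group_a <- group_a[!is.na(group_a)]
  group_b <- group_b[!is.na(group_b)]
  if (length(group_a) < 2 || length(group_b) < 2)
    stop("each group needs at least 2 non-missing observations")
  if (sd(c(group_a - mean(group_a), group_b - mean(group_b))) == 0)
    stop("zero pooled variance")
  tt <- t.test(group_a, group_b, var.equal = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mean_a = mean(group_a), mean_b = mean(group_b))
}

#' Enrichment scan over a strain trait table
#'
#' For every categorical trait and every category with at least
#' `min_count` in-family strains, builds the one-vs-rest 2x2 table over
#' strains with a non-missing value for that trait and computes a Fisher
#' exact p-value; categories below `min_count` are marked not tested.
#' For every quantitative trait a pooled-variance t-test compares the two
#' groups.  No multiple-testing correction is applied to the headline
#' p-values (Benjamini-Hochberg and Bonferroni columns are emitted for
#' information only).
#'
#' @param traits A `strain_traits` table ([read_trait_table()] or
#'   [generate_trait_table()]).
#' @param min_count Minimum in-family count for a category to be tested
#'   (default 5).
#' @return A data.frame with one row per trait/category (or per
#'   quantitative trait) and columns `trait`, `category`, `type`,
#'   `n_family`, `n_other`, `stat`, `p`, `tested`, `p_bh`,
#'   `p_bonferroni`.
#' @export
enrichment_scan <- function(traits, min_count = 5) {
  memb_col <- attr(traits, "membership_col")
  strain_col <- attr(traits, "strain_col")
  if (is.null(memb_col) || !memb_col %in% names(traits))
    stop("trait table lacks a membership column")
  memb <- traits[[memb_col]]
  rows <- list()
  for (tr in setdiff(names(traits), c(memb_col, strain_col))) {
    v <- traits[[tr]]
    ok <- !is.na(v)
    if (is.numeric(v)) {
      res <- tryCatch(student_t_test(v[ok & memb], v[ok & !memb]),
                      error = function(e) NULL)
      rows[[length(rows) + 1L]] <- data.frame(
        trait = tr, category = NA_character_, type = "quantitative",
        n_family = sum(ok & memb), n_other = sum(ok & !memb),
        mean_family = if (is.null(res)) NA_real_ else res$mean_a,
        mean_other = if (is.null(res)) NA_real_ else res$mean_b,
        stat = if (is.null(res)) NA_real_ else res$t,
        p = if (is.null(res)) NA_real_ else res$p,
        tested = !is.null(res), stringsAsFactors = FALSE)
    } else {
      for (cat_lv in sort(unique(v[ok]))) {
        a <- sum(ok & memb & v == cat_lv)      # in family, has category
        b <- sum(ok & memb & v != cat_lv)
        c_ <- sum(ok & !memb & v == cat_lv)
        d <- sum(ok & !memb & v != cat_lv)
        tested <- a >= min_count
        p <- if (tested)
          suppressWarnings(fisher_exact_2x2(a, b, c_, d)) else NA_real_
        rows[[length(rows) + 1L]] <- data.frame(
          trait = tr, category = as.character(cat_lv),
          type = "categorical",
          n_family = a, n_other = c_,
          mean_family = NA_real_, mean_other = NA_real_,
          stat = NA_real_, p = p, tested = tested,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  out$p_bh <- NA_real_
  out$p_bonferroni <- NA_real_
  tested <- which(out$tested & !is.na(out$p))
  out$p_bh[tested] <- p.adjust(out$p[tested], method = "BH")
  out$p_bonferroni[tested] <- p.adjust(out$p[tested], method = "bonferroni")
  rownames(out) <- NULL
  out
}
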