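## GC content at the three codon positions and total, genome-wide
## aggregates, and the two-dispersion-unit deviation rule for flagging
## compositionally atypical genes.

#' GC content by codon position for one coding sequence
#'
#' Codons containing any base outside `{A,C,G,T}` are excluded entirely.
#' `gc_p` is the percentage of G or C among the bases at codon position p
#' over the countable codons; `gct` is computed over all counted bases
#' (the codon-count-weighted mean of the three positions).
#'
#' @param x A nucleotide sequence string, or one row of a [cds_set()].
#' @return A list of class `gc_profile` with elements `gc1`, `gc2`, `gc3`,
#'   `gct` (percentages) and `counted_codons`.
#' @export
gc_profile <- function(x) {
  nt <- if (is.list(x) || is.data.frame(x)) x$nt_seq[1] else x
  cod <- countable_codons(split_codons(nt))
  n <- length(cod)
  if (n == 0L) stop("no countable codons in sequence")
  gc_at <- function(pos) {
    b <- substr(cod, pos, pos)
    100 * sum(b == "G" | b == "C") / n
  }
  g1 <- gc_at(1L); g2 <- gc_at(2L); g3 <- gc_at(3L)
  structure(list(gc1 = g1, gc2 = g2, gc3 = g3, gct = (g1 + g2 + g3) / 3,
                 counted_codons = n),
            class = "gc_profile")
}

#' Per-gene GC profiles for a whole coding-sequence set
#'
#' @param cds A [cds_set()].
#' @return A data.frame with columns `gene_id`, `gc1`, `gc2`, `gc3`,
#'   `gct`, `counted_codons`.
#' @export
gc_profiles <- function(cds) {
  profs <- lapply(cds$nt_seq, gc_profile)
  data.frame(gene_id = cds$gene_id,
             gc1 = vapply(profs, `[[`, 0, "gc1"),
             gc2 = vapply(profs, `[[`, 0, "gc2"),
             gc3 = vapply(profs, `[[`, 0, "gc3"),
             gct = vapply(profs, `[[`, 0, "gct"),
             counted_codons = vapply(profs, `[[`, 0, "counted_codons"),
             stringsAsFactors = FALSE)
}

#' Genome-wide GC summary
#'
#' Unweighted per-gene mean and dispersion of GC1, GC2, GC3 and GCt.
#' The dispersion used for the deviation rule is the standard deviation
#' of the per-gene GC distribution by default (`"sd"`); `"sem"` divides
#' by sqrt(n) for the literal standard-error reading.
#'
#' @param profiles Per-gene profiles from [gc_profiles()] (or a list of
#'   [gc_profile()] objects).
#' @param dispersion `"sd"` (default) or `"sem"`.
#' @return A list of class `genome_gc_summary` with `mean` and
#'   `dispersion` (named vectors over `gc1`, `gc2`, `gc3`, `gct`) and
#'   `n_genes`.
#' @export
genome_gc_summary <- function(profiles, dispersion = c("sd", "sem")) {
  dispersion <- match.arg(dispersion)
  if (is.list(profiles) && !is.data.frame(profiles))
    profiles <- data.frame(gc1 = vapply(profiles, `[[`, 0, "gc1"),
                           gc2 = vapply(profiles, `[[`, 0, "gc2"),
                           gc3 = vapply(profiles, `[[`, 0, "gc3"),
                           gct = vapply(profiles, `[[`, 0, "gct"))
  n <- nrow(profiles)
  if (n < 2L) stop("need at least 2 genes for a genome GC summary")
  pos <- c("gc1", "gc2", "gc3", "gct")
  mu <- vapply(pos, function(p) mean(profiles[[p]]), 0)
  disp <- vapply(pos, function(p) sd(profiles[[p]]), 0)
  if (dispersion == "sem") disp <- disp / sqrt(n)
  structure(list(mean = mu, dispersion = disp, n_genes = n,
                 dispersion_type = dispersion),
            class = "genome_gc_summary")
}

#' Flag a gene whose GC content deviates from its genome
#'
#' A gene is flagged when its total GC deviates by two or more dispersion
#' units from the genome mean, or when the deviations at the first and
#' third codon positions have the same sign and at least one of them is
#' two or more dispersion units (same-sign clause).
#'
#' @param gene A [gc_profile()].
#' @param genome A [genome_gc_summary()].
#' @param threshold Deviation threshold in dispersion units (default 2).
#' @return A list with `flag`, the two clause truth values
#'   (`clause_total`, `clause_13`), and `deviations` (named vector of
#'   per-position deviations in dispersion units; NA where the genome
#'   dispersion is zero).
#' @export
gc_deviation_flag <- function(gene, genome, threshold = 2) {
  pos <- c("gc1", "gc2", "gc3", "gct")
  val <- vapply(pos, function(p) gene[[p]], 0)
  disp <- genome$dispersion[pos]
  dev <- (val - genome$mean[pos]) / disp
  zero <- !is.finite(dev)
  if (any(zero[c("gc1", "gc3", "gct")]))
    warning("zero genome dispersion at position(s): ",
            paste(pos[zero], collapse = ", "), "; position skipped")
  dev[zero] <- NA_real_
  clause_total <- isTRUE(abs(dev["gct"]) >= threshold)
  clause_13 <- isTRUE(sign(dev["gc1"]) == sign(dev["gc3"]) &&
                        max(abs(dev[c("gc1", "gc3")])) >= threshold)
  list(flag = clause_total || clause_13,
       clause_total = clause_total, clause_13 = clause_13,
       deviations = dev)
}
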