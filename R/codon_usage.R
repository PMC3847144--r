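## Relative synonymous codon usage (RSCU), the gene-vs-genome chi-square
## comparison on 41 degrees of freedom, and the codon adaptation index
## computed as CAIobs/CAImax against the whole-genome reference RSCU.

#' Codon occurrence counts
#'
#' Counts over the 64 codons for one sequence or a whole set; codons
#' containing ambiguous bases are excluded.
#'
#' @param x A nucleotide sequence string or a [cds_set()].
#' @return Named integer vector of length 64.
#' @export
codon_counts <- function(x) {
  seqs <- if (is.data.frame(x)) x$nt_seq else x
  all_cod <- countable_codons(unlist(lapply(seqs, split_codons),
                                     use.names = FALSE))
  out <- setNames(integer(64), codon_table()$codon)
  tb <- table(all_cod)
  out[names(tb)] <- as.integer(tb)
  out
}

#' Relative synonymous codon usage
#'
#' For synonymous codon i of an n-fold degenerate amino acid,
#' `RSCU_i = X_i / ((1/n) * sum_j X_j)`: the observed count normalized by
#' the count expected under equal usage of the amino acid's synonymous
#' codons.  Start (ATG), stop and Trp (TGG) codons are excluded.  Codons
#' of amino acids absent from the counts have RSCU recorded as NA.
#'
#' @param counts Named codon counts ([codon_counts()]), or an object
#'   accepted by it.
#' @return A list of class `rscu_table` with `rscu` (59 values, named by
#'   codon), `codon_counts` (the 59 counts used) and `aa_counts`.
#' @export
rscu <- function(counts) {
  if (!is.numeric(counts)) counts <- codon_counts(counts)
  syn <- synonymous_codons()
  x <- counts[syn]
  names(x) <- syn
  aa <- names(syn)
  aa_tot <- tapply(x, aa, sum)
  n_syn <- tapply(x, aa, length)
  vals <- setNames(rep(NA_real_, length(syn)), syn)
  present <- aa_tot[aa] > 0
  vals[present] <- n_syn[aa][present] * x[present] / aa_tot[aa][present]
  structure(list(rscu = vals, codon_counts = x,
                 aa_counts = setNames(as.integer(aa_tot), names(aa_tot))),
            class = "rscu_table")
}

#' Chi-square comparison of a gene's codon usage against the genome
#'
#' Expected gene codon counts are the gene's per-amino-acid totals
#' apportioned by the genome reference's within-amino-acid codon
#' proportions; the statistic is `sum((obs - exp)^2 / exp)` over codons
#' with positive expectation.  The reported degrees of freedom are fixed
#' at 41 (59 synonymous sense codons minus 18 degenerate amino acids);
#' the effective count of contributing cells minus amino acids is also
#' returned for transparency.
#'
#' @param gene_counts Codon counts for the gene ([codon_counts()]).
#' @param genome_reference An [rscu()] table built from genome-wide counts.
#' @return A list with `chi2`, `df` (always [rscu_df()]), `effective_df`
#'   and `p`.
#' @export
rscu_chi2_test <- function(gene_counts, genome_reference) {
  if (!is.numeric(gene_counts)) gene_counts <- codon_counts(gene_counts)
  syn <- synonymous_codons()
  obs <- gene_counts[syn]
  names(obs) <- syn
  if (sum(obs) == 0) stop("gene has no countable synonymous codons")
  aa <- names(syn)
  ref <- genome_reference$codon_counts[syn]
  ref_aa_tot <- tapply(ref, aa, sum)
  prop <- ifelse(ref_aa_tot[aa] > 0, ref / ref_aa_tot[aa], 0)
  gene_aa_tot <- tapply(obs, aa, sum)
  expc <- gene_aa_tot[aa] * prop
  use <- expc > 0
  chi2 <- sum((obs[use] - expc[use])^2 / expc[use])
  eff_df <- sum(use) - length(unique(aa[use]))
  df <- rscu_df()
  list(chi2 = chi2, df = df, effective_df = eff_df,
       p = pchisq(chi2, df = df, lower.tail = FALSE))
}

#' Codon adaptation index of a gene against a genome reference
#'
#' `CAI = CAIobs / CAImax`, where `CAIobs` is the mean of the reference
#' RSCU values over all counted codon occurrences of the gene and
#' `CAImax` is the mean, over the same occurrences, of the maximum
#' reference RSCU among each amino acid's synonymous codons.  A gene that
#' only uses each amino acid's most frequent reference codon therefore
#' scores exactly 1.  Occurrences of amino acids absent from the genome
#' reference are skipped with a warning.
#'
#' @param gene_counts Codon counts for the gene ([codon_counts()]).
#' @param genome_reference An [rscu()] table built from genome-wide counts.
#' @param max_weighting `"gene"` (default): CAImax averaged over the
#'   gene's own occurrences; `"reference"`: unweighted mean of the
#'   per-amino-acid maxima (genome-level alternative).
#' @return A list of class `cai_result` with `cai`, `cai_obs`, `cai_max`
#'   and `skipped_occurrences`.
#' @export
cai <- function(gene_counts, genome_reference,
                max_weighting = c("gene", "reference")) {
  max_weighting <- match.arg(max_weighting)
  if (!is.numeric(gene_counts)) gene_counts <- codon_counts(gene_counts)
  syn <- synonymous_codons()
  x <- gene_counts[syn]
  names(x) <- syn
  aa <- names(syn)
  ref_rscu <- genome_reference$rscu[syn]
  aa_max <- tapply(ref_rscu, aa, function(v)
    if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE))
  usable <- x > 0 & !is.na(aa_max[aa])
  skipped <- sum(x[x > 0 & is.na(aa_max[aa])])
  if (skipped > 0)
    warning(skipped, " codon occurrence(s) of amino acids absent from ",
            "the genome reference were skipped")
  n_occ <- sum(x[usable])
  if (n_occ == 0) stop("gene has no codon occurrences covered by reference")
  rr <- ref_rscu
  rr[is.na(rr)] <- 0       # codon unseen genome-wide but aa present
  cai_obs <- sum(x[usable] * rr[usable]) / n_occ
  cai_max <- if (max_weighting == "gene")
    sum(x[usable] * aa_max[aa][usable]) / n_occ
  else mean(aa_max, na.rm = TRUE)
  structure(list(cai = cai_obs / cai_max, cai_obs = cai_obs,
                 cai_max = cai_max, skipped_occurrences = skipped),
            class = "cai_result")
}

#' Genome reference RSCU table
#'
#' @param cds A [cds_set()].
#' @param pooling `"pooled"` (default): codon counts summed over all
#'   genes before RSCU; `"mean"`: per-gene RSCU values averaged (counts
#'   stored are still the pooled counts, used for chi-square proportions).
#' @return An [rscu()] table.
#' @export
genome_rscu <- function(cds, pooling = c("pooled", "mean")) {
  pooling <- match.arg(pooling)
  pooled <- rscu(codon_counts(cds))
  if (pooling == "mean") {
    per_gene <- vapply(cds$nt_seq,
                       function(s) rscu(codon_counts(s))$rscu,
                       numeric(length(pooled$rscu)))
    pooled$rscu <- rowMeans(per_gene, na.rm = TRUE)
    pooled$rscu[is.nan(pooled$rscu)] <- NA_real_
  }
  pooled
}

#' Genome-wide CAI distribution
#'
#' Per-gene CAI values against the genome reference, with their mean and
#' dispersion (per-gene standard deviation by default).
#'
#' @param cds A [cds_set()].
#' @param genome_reference An [rscu()] table; computed from `cds` when
#'   omitted.
#' @param dispersion `"sd"` (default) or `"sem"`.
#' @return A list with `cai` (named per-gene vector), `mean`,
#'   `dispersion`.
#' @export
genome_cai_summary <- function(cds, genome_reference = NULL,
                               dispersion = c("sd", "sem")) {
  dispersion <- match.arg(dispersion)
  if (is.null(genome_reference)) genome_reference <- genome_rscu(cds)
  vals <- vapply(cds$nt_seq,
                 function(s) cai(codon_counts(s), genome_reference)$cai, 0,
                 USE.NAMES = FALSE)
  names(vals) <- cds$gene_id
  disp <- sd(vals)
  if (dispersion == "sem") disp <- disp / sqrt(length(vals))
  list(cai = vals, mean = mean(vals), dispersion = disp,
       dispersion_type = dispersion)
}

#' Flag a gene whose CAI deviates from the genome average
#'
#' Flag is TRUE when `|gene_cai - genome_mean| > threshold * dispersion`
#' (default threshold 1.5 dispersion units).
#'
#' @param gene_cai The gene's CAI.
#' @param genome_cai_mean,genome_cai_dispersion Genome CAI mean and
#'   dispersion ([genome_cai_summary()]).
#' @param threshold Multiplier on the dispersion (default 1.5).
#' @return A list with `flag` and `deviation` (in dispersion units).
#' @export
cai_deviation_flag <- function(gene_cai, genome_cai_mean,
                               genome_cai_dispersion, threshold = 1.5) {
  if (genome_cai_dispersion <= 0) stop("zero genome CAI dispersion")
  dev <- (gene_cai - genome_cai_mean) / genome_cai_dispersion
  list(flag = abs(dev) > threshold, deviation = dev)
}
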