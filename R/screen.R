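## Per-gene aggregation of the four compositional evidence lines (GC
## deviation, dinucleotide-signature covariation, codon-usage chi-square,
## CAI deviation) into an HGT-signature report for a genome.

#' Screening configuration
#'
#' All thresholds of the compositional screen in one place.
#'
#' @param gc_threshold GC deviation threshold in dispersion units
#'   (default 2).
#' @param cai_threshold CAI deviation threshold in dispersion units
#'   (default 1.5).
#' @param alpha Significance level for the chi-square and covariation
#'   tests (default 0.05).
#' @param gc_dispersion,cai_dispersion `"sd"` (per-gene standard
#'   deviation, default) or `"sem"`.
#' @param rscu_pooling Genome reference RSCU pooling, `"pooled"` or
#'   `"mean"`.
#' @param cai_max_weighting `"gene"` or `"reference"`; see [cai()].
#' @param min_genes Minimum genome size for aggregate building
#'   (default 50).
#' @param leave_one_out If TRUE, each gene's junctions are removed from
#'   the genome dinucleotide profile before comparison (negligible for
#'   genomes of thousands of genes; off by default).
#' @return A list of class `screen_config`.
#' @export
screen_config <- function(gc_threshold = 2, cai_threshold = 1.5,
                          alpha = 0.05,
                          gc_dispersion = c("sd", "sem"),
                          cai_dispersion = c("sd", "sem"),
                          rscu_pooling = c("pooled", "mean"),
                          cai_max_weighting = c("gene", "reference"),
                          min_genes = 50, leave_one_out = FALSE) {
  structure(list(gc_threshold = gc_threshold,
                 cai_threshold = cai_threshold,
                 alpha = alpha,
                 gc_dispersion = match.arg(gc_dispersion),
                 cai_dispersion = match.arg(cai_dispersion),
                 rscu_pooling = match.arg(rscu_pooling),
                 cai_max_weighting = match.arg(cai_max_weighting),
                 min_genes = min_genes,
                 leave_one_out = isTRUE(leave_one_out)),
            class = "screen_config")
}

#' Genome-wide aggregates for the compositional screen
#'
#' Builds, once per genome, everything the per-gene tests compare
#' against: the GC summary, the pooled 3:1 dinucleotide signature, the
#' reference RSCU table and the genome CAI distribution.
#'
#' @param cds A [cds_set()].
#' @param config A [screen_config()].
#' @return A list of class `genome_aggregates`.
#' @export
genome_aggregates <- function(cds, config = screen_config()) {
  if (nrow(cds) < config$min_genes)
    stop("genome has ", nrow(cds), " genes; at least ", config$min_genes,
         " required for stable aggregates")
  profiles <- gc_profiles(cds)
  gc_sum <- genome_gc_summary(profiles, dispersion = config$gc_dispersion)
  dinuc <- dinuc31_profile(cds)
  rscu_ref <- genome_rscu(cds, pooling = config$rscu_pooling)
  cai_sum <- genome_cai_summary(cds, rscu_ref,
                                dispersion = config$cai_dispersion)
  structure(list(genome_id = attr(cds, "genome_id"),
                 n_genes = nrow(cds), gc = gc_sum, dinuc = dinuc,
                 rscu_ref = rscu_ref, cai = cai_sum, config = config),
            class = "genome_aggregates")
}

## genome dinucleotide profile with one gene's junction/positional counts
## removed (leave-one-out comparison)
dinuc_profile_without <- function(cds, gene_id) {
  dinuc31_profile(cds[cds$gene_id != gene_id, , drop = FALSE])
}

#' Screen one gene for HGT signatures
#'
#' Runs the four evidence lines against precomputed genome aggregates and
#' returns a one-row report.  The covariation evidence line is TRUE when
#' the Spearman correlation between the gene's and the genome's 3:1
#' signature is negative or not significant at `alpha` (significant
#' positive covariation argues against transfer).  A stage that fails is
#' recorded as NA and never counted as evidence.  The verdict maps the
#' evidence count 0 / 1-2 / 3-4 to
#' no_signature / weak_signature / strong_signature.
#'
#' @param gene One row of a [cds_set()] (or a list with `gene_id` and
#'   `nt_seq`).
#' @param aggregates A [genome_aggregates()] object.
#' @param cds The full [cds_set()]; only needed when the configuration
#'   requests leave-one-out dinucleotide comparison.
#' @return A one-row data.frame (an HGT report).
#' @export
screen_gene <- function(gene, aggregates, cds = NULL) {
  cfg <- aggregates$config
  gid <- gene$gene_id[1]
  res <- list(gene_id = gid,
              gc1_dev = NA_real_, gc3_dev = NA_real_, gct_dev = NA_real_,
              gc_flag = NA, sigma = NA_real_,
              spearman_rho = NA_real_, spearman_p = NA_real_,
              kendall_tau = NA_real_, kendall_p = NA_real_,
              covariation_flag = NA,
              chi2 = NA_real_, chi2_p = NA_real_, chi2_flag = NA,
              cai = NA_real_, cai_dev = NA_real_, cai_flag = NA)
  gp <- tryCatch(gc_profile(gene$nt_seq[1]), error = function(e) NULL)
  if (!is.null(gp)) {
    gf <- tryCatch(gc_deviation_flag(gp, aggregates$gc,
                                     threshold = cfg$gc_threshold),
                   error = function(e) NULL, warning = function(w) NULL)
    if (!is.null(gf)) {
      res$gc1_dev <- unname(gf$deviations["gc1"])
      res$gc3_dev <- unname(gf$deviations["gc3"])
      res$gct_dev <- unname(gf$deviations["gct"])
      res$gc_flag <- gf$flag
    }
  }
  gene_dinuc <- tryCatch(dinuc31_profile(gene$nt_seq[1]),
                         error = function(e) NULL)
  if (!is.null(gene_dinuc)) {
    genome_dinuc <- if (cfg$leave_one_out && !is.null(cds))
      dinuc_profile_without(cds, gid) else aggregates$dinuc
    s <- tryCatch(sigma_difference(gene_dinuc, genome_dinuc),
                  warning = function(w) NA_real_)
    res$sigma <- s
    rc <- tryCatch(rank_covariation(gene_dinuc, genome_dinuc),
                   warning = function(w) NULL)
    if (!is.null(rc) && !is.na(rc$spearman_rho)) {
      res$spearman_rho <- rc$spearman_rho
      res$spearman_p <- rc$spearman_p
      res$kendall_tau <- rc$kendall_tau
      res$kendall_p <- rc$kendall_p
      res$covariation_flag <- rc$spearman_rho < 0 || rc$spearman_p > cfg$alpha
    }
  }
  counts <- codon_counts(gene$nt_seq[1])
  ch <- tryCatch(rscu_chi2_test(counts, aggregates$rscu_ref),
                 error = function(e) NULL)
  if (!is.null(ch)) {
    res$chi2 <- ch$chi2
    res$chi2_p <- ch$p
    res$chi2_flag <- ch$p < cfg$alpha
  }
  cr <- tryCatch(suppressWarnings(
    cai(counts, aggregates$rscu_ref,
        max_weighting = cfg$cai_max_weighting)), error = function(e) NULL)
  if (!is.null(cr)) {
    cf <- tryCatch(cai_deviation_flag(cr$cai, aggregates$cai$mean,
                                      aggregates$cai$dispersion,
                                      threshold = cfg$cai_threshold),
                   error = function(e) NULL)
    res$cai <- cr$cai
    if (!is.null(cf)) {
      res$cai_dev <- cf$deviation
      res$cai_flag <- cf$flag
    }
  }
  flags <- c(res$gc_flag, res$covariation_flag, res$chi2_flag, res$cai_flag)
  res$evidence_count <- sum(flags, na.rm = TRUE)
  res$verdict <- if (res$evidence_count == 0) "no_signature"
                 else if (res$evidence_count <= 2) "weak_signature"
                 else "strong_signature"
  as.data.frame(res, stringsAsFactors = FALSE)
}

#' Screen a genome (or a target subset) for HGT signatures
#'
#' Computes the genome aggregates once, then the full evidence battery
#' for every target gene.  Output ordering follows the input gene order
#' restricted to targets, so identical inputs give identical reports.
#'
#' @param cds A [cds_set()].
#' @param targets Optional character vector of gene ids to screen
#'   (default: all genes).
#' @param config A [screen_config()].
#' @return A list of class `hgt_screen` with `reports` (data.frame, one
#'   row per target) and `aggregates`.
#' @export
screen_genome <- function(cds, targets = NULL, config = screen_config()) {
  agg <- genome_aggregates(cds, config)
  if (is.null(targets)) targets <- cds$gene_id
  unknown <- setdiff(targets, cds$gene_id)
  if (length(unknown) > 0)
    stop("unknown target gene id(s): ", paste(unknown, collapse = ", "))
  idx <- which(cds$gene_id %in% targets)
  reports <- do.call(rbind, lapply(idx, function(i)
    screen_gene(cds[i, , drop = FALSE], agg, cds = cds)))
  if (is.null(reports))
    reports <- screen_gene(cds[1, , drop = FALSE], agg)[0, , drop = FALSE]
  rownames(reports) <- NULL
  structure(list(reports = reports, aggregates = agg),
            class = "hgt_screen")
}

#' @export
print.hgt_screen <- function(x, ...) {
  cat("<hgt_screen> genome ", x$aggregates$genome_id, ": ",
      nrow(x$reports), " genes screened of ", x$aggregates$n_genes,
      "\n", sep = "")
  tb <- table(factor(x$reports$verdict,
                     levels = c("no_signature", "weak_signature",
                                "strong_signature")))
  print(tb)
  invisible(x)
}
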