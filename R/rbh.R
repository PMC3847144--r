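## Reciprocal-best-hit ortholog detection from all-against-all protein
## similarity searches, with the fixed cutoffs used throughout the
## screen: E-value <= 1e-5, bit score >= 50, and (when sequence lengths
## are available) a mutual full-length coverage requirement.

#' Filter similarity hits by E-value, bit score and coverage
#'
#' Retains hits with `evalue <= evalue_max`, `bitscore >= bitscore_min`
#' and, when query/subject lengths are present in the table, mutual
#' coverage `alignment_length / length >= min_coverage` on both sides
#' (the full-length-sequence criterion).
#'
#' @param hits A `similarity_hits` data.frame ([read_similarity_table()]).
#' @param evalue_max Maximum E-value (default 1e-5).
#' @param bitscore_min Minimum bit score (default 50).
#' @param min_coverage Minimum mutual coverage fraction (default 0.8);
#'   ignored when the table has no length columns.
#' @return The filtered `similarity_hits` data.frame.
#' @export
filter_hits <- function(hits, evalue_max = 1e-5, bitscore_min = 50,
                        min_coverage = 0.8) {
  keep <- hits$evalue <= evalue_max & hits$bitscore >= bitscore_min
  if (all(c("query_length", "subject_length") %in% names(hits)) &&
      nrow(hits) > 0) {
    cov_q <- hits$alignment_length / hits$query_length
    cov_s <- hits$alignment_length / hits$subject_length
    keep <- keep & cov_q >= min_coverage & cov_s >= min_coverage
  }
  out <- hits[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

## best surviving hit per query: max bitscore, ties broken by lowest
## evalue then lexicographically smallest subject id; multiple hits of the
## same query-subject pair collapse to the max-bitscore one first
best_hits <- function(hits) {
  if (nrow(hits) == 0L)
    return(data.frame(query_id = character(0), subject_id = character(0),
                      bitscore = numeric(0)))
  o <- order(hits$query_id, hits$subject_id, -hits$bitscore, hits$evalue)
  h <- hits[o, , drop = FALSE]
  h <- h[!duplicated(h[c("query_id", "subject_id")]), , drop = FALSE]
  o <- order(h$query_id, -h$bitscore, h$evalue, h$subject_id)
  h <- h[o, , drop = FALSE]
  h <- h[!duplicated(h$query_id), , drop = FALSE]
  h[c("query_id", "subject_id", "bitscore")]
}

#' Reciprocal best hits between two genomes
#'
#' Orthology is assumed only when two genes in different genomes are each
#' other's best (maximum bit score) surviving hit.  Both hit lists should
#' already be filtered with [filter_hits()].  Ties are broken by highest
#' bit score, then lowest E-value, then lexicographically smallest
#' subject id, so the output is deterministic.
#'
#' @param hits_ab Filtered hits with genome A genes as queries.
#' @param hits_ba Filtered hits with genome B genes as queries.
#' @param genome_a,genome_b Genome labels for the output.
#' @return A data.frame of class `rbh_pairs` with columns `genome_a`,
#'   `gene_a`, `genome_b`, `gene_b`, `forward_bitscore`,
#'   `reverse_bitscore`, sorted by (`genome_a`, `gene_a`).
#' @export
reciprocal_best_hits <- function(hits_ab, hits_ba,
                                 genome_a = "A", genome_b = "B") {
  fwd <- best_hits(hits_ab)
  rev <- best_hits(hits_ba)
  m <- merge(fwd, rev, by.x = c("query_id", "subject_id"),
             by.y = c("subject_id", "query_id"),
             suffixes = c("_fwd", "_rev"))
  out <- data.frame(genome_a = rep(genome_a, nrow(m)), gene_a = m$query_id,
                    genome_b = rep(genome_b, nrow(m)), gene_b = m$subject_id,
                    forward_bitscore = m$bitscore_fwd,
                    reverse_bitscore = m$bitscore_rev,
                    stringsAsFactors = FALSE)
  out <- out[order(out$genome_a, out$gene_a), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("rbh_pairs", "data.frame")
  out
}
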