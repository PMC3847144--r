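## Readers and validators for the external inputs: nucleotide CDS FASTA,
## BLAST tabular similarity hits, strain trait tables, and the aligned
## protein set + rooted tree + two-cluster assignment used for functional
## divergence.

#' Construct a set of coding sequences
#'
#' A `cds_set` is a data.frame with one row per in-frame coding sequence
#' (columns `gene_id`, `nt_seq`, `codon_count`) and a `genome_id`
#' attribute.  Sequences are uppercased and U is mapped to T.
#'
#' @param gene_id Character vector of unique gene identifiers.
#' @param nt_seq Character vector of nucleotide sequences over
#'   `{A,C,G,T,N}`; each length must be a positive multiple of 3.
#' @param genome_id Single genome identifier.
#' @return An object of class `cds_set`.
#' @export
cds_set <- function(gene_id, nt_seq, genome_id) {
  stopifnot(length(gene_id) == length(nt_seq), length(genome_id) == 1L)
  nt_seq <- chartr("u", "t", toupper(as.character(nt_seq)))
  nt_seq <- chartr("U", "T", nt_seq)
  if (anyDuplicated(gene_id))
    stop("duplicated gene_id within genome: ",
         paste(unique(gene_id[duplicated(gene_id)]), collapse = ", "))
  n <- nchar(nt_seq)
  bad_len <- n == 0L | n %% 3L != 0L
  if (any(bad_len))
    stop("sequence length not a positive multiple of 3 for: ",
         paste(gene_id[bad_len], collapse = ", "))
  bad_chr <- grepl("[^ACGTN]", nt_seq)
  if (any(bad_chr))
    stop("characters outside {A,C,G,T,N} in: ",
         paste(gene_id[bad_chr], collapse = ", "))
  out <- data.frame(gene_id = as.character(gene_id), nt_seq = nt_seq,
                    codon_count = as.integer(n %/% 3L),
                    stringsAsFactors = FALSE)
  attr(out, "genome_id") <- as.character(genome_id)
  class(out) <- c("cds_set", "data.frame")
  out
}

#' @export
print.cds_set <- function(x, ...) {
  cat("<cds_set> genome ", attr(x, "genome_id"), ": ", nrow(x),
      " coding sequences, ", sum(x$codon_count), " codons\n", sep = "")
  invisible(x)
}

#' Read in-frame coding sequences from a FASTA file
#'
#' One record per gene; the record identifier (first whitespace-separated
#' token) is taken as the gene id.  In the default (lenient) mode, records
#' whose length is not a positive multiple of 3 or that contain characters
#' outside `{A,C,G,T,N}` are reported via a warning and skipped; in strict
#' mode they raise an error naming the record.  Records containing `N` are
#' accepted; codons containing any ambiguous base are excluded from all
#' downstream composition counts.  Internal stop codons trigger a warning
#' but the sequence is retained.
#'
#' @param path Path to a nucleotide FASTA file.
#' @param genome_id Genome identifier attached to the returned set.
#' @param strict Error (TRUE) or warn-and-skip (FALSE) on invalid records.
#' @return A [cds_set()].
#' @export
read_fasta_cds <- function(path, genome_id, strict = FALSE) {
  if (!file.exists(path)) stop("cannot read FASTA file: ", path)
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) == 0L) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(seqs))
  nt <- toupper(trimws(as.character(seqs)))
  nt <- chartr("U", "T", nt)
  bad_len <- nchar(nt) == 0L | nchar(nt) %% 3L != 0L
  bad_chr <- grepl("[^ACGTN]", nt)
  bad <- bad_len | bad_chr
  if (any(bad)) {
    msg <- paste0(ids[bad], " (",
                  ifelse(bad_len[bad], "length not a multiple of 3",
                         "invalid characters"), ")", collapse = "; ")
    if (strict) stop("invalid CDS record(s): ", msg)
    warning("skipping invalid CDS record(s): ", msg)
    ids <- ids[!bad]; nt <- nt[!bad]
    if (length(nt) == 0L) stop("no valid CDS records in ", path)
  }
  out <- cds_set(ids, nt, genome_id)
  stops <- c("TAA", "TAG", "TGA")
  has_internal_stop <- vapply(out$nt_seq, function(s) {
    cod <- split_codons(s)
    any(cod[-length(cod)] %in% stops)
  }, logical(1), USE.NAMES = FALSE)
  if (any(has_internal_stop))
    warning("internal stop codon(s) in: ",
            paste(out$gene_id[has_internal_stop], collapse = ", "))
  out
}

#' Write a coding-sequence set to FASTA
#'
#' @param cds A [cds_set()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fasta_cds <- function(cds, path) {
  x <- Biostrings::DNAStringSet(setNames(cds$nt_seq, cds$gene_id))
  Biostrings::writeXStringSet(x, path, width = 70L)
  invisible(path)
}

BLAST12_COLS <- c("query_id", "subject_id", "percent_identity",
                  "alignment_length", "mismatches", "gap_opens",
                  "qstart", "qend", "sstart", "send", "evalue", "bitscore")

#' Read an all-against-all similarity table (BLAST tabular)
#'
#' Accepts the standard 12-column BLAST outfmt-6 dialect
#' (qseqid sseqid pident length mismatch gapopen qstart qend sstart send
#' evalue bitscore) or the 14-column dialect with trailing qlen and slen.
#' Coverage-based filters downstream are active only when the length
#' columns are present.
#'
#' @param path Path to a tab-separated hit table without header.
#' @return A data.frame of class `similarity_hits`; `query_length` /
#'   `subject_length` columns are present only for the 14-column dialect.
#' @export
read_similarity_table <- function(path) {
  if (!file.exists(path)) stop("cannot read similarity table: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  empty <- data.frame(matrix(nrow = 0, ncol = 12,
                             dimnames = list(NULL, BLAST12_COLS)))
  if (length(lines) == 0L) {
    class(empty) <- c("similarity_hits", "data.frame")
    return(empty)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (!all(nf %in% c(12L, 14L)))
    stop("line ", which(!nf %in% c(12L, 14L))[1],
         ": expected 12 or 14 tab-separated columns, found ",
         nf[!nf %in% c(12L, 14L)][1])
  if (length(unique(nf)) > 1L)
    stop("mixed 12- and 14-column lines in ", path)
  has_len <- nf[1] == 14L
  m <- do.call(rbind, fields)
  cols <- if (has_len) c(BLAST12_COLS, "query_length", "subject_length")
          else BLAST12_COLS
  out <- data.frame(m, stringsAsFactors = FALSE)
  names(out) <- cols
  num_cols <- setdiff(cols, c("query_id", "subject_id"))
  for (cc in num_cols) {
    v <- suppressWarnings(as.numeric(out[[cc]]))
    if (anyNA(v))
      stop("line ", which(is.na(v))[1], ": non-numeric value '",
           out[[cc]][is.na(v)][1], "' in column ", cc)
    out[[cc]] <- v
  }
  int_cols <- intersect(c("alignment_length", "mismatches", "gap_opens",
                          "qstart", "qend", "sstart", "send",
                          "query_length", "subject_length"), cols)
  for (cc in int_cols) out[[cc]] <- as.integer(out[[cc]])
  if (any(out$evalue < 0)) stop("negative E-value in ", path)
  if (any(out$bitscore < 0)) stop("negative bit score in ", path)
  class(out) <- c("similarity_hits", "data.frame")
  out
}

#' Read a strain-by-trait table
#'
#' TSV with a header row, one row per strain.  Empty cells and the string
#' `"ND"` are treated as missing.  Columns whose non-missing values all
#' parse as numbers become quantitative traits; all other columns are
#' categorical.  The membership column is parsed as a logical flag
#' (TRUE/FALSE, 1/0, yes/no).
#'
#' @param path Path to the TSV file.
#' @param strain_col Name of the strain-identifier column.
#' @param membership_col Name of the in-family membership column.
#' @return A data.frame of class `strain_traits` with attributes
#'   `strain_col` and `membership_col`.
#' @export
read_trait_table <- function(path, strain_col = "strain_id",
                             membership_col = "in_family") {
  if (!file.exists(path)) stop("cannot read trait table: ", path)
  raw <- read.delim(path, header = TRUE, sep = "\t",
                    colClasses = "character", na.strings = c("", "ND", "NA"),
                    check.names = FALSE)
  if (!strain_col %in% names(raw))
    stop("missing strain column '", strain_col, "'")
  if (!membership_col %in% names(raw))
    stop("missing membership column '", membership_col, "'")
  if (anyDuplicated(raw[[strain_col]]))
    stop("duplicate strain id(s): ",
         paste(unique(raw[[strain_col]][duplicated(raw[[strain_col]])]),
               collapse = ", "))
  memb_raw <- tolower(trimws(raw[[membership_col]]))
  memb <- memb_raw %in% c("true", "1", "yes", "t")
  if (any(!memb_raw %in% c("true", "1", "yes", "t",
                           "false", "0", "no", "f")))
    stop("membership column must be logical-like (TRUE/FALSE, 1/0, yes/no)")
  out <- raw
  out[[membership_col]] <- memb
  for (cc in setdiff(names(out), c(strain_col, membership_col))) {
    v <- out[[cc]]
    num <- suppressWarnings(as.numeric(v))
    if (!anyNA(num[!is.na(v)])) out[[cc]] <- num
  }
  attr(out, "strain_col") <- strain_col
  attr(out, "membership_col") <- membership_col
  class(out) <- c("strain_traits", "data.frame")
  out
}

#' Write a strain-by-trait table to TSV
#'
#' @param traits A `strain_traits` table.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trait_table <- function(traits, path) {
  out <- as.data.frame(traits)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  invisible(path)
}

#' Bundle a protein alignment, rooted tree and two-cluster assignment
#'
#' The container consumed by the functional-divergence stage: aligned
#' protein sequences of equal length, a rooted tree whose tips match the
#' sequence names, and an assignment of every tip to cluster 1 or 2.
#' Each cluster must be monophyletic in the rooted tree.
#'
#' @param aln Named character vector of aligned (gapped) protein
#'   sequences, all the same length.
#' @param tree A rooted `phylo` tree with tip labels matching `names(aln)`.
#' @param cluster1,cluster2 Character vectors of tip names in each cluster.
#' @return An object of class `clustered_alignment` with elements `aln`
#'   (site-by-taxon character matrix), `tree`, `clusters` (named 1/2
#'   vector) and `n_sites`.
#' @export
clustered_alignment <- function(aln, tree, cluster1, cluster2) {
  aln <- setNames(toupper(as.character(aln)), names(aln))
  if (is.null(names(aln)) || anyDuplicated(names(aln)))
    stop("alignment sequences must have unique names")
  if (length(unique(nchar(aln))) != 1L)
    stop("aligned sequences must all have the same length")
  L <- unname(nchar(aln[1]))
  if (L == 0L) stop("alignment has zero sites")
  if (!inherits(tree, "phylo")) stop("tree must be an ape 'phylo' object")
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  if (!setequal(tree$tip.label, names(aln)))
    stop("tree tips and alignment names do not match")
  members <- c(cluster1, cluster2)
  if (anyDuplicated(members)) stop("clusters overlap")
  if (!all(members %in% names(aln)))
    stop("cluster member(s) not in alignment: ",
         paste(setdiff(members, names(aln)), collapse = ", "))
  for (cl in list(cluster1, cluster2)) {
    if (length(cl) == 0L) stop("each cluster needs at least one leaf")
    if (length(cl) > 1L && length(cl) < length(tree$tip.label) &&
        !ape::is.monophyletic(tree, cl))
      stop("cluster is not monophyletic in the supplied tree: ",
           paste(head(cl, 3), collapse = ", "), " ...")
  }
  m <- do.call(cbind, strsplit(aln, "", fixed = TRUE))
  colnames(m) <- names(aln)
  clusters <- setNames(c(rep(1L, length(cluster1)), rep(2L, length(cluster2))),
                       members)
  structure(list(aln = m, tree = tree, clusters = clusters, n_sites = L),
            class = "clustered_alignment")
}

#' Read the functional-divergence inputs from files
#'
#' @param aln_path FASTA file of aligned protein sequences.
#' @param tree_path Newick file with a rooted tree.
#' @param cluster1,cluster2 Character vectors of leaf names (or paths to
#'   one-id-per-line text files).
#' @return A [clustered_alignment()].
#' @export
read_clustered_alignment <- function(aln_path, tree_path, cluster1, cluster2) {
  seqs <- Biostrings::readAAStringSet(aln_path)
  aln <- setNames(as.character(seqs), sub("\\s.*$", "", names(seqs)))
  tree <- ape::read.tree(tree_path)
  read_ids <- function(x) {
    if (length(x) == 1L && file.exists(x)) {
      v <- readLines(x)
      trimws(v[nzchar(trimws(v))])
    } else x
  }
  clustered_alignment(aln, tree, read_ids(cluster1), read_ids(cluster2))
}
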