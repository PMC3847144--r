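## Standard genetic code tables shared by the codon-usage, CAI and
## synthetic-genome machinery.  Start (ATG), stop and Trp (TGG) codons are
## excluded from all synonymous-usage statistics, leaving 59 sense codons
## distributed over 18 degenerate amino acids.

#' The standard genetic code as a codon table
#'
#' @return A data.frame with columns `codon` (64 DNA codons) and `aa`
#'   (one-letter amino acid, `*` for stop).
#' @export
codon_table <- function() {
  gc <- Biostrings::GENETIC_CODE
  data.frame(codon = names(gc), aa = unname(gc), stringsAsFactors = FALSE)
}

#' Codons entering synonymous codon usage statistics
#'
#' The 59 sense codons left after removing the three stop codons and the
#' two non-degenerate codons ATG (Met) and TGG (Trp).
#'
#' @return Character vector of 59 codons, named by amino acid.
#' @export
synonymous_codons <- function() {
  ct <- codon_table()
  keep <- ct$aa != "*" & !ct$codon %in% c("ATG", "TGG")
  setNames(ct$codon[keep], ct$aa[keep])
}

#' Amino acids with more than one synonymous codon
#'
#' @return Character vector of the 18 degenerate amino acids.
#' @export
degenerate_amino_acids <- function() {
  syn <- synonymous_codons()
  sort(unique(names(syn)))
}

#' Degrees of freedom of the genome-vs-gene RSCU comparison
#'
#' Computed from the genetic-code table at run time as the number of
#' synonymous sense codons minus the number of degenerate amino acids
#' (59 - 18 = 41).
#'
#' @return Integer scalar.
#' @export
rscu_df <- function() {
  length(synonymous_codons()) - length(degenerate_amino_acids())
}

## split an in-frame sequence into codons
split_codons <- function(nt_seq) {
  n <- nchar(nt_seq)
  if (n == 0L) return(character(0))
  substring(nt_seq, seq(1L, n, 3L), seq(3L, n, 3L))
}

## codons made only of unambiguous bases; everything else (N etc.) is
## excluded from composition counts
countable_codons <- function(codons) {
  codons[grepl("^[ACGT]{3}$", codons)]
}
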