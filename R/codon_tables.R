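#' NCBI codon translation tables
#'
#' Builds a codon table from an NCBI genetic-code identifier.  The codon map
#' and start codons are taken from [Biostrings::getGeneticCode()], so any
#' table Biostrings knows (standard = 1, vertebrate mitochondrial = 2,
#' ciliate = 6, ...) is available.  Stop codons are represented as `"*"`.
#'
#' @param table_id Integer NCBI translation-table number (default 1).
#' @return An object of class `codon_table` with fields `table_id`,
#'   `codon_to_aa` (named character vector over all 64 codons) and
#'   `start_codons`.
#' @examples
#' ct <- codon_table(1)
#' ct$codon_to_aa[["ATG"]]   # "M"
#' ct$start_codons           # includes "ATG"
#' @export
codon_table <- function(table_id = 1L) {
  gc <- tryCatch(
    Biostrings::getGeneticCode(as.character(table_id), full.search = TRUE),
    error = function(e) af_validation_error(
      sprintf("unknown codon translation table '%s'", table_id))
  )
  codon_to_aa <- as.character(gc)
  names(codon_to_aa) <- names(gc)
  alt <- attr(gc, "alt_init_codons")
  start_codons <- unique(c("ATG", alt))
  start_codons <- start_codons[codon_to_aa[start_codons] != "*"]
  stopifnot(length(codon_to_aa) == 64L, any(codon_to_aa == "*"))
  structure(
    list(table_id = as.integer(table_id),
         codon_to_aa = codon_to_aa,
         start_codons = start_codons),
    class = "codon_table"
  )
}

is_stop_codon <- function(codon, table) {
  aa <- unname(table$codon_to_aa[codon])
  !is.na(aa) & aa == "*"
}

is_start_codon <- function(codon, table) {
  codon %in% table$start_codons
}

# Single-codon lookup; codons containing characters outside A/C/G/T
# (including N) translate to "X" and never match start or stop codons.
codon_aa <- function(codons, table) {
  aa <- unname(table$codon_to_aa[codons])
  aa[is.na(aa)] <- "X"
  aa
}
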