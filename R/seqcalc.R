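# Sequence computations triggered by the editor: longest-ORF finding,
# translation, splice-junction scanning and non-canonical splice flagging.

split_codons <- function(s) {
  n <- nchar(s) %/% 3L
  if (n == 0L) return(character(0))
  substring(s, seq.int(1L, by = 3L, length.out = n),
            seq.int(3L, by = 3L, length.out = n))
}

#' Find the longest open reading frame in a spliced mRNA
#'
#' Scans all three frames of the given strand for (start codon, first
#' in-frame stop) pairs and returns the pair maximizing the nucleotide span;
#' ties break to the 5'-most start.  With `allow_partial`, a start codon with
#' no downstream in-frame stop ("open-ended" reading frame, common on
#' fragmentary assemblies) is returned instead when its stretch to the
#' transcript end is longer than the best complete ORF; such results carry
#' `partial = TRUE` and run to the end of the mRNA.
#'
#' Only the mRNA's own strand is scanned: the editing workflow fixes strand
#' before the ORF is computed.  The minimum accepted complete ORF is two
#' codons (start + stop).
#'
#' @param mrna Spliced transcript sequence (character scalar).
#' @param table A [codon_table()].
#' @param allow_partial Accept open-ended reading frames (default `TRUE`).
#' @return An `orf_result` (`start_offset`, `end_offset` — 0-based half-open
#'   offsets into `mrna`, the stop codon included when present —, `protein`,
#'   `partial`), or `NULL` when no start codon occurs.
#' @export
longest_orf <- function(mrna, table = codon_table(1L), allow_partial = TRUE) {
  if (!is.character(mrna) || length(mrna) != 1L || !nzchar(mrna))
    af_validation_error("mrna must be a non-empty string")
  L <- nchar(mrna)
  best_complete <- NULL   # list(s, e)
  best_open <- NULL       # list(s)
  for (frame in 0:2) {
    codons <- split_codons(substr(mrna, frame + 1L, L))
    if (!length(codons)) next
    starts <- which(is_start_codon(codons, table))       # codon index, 1-based
    if (!length(starts)) next
    stops <- which(is_stop_codon(codons, table))
    for (i in starts) {
      s_nt <- frame + (i - 1L) * 3L                      # 0-based nt offset
      j <- stops[stops >= i]
      if (length(j)) {
        e_nt <- frame + j[1L] * 3L                       # end incl. stop codon
        if (is.null(best_complete) ||
            (e_nt - s_nt) > (best_complete$e - best_complete$s) ||
            ((e_nt - s_nt) == (best_complete$e - best_complete$s) &&
             s_nt < best_complete$s)) {
          best_complete <- list(s = s_nt, e = e_nt)
        }
      } else {
        if (is.null(best_open) || (L - s_nt) > (L - best_open$s) ||
            ((L - s_nt) == (L - best_open$s) && s_nt < best_open$s)) {
          best_open <- list(s = s_nt)
        }
        break  # further starts in this frame are shorter open stretches
      }
    }
  }
  if (is.null(best_complete) && is.null(best_open)) return(NULL)
  use_open <- allow_partial && !is.null(best_open) &&
    (is.null(best_complete) ||
     (nchar(mrna) - best_open$s) > (best_complete$e - best_complete$s))
  if (use_open) {
    s <- best_open$s
    prot <- translate_cds(substr(mrna, s + 1L, L), table)
    structure(list(start_offset = s, end_offset = L, protein = prot,
                   partial = TRUE), class = "orf_result")
  } else if (!is.null(best_complete)) {
    s <- best_complete$s; e <- best_complete$e
    prot <- translate_cds(substr(mrna, s + 1L, e), table)
    structure(list(start_offset = s, end_offset = e, protein = prot,
                   partial = FALSE), class = "orf_result")
  } else {
    NULL
  }
}

#' Translate a coding sequence
#'
#' Successive codons are looked up in the table; a trailing incomplete codon
#' is ignored, a terminal stop is dropped from the protein, internal stops
#' render as `"*"`, and codons containing `N` translate to `"X"`.
#'
#' @param cds Nucleotide string.
#' @param table A [codon_table()].
#' @return Amino-acid string.
#' @export
translate_cds <- function(cds, table = codon_table(1L)) {
  codons <- split_codons(cds)
  if (!length(codons)) return("")
  aa <- codon_aa(codons, table)
  if (aa[length(aa)] == "*") aa <- aa[-length(aa)]
  paste(aa, collapse = "")
}

# Strand-aware dinucleotide occurrence scan.  Returns 0-based genomic start
# (leftmost base) of each occurrence; on the reverse strand an occurrence is
# a position whose reverse complement reads the pattern.
scan_dinucleotides <- function(region, start, end, strand, patterns) {
  if (end - start < 2L) return(integer(0))
  if (strand == "-") patterns <- vapply(patterns, revcomp, character(1))
  pos <- seq.int(start, end - 2L)
  di <- substring(region$residues, pos + 1L, pos + 2L)
  pos[di %in% patterns]
}

#' Scan a window for splice-junction dinucleotides
#'
#' Finds every occurrence of a configured donor or acceptor dinucleotide in
#' the window, read on the window's strand (reverse-strand occurrences are
#' positions whose reverse complement matches).  Positions are 0-based
#' genomic starts (leftmost base of the dinucleotide), sorted ascending.
#'
#' @param region A [seq_region()].
#' @param window A [location()] inside the region.
#' @param config An [organism_config()] supplying `donor_sites` and
#'   `acceptor_sites`.
#' @return `list(donors = integer, acceptors = integer)`.
#' @export
scan_splice_junctions <- function(region, window, config = organism_config()) {
  check_location_bounds(region, window$start, window$end, "scan window")
  list(
    donors = scan_dinucleotides(region, window$start, window$end,
                                window$strand, config$donor_sites),
    acceptors = scan_dinucleotides(region, window$start, window$end,
                                   window$strand, config$acceptor_sites)
  )
}

# Introns of a transcript in 5'->3' transcript order: data.frame(start, end)
# genomic half-open.  Forward: between consecutive exons ascending; reverse:
# descending.
tx_introns <- function(t) {
  ex <- t$exons
  if (nrow(ex) < 2L) return(data.frame(start = integer(0), end = integer(0)))
  introns <- data.frame(start = ex$end[-nrow(ex)], end = ex$start[-1L])
  if (t$strand == "-") introns <- introns[rev(seq_len(nrow(introns))), , drop = FALSE]
  rownames(introns) <- NULL
  introns
}

#' Flag non-canonical splice sites of a transcript
#'
#' For each intron the first two bases (donor) and last two bases (acceptor),
#' read in transcript orientation (reverse-strand introns are read on the
#' reverse complement), are compared against the configured site sets; one
#' warning is emitted per non-conforming intron.  Introns shorter than 4
#' bases are flagged on both sides.  Single-exon transcripts yield no
#' warnings.
#'
#' @param region A [seq_region()].
#' @param t A [transcript()].
#' @param config An [organism_config()].
#' @return List of `splice_warning` objects (`transcript_id`, `intron_index`
#'   0-based in transcript order, `observed_donor`, `observed_acceptor`,
#'   `side` in donor/acceptor/both).
#' @export
flag_noncanonical_splice_sites <- function(region, t,
                                           config = organism_config()) {
  introns <- tx_introns(t)
  warnings <- list()
  for (i in seq_len(nrow(introns))) {
    gs <- introns$start[i]; ge <- introns$end[i]
    left2 <- substr(region$residues, gs + 1L, min(gs + 2L, ge))
    right2 <- substr(region$residues, max(ge - 1L, gs + 1L), ge)
    if (t$strand == "+") {
      donor <- left2; acceptor <- right2
    } else {
      donor <- revcomp(right2); acceptor <- revcomp(left2)
    }
    if (ge - gs < 4L) {
      side <- "both"
    } else {
      bad_d <- !donor %in% config$donor_sites
      bad_a <- !acceptor %in% config$acceptor_sites
      if (!bad_d && !bad_a) next
      side <- if (bad_d && bad_a) "both" else if (bad_d) "donor" else "acceptor"
    }
    warnings[[length(warnings) + 1L]] <- structure(
      list(transcript_id = t$id, intron_index = i - 1L,
           observed_donor = donor, observed_acceptor = acceptor, side = side),
      class = "splice_warning"
    )
  }
  warnings
}
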