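# Domain model: sequence regions, locations, transcripts, genes, organism
# configuration, users, and the annotation project that ties them together.
# Coordinates are 0-based half-open throughout; conversion to the 1-based
# inclusive conventions of GFF3/GenBank/VCF happens only at the format
# boundary (io_formats.R).

norm_strand <- function(strand) {
  s <- switch(as.character(strand),
    "+" = "+", "-" = "-",
    "forward" = "+", "reverse" = "-",
    "1" = "+", "-1" = "-",
    NULL
  )
  if (is.null(s)) af_validation_error(sprintf("invalid strand '%s'", strand))
  s
}

#' Create a reference sequence region
#'
#' @param id Non-empty identifier, unique within a project.
#' @param residues Nucleotide string over A/C/G/T/N.  Lowercase input is
#'   uppercased with a notice (soft-masking is not modelled).
#' @return A `seq_region` with fields `id`, `length`, `residues`.
#' @export
seq_region <- function(id, residues) {
  if (!is.character(id) || length(id) != 1L || !nzchar(id))
    af_validation_error("seq_region id must be a non-empty string")
  residues <- as.character(residues)
  if (grepl("[a-z]", residues)) {
    af_notice("residues of '", id, "' contained lowercase; uppercased on load")
    residues <- toupper(residues)
  }
  if (grepl("[^ACGTN]", residues))
    af_validation_error(sprintf(
      "region '%s' contains characters outside A/C/G/T/N", id))
  structure(
    list(id = id, length = nchar(residues), residues = residues),
    class = "seq_region"
  )
}

#' Create a genomic location
#'
#' 0-based half-open interval on one strand of a region.
#'
#' @param seq_id Region identifier.
#' @param start,end Integers with `0 <= start < end`.
#' @param strand `"+"`/`"-"` (also accepts `"forward"`/`"reverse"`).
#' @export
location <- function(seq_id, start, end, strand = "+") {
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start < 0L || start >= end)
    af_validation_error(sprintf(
      "invalid location [%s,%s) on '%s'", start, end, seq_id))
  structure(
    list(seq_id = seq_id, start = start, end = end, strand = norm_strand(strand)),
    class = "location"
  )
}

check_location_bounds <- function(region, start, end, what = "location") {
  if (start < 0L || end > region$length || start >= end)
    af_bounds_error(sprintf(
      "%s [%d,%d) out of bounds for region '%s' (length %d)",
      what, start, end, region$id, region$length))
  invisible(TRUE)
}

#' Extract a (strand-aware) subsequence
#'
#' Returns `residues[start:end]` of the region, reverse-complemented when the
#' location is on the reverse strand.
#'
#' @param region A [seq_region()].
#' @param loc A [location()] with `loc$seq_id == region$id`.
#' @export
get_subsequence <- function(region, loc) {
  if (!identical(loc$seq_id, region$id))
    af_bounds_error(sprintf("location seq_id '%s' does not match region '%s'",
                            loc$seq_id, region$id))
  check_location_bounds(region, loc$start, loc$end)
  s <- substr(region$residues, loc$start + 1L, loc$end)
  if (loc$strand == "-") s <- revcomp(s)
  s
}

TRANSCRIPT_TYPES <- c("protein_coding", "non_coding", "pseudogene_transcript",
                      "repeat_region", "transposable_element")

#' Create a transcript
#'
#' @param id Transcript identifier.
#' @param seq_id,strand Region and strand shared by all exons.
#' @param exons data.frame with integer columns `start`, `end` (0-based
#'   half-open), non-overlapping; stored sorted by start.
#' @param type One of `r paste(TRANSCRIPT_TYPES, collapse = ", ")`.
#' @param cds Optional genomic CDS span `c(start, end)` (half-open, `start <
#'   end` regardless of strand; on the reverse strand translation starts at
#'   `end`).  Only allowed for `protein_coding`.
#' @param partial Logical: open 3' reading frame (no in-frame stop).
#' @param owner Username of the creating curator.
#' @param name Optional display name.
#' @export
transcript <- function(id, seq_id, strand, exons, type = "protein_coding",
                       cds = NULL, partial = FALSE, owner = "unknown",
                       name = NULL) {
  if (!type %in% TRANSCRIPT_TYPES)
    af_validation_error(sprintf("unknown transcript type '%s'", type))
  exons <- as.data.frame(exons)[, c("start", "end")]
  exons$start <- as.integer(exons$start); exons$end <- as.integer(exons$end)
  exons <- exons[order(exons$start), , drop = FALSE]
  rownames(exons) <- NULL
  t <- structure(
    list(id = id, type = type, seq_id = seq_id, strand = norm_strand(strand),
         exons = exons, cds = if (is.null(cds)) NULL else as.integer(cds),
         partial = isTRUE(partial), owner = owner, name = name,
         needs_review = FALSE, pins = list()),
    class = "transcript"
  )
  viol <- validate_transcript(t)
  if (length(viol)) af_validation_error(paste(viol, collapse = "; "))
  t
}

validate_transcript <- function(t) {
  viol <- character(0)
  ex <- t$exons
  bad <- function(msg) sprintf("transcript %s: %s", t$id, msg)
  if (nrow(ex) == 0L) return(bad("has no exons"))
  if (any(ex$start >= ex$end)) viol <- c(viol, bad("empty or inverted exon"))
  if (nrow(ex) > 1L && any(ex$start[-1L] < ex$end[-nrow(ex)]))
    viol <- c(viol, bad("overlapping exons"))
  if (!is.null(t$cds)) {
    if (t$type != "protein_coding")
      viol <- c(viol, bad(sprintf("type '%s' must not carry a CDS", t$type)))
    cs <- t$cds[1L]; ce <- t$cds[2L]
    if (cs >= ce) viol <- c(viol, bad("empty CDS span"))
    in_exon <- function(p) any(ex$start <= p & p < ex$end)
    if (!in_exon(cs) || !in_exon(ce - 1L))
      viol <- c(viol, bad("CDS boundary outside exons"))
  }
  viol
}

tx_extent <- function(t) c(min(t$exons$start), max(t$exons$end))
tx_spliced_length <- function(t) sum(t$exons$end - t$exons$start)

# Genomic positions of the transcript's bases in 5'->3' spliced order.
tx_genomic_positions <- function(t) {
  pos <- unlist(lapply(seq_len(nrow(t$exons)), function(i)
    seq.int(t$exons$start[i], t$exons$end[i] - 1L)), use.names = FALSE)
  if (t$strand == "-") rev(pos) else pos
}

# Map genomic base positions to 0-based spliced offsets (NA when intronic).
tx_genomic_to_spliced <- function(t, pos) {
  gp <- tx_genomic_positions(t)
  match(pos, gp) - 1L
}

# Map 0-based spliced offsets to genomic base positions.
tx_spliced_to_genomic <- function(t, off) {
  gp <- tx_genomic_positions(t)
  gp[off + 1L]
}

# Genomic CDS base positions in translation (5'->3') order.
tx_cds_positions <- function(t) {
  if (is.null(t$cds)) return(integer(0))
  gp <- tx_genomic_positions(t)
  gp[gp >= t$cds[1L] & gp < t$cds[2L]]
}

# Spliced CDS sequence (translation order).
tx_cds_sequence <- function(region, t) {
  pos <- tx_cds_positions(t)
  if (!length(pos)) return("")
  bases <- strsplit(region$residues, "", fixed = TRUE)[[1L]][pos + 1L]
  s <- paste(bases, collapse = "")
  if (t$strand == "-") s <- chartr("ACGTN", "TGCAN", s)
  s
}

#' Spliced transcript sequence
#'
#' Concatenates the exon subsequences in 5'->3' transcript order; on the
#' reverse strand exons are taken highest-coordinate first and each is
#' reverse-complemented.
#'
#' @param region A [seq_region()].
#' @param t A [transcript()].
#' @export
get_spliced_sequence <- function(region, t) {
  parts <- vapply(seq_len(nrow(t$exons)), function(i) {
    check_location_bounds(region, t$exons$start[i], t$exons$end[i],
                          sprintf("exon %d of %s", i, t$id))
    substr(region$residues, t$exons$start[i] + 1L, t$exons$end[i])
  }, character(1))
  if (t$strand == "-") {
    paste(vapply(rev(parts), revcomp, character(1)), collapse = "")
  } else {
    paste(parts, collapse = "")
  }
}

#' Create a gene
#'
#' A gene is a non-empty group of isoform transcripts on one strand of one
#' region, carrying curation metadata (symbol, description, cross-references,
#' GO terms, publications, free-text comments).
#'
#' @param id Gene identifier.
#' @param transcripts Named list of [transcript()] objects.
#' @param symbol,description Optional curation metadata.
#' @param dbxrefs,go_terms,publications,comments Character vectors.
#' @param owner Username.
#' @export
gene <- function(id, transcripts, symbol = NULL, description = NULL,
                 dbxrefs = character(0), go_terms = character(0),
                 publications = character(0), comments = character(0),
                 owner = "unknown") {
  if (!length(transcripts)) af_validation_error("gene must have >= 1 transcript")
  names(transcripts) <- vapply(transcripts, `[[`, character(1), "id")
  g <- structure(
    list(id = id, symbol = symbol, description = description,
         dbxrefs = dbxrefs, go_terms = go_terms, publications = publications,
         comments = comments, transcripts = transcripts, owner = owner),
    class = "gene"
  )
  refresh_gene_extent(g)
}

refresh_gene_extent <- function(g) {
  ext <- vapply(g$transcripts, tx_extent, integer(2))
  g$seq_id <- g$transcripts[[1L]]$seq_id
  g$strand <- g$transcripts[[1L]]$strand
  g$start <- min(ext[1L, ])
  g$end <- max(ext[2L, ])
  g
}

validate_gene <- function(g) {
  viol <- character(0)
  seqs <- unique(vapply(g$transcripts, `[[`, character(1), "seq_id"))
  strands <- unique(vapply(g$transcripts, `[[`, character(1), "strand"))
  if (length(seqs) > 1L)
    viol <- c(viol, sprintf("gene %s: transcripts span regions %s",
                            g$id, paste(seqs, collapse = ",")))
  if (length(strands) > 1L)
    viol <- c(viol, sprintf("gene %s: transcripts on both strands", g$id))
  ext <- vapply(g$transcripts, tx_extent, integer(2))
  if (g$start != min(ext[1L, ]) || g$end != max(ext[2L, ]))
    viol <- c(viol, sprintf("gene %s: extent is not the transcript hull", g$id))
  c(viol, unlist(lapply(g$transcripts, validate_transcript)))
}

ROLES <- c("admin", "instructor", "annotator", "reader")
EDITING_ROLES <- c("admin", "instructor", "annotator")

#' Create a user
#' @param username Unique username.
#' @param role One of admin, instructor, annotator, reader; only the first
#'   three may edit.
#' @export
user <- function(username, role = "annotator") {
  if (!role %in% ROLES)
    af_validation_error(sprintf("unknown role '%s'", role))
  structure(list(username = username, role = role), class = "af_user")
}

#' Organism configuration
#'
#' @param donor_sites,acceptor_sites Sets of intron-boundary dinucleotides
#'   (canonical GT / AG).
#' @param translation_table NCBI codon table id.
#' @param undo_depth Positive integer or `Inf` (unlimited).
#' @param isoform_strategy `"cds_overlap_in_frame"` (transcripts are isoforms
#'   when their CDSs share a genomic base in the same reading frame) or
#'   `"exon_overlap"` (any exonic overlap on the same strand).
#' @param timestamp_mode `"real"` (wall clock) or `"logical"` (deterministic
#'   counter-derived timestamps, for reproducible sessions).
#' @export
organism_config <- function(donor_sites = "GT", acceptor_sites = "AG",
                            translation_table = 1L, undo_depth = Inf,
                            isoform_strategy = "cds_overlap_in_frame",
                            timestamp_mode = "real") {
  sites <- c(donor_sites, acceptor_sites)
  if (any(nchar(sites) != 2L) || any(grepl("[^ACGT]", sites)))
    af_validation_error("donor/acceptor sites must be dinucleotides over ACGT")
  if (!isoform_strategy %in% c("cds_overlap_in_frame", "exon_overlap"))
    af_validation_error(sprintf("unknown isoform strategy '%s'", isoform_strategy))
  if (!is.infinite(undo_depth) && (undo_depth < 1 || undo_depth != round(undo_depth)))
    af_validation_error("undo_depth must be a positive integer or Inf")
  structure(
    list(donor_sites = toupper(donor_sites),
         acceptor_sites = toupper(acceptor_sites),
         translation_table = as.integer(translation_table),
         codon_table = codon_table(translation_table),
         undo_depth = undo_depth,
         isoform_strategy = isoform_strategy,
         timestamp_mode = timestamp_mode),
    class = "organism_config"
  )
}

#' Create an annotation project
#'
#' The unit the engine operates on: reference regions, the editable gene
#' set, loaded evidence and sequence alterations, users, organism
#' configuration, and the per-feature edit history.
#'
#' @param regions List of [seq_region()] objects.
#' @param config An [organism_config()].
#' @param users List of [user()] objects; an `admin` user is always present.
#' @export
new_project <- function(regions = list(), config = organism_config(),
                        users = list()) {
  names(regions) <- vapply(regions, `[[`, character(1), "id")
  if (anyDuplicated(names(regions)))
    af_validation_error("duplicate region ids in project")
  users <- c(list(user("admin", "admin")), users)
  names(users) <- vapply(users, `[[`, character(1), "username")
  users <- users[!duplicated(names(users))]
  structure(
    list(regions = regions, genes = list(), evidence = list(),
         alterations = list(), users = users, config = config,
         history = list(features = list(), log = list()),
         counters = list(gene = 0L, transcript = 0L, edit = 0L),
         last_edit = NULL),
    class = "annotation_project"
  )
}

project_user_role <- function(project, username) {
  u <- project$users[[username]]
  if (is.null(u)) af_not_found_error(sprintf("unknown user '%s'", username))
  u$role
}

check_can_edit <- function(project, username) {
  role <- project_user_role(project, username)
  if (!role %in% EDITING_ROLES)
    af_permission_error(sprintf(
      "user '%s' (role %s) may not edit", username, role))
  invisible(TRUE)
}

# Locate a transcript: returns list(gene_id, transcript) or NULL.
find_transcript <- function(project, transcript_id) {
  for (g in project$genes) {
    t <- g$transcripts[[transcript_id]]
    if (!is.null(t)) return(list(gene_id = g$id, transcript = t))
  }
  NULL
}

must_find_transcript <- function(project, transcript_id) {
  hit <- find_transcript(project, transcript_id)
  if (is.null(hit))
    af_not_found_error(sprintf("no transcript '%s' in project", transcript_id))
  hit
}

project_region <- function(project, seq_id) {
  r <- project$regions[[seq_id]]
  if (is.null(r)) af_not_found_error(sprintf("no region '%s' in project", seq_id))
  r
}

#' Validate a project
#'
#' Checks every model invariant (region residues, exon ordering, CDS-in-exon,
#' per-gene strand/region consistency, gene extents) and returns a character
#' vector of violation reports, empty when the project is clean.  Validation
#' never throws.
#'
#' @param project An annotation project.
#' @export
validate_project <- function(project) {
  viol <- character(0)
  for (r in project$regions) {
    if (r$length != nchar(r$residues))
      viol <- c(viol, sprintf("region %s: length field != residue count", r$id))
  }
  all_tx <- character(0)
  for (g in project$genes) {
    viol <- c(viol, validate_gene(g))
    for (t in g$transcripts) {
      all_tx <- c(all_tx, t$id)
      r <- project$regions[[t$seq_id]]
      if (is.null(r)) {
        viol <- c(viol, sprintf("transcript %s: unknown region '%s'", t$id, t$seq_id))
      } else if (min(t$exons$start) < 0L || max(t$exons$end) > r$length) {
        viol <- c(viol, sprintf("transcript %s: exon outside region bounds", t$id))
      }
    }
  }
  if (anyDuplicated(all_tx))
    viol <- c(viol, sprintf("duplicate transcript ids: %s",
                            paste(unique(all_tx[duplicated(all_tx)]), collapse = ",")))
  viol
}

#' @export
print.annotation_project <- function(x, ...) {
  cat(sprintf("<annotation_project> %d region(s), %d gene(s), %d evidence, %d alteration(s)\n",
              length(x$regions), length(x$genes), length(x$evidence),
              length(x$alterations)))
  invisible(x)
}

mint_gene_id <- function(project) {
  n <- project$counters$gene + 1L
  list(project = within_counters(project, gene = n),
       id = sprintf("gene_%05d", n))
}

mint_transcript_id <- function(project) {
  n <- project$counters$transcript + 1L
  list(project = within_counters(project, transcript = n),
       id = sprintf("transcript_%05d", n))
}

within_counters <- function(project, ...) {
  upd <- list(...)
  project$counters[names(upd)] <- upd
  project
}
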