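# Sequence alterations (assembly corrections and natural variants), their
# application to a reference, the piecewise coordinate map between reference
# and altered coordinates, and re-projection of transcripts so the effect of
# an alteration is visible on the annotated features.

#' Create a sequence alteration
#'
#' A pure substitution, insertion or deletion against the reference,
#' categorized as an assembly-error *correction* or a naturally occurring
#' *variant* (same machinery, different curation intent).
#'
#' @param kind `"substitution"`, `"insertion"` or `"deletion"`.
#' @param seq_id Region id.
#' @param position 0-based reference coordinate; insertions insert their
#'   bases *before* this position.
#' @param ref_residues Replaced reference bases (empty for insertions).
#' @param alt_residues Replacement bases (empty for deletions).
#' @param category `"assembly_correction"` or `"variant"`.
#' @param id Optional external identifier (dbSNP-style).
#' @export
sequence_alteration <- function(kind, seq_id, position, ref_residues = "",
                                alt_residues = "",
                                category = "variant", id = NULL) {
  if (!kind %in% c("substitution", "insertion", "deletion"))
    af_validation_error(sprintf("unknown alteration kind '%s'", kind))
  if (!category %in% c("assembly_correction", "variant"))
    af_validation_error(sprintf("unknown alteration category '%s'", category))
  ref_residues <- toupper(ref_residues); alt_residues <- toupper(alt_residues)
  nr <- nchar(ref_residues); na <- nchar(alt_residues)
  ok <- switch(kind,
    substitution = nr == na && nr >= 1L,
    insertion = nr == 0L && na >= 1L,
    deletion = nr >= 1L && na == 0L)
  if (!ok)
    af_validation_error(sprintf(
      "%s with |ref|=%d |alt|=%d is inconsistent", kind, nr, na))
  structure(
    list(kind = kind, seq_id = seq_id, position = as.integer(position),
         ref_residues = ref_residues, alt_residues = alt_residues,
         category = category, id = id),
    class = "sequence_alteration"
  )
}

alt_ref_span <- function(a) {
  c(a$position, a$position + nchar(a$ref_residues))
}

check_alterations <- function(region, alts) {
  for (a in alts) {
    if (!identical(a$seq_id, region$id))
      af_bounds_error(sprintf("alteration on '%s' applied to region '%s'",
                              a$seq_id, region$id))
    span <- alt_ref_span(a)
    if (span[1L] < 0L || span[2L] > region$length || span[1L] > region$length)
      af_bounds_error(sprintf("alteration at %d out of bounds for '%s'",
                              a$position, region$id))
    if (nchar(a$ref_residues)) {
      have <- substr(region$residues, span[1L] + 1L, span[2L])
      if (!identical(have, a$ref_residues))
        af_error("af_refcheck_error", sprintf(
          "reference check failed at %s:%d: expected '%s', sequence has '%s'",
          region$id, a$position, a$ref_residues, have))
    }
  }
  if (length(alts) > 1L) {
    spans <- t(vapply(alts, alt_ref_span, integer(2)))
    kinds <- vapply(alts, `[[`, character(1), "kind")
    ord <- order(spans[, 1L], spans[, 2L])
    spans <- spans[ord, , drop = FALSE]; kinds <- kinds[ord]
    for (i in seq_len(nrow(spans) - 1L)) {
      overlap <- spans[i + 1L, 1L] < spans[i, 2L] ||
        (kinds[i] == "insertion" && kinds[i + 1L] == "insertion" &&
           spans[i, 1L] == spans[i + 1L, 1L])
      if (overlap)
        af_error("af_conflict_error", sprintf(
          "overlapping alterations at %d and %d on '%s'",
          spans[i, 1L], spans[i + 1L, 1L], alts[[1L]]$seq_id))
    }
  }
  invisible(TRUE)
}

new_coordinate_map <- function(segments, deleted, ref_length, alt_length) {
  structure(
    list(segments = segments, deleted = deleted,
         ref_length = as.integer(ref_length), alt_length = as.integer(alt_length)),
    class = "coordinate_map"
  )
}

identity_coordinate_map <- function(length) {
  new_coordinate_map(
    data.frame(ref_start = 0L, ref_end = as.integer(length), offset = 0L),
    data.frame(start = integer(0), end = integer(0)),
    length, length
  )
}

#' Apply sequence alterations to a region
#'
#' Applies a set of non-overlapping alterations (verified against the
#' reference residues) and returns the altered region together with the
#' piecewise-monotone coordinate map from reference to altered coordinates.
#' The altered length is the original plus the net indel sum; every
#' surviving reference position maps to exactly one altered position.
#'
#' @param region A [seq_region()].
#' @param alts List of [sequence_alteration()] on that region.
#' @return `list(region = altered seq_region, cmap = coordinate_map)`.
#' @export
apply_alterations <- function(region, alts) {
  check_alterations(region, alts)
  if (!length(alts))
    return(list(region = region, cmap = identity_coordinate_map(region$length)))
  spans <- t(vapply(alts, alt_ref_span, integer(2)))
  is_ins <- vapply(alts, function(a) a$kind == "insertion", logical(1))
  # at equal position a deletion/substitution precedes an insertion
  ord <- order(spans[, 1L], is_ins)
  alts <- alts[ord]
  residues <- region$residues
  # apply right-to-left so earlier coordinates stay valid
  for (a in rev(alts)) {
    span <- alt_ref_span(a)
    residues <- paste0(substr(residues, 1L, span[1L]), a$alt_residues,
                       substr(residues, span[2L] + 1L, nchar(residues)))
  }
  seg_start <- integer(0); seg_end <- integer(0); seg_off <- integer(0)
  del_start <- integer(0); del_end <- integer(0)
  cur <- 0L; off <- 0L
  push_seg <- function(s, e, o) {
    if (e > s) {
      seg_start <<- c(seg_start, s); seg_end <<- c(seg_end, e)
      seg_off <<- c(seg_off, o)
    }
  }
  for (a in alts) {
    span <- alt_ref_span(a)
    if (a$kind == "deletion") {
      push_seg(cur, span[1L], off)
      del_start <- c(del_start, span[1L]); del_end <- c(del_end, span[2L])
      cur <- span[2L]
      off <- off - nchar(a$ref_residues)
    } else if (a$kind == "insertion") {
      push_seg(cur, span[1L], off)
      cur <- span[1L]
      off <- off + nchar(a$alt_residues)
    }
    # substitutions leave coordinates untouched
  }
  push_seg(cur, region$length, off)
  cmap <- new_coordinate_map(
    data.frame(ref_start = seg_start, ref_end = seg_end, offset = seg_off),
    data.frame(start = del_start, end = del_end),
    region$length, nchar(residues)
  )
  altered <- seq_region(region$id, residues)
  stopifnot(altered$length ==
              region$length + sum(vapply(alts, function(a)
                nchar(a$alt_residues) - nchar(a$ref_residues), integer(1))))
  list(region = altered, cmap = cmap)
}

#' Map reference positions through a coordinate map
#'
#' @param cmap A coordinate map from [apply_alterations()].
#' @param ref_pos Integer vector of 0-based reference positions.
#' @return Integer vector of altered positions; `NA` marks deleted bases.
#' @export
map_position <- function(cmap, ref_pos) {
  ref_pos <- as.integer(ref_pos)
  if (any(ref_pos < 0L | ref_pos >= cmap$ref_length))
    af_bounds_error(sprintf("position outside reference bounds [0,%d)",
                            cmap$ref_length))
  out <- rep(NA_integer_, length(ref_pos))
  seg <- cmap$segments
  for (i in seq_len(nrow(seg))) {
    hit <- ref_pos >= seg$ref_start[i] & ref_pos < seg$ref_end[i]
    out[hit] <- ref_pos[hit] + seg$offset[i]
  }
  out
}

# First surviving reference position in [from, to) scanning forward, or NA.
first_surviving <- function(cmap, from, to) {
  for (p in seq.int(from, to - 1L)) {
    m <- map_position(cmap, p)
    if (!is.na(m)) return(p)
  }
  NA_integer_
}
last_surviving <- function(cmap, from, to) {
  for (p in seq.int(to - 1L, from)) {
    m <- map_position(cmap, p)
    if (!is.na(m)) return(p)
  }
  NA_integer_
}

#' Project a transcript through a coordinate map
#'
#' Maps every exon boundary to altered coordinates (boundaries landing in a
#' deleted span snap inward toward the exon body; an exon deleted entirely
#' is dropped), recomputes the ORF on the altered spliced sequence, and
#' reports the effect: exon coordinate changes, CDS start/end movement with
#' oriented deltas (positive = downstream), and the protein before vs after.
#'
#' @param t A [transcript()].
#' @param cmap Coordinate map for the transcript's region.
#' @param altered_region The altered [seq_region()].
#' @param config An [organism_config()].
#' @param original_region The unaltered region (for the "before" protein);
#'   optional — when absent the before-protein is reported as `NA`.
#' @return `list(transcript = projected transcript or NULL, report =
#'   effect_report)`.
#' @export
project_transcript <- function(t, cmap, altered_region, config,
                               original_region = NULL) {
  ex <- t$exons
  new_start <- integer(0); new_end <- integer(0)
  status <- character(nrow(ex))
  for (i in seq_len(nrow(ex))) {
    s_ref <- first_surviving(cmap, ex$start[i], ex$end[i])
    if (is.na(s_ref)) { status[i] <- "dropped"; next }
    e_ref <- last_surviving(cmap, ex$start[i], ex$end[i])
    status[i] <- "kept"
    new_start <- c(new_start, map_position(cmap, s_ref))
    new_end <- c(new_end, map_position(cmap, e_ref) + 1L)
  }
  protein_before <- NA_character_
  if (!is.null(original_region) && !is.null(t$cds)) {
    protein_before <- translate_cds(tx_cds_sequence(original_region, t),
                                    config$codon_table)
  }
  if (!length(new_start)) {
    report <- structure(
      list(transcript_id = t$id, lost = TRUE,
           exon_coordinate_changes = data.frame(
             exon = seq_len(nrow(ex)) - 1L, status = status,
             alt_start = NA_integer_, alt_end = NA_integer_),
           cds_start_moved = NA, cds_start_delta = NA_integer_,
           cds_end_moved = NA, cds_end_delta = NA_integer_,
           protein_before = protein_before, protein_after = NA_character_,
           protein_changed = NA),
      class = "effect_report")
    return(list(transcript = NULL, report = report))
  }
  proj <- t
  proj$exons <- coalesce_exons(data.frame(start = new_start, end = new_end))
  proj$seq_id <- altered_region$id
  proj$pins <- list()
  proj <- compute_cds_with_pins(altered_region, proj, config$codon_table)

  changes <- data.frame(exon = seq_len(nrow(ex)) - 1L, status = status,
                        alt_start = NA_integer_, alt_end = NA_integer_)
  k <- 0L
  for (i in seq_len(nrow(ex))) {
    if (status[i] == "kept") {
      k <- k + 1L
      if (k <= nrow(proj$exons)) {
        changes$alt_start[i] <- new_start[k]
        changes$alt_end[i] <- new_end[k]
      }
    }
  }

  sgn <- if (t$strand == "+") 1L else -1L
  # Expected altered position of a CDS boundary base: the mapped original
  # base or, when that base was deleted, the nearest surviving base toward
  # the CDS body.  `toward` is +1 (scan to larger coordinates) or -1.
  expected_alt <- function(orig_base, toward) {
    surv <- if (toward > 0L) first_surviving(cmap, orig_base, cmap$ref_length)
            else last_surviving(cmap, 0L, orig_base + 1L)
    if (is.na(surv)) NA_integer_ else map_position(cmap, surv)
  }
  cds_cmp <- function(orig_base, new_base, toward) {
    exp_alt <- expected_alt(orig_base, toward)
    direct <- map_position(cmap, orig_base)
    moved <- is.na(direct) || is.na(new_base) || direct != new_base
    delta <- if (!is.na(exp_alt) && !is.na(new_base))
      (new_base - exp_alt) * sgn else NA_integer_
    list(moved = moved, delta = delta)
  }
  if (!is.null(t$cds) && !is.null(proj$cds)) {
    orig_start_base <- if (t$strand == "+") t$cds[1L] else t$cds[2L] - 1L
    orig_end_base <- if (t$strand == "+") t$cds[2L] - 1L else t$cds[1L]
    new_start_base <- if (t$strand == "+") proj$cds[1L] else proj$cds[2L] - 1L
    new_end_base <- if (t$strand == "+") proj$cds[2L] - 1L else proj$cds[1L]
    start_cmp <- cds_cmp(orig_start_base, new_start_base, sgn)    # toward 3'
    end_cmp <- cds_cmp(orig_end_base, new_end_base, -sgn)         # toward 5'
  } else {
    start_cmp <- end_cmp <- list(moved = !is.null(t$cds) || !is.null(proj$cds),
                                 delta = NA_integer_)
  }
  protein_after <- if (!is.null(proj$cds))
    translate_cds(tx_cds_sequence(altered_region, proj), config$codon_table)
    else ""
  pb <- if (is.na(protein_before)) "" else protein_before
  report <- structure(
    list(transcript_id = t$id, lost = FALSE,
         exon_coordinate_changes = changes,
         cds_start_moved = start_cmp$moved, cds_start_delta = start_cmp$delta,
         cds_end_moved = end_cmp$moved, cds_end_delta = end_cmp$delta,
         protein_before = protein_before, protein_after = protein_after,
         protein_changed = !identical(pb, protein_after)),
    class = "effect_report")
  list(transcript = proj, report = report)
}

#' Project a whole project through its alterations
#'
#' Applies all alterations of the selected category per region and projects
#' every transcript, returning a read-only altered view plus per-transcript
#' effect reports.  The original project is untouched; corrections and
#' variants run through identical machinery, distinguished only by their
#' category flag, so corrections can later be committed without redesign.
#'
#' @param project Annotation project.
#' @param category `"assembly_correction"`, `"variant"`, or `"both"`.
#' @return An `altered_view`: `regions` (altered), `cmaps` (per region),
#'   `genes` (projected), `reports` (named by transcript id).
#' @export
project_annotations <- function(project, category = "both") {
  if (!category %in% c("assembly_correction", "variant", "both"))
    af_usage_error(sprintf("unknown category filter '%s'", category))
  keep <- function(a) category == "both" || a$category == category
  regions <- list(); cmaps <- list()
  for (r in project$regions) {
    alts <- Filter(function(a) identical(a$seq_id, r$id) && keep(a),
                   project$alterations)
    res <- apply_alterations(r, alts)
    regions[[r$id]] <- res$region
    cmaps[[r$id]] <- res$cmap
  }
  genes <- list(); reports <- list()
  for (g in project$genes) {
    pg <- g
    pg$transcripts <- list()
    for (t in g$transcripts) {
      pr <- project_transcript(t, cmaps[[t$seq_id]], regions[[t$seq_id]],
                               project$config,
                               original_region = project$regions[[t$seq_id]])
      reports[[t$id]] <- pr$report
      if (!is.null(pr$transcript)) pg$transcripts[[t$id]] <- pr$transcript
    }
    if (length(pg$transcripts)) genes[[g$id]] <- refresh_gene_extent(pg)
  }
  structure(list(regions = regions, cmaps = cmaps, genes = genes,
                 reports = reports, category = category),
            class = "altered_view")
}

#' Tabulate effect reports
#'
#' @param reports List of effect reports (e.g. `view$reports`).
#' @return data.frame, one row per transcript.
#' @export
effect_report_table <- function(reports) {
  do.call(rbind, lapply(reports, function(r) data.frame(
    transcript_id = r$transcript_id, lost = r$lost,
    cds_start_moved = r$cds_start_moved, cds_start_delta = r$cds_start_delta,
    cds_end_moved = r$cds_end_moved, cds_end_delta = r$cds_end_delta,
    protein_before = r$protein_before %||% NA_character_,
    protein_after = r$protein_after %||% NA_character_,
    protein_changed = r$protein_changed)))
}
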