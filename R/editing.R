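# Structural editing operations of the editing workspace: evidence
# promotion, transcript merge/split, exon-boundary dragging and snapping,
# translation-boundary pinning, strand flipping, and reading-frame-aware
# gene membership.  Every operation is atomic (the input project is never
# mutated; errors leave the caller's copy untouched) and every successful
# edit appends exactly one history record per affected gene.

#' Create an evidence feature
#'
#' Read-only aligned or predicted features (transcript alignments, gene
#' predictions) that curators promote into editable annotations.
#'
#' @param id Identifier.
#' @param seq_id Region id.
#' @param blocks data.frame(start, end): exon-like sub-intervals, 0-based
#'   half-open, non-overlapping.
#' @param strand `"+"`/`"-"`; strandless evidence (`NA` or `"*"`) defaults to
#'   forward with a warning, since ORF and splice logic are strand-dependent.
#' @param source_track Name of the originating track.
#' @param name Optional display name.
#' @export
evidence_feature <- function(id, seq_id, blocks, strand = "+",
                             source_track = "evidence", name = NULL) {
  if (is.na(strand) || identical(strand, "*")) {
    af_notice("evidence '", id, "' is strandless; defaulting to forward")
    strand <- "+"
  }
  blocks <- as.data.frame(blocks)[, c("start", "end")]
  blocks$start <- as.integer(blocks$start); blocks$end <- as.integer(blocks$end)
  blocks <- blocks[order(blocks$start), , drop = FALSE]
  rownames(blocks) <- NULL
  if (any(blocks$start >= blocks$end) ||
      (nrow(blocks) > 1L && any(blocks$start[-1L] < blocks$end[-nrow(blocks)])))
    af_validation_error(sprintf("evidence '%s': invalid or overlapping blocks", id))
  structure(
    list(id = id, seq_id = seq_id, strand = norm_strand(strand),
         blocks = blocks, source_track = source_track, name = name),
    class = "evidence_feature"
  )
}

# ---- ORF maintenance ------------------------------------------------------

orf_to_genomic_cds <- function(t, start_offset, end_offset) {
  gp <- tx_genomic_positions(t)
  covered <- gp[seq.int(start_offset + 1L, end_offset)]
  c(min(covered), max(covered) + 1L)
}

set_cds_from_orf <- function(t, orf) {
  if (is.null(orf)) {
    t$cds <- NULL
    t$partial <- FALSE
    t$needs_review <- t$type == "protein_coding"
  } else {
    t$cds <- orf_to_genomic_cds(t, orf$start_offset, orf$end_offset)
    t$partial <- orf$partial
    t$needs_review <- FALSE
  }
  t
}

# Spliced offset (0-based) of a genomic base, erroring outside exons.
spliced_offset_or_null <- function(t, pos) {
  off <- tx_genomic_to_spliced(t, as.integer(pos))
  if (is.na(off)) NULL else off
}

# CDS computation honouring pinned translation boundaries.  Pins store the
# genomic base of the first (start) and/or last (end) CDS base; a pin whose
# base no longer falls inside an exon is dropped with a warning and the ORF
# recomputed automatically.
compute_cds_with_pins <- function(region, t, table) {
  mrna <- get_spliced_sequence(region, t)
  L <- nchar(mrna)
  off_s <- if (!is.null(t$pins$start)) spliced_offset_or_null(t, t$pins$start)
  off_e <- if (!is.null(t$pins$end)) spliced_offset_or_null(t, t$pins$end)
  if (!is.null(t$pins$start) && is.null(off_s)) {
    af_notice("transcript ", t$id, ": pinned translation start left the exons; pin dropped")
    t$pins$start <- NULL
  }
  if (!is.null(t$pins$end) && is.null(off_e)) {
    af_notice("transcript ", t$id, ": pinned translation end left the exons; pin dropped")
    t$pins$end <- NULL
  }
  if (is.null(t$pins$start) && is.null(t$pins$end)) {
    return(set_cds_from_orf(t, longest_orf(mrna, table, allow_partial = TRUE)))
  }
  if (!is.null(off_s) && !is.null(off_e)) {
    s <- off_s; e <- off_e + 1L
  } else if (!is.null(off_s)) {
    s <- off_s
    codons <- split_codons(substr(mrna, s + 1L, L))
    stop_i <- which(is_stop_codon(codons, table))
    e <- if (length(stop_i)) s + stop_i[1L] * 3L else L
  } else {
    e <- off_e + 1L
    codons <- split_codons(substr(mrna, (e %% 3L) + 1L, e))
    n <- length(codons)
    s <- NULL
    if (n >= 2L) {
      starts <- which(is_start_codon(codons[seq_len(n - 1L)], table))
      stops <- which(is_stop_codon(codons, table))
      for (i in starts) {
        if (!any(stops >= i & stops < n)) { s <- (e %% 3L) + (i - 1L) * 3L; break }
      }
    }
    if (is.null(s)) s <- e %% 3L
  }
  if (e <= s) {
    t <- set_cds_from_orf(t, NULL)
    return(t)
  }
  t$cds <- orf_to_genomic_cds(t, s, e)
  last_codon <- substr(mrna, e - 2L, e)
  t$partial <- !((e - s) %% 3L == 0L && (e - s) >= 3L &&
                   is_stop_codon(last_codon, table))
  t$needs_review <- FALSE
  t
}

recompute_transcript_cds <- function(project, t) {
  if (t$type != "protein_coding") {
    t$cds <- NULL
    return(t)
  }
  region <- project_region(project, t$seq_id)
  compute_cds_with_pins(region, t, project$config$codon_table)
}

# ---- gene membership ------------------------------------------------------

# Per-base codon phases of a transcript's CDS: named integer vector,
# names = genomic positions, values = (spliced CDS offset) %% 3.
tx_cds_phases <- function(t) {
  pos <- tx_cds_positions(t)
  if (!length(pos)) return(integer(0))
  stats::setNames(seq_along(pos) - 1L, pos) %% 3L
}

tx_exon_positions_overlap <- function(a, b) {
  for (i in seq_len(nrow(a$exons))) {
    if (any(b$exons$start < a$exons$end[i] & a$exons$start[i] < b$exons$end))
      return(TRUE)
  }
  FALSE
}

# Witnesses that two transcripts are isoforms under cds_overlap_in_frame:
# genomic positions covered by both CDSs at equal phase.
inframe_witnesses <- function(a, b) {
  pa <- tx_cds_phases(a); pb <- tx_cds_phases(b)
  shared <- intersect(names(pa), names(pb))
  shared <- shared[pa[shared] == pb[shared]]
  if (!length(shared)) return(NULL)
  data.frame(position = as.integer(shared), phase = unname(pa[shared]))
}

#' Decide gene membership for a transcript
#'
#' Under the `cds_overlap_in_frame` strategy a transcript joins an existing
#' gene iff, on the same region and strand, some genomic base is covered by
#' the CDS of both the transcript and a member transcript *at the same codon
#' phase* (offset within codon accumulated 5'->3' along the spliced CDS).
#' Under `exon_overlap`, any exonic base overlap on the same strand
#' suffices.  When several genes qualify they are merged; otherwise a new
#' gene is minted.
#'
#' @param project Annotation project.
#' @param t A transcript (object, or id of a placed transcript).
#' @param config Organism config (defaults to the project's).
#' @return A `membership_decision`: `transcript_id`, `matched_genes`
#'   (character, possibly empty), `strategy_used`, `witnesses` (per matched
#'   gene, data.frame of position/phase proofs, or positions for
#'   exon_overlap).
#' @export
assign_gene_membership <- function(project, t, config = project$config) {
  if (is.character(t)) t <- must_find_transcript(project, t)$transcript
  strategy <- config$isoform_strategy
  matched <- character(0)
  witnesses <- list()
  for (g in project$genes) {
    if (!identical(g$seq_id, t$seq_id) || !identical(g$strand, t$strand)) next
    others <- Filter(function(u) u$id != t$id, g$transcripts)
    if (!length(others)) next
    if (strategy == "cds_overlap_in_frame") {
      w <- NULL
      for (u in others) {
        wi <- inframe_witnesses(t, u)
        if (!is.null(wi)) w <- rbind(w, wi)
      }
      if (!is.null(w)) {
        matched <- c(matched, g$id)
        witnesses[[g$id]] <- unique(w[order(w$position), , drop = FALSE])
      }
    } else {
      hit <- Filter(function(u) tx_exon_positions_overlap(t, u), others)
      if (length(hit)) {
        matched <- c(matched, g$id)
        witnesses[[g$id]] <- data.frame(position = vapply(hit, function(u)
          max(u$exons$start[1L], t$exons$start[1L]), integer(1)))
      }
    }
  }
  structure(
    list(transcript_id = t$id, matched_genes = sort(matched),
         strategy_used = strategy, witnesses = witnesses),
    class = "membership_decision"
  )
}

union_metadata <- function(a, b) {
  a$symbol <- a$symbol %||% b$symbol
  a$description <- a$description %||% b$description
  for (f in c("dbxrefs", "go_terms", "publications", "comments")) {
    a[[f]] <- unique(c(a[[f]], b[[f]]))
  }
  a
}

# Merge gene `loser` into `survivor` (both live in project); the absorbed
# gene's history gets a terminal "merged_into" record.
absorb_gene <- function(project, survivor_id, loser_id, username) {
  s <- project$genes[[survivor_id]]
  l <- project$genes[[loser_id]]
  s$transcripts <- c(s$transcripts, l$transcripts)
  s <- union_metadata(s, l)
  project$genes[[survivor_id]] <- refresh_gene_extent(s)
  project <- record_edit(project, loser_id, username, "merged_into",
                         params = list(into = survivor_id), snapshot = l)
  project$genes[[loser_id]] <- NULL
  project
}

# Remove a transcript from its gene; an emptied gene is deleted (with a
# terminal history record).
detach_transcript <- function(project, transcript_id, username) {
  hit <- find_transcript(project, transcript_id)
  if (is.null(hit)) return(project)
  g <- project$genes[[hit$gene_id]]
  g$transcripts[[transcript_id]] <- NULL
  if (!length(g$transcripts)) {
    project <- record_edit(project, g$id, username, "emptied",
                           params = list(), snapshot = g)
    project$genes[[g$id]] <- NULL
  } else {
    project$genes[[g$id]] <- refresh_gene_extent(g)
  }
  project
}

# Place a (detached) transcript into the gene set according to the isoform
# strategy; qualifying genes merge, else a new gene is minted (or, when
# `reuse_gene` is given, that gene shell is revived to keep its id and
# metadata).  Returns the project with $last_edit-free bookkeeping; history
# for the final gene is the caller's responsibility.
place_transcript <- function(project, t, username, reuse_gene = NULL) {
  decision <- assign_gene_membership(project, t)
  if (length(decision$matched_genes)) {
    home <- decision$matched_genes[[1L]]
    for (other in decision$matched_genes[-1L]) {
      project <- absorb_gene(project, home, other, username)
    }
    g <- project$genes[[home]]
    g$transcripts[[t$id]] <- t
    project$genes[[home]] <- refresh_gene_extent(g)
  } else if (!is.null(reuse_gene)) {
    reuse_gene$transcripts <- stats::setNames(list(t), t$id)
    home <- reuse_gene$id
    project$genes[[home]] <- refresh_gene_extent(reuse_gene)
  } else {
    minted <- mint_gene_id(project)
    project <- minted$project
    home <- minted$id
    project$genes[[home]] <- gene(home, list(t), owner = t$owner)
  }
  decision$gene_id <- home
  list(project = project, gene_id = home, decision = decision)
}

# ---- operations -----------------------------------------------------------

#' Promote an evidence feature to an editable transcript
#'
#' The evidence blocks become the exons of a new transcript with the default
#' type "protein coding transcript"; the longest open reading frame of the
#' spliced sequence is computed automatically and sets the CDS (a transcript
#' whose spliced sequence has no start codon is created CDS-less and flagged
#' `needs_review`); gene membership is assigned by the configured isoform
#' strategy; one edit record is written.
#'
#' @param project Annotation project.
#' @param ev An [evidence_feature()] or the id of loaded evidence.
#' @param username Editing user (must hold an editing role).
#' @return Updated project; `project$last_edit$transcript_id` and
#'   `$gene_id` identify the result.
#' @export
promote_evidence <- function(project, ev, username) {
  check_can_edit(project, username)
  if (is.character(ev)) {
    ev_obj <- project$evidence[[ev]]
    if (is.null(ev_obj)) af_not_found_error(sprintf("no evidence '%s'", ev))
    ev <- ev_obj
  }
  region <- project_region(project, ev$seq_id)
  for (i in seq_len(nrow(ev$blocks)))
    check_location_bounds(region, ev$blocks$start[i], ev$blocks$end[i],
                          sprintf("block %d of evidence %s", i, ev$id))
  minted <- mint_transcript_id(project)
  project <- minted$project
  t <- transcript(minted$id, ev$seq_id, ev$strand, ev$blocks,
                  type = "protein_coding", owner = username, name = ev$name)
  t <- recompute_transcript_cds(project, t)
  placed <- place_transcript(project, t, username)
  project <- placed$project
  project <- record_edit(project, placed$gene_id, username, "promote_evidence",
                         params = list(evidence = ev$id, transcript = t$id))
  project$last_edit$transcript_id <- t$id
  project$last_edit$gene_id <- placed$gene_id
  project$last_edit$decision <- placed$decision
  project
}

#' Merge two transcripts into one
#'
#' The merged transcript's exon set is the union of both exon sets with
#' overlapping or bookended exons coalesced; the ORF is recomputed; the two
#' donors are removed and gene grouping is re-evaluated.  When the donors
#' belonged to different genes the genes merge: the survivor keeps the
#' lexicographically smaller id and the union of curation metadata.
#'
#' @param project Annotation project.
#' @param a_id,b_id Ids of the transcripts to merge (`a_id` survives as the
#'   merged transcript's id).
#' @param username Editing user.
#' @return Updated project (`project$last_edit$transcript_id` is the merged
#'   transcript).
#' @export
merge_transcripts <- function(project, a_id, b_id, username) {
  check_can_edit(project, username)
  if (identical(a_id, b_id))
    af_error("af_merge_error", "cannot merge a transcript with itself")
  a <- must_find_transcript(project, a_id)
  b <- must_find_transcript(project, b_id)
  ta <- a$transcript; tb <- b$transcript
  if (!identical(ta$seq_id, tb$seq_id) || !identical(ta$strand, tb$strand))
    af_error("af_merge_error", sprintf(
      "transcripts %s and %s are on different regions or strands", a_id, b_id))
  orig_genes <- unique(c(a$gene_id, b$gene_id))
  shells <- lapply(orig_genes, function(gid) project$genes[[gid]])
  names(shells) <- orig_genes
  project <- detach_transcript(project, a_id, username)
  project <- detach_transcript(project, b_id, username)
  merged <- ta
  merged$exons <- coalesce_exons(rbind(ta$exons, tb$exons))
  merged$pins <- list()
  merged <- recompute_transcript_cds(project, merged)
  reuse <- NULL
  gone <- orig_genes[!orig_genes %in% names(project$genes)]
  if (length(gone)) {
    survivor_id <- sort(gone)[1L]
    reuse <- shells[[survivor_id]]
    for (other in sort(gone)[-1L]) reuse <- union_metadata(reuse, shells[[other]])
  }
  placed <- place_transcript(project, merged, username, reuse_gene = reuse)
  project <- placed$project
  project <- record_edit(project, placed$gene_id, username, "merge_transcripts",
                         params = list(a = a_id, b = b_id))
  project$last_edit$transcript_id <- merged$id
  project$last_edit$gene_id <- placed$gene_id
  project
}

# Exon row index (genomic order) for a 0-based exon index in transcript
# (5'->3') order.
exon_row_for_index <- function(t, exon_index) {
  n <- nrow(t$exons)
  if (exon_index < 0L || exon_index >= n)
    af_bounds_error(sprintf("exon index %d out of range for %s (%d exons)",
                            exon_index, t$id, n))
  if (t$strand == "-") n - exon_index else exon_index + 1L
}

#' Split a transcript between two exons
#'
#' Partitions the exon list after the given exon (0-based, transcript
#' order); both products get independent ORF recomputation and gene
#' membership.  The 5' product keeps the original id.
#'
#' @param project Annotation project.
#' @param t_id Transcript id.
#' @param after_exon 0-based exon index in transcript order; the split falls
#'   in the intron that follows it.
#' @param username Editing user.
#' @return Updated project; `project$last_edit$transcript_ids` names both
#'   products (5' first).
#' @export
split_transcript <- function(project, t_id, after_exon, username) {
  check_can_edit(project, username)
  hit <- must_find_transcript(project, t_id)
  t <- hit$transcript
  n <- nrow(t$exons)
  if (n < 2L)
    af_validation_error(sprintf("cannot split single-exon transcript %s", t_id))
  after_exon <- as.integer(after_exon)
  if (after_exon < 0L || after_exon >= n - 1L)
    af_bounds_error(sprintf("split point %d invalid for %d exons", after_exon, n))
  rows_5p <- if (t$strand == "+") seq_len(after_exon + 1L) else
    seq.int(n - after_exon, n)
  minted <- mint_transcript_id(project)
  project <- minted$project
  t1 <- t; t1$exons <- t$exons[sort(rows_5p), , drop = FALSE]
  t2 <- t; t2$id <- minted$id
  t2$exons <- t$exons[setdiff(seq_len(n), rows_5p), , drop = FALSE]
  rownames(t1$exons) <- rownames(t2$exons) <- NULL
  t1$pins <- t2$pins <- list()
  shell <- project$genes[[hit$gene_id]]
  project <- detach_transcript(project, t_id, username)
  t1 <- recompute_transcript_cds(project, t1)
  t2 <- recompute_transcript_cds(project, t2)
  reuse <- if (!hit$gene_id %in% names(project$genes)) shell
  p1 <- place_transcript(project, t1, username, reuse_gene = reuse)
  project <- p1$project
  p2 <- place_transcript(project, t2, username)
  project <- p2$project
  for (gid in unique(c(p1$gene_id, p2$gene_id))) {
    if (!gid %in% names(project$genes)) next
    project <- record_edit(project, gid, username, "split_transcript",
                           params = list(transcript = t_id,
                                         after_exon = after_exon))
  }
  project$last_edit$transcript_ids <- c(t1$id, t2$id)
  project
}

apply_exon_boundary <- function(project, t_id, row, side, value, username,
                                opname, extra_params = list()) {
  hit <- must_find_transcript(project, t_id)
  t <- hit$transcript
  region <- project_region(project, t$seq_id)
  value <- as.integer(value)
  ex <- t$exons
  old <- ex[row, ]
  if (side == "left") {
    if (value >= ex$end[row])
      af_error("af_boundary_error", sprintf(
        "new start %d would invert exon [%d,%d) of %s",
        value, ex$start[row], ex$end[row], t_id))
    if (row > 1L && value < ex$end[row - 1L])
      af_error("af_boundary_error", sprintf(
        "new start %d crosses the neighboring exon of %s", value, t_id))
    if (value < 0L) af_bounds_error(sprintf("start %d below region start", value))
    ex$start[row] <- value
  } else {
    if (value <= ex$start[row])
      af_error("af_boundary_error", sprintf(
        "new end %d would invert exon [%d,%d) of %s",
        value, ex$start[row], ex$end[row], t_id))
    if (row < nrow(ex) && value > ex$start[row + 1L])
      af_error("af_boundary_error", sprintf(
        "new end %d crosses the neighboring exon of %s", value, t_id))
    if (value > region$length)
      af_bounds_error(sprintf("end %d beyond region '%s' (length %d)",
                              value, region$id, region$length))
    ex$end[row] <- value
  }
  t$exons <- coalesce_exons(ex)
  t <- recompute_transcript_cds(project, t)
  g <- project$genes[[hit$gene_id]]
  g$transcripts[[t_id]] <- t
  project$genes[[hit$gene_id]] <- refresh_gene_extent(g)
  params <- c(list(transcript = t_id, side = side,
                   from = as.integer(if (side == "left") old$start else old$end),
                   to = value), extra_params)
  project <- record_edit(project, hit$gene_id, username, opname, params = params)
  project$last_edit$transcript_id <- t_id
  project
}

# Map a (transcript-oriented) edge of an exon to genomic side left/right.
edge_to_side <- function(t, edge) {
  if (!edge %in% c("five_prime", "three_prime"))
    af_usage_error(sprintf("edge must be five_prime or three_prime, got '%s'", edge))
  if (t$strand == "+") {
    if (edge == "five_prime") "left" else "right"
  } else {
    if (edge == "five_prime") "right" else "left"
  }
}

#' Set an exon boundary to an explicit genomic position
#'
#' Drags one edge of one exon.  `edge` is in transcript orientation
#' (`five_prime` / `three_prime`); the new position is the exon's start
#' (inclusive) when the edge is the genomic left, or its end (exclusive)
#' when the edge is the genomic right.  The edit is rejected atomically when
#' it would invert the exon or cross a neighbor; exons left bookended (gap
#' 0) are coalesced; the ORF is recomputed (pinned translation boundaries
#' are honored while they remain inside exons).  A no-op drag still writes
#' an edit record.
#'
#' @param project Annotation project.
#' @param t_id Transcript id.
#' @param exon_index 0-based exon index in transcript order.
#' @param edge `"five_prime"` or `"three_prime"`.
#' @param new_genomic_pos New boundary coordinate (internal 0-based
#'   convention).
#' @param username Editing user.
#' @return Updated project.
#' @export
set_exon_boundary <- function(project, t_id, exon_index, edge,
                              new_genomic_pos, username) {
  check_can_edit(project, username)
  t <- must_find_transcript(project, t_id)$transcript
  row <- exon_row_for_index(t, as.integer(exon_index))
  side <- edge_to_side(t, edge)
  apply_exon_boundary(project, t_id, row, side, new_genomic_pos, username,
                      "set_exon_boundary",
                      extra_params = list(exon_index = as.integer(exon_index),
                                          edge = edge))
}

#' Snap an exon boundary to the nearest splice junction
#'
#' Moves an exon edge to the nearest configured splice site in the requested
#' direction: a 3' exon edge snaps so the following intron *begins* with a
#' donor dinucleotide, a 5' exon edge so the preceding intron *ends* with an
#' acceptor dinucleotide (both read strand-aware).  The search spans the
#' exon body and the flanking gap up to the neighboring exon, capped at
#' 10 kb; if no junction is found the edit is rejected and the project is
#' unchanged.
#'
#' @inheritParams set_exon_boundary
#' @param direction `"upstream"` (toward the transcript 5' end) or
#'   `"downstream"`.
#' @export
snap_exon_boundary <- function(project, t_id, exon_index, edge, direction,
                               username) {
  check_can_edit(project, username)
  if (!direction %in% c("upstream", "downstream"))
    af_usage_error("direction must be upstream or downstream")
  t <- must_find_transcript(project, t_id)$transcript
  region <- project_region(project, t$seq_id)
  config <- project$config
  row <- exon_row_for_index(t, as.integer(exon_index))
  side <- edge_to_side(t, edge)
  ex <- t$exons
  cap <- 10000L
  cur <- if (side == "left") ex$start[row] else ex$end[row]
  # genomic search window for the dinucleotide's leftmost base
  if (side == "right") {
    lo <- max(ex$start[row] + 1L, cur - cap)
    hi <- min(if (row < nrow(ex)) ex$start[row + 1L] else region$length,
              cur + cap)
  } else {
    lo <- max(if (row > 1L) ex$end[row - 1L] else 0L, cur - cap)
    hi <- min(ex$end[row] - 1L, cur + cap)
  }
  lo <- max(lo - 2L, 0L); hi <- min(hi + 2L, region$length)
  if (hi - lo < 2L) af_error("af_no_junction_error", "search window empty")
  want_donor <- (edge == "three_prime")
  hits <- scan_splice_junctions(region, location(t$seq_id, lo, hi, t$strand),
                                config)
  occ <- if (want_donor) hits$donors else hits$acceptors
  # convert dinucleotide occurrence (leftmost base) to candidate boundary value
  cand <- if (t$strand == "+") {
    if (want_donor) occ else occ + 2L        # donor: intron starts at occ; acceptor: exon starts after it
  } else {
    if (want_donor) occ + 2L else occ        # mirrored on the reverse strand
  }
  # direction in genomic terms
  genomic_up <- if (t$strand == "+") direction == "upstream" else direction == "downstream"
  cand <- if (genomic_up) cand[cand < cur] else cand[cand > cur]
  # stay inside validity limits of the boundary
  if (side == "left") {
    lim_lo <- if (row > 1L) ex$end[row - 1L] else 0L
    cand <- cand[cand >= lim_lo & cand < ex$end[row]]
  } else {
    lim_hi <- if (row < nrow(ex)) ex$start[row + 1L] else region$length
    cand <- cand[cand > ex$start[row] & cand <= lim_hi]
  }
  if (!length(cand))
    af_error("af_no_junction_error", sprintf(
      "no %s junction %s of exon %d edge of %s within the search window",
      if (want_donor) "donor" else "acceptor", direction, exon_index, t_id))
  value <- cand[which.min(abs(cand - cur))]
  apply_exon_boundary(project, t_id, row, side, value, username,
                      "snap_exon_boundary",
                      extra_params = list(exon_index = as.integer(exon_index),
                                          edge = edge, direction = direction))
}

#' Pin a translation boundary
#'
#' Pins the CDS start (first coding base) or end (last coding base,
#' stop-codon inclusive) at a genomic position inside an exon; the other
#' boundary is recomputed: with the start pinned the CDS runs to the first
#' in-frame stop (or, partial, to the transcript end); with the end pinned
#' the 5'-most in-frame start codon with a clean reading frame is chosen.
#' Pins survive later structural edits while the pinned base stays inside an
#' exon; otherwise they are dropped with a notice and the ORF recomputed.
#'
#' @param project Annotation project.
#' @param t_id Transcript id.
#' @param which `"start"` or `"end"`.
#' @param genomic_pos Genomic base (0-based) of the first / last CDS base.
#' @param username Editing user.
#' @export
set_translation_boundary <- function(project, t_id, which, genomic_pos,
                                     username) {
  check_can_edit(project, username)
  if (!which %in% c("start", "end"))
    af_usage_error("which must be 'start' or 'end'")
  hit <- must_find_transcript(project, t_id)
  t <- hit$transcript
  genomic_pos <- as.integer(genomic_pos)
  if (is.na(tx_genomic_to_spliced(t, genomic_pos)))
    af_error("af_invalid_position_error", sprintf(
      "position %d is not inside an exon of %s", genomic_pos, t_id))
  t$pins[[which]] <- genomic_pos
  t <- recompute_transcript_cds(project, t)
  g <- project$genes[[hit$gene_id]]
  g$transcripts[[t_id]] <- t
  project$genes[[hit$gene_id]] <- refresh_gene_extent(g)
  project <- record_edit(project, hit$gene_id, username,
                         "set_translation_boundary",
                         params = list(transcript = t_id, which = which,
                                       position = genomic_pos))
  project$last_edit$transcript_id <- t_id
  project
}

#' Flip a transcript's strand
#'
#' Toggles the strand, reinterprets exon order, drops any translation pins
#' (their reading frame is meaningless on the other strand), recomputes the
#' ORF on the new strand and re-evaluates gene membership.
#'
#' @param project Annotation project.
#' @param t_id Transcript id.
#' @param username Editing user.
#' @export
flip_strand <- function(project, t_id, username) {
  check_can_edit(project, username)
  hit <- must_find_transcript(project, t_id)
  t <- hit$transcript
  t$strand <- if (t$strand == "+") "-" else "+"
  if (length(t$pins)) {
    af_notice("transcript ", t_id, ": translation pins dropped on strand flip")
    t$pins <- list()
  }
  shell <- project$genes[[hit$gene_id]]
  project <- detach_transcript(project, t_id, username)
  t <- recompute_transcript_cds(project, t)
  reuse <- if (!hit$gene_id %in% names(project$genes)) shell
  placed <- place_transcript(project, t, username, reuse_gene = reuse)
  project <- placed$project
  project <- record_edit(project, placed$gene_id, username, "flip_strand",
                         params = list(transcript = t_id))
  project$last_edit$transcript_id <- t_id
  project$last_edit$gene_id <- placed$gene_id
  project
}
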