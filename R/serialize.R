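# Canonical JSON codec for the model.  The same codec serves project
# persistence (CLI project directories) and history snapshots, and is built
# so that deserialize(serialize(x)) reproduces x exactly (including integer
# types, empty vectors and field order), which the test suite asserts.

ser_transcript <- function(t) {
  out <- list(id = t$id, type = t$type, seq_id = t$seq_id, strand = t$strand,
              exon_starts = I(t$exons$start), exon_ends = I(t$exons$end))
  if (!is.null(t$cds)) out$cds <- I(t$cds)
  out$partial <- t$partial
  out$owner <- t$owner
  if (!is.null(t$name)) out$name <- t$name
  out$needs_review <- t$needs_review
  pins <- list()
  if (!is.null(t$pins$start)) pins$start <- t$pins$start
  if (!is.null(t$pins$end)) pins$end <- t$pins$end
  out$pins <- pins
  out
}

deser_transcript <- function(x) {
  pins <- list()
  if (!is.null(x$pins$start)) pins$start <- as.integer(x$pins$start)
  if (!is.null(x$pins$end)) pins$end <- as.integer(x$pins$end)
  structure(
    list(id = x$id, type = x$type, seq_id = x$seq_id, strand = x$strand,
         exons = data.frame(start = as.integer(unlist(x$exon_starts)),
                            end = as.integer(unlist(x$exon_ends))),
         cds = if (!is.null(x$cds)) as.integer(unlist(x$cds)),
         partial = isTRUE(x$partial), owner = x$owner,
         name = x$name, needs_review = isTRUE(x$needs_review), pins = pins),
    class = "transcript"
  )
}

ser_gene <- function(g) {
  list(id = g$id, symbol = g$symbol, description = g$description,
       dbxrefs = I(g$dbxrefs), go_terms = I(g$go_terms),
       publications = I(g$publications), comments = I(g$comments),
       transcripts = lapply(unname(g$transcripts), ser_transcript),
       owner = g$owner, seq_id = g$seq_id, strand = g$strand,
       start = g$start, end = g$end)
}

deser_gene <- function(x) {
  txs <- lapply(x$transcripts, deser_transcript)
  names(txs) <- vapply(txs, `[[`, character(1), "id")
  chr0 <- function(v) as.character(unlist(v) %||% character(0))
  structure(
    list(id = x$id, symbol = x$symbol, description = x$description,
         dbxrefs = chr0(x$dbxrefs), go_terms = chr0(x$go_terms),
         publications = chr0(x$publications), comments = chr0(x$comments),
         transcripts = txs, owner = x$owner, seq_id = x$seq_id,
         strand = x$strand, start = as.integer(x$start),
         end = as.integer(x$end)),
    class = "gene"
  )
}

ser_record <- function(r) {
  list(version = r$version, username = r$username, timestamp = r$timestamp,
       operation = r$operation, params = r$params,
       snapshot = ser_gene(r$snapshot))
}

deser_record <- function(x) {
  structure(
    list(version = as.integer(x$version), username = x$username,
         timestamp = x$timestamp, operation = x$operation,
         params = x$params %||% list(), snapshot = deser_gene(x$snapshot)),
    class = "edit_record"
  )
}

#' Serialize / restore a project as JSON
#'
#' A complete, inspectable JSON form of the project (regions, genes,
#' evidence, alterations, users, config, history with full snapshots,
#' counters).  `project_save()`/`project_load()` wrap these around a project
#' directory, which is how the CLI persists state between invocations.
#'
#' @param project Annotation project.
#' @return `serialize_project`: JSON text.
#' @export
serialize_project <- function(project) {
  cfg <- project$config
  doc <- list(
    format = list(name = "annoforge-project", version = "1.0"),
    config = list(
      donor_sites = I(cfg$donor_sites), acceptor_sites = I(cfg$acceptor_sites),
      translation_table = cfg$translation_table,
      undo_depth = if (is.infinite(cfg$undo_depth)) "unlimited" else cfg$undo_depth,
      isoform_strategy = cfg$isoform_strategy,
      timestamp_mode = cfg$timestamp_mode),
    users = lapply(unname(project$users), function(u)
      list(username = u$username, role = u$role)),
    regions = lapply(unname(project$regions), function(r)
      list(id = r$id, residues = r$residues)),
    genes = lapply(unname(project$genes), ser_gene),
    evidence = lapply(unname(project$evidence), function(e)
      list(id = e$id, seq_id = e$seq_id, strand = e$strand,
           block_starts = I(e$blocks$start), block_ends = I(e$blocks$end),
           source_track = e$source_track, name = e$name)),
    alterations = lapply(project$alterations, function(a)
      list(kind = a$kind, seq_id = a$seq_id, position = a$position,
           ref_residues = a$ref_residues, alt_residues = a$alt_residues,
           category = a$category, id = a$id)),
    history = list(
      features = lapply(project$history$features, function(h)
        list(cursor = h$cursor, records = lapply(h$records, ser_record))),
      log = project$history$log),
    counters = project$counters
  )
  as.character(jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA,
                                null = "null"))
}

#' @rdname serialize_project
#' @param json JSON text produced by `serialize_project`.
#' @export
deserialize_project <- function(json) {
  x <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  cfg <- x$config
  config <- organism_config(
    donor_sites = as.character(unlist(cfg$donor_sites)),
    acceptor_sites = as.character(unlist(cfg$acceptor_sites)),
    translation_table = as.integer(cfg$translation_table),
    undo_depth = if (identical(cfg$undo_depth, "unlimited")) Inf
                 else as.numeric(cfg$undo_depth),
    isoform_strategy = cfg$isoform_strategy,
    timestamp_mode = cfg$timestamp_mode)
  users <- lapply(x$users, function(u) user(u$username, u$role))
  regions <- lapply(x$regions, function(r) seq_region(r$id, r$residues))
  project <- new_project(regions, config, users)
  genes <- lapply(x$genes, deser_gene)
  names(genes) <- vapply(genes, `[[`, character(1), "id")
  project$genes <- genes
  ev <- lapply(x$evidence, function(e) evidence_feature(
    e$id, e$seq_id,
    data.frame(start = as.integer(unlist(e$block_starts)),
               end = as.integer(unlist(e$block_ends))),
    strand = e$strand, source_track = e$source_track, name = e$name))
  names(ev) <- vapply(ev, `[[`, character(1), "id")
  project$evidence <- ev
  project$alterations <- lapply(x$alterations, function(a) sequence_alteration(
    a$kind, a$seq_id, as.integer(a$position),
    ref_residues = a$ref_residues %||% "",
    alt_residues = a$alt_residues %||% "",
    category = a$category, id = a$id))
  project$history$features <- lapply(x$history$features, function(h)
    list(records = lapply(h$records, deser_record),
         cursor = as.integer(h$cursor)))
  project$history$log <- lapply(x$history$log, function(l)
    list(feature_id = l$feature_id, version = as.integer(l$version),
         username = l$username, timestamp = l$timestamp,
         operation = l$operation))
  project$counters <- list(gene = as.integer(x$counters$gene),
                           transcript = as.integer(x$counters$transcript),
                           edit = as.integer(x$counters$edit))
  project
}

#' @rdname serialize_project
#' @param dir Project directory (created by `project_save` if needed).
#' @export
project_save <- function(project, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeLines(serialize_project(project), file.path(dir, "project.json"))
  invisible(dir)
}

#' @rdname serialize_project
#' @export
project_load <- function(dir) {
  path <- file.path(dir, "project.json")
  if (!file.exists(path))
    af_not_found_error(sprintf("no project at '%s'", dir))
  deserialize_project(paste(readLines(path), collapse = "\n"))
}
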