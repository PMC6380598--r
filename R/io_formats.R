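# Readers and writers for the standard formats the engine touches.
# Internal coordinates are 0-based half-open; GFF3/GenBank/VCF are 1-based
# inclusive and converted exactly at this boundary; BED is natively 0-based
# half-open and kept as-is.  Writers are deterministic (sorted output, fixed
# attribute ordering) so identical sessions export identical bytes, and each
# export declares its dialect for reproducibility.

GFF3_DIALECT <- "#!annoforge-dialect gff3/1.0 reserved=owner,date_creation,date_last_modified,status,partial"

TX_TYPE_TO_SO <- c(protein_coding = "mRNA", non_coding = "ncRNA",
                   pseudogene_transcript = "pseudogenic_transcript",
                   repeat_region = "repeat_region",
                   transposable_element = "transposable_element")
SO_TO_TX_TYPE <- stats::setNames(names(TX_TYPE_TO_SO), TX_TYPE_TO_SO)
EVIDENCE_SO_TYPES <- c("match", "cDNA_match", "EST_match", "protein_match",
                       "translated_nucleotide_match")

# ---- FASTA ----------------------------------------------------------------

#' Read / write reference sequences as FASTA
#'
#' Ids are the first whitespace-delimited token of each header.  Lowercase
#' residues are uppercased on load.  Writing wraps at 60 columns, so a
#' read/write cycle is a fixed point on canonical files.
#'
#' @param path File path.
#' @return `read_fasta`: named list of [seq_region()].
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  if (!length(ss)) af_format_error(sprintf("empty FASTA input '%s'", path))
  ids <- vapply(strsplit(names(ss), "[ \t]"), `[[`, character(1), 1L)
  if (anyDuplicated(ids))
    af_format_error(sprintf("duplicate FASTA ids: %s",
                            paste(unique(ids[duplicated(ids)]), collapse = ",")))
  regions <- lapply(seq_along(ss), function(i)
    seq_region(ids[i], as.character(ss[[i]])))
  stats::setNames(regions, ids)
}

#' @rdname read_fasta
#' @param regions List of [seq_region()].
#' @export
write_fasta <- function(regions, path) {
  ss <- Biostrings::DNAStringSet(vapply(regions, `[[`, character(1), "residues"))
  names(ss) <- vapply(regions, `[[`, character(1), "id")
  Biostrings::writeXStringSet(ss, path, width = 60L)
  invisible(path)
}

# ---- GFF3 -----------------------------------------------------------------

gff3_escape <- function(x) {
  x <- gsub("%", "%25", x, fixed = TRUE)
  x <- gsub(";", "%3B", x, fixed = TRUE)
  x <- gsub("=", "%3D", x, fixed = TRUE)
  x <- gsub(",", "%2C", x, fixed = TRUE)
  gsub("\t", "%09", x, fixed = TRUE)
}

gff3_attrs <- function(pairs) {
  keep <- !vapply(pairs, function(v) is.null(v) || !length(v) ||
                    all(!nzchar(as.character(v))), logical(1))
  pairs <- pairs[keep]
  if (!length(pairs)) return(".")
  paste(vapply(names(pairs), function(k)
    paste0(k, "=", paste(gff3_escape(as.character(pairs[[k]])), collapse = ",")),
    character(1)), collapse = ";")
}

gff3_line <- function(seqid, source, type, start0, end0, score = ".",
                      strand = ".", phase = ".", attrs = ".") {
  paste(seqid, source, type, start0 + 1L, end0, score, strand, phase, attrs,
        sep = "\t")
}

# CDS pieces of a transcript with GFF3 phase, in genomic order.
cds_pieces_with_phase <- function(t) {
  if (is.null(t$cds)) return(NULL)
  ex <- t$exons
  piece_start <- pmax(ex$start, t$cds[1L])
  piece_end <- pmin(ex$end, t$cds[2L])
  keep <- piece_start < piece_end
  pieces <- data.frame(start = piece_start[keep], end = piece_end[keep])
  ord_5to3 <- if (t$strand == "-") rev(seq_len(nrow(pieces))) else seq_len(nrow(pieces))
  cum <- 0L
  phase <- integer(nrow(pieces))
  for (i in ord_5to3) {
    phase[i] <- (3L - cum %% 3L) %% 3L
    cum <- cum + pieces$end[i] - pieces$start[i]
  }
  pieces$phase <- phase
  pieces
}

gene_dates <- function(project, gid) {
  h <- project$history$features[[gid]]
  if (is.null(h) || !length(h$records)) return(list(created = NULL, modified = NULL))
  list(created = h$records[[1L]]$timestamp,
       modified = h$records[[length(h$records)]]$timestamp)
}

#' Write a project as GFF3
#'
#' Emits the gene -> mRNA -> exon/CDS hierarchy via ID/Parent with 1-based
#' inclusive coordinates, CDS phase recomputed from the reading frame, and
#' curation provenance in the reserved attributes `owner`, `date_creation`,
#' `date_last_modified`, `status` and `partial`.  Evidence features are
#' written as match/match_part records.  Output is deterministically sorted
#' by (region, start, ID).
#'
#' @param project Annotation project.
#' @param path Output file.
#' @param include_evidence Also write loaded evidence features.
#' @export
write_gff3 <- function(project, path, include_evidence = TRUE) {
  lines <- c("##gff-version 3", GFF3_DIALECT)
  for (rid in sort(names(project$regions))) {
    lines <- c(lines, sprintf("##sequence-region %s 1 %d", rid,
                              project$regions[[rid]]$length))
  }
  genes <- project$genes
  if (length(genes)) {
    ord <- order(vapply(genes, `[[`, character(1), "seq_id"),
                 vapply(genes, `[[`, integer(1), "start"),
                 vapply(genes, `[[`, character(1), "id"))
    genes <- genes[ord]
  }
  for (g in genes) {
    dates <- gene_dates(project, g$id)
    lines <- c(lines, gff3_line(
      g$seq_id, "annoforge", "gene", g$start, g$end, strand = g$strand,
      attrs = gff3_attrs(list(
        ID = g$id, Name = g$symbol, description = g$description,
        Dbxref = g$dbxrefs, Ontology_term = g$go_terms,
        publication = g$publications, Note = g$comments, owner = g$owner,
        date_creation = dates$created, date_last_modified = dates$modified))))
    txs <- g$transcripts
    tord <- order(vapply(txs, function(t) tx_extent(t)[1L], integer(1)),
                  vapply(txs, `[[`, character(1), "id"))
    for (t in txs[tord]) {
      lines <- c(lines, gff3_line(
        t$seq_id, "annoforge", TX_TYPE_TO_SO[[t$type]],
        tx_extent(t)[1L], tx_extent(t)[2L], strand = t$strand,
        attrs = gff3_attrs(list(
          ID = t$id, Parent = g$id, Name = t$name, owner = t$owner,
          status = if (t$needs_review) "needs_review",
          partial = if (t$partial) "true"))))
      for (i in seq_len(nrow(t$exons))) {
        lines <- c(lines, gff3_line(
          t$seq_id, "annoforge", "exon", t$exons$start[i], t$exons$end[i],
          strand = t$strand,
          attrs = gff3_attrs(list(ID = sprintf("%s.exon%d", t$id, i),
                                  Parent = t$id))))
      }
      pieces <- cds_pieces_with_phase(t)
      for (i in seq_len(NROW(pieces))) {
        lines <- c(lines, gff3_line(
          t$seq_id, "annoforge", "CDS", pieces$start[i], pieces$end[i],
          strand = t$strand, phase = pieces$phase[i],
          attrs = gff3_attrs(list(ID = sprintf("%s.cds", t$id),
                                  Parent = t$id))))
      }
    }
  }
  if (include_evidence && length(project$evidence)) {
    evs <- project$evidence
    eord <- order(vapply(evs, `[[`, character(1), "seq_id"),
                  vapply(evs, function(e) e$blocks$start[1L], integer(1)),
                  vapply(evs, `[[`, character(1), "id"))
    for (e in evs[eord]) {
      lines <- c(lines, gff3_line(
        e$seq_id, e$source_track, "match",
        min(e$blocks$start), max(e$blocks$end), strand = e$strand,
        attrs = gff3_attrs(list(ID = e$id, Name = e$name))))
      for (i in seq_len(nrow(e$blocks))) {
        lines <- c(lines, gff3_line(
          e$seq_id, e$source_track, "match_part",
          e$blocks$start[i], e$blocks$end[i], strand = e$strand,
          attrs = gff3_attrs(list(ID = sprintf("%s.part%d", e$id, i),
                                  Parent = e$id))))
      }
    }
  }
  writeLines(lines, path)
  invisible(path)
}

mcol_chr <- function(mc, i, col) {
  if (!col %in% names(mc)) return(NULL)
  v <- mc[[col]][i]
  if (methods::is(v, "List") || is.list(v)) v <- unlist(v)
  v <- as.character(v)
  v <- v[!is.na(v)]
  if (!length(v)) NULL else v
}

#' Read annotations and evidence from GFF3
#'
#' Parses a gene -> mRNA -> exon/CDS hierarchy (via ID/Parent) into the
#' nested model and match/match_part records into evidence features.
#' 1-based inclusive coordinates are converted to the internal 0-based
#' half-open convention; the CDS span is taken from the CDS rows (phase is
#' recomputed on write); reserved attributes restore owner, partial and
#' review status.
#'
#' @param path GFF3 file.
#' @param regions Optional named list of [seq_region()] for bounds checking.
#' @return `list(genes = named list of gene, evidence = named list of
#'   evidence_feature)`.
#' @export
read_gff3 <- function(path, regions = NULL) {
  gr <- rtracklayer::import(path, format = "gff3")
  mc <- S4Vectors::mcols(gr)
  n <- length(gr)
  ids <- as.character(mc$ID)
  types <- as.character(mc$type)
  parents <- lapply(seq_len(n), function(i) mcol_chr(mc, i, "Parent"))
  known <- ids[!is.na(ids)]
  dangling <- setdiff(unlist(parents), known)
  if (length(dangling))
    af_format_error(sprintf("dangling Parent id(s) in '%s': %s", path,
                            paste(sort(dangling), collapse = ",")))
  starts0 <- BiocGenerics::start(gr) - 1L
  ends0 <- BiocGenerics::end(gr)
  seqids <- as.character(GenomicRanges::seqnames(gr))
  strands <- as.character(BiocGenerics::strand(gr))
  if (!is.null(regions)) {
    for (i in seq_len(n)) {
      r <- regions[[seqids[i]]]
      if (!is.null(r) && (starts0[i] < 0L || ends0[i] > r$length))
        af_bounds_error(sprintf(
          "feature %s [%d,%d) out of bounds for region '%s'",
          ids[i] %||% types[i], starts0[i], ends0[i], seqids[i]))
    }
  }
  children_of <- function(pid, want_types) {
    which(vapply(parents, function(p) pid %in% p, logical(1)) &
            types %in% want_types)
  }
  genes <- list()
  for (gi in which(types == "gene")) {
    gid <- ids[gi]
    txs <- list()
    for (ti in children_of(gid, names(SO_TO_TX_TYPE))) {
      tid <- ids[ti]
      exon_rows <- children_of(tid, "exon")
      cds_rows <- children_of(tid, "CDS")
      exons <- data.frame(start = starts0[exon_rows], end = ends0[exon_rows])
      if (!nrow(exons))
        exons <- data.frame(start = starts0[ti], end = ends0[ti])
      cds <- NULL
      partial <- identical(mcol_chr(mc, ti, "partial"), "true")
      if (length(cds_rows)) {
        cds <- c(min(starts0[cds_rows]), max(ends0[cds_rows]))
        cds_len <- sum(ends0[cds_rows] - starts0[cds_rows])
        if (cds_len %% 3L != 0L && !partial)
          warning(sprintf("CDS of %s has length %d (not divisible by 3) without a partial flag",
                          tid, cds_len), call. = FALSE)
      }
      t <- transcript(tid, seqids[ti], strands[ti], exons,
                      type = SO_TO_TX_TYPE[[types[ti]]], cds = cds,
                      partial = partial,
                      owner = mcol_chr(mc, ti, "owner") %||% "unknown",
                      name = mcol_chr(mc, ti, "Name"))
      t$needs_review <- identical(mcol_chr(mc, ti, "status"), "needs_review")
      txs[[tid]] <- t
    }
    if (!length(txs)) next
    genes[[gid]] <- gene(
      gid, txs,
      symbol = mcol_chr(mc, gi, "Name"),
      description = mcol_chr(mc, gi, "description"),
      dbxrefs = mcol_chr(mc, gi, "Dbxref") %||% character(0),
      go_terms = mcol_chr(mc, gi, "Ontology_term") %||% character(0),
      publications = mcol_chr(mc, gi, "publication") %||% character(0),
      comments = mcol_chr(mc, gi, "Note") %||% character(0),
      owner = mcol_chr(mc, gi, "owner") %||% "unknown")
  }
  evidence <- list()
  for (ei in which(types %in% EVIDENCE_SO_TYPES)) {
    eid <- ids[ei]
    part_rows <- children_of(eid, "match_part")
    blocks <- if (length(part_rows)) {
      data.frame(start = starts0[part_rows], end = ends0[part_rows])
    } else {
      data.frame(start = starts0[ei], end = ends0[ei])
    }
    evidence[[eid]] <- evidence_feature(
      eid, seqids[ei], blocks,
      strand = if (strands[ei] %in% c("+", "-")) strands[ei] else NA,
      source_track = as.character(mc$source[ei]),
      name = mcol_chr(mc, ei, "Name"))
  }
  list(genes = genes, evidence = evidence)
}

# ---- VCF ------------------------------------------------------------------

#' Read sequence alterations from a VCF
#'
#' SNV, insertion and deletion records are normalized to the internal pure
#' form: the shared anchor/context bases of each REF/ALT pair are stripped
#' and the position adjusted, so a VCF deletion `POS=5 REF=CTTT ALT=C`
#' becomes a deletion of `TTT` at internal (0-based) position 5.
#' Multi-allelic records are split into one alteration per ALT; symbolic or
#' breakend alleles are skipped with a logged count.
#'
#' @param path VCF 4.x file (site-only or single-sample).
#' @param category `"variant"` or `"assembly_correction"` for all records, or
#'   `"auto"` to take each record's `CATEGORY` INFO tag (defaulting to
#'   variant when absent).
#' @param regions Optional named list of [seq_region()]; REF alleles are
#'   checked against the sequence and a mismatch raises a reference-check
#'   error.
#' @return List of [sequence_alteration()].
#' @export
read_vcf_alterations <- function(path, category = "variant", regions = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- v@fix
  out <- list()
  skipped <- 0L
  for (i in seq_len(nrow(fix))) {
    chrom <- unname(fix[i, "CHROM"]); pos1 <- as.integer(fix[i, "POS"])
    ref <- toupper(unname(fix[i, "REF"]))
    vid <- unname(fix[i, "ID"])
    if (is.na(vid) || vid == ".") vid <- NULL
    cat_i <- category
    if (identical(category, "auto")) {
      info <- unname(fix[i, "INFO"])
      m <- regmatches(info, regexpr("CATEGORY=[A-Za-z_]+", info))
      cat_i <- if (length(m) && nzchar(m)) sub("CATEGORY=", "", m) else "variant"
    }
    for (alt in strsplit(toupper(unname(fix[i, "ALT"])), ",", fixed = TRUE)[[1L]]) {
      if (grepl("[<>\\[\\]*.]", alt)) { skipped <- skipped + 1L; next }
      r <- ref; a <- alt; p0 <- pos1 - 1L
      # strip common prefix, then common suffix
      while (nchar(r) && nchar(a) && substr(r, 1L, 1L) == substr(a, 1L, 1L)) {
        r <- substr(r, 2L, nchar(r)); a <- substr(a, 2L, nchar(a)); p0 <- p0 + 1L
      }
      while (nchar(r) && nchar(a) &&
             substr(r, nchar(r), nchar(r)) == substr(a, nchar(a), nchar(a))) {
        r <- substr(r, 1L, nchar(r) - 1L); a <- substr(a, 1L, nchar(a) - 1L)
      }
      if (!nchar(r) && !nchar(a)) next  # REF == ALT, no-op record
      kind <- if (!nchar(r)) "insertion" else if (!nchar(a)) "deletion"
              else "substitution"
      if (kind == "substitution" && nchar(r) != nchar(a)) {
        # complex allele: represent as deletion+insertion is out of scope;
        # treat as block substitution only when lengths match
        skipped <- skipped + 1L; next
      }
      if (!is.null(regions)) {
        reg <- regions[[chrom]]
        if (!is.null(reg) && nchar(r)) {
          have <- substr(reg$residues, p0 + 1L, p0 + nchar(r))
          if (!identical(have, r))
            af_error("af_refcheck_error", sprintf(
              "VCF REF mismatch at %s:%d: file says '%s', sequence has '%s'",
              chrom, pos1, r, have))
        }
      }
      out[[length(out) + 1L]] <- sequence_alteration(
        kind, chrom, p0, ref_residues = r, alt_residues = a,
        category = cat_i, id = vid)
    }
  }
  if (skipped) af_notice(skipped, " symbolic/complex allele(s) skipped")
  out
}

# ---- BED ------------------------------------------------------------------

#' Read evidence features from BED6/BED12
#'
#' BED12 blocks become evidence blocks; BED's native 0-based half-open
#' coordinates match the internal convention and are kept as-is.
#'
#' @param path BED file.
#' @param source_track Track name recorded on each feature (defaults to the
#'   file's base name).
#' @return Named list of [evidence_feature()].
#' @export
read_bed_evidence <- function(path, source_track = NULL) {
  source_track <- source_track %||% tools::file_path_sans_ext(basename(path))
  gr <- tryCatch(rtracklayer::import(path, format = "bed"),
                 error = function(e) af_format_error(
                   sprintf("malformed BED '%s': %s", path, conditionMessage(e))))
  mc <- S4Vectors::mcols(gr)
  out <- list()
  for (i in seq_along(gr)) {
    ext_start <- BiocGenerics::start(gr)[i] - 1L
    ext_end <- BiocGenerics::end(gr)[i]
    if ("blocks" %in% names(mc) && length(mc$blocks[[i]])) {
      bl <- mc$blocks[[i]]
      blocks <- data.frame(start = ext_start + BiocGenerics::start(bl) - 1L,
                           end = ext_start + BiocGenerics::end(bl))
      if (min(blocks$start) != ext_start || max(blocks$end) != ext_end)
        af_format_error(sprintf(
          "BED line %d: blocks do not tile the feature extent [%d,%d)",
          i, ext_start, ext_end))
    } else {
      blocks <- data.frame(start = ext_start, end = ext_end)
    }
    nm <- if ("name" %in% names(mc) && !is.na(mc$name[i])) mc$name[i] else
      sprintf("%s_%d", source_track, i)
    id <- nm
    k <- 1L
    while (id %in% names(out)) { k <- k + 1L; id <- sprintf("%s.%d", nm, k) }
    strand <- as.character(BiocGenerics::strand(gr)[i])
    out[[id]] <- evidence_feature(
      id, as.character(GenomicRanges::seqnames(gr))[i], blocks,
      strand = if (strand %in% c("+", "-")) strand else NA,
      source_track = source_track, name = nm)
  }
  out
}

# ---- GenBank --------------------------------------------------------------

gb_location <- function(pieces, strand) {
  segs <- sprintf("%d..%d", pieces$start + 1L, pieces$end)
  loc <- if (length(segs) == 1L) segs else
    sprintf("join(%s)", paste(segs, collapse = ","))
  if (strand == "-") sprintf("complement(%s)", loc) else loc
}

gb_feature <- function(key, loc, quals = list()) {
  wrap <- function(text, first_prefix) {
    width <- 79L
    out <- character(0)
    line <- first_prefix
    avail <- width - nchar(line)
    while (nchar(text) > avail) {
      cut <- avail
      out <- c(out, paste0(line, substr(text, 1L, cut)))
      text <- substr(text, cut + 1L, nchar(text))
      line <- strrep(" ", 21L)
      avail <- width - 21L
    }
    c(out, paste0(line, text))
  }
  lines <- wrap(loc, sprintf("     %-16s", key))
  for (k in names(quals)) {
    v <- quals[[k]]
    if (is.null(v)) next
    text <- if (isTRUE(v)) sprintf("/%s", k) else sprintf('/%s="%s"', k, v)
    lines <- c(lines, wrap(text, strrep(" ", 21L)))
  }
  lines
}

#' Write one annotated region as a GenBank flatfile
#'
#' Genes become `gene` features, transcripts `mRNA` features with `join()`
#' locations (reverse strand as `complement(join(...))`), and CDS features
#' carry a `/translation` computed from the spliced coding sequence.
#' Coordinates are 1-based inclusive.
#'
#' @param project Annotation project.
#' @param region_id Region to export.
#' @param path Output file.
#' @export
write_genbank <- function(project, region_id, path) {
  region <- project_region(project, region_id)
  stamp <- af_timestamp(project$config, project$counters$edit)
  date <- toupper(format(as.Date(substr(stamp, 1L, 10L)), "%d-%b-%Y"))
  lines <- c(
    sprintf("LOCUS       %-16s %d bp    DNA     linear   UNA %s",
            substr(region_id, 1L, 16L), region$length, date),
    sprintf("DEFINITION  %s.", region_id),
    sprintf("ACCESSION   %s", region_id),
    "COMMENT     annoforge-dialect genbank/1.0.",
    "FEATURES             Location/Qualifiers",
    gb_feature("source", sprintf("1..%d", region$length))
  )
  genes <- Filter(function(g) identical(g$seq_id, region_id), project$genes)
  if (length(genes)) {
    ord <- order(vapply(genes, `[[`, integer(1), "start"),
                 vapply(genes, `[[`, character(1), "id"))
    genes <- genes[ord]
  }
  table <- project$config$codon_table
  for (g in genes) {
    lines <- c(lines, gb_feature(
      "gene", gb_location(data.frame(start = g$start, end = g$end), g$strand),
      list(gene = g$id, note = g$symbol)))
    txs <- g$transcripts
    tord <- order(vapply(txs, function(t) tx_extent(t)[1L], integer(1)),
                  vapply(txs, `[[`, character(1), "id"))
    for (t in txs[tord]) {
      key <- if (t$type == "protein_coding") "mRNA" else "misc_RNA"
      lines <- c(lines, gb_feature(
        key, gb_location(t$exons, t$strand),
        list(gene = g$id, standard_name = t$id)))
      if (!is.null(t$cds)) {
        pieces <- cds_pieces_with_phase(t)
        translation <- translate_cds(tx_cds_sequence(region, t), table)
        lines <- c(lines, gb_feature(
          "CDS", gb_location(pieces, t$strand),
          list(gene = g$id, standard_name = t$id, codon_start = "1",
               translation = translation)))
      }
    }
  }
  lines <- c(lines, "ORIGIN")
  res <- tolower(region$residues)
  for (off in seq.int(0L, region$length - 1L, by = 60L)) {
    chunk <- substr(res, off + 1L, min(off + 60L, region$length))
    tens <- substring(chunk, seq(1L, nchar(chunk), 10L),
                      pmin(seq(10L, nchar(chunk) + 9L, 10L), nchar(chunk)))
    lines <- c(lines, sprintf("%9d %s", off + 1L, paste(tens, collapse = " ")))
  }
  lines <- c(lines, "//")
  writeLines(lines, path)
  invisible(path)
}

# ---- JSON snippet ---------------------------------------------------------

tx_to_json_list <- function(t) {
  out <- list(id = t$id, type = t$type)
  if (!is.null(t$name)) out$name <- t$name
  out$owner <- t$owner
  out$partial <- t$partial
  out$needs_review <- t$needs_review
  out$start <- tx_extent(t)[1L]
  out$end <- tx_extent(t)[2L]
  out$exons <- lapply(seq_len(nrow(t$exons)), function(i)
    list(start = t$exons$start[i], end = t$exons$end[i]))
  if (!is.null(t$cds)) out$cds <- list(start = t$cds[1L], end = t$cds[2L])
  out
}

gene_to_json_list <- function(g) {
  out <- list(id = g$id)
  if (!is.null(g$symbol)) out$symbol <- g$symbol
  if (!is.null(g$description)) out$description <- g$description
  out$seq_id <- g$seq_id
  out$strand <- g$strand
  out$start <- g$start
  out$end <- g$end
  out$owner <- g$owner
  if (length(g$dbxrefs)) out$dbxrefs <- as.list(g$dbxrefs)
  if (length(g$go_terms)) out$go_terms <- as.list(g$go_terms)
  if (length(g$publications)) out$publications <- as.list(g$publications)
  if (length(g$comments)) out$comments <- as.list(g$comments)
  txs <- g$transcripts[order(names(g$transcripts))]
  out$transcripts <- lapply(unname(txs), tx_to_json_list)
  out
}

#' Export features as a compact JSON snippet
#'
#' Serves a gene (or every gene overlapping a genomic window) as a compact
#' JSON document — gene -> transcripts -> exons/CDS with coordinates,
#' strand and names — with stable key ordering so the output is
#' byte-reproducible.  Giving a transcript id exports its gene.
#'
#' @param project Annotation project.
#' @param feature_id Gene or transcript id (mutually exclusive with
#'   `window`).
#' @param window A [location()] (or list with seq_id/start/end); all
#'   overlapping genes are exported and the window echoed.
#' @return JSON text (character scalar).
#' @export
export_feature_json <- function(project, feature_id = NULL, window = NULL) {
  doc <- list(dialect = list(format = "annoforge-json", version = "1.0"))
  if (!is.null(feature_id)) {
    g <- project$genes[[feature_id]]
    if (is.null(g)) {
      hit <- find_transcript(project, feature_id)
      if (is.null(hit))
        af_not_found_error(sprintf("no feature '%s' in project", feature_id))
      g <- project$genes[[hit$gene_id]]
    }
    doc$features <- list(gene_to_json_list(g))
  } else if (!is.null(window)) {
    doc$window <- list(seq_id = window$seq_id,
                       start = as.integer(window$start),
                       end = as.integer(window$end))
    hits <- Filter(function(g)
      identical(g$seq_id, window$seq_id) &&
        g$start < window$end && window$start < g$end, project$genes)
    hits <- hits[order(names(hits))]
    doc$features <- lapply(unname(hits), gene_to_json_list)
  } else {
    af_usage_error("export_feature_json needs feature_id or window")
  }
  as.character(jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA,
                                null = "null"))
}

# ---- declared-unsupported formats ----------------------------------------

unsupported_format <- function(what) {
  af_format_error(sprintf(
    "%s support is not implemented in this release; use GFF3/BED/VCF/FASTA",
    what))
}

#' @rdname read_fasta
#' @export
read_gtf <- function(path) unsupported_format("GTF")
#' @rdname read_fasta
#' @export
read_gvf <- function(path) unsupported_format("GVF")
#' @rdname read_fasta
#' @export
read_bam_evidence <- function(path) unsupported_format("BAM evidence")
#' @rdname read_fasta
#' @export
read_bigwig_evidence <- function(path) unsupported_format("BigWig evidence")
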