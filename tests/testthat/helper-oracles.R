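# Independent reference implementations (oracles) and small builders used
# across the suite.  Oracles are deliberately naive: exhaustive enumeration
# and base-by-base bookkeeping, sharing no code path with the engine.

rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

mk_region <- function(res, id = "chr") seq_region(id, res)

# Exhaustive ORF oracle: every (start codon position, first in-frame stop)
# pair, scanning 5'->3'; longest span wins, ties to the smallest start;
# open-ended stretches considered when allow_partial.
orf_oracle <- function(mrna, table = codon_table(1L), allow_partial = TRUE) {
  L <- nchar(mrna)
  starts <- Filter(function(s)
    substr(mrna, s + 1L, s + 3L) %in% table$start_codons, 0:(L - 3L))
  best <- NULL; open <- NULL
  for (s in starts) {
    e <- NA
    p <- s
    repeat {
      if (p + 3L > L) break
      codon <- substr(mrna, p + 1L, p + 3L)
      aa <- table$codon_to_aa[codon]
      if (!is.na(aa) && aa == "*") { e <- p + 3L; break }
      p <- p + 3L
    }
    if (!is.na(e)) {
      if (is.null(best) || (e - s) > (best[2] - best[1])) best <- c(s, e)
    } else if (is.null(open)) open <- s
  }
  if (is.null(best) && is.null(open)) return(NULL)
  if (allow_partial && !is.null(open) &&
      (is.null(best) || (L - open) > (best[2] - best[1]))) {
    list(start = open, end = L, partial = TRUE)
  } else if (!is.null(best)) {
    list(start = best[1], end = best[2], partial = FALSE)
  } else NULL
}

# Codon-by-codon dictionary translation oracle.
translate_oracle <- function(cds, table = codon_table(1L)) {
  n <- nchar(cds) %/% 3L
  aa <- character(0)
  for (i in seq_len(n)) {
    codon <- substr(cds, 3L * i - 2L, 3L * i)
    hit <- table$codon_to_aa[codon]
    aa <- c(aa, if (is.na(hit)) "X" else unname(hit))
  }
  if (length(aa) && aa[length(aa)] == "*") aa <- aa[-length(aa)]
  paste(aa, collapse = "")
}

# Naive sliding-window dinucleotide scan (strand-aware).
scan_oracle <- function(region, start, end, strand, patterns) {
  hits <- integer(0)
  for (p in seq_len(max(0L, end - start - 1L)) + start - 1L) {
    di <- substr(region$residues, p + 1L, p + 2L)
    if (strand == "-") di <- annoforge:::revcomp(di)
    if (di %in% patterns) hits <- c(hits, p)
  }
  as.integer(hits)
}

# Per-base phase-comparison membership oracle: do the CDSs of two
# transcripts share any genomic base at equal codon phase?
phase_overlap_oracle <- function(a, b) {
  phases_of <- function(t) {
    gp <- annoforge:::tx_genomic_positions(t)
    cds <- gp[gp >= t$cds[1L] & gp < t$cds[2L]]
    stats::setNames((seq_along(cds) - 1L) %% 3L, cds)
  }
  if (is.null(a$cds) || is.null(b$cds)) return(FALSE)
  if (!identical(a$seq_id, b$seq_id) || !identical(a$strand, b$strand))
    return(FALSE)
  pa <- phases_of(a); pb <- phases_of(b)
  sh <- intersect(names(pa), names(pb))
  length(sh) > 0L && any(pa[sh] == pb[sh])
}

# Provenance-tag rebuild oracle for alteration application: every base of
# the altered sequence carries its reference origin (or NA for inserted
# bases); mapping and sequence both fall out of the rebuilt cell list.
provenance_oracle <- function(region, alts) {
  cells <- lapply(seq_len(region$length) - 1L, function(p)
    list(base = substr(region$residues, p + 1L, p + 1L), ref = p))
  spans <- lapply(alts, function(a) c(a$position, a$position + nchar(a$ref_residues)))
  ord <- order(vapply(spans, `[`, integer(1), 1L),
               vapply(alts, function(a) a$kind == "insertion", logical(1)))
  for (a in rev(alts[ord])) {
    sp <- c(a$position, a$position + nchar(a$ref_residues))
    keep_l <- if (sp[1L] > 0L) cells[seq_len(sp[1L])] else list()
    keep_r <- if (sp[2L] < length(cells)) cells[(sp[2L] + 1L):length(cells)] else list()
    mid <- if (a$kind == "substitution") {
      mapply(function(cell, b) list(base = b, ref = cell$ref),
             cells[(sp[1L] + 1L):sp[2L]],
             strsplit(a$alt_residues, "")[[1L]], SIMPLIFY = FALSE)
    } else {
      lapply(strsplit(a$alt_residues, "")[[1L]], function(b)
        list(base = b, ref = NA_integer_))
    }
    cells <- c(keep_l, mid, keep_r)
  }
  map <- rep(NA_integer_, region$length)
  for (j in seq_along(cells)) {
    rf <- cells[[j]]$ref
    if (!is.na(rf)) map[rf + 1L] <- j - 1L
  }
  list(residues = paste(vapply(cells, `[[`, character(1), "base"), collapse = ""),
       map = map)
}

# Random non-overlapping alteration set on a region.
random_alterations <- function(region, n_max = 4L) {
  n <- sample(seq_len(n_max), 1L)
  alts <- list(); used <- integer(0)
  for (k in seq_len(n)) {
    for (try in 1:20) {
      kind <- sample(c("substitution", "insertion", "deletion"), 1L)
      len <- sample(1:4, 1L)
      p <- sample(0:(region$length - len), 1L)
      span <- if (kind == "insertion") p else p:(p + len - 1L)
      if (length(intersect(span, used))) next
      ref <- if (kind == "insertion") "" else
        substr(region$residues, p + 1L, p + len)
      alt <- if (kind == "deletion") "" else rand_seq(len)
      alts[[length(alts) + 1L]] <- sequence_alteration(kind, region$id, p, ref, alt)
      used <- c(used, span)
      break
    }
  }
  alts
}

# Random multi-exon transcript with a random CDS, for membership tests.
random_transcript <- function(id, region, strand = sample(c("+", "-"), 1L)) {
  n <- sample(1:3, 1L)
  starts <- sort(sample(0:(region$length - 20L), n))
  ex <- annoforge:::coalesce_exons(data.frame(
    start = starts,
    end = pmin(starts + sample(6:15, n, replace = TRUE), region$length)))
  t <- transcript(id, region$id, strand, ex, owner = "tester")
  sl <- annoforge:::tx_spliced_length(t)
  if (sl >= 6L) {
    a <- sample(0:(sl - 4L), 1L)
    b <- sample((a + 3L):sl, 1L)
    gp <- annoforge:::tx_genomic_positions(t)
    cov <- gp[(a + 1L):b]
    t$cds <- c(min(cov), max(cov) + 1L)
  }
  t
}

# Project preloaded with a fixture genome's evidence.
fixture_project <- function(fx) {
  p <- new_project(fx$regions, organism_config(timestamp_mode = "logical"))
  p$evidence <- fx$evidence
  p
}

# Find a live transcript in a project.
get_tx <- function(project, tid) {
  annoforge:::must_find_transcript(project, tid)$transcript
}

# Gene partition as an order- and id-independent canonical form
# (sorted list of sorted evidence-name groups).
gene_partition <- function(project) {
  part <- lapply(project$genes, function(g)
    sort(unname(vapply(g$transcripts, function(t) t$name %||% t$id, character(1)))))
  part <- lapply(part, unname)
  unname(part[order(vapply(part, `[`, character(1), 1L))])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
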