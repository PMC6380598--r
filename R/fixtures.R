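# Deterministic synthetic-genome generator: plants genes with known ORFs,
# canonical (or deliberately non-canonical) introns, evidence matching the
# exon structure (optionally split into overlapping halves to exercise
# merging, or carrying one deliberately mis-placed boundary to exercise
# snapping), and variants with known effects.  Every planted truth is
# recorded in a manifest, which is the oracle for end-to-end tests.  Output
# is a pure function of the spec; only this module consumes randomness.

#' Specification for a synthetic genome
#'
#' @param seed Integer RNG seed; generation is a pure function of the spec.
#' @param n_regions Number of reference regions (scaffolds).
#' @param n_genes Genes planted across the regions (round-robin).
#' @param exons_per_gene Inclusive range `c(lo, hi)`.
#' @param exon_length Inclusive range of exon lengths (bases).
#' @param intron_length Inclusive range of intron lengths (>= 8).
#' @param fraction_reverse_strand Probability a gene sits on the minus strand.
#' @param fraction_noncanonical_introns Probability an intron gets a GC donor
#'   (non-canonical under the default GT donor set).
#' @param fraction_split_evidence Probability a gene's evidence is split into
#'   two overlapping halves (genes with >= 3 exons only).
#' @param n_variants Named counts `c(substitution=, insertion=, deletion=)`.
#' @param region_length Optional fixed region length; an error is raised if
#'   the planted content does not fit ("infeasible spec").
#' @export
fixture_spec <- function(seed = 1L, n_regions = 2L, n_genes = 10L,
                         exons_per_gene = c(2L, 4L),
                         exon_length = c(60L, 150L),
                         intron_length = c(40L, 80L),
                         fraction_reverse_strand = 0.5,
                         fraction_noncanonical_introns = 0,
                         fraction_split_evidence = 0.3,
                         n_variants = c(substitution = 2L, insertion = 2L,
                                        deletion = 2L),
                         region_length = NULL) {
  if (n_regions < 1L || n_genes < 0L || any(n_variants < 0L))
    af_validation_error("fixture spec counts must be >= 0 (>= 1 region)")
  if (intron_length[1L] < 8L)
    af_validation_error("introns shorter than 8 bases make splice planting infeasible")
  if (exon_length[1L] < 12L)
    af_validation_error("exons shorter than 12 bases make codon planting infeasible")
  structure(
    list(seed = as.integer(seed), n_regions = as.integer(n_regions),
         n_genes = as.integer(n_genes),
         exons_per_gene = as.integer(exons_per_gene),
         exon_length = as.integer(exon_length),
         intron_length = as.integer(intron_length),
         fraction_reverse_strand = fraction_reverse_strand,
         fraction_noncanonical_introns = fraction_noncanonical_introns,
         fraction_split_evidence = fraction_split_evidence,
         n_variants = n_variants,
         region_length = region_length),
    class = "fixture_spec"
  )
}

# Brute-force ORF enumerator, independent of longest_orf(): scans every
# offset for a start codon and walks codon by codon to the first stop.
# Used for planted-truth manifests and as a reference in tests.
naive_orf <- function(mrna, table = codon_table(1L), allow_partial = TRUE) {
  L <- nchar(mrna)
  best <- NULL; best_open <- NULL
  for (s in 0:(L - 3L)) {
    if (!is_start_codon(substr(mrna, s + 1L, s + 3L), table)) next
    e <- NA_integer_
    p <- s
    while (p + 3L <= L) {
      if (is_stop_codon(substr(mrna, p + 1L, p + 3L), table)) { e <- p + 3L; break }
      p <- p + 3L
    }
    if (!is.na(e)) {
      if (is.null(best) || (e - s) > (best$e - best$s)) best <- list(s = s, e = e)
    } else if (is.null(best_open)) {
      best_open <- list(s = s)
    }
  }
  if (is.null(best) && is.null(best_open)) return(NULL)
  if (allow_partial && !is.null(best_open) &&
      (is.null(best) || (L - best_open$s) > (best$e - best$s))) {
    list(start_offset = best_open$s, end_offset = L,
         protein = translate_cds(substr(mrna, best_open$s + 1L, L), table),
         partial = TRUE)
  } else if (!is.null(best)) {
    list(start_offset = best$s, end_offset = best$e,
         protein = translate_cds(substr(mrna, best$s + 1L, best$e), table),
         partial = FALSE)
  } else NULL
}

rand_bases <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")

rint <- function(range) if (range[1L] >= range[2L]) range[1L] else
  sample(seq.int(range[1L], range[2L]), 1L)

comp_base <- function(b) chartr("ACGTN", "TGCAN", b)

# Build one gene in transcript orientation.  Returns exon transcript-space
# intervals, the spliced (== coding) sequence, intron descriptors and the
# assembled transcript-oriented block.
plant_gene_structure <- function(spec, gc) {
  k <- rint(spec$exons_per_gene)
  exon_len <- vapply(seq_len(k), function(i) rint(spec$exon_length), integer(1))
  exon_len[k] <- exon_len[k] + (3L - sum(exon_len) %% 3L) %% 3L
  m <- sum(exon_len) %/% 3L
  nonstop <- names(gc)[gc != "*"]
  stops <- names(gc)[gc == "*"]
  codons <- c("ATG", sample(nonstop, m - 2L, replace = TRUE),
              sample(stops, 1L))
  mrna <- paste(codons, collapse = "")
  tx_start <- cumsum(c(0L, exon_len[-k]))
  tx_end <- cumsum(exon_len)
  introns <- list()
  parts <- character(0)
  for (i in seq_len(k)) {
    parts <- c(parts, substr(mrna, tx_start[i] + 1L, tx_end[i]))
    if (i < k) {
      len <- rint(spec$intron_length)
      noncanon <- stats::runif(1L) < spec$fraction_noncanonical_introns
      donor <- if (noncanon) "GC" else "GT"
      introns[[i]] <- list(length = len, noncanonical = noncanon)
      parts <- c(parts, paste0(donor, rand_bases(len - 4L), "AG"))
    }
  }
  list(k = k, exon_tx_start = tx_start, exon_tx_end = tx_end, mrna = mrna,
       protein = {
         aa <- unname(gc[codons])
         paste(aa[-length(aa)], collapse = "")
       },
       introns = introns, block = paste(parts, collapse = ""))
}

# Genomic coordinates of exons given block placement.  Transcript-space
# interval [a,b) maps to genomic [off+a, off+b) on "+", and to
# [off+L-b, off+L-a) on "-".
exon_genomic_coords <- function(g, offset) {
  L <- nchar(g$block)
  if (g$strand == "+") {
    data.frame(start = offset + g$exon_tx_start + g$intron_before,
               end = offset + g$exon_tx_end + g$intron_before)
  } else {
    s <- offset + L - (g$exon_tx_end + g$intron_before)
    e <- offset + L - (g$exon_tx_start + g$intron_before)
    data.frame(start = rev(s), end = rev(e))
  }
}

# Map a transcript-space (spliced) offset to its genomic base.
fixture_tx_to_genomic <- function(gt, off) {
  i <- which(gt$exon_tx_start <= off & off < gt$exon_tx_end)[1L]
  delta <- off - gt$exon_tx_start[i]
  if (gt$strand == "+") {
    gt$exons_genomic$start[i] + delta
  } else {
    row <- nrow(gt$exons_genomic) - i + 1L
    gt$exons_genomic$end[row] - 1L - delta
  }
}

#' Generate a synthetic genome with a planted-truth manifest
#'
#' Plants `n_genes` genes whose spliced transcript is exactly one clean ORF
#' (ATG ... stop, no internal in-frame stop), joined by GT..AG introns
#' except for the requested non-canonical fraction; emits evidence matching
#' the exon structure (some genes split into two overlapping halves, some
#' with one boundary deliberately shifted off its splice junction with no
#' decoy junction in between), and variants with analytically known effects.
#' When `dir` is given, FASTA / truth GFF3 / evidence BED12 / variants VCF /
#' manifest JSON files are written; outputs are byte-identical across runs
#' with the same spec.
#'
#' @param spec A [fixture_spec()].
#' @param dir Optional output directory (created if needed).
#' @return Invisibly, `list(regions, truth_project, evidence, alterations,
#'   manifest, paths)`.
#' @export
generate_genome <- function(spec = fixture_spec(), dir = NULL) {
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(spec$seed)
  gc <- Biostrings::getGeneticCode("1")
  spacing <- 2L * spec$intron_length[2L]

  genes <- list()
  for (gi in seq_len(spec$n_genes)) {
    g <- plant_gene_structure(spec, gc)
    g$id <- sprintf("tgene_%03d", gi)
    g$transcript_id <- sprintf("tmrna_%03d", gi)
    g$strand <- if (stats::runif(1L) < spec$fraction_reverse_strand) "-" else "+"
    # cumulative intron length before each exon (transcript orientation)
    intron_lens <- vapply(g$introns, `[[`, integer(1), "length")
    g$intron_before <- cumsum(c(0L, intron_lens))
    g$region_idx <- ((gi - 1L) %% spec$n_regions) + 1L
    genes[[gi]] <- g
  }

  regions <- list()
  for (ri in seq_len(spec$n_regions)) {
    rid <- sprintf("scaffold_%02d", ri)
    residues <- rand_bases(spacing + rint(c(0L, 20L)))
    for (gi in seq_along(genes)) {
      if (genes[[gi]]$region_idx != ri) next
      offset <- nchar(residues)
      genes[[gi]]$offset <- offset
      genes[[gi]]$region <- rid
      genes[[gi]]$exons_genomic <- exon_genomic_coords(genes[[gi]], offset)
      genes[[gi]]$cds_genomic <- c(offset, offset + nchar(genes[[gi]]$block))
      placed <- if (genes[[gi]]$strand == "-") revcomp(genes[[gi]]$block)
                else genes[[gi]]$block
      residues <- paste0(residues, placed,
                         rand_bases(spacing + rint(c(0L, 20L))))
    }
    if (!is.null(spec$region_length)) {
      if (nchar(residues) > spec$region_length)
        af_validation_error(sprintf(
          "infeasible spec: planted content (%d bp) exceeds region_length %d",
          nchar(residues), spec$region_length))
      residues <- paste0(residues, rand_bases(spec$region_length - nchar(residues)))
    }
    regions[[rid]] <- seq_region(rid, residues)
  }

  # evidence: split halves, or a single feature possibly mis-placed
  evidence <- list()
  for (gi in seq_along(genes)) {
    g <- genes[[gi]]
    region <- regions[[g$region]]
    split <- g$k >= 3L && stats::runif(1L) < spec$fraction_split_evidence
    if (split) {
      j <- ceiling(g$k / 2)
      rows_for <- function(idx_tx) {
        if (g$strand == "+") idx_tx else g$k - idx_tx + 1L
      }
      rows_a <- sort(rows_for(seq_len(j)))
      rows_b <- sort(rows_for(seq.int(j, g$k)))
      for (half in list(list(sfx = "_a", rows = rows_a),
                        list(sfx = "_b", rows = rows_b))) {
        nm <- paste0(g$transcript_id, half$sfx)
        evidence[[nm]] <- evidence_feature(
          nm, g$region, g$exons_genomic[half$rows, , drop = FALSE],
          strand = g$strand, source_track = "planted", name = nm)
      }
      genes[[gi]]$evidence <- list(names = paste0(g$transcript_id, c("_a", "_b")),
                                   split = TRUE, misplaced = NULL)
    } else {
      blocks <- g$exons_genomic
      misplaced <- NULL
      if (g$k >= 2L) {
        for (i_tx in sample(seq_len(g$k - 1L))) {     # junction after exon i_tx
          if (g$introns[[i_tx]]$noncanonical) next    # only canonical donors snap back
          row <- if (g$strand == "+") i_tx else g$k - i_tx + 1L
          found <- FALSE
          for (d in 2:6) {
            if (g$strand == "+") {
              true_val <- blocks$end[row]
              shifted <- true_val - d
              if (shifted <= blocks$start[row] + 1L) break
              decoys <- scan_dinucleotides(region, shifted + 1L, true_val + 1L,
                                           "+", "GT")
              decoys <- decoys[decoys < true_val]
            } else {
              true_val <- blocks$start[row]
              shifted <- true_val + d
              if (shifted >= blocks$end[row] - 1L) break
              occ <- scan_dinucleotides(region, true_val - 1L, shifted, "-", "GT")
              decoys <- occ + 2L
              decoys <- decoys[decoys > true_val]
            }
            if (!length(decoys)) {
              if (g$strand == "+") blocks$end[row] <- shifted
              else blocks$start[row] <- shifted
              misplaced <- list(exon_index = i_tx - 1L, edge = "three_prime",
                                direction = "downstream",
                                shifted_value = shifted, true_value = true_val)
              found <- TRUE
              break
            }
          }
          if (found) break
        }
      }
      nm <- paste0(g$transcript_id, "_ev")
      evidence[[nm]] <- evidence_feature(nm, g$region, blocks,
                                         strand = g$strand,
                                         source_track = "planted", name = nm)
      genes[[gi]]$evidence <- list(names = nm, split = FALSE,
                                   misplaced = misplaced)
    }
  }

  # variants with analytically known effects
  alterations <- list()
  var_truth <- list()
  used_genes <- integer(0)
  vi <- 0L
  next_cat <- function() if (vi %% 2L == 1L) "variant" else "assembly_correction"
  pick_gene <- function(pred = function(g) TRUE) {
    cand <- setdiff(seq_along(genes), used_genes)
    cand <- cand[vapply(genes[cand], pred, logical(1))]
    if (!length(cand)) return(NA_integer_)
    cand[rint(c(1L, length(cand)))]
  }
  # codon (0-based index) whose three bases sit inside one exon
  pick_inner_codon <- function(g) {
    m <- nchar(g$mrna) %/% 3L
    cand <- Filter(function(j) {
      any(g$exon_tx_start <= 3L * j & (3L * j + 3L) <= g$exon_tx_end)
    }, seq.int(1L, m - 2L))
    if (!length(cand)) NA_integer_ else cand[[rint(c(1L, length(cand)))]]
  }
  tx_interval_genomic <- function(g, off_from, off_to) {  # [off_from, off_to)
    p <- vapply(seq.int(off_from, off_to - 1L), function(o)
      fixture_tx_to_genomic(g, o), integer(1))
    c(min(p), max(p) + 1L)
  }
  spliced_truth <- function(g, edited) {
    orf <- naive_orf(edited)
    L0 <- nchar(g$mrna)
    list(start_offset = orf$start_offset, end_offset = orf$end_offset,
         protein_after = orf$protein,
         protein_changed = !identical(orf$protein, g$protein),
         orf_found = !is.null(orf))
  }
  add_variant <- function(kind, g_idx, pos, ref, alt, effect) {
    vi <<- vi + 1L
    a <- sequence_alteration(kind,
                             if (is.na(g_idx)) effect$seq_id else genes[[g_idx]]$region,
                             pos, ref_residues = ref, alt_residues = alt,
                             category = next_cat(), id = sprintf("var_%03d", vi))
    alterations[[length(alterations) + 1L]] <<- a
    var_truth[[a$id]] <<- c(
      list(id = a$id, kind = kind, seq_id = a$seq_id, position = pos,
           ref = ref, alt = alt, category = a$category,
           transcript = if (is.na(g_idx)) NULL else genes[[g_idx]]$transcript_id),
      effect[setdiff(names(effect), "seq_id")])
    if (!is.na(g_idx)) used_genes <<- c(used_genes, g_idx)
  }

  nv <- spec$n_variants
  # deletions: the first removes a start codon (start relocates downstream)
  ndel <- if ("deletion" %in% names(nv)) nv[["deletion"]] else 0L
  if (ndel >= 1L) {
    for (attempt in 1:20) {
      g_idx <- pick_gene(function(g) g$exon_tx_end[1L] >= 6L)
      if (is.na(g_idx)) break
      g <- genes[[g_idx]]
      edited <- substr(g$mrna, 4L, nchar(g$mrna))
      orf <- naive_orf(edited)
      if (is.null(orf) || orf$start_offset == 0L) { next }
      span <- tx_interval_genomic(g, 0L, 3L)
      ref <- substr(regions[[g$region]]$residues, span[1L] + 1L, span[2L])
      st <- spliced_truth(g, edited)
      st$cds_start_moved <- TRUE
      st$cds_end_moved <- (st$end_offset != nchar(edited))
      st$class <- "deletion_before_start"
      add_variant("deletion", g_idx, span[1L], ref, "", st)
      break
    }
  }
  if (ndel >= 2L) {
    for (rep in seq_len(ndel - 1L)) {
      g_idx <- pick_gene(function(g) !is.na(pick_inner_codon(g)))
      if (is.na(g_idx)) break
      g <- genes[[g_idx]]
      j <- pick_inner_codon(g)
      edited <- paste0(substr(g$mrna, 1L, 3L * j),
                       substr(g$mrna, 3L * j + 4L, nchar(g$mrna)))
      span <- tx_interval_genomic(g, 3L * j, 3L * j + 3L)
      ref <- substr(regions[[g$region]]$residues, span[1L] + 1L, span[2L])
      st <- spliced_truth(g, edited)
      st$cds_start_moved <- (st$start_offset != 0L)
      st$cds_end_moved <- (st$end_offset != nchar(edited))
      st$class <- "inframe_codon_deletion"
      add_variant("deletion", g_idx, span[1L], ref, "", st)
    }
  }
  nsub <- if ("substitution" %in% names(nv)) nv[["substitution"]] else 0L
  for (rep in seq_len(nsub)) {
    g_idx <- pick_gene(function(g) !is.na(pick_inner_codon(g)))
    if (is.na(g_idx)) break
    g <- genes[[g_idx]]
    j <- pick_inner_codon(g)
    o <- 3L * j + 2L                       # third base of the codon
    old_tx <- substr(g$mrna, o + 1L, o + 1L)
    new_tx <- sample(setdiff(c("A", "C", "G", "T"), old_tx), 1L)
    edited <- paste0(substr(g$mrna, 1L, o), new_tx,
                     substr(g$mrna, o + 2L, nchar(g$mrna)))
    gx <- fixture_tx_to_genomic(g, o)
    ref <- if (g$strand == "+") old_tx else comp_base(old_tx)
    alt <- if (g$strand == "+") new_tx else comp_base(new_tx)
    st <- spliced_truth(g, edited)
    st$cds_start_moved <- (st$start_offset != 0L)
    st$cds_end_moved <- (st$end_offset != nchar(edited))
    st$class <- "codon_third_base_substitution"
    add_variant("substitution", g_idx, gx, ref, alt, st)
  }
  nins <- if ("insertion" %in% names(nv)) nv[["insertion"]] else 0L
  for (rep in seq_len(nins)) {
    if (rep %% 2L == 1L) {
      g_idx <- pick_gene(function(g) g$k >= 2L)
      if (!is.na(g_idx)) {
        g <- genes[[g_idx]]
        # interior of the first intron, clear of the splice dinucleotides
        intron_rows <- if (g$strand == "+")
          data.frame(start = g$exons_genomic$end[-g$k],
                     end = g$exons_genomic$start[-1L])
        else data.frame(start = g$exons_genomic$end[-g$k],
                        end = g$exons_genomic$start[-1L])
        pos <- intron_rows$start[1L] + 3L +
          rint(c(0L, intron_rows$end[1L] - intron_rows$start[1L] - 7L))
        st <- list(start_offset = 0L, end_offset = nchar(g$mrna),
                   protein_after = g$protein, protein_changed = FALSE,
                   orf_found = TRUE, cds_start_moved = FALSE,
                   cds_end_moved = FALSE, class = "intronic_insertion")
        add_variant("insertion", g_idx, pos, "", rand_bases(5L), st)
        next
      }
    }
    # intergenic insertion on the first region, upstream of everything
    rid <- names(regions)[1L]
    pos <- 5L + rint(c(0L, 20L))
    min_start <- min(c(Inf, vapply(
      Filter(function(g) g$region == rid, genes),
      function(g) g$offset, numeric(1))))
    if (pos >= min_start - 5L) pos <- 5L
    add_variant("insertion", NA_integer_, pos, "", rand_bases(4L),
                list(seq_id = rid, transcript = NULL, protein_changed = FALSE,
                     cds_start_moved = FALSE, cds_end_moved = FALSE,
                     class = "intergenic_insertion"))
  }

  # assemble manifest and model objects
  truth_project <- new_project(regions,
                               organism_config(timestamp_mode = "logical"))
  manifest_genes <- list()
  for (g in genes) {
    tx <- transcript(g$transcript_id, g$region, g$strand, g$exons_genomic,
                     cds = g$cds_genomic, owner = "generator")
    truth_project$genes[[g$id]] <- gene(g$id, list(tx), owner = "generator")
    manifest_genes[[g$id]] <- list(
      id = g$id, transcript = g$transcript_id, region = g$region,
      strand = g$strand,
      exons = lapply(seq_len(nrow(g$exons_genomic)), function(i)
        list(start = g$exons_genomic$start[i], end = g$exons_genomic$end[i])),
      cds = list(start = g$cds_genomic[1L], end = g$cds_genomic[2L]),
      mrna = g$mrna, protein = g$protein,
      noncanonical_introns = which(vapply(g$introns, `[[`, logical(1),
                                          "noncanonical")) - 1L,
      evidence = g$evidence)
  }
  manifest <- list(seed = spec$seed, n_genes = spec$n_genes,
                   regions = lapply(regions, function(r)
                     list(id = r$id, length = r$length)),
                   genes = manifest_genes, variants = var_truth)
  paths <- NULL
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(fasta = file.path(dir, "genome.fa"),
                  gff3 = file.path(dir, "truth.gff3"),
                  bed = file.path(dir, "evidence.bed"),
                  vcf = file.path(dir, "variants.vcf"),
                  manifest = file.path(dir, "manifest.json"))
    write_fasta(regions, paths$fasta)
    write_gff3(truth_project, paths$gff3, include_evidence = FALSE)
    write_evidence_bed(evidence, paths$bed)
    write_alterations_vcf(alterations, regions, paths$vcf)
    writeLines(as.character(jsonlite::toJSON(manifest, auto_unbox = TRUE,
                                             digits = NA, pretty = TRUE)),
               paths$manifest)
  }
  invisible(list(spec = spec, regions = regions, truth_project = truth_project,
                 evidence = evidence, alterations = alterations,
                 manifest = manifest, paths = paths))
}

# BED12 writer for evidence features (native 0-based half-open).
write_evidence_bed <- function(evidence, path) {
  lines <- vapply(evidence, function(e) {
    s <- min(e$blocks$start); en <- max(e$blocks$end)
    paste(e$seq_id, s, en, e$id, 0L, e$strand, s, en, "0,0,0",
          nrow(e$blocks),
          paste0(paste(e$blocks$end - e$blocks$start, collapse = ","), ","),
          paste0(paste(e$blocks$start - s, collapse = ","), ","),
          sep = "\t")
  }, character(1))
  writeLines(unname(lines), path)
  invisible(path)
}

# Minimal site-only VCF 4.2 writer; internal pure indels are re-anchored on
# the preceding base as the format requires.
write_alterations_vcf <- function(alterations, regions, path) {
  header <- c("##fileformat=VCFv4.2",
              "##source=annoforge_fixture_generator",
              '##INFO=<ID=CATEGORY,Number=1,Type=String,Description="assembly_correction or variant">',
              vapply(regions, function(r)
                sprintf("##contig=<ID=%s,length=%d>", r$id, r$length),
                character(1)),
              paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                    "INFO", sep = "\t"))
  rows <- vapply(alterations, function(a) {
    res <- regions[[a$seq_id]]$residues
    if (a$kind == "substitution") {
      pos1 <- a$position + 1L; ref <- a$ref_residues; alt <- a$alt_residues
    } else {
      anchor <- substr(res, a$position, a$position)   # base before, 1-based
      pos1 <- a$position                              # its 1-based coordinate
      if (a$kind == "deletion") {
        ref <- paste0(anchor, a$ref_residues); alt <- anchor
      } else {
        ref <- anchor; alt <- paste0(anchor, a$alt_residues)
      }
    }
    paste(a$seq_id, pos1, a$id %||% ".", ref, alt, ".", "PASS",
          sprintf("CATEGORY=%s", a$category), sep = "\t")
  }, character(1))
  writeLines(c(header, unname(rows)), path)
  invisible(path)
}
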