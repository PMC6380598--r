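test_that("promotion creates a coding transcript with the automatic ORF", {
  # evidence blocks splicing to ATG...TAA
  r <- mk_region("ATGCCCGTAAAGCCCTAAGG")
  p <- new_project(list(r), organism_config(timestamp_mode = "logical"))
  p$evidence <- list(ev1 = evidence_feature(
    "ev1", "chr", data.frame(start = c(0, 12), end = c(6, 18))))
  p <- promote_evidence(p, "ev1", "admin")
  t <- get_tx(p, p$last_edit$transcript_id)
  expect_identical(t$type, "protein_coding")
  expect_identical(get_spliced_sequence(r, t), "ATGCCCCCCTAA")
  expect_identical(t$cds, c(0L, 18L))
  expect_false(t$needs_review)
  expect_identical(t$owner, "admin")
  # one history record on the minted gene
  h <- list_history(p, p$last_edit$gene_id)
  expect_identical(nrow(h), 1L)
  expect_identical(h$operation, "promote_evidence")
})

test_that("promotion without a start codon flags the transcript for review", {
  r <- mk_region("CCCCCCCCCCCC")
  p <- new_project(list(r), organism_config(timestamp_mode = "logical"))
  p$evidence <- list(ev = evidence_feature("ev", "chr",
                                           data.frame(start = 0, end = 12)))
  p <- promote_evidence(p, "ev", "admin")
  t <- get_tx(p, p$last_edit$transcript_id)
  expect_null(t$cds)
  expect_true(t$needs_review)
})

test_that("in-frame overlapping promotions join one gene, UTR-only overlap does not", {
  fx <- generate_genome(fixture_spec(seed = 41, n_genes = 2,
                                     fraction_split_evidence = 0))
  p <- fixture_project(fx)
  ev <- p$evidence[[1]]
  # identical evidence promoted twice: same gene, witnesses everywhere
  p <- promote_evidence(p, ev$id, "admin")
  t1 <- p$last_edit$transcript_id
  ev2 <- ev; ev2$id <- "copy"; ev2$name <- "copy"
  p$evidence$copy <- ev2
  p <- promote_evidence(p, "copy", "admin")
  expect_length(p$genes, 1L)
  dec <- p$last_edit$decision
  expect_identical(dec$strategy_used, "cds_overlap_in_frame")
  expect_gt(nrow(dec$witnesses[[1]]), 0)
  t1_obj <- get_tx(p, t1)
  expect_identical(nrow(dec$witnesses[[1]]),
                   length(annoforge:::tx_cds_positions(t1_obj)))
})

test_that("strategy contrast: exon overlap groups what in-frame CDS overlap keeps apart", {
  # two transcripts overlapping only where one of them is untranslated
  r <- mk_region(paste0("ATGAAATAA", rand_seq(6), "ATGCCCTAA"))
  ex_a <- data.frame(start = 0, end = 9)            # clean ORF at [0,9)
  ex_b <- data.frame(start = 6, end = 24)           # ORF at [15,24), UTR over [6,15)
  for (strategy in c("cds_overlap_in_frame", "exon_overlap")) {
    p <- new_project(list(r), organism_config(isoform_strategy = strategy,
                                              timestamp_mode = "logical"))
    p$evidence <- list(a = evidence_feature("a", "chr", ex_a),
                       b = evidence_feature("b", "chr", ex_b))
    p <- promote_evidence(p, "a", "admin")
    p <- promote_evidence(p, "b", "admin")
    expect_length(p$genes, if (strategy == "exon_overlap") 1L else 2L)
  }
})

test_that("membership decisions match the per-base phase oracle on random pairs", {
  set.seed(42)
  r <- mk_region(rand_seq(300))
  for (i in 1:120) {
    strand <- sample(c("+", "-"), 1)
    a <- random_transcript("a", r, strand)
    b <- random_transcript("b", r, strand)
    if (is.null(a$cds) || is.null(b$cds)) next
    w <- annoforge:::inframe_witnesses(a, b)
    expect_identical(!is.null(w), phase_overlap_oracle(a, b))
    if (!is.null(w)) {
      # witnesses are genuine proofs
      pa <- annoforge:::tx_cds_phases(a); pb <- annoforge:::tx_cds_phases(b)
      key <- as.character(w$position)
      expect_true(all(pa[key] == pb[key]))
      expect_true(all(w$phase == unname(pa[key])))
    }
  }
})

test_that("transcript merge unions exons and survives self-copy idempotently", {
  set.seed(43)
  fx <- generate_genome(fixture_spec(seed = 43, n_genes = 2,
                                     exons_per_gene = c(3, 4),
                                     fraction_split_evidence = 1))
  p <- fixture_project(fx)
  mg <- fx$manifest$genes[[1]]
  stopifnot(isTRUE(mg$evidence$split))
  p <- promote_evidence(p, mg$evidence$names[[1]], "admin")
  a <- p$last_edit$transcript_id
  p <- promote_evidence(p, mg$evidence$names[[2]], "admin")
  b <- p$last_edit$transcript_id
  p <- merge_transcripts(p, a, b, "admin")
  t <- get_tx(p, p$last_edit$transcript_id)
  truth <- do.call(rbind, lapply(mg$exons, as.data.frame))
  expect_identical(t$exons, data.frame(start = as.integer(truth$start),
                                       end = as.integer(truth$end)))
  expect_identical(t$cds, c(as.integer(mg$cds$start), as.integer(mg$cds$end)))
  # merge with a copy of itself leaves the exon set unchanged
  tcopy <- t; tcopy$id <- "copy"; tcopy$name <- "copy"
  g <- p$genes[[p$last_edit$gene_id]]
  g$transcripts$copy <- tcopy
  p$genes[[p$last_edit$gene_id]] <- annoforge:::refresh_gene_extent(g)
  p <- merge_transcripts(p, t$id, "copy", "admin")
  expect_identical(get_tx(p, t$id)$exons, t$exons)
})

test_that("random exon-set merges equal the interval-union oracle", {
  set.seed(44)
  r <- mk_region(rand_seq(400))
  for (i in 1:30) {
    a <- random_transcript("a", r, "+")
    b <- random_transcript("b", r, "+")
    p <- new_project(list(r), organism_config(timestamp_mode = "logical"))
    g <- gene("g1", list(a, b), owner = "u")
    p$genes <- list(g1 = g)
    p <- merge_transcripts(p, "a", "b", "admin")
    got <- get_tx(p, "a")$exons
    # IRanges reduce with min.gapwidth=0 coalesces overlap and bookends
    ir <- IRanges::reduce(IRanges::IRanges(
      start = c(a$exons$start, b$exons$start) + 1L,
      end = c(a$exons$end, b$exons$end)))
    expect_identical(got, data.frame(start = BiocGenerics::start(ir) - 1L,
                                     end = BiocGenerics::end(ir)))
  }
})

test_that("merging across strands or regions is rejected", {
  r <- mk_region(rand_seq(100))
  a <- transcript("a", "chr", "+", data.frame(start = 0, end = 30), owner = "u")
  b <- transcript("b", "chr", "-", data.frame(start = 40, end = 70), owner = "u")
  p <- new_project(list(r), organism_config(timestamp_mode = "logical"))
  p$genes <- list(ga = gene("ga", list(a), owner = "u"),
                  gb = gene("gb", list(b), owner = "u"))
  expect_error(merge_transcripts(p, "a", "b", "admin"),
               class = "af_merge_error")
  expect_error(merge_transcripts(p, "a", "a", "admin"),
               class = "af_merge_error")
})

test_that("split partitions the exon list and merge at the seam restores it", {
  fx <- generate_genome(fixture_spec(seed = 45, n_genes = 3,
                                     exons_per_gene = c(3, 4),
                                     fraction_split_evidence = 0))
  p <- fixture_project(fx)
  for (mg in fx$manifest$genes) {
    if (!is.null(mg$evidence$misplaced)) next
    p <- promote_evidence(p, unlist(mg$evidence$names), "admin")
    tid <- p$last_edit$transcript_id
    t0 <- get_tx(p, tid)
    sp0 <- get_spliced_sequence(fx$regions[[t0$seq_id]], t0)
    cut <- sample(0:(nrow(t0$exons) - 2), 1)
    p2 <- split_transcript(p, tid, cut, "admin")
    ids <- p2$last_edit$transcript_ids
    t1 <- get_tx(p2, ids[1]); t2 <- get_tx(p2, ids[2])
    expect_identical(nrow(t1$exons), cut + 1L)
    # spliced products concatenate (5' then 3') to the original
    expect_identical(paste0(get_spliced_sequence(fx$regions[[t1$seq_id]], t1),
                            get_spliced_sequence(fx$regions[[t2$seq_id]], t2)),
                     sp0)
    p3 <- merge_transcripts(p2, ids[1], ids[2], "admin")
    expect_identical(get_tx(p3, p3$last_edit$transcript_id)$exons, t0$exons)
  }
  # single-exon transcripts cannot be split
  r <- mk_region(rand_seq(60))
  q <- new_project(list(r), organism_config(timestamp_mode = "logical"))
  q$genes <- list(g = gene("g", list(
    transcript("t", "chr", "+", data.frame(start = 0, end = 30), owner = "u")),
    owner = "u"))
  expect_error(split_transcript(q, "t", 0, "admin"),
               class = "af_validation_error")
})

test_that("boundary drags recompute the ORF and reject invalid moves atomically", {
  # extending the terminal exon over one more codon before a downstream stop
  r <- mk_region(paste0("ATGCCCAAA", "TAA", rand_seq(10)))
  p <- new_project(list(r), organism_config(timestamp_mode = "logical"))
  p$evidence <- list(ev = evidence_feature("ev", "chr",
                                           data.frame(start = 0, end = 9)))
  p <- promote_evidence(p, "ev", "admin")
  tid <- p$last_edit$transcript_id
  t <- get_tx(p, tid)
  expect_true(t$partial)                      # no stop inside [0,9)
  p2 <- set_exon_boundary(p, tid, 0, "three_prime", 12, "admin")
  t2 <- get_tx(p2, tid)
  expect_identical(t2$cds, c(0L, 12L))
  expect_false(t2$partial)
  expect_identical(translate_cds(get_spliced_sequence(r, t2)), "MPK")
  # no-op drag still writes a record
  before <- nrow(list_history(p2, p2$last_edit$feature_id))
  p3 <- set_exon_boundary(p2, tid, 0, "three_prime", 12, "admin")
  expect_identical(nrow(list_history(p3, p3$last_edit$feature_id)), before + 1L)
  expect_identical(get_tx(p3, tid), t2)
  # inverting the exon is rejected and the project is untouched
  err <- tryCatch(set_exon_boundary(p2, tid, 0, "five_prime", 13, "admin"),
                  error = function(e) e)
  expect_s3_class(err, "af_boundary_error")
  # crossing a neighbor is rejected
  r2 <- mk_region(rand_seq(60))
  q <- new_project(list(r2), organism_config(timestamp_mode = "logical"))
  q$evidence <- list(ev = evidence_feature(
    "ev", "chr", data.frame(start = c(0, 30), end = c(10, 40))))
  q <- promote_evidence(q, "ev", "admin")
  qt <- q$last_edit$transcript_id
  expect_error(set_exon_boundary(q, qt, 0, "three_prime", 35, "admin"),
               class = "af_boundary_error")
})

test_that("edit errors never change project state", {
  fx <- generate_genome(fixture_spec(seed = 46, n_genes = 2))
  p <- fixture_project(fx)
  p <- promote_evidence(p, names(p$evidence)[1], "admin")
  tid <- p$last_edit$transcript_id
  snapshot <- serialize_project(p)
  for (expr in list(
    function() set_exon_boundary(p, tid, 0, "five_prime", 10^7, "admin"),
    function() split_transcript(p, "no-such", 0, "admin"),
    function() merge_transcripts(p, tid, tid, "admin"),
    function() set_translation_boundary(p, tid, "start", 10^6, "admin")
  )) {
    expect_error(expr())
    expect_identical(serialize_project(p), snapshot)
  }
})

test_that("boundary snapping lands on the nearest configured junction", {
  # exon 3' edge two bases upstream of a GT: snapping downstream moves the
  # intron start onto the GT
  lead <- "ATGCCCAAACCC"                      # 12 bases, no GT
  r <- mk_region(paste0(lead, "GT", rand_seq(20)))
  p <- new_project(list(r), organism_config(timestamp_mode = "logical"))
  p$evidence <- list(ev = evidence_feature("ev", "chr",
                                           data.frame(start = 0, end = 10)))
  p <- promote_evidence(p, "ev", "admin")
  tid <- p$last_edit$transcript_id
  p2 <- snap_exon_boundary(p, tid, 0, "three_prime", "downstream", "admin")
  expect_identical(get_tx(p2, tid)$exons$end, 12L)
  # window devoid of junctions errors out, project unchanged
  r3 <- mk_region(strrep("C", 40))
  q <- new_project(list(r3), organism_config(timestamp_mode = "logical"))
  q$evidence <- list(ev = evidence_feature("ev", "chr",
                                           data.frame(start = 0, end = 20)))
  q <- promote_evidence(q, "ev", "admin")
  expect_error(snap_exon_boundary(q, q$last_edit$transcript_id, 0,
                                  "three_prime", "downstream", "admin"),
               class = "af_no_junction_error")
})

test_that("snapped positions equal the nearest junction from the scan oracle", {
  set.seed(47)
  cfg <- organism_config(timestamp_mode = "logical")
  for (i in 1:25) {
    r <- mk_region(rand_seq(300))
    p <- new_project(list(r), cfg)
    strand <- sample(c("+", "-"), 1)
    p$evidence <- list(ev = evidence_feature(
      "ev", "chr", data.frame(start = c(20, 200), end = c(100, 280)),
      strand = strand))
    p <- promote_evidence(p, "ev", "admin")
    tid <- p$last_edit$transcript_id
    direction <- sample(c("upstream", "downstream"), 1)
    res <- tryCatch(
      snap_exon_boundary(p, tid, 0, "three_prime", direction, "admin"),
      af_no_junction_error = function(e) NULL)
    t0 <- get_tx(p, tid)
    # oracle: donor occurrences around the current edge, nearest in direction
    row <- if (strand == "+") 1L else 2L
    cur <- if (strand == "+") t0$exons$end[row] else t0$exons$start[row]
    occ <- scan_oracle(r, 0, 300, strand, "GT")
    cand <- if (strand == "+") occ else occ + 2L
    genomic_up <- if (strand == "+") direction == "upstream" else direction == "downstream"
    cand <- if (genomic_up) cand[cand < cur] else cand[cand > cur]
    if (strand == "+") {
      cand <- cand[cand > t0$exons$start[1] & cand <= t0$exons$start[2]]
    } else {
      cand <- cand[cand >= t0$exons$end[1] & cand < t0$exons$end[2]]
    }
    if (is.null(res)) {
      expect_length(cand, 0)
    } else {
      want <- cand[which.min(abs(cand - cur))]
      t1 <- get_tx(res, tid)
      got <- if (strand == "+") t1$exons$end[row] else
        t1$exons$start[nrow(t1$exons) - (2L - row)]
      got_val <- if (strand == "+") t1$exons$end[1] else
        t1$exons$start[nrow(t1$exons)]
      # exon may have coalesced if snapped flush against the neighbor
      expect_true(want %in% c(t1$exons$end, t1$exons$start))
    }
  }
})

test_that("translation pins reproduce and constrain the automatic ORF", {
  r <- mk_region(paste0("ATGAAACCC", "TAA", "GGG"))
  p <- new_project(list(r), organism_config(timestamp_mode = "logical"))
  p$evidence <- list(ev = evidence_feature("ev", "chr",
                                           data.frame(start = 0, end = 15)))
  p <- promote_evidence(p, "ev", "admin")
  tid <- p$last_edit$transcript_id
  auto <- get_tx(p, tid)
  # pinning the start where the automatic ORF chose reproduces it
  p2 <- set_translation_boundary(p, tid, "start", 0, "admin")
  expect_identical(get_tx(p2, tid)$cds, auto$cds)
  expect_identical(get_tx(p2, tid)$partial, auto$partial)
  # pin start where no in-frame stop follows: partial, CDS to transcript end
  p3 <- set_translation_boundary(p, tid, "start", 2, "admin")
  t3 <- get_tx(p3, tid)
  expect_true(t3$partial)
  expect_identical(t3$cds[2], 15L)
  # position outside exons is rejected
  expect_error(set_translation_boundary(p, tid, "start", 40, "admin"),
               class = "af_invalid_position_error")
})

test_that("strand flips toggle structure reversibly and relocate the ORF", {
  # a forward transcript whose only ORF lies on the reverse complement
  core <- annoforge:::revcomp("ATGAAAGCCTAA")
  r <- mk_region(paste0("CCCC", core, "CCCC"))
  p <- new_project(list(r), organism_config(timestamp_mode = "logical"))
  p$evidence <- list(ev = evidence_feature("ev", "chr",
                                           data.frame(start = 4, end = 16)))
  p <- promote_evidence(p, "ev", "admin")
  tid <- p$last_edit$transcript_id
  t0 <- get_tx(p, tid)
  expect_null(t0$cds)
  p2 <- flip_strand(p, tid, "admin")
  t1 <- get_tx(p2, tid)
  expect_identical(t1$strand, "-")
  expect_identical(t1$cds, c(4L, 16L))
  expect_identical(translate_cds(get_spliced_sequence(r, t1)), "MKA")
  p3 <- flip_strand(p2, tid, "admin")
  t2 <- get_tx(p3, tid)
  expect_identical(t2$exons, t0$exons)
  expect_identical(t2$strand, t0$strand)
})

test_that("gene grouping is a partition, invariant under promotion order", {
  fx <- generate_genome(fixture_spec(seed = 48, n_genes = 5,
                                     fraction_split_evidence = 0.6))
  p0 <- fixture_project(fx)
  base <- NULL
  set.seed(480)
  for (perm in 1:8) {
    order_names <- if (perm == 1) names(p0$evidence) else sample(names(p0$evidence))
    p <- p0
    for (e in order_names) p <- promote_evidence(p, e, "admin")
    # partition property: every transcript in exactly one gene
    all_tx <- unlist(lapply(p$genes, function(g) names(g$transcripts)))
    expect_false(anyDuplicated(all_tx) > 0)
    part <- gene_partition(p)
    if (is.null(base)) base <- part else expect_identical(part, base)
  }
})
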