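test_that("alteration application: offsets, lengths and deletion markers", {
  set.seed(70)
  r <- mk_region(rand_seq(100), id = "r")
  del <- sequence_alteration("deletion", "r", 10,
                             substr(r$residues, 11, 13), "")
  out <- apply_alterations(r, list(del))
  expect_identical(out$region$length, 97L)
  expect_identical(map_position(out$cmap, 9L), 9L)
  expect_identical(map_position(out$cmap, 13L), 10L)
  expect_true(all(is.na(map_position(out$cmap, 10:12))))
  # substitutions leave the coordinate map as the identity
  sub <- sequence_alteration("substitution", "r", 5,
                             substr(r$residues, 6, 6), "A")
  out2 <- apply_alterations(r, list(sub))
  expect_identical(out2$region$length, r$length)
  expect_identical(map_position(out2$cmap, 0:99), 0:99)
  # bad inputs
  expect_error(apply_alterations(r, list(
    sequence_alteration("deletion", "r", 10, "NNN", ""))),
    class = "af_refcheck_error")
  expect_error(apply_alterations(r, list(
    del, sequence_alteration("deletion", "r", 11,
                             substr(r$residues, 12, 12), ""))),
    class = "af_conflict_error")
  expect_error(map_position(out$cmap, 120L), class = "af_bounds_error")
})

test_that("coordinate maps obey the length law, monotonicity and the provenance oracle", {
  set.seed(71)
  for (i in 1:120) {
    r <- mk_region(rand_seq(sample(50:200, 1)), id = "r")
    alts <- random_alterations(r)
    out <- apply_alterations(r, alts)
    net <- sum(vapply(alts, function(a)
      nchar(a$alt_residues) - nchar(a$ref_residues), integer(1)))
    expect_identical(out$region$length, r$length + net)
    want <- provenance_oracle(r, alts)
    expect_identical(out$region$residues, want$residues)
    got <- map_position(out$cmap, seq_len(r$length) - 1L)
    expect_identical(got, want$map)
    surv <- got[!is.na(got)]
    expect_true(all(diff(surv) > 0))          # strict monotonicity
  }
})

test_that("deleting then re-inserting the same bases is the identity", {
  set.seed(72)
  for (i in 1:20) {
    r <- mk_region(rand_seq(80), id = "r")
    p <- sample(5:60, 1)
    b <- substr(r$residues, p + 1, p + 3)
    step1 <- apply_alterations(r, list(
      sequence_alteration("deletion", "r", p, b, "")))
    ins_pos <- map_position(step1$cmap, p + 3L) # first surviving base after the cut
    step2 <- apply_alterations(step1$region, list(
      sequence_alteration("insertion", "r", ins_pos, "", b)))
    expect_identical(step2$region$residues, r$residues)
    # composed map is the identity on every position
    for (q in seq_len(r$length) - 1L) {
      m1 <- map_position(step1$cmap, q)
      final <- if (is.na(m1)) NA_integer_ else map_position(step2$cmap, m1)
      if (!is.na(final)) expect_identical(final, q)
    }
  }
})

test_that("transcripts untouched by alterations project bit-identically", {
  fx <- generate_genome(fixture_spec(seed = 73, n_genes = 3))
  p <- fx$truth_project
  r <- p$regions[[1]]
  # alteration far downstream of the first gene
  g1 <- p$genes[[1]]
  t1 <- g1$transcripts[[1]]
  pos <- r$length - 5L
  out <- apply_alterations(r, list(sequence_alteration(
    "substitution", r$id, pos, substr(r$residues, pos + 1, pos + 1),
    setdiff(c("A", "C", "G", "T"),
            substr(r$residues, pos + 1, pos + 1))[1])))
  pr <- project_transcript(t1, out$cmap, out$region, p$config,
                           original_region = r)
  if (identical(t1$seq_id, r$id)) {
    expect_identical(pr$transcript$exons, t1$exons)
    expect_identical(pr$transcript$cds, t1$cds)
    expect_false(pr$report$protein_changed)
    expect_false(pr$report$cds_start_moved)
  }
})

test_that("a deletion spanning the start codon relocates the CDS start downstream", {
  fx <- generate_genome(fixture_spec(seed = 74, n_genes = 6))
  truth <- NULL
  for (v in fx$manifest$variants)
    if (identical(v$class, "deletion_before_start")) truth <- v
  expect_false(is.null(truth))   # this seed plants a start-codon deletion
  p <- fx$truth_project
  p$alterations <- fx$alterations
  view <- project_annotations(p, "both")
  rep <- view$reports[[truth$transcript]]
  expect_true(rep$cds_start_moved)
  expect_identical(rep$protein_after, truth$protein_after)
  pt <- NULL
  for (g in view$genes) if (truth$transcript %in% names(g$transcripts))
    pt <- g$transcripts[[truth$transcript]]
  start_base <- if (pt$strand == "+") pt$cds[1] else pt$cds[2] - 1L
  off <- annoforge:::tx_genomic_to_spliced(pt, start_base)
  expect_identical(off, as.integer(truth$start_offset))
  expect_gt(off, 0L)                      # relocated downstream of the old start
  expect_gt(rep$cds_start_delta, 0L)      # oriented downstream
})

test_that("an in-frame codon deletion shortens the protein by one residue", {
  found <- FALSE
  for (seed in 75:80) {
    fx <- generate_genome(fixture_spec(seed = seed, n_genes = 6))
    p <- fx$truth_project
    p$alterations <- fx$alterations
    view <- project_annotations(p, "both")
    for (v in fx$manifest$variants) {
      if (!identical(v$class, "inframe_codon_deletion")) next
      found <- TRUE
      rep <- view$reports[[v$transcript]]
      expect_identical(nchar(rep$protein_after), nchar(rep$protein_before) - 1L)
      expect_identical(rep$protein_after, v$protein_after)
      expect_false(rep$cds_start_moved)
    }
    if (found) break
  }
  expect_true(found)
})

test_that("every planted variant effect is recovered from the manifest", {
  for (seed in c(81, 82)) {
    fx <- generate_genome(fixture_spec(seed = seed, n_genes = 8))
    p <- fx$truth_project
    p$alterations <- fx$alterations
    view <- project_annotations(p, "both")
    for (v in fx$manifest$variants) {
      if (is.null(v$transcript)) next
      rep <- view$reports[[v$transcript]]
      expect_identical(rep$protein_changed, v$protein_changed)
      expect_identical(rep$cds_start_moved, v$cds_start_moved)
      expect_identical(rep$cds_end_moved, v$cds_end_moved)
      expect_identical(rep$protein_after, v$protein_after)
    }
  }
})

test_that("category filters select corrections, variants or both", {
  fx <- generate_genome(fixture_spec(seed = 83, n_genes = 6))
  p <- fx$truth_project
  p$alterations <- fx$alterations
  cats <- vapply(p$alterations, `[[`, character(1), "category")
  expect_gte(length(unique(cats)), 2)   # both categories planted at this seed
  for (category in c("assembly_correction", "variant", "both")) {
    view <- project_annotations(p, category)
    applied <- sum(vapply(p$alterations, function(a)
      category == "both" || a$category == category, logical(1)))
    # bookkeeping law: net length change equals the applied indel sum
    net_regions <- sum(vapply(names(view$regions), function(rid)
      view$regions[[rid]]$length - p$regions[[rid]]$length, integer(1)))
    net_alts <- sum(vapply(Filter(function(a)
      category == "both" || a$category == category, p$alterations),
      function(a) nchar(a$alt_residues) - nchar(a$ref_residues), integer(1)))
    expect_identical(net_regions, net_alts)
  }
  # zero alterations: the view is structurally identical to the project
  p0 <- fx$truth_project
  view0 <- project_annotations(p0, "both")
  expect_identical(lapply(view0$genes, function(g)
    lapply(g$transcripts, `[[`, "exons")),
    lapply(p0$genes, function(g) lapply(g$transcripts, `[[`, "exons")))
  expect_false(any(vapply(view0$reports, `[[`, logical(1), "protein_changed")))
})

test_that("overlapping alterations are rejected rather than composed", {
  r <- mk_region("ACGTACGTACGT", id = "r")
  a <- sequence_alteration("deletion", "r", 2, "GTA", "")
  b <- sequence_alteration("substitution", "r", 4, "A", "C")
  expect_error(apply_alterations(r, list(a, b)), class = "af_conflict_error")
  # two insertions at the same point are ambiguous
  i1 <- sequence_alteration("insertion", "r", 3, "", "AA")
  i2 <- sequence_alteration("insertion", "r", 3, "", "CC")
  expect_error(apply_alterations(r, list(i1, i2)), class = "af_conflict_error")
})
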