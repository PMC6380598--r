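# A small edit vocabulary over one promoted transcript, used to build random
# scripts whose replays must reproduce every stored snapshot.

history_sandbox <- function(seed = 60, undo_depth = Inf) {
  fx <- generate_genome(fixture_spec(seed = seed, n_genes = 2,
                                     fraction_split_evidence = 0))
  p <- new_project(fx$regions, organism_config(undo_depth = undo_depth,
                                               timestamp_mode = "logical"),
                   users = list(user("alice_ok", "annotator")))
  p$evidence <- fx$evidence
  p <- promote_evidence(p, names(p$evidence)[1], "alice_ok")
  list(project = p, gene_id = p$last_edit$gene_id,
       tx_id = p$last_edit$transcript_id, regions = fx$regions)
}

# in history tests the editing user is "admin" unless stated
drag_by <- function(p, tid, delta, user = "admin") {
  t <- get_tx(p, tid)
  row <- nrow(t$exons)
  edge <- if (t$strand == "+") "three_prime" else "five_prime"
  idx <- if (t$strand == "+") row - 1L else 0L
  set_exon_boundary(p, tid, idx, edge, t$exons$end[row] + delta, user)
}

test_that("edits are versioned consecutively and attributed to their users", {
  sb <- history_sandbox()
  p <- sb$project
  p <- drag_by(p, sb$tx_id, 3L, "admin")
  p <- drag_by(p, sb$tx_id, 3L, "admin")
  h <- list_history(p, sb$gene_id)
  expect_identical(h$version, 1:3)
  expect_identical(h$username[1], "alice_ok")   # the promoting user
  expect_identical(sum(h$is_current), 1L)
  expect_true(h$is_current[3])
  expect_true(all(diff(as.POSIXct(h$timestamp, tz = "UTC",
                                  format = "%Y-%m-%dT%H:%M:%SZ")) >= 0))
})

test_that("undo/redo move the cursor and restore exact snapshots", {
  sb <- history_sandbox()
  p <- sb$project
  p <- drag_by(p, sb$tx_id, 3L)
  p <- drag_by(p, sb$tx_id, 3L)
  live_v3 <- p$genes[[sb$gene_id]]
  p2 <- undo_edit(p, sb$gene_id)
  expect_true(list_history(p2, sb$gene_id)$is_current[2])
  p3 <- redo_edit(p2, sb$gene_id)
  expect_identical(p3$genes[[sb$gene_id]], live_v3)
  # k edits then undoing to the floor reproduces the version-1 snapshot
  q <- p
  q <- undo_edit(q, sb$gene_id)
  q <- undo_edit(q, sb$gene_id)
  expect_identical(q$genes[[sb$gene_id]],
                   q$history$features[[sb$gene_id]]$records[[1]]$snapshot)
  expect_error(undo_edit(q, sb$gene_id), class = "af_history_error")
  expect_error(redo_edit(p, sb$gene_id), class = "af_history_error")
})

test_that("editing after undo discards the forward records", {
  sb <- history_sandbox()
  p <- sb$project
  p <- drag_by(p, sb$tx_id, 3L)
  p <- drag_by(p, sb$tx_id, 3L)
  p <- undo_edit(p, sb$gene_id)
  p <- drag_by(p, sb$tx_id, 6L)
  h <- list_history(p, sb$gene_id)
  expect_identical(h$version, 1:3)
  expect_true(h$is_current[3])
})

test_that("a finite undo depth prunes old records but keeps version numbers", {
  sb <- history_sandbox(undo_depth = 2)
  p <- sb$project
  for (d in c(3L, 6L, 9L, 12L)) p <- drag_by(p, sb$tx_id, d)
  h <- list_history(p, sb$gene_id)
  expect_identical(h$version, 4:5)
  p <- undo_edit(p, sb$gene_id)      # to version 4, the earliest retained
  expect_error(undo_edit(p, sb$gene_id), class = "af_history_error")
  expect_error(revert_to_version(p, sb$gene_id, 2, "admin"),
               class = "af_not_found_error")
})

test_that("revert restores a version and appends a new attributed record", {
  sb <- history_sandbox()
  p <- sb$project
  p <- drag_by(p, sb$tx_id, 3L)      # v2
  p <- drag_by(p, sb$tx_id, 3L)      # v3
  v1_snap <- p$history$features[[sb$gene_id]]$records[[1]]$snapshot
  p2 <- revert_to_version(p, sb$gene_id, 1, "admin")
  expect_identical(p2$genes[[sb$gene_id]], v1_snap)
  h <- list_history(p2, sb$gene_id)
  expect_identical(h$version, 1:4)
  expect_identical(h$operation[4], "revert")
  # reverting to the current version changes nothing but still records
  p3 <- revert_to_version(p2, sb$gene_id, 4, "admin")
  expect_identical(p3$genes[[sb$gene_id]], p2$genes[[sb$gene_id]])
  expect_identical(nrow(list_history(p3, sb$gene_id)), 5L)
  # A,B,C then revert(1) then D: 5 records, live = D applied to A's state
  p4 <- drag_by(p2, sb$tx_id, 3L)
  expect_identical(nrow(list_history(p4, sb$gene_id)), 5L)
})

test_that("random edit scripts satisfy cursor-snapshot and replay equivalence", {
  set.seed(61)
  replay <- function(p0, records, upto) {
    p <- p0
    for (r in records[seq_len(upto)]) {
      p <- switch(r$operation,
        promote_evidence = promote_evidence(p, r$params$evidence, r$username),
        set_exon_boundary = set_exon_boundary(
          p, r$params$transcript, r$params$exon_index, r$params$edge,
          r$params$to, r$username),
        set_translation_boundary = set_translation_boundary(
          p, r$params$transcript, r$params$which, r$params$position,
          r$username),
        revert = revert_to_version(p, names(p$genes)[1], r$params$version,
                                   r$username),
        stop("unexpected op ", r$operation))
    }
    p
  }
  for (rep in 1:25) {
    sb <- history_sandbox(seed = 100 + rep)
    p0_before_promote <- new_project(sb$regions,
                                     organism_config(timestamp_mode = "logical"),
                                     users = list(user("alice_ok", "annotator")))
    p0_before_promote$evidence <- sb$project$evidence
    p <- sb$project
    gid <- sb$gene_id; tid <- sb$tx_id
    n_ops <- sample(5:20, 1)
    for (i in seq_len(n_ops)) {
      op <- sample(c("drag", "pin", "undo", "redo", "revert"), 1,
                   prob = c(0.4, 0.15, 0.2, 0.15, 0.1))
      h <- p$history$features[[gid]]
      p <- switch(op,
        drag = tryCatch(drag_by(p, tid, sample(c(-3L, 3L, 6L), 1)),
                        af_boundary_error = function(e) p,
                        af_bounds_error = function(e) p),
        pin = {
          t <- get_tx(p, tid)
          base <- if (t$strand == "+") t$cds[1] %||% t$exons$start[1] else
            (t$cds[2] %||% t$exons$end[nrow(t$exons)]) - 1L
          set_translation_boundary(p, tid, "start", base, "admin")
        },
        undo = tryCatch(undo_edit(p, gid), af_history_error = function(e) p),
        redo = tryCatch(redo_edit(p, gid), af_history_error = function(e) p),
        revert = {
          vs <- vapply(h$records, `[[`, integer(1), "version")
          revert_to_version(p, gid, sample(vs, 1), "admin")
        })
      # live state always equals the snapshot at the cursor
      h2 <- p$history$features[[gid]]
      cursor_rec <- h2$records[[h2$cursor - h2$records[[1]]$version + 1L]]
      expect_identical(p$genes[[gid]], cursor_rec$snapshot)
    }
    # independent replay of operations 1..cursor reproduces the live state
    h <- p$history$features[[gid]]
    upto <- h$cursor
    rp <- replay(p0_before_promote, h$records, upto)
    expect_identical(rp$genes[[gid]], p$genes[[gid]])
  }
})

test_that("history is append-only: records never change once written", {
  sb <- history_sandbox()
  p <- sb$project
  p <- drag_by(p, sb$tx_id, 3L)
  frozen <- p$history$features[[sb$gene_id]]$records
  p <- drag_by(p, sb$tx_id, 3L)
  p <- revert_to_version(p, sb$gene_id, 1, "admin")
  now <- p$history$features[[sb$gene_id]]$records
  expect_identical(now[seq_along(frozen)], frozen)
})

test_that("snapshots round-trip through serialization unchanged", {
  sb <- history_sandbox()
  p <- drag_by(sb$project, sb$tx_id, 3L)
  for (rec in p$history$features[[sb$gene_id]]$records) {
    ser <- jsonlite::toJSON(annoforge:::ser_gene(rec$snapshot),
                            auto_unbox = TRUE, digits = NA, null = "null")
    back <- annoforge:::deser_gene(jsonlite::fromJSON(ser,
                                                      simplifyVector = FALSE))
    expect_identical(back, rec$snapshot)
  }
})

test_that("listeners receive every committed record synchronously", {
  seen <- new.env(); seen$n <- 0L
  clear_edit_listeners()
  register_edit_listener(function(fid, rec) seen$n <- seen$n + 1L)
  sb <- history_sandbox()
  p <- drag_by(sb$project, sb$tx_id, 3L)
  clear_edit_listeners()
  expect_gte(seen$n, 2L)   # promote + drag
  # history export is one JSON object per line
  path <- tempfile(fileext = ".jsonl")
  export_history_jsonl(p, path)
  lines <- readLines(path)
  expect_identical(length(lines), nrow(list_history(p, sb$gene_id)))
  for (l in lines) expect_silent(jsonlite::fromJSON(l))
})
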