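# Attributed, revertible edit history.  Granularity is the top-level feature
# (the gene): each gene carries a linear list of versioned records, each with
# a full state snapshot, plus a cursor marking the live version.  A
# project-level log indexes every record for global search.  Listeners
# registered in-process receive every committed record synchronously.

.af_listeners <- new.env(parent = emptyenv())

#' Register / clear edit listeners
#'
#' Listeners are called synchronously with every committed edit record
#' (`function(feature_id, record)`); they replace network push in a headless
#' setting.
#' @param fn A function of (feature_id, record).
#' @export
register_edit_listener <- function(fn) {
  id <- as.character(length(ls(.af_listeners)) + 1L)
  assign(id, fn, envir = .af_listeners)
  invisible(id)
}

#' @rdname register_edit_listener
#' @export
clear_edit_listeners <- function() {
  rm(list = ls(.af_listeners), envir = .af_listeners)
  invisible(NULL)
}

notify_listeners <- function(feature_id, record) {
  for (id in ls(.af_listeners)) {
    get(id, envir = .af_listeners)(feature_id, record)
  }
}

#' Record an edit against a feature's history
#'
#' Appends a record at `max_version + 1`, attributed to `username` with an
#' ISO-8601 UTC timestamp and a full snapshot of the feature after the edit.
#' When the cursor sits behind the newest version (after undo), the forward
#' records are discarded first.  With a finite `undo_depth`, the oldest
#' records beyond the depth are pruned; version numbers are preserved.
#'
#' This is called by every editing operation; it is exported so variant
#' commits and extensions can participate in the same history.
#'
#' @param project Annotation project.
#' @param feature_id Top-level feature (gene) id.
#' @param username Editing user.
#' @param operation Operation name.
#' @param params Named list of serializable operation parameters.
#' @param snapshot Full feature state after the edit (defaults to the live
#'   gene).
#' @return The updated project; the new record is in `project$last_edit$record`.
#' @export
record_edit <- function(project, feature_id, username, operation,
                        params = list(), snapshot = NULL) {
  snapshot <- snapshot %||% project$genes[[feature_id]]
  h <- project$history$features[[feature_id]] %||% list(records = list(), cursor = 0L)
  if (length(h$records)) {
    keep <- vapply(h$records, function(r) r$version <= h$cursor, logical(1))
    h$records <- h$records[keep]
  }
  version <- if (length(h$records)) h$records[[length(h$records)]]$version + 1L else 1L
  project$counters$edit <- project$counters$edit + 1L
  rec <- structure(
    list(version = version, username = username,
         timestamp = af_timestamp(project$config, project$counters$edit),
         operation = operation, params = params, snapshot = snapshot),
    class = "edit_record"
  )
  h$records[[length(h$records) + 1L]] <- rec
  h$cursor <- version
  depth <- project$config$undo_depth %||% Inf
  if (is.finite(depth) && length(h$records) > depth) {
    h$records <- h$records[seq.int(length(h$records) - depth + 1L, length(h$records))]
  }
  project$history$features[[feature_id]] <- h
  project$history$log[[length(project$history$log) + 1L]] <-
    list(feature_id = feature_id, version = version, username = username,
         timestamp = rec$timestamp, operation = operation)
  project$last_edit <- list(feature_id = feature_id, record = rec)
  notify_listeners(feature_id, rec)
  project
}

feature_history <- function(project, feature_id) {
  h <- project$history$features[[feature_id]]
  if (is.null(h) || !length(h$records))
    af_not_found_error(sprintf("no history for feature '%s'", feature_id))
  h
}

restore_snapshot <- function(project, feature_id, snapshot) {
  project$genes[[feature_id]] <- snapshot
  project
}

#' Undo / redo the last structural edit of a feature
#'
#' Moves the feature's history cursor one version back (or forward) and
#' replaces the live feature with the snapshot at the cursor.  At the
#' boundary (cursor at the earliest retained version, or at the newest) an
#' error is raised and the project is unchanged.
#'
#' @param project Annotation project.
#' @param feature_id Gene id.
#' @return Updated project.
#' @export
undo_edit <- function(project, feature_id) {
  h <- feature_history(project, feature_id)
  earliest <- h$records[[1L]]$version
  if (h$cursor <= earliest)
    af_error("af_history_error",
             sprintf("nothing to undo for '%s' (at earliest retained version %d)",
                     feature_id, earliest))
  h$cursor <- h$cursor - 1L
  rec <- h$records[[h$cursor - earliest + 1L]]
  project$history$features[[feature_id]] <- h
  restore_snapshot(project, feature_id, rec$snapshot)
}

#' @rdname undo_edit
#' @export
redo_edit <- function(project, feature_id) {
  h <- feature_history(project, feature_id)
  latest <- h$records[[length(h$records)]]$version
  if (h$cursor >= latest)
    af_error("af_history_error", sprintf("nothing to redo for '%s'", feature_id))
  h$cursor <- h$cursor + 1L
  earliest <- h$records[[1L]]$version
  rec <- h$records[[h$cursor - earliest + 1L]]
  project$history$features[[feature_id]] <- h
  restore_snapshot(project, feature_id, rec$snapshot)
}

#' Revert a feature to a recorded version
#'
#' Sets the live state to the snapshot at `version` and appends a *new*
#' record ("revert to v") attributed to `username`: history is append-only,
#' and reverting is itself an edit one can undo.
#'
#' @param project Annotation project.
#' @param feature_id Gene id.
#' @param version Retained version number to restore.
#' @param username The reverting user.
#' @return Updated project.
#' @export
revert_to_version <- function(project, feature_id, version, username) {
  check_can_edit(project, username)
  h <- feature_history(project, feature_id)
  versions <- vapply(h$records, `[[`, integer(1), "version")
  idx <- match(as.integer(version), versions)
  if (is.na(idx))
    af_not_found_error(sprintf(
      "version %s of '%s' is unknown or pruned (retained: %d..%d)",
      version, feature_id, min(versions), max(versions)))
  snap <- h$records[[idx]]$snapshot
  # reverting never discards the redo tail: unlike an ordinary edit after
  # undo, the new record is appended after the newest version so that every
  # version a revert record references stays replayable
  h$cursor <- h$records[[length(h$records)]]$version
  project$history$features[[feature_id]] <- h
  project <- restore_snapshot(project, feature_id, snap)
  record_edit(project, feature_id, username, "revert",
              params = list(version = as.integer(version)), snapshot = snap)
}

#' List a feature's retained history
#'
#' @param project Annotation project.
#' @param feature_id Gene id.
#' @return data.frame with columns version, username, timestamp, operation,
#'   is_current (exactly one row current), oldest first.
#' @export
list_history <- function(project, feature_id) {
  h <- feature_history(project, feature_id)
  data.frame(
    version = vapply(h$records, `[[`, integer(1), "version"),
    username = vapply(h$records, `[[`, character(1), "username"),
    timestamp = vapply(h$records, `[[`, character(1), "timestamp"),
    operation = vapply(h$records, `[[`, character(1), "operation"),
    is_current = vapply(h$records, function(r) r$version == h$cursor, logical(1))
  )
}

#' Export history as JSON lines
#'
#' One record per line (version, username, timestamp, operation, params),
#' suitable for audit pipelines.  Snapshots are omitted from the audit
#' export; use the project serializer for full state.
#'
#' @param project Annotation project.
#' @param path Output file.
#' @export
export_history_jsonl <- function(project, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (fid in names(project$history$features)) {
    for (r in project$history$features[[fid]]$records) {
      writeLines(jsonlite::toJSON(
        list(feature_id = fid, version = r$version, username = r$username,
             timestamp = r$timestamp, operation = r$operation,
             params = r$params),
        auto_unbox = TRUE, digits = NA), con)
    }
  }
  invisible(path)
}
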