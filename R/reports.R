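# Consumer-facing query layer. All summaries are unweighted arithmetic means
# over the analyses matching the filter, with n = number of analyses that
# contributed; superseded re-runs of the same identity never contribute.

fetch_scope_rows <- function(store, scope, ids) {
  store$assert_open()
  if (!length(ids)) {
    return(data.frame(analysis_id = integer(0), key = character(0),
                      value = numeric(0), text_value = character(0),
                      position = integer(0), start_pos = integer(0),
                      end_pos = integer(0), description = character(0),
                      stringsAsFactors = FALSE))
  }
  idlist <- paste(ids, collapse = ",")
  if (scope == "analysis") {
    DBI::dbGetQuery(store$con, sprintf(
      "SELECT av.analysis_id, vt.value_type AS key, av.value, av.text_value,
              vt.description
         FROM analysis_value av
         JOIN value_type vt ON av.value_type_id = vt.id
        WHERE av.analysis_id IN (%s)", idlist))
  } else if (scope == "sequence_cumulative") {
    DBI::dbGetQuery(store$con, sprintf(
      "SELECT pv.analysis_id, vt.value_type AS key, pv.position, pv.value,
              vt.description
         FROM per_position_value pv
         JOIN value_type vt ON pv.value_type_id = vt.id
        WHERE pv.analysis_id IN (%s)", idlist))
  } else {
    DBI::dbGetQuery(store$con, sprintf(
      "SELECT pv.analysis_id, vt.value_type AS key, pv.start_pos, pv.end_pos,
              pv.value, vt.description
         FROM per_partition_value pv
         JOIN value_type vt ON pv.value_type_id = vt.id
        WHERE pv.analysis_id IN (%s)", idlist))
  }
}

stored_scope_of <- function(store, key) {
  row <- DBI::dbGetQuery(store$con,
    "SELECT ts.scope FROM value_type vt JOIN type_scope ts
       ON vt.type_scope_id = ts.id WHERE vt.value_type = ?",
    params = list(key))
  if (nrow(row) == 0L) return(NA_character_)
  row$scope
}

guard_scope <- function(store, key, expected, alternative) {
  s <- stored_scope_of(store, key)
  if (!is.na(s) && s != expected) {
    stop(sprintf(
      "value type '%s' has scope '%s', not '%s'; use the %s query instead",
      key, s, expected, alternative), call. = FALSE)
  }
  invisible(s)
}

#' List all runs in the store
#'
#' @param store an open \code{qc_store}.
#' @return Distinct values of the \code{run} property, sorted.
#' @export
list_runs <- function(store) {
  store$assert_open()
  DBI::dbGetQuery(store$con,
    "SELECT DISTINCT value FROM analysis_property
      WHERE property = 'run' AND value IS NOT NULL ORDER BY value")$value
}

#' List the properties usable as query filters
#'
#' The property keys present in the store, restricted to the ten controlled
#' platform-agnostic keys accepted by [property_filter()]; returned in their
#' controlled (query-side) spelling.
#'
#' @param store an open \code{qc_store}.
#' @return Character vector of controlled keys, sorted.
#' @export
list_selectable_properties <- function(store) {
  store$assert_open()
  present <- DBI::dbGetQuery(store$con,
    "SELECT DISTINCT property FROM analysis_property")$property
  sort(names(CONTROLLED_KEY_MAP)[CONTROLLED_KEY_MAP %in% present])
}

#' List stored values of a controlled property
#'
#' @param store an open \code{qc_store}.
#' @param property one of the controlled keys (e.g. \code{"lane"},
#'   \code{"barcode"}); other keys are rejected.
#' @return Distinct stored values, sorted.
#' @export
list_selectable_values_from_property <- function(store, property) {
  store$assert_open()
  if (!(property %in% names(CONTROLLED_KEY_MAP))) {
    stop(sprintf("'%s' is not a controlled query key", property), call. = FALSE)
  }
  DBI::dbGetQuery(store$con,
    "SELECT DISTINCT value FROM analysis_property
      WHERE property = ? AND value IS NOT NULL ORDER BY value",
    params = list(CONTROLLED_KEY_MAP[[property]]))$value
}

#' List registered value types of one scope
#'
#' Returns every value type registered under the scope together with its
#' stored description (the first description ever supplied; later ones are
#' ignored by design). Useful to check whether a value type already exists
#' before inserting it again.
#'
#' @param store an open \code{qc_store}.
#' @param scope one of [TYPE_SCOPES].
#' @return A data.frame with columns \code{value_type}, \code{description}.
#' @export
list_summary_per_scope <- function(store, scope) {
  store$assert_open()
  assert_scope(scope)
  DBI::dbGetQuery(store$con,
    "SELECT vt.value_type, vt.description
       FROM value_type vt JOIN type_scope ts ON vt.type_scope_id = ts.id
      WHERE ts.scope = ? ORDER BY vt.value_type",
    params = list(scope))
}

#' Summary of global (analysis-scope) values
#'
#' One row per analysis-scope value type present among the matching analyses:
#' the key, the arithmetic mean of its numeric values across those analyses,
#' and the number of analyses that contributed. Text-valued entries are
#' excluded from the mean and reported by count only (empty mean cell).
#'
#' @param store an open \code{qc_store}.
#' @param f a [property_filter()]; empty matches everything.
#' @return A [report_table()] with columns \code{key}, \code{mean}, \code{n}.
#' @export
get_average_values <- function(store, f = property_filter()) {
  ids <- active_ids(store, f)
  rows <- fetch_scope_rows(store, "analysis", ids)
  keys <- sort(unique(rows$key))
  out <- data.frame(key = character(0), mean = numeric(0), n = integer(0),
                    stringsAsFactors = FALSE)
  for (k in keys) {
    sub <- rows[rows$key == k, ]
    num <- sub$value[!is.na(sub$value)]
    out <- rbind(out, data.frame(
      key = k,
      mean = if (length(num)) mean(num) else NA_real_,
      n = length(unique(sub$analysis_id)),
      stringsAsFactors = FALSE))
  }
  report_table(out, length(ids))
}

#' Per-position summary of a sequence-cumulative metric
#'
#' Rows of (position, mean value across matching analyses, n of contributing
#' analyses), ordered by position. Querying a key of another scope is an
#' error pointing at the right query.
#'
#' @param store an open \code{qc_store}.
#' @param key a metric with scope \code{sequence_cumulative}.
#' @param f a [property_filter()].
#' @return A [report_table()] with columns \code{position}, \code{mean},
#'   \code{n}.
#' @export
get_per_position_values <- function(store, key, f = property_filter()) {
  guard_scope(store, key, "sequence_cumulative", "partition/global")
  ids <- active_ids(store, f)
  rows <- fetch_scope_rows(store, "sequence_cumulative", ids)
  rows <- rows[rows$key == key, ]
  positions <- sort(unique(rows$position))
  out <- data.frame(position = integer(0), mean = numeric(0), n = integer(0),
                    stringsAsFactors = FALSE)
  for (p in positions) {
    sub <- rows[rows$position == p, ]
    out <- rbind(out, data.frame(
      position = p, mean = mean(sub$value),
      n = length(unique(sub$analysis_id)), stringsAsFactors = FALSE))
  }
  report_table(out, length(ids))
}

#' Per-partition summary of a base-partition metric
#'
#' Rows of (start, end, mean value, n), grouped by identical (start, end)
#' pairs across the matching analyses and ordered by start then end. Analyses
#' whose partitioning differs contribute separate rows; partitions are never
#' blended.
#'
#' @param store an open \code{qc_store}.
#' @param key a metric with scope \code{base_partition}.
#' @param f a [property_filter()].
#' @return A [report_table()] with columns \code{start}, \code{end},
#'   \code{mean}, \code{n}.
#' @export
get_per_partition_values <- function(store, key, f = property_filter()) {
  guard_scope(store, key, "base_partition", "position/global")
  ids <- active_ids(store, f)
  rows <- fetch_scope_rows(store, "base_partition", ids)
  rows <- rows[rows$key == key, ]
  out <- data.frame(start = integer(0), end = integer(0), mean = numeric(0),
                    n = integer(0), stringsAsFactors = FALSE)
  if (nrow(rows)) {
    parts <- unique(rows[, c("start_pos", "end_pos")])
    parts <- parts[order(parts$start_pos, parts$end_pos), , drop = FALSE]
    for (i in seq_len(nrow(parts))) {
      sub <- rows[rows$start_pos == parts$start_pos[i] &
                  rows$end_pos == parts$end_pos[i], ]
      out <- rbind(out, data.frame(
        start = parts$start_pos[i], end = parts$end_pos[i],
        mean = mean(sub$value), n = length(unique(sub$analysis_id)),
        stringsAsFactors = FALSE))
    }
  }
  report_table(out, length(ids))
}

#' Summary values with their descriptive comments
#'
#' For a scope, one row per value type key: the key, its summarised value
#' (mean of numeric values; for text values, the value from the most recent
#' contributing analysis), the description stored with the value type (empty
#' when none), and n. The canonical use is retrieving overrepresented
#' sequences together with their likely source.
#'
#' @param store an open \code{qc_store}.
#' @param scope one of [TYPE_SCOPES].
#' @param f a [property_filter()].
#' @return A [report_table()] with columns \code{key}, \code{value},
#'   \code{description}, \code{n}.
#' @export
get_summary_values_with_comments <- function(store, scope, f = property_filter()) {
  assert_scope(scope)
  ids <- active_ids(store, f)
  rows <- fetch_scope_rows(store, scope, ids)
  keys <- sort(unique(rows$key))
  out <- data.frame(key = character(0), value = character(0),
                    description = character(0), n = integer(0),
                    stringsAsFactors = FALSE)
  for (k in keys) {
    sub <- rows[rows$key == k, ]
    desc <- sub$description[[1L]]
    if (is.na(desc)) desc <- ""
    if (scope == "analysis") {
      num <- sub$value[!is.na(sub$value)]
      val <- if (length(num)) {
        format(mean(num), digits = 15, trim = TRUE, scientific = FALSE)
      } else {
        # text values: latest contributing analysis wins
        txt <- sub$text_value[order(sub$analysis_id)]
        txt[length(txt)]
      }
    } else {
      val <- format(mean(sub$value), digits = 15, trim = TRUE,
                    scientific = FALSE)
    }
    out <- rbind(out, data.frame(
      key = k, value = val, description = desc,
      n = length(unique(sub$analysis_id)), stringsAsFactors = FALSE))
  }
  report_table(out, length(ids))
}

#' Per-position base-content matrix
#'
#' Joins the four per-partition base-content metrics (\code{base_content_a},
#' \code{_c}, \code{_g}, \code{_t}) into one matrix: columns (start, end, A,
#' C, G, T), one row per partition, equal to the column-wise join of four
#' [get_per_partition_values()] calls. A base missing for a partition yields
#' an empty cell.
#'
#' @param store an open \code{qc_store}.
#' @param f a [property_filter()].
#' @return A [report_table()].
#' @export
get_per_position_base_content <- function(store, f = property_filter()) {
  bases <- c(A = "base_content_a", C = "base_content_c",
             G = "base_content_g", T = "base_content_t")
  tabs <- lapply(bases, function(k) {
    if (is.na(stored_scope_of(store, k))) NULL
    else as.data.frame(get_per_partition_values(store, k, f))
  })
  parts <- unique(do.call(rbind, lapply(tabs, function(d) {
    if (is.null(d) || !nrow(d)) NULL else d[, c("start", "end")]
  })))
  n_an <- length(active_ids(store, f))
  if (is.null(parts) || !nrow(parts)) {
    return(report_table(data.frame(start = integer(0), end = integer(0),
                                   A = numeric(0), C = numeric(0),
                                   G = numeric(0), T = numeric(0),
                                   stringsAsFactors = FALSE), n_an))
  }
  parts <- parts[order(parts$start, parts$end), , drop = FALSE]
  out <- data.frame(start = parts$start, end = parts$end,
                    A = NA_real_, C = NA_real_, G = NA_real_, T = NA_real_,
                    stringsAsFactors = FALSE)
  for (b in names(bases)) {
    d <- tabs[[b]]
    if (is.null(d) || !nrow(d)) next
    idx <- match(paste(out$start, out$end), paste(d$start, d$end))
    out[[b]] <- d$mean[idx]
  }
  report_table(out, n_an)
}
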