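#' @importFrom DBI dbConnect dbDisconnect dbExecute dbGetQuery dbBegin dbCommit
#'   dbRollback dbIsValid
NULL

#' Read a store configuration file
#'
#' Plain text, one \code{key<whitespace>value} pair per line, \code{#} comment
#' lines ignored. Two key dialects are accepted and may be mixed:
#' \code{db_string} / \code{db_user} / \code{db_password}, or
#' \code{statsdb.url} / \code{statsdb.username} / \code{statsdb.password} /
#' \code{statsdb.driver}. The connection string (\code{db_string} or
#' \code{statsdb.url}) is required. For the embedded engine it is simply the
#' path of the database file (optionally prefixed \code{sqlite:}), or
#' \code{:memory:} for a transient in-memory store. Server URLs
#' (\code{mysql}/\code{jdbc}) are recognised but rejected: only the embedded
#' engine ships.
#'
#' @param path path to the config file.
#' @return A \code{store_config} object (list with \code{db_string},
#'   \code{user}, \code{password}).
#' @export
read_store_config <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("config file not found: %s", path), call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- list()
  for (ln in lines) {
    # key=value (Java properties) or key<ws>value (Perl dialect)
    if (grepl("=", ln, fixed = TRUE)) {
      key <- trimws(sub("=.*$", "", ln))
      val <- trimws(sub("^[^=]*=", "", ln))
    } else {
      key <- sub("\\s.*$", "", ln)
      val <- trimws(sub("^\\S+\\s*", "", ln))
    }
    if (nzchar(key)) kv[[key]] <- val
  }
  db_string <- kv[["db_string"]] %||% kv[["statsdb.url"]]
  if (is.null(db_string) || !nzchar(db_string)) {
    stop("config error: missing required key 'db_string' (or 'statsdb.url')",
         call. = FALSE)
  }
  structure(
    list(
      db_string = db_string,
      user = kv[["db_user"]] %||% kv[["statsdb.username"]],
      password = kv[["db_password"]] %||% kv[["statsdb.password"]]
    ),
    class = "store_config"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' In-memory store configuration
#'
#' Convenience constructor for a transient embedded store, mostly for tests
#' and examples.
#' @return A \code{store_config} pointing at \code{:memory:}.
#' @export
memory_config <- function() {
  structure(list(db_string = ":memory:", user = NULL, password = NULL),
            class = "store_config")
}

sqlite_path_from_db_string <- function(db_string) {
  s <- db_string
  if (grepl("mysql|jdbc|postgres", s, ignore.case = TRUE)) {
    stop(sprintf(
      "connection error: server engines are not available in this build (db_string '%s'); use an embedded database file path",
      s), call. = FALSE)
  }
  s <- sub("^sqlite:(//)?", "", s)
  s <- sub("^dbi:SQLite:", "", s, ignore.case = TRUE)
  if (!nzchar(s)) stop("config error: empty database path", call. = FALSE)
  s
}

StoreR6 <- R6::R6Class("StoreR6",
  public = list(
    con = NULL,
    path = NULL,
    initialize = function(con, path) {
      self$con <- con
      self$path <- path
    },
    is_open = function() {
      !is.null(self$con) && DBI::dbIsValid(self$con)
    },
    assert_open = function() {
      if (!self$is_open()) stop("store is not open", call. = FALSE)
      invisible(self)
    }
  )
)

SCHEMA_SQL <- c(
  "CREATE TABLE IF NOT EXISTS analysis (
     analysis_id INTEGER PRIMARY KEY AUTOINCREMENT,
     timestamp   REAL NOT NULL
   )",
  "CREATE TABLE IF NOT EXISTS analysis_property (
     analysis_id INTEGER NOT NULL REFERENCES analysis(analysis_id),
     property    TEXT NOT NULL,
     value       TEXT
   )",
  "CREATE TABLE IF NOT EXISTS type_scope (
     id    INTEGER PRIMARY KEY,
     scope TEXT NOT NULL UNIQUE
   )",
  "CREATE TABLE IF NOT EXISTS value_type (
     id            INTEGER PRIMARY KEY AUTOINCREMENT,
     value_type    TEXT NOT NULL UNIQUE,
     type_scope_id INTEGER NOT NULL REFERENCES type_scope(id),
     description   TEXT
   )",
  "CREATE TABLE IF NOT EXISTS analysis_value (
     analysis_id   INTEGER NOT NULL REFERENCES analysis(analysis_id),
     value_type_id INTEGER NOT NULL REFERENCES value_type(id),
     value         REAL,
     text_value    TEXT
   )",
  "CREATE TABLE IF NOT EXISTS per_position_value (
     analysis_id   INTEGER NOT NULL REFERENCES analysis(analysis_id),
     value_type_id INTEGER NOT NULL REFERENCES value_type(id),
     position      INTEGER NOT NULL,
     value         REAL NOT NULL
   )",
  "CREATE TABLE IF NOT EXISTS per_partition_value (
     analysis_id   INTEGER NOT NULL REFERENCES analysis(analysis_id),
     value_type_id INTEGER NOT NULL REFERENCES value_type(id),
     start_pos     INTEGER NOT NULL,
     end_pos       INTEGER NOT NULL,
     value         REAL NOT NULL
   )"
)

#' Open (and on first use create) a metrics store
#'
#' Connects to the embedded SQLite database named by the configuration and
#' creates the schema if the database is empty. The store is append-only:
#' analyses are inserted, never updated or deleted.
#'
#' @param config a \code{store_config} from [read_store_config()] /
#'   [memory_config()], a path to a config file, or directly a database file
#'   path (or \code{":memory:"}).
#' @return An open \code{qc_store} handle.
#' @export
connect_store <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    # a config file if it parses as one, else a bare database path
    if (file.exists(config) && !is_sqlite_file(config)) {
      parsed <- tryCatch(read_store_config(config), error = function(e) e)
      if (inherits(parsed, "error")) {
        if (grepl("^config error", conditionMessage(parsed))) stop(parsed)
      } else {
        config <- parsed
      }
    }
    if (is.character(config)) {
      config <- structure(list(db_string = config, user = NULL, password = NULL),
                          class = "store_config")
    }
  }
  if (!inherits(config, "store_config")) {
    stop("config error: expected a store_config or a path", call. = FALSE)
  }
  path <- sqlite_path_from_db_string(config$db_string)
  con <- tryCatch(
    DBI::dbConnect(RSQLite::SQLite(), path),
    error = function(e) {
      stop(sprintf("connection error: cannot open '%s': %s",
                   path, conditionMessage(e)), call. = FALSE)
    }
  )
  DBI::dbExecute(con, "PRAGMA foreign_keys = ON")
  for (sql in SCHEMA_SQL) DBI::dbExecute(con, sql)
  n_scopes <- DBI::dbGetQuery(con, "SELECT COUNT(*) AS n FROM type_scope")$n
  if (n_scopes == 0L) {
    for (i in seq_along(TYPE_SCOPES)) {
      DBI::dbExecute(con, "INSERT INTO type_scope (id, scope) VALUES (?, ?)",
                     params = list(i, TYPE_SCOPES[i]))
    }
  }
  st <- StoreR6$new(con, path)
  class(st) <- c("qc_store", class(st))
  st
}

is_sqlite_file <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", n = 15L)
  length(hdr) >= 15L && rawToChar(hdr) == "SQLite format 3"
}

#' Close a store handle
#'
#' Closing twice is a no-op; any use after closing raises an error. Data in a
#' file-backed store persists and is visible on reconnect.
#'
#' @param store an open \code{qc_store}.
#' @export
disconnect_store <- function(store) {
  if (inherits(store, "qc_store") && store$is_open()) {
    DBI::dbDisconnect(store$con)
  }
  invisible(NULL)
}

scope_id <- function(scope) match(scope, TYPE_SCOPES)

# Returns the value_type id, registering the type if unseen. A description is
# stored only the first time one is supplied for the key ("first wins").
ensure_value_type <- function(con, key, scope, description = NULL) {
  row <- DBI::dbGetQuery(con,
    "SELECT vt.id, ts.scope, vt.description
       FROM value_type vt JOIN type_scope ts ON vt.type_scope_id = ts.id
      WHERE vt.value_type = ?", params = list(key))
  if (nrow(row) == 0L) {
    DBI::dbExecute(con,
      "INSERT INTO value_type (value_type, type_scope_id, description) VALUES (?, ?, ?)",
      params = list(key, scope_id(scope), description %||% NA_character_))
    return(DBI::dbGetQuery(con, "SELECT last_insert_rowid() AS id")$id)
  }
  if (row$scope != scope) {
    stop(sprintf(
      "value type '%s' already stored with scope '%s'; analysis declares '%s'",
      key, row$scope, scope), call. = FALSE)
  }
  if (!is.null(description) && is.na(row$description)) {
    DBI::dbExecute(con, "UPDATE value_type SET description = ? WHERE id = ?",
                   params = list(description, row$id))
  }
  row$id
}

#' Insert a QC analysis into the store
#'
#' Creates one new analysis record (fresh id, insertion timestamp) and
#' persists all properties and values. Value types not yet present in the
#' store are registered automatically, so no a-priori catalogue of metrics is
#' needed. The insert is atomic: on any error (e.g. a scope conflict with an
#' already-stored value type of the same name) nothing is written.
#' Re-inserting an analysis with identical properties deliberately creates a
#' new record; queries resolve such re-runs with latest-wins semantics.
#'
#' @param store an open \code{qc_store}.
#' @param a a builder-validated [new_analysis()] object.
#' @return The new integer analysis id, invisibly.
#' @export
insert_analysis <- function(store, a) {
  store$assert_open()
  assert_analysis(a)
  con <- store$con
  DBI::dbBegin(con)
  ok <- FALSE
  on.exit(if (!ok) DBI::dbRollback(con))

  # first description seen in this analysis for each key wins locally too
  descs <- list()
  for (gv in a$general_values) {
    if (!is.null(gv$description) && is.null(descs[[gv$key]])) {
      descs[[gv$key]] <- gv$description
    }
  }
  type_ids <- new.env(parent = emptyenv())
  for (key in names(a$valid_types)) {
    assign(key,
           ensure_value_type(con, key, a$valid_types[[key]], descs[[key]]),
           envir = type_ids)
  }

  DBI::dbExecute(con, "INSERT INTO analysis (timestamp) VALUES (?)",
                 params = list(as.numeric(Sys.time())))
  id <- DBI::dbGetQuery(con, "SELECT last_insert_rowid() AS id")$id

  for (key in names(a$properties)) {
    DBI::dbExecute(con,
      "INSERT INTO analysis_property (analysis_id, property, value) VALUES (?, ?, ?)",
      params = list(id, key, a$properties[[key]]))
  }
  for (gv in a$general_values) {
    DBI::dbExecute(con,
      "INSERT INTO analysis_value (analysis_id, value_type_id, value, text_value)
       VALUES (?, ?, ?, ?)",
      params = list(id, get(gv$key, envir = type_ids),
                    gv$value %||% NA_real_, gv$text_value %||% NA_character_))
  }
  if (length(a$position_values)) {
    pv <- a$position_values
    DBI::dbExecute(con,
      "INSERT INTO per_position_value (analysis_id, value_type_id, position, value)
       VALUES (?, ?, ?, ?)",
      params = list(
        rep(id, length(pv)),
        vapply(pv, function(x) get(x$key, envir = type_ids), numeric(1)),
        vapply(pv, function(x) x$position, integer(1)),
        vapply(pv, function(x) x$value, numeric(1))
      ))
  }
  if (length(a$partition_values)) {
    pv <- a$partition_values
    DBI::dbExecute(con,
      "INSERT INTO per_partition_value (analysis_id, value_type_id, start_pos, end_pos, value)
       VALUES (?, ?, ?, ?, ?)",
      params = list(
        rep(id, length(pv)),
        vapply(pv, function(x) get(x$key, envir = type_ids), numeric(1)),
        vapply(pv, function(x) x$range$start, integer(1)),
        vapply(pv, function(x) x$range$end, integer(1)),
        vapply(pv, function(x) x$value, numeric(1))
      ))
  }
  DBI::dbCommit(con)
  ok <- TRUE
  invisible(id)
}

#' One row per analysis, property keys as columns
#'
#' Pivots the long property table into a wide one: the row count equals the
#' number of stored analyses, the column set is the union of property keys
#' present, and a missing property is an empty cell.
#'
#' @param store an open \code{qc_store}.
#' @return A data.frame with column \code{analysis_id} followed by one column
#'   per property key (sorted), values as text, \code{""} where absent.
#' @export
property_view <- function(store) {
  store$assert_open()
  ids <- DBI::dbGetQuery(store$con,
                         "SELECT analysis_id FROM analysis ORDER BY analysis_id")$analysis_id
  props <- DBI::dbGetQuery(store$con,
    "SELECT analysis_id, property, value FROM analysis_property")
  keys <- sort(unique(props$property))
  out <- data.frame(analysis_id = ids, stringsAsFactors = FALSE)
  for (k in keys) {
    col <- rep("", length(ids))
    sub <- props[props$property == k, ]
    col[match(sub$analysis_id, ids)] <- sub$value
    out[[k]] <- col
  }
  out
}

# controlled query key -> stored property name
CONTROLLED_KEY_MAP <- c(
  encoding             = "encoding",
  chemistry            = "chemistry",
  instrument           = "instrument",
  softwareOnInstrument = "software",
  typeOfExperiment     = "type",
  pair                 = "pair",
  sampleName           = "sample_name",
  lane                 = "lane",
  barcode              = "barcode",
  run                  = "run"
)

# properties that define the identity of an analysis for latest-wins
IDENTITY_PROPERTIES <- c("run", "lane", "pair", "barcode", "sample_name", "tool")

#' Build a property filter
#'
#' Queries select analyses by any subset of the ten controlled,
#' platform-agnostic keys: \code{encoding}, \code{chemistry},
#' \code{instrument}, \code{softwareOnInstrument}, \code{typeOfExperiment},
#' \code{pair}, \code{sampleName}, \code{lane}, \code{barcode}, \code{run}.
#' An empty filter is legal and matches every analysis. Keys outside this set
#' are rejected.
#'
#' @param ... named filter entries, e.g. \code{run = "RUN-123", lane = "1"}.
#' @return A \code{property_filter} object.
#' @export
property_filter <- function(...) {
  entries <- list(...)
  if (length(entries) == 1L && is.null(names(entries)) &&
      (is.list(entries[[1L]]) || inherits(entries[[1L]], "property_filter"))) {
    entries <- as.list(entries[[1L]])
  }
  if (length(entries) && (is.null(names(entries)) || any(!nzchar(names(entries))))) {
    stop("all filter entries must be named", call. = FALSE)
  }
  bad <- setdiff(names(entries), names(CONTROLLED_KEY_MAP))
  if (length(bad)) {
    stop(sprintf("unknown filter key(s): %s (allowed: %s)",
                 paste(bad, collapse = ", "),
                 paste(names(CONTROLLED_KEY_MAP), collapse = ", ")),
         call. = FALSE)
  }
  entries <- lapply(entries, as.character)
  structure(entries, class = "property_filter")
}

as_property_filter <- function(f) {
  if (inherits(f, "property_filter")) return(f)
  if (is.null(f)) return(property_filter())
  if (is.list(f) || is.character(f)) return(do.call(property_filter, as.list(f)))
  stop("not a property filter", call. = FALSE)
}

# Analyses matching the filter after excluding superseded re-runs: within each
# identity group (run, lane, pair, barcode, sample_name, tool) only the most
# recent analysis (newest timestamp, tie -> highest id) survives.
active_ids <- function(store, f = property_filter()) {
  store$assert_open()
  f <- as_property_filter(f)
  an <- DBI::dbGetQuery(store$con,
                        "SELECT analysis_id, timestamp FROM analysis")
  if (nrow(an) == 0L) return(integer(0))
  props <- DBI::dbGetQuery(store$con,
    "SELECT analysis_id, property, value FROM analysis_property")
  ids <- an$analysis_id
  for (ck in names(f)) {
    prop <- CONTROLLED_KEY_MAP[[ck]]
    keep <- props$analysis_id[props$property == prop & props$value == f[[ck]]]
    ids <- intersect(ids, keep)
  }
  if (!length(ids)) return(integer(0))
  # latest-wins within identity groups
  identity_of <- function(id) {
    vals <- vapply(IDENTITY_PROPERTIES, function(p) {
      v <- props$value[props$analysis_id == id & props$property == p]
      if (length(v)) v[[1L]] else ""
    }, character(1))
    paste(vals, collapse = "\r")
  }
  groups <- vapply(ids, identity_of, character(1))
  ts <- an$timestamp[match(ids, an$analysis_id)]
  keep <- logical(length(ids))
  for (g in unique(groups)) {
    in_g <- which(groups == g)
    best <- in_g[order(ts[in_g], ids[in_g], decreasing = TRUE)][1L]
    keep[best] <- TRUE
  }
  sort(ids[keep])
}

#' Latest analysis ids for an identity
#'
#' With a filter that fully specifies one analysis identity (run, lane, pair,
#' barcode, sample name), returns only the most recently inserted matching
#' analysis; ties on timestamp are broken by the higher id. With a partial
#' filter, returns the latest representative of every matching identity.
#'
#' @param store an open \code{qc_store}.
#' @param f a [property_filter()].
#' @return Integer vector of analysis ids (possibly empty).
#' @export
latest_analysis_ids <- function(store, f = property_filter()) {
  active_ids(store, f)
}
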