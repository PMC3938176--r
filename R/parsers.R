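# Parser side: the metadata-table reader, the parser registry, and the FastQC
# report parser. Parsers never touch the store; the loader owns the
# connection and forwards finished analyses to insert_analysis().

.parser_registry <- new.env(parent = emptyenv())

#' Register a specific parser
#'
#' A specific parser is any function with signature
#' \code{function(path, analysis)} that reads a QC tool's report at
#' \code{path}, populates the supplied [new_analysis()] object and returns it.
#' Registration is by case-insensitive name; \code{"fastqc"} is always
#' registered. Parsers have no store access: the loader owns the connection.
#'
#' @param name parser name as used in the metadata table's ANALYSIS_TYPE
#'   column and the CLI \code{-p} flag.
#' @param fun the parser function.
#' @export
register_parser <- function(name, fun) {
  stopifnot(is.character(name), length(name) == 1L, is.function(fun))
  assign(tolower(name), fun, envir = .parser_registry)
  invisible(name)
}

#' @rdname register_parser
#' @return \code{list_parsers()} returns the registered names, sorted.
#' @export
list_parsers <- function() sort(ls(.parser_registry))

#' @rdname register_parser
#' @export
get_parser <- function(name) {
  key <- tolower(name)
  if (!exists(key, envir = .parser_registry, inherits = FALSE)) {
    stop(sprintf("no parser registered for analysis type '%s' (registered: %s)",
                 name, paste(list_parsers(), collapse = ", ")), call. = FALSE)
  }
  get(key, envir = .parser_registry, inherits = FALSE)
}

#' Read an analysis-metadata table
#'
#' The metadata table is a tab-delimited flat file supplying one analysis per
#' line: a header line of column names (matched case-insensitively, stored
#' upper-case) followed by data rows. \code{#} comment lines and blank lines
#' are ignored. The canonical columns are TYPE_OF_EXPERIMENT,
#' PATH_TO_ANALYSIS, ANALYSIS_TYPE, INSTRUMENT, CHEMISTRY_VERSION,
#' SOFTWARE_ON_INSTRUMENT_VERSION, CASAVA_VERSION, RUN_FOLDER, SAMPLE_NAME,
#' LANE, BARCODE, PAIR and RUN; extra columns are carried through verbatim.
#' PATH_TO_ANALYSIS must be present.
#'
#' @param path path to the table.
#' @return A list of \code{run_table_entry} objects (named character vectors).
#' @export
parse_run_table <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("metadata table not found: %s", path), call. = FALSE)
  }
  raw <- readLines(path, warn = FALSE)
  raw <- sub("\r$", "", raw)
  keep <- which(nzchar(trimws(raw)) & !startsWith(trimws(raw), "#"))
  if (!length(keep)) stop("metadata table has no header line", call. = FALSE)
  header_line <- keep[1L]
  header <- toupper(strsplit(raw[header_line], "\t", fixed = TRUE)[[1L]])
  if (!("PATH_TO_ANALYSIS" %in% header)) {
    stop(sprintf("metadata table %s: missing required column PATH_TO_ANALYSIS",
                 path), call. = FALSE)
  }
  entries <- list()
  for (ln in keep[-1L]) {
    cells <- strsplit(raw[ln], "\t", fixed = TRUE)[[1L]]
    # trailing empty cells are dropped by strsplit; pad them back
    if (length(cells) < length(header) &&
        grepl("\t$", raw[ln])) {
      cells <- c(cells, rep("", length(header) - length(cells)))
    }
    if (length(cells) != length(header)) {
      stop(sprintf(
        "metadata table %s, line %d: %d field(s) but header has %d",
        path, ln, length(cells), length(header)), call. = FALSE)
    }
    e <- stats::setNames(cells, header)
    if (!nzchar(e[["PATH_TO_ANALYSIS"]])) {
      stop(sprintf("metadata table %s, line %d: empty PATH_TO_ANALYSIS",
                   path, ln), call. = FALSE)
    }
    class(e) <- "run_table_entry"
    entries[[length(entries) + 1L]] <- e
  }
  entries
}

# metadata column -> canonical analysis property
METADATA_PROPERTY_MAP <- c(
  TYPE_OF_EXPERIMENT             = "type",
  ANALYSIS_TYPE                  = "tool",
  INSTRUMENT                     = "instrument",
  CHEMISTRY_VERSION              = "chemistry",
  SOFTWARE_ON_INSTRUMENT_VERSION = "software",
  CASAVA_VERSION                 = "casava_version",
  RUN_FOLDER                     = "run_folder",
  SAMPLE_NAME                    = "sample_name",
  LANE                           = "lane",
  BARCODE                        = "barcode",
  PAIR                           = "pair",
  RUN                            = "run",
  PATH_TO_ANALYSIS               = "path_to_analysis"
)

#' Turn a metadata-table entry into a fresh analysis
#'
#' Maps every metadata column onto exactly one analysis property: the
#' canonical columns onto their controlled property names (ANALYSIS_TYPE
#' becomes \code{tool}, SOFTWARE_ON_INSTRUMENT_VERSION becomes
#' \code{software}, ...), any other column onto its lower-cased name.
#' PATH_TO_ANALYSIS is kept as the retrievable property
#' \code{path_to_analysis}. Empty cells set no property.
#'
#' @param e a \code{run_table_entry} from [parse_run_table()].
#' @return A new [new_analysis()] with the properties set.
#' @export
entry_to_analysis <- function(e) {
  stopifnot(inherits(e, "run_table_entry"))
  a <- new_analysis()
  for (col in names(e)) {
    if (!nzchar(e[[col]])) next
    prop <- METADATA_PROPERTY_MAP[col]
    if (is.na(prop)) prop <- tolower(col)
    add_property(a, prop, e[[col]])
  }
  a
}

# --- FastQC ------------------------------------------------------------------

# module name -> list(key = short key for the <key>_status general value,
#                     handler = function(rows, header_cols, extra, a))
fastqc_module_key <- function(name) {
  gsub("[^a-z0-9]+", "_", tolower(trimws(name)))
}

num_or_na <- function(x) suppressWarnings(as.numeric(x))

add_partition_rows <- function(a, rows, cols, metrics, module, warn_bad = TRUE) {
  # rows: list of character vectors; cols: named indices into each row
  for (r in rows) {
    rng <- parse_range(r[[1L]])
    for (m in names(metrics)) {
      v <- num_or_na(r[[metrics[[m]]]])
      if (is.na(v)) {
        if (warn_bad) {
          warning(sprintf("FastQC module '%s': skipping non-numeric cell for %s at base %s",
                          module, m, r[[1L]]), call. = FALSE)
        }
        next
      }
      add_partition_value(a, rng, m, v)
    }
  }
}

add_position_rows <- function(a, rows, key, module, index_transform = identity) {
  for (r in rows) {
    v <- num_or_na(r[[2L]])
    if (is.na(v)) {
      warning(sprintf("FastQC module '%s': skipping non-numeric count at '%s'",
                      module, r[[1L]]), call. = FALSE)
      next
    }
    pos <- index_transform(r[[1L]])
    if (is.na(pos)) {
      warning(sprintf("FastQC module '%s': skipping unparseable index '%s'",
                      module, r[[1L]]), call. = FALSE)
      next
    }
    add_position_value(a, pos, key, v)
  }
}

#' Parse a FastQC plain-text report into an analysis
#'
#' Reads the \code{fastqc_data.txt} dialect: a \code{##FastQC} version line,
#' then modules delimited by \code{>>Module Name<tab>status} ...
#' \code{>>END_MODULE}, each holding tab-separated rows. Module contents are
#' mapped onto the three scopes as follows:
#' \itemize{
#'   \item Basic Statistics: \code{Encoding} becomes the \code{encoding}
#'     property; totals, GC and sequence-length bounds become the global
#'     values \code{general_total_sequences}, \code{general_filtered_sequences},
#'     \code{general_gc_content}, \code{general_min_length},
#'     \code{general_max_length}.
#'   \item Per base sequence quality: six quantile metrics
#'     (\code{quality_mean}, \code{quality_median},
#'     \code{quality_lower_quartile}, \code{quality_upper_quartile},
#'     \code{quality_10th_percentile}, \code{quality_90th_percentile}) as
#'     base partitions; grouped base labels like \code{"10-14"} become one
#'     partition spanning the range.
#'   \item Per base sequence content / GC content / N content: base
#'     partitions \code{base_content_a/c/g/t}, \code{gc_content_percentage},
#'     \code{base_content_n}.
#'   \item Per sequence quality scores / GC content: cumulative counts
#'     \code{quality_score_count}, \code{gc_content_count}.
#'   \item Sequence Length Distribution: \code{length_count} on the bin's
#'     start position.
#'   \item Sequence Duplication Levels:
#'     \code{duplication_level_relative_count} plus the global
#'     \code{general_duplication_percentage}.
#'   \item Overrepresented sequences, Kmer Content: one global value per row,
#'     keyed by the sequence, valued by its count, with the possible source
#'     as description.
#' }
#' Every module's pass/warn/fail status is stored as the global value
#' \code{<module_key>_status}. Unknown modules are skipped with a warning so
#' reports from newer FastQC versions still load. Rows with empty or
#' \code{NaN} numeric cells are skipped with a warning, never stored as zero.
#'
#' @param path path to a \code{fastqc_data.txt}-style file.
#' @param a the [new_analysis()] to populate (e.g. from [entry_to_analysis()]).
#' @return The populated analysis, invisibly.
#' @export
parse_fastqc <- function(path, a = new_analysis()) {
  if (!file.exists(path)) {
    stop(sprintf("FastQC report not found: %s", path), call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- sub("\r$", "", lines)
  if (!length(lines) || !startsWith(lines[1L], "##FastQC")) {
    stop(sprintf("%s: not a FastQC report (missing ##FastQC header)", path),
         call. = FALSE)
  }
  add_property(a, "tool", a$properties[["tool"]] %||% "FastQC")

  i <- 2L
  n <- length(lines)
  while (i <= n) {
    ln <- lines[i]
    if (!startsWith(ln, ">>")) { i <- i + 1L; next }
    head_cells <- strsplit(sub("^>>", "", ln), "\t", fixed = TRUE)[[1L]]
    module <- head_cells[1L]
    status <- if (length(head_cells) > 1L) head_cells[2L] else ""
    body <- character(0)
    j <- i + 1L
    while (j <= n && !startsWith(lines[j], ">>END_MODULE")) {
      body <- c(body, lines[j])
      j <- j + 1L
    }
    if (j > n) {
      stop(sprintf("%s: module '%s' (line %d) not terminated by >>END_MODULE",
                   path, module, i), call. = FALSE)
    }
    handle_fastqc_module(a, module, status, body, path, i)
    i <- j + 1L
  }
  invisible(a)
}

handle_fastqc_module <- function(a, module, status, body, path, line) {
  key <- fastqc_module_key(module)
  known <- c(
    "basic_statistics", "per_base_sequence_quality",
    "per_sequence_quality_scores", "per_base_sequence_content",
    "per_base_gc_content", "per_base_n_content", "per_sequence_gc_content",
    "sequence_length_distribution", "sequence_duplication_levels",
    "overrepresented_sequences", "kmer_content", "per_tile_sequence_quality",
    "adapter_content"
  )
  if (!(key %in% known)) {
    warning(sprintf("%s: skipping unknown FastQC module '%s' (line %d)",
                    path, module, line), call. = FALSE)
    return(invisible(a))
  }

  extra <- body[startsWith(body, "#")]
  rows <- lapply(body[!startsWith(body, "#") & nzchar(body)],
                 function(x) strsplit(x, "\t", fixed = TRUE)[[1L]])

  if (nzchar(status)) {
    skey <- paste0(key, "_status")
    add_valid_type(a, skey, "analysis")
    add_general_value(a, skey, status)
  }

  need_num <- function(cell, what, rowlab) {
    v <- num_or_na(cell)
    if (is.na(v)) {
      stop(sprintf("%s: module '%s', row '%s': non-numeric %s '%s'",
                   path, module, rowlab, what, cell), call. = FALSE)
    }
    v
  }

  switch(key,
    basic_statistics = {
      for (r in rows) {
        if (length(r) < 2L) next
        measure <- r[[1L]]; value <- r[[2L]]
        if (measure == "Encoding") {
          add_property(a, "encoding", value)
        } else if (measure == "Filename") {
          add_property(a, "filename", value)
        } else if (measure == "File type") {
          add_property(a, "file_type", value)
        } else if (measure == "Total Sequences") {
          add_valid_type(a, "general_total_sequences", "analysis")
          add_general_value(a, "general_total_sequences",
                            need_num(value, "value", measure))
        } else if (measure == "Filtered Sequences") {
          add_valid_type(a, "general_filtered_sequences", "analysis")
          add_general_value(a, "general_filtered_sequences",
                            need_num(value, "value", measure))
        } else if (measure == "Sequence length") {
          rng <- parse_range(value)
          add_valid_type(a, "general_min_length", "analysis")
          add_valid_type(a, "general_max_length", "analysis")
          add_general_value(a, "general_min_length", rng$start)
          add_general_value(a, "general_max_length", rng$end)
        } else if (measure == "%GC") {
          add_valid_type(a, "general_gc_content", "analysis")
          add_general_value(a, "general_gc_content",
                            need_num(value, "value", measure))
        }
      }
    },
    per_base_sequence_quality = {
      metrics <- c(quality_mean = 2L, quality_median = 3L,
                   quality_lower_quartile = 4L, quality_upper_quartile = 5L,
                   quality_10th_percentile = 6L, quality_90th_percentile = 7L)
      for (m in names(metrics)) add_valid_type(a, m, "base_partition")
      add_partition_rows(a, rows, NULL, as.list(metrics), module)
    },
    per_sequence_quality_scores = {
      add_valid_type(a, "quality_score_count", "sequence_cumulative")
      add_position_rows(a, rows, "quality_score_count", module,
                        function(x) as.integer(num_or_na(x)))
    },
    per_base_sequence_content = {
      metrics <- list(base_content_g = 2L, base_content_a = 3L,
                      base_content_t = 4L, base_content_c = 5L)
      for (m in names(metrics)) add_valid_type(a, m, "base_partition")
      add_partition_rows(a, rows, NULL, metrics, module)
    },
    per_base_gc_content = {
      add_valid_type(a, "gc_content_percentage", "base_partition")
      add_partition_rows(a, rows, NULL, list(gc_content_percentage = 2L), module)
    },
    per_base_n_content = {
      add_valid_type(a, "base_content_n", "base_partition")
      add_partition_rows(a, rows, NULL, list(base_content_n = 2L), module)
    },
    per_sequence_gc_content = {
      add_valid_type(a, "gc_content_count", "sequence_cumulative")
      add_position_rows(a, rows, "gc_content_count", module,
                        function(x) as.integer(num_or_na(x)))
    },
    sequence_length_distribution = {
      add_valid_type(a, "length_count", "sequence_cumulative")
      add_position_rows(a, rows, "length_count", module,
                        function(x) parse_range(x)$start)
    },
    sequence_duplication_levels = {
      dup_line <- extra[startsWith(extra, "#Total Duplicate Percentage")]
      if (length(dup_line)) {
        v <- num_or_na(strsplit(dup_line[1L], "\t", fixed = TRUE)[[1L]][2L])
        if (!is.na(v)) {
          add_valid_type(a, "general_duplication_percentage", "analysis")
          add_general_value(a, "general_duplication_percentage", v)
        }
      }
      add_valid_type(a, "duplication_level_relative_count",
                     "sequence_cumulative")
      add_position_rows(a, rows, "duplication_level_relative_count", module,
                        function(x) as.integer(num_or_na(sub("\\+.*$", "", x))))
    },
    overrepresented_sequences = {
      for (r in rows) {
        if (length(r) < 2L) next
        cnt <- num_or_na(r[[2L]])
        if (is.na(cnt)) {
          warning(sprintf("%s: module '%s': skipping non-numeric count for %s",
                          path, module, r[[1L]]), call. = FALSE)
          next
        }
        add_valid_type(a, r[[1L]], "analysis")
        src <- if (length(r) >= 4L && nzchar(r[[4L]])) r[[4L]] else NULL
        add_general_value(a, r[[1L]], cnt, src)
      }
    },
    kmer_content = {
      for (r in rows) {
        if (length(r) < 2L) next
        cnt <- num_or_na(r[[2L]])
        if (is.na(cnt)) next
        add_valid_type(a, r[[1L]], "analysis")
        add_general_value(a, r[[1L]], cnt)
      }
    },
    per_tile_sequence_quality = {
      # status only; the per-tile matrix has no scope in this store
    },
    adapter_content = {
      # status only
    }
  )
  invisible(a)
}

#' Load analyses described by a metadata table
#'
#' The loader pipeline: read the metadata table, and for each entry build an
#' analysis carrying the entry's properties, dispatch to the parser named by
#' its ANALYSIS_TYPE, and insert the result. A failing entry is reported and
#' skipped; the remaining entries still load. In test mode everything is
#' parsed and validated but nothing is written (no store connection is even
#' opened).
#'
#' @param config store configuration (see [connect_store()]); ignored in test
#'   mode.
#' @param metadata_path path to the analysis-metadata table.
#' @param test_mode logical; parse/validate only.
#' @param verbose logical; per-entry progress on stderr.
#' @return A list with counts \code{parsed}, \code{inserted}, \code{failed}
#'   and a character vector \code{errors} (one message per failed entry).
#' @export
load_analyses <- function(config, metadata_path, test_mode = FALSE,
                          verbose = FALSE) {
  entries <- parse_run_table(metadata_path)
  store <- NULL
  if (!test_mode) {
    store <- connect_store(config)
    on.exit(disconnect_store(store))
  }
  parsed <- 0L; inserted <- 0L; failed <- 0L; errors <- character(0)
  for (k in seq_along(entries)) {
    e <- entries[[k]]
    res <- tryCatch({
      a <- entry_to_analysis(e)
      type <- e[["ANALYSIS_TYPE"]]
      if (is.null(type) || is.na(type) || !nzchar(type)) {
        stop("entry has no ANALYSIS_TYPE", call. = FALSE)
      }
      parser <- get_parser(type)
      parser(e[["PATH_TO_ANALYSIS"]], a)
      parsed <- parsed + 1L
      if (!test_mode) {
        insert_analysis(store, a)
        inserted <- inserted + 1L
      }
      if (verbose) {
        message(sprintf("entry %d: %s %s", k, type, e[["PATH_TO_ANALYSIS"]]))
      }
      TRUE
    }, error = function(err) {
      failed <<- failed + 1L
      errors <<- c(errors, sprintf("entry %d: %s", k, conditionMessage(err)))
      message(sprintf("ERROR loading entry %d: %s", k, conditionMessage(err)))
      FALSE
    })
  }
  list(parsed = parsed, inserted = inserted, failed = failed, errors = errors)
}

.onLoad <- function(libname, pkgname) {
  register_parser("fastqc", parse_fastqc)
}
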