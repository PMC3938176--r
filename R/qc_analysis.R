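#' @importFrom R6 R6Class
NULL

#' Metric scopes
#'
#' Every metric key stored by seqqcstore is registered under exactly one of
#' three scopes:
#' \describe{
#'   \item{analysis}{a single value describing the whole analysis, e.g. total
#'     GC content or the count of an overrepresented sequence;}
#'   \item{base_partition}{a value attached to a base position or an inclusive
#'     range of positions, e.g. mean quality over positions 10--14;}
#'   \item{sequence_cumulative}{a count indexed by a score or bin across all
#'     reads, e.g. the number of reads whose mean quality is 30.}
#' }
#' No other scope labels are accepted anywhere in the API.
#'
#' @format A character vector of the three scope labels.
#' @export
TYPE_SCOPES <- c("analysis", "base_partition", "sequence_cumulative")

assert_scope <- function(scope) {
  if (!(is.character(scope) && length(scope) == 1L && scope %in% TYPE_SCOPES)) {
    stop(sprintf(
      "unknown scope label '%s'; must be one of: %s",
      paste(scope, collapse = ","), paste(TYPE_SCOPES, collapse = ", ")
    ), call. = FALSE)
  }
  invisible(scope)
}

#' Inclusive base-position range
#'
#' A partition of the read covering positions \code{start} to \code{end}
#' inclusive, so its width is \code{end - start + 1}. Positions are 1-based
#' (the FastQC convention).
#'
#' @param start,end 1-based integer positions, \code{1 <= start <= end}.
#' @return An object of class \code{qc_range} with fields \code{start},
#'   \code{end} and \code{width}.
#' @seealso [parse_range()]
#' @export
qc_range <- function(start, end = start) {
  if (length(start) != 1L || length(end) != 1L ||
      is.na(suppressWarnings(as.numeric(start))) ||
      is.na(suppressWarnings(as.numeric(end)))) {
    stop("range start and end must be single numbers", call. = FALSE)
  }
  start <- as.numeric(start); end <- as.numeric(end)
  if (start != floor(start) || end != floor(end)) {
    stop("range positions must be integers", call. = FALSE)
  }
  if (start < 1) stop("range start must be >= 1", call. = FALSE)
  if (end < start) {
    stop(sprintf("reversed range: end (%d) < start (%d)", end, start),
         call. = FALSE)
  }
  structure(
    list(start = as.integer(start), end = as.integer(end),
         width = as.integer(end - start + 1L)),
    class = "qc_range"
  )
}

#' @export
format.qc_range <- function(x, ...) {
  if (x$start == x$end) as.character(x$start) else paste0(x$start, "-", x$end)
}

#' @export
print.qc_range <- function(x, ...) {
  cat(sprintf("<qc_range %s (width %d)>\n", format(x), x$width))
  invisible(x)
}

#' Parse a base-range string
#'
#' Converts the string form used by FastQC base labels ("10" or "10-14") into
#' a [qc_range()]. A bare integer denotes a partition of size 1; "A-B" denotes
#' the inclusive range from A to B. Surrounding whitespace is trimmed; no
#' other dialects (e.g. "10..14") are accepted.
#'
#' @param text a single range string.
#' @return A \code{qc_range}.
#' @examples
#' parse_range("10")     # width 1
#' parse_range("10-14")  # width 5
#' @export
parse_range <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text)) {
    stop("parse_range expects a single string", call. = FALSE)
  }
  s <- trimws(text)
  if (grepl("^[0-9]+$", s)) {
    n <- as.integer(s)
    return(qc_range(n, n))
  }
  if (grepl("^[0-9]+-[0-9]+$", s)) {
    parts <- as.integer(strsplit(s, "-", fixed = TRUE)[[1L]])
    if (parts[2L] < parts[1L]) {
      stop(sprintf("reversed range in '%s'", text), call. = FALSE)
    }
    return(qc_range(parts[1L], parts[2L]))
  }
  stop(sprintf("cannot parse range from '%s'", text), call. = FALSE)
}

as_qc_range <- function(r) {
  if (inherits(r, "qc_range")) return(r)
  if (is.character(r) && length(r) == 1L) return(parse_range(r))
  if (is.numeric(r) && length(r) == 2L) return(qc_range(r[1L], r[2L]))
  if (is.numeric(r) && length(r) == 1L) return(qc_range(r, r))
  stop("not a range: supply a qc_range, a string, or a numeric pair",
       call. = FALSE)
}

as_numeric_value <- function(value) {
  # numeric-looking text is promoted to double; everything else stays text
  if (is.numeric(value) && length(value) == 1L && !is.na(value)) {
    return(as.numeric(value))
  }
  if (is.character(value) && length(value) == 1L) {
    v <- suppressWarnings(as.numeric(value))
    if (!is.na(v)) return(v)
  }
  NULL
}

QCAnalysisR6 <- R6::R6Class("QCAnalysisR6",
  public = list(
    properties = NULL,        # named list key -> character value
    valid_types = NULL,       # named character key -> scope
    general_values = NULL,    # list of list(key, value, text_value, description)
    position_values = NULL,   # list of list(position, key, value)
    partition_values = NULL,  # list of list(range, key, value)

    initialize = function() {
      self$properties <- list()
      self$valid_types <- character(0)
      self$general_values <- list()
      self$position_values <- list()
      self$partition_values <- list()
    },

    add_valid_type = function(key, scope) {
      stopifnot(is.character(key), length(key) == 1L, nzchar(key))
      assert_scope(scope)
      existing <- self$valid_types[key]
      if (!is.na(existing) && existing != scope) {
        stop(sprintf(
          "value type '%s' already registered with scope '%s'; cannot re-register as '%s'",
          key, existing, scope
        ), call. = FALSE)
      }
      self$valid_types[key] <- scope
      invisible(self)
    },

    scope_of = function(key) {
      s <- self$valid_types[key]
      if (is.na(s)) {
        stop(sprintf("value type '%s' has not been registered with add_valid_type", key),
             call. = FALSE)
      }
      unname(s)
    },

    check_scope = function(key, expected) {
      s <- self$scope_of(key)
      if (s != expected) {
        stop(sprintf(
          "value type '%s' has scope '%s', but this call requires scope '%s'",
          key, s, expected
        ), call. = FALSE)
      }
      invisible(s)
    },

    add_property = function(key, value) {
      if (!is.character(key) || length(key) != 1L || !nzchar(key)) {
        stop("property key must be a non-empty string", call. = FALSE)
      }
      self$properties[[key]] <- as.character(value)  # last write wins
      invisible(self)
    },

    add_general_value = function(key, value, description = NULL) {
      self$check_scope(key, "analysis")
      num <- as_numeric_value(value)
      self$general_values[[length(self$general_values) + 1L]] <- list(
        key = key,
        value = num,
        text_value = if (is.null(num)) as.character(value) else NULL,
        description = description
      )
      invisible(self)
    },

    add_position_value = function(position, key, value) {
      self$check_scope(key, "sequence_cumulative")
      if (length(position) != 1L || is.na(suppressWarnings(as.numeric(position))) ||
          as.numeric(position) < 0 ||
          as.numeric(position) != floor(as.numeric(position))) {
        stop("position must be a single non-negative integer", call. = FALSE)
      }
      num <- as_numeric_value(value)
      if (is.null(num)) {
        stop(sprintf("non-numeric value for sequence_cumulative type '%s'", key),
             call. = FALSE)
      }
      self$position_values[[length(self$position_values) + 1L]] <- list(
        position = as.integer(position), key = key, value = num
      )
      invisible(self)
    },

    add_partition_value = function(r, key, value) {
      self$check_scope(key, "base_partition")
      r <- as_qc_range(r)
      num <- as_numeric_value(value)
      if (is.null(num)) {
        stop(sprintf("non-numeric value for base_partition type '%s'", key),
             call. = FALSE)
      }
      self$partition_values[[length(self$partition_values) + 1L]] <- list(
        range = r, key = key, value = num
      )
      invisible(self)
    }
  )
)

#' Create an empty QC analysis
#'
#' A \code{qc_analysis} is the in-memory aggregate of one QC analysis: its
#' properties (run, lane, barcode, tool, ...), the registered value types with
#' their scopes, and the global, per-position and per-partition values. It is
#' built up with [add_valid_type()], [add_property()], [add_general_value()],
#' [add_position_value()] and [add_partition_value()], then persisted with
#' [insert_analysis()]. The object has reference semantics: the \code{add_*}
#' functions mutate it in place.
#'
#' @return A new, empty \code{qc_analysis} object.
#' @examples
#' a <- new_analysis()
#' add_property(a, "tool", "FastQC")
#' add_valid_type(a, "quality_mean", "base_partition")
#' add_partition_value(a, parse_range("10-14"), "quality_mean", 38.7)
#' @export
new_analysis <- function() {
  a <- QCAnalysisR6$new()
  class(a) <- c("qc_analysis", class(a))
  a
}

assert_analysis <- function(a) {
  if (!inherits(a, "qc_analysis")) stop("not a qc_analysis object", call. = FALSE)
  invisible(a)
}

#' Register a metric key with its scope
#'
#' Every metric key must be registered before values for it may be added, and
#' a key maps to exactly one scope for the lifetime of the store.
#' Re-registering a key with the same scope is a no-op; with a different scope
#' it is an error.
#'
#' @param a a [new_analysis()] object.
#' @param key metric name, e.g. \code{"quality_mean"}.
#' @param scope one of [TYPE_SCOPES].
#' @export
add_valid_type <- function(a, key, scope) {
  assert_analysis(a)
  a$add_valid_type(key, scope)
  invisible(a)
}

#' Set a property of an analysis
#'
#' Properties carry run metadata: \code{tool}, \code{encoding},
#' \code{chemistry}, \code{instrument}, \code{software}, \code{type},
#' \code{pair}, \code{sample_name}, \code{lane}, \code{run}, \code{barcode},
#' plus any extra keys a parser wants to keep. Repeating a key overwrites the
#' prior value (last write wins), so parsers may refine defaults.
#'
#' @param a a [new_analysis()] object.
#' @param key property name (non-empty string).
#' @param value property value, stored as text.
#' @export
add_property <- function(a, key, value) {
  assert_analysis(a)
  a$add_property(key, value)
  invisible(a)
}

#' Add a global (analysis-scope) value
#'
#' Global values describe the whole analysis: a total sequence count, overall
#' GC percentage, or an overrepresented sequence keyed by the sequence itself
#' with its count as the value and its likely source as the description.
#' Numeric-looking values are stored as doubles; other text is stored verbatim.
#'
#' @param a a [new_analysis()] object.
#' @param key metric name, registered with scope \code{"analysis"}.
#' @param value numeric or text value.
#' @param description optional free text stored with the value type the first
#'   time it is seen; later descriptions for the same key are ignored.
#' @export
add_general_value <- function(a, key, value, description = NULL) {
  assert_analysis(a)
  a$add_general_value(key, value, description)
  invisible(a)
}

#' Add a per-position (sequence-cumulative) count
#'
#' Sequence-cumulative values are counts indexed by a score or bin, e.g.
#' "15000 reads had mean quality 30" is stored as position 30, key
#' \code{quality_score_count}, value 15000. Positions are non-negative
#' integers interpreted as the x-axis index.
#'
#' @param a a [new_analysis()] object.
#' @param position non-negative integer index.
#' @param key metric name, registered with scope \code{"sequence_cumulative"}.
#' @param value numeric value.
#' @export
add_position_value <- function(a, position, key, value) {
  assert_analysis(a)
  a$add_position_value(position, key, value)
  invisible(a)
}

#' Add a per-partition (base-range) value
#'
#' Base-partition values attach to an inclusive range of base positions, e.g.
#' a quality mean over positions 10--14. A width-1 partition is legal and is
#' how ungrouped per-base metrics are stored.
#'
#' @param a a [new_analysis()] object.
#' @param r a [qc_range()], a range string ("10" or "10-14"), or a numeric pair.
#' @param key metric name, registered with scope \code{"base_partition"}.
#' @param value numeric value.
#' @export
add_partition_value <- function(a, r, key, value) {
  assert_analysis(a)
  a$add_partition_value(r, key, value)
  invisible(a)
}

#' @export
print.qc_analysis <- function(x, ...) {
  cat(sprintf(
    "<qc_analysis: %d properties, %d types, %d general, %d position, %d partition values>\n",
    length(x$properties), length(x$valid_types), length(x$general_values),
    length(x$position_values), length(x$partition_values)
  ))
  invisible(x)
}
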