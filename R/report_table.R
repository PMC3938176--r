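#' Report tables
#'
#' Every query returns a \code{report_table}: an ordered set of named columns,
#' rows of numeric or text cells, and a provenance note giving the number of
#' analyses that were aggregated. The table serialises losslessly to JSON
#' (shape \code{{"columns": [...], "rows": [[...], ...], "n_analyses": n}},
#' ready for browser plotting) and to RFC-4180 CSV.
#'
#' @param data a data.frame holding the rows (may have zero rows).
#' @param n_analyses number of analyses that contributed to the table.
#' @return A \code{report_table}.
#' @export
report_table <- function(data, n_analyses = 0L) {
  stopifnot(is.data.frame(data))
  rownames(data) <- NULL
  structure(list(columns = names(data), data = data,
                 n_analyses = as.integer(n_analyses)),
            class = "report_table")
}

#' @export
print.report_table <- function(x, ...) {
  cat(sprintf("<report_table: %d row(s) x %d column(s), %d analyses>\n",
              nrow(x$data), length(x$columns), x$n_analyses))
  if (nrow(x$data)) print(utils::head(x$data, 10L))
  invisible(x)
}

#' @export
dim.report_table <- function(x) dim(x$data)

#' @rdname report_table
#' @param t a \code{report_table}.
#' @export
as.data.frame.report_table <- function(x, ...) x$data

csv_cell <- function(x) {
  if (is.na(x)) return("")
  s <- if (is.numeric(x)) {
    # up to 10 significant digits, no padding
    format(x, digits = 10, trim = TRUE, scientific = FALSE)
  } else {
    as.character(x)
  }
  if (grepl('[",\n\r]', s)) s <- paste0('"', gsub('"', '""', s), '"')
  s
}

#' Serialise a report table to CSV
#'
#' Header line plus one comma-separated line per row; cells containing commas,
#' quotes or newlines are quoted per RFC 4180; missing cells are empty.
#' Numbers are printed with up to 10 significant digits.
#'
#' @param t a [report_table()].
#' @return A single string (lines separated by \code{"\n"}).
#' @export
to_csv <- function(t) {
  stopifnot(inherits(t, "report_table"))
  header <- paste(vapply(t$columns, csv_cell, character(1)), collapse = ",")
  if (!nrow(t$data)) return(paste0(header, "\n"))
  rows <- vapply(seq_len(nrow(t$data)), function(i) {
    paste(vapply(seq_along(t$columns), function(j) {
      csv_cell(t$data[i, j][[1L]])
    }, character(1)), collapse = ",")
  }, character(1))
  paste0(paste(c(header, rows), collapse = "\n"), "\n")
}

#' Serialise a report table to JSON
#'
#' Shape: \code{{"columns": [...], "rows": [[...], ...], "n_analyses": n}}.
#' Full double precision; missing cells are \code{null}.
#'
#' @param t a [report_table()].
#' @return A single JSON string.
#' @export
to_json <- function(t) {
  stopifnot(inherits(t, "report_table"))
  rows <- lapply(seq_len(nrow(t$data)), function(i) {
    lapply(seq_along(t$columns), function(j) {
      v <- t$data[i, j][[1L]]
      if (is.na(v)) NULL else v
    })
  })
  as.character(jsonlite::toJSON(
    list(columns = as.list(t$columns), rows = rows,
         n_analyses = t$n_analyses),
    auto_unbox = TRUE, digits = NA, null = "null"
  ))
}

#' Parse a report table back from CSV / JSON
#'
#' Inverses of [to_csv()] and [to_json()], used to verify that serialisation
#' is lossless. CSV is typeless, so columns whose surviving cells all look
#' numeric come back numeric; [report_tables_equal()] compares accordingly.
#'
#' @param text serialised table text.
#' @return A [report_table()] (CSV tables come back with \code{n_analyses = 0},
#'   since CSV carries data only).
#' @export
from_csv <- function(text) {
  df <- utils::read.csv(text = text, check.names = FALSE,
                        stringsAsFactors = FALSE, colClasses = NA)
  report_table(df, 0L)
}

#' @rdname from_csv
#' @export
from_json <- function(text) {
  obj <- jsonlite::fromJSON(text, simplifyVector = FALSE)
  cols <- unlist(obj$columns)
  if (is.null(cols)) cols <- character(0)
  n <- length(obj$rows)
  df <- as.data.frame(setNames(rep(list(rep(NA, n)), length(cols)), cols),
                      check.names = FALSE, stringsAsFactors = FALSE)
  for (j in seq_along(cols)) {
    cells <- lapply(obj$rows, function(r) r[[j]])
    is_null <- vapply(cells, is.null, logical(1))
    non_null <- cells[!is_null]
    col <- if (length(non_null) && all(vapply(non_null, is.numeric, logical(1)))) {
      vapply(cells, function(v) if (is.null(v)) NA_real_ else as.numeric(v),
             numeric(1))
    } else if (length(non_null)) {
      vapply(cells, function(v) if (is.null(v)) NA_character_ else as.character(v),
             character(1))
    } else {
      rep(NA, n)
    }
    df[[cols[j]]] <- col
  }
  report_table(df, as.integer(obj$n_analyses %||% 0L))
}

#' Compare two report tables cell-wise
#'
#' Tables are equal when columns match and every cell pair is either both
#' missing, numerically equal within \code{tol}, or equal as strings. Used by
#' the serialisation round-trip checks (CSV does not preserve cell types, so
#' comparison coerces).
#'
#' @param a,b report tables.
#' @param tol numeric tolerance.
#' @return TRUE or FALSE.
#' @export
report_tables_equal <- function(a, b, tol = 1e-9) {
  if (!identical(a$columns, b$columns)) return(FALSE)
  if (nrow(a$data) != nrow(b$data)) return(FALSE)
  for (j in seq_along(a$columns)) {
    for (i in seq_len(nrow(a$data))) {
      x <- a$data[i, j][[1L]]; y <- b$data[i, j][[1L]]
      if (is.na(x) && is.na(y)) next
      if (is.na(x) || is.na(y)) {
        # an empty string CSV cell reads back as NA
        if ((is.na(x) && identical(as.character(y), "")) ||
            (is.na(y) && identical(as.character(x), ""))) next
        return(FALSE)
      }
      xn <- suppressWarnings(as.numeric(x))
      yn <- suppressWarnings(as.numeric(y))
      if (!is.na(xn) && !is.na(yn)) {
        if (abs(xn - yn) > tol * max(1, abs(xn), abs(yn))) return(FALSE)
      } else if (as.character(x) != as.character(y)) {
        return(FALSE)
      }
    }
  }
  TRUE
}

setNames <- stats::setNames
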