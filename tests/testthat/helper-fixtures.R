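# Shared test helpers: tiny builders, brute-force oracles, and randomized
# analysis generators. All fixtures are built in code at test time.

mem_store <- function() connect_store(memory_config())

full_filter <- function(run = "RUN-1", lane = "1", pair = "1",
                        barcode = "ACCGTT", sampleName = "S1") {
  property_filter(run = run, lane = lane, pair = pair, barcode = barcode,
                  sampleName = sampleName)
}

# the worked builder example: one property set, one value of each scope
worked_analysis <- function(run = "RUN-1", lane = "1", pair = "1",
                            barcode = "ACCGTT", sample_name = "S1") {
  a <- new_analysis()
  add_property(a, "tool", "FastQC")
  add_property(a, "run", run)
  add_property(a, "lane", lane)
  add_property(a, "pair", pair)
  add_property(a, "barcode", barcode)
  add_property(a, "sample_name", sample_name)
  add_valid_type(a, "quality_score_count", "sequence_cumulative")
  add_valid_type(a, "quality_mean", "base_partition")
  add_valid_type(a, "average_length", "analysis")
  add_valid_type(a, "ACCTGATAT", "analysis")
  add_position_value(a, 30, "quality_score_count", 15000)
  add_partition_value(a, parse_range("10-14"), "quality_mean", 38.7)
  add_general_value(a, "average_length", 100)
  add_general_value(a, "ACCTGATAT", 10,
                    "over-represented common primer in library A")
  a
}

# random analysis over a small universe of metric keys and properties;
# returns the analysis plus a plain-list mirror for brute-force oracles
random_analysis <- function(max_positions = 100L) {
  props <- list(
    tool = "FastQC",
    run = sample(c("R1", "R2", "R3"), 1L),
    lane = as.character(sample(1:2, 1L)),
    pair = as.character(sample(1:2, 1L)),
    barcode = sample(c("AAA", "CCC", "GGG"), 1L),
    sample_name = sample(c("S1", "S2"), 1L),
    instrument = sample(c("MISEQ-1", "HISEQ-1"), 1L)
  )
  a <- new_analysis()
  for (k in names(props)) add_property(a, k, props[[k]])

  gen_keys <- c("general_gc_content", "general_total_sequences")
  pos_keys <- c("quality_score_count", "gc_content_count")
  part_keys <- c("quality_mean", "base_content_c")
  for (k in gen_keys) add_valid_type(a, k, "analysis")
  for (k in pos_keys) add_valid_type(a, k, "sequence_cumulative")
  for (k in part_keys) add_valid_type(a, k, "base_partition")

  mirror <- list(props = props, general = list(), position = list(),
                 partition = list())
  for (k in gen_keys) {
    if (stats::runif(1) < 0.8) {
      v <- round(stats::runif(1, 0, 100), 3)
      add_general_value(a, k, v)
      mirror$general[[length(mirror$general) + 1L]] <- list(key = k, value = v)
    }
  }
  n_pos <- sample.int(max_positions, 1L)
  for (k in pos_keys) {
    positions <- sort(sample.int(max_positions, n_pos))
    for (p in positions) {
      v <- stats::rpois(1, 50)
      add_position_value(a, p, k, v)
      mirror$position[[length(mirror$position) + 1L]] <-
        list(key = k, position = p, value = v)
    }
  }
  widths <- sample(c(1L, 5L), 1L)
  starts <- seq(1L, by = widths, length.out = sample.int(10L, 1L))
  for (k in part_keys) {
    for (s in starts) {
      v <- round(stats::runif(1, 2, 40), 3)
      add_partition_value(a, qc_range(s, s + widths - 1L), k, v)
      mirror$partition[[length(mirror$partition) + 1L]] <-
        list(key = k, start = s, end = s + widths - 1L, value = v)
    }
  }
  list(analysis = a, mirror = mirror)
}

# brute-force oracle over the mirrors: which analyses match the filter,
# excluding superseded identities (latest insertion index wins)
oracle_matching <- function(mirrors, filter) {
  key_map <- c(encoding = "encoding", chemistry = "chemistry",
               instrument = "instrument", softwareOnInstrument = "software",
               typeOfExperiment = "type", pair = "pair",
               sampleName = "sample_name", lane = "lane",
               barcode = "barcode", run = "run")
  idx <- seq_along(mirrors)
  for (ck in names(filter)) {
    prop <- key_map[[ck]]
    idx <- idx[vapply(idx, function(i) {
      identical(mirrors[[i]]$mirror$props[[prop]], filter[[ck]])
    }, logical(1))]
  }
  if (!length(idx)) return(integer(0))
  id_props <- c("run", "lane", "pair", "barcode", "sample_name", "tool")
  identity <- vapply(idx, function(i) {
    paste(vapply(id_props, function(p) mirrors[[i]]$mirror$props[[p]] %||% "",
                 character(1)), collapse = "\r")
  }, character(1))
  keep <- vapply(unique(identity), function(g) max(idx[identity == g]),
                 integer(1))
  sort(unname(keep))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

oracle_general_means <- function(mirrors, idx) {
  vals <- do.call(rbind, lapply(idx, function(i) {
    g <- mirrors[[i]]$mirror$general
    if (!length(g)) return(NULL)
    data.frame(i = i, key = vapply(g, `[[`, character(1), "key"),
               value = vapply(g, `[[`, numeric(1), "value"))
  }))
  if (is.null(vals)) {
    return(data.frame(key = character(0), mean = numeric(0), n = integer(0)))
  }
  keys <- sort(unique(vals$key))
  data.frame(
    key = keys,
    mean = vapply(keys, function(k) mean(vals$value[vals$key == k]), numeric(1)),
    n = vapply(keys, function(k) length(unique(vals$i[vals$key == k])),
               integer(1)),
    row.names = NULL
  )
}

oracle_position_means <- function(mirrors, idx, key) {
  vals <- do.call(rbind, lapply(idx, function(i) {
    p <- mirrors[[i]]$mirror$position
    p <- p[vapply(p, function(x) x$key == key, logical(1))]
    if (!length(p)) return(NULL)
    data.frame(i = i, position = vapply(p, `[[`, numeric(1), "position"),
               value = vapply(p, `[[`, numeric(1), "value"))
  }))
  if (is.null(vals)) {
    return(data.frame(position = integer(0), mean = numeric(0),
                      n = integer(0)))
  }
  pos <- sort(unique(vals$position))
  data.frame(
    position = pos,
    mean = vapply(pos, function(p) mean(vals$value[vals$position == p]),
                  numeric(1)),
    n = vapply(pos, function(p) length(unique(vals$i[vals$position == p])),
               integer(1)),
    row.names = NULL
  )
}

oracle_partition_means <- function(mirrors, idx, key) {
  vals <- do.call(rbind, lapply(idx, function(i) {
    p <- mirrors[[i]]$mirror$partition
    p <- p[vapply(p, function(x) x$key == key, logical(1))]
    if (!length(p)) return(NULL)
    data.frame(i = i, start = vapply(p, `[[`, integer(1), "start"),
               end = vapply(p, `[[`, integer(1), "end"),
               value = vapply(p, `[[`, numeric(1), "value"))
  }))
  if (is.null(vals)) {
    return(data.frame(start = integer(0), end = integer(0),
                      mean = numeric(0), n = integer(0)))
  }
  parts <- unique(vals[, c("start", "end")])
  parts <- parts[order(parts$start, parts$end), , drop = FALSE]
  data.frame(
    start = parts$start, end = parts$end,
    mean = vapply(seq_len(nrow(parts)), function(j) {
      mean(vals$value[vals$start == parts$start[j] & vals$end == parts$end[j]])
    }, numeric(1)),
    n = vapply(seq_len(nrow(parts)), function(j) {
      length(unique(vals$i[vals$start == parts$start[j] &
                           vals$end == parts$end[j]]))
    }, integer(1)),
    row.names = NULL
  )
}

# random report table for serialization round-trips
random_report_table <- function() {
  n <- sample(0:6, 1L)
  df <- data.frame(
    key = replicate(n, paste(sample(letters, 5L), collapse = "")),
    value = round(stats::runif(n, -1000, 1000), 6),
    note = replicate(n, paste(sample(c(letters, ",", '"', " "), 8L,
                                     replace = TRUE), collapse = "")),
    n = sample.int(10L, n, replace = TRUE),
    stringsAsFactors = FALSE
  )
  if (n > 0 && stats::runif(1) < 0.3) df$value[1L] <- NA_real_
  report_table(df, sample(0:5, 1L))
}

table1_entry <- function(path = "/path/to/fastqc_data.txt") {
  e <- c(
    TYPE_OF_EXPERIMENT = "NGS",
    PATH_TO_ANALYSIS = path,
    ANALYSIS_TYPE = "FastQC",
    INSTRUMENT = "MISEQ-1",
    CHEMISTRY_VERSION = "TRUSEQ_SBS_V3",
    SOFTWARE_ON_INSTRUMENT_VERSION = "MCS_2.2.0_RTA_1.17.28.0",
    CASAVA_VERSION = "1.8.2",
    RUN_FOLDER = "/path/to/run_folder",
    SAMPLE_NAME = "TEST_SAMPLE",
    LANE = "1",
    BARCODE = "AAACTGA",
    PAIR = "1",
    RUN = "RUN_NAME"
  )
  class(e) <- "run_table_entry"
  e
}
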