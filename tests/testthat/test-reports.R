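seeded_store <- function() {
  s <- mem_store()
  insert_analysis(s, worked_analysis(run = "R1", barcode = "AAA"))
  insert_analysis(s, worked_analysis(run = "R1", barcode = "CCC"))
  insert_analysis(s, worked_analysis(run = "R2", barcode = "AAA"))
  s
}

test_that("list_runs returns the distinct sorted run set", {
  s <- mem_store()
  expect_length(list_runs(s), 0)
  disconnect_store(s)

  s <- seeded_store()
  on.exit(disconnect_store(s))
  expect_equal(list_runs(s), c("R1", "R2"))
  # brute-force oracle over the property view
  pv <- property_view(s)
  expect_equal(list_runs(s), sort(unique(pv$run)))
})

test_that("list_selectable_properties restricts to the ten controlled keys", {
  s <- seeded_store()
  on.exit(disconnect_store(s))
  props <- list_selectable_properties(s)
  expect_true(all(c("lane", "run", "barcode", "sampleName") %in% props))
  expect_false("casava_version" %in% props)

  a <- new_analysis()
  add_property(a, "casava_version", "1.8.2")
  insert_analysis(s, a)
  expect_false("casava_version" %in% list_selectable_properties(s))
})

test_that("list_selectable_values_from_property lists distinct stored values", {
  s <- seeded_store()
  on.exit(disconnect_store(s))
  expect_equal(list_selectable_values_from_property(s, "barcode"),
               c("AAA", "CCC"))
  expect_equal(list_selectable_values_from_property(s, "lane"), "1")
  expect_error(list_selectable_values_from_property(s, "casava_version"),
               "not a controlled")
  # oracle scan
  pv <- property_view(s)
  expect_equal(list_selectable_values_from_property(s, "run"),
               sort(unique(pv$run[nzchar(pv$run)])))
})

test_that("list_summary_per_scope returns each type once with its description", {
  s <- mem_store()
  on.exit(disconnect_store(s))
  expect_equal(nrow(list_summary_per_scope(s, "base_partition")), 0)
  insert_analysis(s, worked_analysis())
  insert_analysis(s, worked_analysis())  # re-registration must not duplicate
  bp <- list_summary_per_scope(s, "base_partition")
  expect_equal(bp$value_type, "quality_mean")
  an <- list_summary_per_scope(s, "analysis")
  expect_equal(sum(an$value_type == "ACCTGATAT"), 1)
  expect_equal(an$description[an$value_type == "ACCTGATAT"],
               "over-represented common primer in library A")
  expect_error(list_summary_per_scope(s, "per_tile"), "unknown scope")
})

test_that("get_average_values means numeric globals and counts contributors", {
  s <- mem_store()
  on.exit(disconnect_store(s))
  a1 <- new_analysis()
  add_property(a1, "instrument", "MISEQ-1"); add_property(a1, "run", "R1")
  add_valid_type(a1, "general_gc_content", "analysis")
  add_general_value(a1, "general_gc_content", 40)
  insert_analysis(s, a1)
  a2 <- new_analysis()
  add_property(a2, "instrument", "MISEQ-1"); add_property(a2, "run", "R2")
  add_valid_type(a2, "general_gc_content", "analysis")
  add_valid_type(a2, "basic_statistics_status", "analysis")
  add_general_value(a2, "general_gc_content", 60)
  add_general_value(a2, "basic_statistics_status", "pass")
  insert_analysis(s, a2)

  tab <- as.data.frame(get_average_values(
    s, property_filter(instrument = "MISEQ-1")))
  gc <- tab[tab$key == "general_gc_content", ]
  expect_equal(gc$mean, 50)
  expect_equal(gc$n, 2L)
  # text values: counted, no mean
  st <- tab[tab$key == "basic_statistics_status", ]
  expect_true(is.na(st$mean))
  expect_equal(st$n, 1L)

  s_empty <- mem_store()
  expect_equal(nrow(as.data.frame(get_average_values(s_empty))), 0)
  disconnect_store(s_empty)
})

test_that("per-position and per-partition queries mean across analyses", {
  s <- mem_store()
  on.exit(disconnect_store(s))
  mk <- function(run, count, qmean) {
    a <- new_analysis()
    add_property(a, "run", run); add_property(a, "lane", "1")
    add_valid_type(a, "quality_score_count", "sequence_cumulative")
    add_valid_type(a, "quality_mean", "base_partition")
    add_position_value(a, 5, "quality_score_count", count)
    add_partition_value(a, qc_range(1, 1), "quality_mean", qmean)
    a
  }
  insert_analysis(s, mk("R1", 10, 30))
  insert_analysis(s, mk("R2", 20, 40))

  pos <- as.data.frame(get_per_position_values(
    s, "quality_score_count", property_filter(lane = "1")))
  expect_equal(pos, data.frame(position = 5L, mean = 15, n = 2L))

  part <- as.data.frame(get_per_partition_values(
    s, "quality_mean", property_filter(lane = "1")))
  expect_equal(part, data.frame(start = 1L, end = 1L, mean = 35, n = 2L))

  # scope guards point at the right query
  expect_error(get_per_position_values(s, "quality_mean"), "scope")
  expect_error(get_per_partition_values(s, "quality_score_count"), "scope")
})

test_that("differing partitionings yield separate rows, never blended", {
  s <- mem_store()
  on.exit(disconnect_store(s))
  a1 <- new_analysis()
  add_property(a1, "run", "R1")
  add_valid_type(a1, "quality_mean", "base_partition")
  add_partition_value(a1, qc_range(10, 14), "quality_mean", 38.7)
  insert_analysis(s, a1)
  a2 <- new_analysis()
  add_property(a2, "run", "R2")
  add_valid_type(a2, "quality_mean", "base_partition")
  add_partition_value(a2, qc_range(10, 10), "quality_mean", 20)
  insert_analysis(s, a2)

  part <- as.data.frame(get_per_partition_values(s, "quality_mean"))
  expect_equal(nrow(part), 2)
  expect_equal(part$end[part$start == 10 & part$n == 1], c(10L, 14L))
})

test_that("get_summary_values_with_comments carries descriptions", {
  s <- mem_store()
  on.exit(disconnect_store(s))
  insert_analysis(s, worked_analysis())
  tab <- as.data.frame(get_summary_values_with_comments(s, "analysis",
                                                        full_filter()))
  primer <- tab[tab$key == "ACCTGATAT", ]
  expect_equal(as.numeric(primer$value), 10)
  expect_equal(primer$description,
               "over-represented common primer in library A")
  expect_equal(primer$n, 1L)
  # value without a description: empty description cell
  len <- tab[tab$key == "average_length", ]
  expect_equal(len$description, "")
  expect_error(get_summary_values_with_comments(s, "bogus"), "unknown scope")
})

test_that("latest-wins: a fully-specified filter returns only the second insert", {
  s <- mem_store()
  on.exit(disconnect_store(s))
  a1 <- worked_analysis()
  insert_analysis(s, a1)
  a2 <- worked_analysis()
  a2$general_values <- list()
  add_general_value(a2, "average_length", 250)
  a2$position_values <- list()
  add_position_value(a2, 30, "quality_score_count", 99)
  insert_analysis(s, a2)

  avg <- as.data.frame(get_average_values(s, full_filter()))
  expect_equal(avg$mean[avg$key == "average_length"], 250)
  pos <- as.data.frame(get_per_position_values(s, "quality_score_count",
                                               full_filter()))
  expect_equal(pos$mean, 99)
  # the superseded analysis is excluded from partial filters too
  pos_all <- as.data.frame(get_per_position_values(s, "quality_score_count",
                                                   property_filter()))
  expect_equal(pos_all$mean, 99)
})

test_that("base-content matrix equals the join of four partition queries", {
  dir <- withr::local_tempdir()
  rep <- file.path(dir, "fastqc.txt")
  gt <- generate_fastqc_report(
    fixture_params(read_length = 15L, n_reads = 2000L, seed = 21L), rep)
  s <- connect_store(file.path(dir, "s.sqlite"))
  on.exit(disconnect_store(s))
  a <- new_analysis(); add_property(a, "run", "R1")
  parse_fastqc(rep, a)
  insert_analysis(s, a)

  mat <- as.data.frame(get_per_position_base_content(s))
  expect_equal(names(mat), c("start", "end", "A", "C", "G", "T"))
  expect_equal(nrow(mat), 15)
  for (b in c("A", "C", "G", "T")) {
    single <- as.data.frame(get_per_partition_values(
      s, paste0("base_content_", tolower(b))))
    expect_equal(mat[[b]], single$mean, tolerance = 1e-9)
    # uniform composition: cells near 25
    expect_true(all(abs(mat[[b]] - 25) < 3))
  }

  s_empty <- mem_store()
  expect_equal(nrow(as.data.frame(get_per_position_base_content(s_empty))), 0)
  disconnect_store(s_empty)
})

test_that("aggregation oracle: means and counts match brute force on random stores", {
  set.seed(404)
  filters <- list(
    property_filter(),
    property_filter(run = "R1"),
    property_filter(lane = "1"),
    property_filter(instrument = "MISEQ-1", lane = "2"),
    property_filter(run = "R2", barcode = "CCC")
  )
  for (rep in 1:10) {
    s <- mem_store()
    n <- sample.int(6L, 1L)
    mirrors <- vector("list", n)
    for (i in seq_len(n)) {
      mirrors[[i]] <- random_analysis(max_positions = 25L)
      insert_analysis(s, mirrors[[i]]$analysis)
    }
    for (f in filters) {
      idx <- oracle_matching(mirrors, f)
      got <- as.data.frame(get_average_values(s, f))
      want <- oracle_general_means(mirrors, idx)
      expect_equal(got$key, want$key)
      expect_equal(got$mean, want$mean, tolerance = 1e-9)
      expect_equal(got$n, want$n)

      got <- as.data.frame(get_per_position_values(s, "quality_score_count", f))
      want <- oracle_position_means(mirrors, idx, "quality_score_count")
      expect_equal(got$position, want$position)
      expect_equal(got$mean, want$mean, tolerance = 1e-9)
      expect_equal(got$n, want$n)

      got <- as.data.frame(get_per_partition_values(s, "quality_mean", f))
      want <- oracle_partition_means(mirrors, idx, "quality_mean")
      expect_equal(got$start, want$start)
      expect_equal(got$end, want$end)
      expect_equal(got$mean, want$mean, tolerance = 1e-9)
      expect_equal(got$n, want$n)
    }
    disconnect_store(s)
  }
})

test_that("filter monotonicity: adding a constraint never increases any n", {
  set.seed(505)
  s <- mem_store()
  on.exit(disconnect_store(s))
  for (i in 1:8) insert_analysis(s, random_analysis(20L)$analysis)
  base <- as.data.frame(get_per_position_values(s, "quality_score_count",
                                                property_filter()))
  narrower <- as.data.frame(get_per_position_values(
    s, "quality_score_count", property_filter(lane = "1")))
  merged <- merge(base, narrower, by = "position")
  expect_true(all(merged$n.y <= merged$n.x))
})

test_that("property_filter accepts only the ten controlled keys", {
  f <- property_filter(run = "R1", softwareOnInstrument = "RTA")
  expect_s3_class(f, "property_filter")
  expect_error(property_filter(casava = "1.8"), "unknown filter key")
  expect_error(property_filter("R1"), "named")
  expect_length(property_filter(), 0)
})

test_that("CSV and JSON serializations are lossless on randomized tables", {
  set.seed(606)
  for (i in 1:25) {
    t <- random_report_table()
    expect_true(report_tables_equal(t, from_csv(to_csv(t))))
    jt <- from_json(to_json(t))
    expect_true(report_tables_equal(t, jt))
    expect_equal(jt$n_analyses, t$n_analyses)  # JSON keeps provenance
  }
  # empty table: header-only CSV, empty rows array
  empty <- report_table(data.frame(key = character(0), mean = numeric(0)))
  expect_equal(to_csv(empty), "key,mean\n")
  expect_match(to_json(empty), '"rows":\\[\\]')
  # comma-bearing cells are quoted
  t <- report_table(data.frame(key = "a,b", mean = 1), 1L)
  expect_match(to_csv(t), '"a,b"', fixed = TRUE)
})
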