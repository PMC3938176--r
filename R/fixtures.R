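# Synthetic-data side: writes syntactically valid FastQC reports with known
# ground truth, so the parser, store and query layers are testable end to end
# without any sequencer output.

#' Parameters for a synthetic FastQC report
#'
#' The generator emulates a single-end Illumina-style library at desk scale:
#' by default a 100-cycle read (matching an average length of 100 used
#' throughout the worked examples), 250,000 reads, a per-base mean quality
#' starting near Q38.5 and decaying linearly down the read (the familiar
#' Illumina 3'-quality droop), and a uniform A/C/G/T composition.
#'
#' @param read_length read length in bases (>= 1).
#' @param n_reads number of reads (>= 1); per-sequence histograms sum exactly
#'   to this.
#' @param quality_start mean quality at base 1 (Phred units).
#' @param quality_decay drop in mean quality per base.
#' @param base_composition named probabilities for A, C, G, T; must sum to 1.
#' @param n_overrepresented how many overrepresented sequences to fabricate.
#' @param group_bases_from position after which FastQC-style base-range
#'   grouping starts (NULL = every base reported singly).
#' @param group_width width of grouped base ranges.
#' @param seed RNG seed; the same seed yields a byte-identical report.
#' @return A \code{fixture_params} list.
#' @export
fixture_params <- function(read_length = 100L,
                           n_reads = 250000L,
                           quality_start = 38.5,
                           quality_decay = 0.08,
                           base_composition = c(A = 0.25, C = 0.25,
                                                G = 0.25, T = 0.25),
                           n_overrepresented = 2L,
                           group_bases_from = NULL,
                           group_width = 5L,
                           seed = 42L) {
  stopifnot(read_length >= 1, n_reads >= 1, group_width >= 1)
  if (!setequal(names(base_composition), c("A", "C", "G", "T")) ||
      abs(sum(base_composition) - 1) > 1e-9) {
    stop("base_composition must be named A/C/G/T probabilities summing to 1",
         call. = FALSE)
  }
  structure(list(
    read_length = as.integer(read_length),
    n_reads = as.integer(n_reads),
    quality_start = quality_start,
    quality_decay = quality_decay,
    base_composition = base_composition[c("A", "C", "G", "T")],
    n_overrepresented = as.integer(n_overrepresented),
    group_bases_from = if (is.null(group_bases_from)) NULL
                       else as.integer(group_bases_from),
    group_width = as.integer(group_width),
    seed = as.integer(seed)
  ), class = "fixture_params")
}

# inclusive base partitions per the grouping parameters
fixture_partitions <- function(p) {
  L <- p$read_length
  g <- p$group_bases_from
  if (is.null(g) || g > L) {
    return(data.frame(start = seq_len(L), end = seq_len(L)))
  }
  singles <- if (g > 1L) seq_len(g - 1L) else integer(0)
  starts <- c(singles, seq(g, L, by = p$group_width))
  ends <- c(singles, pmin(seq(g, L, by = p$group_width) + p$group_width - 1L, L))
  data.frame(start = as.integer(starts), end = as.integer(ends))
}

fmt_num <- function(x) {
  # fixed notation, trailing zeros trimmed; what gets printed IS ground truth
  s <- formatC(x, format = "f", digits = 10)
  s <- sub("0+$", "", s)
  sub("\\.$", "", s)
}

base_label <- function(start, end) {
  ifelse(start == end, as.character(start), paste0(start, "-", end))
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Generate a synthetic FastQC report with known ground truth
#'
#' Writes a syntactically valid \code{fastqc_data.txt} containing Basic
#' Statistics, Per base sequence quality, Per sequence quality scores, Per
#' base sequence content, Per sequence GC content, Sequence Length
#' Distribution and Overrepresented sequences, and returns every number it
#' wrote. The report is deterministic given \code{p$seed}. The per-base mean
#' quality profile is monotone non-increasing by default; the per-sequence
#' quality counts sum exactly to \code{n_reads}.
#'
#' @param p a [fixture_params()].
#' @param out output file path.
#' @return Invisibly, a \code{fastqc_ground_truth} list with elements
#'   \code{basic_statistics} (named list), \code{per_base_quality},
#'   \code{per_sequence_quality}, \code{base_content},
#'   \code{per_sequence_gc}, \code{length_distribution} and
#'   \code{overrepresented} (data.frames mirroring the file), plus
#'   \code{params}.
#' @export
generate_fastqc_report <- function(p, out) {
  stopifnot(inherits(p, "fixture_params"))
  with_seed(p$seed, {
    parts <- fixture_partitions(p)
    np <- nrow(parts)
    mid <- (parts$start + parts$end) / 2

    # per-base quality quantiles from a linear decay profile, capped to [2,40]
    q <- pmin(pmax(p$quality_start - p$quality_decay * (mid - 1), 2), 40)
    pbq <- data.frame(
      base = base_label(parts$start, parts$end),
      start = parts$start, end = parts$end,
      mean = round(q, 4),
      median = round(pmin(q + 0.2, 40), 4),
      lower_quartile = round(pmax(q - 1.5, 2), 4),
      upper_quartile = round(pmin(q + 1.0, 40), 4),
      p10 = round(pmax(q - 3.0, 2), 4),
      p90 = round(pmin(q + 1.5, 40), 4),
      stringsAsFactors = FALSE
    )

    # per-sequence mean-quality histogram, counts sum exactly to n_reads
    overall_q <- mean(q)
    bins <- 2:40
    w <- stats::dnorm(bins, mean = overall_q - 1, sd = 2.5)
    counts <- as.integer(stats::rmultinom(1L, p$n_reads, w / sum(w)))
    psq <- data.frame(quality = bins, count = counts)[counts > 0L, ]

    # per-base composition percentages with mild positional jitter
    comp <- p$base_composition * 100
    jitter <- matrix(stats::rnorm(np * 4L, 0, 0.4), ncol = 4L)
    bc <- data.frame(
      base = pbq$base, start = parts$start, end = parts$end,
      G = round(pmax(comp[["G"]] + jitter[, 1L], 0), 4),
      A = round(pmax(comp[["A"]] + jitter[, 2L], 0), 4),
      T = round(pmax(comp[["T"]] + jitter[, 3L], 0), 4),
      C = round(pmax(comp[["C"]] + jitter[, 4L], 0), 4),
      stringsAsFactors = FALSE
    )

    # per-sequence GC histogram around the composition's GC fraction
    gc_mean <- 100 * sum(p$base_composition[c("C", "G")])
    gbins <- 0:100
    gw <- stats::dnorm(gbins, mean = gc_mean, sd = 6)
    gcounts <- as.integer(stats::rmultinom(1L, p$n_reads, gw / sum(gw)))
    psg <- data.frame(gc = gbins, count = gcounts)[gcounts > 0L, ]

    len <- data.frame(length = p$read_length, count = p$n_reads)

    over <- NULL
    if (p$n_overrepresented > 0L) {
      seqs <- vapply(seq_len(p$n_overrepresented), function(i) {
        paste(sample(c("A", "C", "G", "T"), 20L, replace = TRUE), collapse = "")
      }, character(1))
      cnt <- as.integer(round(p$n_reads * stats::runif(p$n_overrepresented,
                                                       0.001, 0.005)))
      over <- data.frame(
        sequence = seqs, count = cnt,
        percentage = round(100 * cnt / p$n_reads, 6),
        source = rep(c("No Hit", "TruSeq Adapter, Index 1 (100% over 20bp)"),
                     length.out = p$n_overrepresented),
        stringsAsFactors = FALSE
      )
    } else {
      over <- data.frame(sequence = character(0), count = integer(0),
                         percentage = numeric(0), source = character(0),
                         stringsAsFactors = FALSE)
    }

    basic <- list(
      filename = "synthetic.fastq",
      file_type = "Conventional base calls",
      encoding = "Sanger / Illumina 1.9",
      total_sequences = p$n_reads,
      filtered_sequences = 0L,
      sequence_length = p$read_length,
      gc = as.integer(round(gc_mean))
    )

    lines <- c(
      "##FastQC\t0.10.1",
      ">>Basic Statistics\tpass",
      "#Measure\tValue",
      paste0("Filename\t", basic$filename),
      paste0("File type\t", basic$file_type),
      paste0("Encoding\t", basic$encoding),
      paste0("Total Sequences\t", basic$total_sequences),
      paste0("Filtered Sequences\t", basic$filtered_sequences),
      paste0("Sequence length\t", basic$sequence_length),
      paste0("%GC\t", basic$gc),
      ">>END_MODULE",
      ">>Per base sequence quality\tpass",
      "#Base\tMean\tMedian\tLower Quartile\tUpper Quartile\t10th Percentile\t90th Percentile",
      vapply(seq_len(np), function(i) {
        paste(pbq$base[i], fmt_num(pbq$mean[i]), fmt_num(pbq$median[i]),
              fmt_num(pbq$lower_quartile[i]), fmt_num(pbq$upper_quartile[i]),
              fmt_num(pbq$p10[i]), fmt_num(pbq$p90[i]), sep = "\t")
      }, character(1)),
      ">>END_MODULE",
      ">>Per sequence quality scores\tpass",
      "#Quality\tCount",
      paste(psq$quality, fmt_num(psq$count), sep = "\t"),
      ">>END_MODULE",
      ">>Per base sequence content\tpass",
      "#Base\tG\tA\tT\tC",
      vapply(seq_len(np), function(i) {
        paste(bc$base[i], fmt_num(bc$G[i]), fmt_num(bc$A[i]),
              fmt_num(bc$T[i]), fmt_num(bc$C[i]), sep = "\t")
      }, character(1)),
      ">>END_MODULE",
      ">>Per sequence GC content\tpass",
      "#GC Content\tCount",
      paste(psg$gc, fmt_num(psg$count), sep = "\t"),
      ">>END_MODULE",
      ">>Sequence Length Distribution\tpass",
      "#Length\tCount",
      paste(len$length, fmt_num(len$count), sep = "\t"),
      ">>END_MODULE",
      ">>Overrepresented sequences\tpass",
      "#Sequence\tCount\tPercentage\tPossible Source",
      if (nrow(over)) {
        vapply(seq_len(nrow(over)), function(i) {
          paste(over$sequence[i], over$count[i], fmt_num(over$percentage[i]),
                over$source[i], sep = "\t")
        }, character(1))
      } else character(0),
      ">>END_MODULE"
    )
    writeLines(lines, out)

    invisible(structure(list(
      basic_statistics = basic,
      per_base_quality = pbq,
      per_sequence_quality = psq,
      base_content = bc,
      per_sequence_gc = psg,
      length_distribution = len,
      overrepresented = over,
      params = p
    ), class = "fastqc_ground_truth"))
  })
}

#' Write an analysis-metadata table
#'
#' Writes the tab-delimited table read back by [parse_run_table()]: a header
#' from the union of entry keys (in first-appearance order) and one row per
#' entry, missing keys as empty cells.
#'
#' @param entries a list of named character vectors (or
#'   \code{run_table_entry} objects); names are upper-cased.
#' @param out output file path.
#' @export
write_metadata_table <- function(entries, out) {
  entries <- lapply(entries, function(e) stats::setNames(as.character(e),
                                                         toupper(names(e))))
  header <- unique(unlist(lapply(entries, names)))
  if (!length(header)) stop("no columns to write", call. = FALSE)
  lines <- paste(header, collapse = "\t")
  for (e in entries) {
    cells <- vapply(header, function(h) if (h %in% names(e)) e[[h]] else "",
                    character(1))
    lines <- c(lines, paste(cells, collapse = "\t"))
  }
  writeLines(lines, out)
  invisible(NULL)
}
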