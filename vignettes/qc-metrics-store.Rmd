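---
title: "Storing and querying sequencing run QC metrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Storing and querying sequencing run QC metrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seqqcstore)
```

## The problem and the model

A sequencing facility produces one QC report per analysis — per run, lane,
read pair and (for multiplexed libraries) barcode. Each report is easy to
read on its own and nearly impossible to query across. `seqqcstore` keeps
those metrics in a single relational store with a schema that assumes
nothing about the QC tool, so that questions like "mean per-base quality for
lane 1 across all runs on this instrument" become one API call.

The schema is an entity–attribute–value design normalised to third normal
form. Its core entities are:

* **analysis** — one QC execution, with an auto-incrementing id and an
  insertion timestamp. Re-running QC with the same parameters is a *new*
  analysis; nothing is ever updated or deleted.
* **analysis properties** — free key/value metadata per analysis. Eleven
  property names are controlled so queries work across platforms: `tool`,
  `encoding`, `chemistry`, `instrument`, `software`, `type`, `pair`,
  `sample_name`, `lane`, `run`, `barcode`; parsers may add any others
  (e.g. `casava_version`), which are stored but not queryable as filters.
* **value types** — the registry mapping each metric key to exactly one of
  three scopes, with an optional description. A description is written the
  first time one is supplied and never overwritten afterwards, which keeps
  annotations consistent across analyses by construction.
* **values** — one table per scope: global values (numeric or text),
  per-position values `(position, value)` and per-partition values
  `(start, end, value)` with inclusive 1-based bounds.

The three scopes are the whole tool-independence story. A per-base quality
mean is a `base_partition` value; a histogram of read quality scores is a
`sequence_cumulative` count indexed by the score; a total GC percentage or
an overrepresented sequence's count is an `analysis` value. Any tool whose
output decomposes into these shapes can be loaded by writing a parser — no
schema change required.

## Building and inserting an analysis

Parsers construct a `qc_analysis` in memory before anything touches the
database. The builder enforces the two invariants that make inserts total:
every key used by a value must have been registered with `add_valid_type()`
first, and a value can only go into the container its scope dictates. A
builder-validated analysis therefore always inserts (the insert itself is a
single transaction and rolls back on the only remaining failure mode, a
scope conflict with a type already stored under the same name).

```{r builder}
a <- new_analysis()
add_property(a, "tool", "FastQC")
add_property(a, "run", "RUN-123")
add_valid_type(a, "quality_score_count", "sequence_cumulative")
add_valid_type(a, "quality_mean", "base_partition")
add_valid_type(a, "average_length", "analysis")
add_position_value(a, 30, "quality_score_count", 15000)
add_partition_value(a, parse_range("10-14"), "quality_mean", 38.7)
add_general_value(a, "average_length", 100)
a
```

Two deliberately small semantics here: repeated `add_property()` on the same
key is last-write-wins (parsers refine defaults, e.g. the FastQC parser
overwrites a placeholder encoding with the report's own), and repeated
values for the same `(position, key)` are appended, not de-duplicated —
de-duplication is the parser's job, because only the parser knows whether a
duplicate is meaningful.

`parse_range()` accepts exactly two forms, a bare integer (`"10"`, a
partition of size 1) and an inclusive pair (`"10-14"`, five positions),
after trimming whitespace. Other dialects (`"10..14"`) are rejected rather
than guessed at.

## Query semantics

All queries accept a `property_filter()` over the ten controlled keys; an
empty filter matches everything. Three rules define every result:

1. **Summaries are unweighted arithmetic means** across matching analyses,
   with `n` = the number of analyses contributing to that row. The mean was
   chosen (over sums or medians) because it is the only summary that is
   comparable across groups of different sizes, and the sum is recoverable
   as mean × n. Text-valued globals are excluded from means and reported by
   count.
2. **Latest-wins.** Analyses sharing an identity — the property tuple
   (`run`, `lane`, `pair`, `barcode`, `sample_name`, `tool`) — are re-runs
   of the same QC; only the newest (timestamp, ties broken by the higher id)
   is visible to any query. A fully-specified filter thus returns exactly
   the latest analysis; partial filters aggregate the latest representative
   of each matching identity. Superseded analyses are retained in the store
   but never counted, which keeps historical aggregates from double-counting
   re-runs. (An `include-superseded` query option would be a natural
   extension; it is not implemented.)
3. **Partitions are never blended.** Per-partition summaries group by the
   exact `(start, end)` pair, so two analyses binned differently produce
   separate rows instead of a silently averaged hybrid.

Row ordering is deterministic (position/start ascending, then key), so
serialisations are byte-stable and CLI output can be diffed.

Results come back as a `report_table` — ordered columns, rows, and the
number of analyses aggregated — serialisable with `to_csv()` (RFC-4180
quoting, up to 10 significant digits) and `to_json()`
(`{"columns": ..., "rows": ..., "n_analyses": ...}`, full double precision,
ready for browser plotting). JSON round-trips losslessly including
provenance; CSV is typeless and carries data only, so its round-trip
guarantee is cell-wise value equality, not type identity.

## The FastQC parser

FastQC's `fastqc_data.txt` is a `##FastQC` version line followed by modules
delimited by `>>Name<tab>status` … `>>END_MODULE`. The module-to-scope
mapping is the parser's own (the schema does not care):

| FastQC module | scope | keys |
|---|---|---|
| Basic Statistics | properties + analysis | `encoding` property; `general_total_sequences`, `general_filtered_sequences`, `general_gc_content`, `general_min_length`, `general_max_length` |
| Per base sequence quality | base_partition | `quality_mean`, `quality_median`, `quality_lower_quartile`, `quality_upper_quartile`, `quality_10th_percentile`, `quality_90th_percentile` |
| Per base sequence content | base_partition | `base_content_a/c/g/t` |
| Per base GC content | base_partition | `gc_content_percentage` |
| Per base N content | base_partition | `base_content_n` |
| Per sequence quality scores | sequence_cumulative | `quality_score_count` |
| Per sequence GC content | sequence_cumulative | `gc_content_count` |
| Sequence Length Distribution | sequence_cumulative | `length_count` (on the bin's start) |
| Sequence Duplication Levels | sequence_cumulative + analysis | `duplication_level_relative_count`; `general_duplication_percentage` |
| Overrepresented sequences / Kmer Content | analysis | key = the sequence, value = its count, description = the possible source |

Every module's pass/warn/fail status is stored as the global value
`<module_key>_status`. Grouped base labels (`"10-14"`) become one partition
spanning the range. Numeric cells that are empty or `NaN` are *skipped with
a warning*, never stored as zero — a stored zero would silently poison
means. Unknown module names are skipped with a warning so reports from newer
FastQC versions still load; a missing `##FastQC` sentinel or an unterminated
module is a hard parse error naming the module and line.

Parsers are registered by name (`register_parser("fastqc", parse_fastqc)` is
done at package load) and are plain functions `function(path, analysis)`
with no store access; the loader (`load_analyses()`) owns the connection,
iterates the metadata table, dispatches on each entry's `ANALYSIS_TYPE`, and
reports per-entry failures without aborting the rest. An unknown
`ANALYSIS_TYPE` fails that entry explicitly; only the CLI applies the
FastQC default (with a logged notice), because a silent default in the
library would mask metadata errors.

## The synthetic report generator

`generate_fastqc_report()` exists so the whole pipeline is testable with no
sequencer data: it writes a syntactically valid report *and returns every
number it wrote*, so tests can assert exact closure (generate → load →
query reproduces ground truth to 1e-9).

What it emulates, and the defaults chosen as a realistic stated world:

* a 100-cycle, 250,000-read single-end Illumina-style library (the worked
  examples use an average length of 100; 250k reads is a plausible
  per-barcode yield on a desktop sequencer);
* a monotone non-increasing per-base mean quality, Q38.5 at base 1 with a
  linear decay of 0.08/base — the familiar 3' quality droop; quantiles are
  fixed offsets from the mean, capped to [2, 40]. The decay is configurable
  (including 0) so monotonicity tests are meaningful rather than vacuous;
* per-sequence quality and GC histograms drawn multinomially, so counts sum
  *exactly* to `n_reads` — a conservation law the round-trip tests exploit;
* uniform A/C/G/T composition with mild per-position jitter (σ = 0.4
  percentage points), so base-content cells sit near 25;
* optional FastQC-style base grouping from a given position with a given
  width, the last group clipped at the read end;
* byte-identical output for the same seed, without disturbing the caller's
  RNG stream.

What it does *not* emulate: real FastQC's adaptive binning rules, tile-level
artefacts, adapter-content curves, duplication estimation, or any
correlation between quality and base composition. A green end-to-end test
therefore establishes that parsing, storage, aggregation and serialisation
are faithful — not that the generator's numbers resemble any particular
instrument's failure modes.

## Storage engine and configuration

The store is an embedded SQLite file (or `:memory:`), created on first
connect — zero installation, and the database file is an implementation
artifact: all public access goes through the API and CLI. Systems of this kind often
push query logic into engine-specific stored procedures so the client APIs
stay thin; since procedure syntax is exactly the part that does not port
across engines, this package keeps those query contracts in the API layer
over the same schema instead. Config files accept both
historical key dialects (`db_string`/`db_user`/`db_password` and
`statsdb.url`/`statsdb.username`/`statsdb.password`), `#` comments, and
either `=` or whitespace separators. Server connection strings (`mysql:`,
`jdbc:`) are recognised and rejected with a clear message rather than
half-supported.

Timestamps are recorded at insert in UTC; because inserts in one session can
share a clock tick, the monotonically increasing analysis id is the
documented tie-breaker everywhere latest-wins applies.

## Numerical and edge-case choices

* Values are stored as doubles when the text is numeric, else as text with a
  null numeric slot; query means are computed in double precision and tested
  against brute-force oracles at 1e-9.
* Positions for `sequence_cumulative` values are non-negative integers (a
  quality score of 0 is legal); base positions are 1-based and partitions
  inclusive, so width = end − start + 1.
* An empty query result is a table with its full header and zero rows, and
  the CLI exits 0 on it — an empty answer is an answer.
* CSV prints up to 10 significant digits; JSON keeps full precision.
* The CLI maps failure classes to exit codes (1 usage, 2 partial load
  failure, 3 connection/config) so pipelines can branch on them.

## Known limitations

* Only the FastQC parser ships; the registry is the extension point for
  PacBio `sts.csv`, SAMStat or k-mer-screen parsers.
* No schema migration, deletion, or permission management — the store is
  append-only by design.
* `per_tile_sequence_quality` and `adapter_content` modules contribute only
  their status value; their matrices have no scope in this model.
* Aggregation across analyses with different FastQC binnings yields
  per-binning rows (by design); consumers wanting a common grid must re-bin
  downstream.
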