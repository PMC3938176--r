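# seqqcstore

Modern sequencing centres run every flowcell through QC tools such as FastQC
and end up with thousands of plain-text reports scattered across disk — one
per run, lane, read pair and barcoded sample — with no way to ask questions
that cut across them ("how has per-base quality on instrument MISEQ-1 changed
across runs?", "what is the nucleotide bias for barcode AAACTGA over all
lanes?"). `seqqcstore` is an R package that solves the storage-and-access
half of that problem: a platform-agnostic, tool-independent relational store
for run QC metrics, with a **parser** side that loads QC-tool output into an
embedded SQLite database and a **consumer** side that answers granular
summary queries as CSV/JSON report tables.

The package is aimed at bioinformaticians and sequencing-facility engineers
who want run metrics queryable from a pipeline, a LIMS, or an R session,
without hand-dissecting individual reports.

## The data model

Metrics are stored in a normalised entity–attribute–value schema that is
agnostic to the QC tool. Every metric key is registered once with one of
three **scopes**:

| scope | meaning | example |
|---|---|---|
| `analysis` | one value for the whole analysis | `general_gc_content`, an overrepresented sequence's count |
| `base_partition` | value per base position or inclusive range [start, end] | `quality_mean` over positions 10–14 |
| `sequence_cumulative` | count indexed by a score/bin across all reads | `quality_score_count`: 15000 reads at Q30 |

Each analysis carries free-form **properties** (tool, run, lane, pair,
barcode, sample_name, instrument, chemistry, …). Queries filter on the ten
controlled keys (`run`, `lane`, `pair`, `barcode`, `sampleName`,
`instrument`, `encoding`, `chemistry`, `softwareOnInstrument`,
`typeOfExperiment`) and return **unweighted arithmetic means across the
matching analyses** together with the number of contributing analyses
*n* — so the sum is recoverable as mean × n. Re-running QC on the same
sample appends a new record; queries always resolve re-runs *latest-wins*:
with every identity key specified only the newest analysis is returned, and
even partial filters exclude superseded analyses.

## Worked example

No sequencer data is needed: the package ships a synthetic FastQC report
generator with known ground truth.

```r
library(seqqcstore)

# 1. generate a 20-cycle, 10k-read report; bases grouped FastQC-style from 10
p  <- fixture_params(read_length = 20, n_reads = 10000,
                     group_bases_from = 10, seed = 42)
gt <- generate_fastqc_report(p, "fastqc_data.txt")

# 2. describe the analysis in a metadata table and load it
e <- c(TYPE_OF_EXPERIMENT = "NGS", PATH_TO_ANALYSIS = "fastqc_data.txt",
       ANALYSIS_TYPE = "FastQC", INSTRUMENT = "MISEQ-1",
       SAMPLE_NAME = "TEST_SAMPLE", LANE = "1", BARCODE = "AAACTGA",
       PAIR = "1", RUN = "RUN_NAME")
write_metadata_table(list(e), "metadata.tsv")
load_analyses("store.sqlite", "metadata.tsv")
#> $parsed   [1] 1
#> $inserted [1] 1
#> $failed   [1] 0

# 3. query per-partition mean quality for that run/lane/barcode
s <- connect_store("store.sqlite")
f <- property_filter(run = "RUN_NAME", lane = "1", barcode = "AAACTGA")
cat(to_csv(get_per_partition_values(s, "quality_mean", f)))
disconnect_store(s)
```

which prints (one row per base partition; `mean` is the quality mean, `n`
the number of analyses aggregated — here a single analysis, so the values
are exactly the generator's ground truth, Q38.5 at base 1 decaying down the
read, with the grouped partitions 10–14 and 15–19 intact):

```
start,end,mean,n
1,1,38.5,1
2,2,38.42,1
...
9,9,37.86,1
10,14,37.62,1
15,19,37.22,1
20,20,36.98,1
```

The same queries are available from the shell via the CLI (see
`exec/seqqcstore`), whose output is byte-identical to the library's
serialisers:

```sh
seqqcstore load -m metadata.tsv --db statsdb.properties
seqqcstore query partitions quality_mean --run RUN_NAME --lane 1 --barcode AAACTGA
seqqcstore list runs
```

## Further reading

The methods vignette (`vignettes/qc-metrics-store.Rmd`) documents the data
model, the aggregation and latest-wins semantics, the FastQC module-to-scope
mapping, what the synthetic generator does and does not emulate, and the
package's design decisions.
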