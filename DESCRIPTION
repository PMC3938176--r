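Package: seqqcstore
Title: Relational Storage and Querying of Sequencing Run QC Metrics
Version: 0.1.0
Authors@R: person("SeqQC", "Maintainers", email = "tools@example.org", role = c("aut", "cre"))
Description: A platform-agnostic, tool-independent store for next-generation
    sequencing run quality-control metrics. A parser side loads QC-tool output
    (FastQC plain-text reports, driven by a tab-delimited analysis-metadata
    table) into an embedded relational database; a consumer side answers
    granular summary queries (per run, lane, barcode, instrument, ...) as
    CSV/JSON report tables. Ships a synthetic FastQC report generator so the
    whole pipeline is testable without sequencer data.
License: GPL-3
Encoding: UTF-8
Imports:
    DBI,
    RSQLite,
    R6,
    jsonlite,
    stats,
    utils
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
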