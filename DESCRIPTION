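Package: nmdscan
Title: Discovery and Quantification of Non-Productive (NMD-Inducing)
    Alternative Splicing Events from Splice-Junction Counts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies, classifies, and quantifies non-productive
    alternative-splicing events, i.e. splicing choices that introduce a
    premature termination codon and route the transcript into
    nonsense-mediated mRNA decay (NMD). Builds a transcript database from
    GTF and genePred annotations, labels every exon-exon junction as coding
    or NMD by a transcript-exclusivity rule, applies the 50-nt premature
    termination codon rule, enumerates skipped-exon, alternative splice
    site, and retained-intron (exitron) events, computes percent-spliced-in
    (PSI) from splice-junction count tables, applies abundance filters and
    sample quality-control gates, annotates genes against a gene-disease
    table with alias expansion, partitions exons for conservation analysis,
    and includes a seeded synthetic-data generator with known ground truth
    plus helpers for downstream assay statistics (delta-delta-Ct, standard
    curve interpolation, densitometry percentages).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    rtracklayer,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
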