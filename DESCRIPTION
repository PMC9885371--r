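Package: cndscan
Title: Gene-Level Significance of Recurrent Somatic Copy-Number Deletions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies genes non-randomly targeted by somatic copy-number
    deletions (CND) in a tumor cohort. Per-sample deletion segments are
    collapsed into a breakpoint-partitioned collective track; each gene
    receives a score summing, over the collective segments it overlaps,
    the deleted-sample count divided by the segment length plus the gene
    length, so that recurrence is rewarded and long unspecific segments
    are penalized. Significance is assessed against a within-chromosome
    segment-shuffling null with add-one empirical p-values and
    Benjamini-Yekutieli false-discovery-rate control. Includes the
    model-motivating diagnostics (gene-hit-frequency decay with segment
    size, breakpoint enrichment in curated driver genes), downstream
    gene-set and pathway enrichment with hierarchical clustering and UMAP
    profiling across cohorts, a synthetic-cohort generator with planted
    target genes for end-to-end validation, readers and writers for
    segment tables (pgxseg-style TSV), BED/GFF3 gene annotation and GMT
    gene sets, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    uwot,
    ape,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
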