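Package: cnvscreen
Title: Identify False-Positive Germline CNV Calls Using SNV Allele Frequencies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Screens germline copy-number variant (CNV) calls against the
    single-nucleotide variant (SNV) calls produced by standard sequencing
    pipelines. A heterozygous deletion is a loss-of-heterozygosity region,
    so heterozygous SNVs inside a called deletion are evidence that the
    deletion is a false positive; inside a true duplication the allele
    frequency of heterozygous SNVs shifts from 50% towards 33% or 66%, and a
    fuzzy scoring model turns each SNV's allele frequency into a score in
    [-1, 1] whose sum decides the duplication verdict. The package loads SNVs
    from the VCF dialects of VarScan2, Strelka/Strelka2, freeBayes and the
    GATK HaplotypeCaller/UnifiedGenotyper callers (or any caller via field
    overrides), reads CNV tables with a configurable column map, reports
    per-CNV verdicts with their evidence, draws per-CNV diagnostic plots and
    the scoring-model curve, and ships a seeded synthetic-data generator with
    planted true and false CNVs for end-to-end evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    vcfR,
    GenomicRanges,
    IRanges,
    S4Vectors,
    ggplot2,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
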