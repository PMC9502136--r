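# Shared fixture builders and the independent reference implementation used
# to cross-check the filter engine.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Minimal hand-built VCF for unit tests. `rows` is a data frame with
# chrom/pos/ref/alt/filter/fmt/val columns; meta lines are prepended.
write_test_vcf <- function(rows, path, meta = character(),
                           samples = "sample1") {
  header <- c("##fileformat=VCFv4.2", meta,
              '##FILTER=<ID=PASS,Description="ok">',
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", samples), collapse = "\t"))
  body <- apply(rows, 1, function(r) {
    paste(c(r[["chrom"]], r[["pos"]], ".", r[["ref"]], r[["alt"]], "99",
            r[["filter"]], ".", r[["fmt"]],
            unlist(r[grep("^val", names(r))])), collapse = "\t")
  })
  writeLines(c(header, body), path)
  path
}

gatk_meta <- function() {
  c("##GATKCommandLine=<ID=HaplotypeCaller,Version=test>",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="gt">',
    '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="ad">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="dp">')
}

# One GATK-style VCF row with given counts.
gatk_row <- function(chrom, pos, ref_d, alt_d, gt = "0/1", filter = "PASS",
                     ref = "A", alt = "C") {
  data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt, filter = filter,
             fmt = "GT:AD:DP",
             val = sprintf("%s:%d,%d:%d", gt, ref_d, alt_d, ref_d + alt_d),
             stringsAsFactors = FALSE)
}

# In-memory SNV table for engine tests (bypasses VCF parsing).
make_snvs <- function(pos, af, genotype, chrom = "chr1",
                      sample_id = "sample1", depth = 100) {
  n <- max(length(pos), length(af), length(genotype))
  data.frame(chrom = rep_len(chrom, n), pos = rep_len(pos, n),
             ref = rep_len("A", n), alt = rep_len("C", n),
             alt_depth = round(rep_len(af, n) / 100 * depth),
             total_depth = rep_len(depth, n),
             allele_frequency = rep_len(af, n),
             genotype_class = rep_len(genotype, n),
             sample_id = rep_len(sample_id, n), stringsAsFactors = FALSE)
}

make_cnv <- function(start, end, cnv_type, chrom = "chr1",
                     sample_id = "sample1", call_id = "cnv_0001") {
  data.frame(call_id = call_id, chrom = chrom, start = start, end = end,
             cnv_type = cnv_type, sample_id = sample_id,
             source_tool = NA_character_, stringsAsFactors = FALSE)
}

# ---- independent straight-line reference implementation of the two rules --
# Written as plain per-call loops with direct comparisons, independent of the
# engine's dispatch, overlap machinery and vectorized scorer.

ref_score_one <- function(f, p) {
  xs <- c(p$informative_low, p$expected_dup_mean_low,
          (p$expected_dup_mean_low + p$expected_ht_mean) / 2,
          p$expected_ht_mean,
          (p$expected_ht_mean + p$expected_dup_mean_high) / 2,
          p$expected_dup_mean_high, p$informative_high)
  ss <- c(0, -1, 0, 1, 0, -1, 0)
  if (f <= xs[1] || f >= xs[7]) return(0)
  for (i in 1:6) {
    if (f >= xs[i] && f <= xs[i + 1]) {
      return(ss[i] + (ss[i + 1] - ss[i]) *
               (1 - cos(pi * (f - xs[i]) / (xs[i + 1] - xs[i]))) / 2)
    }
  }
}

ref_decisions <- function(cnvs, snvs, p) {
  out <- character(nrow(cnvs))
  for (i in seq_len(nrow(cnvs))) {
    keep_rows <- snvs$chrom == cnvs$chrom[i] &
      snvs$sample_id == cnvs$sample_id[i] &
      snvs$pos >= cnvs$start[i] & snvs$pos <= cnvs$end[i]
    ov <- snvs[keep_rows, , drop = FALSE]
    if (cnvs$cnv_type[i] == "deletion") {
      gc <- ov$genotype_class[ov$genotype_class != "unknown"]
      out[i] <- if (length(gc) > 0 &&
                    100 * sum(gc == "het") / length(gc) >= p$del_het_threshold_pct)
        "filter" else "keep"
    } else {
      af <- ov$allele_frequency[ov$genotype_class == "het"]
      total <- 0
      for (f in af) total <- total + ref_score_one(f, p)
      out[i] <- if (length(af) > 0 && total > p$dup_score_threshold)
        "filter" else "keep"
    }
  }
  out
}
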