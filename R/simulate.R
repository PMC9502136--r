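#' Configuration for the synthetic CNV/SNV sample generator
#'
#' Describes a simulated germline sample: planted CNVs of four classes
#' (true/false deletions and duplications), a grid of heterozygous SNV
#' sites, and a binomial read-count model over Poisson depths. The generator
#' emulates exactly the statistical structure the screening rules assume —
#' allele-frequency evidence at biallelic het sites — and nothing else (no
#' mapping or GC bias, no contamination), so it isolates the decision rules.
#'
#' Read counts: per-site depth is Poisson(`depth_mean`); alternate reads are
#' Binomial(depth, p) with p = 1/2 at diploid het sites (background, false
#' deletions, false duplications), p drawn from {1/3, 2/3} with equal
#' probability per site inside true duplications, and p = 1 at the sites
#' surviving a true deletion. A true heterozygous deletion is a
#' loss-of-heterozygosity region: each het site inside it lay on the deleted
#' or the surviving haplotype with equal probability, so half the sites
#' disappear and the rest become homozygous.
#'
#' @param chrom_lengths Named numeric vector of chromosome lengths in bp.
#' @param n_true_del,n_false_del,n_true_dup,n_false_dup Planted CNV counts
#'   per class.
#' @param cnv_length_range Length-2 numeric, CNV lengths drawn uniformly
#'   from this range (bp).
#' @param snv_density Heterozygous SNV sites per kb, placed on a regular
#'   grid so site counts per region are reproducible.
#' @param depth_mean Mean of the Poisson read-depth distribution.
#' @param dialect VCF dialect to emit; one of [vcf_dialects()].
#' @param sample_id Sample name written to all outputs.
#' @param seed Integer seed; a fixed seed gives byte-identical outputs.
#' @return Validated list of class `sim_config`.
#' @export
sim_config <- function(chrom_lengths = c(chr1 = 1e7),
                       n_true_del = 5, n_false_del = 5,
                       n_true_dup = 5, n_false_dup = 5,
                       cnv_length_range = c(10e3, 20e3),
                       snv_density = 1,
                       depth_mean = 100,
                       dialect = "gatk_haplotypecaller",
                       sample_id = "sample1",
                       seed = 1L) {
  cfg <- list(chrom_lengths = chrom_lengths,
              n_true_del = n_true_del, n_false_del = n_false_del,
              n_true_dup = n_true_dup, n_false_dup = n_false_dup,
              cnv_length_range = cnv_length_range,
              snv_density = snv_density, depth_mean = depth_mean,
              dialect = dialect, sample_id = sample_id,
              seed = as.integer(seed))
  counts <- c(cfg$n_true_del, cfg$n_false_del, cfg$n_true_dup, cfg$n_false_dup)
  if (any(counts < 0)) stop("planted CNV counts must be non-negative")
  if (cfg$depth_mean <= 0) stop("depth_mean must be positive")
  if (cfg$snv_density <= 0) stop("snv_density must be positive")
  if (length(cfg$cnv_length_range) != 2L ||
      cfg$cnv_length_range[1] > cfg$cnv_length_range[2] ||
      cfg$cnv_length_range[1] < 1) {
    stop("cnv_length_range must be an increasing positive pair")
  }
  if (is.null(names(cfg$chrom_lengths)) || any(cfg$chrom_lengths < 1)) {
    stop("chrom_lengths must be a named vector of positive lengths")
  }
  if (!cfg$dialect %in% vcf_dialects()) {
    stop("dialect must be one of ", paste(vcf_dialects(), collapse = ", "))
  }
  # one CNV per equal-width slot guarantees non-overlap; refuse configs
  # where the slots cannot hold the longest CNV
  n_cnv <- sum(counts)
  if (n_cnv > 0) {
    slot <- sum(cfg$chrom_lengths) / n_cnv
    if (slot < 2 * cfg$cnv_length_range[2]) {
      stop("cannot place ", n_cnv, " non-overlapping CNVs of up to ",
           cfg$cnv_length_range[2], " bp on ", sum(cfg$chrom_lengths),
           " bp of genome; enlarge chrom_lengths or shrink the request")
    }
  }
  structure(cfg, class = "sim_config")
}

# Place planted CNVs: one per equal-width slot (shuffled class labels),
# random offset within the slot, so calls never overlap.
place_cnvs <- function(cfg) {
  classes <- rep(c("true_del", "false_del", "true_dup", "false_dup"),
                 times = c(cfg$n_true_del, cfg$n_false_del,
                           cfg$n_true_dup, cfg$n_false_dup))
  n <- length(classes)
  if (n == 0L) {
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      class = character(), stringsAsFactors = FALSE))
  }
  classes <- sample(classes)
  # distribute slots over chromosomes proportionally to length
  n_per <- pmax(0L, round(n * cfg$chrom_lengths / sum(cfg$chrom_lengths)))
  while (sum(n_per) < n) n_per[which.max(cfg$chrom_lengths)] <- n_per[which.max(cfg$chrom_lengths)] + 1L
  while (sum(n_per) > n) n_per[which.max(n_per)] <- n_per[which.max(n_per)] - 1L
  out <- list(); k <- 0L
  for (ci in seq_along(cfg$chrom_lengths)) {
    if (n_per[ci] == 0L) next
    slot <- floor(cfg$chrom_lengths[ci] / n_per[ci])
    if (slot < 2 * cfg$cnv_length_range[2]) {
      stop("cannot place ", n_per[ci], " non-overlapping CNVs on ",
           names(cfg$chrom_lengths)[ci])
    }
    for (s in seq_len(n_per[ci])) {
      k <- k + 1L
      len <- round(stats::runif(1, cfg$cnv_length_range[1], cfg$cnv_length_range[2]))
      lo <- (s - 1L) * slot + 1L
      start <- lo + floor(stats::runif(1, 0, slot - len))
      out[[k]] <- data.frame(chrom = names(cfg$chrom_lengths)[ci],
                             start = as.integer(start),
                             end = as.integer(start + len - 1L),
                             class = classes[k], stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Simulate a paired CNV-table / VCF / truth-table sample
#'
#' Generates one synthetic sample under `config` (see [sim_config()]) and
#' writes three plain-text files into `dir`: `cnvs.tsv` (the CNV callset in
#' the default [load_cnv_calls()] schema), `snvs.vcf` (the SNV callset in
#' the configured caller dialect) and `truth.tsv` (planted class and the
#' verdict expected under noiseless evidence: planted false CNVs should be
#' flagged, planted true CNVs kept).
#'
#' @param config A [sim_config()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with the three file paths (`cnv_file`,
#'   `vcf_file`, `truth_file`), the truth table, the planted CNV table and
#'   the per-site data frame (`sites`) actually emitted.
#' @export
simulate_sample <- function(config = sim_config(), dir = tempdir()) {
  stopifnot(inherits(config, "sim_config"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  set.seed(config$seed)

  cnvs <- place_cnvs(config)

  # het SNV sites on a regular grid
  step <- max(1L, round(1000 / config$snv_density))
  sites <- do.call(rbind, lapply(seq_along(config$chrom_lengths), function(ci) {
    pos <- seq.int(from = max(1L, floor(step / 2)),
                   to = config$chrom_lengths[ci], by = step)
    data.frame(chrom = names(config$chrom_lengths)[ci], pos = as.integer(pos),
               stringsAsFactors = FALSE)
  }))

  # context of each site: background or the class of the containing CNV
  sites$class <- "background"
  if (nrow(cnvs)) {
    hits <- GenomicRanges::findOverlaps(
      GenomicRanges::GRanges(sites$chrom, IRanges::IRanges(sites$pos, sites$pos)),
      GenomicRanges::GRanges(cnvs$chrom, IRanges::IRanges(cnvs$start, cnvs$end))
    )
    sites$class[S4Vectors::queryHits(hits)] <- cnvs$class[S4Vectors::subjectHits(hits)]
  }

  n <- nrow(sites)
  sites$p <- 0.5
  dup <- sites$class == "true_dup"
  sites$p[dup] <- sample(c(1 / 3, 2 / 3), sum(dup), replace = TRUE)
  del <- sites$class == "true_del"
  # half the het sites sat on the deleted haplotype and vanish; the
  # survivors are hemizygous, reported as homozygous alt
  surviving <- del & (stats::runif(n) < 0.5)
  sites$p[surviving] <- 1
  drop <- del & !surviving

  sites$depth <- stats::rpois(n, config$depth_mean)
  sites$alt <- stats::rbinom(n, sites$depth, sites$p)
  drop <- drop | sites$depth == 0L | sites$alt == 0L   # non-variant sites are not called
  sites <- sites[!drop, , drop = FALSE]

  bases <- c("A", "C", "G", "T")
  sites$ref <- sample(bases, nrow(sites), replace = TRUE)
  sites$alt_base <- vapply(sites$ref,
                           function(r) sample(setdiff(bases, r), 1L), "x")
  sites$af <- 100 * sites$alt / sites$depth
  sites$gt <- ifelse(sites$p == 1, "1/1", "0/1")
  rownames(sites) <- NULL

  cnv_file <- file.path(dir, "cnvs.tsv")
  vcf_file <- file.path(dir, "snvs.vcf")
  truth_file <- file.path(dir, "truth.tsv")

  cnv_tab <- data.frame(chrom = cnvs$chrom, start = cnvs$start,
                        end = cnvs$end,
                        type = ifelse(grepl("del", cnvs$class), "deletion",
                                      "duplication"),
                        sample = rep(config$sample_id, nrow(cnvs)),
                        stringsAsFactors = FALSE)
  utils::write.table(cnv_tab, cnv_file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  truth <- data.frame(call_id = sprintf("cnv_%04d", seq_len(nrow(cnvs))),
                      class = cnvs$class,
                      expected = ifelse(grepl("^false", cnvs$class),
                                        "filter", "keep"),
                      stringsAsFactors = FALSE)
  utils::write.table(truth, truth_file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_dialect_vcf(sites, config, vcf_file)

  invisible(list(cnv_file = cnv_file, vcf_file = vcf_file,
                 truth_file = truth_file, truth = truth, cnvs = cnvs,
                 sites = sites))
}

# Emit the simulated sites as a VCF v4.2 styled after one caller dialect.
write_dialect_vcf <- function(sites, config, path) {
  h <- c("##fileformat=VCFv4.2")
  h <- c(h, switch(config$dialect,
    varscan2 = "##source=VarScan2",
    strelka = "##source=strelka",
    freebayes = "##source=freeBayes v1.3",
    gatk_haplotypecaller = "##GATKCommandLine=<ID=HaplotypeCaller,Version=synthetic>",
    gatk_unifiedgenotyper = "##GATKCommandLine=<ID=UnifiedGenotyper,Version=synthetic>"
  ))
  h <- c(h, paste0("##contig=<ID=", names(config$chrom_lengths),
                   ",length=", format(config$chrom_lengths, scientific = FALSE,
                                      trim = TRUE), ">"))
  fmt_decl <- function(id, number, type, desc) {
    sprintf('##FORMAT=<ID=%s,Number=%s,Type=%s,Description="%s">',
            id, number, type, desc)
  }
  h <- c(h, fmt_decl("GT", "1", "String", "Genotype"))
  h <- c(h, switch(config$dialect,
    varscan2 = c(fmt_decl("DP", "1", "Integer", "Read depth"),
                 fmt_decl("RD", "1", "Integer", "Reference depth"),
                 fmt_decl("AD", "1", "Integer", "Alternate depth"),
                 fmt_decl("FREQ", "1", "String", "Variant allele frequency")),
    strelka = c(fmt_decl("GQX", "1", "Integer", "Genotype quality"),
                fmt_decl("DP", "1", "Integer", "Read depth"),
                fmt_decl("AD", "R", "Integer", "Allelic depths")),
    freebayes = c(fmt_decl("DP", "1", "Integer", "Read depth"),
                  fmt_decl("RO", "1", "Integer", "Reference observations"),
                  fmt_decl("AO", "A", "Integer", "Alternate observations")),
    c(fmt_decl("AD", "R", "Integer", "Allelic depths"),
      fmt_decl("DP", "1", "Integer", "Read depth"))
  ))
  h <- c(h, '##FILTER=<ID=PASS,Description="All filters passed">')
  h <- c(h, paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                  "INFO", "FORMAT", config$sample_id, sep = "\t"))

  n <- nrow(sites)
  if (n > 0) {
    ref_d <- sites$depth - sites$alt
    fmt_and_val <- switch(config$dialect,
      varscan2 = list(fmt = "GT:DP:RD:AD:FREQ",
                      val = sprintf("%s:%d:%d:%d:%.2f%%", sites$gt,
                                    sites$depth, ref_d, sites$alt, sites$af)),
      strelka = list(fmt = "GT:GQX:DP:AD",
                     val = sprintf("%s:99:%d:%d,%d", sites$gt, sites$depth,
                                   ref_d, sites$alt)),
      freebayes = list(fmt = "GT:DP:RO:AO",
                       val = sprintf("%s:%d:%d:%d", sites$gt, sites$depth,
                                     ref_d, sites$alt)),
      list(fmt = "GT:AD:DP",
           val = sprintf("%s:%d,%d:%d", sites$gt, ref_d, sites$alt,
                         sites$depth))
    )
    body <- paste(sites$chrom, sites$pos, ".", sites$ref, sites$alt_base,
                  "100", "PASS", ".", fmt_and_val$fmt, fmt_and_val$val,
                  sep = "\t")
  } else body <- character(0)
  writeLines(c(h, body), path)
  invisible(path)
}

#' Recovery metrics of a screening run against the planted truth
#'
#' Joins verdicts to the planted truth table by `call_id` and reports, per
#' planted class, the fraction of calls flagged as false positives, plus
#' overall metrics: the fraction of planted false CNVs flagged (the
#' screening recall on false positives), the fraction of planted true CNVs
#' wrongly flagged, and the callset F1 before and after removing the flagged
#' calls (planted true CNVs are the positives; before filtering the callset
#' reports everything, so recall is 1 and precision is the planted
#' true-call fraction).
#'
#' @param verdicts `cnv_verdicts` from [filter_cnvs()].
#' @param truth Truth table from [simulate_sample()] (columns `call_id`,
#'   `class`, `expected`).
#' @return List with `per_class` (data frame: class, n, n_flagged,
#'   flagged_rate), `false_flag_recall`, `true_flag_rate`, `f1_before`,
#'   `f1_after`.
#' @export
evaluate_recovery <- function(verdicts, truth) {
  if (!setequal(verdicts$call_id, truth$call_id) ||
      nrow(verdicts) != nrow(truth)) {
    stop("verdict and truth call_ids do not align")
  }
  m <- merge(as.data.frame(verdicts)[, c("call_id", "decision")], truth,
             by = "call_id")
  flagged <- m$decision == "filter"
  is_false <- grepl("^false", m$class)

  per_class <- do.call(rbind, lapply(split(m, m$class), function(g) {
    data.frame(class = g$class[1], n = nrow(g),
               n_flagged = sum(g$decision == "filter"),
               flagged_rate = mean(g$decision == "filter"),
               stringsAsFactors = FALSE)
  }))
  rownames(per_class) <- NULL

  f1 <- function(tp, fp, fn) {
    if (2 * tp + fp + fn == 0) return(NA_real_)
    2 * tp / (2 * tp + fp + fn)
  }
  n_true <- sum(!is_false); n_false <- sum(is_false)
  f1_before <- f1(n_true, n_false, 0)
  tp_after <- sum(!is_false & !flagged)
  fp_after <- sum(is_false & !flagged)
  fn_after <- sum(!is_false & flagged)
  list(per_class = per_class,
       false_flag_recall = if (n_false) mean(flagged[is_false]) else NA_real_,
       true_flag_rate = if (n_true) mean(flagged[!is_false]) else NA_real_,
       f1_before = f1_before,
       f1_after = f1(tp_after, fp_after, fn_after))
}
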