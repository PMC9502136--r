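test_that("invalid simulation configs are refused", {
  expect_error(sim_config(n_true_del = -1), "non-negative")
  expect_error(sim_config(depth_mean = 0), "positive")
  expect_error(sim_config(snv_density = 0), "positive")
  expect_error(sim_config(cnv_length_range = c(5000, 1000)), "increasing")
  # too many CNVs for the genome -> placement impossible
  expect_error(sim_config(chrom_lengths = c(chr1 = 1e5),
                          n_true_del = 10, n_false_del = 10,
                          n_true_dup = 10, n_false_dup = 10),
               "cannot place")
  expect_error(sim_config(dialect = "nope"), "dialect")
})

test_that("a fixed seed gives byte-identical fixture files", {
  cfg <- sim_config(n_true_del = 2, n_false_del = 2, n_true_dup = 2,
                    n_false_dup = 2, seed = 5)
  d1 <- file.path(tempdir(), "det1"); d2 <- file.path(tempdir(), "det2")
  o1 <- simulate_sample(cfg, d1)
  o2 <- simulate_sample(cfg, d2)
  for (f in c("cnv_file", "vcf_file", "truth_file")) {
    expect_identical(readLines(o1[[f]]), readLines(o2[[f]]))
  }
  o3 <- simulate_sample(sim_config(n_true_del = 2, n_false_del = 2,
                                   n_true_dup = 2, n_false_dup = 2, seed = 6),
                        file.path(tempdir(), "det3"))
  expect_false(identical(readLines(o1$vcf_file), readLines(o3$vcf_file)))
})

test_that("site placement follows the configured density and truth labels align", {
  out <- simulate_sample(sim_config(n_true_del = 0, n_false_del = 1,
                                    n_true_dup = 0, n_false_dup = 0,
                                    cnv_length_range = c(10e3, 10e3),
                                    snv_density = 1, seed = 2),
                         file.path(tempdir(), "dens"))
  cnv <- out$cnvs
  inside <- out$sites[out$sites$pos >= cnv$start & out$sites$pos <= cnv$end, ]
  # 1 site per kb over 10 kb; a site is only lost if its alt count draws 0
  expect_gte(nrow(inside), 8)
  expect_lte(nrow(inside), 10)
  expect_true(all(inside$p == 0.5))
  expect_equal(out$truth$class, "false_del")
  expect_equal(out$truth$expected, "filter")
  expect_equal(nrow(out$truth), nrow(out$cnvs))
})

test_that("binomial read counts center on the configured allele fraction", {
  # ~10,000 background het sites at p = 1/2
  out <- simulate_sample(sim_config(n_true_del = 0, n_false_del = 0,
                                    n_true_dup = 0, n_false_dup = 0,
                                    chrom_lengths = c(chr1 = 1e7),
                                    depth_mean = 100, seed = 3),
                         file.path(tempdir(), "binom"))
  frac <- out$sites$alt / out$sites$depth
  n <- length(frac)
  se <- sqrt(0.25 / 100) / sqrt(n)   # binomial sd at p=1/2, depth 100
  expect_gt(n, 9000)
  expect_lt(abs(mean(frac) - 0.5), 3 * se)
})

test_that("true deletions carry no het-labeled SNVs at high depth", {
  out <- simulate_sample(sim_config(n_true_del = 10, n_false_del = 0,
                                    n_true_dup = 0, n_false_dup = 0,
                                    depth_mean = 100, seed = 4),
                         file.path(tempdir(), "loh"))
  snvs <- load_snvs(out$vcf_file)
  cnvs <- load_cnv_calls(out$cnv_file)
  for (i in seq_len(nrow(cnvs))) {
    ov <- overlapping_snvs(cnvs[i, ], snvs)
    expect_equal(sum(ov$genotype_class == "het"), 0)
  }
  # hence the deletion rule can never flag them
  v <- filter_cnvs(cnvs, snvs)
  expect_true(all(v$decision == "keep"))
})

test_that("every emitted dialect reloads with identical counts and frequencies", {
  for (d in vcf_dialects()) {
    out <- simulate_sample(sim_config(n_true_del = 1, n_false_del = 1,
                                      n_true_dup = 1, n_false_dup = 1,
                                      chrom_lengths = c(chr1 = 1e6),
                                      dialect = d, seed = 8),
                           file.path(tempdir(), paste0("dia_", d)))
    snvs <- load_snvs(out$vcf_file)
    r <- load_report(snvs)
    expect_equal(r$dialect, d)
    expect_equal(nrow(snvs), nrow(out$sites), info = d)
    expect_equal(snvs$chrom, out$sites$chrom, info = d)
    expect_equal(snvs$pos, out$sites$pos, info = d)
    expect_equal(snvs$alt_depth, out$sites$alt, info = d)
    expect_equal(snvs$total_depth, out$sites$depth, info = d)
    # FREQ strings are rounded by the caller; everything else is exact
    expect_lt(max(abs(snvs$allele_frequency - out$sites$af)), 0.1)
    expect_equal(snvs$genotype_class, ifelse(out$sites$gt == "0/1", "het", "hom"),
                 info = d)
  }
})

test_that("recovery metrics equal hand-counted confusion arithmetic", {
  set.seed(31)
  truth <- data.frame(call_id = sprintf("cnv_%04d", 1:20),
                      class = sample(c("true_del", "false_del", "true_dup",
                                       "false_dup"), 20, replace = TRUE),
                      stringsAsFactors = FALSE)
  truth$expected <- ifelse(grepl("^false", truth$class), "filter", "keep")
  verdicts <- data.frame(call_id = truth$call_id,
                         decision = sample(c("keep", "filter"), 20,
                                           replace = TRUE),
                         stringsAsFactors = FALSE)
  m <- evaluate_recovery(verdicts, truth)

  flagged <- verdicts$decision == "filter"
  is_false <- grepl("^false", truth$class)
  expect_equal(m$false_flag_recall, sum(flagged & is_false) / sum(is_false))
  expect_equal(m$true_flag_rate, sum(flagged & !is_false) / sum(!is_false))
  tp <- sum(!is_false & !flagged); fp <- sum(is_false & !flagged)
  fn <- sum(!is_false & flagged)
  expect_equal(m$f1_after, 2 * tp / (2 * tp + fp + fn))
  expect_equal(m$f1_before, 2 * sum(!is_false) /
                 (2 * sum(!is_false) + sum(is_false)))
  expect_equal(sum(m$per_class$n), 20)
  expect_equal(sum(m$per_class$n_flagged), sum(flagged))

  # perfect and null filters
  perfect <- data.frame(call_id = truth$call_id, decision = truth$expected)
  mp <- evaluate_recovery(perfect, truth)
  expect_equal(mp$false_flag_recall, 1)
  expect_equal(mp$true_flag_rate, 0)
  null <- data.frame(call_id = truth$call_id, decision = "keep")
  expect_equal(evaluate_recovery(null, truth)$false_flag_recall, 0)
  # misaligned ids are an error
  bad <- verdicts; bad$call_id[1] <- "other"
  expect_error(evaluate_recovery(bad, truth), "align")
})
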