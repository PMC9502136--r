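test_that("overlap uses closed 1-based intervals and matches a brute-force scan", {
  cnv <- make_cnv(1000, 2000, "deletion")
  snvs <- make_snvs(c(999, 1000, 1500, 2000, 2001), 50, "het")
  ov <- overlapping_snvs(cnv, snvs)
  expect_equal(ov$pos, c(1000, 1500, 2000))

  # wrong chromosome or sample never overlaps
  other <- make_snvs(1500, 50, "het", chrom = "chr2")
  expect_equal(nrow(overlapping_snvs(cnv, other)), 0)
  other_s <- make_snvs(1500, 50, "het", sample_id = "s2")
  expect_equal(nrow(overlapping_snvs(cnv, other_s)), 0)

  # property: random SNVs vs exhaustive membership scan
  set.seed(3)
  for (i in 1:5) {
    snvs <- make_snvs(sample.int(5000, 100), runif(100, 0, 100), "het",
                      chrom = sample(c("chr1", "chr2"), 100, replace = TRUE))
    cnv <- make_cnv(800, 3200, "deletion", chrom = "chr1")
    expected <- snvs[snvs$chrom == "chr1" & snvs$pos >= 800 & snvs$pos <= 3200 &
                       snvs$sample_id == "sample1", ]
    got <- overlapping_snvs(cnv, snvs)
    expect_equal(got[order(got$pos), "pos"], expected[order(expected$pos), "pos"])
  }
})

test_that("scoring hits its anchors exactly and its segment midpoints", {
  p <- scoring_params()
  expect_identical(score_dup_snv(50, p), 1)
  expect_identical(score_dup_snv(100 / 3, p), -1)
  expect_identical(score_dup_snv(200 / 3, p), -1)
  expect_identical(score_dup_snv(10, p), 0)
  expect_identical(score_dup_snv(c(0, 28, 72, 100), p), c(0, 0, 0, 0))
  # interior zero crossings at the dup-mean/het-mean midpoints
  expect_equal(score_dup_snv((100 / 3 + 50) / 2, p), 0, tolerance = 1e-12)
  # raised-cosine midpoint of the ascending segment (125/3 -> 50) is 1/2
  mid <- (125 / 3 + 50) / 2
  expect_equal(score_dup_snv(mid, p), 0.5, tolerance = 1e-9)
  expect_error(score_dup_snv(101, p), "0, 100")
  expect_error(score_dup_snv(-0.5, p), "0, 100")
})

test_that("scoring respects shifted anchors", {
  p <- scoring_params(expected_dup_mean_high = 70, informative_high = 80)
  expect_identical(score_dup_snv(70, p), -1)
  expect_identical(score_dup_snv(80, p), 0)
  expect_identical(score_dup_snv(50, p), 1)
})

test_that("deletion rule reproduces threshold arithmetic over all small cases", {
  p <- scoring_params()
  for (n in 1:10) {
    for (n_het in 0:n) {
      snvs <- make_snvs(seq(100, by = 10, length.out = n), 50,
                        c(rep("het", n_het), rep("hom", n - n_het)))
      v <- evaluate_deletion(make_cnv(1, 10000, "deletion"), snvs, p)
      expected <- if (100 * n_het / n >= 30) "filter" else "keep"
      expect_equal(v$decision, expected,
                   info = sprintf("n=%d n_het=%d", n, n_het))
      expect_equal(v$n_het, n_het)
      expect_equal(v$het_fraction_pct, 100 * n_het / n)
    }
  }
  # boundary case from the default threshold: 3/10 het is flagged
  snvs <- make_snvs(1:10 * 100, 50, c(rep("het", 3), rep("hom", 7)))
  expect_equal(evaluate_deletion(make_cnv(1, 10000, "deletion"), snvs, p)$decision,
               "filter")
})

test_that("deletion rule excludes unknown genotypes and handles no evidence", {
  p <- scoring_params()
  cnv <- make_cnv(1, 10000, "deletion")
  # unknowns out of the denominator: 1 het / (1 het + 2 hom) = 33% -> filter
  snvs <- make_snvs(c(100, 200, 300, 400, 500), 50,
                    c("het", "hom", "hom", "unknown", "unknown"))
  v <- evaluate_deletion(cnv, snvs, p)
  expect_equal(v$decision, "filter")
  expect_equal(v$het_fraction_pct, 100 / 3, tolerance = 1e-9)
  # all unknown -> keep, no evidence
  v2 <- evaluate_deletion(cnv, make_snvs(100, 10, "unknown"), p)
  expect_equal(v2$decision, "keep")
  expect_equal(v2$rule, "no_evidence")
  # zero overlapping SNVs -> keep, no evidence
  v3 <- evaluate_deletion(cnv, make_snvs(numeric(0), numeric(0), character(0)), p)
  expect_equal(v3$decision, "keep")
  expect_equal(v3$rule, "no_evidence")
  expect_error(evaluate_deletion(make_cnv(1, 10, "duplication"), snvs, p),
               "duplication")
})

test_that("duplication rule sums het scores with a strict threshold", {
  p <- scoring_params()
  cnv <- make_cnv(1, 10000, "duplication")
  # three hets at the het anchor: +3 > 0.5 -> filter
  v <- evaluate_duplication(cnv, make_snvs(c(100, 200, 300), 50, "het"), p)
  expect_equal(v$decision, "filter")
  expect_equal(v$dup_total_score, 3)
  expect_equal(unlist(v$snv_scores), c(1, 1, 1))
  # hets at both duplication anchors: -2 -> keep
  v2 <- evaluate_duplication(cnv, make_snvs(c(100, 200), c(100 / 3, 200 / 3),
                                            "het"), p)
  expect_equal(v2$decision, "keep")
  expect_equal(v2$dup_total_score, -2)
  # mixed anchors: +1 - 2 = -1 -> keep
  v3 <- evaluate_duplication(cnv, make_snvs(1:3 * 100, c(50, 100 / 3, 100 / 3),
                                            "het"), p)
  expect_equal(v3$dup_total_score, -1)
  expect_equal(v3$decision, "keep")
  # hom SNVs contribute nothing
  v4 <- evaluate_duplication(cnv, make_snvs(1:4 * 100, c(50, 50, 100, 100),
                                            c("het", "het", "hom", "hom")), p)
  expect_equal(v4$dup_total_score, 2)
  expect_equal(v4$n_het, 2)
  # strictness: total exactly at the threshold keeps the call
  p2 <- scoring_params(dup_score_threshold = 1)
  v5 <- evaluate_duplication(cnv, make_snvs(100, 50, "het"), p2)
  expect_equal(v5$dup_total_score, 1)
  expect_equal(v5$decision, "keep")
  # no het evidence -> keep
  v6 <- evaluate_duplication(cnv, make_snvs(100, 100, "hom"), p)
  expect_equal(v6$rule, "no_evidence")
  expect_error(evaluate_duplication(make_cnv(1, 10, "deletion"),
                                    make_snvs(5, 50, "het"), p), "deletion")
})

test_that("appending anchor-valued SNVs moves duplication evidence monotonically", {
  p <- scoring_params()
  cnv <- make_cnv(1, 100000, "duplication")
  set.seed(9)
  for (i in 1:10) {
    n <- sample(1:12, 1)
    snvs <- make_snvs(seq_len(n) * 100, runif(n, 0, 100), "het")
    base <- evaluate_duplication(cnv, snvs, p)$decision
    plus_ht <- rbind(snvs, make_snvs(99000, 50, "het"))
    plus_dup <- rbind(snvs, make_snvs(99000, 100 / 3, "het"))
    d_ht <- evaluate_duplication(cnv, plus_ht, p)$decision
    d_dup <- evaluate_duplication(cnv, plus_dup, p)$decision
    if (base == "filter") expect_equal(d_ht, "filter")   # +1 never un-flags
    if (base == "keep") expect_equal(d_dup, "keep")      # -1 never flags
  }
})

test_that("deletion verdicts ignore SNV order and hom allele frequencies", {
  p <- scoring_params()
  cnv <- make_cnv(1, 10000, "deletion")
  set.seed(21)
  for (i in 1:10) {
    n <- sample(2:12, 1)
    gclass <- sample(c("het", "hom"), n, replace = TRUE)
    snvs <- make_snvs(seq_len(n) * 100, runif(n, 20, 100), gclass)
    v1 <- evaluate_deletion(cnv, snvs, p)
    shuffled <- snvs[sample.int(n), ]
    v2 <- evaluate_deletion(cnv, shuffled, p)
    hom_moved <- snvs
    hom_moved$allele_frequency[hom_moved$genotype_class == "hom"] <- 99
    v3 <- evaluate_deletion(cnv, hom_moved, p)
    expect_equal(v1$decision, v2$decision)
    expect_equal(v1$decision, v3$decision)
    expect_equal(v1$het_fraction_pct, v2$het_fraction_pct)
  }
})

test_that("filter_cnvs dispatches by type, preserves order, and is deterministic", {
  p <- scoring_params()
  cnvs <- rbind(make_cnv(1000, 2000, "deletion", call_id = "a"),
                make_cnv(3000, 4000, "duplication", call_id = "b"),
                make_cnv(5000, 6000, "deletion", call_id = "c"),
                make_cnv(7000, 8000, "duplication", call_id = "d"))
  snvs <- rbind(make_snvs(c(1100, 1200), 50, "het"),
                make_snvs(c(3100, 3200), 50, "het"),
                make_snvs(5100, 100, "hom"),
                make_snvs(7100, 100 / 3, "het"))
  v <- filter_cnvs(cnvs, snvs, p)
  expect_equal(v$call_id, c("a", "b", "c", "d"))
  expect_equal(v$decision, c("filter", "filter", "keep", "keep"))
  expect_equal(v$rule, c("deletion_het", "duplication_score",
                         "deletion_het", "duplication_score"))
  v2 <- filter_cnvs(cnvs, snvs, p)
  expect_identical(as.data.frame(v), as.data.frame(v2))
  # empty callset -> empty verdicts with the full schema
  v0 <- filter_cnvs(cnvs[FALSE, ], snvs, p)
  expect_equal(nrow(v0), 0)
  expect_true(all(c("decision", "rule", "dup_total_score") %in% names(v0)))
})
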