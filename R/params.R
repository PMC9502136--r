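#' Scoring-model parameters
#'
#' Builds the full set of constants used by the two screening rules and by
#' SNV loading. All allele-frequency quantities are percentages in
#' \[0, 100\].
#'
#' In a diploid region a heterozygous SNV has an expected allele frequency
#' (AF) of 50%. Inside a real single-copy duplication the same SNV sits on
#' either the duplicated haplotype (expected AF 2/3) or the non-duplicated
#' one (expected AF 1/3). The duplication scoring model is anchored at these
#' three expectations: +1 at `expected_ht_mean` (evidence the duplication is
#' a false positive), -1 at each duplication mean (evidence it is real), and
#' 0 at and beyond the informative bounds, where the AF carries no usable
#' signal. The defaults place the duplication means at exact thirds
#' (100/3, 200/3) so the default model is exactly symmetric about 50.
#'
#' @param expected_ht_mean Expected AF (percent) of a heterozygous SNV in a
#'   diploid region. Default 50.
#' @param expected_dup_mean_low Expected AF of a het SNV on the
#'   non-duplicated haplotype of a true duplication. Default 100/3.
#' @param expected_dup_mean_high Expected AF of a het SNV on the duplicated
#'   haplotype. Default 200/3.
#' @param informative_low,informative_high Bounds (percent) of the scoring
#'   support; outside them the score is 0. Defaults 28 and 72.
#' @param del_het_threshold_pct Minimum percentage of heterozygous SNVs among
#'   the classifiable SNVs overlapping a deletion for the deletion to be
#'   flagged as a false positive. Default 30.
#' @param dup_score_threshold Value the summed per-SNV scores must strictly
#'   exceed for a duplication to be flagged as a false positive. Default 0.5.
#' @param het_window,hom_window AF windows (percent, \[lo, hi)) used to
#'   classify genotype when no GT field is available; `hom_window` is closed
#'   at 100. Defaults \[20, 80) and \[80, 100\].
#' @param depth_floor Minimum total read depth for an SNV to be used.
#'   Default 10.
#'
#' @return An object of class `scoring_params` (a validated named list).
#' @examples
#' p <- scoring_params()
#' p$expected_dup_mean_low   # 100/3
#' scoring_params(dup_score_threshold = 1.5)$dup_score_threshold
#' @export
scoring_params <- function(expected_ht_mean = 50,
                           expected_dup_mean_low = 100 / 3,
                           expected_dup_mean_high = 200 / 3,
                           informative_low = 28,
                           informative_high = 72,
                           del_het_threshold_pct = 30,
                           dup_score_threshold = 0.5,
                           het_window = c(20, 80),
                           hom_window = c(80, 100),
                           depth_floor = 10) {
  p <- list(
    expected_ht_mean = expected_ht_mean,
    expected_dup_mean_low = expected_dup_mean_low,
    expected_dup_mean_high = expected_dup_mean_high,
    informative_low = informative_low,
    informative_high = informative_high,
    del_het_threshold_pct = del_het_threshold_pct,
    dup_score_threshold = dup_score_threshold,
    het_window = het_window,
    hom_window = hom_window,
    depth_floor = depth_floor
  )
  class(p) <- "scoring_params"
  validate_scoring_params(p)
  p
}

#' Validate scoring parameters
#'
#' Checks the ordering invariant of the allele-frequency anchors
#' (`informative_low < expected_dup_mean_low < expected_ht_mean <
#' expected_dup_mean_high < informative_high`), the genotype windows and the
#' remaining constants. Called by [scoring_params()]; exported so that
#' configurations assembled elsewhere (e.g. parsed from a config file) can be
#' checked before use.
#'
#' @param p A `scoring_params` object.
#' @return `p`, invisibly, if valid; otherwise an error naming the violated
#'   invariant.
#' @export
validate_scoring_params <- function(p) {
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  for (f in c("expected_ht_mean", "expected_dup_mean_low",
              "expected_dup_mean_high", "informative_low", "informative_high",
              "del_het_threshold_pct", "dup_score_threshold", "depth_floor")) {
    if (!num1(p[[f]])) stop("scoring_params$", f, " must be a single finite number")
  }
  anchors <- c(p$informative_low, p$expected_dup_mean_low, p$expected_ht_mean,
               p$expected_dup_mean_high, p$informative_high)
  if (any(diff(anchors) <= 0)) {
    stop("invalid anchor ordering: need informative_low < expected_dup_mean_low < ",
         "expected_ht_mean < expected_dup_mean_high < informative_high, got (",
         paste(signif(anchors, 6), collapse = ", "), ")")
  }
  if (anchors[1] < 0 || anchors[5] > 100) {
    stop("informative bounds must lie within [0, 100]")
  }
  if (p$del_het_threshold_pct < 0 || p$del_het_threshold_pct > 100) {
    stop("del_het_threshold_pct must lie in [0, 100]")
  }
  for (w in c("het_window", "hom_window")) {
    v <- p[[w]]
    if (!is.numeric(v) || length(v) != 2L || v[1] >= v[2] || v[1] < 0 || v[2] > 100) {
      stop("scoring_params$", w, " must be an increasing pair within [0, 100]")
    }
  }
  if (p$depth_floor < 0) stop("depth_floor must be non-negative")
  invisible(p)
}

# Anchor positions (x) and values (s) of the duplication scoring curve.
# Interior zero crossings sit at the midpoints between the het mean and each
# duplication mean.
score_anchors <- function(params) {
  x <- c(params$informative_low,
         params$expected_dup_mean_low,
         (params$expected_dup_mean_low + params$expected_ht_mean) / 2,
         params$expected_ht_mean,
         (params$expected_ht_mean + params$expected_dup_mean_high) / 2,
         params$expected_dup_mean_high,
         params$informative_high)
  list(x = x, s = c(0, -1, 0, 1, 0, -1, 0))
}

#' @export
print.scoring_params <- function(x, ...) {
  cat("Scoring parameters (allele frequencies in percent)\n")
  cat(sprintf("  duplication AF anchors: %.4g / %.4g / %.4g (score -1 / +1 / -1)\n",
              x$expected_dup_mean_low, x$expected_ht_mean, x$expected_dup_mean_high))
  cat(sprintf("  informative AF range  : [%.4g, %.4g]\n",
              x$informative_low, x$informative_high))
  cat(sprintf("  deletion het threshold: %.4g%%   duplication score threshold: %.4g\n",
              x$del_het_threshold_pct, x$dup_score_threshold))
  cat(sprintf("  het window [%g, %g)   hom window [%g, %g]   depth floor %g\n",
              x$het_window[1], x$het_window[2], x$hom_window[1], x$hom_window[2],
              x$depth_floor))
  invisible(x)
}
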