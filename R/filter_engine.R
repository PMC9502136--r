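#' SNVs overlapping one CNV call
#'
#' Closed-interval membership on 1-based coordinates: an SNV overlaps when it
#' shares the CNV's chromosome and sample and `start <= pos <= end`. The
#' interval arithmetic is delegated to `GenomicRanges::findOverlaps()`.
#'
#' @param cnv One CNV call: a one-row data frame (or list) with `chrom`,
#'   `start`, `end`, `sample_id`.
#' @param snvs SNV data frame as returned by [load_snvs()].
#' @return The overlapping subset of `snvs` (possibly empty).
#' @export
overlapping_snvs <- function(cnv, snvs) {
  cnv <- as.list(cnv)
  if (nrow(snvs) == 0L) return(snvs)
  same <- snvs$chrom == cnv$chrom & snvs$sample_id == cnv$sample_id
  if (!any(same)) return(snvs[FALSE, , drop = FALSE])
  cand <- snvs[same, , drop = FALSE]
  hits <- GenomicRanges::findOverlaps(
    GenomicRanges::GRanges(cand$chrom,
                           IRanges::IRanges(cand$pos, cand$pos)),
    GenomicRanges::GRanges(cnv$chrom,
                           IRanges::IRanges(cnv$start, cnv$end))
  )
  cand[S4Vectors::queryHits(hits), , drop = FALSE]
}

#' Score one allele frequency under the duplication model
#'
#' Maps an allele frequency (percent) to a false-positive-evidence score in
#' \[-1, 1\]: +1 at the diploid het expectation (`expected_ht_mean`, AF
#' consistent with no duplication), -1 at each true-duplication expectation
#' (`expected_dup_mean_low/high`), and 0 at and beyond the informative
#' bounds. Between consecutive anchors `(a, s_a)` and `(b, s_b)` the score
#' follows the raised-cosine interpolant
#' `s_a + (s_b - s_a) * (1 - cos(pi * (f - a)/(b - a))) / 2`, which is
#' continuous everywhere, hits every anchor exactly, and is symmetric about
#' 50 under the default anchors. Interior zero crossings sit at the
#' midpoints between the het mean and each duplication mean.
#'
#' @param allele_frequency Numeric vector of allele frequencies in percent;
#'   values outside \[0, 100\] are an error.
#' @param params [scoring_params()].
#' @return Numeric vector of scores in \[-1, 1\].
#' @examples
#' p <- scoring_params()
#' score_dup_snv(c(50, 100/3, 200/3, 10), p)   # +1, -1, -1, 0
#' @export
score_dup_snv <- function(allele_frequency, params = scoring_params()) {
  f <- as.numeric(allele_frequency)
  if (anyNA(f) || any(f < 0 | f > 100)) {
    stop("allele_frequency must lie in [0, 100]")
  }
  an <- score_anchors(params)
  out <- numeric(length(f))
  inside <- f > an$x[1] & f < an$x[length(an$x)]
  if (any(inside)) {
    fi <- f[inside]
    seg <- findInterval(fi, an$x, rightmost.closed = TRUE)
    a <- an$x[seg]; b <- an$x[seg + 1L]
    sa <- an$s[seg]; sb <- an$s[seg + 1L]
    out[inside] <- sa + (sb - sa) * (1 - cos(pi * (fi - a) / (b - a))) / 2
  }
  out
}

# One-row verdict skeleton shared by the evaluators.
new_verdict <- function(cnv, decision, rule, n_snvs, n_het, het_fraction_pct,
                        snv_scores, dup_total_score) {
  cnv <- as.list(cnv)
  df <- data.frame(
    call_id = cnv$call_id %||% NA_character_,
    chrom = cnv$chrom, start = cnv$start, end = cnv$end,
    cnv_type = cnv$cnv_type, sample_id = cnv$sample_id,
    source_tool = cnv$source_tool %||% NA_character_,
    decision = decision, rule = rule,
    n_snvs = n_snvs, n_het = n_het,
    het_fraction_pct = het_fraction_pct,
    dup_total_score = dup_total_score,
    stringsAsFactors = FALSE
  )
  df$snv_scores <- list(snv_scores)
  df
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Apply the heterozygosity rule to one deletion call
#'
#' A heterozygous deletion is a loss-of-heterozygosity region: only one
#' haplotype remains, so no heterozygous SNV can truly lie inside it. To
#' tolerate SNV-calling errors the deletion is flagged as a false positive
#' only when at least `del_het_threshold_pct` percent (default 30) of the
#' classifiable overlapping SNVs are heterozygous. SNVs of genotype class
#' `unknown` are excluded from the denominator — an ambiguous site is
#' evidence for neither hypothesis; the exclusion is auditable through
#' `n_snvs` versus `n_het`. With no classifiable SNV the call is kept with
#' rule `no_evidence`.
#'
#' @param cnv One deletion call (one-row data frame or list).
#' @param snvs Overlapping SNVs (already restricted; see
#'   [overlapping_snvs()]).
#' @param params [scoring_params()].
#' @return One-row verdict data frame.
#' @export
evaluate_deletion <- function(cnv, snvs, params = scoring_params()) {
  cnv <- as.list(cnv)
  if (!identical(cnv$cnv_type, "deletion")) {
    stop("evaluate_deletion() called on a '", cnv$cnv_type, "' call")
  }
  n_all <- nrow(snvs)
  known <- snvs$genotype_class[snvs$genotype_class != "unknown"]
  n_known <- length(known)
  n_het <- sum(known == "het")
  if (n_known == 0L) {
    return(new_verdict(cnv, "keep", "no_evidence", n_all, 0L, NA_real_,
                       numeric(0), NA_real_))
  }
  het_pct <- 100 * n_het / n_known
  decision <- if (het_pct >= params$del_het_threshold_pct) "filter" else "keep"
  new_verdict(cnv, decision, "deletion_het", n_all, n_het, het_pct,
              numeric(0), NA_real_)
}

#' Apply the fuzzy scoring rule to one duplication call
#'
#' Each heterozygous overlapping SNV is scored with [score_dup_snv()]; the
#' duplication is flagged as a false positive when the sum of the scores is
#' strictly greater than `dup_score_threshold` (default 0.5). Homozygous and
#' unknown-genotype SNVs contribute nothing: the model's expectations
#' (1/3, 1/2, 2/3) are defined for heterozygous sites only. With no het SNV
#' the call is kept with rule `no_evidence`.
#'
#' @inheritParams evaluate_deletion
#' @return One-row verdict data frame; `snv_scores` holds the per-het-SNV
#'   scores and `dup_total_score` their sum.
#' @export
evaluate_duplication <- function(cnv, snvs, params = scoring_params()) {
  cnv <- as.list(cnv)
  if (!identical(cnv$cnv_type, "duplication")) {
    stop("evaluate_duplication() called on a '", cnv$cnv_type, "' call")
  }
  n_all <- nrow(snvs)
  het <- snvs[snvs$genotype_class == "het", , drop = FALSE]
  n_het <- nrow(het)
  if (n_het == 0L) {
    return(new_verdict(cnv, "keep", "no_evidence", n_all, 0L, NA_real_,
                       numeric(0), 0))
  }
  scores <- score_dup_snv(het$allele_frequency, params)
  total <- sum(scores)
  decision <- if (total > params$dup_score_threshold) "filter" else "keep"
  het_pct <- if (n_all > 0) 100 * n_het / n_all else NA_real_
  new_verdict(cnv, decision, "duplication_score", n_all, n_het, het_pct,
              scores, total)
}

#' Screen a CNV callset against an SNV callset
#'
#' For every CNV call, gathers the overlapping quality-passing SNVs of the
#' same sample and applies the rule matching the call type: the
#' loss-of-heterozygosity rule for deletions ([evaluate_deletion()]) or the
#' fuzzy scoring rule for duplications ([evaluate_duplication()]). Output
#' order equals input order and the result is deterministic for fixed
#' inputs and parameters.
#'
#' @param cnvs `cnv_calls` data frame from [load_cnv_calls()] (or any data
#'   frame with `call_id`, `chrom`, `start`, `end`, `cnv_type`,
#'   `sample_id`).
#' @param snvs `snv_set` from [load_snvs()] (or equivalent data frame).
#' @param params [scoring_params()].
#' @return Data frame of class `cnv_verdicts`, one row per CNV: the call
#'   fields plus `decision` (`keep`/`filter`), `rule` (`deletion_het`,
#'   `duplication_score` or `no_evidence`), `n_snvs`, `n_het`,
#'   `het_fraction_pct`, `dup_total_score` and the list column `snv_scores`.
#' @export
filter_cnvs <- function(cnvs, snvs, params = scoring_params()) {
  validate_scoring_params(params)
  need <- c("chrom", "start", "end", "cnv_type", "sample_id")
  miss <- setdiff(need, names(cnvs))
  if (length(miss)) stop("cnvs is missing column(s): ", paste(miss, collapse = ", "))
  need_snv <- c("chrom", "pos", "allele_frequency", "genotype_class", "sample_id")
  miss <- setdiff(need_snv, names(snvs))
  if (length(miss)) stop("snvs is missing column(s): ", paste(miss, collapse = ", "))

  if (nrow(cnvs) == 0L) {
    empty <- data.frame(call_id = character(), chrom = character(),
                        start = integer(), end = integer(),
                        cnv_type = character(), sample_id = character(),
                        source_tool = character(), decision = character(),
                        rule = character(), n_snvs = integer(),
                        n_het = integer(), het_fraction_pct = numeric(),
                        dup_total_score = numeric(), stringsAsFactors = FALSE)
    empty$snv_scores <- list()
    return(structure(empty, class = c("cnv_verdicts", "data.frame")))
  }
  rows <- lapply(seq_len(nrow(cnvs)), function(i) {
    cnv <- cnvs[i, , drop = FALSE]
    ov <- overlapping_snvs(cnv, snvs)
    if (cnv$cnv_type == "deletion") {
      evaluate_deletion(cnv, ov, params)
    } else if (cnv$cnv_type == "duplication") {
      evaluate_duplication(cnv, ov, params)
    } else {
      stop("unknown cnv_type '", cnv$cnv_type, "' for call ", cnv$call_id)
    }
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  structure(out, class = c("cnv_verdicts", "data.frame"))
}
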