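# Shared device handling: open png (cairo) or svg by extension/format.
open_device <- function(path, format = NULL, width = 7, height = 4.5) {
  fmt <- format %||% tolower(tools::file_ext(path))
  if (!fmt %in% c("png", "svg")) {
    stop("unsupported image format '", fmt, "' (use png or svg)")
  }
  if (fmt == "png") {
    grDevices::png(path, width = width, height = height, units = "in",
                   res = 150, type = "cairo")
  } else {
    grDevices::svg(path, width = width, height = height)
  }
  fmt
}

#' Diagnostic plot of one CNV call and its SNV evidence
#'
#' Draws genomic position against allele frequency (percent, 0-100) for the
#' SNVs overlapping one CNV call: the CNV span as a shaded band, one marker
#' per SNV colored by genotype class, horizontal guide lines at the expected
#' allele frequencies of the scoring model, and the verdict in the title.
#' Plotting is a pure reader of results — it never alters a verdict.
#'
#' @param cnv One CNV call (one-row data frame or list).
#' @param snvs The SNVs overlapping it (may be empty; the span and guides
#'   are still drawn).
#' @param verdict The one-row verdict for this call (same `call_id`).
#' @param params [scoring_params()]; supplies the guide-line positions.
#' @param path Output image path; format from the extension unless `format`
#'   is given.
#' @param format `"png"` or `"svg"`, optional.
#' @return Invisibly, a layer manifest: list with `file`, `format`,
#'   `n_markers`, `guide_lines`, `decision` — so image content can be
#'   checked without pixel comparison.
#' @export
plot_cnv_region <- function(cnv, snvs, verdict, params = scoring_params(),
                            path, format = NULL) {
  cnv <- as.list(cnv)
  v <- as.list(verdict)
  if (!is.null(cnv$call_id) && !is.null(v$call_id) &&
      !identical(as.character(cnv$call_id), as.character(v$call_id))) {
    stop("verdict call_id (", v$call_id, ") does not match cnv (",
         cnv$call_id, ")")
  }
  guides <- c(params$expected_dup_mean_low, params$expected_ht_mean,
              params$expected_dup_mean_high)
  pad <- max(1, round((cnv$end - cnv$start + 1) * 0.15))
  xlim <- c(cnv$start - pad, cnv$end + pad)
  snvs <- as.data.frame(snvs)

  df <- if (nrow(snvs)) {
    data.frame(pos = snvs$pos, af = snvs$allele_frequency,
               genotype = factor(snvs$genotype_class,
                                 levels = c("het", "hom", "unknown")))
  } else {
    data.frame(pos = numeric(), af = numeric(),
               genotype = factor(character(),
                                 levels = c("het", "hom", "unknown")))
  }
  gg <- ggplot2::ggplot(df, ggplot2::aes(x = pos, y = af)) +
    ggplot2::annotate("rect", xmin = cnv$start, xmax = cnv$end,
                      ymin = -Inf, ymax = Inf, alpha = 0.15,
                      fill = if (cnv$cnv_type == "deletion") "firebrick" else "dodgerblue") +
    ggplot2::geom_hline(yintercept = guides, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(colour = genotype), size = 2) +
    ggplot2::coord_cartesian(xlim = xlim, ylim = c(0, 100)) +
    ggplot2::labs(
      title = sprintf("%s %s:%d-%d [%s] — %s",
                      cnv$cnv_type, cnv$chrom, cnv$start, cnv$end,
                      cnv$call_id %||% "", toupper(v$decision)),
      x = sprintf("position on %s", cnv$chrom),
      y = "allele frequency (%)", colour = "genotype") +
    ggplot2::theme_minimal()
  if (nrow(df)) {   # manual scale warns on empty data
    gg <- gg + ggplot2::scale_colour_manual(
      values = c(het = "#D55E00", hom = "#0072B2", unknown = "grey60"),
      drop = FALSE)
  }

  fmt <- open_device(path, format)
  on.exit(grDevices::dev.off(), add = TRUE)
  print(gg)

  invisible(list(file = path, format = fmt, n_markers = nrow(df),
                 guide_lines = guides, decision = v$decision))
}

#' Plot the duplication scoring model
#'
#' Draws the per-SNV duplication score as a function of allele frequency
#' over the full \[0, 100\] domain, with the expected-AF anchors marked. The
#' curve is sampled from [score_dup_snv()] itself, so this plot can never
#' drift from the scores the engine assigns.
#'
#' @param params [scoring_params()].
#' @param path Output image path.
#' @param format `"png"` or `"svg"`, optional (default from extension).
#' @param n Number of sample points across \[0, 100\] (default 1001).
#' @return Invisibly, a manifest: `file`, `format`, `n_points`, `anchors`
#'   (data frame of anchor AFs and scores) and the sampled `curve`.
#' @export
plot_scoring_model <- function(params = scoring_params(), path,
                               format = NULL, n = 1001) {
  validate_scoring_params(params)
  af <- seq(0, 100, length.out = n)
  curve <- data.frame(af = af, score = score_dup_snv(af, params))
  an <- score_anchors(params)
  anchors <- data.frame(af = an$x, score = an$s)

  gg <- ggplot2::ggplot(curve, ggplot2::aes(x = af, y = score)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70") +
    ggplot2::geom_line(colour = "#0072B2", linewidth = 0.9) +
    ggplot2::geom_point(data = anchors, colour = "#D55E00", size = 2) +
    ggplot2::scale_y_continuous(limits = c(-1.05, 1.05)) +
    ggplot2::labs(title = "Duplication scoring model",
                  subtitle = sprintf("+1 at %.4g%%, -1 at %.4g%% and %.4g%%, 0 outside [%.4g, %.4g]",
                                     params$expected_ht_mean,
                                     params$expected_dup_mean_low,
                                     params$expected_dup_mean_high,
                                     params$informative_low,
                                     params$informative_high),
                  x = "allele frequency (%)", y = "score") +
    ggplot2::theme_minimal()

  fmt <- open_device(path, format, width = 6, height = 4)
  on.exit(grDevices::dev.off(), add = TRUE)
  print(gg)

  invisible(list(file = path, format = fmt, n_points = n, anchors = anchors,
                 curve = curve))
}

#' Summarize a screening run
#'
#' Tallies a verdict collection: kept/filtered counts overall, by CNV type
#' and by decision rule, plus totals of the SNV evidence used. The result
#' serializes cleanly to JSON (see [write_summary()]).
#'
#' @param verdicts `cnv_verdicts` from [filter_cnvs()].
#' @return List of class `run_summary`.
#' @export
summarize_run <- function(verdicts) {
  v <- as.data.frame(verdicts)
  count_by <- function(x, levels) {
    t <- table(factor(x, levels = levels))
    as.list(stats::setNames(as.integer(t), names(t)))
  }
  by_type <- lapply(c(deletion = "deletion", duplication = "duplication"),
                    function(ty) {
                      g <- v[v$cnv_type == ty, , drop = FALSE]
                      count_by(g$decision, c("keep", "filter"))
                    })
  out <- list(
    n_calls = nrow(v),
    n_kept = sum(v$decision == "keep"),
    n_filtered = sum(v$decision == "filter"),
    by_type = by_type,
    by_rule = count_by(v$rule, c("deletion_het", "duplication_score",
                                 "no_evidence")),
    total_snvs = sum(v$n_snvs, na.rm = TRUE),
    total_het_snvs = sum(v$n_het, na.rm = TRUE)
  )
  class(out) <- "run_summary"
  out
}

#' Write a run summary as JSON
#'
#' @param summary A `run_summary` from [summarize_run()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_summary <- function(summary, path) {
  jsonlite::write_json(unclass(summary), path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @export
print.run_summary <- function(x, ...) {
  cat(sprintf("Screened %d CNV calls: %d kept, %d flagged as false positives\n",
              x$n_calls, x$n_kept, x$n_filtered))
  cat(sprintf("  deletions   : %d kept / %d flagged\n",
              x$by_type$deletion$keep, x$by_type$deletion$filter))
  cat(sprintf("  duplications: %d kept / %d flagged\n",
              x$by_type$duplication$keep, x$by_type$duplication$filter))
  cat(sprintf("  evidence: %d overlapping SNVs (%d het); %d calls had no usable evidence\n",
              x$total_snvs, x$total_het_snvs, x$by_rule$no_evidence))
  invisible(x)
}
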