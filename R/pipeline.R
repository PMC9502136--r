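utils::globalVariables(c("pos", "af", "genotype", "score"))

#' Run the whole screening pipeline on files
#'
#' Convenience driver tying the modules together: loads a CNV table and one
#' VCF per sample, screens every call, and writes `results.tsv`,
#' `summary.json` and (optionally) one diagnostic plot per CNV into
#' `out_dir`. This is also what the command-line wrapper shipped in
#' `inst/scripts/cnvscreen.R` calls.
#'
#' @param cnv_file Path to the CNV table (see [load_cnv_calls()]).
#' @param vcf_files Character vector of VCF paths. With several samples,
#'   either name the vector by sample id or rely on each VCF's own sample
#'   column name; every sample named in the CNV table must resolve to
#'   exactly one VCF.
#' @param out_dir Output directory, created if needed.
#' @param params [scoring_params()].
#' @param dialect Dialect argument passed to [load_snvs()].
#' @param plots Also write one PNG per CNV under `out_dir/plots/`
#'   (default `FALSE`).
#' @param pass_only Passed to [load_snvs()].
#' @param column_map,type_vocab,coords Passed to [load_cnv_calls()].
#' @return Invisibly, a list with `verdicts`, `summary`, `results_file`,
#'   `summary_file` and `snv_reports` (one load report per VCF).
#' @export
run_pipeline <- function(cnv_file, vcf_files, out_dir,
                         params = scoring_params(), dialect = "auto",
                         plots = FALSE, pass_only = TRUE,
                         column_map = c(chrom = "chrom", start = "start",
                                        end = "end", type = "type",
                                        sample = "sample"),
                         type_vocab = default_type_vocab(),
                         coords = "1-closed") {
  validate_scoring_params(params)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)

  cnvs <- load_cnv_calls(cnv_file, column_map = column_map,
                         type_vocab = type_vocab, coords = coords)

  snv_sets <- list()
  for (i in seq_along(vcf_files)) {
    sid <- names(vcf_files)[i]
    if (is.null(sid) || !nzchar(sid)) sid <- NULL
    s <- load_snvs(vcf_files[[i]], sample_id = sid, dialect = dialect,
                   params = params, pass_only = pass_only)
    snv_sets[[i]] <- s
  }
  snvs <- do.call(rbind, lapply(snv_sets, as.data.frame))

  missing_samples <- setdiff(unique(cnvs$sample_id), unique(snvs$sample_id))
  if (length(missing_samples)) {
    stop("no VCF provides SNVs for sample(s): ",
         paste(missing_samples, collapse = ", "))
  }

  verdicts <- filter_cnvs(cnvs, snvs, params)
  results_file <- file.path(out_dir, "results.tsv")
  write_results(verdicts, results_file)
  summ <- summarize_run(verdicts)
  summary_file <- file.path(out_dir, "summary.json")
  write_summary(summ, summary_file)

  if (plots) {
    plot_dir <- file.path(out_dir, "plots")
    if (!dir.exists(plot_dir)) dir.create(plot_dir)
    for (i in seq_len(nrow(verdicts))) {
      cnv <- cnvs[i, , drop = FALSE]
      plot_cnv_region(cnv, overlapping_snvs(cnv, snvs),
                      verdicts[i, , drop = FALSE], params,
                      file.path(plot_dir, paste0(cnv$call_id, ".png")))
    }
  }

  invisible(list(verdicts = verdicts, summary = summ,
                 results_file = results_file, summary_file = summary_file,
                 snv_reports = lapply(snv_sets, load_report)))
}
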