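#' Default vocabulary mapping CNV table type labels to deletion/duplication
#'
#' Covers the common caller outputs; anything else must be supplied
#' explicitly via the `type_vocab` argument of [load_cnv_calls()] — unknown
#' labels are rejected, never guessed.
#'
#' @return Named character vector mapping lower-cased labels to
#'   `"deletion"` or `"duplication"`.
#' @export
default_type_vocab <- function() {
  c(deletion = "deletion", del = "deletion", loss = "deletion",
    cn0 = "deletion", cn1 = "deletion",
    duplication = "duplication", dup = "duplication", gain = "duplication",
    cn3 = "duplication", cn4 = "duplication")
}

#' Load a CNV callset from a delimited table
#'
#' Reads a TSV/CSV with a header and maps its columns onto the internal CNV
#' representation: 1-based closed intervals (the VCF convention, so overlap
#' tests against SNV positions need no conversion), a `cnv_type` of
#' `deletion` or `duplication`, and a stable `call_id` assigned in input
#' order. BED-style 0-based half-open coordinates are converted at this
#' boundary and never afterwards.
#'
#' @param path Path to the table. Delimiter is taken from the extension
#'   (`.csv` comma, otherwise tab) unless `delim` is given.
#' @param column_map Named character vector mapping the roles `chrom`,
#'   `start`, `end`, `type` (and optionally `sample`, `tool`) to column
#'   names in the file.
#' @param type_vocab Named vector mapping the file's type labels
#'   (case-insensitive) to `"deletion"`/`"duplication"`; see
#'   [default_type_vocab()].
#' @param coords `"1-closed"` (default) or `"0-half-open"` for BED-style
#'   input.
#' @param sample_id Sample label used when the table has no sample column.
#' @param delim Optional explicit field delimiter.
#' @return Data frame of class `cnv_calls` with columns `call_id`, `chrom`,
#'   `start`, `end`, `cnv_type`, `sample_id`, `source_tool`. Rows whose type
#'   label has no vocabulary entry or whose coordinates do not parse are
#'   dropped with a warning naming the row numbers (kept in the
#'   `rejected_rows` attribute).
#' @export
load_cnv_calls <- function(path,
                           column_map = c(chrom = "chrom", start = "start",
                                          end = "end", type = "type",
                                          sample = "sample"),
                           type_vocab = default_type_vocab(),
                           coords = c("1-closed", "0-half-open"),
                           sample_id = "sample1",
                           delim = NULL) {
  coords <- match.arg(coords)
  if (!file.exists(path)) stop("CNV table not found: ", path)
  if (is.null(delim)) {
    delim <- if (tolower(tools::file_ext(path)) == "csv") "," else "\t"
  }
  tab <- utils::read.table(path, header = TRUE, sep = delim,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           comment.char = "")
  for (role in c("chrom", "start", "end", "type")) {
    col <- if (role %in% names(column_map)) column_map[[role]] else NULL
    if (is.null(col) || !col %in% names(tab)) {
      stop("column_map role '", role, "' (column '", col,
           "') not found in ", basename(path),
           "; available columns: ", paste(names(tab), collapse = ", "))
    }
  }
  if (nrow(tab) == 0L) {
    warning("CNV table ", basename(path), " has no data rows")
  }

  start <- suppressWarnings(as.numeric(tab[[column_map[["start"]]]]))
  end <- suppressWarnings(as.numeric(tab[[column_map[["end"]]]]))
  type_raw <- tolower(as.character(tab[[column_map[["type"]]]]))
  names(type_vocab) <- tolower(names(type_vocab))
  cnv_type <- unname(type_vocab[type_raw])

  bad_coord <- is.na(start) | is.na(end) | end < start
  bad_type <- is.na(cnv_type) | !cnv_type %in% c("deletion", "duplication")
  bad <- which(bad_coord | bad_type)
  if (length(bad)) {
    warning("rejected ", length(bad), " CNV row(s) [",
            paste(utils::head(bad, 20), collapse = ", "),
            "]: unmapped type label or unparseable coordinates")
  }

  samp_col <- if ("sample" %in% names(column_map)) column_map[["sample"]]
  sample_vec <- if (!is.null(samp_col) && !is.na(samp_col) && samp_col %in% names(tab)) {
    as.character(tab[[samp_col]])
  } else rep(sample_id, nrow(tab))
  tool_col <- if ("tool" %in% names(column_map)) column_map[["tool"]]
  tool_vec <- if (!is.null(tool_col) && !is.na(tool_col) && tool_col %in% names(tab)) {
    as.character(tab[[tool_col]])
  } else rep(NA_character_, nrow(tab))

  if (coords == "0-half-open") start <- start + 1  # end already closed-equal

  keep <- setdiff(seq_len(nrow(tab)), bad)
  out <- data.frame(
    call_id = sprintf("cnv_%04d", seq_along(keep)),
    chrom = as.character(tab[[column_map[["chrom"]]]])[keep],
    start = as.integer(start[keep]),
    end = as.integer(end[keep]),
    cnv_type = cnv_type[keep],
    sample_id = sample_vec[keep],
    source_tool = tool_vec[keep],
    stringsAsFactors = FALSE
  )
  structure(out, class = c("cnv_calls", "data.frame"), rejected_rows = bad)
}

#' Write verdict-annotated CNV results to a TSV file
#'
#' One row per input CNV, in input order: every CNV field plus the decision
#' and its evidence. Re-reading the file with [read_results()] reproduces the
#' decisions exactly.
#'
#' @param verdicts A `cnv_verdicts` data frame from [filter_cnvs()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_results <- function(verdicts, path) {
  cols <- c("call_id", "chrom", "start", "end", "cnv_type", "sample_id",
            "source_tool", "decision", "rule", "n_snvs", "n_het",
            "het_fraction_pct", "dup_total_score")
  df <- as.data.frame(verdicts)[, intersect(cols, names(verdicts)), drop = FALSE]
  names(df)[names(df) == "rule"] <- "reason"
  tryCatch({
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
    TRUE
  }, error = function(e) stop("cannot write results to ", path, ": ",
                              conditionMessage(e)))
  invisible(path)
}

#' Read back a results TSV written by [write_results()]
#'
#' @param path Path to the results file.
#' @return Data frame with the written columns (the evidence column is named
#'   `reason` in the file and restored as `rule`).
#' @export
read_results <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  names(df)[names(df) == "reason"] <- "rule"
  df
}
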