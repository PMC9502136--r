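#' Extract allele counts from one VCF record under a dialect
#'
#' Applies a dialect's field rules to the FORMAT values of a single sample in
#' a single VCF record, returning the alternate depth, total depth and
#' allele frequency in percent. Dialects that report the frequency directly
#' as a percent string (VarScan2's `FREQ`) have it parsed; otherwise the
#' frequency is `100 * alt_depth / total_depth`.
#'
#' @param record Named character vector or list of FORMAT values for one
#'   sample, e.g. `c(GT = "0/1", AD = "7,3", DP = "10")`.
#' @param dialect A [dialect_spec()].
#' @return List with `alt_depth`, `total_depth`, `allele_frequency`.
#' @examples
#' extract_allele_counts(c(FREQ = "25%", RD = "15", AD = "5"),
#'                       builtin_dialect("varscan2"))
#' extract_allele_counts(c(AO = "5", RO = "5"), builtin_dialect("freebayes"))
#' @export
extract_allele_counts <- function(record, dialect) {
  stopifnot(inherits(dialect, "dialect_spec"))
  record <- as.list(record)
  get1 <- function(f) {
    if (is.null(f)) return(NA_character_)
    if (!f %in% names(record) || is.na(record[[f]])) {
      stop("required FORMAT field '", f, "' missing from record")
    }
    as.character(record[[f]])
  }
  counts <- dialect_counts(dialect,
                           alt = get1(dialect$alt_field),
                           ref = if (!is.null(dialect$ref_field)) get1(dialect$ref_field),
                           total = if (!is.null(dialect$total_field)) get1(dialect$total_field),
                           af = if (!is.null(dialect$af_field)) get1(dialect$af_field))
  if (!is.na(counts$total) && counts$total <= 0) {
    stop(structure(class = c("cnvscreen_zero_depth", "error", "condition"),
                   list(message = "record rejected: zero total depth",
                        call = sys.call())))
  }
  if (is.na(counts$alt) || is.na(counts$total) || is.na(counts$af)) {
    stop("record not interpretable under dialect '", dialect$name, "'")
  }
  list(alt_depth = counts$alt, total_depth = counts$total,
       allele_frequency = counts$af)
}

#' Fetch one built-in dialect by name
#'
#' @param name One of [vcf_dialects()].
#' @return A `dialect_spec`.
#' @export
builtin_dialect <- function(name) {
  reg <- builtin_dialects()
  if (!name %in% names(reg)) {
    stop("unknown dialect '", name, "'; see vcf_dialects()")
  }
  reg[[name]]
}

# Take component `index` of comma-separated numeric FORMAT values
# (vectorized); index NA means "sum of all components".
split_take <- function(x, index) {
  parts <- strsplit(as.character(x), ",", fixed = TRUE)
  if (is.na(index)) {
    vapply(parts, function(p) {
      v <- suppressWarnings(as.numeric(p))
      if (length(v) == 0L || anyNA(v)) NA_real_ else sum(v)
    }, numeric(1))
  } else {
    vapply(parts, function(p) {
      if (length(p) < index) return(NA_real_)
      suppressWarnings(as.numeric(p[index]))
    }, numeric(1))
  }
}

# Vectorized dialect arithmetic on raw FORMAT strings. Any NA in the result
# marks a record the dialect cannot interpret.
dialect_counts <- function(dialect, alt, ref = NULL, total = NULL, af = NULL) {
  alt_n <- split_take(alt, dialect$alt_index)
  total_n <- switch(dialect$mode,
    alt_and_total = split_take(total, dialect$total_index),
    alt_and_ref = ,
    percent_string = alt_n + split_take(ref, dialect$ref_index)
  )
  af_n <- if (dialect$mode == "percent_string") {
    suppressWarnings(as.numeric(sub("%\\s*$", "", as.character(af))))
  } else {
    ifelse(total_n > 0, 100 * alt_n / total_n, NA_real_)
  }
  data.frame(alt = alt_n, total = total_n, af = af_n)
}

#' Classify an SNV genotype as heterozygous, homozygous or unknown
#'
#' The genotype string is authoritative when present and parseable: two
#' distinct alleles give `het`, two identical alternate alleles give `hom`.
#' Otherwise (absent GT, half-calls, hom-reference) classification falls back
#' to the allele-frequency windows in `params`; a frequency outside both
#' windows is `unknown`.
#'
#' @param allele_frequency Numeric vector, percent in \[0, 100\].
#' @param gt Optional character vector of VCF genotype strings (`"0/1"`,
#'   `"1|1"`, ...), recycled against `allele_frequency`.
#' @param params A [scoring_params()] object supplying `het_window` and
#'   `hom_window`.
#' @return Character vector in `{"het", "hom", "unknown"}`.
#' @examples
#' classify_genotype(c(50, 97, 12))
#' classify_genotype(50, gt = "1/1")   # GT wins over the frequency
#' @export
classify_genotype <- function(allele_frequency, gt = NULL,
                              params = scoring_params()) {
  af <- as.numeric(allele_frequency)
  if (anyNA(af) || any(af < 0 | af > 100)) {
    stop("allele_frequency must lie in [0, 100]")
  }
  n <- length(af)
  out <- rep(NA_character_, n)
  if (!is.null(gt)) {
    gt <- rep_len(as.character(gt), n)
    alleles <- strsplit(sub(":.*$", "", gt), "[/|]")
    out <- vapply(alleles, function(a) {
      if (length(a) != 2L || anyNA(a) || any(a == ".")) return(NA_character_)
      if (a[1] != a[2]) return("het")
      if (a[1] != "0") return("hom")
      NA_character_   # hom-reference: defer to the frequency
    }, character(1))
  }
  fallback <- is.na(out)
  hw <- params$het_window; ow <- params$hom_window
  out[fallback & af >= hw[1] & af < hw[2]] <- "het"
  out[fallback & is.na(out) & af >= ow[1] & af <= ow[2]] <- "hom"
  out[is.na(out)] <- "unknown"
  out
}

#' Load quality-passing biallelic SNVs from a VCF file
#'
#' Reads a VCF (plain or gzip/bgzip-compressed, single- or multi-sample),
#' resolves the caller dialect, and returns one row per accepted SNV with
#' read counts, allele frequency (percent) and genotype class. Records are
#' screened in order: biallelic single-nucleotide records only, then the
#' `FILTER` column (when `pass_only`), then dialect interpretability, then a
#' positive total depth, then the depth floor. Every rejection is counted by
#' reason in the attached load report — nothing is dropped silently.
#'
#' @param path Path to the VCF file.
#' @param sample_id Sample column to read; may be omitted for single-sample
#'   files.
#' @param dialect `"auto"` (default) to detect from the header, a dialect
#'   name from [vcf_dialects()], or a [dialect_spec()] override for callers
#'   outside the built-in set.
#' @param params [scoring_params()]; supplies the depth floor and the
#'   genotype fallback windows.
#' @param pass_only Keep only records whose `FILTER` is `PASS` or `.`
#'   (default `TRUE`).
#' @return A data frame of class `snv_set` with columns `chrom`, `pos`,
#'   `ref`, `alt`, `alt_depth`, `total_depth`, `allele_frequency`,
#'   `genotype_class`, `sample_id`, and a `load_report` attribute (see
#'   [load_report()]). An empty result is returned with a warning when every
#'   record is rejected.
#' @export
load_snvs <- function(path, sample_id = NULL, dialect = "auto",
                      params = scoring_params(), pass_only = TRUE) {
  if (!file.exists(path)) stop("VCF file not found: ", path)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  d <- resolve_dialect(dialect, vcf@meta)

  samples <- colnames(vcf@gt)[-1]
  if (is.null(sample_id)) {
    if (length(samples) != 1L) {
      stop("VCF has ", length(samples), " samples (",
           paste(samples, collapse = ", "), "); pass sample_id to pick one")
    }
    sample_id <- samples
  } else if (!sample_id %in% samples) {
    stop("sample '", sample_id, "' not in VCF header (samples: ",
         paste(samples, collapse = ", "), ")")
  }

  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) {   # single-record VCFs drop to a named vector
    fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  }
  n_total <- nrow(fix)
  reasons <- c(non_snv = 0L, filter = 0L, uninterpretable = 0L,
               zero_depth = 0L, depth = 0L)
  empty <- data.frame(chrom = character(), pos = integer(), ref = character(),
                      alt = character(), alt_depth = numeric(),
                      total_depth = numeric(), allele_frequency = numeric(),
                      genotype_class = character(), sample_id = character(),
                      stringsAsFactors = FALSE)
  finish <- function(df) {
    report <- list(path = path, dialect = d$name, sample_id = sample_id,
                   n_total = n_total, n_accepted = nrow(df),
                   rejected = reasons)
    if (n_total > 0L && nrow(df) == 0L) {
      warning("no usable SNV records in ", basename(path), " (",
              n_total, " rejected); see load_report()")
    }
    structure(df, class = c("snv_set", "data.frame"), load_report = report)
  }
  if (n_total == 0L) return(finish(empty))

  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  nt <- c("A", "C", "G", "T")
  keep <- !is.na(ref) & !is.na(alt) & ref %in% nt & alt %in% nt & ref != alt
  reasons["non_snv"] <- sum(!keep)
  if (pass_only) {
    filt <- fix[, "FILTER"]
    pass <- is.na(filt) | filt %in% c("PASS", ".")
    reasons["filter"] <- sum(keep & !pass)
    keep <- keep & pass
  }

  get_field <- function(f) {
    m <- tryCatch(vcfR::extract.gt(vcf, element = f),
                  error = function(e) {
                    stop("required FORMAT field '", f, "' not found in ",
                         basename(path), " (dialect '", d$name, "')")
                  })
    if (is.matrix(m)) m[, sample_id] else unname(m[sample_id])
  }
  counts <- dialect_counts(
    d,
    alt = get_field(d$alt_field),
    ref = if (!is.null(d$ref_field)) get_field(d$ref_field),
    total = if (!is.null(d$total_field)) get_field(d$total_field),
    af = if (!is.null(d$af_field)) get_field(d$af_field)
  )
  ok_counts <- !is.na(counts$alt) & !is.na(counts$total) & !is.na(counts$af) &
    counts$af >= 0 & counts$af <= 100 & counts$alt >= 0 &
    counts$alt <= counts$total
  reasons["uninterpretable"] <- sum(keep & !ok_counts & counts$total != 0, na.rm = TRUE) +
    sum(keep & is.na(counts$total))
  zero <- !is.na(counts$total) & counts$total == 0
  reasons["zero_depth"] <- sum(keep & zero)
  keep <- keep & ok_counts
  deep <- counts$total >= params$depth_floor
  reasons["depth"] <- sum(keep & !deep, na.rm = TRUE)
  keep <- keep & deep
  keep[is.na(keep)] <- FALSE

  if (!any(keep)) return(finish(empty))

  gt <- tryCatch(vcfR::extract.gt(vcf, element = d$gt_field)[, sample_id],
                 error = function(e) NULL)
  df <- data.frame(
    chrom = fix[keep, "CHROM"],
    pos = as.integer(fix[keep, "POS"]),
    ref = ref[keep],
    alt = alt[keep],
    alt_depth = counts$alt[keep],
    total_depth = counts$total[keep],
    allele_frequency = counts$af[keep],
    genotype_class = classify_genotype(counts$af[keep],
                                       gt = if (!is.null(gt)) gt[keep],
                                       params = params),
    sample_id = sample_id,
    stringsAsFactors = FALSE
  )
  rownames(df) <- NULL
  finish(df)
}

#' Load report of an SNV set
#'
#' @param x An `snv_set` returned by [load_snvs()].
#' @return List with the source path, resolved dialect and sample, the total
#'   number of data lines, the number accepted, and rejection counts by
#'   reason (`non_snv`, `filter`, `uninterpretable`, `zero_depth`, `depth`).
#'   Accepted plus rejected always equals the total.
#' @export
load_report <- function(x) {
  r <- attr(x, "load_report")
  if (is.null(r)) stop("object has no load report; was it made by load_snvs()?")
  r
}

#' @export
print.snv_set <- function(x, ...) {
  r <- attr(x, "load_report")
  if (!is.null(r)) {
    cat(sprintf("<snv_set> %d SNVs from %s (dialect %s, sample %s); %d/%d records rejected\n",
                nrow(x), basename(r$path), r$dialect, r$sample_id,
                sum(r$rejected), r$n_total))
  }
  print.data.frame(x, ...)
  invisible(x)
}
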