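#' VCF dialect specification
#'
#' Describes how one SNV caller encodes per-sample read depths and allele
#' frequencies in VCF FORMAT fields. A dialect yields, for every record it
#' accepts, an alternate-supporting depth and a total depth (or a direct
#' percent frequency plus depths); records it cannot interpret are rejected
#' and counted, never silently zeroed.
#'
#' Three arithmetic modes cover the supported callers and any caller a user
#' wants to describe:
#' * `percent_string` — a FORMAT field carries the frequency as a percent
#'   string (e.g. `"25%"`); depths come from separate alt/ref fields
#'   (VarScan2: `FREQ` with `AD`/`RD`).
#' * `alt_and_total` — one field (possibly comma-separated) carries the alt
#'   depth, another the total depth (Strelka: `AD` ref,alt with `DP`; GATK
#'   callers: alt and total both from the `AD` ref,alt pair).
#' * `alt_and_ref` — separate alt and ref depth fields, total is their sum
#'   (freeBayes: `AO`, `RO`).
#'
#' @param name Dialect name; one of `"varscan2"`, `"strelka"`, `"freebayes"`,
#'   `"gatk_haplotypecaller"`, `"gatk_unifiedgenotyper"`, `"generic"`.
#' @param mode One of `"percent_string"`, `"alt_and_total"`, `"alt_and_ref"`.
#' @param af_field FORMAT field holding the percent-string frequency
#'   (`percent_string` mode only).
#' @param alt_field,alt_index FORMAT field (and 1-based index into its
#'   comma-separated value) holding the alternate depth.
#' @param ref_field,ref_index Field/index for the reference depth
#'   (`percent_string` and `alt_and_ref` modes).
#' @param total_field,total_index Field/index for the total depth
#'   (`alt_and_total` mode).
#' @param gt_field FORMAT field holding the genotype string. Default `"GT"`.
#'
#' @return An object of class `dialect_spec`.
#' @examples
#' # a caller reporting alt depth in "NV" and total depth in "NR":
#' dialect_spec("generic", mode = "alt_and_total",
#'              alt_field = "NV", total_field = "NR")
#' @export
dialect_spec <- function(name = "generic",
                         mode = c("alt_and_total", "alt_and_ref", "percent_string"),
                         af_field = NULL,
                         alt_field = NULL, alt_index = 1L,
                         ref_field = NULL, ref_index = 1L,
                         total_field = NULL, total_index = 1L,
                         gt_field = "GT") {
  mode <- match.arg(mode)
  d <- list(name = name, mode = mode, af_field = af_field,
            alt_field = alt_field, alt_index = as.integer(alt_index),
            ref_field = ref_field, ref_index = as.integer(ref_index),
            total_field = total_field, total_index = as.integer(total_index),
            gt_field = gt_field)
  if (is.null(d$alt_field)) stop("dialect_spec: alt_field is required")
  if (mode == "percent_string" && (is.null(d$af_field) || is.null(d$ref_field)))
    stop("dialect_spec: percent_string mode needs af_field and ref_field")
  if (mode == "alt_and_total" && is.null(d$total_field))
    stop("dialect_spec: alt_and_total mode needs total_field")
  if (mode == "alt_and_ref" && is.null(d$ref_field))
    stop("dialect_spec: alt_and_ref mode needs ref_field")
  class(d) <- "dialect_spec"
  d
}

# Registry of the built-in caller dialects. Field choices are each caller's
# documented germline FORMAT conventions; keeping them here makes corrections
# local.
builtin_dialects <- function() {
  list(
    varscan2 = dialect_spec("varscan2", mode = "percent_string",
                            af_field = "FREQ",
                            alt_field = "AD", ref_field = "RD"),
    strelka = dialect_spec("strelka", mode = "alt_and_total",
                           alt_field = "AD", alt_index = 2L,
                           total_field = "DP"),
    freebayes = dialect_spec("freebayes", mode = "alt_and_ref",
                             alt_field = "AO", ref_field = "RO"),
    gatk_haplotypecaller = dialect_spec("gatk_haplotypecaller",
                                        mode = "alt_and_total",
                                        alt_field = "AD", alt_index = 2L,
                                        total_field = "AD", total_index = NA_integer_),
    gatk_unifiedgenotyper = dialect_spec("gatk_unifiedgenotyper",
                                         mode = "alt_and_total",
                                         alt_field = "AD", alt_index = 2L,
                                         total_field = "AD", total_index = NA_integer_)
  )
}

#' Names of the built-in VCF dialects
#'
#' @return Character vector of dialect names understood by [detect_dialect()]
#'   and [load_snvs()].
#' @export
vcf_dialects <- function() names(builtin_dialects())

#' Detect the SNV caller dialect of a VCF from its header
#'
#' Inspects the `##` meta lines: first the program provenance lines
#' (`##source=`, `##GATKCommandLine=`), then characteristic FORMAT
#' declarations (`FREQ` for VarScan2, `AO`/`RO` for freeBayes, `GQX` for
#' Strelka, an `AD`/`DP` pair for the GATK callers). When nothing matches
#' and `overrides` supplies a [dialect_spec()], that spec is returned;
#' otherwise detection fails with an error listing the evidence examined.
#'
#' @param header_lines Character vector of `##` meta lines of a VCF.
#' @param overrides Optional `dialect_spec` used when no built-in dialect
#'   matches.
#' @return A `dialect_spec`.
#' @examples
#' detect_dialect("##source=VarScan2")$name
#' detect_dialect(c('##FORMAT=<ID=AO,Number=A,Type=Integer,Description="x">',
#'                  '##FORMAT=<ID=RO,Number=1,Type=Integer,Description="x">'))$name
#' @export
detect_dialect <- function(header_lines, overrides = NULL) {
  stopifnot(is.character(header_lines) || length(header_lines) == 0L)
  reg <- builtin_dialects()
  prov <- grep("^##(source|GATKCommandLine)", header_lines, value = TRUE)
  for (line in prov) {
    if (grepl("varscan", line, ignore.case = TRUE)) return(reg$varscan2)
    if (grepl("strelka", line, ignore.case = TRUE)) return(reg$strelka)
    if (grepl("freebayes", line, ignore.case = TRUE)) return(reg$freebayes)
    if (grepl("haplotypecaller", line, ignore.case = TRUE)) return(reg$gatk_haplotypecaller)
    if (grepl("unifiedgenotyper", line, ignore.case = TRUE)) return(reg$gatk_unifiedgenotyper)
  }
  fmt_ids <- sub("^##FORMAT=<ID=([^,>]+).*", "\\1",
                 grep("^##FORMAT=<ID=", header_lines, value = TRUE))
  if ("FREQ" %in% fmt_ids) return(reg$varscan2)
  if (all(c("AO", "RO") %in% fmt_ids)) return(reg$freebayes)
  if ("GQX" %in% fmt_ids && "AD" %in% fmt_ids) return(reg$strelka)
  if (all(c("AD", "DP") %in% fmt_ids)) return(reg$gatk_haplotypecaller)
  if (!is.null(overrides)) {
    if (!inherits(overrides, "dialect_spec")) {
      stop("overrides must be a dialect_spec object")
    }
    return(overrides)
  }
  stop("unrecognized VCF dialect: no provenance line among ",
       if (length(prov)) paste(sQuote(prov), collapse = ", ") else "(none)",
       " and FORMAT fields {", paste(fmt_ids, collapse = ", "),
       "} match no built-in caller; pass a dialect_spec() override to load anyway")
}

# Resolve a user-facing dialect argument ("auto", a name, or a spec) against
# a header. Used by load_snvs().
resolve_dialect <- function(dialect, header_lines) {
  if (inherits(dialect, "dialect_spec")) return(dialect)
  if (identical(dialect, "auto")) return(detect_dialect(header_lines))
  reg <- builtin_dialects()
  if (is.character(dialect) && length(dialect) == 1L && dialect %in% names(reg)) {
    return(reg[[dialect]])
  }
  stop("dialect must be \"auto\", one of ", paste(vcf_dialects(), collapse = "/"),
       ", or a dialect_spec object")
}
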