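#' Read a GWAS summary-statistics table
#'
#' Reads a delimited text file of per-variant association summary statistics
#' (one row per SNP) and returns a validated data frame of variant
#' associations, the elementary record of a two-sample MR analysis. Rows that
#' violate the record invariants (identical alleles, non-positive standard
#' error, unparseable numerics, frequency outside (0,1)) are rejected
#' individually; the reasons are attached to the result rather than silently
#' dropped.
#'
#' @param path Path to a delimited text file (TSV by default).
#' @param column_map Named character vector mapping the canonical field names
#'   (`rsid`, `effect_allele`, `other_allele`, `beta`, `se`, and optionally
#'   `eaf`, `n`, `pvalue`) to the column names used in the file. Use
#'   [neale_column_map()] for UK Biobank releases in the Neale-lab layout, or
#'   [default_column_map()] for files that already use the canonical names.
#' @param delimiter Field separator, `"\t"` by default (`","` for CSV).
#' @return A `variant_associations` data frame with columns `rsid`,
#'   `effect_allele`, `other_allele`, `beta`, `se`, `eaf`, `n`, `pvalue`
#'   (missing optional fields are `NA`), alleles upper-cased, rows in file
#'   order. Rejected rows are recorded in `attr(, "rejections")`, a data frame
#'   with columns `row`, `rsid`, `reason`.
#' @seealso [build_instrument()], [harmonize()]
#' @export
read_summary_table <- function(path,
                               column_map = default_column_map(),
                               delimiter = "\t") {
  if (!file.exists(path)) {
    stop("summary-statistics file not found: ", path, call. = FALSE)
  }
  raw <- utils::read.delim(path, sep = delimiter, header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character")
  required <- c("rsid", "effect_allele", "other_allele", "beta", "se")
  optional <- c("eaf", "n", "pvalue")
  map <- column_map[intersect(names(column_map), c(required, optional))]
  missing_req <- setdiff(required, names(map))
  if (length(missing_req)) {
    stop("column_map does not map required field(s): ",
         paste(missing_req, collapse = ", "), call. = FALSE)
  }
  absent_req <- setdiff(unname(map[required]), names(raw))
  if (length(absent_req)) {
    stop("mapped column(s) absent from ", path, ": ",
         paste(absent_req, collapse = ", "), call. = FALSE)
  }
  # optional fields whose mapped column is not in this file are simply NA
  map <- map[unname(map) %in% names(raw) | names(map) %in% required]
  n_raw <- nrow(raw)
  get_chr <- function(field) {
    if (field %in% names(map)) raw[[map[[field]]]] else rep(NA_character_, n_raw)
  }
  num_or_na <- function(x) suppressWarnings(as.numeric(x))

  out <- data.frame(
    rsid          = get_chr("rsid"),
    effect_allele = toupper(get_chr("effect_allele")),
    other_allele  = toupper(get_chr("other_allele")),
    beta          = num_or_na(get_chr("beta")),
    se            = num_or_na(get_chr("se")),
    eaf           = num_or_na(get_chr("eaf")),
    n             = num_or_na(get_chr("n")),
    pvalue        = num_or_na(get_chr("pvalue")),
    stringsAsFactors = FALSE
  )

  reason <- rep(NA_character_, n_raw)
  bases <- c("A", "C", "G", "T")
  flag <- function(cond, why) {
    cond[is.na(cond)] <- FALSE
    reason[cond & is.na(reason)] <<- why
  }
  flag(is.na(out$beta), "unparseable beta")
  flag(is.na(out$se), "unparseable SE")
  flag(out$se <= 0, "non-positive SE")
  flag(!(out$effect_allele %in% bases), "invalid effect allele")
  flag(!(out$other_allele %in% bases), "invalid other allele")
  flag(out$effect_allele == out$other_allele, "identical alleles")
  flag(!is.na(out$eaf) & (out$eaf <= 0 | out$eaf >= 1),
       "effect-allele frequency outside (0,1)")
  flag(is.na(out$rsid) | out$rsid == "", "missing rsid")

  keep <- is.na(reason)
  rejections <- data.frame(row = which(!keep),
                           rsid = out$rsid[!keep],
                           reason = reason[!keep],
                           stringsAsFactors = FALSE)
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("variant_associations", "data.frame")
  attr(out, "rejections") <- rejections
  attr(out, "source") <- path
  out
}

#' Column-name presets for summary-statistics files
#'
#' `default_column_map()` is the identity mapping for files that already use
#' the canonical column names. `neale_column_map()` targets the UK Biobank
#' sex-stratified releases distributed by the Neale lab, whose headers are
#' `variant`/`rsid`, `minor_allele`, `beta`, `se`, `pval`; the effect allele
#' in those files is the minor allele and the reference allele must be
#' supplied under `other_allele` (the raw releases key variants by
#' chr:pos:ref:alt, so a small amount of pre-processing into rsID-keyed rows
#' is assumed).
#'
#' @return Named character vector usable as `column_map` in
#'   [read_summary_table()].
#' @export
default_column_map <- function() {
  c(rsid = "rsid", effect_allele = "effect_allele",
    other_allele = "other_allele", beta = "beta", se = "se",
    eaf = "eaf", n = "n", pvalue = "pvalue")
}

#' @rdname default_column_map
#' @export
neale_column_map <- function() {
  c(rsid = "rsid", effect_allele = "minor_allele",
    other_allele = "other_allele", beta = "beta", se = "se",
    eaf = "minor_AF", n = "n_complete_samples", pvalue = "pval")
}

#' Assemble the genetic instrument for one exposure
#'
#' Filters a table of variant associations down to the instrument SNPs and
#' labels the result with the exposure name and its iron-status direction.
#' Higher serum iron, ferritin, and transferrin saturation mark higher
#' systemic iron status, whereas higher transferrin marks lower iron status;
#' `direction_flag` records this so downstream reports can annotate
#' transferrin rows without flipping any estimate.
#'
#' @param exposure_name Exposure label, e.g. `"iron"`, `"ferritin"`,
#'   `"transferrin"`, `"transferrin_saturation"`.
#' @param direction_flag `TRUE` if a higher biomarker value indicates higher
#'   systemic iron status (`FALSE` for transferrin).
#' @param associations A `variant_associations` data frame (or compatible
#'   data frame) holding at least the instrument SNPs.
#' @param snp_filter Character vector of rsIDs to retain, in the desired
#'   instrument order; defaults to the three-SNP iron instrument
#'   rs1800562, rs1799945, rs855791.
#' @return An `instrument_set`: list with `exposure_name`, `direction_flag`,
#'   and `variants` (the filtered associations in `snp_filter` order).
#' @export
build_instrument <- function(exposure_name, direction_flag, associations,
                             snp_filter = iron_instrument_snps()) {
  if (length(snp_filter) == 0) {
    stop("instrument may not be empty: snp_filter has no rsIDs", call. = FALSE)
  }
  rsids <- associations$rsid
  dup <- intersect(snp_filter, rsids[duplicated(rsids)])
  if (length(dup)) {
    stop("duplicate rsID(s) in association table: ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  missing <- setdiff(snp_filter, rsids)
  if (length(missing)) {
    stop("instrument SNP(s) missing from association table: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  variants <- associations[match(snp_filter, rsids), , drop = FALSE]
  rownames(variants) <- NULL
  structure(
    list(exposure_name = exposure_name,
         direction_flag = isTRUE(direction_flag),
         variants = variants),
    class = "instrument_set"
  )
}

#' The three-SNP iron-status instrument
#'
#' rsIDs of the three variants associated with all four serum iron biomarkers
#' at genome-wide significance in the Genetics of Iron Status Consortium
#' meta-analysis: rs1800562 and rs1799945 in the hemochromatosis gene region
#' and rs855791 in TMPRSS6.
#'
#' @return Character vector of three rsIDs.
#' @export
iron_instrument_snps <- function() {
  c("rs1800562", "rs1799945", "rs855791")
}

#' Wrap outcome-scan summary statistics
#'
#' @param outcome_name Outcome label.
#' @param stratum One of `"all"`, `"male"`, `"female"`.
#' @param associations `variant_associations` data frame for the outcome scan.
#' @param n_cases,n_total Optional case and total counts.
#' @return An `outcome_set` list.
#' @export
outcome_set <- function(outcome_name, stratum = "all", associations,
                        n_cases = NA_integer_, n_total = NA_integer_) {
  stratum <- match.arg(stratum, c("all", "male", "female"))
  if (anyDuplicated(associations$rsid)) {
    stop("duplicate rsID(s) in outcome table for ", outcome_name, call. = FALSE)
  }
  structure(
    list(outcome_name = outcome_name, stratum = stratum,
         n_cases = n_cases, n_total = n_total, variants = associations),
    class = "outcome_set"
  )
}

#' @export
print.instrument_set <- function(x, ...) {
  cat("Instrument set:", x$exposure_name,
      if (x$direction_flag) "(higher = higher iron status)"
      else "(higher = lower iron status)", "\n")
  cat(nrow(x$variants), "SNP(s):", paste(x$variants$rsid, collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.outcome_set <- function(x, ...) {
  cat("Outcome set:", x$outcome_name, "/", x$stratum, "-",
      nrow(x$variants), "SNP(s)\n")
  invisible(x)
}

#' Write a variant-association table back to delimited text
#'
#' Inverse of [read_summary_table()] under the canonical column names; valid
#' rows round-trip losslessly.
#'
#' @param associations `variant_associations` data frame.
#' @param path Output path.
#' @param delimiter Field separator.
#' @return `path`, invisibly.
#' @export
write_summary_table <- function(associations, path, delimiter = "\t") {
  cols <- c("rsid", "effect_allele", "other_allele", "beta", "se",
            "eaf", "n", "pvalue")
  df <- as.data.frame(associations)[, cols, drop = FALSE]
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) {
    ifelse(is.na(x), NA_character_, formatC(x, digits = 17, format = "g"))
  })
  utils::write.table(df, path, sep = delimiter, quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}
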