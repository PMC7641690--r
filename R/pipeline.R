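#' Bonferroni-corrected per-test threshold for the exposure-outcome grid
#'
#' The family of primary tests is every exposure x outcome cell of the
#' overall grid; the family-wise level is divided by the number of cells.
#' With 4 iron biomarkers and 12 vascular diseases at alpha 0.05 this is
#' 0.05/48, approximately 1.04e-3.
#'
#' @param alpha_family Family-wise level, default 0.05.
#' @param n_exposures,n_outcomes Cell counts, both >= 1.
#' @return The per-test threshold.
#' @export
bonferroni_threshold <- function(alpha_family = 0.05, n_exposures, n_outcomes) {
  if (n_exposures < 1 || n_outcomes < 1) {
    stop("exposure and outcome counts must be at least 1", call. = FALSE)
  }
  if (alpha_family <= 0 || alpha_family >= 1) {
    stop("alpha_family must be in (0,1)", call. = FALSE)
  }
  alpha_family / (n_exposures * n_outcomes)
}

#' Classify a p-value into the significance taxonomy
#'
#' `significant` below the strict (Bonferroni) threshold, `potential` between
#' the strict and nominal thresholds, `null` otherwise.
#'
#' @param pvalue The p-value (vectorized).
#' @param threshold_strict Strict threshold (e.g. 0.05/48).
#' @param threshold_nominal Nominal threshold, default 0.05.
#' @return Character vector in `{"significant", "potential", "null"}`.
#' @export
classify <- function(pvalue, threshold_strict, threshold_nominal = 0.05) {
  if (threshold_strict > threshold_nominal) {
    stop("threshold_strict must not exceed threshold_nominal", call. = FALSE)
  }
  ifelse(pvalue < threshold_strict, "significant",
         ifelse(pvalue < threshold_nominal, "potential", "null"))
}

#' Build an analysis configuration
#'
#' Collects everything [run_grid()] needs: the exposure and outcome file
#' layout, the SNP filter, estimator choices and bootstrap settings,
#' multiplicity control, and the harmonization policy.
#'
#' @param exposures Data frame (or list coercible to one) with columns
#'   `name`, `file`, `direction_flag`.
#' @param outcomes Named list: one entry per outcome, each a named character
#'   vector/list of files keyed by stratum (`all`, `male`, `female`).
#' @param snp_filter rsIDs of the instrument SNPs.
#' @param methods Estimators to run; `ivw_fixed` is always the primary.
#' @param alpha_family Family-wise level for the Bonferroni threshold.
#' @param policy A [harmonization_policy()].
#' @param bootstrap_B,seed Bootstrap replicates and base seed for the median
#'   methods (per-cell seeds are derived deterministically from the base seed
#'   and the cell identity, so results do not depend on grid order).
#' @param se_mode Delta-method convention, see [wald_ratio()].
#' @param column_map Column mapping for [read_summary_table()].
#' @param delimiter Field delimiter of the input files.
#' @param output_dir Where [write_results()] puts its files.
#' @return An `analysis_config` list.
#' @export
analysis_config <- function(exposures, outcomes,
                            snp_filter = iron_instrument_snps(),
                            methods = c("ivw_fixed", "simple_median",
                                        "weighted_median", "egger"),
                            alpha_family = 0.05,
                            policy = harmonization_policy(),
                            bootstrap_B = 5000, seed = 1L,
                            se_mode = "full_delta",
                            column_map = default_column_map(),
                            delimiter = "\t",
                            output_dir = ".") {
  exposures <- as.data.frame(exposures, stringsAsFactors = FALSE)
  stopifnot(all(c("name", "file", "direction_flag") %in% names(exposures)))
  if (nrow(exposures) < 1 || length(outcomes) < 1) {
    stop("at least one exposure and one outcome are required", call. = FALSE)
  }
  methods <- match.arg(methods, several.ok = TRUE)
  if (!"ivw_fixed" %in% methods) methods <- c("ivw_fixed", methods)
  structure(
    list(exposures = exposures, outcomes = outcomes, snp_filter = snp_filter,
         methods = methods, alpha_family = alpha_family, policy = policy,
         bootstrap_B = bootstrap_B, seed = as.integer(seed),
         se_mode = se_mode, column_map = column_map, delimiter = delimiter,
         output_dir = output_dir),
    class = "analysis_config"
  )
}

#' Read an analysis configuration from a YAML file
#'
#' The file mirrors the arguments of [analysis_config()]; see the packaged
#' example written by [simulate_study()] manifests. Relative file paths are
#' resolved against the directory containing the configuration file.
#'
#' @param path Path to a YAML configuration.
#' @return An `analysis_config`.
#' @export
read_analysis_config <- function(path) {
  raw <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(f) {
    ifelse(grepl("^(/|[A-Za-z]:)", f), f, file.path(base, f))
  }
  exposures <- do.call(rbind, lapply(raw$exposures, function(e) {
    data.frame(name = e$name, file = resolve(e$file),
               direction_flag = isTRUE(e$direction_flag),
               stringsAsFactors = FALSE)
  }))
  outcomes <- lapply(raw$outcomes, function(o) {
    files <- lapply(o$files, resolve)
    names(files) <- names(o$files)
    files
  })
  names(outcomes) <- vapply(raw$outcomes, `[[`, character(1), "name")
  pol <- raw$harmonization
  policy <- if (is.null(pol)) harmonization_policy() else {
    harmonization_policy(
      palindromic = if (is.null(pol$palindromic)) "eaf_resolve" else pol$palindromic,
      eaf_threshold = if (is.null(pol$eaf_threshold)) 0.08 else pol$eaf_threshold
    )
  }
  default <- function(x, d) if (is.null(x)) d else x
  analysis_config(
    exposures = exposures, outcomes = outcomes,
    snp_filter = default(raw$snp_filter, iron_instrument_snps()),
    methods = default(unlist(raw$methods),
                      c("ivw_fixed", "simple_median", "weighted_median", "egger")),
    alpha_family = default(raw$alpha_family, 0.05),
    policy = policy,
    bootstrap_B = default(raw$bootstrap_B, 5000),
    seed = default(raw$seed, 1L),
    se_mode = default(raw$se_mode, "full_delta"),
    delimiter = default(raw$delimiter, "\t"),
    output_dir = default(resolve(raw$output_dir), base)
  )
}

# Deterministic per-cell seed derived from the base seed and the cell
# identity, independent of grid traversal order. Kept below 2^31.
.cell_seed <- function(seed, exposure, outcome, stratum) {
  key <- paste(exposure, outcome, stratum, sep = "|")
  h <- 0
  for (code in utf8ToInt(key)) h <- (h * 31 + code) %% 1998244353
  as.integer((as.numeric(seed) * 2654435761 + h) %% 2147483647) + 1L
}

#' Run the full exposure x outcome x stratum analysis grid
#'
#' For every configured cell: read both summary tables, assemble the
#' instrument, harmonize alleles, orient exposure-increasing, check
#' instrument strength, compute the fixed-effect IVW estimate (primary) and
#' any configured sensitivity estimators, attach the MR-Egger pleiotropy
#' intercept p-value, and classify against the Bonferroni threshold. Cells
#' that fail harmonization are recorded as failures and the grid continues.
#' The run is deterministic given the configuration: bootstrap seeds are
#' derived per cell from the base seed and the cell identity.
#'
#' @param config An [analysis_config()] (or a path to a YAML configuration).
#' @return A `mr_grid` data frame: one row per exposure x outcome x stratum x
#'   method with columns `exposure`, `outcome`, `stratum`, `method`, `beta`,
#'   `se`, `or_point`, `ci_low`, `ci_high`, `pvalue`, `n_snps`,
#'   `significance_class`, `weak_instrument_flag`, `direction_note`,
#'   `egger_intercept`, `egger_intercept_p`, `concordant`. Attributes:
#'   `threshold_strict`, `threshold_nominal`, `failures` (data frame),
#'   `sex_differences` (exploratory z-tests for outcomes with both sexes),
#'   `config`.
#' @export
run_grid <- function(config) {
  if (is.character(config)) config <- read_analysis_config(config)
  stopifnot(inherits(config, "analysis_config"))
  thr_strict <- bonferroni_threshold(config$alpha_family,
                                     nrow(config$exposures),
                                     length(config$outcomes))
  thr_nominal <- 0.05

  read_cached <- local({
    cache <- new.env(parent = emptyenv())
    function(path) {
      key <- normalizePath(path)
      if (!exists(key, envir = cache)) {
        assign(key, read_summary_table(path, config$column_map,
                                       config$delimiter),
               envir = cache)
      }
      get(key, envir = cache)
    }
  })

  rows <- list()
  failures <- list()
  sexdiff <- list()

  for (i in seq_len(nrow(config$exposures))) {
    exp_row <- config$exposures[i, ]
    instrument <- build_instrument(exp_row$name, exp_row$direction_flag,
                                   read_cached(exp_row$file),
                                   config$snp_filter)
    for (out_name in names(config$outcomes)) {
      strata <- config$outcomes[[out_name]]
      cell_by_stratum <- list()
      for (stratum in names(strata)) {
        path <- strata[[stratum]]
        if (is.null(path) || is.na(path) || !file.exists(path)) {
          message("no summary file for ", out_name, " (", stratum,
                  "); stratum skipped")
          next
        }
        cell <- tryCatch(
          .run_cell(instrument, out_name, stratum, read_cached(path), config),
          error = function(e) e
        )
        if (inherits(cell, "error")) {
          failures[[length(failures) + 1L]] <- data.frame(
            exposure = exp_row$name, outcome = out_name, stratum = stratum,
            error = conditionMessage(cell), stringsAsFactors = FALSE)
          next
        }
        cell_by_stratum[[stratum]] <- cell
        rows[[length(rows) + 1L]] <- cell$rows
      }
      if (all(c("male", "female") %in% names(cell_by_stratum))) {
        sd <- sex_difference_test(cell_by_stratum$male$ivw,
                                  cell_by_stratum$female$ivw)
        sexdiff[[length(sexdiff) + 1L]] <- data.frame(
          exposure = exp_row$name, outcome = out_name, method = "ivw_fixed",
          z = sd$z, pvalue = sd$pvalue, stringsAsFactors = FALSE)
      }
    }
  }

  if (length(rows) == 0) stop("empty analysis grid: no cell succeeded",
                              call. = FALSE)
  grid <- do.call(rbind, rows)
  grid$significance_class <- classify(grid$pvalue, thr_strict, thr_nominal)
  ord <- order(grid$exposure, grid$outcome,
               match(grid$stratum, c("all", "male", "female")),
               match(grid$method, c("ivw_fixed", "simple_median",
                                    "weighted_median", "egger_slope")))
  grid <- grid[ord, , drop = FALSE]
  rownames(grid) <- NULL
  attr(grid, "threshold_strict") <- thr_strict
  attr(grid, "threshold_nominal") <- thr_nominal
  attr(grid, "failures") <- if (length(failures)) do.call(rbind, failures) else
    data.frame(exposure = character(), outcome = character(),
               stratum = character(), error = character())
  attr(grid, "sex_differences") <- if (length(sexdiff)) do.call(rbind, sexdiff) else
    data.frame(exposure = character(), outcome = character(),
               method = character(), z = numeric(), pvalue = numeric())
  attr(grid, "config") <- config
  class(grid) <- c("mr_grid", "data.frame")
  grid
}

# One exposure x outcome x stratum cell: harmonize, orient, estimate.
.run_cell <- function(instrument, out_name, stratum, out_assoc, config) {
  outc <- outcome_set(out_name, stratum, out_assoc)
  h <- harmonize(instrument, outc, config$policy)
  h <- orient_to_exposure_increasing(h)
  strength <- instrument_strength(h)
  weak <- any(strength$weak)
  seed <- .cell_seed(config$seed, instrument$exposure_name, out_name, stratum)
  J <- length(h$gamma)

  ests <- list(ivw_fixed = ivw_fixed(h, se_mode = config$se_mode))
  if ("simple_median" %in% config$methods) {
    ests$simple_median <- suppressWarnings(
      simple_median(h, B = config$bootstrap_B, seed = seed,
                    se_mode = config$se_mode))
  }
  if ("weighted_median" %in% config$methods) {
    ests$weighted_median <- suppressWarnings(
      weighted_median(h, B = config$bootstrap_B, seed = seed + 1L,
                      se_mode = config$se_mode))
  }
  egg <- NULL
  if ("egger" %in% config$methods && J >= 3) {
    egg <- egger(h)
    ests$egger_slope <- egg$slope
  }

  direction_note <- if (instrument$direction_flag) "" else
    "higher biomarker = lower iron status"
  rows <- do.call(rbind, lapply(ests, function(e) {
    data.frame(exposure = instrument$exposure_name, outcome = out_name,
               stratum = stratum, method = e$method, beta = e$beta, se = e$se,
               or_point = e$or_point, ci_low = e$ci_low, ci_high = e$ci_high,
               pvalue = e$pvalue, n_snps = e$n_snps,
               weak_instrument_flag = weak,
               direction_note = direction_note,
               egger_intercept = if (is.null(egg)) NA_real_ else egg$intercept$estimate,
               egger_intercept_p = if (is.null(egg)) NA_real_ else egg$intercept$pvalue,
               stringsAsFactors = FALSE)
  }))
  rows$concordant <- sensitivity_concordance(rows)
  rownames(rows) <- NULL
  list(rows = rows, ivw = ests$ivw_fixed)
}

#' Directional concordance of the estimators in one cell
#'
#' `TRUE` when the point estimates of every method computed for a cell share
#' a single sign; an exact zero is concordant with either sign. Mirrors the
#' sensitivity check that the median estimators agree in direction with the
#' primary IVW estimate.
#'
#' @param records Data frame of grid rows for one cell (>= 2 methods for the
#'   flag to be meaningful) with a `beta` column.
#' @return Logical scalar.
#' @export
sensitivity_concordance <- function(records) {
  s <- sign(records$beta)
  s <- s[s != 0]
  length(s) == 0 || all(s == s[1])
}

#' Write the grid results and report tables
#'
#' Emits (a) `results_long.tsv`, one row per grid record in a fixed column
#' order; (b) `forest_overall.tsv` and `forest_by_sex.tsv`, forest-plot-ready
#' tables of the IVW estimates (exposure, outcome, stratum, OR, CI, p);
#' (c) `run_metadata.txt` echoing the configuration, seed, thresholds, and
#' package version; (d) `sex_differences.tsv` when stratified cells exist.
#'
#' @param grid An `mr_grid` from [run_grid()].
#' @param output_dir Output directory, created if needed; defaults to the
#'   configuration's `output_dir`.
#' @return Character vector of the files written, invisibly.
#' @export
write_results <- function(grid, output_dir = NULL) {
  if (nrow(grid) == 0) stop("no records to write", call. = FALSE)
  config <- attr(grid, "config")
  if (is.null(output_dir)) output_dir <- config$output_dir
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(output_dir)) {
    stop("cannot create output directory ", output_dir, call. = FALSE)
  }
  fmt <- function(df) {
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], function(x) {
      ifelse(is.na(x), NA_character_, formatC(x, digits = 15, format = "g"))
    })
    df
  }
  written <- character()
  emit <- function(df, name) {
    path <- file.path(output_dir, name)
    utils::write.table(fmt(df), path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
    written <<- c(written, path)
  }

  long_cols <- c("exposure", "outcome", "stratum", "method", "beta", "se",
                 "or_point", "ci_low", "ci_high", "pvalue", "n_snps",
                 "significance_class", "weak_instrument_flag",
                 "direction_note", "egger_intercept", "egger_intercept_p",
                 "concordant")
  emit(as.data.frame(grid)[, long_cols], "results_long.tsv")

  ivw <- grid[grid$method == "ivw_fixed", , drop = FALSE]
  forest_cols <- c("exposure", "outcome", "stratum", "or_point", "ci_low",
                   "ci_high", "pvalue", "significance_class")
  emit(as.data.frame(ivw[ivw$stratum == "all", forest_cols]),
       "forest_overall.tsv")
  by_sex <- ivw[ivw$stratum %in% c("male", "female"), forest_cols]
  if (nrow(by_sex)) emit(as.data.frame(by_sex), "forest_by_sex.tsv")
  sd <- attr(grid, "sex_differences")
  if (!is.null(sd) && nrow(sd)) emit(sd, "sex_differences.tsv")

  meta <- c(
    paste0("package_version: ", as.character(utils::packageVersion("ironmr"))),
    paste0("seed: ", config$seed),
    paste0("bootstrap_B: ", config$bootstrap_B),
    paste0("se_mode: ", config$se_mode),
    paste0("alpha_family: ", config$alpha_family),
    paste0("threshold_strict: ",
           formatC(attr(grid, "threshold_strict"), digits = 15, format = "g")),
    paste0("threshold_nominal: ", attr(grid, "threshold_nominal")),
    paste0("palindromic_policy: ", config$policy$palindromic),
    paste0("eaf_threshold: ", config$policy$eaf_threshold),
    paste0("methods: ", paste(config$methods, collapse = ",")),
    paste0("snp_filter: ", paste(config$snp_filter, collapse = ",")),
    paste0("n_exposures: ", nrow(config$exposures)),
    paste0("n_outcomes: ", length(config$outcomes)),
    paste0("n_records: ", nrow(grid)),
    paste0("n_failures: ", nrow(attr(grid, "failures")))
  )
  meta_path <- file.path(output_dir, "run_metadata.txt")
  writeLines(meta, meta_path)
  written <- c(written, meta_path)
  invisible(written)
}
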