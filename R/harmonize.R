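#' Harmonization policy
#'
#' Controls how allele orientation is reconciled between the exposure and
#' outcome summary statistics. Strand flips (A<->T, C<->G complements) are
#' always attempted when the literal allele pair does not match. Palindromic
#' SNPs (A/T or C/G), whose strand cannot be inferred from the alleles alone,
#' are handled per `palindromic`:
#'
#' * `"eaf_resolve"` (default): orient by comparing effect-allele frequencies;
#'   the SNP is dropped when either frequency is missing or lies within
#'   `eaf_threshold` of 0.5 (too close to be informative). rs1799945 is C/G
#'   palindromic with a strongly skewed frequency, so the default keeps the
#'   published three-SNP instrument intact while refusing genuinely ambiguous
#'   cases.
#' * `"keep"`: assume both studies report on the same strand and match
#'   literally.
#' * `"drop"`: exclude every palindromic SNP.
#'
#' @param palindromic One of `"eaf_resolve"`, `"keep"`, `"drop"`.
#' @param eaf_threshold Frequencies within this distance of 0.5 are treated as
#'   uninformative under `"eaf_resolve"`; default 0.08.
#' @return A `harmonization_policy` list.
#' @export
harmonization_policy <- function(palindromic = c("eaf_resolve", "keep", "drop"),
                                 eaf_threshold = 0.08) {
  palindromic <- match.arg(palindromic)
  stopifnot(eaf_threshold >= 0, eaf_threshold < 0.5)
  structure(list(palindromic = palindromic, eaf_threshold = eaf_threshold),
            class = "harmonization_policy")
}

.complement <- c(A = "T", T = "A", C = "G", G = "C")

.is_palindromic <- function(a1, a2) .complement[a1] == a2

#' Align outcome summary statistics to the exposure's effect alleles
#'
#' For each instrument SNP present in the outcome scan, reconciles the allele
#' orientation so that the exposure beta (gamma) and outcome beta (Gamma)
#' refer to the same allele: matching alleles pass through; swapped alleles
#' flip the outcome beta's sign and complement its frequency; alleles that
#' match only after strand complementation are complemented and re-matched;
#' palindromic SNPs are handled per the policy. Every action is recorded in
#' the orientation log. SNPs absent from the outcome are dropped with a
#' warning (sex-stratified releases may omit variants).
#'
#' @param instrument An [`instrument_set`][build_instrument].
#' @param outcome An [`outcome_set`][outcome_set].
#' @param policy A [harmonization_policy()].
#' @return A `harmonized_instrument`: list with `rsids`, `gamma`, `se_gamma`,
#'   `Gamma`, `se_Gamma`, `eaf_exposure`, `eaf_outcome` (post-alignment), and
#'   `orientation_log` (data frame: rsid, action, detail), plus the exposure
#'   and outcome labels carried through for reporting.
#' @export
harmonize <- function(instrument, outcome, policy = harmonization_policy()) {
  exp_v <- instrument$variants
  out_v <- outcome$variants
  log <- list()
  add_log <- function(rsid, action, detail = "") {
    log[[length(log) + 1L]] <<- data.frame(rsid = rsid, action = action,
                                           detail = detail,
                                           stringsAsFactors = FALSE)
  }
  keep <- logical(nrow(exp_v))
  Gamma <- se_Gamma <- eaf_out <- rep(NA_real_, nrow(exp_v))

  for (j in seq_len(nrow(exp_v))) {
    rsid <- exp_v$rsid[j]
    k <- match(rsid, out_v$rsid)
    if (is.na(k)) {
      warning("SNP ", rsid, " absent from outcome ", outcome$outcome_name,
              " (", outcome$stratum, "); dropped", call. = FALSE)
      add_log(rsid, "dropped", "absent from outcome")
      next
    }
    ea <- exp_v$effect_allele[j]; oa <- exp_v$other_allele[j]
    EA <- out_v$effect_allele[k]; OA <- out_v$other_allele[k]
    b <- out_v$beta[k]; s <- out_v$se[k]; f <- out_v$eaf[k]

    if (.is_palindromic(ea, oa)) {
      res <- .orient_palindromic(rsid, ea, exp_v$eaf[j], EA, OA, b, f,
                                 policy, add_log)
      if (is.null(res)) next
      Gamma[j] <- res$beta; se_Gamma[j] <- s; eaf_out[j] <- res$eaf
      keep[j] <- TRUE
      next
    }

    if (EA == ea && OA == oa) {
      add_log(rsid, "passthrough")
    } else if (EA == oa && OA == ea) {
      b <- -b; f <- if (is.na(f)) f else 1 - f
      add_log(rsid, "allele_swap", "outcome beta sign flipped")
    } else {
      EAc <- .complement[[EA]]; OAc <- .complement[[OA]]
      if (EAc == ea && OAc == oa) {
        add_log(rsid, "strand_flip")
      } else if (EAc == oa && OAc == ea) {
        b <- -b; f <- if (is.na(f)) f else 1 - f
        add_log(rsid, "strand_flip_and_swap", "outcome beta sign flipped")
      } else {
        stop("incompatible alleles for ", rsid, ": exposure ", ea, "/", oa,
             " vs outcome ", EA, "/", OA, call. = FALSE)
      }
    }
    Gamma[j] <- b; se_Gamma[j] <- s; eaf_out[j] <- f
    keep[j] <- TRUE
  }

  if (!any(keep)) {
    stop("harmonization left an empty instrument for ", outcome$outcome_name,
         " (", outcome$stratum, ")", call. = FALSE)
  }
  log_df <- do.call(rbind, log)
  structure(
    list(rsids = exp_v$rsid[keep],
         gamma = exp_v$beta[keep],
         se_gamma = exp_v$se[keep],
         Gamma = Gamma[keep],
         se_Gamma = se_Gamma[keep],
         eaf_exposure = exp_v$eaf[keep],
         eaf_outcome = eaf_out[keep],
         exposure_name = instrument$exposure_name,
         direction_flag = instrument$direction_flag,
         outcome_name = outcome$outcome_name,
         stratum = outcome$stratum,
         orientation_log = log_df),
    class = "harmonized_instrument"
  )
}

# Palindromic orientation. Alleles are strand-symmetric so only the
# effect/other labelling can be compared; under eaf_resolve the orientation
# is taken from whether the two studies' effect-allele frequencies sit on the
# same side of 0.5. Returns list(beta, eaf) or NULL when the SNP is dropped.
.orient_palindromic <- function(rsid, ea, f_exp, EA, OA, b, f_out,
                                policy, add_log) {
  if (!(EA %in% c(ea, .complement[[ea]]) && OA %in% c(ea, .complement[[ea]]))) {
    stop("incompatible alleles for palindromic SNP ", rsid, call. = FALSE)
  }
  if (policy$palindromic == "drop") {
    add_log(rsid, "dropped", "palindromic (policy: drop)")
    return(NULL)
  }
  if (policy$palindromic == "keep") {
    if (EA == ea) {
      add_log(rsid, "passthrough", "palindromic kept as-is")
      return(list(beta = b, eaf = f_out))
    }
    add_log(rsid, "allele_swap", "palindromic, literal swap")
    return(list(beta = -b, eaf = if (is.na(f_out)) f_out else 1 - f_out))
  }
  # eaf_resolve
  thr <- policy$eaf_threshold
  informative <- function(f) !is.na(f) && abs(f - 0.5) > thr
  if (!informative(f_exp) || !informative(f_out)) {
    add_log(rsid, "dropped",
            sprintf("palindromic, frequency uninformative (within %.2f of 0.5 or missing)", thr))
    return(NULL)
  }
  if ((f_exp < 0.5) == (f_out < 0.5)) {
    add_log(rsid, "passthrough",
            "palindromic, orientation inferred from frequency agreement")
    list(beta = b, eaf = f_out)
  } else {
    add_log(rsid, "allele_swap",
            "palindromic, frequencies disagree: outcome beta sign flipped")
    list(beta = -b, eaf = 1 - f_out)
  }
}

#' Orient a harmonized instrument so every exposure beta is positive
#'
#' MR-Egger regression is only identified up to the coding of each variant;
#' the convention is to code alleles so each SNP increases the exposure. For
#' every SNP with a negative exposure beta, both the exposure and outcome
#' betas are negated (a joint sign flip that leaves every Wald ratio
#' unchanged).
#'
#' @param h A `harmonized_instrument`.
#' @return The same object with all `gamma > 0` and flips appended to the
#'   orientation log.
#' @export
orient_to_exposure_increasing <- function(h) {
  if (any(h$gamma == 0)) {
    stop("degenerate instrument: zero exposure beta for ",
         paste(h$rsids[h$gamma == 0], collapse = ", "), call. = FALSE)
  }
  neg <- h$gamma < 0
  if (any(neg)) {
    h$gamma[neg] <- -h$gamma[neg]
    h$Gamma[neg] <- -h$Gamma[neg]
    h$eaf_exposure[neg] <- 1 - h$eaf_exposure[neg]
    h$eaf_outcome[neg] <- 1 - h$eaf_outcome[neg]
    flips <- data.frame(rsid = h$rsids[neg], action = "exposure_reorient",
                        detail = "gamma and Gamma jointly negated",
                        stringsAsFactors = FALSE)
    h$orientation_log <- rbind(h$orientation_log, flips)
  }
  h
}

#' Per-SNP instrument-strength F statistics
#'
#' The strength of each variant as an instrument is summarized by
#' F_j = (gamma_j / se_gamma_j)^2, the squared z-statistic of the
#' SNP-exposure association. F below 10 is the conventional weak-instrument
#' threshold; the three-SNP iron instrument sits far above it.
#'
#' @param h A `harmonized_instrument`.
#' @param weak_threshold Flagging threshold, default 10.
#' @return Data frame with columns `rsid`, `F`, `weak` (logical flag).
#' @export
instrument_strength <- function(h, weak_threshold = 10) {
  stopifnot(all(h$se_gamma > 0))
  F_stat <- (h$gamma / h$se_gamma)^2
  data.frame(rsid = h$rsids, F = F_stat, weak = F_stat < weak_threshold,
             stringsAsFactors = FALSE)
}

#' @export
print.harmonized_instrument <- function(x, ...) {
  cat("Harmonized instrument:", x$exposure_name, "->", x$outcome_name,
      paste0("(", x$stratum, ")"), "-", length(x$rsids), "SNP(s)\n")
  print(data.frame(rsid = x$rsids, gamma = x$gamma, se_gamma = x$se_gamma,
                   Gamma = x$Gamma, se_Gamma = x$se_Gamma))
  invisible(x)
}

#' Write the harmonization audit log
#'
#' One line per SNP per action, tab-separated.
#'
#' @param h A `harmonized_instrument`.
#' @param path Output path; the file is appended to if it exists.
#' @return `path`, invisibly.
#' @export
write_orientation_log <- function(h, path) {
  log <- h$orientation_log
  log$exposure <- h$exposure_name
  log$outcome <- h$outcome_name
  log$stratum <- h$stratum
  log <- log[, c("exposure", "outcome", "stratum", "rsid", "action", "detail")]
  new <- !file.exists(path)
  suppressWarnings(
    utils::write.table(log, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = new, append = !new)
  )
  invisible(path)
}
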