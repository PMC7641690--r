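#' Per-SNP Wald ratio with delta-method standard error
#'
#' The causal effect identified by a single variant is the ratio of its
#' outcome association to its exposure association, theta_j = Gamma_j /
#' gamma_j. Its standard error comes from the delta method in one of two
#' conventions:
#'
#' * `"full_delta"` (default): propagates both sampling errors,
#'   `se = sqrt(se_Gamma^2 / gamma^2 + Gamma^2 * se_gamma^2 / gamma^4)`.
#' * `"first_order"`: treats the exposure association as known,
#'   `se = se_Gamma / |gamma|`. Under this convention fixed-effect IVW
#'   pooling coincides exactly with weighted regression through the origin.
#'
#' All arguments are vectorized over SNPs.
#'
#' @param gamma,se_gamma SNP-exposure betas and standard errors.
#' @param Gamma,se_Gamma SNP-outcome betas and standard errors.
#' @param se_mode `"full_delta"` or `"first_order"`.
#' @param rsid Optional rsIDs carried into the result and error messages.
#' @return Data frame with columns `rsid`, `ratio`, `se`.
#' @export
wald_ratio <- function(gamma, se_gamma, Gamma, se_Gamma,
                       se_mode = c("full_delta", "first_order"),
                       rsid = NULL) {
  se_mode <- match.arg(se_mode)
  if (is.null(rsid)) rsid <- paste0("snp", seq_along(gamma))
  if (any(gamma == 0)) {
    stop("Wald ratio undefined (zero exposure beta) for ",
         paste(rsid[gamma == 0], collapse = ", "), call. = FALSE)
  }
  stopifnot(all(se_Gamma > 0), all(se_gamma >= 0))
  ratio <- Gamma / gamma
  se <- switch(se_mode,
    full_delta = sqrt(se_Gamma^2 / gamma^2 + Gamma^2 * se_gamma^2 / gamma^4),
    first_order = se_Gamma / abs(gamma)
  )
  data.frame(rsid = rsid, ratio = ratio, se = se, stringsAsFactors = FALSE)
}

.wald_from_h <- function(h, se_mode) {
  wald_ratio(h$gamma, h$se_gamma, h$Gamma, h$se_Gamma,
             se_mode = se_mode, rsid = h$rsids)
}

# Common constructor: pooled beta/se -> odds-scale estimate record.
.mr_estimate <- function(method, beta, se, n_snps, level = 0.95,
                         extras = list()) {
  odds <- to_odds_scale(beta, se, level = level)
  structure(
    list(method = method, beta = beta, se = se,
         or_point = odds$or_point, ci_low = odds$ci_low,
         ci_high = odds$ci_high, pvalue = odds$pvalue,
         n_snps = n_snps, level = level, extras = extras),
    class = "mr_estimate"
  )
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("%s: beta %.4g (se %.4g), OR %.4f (%.0f%% CI %.4f-%.4f), p %.3g, %d SNP(s)\n",
              x$method, x$beta, x$se, x$or_point, 100 * x$level,
              x$ci_low, x$ci_high, x$pvalue, x$n_snps))
  invisible(x)
}

#' Fixed-effect inverse-variance weighted estimate
#'
#' Pools the per-SNP Wald ratios with weights w_j = 1/se(theta_j)^2 under a
#' fixed-effect model (one common causal effect): beta = sum(w theta) /
#' sum(w), se = (sum w)^(-1/2), two-sided normal p-value. This is the primary
#' estimator of the pipeline.
#'
#' @param h A `harmonized_instrument`.
#' @param se_mode Delta-method convention, see [wald_ratio()].
#' @param level Confidence level for the odds-scale interval.
#' @return An `mr_estimate` with method `"ivw_fixed"`.
#' @export
ivw_fixed <- function(h, se_mode = c("full_delta", "first_order"),
                      level = 0.95) {
  se_mode <- match.arg(se_mode)
  w <- .wald_from_h(h, se_mode)
  wt <- 1 / w$se^2
  beta <- sum(wt * w$ratio) / sum(wt)
  se <- 1 / sqrt(sum(wt))
  .mr_estimate("ivw_fixed", beta, se, n_snps = nrow(w), level = level,
               extras = list(se_mode = se_mode))
}

#' Simple median estimate with parametric-bootstrap standard error
#'
#' The median of the per-SNP Wald ratios is consistent when at least half of
#' the instruments are valid. Its standard error is estimated by a seeded
#' parametric bootstrap: each replicate draws theta*_j ~ Normal(theta_j,
#' se(theta_j)^2) and takes the median; the reported se is the standard
#' deviation of the replicate medians.
#'
#' @param h A `harmonized_instrument`.
#' @param B Number of bootstrap replicates (>= 100); default 5000.
#' @param seed Integer seed; required so results are reproducible.
#' @param se_mode Delta-method convention for the per-SNP ratio SEs.
#' @param level Confidence level.
#' @return An `mr_estimate` with method `"simple_median"`.
#' @export
simple_median <- function(h, B = 5000, seed,
                          se_mode = c("full_delta", "first_order"),
                          level = 0.95) {
  se_mode <- match.arg(se_mode)
  if (B < 100) stop("bootstrap requires B >= 100 replicates", call. = FALSE)
  if (missing(seed)) stop("a seed is required for the bootstrap", call. = FALSE)
  w <- .wald_from_h(h, se_mode)
  J <- nrow(w)
  if (J < 3) warning("simple median with fewer than 3 SNPs is fragile",
                     call. = FALSE)
  beta <- stats::median(w$ratio)
  se <- withr_seed(seed, {
    draws <- matrix(stats::rnorm(J * B, mean = w$ratio, sd = w$se),
                    nrow = J, ncol = B)
    stats::sd(apply(draws, 2, stats::median))
  })
  .mr_estimate("simple_median", beta, se, n_snps = J, level = level,
               extras = list(B = B, seed = seed, se_mode = se_mode))
}

# Evaluate an expression under a local RNG state (restores the caller's).
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Weighted median of per-SNP ratios
#'
#' Sorts the ratios, normalizes the weights to sum one, forms the
#' standardized cumulative weights s_j = (sum_{i<=j} w_i) - w_j/2, and
#' linearly interpolates the ratio at which s crosses 0.5; if 0.5 falls
#' outside [s_1, s_J] the extreme ratio is returned. With equal weights this
#' reduces to the simple median (interpolated for even counts).
#'
#' @param ratios Numeric vector of per-SNP ratio estimates.
#' @param weights Positive weights, same length.
#' @return The weighted median point estimate.
#' @export
weighted_median_point <- function(ratios, weights) {
  if (length(ratios) == 0) stop("empty input to weighted median", call. = FALSE)
  stopifnot(length(ratios) == length(weights), all(weights > 0))
  ord <- order(ratios)
  x <- ratios[ord]
  w <- weights[ord] / sum(weights)
  s <- cumsum(w) - w / 2
  if (0.5 <= s[1]) return(x[1])
  if (0.5 >= s[length(s)]) return(x[length(x)])
  k <- max(which(s <= 0.5))
  x[k] + (x[k + 1] - x[k]) * (0.5 - s[k]) / (s[k + 1] - s[k])
}

#' Weighted median estimate with parametric-bootstrap standard error
#'
#' The inverse-variance weighted median: [weighted_median_point()] with
#' weights w_j = 1/se(theta_j)^2. It is consistent when valid instruments
#' carry at least half of the total weight. The bootstrap re-draws the
#' SNP-exposure and SNP-outcome betas from their sampling distributions and
#' recomputes the ratios, their SEs, and hence the weights in every
#' replicate.
#'
#' @inheritParams simple_median
#' @return An `mr_estimate` with method `"weighted_median"`.
#' @export
weighted_median <- function(h, B = 5000, seed,
                            se_mode = c("full_delta", "first_order"),
                            level = 0.95) {
  se_mode <- match.arg(se_mode)
  if (B < 100) stop("bootstrap requires B >= 100 replicates", call. = FALSE)
  if (missing(seed)) stop("a seed is required for the bootstrap", call. = FALSE)
  w <- .wald_from_h(h, se_mode)
  J <- nrow(w)
  if (J < 3) warning("weighted median with fewer than 3 SNPs is fragile",
                     call. = FALSE)
  beta <- weighted_median_point(w$ratio, 1 / w$se^2)
  se <- withr_seed(seed, {
    g_star <- matrix(stats::rnorm(J * B, mean = h$gamma, sd = h$se_gamma),
                     nrow = J)
    G_star <- matrix(stats::rnorm(J * B, mean = h$Gamma, sd = h$se_Gamma),
                     nrow = J)
    est <- vapply(seq_len(B), function(b) {
      g <- g_star[, b]
      if (any(g == 0)) g[g == 0] <- .Machine$double.eps
      wb <- wald_ratio(g, h$se_gamma, G_star[, b], h$se_Gamma,
                       se_mode = se_mode)
      weighted_median_point(wb$ratio, 1 / wb$se^2)
    }, numeric(1))
    stats::sd(est)
  })
  .mr_estimate("weighted_median", beta, se, n_snps = J, level = level,
               extras = list(B = B, seed = seed, se_mode = se_mode))
}

#' MR-Egger regression
#'
#' Weighted least squares of the outcome betas on the exposure betas with an
#' unconstrained intercept, weights 1/se(Gamma_j)^2. The slope is a
#' pleiotropy-adjusted causal estimate; the intercept estimates the average
#' directional pleiotropic effect, and its test against zero is the standard
#' check for directional pleiotropy. Requires the instrument to be oriented
#' so every exposure beta is positive (see [orient_to_exposure_increasing()])
#' and at least three SNPs. Inference uses normal quantiles on the
#' fixed-effect (unscaled) WLS covariance; with exactly three SNPs only one
#' residual degree of freedom remains and the result is flagged `low_df`.
#'
#' @param h A `harmonized_instrument`, oriented exposure-increasing.
#' @param level Confidence level.
#' @return An `egger_result`: list with `slope` (an `mr_estimate` of method
#'   `"egger_slope"`) and `intercept` (list: estimate, se, pvalue), plus a
#'   `low_df` flag.
#' @export
egger <- function(h, level = 0.95) {
  J <- length(h$gamma)
  if (J < 3) {
    stop("MR-Egger requires at least 3 SNPs (got ", J, ")", call. = FALSE)
  }
  if (any(h$gamma <= 0)) {
    stop("MR-Egger requires an exposure-increasing orientation; ",
         "call orient_to_exposure_increasing() first", call. = FALSE)
  }
  wt <- 1 / h$se_Gamma^2
  fit <- stats::lm(h$Gamma ~ h$gamma, weights = wt)
  coefs <- stats::coef(fit)
  # Fixed-effect convention: covariance (X'WX)^{-1} without the residual
  # variance factor, consistent with known per-SNP outcome SEs.
  cov_unscaled <- summary(fit)$cov.unscaled
  ses <- sqrt(diag(cov_unscaled))
  p <- 2 * stats::pnorm(-abs(coefs / ses))
  slope <- .mr_estimate("egger_slope", unname(coefs[2]), unname(ses[2]),
                        n_snps = J, level = level,
                        extras = list(low_df = J == 3))
  structure(
    list(slope = slope,
         intercept = list(estimate = unname(coefs[1]), se = unname(ses[1]),
                          pvalue = unname(p[1])),
         low_df = J == 3),
    class = "egger_result"
  )
}

#' @export
print.egger_result <- function(x, ...) {
  print(x$slope)
  cat(sprintf("  intercept %.4g (se %.4g), p %.3g%s\n",
              x$intercept$estimate, x$intercept$se, x$intercept$pvalue,
              if (x$low_df) " [low df: J = 3]" else ""))
  invisible(x)
}

#' Transform a log-scale estimate to the odds-ratio scale
#'
#' OR = exp(beta) with a Wald confidence interval exp(beta +/- z * se) and a
#' two-sided normal p-value. Note the outcome betas from linear-model scans of
#' binary traits are only approximately log-odds, so these ORs inherit that
#' approximation.
#'
#' @param beta,se Estimate and standard error on the log/beta scale.
#' @param level Confidence level in (0,1), default 0.95.
#' @return List: `or_point`, `ci_low`, `ci_high`, `pvalue`.
#' @export
to_odds_scale <- function(beta, se, level = 0.95) {
  if (level <= 0 || level >= 1) {
    stop("confidence level must be in (0,1)", call. = FALSE)
  }
  stopifnot(se > 0)
  z <- stats::qnorm((1 + level) / 2)
  list(or_point = exp(beta),
       ci_low = exp(beta - z * se),
       ci_high = exp(beta + z * se),
       pvalue = 2 * stats::pnorm(-abs(beta / se)))
}

#' Compare a male and a female estimate of the same association
#'
#' Two-sample z-test for a sex difference between stratified causal
#' estimates: z = (beta_m - beta_f) / sqrt(se_m^2 + se_f^2), two-sided normal
#' p-value. Exploratory: not multiplicity-corrected.
#'
#' @param est_male,est_female `mr_estimate` objects from the same method.
#' @return List: `z`, `pvalue`.
#' @export
sex_difference_test <- function(est_male, est_female) {
  if (!identical(est_male$method, est_female$method)) {
    stop("sex-difference test requires estimates from the same method (got ",
         est_male$method, " vs ", est_female$method, ")", call. = FALSE)
  }
  z <- (est_male$beta - est_female$beta) /
    sqrt(est_male$se^2 + est_female$se^2)
  list(z = z, pvalue = 2 * stats::pnorm(-abs(z)))
}
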