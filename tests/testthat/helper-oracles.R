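# Independent oracles, kept deliberately naive and separate from the
# package's own code paths.

# Brute-force inverse-variance weighted mean of per-SNP ratios.
oracle_ivw <- function(ratios, ses) {
  w <- 1 / ses^2
  list(beta = sum(w * ratios) / sum(w), se = sqrt(1 / sum(w)))
}

# Weighted least squares with intercept via explicit normal equations;
# covariance is the unscaled (X'WX)^{-1}, matching known per-point SEs.
oracle_wls <- function(x, y, w) {
  X <- cbind(1, x)
  XtWX <- t(X) %*% (w * X)
  coef <- solve(XtWX, t(X) %*% (w * y))
  list(intercept = coef[1], slope = coef[2],
       se = unname(sqrt(diag(solve(XtWX)))))
}

# Weighted median by root-finding on the piecewise-linear standardized
# cumulative-weight function S(theta), independent of the package's
# closed-form interpolation.
oracle_weighted_median <- function(ratios, weights) {
  ord <- order(ratios)
  x <- ratios[ord]
  w <- weights[ord] / sum(weights)
  s <- cumsum(w) - w / 2
  if (0.5 <= s[1]) return(x[1])
  if (0.5 >= s[length(s)]) return(x[length(x)])
  S <- stats::approxfun(x, s, rule = 2, ties = "ordered")
  stats::uniroot(function(t) S(t) - 0.5, range(x), tol = 1e-14)$root
}

# Standardized cumulative-weight function S(theta) of the weighted median,
# evaluated by interpolation; the estimator is the root of S(theta) = 0.5.
wm_cumweight <- function(theta, ratios, weights) {
  ord <- order(ratios)
  x <- ratios[ord]
  w <- weights[ord] / sum(weights)
  s <- cumsum(w) - w / 2
  stats::approx(x, s, xout = theta, rule = 2, ties = "ordered")$y
}

# Monte-Carlo standard deviation of a ratio of independent normals.
oracle_ratio_sd <- function(gamma, se_gamma, Gamma, se_Gamma,
                            n = 1e6, seed = 42) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  g <- rnorm(n, gamma, se_gamma)
  G <- rnorm(n, Gamma, se_Gamma)
  sd(G / g)
}

# A tiny aligned harmonized instrument built directly, bypassing file I/O.
make_h <- function(gamma, se_gamma, Gamma, se_Gamma,
                   rsids = paste0("rs", seq_along(gamma))) {
  structure(
    list(rsids = rsids, gamma = gamma, se_gamma = se_gamma,
         Gamma = Gamma, se_Gamma = se_Gamma,
         eaf_exposure = rep(0.3, length(gamma)),
         eaf_outcome = rep(0.3, length(gamma)),
         exposure_name = "exposure", direction_flag = TRUE,
         outcome_name = "outcome", stratum = "all",
         orientation_log = data.frame(rsid = character(),
                                      action = character(),
                                      detail = character())),
    class = "harmonized_instrument")
}

# Write a variant table to a temp file in canonical columns.
write_assoc <- function(df, path = tempfile(fileext = ".tsv")) {
  full <- data.frame(rsid = df$rsid, effect_allele = df$effect_allele,
                     other_allele = df$other_allele, beta = df$beta,
                     se = df$se,
                     eaf = if ("eaf" %in% names(df)) df$eaf else NA,
                     n = if ("n" %in% names(df)) df$n else NA,
                     pvalue = if ("pvalue" %in% names(df)) df$pvalue else NA)
  write.table(full, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
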