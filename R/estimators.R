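# Two-sample MR estimators: Wald ratio, IVW (fixed / multiplicative
# random effects), MR-Egger, weighted median.

# One result row shared by every estimator. Intercept columns are NA except
# for MR-Egger.
mr_result_row <- function(method, n_snps, beta, se,
                          intercept = NA_real_, intercept_se = NA_real_) {
  z <- beta / se
  ci <- beta + c(-1, 1) * stats::qnorm(0.975) * se
  intercept_pval <- if (is.na(intercept)) NA_real_ else z_pval(intercept / intercept_se)
  data.frame(method = method, n_snps = as.integer(n_snps),
             beta = beta, se = se, ci_low = ci[1], ci_high = ci[2],
             pval = z_pval(z),
             or = exp(beta), or_ci_low = exp(ci[1]), or_ci_high = exp(ci[2]),
             intercept = intercept, intercept_se = intercept_se,
             intercept_pval = intercept_pval,
             stringsAsFactors = FALSE)
}

as_hs <- function(set) {
  stopifnot(is.data.frame(set),
            all(c("gamma", "se_gamma", "Gamma", "se_Gamma") %in% names(set)))
  set
}

#' Wald ratio for a single instrument
#'
#' `beta = Gamma / gamma` with the first-order standard error
#' `se = se_Gamma / |gamma|`.
#'
#' @param gamma,se_gamma SNP-exposure effect and standard error.
#' @param Gamma,se_Gamma SNP-outcome effect and standard error.
#' @return A one-row MR result data frame.
#' @export
wald_ratio <- function(gamma, se_gamma, Gamma, se_Gamma) {
  if (gamma == 0) stop("Wald ratio undefined for gamma = 0", call. = FALSE)
  mr_result_row("wald", 1L, Gamma / gamma, se_Gamma / abs(gamma))
}

#' Inverse-variance-weighted estimate
#'
#' Combines per-SNP Wald ratios `b_j = Gamma_j / gamma_j` with weights
#' `w_j = gamma_j^2 / se_Gamma_j^2`, which is algebraically the weighted
#' least-squares regression of `Gamma` on `gamma` through the origin with
#' weights `1 / se_Gamma^2`. Under `"multiplicative_random"` the standard
#' error is inflated by `sqrt(max(1, Q / (J - 1)))` where Q is Cochran's Q,
#' so heterogeneity can only widen the interval.
#'
#' @param set A `harmonized_set` (J >= 2; J = 1 falls back to the Wald
#'   ratio).
#' @param mode `"fixed"` or `"multiplicative_random"`.
#' @return A one-row MR result with attribute `Q` (Cochran's Q on the IVW
#'   basis, `NA` for J = 1).
#' @export
mr_ivw <- function(set, mode = c("fixed", "multiplicative_random")) {
  mode <- match.arg(mode)
  set <- as_hs(set)
  J <- nrow(set)
  if (J < 1) stop("empty instrument set", call. = FALSE)
  if (any(set$gamma == 0)) {
    stop("gamma = 0 instrument present; filter upstream", call. = FALSE)
  }
  if (J == 1L) {
    res <- wald_ratio(set$gamma, set$se_gamma, set$Gamma, set$se_Gamma)
    attr(res, "Q") <- NA_real_
    return(res)
  }
  w <- set$gamma^2 / set$se_Gamma^2
  b <- set$Gamma / set$gamma
  beta <- sum(w * b) / sum(w)
  se <- 1 / sqrt(sum(w))
  Q <- sum(w * (b - beta)^2)
  if (mode == "multiplicative_random") se <- se * sqrt(max(1, Q / (J - 1)))
  method <- if (mode == "fixed") "ivw_fe" else "ivw_mre"
  res <- mr_result_row(method, J, beta, se)
  attr(res, "Q") <- Q
  res
}

#' MR-Egger regression
#'
#' Orients every SNP so that `gamma_j >= 0` (negating both effects where
#' needed), then fits the weighted regression
#' `Gamma_j = intercept + beta * gamma_j` with weights `1 / se_Gamma_j^2`.
#' The slope is the causal estimate; a non-zero intercept indicates
#' directional pleiotropy. Under `"multiplicative_random"` both standard
#' errors are scaled by `sqrt(max(1, Q_E / (J - 2)))` with `Q_E` the
#' weighted residual sum of squares.
#'
#' @param set A `harmonized_set` with J >= 3.
#' @param mode `"fixed"` or `"multiplicative_random"`.
#' @return A one-row MR result including `intercept`, `intercept_se` and
#'   `intercept_pval`, with attribute `Q` (= `Q_E`).
#' @export
mr_egger <- function(set, mode = c("fixed", "multiplicative_random")) {
  mode <- match.arg(mode)
  set <- as_hs(set)
  J <- nrow(set)
  if (J < 3) stop("MR-Egger requires at least 3 instruments", call. = FALSE)
  flip <- set$gamma < 0
  x <- ifelse(flip, -set$gamma, set$gamma)
  y <- ifelse(flip, -set$Gamma, set$Gamma)
  w <- 1 / set$se_Gamma^2

  sw <- sum(w); sx <- sum(w * x); sxx <- sum(w * x^2)
  sy <- sum(w * y); sxy <- sum(w * x * y)
  det <- sw * sxx - sx^2
  if (det <= .Machine$double.eps * sw * sxx) {
    stop("no variance in gamma: Egger regression is collinear", call. = FALSE)
  }
  slope <- (sw * sxy - sx * sy) / det
  intercept <- (sxx * sy - sx * sxy) / det
  var_slope <- sw / det
  var_int <- sxx / det
  Q_E <- sum(w * (y - intercept - slope * x)^2)
  scale <- if (mode == "multiplicative_random") sqrt(max(1, Q_E / (J - 2))) else 1
  res <- mr_result_row("egger", J, slope, sqrt(var_slope) * scale,
                       intercept = intercept,
                       intercept_se = sqrt(var_int) * scale)
  attr(res, "Q") <- Q_E
  res
}

# Weighted-median point estimate: order the ratios, normalize the weights,
# interpolate the cumulative-weight midpoints at 0.5. Below the first or
# above the last midpoint the extreme ratio is returned (no extrapolation).
weighted_median_point <- function(b, w) {
  ord <- order(b)
  b <- b[ord]
  p <- cumsum(w[ord]) / sum(w) - w[ord] / (2 * sum(w))
  if (0.5 <= p[1]) return(b[1])
  if (0.5 >= p[length(p)]) return(b[length(b)])
  stats::approx(p, b, xout = 0.5, ties = "ordered")$y
}

#' Weighted-median estimate with parametric-bootstrap standard error
#'
#' The point estimate interpolates the inverse-variance-weighted empirical
#' distribution of the per-SNP ratios at its median; it is consistent when
#' at least half the weight comes from valid instruments. The standard
#' error is the standard deviation of the point estimate across `n_boot`
#' parametric-bootstrap replicates drawing
#' `gamma* ~ N(gamma, se_gamma)` and `Gamma* ~ N(Gamma, se_Gamma)` per SNP.
#'
#' @param set A `harmonized_set` with J >= 3.
#' @param n_boot Bootstrap replicates (default 1000).
#' @param seed Optional seed making the bootstrap reproducible.
#' @return A one-row MR result.
#' @export
mr_weighted_median <- function(set, n_boot = 1000, seed = NULL) {
  set <- as_hs(set)
  J <- nrow(set)
  if (J < 3) stop("weighted median requires at least 3 instruments", call. = FALSE)
  if (any(set$gamma == 0)) stop("gamma = 0 instrument present", call. = FALSE)
  w <- set$gamma^2 / set$se_Gamma^2
  est <- weighted_median_point(set$Gamma / set$gamma, w)
  boots <- with_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      g <- stats::rnorm(J, set$gamma, set$se_gamma)
      G <- stats::rnorm(J, set$Gamma, set$se_Gamma)
      g[g == 0] <- .Machine$double.eps
      weighted_median_point(G / g, g^2 / set$se_Gamma^2)
    }, numeric(1))
  })
  mr_result_row("weighted_median", J, est, stats::sd(boots))
}

#' Run the full estimator battery on one harmonized set
#'
#' Headline inverse-variance-weighted estimate (fixed effects, escalated to
#' multiplicative random effects when Cochran's Q has p < `q_alpha`),
#' plus the weighted median and MR-Egger as supplementary analyses when
#' enough instruments are available. With a single instrument only the
#' Wald ratio is reported.
#'
#' @param set A `harmonized_set`.
#' @param q_alpha Heterogeneity escalation level (default 0.05).
#' @param n_boot Bootstrap replicates for the weighted median.
#' @param seed Seed for the bootstrap.
#' @return Data frame with one row per method; attribute `q_ivw` carries
#'   the IVW-basis Cochran Q statistics.
#' @export
mr_estimates <- function(set, q_alpha = 0.05, n_boot = 1000, seed = NULL) {
  set <- as_hs(set)
  J <- nrow(set)
  if (J == 1L) {
    res <- wald_ratio(set$gamma, set$se_gamma, set$Gamma, set$se_Gamma)
    attr(res, "q_ivw") <- NULL
    return(res)
  }
  q <- cochran_q(set, basis = "ivw")
  mode <- if (q$pval < q_alpha) "multiplicative_random" else "fixed"
  rows <- list(mr_ivw(set, mode = mode))
  if (J >= 3) {
    rows <- c(rows, list(mr_weighted_median(set, n_boot = n_boot, seed = seed),
                         mr_egger(set)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "q_ivw") <- q
  out
}
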