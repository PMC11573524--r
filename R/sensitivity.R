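# Heterogeneity, influence and pleiotropic-outlier diagnostics.

#' Cochran's Q heterogeneity statistic
#'
#' On the IVW basis, `Q = sum w_j (b_j - beta_ivw)^2` with
#' `w_j = gamma_j^2 / se_Gamma_j^2` and J - 1 degrees of freedom. On the
#' Egger basis, Q is the weighted residual sum of squares about the Egger
#' fit with J - 2 degrees of freedom. The p-value is the upper tail of the
#' corresponding chi-squared distribution.
#'
#' @param set A `harmonized_set`.
#' @param basis `"ivw"` (J >= 2) or `"egger"` (J >= 3).
#' @return List with `Q`, `df`, `pval`.
#' @export
cochran_q <- function(set, basis = c("ivw", "egger")) {
  basis <- match.arg(basis)
  set <- as_hs(set)
  J <- nrow(set)
  if (basis == "ivw") {
    if (J < 2) stop("Q on the IVW basis requires J >= 2", call. = FALSE)
    w <- set$gamma^2 / set$se_Gamma^2
    b <- set$Gamma / set$gamma
    beta <- sum(w * b) / sum(w)
    Q <- sum(w * (b - beta)^2)
    df <- J - 1
  } else {
    if (J < 3) stop("Q on the Egger basis requires J >= 3", call. = FALSE)
    Q <- attr(mr_egger(set), "Q")
    df <- J - 2
  }
  list(Q = Q, df = df, pval = stats::pchisq(Q, df, lower.tail = FALSE))
}

#' Leave-one-out influence analysis
#'
#' Re-estimates the IVW effect J times, each time omitting one instrument.
#' An omission is flagged when it flips whether the 95% CI excludes zero,
#' or when it moves the estimate by more than `shift_frac` of the full-set
#' CI half-width.
#'
#' @param set A `harmonized_set` with J >= 3.
#' @param mode IVW mode passed through to [mr_ivw()].
#' @param shift_frac Estimate-shift flag threshold as a fraction of the
#'   full-set CI half-width (default 0.5).
#' @return Data frame with one row per left-out SNP (`excluded_snp`,
#'   estimate columns, `flag`); the full-set result is attached as the
#'   `"full"` attribute.
#' @export
leave_one_out <- function(set, mode = "fixed", shift_frac = 0.5) {
  set <- as_hs(set)
  J <- nrow(set)
  if (J < 3) stop("leave-one-out requires J >= 3", call. = FALSE)
  full <- mr_ivw(set, mode = mode)
  half_width <- (full$ci_high - full$ci_low) / 2
  full_excl0 <- full$ci_low > 0 || full$ci_high < 0
  rows <- lapply(seq_len(J), function(j) {
    res <- mr_ivw(set[-j, , drop = FALSE], mode = mode)
    excl0 <- res$ci_low > 0 || res$ci_high < 0
    cbind(data.frame(excluded_snp = set$snp_id[j], stringsAsFactors = FALSE),
          res[c("n_snps", "beta", "se", "ci_low", "ci_high", "pval")],
          data.frame(flag = (excl0 != full_excl0) ||
                       abs(res$beta - full$beta) > shift_frac * half_width))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "full") <- full
  out
}

# Leave-one-out IVW slopes and scaled squared residuals, vectorized over
# simulation replicates. G, Y are n x J matrices of exposure/outcome
# effects; se_G the length-J outcome standard errors. Returns the n x J
# matrix of (Y_j - G_j * beta_{-j})^2 / se_G_j^2.
presso_rss_matrix <- function(G, Y, se_G) {
  inv_v <- matrix(1 / se_G^2, nrow(G), ncol(G), byrow = TRUE)
  w <- G^2 * inv_v
  wb <- G * Y * inv_v            # w_j * b_j without dividing by gamma
  beta_loo <- (rowSums(wb) - wb) / (rowSums(w) - w)
  (Y - G * beta_loo)^2 * inv_v
}

#' Simulation-based global, outlier and distortion tests
#'
#' Detects pleiotropic outlier instruments by comparing observed weighted
#' residuals about leave-one-out IVW fits against a parametric null.
#'
#' 1. *Global test*: observed residual sum of squares
#'    `RSS = sum_j (Gamma_j - gamma_j * beta_{-j})^2 / se_Gamma_j^2`
#'    against `n_sim` simulations drawing
#'    `gamma* ~ N(gamma, se_gamma)`, `Gamma*_j ~ N(gamma_j beta_{-j},
#'    se_Gamma_j)` and recomputing RSS identically; empirical upper-tail p
#'    with `+1/(n_sim+1)` smoothing.
#' 2. *Outlier test*: each SNP's observed residual against its simulated
#'    distribution; two-sided empirical p, Bonferroni-multiplied by J;
#'    outliers at adjusted p < `sig_level`.
#' 3. *Distortion test*: the relative change of the IVW estimate after
#'    removing the detected outliers, against the distribution of the same
#'    quantity when removing equally many random SNPs.
#'
#' @param set A `harmonized_set` with J >= 4.
#' @param n_sim Simulations for the null distributions (>= 100). Because
#'   empirical p-values are granular, the smallest achievable adjusted
#'   outlier p is `2 J / (n_sim + 1)`; `n_sim` should exceed roughly
#'   `40 J` for outlier detection at the 5% level.
#' @param seed Optional seed; the whole procedure is reproducible given it.
#' @param sig_level Outlier significance level on the adjusted p (0.05).
#' @return An `mr_presso` list: `global_rss_obs`, `global_pval`,
#'   `outlier_table`, `outlier_ids`, `distortion_pval`, `estimate_before`,
#'   `estimate_after`, `degenerate`.
#' @export
mr_presso <- function(set, n_sim = 1000, seed = NULL, sig_level = 0.05) {
  set <- as_hs(set)
  J <- nrow(set)
  if (J < 4) stop("outlier testing requires J >= 4", call. = FALSE)
  if (n_sim < 100) stop("n_sim must be at least 100", call. = FALSE)

  obs_res <- presso_rss_matrix(matrix(set$gamma, 1), matrix(set$Gamma, 1),
                               set$se_Gamma)[1, ]
  rss_obs <- sum(obs_res)

  # Expected outcome effect of SNP j under the leave-one-out IVW fit of the
  # observed data; the simulation draws around it.
  inv_v <- 1 / set$se_Gamma^2
  w <- set$gamma^2 * inv_v
  wb <- set$gamma * set$Gamma * inv_v
  beta_loo <- (sum(wb) - wb) / (sum(w) - w)
  mu_Gamma <- set$gamma * beta_loo

  out <- with_seed(seed, {
    G <- matrix(stats::rnorm(n_sim * J, rep(set$gamma, each = n_sim),
                             rep(set$se_gamma, each = n_sim)), n_sim, J)
    Y <- matrix(stats::rnorm(n_sim * J, rep(mu_Gamma, each = n_sim),
                             rep(set$se_Gamma, each = n_sim)), n_sim, J)
    sim_res <- presso_rss_matrix(G, Y, set$se_Gamma)
    rss_sim <- rowSums(sim_res)
    global_pval <- (1 + sum(rss_sim >= rss_obs)) / (n_sim + 1)

    p_hi <- (1 + colSums(sim_res >= rep(obs_res, each = n_sim))) / (n_sim + 1)
    p_lo <- (1 + colSums(sim_res <= rep(obs_res, each = n_sim))) / (n_sim + 1)
    outlier_p <- pmin(1, 2 * pmin(p_hi, p_lo))
    outlier_padj <- pmin(1, outlier_p * J)
    is_out <- outlier_padj < sig_level

    before <- mr_ivw(set, mode = "fixed")
    n_out <- sum(is_out)
    degenerate <- J - n_out < 2
    after <- before
    distortion_pval <- NA_real_
    if (n_out > 0 && !degenerate) {
      after <- mr_ivw(set[!is_out, , drop = FALSE], mode = "fixed")
      d_obs <- (after$beta - before$beta) / abs(before$beta)
      d_null <- vapply(seq_len(n_sim), function(i) {
        drop_idx <- sample.int(J, n_out)
        bi <- mr_ivw(set[-drop_idx, , drop = FALSE], mode = "fixed")$beta
        (bi - before$beta) / abs(before$beta)
      }, numeric(1))
      d_hi <- (1 + sum(d_null >= d_obs)) / (n_sim + 1)
      d_lo <- (1 + sum(d_null <= d_obs)) / (n_sim + 1)
      distortion_pval <- min(1, 2 * min(d_hi, d_lo))
    }
    list(global_pval = global_pval,
         outlier_table = data.frame(snp_id = set$snp_id, residual = obs_res,
                                    pval = outlier_p, pval_adj = outlier_padj,
                                    is_outlier = is_out,
                                    stringsAsFactors = FALSE),
         outlier_ids = set$snp_id[is_out],
         distortion_pval = distortion_pval,
         estimate_before = before, estimate_after = after,
         degenerate = degenerate)
  })
  structure(c(list(global_rss_obs = rss_obs), out,
              list(n_sim = n_sim, sig_level = sig_level)),
            class = "mr_presso")
}

#' Detect, remove and re-estimate: the outlier-corrected MR loop
#'
#' Runs the full estimator battery, then the simulation-based outlier test;
#' if outliers are found, removes them and reruns the battery once, so both
#' passes are reported (as done for the positive-control analysis where a
#' single outlier was removed and the MR repeated).
#'
#' @param set A `harmonized_set` with J >= 4.
#' @param n_sim,seed,sig_level Passed to [mr_presso()].
#' @param q_alpha,n_boot Passed to [mr_estimates()].
#' @return List with `first_pass` (estimates), `presso`, `outliers`,
#'   `second_pass` (`NULL` when no outliers were removed).
#' @export
mr_with_outlier_removal <- function(set, n_sim = 1000, seed = NULL,
                                    sig_level = 0.05, q_alpha = 0.05,
                                    n_boot = 1000) {
  set <- as_hs(set)
  first <- mr_estimates(set, q_alpha = q_alpha, n_boot = n_boot, seed = seed)
  presso <- mr_presso(set, n_sim = n_sim, seed = seed, sig_level = sig_level)
  second <- NULL
  if (length(presso$outlier_ids) && !presso$degenerate) {
    reduced <- set[!(set$snp_id %in% presso$outlier_ids), , drop = FALSE]
    second <- mr_estimates(reduced, q_alpha = q_alpha, n_boot = n_boot,
                           seed = seed)
  }
  list(first_pass = first, presso = presso,
       outliers = presso$outlier_ids, second_pass = second)
}

#' @export
print.mr_presso <- function(x, ...) {
  cat(sprintf("Global test: RSS = %.3f, p = %.4g\n",
              x$global_rss_obs, x$global_pval))
  if (length(x$outlier_ids)) {
    cat("Outliers:", paste(x$outlier_ids, collapse = ", "), "\n")
    cat(sprintf("Distortion test p = %.4g\n", x$distortion_pval))
  } else {
    cat("No outliers detected.\n")
  }
  invisible(x)
}
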