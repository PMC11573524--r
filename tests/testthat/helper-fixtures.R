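# Shared builders and independent oracles for the test suite.

# Random harmonized set with a known slope; noise on both sides.
random_hs <- function(J = 10, seed = 1, slope = 0.3) {
  set.seed(seed)
  gamma <- stats::runif(J, 0.05, 0.3) * sample(c(-1, 1), J, replace = TRUE)
  se_g <- stats::runif(J, 0.005, 0.02)
  se_G <- stats::runif(J, 0.01, 0.05)
  Gamma <- slope * gamma + stats::rnorm(J, 0, se_G)
  harmonized_set(gamma, se_g, Gamma, se_G)
}

# Null set for calibration studies: strong instruments, exact SEs, no
# pleiotropy, true slope beta0.
null_hs <- function(J, beta0 = 0.1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  gamma_t <- stats::runif(J, 0.05, 0.15)
  se_g <- rep(0.002, J)
  se_G <- stats::runif(J, 0.005, 0.01)
  harmonized_set(stats::rnorm(J, gamma_t, se_g), se_g,
                 stats::rnorm(J, beta0 * gamma_t, se_G), se_G)
}

# Independent IVW oracle: generic weighted least squares through the
# origin via lm(); fixed-effect SE recovered by dividing out sigma.
ivw_oracle <- function(hs) {
  fit <- stats::lm(Gamma ~ 0 + gamma, data = hs, weights = 1 / hs$se_Gamma^2)
  s <- summary(fit)
  list(beta = unname(stats::coef(fit)[1]),
       se_fe = unname(s$coefficients[1, 2] / s$sigma))
}

# Independent MR-Egger oracle: weighted regression with intercept via lm()
# after orienting gamma >= 0.
egger_oracle <- function(hs) {
  flip <- hs$gamma < 0
  x <- abs(hs$gamma)
  y <- ifelse(flip, -hs$Gamma, hs$Gamma)
  fit <- stats::lm(y ~ x, weights = 1 / hs$se_Gamma^2)
  s <- summary(fit)
  list(intercept = unname(stats::coef(fit)[1]),
       slope = unname(stats::coef(fit)[2]),
       se_int_fe = unname(s$coefficients[1, 2] / s$sigma),
       se_slope_fe = unname(s$coefficients[2, 2] / s$sigma))
}

# Brute-force weighted-median oracle: manual evaluation of the
# cumulative-midpoint interpolation definition.
wm_oracle <- function(b, w) {
  ord <- order(b)
  b <- b[ord]
  w <- w[ord] / sum(w)
  p <- cumsum(w) - w / 2
  J <- length(b)
  if (0.5 <= p[1]) return(b[1])
  if (0.5 >= p[J]) return(b[J])
  k <- max(which(p < 0.5))
  b[k] + (b[k + 1] - b[k]) * (0.5 - p[k]) / (p[k + 1] - p[k])
}

toy_gwas <- function(df, trait = "toy", type = "quantitative") {
  suppressMessages(as_gwas_table(df, gwas_meta(trait, type = type)))
}

write_tsv <- function(df, path = tempfile(fileext = ".tsv")) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# Exhaustive pairwise LD-validity check for a clumping result.
all_pairs_below <- function(iset, ld, threshold) {
  ids <- iset$snp_id
  if (length(ids) < 2) return(TRUE)
  pairs <- utils::combn(ids, 2)
  all(ld[cbind(pairs[1, ], pairs[2, ])] <= threshold + 1e-12)
}

# The 5-SNP fixture exercising the adaptive clumping fallback: the primary
# r2 < 0.3 run keeps 2 SNPs, the r2 < 0.4 rerun keeps 4.
fallback_fixture <- function() {
  ids <- paste0("s", 1:5)
  tab <- toy_gwas(data.frame(
    snp_id = ids, chrom = "1", pos = seq(1e6, 1.4e6, by = 1e5),
    effect_allele = "A", other_allele = "G", eaf = 0.3,
    beta = 0.1, se = 0.01,
    pval = c(1e-10, 1e-9, 1e-8, 1e-7, 1e-6), n = 1e5))
  r2 <- diag(1, 5)
  dimnames(r2) <- list(ids, ids)
  set_r2 <- function(a, b, v) {
    r2[a, b] <<- v
    r2[b, a] <<- v
  }
  set_r2("s1", "s2", 0.35); set_r2("s1", "s3", 0.35); set_r2("s1", "s4", 0.9)
  set_r2("s2", "s3", 0.20); set_r2("s2", "s4", 0.9); set_r2("s3", "s4", 0.9)
  set_r2("s1", "s5", 0.05); set_r2("s2", "s5", 0.30); set_r2("s3", "s5", 0.30)
  set_r2("s4", "s5", 0.9)
  list(table = tab, ld = r2)
}
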