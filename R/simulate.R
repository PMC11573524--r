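# Seeded generator of two-sample GWAS summary statistics with known
# causal structure: exposure biomarker, protein mediator, binary outcome.

#' Configuration for the summary-statistics simulator
#'
#' The structural model is, per SNP j,
#' `delta_j = beta1 * gamma_j + m_j` for the mediator and
#' `Gamma_j = (alpha_direct + beta1 * beta2) * gamma_j + beta2 * m_j +
#' theta_j` for the outcome, where `gamma_j` is the true effect of a cis
#' SNP of the exposure gene, `m_j` the true effect of a mediator pQTL
#' (zero for exposure SNPs and vice versa), and `theta_j` a pleiotropic
#' shortcut to the outcome. The true total effect of the exposure is
#' therefore exactly `alpha_direct + beta1 * beta2`. Observed effects add
#' independent normal noise with standard errors derived from sample size
#' and allele frequency: `1 / sqrt(2 n p (1 - p))` for standardized
#' quantitative traits and `1 / sqrt(2 p (1 - p) n phi (1 - phi))` for a
#' binary outcome with case fraction `phi`.
#'
#' Defaults mirror the setting the package targets: a UK Biobank-sized
#' triglyceride GWAS (n = 441,016), an Olink-panel-sized pQTL study
#' (n = 14,824), an atrial-fibrillation-sized case-control outcome
#' (n = 1,030,836, case fraction 0.0588), a total effect of log(0.854)
#' split so that the mediated share is about 9.3%, and cis instruments in
#' the LPL region clustered into LD blocks.
#'
#' @param n_snps Exposure cis SNPs.
#' @param n_snps_mediator Mediator pQTL SNPs.
#' @param n_decoy Null SNPs placed outside the cis window.
#' @param n_exposure,n_mediator,n_outcome GWAS sample sizes.
#' @param alpha_direct Direct exposure-to-outcome effect (log-odds).
#' @param beta1,beta2 Mediator-path effects.
#' @param pleiotropy List `mode` (`"none"`, `"balanced"`, `"directional"`)
#'   and scale `tau` (SD of the pleiotropic effects).
#' @param gamma_dist List `min`, `max`: magnitude range of true instrument
#'   effects (random sign).
#' @param eaf_dist List `min`, `max`: allele-frequency bounds.
#' @param ld List `n_blocks`, `block_size`, `rho`: exposure SNPs are
#'   grouped into blocks with within-block correlation `rho` (stored as
#'   r-squared `rho^2`); everything else is independent.
#' @param outcome_type `"binary"` or `"quantitative"`.
#' @param case_frac Case fraction for a binary outcome.
#' @param gene List describing the exposure gene region (symbol, chrom,
#'   start, end, flank_kb).
#' @param seed Seed making the whole study reproducible.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_snps = 30, n_snps_mediator = 30, n_decoy = 10,
                       n_exposure = 441016, n_mediator = 14824,
                       n_outcome = 1030836,
                       alpha_direct = -0.1432, beta1 = -0.2021, beta2 = 0.0723,
                       pleiotropy = list(mode = "none", tau = 0),
                       gamma_dist = list(min = 0.05, max = 0.15),
                       eaf_dist = list(min = 0.1, max = 0.9),
                       ld = list(n_blocks = 6, block_size = 5, rho = 0.6),
                       outcome_type = c("binary", "quantitative"),
                       case_frac = 0.0588,
                       gene = list(symbol = "LPL", chrom = "8",
                                   start = 19796764, end = 19824770,
                                   flank_kb = 100),
                       seed = 1) {
  outcome_type <- match.arg(outcome_type)
  pleiotropy$mode <- match.arg(pleiotropy$mode,
                               c("none", "balanced", "directional"))
  stopifnot(n_snps >= 1, n_snps_mediator >= 0, n_decoy >= 0,
            n_exposure >= 1, n_mediator >= 1, n_outcome >= 1,
            pleiotropy$tau >= 0,
            gamma_dist$min > 0, gamma_dist$min <= gamma_dist$max,
            eaf_dist$min > 0, eaf_dist$max < 1, eaf_dist$min < eaf_dist$max,
            ld$rho >= 0, ld$rho < 1,
            case_frac > 0, case_frac < 1)
  structure(list(n_snps = n_snps, n_snps_mediator = n_snps_mediator,
                 n_decoy = n_decoy, n_exposure = n_exposure,
                 n_mediator = n_mediator, n_outcome = n_outcome,
                 alpha_direct = alpha_direct, beta1 = beta1, beta2 = beta2,
                 pleiotropy = pleiotropy, gamma_dist = gamma_dist,
                 eaf_dist = eaf_dist, ld = ld, outcome_type = outcome_type,
                 case_frac = case_frac, gene = gene, seed = seed),
            class = "sim_config")
}

# Standard error of a standardized per-allele effect.
se_quantitative <- function(n, p) 1 / sqrt(2 * n * p * (1 - p))
se_binary <- function(n, p, phi) 1 / sqrt(2 * p * (1 - p) * n * phi * (1 - phi))

# Non-palindromic allele pair, one per SNP.
sample_allele_pairs <- function(n) {
  pairs <- rbind(c("A", "G"), c("A", "C"), c("G", "A"), c("C", "A"),
                 c("T", "G"), c("T", "C"), c("G", "T"), c("C", "T"))
  pairs[sample.int(nrow(pairs), n, replace = TRUE), , drop = FALSE]
}

#' Simulate a complete two-sample mediation study
#'
#' Generates exposure, mediator and outcome summary-statistics tables over
#' a shared SNP panel (cis instruments of the exposure gene, mediator
#' pQTLs on another chromosome, and null decoy SNPs outside the cis
#' window), a block-diagonal LD matrix, the exposure gene region, and a
#' truth object recording every generating parameter. Noise draws are
#' independent across the three tables, emulating non-overlapping samples.
#'
#' @param config A [sim_config()].
#' @return List with `exposure`, `mediator`, `outcome` (`gwas_table`s),
#'   `ld` (r-squared matrix), `region` ([gene_region()]), `truth` (per-SNP
#'   effects plus `alpha_total` and `proportion`), and the `config`.
#' @export
simulate_study <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    ne <- config$n_snps; nm <- config$n_snps_mediator; nd <- config$n_decoy
    J <- ne + nm + nd
    role <- c(rep("exposure_cis", ne), rep("mediator_pqtl", nm),
              rep("decoy", nd))
    snp_id <- sprintf("rs%07d", sample.int(9999999, J))

    gene <- config$gene
    win <- c(gene$start - gene$flank_kb * 1000, gene$end + gene$flank_kb * 1000)
    pos <- numeric(J)
    chrom <- character(J)
    pos[role == "exposure_cis"] <- sort(round(stats::runif(ne, win[1], win[2])))
    chrom[role == "exposure_cis"] <- gene$chrom
    if (nm > 0) {  # trans region on another chromosome (mediator gene locus)
      pos[role == "mediator_pqtl"] <- sort(round(stats::runif(nm, 81e6, 81.4e6)))
      chrom[role == "mediator_pqtl"] <- "4"
    }
    if (nd > 0) {  # same chromosome as the gene but far outside the window
      pos[role == "decoy"] <- sort(round(stats::runif(nd, win[2] + 2e6,
                                                      win[2] + 12e6)))
      chrom[role == "decoy"] <- gene$chrom
    }

    alleles <- sample_allele_pairs(J)
    eaf <- stats::runif(J, config$eaf_dist$min, config$eaf_dist$max)

    draw_effects <- function(n) {
      stats::runif(n, config$gamma_dist$min, config$gamma_dist$max) *
        sample(c(-1, 1), n, replace = TRUE)
    }
    gamma <- ifelse(role == "exposure_cis", draw_effects(J), 0)
    m_eff <- ifelse(role == "mediator_pqtl", draw_effects(J), 0)
    theta <- numeric(J)
    tau <- config$pleiotropy$tau
    if (config$pleiotropy$mode != "none" && tau > 0) {
      raw <- abs(stats::rnorm(J, 0, tau))
      sign_v <- if (config$pleiotropy$mode == "balanced") {
        sample(c(-1, 1), J, replace = TRUE)
      } else 1
      theta <- ifelse(role == "exposure_cis", raw * sign_v, 0)
    }

    alpha_total <- config$alpha_direct + config$beta1 * config$beta2
    delta <- config$beta1 * gamma + m_eff
    Gamma <- alpha_total * gamma + config$beta2 * m_eff + theta

    se_e <- se_quantitative(config$n_exposure, eaf)
    se_m <- se_quantitative(config$n_mediator, eaf)
    se_o <- if (config$outcome_type == "binary") {
      se_binary(config$n_outcome, eaf, config$case_frac)
    } else {
      se_quantitative(config$n_outcome, eaf)
    }

    make_table <- function(truth, se, meta, n) {
      beta_hat <- truth + stats::rnorm(J, 0, se)
      as_gwas_table(data.frame(snp_id = snp_id, chrom = chrom, pos = pos,
                               effect_allele = alleles[, 1],
                               other_allele = alleles[, 2],
                               eaf = eaf, beta = beta_hat, se = se,
                               pval = z_pval(beta_hat / se), n = n,
                               stringsAsFactors = FALSE),
                    meta)
    }
    exposure <- make_table(gamma, se_e,
                           gwas_meta("exposure_biomarker"), config$n_exposure)
    mediator <- make_table(delta, se_m,
                           gwas_meta("mediator_protein"), config$n_mediator)
    outcome <- make_table(Gamma, se_o,
                          gwas_meta("outcome",
                                    type = if (config$outcome_type == "binary")
                                      "binary" else "quantitative"),
                          config$n_outcome)

    # Block LD among the exposure cis SNPs; everything else independent.
    ld <- diag(1, J)
    dimnames(ld) <- list(snp_id, snp_id)
    if (config$ld$rho > 0 && ne > 1) {
      block <- rep(seq_len(ceiling(ne / config$ld$block_size)),
                   each = config$ld$block_size)[seq_len(ne)]
      idx <- which(role == "exposure_cis")
      for (bl in unique(block)) {
        members <- idx[block == bl]
        ld[members, members] <- config$ld$rho^2
      }
      diag(ld) <- 1
    }

    region <- gene_region(gene$symbol, gene$chrom, gene$start, gene$end,
                          flank_kb = gene$flank_kb)
    truth <- list(
      per_snp = data.frame(snp_id = snp_id, role = role, gamma = gamma,
                           m_eff = m_eff, theta = theta, delta = delta,
                           Gamma = Gamma, stringsAsFactors = FALSE),
      alpha_direct = config$alpha_direct, beta1 = config$beta1,
      beta2 = config$beta2, alpha_total = alpha_total,
      proportion = config$beta1 * config$beta2 / alpha_total)

    list(exposure = exposure, mediator = mediator, outcome = outcome,
         ld = ld, region = region, truth = truth, config = config)
  })
}

#' Write the named fixture suite used by tests and documentation
#'
#' Produces small, fully seeded studies in the TSV dialect [read_gwas()]
#' reads, each with a JSON truth sidecar: a clean study (no pleiotropy, no
#' LD), a directional-pleiotropy study, a single-outlier study (one
#' outcome effect displaced by 10 standard errors; the displaced SNP id is
#' recorded in the sidecar), and a mediation study whose true proportion
#' mediated is about 0.093.
#'
#' @param out_dir Output directory.
#' @param seed Base seed; each fixture derives its own offset from it.
#' @return Invisibly, a named list of the per-fixture file paths.
#' @export
make_fixture_suite <- function(out_dir, seed = 1) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  specs <- list(
    clean = sim_config(ld = list(n_blocks = 1, block_size = 1, rho = 0),
                       n_decoy = 0, seed = seed),
    directional_pleiotropy = sim_config(
      pleiotropy = list(mode = "directional", tau = 0.02),
      ld = list(n_blocks = 1, block_size = 1, rho = 0),
      n_decoy = 0, seed = seed + 1),
    single_outlier = sim_config(ld = list(n_blocks = 1, block_size = 1, rho = 0),
                                n_decoy = 0, seed = seed + 2),
    mediation = sim_config(seed = seed + 3)
  )
  out <- list()
  for (nm in names(specs)) {
    study <- simulate_study(specs[[nm]])
    extra <- list()
    if (nm == "single_outlier") {
      # Displace the strongest cis SNP's outcome effect by 10 SEs.
      cis <- which(study$truth$per_snp$role == "exposure_cis")
      j <- cis[which.max(abs(study$truth$per_snp$gamma[cis]))]
      study$outcome$beta[j] <- study$outcome$beta[j] +
        10 * study$outcome$se[j]
      study$outcome$pval[j] <- z_pval(study$outcome$beta[j] / study$outcome$se[j])
      extra$outlier_snp <- study$outcome$snp_id[j]
    }
    paths <- list(
      exposure = file.path(out_dir, paste0(nm, "_exposure.tsv")),
      mediator = file.path(out_dir, paste0(nm, "_mediator.tsv")),
      outcome = file.path(out_dir, paste0(nm, "_outcome.tsv")),
      truth = file.path(out_dir, paste0(nm, "_truth.json"))
    )
    write_gwas(study$exposure, paths$exposure)
    write_gwas(study$mediator, paths$mediator)
    write_gwas(study$outcome, paths$outcome)
    truth <- c(study$truth, extra,
               list(seed = specs[[nm]]$seed, fixture = nm))
    jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA, dataframe = "columns")
    # LD as a long-format triplet file (every off-diagonal pair, since
    # entries absent from a triplet file are treated as unknown, not zero).
    ldp <- file.path(out_dir, paste0(nm, "_ld.tsv"))
    ut <- which(upper.tri(study$ld), arr.ind = TRUE)
    trip <- data.frame(snp_a = rownames(study$ld)[ut[, 1]],
                       snp_b = colnames(study$ld)[ut[, 2]],
                       r2 = study$ld[ut])
    utils::write.table(trip, ldp, sep = "\t", quote = FALSE, row.names = FALSE)
    paths$ld <- ldp
    out[[nm]] <- paths
  }
  invisible(out)
}
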