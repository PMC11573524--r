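# Config-driven orchestration of the full drug-target MR + mediation study.

default_pipeline_settings <- function() {
  list(
    flank_kb = 100,
    palindrome_policy = "infer-by-frequency",
    thresholds = list(p_exposure = 5e-8, p_mediator = 5e-6, eaf_min = 0.01),
    clump = list(r2 = 0.3, r2_fallback = 0.4, min_snps = 3, window_kb = 10000),
    estimators = list(n_boot = 1000, n_sim = 1000, q_alpha = 0.05,
                      sig_level = 0.05),
    bonferroni = list(m_targets = NULL, m_mediators = NULL),
    overlap_policy = "drop-shared",
    seed = 1
  )
}

merge_settings <- function(defaults, user) {
  for (nm in names(user)) {
    defaults[[nm]] <- if (is.list(defaults[[nm]]) && is.list(user[[nm]])) {
      merge_settings(defaults[[nm]], user[[nm]])
    } else {
      user[[nm]]
    }
  }
  defaults
}

#' Load and validate a pipeline run configuration
#'
#' @param config Path to a YAML file or an already-parsed list. Required
#'   keys: `exposures` (each with `name`, `gwas`, `gene`), `outcomes`
#'   (each with `name`, `gwas`, optional `type`), `ld_matrix`; optional:
#'   `mediators`, `gene_regions`, `blocklist`, `output_dir`, `seed`, and
#'   the threshold/clumping/estimator settings (see
#'   `default_pipeline_settings`).
#' @return Validated configuration list.
#' @export
load_run_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config,
                                   call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  cfg <- merge_settings(default_pipeline_settings(), config)
  for (key in c("exposures", "outcomes", "ld_matrix")) {
    if (is.null(cfg[[key]])) stop("config misses required key: ", key,
                                  call. = FALSE)
  }
  ref_paths <- c(cfg$ld_matrix, cfg$gene_regions, cfg$blocklist,
                 vapply(cfg$exposures, `[[`, "", "gwas"),
                 vapply(cfg$outcomes, `[[`, "", "gwas"),
                 vapply(cfg$mediators %||% list(), `[[`, "", "gwas"))
  missing <- ref_paths[!file.exists(ref_paths)]
  if (length(missing)) {
    stop("referenced file(s) not found: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  cfg
}

read_cfg_gwas <- function(entry) {
  type <- entry$type %||% "quantitative"
  read_gwas(entry$gwas, trait_meta = gwas_meta(entry$name, type = type))
}

#' Run the full drug-target MR and mediation pipeline
#'
#' Per exposure: cis-instrument selection, adaptive clumping, confounder
#' exclusion and F-statistics; then harmonization against every outcome,
#' the estimator battery, and the sensitivity suite (Cochran's Q, Egger
#' intercept, outlier detection with one remove-and-rerun pass,
#' leave-one-out). Exposures whose headline estimate passes the Bonferroni
#' family threshold continue into the mediator screen (exposure
#' instruments vs each mediator GWAS); mediators passing their own family
#' are estimated against the outcome with their pQTL instruments (shared
#' exposure instruments excluded) and the product-of-coefficients
#' decomposition is computed. Estimation degeneracies (e.g. no shared
#' SNPs) are recorded per-row; only unreadable inputs abort the run.
#'
#' @param config Path to a YAML configuration or a list
#'   (see [load_run_config()]).
#' @param out_dir Optional output directory overriding `config$output_dir`.
#' @return Invisibly, a list of result data frames (`mr_results`,
#'   `sensitivity`, `leave_one_out`, `instruments`, `mediation`); written
#'   as TSVs plus a JSON manifest when an output directory is configured.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  cfg <- load_run_config(config)
  out_dir <- out_dir %||% cfg$output_dir
  est <- cfg$estimators
  thr <- cfg$thresholds
  seed <- cfg$seed

  ld <- read_ld_matrix(cfg$ld_matrix)
  regions <- if (!is.null(cfg$gene_regions)) {
    read_gene_regions(cfg$gene_regions, flank_kb = cfg$flank_kb)
  } else {
    drug_target_regions(flank_kb = cfg$flank_kb)
  }
  blocklist <- if (!is.null(cfg$blocklist)) read_blocklist(cfg$blocklist)
  dt_params <- clump_params(r2_primary = cfg$clump$r2,
                            r2_fallback = cfg$clump$r2_fallback,
                            min_snps = cfg$clump$min_snps,
                            window_kb = cfg$clump$window_kb,
                            p_threshold = thr$p_exposure)
  pqtl_params <- clump_params(preset = "pqtl")

  mr_rows <- list(); sens_rows <- list(); loo_rows <- list()
  instr_rows <- list(); med_rows <- list()
  instruments <- list()
  exposure_tables <- list()

  for (ex in cfg$exposures) {
    tab <- read_cfg_gwas(ex)
    exposure_tables[[ex$name]] <- tab
    region <- regions[[ex$gene %||% ex$name]]
    if (is.null(region)) stop("no gene region for exposure ", ex$name,
                              call. = FALSE)
    cis <- select_cis_snps(tab, region, p_threshold = thr$p_exposure,
                           eaf_min = thr$eaf_min)
    iset <- if (nrow(cis)) clump(cis, ld, dt_params) else cis
    iset <- exclude_confounder_snps(iset, blocklist)
    fs <- if (nrow(iset)) f_statistics(iset) else
      list(mean_f = NA_real_, weak = NA)
    message(sprintf("[%s] %d cis SNPs -> %d instruments (mean F = %.1f)",
                    ex$name, nrow(cis), nrow(iset), fs$mean_f))
    instruments[[ex$name]] <- iset
    instr_rows[[ex$name]] <- data.frame(
      exposure = ex$name, n_cis = nrow(cis), n_instruments = nrow(iset),
      r2_threshold = attr(iset, "r2_threshold") %||% NA_real_,
      mean_f = fs$mean_f, weak_flag = fs$weak, stringsAsFactors = FALSE)
  }

  headline <- list()
  for (oc in cfg$outcomes) {
    otab <- read_cfg_gwas(oc)
    for (ex_name in names(instruments)) {
      iset <- instruments[[ex_name]]
      key <- paste(ex_name, oc$name, sep = "|")
      if (nrow(iset) == 0L) {
        mr_rows[[key]] <- data.frame(exposure = ex_name, outcome = oc$name,
                                     method = "none", n_snps = 0L,
                                     beta = NA_real_, se = NA_real_,
                                     ci_low = NA_real_, ci_high = NA_real_,
                                     pval = NA_real_, or = NA_real_,
                                     or_ci_low = NA_real_, or_ci_high = NA_real_,
                                     note = "no instruments",
                                     stringsAsFactors = FALSE)
        next
      }
      hs <- tryCatch(harmonize(iset, otab,
                               palindrome_policy = cfg$palindrome_policy),
                     error = function(e) NULL)
      if (is.null(hs)) {
        mr_rows[[key]] <- data.frame(exposure = ex_name, outcome = oc$name,
                                     method = "none", n_snps = 0L,
                                     beta = NA_real_, se = NA_real_,
                                     ci_low = NA_real_, ci_high = NA_real_,
                                     pval = NA_real_, or = NA_real_,
                                     or_ci_low = NA_real_, or_ci_high = NA_real_,
                                     note = "harmonization failed",
                                     stringsAsFactors = FALSE)
        next
      }
      if (nrow(hs) >= 4) {
        loop <- mr_with_outlier_removal(hs, n_sim = est$n_sim, seed = seed,
                                        sig_level = est$sig_level,
                                        q_alpha = est$q_alpha,
                                        n_boot = est$n_boot)
        res <- if (!is.null(loop$second_pass)) loop$second_pass else
          loop$first_pass
        presso <- loop$presso
        hs_final <- if (length(loop$outliers)) {
          hs[!(hs$snp_id %in% loop$outliers), , drop = FALSE]
        } else hs
      } else {
        res <- mr_estimates(hs, q_alpha = est$q_alpha, n_boot = est$n_boot,
                            seed = seed)
        presso <- NULL
        loop <- NULL
        hs_final <- hs
      }
      note <- if (!is.null(loop) && length(loop$outliers)) {
        paste("outliers removed:", paste(loop$outliers, collapse = ","))
      } else ""
      mr_rows[[key]] <- cbind(data.frame(exposure = ex_name, outcome = oc$name,
                                         stringsAsFactors = FALSE),
                              res[!(names(res) %in%
                                      c("intercept", "intercept_se",
                                        "intercept_pval"))],
                              note = note)
      headline[[oc$name]][[ex_name]] <- res[1, ]

      q_ivw <- cochran_q(hs_final, basis = "ivw")
      eg <- if (nrow(hs_final) >= 3) mr_egger(hs_final)
      q_eg <- if (nrow(hs_final) >= 3) cochran_q(hs_final, basis = "egger")
      sens_rows[[key]] <- data.frame(
        exposure = ex_name, outcome = oc$name,
        n_snps = nrow(hs_final),
        q_ivw = q_ivw$Q, q_ivw_df = q_ivw$df, q_ivw_pval = q_ivw$pval,
        q_egger = if (is.null(q_eg)) NA_real_ else q_eg$Q,
        q_egger_pval = if (is.null(q_eg)) NA_real_ else q_eg$pval,
        egger_intercept = if (is.null(eg)) NA_real_ else eg$intercept,
        egger_intercept_pval = if (is.null(eg)) NA_real_ else eg$intercept_pval,
        presso_global_pval = if (is.null(presso)) NA_real_ else
          presso$global_pval,
        presso_outliers = if (is.null(presso)) "" else
          paste(presso$outlier_ids, collapse = ","),
        presso_distortion_pval = if (is.null(presso)) NA_real_ else
          presso$distortion_pval,
        stringsAsFactors = FALSE)

      if (nrow(hs_final) >= 3) {
        loo <- leave_one_out(hs_final)
        loo_rows[[key]] <- cbind(data.frame(exposure = ex_name,
                                            outcome = oc$name,
                                            stringsAsFactors = FALSE), loo)
      }
    }
  }

  # Bonferroni screen over the headline estimates, then mediation.
  mediators <- cfg$mediators %||% list()
  for (oc in cfg$outcomes) {
    hl <- headline[[oc$name]]
    if (is.null(hl) || !length(mediators)) next
    pvals <- vapply(hl, `[[`, numeric(1), "pval")
    fam <- bonferroni_family(pvals,
                             m = cfg$bonferroni$m_targets %||% length(pvals),
                             name = paste0("targets_vs_", oc$name))
    passing <- fam$members$id[fam$members$significant]
    message(sprintf("[%s] Bonferroni threshold %.3g; %d/%d exposure(s) pass",
                    oc$name, fam$threshold, length(passing), length(pvals)))
    otab <- read_cfg_gwas(oc)

    for (ex_name in passing) {
      iset <- instruments[[ex_name]]
      alpha <- hl[[ex_name]]
      b1_res <- list()
      for (md in mediators) {
        mtab <- read_cfg_gwas(md)
        hs1 <- tryCatch(harmonize(iset, mtab,
                                  palindrome_policy = cfg$palindrome_policy),
                        error = function(e) NULL)
        if (!is.null(hs1)) {
          b1_res[[md$name]] <- total_effect(hs1, q_alpha = est$q_alpha)
        }
      }
      if (!length(b1_res)) next
      fam_med <- bonferroni_family(
        vapply(b1_res, `[[`, numeric(1), "pval"),
        m = cfg$bonferroni$m_mediators %||% length(b1_res),
        name = paste0(ex_name, "_vs_mediators"))
      pass_med <- fam_med$members$id[fam_med$members$significant]
      message(sprintf("[%s] mediator screen threshold %.3g; %d/%d pass",
                      ex_name, fam_med$threshold, length(pass_med),
                      length(b1_res)))

      for (md_name in pass_med) {
        md <- mediators[[which(vapply(mediators, `[[`, "", "name") == md_name)]]
        mtab <- read_cfg_gwas(md)
        # pQTL instruments: genome-wide significance filter then strict
        # clumping; exposure instruments excluded from the beta2 fit.
        cand <- mtab[!is.na(mtab$pval) & mtab$pval < thr$p_mediator &
                       !is.na(mtab$eaf) & mtab$eaf > thr$eaf_min, ,
                     drop = FALSE]
        cand <- structure(cand, class = class(mtab),
                          trait_meta = attr(mtab, "trait_meta"))
        key <- paste(ex_name, md_name, oc$name, sep = "|")
        if (nrow(cand) == 0L) next
        miset <- clump(cand, ld, pqtl_params)
        # drop-shared overlap policy: exclude mediator instruments that are
        # exposure instruments or in LD (r2 > 0.001) with one
        keep <- !(miset$snp_id %in% iset$snp_id)
        expo_in_ld <- intersect(iset$snp_id, rownames(ld))
        if (length(expo_in_ld)) {
          in_ld <- vapply(miset$snp_id, function(s) {
            s %in% rownames(ld) &&
              any(ld[s, expo_in_ld] > 0.001, na.rm = TRUE)
          }, logical(1))
          keep <- keep & !in_ld
        }
        if (any(!keep)) {
          message(sprintf("[%s] dropped %d mediator instrument(s) shared %s",
                          md_name, sum(!keep), "with the exposure set"))
        }
        miset <- miset[keep, , drop = FALSE]
        if (nrow(miset) == 0L) {
          med_rows[[key]] <- data.frame(exposure = ex_name, mediator = md_name,
                                        outcome = oc$name, note = "beta2 non-estimable",
                                        stringsAsFactors = FALSE)
          next
        }
        hs2 <- tryCatch(harmonize(miset, otab,
                                  palindrome_policy = cfg$palindrome_policy),
                        error = function(e) NULL)
        if (is.null(hs2)) next
        b2 <- total_effect(hs2, q_alpha = est$q_alpha)
        b1 <- b1_res[[md_name]]
        med <- mediate(alpha$beta, alpha$se, b1$beta, b1$se, b2$beta, b2$se)
        med_rows[[key]] <- data.frame(
          exposure = ex_name, mediator = md_name, outcome = oc$name,
          alpha = med$alpha, alpha_se = med$alpha_se,
          beta1 = med$beta1, beta1_se = med$beta1_se,
          beta2 = med$beta2, beta2_se = med$beta2_se,
          indirect = med$indirect, indirect_se = med$indirect_se,
          direct = med$direct,
          proportion = med$proportion, proportion_se = med$proportion_se,
          proportion_pct = med$proportion_pct,
          note = "", stringsAsFactors = FALSE)
      }
    }
  }

  rbind_fill <- function(rows) {
    rows <- Filter(Negate(is.null), rows)
    if (!length(rows)) return(data.frame())
    cols <- unique(unlist(lapply(rows, names)))
    rows <- lapply(rows, function(r) {
      for (cl in setdiff(cols, names(r))) r[[cl]] <- NA
      r[cols]
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  }
  results <- list(mr_results = rbind_fill(mr_rows),
                  sensitivity = rbind_fill(sens_rows),
                  leave_one_out = rbind_fill(loo_rows),
                  instruments = rbind_fill(instr_rows),
                  mediation = rbind_fill(med_rows))
  if (!is.null(out_dir)) {
    write_results(results, out_dir, config = cfg, seed = seed)
  }
  invisible(results)
}
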