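test_that("read_gwas round-trips a well-formed table and validates records", {
  df <- data.frame(rsid = c("rs1", "rs2", "rs3"),
                   chromosome = "8",
                   base_pair_location = c(100, 200, 300),
                   effect_allele = c("a", "C", "G"),
                   other_allele = c("g", "T", "A"),
                   effect_allele_frequency = c(0.1, 0.5, 0.9),
                   beta = c(0.1, -0.2, 0), standard_error = c(0.01, 0.02, 0.03),
                   p_value = c(1e-10, 1e-6, 0.9), n = 1000)
  tab <- read_gwas(write_tsv(df), trait_meta = gwas_meta("TG"))
  expect_s3_class(tab, "gwas_table")
  expect_equal(nrow(tab), 3L)
  expect_equal(tab$effect_allele, c("A", "C", "G"))  # lowercase normalized
  expect_equal(tab$beta, df$beta)

  # invariant violations are dropped with a log, not fatal
  df_bad <- df
  df_bad$standard_error[2] <- 0
  expect_message(tab2 <- read_gwas(write_tsv(df_bad), trait_meta = gwas_meta("TG")),
                 "bad_se")
  expect_equal(tab2$snp_id, c("rs1", "rs3"))
  expect_equal(attr(tab2, "drops")[["bad_se"]], 1)

  # missing mandatory column is a configuration error
  expect_error(read_gwas(write_tsv(df[setdiff(names(df), "beta")]),
                         trait_meta = gwas_meta("TG")),
               "beta")
})

test_that("p-values of exactly zero are replaced by the smallest double", {
  df <- data.frame(snp_id = "rs1", chrom = "1", pos = 1, effect_allele = "A",
                   other_allele = "G", eaf = 0.2, beta = 1, se = 0.01,
                   pval = 0, n = 10)
  expect_message(tab <- as_gwas_table(df, gwas_meta("x")), "exactly 0")
  expect_gt(tab$pval, 0)
  expect_equal(tab$pval, .Machine$double.xmin)
})

test_that("duplicate SNP ids are dropped beyond the first occurrence", {
  df <- data.frame(snp_id = c("rs1", "rs1", "rs2"), chrom = "1", pos = 1:3,
                   effect_allele = "A", other_allele = "G", eaf = 0.2,
                   beta = 1:3, se = 0.01, pval = 0.5, n = 10)
  expect_message(tab <- as_gwas_table(df, gwas_meta("x")), "duplicate")
  expect_equal(tab$snp_id, c("rs1", "rs2"))
  expect_equal(tab$beta[1], 1)
})

make_pair <- function(e_alleles, o_alleles, e_eaf = 0.2, o_eaf = 0.2,
                      e_beta = 0.1, o_beta = -0.05) {
  e <- toy_gwas(data.frame(snp_id = "rs1", chrom = "1", pos = 100,
                           effect_allele = e_alleles[1],
                           other_allele = e_alleles[2],
                           eaf = e_eaf, beta = e_beta, se = 0.01,
                           pval = 1e-8, n = 1e5))
  o <- toy_gwas(data.frame(snp_id = "rs1", chrom = "1", pos = 100,
                           effect_allele = o_alleles[1],
                           other_allele = o_alleles[2],
                           eaf = o_eaf, beta = o_beta, se = 0.02,
                           pval = 0.01, n = 1e5))
  list(e = e, o = o)
}

test_that("harmonize aligns, swaps, strand-flips and drops mismatches", {
  # allele swap negates the outcome effect
  p <- make_pair(c("A", "G"), c("G", "A"))
  hs <- harmonize(p$e, p$o)
  expect_equal(hs$Gamma, 0.05)
  expect_equal(hs$gamma, 0.1)

  # identical alleles pass through unchanged
  p <- make_pair(c("A", "G"), c("A", "G"))
  expect_equal(harmonize(p$e, p$o)$Gamma, -0.05)

  # strand flip: outcome reported on the other strand (T/C vs A/G)
  p <- make_pair(c("A", "G"), c("T", "C"))
  expect_equal(harmonize(p$e, p$o)$Gamma, -0.05)
  # strand flip plus swap
  p <- make_pair(c("A", "G"), c("C", "T"))
  expect_equal(harmonize(p$e, p$o)$Gamma, 0.05)

  # a genuinely different variant is dropped
  p <- make_pair(c("A", "G"), c("A", "C"))
  expect_error(suppressMessages(harmonize(p$e, p$o)), "no SNPs remain")
})

test_that("palindromic SNPs follow the frequency-inference policy", {
  # enumeration of the orientation cases for an A/T SNP with exposure
  # EAF 0.10: label/frequency combinations determine the sign.
  cases <- list(
    list(o = c("A", "T"), eaf = 0.12, Gamma = -0.05),  # aligned
    list(o = c("A", "T"), eaf = 0.88, Gamma = 0.05),   # strand-flipped
    list(o = c("T", "A"), eaf = 0.12, Gamma = -0.05),  # swapped labels, flipped
    list(o = c("T", "A"), eaf = 0.88, Gamma = 0.05)    # swapped labels
  )
  for (cs in cases) {
    p <- make_pair(c("A", "T"), cs$o, e_eaf = 0.10, o_eaf = cs$eaf)
    hs <- harmonize(p$e, p$o)
    expect_equal(hs$Gamma, cs$Gamma, info = paste(cs$o, cs$eaf))
  }

  # near-0.5 frequency cannot resolve strand: dropped as ambiguous
  p <- make_pair(c("A", "T"), c("A", "T"), e_eaf = 0.10, o_eaf = 0.49)
  expect_error(suppressMessages(harmonize(p$e, p$o)), "no SNPs remain")

  # missing EAF on either side drops the SNP under the default policy
  p <- make_pair(c("G", "C"), c("G", "C"), e_eaf = NA, o_eaf = 0.2)
  expect_error(suppressMessages(harmonize(p$e, p$o)), "no SNPs remain")

  # explicit drop policy removes all palindromes
  p <- make_pair(c("A", "T"), c("A", "T"), e_eaf = 0.1, o_eaf = 0.1)
  expect_error(suppressMessages(harmonize(p$e, p$o, palindrome_policy = "drop")),
               "no SNPs remain")
  expect_equal(nrow(harmonize(p$e, p$o)), 1L)  # inferable case retained
})

test_that("harmonization is idempotent and conserves record counts", {
  study <- simulate_study(sim_config(seed = 11, n_decoy = 0))
  hs <- harmonize(study$exposure, study$outcome)
  expect_equal(nrow(hs) + nrow(attr(hs, "drops")), attr(hs, "n_shared"))

  # feed the harmonized set back in as exposure/outcome tables: nothing
  # may change
  as_tab <- function(beta, se) {
    toy_gwas(data.frame(snp_id = hs$snp_id, chrom = hs$chrom, pos = hs$pos,
                        effect_allele = hs$effect_allele,
                        other_allele = hs$other_allele,
                        eaf = hs$eaf_exposure, beta = beta, se = se,
                        pval = 0.5, n = 100))
  }
  hs2 <- harmonize(as_tab(hs$gamma, hs$se_gamma), as_tab(hs$Gamma, hs$se_Gamma))
  expect_equal(hs2$Gamma[match(hs$snp_id, hs2$snp_id)], hs$Gamma)
  expect_equal(nrow(attr(hs2, "drops")), 0L)

  # double allele swap is an involution
  o_swapped <- study$outcome
  o_swapped[c("effect_allele", "other_allele")] <-
    o_swapped[c("other_allele", "effect_allele")]
  o_swapped$beta <- -o_swapped$beta
  o_swapped$eaf <- 1 - o_swapped$eaf
  hs3 <- harmonize(study$exposure, o_swapped)
  expect_equal(hs3$Gamma[match(hs$snp_id, hs3$snp_id)], hs$Gamma)
})

test_that("write_results emits reproducible TSVs and a manifest", {
  res <- list(mr_results = data.frame(exposure = sprintf("E%d", 1:10),
                                      beta = 1:10 / 10),
              empty = data.frame(a = character(0), b = numeric(0)))
  d1 <- file.path(tempfile(), "run1")
  d2 <- file.path(tempfile(), "run2")
  write_results(res, d1, config = list(seed = 1), seed = 1)
  write_results(res, d2, config = list(seed = 1), seed = 1)

  # empty result family -> header-only TSV
  expect_equal(readLines(file.path(d1, "empty.tsv")), "a\tb")
  # cardinality preserved
  expect_equal(nrow(utils::read.delim(file.path(d1, "mr_results.tsv"))), 10L)
  # reruns are byte-identical apart from the manifest timestamp
  expect_equal(unname(tools::md5sum(file.path(d1, "mr_results.tsv"))),
               unname(tools::md5sum(file.path(d2, "mr_results.tsv"))))
  m1 <- jsonlite::read_json(file.path(d1, "manifest.json"))
  m2 <- jsonlite::read_json(file.path(d2, "manifest.json"))
  expect_equal(m1$md5, m2$md5)
  expect_equal(m1$tables$mr_results, 10L)
})
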