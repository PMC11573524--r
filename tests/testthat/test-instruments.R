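cis_table <- function() {
  # gene at [1,000,000, 1,020,000], flank 100 kb -> window [900,000, 1,120,000]
  toy_gwas(data.frame(
    snp_id = paste0("rs", 1:6), chrom = c(rep("2", 5), "3"),
    pos = c(900000, 1000000, 1119999, 899999, 1010000, 1000000),
    effect_allele = "A", other_allele = "G",
    eaf = c(0.2, 0.3, 0.4, 0.3, 0.005, 0.3),
    beta = 0.1, se = 0.01,
    pval = c(1e-9, 5e-8, 1e-12, 1e-20, 1e-15, 1e-30), n = 1e5))
}

test_that("cis selection applies window, significance and EAF rules", {
  region <- gene_region("GENE", "2", 1000000, 1020000, flank_kb = 100)
  sel <- select_cis_snps(cis_table(), region)

  # manual row-by-row oracle:
  # rs1 at exactly start - 100 kb: retained (inclusive boundary)
  # rs2 p = 5e-8 exactly: excluded (strict <)
  # rs3 inside window, significant: retained
  # rs4 1 bp outside the window: excluded
  # rs5 EAF 0.005 <= 0.01: excluded
  # rs6 other chromosome: ignored
  expect_equal(sel$snp_id, c("rs1", "rs3"))
  prov <- attr(sel, "provenance")
  expect_equal(unname(prov["off_chromosome"]), 1)
  expect_equal(unname(prov["outside_window"]), 1)
  expect_equal(unname(prov["not_significant"]), 1)
  expect_equal(unname(prov["eaf_filtered"]), 1)
  # filter pipeline conserves counts
  expect_equal(nrow(sel) + sum(prov[c("outside_window", "not_significant",
                                      "eaf_filtered")]) + prov[["off_chromosome"]],
               nrow(cis_table()))

  # strict-MAF mode also removes high-frequency effect alleles
  tab <- cis_table()
  tab$eaf[1] <- 0.995
  expect_equal(select_cis_snps(tab, region, strict_maf = TRUE)$snp_id, "rs3")

  # raising the p threshold never shrinks the selection
  loose <- select_cis_snps(cis_table(), region, p_threshold = 1e-6)
  expect_true(all(sel$snp_id %in% loose$snp_id))
})

test_that("greedy clumping keeps the most significant SNP per LD cluster", {
  ids <- c("a", "b", "c")
  tab <- toy_gwas(data.frame(snp_id = ids, chrom = "1", pos = c(100, 200, 300),
                             effect_allele = "A", other_allele = "G", eaf = 0.3,
                             beta = 0.1, se = 0.01,
                             pval = c(1e-10, 1e-9, 1e-8), n = 1e5))
  r2 <- diag(1, 3); dimnames(r2) <- list(ids, ids)

  # dominance: r2 = 0.9 pair keeps only the smaller p
  r2a <- r2; r2a["a", "b"] <- r2a["b", "a"] <- 0.9
  expect_equal(clump(tab[1:2, ], r2a, clump_params())$snp_id, "a")

  # mutually independent SNPs are all retained
  expect_equal(sort(clump(tab, r2, clump_params())$snp_id), ids)
  expect_false(attr(clump(tab, r2, clump_params()), "fallback_used"))

  # SNP missing from the LD matrix is a configuration error naming it
  expect_error(clump(tab, r2[1:2, 1:2], clump_params()), "c")
})

test_that("the adaptive fallback reruns at the relaxed threshold", {
  fx <- fallback_fixture()
  primary_only <- clump_params(r2_primary = 0.3, r2_fallback = 0.3,
                               min_snps = 1)
  at03 <- clump(fx$table, fx$ld, primary_only)
  expect_equal(sort(at03$snp_id), c("s1", "s5"))         # 2 survivors
  expect_true(all_pairs_below(at03, fx$ld, 0.3))

  adaptive <- clump(fx$table, fx$ld, clump_params())     # min_snps = 3
  expect_true(attr(adaptive, "fallback_used"))
  expect_equal(attr(adaptive, "r2_threshold"), 0.4)
  expect_equal(sort(adaptive$snp_id), c("s1", "s2", "s3", "s5"))
  expect_true(all_pairs_below(adaptive, fx$ld, 0.4))

  # exactly min_snps survivors at the primary threshold stand (no fallback)
  ids <- paste0("t", 1:3)
  tab <- toy_gwas(data.frame(snp_id = ids, chrom = "1", pos = c(1, 2, 3) * 1e5,
                             effect_allele = "A", other_allele = "G", eaf = 0.3,
                             beta = 0.1, se = 0.01, pval = c(1e-10, 1e-9, 1e-8),
                             n = 1e5))
  r2 <- diag(1, 3); dimnames(r2) <- list(ids, ids)
  res <- clump(tab, r2, clump_params())
  expect_equal(nrow(res), 3L)
  expect_false(attr(res, "fallback_used"))
  expect_equal(attr(res, "r2_threshold"), 0.3)
})

test_that("clumping is deterministic and LD-valid on block structures", {
  for (seed in 1:5) {
    study <- simulate_study(sim_config(
      seed = seed, n_decoy = 0, n_snps_mediator = 0,
      ld = list(n_blocks = 6, block_size = 5, rho = 0.7)))
    cis <- select_cis_snps(study$exposure, study$region)
    res <- clump(cis, study$ld, clump_params())
    expect_true(all_pairs_below(res, study$ld, attr(res, "r2_threshold")))

    # permuting the input rows never changes the selected set
    set.seed(seed)
    perm <- cis[sample.int(nrow(cis)), , drop = FALSE]
    perm <- structure(perm, class = class(cis),
                      trait_meta = attr(cis, "trait_meta"))
    expect_setequal(clump(perm, study$ld, clump_params())$snp_id, res$snp_id)

    # a looser threshold never shrinks the result on block LD
    looser <- clump(cis, study$ld,
                    clump_params(r2_primary = 0.6, r2_fallback = 0.6,
                                 min_snps = 1))
    expect_gte(nrow(looser), nrow(res))
  }
})

test_that("confounder blocklist exclusion logs annotated removals", {
  fx <- fallback_fixture()
  iset <- clump(fx$table, fx$ld, clump_params())
  # disjoint blocklist: unchanged
  bl0 <- data.frame(snp_id = "rs999", trait = "smoking")
  expect_equal(exclude_confounder_snps(iset, bl0)$snp_id, iset$snp_id)
  expect_equal(exclude_confounder_snps(iset, NULL)$snp_id, iset$snp_id)

  bl <- data.frame(snp_id = "s2", trait = "body mass index")
  expect_message(out <- exclude_confounder_snps(iset, bl), "body mass index")
  expect_false("s2" %in% out$snp_id)
  expect_equal(attr(out, "confounders_removed")$trait, "body mass index")
  expect_equal(unname(attr(out, "provenance")["confounder"]), 1)

  bl_all <- data.frame(snp_id = iset$snp_id, trait = "obesity")
  expect_warning(suppressMessages(empty <- exclude_confounder_snps(iset, bl_all)),
                 "blocklisted")
  expect_equal(nrow(empty), 0L)
})

test_that("F-statistics follow the (beta/se)^2 form", {
  tab <- toy_gwas(data.frame(snp_id = c("a", "b", "c"), chrom = "1",
                             pos = 1:3, effect_allele = "A",
                             other_allele = "G", eaf = 0.3,
                             beta = c(0.05, 0.1, 0.2), se = 0.01,
                             pval = 1e-8, n = 1e5))
  fs <- f_statistics(tab)
  expect_equal(fs$per_snp$f, c(25, 100, 400))
  expect_equal(fs$mean_f, 175)
  expect_false(fs$weak)

  weakest <- toy_gwas(data.frame(snp_id = "a", chrom = "1", pos = 1,
                                 effect_allele = "A", other_allele = "G",
                                 eaf = 0.3, beta = 0.02, se = 0.01,
                                 pval = 0.05, n = 1e5))
  expect_true(f_statistics(weakest)$weak)  # F = 4 <= 10
})

test_that("LD matrices read from square and triplet formats agree", {
  ids <- c("x", "y", "z")
  m <- diag(1, 3); dimnames(m) <- list(ids, ids)
  m["x", "y"] <- m["y", "x"] <- 0.5
  m["x", "z"] <- m["z", "x"] <- 0.1
  m["y", "z"] <- m["z", "y"] <- 0.2

  sq <- tempfile(fileext = ".tsv")
  utils::write.table(cbind(snp = ids, as.data.frame(m)), sq, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  trip <- data.frame(snp_a = c("x", "x", "y"), snp_b = c("y", "z", "z"),
                     r2 = c(0.5, 0.1, 0.2))
  tr <- write_tsv(trip)

  m_sq <- read_ld_matrix(sq)
  m_tr <- read_ld_matrix(tr)
  expect_equal(m_sq[ids, ids], m)
  expect_equal(m_tr[ids, ids], m)

  # out-of-range entries are rejected
  bad <- trip; bad$r2[1] <- 1.5
  expect_error(read_ld_matrix(write_tsv(bad)), "\\[0, 1\\]")
})
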