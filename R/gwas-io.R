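# Reading, validating and harmonizing two-sample GWAS summary statistics.

#' Trait metadata for a summary-statistics table
#'
#' Records what the effect column of a GWAS table means: the trait name,
#' whether the trait is quantitative or binary, the effect scale (SD units
#' for quantitative traits, log-odds for binary ones) and the genome build
#' of the coordinates.
#'
#' @param trait Trait name, e.g. `"TG"` or `"AF"`.
#' @param type `"quantitative"` or `"binary"`.
#' @param effect_scale Effect scale label; defaults to `"SD"` for
#'   quantitative and `"log-odds"` for binary traits.
#' @param genome_build Build label for positions (default `"GRCh37"`).
#' @return A `gwas_meta` list.
#' @export
gwas_meta <- function(trait, type = c("quantitative", "binary"),
                      effect_scale = NULL, genome_build = "GRCh37") {
  type <- match.arg(type)
  if (is.null(effect_scale)) {
    effect_scale <- if (type == "binary") "log-odds" else "SD"
  }
  structure(list(trait = trait, type = type, effect_scale = effect_scale,
                 genome_build = genome_build),
            class = "gwas_meta")
}

#' Column mapping for summary-statistics files
#'
#' Maps the canonical internal names onto the column headers of an input
#' file. Defaults follow GWAS-SSF-style naming.
#'
#' @param snp_id,chrom,pos,effect_allele,other_allele,eaf,beta,se,pval,n
#'   Header names in the file for each canonical field.
#' @return Named list of column names.
#' @export
gwas_columns <- function(snp_id = "rsid", chrom = "chromosome",
                         pos = "base_pair_location",
                         effect_allele = "effect_allele",
                         other_allele = "other_allele",
                         eaf = "effect_allele_frequency",
                         beta = "beta", se = "standard_error",
                         pval = "p_value", n = "n") {
  list(snp_id = snp_id, chrom = chrom, pos = pos,
       effect_allele = effect_allele, other_allele = other_allele,
       eaf = eaf, beta = beta, se = se, pval = pval, n = n)
}

# Canonical fields a table must carry; eaf and n may be absent (filled NA).
.gwas_mandatory <- c("snp_id", "chrom", "pos", "effect_allele",
                     "other_allele", "beta", "se", "pval")

#' Build a validated GWAS table from a data frame
#'
#' Normalizes allele case, replaces p-values of exactly zero by the smallest
#' positive double (logged), and drops rows violating the record invariants
#' (identical or non-ACGT alleles, non-positive or non-finite standard
#' errors, p outside (0, 1], allele frequency outside \[0, 1\], duplicated
#' SNP ids). Per-reason drop counts are attached as the `"drops"` attribute.
#'
#' @param df Data frame with canonical columns (`snp_id`, `chrom`, `pos`,
#'   `effect_allele`, `other_allele`, `beta`, `se`, `pval`, optionally
#'   `eaf`, `n`).
#' @param trait_meta A [gwas_meta()] object.
#' @return A `gwas_table` (data frame subclass) with attributes
#'   `trait_meta` and `drops`.
#' @export
as_gwas_table <- function(df, trait_meta) {
  stopifnot(inherits(trait_meta, "gwas_meta"))
  missing_cols <- setdiff(.gwas_mandatory, names(df))
  if (length(missing_cols)) {
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(df$eaf)) df$eaf <- NA_real_
  if (is.null(df$n)) df$n <- NA_real_
  df <- df[c(.gwas_mandatory[1:5], "eaf", .gwas_mandatory[6:8], "n")]

  df$snp_id <- as.character(df$snp_id)
  df$chrom <- as.character(df$chrom)
  df$pos <- as.numeric(df$pos)
  df$effect_allele <- toupper(as.character(df$effect_allele))
  df$other_allele <- toupper(as.character(df$other_allele))
  for (col in c("eaf", "beta", "se", "pval", "n")) df[[col]] <- as.numeric(df[[col]])

  zero_p <- !is.na(df$pval) & df$pval == 0
  if (any(zero_p)) {
    df$pval[zero_p] <- .Machine$double.xmin
    message(sprintf("replaced %d p-value(s) of exactly 0 by %.3g",
                    sum(zero_p), .Machine$double.xmin))
  }

  ok_allele <- df$effect_allele %in% c("A", "C", "G", "T") &
    df$other_allele %in% c("A", "C", "G", "T") &
    df$effect_allele != df$other_allele
  ok_se <- is.finite(df$se) & df$se > 0
  ok_beta <- is.finite(df$beta)
  ok_pval <- is.finite(df$pval) & df$pval > 0 & df$pval <= 1
  ok_eaf <- is.na(df$eaf) | (df$eaf >= 0 & df$eaf <= 1)
  ok_pos <- is.finite(df$pos)

  reasons <- c(bad_alleles = sum(!ok_allele),
               bad_se = sum(ok_allele & !ok_se),
               bad_beta = sum(ok_allele & ok_se & !ok_beta),
               bad_pval = sum(ok_allele & ok_se & ok_beta & !ok_pval),
               bad_eaf = sum(ok_allele & ok_se & ok_beta & ok_pval & !ok_eaf),
               bad_pos = sum(ok_allele & ok_se & ok_beta & ok_pval & ok_eaf & !ok_pos))
  keep <- ok_allele & ok_se & ok_beta & ok_pval & ok_eaf & ok_pos
  df <- df[keep, , drop = FALSE]

  dup <- duplicated(df$snp_id)
  reasons <- c(reasons, duplicate_id = sum(dup))
  df <- df[!dup, , drop = FALSE]

  for (r in names(reasons)) log_drop(reasons[[r]], r)
  if (nrow(df) == 0L) stop("no valid records after validation", call. = FALSE)

  rownames(df) <- NULL
  structure(df, class = c("gwas_table", "data.frame"),
            trait_meta = trait_meta, drops = reasons)
}

#' Read GWAS summary statistics from a delimited text file
#'
#' @param path File path; tab- or comma-delimited with a header row. The
#'   delimiter is auto-detected from the header unless `sep` is given.
#' @param column_map A [gwas_columns()] mapping of canonical fields to the
#'   file's header names.
#' @param trait_meta A [gwas_meta()] object describing the trait.
#' @param sep Optional explicit field separator.
#' @return A validated `gwas_table`; see [as_gwas_table()].
#' @export
read_gwas <- function(path, column_map = gwas_columns(), trait_meta, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  header <- readLines(path, n = 1L)
  if (is.null(sep)) sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           comment.char = "", quote = "\"")
  optional <- c("eaf", "n")
  mapped <- names(column_map)
  missing_cols <- vapply(mapped, function(f) !(column_map[[f]] %in% names(raw)),
                         logical(1))
  hard_missing <- mapped[missing_cols & !(mapped %in% optional)]
  if (length(hard_missing)) {
    stop("column(s) mapped but absent from file: ",
         paste(sprintf("%s (\"%s\")", hard_missing,
                       unlist(column_map[hard_missing])), collapse = ", "),
         call. = FALSE)
  }
  df <- data.frame(row.names = seq_len(nrow(raw)))
  for (f in mapped) {
    df[[f]] <- if (column_map[[f]] %in% names(raw)) raw[[column_map[[f]]]] else NA
  }
  as_gwas_table(df, trait_meta)
}

#' Write a GWAS table as a GWAS-SSF-style TSV
#'
#' Inverse of [read_gwas()] with the default column mapping; used for
#' fixtures and simulated studies.
#'
#' @param x A `gwas_table`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gwas <- function(x, path) {
  cm <- gwas_columns()
  out <- x[names(cm)]
  names(out) <- unlist(cm)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a harmonized exposure/outcome set directly
#'
#' Assembles per-SNP aligned exposure effects (`gamma`, `se_gamma`) and
#' outcome effects (`Gamma`, `se_Gamma`) without going through file I/O;
#' the estimators consume this class.
#'
#' @param gamma,se_gamma Exposure effect and its standard error, per SNP.
#' @param Gamma,se_Gamma Outcome effect and its standard error, per SNP.
#' @param snp_id Optional SNP ids (defaults to `snp_1 ... snp_J`).
#' @param effect_allele Optional shared effect alleles.
#' @return A `harmonized_set` data frame.
#' @export
harmonized_set <- function(gamma, se_gamma, Gamma, se_Gamma,
                           snp_id = NULL, effect_allele = NA_character_) {
  J <- length(gamma)
  stopifnot(J >= 1, length(se_gamma) == J, length(Gamma) == J,
            length(se_Gamma) == J)
  if (is.null(snp_id)) snp_id <- sprintf("snp_%d", seq_len(J))
  if (!all(is.finite(gamma) & is.finite(Gamma) &
           is.finite(se_gamma) & is.finite(se_Gamma))) {
    stop("all effects and standard errors must be finite", call. = FALSE)
  }
  if (any(se_gamma <= 0) || any(se_Gamma <= 0)) {
    stop("standard errors must be > 0", call. = FALSE)
  }
  structure(data.frame(snp_id = as.character(snp_id),
                       effect_allele = effect_allele,
                       gamma = gamma, se_gamma = se_gamma,
                       Gamma = Gamma, se_Gamma = se_Gamma,
                       stringsAsFactors = FALSE),
            class = c("harmonized_set", "data.frame"))
}

#' Align outcome effects to the exposure's effect alleles
#'
#' For each SNP shared by the two tables the outcome association is
#' re-expressed per copy of the exposure's effect allele: matching alleles
#' pass through; swapped alleles negate the outcome beta (and reflect its
#' allele frequency); strand flips (A<->T, C<->G complementation) are
#' resolved by complementing the outcome alleles first. Palindromic SNPs
#' (A/T or C/G pairs) carry no strand information in their labels and are
#' handled by `palindrome_policy`:
#'
#' * `"infer-by-frequency"` (default): orient by allele frequency when both
#'   studies report an EAF and both minor-allele frequencies are below
#'   `maf_threshold`; otherwise drop the SNP as ambiguous. Missing EAF on
#'   either side also drops the SNP.
#' * `"drop"`: drop every palindromic SNP.
#' * `"keep"`: trust the allele labels as printed (not recommended).
#'
#' Unresolvable SNPs are dropped with a per-reason log; the drop table is
#' attached as the `"drops"` attribute so that
#' `|shared| = |harmonized| + |dropped|` is auditable.
#'
#' @param exposure,outcome `gwas_table` objects.
#' @param palindrome_policy See above.
#' @param maf_threshold Frequency-inference cutoff (default 0.42).
#' @return A `harmonized_set` with attributes `drops` (data frame of
#'   `snp_id`, `reason`) and `n_shared`.
#' @export
harmonize <- function(exposure, outcome,
                      palindrome_policy = c("infer-by-frequency", "drop", "keep"),
                      maf_threshold = 0.42) {
  policy <- match.arg(palindrome_policy)
  shared <- intersect(exposure$snp_id, outcome$snp_id)
  if (length(shared) == 0L) {
    stop("exposure and outcome share no SNPs", call. = FALSE)
  }
  e <- exposure[match(shared, exposure$snp_id), , drop = FALSE]
  o <- outcome[match(shared, outcome$snp_id), , drop = FALSE]
  J <- length(shared)

  action <- rep(NA_character_, J)   # "keep" or "negate"
  reason <- rep(NA_character_, J)

  pal <- is_palindromic(e$effect_allele, e$other_allele)
  same <- o$effect_allele == e$effect_allele & o$other_allele == e$other_allele
  swap <- o$effect_allele == e$other_allele & o$other_allele == e$effect_allele
  o_ea_c <- complement_allele(o$effect_allele)
  o_oa_c <- complement_allele(o$other_allele)
  same_f <- o_ea_c == e$effect_allele & o_oa_c == e$other_allele
  swap_f <- o_ea_c == e$other_allele & o_oa_c == e$effect_allele

  np <- !pal
  action[np & (same | same_f)] <- "keep"
  action[np & !(same | same_f) & (swap | swap_f)] <- "negate"
  reason[np & is.na(action)] <- "allele_mismatch"

  if (any(pal)) {
    # For palindromes the complemented cases coincide with same/swap.
    pair_ok <- same | swap
    reason[pal & !pair_ok] <- "allele_mismatch"
    idx <- which(pal & pair_ok)
    if (policy == "drop") {
      reason[idx] <- "palindromic"
    } else if (policy == "keep") {
      action[idx] <- ifelse(same[idx], "keep", "negate")
    } else if (length(idx)) {
      eaf_e <- e$eaf[idx]
      eaf_o <- o$eaf[idx]
      miss <- is.na(eaf_e) | is.na(eaf_o)
      ambig <- !miss & (pmin(eaf_e, 1 - eaf_e) >= maf_threshold |
                          pmin(eaf_o, 1 - eaf_o) >= maf_threshold)
      # Frequency of the exposure's effect allele under the printed labels;
      # if it falls on the wrong side of 0.5 the strand must be flipped,
      # which for a palindrome reverses the orientation.
      q_label <- ifelse(same[idx], eaf_o, 1 - eaf_o)
      label_ok <- (q_label < 0.5) == (eaf_e < 0.5)
      act <- ifelse(label_ok == same[idx], "keep", "negate")
      ok <- !miss & !ambig
      reason[idx[miss]] <- "palindromic_missing_eaf"
      reason[idx[!miss & ambig]] <- "palindromic_ambiguous"
      action[idx[ok]] <- act[ok]
    }
  }

  kept <- !is.na(action)
  negate <- kept & action == "negate"
  Gamma <- ifelse(negate, -o$beta, o$beta)
  eaf_out <- ifelse(negate, 1 - o$eaf, o$eaf)

  drops <- data.frame(snp_id = shared[!kept], reason = reason[!kept],
                      stringsAsFactors = FALSE)
  if (nrow(drops)) {
    for (r in unique(drops$reason)) log_drop(sum(drops$reason == r), r)
  }
  if (!any(kept)) stop("no SNPs remain after harmonization", call. = FALSE)

  hs <- data.frame(snp_id = shared, effect_allele = e$effect_allele,
                   other_allele = e$other_allele,
                   chrom = e$chrom, pos = e$pos,
                   gamma = e$beta, se_gamma = e$se,
                   Gamma = Gamma, se_Gamma = o$se,
                   eaf_exposure = e$eaf, eaf_outcome = eaf_out,
                   stringsAsFactors = FALSE)[kept, , drop = FALSE]
  rownames(hs) <- NULL
  structure(hs, class = c("harmonized_set", "data.frame"),
            drops = drops, n_shared = J)
}

#' Drop log of a harmonization or filtering step
#' @param x Object carrying a `"drops"` attribute.
#' @return The drop record (data frame or named counts), possibly empty.
#' @export
harmonization_drops <- function(x) attr(x, "drops")

#' Write result tables plus a machine-readable run manifest
#'
#' Writes one TSV per named result table and a `manifest.json` recording
#' the package version, seed, configuration echo, per-table row counts and
#' the MD5 checksum of every written TSV. Re-running with the same inputs
#' and seed reproduces the TSVs byte-for-byte; only the manifest timestamp
#' differs.
#'
#' @param results Named list of data frames.
#' @param out_dir Output directory (created if needed).
#' @param config Optional configuration object echoed into the manifest.
#' @param seed Optional seed(s) echoed into the manifest.
#' @return Invisibly, the paths written.
#' @export
write_results <- function(results, out_dir, config = NULL, seed = NULL) {
  stopifnot(is.list(results), length(names(results)) == length(results))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (nm in names(results)) {
    p <- file.path(out_dir, paste0(nm, ".tsv"))
    df <- as.data.frame(results[[nm]])
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE,
                       na = "NA")
    paths <- c(paths, p)
  }
  md5 <- tools::md5sum(paths)
  names(md5) <- basename(paths)
  manifest <- list(
    package = "targetmr",
    version = as.character(utils::packageVersion("targetmr")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    config = config,
    tables = lapply(results, function(df) nrow(as.data.frame(df))),
    md5 = as.list(md5)
  )
  mp <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, pretty = TRUE,
                       null = "null", digits = NA)
  invisible(c(paths, mp))
}
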