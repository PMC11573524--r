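# Instrument selection: cis windows, LD clumping, confounder exclusion,
# instrument strength.

#' Define a gene region for cis-instrument selection
#'
#' @param gene_symbol Gene name (e.g. `"LPL"`).
#' @param chrom Chromosome label.
#' @param start,end Gene span in base pairs (1-based inclusive).
#' @param flank_kb Flanking window added on each side, in kb (default 100,
#'   i.e. instruments within +/-100 kb of the gene).
#' @return A `gene_region` list.
#' @export
gene_region <- function(gene_symbol, chrom, start, end, flank_kb = 100) {
  start <- as.numeric(start); end <- as.numeric(end)
  stopifnot(start <= end, flank_kb >= 0)
  structure(list(gene_symbol = gene_symbol, chrom = as.character(chrom),
                 start = start, end = end, flank_kb = flank_kb),
            class = "gene_region")
}

# Inclusive window [start - flank, end + flank] in bp.
region_window <- function(region) {
  c(region$start - region$flank_kb * 1000, region$end + region$flank_kb * 1000)
}

#' Clumping parameters
#'
#' The adaptive drug-target rule clumps at `r2_primary`; if fewer than
#' `min_snps` instruments survive, clumping is rerun from scratch at
#' `r2_fallback`. Two presets encode the rule-sets used for drug-target
#' biomarker instruments (`"drug_target"`: p < 5e-8, r2 < 0.3 falling back
#' to 0.4 when fewer than 3 SNPs survive) and for pQTL instruments
#' (`"pqtl"`: p < 5e-6, r2 < 0.001, 10,000 kb window, no fallback).
#'
#' @param r2_primary Primary LD r-squared threshold.
#' @param r2_fallback Relaxed threshold used when the primary run returns
#'   fewer than `min_snps` SNPs.
#' @param min_snps Count below which the fallback triggers. Exactly
#'   `min_snps` survivors at the primary threshold stand.
#' @param window_kb Clumping window in kb.
#' @param p_threshold Instrument significance threshold.
#' @param preset `"drug_target"` or `"pqtl"`; overrides the defaults.
#' @return A `clump_params` list.
#' @export
clump_params <- function(r2_primary = 0.3, r2_fallback = 0.4, min_snps = 3,
                         window_kb = 10000, p_threshold = 5e-8, preset = NULL) {
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("drug_target", "pqtl"))
    if (preset == "pqtl") {
      r2_primary <- 0.001; r2_fallback <- 0.001; min_snps <- 1
      window_kb <- 10000; p_threshold <- 5e-6
    }
  }
  stopifnot(r2_primary > 0, r2_primary <= r2_fallback, r2_fallback < 1,
            min_snps >= 1, window_kb > 0)
  structure(list(r2_primary = r2_primary, r2_fallback = r2_fallback,
                 min_snps = min_snps, window_kb = window_kb,
                 p_threshold = p_threshold, preset = preset),
            class = "clump_params")
}

#' Select cis SNPs around a drug-target gene
#'
#' Retains records on the region's chromosome with position inside the
#' inclusive window `[start - flank, end + flank]`, p-value strictly below
#' `p_threshold`, and effect-allele frequency above `eaf_min` (applied to
#' the stored EAF as reported; `strict_maf = TRUE` instead requires
#' `min(eaf, 1 - eaf) > eaf_min`). Records with missing EAF fail the
#' frequency filter. Per-filter drop counts are attached as `"provenance"`.
#'
#' @param table A `gwas_table`.
#' @param region A [gene_region()].
#' @param p_threshold Significance threshold (strict `<`; default 5e-8).
#' @param eaf_min Frequency threshold (strict `>`; default 0.01).
#' @param strict_maf Apply the threshold to the minor-allele frequency.
#' @return The filtered `gwas_table` (possibly empty, with a warning).
#' @export
select_cis_snps <- function(table, region, p_threshold = 5e-8,
                            eaf_min = 0.01, strict_maf = FALSE) {
  stopifnot(inherits(region, "gene_region"))
  win <- region_window(region)
  on_chr <- table$chrom == region$chrom
  in_win <- on_chr & table$pos >= win[1] & table$pos <= win[2]
  sig <- !is.na(table$pval) & table$pval < p_threshold
  freq <- if (strict_maf) pmin(table$eaf, 1 - table$eaf) else table$eaf
  eaf_ok <- !is.na(freq) & freq > eaf_min
  keep <- in_win & sig & eaf_ok
  provenance <- c(off_chromosome = sum(!on_chr),
                  outside_window = sum(on_chr & !in_win),
                  not_significant = sum(in_win & !sig),
                  eaf_filtered = sum(in_win & sig & !eaf_ok))
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) == 0L) {
    warning(sprintf("no cis instruments for %s after filtering",
                    region$gene_symbol), call. = FALSE)
  }
  structure(out, class = class(table), trait_meta = attr(table, "trait_meta"),
            provenance = provenance, region = region)
}

#' Greedy LD clumping with the adaptive fallback rule
#'
#' Sorts SNPs by ascending p-value (ties broken by position, then SNP id)
#' and keeps a SNP only if its r-squared with every already-kept SNP on the
#' same chromosome within `window_kb` is at or below the threshold. The run
#' uses `r2_primary`; if fewer than `min_snps` survive, it reruns from
#' scratch at `r2_fallback`, and the threshold actually applied is recorded
#' in the `"r2_threshold"` attribute.
#'
#' @param table A `gwas_table` of candidate instruments.
#' @param ld LD matrix of squared correlations covering every candidate
#'   (see [read_ld_matrix()]). Missing entries are an error.
#' @param params A [clump_params()] object.
#' @return An `instrument_set`: the retained rows with attributes
#'   `r2_threshold`, `fallback_used` and `provenance`.
#' @export
clump <- function(table, ld, params = clump_params()) {
  stopifnot(inherits(params, "clump_params"))
  missing_ids <- setdiff(table$snp_id, rownames(ld))
  if (length(missing_ids)) {
    stop("SNP(s) absent from the LD matrix: ",
         paste(missing_ids, collapse = ", "), call. = FALSE)
  }
  ord <- order(table$pval, table$pos, table$snp_id)
  ids <- table$snp_id[ord]
  pos <- table$pos[ord]
  chrom <- table$chrom[ord]
  win_bp <- params$window_kb * 1000

  greedy <- function(thr) {
    kept <- integer(0)
    for (i in seq_along(ids)) {
      conflict <- FALSE
      for (k in kept) {
        if (chrom[i] != chrom[k] || abs(pos[i] - pos[k]) > win_bp) next
        r2 <- ld[ids[i], ids[k]]
        if (is.na(r2)) {
          stop(sprintf("missing LD entry for pair %s / %s", ids[i], ids[k]),
               call. = FALSE)
        }
        if (r2 > thr) { conflict <- TRUE; break }
      }
      if (!conflict) kept <- c(kept, i)
    }
    kept
  }

  kept <- greedy(params$r2_primary)
  threshold <- params$r2_primary
  fallback <- FALSE
  if (length(kept) < params$min_snps &&
      params$r2_fallback > params$r2_primary) {
    kept <- greedy(params$r2_fallback)
    threshold <- params$r2_fallback
    fallback <- TRUE
  }

  out <- table[ord[kept], , drop = FALSE]
  rownames(out) <- NULL
  structure(out,
            class = unique(c("instrument_set", class(table))),
            trait_meta = attr(table, "trait_meta"),
            r2_threshold = threshold, fallback_used = fallback,
            provenance = c(attr(table, "provenance"),
                           clumped = nrow(table) - nrow(out)))
}

#' Remove instruments listed in a confounder-SNP blocklist
#'
#' The blocklist is a user-supplied table of SNP ids annotated with the
#' confounding trait that links them (e.g. obesity, smoking); any
#' instrument appearing in it is removed and the removal is logged with
#' its annotation.
#'
#' @param instruments An `instrument_set` (or any `gwas_table`).
#' @param blocklist Data frame with columns `snp_id` and `trait`, or `NULL`.
#' @return The filtered set; removals appended to `"provenance"` and the
#'   removed rows stored in the `"confounders_removed"` attribute.
#' @export
exclude_confounder_snps <- function(instruments, blocklist = NULL) {
  if (is.null(blocklist) || nrow(blocklist) == 0L) return(instruments)
  stopifnot(all(c("snp_id", "trait") %in% names(blocklist)))
  hit <- instruments$snp_id %in% blocklist$snp_id
  removed <- blocklist[match(instruments$snp_id[hit], blocklist$snp_id),
                       c("snp_id", "trait")]
  if (nrow(removed)) {
    message(sprintf("removed %d confounder-associated instrument(s): %s",
                    nrow(removed),
                    paste(sprintf("%s (%s)", removed$snp_id, removed$trait),
                          collapse = ", ")))
  }
  out <- instruments[!hit, , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) == 0L) warning("all instruments were blocklisted", call. = FALSE)
  structure(out, class = class(instruments),
            trait_meta = attr(instruments, "trait_meta"),
            r2_threshold = attr(instruments, "r2_threshold"),
            fallback_used = attr(instruments, "fallback_used"),
            provenance = c(attr(instruments, "provenance"),
                           confounder = nrow(removed)),
            confounders_removed = removed)
}

#' Per-SNP F-statistics and the mean-F weak-instrument diagnostic
#'
#' `F_j = (beta_j / se_j)^2`; a mean F at or below 10 raises the
#' conventional weak-instrument flag.
#'
#' @param table A `gwas_table` restricted to the instruments.
#' @return List with `per_snp` (data frame of `snp_id`, `f`), `mean_f` and
#'   logical `weak`.
#' @export
f_statistics <- function(table) {
  f <- (table$beta / table$se)^2
  list(per_snp = data.frame(snp_id = table$snp_id, f = f,
                            stringsAsFactors = FALSE),
       mean_f = mean(f), weak = mean(f) <= 10)
}

#' Read an LD matrix of squared correlations
#'
#' Accepts either a square matrix file (header row of SNP ids, first column
#' of SNP ids) or a long-format triplet file with columns
#' `snp_a`, `snp_b`, `r2`. Triplet files leave unlisted off-diagonal pairs
#' missing (`NA`), which [clump()] treats as an error rather than assuming
#' independence. The diagonal is forced to 1 and the matrix symmetrized.
#'
#' @param path File path (TSV/CSV).
#' @return Numeric matrix with SNP ids as dimnames.
#' @export
read_ld_matrix <- function(path) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  fields <- strsplit(header, sep, fixed = TRUE)[[1]]
  if (length(fields) == 3L && any(tolower(fields) %in% c("r2", "snp_a"))) {
    trip <- utils::read.table(path, header = TRUE, sep = sep,
                              stringsAsFactors = FALSE)
    ids <- unique(c(trip$snp_a, trip$snp_b))
    m <- matrix(NA_real_, length(ids), length(ids), dimnames = list(ids, ids))
    diag(m) <- 1
    for (i in seq_len(nrow(trip))) {
      m[trip$snp_a[i], trip$snp_b[i]] <- trip$r2[i]
      m[trip$snp_b[i], trip$snp_a[i]] <- trip$r2[i]
    }
  } else {
    raw <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1,
                             check.names = FALSE)
    m <- as.matrix(raw)
  }
  validate_ld_matrix(m)
}

validate_ld_matrix <- function(m) {
  stopifnot(is.matrix(m), nrow(m) == ncol(m), !is.null(rownames(m)))
  vals <- m[!is.na(m)]
  if (any(vals < 0 | vals > 1)) stop("LD r2 outside [0, 1]", call. = FALSE)
  if (any(abs(diag(m) - 1) > 1e-8)) stop("LD diagonal must be 1", call. = FALSE)
  if (!isTRUE(all.equal(m, t(m), tolerance = 1e-8))) {
    stop("LD matrix must be symmetric", call. = FALSE)
  }
  m
}

#' Read gene regions from a BED-like four-column table
#'
#' Columns: chrom, start, end, gene_symbol (tab-separated; a header line is
#' detected and skipped automatically).
#'
#' @param path File path.
#' @param flank_kb Flank applied to every region (default 100).
#' @return Named list of [gene_region()] objects keyed by gene symbol.
#' @export
read_gene_regions <- function(path, flank_kb = 100) {
  first <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  header <- suppressWarnings(is.na(as.numeric(first[2])))
  df <- utils::read.table(path, header = header, sep = "\t",
                          stringsAsFactors = FALSE)
  names(df)[1:4] <- c("chrom", "start", "end", "gene_symbol")
  regions <- lapply(seq_len(nrow(df)), function(i) {
    gene_region(df$gene_symbol[i], df$chrom[i], df$start[i], df$end[i],
                flank_kb = flank_kb)
  })
  names(regions) <- df$gene_symbol
  regions
}

#' Packaged drug-target gene regions
#'
#' Approximate GRCh37 spans of the ten lipid-lowering drug-target genes
#' (LDL-C: LDLR, HMGCR, NPC1L1, PCSK9, APOB, ABCG5, ABCG8; TG: LPL, APOC3,
#' PPARA), for cis-window selection.
#'
#' @param flank_kb Flank in kb (default 100).
#' @return Named list of [gene_region()] objects.
#' @export
drug_target_regions <- function(flank_kb = 100) {
  path <- system.file("extdata", "drug_target_regions.tsv",
                      package = "targetmr", mustWork = TRUE)
  read_gene_regions(path, flank_kb = flank_kb)
}

#' Read a confounder-SNP blocklist
#'
#' Two-column TSV (`snp_id`, `trait`); a header line is detected
#' automatically.
#'
#' @param path File path.
#' @return Data frame with columns `snp_id`, `trait`.
#' @export
read_blocklist <- function(path) {
  first <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  header <- identical(tolower(first[1]), "snp_id")
  df <- utils::read.table(path, header = header, sep = "\t",
                          stringsAsFactors = FALSE)
  names(df)[1:2] <- c("snp_id", "trait")
  df
}
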