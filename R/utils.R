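# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG state
#'
#' Seeds the RNG, evaluates `expr`, then restores the caller's RNG state so
#' that seeded internals (bootstraps, simulation-based tests) never perturb
#' the global random stream. A `NULL` seed evaluates `expr` as-is.
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = env)
    } else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(list = ".Random.seed", envir = env)
    }
  })
  set.seed(seed)
  expr
}

complement_allele <- function(x) chartr("ACGT", "TGCA", x)

# A/T and C/G pairs: the two strands carry the same two letters, so strand
# cannot be resolved from allele labels alone.
is_palindromic <- function(effect_allele, other_allele) {
  complement_allele(effect_allele) == other_allele
}

# Two-sided p from a standard-normal z.
z_pval <- function(z) 2 * stats::pnorm(-abs(z))

log_drop <- function(n, what) {
  if (n > 0) message(sprintf("dropped %d record(s): %s", n, what))
  invisible(n)
}
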