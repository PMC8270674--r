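# Internal helpers shared across modules.

DOMAINS <- c("bacteria", "archaea", "eukaryota")

#' Evaluate code under a fixed RNG seed, restoring the caller's RNG state
#'
#' All stochastic operations in the package route their randomness through
#' this helper so that a given seed yields identical output regardless of
#' what the caller's random stream looked like beforehand.
#'
#' @param seed integer seed, or `NULL` to leave the RNG stream untouched.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = env)
    } else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  })
  set.seed(seed)
  force(code)
}

# Deterministic per-stage seed derived from a single global seed, so
# pipeline stages do not share or perturb each other's random streams.
# Kept below 2^31 - 1 (R integers are 32 bit).
stage_seed <- function(seed, stage) {
  u <- utf8ToInt(stage)
  h <- sum(u * seq_along(u))
  as.integer((as.numeric(seed) %% 1e6 * 7919 + h * 104729) %% 2147483646L + 1)
}

# Overflow-safe log of the mean of exp(x).
log_mean_exp <- function(x) {
  m <- max(x)
  m + log(mean(exp(x - m)))
}

is_count_vector <- function(x) {
  is.numeric(x) && all(is.finite(x)) && all(x >= 0) && all(x == round(x))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Floats written to disk carry 6 significant digits (counts stay integer).
format_num <- function(x) {
  if (is.numeric(x) && !all(x == round(x), na.rm = TRUE)) {
    formatC(x, digits = 6, format = "g")
  } else {
    x
  }
}

write_tsv <- function(df, path) {
  out <- df
  for (j in seq_along(out)) out[[j]] <- format_num(out[[j]])
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
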