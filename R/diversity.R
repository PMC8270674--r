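# Rarefaction, alpha-diversity estimators and diversity-environment
# regressions. Estimator formulas follow the mothur conventions: Chao1 is
# bias-corrected by default, ACE uses the standard rare-abundance cutoff of
# 10 reads, Shannon is in nats, and Simpson is reported as the unbiased
# Gini-Simpson complement (the dominance form is available as a variant).

#' Rarefy a count vector to a fixed depth
#'
#' Subsamples reads without replacement so the result sums exactly to
#' `depth`; deterministic for a given seed.
#'
#' @param counts non-negative integer vector.
#' @param depth number of reads to keep (1 <= depth <= sum(counts)).
#' @param seed integer seed (NULL leaves the RNG stream untouched).
#' @return integer vector of the same length summing to `depth`.
#' @export
rarefy <- function(counts, depth, seed = NULL) {
  stopifnot(is_count_vector(counts), depth >= 1)
  total <- sum(counts)
  if (depth > total) {
    stop(sprintf("depth %d exceeds total reads %d", depth, total))
  }
  pool <- rep.int(seq_along(counts), counts)
  keep <- pool[with_seed(seed, sample.int(length(pool), depth))]
  out <- tabulate(keep, nbins = length(counts))
  names(out) <- names(counts)
  out
}

#' Rarefy every sample of an OTU table to per-domain depths
#'
#' Samples whose domain total falls short of the requested depth are
#' excluded for that domain with a warning (never silently kept).
#'
#' @param table an [otu_table()].
#' @param depths named vector of depths per domain.
#' @param seed integer seed; each sample-domain draw gets a derived seed.
#' @return an [otu_table()] of rarefied counts; excluded sample-domain
#'   combinations are recorded in attribute `excluded`.
#' @export
rarefy_table <- function(table, depths, seed = 1L) {
  counts <- table$counts
  out <- counts
  excluded <- character(0)
  for (d in intersect(DOMAINS, unique(table$domain))) {
    depth <- depths[[d]]
    if (is.null(depth) || is.na(depth)) stop("no rarefaction depth for domain ", d)
    rows <- names(table$domain)[table$domain == d]
    for (j in seq_len(ncol(counts))) {
      v <- counts[rows, j]
      if (sum(v) < depth) {
        excluded <- c(excluded, paste0(colnames(counts)[j], ":", d))
        out[rows, j] <- NA_integer_
        next
      }
      out[rows, j] <- rarefy(v, depth,
                             seed = stage_seed(seed, paste0(d, j)))
    }
  }
  if (length(excluded)) {
    warning("excluded (total reads below depth): ", paste(excluded, collapse = ", "))
  }
  res <- table
  res$counts <- out
  attr(res, "excluded") <- excluded
  res
}

#' Chao1 richness estimator
#'
#' Bias-corrected form `S_obs + F1 (F1 - 1) / (2 (F2 + 1))` with F1 and F2
#' the singleton and doubleton counts; the classic form
#' `S_obs + F1^2 / (2 F2)` is available via `bias_corrected = FALSE`.
#'
#' @param counts non-negative integer vector.
#' @param bias_corrected use the bias-corrected denominator (default TRUE).
#' @return richness estimate (>= observed richness).
#' @export
chao1 <- function(counts, bias_corrected = TRUE) {
  stopifnot(is_count_vector(counts))
  if (sum(counts) == 0) stop("chao1 undefined for an all-zero vector")
  s_obs <- sum(counts > 0)
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)
  if (bias_corrected) {
    s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
  } else {
    if (f2 == 0) return(s_obs + f1 * (f1 - 1) / 2)
    s_obs + f1^2 / (2 * f2)
  }
}

#' ACE richness estimator
#'
#' Abundance-based coverage estimator with rare cutoff `rare_cutoff`
#' (default 10 reads): `S_abund + S_rare / C + (F1 / C) * gamma^2`, with
#' `C = 1 - F1 / N_rare` the rare-class sample coverage and `gamma^2` the
#' rare-class coefficient of variation (floored at 0). When every rare read
#' is a singleton (C = 0) the estimator is undefined and the function falls
#' back to [chao1()] with a warning.
#'
#' @param counts non-negative integer vector.
#' @param rare_cutoff abundance cutoff separating rare from abundant OTUs.
#' @return richness estimate (>= observed richness).
#' @export
ace <- function(counts, rare_cutoff = 10) {
  stopifnot(is_count_vector(counts))
  if (sum(counts) == 0) stop("ace undefined for an all-zero vector")
  s_abund <- sum(counts > rare_cutoff)
  rare <- counts[counts > 0 & counts <= rare_cutoff]
  if (!length(rare)) return(s_abund)
  s_rare <- length(rare)
  n_rare <- sum(rare)
  f1 <- sum(rare == 1)
  c_ace <- 1 - f1 / n_rare
  if (c_ace == 0) {
    warning("all rare reads are singletons (C_ACE = 0); falling back to chao1")
    return(chao1(counts))
  }
  fi <- tabulate(rare, nbins = rare_cutoff)
  ssq <- sum(seq_len(rare_cutoff) * (seq_len(rare_cutoff) - 1) * fi)
  gamma2 <- if (n_rare > 1) {
    max(s_rare / c_ace * ssq / (n_rare * (n_rare - 1)) - 1, 0)
  } else 0
  s_abund + s_rare / c_ace + f1 / c_ace * gamma2
}

#' Shannon diversity index (natural log)
#' @param counts non-negative integer vector with positive total.
#' @param base logarithm base (default `exp(1)`: nats).
#' @return Shannon entropy `-sum p_i log p_i` over nonzero proportions.
#' @export
shannon <- function(counts, base = exp(1)) {
  stopifnot(is_count_vector(counts))
  n <- sum(counts)
  if (n == 0) stop("shannon undefined for an all-zero vector")
  p <- counts[counts > 0] / n
  -sum(p * log(p, base = base))
}

#' Simpson diversity index (unbiased)
#'
#' Dominance form `sum n_i (n_i - 1) / (N (N - 1))` — the probability two
#' reads drawn without replacement belong to the same OTU — and its
#' Gini-Simpson complement (the default).
#'
#' @param counts non-negative integer vector with total >= 2.
#' @param variant `"gini_simpson"` (1 - dominance, default) or
#'   `"dominance"`.
#' @return index in [0, 1).
#' @export
simpson <- function(counts, variant = c("gini_simpson", "dominance")) {
  variant <- match.arg(variant)
  stopifnot(is_count_vector(counts))
  n <- sum(counts)
  if (n < 2) stop("simpson requires at least 2 reads")
  dom <- sum(counts * (counts - 1)) / (n * (n - 1))
  if (variant == "dominance") dom else 1 - dom
}

#' Good's coverage
#' @param counts non-negative integer vector with positive total.
#' @return `1 - F1 / N`: the estimated probability that one more read
#'   belongs to an already-observed OTU.
#' @export
goods_coverage <- function(counts) {
  stopifnot(is_count_vector(counts))
  n <- sum(counts)
  if (n == 0) stop("goods_coverage undefined for an all-zero vector")
  1 - sum(counts == 1) / n
}

#' Per-sample, per-domain diversity table
#'
#' Rarefies each sample's domain slice to the domain depth (single seeded
#' draw per sample) and computes observed richness, Chao1, ACE, Shannon,
#' Simpson (Gini-Simpson) and Good's coverage.
#'
#' @param table an [otu_table()].
#' @param depths named per-domain rarefaction depths.
#' @param seed integer seed for the rarefaction draws.
#' @return data frame with one row per retained sample-domain combination.
#' @export
diversity_table <- function(table, depths, seed = 1L) {
  rt <- rarefy_table(table, depths, seed = seed)
  rows <- list()
  for (d in intersect(DOMAINS, unique(table$domain))) {
    ids <- names(table$domain)[table$domain == d]
    for (j in seq_len(ncol(rt$counts))) {
      v <- rt$counts[ids, j]
      if (anyNA(v)) next
      rows[[length(rows) + 1]] <- data.frame(
        sample_id = colnames(rt$counts)[j], domain = d,
        observed_otus = sum(v > 0),
        chao1 = chao1(v), ace = ace(v),
        shannon = shannon(v), simpson = simpson(v),
        goods_coverage = goods_coverage(v),
        depth_used = as.integer(depths[[d]]),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Ordinary least-squares fit of a diversity index against a covariate
#'
#' @param x covariate vector (not constant; n >= 3).
#' @param y response vector.
#' @return list of class `regression_fit` with `slope`, `intercept`,
#'   `r_squared`, `p_value` (two-sided t test on the slope, n - 2 df) and
#'   `n`. A constant response yields slope 0, R-squared 0, p 1.
#' @export
fit_linear <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("fit_linear needs at least 3 complete observations")
  if (stats::sd(x) == 0) stop("fit_linear: constant covariate")
  if (stats::sd(y) == 0) {
    return(structure(list(slope = 0, intercept = y[1], r_squared = 0,
                          p_value = 1, n = n), class = "regression_fit"))
  }
  fit <- stats::lm(y ~ x)
  # summary.lm warns on an exact fit; slope/R2/p are still well defined
  sm <- suppressWarnings(summary(fit))
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = sm$r.squared,
                 p_value = unname(sm$coefficients[2, 4]),
                 n = n), class = "regression_fit")
}

#' @export
print.regression_fit <- function(x, ...) {
  cat(sprintf("y = %.4fx + %.4f  (R2 = %.4f, P = %.4g, n = %d)\n",
              x$slope, x$intercept, x$r_squared, x$p_value, x$n))
  invisible(x)
}

#' Diversity-environment regression table
#'
#' Fits, per domain, one OLS regression of a diversity index against each
#' environmental variable, mirroring the usual elevational-gradient
#' reporting (equation, R-squared, P).
#'
#' @param div output of [diversity_table()].
#' @param metadata a `sample_metadata` data frame.
#' @param index diversity column to regress (default `"chao1"`).
#' @param variables metadata columns to use as covariates.
#' @return data frame with columns `domain`, `variable`, `slope`,
#'   `intercept`, `r_squared`, `p_value`, `n`.
#' @export
regression_table <- function(div, metadata, index = "chao1",
                             variables = c("latitude", "longitude",
                                           "elevation", "MAT", "MAP", "pH",
                                           "TC", "TN", "TC_TN", "EC")) {
  stopifnot(index %in% colnames(div))
  miss <- setdiff(variables, colnames(metadata))
  if (length(miss)) stop("metadata missing variables: ", paste(miss, collapse = ", "))
  rows <- list()
  for (d in unique(div$domain)) {
    sub <- div[div$domain == d, ]
    m <- metadata[match(sub$sample_id, metadata$sample_id), ]
    for (v in variables) {
      f <- fit_linear(m[[v]], sub[[index]])
      rows[[length(rows) + 1]] <- data.frame(
        domain = d, variable = v, slope = f$slope, intercept = f$intercept,
        r_squared = f$r_squared, p_value = f$p_value, n = f$n,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
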