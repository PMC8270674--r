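# Linear ordination of community composition: PCA, redundancy analysis
# (RDA) against environmental variables, and adjusted-R-squared variance
# partitioning. Communities are Hellinger-transformed by default, the
# standard pre-transformation that makes count data suitable for
# Euclidean-geometry ordination; `relative` and `none` are provided for
# sensitivity runs. All three operations are deterministic.

community_matrix <- function(table, domain = NULL) {
  if (inherits(table, "otu_table")) {
    if (!is.null(domain)) table <- subset_domain(table, domain)
    t(table$counts)                       # samples x OTUs
  } else {
    as.matrix(table)
  }
}

transform_community <- function(m, transform = c("hellinger", "relative", "none")) {
  transform <- match.arg(transform)
  switch(transform,
         none = m,
         relative = sweep(m, 1, pmax(rowSums(m), .Machine$double.eps), "/"),
         hellinger = sqrt(sweep(m, 1, pmax(rowSums(m), .Machine$double.eps), "/")))
}

# Flip axis signs so the largest-magnitude species loading on each axis is
# positive (eigenvector signs are otherwise arbitrary).
fix_signs <- function(scores, loadings) {
  for (k in seq_len(ncol(loadings))) {
    j <- which.max(abs(loadings[, k]))
    if (loadings[j, k] < 0) {
      loadings[, k] <- -loadings[, k]
      scores[, k] <- -scores[, k]
    }
  }
  list(scores = scores, loadings = loadings)
}

#' Principal components analysis of community composition
#'
#' Eigen-decomposition of the covariance of the transformed, column-centred
#' community matrix; axis k explains `lambda_k / sum(lambda)` of the total
#' variance, so the fractions over all axes sum to 1.
#'
#' @param table an [otu_table()] or a samples-x-OTUs matrix.
#' @param transform community pre-transformation (default `"hellinger"`).
#' @param domain optional domain to subset an [otu_table()] to.
#' @return object of class `ordination_result` with `method = "PCA"`,
#'   `site_scores` (samples x axes), `variance_explained` and
#'   `transform_used`.
#' @export
community_pca <- function(table, transform = "hellinger", domain = NULL) {
  m <- community_matrix(table, domain)
  if (nrow(m) < 3) stop("PCA needs at least 3 samples")
  if (ncol(m) < 2) stop("PCA needs at least 2 OTUs")
  y <- transform_community(m, transform)
  pc <- stats::prcomp(y, center = TRUE, scale. = FALSE)
  eig <- pc$sdev^2
  fx <- fix_signs(pc$x, pc$rotation)
  colnames(fx$scores) <- paste0("PC", seq_len(ncol(fx$scores)))
  structure(list(method = "PCA",
                 site_scores = fx$scores,
                 species_scores = fx$loadings,
                 variance_explained = eig / sum(eig),
                 transform_used = transform),
            class = "ordination_result")
}

scale_x <- function(xdf, vars) {
  x <- as.matrix(xdf[, vars, drop = FALSE])
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    stop("constant explanatory variable(s): ",
         paste(vars[sds == 0], collapse = ", "))
  }
  scale(x)
}

check_collinearity <- function(x) {
  s <- svd(x, nu = 0, nv = 0)$d
  if (s[1] / max(s[length(s)], .Machine$double.xmin) > 1e8) {
    qrx <- qr(x, tol = 1e-8)
    bad <- colnames(x)[qrx$pivot[seq(qrx$rank + 1, ncol(x))]]
    if (!length(bad)) bad <- colnames(x)
    stop("collinear explanatory variables (condition number > 1e8): ",
         paste(bad, collapse = ", "))
  }
}

#' Redundancy analysis of community composition
#'
#' Regresses the transformed, centred community matrix on the standardized
#' explanatory matrix and takes the PCA of the fitted values; constrained
#' axis variance is reported as a fraction of the *total* community
#' variance, so the constrained fractions sum to the (unadjusted)
#' redundancy R-squared.
#'
#' @param table an [otu_table()] or samples-x-OTUs matrix.
#' @param metadata a `sample_metadata` data frame (or any data frame with
#'   the explanatory columns), rows matching the samples.
#' @param variables explanatory column names.
#' @param transform community pre-transformation.
#' @param domain optional domain subset.
#' @return `ordination_result` with `method = "RDA"`, constrained
#'   `site_scores`, per-axis `variance_explained` (fractions of total
#'   variance), `variable_scores` (correlations of the standardized
#'   explanatory variables with the axes) and `constrained_fraction`.
#' @export
community_rda <- function(table, metadata, variables, transform = "hellinger",
                          domain = NULL) {
  m <- community_matrix(table, domain)
  miss <- setdiff(variables, colnames(metadata))
  if (length(miss)) stop("missing explanatory columns: ", paste(miss, collapse = ", "))
  x <- scale_x(as.data.frame(metadata), variables)
  n <- nrow(m)
  if (n <= length(variables)) {
    stop("need more samples than explanatory variables")
  }
  check_collinearity(x)
  y <- scale(transform_community(m, transform), center = TRUE, scale = FALSE)
  fit <- qr.fitted(qr(x), y)
  sv <- svd(fit)
  rank <- sum(sv$d > sv$d[1] * 1e-10)
  eig <- sv$d[seq_len(rank)]^2 / (n - 1)
  total <- sum(y^2) / (n - 1)
  scores <- sv$u[, seq_len(rank), drop = FALSE] %*% diag(sv$d[seq_len(rank)], rank)
  loadings <- sv$v[, seq_len(rank), drop = FALSE]
  fx <- fix_signs(scores, loadings)
  dimnames(fx$scores) <- list(rownames(m), paste0("RDA", seq_len(rank)))
  var_scores <- suppressWarnings(stats::cor(x, fx$scores))
  structure(list(method = "RDA",
                 site_scores = fx$scores,
                 species_scores = fx$loadings,
                 variance_explained = eig / total,
                 constrained_fraction = sum(eig) / total,
                 variable_scores = var_scores,
                 transform_used = transform),
            class = "ordination_result")
}

#' @export
print.ordination_result <- function(x, ...) {
  ve <- x$variance_explained
  cat(sprintf("%s (%s transform): first axes explain %s\n", x$method,
              x$transform_used,
              paste(sprintf("%.1f%%", 100 * utils::head(ve, 3)), collapse = ", ")))
  invisible(x)
}

# Redundancy R-squared of the community on a set of explanatory columns,
# with Ezekiel's adjustment.
redundancy_r2 <- function(y, xdf, vars, adjusted = TRUE) {
  n <- nrow(y)
  if (!length(vars)) return(0)
  x <- scale_x(xdf, vars)
  fit <- qr.fitted(qr(x), y)
  r2 <- sum(fit^2) / sum(y^2)
  if (!adjusted) return(r2)
  p <- length(vars)
  if (n - p - 1 <= 0) stop("too many predictors for adjusted R2 (n - p - 1 <= 0)")
  1 - (1 - r2) * (n - 1) / (n - p - 1)
}

#' Variance partitioning of community composition
#'
#' Partitions community variance among 2-4 named groups of explanatory
#' variables using adjusted (Ezekiel) R-squared from full and reduced
#' redundancy models: a group's unique fraction is
#' `R2adj(all) - R2adj(all minus group)`, the shared fraction is whatever
#' the groups jointly explain beyond the sum of unique fractions, and the
#' residual is `1 - R2adj(all)`, so unique + shared + residual sums to 1 by
#' construction. Individual variable contributions partial out all other
#' variables the same way. Adjusted fractions can be slightly negative and
#' are reported as-is.
#'
#' @param table an [otu_table()] or samples-x-OTUs matrix.
#' @param metadata data frame with the explanatory columns.
#' @param groups named list of disjoint character vectors of column names.
#' @param transform community pre-transformation.
#' @param domain optional domain subset.
#' @return object of class `vpa_result` with `group_fractions`,
#'   `individual_fractions`, `shared_fraction`, `residual_fraction`.
#' @export
variation_partition <- function(table, metadata, groups,
                                transform = "hellinger", domain = NULL) {
  if (length(groups) < 2 || length(groups) > 4) stop("need 2-4 groups")
  if (is.null(names(groups)) || any(names(groups) == "")) stop("groups must be named")
  if (any(!lengths(groups))) stop("every group must be nonempty")
  all_vars <- unlist(groups)
  if (anyDuplicated(all_vars)) {
    stop("groups overlap: ", paste(unique(all_vars[duplicated(all_vars)]), collapse = ", "))
  }
  xdf <- as.data.frame(metadata)
  miss <- setdiff(all_vars, colnames(xdf))
  if (length(miss)) stop("missing explanatory columns: ", paste(miss, collapse = ", "))
  m <- community_matrix(table, domain)
  y <- scale(transform_community(m, transform), center = TRUE, scale = FALSE)
  r2_full <- redundancy_r2(y, xdf, all_vars)
  unique_g <- vapply(groups, function(g) {
    r2_full - redundancy_r2(y, xdf, setdiff(all_vars, g))
  }, 0)
  individual <- vapply(all_vars, function(v) {
    r2_full - redundancy_r2(y, xdf, setdiff(all_vars, v))
  }, 0)
  structure(list(group_fractions = unique_g,
                 individual_fractions = individual,
                 shared_fraction = r2_full - sum(unique_g),
                 residual_fraction = 1 - r2_full,
                 transform_used = transform),
            class = "vpa_result")
}

#' @export
print.vpa_result <- function(x, ...) {
  cat("Variance partitioning (adjusted R2 fractions):\n")
  for (g in names(x$group_fractions)) {
    cat(sprintf("  %s: %.3f\n", g, x$group_fractions[[g]]))
  }
  cat(sprintf("  shared: %.3f\n  residual: %.3f\n",
              x$shared_fraction, x$residual_fraction))
  invisible(x)
}
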