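# Co-occurrence network construction: rare-OTU filtering, Spearman and
# SparCC correlation matrices with p-values, edge thresholding into a
# domain-labelled undirected graph, and per-scope topology summaries.
#
# SparCC (the sparse compositional correlation algorithm) estimates the
# correlations of the unobserved *basis* abundances from the log-ratio
# variances of the observed compositions: T_ij = var(log(x_i / x_j)) is
# computed on Dirichlet-resampled fractions, basis variances solve the
# linear system that assumes most pairs are uncorrelated, and the strongest
# correlated pairs are iteratively excluded from that system. The final
# estimate is the median over the outer resampling iterations; p-values
# come from a permutation bootstrap in which each OTU's counts are shuffled
# independently across samples.

#' Construct a correlation-matrix object
#'
#' @param r symmetric correlation matrix in [-1, 1] with unit diagonal and
#'   OTU ids as dimnames.
#' @param p symmetric p-value matrix in [0, 1] with zero diagonal.
#' @param method `"spearman"` or `"sparcc"`.
#' @param n_samples number of samples the correlations were estimated from.
#' @return object of class `corr_matrix`.
#' @export
corr_matrix <- function(r, p, method, n_samples) {
  stopifnot(is.matrix(r), is.matrix(p), nrow(r) == ncol(r),
            all(dim(r) == dim(p)), !is.null(rownames(r)))
  psym <- if (all(is.na(p))) 0 else max(abs(p - t(p)), na.rm = TRUE)
  if (max(abs(r - t(r))) > 1e-12 || psym > 1e-12) {
    stop("correlation and p matrices must be symmetric")
  }
  if (any(abs(r) > 1 + 1e-12)) stop("|r| must be <= 1")
  structure(list(otu_ids = rownames(r), r = r, p = p,
                 method = method, n_samples = as.integer(n_samples)),
            class = "corr_matrix")
}

#' @export
print.corr_matrix <- function(x, ...) {
  cat(sprintf("corr_matrix (%s): %d OTUs, n = %d samples\n",
              x$method, length(x$otu_ids), x$n_samples))
  invisible(x)
}

#' Discard rare OTUs before correlation analysis
#'
#' Keeps an OTU only if its pooled count across samples exceeds
#' `min_rel_abund` of its own domain's pooled total (strict inequality: an
#' OTU at exactly the threshold is discarded).
#'
#' @param table an [otu_table()].
#' @param min_rel_abund relative-abundance threshold (default 0.0005,
#'   i.e. 0.05%).
#' @return filtered [otu_table()].
#' @export
filter_rare_otus <- function(table, min_rel_abund = 0.0005) {
  stopifnot(inherits(table, "otu_table"))
  pooled <- rowSums(table$counts)
  dom <- as.character(table$domain)
  dom_tot <- tapply(pooled, dom, sum)
  keep <- pooled / dom_tot[dom] > min_rel_abund
  for (d in unique(dom)) {
    if (!any(keep[dom == d])) {
      stop("rare-OTU filter removed every ", d, " OTU")
    }
  }
  otu_table(table$counts[keep, , drop = FALSE], table$domain[keep],
            table$lineage[keep])
}

# all permutations of 1..n (used for exhaustive permutation p-values)
all_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

#' Spearman correlation matrix with p-values
#'
#' Rank correlation (average ranks for ties) between every pair of OTUs
#' across samples. P-values come either from the t approximation
#' `t = r sqrt((n-2)/(1-r^2))` on n - 2 df, or from permutation of one
#' member of each pair: when `factorial(n) <= n_perm` all permutations are
#' enumerated (exact p), otherwise `n_perm` random permutations are drawn
#' and p = (k + 1) / (n_perm + 1).
#'
#' Constant OTU rows have undefined correlations; their pairs are set to
#' r = 0, p = 1 with a message.
#'
#' @param table an [otu_table()] or an OTUs-x-samples count matrix.
#' @param p_method `"t_approx"` (default) or `"permutation"`.
#' @param n_perm permutations for `p_method = "permutation"`.
#' @param seed seed for the random permutations.
#' @return a [corr_matrix()].
#' @export
spearman_matrix <- function(table, p_method = c("t_approx", "permutation"),
                            n_perm = 999, seed = NULL) {
  p_method <- match.arg(p_method)
  x <- if (inherits(table, "otu_table")) table$counts else as.matrix(table)
  n <- ncol(x)
  if (n < 4) stop("need at least 4 samples")
  ranks <- t(apply(x, 1, rank))
  const <- apply(ranks, 1, function(v) stats::sd(v) == 0)
  r <- suppressWarnings(stats::cor(t(ranks)))
  if (any(const)) {
    message(sum(const), " constant OTU row(s): correlations set to 0, p to 1")
    r[const, ] <- 0; r[, const] <- 0
  }
  diag(r) <- 1
  r <- (r + t(r)) / 2
  if (p_method == "t_approx") {
    tt <- abs(r) * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
    p <- 2 * stats::pt(tt, df = n - 2, lower.tail = FALSE)
    p[abs(r) >= 1 - 1e-15] <- 0
  } else {
    p <- with_seed(seed, {
      exhaustive <- factorial(n) <= n_perm
      perms <- if (exhaustive) {
        all_perms(n)
      } else {
        t(replicate(n_perm, sample.int(n)))
      }
      cnt <- matrix(0L, nrow(x), nrow(x))
      for (b in seq_len(nrow(perms))) {
        rb <- suppressWarnings(stats::cor(t(ranks), t(ranks[, perms[b, ], drop = FALSE])))
        rb[is.na(rb)] <- 0
        cnt <- cnt + (abs(rb) >= abs(r) - 1e-12)
      }
      if (exhaustive) cnt / nrow(perms) else (cnt + 1) / (nrow(perms) + 1)
    })
    p <- (p + t(p)) / 2
  }
  if (any(const)) {
    p[const, ] <- 1; p[, const] <- 1
  }
  diag(p) <- 0
  dimnames(r) <- dimnames(p) <- list(rownames(x), rownames(x))
  corr_matrix(r, p, method = "spearman", n_samples = n)
}

# basis correlations from a log-ratio variance matrix, with iterative
# exclusion of the strongest correlated pairs
sparcc_basis <- function(Tm, n_exclusion_iter, exclusion_threshold) {
  D <- nrow(Tm)
  M <- matrix(1, D, D); diag(M) <- D - 1
  tvec <- rowSums(Tm)
  excluded <- matrix(FALSE, D, D)
  solve_rho <- function() {
    om <- pmax(solve(M, tvec), 1e-10)
    rho <- (outer(om, om, "+") - Tm) / (2 * sqrt(outer(om, om)))
    rho[rho > 1] <- 1
    rho[rho < -1] <- -1
    diag(rho) <- 1
    rho
  }
  rho <- solve_rho()
  for (k in seq_len(n_exclusion_iter)) {
    cand <- abs(rho)
    diag(cand) <- 0
    cand[excluded] <- 0
    if (max(cand) <= exclusion_threshold) break
    ij <- which(cand == max(cand), arr.ind = TRUE)[1, ]
    i <- ij[1]; j <- ij[2]
    excluded[i, j] <- excluded[j, i] <- TRUE
    M[i, i] <- M[i, i] - 1; M[j, j] <- M[j, j] - 1
    M[i, j] <- M[i, j] - 1; M[j, i] <- M[j, i] - 1
    tvec[i] <- tvec[i] - Tm[i, j]
    tvec[j] <- tvec[j] - Tm[i, j]
    rho <- solve_rho()
  }
  rho
}

sparcc_r_once <- function(x, pseudocount, n_outer_iter, n_exclusion_iter,
                          exclusion_threshold) {
  D <- nrow(x)
  reps <- array(NA_real_, c(D, D, n_outer_iter))
  alpha <- x + pseudocount
  for (b in seq_len(n_outer_iter)) {
    g <- matrix(stats::rgamma(length(alpha), shape = alpha), nrow = D)
    fr <- sweep(g, 2, colSums(g), "/")
    lf <- log(pmax(fr, .Machine$double.xmin))
    C <- stats::cov(t(lf))
    v <- diag(C)
    Tm <- outer(v, v, "+") - 2 * C
    reps[, , b] <- sparcc_basis(Tm, n_exclusion_iter, exclusion_threshold)
  }
  r <- apply(reps, c(1, 2), stats::median)
  r <- (r + t(r)) / 2
  diag(r) <- 1
  r
}

#' SparCC compositional correlation matrix
#'
#' @param table an [otu_table()] or an OTUs-x-samples count matrix with at
#'   least 10 OTUs (the basis-variance approximation needs a reasonably
#'   large composition) and at least 4 samples.
#' @param n_outer_iter Dirichlet resampling iterations; the reported r is
#'   the per-entry median across them.
#' @param n_exclusion_iter maximum strongly-correlated pairs excluded from
#'   the basis-variance system.
#' @param exclusion_threshold |r| above which a pair can be excluded.
#' @param n_bootstrap permutation datasets for p-values (each OTU's counts
#'   shuffled independently); 0 skips p-values (p = NA).
#' @param pseudocount added to every count before fraction estimation.
#' @param seed integer seed.
#' @return a [corr_matrix()] with `method = "sparcc"`.
#' @export
sparcc_matrix <- function(table, n_outer_iter = 20, n_exclusion_iter = 10,
                          exclusion_threshold = 0.1, n_bootstrap = 100,
                          pseudocount = 1, seed = NULL) {
  x <- if (inherits(table, "otu_table")) table$counts else as.matrix(table)
  if (nrow(x) < 10) {
    stop("SparCC needs at least 10 OTUs; use spearman_matrix() for smaller tables")
  }
  if (ncol(x) < 4) stop("need at least 4 samples")
  with_seed(seed, {
    r <- sparcc_r_once(x, pseudocount, n_outer_iter, n_exclusion_iter,
                       exclusion_threshold)
    if (n_bootstrap > 0) {
      cnt <- matrix(0L, nrow(x), nrow(x))
      for (b in seq_len(n_bootstrap)) {
        xb <- t(apply(x, 1, sample))
        rb <- sparcc_r_once(xb, pseudocount, n_outer_iter, n_exclusion_iter,
                            exclusion_threshold)
        cnt <- cnt + (abs(rb) >= abs(r))
      }
      p <- (cnt + 1) / (n_bootstrap + 1)
      p <- (p + t(p)) / 2
    } else {
      p <- matrix(NA_real_, nrow(x), nrow(x))
    }
    diag(p) <- 0
    dimnames(r) <- dimnames(p) <- list(rownames(x), rownames(x))
    corr_matrix(r, p, method = "sparcc", n_samples = ncol(x))
  })
}

#' Pooled within-domain relative abundance per OTU
#' @param table an [otu_table()].
#' @return named vector: pooled count / pooled total of the OTU's domain.
#' @export
pooled_rel_abundance <- function(table) {
  pooled <- rowSums(table$counts)
  dom <- as.character(table$domain)
  pooled / tapply(pooled, dom, sum)[dom]
}

#' Build a thresholded co-occurrence network
#'
#' An edge connects two OTUs iff `|r| > r_threshold` and `p < p_threshold`
#' (both strict). Nodes are *all* OTUs that entered the correlation
#' analysis, isolates included, each labelled with its domain and pooled
#' relative abundance.
#'
#' @param corr a [corr_matrix()].
#' @param domains named domain vector covering every OTU in `corr`.
#' @param abundances named pooled relative abundances (default 0).
#' @param r_threshold,p_threshold edge thresholds, both in (0, 1).
#' @return object of class `coocc_network` wrapping an igraph graph with
#'   vertex attributes `domain`, `abundance` and edge attributes `r`, `p`,
#'   `sign`, `link_class`.
#' @export
build_network <- function(corr, domains, abundances = NULL,
                          r_threshold = 0.6, p_threshold = 0.01) {
  stopifnot(inherits(corr, "corr_matrix"),
            r_threshold > 0, r_threshold < 1,
            p_threshold > 0, p_threshold < 1)
  ids <- corr$otu_ids
  miss <- setdiff(ids, names(domains))
  if (length(miss)) stop("no domain label for: ", paste(utils::head(miss, 5), collapse = ", "))
  if (is.null(abundances)) abundances <- stats::setNames(numeric(length(ids)), ids)
  ut <- upper.tri(corr$r)
  sel <- ut & abs(corr$r) > r_threshold & corr$p < p_threshold
  idx <- which(sel, arr.ind = TRUE)
  edges <- data.frame(
    source = ids[idx[, 1]], target = ids[idx[, 2]],
    r = corr$r[sel], p = corr$p[sel],
    sign = ifelse(corr$r[sel] > 0, "positive", "negative"),
    stringsAsFactors = FALSE)
  edges$link_class <- ifelse(domains[edges$source] == domains[edges$target],
                             "intradomain", "interdomain")
  vertices <- data.frame(name = ids,
                         domain = as.character(domains[ids]),
                         abundance = as.numeric(abundances[ids]),
                         stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE, vertices = vertices)
  g <- igraph::set_graph_attr(g, "r_threshold", r_threshold)
  g <- igraph::set_graph_attr(g, "p_threshold", p_threshold)
  g <- igraph::set_graph_attr(g, "method", corr$method)
  structure(list(graph = g, r_threshold = r_threshold,
                 p_threshold = p_threshold, method = corr$method),
            class = "coocc_network")
}

#' Edge table of a co-occurrence network
#' @param network a `coocc_network`.
#' @return data frame with columns `source`, `target`, `r`, `p`, `sign`,
#'   `link_class`.
#' @export
network_edges <- function(network) {
  g <- network$graph
  el <- igraph::as_edgelist(g)
  data.frame(source = el[, 1], target = el[, 2],
             r = igraph::E(g)$r, p = igraph::E(g)$p,
             sign = igraph::E(g)$sign,
             link_class = igraph::E(g)$link_class,
             stringsAsFactors = FALSE)
}

#' Domain label per network node
#' @param network a `coocc_network`.
#' @return named character vector.
#' @export
node_domains <- function(network) {
  g <- network$graph
  stats::setNames(igraph::V(g)$domain, igraph::V(g)$name)
}

#' @export
print.coocc_network <- function(x, ...) {
  g <- x$graph
  cat(sprintf("coocc_network (%s, |r| > %g, p < %g): %d nodes, %d edges\n",
              x$method, x$r_threshold, x$p_threshold,
              igraph::vcount(g), igraph::ecount(g)))
  invisible(x)
}

scope_metrics <- function(g, scope) {
  nn <- igraph::vcount(g)
  ne <- igraph::ecount(g)
  dens <- if (nn < 2) 0 else ne / (nn * (nn - 1) / 2)
  trans <- igraph::transitivity(g, type = "global")
  signs <- if (ne > 0) igraph::E(g)$sign else character(0)
  data.frame(
    scope = scope, n_nodes = nn, n_edges = ne,
    density = dens,
    avg_degree = if (nn > 0) 2 * ne / nn else 0,
    mean_betweenness = if (nn > 0) mean(igraph::betweenness(g, weights = NA)) else 0,
    transitivity = if (is.nan(trans)) NA_real_ else trans,
    n_positive = sum(signs == "positive"),
    n_negative = sum(signs == "negative"),
    pct_positive = if (ne > 0) 100 * mean(signs == "positive") else NA_real_,
    stringsAsFactors = FALSE)
}

#' Topological features per domain scope and for the whole network
#'
#' Per-domain rows are computed on the subgraph induced by that domain's
#' nodes (intradomain edges only); the `total` row covers the whole graph.
#' Density is `2E / (N (N - 1))`, average degree `2E / N`, betweenness is
#' the unnormalized shortest-path betweenness averaged over nodes, and
#' transitivity is the global clustering coefficient
#' (3 triangles / connected triples).
#'
#' @param network a `coocc_network`.
#' @return data frame, one row per scope.
#' @export
network_topology <- function(network) {
  g <- network$graph
  if (igraph::vcount(g) == 0) stop("empty network")
  doms <- intersect(DOMAINS, unique(igraph::V(g)$domain))
  rows <- lapply(doms, function(d) {
    sub <- igraph::induced_subgraph(g, igraph::V(g)[igraph::V(g)$domain == d])
    scope_metrics(sub, d)
  })
  rows[[length(rows) + 1]] <- scope_metrics(g, "total")
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
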