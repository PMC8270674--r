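# Domain-importance statistics: correlation frequency between and within
# domains under absence/presence scenarios, and natural-connectivity
# robustness of the network under node removal with whole-domain ablation.
#
# Natural connectivity is the spectral robustness measure
# ln( (1/N) sum_i exp(lambda_i) ) over the adjacency eigenvalues: the log
# of the average weighted count of closed walks, which decreases as the
# graph loses redundant paths.

#' Natural connectivity of an undirected graph
#'
#' @param adjacency square symmetric 0/1 matrix with zero diagonal.
#' @return `ln(mean(exp(lambda)))` over the adjacency eigenvalues, computed
#'   via symmetric eigendecomposition with an overflow-safe log-sum-exp
#'   (0 for an empty graph on any number of nodes).
#' @export
natural_connectivity <- function(adjacency) {
  a <- as.matrix(adjacency)
  if (nrow(a) == 0) return(0)
  if (nrow(a) != ncol(a)) stop("adjacency must be square")
  if (max(abs(a - t(a))) > 0) stop("adjacency must be symmetric")
  if (any(diag(a) != 0)) stop("adjacency must have a zero diagonal")
  if (!all(a %in% c(0, 1))) stop("adjacency must be a 0/1 matrix")
  lambda <- eigen(a, symmetric = TRUE, only.values = TRUE)$values
  log_mean_exp(lambda)
}

network_adjacency <- function(network, node_scope = NULL) {
  g <- if (inherits(network, "coocc_network")) network$graph else network
  if (!is.null(node_scope)) {
    g <- igraph::induced_subgraph(g, node_scope)
  }
  a <- as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE))
  a[a > 0] <- 1
  a
}

#' Correlation frequency between (or within) two domains
#'
#' Realized links divided by possible links, in percent. For two distinct
#' domains the possible links are `n_a * n_b`; within one domain they are
#' `n (n - 1) / 2`. Denominators use all analysed nodes (isolates
#' included).
#'
#' @param network a `coocc_network`.
#' @param domain_a,domain_b domain names (equal for intradomain frequency).
#' @return list with `real`, `possible`, `percent`.
#' @export
correlation_frequency <- function(network, domain_a, domain_b) {
  domain_a <- match.arg(domain_a, DOMAINS)
  domain_b <- match.arg(domain_b, DOMAINS)
  doms <- node_domains(network)
  n_a <- sum(doms == domain_a)
  n_b <- sum(doms == domain_b)
  if (n_a == 0 || n_b == 0) {
    stop("domain absent from network: ",
         paste(c(domain_a, domain_b)[c(n_a, n_b) == 0], collapse = ", "))
  }
  e <- network_edges(network)
  da <- doms[e$source]
  db <- doms[e$target]
  if (domain_a == domain_b) {
    real <- sum(da == domain_a & db == domain_a)
    possible <- n_a * (n_a - 1) / 2
  } else {
    real <- sum((da == domain_a & db == domain_b) |
                  (da == domain_b & db == domain_a))
    possible <- n_a * n_b
  }
  list(real = real, possible = possible, percent = 100 * real / possible)
}

#' Correlation-frequency table under domain ablation
#'
#' For each absent domain, reports the interdomain frequency between the
#' two remaining domains and the intradomain frequency within each,
#' computed by subsetting the full network's edges to the remaining node
#' set (no correlation re-estimation). With `reestimate` data, a caller can
#' instead rebuild the network per scenario and pass it here scenario by
#' scenario; the tabulated subsetting convention is the default because it
#' derives every scenario from one network.
#'
#' @param network a `coocc_network` containing all three domains.
#' @return data frame with columns `absent_domain`, `domain_pair`,
#'   `real_links`, `possible_links`, `frequency` (percent).
#' @export
ablation_frequencies <- function(network) {
  doms <- node_domains(network)
  present <- intersect(DOMAINS, unique(doms))
  if (length(present) < 3) stop("need a 3-domain network")
  rows <- list()
  for (absent in DOMAINS) {
    rest <- setdiff(DOMAINS, absent)
    combos <- list(c(rest[1], rest[2]), c(rest[1], rest[1]), c(rest[2], rest[2]))
    for (pair in combos) {
      f <- correlation_frequency(network, pair[1], pair[2])
      rows[[length(rows) + 1]] <- data.frame(
        absent_domain = absent,
        domain_pair = paste(unique(pair), collapse = "-"),
        real_links = f$real, possible_links = f$possible,
        frequency = f$percent, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

nc_after_removal <- function(a, drop_idx) {
  if (length(drop_idx)) a <- a[-drop_idx, -drop_idx, drop = FALSE]
  if (nrow(a) == 0) return(0)
  lambda <- eigen(a, symmetric = TRUE, only.values = TRUE)$values
  log_mean_exp(lambda)
}

#' Natural-connectivity robustness curve under node removal
#'
#' For each removal fraction, removes that share of the scope's nodes
#' (random removal: uniform without replacement, averaged over `n_reps`
#' seeded draws; `degree_desc`: deterministic, highest degree first) and
#' recomputes natural connectivity on the induced remaining subgraph, with
#' the remaining node count in the denominator and isolates kept.
#'
#' @param network a `coocc_network` or igraph graph.
#' @param node_scope optional vector of node names defining the scope
#'   (default: all nodes).
#' @param removal `"random"` or `"degree_desc"`.
#' @param fractions removal fractions in [0, 1).
#' @param n_reps repetitions for random removal.
#' @param seed integer seed.
#' @param scenario label stored on the curve.
#' @return object of class `robustness_curve`: a summary data frame
#'   (`fraction`, `mean`, `sd`) plus the per-rep value matrix.
#' @export
robustness_curve <- function(network, node_scope = NULL,
                             removal = c("random", "degree_desc"),
                             fractions = seq(0, 0.8, by = 0.2),
                             n_reps = 100, seed = 1L, scenario = "network") {
  removal <- match.arg(removal)
  if (any(fractions < 0 | fractions >= 1)) stop("fractions must lie in [0, 1)")
  a <- network_adjacency(network, node_scope)
  n <- nrow(a)
  if (n == 0) stop("empty node scope")
  fractions <- sort(fractions)
  if (removal == "degree_desc") {
    ord <- order(rowSums(a), rownames(a) %||% seq_len(n), decreasing = c(TRUE, FALSE),
                 method = "radix")
    values <- matrix(vapply(fractions, function(f) {
      nc_after_removal(a, ord[seq_len(floor(f * n))])
    }, 0), nrow = 1)
  } else {
    values <- with_seed(seed, {
      vapply(seq_len(n_reps), function(rep) {
        perm <- sample.int(n)
        vapply(fractions, function(f) {
          nc_after_removal(a, perm[seq_len(floor(f * n))])
        }, 0)
      }, numeric(length(fractions)))
    })
    values <- t(values)                  # reps x fractions
  }
  summary <- data.frame(fraction = fractions,
                        mean = colMeans(values),
                        sd = apply(values, 2, stats::sd))
  structure(list(scenario = scenario, removal = removal, summary = summary,
                 values = values, n_reps = nrow(values), seed = seed),
            class = "robustness_curve")
}

#' @export
print.robustness_curve <- function(x, ...) {
  cat(sprintf("robustness_curve [%s, %s removal, %d reps]: nc %.3f -> %.3f over fractions %g..%g\n",
              x$scenario, x$removal, x$n_reps,
              x$summary$mean[1], x$summary$mean[nrow(x$summary)],
              min(x$summary$fraction), max(x$summary$fraction)))
  invisible(x)
}

#' Robustness curves under whole-domain ablation
#'
#' Computes four random-removal robustness curves on a shared fraction
#' grid: the full three-domain network and each two-domain subnetwork (one
#' domain deleted before the removal experiment). Alongside the curves, a
#' per-fraction pairwise rank-sum (Wilcoxon) comparison across reps between
#' the three ablated scenarios is returned.
#'
#' @param network a `coocc_network` with all three domains.
#' @param fractions removal fractions in [0, 1).
#' @param n_reps random-removal repetitions per fraction.
#' @param seed integer seed.
#' @return list with `curves` (named list of [robustness_curve()]s, the
#'   full network under `"all-three"`) and `comparisons` (data frame of
#'   per-fraction Wilcoxon p-values between ablated scenarios).
#' @export
ablation_robustness <- function(network, fractions = seq(0, 0.8, by = 0.2),
                                n_reps = 100, seed = 1L) {
  doms <- node_domains(network)
  if (length(intersect(DOMAINS, unique(doms))) < 3) stop("need a 3-domain network")
  scen <- c(list(`all-three` = NULL),
            stats::setNames(as.list(DOMAINS), paste0(DOMAINS, "-absent")))
  curves <- list()
  for (nm in names(scen)) {
    absent <- scen[[nm]]
    scope <- if (is.null(absent)) names(doms) else names(doms)[doms != absent]
    curves[[nm]] <- robustness_curve(network, node_scope = scope,
                                     removal = "random", fractions = fractions,
                                     n_reps = n_reps,
                                     seed = stage_seed(seed, nm),
                                     scenario = nm)
  }
  ablated <- setdiff(names(curves), "all-three")
  comp <- list()
  for (i in seq_along(ablated)) {
    for (j in seq_along(ablated)) {
      if (i >= j) next
      a <- curves[[ablated[i]]]; b <- curves[[ablated[j]]]
      for (k in seq_along(fractions)) {
        va <- a$values[, k]; vb <- b$values[, k]
        pv <- if (max(c(va, vb)) - min(c(va, vb)) < 1e-15) 1 else
          suppressWarnings(stats::wilcox.test(va, vb, exact = FALSE)$p.value)
        comp[[length(comp) + 1]] <- data.frame(
          fraction = sort(fractions)[k],
          scenario_a = ablated[i], scenario_b = ablated[j],
          mean_a = mean(a$values[, k]), mean_b = mean(b$values[, k]),
          p_value = pv, stringsAsFactors = FALSE)
      }
    }
  }
  list(curves = curves,
       comparisons = do.call(rbind, c(comp, list(make.row.names = FALSE))))
}
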