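# Rare-OTU filtering, correlation matrices against brute-force oracles,
# the edge thresholding contract and graph topology.

test_that("rare-OTU filter applies a strict per-domain threshold", {
  counts <- matrix(0L, 5, 4,
                   dimnames = list(paste0("b", 1:5), paste0("S", 1:4)))
  counts[1, ] <- c(4000L, 3000L, 1500L, 1487L)   # abundant
  counts[2, ] <- c(2L, 1L, 1L, 1L)               # exactly 0.05% of 10000
  counts[3, ] <- c(3L, 1L, 1L, 1L)               # 0.06% -> retained
  counts[4, ] <- c(0L, 0L, 0L, 0L)               # absent
  counts[5, ] <- c(1L, 1L, 0L, 0L)               # 0.02%
  stopifnot(sum(counts) == 10000)
  dom <- stats::setNames(rep("bacteria", 5), rownames(counts))
  tab <- otu_table(counts, dom)
  kept <- rownames(filter_rare_otus(tab, 0.0005)$counts)
  expect_setequal(kept, c("b1", "b3"))
  kept0 <- rownames(filter_rare_otus(tab, 0)$counts)
  expect_setequal(kept0, c("b1", "b2", "b3", "b5"))
  expect_error(filter_rare_otus(tab, 0.999), "bacteria")
})

test_that("spearman matrix matches perfect monotone relationships", {
  x <- rbind(a = 1:6, b = c(2, 4, 7, 8, 9, 20), c = c(20, 9, 8, 7, 4, 2))
  colnames(x) <- paste0("S", 1:6)
  cm <- spearman_matrix(x)
  expect_equal(cm$r["a", "b"], 1)
  expect_equal(cm$r["a", "c"], -1)
  expect_equal(cm$p["a", "b"], 0)
  expect_equal(unname(diag(cm$r)), rep(1, 3))
  expect_equal(unname(diag(cm$p)), rep(0, 3))
})

test_that("spearman equals the rank-then-pearson brute force on 500 random pairs", {
  set.seed(99)
  for (i in 1:500) {
    n <- sample(5:25, 1)
    x <- stats::rpois(n, 6)
    y <- stats::rpois(n, 6)
    m <- rbind(a = x, b = y)
    colnames(m) <- paste0("S", seq_len(n))
    cm <- suppressMessages(spearman_matrix(m))
    oracle <- suppressWarnings(stats::cor(rank(x), rank(y)))
    if (is.na(oracle)) oracle <- 0     # constant vector convention
    expect_equal(cm$r["a", "b"], oracle, tolerance = 1e-12)
    oracle2 <- suppressWarnings(stats::cor(x, y, method = "spearman"))
    if (!is.na(oracle2)) expect_equal(cm$r["a", "b"], oracle2, tolerance = 1e-12)
  }
})

test_that("permutation p at n = 5 equals exhaustive enumeration", {
  # independent oracle: recursive enumeration of all 120 permutations
  permute_all <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in permute_all(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    }
    out
  }
  x <- c(3, 1, 4, 1, 5)
  y <- c(2, 7, 1, 8, 2)
  m <- rbind(a = x, b = y)
  colnames(m) <- paste0("S", 1:5)
  cm <- spearman_matrix(m, p_method = "permutation", n_perm = 120, seed = 1)
  r_obs <- suppressWarnings(stats::cor(x, y, method = "spearman"))
  r_null <- vapply(permute_all(seq_len(5)), function(pm) {
    suppressWarnings(stats::cor(x, y[pm], method = "spearman"))
  }, 0)
  p_oracle <- mean(abs(r_null) >= abs(r_obs) - 1e-12)
  expect_equal(cm$p["a", "b"], p_oracle)
})

test_that("constant OTU rows yield r = 0 and p = 1 with a note", {
  m <- rbind(a = c(5, 5, 5, 5, 5), b = c(1, 3, 2, 5, 4), c = c(2, 1, 4, 3, 5))
  colnames(m) <- paste0("S", 1:5)
  expect_message(cm <- spearman_matrix(m), "constant")
  expect_equal(cm$r["a", "b"], 0)
  expect_equal(cm$p["a", "c"], 1)
  expect_equal(cm$r["a", "a"], 1)
})

test_that("sparcc returns a unit diagonal and rejects tiny compositions", {
  sim <- recovery_sim()
  sp <- cached("sparcc_recovery",
               sparcc_matrix(sim$table, seed = 3))
  expect_equal(unname(diag(sp$r)), rep(1, nrow(sp$r)))
  expect_lt(max(abs(sp$r - t(sp$r))), 1e-12)
  expect_error(sparcc_matrix(sim$table$counts[1:5, ]), "at least 10 OTUs")
})

test_that("sparcc is near zero on a structure-free shuffled table", {
  sim <- recovery_sim()
  x <- sim$table$counts
  set.seed(9)
  xs <- t(apply(x, 1, sample))
  rownames(xs) <- rownames(x)
  spn <- sparcc_matrix(xs, n_bootstrap = 0, seed = 4)
  off <- abs(spn$r[upper.tri(spn$r)])
  expect_gte(mean(off < 0.3), 0.99)
})

test_that("sparcc recovers a planted basis correlation of 0.8 within 0.15", {
  sp <- cached("sparcc_recovery", sparcc_matrix(recovery_sim()$table, seed = 3))
  expect_lt(abs(sp$r["bac0001", "bac0002"] - 0.8), 0.15)
  expect_lt(abs(sp$r["bac0003", "bac0004"] - 0.8), 0.15)
  expect_lt(abs(sp$r["bac0006", "bac0008"] - (-0.8)), 0.15)
})

test_that("network edges obey the |r| and p thresholds strictly", {
  ids <- c("x", "y", "z", "w")
  rm_ <- diag(4); pm <- matrix(1, 4, 4); diag(pm) <- 0
  dimnames(rm_) <- dimnames(pm) <- list(ids, ids)
  rm_["x", "y"] <- rm_["y", "x"] <- 0.7;  pm["x", "y"] <- pm["y", "x"] <- 0.005
  rm_["x", "z"] <- rm_["z", "x"] <- 0.7;  pm["x", "z"] <- pm["z", "x"] <- 0.02
  rm_["y", "z"] <- rm_["z", "y"] <- -0.65; pm["y", "z"] <- pm["z", "y"] <- 0.001
  rm_["x", "w"] <- rm_["w", "x"] <- 0.6;  pm["x", "w"] <- pm["w", "x"] <- 0.001
  corr <- corr_matrix(rm_, pm, "spearman", 14)
  net <- build_network(corr, stats::setNames(rep("bacteria", 4), ids))
  e <- network_edges(net)
  expect_equal(nrow(e), 2)
  expect_setequal(pair_key(e$source, e$target), c("x y", "y z"))
  expect_identical(e$sign[pair_key(e$source, e$target) == "y z"], "negative")
  expect_equal(igraph::vcount(net$graph), 4)   # isolates retained
})

test_that("every emitted edge re-checks against the thresholds on synthetic data", {
  net <- default_network()
  e <- network_edges(net)
  expect_true(all(abs(e$r) > net$r_threshold))
  expect_true(all(e$p < net$p_threshold))
  expect_false(any(e$source == e$target))
  expect_false(anyDuplicated(pair_key(e$source, e$target)) > 0)
})

test_that("triangle and path topologies match hand enumeration", {
  tri <- network_from_edges(c("a", "b", "c"), rep("bacteria", 3),
                            rbind(c("a", "b"), c("b", "c"), c("a", "c")))
  tt <- network_topology(tri)
  tot <- tt[tt$scope == "total", ]
  expect_equal(tot$density, 1)
  expect_equal(tot$avg_degree, 2)
  expect_equal(tot$transitivity, 1)
  expect_equal(tot$mean_betweenness, 0)
  path <- network_from_edges(c("a", "b", "c"), rep("bacteria", 3),
                             rbind(c("a", "b"), c("b", "c")))
  pt <- network_topology(path)[1, ]     # single-domain scope == total
  expect_equal(pt$density, 2 / 3)
  expect_equal(pt$transitivity, 0)
  g <- path$graph
  expect_equal(unname(igraph::betweenness(g, weights = NA)[["b"]]), 1)
})

test_that("per-domain topology counts only intradomain structure", {
  net <- network_from_edges(c("a", "b", "p", "q"),
                            c("bacteria", "bacteria", "archaea", "archaea"),
                            rbind(c("a", "b"), c("a", "p"), c("p", "q")))
  tt <- network_topology(net)
  expect_equal(tt$n_edges[tt$scope == "bacteria"], 1)
  expect_equal(tt$n_edges[tt$scope == "archaea"], 1)
  expect_equal(tt$n_edges[tt$scope == "total"], 3)
  tot <- tt[tt$scope == "total", ]
  expect_equal(tot$avg_degree, tot$density * (tot$n_nodes - 1))
})

test_that("recovered network is dominated by positive and intradomain links", {
  e <- network_edges(default_network())
  expect_gt(sum(e$sign == "positive"), sum(e$sign == "negative"))
  expect_gt(sum(e$link_class == "intradomain"),
            sum(e$link_class == "interdomain"))
})

test_that("planted edges are recovered with high precision at 100 samples", {
  sim <- recovery_sim()
  sp <- cached("sparcc_recovery", sparcc_matrix(sim$table, seed = 3))
  net <- build_network(sp, sim$table$domain, pooled_rel_abundance(sim$table))
  e <- network_edges(net)
  pl <- sim$truth$edges
  expect_gt(nrow(e), 0)
  precision <- mean(pair_key(e$source, e$target) %in%
                      pair_key(pl$otu_a, pl$otu_b))
  expect_gte(precision, 0.8)
})
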