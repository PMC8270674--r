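# Natural connectivity, correlation frequencies and robustness under
# domain ablation, checked against eigenvalue closed forms and symmetry.

test_that("natural connectivity matches eigenvalue closed forms", {
  expect_equal(natural_connectivity(matrix(0, 5, 5)), 0)
  k3 <- matrix(1, 3, 3) - diag(3)
  expect_equal(natural_connectivity(k3),
               log((exp(2) + 2 * exp(-1)) / 3), tolerance = 1e-12)
  star <- matrix(0, 4, 4)
  star[1, 2:4] <- star[2:4, 1] <- 1
  expect_equal(natural_connectivity(star),
               log((exp(sqrt(3)) + 2 + exp(-sqrt(3))) / 4), tolerance = 1e-12)
  expect_error(natural_connectivity(matrix(c(0, 1, 0, 0), 2, 2)), "symmetric")
  expect_error(natural_connectivity(k3 + diag(3)), "diagonal")
})

test_that("natural connectivity is relabeling-invariant and monotone in edges", {
  set.seed(12)
  for (i in 1:40) {
    n <- sample(6:14, 1)
    a <- matrix(stats::rbinom(n * n, 1, 0.35), n, n)
    a[lower.tri(a)] <- t(a)[lower.tri(a)]
    diag(a) <- 0
    v <- natural_connectivity(a)
    pm <- sample.int(n)
    expect_equal(natural_connectivity(a[pm, pm]), v, tolerance = 1e-10)
  }
  # closed walks only decrease when an edge is deleted
  set.seed(13)
  for (i in 1:200) {
    n <- sample(5:12, 1)
    a <- matrix(stats::rbinom(n * n, 1, 0.4), n, n)
    a[lower.tri(a)] <- t(a)[lower.tri(a)]
    diag(a) <- 0
    edges <- which(upper.tri(a) & a == 1, arr.ind = TRUE)
    if (nrow(edges) == 0) next
    pick <- edges[sample.int(nrow(edges), 1), ]
    a2 <- a
    a2[pick[1], pick[2]] <- a2[pick[2], pick[1]] <- 0
    expect_lte(natural_connectivity(a2), natural_connectivity(a) + 1e-12)
  }
})

test_that("log-sum-exp agrees with the direct sum and survives large graphs", {
  set.seed(14)
  a <- matrix(stats::rbinom(225, 1, 0.3), 15, 15)
  a[lower.tri(a)] <- t(a)[lower.tri(a)]
  diag(a) <- 0
  lambda <- eigen(a, symmetric = TRUE, only.values = TRUE)$values
  expect_equal(natural_connectivity(a), log(mean(exp(lambda))), tolerance = 1e-9)
  # K_800: top eigenvalue 799, exp() overflows without log-sum-exp
  n <- 800
  expect_equal(natural_connectivity(matrix(1, n, n) - diag(n)),
               nc_complete(n), tolerance = 1e-9)
})

test_that("correlation frequency covers bipartite, empty and intradomain cases", {
  nodes <- c("a1", "a2", "b1", "b2", "b3")
  doms <- c("archaea", "archaea", "bacteria", "bacteria", "bacteria")
  full <- t(utils::combn(nodes, 2))
  bip <- full[xor(grepl("^a", full[, 1]), grepl("^a", full[, 2])), ]
  net <- network_from_edges(nodes, doms, bip)
  f <- correlation_frequency(net, "archaea", "bacteria")
  expect_equal(f$real, 6); expect_equal(f$possible, 6)
  expect_equal(f$percent, 100)
  expect_equal(correlation_frequency(net, "bacteria", "bacteria")$percent, 0)
  intra <- network_from_edges(nodes, doms, rbind(c("b1", "b2")))
  expect_equal(correlation_frequency(intra, "archaea", "bacteria")$percent, 0)
  fb <- correlation_frequency(intra, "bacteria", "bacteria")
  expect_equal(fb$possible, 3)
  expect_equal(fb$percent, 100 / 3, tolerance = 1e-9)
  expect_error(correlation_frequency(net, "eukaryota", "bacteria"), "absent")
})

test_that("ablation table is symmetric for symmetric networks and consistent", {
  nodes <- c("b1", "b2", "a1", "a2", "e1", "e2")
  doms <- c("bacteria", "bacteria", "archaea", "archaea",
            "eukaryota", "eukaryota")
  # every domain pair connected by exactly one edge; no intradomain edges
  edges <- rbind(c("b1", "a1"), c("b2", "e1"), c("a2", "e2"))
  net <- network_from_edges(nodes, doms, edges)
  tab <- ablation_frequencies(net)
  inter <- tab[grepl("-", tab$domain_pair), ]
  expect_equal(nrow(inter), 3)
  expect_lt(max(inter$frequency) - min(inter$frequency), 1e-9)
  expect_true(all(tab$frequency ==
                    100 * tab$real_links / tab$possible_links))
  intra_rows <- tab[!grepl("-", tab$domain_pair), ]
  expect_true(all(intra_rows$frequency == 0))
})

test_that("interdomain frequency is invariant under graph blow-up", {
  nodes <- c("b1", "b2", "a1")
  doms <- c("bacteria", "bacteria", "archaea")
  net <- network_from_edges(nodes, doms, rbind(c("b1", "a1")))
  f1 <- correlation_frequency(net, "archaea", "bacteria")
  # duplicate every node; connect copies wherever originals were connected
  big_nodes <- paste0(rep(nodes, each = 2), c(".1", ".2"))
  big_doms <- rep(doms, each = 2)
  orig <- rbind(c("b1", "a1"))
  big_edges <- do.call(rbind, lapply(seq_len(nrow(orig)), function(k) {
    expand.grid(paste0(orig[k, 1], c(".1", ".2")),
                paste0(orig[k, 2], c(".1", ".2")),
                stringsAsFactors = FALSE)
  }))
  net2 <- network_from_edges(big_nodes, big_doms, as.matrix(big_edges))
  f2 <- correlation_frequency(net2, "archaea", "bacteria")
  expect_equal(f1$percent, f2$percent, tolerance = 1e-9)
})

test_that("robustness on the complete graph matches the closed form at every count", {
  net <- complete_graph_network(10)
  fr <- (0:8) / 10
  cu <- robustness_curve(net, fractions = fr, n_reps = 5, seed = 2)
  expect_equal(cu$summary$mean, vapply(10 - (0:8), nc_complete, 0),
               tolerance = 1e-10)
  expect_equal(max(cu$summary$sd), 0, tolerance = 1e-12)
  cu2 <- robustness_curve(net, fractions = fr, n_reps = 5, seed = 2)
  expect_identical(cu$values, cu2$values)
  dd <- robustness_curve(net, removal = "degree_desc", fractions = fr)
  expect_equal(dd$summary$mean, cu$summary$mean, tolerance = 1e-10)
  expect_error(robustness_curve(net, fractions = c(0, 1)), "fractions")
})

test_that("removal fraction zero reproduces the whole-scope connectivity", {
  net <- default_network()
  cu <- robustness_curve(net, fractions = 0, n_reps = 3, seed = 7)
  expect_equal(cu$summary$mean[1],
               natural_connectivity(elevnet:::network_adjacency(net)),
               tolerance = 1e-10)
})

test_that("structurally identical domains give coinciding ablated curves", {
  # one triangle per domain, no interdomain edges
  nodes <- c(paste0("b", 1:3), paste0("a", 1:3), paste0("e", 1:3))
  doms <- rep(c("bacteria", "archaea", "eukaryota"), each = 3)
  tri <- function(p) rbind(c(paste0(p, 1), paste0(p, 2)),
                           c(paste0(p, 2), paste0(p, 3)),
                           c(paste0(p, 1), paste0(p, 3)))
  net <- network_from_edges(nodes, doms, rbind(tri("b"), tri("a"), tri("e")))
  rob <- ablation_robustness(net, fractions = c(0, 0.3), n_reps = 40, seed = 3)
  m <- vapply(rob$curves[-1], function(cu) cu$summary$mean, numeric(2))
  expect_lt(max(m[1, ]) - min(m[1, ]), 1e-9)       # deterministic at f = 0
  expect_lt(max(m[2, ]) - min(m[2, ]), 0.15)       # Monte-Carlo error at f > 0
})

test_that("with archaea as the planted hub, removing archaea hurts most", {
  net <- default_network()
  rob <- cached("ablation30",
                ablation_robustness(net, fractions = seq(0, 0.8, 0.2),
                                    n_reps = 30, seed = 5))
  m <- vapply(rob$curves, function(cu) cu$summary$mean, numeric(5))
  expect_true(all(m[, "archaea-absent"] < m[, "bacteria-absent"]))
  expect_true(all(m[, "archaea-absent"] < m[, "eukaryota-absent"]))
  expect_equal(rob$curves[["all-three"]]$summary$mean[1],
               natural_connectivity(elevnet:::network_adjacency(net)),
               tolerance = 1e-10)
})

test_that("archaea-involving correlation frequencies are the largest interdomain ones", {
  tab <- ablation_frequencies(default_network())
  inter <- tab[grepl("-", tab$domain_pair), ]
  get <- function(p) inter$frequency[inter$domain_pair == p][1]
  expect_gt(get("archaea-eukaryota"), get("bacteria-eukaryota"))
  expect_gt(get("bacteria-archaea"), get("bacteria-eukaryota"))
})
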