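# PCA / RDA / variance partitioning: closed-form cases, vegan as the
# independent oracle, and the adjusted-R2 partition identity.

random_community <- function(n = 12, p = 30, seed = 5) {
  set.seed(seed)
  matrix(stats::rpois(n * p, 5), n, p,
         dimnames = list(sprintf("S%02d", 1:n), sprintf("sp%02d", 1:p)))
}

test_that("samples on a line load entirely on PC1", {
  base <- c(1, 2, 3, 4, 5)
  m <- outer(seq(1, 4, length.out = 6), base)   # rank-1 community
  res <- community_pca(m, transform = "none")
  expect_equal(res$variance_explained[1], 1, tolerance = 1e-12)
})

test_that("PCA axis variance fractions sum to one and replicate vegan", {
  m <- random_community()
  res <- community_pca(m, transform = "hellinger")
  expect_equal(sum(res$variance_explained), 1, tolerance = 1e-9)
  expect_true(all(diff(res$variance_explained) <= 1e-12))
  skip_if_not_installed("vegan")
  hel <- vegan::decostand(m, "hellinger")
  veg <- vegan::rda(hel)
  ve <- veg$CA$eig / sum(veg$CA$eig)
  k <- length(ve)
  expect_equal(unname(res$variance_explained[1:k]), unname(ve), tolerance = 1e-8)
})

test_that("duplicated samples receive identical scores and tiny inputs error", {
  m <- random_community(n = 6)
  m2 <- rbind(m, m[3, , drop = FALSE])
  res <- community_pca(m2, transform = "relative")
  expect_equal(unname(res$site_scores[3, ]), unname(res$site_scores[7, ]),
               tolerance = 1e-10)
  expect_error(community_pca(m[1:2, ]), "3 samples")
})

test_that("RDA spans nothing for orthogonal predictors and everything for a saturated fit", {
  set.seed(9)
  n <- 20
  x <- data.frame(a = stats::rnorm(n), b = stats::rnorm(n))
  # community varying only in directions orthogonal to x
  y0 <- matrix(stats::rnorm(n * 5), n, 5)
  y_orth <- qr.resid(qr(scale(as.matrix(x))), y0)
  res <- community_rda(y_orth, x, c("a", "b"), transform = "none")
  expect_lt(res$constrained_fraction, 1e-10)
  # community an exact linear function of the predictors
  b <- matrix(stats::rnorm(2 * 4), 2, 4)
  y_lin <- scale(as.matrix(x)) %*% b
  res2 <- community_rda(y_lin, x, c("a", "b"), transform = "none")
  expect_equal(res2$constrained_fraction, 1, tolerance = 1e-10)
  expect_equal(sum(res2$variance_explained), 1, tolerance = 1e-10)
})

test_that("RDA axis fractions of total variance replicate vegan", {
  skip_if_not_installed("vegan")
  m <- random_community(n = 14, p = 25, seed = 13)
  set.seed(14)
  env <- data.frame(e1 = stats::rnorm(14), e2 = stats::rnorm(14),
                    e3 = stats::rnorm(14))
  res <- community_rda(m, env, c("e1", "e2", "e3"), transform = "hellinger")
  hel <- vegan::decostand(m, "hellinger")
  veg <- vegan::rda(hel ~ e1 + e2 + e3, data = env)
  tot <- veg$tot.chi
  expect_equal(unname(res$variance_explained),
               unname(veg$CCA$eig / tot), tolerance = 1e-8)
  expect_equal(res$constrained_fraction, veg$CCA$tot.chi / tot, tolerance = 1e-10)
})

test_that("collinear and constant predictors are rejected by name", {
  m <- random_community(n = 10)
  env <- data.frame(a = 1:10, b = 2 * (1:10), c = stats::rnorm(10))
  expect_error(community_rda(m, env, c("a", "b", "c"), transform = "none"),
               "collinear")
  env2 <- data.frame(a = 1:10, k = rep(1, 10))
  expect_error(community_rda(m, env2, c("a", "k"), transform = "none"),
               "constant.*k")
})

test_that("VPA recovers generative variance shares of orthogonal drivers", {
  set.seed(31)
  n <- 60
  x1 <- stats::rnorm(n); x2 <- stats::rnorm(n)
  x2 <- stats::residuals(stats::lm(x2 ~ x1))      # exactly orthogonal
  x1 <- scale(x1)[, 1]; x2 <- scale(x2)[, 1]
  p <- 20
  b1 <- stats::rnorm(p, 0, 1); b2 <- stats::rnorm(p, 0, 0.6)
  y <- outer(x1, b1) + outer(x2, b2) + matrix(stats::rnorm(n * p, 0, 1), n, p)
  # generative variance shares, computable from the coefficients
  tot <- sum(b1^2) + sum(b2^2) + p
  share1 <- sum(b1^2) / tot
  share2 <- sum(b2^2) / tot
  env <- data.frame(x1 = x1, x2 = x2)
  vp <- variation_partition(y, env, list(g1 = "x1", g2 = "x2"),
                            transform = "none")
  expect_lt(abs(vp$group_fractions[["g1"]] - share1), 0.05)
  expect_lt(abs(vp$group_fractions[["g2"]] - share2), 0.05)
})

test_that("VPA partition sums to one and rejects overlapping groups", {
  m <- random_community(n = 14, p = 20, seed = 17)
  md <- default_metadata()
  vp <- variation_partition(m, md,
                            list(climate = c("MAT", "MAP"),
                                 soil = c("pH", "EC", "TC_TN")))
  total <- sum(vp$group_fractions) + vp$shared_fraction + vp$residual_fraction
  expect_equal(total, 1, tolerance = 1e-6)
  expect_error(variation_partition(m, md, list(a = "pH", b = "pH")), "overlap")
  expect_error(variation_partition(m, md, list(a = "pH")), "2-4 groups")
})

test_that("two-group VPA agrees with the vegan varpart oracle", {
  skip_if_not_installed("vegan")
  m <- random_community(n = 16, p = 22, seed = 23)
  set.seed(24)
  env <- data.frame(a = stats::rnorm(16), b = stats::rnorm(16),
                    c = stats::rnorm(16))
  vp <- variation_partition(m, env, list(g1 = "a", g2 = c("b", "c")),
                            transform = "hellinger")
  hel <- vegan::decostand(m, "hellinger")
  vv <- vegan::varpart(hel, ~ a, ~ b + c, data = env)
  ind <- vv$part$indfract$Adj.R.square
  expect_equal(unname(vp$group_fractions[["g1"]]), ind[1], tolerance = 1e-8)
  expect_equal(unname(vp$group_fractions[["g2"]]), ind[2], tolerance = 1e-8)
  expect_equal(vp$shared_fraction, ind[3], tolerance = 1e-8)
  expect_equal(vp$residual_fraction, ind[4], tolerance = 1e-8)
})
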