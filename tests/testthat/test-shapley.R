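# Constructed score functions take a matrix (rows = instances) and return a
# vector, the same contract the detectors' scorers satisfy.
lin_fn <- function(w) function(Z) as.numeric(matrix(Z, ncol = length(w)) %*% w)

test_that("exact Shapley recovers coefficients of a linear score", {
  f <- lin_fn(c(2, 3))
  attr <- exact_shapley(f, x = c(1, 1), background = rbind(c(0, 0)))
  expect_equal(attr$phi, c(2, 3), tolerance = 1e-12)
  expect_equal(attr(attr, "base_value"), 0)
  expect_equal(attr(attr, "score"), 5)
})

test_that("exact Shapley satisfies the null-player and symmetry axioms", {
  # score ignores every feature
  const_fn <- function(Z) rep(4.2, nrow(matrix(Z, ncol = 3)))
  a <- exact_shapley(const_fn, x = c(1, 2, 3),
                     background = rbind(c(0, 0, 0), c(1, 1, 1)))
  expect_equal(a$phi, c(0, 0, 0), tolerance = 1e-12)
  # symmetric score with symmetric inputs and background
  sym_fn <- lin_fn(c(1, 1))
  b <- exact_shapley(sym_fn, x = c(2, 2), background = rbind(c(0, 0)))
  expect_equal(b$phi[1], b$phi[2], tolerance = 1e-12)
})

test_that("exact Shapley is linear in the score function", {
  set.seed(201)
  bg <- matrix(rnorm(12), ncol = 3)
  x <- rnorm(3)
  f <- function(Z) { Z <- matrix(Z, ncol = 3); Z[, 1]^2 + Z[, 2] }
  g <- function(Z) { Z <- matrix(Z, ncol = 3); sin(Z[, 3]) + Z[, 1] * Z[, 2] }
  af <- exact_shapley(f, x, bg)$phi
  ag <- exact_shapley(g, x, bg)$phi
  combo <- function(Z) 2 * f(Z) - 0.5 * g(Z)
  expect_equal(exact_shapley(combo, x, bg)$phi, 2 * af - 0.5 * ag,
               tolerance = 1e-9)
})

test_that("efficiency holds to 1e-9 on random nonlinear instances", {
  set.seed(202)
  for (trial in 1:5) {
    d <- sample(2:6, 1)
    bg <- matrix(rnorm(10 * d), ncol = d)
    x <- rnorm(d)
    f <- function(Z) { Z <- matrix(Z, ncol = d); exp(rowMeans(Z)) + Z[, 1]^2 }
    a <- exact_shapley(f, x, bg)
    expect_equal(sum(a$phi) + attr(a, "base_value"),
                 as.numeric(f(matrix(x, nrow = 1))), tolerance = 1e-9)
  }
})

test_that("group-level coalitions equal per-column attribution summed by group", {
  set.seed(203)
  gm <- tibble::tibble(feature = c("f1", "f2"), type = c("numerical", "categorical"),
                       first = c(1L, 3L), last = c(2L, 4L))
  bg <- matrix(rnorm(20), ncol = 4)
  x <- rnorm(4)
  f <- lin_fn(c(1, -2, 0.5, 3))  # linear, so the two routes coincide exactly
  by_group <- exact_shapley(f, x, bg, gm)
  per_col <- group_attributions(exact_shapley(f, x, bg), gm)
  expect_equal(by_group$phi, per_col$phi, tolerance = 1e-9)
  expect_equal(sum(per_col$phi), sum(exact_shapley(f, x, bg)$phi),
               tolerance = 1e-12)
})

test_that("group summation preserves totals and rejects bad maps", {
  a <- exact_shapley(lin_fn(c(1, 1, 1)), c(1, 2, 3), rbind(c(0, 0, 0)))
  gm <- tibble::tibble(feature = "all", type = "numerical", first = 1L, last = 3L)
  g <- group_attributions(a, gm)
  expect_equal(g$phi, sum(a$phi))
  bad <- tibble::tibble(feature = "x", type = "numerical", first = 1L, last = 5L)
  expect_error(group_attributions(a, bad), "match")
})

test_that("exact enumeration refuses too many groups and points to Monte Carlo", {
  f <- lin_fn(rep(1, 13))
  expect_error(exact_shapley(f, rep(1, 13), rbind(rep(0, 13))), "monte_carlo")
})

test_that("Monte-Carlo Shapley is seeded-deterministic and near the exact answer", {
  set.seed(204)
  d <- 6
  bg <- matrix(rnorm(15 * d), ncol = d)
  x <- rnorm(d) + 2
  f <- function(Z) { Z <- matrix(Z, ncol = d)
    Z[, 1]^2 + 3 * Z[, 2] - Z[, 3] * Z[, 4] + abs(Z[, 5]) }
  mc1 <- monte_carlo_shapley(f, x, bg, n_permutations = 400, seed = 11)
  mc2 <- monte_carlo_shapley(f, x, bg, n_permutations = 400, seed = 11)
  expect_equal(mc1$phi, mc2$phi, tolerance = 1e-15)
  exact <- exact_shapley(f, x, bg)
  err <- abs(mc1$phi - exact$phi)
  expect_true(all(err <= 3 * pmax(mc1$se, 1e-12)))
})

test_that("Monte-Carlo standard errors shrink as 1/sqrt(permutations)", {
  set.seed(205)
  d <- 5
  bg <- matrix(rnorm(10 * d), ncol = d)
  x <- rnorm(d)
  f <- function(Z) { Z <- matrix(Z, ncol = d); rowSums(Z^2) }
  se_small <- mean(monte_carlo_shapley(f, x, bg, n_permutations = 50,
                                       seed = 2)$se)
  se_big <- mean(monte_carlo_shapley(f, x, bg, n_permutations = 800,
                                     seed = 2)$se)
  expect_lt(se_big, se_small / 2.5)   # expect ~1/4, allow sampling noise
})

test_that("consensus attribution l1-rescales then averages across models", {
  mk <- function(phi) claimscope:::new_attribution(c("f1", "f2"), phi,
                                                   se = c(0, 0), 0, 0, "exact")
  cons <- consensus_attribution(list(mk(c(2, 2)), mk(c(1, 3))))
  expect_equal(cons$phi, c(0.375, 0.625), tolerance = 1e-12)
  single <- consensus_attribution(list(mk(c(2, 6))))
  expect_equal(single$phi, c(0.25, 0.75))
  with_zero <- consensus_attribution(list(mk(c(2, 2)), mk(c(0, 0))))
  expect_equal(with_zero$phi, c(0.25, 0.25))
  expect_error(consensus_attribution(list(mk(c(1, 2)),
                                          claimscope:::new_attribution("f1", 1, 0, 0, 0, "exact"))),
               "different feature sets")
})

test_that("detector scorers explain their own training rows consistently", {
  bc <- suppressWarnings(benchmark_claims(seed = 5, n_entities = 80))
  emb <- fit_embeddings(bc$table, k = 3)
  pr <- standardize_profiles(build_profiles(bc$table, emb))
  sc <- run_ensemble(pr, list(detector("ecdf", "ecdf_tail")))
  fn <- detector_score_fn(sc, "ecdf")
  X <- profile_matrix(pr)
  expect_equal(as.numeric(fn(X)), sc$ecdf, tolerance = 1e-12)
  expl <- explain_entity(pr, sc, pr$entity_ids[1], seed = 2)
  a <- expl$per_detector$ecdf
  expect_equal(sum(a$phi) + attr(a, "base_value"), sc$ecdf[1],
               tolerance = 1e-9)
})
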