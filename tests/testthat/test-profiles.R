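test_that("the six aggregate statistics are computed in fixed order", {
  expect_equal(aggregate_numerical(c(1, 2, 3)),
               c(sum = 6, mean = 2, median = 2, std = sqrt(2 / 3),
                 min = 1, max = 3),
               tolerance = 1e-9)
  expect_equal(unname(aggregate_numerical(5)), c(5, 5, 5, 0, 5, 5))
  expect_equal(unname(aggregate_numerical(c(2, 2, 2, 2))),
               c(8, 2, 2, 0, 2, 2))
})

test_that("missing values are excluded, all-missing is an error naming the feature", {
  expect_equal(unname(aggregate_numerical(c(1, NA, 3))[2]), 2)
  expect_error(aggregate_numerical(c(NA_real_, NA_real_),
                                   entity = "E1", feature = "amount"),
               "E1.*amount", class = "claimscope_aggregate_error")
})

test_that("embedded aggregation is the componentwise mean", {
  expect_equal(aggregate_embedded(rbind(c(1, 0, 0), c(0, 1, 0))),
               c(0.5, 0.5, 0))
  v <- c(0.2, -0.4, 0.9)
  expect_equal(aggregate_embedded(rbind(v)), v)
  expect_equal(aggregate_embedded(rbind(v, v, v, v)), v)
})

test_that("profile dimensionality is 6m + kq with the schema's layout", {
  tbl <- toy_claims()
  emb <- fit_embeddings(tbl, k = 2)
  pr <- build_profiles(tbl, emb)
  # 1 numerical * 6 + 2 categorical * 2
  expect_equal(ncol(profile_matrix(pr)), 6 + 2 * 2)
  expect_equal(pr$group_map$feature, c("amount", "spec", "code"))
  expect_equal(pr$expanded_names[1:6],
               paste0("amount__", c("sum", "mean", "median", "std", "min", "max")))
  # numerical-only schema
  num_only <- as_claims(tibble::tibble(gp_id = c("a", "b"), amount = c(1, 2)),
                        claims_schema("gp_id", numerical = "amount"))
  expect_equal(ncol(profile_matrix(build_profiles(num_only))), 6)
})

test_that("profile rows match hand-aggregated statistics and mean embeddings", {
  tbl <- toy_claims()
  emb <- fit_embeddings(tbl, k = 2)
  pr <- build_profiles(tbl, emb)
  X <- profile_matrix(pr)
  expect_equal(unname(X["a", 1:6]),
               unname(aggregate_numerical(c(1, 2, 3))), tolerance = 1e-12)
  want <- aggregate_embedded(rbind(embed_value(emb, "code", "X"),
                                   embed_value(emb, "code", "X"),
                                   embed_value(emb, "code", "Y")))
  expect_equal(unname(X["a", c("code__emb1", "code__emb2")]), want,
               tolerance = 1e-12)
})

test_that("profiles are invariant to action row order within an entity", {
  tbl <- toy_claims()
  emb <- fit_embeddings(tbl, k = 2)
  perm <- c(3, 1, 2, 5, 4, 6)  # permutes within entities a and b
  tbl2 <- as_claims(tibble::as_tibble(tbl)[perm, ], toy_schema())
  expect_equal(profile_matrix(build_profiles(tbl, emb)),
               profile_matrix(build_profiles(tbl2, emb)), tolerance = 1e-12)
})

test_that("standardization is the population z-score with constant-column guard", {
  tbl <- sized_claims(c(a = 1, b = 1, c = 1))
  pr <- build_profiles(tbl)
  pr$values[, 1] <- c(1, 2, 3)          # amount__sum column
  pr$values[, 4] <- 7                    # a constant column
  st <- standardize_profiles(pr)
  Z <- profile_matrix(st)
  expect_equal(unname(Z[, 1]), c(-1.22474487, 0, 1.22474487), tolerance = 1e-7)
  expect_equal(unname(Z[, 4]), c(0, 0, 0))
  expect_true(st$standardization$constant[4])
  expect_equal(st$standardization$scale[4], 1)
})

test_that("standardizing twice changes nothing on non-constant columns", {
  bc <- suppressWarnings(benchmark_claims(seed = 2, n_entities = 80))
  emb <- fit_embeddings(bc$table, k = 3)
  st1 <- standardize_profiles(build_profiles(bc$table, emb))
  st2 <- standardize_profiles(st1)
  keep <- !st1$standardization$constant
  expect_equal(profile_matrix(st2)[, keep], profile_matrix(st1)[, keep],
               tolerance = 1e-9)
})

test_that("fitted standardization applies to held-out rows", {
  tbl <- sized_claims(c(a = 2, b = 2, c = 2))
  pr <- build_profiles(tbl)
  st <- standardize_profiles(pr)
  z <- apply_standardization(st, pr$values[1, , drop = FALSE])
  expect_equal(unname(z[1, ]), unname(profile_matrix(st)[1, ]), tolerance = 1e-12)
  # a value equal to the column mean maps to 0
  mu <- st$standardization$mean
  expect_equal(unname(apply_standardization(st, matrix(mu, nrow = 1))[1, ]),
               rep(0, length(mu)))
})

test_that("the group map partitions the expanded columns exactly", {
  bc <- suppressWarnings(benchmark_claims(seed = 6, n_entities = 50))
  emb <- fit_embeddings(bc$table, k = 3)
  pr <- build_profiles(bc$table, emb)
  gm <- pr$group_map
  covered <- unlist(purrr::map2(gm$first, gm$last, seq))
  expect_equal(sort(covered), seq_len(ncol(profile_matrix(pr))))
  expect_equal(anyDuplicated(covered), 0L)
})

test_that("one-hot profiles carry within-entity token frequencies", {
  tbl <- toy_claims()
  pr <- build_profiles(tbl, encoder = "onehot")
  X <- profile_matrix(pr)
  expect_equal(unname(X["a", "code__onehot_X"]), 2 / 3)
  expect_equal(unname(X["a", "code__onehot_Y"]), 1 / 3)
  expect_equal(unname(X["a", "code__onehot_Z"]), 0)
})

test_that("profiles persist to delimited text and back", {
  tbl <- toy_claims()
  emb <- fit_embeddings(tbl, k = 2)
  st <- standardize_profiles(build_profiles(tbl, emb))
  path <- withr::local_tempfile(fileext = ".csv")
  write_profiles(st, path)
  back <- read_profiles(path)
  expect_equal(back$entity_ids, st$entity_ids)
  expect_equal(unname(back$values), unname(st$values), tolerance = 1e-12)
  expect_equal(back$group_map$feature, st$group_map$feature)
  expect_equal(back$standardization$mean, st$standardization$mean,
               tolerance = 1e-12)
})
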