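test_that("one-hot encoding follows the indicator definition", {
  expect_equal(unname(one_hot_encode("b", c("a", "b", "c"))), c(0, 1, 0))
  expect_equal(unname(one_hot_encode("a", "a")), 1)
  expect_equal(unname(one_hot_encode("z", c("a", "b", "c"))), c(0, 0, 0))
})

test_that("co-occurrence matrix marks category presence per action", {
  tbl <- as_claims(tibble::tibble(gp_id = c("g", "g"), spec = c("GP", "GP"),
                                  code = c("X", "Y"), amount = c(1, 2)),
                   toy_schema())
  cooc <- build_cooccurrence(tbl)
  X <- as.matrix(cooc$X)
  v <- cooc$vocabulary
  expect_equal(X[v$index[v$token == "GP"], ], c(1, 1))
  expect_equal(X[v$index[v$token == "X"], ], c(1, 0))
  expect_equal(X[v$index[v$token == "Y"], ], c(0, 1))
  # one 1 per categorical schema column in every action column
  expect_equal(unname(colSums(X)), c(2, 2))
})

test_that("identical actions give an all-ones row and column sums equal #categorical", {
  tbl <- as_claims(tibble::tibble(gp_id = rep("g", 3), spec = "GP",
                                  code = "X", amount = 1:3),
                   toy_schema())
  X <- as.matrix(build_cooccurrence(tbl)$X)
  expect_true(all(X == 1))
  expect_equal(unname(colSums(X)), rep(2, 3))
})

test_that("rank-1 LSA of a hand-worked matrix matches the closed form", {
  # X'X = [[2,1],[1,2]] has top eigenpair 3, (1,1)/sqrt(2), so
  # CS = X p1 * 1 = (2,1,1)/sqrt(2)
  X <- rbind(c(1, 1), c(1, 0), c(0, 1))
  emb <- fit_lsa(X, k = 1)
  expect_equal(unname(emb$raw[, 1]), c(1.41421356, 0.70710678, 0.70710678),
               tolerance = 1e-7)
  expect_equal(emb$singular_values, sqrt(3), tolerance = 1e-12)
})

test_that("truncated factorisation agrees with the dense SVD oracle", {
  set.seed(31)
  for (trial in 1:5) {
    X <- matrix(rbinom(12 * 30, 1, 0.3), nrow = 12)
    X <- X[rowSums(X) > 0, , drop = FALSE]
    k <- 3
    emb <- fit_lsa(X, k = k)
    sv <- svd(X)
    expect_equal(emb$singular_values, sv$d[seq_len(k)], tolerance = 1e-9)
    oracle_raw <- sv$u[, seq_len(k), drop = FALSE] %*% diag(sv$d[seq_len(k)], k)
    for (j in seq_len(k)) {
      # compare up to sign (the oracle has its own sign convention)
      expect_equal(abs(unname(emb$raw[, j])), abs(oracle_raw[, j]),
                   tolerance = 1e-8)
    }
  }
})

test_that("embeddings are unit l2-normalized", {
  bc <- suppressWarnings(benchmark_claims(seed = 3, n_entities = 100))
  emb <- fit_embeddings(bc$table, k = 3)
  norms <- sqrt(rowSums(emb$vectors^2))
  expect_true(all(abs(norms - 1) < 1e-9))
})

test_that("identical co-occurrence rows get identical embeddings", {
  X <- rbind(c(1, 0, 1, 0), c(1, 0, 1, 0), c(0, 1, 0, 1))
  emb <- fit_lsa(X, k = 2)
  expect_equal(unname(emb$vectors[1, ]), unname(emb$vectors[2, ]),
               tolerance = 1e-9)
})

test_that("the sign convention makes embeddings invariant to action order", {
  tbl <- toy_claims()
  emb1 <- fit_embeddings(tbl, k = 2)
  perm <- c(4, 2, 6, 1, 5, 3)
  tbl2 <- as_claims(tibble::as_tibble(tbl)[perm, ], toy_schema())
  emb2 <- fit_embeddings(tbl2, k = 2)
  expect_equal(emb1$vectors, emb2$vectors, tolerance = 1e-9)
})

test_that("rank-k reconstruction error is nonincreasing in k (Eckart-Young)", {
  set.seed(99)
  X <- matrix(rbinom(10 * 40, 1, 0.4), nrow = 10)
  X <- X[rowSums(X) > 0, , drop = FALSE]
  errs <- sapply(1:5, function(k) {
    sv <- svd(X)
    emb <- fit_lsa(X, k = k)
    # reconstruction via the package's triplets: CS P' with P from X'U/sigma
    U <- emb$raw %*% diag(1 / emb$singular_values, k)
    P <- t(X) %*% U %*% diag(1 / emb$singular_values, k)
    sqrt(sum((X - emb$raw %*% t(P))^2))
  })
  expect_true(all(diff(errs) <= 1e-9))
})

test_that("embed_value looks up stored vectors and zeroes unseen tokens", {
  tbl <- toy_claims()
  emb <- fit_embeddings(tbl, k = 2)
  v <- embed_value(emb, "code", "X")
  expect_length(v, 2)
  expect_equal(sqrt(sum(v^2)), 1, tolerance = 1e-9)
  expect_equal(embed_value(emb, "code", "NEVER_SEEN"), c(0, 0))
  expect_identical(embed_value(emb, "code", "X"), v)
  expect_error(embed_value(emb, "nope", "X"), "unknown")
})

test_that("k above the matrix rank is truncated with a warning", {
  X <- rbind(c(1, 1, 0), c(1, 1, 0))  # rank 1
  expect_warning(emb <- fit_lsa(X, k = 2), "rank")
  expect_equal(emb$k, 1L)
})

test_that("embedding tables persist through the versioned file format", {
  emb <- fit_embeddings(toy_claims(), k = 2)
  path <- withr::local_tempfile(fileext = ".json")
  write_embedding(emb, path)
  back <- read_embedding(path)
  expect_equal(back$vectors, emb$vectors, tolerance = 1e-12)
  expect_equal(back$singular_values, emb$singular_values, tolerance = 1e-12)
  expect_equal(back$vocabulary, emb$vocabulary)
})

test_that("unrelated tokens decorrelate as the action count grows", {
  set.seed(12)
  n <- 4000
  tbl <- as_claims(tibble::tibble(
    gp_id = "g",
    a = sample(c("u", "v"), n, replace = TRUE),
    b = sample(c("x", "y"), n, replace = TRUE),
    amount = 1
  ), claims_schema("gp_id", categorical = c("a", "b"), numerical = "amount"))
  emb <- fit_embeddings(tbl, k = 3)
  cos_uv <- sum(embed_value(emb, "a", "u") * embed_value(emb, "b", "x"))
  # independent tokens co-occur at chance level; cosine stays moderate
  expect_lt(abs(cos_uv), 0.9)
})
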