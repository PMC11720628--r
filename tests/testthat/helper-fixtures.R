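# Shared fixture builders: everything is generated in code at test time.

toy_schema <- function(period = NULL) {
  claims_schema("gp_id", categorical = c("spec", "code"),
                numerical = "amount", period = period)
}

# Hand-written 6-row claims table over 3 entities.
toy_claims <- function() {
  as_claims(tibble::tibble(
    gp_id = c("a", "a", "a", "b", "b", "c"),
    spec = c("GP", "GP", "GP", "GP", "OR", "OR"),
    code = c("X", "X", "Y", "X", "Z", "Z"),
    amount = c(1, 2, 3, 5, 7, 11)
  ), toy_schema())
}

# Claims table with n_per entity sizes, single categorical column; useful for
# filter threshold tests.
sized_claims <- function(sizes) {
  ids <- rep(names(sizes), times = sizes)
  as_claims(tibble::tibble(
    gp_id = ids,
    amount = seq_along(ids)
  ), claims_schema("gp_id", numerical = "amount"))
}

# Tiny two-specialty population spec for generator tests.
toy_pop_spec <- function(n_entities = 50, mean_actions = 30) {
  population_spec(
    n_entities = n_entities,
    actions = list(mean = mean_actions, dispersion = 10),
    specialties = list(
      alpha = list(
        categorical = list(code = c(A = 0.7, B = 0.2, C = 0.1)),
        numerical = list(amount = c(meanlog = log(10), sdlog = 0.5))
      ),
      beta = list(
        categorical = list(code = c(A = 0.1, B = 0.2, C = 0.7)),
        numerical = list(amount = c(meanlog = log(50), sdlog = 0.5))
      )
    )
  )
}

# Brute-force mean-distance-to-k-nearest oracle (O(n^2), the reference for
# the native kNN scorer).
knn_oracle <- function(X, k) {
  X <- as.matrix(X)
  n <- nrow(X)
  sapply(seq_len(n), function(i) {
    d <- sqrt(colSums((t(X[-i, , drop = FALSE]) - X[i, ])^2))
    mean(sort(d)[seq_len(k)])
  })
}

# Exhaustive pairwise-comparison AUROC oracle (ties count 1/2).
auroc_oracle <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + (p > q) + 0.5 * (p == q)
  }
  total / (length(pos) * length(neg))
}
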