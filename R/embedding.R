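#' One-hot encode a categorical value
#'
#' The dummy-encoding baseline: a value equal to the i-th vocabulary token
#' maps to the indicator vector with a single 1 at position i. Values outside
#' the vocabulary map to the all-zero vector.
#'
#' @param value A token.
#' @param vocab Ordered character vector of vocabulary tokens.
#' @return A binary vector of length `length(vocab)`, named by token.
#' @export
one_hot_encode <- function(value, vocab) {
  stopifnot(length(vocab) >= 1)
  setNames(as.numeric(vocab == value), vocab)
}

#' Build the binary category-by-action co-occurrence matrix
#'
#' Rows are all (column, token) pairs pooled over every categorical column of
#' the schema (tokens are namespaced by column, so identical spellings in
#' different columns stay distinct); columns are the individual actions.
#' Entry (i, j) is 1 iff vocabulary entry i appears in action j — strictly
#' presence, not counts. Each action column therefore has exactly one 1 per
#' categorical schema column.
#'
#' @param claims A `claims_tbl` with at least one categorical column and row.
#' @return A `cooccurrence` object: sparse binary matrix `X` (c x p) plus a
#'   `vocabulary` tibble (column, token, index).
#' @export
build_cooccurrence <- function(claims) {
  schema <- claims_schema_of(claims)
  if (length(schema$categorical) == 0L || nrow(claims) == 0L) {
    abort("co-occurrence matrix needs >= 1 categorical column and >= 1 row")
  }
  p <- nrow(claims)
  vocab_list <- map(schema$categorical, function(col) {
    tibble(column = col, token = sort(unique(claims[[col]])))
  })
  vocabulary <- bind_rows(vocab_list)
  vocabulary$index <- seq_len(nrow(vocabulary))
  key_index <- setNames(vocabulary$index, vocab_key(vocabulary$column, vocabulary$token))

  i_idx <- unlist(map(schema$categorical, function(col) {
    unname(key_index[vocab_key(col, claims[[col]])])
  }))
  j_idx <- rep(seq_len(p), times = length(schema$categorical))
  X <- Matrix::sparseMatrix(i = i_idx, j = j_idx, x = 1,
                            dims = c(nrow(vocabulary), p))
  X@x[] <- 1  # presence, not counts (relevant only if duplicates arose)
  structure(list(X = X, vocabulary = vocabulary), class = "cooccurrence")
}

#' Fit LSA embeddings by truncated SVD of the co-occurrence matrix
#'
#' Computes the top-k singular triplets of the binary co-occurrence matrix X
#' and takes the category side of the decomposition, `CS = XP` (one row per
#' vocabulary entry), then l2-normalises each row. The factorisation is
#' obtained from the symmetric eigendecomposition of the smaller Gram matrix
#' (XX' when there are fewer categories than actions, X'X otherwise), which
#' is exact and avoids densifying X.
#'
#' Sign indeterminacy is fixed per component: the entry of largest magnitude
#' in the corresponding action-side singular vector is made positive (ties
#' broken by lowest index), so embeddings are reproducible across runs and
#' action orderings.
#'
#' @param cooc A `cooccurrence` object from [build_cooccurrence()], or a
#'   plain (sparse or dense) binary matrix for low-level use.
#' @param k Embedding dimension (default 3). If `k` exceeds the numerical
#'   rank of X the table is truncated to the rank with a warning.
#' @return An `lsa_embedding`: `vectors` (c x k matrix of unit rows),
#'   `raw` (the un-normalised CS rows), `singular_values` (nonincreasing),
#'   `vocabulary`, `k`.
#' @export
fit_lsa <- function(cooc, k = 3) {
  if (inherits(cooc, "cooccurrence")) {
    X <- cooc$X
    vocabulary <- cooc$vocabulary
  } else {
    X <- methods::as(Matrix::Matrix(cooc, sparse = TRUE), "generalMatrix")
    vocabulary <- tibble(column = "feature",
                         token = as.character(seq_len(nrow(X))),
                         index = seq_len(nrow(X)))
  }
  c_dim <- nrow(X); p_dim <- ncol(X)
  stopifnot(k >= 1)
  if (k > min(c_dim, p_dim)) {
    abort("k must be <= min(dim(X))")
  }

  if (c_dim <= p_dim) {
    G <- as.matrix(Matrix::tcrossprod(X))        # c x c
    eg <- eigen(G, symmetric = TRUE)
    ev <- pmax(eg$values, 0)
    rank_tol <- max(ev) * max(c_dim, p_dim) * .Machine$double.eps
    rank_X <- sum(ev > rank_tol)
    k_eff <- min(k, rank_X)
    if (k_eff < k) {
      warn(paste0("requested k = ", k, " exceeds rank ", rank_X,
                  "; returning rank-limited embedding"))
    }
    sigma <- sqrt(ev[seq_len(k_eff)])
    U <- eg$vectors[, seq_len(k_eff), drop = FALSE]
    # action-side vectors for the sign convention: v_j = X'u_j / sigma_j
    V <- as.matrix(Matrix::crossprod(X, U)) %*% diag(1 / sigma, k_eff)
  } else {
    G <- as.matrix(Matrix::crossprod(X))         # p x p
    eg <- eigen(G, symmetric = TRUE)
    ev <- pmax(eg$values, 0)
    rank_tol <- max(ev) * max(c_dim, p_dim) * .Machine$double.eps
    rank_X <- sum(ev > rank_tol)
    k_eff <- min(k, rank_X)
    if (k_eff < k) {
      warn(paste0("requested k = ", k, " exceeds rank ", rank_X,
                  "; returning rank-limited embedding"))
    }
    sigma <- sqrt(ev[seq_len(k_eff)])
    V <- eg$vectors[, seq_len(k_eff), drop = FALSE]
    U <- as.matrix(X %*% V) %*% diag(1 / sigma, k_eff)
  }

  # sign convention: largest-|.|  entry of each action-side vector positive
  for (j in seq_len(k_eff)) {
    idx <- which.max(abs(V[, j]))   # ties: lowest index (which.max contract)
    if (V[idx, j] < 0) {
      V[, j] <- -V[, j]
      U[, j] <- -U[, j]
    }
  }

  raw <- U %*% diag(sigma, k_eff)   # rows of CS = XP
  norms <- sqrt(rowSums(raw^2))
  vectors <- raw / ifelse(norms > 0, norms, 1)
  rownames(raw) <- rownames(vectors) <- vocab_key(vocabulary$column, vocabulary$token)

  structure(
    list(k = k_eff, vectors = vectors, raw = raw, singular_values = sigma,
         vocabulary = vocabulary, sign_convention = "max-abs-P-entry-positive"),
    class = "lsa_embedding"
  )
}

#' Fit LSA embeddings directly from a claims table
#' @param claims A `claims_tbl`.
#' @param k Embedding dimension (default 3).
#' @return An `lsa_embedding` (see [fit_lsa()]).
#' @export
fit_embeddings <- function(claims, k = 3) {
  fit_lsa(build_cooccurrence(claims), k = k)
}

#' Look up the embedding of a categorical value
#'
#' @param embedding An `lsa_embedding`.
#' @param column Categorical column name (must have been seen at fit time).
#' @param value Token. Unseen tokens map to the zero vector (a neutral
#'   contribution under mean aggregation).
#' @return A numeric vector of length `k`.
#' @export
embed_value <- function(embedding, column, value) {
  stopifnot(inherits(embedding, "lsa_embedding"))
  if (!column %in% embedding$vocabulary$column) {
    abort(paste0("unknown categorical column: ", column))
  }
  key <- vocab_key(column, value)
  if (key %in% rownames(embedding$vectors)) {
    unname(embedding$vectors[key, ])
  } else {
    numeric(embedding$k)
  }
}

#' @export
print.lsa_embedding <- function(x, ...) {
  cat("<lsa_embedding> k =", x$k, "|", nrow(x$vectors), "categories over",
      length(unique(x$vocabulary$column)), "column(s)\n")
  cat("  singular values:", paste(signif(x$singular_values, 5), collapse = ", "), "\n")
  invisible(x)
}

#' @describeIn fit_lsa Tidy view: one row per (column, token, dimension).
#' @param x An `lsa_embedding`.
#' @param ... Unused.
#' @method tidy lsa_embedding
#' @export
tidy.lsa_embedding <- function(x, ...) {
  vecs <- as_tibble(x$vectors, .name_repair = ~ paste0("emb", seq_along(.)))
  bind_cols(x$vocabulary[c("column", "token")], vecs) |>
    tidyr::pivot_longer(dplyr::starts_with("emb"),
                        names_to = "dimension", values_to = "value")
}

#' @describeIn fit_lsa One-row summary: k, vocabulary size, spectrum share.
#' @method glance lsa_embedding
#' @export
glance.lsa_embedding <- function(x, ...) {
  tibble(k = x$k, n_categories = nrow(x$vectors),
         n_columns = length(unique(x$vocabulary$column)),
         sigma_1 = x$singular_values[1],
         sigma_k = x$singular_values[x$k])
}

#' Persist / restore an embedding table
#'
#' Writes a versioned plain-text (JSON) representation: vocabulary, k,
#' vectors, singular values, and the sign-convention tag.
#'
#' @param embedding An `lsa_embedding`.
#' @param path Output path.
#' @return `path` invisibly; `read_embedding()` returns the `lsa_embedding`.
#' @export
write_embedding <- function(embedding, path) {
  payload <- list(
    format = "claimscope-embedding/1",
    k = embedding$k,
    sign_convention = embedding$sign_convention,
    singular_values = embedding$singular_values,
    vocabulary = embedding$vocabulary,
    vectors = unname(as.matrix(embedding$vectors)),
    raw = unname(as.matrix(embedding$raw))
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_embedding
#' @export
read_embedding <- function(path) {
  payload <- jsonlite::fromJSON(path)
  vocabulary <- as_tibble(payload$vocabulary)
  vectors <- as.matrix(payload$vectors)
  raw <- as.matrix(payload$raw)
  rownames(vectors) <- rownames(raw) <- vocab_key(vocabulary$column, vocabulary$token)
  structure(
    list(k = payload$k, vectors = vectors, raw = raw,
         singular_values = as.numeric(payload$singular_values),
         vocabulary = vocabulary, sign_convention = payload$sign_convention),
    class = "lsa_embedding"
  )
}
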