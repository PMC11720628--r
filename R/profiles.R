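#' Aggregate a numerical feature over an entity's actions
#'
#' The six summary statistics, in fixed order: sum, mean, median, standard
#' deviation (population form, so a singleton has sd 0), minimum, maximum.
#' Missing values are excluded, never imputed as zero; an all-missing input
#' is an error.
#'
#' @param values Numeric vector (one entity's values of one feature).
#' @param entity,feature Optional labels used in the all-missing error.
#' @return Named numeric 6-vector: sum, mean, median, std, min, max.
#' @export
aggregate_numerical <- function(values, entity = NULL, feature = NULL) {
  v <- values[!is.na(values)]
  if (length(v) == 0L) {
    abort(paste0("all values missing",
                 if (!is.null(entity)) paste0(" for entity '", entity, "'"),
                 if (!is.null(feature)) paste0(", feature '", feature, "'")),
          class = "claimscope_aggregate_error")
  }
  c(sum = sum(v), mean = mean(v), median = median(v),
    std = pop_sd(v), min = min(v), max = max(v))
}

#' Aggregate embedded categorical values over an entity's actions
#'
#' Componentwise mean of the per-action embedding vectors.
#'
#' @param vectors Matrix with one row per action (or a list of equal-length
#'   vectors).
#' @return Numeric k-vector.
#' @export
aggregate_embedded <- function(vectors) {
  if (is.list(vectors)) {
    lens <- lengths(vectors)
    stopifnot(length(vectors) >= 1, length(unique(lens)) == 1)
    vectors <- do.call(rbind, vectors)
  }
  if (is.null(dim(vectors))) vectors <- matrix(vectors, nrow = 1)
  if (nrow(vectors) == 0L) abort("no vectors to aggregate")
  colMeans(vectors)
}

# ---- profile matrix -------------------------------------------------------

new_profiles <- function(values, entity_ids, group_map, expanded_names,
                         standardization = NULL, encoder = "lsa") {
  rownames(values) <- entity_ids
  colnames(values) <- expanded_names
  structure(
    list(entity_ids = entity_ids, values = values, group_map = group_map,
         expanded_names = expanded_names, standardization = standardization,
         encoder = encoder),
    class = "claims_profiles"
  )
}

#' @export
print.claims_profiles <- function(x, ...) {
  cat("<claims_profiles> ", length(x$entity_ids), " entities x ",
      ncol(x$values), " expanded features (",
      nrow(x$group_map), " original features; encoder: ", x$encoder, ")\n",
      sep = "")
  cat(if (is.null(x$standardization)) "  unstandardized\n" else "  standardized\n")
  invisible(x)
}

#' Collapse a claims table into one profile row per entity
#'
#' Builds the fixed-length provider profile: every numerical schema column
#' contributes its six aggregate statistics; every categorical column
#' contributes the mean of its per-action embedding vectors (`k` values with
#' the LSA encoder, or the within-entity token frequency vector with the
#' one-hot baseline). Column layout is all numerical groups first (schema
#' order, `feature__sum` ... `feature__max`), then all categorical groups
#' (schema order, `feature__emb1` ... or `feature__onehot_<token>`); a group
#' map ties every expanded column back to its original feature.
#'
#' @param claims A `claims_tbl`.
#' @param embedding An `lsa_embedding` covering the schema's categorical
#'   columns (required when `encoder = "lsa"` and there are categorical
#'   columns).
#' @param encoder `"lsa"` (default) or `"onehot"`.
#' @return An unstandardized `claims_profiles` object.
#' @export
build_profiles <- function(claims, embedding = NULL,
                           encoder = c("lsa", "onehot")) {
  encoder <- match.arg(encoder)
  schema <- claims_schema_of(claims)
  ids <- claims[[schema$entity_id]]
  entity_ids <- sort(unique(ids))
  n <- length(entity_ids)
  ent_idx <- match(ids, entity_ids)
  counts <- tabulate(ent_idx, nbins = n)

  blocks <- list()
  groups <- list()
  col_cursor <- 0L

  for (col in schema$numerical) {
    v <- claims[[col]]
    ok <- !is.na(v)
    n_ok <- tabulate(ent_idx[ok], nbins = n)
    if (any(n_ok == 0L)) {
      bad <- entity_ids[which(n_ok == 0L)[1L]]
      abort(paste0("all values missing for entity '", bad, "', feature '", col, "'"),
            class = "claimscope_aggregate_error")
    }
    sums <- rowsum_vec(v[ok], ent_idx[ok], n)
    means <- sums / n_ok
    sq <- rowsum_vec(v[ok]^2, ent_idx[ok], n)
    stds <- sqrt(pmax(sq / n_ok - means^2, 0))
    meds <- rep(NA_real_, n); mins <- rep(NA_real_, n); maxs <- rep(NA_real_, n)
    split_vals <- split(v[ok], ent_idx[ok])
    pos <- as.integer(names(split_vals))
    meds[pos] <- vapply(split_vals, median, numeric(1))
    mins[pos] <- vapply(split_vals, min, numeric(1))
    maxs[pos] <- vapply(split_vals, max, numeric(1))
    block <- cbind(sums, means, meds, stds, mins, maxs)
    colnames(block) <- paste0(col, "__", c("sum", "mean", "median", "std", "min", "max"))
    blocks[[length(blocks) + 1L]] <- block
    groups[[length(groups) + 1L]] <-
      tibble(feature = col, type = "numerical",
             first = col_cursor + 1L, last = col_cursor + 6L)
    col_cursor <- col_cursor + 6L
  }

  for (col in schema$categorical) {
    if (encoder == "lsa") {
      if (is.null(embedding)) {
        abort("encoder = 'lsa' requires a fitted embedding table")
      }
      keys <- vocab_key(col, claims[[col]])
      ridx <- match(keys, rownames(embedding$vectors))
      E <- matrix(0, nrow(claims), embedding$k)
      seen <- !is.na(ridx)
      E[seen, ] <- embedding$vectors[ridx[seen], , drop = FALSE]
      block <- rowsum(E, ent_idx) / counts[sort(unique(ent_idx))]
      # rowsum orders by group value; align to entity order
      block <- block[match(seq_len(n), as.integer(rownames(block))), , drop = FALSE]
      colnames(block) <- paste0(col, "__emb", seq_len(embedding$k))
      width <- embedding$k
    } else {
      vocab <- sort(unique(claims[[col]]))
      M <- Matrix::sparseMatrix(i = ent_idx, j = match(claims[[col]], vocab),
                                x = 1, dims = c(n, length(vocab)))
      block <- as.matrix(M) / counts
      colnames(block) <- paste0(col, "__onehot_", vocab)
      width <- length(vocab)
    }
    blocks[[length(blocks) + 1L]] <- block
    groups[[length(groups) + 1L]] <-
      tibble(feature = col, type = "categorical",
             first = col_cursor + 1L, last = col_cursor + width)
    col_cursor <- col_cursor + as.integer(width)
  }

  values <- do.call(cbind, blocks)
  group_map <- bind_rows(groups)
  new_profiles(values, entity_ids, group_map, colnames(values), encoder = encoder)
}

rowsum_vec <- function(x, g, n) {
  out <- numeric(n)
  s <- rowsum(x, g)
  out[as.integer(rownames(s))] <- s[, 1]
  out
}

#' Standardize a profile matrix
#'
#' Per column: subtract the column mean and divide by the column standard
#' deviation (population form). Constant columns are centred and divided by
#' 1 (flagged), so they become all-zero without being dropped — the group
#' map stays valid. The fitted (mean, scale) pairs are stored for reuse on
#' held-out entities via [apply_standardization()].
#'
#' @param profiles A `claims_profiles` (>= 2 entities).
#' @return The standardized `claims_profiles`.
#' @export
standardize_profiles <- function(profiles) {
  stopifnot(inherits(profiles, "claims_profiles"))
  X <- profiles$values
  if (nrow(X) < 2L) abort("standardization needs >= 2 entities")
  mu <- colMeans(X)
  sdv <- sqrt(pmax(colMeans(X^2) - mu^2, 0))
  constant <- sdv <= .Machine$double.eps^0.5 * pmax(abs(mu), 1)
  scale <- ifelse(constant, 1, sdv)
  Z <- sweep(sweep(X, 2, mu, "-"), 2, scale, "/")
  Z[, constant] <- 0
  profiles$values <- Z
  profiles$standardization <- tibble(
    column = profiles$expanded_names, mean = unname(mu),
    scale = unname(scale), constant = unname(constant)
  )
  profiles
}

#' @rdname standardize_profiles
#' @param newdata A numeric matrix (rows in the profile column layout) to
#'   standardize with previously fitted parameters.
#' @export
apply_standardization <- function(profiles, newdata) {
  st <- profiles$standardization
  if (is.null(st)) abort("profiles are not standardized yet")
  newdata <- matrix(newdata, ncol = length(st$column))
  Z <- sweep(sweep(newdata, 2, st$mean, "-"), 2, st$scale, "/")
  Z[, st$constant] <- 0
  Z
}

#' Matrix view of a profile object
#' @param profiles A `claims_profiles`.
#' @return The numeric entity-by-feature matrix (row/col names set).
#' @export
profile_matrix <- function(profiles) profiles$values

#' @describeIn build_profiles Tidy view: one row per (entity, expanded column).
#' @param x A `claims_profiles`.
#' @param ... Unused.
#' @method tidy claims_profiles
#' @export
tidy.claims_profiles <- function(x, ...) {
  key <- expand_group_map(x$group_map)
  key$column <- x$expanded_names[key$index]
  as_tibble(x$values, rownames = "entity_id") |>
    tidyr::pivot_longer(-"entity_id", names_to = "column", values_to = "value") |>
    left_join(key[c("column", "feature", "type")], by = "column")
}

#' @describeIn build_profiles One-row summary of the profile matrix.
#' @method glance claims_profiles
#' @export
glance.claims_profiles <- function(x, ...) {
  tibble(n_entities = length(x$entity_ids), n_expanded = ncol(x$values),
         n_features = nrow(x$group_map), encoder = x$encoder,
         standardized = !is.null(x$standardization))
}

expand_group_map <- function(group_map) {
  bind_rows(map(seq_len(nrow(group_map)), function(i) {
    tibble(feature = group_map$feature[i], type = group_map$type[i],
           index = group_map$first[i]:group_map$last[i])
  }))
}

#' Persist / restore a profile matrix
#'
#' Delimited text: the entity-by-feature table plus JSON sidecars for the
#' group map and standardization parameters.
#'
#' @param profiles A `claims_profiles`.
#' @param path Output CSV path (sidecar written to `<path>.meta.json`).
#' @return `path` invisibly; `read_profiles()` returns the object.
#' @export
write_profiles <- function(profiles, path) {
  tbl <- as_tibble(profiles$values)
  tbl <- bind_cols(tibble(entity_id = profiles$entity_ids), tbl)
  readr::write_csv(tbl, path)
  meta <- list(group_map = profiles$group_map, encoder = profiles$encoder,
               standardization = profiles$standardization)
  jsonlite::write_json(meta, paste0(path, ".meta.json"), digits = NA,
                       auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_profiles
#' @export
read_profiles <- function(path) {
  tbl <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  meta <- jsonlite::fromJSON(paste0(path, ".meta.json"))
  values <- as.matrix(tbl[-1])
  st <- if (is.null(meta$standardization) || length(meta$standardization) == 0) {
    NULL
  } else {
    as_tibble(meta$standardization)
  }
  new_profiles(values, tbl$entity_id, as_tibble(meta$group_map),
               colnames(values), standardization = st, encoder = meta$encoder)
}
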