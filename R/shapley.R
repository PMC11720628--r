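#' Background set for Shapley attributions
#'
#' A seeded sample of profile rows serving as the reference distribution:
#' "absent" features are replaced by background values, so an attribution
#' measures how much moving a feature from typical to observed changes the
#' anomaly score.
#'
#' @param profiles A `claims_profiles` (standardized) or numeric matrix.
#' @param size Number of rows to sample without replacement (default 100,
#'   capped at the number of entities).
#' @param seed Integer seed.
#' @return A numeric matrix of background rows.
#' @export
background_set <- function(profiles, size = 100, seed = 1L) {
  X <- as_matrix_input(profiles)
  size <- min(size, nrow(X))
  stopifnot(size >= 1)
  old <- .Random.seed_exists(); on.exit(restore_rng(old), add = TRUE)
  set.seed(mix_seed(seed, 424243L))
  X[sample.int(nrow(X), size), , drop = FALSE]
}

# Column-index groups from a FeatureGroupMap (or one group per column).
attribution_groups <- function(x, group_map = NULL) {
  if (is.null(group_map)) {
    setNames(as.list(seq_along(x)),
             names(x) %||% paste0("x", seq_along(x)))
  } else {
    setNames(map(seq_len(nrow(group_map)),
                 function(i) group_map$first[i]:group_map$last[i]),
             group_map$feature)
  }
}

# Coalition value v(S): mean over background rows of score_fn applied to the
# background with the columns of in-coalition groups overwritten by x.
# Evaluates all requested masks in one batched score_fn call.
coalition_values <- function(score_fn, x, background, groups, masks) {
  b <- nrow(background)
  d <- length(x)
  g <- length(groups)
  rows <- matrix(0, nrow = length(masks) * b, ncol = d)
  for (m_i in seq_along(masks)) {
    mask <- masks[m_i]
    block <- background
    for (j in seq_len(g)) {
      if (bitwAnd(mask, bitwShiftL(1L, j - 1L)) != 0L) {
        block[, groups[[j]]] <- matrix(x[groups[[j]]], b,
                                       length(groups[[j]]), byrow = TRUE)
      }
    }
    rows[((m_i - 1L) * b + 1L):(m_i * b), ] <- block
  }
  s <- score_fn(rows)
  stopifnot(length(s) == length(masks) * b)
  colMeans(matrix(s, nrow = b))
}

new_attribution <- function(terms, phi, se, base_value, score, method,
                            entity_id = NA_character_, detector = NA_character_) {
  structure(
    tibble(term = terms, phi = phi, se = se),
    base_value = base_value, score = score, method = method,
    entity_id = entity_id, detector = detector,
    class = c("claims_attribution", class(tibble())))
}

#' Exact Shapley attribution over feature groups
#'
#' Classic Shapley values by full coalition enumeration. Players are feature
#' *groups* (all expanded columns of one original feature toggled together);
#' with `group_map = NULL` every column is its own player. The value of a
#' coalition is the mean score over the background set with in-coalition
#' features set to the explained row. Satisfies efficiency exactly:
#' `sum(phi) + base_value = score(x)`.
#'
#' @param score_fn Function mapping a numeric matrix (rows = profiles in the
#'   expanded column layout) to a numeric score vector, e.g. a fitted
#'   detector's scorer (see [detector_score_fn()]).
#' @param x The profile row to explain (numeric vector).
#' @param background Matrix from [background_set()].
#' @param group_map Optional `FeatureGroupMap` tibble
#'   (`claims_profiles$group_map`).
#' @return A `claims_attribution` tibble: `term`, `phi`, `se` (0 for the
#'   exact estimator), with `base_value`, `score` attributes.
#' @export
exact_shapley <- function(score_fn, x, background, group_map = NULL) {
  groups <- attribution_groups(x, group_map)
  g <- length(groups)
  if (g > 12L) {
    abort(paste0("exact enumeration over ", g,
                 " groups is intractable; use monte_carlo_shapley()"))
  }
  masks <- 0:(2^g - 1L)
  v <- coalition_values(score_fn, x, background, groups, masks)
  fact <- factorial(0:g)
  w <- fact[1:g] * fact[g:1] / fact[g + 1L]   # w[s+1] = s!(g-1-s)!/g!
  popcount <- vapply(masks, function(m) sum(bitwAnd(m, bitwShiftL(1L, 0:(g - 1L))) != 0L),
                     numeric(1))
  phi <- numeric(g)
  for (j in seq_len(g)) {
    bit <- bitwShiftL(1L, j - 1L)
    without <- masks[bitwAnd(masks, bit) == 0L]
    s <- popcount[without + 1L]
    phi[j] <- sum(w[s + 1L] * (v[bitwOr(without, bit) + 1L] - v[without + 1L]))
  }
  new_attribution(names(groups), phi, se = rep(0, g),
                  base_value = v[1L], score = v[length(v)], method = "exact")
}

#' Monte-Carlo (permutation-sampling) Shapley attribution
#'
#' Unbiased permutation estimator for instances with too many feature groups
#' to enumerate: for each sampled ordering, every group's marginal
#' contribution when appended to its predecessors is recorded; the Shapley
#' value is the average, and a per-group standard error
#' (`sd / sqrt(n_permutations)`) is reported.
#'
#' @inheritParams exact_shapley
#' @param n_permutations Number of sampled orderings (default 200).
#' @param seed Integer seed.
#' @return A `claims_attribution` tibble (method `"monte_carlo"`).
#' @export
monte_carlo_shapley <- function(score_fn, x, background, group_map = NULL,
                                n_permutations = 200, seed = 1L) {
  stopifnot(n_permutations >= 1)
  groups <- attribution_groups(x, group_map)
  g <- length(groups)
  old <- .Random.seed_exists(); on.exit(restore_rng(old), add = TRUE)
  set.seed(mix_seed(seed, 70717L))

  b <- nrow(background)
  contrib <- matrix(0, n_permutations, g)
  base_value <- mean(score_fn(background))
  score_x <- as.numeric(score_fn(matrix(x, nrow = 1)))
  for (p_i in seq_len(n_permutations)) {
    ord <- sample.int(g)
    # nested coalitions along the ordering: overwrite groups progressively
    rows <- matrix(0, g * b, length(x))
    block <- background
    for (step in seq_len(g)) {
      cols <- groups[[ord[step]]]
      block[, cols] <- matrix(x[cols], b, length(cols), byrow = TRUE)
      rows[((step - 1L) * b + 1L):(step * b), ] <- block
    }
    v <- colMeans(matrix(score_fn(rows), nrow = b))
    v_prev <- c(base_value, v[-g])
    contrib[p_i, ord] <- v - v_prev
  }
  phi <- colMeans(contrib)
  se <- apply(contrib, 2, stats::sd) / sqrt(n_permutations)
  new_attribution(names(groups), phi, se, base_value = base_value,
                  score = score_x, method = "monte_carlo")
}

#' Scoring function of a fitted ensemble detector
#'
#' Extracts a vectorised `matrix -> scores` function for one detector from a
#' [run_ensemble()] result, for use as `score_fn` in the Shapley engines
#' (model-agnostic: any detector output can be explained).
#'
#' @param scores A `claims_scores` tibble (with fitted scorers attached).
#' @param name Detector name.
#' @return A function `(matrix) -> numeric`.
#' @export
detector_score_fn <- function(scores, name) {
  fits <- attr(scores, "fits")
  if (is.null(fits[[name]])) abort(paste0("no fitted detector named '", name, "'"))
  f <- fits[[name]]$score_new
  if (is.null(f)) abort(paste0("detector '", name, "' cannot score new rows"))
  f
}

#' Sum expanded-column attributions into original-feature importances
#'
#' The additivity of Shapley values means per-column attributions of an
#' expanded representation (six statistics, k embedding dimensions) can
#' simply be summed per original feature; the total importance is preserved
#' exactly.
#'
#' @param attribution A `claims_attribution` whose terms are expanded
#'   columns.
#' @param group_map `FeatureGroupMap` tibble covering exactly the
#'   attribution's terms.
#' @return A `claims_attribution` with one row per original feature.
#' @export
group_attributions <- function(attribution, group_map) {
  d <- max(group_map$last)
  if (nrow(attribution) != d) {
    abort("attribution length does not match the group map's expanded columns")
  }
  phi <- map_dbl(seq_len(nrow(group_map)), function(i) {
    sum(attribution$phi[group_map$first[i]:group_map$last[i]])
  })
  se <- map_dbl(seq_len(nrow(group_map)), function(i) {
    sqrt(sum(attribution$se[group_map$first[i]:group_map$last[i]]^2))
  })
  new_attribution(group_map$feature, phi, se,
                  base_value = attr(attribution, "base_value"),
                  score = attr(attribution, "score"),
                  method = attr(attribution, "method"),
                  entity_id = attr(attribution, "entity_id"),
                  detector = attr(attribution, "detector"))
}

#' Average rescaled attributions across detectors
#'
#' Different detectors score on incommensurable scales, so each model's
#' grouped importance vector is first rescaled to unit l1 norm (all-zero
#' vectors stay zero) and the consensus importance is the componentwise mean
#' across models. Sign is preserved.
#'
#' @param attributions List of grouped `claims_attribution`s for one entity,
#'   one per detector, over identical feature sets.
#' @return A `claims_attribution` with detector `"consensus"`.
#' @export
consensus_attribution <- function(attributions) {
  stopifnot(length(attributions) >= 1)
  terms <- attributions[[1]]$term
  for (a in attributions) {
    if (!identical(a$term, terms)) abort("attributions cover different feature sets")
  }
  rescaled <- vapply(attributions, function(a) {
    l1 <- sum(abs(a$phi))
    if (l1 > 0) a$phi / l1 else a$phi
  }, numeric(length(terms)))
  rescaled <- matrix(rescaled, nrow = length(terms))
  new_attribution(terms, rowMeans(rescaled), se = rep(NA_real_, length(terms)),
                  base_value = NA_real_, score = NA_real_,
                  method = "consensus",
                  entity_id = attr(attributions[[1]], "entity_id"),
                  detector = "consensus")
}

#' Explain one entity across a detector ensemble
#'
#' Computes grouped Shapley attributions of an entity's profile row for every
#' detector (exact enumeration when the schema has at most `exact_max_groups`
#' original features, permutation sampling otherwise) and their consensus.
#'
#' @param profiles Standardized `claims_profiles`.
#' @param scores A `claims_scores` from [run_ensemble()] on these profiles.
#' @param entity_id Entity to explain.
#' @param background Background matrix (default: [background_set()] of the
#'   profiles).
#' @param n_permutations Permutations for the Monte-Carlo path.
#' @param exact_max_groups Switch-over point between exact and Monte-Carlo
#'   estimation (default 12).
#' @param seed Integer seed.
#' @return List: `per_detector` (named list of grouped attributions) and
#'   `consensus` (their [consensus_attribution()]).
#' @export
explain_entity <- function(profiles, scores, entity_id,
                           background = NULL, n_permutations = 200,
                           exact_max_groups = 12, seed = 1L) {
  X <- profile_matrix(profiles)
  idx <- match(entity_id, profiles$entity_ids)
  if (is.na(idx)) abort(paste0("unknown entity: ", entity_id))
  x <- X[idx, ]
  if (is.null(background)) background <- background_set(profiles, seed = seed)
  gmap <- profiles$group_map
  det <- names(attr(scores, "fits"))
  per_detector <- setNames(vector("list", length(det)), det)
  for (d in det) {
    fn <- detector_score_fn(scores, d)
    attr_d <- if (nrow(gmap) <= exact_max_groups) {
      exact_shapley(fn, x, background, gmap)
    } else {
      monte_carlo_shapley(fn, x, background, gmap,
                          n_permutations = n_permutations,
                          seed = mix_seed(seed, match(d, det)))
    }
    attr(attr_d, "entity_id") <- entity_id
    attr(attr_d, "detector") <- d
    per_detector[[d]] <- attr_d
  }
  list(per_detector = per_detector,
       consensus = consensus_attribution(unname(per_detector)))
}

#' @describeIn exact_shapley Broom-style view of an attribution.
#' @param x A `claims_attribution`.
#' @param ... Unused.
#' @method tidy claims_attribution
#' @export
tidy.claims_attribution <- function(x, ...) {
  tibble(term = x$term, estimate = x$phi, std.error = x$se)
}

#' @describeIn exact_shapley One-row summary (efficiency check included).
#' @method glance claims_attribution
#' @export
glance.claims_attribution <- function(x, ...) {
  tibble(n_terms = nrow(x), method = attr(x, "method"),
         base_value = attr(x, "base_value"), score = attr(x, "score"),
         total_phi = sum(x$phi))
}

#' @describeIn exact_shapley Importance bar chart (signed attributions).
#' @param object A `claims_attribution`.
#' @method autoplot claims_attribution
#' @export
autoplot.claims_attribution <- function(object, ...) {
  d <- as_tibble(object)
  d$term <- factor(d$term, levels = d$term[order(abs(d$phi))])
  ggplot2::ggplot(d, ggplot2::aes(x = .data$phi, y = .data$term,
                                  fill = .data$phi > 0)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::labs(x = "attribution (score units)", y = NULL)
}
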