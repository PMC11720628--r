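#' Specify an anomaly detector for the ensemble
#'
#' Native kinds: `"knn"` (mean distance to the k nearest neighbours),
#' `"hist"` (histogram-based score: sum over dimensions of the negative log
#' bin density), `"ecdf_tail"` (parameter-free: sum over dimensions of the
#' negative log of the smaller empirical-CDF tail at the sample's value).
#' Kind `"adapter"` attaches any external implementation through a
#' fit-then-score contract: `fit(X, spec)` is called with the full profile
#' matrix and must return `list(scores = <one score per row, higher = more
#' anomalous>, score_new = <optional function(matrix) -> vector>)`.
#'
#' @param name Unique detector name within an ensemble.
#' @param kind `"knn"`, `"hist"`, `"ecdf_tail"` or `"adapter"`.
#' @param ... Hyperparameters: `n_neighbors` (default 20) for knn; `n_bins`
#'   (default 10) for hist; `fit` (the function above) for adapter. (Named
#'   `n_neighbors`, not `k`, so it cannot partially match the `kind`
#'   argument.)
#' @param seed Optional integer seed, set before fitting stochastic
#'   detectors.
#' @return A `detector_spec` object.
#' @export
detector <- function(name, kind = c("knn", "hist", "ecdf_tail", "adapter"),
                     ..., seed = NULL) {
  kind <- match.arg(kind)
  hyper <- list(...)
  if (kind == "adapter" && !is.function(hyper$fit)) {
    abort("adapter detectors need a `fit` function")
  }
  structure(list(name = name, kind = kind, hyper = hyper, seed = seed),
            class = "detector_spec")
}

#' Default detector battery
#' @param knn_k Neighbour count for the kNN scorer (default 20).
#' @param n_bins Bin count for the histogram scorer (default 10).
#' @return List of [detector()] specs: knn, hist, ecdf.
#' @export
default_detectors <- function(knn_k = 20, n_bins = 10) {
  list(detector("knn", "knn", n_neighbors = knn_k),
       detector("hist", "hist", n_bins = n_bins),
       detector("ecdf", "ecdf_tail"))
}

LOG_EPS <- 1e-12

as_matrix_input <- function(profiles) {
  if (inherits(profiles, "claims_profiles")) profile_matrix(profiles)
  else as.matrix(profiles)
}

#' kNN mean-distance outlier score
#'
#' Score of row i = mean Euclidean distance from row i to its `k` nearest
#' *other* rows. Distant, isolated profiles score high. Intended for
#' standardized profiles, where unweighted Euclidean distance is meaningful.
#'
#' @param profiles A `claims_profiles` or numeric matrix.
#' @param k Neighbour count; must be `< n` rows.
#' @return Numeric score vector (one per row; higher = more anomalous).
#' @export
knn_score <- function(profiles, k = 20) {
  X <- as_matrix_input(profiles)
  n <- nrow(X)
  if (k >= n) abort("k must be smaller than the number of entities")
  D <- as.matrix(stats::dist(X))
  diag(D) <- Inf
  unname(apply(D, 1, function(d) mean(sort(d, partial = k)[seq_len(k)])))
}

fit_knn <- function(X, k) {
  list(scores = knn_score(X, k),
       score_new = function(Z) {
         Z <- matrix(Z, ncol = ncol(X))
         # distances from new rows to the training rows
         cross <- sqrt(pmax(outer(rowSums(Z^2), rowSums(X^2), "+") -
                              2 * Z %*% t(X), 0))
         apply(cross, 1, function(d) mean(sort(d, partial = k)[seq_len(k)]))
       })
}

#' Histogram-based outlier score
#'
#' Per dimension, an equal-width histogram over the observed range; the
#' per-sample density is the occupied bin's count divided by n, and the
#' score sums `-log(density + eps)` over dimensions (independence across
#' dimensions assumed). Zero-range dimensions contribute 0 to every score;
#' out-of-range values (possible for new data) fall in an empty bin.
#'
#' @inheritParams knn_score
#' @param n_bins Number of bins (>= 2, default 10).
#' @return Numeric score vector.
#' @export
hist_score <- function(profiles, n_bins = 10) {
  X <- as_matrix_input(profiles)
  fit_hist(X, n_bins)$scores
}

fit_hist <- function(X, n_bins) {
  if (n_bins < 2) abort("n_bins must be >= 2")
  n <- nrow(X)
  dims <- lapply(seq_len(ncol(X)), function(j) {
    x <- X[, j]
    rng <- range(x)
    if (diff(rng) <= 0) return(NULL)  # degenerate dimension: contributes 0
    breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
    bin <- pmin(pmax(findInterval(x, breaks, rightmost.closed = TRUE), 1L), n_bins)
    counts <- tabulate(bin, nbins = n_bins)
    list(breaks = breaks, counts = counts)
  })
  score_of <- function(Z) {
    Z <- matrix(Z, ncol = ncol(X))
    s <- numeric(nrow(Z))
    for (j in seq_len(ncol(X))) {
      d <- dims[[j]]
      if (is.null(d)) next
      bin <- findInterval(Z[, j], d$breaks, rightmost.closed = TRUE)
      dens <- ifelse(bin >= 1 & bin <= n_bins, d$counts[pmax(bin, 1L)] / n, 0)
      s <- s - log(dens + LOG_EPS)
    }
    s
  }
  list(scores = score_of(X), score_new = score_of)
}

#' ECDF-tail outlier score
#'
#' Parameter-free distribution-tail scorer: per dimension, the left tail
#' `F_left(z) = #\{x <= z\}/n` and right tail `F_right(z) = #\{x >= z\}/n`
#' are evaluated at the sample's value, the smaller of the two is the tail
#' probability, and the score sums `-log(tail)` over dimensions. Values deep
#' in either tail of any dimension score high; a constant dimension has
#' tail 1 everywhere and contributes 0.
#'
#' @inheritParams knn_score
#' @return Numeric score vector.
#' @export
ecdf_tail_score <- function(profiles) {
  X <- as_matrix_input(profiles)
  if (nrow(X) < 2) abort("ECDF-tail score needs >= 2 entities")
  fit_ecdf_tail(X)$scores
}

fit_ecdf_tail <- function(X) {
  n <- nrow(X)
  sorted <- lapply(seq_len(ncol(X)), function(j) sort(X[, j]))
  score_of <- function(Z) {
    Z <- matrix(Z, ncol = ncol(X))
    s <- numeric(nrow(Z))
    for (j in seq_len(ncol(X))) {
      srt <- sorted[[j]]
      f_left <- findInterval(Z[, j], srt) / n                       # P(x <= z)
      f_right <- (n - findInterval(Z[, j], srt, left.open = TRUE)) / n  # P(x >= z)
      tail_p <- pmin(f_left, f_right)
      s <- s - log(pmax(tail_p, LOG_EPS))
    }
    s
  }
  list(scores = score_of(X), score_new = score_of)
}

fit_detector <- function(X, spec) {
  if (!is.null(spec$seed)) set.seed(spec$seed)
  switch(spec$kind,
    knn = fit_knn(X, spec$hyper[["n_neighbors"]] %||% spec$hyper[["k"]] %||% 20),
    hist = fit_hist(X, spec$hyper$n_bins %||% 10),
    ecdf_tail = fit_ecdf_tail(X),
    adapter = {
      res <- spec$hyper$fit(X, spec)
      if (!is.list(res) || is.null(res$scores)) {
        abort("adapter fit must return list(scores = ..., score_new = ...)")
      }
      res
    }
  )
}

#' Run a detector ensemble over a profile matrix
#'
#' Fits every detector on the full standardized profile matrix and collects
#' one score per entity and detector (higher = more anomalous). A failing
#' adapter is dropped with a warning and the run continues. Stochastic
#' detectors are seeded from their spec.
#'
#' @param profiles A `claims_profiles` (standardized) or numeric matrix.
#' @param detectors List of [detector()] specs (default [default_detectors()]).
#' @return A `claims_scores` tibble: `entity_id` plus one numeric column per
#'   detector, in spec order; fitted scorers for reuse on modified rows are
#'   attached as the `fits` attribute.
#' @export
run_ensemble <- function(profiles, detectors = default_detectors()) {
  if (inherits(detectors, "detector_spec")) detectors <- list(detectors)
  stopifnot(length(detectors) >= 1)
  X <- as_matrix_input(profiles)
  ids <- if (inherits(profiles, "claims_profiles")) profiles$entity_ids
         else rownames(X) %||% as.character(seq_len(nrow(X)))
  nm <- map_chr(detectors, "name")
  if (anyDuplicated(nm)) abort("detector names must be unique")

  out <- tibble(entity_id = ids)
  fits <- list()
  for (spec in detectors) {
    res <- tryCatch(fit_detector(X, spec), error = function(e) {
      warn(paste0("detector '", spec$name, "' failed and was dropped: ",
                  conditionMessage(e)))
      NULL
    })
    if (is.null(res)) next
    if (anyNA(res$scores) || length(res$scores) != nrow(X)) {
      warn(paste0("detector '", spec$name,
                  "' returned invalid scores and was dropped"))
      next
    }
    out[[spec$name]] <- as.numeric(res$scores)
    fits[[spec$name]] <- res
  }
  if (ncol(out) < 2L) abort("every detector failed")
  structure(out, fits = fits, class = c("claims_scores", class(out)))
}

#' Area under the ROC curve of a score vector
#'
#' Probability that a randomly chosen positive outranks a randomly chosen
#' negative, with ties counted half (the Mann-Whitney form). Exact and
#' deterministic; immune to class imbalance.
#'
#' @param scores Numeric anomaly scores (higher = more anomalous).
#' @param labels 0/1 vector; both classes must be present.
#' @return AUROC in `[0, 1]`.
#' @export
evaluate_auroc <- function(scores, labels) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% c(0L, 1L)))
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) abort("both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' @describeIn run_ensemble Tidy view: one row per (entity, detector).
#' @param x A `claims_scores` tibble.
#' @param ... Unused.
#' @method tidy claims_scores
#' @export
tidy.claims_scores <- function(x, ...) {
  as_tibble(x) |>
    tidyr::pivot_longer(-"entity_id", names_to = "detector", values_to = "score")
}

#' @describeIn run_ensemble One-row summary.
#' @method glance claims_scores
#' @export
glance.claims_scores <- function(x, ...) {
  tibble(n_entities = nrow(x), n_detectors = ncol(x) - 1L,
         detectors = paste(setdiff(names(x), "entity_id"), collapse = ","))
}

#' @describeIn run_ensemble Score distributions per detector.
#' @param object A `claims_scores` tibble.
#' @method autoplot claims_scores
#' @export
autoplot.claims_scores <- function(object, ...) {
  tidy(object) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$score)) +
    ggplot2::geom_histogram(bins = 40) +
    ggplot2::facet_wrap(~detector, scales = "free") +
    ggplot2::labs(x = "anomaly score", y = "entities")
}
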