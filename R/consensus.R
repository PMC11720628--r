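#' Per-detector top-k anomaly sets
#'
#' For each detector, the `k` entities with the highest scores. Score ties at
#' the boundary are broken by lexicographic entity ID, so the sets are
#' deterministic.
#'
#' @param scores A `claims_scores` tibble from [run_ensemble()].
#' @param k Set size (`0` gives empty sets; must be `<=` number of entities).
#' @return Named list of character vectors (entity IDs), one per detector.
#' @export
top_k_sets <- function(scores, k) {
  det <- setdiff(names(scores), "entity_id")
  stopifnot(k >= 0, k <= nrow(scores))
  setNames(map(det, function(d) {
    ord <- order(-scores[[d]], scores$entity_id)
    scores$entity_id[ord][seq_len(k)]
  }), det)
}

dense_rank_desc <- function(x) match(-x, sort(unique(-x)))

#' Consensus ranking across detectors
#'
#' Counts, for every entity, how many detectors place it in their top-k
#' anomaly list and ranks entities by that count (descending). Only entities
#' appearing in at least one top-k set are listed. Count ties are resolved by
#' mean per-detector dense rank (ascending), then lexicographic entity ID.
#'
#' @param scores A `claims_scores` tibble.
#' @param k Top-list size per detector (default 50, a plausible expert-review
#'   workload).
#' @return A `claims_consensus` tibble: `entity_id`, `consensus_count`,
#'   `mean_rank`, and one `rank_<detector>` column per detector.
#' @export
build_consensus <- function(scores, k = 50) {
  det <- setdiff(names(scores), "entity_id")
  sets <- top_k_sets(scores, k)
  counts <- rowSums(vapply(det, function(d) scores$entity_id %in% sets[[d]],
                           logical(nrow(scores))))
  ranks <- vapply(det, function(d) dense_rank_desc(scores[[d]]),
                  numeric(nrow(scores)))
  ranks <- matrix(ranks, nrow = nrow(scores),
                  dimnames = list(NULL, paste0("rank_", det)))
  out <- tibble(entity_id = scores$entity_id,
                consensus_count = as.integer(counts),
                mean_rank = rowMeans(ranks))
  out <- bind_cols(out, as_tibble(ranks))
  out <- out[out$consensus_count >= 1L, , drop = FALSE]
  out <- out[order(-out$consensus_count, out$mean_rank, out$entity_id), ]
  structure(out, top_k = k, class = c("claims_consensus", class(out)))
}

#' @describeIn build_consensus One-row summary.
#' @param x A `claims_consensus` tibble.
#' @param ... Unused.
#' @method glance claims_consensus
#' @export
glance.claims_consensus <- function(x, ...) {
  tibble(n_flagged = nrow(x), top_k = attr(x, "top_k"),
         max_count = if (nrow(x)) max(x$consensus_count) else 0L)
}

#' @describeIn build_consensus Consensus counts for the leading entities.
#' @param object A `claims_consensus` tibble.
#' @param n_show Number of entities to display (default 20).
#' @method autoplot claims_consensus
#' @export
autoplot.claims_consensus <- function(object, n_show = 20, ...) {
  d <- utils::head(as_tibble(object), n_show)
  d$entity_id <- factor(d$entity_id, levels = rev(d$entity_id))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$consensus_count, y = .data$entity_id)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "detectors flagging entity (top-k membership count)",
                  y = NULL)
}
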