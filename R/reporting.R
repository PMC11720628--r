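#' Compare an entity's categorical distribution with the population
#'
#' Relative token frequencies over the entity's actions versus over *all*
#' actions (the population is action-weighted; busy providers weigh more, as
#' the raw claims stream does). Tokens the entity never uses are reported
#' with frequency 0.
#'
#' @param claims A `claims_tbl`.
#' @param entity_id Entity to report.
#' @param feature Categorical schema column.
#' @param top_n Tokens listed in `top_tokens` (by entity frequency).
#' @return A `categorical_comparison`: tibble (token, entity_freq,
#'   population_freq) sorted by entity frequency, with attributes `feature`,
#'   `entity_id`, `top_tokens`.
#' @export
compare_categorical <- function(claims, entity_id, feature, top_n = 10) {
  schema <- claims_schema_of(claims)
  if (!feature %in% schema$categorical) {
    abort(paste0("'", feature, "' is not a categorical schema column"))
  }
  ids <- claims[[schema$entity_id]]
  if (!entity_id %in% ids) abort(paste0("unknown entity: ", entity_id))
  pop <- table(claims[[feature]])
  ent <- table(claims[[feature]][ids == entity_id])
  tokens <- names(pop)
  out <- tibble(
    token = tokens,
    entity_freq = as.numeric(ent[tokens]) / sum(ent),
    population_freq = as.numeric(pop[tokens]) / sum(pop)
  )
  out$entity_freq[is.na(out$entity_freq)] <- 0
  out <- out[order(-out$entity_freq, out$token), ]
  structure(out, feature = feature, entity_id = entity_id,
            top_tokens = utils::head(out$token, top_n),
            class = c("categorical_comparison", class(out)))
}

#' Compare an entity's numerical aggregates with the population
#'
#' The entity's six aggregate statistics (sum, mean, median, std, min, max)
#' of a numerical feature, against the mean and (population) standard
#' deviation of each statistic across all entities, with z-scores. A
#' statistic that is constant across the population gets z = 0 and is
#' flagged.
#'
#' @param profiles An *unstandardized* `claims_profiles`.
#' @param entity_id Entity to report.
#' @param feature Numerical schema column.
#' @return A `numerical_comparison` tibble: statistic, entity_value,
#'   population_mean, population_std, z_score, degenerate.
#' @export
compare_numerical <- function(profiles, entity_id, feature) {
  stopifnot(inherits(profiles, "claims_profiles"))
  if (!is.null(profiles$standardization)) {
    abort("compare_numerical expects unstandardized profiles")
  }
  gm <- profiles$group_map
  row <- which(gm$feature == feature & gm$type == "numerical")
  if (length(row) != 1L) {
    abort(paste0("'", feature, "' is not a numerical profile feature"))
  }
  idx <- match(entity_id, profiles$entity_ids)
  if (is.na(idx)) abort(paste0("unknown entity: ", entity_id))
  cols <- gm$first[row]:gm$last[row]
  block <- profiles$values[, cols, drop = FALSE]
  mu <- colMeans(block)
  sdv <- apply(block, 2, pop_sd)
  degenerate <- sdv <= 0
  z <- ifelse(degenerate, 0, (block[idx, ] - mu) / ifelse(degenerate, 1, sdv))
  out <- tibble(
    statistic = c("sum", "mean", "median", "std", "min", "max"),
    entity_value = unname(block[idx, ]),
    population_mean = unname(mu),
    population_std = unname(sdv),
    z_score = unname(z),
    degenerate = unname(degenerate)
  )
  structure(out, feature = feature, entity_id = entity_id,
            class = c("numerical_comparison", class(out)))
}

#' Assemble the expert-facing report for one flagged entity
#'
#' Combines the consensus importance ranking with univariate population
#' comparisons for the top-m features (categorical or numerical as
#' appropriate). The billing-code feature, when named, is always included
#' regardless of its importance rank — investigators always see the
#' nomenclature distribution.
#'
#' @param claims The (filtered) `claims_tbl`.
#' @param profiles_raw The *unstandardized* `claims_profiles`.
#' @param consensus A `claims_consensus` ranking.
#' @param explanation Result of [explain_entity()] for this entity.
#' @param entity_id Entity to report.
#' @param m Number of top features to detail (default 5).
#' @param code_feature Name of the billing-code column to always include
#'   (default `NULL`: no forced feature).
#' @return An `entity_report` list.
#' @export
entity_report <- function(claims, profiles_raw, consensus, explanation,
                          entity_id, m = 5, code_feature = NULL) {
  schema <- claims_schema_of(claims)
  cons_attr <- explanation$consensus
  ord <- order(-abs(cons_attr$phi))
  ranked <- cons_attr$term[ord]
  chosen <- utils::head(ranked, m)
  if (!is.null(code_feature) && !code_feature %in% chosen) {
    chosen <- c(chosen, code_feature)
  }
  comparisons <- map(chosen, function(f) {
    if (f %in% schema$categorical) {
      compare_categorical(claims, entity_id, f)
    } else {
      compare_numerical(profiles_raw, entity_id, f)
    }
  })
  names(comparisons) <- chosen
  cc <- consensus$consensus_count[match(entity_id, consensus$entity_id)]
  structure(
    list(entity_id = entity_id,
         consensus_count = if (is.na(cc)) 0L else as.integer(cc),
         importance = tibble(feature = cons_attr$term[ord],
                             importance = cons_attr$phi[ord]),
         comparisons = comparisons,
         code_feature = code_feature),
    class = "entity_report"
  )
}

#' @export
print.entity_report <- function(x, ...) {
  cat("<entity_report>", x$entity_id,
      "| flagged by", x$consensus_count, "detector(s)\n")
  print(utils::head(x$importance, 5))
  invisible(x)
}

report_to_list <- function(report) {
  list(
    format = "claimscope-report/1",
    entity_id = report$entity_id,
    consensus_count = report$consensus_count,
    code_feature = report$code_feature,
    importance = report$importance,
    comparisons = imap(report$comparisons, function(cmp, f) {
      if (inherits(cmp, "categorical_comparison")) {
        list(feature = f, type = "categorical",
             entity_id = attr(cmp, "entity_id"),
             top_tokens = as.character(attr(cmp, "top_tokens")),
             table = as_tibble(cmp))
      } else {
        list(feature = f, type = "numerical",
             entity_id = attr(cmp, "entity_id"), table = as_tibble(cmp))
      }
    })
  )
}

#' Render an entity report
#'
#' Deterministic document rendering. `"json"` is machine-round-trippable via
#' [parse_report()]; `"markdown"` is a plain-text summary; `"html"` embeds a
#' consensus-importance bar chart as inline SVG plus the comparison tables.
#'
#' @param report An [entity_report()].
#' @param format `"json"`, `"markdown"` or `"html"`.
#' @return A single string (the document).
#' @export
render_report <- function(report, format = c("json", "markdown", "html")) {
  format <- match.arg(format)
  switch(format,
         json = render_report_json(report),
         markdown = render_report_markdown(report),
         html = render_report_html(report))
}

render_report_json <- function(report) {
  jsonlite::toJSON(report_to_list(report), digits = NA, auto_unbox = TRUE,
                   null = "null", pretty = TRUE)
}

#' @rdname render_report
#' @param json A JSON string or file path produced by the `"json"` format.
#' @return `parse_report()` returns the reconstructed `entity_report`.
#' @export
parse_report <- function(json) {
  p <- jsonlite::fromJSON(json, simplifyVector = TRUE)
  comparisons <- map(p$comparisons, function(cmp) {
    tbl <- as_tibble(cmp$table)
    if (identical(cmp$type, "categorical")) {
      structure(tbl, feature = cmp$feature, entity_id = cmp$entity_id,
                top_tokens = cmp$top_tokens,
                class = c("categorical_comparison", class(tbl)))
    } else {
      structure(tbl, feature = cmp$feature, entity_id = cmp$entity_id,
                class = c("numerical_comparison", class(tbl)))
    }
  })
  names(comparisons) <- map_chr(p$comparisons, "feature")
  structure(
    list(entity_id = p$entity_id,
         consensus_count = as.integer(p$consensus_count),
         importance = as_tibble(p$importance),
         comparisons = comparisons,
         code_feature = p$code_feature),
    class = "entity_report"
  )
}

fmt_num <- function(x) formatC(x, digits = 5, format = "g")

render_report_markdown <- function(report) {
  lines <- c(
    paste0("# Entity report: ", report$entity_id),
    "",
    paste0("Flagged by **", report$consensus_count, "** detector(s)."),
    "",
    "## Consensus feature importance",
    "",
    "| feature | importance |",
    "|---|---|",
    paste0("| ", report$importance$feature, " | ",
           fmt_num(report$importance$importance), " |"),
    ""
  )
  for (f in names(report$comparisons)) {
    cmp <- report$comparisons[[f]]
    lines <- c(lines, paste0("## ", f), "")
    if (inherits(cmp, "categorical_comparison")) {
      top <- utils::head(as_tibble(cmp), 10)
      lines <- c(lines,
                 "| token | entity freq | population freq |",
                 "|---|---|---|",
                 paste0("| ", top$token, " | ", fmt_num(top$entity_freq),
                        " | ", fmt_num(top$population_freq), " |"),
                 "")
    } else {
      tbl <- as_tibble(cmp)
      lines <- c(lines,
                 "| statistic | entity | population mean | z |",
                 "|---|---|---|---|",
                 paste0("| ", tbl$statistic, " | ", fmt_num(tbl$entity_value),
                        " | ", fmt_num(tbl$population_mean), " | ",
                        fmt_num(tbl$z_score), " |"),
                 "")
    }
  }
  paste(lines, collapse = "\n")
}

# Hand-built horizontal bar chart as deterministic inline SVG (no graphics
# device involved, so renders are byte-stable).
svg_importance_bars <- function(importance, width = 560, bar_h = 18, gap = 6) {
  n <- nrow(importance)
  maxabs <- max(abs(importance$importance), 1e-12)
  mid <- width / 2
  rows <- map_chr(seq_len(n), function(i) {
    v <- importance$importance[i]
    w <- abs(v) / maxabs * (width / 2 - 120)
    x <- if (v >= 0) mid else mid - w
    y <- (i - 1) * (bar_h + gap) + 4
    paste0(
      "<rect x='", fmt_num(x), "' y='", y, "' width='", fmt_num(w),
      "' height='", bar_h, "' fill='", if (v >= 0) "#b2182b" else "#2166ac", "'/>",
      "<text x='4' y='", y + bar_h - 4, "' font-size='12'>",
      importance$feature[i], "</text>"
    )
  })
  h <- n * (bar_h + gap) + 8
  paste0("<svg xmlns='http://www.w3.org/2000/svg' width='", width,
         "' height='", h, "'>",
         "<line x1='", mid, "' y1='0' x2='", mid, "' y2='", h,
         "' stroke='#888'/>", paste(rows, collapse = ""), "</svg>")
}

render_report_html <- function(report) {
  body <- gsub("\n", "<br/>\n",
               gsub("&", "&amp;", render_report_markdown(report), fixed = TRUE))
  paste0(
    "<!DOCTYPE html>\n<html><head><meta charset='utf-8'/><title>",
    report$entity_id, "</title></head><body>\n",
    "<h1>Entity report: ", report$entity_id, "</h1>\n",
    svg_importance_bars(utils::head(report$importance, 15)), "\n<pre>\n",
    body, "\n</pre>\n</body></html>\n"
  )
}

#' @describeIn compare_categorical Side-by-side frequency bars.
#' @param object A `categorical_comparison`.
#' @param top_n Tokens shown.
#' @param ... Unused.
#' @method autoplot categorical_comparison
#' @export
autoplot.categorical_comparison <- function(object, top_n = 10, ...) {
  d <- utils::head(as_tibble(object), top_n) |>
    tidyr::pivot_longer(c("entity_freq", "population_freq"),
                        names_to = "who", values_to = "freq")
  d$token <- factor(d$token, levels = rev(unique(d$token)))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$freq, y = .data$token,
                                  fill = .data$who)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "relative frequency", y = NULL, fill = NULL,
                  title = attr(object, "feature"))
}

#' @describeIn compare_numerical z-scores of the entity's aggregates.
#' @param object A `numerical_comparison`.
#' @param ... Unused.
#' @method autoplot numerical_comparison
#' @export
autoplot.numerical_comparison <- function(object, ...) {
  d <- as_tibble(object)
  d$statistic <- factor(d$statistic, levels = d$statistic)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$statistic, y = .data$z_score)) +
    ggplot2::geom_col() +
    ggplot2::labs(y = "z-score vs population", x = NULL,
                  title = attr(object, "feature"))
}
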