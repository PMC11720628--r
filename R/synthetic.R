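#' Specify a synthetic claims population
#'
#' Describes a population of care providers whose per-action records are drawn
#' from specialty-specific distributions. Each entity is assigned a specialty;
#' its number of actions is negative-binomial; each action draws every
#' categorical column from the specialty's token distribution and every
#' numerical column from the specialty's log-normal amount distribution
#' (positive, right-skewed, as billing amounts are).
#'
#' @param n_entities Number of entities (>= 2).
#' @param actions Mean and dispersion of the negative-binomial actions-per-
#'   entity count, as `list(mean =, dispersion =)`; every entity gets at
#'   least one action.
#' @param specialties Named list. Each element describes one specialty:
#'   `list(categorical = list(col = named probability vector, ...),
#'   numerical = list(col = c(meanlog =, sdlog =), ...))`. Probability vectors
#'   are normalised; all specialties must cover the same columns.
#' @param weights Optional specialty assignment probabilities (named, or in
#'   `specialties` order). Default uniform.
#' @param schema Optional [claims_schema()]; derived from the specialty column
#'   sets when omitted (entity column `entity_id`).
#' @return A `population_spec` object.
#' @seealso [generate_population()], [benchmark_spec()]
#' @export
population_spec <- function(n_entities, actions = list(mean = 100, dispersion = 5),
                            specialties, weights = NULL, schema = NULL) {
  stopifnot(n_entities >= 2, length(specialties) >= 1, !is.null(names(specialties)))
  cat_cols <- names(specialties[[1]]$categorical %||% list())
  num_cols <- names(specialties[[1]]$numerical %||% list())
  for (sp in names(specialties)) {
    s <- specialties[[sp]]
    if (!identical(names(s$categorical %||% list()), cat_cols) ||
        !identical(names(s$numerical %||% list()), num_cols)) {
      abort("all specialties must define the same categorical/numerical columns",
            class = "claimscope_spec_error")
    }
    for (col in cat_cols) {
      p <- s$categorical[[col]]
      if (any(p < 0) || sum(p) <= 0 || is.null(names(p))) {
        abort(paste0("invalid distribution for '", col, "' in specialty '", sp,
                     "': need named non-negative weights with positive mass"),
              class = "claimscope_spec_error")
      }
      specialties[[sp]]$categorical[[col]] <- p / sum(p)
    }
  }
  if (is.null(weights)) weights <- rep(1 / length(specialties), length(specialties))
  weights <- weights / sum(weights)
  if (is.null(schema)) {
    schema <- claims_schema("entity_id", categorical = cat_cols, numerical = num_cols)
  }
  structure(
    list(n_entities = as.integer(n_entities), actions = actions,
         specialties = specialties, weights = weights, schema = schema),
    class = "population_spec"
  )
}

#' Describe a planted anomaly archetype
#'
#' Archetypes perturb *action-level sampling* for a small fraction of
#' entities, so a planted anomaly must survive the whole embed-aggregate-
#' detect pipeline to be found — they are not profile-level shortcuts.
#'
#' * `excessive_code`: multiplies the sampling odds of designated tokens of a
#'   categorical column by `strength` (over-use of particular billing codes).
#' * `off_specialty`: resamples a fraction of an entity's actions from a
#'   different specialty's profile (e.g. a GP mostly assisting orthopedic
#'   surgery).
#' * `inflated_amount`: multiplies a numerical column by `strength`.
#'
#' @param kind One of `"excessive_code"`, `"off_specialty"`,
#'   `"inflated_amount"`.
#' @param strength Positive multiplier (odds multiplier for `excessive_code`,
#'   scale factor for `inflated_amount`; unused by `off_specialty`).
#' @param affected_fraction Fraction of entities affected (default 0.003,
#'   matching heavy real-world imbalance).
#' @param parameters Archetype-specific settings: `column`, `tokens`
#'   (excessive_code), `fraction` and `target_specialty` (off_specialty).
#' @return An `anomaly_archetype` object.
#' @export
anomaly_archetype <- function(kind = c("excessive_code", "off_specialty", "inflated_amount"),
                              strength = 1, affected_fraction = 0.003,
                              parameters = list()) {
  kind <- match.arg(kind)
  stopifnot(strength > 0, affected_fraction > 0, affected_fraction < 1)
  structure(list(kind = kind, strength = strength,
                 affected_fraction = affected_fraction, parameters = parameters),
            class = "anomaly_archetype")
}

# Draw n action rows from one specialty's distributions (categorical token
# draws + lognormal numerical draws); RNG state of the caller is used.
draw_actions <- function(spec, specialty, n) {
  s <- spec$specialties[[specialty]]
  out <- vector("list", length(s$categorical) + length(s$numerical))
  names(out) <- c(names(s$categorical), names(s$numerical))
  for (col in names(s$categorical)) {
    p <- s$categorical[[col]]
    out[[col]] <- sample(names(p), n, replace = TRUE, prob = p)
  }
  for (col in names(s$numerical)) {
    par <- s$numerical[[col]]
    out[[col]] <- rlnorm(n, meanlog = par[["meanlog"]], sdlog = par[["sdlog"]])
  }
  as_tibble(out)
}

#' Generate a synthetic claims population
#'
#' Fully deterministic given `spec` and its seed: each entity draws from its
#' own RNG substream (derived by integer-mixing the seed with the entity
#' index), so enlarging the population does not perturb existing entities.
#'
#' @param spec A [population_spec()].
#' @param seed Integer seed for the whole population.
#' @return A `claims_tbl` with one row per action, carrying an
#'   `entity_info` attribute (tibble: entity_id, specialty, n_actions).
#' @export
generate_population <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "population_spec"))
  n <- spec$n_entities
  width <- max(4L, nchar(as.character(n)))
  ids <- sprintf(paste0("E%0", width, "d"), seq_len(n))
  sp_names <- names(spec$specialties)

  old <- .Random.seed_exists()
  on.exit(restore_rng(old), add = TRUE)

  specialty <- character(n)
  n_actions <- integer(n)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    # everything about entity i lives in its own substream, so growing the
    # population leaves existing entities bit-identical
    set.seed(mix_seed(seed, i))
    specialty[i] <- sample(sp_names, 1L, prob = spec$weights)
    n_actions[i] <- max(1L, rnbinom(1L, mu = spec$actions$mean,
                                    size = spec$actions$dispersion))
    acts <- draw_actions(spec, specialty[i], n_actions[i])
    acts[[spec$schema$entity_id]] <- ids[i]
    rows[[i]] <- acts
  }
  tbl <- bind_rows(rows)
  claims <- as_claims(tbl, spec$schema)
  attr(claims, "entity_info") <- tibble(
    entity_id = ids, specialty = specialty, n_actions = as.integer(n_actions)
  )
  attr(claims, "population_spec") <- spec
  claims
}

.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Plant labeled anomalies in a synthetic claims table
#'
#' Applies one or more [anomaly_archetype()]s to disjoint, seeded subsets of
#' entities and returns the perturbed table together with ground-truth labels.
#' Each archetype affects `ceiling(affected_fraction * n_entities)` entities
#' (a warning is raised when the fraction alone would affect none).
#'
#' @param claims A `claims_tbl` produced by [generate_population()] (the
#'   attached population spec is needed to resample actions).
#' @param archetypes A single [anomaly_archetype()] or a list of them.
#' @param seed Integer seed for entity selection and resampling.
#' @return A `labeled_claims` list: `table` (the perturbed `claims_tbl`),
#'   `labels` (tibble: entity_id, label in 0/1), `ground_truth` (tibble:
#'   entity_id, kind).
#' @export
inject_anomalies <- function(claims, archetypes, seed = 1L) {
  if (inherits(archetypes, "anomaly_archetype")) archetypes <- list(archetypes)
  stopifnot(nrow(claims) > 0, length(archetypes) >= 1)
  spec <- attr(claims, "population_spec")
  if (is.null(spec)) {
    abort("inject_anomalies needs a table from generate_population (population spec attached)")
  }
  schema <- claims_schema_of(claims)
  info <- attr(claims, "entity_info")
  ids <- info$entity_id

  old <- .Random.seed_exists()
  on.exit(restore_rng(old), add = TRUE)

  set.seed(mix_seed(seed, 999883L))
  available <- ids
  assignment <- list()
  for (a_idx in seq_along(archetypes)) {
    arch <- archetypes[[a_idx]]
    n_aff <- arch$affected_fraction * length(ids)
    if (n_aff < 1) {
      warn(paste0("affected_fraction ", arch$affected_fraction,
                  " covers < 1 entity; affecting one anyway"))
    }
    n_aff <- max(1L, ceiling(n_aff))
    chosen <- sample(available, min(n_aff, length(available)))
    available <- setdiff(available, chosen)
    assignment[[a_idx]] <- chosen
  }

  tbl <- as_tibble(claims)
  for (a_idx in seq_along(archetypes)) {
    arch <- archetypes[[a_idx]]
    for (eid in assignment[[a_idx]]) {
      set.seed(mix_seed(seed, match(eid, ids) + 104729L * a_idx))
      rows <- which(tbl[[schema$entity_id]] == eid)
      specialty <- info$specialty[match(eid, ids)]
      tbl[rows, ] <- apply_archetype(tbl[rows, , drop = FALSE], arch, spec,
                                     specialty, schema)
    }
  }

  labels <- tibble(entity_id = ids,
                   label = as.integer(ids %in% unlist(assignment)))
  ground_truth <- bind_rows(imap(assignment, function(ent, i) {
    tibble(entity_id = ent, kind = archetypes[[as.integer(i)]]$kind)
  }))
  out_claims <- as_claims(tbl, schema)
  attr(out_claims, "entity_info") <- info
  attr(out_claims, "population_spec") <- spec
  structure(list(table = out_claims, labels = labels, ground_truth = ground_truth),
            class = "labeled_claims")
}

apply_archetype <- function(rows, arch, spec, specialty, schema) {
  n <- nrow(rows)
  par <- arch$parameters
  if (arch$kind == "excessive_code") {
    col <- par$column %||% schema$categorical[[length(schema$categorical)]]
    p <- spec$specialties[[specialty]]$categorical[[col]]
    tokens <- par$tokens %||% utils::head(names(sort(p, decreasing = TRUE)), 2L)
    boost <- p
    boost[names(boost) %in% tokens] <- boost[names(boost) %in% tokens] * arch$strength
    boost <- boost / sum(boost)
    rows[[col]] <- sample(names(boost), n, replace = TRUE, prob = boost)
  } else if (arch$kind == "off_specialty") {
    frac <- par$fraction %||% 0.5
    others <- setdiff(names(spec$specialties), specialty)
    target <- par$target_specialty %||% sample(others, 1L)
    n_swap <- max(1L, round(frac * n))
    swap <- sample.int(n, n_swap)
    repl <- draw_actions(spec, target, n_swap)
    for (col in c(schema$categorical, schema$numerical)) {
      rows[[col]][swap] <- repl[[col]]
    }
  } else if (arch$kind == "inflated_amount") {
    col <- par$column %||% schema$numerical[[1L]]
    rows[[col]] <- rows[[col]] * arch$strength
  }
  rows
}

#' Default desk-scale benchmark population
#'
#' Mirrors the scale *ratios* of a national GP claims database at a size that
#' runs in seconds: 2000 providers, ~100 actions each (negative binomial,
#' dispersion 5), three specialties, a billing-code column of cardinality 600
#' with Zipf-weighted specialty-specific vocabularies, a discipline column
#' tied to the specialty, a location column of cardinality 8, and a
#' log-normal billed amount whose scale differs by specialty.
#'
#' @param n_entities Number of providers (default 2000).
#' @param code_cardinality Size of the billing-code vocabulary (default 600).
#' @return A [population_spec()].
#' @export
benchmark_spec <- function(n_entities = 2000, code_cardinality = 600) {
  stopifnot(code_cardinality >= 6)
  codes <- sprintf("N%06d", seq_len(code_cardinality))
  third <- floor(code_cardinality / 3)
  zipf <- function(m) { w <- 1 / seq_len(m); w / sum(w) }
  # each specialty concentrates on its own third of the code vocabulary, with
  # a thin uniform tail over the rest (shared codes exist in practice)
  code_dist <- function(block) {
    w <- rep(0.02 / code_cardinality, code_cardinality)
    idx <- ((block - 1) * third + 1):(block * third)
    w[idx] <- w[idx] + 0.98 * zipf(length(idx))
    setNames(w, codes)
  }
  locations <- sprintf("L%02d", 1:8)
  loc_dist <- function(shift) {
    w <- zipf(8)[((seq_len(8) + shift - 1) %% 8) + 1]
    setNames(w, locations)
  }
  mk <- function(block, disc, shift, meanlog) {
    list(
      categorical = list(
        discipline = setNames(c(0.9, 0.05, 0.05),
                              c(disc, setdiff(c("gp", "ortho", "derm"), disc))),
        location = loc_dist(shift),
        code = code_dist(block)
      ),
      numerical = list(amount = c(meanlog = meanlog, sdlog = 0.6))
    )
  }
  population_spec(
    n_entities = n_entities,
    actions = list(mean = 100, dispersion = 5),
    specialties = list(
      gp = mk(1, "gp", 0, log(30)),
      ortho = mk(2, "ortho", 3, log(150)),
      derm = mk(3, "derm", 6, log(60))
    ),
    weights = c(gp = 0.7, ortho = 0.15, derm = 0.15)
  )
}

#' Default planted-anomaly archetypes for the benchmark
#'
#' Three archetypes, each affecting 0.1% of entities (0.3% anomalous in
#' total): billing-code over-use (odds multiplied by 20), off-specialty
#' activity (half of the actions resampled from the orthopedics profile), and
#' amount inflation (x5).
#'
#' @return A list of [anomaly_archetype()] objects.
#' @export
benchmark_archetypes <- function() {
  list(
    anomaly_archetype("excessive_code", strength = 20, affected_fraction = 0.001,
                      parameters = list(column = "code")),
    anomaly_archetype("off_specialty", strength = 1, affected_fraction = 0.001,
                      parameters = list(fraction = 0.5, target_specialty = "ortho")),
    anomaly_archetype("inflated_amount", strength = 5, affected_fraction = 0.001,
                      parameters = list(column = "amount"))
  )
}

#' Generate the default labeled benchmark
#'
#' Convenience wrapper: [generate_population()] on [benchmark_spec()] followed
#' by [inject_anomalies()] with [benchmark_archetypes()].
#'
#' @param seed Integer seed.
#' @param n_entities Population size (default 2000).
#' @return A `labeled_claims` list (see [inject_anomalies()]).
#' @export
benchmark_claims <- function(seed = 1L, n_entities = 2000) {
  pop <- generate_population(benchmark_spec(n_entities = n_entities), seed = seed)
  inject_anomalies(pop, benchmark_archetypes(), seed = mix_seed(seed, 7L))
}

#' Write labels as a two-column delimited file
#' @param labels Tibble with `entity_id` and `label` columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_labels <- function(labels, path) {
  readr::write_csv(labels[c("entity_id", "label")], path)
  invisible(path)
}
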