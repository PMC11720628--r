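test_that("categorical comparison counts entity vs population frequencies", {
  tbl <- toy_claims()
  cmp <- compare_categorical(tbl, "a", "code")
  expect_equal(cmp$entity_freq[cmp$token == "X"], 2 / 3)
  expect_equal(cmp$entity_freq[cmp$token == "Y"], 1 / 3)
  expect_equal(cmp$entity_freq[cmp$token == "Z"], 0)   # never used by 'a'
  expect_equal(sum(cmp$entity_freq), 1, tolerance = 1e-9)
  expect_equal(sum(cmp$population_freq), 1, tolerance = 1e-9)
  # single-action entity is a point mass
  pm <- compare_categorical(tbl, "c", "code")
  expect_equal(pm$entity_freq[pm$token == "Z"], 1)
  expect_error(compare_categorical(tbl, "nobody", "code"), "unknown")
  expect_error(compare_categorical(tbl, "a", "amount"), "categorical")
})

test_that("an entity matching the population mixture shows matching distributions", {
  set.seed(300)
  n <- 2000
  tbl <- as_claims(tibble::tibble(
    gp_id = rep(c("big", "rest"), each = n),
    code = sample(c("X", "Y"), 2 * n, replace = TRUE, prob = c(0.6, 0.4)),
    amount = 1
  ), claims_schema("gp_id", categorical = "code", numerical = "amount"))
  cmp <- compare_categorical(tbl, "big", "code")
  expect_equal(cmp$entity_freq, cmp$population_freq, tolerance = 0.05)
})

test_that("numerical comparison z-scores use the population std of each statistic", {
  tbl <- as_claims(tibble::tibble(
    gp_id = rep(c("a", "b", "c"), each = 1),
    code = "X",
    amount = c(1, 2, 3)
  ), claims_schema("gp_id", categorical = "code", numerical = "amount"))
  pr <- build_profiles(tbl, fit_embeddings(tbl, k = 1))
  cmp <- compare_numerical(pr, "c", "amount")
  # population of entity means is (1,2,3); entity c's mean is 3
  z_mean <- cmp$z_score[cmp$statistic == "mean"]
  expect_equal(z_mean, 1.22474487, tolerance = 1e-7)
  # std is 0 for every singleton entity: degenerate, z = 0
  expect_true(cmp$degenerate[cmp$statistic == "std"])
  expect_equal(cmp$z_score[cmp$statistic == "std"], 0)
})

test_that("entity z is 0 when the entity sits at the population mean", {
  tbl <- sized_claims(c(a = 1, b = 1, c = 1))  # amounts 1, 2, 3
  pr <- build_profiles(tbl)
  cmp <- compare_numerical(pr, "b", "amount")
  expect_equal(cmp$z_score[cmp$statistic == "mean"], 0, tolerance = 1e-12)
})

report_fixture <- function(seed = 1) {
  bc <- suppressWarnings(benchmark_claims(seed = seed, n_entities = 120))
  emb <- fit_embeddings(bc$table, k = 3)
  pr_raw <- build_profiles(bc$table, emb)
  pr <- standardize_profiles(pr_raw)
  sc <- run_ensemble(pr)
  cons <- build_consensus(sc, k = 10)
  eid <- cons$entity_id[1]
  expl <- explain_entity(pr, sc, eid, seed = seed)
  list(report = entity_report(bc$table, pr_raw, cons, expl, eid,
                              m = 2, code_feature = "code"),
       bc = bc, eid = eid)
}

test_that("reports render deterministically and round-trip through JSON", {
  fx <- report_fixture()
  rep <- fx$report
  expect_identical(render_report(rep, "markdown"), render_report(rep, "markdown"))
  j1 <- render_report(rep, "json")
  expect_identical(j1, render_report(rep, "json"))
  back <- parse_report(j1)
  expect_equal(back$entity_id, rep$entity_id)
  expect_equal(back$consensus_count, rep$consensus_count)
  expect_equal(back$importance, rep$importance, tolerance = 1e-12)
  expect_equal(names(back$comparisons), names(rep$comparisons))
  expect_equal(tibble::as_tibble(back$comparisons[[1]]),
               tibble::as_tibble(rep$comparisons[[1]]), tolerance = 1e-12)
})

test_that("report sections follow m plus the always-included code feature", {
  fx <- report_fixture()
  rep <- fx$report
  expect_true("code" %in% names(rep$comparisons))
  expect_lte(length(rep$comparisons), 3)  # m = 2 (+ code when not in top 2)
  expect_equal(rep$importance$feature[order(-abs(rep$importance$importance))],
               rep$importance$feature)   # sorted by |importance|
  html <- render_report(rep, "html")
  expect_match(html, "<svg", fixed = TRUE)
  expect_match(html, rep$entity_id, fixed = TRUE)
})

test_that("the report surfaces the planted cause of an inflated-amount anomaly", {
  hits <- vapply(1:5, function(seed) {
    pop <- generate_population(benchmark_spec(n_entities = 150), seed = seed)
    arch <- anomaly_archetype("inflated_amount", strength = 5,
                              affected_fraction = 0.01,
                              parameters = list(column = "amount"))
    lab <- inject_anomalies(pop, arch, seed = seed)
    emb <- fit_embeddings(lab$table, k = 3)
    pr_raw <- build_profiles(lab$table, emb)
    pr <- standardize_profiles(pr_raw)
    sc <- run_ensemble(pr)
    aff <- lab$ground_truth$entity_id[1]
    expl <- explain_entity(pr, sc, aff, seed = seed)
    cons_imp <- expl$consensus
    top3 <- cons_imp$term[order(-abs(cons_imp$phi))][1:3]
    "amount" %in% top3
  }, logical(1))
  expect_gt(mean(hits), 0.5)
})

test_that("excessive-code anomalies show the boosted token above population frequency", {
  pop <- generate_population(benchmark_spec(n_entities = 150), seed = 9)
  arch <- anomaly_archetype("excessive_code", strength = 20,
                            affected_fraction = 0.01,
                            parameters = list(column = "code"))
  lab <- inject_anomalies(pop, arch, seed = 9)
  aff <- lab$ground_truth$entity_id[1]
  cmp <- compare_categorical(lab$table, aff, "code")
  top_token <- cmp$token[1]
  expect_gt(cmp$entity_freq[1], cmp$population_freq[cmp$token == top_token])
})
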