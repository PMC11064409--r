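zero_rates <- setNames(rep(0, 13), criterion_ids())

test_that("zero rates produce an all-negative cohort despite decoy events", {
  cfg <- generator_config(n_children = 200, base_rates = zero_rates,
                          co_occurrence_pairs = list(), seed = 12)
  gen <- generate_cohort(cfg)
  expect_false(any(as.matrix(gen$truth[paste0("intent_", criterion_ids())])))
  prof <- evaluate_cohort(gen$cohort, TEST_SPECS, TEST_VOCAB)
  expect_false(any(met_matrix(prof)))
  res <- classify_cohort(prof, TEST_SPECS, quiet = TRUE)
  expect_equal(sum(res$classification == "positive"), 0L)
})

test_that("a rate of 1 forces the criterion for every child", {
  rates <- zero_rates
  rates["er_visits"] <- 1
  cfg <- generator_config(n_children = 150, preterm_fraction = 0,
                          base_rates = rates, co_occurrence_pairs = list(),
                          seed = 13)
  gen <- generate_cohort(cfg)
  prof <- evaluate_cohort(gen$cohort, TEST_SPECS, TEST_VOCAB)
  expect_true(all(met_matrix(prof)[, "er_visits"]))
})

test_that("generation is deterministic given the seed", {
  cfg <- generator_config(n_children = 250, seed = 14)
  g1 <- suppressWarnings(generate_cohort(cfg))
  g2 <- suppressWarnings(generate_cohort(cfg))
  expect_identical(g1$truth, g2$truth)
  for (tab in c("children", "encounters", "diagnoses", "procedures",
                "lab_orders")) {
    expect_identical(g1$cohort[[tab]], g2$cohort[[tab]], info = tab)
  }
  g3 <- suppressWarnings(
    generate_cohort(generator_config(n_children = 250, seed = 15)))
  expect_false(identical(g1$cohort$encounters, g3$cohort$encounters))
})

test_that("engine recovers every generated intent at zero noise", {
  gen <- suppressWarnings(
    generate_cohort(generator_config(n_children = 300, seed = 16)))
  prof <- evaluate_cohort(gen$cohort, TEST_SPECS, TEST_VOCAB)
  m <- met_matrix(prof)
  ti <- as.matrix(gen$truth[paste0("intent_", criterion_ids())])
  colnames(ti) <- criterion_ids()
  expect_identical(unname(m), unname(ti))
})

test_that("documentation noise flips extraction at the configured rate", {
  cfg <- generator_config(n_children = 400, seed = 17)
  gen <- suppressWarnings(generate_cohort(cfg))

  unchanged <- inject_documentation_noise(gen$cohort, gen$truth,
                                          zero_rates, seed = 18)
  expect_identical(unchanged, gen$cohort)

  # total flip: extraction disagrees with truth for every child (ER),
  # and for every full-term child (NICU, structurally fixed for pre-term)
  noisy <- inject_documentation_noise(gen$cohort, gen$truth,
                                      c(er_visits = 1, nicu_stay = 1),
                                      seed = 19)
  prof <- evaluate_cohort(noisy, TEST_SPECS, TEST_VOCAB)
  gold <- truth_as_profiles(gen$truth, gen$cohort$children)
  m <- met_matrix(prof)
  g <- met_matrix(gold)
  expect_true(all(m[, "er_visits"] != g[, "er_visits"]))
  ft <- prof$term_status == "full_term"
  expect_true(all(m[ft, "nicu_stay"] != g[ft, "nicu_stay"]))
  expect_true(all(m[!ft, "nicu_stay"] == g[!ft, "nicu_stay"]))
  # untouched criteria still agree exactly
  expect_true(all(m[, "imaging"] == g[, "imaging"]))
})

test_that("classification prevalence responds monotonically to multipliers", {
  rate_pos <- function(mult) {
    cfg <- generator_config(
      n_children = 3000,
      disorder_rate_multipliers = setNames(rep(mult, 13), criterion_ids()),
      co_occurrence_pairs = list(), seed = 20)
    gen <- generate_cohort(cfg)
    prof <- evaluate_cohort(gen$cohort, TEST_SPECS, TEST_VOCAB)
    res <- classify_cohort(prof, TEST_SPECS, quiet = TRUE)
    mean(res$classification == "positive")
  }
  rates <- vapply(c(1, 8, 25), rate_pos, 0)
  expect_true(all(diff(rates) > 0))
})

test_that("co-occurrence coupling preserves marginals while raising overlap", {
  cfg0 <- generator_config(n_children = 6000, co_occurrence_pairs = list(),
                           seed = 21)
  cfg1 <- generator_config(n_children = 6000, seed = 21)
  t0 <- generate_cohort(cfg0)$truth
  t1 <- suppressWarnings(generate_cohort(cfg1)$truth)
  expect_equal(sum(t0$intent_nicu_stay), sum(t1$intent_nicu_stay))
  expect_equal(sum(t0$intent_heart_surgery), sum(t1$intent_heart_surgery))
  jac <- function(tt) {
    a <- tt$intent_nicu_stay; b <- tt$intent_heart_surgery
    sum(a & b) / sum(a | b)
  }
  expect_gt(jac(t1), jac(t0))
})
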