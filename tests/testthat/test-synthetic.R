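test_that("the binormal effect-size conversion satisfies its inverse identity", {
  for (a in c(0.51, 0.678, 0.738, 0.785, 0.818, 0.976, 0.999)) {
    expect_equal(auc_for_effect_size(effect_size_for_auc(a)), a,
                 tolerance = 1e-12)
  }
  expect_equal(effect_size_for_auc(0.785), 1.115, tolerance = 1e-3)
  expect_equal(effect_size_for_auc(0.976), 2.80, tolerance = 1e-2)
  expect_lt(effect_size_for_auc(0.5 + 1e-9), 1e-6)
  expect_error(effect_size_for_auc(0.5), "between 0.5 and 1")
  expect_error(effect_size_for_auc(1), "between 0.5 and 1")
})

test_that("generation is byte-identical under a fixed seed", {
  cfg <- cohort_config(n_baseline = 80, seed = 123)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$baseline, b$baseline)
  expect_identical(a$followup, b$followup)
  expect_identical(a$truth, b$truth)
  # ambient RNG state must not leak into the output
  set.seed(999)
  runif(10)
  expect_identical(generate_cohort(cfg)$baseline, a$baseline)
})

test_that("sample-flow bookkeeping is conserved", {
  coh <- generate_cohort(cohort_config(n_baseline = 120, seed = 17))
  expect_equal(length(unique(coh$baseline$id)), 120)
  expect_setequal(coh$truth$id, coh$baseline$id)
  expect_true(all(coh$followup$id %in% coh$baseline$id))
  expect_equal(nrow(coh$followup), sum(coh$truth$returned))
  omp <- score_ompsq(coh$baseline)
  expect_equal(sum(omp$valid) + sum(!omp$valid), 120)
})

test_that("rate knobs at their extremes behave as promised", {
  cfg <- cohort_config(n_baseline = 30, invalid_rate = 0,
                       hkf_invalid_rate = 0, followup_rate = 1,
                       checkbox_rate = 0, stray_missing_rate = 0,
                       sickdays_missing_rate = 0, seed = 5)
  coh <- generate_cohort(cfg)
  expect_equal(nrow(coh$followup), 30)
  expect_true(all(score_ompsq(coh$baseline)$valid))
  expect_true(all(score_hkf(coh$baseline)$valid))
  expect_false(any(unlist(coh$baseline[, paste0("omp_",
                                                c(8, 16, 17), "_nw")])))
})

test_that("checkbox missingness produces substituted, still-valid records", {
  cfg <- cohort_config(n_baseline = 400, invalid_rate = 0,
                       stray_missing_rate = 0, checkbox_rate = 0.3, seed = 29)
  coh <- generate_cohort(cfg)
  omp <- score_ompsq(coh$baseline)
  ticked <- rowSums(as.matrix(coh$baseline[, paste0("omp_",
                                                    c(8, 16, 17), "_nw")]))
  expect_true(all(omp$valid))  # at most 3 checkbox items exist
  expect_equal(omp$n_substituted, as.integer(ticked))
})

test_that("follow-up key variables encode the latent outcome states", {
  coh <- generate_cohort(cohort_config(n_baseline = 200, seed = 71))
  tr <- coh$truth[match(coh$followup$id, coh$truth$id), ]
  lab <- label_outcomes(coh$followup)
  for (oc in c("ompsq_pain", "ompsq_function", "ompsq_sickleave",
               "hkf_pain")) {
    l <- lab[lab$outcome == oc, ]
    truth_state <- tr[[paste0("state_", oc)]][match(l$id, coh$followup$id)]
    expect_equal(!l$recovered, truth_state)
  }
})

test_that("a near-chance target gives a small Youden index", {
  js <- vapply(1:12, function(s) {
    cfg <- cohort_config(n_baseline = 400, followup_rate = 1,
                         invalid_rate = 0, hkf_invalid_rate = 0,
                         checkbox_rate = 0, stray_missing_rate = 0,
                         sickdays_missing_rate = 0,
                         target_auc = c(ompsq_pain = 0.501,
                                        ompsq_sickleave = 0.501,
                                        ompsq_function = 0.501,
                                        hkf_pain = 0.501),
                         seed = 1000 + s)
    coh <- generate_cohort(cfg)
    sub <- build_subsamples(score_ompsq(coh$baseline),
                            score_hkf(coh$baseline),
                            label_outcomes(coh$followup))$ompsq_pain
    youden_optimal(roc_curve(sub$score, sub$not_recovered))$youden_j
  }, 0)
  expect_gte(sum(js < 0.15), 10)
})
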