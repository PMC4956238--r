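test_that("pain dichotomization multiplies items 10 and 11 with cut-off 17", {
  expect_true(dichotomize_pain_ompsq(0, 10)$recovered)
  d <- dichotomize_pain_ompsq(c(1, 5), c(10, 4))
  expect_equal(d$raw_value, c(10, 20))
  expect_equal(d$recovered, c(TRUE, FALSE))
  # boundary: the smallest attainable products on both sides of 17
  near <- expand.grid(a = 0:10, b = 0:10)
  near <- near[near$a * near$b %in% c(16, 18), ]
  d2 <- dichotomize_pain_ompsq(near$a, near$b)
  expect_equal(d2$recovered, d2$raw_value < 17)
  expect_error(dichotomize_pain_ompsq(11, 1), "out of range")
})

test_that("function dichotomization sums raw items 21-25 with cut-off 45", {
  expect_true(dichotomize_function(matrix(10, 1, 5))$recovered)   # sum 50
  expect_true(dichotomize_function(matrix(9, 1, 5))$recovered)    # sum 45
  m44 <- matrix(c(9, 9, 9, 9, 8), 1)
  expect_false(dichotomize_function(m44)$recovered)               # sum 44
  withNA <- matrix(c(9, 9, 9, 9, NA), 1)
  expect_true(is.na(dichotomize_function(withNA)$recovered))
  expect_error(dichotomize_function(matrix(1, 1, 4)), "five items")
})

test_that("sick-leave dichotomy and trichotomy agree at their boundaries", {
  d <- dichotomize_sickleave(c(0, 1, 30, 31, 365))
  expect_equal(d$recovered, c(TRUE, FALSE, FALSE, FALSE, FALSE))
  tri <- trichotomize_sickleave(c(0, 1, 30, 31, 365))
  expect_equal(as.character(tri),
               c("none", "short_term", "short_term", "long_term", "long_term"))
  # recovered if and only if the trichotomy says "none"
  days <- 0:100
  expect_equal(dichotomize_sickleave(days)$recovered,
               trichotomize_sickleave(days) == "none")
  expect_error(dichotomize_sickleave(-1), "non-negative")
  expect_error(trichotomize_sickleave(1.5), "integers")
})

test_that("HKF pain dichotomization uses the 30-point VAS cut-off", {
  d <- dichotomize_pain_hkf(c(0, 29, 30, 100))
  expect_equal(d$recovered, c(TRUE, TRUE, FALSE, FALSE))
  expect_error(dichotomize_pain_hkf(101), "out of range")
})

test_that("label_outcomes emits one row per present label, order-invariant", {
  fu <- tibble::tibble(
    id = c("a", "b", "c"),
    fu_omp_10 = c(2, NA, 8), fu_omp_11 = c(3, 5, 9),
    fu_omp_21 = c(10, 9, 0), fu_omp_22 = c(10, 9, 0),
    fu_omp_23 = c(10, 9, 0), fu_omp_24 = c(10, 9, 0),
    fu_omp_25 = c(10, 9, 1),
    fu_sickdays = c(0, 12, NA), fu_hkf_5 = c(10, 30, 75)
  )
  lab <- label_outcomes(fu)
  # b lacks pain (item 10 missing), c lacks sick leave
  expect_equal(sum(lab$outcome == "ompsq_pain"), 2)
  expect_equal(sum(lab$outcome == "ompsq_sickleave"), 2)
  expect_equal(sum(lab$outcome == "ompsq_function"), 3)
  expect_equal(sum(lab$outcome == "hkf_pain"), 3)
  expect_true(lab$recovered[lab$id == "a" & lab$outcome == "ompsq_pain"])

  shuf <- fu[c(3, 1, 2), ]
  lab2 <- label_outcomes(shuf)
  key <- function(x) x[order(x$id, x$outcome), c("id", "outcome", "recovered")]
  expect_equal(key(as.data.frame(lab)), key(as.data.frame(lab2)),
               ignore_attr = TRUE)

  expect_error(label_outcomes(rbind(fu, fu[1, ])), "duplicate")
})

test_that("sub-samples are the intersection of valid baselines and labels", {
  coh <- generate_cohort(cohort_config(n_baseline = 150, seed = 99))
  omp <- score_ompsq(coh$baseline)
  hkf <- score_hkf(coh$baseline)
  labels <- label_outcomes(coh$followup)
  subs <- build_subsamples(omp, hkf, labels)

  # brute-force set-intersection oracle per outcome
  for (oc in names(subs)) {
    sc <- if (oc == "hkf_pain") hkf else omp
    valid_ids <- sc$id[sc$valid]
    labelled_ids <- labels$id[labels$outcome == oc]
    expect_setequal(subs[[oc]]$id, intersect(valid_ids, labelled_ids))
    expect_lte(nrow(subs[[oc]]), nrow(coh$followup))
  }

  # added missingness can only shrink a sub-sample
  fu2 <- coh$followup
  fu2$fu_sickdays[seq_len(10)] <- NA
  subs2 <- build_subsamples(omp, hkf, label_outcomes(fu2))
  expect_lte(nrow(subs2$ompsq_sickleave), nrow(subs$ompsq_sickleave))
  expect_equal(nrow(subs2$ompsq_pain), nrow(subs$ompsq_pain))
})

test_that("a complete cohort flows through without losses", {
  cfg <- cohort_config(n_baseline = 40, invalid_rate = 0,
                       hkf_invalid_rate = 0, followup_rate = 1,
                       checkbox_rate = 0, stray_missing_rate = 0,
                       sickdays_missing_rate = 0, seed = 3)
  coh <- generate_cohort(cfg)
  omp <- score_ompsq(coh$baseline)
  subs <- build_subsamples(omp, score_hkf(coh$baseline),
                           label_outcomes(coh$followup))
  expect_true(all(omp$valid))
  for (oc in names(subs)) expect_equal(nrow(subs[[oc]]), 40)
})
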