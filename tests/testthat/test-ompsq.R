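test_that("item transformation applies reverse coding and doubling", {
  it <- ompsq_item_spec()
  inv <- it[it$item_id == 12, ]
  sites <- it[it$item_id == 5, ]
  plain <- it[it$item_id == 9, ]

  expect_equal(transform_item(0, inv), 10)
  expect_equal(transform_item(7, inv), 3)
  expect_equal(transform_item(1, sites), 2)
  expect_equal(transform_item(6, sites), 12)
  expect_equal(transform_item(0:10, plain), 0:10)

  # reverse coding is an involution on the 0-10 scale
  expect_equal(10 - transform_item(0:10, inv), 0:10)

  expect_error(transform_item(11, plain), "out of range.*item 9")
  expect_error(transform_item(7, sites), "out of range.*item 5")
})

test_that("default item table carries the published structure", {
  it <- ompsq_item_spec()
  expect_equal(nrow(it), 21)
  expect_equal(sum(it$inverted), 8)
  expect_equal(sort(it$item_id[it$inverted]), c(12, 16, 17, 21:25))
  expect_equal(it$item_id[it$doubled], 5)
  expect_equal(sort(it$item_id[it$checkbox_allowed]), c(8, 16, 17))
  expect_equal(sum(it$scale_min == 1), 3)
  expect_equal(ompsq_total_range(it), c(4, 212))
})

test_that("a scale value overrides a ticked checkbox; ticks become missing", {
  expect_equal(resolve_checkbox(6, TRUE), 6)
  expect_true(is.na(resolve_checkbox(NA, TRUE)))
  expect_true(is.na(resolve_checkbox(NA, FALSE)))
  expect_equal(resolve_checkbox(c(6, NA, 0), c(TRUE, TRUE, FALSE)),
               c(6, NA, 0))
})

test_that("mean substitution completes up to three items and preserves the mean", {
  none <- substitute_missing(c(1, 2, 3))
  expect_equal(none$values, c(1, 2, 3))
  expect_equal(none$n_substituted, 0L)

  one <- substitute_missing(c(rep(5, 20), NA))
  expect_equal(one$values[21], 5)

  set.seed(11)
  base <- round(runif(18, 0, 10), 1)
  m <- sum(base) / length(base)  # independent mean
  three <- substitute_missing(c(base, NA, NA, NA))
  expect_equal(three$n_substituted, 3L)
  expect_equal(three$values[19:21], rep(m, 3))
  expect_equal(sum(three$values), 21 * m)
  # substitution preserves the mean of the transformed vector exactly
  expect_identical(mean(three$values), m)

  expect_error(substitute_missing(c(rep(1, 17), rep(NA, 4))),
               "at most 3")
})

test_that("scoring endpoints give the published 4-212 range and bands", {
  lo <- score_ompsq(omp_baseline_row(omp_min_raws()))
  hi <- score_ompsq(omp_baseline_row(omp_max_raws()))
  expect_true(lo$valid)
  expect_equal(lo$total, 4)
  expect_equal(as.character(lo$risk_band), "low")
  expect_equal(hi$total, 212)
  expect_equal(as.character(hi$risk_band), "high")
})

test_that("risk banding uses the German cut-offs on the unrounded total", {
  expect_equal(as.character(ompsq_risk_band(c(90.9, 91, 106, 106.1))),
               c("low", "medium", "medium", "high"))
})

test_that("records with more than three missing items are rejected", {
  raws <- omp_max_raws()
  r4 <- raws; r4[c("9", "10", "11", "13")] <- NA
  res4 <- score_ompsq(omp_baseline_row(r4))
  expect_false(res4$valid)
  expect_equal(res4$reason, "too many missing")

  r3 <- raws; r3[c("9", "10", "11")] <- NA
  res3 <- score_ompsq(omp_baseline_row(r3))
  expect_true(res3$valid)
  expect_equal(res3$n_substituted, 3L)

  v <- validate_ompsq(unname(r4[as.character(5:25)]))
  expect_false(v$valid)
  expect_equal(v$n_missing, 4)
})

test_that("out-of-range values reject the record with the offending item", {
  raws <- omp_min_raws()
  raws["9"] <- 11
  res <- score_ompsq(omp_baseline_row(raws))
  expect_false(res$valid)
  expect_match(res$reason, "out of range \\(item 9\\)")
})

test_that("a fixed record with two ticked work items scores to the hand value", {
  raws <- c("5" = 3, "6" = 4, "7" = 9, "8" = NA, "9" = 2, "10" = 5,
            "11" = 7, "12" = 8, "13" = 1, "14" = 0, "15" = 10, "16" = 4,
            "17" = NA, "18" = 3, "19" = 6, "20" = 2, "21" = 9, "22" = 0,
            "23" = 5, "24" = 10, "25" = 7)
  res <- score_ompsq(omp_baseline_row(raws, ticked = c(8, 17)))
  # hand scoring: transformed present values (doubling item 5, reverse
  # coding 12, 16, 21-25), then two substitutions by the mean of the 19
  transformed <- c(2 * 3, 4, 9, 2, 5, 7, 10 - 8, 1, 0, 10, 10 - 4, 3, 6, 2,
                   10 - 9, 10 - 0, 10 - 5, 10 - 10, 10 - 7)
  expected <- sum(transformed) + 2 * mean(transformed)
  expect_true(res$valid)
  expect_equal(res$n_substituted, 2L)
  expect_equal(res$total, expected)
  expect_equal(res$total, 82 * 21 / 19)
})

test_that("scoring is invariant to column order and monotone in risk", {
  set.seed(21)
  it <- ompsq_item_spec()
  raws <- stats::setNames(
    mapply(function(lo, hi) sample(lo:hi, 1), it$scale_min, it$scale_max),
    it$item_id)
  row <- omp_baseline_row(raws)
  shuffled <- row[, sample(names(row))]
  expect_equal(score_ompsq(row)$total, score_ompsq(shuffled)$total)

  base_total <- score_ompsq(row)$total
  for (k in c(9, 12)) {  # one plain, one reverse-coded item
    it_row <- it[it$item_id == k, ]
    up <- raws
    up[as.character(k)] <- if (it_row$inverted) {
      max(it_row$scale_min, raws[as.character(k)] - 1)
    } else {
      min(it_row$scale_max, raws[as.character(k)] + 1)
    }
    expect_gte(score_ompsq(omp_baseline_row(up))$total, base_total)
  }
})

test_that("random valid records stay inside the published total range", {
  set.seed(31)
  it <- ompsq_item_spec()
  for (rep in 1:25) {
    raws <- stats::setNames(
      mapply(function(lo, hi) sample(lo:hi, 1), it$scale_min, it$scale_max),
      it$item_id)
    n_miss <- sample(0:3, 1)
    if (n_miss > 0) raws[sample(21, n_miss)] <- NA
    res <- score_ompsq(omp_baseline_row(raws))
    expect_true(res$valid)
    expect_gte(res$total, 4)
    expect_lte(res$total, 212)
  }
})
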