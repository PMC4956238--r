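#' Construct a confusion matrix
#'
#' Counts of true/false positives and negatives at one cut-off, with the
#' convention that "diseased" means the unfavourable 6-month state (not
#' recovered) and "test-positive" means the baseline score meets the cut-off.
#'
#' @param tp,fp,tn,fn Non-negative integer counts.
#' @return Object of class `confusion_matrix` (named list).
#' @export
#' @examples
#' confusion_matrix(tp = 44, fp = 15, tn = 46, fn = 17)
confusion_matrix <- function(tp, fp, tn, fn) {
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(is.na(counts)) || any(counts < 0) || any(counts != floor(counts))) {
    stop("tp, fp, tn, fn must be non-negative integers", call. = FALSE)
  }
  if (sum(counts) == 0) stop("empty confusion matrix", call. = FALSE)
  structure(as.list(counts), class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2,
              dimnames = list(test = c("positive", "negative"),
                              state = c("not recovered", "recovered")))
  print(m)
  invisible(x)
}

#' Confusion matrix at a score cut-off
#'
#' @param scores Numeric vector of baseline scores.
#' @param diseased Logical vector, `TRUE` for the unfavourable actual state
#'   (not recovered).
#' @param cutoff Cut-off value; a record is test-positive when its score is
#'   at or above the cut-off (or strictly above with `strict = TRUE`).
#' @param strict Use `score > cutoff` instead of the default `>=`.
#' @return A `confusion_matrix`.
#' @export
confusion_at_cutoff <- function(scores, diseased, cutoff, strict = FALSE) {
  if (length(scores) == 0 || length(scores) != length(diseased)) {
    stop("scores and diseased must be equally long and non-empty",
         call. = FALSE)
  }
  if (anyNA(scores) || anyNA(diseased)) {
    stop("scores and diseased must not contain NA", call. = FALSE)
  }
  positive <- if (strict) scores > cutoff else scores >= cutoff
  confusion_matrix(tp = sum(positive & diseased),
                   fp = sum(positive & !diseased),
                   tn = sum(!positive & !diseased),
                   fn = sum(!positive & diseased))
}

#' Cut-off-associated validity metrics
#'
#' The metric bundle reported per ROC coordinate point: sensitivity,
#' specificity, Youden's J (sensitivity + specificity - 1), positive and
#' negative likelihood ratios, predictive values, accuracy and sample
#' prevalence. Division by zero yields `Inf` for a likelihood ratio and `NA`
#' (undefined) for a predictive value with no positive (negative) tests;
#' no exceptions are thrown for those degeneracies.
#'
#' @param cm A `confusion_matrix`.
#' @param cutoff Optional cut-off annotation carried into the result.
#' @return One-row tibble with columns `cutoff`, `tp`, `fp`, `tn`, `fn`,
#'   `prevalence`, `sensitivity`, `specificity`, `youden_j`, `plr`, `nlr`,
#'   `ppv`, `npv`, `accuracy`.
#' @export
#' @examples
#' cm_metrics(confusion_matrix(44, 15, 46, 17))
cm_metrics <- function(cm, cutoff = NA_real_) {
  stopifnot(inherits(cm, "confusion_matrix"))
  n <- cm$tp + cm$fp + cm$tn + cm$fn
  n_dis <- cm$tp + cm$fn
  n_non <- cm$tn + cm$fp
  if (n_dis == 0 || n_non == 0) {
    stop("both actual states must be present to compute validity metrics",
         call. = FALSE)
  }
  sens <- cm$tp / n_dis
  spec <- cm$tn / n_non
  plr <- safe_ratio(sens, 1 - spec)
  nlr <- safe_ratio(1 - sens, spec)
  tibble::tibble(
    cutoff = cutoff, tp = cm$tp, fp = cm$fp, tn = cm$tn, fn = cm$fn,
    prevalence = n_dis / n,
    sensitivity = sens, specificity = spec,
    youden_j = sens + spec - 1,
    plr = plr, nlr = nlr,
    ppv = if (cm$tp + cm$fp > 0) cm$tp / (cm$tp + cm$fp) else NA_real_,
    npv = if (cm$tn + cm$fn > 0) cm$tn / (cm$tn + cm$fn) else NA_real_,
    accuracy = (cm$tp + cm$tn) / n
  )
}

safe_ratio <- function(num, den) {
  if (den > 0) num / den else if (num > 0) Inf else NaN
}

#' Re-adjust predictive values to a population prevalence
#'
#' Predictive values are post-test probabilities and depend on the pre-test
#' probability (prevalence). When a sample's prevalence does not match the
#' epidemiological one, the PPV and NPV are re-computed from the
#' prevalence-independent likelihood ratios through the odds form of Bayes'
#' theorem: with pre-test odds o = p / (1 - p),
#' PPV = o * PLR / (1 + o * PLR) and NPV = 1 / (1 + o * NLR).
#'
#' @param plr,nlr Positive/negative likelihood ratios (non-negative; an
#'   infinite PLR gives PPV 1).
#' @param prevalence Population prevalence(s) in (0, 1); vectorized.
#' @return Tibble with columns `prevalence`, `ppv`, `npv`.
#' @export
#' @examples
#' # a test with sensitivity = specificity = 0.95 at 10% prevalence
#' adjust_pv(plr = 19, nlr = 0.05 / 0.95, prevalence = 0.10)
adjust_pv <- function(plr, nlr, prevalence) {
  if (any(prevalence <= 0 | prevalence >= 1)) {
    stop("prevalence must lie strictly between 0 and 1", call. = FALSE)
  }
  if (any(c(plr, nlr) < 0, na.rm = TRUE)) {
    stop("likelihood ratios must be non-negative", call. = FALSE)
  }
  n <- max(length(plr), length(nlr), length(prevalence))
  plr <- rep_len(plr, n)
  nlr <- rep_len(nlr, n)
  prevalence <- rep_len(prevalence, n)
  odds <- prevalence / (1 - prevalence)
  ppv <- ifelse(is.infinite(plr), 1, (odds * plr) / (1 + odds * plr))
  npv <- ifelse(is.infinite(nlr), 0, 1 / (1 + odds * nlr))
  tibble::tibble(prevalence = prevalence, ppv = ppv, npv = npv)
}

#' Classify test efficiency from likelihood ratios
#'
#' Conventional bands for screening-test efficiency. Positive likelihood
#' ratio: 10 or more very high, 5 to under 10 high, 2 to under 5 moderate,
#' 1 to under 2 low, under 1 uninformative. Negative likelihood ratio:
#' under 0.1 very high, 0.1 to under 0.2 high, 0.2 to under 0.5 moderate,
#' 0.5 to 1 low, above 1 uninformative. The printed source bands overlap at
#' their endpoints; they are resolved as half-open intervals as listed.
#'
#' @param plr,nlr Numeric vectors of likelihood ratios.
#' @return Factor with levels `uninformative`, `low`, `moderate`, `high`,
#'   `very_high`.
#' @export
#' @examples
#' classify_plr(c(4.25, 19))
#' classify_nlr(0.06)
classify_plr <- function(plr) {
  lev <- c("uninformative", "low", "moderate", "high", "very_high")
  b <- ifelse(plr >= 10, "very_high",
       ifelse(plr >= 5, "high",
       ifelse(plr >= 2, "moderate",
       ifelse(plr >= 1, "low", "uninformative"))))
  factor(b, levels = lev)
}

#' @rdname classify_plr
#' @export
classify_nlr <- function(nlr) {
  lev <- c("uninformative", "low", "moderate", "high", "very_high")
  b <- ifelse(nlr < 0.1, "very_high",
       ifelse(nlr < 0.2, "high",
       ifelse(nlr < 0.5, "moderate",
       ifelse(nlr <= 1, "low", "uninformative"))))
  factor(b, levels = lev)
}

#' Quality bands for percentage-valued measures
#'
#' Quality classification used for AUCs (as percentages) and single
#' sensitivity/specificity values: below 70% low, 70% to under 80% moderate,
#' 80% to under 90% good, 90% and above very good. `classify_quality_sum()`
#' applies the doubled bands to the SUM of sensitivity and specificity (in
#' percent, 0-200): below 140 low, 140 to under 160 moderate, 160 to under
#' 180 good, 180 and above very good.
#'
#' @param value_pct Percentage in 0-100 (`classify_quality`) or 0-200
#'   (`classify_quality_sum`).
#' @return Factor with levels `low`, `moderate`, `good`, `very_good`.
#' @export
#' @examples
#' classify_quality(78.5)        # AUC 0.785 -> moderate
#' classify_quality_sum(72 + 75) # moderate
classify_quality <- function(value_pct) {
  if (any(value_pct < 0 | value_pct > 100, na.rm = TRUE)) {
    stop("value_pct must be in [0, 100]", call. = FALSE)
  }
  quality_bands(value_pct, c(70, 80, 90))
}

#' @rdname classify_quality
#' @export
classify_quality_sum <- function(value_pct) {
  if (any(value_pct < 0 | value_pct > 200, na.rm = TRUE)) {
    stop("sum of percentages must be in [0, 200]", call. = FALSE)
  }
  quality_bands(value_pct, c(140, 160, 180))
}

quality_bands <- function(x, cuts) {
  lev <- c("low", "moderate", "good", "very_good")
  b <- ifelse(x < cuts[1], "low",
       ifelse(x < cuts[2], "moderate",
       ifelse(x < cuts[3], "good", "very_good")))
  factor(b, levels = lev)
}
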