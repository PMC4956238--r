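#' Synthetic item manifest for the HKF-R 10
#'
#' The Heidelberger Kurzfragebogen Rueckenschmerz has 27 items:
#' sociodemographics (gender, graduation), four pain intensity/duration
#' items, the last-week pain VAS (item 5, 0-100, excluded from scoring and
#' used as the follow-up pain outcome), one massage-efficacy item, five
#' Zung depression items, and the Kieler Schmerzinventar with five
#' catastrophising and nine helplessness/hopelessness items.
#'
#' The instrument itself (item order and response scales) is not reprinted
#' with its validation studies, so this manifest is a SYNTHETIC stand-in that
#' preserves the published structure: 27 items, item 5 unscored, plausible
#' response ranges per item group. Replace it (and the weight file) with the
#' licensed instrument's manifest for real use.
#'
#' @return A tibble with columns `item_id`, `lo`, `hi`, `scored`, `group`.
#' @export
hkf_item_spec <- function() {
  tibble::tibble(
    item_id = 1:27,
    lo = c(0, 1, 0, 0, 0, 0, 0, 0, rep(1, 5), rep(0, 14)),
    hi = c(1, 6, 10, 10, 100, 10, 10, 1, rep(4, 5), rep(6, 14)),
    scored = !(1:27 %in% 5L),
    group = c("socio", "socio", "pain", "pain", "vas_lastweek", "pain",
              "pain", "massage", rep("zung", 5), rep("ksi_catastrophising", 5),
              rep("ksi_helplessness", 9))
  )
}

#' Synthetic toy weight specification for the HKF-R 10
#'
#' The HKF-R 10 total is a non-linear score built from positive and negative
#' sum products of an underlying multiple regression model. The published
#' coefficients are not reprinted in the validation literature this package
#' accompanies, so the bundled weights are SYNTHETIC: they exercise the
#' scoring machinery (signed weights, intercept, five category boundaries)
#' and span all five risk categories over the manifest's response ranges,
#' but carry no clinical meaning. Supply the licensed weights through
#' [read_weight_spec()] for real use.
#'
#' @return List with `intercept` (real) and `weights` (named numeric vector,
#'   names are scored item ids).
#' @export
hkf_weight_spec <- function() {
  items <- hkf_item_spec()
  w <- c("1" = 2, "2" = -1,
         "3" = 1, "4" = 1, "6" = 1, "7" = 1,
         "8" = -3,
         stats::setNames(rep(1.5, 5), 9:13),
         stats::setNames(rep(1.2, 5), 14:18),
         stats::setNames(rep(0.8, 9), 19:27))
  stopifnot(setequal(names(w), items$item_id[items$scored]))
  list(intercept = -20, weights = w)
}

check_weight_spec <- function(weights, items) {
  if (!is.list(weights) || !all(c("intercept", "weights") %in% names(weights))) {
    stop("weight spec must be a list with 'intercept' and 'weights'",
         call. = FALSE)
  }
  scored <- as.character(items$item_id[items$scored])
  have <- names(weights$weights)
  if (!setequal(have, scored)) {
    stop("weight spec must cover every scored item exactly once; ",
         "mismatch on items: ",
         paste(c(setdiff(scored, have), setdiff(have, scored)), collapse = ", "),
         call. = FALSE)
  }
  invisible(weights)
}

#' Five-category HKF-R 10 risk classification
#'
#' Category boundaries as published with the instrument: low risk at or below
#' -2.5; probably low risk above -2.5 up to 8; no prediction possible above 8
#' and below 28; probably high risk from 28 up to (excluding) 37; high risk
#' at or above 37.
#'
#' @param score Numeric vector of HKF-R 10 scores (must be finite).
#' @return Factor with levels `low`, `probably_low`, `no_prediction`,
#'   `probably_high`, `high`.
#' @export
#' @examples
#' classify_hkf(c(-2.5, 8, 8.0001, 28, 37))
classify_hkf <- function(score) {
  if (any(!is.finite(score))) {
    stop("HKF-R 10 score must be finite", call. = FALSE)
  }
  lev <- c("low", "probably_low", "no_prediction", "probably_high", "high")
  cat <- ifelse(score <= -2.5, "low",
         ifelse(score <= 8, "probably_low",
         ifelse(score < 28, "no_prediction",
         ifelse(score < 37, "probably_high", "high"))))
  factor(cat, levels = lev)
}

#' Validate a single HKF-R 10 record
#'
#' Missing values are not allowed among scored items (no imputation for this
#' instrument); a record with any scored item missing or out of range is
#' invalid. A missing item 5 does not invalidate baseline scoring -- it is
#' excluded from the score -- but the record is flagged as unusable for the
#' pain outcome (`has_item5 = FALSE`).
#'
#' @param values Numeric vector of item values in manifest order, `NA` for
#'   missing.
#' @param items Item manifest, see [hkf_item_spec()].
#' @return List with `valid`, `reason`, `has_item5`.
#' @export
validate_hkf <- function(values, items = hkf_item_spec()) {
  stopifnot(length(values) == nrow(items))
  scored <- items$scored
  miss <- is.na(values) & scored
  if (any(miss)) {
    return(list(valid = FALSE,
                reason = sprintf("missing scored item %d",
                                 items$item_id[which(miss)[1]]),
                has_item5 = !is.na(values[!scored][1])))
  }
  bad <- !is.na(values) & (values < items$lo | values > items$hi)
  if (any(bad)) {
    return(list(valid = FALSE,
                reason = sprintf("out of range (item %d)",
                                 items$item_id[which(bad)[1]]),
                has_item5 = !is.na(values[!scored][1])))
  }
  list(valid = TRUE, reason = NA_character_,
       has_item5 = !is.na(values[!scored][1]))
}

#' Score HKF-R 10 baseline records
#'
#' The score is the intercept plus the weighted sum of the scored item
#' values (positive and negative weights, i.e. the instrument's "sum
#' products"); the category follows [classify_hkf()]. Records with any
#' missing or out-of-range scored item are rejected, never imputed.
#'
#' @param baseline Data frame with a character `id` column and item columns
#'   `hkf_<item_id>`.
#' @param weights Weight spec (list with `intercept` and named `weights`),
#'   see [hkf_weight_spec()].
#' @param items Item manifest, see [hkf_item_spec()].
#' @return A tibble with columns `id`, `valid`, `reason`, `score`,
#'   `category`, `has_item5`.
#' @export
score_hkf <- function(baseline, weights = hkf_weight_spec(),
                      items = hkf_item_spec()) {
  check_weight_spec(weights, items)
  item_cols <- paste0("hkf_", items$item_id)
  missing_cols <- setdiff(c("id", item_cols), names(baseline))
  if (length(missing_cols) > 0) {
    stop("baseline lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(baseline$id)) {
    stop("duplicate participant ids in baseline", call. = FALSE)
  }
  vals <- as.matrix(baseline[, item_cols, drop = FALSE])
  storage.mode(vals) <- "double"
  n <- nrow(baseline)
  out <- tibble::tibble(
    id = as.character(baseline$id),
    valid = logical(n), reason = NA_character_,
    score = NA_real_,
    category = factor(rep(NA, n),
                      levels = c("low", "probably_low", "no_prediction",
                                 "probably_high", "high")),
    has_item5 = logical(n)
  )
  scored_idx <- which(items$scored)
  w <- weights$weights[as.character(items$item_id[scored_idx])]
  for (i in seq_len(n)) {
    v <- validate_hkf(vals[i, ], items)
    out$valid[i] <- v$valid
    out$reason[i] <- v$reason
    out$has_item5[i] <- v$has_item5
    if (v$valid) {
      out$score[i] <- weights$intercept + sum(w * vals[i, scored_idx])
    }
  }
  ok <- out$valid
  out$category[ok] <- classify_hkf(out$score[ok])
  out
}
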