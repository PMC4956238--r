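#' Default item table for the German 21-item OMPSQ
#'
#' The German translation of the Orebro Musculoskeletal Pain Screening
#' Questionnaire scores 21 of its 25 items (four sociodemographic items are
#' excluded). Items are referenced by their questionnaire number, 5 to 25:
#'
#' * item 5 is the number-of-pain-sites item with six categories (1-6) whose
#'   value is doubled before summing;
#' * items 6 and 7 are the two remaining 1-10 scaled items (the instrument
#'   itself is not reprinted here, so which two items carry the 1-10 scale is
#'   a configurable convention -- change the table, not the code);
#' * items 12, 16, 17 and 21-25 are reverse coded (`10 - raw`) so that a
#'   higher transformed value always means higher risk;
#' * the three work-related items 8, 16 and 17 carry a "not working" checkbox
#'   whose tick is treated as a missing value.
#'
#' With this table the transformed total spans 4 to 212 and the risk bands
#' are low (< 91), medium (91-106) and high (> 106).
#'
#' @return A tibble with columns `item_id`, `scale_min`, `scale_max`,
#'   `inverted`, `doubled`, `checkbox_allowed`.
#' @export
#' @examples
#' spec <- ompsq_item_spec()
#' sum(spec$inverted)          # 8 reverse-coded items
#' range(ompsq_total_range(spec))
ompsq_item_spec <- function() {
  ids <- 5:25
  tibble::tibble(
    item_id = as.integer(ids),
    scale_min = ifelse(ids %in% c(5L, 6L, 7L), 1L, 0L),
    scale_max = ifelse(ids == 5L, 6L, 10L),
    inverted = ids %in% c(12L, 16L, 17L, 21L:25L),
    doubled = ids == 5L,
    checkbox_allowed = ids %in% c(8L, 16L, 17L)
  )
}

check_item_spec <- function(items) {
  stopifnot(is.data.frame(items))
  needed <- c("item_id", "scale_min", "scale_max", "inverted", "doubled",
              "checkbox_allowed")
  missing_cols <- setdiff(needed, names(items))
  if (length(missing_cols) > 0) {
    stop("item spec lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(items$item_id)) {
    stop("item spec has duplicated item_id", call. = FALSE)
  }
  if (any(items$inverted & items$doubled)) {
    stop("an item cannot be both inverted and doubled", call. = FALSE)
  }
  invisible(items)
}

#' Attainable range of the transformed OMPSQ total
#'
#' Derived from the item table, not hard-coded: the minimum (maximum) total
#' is the sum of the per-item transformed minima (maxima).
#'
#' @param items Item table as returned by [ompsq_item_spec()].
#' @return Numeric vector `c(min, max)` (4 and 212 for the default table).
#' @export
ompsq_total_range <- function(items = ompsq_item_spec()) {
  check_item_spec(items)
  lo <- transform_item(items$scale_min, items)
  hi <- transform_item(items$scale_max, items)
  c(sum(pmin(lo, hi)), sum(pmax(lo, hi)))
}

#' Transform a raw OMPSQ item value onto the risk scale
#'
#' Applies the per-item scoring rule: reverse-coded items become `10 - raw`,
#' the doubled pain-sites item becomes `2 * raw`, all others pass through.
#' Inversion and doubling never co-occur in the default table.
#'
#' @param raw Numeric vector of raw responses (NA allowed, passed through).
#' @param spec One row of the item table, or the full table when `raw` has
#'   one value per item (matched positionally).
#' @return Transformed numeric vector.
#' @export
#' @examples
#' it <- ompsq_item_spec()
#' transform_item(7, it[it$item_id == 12, ])  # reverse coded -> 3
#' transform_item(6, it[it$item_id == 5, ])   # pain sites -> 12
transform_item <- function(raw, spec) {
  if (nrow(spec) != 1 && nrow(spec) != length(raw)) {
    stop("spec must have one row, or one row per raw value", call. = FALSE)
  }
  bad <- !is.na(raw) & (raw < spec$scale_min | raw > spec$scale_max)
  if (any(bad)) {
    stop(sprintf("raw value out of range [%d, %d] for item %d",
                 spec$scale_min[which(bad)[1]], spec$scale_max[which(bad)[1]],
                 spec$item_id[which(bad)[1]]), call. = FALSE)
  }
  out <- raw
  inv <- if (nrow(spec) == 1) rep(spec$inverted, length(raw)) else spec$inverted
  dbl <- if (nrow(spec) == 1) rep(spec$doubled, length(raw)) else spec$doubled
  out[inv] <- 10 - raw[inv]
  out[dbl] <- 2 * raw[dbl]
  out
}

#' Resolve a "not working" checkbox against a scale value
#'
#' The three work-related items carry a checkbox whose tick is treated as a
#' missing value; an existing scale (VAS) value, however, overrides the
#' checkbox so that a double entry does not force mean substitution.
#'
#' @param raw Numeric vector, `NA` for an empty scale.
#' @param ticked Logical vector, `TRUE` when the checkbox is ticked.
#' @return `raw` where present, `NA` otherwise (ticked or simply empty).
#' @export
#' @examples
#' resolve_checkbox(6, TRUE)    # value wins: 6
#' resolve_checkbox(NA, TRUE)   # missing
resolve_checkbox <- function(raw, ticked) {
  ticked[is.na(ticked)] <- FALSE
  ifelse(!is.na(raw), raw, NA_real_)
}

#' Mean-substitute missing transformed item values
#'
#' Replaces each missing value by the arithmetic mean of the present
#' transformed values. At most `max_substitutions` items (3 of 21, about 14%)
#' may be substituted; callers should screen records with [validate_ompsq()]
#' first -- this function errors on a precondition violation.
#'
#' @param transformed Numeric vector with `NA` for missing items.
#' @param max_substitutions Cap on the number of substituted items.
#' @return List with `values` (completed vector) and `n_substituted`.
#' @export
substitute_missing <- function(transformed, max_substitutions = 3L) {
  n_miss <- sum(is.na(transformed))
  if (n_miss > max_substitutions) {
    stop(sprintf("%d items missing; at most %d may be substituted",
                 n_miss, max_substitutions), call. = FALSE)
  }
  if (n_miss > 0) {
    transformed[is.na(transformed)] <- mean(transformed, na.rm = TRUE)
  }
  list(values = transformed, n_substituted = as.integer(n_miss))
}

#' OMPSQ three-level risk band
#'
#' Bands for the German 4-212 total: low risk below 91, medium risk 91-106,
#' high risk above 106. The (possibly fractional) total is banded directly,
#' without prior rounding.
#'
#' @param total Numeric vector of transformed totals.
#' @return Factor with levels `low`, `medium`, `high`.
#' @export
ompsq_risk_band <- function(total) {
  band <- ifelse(total < 91, "low", ifelse(total <= 106, "medium", "high"))
  factor(band, levels = c("low", "medium", "high"))
}

# Internal: per-record pipeline on raw vectors ordered as the item table.
# Returns values on the transformed scale plus validity bookkeeping.
ompsq_score_one <- function(raw, ticked, items, max_substitutions = 3L) {
  resolved <- raw
  cb <- items$checkbox_allowed
  resolved[cb] <- resolve_checkbox(raw[cb], ticked[cb])
  bad <- !is.na(resolved) &
    (resolved < items$scale_min | resolved > items$scale_max)
  if (any(bad)) {
    return(list(valid = FALSE,
                reason = sprintf("out of range (item %d)",
                                 items$item_id[which(bad)[1]]),
                total = NA_real_, n_substituted = NA_integer_,
                per_item = NULL))
  }
  transformed <- rep(NA_real_, nrow(items))
  present <- !is.na(resolved)
  transformed[present] <- transform_item(resolved[present],
                                         items[present, , drop = FALSE])
  n_miss <- sum(!present)
  if (n_miss > max_substitutions) {
    return(list(valid = FALSE, reason = "too many missing",
                total = NA_real_, n_substituted = NA_integer_,
                per_item = NULL))
  }
  sub <- substitute_missing(transformed, max_substitutions)
  list(valid = TRUE, reason = NA_character_,
       total = sum(sub$values), n_substituted = sub$n_substituted,
       per_item = stats::setNames(sub$values, items$item_id))
}

#' Validate a single OMPSQ record
#'
#' A record is valid when, after checkbox resolution, every scored item has an
#' in-range value or can be completed within the substitution cap.
#'
#' @param raw Numeric vector of raw responses, one per row of `items`
#'   (the item-table order), `NA` for empty cells.
#' @param ticked Logical vector of checkbox states, same length (ignored for
#'   items without a checkbox).
#' @param items Item table, see [ompsq_item_spec()].
#' @param max_substitutions Substitution cap (default 3).
#' @return List with `valid` (logical), `reason` (`NA` when valid) and
#'   `n_missing` after checkbox resolution.
#' @export
validate_ompsq <- function(raw, ticked = rep(FALSE, length(raw)),
                           items = ompsq_item_spec(),
                           max_substitutions = 3L) {
  check_item_spec(items)
  res <- ompsq_score_one(raw, ticked, items, max_substitutions)
  n_missing <- {
    resolved <- raw
    cb <- items$checkbox_allowed
    resolved[cb] <- resolve_checkbox(raw[cb], ticked[cb])
    sum(is.na(resolved))
  }
  list(valid = res$valid, reason = res$reason, n_missing = n_missing)
}

#' Score OMPSQ baseline records
#'
#' Applies, in order: checkbox resolution (a present scale value overrides a
#' ticked "not working" box), range validation, reverse coding and doubling,
#' then mean substitution of up to 3 missing items. Totals are kept as reals
#' (substitution can produce fractions) and banded directly.
#'
#' @param baseline Data frame with one row per participant: a character `id`
#'   column, item columns `omp_<item_id>` and checkbox columns
#'   `omp_<item_id>_nw` for the checkbox-bearing items.
#' @param items Item table, see [ompsq_item_spec()].
#' @param max_substitutions Substitution cap (default 3).
#' @return A tibble with columns `id`, `valid`, `reason`, `total`,
#'   `n_substituted`, `risk_band`.
#' @export
#' @examples
#' rec <- as.data.frame(as.list(stats::setNames(
#'   ompsq_item_spec()$scale_max, paste0("omp_", 5:25))))
#' rec$id <- "A1"
#' score_ompsq(rec)$total  # 212, the maximal-risk record
score_ompsq <- function(baseline, items = ompsq_item_spec(),
                        max_substitutions = 3L) {
  check_item_spec(items)
  item_cols <- paste0("omp_", items$item_id)
  missing_cols <- setdiff(c("id", item_cols), names(baseline))
  if (length(missing_cols) > 0) {
    stop("baseline lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(baseline$id)) {
    stop("duplicate participant ids in baseline", call. = FALSE)
  }
  cb_cols <- paste0("omp_", items$item_id, "_nw")
  n <- nrow(baseline)
  vals <- as.matrix(baseline[, item_cols, drop = FALSE])
  storage.mode(vals) <- "double"
  ticked <- matrix(FALSE, n, nrow(items))
  for (j in which(items$checkbox_allowed)) {
    if (cb_cols[j] %in% names(baseline)) {
      ticked[, j] <- isTRUE_vec(baseline[[cb_cols[j]]])
    }
  }
  out <- tibble::tibble(
    id = as.character(baseline$id),
    valid = logical(n), reason = NA_character_,
    total = NA_real_, n_substituted = NA_integer_,
    risk_band = factor(rep(NA, n), levels = c("low", "medium", "high"))
  )
  for (i in seq_len(n)) {
    res <- ompsq_score_one(vals[i, ], ticked[i, ], items, max_substitutions)
    out$valid[i] <- res$valid
    out$reason[i] <- res$reason
    out$total[i] <- res$total
    out$n_substituted[i] <- res$n_substituted
  }
  out$risk_band <- ompsq_risk_band(out$total)
  out
}

# Coerce the accepted checkbox encodings (logical, 0/1, "TRUE"/"FALSE") to
# logical, with empty/NA meaning unticked.
isTRUE_vec <- function(x) {
  if (is.logical(x)) return(!is.na(x) & x)
  if (is.numeric(x)) return(!is.na(x) & x != 0)
  x <- trimws(as.character(x))
  !is.na(x) & x %in% c("TRUE", "true", "T", "1")
}
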