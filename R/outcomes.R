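#' Dichotomize the 6-month pain outcome (OMPSQ key items)
#'
#' Pain is the product of follow-up pain intensity and pain frequency during
#' the last 3 months (questionnaire items 10 and 11, each 0-10, product range
#' 0-100). Recovered below 17, not recovered at or above 17.
#'
#' @param i10,i11 Numeric vectors in 0-10; `NA` drops the record from this
#'   outcome's sub-sample (`recovered` is `NA`).
#' @return Tibble with `raw_value` (the product) and `recovered` (logical).
#' @export
#' @examples
#' dichotomize_pain_ompsq(5, 4)  # product 20 -> not recovered
dichotomize_pain_ompsq <- function(i10, i11) {
  check_range(i10, 0, 10, "item 10")
  check_range(i11, 0, 10, "item 11")
  raw <- i10 * i11
  tibble::tibble(raw_value = raw, recovered = raw < 17)
}

#' Dichotomize the 6-month function outcome (OMPSQ items 21-25)
#'
#' The five activity items are summed on their RAW 0-10 scale, where 10 means
#' full ability (range 0-50); recovered at or above 45. Note the asymmetry
#' with baseline scoring, which reverse-codes these items so that high
#' transformed values mean risk: the outcome uses the raw direction, so high
#' sums mean recovery.
#'
#' @param m Numeric matrix or data frame with five columns (items 21-25, raw
#'   0-10 values), one row per participant.
#' @return Tibble with `raw_value` (the sum) and `recovered`; any missing
#'   item gives `NA`.
#' @export
dichotomize_function <- function(m) {
  m <- as.matrix(m)
  if (ncol(m) != 5) stop("function outcome needs the five items 21-25",
                         call. = FALSE)
  check_range(as.vector(m), 0, 10, "items 21-25")
  raw <- rowSums(m)  # NA if any item missing
  tibble::tibble(raw_value = raw, recovered = raw >= 45)
}

#' Dichotomize 6-month self-reported sick leave
#'
#' Recovered means no sick leave at all (0 days) during the 6-month follow-up
#' window; any sick leave (> 0 days) means not recovered.
#'
#' @param days Non-negative integer vector of self-reported sick-leave days.
#' @return Tibble with `raw_value` (days) and `recovered`.
#' @export
dichotomize_sickleave <- function(days) {
  check_days(days)
  tibble::tibble(raw_value = as.numeric(days), recovered = days == 0)
}

#' Trichotomize 6-month self-reported sick leave
#'
#' Descriptive grouping retained alongside the dichotomy: no sick leave
#' (0 days), short-term (1-30 days), long-term (more than 30 days).
#'
#' @inheritParams dichotomize_sickleave
#' @return Factor with levels `none`, `short_term`, `long_term`.
#' @export
trichotomize_sickleave <- function(days) {
  check_days(days)
  g <- ifelse(days == 0, "none", ifelse(days <= 30, "short_term", "long_term"))
  factor(g, levels = c("none", "short_term", "long_term"))
}

#' Dichotomize the 6-month pain outcome (HKF-R 10 item 5)
#'
#' The last-week pain VAS (0-100), excluded from baseline scoring, is the
#' HKF-R 10 outcome variable: recovered below 30, not recovered at or
#' above 30.
#'
#' @param vas Numeric vector in 0-100.
#' @return Tibble with `raw_value` and `recovered`.
#' @export
dichotomize_pain_hkf <- function(vas) {
  check_range(vas, 0, 100, "HKF item 5")
  tibble::tibble(raw_value = vas, recovered = vas < 30)
}

check_range <- function(x, lo, hi, what) {
  bad <- !is.na(x) & (x < lo | x > hi)
  if (any(bad)) {
    stop(sprintf("%s out of range [%g, %g]: %g", what, lo, hi, x[which(bad)[1]]),
         call. = FALSE)
  }
  invisible(x)
}

check_days <- function(days) {
  bad <- !is.na(days) & (days < 0 | days != floor(days))
  if (any(bad)) {
    stop("sick-leave days must be non-negative integers", call. = FALSE)
  }
  invisible(days)
}

#' Label all four 6-month outcomes from a follow-up table
#'
#' @param followup Data frame with columns `id`, `fu_omp_10`, `fu_omp_11`,
#'   `fu_omp_21` .. `fu_omp_25`, `fu_sickdays`, `fu_hkf_5` (`NA` allowed
#'   everywhere; a record missing an outcome's key items simply drops from
#'   that outcome's sub-sample).
#' @return A long tibble with columns `id`, `outcome` (one of `ompsq_pain`,
#'   `ompsq_function`, `ompsq_sickleave`, `hkf_pain`), `raw_value`,
#'   `recovered`; rows with an absent label are dropped.
#' @export
label_outcomes <- function(followup) {
  needed <- c("id", "fu_omp_10", "fu_omp_11", paste0("fu_omp_", 21:25),
              "fu_sickdays", "fu_hkf_5")
  missing_cols <- setdiff(needed, names(followup))
  if (length(missing_cols) > 0) {
    stop("follow-up lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(followup$id)) {
    stop("duplicate participant ids in follow-up", call. = FALSE)
  }
  id <- as.character(followup$id)
  pain <- dichotomize_pain_ompsq(followup$fu_omp_10, followup$fu_omp_11)
  fct <- dichotomize_function(followup[, paste0("fu_omp_", 21:25)])
  sick <- dichotomize_sickleave(followup$fu_sickdays)
  hkf <- dichotomize_pain_hkf(followup$fu_hkf_5)
  one <- function(outcome, d) {
    tibble::tibble(id = id, outcome = outcome,
                   raw_value = d$raw_value, recovered = d$recovered)
  }
  out <- rbind(one("ompsq_pain", pain), one("ompsq_function", fct),
               one("ompsq_sickleave", sick), one("hkf_pain", hkf))
  out[!is.na(out$recovered), ]
}

#' Build per-outcome paired sub-samples
#'
#' Each outcome's sub-sample contains exactly the participants with a valid
#' baseline score on the relevant instrument AND a present outcome label.
#' The OMPSQ outcomes are paired with the OMPSQ total, the HKF pain outcome
#' with the HKF-R 10 score.
#'
#' @param ompsq_scores Tibble from [score_ompsq()].
#' @param hkf_scores Tibble from [score_hkf()].
#' @param labels Long tibble from [label_outcomes()].
#' @return Named list of tibbles (`ompsq_pain`, `ompsq_function`,
#'   `ompsq_sickleave`, `hkf_pain`), each with columns `id`, `score`,
#'   `not_recovered` (the "test-positive actual state").
#' @export
build_subsamples <- function(ompsq_scores, hkf_scores, labels) {
  if (anyDuplicated(ompsq_scores$id) || anyDuplicated(hkf_scores$id)) {
    stop("duplicate participant ids in baseline scores", call. = FALSE)
  }
  base <- list(
    ompsq_pain = ompsq_scores, ompsq_function = ompsq_scores,
    ompsq_sickleave = ompsq_scores, hkf_pain = hkf_scores
  )
  score_col <- c(ompsq_pain = "total", ompsq_function = "total",
                 ompsq_sickleave = "total", hkf_pain = "score")
  out <- lapply(names(base), function(oc) {
    b <- base[[oc]]
    b <- b[b$valid, c("id", score_col[[oc]])]
    names(b)[2] <- "score"
    lab <- labels[labels$outcome == oc, c("id", "recovered")]
    m <- merge(b, lab, by = "id")
    tibble::tibble(id = m$id, score = m$score, not_recovered = !m$recovered)
  })
  stats::setNames(out, names(base))
}
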