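#' Binormal effect size for a target AUC
#'
#' Under the equal-variance binormal model, scores of diseased and
#' non-diseased subjects are normal with common unit variance and mean
#' separation Delta, giving AUC = Phi(Delta / sqrt(2)). The inverse,
#' Delta = sqrt(2) * Phi^-1(AUC), converts a target AUC into the separation
#' the generator must induce.
#'
#' @param auc Target AUC in (0.5, 1).
#' @return The binormal separation Delta.
#' @export
#' @examples
#' effect_size_for_auc(0.785)
#' auc_for_effect_size(effect_size_for_auc(0.785))  # back to 0.785
effect_size_for_auc <- function(auc) {
  if (any(auc <= 0.5 | auc >= 1)) {
    stop("target AUC must lie strictly between 0.5 and 1", call. = FALSE)
  }
  sqrt(2) * stats::qnorm(auc)
}

#' @rdname effect_size_for_auc
#' @param delta Binormal separation.
#' @export
auc_for_effect_size <- function(delta) {
  stats::pnorm(delta / sqrt(2))
}

#' Configuration for the synthetic study cohort
#'
#' Defaults emulate the validation study's sample flow and discrimination:
#' 265 baseline participants, about 9% invalid OMPSQ baselines (24/265) and
#' a matching HKF-R 10 invalidity rate (23/265), a 50% follow-up return
#' (133/265), outcome prevalences 0.50 / 0.37 / 0.52 / 0.70 and target AUCs
#' 0.785 / 0.738 / 0.818 / 0.678 for pain / sick leave / function / HKF
#' pain, work-item checkbox missingness informed by 46 ticks over 265
#' participants and three items, sick-leave follow-up missingness 17/133,
#' and a low rate of stray empty cells.
#'
#' @param n_baseline Number of baseline participants.
#' @param invalid_rate Probability a participant's OMPSQ baseline is made
#'   invalid (more than 3 scored items deleted).
#' @param hkf_invalid_rate Probability the HKF-R 10 baseline is made invalid
#'   (scored items deleted; no substitution is allowed for this instrument).
#' @param followup_rate Probability a participant returns the 6-month
#'   follow-up questionnaire.
#' @param outcome_prevalence Named probabilities of the unfavourable state
#'   per outcome (`ompsq_pain`, `ompsq_sickleave`, `ompsq_function`,
#'   `hkf_pain`).
#' @param target_auc Named target AUCs in (0.5, 1), same names.
#' @param checkbox_rate Per-item probability that a work item (8, 16, 17) is
#'   left empty with its "not working" box ticked.
#' @param stray_missing_rate Per-cell probability of a stray empty OMPSQ item
#'   (neither scale nor checkbox filled).
#' @param sickdays_missing_rate Probability the returned follow-up lacks the
#'   sick-leave day count.
#' @param risk_dropout Log-odds decrease of the return probability per
#'   standard deviation of latent risk (0 = dropout completely at random;
#'   positive values emulate selective loss of high-risk participants).
#' @param seed Master seed; all stages derive their own sub-seed from it.
#' @return List of class `cohort_config`.
#' @export
cohort_config <- function(n_baseline = 265,
                          invalid_rate = 24 / 265,
                          hkf_invalid_rate = 23 / 265,
                          followup_rate = 133 / 265,
                          outcome_prevalence = c(ompsq_pain = 0.50,
                                                 ompsq_sickleave = 0.37,
                                                 ompsq_function = 0.52,
                                                 hkf_pain = 0.70),
                          target_auc = c(ompsq_pain = 0.785,
                                         ompsq_sickleave = 0.738,
                                         ompsq_function = 0.818,
                                         hkf_pain = 0.678),
                          checkbox_rate = 46 / (265 * 3),
                          stray_missing_rate = 0.003,
                          sickdays_missing_rate = 17 / 133,
                          risk_dropout = 0,
                          seed = 1L) {
  outcomes <- c("ompsq_pain", "ompsq_sickleave", "ompsq_function", "hkf_pain")
  probs <- c(invalid_rate, hkf_invalid_rate, followup_rate, checkbox_rate,
             stray_missing_rate, sickdays_missing_rate, outcome_prevalence)
  if (any(probs < 0 | probs > 1)) {
    stop("all rates and prevalences must lie in [0, 1]", call. = FALSE)
  }
  if (!setequal(names(outcome_prevalence), outcomes) ||
      !setequal(names(target_auc), outcomes)) {
    stop("outcome_prevalence and target_auc must be named after the four ",
         "outcomes: ", paste(outcomes, collapse = ", "), call. = FALSE)
  }
  if (any(target_auc <= 0.5 | target_auc >= 1)) {
    stop("target AUCs must lie strictly between 0.5 and 1", call. = FALSE)
  }
  structure(list(n_baseline = as.integer(n_baseline),
                 invalid_rate = invalid_rate,
                 hkf_invalid_rate = hkf_invalid_rate,
                 followup_rate = followup_rate,
                 outcome_prevalence = outcome_prevalence[outcomes],
                 target_auc = target_auc[outcomes],
                 checkbox_rate = checkbox_rate,
                 stray_missing_rate = stray_missing_rate,
                 sickdays_missing_rate = sickdays_missing_rate,
                 risk_dropout = risk_dropout,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

# One master seed feeds a per-stage seed sequence so stages can be
# regenerated independently of one another.
derive_stage_seeds <- function(seed, n_stages) {
  old <- globalenv()$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n_stages)
}

# Attach binary outcome states to observed scores by rank matching against
# a binormal draw: states are Bernoulli(prevalence); latent severities V sit
# on the exact normal quantile grids of the two binormal class distributions
# (separation Delta), and the j-th smallest observed score receives the
# state of the j-th smallest V. Rank statistics (AUC) of (score, state) then
# match those of (V, state) up to the granularity of ties in the observed
# score, and the quantile grids keep the calibration error of the empirical
# AUC at O(1/n) rather than the O(1/sqrt(n)) of iid severity draws.
assign_states <- function(score, prevalence, auc) {
  n <- length(score)
  if (n == 0) return(logical(0))
  delta <- effect_size_for_auc(auc)
  d <- stats::rbinom(n, 1L, prevalence) == 1L
  n1 <- sum(d)
  v <- numeric(n)
  if (n1 > 0) v[d] <- delta + stats::qnorm(stats::ppoints(n1))
  if (n1 < n) v[!d] <- stats::qnorm(stats::ppoints(n - n1))
  out <- logical(n)
  out[order(score, stats::runif(n))] <- d[order(v)]
  out
}

# Integer composition: k values in [0, cap] with the given sum.
compose_sum <- function(s, k, cap) {
  stopifnot(s >= 0, s <= k * cap)
  v <- if (s > 0) tabulate(sample.int(k, s, replace = TRUE), nbins = k) else
    integer(k)
  while (any(v > cap)) {
    i <- which.max(v)
    room <- which(v < cap)
    j <- room[sample.int(length(room), 1)]
    shift <- min(v[i] - cap, cap - v[j])
    v[i] <- v[i] - shift
    v[j] <- v[j] + shift
  }
  v
}

# Pairs (a, b) in {0..10}^2 with product on the requested side of 17.
sample_pain_pairs <- function(not_recovered) {
  n <- length(not_recovered)
  a <- sample(0:10, n, replace = TRUE)
  b <- sample(0:10, n, replace = TRUE)
  bad <- (a * b >= 17) != not_recovered
  while (any(bad)) {
    a[bad] <- sample(0:10, sum(bad), replace = TRUE)
    b[bad] <- sample(0:10, sum(bad), replace = TRUE)
    bad <- (a * b >= 17) != not_recovered
  }
  cbind(a, b)
}

#' Generate a synthetic baseline + follow-up cohort
#'
#' Emulates the validation study's data: a latent risk per participant
#' drives both questionnaires' item responses; each outcome's unfavourable
#' state is attached to the relevant baseline score by rank matching against
#' an exactly binormal draw with separation Delta = sqrt(2) Phi^-1(target
#' AUC), so the score discriminates the states at the configured AUC;
#' follow-up returns, invalid baselines, checkbox missingness and stray
#' empty cells are applied at the configured rates. Fully reproducible from
#' the master seed.
#'
#' @param config A [cohort_config()].
#' @param items OMPSQ item table (default [ompsq_item_spec()]).
#' @param hkf_items HKF-R 10 item manifest (default [hkf_item_spec()]).
#' @param weights HKF-R 10 weight spec (default [hkf_weight_spec()]).
#' @return List of class `synthetic_cohort` with tibbles `baseline`
#'   (schema of [read_baseline()]), `followup` (schema of
#'   [read_followup()], returners only) and `truth` (per-participant latent
#'   risk, pre-missingness scores, true outcome states, return flag), plus
#'   the `config`.
#' @export
#' @examples
#' coh <- generate_cohort(cohort_config(n_baseline = 50, seed = 7))
#' nrow(coh$baseline)
generate_cohort <- function(config = cohort_config(),
                            items = ompsq_item_spec(),
                            hkf_items = hkf_item_spec(),
                            weights = hkf_weight_spec()) {
  stopifnot(inherits(config, "cohort_config"))
  check_item_spec(items)
  n <- config$n_baseline
  ss <- derive_stage_seeds(config$seed, 8L)

  set.seed(ss[1])
  theta <- stats::rnorm(n)
  id <- sprintf("S%06d", seq_len(n))

  # --- OMPSQ items: discretized, range-clipped affine functions of the
  # latent risk plus independent item noise (reverse-coded items move
  # against the risk so their transformed value moves with it).
  set.seed(ss[2])
  n_items <- nrow(items)
  omp <- matrix(NA_real_, n, n_items)
  for (j in seq_len(n_items)) {
    d <- if (items$inverted[j]) -1 else 1
    x <- 0.6 * d * theta + 0.8 * stats::rnorm(n)
    centre <- (items$scale_min[j] + items$scale_max[j]) / 2
    span <- (items$scale_max[j] - items$scale_min[j]) / 4.2
    omp[, j] <- pmin(pmax(round(centre + span * x), items$scale_min[j]),
                     items$scale_max[j])
  }
  colnames(omp) <- paste0("omp_", items$item_id)

  # --- HKF items: probit-mapped affine functions of the latent risk; items
  # with negative toy weight (protective) move against the risk.
  set.seed(ss[3])
  w_all <- stats::setNames(rep(1, nrow(hkf_items)), hkf_items$item_id)
  w_all[names(weights$weights)] <- weights$weights
  hkf <- matrix(NA_real_, n, nrow(hkf_items))
  for (j in seq_len(nrow(hkf_items))) {
    d <- if (w_all[as.character(hkf_items$item_id[j])] < 0) -1 else 1
    q <- stats::pnorm(0.6 * d * theta + 0.8 * stats::rnorm(n))
    hkf[, j] <- hkf_items$lo[j] + round(q * (hkf_items$hi[j] - hkf_items$lo[j]))
  }
  colnames(hkf) <- paste0("hkf_", hkf_items$item_id)

  # --- Pre-missingness ("true") instrument scores
  base_complete <- data.frame(id = id, omp, hkf, check.names = FALSE)
  omp_true <- score_ompsq(base_complete, items)$total
  hkf_true <- score_hkf(base_complete, weights, hkf_items)$score

  # --- Follow-up return (optionally risk-dependent)
  set.seed(ss[4])
  p_ret <- stats::plogis(stats::qlogis(config$followup_rate) -
                           config$risk_dropout * theta)
  returned <- stats::runif(n) < p_ret

  # --- True outcome states, rank-matched to the instrument that predicts
  # the outcome. Calibration runs separately within returners and
  # non-returners: the published discrimination figures are measurements on
  # the follow-up sub-samples, so that is the stratum whose AUC the
  # generator pins to the target.
  set.seed(ss[5])
  instrument_score <- list(ompsq_pain = omp_true, ompsq_sickleave = omp_true,
                           ompsq_function = omp_true, hkf_pain = hkf_true)
  states <- lapply(names(instrument_score), function(oc) {
    s <- logical(n)
    for (grp in list(which(returned), which(!returned))) {
      s[grp] <- assign_states(instrument_score[[oc]][grp],
                              config$outcome_prevalence[[oc]],
                              config$target_auc[[oc]])
    }
    s
  })
  names(states) <- names(instrument_score)

  # --- Follow-up key variables consistent with the true states
  set.seed(ss[6])
  idx <- which(returned)
  nf <- length(idx)
  pain_pairs <- sample_pain_pairs(states$ompsq_pain[idx])
  fct_sum <- ifelse(states$ompsq_function[idx],
                    sample(0:44, nf, replace = TRUE),
                    sample(45:50, nf, replace = TRUE))
  fct_items <- t(vapply(fct_sum, compose_sum, integer(5), k = 5L, cap = 10L))
  sickdays <- ifelse(states$ompsq_sickleave[idx],
                     ifelse(stats::runif(nf) < 0.7,
                            sample(1:30, nf, replace = TRUE),
                            sample(31:120, nf, replace = TRUE)),
                     0L)
  hkf_vas <- ifelse(states$hkf_pain[idx],
                    sample(30:100, nf, replace = TRUE),
                    sample(0:29, nf, replace = TRUE))
  sickdays[stats::runif(nf) < config$sickdays_missing_rate] <- NA_integer_
  followup <- tibble::tibble(
    id = id[idx],
    fu_omp_10 = pain_pairs[, 1], fu_omp_11 = pain_pairs[, 2],
    fu_omp_21 = fct_items[, 1], fu_omp_22 = fct_items[, 2],
    fu_omp_23 = fct_items[, 3], fu_omp_24 = fct_items[, 4],
    fu_omp_25 = fct_items[, 5],
    fu_sickdays = sickdays, fu_hkf_5 = hkf_vas
  )

  # --- Baseline missingness: invalid records, checkbox ticks, stray cells
  set.seed(ss[7])
  nw <- matrix(FALSE, n, 3,
               dimnames = list(NULL, paste0("omp_", c(8, 16, 17), "_nw")))
  cb_idx <- match(c(8, 16, 17), items$item_id)
  for (k in 1:3) {
    tick <- stats::runif(n) < config$checkbox_rate
    nw[tick, k] <- TRUE
    omp[tick, cb_idx[k]] <- NA_real_
  }
  stray <- matrix(stats::runif(n * n_items) < config$stray_missing_rate,
                  n, n_items)
  omp[stray] <- NA_real_
  invalid <- stats::runif(n) < config$invalid_rate
  for (i in which(invalid)) {
    drop <- sample.int(n_items, 4L + sample.int(4L, 1L))
    omp[i, drop] <- NA_real_
  }
  hkf_invalid <- stats::runif(n) < config$hkf_invalid_rate
  scored_cols <- which(hkf_items$scored)
  for (i in which(hkf_invalid)) {
    hkf[i, sample(scored_cols, 1L + sample.int(2L, 1L))] <- NA_real_
  }

  set.seed(ss[8])
  baseline <- tibble::as_tibble(
    data.frame(id = id, omp, nw, hkf, check.names = FALSE)
  )

  truth <- tibble::tibble(
    id = id, theta = theta,
    ompsq_total_true = omp_true, hkf_score_true = hkf_true,
    state_ompsq_pain = states$ompsq_pain,
    state_ompsq_sickleave = states$ompsq_sickleave,
    state_ompsq_function = states$ompsq_function,
    state_hkf_pain = states$hkf_pain,
    returned = returned
  )
  structure(list(baseline = baseline, followup = followup, truth = truth,
                 config = config),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d baseline, %d returned follow-up (seed %d)\n",
              nrow(x$baseline), nrow(x$followup), x$config$seed))
  invisible(x)
}

#' Write a synthetic cohort to CSV files
#'
#' Emits `baseline.csv` and `followup.csv` in the schemas consumed by
#' [read_baseline()] / [read_followup()], plus `truth.csv` with the latent
#' states for test assertions.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the three file paths.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, c("baseline.csv", "followup.csv", "truth.csv"))
  utils::write.csv(cohort$baseline, paths[1], row.names = FALSE, na = "")
  utils::write.csv(cohort$followup, paths[2], row.names = FALSE, na = "")
  utils::write.csv(cohort$truth, paths[3], row.names = FALSE, na = "")
  invisible(paths)
}
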