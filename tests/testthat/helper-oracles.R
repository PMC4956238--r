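# Independent brute-force oracles and fixture builders used across tests.
# These deliberately avoid the package's own code paths.

# O(n^2) pairwise Mann-Whitney AUC with the half-tie convention.
brute_auc <- function(scores, diseased) {
  xd <- scores[diseased]
  xn <- scores[!diseased]
  s <- 0
  for (a in xd) {
    for (b in xn) s <- s + (a > b) + 0.5 * (a == b)
  }
  s / (length(xd) * length(xn))
}

# Exhaustive per-element confusion counts at a cut-off (>= positivity).
brute_confusion <- function(scores, diseased, cutoff) {
  tp <- fp <- tn <- fn <- 0L
  for (i in seq_along(scores)) {
    pos <- scores[i] >= cutoff
    if (pos && diseased[i]) tp <- tp + 1L
    if (pos && !diseased[i]) fp <- fp + 1L
    if (!pos && !diseased[i]) tn <- tn + 1L
    if (!pos && diseased[i]) fn <- fn + 1L
  }
  c(tp = tp, fp = fp, tn = tn, fn = fn)
}

# One-row baseline data frame from a named vector of raw OMPSQ values
# (names "5".."25"; NA for empty cells) and ticked checkbox item ids.
omp_baseline_row <- function(values, ticked = integer(0), id = "P1") {
  row <- as.data.frame(as.list(stats::setNames(
    values[as.character(5:25)], paste0("omp_", 5:25))))
  for (it in c(8, 16, 17)) {
    row[[paste0("omp_", it, "_nw")]] <- it %in% ticked
  }
  row$id <- id
  row
}

# Raw responses minimizing / maximizing the transformed total under the
# default item table (reverse-coded items need the opposite raw endpoint).
omp_min_raws <- function() {
  it <- backscreen::ompsq_item_spec()
  stats::setNames(ifelse(it$inverted, it$scale_max, it$scale_min),
                  it$item_id)
}
omp_max_raws <- function() {
  it <- backscreen::ompsq_item_spec()
  stats::setNames(ifelse(it$inverted, it$scale_min, it$scale_max),
                  it$item_id)
}

# The four published confusion matrices (counts TN/FP/TP/FN per outcome).
published_matrices <- function() {
  list(
    ompsq_pain      = backscreen::confusion_matrix(tp = 44, fp = 15, tn = 46, fn = 17),
    ompsq_sickleave = backscreen::confusion_matrix(tp = 25, fp = 10, tn = 58, fn = 15),
    ompsq_function  = backscreen::confusion_matrix(tp = 62, fp = 25, tn = 33, fn = 2),
    hkf_pain        = backscreen::confusion_matrix(tp = 45, fp = 6,  tn = 32, fn = 45)
  )
}
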