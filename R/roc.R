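#' Nonparametric AUC with Hanley-McNeil standard error
#'
#' The area under the ROC curve equals the Mann-Whitney probability that a
#' randomly drawn diseased (not recovered) subject outscores a randomly drawn
#' non-diseased one, with ties counted one half. It is computed from mean
#' ranks, which implements the half-tie convention exactly. The standard
#' error follows the Hanley-McNeil distribution-free formula with
#' Q1 = A/(2-A) and Q2 = 2A^2/(1+A); the significance test is a normal
#' z-test of the null "true area = 0.5", and the 95% confidence interval is
#' A +/- 1.96 SE clipped to the unit interval.
#'
#' @param scores Numeric vector of baseline scores.
#' @param diseased Logical vector of actual states (`TRUE` = not recovered).
#' @return List of class `auc_estimate` with elements `auc`, `se`,
#'   `p_value`, `ci` (length-2 vector), `n_diseased`, `n_nondiseased`.
#' @export
#' @examples
#' auc_mw(c(1, 2, 3, 4), c(FALSE, FALSE, TRUE, TRUE))$auc  # 1
auc_mw <- function(scores, diseased) {
  if (length(scores) != length(diseased) || length(scores) == 0) {
    stop("scores and diseased must be equally long and non-empty",
         call. = FALSE)
  }
  if (anyNA(scores) || anyNA(diseased)) {
    stop("scores and diseased must not contain NA", call. = FALSE)
  }
  diseased <- as.logical(diseased)
  n1 <- sum(diseased)
  n0 <- sum(!diseased)
  if (n1 == 0 || n0 == 0) {
    stop("both actual states must be present", call. = FALSE)
  }
  r <- rank(scores)  # mean ranks: half-tie Mann-Whitney convention
  a <- (sum(r[diseased]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  q1 <- a / (2 - a)
  q2 <- 2 * a^2 / (1 + a)
  se <- sqrt((a * (1 - a) + (n1 - 1) * (q1 - a^2) + (n0 - 1) * (q2 - a^2)) /
               (n1 * n0))
  p <- if (se > 0) {
    2 * stats::pnorm(-abs(a - 0.5) / se)
  } else if (a == 0.5) 1 else 0
  ci <- pmin(pmax(a + c(-1, 1) * stats::qnorm(0.975) * se, 0), 1)
  structure(list(auc = a, se = se, p_value = p, ci = ci,
                 n_diseased = n1, n_nondiseased = n0),
            class = "auc_estimate")
}

#' @export
print.auc_estimate <- function(x, ...) {
  cat(sprintf("AUC %.3f (SE %.3f, 95%% CI %.3f-%.3f, p vs 0.5 = %.4g)\n",
              x$auc, x$se, x$ci[1], x$ci[2], x$p_value))
  invisible(x)
}

# Candidate cut-offs mirroring statistics-package coordinate tables:
# midpoints between consecutive distinct observed scores, plus one sentinel
# below the minimum and one above the maximum (k distinct scores -> k + 1
# candidate cut-offs, strictly increasing).
candidate_cutoffs <- function(scores) {
  s <- sort(unique(scores))
  k <- length(s)
  if (k == 1) return(c(s - 1, s + 1))
  c(s[1] - 1, (s[-k] + s[-1]) / 2, s[k] + 1)
}

#' Full ROC coordinate table with AUC
#'
#' One coordinate point per candidate cut-off (midpoints between consecutive
#' distinct observed scores plus sentinels below the minimum and above the
#' maximum), each carrying the complete validity-metric bundle of
#' [cm_metrics()]. Test-positivity is `score >= cutoff`, so sensitivity is
#' non-increasing along the table.
#'
#' @inheritParams auc_mw
#' @param strict Use `score > cutoff` positivity instead of `>=`.
#' @return Object of class `roc_curve`: list with `points` (tibble of
#'   coordinate points), `auc`, `se`, `p_value`, `ci`, `n_diseased`,
#'   `n_nondiseased`.
#' @export
roc_curve <- function(scores, diseased, strict = FALSE) {
  est <- auc_mw(scores, diseased)
  cuts <- candidate_cutoffs(scores)
  pts <- do.call(rbind, lapply(cuts, function(ct) {
    cm_metrics(confusion_at_cutoff(scores, diseased, ct, strict), cutoff = ct)
  }))
  structure(list(points = pts, auc = est$auc, se = est$se,
                 p_value = est$p_value, ci = est$ci,
                 n_diseased = est$n_diseased,
                 n_nondiseased = est$n_nondiseased),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("ROC curve: %d coordinate points, %d / %d diseased / non-diseased\n",
              nrow(x$points), x$n_diseased, x$n_nondiseased))
  print.auc_estimate(x, ...)
  invisible(x)
}

#' Youden-optimal coordinate point
#'
#' Returns the coordinate point maximizing Youden's
#' J = sensitivity + specificity - 1, the statistically optimal cut-off;
#' ties are broken by the smallest cut-off.
#'
#' @param curve A `roc_curve` (or its `points` tibble).
#' @return One-row tibble (the optimal coordinate point).
#' @export
youden_optimal <- function(curve) {
  pts <- if (inherits(curve, "roc_curve")) curve$points else curve
  if (is.null(pts) || nrow(pts) == 0) stop("empty ROC curve", call. = FALSE)
  best <- which(pts$youden_j == max(pts$youden_j))
  pts[best[which.min(pts$cutoff[best])], ]
}

#' Trapezoidal area under the ROC polyline
#'
#' Tie-aware trapezoidal integration of the (1 - specificity, sensitivity)
#' polyline of a coordinate table; equals the Mann-Whitney AUC and serves as
#' an internal consistency check.
#'
#' @param curve A `roc_curve`.
#' @return The trapezoidal area.
#' @export
auc_trapezoid <- function(curve) {
  pts <- if (inherits(curve, "roc_curve")) curve$points else curve
  # sorted ascending; sentinels already contribute the (0,0) and (1,1) ends
  fpr <- sort(1 - pts$specificity)
  tpr <- sort(pts$sensitivity)
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}
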