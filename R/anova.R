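#' One-way analysis of variance between outcome groups
#'
#' Preliminary check that baseline total scores differ between recovered and
#' non-recovered participants (or any grouping): the classical one-way
#' decomposition F = (SSB / df_between) / (SSW / df_within), fitted with
#' `stats::aov`, with the p-value from the upper tail of the F distribution.
#'
#' @param values Numeric vector of baseline totals.
#' @param groups Vector (factor/character/logical) of group labels, same
#'   length.
#' @return One-row tibble with `f`, `df_between`, `df_within`, `p_value` and
#'   the group count `k`.
#' @export
#' @examples
#' oneway_anova(c(1, 2, 3, 7, 8, 9), rep(c("a", "b"), each = 3))
oneway_anova <- function(values, groups) {
  if (length(values) != length(groups)) {
    stop("values and groups must be equally long", call. = FALSE)
  }
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]
  g <- factor(groups[keep])
  g <- droplevels(g)
  k <- nlevels(g)
  if (k < 2) stop("need at least two non-empty groups", call. = FALSE)
  if (length(values) <= k) {
    stop("need more observations than groups", call. = FALSE)
  }
  if (stats::var(values) == 0) {
    stop("zero total variance; F is undefined", call. = FALSE)
  }
  fit <- stats::aov(values ~ g)
  tab <- summary(fit)[[1]]
  tibble::tibble(
    f = tab[["F value"]][1],
    df_between = tab[["Df"]][1],
    df_within = tab[["Df"]][2],
    p_value = tab[["Pr(>F)"]][1],
    k = k
  )
}
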