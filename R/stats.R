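## Statistical comparison of measurement tables (fractal dimensions per
## medium and timepoint, percent red per medium): two-way ANOVA with Type
## II sums of squares for the mildly unbalanced designs typical of drop
## experiments, Tukey HSD pairwise contrasts, and Welch t tests for the
## two-group bacterial-fungal comparison.

#' Two-way ANOVA on a long-format measurement table
#'
#' Fits `value ~ factor_a * factor_b` and reports main effects and the
#' interaction with Type II sums of squares (via [car::Anova()]), the
#' conventional choice for testing main effects in unbalanced designs
#' without assuming the interaction.
#'
#' @param table data frame with at least the three columns named below.
#' @param value,factor_a,factor_b column names (strings).
#' @param type sums-of-squares type, `2` (default) or `3`.
#' @return data frame of class `anova_result`: term, sum_sq, df,
#'   statistic (F), p_value.
#' @export
two_way_anova <- function(table, value = "value", factor_a = "factor_a",
                          factor_b = "factor_b", type = 2) {
  stopifnot(all(c(value, factor_a, factor_b) %in% names(table)))
  d <- data.frame(value = table[[value]],
                  A = factor(table[[factor_a]]),
                  B = factor(table[[factor_b]]))
  if (nlevels(d$A) < 2L || nlevels(d$B) < 2L)
    stop("each factor needs at least 2 levels", call. = FALSE)
  fit <- stats::lm(value ~ A * B, data = d)
  at <- car::Anova(fit, type = type)
  out <- data.frame(term = c(factor_a, factor_b,
                             paste(factor_a, factor_b, sep = ":"),
                             "residuals"),
                    sum_sq = at[["Sum Sq"]], df = at[["Df"]],
                    statistic = at[["F value"]], p_value = at[["Pr(>F)"]])
  class(out) <- c("anova_result", class(out))
  out
}

#' One-way ANOVA on a long-format measurement table
#'
#' Used for single-factor designs such as percent red ~ medium.
#'
#' @inheritParams two_way_anova
#' @return data frame: term, sum_sq, df, statistic, p_value.
#' @export
one_way_anova <- function(table, value = "value", factor_a = "factor_a") {
  stopifnot(all(c(value, factor_a) %in% names(table)))
  d <- data.frame(value = table[[value]], A = factor(table[[factor_a]]))
  if (nlevels(d$A) < 2L)
    stop("the factor needs at least 2 levels", call. = FALSE)
  at <- stats::anova(stats::lm(value ~ A, data = d))
  data.frame(term = c(factor_a, "residuals"),
             sum_sq = at[["Sum Sq"]], df = at[["Df"]],
             statistic = at[["F value"]], p_value = at[["Pr(>F)"]])
}

#' Tukey HSD pairwise contrasts
#'
#' Studentized-range adjusted pairwise comparisons for one term of an
#' ANOVA design (via [stats::TukeyHSD()] on the corresponding `aov` fit).
#'
#' @param table long-format data frame.
#' @param term which factor's levels to compare: `"factor_a"`,
#'   `"factor_b"`, or `"interaction"`.
#' @param value,factor_a,factor_b column names; `factor_b = NULL` fits a
#'   one-way design.
#' @return data frame: term, contrast, diff, lwr, upr, p_adj.
#' @export
tukey_hsd <- function(table, term = "factor_a", value = "value",
                      factor_a = "factor_a", factor_b = NULL) {
  d <- data.frame(value = table[[value]], A = factor(table[[factor_a]]))
  if (!is.null(factor_b)) {
    d$B <- factor(table[[factor_b]])
    fit <- stats::aov(value ~ A * B, data = d)
    which <- switch(term, factor_a = "A", factor_b = "B",
                    interaction = "A:B",
                    stop("unknown term: ", term, call. = FALSE))
  } else {
    if (term != "factor_a") stop("unknown term: ", term, call. = FALSE)
    fit <- stats::aov(value ~ A, data = d)
    which <- "A"
  }
  tk <- stats::TukeyHSD(fit, which = which)[[which]]
  data.frame(term = term, contrast = rownames(tk), diff = tk[, "diff"],
             lwr = tk[, "lwr"], upr = tk[, "upr"], p_adj = tk[, "p adj"],
             row.names = NULL)
}

#' Welch two-sample t test
#'
#' Unequal-variance t test with Welch-Satterthwaite degrees of freedom
#' (the default); a pooled-variance Student test is available with
#' `var_equal = TRUE`.
#'
#' @param values_a,values_b numeric vectors, n >= 2 each.
#' @param var_equal pool the variances (classic Student test)?
#' @return list of class `welch_result`: statistic (t), df, p_value,
#'   and per-group mean/sd/n.
#' @export
welch_t_test <- function(values_a, values_b, var_equal = FALSE) {
  stopifnot(length(values_a) >= 2L, length(values_b) >= 2L)
  if (stats::sd(values_a) == 0 && stats::sd(values_b) == 0)
    stop("zero variance in both groups", call. = FALSE)
  tt <- stats::t.test(values_a, values_b, var.equal = var_equal)
  structure(list(statistic = unname(tt$statistic),
                 df = unname(tt$parameter), p_value = tt$p.value,
                 mean_a = mean(values_a), sd_a = stats::sd(values_a),
                 n_a = length(values_a),
                 mean_b = mean(values_b), sd_b = stats::sd(values_b),
                 n_b = length(values_b)),
            class = "welch_result")
}

#' Welch-Satterthwaite degrees of freedom from summary statistics
#'
#' `df = (v1 + v2)^2 / (v1^2/(n1-1) + v2^2/(n2-1))` with `vi = si^2/ni`.
#' Always at most `n1 + n2 - 2`, with equality when variances and group
#' sizes match.
#'
#' @param n1,n2 group sizes (>= 2).
#' @param s1,s2 group standard deviations.
#' @return fractional degrees of freedom.
#' @examples
#' welch_df(6, 0.050, 6, 0.077)  # ~8.58
#' @export
welch_df <- function(n1, s1, n2, s2) {
  stopifnot(n1 >= 2, n2 >= 2, s1 >= 0, s2 >= 0, s1 + s2 > 0)
  v1 <- s1^2 / n1
  v2 <- s2^2 / n2
  (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
}
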