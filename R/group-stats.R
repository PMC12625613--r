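#' Percent change between group means
#'
#' `100 * (treated - control) / control`. Headline reporting rounds to the
#' nearest integer percent with ties away from zero (see
#' [round_half_away()]). Note the asymmetry: swapping the roles changes the
#' magnitude, not just the sign, because the baseline changes; when a
#' convention is ambiguous, [percent_change_both()] reports both baselines.
#'
#' @param treated_mean,control_mean Group means; `control_mean` must be
#'   nonzero.
#' @return The raw (unrounded) percent change.
#' @examples
#' percent_change(25.2, 44.4)            # -43.24...
#' round_half_away(percent_change(25.2, 44.4))  # -43
#' @export
percent_change <- function(treated_mean, control_mean) {
  if (any(control_mean == 0)) abort("`control_mean` must be nonzero.")
  100 * (treated_mean - control_mean) / control_mean
}

#' Round half away from zero
#'
#' Integer rounding with ties going away from zero (2.5 -> 3, -2.5 -> -3),
#' the convention of headline integer percentages; base R's `round()` uses
#' round-half-even instead.
#'
#' @param x Numeric vector.
#' @return Rounded numeric vector.
#' @export
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Percent change under both baseline conventions
#'
#' Published percent figures sometimes use the control mean as baseline and
#' sometimes other baselines; when the convention is not stated, both the
#' control-baseline change and the symmetric (mean-baseline) change are
#' worth inspecting.
#'
#' @inheritParams percent_change
#' @return Tibble with `baseline` (`"control"`, `"mean"`), `percent_change`
#'   and `percent_change_rounded`.
#' @export
percent_change_both <- function(treated_mean, control_mean) {
  ctrl <- percent_change(treated_mean, control_mean)
  symm <- 100 * (treated_mean - control_mean) /
    ((treated_mean + control_mean) / 2)
  tibble(baseline = c("control", "mean"),
         percent_change = c(ctrl, symm),
         percent_change_rounded = round_half_away(c(ctrl, symm)))
}

comparison_row <- function(test_used, ht, x, y) {
  tibble(test_used = test_used,
         percent_change = percent_change(mean(x), mean(y)),
         t = unname(ht$statistic), df = unname(ht$parameter),
         p = unname(ht$p.value))
}

#' Two-tailed Student's t-test (pooled variance)
#'
#' Compares a treated sample `x` against a control sample `y` with the
#' pooled-variance t statistic on `n1 + n2 - 2` degrees of freedom. Two
#' identical constant samples return `t = 0, p = 1` by convention instead
#' of failing on zero pooled variance.
#'
#' @param x Treated-group sample (numeric, n >= 2).
#' @param y Control-group sample (numeric, n >= 2).
#' @return One-row tibble: `test_used` (`"student"`), `percent_change`
#'   (treated vs control baseline), `t`, `df`, `p`.
#' @examples
#' students_t_two_tailed(c(1, 2, 3), c(4, 5, 6))
#' @export
students_t_two_tailed <- function(x, y) {
  if (length(x) < 2 || length(y) < 2)
    abort("Each sample needs at least two observations.")
  if (sd(x) == 0 && sd(y) == 0) {
    if (mean(x) == mean(y)) {
      return(tibble(test_used = "student",
                    percent_change = percent_change(mean(x), mean(y)),
                    t = 0, df = length(x) + length(y) - 2, p = 1))
    }
    abort("Zero variance in both samples with unequal means; t undefined.")
  }
  ht <- t.test(x, y, var.equal = TRUE)
  comparison_row("student", ht, x, y)
}

#' Variance-checked two-sample comparison
#'
#' Runs a two-sided F-test of variance equality; when the F-test rejects at
#' `variance_alpha`, the comparison uses Welch's t (Welch--Satterthwaite
#' degrees of freedom), otherwise the pooled-variance Student's t. This is
#' the standard "test variances, fall back to Welch" reporting workflow.
#'
#' @inheritParams students_t_two_tailed
#' @param variance_alpha Significance level of the F-test. Default 0.05.
#' @return One-row tibble as in [students_t_two_tailed()], with
#'   `test_used` `"student"` or `"welch"` plus `variance_p` (F-test
#'   p-value).
#' @export
choose_and_run_test <- function(x, y, variance_alpha = 0.05) {
  if (length(x) < 2 || length(y) < 2)
    abort("Each sample needs at least two observations.")
  if (sd(x) == 0 && sd(y) == 0) {
    out <- students_t_two_tailed(x, y)
    out$variance_p <- 1
    return(out)
  }
  vp <- var.test(x, y)$p.value
  out <- if (vp < variance_alpha) {
    comparison_row("welch", t.test(x, y, var.equal = FALSE), x, y)
  } else {
    students_t_two_tailed(x, y)
  }
  out$variance_p <- vp
  out
}

#' Compare two groups in a tidy table
#'
#' Data-frame-first wrapper: takes raw observations with a group column,
#' computes the percent change of the treated mean versus the control mean,
#' and runs the variance-checked t-test.
#'
#' @param data Data frame of raw values.
#' @param value,group Column names (strings) of the measurement and the
#'   group label.
#' @param control Label of the control group; every other label is compared
#'   against it.
#' @param variance_alpha Significance level for the variance F-test.
#' @return Tibble with one row per non-control group: `group`, `control`,
#'   `n`, `n_control`, `mean`, `mean_control`, plus the columns of
#'   [choose_and_run_test()] and `percent_change_rounded`.
#' @export
compare_groups <- function(data, value = "value", group = "group",
                           control = "control", variance_alpha = 0.05) {
  g <- data[[group]]
  if (!control %in% g)
    abort(paste0("Control group '", control, "' not found."))
  y <- data[[value]][g == control]
  others <- setdiff(unique(g), control)
  bind_rows(lapply(others, function(lv) {
    x <- data[[value]][g == lv]
    res <- choose_and_run_test(x, y, variance_alpha)
    tibble(group = lv, control = control,
           n = length(x), n_control = length(y),
           mean = mean(x), mean_control = mean(y)) %>%
      dplyr::bind_cols(res) %>%
      mutate(percent_change_rounded = round_half_away(.data$percent_change))
  }))
}
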