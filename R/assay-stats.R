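#' Fold change and two-sided two-sample comparison
#'
#' Normalized comparison of reporter ratios between a treated and a
#' control group, as used for knockdown and interferon-induction
#' experiments: fold change is the ratio of group means, significance is
#' a two-sided Student's t-test (equal variances by default, matching
#' the classical test; set `var_equal = FALSE` for Welch). Significance
#' stars follow the 0.01 / 0.001 convention: `**` for p < 0.01, `***`
#' for p < 0.001, `NS` otherwise. With fewer than two values in either
#' group the fold change is still reported but the p-value is `NA`. The
#' statistic is scale-invariant: multiplying both groups by a positive
#' constant changes neither fold nor p.
#'
#' @param treated,control Numeric vectors of (ratio) values; both must
#'   have positive means.
#' @param var_equal Use the pooled-variance Student's t-test (default
#'   `TRUE`).
#' @return A one-row tibble: `fold`, `p_value`, `stars`, `n_treated`,
#'   `n_control`, `mean_treated`, `mean_control`.
#' @examples
#' fold_change(c(1.7, 1.9, 1.8, 1.75), c(1.0, 1.05, 0.95, 1.0))
#' @export
fold_change <- function(treated, control, var_equal = TRUE) {
  treated <- treated[is.finite(treated)]
  control <- control[is.finite(control)]
  if (length(treated) == 0 || length(control) == 0)
    rlang::abort("Both groups must be non-empty.")
  m_t <- mean(treated); m_c <- mean(control)
  if (m_t <= 0 || m_c <= 0)
    rlang::abort("Group means must be positive for a fold change.")
  p <- if (length(treated) >= 2 && length(control) >= 2) {
    stats::t.test(treated, control, var.equal = var_equal,
                  alternative = "two.sided")$p.value
  } else {
    NA_real_
  }
  stars <- dplyr::case_when(
    is.na(p) ~ NA_character_,
    p < 0.001 ~ "***",
    p < 0.01 ~ "**",
    TRUE ~ "NS"
  )
  tibble::tibble(fold = m_t / m_c, p_value = p, stars = stars,
                 n_treated = length(treated), n_control = length(control),
                 mean_treated = m_t, mean_control = m_c)
}
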