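#' Four-parameter logistic dose-response fit
#'
#' Fits `response = bottom + (top - bottom) / (1 + (ic50 / dose)^hill)`
#' by Levenberg-Marquardt least squares on a log10(IC50)
#' parameterization. For confirmation experiments with few doses (e.g.
#' 2.5 / 5 / 10 uM) the curve can be constrained by fixing `top` and/or
#' `bottom` (typically 100 and 0 on the percent-inhibition scale),
#' leaving a two-parameter fit that is identifiable from three points.
#'
#' The `converged` flag is honest: non-convergence, essentially flat
#' responses, or a fitted IC50 more than two decades outside the tested
#' dose span all yield `converged = FALSE` (never an exception).
#'
#' @param dose Numeric vector of doses in uM (> 0).
#' @param response Numeric vector of responses (percent inhibition).
#' @param top,bottom Optional fixed asymptotes; `NULL` (default) fits
#'   them. At least 4 points are required for the full 4PL, 2 when both
#'   asymptotes are fixed, 3 when one is.
#' @param hill_init Starting Hill slope (default 1).
#' @return An object of class `dose_response_fit` with fields `ic50`,
#'   `hill`, `top`, `bottom`, `converged`, `data` (tibble of dose,
#'   response, fitted) and `rss`. `NA` estimates when not converged.
#'   Has [generics::tidy()] and [generics::glance()] methods and an
#'   [ggplot2::autoplot()].
#' @examples
#' d <- c(0.001, 0.01, 0.03, 0.1, 0.3, 1, 3, 10)
#' y <- 100 * d / (d + 0.08)
#' fit_4pl(d, y)
#' @export
fit_4pl <- function(dose, response, top = NULL, bottom = NULL,
                    hill_init = 1) {
  if (length(dose) != length(response))
    rlang::abort("`dose` and `response` must have equal length.")
  keep <- is.finite(dose) & is.finite(response)
  dose <- dose[keep]; response <- response[keep]
  if (any(dose <= 0))
    rlang::abort("Doses must be positive (the 4PL is defined on log dose).")
  n_par <- 2 + is.null(top) + is.null(bottom)
  fail <- function(note) {
    structure(list(ic50 = NA_real_, hill = NA_real_,
                   top = top %||% NA_real_, bottom = bottom %||% NA_real_,
                   converged = FALSE, note = note,
                   data = tibble::tibble(dose = dose, response = response,
                                         fitted = NA_real_),
                   rss = NA_real_, n = length(dose)),
              class = "dose_response_fit")
  }
  if (length(dose) < n_par)
    return(fail(sprintf("need >= %d points for %d parameters", n_par, n_par)))
  if (diff(range(response)) < 1e-8 * max(1, max(abs(response))))
    return(fail("flat responses"))

  df <- data.frame(dose = dose, response = response)
  start <- list(lic50 = stats::median(log10(dose)), hill = hill_init)
  if (is.null(bottom)) start$bottom <- min(response)
  if (is.null(top)) start$top <- max(response)
  # response as a function of log10 dose; lic50 = log10(ic50)
  rhs <- paste0(
    if (is.null(bottom)) "bottom" else format(bottom, digits = 15),
    " + (", if (is.null(top)) "top" else format(top, digits = 15),
    " - ", if (is.null(bottom)) "bottom" else format(bottom, digits = 15),
    ") / (1 + 10^((lic50 - log10(dose)) * hill))")
  form <- stats::as.formula(paste("response ~", rhs))

  fit <- tryCatch(
    minpack.lm::nlsLM(form, data = df, start = start,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(fail("optimizer failed"))
  cf <- stats::coef(fit)
  ic50 <- 10^cf[["lic50"]]
  span <- range(dose)
  if (!is.finite(ic50) || ic50 < span[1] * 1e-2 || ic50 > span[2] * 1e2)
    return(fail("IC50 outside tested dose span x [1e-2, 1e2]"))
  fitted_vals <- stats::fitted(fit)
  structure(list(
    ic50 = ic50,
    hill = cf[["hill"]],
    top = if (is.null(top)) cf[["top"]] else top,
    bottom = if (is.null(bottom)) cf[["bottom"]] else bottom,
    converged = TRUE, note = NA_character_,
    data = tibble::tibble(dose = dose, response = response,
                          fitted = as.numeric(fitted_vals)),
    rss = sum(stats::resid(fit)^2), n = length(dose)
  ), class = "dose_response_fit")
}

#' @export
print.dose_response_fit <- function(x, ...) {
  if (x$converged) {
    cat(sprintf(
      "4PL dose-response fit: IC50 %.4g uM, hill %.3g, top %.4g, bottom %.4g (n = %d)\n",
      x$ic50, x$hill, x$top, x$bottom, x$n))
  } else {
    cat(sprintf("4PL dose-response fit: not converged (%s; n = %d)\n",
                x$note, x$n))
  }
  invisible(x)
}

#' @rdname fit_4pl
#' @param x A `dose_response_fit`.
#' @param ... Unused.
#' @export
tidy.dose_response_fit <- function(x, ...) {
  tibble::tibble(term = c("ic50", "hill", "top", "bottom"),
                 estimate = c(x$ic50, x$hill, x$top, x$bottom))
}

#' @rdname fit_4pl
#' @export
glance.dose_response_fit <- function(x, ...) {
  tibble::tibble(ic50 = x$ic50, hill = x$hill, top = x$top,
                 bottom = x$bottom, converged = x$converged,
                 rss = x$rss, n = x$n)
}

#' Confirm primary hits at several doses
#'
#' Re-tests primary hits in an independent simulated experiment at the
#' confirmation doses (default 2.5, 5 and 10 uM, each with its own
#' negative- and positive-control set), recomputes percent inhibition
#' per dose and flags a hit `confirmed` when its inhibition is monotone
#' non-decreasing with dose — allowing dips up to `dip_tolerance`
#' percentage points between adjacent doses as measurement-noise
#' slack — and reaches `hit_threshold` at the top dose. Hits without a
#' ground-truth record are marked `untestable`.
#'
#' @param hits Character vector of compound ids, or a [call_hits()] /
#'   [analyze_screen()] result from which flagged hits are taken.
#' @param truth Ground-truth tibble (`compound_id`, `action`, `ic50`,
#'   `hill`, `max_effect`) as produced by [simulate_screen()].
#' @param params A [reporter_params()] object.
#' @param noise A [noise_config()] object; `noise$seed` (offset so the
#'   confirmation run is independent of the primary screen) drives the
#'   new measurement noise.
#' @param doses Confirmation concentrations in uM, increasing.
#' @param control_dose Concentration of the positive-control Nluc
#'   inhibitor, fixed at 10 uM on every confirmation plate.
#' @param hit_threshold Percent inhibition required at the top dose.
#' @param dip_tolerance Allowed drop between adjacent doses (percentage
#'   points).
#' @param n_controls Control wells per role and dose (default 16).
#' @return A tibble with one row per hit and dose: `compound_id`,
#'   `dose_uM`, `pct_inhibition`, plus per-compound `confirmed` and
#'   `untestable` flags.
#' @export
retest <- function(hits, truth, params = reporter_params(),
                   noise = noise_config(), doses = c(2.5, 5, 10),
                   hit_threshold = 70, dip_tolerance = 10,
                   n_controls = 16, control_dose = 10) {
  if (inherits(hits, "screen_result")) hits <- hits$hits$compound_id
  if (is.data.frame(hits)) hits <- hits$compound_id[hits$hit_flag]
  hits <- unique(as.character(hits))
  doses <- sort(doses)
  if (length(hits) == 0) {
    return(tibble::tibble(compound_id = character(), dose_uM = numeric(),
                          pct_inhibition = numeric(), confirmed = logical(),
                          untestable = logical()))
  }
  key <- match(hits, truth$compound_id)
  untestable <- is.na(key)

  withr::with_seed(noise$seed + 1000003L, {
    per_dose <- purrr::map(doses, function(dz) {
      mu_n <- mean(
        signal_core("inactive", 1, 1, 0, 0, params)$nluc /
          signal_core("inactive", 1, 1, 0, 0, params)$ffl *
          lognormal_noise(n_controls, noise$cv_nluc) /
          lognormal_noise(n_controls, noise$cv_ffl))
      pos <- signal_core("nluc_enzyme_inhibitor", 0.08, 1, 1, control_dose, params)
      mu_p <- mean(pos$nluc * lognormal_noise(n_controls, noise$cv_nluc) /
                     (pos$ffl * lognormal_noise(n_controls, noise$cv_ffl)))
      core <- signal_core(
        ifelse(untestable, "inactive", truth$action[key]),
        ifelse(untestable, 1, truth$ic50[key]) %|NA|% 1,
        ifelse(untestable, 1, truth$hill[key]) %|NA|% 1,
        ifelse(untestable, 0, truth$max_effect[key]) %|NA|% 0,
        rep(dz, length(hits)), params)
      ratio <- core$nluc * lognormal_noise(length(hits), noise$cv_nluc) /
        (core$ffl * lognormal_noise(length(hits), noise$cv_ffl))
      tibble::tibble(compound_id = hits, dose_uM = dz,
                     pct_inhibition = pct_inhibition(ratio, mu_n, mu_p))
    })
  })
  long <- dplyr::bind_rows(per_dose)
  conf <- dplyr::group_by(long, .data$compound_id) |>
    dplyr::arrange(.data$dose_uM, .by_group = TRUE) |>
    dplyr::summarise(
      confirmed = all(diff(.data$pct_inhibition) >= -dip_tolerance) &&
        dplyr::last(.data$pct_inhibition) >= hit_threshold,
      .groups = "drop")
  out <- dplyr::left_join(long, conf, by = "compound_id")
  out$untestable <- untestable[match(out$compound_id, hits)]
  out$confirmed <- out$confirmed & !out$untestable
  out$pct_inhibition[out$untestable] <- NA_real_
  dplyr::arrange(out, .data$compound_id, .data$dose_uM)
}

`%|NA|%` <- function(x, y) ifelse(is.na(x), y, x)
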