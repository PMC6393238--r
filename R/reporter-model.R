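#' Parameters of the dual-luciferase editing reporter
#'
#' The reporter expresses firefly luciferase (FFL) from every transcript;
#' editing of an amber stop codon allows read-through into a downstream
#' nanoluciferase (Nluc), so Nluc is produced only from the FFL-Nluc
#' fusion of edited transcripts. Four parameters describe the system:
#'
#' * `beta` — per-molecule brightness of Nluc relative to FFL
#'   (dimensionless; Nluc is reported to be more than 150-fold brighter,
#'   hence the default 150).
#' * `s` — steady-state stability of the FFL-Nluc fusion relative to free
#'   FFL, in (0, 1]. The fusion is turned over much faster than free FFL,
#'   which is why measured Nluc/FFL ratios sit far below `beta * e`;
#'   default 0.01 reproduces that qualitative observation and is a free
#'   simulator parameter, not an estimate.
#' * `e0` — baseline editing fraction of the cell line in \[0, 1\]
#'   (default 0.39, the editing level of the screening clone).
#' * `amplitude` — transcript/translation scale in arbitrary luminescence
#'   units (default 1e6).
#'
#' @param beta,s,e0,amplitude See above.
#' @return An object of class `reporter_params`.
#' @examples
#' reporter_params()
#' @export
reporter_params <- function(beta = 150, s = 0.01, e0 = 0.39,
                            amplitude = 1e6) {
  if (!is.numeric(beta) || length(beta) != 1 || !is.finite(beta) || beta <= 0)
    rlang::abort("`beta` must be a single positive number.")
  if (!is.numeric(s) || length(s) != 1 || !is.finite(s) || s <= 0 || s > 1)
    rlang::abort("`s` must be a single number in (0, 1].")
  if (!is.numeric(e0) || length(e0) != 1 || !is.finite(e0) || e0 < 0 || e0 > 1)
    rlang::abort("`e0` must be a single number in [0, 1].")
  if (!is.numeric(amplitude) || length(amplitude) != 1 ||
      !is.finite(amplitude) || amplitude <= 0)
    rlang::abort("`amplitude` must be a single positive number.")
  structure(list(beta = beta, s = s, e0 = e0, amplitude = amplitude),
            class = "reporter_params")
}

compound_actions <- c("inactive", "editing_inhibitor", "editing_activator",
                      "nluc_enzyme_inhibitor", "cytotoxic")

#' Latent action of a screened compound
#'
#' A compound acts through one of five mechanisms: `inactive`;
#' `editing_inhibitor` (reduces the editing fraction);
#' `editing_activator` (raises it); `nluc_enzyme_inhibitor` (quenches the
#' Nluc enzymatic reaction without touching editing or FFL — the
#' positive-control mechanism and the designed false-positive class); or
#' `cytotoxic` (depresses both channels). Potency follows a Hill
#' occupancy `f(dose) = max_effect * dose^hill / (dose^hill + ic50^hill)`.
#'
#' @param action One of `r paste0('"', compound_actions, '"', collapse = ", ")`.
#' @param ic50 Potency in uM; required positive for non-inactive actions.
#' @param hill Hill slope (default 1).
#' @param max_effect Fraction of complete action at saturating dose, in
#'   \[0, 1\] (default 1).
#' @return An object of class `compound_effect`.
#' @examples
#' compound_effect("editing_inhibitor", ic50 = 0.5)
#' @export
compound_effect <- function(action, ic50 = NA_real_, hill = 1,
                            max_effect = 1) {
  action <- match.arg(action, compound_actions)
  if (action != "inactive" &&
      (!is.numeric(ic50) || length(ic50) != 1 || !is.finite(ic50) || ic50 <= 0))
    rlang::abort("`ic50` must be a single positive number for active compounds.")
  if (!is.numeric(hill) || length(hill) != 1 || !is.finite(hill) || hill <= 0)
    rlang::abort("`hill` must be a single positive number.")
  if (!is.numeric(max_effect) || length(max_effect) != 1 ||
      !is.finite(max_effect) || max_effect < 0 || max_effect > 1)
    rlang::abort("`max_effect` must be a single number in [0, 1].")
  structure(list(action = action, ic50 = as.numeric(ic50), hill = hill,
                 max_effect = max_effect),
            class = "compound_effect")
}

# Vectorized mechanistic core shared by expected_signals() and the
# simulator. All arguments are vectors of one common length except the
# reporter parameters. Returns a list with ffl, nluc, e, f.
signal_core <- function(action, ic50, hill, max_effect, dose, params) {
  f <- ifelse(action == "inactive" | dose <= 0, 0,
              max_effect * dose^hill / (dose^hill + ic50^hill))
  e <- rep(params$e0, length(action))
  e <- ifelse(action == "editing_inhibitor", params$e0 * (1 - f), e)
  e <- ifelse(action == "editing_activator",
              params$e0 + (1 - params$e0) * f, e)
  eta <- ifelse(action == "nluc_enzyme_inhibitor", 1 - f, 1)
  viab <- ifelse(action == "cytotoxic", 1 - f, 1)
  ffl <- params$amplitude * ((1 - e) + params$s * e) * viab
  nluc <- params$amplitude * e * params$s * params$beta * eta * viab
  list(ffl = ffl, nluc = nluc, e = e, f = f)
}

#' Expected reporter signals for a compound at a dose
#'
#' Deterministic (noise-free) expectation of the two luminescence
#' channels under the mechanistic reporter model. With editing fraction
#' `e` and fusion stability `s`, every transcript contributes FFL
#' (free FFL from unedited transcripts, fusion FFL from edited ones) and
#' only edited transcripts contribute Nluc:
#' `FFL = amplitude * ((1 - e) + s * e)` and
#' `Nluc = amplitude * e * s * beta`. Editing inhibitors scale `e` down
#' by the Hill occupancy `f`, activators move it toward 1, Nluc enzyme
#' inhibitors multiply only the Nluc channel by `(1 - f)`, and cytotoxic
#' compounds multiply both channels by `(1 - f)` — which leaves the
#' Nluc/FFL ratio unchanged, the basis of the ratio readout's robustness.
#'
#' @param params A [reporter_params()] object.
#' @param effect A [compound_effect()] object.
#' @param dose Numeric vector of doses in uM (>= 0).
#' @return A tibble with columns `dose_uM`, `ffl`, `nluc`, `ratio` and
#'   the latent `editing_fraction`.
#' @examples
#' expected_signals(reporter_params(), compound_effect("editing_inhibitor",
#'   ic50 = 1), dose = c(0, 1, 10))
#' @export
expected_signals <- function(params, effect, dose) {
  if (!inherits(params, "reporter_params"))
    params <- do.call(reporter_params, as.list(params))
  if (!inherits(effect, "compound_effect"))
    effect <- do.call(compound_effect, as.list(effect))
  if (any(!is.finite(dose)) || any(dose < 0))
    rlang::abort("`dose` must be finite and non-negative.")
  core <- signal_core(rep(effect$action, length(dose)),
                      rep(effect$ic50, length(dose)),
                      rep(effect$hill, length(dose)),
                      rep(effect$max_effect, length(dose)),
                      dose, params)
  tibble::tibble(dose_uM = dose, ffl = core$ffl, nluc = core$nluc,
                 ratio = ifelse(core$ffl > 0, core$nluc / core$ffl, NA_real_),
                 editing_fraction = core$e)
}

#' Naive expected Nluc/FFL ratio
#'
#' The back-of-the-envelope reporter arithmetic: if Nluc is `beta`-fold
#' brighter per molecule than FFL and every transcript yields FFL while a
#' fraction `e` also yields Nluc, the expected ratio is simply
#' `beta * e` — 1.5 at 1% editing and 150 at 100% editing for
#' `beta = 150`. Fusion-protein instability and FFL depletion are
#' deliberately ignored; measured ratios fall well below this line, which
#' the mechanistic model attributes to the stability factor `s`.
#'
#' @param e Editing fraction(s) in \[0, 1\].
#' @param beta Per-molecule brightness ratio (default 150).
#' @return Numeric vector `beta * e`.
#' @examples
#' naive_ratio(0.01, 150)
#' @export
naive_ratio <- function(e, beta = 150) {
  if (any(!is.finite(e)) || any(e < 0) || any(e > 1))
    rlang::abort("`e` must be within [0, 1].")
  if (any(!is.finite(beta)) || any(beta <= 0))
    rlang::abort("`beta` must be positive.")
  beta * e
}

#' Saturating editing response to an ADAR expression surrogate
#'
#' Editing fraction as a function of an ADAR expression dose surrogate:
#' `e(dose) = e_max * (1 - exp(-k * dose))`, monotone increasing and
#' saturating at `e_max`. Combined with the reporter model this
#' reproduces the observed qualitative chain — reporter ratio roughly
#' linear in expression dose, editing logarithmic in dose, and ratio
#' convex (exponential-like) in editing percentage.
#'
#' @param dose Non-negative expression surrogate (arbitrary units).
#' @param e_max Saturating editing fraction in (0, 1\].
#' @param k Rate constant > 0 (per dose unit).
#' @return Editing fraction(s) in \[0, `e_max`).
#' @examples
#' editing_dose_curve(1, e_max = 0.8, k = 1)
#' @export
editing_dose_curve <- function(dose, e_max, k) {
  if (any(!is.finite(dose)) || any(dose < 0))
    rlang::abort("`dose` must be finite and non-negative.")
  if (!is.numeric(e_max) || any(e_max <= 0) || any(e_max > 1))
    rlang::abort("`e_max` must be in (0, 1].")
  if (!is.numeric(k) || any(k <= 0))
    rlang::abort("`k` must be positive.")
  e_max * (1 - exp(-k * dose))
}

#' @export
print.reporter_params <- function(x, ...) {
  cat("Dual-luciferase reporter parameters\n")
  cat(sprintf("  brightness ratio beta : %g\n", x$beta))
  cat(sprintf("  fusion stability s    : %g\n", x$s))
  cat(sprintf("  baseline editing e0   : %g\n", x$e0))
  cat(sprintf("  amplitude             : %g\n", x$amplitude))
  invisible(x)
}

#' @export
print.compound_effect <- function(x, ...) {
  cat(sprintf("Compound effect: %s (IC50 %s uM, hill %g, max effect %g)\n",
              x$action, format(x$ic50), x$hill, x$max_effect))
  invisible(x)
}
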