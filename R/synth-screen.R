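#' Well-noise configuration for the screen simulator
#'
#' Multiplicative lognormal noise per channel (mean 1, given CV):
#' luminescence counts are positive and roughly CV-stable, so lognormal
#' noise is used rather than additive Gaussian, which would allow
#' negative counts. The default CV of 0.075 per channel gives a
#' control-ratio CV of about 0.106 and a closed-form plate Z'-factor of
#' about 0.68, matching the reported average plate quality of the
#' campaign the simulator emulates.
#'
#' Substrate decay is modelled as a static per-channel factor
#' `(1 - read_decay)^read_time_h`: the FFL signal half-life is about
#' one hour (decay 0.5/h) while Nluc is stable. Because the factor is
#' common to all wells of a channel it cancels from the ratio-based
#' statistics; it matters only for absolute counts. An optional
#' multiplicative row/column gradient (`gradient_strength`) exists for
#' robustness testing and is off by default, reflecting that no
#' systematic plate effects were observed in the assay.
#'
#' @param cv_ffl,cv_nluc Coefficient of variation of well noise per channel.
#' @param read_decay_ffl,read_decay_nluc Fractional signal loss per hour
#'   after reagent addition, in \[0, 1).
#' @param read_time_h Hours between reagent addition and the read
#'   (default 0: read immediately).
#' @param gradient_strength Amplitude of an optional linear row+column
#'   gradient (0 disables it).
#' @param seed Integer RNG seed; the simulator is deterministic given it.
#' @return An object of class `noise_config`.
#' @export
noise_config <- function(cv_ffl = 0.075, cv_nluc = 0.075,
                         read_decay_ffl = 0.5, read_decay_nluc = 0,
                         read_time_h = 0, gradient_strength = 0,
                         seed = 1L) {
  if (cv_ffl < 0 || cv_nluc < 0)
    rlang::abort("Noise CVs must be non-negative.")
  if (read_decay_ffl < 0 || read_decay_ffl >= 1 ||
      read_decay_nluc < 0 || read_decay_nluc >= 1)
    rlang::abort("Read decay fractions must lie in [0, 1).")
  if (read_time_h < 0) rlang::abort("`read_time_h` must be non-negative.")
  structure(list(cv_ffl = cv_ffl, cv_nluc = cv_nluc,
                 read_decay_ffl = read_decay_ffl,
                 read_decay_nluc = read_decay_nluc,
                 read_time_h = read_time_h,
                 gradient_strength = gradient_strength,
                 seed = as.integer(seed)),
            class = "noise_config")
}

#' Composition of a simulated compound library
#'
#' Declares the library size, the mix of latent mechanisms and the
#' potency distribution. Plates are derived as `ceiling(n / 352)` with
#' the default 384-well layout (22 compound columns of 16 wells). The
#' default mechanism fractions are illustrative — they bracket the ~1%
#' primary hit rate typical of a diverse library — since the true
#' mechanism mix behind a screen's hits is not observable without
#' counter-screens.
#'
#' @param n_compounds Library size (default 33000).
#' @param frac_by_action Named proportions over the five
#'   [compound_effect()] actions; must sum to 1.
#' @param ic50_range Log-uniform IC50 sampling range in uM for active
#'   compounds (default 0.1 to 10).
#' @param hill Hill slope given to every compound (default 1).
#' @param max_effect Saturating effect fraction for active compounds
#'   (default 1).
#' @return An object of class `library_spec` with derived field
#'   `plates_per_screen`.
#' @export
library_spec <- function(n_compounds = 33000,
                         frac_by_action = c(inactive = 0.98,
                                            editing_inhibitor = 0.008,
                                            editing_activator = 0.002,
                                            nluc_enzyme_inhibitor = 0.005,
                                            cytotoxic = 0.005),
                         ic50_range = c(0.1, 10),
                         hill = 1, max_effect = 1) {
  if (n_compounds < 1) rlang::abort("`n_compounds` must be >= 1.")
  if (is.null(names(frac_by_action)) ||
      !all(names(frac_by_action) %in% compound_actions))
    rlang::abort(paste0("`frac_by_action` must be named with actions among: ",
                        paste(compound_actions, collapse = ", ")))
  if (any(frac_by_action < 0) || abs(sum(frac_by_action) - 1) > 1e-8)
    rlang::abort("`frac_by_action` proportions must be non-negative and sum to 1.")
  if (length(ic50_range) != 2 || any(ic50_range <= 0) ||
      ic50_range[1] > ic50_range[2])
    rlang::abort("`ic50_range` must be two positive increasing values (uM).")
  structure(list(n_compounds = as.integer(n_compounds),
                 frac_by_action = frac_by_action,
                 ic50_range = ic50_range, hill = hill,
                 max_effect = max_effect,
                 plates_per_screen = as.integer(ceiling(n_compounds / 352))),
            class = "library_spec")
}

#' Simulate a full single-concentration reporter screen
#'
#' Generates a complete synthetic screening campaign: compounds are
#' assigned latent mechanisms and log-uniform potencies, laid out on
#' 384-well plates (columns 1-22 compounds, 23 vehicle negative
#' controls, 24 positive controls treated with an Nluc enzyme inhibitor
#' of IC50 0.08 uM at the screening dose), expected signals are computed
#' from the mechanistic reporter model and multiplicative lognormal well
#' noise is applied per channel. Deterministic given `noise$seed`.
#'
#' @param params A [reporter_params()] object.
#' @param lib A [library_spec()] object.
#' @param noise A [noise_config()] object.
#' @param dose Screening concentration in uM (default 10).
#' @return An object of class `edit_screen`: a list with
#'   * `wells` — tibble of every well (`plate_id`, `well`, `row`,
#'     `column`, `role`, `compound_id`, `dose_uM`, `ffl`, `nluc`, plus
#'     latent `expected_ffl`, `expected_nluc`);
#'   * `ground_truth` — tibble of `compound_id`, `action`, `ic50`,
#'     `hill`, `max_effect`.
#' @examples
#' scr <- simulate_screen(lib = library_spec(n_compounds = 352))
#' dplyr::count(scr$ground_truth, action)
#' @export
simulate_screen <- function(params = reporter_params(),
                            lib = library_spec(),
                            noise = noise_config(),
                            dose = 10) {
  stopifnot(inherits(params, "reporter_params"),
            inherits(lib, "library_spec"),
            inherits(noise, "noise_config"))
  if (dose < 0) rlang::abort("`dose` must be non-negative.")
  withr::with_seed(noise$seed, {
    n <- lib$n_compounds
    actions <- sample(names(lib$frac_by_action), n, replace = TRUE,
                      prob = lib$frac_by_action)
    ic50 <- exp(stats::runif(n, log(lib$ic50_range[1]),
                             log(lib$ic50_range[2])))
    ic50[actions == "inactive"] <- NA_real_
    truth <- tibble::tibble(
      compound_id = sprintf("CMPD%06d", seq_len(n)),
      action = actions, ic50 = ic50,
      hill = lib$hill, max_effect = lib$max_effect
    )

    n_plates <- lib$plates_per_screen
    layout <- default_layout()
    wells <- tidyr::expand_grid(
      plate_id = sprintf("P%03d", seq_len(n_plates)), layout)
    cmpd_idx <- which(wells$role == "compound")
    assign_idx <- cmpd_idx[seq_len(min(n, length(cmpd_idx)))]
    wells$compound_id <- NA_character_
    wells$compound_id[assign_idx] <- truth$compound_id
    # trailing unassigned compound wells on the last plate stay empty
    wells$role[setdiff(cmpd_idx, assign_idx)] <- "empty"
    wells$dose_uM <- dplyr::case_when(
      wells$role == "compound" ~ dose,
      wells$role == "pos_control" ~ dose,
      TRUE ~ 0
    )

    key <- match(wells$compound_id, truth$compound_id)
    w_action <- dplyr::case_when(
      wells$role == "compound" ~ truth$action[key],
      wells$role == "pos_control" ~ "nluc_enzyme_inhibitor",
      TRUE ~ "inactive"
    )
    w_ic50 <- ifelse(wells$role == "pos_control", 0.08, truth$ic50[key])
    w_hill <- ifelse(wells$role == "pos_control", 1, truth$hill[key])
    w_hill[is.na(w_hill)] <- 1
    w_max <- ifelse(wells$role == "pos_control", 1, truth$max_effect[key])
    w_max[is.na(w_max)] <- 1
    w_ic50[is.na(w_ic50)] <- 1  # occupancy is 0 for inactive regardless

    core <- signal_core(w_action, w_ic50, w_hill, w_max, wells$dose_uM,
                        params)
    exp_ffl <- core$ffl * (1 - noise$read_decay_ffl)^noise$read_time_h
    exp_nluc <- core$nluc * (1 - noise$read_decay_nluc)^noise$read_time_h

    if (noise$gradient_strength != 0) {
      r <- match(wells$row, plate_rows)
      grad <- 1 + noise$gradient_strength *
        ((r - 8.5) / 15 + (wells$column - 12.5) / 23)
      exp_ffl <- exp_ffl * grad
      exp_nluc <- exp_nluc * grad
    }

    nw <- nrow(wells)
    exp_ffl[wells$role == "empty"] <- NA_real_
    exp_nluc[wells$role == "empty"] <- NA_real_
    wells$expected_ffl <- exp_ffl
    wells$expected_nluc <- exp_nluc
    wells$ffl <- exp_ffl * lognormal_noise(nw, noise$cv_ffl)
    wells$nluc <- exp_nluc * lognormal_noise(nw, noise$cv_nluc)

    wells <- dplyr::select(wells, "plate_id", "well", "row", "column",
                           "role", "compound_id", "dose_uM", "ffl", "nluc",
                           "expected_ffl", "expected_nluc")
    structure(list(wells = wells, ground_truth = truth,
                   params = params, lib = lib, noise = noise, dose = dose),
              class = "edit_screen")
  })
}

# lognormal multiplicative noise with mean 1 and the requested CV
lognormal_noise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' @export
print.edit_screen <- function(x, ...) {
  cat(sprintf(
    "Simulated editing-reporter screen: %d compounds on %d plate(s) at %g uM\n",
    x$lib$n_compounds, x$lib$plates_per_screen, x$dose))
  print(dplyr::count(x$ground_truth, .data$action))
  invisible(x)
}

#' Simulate Sanger chromatogram peak heights around an editing site
#'
#' Generates per-position peak heights for A, C, G and T along a context
#' sequence. At each planted editing site (a reference A) the A peak
#' carries `(100 - edit_pct)%` and the G peak `edit_pct%` of the signal
#' amplitude — the dual A/G peak of a partially edited site — while
#' every other position shows its called base at full amplitude over a
#' small uniform background on the non-called bases. Multiplicative
#' lognormal noise is applied per peak. With zero noise,
#' [editing_pct()] recovers the planted percentage exactly.
#'
#' @param edit_pct Editing percentage(s) in \[0, 100\], one per site.
#' @param site_index 1-based position(s) of the edited adenosine(s) in
#'   `context`; must call `A` there.
#' @param context Reference base-call sequence (string over A/C/G/T).
#' @param peak_noise_cv CV of multiplicative per-peak noise (default 0).
#' @param seed Integer RNG seed (default 1).
#' @param amplitude Full peak height in arbitrary fluorescence units.
#' @param baseline Background height of non-called bases.
#' @return A tibble with columns `position`, `base` (the reference call)
#'   and peak heights `A`, `C`, `G`, `T`.
#' @examples
#' tr <- simulate_trace(39, 11, "CATTTGATCAACCAGATAAACC")
#' editing_at(tr, 11)
#' @export
simulate_trace <- function(edit_pct, site_index, context,
                           peak_noise_cv = 0, seed = 1L,
                           amplitude = 1000, baseline = 5) {
  bases <- strsplit(toupper(context), "")[[1]]
  if (!all(bases %in% c("A", "C", "G", "T")))
    rlang::abort("`context` must contain only A, C, G, T.")
  n <- length(bases)
  if (length(edit_pct) != length(site_index))
    rlang::abort("`edit_pct` and `site_index` must have equal length.")
  if (any(site_index < 1) || any(site_index > n))
    rlang::abort("`site_index` out of range for the context sequence.")
  if (any(bases[site_index] != "A"))
    rlang::abort("Every editing site must be an A in the context sequence.")
  if (any(edit_pct < 0) || any(edit_pct > 100))
    rlang::abort("`edit_pct` must lie in [0, 100].")

  heights <- matrix(baseline, nrow = n, ncol = 4,
                    dimnames = list(NULL, c("A", "C", "G", "T")))
  heights[cbind(seq_len(n), match(bases, colnames(heights)))] <- amplitude
  heights[site_index, "A"] <- amplitude * (100 - edit_pct) / 100
  heights[site_index, "G"] <- amplitude * edit_pct / 100
  heights[site_index, c("C", "T")] <- baseline

  if (peak_noise_cv > 0) {
    withr::with_seed(as.integer(seed), {
      heights <- heights * matrix(lognormal_noise(n * 4, peak_noise_cv),
                                  nrow = n)
    })
  }
  tibble::tibble(position = seq_len(n), base = bases,
                 A = heights[, "A"], C = heights[, "C"],
                 G = heights[, "G"], T = heights[, "T"])
}
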