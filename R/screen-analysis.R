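#' Nluc/FFL well ratio
#'
#' The reporter's editing readout: editing-dependent Nluc luminescence
#' over editing-independent FFL luminescence. Wells with a non-positive
#' or missing FFL read cannot be normalized (likely dead wells) and
#' return `NA` with a warning rather than a silent zero; downstream
#' functions record such wells as excluded.
#'
#' @param nluc,ffl Numeric vectors of luminescence counts.
#' @return Numeric vector of ratios, `NA` where `ffl <= 0` or missing.
#' @examples
#' well_ratio(150, 100)
#' @export
well_ratio <- function(nluc, ffl) {
  if (length(nluc) != length(ffl))
    rlang::abort("`nluc` and `ffl` must have equal length.")
  bad <- !is.finite(ffl) | ffl <= 0
  if (any(bad))
    rlang::warn(sprintf(
      "%d well(s) with non-positive or missing FFL excluded from the ratio.",
      sum(bad)))
  ifelse(bad, NA_real_, nluc / ffl)
}

#' Z'-factor screening-window statistic
#'
#' `Z' = 1 - 3 * (sd(pos) + sd(neg)) / |mean(pos) - mean(neg)|`, computed
#' with sample standard deviations on the control ratio values. Z' is at
#' most 1 (zero-variance controls), values >= 0.5 are conventionally
#' excellent and the assay accepted plates down to about 0.4. The
#' statistic is invariant under a common affine transform of both
#' control groups.
#'
#' @param neg,pos Numeric vectors of negative / positive control values
#'   (at least 2 each).
#' @return The Z'-factor (numeric scalar, <= 1).
#' @examples
#' zprime(c(1, 1.1, 0.9), c(0, 0.05, -0.05))
#' @export
zprime <- function(neg, pos) {
  neg <- neg[is.finite(neg)]; pos <- pos[is.finite(pos)]
  if (length(neg) < 2 || length(pos) < 2)
    rlang::abort("Z'-factor needs at least 2 finite values per control group.")
  mu_n <- mean(neg); mu_p <- mean(pos)
  if (mu_n == mu_p)
    rlang::abort("Z'-factor undefined: control means are equal.")
  1 - 3 * (stats::sd(pos) + stats::sd(neg)) / abs(mu_p - mu_n)
}

#' Percent inhibition relative to plate controls
#'
#' Linear rescaling of a well's ratio so the negative-control mean maps
#' to 0% inhibition and the positive-control mean to 100%:
#' `100 * (mu_n - value) / (mu_n - mu_p)`. Values below the positive
#' mean exceed 100%; values above the negative mean are negative and
#' indicate activation.
#'
#' @param value Numeric vector of well ratios.
#' @param mu_n,mu_p Negative / positive control mean ratios.
#' @return Numeric vector of percent inhibition.
#' @examples
#' pct_inhibition(c(1, 0.5, 0), mu_n = 1, mu_p = 0)
#' @export
pct_inhibition <- function(value, mu_n, mu_p) {
  if (any(mu_n == mu_p))
    rlang::abort("Percent inhibition undefined: control means are equal.")
  100 * (mu_n - value) / (mu_n - mu_p)
}

#' Percent inhibition of the FFL (viability) channel
#'
#' The cytotoxicity readout: `100 * (1 - ffl / mu_n_ffl)`, normalized to
#' the negative control only, since the positive control inhibits the
#' Nluc enzyme without altering FFL.
#'
#' @param ffl Numeric vector of FFL counts.
#' @param mu_n_ffl Mean FFL of the plate's negative controls (> 0).
#' @return Numeric vector of FFL percent inhibition (negative values
#'   mean FFL above the control mean).
#' @examples
#' ffl_inhibition(c(60, 100, 120), mu_n_ffl = 100)
#' @export
ffl_inhibition <- function(ffl, mu_n_ffl) {
  if (any(!is.finite(mu_n_ffl)) || any(mu_n_ffl <= 0))
    rlang::abort("`mu_n_ffl` must be positive.")
  100 * (1 - ffl / mu_n_ffl)
}

#' Per-plate quality control via the Z'-factor
#'
#' Summarises each plate's control wells on the ratio channel (means and
#' sample SDs of negative and positive controls, mean negative-control
#' FFL) and computes the Z'-factor. A plate passes when
#' `zprime >= z_min`. Plates whose Z' is undefined (equal control means,
#' too few usable control wells) fail QC with the reason recorded in
#' `note` instead of aborting the run.
#'
#' @param wells Well tibble (from [read_plate_table()] or
#'   [simulate_screen()]).
#' @param z_min Minimum acceptable Z' (default 0.4, the assay's floor).
#' @return A tibble with one row per plate: `plate_id`, `n_neg`, `n_pos`,
#'   `mu_n`, `sigma_n`, `mu_p`, `sigma_p`, `mu_n_ffl`, `zprime`,
#'   `passed`, `note`.
#' @export
qc_plates <- function(wells, z_min = 0.4) {
  validate_wells(wells)
  ctrl <- dplyr::filter(wells, .data$role %in% c("neg_control", "pos_control"))
  ctrl$ratio <- suppressWarnings(well_ratio(ctrl$nluc, ctrl$ffl))
  dplyr::group_by(ctrl, .data$plate_id) |>
    dplyr::group_modify(function(d, key) {
      neg <- d$ratio[d$role == "neg_control" & is.finite(d$ratio)]
      pos <- d$ratio[d$role == "pos_control" & is.finite(d$ratio)]
      negf <- d$ffl[d$role == "neg_control" & is.finite(d$ffl)]
      z <- tryCatch(zprime(neg, pos), error = function(e) NA_real_)
      note <- if (is.na(z)) "Z' undefined (control degeneracy or < 2 wells per group)" else NA_character_
      tibble::tibble(
        n_neg = length(neg), n_pos = length(pos),
        mu_n = if (length(neg)) mean(neg) else NA_real_,
        sigma_n = if (length(neg) > 1) stats::sd(neg) else NA_real_,
        mu_p = if (length(pos)) mean(pos) else NA_real_,
        sigma_p = if (length(pos) > 1) stats::sd(pos) else NA_real_,
        mu_n_ffl = if (length(negf)) mean(negf) else NA_real_,
        zprime = z,
        passed = !is.na(z) && z >= z_min,
        note = note
      )
    }) |>
    dplyr::ungroup()
}

#' Call hits and activators with a cytotoxicity filter
#'
#' Normalizes every compound well to its own plate's control means
#' (per-plate normalization allows plates and runs to be compared),
#' applies the FFL toxicity filter and calls hits and activators:
#'
#' * `pct_inhibition` — ratio channel, 0% at the negative-control mean,
#'   100% at the positive-control mean;
#' * `toxic_flag` — FFL inhibition strictly greater than
#'   `tox_threshold` (default 40%): such compounds likely kill cells or
#'   shut down translation and are removed before hit calling;
#' * `hit_flag` — not toxic and `pct_inhibition >= hit_threshold`
#'   (default 70%);
#' * `activator_flag` — not toxic and
#'   `pct_inhibition <= activator_threshold` (default -50%; the
#'   activator cut is a configurable convention, roughly symmetric to
#'   the hit cut, as no published threshold exists).
#'
#' Plates failing QC are excluded with a message; wells with unusable
#' FFL are excluded with a recorded reason. A compound appearing on more
#' than one plate is an error (no replicate handling in the
#' single-concentration pass).
#'
#' @param wells Well tibble.
#' @param qc Optional precomputed [qc_plates()] table; computed from
#'   `wells` when `NULL`.
#' @param hit_threshold Percent inhibition at or above which a non-toxic
#'   compound is a hit.
#' @param tox_threshold FFL percent inhibition above which (strictly) a
#'   compound is flagged toxic.
#' @param activator_threshold Percent inhibition at or below which a
#'   non-toxic compound is an activator.
#' @param z_min Passed to [qc_plates()] when `qc` is `NULL`.
#' @return A tibble sorted by `compound_id` with columns `compound_id`,
#'   `plate_id`, `well`, `dose_uM`, `ratio`, `pct_inhibition`,
#'   `pct_ffl_inhibition`, `toxic_flag`, `hit_flag`, `activator_flag`,
#'   `excluded`, `exclude_reason`.
#' @export
call_hits <- function(wells, qc = NULL, hit_threshold = 70,
                      tox_threshold = 40, activator_threshold = -50,
                      z_min = 0.4) {
  validate_wells(wells)
  if (is.null(qc)) qc <- qc_plates(wells, z_min = z_min)
  failed <- qc$plate_id[!qc$passed]
  if (length(failed) > 0) {
    message(sprintf("Excluding %d plate(s) failing QC: %s",
                    length(failed), paste(failed, collapse = ", ")))
  }
  cmpd <- dplyr::filter(wells, .data$role == "compound",
                        !.data$plate_id %in% failed)
  dup <- cmpd$compound_id[duplicated(cmpd$compound_id)]
  if (length(dup) > 0) {
    rlang::abort(paste0(
      "Compound(s) present in more than one well (no replicate handling): ",
      paste(utils::head(unique(dup), 5), collapse = ", ")))
  }
  cmpd <- dplyr::left_join(
    cmpd,
    dplyr::select(qc, "plate_id", "mu_n", "mu_p", "mu_n_ffl"),
    by = "plate_id")
  cmpd$ratio <- suppressWarnings(well_ratio(cmpd$nluc, cmpd$ffl))
  excluded <- is.na(cmpd$ratio)
  res <- dplyr::mutate(
    cmpd,
    pct_inhibition = ifelse(excluded, NA_real_,
                            pct_inhibition(.data$ratio, .data$mu_n, .data$mu_p)),
    pct_ffl_inhibition = ifelse(excluded, NA_real_,
                                ffl_inhibition(.data$ffl, .data$mu_n_ffl)),
    toxic_flag = !excluded & .data$pct_ffl_inhibition > tox_threshold,
    hit_flag = !excluded & !.data$toxic_flag &
      .data$pct_inhibition >= hit_threshold,
    activator_flag = !excluded & !.data$toxic_flag &
      .data$pct_inhibition <= activator_threshold,
    excluded = excluded,
    exclude_reason = ifelse(excluded, "non-positive or missing FFL",
                            NA_character_)
  )
  dplyr::select(res, "compound_id", "plate_id", "well", "dose_uM", "ratio",
                "pct_inhibition", "pct_ffl_inhibition", "toxic_flag",
                "hit_flag", "activator_flag", "excluded",
                "exclude_reason") |>
    dplyr::arrange(.data$compound_id)
}

#' Primary hit rate
#'
#' `100 * n_active / n_screened`, reported to one decimal place — e.g.
#' 300 actives out of 33000 screened compounds is a 0.9% primary hit
#' rate.
#'
#' @param n_active Number of compounds passing the activity threshold.
#' @param n_screened Number of compounds screened (> 0).
#' @return Percent hit rate rounded to one decimal.
#' @examples
#' hit_rate(300, 33000)
#' @export
hit_rate <- function(n_active, n_screened) {
  if (any(n_screened <= 0)) rlang::abort("`n_screened` must be positive.")
  if (any(n_active < 0) || any(n_active > n_screened))
    rlang::abort("`n_active` must lie in [0, n_screened].")
  round(100 * n_active / n_screened, 1)
}

#' Run the full screening analysis
#'
#' Convenience pipeline: per-plate QC, per-plate control normalization,
#' toxicity filtering and hit/activator calling, returning everything a
#' screening report needs in one object.
#'
#' @inheritParams call_hits
#' @return An object of class `screen_result` with elements `qc`
#'   ([qc_plates()] table), `results` ([call_hits()] table), `hits`,
#'   `activators` (subsets of `results`) and `thresholds`. Has
#'   [generics::glance()], [generics::tidy()] and
#'   [ggplot2::autoplot()] methods.
#' @examples
#' scr <- simulate_screen(lib = library_spec(n_compounds = 704))
#' res <- analyze_screen(scr$wells)
#' glance(res)
#' @export
analyze_screen <- function(wells, hit_threshold = 70, tox_threshold = 40,
                           activator_threshold = -50, z_min = 0.4) {
  qc <- qc_plates(wells, z_min = z_min)
  results <- call_hits(wells, qc = qc, hit_threshold = hit_threshold,
                       tox_threshold = tox_threshold,
                       activator_threshold = activator_threshold)
  structure(list(
    qc = qc,
    results = results,
    hits = dplyr::filter(results, .data$hit_flag),
    activators = dplyr::filter(results, .data$activator_flag),
    thresholds = list(hit_threshold = hit_threshold,
                      tox_threshold = tox_threshold,
                      activator_threshold = activator_threshold,
                      z_min = z_min)
  ), class = "screen_result")
}

#' @export
print.screen_result <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    paste0("Editing-reporter screen: %d compounds on %d plate(s) ",
           "(%d passed QC, mean Z' %.2f)\n"),
    g$n_screened, g$n_plates, g$n_plates_passed, g$mean_zprime))
  cat(sprintf("  toxic (FFL filter > %g%%): %d\n",
              x$thresholds$tox_threshold, g$n_toxic))
  cat(sprintf("  hits (>= %g%% inhibition): %d (hit rate %.1f%%)\n",
              x$thresholds$hit_threshold, g$n_hits, g$hit_rate_pct))
  cat(sprintf("  activators (<= %g%%): %d\n",
              x$thresholds$activator_threshold, g$n_activators))
  invisible(x)
}

#' @rdname analyze_screen
#' @param x A `screen_result`.
#' @param ... Unused.
#' @export
glance.screen_result <- function(x, ...) {
  r <- x$results
  n_screened <- sum(!r$excluded)
  tibble::tibble(
    n_plates = nrow(x$qc),
    n_plates_passed = sum(x$qc$passed),
    mean_zprime = mean(x$qc$zprime, na.rm = TRUE),
    n_screened = n_screened,
    n_excluded_wells = sum(r$excluded),
    n_toxic = sum(r$toxic_flag, na.rm = TRUE),
    n_hits = sum(r$hit_flag, na.rm = TRUE),
    n_activators = sum(r$activator_flag, na.rm = TRUE),
    hit_rate_pct = hit_rate(sum(r$hit_flag, na.rm = TRUE), n_screened)
  )
}

#' @rdname analyze_screen
#' @export
tidy.screen_result <- function(x, ...) x$results

#' Write screening outputs to disk
#'
#' Emits `plate_qc.csv`, `compound_results.csv`, `hits.csv` and a JSON
#' run summary `summary.json` into `dir`.
#'
#' @param x A `screen_result` from [analyze_screen()].
#' @param dir Output directory (created if needed).
#' @return The paths written, invisibly.
#' @export
write_screen_results <- function(x, dir) {
  stopifnot(inherits(x, "screen_result"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("plate_qc.csv", "compound_results.csv",
                            "hits.csv", "summary.json"))
  readr::write_csv(x$qc, paths[1], progress = FALSE)
  readr::write_csv(x$results, paths[2], progress = FALSE)
  readr::write_csv(x$hits, paths[3], progress = FALSE)
  jsonlite::write_json(c(as.list(glance(x)), x$thresholds), paths[4],
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(paths)
}
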