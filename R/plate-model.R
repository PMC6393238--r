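#' Parse 384-well addresses
#'
#' Validates and decomposes well addresses of the form letter + column
#' ("A1" .. "P24", no zero padding). Rows span A-P, columns 1-24.
#'
#' @param well Character vector of well addresses.
#' @return A tibble with columns `well`, `row` (character) and
#'   `column` (integer).
#' @examples
#' parse_well(c("A1", "P24"))
#' @export
parse_well <- function(well) {
  well <- as.character(well)
  ok <- grepl("^[A-P]([1-9]|1[0-9]|2[0-4])$", well)
  if (any(!ok)) {
    rlang::abort(paste0(
      "Malformed well address(es): ",
      paste(unique(well[!ok]), collapse = ", "),
      ". Expected letter A-P followed by column 1-24 (e.g. 'A1', 'P24')."
    ))
  }
  tibble::tibble(
    well = well,
    row = substr(well, 1, 1),
    column = as.integer(substr(well, 2, nchar(well)))
  )
}

plate_rows <- LETTERS[1:16]

#' Default 384-well screening layout
#'
#' The standard single-concentration screening layout: compounds occupy
#' columns 1-22 (352 wells), the vehicle negative control (0.1% DMSO)
#' fills column 23 and the positive control (10 uM Nluc enzyme inhibitor)
#' fills column 24, 16 wells each.
#'
#' @return A tibble with 384 rows and columns `well`, `row`, `column`,
#'   `role` (one of `"compound"`, `"neg_control"`, `"pos_control"`).
#' @examples
#' table(default_layout()$role)
#' @export
default_layout <- function() {
  grid <- tidyr::expand_grid(row = plate_rows, column = 1:24)
  dplyr::mutate(
    grid,
    well = paste0(.data$row, .data$column),
    role = dplyr::case_when(
      .data$column <= 22 ~ "compound",
      .data$column == 23 ~ "neg_control",
      TRUE ~ "pos_control"
    )
  ) |>
    dplyr::select("well", "row", "column", "role")
}

well_roles <- c("compound", "neg_control", "pos_control", "empty")

validate_wells <- function(wells, require_signals = TRUE) {
  needed <- c("plate_id", "well", "role", "compound_id", "dose_uM")
  if (require_signals) needed <- c(needed, "ffl", "nluc")
  missing <- setdiff(needed, names(wells))
  if (length(missing) > 0) {
    rlang::abort(paste0("Well table lacks column(s): ",
                        paste(missing, collapse = ", ")))
  }
  bad_role <- setdiff(unique(wells$role), well_roles)
  if (length(bad_role) > 0) {
    rlang::abort(paste0("Unknown well role(s): ", paste(bad_role, collapse = ", ")))
  }
  no_id <- wells$role == "compound" & (is.na(wells$compound_id) | wells$compound_id == "")
  if (any(no_id)) {
    rlang::abort(paste0(sum(no_id), " compound well(s) lack a compound_id."))
  }
  if (require_signals) {
    vals <- c(wells$ffl[wells$role != "empty"], wells$nluc[wells$role != "empty"])
    if (any(!is.finite(vals)) || any(vals < 0)) {
      rlang::abort("Luminescence counts must be finite and non-negative.")
    }
  }
  invisible(wells)
}

#' Read a dual-channel plate measurement table and plate map
#'
#' Reads the two universal plate-reader export files into one tidy well
#' table. The measurement CSV holds one row per (plate, well, channel)
#' with channels exactly `FFL` and `Nluc`; the plate-map CSV assigns a
#' role, compound and dose to every well. A well present in the map but
#' missing either channel value is marked `role = "empty"` (with a
#' warning) rather than failing the plate, so one bad read does not void
#' the other 383 wells.
#'
#' @param measurements_path CSV with columns `plate_id, well, channel, value`.
#' @param platemap_path CSV with columns
#'   `plate_id, well, role, compound_id, dose_uM`.
#' @return A tibble with one row per mapped well and columns `plate_id`,
#'   `well`, `row`, `column`, `role`, `compound_id`, `dose_uM`, `ffl`,
#'   `nluc`.
#' @seealso [write_plate_table()], [default_layout()]
#' @export
read_plate_table <- function(measurements_path, platemap_path) {
  meas <- readr::read_csv(measurements_path, show_col_types = FALSE,
                          progress = FALSE)
  pmap <- readr::read_csv(platemap_path, show_col_types = FALSE,
                          progress = FALSE)
  need_m <- c("plate_id", "well", "channel", "value")
  if (!all(need_m %in% names(meas))) {
    rlang::abort(paste0("Measurement table must have columns: ",
                        paste(need_m, collapse = ", ")))
  }
  need_p <- c("plate_id", "well", "role", "compound_id", "dose_uM")
  if (!all(need_p %in% names(pmap))) {
    rlang::abort(paste0("Plate map must have columns: ",
                        paste(need_p, collapse = ", ")))
  }
  meas$plate_id <- as.character(meas$plate_id)
  pmap$plate_id <- as.character(pmap$plate_id)
  pmap$compound_id <- as.character(pmap$compound_id)

  bad_chan <- setdiff(unique(meas$channel), c("FFL", "Nluc"))
  if (length(bad_chan) > 0) {
    rlang::abort(paste0("Unknown channel label(s): ",
                        paste(bad_chan, collapse = ", "),
                        ". Expected 'FFL' and 'Nluc'."))
  }
  dup <- duplicated(meas[, c("plate_id", "well", "channel")])
  if (any(dup)) {
    i <- which(dup)[1]
    rlang::abort(sprintf(
      "Duplicate measurement row(s): first duplicate at row %d (plate %s, well %s, channel %s).",
      i, meas$plate_id[i], meas$well[i], meas$channel[i]))
  }
  parse_well(unique(c(meas$well, pmap$well)))  # address validation

  wide <- tidyr::pivot_wider(meas, names_from = "channel",
                             values_from = "value")
  if (!"FFL" %in% names(wide)) wide$FFL <- NA_real_
  if (!"Nluc" %in% names(wide)) wide$Nluc <- NA_real_

  stray <- dplyr::anti_join(wide, pmap, by = c("plate_id", "well"))
  if (nrow(stray) > 0) {
    rlang::abort(sprintf(
      "%d measured well(s) absent from the plate map (e.g. plate %s well %s).",
      nrow(stray), stray$plate_id[1], stray$well[1]))
  }

  wells <- dplyr::left_join(pmap, wide, by = c("plate_id", "well")) |>
    dplyr::rename(ffl = "FFL", nluc = "Nluc")
  incomplete <- is.na(wells$ffl) | is.na(wells$nluc)
  if (any(incomplete)) {
    rlang::warn(sprintf(
      "%d well(s) missing a channel value were marked empty: %s",
      sum(incomplete),
      paste(utils::head(paste(wells$plate_id[incomplete],
                              wells$well[incomplete]), 10),
            collapse = ", ")))
    wells$role[incomplete] <- "empty"
  }
  addr <- parse_well(wells$well)
  wells <- dplyr::mutate(wells, row = addr$row, column = addr$column) |>
    dplyr::select("plate_id", "well", "row", "column", "role",
                  "compound_id", "dose_uM", "ffl", "nluc")
  validate_wells(wells)
  wells
}

#' Write a well table back to measurement and plate-map CSVs
#'
#' Inverse of [read_plate_table()]: emits the long measurement table
#' (one row per well and channel; wells with a missing channel value are
#' omitted from the measurement file) and the plate map.
#'
#' @param wells Well tibble as returned by [read_plate_table()] or
#'   [simulate_screen()].
#' @inheritParams read_plate_table
#' @return `wells`, invisibly.
#' @export
write_plate_table <- function(wells, measurements_path, platemap_path) {
  validate_wells(wells, require_signals = FALSE)
  meas <- dplyr::select(wells, "plate_id", "well", FFL = "ffl",
                        Nluc = "nluc") |>
    tidyr::pivot_longer(c("FFL", "Nluc"), names_to = "channel",
                        values_to = "value") |>
    dplyr::filter(!is.na(.data$value))
  readr::write_csv(meas, measurements_path, progress = FALSE)
  pmap <- dplyr::select(wells, "plate_id", "well", "role", "compound_id",
                        "dose_uM")
  readr::write_csv(pmap, platemap_path, progress = FALSE)
  invisible(wells)
}

#' Final compound concentration of an acoustic-dispense dilution chain
#'
#' Follows compound mass through the two-step dilution used in acoustic
#' screening: a nanolitre volume of DMSO stock is dispensed into an
#' intermediate diluent volume, then part of the intermediate solution is
#' transferred onto the assay volume. The screen's protocol (60 nl of
#' 10 mM stock into 20 ul medium, 10 ul transferred onto 20 ul of cells)
#' yields 9.97 uM compound and 0.0997% DMSO, i.e. the nominal 10 uM /
#' 0.1% conditions.
#'
#' Volumes are converted to litres internally; the result is homogeneous
#' of degree 1 in `stock_conc_mM` and invariant under a common rescaling
#' of all volumes.
#'
#' @param stock_conc_mM Stock concentration in mM (compound in pure DMSO).
#' @param dispensed_vol_nl Acoustically dispensed stock volume in nl
#'   (0 allowed: nothing dispensed).
#' @param diluent_vol_ul Intermediate diluent volume in ul.
#' @param transfer_vol_ul Volume of intermediate solution transferred, ul.
#' @param recipient_vol_ul Assay volume already in the destination well, ul
#'   (0 means no further dilution).
#' @return A tibble with columns `compound_uM` and `dmso_pct` (% v/v).
#' @examples
#' final_concentration(10, 60, 20, 10, 20)
#' @export
final_concentration <- function(stock_conc_mM, dispensed_vol_nl,
                                diluent_vol_ul, transfer_vol_ul,
                                recipient_vol_ul) {
  args <- vctrs_recycle(stock_conc_mM, dispensed_vol_nl, diluent_vol_ul,
                        transfer_vol_ul, recipient_vol_ul)
  stock_conc_mM <- args[[1]]; dispensed_vol_nl <- args[[2]]
  diluent_vol_ul <- args[[3]]; transfer_vol_ul <- args[[4]]
  recipient_vol_ul <- args[[5]]
  if (any(stock_conc_mM < 0) || any(dispensed_vol_nl < 0) ||
      any(diluent_vol_ul < 0) || any(transfer_vol_ul < 0) ||
      any(recipient_vol_ul < 0)) {
    rlang::abort("Concentrations and volumes must be non-negative.")
  }
  v_disp <- dispensed_vol_nl * 1e-9
  v_dil <- diluent_vol_ul * 1e-6
  v_tr <- transfer_vol_ul * 1e-6
  v_rec <- recipient_vol_ul * 1e-6
  if (any(v_disp + v_dil <= 0) || any(v_tr + v_rec <= 0)) {
    rlang::abort("Total volume is zero at one of the dilution steps.")
  }
  stock_uM <- stock_conc_mM * 1000
  frac1 <- v_disp / (v_disp + v_dil)
  frac2 <- v_tr / (v_tr + v_rec)
  tibble::tibble(
    compound_uM = stock_uM * frac1 * frac2,
    dmso_pct = 100 * frac1 * frac2
  )
}

# common-length recycling for scalar-or-vector arguments
vctrs_recycle <- function(...) {
  args <- list(...)
  n <- max(lengths(args))
  lapply(args, function(x) {
    if (length(x) == n) x
    else if (length(x) == 1) rep(x, n)
    else rlang::abort("Arguments must be length 1 or a common length.")
  })
}
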