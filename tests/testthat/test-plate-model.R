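test_that("default layout assigns the control columns and 352 compound wells", {
  lay <- default_layout()
  expect_equal(nrow(lay), 384)
  expect_equal(anyDuplicated(lay$well), 0)
  expect_equal(sum(lay$role == "compound"), 352)
  expect_equal(sum(lay$role == "neg_control"), 16)
  expect_equal(sum(lay$role == "pos_control"), 16)
  expect_equal(lay$role[lay$well == "C23"], "neg_control")
  expect_equal(lay$role[lay$well == "A24"], "pos_control")
  expect_equal(lay$role[lay$well == "A1"], "compound")
  # exactly 16 wells in each control column
  expect_true(all(table(lay$column[lay$role != "compound"]) == 16))
})

test_that("well addresses validate and parse", {
  p <- parse_well(c("A1", "P24", "H12"))
  expect_equal(p$row, c("A", "P", "H"))
  expect_equal(p$column, c(1L, 24L, 12L))
  expect_error(parse_well("Q1"), "Malformed")
  expect_error(parse_well("A25"), "Malformed")
  expect_error(parse_well("A01"), "Malformed")
})

test_that("plate tables round-trip through CSV up to row order", {
  scr <- small_screen(n = 352)
  paths <- write_fixture_csvs(scr$wells)
  back <- read_plate_table(paths$measurements, paths$platemap)
  orig <- dplyr::arrange(scr$wells[, names(back)], plate_id, well)
  back <- dplyr::arrange(back, plate_id, well)
  expect_equal(as.data.frame(back), as.data.frame(orig), tolerance = 1e-12)
  expect_equal(sum(back$role == "compound"), 352)
  expect_equal(sum(back$role == "neg_control"), 16)
  expect_equal(sum(back$role == "pos_control"), 16)
})

test_that("reader rejects malformed input and flags missing channels", {
  scr <- small_screen(n = 352)
  dir <- withr::local_tempdir()
  paths <- write_fixture_csvs(scr$wells, dir)

  m <- readr::read_csv(paths$measurements, show_col_types = FALSE)

  # one well missing its Nluc read -> marked empty with a warning
  drop <- file.path(dir, "drop.csv")
  readr::write_csv(m[!(m$well == "B2" & m$channel == "Nluc"), ], drop)
  expect_warning(wells <- read_plate_table(drop, paths$platemap),
                 "marked empty")
  expect_equal(wells$role[wells$well == "B2"], "empty")
  expect_equal(sum(wells$role == "empty"), 1)

  # duplicated (plate, well, channel) row -> error naming the row
  dup <- file.path(dir, "dup.csv")
  readr::write_csv(rbind(m, m[5, ]), dup)
  expect_error(read_plate_table(dup, paths$platemap), "Duplicate")

  # unknown channel label -> error
  bad <- m; bad$channel[1] <- "Renilla"
  badp <- file.path(dir, "bad.csv")
  readr::write_csv(bad, badp)
  expect_error(read_plate_table(badp, paths$platemap), "Unknown channel")

  # malformed well address in the map -> error
  pm <- readr::read_csv(paths$platemap, show_col_types = FALSE)
  pm$well[1] <- "Q1"
  badmap <- file.path(dir, "badmap.csv")
  readr::write_csv(pm, badmap)
  expect_error(read_plate_table(paths$measurements, badmap), "Malformed")
})

test_that("dilution chain reproduces the screening protocol concentrations", {
  fc <- final_concentration(10, 60, 20, 10, 20)
  # 60 nl of 10 mM into 20 ul, 10 ul onto 20 ul -> ~9.97 uM, ~0.0997% DMSO
  expect_equal(fc$compound_uM, 10000 * (60 / 20060) / 3, tolerance = 1e-12)
  expect_equal(signif(fc$compound_uM, 2), 10)
  expect_equal(signif(fc$dmso_pct, 1), 0.1)
})

test_that("dilution arithmetic edge cases and invariances hold", {
  # nothing dispensed
  z <- final_concentration(10, 0, 20, 10, 20)
  expect_equal(z$compound_uM, 0)
  expect_equal(z$dmso_pct, 0)
  # transfer into an empty recipient leaves the concentration unchanged
  keep <- final_concentration(10, 60, 20, 10, 0)
  inter <- 10000 * 60 / 20060
  expect_equal(keep$compound_uM, inter, tolerance = 1e-12)
  # homogeneous of degree 1 in stock concentration
  f1 <- final_concentration(5, 60, 20, 10, 20)
  f2 <- final_concentration(10, 60, 20, 10, 20)
  expect_equal(2 * f1$compound_uM, f2$compound_uM, tolerance = 1e-12)
  # invariant under a common rescaling of all volumes
  f3 <- final_concentration(10, 60 * 7, 20 * 7, 10 * 7, 20 * 7)
  expect_equal(f3, f2, tolerance = 1e-12)
  # zero total volume errors
  expect_error(final_concentration(10, 0, 0, 10, 20), "zero")
})
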