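test_that("well ratio handles degenerate FFL reads as exclusions", {
  expect_equal(well_ratio(150, 100), 1.5)
  expect_equal(well_ratio(0, 100), 0)
  expect_warning(r <- well_ratio(c(10, 10), c(0, 100)), "excluded")
  expect_true(is.na(r[1]))
  expect_equal(r[2], 0.1)
})

test_that("Z'-factor matches a hand-coded oracle and its fixed points", {
  # zero-variance controls
  expect_equal(zprime(rep(1, 4), rep(0, 4)), 1)
  # constructed samples with exact moments mu_n 1 sd 0.05, mu_p 0 sd 0.05
  neg <- exact_moments(1, 0.05)
  pos <- exact_moments(0, 0.05)
  expect_equal(zprime(neg, pos), 0.7, tolerance = 1e-12)
  # random-sample equivalence with the independent oracle
  withr::with_seed(11, {
    for (i in 1:25) {
      n <- stats::rlnorm(16, 0, 0.2)
      p <- 0.01 * stats::rlnorm(16, 0, 0.2)
      expect_equal(zprime(n, p), zprime_oracle(n, p), tolerance = 1e-12)
    }
  })
  expect_error(zprime(rep(1, 4), rep(1, 4)), "equal")
  expect_error(zprime(1, c(0, 0.1)), "at least 2")
})

test_that("Z'-factor is invariant under affine transforms of both groups", {
  withr::with_seed(3, {
    neg <- stats::rnorm(16, 1, 0.05)
    pos <- stats::rnorm(16, 0.01, 0.01)
    z <- zprime(neg, pos)
    for (ab in list(c(2, 5), c(-3, 0.1), c(0.01, -7))) {
      expect_equal(zprime(ab[1] * neg + ab[2], ab[1] * pos + ab[2]), z,
                   tolerance = 1e-9)
    }
  })
})

test_that("percent inhibition has its control fixed points", {
  expect_equal(pct_inhibition(1, 1, 0), 0)
  expect_equal(pct_inhibition(0, 1, 0), 100)
  expect_equal(pct_inhibition(0.5, 1, 0), 50)
  # below the positive mean exceeds 100; above the negative mean is negative
  expect_gt(pct_inhibition(-0.1, 1, 0), 100)
  expect_lt(pct_inhibition(1.5, 1, 0), 0)
  expect_error(pct_inhibition(0.5, 1, 1), "equal")
  # invariance under common rescaling of all plate ratios
  v <- c(0.2, 0.5, 0.9)
  expect_equal(pct_inhibition(3 * v, 3 * 1, 3 * 0.01),
               pct_inhibition(v, 1, 0.01))
})

test_that("FFL inhibition is normalized to the negative control only", {
  expect_equal(ffl_inhibition(100, 100), 0)
  expect_equal(ffl_inhibition(50, 100), 50)
  expect_equal(ffl_inhibition(120, 100), -20)
  expect_error(ffl_inhibition(50, 0), "positive")
})

test_that("plate QC passes clean plates and fails degenerate ones", {
  scr <- small_screen(n = 352)
  qc <- qc_plates(scr$wells)
  expect_equal(qc$zprime, 1)
  expect_true(qc$passed)
  expect_equal(qc$n_neg, 16)
  expect_equal(qc$n_pos, 16)

  # identical control means -> Z' undefined -> recorded failure, no abort
  w <- scr$wells
  w$nluc[w$role == "pos_control"] <- w$nluc[w$role == "neg_control"]
  w$ffl[w$role == "pos_control"] <- w$ffl[w$role == "neg_control"]
  qc2 <- qc_plates(w)
  expect_true(is.na(qc2$zprime))
  expect_false(qc2$passed)
  expect_match(qc2$note, "undefined")
})

test_that("hit calling reproduces a brute-force hand fixture", {
  # 4 compounds: clear hit / sub-threshold / strong-but-toxic / activator.
  # Controls: neg ratio 1 (ffl 100), pos ratio 0.
  lay <- default_layout()
  ctrl <- lay[lay$role != "compound", ]
  ctrl$plate_id <- "P1"; ctrl$compound_id <- NA_character_; ctrl$dose_uM <- 0
  ctrl$ffl <- 100
  ctrl$nluc <- ifelse(ctrl$role == "neg_control", 100, 0)
  # tiny control jitter so Z' is defined and excellent
  ctrl$nluc[ctrl$role == "neg_control"] <-
    100 + rep(c(-1, 1), 8) * 0.5 / sqrt(2)
  cmpd <- tibble::tibble(
    plate_id = "P1",
    well = c("A1", "A2", "A3", "A4"),
    row = "A", column = 1:4,
    role = "compound",
    compound_id = c("hit80", "mid65", "tox90", "act-60"),
    dose_uM = 10,
    ffl = c(100, 100, 50, 100),          # 50% FFL inhibition on tox90
    nluc = c(20, 35, 5, 160)             # ratios 0.2 0.35 0.1 1.6
  )
  wells <- dplyr::bind_rows(ctrl, cmpd)
  res <- call_hits(wells)
  res <- res[match(cmpd$compound_id, res$compound_id), ]
  expect_equal(res$pct_inhibition, c(80, 65, 90, -60), tolerance = 1e-9)
  expect_equal(res$toxic_flag, c(FALSE, FALSE, TRUE, FALSE))
  expect_equal(res$hit_flag, c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(res$activator_flag, c(FALSE, FALSE, FALSE, TRUE))
})

test_that("threshold comparisons are >= for hits and strictly > for toxicity", {
  neg <- exact_moments(1, 0.001)
  lay <- default_layout()
  ctrl <- lay[lay$role != "compound", ][1:4, ]
  ctrl$plate_id <- "P1"; ctrl$compound_id <- NA_character_; ctrl$dose_uM <- 0
  ctrl$role <- rep(c("neg_control", "pos_control"), each = 2)
  ctrl$ffl <- 100
  ctrl$nluc <- c(100 * neg, 0, 1e-9)
  cmpd <- tibble::tibble(
    plate_id = "P1", well = c("A1", "A2"), row = "A", column = 1:2,
    role = "compound", compound_id = c("at70", "at40tox"), dose_uM = 10,
    ffl = c(100, 60), nluc = c(30, 18)   # exactly 70% inh; exactly 40% FFL inh
  )
  res <- call_hits(dplyr::bind_rows(ctrl, cmpd))
  res <- res[match(cmpd$compound_id, res$compound_id), ]
  expect_equal(res$pct_inhibition[1], 70, tolerance = 1e-6)
  expect_true(res$hit_flag[1])                   # >= 70 is a hit
  expect_equal(res$pct_ffl_inhibition[2], 40, tolerance = 1e-9)
  expect_false(res$toxic_flag[2])                # exactly 40 is not toxic
  expect_true(res$hit_flag[2])
})

test_that("hit calling is invariant to well and plate permutation", {
  scr <- small_screen(
    n = 704, noise = noise_config(cv_ffl = 0.05, cv_nluc = 0.05, seed = 5),
    frac = c(inactive = 0.9, editing_inhibitor = 0.04,
             editing_activator = 0.02, nluc_enzyme_inhibitor = 0.02,
             cytotoxic = 0.02))
  res1 <- call_hits(scr$wells)
  withr::with_seed(99, {
    res2 <- call_hits(scr$wells[sample.int(nrow(scr$wells)), ])
  })
  expect_equal(res1, res2)
})

test_that("a noiseless planted inhibitor is the unique hit", {
  scr <- small_screen(n = 352)
  truth <- scr$ground_truth
  w <- scr$wells
  # plant one saturating editing inhibitor by overwriting its well signals
  target <- truth$compound_id[10]
  eff <- expected_signals(reporter_params(),
                          compound_effect("editing_inhibitor", ic50 = 0.01),
                          dose = 10)
  i <- which(w$compound_id == target)
  w$ffl[i] <- eff$ffl; w$nluc[i] <- eff$nluc
  res <- call_hits(w)
  expect_equal(res$compound_id[res$hit_flag], target)
  # all wells equal to the negative controls -> zero hits
  res0 <- call_hits(scr$wells)
  expect_equal(sum(res0$hit_flag), 0)
})

test_that("compounds appearing on multiple plates are rejected", {
  scr <- small_screen(n = 704)  # 2 plates
  w <- scr$wells
  ids <- w$compound_id
  first <- which(w$role == "compound")[1]
  dup_target <- which(w$plate_id == "P002" & w$role == "compound")[1]
  w$compound_id[dup_target] <- w$compound_id[first]
  expect_error(call_hits(w), "more than one well")
})

test_that("hit rate arithmetic matches the printed campaign numbers", {
  expect_equal(hit_rate(300, 33000), 0.9)
  expect_equal(hit_rate(0, 500), 0)
  expect_equal(hit_rate(500, 500), 100)
  expect_error(hit_rate(1, 0), "positive")
  expect_error(hit_rate(-1, 10), "n_active")
})

test_that("analyze_screen wires QC, calling and summaries together", {
  scr <- small_screen(
    n = 704, noise = noise_config(cv_ffl = 0.05, cv_nluc = 0.05, seed = 2),
    frac = c(inactive = 0.95, editing_inhibitor = 0.03,
             editing_activator = 0, nluc_enzyme_inhibitor = 0.01,
             cytotoxic = 0.01), ic50_range = c(0.01, 0.1))
  res <- analyze_screen(scr$wells)
  g <- glance(res)
  expect_equal(g$n_plates, 2)
  expect_equal(g$n_plates_passed, 2)
  expect_equal(g$n_screened, 704)
  expect_equal(g$n_hits, nrow(res$hits))
  expect_equal(tidy(res), res$results)
  dir <- withr::local_tempdir()
  paths <- write_screen_results(res, dir)
  expect_true(all(file.exists(paths)))
  qc_back <- readr::read_csv(paths[1], show_col_types = FALSE)
  expect_equal(nrow(qc_back), 2)
})
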