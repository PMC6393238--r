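# Shared fixture builders. Everything is generated in code; no stored data.

# A small single-plate screen with controllable mechanism mix and noise.
small_screen <- function(n = 352, noise = noise_config(cv_ffl = 0, cv_nluc = 0),
                         frac = c(inactive = 1, editing_inhibitor = 0,
                                  editing_activator = 0,
                                  nluc_enzyme_inhibitor = 0, cytotoxic = 0),
                         ic50_range = c(0.1, 10), ...) {
  simulate_screen(lib = library_spec(n_compounds = n, frac_by_action = frac,
                                     ic50_range = ic50_range),
                  noise = noise, ...)
}

# Write a screen's wells to measurement/plate-map CSVs; returns the paths.
write_fixture_csvs <- function(wells, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  m <- file.path(dir, "measurements.csv")
  p <- file.path(dir, "platemap.csv")
  write_plate_table(wells, m, p)
  list(measurements = m, platemap = p)
}

# Hand-coded Z'-factor oracle, independent of the implementation.
zprime_oracle <- function(neg, pos) {
  1 - (3 * stats::sd(pos) + 3 * stats::sd(neg)) / abs(mean(pos) - mean(neg))
}

# Two-point samples with exact mean m and sample sd s.
exact_moments <- function(m, s, n = 2) m + c(-1, 1) * s / sqrt(2)

# reverse complement, independent of the package internals
rev_comp_str <- function(x) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", x), "")[[1]]), collapse = "")
}
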