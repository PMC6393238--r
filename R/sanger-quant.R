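#' Editing percentage from chromatogram peak heights
#'
#' A-to-I editing is read as G in Sanger sequencing of the cDNA, so a
#' partially edited adenosine shows a dual A/G peak. The editing level
#' is `100 * G / (A + G)` computed on peak heights; C and T heights are
#' ignored. Scaling all heights by a constant leaves the result
#' unchanged. Heights are used as exported (no baseline subtraction),
#' which can diverge slightly from chromatogram viewers that
#' background-correct.
#'
#' @param a,g Peak heights of A and G at the site (>= 0), vectorized.
#' @return Editing percentage(s) in \[0, 100\].
#' @examples
#' editing_pct(61, 39)
#' @export
editing_pct <- function(a, g) {
  if (length(a) != length(g))
    rlang::abort("`a` and `g` must have equal length.")
  if (any(!is.finite(a)) || any(!is.finite(g)) || any(a < 0) || any(g < 0))
    rlang::abort("Peak heights must be finite and non-negative.")
  if (any(a + g <= 0))
    rlang::abort("A + G peak height is zero: not an A/G position.")
  100 * g / (a + g)
}

#' Editing percentage at a trace position
#'
#' @param trace Trace tibble (`position`, `base`, `A`, `C`, `G`, `T`)
#'   from [simulate_trace()] or [read_trace_csv()].
#' @param position 1-based position(s) in the trace.
#' @return Editing percentage(s).
#' @export
editing_at <- function(trace, position) {
  idx <- match(position, trace$position)
  if (any(is.na(idx)))
    rlang::abort("Position(s) not present in the trace.")
  editing_pct(trace$A[idx], trace$G[idx])
}

#' Read a per-site peak-height table
#'
#' Plain-text alternative to binary trace files: a CSV with columns
#' `position, A, C, G, T` (optionally `sample` and `base`; the called
#' base is inferred as the tallest peak when absent).
#'
#' @param path CSV path.
#' @return A trace tibble (`position`, `base`, `A`, `C`, `G`, `T`, and
#'   `sample` if present).
#' @export
read_trace_csv <- function(path) {
  tr <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("position", "A", "C", "G", "T")
  if (!all(need %in% names(tr)))
    rlang::abort(paste0("Trace CSV must have columns: ",
                        paste(need, collapse = ", ")))
  if (!"base" %in% names(tr)) {
    tr$base <- c("A", "C", "G", "T")[
      max.col(as.matrix(tr[, c("A", "C", "G", "T")]), ties.method = "first")]
  }
  cols <- intersect(c("sample", "position", "base", "A", "C", "G", "T"),
                    names(tr))
  tibble::as_tibble(tr[, cols])
}

rev_comp <- function(x) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", toupper(x)), "")[[1]]),
        collapse = "")
}

#' Locate an editing site by anchor sequence
#'
#' Finds a unique anchor subsequence (e.g. a PCR primer) in the
#' base-call sequence and returns the 1-based position `anchor start +
#' offset`. If the anchor instead matches the reverse complement of the
#' call sequence, the coordinate is flipped accordingly (site at
#' `anchor-end - offset`). Zero or multiple matches — counting both
#' strands — are an error naming the count, since the site would be
#' ambiguous.
#'
#' @param basecalls Base-call sequence (string over A/C/G/T).
#' @param anchor Anchor sequence, at least 10 nt.
#' @param offset Signed distance (nt) from the anchor start to the site.
#' @return 1-based site position in `basecalls`.
#' @examples
#' locate_site("CCCCATTTGATCACCAGATAAACCCC", "CATTTGATCACCAGATAAACC", 12)
#' @export
locate_site <- function(basecalls, anchor, offset = 0L) {
  basecalls <- toupper(basecalls); anchor <- toupper(anchor)
  if (nchar(anchor) < 10)
    rlang::abort("`anchor` must be at least 10 nt.")
  fwd <- gregexpr(anchor, basecalls, fixed = TRUE)[[1]]
  fwd <- fwd[fwd > 0]
  rc <- gregexpr(rev_comp(anchor), basecalls, fixed = TRUE)[[1]]
  rc <- rc[rc > 0]
  n_match <- length(fwd) + length(rc)
  if (n_match != 1)
    rlang::abort(sprintf(
      "Anchor matched %d time(s) in the base calls; exactly 1 required.",
      n_match))
  pos <- if (length(fwd) == 1) {
    fwd + offset
  } else {
    # anchor lies on the minus strand: walk the offset in the anchor's
    # own 5'->3' direction, i.e. leftwards on the call sequence
    (rc + nchar(anchor) - 1L) - offset
  }
  if (pos < 1 || pos > nchar(basecalls))
    rlang::abort("Located site falls outside the base-call sequence.")
  as.integer(pos)
}

#' Scan flanking adenosines for off-target editing
#'
#' ADARs frequently edit additional adenosines near the intended site.
#' This scans every reference-A position within `center +/- window`
#' (truncated silently at the trace ends), computes `editing_pct` at
#' each, and reports the calls at or above `min_pct`; positions below
#' the cutoff are suppressed from the report but counted in the
#' attached summary (attributes `n_scanned` and `n_suppressed`).
#'
#' @param trace Trace tibble.
#' @param center 1-based position of the primary editing site.
#' @param window Half-width of the scan in nt (0 scans only the center).
#' @param min_pct Minimum editing percentage to report (default 5).
#' @return A tibble (`position`, `offset`, `editing_pct`) of reported
#'   calls, ordered by position, with attributes `n_scanned` and
#'   `n_suppressed`.
#' @export
offtarget_scan <- function(trace, center, window, min_pct = 5) {
  if (!center %in% trace$position)
    rlang::abort("`center` is out of range for the trace.")
  if (window < 0) rlang::abort("`window` must be non-negative.")
  lo <- max(min(trace$position), center - window)
  hi <- min(max(trace$position), center + window)
  sub <- dplyr::filter(trace, .data$position >= lo, .data$position <= hi,
                       .data$base == "A")
  calls <- tibble::tibble(
    position = sub$position,
    offset = sub$position - center,
    editing_pct = editing_pct(sub$A, sub$G)
  )
  out <- dplyr::filter(calls, .data$editing_pct >= min_pct) |>
    dplyr::arrange(.data$position)
  attr(out, "n_scanned") <- nrow(calls)
  attr(out, "n_suppressed") <- nrow(calls) - nrow(out)
  out
}
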