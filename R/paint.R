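#' Paint a transconjugant genome by parental origin
#'
#' The full painting pipeline: tile the transconjugant into nonoverlapping
#' windows (default 500 bp), score each window's identity to both parents,
#' assign origins with the tie-inheritance rule, concatenate same-origin
#' windows into segments, and summarise. In `"aligned"` mode (the default,
#' for collinear genomes sharing one coordinate frame) identity is exact
#' per-position identity; in `"mapping"` mode each window is located in each
#' parent by k-mer seeding and scored by edit distance, for parents that are
#' not perfectly collinear.
#'
#' @param transconjugant,recipient,donor One-row genome tibbles (or bare
#'   sequence strings). In aligned mode all three must have equal length.
#' @param window_bp Window width W in bp (default 500).
#' @param min_identity Minimum identity tau for assignment (default 0.9).
#' @param mode `"aligned"` or `"mapping"`.
#' @param background Origin assumed when the first windows are ambiguous
#'   (default `"recipient"`).
#' @param k Seed k-mer length for mapping mode (default 16).
#' @return An object of class `dct_paint` with elements `windows`
#'   (classified window calls), `segments`, `report` (one-row tibble) and
#'   `config`. [tidy()][generics::tidy] returns the window calls,
#'   [glance()][generics::glance] the report row, and
#'   [autoplot()][ggplot2::autoplot] draws the mosaic.
#' @examples
#' pair <- generate_parent_pair(50000, 0.01, seed = 1)
#' cross <- simulate_transconjugant(pair$recipient, pair$donor,
#'   n_segments = 2, segment_lengths = c(3000, 5000),
#'   target_donor_fraction = NULL, seed = 2)
#' p <- paint_genome(cross$transconjugant, pair$recipient, pair$donor)
#' glance(p)
#' @export
paint_genome <- function(transconjugant, recipient, donor,
                         window_bp = 500, min_identity = 0.9,
                         mode = c("aligned", "mapping"),
                         background = c("recipient", "donor"),
                         k = 16) {
  mode <- match.arg(mode)
  background <- match.arg(background)
  tc_seq <- genome_seq(transconjugant)
  windows <- tile_windows(nchar(tc_seq), window_bp)
  if (mode == "aligned") {
    scores <- score_windows_aligned(transconjugant, recipient, donor, windows)
  } else {
    rs <- genome_seq(recipient); ds <- genome_seq(donor)
    wseq <- substring(tc_seq, windows$start + 1L, windows$end)
    scores <- windows
    scores$identity_recipient <- vapply(wseq, score_window_mapping, numeric(1),
                                        parent = rs, k = k, USE.NAMES = FALSE)
    scores$identity_donor <- vapply(wseq, score_window_mapping, numeric(1),
                                    parent = ds, k = k, USE.NAMES = FALSE)
  }
  calls <- classify_windows(scores, min_identity = min_identity,
                            background = background)
  tc_name <- genome_name(transconjugant, "transconjugant")
  segments <- merge_runs(calls, genome = tc_name)
  report <- transconjugant_report(
    segments, nchar(tc_seq),
    recipient = genome_name(recipient, "recipient"),
    donor = genome_name(donor, "donor"),
    window_bp = window_bp, transconjugant = tc_name
  )
  structure(
    list(
      windows = calls, segments = segments, report = report,
      config = list(window_bp = window_bp, min_identity = min_identity,
                    mode = mode, background = background, k = k)
    ),
    class = "dct_paint"
  )
}

#' @export
print.dct_paint <- function(x, ...) {
  r <- x$report
  cat(sprintf(
    "<dct_paint> %s (W = %d bp, tau = %.2f, %s mode)\n",
    r$transconjugant, x$config$window_bp, x$config$min_identity, x$config$mode
  ))
  cat(sprintf("  %s: %.2f%%   %s: %.2f%%   unassigned: %.2f%%\n",
              r$recipient, r$pct_recipient, r$donor, r$pct_donor,
              r$pct_unassigned))
  cat(sprintf("  transferred regions: %d (largest %s bp)\n",
              r$n_transferred_regions,
              format(r$largest_region_bp, big.mark = ",")))
  invisible(x)
}

#' Turn a painting into a tidy tibble of window calls
#'
#' @param x A `dct_paint` object.
#' @param ... Unused.
#' @return The classified window tibble.
#' @method tidy dct_paint
#' @export
tidy.dct_paint <- function(x, ...) x$windows

#' One-row summary of a painting
#'
#' @param x A `dct_paint` object.
#' @param ... Unused.
#' @return The one-row report tibble.
#' @method glance dct_paint
#' @export
glance.dct_paint <- function(x, ...) x$report

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
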