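#' Concatenate same-origin windows into segments
#'
#' Maximal runs of consecutive windows with identical origin become one
#' segment, defining the extent of each inherited region. The output tiles
#' the genome exactly.
#'
#' @param calls Classified window tibble from [classify_windows()] (ordered,
#'   tiled, with an `origin` column).
#' @param genome Name of the genome the windows tile (recorded in the
#'   `genome` column; default `"transconjugant"`).
#' @return A segment tibble: `genome`, `start`, `end`, `origin`,
#'   `n_windows`, `length_bp` and, when identities are present in `calls`,
#'   `mean_identity` (mean identity to the assigned parent; max identity for
#'   unassigned segments).
#' @export
merge_runs <- function(calls, genome = "transconjugant") {
  if (!"origin" %in% names(calls)) stop("expected classified windows with an origin column")
  n <- nrow(calls)
  if (n == 0) stop("no windows")
  if (n > 1 && any(calls$start[-1] != calls$end[-n])) {
    stop("not tiled: consecutive windows must abut")
  }
  r <- rle(calls$origin)
  last <- cumsum(r$lengths)
  first <- last - r$lengths + 1L
  seg <- tibble::tibble(
    genome = genome,
    start = calls$start[first],
    end = calls$end[last],
    origin = r$values,
    n_windows = r$lengths,
    length_bp = calls$end[last] - calls$start[first]
  )
  if (all(c("identity_recipient", "identity_donor") %in% names(calls))) {
    win_best <- dplyr::case_when(
      calls$origin == "recipient" ~ calls$identity_recipient,
      calls$origin == "donor" ~ calls$identity_donor,
      .default = pmax(calls$identity_recipient, calls$identity_donor)
    )
    seg$mean_identity <- vapply(seq_len(nrow(seg)), function(i) {
      mean(win_best[first[i]:last[i]])
    }, numeric(1))
  }
  seg
}

#' Per-transconjugant painting summary
#'
#' Computes one report row in the shape of a transconjugant-genome analysis
#' table: the percent of the genome inherited from each parent (to 2
#' decimals), the number of transferred regions (donor-origin segments at
#' least one window long -- sub-window rearrangements are not counted as
#' events), and the largest transferred region in bp. The background
#' (recipient) parent is the parent contributing the larger share.
#'
#' @param segments Segment tibble from [merge_runs()] (origins in
#'   `{recipient, donor, unassigned}`, tiling the genome).
#' @param genome_length Transconjugant length in bp (the percentage
#'   denominator).
#' @param recipient,donor Parent names for the report.
#' @param window_bp Window width W; donor segments shorter than W are not
#'   counted as transferred regions (default 500).
#' @param transconjugant Name of the transconjugant.
#' @return A one-row tibble: `transconjugant`, `recipient`, `pct_recipient`,
#'   `donor`, `pct_donor`, `pct_unassigned`, `n_transferred_regions`,
#'   `largest_region_bp`, `background_parent`.
#' @export
transconjugant_report <- function(segments, genome_length,
                                  recipient = "recipient", donor = "donor",
                                  window_bp = 500,
                                  transconjugant = "transconjugant") {
  segments <- dplyr::arrange(segments, .data$start)
  if (nrow(segments) == 0 || segments$start[1] != 0 ||
      segments$end[nrow(segments)] != genome_length ||
      (nrow(segments) > 1 && any(segments$start[-1] != segments$end[-nrow(segments)]))) {
    stop("incomplete tiling: segments must tile [0, genome_length) exactly")
  }
  bp <- function(o) sum(segments$length_bp[segments$origin == o])
  pct <- function(o) round(100 * bp(o) / genome_length, 2)
  donor_segs <- segments[segments$origin == "donor", ]
  transferred <- donor_segs[donor_segs$length_bp >= window_bp, ]
  pr <- pct("recipient"); pd <- pct("donor")
  tibble::tibble(
    transconjugant = transconjugant,
    recipient = recipient,
    pct_recipient = pr,
    donor = donor,
    pct_donor = pd,
    pct_unassigned = pct("unassigned"),
    n_transferred_regions = nrow(transferred),
    largest_region_bp = if (nrow(donor_segs)) max(donor_segs$length_bp) else 0L,
    background_parent = if (pd > pr) donor else recipient
  )
}

#' Cohort summary across transconjugant reports
#'
#' @param reports Tibble of report rows from [transconjugant_report()] (one
#'   per transconjugant).
#' @return One-row tibble: `n_transconjugants`, `mean_events` (mean number
#'   of transferred regions), `mean_events_rounded` (nearest integer, halves
#'   away from zero), `donor_pct_min`, `donor_pct_max`.
#' @export
cohort_summary <- function(reports) {
  if (is.null(reports) || nrow(reports) == 0) stop("no reports")
  m <- mean(reports$n_transferred_regions)
  tibble::tibble(
    n_transconjugants = nrow(reports),
    mean_events = m,
    mean_events_rounded = round_half_up(m),
    donor_pct_min = min(reports$pct_donor),
    donor_pct_max = max(reports$pct_donor)
  )
}

# round half away from zero (base round() rounds halves to even)
round_half_up <- function(x) {
  as.integer(sign(x) * floor(abs(x) + 0.5))
}
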