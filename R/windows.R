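#' Tile a genome into nonoverlapping windows
#'
#' Windows are `[0, W), [W, 2W), ...`. A final partial window is kept as its
#' own window when its length is at least `W / 2`; a shorter tail is merged
#' into the last full window, so the tiling always covers `[0, L)` exactly.
#'
#' @param length_bp Genome length L (must be at least `window_bp`).
#' @param window_bp Window width W in bp (default 500, minimum 50).
#' @return A tibble of 0-based half-open intervals `start`, `end`.
#' @export
tile_windows <- function(length_bp, window_bp = 500) {
  if (window_bp < 50) stop("window_bp must be >= 50")
  if (length_bp < window_bp) stop("genome shorter than window")
  n_full <- length_bp %/% window_bp
  starts <- (seq_len(n_full) - 1L) * window_bp
  ends <- starts + window_bp
  tail_len <- length_bp - n_full * window_bp
  if (tail_len >= window_bp / 2) {
    starts <- c(starts, n_full * window_bp)
    ends <- c(ends, length_bp)
  } else {
    ends[n_full] <- length_bp
  }
  tibble::tibble(start = as.integer(starts), end = as.integer(ends))
}

# 0-based positions at which two equal-length sequences mismatch. An N in
# either sequence counts as a mismatch (conservative, deterministic), even
# against another N.
mismatch_positions <- function(a, b) {
  ra <- charToRaw(a); rb <- charToRaw(b)
  if (length(ra) != length(rb)) stop("frame mismatch: sequences differ in length")
  n <- charToRaw("N")
  which(ra != rb | ra == n | rb == n) - 1L
}

#' Score tiled windows against both parents (aligned mode)
#'
#' For collinear genomes sharing one coordinate frame, the identity of a
#' window to a parent is simply the fraction of matching positions -- the
#' exact per-position equivalent of a fragment-mapping ANI score. `N` counts
#' as a mismatch to every parental base.
#'
#' @param transconjugant,recipient,donor Equal-length nucleotide strings or
#'   one-row genome tibbles in the same coordinate frame.
#' @param windows Window tibble from [tile_windows()]; default tiles the
#'   transconjugant at 500 bp.
#' @param window_bp Window width used when `windows` is `NULL`.
#' @return `windows` with columns `identity_recipient`, `identity_donor`
#'   appended.
#' @export
score_windows_aligned <- function(transconjugant, recipient, donor,
                                  windows = NULL, window_bp = 500) {
  tc <- genome_seq(transconjugant)
  rs <- genome_seq(recipient)
  ds <- genome_seq(donor)
  if (nchar(tc) != nchar(rs) || nchar(tc) != nchar(ds)) {
    stop("frame mismatch: sequences must have equal length in aligned mode")
  }
  if (is.null(windows)) windows <- tile_windows(nchar(tc), window_bp)
  windows$identity_recipient <- window_identity(tc, rs, windows)
  windows$identity_donor <- window_identity(tc, ds, windows)
  windows
}

window_identity <- function(seq_a, seq_b, windows) {
  mm <- mismatch_positions(seq_a, seq_b)
  idx <- findInterval(mm, windows$start)
  counts <- tabulate(idx, nbins = nrow(windows))
  1 - counts / (windows$end - windows$start)
}

#' Score one window against a parent by seeded mapping
#'
#' Mapping mode for genomes that are not perfectly collinear: candidate loci
#' in the parent are located by shared k-mer seeding (non-overlapping
#' k-mers of the window, default k = 16), and the identity to the best
#' candidate locus is `1 - edit_distance / window_length`. A window with no
#' seed hits anywhere in the parent scores 0 (not an error).
#'
#' @param window_seq Nucleotide string (length at least `k`).
#' @param parent Parent genome (string or one-row genome tibble).
#' @param k Seed k-mer length (default 16).
#' @param max_candidates Number of top-voted candidate loci to evaluate by
#'   edit distance (default 5).
#' @return Identity in `[0, 1]`.
#' @export
score_window_mapping <- function(window_seq, parent, k = 16, max_candidates = 5) {
  parent_seq <- genome_seq(parent)
  W <- nchar(window_seq)
  if (W < k) stop("window length must be >= k")
  offs <- seq(1L, W - k + 1L, by = k)
  seeds <- substring(window_seq, offs, offs + k - 1L)
  keep <- !grepl("N", seeds, fixed = TRUE)
  if (!any(keep)) return(0)
  pd <- Biostrings::PDict(Biostrings::DNAStringSet(seeds[keep]))
  hits <- Biostrings::matchPDict(pd, Biostrings::DNAString(parent_seq))
  cand <- integer(0)
  for (i in seq_along(hits)) {
    st <- BiocGenerics::start(hits[[i]])
    if (length(st)) cand <- c(cand, st - (offs[keep][i] - 1L))
  }
  if (length(cand) == 0) return(0)
  cand <- pmax(1L, pmin(cand, nchar(parent_seq) - W + 1L))
  votes <- sort(table(cand), decreasing = TRUE)
  top <- as.integer(names(votes))[seq_len(min(max_candidates, length(votes)))]
  best <- min(vapply(top, function(s) {
    locus <- substr(parent_seq, s, s + W - 1L)
    as.integer(utils::adist(window_seq, locus))
  }, integer(1)))
  max(0, 1 - best / W)
}

#' Assign a parental origin to each scored window
#'
#' The painting rule: a window below the minimum identity to both parents is
#' `unassigned`; a window with 100% identity to both parents inherits the
#' origin of the nearest preceding assigned window (or the declared
#' background parent when none exists yet); a tied identity below 100%
#' inherits the same way and is flagged; otherwise the parent with strictly
#' greater identity wins.
#'
#' @param scores Tibble from [score_windows_aligned()] (ordered, tiled;
#'   columns `start`, `end`, `identity_recipient`, `identity_donor`).
#' @param min_identity Minimum identity tau below which a window is
#'   `unassigned` (default 0.9; must be < 1). The unassigned class absorbs
#'   marker-cassette windows and tracts diverged beyond recognition.
#' @param background Origin used when a tie occurs before any window has
#'   been assigned: `"recipient"` or `"donor"`.
#' @return `scores` with columns `origin` (`"recipient"`, `"donor"` or
#'   `"unassigned"`) and `ambiguous_inherited` (TRUE where the origin was
#'   inherited from the preceding assigned window because the identities
#'   were tied).
#' @export
classify_windows <- function(scores, min_identity = 0.9,
                             background = c("recipient", "donor")) {
  background <- match.arg(background)
  stopifnot(min_identity < 1)
  need <- c("start", "end", "identity_recipient", "identity_donor")
  if (!all(need %in% names(scores))) {
    stop("expected columns start, end, identity_recipient, identity_donor")
  }
  n <- nrow(scores)
  if (n > 1) {
    if (is.unsorted(scores$start, strictly = TRUE) ||
        any(scores$start[-1] < scores$end[-n])) {
      stop("not tiled: windows must be ordered and nonoverlapping")
    }
  }
  ir <- scores$identity_recipient
  id <- scores$identity_donor
  origin <- character(n)
  ambiguous <- logical(n)
  carry <- background
  for (i in seq_len(n)) {
    if (max(ir[i], id[i]) < min_identity) {
      origin[i] <- "unassigned"
    } else if (ir[i] == id[i]) {
      origin[i] <- carry
      ambiguous[i] <- TRUE
      carry <- origin[i]
    } else {
      origin[i] <- if (ir[i] > id[i]) "recipient" else "donor"
      carry <- origin[i]
    }
  }
  scores$origin <- origin
  scores$ambiguous_inherited <- ambiguous
  scores
}
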