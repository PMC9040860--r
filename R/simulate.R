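#' Generate a random genome
#'
#' Mycobacterial chromosomes are GC-rich, so the default base composition is
#' 67% G+C; composition has no effect on downstream identity scoring, which
#' is purely positional.
#'
#' @param length_bp Genome length in bp.
#' @param name Genome identifier.
#' @param gc G+C fraction in `[0, 1]` (default 0.67).
#' @param seed Integer seed; the draw is deterministic given the seed.
#' @param topology `"linear"` or `"circular"`.
#' @return A one-row genome tibble.
#' @export
random_genome <- function(length_bp, name = "genome", gc = 0.67, seed = 1,
                          topology = "circular") {
  stopifnot(length_bp >= 1, gc >= 0, gc <= 1)
  seq <- withr::with_seed(seed, {
    p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    paste(sample(names(p), length_bp, replace = TRUE, prob = p), collapse = "")
  })
  genome_tbl(name, seq, topology = topology)
}

#' Generate a divergent, collinear parental genome pair
#'
#' Emulates a pair of M. smegmatis-like parents that differ only by point
#' substitutions at a controlled density: a recipient genome is drawn at
#' random and a donor is derived from it by substituting `round(d * L)`
#' uniformly chosen sites (without replacement), each to a base drawn
#' uniformly from the three non-reference bases. Typical densities are
#' `snv_density = 0.01` (about 1 SNV per 100 nt, an MKD8-vs-mc2 155-like
#' pair) and `snv_density = 0.001` (about 1 per kb, a Jucho-vs-mc2 155-like
#' pair).
#'
#' @param length_bp Genome length L (at least 10 window widths, i.e. 5 kb at
#'   the default 500-bp window).
#' @param snv_density Substitutions per bp, in `[0, 0.25]`.
#' @param seed Integer seed; output is byte-identical across runs for a
#'   fixed seed.
#' @param names Length-2 character vector `(recipient, donor)`.
#' @param gc G+C fraction of the recipient draw.
#' @return An object of class `parent_pair`: a list with elements
#'   `recipient` and `donor` (one-row genome tibbles) and `variants`, a
#'   variant tibble with 0-based `position`, `base_a` (recipient base) and
#'   `base_b` (donor base), carrying the genome names in attributes
#'   `genome_a` / `genome_b`.
#' @export
generate_parent_pair <- function(length_bp, snv_density, seed = 1,
                                 names = c("recipient", "donor"), gc = 0.67) {
  stopifnot(snv_density >= 0, snv_density <= 0.25, length_bp >= 10 * 500)
  n_var <- round(snv_density * length_bp)
  if (n_var < 1) stop("no variants requested: round(snv_density * length_bp) < 1")
  recipient <- random_genome(length_bp, names[1], gc = gc, seed = seed)
  mut <- withr::with_seed(seed + 1L, {
    pos <- sort(sample.int(length_bp, n_var)) # 1-based while indexing raw
    ref <- substring_bases(recipient$sequence, pos)
    alt <- vapply(ref, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1),
                  character(1), USE.NAMES = FALSE)
    list(pos = pos, ref = ref, alt = alt)
  })
  donor_seq <- replace_bases(recipient$sequence, mut$pos, mut$alt)
  donor <- genome_tbl(names[2], donor_seq, topology = recipient$topology)
  variants <- tibble::tibble(
    position = mut$pos - 1L,
    base_a = mut$ref,
    base_b = mut$alt
  )
  attr(variants, "genome_a") <- names[1]
  attr(variants, "genome_b") <- names[2]
  structure(
    list(recipient = recipient, donor = donor, variants = variants),
    class = "parent_pair"
  )
}

#' @export
print.parent_pair <- function(x, ...) {
  cat(sprintf(
    "<parent_pair> %s / %s: %s bp, %s substitutions (%.4g per bp)\n",
    x$recipient$name, x$donor$name,
    format(x$recipient$length_bp, big.mark = ","),
    format(nrow(x$variants), big.mark = ","),
    nrow(x$variants) / x$recipient$length_bp
  ))
  invisible(x)
}

substring_bases <- function(seq, pos_1based) {
  if (length(pos_1based) == 0) return(character(0))
  substring(seq, pos_1based, pos_1based)
}

replace_bases <- function(seq, pos_1based, bases) {
  r <- charToRaw(seq)
  r[pos_1based] <- charToRaw(paste(bases, collapse = ""))
  rawToChar(r)
}

#' Simulate a mosaic transconjugant genome with ground truth
#'
#' Builds a transconjugant as a recipient backbone in which `n_segments`
#' noncontiguous tracts are replaced by the donor's bases over the same
#' intervals, emulating distributive conjugal transfer. Defaults follow the
#' observed behaviour of M. smegmatis crosses: the number of transferred
#' segments is drawn with mean 16 (zero-truncated Poisson), segment lengths
#' are log-uniform on 1--250 kb (bracketing the observed 1,000--260,500 bp
#' range of largest transferred regions), and the realised donor fraction is
#' targeted to the observed 1--12% range by redrawing the length set.
#' Optionally a marker cassette -- random sequence matching neither parent,
#' standing in for an antibiotic-resistance insertion such as a Km gene at
#' attL5 -- is inserted at a configurable position (default ~8/12 of the
#' genome, the "8 o'clock" position of the cassette in the strains this
#' emulates).
#'
#' @param recipient,donor One-row genome tibbles of equal length (collinear,
#'   e.g. from [generate_parent_pair()]).
#' @param n_segments Number of donor tracts `k >= 0`; `NULL` draws
#'   zero-truncated Poisson with mean `mean_segments`.
#' @param mean_segments Mean of the segment-count draw when `n_segments` is
#'   `NULL` (default 16).
#' @param segment_length_range Range of the log-uniform segment-length
#'   distribution in bp (default `c(1e3, 2.5e5)`).
#' @param segment_lengths Optional explicit segment lengths (overrides the
#'   distribution).
#' @param target_donor_fraction Length-2 numeric: the drawn length set is
#'   rescaled so the summed length / L equals a fraction sampled uniformly
#'   from this interval (default `c(0.01, 0.12)`), preserving the relative
#'   length shape; `NULL` disables targeting. Ignored when `segment_lengths`
#'   is supplied.
#' @param min_gap Minimum distance in bp between placed segments (and from
#'   each other), default one window (500 bp), so ground-truth event counts
#'   are unambiguous.
#' @param marker `NULL` (default) or a list with `length_bp` (default 1500)
#'   and optional `position` (0-based insertion offset; default
#'   `round(8 / 12 * L)`).
#' @param seed Integer seed; output is byte-identical across runs for a
#'   fixed seed.
#' @param name Name of the transconjugant genome.
#' @return An object of class `dct_cross`: a list with `transconjugant`
#'   (one-row genome tibble), `truth` (tibble `start`, `end`, `origin` in
#'   `{recipient, donor, marker}` tiling the transconjugant exactly), and
#'   `config` (realised configuration, including `donor_fraction`).
#' @export
simulate_transconjugant <- function(recipient, donor,
                                    n_segments = NULL,
                                    mean_segments = 16,
                                    segment_length_range = c(1e3, 2.5e5),
                                    segment_lengths = NULL,
                                    target_donor_fraction = c(0.01, 0.12),
                                    min_gap = 500,
                                    marker = NULL,
                                    seed = 1,
                                    name = "transconjugant") {
  assert_genomes(recipient); assert_genomes(donor)
  L <- recipient$length_bp
  if (donor$length_bp != L) stop("not collinear: parent genomes differ in length")

  placed <- withr::with_seed(seed, {
    k <- n_segments
    if (is.null(k)) {
      k <- 0L
      while (k == 0L) k <- stats::rpois(1, mean_segments)
    }
    lens <- segment_lengths
    if (is.null(lens) && k > 0) {
      draw_lens <- function() {
        round(exp(stats::runif(k, log(segment_length_range[1]),
                               log(segment_length_range[2]))))
      }
      lens <- draw_lens()
      if (!is.null(target_donor_fraction)) {
        # rescale the drawn length set to a donor fraction sampled from the
        # target range, preserving the relative (log-uniform) length shape;
        # lengths are clamped below at the distribution minimum
        f <- stats::runif(1, target_donor_fraction[1], target_donor_fraction[2])
        lens <- round(lens * f * L / sum(lens))
        lens <- pmax(lens, round(segment_length_range[1]))
      }
    }
    if (k == 0) {
      list(start = integer(0), end = integer(0))
    } else {
      if (length(lens) != k) stop("segment_lengths must have length n_segments")
      if (sum(lens) + (k - 1) * min_gap > L) stop("placement failure: segments do not fit")
      starts <- integer(0); ends <- integer(0)
      for (len in sort(lens, decreasing = TRUE)) {
        ok <- FALSE
        for (attempt in seq_len(1000)) {
          s <- sample.int(L - len + 1L, 1) - 1L
          e <- s + len
          if (all(s >= ends + min_gap | e <= starts - min_gap)) {
            starts <- c(starts, s); ends <- c(ends, e); ok <- TRUE; break
          }
        }
        if (!ok) stop("placement failure: could not place segments disjointly after 1,000 attempts")
      }
      o <- order(starts)
      list(start = starts[o], end = ends[o])
    }
  })

  # splice donor tracts into the recipient backbone
  tc_raw <- charToRaw(recipient$sequence)
  donor_raw <- charToRaw(donor$sequence)
  for (i in seq_along(placed$start)) {
    idx <- (placed$start[i] + 1L):placed$end[i]
    tc_raw[idx] <- donor_raw[idx]
  }
  tc_seq <- rawToChar(tc_raw)

  truth <- tile_origins(L, placed$start, placed$end,
                        recipient$name, donor$name)

  marker_len <- 0L
  if (!is.null(marker)) {
    marker_len <- as.integer(marker$length_bp %||% 1500L)
    mpos <- as.integer(marker$position %||% round(8 / 12 * L))
    stopifnot(mpos >= 0, mpos <= L)
    cassette <- withr::with_seed(seed + 2L, paste(
      sample(c("A", "C", "G", "T"), marker_len, replace = TRUE), collapse = ""
    ))
    tc_seq <- paste0(substr(tc_seq, 1, mpos), cassette,
                     substr(tc_seq, mpos + 1, L))
    truth <- insert_marker_truth(truth, mpos, marker_len)
  }

  transconjugant <- genome_tbl(name, tc_seq, topology = recipient$topology)
  donor_bp <- sum(truth$end[truth$origin == donor$name] -
                  truth$start[truth$origin == donor$name])
  structure(
    list(
      transconjugant = transconjugant,
      truth = truth,
      config = list(
        recipient = recipient$name, donor = donor$name,
        length_bp = transconjugant$length_bp,
        n_segments = length(placed$start),
        segment_lengths = placed$end - placed$start,
        donor_fraction = donor_bp / transconjugant$length_bp,
        marker_bp = marker_len,
        min_gap = min_gap, seed = seed
      )
    ),
    class = "dct_cross"
  )
}

#' @export
print.dct_cross <- function(x, ...) {
  cat(sprintf(
    "<dct_cross> %s: %s bp; %d donor segments (%s bp, %.2f%% of genome)%s\n",
    x$transconjugant$name,
    format(x$transconjugant$length_bp, big.mark = ","),
    x$config$n_segments,
    format(sum(x$config$segment_lengths), big.mark = ","),
    100 * x$config$donor_fraction,
    if (x$config$marker_bp > 0) sprintf("; %d-bp marker cassette", x$config$marker_bp) else ""
  ))
  invisible(x)
}

# Tile [0, L) with donor intervals and recipient gaps.
tile_origins <- function(L, starts, ends, recipient_name, donor_name) {
  bounds <- sort(unique(c(0L, starts, ends, L)))
  out_start <- bounds[-length(bounds)]
  out_end <- bounds[-1]
  is_donor <- vapply(out_start, function(s) any(starts <= s & ends > s), logical(1))
  tibble::tibble(
    start = as.integer(out_start),
    end = as.integer(out_end),
    origin = ifelse(is_donor, donor_name, recipient_name)
  )
}

# Insert a marker segment at mpos, shifting downstream truth intervals.
insert_marker_truth <- function(truth, mpos, marker_len) {
  pre <- truth[truth$end <= mpos, ]
  post <- truth[truth$start >= mpos, ]
  hit <- truth[truth$start < mpos & truth$end > mpos, ]
  if (nrow(hit) == 1) {
    pre <- dplyr::bind_rows(pre, tibble::tibble(
      start = hit$start, end = mpos, origin = hit$origin))
    post <- dplyr::bind_rows(tibble::tibble(
      start = mpos, end = hit$end, origin = hit$origin), post)
  }
  post$start <- post$start + marker_len
  post$end <- post$end + marker_len
  out <- dplyr::bind_rows(
    pre,
    tibble::tibble(start = mpos, end = mpos + marker_len, origin = "marker"),
    post
  )
  out$start <- as.integer(out$start); out$end <- as.integer(out$end)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
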