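#' Tabulate substitutions between two collinear genomes
#'
#' One row per position at which the two sequences carry different bases and
#' neither is `N`, in the shared (0-based) coordinate frame. Equal lengths
#' are required: the comparison is positional, as for genomes that are
#' collinear by construction or pre-aligned.
#'
#' @param a,b One-row genome tibbles or bare sequence strings of equal
#'   length.
#' @return A variant tibble with columns `position` (0-based), `base_a`,
#'   `base_b`, and attributes `genome_a`, `genome_b`.
#' @export
snv_table <- function(a, b) {
  sa <- genome_seq(a); sb <- genome_seq(b)
  if (nchar(sa) != nchar(sb)) stop("not collinear: sequences differ in length")
  ra <- charToRaw(sa); rb <- charToRaw(sb)
  n <- charToRaw("N")
  pos <- which(ra != rb & ra != n & rb != n)
  out <- tibble::tibble(
    position = pos - 1L,
    base_a = strsplit(rawToChar(ra[pos]), "")[[1]],
    base_b = strsplit(rawToChar(rb[pos]), "")[[1]]
  )
  attr(out, "genome_a") <- genome_name(a, "a")
  attr(out, "genome_b") <- genome_name(b, "b")
  out
}

#' Pairwise SNV distance matrix
#'
#' Counts of substitution differences for every pair of collinear genomes, in
#' the symmetric zero-diagonal shape of an snp-dists table.
#'
#' @param genomes A genome tibble (two or more rows, equal lengths).
#' @return A symmetric integer matrix with the genome names as dimnames.
#' @export
snv_matrix <- function(genomes) {
  assert_genomes_multi(genomes)
  n <- nrow(genomes)
  m <- matrix(0L, n, n, dimnames = list(genomes$name, genomes$name))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d <- nrow(snv_table(genomes$sequence[i], genomes$sequence[j]))
      m[i, j] <- d
      m[j, i] <- d
    }
  }
  m
}

assert_genomes_multi <- function(genomes) {
  assert_genomes_cols(genomes)
  if (nrow(genomes) < 2) stop("need at least two genomes")
  if (length(unique(genomes$length_bp)) != 1) {
    stop("not collinear: genomes differ in length")
  }
  invisible(TRUE)
}

assert_genomes_cols <- function(genomes) {
  need <- c("name", "sequence", "length_bp")
  if (!is.data.frame(genomes) || !all(need %in% names(genomes))) {
    stop("expected a genome tibble with columns name, sequence, length_bp")
  }
  invisible(TRUE)
}

#' Windowed SNV-density track
#'
#' Counts variant positions per tiled window -- the numeric form of a
#' per-genome SNV-density bar track along a reference.
#'
#' @param variants A variant tibble (see [snv_table()]).
#' @param window_bp Window width in bp (at least 1).
#' @param genome_length Length of the coordinate frame in bp.
#' @return A tibble `start`, `end`, `count` tiling `[0, genome_length)`.
#' @export
snv_density_track <- function(variants, window_bp, genome_length) {
  stopifnot(window_bp >= 1, genome_length >= 1)
  n_win <- max(1L, ceiling(genome_length / window_bp))
  starts <- (seq_len(n_win) - 1L) * window_bp
  windows <- tibble::tibble(
    start = as.integer(starts),
    end = as.integer(pmin(starts + window_bp, genome_length))
  )
  idx <- findInterval(variants$position, windows$start)
  windows$count <- tabulate(idx, nbins = nrow(windows))
  windows
}
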