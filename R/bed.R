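#' Write segments to a BED6 file
#'
#' Segments are written in the standard 6-column BED format: `chrom` is the
#' genome name, `name` is the origin label, `score` is the mean window
#' identity scaled to 0--1000 (clamped), strand is `"."`. Coordinates are
#' 0-based half-open, as everywhere in the package.
#'
#' @param segments A segment tibble with columns `genome`, `start`, `end`,
#'   `origin` and optionally `mean_identity`. All rows must refer to one
#'   genome and must be disjoint (segments from one painting tile the genome).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(segments, path) {
  need <- c("genome", "start", "end", "origin")
  if (!is.data.frame(segments) || !all(need %in% names(segments))) {
    stop("expected a segment tibble with columns genome, start, end, origin")
  }
  if (nrow(segments) == 0) {
    writeLines("# BED6: chrom start end origin score strand", path)
    return(invisible(path))
  }
  if (length(unique(segments$genome)) != 1) {
    stop("all segments must refer to one genome")
  }
  segments <- dplyr::arrange(segments, .data$start)
  if (any(segments$start < 0) || any(segments$end <= segments$start)) {
    stop("invalid interval: require 0 <= start < end")
  }
  if (nrow(segments) > 1 &&
      any(segments$start[-1] < segments$end[-nrow(segments)])) {
    stop("overlap: segments must tile the genome disjointly")
  }
  score <- if ("mean_identity" %in% names(segments)) {
    pmin(1000, pmax(0, round(segments$mean_identity * 1000)))
  } else {
    rep(0, nrow(segments))
  }
  gr <- GenomicRanges::GRanges(
    seqnames = segments$genome,
    ranges = IRanges::IRanges(start = segments$start + 1L, end = segments$end),
    strand = "*"
  )
  gr$name <- as.character(segments$origin)
  gr$score <- as.numeric(score)
  rtracklayer::export.bed(gr, path)
  invisible(path)
}

#' Read a BED file back into a segment tibble
#'
#' Inverse of [write_bed()]: returns 0-based half-open intervals with the BED
#' `name` column as `origin` and `score/1000` as `mean_identity`.
#'
#' @param path Path to a BED file.
#' @return A tibble with columns `genome`, `start`, `end`, `origin`,
#'   `mean_identity`.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(lines) == 0) {
    return(tibble::tibble(
      genome = character(), start = integer(), end = integer(),
      origin = character(), mean_identity = numeric()
    ))
  }
  gr <- rtracklayer::import(path, format = "bed")
  tibble::tibble(
    genome = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    origin = if (!is.null(gr$name)) gr$name else NA_character_,
    mean_identity = if (!is.null(gr$score)) as.numeric(gr$score) / 1000 else NA_real_
  )
}
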