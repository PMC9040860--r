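#' Genome tables
#'
#' A genome is represented as one row of a tibble with columns `name`,
#' `sequence` (upper-case nucleotides over `A`, `C`, `G`, `T`, `N`),
#' `topology` (`"circular"` or `"linear"`) and `length_bp`. All interval
#' arithmetic in the package is 0-based half-open (BED-compatible);
#' positions are 1-based only where a report echoes a published coordinate,
#' and such columns are labelled.
#'
#' @param name Character vector of genome identifiers (nonempty, unique).
#' @param sequence Character vector of nucleotide sequences.
#' @param topology `"linear"` or `"circular"`. Topology is recorded but the
#'   window scan never wraps the origin: the painting procedure is a linear
#'   scan over the transconjugant.
#' @return A tibble with columns `name`, `sequence`, `topology`, `length_bp`.
#' @export
genome_tbl <- function(name, sequence, topology = "linear") {
  stopifnot(length(name) == length(sequence))
  if (any(!nzchar(name))) stop("genome names must be nonempty")
  if (anyDuplicated(name)) {
    stop("duplicate identifier: ", name[duplicated(name)][1])
  }
  sequence <- chartr("U", "T", toupper(sequence))
  check_alphabet(sequence, name)
  topology <- rep_len(topology, length(name))
  stopifnot(all(topology %in% c("linear", "circular")))
  tibble::tibble(
    name = unname(as.character(name)),
    sequence = unname(sequence),
    topology = unname(topology),
    length_bp = unname(nchar(sequence))
  )
}

check_alphabet <- function(sequence, name) {
  bad <- regexpr("[^ACGTN]", sequence)
  if (any(bad > 0)) {
    i <- which(bad > 0)[1]
    stop(sprintf(
      "invalid alphabet: record '%s' has illegal character '%s' at offset %d",
      name[i], substr(sequence[i], bad[i], bad[i]), bad[i] - 1L
    ))
  }
  invisible(TRUE)
}

#' Read genomes from a FASTA file
#'
#' Sequences are upper-cased, `U` is mapped to `T`, and any character outside
#' `A`, `C`, `G`, `T`, `N` is rejected with the offending record and 0-based
#' offset named in the error.
#'
#' @param path Path to a FASTA file.
#' @param topology Topology recorded for every record (default `"linear"`).
#' @return A tibble of genomes, one row per FASTA record (see [genome_tbl()]).
#' @export
read_fasta <- function(path, topology = "linear") {
  if (!file.exists(path)) stop("file not found: ", path)
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop("no records in FASTA file: ", path)
  )
  if (length(set) == 0) stop("no records in FASTA file: ", path)
  nm <- sub("\\s.*$", "", names(set))
  genome_tbl(nm, as.character(set), topology = topology)
}

#' Write genomes to a FASTA file
#'
#' @param genomes A genome tibble (see [genome_tbl()]).
#' @param path Output path.
#' @param width Line width for wrapped sequence (default 70).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genomes, path, width = 70) {
  assert_genomes(genomes)
  set <- Biostrings::DNAStringSet(stats::setNames(genomes$sequence, genomes$name))
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

assert_genomes <- function(genomes) {
  need <- c("name", "sequence", "length_bp")
  if (!is.data.frame(genomes) || !all(need %in% names(genomes))) {
    stop("expected a genome tibble with columns name, sequence, length_bp")
  }
  if (!all(genomes$length_bp == nchar(genomes$sequence))) {
    stop("length_bp does not match sequence length")
  }
  invisible(TRUE)
}

# Fetch the sequence of one named genome out of a genome tibble (or pass a
# bare string through).
genome_seq <- function(genome) {
  if (is.character(genome) && length(genome) == 1 && !file.exists(genome)) {
    return(genome)
  }
  assert_genomes(genome)
  if (nrow(genome) != 1) stop("expected exactly one genome")
  genome$sequence
}

genome_name <- function(genome, default = "genome") {
  if (is.character(genome)) return(default)
  genome$name
}
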