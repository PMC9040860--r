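#' Global protein percent identity
#'
#' Needleman-Wunsch global alignment with affine gap penalties (BLOSUM62,
#' gap open 10, gap extend 0.5 by default). Percent identity is the number
#' of identical aligned residue pairs divided by the total number of
#' alignment columns, gap columns included in the denominator -- a
#' conservative convention that depresses low identities slightly relative
#' to gap-excluded conventions.
#'
#' @param seq_a,seq_b Amino-acid strings over the 20 standard residues plus
#'   `X` (nonempty).
#' @param gap_open,gap_extend Affine gap penalties (positive numbers).
#' @param substitution_matrix Scoring matrix name (default `"BLOSUM62"`).
#' @return A one-row tibble: `percent_identity` (0--100, 1 decimal),
#'   `matches`, `alignment_columns`.
#' @export
global_identity <- function(seq_a, seq_b, gap_open = 10, gap_extend = 0.5,
                            substitution_matrix = "BLOSUM62") {
  check_protein(seq_a, "seq_a")
  check_protein(seq_b, "seq_b")
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(seq_a), Biostrings::AAString(seq_b),
    type = "global", substitutionMatrix = substitution_matrix,
    gapOpening = gap_open, gapExtension = gap_extend
  )
  pa <- as.character(Biostrings::alignedPattern(aln))
  ps <- as.character(Biostrings::alignedSubject(aln))
  cols <- nchar(pa)
  matches <- sum(charToRaw(pa) == charToRaw(ps) &
                 charToRaw(pa) != charToRaw("-"))
  tibble::tibble(
    percent_identity = round(100 * matches / cols, 1),
    matches = as.integer(matches),
    alignment_columns = as.integer(cols)
  )
}

check_protein <- function(seq, what) {
  if (!is.character(seq) || length(seq) != 1 || !nzchar(seq)) {
    stop("empty protein: ", what)
  }
  if (grepl("[^ACDEFGHIKLMNPQRSTVWYX]", toupper(seq))) {
    stop("invalid residue in ", what,
         ": only the 20 standard amino acids plus X are allowed")
  }
  invisible(TRUE)
}

#' Catalogue SNVs between two near-identical loci
#'
#' Aligns two versions of a locus (directly when they are the same length
#' and near-identical, by indel-tolerant global alignment otherwise) and
#' lists every substitution column, annotated with the overlapping feature
#' and its coding effect. Indel columns are never reported as SNVs.
#' Positions are 0-based offsets in `locus_a`'s frame.
#'
#' @param locus_a,locus_b Nucleotide strings (alignable end to end; an
#'   alignment identity below 80% is an error, not a catalogue).
#' @param features Optional feature tibble with columns `name`, `start`,
#'   `end` (0-based half-open in `locus_a`'s frame) and optionally `strand`
#'   (`"+"`/`"-"`). With strand information the coding effect of each
#'   substitution is classified as `silent` or `missense` by translating the
#'   affected codon; features without strand give `unknown`; positions in no
#'   feature are `noncoding`.
#' @return A tibble: `position`, `base_a`, `base_b`, `feature`,
#'   `coding_effect`, `aa_a`, `aa_b` (reference and substituted residues,
#'   `NA` outside coding features).
#' @export
locus_snv_report <- function(locus_a, locus_b, features = NULL) {
  la <- chartr("U", "T", toupper(genome_seq(locus_a)))
  lb <- chartr("U", "T", toupper(genome_seq(locus_b)))
  if (!nzchar(la) || !nzchar(lb)) stop("empty locus")
  if (nchar(la) == nchar(lb)) {
    pos0 <- mismatch_pos_no_n(la, lb)
    if (length(pos0) / nchar(la) > 0.2) {
      stop("loci too diverged for SNV cataloging (alignment identity < 80%)")
    }
    subs <- tibble::tibble(
      position = pos0,
      base_a = substring_bases(la, pos0 + 1L),
      base_b = substring_bases(lb, pos0 + 1L)
    )
  } else {
    subs <- aligned_substitutions(la, lb)
  }
  annotate_substitutions(subs, la, features)
}

mismatch_pos_no_n <- function(a, b) {
  ra <- charToRaw(a); rb <- charToRaw(b)
  n <- charToRaw("N")
  which(ra != rb & ra != n & rb != n) - 1L
}

# indel-tolerant comparison via global nucleotide alignment; positions
# reported in locus_a's ungapped frame
aligned_substitutions <- function(la, lb) {
  if (max(nchar(la), nchar(lb)) > 50000) {
    stop("loci too long for indel-tolerant alignment; supply equal-length loci")
  }
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(la), Biostrings::DNAString(lb),
    type = "global", gapOpening = 10, gapExtension = 0.5
  )
  pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  ps <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  non_gap <- pa != "-" & ps != "-"
  ident <- sum(pa == ps & non_gap) / length(pa)
  if (ident < 0.8) {
    stop("loci too diverged for SNV cataloging (alignment identity < 80%)")
  }
  a_off <- cumsum(pa != "-") # 1-based position in la at each column
  is_sub <- non_gap & pa != ps & pa != "N" & ps != "N"
  tibble::tibble(
    position = a_off[is_sub] - 1L,
    base_a = pa[is_sub],
    base_b = ps[is_sub]
  )
}

annotate_substitutions <- function(subs, la, features) {
  n <- nrow(subs)
  feature <- rep(NA_character_, n)
  effect <- rep("noncoding", n)
  aa_a <- rep(NA_character_, n)
  aa_b <- rep(NA_character_, n)
  if (n > 0 && !is.null(features) && nrow(features) > 0) {
    has_strand <- "strand" %in% names(features)
    for (i in seq_len(n)) {
      p <- subs$position[i]
      hit <- which(features$start <= p & features$end > p)
      if (length(hit) == 0) next
      hit <- hit[1]
      feature[i] <- features$name[hit]
      strand <- if (has_strand) features$strand[hit] else NA_character_
      if (is.na(strand) || !strand %in% c("+", "-")) {
        effect[i] <- "unknown"
        next
      }
      cod <- codon_effect(la, p, subs$base_b[i],
                          features$start[hit], features$end[hit], strand)
      effect[i] <- cod$effect
      aa_a[i] <- cod$aa_a
      aa_b[i] <- cod$aa_b
    }
  }
  subs$feature <- feature
  subs$coding_effect <- effect
  subs$aa_a <- aa_a
  subs$aa_b <- aa_b
  subs
}

# classify one substitution inside a stranded CDS as silent/missense
codon_effect <- function(la, pos0, alt_base, cds_start, cds_end, strand) {
  if (strand == "+") {
    off <- pos0 - cds_start # 0-based offset into CDS
  } else {
    off <- (cds_end - 1L) - pos0
  }
  codon_i <- off %/% 3L
  within <- off %% 3L
  if (strand == "+") {
    c_start <- cds_start + 3L * codon_i # 0-based
    codon <- substr(la, c_start + 1L, c_start + 3L)
    alt_codon <- codon
    substr(alt_codon, within + 1L, within + 1L) <- alt_base
  } else {
    c_end <- cds_end - 3L * codon_i # 0-based exclusive
    codon_fwd <- substr(la, c_end - 2L, c_end)
    alt_fwd <- codon_fwd
    substr(alt_fwd, 3L - within, 3L - within) <- alt_base
    codon <- revcomp(codon_fwd)
    alt_codon <- revcomp(alt_fwd)
  }
  if (nchar(codon) != 3 || grepl("[^ACGT]", codon) || grepl("[^ACGT]", alt_codon)) {
    return(list(effect = "unknown", aa_a = NA_character_, aa_b = NA_character_))
  }
  aa_a <- Biostrings::GENETIC_CODE[[codon]]
  aa_b <- Biostrings::GENETIC_CODE[[alt_codon]]
  list(
    effect = if (identical(aa_a, aa_b)) "silent" else "missense",
    aa_a = aa_a, aa_b = aa_b
  )
}

revcomp <- function(x) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(x, "")[[1]]), collapse = ""))
}

#' Are two mid loci identical?
#'
#' The self-identity flag: two strains with identical mid regions exclude
#' each other as conjugal partners. Returns `TRUE` when the SNV catalogue of
#' the designated mid interval is empty.
#'
#' @param locus_a,locus_b Nucleotide strings of the locus in a shared frame.
#' @param mid_interval Optional list or tibble row with `start`, `end`
#'   (0-based half-open in `locus_a`'s frame); default compares the whole
#'   locus.
#' @return Logical scalar `mid_identical`.
#' @export
mid_identical <- function(locus_a, locus_b, mid_interval = NULL) {
  rep_tbl <- locus_snv_report(locus_a, locus_b)
  if (is.null(mid_interval)) return(nrow(rep_tbl) == 0)
  !any(rep_tbl$position >= mid_interval$start & rep_tbl$position < mid_interval$end)
}
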