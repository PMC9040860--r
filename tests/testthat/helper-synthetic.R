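# Shared fixture builders; everything is generated in code at test time.

write_tmp_fasta <- function(seqs) {
  f <- tempfile(fileext = ".fasta")
  writeLines(unlist(lapply(names(seqs), function(n) c(paste0(">", n), seqs[[n]]))), f)
  f
}

random_dna <- function(n, seed = 1, gc = 0.5) {
  withr::with_seed(seed, paste(
    sample(c("A", "C", "G", "T"), n, replace = TRUE,
           prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
    collapse = ""
  ))
}

random_protein <- function(n, seed = 1) {
  withr::with_seed(seed, paste(
    sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n, replace = TRUE),
    collapse = ""
  ))
}

# A synthetic ~33-kb esx1-like locus pair: locus_b differs from locus_a by
# exactly two planted substitutions inside CDS features -- one missense
# CGC(Arg)->CCC(Pro) and one silent CTC(Leu)->CTT(Leu) C->T transition --
# mirroring the kind of near-identity seen between closely related strains.
synthetic_esx1_pair <- function(seed = 42) {
  L <- 33000L
  base <- random_dna(L, seed = seed, gc = 0.67)
  # plus-strand CDS [6000, 7500); plant CGC codon at codon index 100
  cds1_start <- 6000L
  arg_codon_at <- cds1_start + 300L # 0-based start of the codon
  # plus-strand CDS [20000, 21200); plant CTC codon at codon offset 150
  cds2_start <- 20000L
  leu_codon_at <- cds2_start + 450L
  base <- `substr<-`(base, arg_codon_at + 1L, arg_codon_at + 3L, "CGC")
  base <- `substr<-`(base, leu_codon_at + 1L, leu_codon_at + 3L, "CTC")
  locus_a <- base
  locus_b <- base
  # G->C at codon position 2 of CGC -> CCC (Arg->Pro, missense)
  substr(locus_b, arg_codon_at + 2L, arg_codon_at + 2L) <- "C"
  # C->T at codon position 3 of CTC -> CTT (Leu, silent)
  substr(locus_b, leu_codon_at + 3L, leu_codon_at + 3L) <- "T"
  features <- tibble::tibble(
    name = c("msmeg0067_like", "eccE_like"),
    start = c(cds1_start, cds2_start),
    end = c(cds1_start + 1500L, cds2_start + 1200L),
    strand = c("+", "+")
  )
  list(
    locus_a = locus_a, locus_b = locus_b, features = features,
    missense_pos = arg_codon_at + 1L, # 0-based position of the substitution
    silent_pos = leu_codon_at + 2L
  )
}

# Deposited-genome files (GenBank accessions) are looked for here; they are
# not bundled and must be supplied by the user for real-data checks.
deposited_path <- function(file) {
  file.path(system.file("extdata", package = "dctpaint"), "accessions", file)
}
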