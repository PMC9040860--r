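# Independent brute-force oracles, deliberately naive and separate from the
# package's own code paths.

# position-by-position mismatch count; N mismatches everything, including N
hamming_oracle <- function(a, b) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  stopifnot(length(ca) == length(cb))
  sum(ca != cb | ca == "N" | cb == "N")
}

# per-window identity by direct substring comparison
window_identity_oracle <- function(query, subject, starts0, ends0) {
  vapply(seq_along(starts0), function(i) {
    qa <- substr(query, starts0[i] + 1, ends0[i])
    qb <- substr(subject, starts0[i] + 1, ends0[i])
    1 - hamming_oracle(qa, qb) / nchar(qa)
  }, numeric(1))
}

# exhaustive best-locus edit distance of a window against every start
# position of a parent sequence
sliding_edit_oracle <- function(window, parent) {
  W <- nchar(window)
  starts <- seq_len(nchar(parent) - W + 1)
  min(vapply(starts, function(s) {
    as.integer(utils::adist(window, substr(parent, s, s + W - 1)))
  }, integer(1)))
}

# Gotoh global alignment score with affine gaps (gap of length k costs
# gap_open + k * gap_extend), scored with a Biostrings substitution matrix.
# Score-only dynamic program over the full (n+1) x (m+1) lattice.
gotoh_score_oracle <- function(a, b, mat, gap_open = 10, gap_extend = 0.5) {
  va <- strsplit(a, "")[[1]]
  vb <- strsplit(b, "")[[1]]
  n <- length(va); m <- length(vb)
  neg <- -1e18
  M <- matrix(neg, n + 1, m + 1)
  E <- matrix(neg, n + 1, m + 1) # gap in b (vertical)
  F_ <- matrix(neg, n + 1, m + 1) # gap in a (horizontal)
  M[1, 1] <- 0
  for (i in 2:(n + 1)) E[i, 1] <- -(gap_open + (i - 1) * gap_extend)
  for (j in 2:(m + 1)) F_[1, j] <- -(gap_open + (j - 1) * gap_extend)
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- mat[va[i - 1], vb[j - 1]]
      M[i, j] <- max(M[i - 1, j - 1], E[i - 1, j - 1], F_[i - 1, j - 1]) + s
      E[i, j] <- max(M[i - 1, j] - gap_open - gap_extend, E[i - 1, j] - gap_extend)
      F_[i, j] <- max(M[i, j - 1] - gap_open - gap_extend, F_[i, j - 1] - gap_extend)
    }
  }
  max(M[n + 1, m + 1], E[n + 1, m + 1], F_[n + 1, m + 1])
}

# majority vote of per-base ground-truth origin over the informative sites
# (positions where the parents differ) inside each window
truth_vote_oracle <- function(truth, variants, starts0, ends0) {
  site_pos <- variants$position
  origin_at <- function(p) {
    truth$origin[truth$start <= p & truth$end > p]
  }
  site_origin <- vapply(site_pos, origin_at, character(1))
  vapply(seq_along(starts0), function(i) {
    sel <- site_pos >= starts0[i] & site_pos < ends0[i]
    if (sum(sel) == 0) return(NA_character_)
    votes <- table(site_origin[sel])
    names(votes)[which.max(votes)]
  }, character(1))
}
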