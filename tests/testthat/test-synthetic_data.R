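test_that("parent pairs carry exactly the requested substitution load", {
  pair <- generate_parent_pair(100000, 0.01, seed = 7)
  expect_equal(nrow(pair$variants), 1000L)
  expect_equal(pair$recipient$length_bp, pair$donor$length_bp)
  expect_equal(hamming_oracle(pair$recipient$sequence, pair$donor$sequence), 1000L)

  # density too low to realise a single variant is an error
  expect_error(generate_parent_pair(100000, 4e-6, seed = 1), "no variants")
})

test_that("planted variants agree with a brute-force base-by-base recount", {
  pair <- generate_parent_pair(50000, 0.001, seed = 1)
  expect_equal(nrow(pair$variants), 50L)
  expect_equal(hamming_oracle(pair$recipient$sequence, pair$donor$sequence), 50L)
  # every listed site really differs, every unlisted site matches
  ca <- strsplit(pair$recipient$sequence, "")[[1]]
  cb <- strsplit(pair$donor$sequence, "")[[1]]
  expect_equal(which(ca != cb) - 1L, pair$variants$position)
  expect_equal(ca[pair$variants$position + 1L], pair$variants$base_a)
  expect_equal(cb[pair$variants$position + 1L], pair$variants$base_b)
})

test_that("a cross with no transfer reproduces the recipient", {
  pair <- generate_parent_pair(20000, 0.01, seed = 2)
  cross <- simulate_transconjugant(pair$recipient, pair$donor,
                                   n_segments = 0, seed = 3)
  expect_identical(cross$transconjugant$sequence, pair$recipient$sequence)
  expect_equal(nrow(cross$truth), 1L)
  expect_equal(cross$truth$start, 0L)
  expect_equal(cross$truth$end, 20000L)
  expect_equal(cross$truth$origin, pair$recipient$name)
  expect_equal(cross$config$donor_fraction, 0)
})

test_that("donor tracts carry donor bases exactly over their intervals", {
  pair <- generate_parent_pair(50000, 0.01, seed = 4)
  cross <- simulate_transconjugant(pair$recipient, pair$donor,
                                   segment_lengths = 10000, n_segments = 1,
                                   target_donor_fraction = NULL, seed = 5)
  seg <- cross$truth[cross$truth$origin == pair$donor$name, ]
  expect_equal(nrow(seg), 1L)
  tc <- cross$transconjugant$sequence
  expect_identical(substr(tc, seg$start + 1, seg$end),
                   substr(pair$donor$sequence, seg$start + 1, seg$end))
  out <- cross$truth[cross$truth$origin == pair$recipient$name, ]
  for (i in seq_len(nrow(out))) {
    expect_identical(substr(tc, out$start[i] + 1, out$end[i]),
                     substr(pair$recipient$sequence, out$start[i] + 1, out$end[i]))
  }
})

test_that("per-base origins match the ground truth at every informative site", {
  pair <- generate_parent_pair(500000, 0.01, seed = 3)
  cross <- simulate_transconjugant(pair$recipient, pair$donor,
                                   n_segments = 10,
                                   segment_length_range = c(2000, 30000),
                                   target_donor_fraction = NULL, seed = 3)
  # realized donor fraction recomputed from truth
  donor_bp <- with(cross$truth, sum((end - start)[origin == pair$donor$name]))
  expect_equal(cross$config$donor_fraction, donor_bp / cross$transconjugant$length_bp)
  # at each site where the parents differ, the transconjugant base determines
  # its origin; it must agree with the truth tiling
  tc <- strsplit(cross$transconjugant$sequence, "")[[1]]
  v <- pair$variants
  base_at <- tc[v$position + 1L]
  in_donor <- vapply(v$position, function(p) {
    any(cross$truth$start <= p & cross$truth$end > p &
        cross$truth$origin == pair$donor$name)
  }, logical(1))
  expect_identical(base_at[in_donor], v$base_b[in_donor])
  expect_identical(base_at[!in_donor], v$base_a[!in_donor])
})

test_that("truth segments tile the transconjugant exactly, marker included", {
  pair <- generate_parent_pair(60000, 0.01, seed = 8)
  cross <- simulate_transconjugant(pair$recipient, pair$donor, n_segments = 3,
                                   segment_length_range = c(1000, 5000),
                                   target_donor_fraction = NULL,
                                   marker = list(length_bp = 1500), seed = 9)
  truth <- cross$truth
  expect_equal(truth$start[1], 0L)
  expect_equal(truth$end[nrow(truth)], cross$transconjugant$length_bp)
  expect_equal(truth$start[-1], truth$end[-nrow(truth)])
  expect_equal(cross$transconjugant$length_bp, 60000L + 1500L)
  mk <- truth[truth$origin == "marker", ]
  expect_equal(mk$end - mk$start, 1500L)
  expect_equal(mk$start, round(8 / 12 * 60000))
  # every non-marker truth segment maps back onto its parent's sequence in
  # the original (pre-insertion) frame
  tc <- cross$transconjugant$sequence
  shift <- ifelse(truth$start >= mk$end, 1500L, 0L)
  for (i in which(truth$origin != "marker")) {
    parent_seq <- if (truth$origin[i] == pair$donor$name) {
      pair$donor$sequence
    } else {
      pair$recipient$sequence
    }
    expect_identical(
      substr(tc, truth$start[i] + 1L, truth$end[i]),
      substr(parent_seq, truth$start[i] + 1L - shift[i], truth$end[i] - shift[i])
    )
  }
})

test_that("simulation is byte-identical under a fixed seed", {
  a <- generate_parent_pair(20000, 0.01, seed = 11)
  b <- generate_parent_pair(20000, 0.01, seed = 11)
  expect_identical(a$recipient$sequence, b$recipient$sequence)
  expect_identical(a$donor$sequence, b$donor$sequence)
  expect_identical(a$variants, b$variants)
  ca <- simulate_transconjugant(a$recipient, a$donor, n_segments = 4, seed = 12,
                                segment_length_range = c(1000, 3000),
                                target_donor_fraction = NULL)
  cb <- simulate_transconjugant(b$recipient, b$donor, n_segments = 4, seed = 12,
                                segment_length_range = c(1000, 3000),
                                target_donor_fraction = NULL)
  expect_identical(ca$transconjugant$sequence, cb$transconjugant$sequence)
  expect_identical(ca$truth, cb$truth)
})

test_that("impossible placements fail with a placement error", {
  pair <- generate_parent_pair(10000, 0.01, seed = 13)
  expect_error(
    simulate_transconjugant(pair$recipient, pair$donor, n_segments = 3,
                            segment_lengths = c(5000, 4000, 3000),
                            target_donor_fraction = NULL, seed = 1),
    "placement failure"
  )
})
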