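test_that("window tiling follows the half-window tail rule", {
  w <- tile_windows(2000, 500)
  expect_equal(w$start, c(0L, 500L, 1000L, 1500L))
  expect_equal(w$end, c(500L, 1000L, 1500L, 2000L))

  # 300-bp tail >= W/2: kept as its own window
  w <- tile_windows(1300, 500)
  expect_equal(nrow(w), 3L)
  expect_equal(w$start[3], 1000L)
  expect_equal(w$end[3], 1300L)

  # 100-bp tail < W/2: merged into the last full window
  w <- tile_windows(1100, 500)
  expect_equal(nrow(w), 2L)
  expect_equal(w$end[2], 1100L)

  expect_error(tile_windows(400, 500), "genome shorter than window")
})

test_that("aligned-mode identities equal brute-force Hamming identity", {
  # direct arithmetic case: 5 mismatches to recipient, 0 to donor
  donor <- random_dna(500, seed = 21)
  recipient <- donor
  for (p in c(10, 100, 250, 400, 499)) substr(recipient, p, p) <- "N"
  s <- score_windows_aligned(donor, recipient, donor,
                             tibble::tibble(start = 0L, end = 500L))
  expect_equal(s$identity_recipient, 0.99)
  expect_equal(s$identity_donor, 1.0)

  # property: equality with the oracle on all windows of seeded instances
  for (seed in 1:5) {
    pair <- generate_parent_pair(20000, 0.01, seed = seed)
    cross <- simulate_transconjugant(pair$recipient, pair$donor, n_segments = 3,
                                     segment_length_range = c(1000, 4000),
                                     target_donor_fraction = NULL, seed = seed + 100)
    sc <- score_windows_aligned(cross$transconjugant, pair$recipient, pair$donor)
    expect_equal(
      sc$identity_recipient,
      window_identity_oracle(cross$transconjugant$sequence,
                             pair$recipient$sequence, sc$start, sc$end)
    )
    expect_equal(
      sc$identity_donor,
      window_identity_oracle(cross$transconjugant$sequence,
                             pair$donor$sequence, sc$start, sc$end)
    )
  }
})

test_that("unequal frames are rejected in aligned mode", {
  expect_error(score_windows_aligned("ACGTACGTAC", "ACGT", "ACGTACGTAC"),
               "frame mismatch")
})

test_that("mapping-mode identity finds the best locus by seeded edit distance", {
  parent <- random_dna(3000, seed = 31)
  # verbatim window
  win <- substr(parent, 1001, 1500)
  expect_equal(score_window_mapping(win, parent), 1.0)

  # window with 3 substitutions: identity 1 - 3/500
  win3 <- win
  for (p in c(50, 250, 450)) {
    old <- substr(win3, p, p)
    substr(win3, p, p) <- setdiff(c("A", "C", "G", "T"), old)[1]
  }
  got <- score_window_mapping(win3, parent)
  expect_equal(got, 1 - 3 / 500)
  expect_equal(got, 1 - sliding_edit_oracle(win3, parent) / 500)

  # random window absent from the parent: no seeds, identity 0
  alien <- random_dna(500, seed = 99, gc = 0.2)
  expect_equal(score_window_mapping(alien, parent), 0)
})

test_that("origin assignment applies the tie-inheritance rule", {
  w <- tibble::tibble(
    start = c(0L, 500L, 1000L), end = c(500L, 1000L, 1500L),
    identity_recipient = c(1.0, 1.0, 0.99),
    identity_donor = c(0.99, 1.0, 1.0)
  )
  out <- classify_windows(w, background = "recipient")
  expect_equal(out$origin, c("recipient", "recipient", "donor"))
  expect_equal(out$ambiguous_inherited, c(FALSE, TRUE, FALSE))

  # first window ambiguous: falls back to the declared background
  w1 <- tibble::tibble(start = 0L, end = 500L,
                       identity_recipient = 1.0, identity_donor = 1.0)
  out1 <- classify_windows(w1, background = "recipient")
  expect_equal(out1$origin, "recipient")
  expect_true(out1$ambiguous_inherited)
  out1d <- classify_windows(w1, background = "donor")
  expect_equal(out1d$origin, "donor")

  # below tau on both sides: unassigned, and it does not update the carry
  w2 <- tibble::tibble(
    start = c(0L, 500L, 1000L), end = c(500L, 1000L, 1500L),
    identity_recipient = c(0.95, 0.2, 0.97),
    identity_donor = c(0.91, 0.25, 0.97)
  )
  out2 <- classify_windows(w2)
  expect_equal(out2$origin, c("recipient", "unassigned", "recipient"))

  expect_error(
    classify_windows(tibble::tibble(
      start = c(500L, 0L), end = c(1000L, 500L),
      identity_recipient = c(1, 1), identity_donor = c(0.9, 0.9)
    )),
    "not tiled"
  )
})

test_that("painted origins agree with the ground-truth majority vote", {
  pair <- generate_parent_pair(2e6, 0.01, seed = 11)
  cross <- simulate_transconjugant(pair$recipient, pair$donor, n_segments = 8,
                                   segment_length_range = c(2000, 40000),
                                   target_donor_fraction = NULL, seed = 11)
  p <- paint_genome(cross$transconjugant, pair$recipient, pair$donor)
  votes <- truth_vote_oracle(cross$truth, pair$variants,
                             p$windows$start, p$windows$end)
  # compare wherever the window holds at least 5 informative sites
  n_sites <- snv_density_track(pair$variants, 500, 2e6)$count
  strong <- !is.na(votes) & n_sites >= 5
  mapped <- ifelse(votes == pair$donor$name, "donor", "recipient")
  expect_identical(p$windows$origin[strong], mapped[strong])
})

test_that("adding donor-specific variants never raises recipient identity", {
  recipient <- random_dna(5000, seed = 41)
  donor <- recipient
  win <- tile_windows(5000, 500)
  prev <- rep(1, nrow(win))
  positions <- withr::with_seed(42, sample.int(5000, 60))
  for (i in seq(10, 60, by = 10)) {
    donor2 <- recipient
    for (p in positions[1:i]) {
      substr(donor2, p, p) <- setdiff(c("A", "C", "G", "T"), substr(recipient, p, p))[1]
    }
    s <- score_windows_aligned(donor2, recipient, donor2, win)
    expect_true(all(s$identity_recipient <= prev + 1e-12))
    prev <- s$identity_recipient
  }
})

test_that("marker-cassette windows are unassigned in mapping mode", {
  pair <- generate_parent_pair(30000, 0.01, seed = 51)
  cross <- simulate_transconjugant(pair$recipient, pair$donor, n_segments = 1,
                                   segment_lengths = 4000,
                                   target_donor_fraction = NULL,
                                   marker = list(length_bp = 1500), seed = 52)
  p <- paint_genome(cross$transconjugant, pair$recipient, pair$donor,
                    mode = "mapping")
  mk <- cross$truth[cross$truth$origin == "marker", ]
  core <- p$windows$start >= mk$start & p$windows$end <= mk$end
  expect_true(any(core))
  expect_true(all(p$windows$origin[core] == "unassigned"))
  expect_lt(p$report$pct_recipient + p$report$pct_donor, 100)
})
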