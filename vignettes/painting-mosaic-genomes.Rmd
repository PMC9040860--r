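---
title: "Painting mosaic genomes produced by distributive conjugal transfer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Painting mosaic genomes produced by distributive conjugal transfer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dctpaint)
```

## The problem

Mycobacteria exchange chromosomal DNA by distributive conjugal transfer
(DCT): a recipient cell acquires multiple, noncontiguous segments of the
donor chromosome, which recombine with homologous recipient sequence. The
progeny ("transconjugant") genome is therefore a mosaic — a recipient
backbone punctuated by donor-derived tracts. Because conjugal M. smegmatis
strains are collinear and differ by abundant point substitutions (on the
order of 1 SNV per 100 nt for distant pairs, 1 per kb for close ones),
parental origin can be read directly off the transconjugant sequence:
every position where the parents differ is an informative site.

`dctpaint` implements this chromosome-painting analysis end to end, plus a
simulator that produces transconjugants with known ground truth so every
stage is testable without sequencing data.

## The painting procedure

1. **Tiling.** The transconjugant is cut into nonoverlapping windows of
   `window_bp` (default 500 bp, the width at which transferred-region
   counts and largest-region sizes are conventionally quoted). A final
   partial window shorter than half a window is merged into its neighbour,
   so the tiling always covers the genome exactly. Windows never wrap the
   replication origin: the scan is linear even for circular chromosomes,
   which is what makes reported largest-region sizes multiples of the
   window width.
2. **Scoring.** Each window receives an identity score against each
   parent. In *aligned* mode (collinear genomes in one coordinate frame)
   identity is exact per-position identity, `1 - mismatches / W` — the
   limit of a fragment-mapping ANI score when the mapping is known. In
   *mapping* mode, for genomes that are not perfectly collinear, the
   window is located in each parent by shared k-mer seeding (k = 16) and
   scored as `1 - edit_distance / W` against the best candidate locus;
   a window with no seed hits scores 0. `N` counts as a mismatch to every
   parental base (conservative and deterministic).
3. **Assignment.** The parent with strictly greater identity wins. A
   window with 100% identity to both parents is uninformative and inherits
   the origin of the nearest preceding assigned window; the same one-step
   lookback is applied to the (rare) tied identities below 100%, and such
   windows are flagged `ambiguous_inherited`. A window below the minimum
   identity `min_identity` (default 0.9) to both parents is `unassigned`.
4. **Segmentation.** Maximal runs of same-origin windows are concatenated
   into segments; donor segments at least one window long are counted as
   transferred regions, and per-parent percentages are reported to two
   decimals against the transconjugant length.

The one-step lookback is deliberate: it is the published rule for
uninformative windows, not a hidden-Markov smoother, and we keep it that
way for fidelity. It also means a transferred tract is only detectable if
at least one of its windows contains an informative site; at the default
density of 0.01 substitutions per bp a 500-bp window is empty of
informative sites with probability ≈ `0.99^500` ≈ 0.7%, so tracts
spanning two or more windows are recovered essentially always.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `window_bp` | 500 bp | tiling width; sets the resolution of segment boundaries (±1 window) and the granularity of largest-region sizes |
| `min_identity` | 0.9 | identity below which a window is unassigned; creates the class that absorbs marker cassettes and diverged tracts, which is why per-parent percentages can sum to slightly under 100 |
| `mode` | aligned | aligned (exact, collinear frames) vs mapping (seeded best-locus edit distance) |
| `background` | recipient | origin used when the very first windows are already ambiguous; the published genomes begin in conserved sequence, so the choice is inert in practice |
| `k` | 16 | seed length in mapping mode; 16-mers are effectively unique in a 7-Mb genome |

`min_identity = 0.9` is far below any identity an informative window can
take at realistic densities (a 500-bp window at 1 SNV/100 nt averages
0.99 identity to one parent), and far above the ~0.25 identity of random
sequence: the threshold separates "belongs to neither parent" from
"belongs to one of them" with a wide margin, and results are insensitive
to it across 0.5–0.98.

## What the simulator emulates

`generate_parent_pair()` draws a GC-rich (67% G+C by default) genome and
derives a second, collinear genome by substituting `round(d·L)` uniformly
placed sites — the substitution-only divergence model under which the
painting analysis operates. Defaults for `d` follow the two observed
regimes: 0.01 (distant pair) and 0.001 (close pair).

`simulate_transconjugant()` replaces `k` noncontiguous recipient
intervals with the donor's bases. Defaults are chosen to match observed
crosses: `k` is drawn with mean 16 (zero-truncated Poisson); segment
lengths are log-uniform on 1–250 kb, bracketing the observed
1,000–260,500 bp range of transferred regions — the true tract-length
distribution is not known, so this is a stand-in, not an inference; the
realised donor fraction is steered into the observed 1–12% range by
sampling a target fraction uniformly and rescaling the drawn length set
(rejection sampling was rejected: for a 2-Mb genome with 16 log-uniform
segments the acceptance region has negligible probability). Placed
segments are kept at least one window apart (configurable) so planted
event counts are unambiguous. An optional marker cassette — 1.5 kb of
random sequence matching neither parent, by default at ~8/12 of the
genome, emulating an antibiotic-resistance insertion — is inserted rather
than substituted; because insertion breaks the shared coordinate frame,
marker-bearing simulations are classified in mapping mode.

What the simulator does *not* model: indels and rearrangements between
parents (an indel-bearing comparison must come pre-aligned or use mapping
mode), IS-element dynamics, mutation spectra, selection, and shared
ancestral mosaicism between the parents themselves. Passing tests on
synthetic data therefore demonstrate the correctness of the painting
machinery under the substitution-only model, not the full messiness of
real assemblies — which is why the accession-backed checks on deposited
genomes exist separately (they require the user to supply the deposited
FASTA files; see `tests/testthat/test-acceptance.R`).

## Numerical choices and degenerate inputs

* All coordinates are 0-based half-open everywhere (BED-compatible);
  1-based coordinates appear only when echoing published positions and
  are labelled.
* Percentages are rounded to two decimals at the report boundary only;
  internal arithmetic is exact.
* Cohort mean event counts round halves away from zero (so 15.5 → 16),
  not to even.
* `N` is a mismatch to everything, including another `N`; SNV tables skip
  positions where either base is `N`.
* A genome shorter than one window is an error, not an empty tiling.
* Tie-breaks: equal identities inherit the previous assigned origin; the
  first window of a genome falls back to the declared background parent.
* Segment placement failing 1,000 rejection attempts raises a placement
  error rather than silently reducing `k`.
* Locus SNV catalogues compare equal-length loci positionally; unequal
  lengths go through indel-tolerant global alignment (capped at 50 kb, the
  practical limit of dense dynamic programming), and an alignment identity
  below 80% is refused rather than catalogued.

## Problem sizes used in the test-suite and acceptance runs

Property checks run on 2-Mb genomes at 0.01 substitutions/bp — large
enough that every window statistic is in its asymptotic regime (4,000
windows, ~20,000 informative sites) while a 50-simulation recovery study
completes in under a minute. Oracle-equivalence checks (brute-force
Hamming, exhaustive sliding edit distance, independent Gotoh alignment
DP) use 20-kb genomes and ~60-residue proteins, where exhaustive
recomputation is cheap. These sizes are the package's own choice of
study conditions for validation.

## Known limitations

* Exactly two candidate parents; no multi-way painting.
* No HMM smoothing (by design, see above): single uninformative windows
  inside a tract are carried by the lookback rule, but a tract whose
  *every* window lacks informative sites is invisible.
* Mapping mode evaluates the top-voted seed candidates only; a window
  whose true locus shares no 16-mer with it (≥ ~3% divergence scattered
  every 16 bp) can score 0.
* Real-data SNV counts restricted to ortholog sets depend on the
  annotation pipeline that produced them and are out of scope; `dctpaint`
  counts SNVs on alignable sequence.
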