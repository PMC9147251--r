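---
title: "Quantifying micro-modular homology between genomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying micro-modular homology between genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(micromod)
```

## The question

When two genomes with no common ancestry worth speaking of — say a
coronavirus RNA genome and a bacterial chromosome — are aligned, the
alignment is far from featureless.  It shows *micro-modular homology*:
short runs of 3 to roughly 13 identical nucleotides, alternating with
non-matching stretches in a "patchy" pattern, and local windows in which
the overall identity climbs into the mid-40-percent range.  With a
four-letter alphabet most of this structure is statistically expected, and
that is precisely why it is interesting: any two genomes, related or not,
carry an abundant reservoir of short perfectly-complementary patches that
can anneal, and such patches are known signals at sites of integrative
recombination.

`micromod` quantifies this structure reproducibly.  It aligns nucleotide
sequences under an affine-gap model, extracts the per-column match mask,
summarizes it as an identity-run-length spectrum and a patch string,
selects locally maximal "frames", scans megabase subjects in chunks, and —
crucially — calibrates everything against composition-matched randomized
genomes, with shuffle-based Gumbel significance for alignment scores.

## The alignment model and its dialect

Alignments use the standard three-state (Gotoh) affine-gap dynamic
program.  A gap of $k$ columns costs $g_o + (k-1)\,g_e$; matches score
$+1.9$ and mismatches $0$, the classic DNA weights of the ClustalW family
of aligners from which the original analyses' commercial tool descends.
`N` never counts as a match and scores as a mismatch, so "identity" always
means literal identity of unambiguous letters.

Two decisions deserve emphasis, because the headline percentages depend on
them:

* **Identity denominator.**  `alignment_identity()` divides match columns
  by *all* alignment columns, including gap and free end-gap columns.
  This is the only denominator under which whole-genome ("overall") and
  segment percentages are commensurable, and it is the denominator that
  places composition-matched random 30-kb pairs in the observed control
  band (below).  For a short frame aligned inside a long subject the
  `"footprint"` scope restricts to the columns the frame actually spans.

* **Gap-penalty dialect (`gap_scale`).**  Tools of the ClustalW family
  display gap penalties (here 15 for opening, 6.66 for extension) but do
  not apply them as raw score units; they rescale them internally against
  the substitution matrix.  Taken literally, open 15 / extend 6.66 with a
  $+1.9/0$ matrix makes gaps so expensive that random 30-kb
  composition-matched pairs align at only ~31–33% identity — nowhere near
  the published randomized-control band of 44.3–44.8%.  `micromod`
  therefore keeps the displayed penalties as the user-facing parameters
  and applies a single dialect factor `gap_scale` to both.  The default
  `gap_scale = 0.25` (effective open 3.75, extend 1.665) was fixed once,
  by requiring that exact-composition random 30-kb pairs reproduce the
  randomized-control band — the same internal calibration standard the
  original control series provides.  With it, five random replicates give
  identities of about 44.3–44.9 with a mean within a few tenths of 44.5.
  Setting `gap_scale = 1` recovers the literal reading.  The exact
  match/mismatch weights behind the original tool's displayed percentages
  are not recoverable from published material, so agreement to fractions
  of a percentage point is dialect luck, not a claim.

End gaps are free by default in global mode (`end_gaps_free = TRUE`):
genome segments of unequal length must be allowed to overhang, otherwise
an "overall" homology of a 30-kb genome against a 170-kb genome could not
be a single-digit percentage.  The free end-gap columns still count in the
identity denominator.

Tie-breaks in the traceback are fixed (diagonal over gap-in-`a` over
gap-in-`b`), so every alignment is deterministic — a requirement for
reproducible spectra, not a biological statement.

### Exact, local and seeded modes

`align_global()` runs the full matrix and refuses problems above the DP
budget (default $2\times10^8$ cells, `options(micromod.dp_budget=)`).
`align_local()` is Smith–Waterman–Gotoh with the classic $+5/-4$ local
weights (a mismatch score of 0 would make local alignment degenerate,
since its expected column score must be negative).  `align_seeded()`
handles long pairs: 2-mer word matches are binned by diagonal
(Wilbur–Lipman), smoothed over a 9-diagonal window, and diagonals whose
hit counts exceed the composition-based expectation by six standard
deviations are retained (at most `best_diagonals`); the affine DP then
runs in a band around those diagonals plus the corner-to-corner
diagonals, padded by 3% of the shorter sequence.  Measured off-diagonal
drift of optimal paths on random 30-kb pairs is ~0.5–1.5% of the length,
so the band contains the exact optimum in practice; on 1.5-kb random
pairs the seeded and exact scores agree exactly in the test suite, and in
general the seeded score is a lower bound.

## Run spectra, patch strings, frames

The match mask of an alignment is summarized by `run_spectrum()`: counts
of maximal runs of consecutive match columns by exact length, with a
pooled bin above `max_tracked = 13` (the longest cluster the cross-genome
comparisons reach).  A single mismatch *or gap* column terminates a run;
interrupted near-runs (e.g. a 10-mer with one interruption) are *not*
merged — they remain visible in the `patch_string()` encoding, which
renders each run as its decimal length and each non-match column as one
dot (`"2.3."` for mask `1101110`), losslessly.

Bar-graph percentages follow the percent-of-total convention:
`spectrum_percentages()` expresses the counts at $k \ge 3$ (including the
pooled bin) as percentages of their total.  1- and 2-mers are tracked but
excluded, as in the published graphs.

`find_top_frames()` implements segment selection: a 550-nt frame (the
scale of the published screen shots) slides in 25-nt steps, each frame is
aligned in seeded mode, and frames are ranked by footprint identity.
`scan_genome()` applies this per chunk of a long subject (default 50-kb
chunks overlapping by one frame length, so no candidate frame is lost at
a seam) and keeps the best frame's spectrum per chunk.  Whether published
bar-graph counts were taken over ~550-nt frames or over full alignments
is not documented; both scopes are computable here, and the package makes
the scope explicit in every result.

## The randomized null

`random_sequence()` draws a uniformly random permutation of the exact
letter multiset of a template composition — composition is conserved
*exactly*, which makes conservation a testable invariant rather than an
approximation.  `sarscov2_composition()` ships the published base counts
of the 29,903-nt Wuhan reference (A 8954, C 5492, G 5863, T 9594); the
control analyses build synthetic stand-in references from it rather than
shipping genome records.  `shuffle_sequence()` permutes an existing
sequence (globally or within windows).  A dinucleotide-preserving shuffle
is deliberately out of scope for now; nothing suggests the original
shuffle test used one.

`shuffle_significance()` mirrors standard shuffle-test practice: the
observed local alignment score of query against subject is compared with
local scores of shuffled queries, a Gumbel law is fitted to the null
sample (method of moments, refined by maximum likelihood), and the
upper-tail p-value is reported.  The E-value equals the p-value — a
single-comparison convention, stated openly; no database-size multiplier
is applied.  With 100–1000 shuffles, unrelated composition-matched
600-nt pairs give E-values spread over roughly 0.005–0.9 with a median
near 0.5, matching the published non-significance band (range 0.2–1,
median 0.53) for random controls.

`expected_run_counts()` provides the closed-form expectation of maximal
run counts in an i.i.d. Bernoulli mask — the independent oracle against
which simulated spectra are tested (three match probabilities, 200
replicates of length 10,000, agreement within three standard errors).

## What the synthetic data do and do not show

The generator emulates the published control conditions: uniformly random
sequences of 29,903 nt with the exact Wuhan base composition, plus
shuffled permutations of given sequences.  It does not emulate real
genome features — codon structure, dinucleotide bias (notably CpG
depletion), repeats, or conserved elements.  Tests passing on synthetic
data therefore validate the *machinery* and the *null calibration*; they
show that the mid-40s identity band and the 3-to-10-mer spectrum shape
are properties of the four-letter alphabet plus composition, which is the
control result.  They cannot certify the five printed segment homologies
of specific NCBI records; that comparison runs only when the user
supplies those records (see the acceptance test), since genome records
are not redistributable inside the package and the original accession
list is not in the main text.

## Numerical choices and degenerate inputs

* Scores are doubles; ties are resolved by the fixed state preference,
  never by floating-point accident at equal scores.
* An empty local alignment (no positive-scoring pair) is a score of 0
  with empty spans, not an error.
* `spectrum_percentages()` of a spectrum with no run at $k \ge 3$ returns
  a zero-row table rather than dividing by zero.
* `fit_evd()` refuses fewer than 30 scores and constant score vectors.
* `chunk_genome()` of a sequence shorter than one chunk returns the
  single full-span interval.
* Ambiguity letters other than `N` are rejected with their position
  (strict mode) or mapped to `N` (`lenient = TRUE`); the analysis treats
  only A/C/G/T identity.
* Desk-scale problem sizes used throughout the tests and the acceptance
  script — 5 control replicates, 50 ensemble pairs, 100 shuffles, 600-nt
  shuffle subjects — were chosen as the package's default desk scale;
  full-fidelity sizes (1000 sequences, 1000 shuffles) are a matter of
  compute time only and use the same code paths.

## A worked example

```{r example, eval = FALSE}
prof <- sarscov2_composition()
ref <- random_sequence(29903, prof, seed = 101, id = "synthetic_reference")
r1  <- random_sequence(29903, prof, seed = 1, id = "random_1")

aln <- align_seeded(r1, ref)
alignment_identity(aln)          # ~44.5 — the randomized-control band

sp <- run_spectrum(aln)
spectrum_percentages(sp)         # 3-mers modal, steep decay to 8-mers
autoplot(sp)

substr(patch_string(aln), 1, 60) # "..2.1...3.1..." patch notation

null <- shuffle_significance(random_sequence(600, prof, 5),
                             random_sequence(600, prof, 6),
                             n_shuffles = 100, seed = 7)
glance(null)                     # E-value in the non-significance band
```

## Known limitations

* The vendor aligner's exact scoring is unknowable; `gap_scale` is a
  calibrated dialect, and printed per-segment percentages are reproduced
  only within an aligner-dialect tolerance of a couple of percentage
  points.
* Seeded mode guarantees a lower bound on the exact score, not equality,
  when true homology lies far off the retained diagonals *and* off the
  corner-to-corner band.
* No multiple alignment, no protein alignment, no substitution matrices:
  every analysis here is pairwise and nucleotide-level; peptide support
  is limited to shared-k-mer queries.
* Exact DP memory is one byte per cell; a full 30-kb x 30-kb exact
  alignment transiently needs ~1.8 GB, which is why long pairs default to
  the banded seeded mode.
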