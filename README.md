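# micromod

Micro-modular homology analysis of genome sequences.

When any two nucleotide sequences are aligned — even a viral RNA genome
against a bacterial chromosome, or against a computer-randomized sequence —
the alignment shows short runs of 3–13 identical nucleotides alternating
with non-matching stretches ("patchy" homology), and selected windows whose
identity reaches the mid-40-percent range. This structure is statistically
inherent in the four-letter alphabet, and short perfectly-complementary
patches of this kind are known signals at sites of integrative
recombination. `micromod` measures it reproducibly and calibrates it
against composition-matched randomized genomes.

## What it computes

* **Affine-gap pairwise alignment** (Gotoh three-state DP, Rcpp core) in
  exact global, local (Smith–Waterman) and seeded/banded modes, with free
  end gaps, deterministic tie-breaks, and a calibrated scoring dialect:
  match +1.9, mismatch 0, tool-level gap penalties 15 / 6.66 scaled by
  `gap_scale = 0.25` (see the vignette for why the displayed penalties are
  not raw score units).
* **Identity-run spectra**: counts of maximal match runs by exact length
  k = 1..13 plus a pooled bin, percent-of-total bar-graph tables, patch
  strings (`"2.3."` = a 2-mer, a non-match, a 3-mer, a non-match).
* **Frame selection and genome scans**: sliding 550-nt frames ranked by
  identity, and chunked scans of megabase subjects with per-segment
  spectra.
* **Randomized nulls**: exact-composition random genomes, global/windowed
  shuffles, Gumbel (type-I extreme value) significance of local alignment
  scores from shuffle nulls, and randomized-pair ensembles.
* A thin command-line interface (`inst/scripts/micromod.R`) over the same
  functions: `align`, `frames`, `random`, `shuffle`, `null`, `ensemble`,
  `scan`.

The identity percentage of an alignment is matches divided by **all**
columns, gap columns included — the convention that makes whole-genome and
segment homologies comparable and places randomized controls at ~44.5%.

## A worked example

```r
library(micromod)

prof <- sarscov2_composition()   # published Wuhan base counts, 29,903 nt
ref  <- random_sequence(29903, prof, seed = 101, id = "synthetic_reference")
r1   <- random_sequence(29903, prof, seed = 1,   id = "random_1")

aln <- align_seeded(r1, ref)
aln
#> <mm_alignment> random_1 vs synthetic_reference (seeded): 30809 columns,
#>   13863 matches (45.0%), score 21039.23

spectrum_percentages(run_spectrum(aln))
#> # A tibble: 12 x 3
#>   k     count percent
#>   <chr> <int>   <dbl>
#> 1 3       876  60.7
#> 2 4       351  24.3
#> 3 5       142   9.83
#> 4 6        59   4.09
#> ...
```

Two *unrelated random* 30-kb sequences of the same base composition align
at ~45% identity, and their shared identity-runs decay steeply from
3-mers (the modal class, ~61% of runs ≥ 3) through 8-mers, with runs above
10 rare — the randomized-control picture that any observed cross-genome
patchiness must be judged against. A shuffle test of the same kind of pair
gives a non-significant E-value near 0.5:

```r
null <- shuffle_significance(random_sequence(600, prof, 5),
                             random_sequence(600, prof, 6),
                             n_shuffles = 100, seed = 7)
glance(null)
#> # A tibble: 1 x 6
#>   observed_score    mu  beta p_value e_value n_shuffles
#> 1            112  103.  13.8   0.397   0.397        100
```

(Output shown is from these exact calls.)

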