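---
title: "Whole-genome k-mer signatures: model, parameters and validation"
author: "kmersig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Whole-genome k-mer signatures: model, parameters and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The model

`kmersig` compares genomes without alignment, through the distribution of
their short oligonucleotides. For a fixed k (7–9 bp in practice; any k ≥ 1
is accepted), every one of the 4^k possible k-mers — the *motifome* — is
assigned a normalized score

    S = (O − E) / (O + E)

where O is the k-mer's observed occurrence, counted over all overlapping
forward-strand windows of the sequence set, and E is the occurrence
expected under a zero-order Markov background:

    E = l_used · p(b1) · p(b2) · … · p(bk)

with p(·) the genome-wide A/C/G/T fractions and `l_used` the usable genome
length. The score is bounded: S → +1 for strong over-representation,
S → −1 for a k-mer that is expected but absent, and S ≈ 0 for a k-mer
occurring at its random rate. Two useful reference points follow directly
from the formula: a k-mer observed at twice its expectation scores exactly
1/3 (≈ 0.333), and at three times its expectation exactly 0.5.

The vector of scores over all k-mers is the genome's *k-mer signature*
(whole genome, or per region: 5′UTR, 3′UTR, intron collections built from
FASTA sets). Two species are compared by the Pearson correlation
coefficient (CC) of their score vectors over the k-mers present in both
signatures; `1 − CC` is then a distance for UPGMA/WPGMA/NJ clustering.

### Assumptions

* The background is zero-order: each base is drawn independently from the
  genome-wide composition. Local composition heterogeneity (isochores, GC
  gradients) is deliberately ignored — deviations from this simple null
  are exactly what the score measures.
* Counting is on the given (forward) strand with stride 1. Reverse
  complements are a separate, explicit analysis
  (`abundant_high_scoring(..., require_revcomp_pair=)`, or
  `canonical = TRUE` for strand-pooled counting).
* Windows never span record boundaries (contigs are not adjacent in
  reality) and any window containing an ambiguous base is skipped.

## Key parameters

| parameter | default | meaning |
|---|---|---|
| `k` | 8 | k-mer length (bp); 7–9 is the studied range |
| `length_mode` | `valid_windows` | what `l_used` is (see below) |
| `sd_mult` | 2 | significance cutoff at mean + 2·SD of all scores |
| `min_score` (common) | 0.5 | "three times more frequent than expected" |
| `min_fraction` | 0.5 | k-mer must pass in ≥ ⌈fraction·n⌉ species |
| `min_score` (abundant) | 0.8 | near-saturated over-representation |
| `min_occurrence` | 10000 | absolute abundance floor (occurrences) |
| `pwm cutoff` | 0.8 | PWM similarity needed to call a motif match |

The defaults reproduce the study settings end to end, so a pipeline run
with no flags applies the published thresholds.

## Design choices that were genuinely open

**Usable length.** The expected occurrence multiplies a probability by "the
genome length". We take `l_used` to be the number of valid k-windows
(`count_valid_windows()`), not the raw base count: with that choice
`sum(E)` over the motifome equals `l_used` algebraically (the composition
fractions sum to 1, so the multinomial expansion of
`(pA+pC+pG+pT)^k` is exact) and also equals `sum(O)`, making the observed
and expected totals conserved and directly comparable.
`length_mode = "raw"` reproduces the literal raw-length reading for
comparison; on a genome with few ambiguous bases the two differ by well
under a percent.

**Missing k-mers.** A k-mer with O = 0 and E = 0 (possible only when some
base fraction is zero, typical for short region sets) is dropped from the
signature and therefore omitted from any pairwise correlation — the
"present in both species" rule. K-mers with O = 0 but E > 0 are *kept*:
their score of −1 is informative under-representation, not missing data.
`pairwise_cc(..., omit_zero_observed = TRUE)` implements the stricter
reading that drops them.

**One-sided significance.** The mean ± 2 SD rule is applied to the upper
tail only (`S > mean + 2·SD`), matching the intended use of the selected
k-mers as over-represented candidate regulatory motifs; `two_sided = TRUE`
also returns the strongly under-represented tail. The SD is the sample
(n−1) SD, R's default.

**"At least half of all species"** uses the ceiling: with 11 of 22, 15 of
30, 5 of 6 as the worked thresholds, odd-n genera need ⌈n/2⌉.

**PWM similarity.** "80% sequence similarity" against a position frequency
matrix is implemented as the per-column ratio-to-maximum averaged over the
aligned overlap: each aligned k-mer base contributes
`f(base, column) / max(f(·, column))`. On a one-hot matrix this reduces to
percent identity against the consensus, which is the most defensible
reading; `metric = "consensus"` gives strict consensus identity (ties in a
column count as matches). The scan slides the shorter of k-mer and matrix
over the longer through all full-overlap offsets and keeps the best offset
(ties broken toward the smallest offset). Reverse-strand scanning is off by
default (`both_strands = TRUE` enables it).

**Repetitive k-mers.** A k-mer is "repetitive" when it is a 1-, 2- or 3-bp
unit tiled and truncated to length k (`kmer[i] == kmer[i mod p]`, p ≤ 3).
By this definition every k-mer of length ≤ 3 is trivially repetitive; the
filter is meaningful for the k ≥ 4 range it is used in.

**Trees.** UPGMA/WPGMA are computed by phangorn (the same engine the
analysis environment of the original study used) and are rooted and
ultrametric by construction; NJ comes from ape's Q-criterion implementation
and is unrooted. Negative NJ branch lengths — possible on non-additive
distance matrices — are clamped to zero with a warning, the standard
practical convention. Merge ties are resolved by the deterministic rule of
the underlying hierarchical-clustering engine, so identical inputs give
identical trees across runs and platforms. Heatmap export orders rows and
columns by the UPGMA tree's leaf order.

**Cohen's d.** The effect size for within- vs between-group CC values uses
the pooled sample SD, with a 95% CI from the Hedges–Olkin
normal-approximation variance `Var(d) = (n1+n2)/(n1·n2) + d²/(2(n1+n2))`.
Note that d computed with sample SDs is exactly invariant under a common
affine rescaling of both groups, but only asymptotically invariant under
duplicating the samples (the n−1 denominators shift at tiny n).

## The synthetic-genome generator

Real Dipteran genomes are hundreds of Mbp and must be downloaded; the
package instead validates itself on genomes it can build deterministically
(`generate_genome()`, `evolve_clades()`):

* i.i.d. background bases at a target composition (default uniform);
* planted k-mers overwritten into the background at non-overlapping random
  positions until the copy number reaches `multiplier × E`, so a planted
  k-mer is about `multiplier + 1` times over-represented once background
  occurrences are included. Planting replaces bases, keeping length fixed;
* tandem-repeat blocks (`unit × copies`) tiled the same way, emulating the
  repeat-rich-genome scenario in which abundant high-scoring k-mers depress
  a species' correlations;
* clade structure by point substitution: one root genome, clade ancestors
  at a `between` substitution rate, species at a `within` rate
  (Jukes–Cantor-like uniform replacement, no indels). `within < between`
  is enforced. All randomness flows from one integer seed through derived
  sub-seeds, so each species can be regenerated independently.

What this emulates is *compositional* divergence — exactly the signal the
signature reads. What it does not emulate: indels and rearrangements,
repeat-family evolution, GC heterogeneity along the chromosome, and real
genome sizes (fixtures are 0.05–1 Mbp). Passing the validation suite
therefore demonstrates the correctness of the computation and the
recoverability of planted structure, not that any particular pair of real
genomes will separate at a given CC.

## Validation problem sizes and numerical notes

The test suite checks the counting path against a brute-force sliding
window oracle on 100 random sequences (≤ 1 kbp, k ∈ {2, 3, 7}); the
conservation identities `sum(O) = valid windows` and `sum(E) = l_used`
(relative tolerance 1e−6, covering float summation over the motifome) on
every fixture; recovery of a k-mer planted at 3× expectation by the
mean + 2 SD rule in 20 independent 1 Mbp genomes at k = 8; exact recovery
of 3 planted clades × 4 species (0.5 Mbp, within 0.01 / between 0.15
substitutions per site, k = 8) as monophyletic groups of the UPGMA tree of
1 − CC; ultrametricity of UPGMA/WPGMA outputs (tolerance 1e−9) and exact
NJ path-length reproduction on additive matrices (1e−9); and agreement of
the repetitive-k-mer filter with an exhaustive minimal-period computation
over all 65,536 octamers.

Expected occurrences are computed in double precision as products of base
fractions; for the k ≤ 9 range underflow is impossible (the smallest
possible E factor is far above double precision limits), so no log-space
path is needed. Signature TSVs carry 15 significant digits so round trips
preserve E and S to ≥ 12 significant digits; observed counts are exact
integers. Pearson correlations require ≥ 3 shared k-mers and nonzero score
variance on both sides, otherwise the comparison errors rather than
returning NA silently.

## Known limitations

* The zero-order background can make composition-extreme genomes look
  artificially similar; higher-order Markov backgrounds are out of scope.
* CC values between signatures of very different `k` coverage (e.g. a
  legacy two-column signature vs a full one) rest on whatever k-mers are
  shared; the functions enforce only the ≥ 3-shared-k-mer floor.
* PWM matching is a similarity screen, not a calibrated binding-site
  predictor: no p-values, no information-content weighting.
* The simulator's divergence is substitution-only; do not interpret its
  branch lengths as evolutionary time.
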