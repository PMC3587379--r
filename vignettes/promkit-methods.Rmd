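---
title: "Methods: CpG-stratified promoter identification and cis-regulatory co-occurrence mining"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CpG-stratified promoter identification and cis-regulatory co-occurrence mining}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(promkit)
```

## The problem

Proximal promoters — the few hundred base pairs around a transcriptional
start site (TSS) — differ from bulk genomic sequence in several measurable
ways: certain hexamers are strongly over-represented, mono-/di-/tri-
nucleotide composition shifts near the TSS, the DNA duplex is locally *less*
stable just upstream of the TSS (the TATA region), and many mammalian
promoters sit inside CpG islands. Promoters with and without CpG islands
are statistically quite different populations, so `promkit` trains and
applies two models, routed by CpG-island detection. A second, independent
task is supported on top of the annotation machinery: given a group of
co-expressed genes, find combinations of transcription-factor binding sites
(TFBSs) that co-occur in their promoters more often than a background set
can explain.

## Coordinate convention

All user-facing positions are TSS-relative with the TSS at +1 and **no
position 0**; −1 is the base immediately upstream. Internally everything is
0-based half-open. The window −200..+100 therefore spans exactly 300 bp.
The five candidate training windows are −60..+20, −100..+50, −200..+100,
−300..+150 and −400..+200, with −200..+100 as the working default — the
classical definition of the proximal promoter.

## DNA stability

Duplex free energy is the sum of unified nearest-neighbor ΔG°₃₇ values
(kcal/mol) over overlapping dinucleotide steps; the ten canonical steps are
closed under reverse complement to all sixteen dinucleotides. Profiles use
a 15-nt sliding window with 1-nt step. Two deliberate choices:

- **No initiation/terminal terms by default.** Profiles compare windows of
  identical length, so constant terms cancel; `duplex_delta_g(...,
  initiation = TRUE)` adds them for standalone use.
- **Window anchoring.** Profile values are anchored at the window *start*;
  statements about peak location (e.g. "the free-energy maximum falls in
  −40..−10") are evaluated at the window midpoint (start + 7 for the 15-nt
  window), since a window's evidence is centered, not left-aligned.

Windows containing N yield `NA` and are excluded from downstream averages;
every scoring formula in the package assumes a 4-letter alphabet, so
degenerate IUPAC codes other than N are rejected at the door.

## Over-represented oligonucleotides

Occurrence counting is always overlapping (the count of `AA` in `AAAA` is
3). For a word of background probability $p$ observed $n$ times over $N$
scanned positions, the z-score is the binomial normal approximation

$$z = \frac{n - Np}{\sqrt{Np(1-p)}}.$$

Counts are pooled across windows rather than computed per sequence, and
self-overlap of periodic words is *not* variance-corrected — a documented
simplification; the null-calibration test shows the ensemble of hexamer
z-scores on background-matched input has mean ≈ 0 and variance ≈ 1 at
10⁵ scanned positions. Two practical caveats:

- The "entire genome" background is replaced by an estimable surrogate: a
  user-supplied background sequence set fitted as a Markov chain of order
  0–2 (default order 0), or explicit base frequencies.
- For long words (k ≈ 10–12) on small inputs, $Np$ is far below 1 and the
  normal approximation is anticonservative: two occurrences of a 12-mer
  already exceed z = 5. The z > 5 reporting rule (the field's conventional
  threshold) is therefore trustworthy for hexamers at reasonable $N$, while
  long-word reports on small inputs should be read as candidates, not
  calibrated discoveries.

The top 100 hexamers by z (ties broken lexicographically) form the OR
feature block; selection is per training set (per CpG branch), and inside
cross-validation it is re-run on each fold's training portion so no
information leaks from validation records.

## CpG islands

The standard three-criterion rule — length ≥ 500 bp, GC ≥ 0.5, and CpG
observed/expected ≥ 0.6 with obs/exp = (#CG · L)/(#C · #G) — is applied by
a greedy seed–extend–merge scan: every 500-bp window satisfying all
criteria seeds a candidate, overlapping seeds are unioned, and a union that
fails as a whole is trimmed from the right until it passes. Reported
islands always satisfy all three criteria on independent recount, are
non-overlapping and sorted; boundaries can smear by up to half a window
into flanking sequence because mixed windows still pass the criteria (a
property shared by all window-seeded detectors). This detector plays the
stratification role an external CpG-island predictor would play in a
database-backed pipeline; it makes no claim to reproduce any particular
published program's output.

## MATCH-style PWM scanning

Named tools are reconstructed from their published scoring form. Position
$i$ of a matrix carries information value $I(i) = \sum_b f(i,b)\ln(4
f(i,b))$; a site is scored by $\sum_i I(i) f(i, s_i)$, min–max normalized
over per-position best/worst bases so the consensus scores exactly 1. The
core score is the same quantity over the 5 consecutive positions of
maximal summed information (leftmost on ties). Both strands are scanned;
default cutoffs are core ≥ 1.0 and matrix similarity ≥ 0.7 (0.9 is the
stricter setting used for gene-group scans in the worked examples). A
fully uniform matrix region makes max = min; the score is then defined as
1.0 with a warning, since every site is equally consistent. The TATA /
CCAAT / GC box matrices bundled under `inst/extdata/` are *synthetic*
consensus-derived profiles (TATAWAW, CCAAT, GGGCGG with mild smoothing) —
curated database matrices cannot be redistributed — and the TATA −100..−1
and CCAAT/GC −200..−1 search windows are conventional defaults, not
measurements.

## The promoter SVM

Each candidate window is a 204-dimension vector: OR (100 hexamer
overlapping-count densities, count/L), NC (84 k-mer occurrence rates,
count/(L−k+1), one simplex per k so the block sums to 3), DS (the 15-nt
ΔG profile averaged into 20 equal-width positional bins). The encodings
keep dimensionality fixed across the five candidate windows and keep the
three families separable for OR+NC / OR+DS / NC+DS / OR+NC+DS ablations
(`features =` argument). The positional 20-bp composition profiles and
their Pearson clustering into A-like and G-like families are provided as
diagnostics (`kmer_rate_profile()`, `cluster_profiles()`) but do not feed
the feature vector, because no principled mapping from cluster membership
to a fixed-length encoding exists.

Training uses libsvm's C-SVC with an RBF kernel on z-standardized features
(scaling fitted on training data only; constant features get unit scale).
Default hyperparameters are C = 1 and γ = 1/204; passing `C = NULL` or
`gamma = NULL` triggers an inner 3-fold grid search over C ∈ 2^{−3..7},
γ ∈ 2^{−9..1}. Negatives are sampled one per record, uniformly over the
record with zero overlap with the positive window, so classes are exactly
balanced. Five-fold CV splits at the *record* level (a record's positive
and negative stay together), and the decision threshold is 0. At
prediction time the window slides with a configurable stride, each window
is routed by CpG-island overlap of a ±500 bp padded context, and
overlapping positive windows merge into regions keeping the maximum
decision value.

## Co-occurrence mining

Each promoter maps to a transaction: the set of matrix identifiers with at
least one hit. Apriori mines frequent itemsets levelwise with candidate
pruning, and rules A ⇒ B with confidence support(A∪B)/support(A); support
and confidence accept percent (90) or fraction (0.9) inputs, defaulting to
0.9. Combinations of size ≥ 2 are scored against a background set by the
hypergeometric upper tail

$$P(t) = \sum_{i=t}^{\min(T,k)} \frac{\binom{T}{i}\binom{K-T}{k-i}}{\binom{K}{k}},$$

computed in log-space (the upper summation limit is the standard tail
limit min(T, k)). The background is user-supplied and must be scanned with
the same matrices and cutoffs; when the observed genes are not part of the
background it is possible to observe t > k, in which case the background
count is conservatively raised to t for the tail computation (the raw k is
still reported). Raw p-values are reported by default; Benjamini–Hochberg
adjustment is opt-in, across the scored itemsets.

## Synthetic study conditions

The generator emulates TSS-anchored training data: ±3000 bp flanks around
a central TSS at mammalian-like GC 0.41; a TATAAAA cassette at −31 sampled
base-wise at strength 0.9; six planted hexamers each embedded with
probability 0.8 at random non-colliding positions in −200..+100; an
AT-rich (90% A/T) stability dip at −40..−20; and, for the with-CpG class,
a 600-bp i.i.d. segment at −350..+250 with P(C) = P(G) = 0.33 — GC ≈ 0.66
and CpG obs/exp ≈ 1, comfortably above the island thresholds. Collisions
are resolved by rejection sampling with a 100-attempt cap. Effect sizes
default to strongly separable; `hard = TRUE` halves the TATA strength and
hexamer rate for sensitivity analyses. Everything is a pure function of
its seed.

What the generator does *not* emulate: repeats and isochore structure,
positional hexamer preferences, TATA-less CpG promoters (both classes get
a TATA cassette), dinucleotide correlations of real genomic background,
and homology structure between related promoters. Passing tests on this
data therefore demonstrate that the pipeline recovers the signals it is
built to detect at realistic magnitudes — not that real-genome performance
matches any particular published figure; headline accuracies on real
TSS-database training sets are out of scope by design.

## Problem sizes and numerical choices

The validation suite runs 200 records per CpG class (2 × 400 windows) for
the five-fold CV recovery check with fixed hyperparameters (C = 1,
γ = 1/204; the inner grid search is available but not exercised there),
10⁵ scanned positions for the z-score null calibration, and a 10-observed
vs 100-background gene group for planted co-occurrence recovery. At the
default effect sizes both CV branches sit near ceiling (accuracy
0.99–1.00), so a single CV realization resolves the with-CpG ≥ without-CpG
ordering only to one misclassified window (0.0025); the ordering is
therefore assessed on the mean over three replicate seed pairs. The one
recurring error mode is instructive: a negative window drawn over the edge
of the planted CpG island is locally indistinguishable from a positive and
occasionally produces a false positive in the with-CpG branch.

Other numerical details: PWM parsing adds a pseudocount of
0.01·(rowtotal+1)/4 per cell before renormalization so information values
never hit log(0); score comparisons against the 1.0 core cutoff use a 1e−9
guard for float round-off; hexamer ranking breaks ties lexicographically;
Apriori output is ordered (size, support desc, lexical) so results are
byte-stable under permutation of input.

## Known limitations

- The z-score lacks an overlap (periodic-word) variance correction.
- CpG-island boundaries smear by up to 250 bp around sharp composition
  changes.
- The background model reaches Markov order 2 at most; long-range genomic
  heterogeneity is not modeled.
- `parse_transfac_matrices()` reads the TRANSFAC flat dialect only; other
  matrix formats must be converted by the user.
- The co-occurrence p-value treats promoters as exchangeable draws; shared
  ancestry or shared repeats among observed promoters will deflate it.
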