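---
title: "Estimating and projecting fungal secondary-metabolite diversity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating and projecting fungal secondary-metabolite diversity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smprospect)
```

## The estimation problem

Genome mining of filamentous fungi (Pezizomycotina) predicts tens of
biosynthetic gene clusters (BGCs) per genome, grouped by similarity networks
(e.g. BiG-SCAPE) into gene cluster families (GCFs), each family presumed to
encode the same or closely related secondary metabolites (SMs). Two
empirical regularities make the encoded chemistry look vastly undersampled:
most GCFs are seen in only a single sampled species, and each newly sampled
genome keeps contributing families never seen before. `smprospect`
implements the estimation chain that turns those observations into
quantitative diversity projections:

* **incidence-based richness estimation** — how many GCFs does a clade
  contain, given presence/absence of each family across sampled species?
* **a discovery-ratio projection** — scale BGC counts across a large species
  pool down to families, and up to metabolites;
* **an effective SMs-per-BGC statistic** — how many distinct compounds does
  a cluster contribute, once compounds made by several clusters are not
  double-counted;
* **a structural diversity metric** over molecular fingerprints.

Everything operates on plain-text inputs (clustering TSVs, link tables,
fingerprint tables); nothing here runs antiSMASH or BiG-SCAPE, parses
sequence data, or queries databases.

## Incidence and richness

The sampling unit is the **species** (one genome per species; when several
genomes share a species the lexicographically smallest genome identifier is
kept, a deterministic and reproducible deduplication). The incidence matrix
has a 1 in cell (u, g) iff at least one BGC of family g occurs in unit u —
multiple same-family copies within a unit collapse, because all richness
machinery is incidence-based, not abundance-based.

From the matrix, the sufficient statistics are the number of units $T$, the
occupancy counts $Y_i$ of each observed family, the observed richness
$S_{obs}$, and the uniques/duplicates $Q_1, Q_2$ (families in exactly one /
two units).

**Rarefaction.** The expected richness in a random subsample of $t$ units is
the exact hypergeometric mean

$$E[S(t)] = S_{obs} - \sum_i \binom{T-Y_i}{t} \Big/ \binom{T}{t},$$

evaluated through log-gamma differences (`lchoose`) because quantities like
$\binom{135}{60}$ overflow direct floating-point binomials. The suite checks
this against exhaustive subset enumeration for all matrices with $T \le 6$
and against vegan's exact species-accumulation curve at larger sizes.

**Undetected richness.** The Chao2 estimator with the small-sample
correction:

$$\hat Q_0 = \frac{T-1}{T}\,\frac{Q_1^2}{2Q_2} \quad (Q_2>0), \qquad
\hat Q_0 = \frac{T-1}{T}\,\frac{Q_1(Q_1-1)}{2} \quad (Q_2=0),$$

with $\hat S = S_{obs} + \hat Q_0$. The bias-corrected branch avoids
division by zero; both branches are cross-checked against vegan's
`specpool`. Chao2 is a *lower-bound-type* estimator: it is approximately
unbiased when detection is homogeneous and conservative when it is not.

**Extrapolation.** Expected richness $t^*$ units beyond the sample follows
the standard incidence form

$$S(T+t^*) = S_{obs} + \hat Q_0\left[1 - \left(1 -
\frac{Q_1}{Q_1 + T\hat Q_0}\right)^{t^*}\right],$$

which is continuous with rarefaction at $t^*=0$, monotone, and approaches
$S_{obs}+\hat Q_0$ from below. These three classical formulas are the
canonical machinery behind sample-based rarefaction/extrapolation curves;
they are adopted here because they reproduce all the qualitative behaviour
such curves display (interpolation anchored at $S_{obs}$, a dashed
extrapolation bending toward a Chao2 asymptote) without inventing anything
beyond standard practice.

**Confidence bands.** `gcf_rarefaction()` attaches pointwise 95% percentile
bootstrap intervals: the $T$ sampling units are resampled with replacement
`n_boot` times (default 200) and the full curve is recomputed per replicate.
The seed is a required argument of every stochastic path; identical inputs
and seed give bit-identical curves. This unit bootstrap is assumption-light
but known to be conservative-downward for the asymptote: resampling
duplicates units, which deflates $Q_1$ and hence the resampled Chao2, so the
band around the extrapolated tail is wide and its lower edge can undershoot.
Assemblage-style bootstraps that resample from an estimated complete
community would tighten this, and are out of scope here.

## Effective SMs per BGC

MIBiG-style link tables pair BGCs with their experimentally verified
compounds. Counting every link in full would double-count a compound made by
several clusters, so each SM linked to $k$ BGCs contributes $1/k$ to every
linked cluster:

$$\mathrm{eff}(b) = \sum_{s \in SM(b)} \frac{1}{k_s}.$$

This is an *interpretation* — the simplest scheme consistent with
"down-weight shared compounds" — and it carries a clean accounting identity
that the tests exploit: effective counts sum to the number of distinct SMs,
so the mean equals distinct SMs / BGCs exactly, for every table. Structural
variants (aflatoxin B1 vs B2) are distinct only if the input lists them
distinctly; no name normalisation is attempted, because that is curation,
not computation.

## The projection grid

The scenario arithmetic is deliberately plain: with $B$ BGCs per species,
$N$ species, discovery ratio $r$ (fraction of BGCs that are the first
instance of their family) and $m$ effective SMs per BGC,

$$\mathrm{GCFs} = B \cdot N \cdot r, \qquad \mathrm{SMs} = B \cdot N \cdot r \cdot m.$$

Three numerical choices matter, and all are tested cell-by-cell:

* $r$ is carried as an **exact count pair** (4,463/6,972 and 9,808/28,696 by
  default), never as the rounded percentage; the published projection table
  is only reproducible from the exact fractions.
* rounding is **half away from zero**, applied **only at display**;
* the displayed SM count is derived from the **unrounded** GCF intermediate
  (rounding the GCF count first is off by one in the $B=40$, 64%-ratio
  cell: 3,417,025 instead of 3,417,024).

The default grid ($B \in \{30,40,50\}$, $N = 85{,}000$, both ratios,
$m = 1.57$) spans roughly 0.87–2.72 million GCFs and 1.37–4.27 million SMs;
the same chain at $N = 10^6$ species and the conservative 34.2% ratio
exceeds 16 million SMs. No uncertainty is propagated through this chain —
the scenarios are point projections by design, and the grid rows (not error
bars) express the sensitivity to $B$ and $r$.

## Structural diversity

For a set of binary molecular fingerprints, $d = 1 - $ mean pairwise
Tanimoto similarity over all $n(n-1)/2$ unordered pairs. Self-pairs are
excluded (including the diagonal of 1s would deflate $d$), all-zero
fingerprints are rejected rather than scored (0/0 is undefined; silent
conventions corrupt the mean), and the vectorized bit-matrix implementation
is required by the tests to agree with a literal double loop up to $n = 50$.
The metric is fingerprint-agnostic; the optional ChemmineR-based SMILES
adapter (atom-pair fingerprints, 1024 bits by default) is isolated and
swappable, since no particular fingerprint type is canonical for this
purpose.

## What the synthetic generator emulates

The generator provides survey-shaped inputs with full ground-truth
bookkeeping, calibrated to three observed statistics of a 135-genome
*Aspergillus* survey: an ~80.8% singleton fraction (3,607/4,463), a GCF:BGC
count ratio of ~0.640 (4,463/6,972), and the ~51.6 BGCs per species those
counts imply.

* **Occupancy** of each of the `s_true` families is truncated-Zipf on
  $\{1..T\}$: $P(Y=k) \propto k^{-\alpha}$. One parameter reaches an 80%
  singleton fraction while keeping a heavy tail (a few families in many
  species). `calibrate_occupancy()` solves $P(Y=1) = $ target by bisection
  ($\alpha \approx 2.84$ at $T=135$); $P(Y=1)$ is monotone in $\alpha$, and
  unattainable targets (below $1/T$) raise an error naming the feasible
  range.
* **Duplication**: each presence becomes $1 + \mathrm{Poisson}(\lambda)$ BGC
  records. Since a family contributes $E[Y](1+\lambda)$ records in
  expectation, $\lambda = 1/(r\,E[Y]) - 1$ hits a target count ratio $r$
  ($\lambda \approx 0.07$ at the defaults) — an analytically inverted second
  knob, independent of the occupancy shape.
* **Link tables**: per-BGC link counts $1 + \mathrm{Poisson}(0.8)$ with a
  15% chance each link reuses an existing compound. The defaults (158 BGCs,
  mean 1.8 SMs per BGC) mirror the scale of curated *Aspergillus* link sets
  and yield moderate sharing; they are a realism choice, not a calibration
  target.
* **Fingerprints**: disjoint per-family core bits plus private noise bits;
  `within_family_overlap` tunes how much more similar family members are to
  each other than to outsiders.

What the generator does **not** emulate: phylogenetic autocorrelation of
presence/absence (real occupancy is clumped by clade), class-dependent
family sizes, genuinely undetected families (every pool family occupies at
least one unit, so on the full matrix $S_{obs} = s_{true}$ — partial
detection is studied by subsetting units), or realistic chemistry. Passing
tests on this generator therefore demonstrate the correctness of the
estimators' mathematics under a controlled occupancy model, not the
field-accuracy of any particular extrapolation.

Because all pool families are observed, Chao2's *recovery* of a true total
is tested under a different, homogeneous model (each of $S_{true}$ families
present in each of $T$ units independently with probability $p$), where
undetected families genuinely exist and Chao2 is approximately unbiased. The
acceptance band for that check, $[0.8, 1.3] \times S_{true}$, was fixed in
advance from an independent 200-replicate pilot (observed range
0.91–1.10); it is asymmetric because the estimator is a lower bound with
occasional overshoot in the singleton-heavy regime.

## Problem sizes and numerical choices

The test suite runs at deliberately small scale — enumeration oracles at
$T \le 6$ (where $\binom{T}{t}$ subsets are exhaustible), bootstrap checks
at $T \le 15$ with tens of replicates, calibration checks over 20 seeds of
the full 135 × 4,463 default model, and 100-replicate bound checks at
$T = 40$, $s_{true} = 300$ — sizes chosen so the whole suite completes in
well under a minute while still exercising every formula branch. Degenerate
inputs are contracts, not surprises: $Q_1 = 0$ gives a flat extrapolation at
$S_{obs}$ (not an error); $Q_2 = 0$ switches the Chao2 branch; `n_boot = 1`
yields a degenerate interval equal to the single resample; empty record
sets, all-zero fingerprints, over-exclusion, and out-of-range rarefaction
sizes all raise informative errors.

## Known limitations

* The unit bootstrap's downward bias on resampled Chao2 (above) makes the
  extrapolated band conservative at its lower edge.
* The discovery ratio treats family membership as fixed at one clustering
  cutoff; families are not merged across cutoffs, because mixing cutoffs
  changes richness.
* The down-weighting scheme behind $m$ is one defensible reading of shared
  attribution; alternatives (e.g. splitting by pathway evidence) would give
  different multipliers.
* Projections inherit every upstream assumption linearly: if $B$, $r$ or
  $m$ shift, the projected SM count shifts proportionally, which is exactly
  why the grid exposes them as scenario parameters rather than constants.
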