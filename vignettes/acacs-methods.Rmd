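---
title: "Averaged chemical shift composition features: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Averaged chemical shift composition features: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acacs)
```

## The problem

Most sequence-based protein classifiers (subcellular localization,
enzyme-class discrimination and the like) represent a protein by
composition statistics of its residue string — amino-acid composition
(AAC), dipeptide composition (DC), pseudo-amino-acid variants. These carry
no direct structural information. NMR chemical shifts do: the resonance
offset of a backbone nucleus is sensitive to local conformation, and its
average over many observations varies systematically with both residue
type and secondary-structure state. This package turns that regularity
into a fixed-length, structure-aware feature vector that can be
concatenated with composition features and fed to any standard classifier.

## The statistic: the ACS table

For backbone nucleus $i \in \{{}^{15}\mathrm{N},\ {}^{13}\mathrm{C}^\alpha,\
{}^{1}\mathrm{H}^\alpha,\ {}^{1}\mathrm{H}^N\}$, residue type $j$ (20
standard amino acids) and secondary-structure state
$k \in \{H, E, C\}$, the averaged chemical shift is the pooled mean

$$C_k^i(j) = \frac{1}{N}\sum_{N} \omega_k^i(j),$$

where the $\omega$ are all assigned shifts routed to that cell and $N$
their count. `build_acs_table()` computes the full
$4 \times 20 \times 3 = 240$-cell grid from a set of per-residue shift
observations and their aligned secondary-structure strings. Pooling is
across proteins (every observation has equal weight), not per-protein
averaging first: the defining equation counts individual shift items, and
pooling is the reading consistent with that.

Cells can be empty. Proline's amide-proton cells are empty by chemistry —
proline has no backbone H$^N$ — and a small corpus can leave other cells
unpopulated. Empty cells stay in the grid with count 0 and are flagged,
rather than erroring at build time; what to do about them is an
encoding-time policy (below). The table also records a per-cell standard
deviation. That is an addition beyond the defining statistic: it makes the
parameter-recovery tests sharp and supports count-weighted imputation.

The three-state alphabet comes from the standard DSSP reduction
(`reduce_8_to_3()`): $\{H,G,I\}\to H$, $\{E,B\}\to E$, everything else
$\to C$. Only the three target states are fixed by the method; the
grouping is configurable because other reductions exist in the
literature. Secondary structure is a required input throughout — the
package deliberately does not predict it, so it is agnostic about whether
the strings come from DSSP assignments or from a prediction server.

## The encoder: acACS

Given a protein $P = [j_1 \dots j_L]$ with secondary structure
$[k_1 \dots k_L]$ and a table, each residue is replaced by its cell value,
giving the per-atom series $S^i_l = C^i_{k_l}(j_l)$. The series is
summarized by lagged mean squared differences

$$\theta^i(\lambda) = \frac{1}{L-\lambda} \sum_{l=1}^{L-\lambda}
  \left(S^i_l - S^i_{l+\lambda}\right)^2, \qquad 0 < \lambda < L,$$

a variogram-style statistic (often loosely called autocovariance in the
feature-engineering literature): nonnegative, zero iff the series is
lag-$\lambda$ periodic, invariant to adding a constant, and scaling the
series by $a$ scales it by $a^2$. At $\lambda = 0$ the formula is
identically zero and carries no information, so the lag-0 slot is filled
with the series mean $\bar S^i$ instead, preserving the absolute shift
level the differences discard. "The mean" here is the per-sequence
arithmetic mean — the only well-defined scalar reading of a
mean-substitution rule (a single-position reading has no determinate
position).

The feature vector concatenates per-atom blocks
$[\bar S^i, \theta^i(1), \dots, \theta^i(\lambda)]$ in the fixed nucleus
order $^{15}$N, $^{13}$C$^\alpha$, $^{1}$H$^\alpha$, $^{1}$H$^N$
(restricted to the selected subset). Block-per-atom layout, rather than
interleaving lags across atoms, matches the per-atom output convention of
the method's reference implementation. Total length is
$|\mathrm{atoms}| \times (\lambda + 1)$; the conventional default
$\lambda = 12$ with the two proton nuclei gives 26 components.

**Tunable parameters.**

* `lambda` (default 12): maximum lag, in residues. Must be smaller than
  the shortest sequence encoded. Larger values resolve longer-range
  periodicity at the cost of noisier high-lag terms (only $L - \lambda$
  pairs contribute).
* `atoms` (default all four): which nuclei contribute blocks. The two
  proton nuclei are the cheapest to assign experimentally and are the
  conventional minimal choice.
* `missing_policy` (default `"cell_row_mean"`): what a lookup does on an
  empty cell. `"error"` is the strict mode; `"cell_row_mean"` substitutes
  the count-weighted mean of the same (atom, residue) across the SS states
  that do have data, falling back to the atom-wide mean — this keeps every
  proline-containing protein encodable with the amide-proton block while
  staying on the ppm scale of the atom; `"zero"` substitutes 0 and is
  only sensible when a downstream model treats 0 as "missing".
* Non-standard residues (B, J, O, U, X, Z) are rejected with a
  position-listing error by default; `nonstandard = "average"` maps them
  to the (atom, SS)-matched residue-averaged value. Silent coercion is
  never done: it corrupts features invisibly.

No scaling or normalization happens inside the encoder; standardization
belongs to the classifier harness, where it can be computed on training
folds only.

## Corpus curation

`curate_observations()` applies the two standard benchmark filters —
drop proteins shorter than 50 residues and proteins without a matching
SS-annotated record — and reports what it removed and why.
`identity_filter()` removes redundancy at a 40% identity threshold with a
greedy longest-first pass, identity being the exact-match fraction of a
global Needleman–Wunsch alignment (via Biostrings). This is a deliberate
simplification of CD-HIT: it makes the redundancy-screened pipeline
runnable end to end in pure R, and is not intended to reproduce CD-HIT's
word-filter clusters.

## The evaluation harness

`jackknife_eval()` is strict leave-one-out: each sample is predicted by a
soft-margin SVM trained on the other $N-1$. Defaults are the conventional
ones — RBF kernel, $C = 1$, $\gamma = 1/d$ — with features standardized
using training-fold statistics only, so the held-out sample never leaks
into the scaling. $k$-fold evaluation is not silently substituted;
leave-one-out is what the protocol means.

Class weights are balanced (inverse training-fold frequency) by default.
This is not cosmetic: under leave-one-out the held-out sample's class is
always one member short in the training fold, and with weak or absent
signal an unweighted margin drifts toward the fold's majority class —
which is systematically the *wrong* class for the held-out sample. On
signal-free data that artifact pushes leave-one-out accuracy far below
chance. Balancing restores the property that an uninformative feature set
scores at chance, which is what a sane harness must do and what the
harness's own null-contract tests assert.

`ablation()` runs the with/without protocol: two jackknife evaluations
identical in every respect except that one feature set includes the acACS
blocks alongside AAC + DC and the other carries AAC + DC alone. The
accuracy difference isolates the contribution of the structure-derived
features.

## What the synthetic generators emulate

`generate_shift_corpus()` emulates a curated shift benchmark with known
ground truth: random sequences, secondary structure drawn i.i.d. per
position (or from a sticky Markov chain whose stationary distribution
matches the requested state mix, giving realistic helix/strand run
lengths), and every residue emitting one shift per applicable atom from
$\mathcal{N}(\mu_{\text{cell}}, \sigma)$. The default cell means are
literature-scale — alpha protons near 4 ppm, amide protons near 8 ppm,
alpha carbons in the 45–70 ppm band, amide nitrogens in the 105–130 ppm
band — with secondary-structure offsets of a few tenths of a ppm for
protons and 1.5–2.5 ppm for the heavy atoms, helix and strand displacing
each cell in opposite directions about coil, the qualitative pattern seen
in random-coil shift statistics. $\sigma = 0.3$ ppm is the default
within-cell spread. Proline never emits an amide proton. The generator
returns a complete emission log, so the star-format round trip and the
table build can both be audited value by value.

`generate_labeled_dataset()` emulates a labeled classification benchmark.
The designed `ss_signal_classes()` preset is the construction behind the
ablation protocol: both classes share an identical (uniform) residue
distribution, so AAC and DC carry no class signal in expectation, while
the helix fraction differs by 0.2 (0.3 vs 0.5, traded against coil at a
fixed 0.2 strand fraction) — structure-aware features are the only route
to separating the classes. `no_signal_classes()` makes the two classes
identically distributed as a null control.

What the synthetic data does *not* emulate: real shift distributions are
not Gaussian within a cell, real assignment tables have missing-value
patterns far beyond the proline rule, referencing errors shift whole
proteins coherently, and real class boundaries are not clean draws from
per-position distributions. Passing tests on this data therefore
demonstrate that the statistics, the encoder and the harness are computed
correctly and that the ablation logic detects a designed structural
signal — not that any particular accuracy will be achieved on real
benchmarks.

## Numerical choices and degenerate inputs

* Table serialization prints doubles with `%.17g`, so TSV round-trips are
  bit-exact; the same applies to the star-format writer.
* A cell with one observation has standard deviation 0 (not NA); a cell
  with none has NA mean and is flagged missing.
* Merging two observation sets and building once equals the
  count-weighted combination of the two separate builds to $10^{-9}$;
  build order never matters.
* $\theta$ rejects $\lambda \le 0$ and $\lambda \ge L$ rather than
  returning a degenerate value; the encoder names the offending protein
  when a dataset contains a sequence shorter than $\lambda + 1$.
* Constant feature columns inside a training fold pass through centering
  with unit scale rather than dividing by zero.
* Ties in the greedy identity filter (equal lengths) are broken by input
  order, so the retained set is deterministic.
* Command-line outputs are written to a temporary file and renamed on
  success; a failing run never leaves a partial file.

## Problem sizes

The shipped checks use corpora sized so every populated table cell
receives well over 500 draws (600 proteins of 140–160 residues,
about 355,000 observations) for parameter recovery, and a
2-class × 50-sequence dataset for the ablation — sizes at which the
recovery bound $4\sigma/\sqrt{N}$ is sharp and a leave-one-out run
completes in seconds. The bundled example table in
`inst/extdata/synthetic_acs_table.tsv` is built from a smaller synthetic
corpus (80 proteins, seed 2014) and is labelled synthetic: it exists so
encoding works out of the box, not as a reference for real data.

## Known limitations

* The package consumes secondary-structure strings; it does not predict
  them, run DSSP, or parse PDB files.
* Only a minimal star-like subset (one shift loop per save-frame) is
  parsed — not the full NMR-STAR 2.1/3.x grammar — and no
  chemical-shift re-referencing is attempted.
* The identity filter approximates, and does not reproduce, CD-HIT.
* Profile (PSSM), gene-ontology and physicochemical-property feature
  families are out of scope; the fusion layout accepts extra blocks if a
  user computes them elsewhere.
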