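---
title: "Methods: sequence encodings and the interaction classifier"
author: "rpiforest"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sequence encodings and the interaction classifier}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rpiforest)
```

# The prediction problem

Given a protein sequence and an RNA sequence, the package predicts the
binary event that the two physically interact. The working assumption
is the standard one for sequence-only interaction predictors: binding
propensity leaves a signature in local sequence composition — short
physicochemical motifs on the protein side, short base motifs on the
RNA side — that a k-mer-style encoding can expose to a generic
classifier. Nothing about structure, conservation or expression enters
the model; when those signals matter, a sequence-only model is a
lower bound, not a substitute.

# Encodings

## Conjoint triads (protein) and 4-mers (RNA)

The protein alphabet is collapsed into seven physicochemical groups
({AGV}, {ILFP}, {YMTS}, {HNQW}, {RK}, {DE}, {C}, numbered 1–7). Every
window of three successive residues is an ordered triad over the
groups; a protein of length $L$ has $L-2$ windows, and the encoding is
the 343-vector of triad frequencies $f_i = m_i/(L-2)$, which therefore
sums to exactly 1. Triads are stored in lexicographic order,
$i = 49(g_1-1) + 7(g_2-1) + g_3$; the classifier is order-insensitive,
but a fixed order is what makes persisted models portable.

The RNA encoding counts the 256 4-mers over {A,C,G,U}. Its
conventional normalisation divides by $N-2$ although a sequence of
length $N$ has $N-3$ windows, so the vector sums to $(N-3)/(N-2)$
rather than 1. Both behaviours are exposed
(`denominator = "published"` / `"exact"`); the published form is the
default because reproducing the method as circulated is this package's
contract, and a global scale factor is irrelevant to a random forest.
The discrepancy is visible only for very short RNAs.

## Chaos game representations

A chaos game maps a sequence to a trajectory: point $i$ is the
midpoint of point $i-1$ and the vertex assigned to symbol $i$.
Proteins play on a 12-gon inscribed in the unit circle,
$V_1 = (1,0)$, $V_k = (\cos\frac{(k-1)\pi}{6}, \sin\frac{(k-1)\pi}{6})$,
starting from the centre $(0,0)$; RNA plays on the unit square with
A, C, G, U at $(0,0), (1,0), (1,1), (0,1)$, starting from
$(0.5, 0.5)$. Because each step halves the distance to a vertex, every
protein point stays inside the unit disc and every RNA point inside
the square (property-tested). The trajectory is summarised as segment
occupancy frequencies $D_k = L_k/N$: 24 segments for proteins, 16 for
RNA, each histogram summing to 1.

Three details here were genuinely open and are package decisions:

- **The 12-class amino-acid partition.** The CGR-24 literature does
  not fix a single partition and the grouping behind the published
  figure is not recoverable. The default splits the seven triad groups
  into {A}, {G}, {V}, {IL}, {FP}, {YW}, {M}, {TS}, {HNQ}, {RK}, {DE},
  {C} (note {YW} deliberately collects the two bulky aromatics even
  though Y and W sit in different triad groups). Any total map of the
  20 amino acids onto the 12 vertices yields a valid encoding, so the
  partition is treated as configuration: `validate_twelve_map()` /
  `read_twelve_map()` accept user overrides, letting any published
  CGR-24 variant be reproduced exactly.
- **Segment geometry.** For the 12-gon, 12 angular sectors of 30°
  crossed with 2 radial bands split at $r = 0.5$ give 24 segments with
  a one-line deterministic assignment; angle boundaries belong to the
  higher sector via `floor`, and $r = 0.5$ is outer. For the square,
  the canonical 4×4 grid (the resolution-2 frequency-CGR), half-open
  cells with the top/right edges clamped inward. Any fixed relabelling
  of segments permutes feature columns and leaves the forest
  invariant, so nothing downstream depends on matching any particular
  figure's numbering.
- **Vertex-for-step reading.** The iteration is implemented as "the
  vertex of the class of the $i$-th symbol", the only reading
  consistent with the chaos-game literature.

## Feature sets

Pairs concatenate per-sequence blocks in a fixed order (families CTF,
CGR, AAC, NC; protein before RNA inside each family), giving the five
canonical sets with dimensions 24, 599, 40, 639 and 663. No scaling is
applied: random forests are invariant to monotone per-feature
transforms, and frequencies are already commensurate.

# Classifier and evaluation

`train_rf()` fits a `randomForest` with the pair's vote fraction as a
continuous score; class calls use a configurable threshold (default
0.5, with a score of exactly 0.5 called interacting — the boundary
must land somewhere and is documented rather than implicit).
`cross_validate()` uses stratified folds (class-ratio-preserving, a
fixed seed, fold sizes within one), because the benchmarks this
method targets are balanced and stratification reduces fold variance.
Reported metrics are computed from the out-of-fold confusion counts
pooled over the ten folds, and AUC from the pooled out-of-fold
scores; per-fold numbers are kept alongside since conventions differ
between papers.

The metric engine evaluates Sens, Spec, ACC and MCC in closed form.
When an MCC denominator factor is zero (e.g. a positives-only test
set), the coefficient is undefined; the engine warns and returns 0.
AUC is the Mann–Whitney rank statistic with ties counted half —
equivalent to the trapezoid over the tie-collapsed ROC staircase, and
well defined for the heavily tied vote fractions a forest produces.

`grid_search()` scans `ntree` ∈ {300, 350, 400, 450, 500} and ~8
log-spaced `mtry` values in $[1, n]$ (always including
$\lfloor\sqrt n\rfloor$) by default, selecting on pooled CV accuracy
with ties to the smaller `ntree` then the smaller `mtry`. The
canonical search ranges are preserved; full-density grids (which
published optima like `mtry` = 442 imply) are possible by passing
explicit grids, at correspondingly higher cost.

# Dataset construction from structures

`build_dataset()` reproduces the contact-based construction of
positive pairs. Chains are extracted from PDB-format files (model 1;
highest-occupancy alternate conformers; DNA, mixed or unrecognised
chains skipped with warnings), typed by residue chemistry. Two chains
interact when at least one protein-atom/RNA-atom pair lies strictly
below 3.4 Å; the decision is made on squared distances with identical
arithmetic to the contact count, so a pair at exactly the cutoff can
never be admitted by a rounding artefact. All atoms present
participate, hydrogens included if the file has them.

The published length rule — removing pairs "simultaneously shorter
than" 25 residues and 10 bases — is ambiguous between per-chain
thresholds and a literal both-short reading. The default applies the
per-chain thresholds (protein ≥ 25 aa AND RNA ≥ 10 nt), the stricter
and more common convention in this literature;
`filter_mode = "both-short"` implements the literal reading. The
builder emits positives only; how negatives should be sampled is a
dataset-design question the construction procedure does not answer.
Release-date windows operate on user-supplied metadata — the package
never queries external services.

# The synthetic benchmark

`generate_pairs()` emulates a labelled RPI benchmark whose truth is
known by construction: a pair interacts iff the protein contains a
planted amino-acid motif (default `CWKDEMH`) and the RNA a planted
base motif (default `GACUCG`). Defaults are 200 pairs at 50% positive
fraction, protein lengths 50–150, RNA lengths 40–120 — the scale of
the smaller published benchmarks and large enough for stable 10-fold
CV at desk cost. Motifs are implanted at uniform random positions,
overwriting an i.i.d. uniform background, so composition features
carry almost no signal and the test genuinely exercises
order-sensitive encodings; motif lengths (≥ 3 residues, ≥ 4 bases)
guarantee visibility to the triad and 4-mer windows. Negatives carry
at most one motif (protein-only / RNA-only / neither in equal shares),
which makes single-molecule shortcuts unreliable. Everything is
deterministic given the seed, to the byte on disk.

What passing on this benchmark shows — and what it does not: the
pipeline recovers a sequence-determined interaction rule through the
encoders (pooled AUC ≈ 0.99 at 200 pairs, noise 0, against ≈ 0.5 with
permuted labels). Real interaction data differ in every inconvenient
way: non-uniform residue composition, homology between pairs,
structure-mediated binding with weak sequence signature, and label
noise from incomplete assays. A frequency-table background option
exists for mild realism, but claims about real data must rest on real
benchmarks.

# Numerical and degenerate-input conventions

- Sequence sanitisation uppercases, maps T→U in RNA, and drops
  out-of-alphabet characters with a warning (strict mode errors);
  k-mer windows are formed on the cleaned string, so dropping joins
  neighbours. Dropping preserves k-mer locality better than
  substituting a wildcard for the short runs typical of
  structure-derived sequences.
- Length preconditions error early: triads need $L \ge 3$, 4-mers
  $N \ge 4$, compositions and trajectories non-empty sequences.
- Encoding caches per unique sequence in `build_matrix()` are
  contract-tested to equal per-pair recomputation exactly.
- All stochastic steps (simulation, folds, forests) consume explicit
  integer seeds; identical seeds reproduce identical CV reports and
  byte-identical simulation files.

# Problem sizes

The shipped tests and the acceptance script run at desk scale chosen
for the package's own development loop: oracle equivalence on 100–200
random sequences per encoder, the learnability benchmark at 200 pairs
with `ntree` = 400, smaller 60-pair forests for determinism checks,
and structure fixtures under 200 atoms against a brute-force
all-pairs distance oracle. These sizes make the full suite complete
in about a minute while keeping every statistical conclusion stable
across seeds.

# Known limitations

- Sequence-only features; no structure, conservation or domain
  information.
- The published 12-class CGR partition is unknown; results under the
  default partition are well-defined but not guaranteed to match any
  specific published CGR-24 variant (hence the override mechanism).
- The RNA 4-mer normalisation follows the published $N-2$ convention
  by default, which is very likely a carried-over protein formula;
  both modes are exposed and documented.
- No probability calibration and no alternative classifiers; vote
  fractions are scores, not calibrated probabilities.
- The dataset builder reads PDB-format files only and emits positives
  only.
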