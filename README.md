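# rpiforest

Sequence-based prediction of RNA–protein interactions (RPIs) with
conjoint triad and chaos game representation features.

Most RNAs act through complexes with RNA-binding proteins, but only a
small fraction of real RNA–protein pairs have been resolved
experimentally. `rpiforest` is for computational biologists who need a
sequence-only classifier for candidate pairs: it turns a protein
sequence and an RNA sequence into a fixed-length numeric vector,
trains a random forest on labelled pairs, and scores unlabelled ones.

## Method

Each pair is encoded by up to four feature families:

- **CTF (conjoint triad feature).** The 20 amino acids are reduced to
  seven physicochemical groups ({AGV}, {ILFP}, {YMTS}, {HNQW}, {RK},
  {DE}, {C}); every window of three successive residues is a triad over
  those groups, and the protein is the vector of normalised triad
  frequencies *f*<sub>i</sub> = *m*<sub>i</sub>/(*L*−2), i = 1…343.
  The RNA analogue counts all 256 4-mers over {A,C,G,U}, normalised by
  *N*−2 (as conventionally published; an exact *N*−3 mode is provided).
- **CGR (chaos game representation).** Proteins play the chaos game on
  a 12-gon inscribed in the unit circle (V₁ = (1,0),
  V<sub>k</sub> = (cos((k−1)π/6), sin((k−1)π/6))), one vertex per
  amino-acid class, starting at the centre; each residue moves the
  point half way towards its class vertex. The occupancy frequencies
  D<sub>k</sub> = L<sub>k</sub>/L of 24 segments (12 sectors × 2 radial
  bands) summarise the trajectory. RNA plays on the unit square
  (A,C,G,U at the corners) and is summarised over a 4×4 grid (16 cells).
- **AAC / NC.** Plain amino-acid (20) and nucleotide (4) compositions.

Five canonical feature sets are supported, with fixed dimensions
AAC+NC = 24, CTF = 599 (343+256), CGR = 40 (24+16), CTF+CGR = 639 and
CTF+CGR+AAC+NC = 663. A random forest classifies pairs; `ntree` and
`mtry` are tuned by grid search over the canonical ranges
(`ntree` ∈ [300, 500], `mtry` ∈ [1, n]) under stratified 10-fold
cross-validation, and performance is reported as Sens, Spec, ACC,
MCC and ROC/AUC (rank-statistic AUC, ties counted half).

The package also includes the structure-based dataset builder used to
assemble positive pairs from PDB complexes (two chains interact when
some protein-atom/RNA-atom distance is strictly below 3.4 Å, with
chain-length filters), and a synthetic benchmark generator that plants
sequence motifs so the whole pipeline can be exercised without any
external download.

## Worked example

```r
library(rpiforest)

sim <- generate_pairs(synthetic_config(n_pairs = 200, seed = 1))
sim
#> <rpi_sim> 200 pairs (100 positive); seed 1

mat <- build_matrix(sim$pairs, sim$proteins, sim$rnas, "CTF+CGR")
mat
#> <rpi_matrix> 200 pairs x 639 features (CTF+CGR); labels: 100 positive / 100 negative

cv <- cross_validate(mat, ntree = 400, seed = 1)
cv
#> <rpi_cv> 10-fold CV (ntree = 400, mtry = 25)
#>   Sens 0.9800  Spec 0.9300  ACC 0.9550  MCC 0.9111  AUC 0.9916
```

The simulated benchmark labels a pair interacting exactly when the
protein and the RNA both carry their planted motif; out-of-fold
accuracy 0.955 and AUC 0.992 show the CTF+CGR encoding recovers that
sequence-determined rule almost perfectly. `Sens`/`Spec` are the
out-of-fold true-positive and true-negative rates pooled over the ten
folds, `MCC` the Matthews correlation, and `AUC` the probability that
a random interacting pair outscores a random non-interacting one.

A thin command-line front end wraps the same functions:

```sh
RPI=$(Rscript -e 'cat(system.file("exec", "rpi.R", package = "rpiforest"))')
Rscript $RPI simulate --n 200 --seed 1 --out-dir sim/
Rscript $RPI cv --features ctf+cgr --protein-fasta sim/protein.fasta \
    --rna-fasta sim/rna.fasta --pairs sim/pairs.tsv --ntree 400 \
    --seed 1 --out report.json
Rscript $RPI build-dataset --pdb complex1.pdb,complex2.pdb \
    --cutoff 3.4 --min-protein 25 --min-rna 10 --out-dir dataset/
```

Every subcommand writes a `run_manifest.json` (resolved parameters,
input digests, seed, version) sufficient to reproduce its outputs.

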