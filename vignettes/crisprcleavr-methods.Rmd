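---
title: "Methods: benchmarking cleavage-site classifiers for plant CRISPR-Cas9"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: benchmarking cleavage-site classifiers for plant CRISPR-Cas9}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crisprcleavr)
```

## The problem

CRISPR-Cas9 cleaves where its single-guide RNA (sgRNA) base-pairs with a
genomic protospacer flanked by a 3-nt PAM (canonically NGG, with NAG
tolerated). Partial complementarity means the nuclease also cuts
unintended, *off-target* sites; in crop genome editing these unwanted
edits are a practical safety and regulatory concern. `crisprcleavr`
frames off-target recognition as binary classification: given an sgRNA
and a candidate site (protospacer + PAM + flanking context), predict
whether the site is a true cleavage site (label 1, on-target) or an
off-target (label 0), using sequence-derived features only. Around that
classifier it provides a complete benchmarking study: a synthetic
labeled-data generator, an eleven-model suite, an eight-metric
evaluation, and TOPSIS multi-criteria ranking of the models.

## Data model and conventions

A dataset couples a guides table (id, 17–20-nt sequence, crop tag) with a
sites table (id, guide id, protospacer, 3-nt PAM, context window, label,
strand, source). Coordinates are **0-based half-open** internally;
human-readable reports use 1-based inclusive positions. Minus-strand
sites are stored already reverse-complemented into protospacer
orientation, so `strand` is pure metadata. Ambiguous bases (`N`) are
tolerated only in context flanks; a site with `N` in its protospacer or
PAM is rejected during validation, with a row-level diagnostic.

Guide positions are numbered 1 at the PAM-distal (5′) end and `L` at the
PAM-proximal end, so "positions 17–20" of a 20-mer are the seed region
next to the PAM — the region where mismatches most strongly abolish
cleavage. For shorter guides the seed window is the 4 PAM-proximal
positions.

## Guide–site alignment

`align_guide_to_site()` computes a global (Needleman–Wunsch) alignment
of guide versus protospacer under a match/mismatch/linear-gap triple,
default **+1/−1/−2**. The triple is configurable and recorded in the
alignment object; the default was chosen as the simplest scheme that
prefers a single bulge (−2) over two substitutions (−2 vs −2 ties, so
substitutions win through the traceback preference) and is symmetric
between the sequences. Ties in the dynamic program are broken
deterministically: diagonal over gap-in-site over gap-in-guide, so every
input has exactly one canonical alignment. Affine gaps and local
alignment are deliberately out of scope: at protospacer scale (17–21
columns, at most two 1-nt bulges) they add parameters without adding
discrimination.

Each column is classified: identity → `MATCH`; gap in the site row →
`RNA_BULGE` (an unpaired guide base); gap in the guide row →
`DNA_BULGE`; otherwise a mismatch typed by base chemistry — `RR`
(purine–purine), `YY` (pyrimidine–pyrimidine), `TV` (transversion). A
**wobble flag** is raised on top of the RR/YY class when the pairing with
the target strand is the tolerated rG:dT or rU:dG pair, i.e. guide G over
site A or guide T over site C in protospacer-strand coordinates. Wobble
columns therefore count **both** in their RR/YY total and in the wobble
total; the two features deliberately overlap because the registry lists
them as separate quantities. Featurization refuses alignments with more
than 2 total bulges (configurable): larger indel structures are outside
the CRISPR off-target regime.

## The feature registry

Thirty features in three blocks, in a fixed registry order that equals
the feature-matrix header (`feature_registry()` is the machine-readable
manifest):

* **alignment block (9)** — pairwise alignment score, wobble total, RNA
  bulges, mismatches in the seed window (positions 17–20), total
  mismatches, DNA bulges, and the TV/RR/YY totals;
* **nucleotide-content block (12)** — the bases at guide positions 2, 4
  and 20 and the 4–5 dinucleotide (one-hot), GC content and
  nearest-neighbor DNA enthalpy over the extended window, and the
  chromatin-context signals (minor groove width at the PAM pentamer,
  DNase-hypersensitivity signal, guanine occupancy, nucleosome distance,
  transcription/coding flags);
* **PAM block (9)** — PAM type (NGG/NAG/other), the PAM `N` base,
  downstream bases 1, 2 and 5 past the PAM, exon flags per strand, and
  strandwise expression signals.

One-hot expansion (plus a missingness flag for the three downstream-base
features, which can run off a short context) yields a fixed 71-column
matrix. One-hot groups always sum to 1, or to 0 with the missingness
flag set — absent bases are flagged, never imputed.

The **extended window** is up to 223 nt of context centered on the
protospacer+PAM span (clamped symmetrically when the context is
shorter). The corpus this emulates names the window length but not its
anchor; centering is the only choice that treats both flanks alike. GC
content and enthalpy share the window.

**Nearest-neighbor enthalpy** sums dinucleotide-stack ΔH° values over the
window; the default parameter set is the SantaLucia (1998) unified
DNA/DNA table, shipped as a versioned plain-text file
(`extdata/santalucia1998_unified_dH.tsv`) and replaceable by any
16-entry table. The table is strand-symmetric (ΔH of a sequence equals
that of its reverse complement), a property the test suite checks.

**Annotation features** (DHS, nucleosome distance, expression,
exon/transcription/coding flags, guanine occupancy, minor groove width)
require genome-browser tracks that exist for few plant genomes, so they
enter through a provider interface. The default provider returns a
documented neutral value — 0 — for every field, including the minor
groove width: no redistributable pentamer MGW reference table is
available, and shipping a fabricated one would dress up noise as a
published measurement. Users with real tracks supply them through the
file-backed provider (`annotation_provider_table()`). Under neutral
defaults these columns are constant and contribute nothing to the
classifiers, which is the honest behaviour on unannotated data. A
bending-stiffness feature is mentioned in the corpus prose but absent
from its feature table, and is not implemented; likewise the corpus
documentation variously mentions 48 and 31 variables, but tabulates 30 —
the registry implements the 30 tabulated features and takes no position
on the others.

## The synthetic-data generator

The curated corpus of plant guide/site pairs this package emulates is
not publicly distributable, so the generator is the test substrate by
design. Its default profile reproduces the corpus composition: 15 crops,
51 guides, 174 on-targets and 205 off-targets — 379 sites. One printed
per-crop breakdown of that corpus is internally inconsistent (its
on-target column sums to 184 against a corroborated total of 174); the
default profile keeps every per-crop row as printed except maize, which
absorbs the 10-site discrepancy (21 rather than 31 on-targets), because
the totals — not the maize row — are corroborated by the downstream
split arithmetic (379 sites, 265/114 at 70/30).

Guide lengths are drawn from {17, 18, 19, 20} with probabilities
(0.1, 0.1, 0.1, 0.7) — most real sgRNAs are 20-mers, truncated guides
are the exception. On-targets embed the guide exactly, with an N+GG PAM,
centered in 223 nt of uniform-random context. Off-targets carry *k*
substitutions, *k* drawn from a distribution over 1..6 (default mass
0.10/0.20/0.30/0.20/0.12/0.08 — mostly 2–4 mismatches, as expected of
sites that survive a genome-wide similarity search), placed with the 4
seed positions down-weighted by a factor of 4 (off-targets tolerate
PAM-distal mismatches far better than seed mismatches); with probability
0.1 one 1-nt bulge is added, and with probability 0.2 the PAM is NAG
rather than NGG. These knobs are declared modelling assumptions, chosen
once so that the classes are separable but not trivially so; none is
inferred from the emulated corpus, which does not publish its mismatch
spectrum.

What the generator does **not** emulate: real genomic sequence
composition (contexts are uniform-random, so GC/enthalpy features carry
no biological signal), annotation tracks (neutral defaults), guide
re-use across paralogous sites, or experimentally validated cleavage
labels. Passing tests on synthetic data therefore demonstrate that the
pipeline machinery is correct and that the models can learn the
constructed class structure — they do not certify real-world off-target
accuracy, which is exactly why the published benchmark numbers are
shipped as reference tables rather than re-claimed.

Every label-1 site aligns to its guide with zero mismatches and bulges;
every label-0 site deviates in at least one column — an invariant the
suite checks exhaustively. Generation is a deterministic function of one
seed.

## The model suite

Eleven fixed configurations — no hyperparameter search:

| family | configurations | knobs |
|---|---|---|
| ANN | 2 architectures × 3 activations | hidden layers 25-25-25 (ANN1) or 30-20-10-5 (ANN2); logistic/tanh/ReLU; Adam, initial learning rate 0.001 |
| SVM | 4 kernels | linear, polynomial (degree 3), Gaussian RBF, sigmoid; C = 1 |
| RF | 1 | 100 trees, Gini criterion, bootstrap sampling |

The multilayer perceptrons are implemented in the package itself
(minibatch Adam on log-loss, Glorot initialization, small L2 penalty
1e-4, at most 1,000 epochs with early stopping on a 10% validation split
at tolerance 1e-4, patience 10): the architecture calls for several
hidden layers, which no single-hidden-layer fitter provides. SVMs use
`e1071` with Platt-calibrated probability outputs — a monotone mapping
of the decision values, so ranking metrics are unaffected by the
calibration; the random forest uses `randomForest`.

Continuous features are standardized to zero mean/unit variance for the
perceptron and SVM families — both behave pathologically on mixed-scale
inputs — with statistics computed **on the training portion only** and
carried inside the fitted model; the forest sees raw features. The
classification threshold is 0.5 on the predicted score; AUC uses raw
scores. Evaluation is produced on three surfaces and labelled as such:
`holdout` (the 70/30 test portion), `cv_mean` (metric means over 5-fold
cross-validation of the training portion, per-fold preprocessing
included) and `cv_pooled` (metrics of the pooled out-of-fold
predictions). The emulated study reports both a holdout and 5-fold CV
without stating which produced its tables, so this package computes all
surfaces and leaves the choice explicit. A leakage probe in the test
suite verifies that a feature equal to the label on held-out rows only
cannot inflate the CV estimate.

## Evaluation metrics

Eight metrics per report, all percentages (full precision internally,
two decimals for display): accuracy, precision, recall/sensitivity,
false-positive rate, specificity (= 100 − FPR, exactly), F1, F2 and AUC.
F-beta is $(1+\beta^2)PR/(\beta^2 P + R)$; β = 2 weighs recall four
times precision. ROC curves sweep the distinct score values with tied
scores grouped, so the trapezoidal AUC equals the Mann–Whitney pair
statistic (concordant + half-tied pairs) — an equivalence the tests
check against brute-force pair counting and against an independent ROC
implementation. A metric with a zero denominator is reported `NA` with a
warning, never silently 0. A constant-score classifier comes out with
recall 100, specificity 0 and AUC exactly 50 — the degenerate signature
to look for when a kernel collapses.

## TOPSIS ranking

The ranking stage is classical Hwang–Yoon TOPSIS over the 11 × 8
model-by-metric matrix: per-column vector normalization
$r_{ij} = x_{ij}/\lVert x_{\cdot j}\rVert_2$, equal weights 1/8, FPR as
the sole cost criterion, Euclidean distances to the per-column ideal and
anti-ideal, closeness $C_i = S^-_i/(S^+_i + S^-_i)$, rank by descending
closeness with ties broken by model id. Vector normalization makes the
closeness invariant to positively rescaling any criterion, and an
alternative identical to the (anti-)ideal scores exactly 1 (0) — both
properties are tested, alongside a step-by-step independent
re-computation of the five TOPSIS stages.

A min–max normalization variant and per-criterion direction overrides
are exposed, and `topsis_variant_sweep()` runs all normalization ×
FPR-direction combinations against a reference ranking. Applied to the
published reference matrix shipped with the package, **no standard
variant reproduces the published closeness scores** (best agreement
leaves a maximum absolute deviation above 0.3, and a wider exploratory
sweep over weightings, distances and criterion subsets did no better);
the published record is itself internally inconsistent about one of the
scores. The default variant does reproduce the qualitative outcome — the
random forest ranks first by a wide margin — and the package reports its
own computed closeness values rather than adjusting the method toward
the published ones. The acceptance suite records this deviation openly.

## Pipeline and reproducibility

`run_pipeline()` chains generation (or file input), featurization, the
70/30 split (training size `floor(0.7 N)`; the split is by site record —
a `group_by_guide` option exists but is off by default, matching the
random-record protocol of the emulated study), training, evaluation on
all surfaces, and ranking, writing every artifact plus a JSON manifest.
One global seed fans out as `stage_seed = 100·seed + stage index` (data
= 1, split = 2, models = 3, model *i* adding *i*), so each stage is
independently re-runnable. Chaining the stage functions by hand with
those seeds reproduces `run_all` output file-for-file — the composition
property the pipeline tests assert.

Problem sizes used throughout the tests are the study-scale defaults:
379 sites (265/114 split, 53-site CV folds), the full 71-column matrix,
all eleven models in the pipeline tests' reduced form and a full
eleven-model run of about half a minute. Known limitations: no
genome-wide candidate-site scanning (sites are given), no affine-gap or
local alignment, no feature selection, no deep-learning models, and
synthetic contexts are compositionally unrealistic by construction.
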