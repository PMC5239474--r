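---
title: "Methods: pseudo-component ensembles for phosphosite prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pseudo-component ensembles for phosphosite prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phosforest)
```

## The problem

Phosphorylation — the addition of a phosphoryl group to a serine, threonine
or tyrosine residue — is among the most common post-translational
modifications, and mapping which S/T/Y residues of a protein can be
phosphorylated is a standing problem in proteomics. Experimental mapping is
slow and expensive, so sequence-based classifiers are used to triage
candidate residues. `phosforest` implements such a classifier: every
candidate residue is represented by the 13-residue peptide window centered
on it, the window is encoded under four complementary numeric feature
views, one random forest is trained per view, and the four votes are fused
by majority into the final call. One model is trained per phosphorylation
type (S, T or Y); types are never pooled, because their sequence contexts
differ.

## Peptide windows and benchmark construction

For a half-width $\xi$ the window around a candidate residue is the
$(2\xi+1)$-tuple of residues centered on it. The package default is
$\xi = 6$ (13 residues), the window length repeatedly found most effective
for phosphosite models; it is configurable. Windows that overrun a terminus
are completed by replicating the nearest existing residue toward that
terminus, independently per side, so an N-terminal serine at position 1
yields a window whose six upstream slots all carry residue 1's letter.

`build_dataset()` labels every extracted window positive (annotated
phosphosite at its center) or negative (any other occurrence of the center
residue), then reduces redundancy: within each class, identical window
strings are collapsed to a single representative, and a string occurring in
both classes is kept only as a positive. Collapse-to-one (rather than
removing all copies of a repeated string) is deliberate: discarding every
repeated motif would delete exactly the conserved contexts the classifier
should learn. Cross-class conflicts resolve in favor of the positive label
because positive annotations are experimental assertions while negatives
are merely absence of annotation. Non-standard letters (U, B, Z, J, O, `*`)
are normalized to `X` at ingest; `X` belongs to no attribute group, counts
toward no composition component, and contributes its own BLOSUM62 column in
similarity sums. All user-facing coordinates are 1-based and inclusive.

The protein-collection protocol that typically precedes benchmark
construction (experimental-evidence filtering, a minimum length of 50
residues, removal of proteins with ≥50% pairwise identity) is documented
here as the expected provenance of the input proteome but is not automated:
the builder consumes a local FASTA plus an annotation TSV and assumes the
proteome has already been screened.

## The four feature views

Each view maps a window to a fixed-length numeric vector; at $\xi = 6$ the
dimensions are 13 / 5 / 20 / 5 (43 numbers in total).

**DS (disorder scores, 13-d).** Phosphosites are strongly enriched in
intrinsically disordered regions, so component $i$ is the per-residue
disorder score of the residue occupying window slot $i$; padded slots
inherit the replicated terminal residue's score. Scores come either from
files produced by an external disorder predictor
(`read_disorder_scores()`) or from the package's own deterministic
provider: the TOP-IDP per-amino-acid disorder propensity scale, min-max
scaled to $[0,1]$, mean-smoothed over a sliding window (half-width 10 by
default, a common window for profile smoothing at protein scale). The
provider is a simple propensity profile, not a trained disorder predictor;
when accuracy of the disorder channel matters, precomputed scores from a
dedicated tool should be supplied.

**KNNS (nearest-neighbor scores, 5-d).** Local sequence clusters recur
around phosphosites, so the query window is compared against a reference
pool of labeled windows using the ungapped column-sum BLOSUM62 similarity
$\sum_i B(a_i, b_i)$. For each $k \in \{2, 4, 8, 16, 32\}$ the component
is the fraction of positive labels among the $k$ most similar reference
windows. The five $k$ values span neighborhood scales in powers of two and
are configurable; similarity ties break by stable reference order so the
encoding is deterministic. When the query is itself a reference member
(training-set encoding) it is excluded from its own neighbor list —
otherwise every training window would trivially see its own label, leaking
it into the feature. The BLOSUM62 matrix ships as an NCBI-format text file
and any matrix in that format is a drop-in replacement.

**AAOF (occurrence frequencies, 20-d).** Component $j$ is the count of
amino acid $j$ in the window divided by 13, in single-letter alphabetical
order. Components sum to 1 for X-free windows and to $1 - \#X/13$
otherwise.

**PWAAC (position-weighted composition, 5-d).** Residues are partitioned
into five physicochemical groups — aliphatic $\{G,A,V,L,I,P\}$, aromatic
$\{F,Y,W\}$, polar-neutral $\{S,T,C,M,N,Q\}$, positively charged
$\{K,R,H\}$, negatively charged $\{D,E\}$ — and, indexing window slots
$j = -\xi \ldots +\xi$ with 0 at the center, component $i$ is

$$c_i = \frac{1}{\xi(\xi+1)} \sum_{j=-\xi}^{\xi}
\delta_i(j)\,\bigl(j + |j|\bigr),$$

where $\delta_i(j)$ indicates that the residue at slot $j$ belongs to group
$i$. The weight $j + |j|$ equals $2j$ downstream of the center and 0 at and
upstream of it, and since $\sum_{j=1}^{\xi} 2j = \xi(\xi+1)$ each $c_i$
lies in $[0,1]$, with $\sum_i c_i = 1$ whenever every downstream residue is
grouped. This weighting was adopted because it is the reading under which
the $\xi(\xi+1)$ normalizer is exact; whether upstream positions should
receive any weight is genuinely open, so the weight vector is a function
argument and alternative weightings are drop-in.

## Ensemble fusion

Each view's forest is a 100-tree probability random forest (unlimited
depth; both surfaced in `forest_spec()`), trained on that view's encodings
of the same windows; per-view seeds derive from one master seed by fixed
offsets. A view votes positive when its positive-class probability is at
least 0.5. The fused call is positive when more than two of the four views
vote positive. A 2–2 tie is resolved by a seeded uniform pick between the
two labels — the behavior a voting ensemble with an even member count
implies — and the prediction records that the tie was broken; because a
random tie cannot be asserted in tests, a deterministic mode instead
thresholds the fused score (the arithmetic mean of the four probabilities)
at 0.5. The fused score is also the ensemble's continuous score for ROC
purposes; the mean was chosen over alternatives (median, vote count)
because it is strictly monotone in every member probability and so yields
a fine-grained ranking. Models serialize to a single-file archive carrying
the four forests, the encoder context and the KNNS reference pool, with a
format version that is checked on load.

## Metrics, cross-validation and class imbalance

With $N^+$ positives of which $N_-^+$ are missed and $N^-$ negatives of
which $N_+^-$ are falsely called:

$$\mathrm{Sn} = 1 - \frac{N_-^+}{N^+}, \quad
  \mathrm{Sp} = 1 - \frac{N_+^-}{N^-}, \quad
  \mathrm{Acc} = 1 - \frac{N_-^+ + N_+^-}{N^+ + N^-},$$

$$\mathrm{MCC} = \frac{1 - \left(\frac{N_-^+}{N^+} +
  \frac{N_+^-}{N^-}\right)}
  {\sqrt{\left(1 + \frac{N_+^- - N_-^+}{N^+}\right)
         \left(1 + \frac{N_-^+ - N_+^-}{N^-}\right)}}.$$

This "intuitive" MCC form is algebraically identical to the standard
Matthews correlation coefficient (the test suite asserts the identity on a
thousand random confusion tables). When a factor under the radical is zero
— every prediction in one class — the MCC is reported as *undefined* with
a flag rather than silently as 0, because a silent zero is
indistinguishable from a genuinely uninformative classifier.

Evaluation uses stratified five-fold cross-validation: per class, fold
sizes differ by at most one; each fold is held out in turn and predicted
by a model trained on the other four. Within cross-validation the KNNS
reference pool is strictly the training folds — the protocol's one subtle
leakage point: had held-out windows remained in the pool, their labels
would enter the test encodings and inflate every metric. Both the mean
over fold metrics (the headline convention) and metrics pooled over all
held-out predictions are reported, since the two conventions differ
slightly and a reader should be able to inspect either.

Phosphoproteome benchmarks are heavily imbalanced (roughly 10 negatives
per positive). Training on the skewed set would bias the classifier toward
the majority class, so `balanced_evaluation()` splits the negatives into
ten seeded groups of near-equal size, pairs each group with the full
positive subset, cross-validates each of the ten balanced sets, and
averages the ten per-run means into the final score. For deployment,
`cmd_train()` uses a single balanced draw (the first negative group) by
default; averaging over the ten draws is an evaluation-time protocol, and
whether a deployed model should instead aggregate ten forests is left to
the user (both modes are reachable through the API).

ROC curves sweep the unique fused scores as thresholds and report
(FPR, TPR) points with trapezoidal AUC; the implementation is checked in
the tests against the pairwise Mann–Whitney formulation and against an
independent library.

## The synthetic generator

`generate_synthetic_study()` produces annotated proteomes so the whole
pipeline is testable without downloads. Background residues are uniform
over the 20 standard letters (configurable); candidate anchors are laid
out every 13 residues away from the termini and planted as positive sites
at a configurable rate; the center-type letter's frequency at non-anchor
positions is tuned analytically so the realized negative:positive ratio
lands near the requested target (default 10:1, the imbalance typical of
real per-type benchmarks; the generator raises an error if the realized
ratio misses by more than 20%). Signal is injected into both channels the
views can see, because a view with no recoverable signal would reduce the
ensemble to three informative members: around each planted site, flanking
residues are redrawn with probability `effect_strength` from upstream
(R/K) and downstream (P/E/D) motif distributions — downstream bias is
essential for the PWAAC view, which weights only downstream slots — and
the disorder profile is raised by 0.3 × `effect_strength` within ±10
residues, emulating the disorder enrichment of real phosphosites. Motif
redraw never overwrites a center-type letter, so candidate density is
independent of effect strength and `effect_strength = 0` is *exactly* the
background process — the null case used to check that the pipeline finds
nothing when there is nothing to find.

What the generator does not emulate: real phosphosite motif statistics
(kinase-specific motifs, position-specific information content),
sequence-identity structure between proteins, and annotation noise
(unlabeled true sites in the negative class). Passing tests therefore
demonstrate that the machinery recovers planted signal and stays calibrated
under null, not that any particular accuracy will be achieved on a real
proteome.

## Problem sizes and numerical choices

The test suite validates signal recovery and null calibration on a
benchmark-shaped study of about 600 positives and 6,000 negatives
(60 proteins of ~1,300 residues) under the full balanced 10-group × 5-fold
protocol, and the monotonicity of accuracy in effect strength at a reduced
size (about 100 positives and 1,000 negatives per level, five levels) —
sizes chosen so the full suite runs in a few minutes on one CPU while
keeping per-fold class counts large enough for stable fold metrics.
Encoder correctness is asserted against exhaustive oracles at tiny sizes
(reference pools of up to 8 windows for KNNS, position-by-position double
loops for PWAAC).

Numerical conventions worth stating: similarity ties in KNNS break by
stable reference order; forest seeds and `num.threads = 1` make ranger
training deterministic; all randomness (fold assignment, negative-group
splitting, tie resolution, generation) is derived from explicit seeds
through a save/restore wrapper, so no call disturbs the session RNG;
report files are written with fixed-format numbers so identical runs are
byte-identical; degenerate inputs (empty sequences, one-class ROC input,
classes smaller than the fold count, k exceeding the reference pool,
residues outside every attribute group) raise immediate errors rather than
propagating NaN.

## Limitations

The disorder provider is a propensity profile, not a disorder predictor;
the KNNS k-grid and the five-group partition are declared defaults, not
values recovered from any published predictor; no probability calibration
is applied to the fused score; and multi-label proteins (phosphorylated at
more than one residue type) are handled by independent per-type models
with no cross-type coupling.
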