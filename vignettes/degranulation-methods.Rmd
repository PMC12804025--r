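---
title: "Methods: time-resolved secretome analysis of neutrophil degranulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: time-resolved secretome analysis of neutrophil degranulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(granulekit)
```

## The measurement model

`granulekit` analyzes two parallel DIA label-free quantification (LFQ)
readouts of stimulated neutrophils:

* **Cellular proteome** — protein-group intensities (`PG.MaxLFQ`) for
  CONTROL and stimulated conditions at 0, 15, 30, 60, 120 and 240 min with
  three biological replicates. The quantity of interest is the *relative
  percentage*: the replicate-mean intensity at time *t* as a percentage of
  the 0-min baseline mean of the same condition, so every trajectory starts
  at 100 and depletion or induction reads directly as departures from it.
* **Secretome** — conditioned-media intensities for control plus stimulated
  conditions at 0, 5, 15, 30, 60 and 120 min, one sample per condition-time
  (trend information over six points substitutes for replication). The
  quantity of interest is the *fold change* FC(t) = stim(t)/control(t) at
  matched times.

Secretome tables are normalized in two steps, in this order:
median normalization (each sample's log2 intensities shifted so its median
equals the grand median of sample medians) and external-standard
normalization: each sample is divided by its spike-in intensity relative to
the geometric mean of the spike-in across samples. The geometric mean is a
deliberate choice of reference — it is scale-free and makes the operation
idempotent — and its consequence is that absolute intensities are recovered
only up to one global constant; every downstream quantity is a ratio, so
the constant cancels. The spike-in matters because genuine bulk secretion
changes the median: median normalization alone would flatten real signal,
while a constant-amount foreign standard tracks only technical run-level
variation.

## The release screen

For each stimulated condition, each protein's FC trajectory is fitted by
ordinary least squares against time in hours, and the protein is called
**released** when

1. the fitted slope is strictly positive, and
2. the *observed* FC exceeds 1.5 at one or more post-baseline time points
   (the 0-min point carries no stimulation signal and is excluded from the
   max; it still anchors the fit).

Both inequalities are strict. Exclusions (mitochondrial, ribosomal,
histone) are applied after the threshold rule so every discarded call
carries its reason; exclusion lists are data (an annotation column), with
`infer_exclusion_class()` offering a keyword screen (RPL/RPS, histone
families, MT- prefixes) as a convenience. Per-condition calls are combined
by set union, and the catalog is split by prior granule-subset annotation
into canonical (non-empty membership, counted per subset with
multi-membership honored) and non-canonical proteins, the latter summarized
against four externally predicted secretion routes (classical signal
peptide, nonclassical, transmembrane, vesicle) with "predicted secreted" as
their OR.

Two design points deserve emphasis. Criterion (2) is evaluated on
*observed* FCs rather than fitted values — the more sensitive and less
specific convention, kept as the default. And the screen has no
error control by construction: with single-sample trajectories and
multiplicative noise of CV 0.2 in both numerator and denominator,
sd(log FC) ≈ 0.28, so a flat background protein exceeds FC 1.5 at at least
one of five points with probability ≈ 0.3, and the slope sign adds only a
factor ≈ 2 of protection. After the three-condition union roughly a third
of background proteins pass. The synthetic-data tests make this visible:
recall of planted released proteins is ≈ 0.99 while precision is ≈ 0.4.
Users should read the catalog as a high-sensitivity candidate list whose
specificity comes from the orthogonal evidence layered on top (cellular
depletion, kinetic similarity, topology), not from the screen itself; a
per-measurement CV below ≈ 0.1 — e.g. replicated secretome sampling —
would be needed before the raw screen itself became high-precision.

## Differential testing

Cellular differential abundance at a (condition, time) stratum is a
two-tailed Welch t test on log2 intensities, Benjamini–Hochberg adjusted
within the stratum, significant at adjusted p ≤ 0.01 together with
|FC| ≥ 1.5. The variance-moderated statistic used by MS-focused pipelines
is intentionally not reimplemented: the screens here are driven by the
thresholds, not the moderation, and the Welch test is exactly calibrated
(empirical type-I ≈ 0.036 at nominal 0.05 for 3 v 3; the mild conservatism
is the known small-sample behavior of Welch's approximation). The cost of
foregoing moderation is power: at three replicates the attainable p-value
is bounded by the tiny degrees of freedom, so after FDR adjustment even
4-fold shifts at 5% CV are detected with probability ≈ 0.85, not 1, and at
20% CV the adjusted threshold is effectively unreachable. Where a
downstream stage only needs a ranked input set (clustering, below), it
falls back to the unadjusted p threshold with a logged message rather than
failing on an empty set.

The **conserved core set** across the three stimuli takes the final-time
strata, requires adjusted p < 0.05 in all three conditions, and keeps
proteins whose log2 FC carries the same sign throughout, recording the
shared direction.

## Temporal clustering

Profiles (replicate-mean log2 intensities over time) of the differential
proteins are standardized per protein to mean 0 and unit spread using the
population standard deviation — the trajectory is the complete object of
interest, not a sample — and flat profiles are dropped with a record.
Fuzzy c-means then alternates the standard updates: memberships
$u_{ij} = 1/\sum_k (d_{ij}/d_{ik})^{2/(m-1)}$ with Euclidean distances and
centroids $c_j = \sum_i u_{ij}^m x_i / \sum_i u_{ij}^m$, with centroids
initialized by seeded sampling of input rows (fully deterministic given the
seed), stopping when the largest membership change drops below `tol`. A
point coincident with a centroid takes full membership there (the limit
convention). The objective trace is recorded and is non-increasing; this is
asserted in the test suite on every run. The default fuzzifier is m = 2,
the customary choice for omics profiles; as m → 1 the algorithm reproduces
seeded Lloyd k-means, which the tests verify on well-separated instances
(the regime where the hard limit is well defined — near ambiguous
boundaries a soft and a hard assignment legitimately differ).

The cluster number is chosen by maximizing the mean silhouette width of the
hardened assignment over a candidate range, ties broken toward fewer
clusters. The upstream tool the analysis emulates auto-infers its cluster
count without documenting the rule; silhouette was adopted as a standard,
reproducible criterion, which is also why cluster *counts* are not treated
as fixed targets anywhere in the package.

## Pattern integration and kinetic assignment

"Increase in the supernatant with a concordant decrease in the cell" is,
in practice, a visual judgement; reproducibility demands numbers, so
the package defines explicit, configurable stand-ins: **depletion** is a
negative cellular slope with a minimum at or below 100 − 20 percent, and
**induction** a positive slope with a maximum at or above 100 + 50 percent.
The release flag (from the secretome screen) crossed with
depletion/induction yields five exhaustive, mutually exclusive labels.
The deltas (20 and 50) are stated in every output as parameters, not
discoveries.

Kinetic subset assignment builds one consensus per granule subset as the
mean of its markers' z-scored FC trajectories (default marker panels: AG —
AZU1, MPO, ELANE, PRTN3; SG — LCN2, LTF, MMP8, CHI3L1, CRISP3, TCN1, LRG1,
OLFM4; GG — FCN1, FGL2, MMP9, CAMP, CHIT1, CD93, PGLYRP1; SV — FCGR3B,
CD14, ITGAM; all editable), scores each protein by Pearson correlation
against each consensus, and assigns the best subset when r ≥ 0.8.
Z-scoring makes the score invariant to affine rescaling of the trajectory,
so abundance and release magnitude do not leak into the kinetic match.
Correlation similarity is suggestive, not locative: the package never
claims subcellular localization from kinetics alone.

## Sheddase substrates and topology

Substrate calls compare stimulus versus stimulus-plus-inhibitor conditioned
media (three replicates per arm) by a two-tailed Welch t on log2
intensities; a substrate requires p < 0.05 *and* a directional effect
log2(mean stim / mean stim+inhibitor) > 0.6 — the inhibitor must reduce
the soluble level; an increase never qualifies regardless of significance.
No multiplicity adjustment is applied by default (the convention is a
plain per-protein test; BH is available by flag). The effect gate dominates
the operating characteristics: under the null the Welch test alone passes
≈ 3.5% of proteins, but the joint rule passes ≈ 0, while 2-fold planted
reductions at 10% CV are recovered with power > 0.99.

Peptides are mapped onto single-pass topology models by interval logic: for
a type I protein the N-terminal side of the first transmembrane span is
extracellular and the C-terminal side intracellular; type II is reversed. A
peptide fully inside one region takes its label, fully inside a
transmembrane span is `transmembrane`, and anything crossing a boundary —
including interior loops of multi-pass models, whose sidedness this
convention cannot resolve — is `spanning`. The per-protein ectodomain
fraction is computed over non-spanning peptides with a strict majority
flag. Transmembrane span coordinates are inputs (external topology
predictions); the package does not predict them.

## The synthetic-data generator

The generator exists to give every classifier a ground truth under the
study's own design: 4 cellular conditions × 6 times × 3 replicates;
control + 3 stimulated secretome conditions × 6 times × 1 sample with a
constant-amount spike-in; stimulus ± inhibitor × 3 replicates. Class
templates are deliberately simple stand-ins (per-protein kinetic
parameters are not available to estimate from):

* released: supernatant FC(t) = 1 + (A − 1)·t/(t + t½) with A = 3 and
  t½ = 30 min — a saturating curve matching the observed rapid secretion
  phase between 15 and 30 min without claiming exact kinetics;
* depleted: cellular relative percentage falling linearly from 100 to a
  floor of 40%; induced: rising linearly to 300% (the scale of strongly
  induced cytokines); background flat.

Noise is multiplicative log-normal with σ chosen so the CV matches
`noise_cv` (default 0.2, a realistic protein-level figure for biological
replicates); missingness is completely at random at `dropout_rate`
(default 0.1) — intensity-dependent missingness is real in LFQ data but is
deliberately not modeled, so tests that pass here say nothing about
missing-not-at-random regimes. Secretome runs carry a uniform run-level
scale distortion (default [0.8, 1.25]) that the spike-in row tracks
noise-free, making normalization testable: with noise off, planted FC
trajectories are recovered to 1e-9 after spike-in normalization. Route
flags of planted released proteins are drawn at per-route prediction rates
typical of neutrophil-released proteins (20.4% signal peptide, 33.1%
nonclassical, 10.7% transmembrane, 59.1% vesicle); half of planted released proteins carry
granule-subset annotations (the canonical arm). Shed membrane proteins are
flat in the secretome time course — their planted signal lives entirely in
the inhibitor experiment, keeping the release and shedding ground truths
orthogonal — and are substrates in all three stimuli. Everything is
deterministic from the config seed; the cellular, secretome and shedding
simulations derive the same truth from the same config.

What the generator does **not** emulate: peptide-to-protein rollup,
retention-time effects, intensity-dependent missingness, batch structure,
and correlated noise between compartments. Classifier recovery on this
synthetic data demonstrates the implementations are correct under the
stated model, not that real-data operating characteristics will match.

## Numerical choices and degenerate inputs

* Replicate aggregation is the arithmetic mean of intensities before
  ratios (ratio-of-means is stable under dropout).
* A zero or missing 0-min baseline marks a relative-percentage trajectory
  undefined rather than erroring; undefined slopes flag the protein.
* Zero variance in both arms with equal means gives p = 1 (never a call);
  with unequal means, p = 0.
* Fewer than two complete replicates in an arm marks a protein untested.
* Strict inequalities throughout the release and substrate rules.
* Silhouette ties break toward fewer clusters; degenerate (all-identical)
  profile sets are an error.
* Problem sizes in the test suite and acceptance script are chosen for
  desk-scale runs: 1000-protein release recovery, 20,000-protein null
  calibrations (the Welch 3 v 3 size ≈ 0.036 needs that many draws for a
  stable estimate), 20 instances for the k-means-limit check.

## Known limitations

The release screen's precision at single-sample, CV-0.2 noise is ≈ 0.4 (see
above) — by design it trades specificity for sensitivity. The Welch test
deliberately forgoes variance moderation, costing power at n = 3 after FDR
control. Kinetic similarity assumes subset-coherent kinetics, which the
marker consensus only approximates. Topology calls ignore post-cleavage
fragment boundaries: a peptide's domain is read off the intact model.
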