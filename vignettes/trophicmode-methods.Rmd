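---
title: "Methods: gene-content trophic-mode prediction and cytometric bacterivory assays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gene-content trophic-mode prediction and cytometric bacterivory assays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trophicmode)
```

# Overview

`trophicmode` implements two connected analyses for studying
phago-mixotrophy — the combination of photosynthesis and particle
ingestion in one organism:

1. a **gene-based predictor** that turns a strain's predicted protein set
   into posterior probabilities of three trophic capabilities
   (phagocytosis, photosynthesis, prototrophy), and
2. a **flow-cytometric feeding assay** that quantifies ingestion of
   fluorescently labelled bacteria (FLB) and tests it against fixed
   controls.

Real studies of this kind train on curated genomes and score large
transcriptome collections; those inputs are far beyond a package test
suite. Both arms therefore ship *synthetic generators* that are
first-class, tested code: they define the statistical world in which every
claim made by the test suite holds. The limits of that world are discussed
at the end.

# The prediction arm

## Training world

`generate_world()` simulates a training set of 35 genomes whose trait
composition matches the canonical training panel: 14 photosynthetic, 16
phagocytotic, and 21 prototrophic organisms, with traits not mutually
exclusive. Marginal counts are matched exactly; the overlap structure is
randomized because only the marginals are fixed by the study design (an
open point we resolve by randomization). Each world also plants:

* **trait-linked families** (default 25 per trait) carried with
  probability `p_in = 0.9` by trait-positive genomes and `p_out = 0.05`
  otherwise,
* **universal marker families** (default 50) carried by every genome,
  standing in for universal single-copy orthologs and powering the
  completeness gate, and
* **background families** (default 40) carried at rate 0.5 with no trait
  signal.

Every family has one ancestral random sequence (default 120 residues);
each carrying genome receives a copy mutated by i.i.d. substitutions
(default rate 0.05/site). Substitution-only evolution keeps family members
equal-length, so the clustering stage has an exact oracle; an optional
indel rate exercises the alignment machinery when wanted. Held-out
evaluation strains (default 20) are generated the same way, with trait
labels drawn at the training marginal frequencies, and are degraded to
transcriptome-like sets by removing a fixed fraction of proteins uniformly
at random (`degrade_to_transcriptome()`), mimicking the incompleteness of
expression-dependent assemblies.

The defaults above are the conditions under which the end-to-end
acceptance checks are run; they were chosen once, to be realistic for the
problem (strong but imperfect trait linkage, ~10% transcriptome dropout),
and are all exposed in `world_config()`.

## Gene families

`pairwise_similarity()` builds the all-vs-all similarity graph. Pairs are
prefiltered by exact shared 5-mer counts (two or more shared 5-mers by
default); surviving pairs are scored by affine-gap Smith–Waterman local
alignment under BLOSUM62 (gap open 11, extend 1) in compiled code, and
edges below a score cutoff (default 50) are dropped. The prefilter is what
makes all-vs-all tractable: unrelated random sequences essentially never
share two 5-mers, while family members at 5% divergence share most of
them. An optional band argument restricts the alignment diagonal; the
default is the exact, unbanded score because the sequences involved are
short.

`mcl_cluster()` is a faithful Markov Cluster iteration: the edge-weight
matrix gains self-loops at the column maximum, is column-normalized, and
then alternates expansion (matrix power, default 2) with inflation
(entrywise power, default 2.0, followed by column renormalization).
Entries below `1e-5` are pruned each iteration — standard MCL practice
that keeps the matrix sparse; iteration stops when the largest entrywise
change falls below `1e-6` (warning and current partition on
non-convergence). Clusters are read off as connected components of the
converged support. Proteins with no surviving edge become singleton
families, which the downstream diversity criterion removes; this is the
conservative resolution of an unspecified corner.

`diversity_filter()` applies the eligibility rule for model building:
a family must contain genes from at least 3 distinct genomes.

## Profile models and presence calls

Eligible families are aligned (`align_family()`) and converted to
position-specific profile models (`build_profile()`). The alignment is a
deterministic center-star: the longest member anchors global pairwise
alignments that are merged on center coordinates. In substitution-only
worlds this reduces to a gapless stack, which is exact. Match columns are
those with at most 50% gaps; column probabilities use pseudocounts,
`P(r) = (count_r + alpha * bg_r) / (n + alpha)` with `alpha = 1` and a
uniform background.

Presence scoring (`score_presence()`) is an ungapped best-window log-odds
scan rather than a full forward/Viterbi profile-HMM pass: the score of a
protein is the maximum over all placements of the profile of the summed
`log2(P(r)/bg_r)`. This preserves the presence/absence contract at package
scale, and a full profile-HMM backend could be swapped in behind the same
operation. The presence threshold is self-calibrated per family as a
fraction (default 0.7) of the *minimum* training-member score — every
training member clears it with margin, while decoys (shuffled or reversed
sequences) fall far below; the original tool's detection threshold is not
published, so self-calibration is the package's own definition.

## Enrichment, GO scores, feature selection, classifier

`proportion_enrichment()` tests each family's carriage in trait-positive
vs trait-negative training organisms with a one-sided pooled-variance
two-proportion z-test; a family is enriched when `p <= 0.05` with positive
direction. No multiple-testing correction is applied (the upstream tool's
behaviour is unstated; `alpha` is exposed). Two numerical conventions
matter: a pooled proportion of exactly 0 or 1 makes the statistic 0/0 and
is defined as `z = 0` (the observed proportions are equal there), and the
test is one-sided by design — the method looks for enrichment, never
depletion. The exact Fisher test is deliberately *not* the implementation:
it serves as the independent oracle in the test suite. The two tests
agree in direction everywhere and the z-test flags every Fisher-significant
table; the z-test additionally flags a small fraction of borderline tables
that the (conservative) exact test does not — an irreducible property of
the normal approximation at these group sizes, quantified exhaustively in
the acceptance suite.

Enriched families are grouped by their GO biological-process annotations
(`go_group()`; families without annotation fall into an `unassigned`
category, and multi-annotated families join every category they name).
`weighted_scores()` summarises each category per organism as a weighted
carriage fraction with weights `w = min(-log10 p, 10)`: the weighting
scheme of the upstream tool is unpublished, so this definition — more
significantly enriched families count more, capped to keep one family from
dominating — is the package's own, isolated behind one function so
alternatives are pluggable.

`boruta_select()` implements Boruta all-relevant feature selection:
shuffled "shadow" copies of the features (padded to at least five) join
the design, an ensemble of randomized trees (`ranger`, permutation
importance scaled by its standard error) scores importances, a feature
scores a *hit* when it beats the best shadow, and a two-sided binomial
test on hit counts (Bonferroni-corrected over features) confirms or
rejects; decisions are sticky and rejected features leave the model.
Features still tentative at the iteration cap are resolved by the
classical "rough fix" (median importance vs median best-shadow importance)
because the pipeline needs a hard feature set.

`pnn_fit()`/`pnn_predict()` implement the probabilistic neural network — a
Parzen kernel-density classifier. Three independent binary networks are
trained, one per capability, because organisms can hold several
capabilities at once; the alternative of one eight-class network was
rejected on that ground. The posterior is the prior-weighted normalized
Gaussian kernel density over the stored class vectors. The bandwidth is
selected by a leave-one-out accuracy grid over `{0.05, …, 1.0}` (smallest
maximizer wins, recorded in the model); priors are class frequencies, e.g.
16/35 positive for phagocytosis. Per-vector kernel weights support an
exact invariance: duplicating a training vector while halving its weight
changes nothing.

Calls use a strict `p > 0.5` threshold, and the four Boolean combinations
collapse to categories: phagotrophy + photosynthesis = phago-mixotroph;
photosynthesis alone = photo-autotroph; prototrophy without either =
strict osmotroph; phagotrophy without photosynthesis = phago-heterotroph;
none = unclassified.

`completeness_gate()` re-expresses assembly completeness as the fraction
of universal marker families detected; sets missing 32% or more are
flagged (`gated = TRUE`) but still scored, with a whitelist mirroring how
borderline transcriptomes are sometimes retained deliberately. Within the
pipeline, the marker set is identified as the trained families detected in
*all* training genomes.

## Map projection

For visualisation, the three posteriors gain a dependent fourth "absence"
coordinate `mean(1 - p_i)` and are normalized onto the simplex
(`to_composition()`). The composition is embedded at the corresponding
barycentric point of a regular tetrahedron with unit vertices
`(1,1,1), (1,-1,-1), (-1,1,-1), (-1,-1,1)` (scaled by `1/sqrt(3)`), in the
order phagotrophy, photosynthesis, prototrophy, absence; the direction of
that point gives latitude and longitude, with the barycenter mapped to
(0°, 0°) by convention. Any rigid rotation of the tetrahedron would be
visually equivalent; fixing this one makes tests exact.
`mollweide()` then solves `2*theta + sin(2*theta) = pi*sin(phi)` by Newton
iteration (tolerance `1e-10`, start `theta = phi`, poles handled
analytically, iterates clamped to the valid range so the vanishing
derivative at the poles cannot destabilize the solve) and maps to the
equal-area ellipse `x = (2*sqrt(2)/pi) R lambda cos(theta)`,
`y = sqrt(2) R sin(theta)`. An inverse projection exists for round-trip
testing.

# The assay arm

## What the generator emulates

`generate_facs_run()` simulates, per treatment and replicate, a
pre-inoculation baseline read and reads at t = 0–3 h: algal events with
log-normal forward scatter, chlorophyll red fluorescence and baseline
green fluorescence; co-occurring FLB events (low scatter and red, bright
green); a fed fraction following `f(t) = f_max (1 - e^{-rate t})` in which
each fed cell gains the summed green of a zero-truncated Poisson number of
ingested FLB; and — the key artifact — an extracellular-fluorophore
background `b0 * e^{-beta t}` added to the green channel of *every*
post-inoculation event. The background produces the jump in apparent
green fluorescence right after FLB addition, and its photobleaching decay
produces the slow decline that can drive the fed-cell change negative for
slow grazers. Background is additive per event rather than a separate
small-particle population — the simplest mechanism that reproduces both
described behaviours in the gated population. Fixed (`CT_PFA`) and
heat-killed (`DTAF`) treatments force the fed fraction to zero. Default
reads carry 10,000 algal events, mirroring assays run at dilute algal
densities with a capped event count per subsample; all intensities are
arbitrary units, and true fed labels ride along for oracle tests.

## Quantification

`gate_algae()` selects the algal population on red fluorescence and
forward scatter. The default red threshold is a deterministic 1-D
two-means split of `log(red)` (Lloyd iterations from the extreme values,
threshold at the geometric mean of the centers) with a unimodality guard:
when the two centers are closer than twice the summed within-cluster
spreads, the read is treated as a single algal population and kept whole.
The guard is what makes gating idempotent and robust to unbalanced
algal/bacterial mixtures, where a fixed median split would misclassify;
fixed-quantile and absolute-threshold policies remain available.

`gf_prior()` takes the maximum gated green fluorescence of the baseline
read (a quantile policy exists for very large baselines);
`per_fed()` counts gated cells whose green *strictly* exceeds that
threshold — ties count as not fed — and reports the percentage;
`per_delta()` is the t3 − t0 difference of those percentages, which is
how the assay removes the background jump present in both time points.
Negative values are legal and meaningful (photobleaching outrunning slow
ingestion). `flb_stability()` runs a two-sided Student's t-test on the
FLB-only reads at t0 and t3 to confirm the label itself was stable.

## Statistics

`feeding_significance()` reproduces the assay's decision chain per strain
and nutrient condition: Shapiro–Wilk normality checks on each arm's
per-delta triplicates (failures are recorded as warnings, not errors —
with n = 3 the test has almost no power, and the chain is described as
confirmatory), an F-test of variance homogeneity between the live-prey arm
and the fixed control, then a one-tailed Student's t-test — or Welch's
when the F-test rejects at the same 0.05 threshold — of live > control.
One global `alpha = 0.05` drives every test in the chain. Control
comparisons default to per-strain triplicates; a pooled-control mode
exists because the pooling level of the original comparisons is ambiguous.

# What the synthetic worlds do and do not show

The generators are designed so that every pipeline stage has a
planted-truth oracle: family recovery can be checked exactly, presence
errors equal the dropout rate by construction, fed-cell recovery is
binomial around the planted trajectory. Passing these tests demonstrates
the machinery is correct *in the stated statistical world*. That world
deliberately omits: phylogenetic correlation among genomes (carriage draws
are conditionally independent given labels), paralogy (one copy per
carrying genome), domain shuffling and partial homology, real GO DAG
structure (the ontology is flat), instrument artifacts beyond the additive
background (no spillover, no doublets), and any physical calibration of
arbitrary units. Results on real data depend on how far those omissions
matter; the package's claims are about the algorithms, not about any
particular organism.

# Problem sizes and determinism

All stochastic components draw from explicit seeds carried in the config
objects; identical seeds give byte-identical outputs, including written
FASTA/CSV artifacts. The shipped acceptance checks use: 10 independent
worlds of 35 training + 20 held-out genomes for end-to-end recovery
(~11 s per world on one core), the exhaustive 10,028-table oracle
comparison for the enrichment test, 100 all-noise worlds for the Boruta
false-confirmation rate, 73 simulated cytometry runs of 10,000 algal
events for the assay properties, and 10^5 points for the equal-area check
of the projection — sizes chosen so the whole suite runs in minutes while
keeping every Monte-Carlo margin wide relative to its threshold.
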