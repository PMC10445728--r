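---
title: "Methods: quantifying lipid-raft proximity proteomes across BCR activation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying lipid-raft proximity proteomes across BCR activation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(raftquant)
```

## The experiment this package analyzes

APEX2 proximity biotinylation targeted to plasma-membrane lipid rafts tags,
with biotin, every protein within roughly 20 nm of the enzyme during a
one-minute labeling window. Applied to B cells across an anti-IgM activation
time course, it yields a label-free LC-MS/MS experiment with six conditions —
two biotinylation controls (no H~2~O~2~, no biotin-phenol) and four
activation time points (0, 5, 10 and 15 min) — each in triplicate, eighteen
samples in all. The search engine's protein-level output (a `proteinGroups`
table: accessions, unique-peptide counts, decoy and contaminant flags, one
raw intensity column per sample) is the input to everything here.

Four questions drive the analysis, and each gets a module:

1. *Which proteins are identified?* — decoy/contaminant removal and a
   unique-peptide threshold (`filter_identified()`).
2. *Which proteins move toward or away from the rafts when the BCR is
   engaged?* — a complete normalized log2 matrix
   (`preprocess()`) followed by moderated-t contrasts of each activation
   time point against resting (`moderated_t()`, `call_significant()`).
3. *Which proteins simply live in the rafts?* — the two-step
   baseline-enrichment / stimulation-stability classifier
   (`classify_raft_resident()`), plus detection-based presence/absence set
   algebra on the raw table (`detect_condition_presence()`,
   `exclusive_sets()`).
4. *How do the responders co-behave over time?* — k-means on per-time-point
   log2 fold-change profiles with internal-validity selection of the cluster
   count (`select_k()`, `kmeans_profiles()`).

Flow-cytometry scalars used around the proteomics — the detergent resistance
index and the receptor internalization fraction — are in `cytometry`
functions, and a synthetic-data generator with planted ground truth
(`simulate_experiment()`) makes the whole pipeline testable end to end.

## Preprocessing model and its assumptions

Raw intensities are treated as log-normal: all statistics operate on
`log2(intensity)`, and a recorded intensity of 0 means *not quantified*, not
"zero abundance". Three fixed steps turn the raw matrix into a complete one;
the order is enforced because each step's assumptions depend on the previous
one.

**Missingness filter.** A protein missing in more than `max_missing = 6` of
the 18 samples (i.e. quantified in fewer than 12) is excluded from
quantitative analysis. The boundary is inclusive: exactly 6 missing is kept.
The rule is deliberately phrased per *sample*, not per condition — with
triplicates, 12-of-18 admits proteins absent from up to two whole
conditions, which is what lets genuinely condition-exclusive proteins fall
out of the quantitative branch and be handled by the presence/absence branch
instead.

**kNN imputation.** Label-free missingness is dominated by low-abundance
dropout (missing not at random), so holes are filled from the `k = 10`
proteins with the most similar intensity profiles: for a missing cell
(protein *p*, sample *s*), the imputed value is the mean over the *k*
nearest neighbours of *p* (Euclidean distance on co-observed samples, scaled
by $\sqrt{n_{samples}/n_{co\text{-}observed}}$ so sparse overlaps are not
spuriously close) that are observed in *s*. Neighbours are proteins, not
samples; ties in distance are broken by input row order, making the result
deterministic. Cells with fewer than *k* eligible donors use the mean over
the eligible ones; cells with none use the protein's own row mean — both
fall-backs warn, because they signal that the missingness filter was too
permissive for that matrix. Observed values are never altered, and every
imputed cell is recorded in a provenance mask that travels with the matrix.

**Quantile normalization.** Each column's order statistics are replaced by
the across-column means of order statistics, making all sample
distributions identical while preserving within-sample ranks. Ties receive
the average of the reference quantiles they span. The transform is
idempotent, and after it the sorted column vectors agree exactly — a
property the tests assert rather than assume. Normalization runs after
imputation because order statistics of an incomplete column are not
comparable across columns with different missingness.

A caveat worth knowing: imputation pulls cells that are missing *because*
of a condition effect toward flat-profile neighbours, and quantile
normalization compresses column extremes. Both effects attenuate true fold
changes slightly (a fraction of a log2 unit at the defaults); this is a
property of the standard pipeline itself, visible in the synthetic recovery
scores, not an artifact of this implementation.

## Differential enrichment

For each protein, a one-way group-means model over all six conditions gives
a residual variance $s^2$ with $d = 12$ degrees of freedom. Sharing
information across proteins, a scaled inverse-chi-square prior
$(d_0, s_0^2)$ is estimated from all $\log s^2$ by method of moments
(digamma/trigamma matching, trigamma inverted by Newton iteration), and
each protein's variance is shrunk to

$$\tilde s^2 = \frac{d_0 s_0^2 + d s^2}{d_0 + d},$$

giving the moderated statistic
$t = \Delta / (\tilde s \sqrt{1/n_1 + 1/n_2})$ on $d + d_0$ degrees of
freedom for the contrast difference $\Delta$ of group means. This is the
standard empirical-Bayes moderated t of microarray/proteomics practice,
implemented here directly; the independent reference implementation in
`limma` is used as a cross-check oracle in the test suite, never as the
computation. Two escape hatches support verification and sensitivity
analysis: `prior_df = 0` recovers the ordinary pooled-variance t exactly,
and `pool = "pair"` restricts variance pooling to the two contrasted
groups.

P-values are two-sided and adjusted by Benjamini–Hochberg *within each
contrast* (each volcano plot is its own multiple-testing family; the
adjustment delegates to `stats::p.adjust` and is oracle-checked against a
brute-force step-up in the tests). A protein is *called* at a time point
when its adjusted P is at most `alpha = 0.05` **and** its
|log2 fold change| is at least `fc_threshold = 1.5`; the union over time
points is the dynamic-protein set, the intersection the
always-responding set. Fold changes are computed on the imputed, normalized
matrix — the same matrix the statistic sees.

## Raft-resident classification

Proteins constitutively at the enzyme's closest vicinity are biotinylated
even at basal peroxidase activity and label very efficiently once
H~2~O~2~ is added. The classifier encodes that reading in two steps on the
normalized matrix:

1. keep proteins with log2 fold change of resting biotinylated cells over
   the no-H~2~O~2~ control of at least `enrich_threshold = 1.5`
   (inclusive);
2. among those, remove proteins whose activation-vs-resting fold change
   reaches `response_threshold = 1.0` in magnitude at any time point —
   those are `stimulation_responsive`; the survivors are `raft_resident`,
   everything else `other`. The three labels partition the protein set.

The response screen uses |FC| by default: a protein leaving the rafts upon
stimulation is as much *not constitutively resident* as one arriving. The
source wording for this step is ambiguous between signed and absolute
responses, so `response_rule = "signed"` is provided for sensitivity
analysis. Classification deliberately runs on the same matrix as the
differential analysis, for internal consistency.

Detection-based set algebra runs on the *raw pre-imputation* table:
a protein is present in a condition when its intensity is nonzero in at
least `min_replicates = 1` replicates (the threshold is a reported
parameter, since a single-replicate detection rule is a genuine analysis
choice). From the presence matrix the presets are: `common_to_all`,
`resting_only` (present at 0 min, absent at all activation time points),
`activated_only` (present at some activation time point, absent from
resting and both controls), and `all_activation_not_controls` (present at
*every* activation time point and in no non-activated condition — the
signature of proteins recruited only upon receptor engagement). Which
conditions "all conditions" should span is genuinely open (four
experimental versus all six including controls); the presets make both
readings computable from the same presence matrix. Reference-list overlap
(e.g. against a curated raft-proteome database export supplied by the
user) reports the overlap count, the fraction of the query covered, and a
hypergeometric upper-tail P, exhaustively verified on small universes in
the tests. Protein groups are never merged by gene name — collisions stay
separate rows.

## Temporal clustering

Input profiles are each significant protein's three per-time-point log2
fold changes. For every candidate k (default 2–30), k-means (Euclidean,
25 random restarts, best by within-cluster sum of squares, deterministic
given the seed; `stats::kmeans` does the iterations) is scored by three
internal-validity indices computed on the same distance: mean silhouette
width, Dunn index, and connectivity with a neighbourhood of
`n_neighbors = 2` (small because the profile space is only
three-dimensional and cluster counts routinely exceed 20, leaving few
same-cluster neighbours). The silhouette-optimal k is selected by default,
but the full validity table is always returned — the indices need not
agree, and on real data the choice deserves eyes. All three indices are
label-permutation invariant and tested against brute-force oracles.

## Flow-cytometry metrics

The detergent resistance index of a membrane marker is

$$DRI = \frac{FL_{det} - FLBg_{det}}{FL_{max} - FLBg}$$

with $FL_{det}$ the mean fluorescence of detergent-treated labeled cells,
$FLBg_{det}$ the matching autofluorescence, $FL_{max}$ the labeled
untreated cells and $FLBg$ the unlabeled untreated background (all in
arbitrary units). A raft-resident marker resists Triton extraction
(DRI near 1); a soluble one is stripped (DRI near 0). The index is
invariant under common rescaling of all four channels and is *not* clipped
to [0, 1] — noisy measurements outside the range are informative and are
flagged instead. Replicate sets are summarized per row plus mean ± sd,
since the aggregation convention across repeated experiments is not fixed
by the assay.

The internalization fraction at time t is the background-corrected
complement of remaining surface signal,
$1 - (MFI(t) - bg)/(MFI(0) - bg)$ — the standard convention for
surface-label decay assays; it is a convention adopted here, not a formula
unique to this analysis.

## The synthetic generator: what it emulates, and what not

`simulate_experiment()` draws per-protein baseline log2 abundance from
N(25, 2) (the scale of Orbitrap label-free intensities), adds planted
class effects — raft residents +2.5 log2 in every biotinylated condition;
responders ±2.0 log2 at one time point; exclusive classes shifted to 4
log2 units *below* the detection midpoint in their excluded conditions —
and replicate noise of sd 0.3 log2 units. Detection is Bernoulli with
probability logistic in the log2 intensity (midpoint 18, slope 1), and an
additional 2% of cells are lost completely at random; exclusive-class
absence therefore *emerges from the dropout model* rather than being
hard-coded zeros. Contaminant and decoy rows (2% each) are appended with
flags, and unique-peptide counts are 1 + Poisson(5). Identical parameters
and seed give byte-identical tables.

The detection midpoint sits 3.5 baseline standard deviations below the
typical abundance, confining intensity-dependent dropout to the
low-abundance tail; the resulting overall missingness (a few percent of
cells) is *milder* than in the real experiment, where a quarter of the
identified proteins failed the 12-of-18 rule. Passing recovery tests on
this generator therefore demonstrates correctness of the machinery and
behaviour under moderate MNAR dropout — not performance under the heavy
censoring of real label-free data. Other simplifications: no batch or
run-order effects, no peptide-level roll-up, no correlation between
abundance and peptide count, and class effects that are exact step
functions in time.

## Numerical choices and problem sizes

* Zero and absent intensities are both "not quantified"; no distinction is
  kept.
* Written tables round floats to 6 significant digits; a write–read–write
  cycle is byte-stable.
* Degenerate zero residual variances are floored at 10^-6^ times the
  smallest positive variance before the prior fit.
* `fit_variance_prior()` returns an infinite prior df when the moment
  estimate of the log-variance spread is non-positive; posterior variances
  then shrink fully to the prior.
* k equal to the number of profiles returns the singleton partition
  directly; automatic selection caps candidates at one below the number of
  distinct profiles.
* Test and acceptance runs use 2000-protein experiments (the scale at
  which the class proportions yield ~100 planted proteins per class),
  500-protein matrices for imputation masking, and toys of at most 8
  points wherever an exhaustive oracle is the comparator.

## Known limitations

Reproducing the original deposited experiment requires its MaxQuant output
(ProteomeXchange accession PXD025111) as input; the package ships no data
and the identification-cascade counts of that study are therefore
reproduction targets for a user with the download, not unit-test
assertions. The moderated-t implementation covers the standard case
(common residual df across proteins, no intensity trend, no robust prior
estimation). Fold-change attenuation by imputation and normalization, noted
above, means recovery of planted effects near the fold-change threshold is
conservative.
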