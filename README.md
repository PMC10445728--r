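# raftquant

Quantitative analysis of APEX2 proximity-biotinylation label-free
proteomics of B-cell lipid rafts across a BCR-activation time course.

When the B cell receptor (BCR) binds antigen it translocates into
cholesterol-rich, detergent-resistant membrane domains — lipid rafts — and
an APEX2 peroxidase targeted there biotinylates every protein within
~20 nm during a one-minute window. Sampling at 0, 5, 10 and 15 min of
anti-IgM stimulation, with no-H₂O₂ and no-biotin-phenol controls in
triplicate, yields an 18-sample label-free MS experiment whose MaxQuant
`proteinGroups` output this package turns into:

* **identified proteins** — decoy/contaminant removal, ≥ 2 unique peptides;
* **differentially enriched proteins per time point** — empirical-Bayes
  moderated t on a complete log2 matrix (missingness filter at ≤ 6 of 18,
  k-nearest-neighbour imputation, quantile normalization), with
  Benjamini–Hochberg FDR per contrast and calls at adjusted P ≤ 0.05 and
  |log2FC| ≥ 1.5;
* **raft-resident proteins** — baseline-enriched (≥ 1.5 log2 over the
  no-H₂O₂ control) and stimulation-stable (< 1.0 log2 response at every
  time point);
* **condition-exclusive sets** — upset-style presence/absence algebra on
  the raw table;
* **temporal clusters** — k-means on per-time-point log2 fold-change
  profiles, k chosen by silhouette/Dunn/connectivity;
* **flow-cytometry metrics** — detergent resistance index
  DRI = (FL_det − FLBg_det)/(FL_max − FLBg) and receptor internalization
  fractions.

The moderated statistic shrinks each protein's residual variance s² (df d,
pooled across the six conditions) toward an empirical prior (d₀, s₀²)
fitted by method of moments on log s²:

    s̃² = (d₀·s₀² + d·s²) / (d₀ + d),   t = Δ / (s̃·√(1/n₁ + 1/n₂)),

with d + d₀ degrees of freedom. A synthetic-data generator with planted
ground truth (raft residents, up/down responders per time point,
condition-exclusive proteins, MNAR + MCAR dropout) makes every stage
testable without downloads, and recovery against the planted truth is the
package's primary validation.

## Worked example

The `analysis/` directory holds the numbered drivers of the full analysis
on a simulated experiment (2000 proteins, 5% planted raft residents, 5%
responders). Running them in order:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_preprocess.R
Rscript analysis/03_differential.R
Rscript analysis/04_classification_sets.R
Rscript analysis/05_clustering.R
Rscript analysis/06_cytometry.R
```

prints, among other things:

```
identified (non-decoy, non-contaminant, >=2 unique peptides): 1989
retained after missingness filter (<=6 of 18 missing): 1949
imputed 921 cells (2.63% of the filtered matrix)

significantly enriched proteins (adj P <= 0.05, |log2FC| >= 1.5):
 ACT_5_vs_ACT_0 ACT_10_vs_ACT_0 ACT_15_vs_ACT_0           union    intersection
             31              32              29              92               0
planted responders recovered in the union: 92/100 (92%)
union calls outside the planted responder set: 0

raft classification:
        other raft_resident stimulation_responsive
         1850            99                      0
sensitivity 0.99, precision 1.00

detection-based sets (raw table, present in >=1 replicate):
  common_to_all                1950
  resting_only                 15
  activated_only               17
```

Reading: of 2080 input rows, 1989 survive identification filtering and
1949 the missingness rule; 92 proteins are called dynamic at some time
point — 92 of the 100 planted responders and no false calls (the
shortfall is fold-change attenuation near the |log2FC| ≥ 1.5 threshold,
discussed in the methods vignette). The raft classifier recovers 99 of
100 planted residents with no false positives, and the detection sets
isolate the planted exclusive classes. Each script writes its tables under
`results/`.

Equivalently, one call runs everything from a single configuration:

```r
library(raftquant)
res <- run_pipeline(raft_config(seed = 1L,
                                simulate = simulation_params(seed = 1L),
                                out_dir = "results/run"))
res$report$counts
```

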