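# lpcmod

Analysis toolkit for studying **liver progenitor cell (LPC) heterogeneity**
in single-cell and spatial transcriptomic data of human liver.

LPCs are rare bipotent cells able to regenerate both hepatocytes and
cholangiocytes. They are hard to study because they make up only a few
percent of the epithelial compartment and share markers with both epithelial
lineages. `lpcmod` implements the quantitative pipeline such a study needs,
end to end, with a synthetic-data generator that plants known ground truth
so every stage can be validated without access to patient data:

- **QC filtering** with the standard four cell-level metrics (detected genes
  strictly in (200, 6000), UMI > 150, mitochondrial fraction < 50%, genes
  detected in ≥ 3 cells), ambient-contamination exclusion (score > 0.4) and
  a 5% doublet-rate removal, all reconciled in an auditable report.
- **Marker-panel annotation**: per-gene, per-cluster z-scores of mean
  log-normalized expression, z<sub>g,c</sub> = (m<sub>g,c</sub> − mean m<sub>g,·</sub>) / sd m<sub>g,·</sub>;
  clusters are labeled by the argmax panel-mean z, and a cluster is flagged
  as LPC iff its progenitor, hepatocyte **and** cholangiocyte panel-mean
  z-scores all reach a threshold τ (the bipotency rule).
- **Gene-set module scores** (binned-control style): genes are binned by
  average expression, each set gene draws expression-matched controls, and
  the per-cell score is the set mean minus the control mean.
- **Cellular modules (CMs)**: cluster-by-individual frequency tables,
  Pearson correlation across individuals, correlation distance d = 1 − r,
  and agglomerative **ward.D** clustering — the Lance–Williams recurrence
  with Ward coefficients applied directly to the *unsquared*
  dissimilarities:
  d(k, i∪j) = [(n<sub>i</sub>+n<sub>k</sub>)d(k,i) + (n<sub>j</sub>+n<sub>k</sub>)d(k,j) − n<sub>k</sub>d(i,j)] / (n<sub>i</sub>+n<sub>j</sub>+n<sub>k</sub>) —
  cut at k modules, with rank-sum (Wilcoxon) marker statistics and BH
  adjustment per contrast.
- **Spatial colocalization**: per-LPC mean Euclidean distance to the k = 4
  nearest cells of every type from cellbin centroid coordinates, type
  ranking by median distance, distance-profile clustering, and pseudo-bulk
  (sum → CPM → log1p) concordance between modalities.

The rank-sum engine is written once and shared: exact enumeration when both
groups have ≤ 10 observations, and an Edgeworth-refined normal approximation
(exact first four null moments of the midrank sum, so tie correction is
built in) otherwise.

## Worked example

```r
library(lpcmod)

cfg <- pipeline_config(
  seed   = 1,
  cohort = cohort_sim_config(n_individuals = 6, cells_per_individual = 200),
  spatial = spatial_sim_config(window = c(0, 600, 0, 600)))
rep <- run_pipeline(cfg)
rep
#> <run_report>
#>   cells simulated: 1200; after QC: 1071
#>   LPC clusters: LPC
#>   LPC proportion: 3.58% +/- 2.13% (n=6)
#>   modules: 4; nearest spatial type to LPC: LPC
#>   wall clock: 2.0 s
```

Reading the report: 1200 cells were simulated for 6 individuals; QC removed
low-quality cells, contaminated cells and putative doublets; the bipotency
rule flagged exactly the planted LPC cluster; the per-individual LPC
proportion of the merged epithelial + LPC compartment averaged 3.58% on
this small demo cohort (the generator plants a 2.95% ± 1.91% distribution);
frequency correlations were cut into 4 cellular modules; and in the
simulated tissue map the type ranked spatially nearest to LPCs is LPC
itself, with cholangiocytes next — exactly the self- and
cholangiocyte-attraction the generator plants (LPCs scatter around the same
cholangiocyte cluster centres, so they sit closest to each other).

Individual stages are plain functions on plain objects — e.g.

```r
sim <- simulate_cohort(cohort_sim_config(n_individuals = 42, seed = 1))
qc  <- qc_filter(sim$expr)
ann <- annotate_cohort(qc$expr, tau = 0.5)
lpc_proportions(ann$cell_type, qc$expr$cell_meta$individual)
#> <lpc_proportions> 2.99% +/- 2.09% (n=42)
```

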