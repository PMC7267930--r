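# dynmod — temporal dynamics of modular brain network organization

dynmod is an R package for network neuroscientists who want to quantify how
stable the modular (community) organization of a functional brain network is
over the course of a resting-state scan, and to relate that stability to a
per-subject phenotype such as general intelligence. It implements the full
chain from parcellated BOLD time series to association statistics:

1. **Windowed connectivity** — tapered sliding windows (default 156 time
   points, step 10) of Fisher-z weighted Pearson correlations; signed,
   unthresholded, zero-diagonal matrices.
2. **Community detection** — two-phase Louvain maximization of
   resolution-parameterized modularity. For a non-negative matrix,

   Q = (1/2m) Σᵢⱼ (wᵢⱼ − γ kᵢkⱼ/2m) δ(cᵢ, cⱼ);

   for signed matrices the default is the asymmetric signed quality
   Q\* = Q⁺ − (v⁻/(v⁺+v⁻)) Q⁻. 100 seeded restarts per matrix, ties to the
   lowest seed; fully deterministic given a seed.
3. **Resolution selection** — each subject's γ is chosen on the grid
   0.1–6.0 (60 levels) by mutual-information agreement between the static
   partition and a canonical 17-network reference labeling.
4. **Temporal dynamics** — the window-wise modularity trace Q(t); the
   stability statistic **SD(Q)** (sample SD, lower = more stable);
   high/low-modularity state detection at mean ± fraction·mean thresholds
   (individual or group convention) with a threshold sensitivity sweep.
5. **Coclassification** — per-pair fraction of windows with a shared module
   assignment, aggregated into 28 within/between-network stability scores
   (7 canonical networks, hemispheres merged).
6. **Statistics** — partial Spearman correlations of every measure with the
   phenotype controlling for age, sex, handedness and mean framewise
   displacement; Bonferroni correction for the 28 network scores
   (α/28 = 0.0018); Mann–Whitney contrasts between subjects with and
   without extreme states.

A seedable synthetic-cohort generator (`generate_cohort()`) plants
time-varying modular structure with a known per-subject stability parameter
and a phenotype linked to it, so the entire pipeline is testable without
access to raw imaging data. See `vignettes/dynamic-modularity.Rmd` for the
model details and design decisions.

## Worked example

```r
library(dynmod)

cfg  <- simulation_config(n_subjects = 20, seed = 1)   # 114 nodes, 884 TPs
pipe <- pipeline_config(simulation = cfg, gamma = 1, n_runs = 20, seed = 1)
res  <- run_pipeline(pipe, "dynmod-demo")
res$report
```

```
association report (n = 20, covariates: age, sex, mean_fd)
    measure        rho      p_value r_squared  n
       sd_q -0.9172932 2.193676e-07 0.8414269 20
     mean_q  0.8586466 1.024241e-05 0.7372740 20
 n_high_ind -0.8781955 3.558724e-06 0.7712273 20
  n_low_ind -0.7518797 4.997826e-04 0.5653231 20
 n_high_grp  0.5684211 1.727633e-02 0.3231025 20
  n_low_grp -0.7699248 3.003962e-04 0.5927842 20
network battery: 0/28 pass Bonferroni (threshold 0.0018)
     states outcome  u          z      p_value method n_with n_without
 n_high_ind    fsiq  1 -3.6847253 2.381519e-05  exact     11         9
 n_high_ind mean_fd 53  0.2659080 8.237557e-01  exact     11         9
  n_low_ind    fsiq  1 -3.6261287 3.175359e-05  exact      8        12
  n_low_ind mean_fd 46 -0.1543033 9.101056e-01  exact      8        12
```

The demo cohort plants a *negative* phenotype–instability relation, and the
pipeline recovers it: SD(Q) correlates at rho = −0.92 with the IQ-scale
phenotype after covariate control (the planted effect in this 20-subject
demo is deliberately strong; handedness was dropped automatically because
it is constant in so small a draw). Subjects with extreme-modularity states
score lower on the phenotype (Mann–Whitney on `fsiq`), while head motion
(`mean_fd`) shows no group difference — the motion contrast guards against
a common confound. Per-subject measures, the 28 network-stability scores,
all correlation tables and a reproducibility manifest are written to the
output directory.

For real data, pass per-subject TSV time series, a node labeling table and
a phenotype CSV to `pipeline_config()` instead of a simulation config, and
use `gamma = "auto"` to select each subject's resolution level.

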