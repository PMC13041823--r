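# tptenet

Transplacental transfer efficiency (TPTE) and the architecture of
placental transcriptional mediation.

## The problem

Per- and polyfluoroalkyl substances (PFAS) are persistent contaminants
that cross the placenta to very different degrees: the TPTE of a
compound — its average cord:maternal blood concentration ratio —
spans from below 0.5 (long-chain compounds such as PFOS) to above 2
(short-chain compounds such as PFBS).  `tptenet` is for researchers
asking whether this natural dose gradient of direct fetal exposure
systematically reorganizes the placental transcriptional pathways that
link exposure to perinatal outcomes (birth weight, gestational age).

The package implements, end to end:

* **NB differential expression** of transcript counts on exposure
  z-scores (edgeR-fitted GLMs, quasi-likelihood Wald tests;
  significant at BH FDR < 0.1 and |log2FC| > 1);
* **transcriptome-wide causal mediation** — for each transcript `m`,
  OLS models `m ~ x + C` and `y ~ x + m + C` with quasi-Bayesian
  draws give the average causal mediation effect
  `ACME = E[a·b]`, the average direct effect `ADE = E[c']`, percentile
  CIs and Monte Carlo p-values (significant at BH FDR < 0.05 with CI
  excluding 0);
* **signed co-expression networks**: adjacency
  `a_ij = ((1 + r_ij)/2)^β`, topological overlap
  `TOM_ij = (Σ_u a_iu a_uj + a_ij)/(min(k_i,k_j) + 1 − a_ij)`,
  clustering swept over 144 parameter combinations, kME = cor(feature,
  eigengene), consensus hubs = union of top-10 |kME| per module per
  iteration;
* **edge-weighted topology**: module hubs by eigenvector centrality,
  Dijkstra distances on `1/|r|` weights, KDE-mode peak distances `D_f`
  and `D_m` for fetal/maternal mediators, compartmentalization
  `|D_f − D_m|`;
* **TPTE scaling**: per-property regressions of compound-level
  summaries on TPTE, and a bootstrapped ANOVA/Tukey comparison of
  |ACME| across DE features, hub mediators, and hub non-mediators;
* a **synthetic-study generator** emulating the statistical structure
  of such a cohort (124 samples, 8 compounds, modular NB counts with
  isoform architecture, planted mediation paths) with recorded ground
  truth.

## Worked example

Generate a synthetic study at desk scale and run the full pipeline
(about five minutes on one CPU):

```r
library(tptenet)

design <- simulation_design(n_transcripts = 1600, n_modules = 8,
                            seed = 3)
config <- analysis_config(n_sims = 2000, seed = 3,
                          grid = network_params_grid(
                            c(3, 4), min_module_size = c(30, 50),
                            deep_split = c(2, 3, 4),
                            merge_cut_height = c(0.15, 0.25)))
res <- run_pipeline(design, config, outdir = "tptenet_run")

sc <- res$scaling
sc[sc$property %in% c("mediator_count", "peak_kme", "centrality",
                      "compartmentalization") &
     sc$source %in% c("fetal", "both"),
   c("property", "source", "outcome", "r", "p", "slope")]
```

```
               property source         outcome        r       p    slope
1  compartmentalization   both    birth_weight  0.90277 0.00213  0.50943
2            centrality  fetal    birth_weight  0.63428 0.09120  0.26105
3        mediator_count  fetal    birth_weight  0.75459 0.03048 13.01689
5              peak_kme  fetal    birth_weight  0.71175 0.04768  0.07196
10 compartmentalization   both gestational_age -0.18296 0.66452 -0.08875
11           centrality  fetal gestational_age  0.00748 0.98598  0.00305
12       mediator_count  fetal gestational_age  0.08191 0.84710  0.46039
14             peak_kme  fetal gestational_age  0.36746 0.37053  0.02613
```

Reading the table: for **birth weight**, the number of significant
fetal-exposure mediators, their co-expression strength (peak |kME|),
their network centrality (negated peak hub distance) and the
maternal-fetal compartmentalization `|D_f − D_m|` all rise with TPTE —
the generator plants exactly this architecture, and the pipeline
recovers it (the centrality contrast is the noisiest of the four in a
single study because it rests on kernel-density modes of hub
distances; the package's validation suite pools two replicate studies,
where all four slopes are decisively significant).  For **gestational
age** the same statistics show no TPTE relationship, matching the null
structure planted for that outcome.  `res$comparison` holds the
bootstrapped Tukey test showing hub mediators carry far larger |ACME|
than differentially expressed features, and `res$truth` carries the
generator's ground truth for any further recovery checks.

Per-stage outputs (DE tables, mediation tables, consensus hubs,
topology units, scaling results, run manifest with checksums) are
written under `outdir`; re-running with the same configuration resumes
from intact stage outputs.  A thin command-line wrapper is included at
`inst/scripts/tptenet.R` (`simulate`, `all`, `validate` subcommands).

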