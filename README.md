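# pepfunnel

Computational triage for designed GLP-1 receptor agonist (GLP-1RA)
peptides. Deep-learning design tools emit candidate pools far larger than
any assay campaign can absorb; `pepfunnel` implements the screening funnel
that narrows such a pool — template-constrained variants of the
Semaglutide backbone, GLP-1(7–37) with Aib8 and Arg34 — down to a short,
diverse list worth expressing, and the bookkeeping used once in-vitro
results return.

The funnel applies three gates in sequence, after deduplication:

* **Stability** — scan for the six NEP-24.11 cleavage sites
  (Asp15-Val16, Ser18-Tyr19, Tyr19-Leu20, Glu27-Phe28, Phe28-Ile29,
  Trp31-Leu32; zero tolerated by default) and profile net charge
  (Henderson–Hasselbalch at pH 7.4), isoelectric point (bisection),
  Kyte–Doolittle hydropathy and mean helix propensity.
* **Efficacy** — score predicted complexes against the native reference:
  TM-score (d0 = 1.24·(L−15)^⅓ − 1.8, iterative Kabsch reweighting),
  Cα-RMSD (Kabsch, SVD with reflection correction), mean pLDDT (B-factor
  convention), interface pAE (mean over inter-chain blocks), and spatial
  aggregation propensity, SAP(r) = Σ_{side-chain atoms j near r}
  (SASA_j / SASA_max) · hydrophobicity_j, with Shrake–Rupley SASA on a
  deterministic golden-spiral point set. Thresholds are derived from the
  reference complex's own scores with a configurable slack.
* **Diversity** — neighbor-joining tree on 1 − alignment-identity
  distances, k-cluster cut, one representative per cluster (highest
  recovery by default), plus a patent-similarity cap against the marketed
  template.

Sequences carry extended residue tokens (`H[Aib]EGT…`); Aib matches Ala
under the recovery/identity policy, so the Aib-containing template scores
1 against itself while bacterially expressed Ala8 constructs remain
comparable. A first-class synthetic-data module generates candidate pools
(with controlled duplicate fractions and cleavage spikes), ideal α-helical
structures and mock pLDDT/pAE files, so the entire funnel is testable
offline.

## Worked example

```r
library(pepfunnel)

spec   <- generator_spec(n = 2000, seed = 7)       # template-constrained pool
cands  <- generate_candidates(spec)
cfg    <- funnel_config(stages = c("dedupe", "stability", "diversity"),
                        target_count = 20)
report <- run_funnel(cands, semaglutide_spec(), config = cfg)
funnel_counts(report)
#>               stage n_in n_out
#> dedupe       dedupe 2000   289
#> stability stability  289   275
#> diversity diversity  275    20
```

The generator's default duplicate fraction (0.8557) mimics the redundancy
of low-temperature sampling in a constrained design space, so 2000 draws
collapse to 289 unique sequences; 14 of those carry a cleavage site by
chance and fail the stability gate; clustering the survivors' NJ tree into
20 clusters and keeping one representative each yields the final list.
Per-candidate scorecards hold the underlying numbers:

```r
subset(report$scorecards, id == report$final_ids[1],
       c(id, recovery, n_cleavage, net_charge, gravy, helix_propensity))
#>       id recovery n_cleavage net_charge    gravy helix_propensity
#> 9 D00009     0.45          0   1.053335 -1.13871        -0.776129
```

The assay-table bookkeeping reproduces the recorded screening arithmetic:

```r
tab <- glp1_assay_table()
count_labels(tab, "pulldown", "Success")   # 31 binders (29 Fail)
apply_expression_filter(tab, 0.7)$excluded
#> "D19" "D35" "D50" "D57" "D59"            # strictly below 0.7; 0.70 is kept
recovery(semaglutide_template(), semaglutide_template())
#> 1
```

A thin CLI wraps the same functions
(`inst/cli/pepfunnel.R screen|stability|table|synth`); exit status 2
signals a validation error.

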