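# acidep — acidic extracellular pH dependency scoring for tumor transcriptomes

Tumor tissue is chronically acidic: extracellular pH (pHe) sits around
6.8 under mild and below 6.5 under severe acidosis, and tumor cells
mount a broad transcriptional response to it. `acidep` implements the
computational pipeline for asking how much a tumor type's *prognosis*
depends on that acidosis response:

1. **Differential expression** of acid-treated vs control cultures
   (e.g. pHe 6.8 and 5.9 vs 7.4, quadruplicate two-color microarrays).
   Per gene g and condition c the fold change is the geometric-mean
   ratio

   FC(g, c) = 2^( mean log2 x(g, c) − mean log2 x(g, control) ),

   with a per-gene two-sided pooled-variance Student's t-test
   (df = n1 + n2 − 2; Welch and Bonferroni variants available).
2. **Thresholded gene sets and Venn partitioning**: genes with
   FC ≥ θ (induced) or FC ≤ 1/θ (reduced), θ ∈ {2, 4}, partitioned
   into condition-specific and shared subsets.
3. **Signature comparison**: 2×2 contingency of acid-up/down sets
   against an external high/low expression signature with an
   uncorrected Pearson chi-squared test (df = 1), plus Spearman
   rank-order concordance with a permutation p-value, and
   mouse-to-human symbol mapping.
4. **Hit scoring**: over the top-100 acid-induced and top-100
   acid-reduced genes, a gene is a *hit* in a tumor type when its
   acid-response direction matches its prognostic annotation
   (induced ↔ unfavorable/shorter survival, reduced ↔
   favorable/longer survival, database-flagged significant). Tallies
   are kept strictly and tolerantly (counting significant *reversals*
   whose effect magnitude is within 20%), tumors are ranked by total
   hits and typed by the dominant role (acid-induced vs acid-reduced
   type), per-gene hit rates are computed across the tumor panel, and
   genes with a hit rate ≥ 50% are followed up for concordance with
   pathological staging.
5. **Synthetic data**: generators for expression matrices with planted
   up/down effects in a known Venn structure, reference signatures
   with controllable enrichment, and prognostic/stage annotations with
   planted per-tumor concordance — so the entire pipeline can be
   benchmarked offline against ground truth.

The expected users are computational biologists evaluating
acidosis-dependency signatures (e.g. for alkalinization-adjuvant
therapy stratification) or benchmarking fold-change set-selection
pipelines.

## Worked example

Simulate a study with the canonical planted Venn structure
(25/85/131 genes up at pHe 6.8 only / both / 5.9 only; 63/118/82
down), an eight-tumor annotation panel with different planted
concordances, and run the full pipeline:

```r
library(acidep)
cfg <- pipeline_config(
  simulate = simulation_config(n_genes = 2000, seed = 42, noise_sd_log2 = 0),
  annotation_sim = annotation_sim_config(
    concordance_q = c(breast = 0.45, colorectal = 0.75, prostate = 0.15,
                      gastric = 0.55, liver = 0.55, lung = 0.75,
                      "head and neck" = 0.70, melanoma = 0.50),
    missing_rate = 0.05, seed = 43),
  stage_sim = list(concordance = 0.4),
  top_n = 100, seed = 42)
bundle <- run_pipeline(cfg)
make_report(bundle, top_genes = 5)
```

```
== acidosis-dependency pipeline report ==

venn up_2      a_only   25 | common   85 | b_only  131
venn down_2    a_only   63 | common  118 | b_only   82
venn up_4      a_only   25 | common   85 | b_only  131
venn down_4    a_only   63 | common  118 | b_only   82

tumor ranking (strict | tolerant hits, dominance):
  colorectal      142 |  146  balanced
  head and neck   139 |  145  reduced_type
  lung            139 |  145  induced_type
  liver           113 |  122  reduced_type
  gastric         110 |  124  induced_type
  melanoma        101 |  118  induced_type
  breast           88 |  103  balanced
  prostate         28 |   52  reduced_type
```

Reading the output: the Venn lines recover the planted partition
exactly (every planted effect is 4-fold, so the 2-fold and 4-fold
selections coincide in this noiseless run). The ranking orders tumor
types by strict hit total out of 200 list genes — the planted
concordance order (colorectal/lung/head-and-neck high, prostate low)
is recovered, and each tumor is typed by whether acid-induced or
acid-reduced genes contribute more hits. The tolerant column adds
significant prognostic reversals with effect magnitude ≤ 0.20.

The published contingency counts of acid-modulated genes against the
GSE8401 melanoma signature classes ship with the package:

```r
published_contingency_tests()
#>          contrast condition high_up high_down low_up low_down   chi2      p
#> 1 Mets vs primary     pH6.8     119        68     14       10 0.2567 0.6124
#> 3  CTC vs primary     pH6.8      71        43    822      334 3.8731 0.0491
#> ...
```

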