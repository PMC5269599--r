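# riboTE

Quantifying translational regulation from paired ribosome-footprint (RF)
and RNA-seq data.

Neural activity, stress and stimulation reshape gene expression not only
by transcription but by changing how heavily existing mRNAs are
translated. Ribosome footprinting measures ribosomal occupancy at
nucleotide resolution; paired with RNA-seq it yields **translation
efficiency** for each transcript region,

    TE = RF RPKM (CDS, masked) / RNA RPKM (exonic, masked),

a proxy for ribosomes per mRNA copy. riboTE is an R package for the full
downstream analysis of such experiments:

* **quantify** — region counting in transcript coordinates with the
  start/stop-codon mask `[s−9,s) ∪ [s+3,s+18) ∪ [t−15,t) ∪ [t+3,t+18)`,
  CPM/RPKM normalisation, the robust-expression filter
  (RPKM ≥ 10 in ≥ 2 samples for both assays), and TE;
* **difftest** — per-transcript log2 fold changes and resampling t-test
  p-values for RNA abundance, ribosomal occupancy and TE between
  conditions with as few as 3 vs 2 replicates, plus classification into
  forwarded / TE-only / homeostatic / synergistic response patterns and
  variance-explained summaries (OLS on fold changes; Gamma-GLM pseudo-R²
  at baseline);
* **metagene** — average footprint-density profiles anchored at start and
  stop codons, with peak enrichment scores;
* **seqfeat** — per-transcript sequence predictors: GC content, region
  lengths, uAUG and upstream-Kozak counts (purine at −3, G at +4), and a
  built-in weighted base-pair-maximisation folding score (GC=3, AU=2,
  GU=1, loop ≥ 3) with a pluggable external-engine hook;
* **model** — univariate scans, BIC-stepwise multivariate selection with
  a centred interaction term, quartile-bin ANOVA and direction
  chi-square tests relating TE change to sequence features;
* **overlap** — one-tailed Fisher enrichment of regulated genes in
  external target sets against the measurable universe, with BH
  correction and length/expression bias diagnostics;
* **synthetic data** — a seeded generator planting transcriptional fold
  changes and sequence-feature-driven TE changes in NB-noised coverage,
  so every stage is validated against known ground truth.

## Worked example

```r
library(riboTE)

cfg <- simulation_config(n_transcripts = 300, seed = 7)
ex  <- simulate_experiment(cfg)             # transcripts + RF/RNA coverage

expr <- quantify_expression(ex$transcripts, rf = ex$rf, rna = ex$rna)
kept <- filter_expressed(expr)              # robust-expression filter
dt   <- differential_table(expr[expr$transcript_id %in% kept, ],
                           n_resamples = 1000, seed = 8)

length(kept)          # 300  measurable transcripts at this depth
sum(dt$sig_te)        # 89   transcripts with significant TE change
table(dt$pattern[dt$sig_te])
#  homeostatic  synergistic_down  synergistic_up  te_only_down  te_only_up
#            5                11               4            43          21
#  unclassified
#            5

fc_variance_explained(dt$log2fc_rna, dt$log2fc_rf)$r_squared
# 0.366  — share of the change in occupancy explained by transcript change
```

The numbers above are what this exact script prints: 300 of 300 synthetic
transcripts pass the expression filter at depth 10⁴, 89 change TE at
unadjusted p < 0.05 (the generator plants feature-driven TE changes in the
treated condition), the pattern table splits them into pure-TE,
homeostatic and synergistic responders, and ~37% of the variance in the
RF fold change is attributable to the RNA fold change.

Sequence features and the TE-change model:

```r
fe   <- feature_table(ex$transcripts)        # GC, lengths, uAUG/Kozak, folding
resp <- dt$log2fc_te[match(kept, dt$transcript_id)]
stepwise_select(fe[match(kept, fe$transcript_id), ], resp)
# model_fit (bic): short_utr3 + n_upstream_kozak + norm_ss_utr5
#   adj R^2 = 0.1855, p = 8.98e-14, n = 300
```

All three planted predictors survive BIC selection even at n = 300, with
adjusted R² ≈ 0.19 against the planted 0.17 (see the methods vignette,
`vignettes/translation-efficiency-methods.Rmd`, for the model, the
calibration of the resampling test, and every default).

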