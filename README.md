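# synshift

Shift-ability screening of perturbation transcriptomes for
chemo-immunotherapy synergy.

## The problem

Only a minority of cancer patients respond to immune checkpoint blockade
such as anti-PD-1 therapy, and combining it with chemo- or targeted
therapy is one of the most practical routes to a higher response rate.
`synshift` implements an in-silico screen for such combinations, built on
the idea that *treatment-induced* expression changes — not baseline
expression — carry the response signal:

1. **Response signatures.** From paired pre-/on-treatment tumor
   transcriptomes, the per-patient induced change of each gene is the log2
   fold change between on- and pre-treatment expression. A two-sided
   Wilcoxon rank-sum test between responders and non-responders splits the
   significant genes (p < 0.05) into a **sensitivity (S) signature**
   (changes higher in responders) and a **resistance (R) signature**
   (changes higher in non-responders).
2. **Shift ability.** Each perturbation experiment (a compound or shRNA
   applied to a cell line, profiled as a level-5-style z-score signature)
   is ranked descending and both signatures are scored with the weighted
   Kolmogorov–Smirnov enrichment statistic (preranked GSEA, weight 1):

   *ΔES = ES_S − ES_R* ∈ [−2, 2]

   A perturbation with ΔES ≥ 0.7 suppresses the R signature while
   inducing the S signature — an **R-to-S shift** toward an
   immunotherapy-sensitive state.
3. **Target prioritization.** Drug targets whose pharmacological
   (compound) and genetic (efficient shRNA knockdown) inhibition both
   produce R-to-S calls in the same cell line are *concordant*; those
   whose expression is significantly negatively correlated (Pearson,
   p < 0.05) with ssGSEA-based immune-activation scores in enough cancer
   types are *prioritized* synergy targets.
4. **Mechanism clusters.** R-to-S compounds are summarized by consensus
   expression indicators (z > 1 → +1, z < −1 → −1, summed over
   experiments), clustered with Ward linkage on 1 − Pearson distance, and
   each cluster's descending-ranked median consensus signature is
   annotated by preranked GSEA against a gene-set collection.

The package also associates signature averages with immune infiltration
and survival (single-covariate Cox proportional hazards, tertile log-rank)
in pan-cancer cohorts, and ships synthetic-data generators that emulate
every input — paired cohorts, perturbation compendia with planted
shifters/knockdowns/mechanisms, and pan-cancer cohorts with immune latent
factors and survival — so the whole pipeline is testable with no external
download. It is aimed at computational biologists working with
immunotherapy cohort data and LINCS/CMap-style perturbation resources.

## Worked example

```r
library(synshift)

# a paired anti-PD-1 cohort with 100 planted S and 100 planted R genes
sim     <- gen_paired_cohort(n_genes = 2000, n_planted = 100, seed = 42)
changes <- compute_induced_changes(sim$cohort)
sig     <- derive_signatures(changes, sim$cohort$response)
print(sig)
#> Anti-PD-1 response signature (alpha = 0.05)
#>   R (resistance) genes: 145
#>   S (sensitivity) genes: 143
#>   tested: 2000 genes; 0 significant gene(s) excluded for tied medians

score <- pca_response_score(changes, sig)
roc_auc(score, sim$cohort$response, positive = "R")
#> [1] 1

# screen a synthetic perturbation compendium with the derived signature
gen  <- gen_perturbation_compendium(n_genes = 2000,
                                    r_sig = sim$truth$planted_r_genes,
                                    s_sig = sim$truth$planted_s_genes,
                                    seed = 42)
kept   <- filter_profiles(gen$compendium, tas_min = 0.4)
#> filter_profiles: kept 549 of 900 experiments at TAS >= 0.4
screen <- shift_screen(kept, sig, threshold = 0.7)
print(screen)
#> Shift-ability screen: 549 experiments, threshold 0.7
#>   R-to-S calls: 385 ( 70.1 % )
#>   shift ability: median 1.43 , range [ -0.556 , 1.54 ]
```

The signature recovers the planted response genes (145 R / 143 S called
at the nominal 5% level, including essentially all 200 planted genes),
the induced-change PCA score separates responders perfectly on this
synthetic cohort, and the screen calls the planted shifting perturbagens
(high TAS experiments are enriched for true shifters, hence the high call
rate after filtering). The full orchestrated run — signatures → screen →
concordance → prioritization → clustering → survival — is one call:

```r
report <- run_pipeline(pipeline_config(out_dir = "synshift_out", seed = 1))
print(report)
```

which writes stamped, byte-reproducible TSVs plus `report.json` with
planted-vs-recovered counts for every stage.

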