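# zdimorph

Sex-biased gene expression analysis for avian Z-chromosome dosage studies.

## What this is for

In birds, males are ZZ and females ZW. Because avian dosage compensation is
incomplete, Z-linked genes that escape compensation are expressed more
highly in males simply through the double Z dose. On a brain expression
microarray this shows up as hundreds of modestly male-biased, Z-linked
probe sets; comparing two related species then reveals which genes escape
compensation in each. `zdimorph` is for researchers analysing that kind of
probe-level two-species microarray experiment. It implements the full
chain:

1. **Preprocess** — quantile normalization across arrays and median-polish
   summarization of probes to one log2 value per EST (probe set) per
   sample, plus replicate-correlation QC.
2. **Filter** — the per-EST standard-deviation rule (remove ESTs whose
   unlogged SD exceeds 30% of their median signal) and, for cross-species
   hybridizations, a CGH probe mask with an at-least-8-retained-probes
   rule; both with exact accounting.
3. **Test** — a from-scratch two-class unpaired Significance Analysis of
   Microarrays (SAM): the moderated statistic

   d_i = (x̄_treatment,i − x̄_control,i) / (s_i + s0),

   with s_i the pooled two-sample standard error and s0 a fudge factor
   chosen by a percentile scan; significance is judged against
   permutation-derived expected order statistics, with the cut parameter
   delta selected to approach a target false discovery rate (default 3%),
   and unlogged fold changes (mean male / mean female) for called ESTs.
4. **Collapse** — redundant significant ESTs to non-redundant genes, with
   ambiguity detection (genes carrying both male- and female-biased ESTs)
   and chromosome classification under the BLAST E ≤ 1e-20 rule.
5. **Enrich** — two-sided Fisher exact tests of Z-versus-autosome
   distribution against the array's annotation background.
6. **Compare** — shared, reversed, and species-specific sex-biased gene
   sets across two species, plus a population-vs-sex confounding check.

A probe-level simulator with known ground truth (`simulate_experiment()`)
emulates the whole study — Z dosage effects, redundant genes, failed
cross-species probes — so every stage is testable without any external
data.

## Worked example

```r
library(zdimorph)

report <- run_pipeline(sim_config(seed = 1), sam_config(seed = 1))
print(report)
#> speciesA: 2000 ESTs analysed, 27 significant (delta 0.50, est. FDR 3.7%), 27 genes (0 ambiguous)
#> speciesB: 1997 ESTs analysed, 25 significant (delta 0.47, est. FDR 4.0%), 25 genes (0 ambiguous)
#> shared same-direction genes: 17; unique to A: 10; unique to B: 8

print(report$species$speciesA$sam)
#> sam_result: 2000 ESTs; 27 significant (delta = 0.50, est. FDR = 3.7%, s0 = 0.06951)
#>   direction: female = 1, male = 26

print(report$species$speciesA$enrichment$male$test)
#> enrichment: 23 Z / 3 autosomal observed (prop Z 0.885, expected 0.058), Fisher p = 5.84e-27
```

Reading this: of 2,000 simulated ESTs, 27 were called sex-biased at an
estimated FDR of 3.7% (the delta-selection step lands as close to the 3%
target as the permutation grid allows); 26 of the 27 are male-biased, and
the male-biased gene set is overwhelmingly Z-linked (88.5% observed vs
5.8% expected if location were random; Fisher p ≈ 6e-27) — the signature
of incomplete dosage compensation. Against the simulator's truth table
this run recovers 96% of planted effects with no direction errors and a
mean recovered fold change of 1.21 for a planted effect of 1.2
(`report$species$speciesA$recovery`).

Individual stages are exported (`quantile_normalize()`,
`median_polish_summarize()`, `filter_ests()`, `sam()`, `collapse_genes()`,
`fisher_enrichment()`, `compare_species()`, …) and all artifacts are plain
TSV/JSON; `inst/scripts/zdimorph.R` is a thin command-line wrapper over
`run_pipeline()`.

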