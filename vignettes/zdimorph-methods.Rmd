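---
title: "Detecting sex-biased expression on the avian Z chromosome: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting sex-biased expression on the avian Z chromosome: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The scientific problem

In birds, males carry two Z chromosomes and females one Z and one W. When
dosage compensation is incomplete — as it is in birds — Z-linked genes tend
to be expressed more highly in the homogametic males simply because of the
double gene dose. On a brain expression microarray this manifests as a large
set of modestly male-biased, Z-linked probe sets, and comparing two related
species asks which genes escape compensation in each.

`zdimorph` implements the full analysis chain for this question on
probe-level microarray data: normalization and probe-set summarization,
noise and cross-species filtering, a permutation test for sex-biased
expression (SAM), collapse of redundant probe sets (ESTs) to genes,
a Fisher exact test of Z enrichment against the array background, and a
two-species concordance comparison. Because the real arrays are not needed
to validate the machinery, the package ships a probe-level simulator with
known ground truth; every stage is tested against it.

# The synthetic study

`sim_config()` defines the study the tests and the acceptance script run.
Its defaults emulate the kind of two-songbird experiment the pipeline
targets, scaled to desk size:

* **Array**: 2,000 ESTs (scaled down from a 23,136-EST array; the full
  scale is available via `n_ests`), 11 probes per EST with a small fraction
  (148/23,136) carrying 8–10 probes; probe intensities are strictly
  positive and analysed on the log2 scale.
* **Annotation**: 4.6% of ESTs Z-linked, 17.8% unannotated, the rest on
  named autosomes; annotated ESTs carry BLAST-like E-values below 1e-20,
  and 10% of annotated ESTs are paired into two-EST genes to exercise the
  redundancy collapse.
* **Samples**: 6 males and 6 females per species; species B samples carry
  balanced population labels so the population-vs-sex confounding check has
  something to chew on.
* **Effects**: a third of Z-linked genes escape compensation and receive a
  constant male−female effect of log2(1.2) (the modest fold-change regime
  reported for brain tissue); 0.2% of autosomal ESTs are sex-biased at
  ±0.6 log2 with either direction allowed, providing the female-biased
  minority. Each true effect is present in both species with probability
  0.5, otherwise in exactly one — mirroring the observation that roughly
  half of sex-biased genes are species-specific.
* **Noise**: log2 baselines N(8, 1.5), per-probe affinities N(0, 0.7),
  residual noise N(0, 0.25).
* **Cross-species dropout**: 3.9% of probes (9,827/254,430 as a fraction)
  are listed in a CGH mask; in species B those probes are simulated as
  depressed, noisier background — they are *not* deleted, so removing them
  is the filter's job, and a test that forgets the mask sees realistic
  contamination.

Effect sizes are deterministic rather than drawn from a distribution: the
reported fold-change ranges in this literature are narrow and give no
usable shape for a per-gene effect distribution, and constant effects make
the recovery checks sharp (the mean recovered fold change of true positives
has a known target, 1.2). What the generator does **not** emulate:
probe-sequence thermodynamics, spatial artifacts, batch effects,
inter-gene expression correlation beyond the shared sex effect, and
heavy-tailed noise. Passing recovery tests therefore show the machinery is
correct and calibrated under the generative model, not that real arrays
behave this well.

# Preprocessing

Quantile normalization (the between-array step of RMA) forces all samples
to share one empirical intensity distribution; ties within a column receive
the mean of the target values they span, which makes the output independent
of sort stability. It is idempotent to numerical precision and preserves
the matrix total.

Summarization fits, per EST, the additive model
`log2(y_ps) = mu + probe_p + sample_s + r_ps` by Tukey median polish
(rows first, tolerance 0.01 on the log2 scale, at most 10 sweep
iterations — the conventional RMA settings) and reports `mu + sample_s`.
Two numerical properties deserve a note:

* **Shift equivariance.** Adding a constant to one sample's log2
  intensities shifts that sample's summaries by the same constant *exactly*
  when the data are exactly additive (the shift is absorbed by the sample
  effect). With residual noise the robust sweeps can settle in a nearby
  alternative fixed point — median polish solutions are not unique — so on
  noisy data the property holds only approximately, at the scale of the
  residual noise. The tests assert both regimes.
* **Degenerate inputs.** An EST whose probes all vanish from the matrix is
  an error; a single surviving probe collapses the model to that probe.

Full RMA background correction (normal+exponential deconvolution) is
omitted: the analysis rests on within-EST between-sex contrasts, which a
global background shift leaves essentially unchanged. Replicate-correlation
QC (`sample_qc()`) flags samples whose mean within-species Pearson
correlation falls below 0.9 — a quantitative stand-in for the visual
"deviating profile" judgement such studies describe; exclusion is opt-in
(`drop_flagged`).

# Filtering

Two rules, applied in this order, with exact accounting
(`n_input − n_removed_sd − n_removed_retention = n_remaining` is asserted
on every run):

1. **SD filter**: an EST is removed when the standard deviation of its
   unlogged signal across arrays exceeds 30% of its median unlogged
   signal. The scale (unlogged normalized) and the per-EST median are
   interpretive choices — the originating description names neither — and
   both are configurable. The inequality is strict: an EST sitting exactly
   at the boundary is kept.
2. **Retention filter**: after removing CGH-masked probes, only ESTs
   retaining at least 8 probes are analysed. The cutoff is an absolute
   count, applied equally to short probe sets: an 8-probe EST that loses a
   single probe is removed.

# The SAM permutation test

The two-class unpaired statistic for EST *i* is

$$d_i = \frac{\bar{x}_{T,i} - \bar{x}_{C,i}}{s_i + s_0}, \qquad
s_i = \sqrt{\left(\tfrac{1}{n_1}+\tfrac{1}{n_2}\right)
\frac{\sum_{C}(x-\bar{x}_C)^2 + \sum_{T}(x-\bar{x}_T)^2}{n_1+n_2-2}}$$

At $s_0 = 0$ this is the pooled-variance t statistic (tested against the
closed form). The fudge factor $s_0$ is chosen by scanning candidates at
the 0–95th percentiles of $s$ and minimizing the coefficient of variation
of window-wise MADs of $d(\alpha)$ across 20 standard-error windows,
making the spread of $d$ independent of expression variability; ties
resolve to the smallest candidate, and a degenerate all-equal $s$ yields
the smallest candidate trivially.

The null distribution permutes sample labels jointly across ESTs
(preserving inter-gene correlation). All $\binom{n}{n_1}$ distinct
assignments are enumerated when there are at most `n_permutations` (500 by
default) of them — so small designs are fully deterministic — otherwise
that many distinct assignments are sampled without replacement under the
configured seed. The expected order statistics $\bar{d}_{(i)}$ are the
means of the per-permutation sorted $d$.

**Delta selection.** For each candidate delta the observed order statistics
are compared with $\bar{d}_{(i)}$, scanning outward from the origin: the
upper cut is the smallest observed $d$ among order statistics with
non-negative expected value lying at least delta above the identity line;
the lower cut mirrors it below. (Scanning from the origin matters: a
compressed lower tail can also sit "above the line", and admitting it
would collapse the cuts.) ESTs outside the cuts are called, and
FDR(delta) = $\pi_0 \times$ median permutation exceedance / calls, with
$\pi_0 = 1$ by default (conservative; an interquartile-band estimator is
available). The chosen delta minimizes |FDR − target| over deltas with at
least one call. When several deltas tie — typically a plateau where the
estimate is exactly zero because the median permutation exceedance has
saturated at 0 — the most inclusive called set is preferred, then the
larger delta: operating points tied in estimated error are distinguished
by power, and collapsing to the single most extreme EST would defeat the
test's purpose.

Directions are assigned from the sex means (male-biased iff the male mean
exceeds the female mean), so they are invariant to which group is labelled
control. Fold changes are computed on unlogged data for called ESTs as
mean male over mean female expression.

Under a global null the selection step is mildly anticonservative — it
prefers operating points whose estimated FDR happens to fall near the
target — so the realized false-call count is checked against the estimate
over 50 simulated null studies in the test suite rather than assumed.

# Gene collapse and enrichment

Significant ESTs are grouped by shared gene id; ESTs without annotation
are their own singleton genes. A gene with both male- and female-biased
member ESTs is *ambiguous* (its majority direction is retained for the
cross-species comparison); ambiguous genes are excluded from the
chromosomal-distribution analysis. Chromosome class applies the E ≤ 1e-20
significance rule: Z, autosomal, or none. A gene whose members disagree in
class draws a warning and takes the majority, with ties going to none.
Gene-level fold change is the arithmetic mean over member ESTs, and the
direction-wise summary averages it again over genes — the aggregation
level such tables print is not stated anywhere we know of, so the simplest
choice is used and documented.

Z enrichment uses the 2×2 table
`[[obs_Z, obs_A], [bg_Z − obs_Z, bg_A − obs_A]]` with the EST-level array
annotation as background (a gene-level background is available but off by
default; the EST-level background is what printed expected proportions in
this literature correspond to). The two-sided p sums hypergeometric
probabilities of tables no more probable than the observed one — the
convention of mainstream statistical software — and is tested to 1e-12
against a full enumeration oracle on every table with total ≤ 25.
Unannotated genes are reported for the histogram but excluded from the
test. Published p-values for such tables are *not* reproduction targets:
the exact 2×2 construction behind them is ambiguous, so the package
documents its own.

# Cross-species comparison

The union of the two species' sex-biased gene sets is partitioned into
shared same-direction, reversed, shared-ambiguous, discordant-ambiguous,
and species-unique sets. Two deliberate edges:

* A gene ambiguous in one species and directional in the other counts as
  shared only when the directional call matches the ambiguous gene's
  majority direction; otherwise it lands in a separate
  discordant-ambiguous bucket, keeping the choice auditable.
* Genes significant in species A whose member ESTs were entirely filtered
  away in species B are reported as *untestable in B*, not as evidence of
  species-specific bias — absence of data is not absence of dimorphism.

The population check reruns SAM on species B grouped by sampling
population instead of sex and intersects the two significant sets; on
simulated data with no population effect the expected overlap is zero.

# Problem sizes and reproducibility

The shipped tests and the acceptance script run the default synthetic
study: 2,000 ESTs × 12 samples per species, 500 permutations, 50 null
replicates for the FDR calibration and 20 seeds for effect recovery —
sizes chosen so the whole suite completes in a few minutes on one core
while leaving the binomial noise on recovery rates small. Every random
stage draws from an explicitly seeded generator (per-species and
per-stage seeds are salted from one global seed), so a run is reproducible
end to end, and `run_pipeline()` writes every intermediate artifact in
plain TSV/JSON so any downstream stage can be rerun from disk.

# Known limitations

* No background correction; arrays with strong optical background would
  need the RMA convolution step.
* The FDR is a set-level estimate (as in the original SAM); per-gene
  q-values are not computed.
* Exact numerical agreement with the historical Excel SAM plugin is not
  claimed: its s0 and pi0 settings are undocumented, so published
  operating points (delta, FDR pairs) are qualitative references only.
* The simulator's species share baselines and probe affinities; true
  cross-species probe-affinity divergence is represented only through the
  CGH mask.
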