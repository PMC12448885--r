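---
title: "Scoring site-saturation yeast two-hybrid screens: model and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring site-saturation yeast two-hybrid screens: model and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(satscreen)
library(dplyr)
```

# The experiment this package models

A site-saturation mutagenesis library mutates every residue of a protein
domain to the 19 alternative amino acids. Fused to a yeast two-hybrid (Y2H)
DNA-binding domain and co-expressed with an activation-domain-fused partner
protein, each variant either reconstitutes the transcription factor — and
grows on selective medium — or does not. Sequencing the variant pool before
and after selection turns colony growth into a per-variant, per-partner
binding readout.

The default design mirrors a screen of the tandem BRCT repeats of BRCA1
(214 residues, numbered 1646–1859 in full-protein coordinates) against two
partner proteins, giving 19 × 214 = 4,066 missense variants. Three design
elements make the sequencing readout interpretable:

* **Overlapping amplicon fragments.** A 642-nt domain does not fit in one
  250-nt read, so the domain is amplified and sequenced as three
  overlapping windows (74 residues, 222 nt each; adjacent windows share 4
  residues). Each fragment is a separate library, so score scales must be
  reconciled afterwards (see *Cross-fragment normalization*).
* **A synonymously marked wild type.** A fragment-local wild-type read is
  ambiguous: it may be true WT, or a variant whose mutation lies in another
  fragment. A spiked-in WT construct carrying a synonymous codon change
  every 15 residues is the only *trusted* WT observation; plain-WT reads
  are tabulated as `apparent_wt` and excluded from scoring.
* **A premature-stop control.** A guaranteed non-binder that must deplete
  completely, anchoring the bottom of the scale.

# The scoring model

For variant $v$ in replicate $r$, with selective/non-selective counts
$c^{sel}_v, c^{non}_v$ and marked-WT counts $w^{sel}, w^{non}$ from the
same samples, the per-replicate depletion score is the WT-referenced
log-ratio with pseudocount $p = 0.5$:

$$ s_{v,r} = \ln\frac{c^{sel}_v + p}{w^{sel} + p} -
             \ln\frac{c^{non}_v + p}{w^{non} + p}, \qquad
   \mathrm{se}_{v,r} = \sqrt{\textstyle\sum_{x} \frac{1}{x + p}} $$

with the sum over the four counts. Referencing to the marked WT cancels
library-size normalization; the marked WT itself scores exactly 0 in every
replicate. Under the generative model used by the simulator (survival
proportional to a latent binding fitness $b_v \in [0,1]$), the expected
score is $\ln b_v$, which is what makes ground-truth recovery testable.

Replicates are combined by random-effects meta-analysis: the
between-replicate variance $\sigma^2_b$ is the DerSimonian–Laird
method-of-moments estimate (clamped at 0), weights are
$1/(\mathrm{se}_{v,r}^2 + \sigma^2_b)$, and the combined score is the
weighted mean. This mirrors how the established enrichment-scoring tools
treat replicate heterogeneity; an unweighted-mean mode is provided for
ablation. The implementation is cross-checked against
`metafor::rma(method = "DL")` in the test suite.

## Cross-fragment normalization

Variants at the 4 shared residues of each junction are scored in both
fragments; the per-junction offset is the median of their left-minus-right
score differences, restricted to variants detected under selection (the
pseudocount-dominated scores of dropouts would bias the estimate). Fragment
1 anchors the scale, offsets accumulate left-to-right, and overlap variants
receive the mean of their two aligned scores. The median is the default
estimator because a junction has only 57–76 variants and a few dropouts are
expected; a mean mode exists. Junctions with fewer than 5 usable variants
fall back to offset 0 with a warning rather than propagating a noise-only
estimate.

A practical note on precision: with measurement noise of standard
deviation $\sigma$ per fragment score, the junction offset is estimated
with standard error $\approx 1.25\,\sigma\sqrt{2}/\sqrt{n}$ for the median
over $n$ overlap variants. At $n = 76$ the offset is recovered to roughly
$\pm 0.1$ at typical noise levels — adequate for aligning scales, but not a
precision instrument; designs needing tighter alignment should widen the
overlaps.

## Dropout curation (the −5 floor)

A log-ratio cannot be computed for a variant absent from every selective
sample; it is beyond the dynamic range, not missing at random. The curation
rule distinguishes two cases *after* normalization (so the constant lives
on the final reported scale):

* selective count 0 in **all** replicates and non-selective count ≥ 10 in
  at least one replicate → status `floored`, score set to the floor
  constant (default −5, matching the convention of reporting
  completely-depleted variants at a fixed value below the observable
  range);
* non-selective count < 10 in all replicates as well → status `missing`
  (library dropout; no claim about binding is made).

The input-count gate (default 10) prevents a variant that was never
adequately represented from being mistaken for a non-binder.

# The synthetic screen

`draw_effects()` and `simulate_counts()` generate screens with known
truth. The generator's defaults are the study conditions:

* **Residue classes.** Eight *critical* residues (1655, 1656, 1699, 1701,
  1702, 1704, 1775, 1839 — the phospho-binding-pocket core) draw
  $b \sim U(0, 0.02)$; their immediate neighbours are *intermediate*,
  $b \sim U(0.05, 0.6)$; all other residues are *neutral*,
  $b \sim U(0.6, 1)$. Continuous within-class draws avoid degenerate tied
  ranks and let rank-recovery be measured across the full scale.
* **Separation-of-function injections.** Four validated
  partner-specific losses are injected as exact overrides by default:
  1699C (loses bait A only), 1739F, 1741K, 1749R (lose bait B only), with
  $b = 0$ for the lost partner and $b = 1$ for the retained one.
* **Abundances and sampling.** Input abundances are log-normal
  ($\sigma = 0.3$), shared across conditions and fragments within a
  replicate; spike-ins sit at the median library abundance (the real
  spike-in proportions are not published; the median keeps them typical).
  Each of the 3 replicates × 2 conditions × 3 fragments samples is a
  multinomial draw over the fragment's member variants plus spike-ins,
  with selective probabilities $\propto a_v b_v^g$. Selection is modeled
  as a single survival round ($g = 1$): plate selection is a viability
  readout, and proportional survival keeps $\ln b_v$ recoverable as the
  expected score. A `generations` option exposes $b^g$ for multi-round
  regimes.
* **Depth.** The default 2 × 10^5 reads per sample keeps a full two-bait
  screen under a few seconds; recovery benchmarks use 10^6 reads per
  sample, at which combined-score noise is ≈ 0.04 and the Spearman
  correlation between $\ln b$ and the combined score exceeds 0.98.

What the generator deliberately does **not** emulate: PCR jackpotting and
chimeras, index hopping, position-dependent sequencing error, growth-rate
(rather than survival) selection, and plasmid copy-number effects. Passing
tests therefore demonstrate correctness of the inference given the
sampling model, not robustness to every artefact of a real screen; the
discard accounting in the variant caller is the main line of defence the
package offers against such artefacts.

The bundled default domain sequence is a synthetic surrogate: it has the
real coordinates, length, and the documented wild-type identities at the
residues named above, but arbitrary composition elsewhere. Every
positional constant (4,066 variants, 3 fragments, marker layout) is
independent of the letters; real analyses should supply the genuine
sequence via `domain_spec()`.

# Variant calling choices

Reads are assigned to fragments by best forward-anchor match (exact by
default, configurable up to 2 mismatches), length-gated (fixed-length
amplicons; no alignment, frame anchored at the amplicon start), then
compared codon-by-codon to the wild-type window:

* `marked_wt` requires **all** of the fragment's marker codons (each
  window carries 4–5). Requiring the full set rather than ≥ 1 makes a
  sequencing error far more likely to demote a true marked-WT read to
  `ambiguous` (discarded) than to promote anything into the WT reference,
  protecting the denominator of every score.
* `missense` requires exactly one amino-acid change and tolerates at most
  `max_err_nt = 1` additional mismatch, which must be synonymous. A
  non-synonymous sequencing error therefore discards the read
  (`multi_aa_change`) instead of miscalling a double mutant; at a per-base
  error rate of 0.002 this costs roughly a quarter of the reads — the
  price of codon-exact calling without consensus correction.
* The stop control is recognized by its designed stop codons exactly;
  tolerant whole-amplicon matching is deliberately avoided because a
  missense codon one nucleotide away from TAA would otherwise be absorbed
  into the control. The package places a TAA at the second residue of
  every fragment window so the control is visible per fragment (a stop
  placed upstream of the amplified region — as in the physical construct —
  would be invisible to sequencing).

# Downstream analyses

* **Heatmap matrices** (`heatmap_matrix()`): positions × 20 amino acids in
  fixed alphabetical order, with `wt`/`floored`/`missing` masks, floored
  cells carrying −5.
* **Residue aggregation** (`residue_aggregate()`): per-residue sum of
  substitution scores below τ = 0 (any negative score counts; the
  threshold is exposed since reasonable analyses might restrict to, say,
  < −1). Exported in the per-residue attribute ("defattr") text convention
  for painting onto structures.
* **Separation-of-function calls** (`classify_sof()`): loss when
  s ≤ −2, retention when s ≥ −1. The loss threshold sits between the
  floored/near-floored cloud and partial binders on the score scale the
  floor defines; the band between the two thresholds is reported
  `indeterminate` rather than forced into a class.
* **Concordance** (`external_concordance()`): the combined statistic is
  min(s_A, s_B) — loss of either interaction is the biologically relevant
  event. Categorical annotations get a rank-sum AUC (probability that a
  positive-group variant scores below a negative-group one); numeric
  annotations get Spearman correlations. Variants of uncertain
  significance with combined score at or below the loss threshold are
  flagged, not reclassified.

# Numerical and reproducibility notes

* All randomness flows from one root seed through named child streams
  (stage, bait, replicate, condition, fragment), so toggling one stage
  never shifts another's draws; identical configuration and seed give
  byte-identical TSV outputs.
* Ties in the overlap-offset median and in AUC ranks are handled by
  `stats::median` and midranks respectively; no tie-breaking randomness
  exists anywhere in scoring.
* Degenerate inputs are rejected loudly: empty replicate sets, all-zero
  effect maps, counts tables without a marked-WT row, out-of-range
  injections, infeasible fragmentations (with the minimum feasible
  fragment count in the message).
* Test problem sizes: unit tests run on a 40-residue, 2-fragment design;
  recovery benchmarks use the full 214-residue design at 10^6 reads per
  sample (single bait) and 20 seeded replicate screens at the default
  depth for the stop-control and separation-of-function suites.

# Known limitations

* No paired-end merging, UMI handling, indel-tolerant alignment, or
  chimera detection; reads must span the amplicon.
* The floor constant compresses everything below the detection limit to
  one value; analyses treating scores as interval-scaled below −4 will
  overinterpret.
* Random-effects weights assume approximately normal per-replicate score
  errors; at very low counts (< ~5) the log-ratio error is skewed and the
  combined standard error is optimistic.
* Junction offsets are single constants per junction; a depth- or
  position-dependent scale difference between fragments would not be
  corrected.
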