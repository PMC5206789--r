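---
title: "Methods: surfaceome cataloging, S-score prioritization and survival signatures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: surfaceome cataloging, S-score prioritization and survival signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(surfscore)
```

This vignette documents the models and procedures the package implements,
the assumptions behind them, the tunable parameters and their defaults, what
the synthetic-data generators do and do not emulate, and the design choices
made where the design was genuinely open. It states no empirical result that
the test suite does not itself compute.

## 1. The surfaceome membership model

The catalog answers one question per gene: does at least one of its protein
isoforms plausibly reach the cell surface? Evidence is purely computational:
predicted transmembrane (TM) helices (residue intervals, 1-based inclusive —
the TMHMM coordinate convention), predicted signal peptides, and GO
cellular-component annotation. The rules, in fixed order per isoform:

* **R1** — no TM segment: the isoform cannot be a surface protein (`no_tm`).
* **R2** — exactly one TM segment ending within the first `tm_boundary`
  residues (default **50**): a lone N-terminal hydrophobic stretch is most
  likely a signal peptide, so the protein is classified `secreted`.
* **R3** — signal-peptide positive *and* exactly one TM segment *and* that
  segment contained in the predicted signal peptide (segment end ≤ cleavage
  position): `secreted`.
* Otherwise the isoform is a surface **candidate**.

At gene level, a gene with ≥ 1 candidate isoform is excluded only when its
compartment annotation is nonempty **and entirely contained** in the
exclusion vocabulary (lysosome, endoplasmic reticulum, mitochondria,
cytoskeleton, endosome, liposome, nucleolus, nucleus, ribosome); it is then
`internal_compartment`, otherwise `surfaceome`. Genes without candidate
isoforms take the most permissive isoform verdict (`secreted` > `no_tm`).

Design choices that were genuinely open, and how they were settled:

* **R2 geometry.** "One TM domain in the first 50 residues" is
  operationalized as *segment end ≤ 50*: the strictest reading that cannot
  misclassify a genuine TM helix straddling the boundary. `catalog_config()`
  allows `boundary_anchor = "start"` instead.
* **R3 combination logic.** A signal-peptide call alone cannot veto a
  multi-TM protein; the call only explains away the *sole* TM segment when
  that segment lies inside the predicted signal peptide. This keeps R3 a
  refinement of R2 rather than an independent filter.
* **Unannotated genes.** A gene with no compartment annotation is *not*
  excluded: exclusion demands positive evidence of exclusively internal
  localization. The exclusivity predicate is therefore
  `compartments ≠ ∅ ∧ compartments ⊆ vocabulary`, and the test suite checks
  it against brute-force enumeration over all 2^10 subsets of a toy
  vocabulary.
* **Isoform aggregation.** Any-isoform semantics: one candidate isoform
  makes the gene a candidate. This is the inclusive reading of a
  sequence-level filter whose results are reported per gene.
* **"liposome".** The label is anomalous as a cellular compartment (likely a
  transcription slip for another organelle in the source material of this
  analysis tradition) but is kept verbatim in the default vocabulary, which
  is fully configurable.

## 2. The integrative S-score

For gene *g* and sample *i*, evidence
$e(g,i) = \mathrm{sign}(\#\text{onc} - \#\text{sup}) \in \{-1, 0, +1\}$,
where oncogene-like signals are high-level amplification (GISTIC call +2)
and expression z > 2, and suppressor-like signals are deep deletion (−2),
expression z < −2, and ≥ 1 deleterious mutation (nonsense, frameshift,
splice-site). Conflicting evidence cancels. Then

$$S(g) = 100 \cdot \frac{1}{N}\sum_{i=1}^{N} e(g,i) \in [-100, 100],$$

a percent-like net alteration frequency whose sign encodes the role. The
scale factor and the sign rule are this package's instantiation of the
S-score contract (sign = role, magnitude = cohort alteration frequency); the
original score's exact multi-omics weighting is not published in a form
reproducible here, so all signal definitions sit in one `score_config()`
block where an alternative weighting can be swapped in.

S-scores are standardized per tumor type over all scored genes
(`z = (S - \bar S)/\mathrm{sd}(S)`, sample sd). Oncogene/suppressor calls
use **z ≥ 3 / z ≤ −3 inclusive** at the main threshold and **z > 2 / z < −2
strict** in relaxed mode — each convention matching the printed form of the
corresponding analysis step; both are arguments. The scored population is
the surfaceome set (not genome-wide), matching the analysis the package
reproduces; standardizing over a different universe changes z and is the
caller's choice via the `genes` argument. Missense mutations are neutral by
default (`missense_role = "oncogenic"` flips them), since only
nonsense/frameshift/splice-site are declared deleterious.

One ambiguity is flagged rather than resolved: the survival-gene selection
step of the source analysis is described once as an S-score threshold and
twice as a z-score threshold. The pipeline thresholds on **z** (consistent
with the main classification); the relaxed strict form |z| > 2 is the
default for survival screening.

## 3. Alteration model and survival statistics

A sample is **altered** for a gene iff
(expr z > 2) ∨ (expr z < −2) ∨ (CNA = +2) ∨ (CNA = −2) ∨ (deleterious
mutation). Shallow copy-number events (±1) never count under the default
`alteration_config()` — the cBioPortal-style convention — but the calls are
configurable. Signatures use OR semantics: a sample carries the signature
alteration when at least one member gene is altered. Missing omics layers
contribute no events.

**Kaplan–Meier.** Product-limit estimator evaluated at the distinct event
times; censored subjects at an event time remain at risk for that time
(events-before-censoring tie rule). With no censoring the curve equals
1 − ECDF of the event times, which the tests verify on 1,000 random
instances.

**Log-rank.** $O_1$, $E_1 = \sum_j n_{1j} d_j / n_j$,
$V = \sum_j d_j (n_{1j}/n_j)(n_{2j}/n_j)(n_j - d_j)/(n_j - 1)$ (strata with
$n_j = 1$ skipped), $\chi^2 = (O_1 - E_1)^2 / V$, p from the upper tail of
$\chi^2_1$, no continuity correction. Zero total events yields statistic 0
and p = 1 with a warning. Numerical notes: the statistic is label-swap
invariant by construction; the test suite checks the χ² value against an
independently coded brute-force summation **over every label assignment of
every small instance** (exhaustive enumeration, n ≤ 8) and against
`survival::survdiff`. The asymptotic χ² p-value and the *exact permutation*
p-value are different quantities at such small n (the permutation
distribution is discrete with steps of 1/C(n, n₁)); the suite therefore
asserts exact agreement of the statistic, not of the two p-values, and a
separate calibration test checks that null p-values are uniform (2,000
simulations, KS test at α = 0.01, fixed seed battery documented in the test
file).

**Screen and combination search.** Per-gene altered-vs-unaltered log-rank;
selection on raw p < α (default 0.05); genes with identical altered-sample
sets are redundant (identical tests) and collapsed to the lexicographically
first symbol — a Jaccard > 0.95 alternative is available; up to `top_k`
(default 20) genes are kept, ranked by ascending p with lexicographic tie
break. No multiple-testing correction is applied to the selection (the
analysis this reproduces reports raw log-rank p); BH-adjusted values are
emitted alongside for transparency. The k-gene search evaluates **every**
k-subset (C(20, 3) = 1,140 at the defaults); subsets splitting the cohort
degenerately (all or no samples altered) get p = NA and rank last; ranking
is deterministic.

## 4. Clustering and enrichment

The genes × tumor-types S-score matrix is clustered with agglomerative
hierarchical clustering, Euclidean distance, Ward linkage (`ward.D2`, i.e.
proper Ward on squared Euclidean distances), cut at `n_clusters = 3` —
the standard heatmap default, since the grouping method behind the original
three-cluster figure is unstated; linkage and distance are arguments.
Missing scores are imputed as 0 (no evidence) with a message.

Enrichment per cluster is the hypergeometric upper tail
$P[X \ge k]$, $X \sim \mathrm{Hyper}(N, K, n)$, computed with
`stats::phyper` and verified in the tests against exhaustive subset
enumeration for every universe size N ≤ 12. The BH step-up adjustment is
implemented directly (cummin of $m\,p_{(i)}/i$) and checked against the
closed form and `stats::p.adjust`. Because the displayed quantity in the
analysis tradition is the adjusted p while the stated cutoff ("p < 0.01")
does not say raw or adjusted, filtering is on **BH-adjusted p < 0.01**. The
universe is the set of catalog genes with ≥ 1 annotation in the supplied
term map.

## 5. What the synthetic generators emulate — and what they do not

`gen_annotation_bundle()` emits genes in five strata with deterministic
largest-remainder counts (defaults 20% no-TM, 20% single-early-TM secreted,
10% signal-peptide-covered single TM, 40% multi-TM surface, 10% multi-TM but
exclusively internal), 20% of genes with a second same-stratum isoform, and
random amino-acid sequences consistent with the declared lengths. Every
stratum triggers exactly one rule, so the catalog must recover 100% of the
labels — the recovery test validates rule wiring, not biological accuracy.

`gen_cohort()` (defaults: 2,000 genes × 500 samples, background channel rate
1%, 10 + 10 planted genes at 15% frequency) plants suppressor-like events by
choosing uniformly per event among deletion / expression-down / deleterious
mutation, and oncogene-like events among amplification / expression-up.
Expression is N(0, 1) background with expression-channel cells pushed to
±(2.5 + |N(0, 0.5)|); the natural N(0,1) tail beyond |z| = 2 (≈ 4.6%) is
deliberately left in, so null genes carry realistic spurious evidence.
Shallow CNA (±1) background (~6% of cells) is present and must never
trigger alteration. Channels are independent (no mutual exclusivity),
matching the OR alteration semantics. Not emulated: mutation signatures,
CNA segment geometry, gene–gene expression correlation, tumor purity,
subtype structure — so a green recovery test establishes the statistics are
wired correctly at realistic effect sizes, not that the pipeline is robust
to every real-data pathology.

`gen_survival()` draws exponential event times (baseline hazard 1/1000 per
day, i.e. median survival ≈ 693 days, a breast-cancer-like scale) with a
proportional hazard `hazard_ratio` (default 3) on signature-altered samples,
and independent exponential censoring whose rate is solved numerically
(`uniroot`) so the expected censored fraction equals `censoring_rate`
(default 0.3). Exponential proportional hazards is the minimal model with a
log-rank-detectable effect; nothing stronger is warranted because no
survival model is fit anywhere in the pipeline.

The full-pipeline preset (`simulate_pipeline_inputs()`: 300 bundle genes →
~120 surfaceome genes, 2 tumor types × 200 samples, a 3-gene suppressor
signature planted at 15% frequency) uses slightly fewer planted
non-signature genes than the cohort default so that the signature genes
clear the relaxed |z| > 2 gate with margin; this is a property of the stated
synthetic world, chosen once, not tuned against test outcomes.

## 6. Numerical and formatting choices

* All doubles are written with 17 significant digits, so every table
  round-trips to an identical in-memory value; reruns of the pipeline are
  byte-identical (no timestamps anywhere in outputs).
* Residue coordinates 1-based inclusive throughout; gene symbols are
  case-sensitive join keys.
* The sample set of a survival analysis is the intersection of the omics
  and clinical tables; drops are reported, never silent.
* Degenerate inputs fail loudly: zero-variance standardization, empty
  groups, CNA values outside {−2..2}, negative survival times are all hard
  errors; the one documented soft fallback is unknown MAF variant classes →
  `other` with a warning.

## 7. Known limitations

* The catalog can only be as good as the upstream TM/signal-peptide
  predictions it consumes; it does not re-predict topology, handle
  GPI-anchored proteins (no TM helix), or use evidence codes on GO
  annotations.
* The S-score instantiation is a faithful implementation of the published
  contract, not of the unpublished original weighting; absolute S values
  are therefore not comparable to the original study's printed scores,
  which additionally depend on specific TCGA/RefSeq releases.
* The log-rank p is asymptotic; for very small strata an exact permutation
  test would be preferable (the package's oracle code shows how, but the
  pipeline intentionally reports the standard χ² p).
* Enrichment ignores the GO graph (no true-path propagation); terms are
  treated as flat sets.
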