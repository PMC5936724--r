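---
title: "Methods: reference-free proteome normalization and transcript-protein integration"
author: "stressomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: reference-free proteome normalization and transcript-protein integration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stressomics)
```

# The analysis problem

Symbiotic cnidarians respond to heat stress on several molecular levels at
once. A joint transcriptome (RNA-seq, summarized as transcripts per
million, TPM) and proteome (isobarically labelled LC-MS/MS, summarized as
peptide spectral intensities) experiment across several host strains and
two temperatures raises three recurring analysis tasks:

1. turning multiplexed, multi-run peptide intensities into **relative
   protein expression** comparable across runs *without a reference
   channel*;
2. calling **differential expression** of transcripts and proteins within
   and between strains, and asking whether the two molecular levels move
   together — in absolute abundance and in their temperature-driven fold
   changes; and
3. supporting analyses: GO term over-representation against an expressed
   background, and normalization of reactive oxygen species (ROS) assays.

stressomics implements this chain as composable functions, and pairs it
with a synthetic-data generator that reproduces the statistical structure
the pipeline assumes, so every estimator can be validated against known
ground truth.

# Reference-free proteome normalization

Let $y_{pgc}$ be the log2 spectral intensity of peptide $p$ (of gene $g$)
in channel $c$ of run $r(c)$. Two median-based corrections are applied in
sequence:

**Loading correction** (`log2LoadingCorrect`). Each channel receives a
different amount of input material, shifting *all* its intensities. The
median log2 intensity of the channel over all its peptides is subtracted,
so each channel has median 0 afterwards. The median (rather than the mean)
makes the correction insensitive to the minority of genuinely regulated
peptides.

**Per-gene median polish** (`medianPolishGenes`). Absolute intensities of
the same protein are not comparable across runs (different fractionation,
different co-isolation). For each gene, its values within a run are
summarized by their median; the median of these run summaries across runs
is then subtracted from all the gene's values. Afterwards each gene's
cross-run median of run summaries is 0, so only *relative* expression
within a gene remains — exactly what the downstream contrasts use. One
pass per axis is performed, not an iterated Tukey polish: each subtraction
is an idempotent median-centring, and the tests verify idempotence
directly.

Together these define the reference-free contract: adding any constant to
one channel, or to one gene across all runs, leaves every downstream group
difference unchanged. Both invariances are tested, the channel one
end-to-end through the whole pipeline.

Peptides that map ambiguously to several gene models are *retained*
through normalization (polished as their own multi-gene group, in the
spirit of protein groups) and excluded at gene-level summarization and
beyond; `dropAmbiguousPeptides` and `chooseRepresentative` implement the
two downstream policies (removal for correlation analyses; single
most-abundant representative for enrichment, to avoid over-representing
functional categories shared by all candidates of one peptide).

**Detection filter** (`filterDetection`). Within each strain-temperature
group a peptide is kept only if detected in at least 2 technical replicate
channels and at least 1 biological replicate. By default the technical
count pools channels across biological replicates (so 2 channels in one
biological replicate, or one channel in each of two, both qualify); a
stricter reading — two channels within a *single* biological replicate —
is available via `strict = TRUE`. The choice is exposed because the rule's
natural-language form admits both readings.

**Summaries** (`summarizeRelExpr`). Relative expression per gene and
strain-temperature group is the mean of all surviving peptide-channel
values; its standard error uses the sample (n−1) standard deviation over
those values. This SE is deliberately computed over peptide-channel values
rather than biological-replicate means: it is conservative for
between-temperature differences (peptide efficiencies cancel between
groups but still widen the SE), which the effect-recovery checks make
visible — empirical coverage of the true simulated effect at ±2 SE is
well above 95%.

# Differential expression

**Transcripts** (`transcriptDe`). A Welch t-test on `log2(TPM + 1)`,
stress versus control within a strain, Benjamini–Hochberg corrected over
the genes expressed in that strain, significant at q < 0.05. This is a
deliberate proxy for bootstrap-aware transcript-level engines: abundance
uncertainty from the quantifier is not modelled here (a documented
divergence; no count-level or dispersion-shrinkage machinery is
implemented). The +1 pseudocount keeps zero TPMs finite; at the simulated
abundance scale it perturbs high-abundance genes negligibly and compresses
only the low tail.

**Proteins.** The primary caller (`proteinFcDe`) is a permissive rule:
|log2 fold change| ≥ log2(1.2), boundary inclusive, between mean relative
expression at stress and control. It attaches no p-value — it is a
screening rule, reported alongside two model-based analyses rather than
intersected with them: per-gene Welch t-tests on the polished channel
values (`proteinTtest`, BH over the filtered protein universe), and a
per-gene Gaussian two-factor linear model
`value ~ strain + temperature + strain:temperature` (`proteinGlm`) with
partial F-tests per term (type II: main effects against the additive
model, the interaction against the full model) and BH per term across
genes. A Gaussian identity-link model is appropriate because the polished
log2 values are continuous and approximately normal; F-tests were chosen
over Wald tests because they are exact under the model at these small
replicate counts, which the calibration tests exploit.

All multiple-testing correction goes through `bhAdjust`, a thin wrapper
over `stats::p.adjust(method = "BH")` whose one behavioural commitment is
that missing p-values are excluded from the number of tests; the test
suite checks it against an independent brute-force step-up implementation.

**Between-strain contrasts** (`pairwiseStrainContrasts` and the
per-pair functions) reuse the same machinery with groups being two strains
at a fixed temperature, and `extractPanel` lays the fold changes of a gene
panel (e.g. oxidative-stress-related genes) out as one wide
genes-by-contrasts table.

## Statistical calibration and the Welch safeguard

The Welch (unequal-variance) form was chosen wherever the method statement
says only "t-test": it is never anticonservative when variances differ.
The flip side, documented here because the tests verify it: at four
replicates per group with equal variances the Satterthwaite degrees of
freedom underestimate the true df, and the test's empirical size is
around 0.04 rather than 0.05. The calibration tests therefore check
nominal size (within the 95% binomial interval of 0.05) at ten replicates
per group, where the approximation is accurate, and check one-sided
non-anticonservatism at the study's four replicates. The two-factor
model's F-tests are exact and are checked at study sizes directly.

Calibration is assessed at each caller's own interface on null
replicate-level data rather than through the full generator: library-size
rescaling (TPM) and channel-median centring both introduce small
common-mode shifts shared by all genes of a sample, which violate the
independence assumption behind a binomial check of the rejection rate
while saying nothing about the tests themselves. Propagation through the
full pipeline is covered separately by the normalization-contract,
effect-recovery and headline-pattern checks.

# Transcript-protein integration

Protein abundance comparable to TPM is built by `proteinScpm`: raw
intensities of single-gene peptides are summed per gene within each
channel, each channel is rescaled to spectral counts per million (SCPM,
column sum $10^6$ — `computeScpm`), and channels of a biological
replicate are averaged. Because a channel's loading offset multiplies all
its intensities equally, the per-channel rescaling removes it exactly.

**Absolute coupling** (`absoluteCorrelation`): ordinary least squares of
`log2(SCPM + 1)` on `log2(TPM + 1)` over pooled (gene, biological
replicate) points of one strain and temperature, restricted to points
detected in both data sets. Pooling replicates follows the convention of
plotting all replicates of a strain per condition; per-replicate
regressions are available via `perReplicate = TRUE`. The reported
r-squared equals the squared Pearson correlation of the point cloud (an
invariant under exchanging axes, which the tests check against an
independent computation).

**Fold-change coupling** (`foldchangeCorrelation`): OLS of protein log2
fold changes on transcript log2 fold changes over shared genes, optionally
restricted to significant proteins — the restriction reproduces the check
that removing non-significant proteins does not rescue a vanishing
fold-change correlation.

**Concordance** (`classifyConcordance`): each differentially expressed
protein is classified against its transcript as *concordant* (transcript
significantly changed in the same direction), *discordant* (opposite
direction) or *protein-only* (no significant transcript change). The
classes partition the DEP set; the summary reports the concordant
percentage of all DEPs. Transcript direction deliberately means
*significant* direction — a non-significant transcript contributes
"none", not its noise sign.

# GO enrichment against an expressed background

`fisherEnrichment` performs classic one-sided hypergeometric
(over-representation) tests per term, with the universe restricted to the
genes with detectable expression. That restriction is the scientifically
important part: against a whole-genome background, any expressed gene set
appears enriched for terms that simply accompany expression. A term is
reported only when p < 0.05 *and* it occurs at least 5 times in the
background; no multiple-testing adjustment is applied because tests along
an ontology DAG are strongly dependent — both filters are deliberate
reporting rules, not oversights, and both are asserted in the tests.
Weighted/eliminating DAG algorithms are intentionally out of scope; with
`propagateAnnotations` (true-path propagation over `is_a` edges, minimal
OBO parsing via `readObo`) the counts at general terms behave correctly
under the classic test.

# ROS assays

`normalizeRos` converts dye fluorescence to per-cell values (fluorescence
divided by symbiont cell count; rows without a positive count are rejected
and reported), and `compareRos` applies the same Welch comparison of
stress versus control per strain and context. Per-cell normalization is
used for both in-host and isolate measurements. The in-host versus isolate
comparison remains descriptive (means and standard errors side by side);
no formal interaction test is fitted.

# The synthetic-data generator

`simulateStudy` draws studies with the structure the pipeline assumes.
Defaults (`SimConfig()`) encode the emulated study layout and regimes:

| Parameter | Default | Meaning / rationale |
|---|---|---|
| `strains`, `nBioReps` | 3 strains, 4 | layout of the emulated study |
| `temperatures` | control, stress | 25°C vs 32°C analogue |
| `nTechReps` | 2 | matches the ≥2-technical-replicate filter |
| `nRuns` | blocks/2 | two biological-sample blocks per run (8-plex-like); both temperatures in every run so temperature is never confounded with run |
| `couplingRho` | 0.45 | latent log2 transcript-protein correlation; squared gives the weak absolute coupling regime, r² ≈ 0.2 |
| `fcCouplingRho` | 0 | temperature effects on transcript and protein independent — the decoupled fold-change regime |
| `deFraction` | 0.10 | per-strain fraction of genes with a temperature effect (comparable to the largest observed DET fraction of the gene catalogue) |
| `effectSizeSd` | 1 | log2 effect scale of affected genes |
| `latentMean`, `latentSd` | 6, 2 | log-normal (on log2 scale) latent abundances; log2 transforms of abundance data are approximately normal |
| `loadingOffsetSd` | 0.5 | per-channel loading artefact removed by normalization |
| `peptidesPerGene` | 3 | shifted Poisson, minimum 1 |
| `peptideEffectSd` | 0.5 | per-peptide efficiency spread; kept small relative to `latentSd` so the absolute-coupling calibration (measured r² ≈ `couplingRho`²) holds, which is the generator's stated contract |
| `ambiguousFraction` | 0.10 | peptides mapping to >1 gene model, partner chosen as the gene with the nearest latent protein abundance so representative selection is nontrivial |
| `detectProb` | 0.85 | missing-at-random detection per peptide and channel |
| `noiseSdTranscript`, `noiseSdProtein` | 0.25 | log2 measurement noise |

Differential flags are shared between the two molecular levels of a gene
(a temperature-responsive gene responds in both), while the *effect
sizes* are bivariate normal with correlation `fcCouplingRho` — at 0,
directions and magnitudes are independent, which is what makes the
decoupled regime and the near-chance concordance level reproducible.

What the generator does **not** emulate: count noise of sequencing,
spectral interference and ratio compression of isobaric labelling,
missingness that depends on abundance, batch structure beyond per-channel
offsets, and any time dependence of translation. Passing tests therefore
validate the estimators under clean log-normal assumptions, not the
pipeline's behaviour on every pathology of real data.

# Numerical and design choices

* Medians and centring are exact identities; idempotence and the
  median-zero postconditions are asserted to 1e−9.
* Degenerate Welch inputs: zero variance in both groups gives p = 1 for
  equal means and p = 0 otherwise; groups with fewer than two values are
  skipped and reported, never silently dropped.
* Ties: longest-isoform reduction and representative-gene choice break
  ties by the lexicographically smallest identifier, making outputs
  deterministic.
* The spec-level idealization that zero-noise simulations recover effects
  *exactly* holds only when regulated genes do not move the channel
  medians; the tests verify exactness on a fixture constructed with
  pinned middle order statistics, and near-exactness (max error < 0.1 at
  effect scale 1) on zero-noise simulations.
* All simulation randomness flows from one integer seed; sub-stages use
  fixed offsets of it, so partial re-simulation is reproducible and
  identical configurations are byte-identical.
* Open reading of "correction factor subtracted from each run": applied
  per channel within run (a per-run constant would not remove
  channel-level loading differences); the per-gene polish then works on
  run-level summaries.
* BH universes: per strain for transcript tests, the filtered protein set
  for t-tests, per term for the two-factor model.

# Problem sizes used in validation

The packaged checks run one full synthetic twin (5000 genes, 3 strains ×
2 temperatures × 4 biological replicates × 2 technical channels),
calibration simulations of 2000–4000 genes or repeats per caller, and a
40-replicate FDR estimate of 2000 genes each — sizes at which the
binomial and coupling tolerances stated in the tests are meaningful for
desk-scale validation.

# Known limitations

* The transcript caller is a proxy; quantifier uncertainty is ignored.
* Classic Fisher enrichment over-counts dependent ancestor terms compared
  with eliminating algorithms; results are reporting-filtered, not
  corrected.
* The fold-change rule has no error control by construction; use the
  t-test and model outputs alongside it.
* SCPM from summed intensities is a pragmatic absolute-abundance unit;
  no peptide-level normalization for length or detectability is applied.
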