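---
title: "Reference-gene stability: models, estimators and design choices"
author: "qpcrStab"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reference-gene stability: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qpcrStab)
```

# The problem

Relative RT-qPCR quantification reports a target gene's expression as a
ratio to one or more reference genes measured in the same sample. The
method is only as good as the references: a "housekeeping" gene that
responds to the experimental condition injects its own response into
every normalized value. `qpcrStab` implements the community-standard
workflow for choosing and validating reference genes: screen candidates
from RNA-seq, score their Ct profiles with four independent stability
estimators, aggregate the rankings, decide how many references are
needed, and demonstrate the consequence of a bad choice on a target
gene.

# Data model

The central container is `CtExperiment`, a `SummarizedExperiment` whose
`"ct"` assay holds threshold-cycle values (genes × samples). Ct is the
PCR cycle at which fluorescence crosses a fixed threshold; one cycle ≈
one doubling of template, so Ct is a (negative) log2 expression scale.
`colData` carries the sample sheet — `tissue`, condition `subset`
(developmental / cold / drought / custom), `group` within the subset
(e.g. `ck`, `4h`, `12h`) and `replicate` — and `rowData` the per-gene
amplification efficiency in percent. `"total"` always denotes the union
of all subsets.

Conventions fixed here (and used by all tests):

* **Missing Ct**: the reader maps empty cells and a configurable token
  (default `"Undetermined"`, the ABI-instrument convention) to `NA`;
  values above a detection ceiling (default 40 cycles) can be masked at
  construction.
* **Efficiency default**: genes without a measured efficiency get 100%
  (perfect doubling, E_fold = 2), because the ΔCt and 2^−ΔΔCt
  formalisms implicitly assume doubling. Values outside 90–110% load
  with a warning — they are suspect standard curves, not fatal errors.
* **Boxplot summaries** (`ctDescriptives()`): quartiles use the
  linear-interpolation rule (R type 7); outliers are points beyond
  1.5 × IQR from the box and extremes beyond 3 × IQR — the usual Tukey
  fences, matching the circles/asterisks convention of qPCR
  descriptive figures. No claim is made that any specific instrument
  software uses the same quantile rule; the choice is documented and
  frozen so results are reproducible.
* **Standard-curve efficiency**: `E = (10^(−1/slope) − 1) × 100` with
  slope the Ct-per-log10-dilution regression coefficient
  (`efficiencyFromSlope()`).

# Candidate screening

`screenStats()` computes per gene, over a TPM matrix: mean (MV), n−1
SD, CV = SD/MV, per-tissue means, and
log2FC = log2(max tissue mean / min tissue mean). `screenCandidates()`
applies the two-stage filter:

| stage | expression | log2FC | CV |
|---|---|---|---|
| 1 (lenient) | MV ≥ 5 TPM | ≤ 2 | ≤ 0.5 |
| 2 (strict)  | (stage 1)  | < 0.2 | < 0.3 |

Stage 1 is ranked by ascending CV and truncated to `topK` (default 50).
Stage 1 uses inclusive comparisons and stage 2 strict ones, mirroring
how the cutoffs are usually phrased ("lower than five TPM" excludes,
"reducing the cut-off to 0.3" tightens past the boundary). The
expression floor applies to the mean TPM by default; a `minTpmRule =
"all"` switch requires every sample to pass instead, since "expression
level below 5 TPM" is ambiguous between the two readings.

# The four stability estimators

All four run per sample subset. geNorm and NormFinder operate on
*relative quantities* `Q = E_fold^(minCt − Ct)` (per gene, anchored at
its best-expressed sample so Q ∈ (0, 1]; the anchor cancels in every
ratio and only bounds the numeric range). By default E_fold = 2 for all
genes; `efficiencyCorrection = TRUE` uses the stored per-gene
efficiencies instead — whether a given study used corrected quantities
is rarely stated, so both are supported with doubling as the default.
ΔCt and BestKeeper are defined on raw Ct.

**Comparative ΔCt.** score_j = mean over partner genes k of the n−1 SD
of Ct_j − Ct_k over samples. Differences cancel anything shared by all
genes of a sample (cDNA input, reverse-transcription yield), so the
score is exactly invariant to per-sample loading shifts. With perfect
doubling, SD(log2 Q_j/Q_k) = SD(Ct_j − Ct_k), so ΔCt scores equal
first-round geNorm M values to numerical precision — the two modules
cross-check each other in the tests at 1e−9.

**geNorm.** M_j = mean over k of SD(log2 Q_j/Q_k). The ranking removes
the highest-M gene and recomputes until two genes remain; those two are
mutually indistinguishable (their M values are identical by
construction) and share rank 1.5. Ties at the exclusion step break by
gene-id lexicographic order, with a message. The pairwise variation
V(n/n+1) is the SD over samples of log2(NF_n/NF_{n+1}), where NF_n is
the geometric mean of the top-n genes' Q; the optimal reference count
is the smallest n with V < 0.15. When no V falls below the cutoff the
full panel size is returned and the result flagged
(`@vBelowCutoff = FALSE`) — the data then do not support a compact
reference set.

**NormFinder-style decomposition.** With log2 quantities x (gene i,
group g, sample j):

1. center each sample across genes: z = x − sample mean (removes
   loading);
2. per gene × group: mean z̄(i,g) and residual variance s²(i,g) (n−1);
3. bias-correct for the centering (k genes):
   σ̂²(i,g) = max{0, (s²(i,g) − mean_i s²(i,g)/(k−1)) / (1 − 2/k)} —
   undefined for k ≤ 2, hence the 3-gene minimum;
4. intergroup effects d(i,g) = z̄(i,g) − mean_g z̄(i,g), their panel
   dispersion γ̂² = max{0, Σd²/((k−1)(G−1)) − mean(σ̂²/n_g)}, and the
   shrunken effect d̃ = d · γ̂²/(γ̂² + σ̂²/n_g);
5. SV_i = mean_g( |d̃(i,g)| + √(σ̂²(i,g)/n_g) ).

The shrinkage treats each gene's observed group effect as a noisy draw
from a panel-wide distribution: effects supported by little evidence
(large σ̂²/n relative to γ̂²) are pulled towards zero. The sampling-SE
term in step 5 is deliberately *not* multiplied by the shrinkage
factor: γ̂² is floored at zero and in panels with no real intergroup
variation the floor is hit with substantial probability, which would
collapse every SV to zero and declare a noisy gene exactly as stable as
a quiet one. Keeping the plain √(σ̂²/n_g) term makes SV degrade
gracefully to a pure intragroup-noise ranking in that regime — the
parameter-recovery tests (Spearman ≥ 0.9 against planted noise SDs with
no group effects) validate exactly this behavior. With a single group
(or after dropping groups with fewer than two samples) SV reduces to
√σ̂².

For the `"total"` subset the three condition subsets act as the groups,
since the union has no within-subset grouping of its own; this choice
is recorded in the result (`@groupSizes` names) and can be overridden
via the `groups` argument.

**BestKeeper.** Per gene on raw Ct: arithmetic and geometric mean, min,
max, n−1 SD, CV% = SD/mean × 100, and the Pearson correlation r with
the BestKeeper index — the per-sample geometric mean Ct over qualifying
genes. Genes with SD > 1 cycle (strictly greater; SD = 1.00 stays) are
excluded from the index but retained in the report and ranking, so the
composite stays comparable across the whole panel. Genes are ranked by
ascending SD, ascending CV% and descending r (stable genes co-vary
positively with the index; |r| would reward anti-correlation), and the
composite is the geometric mean of the three rank positions. A
zero-variance gene has undefined r and takes the best r-rank — it is
perfectly stable, not unrankable. The dispersion measure is the sample
SD by default; `dispersion = "mad"` gives the mean absolute deviation
used by some BestKeeper descriptions. The index is built once from the
SD-qualified set (no iterative re-exclusion); whether r should be
computed against an index including SD-rejected genes is genuinely
ambiguous in the literature, so `indexOnQualified = FALSE` provides the
alternative.

# Consensus and the recommended set

`consensusRank()` aggregates the four rank vectors by geometric mean —
the scale-free choice for combining rank positions — and ranks the
geomeans ascending (ties averaged; display order breaks ties by gene
id). The geNorm final pair contributes rank 1.5 to each member. The
recommended set is the top `optimalN` genes, with `optimalN` taken from
the geNorm pairwise variation unless given explicitly. Methods must
have been run on identical gene sets; a missing gene is an error, not a
silent drop.

# 2^−ΔΔCt validation

`ddctQuantify()` computes, per sample,
δ = log2 Q_target − log2 NF_ref (NF_ref = geometric mean of the
reference genes' Q — the multi-reference combination rule matching the
geNorm normalization-factor convention), then scales 2^δ within each
tissue by the mean of the control group's values. Anchoring on the
linear scale makes the control group's mean RQ exactly 1 — the natural
invariant for "expression relative to control" — where anchoring on the
log scale would leave the control mean above 1 by Jensen's inequality
whenever replicates disagree. With a single reference, perfect
doubling and one control sample this is algebraically the textbook
2^−ΔΔCt. Replicate-level RQs are retained; the summary reports their
arithmetic mean and SD per tissue × group.

`compareNormalizers()` runs several normalizer sets side by side and
reports, per pair, the maximum and mean |log2 ratio| of the summarized
RQ profiles — an unstable reference with a condition shift of c cycles
biases the apparent target expression by 2^c in that condition.

# The simulator and what it does (not) emulate

`simulateCt()` draws
`Ct(i, s) = μ_i + loading(s) + Δ(i, group(s)) + N(0, σ_i)`, with
`loading ~ N(0, τ)` shared by all genes of a sample. This is the
standard additive-on-Ct (log-scale on expression) qPCR error model; the
loading term models cDNA-input differences that any good normalization
must cancel, and the Δ table plants condition-specific shifts — the
classic misbehaving-housekeeper failure mode. The default configuration
mirrors a typical medicinal-plant reference-gene study: 15 candidate
genes, three tissues (leaf/stem/root), a developmental series
(ck/15d/30d), a cold time course (ck/4h/8h/12h), a drought series
(ck/5d/10d), three biological replicates (90 samples), baselines
μ ∈ [18, 32] cycles, τ = 0.2 cycles, efficiencies spread over 91–109%.
The planted panel has three very stable genes (σ = 0.05, Δ = 0), ten
intermediate genes (σ = 0.15–0.6) and two unstable genes (σ = 0.5 with
±0.5–2-cycle shifts across the stress groups). An optional target gene
converts a fold-change schedule into Ct displacements (−log2 fold).

The declared "true" stability order used by recovery tests is
ascending `sqrt(σ_i² + Var_g(Δ_i,g))`, with the Δ variance taken over
the realized per-sample group assignments — one concrete, documented
composite of noise and condition response, not a claim about how any
published study's genes truly rank.

`simulateTpm()` plants screening statistics *exactly*: tissue means are
set to realize the requested log2FC, within-tissue residuals are
standardized (bounded uniforms, keeping TPM positive) so the realized
MV, CV and log2FC equal their targets to floating-point precision at
any seed. Expected stage membership is therefore known in advance,
which is what makes the screening-filter test exact rather than
statistical.

What the simulator does **not** emulate: amplification-curve artifacts
(the generator plants Ct directly), inhibitor- or dilution-dependent
efficiency drift, technical-replicate structure nested inside
biological replicates, correlated noise between genes beyond the shared
loading term, and log-normal TPM heavy tails beyond the bounded
residual construction. Passing tests therefore demonstrate that the
estimators recover planted structure under the stated error model — not
that any particular wet-lab data set satisfies that model.

# Numerical and degenerate-case policy

* n−1 (sample) SDs and variances throughout, matching spreadsheet
  `STDEV` conventions.
* Pairwise statistics use pairwise-complete samples with a minimum of
  3; pairs below the floor are dropped with a warning rather than
  failing the whole panel, and a gene with no usable partner is removed
  with a warning.
* Negative variance estimates (NormFinder steps 3–4) floor at 0.
* Rank ties average; argmax ties in the geNorm exclusion break
  lexicographically and are messaged.
* geNorm needs ≥ 3 genes to rank (2 to compute M); NormFinder needs
  > 2 genes and ≥ 2 samples per group; BestKeeper needs ≥ 3 genes and
  ≥ 3 samples; ΔCt works from 2 genes (both scores then equal the
  single pairwise SD).
* All simulations are deterministic given a seed, and the RNG state of
  the caller is restored afterwards.

# Problem sizes in the test suite

The suite validates the estimators at deliberately modest sizes chosen
to make every property measurable in seconds: hand-computable 3-gene /
4-sample toys for exact values; 100 random instances for the ΔCt/geNorm
equivalence; 20 replicate data sets (15 genes, 3 groups of 6) for
NormFinder rank recovery plus 20 at 600 samples for variance recovery;
100 simulated studies at the full 90-sample design for end-to-end
consensus recovery; and 10,000-sample runs for the noise-model sanity
check.

# Known limitations

* geNorm cannot order its final pair; both report rank 1.5, and the
  consensus inherits that tie. Published tables that order the top two
  genes used information geNorm itself does not provide.
* The NormFinder SV here follows the variance-decomposition family but,
  like every reimplementation of a method published as a binary/Excel
  tool, it is validated by parameter recovery on simulated data, not by
  byte-agreement with the original program's output.
* BestKeeper's r is computed against an index that contains the gene
  itself (the standard construction); for small panels this inflates r
  and the index reweights slightly when a member gene shifts.
* Efficiency correction assumes a single per-gene efficiency across all
  samples; condition-dependent efficiencies are out of scope.
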