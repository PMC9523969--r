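---
title: "Methods: discovering immune-related lncRNA prognostic signatures"
author: "irlncsig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: discovering immune-related lncRNA prognostic signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## Scope and model overview

`irlncsig` implements a discovery workflow for immune-related long
non-coding RNA (ir-lncRNA) prognostic signatures from bulk expression
cohorts. The biological premise is that coordinated Th1/cytotoxic immune
activation in a tumor — summarized by a 20-gene immunologic constant of
rejection (ICR) module — defines immune-hot versus immune-cold phenotypes,
and that lncRNAs differentially expressed between these phenotypes
(ir-lncRNAs) carry prognostic information of their own. Because most
lncRNAs are functionally unannotated, the workflow interprets them
indirectly: it propagates their identity over a coding–non-coding (CNC)
co-expression network to find the protein-coding genes most proximal to the
ir-lncRNA set, and it compresses the lncRNAs themselves into small
signatures whose per-sample enrichment scores are evaluated against overall
survival.

The six stages are:

1. **Immune phenotype calling.** Resampling-based consensus clustering of
   the ICR submatrix, Ward-linkage (Ward.D2) inner clustering on Euclidean
   distance of per-gene z-scored values, complete-linkage outer clustering
   of `1 - consensus`, and cluster-number selection by the
   Calinski–Harabasz (CH) criterion
   \[ CH(k) = \frac{B(k)/(k-1)}{W(k)/(n-k)}, \]
   ties toward the smallest k. Clusters are ranked by mean ICR expression
   into `ICR_high … ICR_low` tiers; downstream comparisons use only the
   extreme tiers.
2. **Differential lncRNA expression.** A two-group moderated t per lncRNA:
   empirical-Bayes variance moderation with a scaled inverse-chi-square
   prior \((d_0, s_0^2)\) estimated by moment matching on \(\log s_g^2\)
   (digamma/trigamma closed forms, own trigamma inverse), posterior
   variance \(\tilde s_g^2 = (d_0 s_0^2 + d_g s_g^2)/(d_0 + d_g)\), and
   p-values on \(d_0 + d_g\) degrees of freedom. When the log-variances
   show no excess spread the prior degenerates (\(d_0 = \infty\), \(s_0^2\)
   the mean sample variance) and the statistic reduces to the ordinary
   pooled t. FDR control is Benjamini–Hochberg; the ir-lncRNA filter keeps
   q < 0.05 and |log2FC| > 1 (two-sided, since both up- and down-regulated
   lncRNAs are of interest).
3. **Network propagation.** The CNC network links any pair of features with
   |correlation| at or above a threshold, weighted by |correlation|; the
   transition operator is the column-normalized weight matrix, with
   self-loops on otherwise isolated nodes so every column stays stochastic
   without teleporting mass to the whole graph. Random walk with restart
   iterates \(p \leftarrow (1-r)Wp + r p_0\) from a uniform distribution
   over the ir-lncRNA seeds until the L1 change falls below 1e-10; the
   fixed point solves \(p = r(I - (1-r)W)^{-1}p_0\). Coding genes with
   walkscore ≥ 0.01 form the ranked proxy list.
4. **Pathway enrichment.** Either a Kolmogorov–Smirnov-like statistic on
   the walkscore-weighted running sum over the ranked coding genes, with a
   permutation null from relabeling pathway membership
   (\(p = (1 + \#\{null \ge obs\})/(B+1)\), so p is floored at
   \(1/(B+1)\)), or classical upper-tail hypergeometric
   over-representation of the selected proxy list; BH across pathways.
5. **Signature derivation.** Three signatures: top-k ir-lncRNAs by
   differential-expression strength (ascending q, then descending |log2FC|,
   then id); top-k by checkpoint association (descending signed row-sum of
   the Spearman correlation matrix against a checkpoint panel — the same
   statistic that orders the correlation heatmap); and their intersection
   as the minimal signature. All ties break lexicographically so
   derivations are platform-independent.
6. **Survival evaluation.** Per-sample ssGSEA scores for the ICR module and
   each signature; univariate Cox proportional-hazards fits on the
   continuous scores (Efron ties); a combined model summing the two
   z-scaled enrichment scores; AIC comparison
   (\(\Delta AIC = AIC_a - AIC_b\), negative favoring model a);
   a cross-validated optimal Kaplan–Meier cutpoint with a log-rank test;
   and a cohort-level call: *enabled* when HR < 1 with p < 0.05,
   *disabled* when HR > 1 with p < 0.05, else *neutral*.

## Key parameters

| parameter | default | meaning |
|---|---|---|
| `k_range` | 2–5 | candidate cluster numbers for consensus clustering |
| `reps` | 5000 (production) | consensus subsampling repeats; 50–200 suffice for well-separated data and are used throughout the test suite |
| `p_item` | 0.8 | subsample fraction per repeat |
| `q_max`, `lfc_min` | 0.05, 1.0 | ir-lncRNA filter (FDR, |log2FC|) |
| `r_min` | 0.5 (function) / 0.7 (pipeline profile) | CNC edge threshold on &#124;correlation&#124; |
| `restart_r` | 0.7 (function) / 0.3 (pipeline profile) | RWR restart probability |
| `walkscore_cutoff` | 0.01 | proxy-gene selection rule |
| `alpha` | 0.25 | ssGSEA rank-weight exponent |
| `k_signature` | 20 | size of the DE- and checkpoint-derived signatures |
| `folds`, `min_group_frac` | 5, 0.10 | CV cutpoint folds and minimum group size |

### Why the pipeline profile lowers `restart_r` and raises `r_min`

The walkscore vector is normalized to total mass one. For a seed set of
size \(|S|\) with uniform seed mass \(q = 1/|S|\), a non-seed node's
walkscore is maximized in the topology where one seed is exclusively
connected to it, giving the closed-form bound
\[ p_{\max} = q\,\frac{1-r}{2-r}. \]
At \(|S| = 40\) and \(r = 0.7\) the bound is 0.0058 — below the 0.01
selection rule — so no coding gene can ever be selected, whatever the data.
The stringent cutoff is attainable for moderate seed sets only when
\(r \le 1/3\); the pipeline profile therefore uses `restart_r = 0.3` while
the `rwr()` function default remains the conventional 0.7 for general
propagation use. Separately, when an effect of size \(\delta\) on log2
scale separates phenotypes with residual SD \(\sigma\), any two
phenotype-responsive features share a correlation of about
\(\frac{\delta^2/4}{\delta^2/4 + \sigma^2}\) — exactly 0.5 at the default
study conditions (\(\delta = 2, \sigma = 1\)). An edge threshold of 0.5
therefore floods the network with module co-regulation edges that drown
the direct lncRNA–proxy couplings (|r| ≈ 0.9); the profile threshold 0.7
sits between the two regimes.

## The synthetic cohort generator

`generate_cohort()` draws the statistical structure the analysis assumes,
plus a full ground-truth record, so every stage has a recovery test:

* a latent binary hot/cold phenotype (Bernoulli, default 0.5);
* Gaussian log2-scale expression (baseline Uniform(4, 8), residual SD 1) —
  matrices are modeled after already-normalized log-expression values, so
  there is no raw-count layer;
* a 20-gene ICR module and a 30-gene checkpoint panel shifted up by
  `de_effect` (default 2) in hot samples;
* 40 planted ir-lncRNAs, 17 up- and 23 down-regulated (mirroring, at
  reduced scale, the preponderance of down-regulated ir-lncRNAs in
  immune-hot tumors);
* 30 proxy coding genes, each a noisy linear image of one planted lncRNA
  (slope ±Uniform(0.7, 1), noise SD half the residual SD, guaranteeing
  |r| above any sensible edge threshold);
* exponential survival with log-hazard `hazard_coef` (default −0.7, i.e.
  an immune-favorable cohort) per unit standardized mean ICR expression,
  and administrative uniform censoring whose window is found by bisection
  to hit the target censoring rate;
* two RNG sub-streams (expression, survival) derived from one master seed,
  so survival parameters can change without perturbing expression, and
  identical seeds give bit-identical cohorts.

What the generator does **not** emulate: count-level noise and library-size
effects, batch effects, tumor purity, correlated background co-expression
structure, and non-proportional hazards. Passing recovery tests therefore
demonstrates internal consistency of the pipeline under its own
assumptions, not performance on real tumor cohorts.

## Numerical choices and degenerate inputs

* Consensus entries are co-clustering counts over co-sampling counts;
  pairs never co-sampled contribute 0 and the diagonal is fixed at 1.
* `select_k` skips candidates with empty clusters or k < 2 and errors only
  if nothing remains; ties go to the smallest k.
* Zero-variance features: floored (with a message) in the moderated t
  (p = 1 and t = 0 when the fold-change is also zero), excluded from
  network construction and from Spearman matrices.
* RWR converges for any restart in (0, 1]; the iteration errors after
  10000 sweeps rather than returning an unconverged vector. Walkscore ties
  in rankings break lexicographically by id.
* ssGSEA uses average ranks for ties and is invariant to strictly monotone
  transforms; the variant is the weighted running sum with
  \(\alpha = 0.25\) and no final normalization by feature count. Where a
  per-sample enrichment method had to be fixed among the common variants,
  this choice is recorded in the score table's metadata attribute.
* BH adjustment is monotone in p but **not** idempotent: re-adjusting an
  adjusted vector multiplies by n/rank a second time, so
  \(f(f(p)) \ge f(p)\) with equality only for flat q-vectors. Code should
  never re-adjust adjusted values.
* The Cox fit refuses constant covariates, cohorts with fewer than two
  events, and monotone-likelihood separations; Efron and Breslow tie
  handling agree exactly on tie-free data (a cross-check in the suite).
* The CV cutpoint grid spans the 20th–80th score percentiles in steps of
  0.05, candidates leaving a group under 10% of the cohort are skipped,
  the objective is the mean training-split log-rank statistic, and ties
  resolve toward the median score. Fold assignment is event-stratified and
  seeded.
* Quantile normalization follows the classical per-rank-mean definition
  with tie averaging; it is applied per feature class by default (the
  coding and lncRNA matrices are normalized separately), since the two
  biotypes have very different abundance distributions.

## Design decisions on genuinely open points

* "Top 20 by differential expression" is ranked by adjusted p then
  |log2FC|; the ordering key is recorded in each signature's derivation
  record.
* "Associated with immune checkpoints" is ranked by the *signed* Spearman
  row sum, mirroring the heatmap column-ordering statistic; an
  absolute-sum variant is available (`use_abs`). A checkpoint showing an
  opposite correlation pattern (e.g. CD276-like behavior) is deliberately
  left in the configurable panel — panel curation is the user's call.
* The 20-gene ICR membership and the 30-gene checkpoint panel ship as
  editable GMT defaults under `inst/extdata/` (literature-based lists);
  both are plain config inputs, not hard-coded constants.
* log2FC is oriented high − low, so positive values mean higher expression
  in immune-hot samples.
* Continuous-score Cox models use the raw enrichment score; per-unit HRs
  are therefore close to 1 in magnitude on large-scale scores (z-scaled
  variants are available for cross-cohort comparability, and the combined
  model always uses z-scaled scores).

## Problem sizes used by the tests

The suite exercises the full pipeline on cohorts of 120–300 samples with
150–500 coding genes and 80–200 lncRNAs, consensus clustering at 40–200
repeats, 200–1000-permutation enrichment nulls, and 200-replicate coverage
simulations for the Cox model — sizes chosen so the whole suite and the
acceptance script each complete in a few minutes on a single CPU while
every recovery property remains far from its decision boundary.

## Known limitations

* The CNC network is dense-matrix based; transcriptome-scale networks
  (tens of thousands of nodes) should be supplied as sparse edge lists and
  would need a sparse transition operator for comfortable memory use.
* The generator's Gaussian expression model makes moderated-t assumptions
  exactly true; real RNA-seq deviates (mean–variance trend, outliers), and
  the package intentionally omits trend/robust variants.
* Signature scores mix up- and down-regulated members in one enrichment
  score; strongly mixed signatures can have unstable prognostic direction.
  The checkpoint-derived ranking counteracts this by favoring positively
  correlated (up-regulated) lncRNAs, which is why the intersection
  signature has a stable direction in practice.
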