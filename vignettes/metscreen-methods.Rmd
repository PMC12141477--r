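---
title: "Hit calling for in vivo CRISPR metastasis screens: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hit calling for in vivo CRISPR metastasis screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metscreen)
```

## The problem

In a pooled CRISPR knockout screen read out in vivo, a cell population in
which every cell carries one sgRNA is transplanted into mice; after tumor
growth and metastatic spread, sgRNA abundances in each tissue are read out
by sequencing. A *metastasis suppressor* is a gene whose loss increases
metastatic capacity, so its sgRNAs become **enriched** in metastatic
lesions relative to the matched primary tumor of the same mouse. The screen
design this package targets is: two cell lines, five replicate mice per
line, infection at MOI ~0.3 so that most infected cells carry a single
sgRNA, at least 200-fold per-sgRNA cellular coverage per mouse, and paired
primary / lung (and optionally liver) samples per mouse.

`metscreen` implements the full hit-calling chain on top of MAGeCK-style
count tables, plus a generative simulator with planted suppressors so that
every stage can be validated without sequencing data.

## Per-sgRNA model

Counts are normalized by median-of-ratios (DESeq-style): the size factor of
a sample is the median, over sgRNAs positive in every sample, of the count
divided by the sgRNA's geometric mean. When the metastasis bottleneck
leaves no sgRNA positive everywhere — common for in vivo screens — the
estimator is undefined and the package falls back to total-count size
factors with a warning. Size factors are defined up to one common
constant; all downstream statistics are invariant to it.

The mean-variance relation `var(mu) = mu + k * mu^b` is fitted on the
replicated control (primary) samples by regressing `log(var - mean)` on
`log(mean)` over sgRNAs with empirical variance above their mean; `k > 0`
guarantees the predicted variance never falls below the mean. With a
single control sample or too few overdispersed sgRNAs the fallback
`var = mu + 0.01 mu^2` is used.

For the paired comparison within one mouse, the primary-tumor normalized
count (plus pseudocount) sets the null mean `mu`, the model sets the
variance, and the metastasis value `t` is scored by negative-binomial
tails (`size = mu^2/(v - mu)`; Poisson when `v <= mu`):
`p_high = P(X >= t)` flags enrichment (positive selection, the suppressor
signature), `p_low = P(X <= t)` flags depletion. Two numerical choices
matter in practice:

* the pseudocount (default 1) is added to **both** sides, so two identical
  samples give a score of exactly 0 and near-centered tails; adding it to
  the control only would shift every null comparison by one count;
* tails are computed and ranked **in log space**. Under a tight seeding
  bottleneck the strongest enrichments have upper tails far below the
  smallest positive double; clamped linear-scale values would tie and
  erase the ordering at the exact top of the ranking where it matters
  most.

## Gene-level aggregation (alpha-RRA)

Per direction, sgRNA p-values are converted to fractional ranks
(`rank/n`, ties averaged). For a gene with sorted percentiles
`r_1 <= ... <= r_m`, the score is

`rho = min over {i : r_i <= alpha} of I_{r_i}(i, m - i + 1)`,

the minimum over the qualifying order statistics of the probability that
the i-th of m uniforms falls at or below `r_i`; `rho = 1` when no
percentile enters the top-`alpha` fraction (default `alpha = 0.05`).

Significance comes from a permutation null preserving each gene's sgRNA
count: for each gene size `m`, `n_perm` draws of `m` percentiles are
sampled without replacement from the observed pool, and

`p = (1 + #{(rho, mean pct)_perm <=lex (rho, mean pct)_obs}) / (1 + n_perm)`.

The comparison is **lexicographic**, with the gene's mean sgRNA percentile
as a continuous tie-break. This choice is load-bearing: `rho` has a large
atom at 1 (every gene with no sgRNA in the top-`alpha`), and comparing
`rho` alone would put a point mass of null p-values at 1, leaving most of
the report tied. Tie-breaking by a continuous exchangeable statistic
spreads the atom exactly uniformly, so null gene-level p-values are
uniform (the package's calibration tests verify a Kolmogorov–Smirnov
statistic of ~0.02 on pure-null screens) and the report ranks are fully
ordered. Report ranks order by ascending p, then `rho`, then mean
percentile, then gene id — a deterministic 1..n permutation; a pure
gene-id tie-break would make the lung and liver reports' tie blocks
identically ordered and degrade the rank filter below to a coin flip.

FDR is Benjamini–Hochberg. One practical note on `n_perm` (default
10000): the permutation p floor is `1/(n_perm + 1)`, and BH-adjusted
significance at threshold `q` with `k` true hits among `n` genes needs the
floor well below `q * k / n`. For genome-scale reports intended to be
thresholded on FDR, 50000 or more permutations are appropriate; rank-based
use is insensitive to this.

## Replicate integration and hit calling

Following the screen's design, mice are first filtered by lung preference:
of the five replicates, the four with the highest fraction of metastatic
burden in the lung are kept (`select_mice`), because the tumor type is
strongly lung-tropic and lung-consistent genes are the biologically
relevant ones. Per gene, the **essentiality score** is `-log10` of the
smallest FDR-adjusted p across the selected mice's lung comparisons; genes
are ranked by that minimum (ties by the best per-mouse `rho`, then id).
Two lines are compared by `cross_line_concordance`: concordant genes are
significant in both lines at the chosen threshold, and the combined rank
is the worse of the two per-line ranks, so the shared top list requires
strength in both lines.

The alternative route, `lung_liver_rank_filter`, asks for organ
specificity directly: a gene passes in a mouse when its depletion rank in
the lung report is strictly worse than in the paired liver report **and**
its enrichment rank is strictly better; a gene passes overall only when it
passes in every replicate. For passing genes, per-mouse p-values of the
chosen direction are combined by Fisher's method (the combination rule is
not dictated by the screen description; Fisher is the standard choice for
independent replicates and is exposed as such). Note the strictness of the
all-replicates rule: a truly lung-specific gene sits near the very bottom
of the lung depletion ranking, and a neutral gene's liver rank exceeds it
with small but nonzero probability in each mouse, so even strong planted
hits pass at a rate around 0.75–0.9 rather than 1.0. The direction flag
defaults to `pos` (enrichment in metastases), matching the suppressor
signature; the depletion-direction reading is available via
`direction = "neg"`.

## The simulator

`simulate_screen` mirrors the physical experiment stage by stage:
log-normal plasmid abundances (sigma 0.5); founder infection as a
multinomial draw of `cells_per_mouse * moi` cells (default sized so
coverage is at least 200x); gamma-multiplicative clonal growth noise
(per-cell clone size `Gamma(shape = 1/dispersion, mean 1)`, dispersion
0.5, which yields negative-binomial-like count marginals); per-cell organ
seeding (`Binomial(cells_g, base_seed_prob * effect_g)`) truncated to an
organ bottleneck by sampling without replacement; the same clonal noise
for metastatic outgrowth; and multinomial sequencing at fixed depth.
Planted suppressors multiply the per-cell seeding probability
(`lung_effect`, `liver_effect >= 1`).

Defaults are desk-scale study conditions: 2000 genes x 4 sgRNAs, 5 mice,
MOI 0.3, 200x coverage, a 5e6-cell primary tumor at seeding, per-cell
seeding probabilities 4e-4 (lung) and 1e-4 (liver) — the ~4:1 ratio
mirrors the lung-over-liver tropism of clear cell renal cell carcinoma —
and bottlenecks of 2000 (lung) and 1000 (liver) cells, reflecting
metastases founded by few clones. At these values a null sgRNA contributes
on average ~0.2 cells to a lung metastasis, so most sgRNAs drop out of
each lung sample — the dominant statistical feature of real in vivo
screens that distinguishes them from in vitro screens. All randomness
derives from one master seed through per-stage substream seeds, so runs
are byte-identical.

What the simulator does **not** model: immune editing, copy-number
artifacts on sgRNA counts, multi-step metastatic cascades, inter-sgRNA
efficacy differences, and PCR/sequencing biases beyond multinomial
sampling. Passing recovery tests on simulated screens therefore
demonstrates the statistical machinery under a faithful bottleneck model,
not performance on any particular real dataset.

## Validation strategy and measured behavior

The test suite asserts, among other properties: exact agreement of the
alpha-RRA score with numerically integrated order-statistic CDFs;
agreement of sampled permutation p-values with exhaustive enumeration over
all rank assignments on small instances; uniformity of gene-level null
p-values on pure-null simulated screens; recovery of at least 80% of 20
planted suppressors (lung effect 10) within the top 1% of final ranks by
the full replicate pipeline; and separation of planted lung-specific from
pan-organ genes by the rank filter. Problem sizes (1000–2000 genes, 4
sgRNAs per gene, 10000–50000 permutations) were chosen so the entire suite
runs in well under a minute on a laptop while keeping Monte-Carlo margins
comfortable.

## Quantification helpers

The small formulas used around such a study are included with exact
semantics: RNAscope H-score
(`sum_k k * (% cells in bin k)`, bins 0 / 1–3 / 4–9 / 10–15 / >15
dots per cell, exact rational percentages); ChIP percent input
(`100 * 2^(CT_input - CT_IP)`, with an optional explicit dilution
adjustment, off by default because the plain formula is the printed
convention); relative expression `2^-ddCt`; caliper tumor volume
`0.5 * L * W^2`; and single-cell track statistics where velocity is
accumulated path length over elapsed time (the common track-tool
convention) and directionality is the Euclidean-to-accumulated ratio,
defined as 0 for a motionless track.

## Known limitations

* The sgRNA model is a re-implementation of the negative-binomial
  rank-aggregation class of screen analysis, not a bit-level reproduction
  of any specific external tool; numerics differ in the tails.
* Permutation p-values are exchangeable across genes only when sgRNA
  assignment is; strong inter-gene count correlations (e.g. clonal
  hitchhiking under extreme bottlenecks) would make them conservative
  rather than anti-conservative.
* `lung_preference` must be supplied for real data (imaging signal or
  nodule counts); only the simulator provides a ground-truth value.
* The concordance defaults (significance 0.05, top-10 lists) are analysis
  conventions, configurable per study.
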