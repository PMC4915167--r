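---
title: "QTL mapping with BayesC: model, evidence scale and region calling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{QTL mapping with BayesC: model, evidence scale and region calling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bayescqtl)
```

## The problem

Maternal performance of beef cows — how easily a cow calves, and how well she
milks and raises her calf — is economically central but hard to dissect
genetically: the phenotypes are expensive (progeny-test stations, weigh-suckle-
weigh milk records) and the mapping populations are modest, typically a couple
of thousand animals structured in large paternal half-sib families and
genotyped on dense SNP chips. With far more markers than records, single-
marker regression is underpowered and multiple-testing-ridden; the standard
answer in animal genetics is Bayesian variable selection over all markers
jointly. This package implements that analysis end to end: a weighted BayesC
Gibbs sampler, a Bayes Factor evidence scale, sliding-window QTL region
calling, cross-trait comparison of called regions, and a synthetic-data
generator that emulates the population structure the method assumes, so every
stage is testable without any proprietary data.

## The model

For animal $i$ with genotype codes $z_{ij} \in \{-1, 0, 1\}$ (homozygote /
heterozygote / other homozygote) the phenotype is modelled as

$$ y_i = \mu + \sum_{j=1}^{n} z_{ij}\, a_j \delta_j + e_i, \qquad
   e_i \sim N(0, \sigma^2_e / w_i), $$

where $\delta_j \sim \text{Bernoulli}(\pi)$ switches marker $j$ in or out of
the model, $a_j \sim N(0, \sigma^2_a)$ is its effect when in, and $w_i$ is a
per-record residual weight. Station traits use $w_i = 1$. Field traits enter
as deregressed EBV (DEBV) pseudo-phenotypes whose information content varies
strongly between animals; the weight is the standard reliability mapping
$w_i = r_i / (1 - r_i)$, so a record with reliability 0.5 counts as one
own-performance equivalent. The prior inclusion fraction $\pi$ is a fixed
constant of the run (default $0.00025$, i.e. 0.025 % of markers in the model
at each iteration — 177 markers on a 706,791-SNP high-density chip).

### Gibbs sampler

Full conditionals follow the canonical BayesC scheme:

* $\mu$ from its weighted normal conditional under a flat prior;
* each $\delta_j$ from a Bernoulli whose odds multiply the prior odds
  $\pi/(1-\pi)$ by the marginal likelihood ratio with $a_j$ integrated out;
  when $\delta_j = 1$, $a_j$ from its normal conditional;
* $\sigma^2_a$ and $\sigma^2_e$ from scaled-inverse-chi-square conditionals
  (the residual sum of squares is weighted, $\sum_i w_i e_i^2$).

Markers are updated in fixed map order within an iteration and all draws come
from R's RNG, so a seed makes the whole chain bit-reproducible. The inner
loop is compiled (Rcpp) and maintains the weighted residual vector
incrementally, which keeps a 2,000-animal × 10,000-marker chain at roughly
25 ms per iteration on one core.

Default chain length is 100,000 iterations with 20,000 burn-in and no
thinning — the production setting for a full analysis. The package's own
tests and the acceptance script use shorter chains matched to their problem
sizes (e.g. 20,000 iterations at $n = 500$, $m = 2{,}000$ for single-QTL
recovery; 3,000 iterations at $n = 2{,}000$, $m = 10{,}000$ for the
variance-capture check), chosen so each check mixes adequately at desk scale.

### Priors and the preliminary variance estimates

The variance priors need a scale. A full evaluation would take preliminary
$\hat\sigma^2_u$ and $\hat\sigma^2_e$ from a pedigree BLUP run; pedigrees are
out of scope here, so `model_config()` accepts the pair directly (from the
simulator's truth, or a rough phenotypic split when absent) and converts the
genetic variance to a per-effect scale as
$\sigma^2_{a,0} = \hat\sigma^2_u / (\pi \cdot 2\sum_i p_i(1-p_i))$ — the
variance the $\pi n$ included effects need in order to carry
$\hat\sigma^2_u$. Prior degrees of freedom default to 4 (weakly informative);
chains start at the prior means. Both variances can instead be held fixed
(`fix_sigma2_a`, `fix_sigma2_e`), which together with $\pi = 1$ gives the
ridge/SNP-BLUP limit used as a closed-form cross-check in the tests.

### Captured genetic variance

The genetic variance the markers capture is summarised as
$\hat\sigma^2_u = 2 \sum_i p_i (1 - p_i)\, \pi\, \hat\sigma^2_a$. The
$\pi$ factor deserves a note: under the mixture, the marginal effect variance
of a marker is $\pi \sigma^2_a$, and only with it does the sum reproduce the
genetic variance when the included markers carry the signal (without it the
summary would overshoot by orders of magnitude whenever $\pi \ll 1$). The
pure function `captured_variance(p, s2)` computes the plain
$2\sum p(1-p)\,s2$; the fit object supplies $\pi\,\hat\sigma^2_a$ as the
per-marker variance. On simulated $h^2 = 0.4$ data the captured fraction of
the true genetic variance comes out around 0.75–0.95, consistent with the
63–97 % range typical of dense-chip analyses of these traits.

## Evidence scale and thresholds

Marker evidence is the Bayes Factor
$\mathrm{BF}_i = \frac{P_i/(1-P_i)}{\pi/(1-\pi)}$, the posterior odds of
inclusion over the prior odds, with $P_i$ the post-burn-in frequency of
$\delta_i = 1$ (the direct empirical estimate; a Rao-Blackwellised variant
would be a natural extension). Because a finite chain can return $P_i = 1$,
probabilities are capped half a sample from the boundaries,
$P_i \in [1/(2S),\, 1 - 1/(2S)]$ for $S$ kept samples, keeping the evidence
finite and sample-size aware.

Reporting uses $\mathrm{logBF} = 2\ln \mathrm{BF}$, which lives on the same
scale as a likelihood-ratio statistic. Thresholds (all strict):

| class | rule | BF equivalent |
|---|---|---|
| major | logBF > 12 | ≈ 400 |
| qtl | logBF > 8 | ≈ 55 |
| putative | logBF > 6 | ≈ 20 |

## Region calling

A QTL is a region, not a point: the top marker need not be the one closest
to the causal variant, so markers in local LD with the peak are folded in.
The rule implemented: seed a region at each marker above the peak threshold
(processed in decreasing logBF; a lower peak inside an existing region merges
into it); from the peak, grow each direction through a 0.5 Mb sliding
window — while any marker with logBF > 3 lies within 0.5 Mb beyond the
current frontier, the frontier jumps to the outermost such marker; region
bounds are the last markers absorbed.

Two points in this rule are genuinely open to reading and were fixed as
design choices: (i) the window is anchored at the moving frontier (the
outermost qualifying marker so far), not at the peak, which is what lets a
chain of sub-threshold markers extend a region stepwise; and (ii) growth
stops at the boundary of any previously called region, so regions are
disjoint and every super-threshold marker belongs to exactly one region. The
test suite checks the caller against an independently coded brute-force
window simulation on a thousand random tracks.

Putative regions are reported but flagged: their peak markers are included
in well under half of the kept iterations (the per-region maximum $P_i$ is
reported so users can filter on it).

## Cross-trait comparison

Traits measuring the same maternal performance (e.g. milk yield, udder score
and maternal weaning weight for suckling) are compared at the qtl class or
better: same-chromosome regions with a non-empty closed-interval overlap
yield their intersection `[max(starts), min(ends)]` plus both peaks
(`common_regions()`), three-way sharing is counted reference-trait-oriented
(`venn_counts()`), and regions are annotated with overlapping genes or, when
none overlaps, the nearest gene with its gap in Mb (`annotate_genes()`).
A shared boundary SNP counts as overlap — regions are sets of SNP positions,
and a shared SNP is shared evidence. Interval work is delegated to
GenomicRanges. The package bundles the reported major-QTL, common-region and
candidate-gene tables for the six cattle maternal traits as reference
fixtures; the interval operations reproduce the reported chr6 suckling
intersection and peak distances from them exactly.

## The synthetic population

`simulate_genotypes()` emulates the features of a progeny-test half-sib
population that matter to the sampler:

* **Block LD** by copy-with-mutation: each LD block (default 20 markers) has
  a pool of 10 founder haplotype segments; a population haplotype copies one
  founder per block and resamples each site with probability 0.03 from its
  allele frequency (which preserves the per-site marginals while the shared
  founders create within-block correlation). Setting `ld_block_len = 1`
  collapses adjacent-marker r² to the background level.
* **Half-sib structure**: each animal's paternal haplotype is assembled
  per-block from the two haplotypes of one of `n_sires` sires (default 78,
  the progeny-test scale); the maternal haplotype is drawn fresh.
* **Traits** as $y = \mu + Z_{qtl} a + u_{poly} + e$ with each component
  rescaled to its exact target sample variance, so realized $h^2$ tracks the
  configuration (defaults: $h^2 = 0.4$ within the 0.04–0.48 span of these
  traits; 10 QTL carrying 60 % of the genetic variance over a polygenic
  background — a "few medium/large QTL plus background" architecture; the
  effect-size distribution is configurable rather than asserted, since it is
  unknown for the real traits).
* **DEBV pseudo-phenotypes** as truth plus noise with variance
  $\sigma^2_u (1-r)/r$, reliabilities uniform in \[0.05, 0.33\] (the span
  observed in field evaluations of these traits), weights $r/(1-r)$.

What the generator does *not* emulate: genuine recombination maps and
coalescent LD decay, selection, multi-breed structure, non-additive effects,
and the pedigree dependence between DEBV of relatives. Passing tests
therefore demonstrate that the machinery is correct and well calibrated
under the assumed model, not that the model is adequate for any particular
real dataset.

## Quality control

Marker editing mirrors standard chip QC: keep markers with call rate
*strictly* above 0.90 (a marker called in exactly 90 % of animals is
removed), then keep markers whose 1-df chi-square Hardy-Weinberg test (on
non-missing calls, after the call-rate filter) has p *strictly* above
10⁻⁴. The chi-square form is used rather than the exact test — standard at
these sample sizes; monomorphic markers return p = 1. Both filters are
idempotent and the order is fixed and logged. Remaining missing calls are
mean-imputed per marker (continuous dosage) before model fitting; genotypes
are used in the raw −1/0/1 coding, not centred.

## Numerical and degenerate-input choices

* Empirical $P_i$ capping as above; $\pi = 1$ has no prior odds, so BF/logBF
  are reported as `NA` in the ridge limit.
* `log_bf(0)` returns `-Inf` rather than erroring.
* Zero-variance phenotypes, non-positive weights, fully missing markers and
  $h^2 = 1$ (no residual variance) are rejected with informative errors.
* Scaling all weights and the residual prior scale by the same factor leaves
  the posterior of $(\mu, a, \delta)$ unchanged — checked bit-for-bit in the
  tests.
* Positions are 1-based bp internally; Mb values in reports use 6 decimals;
  BED export converts to 0-based half-open at the boundary.

## Limitations

* $\pi$ is fixed, not estimated (BayesCπ is out of scope), and the evidence
  scale is sensitive to it.
* No polygenic pedigree component: with strong family structure and very
  unevenly weighted DEBV, large sire families can dominate detections.
* Region calling has no FDR control; the BF thresholds are conventional, and
  comparisons across traits are the main guard against false positives.
* The DEBV derivation itself (deregression) is consumed, not implemented.
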