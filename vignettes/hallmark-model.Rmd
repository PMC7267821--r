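---
title: "A hallmark-driven model of cancer clonal evolution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A hallmark-driven model of cancer clonal evolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hallmarksim)
```

## Why model genes through hallmarks?

Most branching-process models of tumor evolution work with abstract
fitness effects: a mutation changes a birth or death rate by some amount,
and the identity of the mutated gene is lost. That makes it hard to ask
gene-level questions — what would happen to this tumor's metastatic burden
if TP53 function were restored? hallmarksim instead routes every gene's
mutational state through the hallmarks of cancer. A gene can contribute to
several hallmarks and a hallmark can draw on several genes (TP53, for
instance, is classically tied to both apoptosis and growth control), so
the mapping is a weighted many-to-many bipartite graph, and those weights
are the quantities inference targets.

## The model

### State

The simulator tracks *clones*: groups of cells sharing a genotype, which
is a binary vector `x` over the gene panel (`x[g] = 1` once gene `g`'s
tumor-related function is impaired). Each clone records its cell count,
its compartment (primary or metastatic), a lineage division counter, its
parent clone, and the order in which its lineage's genes were first hit.

### Hallmarks

Five hallmark variables are weighted sums of the indicators,

$$H_h = \sum_g w_{g,h}\, x_g, \qquad h \in \{H_a, H_d, H_i, H_b, H_{im}\},$$

covering apoptosis evasion ($H_a$), division drive ($H_d$),
immortalization ($H_i$), angiogenesis ($H_b$) and invasion/metastasis
($H_{im}$). The classical six hallmarks collapse to five variables here
because self-sufficiency in growth signals and insensitivity to
anti-growth signals act on the same division trial; a single $H_d$ carries
both. Weight columns with any mass are normalized to sum to one, so every
hallmark lies in $[0, 1]$ and can offset a probability directly; the
all-mutated genotype saturates each weighted hallmark at 1. Whether the
original formulation constrains weights to the simplex or merely to
non-negative values is not decidable from the information we build on;
normalization was chosen because it makes the interference algebra closed
under clamping and gives the ABC prior a natural support (see below).

### Fate trials

Each time step, every cell passes through Bernoulli trials in a fixed
order: apoptosis → environmental death → replicative-limit check →
division → invasion. The apoptosis probability is
$\mathrm{clamp}(a_0 - H_a, 0, 1)$ — the hallmark interferes subtractively
with the base rate. The remaining interference forms follow the same
pattern and are deliberately isolated in `trial_probabilities()` so they
can be swapped in one place:

* environmental death: constant $k_0$ (not hallmark-modified);
* immortalization: once a lineage has divided `c_max` times, each cell
  survives the senescence check with probability $H_i$ — a Hayflick-style
  limit that immortalization disarms ($H_i = 1$ makes the limit inert,
  $H_i = 0$ kills every cell at the limit, so no lineage ever exceeds
  `c_max` divisions);
* division: $\mathrm{clamp}((d_0 + H_d)(1 - E' N_{prim}), 0, 1)$ for
  primary cells, with $E' = E_0 / (1 + F H_b)$ — logistic friction whose
  carrying capacity the angiogenesis hallmark stretches; metastatic cells
  divide at $\mathrm{clamp}(d_0 + H_d, 0, 1)$ with no friction;
* invasion: primary survivors convert to the metastatic compartment with
  probability $H_{im}$.

All trials are executed as aggregated binomial draws per clone, which is
distributionally identical to per-cell Bernoulli trials and keeps runs
with $10^5$–$10^6$ cells fast. The division counter is tracked per clone
(the lineage maximum, incremented whenever the clone divides); this is the
conservative choice — the limit binds as early as it possibly could for
any cell of the clone.

### Mutation and clone bookkeeping

A division replaces one cell by two daughters. Each daughter acquires a
new hit in each still-intact gene with probability $m_0 L_g / \bar L$
(CDS-length weighted when lengths are given, uniform otherwise). Daughters
sharing a new genotype found a single new clone; unmutated daughters stay
with the parent. Mutational state is binary per gene — one hit impairs
function regardless of the oncogene/suppressor annotation, which is
carried but inert; distinguishing one-hit from two-hit dynamics is a
natural extension slot. Clones with equal genotypes but different parents
stay distinct, so clone counts and the order-of-dysfunction readout are
lineage-true.

A run stops at `t_max` steps, on extinction, or at a hard cap `N_cap`
(default $10^6$ cells) that guards against unbounded exponential phases.
All randomness flows through one global seeded stream and clones are
processed in id order, so a seed plus a configuration reproduces a run
bit-for-bit.

## VAFs as summary statistics

The forward map from a population to data is deliberately minimal: under
the heterozygous-diploid convention, gene `g`'s variant allele frequency
is mutated cells over `ploidy ×` total cells, so a clonal mutation sits at
0.5. No purity or copy-number distortion is modeled; an optional binomial
read-sampling layer (`depth`) can add counting noise but is off by
default. Pooled (primary + metastatic) VAFs are the default ABC summary —
the analogue of bulk sequencing of the whole tumor mass; per-compartment
VAFs are exposed for experimentation.

## Calibration by rejection ABC

`abc_rejection()` draws weight matrices from a prior that is flat
(symmetric Dirichlet, concentration 1) on each hallmark's
participating-gene simplex, with the participation mask taken from the
nonzero pattern of the supplied weight table. Each draw is pushed through
the forward simulator (optionally averaging VAFs over a few replicate
seeds), scored by the Euclidean distance between simulated and observed
VAF vectors, and accepted under a quantile or absolute tolerance.
Proposals whose simulations go extinct score infinite distance: an
observed tumor implies survival, so extinction is treated as prior
incompatibility rather than data. The MAP estimate is the mode of a
per-parameter kernel-density estimate over accepted draws (a product
approximation — desk-scale acceptance counts are too small for stable
multivariate KDE), projected back onto the simplex; below 20 accepted
draws the minimum-distance draw is returned and flagged.

The sampler itself (`rejection_sampler()`) is model-agnostic, and the test
suite exploits that: with the forward model swapped for a single binomial
draw under a uniform prior, the ABC posterior must approach the analytic
Beta posterior, which pins down the acceptance logic independently of the
simulator.

Nullification experiments (`nullification_battery()`) rerun the simulator
with one gene's weights zeroed — without renormalizing the remaining
weights, since the experiment measures the removal of exactly that gene's
contribution while the others keep their calibrated values. Per-run seeds
are derived once from the master seed and shared across conditions, which
makes the battery deterministic and lets a zero-weight knockout reproduce
its baseline bit-for-bit — a built-in negative control.

## Default parameters and problem sizes

The package defaults (`sim_params()`) describe a mildly sub-critical
unmutated epithelium: $a_0 = 0.2$, $d_0 = 0.3$, $k_0 = 0.05$,
$E_0 = 10^{-4}$ (carrying capacity $10^4$ cells for an unaided clone),
$F = 10$, $c_{max} = 50$, $m_0 = 5\times 10^{-4}$ per gene per daughter,
$N_0 = 1000$. Per step the unmutated growth factor is
$(1-a_0)(1-k_0)(1+d_0(1-E_0 N)) \approx 0.96$ at $N_0$ — the population
drifts downward until a driver hit pushes some hallmark up, which is the
regime in which selection on driver mutations is visible. The bundled
four-gene colorectal-style scenario (`scenario_spec()`) scales this to
desk size ($N_0 = 500$, 50 steps, cap $5\times10^4$) and gives APC/TP53
apoptosis weight and KRAS/PIK3CA division/invasion weight, with TP53
deliberately on two hallmarks; the weights are illustrative, not
biological estimates.

The ABC recovery experiments in the tests and the acceptance script use a
further scaled configuration ($N_0 = 200$, 30 steps, cap 5000, $m_0 =
2\times10^{-3}$, 1500–2000 proposals, 10 % tolerance quantile) with two
free hallmarks over disjoint gene pairs (APC/TP53 on apoptosis,
KRAS/PIK3CA on invasion). The pairs are disjoint on purpose: with a
single pooled-VAF vector as data, allocating one gene's selective
advantage between two growth-side hallmarks is not identifiable, whereas
dominance *within* a hallmark leaves a clear VAF signature (apoptosis
dominance sweeps the primary tumor; invasion dominance inflates the
metastatic share of the pooled mass). Observed vectors are averaged over
three truth-seeded runs to temper simulator noise.

## What the synthetic data does and does not emulate

The generator reproduces the mechanistic skeleton — stochastic clonal
expansion under hallmark-mediated selection, a friction-free metastatic
compartment, driver accumulation, and the cell-fraction → VAF map. It does
not emulate sequencing depth or purity noise (unless `depth` is set),
copy-number change, spatial structure, or neutral passenger mutations, so
passing the recovery tests shows the inference machinery is sound at the
stated scale — not that real tumor VAFs identify real hallmark weights.
Calibration against patient data would additionally face the forward
model's idealizations.

## Numerical and design notes

* All interference results are clamped to $[0,1]$ after the algebra;
  user-supplied weights can otherwise push $a_0 - H_a$ negative.
* Mutant daughters are sampled exactly: the number of mutated daughters is
  binomial in $1 - \prod_g (1 - m_g)$, and each mutant's hit pattern is
  drawn from the independent-Bernoulli law conditioned on at least one
  hit, via sequential suffix products — no rejection loops at small
  $m_0$.
* Invasion is drawn over a clone's post-death survivors and capped by the
  cells remaining after division bookkeeping; invading cells join (or
  found) a metastatic clone keyed by genotype and source clone, so
  repeated invasion from the same clone accumulates rather than
  fragmenting.
* Quantile tolerances are computed over finite (non-extinct) distances
  with R's default type-7 quantile.
* Hallmark values are cached per genotype bitstring for the duration of a
  run; the cache is exact (a dot product), so no refresh policy is
  needed.
* Empty compartments raise an explicit error from `compute_vaf()`
  (`vaf_table()` maps them to `NA`) rather than silently returning 0.

## Known limitations

Binary one-hit genotypes; no back-mutation; the division counter is
clone-level, so the replicative limit is conservative; metastatic cells
form one well-mixed compartment with no further seeding structure;
rejection ABC only (no SMC or regression adjustment) — posterior quality
therefore degrades quickly as the number of free weights grows beyond a
handful.
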