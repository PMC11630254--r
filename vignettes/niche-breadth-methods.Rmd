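---
title: "pH niche breadth, activity and diversification: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{pH niche breadth, activity and diversification: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

phniche is an analysis pipeline for pH niche specialization in soil
ammonia-oxidizing archaea (AOA). Its units of analysis are *amoA*
phylotypes — marker-gene clusters at a fixed identity threshold — observed
across soils spanning a wide pH gradient, followed through pH-shift
incubations, and placed on a phylogeny. This vignette explains the models
the package implements, the assumptions behind them, the tunable
parameters, what the synthetic-data generators do and do not emulate, and
the numerical choices made where the design was genuinely open.

## 1. The niche-breadth index and the specialist/generalist split

Niche breadth is computed on hydrogen-ion concentrations,
$[\mathrm{H^+}] = 10^{-\mathrm{pH}}$, not on pH itself: pH is a logarithmic
trait, and a fixed pH interval corresponds to vastly different proton
concentration intervals at either end of the gradient. For phylotype $j$
present in $n_j$ soils, with mean $\mu_j$ and variance $\sigma_j^2$ of the
occupied soils' $[\mathrm{H^+}]$,

$$B_j = \frac{1}{\sqrt{n_j}} \cdot \frac{\sigma_j^2}{\mu_j^2}.$$

Small $B$ means a narrow pH niche (specialist), large $B$ a wide one
(generalist). The $1/\sqrt{n_j}$ factor keeps the index homogeneously
distributed across the occupancy/abundance gradient, which neither the raw
standard deviation nor the standard error achieves;
`nb_index_diagnostics()` tabulates all three candidates against the
abundance rank so this choice can be inspected rather than trusted.

Classification decisions, and why:

* **Moments are unweighted** over occupied samples, with the $n-1$
  variance denominator. The index defines $n_j$ as a sample count and
  nothing in its definition weights by abundance; an abundance-weighted
  variant (frequency weights) is available behind `weighted = TRUE` for
  sensitivity analysis.
* **The cut-off is the median** of the defined $B$ values: at or below the
  median is a specialist, above it a generalist. Ties go to the specialist
  side by default (`tie = "le"`); with ties at the cut-off this produces
  the slightly asymmetric splits seen in real data. `tie = "lt"` flips the
  convention.
* **Single-soil phylotypes are putative specialists**: their $B$ is
  undefined ($n_j = 1$), they are reported as their own class, and the
  evolutionary analyses treat them as specialists.
* **Presence** is any abundance strictly above 0 by default; a threshold
  is configurable. Range classes are occupancy-based: up to 3 soils is
  endemic, more is cosmopolitan (`endemic_max` configurable).
* pH converts to mol L$^{-1}$ with no activity-coefficient correction.

## 2. Absolute abundance, activity and dormancy

Amplicon relative abundances are scaled to absolute cell abundances with
per-sample qPCR totals of *amoA* copies g$^{-1}$ soil
(`to_cell_abundance()`), so that within-sample composition and
between-sample totals come from the two assays that measure them best.

Activity over a 30-day incubation is defined per phylotype as:

* **growth** (DNA): abundance at the final minus the initial time point;
* **transcriptional activity** (RNA): the sum over successive-interval
  differentials (days 0–1, 1–3, 3–10, 10–30);
* **DNA replication** (SIP analogue): the end-point abundance of the
  isotopically labeled, replicating subset.

Negative differentials are reported as null: a decline is loss, not
activity. Because the truncation is nonlinear, replicates are averaged
*after* activity computation, not before (configurable by the caller
simply by averaging inputs first). Per-phenotype sums conserve the input
total exactly. How per-interval RNA activity should be aggregated is a
genuinely open choice; summation was chosen and the per-interval table is
also returned.

The combined dormancy + death fraction is $1 - \text{active}/\text{resident}$,
clipped to $[0, 1]$; with noisy qPCR the active estimate can exceed the
resident one, which is clipped to 0 with a machine-greppable warning
(`AC01`). Shannon diversity uses natural logs and no rarefaction.
Bray–Curtis distances use the classical formula.

Group comparisons are assumption-gated: Shapiro–Wilk normality per group
and Bartlett homogeneity across groups, each at $\alpha = 0.05$ (the gate
tests are fixed by the protocol; the level is this package's default);
both pass → Welch two-sample *t*-test, otherwise Kruskal–Wallis. Welch's
test does not itself assume equal variances — the Bartlett gate is
retained as part of the protocol and the report records all gate
p-values. Under Gaussian equal-variance
inputs the Welch branch is selected at close to the $(0.95)^3$ rate
implied by three independent 5% gates, which the tests verify.

The "extreme range" grouping of soils uses pH ≤ 5.0 or ≥ 8.5
(configurable), where the costs of generalism are expected to bind.

## 3. Community phylogenetics

The phylogenetic relatedness of each soil's community is the
abundance-weighted mean pairwise patristic distance
$$\mathrm{mpd} = \sum_{i \ne j} w_i w_j d_{ij} \Big/ \sum_{i \ne j} w_i w_j$$
over present taxa. Significance uses the **richness** null: each of the
999 null communities draws the observed number of taxa uniformly without
replacement from the pool (all tree tips) and reassigns the observed
abundance multiset to them in random order — richness and the abundance
distribution are preserved, only identity is randomized. The richness
algorithm by itself does not dictate how abundances are handled;
reassigning the observed multiset is the convention adopted here. The standardized effect size is
$(\mathrm{mpd}_{obs} - \bar{\mathrm{mpd}}_{null})/\mathrm{sd}_{null}$;
negative values mean the community is more closely related than chance.
The two-sided p-value is the rank of the observed value among the nulls
with the $+1$ correction, $p = 2\min(r, n+1-r)/(n+1)$. A community equal
to the whole pool makes every null identical; this degenerate case errors
rather than returning a meaningless ses. Taxa absent from the tree are
dropped with a warning (`CP01`).

Phylogenetic signal of generalism uses Blomberg's K: the observed
MSE$_0$/MSE ratio (trait error around the phylogenetically corrected mean
over the GLS error under the tree variance–covariance matrix) divided by
its Brownian-motion expectation computed *exactly* from the VCV, not by
simulation. K = 1 matches BM; K ≪ 1 means less signal than BM. The
permutation p-value shuffles tip labels and uses the same variance ratio,
one-sided. K is invariant to affine trait transforms, polytomies are
acceptable (the VCV is well-defined), and a zero-variance trait errors.

The ses.mpd–pH relationship is ordinary least-squares simple regression
(`ses_mpd_vs_ph()`); richer linear models are left to standard R
modeling, as is ordination.

## 4. State-dependent diversification

The evolutionary analysis asks whether pH specialization and geographic
range shape speciation ($\lambda$), extinction ($\mu$) and trait
transition ($q$) rates over the AOA phylogeny. Each phylotype gets a joint
state from {pH specialist, pH generalist} × {endemic, cosmopolitan}: ES,
CS, EG, CG (putative specialists count as specialists).

### The likelihood

Along each branch the standard state-dependent speciation–extinction
(SSE) equations are integrated backward in time for extinction
probabilities $E_i(t)$ and partial likelihood densities $D_i(t)$:

$$\frac{dE_i}{dt} = \mu_i - (\lambda_i + \mu_i + \textstyle\sum_j q_{ij}) E_i
  + \lambda_i E_i^2 + \textstyle\sum_j q_{ij} E_j$$
$$\frac{dD_i}{dt} = -(\lambda_i + \mu_i + \textstyle\sum_j q_{ij}) D_i
  + 2 \lambda_i E_i D_i + \textstyle\sum_j q_{ij} D_j$$

Tips start at $D_i = \rho_i$ for compatible states and $E_i = 1 - \rho_i$
($\rho$ = per-state sampling fraction, default 1); nodes multiply daughter
$D$ vectors and the state's $\lambda_i$; the root uses weights
proportional to $D$ (the standard observation-weighting) and, by default,
conditions on the survival of both crown lineages. Both root choices are
flags. Ambiguous tip states are comma-joined sets, `NA` is fully unknown.

Numerics: an adaptive Dormand–Prince 5(4) integrator (absolute/relative
tolerances $10^{-12}$/$10^{-9}$) in compiled code; per-branch rescaling of
$D$ with a log accumulator prevents underflow; halving the tolerances
moves the log-likelihood by far less than $10^{-4}$ on the test fixtures.
Degenerate special case: when *every* $\lambda_i = 0$ the node speciation
factors and survival conditioning are dropped, and the computation
becomes the plain continuous-time Markov (Mk) character likelihood — this
limit anchors the engine to a matrix-exponential oracle in the tests, and
the state-independent case factorizes exactly into (Mk character
likelihood) + (constant-rate birth–death tree likelihood), a second
analytic anchor.

### The 18-model set

Six transition structures are crossed with three diversification modes.
The structures encode which of the single moves (pH state S↔G, range
state E↔C) and dual moves (ES↔CG, CS↔EG — both traits at once) are
allowed and which rates are shared:

| structure | pH rates | range rates | dual moves | q parameters |
|---|---|---|---|---|
| M1 | one symmetric | one symmetric | no | 2 |
| M2 | one symmetric | one symmetric | yes (shared) | 3 |
| M3 | asymmetric | one symmetric | no | 3 |
| M4 | one symmetric | asymmetric | no | 3 |
| M5 | asymmetric | asymmetric | no | 4 |
| M6 | asymmetric | asymmetric | yes | 5 |

The exact supplementary definitions of the original six models were not
available when this reconstruction was fixed; the table above is the
package's documented convention, `build_structure()` is a plain
configuration function, and a `dual_rate_shared = FALSE` flag splits the
dual rates by pH direction, so alternative definitions drop in without
code changes.

Diversification modes: **ETD** (examined-trait-dependent; $\lambda, \mu$
per joint state: 8 diversification parameters), **CTD**
(concealed-trait-dependent; two hidden rate classes A/B with $\lambda,
\mu$ depending only on the hidden state, examined transitions mirrored
across layers, and one shared hidden-switch rate — the standard
hidden-state control for rate heterogeneity unlinked to the focal trait),
and **CR** (constant rate; one $\lambda$, one $\mu$). 6 × 3 = 18 models;
free-parameter counts are ETD 8+q, CTD 5+q, CR 2+q.

### Fitting, model choice, ancestral states

Each model is maximized over log-parameters bounded in
$[10^{-8}, 10^3]$ from three starts — one heuristic central start (a
Yule-scaled $\lambda$, $\mu = \lambda/10$, $q = \lambda/5$) and the rest
from a seeded Latin hypercube over a log-box two orders of magnitude
around it — using Nelder–Mead with a $10^{-8}$ relative tolerance on the
log-likelihood. All starts are recorded. Models are ranked by
$\mathrm{AIC} = 2k - 2\ln L$, ties broken toward fewer parameters, and
`compare_aic()` refuses to rank fits made on different data. The headline
quantity is the transition asymmetry $q_{G \to S}/q_{S \to G}$ of the
best asymmetric structure.

Marginal ancestral states restrict the node's partial likelihood vector
to one examined state (all hidden layers kept), re-propagate it to the
root along stored sibling vectors, and normalize the resulting root
likelihoods; flat root weights are used at this step so the marginal is
linear in the restricted vector. This is one of several valid SSE
reconstruction conventions and is documented as such. Hidden states are
marginalized. Polytomies are rejected (the empirical tree is a resolved
ML tree); zero-length branches are permitted.

### Simulation

`simulate_sse()` runs a forward Gillespie birth–death process from two
crown lineages with state-change events at the $q$ rates. It stops at the
moment the target richness is first reached plus one further waiting time
drawn at that richness — for the pure-birth single-state case this makes
the expected crown depth exactly $\sum_{k=2}^{n} 1/(\lambda k)$, the
anchor used in the tests. Extinct lineages are pruned; everything is
seed-reproducible.

## 5. What the synthetic data emulate — and what they do not

The gradient generator reproduces the survey's design: 47 soils spanning
pH 3.48–8.74, 425 phylotypes with Gaussian niche response curves on the
pH axis (so narrow/broad is interpretable in pH units; an
$[\mathrm{H^+}]$-scale variant probes the index's scale sensitivity), a
bimodal narrow/broad breadth mixture (0.35 vs 1.5 pH units, 50/50),
lognormal carrying abundances (log-mean $\ln 20$, log-sd 2.5), lognormal
environmental noise, Poisson count sampling, and lognormal per-soil qPCR
totals. The truth table (optimum, breadth, component, carrying abundance)
accompanies every dataset so recovery is testable end-to-end.

The incubation generator encodes the designed phenotype ranking as its
stated world: specialists outgrow generalists after the acid shift to pH
4.5 (the extreme condition), generalists win at native pH 6.0 and after
the alkaline shift; a condition-dependent dormant fraction (0.4 native,
0.6 perturbed — inside the observed 32–67% range) is inert while the
active fraction grows exponentially; DNA, RNA (noisier, as in the real
assays) and SIP analogues are emitted per replicate. Note that the
*measured* day-30 dormancy falls below the designed initial inert
fraction whenever net growth is strong, because growth dilutes the inert
pool — the two coincide exactly only at zero net growth, which is what
the exactness tests use.

Not emulated, hence not established by green tests: finite sequencing
depth and uneven soil spacing (the real survey's large single-soil
putative-specialist fraction — 58% of phylotypes — arises mostly from
these, while the density-based generator produces only a small one);
compositional coupling between taxa; PCR/chimera artifacts; qPCR
efficiency bias; any correlation between niche breadth and phylogeny (the
synthetic tree is independent of the synthetic traits, so community tests
are calibrated under the null rather than reproducing the empirical
clustering); and real replicate covariance structure.

## 6. Known limitations

* The empirical headline numbers (91/87/247 classification split,
  K = 0.1 with p = .054, the six-fold transition asymmetry on the 370-tip
  tree) require the original survey matrix and phylogeny, which are
  external data; the pipeline applies to them directly once supplied, and
  nothing in the package asserts them from synthetic data.
* ETD/CTD fits on small trees (a few hundred tips) are weakly identified;
  `fit_model()` warns when the parameter count is large for the tip
  count. Ratios of small transition rates are noisy — recovery tests
  therefore check order-of-magnitude behavior, not point estimates.
* The SSE engine covers anagenetic state change only (no cladogenetic
  change, no time-varying rates, at most 2 hidden states), and fits by
  maximum likelihood, not MCMC.
* ses.mpd supports the richness null only; alternative nulls
  (independent-swap, label shuffle) and mntd-type metrics are out of
  scope.
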