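# phniche

Soil ammonia-oxidizing archaea (AOA, Thaumarchaeota) drive nitrification
across nearly the full soil pH range, and individual *amoA* phylotypes
differ sharply in how much of that range they tolerate. **phniche** is an
analysis pipeline for asking, in both ecological and evolutionary time,
whether pH *specialists* (narrow niche) or *generalists* (wide niche) win:
who dominates where along a pH gradient, who grows after an abrupt pH
shift, whether specialism is phylogenetically conserved, and whether
lineages gain or lose specialism faster over evolutionary history. It is
written for microbial ecologists working with phylotype abundance tables,
qPCR totals and marker-gene phylogenies.

## What it computes

**Niche breadth.** Each phylotype's pH niche breadth is a modified Levins
index on hydrogen-ion concentrations ([H⁺] = 10^−pH) over the n_j soils
it occupies:

    B_j = (1 / sqrt(n_j)) * sigma_j^2 / mu_j^2

Specialist vs generalist is a median split of B; single-soil phylotypes
are *putative specialists*; ≤ 3 occupied soils is *endemic*, more is
*cosmopolitan*.

**Activity and dormancy.** Relative abundances × qPCR totals give
absolute abundances; growth (DNA), transcriptional activity (RNA) and DNA
replication (SIP) are truncated temporal differentials (negative → 0);
per-phenotype sums conserve totals; dormancy+death is the clipped
complement of active/resident; Shannon and Bray–Curtis come with no
rarefaction; two-group comparisons use the Shapiro–Wilk/Bartlett-gated
Welch-or-Kruskal–Wallis rule.

**Community phylogenetics.** Abundance-weighted mean pairwise distance
per soil, standardized against 999 "richness" nulls (ses.mpd), regressed
on pH; Blomberg's K with a permutation test for phylogenetic signal of
generalism.

**Diversification.** A four-state (specialist/generalist ×
endemic/cosmopolitan) state-dependent speciation–extinction engine with
an adaptive Dormand–Prince integrator in compiled code: 6 transition
structures × {trait-dependent, hidden-state, constant-rate} = 18 models,
fitted by 3-start maximum likelihood, ranked by AIC, yielding the
generalist→specialist vs reverse transition-rate ratio and marginal
ancestral states. A forward Gillespie simulator generates labeled
ultrametric trees for recovery testing.

Every input has a seeded synthetic generator (47-soil pH gradient,
pH-shift incubation series, birth–death trees with Markov state change),
so the full pipeline is testable offline; generators emit truth tables
for end-to-end recovery checks.

## Worked example

```r
library(phniche)

# the index on two soils at pH 5 and 7
niche_breadth_index(c(1, 1), ph_to_hplus(c(5, 7)))
#> [1] 1.35876

# classify a synthetic 47-soil survey
grad <- gen_soil_gradient(gradient_scenario(), seed = 1)
cls  <- classify_niche_breadth(grad$counts, grad$meta)
table(cls$nb_class)
#> specialist  generalist  putative_specialist
#>        198         198                   12

# who grows after an acid shift to pH 4.5?
inc <- gen_incubation(incubation_scenario(), cls, seed = 2)
m   <- inc$dna$pH4.5[[1]]
phenotype_sums(growth(m[, 1], m[, ncol(m)]), cls)["specialist"] # 2.7e8
```

The B value of 1.35876 says the pH 5/7 pair spans a wide [H⁺] spread
relative to its mean — a generalist-like breadth. In the synthetic
survey the median-B split classifies the defined phylotypes into equal
halves by construction (198/198), with 12 single-soil putative
specialists; after the simulated acid shift, summed specialist growth
(2.7 × 10⁸ copies g⁻¹) exceeds generalist growth by two orders of
magnitude, the designed extreme-pH advantage.

## Analysis workflow

Numbered drivers under `analysis/` run the full study shape and write
tables under `results/`:

| script | does | key outputs |
|---|---|---|
| `01_simulate.R` | synthetic gradient, incubations, phylogeny | `results/sim/*` |
| `02_classify.R` | B index, median split, range classes, index diagnostics | `classification.tsv` |
| `03_activity.R` | growth/RNA/SIP sums per phenotype, dormancy, diversity | `phenotype_activity.tsv`, `dormancy.tsv` |
| `04_community_phylo.R` | ses.mpd per soil, ses.mpd~pH, Blomberg's K | `ses_mpd.tsv`, `phylosignal.tsv` |
| `05_diversification.R` | 18-model SSE fit, AIC ranking, asymmetry, ancestral states | `model_comparison.tsv`, `transition_asymmetry.tsv` |

Stage 5 takes some minutes (hidden-state fits dominate). On the default
200-tip synthetic clade the constant-rate symmetric model wins by AIC —
a deliberately honest illustration that clades of this size are weakly
informative about transition asymmetry; the package's recovery tests show
the designed six-fold asymmetry is recovered at 300 tips.

## Acceptance script

`scripts/acceptance.R` re-runs the pipeline's main computation from
scratch against the installed package — gradient classification,
incubation activity sums, ses.mpd and phylogenetic signal, and an
asymmetric-vs-symmetric SSE model comparison on a simulated labeled tree
— and writes a JSON report:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
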