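---
title: "Simulating genomic-selection breeding programs with gene-bank bridging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating genomic-selection breeding programs with gene-bank bridging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`gsbridge` is a forward-in-time stochastic simulator of doubled-haploid (DH)
breeding programs under genomic selection (GS). It compares *closed* elite
programs, where the same germplasm is recycled indefinitely, with *open*
programs that introduce gene-bank donors through a *bridging* component:
donor x elite crosses whose progeny are preselected before entering the
elite population. This vignette is the package's methods account: the model,
its assumptions, the tunable parameters, and the design decisions taken
where the problem was genuinely open.

## Genetic model

**Lines and genomes.** Every individual is a fully homozygous inbred or DH
line, stored as a single binary haplotype over a marker panel; the genotype
dosage at a marker is twice the haplotype allele, so dosages live in
{0, 2}. The genome is 10 chromosomes of 160 cM by default (a maize-like
map), with markers uniformly spaced.

**Meiosis.** A DH line is one gamete of the virtual F1 between two inbred
parents, doubled. Per chromosome the crossover count is Poisson(length in
Morgans) with positions i.i.d. uniform and alternating parental origin from
a fair coin — no interference, hence Haldane's map function
`r(d) = (1 - exp(-2d))/2` links map distance to recombination. A Poisson
draw of zero is allowed (no obligate chiasma): this is the literal reading
of a Poisson crossover process.

**Trait.** One quantitative trait controlled by `n_qtl = 1000` additive
QTLs sampled among the markers with a minimal spacing of 0.2 cM between
consecutive QTLs, effects i.i.d. Normal(0, 0.05). True breeding value (TBV)
is the dosage-weighted effect sum. A disjoint set of `n_neutral = 2000`
markers is used both as the GS genotyping panel and for diversity
monitoring; QTL genotypes are never visible to selection. Spacing is
enforced by rejection sampling of whole QTL sets (1,000 retries) with a
greedy left-to-right fallback — exact uniformity over admissible sets is
not required by the model, only the spacing constraint. No dominance,
epistasis or mutation.

**Phenotypes.** The error variance is calibrated once on the founders so the
trait shows heritability 0.7 there: `Ve = Vg (1 - h2) / h2`. The default
0.7 corresponds to the mean of a single-replicate trial in 4 environments
with single-trial repeatability 0.37 (`0.37 / (0.37 + 0.63/4) = 0.70`); the
multi-environment structure is collapsed into one Gaussian deviate per line.
`Ve` is then fixed forever, so realized heritability erodes as selection
consumes genetic variance — a deliberate property, verified by a test.
Every line is phenotyped exactly once, at creation.

## Genomic prediction

GBLUP with a *fixed* error variance ("direct" fit, no REML): dosages are
centred at training means, the genomic relationship matrix is
VanRaden-scaled `G = WW'/c` with `c = 2 * sum(p(1-p))` recomputed from the
training set at every refit, and the shrinkage is
`lambda = (1 - h2_model)/h2_model` with `h2_model = 0.7`. Marker effects are
recovered by backsolving, which is algebraically identical to ridge
regression on centred markers with penalty `c * lambda`; the implementation
solves in whichever of marker or individual space is smaller and a test
pins the equivalence at 1e-8. Models are refitted every generation on the
phenotyped progeny of generations T-3, T-4 and T-5 (the production lag of a
DH cohort), restricted to one component (elite- or bridging-specific) or
pooled ("joint").

## Cross selection

For a cross j x k, the predicted genetic standard deviation of its DH
progeny uses estimated marker effects and map-based linkage:

    sigma2_jk = sum_lm beta_l beta_m s_l s_m (1 - 2 r_lm),

with `s_m = (a_jm - a_km)/2` in {-1, 0, 1} and `r_lm` Haldane within a
chromosome, 0.5 across. Because `1 - 2r` is multiplicative along a
chromosome under Haldane, the double sum is evaluated in O(m) with
cumulative products; a test proves equality with exhaustive enumeration of
all DH origin patterns to 1e-10. The usefulness criterion of a cross is

    UC_jk = (GEBV_j + GEBV_k)/2 + i * h * sigma_jk,

with selection intensity `i = 2.06` (top 5% of a standard normal) and
accuracy `h = 1`.

**Diversity constraint.** Neutral Nei diversity is
`He = mean 2p(1-p)` over the neutral panel. Optimal cross selection (OCS)
maximizes the plan's mean score subject to the *expected* next-generation
He staying at or above a target trajectory: either constant at the burn-in
level or declining linearly (default 0.5% of the burn-in He per generation;
the decline slope is a free parameter of the method and other values are
one `scheme_config()` argument away). Expected frequencies after a plan are
progeny-weighted midparent frequencies. The UCPC variant scores crosses by
UC and additionally shifts each cross's expected frequency contribution by
the first-order truncation-selection regression
`i * h * cov(dosage_m, GEBV)/(2 sigma_jk)` — an explicit approximation of
within-cross selection; the covariance uses the same O(m) recursion and is
tested against exact enumeration.

**Optimizer.** Plan selection is simulated annealing over cross lists:
a move swaps one cross for a random candidate pair, a specific unordered
pair may appear at most once per plan while parents may repeat, geometric
cooling over a fixed iteration budget (20,000 by default; scaled runs use
5,000-8,000). Constraint handling is penalty-based until a feasible plan is
visited, then projection (moves violating the target are rejected). If no
feasible plan is found the maximal-He plan is returned with an infeasibility
flag — the engine logs it rather than halting. On every instance small
enough to enumerate (6 parents, up to 3 crosses) the annealer matches the
brute-force optimum in the tests; that is the evidence we can offer that
the budget is adequate at the scales used.

**Conditional bridging selection.** Bridging crosses (donor x elite, plus
DE x elite in multiple-stage modes) are chosen *after* the elite list is
fixed, with the He constraint evaluated on the union of both lists — so the
bridging component is steered toward complementing the elite one. With
GS-scored donors the criterion is UC; with phenotype-scored donors (no
progeny-variance prediction possible) it is the plain midparent mean of the
donor's centred, shrunk phenotype (`observed_h2 * (y - mean(y))`, the
plug-in `Vg/(Vg+Ve)` from the simulated donor trial) and the elite GEBV,
under classical OCS.

**H criterion.** Donor screening tiles the genome into 20 cM windows on a
10 cM grid; a window's value is the effect-weighted dosage sum, and
`H = sum over a greedy left-to-right non-overlapping cover of
max(donor window value, best elite window value)` — the best DH
conceivably assembled from donor and elite segments. The cover is
value-independent (first admissible window), which keeps H monotone: it can
never fall below the best elite segment sum. The top 20 donors by H enter
phenotype-based OCS.

## Scheme engine

Burn-in (20 generations): 20 random founders from the first panel group are
intermated (10 families x 80 DH for 3 generations), then for 17 generations
the 50 best progeny by phenotype from T-3..T-5 are randomly intermated into
20 families of 80. Post burn-in, closed strategies preselect the top 5% per
family (4 of 80) from T-3..T-5 — 240 candidates — and select 20 crosses by
midparent phenotype, midparent GEBV, UC, OCS or UCPC; every generation
produces 1,600 DH. Open programs reallocate those resources between elite
(CE) and bridging (CB) crosses: 15x80 + 5x80, 15x80 + 10x40 or
10x80 + 10x80. DE progeny preselected by the same 5%-per-family rule are
candidate parents of the *elite* cross list — that is how donor germplasm
enters the elite pool — while the donor collection itself is static.
Bridging-specific and joint GS models need three DE cohorts to exist and at
least one inside the T-3..T-5 window; until then every selection falls back
to the elite-specific model.

Tie-breaking everywhere is deterministic: score descending, then id
ascending. Replicate r reseeds with `base_seed + r` and resamples the trait
architecture and burn-in; the founder panel is generated once, like a real
genotyped collection.

## What the generator emulates — and what it does not

The synthetic founder generator reproduces the three statistical features
the engine is sensitive to: (i) subpopulation structure via Balding-Nichols
Beta-dispersed group frequencies around shared ancestral frequencies
(Hudson Fst recovers the divergence parameter within +/-0.1 in the tests);
(ii) within-group LD decaying with map distance via a Gaussian-copula AR(1)
along each chromosome (`exp(-d/5 cM)` latent correlation, giving monotone
r^2 decay across 0-1 / 1-5 / 5-20 cM bins); and (iii) fully inbred lines.
It does *not* reproduce a real panel's site-frequency spectrum, haplotype
blocks from historical bottlenecks, or a real consensus map's marker
density gradients. Passing tests therefore demonstrate correctness of the
machinery and qualitative behaviour (diversity erosion, donor uptake,
gain/diversity trade-offs), not quantitative predictions for any particular
real panel.

## Problem sizes and numerical choices

Tests and the analysis scripts run the engine at reduced scale, chosen as
the smallest sizes at which every selection rule still operates unchanged:
`scale = 4` divides family counts and sizes by four (5 elite crosses x 20
DH), marker panels of 600-3,000 SNPs with 150-1,000 QTLs and 300-2,000
neutral markers, 3-10 replicates over 4-20 post-burn-in generations.
Structural counts (240 candidates, 4,800 training records, 1,600 DH) are
checked at full per-generation scale with a 3,000-marker panel. The
realized-heritability calibration uses 50,000 lines. Degenerate inputs are
handled explicitly: zero-length chromosomes never recombine, `sigma2` is
clipped at zero before the square root, fixed marker panels make the UCPC
shift fall back to midparent frequencies, and an all-fixed training panel
is an error (the VanRaden scale would vanish).

## Known limitations

* Single additive trait; no dominance, epistasis, mutation or GxE.
* Pedigree-expectation donor contributions, not realized IBD tracking.
* The within-cross UCPC frequency shift is a first-order approximation of
  selection on cross progeny.
* The He linear-loss slope and the simulated-annealing budget are method
  parameters, not biology; conclusions about *when* diversity management
  overtakes truncation selection depend on both and on program scale. At
  quarter scale and short horizons (~20 generations) truncation GEBV
  selection can still lead in mean final gain; the advantage of
  diversity-managed selection is a long-horizon property.
* Donor phenotyping uses the routine error variance and a single record;
  real genebank characterization is noisier and multi-trait.
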