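---
title: "hexpop: model, calibration, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{hexpop: model, calibration, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

hexpop is a forward-time, individual-based, demo-genetic simulator on a
hexagonal-cell landscape whose structure (barriers, barrier gaps, habitat
types) changes across scheduled epochs. This vignette records the model's
assumptions, the meaning and provenance of every tunable parameter, the
calibration choices made where the design was genuinely open, and what the
built-in scenario can and cannot tell you about real systems.

## The landscape

Habitat is a set of hexagonal cells (flat-top hexagons on an axial
coordinate system; rectangular patches are specified as columns × rows on
an offset grid and converted internally). The default layout places two
large patches (26 × 51 = 1326 cells each) adjoining at the center, with
two medium (10 × 20) and two small (5 × 10) patches abutting the large
patches but never each other — 3152 cells, six patches, five patch
interfaces. Everything outside is matrix: matrix edges always have
transmission probability 0, so walkers reflect off them and individuals
can never occupy matrix.

Movement constraints live on edges. An epoch sets every inter-patch edge
to 1 (continuous), 0 (isolated), or — in gapped epochs — to the gap
permeability on a small set of designated *gap edges* and 0 elsewhere.
Gap edges are a contiguous run centered on each interface, with the same
count on every interface, so all patch pairs offer the same total crossing
opportunity. Within-patch edges are always 1.

Reachability (for resource acquisition and pairing) means: connected to
the focal cell through edges of permeability > 0 by a path of length at
most the neighborhood radius (3 cells, a 37-cell disk in open habitat).
A gap edge is "reachable through" for these purposes — only absolute
barriers sever neighborhoods.

## The life cycle

Each step (= one year) runs: (a) resource acquisition, (b) pair formation,
(c) reproduction, (d) juvenile natal dispersal, (e) survival of everyone,
then age increment and juvenile→adult promotion. Epoch transitions are
applied at the start of the boundary step. The simulation starts with the
landscape saturated: one adult (age 1, sex 50/50, founder genotype) per
habitat cell.

**Resources.** Each cell produces one unit per step, split equally among
every individual whose reachable neighborhood contains the cell (scramble
competition). An individual's total, divided by its resource goal and
clipped to [0, 1], is its resource fraction *f*.

**Pairing.** Monogamous: a female pairs with the nearest available male
reachable within 3 cells; equidistant males tie-break by smallest id.
Females are processed in uniformly random order each step. The order
matters: processing by id (equivalently, by age) would hand senior females
systematic priority wherever males are locally scarce, which measurably
inflates the mean age of reproducing females; random order restores the
age-independent breeding the model intends. The permutation is drawn from
the replicate's single RNG stream, so runs remain bit-reproducible.

**Reproduction.** A paired female draws
round(Normal(fecundity_max × *f*, fecundity_sd)), truncated at zero.
Offspring inherit one uniformly chosen allele per parent at each of the 10
unlinked loci; there is no mutation operator anywhere in the code path,
and locus pairs are stored unordered (sorted) because phase carries no
information here.

**Dispersal.** Juveniles draw a path length uniformly from 1–5 (short) or
5–25 (long) and walk cell to adjacent cell. The previous direction is kept
with probability autocorrelation/100 (default 75; 100 gives straight
paths); otherwise, and on the first step, the direction is uniform. A
proposed move across an edge of permeability *p* succeeds with probability
*p* per encounter. A failed crossing consumes the step — the movement
effort is spent at the barrier — and redirects the walker uniformly among
the currently passable edges; this makes "per encounter" well defined. An
individual on a cell with no passable edges stays put. Any successful
crossing of an edge with 0 < *p* < 1 latches the individual's gap-crossing
flag for life. Adults never move.

**Survival.** Annual survival is 0.500 (juvenile) / 0.885 (adult).
Individuals below 20 % of the resource goal incur an additional 0.10
mortality (additive on the mortality scale, floored at survival 0).
Juveniles settled on typed habitat add S × (matching adaptive allele
copies), capped at 1. Newborns carry resource fraction 1: the life-cycle
order means they never forage in their birth year, so the resource penalty
cannot bind on them; density dependence reaches them through their
mother's fecundity instead. `survival_probability()` is nevertheless a
pure function of stage and fraction, so the penalty applies to either
stage if you call it directly.

## Genetics

Ten diploid loci, alleles coded 1–5, initial frequencies from the built-in
locus table: the five neutral loci use equal (0.2 × 5), unequal
(0.30/0.25/0.20/0.15/0.10, both orientations), and rare-dominated
(0.01/0.04/0.15/0.30/0.50, both orientations) profiles; loci 6–10 carry
adaptive alleles (locus 6 has two — allele 2 adapted to habitat A and
allele 4 to B — the others one each). Founder genotypes are drawn
independently per allele with no spatial stratification, so the population
starts at Hardy–Weinberg equilibrium and panmixia.

Metric conventions worth noting:

* **Allelic evenness** is −Σ p ln p / ln 5 over extant alleles. The
  analytic values for the three initial profiles are 1.000, 0.9596, and
  0.7252 (the last truncates, not rounds, to the conventional "0.72"
  anchor).
* **Heterozygosity deficit** uses H_exp = 1 − Σ q² over *extant* alleles,
  so its baseline shifts as alleles are lost — by design.
* **Genetic distance** between individuals is the fraction of loci whose
  unordered allele pairs differ ({1,2} vs {1,1} differs; {1,2} vs {2,1}
  does not). The test suite cross-checks this against
  `ape::dist.gene(method = "percentage")` on canonical locus strings.
* **Migrants** are individuals whose gap-crossing flag is set and whose
  *first* reproduction happened outside their natal patch; non-breeders
  and crossers that returned home to breed are excluded. Migrants per
  generation divides the migrant count by (window length / generation time
  measured in the same window) — not by a fixed nominal generation time.

## Parameters, defaults, and why

| Parameter | Default | Units | Provenance |
|---|---|---|---|
| juvenile / adult survival | 0.500 / 0.885 | probability/yr | scenario constants |
| resource penalty | +0.10 mortality below 20 % of goal | probability | scenario constants |
| dispersal ranges | 1–5 / 5–25 | cells | scenario constants |
| autocorrelation | 75 | 0–100 | scenario constant |
| gap permeability | 0.02 / 0.70 | probability/encounter | treatment levels |
| selection S | 0.01 / 0.10 | survival/allele copy | treatment levels |
| pairing radius | 3 | cells | same radius as the resource neighborhood |
| fecundity_max | 1.2 | offspring/litter | calibration, below |
| fecundity_sd | 0.5 | offspring | calibration, below |
| resource_goal | 2.5 | units | calibration, below |
| gap_edges | 1 | edges/interface | calibration, below |
| horizon | 4000 (5000 optional) | steps | epoch schedule, 4 × 1000 |

**Fecundity and the resource goal.** The scenario fixes the reproduction
*family* (resource-scaled normal) but not its constants, and the emergent
demography is sensitive to them. Three constraints pin the calibration:
(i) deterministic growth at full resources must exceed 1 so empty habitat
refills; (ii) the stationary resource fraction must sit well above the
0.20 penalty threshold — otherwise the population equilibrates *on* the
extra-mortality boundary, adult survival mixes 0.885 with 0.785, and the
emergent generation time collapses below the 8.7 years that the survival
schedule implies; (iii) the stationary density should sit near the
saturated initial condition of one adult per cell, which the scenario
presents as a sensible starting state rather than a 2–3× undershoot of
carrying capacity. With mean litter = fecundity_max × f and f ≈
goal⁻¹ × density⁻¹, the stationary balance 0.115 = 0.5 · pairing ·
E[litter] · 0.5 gives f* ≈ 0.44/fecundity_max and density ≈
fecundity_max/(0.44 · goal). fecundity_max = 1.2, fecundity_sd = 0.5,
resource_goal = 2.5 satisfy all three: growth 1.17 at full resources,
f* ≈ 0.37, stationary density ≈ 1.05 adults/cell. These were fixed from
this analysis, once, before the acceptance measurements.

**Gap size.** Only the *equality* of total gap size across interfaces is
structurally required; the count itself is free. Absolute migrant counts
scale roughly linearly with both gap count and population size, so with
the density calibration above, a single gap edge per interface
(gap_edges = 1) places the four dispersal × permeability treatments in
the intended migration regime — above 15 migrants/generation for
long/high, below 1 for long/low. Both knobs are exposed in the
configuration.

**Habitat typing.** In selection epochs, patches 1 (large), 4 (medium),
and 6 (small) are type A and patches 2, 3, 5 type B, so every patch
adjoins at least one patch of the opposite type and asymmetric migration
can oppose local selection at the doubly adaptive locus 6.

## Numerical and engineering choices

* One R RNG stream per replicate; the engine's draw order is fixed
  (resources use no draws; pairing permutation; litter normals; offspring
  sexes; dispersal walks in offspring order; adult then juvenile survival).
  (config, seed) determines every output byte, which the determinism tests
  assert.
* The hot paths — radius-limited BFS reachability, nearest-male matching,
  and the dispersal walks — are small C++ routines using R's RNG;
  scramble-competition shares are two sparse matrix–vector products per
  step (competitors per cell, then acquisitions per cell).
* Degenerate inputs: an empty population steps quietly to the horizon; a
  patch with zero individuals is a skipped stratum (with a warning) in
  stratified sampling and STRUCTURE export; a walker with no passable
  edges stays put; litter draws below zero truncate.
* Epoch application is idempotent and reversible (the edge set is rebuilt
  from the base landscape each time, never mutated incrementally).

## What the built-in scenario does and does not emulate

The generator reproduces the study conditions: the six-patch geometry, the
four-epoch schedule, the factorial treatments, the locus table, and the
demographic constants. It does *not* emulate features of real data —
mutation, linkage, sex-biased or condition-dependent dispersal, mate
choice, age-structured fecundity, environmental stochasticity, or
landscape noise. Passing tests therefore demonstrate internal consistency
of the mechanism (drift scaling with patch size, gap-flux scaling with
permeability and dispersal range, selection–migration balance), not
calibration to any empirical system. The absolute migration magnitudes in
particular inherit the gap-size and fecundity calibration above; their
treatment *ratios* and orderings are the robust quantities.

## Problem sizes used by the tests and acceptance script

Unit tests run on a three-patch miniature landscape (~100 cells, tens of
steps). The emergent-property checks use the full 3152-cell landscape
with runs scaled to what the quantities need: 400 steps (100 burn-in +
300 measured) for stationary generation time and isolation-by-distance;
150 + 500 steps for each migration treatment (three replicates in the
acceptance script); 100 + 300 steps for drift/homozygosity contrasts; and
100 + 200 steps for the selection response. These sizes were chosen so
that every measured quantity reaches its quasi-stationary regime — the
age structure converges in well under 100 steps (0.885¹⁰⁰ ≈ 5 × 10⁻⁶),
and a 500-step migration window accumulates enough migrant events that
replicate means are stable.

## Known limitations

* Generation time is measured per reproducing-female event; litters are
  not weighted by size (the two differ negligibly here).
* The gap placement is centered and contiguous; migration through corner
  vs mid-interface gaps is not distinguished.
* The IBD correlogram subsamples pairs for large populations; its bin
  means are unweighted by pair counts.
* `run_experiment()` executes replicates serially; the full 8 × 10 grid at
  horizon 4000 is hours of compute, which is why the shipped checks use
  the scaled windows above.
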