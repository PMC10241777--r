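---
title: "Methods: dispersal simulation and clonal population genetics in driftline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dispersal simulation and clonal population genetics in driftline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(driftline)
```

`driftline` couples two estimates of connectivity among coastal
populations of a passively dispersed, partially clonal species: a forward
biophysical model of surface drift on ocean currents, and population-genetic
differentiation from multilocus microsatellite genotypes. Each side is
useful alone; together they let you ask whether currents are sufficient to
explain observed gene flow, or whether other vectors must be invoked.

## 1. The biophysical model

### Forcing and interpolation

The forcing is a gridded daily surface-current product: `u`, `v` in m/s on
a regular lon/lat grid, one slice per day, with land as missing values
(`velocity_field`). Velocities at particle positions are obtained by
**spatial bilinear interpolation** over the four surrounding nodes.
Land nodes are excluded and the remaining weights renormalised; if all four
nodes are land the sample is (0, 0) with a flag. Daily slices are held
constant within the day — the model updates positions sub-daily against
daily forcing, and temporal interpolation is deliberately not applied
(`sample_velocity`). Queries outside the grid hull return an out-of-domain
signal rather than an error; during integration this becomes the
`lost_domain` fate.

### Integration and fates

Particles are released from every habitat site on every day of a simulated
year (`run_year`) and stepped with time step `dt` (default 1 h, any divisor
of 24):

- `dlon = u · dt / (R cos φ) · 180/π`, `dlat = v · dt / R · 180/π`,
  with R = 6371 km (the same constant used for all great-circle
  distances, so the two sides of the pipeline share one geometry).
- The default integrator is forward **Euler** at hourly steps, mirroring
  plain hourly updating against daily forcing; a midpoint (`rk2`)
  integrator is available and is used in the convergence tests.
- There is **no diffusion term**: given the field and configuration the
  simulation is fully deterministic. Randomness lives only in the
  synthetic-data generators.

Each particle terminates with exactly one fate, checked in this order after
every step: leaving the grid hull (`lost_domain`); first position within
the **capture radius** (default: the site-aggregation resolution) of an
eligible site (`event`, the connectivity event at that site); landing on a
land node away from any site (`beached_no_site`, the particle is excluded
from connectivity); reaching the maximum pelagic duration (default 60 days)
without an event (`expired`), unless it expires inside its source's capture
radius, which is scored as retention — an event at the source. The source
site only becomes event-eligible after the particle first leaves the
source's capture radius; otherwise every particle would terminate at step
zero, and retention could never be distinguished from release.

These event rules are the one place the model had to commit where common
practice varies: capture criterion, temporal interpolation, integrator and
release multiplicity are all exposed in `sim_config` so their influence can
be probed.

### Connectivity, averaging, statistics

`build_matrix` counts events per ordered site pair: `P_ij = n_ij / N_i`,
exactly, with retention on the diagonal. Yearly matrices are averaged
element-wise (`mean_matrix`). `event_statistics` reports the mean ± SD and
maximum of the great-circle event distance (each pair weighted by its event
count), and the mean ± SD of `P` and of event counts **over ordered pairs
with at least one event** (diagonal included). Conditioning on realised
links is the default because connectivity matrices of real coastlines are
dominated by structural zeros; the unconditional average is available via
`connected_only = FALSE`. SDs are population SDs over the event or pair
multiset.

### Stepping-stone closure

Direct connectivity within one pelagic duration misses multigenerational
transport. `stepping_stone` computes, for every ordered pair, the maximum
over paths of the product of per-edge probabilities — equivalently, the
shortest path under edge weights `−ln P_ij`, found with Floyd–Warshall.
All computation stays in log space, so a 200-step chain of P = 0.05
(product ≈ 10⁻²⁶⁰) is handled without underflow. Conventions: `SS_ii = 1`
(the zero-length path; retention stays available in the connectivity
matrix); unreachable pairs get `SS = 0` plus an explicit `reachable = FALSE`
flag, and are later excluded from comparisons rather than imputed. Ties
between equal-weight paths are broken deterministically by the relaxation
order (successor updates on `<=`), and paths are recoverable with
`ss_path`.

## 2. The genetic model

### Clone discrimination

Clonal plants are sampled as ramets; statistics are computed on genets.
`find_mlgs` groups identical multilocus genotypes within populations,
treating missing loci as wildcards (herbarium-quality data motivate this
default; `match_missing = FALSE` demands identical missingness). Ramets
missing more than half their loci are never merged; ramets with no scored
loci are excluded with a warning. Because wildcard matching is not
transitive, assignment is deterministic: each ramet joins the first
existing MLG whose first member it matches, in input order.

Repeated MLGs are then tested with **Psex**: with `pgen` the Hardy–Weinberg
probability of the genotype (product over scored loci of `p²` or `2pq`,
frequencies from the genet-level data of that population), the probability
that an MLG seen `n` times among `N` ramets arose from independent sexual
events is the unconditional binomial upper tail
`Σ_{i=n}^{N} C(N,i) pgen^i (1−pgen)^{N−i}`. Copies with `Psex < 0.01`
collapse into one genet; otherwise they stand as distinct genets sharing a
genotype. The variant choices here — unconditional tail at the observed
count, genet-level frequencies, no FIS correction — are the defaults;
ramet-level frequencies are available via `freq_level = "ramet"`. Genet
assignment feeds clonal richness `R = (G−1)/(N−1)` (0 = one clone,
1 = every ramet a distinct genet; undefined at N = 1 and flagged).
Re-running discrimination on the genet-level dataset converges immediately
on our fixtures, but is not guaranteed to be a no-op in general because
allele frequencies are recomputed.

### Diversity and differentiation

Per population and locus: `HO` (fraction heterozygous), Nei's unbiased
`HE = n/(n−1)·(1−Σp²)` with `n` scored gene copies, and `FIS = 1 − HO/HE`
(monomorphic loci flagged, not zeroed — the per-locus FIS distribution is
retained because heterozygote excess varies informatively across loci in
clonal populations). Allelic richness Â and private allelic richness PÂ
use exact hypergeometric rarefaction to a standardised number of gene
copies `g`; by default `g` is the largest value valid at every locus in
every population (with complete data this is twice the smallest genet
count). Populations with fewer than 5 genets are flagged, never dropped.

Differentiation is Weir–Cockerham θ from the 1984 variance components
(`a` among populations, `b` among individuals, `c` within individuals),
summed over loci and alleles; negative estimates are reported as computed.
`pairwise_fst` assembles the population-pair matrix;
`linearize_fst` gives `θ/(1−θ)` for distance comparisons. The test suite
checks the implementation against an independent derivation via nested
sums of squares, against exact endpoint cases (θ = 1 under fixed
alternative alleles), and against the parametric θ implied by the
generator's realised allele frequencies.

## 3. Comparing the two

`compare_genetics_currents` computes the Mantel correlation between
linearised FST and `−log` symmetrised stepping-stone probability
(element-wise `max` of the two directions by default, since SS is
directional and FST is not), over population pairs matched to simulation
sites by nearest great-circle distance. Significance comes from
simultaneous row/column permutation of the oceanographic matrix,
`p = (1 + #{|r*| ≥ |r|}) / (1 + n_perm)`, 9,999 permutations by default,
seed recorded. Pairs with zero symmetrised connectivity are excluded via a
mask and reported as a count: a zero-probability pair is a qualitative
finding, not a finite distance. When masked entries resurface under
permutation they drop out of that permutation's correlation. The Mantel
operationalisation is this package's own, explicit way of quantifying a
comparison that is often made by eye.

## 4. Synthetic data: what it emulates, what it does not

`make_velocity_field` provides four analytic regimes: still water, uniform
flow, solid rotation (speed = ωr; ω defaults so the farthest grid corner
moves at `amplitude`), and a double gyre derived from the streamfunction
`ψ ∝ sin(2π sx + φ) sin(π sy)`, hence divergence-free by construction.
The optional `wobble` parameter oscillates the gyre phase seasonally
(period 365 days), one phase per daily slice. This matters: with steady
forcing and no diffusion every release day is identical, so connection
probabilities collapse to 0 or 1 and the stepping-stone matrix degenerates
— day-to-day variability is the property of hindcast forcing that makes
probabilities informative. The divergence test uses the steady 2:1-domain
configuration, where the central-difference divergence cancels exactly
because the zonal and meridional phase increments per grid step coincide.

`make_occurrences` jitters records around supplied centres (truncated
normal, |z| ≤ 3) and refuses centres on land. `aggregate_occurrences`
snaps records to a fixed equal-angle grid: latitudinal step
`resolution/111.32` degrees, longitudinal step scaled by `cos(ref_lat)`
held constant across the domain, 0-based half-open cells anchored at
(−180, −90). Grid-cell snapping (rather than distance clustering) is
order-independent and idempotent given the same `ref_lat`; since the
aggregation rule and grid origin materially affect the resulting site
count, both are explicit and documented. Records on land snap to the
nearest ocean cell within 2 cells, else are dropped with a warning count.

`make_genotypes` draws per-population allele frequencies from a Dirichlet
centred on global frequencies with concentration `(1−d)/d`, so the
expected FST is approximately the differentiation knob `d`. Each
population hosts `genets_per_pop` resident founder genets; each ramet is a
copy of a uniformly chosen founder with probability `clonality`, otherwise
a fresh Hardy–Weinberg draw. With the default single founder, clonality 1
yields one genet per population (R = 0) and clonality 0 yields all-distinct
genets (R = 1, up to vanishing genotype-collision probability); the
defaults (19 populations × 25 ramets, 8 loci, 6 alleles, clonality 0.6,
differentiation 0.25, 2% missing) emulate a realistic range-wide clonal
seagrass survey with mean R near 0.4. All generators draw from private RNG
streams seeded from a single argument, so fixtures are reproducible and
independent of the caller's RNG state.

What the synthetic data does **not** emulate: mesoscale turbulence, tides,
wind waves and windage (absent from the drift model too), 3-D circulation,
linkage disequilibrium, null alleles, genotyping error, and mutation.
Passing tests therefore demonstrate correctness of the algorithms under
the stated model, not robustness of biological conclusions to these real
phenomena.

## 5. Numerical choices and degenerate inputs

- All distances are haversine with R = 6371 km (cross-checked against
  `geosphere` in the tests).
- Stepping-stone computation is entirely in log space; probabilities are
  re-exponentiated only at output.
- Rarefaction uses `choose` ratios, exact at the sample sizes where they
  are enumerable and stable elsewhere; `Psex` uses the `pbinom` upper tail.
- Undefined quantities are flags, not crashes: zero-event matrices, N = 1
  clonal richness, monomorphic FIS/FST, zero-variance Mantel inputs.
- Euler global error on smooth fields is first order in `dt` (verified
  against an analytic rotation with a Grönwall bound and a dt-halving
  check); `rk2` is second order.

## 6. Problem sizes

The shipped acceptance run (`scripts/acceptance.R`) uses a 0.5°, 20°×10°
double-gyre basin with 19 sites aggregated at 25 km, two years of daily
releases at `dt` = 3 h with a 20-day pelagic limit (~14,000 trajectories),
the default 19-population genetic design, and 9,999 Mantel permutations —
sizes chosen so a complete from-scratch reproduction stays in the
tens-of-seconds range while every stage runs at realistic dimensionality.
The stated release-scheme arithmetic (183 sites × 3,653 days = 668,499
particles over 2008–2017) is verified exactly from the calendar ledger,
which does not require integrating the trajectories.

## 7. Known limitations

- The event rule fires at the first position within a capture radius;
  with site spacing below the capture radius, neighbouring sites capture
  each other's releases immediately. Aggregation resolution and capture
  radius should be kept equal (the default) or chosen together.
- Wildcard MLG matching is order-deterministic but not transitive; heavily
  missing data can split true clones (mitigated by the forced-singleton
  rule) — this mirrors the behaviour of standard clonal-discrimination
  software rather than solving the underlying ambiguity.
- The Dirichlet island model has no spatial structure: differentiation is
  exchangeable across population pairs, so isolation-by-distance in the
  genetic data must be built by the user if wanted.
- Stepping-stone probabilities multiply single-generation probabilities
  along one best path; they ignore path multiplicity and generation time,
  so they rank connections rather than estimate per-generation migration.
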