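---
title: "Superimposed pollination networks: construction, structure, and the synthetic testbed"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Superimposed pollination networks: construction, structure, and the synthetic testbed}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem this package addresses

Plant–pollinator interaction networks are usually sampled from the plant
side: an observer watches flowers and records which insects touch them.
That method is blind at night and misses visits that happened outside the
observation windows. The complementary method samples from the animal
side: captured insects are washed and the pollen grains on their bodies
are identified, so each specimen testifies to the plants it recently
visited — including nocturnal visits by moths caught in light traps, for
which direct observation is impractical.

`pollinet` implements the full comparative workflow for these two kinds
of evidence. From raw sampling records it builds five qualitative
(binary) plant × pollinator matrices —

* `V_d`: diurnal field visitation,
* `P_d`: diurnal pollen loads,
* `V_dP_d`: their superimposition,
* `P_n`: nocturnal pollen loads,
* `V_dP_dP_n`: all three layers —

and then asks how the network's structure changes as each layer of
evidence is added. Every link in a superimposed matrix keeps the set of
methods that detected it, so the seven-way provenance tally (only
`V_d`, only `P_d`, …, all three) is always available.

## Matrix construction

**Visitation.** A link is present when at least one visit event was
recorded for the (plant, pollinator) pair. Repeated events are retained
in the record tables — they carry the interaction frequencies *f* and the
rarefaction effort — and collapse only at the binary-matrix stage.

**Pollen loads.** Grain counts are summed per (specimen, plant); a
(plant, pollinator-taxon) link is accepted when at least one specimen of
that taxon carries ≥ 5 grains of that plant (`min_grains`, configurable).
The threshold is applied per specimen, not summed across specimens: each
insect is an independent witness, and five grains on one body is evidence
while two grains on each of three bodies is not. Raising the threshold
can only remove links (tested as a monotonicity property).

**Ordering.** Species in every matrix are ordered by descending degree
with ties broken alphabetically. The choice is arbitrary but fixed, so
identical record sets serialize to byte-identical matrices.

## Structural descriptors

For a matrix with $P$ plants, $A$ pollinators and $L$ links:

* **Connectance** $C = L/(PA)$, and mean connectivities $S_P = L/P$,
  $S_A = L/A$. These are exact integer identities, reported at the
  conventional 2–3 decimals.
* **Extreme specialists**: the percentage of one-link species, reported
  for pollinators by default (the guild where the diurnal/nocturnal
  contrast shows).
* **Degree centralization**: Freeman's index over the single graph of
  all $N = P + A$ species, $\sum_i (d_{\max} - d_i) / ((N-1)(N-2))$. The
  field convention is anchored on the star network: one hub linked to
  every other node scores exactly 1, a degree-regular network 0. The
  bipartite-specific normalisation is not used; the unipartite form is
  the one for which the star anchor holds exactly.
* **NODF**: for every pair of rows (and of columns) whose marginal
  totals differ strictly, the pair contributes
  $100\,|\mathrm{overlap}|/\min(\mathrm{fill})$; equal totals contribute
  0 (the strict decreasing-fill rule of the metric's original
  definition). NODF is the mean over all row and column pairs. The
  implementation is order-free and therefore invariant to permutations
  of the input; it is tested against a brute-force enumerator and
  against `vegan::nestednodf`.

## Null models

Significance of NODF and modularity is assessed against fixed-margin
random tables. The sampler pairs the $F$ row tokens uniformly at random
with the $F$ column tokens, which yields the multiple hypergeometric
distribution — the same law as Patefield's algorithm (`stats::r2dtable`,
used as an independent cross-check in the tests, never as the
implementation). Margins are the observed binary degree sums, and each
sampled integer table is binarized (cell > 0 → 1) before the binary
statistic is computed. The empirical $p$ is one-sided with an add-one
correction, $p = (1 + \#\{\text{null} \ge \text{obs}\})/(n_{\rm reps}+1)$,
appropriate for statistics expected to exceed their null when the
network is structured. When the null ensemble is degenerate (sd = 0) the
z-score is flagged undefined and $p$ is still reported.

One consequence of binarization deserves emphasis: token collisions make
a binarized null table slightly sparser than the observed matrix (a few
per cent of links), and sparser webs carry somewhat higher modularity.
The modularity null test is therefore *conservative*: on neutral
(unstructured) communities its z-scores centre below zero rather than at
zero, and the calibrated property — verified in the tests — is that
neutral webs are never declared significantly modular. NODF shows no
such bias on webs drawn from the null itself.

## Modularity, roles, and link gain

**Barber modularity.** For a partition $g$ in which plants and
pollinators share module labels,
$$Q = \frac{1}{F}\sum_{ij}\left(A_{ij} - \frac{k_i d_j}{F}\right)
      [g_i = g_j],$$
with $F$ the link total and $k, d$ the degrees. Two disconnected
$K_{b,b}$ blocks under their natural partition give $Q = 1/2$, the
one-module partition always gives 0.

**Optimisation.** Simulated annealing over partitions: single-species
reassignments with Metropolis acceptance $\exp(\Delta Q/T)$, plus one
module-merge and one module-split proposal per sweep. The initial
temperature is calibrated from 100 sampled moves so that a
median-magnitude downhill move would be accepted with probability ½;
cooling is geometric (0.995 per sweep); a restart stops after 200 sweeps
without improvement. Each restart ends with a greedy refinement pass,
and the best of `n_restarts` (default 10) is returned — never below the
trivial $Q = 0$. The search is exact on small webs (verified against
exhaustive partition enumeration up to 8 species) and recovers planted
partitions on synthetic communities. Identical seeds give identical
partitions.

**Roles.** Within-module standardized degree
$z_i = (k_i^{\rm in} - \bar k^{\rm in}_{m})/\sigma_m$ (0 where a module's
sd is 0) and participation $c_i = 1 - \sum_m (k_{i,m}/k_i)^2$, with the
conventional thresholds $z = 2.5$ and $c = 0.62$ classifying species as
peripheral, connector, module hub or network hub.

**Link gain.** Links added by a pollen layer are labelled within- or
between-module relative to the base partition. Significance uses a
permutation test that shuffles the pollinator endpoints across the added
links — preserving every species' added-link count — rather than a GLMM:
the question "do added links fall within modules more often than
chance?" is answered directly by the permutation distribution of the
within-fraction, without distributional assumptions on per-species
percentages. Links involving species absent from the base network are
excluded from the within/between comparison and reported separately.

## Connectivity distributions and the f–s relationship

The cumulative connectivity distribution $P(\ge k)$ of each guild is fit
by three candidates, all linear in their parameters in log space and
estimated by ordinary least squares on the log-cumulative data (the
classical approach in this literature; the alternative MLE-on-raw-degrees
route is out of scope):

* exponential: $\log_{10} P = a - k/\gamma$,
* power law: $\log_{10} P = a - b \log_{10} k$,
* truncated power law: $\log_{10} P = a - b\log_{10} k - k/k_x$.

Selection is by $\mathrm{AIC} = n\ln(\mathrm{RSS}/n) + 2p$. The RSS is
floored at $n \times 10^{-20}$ (residuals of $10^{-10}$ per point, far
below any real data noise) so that on *exact* synthetic data the nested
models tie on fit and the parameter penalty decides — the truncated
model nests the power law as $k_x \to \infty$, and without the floor the
selection would be decided by floating-point noise. The truncated fit is
skipped, with a notice, below 4 distinct degrees.

The f–s relationship regresses $\log_{10} s$ (connectivity) on
$\log_{10} f$ (interaction frequency). *f* comes from visitation events
only — a pollinator's event count, or the events a plant received;
pollen records add links but carry no meaningful frequency, since one
specimen's load reflects an unknown number of visits. Slope differences
across matrices are tested ANCOVA-style: the full model
`log10(s) ~ log10(f) * matrix` against the common-slope model, giving an
$F$ with $(G-1,\; N-2G)$ degrees of freedom for $G$ matrices over $N$
points.

## Rarefaction

Each distinct link is treated as a "species" and each sampling unit — a
visit event, or a pollen specimen evidencing the link at threshold — as
an "individual". The expected number of distinct links at subsample size
$m$ is Hurlbert's
$$E[S(m)] = \sum_i \left(1 - \binom{n - x_i}{m}\Big/\binom{n}{m}\right),$$
evaluated with log-gamma arithmetic. No extrapolation beyond $n$ is
offered. Uncertainty comes from a multinomial bootstrap of the
record-to-link assignment (default $B = 200$); the 95% band is the
2.5/97.5 percentile of the bootstrap *deviations*, centred on the point
estimate, so the band always contains it — in particular at $m = n$,
where $E[S(n)] = S_{\rm obs}$ exactly but every plain bootstrap
percentile would sit below it (resampling loses rare links).

## The synthetic community generator

`simulate_community()` produces communities with known ground truth:

* lognormal species abundances $a_i, b_j$ (σ = 1 by default);
* link propensity $w_{ij} = a_i b_j (1 + \lambda\,[\text{same module}])$,
  with $G$ planted modules assigned round-robin (defaults $G = 5$,
  λ = 2; recovery tests use the strongly structured λ = 50, $G = 3$
  regime);
* a per-taxon visit profile drawn once from a Dirichlet centred on the
  taxon's propensity column, with concentration κ scaled by the
  propensity's mean so κ is comparable across taxa. The two guilds get
  different κ (defaults $\kappa_d = 5$, $\kappa_n = 0.1$): a low-κ taxon's
  whole population concentrates on the same one or two plants, which is
  what makes the *taxon-level* one-link share rise in the nocturnal
  guild. Drawing the profile per specimen instead would average the
  specialization away.

Sampling emulates the field design at its published scale: 1693
visitation events drawn i.i.d. with probability ∝ w over diurnal
pollinators; 272 diurnal and 753 nocturnal pollen specimens whose taxon
follows guild abundance, contacting $1 + \mathrm{Poisson}(\nu)$ plants
sampled from the taxon profile, with negative-binomial grain counts
(mean 20, dispersion 1) whose per-plant mean follows the profile share —
so a specialist's grain mass piles onto its dominant plant and
sub-threshold traces on the others are discarded by the 5-grain rule.
Census and meadow labels are cosmetic round-robin assignments.

What the generator does **not** emulate: flowering phenology and
turnover across censuses, spatial structure among meadows, pollinator
movement, observation error in pollen identification, and taxonomic
uncertainty. Tests that pass on these communities therefore demonstrate
that the *algorithms* recover known structure under abundance-driven,
module-structured sampling — they do not certify behaviour under
phenological or spatial confounding.

`simulate_reference_records()` is different in kind: a deterministic
constraint solver that builds record sets whose five matrices realize a
fixed species/link/overlap count structure exactly (352 visitation
links, 413 diurnal pollen links with 183 shared, 96 nocturnal links with
13 shared, unions 582 and 665, fold-change 1.89). It places the shared
links first, covers every species, fills the remaining quotas at random,
and asserts every target count before returning. It exists so the
count-arithmetic rows of the comparative table are reproducible to the
printed digit without any external data file.

## Numerical and design choices

* Exact string matching (after whitespace trimming) for taxon labels; no
  fuzzy synonymy.
* One-sided empirical p-values with add-one correction throughout.
* All stochastic steps take explicit integer seeds; stage seeds in
  `run_study()` are derived from the single config seed by fixed
  offsets. Reruns are byte-identical.
* Degenerate inputs error early with informative messages: empty
  matrices, 1×1 NODF, centralization below 3 species, single-point
  distributions, rarefaction beyond $n$.
* Test problem sizes: oracle equivalences use webs of ≤ 8 species per
  side (NODF) and ≤ 8 species total (exhaustive modularity); the
  planted-recovery community has 12 plants and 22 pollinators with 150
  visit events — small enough for the annealer to be exact in seconds,
  large enough for the module signal (within-module link fraction > 0.9
  at λ = 50) to dominate.

## Known limitations

* Binary matrices only; weighted (quantitative) webs, WNODF and H2′ are
  out of scope.
* The modularity null test is conservative (see above); printed
  module counts and z-scores from field studies depend on unstated
  algorithmic details and are not reproduced, only the count-arithmetic
  quantities are.
* Rarefaction is interpolation-only; no coverage standardization or
  Hill-number profiles.
* The annealer is exact only at small sizes; at field scale it returns
  the best of its restarts, which is the standard practice but carries
  no global-optimality guarantee.
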