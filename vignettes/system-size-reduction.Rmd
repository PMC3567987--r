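---
title: "Facilitated diffusion on a DNA lattice and system-size reduction"
author: "fdsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Facilitated diffusion on a DNA lattice and system-size reduction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fdsim)
```

## The model

Site-specific transcription factors (TFs) find their operators by
*facilitated diffusion*: rounds of three-dimensional diffusion through the
cytoplasm interleaved with one-dimensional sliding along the DNA. `fdsim`
simulates this as an event-driven kinetic Monte Carlo process on a linear
DNA lattice of `M` bp:

* **Association.** The free pool of each species binds with total
  propensity `k_assoc * n_free * A_free/A_total`, where `A_free/A_total`
  is the fraction of start positions at which the molecule's footprint
  (default 23 bp, the average prokaryotic motif length) fits without
  overlapping another bound molecule. The landing position is uniform over
  those free positions, and the molecule's orientation (which strand's
  energies it reads) is chosen uniformly at binding.
* **Sliding and unbinding.** A bound molecule at position `j` waits an
  exponential time with mean `tau0 * exp(E_j)` — `tau0` is the specific
  waiting time and `E_j` the binding energy (in kT) of the recognition
  window under the molecule — then either dissociates with probability
  `p_unbind` or attempts a 1 bp slide, left or right with equal
  probability. A slide blocked by a neighbouring footprint or by a
  sequence end is rejected (volume exclusion, reflecting boundaries): the
  clock still advances. Non-cognate "crowder" species read a flat
  landscape (`E = 0`).
* **Scheduling.** Bound-molecule events live in a time-ordered queue;
  the association channel is re-drawn after every binding or unbinding and
  rescaled exactly (next-reaction style) when exclusion changes its
  propensity. All waiting times are exponential, so the simulation is
  statistically exact for this model.

The sequence specificity comes from a position frequency matrix built from
aligned high-affinity sites with a pseudo-count `zeta` (default 1):

\[ \nu_{x,k} = \frac{n_{x,k} + \zeta\,\nu_x}{\sum_y n_{y,k} + \zeta},
\qquad E(j) = \sum_{k}\ \ln \frac{\nu_{x_{j+k},k}}{\nu_{x_{j+k}}} \]

with the genomic background `nu_x` as reference. Under this convention the
expectation of `exp(E)` over background-distributed sequence is exactly 1,
which ties the energy scale to the waiting times: on background DNA the
mean waiting time is `tau0`. The bundled lac repressor motif is built from
the three known operators with a 9 bp central gap (the tetramer's two
dimers each read only 6 bp); gap columns contribute nothing to any score.
Both strands are always scored, the reverse strand by reverse-complementing
the window. The package predicts O1 as the strongest operator, as it
should.

### Default lacI parameters

| parameter | default | units | meaning |
|---|---|---|---|
| `footprint` | 23 | bp | occluded length, volume exclusion |
| `tau0` | 1.18e-6 | s | waiting time on background DNA |
| `k_assoc` | 2400 | 1/s | association rate per free molecule |
| `p_unbind` | 2.7e-4 | — | dissociation probability per event |
| `zeta` | 1 | — | PFM pseudo-count |
| background | A/T 0.246, C/G 0.254 | — | E. coli K-12 composition |

These imply a residence time `t_R = tau0 <exp E>/p_unbind ~ 4.4-4.6 ms`, a
sliding length `sqrt(2/p_unbind) ~ 86 bp` per visit and a bound-time
fraction around 0.86–0.88 in the crowded reference system — the
experimentally motivated regime for lacI. Crowders default to the same
kinetics; 50000 of them on 4.6 Mbp give ~22% DNA coverage, near the ~25%
bacterial estimate (exactly 25% would require every crowder permanently
bound, so the crowded coverage sits slightly below it).

## Reducing the system

Simulating a 4.6 Mbp genome is expensive; the scientific questions usually
concern a target region a hundred times smaller. A subsystem of relative
size `lambda` (the length ratio) is *equivalent* to the full system when
the 1D parameters are untouched and the local crowding — bound molecules
per bp — is preserved. Two parameterizations achieve this:

* **Copy-number model:** scale every species' copy number,
  `TF_lambda = round(lambda * TF)` (round half to even). Fails when the
  rounded value drops below one molecule — for a 10-copy TF the smallest
  feasible subsystem of a 4.6 Mbp genome is 460 Kbp.
* **Association-rate model:** keep all copies but scale the association
  rate by `gamma = lambda (1-f) / (1 - lambda f)`, where `f` is the
  fraction of time a molecule spends bound in the full system. The
  subsystem bound fraction becomes `lambda f`, preserving bound molecules
  per bp with no integer constraint. `f` is measured from replicate
  simulations of the full system (`estimate_f()`; 20+ replicates
  recommended) or supplied by the user.

`subsystem_equivalence()` runs the whole comparison protocol: it extracts
the subsystem window centred on the target (margins keep the target at
least 10% of the window away from either end, avoiding reflecting-boundary
artefacts), simulates the full system, both adjusted subsystems and an
unadjusted negative control for equal durations, and collects per
replicate: the occupancy-bias correlation to the mean full-system profile
on the common window, the first-passage time to O1 and the O1 occupancy
probability, plus per-replicate 1D statistics. `compare_to_full()`
summarizes each subsystem against the full system with two-sample KS
tests and a standardized mean difference.

## Observables and estimators

* **Occupancy bias** — per-bp covered-time fraction divided by its window
  mean. Scale-free, so profiles of systems with different size and copy
  number are comparable; Pearson correlation is computed against the mean
  full-system profile.
* **Residence time `t_R`** — total bound molecule-time divided by the
  number of binding events (completed visits plus those still open at the
  horizon). This renewal (ratio) estimator is used deliberately: it is the
  quantity that makes `f = t_R/(t_R + t_free)` and the association-rate
  inversion `k = (1/t_R) f/(1-f) (A_max/A_total)` exact, and it does not
  discard visits cut off by the end of the run. The mean over completed
  visits only (`t_R_completed`) is reported alongside; it is biased low on
  landscapes with deep traps (the operators), where a visit's dwell can be
  comparable to the whole run.
* **Sliding length `sl_obs`** — `sqrt(2 N)` bp with `N` the mean number of
  1D events per completed visit; for a symmetric walk `N` is geometric
  with mean `1/p_unbind`, giving `sl_obs ~ sqrt(2/p_unbind)`.
* **Affinity/occupancy ratio** — over the strong-site set (scores within
  30% of the score *range* below the maximum, both strands), normalized
  affinity `a ~ exp(E)` against normalized occupancy at the site start;
  at low copy number and long times both converge to the Boltzmann
  distribution and the ratio to 1, while crowding flattens occupancy and
  pushes weak-site ratios below 1 (false-positive regime).
* **Target occupancy / first passage** — the target counts as occupied
  only when a cognate recognition window starts exactly at the annotated
  site start (either strand); the 21 bp window is anchored 1 bp inside the
  23 bp footprint. First passages that never happen are censored at the
  run length and excluded from means (the censored count is kept).

## The synthetic genome, and what it does not emulate

`lac_region_genome()` draws i.i.d. sequence at the printed E. coli base
composition and plants the three lac operators at their native relative
offsets (O3 at −92 bp, O2 at +401 bp from the O1 start). It reproduces the
background energy statistics (`<exp E> = 1` in expectation) and the
operator cluster, but not real-genome features: no correlated sequence, no
codon or repeat structure, and a thinner population of moderate-affinity
background sites than a 4.6 Mbp genome accumulates. Consequently
realized `<exp E>` over a 46 Kbp draw fluctuates (roughly 0.8–1.7 across
seeds), and statistics dominated by the landscape tail inherit that
fluctuation. Equivalence experiments are insensitive to this because every
system shares the same planted window; the absolute calibration run
(`scripts/acceptance.R`) pools replicates on one fixed genome.

## Numerical choices

* Exponential waiting times throughout; memorylessness makes event-queue
  simulation exact and association-channel rescaling valid.
* Blocked slides are rejected with the clock advanced, the standard
  lattice-exclusion convention; each event counts one step `N` whether or
  not the move succeeded.
* Round half to even for copy-number scaling (it reproduces the integer
  subsystem abundances, including the infeasible 230 Kbp/10-copy case,
  from the exact length ratios).
* `lambda` is always computed from constructed sequence lengths, never
  from nominal labels; `lambda_from_waiting_times()` offers the
  waiting-time-weighted alternative, which reduces to the length ratio on
  background sequence.
* Ties in `strongest_site()` break to the smallest position, forward
  strand first. Coordinates are 1-based inside R; BED/bedGraph exports are
  0-based half-open.
* RNG: xoshiro256++ inside the C++ core, seeded by splitmix64 from
  (seed, replicate); replicate streams are independent and every result is
  bit-reproducible for a given seed.
* A landscape with a zero pseudo-counted frequency (possible only with
  `zeta = 0`) fails at scoring time, naming the offending column.

## Problem sizes used by the test-suite

The test suite exercises the full protocol at sizes chosen to give clear
statistics at desk scale: the calibration run uses the 46 Kbp
copy-number replica (10 cognate + 500 crowders) with 10 replicates of 2 s;
the equivalence suite uses a 460 Kbp full system against 46 Kbp
subsystems, 60 replicates of 6 s each, all systems at identical durations
so censoring acts identically. Mean first passage in these systems is
~2–3 s, so 6 s horizons censor under ~10% of passages. Oracle tests
(geometric visit law, renewal bound fraction, Boltzmann ratios) run on
small flat or two-site systems where closed forms are exact.

## Known limitations

* Pure sliding: no hopping, jumping, inter-segment transfer or explicit
  3D diffusion; no TF–TF cooperativity; no gene-expression readout.
* The unbinding probability is energy-independent; `p_unbind = 2.7e-4` is
  a calibration constant chosen to reproduce the lacI residence time given
  `tau0`, not a derived quantity.
* On landscapes with very deep traps the infinite-horizon mean visit dwell
  is dominated by rare trap visits; any finite run under-samples that
  tail, which is why the ratio estimator and the run lengths above are
  stated explicitly.
* Subsystems are linear fragments with reflecting ends; circular topology
  is not modelled.
* The target trap is non-extensive: O1 is a single site, so its dwell
  share per molecule grows as the system shrinks (one molecule owns the
  whole trap in a `lambda = 0.1`, 10-copy reduction, versus a tenth of it
  in the full system). Both reductions therefore carry small (~3–4%)
  systematic residuals in the bound fraction and residence time at low
  copy number — two orders of magnitude smaller than the bias of an
  unadjusted subsystem, but resolvable with 60 replicates. The sliding
  length, first-passage and target-occupancy distributions are
  insensitive to this. On real genomic windows, where strong sites occur
  at comparable density inside and outside the window, the effect is
  diluted; the i.i.d. synthetic fixture concentrates all deep traps at
  the planted operators and so shows it maximally.
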