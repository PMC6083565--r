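---
title: "Folding HP chains on the triangular lattice with ions motion optimization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Folding HP chains on the triangular lattice with ions motion optimization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(imogfold)
```

## The model

The hydrophobic–polar (HP) model reduces a protein to a chain of two residue
types, H (hydrophobic) and P (polar), folded as a self-avoiding walk on a
lattice. Here the lattice is the two-dimensional triangular lattice: every
site has six neighbors, reached by the unit steps labelled `1..6`
(counterclockwise from `(1, 0)` in axial coordinates). Unlike the square
lattice, residues `i` and `i + 2` can touch, so even very short chains have
non-trivial optima.

A conformation is a vector of `n - 1` direction labels; decoding places
residue 1 at the origin and walks the chain. The energy is

$$E = -\,h,$$

where `h` counts pairs of H residues that are lattice-adjacent but not
consecutive along the chain, each contributing one unit of contact energy.
Folding means minimizing `E`. The decision problem is NP-hard, which is why
the package pairs a metaheuristic with an exact enumeration oracle for short
chains.

Two policies need fixing that the model statement leaves open:

* **Invalid decodes.** A direction vector may revisit sites. Such
  conformations get the surrogate fitness `+c`, where `c` is the number of
  coincident residue pairs, and their contacts are ignored. Every
  self-avoiding fold (fitness `<= 0`) therefore strictly dominates every
  colliding one, and the optimizer still senses progress toward fewer
  collisions.
* **Direction labels are cyclic.** Out-of-range continuous coordinates are
  wrapped with period 6 (fundamental domain `[1, 7)`), never clamped;
  clamping would bias the search toward labels 1 and 6. Wrapping commutes
  with the rounding rule below, so it never changes a decoded conformation.

## The optimizer

IMOG couples ions motion optimization (IMO) with a greedy local search. Two
populations of `N = 100` real-valued vectors ("anions" and "cations", one
coordinate per chain bond, initialized uniformly on `[1, 6]`) evolve for
2000 iterations. Fitness is evaluated after rounding each coordinate
half-away-from-zero and wrapping into `{1..6}`.

**Liquid phase** (every iteration). Each anion coordinate moves toward the
best cation by the fraction

$$AF = \frac{1}{1 + e^{-0.1/d}},$$

where `d` is the per-coordinate distance to the best opposite-charge vector
(`AF = 1` at `d = 0`, the continuous limit; `AF -> 0.5` for large `d`);
cations move symmetrically toward the best anion. The update is a strict
per-coordinate contraction, so the populations collapse onto the two
incumbents within a few dozen iterations — the liquid phase is the
intensification mechanism, and everything after the collapse depends on the
solid phase.

**Solid phase** (the escape mechanism). Stall counters track how long each
incumbent's fitness has gone without strict improvement. While **both**
exceed `solid_num` (default 50), each iteration additionally: perturbs every
individual by `A_i + \Phi\,(Cbest - 1)` or `A_i + \Phi\,Cbest`
(`\Phi \sim U(-1, 1)` per individual, branch chosen by a fair coin);
re-initializes a pair uniformly with probability 0.05; and applies one
greedy sweep to every other pair. The decoded incumbents themselves are also
greedy-swept until their fitness stops improving. The original fitness-ratio
trigger (`CbestFit >= CworstFit / 2` and the anion analogue) is implemented
for completeness (`solid_variant = "original"`) but is ill-behaved once
fitnesses go negative, which is why the stall-triggered variant is the
default.

**Greedy local search.** One sweep visits bond positions in chain order,
selects each independently with probability 0.25, and replaces the selected
label by the best of the six alternatives under full-chain fitness
(re-decoding the whole chain — changing one label rigidly moves the tail).
The incumbent label is kept on ties; among non-incumbent ties the smallest
label wins, which makes sweeps deterministic given the selected positions.

### Design choices that mattered

The published description leaves several details open; the package resolves
them as follows, in each case the variant that measurably recovers the
published benchmark energies:

* **Stall counters are reset only by strict improvement**, so the solid
  phase keeps firing on every iteration of a stagnant stretch. Resetting
  the counters after a single firing leaves the collapsed population idle
  for `solid_num` iterations at a time and costs 2–6 energy units on the
  benchmark chains.
* **Plateau drift.** When a population member ties the incumbent's fitness,
  its vector replaces the incumbent (the fitness, and hence the stall
  counter, is unchanged). HP contact landscapes are dominated by wide
  plateaus; with incumbent-keeping ties the search gets pinned at the first
  conformation of each energy level and misses printed optima by several
  units.
* **The 5% branch of the solid phase is the restart.** The pair is
  re-initialized with probability 0.05 — the restart clause of the original
  solid phase — and the greedy sweep is applied to the remaining 95%.
  Assigning the 5% to the greedy instead (and re-initializing 95% of both
  populations every stalled iteration) erases all incumbent-centred
  refinement and demonstrably cannot reach the published energies.
* **The incumbents are locally searched too** (sweeps repeated to a
  fixpoint), mirroring the published worked example, which applies the
  greedy point search to the running best solution.
* **`solid_num = 50`** by default; the benchmark results are insensitive
  across 25–100 (the acceptance suite checks 25, 50 and 100), so the value
  only sets how long the liquid phase is given before escaping.

## The exact oracle

For chains of up to 13 residues, `enumerate_min_energy()` enumerates every
self-avoiding walk depth-first with an occupancy grid and incremental
contact counting. With `symmetry_fix = TRUE` the first step is pinned to
label 1 and the first off-axis step to the upper half-plane, which
quotients out the 12 lattice point-group isometries without changing the
minimum (the tests verify the orbit expansion against the unrestricted
count, including the straight chain, whose orbit is smaller because it is
its own mirror image). The 12-residue benchmark chain enumerates about
1.5 million walks in well under a second; the cap of 13 keeps the worst
case near `10^7` nodes. No branch-and-bound is attempted — the oracle's job
is to be obviously correct.

## What the runs look like

`run_imog()` is one seeded optimization; `run_batch()` runs independent
seeds `seed, seed + 1, ...` and reports the best and mean of the per-run
best energies, the batch statistic used for stability comparisons in the
benchmark literature. With `stop_at_target = TRUE` and a known target
energy, a run (and the batch) exits as soon as the target is reached — off
by default, used by the acceptance checks where the published optimum is
the stopping point.

All randomness flows through R's RNG from the single seed, so identical
seed and configuration reproduce a run bit for bit. The compiled kernel
(decoding, contact counting, greedy candidate evaluation, enumeration) is
deterministic.

Typical problem sizes, measured with the default configuration on one CPU:
a 12-residue run takes a few seconds; 20–25 residues, 15–30 s per run; the
37-residue benchmark chain, ~25 s per run. The published optima for the
20- and 25-residue chains are usually recovered within the first handful
of a 30-run batch; the 24-residue chain (whose optimum is a perfect
packing of its ten H residues) is the hardest and can need most of the
batch. For the 37-residue chain the published −29 is out of reach at
this budget (batches reach −18 to −21); the package reports the best energy
found, and an independent basin-hopping probe with far larger budgets
reached −28, suggesting the printed value requires either much longer runs
or additional move types.

## The synthetic benchmark fixtures

The 28 packaged instances are transcribed from the published benchmark
tables (binary repeat notation, digit `1` = H — the convention pinned down
by the all-1s chain whose printed energy is impossible for an all-polar
sequence). The transcription is locked by a test asserting that every
expanded sequence matches its stated length. Four entries required
repairing single characters lost where the source tables run columns
together; each repair is the unique reading that matches the stated length
(and, for the two longest chains, reproduces the classic 60- and 64-residue
benchmark sequences exactly).

## Limitations

* The model is the pure HP contact potential: no H–P/P–P terms, no shifted
  potentials, no 20-letter alphabet, no square-lattice or 3D variants.
* The greedy neighborhood is single-label only (no pull or crankshaft
  moves), which bounds how deep the optimizer can go on chains beyond ~30
  residues at the default budget.
* Passing the packaged benchmarks shows the optimizer reproduces published
  lattice-model energies; it says nothing about real, off-lattice protein
  structures.
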