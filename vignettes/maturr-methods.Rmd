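---
title: "Methods: repertoire mutation analysis and the affinity-maturation model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: repertoire mutation analysis and the affinity-maturation model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(maturr)
```

maturr analyses somatic hypermutation (SHM) in heavy-chain B-cell
receptor (BCR) repertoires that derive from a single germline V gene —
the situation in the murine anti-nitrophenol (NP) response, which is
dominated by Vh186.2/IGHV1-72 — and simulates the clonal dynamics that
produce such repertoires under two contrasting selection environments: a
structured germinal centre with dark-zone/light-zone (DZ/LZ) shuttling,
and an unstructured tissue infiltrate with constant but decaying access
to help. This vignette documents the model and the analysis pipeline,
the parameters that matter, the numerical choices, and what the
synthetic-data validation does and does not establish.

## The germline reference

Every analysis is expressed in the coordinate system of a
`germline_reference`: a nucleotide sequence plus an ordered
FR1–CDR1–FR2–CDR2–FR3–CDR3–FR4 region map in 0-based half-open
nucleotide coordinates, each region a whole number of codons.
Amino-acid positions are numbered sequentially over the reference
translation (1-based), so "position 33" is the 33rd codon; the canonical
affinity-relevant exchanges W33L (and W33→other), G57D, K59R, and Y101F
are defined at these positions (`key_mutation_table()`).

The packaged reference (`default_germline()`) is a **synthetic
reconstruction** of Vh186.2: its protein sequence matches the canonical
V region (tryptophan 33, glycine 57, lysine 59) with a canonical
NP-response junction (tyrosine 101 in CDR3) and framework 4, but the
codon-level nucleotide sequence could not be taken from the IMGT
reference allele and is a best-effort reconstruction, labelled as such
in `inst/extdata/vh186_2_synthetic.fasta`. Every sequence-derived
constant (notably the random-mutation R/S baseline) is therefore an
approximation of the value the canonical allele would give; users with
access to the IMGT allele can substitute it via `read_germline()`
without touching any other code.

## Isotype classification

Reads are classified from short constant-region motifs located anywhere
in the read: one motif each for IgM and IgA, and a degenerate IgG motif
whose three wildcard positions (N1, N2, N3) encode the subclass
(G/C/T → IgG1, A/G/G → IgG2a, A/C/A → IgG2b, A/G/T → IgG3; any other
combination is `IgG-unsubtyped`). Matching is windowed Hamming distance
— no indels inside a motif — with at most one mismatch; wildcard
offsets and `N` bases in the read never count as mismatches. When two
different motifs both match within one mismatch, the read is left
`unclassified` with a warning rather than guessed. Classification is by
construction invariant to the motif's position and flanking sequence,
and the test suite checks this property on randomised flanks.

## Alignment and mutation calling

Each read is aligned globally (Needleman–Wunsch, affine gaps) to the
germline via `Biostrings::pairwiseAlignment()`. Default scoring is
match +5, mismatch −4, gap open −10, gap extend −1 (a gap of length L
costs `gap_open + L*gap_extend`); all four numbers are exposed through
`alignment_scoring()` because the source protocol does not fix them.
The test suite verifies optimality against an independent, plain-R
Gotoh dynamic program on hundreds of random short pairs, and verifies
that re-scoring the emitted alignment reproduces the optimiser's score.

Mutation calling walks the alignment columns:

* Nucleotide mismatches (read base ≠ germline base, `N` excluded) are
  binned by region. Each point mutation is classified
  replacement/silent by the effect of **that substitution alone** on
  its germline codon — the same semantics as the enumeration baseline
  below — so R + S always equals the number of point mutations.
* Each mutated codon is additionally re-translated on the read side and
  compared with the germline residue; these codon-level calls drive
  key-mutation detection (a codon carrying two changes is judged by its
  final translation). At SHM-typical mutation densities the two
  classifications almost always coincide; both are reported.
* Insertions and deletions are recorded separately and never enter R/S
  counts. An indel whose length is not a multiple of three inside
  FR1–FR4 flags the profile `frame_disrupted`; amino-acid calls are
  suppressed from the first frame-breaking position onwards, and such
  sequences are excluded from clone definition.
* Per-region counts are normalised by region nucleotide length exactly
  (`n_nt / length_nt`).

## The random-mutation R/S baseline

`expected_random_rs()` enumerates all `3L` single-nucleotide
substitutions over a region set (every position, every alternative
base, equal weight), classifies each by codon translation, and returns
replacement/silent. This is the no-selection reference against which
observed repertoire R/S ratios are judged.

Two design choices deserve comment:

* **Stop codons are excluded by default.** The baseline is compared
  against productive, surface-expressed receptors; a clone whose codon
  became a terminator is never observed, so nonsense substitutions
  belong in neither R nor S. The alternative convention (count them as
  replacement) is available via `stop_handling = "replacement"`.
* **The default region set is the whole V gene** (FR1 through FR3,
  CDRs included). A CDR-only enumeration is mathematically forced into
  the range ≈5–6 for the amino acids of the Vh186.2 CDRs (W, Y, S, T
  are replacement-susceptible), so published sequence-specific
  no-selection values near 3 can only refer to a sequence-wide
  computation. On the packaged reconstruction the acceptance script
  computes ≈3.30 for the V gene (≈3.55 with stops counted as
  replacement), ≈5.2 for CDR1+2, and ≈3.17 for the frameworks alone;
  all region sets are user-selectable, so either reading is one call
  away.

The enumeration is exact and order-invariant (tested under codon
permutations), and the synthetic generator run in neutral mode
reproduces it within binomial sampling error, closing the loop between
the two implementations.

## Clones, lineage trees, and the overlap test

A **clone** is the set of sequences sharing an identical FR1–FR4
nucleotide sequence; clone UMI totals define the clonal space
(`clonal_space()` reports the dominant-clone fraction and top-25
statistics, UMI-weighted).

**Lineage trees** grow from the germline root: at each step the
unplaced clone with the smallest nucleotide edit distance to any
current tree node is attached, and when that distance exceeds one,
inferred intermediates are inserted along one minimum-edit path so
every edge has distance one. Ties break deterministically (smaller
distance, then larger UMI count, then lexicographic sequence; among
equidistant nodes the earliest-added wins), and the edit path is
canonicalised by applying alignment-column edits left to right. Tree
**levels count edges from the root including unit-expansion
intermediates**; `tree_level_histogram()` counts observed clones only,
split into shared/compartment-private. Greedy nearest-first growth is
not guaranteed to minimise total edit cost over all attachment orders —
on random tiny instances it matches the exhaustive-order minimum most
of the time and exceeds it by one edit otherwise — and the tests assert
exactly that relation rather than pretending optimality.

The **compartment-overlap test** counts distinct clonal sequences (with
at least `min_mutations` nucleotide mutations, default 2) present in
both compartments, then rebuilds that count under a null in which all
sequence instances are pooled and compartment labels are reassigned at
random, preserving per-compartment instance counts (1000 shuffles by
default). The lower-tail p-value uses the +1 pseudo-count convention,
`p = (#{null ≤ obs} + 1)/(n + 1)`, and so is never exactly zero. Because
the overlap statistic is discrete, this p-value is **valid but
conservative** (super-uniform) — exact uniformity under the null is a
property only of the tie-randomised p-value, and the test suite checks
precisely that pair of facts: the randomised p passes a
Kolmogorov–Smirnov uniformity test, and the reported p is never
anti-conservative.

## The affinity-maturation model

Each cell `i` carries a scalar fitness `w_i ≥ 0`. Birth and death are
Poisson processes with rates

```
lambda_i = lambda0 * f_lambda(w_i) / mean(f_lambda)
delta_i  = delta0  * f_delta(w_i)  / mean(f_delta) + (lambda0 - delta0) * M / C
```

with Hill-type modulations `f_lambda(w) = 1 + (g_lambda − 1)·w^h/(1 +
w^h)` and `f_delta(w) = (1 + w^h)/(1 + g_delta·w^h)`, so that
`f(0) = 1`, `f_lambda → g_lambda` and `f_delta → 1/g_delta` for
`w ≫ 1`. The mean normalisation conserves the population averages
exactly — mean birth rate `lambda0`, mean death rate `delta0` plus the
capacity term — for any fitness distribution; the tests assert this to
1e−9 together with the closed forms for homogeneous populations and for
`M = C` (zero net growth). At division one daughter mutates,
`w_child = max(0, w_parent + N(0, sqrt(2D)))`; the parent keeps its
fitness.

Scenarios (all share a competition-free growth phase `t < T_g` with
`f ≡ 1`):

* **no_selection** — `f ≡ 1` throughout; fitness drifts neutrally.
* **lung_no_decay** — full selection from `T_g` on.
* **lung** — additionally, the average growth rate decays after
  `T_dec`: `lambda0_eff = (lambda0 − delta0)·exp(−kappa·(t − T_dec)) +
  delta0`, continuous at `T_dec` and bounded below by `delta0`. The
  decay exponent is implemented as `exp(−kappa Δt)` with `kappa > 0`
  interpreted as a decay-rate magnitude.
* **lymph_node** — cells shuttle DZ↔LZ as Poisson processes with rates
  `k_DZLZ`, `k_LZDZ`; only DZ cells divide, compensated by
  `lambda0_eff = alpha_LN·lambda0` (`alpha_LN = 2` offsets 50% DZ
  occupancy at equal rates). Per-cell rates are frozen between
  transitions: the death rate is refreshed on DZ→LZ transit, the birth
  rate only on LZ→DZ re-entry; LZ cells cannot divide. Newborn cells
  enter the DZ with a freshly computed birth rate. At `T_g` zones are
  assigned from the stationary split `k_LZDZ/(k_DZLZ + k_LZDZ)`.

Design choices made where the formulation was genuinely open:

* **Population averages** `mean(f_lambda)`, `mean(f_delta)` are taken
  over *all* live cells in the lymph-node scenario (not zone-restricted
  subsets).
* **Capacity term.** By default (`capacity_lambda0 = "auto"`) the
  lymph-node scenario uses `alpha_LN·lambda0` in the capacity term —
  the modified rate replaces the baseline throughout the formalism
  there — while the lung decay leaves the baseline in place (the decay
  modifies only the birth side). With the baseline rate in the
  lymph-node capacity term the population would equilibrate far above
  the nominal capacity, contradicting its meaning; both alternatives
  remain selectable.
* **Fitness domain.** `w` is clamped at zero and unbounded above
  (high-fitness behaviour is part of the model); founders draw
  `w0 ~ U(0, 1)` unless fixed.

### Simulation scheme and numerics

The simulator is an event-driven exact algorithm (next-event sampling
over the total rate), written in C++ for throughput; a run at the
default scale executes on the order of 10^5 events. Conservation makes
the total birth and death rates available in closed form in the
lung-type scenarios, so only the *identity* of the affected cell needs
a weighted draw. Between events in the decaying-lung regime the total
rate only falls, so the time-varying process is simulated by thinning
(propose with the current rate, accept with the ratio at the proposed
time); rate-regime boundaries (`T_g`, `T_dec`) are handled by advancing
to the boundary and redrawing, which is exact for exponential clocks.
Running sums of the Hill factors are refreshed in full every 4096
events to eliminate floating-point drift. All randomness flows through
R's RNG, so a `sim_config()` seed fully reproduces a trajectory,
including its optional event log.

### Parameters and defaults

The defaults are the package's own desk-scale operating point, chosen
once: `lambda0 = 2/day`, `delta0 = 0.5/day`, `g_lambda = g_delta = 2`,
`h = 2`, `C = 2000` cells, 50 founders, `T_g = 5 d`, `T_end = 12 d`,
`T_dec = 7 d`, `kappa = 0.5/day`, `k_DZLZ = k_LZDZ = 6/day`,
`alpha_LN = 2`. The fitness diffusion default is `D = 0.001`: with the
per-division step `sqrt(2D) ≈ 0.045` the no-selection control stays at
its founder mean over the 12-day horizon, as a neutral control must. A
step an order of magnitude larger makes the zero-clamp act as a
reflecting boundary and drifts the neutral control upward by ~0.3 —
a numerical artefact, not selection — which is why the larger value was
rejected. At these defaults the lymph-node/lung contrast is
qualitatively the published one (larger clones and a more dominant
clone in the lymph node, flat neutral control); the quantitative
clone-size ratio lands near 10 rather than the published fourfold,
which is expected to be sensitive to the unavailable original parameter
table and is reported as computed, not tuned.

Ensembles (`ensemble()`) derive per-run seeds as `seed + run` and
report day-12 statistics with SEM; the acceptance script uses 100-run
ensembles, the unit tests smaller ones.

## The synthetic-repertoire generator

`generate_repertoire()` produces ground-truth repertoires so every
analysis stage is testable offline: lineages grow from the germline as
chains of point-mutation rounds (rounds ~ Poisson, mutations per round
~ zero-truncated Poisson); proposals are uniform single-base
substitutions (optionally CDR-biased), accepted with probability 1 for
silent and `s/max(1, s)` versus `1/max(1, s)` for replacement versus
silent, so `selection_strength = 1` reproduces exactly the uniform
process the enumeration baseline describes; W33L can be planted
per-compartment; the isotype motif (with subclass wildcards filled) is
appended in a short constant-region context; UMI counts are
1 + geometric; a configured fraction of lineages appears in both
compartments. The truth table records lineage, mutation positions,
isotype, sharing, and planting per record, and the generator is
deterministic given its seed.

What the generator emulates: per-lineage mutation accumulation from a
single germline, replacement selection, compartment structure with
controllable sharing, isotype mixtures (IgA essentially lung-restricted
in the defaults), UMI weighting. What it does not: AID hotspot motifs
or any sequence-context mutation bias, indels (off by default — clone
and R/S logic are point-mutation-centric), class-switch phylogeny
within lineages, or sequencing error. Closed-loop recovery (≥99%
isotypes, ≥95% mutation positions, exact sequence-level shared-clone
recovery at ~1000 UMIs) therefore demonstrates internal correctness of
the pipeline, not robustness to real-data artefacts such as alignment
ambiguity around indels or degraded base quality.

One subtlety the closed loop surfaced: with many single-mutation
lineages, identical clones arise *convergently* in both compartments.
Sharing is a property of the sequence, so the ground truth for overlap
recovery is sequence-level co-presence, which includes these convergent
clones alongside the planted ones.

## Problem sizes

The shipped tests and the acceptance script run at sizes chosen for a
single CPU: 200 random pairs for the alignment oracle, 20–25 instances
for the tree oracle (≤5 leaves, brute-force over attachment orders),
4000 shuffles against the exact 8-instance permutation distribution,
200 null datasets for the p-value calibration, ~350-record /
1000+-UMI synthetic repertoires for closed-loop recovery, 100-run
ensembles for the scenario contrast, and a 10^4-day trajectory for the
DZ-occupancy check.

## Known limitations

* The germline is a labelled reconstruction; sequence-derived constants
  shift slightly under the canonical allele.
* Single-germline design: no V(D)J assignment across gene segments, no
  light chains, no UMI consensus building (upstream tools own those).
* The overlap test's reported p-value is conservative by construction
  (discrete statistic); use the null draws in the returned object if a
  randomised p is needed.
* Greedy lineage growth can exceed the optimal attachment order by an
  edit on adversarial instances; tree topologies near ties depend on
  the documented tie-breaking.
* The simulator has no spatial structure, no explicit antigen or T-cell
  agents, and no sequence-level genotype; fitness is the scalar `w`.
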