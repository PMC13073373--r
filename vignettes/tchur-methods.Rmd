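---
title: "Biophysical sequence design with TC-HUR: model, algorithm and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Biophysical sequence design with TC-HUR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tchur)
```

## The design problem

A storage oligo must satisfy conflicting biophysical requirements at once:
balanced GC content for duplex stability, homopolymer runs no longer than
3 nt to avoid polymerase slippage, a melting temperature inside a PCR-safe
window, moderate stacking free energy (neither too weak nor kinetically
trapped), sufficient Hamming distance from other sequences in the pool,
and low similarity to its own reverse complement to avoid hairpins and
self-dimers. `tchur` expresses all six as soft quadratic (or, for the
reverse-complement term, linear-above-threshold) penalties and minimizes
their weighted sum. Soft constraints are deliberate: in a high-dimensional
discrete space the feasible region for the hard versions of all six
constraints may be empty, and the weighted formulation lets the optimizer
trade residual violations off against each other.

Two terms are structurally coupled: the melting-temperature model used here
is a function of GC content alone, `Tm = 64.9 + 41·(GC% − 16.4)/100`, so at
50% GC the predicted Tm (78.7 °C) sits above the default [55, 65] °C
window. The GC term pulls towards 50%, the Tm term towards ≤ 16.6%; the
optimum under the default weights lies between (GC in the high 30s to low
40s, Tm in the low 70s). This is a property of the model, not a defect of
the optimizer, and it is why converged designs report a non-zero total.

## Fitness terms and their defaults

| term | form | default parameters |
|------|------|--------------------|
| GC | `(GC% − 50)²` | ideal 50% |
| homopolymer | `Σ (h_k − 3)²`, runs `h_k > 3` | limit 3 nt |
| free energy | `|mean step ΔG − target|·100` | target −1.45 kcal/mol |
| Tm | squared distance to nearest bound | window [55, 65] °C |
| Hamming | `(d_min − min d)²` if `min d < d_min` | archive empty, `d_min` 0 |
| reverse complement | `(r − 0.15)·100` if `r > 0.15` | threshold 15% |

Weights are not part of the published model beyond the statement that
homopolymer and melting-temperature terms are prioritized; the package
defaults are `w_obj = (gc 1, hp 10, dg 1)` and `w_cons = (tm 5, hamming 1,
rc 5)`, chosen once to encode that priority. All reported fitness values
are therefore weight-relative: two configurations are comparable only
under the same `fitness_weights()`.

Three formulation details were genuinely open and are fixed as follows:

- **Free-energy divisor and sign.** The mean step energy divides by the
  number of dinucleotide steps `L − 1` (not `L`), so a sequence whose every
  step equals the target scores exactly 0 at any length; the deviation is
  taken as an absolute value, since a signed quantity has no meaning inside
  a minimization sum.
- **Reverse-complement similarity** is the global position-wise match
  fraction against the full-length reverse complement (random expectation
  0.25). Windowed or local variants would detect short hairpins better but
  are out of scope.
- **Empty archive** disables the Hamming term (single-sequence design
  mode). The benchmark harness instead installs one seeded random
  reference with `d_min = ⌈0.75·L⌉`, the expected Hamming distance of a
  random pair, so the term is active but not binding for well-mixed
  sequences.

The ΔG table ships as `inst/extdata/nn_dg37.tsv` (unified nearest-neighbour
stacking energies at 37 °C); any 16-entry table can be supplied through
`thermo_table(file = ...)`.

## The TC-HUR optimizer

The search runs over the continuous relaxation `[0,3]^L`; every fitness
evaluation first clips to bounds and digitizes round-half-up (1.5 → 2), so
the continuous vector is purely internal state and fitness is always that
of a valid sequence. With switching ratio `SR = 0.5` and budget `Tmax`,
iterations `t ≤ T_HGS = round(SR·Tmax)` run phase 1; the rest run phases
2+3 together.

**Phase 1 — hunger-driven exploration.** Each individual keeps a hunger
memory: reset to 0 on reaching the global best, otherwise incremented and
capped. Normalized hungers act as per-individual probabilities of
aggressive self-perturbation (`x·(1 + randn)`); otherwise the individual
moves towards the best (with probability `sech|f_i − f_best|`, so
exploitation pressure grows near the incumbent) or between two random
peers. The move amplitude vector is uniform in `[−a, a]` with
`a(t) = 2·(1 − t/T_HGS)` shrinking over the phase. Once per iteration a
Cauchy jump perturbs the best solution with heavy-tailed noise scaled by
`β(t) = 0.015·(1 − t/T_HGS)`; the candidate replaces the best only on
improvement. The heavy tails matter: occasional long-range jumps can break
several consecutive reverse-complementary positions in one move, which
Gaussian perturbations of comparable scale almost never do.

**Phase 2 — elite refinement.** The best 30% of the population receive
candidates `x_best + r·f_refine(t)·(x_best − x_rand)` with
`f_refine(t) = 0.008·e^(−3t/Tmax)`, accepted greedily. Greedy acceptance is
stated for the Cauchy jump and extended here to refinement: it preserves
elitism at the cost of some diversity, which phase 3 restores.

**Phase 3 — targeted mutation.** Each post-switch iteration, a random 20%
of the population undergo constraint-directed repair at rate
`0.02 + 0.03·(t − 0.5·Tmax)/(0.5·Tmax)`: only positions inside homopolymer
runs > 3 or matching the complement of their mirror position are touched,
and each flip chooses a base that breaks the violation. Homopolymer repairs
additionally avoid both current neighbours, which guarantees that a
full-rate pass leaves zero homopolymer penalty — the property the test
suite asserts on a 200-nt poly-A sequence.

Unspecified constants were fixed once: the hunger increment is
`uniform(0,1]` per iteration (only relative hunger matters through the
normalization, so the scale is benign); the diversity-weight coefficients
are `w1 = w2 = 1`; branch 1 of the position update is tested before branch
2, with fresh uniforms per individual per iteration; mutation targets are
drawn uniformly (the source does not say *which* 20%). All are
`tchur_config()` fields.

**Trace convention.** Iteration `t` records the elitist best *before* that
iteration's updates, and no updates run at `t = Tmax`. The trace is
non-increasing by construction, its first entry is the initial-population
best (the usual convergence-curve convention), and a budget of one
iteration returns the digitized best initial individual for every
algorithm, TC-HUR and baselines alike.

## Baselines

PSO (global-best velocity form, `c1 = c2 = 2.05`, `w = 0.4`), GWO
(alpha/beta/delta averaging, `a` linear 2 → 0), HGS (the original
two-weight hunger model with `PUP = 0.08`, `LH = 10 000` — deliberately
distinct from TC-HUR's phase 1, which uses the sensitivity-based variant),
and RUN (a condensed RK4-displacement search with an
enhanced-solution-quality move, `a = 20`, `f = 0.1`, greedy selection).
Only parameter values, not update rules, are fixed by the benchmark
protocol; the canonical published forms are used, and the benchmark
results for baselines are qualitative (ordering), never value-level
reproductions.

## Synthetic payloads

`make_benchmark_text(target_nt, seed)` draws uniform random bytes that
encode to exactly `target_nt` nucleotides (2 bits/nt, MSB-first bit pairs,
zero-padded final partial byte with the pad length recorded). It stands in
for an undisclosed 1853-nt natural-language benchmark text. Uniform bytes
are the right stand-in for *this* pipeline because the optimizer explores
the sequence space freely from a random population — the payload only sets
the problem dimension and seeds one individual — but they do not emulate
the skewed byte statistics of natural text, so encoded-payload GC bias of
real archives is not represented. Passing tests demonstrate optimizer and
channel behaviour, not recovery guarantees for structured payloads (no
error-correcting code layer is included; that is explicitly out of scope).

## The error channel

`simulate_read()` makes one left-to-right pass over the reference; each
position draws exactly one of deletion, insertion-before (the reference
base is then emitted unchanged), substitution, or match. This makes the
expected per-nt event rates equal to the profile probabilities — the
calibration property the tests check within 3 standard errors over 10⁷
position draws. Indel probabilities are multiplied (default ×3) inside
homopolymer runs ≥ 4 nt to emulate slippage; when boosting would push the
per-position event probability past 1 the three error probabilities are
rescaled proportionally. Insertion bases are uniform over the alphabet;
substitution alternatives are uniform over the three non-reference bases.

The regime → probability map is a calibration, not a reproduction of any
external simulator: `p = base_rate × central_cycles` with per-cycle rates
(sub 6e−5, ins 1.6e−4, del 4e−5) and central cycle counts 50/200/500 for
the low/medium/high regimes, placing the high regime near per-nt rates
0.03/0.08/0.02. Published NED values from other simulators are treated as
ordering evidence only.

Scoring: NED is Levenshtein distance over the longer length (bounded in
[0,1]); error decomposition backtraces one minimal alignment with the
deterministic tie-break match > substitution > deletion > insertion, so
counts always sum to the edit distance and are reproducible even though
minimal alignments are not unique. "Homopolymer context" means within 1 nt
of a reference run ≥ 3 for indels, strictly inside for substitutions;
percentages over zero substitutions are reported as `NA`, never 0.

## Numerical and degenerate-input conventions

- Digitization is round-half-up after clipping; `NaN` positions are an
  error, never silently clipped.
- All-zero hunger vectors normalize to the uniform distribution.
- Length-1 sequences have no dinucleotide step; the ΔG penalty is 0 with a
  warning.
- Two empty strings have NED 0 by convention.
- A fully tied fitness matrix yields Friedman statistic 0 (p = 1) rather
  than the undefined ratio.
- Per-run benchmark seeds are `master_seed + run_index`, identical across
  algorithms so runs are paired for the signed-rank test; every source of
  randomness flows from the single seeded generator of the run.

## Problem sizes used by the test suite

The distribution-level and ordering checks run at reduced scale, chosen as
the smallest sizes at which the claims are meaningful rather than noisy:
mini-runs at L = 50, N = 10, T = 20 for the elitism/bounds properties; the
TC-HUR ≤ HGS ≤ random-search mean-fitness ordering at L = 400, N = 30,
T = 60 over 10 paired seeds; channel calibration over 10⁴ reads of a
1000-nt reference. The full published protocol (L = 1853, N = 50,
T = 100, 30 runs per algorithm) is available unchanged through
`run_experiment()`.

## Known limitations

- The Tm model is a GC-only empirical line; salt- and
  concentration-parameterized models, true secondary-structure prediction
  (MFE folding, hairpin enumeration) and cross-hybridization scores are
  out of scope.
- Absolute fitness values are weight-relative; published absolute numbers
  are not reproducible because the weights and benchmark text behind them
  are not disclosed.
- The channel is a structural model of substitution/insertion/deletion
  processes, not a port of any platform-specific (nanopore/synthesis)
  error profile.
- Single-sequence design: joint design of orthogonal libraries (mutual
  Hamming/cross-talk constraints across millions of oligos) is future
  work; the archive mechanism handles small explicit pools only.
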