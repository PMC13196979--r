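---
title: "Non-deterministic genotype-phenotype maps: models, properties and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Non-deterministic genotype-phenotype maps: models, properties and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

A genotype-phenotype (GP) map assigns phenotypes to the `K^L` sequences of
length `L` over an alphabet of size `K`. Classic GP-map theory treats this
assignment as deterministic — one categorical phenotype per genotype — but
many biological systems are better described *non-deterministically* (ND):
an RNA sequence populates a Boltzmann ensemble of secondary structures, an
HP lattice protein folds into several minimum-or-near-minimum-energy
conformations, and stochastic tile self-assembly produces a distribution of
shapes. In an ND GP map every genotype `g` carries a probability
distribution `P(p|g)` over phenotypes, and mutations shift these
distributions continuously rather than flipping a single label.

`ndgpmap` provides

* a tuneable **synthetic generator** of ND GP maps;
* exhaustive builders for two biophysical reference maps — the **4x4 HP
  lattice protein** and **Polyomino tile self-assembly** — plus an **RNA
  adapter** that delegates free energies to an injected evaluator;
* the full **ND property suite**: phenotypic frequency, genotypic and
  phenotypic robustness and evolvability, the mutational-neighbour
  covariance diagnostic, the genotypic trade-off bound and map-level
  summary statistics.

## The five map properties

With `P(p|g)` the ensemble probability, `N(g)` the `(K-1)L` point-mutation
neighbours of `g`, and sums over genotypes running over all `K^L`
sequences:

* **phenotypic frequency** `f_p = (1/K^L) sum_g P(p|g)` — the mean
  ensemble probability of `p`, whose variation across phenotypes is
  *phenotypic bias*;
* **genotypic robustness**
  `rho_g = (1/(K-1)L) sum_p P(p|g) sum_{g' in N(g)} P(p|g')` — the
  probability that a random mutation conserves the phenotype;
* **phenotypic robustness** `rho_p` — the same conservation probability
  conditioned on the initial phenotype being `p` (the shared double sum
  divided by `K^L f_p (K-1)L`);
* **genotypic evolvability**
  `eps_g = sum_p P(p|g) sum_{p' != p} (1 - prod_{g'} (1 - P(p'|g')))` —
  the expected number of *distinct* alternative phenotypes accessible by
  single mutations;
* **phenotypic evolvability**
  `eps_p = sum_{p' != p} (1 - prod_g prod_{g'} (1 - P(p'|g') P(p|g)))` —
  the number of alternatives accessible from anywhere `p` is produced.

Frequency and robustness are normalised into `[0, 1]`; evolvabilities
count phenotypes (`<= n_p - 1`, with `n_p` the number of phenotypes with
`f_p > 0` in the map, not the configured total). Two structural results
frame the analyses: the genotypic trade-off bound
`eps_g <= (K-1)L (1 - rho_g)` (a genotype has only `(K-1)L` neighbours, so
robustness and evolvability compete), and the equivalence between *genetic
correlations* `rho_p > f_p` and a positive covariance of `P(p|g)` between
mutational neighbours, which `neighbour_covariance()` estimates directly
against a random-pair null.

## The synthetic model

`build_synthetic_map()` composes three ingredients:

1. **Additive genotype dependence.** Genotypes are +1/-1 spin vectors;
   each phenotype owns an `L`-vector `v_p` and
   `G_p(g) = -(g . v_p)` (optionally plus a phenotype constant). A single
   mutation flips one spin and therefore changes one summand, which is the
   mechanistic source of genetic correlations in this model.
2. **A nonlinearity** converting a genotype's `n_p` scalars into
   probabilities. The default is the Boltzmann form
   `P(p|g) ∝ exp(-G_p(g)/T)`; five alternatives (shifted linear,
   inverse-squared, Gaussian, ReLU, Softplus) are provided, all
   non-negative, monotone (lower `G`, weakly higher probability) and
   converging to the uniform ensemble `1/n_p` as `T` grows.
3. **A parameter initialisation** for the `v_p`: elementwise N(1, 1) by
   default, with log-normal(0, 1), uniform[0, 1], norm-rescaled normal,
   binary {0.25, 0.75} and normal-with-offset alternatives. The binary
   scheme deliberately mimics the discrete energy spectrum of the lattice
   protein; the rescaled scheme removes the vector-norm differences that
   `vector_norm_frequency()` shows to drive phenotypic bias.

### Tunable parameters

| parameter | meaning | default / convention |
|---|---|---|
| `L` | sequence length (positions) | 15 in the reference analyses |
| `K` | alphabet size | 2 (spins); `K = 4` uses a per-(phenotype, position, symbol) coefficient tensor whose `K = 2` slice with `{+v, -v}` recovers the dot product |
| `n_p` | number of phenotypes | 20–500 in the reference analyses |
| `T` | stochasticity (dimensionless, same scale as `G`) | `NULL` defers to the mean-gap rule; `Inf` is the exact uniform limit |
| `cutoff` | probability floor | `1e-4` |
| `seed` | RNG seed | draw order is phenotype-major, position-minor, so parameter sets are stable |

The **mean-gap rule** (`reference_T()`) sets `T` to the genotypic average
of the difference between the two lowest `G` values. It keeps the *level*
of non-determinism comparable when `n_p` or the initialisation changes:
the same absolute `T` means different things when the `G` spectrum
changes scale. Under this rule a typical genotype's top ensemble
probability is around 0.3–0.5 — genuinely non-deterministic, well away
from both the deterministic and the uniform limit. Stronger low-`T`
features (e.g. robustness ranges above 0.5) appear when `T` is pushed a
factor 3–5 below the mean gap; the builders expose `T` directly, and the
pipeline expresses sweeps as explicit lists, never hard-coded values.

The **deterministic projection** maps each genotype to its lowest-`G`
phenotype, assigning the reserved *undefined* phenotype when the two
lowest `G` values lie within `1e-4` of each other (the same tie
convention as the lattice model's discrete spectrum).

### What the generator emulates — and what it does not

The synthetic maps reproduce the features the biophysical maps share:
phenotypic bias spanning orders of magnitude, genetic correlations,
the genotypic robustness-evolvability trade-off and a non-negative
phenotypic robustness-evolvability trend. They do **not** emulate
sequence-structure specifics: there is no notion of a structural
phenotype, no epistatic (second-order) terms in `G`, no correlation
structure between parameter vectors, and the number of phenotypes is
fixed rather than emergent. Tests passing on synthetic maps therefore
validate the property machinery and the qualitative shared features, not
any particular biophysical system.

## The lattice-protein map

Chains of `L = 16` H/P residues on the 4x4 lattice. Conformations are the
compact (lattice-filling) self-avoiding walks, deduplicated under the 8
grid symmetries with the chain direction kept distinct (backbones are
directional); the canonical representative of a walk is the
lexicographically smallest coordinate sequence among its 8 transforms.
This yields 69 conformations, each with exactly 9 contacts. Contact
energies default to `cHH = -2.3`, `cHP = -1`, `cPP = 0`, a potential
chosen because it minimises ground-state degeneracy among standard HP
potentials — and even so, about 62% of the 65536 genotypes have a
degenerate (within `1e-4`) minimum energy, which is why this map behaves
like a high-stochasticity ensemble model: weak phenotypic bias and
phenotypic evolvabilities saturating at `n_p - 1`. Ensembles are
Boltzmann at a dimensionless `kBT` (the builder exposes it; `1` is the
reference single choice and `{0.5, 1, 2}` a reasonable sweep).

## The Polyomino map

In `S_{t,c}`, a genotype of length `4t` over `0..c-1` labels the faces
(N, E, S, W) of `t` square tiles; label 0 is inert and odd label `a`
binds `a + 1`. `assemble_once()` seeds with the first tile, then
repeatedly places a uniformly random (empty perimeter cell, tile type,
rotation) whose placement binds at least one adjacent face — one
matching interface suffices, touching non-binding faces are allowed, and
placement is irreversible. Assemblies exceeding `(4t)^2/2` cells (growth
can be unbounded) return the reserved *undefined* phenotype. Shapes are
occupied-cell sets canonicalised under rotation and translation but not
mirroring. `estimate_ensemble()` repeats the assembly 5000 times and
merges shapes seen fewer than 50 times into the undefined placeholder
(their frequencies cannot be estimated reliably; cut-offs of 25 or 100
leave the qualitative picture unchanged).

Full maps exploit the **assembly graph**: genotypes whose tiles have the
same binding topology produce the same ensemble, so assembly is
simulated once per class. The canonical key minimises the genotype over
tile permutations and per-tile rotations after canonical relabelling
(unbindable faces to 0, binding pairs renamed in order of first
occurrence); residual collisions are merged by VF2 isomorphism on a
directed face graph (tile cycles keep mirrored tiles distinct). One
refinement is deliberate: because the *first* tile seeds the assembly,
a bare tile swap can move the seed onto a tile that is disconnected from
the active binding component and change the ensemble. The key therefore
first zeroes every tile the seed cannot reach through binding
interactions — such tiles can never attach — which restores exact
ensemble-equality within classes while still merging everything the
swap/rotation/relabel operations merge among seed-connected tiles.
Sampling error of a class representative propagates to the whole class;
the per-genotype class index and tallies are exposed for exactly that
reason.

## The RNA adapter

For short sequences the package enumerates **all** pseudoknot-free
secondary structures compatible with the sequence (Watson-Crick plus
GU/UG wobble pairs, hairpins spanning at least 3 unpaired bases,
including the open structure) and Boltzmann-weights them with free
energies from an injected evaluator `(sequence, structure) -> G`;
`rnaeval_energy()` adapts the external `RNAeval` tool to that contract,
and the adapter fails with an explicit message when no evaluator is
available. The open structure is registered as the undefined phenotype:
at these lengths its prevalence is an artefact of the sequence being too
short to fold stably. No energy model is implemented natively, and the
full `4^12` map is intentionally out of scope — it depends on the
version of the external energy model.

## Numerical choices

* **Cutoff without renormalisation.** `P(p|g) < 1e-4` is treated as 0.
  The retained probabilities are *not* rescaled: the property formulas
  divide by `K^L` and `(K-1)L`, and silent renormalisation would change
  those sums. `apply_cutoff(renormalise = TRUE)` exists so the
  alternative reading can be tested explicitly, and every map records
  which convention it carries.
* **Log-space products.** The products `prod (1 - x)` in both
  evolvabilities are accumulated as `sum log1p(-x)` with `x` clamped at
  `1 - 1e-12`; `eps_p` involves up to `K^L (K-1) L` factors, which would
  underflow as a direct product. Only stored (above-cutoff) entries
  contribute non-unit factors, so the compiled kernel's cost scales with
  the stored ensemble sizes.
* **Overflow-safe forms.** The Boltzmann form subtracts the row minimum
  before exponentiating; Softplus switches to its linear asymptote for
  large arguments. `T = Inf` (the uniform limit) is handled exactly,
  as a flagged limit rather than a large float. A ReLU genotype whose
  weights are all zero receives the uniform ensemble and is counted in a
  warning, keeping the map total.
* **Ties.** Deterministic projections use a `1e-4` tie tolerance and the
  undefined phenotype; the trade-off check allows `1e-4` of numerical
  slack, matching the accumulation error observed at `K^L ~ 6.5e4`.
* **Undefined phenotypes** are excluded from every sum over phenotypes,
  but their ensemble mass stays in place — frequencies of the remaining
  phenotypes need not sum to 1.

## Problem sizes

The test suite exercises brute-force oracle equivalence on random maps
with `K^L <= 256` (100 maps), exact closed-form checks of the uniform
limit at `L = 8`, the full 4x4 lattice map (65536 genotypes, 69
phenotypes), synthetic reference maps at `L = 15`, `n_p = 100`, and the
exhaustive `S_{2,3}` Polyomino map (6561 genotypes) at 5000 assembly
repetitions; `S_{3,3}` (531441 genotypes) is supported by the same code
path but is a long-running batch job rather than a test-suite citizen.
These sizes were chosen so that each family is exercised exhaustively at
a scale where every quantity can also be recomputed independently.

## Known limitations

* Genotype spaces are dense and in-memory (`K^L` guard at `1e7`); there
  is no streaming mode and no position-dependent alphabet.
* The Polyomino move kinetics (uniform over binding placements, no
  detachment, unweighted tile types) is one concrete reading of
  stochastic tile assembly; the move distribution sits behind
  `assemble_once()` so alternatives can be swapped in.
* `eps_p` is quadratic in ensemble sizes along edges; for maps whose
  ensembles stay dense at `K^L > 10^5` it is the dominant cost
  (`phenotypic_evolvability = FALSE` skips it).
* The synthetic `K = 4` generalisation draws an independent coefficient
  per (phenotype, position, symbol); it degenerates exactly to the spin
  model at `K = 2` but is one of several possible encodings.
* Negative `T` for the ReLU form (which would sharpen bias at the cost
  of the form's linear-approximation role) is rejected by design.
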