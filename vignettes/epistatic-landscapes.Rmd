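---
title: "Models, metrics and simulations for complete epistatic fitness landscapes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, metrics and simulations for complete epistatic fitness landscapes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epiland)
```

## Scope

`epiland` analyses combinatorially complete biallelic fitness landscapes:
all `2^L` combinations of a fixed set of `L` mutations, each assigned a
real-valued fitness (in the motivating application, a log-enrichment
score from a selection experiment on an antibody variable domain, used as
a proxy for folding stability).  The package covers four layers:

1. **Models.** A specific-epistasis (Ising-type) expansion
   `F(s) = Σ h_i s_i + Σ J_ij s_i s_j + Σ K_ijk s_i s_j s_k` over
   wild-type/mutant spins `s_i ∈ {0, 1}` (so the all-wild-type germline
   has fitness 0 by construction), and a global-epistasis model
   `F(s) = g(Σ h_i s_i)` with a monotone nondecreasing nonlinearity `g`.
2. **Ruggedness statistics.** Directed correlations of fitness effects
   `γ_{i→j}`, their generalization `γ(n, d)` to pinned sublandscapes,
   local-optima censuses, and the slope-to-roughness funneling ratio.
3. **Evolutionary dynamics.** Strong-selection weak-mutation (SSWM)
   adaptive walks as absorbing Markov chains, and Wright–Fisher (WF)
   populations on a ring lattice with a tunable migration range.
4. **Paths and visualization.** Lines of descent, path-weight ensembles,
   scaled path entropy, mutation-ordering matrices, stepwise
   distributions of fitness effects, and seeded 2D embeddings.

## Genotype encoding

A genotype is a 0/1 vector over sites `1..L` (`1` = mutated).  Site `i`
maps to bit `2^(i-1)` of an integer code, so a complete landscape is a
numeric vector indexed by `code + 1`; bitstrings in files list site 1
first.  This fixed convention gives O(1) lookups and makes the
Walsh–Hadamard machinery index-free.

## Inference and denoising

Under i.i.d. Gaussian measurement noise of equal variance per genotype —
the simplest model consistent with noise dominated by finite sequencing
sampling — maximum likelihood for the specific-epistasis model is
ordinary least squares on the subset-product design.  There is no
intercept, which enforces zero germline fitness; noisy germline
measurements are thereby handled without any explicit re-referencing.
The interaction order is selected by 10-fold cross-validation over
genotypes (seeded fold assignment), minimizing held-out squared error
with a one-standard-error tie-break toward the lower order, which favors
parsimony when orders are statistically indistinguishable.

The spectral route uses the Walsh–Hadamard transform in the `{−1, +1}`
basis with the `2^-L` normalization, so the order-0 coefficient is the
mean fitness and Parseval reads `Σ_s F(s)² = 2^L Σ_S a_S²`.  Band-pass
denoising zeroes all coefficients of interaction order above 3 — in this
data class, third order is where signal ends and higher orders reflect
noise — and is a projection (idempotent).  No magnitude thresholding is
applied by default; an optional threshold argument exists but is off,
since order truncation alone is the documented procedure.  Truncation is
performed in the Fourier basis and converted exactly to `{0, 1}`-basis
coefficients for reporting; order-limited support is preserved by the
basis change in both directions, so this choice is testable but not
consequential.

The global-epistasis fit alternates between a least-squares update of the
latent additive effects `h` (using pseudo-observations obtained by
inverting the current `g`) and an isotonic-regression update of `g`
discretized at 50 equally spaced knots with linear interpolation, until
the squared error stabilizes.  Because the model is invariant to affine
reparameterization, identifiability is fixed by `‖h‖₂ = 1` with the
largest-magnitude effect positive; `g` absorbs scale and offset.

## Ruggedness statistics

`γ_{i→j}` is the Pearson correlation between the fitness effect of
mutation j across backgrounds and the same effect with mutation i
present, over all backgrounds with both focal sites wild-type.  A value
near 1 indicates additivity; values at or below 0 indicate sign
epistasis.  Degenerate correlations (effect vectors constant up to
rounding noise) are reported as missing and excluded from summaries,
never imputed: on a *purely* additive landscape every per-pair effect
vector is constant, so the per-pair matrix is entirely missing there —
the additivity limit is instead exhibited exactly by the pooled
`γ(n, d)` estimator, which pools effects over all free sites j and all
background pairs at Hamming distance d within a pinned subspace and
equals 1 on additive landscapes.  Pair enumeration is exhaustive (no
sampling) — a `2^10` space is fully enumerable.  The directed estimator
reads "the presence of mutation i" as the 0→1 flip; a symmetrized
variant is available behind a flag for sensitivity analysis.

The funneling metric fits the closest additive landscape by least
squares after shifting the germline to zero fitness, and reports the
mean slope `s = L^-1 Σ |h_i^(a)|`, the roughness
`r = sqrt(2^-L Σ (F − F^(a))²)` and `s/r` (`Inf`, as a sentinel, when
the fit is exact to rounding).  Large `s/r` means a smooth, Mt.
Fuji-like global shape.

## NK landscapes

The NK generator uses the standard variant: uniformly sampled
neighborhoods of `K` distinct partners per site and i.i.d. uniform
`[0, 1)` contribution tables over the `2^(K+1)` local states (adjacent
neighborhoods and Gaussian contributions are available behind flags),
fitness being the site-mean shifted to zero germline fitness.
Constrained ensembles are produced by rejection sampling only — keeping
draws whose local-optima count and germline-to-optimum distance match
the targets exactly — which preserves the NK distribution conditioned on
that topography; no landscape surgery is performed.  Per-attempt seeds
derive arithmetically from the master seed, so accepted sets are
reproducible and order-independent.

## Evolutionary dynamics

The SSWM chain moves from a genotype to a neighbor with probability
proportional to the positive fitness increment (a uniform-over-beneficial
kernel is available behind a flag, since the exact kernel is a modeling
choice); local optima are absorbing, and exact absorption probabilities
come from solving `(I − Q)B = R`.  Fitness-tie plateaus — measure-zero
for continuous fitness — are treated as absorbing with a warning.

WF dynamics place `Npop = 500` individuals on a ring.  Each generation,
node i synchronously copies a genotype from its `2r + 1`-neighborhood
with softmax weights `exp(F)` (computed with a global shift for overflow
safety), then every locus of every individual flips with probability
`μ = 10⁻³`.  `r = 2` is the structured condition and `r = Npop`
well-mixed (served by an exact panmictic sampling path).  A replicate
*succeeds* if the global optimum reaches the occupancy threshold
(default 0.5) strictly before any local optimum; same-generation ties
count as failure (conservative).  Replicates stop at the first decision,
which changes no outcome but saves most of the runtime; replicate seeds
derive from (master seed, replicate index).

Lines of descent follow the first individual to carry the target back
through its parent pointers; mutation events along the lineage are
replayed forward, multi-mutation generations are expanded into
consecutive single-site steps in increasing site order (a rare event at
`μ = 10⁻³`), and acquired-then-reverted mutations are retained as two
steps, so indirect paths are preserved.  Distinct paths are identified
by their exact genotype sequence, and the scaled entropy divides the
Gibbs–Shannon entropy of path weights by `ln(m)` over the `m` distinct
*realized* paths (0 when `m = 1`).  Ordering statistics count each
site's first forward (0→1) mutation among the required sites, ignoring
reversions of non-required sites, which keeps the matrix well defined on
indirect paths.

## The synthetic antibody-like fixture

Real data for the motivating system are not redistributable here, so the
package ships a synthetic stand-in: an `L = 10` landscape over sites
labelled 26, 27, 28, 31, 35 (first loop) and 50, 53, 56, 57, 58 (second
loop) — 28 and 31 are placeholder labels — constructed to reproduce the
documented qualitative topography:

- germline fitness 0; global optimum mutated at exactly 8 sites with 50
  and 57 wild-type; exactly 7 local optima;
- site 53 ("the hotspot") has the largest positive additive effect, site
  50 the most negative; third-order interactions concentrate on site 53;
- the hotspot's γ row-mean is the matrix minimum; pinning the hotspot
  mutated lowers γ(1, 1) relative to pinning it wild-type; and pinning
  it mutated raises the SSWM absorbing probability of the sublandscape
  optimum from the sub-germline.

The generator draws coefficients with this sign/magnitude structure —
single-mutant effects mostly within ±1 on the log-enrichment scale, a
hotspot effect of 1.2–1.8, mild negative bias on pairs mixing optimum
and non-optimum sites, and hotspot-centered triplet terms whose widest
components involve the optimum-absent sites 50/57, which places
suboptimal peaks in regions that cannot contest the global optimum —
and accepts the first draw for which *all* constraints verify by
exhaustive enumeration over the 1,024 genotypes, including Wright–Fisher
checks that structured populations succeed at threshold 0.5 at least as
often as well-mixed ones.  The accepted draw is frozen into
`inst/extdata/` (files are labelled synthetic) and regenerated exactly
by `make_antibody_like_landscape()` at the recorded seed and attempt.

What a green fixture test does and does not establish: the fixture
reproduces the *stated, qualitative* topography and the directional
accessibility/evolvability behavior, so pipeline code paths are
exercised end to end on realistic structure.  It does not reproduce the
real system's coefficient values (not published), its noise anatomy
(counts, PCR, sorting), or every published quantitative curve.  One
documented direction is not met by the frozen draw: its
slope-to-roughness ratio (≈0.59) does not exceed every member of the
topography-matched NK(K = 2) reference ensemble (max ≈0.69).  Within
this generator family, the exhaustively checked constraint set and an
`s/r` above the NK maximum turn out to be in tension: the suboptimal
peaks demanded by the 7-optima constraint are carved by wide interaction
terms whose residual *is* roughness, whereas the empirical system
apparently achieves heterogeneous ruggedness more "efficiently" than
independent random coefficients can.  The corresponding acceptance
property is therefore expected to fail and is intentionally left in
place rather than weakened; treating it as a falsifiable statement about
the stand-in seemed more useful than tuning it away.

The measurement-noise model is homoscedastic Gaussian per genotype and
replicate, matching the inference likelihood; replicates are independent
and the germline rows are noisy like any other (re-referencing is the
fitter's job).

## Numerical choices

- Local optima use strict inequality over all L neighbors; exact
  neighbor ties disqualify both genotypes with a warning.
- Degenerate γ entries are those whose effect-vector standard deviation
  is below `1e-9` of the largest effect magnitude (rounding-noise
  threshold).
- The WF softmax shifts by the global maximum fitness, which is
  algebraically identical per neighborhood and overflow-safe.
- Cross-validation folds, layout algorithms, t-SNE and all simulations
  are seeded; the embedding determinism contract is "same inputs + seed
  + library version → same coordinates".
- Rigid layout alignment solves the 2D orthogonal Procrustes problem
  restricted to proper rotations (no reflection, no scaling);
  reflections are available behind a flag.

## Known limitations

Alphabet is strictly biallelic; incomplete landscapes are rejected
rather than imputed; the SSWM kernel's exact published form is a
modeling choice (both common variants implemented); heteroscedastic or
count-based noise models are out of scope; and reported NK ensemble
statistics depend on the stated uniform-contribution variant.
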