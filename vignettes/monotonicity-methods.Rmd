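---
title: "Measuring monotonicity of genotype-phenotype maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring monotonicity of genotype-phenotype maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gpmono)
```

## The problem

A genotype-phenotype (GP) map over `N` biallelic diploid loci assigns a
genotypic value `G(g)` -- the mean trait value -- to each of the `3^N`
genotypes. The 2-allele content of each locus (0, 1 or 2 copies of the
allele indexed 2) induces a product partial order on genotype space: within
every genetic background, `11 < 12 < 22` at each locus. A map is *monotone*
(order-preserving) with respect to locus `k` when `G` is non-decreasing
along that chain in every background, with allele labels chosen so that
`G(11...11)` is the smallest fully homozygous value. Non-strict inequalities
deliberately admit complete dominance and magnitude epistasis; what
monotonicity excludes is *sign* behaviour -- overdominance and sign
epistasis.

Monotonicity matters because order-preserving maps are precisely the ones on
which regression on gene content works well across the allele-frequency
spectrum: they predispose for a high ratio of additive to total genetic
variance and therefore a predictable parent-offspring relationship. gpmono
quantifies monotonicity in two complementary ways and then asks, with a
mechanistic simulator, which gene-regulatory architectures produce
non-monotone maps.

## Measure 1: substitution effects

For locus `k` and each of the `3^(N-1)` backgrounds there are two
single-allele substitution effects, `G(..12..) - G(..11..)` and
`G(..22..) - G(..12..)`. Writing `P_k` for the sum of positive effects and
`N_k` for the summed magnitude of negative effects, `T_k = P_k + N_k`,

```
m_k = |P_k - N_k| / T_k,     m = sum_k m_k T_k / sum_k T_k .
```

`m_k` is invariant to allele relabelling (relabelling maps each effect to
minus the other one of its pair) and to positive affine rescaling of the
trait, and by the triangle inequality `m_k <= 1` with equality exactly when
all non-zero effects share one sign. The `T_k` weighting makes `m` an
effect-size-weighted consensus: a major locus dominates `m`, which is the
intended behaviour for a map-level summary.

Two numerical conventions are ours to fix:

* **zero tolerance.** Effects with `|s| <= zero_tol` are excluded from both
  sign sets, mirroring the strict inequalities in the sign-set definitions.
  The default is `1e-9 * (max - min)` of the genotypic values -- far below
  any biologically meaningful effect, but above the numerical noise of the
  equilibria produced by the network simulator (see below). With exact
  (catalog or file-based) maps the tolerance is effectively inactive.
* **loci without variation.** A locus with `T_k = 0` contributes no weight
  to `m` and its `m_k` is reported as `NA`. A completely flat map yields
  `m = NA` with a warning flag rather than an arbitrary 0 or 1.
* **order-breaking flags.** Monotone-with-respect-to-locus-`k` is decided
  sign-symmetrically: all beyond-tolerance locus-`k` effects share one
  sign, which is exactly `m_k = 1`. An equivalent reading -- effects
  non-negative after orienting the map by its minimal homozygote -- fails
  on maps with exactly tied homozygote corners (common in simulated maps
  when a gene saturates to zero expression), where the tie-break can leave
  a genuinely monotone-decreasing locus unflipped. The sign-symmetric flag
  is invariant to allele relabelling, like `m` itself.

The worked two-locus example (10-week body weight in a mouse F2 cross)
gives `m_1 = 0.86`, `m_2 = 0.71`, `m = 0.79`:

```{r}
mw <- catalog_map("mouseweight")
degree_of_monotonicity(mw)
```

## Measure 2: isotonic regression

The monotone component `G_M` of a map is its least-squares projection onto
the closed convex cone of maps respecting every cover edge of the partial
order; the projection is unique by strict convexity. The residual
`G_N = G - G_M` is orthogonal to the fit and sums to zero, giving the
orthogonal decomposition `G = G_M + G_N` with
`var(G) = var(G_M) + var(G_N)` and

```
R2_mono = var(G_M) / var(G) .
```

`R2_mono = 1` iff the map is monotone; it stays strictly positive even for
purely overdominant or purely epistatic maps because the nearest monotone
map is never flat-at-the-mean for such inputs. Unlike `m`, `R2_mono` is
*not* invariant to allele relabelling, so the fit applies the orientation
convention (minimal homozygote at `11...11`) by default; `orient = FALSE`
disables it. Variance is the population variance over the `3^N` genotypic
values (divisor `3^N`); the ratio is divisor-invariant.

**Algorithm.** Isotonic regression on a DAG has no single canonical solver;
we use Dykstra's cyclic projection onto the cover-edge half-spaces, which
converges to the exact projection of a point onto an intersection of convex
sets and maintains explicit non-negative per-constraint corrections (the
dual multipliers). Iteration stops when the per-cycle change and the
maximal constraint violation fall below `tol` (default `1e-10`, relative to
the value range). The converged iterate is then snapped to exact block
means over its level sets (connected components of near-equal cover edges,
grouped at `1e-7` of the range); block means are what the true projection
consists of, and they make the orthogonality identities hold to machine
precision. The polish is accepted only if it remains feasible and does not
worsen the objective, otherwise the raw iterate is returned. Correctness is
checked in the test suite against an independent generic
quadratic-programming solve of the same constrained least-squares problem
on hundreds of random 2- and 3-locus maps (objective agreement to 1e-6 and
better). Ties among optimal level-set partitions are immaterial: the fitted
values are unique regardless of how the partition is represented.

```{r}
decompose_monotone(mw)$r2_mono
```

## Variance decomposition

`variance_components()` performs the statistical decomposition of a GP map
under equal genotype frequencies (`1/3^N`), the idealised population in
which the statistical and functional formulations and unweighted regression
on gene content all coincide. The design matrix is the Kronecker product,
across loci, of the per-locus orthogonal basis: intercept `(1,1,1)`,
additive contrast `(-1,0,1)` and dominance contrast `(-1,2,-1)`. Contrast
scaling is irrelevant because each term's variance component is the
population variance of its projection, not its raw coefficient. `V_G`
equals the population variance of the genotypic values exactly (full-rank
orthogonal basis), `V_A` sums the single-locus additive terms, and
epistatic variance is additionally reported by interaction order as a
diagnostic. The classical anchors hold exactly: `V_A/V_G = 1` for the
additive map, `0` for pure overdominance and pure epistasis, and `0.375`
for duplicate dominant epistasis, the most extreme fully monotone case.

## The network simulator

`simulate_gpmap()` generates GP maps mechanistically: each of three diploid
genes is modelled with one ODE per allele,

```
dx[k,i]/dt = alpha[k,i] * R_ki(y1, y2, y3) - gamma * x[k,i],   y_k = x[k,1] + x[k,2],
```

where the regulation function `R_ki` is 1 for an unregulated gene, a Hill
function `S(y, theta, p) = y^p / (y^p + theta^p)` (or `1 - S` for
repression) for one regulator, and the product of two Hill terms (Boolean
AND) for two regulators. The wiring is a 3x3 signed connectivity matrix
with at most two regulators per gene. The phenotype of a genotype is the
equilibrium total expression `y_3` of gene 3.

Study conditions (the defaults): production rates `alpha ~ U(100, 200)`,
thresholds `theta ~ U(20, 40)`, steepnesses `p ~ U(1, 10)`, decay rates
fixed at 10. Without pleiotropy, allelic variation enters only through
`alpha`, with `theta` and `p` drawn once per gene-regulator pair and shared
by both alleles; with pleiotropy each allelic variant carries its own
`theta` and `p` too. Whether the shared regulation parameters should be
fixed constants or redrawn per replicate is underdetermined; we redraw them
each replicate, mirroring the pleiotropy condition's sampling, so the two
conditions differ only in where allelic variation enters.

Numerical choices:

* **Initial condition** all-zero (the natural "switched-off" state); in
  multistationary systems this selects one attractor consistently, which is
  recorded here as a modelling choice.
* **Convergence.** lsoda integration in windows of 10 time units (the decay
  rate sets an intrinsic time constant of 0.1) up to `t_max = 1000`;
  settled when the relative state change per window and the residual both
  drop below `1e-6`. The located equilibrium is then polished by Newton
  iteration on the algebraic system and accepted only if strictly stable
  (all Jacobian eigenvalues with negative real part). This makes phenotypes
  accurate to ~1e-12 relative, so the `zero_tol` default is meaningful for
  simulated maps. Oscillation, divergence, Newton failure and
  non-hyperbolic points are all reported as non-convergence, and a
  replicate is discarded if any of its 27 genotypes fails. A slowly-passing
  saddle transit could in principle fool the window test, but the stability
  check rejects the saddle, so such replicates are discarded rather than
  mis-scored.
* **Flat maps.** Replicates whose 27 genotypic values have absolute range
  `<= 0.01` or relative range (range/mean) `<= 0.01` are discarded as flat;
  phenotypes are non-negative so the mean is safe as denominator.

`monte_carlo_study()` wraps this per motif: a per-motif RNG stream derived
from the root seed makes any subset of motifs exactly reproducible. The
full study design is 1000 replicates for each of the 1881 motif
representatives; the packaged tests run a deliberately smaller design (20
motifs of one class, 50 replicates) that exercises every code path, and the
motif-inclusion threshold (100 usable maps per 1000 replicates) scales
proportionally with the replicate count and is recorded in the output.

## Motif space

The 3-gene connectivity space with at most two regulators per gene contains
`19^3 = 6859` matrices; requiring gene 3 downstream of both others leaves
3724; one representative per X1/X2-relabelling orbit leaves 1881 (the
canonical representative is the lexicographically smaller flattening -- the
choice is immaterial because all loop products and classes are
swap-invariant, which the tests assert). Weak connectedness is implied by
the downstream condition and asserted rather than filtered. Motifs are
classified by two booleans: presence of an incoherent feedforward (negative
feedforward product `FFL32` or `FFL31`) and presence of a positive feedback
loop (any of the eight loop products positive, positive autoregulation
included -- the definition under which the four class counts
287/48/1294/252 are reproduced exactly). Without pleiotropy these two
features are necessary for order-breaking, so the class with neither must
produce only monotone maps; this theorem is checked empirically in the test
suite on the scaled-down Monte Carlo design.

## What the generators do and do not emulate

Random maps (`random_gpmap`) draw genotypic values i.i.d. uniform -- the
harshest case for monotonicity, useful for calibrating the measures and for
the monotonicity-additivity association, but unlike real maps they carry no
effect-size hierarchy among loci. The network simulator produces maps with
realistic structure (saturation, epistasis from shared pathways) but only
for 3 loci, one phenotype, Hill-AND regulation and equilibrium phenotypes;
molecular noise, time-course phenotypes and more than two regulators per
gene are out of scope. Passing tests therefore demonstrate correctness of
the measures and the stated architecture-monotonicity relationships within
this model family, not claims about any particular empirical system.

## Known limitations

* `m` offers per-locus resolution but `R2_mono` does not; both are
  dominated by major loci.
* Maps with missing genotypes, more than two alleles per locus, or
  non-equal genotype frequencies are not supported.
* Exact discard counts in large Monte Carlo runs depend on integrator
  tolerances and the initial condition; class-level patterns are robust,
  per-motif counts are not.
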