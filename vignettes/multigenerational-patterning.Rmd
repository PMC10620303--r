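---
title: "Multigenerational Turing patterning in a diploid cross"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multigenerational Turing patterning in a diploid cross}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mgturing)
```

## The model

Anthocyanin spotting on monkeyflower petals is controlled by a small
activator–inhibitor gene regulatory network: an activator complex (centred
on R2R3-MYB transcription factors) up-regulates both itself and an
inhibitor (an R3-MYB), the inhibitor suppresses activator production, and
the inhibitor moves between cells much faster than the activator. Those are
the ingredients of Turing-type diffusion-driven instability, and
`mgturing` models them as a reaction–diffusion system in which every rate
and binding constant is *heritable*.

The haploid core is a two-species system for activator $u$ and inhibitor
$v$:

$$
\partial_t u = D_u \nabla^2 u + \alpha_u - \beta_u u
  + \gamma_u \left( \frac{\kappa_{uu} u}{1 + \kappa_{uu} u + \kappa_{uv} v}
  \right)^2,
$$

and similarly for $v$ with $\alpha_v, \beta_v, \gamma_v$ and
$\kappa_{vu}, \kappa_{vv}$. Each gene's regulated production is a squared
competitive Hill term: two identical, independent binding sites at which
the activator (numerator) competes with the inhibitor (denominator).
$\kappa_{xy}$ is the association constant of transcription factor $y$
binding the regulatory region of gene $x$; concentrations carry arbitrary
units, so each $\kappa \cdot \text{concentration}$ product is
dimensionless.

A diploid carries two copies of each locus, so a genotype has up to four
distinct gene products $(u, v, \hat u, \hat v)$ — one activator and one
inhibitor per haplotype. Duplicating the network gives four equations
whose Hill terms mix all species; allele-resolving every constant yields
four rate triples $(\alpha, \beta, \gamma)$ and a $4 \times 4$ table of 16
binding constants $\kappa_{xy}^{a b}$: regulated gene $x$ of allele $a$,
bound by product $y$ of allele $b$. That 16-entry table, the four rate
triples, and $(D_u, D_v)$ form the `mg_params` object — the complete
heritable description of one cross.

## Inheritance

Parents are inbred homozygotes (`U:AA,V:AA` and `U:BB,V:BB`); their F1 is
doubly heterozygous (`U:AB,V:AB`) and uses all 16 binding constants.
Selfing the F1 segregates each locus 1:2:1 independently, giving the 9 F2
genotypes enumerated by `enumerate_f2()`. Each genotype uses the subset of
the F1 parameterization dictated by its alleles: doubly homozygous
genotypes reference 4 binding constants, singly heterozygous ones 9, the
F1 all 16 (`count_kappa()`).

At a homozygous locus the two gene products obey identical equations, so
the pair is replaced by its sum (`contract_system()`): zeroth-order rates
($\alpha$, $\gamma$) double, the first-order rate $\beta$ does not. The
contraction is performed on the symbolic rate/binding tables, keyed off
the genotype alone, so the full four-species and contracted systems can be
cross-validated numerically — the test suite integrates both with an
independent ODE solver and compares summed trajectories at `1e-8`
tolerance. A heterozygous locus whose two alleles happen to carry equal
parameter values is deliberately *not* contracted.

## Linear analysis and the critical diffusion ratio

For each genotype the package finds the homogeneous steady state by damped
Newton iteration from 32 starting points, log-spaced over
$[10^{-3}, 10^3] \times \alpha/\beta$ (root tolerance $10^{-10}$).
Multiple distinct roots can occur — the Hill nonlinearity admits
three steady states in parts of parameter space — and such systems are
flagged non-unique and excluded from admissible sets rather than analysed.

The reaction Jacobian has closed form
$J_{ij} = -\beta_i \delta_{ij} + 2 \gamma_i U_i
\left[ K^{U}_{ij} (1 + V_i) - U_i K^{V}_{ij} \right] / (1 + U_i + V_i)^3$,
with $U_i, V_i$ the activator/inhibitor Hill aggregates of row $i$.
"Stable" always means max real eigenvalue $< -10^{-9}$, a strict margin
that avoids classifying marginal cases. Linearizing the full
reaction–diffusion operator adds $-k^2 \mathrm{diag}(D)$; the dispersion
relation is the maximal real eigenvalue as a function of spatial frequency
$k$. The supremum over $k$ is located on a coarse log-spaced grid in $k^2$
and refined by golden-section search, so it is not grid-limited.

Writing $d = D_v / D_u$ (inhibitor-to-activator diffusion ratio — the
package standardizes on this orientation throughout, since instability
requires the inhibitor to be the faster diffuser, $d > 1$), each
Turing-capable genotype has a critical ratio $d_\star$ at which the
dispersion maximum first touches zero. `critical_diffusion_ratio()`
bisects $d$ to $10^{-6}$ relative tolerance and returns `Inf` when the
system is stable throughout the bracket (no Turing bifurcation).

A parameter set is **admissible** at a working ratio $d$ when both parents
and the F1 have unique, kinetically stable steady states and

$$ d_\star^{F1} < d < \min(d_\star^{A}, d_\star^{B}): $$

solid parents, spotted F1 — a transgressive hybrid phenotype from two
unpatterned lines.

## The admissible-set search

No usable published table of numerical values accompanies the model, so
working parameter sets are generated by seeded log-uniform random search
(`search_admissible()`), and the two packaged fixtures record their seed
and try index for exact regeneration (`scripts/make_fixtures.R`). The
default bounds are the package's choice of realistic kinetics:
$\alpha \in [10^{-3}, 5 \times 10^{-2}]$ (leaky baseline transcription
well below regulated production), $\beta \in [0.5, 2]$ (degradation sets
the time unit), $\gamma \in [5, 50]$, $\kappa \in [1, 50]$ (Hill terms
near half-saturation at steady state). Under these bounds roughly one
draw in six yields a Turing-capable haploid system, and an admissible
multigenerational set is typically found within a few dozen draws.

Accepted sets must additionally satisfy two robustness conditions, fixed
as part of the search design: the gap
$\min(d_\star^{A}, d_\star^{B}) / d_\star^{F1}$ must be at least 2.5, with
the working $d$ placed well inside it ($d = d_\star^{F1} \cdot
\min(2, \sqrt{\text{gap}})$), so that the F1 instability and the parents'
stability are both robust rather than marginal; and every F2 genotype
must have a unique stable steady state, so that all nine phenotype
simulations are well posed. Finally $D_u$ is rescaled so the F1's
fastest-growing wavelength is about 12 length units — a convenient scale
for the default 128-unit domain.

The `"symmetric"` search mode generates the identical-parents limit:
allele-independent kinetics and *cis* binding constants, with the F1
differing only through a reduced *trans* efficacy $m_{vu}$ (below). Its
parent draws are additionally required to sit in the modal single-axis
response regime (see the next section) with a monotone
$d_\star(m_{vu})$ curve, so the packaged limit case is representative of
the common behaviour of admissible sets rather than an edge case.

## The trans/cis mechanism for transgressive F1 phenotypes

When the two parents are phenotypically identical (allele-independent
rates, $\kappa^{AA} = \kappa^{BB} = \kappa^{cis}$), the only way the F1
can differ from them is through the eight *trans* constants
$\kappa^{AB} = \kappa^{BA} = m \, \kappa^{cis}$ — a transcription factor
of one parental allele binding the regulatory site of the other. Small
structural differences between allelic products make trans binding weaker:
$0 \le m_{xy} < 1$.

On the symmetric manifold $u = \hat u$, $v = \hat v$, the four-species F1
contracts exactly to two total-concentration species with effective
binding constants

$$ \kappa^{\mathrm{eff}}_{xy} = \kappa^{cis}_{xy} \, (1 + m_{xy}) / 2 , $$

production $2\alpha$, $2\gamma$, and unchanged $\beta$. At $m = 1$ this
is exactly the contracted parent system, and at $m = 0$ every effective
constant is half the parental value. (The normalization matters: defining
the effective constant without the factor $1/2$ would fail to recover the
parents at $m = 1$, and the package's convention is verified in the test
suite against the full four-species pipeline, whose steady states, Jacobian
restriction $P + Q$, and $d_\star$ the contraction must reproduce.)

`dstar_sweep()` traces $d_\star(m)$ as one efficacy is reduced with the
other three at 1. For the packaged symmetric fixture — and for the modal
regime of admissible sets generally — weakening either cross-regulation
(`m_vu`: activator driving inhibitor production; `m_uv`: inhibitor
suppressing activator production) *lowers* $d_\star$, while weakening
either self-interaction (`m_uu`, `m_vv`) raises it. Hence identical solid
parents sharing $d_\star^{parent}$ can produce a spotted F1: reduced
$m_{vu}$ pulls $d_\star^{F1}$ below $d_\star^{parent}$, and any
$d$ between the two gives stable parents and an unstable hybrid. The
direction of these responses is parameter-dependent (a minority of
admissible parents respond oppositely), so the suite pins it for the
packaged fixture rather than asserting it as a theorem, and the
$d_\star(m)$ curves can be non-monotone near $m = 0$ even in the modal
regime.

## Simulation and phenotype readout

Fields are integrated on a rectangular grid (default $128 \times 128$,
spacing 1, no-flux boundaries) by Peaceman–Rachford ADI with
Crank–Nicolson weighting: diffusion advances as an x-implicit then
y-implicit half-step pair, which for constant coefficients reduces to two
dense propagator multiplications per species and conserves total mass
exactly; the reaction advances explicitly within the splitting (a Strang
option with midpoint reaction half-steps is available when second-order
accuracy in `dt` is wanted). The default `dt = 0.1` resolves kinetics with
$\beta \le 2$; the solver detects divergence and clamps (and counts)
negative roundoff values, warning above 0.1% of updates. The petal is a
rectangle: figure-style petal outlines are a rendering concern, not a
solver one.

Initial conditions are the homogeneous steady state plus seeded uniform
noise of 1% relative amplitude. The run stops at strict convergence
($\max |\Delta|/\mathrm{d}t < 10^{-7}$), or — under the `"saturated"`
stopping rule — once the pattern amplitude has been stationary to 0.1%
over three consecutive checks. The distinction matters: developed Turing
spot patterns keep rearranging their spot positions on timescales far
beyond any practical integration horizon, while amplitude and wavelength
are established early; phenotype classification needs only the latter, so
the F2 grid uses the saturated rule by default and reports both flags.

A field is **patterned** when the spatial coefficient of variation of the
total activator $u + \hat u$ (the proxy for pigment intensity) exceeds
0.05 — in practice Turing patterns and residual numerical inhomogeneity
differ by at least two orders of magnitude on this scale, and the
threshold is configurable. The dominant wavelength is the peak of the
radially binned power spectrum (resolution: one spectral bin, $L/b$ for
domain side $L$ and integer mode $b$); spots are connected components
above the $(\max + \min)/2$ level, with a labyrinthine flag when the
largest component spans more than a quarter of the domain. Renders map
activator onto a yellow-to-red ramp over a range shared across panels so
parents, F1, and F2 genotypes are directly comparable.

## What the simulated conditions do and do not show

The synthetic study emulates: inbred homozygous parents crossed to a
doubly heterozygous F1, selfing to nine F2 genotypes with Mendelian
frequencies, allele-resolved kinetics with competitive two-site binding,
and diffusion-driven patterning read out as total activator. It does not
emulate: the accessory proteins of the real activator complex, multiple
inhibitor gene copies, more than two alleles per locus, linkage, petal
geometry or growth, or pigment chemistry beyond a single activator axis.
Passing tests therefore demonstrate the inheritance-driven instability
mechanism, not a quantitative fit to any real flower; wavelengths and
spot counts are properties of the searched parameter sets, whose scale
was deliberately calibrated, and printed figure layouts of the original
experimental system are not reproduction targets.

Problem sizes used by the test and acceptance runs — $16^2$ grids for
solver-oracle comparisons, $24^2$–$64^2$ for equivalence and concordance
checks, $128^2$ for the headline parents-vs-F1 demonstration, and
four-point efficacy grids for sweep directions — are the package's choice
of smallest sizes that leave each scientific signal unambiguous (e.g. a
dozen pattern wavelengths per domain side, spectral bins fine enough to
separate adjacent modes).

## Numerical choices collected

* Steady states: 32 Newton starts, residual $\le 10^{-10}$; roots closer
  than $10^{-6}$ relative are identified; non-unique systems flagged.
* Stability margin: eigenvalue real part $< -10^{-9}$.
* $\sup_k$: coarse log grid in $k^2$ (60 points over 7 decades around
  $\beta_{\max}/D_u$) + golden-section refinement.
* $d_\star$ bisection: relative tolerance $10^{-6}$, bracket
  $[1, 10^4]$, `Inf` sentinel above.
* ADI: propagator matrices per species per direction; exact mass
  conservation checked to $10^{-12}$; splitting error first-order in
  `dt` by default (Strang option second-order).
* Pattern classification: CV threshold 0.05; wavelength to one spectral
  bin; spot level $(\max + \min)/2$; labyrinthine above 25% coverage.
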