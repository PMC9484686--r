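---
title: "Quantifying selection on modifiers of genetic architecture under migration load"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying selection on modifiers of genetic architecture under migration load}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(migmod)
```

## The question

Two demes exchange migrants while each adapts to its own habitat. Gene flow
keeps the mean fitness of each deme below 1 — the *migration load* — and that
shortfall is an opportunity: a rare mutant allele that rearranges the genetic
architecture (tightening linkage, changing dominance or epistasis, lowering
its carrier's dispersal, or directly shrinking the cost of maladaptation) can
be favored even though it creates no new adaptive variant. `migmod`
implements the deterministic machinery to put a number on that advantage: the
long-run growth rate $\lambda$ of the rare modifier lineage, whose selection
coefficient is $\lambda - 1$.

## The model

**Genetics.** A single linear chromosome carries $k \le 5$ local-adaptation
loci, plus a modifier locus at position 1. Each local-adaptation allele is
either the deme-1-adapted variant (state 1) or the deme-2-adapted variant
(state 0). Adjacent loci recombine independently with per-interval
probabilities $r$ ($r_m$ for the modifier interval); $r = 0.5$ recovers free
segregation. Haplotypes are bit-encoded (position 1 = most significant bit),
and meiosis is summarised once per recombination vector as an exact gamete
tensor $G[l, i, j]$ — the probability that a parent with haplotypes $i, j$
produces gamete $l$ — built by enumerating strand-origin masks (a two-strand
model, no interference). At the 6-locus maximum the tensor has
$64^3 = 262{,}144$ entries; tensors are cached per recombination vector.

**Life cycle.** Census at the haploid gametic stage. Each generation:
random syngamy within the natal deme, diploid migration at rates $m_d$,
viability selection in the deme of arrival, then meiosis:

$$x_i^{d\,\prime} = \sum_{j,k} w^d_{j,k}
  \left( x^d_j x^d_k (1 - m_d) + x^{\hat d}_j x^{\hat d}_k m_{\hat d} \right)
  G_{i,j,k}, \qquad
  \bar w_d = \sum_i x_i^{d\,\prime},$$

with frequencies renormalised by $\bar w_d$. The load is
$L_d = 1 - \bar w_d$.

**Fitness.** Fitness is driven by the *effective* fraction of maladapted
alleles, built in two logistic stages. Per locus, a heterozygote contributes
$1/(1+e^{\theta_i})$ to the maladapted fraction in deme 1 (so $\theta_i = 0$
is additivity and $\theta_i > 0$ makes the locally adapted allele dominant
there); homozygotes contribute 0 (favored) or 1 (disfavored). The average
over loci, $dom$, is then shifted on the logit scale by the epistasis
parameter: $l = \text{logistic}(\text{logit}(dom) - \phi)$, the identity at
$\phi = 0$. Finally $W = (1-S)^l$, evaluated in log space, so the best
genotype has fitness 1 and the worst $1 - S$.

## Conventions that the source leaves open

Three places in the verbal model description are internally inconsistent,
and the package fixes them as follows (each choice is pinned by a test):

* **Heterozygote indicator.** Read literally, a heterozygote would trip both
  the het and hom indicators in the dominance average. We treat them as
  exclusive; this is the only reading under which $\theta = \phi = 0$
  reproduces the literal maladapted-allele fraction (the additive anchor
  test enumerates all zygosity classes).
* **Epistasis boundaries.** The transform's algebra fixes $dom = 0$ and
  $dom = 1$ ($l = 0$ and $l = 1$) for any finite $\phi$; prose suggesting
  the opposite is not followed, preserving continuity with the $\phi = 0$
  identity. Boundaries are short-circuited rather than evaluated through
  infinite logits.
* **Deme-2 polarity.** Deme 2 is evaluated by complementing allele states
  and negating $\theta$ and $\phi$: gene expression is
  environment-independent, so an allele (or a modifier's dominance/epistasis
  shift) that helps in deme 1 hurts in deme 2. We tested the alternative
  mirror-symmetric reading (effects beneficial in both demes) and rejected
  it empirically: it makes dispersal-modifier selection *decrease* with
  rising ancestral epistasis and lets extreme modifiers saturate the
  theoretical maximum, both contrary to the source analyses; the
  environment-independent reading reproduces the observed directions
  (dispersal up, dominance down, epistasis and recombination up-then-down as
  ancestral $\phi$ grows). A consequence worth knowing: with nonzero
  ancestral $\phi$ the two demes' loads are *not* equal.

A global sign flip of all $\theta$, $\phi$ plus allele complementation is an
exact symmetry of the model (tested), so these polarity choices affect
labels, never magnitudes.

## Resident equilibrium

`solve_equilibrium()` initialises each deme with its favored haplotype at
frequency 0.9999 and the residual $10^{-4}$ spread by seeded uniform draws
over the other haplotypes — deliberately asymmetric, to avoid being trapped
on the symmetric unstable equilibrium — and iterates until the largest
per-generation frequency change falls below `tol` ($10^{-8}$ by default,
maximum absolute change across both demes, since no norm is canonical) or
`max_gen` generations (default 5000) elapse. Non-convergence is flagged, not
raised. The stable equilibrium is initialisation-independent (tested across
seeds), and `check_polymorphic()` verifies that local adaptation actually
survived, which matters once parameters are asymmetric or migration is
strong.

Two numerical notes. First, the neutrality of a *null* modifier —
$\lambda = 1$, the single most important regression property — is only as
exact as the equilibrium: the eigenvalue error tracks the residual frequency
drift, so tests asserting $|\lambda - 1| \le 10^{-8}$ solve with
`tol = 1e-11`. Second, large ancestral $\phi$ slows convergence badly
(at $k = 5$, $\phi = 1$ already needs ~11,500 generations); analyses at the
top of the ancestral-epistasis range pass `max_gen = 60000` rather than the
default cap.

## Invasion analysis

A rare modifier lineage is tracked over carrier states
$(\text{deme}, \mu, \rho)$ — the modifier-bearing haplotype's local alleles
$\mu$ and its resident partner haplotype $\rho$ — a
$2^{2k+1}$-dimensional linearisation around the resident equilibrium.
The matrix is assembled in three stages:

1. **Reproduction** $R^d[i,j] = 2\, G[j_\mu \mid i_\mu, i_\rho]\, v^d[j_\rho]$:
   meiosis of the carrier adult (at the *mutant* recombination vector — the
   recombination modifier is dominant), fusion with a resident gamete drawn
   from the natal deme's equilibrium pool $v^d$, and two successful gametes
   per adult at demographic equilibrium. Rows sum to 1: a carrier transmits
   the modifier to half its gametes regardless of linkage.
2. **Dispersal**: carriers migrate at the mutant rates $\hat m_d$ (block
   structure over the two demes).
3. **Selection**: each destination state is weighted by its carrier fitness
   under the hat parameters, normalised by the resident deme mean
   $\bar w_d$. Fitness and dispersal modifiers are co-dominant in the sense
   that the hat value is what heterozygous carriers express; carrier
   homozygotes are negligible during invasion, so no homozygote effect needs
   defining.

$\lambda$ is the Perron root, extracted by dense eigendecomposition
(dimension at most $2^{11}$; a power-iteration mode exists and is used as an
independent oracle in the tests — dense is preferred because invasion
spectra often have tiny gaps that stall iterative methods). The package's
strongest validation is end-to-end: for $k \le 2$, $\lambda$ matches the
measured per-generation growth of the modifier at frequency $10^{-8}$ in a
full nonlinear two-allele simulation to ~$10^{-10}$, for every modifier
type.

**Theoretical maximum.** No modifier that cannot push absolute fitness above
1 can outgrow a hypothetical load-free carrier, whose deme-$d$ relative
fitness is $1/\bar w_d$. The bound is the dominant eigenvalue, minus 1, of

$$\begin{pmatrix}(1-m_1)c_1 & m_1 c_2\\ m_2 c_1 & (1-m_2) c_2\end{pmatrix},
\qquad c_d = 1/\bar w_d,$$

which for symmetric demes is $L/(1-L)$. The printed form of this matrix in
the source contains an undefined symbol; the $c_d = 1/\bar w_d$ reading is
validated three ways: every computed modifier respects it, a modifier that
erases the fitness cost entirely ($\hat S = 0$) attains it exactly (the
matrix then lumps exactly onto the 2×2), and in the one-way-migration
continent–island limit with additive fitness an inversion's advantage
approaches the classical $L - m$.

## Sweeps and the figure presets

`figure_preset()` reproduces the published parameter grids: the baseline
($S = 0.1$, $m = 0.05$, free recombination, additive fitness, modifier fully
linked to locus 1) swept over modifier strength at $k = 2, 5$; extreme
(dominance/epistasis 10, recombination/dispersal 0) and modest (1.5, or half
the resident rate) modifiers across $k = 2..5$; dominance-modifier locus
masks; ancestral $\phi \in [0, 10]$ at $k = 5$; and $S$ from weak (0.02) to
strong (0.2) at $k = 3$. Modifier strengths are reported as fractions of the
largest possible change — $(0.5 - \hat r)/0.5$ for recombination,
$(m - \hat m)/m$ for dispersal, $|\hat\theta|/3$ and $|\hat\phi|/3$ (capped
at 1; the logistic effect saturates near 3) for dominance and epistasis.
Grid resolutions are not data — captions fix endpoints only — so the presets
choose round grids and expose overrides. Equilibria are memoised per
parameterisation; caching is transparent (tested byte-identical).

## What a green test does and does not establish

The model is deterministic; there is no synthetic-data generator beyond the
seeded spread of the $10^{-4}$ initial residue, and the same seed reproduces
every number bitwise. Green tests establish that the recursion, fitness
machinery and linearisation are mutually consistent and agree with
independent re-implementations at small $k$. They do not establish anything
about finite populations: drift, establishment probabilities of rare
modifiers, demographic stochasticity, more than two demes, unequal deme
sizes, fertility selection or crossover interference are all out of scope.

## Known quantitative discrepancies

Two printed anchor values could not be reproduced, under any convention we
tested, by machinery that demonstrably matches the nonlinear dynamics:

* the epistasis-over-inversion fold advantage at $k = 3$, quoted as "about
  6": we compute 4.3 at $S = 0.1$, drifting from 5.0 to 3.6 across the
  weak-to-strong-selection grid (so not constant either);
* the extreme dominance modifier's share of the theoretical maximum, quoted
  as about one third: we compute 0.21 at $k = 2$ (0.16 at $k = 5$).

The corresponding acceptance tests assert the quoted values and are left
failing deliberately. Both discrepancies move in the same direction
(dominance/epistasis modifiers stronger in the source than here); the
mirror-symmetric deme-2 convention would overshoot them from the other side
(~12-fold and 0.55) while breaking the ancestral-epistasis directions, so we
keep the environment-independent convention that reproduces every other
anchor: the $k=5$ inversion-to-epistasis ratio of ~1/4, the ~10% load rise
and ~50% dispersal-selection drop from $k = 2$ to 5, the modifier-type
ordering, and the monotone rise of all selection coefficients with $S$.

## A worked example

```{r example, eval = FALSE}
eq <- solve_equilibrium(k = 2, S = 0.1, m = 0.05)
glance(eq)

inv <- invasion_analysis(eq, modifier_spec(phi_hat = 10))
tidy(inv)

sw <- run_sweep(figure_preset("fig2", k = 2, effect = seq(0, 1, 0.25)))
autoplot(sw)
```
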