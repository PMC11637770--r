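---
title: "Computing the genealogical divergence index under migration"
author: "gdidelim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Computing the genealogical divergence index under migration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gdidelim)
```

## The model and the index

Candidate species are populations on a rooted binary guide tree.  Each
branch carries a population-size parameter $\theta = 4N\mu$ and each
internal node a divergence time $\tau = T\mu$, both in expected mutations
per site, so a branch of length $2\tau/\theta = T/(2N)$ coalescent units
hides one expected pairwise coalescence.  Directed migration events connect
contemporaneous branches: migrants move from a donor to a recipient
population, forward in time, at rate $M = mN$ (with $N$ of the recipient)
migrants per generation.  This is the multispecies coalescent with
migration (MSC-M); removing all events recovers the plain MSC.

The genealogical divergence index (gdi) asks how distinct population A is
from population B by following three sampled sequences backward in time:
two from A ($a_1, a_2$) and one from B ($b$).  Three rooted gene-tree
topologies are possible, and the one grouping the duplicated pair,
$G_1 = ((a_1,a_2),b)$, is the signature of divergence.  Two definitions
are implemented:

* **gdiJ** rescales $P(G_1)$ from its no-gene-flow range $[1/3, 1]$ onto
  $[0, 1]$: $\mathrm{gdi}_J = (P_1 - 1/3)/(2/3)$.  Under gene flow
  $P(G_1)$ can drop below $1/3$ (two A sequences can be, on average, more
  distant from each other than from a B sequence), making gdiJ negative.
* **gdiK** is $P(G_{1a})$: the probability that $a_1$ and $a_2$ coalesce
  with each other, in whatever population, before the focal divergence
  time.  It needs no rescaling and stays in $[0, 1]$.

Without gene flow both equal $1 - e^{-2\tau/\theta_A}$.  The package
defaults to gdiK under gene flow because of its boundedness; gdiJ is
always computed alongside and can drive decisions instead.  Negative gdiJ
values are reported raw; clamping to zero is opt-in (`clamp = TRUE`).

Because the duplicated sample can be taken from either population, every
pair yields two indexes (gdiA from `aab` sampling, gdiB from `abb`).  They
can disagree strongly under size or migration asymmetry, which is why the
decision rules below use both.

## Three computation paths

`gdiPair()` dispatches on the migration pattern touching the focal pair:

1. **No gene flow into the pair or its ancestors** — closed form.  For
   sister populations this is the textbook $1 - e^{-2\tau/\theta}$; for
   non-sister pairs the package multiplies survival factors
   $e^{-2\Delta t_i/\theta_i}$ over the branch segments the duplicated
   pair traverses below the pair's most recent common ancestor, which is
   exact because the two sides of the tree cannot share lineages below
   that node.  Gene flow *out of* the pair into third populations leaves
   the calculation untouched and is ignored.
2. **Gene flow only between the two (sister) populations** — the
   structured-coalescent Markov chain.  The three lineages occupy 21
   states (8 three-lineage location states, 12 states with one pair
   coalesced, one absorbing state).  The generator applies per-lineage
   backward migration at rate $\varpi_P = 4M_{P'\to P}/\theta_P$ and
   per-pair coalescence at $c_P = 2/\theta_P$.  $P(G_{1a})$ integrates
   the density of the first duplicated-pair coalescence over $(0, \tau)$
   via the spectral form of the generator, and
   $P(G_1) = P(G_{1a}) + \frac13 P(\text{no coalescence by } \tau)$.
   When migration is unidirectional the chain reduces to 11 (`aab`) or 7
   (`abb`) reachable states with known closed-form solutions
   (`casebAab()`, `casebAbb()`), which the package uses directly and the
   test suite verifies against the chain to $10^{-8}$.  A ghost-lineage
   variant (an unsampled third species donating into A) has its own
   4-state chain and closed form (`ghostTransitionProbs()`, `ghostPG1()`).
3. **Gene flow from third populations** — simulation.  An event-driven
   structured-coalescent simulator (C++ core) draws gene trees for the
   three sampled sequences on the full model; the topology is decided by
   the first coalescing pair, so each replicate stops early.  Estimates
   carry binomial standard errors, and the default $R = 10^5$ replicates
   put the Monte-Carlo standard error of a probability near 0.0016;
   $R = 10^6$ is preferable for publication-grade surfaces and is used in
   the deeper verification runs.

## Numerical choices

The spectral path assumes a diagonalizable generator with real
eigenvalues.  Before use, the eigendecomposition is validated by
reconstruction error (relative tolerance $10^{-8}$) and conditioning
(`rcond(U)` above $10^{-10}$); on failure the code falls back to a dense
scaling-and-squaring matrix exponential, and the time-integral to the
exponential of the augmented block matrix $[[Q, I], [0, 0]]$, whose
top-right block is $\int_0^\tau e^{Qt}\,dt$ exactly.  The printed closed
forms have removable singularities (for example $M\theta_B = \theta_A$);
within a relative distance of $10^{-10}$ of those manifolds the chain path
is evaluated instead, because no limit expressions are available.  Two
exponential products in the case-b formulas are combined analytically
(e.g. $e_3 e_4 = e^{-4M\tau/\theta_A - 2\tau/\theta_B}$) so that no
intermediate term has a positive exponent that could overflow.

The simulator consumes R's global random number stream, so `set.seed()`
(or the `seed` arguments) makes every estimate reproducible; delimitation
runs derive one seed per gdi evaluation from the engine's base seed.

## Hierarchical merge and split

`runDelimitation()` drives two greedy heuristics over the guide tree:

* **Merge** starts with every population a species and works tip-ward:
  each pass evaluates every cherry with both sampling configurations and
  merges it when *either* index falls below the merge cutoff (default
  0.2).  All acceptable cherries merge within a pass — decisions within a
  pass are independent because parameters are refreshed by the backend
  only between passes.  Merging collapses the cherry into one tip
  (labels concatenate in tree order), deletes migration between the pair
  and re-attaches events with third parties to the merged tip.
* **Split** starts from one species and works root-ward: a species splits
  into the two daughter clades of its node when both indexes exceed 0.5
  and at least one exceeds 0.7.  A candidate split is evaluated on the
  model in which every current species is collapsed to a single tip and
  the two daughters stand as separate populations.
* **Non-sister merges** (opt-in) address paraphyletic species: when no
  sister pair can merge in an iteration, the migration-connected
  non-sister pair with the smallest gdi (ties: lexicographically smallest
  pair) may merge if it passes the cutoff — at most one per iteration.
  The absorbed tip is deleted and its samples ride on the survivor, with
  the donor of the larger migration rate surviving (the displayed-tree
  rule); on equal rates the lexicographically smaller label survives.

Under no gene flow and gdi decreasing toward the tips, merge and split
with a common cutoff provably meet at the same delimitation, which the
test suite checks; with gene flow or non-monotone gdi they may differ, and
both should be run.

Two open conventions were settled as follows.  The theta of a merged
population is not specified by the decision rules; the package lets the
merged tip inherit the surviving member's theta and expects the backend to
re-estimate it on the next pass (`fixedBackend(rule = "inherit")` keeps
inherited values; `rule = "strict"` makes a missing entry an error).
Merges are proposed on the *current* tree, not the original guide tree, so
a merged tip can immediately participate in the next cherry.

## Parameter uncertainty

With MCMC output (bpp-style column tables; `readPosteriorSample()`)
`posteriorGdi()` recomputes the index per draw and reports the posterior
mean, the 95% equal-tail interval, and the 95% HPD interval computed as
the shortest window of $\lceil 0.95\,n \rceil$ consecutive order
statistics (assuming a unimodal, single-interval HPD region).  On the
simulation path the draw list is thinned to at most 1000 evenly spaced
draws.  Delimitation decisions use the posterior mean of the index; the
intervals are logged.  A plug-in evaluation at the posterior-mean
parameters is available through `posteriorBackend()` and is close to full
propagation whenever the data are informative.

## Scope of the verification runs

The isolation-by-distance benchmark used in the tests and the acceptance
script has five populations (X isolated; A–D exchanging $M = 2$ migrants
per generation between neighbours, $\theta = 0.01$, splits at
$\tau = 0.01$–$0.04$) with gdi estimated from $R = 10^5$ simulated gene
trees per evaluation — enough to separate the decision values involved
(the closest call is roughly 0.03 away from a cutoff, about 20 standard
errors).  The cross-route property checks use 100 random parameter draws
for closed-form-versus-chain agreement and 20 draws at $R = 10^5$ for
simulator-versus-chain agreement.  What these runs demonstrate is the
internal correctness of the calculators and the decision machinery on
models with known parameters; they do not exercise parameter estimation
from sequence data, which belongs to an external inference program wired
in through `bppAdapter()`.

## Known limitations

* Exactly three sampled sequences per evaluation; the chain covers at
  most two contemporaneous populations, everything else simulates.
* Guide trees must be strictly binary; populations are never subdivided.
* Migration between non-contemporaneous branches is rejected at model
  construction.
* The HPD routine assumes a single interval; strongly multimodal
  posteriors would need a density-based method.
* Composite decision criteria (absolute split times, migration-rate
  ratios) are out of scope; thresholds act on the gdi alone.
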