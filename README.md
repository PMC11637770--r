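# gdidelim

Genealogical divergence index (gdi) calculators and hierarchical
merge/split species-delimitation heuristics under the multispecies
coalescent with migration (MSC-M), for R.

## The problem

Deciding whether two candidate populations are one species or two from
genomic data is often reduced to an empirical criterion on the parameters
of their divergence history: split time `τ = Tμ`, population sizes
`θ = 4Nμ`, and migration rates `M = mN` (migrants/generation).  The gdi
condenses these into the probability that two sequences sampled from
population A (`a1`, `a2`) coalesce with each other before either meets a
sequence from B.  Writing `G1 = ((a1,a2),b)` for the gene-tree topology
that groups the duplicated pair and `G1a` for the event that its first
coalescence predates the split,

* `gdiJ = (P(G1) − 1/3) / (2/3)` — the classical rescaling of the
  topology probability; it can go negative under gene flow;
* `gdiK = P(G1a)` — the coalescence-before-divergence probability, always
  in [0, 1].

Without gene flow both reduce to `1 − exp(−2τ/θ_A)`.  A common rule of
thumb treats `gdi < 0.2` as one species and `gdi > 0.7` as two.

The package computes both indexes for any pair of populations on a guide
tree with an arbitrary pattern of directed migration events, by exact
closed forms, by a 21-state structured-coalescent Markov chain, or by
fast coalescent simulation (C++ core), choosing automatically; propagates
MCMC parameter uncertainty into the index (posterior mean, equal-tail and
HPD intervals); and drives hierarchical merge and split algorithms over
the guide tree, including single non-sister merges for paraphyletic
species.  Intended users are systematists running heuristic species
delimitation downstream of MSC-M parameter estimation (e.g. with bpp) and
methodologists studying the behaviour of the index itself.

## Worked example: gene flow from a ghost lineage

Species A and B diverged at `τ_AB = 0.005`; an unsampled outgroup C
(split at `τ_ABC = 0.01`) donates `M = 1` migrant per generation into A.
With `θ_A = θ_C = 0.05` and `θ_AB = 0.001`, the history of the two A
sequences up to `τ_AB` is a 4-state chain whose transition probabilities
give `P(G1)` in closed form:

```r
library(gdidelim)
gp <- ghostParams(tauABC = 0.01, tauAB = 0.005, thetaA = 0.05,
                  thetaC = 0.05, thetaAB = 0.001, M = 1)
round(ghostTransitionProbs(gp), 4)
#>    p11    p12    p13    p14
#> 0.3679 0.4033 0.0952 0.1337
cat("P(G1) =", round(ghostPG1(gp), 4),
    " gdiJ =", round(gdiJFromP1(ghostPG1(gp)), 4), "\n")
#> P(G1) = 0.2995  gdiJ = -0.0507
```

`p14 = 0.1337` is `gdiK`: the pair coalesces before the split only 13%
of the time.  `P(G1) < 1/3` — migration into A makes two A sequences
*less* similar to each other than to a B sequence — so `gdiJ` is
negative.  Simulation on the full three-species model confirms the
closed form:

```r
m <- parseGuideTree("((A,B),C);", tau = c(AB = 0.005, ABC = 0.01),
                    theta = c(A = 0.05, B = 0.05, C = 0.05,
                              AB = 0.001, ABC = 0.01),
                    migration = migrationEvents("C", "A", 1))
estimateGdiSim(m, "A", "B", "aab", reps = 1e6, seed = 1)
#> SimEstimate: R = 1e+06 gene trees (seed 1)
#>   counts: G1 = 298970 (G1a = 133504), G2 = 350933, G3 = 350097
#>   P(G1)  = 0.2990 (SE 0.0005)   P(G1a) = 0.1335 (SE 0.0003)
#>   gdiJ   = -0.0515              gdiK   = 0.1335
```

## Worked example: delimiting a paraphyletic species

Five populations: X split from A at `τ = 0.01` in complete isolation,
while A–B–C–D are geographic neighbours exchanging `M = 2` migrants per
generation (`θ = 0.01` everywhere, splits at 0.02/0.03/0.04).  The merge
algorithm with non-sister merging, driven by `gdiJ` at cutoff 0.2:

```r
ibd <- parseGuideTree("((((X,A),B),C),D);",
  tau = c(XA = 0.01, XAB = 0.02, XABC = 0.03, XABCD = 0.04),
  theta = 0.01,
  migration = migrationEvents(c("A","B","B","C","C","D"),
                              c("B","A","C","B","D","C"), 2))
st <- runDelimitation(ibd, "merge", gdiThresholds(merge = 0.2),
                      gdiEngine("gdiJ", reps = 1e5, seed = 42),
                      nonsister = TRUE)
st
#> DelimitationState: 2 species after 4 iteration(s)
#>   ABCD  <- {A, B, C, D}
#>   X  <- {X}
#>   10 gdi evaluations logged
```

The iteration log (`iterationLog(st)`) narrates each decision: the X–A
cherry never merges (`gdiA = 0.96`), while the migration-connected
non-sister pairs A–B, then AB–C, then ABC–D merge one per iteration
(`gdi ≈ 0.03–0.08`), recovering the paraphyletic species ABCD next to
the genuinely isolated X.  Running the same model with `gdiK` leaves all
five populations distinct at cutoff 0.2 and lumps everything at cutoff
0.7 — the two definitions embody different species concepts under strong
gene flow.

Control-file driven runs (`runDelimitationFromControl()`, or the
`exec/gdidelim` script with `--cfile`) accept a bpp-flavoured plain-text
configuration; parameters come from a fixed table or from an external
MCMC run wired in through `bppAdapter()`.

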