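#' @import methods
#' @importFrom stats setNames quantile runif
NULL

setOldClass("phylo")

## ---------------------------------------------------------------------------
## SpeciesTree
## ---------------------------------------------------------------------------

#' Species tree with divergence times and population sizes
#'
#' A rooted, strictly binary species (or population) tree in which every node
#' -- tips and internal nodes alike -- carries a unique label, a divergence
#' time \code{tau} and a population-size parameter \code{theta}.  Times and
#' sizes are both measured in expected mutations per site: \eqn{\tau = T\mu}
#' for a split \eqn{T} generations ago and \eqn{\theta = 4N\mu} for an
#' effective population size \eqn{N}.  Tips have \code{tau = 0}; each branch,
#' including the root branch, has its own \code{theta}.
#'
#' Validity requires: unique labels; a strictly binary rooted topology;
#' \code{theta > 0} everywhere; \code{tau >= 0} with every internal node at
#' least as old as each of its children (equality is permitted only as the
#' panmixia boundary, e.g. a two-population tree with \eqn{\tau = 0}).
#'
#' @slot phy an \code{ape} \code{phylo} object holding the topology, with
#'   \code{node.label} set for every internal node.
#' @slot tau named numeric vector of node ages, one entry per label.
#' @slot theta named numeric vector of population-size parameters, one entry
#'   per label.
#'
#' @seealso [speciesTree()], [parseGuideTree()]
#' @export
setClass("SpeciesTree",
  representation(phy = "phylo", tau = "numeric", theta = "numeric"))

setValidity("SpeciesTree", function(object) {
  phy <- object@phy
  labs <- c(phy$tip.label, phy$node.label)
  if (anyDuplicated(labs))
    return(sprintf("duplicate node labels: %s",
                   paste(unique(labs[duplicated(labs)]), collapse = ", ")))
  if (any(labs == "") || anyNA(labs))
    return("every node must be labelled")
  if (!ape::is.rooted(phy)) return("tree must be rooted")
  if (!ape::is.binary(phy)) return("tree must be strictly binary")
  for (v in list(object@tau, object@theta))
    if (is.null(names(v)) || !setequal(names(v), labs))
      return("tau and theta must be named vectors covering every node label")
  if (any(object@theta <= 0)) return("all theta must be > 0")
  if (any(object@tau < 0)) return("all tau must be >= 0")
  if (any(object@tau[phy$tip.label] != 0))
    return("tip tau must be 0 (contemporary populations)")
  ## age ordering: parent at least as old as child (equality = panmixia limit)
  e <- phy$edge
  nodelab <- .allLabels(phy)
  bad <- object@tau[nodelab[e[, 1]]] < object@tau[nodelab[e[, 2]]]
  if (any(bad))
    return(sprintf("tau ordering violated on branch(es): %s",
                   paste(nodelab[e[bad, 2]], collapse = ", ")))
  TRUE
})

## label of every node in phylo numbering (1..Ntip tips, then internals)
.allLabels <- function(phy) c(phy$tip.label, phy$node.label)

## ---------------------------------------------------------------------------
## MSCMModel
## ---------------------------------------------------------------------------

#' Multispecies coalescent model with migration (MSC-M)
#'
#' Couples a [SpeciesTree-class] with a set of directed migration events.
#' Each event moves migrants from a donor population to a recipient
#' population (forward in time) at rate \eqn{M} migrants per generation,
#' with \eqn{M = mN} of the recipient.  The parameter vector
#' \eqn{\Theta} of the model collects all \eqn{\tau}, \eqn{\theta} and
#' \eqn{M}; see [paramVector()].
#'
#' Validity requires that donor and recipient are distinct existing labels,
#' that their branches overlap in time (migration only between
#' contemporaneous populations), that rates are non-negative, and that no
#' (donor, recipient) pair is duplicated.  Removing all migration events
#' always leaves a valid no-gene-flow MSC model.
#'
#' @slot tree a [SpeciesTree-class].
#' @slot migration data.frame with columns \code{donor}, \code{recipient},
#'   \code{rate}.
#'
#' @seealso [parseGuideTree()], [migrationEvents()], [mergePopulations()]
#' @export
setClass("MSCMModel",
  representation(tree = "SpeciesTree", migration = "data.frame"))

setValidity("MSCMModel", function(object) {
  mig <- object@migration
  if (!all(c("donor", "recipient", "rate") %in% names(mig)))
    return("migration must have columns donor, recipient, rate")
  if (nrow(mig) == 0L) return(TRUE)
  tr <- object@tree
  labs <- .allLabels(tr@phy)
  if (!all(c(mig$donor, mig$recipient) %in% labs))
    return("migration event names a label not on the tree")
  if (any(mig$donor == mig$recipient))
    return("migration donor and recipient must differ")
  if (any(mig$rate < 0)) return("migration rates must be >= 0")
  if (anyDuplicated(mig[c("donor", "recipient")]))
    return("duplicate (donor, recipient) migration pair")
  for (i in seq_len(nrow(mig))) {
    bi <- .branchInterval(tr, mig$donor[i])
    bj <- .branchInterval(tr, mig$recipient[i])
    if (max(bi[1], bj[1]) >= min(bi[2], bj[2]))
      return(sprintf("branches %s and %s do not overlap in time",
                     mig$donor[i], mig$recipient[i]))
  }
  TRUE
})

## ---------------------------------------------------------------------------
## GdiResult
## ---------------------------------------------------------------------------

#' Result of a gdi computation for one ordered population pair
#'
#' Holds the gene-tree probabilities and both definitions of the
#' genealogical divergence index for a focal ordered pair (the reference
#' population first) under one sampling configuration: \code{aab} samples
#' two sequences from the first population, \code{abb} two from the second.
#'
#' \code{gdiK = P(G1a)} is the probability that the two sequences from the
#' duplicated population coalesce first, before the focal divergence time;
#' it lies in \eqn{[0, 1]}.  \code{gdiJ = (P(G1) - 1/3) / (2/3)} rescales the
#' probability of the gene-tree topology grouping the duplicated pair; under
#' gene flow it can be negative (down to \eqn{-1/2}).
#'
#' @slot pair character(2), ordered focal pair (reference first).
#' @slot config \code{"aab"} or \code{"abb"}.
#' @slot pG1,pG1a gene-tree probabilities.
#' @slot gdiJ,gdiK the two index definitions.
#' @slot method computation path actually taken: one of
#'   \code{"nomig-closed"}, \code{"ctmc"}, \code{"caseb-closed"},
#'   \code{"ghost-closed"}, \code{"simulation"}.
#' @slot se named numeric, Monte-Carlo standard errors (\code{NA} for exact
#'   methods).
#' @slot replicates simulation replicates used (\code{NA} for exact methods).
#' @slot clamped logical; whether a negative \code{gdiJ} was clamped to 0.
#' @slot posterior list; posterior summaries (mean, equal-tail and HPD 95\%
#'   intervals per definition) when computed from a posterior sample, else
#'   empty.
#' @export
setClass("GdiResult",
  representation(pair = "character", config = "character",
                 pG1 = "numeric", pG1a = "numeric",
                 gdiJ = "numeric", gdiK = "numeric",
                 method = "character", se = "numeric",
                 replicates = "numeric", clamped = "logical",
                 posterior = "list"),
  prototype(se = c(pG1 = NA_real_, pG1a = NA_real_),
            replicates = NA_real_, clamped = FALSE, posterior = list()))

setValidity("GdiResult", function(object) {
  if (length(object@pair) != 2L) return("pair must have length 2")
  if (!object@config %in% c("aab", "abb")) return("config must be aab or abb")
  if (!is.na(object@gdiK) && (object@gdiK < -1e-9 || object@gdiK > 1 + 1e-9))
    return("gdiK outside [0, 1]")
  TRUE
})

## ---------------------------------------------------------------------------
## SimEstimate
## ---------------------------------------------------------------------------

#' Monte-Carlo estimate of gene-tree probabilities and gdi
#'
#' Counts of simulated gene-tree topologies for three sampled sequences and
#' the derived estimates.  \code{gdiK} is the proportion of \code{G1a} trees
#' (topology grouping the duplicated pair, first coalescence predating the
#' focal split); \code{gdiJ} rescales the proportion of \code{G1}.
#' Standard errors are binomial, \eqn{\sqrt{p(1-p)/R}}.
#'
#' @slot counts named integer: \code{G1}, \code{G2}, \code{G3}, \code{G1a}.
#' @slot replicates number of simulated gene trees \eqn{R}.
#' @slot pG1,pG1a,gdiJ,gdiK point estimates.
#' @slot se named numeric standard errors for \code{pG1} and \code{pG1a}.
#' @slot seed the seed used, or \code{NA}.
#' @export
setClass("SimEstimate",
  representation(counts = "integer", replicates = "numeric",
                 pG1 = "numeric", pG1a = "numeric",
                 gdiJ = "numeric", gdiK = "numeric",
                 se = "numeric", seed = "numeric"))

setValidity("SimEstimate", function(object) {
  if (!setequal(names(object@counts), c("G1", "G2", "G3", "G1a")))
    return("counts must be named G1, G2, G3, G1a")
  cts <- object@counts
  if (cts[["G1"]] + cts[["G2"]] + cts[["G3"]] != object@replicates)
    return("topology counts must sum to the number of replicates")
  if (cts[["G1a"]] > cts[["G1"]]) return("G1a count cannot exceed G1 count")
  TRUE
})

## ---------------------------------------------------------------------------
## DelimitationState
## ---------------------------------------------------------------------------

#' State of a hierarchical merge/split delimitation run
#'
#' Tracks the current MSC-M model (tree plus migration events), the mapping
#' from original guide-tree populations to current species, the iteration
#' counter and a log of every proposal with the gdi values and decision.
#'
#' @slot model current [MSCMModel-class].
#' @slot guide the original guide model (scaffold for the split algorithm).
#' @slot assignment named character: original population -> current species
#'   label.
#' @slot iteration integer iteration counter.
#' @slot log data.frame of proposals (iteration, pair, gdiA, gdiB,
#'   definition, method, decision).
#' @slot evals integer; number of gdi evaluations performed so far (used to
#'   derive per-evaluation simulation seeds).
#' @export
setClass("DelimitationState",
  representation(model = "MSCMModel", guide = "MSCMModel",
                 assignment = "character", iteration = "integer",
                 log = "data.frame", evals = "integer"),
  prototype(iteration = 0L, evals = 0L))

setValidity("DelimitationState", function(object) {
  gtips <- object@guide@tree@phy$tip.label
  if (!setequal(names(object@assignment), gtips))
    return("assignment must cover every original population")
  TRUE
})
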