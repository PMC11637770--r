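## Monte-Carlo estimation of gene-tree probabilities and gdi by event-driven
## simulation of the structured coalescent for three sampled sequences.

#' @useDynLib gdidelim, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

## flatten a model into index form for the C++ core
.flattenModel <- function(model) {
  tree <- model@tree
  labs <- .allLabels(tree@phy)
  pm <- .parentMap(tree@phy)
  parent <- ifelse(is.na(pm[labs]), -1L, match(pm[labs], labs) - 1L)
  mig <- migrations(model)
  active <- mig$rate > 0
  list(labs = labs,
       parent = as.integer(parent),
       tau = unname(tree@tau[labs]),
       theta = unname(tree@theta[labs]),
       mdonor = match(mig$donor[active], labs) - 1L,
       mrecip = match(mig$recipient[active], labs) - 1L,
       mrate = mig$rate[active])
}

.simCore <- function(model, x, y, config, reps, record) {
  fl <- .flattenModel(model)
  dup <- if (config == "aab") x else y
  single <- if (config == "aab") y else x
  initpop <- match(c(dup, dup, single), fl$labs) - 1L
  taufocal <- model@tree@tau[[.mrca(model@tree, x, y)]]
  .simFirstCoalCpp(fl$parent, fl$tau, fl$theta, fl$mdonor, fl$mrecip,
                   fl$mrate, initpop, taufocal, as.integer(reps), record)
}

#' Simulate gene trees for three sampled sequences
#'
#' Draws gene trees under the structured coalescent on the full MSC-M model:
#' within each inter-node epoch, coalescence of each co-located lineage pair
#' (rate \eqn{2/\theta_P}) competes with backward migration of each lineage
#' along every active migration event (per-lineage rate
#' \eqn{4M_{D \to P}/\theta_P}); at each species-tree node surviving
#' lineages relocate into the ancestral population.  Two sequences are taken
#' from the duplicated population of the focal pair and one from the other;
#' no samples are taken from any other population.  Migration events whose
#' donor or recipient branch is not alive at the current time are inactive.
#'
#' The topology is determined by the first coalescing pair: \code{G1} groups
#' the duplicated pair, \code{G2}/\code{G3} the two mixed pairs.  A
#' \code{G1} tree whose first coalescence predates the focal divergence is
#' additionally flagged \code{G1a}.
#'
#' @param model an [MSCMModel-class].
#' @param x,y tip labels of the focal pair (reference first).
#' @param config \code{"aab"} (two sequences from \code{x}) or \code{"abb"}
#'   (two from \code{y}).
#' @param reps number of gene trees.
#' @param seed optional integer seed (applied via [set.seed()]).
#' @return data.frame with one row per tree: \code{topology},
#'   \code{t1}, \code{t2} (first/second coalescence times) and
#'   \code{firstBeforeSplit}.
#' @seealso [estimateGdiSim()] which only tallies counts and is much
#'   lighter for large \code{reps}.
#' @export
simulateGeneTrees <- function(model, x, y, config = c("aab", "abb"),
                              reps = 1000L, seed = NULL) {
  config <- match.arg(config)
  .checkPair(model, x, y)
  if (!is.null(seed)) set.seed(seed)
  out <- .simCore(model, x, y, config, reps, record = TRUE)
  rec <- out$record
  taufocal <- model@tree@tau[[.mrca(model@tree, x, y)]]
  data.frame(topology = paste0("G", rec[, 1]),
             t1 = rec[, 2], t2 = rec[, 3],
             firstBeforeSplit = rec[, 2] < taufocal)
}

#' Newick strings for simulated gene trees
#'
#' Renders the output of [simulateGeneTrees()] as rooted three-taxon Newick
#' strings with branch lengths in expected mutations per site, for
#' cross-checking against external coalescent simulators.
#'
#' @param sim data.frame from [simulateGeneTrees()].
#' @param config the sampling configuration used.
#' @return character vector of Newick strings.
#' @export
geneTreeNewick <- function(sim, config = c("aab", "abb")) {
  config <- match.arg(config)
  nm <- .seqNames(config)
  pairmap <- list(G1 = c(1, 2, 3), G2 = c(1, 3, 2), G3 = c(2, 3, 1))
  vapply(seq_len(nrow(sim)), function(i) {
    p <- pairmap[[sim$topology[i]]]
    t1 <- sim$t1[i]; t2 <- sim$t2[i]
    sprintf("((%s:%g,%s:%g):%g,%s:%g);",
            nm[p[1]], t1, nm[p[2]], t1, t2 - t1, nm[p[3]], t2)
  }, character(1))
}

#' Monte-Carlo estimate of gene-tree probabilities and gdi
#'
#' Simulates \code{reps} gene trees for the focal pair and tallies
#' topologies: \eqn{\hat{gdi}_K = \#G_{1a} / R} and \eqn{\hat{gdi}_J =
#' (\#G_1/R - 1/3) / (2/3)}, with binomial standard errors
#' \eqn{\sqrt{p(1-p)/R}}.  This is the computation path for focal pairs
#' receiving gene flow from third populations, where no closed form is
#' available, and serves as the validation oracle for the analytic paths
#' elsewhere.
#'
#' @inheritParams simulateGeneTrees
#' @param reps number of replicate gene trees R (default \code{1e5}; use
#'   \code{1e6} or more for publication-grade precision).
#' @return a [SimEstimate-class].
#' @examples
#' m <- parseGuideTree("(A,B);", tau = c(AB = 0.004), theta = 0.01)
#' est <- estimateGdiSim(m, "A", "B", "aab", reps = 2e4, seed = 1)
#' est@gdiK            # close to 1 - exp(-2*0.004/0.01)
#' @export
estimateGdiSim <- function(model, x, y, config = c("aab", "abb"),
                           reps = 1e5, seed = NULL) {
  config <- match.arg(config)
  .checkPair(model, x, y)
  stopifnot(reps >= 1)
  if (!is.null(seed)) set.seed(seed)
  out <- .simCore(model, x, y, config, reps, record = FALSE)
  cts <- out$counts
  counts <- c(G1 = cts[["p12"]], G2 = cts[["p13"]], G3 = cts[["p23"]],
              G1a = cts[["p12a"]])
  pg1 <- counts[["G1"]] / reps
  pg1a <- counts[["G1a"]] / reps
  se <- c(pG1 = sqrt(pg1 * (1 - pg1) / reps),
          pG1a = sqrt(pg1a * (1 - pg1a) / reps))
  new("SimEstimate", counts = counts, replicates = as.numeric(reps),
      pG1 = pg1, pG1a = pg1a,
      gdiJ = (pg1 - 1 / 3) / (2 / 3), gdiK = pg1a, se = se,
      seed = if (is.null(seed)) NA_real_ else as.numeric(seed))
}

.checkPair <- function(model, x, y) {
  tips <- tipLabels(model)
  if (identical(x, y)) stop("focal pair must be two distinct populations")
  if (!x %in% tips || !y %in% tips)
    stop("focal pair must be current tips of the tree")
  invisible(TRUE)
}

#' @rdname gdiValue
setMethod("gdiValue", "SimEstimate",
  function(object, definition = c("gdiK", "gdiJ")) {
    definition <- match.arg(definition)
    if (definition == "gdiK") object@gdiK else object@gdiJ
  })

setMethod("show", "SimEstimate", function(object) {
  cat(sprintf(
    "SimEstimate: R = %g gene trees%s\n", object@replicates,
    if (is.na(object@seed)) "" else sprintf(" (seed %g)", object@seed)))
  cat(sprintf("  counts: G1 = %d (G1a = %d), G2 = %d, G3 = %d\n",
              object@counts[["G1"]], object@counts[["G1a"]],
              object@counts[["G2"]], object@counts[["G3"]]))
  cat(sprintf("  P(G1)  = %.4f (SE %.4f)   P(G1a) = %.4f (SE %.4f)\n",
              object@pG1, object@se[["pG1"]],
              object@pG1a, object@se[["pG1a"]]))
  cat(sprintf("  gdiJ   = %.4f              gdiK   = %.4f\n",
              object@gdiJ, object@gdiK))
})
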