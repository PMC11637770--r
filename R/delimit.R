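## Hierarchical merge and split heuristics over a guide tree, with migration
## bookkeeping, optional non-sister merging and iteration logging.

#' Decision thresholds for the hierarchical algorithms
#'
#' A merge of two populations is accepted when either of the two gdi
#' indexes (reference A, \code{aab}; reference B, \code{abb}) falls below
#' \code{merge}.  A split is accepted when both indexes exceed
#' \code{splitLower} and at least one exceeds \code{splitUpper}.  The
#' conventional rule of thumb is one species below gdi 0.2 and two species
#' above 0.7, with the interval in between indecisive.
#'
#' @param merge merge cutoff, in (0, 1); default 0.2.
#' @param splitUpper,splitLower split cutoffs, \code{0 < splitLower <=
#'   splitUpper < 1}; defaults 0.7 and 0.5.
#' @return validated list of class \code{"gdiThresholds"}.
#' @export
gdiThresholds <- function(merge = 0.2, splitUpper = 0.7, splitLower = 0.5) {
  stopifnot(merge > 0, merge < 1, splitLower > 0,
            splitLower <= splitUpper, splitUpper < 1)
  structure(list(merge = merge, splitUpper = splitUpper,
                 splitLower = splitLower), class = "gdiThresholds")
}

#' gdi evaluation settings for delimitation runs
#'
#' @param definition index definition driving decisions (both are logged).
#' @param reps simulation replicates per evaluation on the simulation path.
#' @param seed optional base seed; each evaluation derives its own seed
#'   deterministically from it, so a run is reproducible end to end.
#' @param clamp clamp negative gdiJ to 0 before comparing to thresholds.
#' @return list of class \code{"gdiEngine"}.
#' @export
gdiEngine <- function(definition = c("gdiK", "gdiJ"), reps = 1e5,
                      seed = NULL, clamp = FALSE) {
  definition <- match.arg(definition)
  structure(list(definition = definition, reps = reps, seed = seed,
                 clamp = clamp), class = "gdiEngine")
}

#' Initialize a delimitation state from a guide model
#'
#' @param model guide [MSCMModel-class] (the starting delimitation: every
#'   tip is a candidate species).
#' @return a [DelimitationState-class].
#' @export
initDelimitation <- function(model) {
  tips <- tipLabels(model)
  new("DelimitationState", model = model, guide = model,
      assignment = setNames(tips, tips), iteration = 0L,
      log = .emptyLog(), evals = 0L)
}

.emptyLog <- function() {
  data.frame(iteration = integer(), pass = character(),
             x = character(), y = character(),
             gdiA = numeric(), gdiB = numeric(),
             definition = character(), methodA = character(),
             methodB = character(), decision = character(),
             stringsAsFactors = FALSE)
}

## evaluate both indexes for a pair, with per-evaluation derived seeds
.evalBoth <- function(state, model, x, y, engine) {
  sA <- if (is.null(engine$seed)) NULL else engine$seed + 2L * state@evals
  sB <- if (is.null(engine$seed)) NULL else engine$seed + 2L * state@evals + 1L
  rA <- gdiPair(model, x, y, definition = engine$definition, config = "aab",
                reps = engine$reps, seed = sA, clamp = engine$clamp)
  rB <- gdiPair(model, x, y, definition = engine$definition, config = "abb",
                reps = engine$reps, seed = sB, clamp = engine$clamp)
  state@evals <- state@evals + 1L
  list(state = state, A = rA, B = rB,
       vA = gdiValue(rA, engine$definition),
       vB = gdiValue(rB, engine$definition))
}

.logRow <- function(state, pass, x, y, ev, engine, decision) {
  state@log <- rbind(state@log, data.frame(
    iteration = state@iteration, pass = pass, x = x, y = y,
    gdiA = ev$vA, gdiB = ev$vB, definition = engine$definition,
    methodA = ev$A@method, methodB = ev$B@method, decision = decision,
    stringsAsFactors = FALSE))
  rownames(state@log) <- NULL
  state
}

## cherries (pairs of sister tips) of the current tree, left to right
.cherries <- function(tree) {
  children <- .childList(tree@phy)
  tips <- tipLabels(tree)
  out <- list()
  rec <- function(lab) {
    kids <- children[[lab]]
    if (is.null(kids)) return(invisible())
    if (all(kids %in% tips)) out[[length(out) + 1L]] <<- kids
    for (k in kids) rec(k)
  }
  rec(.rootLabel(tree@phy))
  out
}

## remap the original-population assignment after tips were merged
.remapAssignment <- function(assignment, oldTips, newLabel) {
  assignment[assignment %in% oldTips] <- newLabel
  assignment
}

#' One pass of the hierarchical merge algorithm over sister pairs
#'
#' Every cherry of the current tree is evaluated with both sampling
#' configurations; a merge is accepted when either index falls below the
#' merge cutoff.  All acceptable cherries are merged within the same pass
#' (decisions within a pass are independent; parameters are refreshed by
#' the backend between passes).
#'
#' @param state a [DelimitationState-class].
#' @param thresholds a [gdiThresholds()] object.
#' @param engine a [gdiEngine()] object.
#' @param backend parameter backend, a function \code{model -> model} (see
#'   [fixedBackend()]), applied after the pass if any merge occurred;
#'   \code{NULL} keeps inherited parameters.
#' @return updated state; \code{attr(, "changed")} says whether any merge
#'   was accepted.
#' @export
mergePass <- function(state, thresholds, engine, backend = NULL) {
  model <- state@model
  changed <- FALSE
  for (ch in .cherries(model@tree)) {
    x <- ch[1]; y <- ch[2]
    if (!all(c(x, y) %in% tipLabels(model))) next  # merged earlier this pass
    ev <- .evalBoth(state, model, x, y, engine)
    state <- ev$state
    accept <- min(ev$vA, ev$vB) < thresholds$merge
    state <- .logRow(state, "merge", x, y, ev, engine,
                     if (accept) "merged" else "kept distinct")
    if (accept) {
      if (length(tipLabels(model)) == 2L) {
        ## terminal merge: a single-population tree is not representable,
        ## so record the one-species delimitation at the assignment level
        state@assignment <- .remapAssignment(state@assignment, c(x, y),
                                             paste0(x, y))
      } else {
        model <- mergePopulations(model, x, y)
        state@assignment <- .remapAssignment(state@assignment, c(x, y),
                                             attr(model, "mergedLabel"))
      }
      changed <- TRUE
    }
  }
  if (changed && !is.null(backend)) model <- backend(model)
  state@model <- model
  attr(state, "changed") <- changed
  state
}

#' One pass of non-sister merging
#'
#' Considered only when no sister pair could be merged in the current
#' iteration: among non-sister tip pairs connected by at least one
#' migration event, the pair with the smallest gdi (smaller of the two
#' indexes; ties broken by lexicographically smallest pair) is merged if
#' that gdi is below the merge cutoff.  At most one non-sister pair is
#' merged per iteration.  The absorbed tip is chosen by the
#' displayed-species-tree rule: the donor of the larger migration rate
#' between the pair survives; migration between the merged pair is removed.
#'
#' @inheritParams mergePass
#' @return updated state with \code{attr(, "changed")}.
#' @export
nonsisterMergePass <- function(state, thresholds, engine, backend = NULL) {
  model <- state@model
  mig <- migrations(model)
  mig <- mig[mig$rate > 0, , drop = FALSE]
  tips <- tipLabels(model)
  cand <- unique(t(apply(
    mig[mig$donor %in% tips & mig$recipient %in% tips,
        c("donor", "recipient"), drop = FALSE], 1, sort)))
  attr(state, "changed") <- FALSE
  if (is.null(dim(cand)) || nrow(cand) == 0L) return(state)
  keep <- !apply(cand, 1, function(p) .isCherry(model@tree, p[1], p[2]))
  cand <- cand[keep, , drop = FALSE]
  if (nrow(cand) == 0L) return(state)
  ord <- order(cand[, 1], cand[, 2])
  cand <- cand[ord, , drop = FALSE]
  best <- NULL
  for (i in seq_len(nrow(cand))) {
    x <- cand[i, 1]; y <- cand[i, 2]
    ev <- .evalBoth(state, model, x, y, engine)
    state <- ev$state
    v <- min(ev$vA, ev$vB)
    state <- .logRow(state, "nonsister", x, y, ev, engine, "evaluated")
    if (is.null(best) || v < best$v)  # strict <: lexicographic tie-break
      best <- list(x = x, y = y, v = v)
  }
  if (best$v < thresholds$merge) {
    model <- mergePopulations(model, best$x, best$y, direction = "auto")
    state@assignment <- .remapAssignment(state@assignment,
                                         c(best$x, best$y),
                                         attr(model, "mergedLabel"))
    hit <- which(state@log$iteration == state@iteration &
                 state@log$pass == "nonsister" &
                 state@log$x == best$x & state@log$y == best$y)
    state@log$decision[hit[length(hit)]] <- "merged (non-sister)"
    if (!is.null(backend)) model <- backend(model)
    state@model <- model
    attr(state, "changed") <- TRUE
  }
  state
}

## tip labels of the clade below `node` in newick order, concatenated
.cladeLabel <- function(tree, node) {
  children <- .childList(tree@phy)
  tips <- tipLabels(tree)
  rec <- function(lab)
    if (lab %in% tips) lab
    else paste(vapply(children[[lab]], rec, character(1)), collapse = "")
  rec(node)
}

.cladeTips <- function(tree, node) {
  children <- .childList(tree@phy)
  tips <- tipLabels(tree)
  rec <- function(lab)
    if (lab %in% tips) lab
    else unlist(lapply(children[[lab]], rec))
  rec(node)
}

## collapse each multi-population species (a clade of the guide tree) into a
## single tip by repeated sister merges; species labels are the newick-order
## concatenations of their member populations
.collapseModel <- function(guide, assignment, backend = NULL) {
  model <- guide
  for (sp in unique(assignment)) {
    members <- names(assignment)[assignment == sp]
    while (length(members) > 1L) {
      merged <- FALSE
      for (i in seq_along(members)) {
        for (j in seq_along(members)) {
          if (i >= j) next
          if (.isCherry(model@tree, members[i], members[j])) {
            model <- mergePopulations(model, members[i], members[j])
            nl <- attr(model, "mergedLabel")
            members <- c(setdiff(members, members[c(i, j)]), nl)
            merged <- TRUE
            break
          }
        }
        if (merged) break
      }
      if (!merged) stop("species ", sp, " is not a clade of the guide tree")
    }
  }
  if (!is.null(backend)) model <- backend(model)
  model
}

#' One pass of the hierarchical split algorithm
#'
#' Starting from the coarsest delimitation, each current species comprising
#' more than one population is a split candidate: the species' clade root on
#' the guide tree is split into its two daughter clades, the two daughters
#' are treated as separate populations (all other current species intact)
#' and both gdi indexes are evaluated on the collapsed model.  The split is
#' accepted when both indexes exceed the lower cutoff and at least one
#' exceeds the upper cutoff; accepted daughters become candidates in the
#' next pass.
#'
#' @inheritParams mergePass
#' @return updated state with \code{attr(, "changed")}.
#' @export
splitPass <- function(state, thresholds, engine, backend = NULL) {
  guide <- state@guide
  changed <- FALSE
  for (sp in unique(state@assignment)) {
    members <- names(state@assignment)[state@assignment == sp]
    if (length(members) < 2L) next
    node <- if (length(members) == length(tipLabels(guide)))
              .rootLabel(guide@tree@phy)
            else Reduce(function(a, b) .mrca(guide@tree, a, b), members)
    kids <- .childList(guide@tree@phy)[[node]]
    d1 <- .cladeTips(guide@tree, kids[1])
    d2 <- .cladeTips(guide@tree, kids[2])
    trial <- state@assignment
    trial[d1] <- .cladeLabel(guide@tree, kids[1])
    trial[d2] <- .cladeLabel(guide@tree, kids[2])
    cmod <- .collapseModel(guide, trial, backend)
    x <- trial[[d1[1]]]; y <- trial[[d2[1]]]
    ev <- .evalBoth(state, cmod, x, y, engine)
    state <- ev$state
    accept <- min(ev$vA, ev$vB) > thresholds$splitLower &&
              max(ev$vA, ev$vB) > thresholds$splitUpper
    state <- .logRow(state, "split", x, y, ev, engine,
                     if (accept) "split" else "kept merged")
    if (accept) {
      state@assignment <- trial
      changed <- TRUE
    }
  }
  attr(state, "changed") <- changed
  state
}

#' Run the hierarchical merge or split algorithm to convergence
#'
#' Merge mode starts from the guide delimitation (every population a
#' species) and merges tip-ward pairs until no pass changes anything; when
#' \code{nonsister = TRUE} and no sister pair can be merged in an
#' iteration, one non-sister migration-connected pair may be merged
#' instead.  Split mode starts from one species and splits root-ward until
#' no pass changes anything.  The backend refreshes model parameters
#' between passes.
#'
#' @param model guide [MSCMModel-class].
#' @param mode \code{"merge"} or \code{"split"}.
#' @param thresholds a [gdiThresholds()] object.
#' @param engine a [gdiEngine()] object.
#' @param backend optional parameter backend (see [fixedBackend()]).
#' @param nonsister allow non-sister merges (merge mode only).
#' @param maxIter safety bound on iterations.
#' @return final [DelimitationState-class].
#' @examples
#' m <- parseGuideTree("((A,B),C);",
#'                     tau = c(AB = 0.001, ABC = 0.02), theta = 0.01)
#' st <- runDelimitation(m, "merge", gdiThresholds(merge = 0.2))
#' speciesAssignment(st)   # A and B merge, C stays distinct
#' @export
runDelimitation <- function(model, mode = c("merge", "split"),
                            thresholds = gdiThresholds(),
                            engine = gdiEngine(), backend = NULL,
                            nonsister = FALSE, maxIter = 100L) {
  mode <- match.arg(mode)
  if (!is.null(backend)) model <- backend(model)
  state <- initDelimitation(model)
  if (mode == "split") {
    state@assignment[] <- .cladeLabel(model@tree, .rootLabel(model@tree@phy))
  }
  repeat {
    state@iteration <- state@iteration + 1L
    if (state@iteration > maxIter) {
      warning("delimitation did not converge within ", maxIter,
              " iterations")
      break
    }
    if (mode == "merge") {
      if (nSpecies(state) < 2L) break
      state <- mergePass(state, thresholds, engine, backend)
      changed <- attr(state, "changed")
      if (!changed && nonsister) {
        state <- nonsisterMergePass(state, thresholds, engine, backend)
        changed <- attr(state, "changed")
      }
    } else {
      state <- splitPass(state, thresholds, engine, backend)
      changed <- attr(state, "changed")
    }
    if (!changed) break
  }
  state
}

## -- accessors / reporting ---------------------------------------------------

#' @rdname speciesAssignment
setMethod("speciesAssignment", "DelimitationState", function(object) {
  split(names(object@assignment), object@assignment)
})

#' @rdname iterationLog
setMethod("iterationLog", "DelimitationState", function(object) object@log)

#' Number of species in the current delimitation
#' @param state a [DelimitationState-class].
#' @return integer count.
#' @export
nSpecies <- function(state) length(unique(state@assignment))

setMethod("show", "DelimitationState", function(object) {
  sp <- speciesAssignment(object)
  cat(sprintf("DelimitationState: %d species after %d iteration(s)\n",
              length(sp), object@iteration))
  for (s in names(sp))
    cat(sprintf("  %s  <- {%s}\n", s, paste(sp[[s]], collapse = ", ")))
  cat(sprintf("  %d gdi evaluations logged\n", nrow(object@log)))
})
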