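## Model construction, accessors, tree surgery and serialization.

## -- internal topology helpers ----------------------------------------------

## ordered children of every internal node, as labels; preserves the
## left-to-right order of the Newick string (ape keeps edge order cladewise)
.childList <- function(phy) {
  labs <- .allLabels(phy)
  out <- list()
  for (i in seq_len(nrow(phy$edge))) {
    p <- labs[phy$edge[i, 1]]
    out[[p]] <- c(out[[p]], labs[phy$edge[i, 2]])
  }
  out
}

.rootLabel <- function(phy) .allLabels(phy)[ape::Ntip(phy) + 1L]

## parent lookup: named character, root maps to NA
.parentMap <- function(phy) {
  labs <- .allLabels(phy)
  p <- setNames(rep(NA_character_, length(labs)), labs)
  p[labs[phy$edge[, 2]]] <- labs[phy$edge[, 1]]
  p
}

## time interval [start, end) during which the branch above `label` exists
.branchInterval <- function(tree, label) {
  pm <- .parentMap(tree@phy)
  end <- if (is.na(pm[[label]])) Inf else tree@tau[[pm[[label]]]]
  c(tree@tau[[label]], end)
}

## labels on the path from `label` (exclusive) up to the root (inclusive)
.ancestors <- function(tree, label) {
  pm <- .parentMap(tree@phy)
  out <- character()
  while (!is.na(pm[[label]])) {
    label <- pm[[label]]
    out <- c(out, label)
  }
  out
}

.mrca <- function(tree, x, y) {
  ax <- c(x, .ancestors(tree, x))
  ay <- c(y, .ancestors(tree, y))
  ax[ax %in% ay][1L]
}

.isCherry <- function(tree, x, y) {
  pm <- .parentMap(tree@phy)
  !is.na(pm[[x]]) && identical(pm[[x]], pm[[y]])
}

## rebuild a phylo from a child list (used after tree surgery)
.newickFromChildren <- function(children, root) {
  rec <- function(lab) {
    if (is.null(children[[lab]])) return(lab)
    kids <- vapply(children[[lab]], rec, character(1))
    paste0("(", paste(kids, collapse = ","), ")", lab)
  }
  paste0(rec(root), ";")
}

## -- constructors ------------------------------------------------------------

#' Construct a species tree from a phylo object
#'
#' Unlabelled internal nodes are auto-labelled by concatenating their child
#' labels in left-to-right Newick order (so the parent of tips \code{X} and
#' \code{A} becomes \code{XA}).  \code{theta} may be a single value, which is
#' recycled to every branch.
#'
#' @param phy rooted, strictly binary \code{phylo} object.
#' @param tau named numeric of node ages for internal nodes (tips are fixed
#'   at 0; tip entries, if given, must be 0).
#' @param theta named numeric of population sizes per node label, or one
#'   unnamed value for all branches.
#' @return a validated [SpeciesTree-class].
#' @export
speciesTree <- function(phy, tau, theta) {
  if (!inherits(phy, "phylo")) stop("phy must be a phylo object")
  phy <- .autoLabel(phy)
  labs <- .allLabels(phy)
  full_tau <- setNames(rep(0, length(labs)), labs)
  if (!is.null(tau)) {
    if (is.null(names(tau))) stop("tau must be a named vector")
    unknown <- setdiff(names(tau), labs)
    if (length(unknown))
      stop("tau given for unknown label(s): ", paste(unknown, collapse = ", "))
    full_tau[names(tau)] <- tau
  }
  if (length(theta) == 1L && is.null(names(theta)))
    theta <- setNames(rep(theta, length(labs)), labs)
  if (is.null(names(theta))) stop("theta must be named (or a single value)")
  unknown <- setdiff(names(theta), labs)
  if (length(unknown))
    stop("theta given for unknown label(s): ", paste(unknown, collapse = ", "))
  missing <- setdiff(labs, names(theta))
  if (length(missing))
    stop("theta missing for label(s): ", paste(missing, collapse = ", "))
  new("SpeciesTree", phy = phy, tau = full_tau[labs], theta = theta[labs])
}

## fill empty internal labels by concatenating child labels, bottom-up
.autoLabel <- function(phy) {
  nt <- ape::Ntip(phy)
  nn <- phy$Nnode
  if (is.null(phy$node.label)) phy$node.label <- rep("", nn)
  phy$node.label[is.na(phy$node.label)] <- ""
  lab <- c(phy$tip.label, phy$node.label)
  ## children in edge order for each internal node
  kids <- split(phy$edge[, 2], phy$edge[, 1])
  ord <- rev(unique(phy$edge[, 1]))  # parents, deepest first (cladewise)
  for (v in ord) {
    if (lab[v] == "")
      lab[v] <- paste(lab[kids[[as.character(v)]]], collapse = "")
  }
  phy$node.label <- lab[nt + seq_len(nn)]
  phy
}

#' Build a migration-event table
#'
#' @param donor,recipient character vectors of population labels
#'   (forward-time direction: migrants move donor -> recipient).
#' @param rate numeric vector of rates M (migrants per generation,
#'   \eqn{M = mN} of the recipient); recycled.
#' @return data.frame usable as the \code{migration} argument of
#'   [parseGuideTree()].
#' @export
migrationEvents <- function(donor = character(), recipient = character(),
                            rate = numeric()) {
  n <- max(length(donor), length(recipient))
  data.frame(donor = as.character(donor),
             recipient = as.character(recipient),
             rate = if (length(rate)) rep_len(as.numeric(rate), n)
                    else rep(0, n),
             stringsAsFactors = FALSE)
}

#' Parse a guide tree with parameters into an MSC-M model
#'
#' The primary constructor: parses a Newick string (internal node labels
#' optional; missing ones are auto-generated by concatenating child labels,
#' e.g. the parent of \code{X} and \code{A} becomes \code{XA}), attaches
#' divergence times and population sizes, and optionally a set of directed
#' migration events.  The result is validated against all model invariants.
#'
#' @param newick a rooted, strictly binary Newick string.
#' @param tau named numeric of internal-node ages (expected mutations/site).
#' @param theta named numeric of per-branch population sizes, or a single
#'   value used for every branch.
#' @param migration optional data.frame from [migrationEvents()].
#' @return a validated [MSCMModel-class].
#' @examples
#' m <- parseGuideTree("((X,A),B);", tau = c(XA = 0.01, XAB = 0.02),
#'                     theta = 0.01)
#' tipLabels(m)
#' paramVector(m)
#' @export
parseGuideTree <- function(newick, tau = NULL, theta, migration = NULL) {
  phy <- tryCatch(
    suppressWarnings(ape::read.tree(text = newick)),
    error = function(e) NULL)
  if (is.null(phy)) stop("cannot parse Newick string: ", newick)
  if (!ape::is.rooted(phy) || !ape::is.binary(phy))
    stop("guide tree must be rooted and strictly binary")
  tree <- speciesTree(phy, tau = tau, theta = theta)
  if (is.null(migration)) migration <- migrationEvents()
  mod <- new("MSCMModel", tree = tree, migration = migration)
  validObject(mod@tree)
  validObject(mod)
  mod
}

## -- accessors ---------------------------------------------------------------

#' @rdname tipLabels
setMethod("tipLabels", "SpeciesTree", function(object) object@phy$tip.label)

#' @rdname tipLabels
setMethod("tipLabels", "MSCMModel", function(object) tipLabels(object@tree))

#' @rdname guideTree
setMethod("guideTree", "MSCMModel", function(object) object@tree)

#' @rdname migrations
setMethod("migrations", "MSCMModel", function(object) object@migration)

#' @rdname tauOf
setMethod("tauOf", "SpeciesTree", function(object, label) {
  if (missing(label)) object@tau else object@tau[label]
})

#' @rdname tauOf
setMethod("tauOf", "MSCMModel",
  function(object, label) tauOf(object@tree, label))

#' @rdname thetaOf
setMethod("thetaOf", "SpeciesTree", function(object, label) {
  if (missing(label)) object@theta else object@theta[label]
})

#' @rdname thetaOf
setMethod("thetaOf", "MSCMModel",
  function(object, label) thetaOf(object@tree, label))

#' @rdname paramVector
setMethod("paramVector", "MSCMModel", function(object) {
  tr <- object@tree
  internal <- tr@phy$node.label
  out <- c(setNames(tr@tau[internal], paste0("tau_", internal)),
           setNames(tr@theta, paste0("theta_", names(tr@theta))))
  mig <- object@migration
  if (nrow(mig))
    out <- c(out, setNames(mig$rate,
                           paste0("M_", mig$donor, "_", mig$recipient)))
  out
})

#' Update model parameters from a named vector
#'
#' The inverse of [paramVector()]: entries named \code{tau_<label>},
#' \code{theta_<label>} and \code{M_<donor>_<recipient>} overwrite the
#' corresponding parameters.  Names that match no parameter of the model are
#' ignored (posterior tables routinely carry parameters of populations not
#' present in the current delimitation); matched values are validated.
#'
#' @param model an [MSCMModel-class].
#' @param params named numeric vector.
#' @return the updated, re-validated model.
#' @export
updateModelParams <- function(model, params) {
  tr <- model@tree
  for (nm in names(params)) {
    if (startsWith(nm, "tau_")) {
      lab <- sub("^tau_", "", nm)
      if (lab %in% names(tr@tau)) tr@tau[[lab]] <- params[[nm]]
    } else if (startsWith(nm, "theta_")) {
      lab <- sub("^theta_", "", nm)
      if (lab %in% names(tr@theta)) tr@theta[[lab]] <- params[[nm]]
    } else if (startsWith(nm, "M_")) {
      pq <- strsplit(sub("^M_", "", nm), "_", fixed = TRUE)[[1]]
      if (length(pq) == 2L) {
        hit <- model@migration$donor == pq[1] &
               model@migration$recipient == pq[2]
        model@migration$rate[hit] <- params[[nm]]
      }
    }
  }
  model@tree <- tr
  validObject(model@tree)
  validObject(model)
  model
}

#' Serialize a species tree or model to Newick
#'
#' Internal node labels are embedded, so [parseGuideTree()] on the output
#' together with [paramVector()] values round-trips the model exactly.
#'
#' @param object a [SpeciesTree-class] or [MSCMModel-class].
#' @return a Newick string.
#' @export
newickString <- function(object) {
  tree <- if (is(object, "MSCMModel")) object@tree else object
  .newickFromChildren(.childList(tree@phy), .rootLabel(tree@phy))
}

## -- merges ------------------------------------------------------------------

#' Merge two populations of a model
#'
#' Sister tips are collapsed into a single tip labelled by concatenating the
#' two labels in tree order.  For non-sister tips the absorbed tip is
#' deleted, its parent node is suppressed, and the surviving tip is renamed
#' (survivor label first) -- the "displayed species tree" rule: the merged
#' population is placed on the branch of the surviving tip.  In both cases
#' migration events between the merged pair are removed; events connecting
#' either member to a third population are re-attached to the merged tip
#' (duplicate re-attached pairs are collapsed, keeping the larger rate, on
#' the understanding that the backend re-estimates a fresh rate on the next
#' pass).
#'
#' @param model an [MSCMModel-class].
#' @param x,y tip labels to merge.
#' @param direction for non-sister merges: \code{"keep-x"} absorbs y into x,
#'   \code{"keep-y"} the reverse, \code{"auto"} keeps the donor of the larger
#'   rate between the pair (ties: lexicographically smaller label survives).
#' @param newTheta optional population size for the merged tip; default is
#'   the surviving (left, for sister merges) member's theta, pending backend
#'   re-estimation.
#' @return the merged, validated [MSCMModel-class]; the merged tip label is
#'   in \code{attr(, "mergedLabel")}.
#' @export
mergePopulations <- function(model, x, y,
                             direction = c("auto", "keep-x", "keep-y"),
                             newTheta = NULL) {
  direction <- match.arg(direction)
  tree <- model@tree
  tips <- tipLabels(tree)
  if (identical(x, y)) stop("cannot merge a population with itself")
  if (!x %in% tips || !y %in% tips)
    stop("both populations must be current tips")
  children <- .childList(tree@phy)
  pm <- .parentMap(tree@phy)
  root <- .rootLabel(tree@phy)
  tau <- tree@tau; theta <- tree@theta
  mig <- model@migration

  if (.isCherry(tree, x, y)) {
    p <- pm[[x]]
    kids <- children[[p]]
    newlab <- paste0(kids[1], kids[2])  # left-to-right order
    survivor_theta <- theta[[kids[1]]]
    children[[p]] <- NULL
    gp <- pm[[p]]
    if (!is.na(gp)) children[[gp]][children[[gp]] == p] <- newlab
    else root <- newlab
    drop <- c(x, y, p)
    tau <- tau[!names(tau) %in% drop]
    theta <- theta[!names(theta) %in% drop]
    tau[newlab] <- 0
    theta[newlab] <- if (is.null(newTheta)) survivor_theta else newTheta
    renames <- setNames(c(newlab, newlab), c(x, y))
  } else {
    if (direction == "auto") {
      rxy <- mig$rate[mig$donor == x & mig$recipient == y]
      ryx <- mig$rate[mig$donor == y & mig$recipient == x]
      rxy <- if (length(rxy)) rxy[1] else 0
      ryx <- if (length(ryx)) ryx[1] else 0
      survivor <- if (rxy > ryx) x
                  else if (ryx > rxy) y
                  else sort(c(x, y))[1]
    } else survivor <- if (direction == "keep-x") x else y
    absorbed <- setdiff(c(x, y), survivor)
    newlab <- paste0(survivor, absorbed)
    ## delete absorbed tip: its parent is suppressed
    p <- pm[[absorbed]]
    if (is.na(p)) stop("cannot absorb the root")
    sib <- setdiff(children[[p]], absorbed)
    children[[p]] <- NULL
    gp <- pm[[p]]
    if (!is.na(gp)) children[[gp]][children[[gp]] == p] <- sib
    else root <- sib
    drop <- c(absorbed, p)
    tau <- tau[!names(tau) %in% drop]
    theta <- theta[!names(theta) %in% drop]
    ## rename survivor
    sp <- pm[[survivor]]
    if (identical(sp, p)) sp <- gp  # survivor was the sibling
    if (!is.na(sp) && sp %in% names(children))
      children[[sp]][children[[sp]] == survivor] <- newlab
    else if (identical(root, survivor)) root <- newlab
    names(tau)[names(tau) == survivor] <- newlab
    names(theta)[names(theta) == survivor] <- newlab
    if (!is.null(newTheta)) theta[[newlab]] <- newTheta
    renames <- setNames(c(newlab, newlab), c(x, y))
  }

  ## migration bookkeeping
  if (nrow(mig)) {
    between <- (mig$donor %in% c(x, y)) & (mig$recipient %in% c(x, y))
    mig <- mig[!between, , drop = FALSE]
    mig$donor[mig$donor %in% names(renames)] <-
      renames[mig$donor[mig$donor %in% names(renames)]]
    mig$recipient[mig$recipient %in% names(renames)] <-
      renames[mig$recipient[mig$recipient %in% names(renames)]]
    if (nrow(mig)) {
      key <- paste(mig$donor, mig$recipient, sep = "\r")
      if (anyDuplicated(key)) {
        mig <- do.call(rbind, lapply(split(mig, key), function(d)
          d[which.max(d$rate), , drop = FALSE]))
        rownames(mig) <- NULL
      }
    }
  }

  phy <- suppressWarnings(
    ape::read.tree(text = .newickFromChildren(children, root)))
  if (is.null(phy)) stop("merge produced an invalid tree")
  ntree <- new("SpeciesTree", phy = phy,
               tau = tau[.allLabels(phy)], theta = theta[.allLabels(phy)])
  validObject(ntree)
  out <- new("MSCMModel", tree = ntree, migration = mig)
  validObject(out)
  attr(out, "mergedLabel") <- newlab
  out
}

## -- Imap --------------------------------------------------------------------

#' Read an Imap file (individual-to-population assignment)
#'
#' Two whitespace-delimited columns: individual ID, population label -- the
#' format used by bpp.
#'
#' @param path file path.
#' @param model optional [MSCMModel-class]; if given, every mapped population
#'   must be a tip of its tree.
#' @return named character vector: individual -> population.
#' @export
readImap <- function(path, model = NULL) {
  tab <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("individual", "population"))
  map <- setNames(as.character(tab$population), tab$individual)
  if (anyDuplicated(names(map)))
    stop("duplicate individual IDs in Imap")
  if (!is.null(model)) {
    bad <- setdiff(unique(map), tipLabels(model))
    if (length(bad))
      stop("Imap names population(s) not on the tree: ",
           paste(bad, collapse = ", "))
  }
  map
}

#' Write an Imap file
#' @param map named character vector (individual -> population).
#' @param path file path.
#' @export
writeImap <- function(map, path) {
  utils::write.table(data.frame(names(map), unname(map)), path,
                     quote = FALSE, row.names = FALSE, col.names = FALSE,
                     sep = "\t")
  invisible(path)
}

## -- show methods ------------------------------------------------------------

setMethod("show", "SpeciesTree", function(object) {
  cat("SpeciesTree with", ape::Ntip(object@phy), "populations:",
      paste(tipLabels(object), collapse = ", "), "\n")
  cat("  newick:", newickString(object), "\n")
  int <- object@phy$node.label
  cat("  tau:  ", paste(sprintf("%s=%g", int, object@tau[int]),
                        collapse = ", "), "\n")
  rng <- range(object@theta)
  cat("  theta:", if (rng[1] == rng[2]) sprintf("%g (all branches)", rng[1])
      else paste(sprintf("%s=%g", names(object@theta), object@theta),
                 collapse = ", "), "\n")
})

setMethod("show", "MSCMModel", function(object) {
  show(object@tree)
  mig <- object@migration
  if (nrow(mig) == 0L) cat("  no migration (plain MSC)\n")
  else cat("  migration:",
           paste(sprintf("%s->%s (M=%g)", mig$donor, mig$recipient, mig$rate),
                 collapse = ", "), "\n")
})
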