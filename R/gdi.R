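## gdi definitions, computation-path dispatch, and posterior propagation.

#' Rescale P(G1) into the gdiJ index
#'
#' \eqn{gdi_J = (P_1 - 1/3) / (1 - 1/3)}: maps the no-gene-flow range of
#' \eqn{P(G_1)} from [1/3, 1] onto [0, 1].  Under gene flow \eqn{P(G_1)}
#' can fall below 1/3, making the index negative; one convention is to
#' clamp such values to 0, applied only when \code{clamp = TRUE}.
#'
#' @param p1 probability of gene tree G1, in [0, 1].
#' @param clamp set negative values to 0.
#' @return gdiJ in [-1/2, 1] (or [0, 1] when clamped).
#' @examples
#' gdiJFromP1(1/3)  # 0
#' gdiJFromP1(1)    # 1
#' @export
gdiJFromP1 <- function(p1, clamp = FALSE) {
  stopifnot(all(p1 >= 0 & p1 <= 1))
  g <- (p1 - 1 / 3) / (2 / 3)
  if (clamp) g <- pmax(g, 0)
  g
}

## which computation case applies to the focal pair:
##   a: no gene flow into x, y or any of their ancestors
##   b: x, y are sisters and the only such gene flow is between x and y
##   c: anything else (third-party gene flow, or non-sister pair with flow)
.gdiCase <- function(model, x, y) {
  tree <- model@tree
  mig <- migrations(model)
  mig <- mig[mig$rate > 0, , drop = FALSE]
  relevant <- unique(c(x, y, .ancestors(tree, x), .ancestors(tree, y)))
  incoming <- mig[mig$recipient %in% relevant, , drop = FALSE]
  if (nrow(incoming) == 0L) return("a")
  within <- all(incoming$donor %in% c(x, y)) &&
            all(incoming$recipient %in% c(x, y))
  if (within && .isCherry(tree, x, y)) return("b")
  "c"
}

## case (a): product of survival over the branch segments the duplicated
## pair traverses below the focal divergence (exact also for non-sister
## pairs, where the pair passes through ancestral populations of varying
## theta before reaching the MRCA)
.pgNoMig <- function(model, dup, other) {
  tree <- model@tree
  anc <- .mrca(tree, dup, other)
  pm <- .parentMap(tree@phy)
  S <- 0
  node <- dup
  t0 <- tree@tau[[dup]]
  while (!identical(node, anc)) {
    p <- pm[[node]]
    S <- S + 2 * (tree@tau[[p]] - t0) / tree@theta[[node]]
    t0 <- tree@tau[[p]]
    node <- p
  }
  surv <- exp(-S)
  c(pG1a = 1 - surv, pG1 = 1 - (2 / 3) * surv)
}

#' Genealogical divergence index for a pair of populations
#'
#' Computes \eqn{P(G_1)}, \eqn{P(G_{1a})} and both index definitions for an
#' ordered focal pair, dispatching on the migration pattern of the model:
#'
#' \describe{
#'   \item{no gene flow into the pair (\code{"nomig-closed"})}{the exact
#'     survival product over the branch segments traversed by the
#'     duplicated pair; gene flow out of the pair into third populations is
#'     irrelevant and ignored.}
#'   \item{gene flow only between the two (sister) populations}{the
#'     two-population chain: the printed closed forms when migration is
#'     unidirectional (\code{"caseb-closed"}), the general 21-state
#'     spectral computation when bidirectional (\code{"ctmc"}).}
#'   \item{gene flow from third populations (\code{"simulation"})}{
#'     Monte-Carlo estimation via [estimateGdiSim()] on the full model.}
#' }
#'
#' The result records which path was taken.  \code{method = "auto"} selects
#' as above; \code{"sim"} forces simulation for any pair.
#'
#' @param model an [MSCMModel-class].
#' @param x,y tip labels; \code{x} is the reference population.
#' @param definition preferred index definition, recorded for downstream
#'   decisions (both are always computed).
#' @param config \code{"aab"} duplicates \code{x}, \code{"abb"} duplicates
#'   \code{y}.
#' @param method \code{"auto"} or \code{"sim"}.
#' @param reps simulation replicates (simulation path only); must be >= 1.
#' @param seed optional seed for the simulation path.
#' @param clamp clamp negative gdiJ to 0 when its value is requested.
#' @return a [GdiResult-class].
#' @examples
#' m <- parseGuideTree("(A,B);", tau = c(AB = 0.005), theta = 0.01)
#' gdiPair(m, "A", "B", config = "aab")
#' @export
gdiPair <- function(model, x, y, definition = c("gdiK", "gdiJ"),
                    config = c("aab", "abb"), method = c("auto", "sim"),
                    reps = 1e5, seed = NULL, clamp = FALSE) {
  definition <- match.arg(definition)
  config <- match.arg(config)
  method <- match.arg(method)
  .checkPair(model, x, y)
  tree <- model@tree
  cs <- if (method == "sim") "c" else .gdiCase(model, x, y)
  se <- c(pG1 = NA_real_, pG1a = NA_real_)
  nrep <- NA_real_

  if (cs == "a") {
    dup <- if (config == "aab") x else y
    other <- setdiff(c(x, y), dup)
    pg <- .pgNoMig(model, dup, other)
    used <- "nomig-closed"
  } else if (cs == "b") {
    tau <- tree@tau[[.mrca(tree, x, y)]]
    thx <- tree@theta[[x]]; thy <- tree@theta[[y]]
    mig <- migrations(model)
    getM <- function(d, r) {
      hit <- mig$donor == d & mig$recipient == r
      if (any(hit)) mig$rate[hit][1] else 0
    }
    Mxy <- getM(x, y); Myx <- getM(y, x)
    if (Mxy > 0 && Myx > 0) {
      pg <- .pgCaseB(thx, thy, Mxy, Myx, tau, config)
      used <- "ctmc"
    } else if (Myx > 0) {     # flow y -> x: x plays A, y plays B
      pg <- if (config == "aab") casebAab(tau, thx, thy, Myx)
            else casebAbb(tau, thx, thy, Myx)
      used <- "caseb-closed"
    } else {                  # flow x -> y: y plays A, x plays B
      pg <- if (config == "aab") casebAbb(tau, thy, thx, Mxy)
            else casebAab(tau, thy, thx, Mxy)
      used <- "caseb-closed"
    }
  } else {
    if (reps < 1) stop("simulation budget must be >= 1 replicate")
    est <- estimateGdiSim(model, x, y, config, reps = reps, seed = seed)
    pg <- c(pG1a = est@pG1a, pG1 = est@pG1)
    se <- est@se
    nrep <- est@replicates
    used <- "simulation"
  }

  res <- new("GdiResult", pair = c(x, y), config = config,
             pG1 = pg[["pG1"]], pG1a = pg[["pG1a"]],
             gdiJ = gdiJFromP1(pg[["pG1"]]), gdiK = pg[["pG1a"]],
             method = used, se = se, replicates = nrep, clamped = clamp)
  validObject(res)
  res
}

#' @rdname gdiValue
setMethod("gdiValue", "GdiResult",
  function(object, definition = c("gdiK", "gdiJ")) {
    definition <- match.arg(definition)
    if (definition == "gdiK") return(object@gdiK)
    if (object@clamped) max(object@gdiJ, 0) else object@gdiJ
  })

setMethod("show", "GdiResult", function(object) {
  cat(sprintf("GdiResult for pair %s-%s (%s sampling), method %s\n",
              object@pair[1], object@pair[2], object@config, object@method))
  fmt <- function(v, s) if (is.na(s)) sprintf("%.4f", v)
                        else sprintf("%.4f (SE %.4f)", v, s)
  cat("  P(G1)  =", fmt(object@pG1, object@se[["pG1"]]),
      "  P(G1a) =", fmt(object@pG1a, object@se[["pG1a"]]), "\n")
  cat(sprintf("  gdiJ   = %.4f%s              gdiK   = %.4f\n",
              object@gdiJ,
              if (object@clamped && object@gdiJ < 0) " (clamped to 0)" else "",
              object@gdiK))
  if (length(object@posterior)) {
    for (d in c("gdiJ", "gdiK")) {
      s <- object@posterior[[d]]
      if (is.null(s)) next
      cat(sprintf(
        "  posterior %s: mean %.4f, 95%% ETI [%.4f, %.4f], HPD [%.4f, %.4f]\n",
        d, s$mean, s$etCI[1], s$etCI[2], s$hpdCI[1], s$hpdCI[2]))
    }
  }
})

## -- posterior propagation ---------------------------------------------------

#' Highest-posterior-density interval from a sample
#'
#' The shortest interval containing \code{ceiling(coverage * n)} consecutive
#' order statistics: the 95\% equal-tail window is slid across the sorted
#' sample and the shortest induced interval kept (leftmost on ties).
#' Assumes the HPD region is a single interval.
#'
#' @param draws numeric sample (sorted internally).
#' @param coverage interval mass, default 0.95.
#' @return numeric(2): lower and upper bound.
#' @export
hpdInterval <- function(draws, coverage = 0.95) {
  stopifnot(coverage > 0, coverage < 1)
  x <- sort(draws)
  n <- length(x)
  if (n < ceiling(1 / (1 - coverage)))
    stop("too few draws for a ", coverage * 100, "% HPD interval")
  k <- ceiling(coverage * n)
  widths <- x[k:n] - x[seq_len(n - k + 1L)]
  i <- which.min(widths)  # leftmost minimum
  c(x[i], x[i + k - 1L])
}

#' Propagate posterior parameter uncertainty into the gdi
#'
#' For each posterior draw of the model parameters the gdi is recomputed
#' with [gdiPair()]; the resulting values are a sample from the posterior
#' distribution of the index, summarized by its mean, 95\% equal-tail
#' interval and 95\% HPD interval.  When the focal pair requires the
#' simulation path, the draw list is first thinned to at most
#' \code{thinTo} evenly spaced draws.
#'
#' @param samples data.frame of posterior draws; columns named as in
#'   [paramVector()] (\code{tau_<label>}, \code{theta_<label>},
#'   \code{M_<donor>_<recipient>}).  Every parameter the computation needs
#'   must be present; extra columns are ignored.
#' @param model template [MSCMModel-class] supplying the topology and any
#'   parameters not sampled.
#' @inheritParams gdiPair
#' @param thinTo maximum number of draws evaluated on the simulation path
#'   (default 1000).
#' @param reps simulation replicates per draw (simulation path).
#' @param seed seed applied once before the per-draw loop.
#' @return a [GdiResult-class] whose point values are posterior means and
#'   whose \code{posterior} slot holds the summaries and per-draw values.
#' @export
posteriorGdi <- function(samples, model, x, y,
                         definition = c("gdiK", "gdiJ"),
                         config = c("aab", "abb"), thinTo = 1000L,
                         reps = 1e4, seed = NULL, clamp = FALSE) {
  definition <- match.arg(definition)
  config <- match.arg(config)
  if (!is.data.frame(samples) || nrow(samples) < 2L)
    stop("samples must be a data.frame with at least 2 draws")
  needed <- names(paramVector(model))
  missing <- setdiff(needed, names(samples))
  ## tau/theta columns of populations absent from the table are an error
  ## only if they vary the computation; require full coverage for safety
  if (length(missing))
    stop("posterior sample lacks parameter column(s): ",
         paste(missing, collapse = ", "))
  cs <- .gdiCase(model, x, y)
  if (cs == "c" && nrow(samples) > thinTo) {
    idx <- unique(round(seq(1L, nrow(samples), length.out = thinTo)))
    samples <- samples[idx, , drop = FALSE]
  }
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(samples)
  gJ <- gK <- p1 <- p1a <- numeric(n)
  for (i in seq_len(n)) {
    mi <- updateModelParams(model, unlist(samples[i, needed]))
    ri <- gdiPair(mi, x, y, definition = definition, config = config,
                  reps = reps, seed = NULL, clamp = FALSE)
    gJ[i] <- ri@gdiJ; gK[i] <- ri@gdiK
    p1[i] <- ri@pG1; p1a[i] <- ri@pG1a
  }
  summ <- function(v) list(
    mean = mean(v),
    etCI = unname(quantile(v, c(0.025, 0.975), type = 1)),
    hpdCI = if (n >= 20) hpdInterval(v) else c(NA_real_, NA_real_))
  res <- new("GdiResult", pair = c(x, y), config = config,
             pG1 = mean(p1), pG1a = mean(p1a),
             gdiJ = mean(gJ), gdiK = mean(gK),
             method = if (cs == "c") "simulation" else
                      c(a = "nomig-closed", b = "caseb-closed")[[cs]],
             se = c(pG1 = stats::sd(p1) / sqrt(n),
                    pG1a = stats::sd(p1a) / sqrt(n)),
             replicates = if (cs == "c") reps else NA_real_,
             clamped = clamp,
             posterior = list(gdiJ = summ(gJ), gdiK = summ(gK),
                              draws = data.frame(gdiJ = gJ, gdiK = gK),
                              n = n))
  validObject(res)
  res
}

#' Read a posterior-sample table
#'
#' Whitespace-delimited table with a header row of parameter names, as
#' written by bpp-style MCMC samplers.  Column names are normalized to the
#' [paramVector()] scheme: \code{M_A->B} becomes \code{M_A_B}.
#'
#' @param path file path.
#' @return data.frame of draws.
#' @export
readPosteriorSample <- function(path) {
  tab <- utils::read.table(path, header = TRUE, check.names = FALSE,
                           stringsAsFactors = FALSE)
  names(tab) <- gsub("->", "_", names(tab), fixed = TRUE)
  tab
}
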