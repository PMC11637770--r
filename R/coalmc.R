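## Structured-coalescent continuous-time Markov chain for 3 sampled
## sequences in a 2-population system: state enumeration, generator,
## transition probabilities and their time-integrals.

## pair codes over lineage indices 1..3 (1,2)=12, (1,3)=13, (2,3)=23
.PAIRS <- list(`12` = c(1L, 2L), `13` = c(1L, 3L), `23` = c(2L, 3L))

.seqNames <- function(config)
  if (config == "aab") c("a1", "a2", "b") else c("a", "b1", "b2")

.focalPair <- function(config) if (config == "aab") c(1L, 2L) else c(2L, 3L)

.initLocs <- function(config)
  if (config == "aab") c(1L, 1L, 2L) else c(1L, 2L, 2L)

## state label in the printed-matrix style: the coalesced pair is written as
## its location only, the remaining singleton as location + sequence name;
## a-type singletons precede the pair, b-type singletons follow it
.stateLabel <- function(phase, pair, loc, seqnames) {
  L <- c("A", "B")
  if (phase == 3L) return(paste0(L[loc[1]], L[loc[2]], L[loc[3]]))
  if (phase == 1L) return("A|B")
  pr <- .PAIRS[[as.character(pair)]]
  rem <- setdiff(1:3, pr)
  anc_txt <- L[loc[1]]
  rem_txt <- paste0(L[loc[2]], seqnames[rem])
  if (startsWith(seqnames[rem], "a")) paste0(rem_txt, anc_txt)
  else paste0(anc_txt, rem_txt)
}

#' Enumerate states of the two-population coalescent chain
#'
#' For 3 sampled sequences in two populations A and B the chain has 21
#' states: 8 with all three lineages distinct (one location per lineage),
#' 12 with one pair coalesced (identity of the pair, location of its
#' ancestor, location of the remaining lineage), and one artificial
#' absorbing state after the final coalescence.  States are ordered
#' canonically: three-lineage states in lexicographic location order,
#' two-lineage states grouped by coalesced pair, absorbing state last.
#'
#' With \code{reachability = "prune"} and a model with some migration rates
#' equal to zero, states unreachable from the initial state (\code{AAB} for
#' \code{aab} sampling, \code{ABB} for \code{abb}) are removed: for
#' unidirectional migration into the first population this leaves the
#' classical 11-state (\code{aab}) and 7-state (\code{abb}) chains.
#'
#' @param config \code{"aab"} (two sequences from A, one from B) or
#'   \code{"abb"}.
#' @param reachability \code{"full"} or \code{"prune"}.
#' @param model 2-population [MSCMModel-class], required for pruning.
#' @return data.frame with columns \code{phase} (3, 2 or 1 lineages-ish
#'   phase code; 1 is the absorbed state), \code{pair} (coalesced pair code
#'   12/13/23, \code{NA} otherwise), \code{loc1..loc3} (1 = A, 2 = B;
#'   for two-lineage states \code{loc1} is the pair ancestor and
#'   \code{loc2} the remaining lineage), and \code{label}.
#' @examples
#' nrow(enumerateStates("aab"))  # 21
#' @export
enumerateStates <- function(config = c("aab", "abb"),
                            reachability = c("full", "prune"),
                            model = NULL) {
  config <- match.arg(config)
  reachability <- match.arg(reachability)
  sq <- .seqNames(config)
  rows <- list()
  for (l1 in 1:2) for (l2 in 1:2) for (l3 in 1:2)
    rows[[length(rows) + 1L]] <-
      data.frame(phase = 3L, pair = NA_integer_,
                 loc1 = l1, loc2 = l2, loc3 = l3,
                 label = .stateLabel(3L, NA, c(l1, l2, l3), sq))
  for (p in c(12L, 13L, 23L)) for (la in 1:2) for (lr in 1:2)
    rows[[length(rows) + 1L]] <-
      data.frame(phase = 2L, pair = p, loc1 = la, loc2 = lr,
                 loc3 = NA_integer_,
                 label = .stateLabel(2L, p, c(la, lr), sq))
  rows[[length(rows) + 1L]] <-
    data.frame(phase = 1L, pair = NA_integer_, loc1 = NA_integer_,
               loc2 = NA_integer_, loc3 = NA_integer_, label = "A|B")
  states <- do.call(rbind, rows)
  attr(states, "config") <- config
  if (reachability == "prune") {
    if (is.null(model)) stop("pruning requires a model")
    Q <- buildGenerator(model, states)
    init <- match(if (config == "aab") "AAB" else "ABB", states$label)
    keep <- .reachableFrom(Q, init)
    states <- states[sort(keep), , drop = FALSE]
    rownames(states) <- NULL
    attr(states, "config") <- config
  }
  states
}

.reachableFrom <- function(Q, init) {
  seen <- logical(nrow(Q))
  seen[init] <- TRUE
  frontier <- init
  while (length(frontier)) {
    nxt <- integer()
    for (i in frontier) {
      js <- which(Q[i, ] > 0)
      js <- js[js != i & !seen[js]]
      seen[js] <- TRUE
      nxt <- c(nxt, js)
    }
    frontier <- nxt
  }
  which(seen)
}

## migration/coalescent rates of a 2-population model, oriented so that
## population "A" is the first tip.  Backward in time a lineage currently in
## recipient population R is traced into donor D at rate 4 M_{D->R} / theta_R.
.twoPopRates <- function(model) {
  tips <- tipLabels(model)
  if (length(tips) != 2L)
    stop("a 2-population model is required (found ", length(tips), " tips)")
  A <- tips[1]; B <- tips[2]
  mig <- migrations(model)
  getM <- function(d, r) {
    hit <- mig$donor == d & mig$recipient == r
    if (any(hit)) mig$rate[hit][1] else 0
  }
  thA <- thetaOf(model, A)[[1]]; thB <- thetaOf(model, B)[[1]]
  list(w = c(4 * getM(B, A) / thA, 4 * getM(A, B) / thB),
       cc = c(2 / thA, 2 / thB),
       tau = tauOf(model, .rootLabel(model@tree@phy))[[1]])
}

#' Build the generator matrix of the two-population chain
#'
#' Transition rates follow the structured coalescent: a lineage in
#' population P is traced (backward in time) into the other population P' at
#' the per-lineage migration rate \eqn{\varpi_P = 4 M_{P' \to P} / \theta_P}
#' (equivalently \eqn{m/\mu}), and each pair of lineages co-located in P
#' coalesces at rate \eqn{c_P = 2/\theta_P}.  Rows sum to zero.
#'
#' @param model a 2-population [MSCMModel-class]; the first tip plays the
#'   role of population A.
#' @param states state table from [enumerateStates()] (full or pruned).
#' @return square rate matrix with the state labels as dimnames and the
#'   derived rates in \code{attr(, "rates")}.
#' @export
buildGenerator <- function(model, states) {
  r <- .twoPopRates(model)
  Q <- .generatorCore(states, r$w, r$cc)
  attr(Q, "rates") <- r
  Q
}

.generatorCore <- function(states, w, cc) {
  n <- nrow(states)
  key <- with(states, paste(phase, pair, loc1, loc2, loc3, sep = "|"))
  idx <- function(phase, pair, loc) {
    loc <- c(loc, rep(NA_integer_, 3 - length(loc)))
    match(paste(phase, pair, loc[1], loc[2], loc[3], sep = "|"), key)
  }
  Q <- matrix(0, n, n, dimnames = list(states$label, states$label))
  absorb <- which(states$phase == 1L)
  for (i in seq_len(n)) {
    s <- states[i, ]
    if (s$phase == 3L) {
      loc <- c(s$loc1, s$loc2, s$loc3)
      for (l in 1:3) {                       # migration of one lineage
        nl <- loc; nl[l] <- 3L - loc[l]
        j <- idx(3L, NA_integer_, nl)
        if (!is.na(j)) Q[i, j] <- Q[i, j] + w[loc[l]]
      }
      for (pc in c(12L, 13L, 23L)) {         # coalescence of a pair
        pr <- .PAIRS[[as.character(pc)]]
        if (loc[pr[1]] == loc[pr[2]]) {
          rem <- setdiff(1:3, pr)
          j <- idx(2L, pc, c(loc[pr[1]], loc[rem]))
          if (!is.na(j)) Q[i, j] <- Q[i, j] + cc[loc[pr[1]]]
        }
      }
    } else if (s$phase == 2L) {
      loc <- c(s$loc1, s$loc2)
      for (l in 1:2) {
        nl <- loc; nl[l] <- 3L - loc[l]
        j <- idx(2L, s$pair, nl)
        if (!is.na(j)) Q[i, j] <- Q[i, j] + w[loc[l]]
      }
      if (loc[1] == loc[2] && length(absorb))
        Q[i, absorb] <- Q[i, absorb] + cc[loc[1]]
    }
  }
  diag(Q) <- diag(Q) - rowSums(Q)
  Q
}

## -- spectral machinery ------------------------------------------------------

#' Spectral decomposition of a generator matrix
#'
#' Attempts the eigendecomposition \eqn{Q = U \Lambda U^{-1}} with real
#' eigenvalues.  Returns \code{NULL} when the decomposition is unreliable
#' (complex eigenvalues, ill-conditioned eigenvectors, or reconstruction
#' error above tolerance), in which case callers fall back to a dense matrix
#' exponential.
#'
#' @param Q square rate matrix.
#' @param tol reconstruction tolerance (relative to the largest rate).
#' @return list with \code{lambda}, \code{U}, \code{V = U^{-1}}, or
#'   \code{NULL}.
#' @export
spectralDecomposition <- function(Q, tol = 1e-9) {
  e <- tryCatch(eigen(Q), error = function(err) NULL)
  if (is.null(e)) return(NULL)
  if (any(abs(Im(e$values)) > tol * max(1, max(abs(Q))))) return(NULL)
  U <- Re(e$vectors)
  lambda <- Re(e$values)
  if (rcond(U) < 1e-10) return(NULL)
  V <- tryCatch(solve(U), error = function(err) NULL)
  if (is.null(V)) return(NULL)
  err <- max(abs(U %*% (lambda * V) - Q))
  if (err > 1e-8 * max(1, max(abs(Q)))) return(NULL)
  list(lambda = lambda, U = U, V = V)
}

#' Transition probability matrix P(t) = exp(Qt)
#'
#' Uses the spectral form \eqn{p_{ij}(t) = \sum_k u_{ik} v_{kj} e^{\lambda_k
#' t}} when the eigendecomposition is well-conditioned, otherwise a dense
#' scaling-and-squaring matrix exponential.  Rows sum to 1; entries are
#' clamped into [0, 1] against numerical noise.
#'
#' @param Q generator matrix from [buildGenerator()].
#' @param t time (same mutation units as tau); must be >= 0.
#' @return row-stochastic matrix.
#' @export
transitionMatrix <- function(Q, t) {
  stopifnot(t >= 0)
  sd <- spectralDecomposition(Q)
  P <- if (!is.null(sd)) sd$U %*% (exp(sd$lambda * t) * sd$V)
       else as.matrix(Matrix::expm(Q * t))
  P <- pmin(pmax(P, 0), 1)
  dimnames(P) <- dimnames(Q)
  P
}

#' Integrated transition probabilities
#'
#' Computes \eqn{\int_0^\tau p_{ij}(t)\,dt} for all state pairs.  In the
#' spectral form the zero eigenvalue contributes \eqn{u_{i1} v_{1j} \tau}
#' and every other eigenvalue \eqn{u_{ik} v_{kj} (e^{\lambda_k \tau} - 1) /
#' \lambda_k}.  When the decomposition is unreliable the integral is taken
#' from the matrix exponential of the augmented block matrix
#' \eqn{[[Q, I], [0, 0]]}, whose top-right block is exactly the integral.
#'
#' @param Q generator matrix.
#' @param tau upper integration limit (>= 0).
#' @return matrix of integrals (entries >= 0; the zero matrix at tau = 0).
#' @export
integrateTransition <- function(Q, tau) {
  stopifnot(tau >= 0)
  n <- nrow(Q)
  sd <- spectralDecomposition(Q)
  if (!is.null(sd)) {
    zero <- abs(sd$lambda) < 1e-12 * max(1, max(abs(sd$lambda)))
    g <- ifelse(zero, tau, expm1(sd$lambda * tau) / sd$lambda)
    I <- sd$U %*% (g * sd$V)
  } else {
    A <- rbind(cbind(Q, diag(n)), matrix(0, n, 2 * n))
    E <- as.matrix(Matrix::expm(A * tau))
    I <- E[seq_len(n), n + seq_len(n)]
  }
  I <- pmax(I, 0)
  dimnames(I) <- dimnames(Q)
  I
}

## -- gene-tree probabilities -------------------------------------------------

## core: both P(G1a) and P(G1) for a 2-population chain with arbitrary rates
.pgCaseB <- function(thetaA, thetaB, MAB, MBA, tau,
                     config = c("aab", "abb")) {
  config <- match.arg(config)
  states <- enumerateStates(config)
  w <- c(4 * MBA / thetaA, 4 * MAB / thetaB)
  cc <- c(2 / thetaA, 2 / thetaB)
  Q <- .generatorCore(states, w, cc)
  init <- match(if (config == "aab") "AAB" else "ABB", states$label)
  fp <- .focalPair(config)
  I <- integrateTransition(Q, tau)
  three <- states$phase == 3L
  loc <- as.matrix(states[c("loc1", "loc2", "loc3")])
  co <- three & loc[, fp[1]] == loc[, fp[2]]
  pg1a <- sum(I[init, co] * cc[loc[co, fp[1]]])
  P <- transitionMatrix(Q, tau)
  pg1 <- pg1a + sum(P[init, three]) / 3
  c(pG1a = min(max(pg1a, 0), 1), pG1 = min(max(pg1, 0), 1))
}

#' Probability of gene tree G1a by Markov-chain integration
#'
#' \eqn{P(G_{1a})} is the probability that the two sequences sampled from
#' the duplicated population coalesce with each other -- in either
#' population -- before the focal divergence time \eqn{\tau}.  It is
#' obtained by integrating the coalescent density
#' \eqn{f(t) = \sum_s p_{\mathrm{init},s}(t)\, c_{P(s)}} over \eqn{(0,
#' \tau)}, where the sum runs over three-lineage states \eqn{s} in which the
#' duplicated pair is co-located in population \eqn{P(s)}.  This probability
#' is the \eqn{gdi_K} definition of the genealogical divergence index.
#'
#' @param model a 2-population [MSCMModel-class] (first tip = population A).
#' @param config \code{"aab"} or \code{"abb"}.
#' @param tau upper limit; defaults to the root age of the model.
#' @return probability in [0, 1].
#' @seealso [pG1Markov()], [casebAab()], [casebAbb()]
#' @export
pG1aMarkov <- function(model, config = c("aab", "abb"), tau = NULL) {
  config <- match.arg(config)
  r <- .twoPopRates(model)
  if (is.null(tau)) tau <- r$tau
  tips <- tipLabels(model)
  mig <- migrations(model)
  getM <- function(d, rr) {
    hit <- mig$donor == d & mig$recipient == rr
    if (any(hit)) mig$rate[hit][1] else 0
  }
  .pgCaseB(thetaOf(model, tips[1])[[1]], thetaOf(model, tips[2])[[1]],
           getM(tips[1], tips[2]), getM(tips[2], tips[1]), tau,
           config)[["pG1a"]]
}

#' Probability of gene tree G1 by Markov-chain integration
#'
#' Adds to \eqn{P(G_{1a})} the probability \eqn{P(G_{1b})} that no
#' coalescence occurs before \eqn{\tau} -- so that all three lineages enter
#' the ancestral population and coalesce in random order, producing topology
#' G1 with probability 1/3.
#'
#' @inheritParams pG1aMarkov
#' @return probability in [0, 1].
#' @export
pG1Markov <- function(model, config = c("aab", "abb"), tau = NULL) {
  config <- match.arg(config)
  r <- .twoPopRates(model)
  if (is.null(tau)) tau <- r$tau
  tips <- tipLabels(model)
  mig <- migrations(model)
  getM <- function(d, rr) {
    hit <- mig$donor == d & mig$recipient == rr
    if (any(hit)) mig$rate[hit][1] else 0
  }
  .pgCaseB(thetaOf(model, tips[1])[[1]], thetaOf(model, tips[2])[[1]],
           getM(tips[1], tips[2]), getM(tips[2], tips[1]), tau,
           config)[["pG1"]]
}
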