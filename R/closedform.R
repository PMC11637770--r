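## Analytic gdi formulas: no gene flow, unidirectional two-population
## migration (aab and abb sampling), and gene flow from a ghost lineage.
## Every expression is cross-checked against the Markov-chain computation in
## the test suite; near removable singularities the chain path is used.

## relative guard for removable singularities in the printed expressions
.SINGULAR_TOL <- 1e-10

#' Gene-tree probability P(G1) with no gene flow
#'
#' With complete isolation, the two sequences from the duplicated population
#' coalesce before \eqn{\tau} with probability \eqn{1 - e^{-2\tau/\theta}};
#' otherwise all three lineages coalesce in random order in the ancestor,
#' giving G1 with probability 1/3: \eqn{P_1 = 1 - \frac{2}{3} e^{-2\tau /
#' \theta}}.
#'
#' @param tau divergence time (expected mutations/site).
#' @param theta population-size parameter of the duplicated (focal)
#'   population.
#' @return probability in [1/3, 1).
#' @export
p1NoMig <- function(tau, theta) {
  stopifnot(tau >= 0, theta > 0)
  1 - (2 / 3) * exp(-2 * tau / theta)
}

#' Genealogical divergence index with no gene flow
#'
#' \eqn{gdi = 1 - e^{-2\tau/\theta} = 1 - e^{-T/(2N)}}: the probability that
#' the duplicated pair coalesces before the split, i.e. the rescaling of
#' [p1NoMig()] from [1/3, 1] onto [0, 1].  Under isolation the two
#' definitions gdiJ and gdiK coincide and equal this value.
#'
#' @inheritParams p1NoMig
#' @return gdi in [0, 1).
#' @export
gdiNoMig <- function(tau, theta) {
  stopifnot(tau >= 0, theta > 0)
  -expm1(-2 * tau / theta)
}

#' Closed-form gdi under unidirectional migration, aab sampling
#'
#' Two populations A and B with migrants moving B to A forward in time at
#' rate \eqn{M} per generation (so backward in time the two A lineages are
#' traced into B at per-lineage rate \eqn{4M/\theta_A}), and two sequences
#' sampled from A plus one from B.  Returns the exact
#' \eqn{P(G_{1a})} and \eqn{P(G_1)} from the 11-state chain's closed-form
#' solution.  Denominator factors such as \eqn{(M\theta_B - \theta_A)}
#' vanish on removable-singularity manifolds; within a relative tolerance of
#' those manifolds the Markov-chain path is evaluated instead.
#'
#' Under this model \eqn{P(G_1)} can drop below 1/3 when A is much larger
#' than B or migration is strong (the duplicated pair is then more likely to
#' be split by a coalescence with b), so gdiJ can be negative; gdiK stays in
#' [0, 1].
#'
#' @param tau divergence time.
#' @param thetaA,thetaB population sizes.
#' @param M migration rate (migrants/generation) from B into A.
#' @return named numeric: \code{pG1a}, \code{pG1}.
#' @export
casebAab <- function(tau, thetaA, thetaB, M) {
  stopifnot(tau >= 0, thetaA > 0, thetaB > 0, M >= 0)
  scale <- max(thetaA, thetaB)
  dens <- c(M * thetaB - thetaA,
            3 * thetaA - thetaB - 4 * M * thetaB,
            thetaA - 2 * M * thetaB - thetaB)
  if (any(abs(dens) < .SINGULAR_TOL * scale))
    return(.pgCaseB(thetaA, thetaB, 0, M, tau, "aab"))
  e1 <- exp(-6 * tau / thetaB)
  e2 <- exp(-4 * M * tau / thetaA - 2 * tau / thetaB)
  e3 <- exp(-2 * (1 + 4 * M) * tau / thetaA)
  pg1a <-
    4 * e1 * thetaB^2 * M^2 /
      (3 * (M * thetaB - thetaA) * (3 * thetaA - thetaB - 4 * M * thetaB)) +
    4 * e2 * thetaA * thetaB^2 * M^2 /
      ((thetaA - M * thetaB) * (thetaA + 2 * M * thetaB) *
       (thetaA - 2 * M * thetaB - thetaB)) +
    (3 * thetaA + 2 * M * (4 * M + 3) * thetaB) /
      (3 * (1 + 4 * M) * (thetaA + 2 * M * thetaB)) -
    e3 / (1 + 4 * M) -
    8 * e3 * thetaA * thetaB * M^2 /
      ((thetaA - thetaB - 2 * M * thetaB) *
       (3 * thetaA - thetaB - 4 * M * thetaB) * (1 + 4 * M))
  ## e3 * e4 simplifies to exp(-4M tau/thetaA - 2 tau/thetaB) = e2; using the
  ## combined form avoids overflow of the positive exponent in e4
  pg1 <- (4 * thetaA * thetaB * e2 * (1 + 4 * M) * M -
          thetaA * thetaB * (8 * M^2 - 3) -
          thetaA * thetaB * e3 * (8 * M^2 + 2) +
          (2 * e3 - 4 * M * e3 - 3) * thetaA^2 +
          2 * thetaB^2 * M * (2 * M + 1) * (4 * M + 3 - 2 * e3)) /
         (3 * (1 + 4 * M) * (thetaA + 2 * thetaB * M) *
          (thetaB + 2 * thetaB * M - thetaA))
  c(pG1a = min(max(pg1a, 0), 1), pG1 = min(max(pg1, 0), 1))
}

#' Closed-form gdi under unidirectional migration, abb sampling
#'
#' Same model as [casebAab()] (forward migration B into A) but with two
#' sequences sampled from B and one from A, solved from the 7-state chain.
#' Here \eqn{P(G_1)} always exceeds 1/3, so gdiJ is never negative.
#'
#' @inheritParams casebAab
#' @return named numeric: \code{pG1a}, \code{pG1}.
#' @export
casebAbb <- function(tau, thetaA, thetaB, M) {
  stopifnot(tau >= 0, thetaA > 0, thetaB > 0, M >= 0)
  scale <- max(thetaA, thetaB)
  if (abs(thetaA - M * thetaB) < .SINGULAR_TOL * scale)
    return(.pgCaseB(thetaA, thetaB, 0, M, tau, "abb"))
  e1 <- exp(-6 * tau / thetaB)
  ## e1 * e2 simplifies to exp(-4M tau/thetaA - 2 tau/thetaB) (log-safe)
  e12 <- exp(-4 * M * tau / thetaA - 2 * tau / thetaB)
  e3 <- e12
  pg1a <- (3 * thetaA^2 - 2 * thetaB^2 * M^2 - thetaA * thetaB * M -
           3 * e12 * thetaA^2 +
           e1 * thetaB * M * (thetaA + 2 * thetaB * M)) /
          (3 * (thetaA - M * thetaB) * (thetaA + 2 * M * thetaB))
  pg1 <- ((3 - 2 * e3) * thetaA + 2 * M * thetaB) /
         (3 * (thetaA + 2 * M * thetaB))
  c(pG1a = min(max(pg1a, 0), 1), pG1 = min(max(pg1, 0), 1))
}

## -- ghost-lineage model -----------------------------------------------------

#' Parameters of the ghost-lineage migration model
#'
#' Three species A, B, C: A and B are sisters separated at \eqn{\tau_{AB}},
#' C is an outgroup ("ghost", unsampled) separated at \eqn{\tau_{ABC}} that
#' has been contributing migrants into A at rate \eqn{M_{CA}} per
#' generation.  Two sequences are sampled from A and one from B; none from
#' C.
#'
#' @param tauABC,tauAB divergence times, \code{tauABC > tauAB >= 0}.
#' @param thetaA,thetaB,thetaC,thetaAB,thetaABC population sizes (> 0;
#'   \code{thetaB} and \code{thetaABC} do not enter P(G1) but are carried
#'   for completeness).
#' @param M migration rate C into A (>= 0).
#' @return validated list of class \code{"GhostModelParams"} with the
#'   derived \code{deltaTau = tauABC - tauAB}.
#' @export
ghostParams <- function(tauABC, tauAB, thetaA, thetaB = thetaA, thetaC,
                        thetaAB, thetaABC = thetaAB, M) {
  stopifnot(tauABC > tauAB, tauAB >= 0, thetaA > 0, thetaB > 0, thetaC > 0,
            thetaAB > 0, thetaABC > 0, M >= 0)
  structure(list(tauABC = tauABC, tauAB = tauAB, thetaA = thetaA,
                 thetaB = thetaB, thetaC = thetaC, thetaAB = thetaAB,
                 thetaABC = thetaABC, M = M,
                 deltaTau = tauABC - tauAB),
            class = "GhostModelParams")
}

## the 4-state generator for the pair (a1, a2): states AA, AC, CC, coalesced
.ghostQ <- function(w, cA, cC) {
  matrix(c(-(2 * w + cA), 2 * w,  0,  cA,
           0,             -w,     w,  0,
           0,             0,     -cC, cC,
           0,             0,      0,  0),
         4, 4, byrow = TRUE,
         dimnames = list(c("AA", "AC", "CC", "A|C"),
                         c("AA", "AC", "CC", "A|C")))
}

#' Transition probabilities of the ghost-lineage chain
#'
#' The history of the two A sequences up to \eqn{\tau_{AB}} is a 4-state
#' chain (both in A; one in A one in C; both in C; coalesced) with
#' eigenvalues \eqn{0, -c_C, -c_A - 2\varpi, -\varpi} where \eqn{\varpi =
#' 4M/\theta_A} and \eqn{c_P = 2/\theta_P}.  Returns the first row of
#' \eqn{P(\tau_{AB})}; the last entry \eqn{p_{14}} is \eqn{P(G_{1a}) =
#' gdi_K}.  Near the removable singularities \eqn{c_C = \varpi} or
#' \eqn{c_A - c_C + 2\varpi = 0} the dense matrix exponential is used.
#'
#' @param params a [ghostParams()] object.
#' @return named numeric \code{p11..p14}, non-negative, summing to 1.
#' @export
ghostTransitionProbs <- function(params) {
  stopifnot(inherits(params, "GhostModelParams"))
  tau <- params$tauAB
  w <- 4 * params$M / params$thetaA
  cA <- 2 / params$thetaA
  cC <- 2 / params$thetaC
  scale <- max(w, cA, cC)
  if (w == 0) {
    p <- c(p11 = exp(-cA * tau), p12 = 0, p13 = 0)
    return(c(p, p14 = 1 - p[["p11"]]))
  }
  if (abs(cC - w) < .SINGULAR_TOL * scale ||
      abs(cA - cC + 2 * w) < .SINGULAR_TOL * scale) {
    P <- as.matrix(Matrix::expm(.ghostQ(w, cA, cC) * tau))
    p <- P[1, ]
    return(c(p11 = p[[1]], p12 = p[[2]], p13 = p[[3]], p14 = p[[4]]))
  }
  p11 <- exp(-(cA + 2 * w) * tau)
  p12 <- 2 * w / (cA + w) * (exp(-w * tau) - exp(-(cA + 2 * w) * tau))
  p13 <- 2 * w^2 * ((cC - w) * exp(-(cA + 2 * w) * tau) -
                    (cA + w) * exp(-cC * tau) +
                    (cA - cC + 2 * w) * exp(-w * tau)) /
         ((cA + w) * (cC - w) * (cA - cC + 2 * w))
  p14 <- 1 - p11 - p12 - p13
  c(p11 = p11, p12 = p12, p13 = p13, p14 = p14)
}

#' Probability of gene tree G1 under ghost-lineage gene flow
#'
#' Averages over the state of the pair (a1, a2) at \eqn{\tau_{AB}}:
#' \deqn{P(G_1) = p_{11} \tfrac13 + p_{12} e^{-2\Delta\tau/\theta_{AB}}
#' \tfrac13 + p_{13} (1 - \tfrac23 e^{-2\Delta\tau/\theta_C}) + p_{14},}
#' with \eqn{\Delta\tau = \tau_{ABC} - \tau_{AB}}.  Both A sequences still
#' in A at \eqn{\tau_{AB}} leaves a random-order coalescence (1/3); one
#' sequence in C must avoid the b lineage through the AB ancestor; both in C
#' give G1 if they coalesce in C or in the ABC ancestor; an already
#' coalesced pair is G1 (indeed G1a) outright.  Migration into A can make
#' \eqn{P(G_1) < 1/3} and hence gdiJ negative.
#'
#' @param params a [ghostParams()] object.
#' @return probability in [0, 1]; \eqn{P(G_2) = P(G_3) = (1 - P(G_1))/2}.
#' @export
ghostPG1 <- function(params) {
  p <- ghostTransitionProbs(params)
  dt <- params$deltaTau
  p[["p11"]] / 3 +
    p[["p12"]] * exp(-2 * dt / params$thetaAB) / 3 +
    p[["p13"]] * (1 - (2 / 3) * exp(-2 * dt / params$thetaC)) +
    p[["p14"]]
}
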