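## Model builders and independent oracles shared across the test files.

## two populations A, B diverged at `tau`, optional migration in both
## forward directions (MAB: A donates to B, MBA: B donates to A)
twoPopModel <- function(tau, thetaA, thetaB, MAB = 0, MBA = 0,
                        thetaRoot = thetaA) {
  mig <- NULL
  if (MAB > 0 || MBA > 0) {
    mig <- migrationEvents(c("A", "B")[c(MAB > 0, MBA > 0)],
                           c("B", "A")[c(MAB > 0, MBA > 0)],
                           c(MAB, MBA)[c(MAB > 0, MBA > 0)])
  }
  parseGuideTree("(A,B);", tau = c(AB = tau),
                 theta = c(A = thetaA, B = thetaB, AB = thetaRoot),
                 migration = mig)
}

## the five-population isolation-by-distance model: X split from A in full
## isolation, symmetric migration M between adjacent populations of A-B-C-D
ibdModel <- function(M = 2) {
  mig <- if (M > 0)
    migrationEvents(c("A", "B", "B", "C", "C", "D"),
                    c("B", "A", "C", "B", "D", "C"), M)
  parseGuideTree("((((X,A),B),C),D);",
                 tau = c(XA = 0.01, XAB = 0.02, XABC = 0.03, XABCD = 0.04),
                 theta = 0.01, migration = mig)
}

## three species with a ghost outgroup C donating into A
ghostModel <- function(tauABC = 0.01, tauAB = 0.005, thetaA = 0.05,
                       thetaB = 0.05, thetaC = 0.05, thetaAB = 0.001,
                       thetaABC = 0.01, M = 1) {
  parseGuideTree("((A,B),C);", tau = c(AB = tauAB, ABC = tauABC),
                 theta = c(A = thetaA, B = thetaB, C = thetaC,
                           AB = thetaAB, ABC = thetaABC),
                 migration = migrationEvents("C", "A", M))
}

ghostWorkedParams <- function()
  ghostParams(tauABC = 0.01, tauAB = 0.005, thetaA = 0.05, thetaC = 0.05,
              thetaAB = 0.001, M = 1)

## ---------------------------------------------------------------------------
## printed generator matrices for the unidirectional chain (forward flow
## B -> A), as functions of w = 4M/thetaA, cA = 2/thetaA, cB = 2/thetaB;
## independent hard-coded oracles for the generator builder
## ---------------------------------------------------------------------------

printedQ11 <- function(w, cA, cB) {
  labs <- c("AAB", "ABB", "BAB", "BBB", "ABb", "Aa1B", "Aa2B",
            "BBb", "Ba1B", "Ba2B", "A|B")
  Q <- matrix(0, 11, 11, dimnames = list(labs, labs))
  Q["AAB", ] <- c(-2 * w - cA, w, w, 0, cA, 0, 0, 0, 0, 0, 0)
  Q["ABB", ] <- c(0, -w - cB, 0, w, 0, cB, 0, 0, 0, 0, 0)
  Q["BAB", ] <- c(0, 0, -w - cB, w, 0, 0, cB, 0, 0, 0, 0)
  Q["BBB", ] <- c(0, 0, 0, -3 * cB, 0, 0, 0, cB, cB, cB, 0)
  Q["ABb", ] <- c(0, 0, 0, 0, -w, 0, 0, w, 0, 0, 0)
  Q["Aa1B", ] <- c(0, 0, 0, 0, 0, -w, 0, 0, w, 0, 0)
  Q["Aa2B", ] <- c(0, 0, 0, 0, 0, 0, -w, 0, 0, w, 0)
  Q["BBb", ] <- c(0, 0, 0, 0, 0, 0, 0, -cB, 0, 0, cB)
  Q["Ba1B", ] <- c(0, 0, 0, 0, 0, 0, 0, 0, -cB, 0, cB)
  Q["Ba2B", ] <- c(0, 0, 0, 0, 0, 0, 0, 0, 0, -cB, cB)
  Q
}

printedQ7 <- function(w, cB) {
  labs <- c("ABB", "BBB", "AaB", "BaB", "BBb1", "BBb2", "A|B")
  Q <- matrix(0, 7, 7, dimnames = list(labs, labs))
  Q["ABB", ] <- c(-w - cB, w, cB, 0, 0, 0, 0)
  Q["BBB", ] <- c(0, -3 * cB, 0, cB, cB, cB, 0)
  Q["AaB", ] <- c(0, 0, -w, w, 0, 0, 0)
  Q["BaB", ] <- c(0, 0, 0, -cB, 0, 0, cB)
  Q["BBb1", ] <- c(0, 0, 0, 0, -cB, 0, cB)
  Q["BBb2", ] <- c(0, 0, 0, 0, 0, -cB, cB)
  Q
}

## dense matrix-exponential oracle (scaling-and-squaring via Matrix)
expmOracle <- function(Q, t) as.matrix(Matrix::expm(Q * t))

## brute-force shortest-window HPD search
hpdBruteForce <- function(x, coverage = 0.95) {
  x <- sort(x)
  n <- length(x)
  k <- ceiling(coverage * n)
  best <- NULL
  for (i in seq_len(n - k + 1)) {
    wdt <- x[i + k - 1] - x[i]
    if (is.null(best) || wdt < best$w) best <- list(w = wdt, lo = x[i],
                                                    hi = x[i + k - 1])
  }
  c(best$lo, best$hi)
}
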