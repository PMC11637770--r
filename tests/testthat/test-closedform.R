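test_that("no-gene-flow formulas hit the calibration anchors", {
  expect_equal(p1NoMig(0, 0.01), 1 / 3)
  expect_equal(gdiNoMig(0, 0.01), 0)
  ## gdi = 0.2 and 0.7 correspond to split times -log(0.8) and -log(0.3)
  ## coalescent units, i.e. 0.22 and 1.20, and to P(G1) = 0.47 and 0.8
  ct <- function(gdi) -log(1 - gdi)
  expect_equal(round(ct(0.2), 2), 0.22)
  expect_equal(round(ct(0.7), 2), 1.20)
  theta <- 0.01
  expect_equal(round(p1NoMig(ct(0.2) * theta / 2, theta), 2), 0.47)
  expect_equal(round(p1NoMig(ct(0.7) * theta / 2, theta), 1), 0.8)
  ## gdiNoMig inverts the coalescent-unit anchors
  expect_lt(abs(gdiNoMig(0.22 * theta / 2, theta) - 0.2), 0.005)
  expect_lt(abs(gdiNoMig(1.20 * theta / 2, theta) - 0.7), 0.005)
})

test_that("unidirectional closed forms match the chain to 1e-8", {
  set.seed(10)
  for (i in 1:30) {
    thA <- runif(1, 0.004, 0.08)
    thB <- runif(1, 0.004, 0.08)
    M <- runif(1, 0.05, 3)
    tau <- runif(1, 0.2, 4) * thB
    chainA <- gdidelim:::.pgCaseB(thA, thB, 0, M, tau, "aab")
    closedA <- casebAab(tau, thA, thB, M)
    expect_equal(closedA[["pG1a"]], chainA[["pG1a"]], tolerance = 1e-8)
    expect_equal(closedA[["pG1"]], chainA[["pG1"]], tolerance = 1e-8)
    chainB <- gdidelim:::.pgCaseB(thA, thB, 0, M, tau, "abb")
    closedB <- casebAbb(tau, thA, thB, M)
    expect_equal(closedB[["pG1a"]], chainB[["pG1a"]], tolerance = 1e-8)
    expect_equal(closedB[["pG1"]], chainB[["pG1"]], tolerance = 1e-8)
    expect_lte(closedA[["pG1a"]], closedA[["pG1"]] + 1e-12)
    expect_lte(closedB[["pG1a"]], closedB[["pG1"]] + 1e-12)
  }
})

test_that("closed forms reduce to the no-migration limits", {
  tau <- 0.006; thA <- 0.012; thB <- 0.03
  a <- casebAab(tau, thA, thB, 0)
  expect_equal(a[["pG1a"]], gdiNoMig(tau, thA), tolerance = 1e-10)
  expect_equal(a[["pG1"]], p1NoMig(tau, thA), tolerance = 1e-10)
  b <- casebAbb(tau, thA, thB, 0)
  expect_equal(b[["pG1a"]], gdiNoMig(tau, thB), tolerance = 1e-10)
  expect_equal(b[["pG1"]], p1NoMig(tau, thB), tolerance = 1e-10)
})

test_that("removable singularities are guarded", {
  ## M * thetaB == thetaA exactly
  v <- casebAab(0.01, 0.02, 0.01, 2)
  ref <- gdidelim:::.pgCaseB(0.02, 0.01, 0, 2, 0.01, "aab")
  expect_equal(v[["pG1a"]], ref[["pG1a"]], tolerance = 1e-8)
  v2 <- casebAbb(0.01, 0.02, 0.01, 2)
  ref2 <- gdidelim:::.pgCaseB(0.02, 0.01, 0, 2, 0.01, "abb")
  expect_equal(v2[["pG1"]], ref2[["pG1"]], tolerance = 1e-8)
  ## ghost chain with cC == w
  gp <- ghostParams(0.01, 0.005, thetaA = 0.05, thetaC = 0.05,
                    thetaAB = 0.001, M = 0.5)  # w = 40 = cC
  p <- ghostTransitionProbs(gp)
  Q <- gdidelim:::.ghostQ(4 * 0.5 / 0.05, 2 / 0.05, 2 / 0.05)
  expect_equal(unname(p), expmOracle(Q, 0.005)[1, ], tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("aab sampling admits negative gdiJ, abb does not", {
  ## large donor-side size ratio and strong migration: P(G1) < 1/3
  v <- casebAab(5 * 0.01, 0.1, 0.01, 3)
  expect_lt(v[["pG1"]], 1 / 3)
  expect_lt(gdiJFromP1(v[["pG1"]]), 0)
  ## abb: P(G1) > 1/3 across a parameter grid
  for (M in c(0, 0.5, 1, 3)) for (ratio in c(0.1, 1, 10)) {
    thB <- 0.01; thA <- ratio * thB
    v <- casebAbb(5 * thB, thA, thB, M)
    expect_gte(gdiJFromP1(v[["pG1"]]), 0)
  }
})

test_that("ghost-lineage transition probabilities follow the 4-state chain", {
  gp <- ghostWorkedParams()
  p <- ghostTransitionProbs(gp)
  expect_equal(sum(p), 1, tolerance = 1e-12)
  expect_true(all(p >= 0 & p <= 1))
  ## against the dense exponential of the generator
  Q <- gdidelim:::.ghostQ(4 * gp$M / gp$thetaA, 2 / gp$thetaA, 2 / gp$thetaC)
  expect_equal(unname(p), expmOracle(Q, gp$tauAB)[1, ], tolerance = 1e-10,
               ignore_attr = TRUE)
  ## eigenvalues of the generator are {0, -cC, -cA-2w, -w}
  ev <- sort(eigen(Q, only.values = TRUE)$values)
  expect_equal(ev, sort(c(0, -2 / gp$thetaC,
                          -2 / gp$thetaA - 8 * gp$M / gp$thetaA,
                          -4 * gp$M / gp$thetaA)), tolerance = 1e-9)
  ## no migration: pure within-A coalescence
  g0 <- ghostParams(0.01, 0.005, 0.05, thetaC = 0.05, thetaAB = 0.001, M = 0)
  p0 <- ghostTransitionProbs(g0)
  expect_equal(p0[["p11"]], exp(-2 * 0.005 / 0.05), tolerance = 1e-12)
  expect_identical(p0[["p12"]], 0)
  expect_identical(p0[["p13"]], 0)
  expect_equal(p0[["p14"]], 1 - exp(-2 * 0.005 / 0.05), tolerance = 1e-12)
})

test_that("ghost-model P(G1) reproduces the worked example", {
  pg1 <- ghostPG1(ghostWorkedParams())
  expect_equal(round(pg1, 4), 0.2995)
  expect_lt(pg1, 1 / 3)           # the anomaly region: gdiJ < 0
  ## no-migration limit collapses to the isolation formula
  g0 <- ghostParams(0.01, 0.005, 0.05, thetaC = 0.05, thetaAB = 0.001, M = 0)
  expect_equal(ghostPG1(g0), p1NoMig(0.005, 0.05), tolerance = 1e-12)
})

test_that("random ghost parameters stay consistent with the 4-state chain", {
  set.seed(11)
  for (i in 1:20) {
    gp <- ghostParams(tauABC = runif(1, 0.008, 0.03),
                      tauAB = runif(1, 0.001, 0.007),
                      thetaA = runif(1, 0.01, 0.08),
                      thetaC = runif(1, 0.01, 0.08),
                      thetaAB = runif(1, 0.001, 0.02),
                      M = runif(1, 0.05, 2))
    p <- ghostTransitionProbs(gp)
    Q <- gdidelim:::.ghostQ(4 * gp$M / gp$thetaA, 2 / gp$thetaA,
                            2 / gp$thetaC)
    expect_equal(unname(p), expmOracle(Q, gp$tauAB)[1, ], tolerance = 1e-8,
                 ignore_attr = TRUE)
    expect_gte(ghostPG1(gp), 0)
    expect_lte(ghostPG1(gp), 1)
  }
})

test_that("a symmetric model is invariant to the sampling configuration", {
  m <- twoPopModel(0.006, 0.02, 0.02, MAB = 0.8, MBA = 0.8)
  expect_equal(pG1aMarkov(m, "aab"), pG1aMarkov(m, "abb"), tolerance = 1e-10)
  expect_equal(pG1Markov(m, "aab"), pG1Markov(m, "abb"), tolerance = 1e-10)
})
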