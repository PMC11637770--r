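test_that("the gdiJ rescaling maps [1/3, 1] onto [0, 1]", {
  expect_equal(gdiJFromP1(1 / 3), 0)
  expect_equal(gdiJFromP1(1), 1)
  ## the ghost-model anomaly value: P(G1) = 0.2995 gives gdiJ = -0.0508
  expect_lt(abs(gdiJFromP1(0.2995) - (-0.0508)), 5.1e-5)
  expect_identical(gdiJFromP1(0.2995, clamp = TRUE), 0)
  expect_equal(gdiJFromP1(c(0.5, 0.9)), c(0.25, 0.85), tolerance = 1e-12)
})

test_that("gdiPair dispatches on the migration pattern", {
  ## (a) no gene flow at all
  m0 <- twoPopModel(0.005, 0.01, 0.02)
  r0 <- gdiPair(m0, "A", "B", config = "aab")
  expect_identical(r0@method, "nomig-closed")
  expect_equal(r0@gdiK, gdiNoMig(0.005, 0.01), tolerance = 1e-12)
  ## outgoing flow into a third population is ignored for the pair
  m0b <- parseGuideTree("((A,B),C);", tau = c(AB = 0.005, ABC = 0.02),
                        theta = 0.01,
                        migration = migrationEvents("A", "C", 2))
  expect_identical(gdiPair(m0b, "A", "B")@method, "nomig-closed")
  ## (b) unidirectional between the pair
  m1 <- twoPopModel(0.005, 0.05, 0.01, MBA = 1)
  r1 <- gdiPair(m1, "A", "B", config = "aab")
  expect_identical(r1@method, "caseb-closed")
  expect_equal(r1@pG1a, casebAab(0.005, 0.05, 0.01, 1)[["pG1a"]],
               tolerance = 1e-12)
  ## (b) bidirectional: the general chain
  m2 <- twoPopModel(0.005, 0.05, 0.01, MAB = 0.5, MBA = 1)
  r2 <- gdiPair(m2, "A", "B", config = "abb")
  expect_identical(r2@method, "ctmc")
  expect_equal(r2@pG1, pG1Markov(m2, "abb"), tolerance = 1e-12)
  ## (c) third-party inflow forces simulation
  m3 <- ghostModel()
  r3 <- gdiPair(m3, "A", "B", config = "aab", reps = 5e3, seed = 1)
  expect_identical(r3@method, "simulation")
  expect_identical(r3@replicates, 5000)
  expect_false(is.na(r3@se[["pG1"]]))
  expect_error(gdiPair(m3, "A", "B", reps = 0), "budget")
  expect_error(gdiPair(m3, "A", "Z"), "tips")
})

test_that("unidirectional orientation is consistent for every layout", {
  ## flow A -> B forward: B is the receiving side; closed forms must be
  ## applied with swapped roles, which the chain verifies exactly
  m <- twoPopModel(0.006, 0.03, 0.012, MAB = 0.7)
  for (cfg in c("aab", "abb")) {
    r <- gdiPair(m, "A", "B", config = cfg)
    expect_identical(r@method, "caseb-closed")
    expect_equal(r@pG1, pG1Markov(m, cfg), tolerance = 1e-8)
    expect_equal(r@pG1a, pG1aMarkov(m, cfg), tolerance = 1e-8)
  }
})

test_that("the two definitions coincide exactly without gene flow", {
  set.seed(12)
  for (i in 1:8) {
    m <- twoPopModel(runif(1, 0, 0.01), runif(1, 0.005, 0.05),
                     runif(1, 0.005, 0.05))
    r <- gdiPair(m, "A", "B", config = sample(c("aab", "abb"), 1))
    expect_equal(r@gdiJ, r@gdiK, tolerance = 1e-12)
  }
  ## also for a non-sister pair on a larger tree without migration
  m <- ibdModel(M = 0)
  r <- gdiPair(m, "A", "C", config = "aab")
  expect_identical(r@method, "nomig-closed")
  expect_equal(r@gdiJ, r@gdiK, tolerance = 1e-12)
  ## the duplicated pair traverses A and XA before reaching the MRCA XABC
  S <- 2 * (0.01 / 0.01) + 2 * ((0.02 - 0.01) / 0.01) +
       2 * ((0.03 - 0.02) / 0.01)
  expect_equal(r@gdiK, 1 - exp(-S), tolerance = 1e-12)
})

test_that("symmetric models give gdiA = gdiB", {
  m <- twoPopModel(0.004, 0.015, 0.015)
  expect_equal(gdiPair(m, "A", "B", config = "aab")@gdiK,
               gdiPair(m, "A", "B", config = "abb")@gdiK,
               tolerance = 1e-12)
})

test_that("strong inflow from the sister makes gdiJ negative, never gdiK", {
  m <- twoPopModel(0.05, 0.1, 0.01, MBA = 3)
  r <- gdiPair(m, "A", "B", config = "aab")
  expect_lt(r@gdiJ, 0)
  expect_gte(r@gdiK, 0)
  expect_lte(r@gdiK, 1)
  ## clamping affects only the requested value, not the stored raw index
  rc <- gdiPair(m, "A", "B", config = "aab", clamp = TRUE)
  expect_lt(rc@gdiJ, 0)
  expect_identical(gdiValue(rc, "gdiJ"), 0)
  expect_identical(gdiValue(r, "gdiJ"), r@gdiJ)
})

test_that("HPD intervals are the shortest covering windows", {
  expect_equal(hpdInterval(1:100, 0.95), c(1, 95))  # ties: leftmost window
  expect_error(hpdInterval(1:10, 0.95), "too few")
  set.seed(13)
  x <- rexp(400)  # right-skewed: HPD strictly shorter than equal-tail
  h <- hpdInterval(x)
  et <- unname(quantile(x, c(0.025, 0.975), type = 1))
  expect_lt(diff(h), diff(et))
  for (i in 1:5) {
    y <- rnorm(500, sd = runif(1, 0.5, 2)) + rexp(500, runif(1, 0.5, 2))
    expect_equal(hpdInterval(y), hpdBruteForce(y), tolerance = 1e-12)
  }
})

test_that("posterior propagation reduces to the plug-in at a point mass", {
  m <- twoPopModel(0.005, 0.05, 0.01, MBA = 1)
  pv <- paramVector(m)
  draws <- as.data.frame(t(replicate(30, pv)))
  r <- posteriorGdi(draws, m, "A", "B", config = "aab")
  plug <- gdiPair(m, "A", "B", config = "aab")
  expect_equal(r@gdiK, plug@gdiK, tolerance = 1e-12)
  expect_equal(unname(diff(r@posterior$gdiK$etCI)), 0, tolerance = 1e-12)
  expect_equal(unname(diff(r@posterior$gdiK$hpdCI)), 0, tolerance = 1e-12)
})

test_that("posterior mean matches a brute-force two-point average", {
  m <- twoPopModel(0.005, 0.05, 0.01, MBA = 1)
  pv1 <- paramVector(m)
  pv2 <- pv1; pv2[["tau_AB"]] <- 0.01
  draws <- as.data.frame(rbind(t(replicate(10, pv1)),
                               t(replicate(30, pv2))))
  r <- posteriorGdi(draws, m, "A", "B", config = "aab")
  g1 <- gdiPair(m, "A", "B", config = "aab")@gdiK
  g2 <- gdiPair(updateModelParams(m, pv2), "A", "B", config = "aab")@gdiK
  expect_equal(r@gdiK, (10 * g1 + 30 * g2) / 40, tolerance = 1e-12)
})

test_that("posterior propagation around fixed parameters recovers them", {
  set.seed(14)
  m <- twoPopModel(0.005, 0.05, 0.01, MBA = 1)
  pv <- paramVector(m)
  n <- 400
  draws <- as.data.frame(t(replicate(n, pv * exp(rnorm(length(pv), 0, 0.05)))))
  r <- posteriorGdi(draws, m, "A", "B", config = "aab")
  plug <- gdiPair(m, "A", "B", config = "aab")
  sdJ <- sd(r@posterior$draws$gdiJ)
  expect_lt(abs(r@gdiJ - plug@gdiJ), 4 * sdJ / sqrt(n) + 0.01)
  expect_lt(r@posterior$gdiJ$hpdCI[1], plug@gdiJ)
  expect_gt(r@posterior$gdiJ$hpdCI[2], plug@gdiJ)
  expect_lte(diff(r@posterior$gdiJ$hpdCI), diff(r@posterior$gdiJ$etCI))
})

test_that("simulation-path posteriors are thinned and validated", {
  m <- ghostModel()
  pv <- paramVector(m)
  draws <- as.data.frame(t(replicate(50, pv)))
  r <- posteriorGdi(draws, m, "A", "B", config = "aab", thinTo = 10,
                    reps = 2000, seed = 15)
  expect_identical(r@posterior$n, 10L)
  expect_identical(r@method, "simulation")
  expect_error(posteriorGdi(draws[, -1], m, "A", "B"), "lacks parameter")
  expect_error(posteriorGdi(draws[1, , drop = FALSE], m, "A", "B"),
               "at least 2")
})
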