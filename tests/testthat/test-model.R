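test_that("guide trees parse with auto-generated internal labels", {
  m <- parseGuideTree("((X,A),B);", tau = c(XA = 0.01, XAB = 0.02),
                      theta = 0.01)
  expect_s4_class(m, "MSCMModel")
  expect_identical(tipLabels(m), c("X", "A", "B"))
  expect_setequal(guideTree(m)@phy$node.label, c("XA", "XAB"))
  expect_equal(tauOf(m, "XA")[[1]], 0.01)
  expect_equal(tauOf(m, "XAB")[[1]], 0.02)

  ## explicit internal labels are kept as given
  m2 <- parseGuideTree("((X,A)u,B)v;", tau = c(u = 0.01, v = 0.02),
                       theta = 0.01)
  expect_setequal(guideTree(m2)@phy$node.label, c("u", "v"))
})

test_that("the zero-divergence (panmixia) boundary is constructible", {
  m <- parseGuideTree("(A,B);", tau = c(AB = 0), theta = 0.01)
  expect_equal(unname(tauOf(m)), c(0, 0, 0))
})

test_that("malformed or invalid trees and parameters are rejected", {
  expect_error(parseGuideTree("((A,B),(C,D);", theta = 0.01))
  expect_error(parseGuideTree("(A,B,C);", theta = 0.01), "binary")
  expect_error(parseGuideTree("((A,B),A);", tau = c(AB = 0.01, ABA = 0.02),
                              theta = 0.01), "duplicate")
  ## tau ordering: parent younger than child
  expect_error(parseGuideTree("((A,B),C);",
                              tau = c(AB = 0.02, ABC = 0.01), theta = 0.01),
               "tau ordering")
  expect_error(parseGuideTree("(A,B);", tau = c(AB = 0.01), theta = -1),
               "theta")
})

test_that("migration events are validated against the tree", {
  mk <- function(mig) parseGuideTree("((A,B),C);",
                                     tau = c(AB = 0.01, ABC = 0.02),
                                     theta = 0.01, migration = mig)
  expect_error(mk(migrationEvents("A", "Z", 1)), "label")
  expect_error(mk(migrationEvents("A", "A", 1)), "differ")
  expect_error(mk(migrationEvents("A", "B", -1)), ">= 0")
  expect_error(mk(migrationEvents(c("A", "A"), c("B", "B"), 1)), "duplicate")
  ## A is extinct (merged into AB) before the AB branch begins
  expect_error(mk(migrationEvents("A", "AB", 1)), "overlap")
  ## contemporaneous internal-tip pair is fine
  expect_s4_class(mk(migrationEvents("AB", "C", 1)), "MSCMModel")
})

test_that("sister merges collapse cherries and re-attach migration", {
  m <- parseGuideTree("((A,(B,C)),D);",
                      tau = c(BC = 0.005, ABC = 0.01, ABCD = 0.02),
                      theta = 0.01,
                      migration = migrationEvents("A", "B", 1.5))
  m1 <- mergePopulations(m, "B", "C")
  expect_identical(attr(m1, "mergedLabel"), "BC")
  expect_setequal(tipLabels(m1), c("A", "BC", "D"))
  ## the A -> B event now points at the merged population
  expect_identical(migrations(m1)$recipient, "BC")
  expect_identical(migrations(m1)$donor, "A")
  ## merging A with BC removes the now intra-population event
  m2 <- mergePopulations(m1, "A", "BC")
  expect_identical(nrow(migrations(m2)), 0L)
  expect_setequal(tipLabels(m2), c("ABC", "D"))
})

test_that("degenerate merges are rejected", {
  m <- twoPopModel(0.01, 0.01, 0.01)
  expect_error(mergePopulations(m, "A", "A"), "itself")
  expect_error(mergePopulations(m, "A", "Z"), "tips")
})

test_that("non-sister merges follow the displayed-tree direction rule", {
  m <- ibdModel(M = 2)
  ## equal rates between A and B: lexicographic survivor, so A absorbs B
  m1 <- mergePopulations(m, "A", "B")
  expect_identical(attr(m1, "mergedLabel"), "AB")
  expect_setequal(tipLabels(m1), c("X", "AB", "C", "D"))
  ## B's events with C re-attached; A-B events gone
  mg <- migrations(m1)
  expect_false(any(mg$donor == mg$recipient))
  expect_setequal(paste(mg$donor, mg$recipient),
                  c("AB C", "C AB", "C D", "D C"))
  ## unequal rates: donor of the larger rate survives
  m2 <- parseGuideTree("((A,B),(C,D));",
                       tau = c(AB = 0.01, CD = 0.01, ABCD = 0.02),
                       theta = 0.01,
                       migration = migrationEvents(c("B", "D"), c("D", "B"),
                                                   c(3, 1)))
  m3 <- mergePopulations(m2, "B", "D")
  expect_identical(attr(m3, "mergedLabel"), "BD")  # B donated more
  expect_setequal(tipLabels(m3), c("A", "BD", "C"))
})

test_that("merges shrink the tip count by one and never add migration", {
  set.seed(42)
  m <- ibdModel(M = 2)
  while (length(tipLabels(m)) > 2) {
    tips <- tipLabels(m)
    pair <- sample(tips, 2)
    nm0 <- nrow(migrations(m))
    m <- mergePopulations(m, pair[1], pair[2])
    expect_length(tipLabels(m), length(tips) - 1L)
    expect_lte(nrow(migrations(m)), nm0)
    expect_false(any(migrations(m)$donor == migrations(m)$recipient))
  }
})

test_that("models round-trip through Newick + parameter vector", {
  m <- ibdModel(M = 2)
  pv <- paramVector(m)
  tau <- pv[startsWith(names(pv), "tau_")]
  names(tau) <- sub("^tau_", "", names(tau))
  theta <- pv[startsWith(names(pv), "theta_")]
  names(theta) <- sub("^theta_", "", names(theta))
  m2 <- parseGuideTree(newickString(m), tau = tau, theta = theta,
                       migration = migrations(m))
  expect_identical(newickString(m2), newickString(m))
  expect_identical(paramVector(m2), paramVector(m))
})

test_that("updateModelParams matches paramVector naming", {
  m <- twoPopModel(0.005, 0.01, 0.02, MBA = 1)
  m2 <- updateModelParams(m, c(tau_AB = 0.007, theta_A = 0.03,
                               M_B_A = 2.5, theta_Q = 9))  # unknown ignored
  expect_equal(tauOf(m2, "AB")[[1]], 0.007)
  expect_equal(thetaOf(m2, "A")[[1]], 0.03)
  expect_equal(migrations(m2)$rate, 2.5)
})

test_that("Imap files round-trip and are validated against the tree", {
  m <- parseGuideTree("((A,B),C);", tau = c(AB = 0.01, ABC = 0.02),
                      theta = 0.01)
  map <- c(a1 = "A", a2 = "A", b1 = "B", c1 = "C")
  path <- withr::local_tempfile(fileext = ".txt")
  writeImap(map, path)
  expect_identical(readImap(path, m), map)
  writeImap(c(map, z1 = "Z"), path)
  expect_error(readImap(path, m), "Z")
})
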