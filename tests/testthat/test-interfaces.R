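writeTestControl <- function(path, extra = character(),
                             drop = character()) {
  lines <- c(
    "# merge analysis of the five-population isolation-by-distance model",
    "output_directory = out",
    "seqfile = sim.phy",
    "Imapfile = sim.Imap.txt",
    "guide_tree = ((((X,A),B),C),D);",
    "mode = merge",
    "GDI_threshold = 0.2",
    "threads = 2",
    "burnin = 10000",
    "sampfreq = 10",
    "nsample = 50000",
    "migration = A>B:2, B>A:2, B>C:2, C>B:2, C>D:2, D>C:2")
  for (d in drop) lines <- lines[!startsWith(lines, paste(d, "="))]
  lines <- c(lines, extra)
  writeLines(lines, path)
  path
}

test_that("a standard merge control file parses", {
  path <- withr::local_tempfile(fileext = ".txt")
  cfg <- parseControl(writeTestControl(path))
  expect_s3_class(cfg, "ControlConfig")
  expect_identical(cfg$mode, "merge")
  expect_equal(cfg$GDI_threshold, 0.2)
  expect_identical(cfg$Imapfile, "sim.Imap.txt")
  expect_identical(nrow(cfg$migration), 6L)
  expect_true(all(cfg$migration$rate == 2))
  expect_identical(cfg$definition, "gdiK")  # default
})

test_that("invalid control files are rejected with named errors", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeTestControl(path, extra = "mode2 = merge")
  expect_error(parseControl(path), "mode2")
  writeTestControl(path, drop = "Imapfile")
  expect_error(parseControl(path), "Imapfile")
  writeTestControl(path, drop = "mode", extra = "mode = both")
  expect_error(parseControl(path), "merge")
  writeTestControl(path, drop = "guide_tree",
                   extra = "guide_tree = ((A,B),(C,D);")
  expect_error(parseControl(path), "Newick")
  writeTestControl(path, drop = "GDI_threshold",
                   extra = "GDI_threshold = 1.4")
  expect_error(parseControl(path), "GDI_threshold")
})

test_that("control round-trip is idempotent", {
  p1 <- withr::local_tempfile(fileext = ".txt")
  p2 <- withr::local_tempfile(fileext = ".txt")
  cfg1 <- parseControl(writeTestControl(p1, extra = c("seed = 7",
                                                      "nonsister = 1")))
  writeControl(cfg1, p2)
  cfg2 <- parseControl(p2)
  expect_equal(cfg2[order(names(cfg2))], cfg1[order(names(cfg1))])
})

test_that("fixed backends serve and police parameter tables", {
  m <- twoPopModel(0.005, 0.05, 0.01, MBA = 1)
  be <- fixedBackend(c(tau_AB = 0.008, theta_A = 0.02, M_B_A = 1.5))
  m2 <- be(m)
  expect_equal(tauOf(m2, "AB")[[1]], 0.008)
  expect_equal(thetaOf(m2, "A")[[1]], 0.02)
  expect_equal(migrations(m2)$rate, 1.5)
  ## inherit rule: untouched parameters keep their current values
  expect_equal(thetaOf(m2, "B")[[1]], 0.01)
  ## strict rule requires full coverage of the proposed model
  beS <- fixedBackend(c(tau_AB = 0.008), rule = "strict")
  expect_error(beS(m), "theta_A")
  ## file-based table
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("tau_AB 0.003", "theta_B 0.04"), path)
  m3 <- fixedBackend(path)(m)
  expect_equal(tauOf(m3, "AB")[[1]], 0.003)
  expect_equal(thetaOf(m3, "B")[[1]], 0.04)
})

test_that("generated bpp files carry the delimitation and migration", {
  m <- ibdModel(M = 2)
  imap <- setNames(rep(tipLabels(m), each = 2),
                   paste0(rep(tolower(tipLabels(m)), each = 2), 1:2))
  dir <- withr::local_tempdir()
  cfg <- structure(list(seqfile = "sim.phy", burnin = 100L, sampfreq = 2L,
                        nsample = 1000L), class = "ControlConfig")
  paths <- writeBppFiles(m, imap, cfg, dir)
  ctl <- readLines(paths$control)
  expect_true(any(grepl(newickString(m), ctl, fixed = TRUE)))
  expect_true(any(grepl("migration = 6", ctl, fixed = TRUE)))
  expect_true(any(grepl("^  A B$", ctl)))
  expect_identical(readImap(paths$imap, m), imap)
})

test_that("the external adapter replays a recorded run directory", {
  m <- twoPopModel(0.005, 0.05, 0.01, MBA = 1)
  dir <- withr::local_tempdir()
  set.seed(30)
  draws <- data.frame(`tau_AB` = rnorm(200, 0.006, 1e-4),
                      `theta_A` = rnorm(200, 0.04, 1e-3),
                      `theta_B` = rnorm(200, 0.012, 1e-3),
                      `theta_AB` = rnorm(200, 0.02, 1e-3),
                      `M_B->A` = rnorm(200, 1.2, 0.05),
                      check.names = FALSE)
  write.table(draws, file.path(dir, "mcmc.txt"), row.names = FALSE,
              quote = FALSE)
  be <- bppAdapter(dir)
  m2 <- be(m)
  expect_equal(tauOf(m2, "AB")[[1]], mean(draws$tau_AB), tolerance = 1e-12)
  expect_equal(migrations(m2)$rate, mean(draws$`M_B->A`), tolerance = 1e-12)
  ## the parsed draw table is exposed for posterior propagation
  samples <- attr(be, "samples")()
  expect_identical(names(samples)[5], "M_B_A")
  r <- posteriorGdi(samples, m2, "A", "B", config = "aab")
  expect_identical(r@posterior$n, 200L)
  ## a missing output directory is a named failure
  expect_error(bppAdapter(file.path(dir, "nope"))(m), "not found")
})

test_that("a control-file run is reproducible end to end", {
  dir <- withr::local_tempdir()
  imap <- c(a1 = "A", a2 = "A", b1 = "B", b2 = "B", c1 = "C")
  writeImap(imap, file.path(dir, "test.Imap.txt"))
  writeLines(c("tau_AB 0.0006", "tau_ABC 0.02",
               "theta_A 0.01", "theta_B 0.01", "theta_C 0.01",
               "theta_AB 0.01", "theta_ABC 0.01",
               "M_C_B 1.5"), file.path(dir, "params.txt"))
  ctl <- file.path(dir, "run.ctl")
  writeLines(c(sprintf("output_directory = %s", file.path(dir, "out")),
               sprintf("Imapfile = %s", file.path(dir, "test.Imap.txt")),
               "guide_tree = ((A,B),C);",
               "mode = merge",
               "GDI_threshold = 0.2",
               "migration = C>B:1.5",
               "definition = gdiK",
               "replicates = 5000",
               "seed = 41",
               sprintf("param_table = %s", file.path(dir, "params.txt"))),
             ctl)
  st1 <- runDelimitationFromControl(ctl)
  st2 <- runDelimitationFromControl(ctl)
  expect_identical(iterationLog(st1), iterationLog(st2))
  ## the shallow A-B cherry merges; C stays distinct
  expect_identical(sort(names(speciesAssignment(st1))), c("AB", "C"))
  expect_true(file.exists(file.path(dir, "out", "delimitation_log.tsv")))
  fin <- readLines(file.path(dir, "out", "final_delimitation.txt"))
  expect_true(any(grepl("AB", fin)))
})
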