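test_that("fold changes are exact on constructed traces", {
  const <- makeTrajectoryFixture("constant", level = 100)
  expect_equal(foldChangeAt(const, "x", 12 * 3600, baseline = 100), 1.0)
  expect_equal(foldChangeAt(const, "x", 47 * 3600, baseline = const), 1.0)
  expect_error(foldChangeAt(const, "x", 3600, baseline = 0), "baseline")

  # pure-death ensemble at one half-life ~ 0.5
  es <- runEnsemble(pureDeathModel(kDeg = 1e-3, x0 = 200), nReps = 400,
                    duration = 693.147, nIntervals = 20, baseSeed = 9)
  expect_equal(foldChangeAt(es, "A", 693.147, baseline = 200), 0.5,
               tolerance = 0.03)
})

test_that("total: observables sum the free pool and its mRNA complexes only", {
  m <- buildTgfbSmad3Model("with_miR140")
  tr <- simulateSSA(m, 3600, nIntervals = 10, seed = 1)
  tot <- observableTrace(tr, "total:miR140")
  # free + SMAD3-mRNA complex, but not the gene-state bookkeeping species
  expect_equal(tot, speciesCounts(tr)[, "miR140"] +
                 speciesCounts(tr)[, "miR140_SMAD3mRNA"])
  expect_error(observableTrace(tr, "total:NOPE"), "no species match")
  expect_error(observableTrace(tr, "NOPE"), "unknown species")
})

test_that("peak detection recovers constructed peaks and flags monotone traces", {
  pulse <- makeTrajectoryFixture("pulse", duration = 48 * 3600,
                                 peakTime = 10 * 3600)
  pk <- peakTime(pulse, "x", smoothingWindow = 11)
  expect_true(pk$interior)
  expect_lt(abs(pk$time - 10 * 3600), 48 * 3600 / 1000 * 11)

  noisy <- makeTrajectoryFixture("pulse", duration = 48 * 3600,
                                 peakTime = 10 * 3600, noiseSd = 5, seed = 2)
  pkn <- peakTime(noisy, "x", smoothingWindow = 11)
  expect_lt(abs(pkn$time - 10 * 3600), 2 * 3600)

  mono <- makeTrajectoryFixture("monotone_rise")
  expect_false(peakTime(mono, "x")$interior)
  death <- simulateODE(pureDeathModel(), 1e4, 100)
  pkd <- peakTime(death, "A")
  expect_false(pkd$interior)
  expect_equal(pkd$time, 0)
  expect_error(peakTime(pulse, "x", smoothingWindow = 2000), "window")
})

test_that("return-to-basal finds constructed recovery times and flags non-returns", {
  const <- makeTrajectoryFixture("constant", level = 100)
  rb <- returnToBasalTime(const, "x", basal = 100)
  expect_equal(rb$time, 0)
  expect_true(rb$returned)

  dip <- makeTrajectoryFixture("dip_recover", duration = 96 * 3600,
                               recoveryTime = 48 * 3600, level = 100)
  rb2 <- returnToBasalTime(dip, "x", basal = 100, toleranceFraction = 0.05)
  expect_true(rb2$returned)
  expect_lt(abs(rb2$time - 48 * 3600), 2 * 3600)

  mono <- makeTrajectoryFixture("monotone_rise", level = 100)
  rb3 <- returnToBasalTime(mono, "x", basal = 50)  # never returns to 50
  expect_false(rb3$returned)
  expect_identical(rb3$time, Inf)
  expect_error(returnToBasalTime(mono, "x", basal = 0), "basal")
})

test_that("the scan runs its full grid with deterministic per-cell seeding", {
  grid <- scanGrid(il1Values = c(0, 800), tgfbValues = c(1, 1000), nReps = 2)
  df <- runDoseResponseScan(grid, antiMir140Doses = 0,
                            endTime = 36 * 3600, baseSeed = 5,
                            nIntervals = 30)
  expect_equal(nrow(df), 2 * 2 * 1 * 2)  # cells x readouts
  expect_setequal(unique(df$species), c("AggFrag", "ColFrag"))
  # no catabolic stimulus: no aggrecan fragments
  expect_equal(df$mean[df$il1 == 0 & df$species == "AggFrag"], c(0, 0))
  df2 <- runDoseResponseScan(grid, antiMir140Doses = 0,
                             endTime = 36 * 3600, baseSeed = 5,
                             nIntervals = 30)
  expect_identical(df, df2)
  expect_error(runDoseResponseScan(list()), "scanGrid")
  expect_error(scanGrid(nReps = 1), "nReps")
})

test_that("figure runners execute their documented panel and write outputs", {
  dir <- tempfile("figs")
  out <- reproduceFigure("5C", seed = 3, dir = dir, nIntervals = 200)
  expect_true(all(file.exists(out$files)))
  expect_setequal(unique(out$data$species),
                  c("IL1", "NFkB", "miR140", "MMP13"))
  expect_equal(out$provenance$model, "il1_mmp13")
  expect_equal(out$provenance$n_reps, 1)
  # deterministic re-run reproduces the same data
  out2 <- reproduceFigure("5C", seed = 3, dir = tempfile("figs"),
                          nIntervals = 200)
  expect_identical(out$data, out2$data)
  expect_error(reproduceFigure("99Z"), "unknown figure")

  outD <- reproduceFigure("7D", seed = 3, dir = dir, nReps = 3,
                          nIntervals = 60)
  expect_equal(nrow(outD$data), 3)   # one summary row per miR-140 preset
  expect_true(all(c("ci_lo", "ci_hi") %in% names(outD$data)))
})
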