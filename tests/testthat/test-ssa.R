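test_that("propensities follow mass-action combinatorics", {
  st <- c(miR140 = 0, IL1 = 500, mRNA = 100, X = 3)
  expect_equal(propensity(reactionSpec("miR140", character(0), "k"),
                          st, c(k = 0.0018)), 0)
  expect_equal(propensity(reactionSpec(c("IL1", "mRNA"), "IL1", "k"),
                          st, c(k = 2e-5)), 1.0)
  expect_equal(propensity(reactionSpec(c("X", "X"), character(0), "k"),
                          st, c(k = 2)), 6)  # k * x * (x-1) / 2
  expect_equal(propensity(reactionSpec(character(0), "X", "k"),
                          st, c(k = 0.42)), 0.42)
  expect_error(propensity(reactionSpec("X", character(0), "k"),
                          c(X = -1), c(k = 1)), ">= 0")
})

test_that("a pure-death ensemble mean follows the exponential decay law", {
  m <- pureDeathModel(kDeg = 1e-3, x0 = 100)
  # t = ln(2)/k = 693 s: mean should be ~50
  es <- runEnsemble(m, nReps = 1000, duration = 693.147, nIntervals = 20,
                    baseSeed = 7)
  final <- ensembleMean(es)[21, "A"]
  expect_lt(abs(final - 50), 3 * sqrt(25 / 1000) * 3)  # binomial var = 25
})

test_that("identical seeds give bit-identical trajectories", {
  m <- buildTgfbSmad3Model("with_miR140")
  t1 <- simulateSSA(m, 4 * 3600, nIntervals = 400, seed = 99L)
  t2 <- simulateSSA(m, 4 * 3600, nIntervals = 400, seed = 99L)
  expect_identical(speciesCounts(t1), speciesCounts(t2))
  t3 <- simulateSSA(m, 4 * 3600, nIntervals = 400, seed = 100L)
  expect_false(identical(speciesCounts(t1), speciesCounts(t3)))
})

test_that("an absorbing state freezes the remaining grid without error", {
  m <- pureDeathModel(kDeg = 0.1, x0 = 5)
  tr <- simulateSSA(m, 1e5, nIntervals = 100, seed = 1)
  expect_equal(unname(speciesCounts(tr)[101, "A"]), 0)
  # degenerate model whose only reaction can never fire: constant trace
  m0 <- buildModel("frozen", rbind(speciesSpec("A", 7), speciesSpec("B", 0)),
                   list(reactionSpec("B", "A", "k")), c(k = 1))
  tr0 <- simulateSSA(m0, 1000, nIntervals = 10, seed = 1)
  expect_true(all(speciesCounts(tr0)[, "A"] == 7))
})

test_that("conversion-only subnetworks conserve their total copy number", {
  m <- conversionModel(300, 200)
  tr <- simulateSSA(m, 5e4, nIntervals = 500, seed = 11)
  expect_true(all(rowSums(speciesCounts(tr)) == 500))
  # same invariant for total TGF-beta in the pathway model
  mt <- buildTgfbSmad3Model("with_miR140")
  trt <- simulateSSA(mt, 24 * 3600, nIntervals = 200, seed = 2)
  tot <- rowSums(speciesCounts(trt)[, c("TGFb_A", "TGFb_I")])
  expect_true(all(tot == 500))
})

test_that("ensembles require >= 2 replicates and degenerate replicates give zero-width CIs", {
  m <- birthDeathModel()
  expect_error(runEnsemble(m, nReps = 1, duration = 100), "nReps")
  m0 <- buildModel("frozen", rbind(speciesSpec("A", 7), speciesSpec("B", 0)),
                   list(reactionSpec("B", "A", "k")), c(k = 1))
  es <- runEnsemble(m0, nReps = 5, duration = 1000, nIntervals = 10,
                    baseSeed = 1)
  ci <- ensembleCI(es)
  expect_true(all(ci$upper - ci$lower == 0))
  expect_identical(nReplicates(es), 5L)
})

test_that("the stationary mean of a birth-death ensemble lies inside its own CI", {
  m <- birthDeathModel(kSyn = 0.01, kDeg = 1e-4, x0 = 100)  # starts at ss
  es <- runEnsemble(m, nReps = 100, duration = 1e5, nIntervals = 50,
                    baseSeed = 13)
  ci <- ensembleCI(es)
  last <- 51
  expect_gte(100, ci$lower[last, "A"])
  expect_lte(100, ci$upper[last, "A"])
})

test_that("replicate trajectories are retrievable and match their seeds", {
  m <- birthDeathModel()
  es <- runEnsemble(m, nReps = 3, duration = 1e4, nIntervals = 20,
                    baseSeed = 17, keepTrajectories = TRUE)
  trajs <- attr(es, "trajectories")
  expect_length(trajs, 3)
  direct <- simulateSSA(m, 1e4, nIntervals = 20, seed = 18L)  # baseSeed + 1
  expect_identical(speciesCounts(trajs[[2]]), speciesCounts(direct))
  # ensemble mean equals the average of the replicates
  avg <- Reduce(`+`, lapply(trajs, speciesCounts)) / 3
  expect_equal(ensembleMean(es), avg)
})

test_that("tidy export carries the full trajectory and ensemble summaries", {
  m <- conversionModel(30, 20)
  tr <- simulateSSA(m, 1000, nIntervals = 10, seed = 3)
  df <- asTidyFrame(tr)
  expect_identical(names(df), c("time", "species", "value"))
  expect_equal(nrow(df), 11 * 2)
  expect_equal(df$value[df$species == "A" & df$time == 0], 30)
  es <- runEnsemble(m, nReps = 4, duration = 1000, nIntervals = 10,
                    baseSeed = 3)
  f <- tempfile(fileext = ".csv")
  dfe <- asTidyFrame(es, file = f)
  expect_true(file.exists(f))
  expect_identical(names(dfe), c("time", "species", "mean", "ci_lo", "ci_hi"))
})
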