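test_that("generated tables satisfy the interaction-table invariants", {
  g <- generateTargetTable(plantedEnrichmentDesign(
    nMirnas = 30, nGenes = 300, nDiseaseGenes = 20,
    targetsPerMirna = c(10, 30), nPlanted = 3, plantedRatio = 3, seed = 5))
  tab <- g$table
  expect_false(any(duplicated(tab[c("mirna", "gene")])))
  expect_true(all(nzchar(tab$mirna)) && all(nzchar(tab$gene)))
  expect_length(unique(g$truth$mirna), 30)
  expect_equal(sum(g$truth$planted), 3)
  # the truth record reproduces the realised counts in the table
  byM <- split(tab$gene, tab$mirna)
  expect_equal(unname(vapply(byM[g$truth$mirna], length, integer(1))),
               g$truth$n_targets)
  expect_equal(unname(vapply(byM[g$truth$mirna],
                             function(x) sum(x %in% g$diseaseGenes),
                             integer(1))),
               g$truth$k_disease)
})

test_that("generation is reproducible from the seed and responsive to it", {
  d <- plantedEnrichmentDesign(nMirnas = 20, nGenes = 200,
                               nDiseaseGenes = 15, targetsPerMirna = c(5, 15),
                               nPlanted = 2, plantedRatio = 2, seed = 11)
  g1 <- generateTargetTable(d)
  g2 <- generateTargetTable(d)
  expect_identical(g1$table, g2$table)
  expect_identical(g1$diseaseGenes, g2$diseaseGenes)
  d2 <- d; d2$seed <- 12L
  expect_false(identical(generateTargetTable(d2)$table, g1$table))
})

test_that("planting concentrates disease genes at the requested ratio", {
  d <- plantedEnrichmentDesign(seed = 21)   # 200/2000/100, ratio 3
  g <- generateTargetTable(d)
  tr <- g$truth
  fracP <- sum(tr$k_disease[tr$planted]) / sum(tr$n_targets[tr$planted])
  frac0 <- sum(tr$k_disease[!tr$planted]) / sum(tr$n_targets[!tr$planted])
  expect_equal(fracP / (100 / 2000), 3, tolerance = 0.25)
  expect_equal(frac0 / (100 / 2000), 1, tolerance = 0.15)
  # exact-k mode pins each planted count at its expectation
  ge <- generateTargetTable(d, exactK = TRUE)
  te <- ge$truth
  expect_equal(te$k_disease[te$planted],
               as.integer(round(3 * 100 / 2000 * te$n_targets[te$planted])))
  # a ratio-1 design is a null design
  expect_error(plantedEnrichmentDesign(plantedRatio = 0.5), ">= 1")
  expect_error(plantedEnrichmentDesign(plantedRatio = 50), "infeasible")
})

test_that("trajectory fixtures encode their ground truth", {
  pulse <- makeTrajectoryFixture("pulse", peakTime = 6 * 3600)
  expect_equal(attr(pulse, "truth")$peakTime, 6 * 3600)
  y <- observableTrace(pulse, "x")
  expect_equal(gridTimes(pulse)[which.max(y)], 6 * 3600,
               tolerance = 0.01)
  const <- makeTrajectoryFixture("constant", level = 50)
  expect_true(all(observableTrace(const, "x") == 50))
  # seeded noise is reproducible
  n1 <- makeTrajectoryFixture("pulse", noiseSd = 3, seed = 8)
  n2 <- makeTrajectoryFixture("pulse", noiseSd = 3, seed = 8)
  expect_identical(speciesCounts(n1), speciesCounts(n2))
  expect_error(makeTrajectoryFixture("sawtooth"), "arg")
})
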