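test_that("the hypergeometric tail matches exhaustive enumeration for all small universes", {
  for (N in c(4, 6, 8, 10, 12)) {
    for (K in 0:N) {
      for (n in 1:N) {
        for (k in 0:min(n, K)) {
          expect_equal(hypergeomTailP(k, K, n, N), enumTailP(k, K, n, N),
                       tolerance = 1e-12,
                       info = sprintf("k=%d K=%d n=%d N=%d", k, K, n, N))
        }
      }
    }
  }
  # spot values forced by the definition
  expect_equal(hypergeomTailP(0, 3, 2, 10), 1)
  expect_equal(hypergeomTailP(2, 10, 3, 10), 1)  # K = N: certain
  expect_equal(hypergeomTailP(2, 4, 3, 10), 1 / 3)
  expect_error(hypergeomTailP(4, 2, 3, 10), "inconsistent")
  # agreement with the library survival function on a larger instance
  expect_equal(hypergeomTailP(30, 100, 200, 2000),
               stats::phyper(29, 100, 1900, 200, lower.tail = FALSE))
})

test_that("miRNAs need more than one disease target to pass the filter", {
  tab <- targetTable(
    mirna = c("a", "a", "a", "b", "b", "c"),
    gene = c("g1", "g2", "g3", "g1", "g4", "g5"))
  disease <- c("g1", "g2")
  kept <- filterMirnas(tab, disease)
  expect_setequal(unique(kept$mirna), "a")        # 2 disease targets kept
  expect_false("b" %in% kept$mirna)               # exactly 1: removed
  expect_equal(nrow(filterMirnas(tab, character(0))), 0)  # empty disease set
})

test_that("p-value adjustment reproduces the direct step-up computation", {
  expect_equal(adjustPvalues(0.01), 0.01)
  expect_equal(adjustPvalues(c(0.01, 0.02, 0.03, 0.04)),
               c(0.04, 0.04, 0.04, 0.04))
  set.seed(42)
  for (i in 1:20) {
    p <- runif(sample(3:40, 1))^sample(1:3, 1)
    expect_equal(adjustPvalues(p), bhDirect(p))
    expect_true(all(adjustPvalues(p) >= p))
    expect_true(all(adjustPvalues(p, "bonferroni") == pmin(p * length(p), 1)))
  }
  expect_error(adjustPvalues(c(0.1, 1.2)), "0, 1")
})

test_that("ranking is by adjusted p with deterministic tie-breaking", {
  # one planted miRNA constructed so its tail-p is minimal by design
  tab <- targetTable(
    mirna = rep(c("hit", "bg1", "bg2"), each = 4),
    gene = c("d1", "d2", "d3", "g1",      # 3/4 disease targets
             "d1", "d2", "g2", "g3",      # 2/4
             "d2", "d3", "g4", "g5"))     # 2/4
  disease <- c("d1", "d2", "d3")
  r <- rankMirnas(tab, disease)
  expect_equal(r$mirna[1], "hit")
  expect_equal(r$rank, 1:3)
  expect_equal(r$universe_size[1], 8)     # distinct target genes
  expect_equal(r$expected, r$n_targets * r$disease_in_universe / 8)
  expect_equal(r$enrichment_ratio, r$n_disease_targets / r$expected)
  # identical miRNAs tie; order falls back to the identifier
  tab2 <- targetTable(mirna = rep(c("zzz", "aaa"), each = 3),
                      gene = rep(c("d1", "d2", "g1"), 2))
  r2 <- rankMirnas(tab2, c("d1", "d2"))
  expect_equal(r2$p_adjusted[1], r2$p_adjusted[2])
  expect_equal(r2$mirna, c("aaa", "zzz"))
  # empty after filtering
  expect_equal(nrow(rankMirnas(tab, "absent-gene")), 0)
})

test_that("raw p-values are conservative under the global null", {
  # uniform random table with no planted structure: the discrete test's
  # raw p-values are stochastically >= uniform
  g <- generateTargetTable(plantedEnrichmentDesign(
    nMirnas = 150, nGenes = 1500, nDiseaseGenes = 75,
    targetsPerMirna = c(40, 80), nPlanted = 0, plantedRatio = 1, seed = 99))
  r <- rankMirnas(g$table, g$diseaseGenes, filter = FALSE)
  expect_lte(mean(r$p_raw < 0.05), 0.05 + 2 * sqrt(0.05 * 0.95 / nrow(r)))
  expect_lte(mean(r$p_raw < 0.2), 0.2 + 2 * sqrt(0.2 * 0.8 / nrow(r)))
})

test_that("file readers round-trip the generated layouts", {
  g <- generateTargetTable(plantedEnrichmentDesign(
    nMirnas = 12, nGenes = 100, nDiseaseGenes = 10,
    targetsPerMirna = c(5, 10), nPlanted = 2, plantedRatio = 3, seed = 1))
  files <- writeTargetTableFiles(g, dir = tempfile("enr"))
  tab <- readTargetTable(files["interactions"])
  expect_s3_class(tab, "targetTable")
  expect_setequal(tab$mirna, g$table$mirna)
  expect_equal(nrow(tab), nrow(g$table))
  expect_true(all(tab$support == "Functional MTI"))
  dz <- readDiseaseGenes(files["diseaseGenes"])
  expect_setequal(dz, g$diseaseGenes)
  # ranked table writes as CSV with its columns intact
  out <- tempfile(fileext = ".csv")
  writeEnrichmentTable(rankMirnas(tab, dz), out)
  back <- read.csv(out)
  expect_true(all(c("mirna", "enrichment_ratio", "p_adjusted", "rank")
                  %in% names(back)))
})
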