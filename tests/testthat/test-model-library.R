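test_that("every registered model builds, validates, and runs under both engines", {
  for (name in listModels()) {
    m <- getModel(name)
    expect_s4_class(m, "KineticModel")
    expect_true(validObject(m))
    tr <- simulateSSA(m, duration = 2 * 3600, nIntervals = 50, seed = 1)
    expect_true(all(speciesCounts(tr) >= 0))
    od <- simulateODE(m, duration = 2 * 3600, nPoints = 50)
    expect_equal(length(gridTimes(od)), 51)
  }
  expect_error(getModel("not_a_model"), "unknown model")
  expect_error(buildTgfbSmad3Model("nope"), "arg")
  expect_error(buildIl1Mmp13Model("nope"), "arg")
  expect_error(buildGenericMotif("nope"), "arg")
  expect_error(buildIntegratedModel(-5), ">= 0")
})

test_that("figure-legend parameter values are wired into the presets", {
  expect_equal(unname(rateValues(buildTgfbSmad3Model())["k_synmiR140"]), 0.0018)
  expect_equal(unname(initialCounts(buildTgfbSmad3Model())["miR140"]), 500)
  n <- buildTgfbSmad3Model("no_miR140")
  expect_equal(unname(initialCounts(n)["miR140"]), 0)
  expect_false("k_synmiR140" %in% names(rateValues(n)))

  expect_equal(unname(rateValues(buildIl1Mmp13Model())["k_actNFkB"]), 5e-4)
  expect_equal(unname(rateValues(
    buildIl1Mmp13Model("NFkB_inhibition"))["k_actNFkB"]), 1e-4)
  expect_equal(unname(rateValues(
    buildIl1Mmp13Model("miR140_inhibition"))["k_synmiR140"]), 0.0009)
  ov <- buildIl1Mmp13Model("miR140_overexpression")
  expect_equal(unname(rateValues(ov)["k_synmiR140"]), 0.0036)
  expect_equal(unname(initialCounts(ov)["miR140"]), 500)

  low <- buildTnfaIgfbp5Model("miR140_low", "tnfa_chronic")
  expect_equal(unname(initialCounts(low)[c("miR140", "Tnfa")]), c(30, 500))
  expect_equal(unname(rateValues(low)[c("k_synmiR140", "k_synmiR140NFkB",
                                        "k_degTnfa")]),
               c(6e-5, 1.5e-4, 1e-5))
  bas <- buildTnfaIgfbp5Model("miR140_basal", "tnfa_500")
  expect_equal(unname(initialCounts(bas)["miR140"]), 200)
  expect_equal(unname(rateValues(bas)[c("k_synmiR140", "k_synmiR140NFkB")]),
               c(4e-4, 1e-3))
  hi <- buildTnfaIgfbp5Model("miR140_high", "tnfa_chronic")
  expect_equal(unname(initialCounts(hi)["miR140"]), 900)
  expect_equal(unname(rateValues(hi)[c("k_synmiR140", "k_synmiR140NFkB")]),
               c(1.8e-3, 4.5e-3))
  # presets are mutually consistent with one miR-140 turnover rate
  expect_equal(unname(rateValues(bas)["k_synmiR140"] /
                        rateValues(bas)["k_degmiR140"]), 200)
  expect_equal(unname(rateValues(low)["k_synmiR140"] /
                        rateValues(low)["k_degmiR140"]), 30)
})

test_that("with/without-miR-140 variants differ only in the miR-140 knobs", {
  for (builder in list(buildTgfbSmad3Model, buildSox9Runx2Model,
                       buildIl1Adamts5Model, buildIl1Mmp13Model)) {
    w <- builder("with_miR140")
    n <- builder("no_miR140")
    expect_identical(speciesNames(w), speciesNames(n))
    iw <- initialCounts(w); inn <- initialCounts(n)
    diffSp <- names(iw)[iw != inn]
    expect_true(all(diffSp %in% "miR140"))
    # all reactions except those driven by k_synmiR140 are shared
    sig <- function(m) vapply(reactionList(m), function(r)
      paste(paste(r$reactants, collapse = "+"), "->",
            paste(r$products, collapse = "+"), "@", r$rate), character(1))
    expect_identical(setdiff(sig(w), sig(n)),
                     sig(w)[vapply(reactionList(w),
                                   function(r) r$rate == "k_synmiR140",
                                   logical(1))])
    rw <- rateValues(w); rn <- rateValues(n)
    shared <- intersect(names(rw), names(rn))
    expect_identical(rw[shared], rn[shared])
  }
})

test_that("the integrated model exposes the matrix readouts and accepts a dose", {
  m <- buildIntegratedModel(500)
  expect_true(all(c("ADAMTS5", "MMP13", "AggFrag", "ColFrag", "antimiR140",
                    "miR140_antimiR140", "Aggrecan", "Collagen2")
                  %in% speciesNames(m)))
  ic <- initialCounts(m)
  expect_equal(unname(ic["antimiR140"]), 500)
  expect_equal(unname(ic[c("IL1", "Tnfa", "TGFb_A")]), c(500, 500, 500))
  expect_equal(unname(ic[c("Aggrecan", "Collagen2")]), c(10000, 10000))
  expect_equal(unname(ic[c("AggFrag", "ColFrag")]), c(0, 0))
  m2 <- buildIntegratedModel(0, il1 = 800, tgfb = 31.6)  # non-integer rounded
  expect_equal(unname(initialCounts(m2)["TGFb_A"]), 32)
})

test_that("registry variants resolve and reject malformed labels", {
  expect_s4_class(getModel("tnfa_igfbp5", "miR140_low/tnfa_chronic"),
                  "KineticModel")
  expect_error(getModel("tnfa_igfbp5", "miR140_low"), "variant")
  expect_s4_class(getModel("integrated", "anti_miR140_3000"), "KineticModel")
  expect_equal(unname(initialCounts(
    getModel("integrated", "anti_miR140_3000"))["antimiR140"]), 3000)
})

test_that("the ADAMTS5 response is a pulse with miR-140 and keeps rising without it", {
  tw <- simulateODE(buildIl1Adamts5Model("with_miR140"), 48 * 3600, 400)
  a <- observableTrace(tw, "ADAMTS5")
  i <- which.max(a)
  expect_gt(i, 1); expect_lt(i, length(a))           # interior maximum
  expect_lt(a[length(a)], 0.1 * a[i])                # clear decline

  t0 <- simulateODE(buildIl1Adamts5Model("no_miR140"), 48 * 3600, 400)
  a0 <- observableTrace(t0, "ADAMTS5")
  il1 <- observableTrace(t0, "IL1")
  # IL-1 has decayed below 10% by 3 h, yet ADAMTS5 mRNA keeps rising
  i3h <- which.min(abs(gridTimes(t0) - 3 * 3600))
  i8h <- which.min(abs(gridTimes(t0) - 8 * 3600))
  expect_lt(il1[i3h], 50)
  expect_gt(a0[i8h], a0[i3h])
})

test_that("miR-140 raises the late RUNX2 level and sustains MMP13 in the SOX9 pathway", {
  dur <- 4 * 86400
  ew <- runEnsemble(buildSox9Runx2Model("with_miR140"), nReps = 10,
                    duration = dur, nIntervals = 200, baseSeed = 4)
  e0 <- runEnsemble(buildSox9Runx2Model("no_miR140"), nReps = 10,
                    duration = dur, nIntervals = 200, baseSeed = 4)
  last <- 201
  runxW <- ensembleMean(ew)[last, "RUNX2"]
  runx0 <- ensembleMean(e0)[last, "RUNX2"]
  expect_gt(runxW, runx0)                            # strictly greater
  # without miR-140 the MMP13 transcript decays toward zero
  expect_lt(ensembleMean(e0)[last, "MMP13"], 10)
  expect_gt(ensembleMean(ew)[last, "MMP13"], ensembleMean(e0)[last, "MMP13"])
})
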