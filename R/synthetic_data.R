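#' Design for a synthetic miRNA-target table with planted enrichment
#'
#' Describes a synthetic stand-in for a miRNA-target interaction download
#' crossed with a disease gene list: a gene universe, per-miRNA target-set
#' sizes, a disease gene subset, and a small set of "planted" miRNAs whose
#' target sets are enriched for disease genes at a controlled expected
#' enrichment ratio.
#'
#' @param nMirnas number of miRNAs.
#' @param nGenes size of the gene universe.
#' @param nDiseaseGenes number of disease-associated genes.
#' @param targetsPerMirna length-2 range of the (uniform) per-miRNA
#'   target-set size.
#' @param nPlanted number of planted (truly enriched) miRNAs.
#' @param plantedRatio expected enrichment ratio of planted miRNAs (>= 1);
#'   planting inflates the per-draw disease-gene probability to
#'   \code{plantedRatio * K/N}, so realised counts remain stochastic.
#' @param seed integer seed.
#' @return list of class \code{"plantedEnrichmentDesign"}.
#' @export
plantedEnrichmentDesign <- function(nMirnas = 200L, nGenes = 2000L,
                                    nDiseaseGenes = 100L,
                                    targetsPerMirna = c(150L, 250L),
                                    nPlanted = 5L, plantedRatio = 3,
                                    seed = 1L) {
  if (plantedRatio < 1) stop("plantedRatio must be >= 1")
  if (nDiseaseGenes > nGenes) stop("more disease genes than genes")
  if (nPlanted > nMirnas) stop("more planted miRNAs than miRNAs")
  p <- plantedRatio * nDiseaseGenes / nGenes
  if (p > 1)
    stop("infeasible design: planted disease-draw probability exceeds 1")
  if (max(targetsPerMirna) > nGenes)
    stop("target sets larger than the universe")
  structure(list(nMirnas = as.integer(nMirnas), nGenes = as.integer(nGenes),
                 nDiseaseGenes = as.integer(nDiseaseGenes),
                 targetsPerMirna = as.integer(targetsPerMirna),
                 nPlanted = as.integer(nPlanted),
                 plantedRatio = plantedRatio, seed = as.integer(seed)),
            class = "plantedEnrichmentDesign")
}

#' Generate a synthetic target table and disease gene set
#'
#' Non-planted miRNAs draw their target sets uniformly from the gene
#' universe. Planted miRNAs draw a Binomial(n, plantedRatio * K/N) number
#' of disease genes (so hypergeometric assumptions stay honest) and fill
#' the rest of the set from non-disease genes; with \code{exactK = TRUE}
#' the disease-target count is fixed at \code{round(ratio * n * K/N)}
#' instead, for deterministic unit tests. Fully reproducible from the
#' design seed.
#'
#' @param design a [plantedEnrichmentDesign()].
#' @param exactK fix each planted miRNA's disease-target count at its
#'   expectation instead of drawing it.
#' @return list with \code{table} (a [targetTable()]), \code{diseaseGenes}
#'   (character vector) and \code{truth} (data.frame with one row per
#'   miRNA: \code{mirna, planted, n_targets, k_disease}).
#' @export
generateTargetTable <- function(design, exactK = FALSE) {
  stopifnot(inherits(design, "plantedEnrichmentDesign"))
  set.seed(design$seed)
  genes <- sprintf("GENE%04d", seq_len(design$nGenes))
  mirnas <- sprintf("miR-%03d", seq_len(design$nMirnas))
  disease <- sample(genes, design$nDiseaseGenes)
  nonDisease <- setdiff(genes, disease)
  planted <- mirnas[seq_len(design$nPlanted)]
  p <- design$plantedRatio * design$nDiseaseGenes / design$nGenes

  rows <- vector("list", design$nMirnas)
  truth <- data.frame(mirna = mirnas, planted = mirnas %in% planted,
                      n_targets = 0L, k_disease = 0L)
  for (i in seq_along(mirnas)) {
    n <- sample(design$targetsPerMirna[1]:design$targetsPerMirna[2], 1L)
    if (truth$planted[i]) {
      k <- if (exactK) as.integer(round(p * n))
           else stats::rbinom(1L, n, p)
      k <- min(k, design$nDiseaseGenes, n)
      tg <- c(sample(disease, k), sample(nonDisease, n - k))
    } else {
      tg <- sample(genes, n)
    }
    truth$n_targets[i] <- n
    truth$k_disease[i] <- sum(tg %in% disease)
    rows[[i]] <- data.frame(mirna = mirnas[i], gene = tg)
  }
  df <- do.call(rbind, rows)
  list(table = targetTable(df$mirna, df$gene),
       diseaseGenes = disease, truth = truth)
}

#' Write synthetic enrichment inputs in the layouts the readers accept
#'
#' Emits a tab-separated interaction file (miRNA / Target Gene / Support
#' Type columns) and a one-gene-per-row disease list, as produced by
#' [generateTargetTable()].
#'
#' @param generated output of [generateTargetTable()].
#' @param dir output directory.
#' @return character vector of the two file paths.
#' @export
writeTargetTableFiles <- function(generated, dir = tempdir()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  interactions <- file.path(dir, "synthetic_mti.tsv")
  tab <- generated$table
  utils::write.table(
    data.frame("miRNA" = tab$mirna, "Target Gene" = tab$gene,
               "Support Type" = "Functional MTI", check.names = FALSE),
    interactions, sep = "\t", row.names = FALSE, quote = FALSE)
  diseases <- file.path(dir, "synthetic_disease_genes.txt")
  writeLines(c("gene", generated$diseaseGenes), diseases)
  c(interactions = interactions, diseaseGenes = diseases)
}

#' Synthetic trajectory fixtures with known ground truth
#'
#' Deterministic base curves plus seeded Gaussian noise, for testing the
#' summary statistics: \code{constant}, \code{pulse} (gamma-shaped rise and
#' decline with a known peak time), \code{monotone_rise} (saturating), and
#' \code{dip_recover} (transient dip below a basal level with a known
#' recovery time).
#'
#' @param shape one of \code{"constant"}, \code{"pulse"},
#'   \code{"monotone_rise"}, \code{"dip_recover"}.
#' @param duration trace duration in seconds.
#' @param nIntervals reporting intervals.
#' @param level basal/plateau level.
#' @param peakTime (pulse) time of the true maximum, seconds.
#' @param recoveryTime (dip_recover) time after which the trace is back
#'   within 5\% of basal, seconds.
#' @param noiseSd standard deviation of added noise (0 = deterministic).
#' @param seed integer seed for the noise.
#' @return a [Trajectory-class] (species column \code{"x"}) with the ground
#'   truth attached as attribute \code{"truth"}.
#' @export
makeTrajectoryFixture <- function(shape = c("constant", "pulse",
                                            "monotone_rise", "dip_recover"),
                                  duration = 48 * 3600, nIntervals = 1000L,
                                  level = 100, peakTime = duration / 4,
                                  recoveryTime = duration / 2,
                                  noiseSd = 0, seed = 1L) {
  shape <- match.arg(shape)
  tt <- seq(0, duration, length.out = nIntervals + 1L)
  y <- switch(shape,
    constant = rep(level, length(tt)),
    pulse = {
      # gamma-like pulse: t*exp(1 - t/peak), maximum exactly at peakTime
      z <- tt / peakTime
      level * z * exp(1 - z)
    },
    monotone_rise = level * (1 - exp(-3 * tt / duration)),
    dip_recover = {
      # exponential dip recovering so the trace re-enters +/-5% of basal
      # at recoveryTime and stays inside afterwards
      depth <- 0.5
      tau <- recoveryTime / log(depth / 0.05)
      level * (1 - depth * exp(-tt / tau) * (tt > 0))
    })
  if (noiseSd > 0) {
    set.seed(seed)
    y <- y + rnorm(length(y), sd = noiseSd)
  }
  truth <- list(shape = shape, level = level,
                peakTime = if (shape == "pulse") peakTime else NA_real_,
                recoveryTime = if (shape == "dip_recover") recoveryTime
                               else NA_real_)
  counts <- matrix(y, ncol = 1, dimnames = list(NULL, "x"))
  out <- new("Trajectory", times = tt, counts = counts,
             seed = as.integer(seed), stochastic = FALSE)
  attr(out, "truth") <- truth
  out
}
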