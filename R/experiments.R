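#' Fold change of an observable at a time point
#'
#' Ratio of the (ensemble-mean) observable at time \code{t} to a reference
#' value. For \code{"total:"} observables the free and complexed pools are
#' summed (e.g. \code{"total:miR140"}, \code{"total:IGFBP5_mRNA"}).
#'
#' @param object a [Trajectory-class] or [EnsembleSummary-class].
#' @param observable species, set of species, or \code{"total:<stem>"}.
#' @param t time in seconds (snapped to the nearest grid point).
#' @param baseline a positive reference value, or a second
#'   Trajectory/EnsembleSummary whose observable at \code{t} is the
#'   reference (e.g. an unstimulated control run).
#' @return the fold change (dimensionless).
#' @export
foldChangeAt <- function(object, observable, t, baseline) {
  y <- observableTrace(object, observable)
  i <- which.min(abs(gridTimes(object) - t))
  base <- if (is(baseline, "Trajectory") || is(baseline, "EnsembleSummary")) {
    yb <- observableTrace(baseline, observable)
    ib <- which.min(abs(gridTimes(baseline) - t))
    yb[ib]
  } else baseline
  if (!is.numeric(base) || base <= 0)
    stop("fold change undefined: baseline must be > 0")
  unname(y[i] / base)
}

#' Peak time of a (smoothed) observable trace
#'
#' Time of the maximum of the moving-average-smoothed trace; ties broken to
#' the earliest grid point. A maximum on the first or last grid point is
#' flagged as a boundary (no interior peak).
#'
#' @param object a [Trajectory-class] or [EnsembleSummary-class].
#' @param observable species, set of species, or \code{"total:<stem>"}.
#' @param smoothingWindow moving-average window in grid points (default 11,
#'   about 1\% of a 1000-interval trace); 1 disables smoothing.
#' @return list with \code{time} (seconds), \code{value} (smoothed height)
#'   and \code{interior} (FALSE when the maximum sits on the boundary).
#' @export
peakTime <- function(object, observable, smoothingWindow = 11L) {
  y <- observableTrace(object, observable)
  if (length(y) <= smoothingWindow)
    stop("trace shorter than the smoothing window")
  ys <- .movingAverage(y, smoothingWindow)
  i <- which.max(ys)
  tt <- gridTimes(object)
  list(time = tt[i], value = ys[i],
       interior = i > 1L && i < length(ys))
}

#' Time of return to a basal band
#'
#' Earliest grid time after the largest excursion from basal at which the
#' (ensemble-mean) observable lies within \code{toleranceFraction * basal}
#' of basal and stays there for the remainder of the trace.
#'
#' @param object a [Trajectory-class] or [EnsembleSummary-class].
#' @param observable species, set of species, or \code{"total:<stem>"}.
#' @param basal positive basal reference level.
#' @param toleranceFraction half-width of the band as a fraction of basal
#'   (default 0.1).
#' @return list with \code{time} (seconds; \code{Inf} when the trace never
#'   settles back), \code{returned} (logical) and \code{extremum} (time of
#'   the largest excursion).
#' @export
returnToBasalTime <- function(object, observable, basal,
                              toleranceFraction = 0.1) {
  y <- observableTrace(object, observable)
  .returnToBasal(gridTimes(object), y, basal, toleranceFraction)
}

#' Dose-response scan grid
#'
#' IL-1 spans 0-1000 in 10 evenly spaced levels (endpoints included) and
#' TGF-beta spans 1-1000 in 3 log-spaced levels (the layout of the
#' combined-stimulus scan experiments); both axes are configurable.
#'
#' @param il1Values numeric IL-1 initial amounts.
#' @param tgfbValues numeric TGF-beta initial amounts.
#' @param nReps stochastic replicates per grid cell (>= 2).
#' @return list of class \code{"scanGrid"}.
#' @export
scanGrid <- function(il1Values = seq(0, 1000, length.out = 10),
                     tgfbValues = 10^seq(0, 3, length.out = 3),
                     nReps = 100L) {
  if (nReps < 2L) stop("nReps must be >= 2")
  structure(list(il1Values = il1Values, tgfbValues = tgfbValues,
                 nReps = as.integer(nReps)), class = "scanGrid")
}

#' IL-1 x TGF-beta dose-response scan of the integrated model
#'
#' For every (IL-1, TGF-beta, anti-miR-140 dose) combination, runs
#' \code{nReps} stochastic replicates of the integrated model and records
#' the mean and 95\% confidence interval of the AggFrag and ColFrag
#' readouts at the end time. Per-cell seeds are derived deterministically
#' from \code{baseSeed}, so the scan is reproducible.
#'
#' @param grid a [scanGrid()].
#' @param antiMir140Doses numeric vector of anti-miR-140 doses.
#' @param endTime end of the simulation in seconds (default 7 days).
#' @param baseSeed integer.
#' @param nIntervals reporting intervals per replicate.
#' @return data.frame with columns \code{il1, tgfb, dose, species, mean,
#'   ci_lo, ci_hi, n_reps}.
#' @export
runDoseResponseScan <- function(grid, antiMir140Doses = c(0, 500),
                                endTime = 7 * 86400, baseSeed = 1L,
                                nIntervals = 200L) {
  stopifnot(inherits(grid, "scanGrid"))
  cells <- expand.grid(il1 = grid$il1Values, tgfb = grid$tgfbValues,
                       dose = antiMir140Doses)
  out <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    cell <- cells[i, ]
    es <- tryCatch(
      runEnsemble(buildIntegratedModel(cell$dose, il1 = cell$il1,
                                       tgfb = cell$tgfb),
                  nReps = grid$nReps, duration = endTime,
                  nIntervals = nIntervals,
                  baseSeed = baseSeed + (i - 1L) * grid$nReps),
      error = function(e) stop(sprintf(
        "scan cell (IL1=%g, TGFb=%g, dose=%g) failed: %s",
        cell$il1, cell$tgfb, cell$dose, conditionMessage(e))))
    last <- length(es@times)
    out[[i]] <- data.frame(
      il1 = cell$il1, tgfb = cell$tgfb, dose = cell$dose,
      species = c("AggFrag", "ColFrag"),
      mean = es@mean[last, c("AggFrag", "ColFrag")],
      ci_lo = es@ciLower[last, c("AggFrag", "ColFrag")],
      ci_hi = es@ciUpper[last, c("AggFrag", "ColFrag")],
      n_reps = grid$nReps, row.names = NULL)
  }
  do.call(rbind, out)
}

# registry of the documented simulation panels: model/variant, duration,
# replication and the species plotted
.figureRegistry <- list(
  "2C" = list(model = "tgfb_smad3", variant = "with_miR140",
              hours = 72, reps = 1,
              species = c("miR140", "pSMAD3", "SMAD3", "TGFb_A")),
  "2D" = list(model = "tgfb_smad3", variant = "no_miR140",
              hours = 72, reps = 1,
              species = c("pSMAD3", "SMAD3", "TGFb_A")),
  "3C" = list(model = "sox9_runx2", variant = "with_miR140",
              hours = 96, reps = 1,
              species = c("miR140", "RUNX2", "HDAC4", "MMP13")),
  "3D" = list(model = "sox9_runx2", variant = "no_miR140",
              hours = 96, reps = 1,
              species = c("RUNX2", "HDAC4", "MMP13")),
  "4C" = list(model = "il1_adamts5", variant = "with_miR140",
              hours = 48, reps = 1,
              species = c("IL1", "miR140", "ADAMTS5")),
  "4D" = list(model = "il1_adamts5", variant = "no_miR140",
              hours = 48, reps = 1, species = c("IL1", "ADAMTS5")),
  "5C" = list(model = "il1_mmp13", variant = "with_miR140",
              hours = 48, reps = 1,
              species = c("IL1", "NFkB", "miR140", "MMP13")),
  "5D" = list(model = "il1_mmp13", variant = "no_miR140",
              hours = 48, reps = 1, species = c("IL1", "NFkB", "MMP13")),
  "5E" = list(model = "il1_mmp13", variant = "NFkB_inhibition",
              hours = 48, reps = 1,
              species = c("NFkB", "miR140", "MMP13")),
  "5F" = list(model = "il1_mmp13", variant = "miR140_inhibition",
              hours = 48, reps = 1,
              species = c("NFkB", "miR140", "MMP13")),
  "5G" = list(model = "il1_mmp13", variant = "miR140_overexpression",
              hours = 48, reps = 1,
              species = c("NFkB", "miR140", "MMP13")),
  "6C" = list(model = "tnfa_igfbp5", variant = "miR140_basal/tnfa_0",
              hours = 30, reps = 1,
              species = c("total:miR140", "total:IGFBP5_mRNA")),
  "6D" = list(model = "tnfa_igfbp5", variant = "miR140_basal/tnfa_500",
              hours = 30, reps = 1,
              species = c("total:miR140", "total:IGFBP5_mRNA")),
  "6E" = list(model = "tnfa_igfbp5", variant = "miR140_inhibition/tnfa_0",
              hours = 30, reps = 1,
              species = c("total:miR140", "total:IGFBP5_mRNA")),
  "6F" = list(model = "tnfa_igfbp5", variant = "miR140_overexpression/tnfa_0",
              hours = 30, reps = 1,
              species = c("total:miR140", "total:IGFBP5_mRNA")),
  "7A" = list(model = "tnfa_igfbp5", variant = "miR140_low/tnfa_chronic",
              hours = 168, reps = 1,
              species = c("total:miR140", "total:IGFBP5_mRNA", "IGFBP5")),
  "7B" = list(model = "tnfa_igfbp5", variant = "miR140_basal/tnfa_chronic",
              hours = 168, reps = 1,
              species = c("total:miR140", "total:IGFBP5_mRNA", "IGFBP5")),
  "7C" = list(model = "tnfa_igfbp5", variant = "miR140_high/tnfa_chronic",
              hours = 168, reps = 1,
              species = c("total:miR140", "total:IGFBP5_mRNA", "IGFBP5")),
  "7D" = list(model = "tnfa_igfbp5",
              variant = c("miR140_low/tnfa_chronic",
                          "miR140_basal/tnfa_chronic",
                          "miR140_high/tnfa_chronic"),
              hours = 168, reps = 100, species = "ACAN"),
  "8B" = list(model = "integrated", variant = "anti_miR140_0",
              hours = 168, reps = 1,
              species = c("ADAMTS5", "MMP13", "AggFrag", "ColFrag")),
  "8C" = list(model = "integrated", variant = "anti_miR140_500",
              hours = 168, reps = 1,
              species = c("ADAMTS5", "MMP13", "AggFrag", "ColFrag")),
  "8D" = list(model = "integrated", variant = "anti_miR140_3000",
              hours = 168, reps = 1,
              species = c("ADAMTS5", "MMP13", "AggFrag", "ColFrag")),
  "9A" = list(scan = TRUE, dose = 0, readout = "AggFrag"),
  "9B" = list(scan = TRUE, dose = 0, readout = "ColFrag"),
  "9C" = list(scan = TRUE, dose = 500, readout = "AggFrag"),
  "9D" = list(scan = TRUE, dose = 500, readout = "ColFrag")
)

#' Reproduce a documented simulation panel
#'
#' Runs the panel's documented model/variant, duration and replication,
#' writes the trajectory (or scan) data as tidy CSV plus a plot, and
#' records provenance (model name, variant, seeds) alongside.
#'
#' @param figureId panel identifier, e.g. \code{"2C"}, \code{"5F"},
#'   \code{"7D"}, \code{"9C"}; see \code{names(mir140sim:::.figureRegistry)}.
#' @param seed base seed.
#' @param dir output directory (created if needed).
#' @param nReps optional override of the panel's replicate count (used to
#'   scale long scans down).
#' @param nIntervals reporting intervals.
#' @return invisibly, a list with the computed data (data.frame), the file
#'   paths written, and the provenance record.
#' @export
reproduceFigure <- function(figureId, seed = 1L, dir = tempdir(),
                            nReps = NULL, nIntervals = 1000L) {
  spec <- .figureRegistry[[figureId]]
  if (is.null(spec)) stop("unknown figure id: ", figureId)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  csv <- file.path(dir, paste0("figure_", figureId, ".csv"))
  png <- file.path(dir, paste0("figure_", figureId, ".png"))

  if (isTRUE(spec$scan)) {
    grid <- scanGrid(nReps = if (is.null(nReps)) 100L else as.integer(nReps))
    df <- runDoseResponseScan(grid, antiMir140Doses = spec$dose,
                              baseSeed = seed, nIntervals = 200L)
    df <- df[df$species == spec$readout, ]
    p <- ggplot2::ggplot(df, ggplot2::aes(x = il1, y = mean,
                                          colour = factor(tgfb))) +
      ggplot2::geom_line() + ggplot2::geom_point() +
      ggplot2::geom_errorbar(ggplot2::aes(ymin = ci_lo, ymax = ci_hi),
                             width = 20) +
      ggplot2::labs(x = "IL-1 (initial molecules)", y = spec$readout,
                    colour = "TGF-beta") +
      ggplot2::theme_bw()
    prov <- list(figure = figureId, scan = TRUE, dose = spec$dose,
                 n_reps = grid$nReps, base_seed = seed)
  } else {
    variants <- spec$variant
    dur <- spec$hours * 3600
    parts <- lapply(variants, function(v) {
      model <- getModel(spec$model, v)
      if (spec$reps == 1L) {
        tr <- simulateSSA(model, dur, nIntervals = nIntervals, seed = seed)
        long <- do.call(rbind, lapply(spec$species, function(sp) data.frame(
          time = tr@times, species = sp,
          value = observableTrace(tr, sp))))
        long$variant <- v
        long
      } else {
        es <- runEnsemble(model, nReps = if (is.null(nReps)) spec$reps
                                          else as.integer(nReps),
                          duration = dur, nIntervals = nIntervals,
                          baseSeed = seed)
        last <- length(es@times)
        do.call(rbind, lapply(spec$species, function(sp) {
          cols <- .observableColumns(colnames(es@mean), sp)
          data.frame(time = es@times[last], species = sp,
                     value = sum(es@mean[last, cols]),
                     ci_lo = sum(es@ciLower[last, cols]),
                     ci_hi = sum(es@ciUpper[last, cols]),
                     variant = v)
        }))
      }
    })
    df <- do.call(rbind, parts)
    p <- if (spec$reps == 1L) {
      ggplot2::ggplot(df, ggplot2::aes(x = time / 3600, y = value,
                                       colour = species)) +
        ggplot2::geom_line() +
        ggplot2::facet_wrap(~variant) +
        ggplot2::labs(x = "time (h)", y = "molecules") +
        ggplot2::theme_bw()
    } else {
      ggplot2::ggplot(df, ggplot2::aes(x = variant, y = value)) +
        ggplot2::geom_col(fill = "grey70") +
        ggplot2::geom_errorbar(ggplot2::aes(ymin = ci_lo, ymax = ci_hi),
                               width = 0.2) +
        ggplot2::labs(y = paste(spec$species, "(ensemble mean)")) +
        ggplot2::theme_bw()
    }
    prov <- list(figure = figureId, model = spec$model,
                 variant = variants, hours = spec$hours,
                 n_reps = if (is.null(nReps)) spec$reps else nReps,
                 base_seed = seed)
  }
  write.csv(df, csv, row.names = FALSE)
  ggplot2::ggsave(png, p, width = 7, height = 4.5, dpi = 120)
  invisible(list(data = df, files = c(csv = csv, png = png),
                 provenance = prov))
}
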