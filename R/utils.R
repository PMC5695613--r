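# Internal helpers shared by the simulation engines and experiment
# statistics.

# Resolve an observable to a single trace. `observable` is a species name,
# a character vector of species names (summed), or "total:<stem>" which sums
# every species whose name contains <stem> (free plus complexed pools).
.observableColumns <- function(speciesNames, observable) {
  if (length(observable) == 1L && startsWith(observable, "total:")) {
    stem <- sub("^total:", "", observable)
    cols <- grep(stem, speciesNames, fixed = TRUE, value = TRUE)
    # the molecular total is the free pool plus mRNA-bound complexes;
    # gene-state species and anti-miR-sequestered (inert) pools are not
    # part of it
    cols <- cols[!grepl("gene|antimiR", cols)]
    if (!length(cols))
      stop("no species match total group '", observable, "'")
    return(cols)
  }
  missing <- setdiff(observable, speciesNames)
  if (length(missing))
    stop("unknown species: ", paste(missing, collapse = ", "))
  observable
}

#' Extract an observable trace from a trajectory or ensemble
#'
#' @param object a [Trajectory-class] or [EnsembleSummary-class].
#' @param observable species name, character vector of species names (summed),
#'   or \code{"total:<stem>"} summing all species whose name contains the stem
#'   (free plus complexed pools, e.g. \code{"total:miR140"}).
#' @return numeric vector along the reporting grid (ensemble mean for
#'   ensembles).
#' @export
observableTrace <- function(object, observable) {
  mat <- if (is(object, "Trajectory")) object@counts
         else if (is(object, "EnsembleSummary")) object@mean
         else stop("object must be a Trajectory or EnsembleSummary")
  cols <- .observableColumns(colnames(mat), observable)
  if (length(cols) == 1L) mat[, cols] else rowSums(mat[, cols, drop = FALSE])
}

# centred moving average with window w (odd); edges use shrunken windows
.movingAverage <- function(y, w) {
  if (w <= 1L) return(y)
  n <- length(y)
  half <- w %/% 2L
  vapply(seq_len(n), function(i) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    mean(y[lo:hi])
  }, numeric(1))
}

# earliest grid time after the largest deviation from basal at which the
# trace is within tol*basal of basal and stays there for the rest of the
# trace; +Inf with returned=FALSE if never
.returnToBasal <- function(times, y, basal, tol = 0.1) {
  if (basal <= 0) stop("basal must be > 0")
  dev <- abs(y - basal)
  inBand <- dev <= tol * basal
  iExt <- which.max(dev)
  if (all(inBand)) return(list(time = 0, returned = TRUE, extremum = times[iExt]))
  stays <- rev(cumprod(rev(inBand))) == 1
  idx <- which(stays & seq_along(y) >= iExt)
  if (!length(idx))
    return(list(time = Inf, returned = FALSE, extremum = times[iExt]))
  list(time = times[idx[1]], returned = TRUE, extremum = times[iExt])
}

# hours/days helpers used by the reporting layers (internal clock is seconds)
.hours <- function(h) h * 3600
.days <- function(d) d * 86400
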