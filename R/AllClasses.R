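#' @import methods
#' @importFrom stats qt sd setNames rnorm runif optim
#' @importFrom utils head tail write.csv
NULL

#' KineticModel: a named mass-action reaction network
#'
#' A \code{KineticModel} holds species with integer initial copy numbers and
#' a list of mass-action reactions of total reactant order at most 2.
#' Rate constants are stored in a named numeric vector so interventions and
#' parameter calibration can address them by name.
#'
#' Units: copy numbers are molecules (dimensionless), time is seconds.
#' Rate constants are s^-1 for order 0/1 reactions and molecule^-1 s^-1 for
#' order 2 reactions.
#'
#' @slot name single character, model name.
#' @slot species data.frame with columns \code{name} (character),
#'   \code{initial} (non-negative integer-valued numeric) and \code{role}
#'   (character annotation, e.g. "mRNA", "miRNA", "protein", "readout").
#' @slot reactions list; each element is a list with character vectors
#'   \code{reactants} and \code{products} (species names, possibly repeated
#'   for stoichiometry > 1, length of reactants <= 2) and a single character
#'   \code{rate} naming the rate constant.
#' @slot rates named numeric vector of positive rate constants.
#' @slot notes free-text provenance.
#'
#' @seealso [buildModel()] which validates its arguments and constructs the
#'   object, [applyIntervention()], [simulateSSA()], [simulateODE()].
#' @export
setClass("KineticModel",
  representation(
    name = "character",
    species = "data.frame",
    reactions = "list",
    rates = "numeric",
    notes = "character"
  ),
  prototype(notes = "")
)

setValidity("KineticModel", function(object) {
  msg <- character()
  sp <- object@species
  if (length(object@name) != 1L || !nzchar(object@name))
    msg <- c(msg, "model name must be a single non-empty string")
  if (!all(c("name", "initial", "role") %in% names(sp)))
    msg <- c(msg, "species must have columns name, initial, role")
  else {
    if (anyDuplicated(sp$name))
      msg <- c(msg, "duplicate species names")
    if (any(!nzchar(sp$name)))
      msg <- c(msg, "empty species name")
    if (any(sp$initial < 0) || any(sp$initial != round(sp$initial)))
      msg <- c(msg, "initial counts must be non-negative integers")
  }
  if (length(object@reactions) < 1L)
    msg <- c(msg, "model must contain at least one reaction")
  rate_names <- names(object@rates)
  if (length(object@rates) && (is.null(rate_names) || anyDuplicated(rate_names)))
    msg <- c(msg, "rates must be uniquely named")
  if (any(object@rates <= 0))
    msg <- c(msg, "rate constants must be positive")
  for (i in seq_along(object@reactions)) {
    rx <- object@reactions[[i]]
    if (!is.list(rx) || !all(c("reactants", "products", "rate") %in% names(rx))) {
      msg <- c(msg, sprintf("reaction %d malformed", i))
      next
    }
    if (length(rx$reactants) > 2L)
      msg <- c(msg, sprintf("reaction %d: reactant order > 2", i))
    unknown <- setdiff(c(rx$reactants, rx$products), sp$name)
    if (length(unknown))
      msg <- c(msg, sprintf("reaction %d references unknown species: %s",
                            i, paste(unknown, collapse = ", ")))
    if (length(rx$rate) != 1L || !(rx$rate %in% rate_names))
      msg <- c(msg, sprintf("reaction %d: rate constant '%s' not defined",
                            i, paste(rx$rate, collapse = ",")))
  }
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' Intervention: declarative override of initial counts and rate constants
#'
#' Interventions express knockdown, overexpression and anti-miR dosing the
#' way the figure legends do: by replacing species initial copy numbers
#' and/or rate-constant values. Rate overrides of exactly 0 are allowed
#' (switching synthesis off); the resulting reactions are dropped from the
#' model rather than stored with a zero constant.
#'
#' @slot label single character.
#' @slot initialOverrides named numeric (species name -> new count).
#' @slot rateOverrides named numeric (rate-constant name -> new value >= 0).
#' @seealso [applyIntervention()]
#' @export
setClass("Intervention",
  representation(
    label = "character",
    initialOverrides = "numeric",
    rateOverrides = "numeric"
  ),
  prototype(label = "intervention",
            initialOverrides = setNames(numeric(0), character(0)),
            rateOverrides = setNames(numeric(0), character(0)))
)

setValidity("Intervention", function(object) {
  msg <- character()
  io <- object@initialOverrides
  ro <- object@rateOverrides
  if (length(io) && (is.null(names(io)) || any(!nzchar(names(io)))))
    msg <- c(msg, "initialOverrides must be named")
  if (length(ro) && (is.null(names(ro)) || any(!nzchar(names(ro)))))
    msg <- c(msg, "rateOverrides must be named")
  if (any(io < 0) || any(io != round(io)))
    msg <- c(msg, "initial overrides must be non-negative integers")
  if (any(ro < 0))
    msg <- c(msg, "rate overrides must be >= 0")
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' Trajectory: species counts on a uniform reporting grid
#'
#' @slot times numeric grid of reporting times in seconds, strictly
#'   increasing from 0, length nIntervals + 1.
#' @slot counts numeric matrix, one row per reporting time, one column per
#'   species (integer-valued for stochastic runs, real-valued for ODE runs).
#' @slot seed integer seed used (NA for deterministic runs).
#' @slot stochastic logical.
#' @export
setClass("Trajectory",
  representation(
    times = "numeric",
    counts = "matrix",
    seed = "integer",
    stochastic = "logical"
  )
)

setValidity("Trajectory", function(object) {
  msg <- character()
  tt <- object@times
  if (length(tt) < 2L || tt[1] != 0 || any(diff(tt) <= 0))
    msg <- c(msg, "times must increase strictly from 0")
  if (nrow(object@counts) != length(tt))
    msg <- c(msg, "counts must have one row per time")
  if (is.null(colnames(object@counts)))
    msg <- c(msg, "counts must have species column names")
  if (object@stochastic && any(object@counts < 0))
    msg <- c(msg, "stochastic counts must be non-negative")
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' EnsembleSummary: per-species mean and 95\% confidence interval over
#' independent stochastic replicates
#'
#' The confidence interval is the Student-t interval on the replicate values
#' at each grid point.
#'
#' @slot times reporting grid (seconds).
#' @slot mean,ciLower,ciUpper numeric matrices (time x species).
#' @slot nReps integer number of replicates.
#' @slot seeds integer vector of per-replicate seeds.
#' @export
setClass("EnsembleSummary",
  representation(
    times = "numeric",
    mean = "matrix",
    ciLower = "matrix",
    ciUpper = "matrix",
    nReps = "integer",
    seeds = "integer"
  )
)

setValidity("EnsembleSummary", function(object) {
  msg <- character()
  if (object@nReps < 2L) msg <- c(msg, "nReps must be >= 2")
  d <- dim(object@mean)
  if (!identical(d, dim(object@ciLower)) || !identical(d, dim(object@ciUpper)))
    msg <- c(msg, "mean/ciLower/ciUpper dimensions differ")
  if (d[1] != length(object@times))
    msg <- c(msg, "mean must have one row per time")
  if (any(object@ciUpper - object@ciLower < -1e-9))
    msg <- c(msg, "ciUpper must be >= ciLower")
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' OdeSettings: integrator settings mirroring the LSODA defaults used for
#' the deterministic runs
#'
#' @slot relTol relative tolerance (default 1e-6).
#' @slot absTol absolute tolerance (default 1e-13).
#' @slot maxInternalSteps maximum number of internal integrator steps
#'   (default 10000).
#' @export
setClass("OdeSettings",
  representation(
    relTol = "numeric",
    absTol = "numeric",
    maxInternalSteps = "integer"
  ),
  prototype(relTol = 1e-6, absTol = 1e-13, maxInternalSteps = 10000L)
)

setValidity("OdeSettings", function(object) {
  if (object@relTol <= 0 || object@absTol <= 0)
    "tolerances must be positive"
  else if (object@maxInternalSteps < 1L)
    "maxInternalSteps must be >= 1"
  else TRUE
})

#' @describeIn OdeSettings-class constructor.
#' @param relTol,absTol,maxInternalSteps see slots.
#' @export
odeSettings <- function(relTol = 1e-6, absTol = 1e-13,
                        maxInternalSteps = 10000L) {
  new("OdeSettings", relTol = relTol, absTol = absTol,
      maxInternalSteps = as.integer(maxInternalSteps))
}

## ---- accessors ----

#' Accessors for KineticModel, Trajectory and EnsembleSummary
#'
#' @param object a \code{KineticModel}, \code{Trajectory} or
#'   \code{EnsembleSummary}.
#' @return \code{modelName}: the model name; \code{speciesNames}: character
#'   vector; \code{initialCounts}: named numeric of initial copy numbers;
#'   \code{rateValues}: named numeric of rate constants; \code{reactionList}:
#'   list of reactions; \code{gridTimes}: the reporting grid in seconds;
#'   \code{speciesCounts}: the time x species matrix; \code{ensembleMean},
#'   \code{ensembleCI}: summary matrices.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("modelName", function(object) standardGeneric("modelName"))
#' @rdname accessors
#' @export
setMethod("modelName", "KineticModel", function(object) object@name)

#' @rdname accessors
#' @export
setGeneric("speciesNames", function(object) standardGeneric("speciesNames"))
#' @rdname accessors
#' @export
setMethod("speciesNames", "KineticModel", function(object) object@species$name)
#' @rdname accessors
#' @export
setMethod("speciesNames", "Trajectory", function(object) colnames(object@counts))
#' @rdname accessors
#' @export
setMethod("speciesNames", "EnsembleSummary", function(object) colnames(object@mean))

#' @rdname accessors
#' @export
setGeneric("initialCounts", function(object) standardGeneric("initialCounts"))
#' @rdname accessors
#' @export
setMethod("initialCounts", "KineticModel", function(object)
  setNames(object@species$initial, object@species$name))

#' @rdname accessors
#' @export
setGeneric("rateValues", function(object) standardGeneric("rateValues"))
#' @rdname accessors
#' @export
setMethod("rateValues", "KineticModel", function(object) object@rates)

#' @rdname accessors
#' @export
setGeneric("reactionList", function(object) standardGeneric("reactionList"))
#' @rdname accessors
#' @export
setMethod("reactionList", "KineticModel", function(object) object@reactions)

#' @rdname accessors
#' @export
setGeneric("gridTimes", function(object) standardGeneric("gridTimes"))
#' @rdname accessors
#' @export
setMethod("gridTimes", "Trajectory", function(object) object@times)
#' @rdname accessors
#' @export
setMethod("gridTimes", "EnsembleSummary", function(object) object@times)

#' @rdname accessors
#' @export
setGeneric("speciesCounts", function(object) standardGeneric("speciesCounts"))
#' @rdname accessors
#' @export
setMethod("speciesCounts", "Trajectory", function(object) object@counts)

#' @rdname accessors
#' @export
setGeneric("ensembleMean", function(object) standardGeneric("ensembleMean"))
#' @rdname accessors
#' @export
setMethod("ensembleMean", "EnsembleSummary", function(object) object@mean)

#' @rdname accessors
#' @export
setGeneric("ensembleCI", function(object) standardGeneric("ensembleCI"))
#' @rdname accessors
#' @export
setMethod("ensembleCI", "EnsembleSummary", function(object)
  list(lower = object@ciLower, upper = object@ciUpper))

#' @rdname accessors
#' @export
setGeneric("nReplicates", function(object) standardGeneric("nReplicates"))
#' @rdname accessors
#' @export
setMethod("nReplicates", "EnsembleSummary", function(object) object@nReps)

## ---- show methods ----

setMethod("show", "KineticModel", function(object) {
  cat("KineticModel:", object@name, "\n")
  cat(" ", nrow(object@species), "species,",
      length(object@reactions), "reactions,",
      length(object@rates), "rate constants\n")
  nz <- object@species[object@species$initial > 0, , drop = FALSE]
  if (nrow(nz)) {
    shown <- head(nz, 8L)
    cat("  nonzero initials:",
        paste(sprintf("%s=%g", shown$name, shown$initial), collapse = ", "),
        if (nrow(nz) > 8L) "..." else "", "\n")
  }
  if (nzchar(object@notes)) cat("  notes:", object@notes, "\n")
  invisible(NULL)
})

setMethod("show", "Intervention", function(object) {
  cat("Intervention:", object@label, "\n")
  if (length(object@initialOverrides))
    cat("  initials:",
        paste(sprintf("%s=%g", names(object@initialOverrides),
                      object@initialOverrides), collapse = ", "), "\n")
  if (length(object@rateOverrides))
    cat("  rates:",
        paste(sprintf("%s=%g", names(object@rateOverrides),
                      object@rateOverrides), collapse = ", "), "\n")
  invisible(NULL)
})

setMethod("show", "Trajectory", function(object) {
  cat(if (object@stochastic) "Stochastic" else "Deterministic",
      "Trajectory:", ncol(object@counts), "species,",
      length(object@times) - 1L, "intervals, duration",
      max(object@times), "s\n")
  invisible(NULL)
})

setMethod("show", "EnsembleSummary", function(object) {
  cat("EnsembleSummary:", object@nReps, "replicates,",
      ncol(object@mean), "species,",
      length(object@times) - 1L, "intervals, duration",
      max(object@times), "s\n")
  invisible(NULL)
})
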