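#' Define a species
#'
#' @param name identifier (unique within a model).
#' @param initial non-negative integer initial copy number.
#' @param role free-text annotation ("mRNA", "miRNA", "protein", "readout", ...).
#' @return one-row data.frame suitable for [buildModel()].
#' @export
speciesSpec <- function(name, initial = 0, role = "") {
  data.frame(name = name, initial = initial, role = role,
             stringsAsFactors = FALSE)
}

#' Define a mass-action reaction
#'
#' Reactants and products are given as character vectors of species names;
#' repeat a name for stoichiometry 2. Total reactant order must be 0, 1 or 2.
#'
#' @param reactants character vector (length 0, 1 or 2), may be `character(0)`
#'   for zeroth-order synthesis.
#' @param products character vector (possibly empty for pure degradation).
#' @param rate name of the rate constant governing the reaction.
#' @return a reaction record (list).
#' @examples
#' reactionSpec(character(0), "miR140", "k_synmiR140")   # synthesis
#' reactionSpec("miR140", character(0), "k_degmiR140")   # decay
#' reactionSpec(c("IL1", "miR140"), "IL1", "k_degmiR140IL1") # catalysed removal
#' @export
reactionSpec <- function(reactants, products, rate) {
  list(reactants = as.character(reactants),
       products = as.character(products),
       rate = as.character(rate))
}

#' Build a validated kinetic model
#'
#' Checks referential integrity (every species named in a reaction exists,
#' every reaction's rate constant is defined), uniqueness of species names,
#' integer non-negative initial counts and positive rate constants, then
#' returns an immutable [KineticModel-class].
#'
#' @param name model name.
#' @param species data.frame from rbind-ing [speciesSpec()] rows.
#' @param reactions list of [reactionSpec()] records.
#' @param rates named numeric vector of positive rate constants.
#' @param notes optional provenance text.
#' @return a [KineticModel-class].
#' @examples
#' m <- buildModel("birth_death",
#'   rbind(speciesSpec("A", 10)),
#'   list(reactionSpec(character(0), "A", "k_syn"),
#'        reactionSpec("A", character(0), "k_deg")),
#'   c(k_syn = 1e-3, k_deg = 1e-4))
#' @export
buildModel <- function(name, species, reactions, rates, notes = "") {
  new("KineticModel", name = name, species = species,
      reactions = reactions, rates = rates, notes = notes)
}

#' Synthesis rate giving a chosen steady state
#'
#' For zeroth-order synthesis balanced by first-order decay the stationary
#' mean is k_syn / k_deg, so the synthesis rate that yields a target level
#' is k_deg * target.
#'
#' @param kDeg first-order degradation rate (s^-1), > 0.
#' @param targetLevel desired steady-state copy number, >= 0.
#' @return zeroth-order synthesis rate (molecules s^-1).
#' @examples
#' steadyStateSynthesisRate(1e-4, 100) # 0.01
#' @export
steadyStateSynthesisRate <- function(kDeg, targetLevel) {
  if (!is.numeric(kDeg) || kDeg <= 0)
    stop("kDeg must be > 0")
  if (targetLevel < 0)
    stop("targetLevel must be >= 0")
  kDeg * targetLevel
}

#' Convert a half-life to a first-order rate constant
#'
#' @param halfLife half-life in seconds, > 0.
#' @return rate constant ln(2) / halfLife (s^-1).
#' @examples
#' halfLifeToRate(3600)   # ~1.925e-4 s^-1
#' @export
halfLifeToRate <- function(halfLife) {
  if (!is.numeric(halfLife) || halfLife <= 0)
    stop("halfLife must be > 0")
  log(2) / halfLife
}

#' Construct an intervention
#'
#' @param label description of the intervention.
#' @param initialOverrides named numeric, species name -> new integer count.
#' @param rateOverrides named numeric, rate-constant name -> new value
#'   (0 allowed, switching the reaction off).
#' @return an [Intervention-class].
#' @examples
#' intervention("miR-140 null",
#'   initialOverrides = c(miR140 = 0),
#'   rateOverrides = c(k_synmiR140 = 0))
#' @export
intervention <- function(label = "intervention",
                         initialOverrides = numeric(0),
                         rateOverrides = numeric(0)) {
  if (!length(initialOverrides))
    initialOverrides <- setNames(numeric(0), character(0))
  if (!length(rateOverrides))
    rateOverrides <- setNames(numeric(0), character(0))
  new("Intervention", label = label,
      initialOverrides = initialOverrides, rateOverrides = rateOverrides)
}

#' Apply an intervention to a model
#'
#' Returns a new model with the overridden initial counts and rate constants;
#' the input model is unchanged and all non-overridden entries are identical.
#' A rate override of exactly 0 removes the affected reactions (a switched-off
#' synthesis), keeping the positivity invariant of stored rate constants.
#'
#' @param model a [KineticModel-class].
#' @param iv an [Intervention-class].
#' @return a new [KineticModel-class].
#' @export
applyIntervention <- function(model, iv) {
  stopifnot(is(model, "KineticModel"), is(iv, "Intervention"))
  validObject(iv)
  unknown_sp <- setdiff(names(iv@initialOverrides), model@species$name)
  if (length(unknown_sp))
    stop("unknown species in intervention: ", paste(unknown_sp, collapse = ", "))
  unknown_k <- setdiff(names(iv@rateOverrides), names(model@rates))
  if (length(unknown_k))
    stop("unknown rate constant in intervention: ",
         paste(unknown_k, collapse = ", "))
  species <- model@species
  idx <- match(names(iv@initialOverrides), species$name)
  species$initial[idx] <- unname(iv@initialOverrides)
  rates <- model@rates
  rates[names(iv@rateOverrides)] <- unname(iv@rateOverrides)
  reactions <- model@reactions
  zero <- names(rates)[rates == 0]
  if (length(zero)) {
    keep <- !vapply(reactions, function(rx) rx$rate %in% zero, logical(1))
    reactions <- reactions[keep]
    rates <- rates[!(names(rates) %in% zero)]
  }
  buildModel(model@name, species, reactions, rates,
             notes = paste0(model@notes,
                            if (nzchar(model@notes)) " | " else "",
                            "intervention: ", iv@label))
}

#' Define a behavioural calibration constraint
#'
#' @param observable species name, or \code{"total:<stem>"} to sum free and
#'   complexed forms (all species whose name contains the stem).
#' @param statistic one of \code{"value_at_time"}, \code{"fold_change_at_time"},
#'   \code{"peak_time"}, \code{"return_to_basal_time"}.
#' @param time time (seconds) at which the statistic is read
#'   (for peak/return statistics, the simulation horizon).
#' @param target target value of the statistic.
#' @param tolerance relative tolerance (> 0), e.g. 0.2 for +/- 20\%.
#' @param baseline reference for fold changes and return-to-basal; defaults
#'   to the observable's value at t = 0.
#' @return constraint record (list).
#' @export
calibrationConstraint <- function(observable, statistic, time, target,
                                  tolerance, baseline = NULL) {
  statistic <- match.arg(statistic, c("value_at_time", "fold_change_at_time",
                                      "peak_time", "return_to_basal_time"))
  if (tolerance <= 0) stop("tolerance must be > 0")
  list(observable = observable, statistic = statistic, time = time,
       target = target, tolerance = tolerance, baseline = baseline)
}

.constraintStatistic <- function(traj, con) {
  tt <- traj@times
  y <- observableTrace(traj, con$observable)
  switch(con$statistic,
    value_at_time = y[which.min(abs(tt - con$time))],
    fold_change_at_time = {
      base <- if (is.null(con$baseline)) y[1] else con$baseline
      if (base <= 0) stop("fold change undefined: zero baseline")
      y[which.min(abs(tt - con$time))] / base
    },
    peak_time = tt[which.max(y)],
    return_to_basal_time = {
      base <- if (is.null(con$baseline)) y[1] else con$baseline
      .returnToBasal(tt, y, base, 0.1)$time
    })
}

.constraintResiduals <- function(model, constraints, duration, nPoints = 400) {
  traj <- simulateODE(model, duration = duration, nPoints = nPoints)
  vapply(constraints, function(con) {
    achieved <- .constraintStatistic(traj, con)
    (achieved - con$target) / abs(con$target)
  }, numeric(1))
}

#' Calibrate free rate constants against behavioural constraints
#'
#' Bounded search over the named free parameters: log-uniform sampling of
#' candidate points followed by Nelder-Mead refinement in log-parameter
#' space, minimising the sum of squared relative residuals of the
#' deterministic (ODE) statistics. Succeeds when every constraint is met
#' within its tolerance.
#'
#' @param model a [KineticModel-class].
#' @param constraints list of [calibrationConstraint()] records.
#' @param freeParams character vector of rate-constant names to calibrate.
#' @param lower,upper named (or recycled) positive bounds for the free
#'   parameters.
#' @param seed integer seed for the sampling stage.
#' @param nSamples number of log-uniform candidate points.
#' @param duration simulation horizon (seconds); defaults to 1.2x the latest
#'   constraint time.
#' @return the calibrated model, with the achieved statistic per constraint
#'   attached as attribute \code{"calibration"}.
#' @export
calibrateModel <- function(model, constraints, freeParams, lower, upper,
                           seed = 1L, nSamples = 60L, duration = NULL) {
  stopifnot(is(model, "KineticModel"), length(freeParams) >= 1L)
  if (!all(freeParams %in% names(model@rates)))
    stop("freeParams must name existing rate constants")
  lower <- rep_len(lower, length(freeParams))
  upper <- rep_len(upper, length(freeParams))
  if (any(lower <= 0) || any(upper <= lower))
    stop("bounds must satisfy 0 < lower < upper")
  if (is.null(duration))
    duration <- 1.2 * max(vapply(constraints, `[[`, numeric(1), "time"))

  tolvec <- vapply(constraints, `[[`, numeric(1), "tolerance")
  withParams <- function(theta) {
    m <- model
    m@rates[freeParams] <- theta
    m
  }
  objective <- function(logTheta) {
    res <- tryCatch(
      .constraintResiduals(withParams(exp(logTheta)), constraints, duration),
      error = function(e) rep(1e6, length(constraints)))
    sum(res^2)
  }

  # a parameter set already satisfying every constraint is returned as-is
  res0 <- tryCatch(.constraintResiduals(model, constraints, duration),
                   error = function(e) rep(Inf, length(constraints)))
  if (all(abs(res0) <= tolvec)) {
    attr(model, "calibration") <- data.frame(
      statistic = vapply(constraints, `[[`, character(1), "statistic"),
      target = vapply(constraints, `[[`, numeric(1), "target"),
      relative_residual = res0)
    return(model)
  }

  set.seed(seed)
  cand <- matrix(runif(nSamples * length(freeParams)), nSamples)
  logL <- log(lower); logU <- log(upper)
  cand <- sweep(sweep(cand, 2, logU - logL, "*"), 2, logL, "+")
  cand <- rbind(log(unname(model@rates[freeParams])), cand)
  scores <- apply(cand, 1, objective)
  best <- cand[which.min(scores), , drop = TRUE]
  opt <- if (length(freeParams) == 1L)
    optim(best, objective, method = "Brent", lower = logL, upper = logU,
          control = list(maxit = 200))
  else
    optim(best, objective, method = "Nelder-Mead",
          control = list(maxit = 200, reltol = 1e-8))
  theta <- pmin(pmax(exp(opt$par), lower), upper)
  fitted <- withParams(theta)
  res <- .constraintResiduals(fitted, constraints, duration)
  report <- data.frame(
    statistic = vapply(constraints, `[[`, character(1), "statistic"),
    target = vapply(constraints, `[[`, numeric(1), "target"),
    relative_residual = res,
    tolerance = tolvec)
  if (!all(abs(res) <= tolvec)) {
    stop("calibration failed; best residuals:\n",
         paste(utils::capture.output(print(report)), collapse = "\n"))
  }
  attr(fitted, "calibration") <- report
  fitted
}
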