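#' @useDynLib mir140sim, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Compile a KineticModel into flat index tables for the simulation kernels.
.compileModel <- function(model) {
  validObject(model)
  sp <- model@species$name
  S <- length(sp)
  R <- length(model@reactions)
  stoich <- matrix(0L, S, R, dimnames = list(sp, NULL))
  r1 <- integer(R); r2 <- integer(R); homo <- logical(R); rate <- numeric(R)
  for (j in seq_len(R)) {
    rx <- model@reactions[[j]]
    ri <- match(rx$reactants, sp)
    pi <- match(rx$products, sp)
    for (i in ri) stoich[i, j] <- stoich[i, j] - 1L
    for (i in pi) stoich[i, j] <- stoich[i, j] + 1L
    r1[j] <- if (length(ri) >= 1L) ri[1] - 1L else -1L
    r2[j] <- if (length(ri) == 2L) ri[2] - 1L else -1L
    homo[j] <- length(ri) == 2L && ri[1] == ri[2]
    rate[j] <- model@rates[[rx$rate]]
  }
  list(x0 = setNames(as.numeric(model@species$initial), sp),
       stoich = stoich, r1 = r1, r2 = r2, homo = homo, rate = rate,
       species = sp)
}

#' Propensity of a single mass-action reaction
#'
#' Order 0 gives k; order 1 gives k*x; a heterodimer reaction gives k*x*y;
#' a homodimer (self-interaction) gives k*x*(x-1)/2.
#'
#' @param reaction a [reactionSpec()] record.
#' @param state named numeric vector of current copy numbers (>= 0).
#' @param rates named numeric vector supplying the reaction's rate constant.
#' @return non-negative propensity (s^-1).
#' @examples
#' propensity(reactionSpec("miR140", character(0), "k"), c(miR140 = 0), c(k = 0.0018))
#' @export
propensity <- function(reaction, state, rates) {
  if (any(state < 0)) stop("state counts must be >= 0")
  k <- rates[[reaction$rate]]
  r <- reaction$reactants
  if (length(r) == 0L) return(k)
  if (length(r) == 1L) return(k * state[[r]])
  if (r[1] == r[2]) return(k * state[[r[1]]] * (state[[r[1]]] - 1) / 2)
  k * state[[r[1]]] * state[[r[2]]]
}

#' Exact stochastic simulation (Gillespie direct method)
#'
#' Simulates every reaction event: waiting times are exponential with rate
#' equal to the total propensity and the firing reaction is chosen with
#' probability proportional to its propensity. The state is recorded on a
#' uniform grid of \code{nIntervals + 1} reporting times. The same
#' (model, duration, seed) triple yields a bit-identical trajectory.
#'
#' @param model a [KineticModel-class].
#' @param duration virtual time in seconds, > 0.
#' @param nIntervals number of reporting intervals (default 1000).
#' @param seed integer seed.
#' @return a stochastic [Trajectory-class].
#' @examples
#' m <- buildModel("bd", rbind(speciesSpec("A", 100)),
#'   list(reactionSpec("A", character(0), "k_deg")), c(k_deg = 1e-3))
#' tr <- simulateSSA(m, duration = 693, seed = 1)
#' @export
simulateSSA <- function(model, duration, nIntervals = 1000L, seed = 1L) {
  if (duration <= 0) stop("duration must be > 0")
  if (nIntervals < 1L) stop("nIntervals must be >= 1")
  cm <- .compileModel(model)
  grid <- seq(0, duration, length.out = nIntervals + 1L)
  set.seed(as.integer(seed))
  counts <- ssa_run_cpp(cm$x0, cm$stoich, cm$r1, cm$r2, cm$homo, cm$rate, grid)
  colnames(counts) <- cm$species
  new("Trajectory", times = grid, counts = counts,
      seed = as.integer(seed), stochastic = TRUE)
}

#' Ensemble of stochastic replicates with mean and 95\% confidence interval
#'
#' Runs \code{nReps} independent replicates with per-replicate seeds derived
#' deterministically from \code{baseSeed} (baseSeed + replicate index) and
#' summarises each species at each grid time by the replicate mean and the
#' Student-t 95\% confidence interval of the mean.
#'
#' @param model a [KineticModel-class].
#' @param nReps number of replicates, >= 2.
#' @param duration,nIntervals as in [simulateSSA()].
#' @param baseSeed integer base seed.
#' @param keepTrajectories if TRUE the replicate trajectories are attached
#'   as attribute \code{"trajectories"}.
#' @return an [EnsembleSummary-class].
#' @export
runEnsemble <- function(model, nReps = 100L, duration, nIntervals = 1000L,
                        baseSeed = 1L, keepTrajectories = FALSE) {
  if (nReps < 2L) stop("nReps must be >= 2 to form a confidence interval")
  seeds <- as.integer(baseSeed) + seq_len(nReps) - 1L
  cm <- .compileModel(model)
  grid <- seq(0, duration, length.out = nIntervals + 1L)
  G <- length(grid); S <- length(cm$species)
  sumx <- matrix(0, G, S); sumx2 <- matrix(0, G, S)
  trajs <- if (keepTrajectories) vector("list", nReps) else NULL
  for (r in seq_len(nReps)) {
    set.seed(seeds[r])
    counts <- ssa_run_cpp(cm$x0, cm$stoich, cm$r1, cm$r2, cm$homo, cm$rate, grid)
    sumx <- sumx + counts
    sumx2 <- sumx2 + counts^2
    if (keepTrajectories) {
      colnames(counts) <- cm$species
      trajs[[r]] <- new("Trajectory", times = grid, counts = counts,
                        seed = seeds[r], stochastic = TRUE)
    }
  }
  mu <- sumx / nReps
  # unbiased variance; guard tiny negatives from cancellation
  v <- pmax((sumx2 - nReps * mu^2) / (nReps - 1), 0)
  half <- qt(0.975, df = nReps - 1L) * sqrt(v / nReps)
  dimnames(mu) <- list(NULL, cm$species)
  out <- new("EnsembleSummary", times = grid, mean = mu,
             ciLower = mu - half, ciUpper = mu + half,
             nReps = as.integer(nReps), seeds = seeds)
  if (keepTrajectories) attr(out, "trajectories") <- trajs
  out
}

#' Deterministic simulation of the mass-action rate equations
#'
#' Integrates the deterministic counterparts of the stochastic propensities
#' (homodimer term k*x^2/2) with the LSODA stiff/non-stiff switching solver.
#' Default tolerances: relative 1e-6, absolute 1e-13, at most 10000 internal
#' steps.
#'
#' @param model a [KineticModel-class].
#' @param duration virtual time in seconds, > 0.
#' @param nPoints number of reporting intervals (default 1000).
#' @param settings an [OdeSettings-class].
#' @return a real-valued deterministic [Trajectory-class]. Concentrations
#'   more negative than the absolute tolerance trigger a warning; reported
#'   values are clipped at 0.
#' @export
simulateODE <- function(model, duration, nPoints = 1000L,
                        settings = odeSettings()) {
  if (duration <= 0) stop("duration must be > 0")
  validObject(settings)
  cm <- .compileModel(model)
  grid <- seq(0, duration, length.out = nPoints + 1L)
  o1 <- which(cm$r1 >= 0 & cm$r2 < 0)
  o2h <- which(cm$r2 >= 0 & !cm$homo)
  o2s <- which(cm$r2 >= 0 & cm$homo)
  i1 <- cm$r1 + 1L; i2 <- cm$r2 + 1L
  k <- cm$rate; St <- cm$stoich
  deriv <- function(t, x, parms) {
    a <- k
    a[o1] <- a[o1] * x[i1[o1]]
    a[o2h] <- a[o2h] * x[i1[o2h]] * x[i2[o2h]]
    a[o2s] <- a[o2s] * x[i1[o2s]]^2 / 2
    list(as.vector(St %*% a))
  }
  sol <- deSolve::lsoda(y = cm$x0, times = grid, func = deriv, parms = NULL,
                        rtol = settings@relTol, atol = settings@absTol,
                        maxsteps = settings@maxInternalSteps)
  if (attr(sol, "istate")[1] < 0)
    stop("ODE integrator failure: ",
         paste(attr(sol, "istate"), collapse = " "))
  counts <- unname(sol[, -1, drop = FALSE])
  colnames(counts) <- cm$species
  if (any(counts < -settings@absTol))
    warning("negative concentrations beyond absTol; clipped for reporting")
  counts[counts < 0] <- 0
  new("Trajectory", times = grid, counts = counts,
      seed = NA_integer_, stochastic = FALSE)
}

#' Export a trajectory or ensemble to tidy long-format data
#'
#' @param object a [Trajectory-class] or [EnsembleSummary-class].
#' @param file optional path; when given, written as CSV.
#' @return a data.frame in long format: \code{time, species, value} for a
#'   trajectory; \code{time, species, mean, ci_lo, ci_hi} for an ensemble.
#' @export
asTidyFrame <- function(object, file = NULL) {
  if (is(object, "Trajectory")) {
    df <- data.frame(
      time = rep(object@times, times = ncol(object@counts)),
      species = rep(colnames(object@counts), each = length(object@times)),
      value = as.vector(object@counts))
  } else if (is(object, "EnsembleSummary")) {
    df <- data.frame(
      time = rep(object@times, times = ncol(object@mean)),
      species = rep(colnames(object@mean), each = length(object@times)),
      mean = as.vector(object@mean),
      ci_lo = as.vector(object@ciLower),
      ci_hi = as.vector(object@ciUpper))
  } else stop("object must be a Trajectory or EnsembleSummary")
  if (!is.null(file)) write.csv(df, file, row.names = FALSE)
  df
}
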