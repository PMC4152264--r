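#' Construct a simulation configuration
#'
#' Convenience constructor for \code{\link{BDConfig-class}}; any slot can be
#' set by name, the rest keep their defaults (406 A box, dt = 0.01 ns, save
#' every 10 ns, T = 298.15 K, eta = 0.891 mPa s, HI and repulsion enabled,
#' k_s = 0.06, k_b = 0.006, k_r = 0.1 kcal/mol with the E = k x^2
#' convention).
#'
#' @param ... named slot values, e.g. \code{bdConfig(nSteps = 1e5,
#'   hydrodynamics = FALSE)}.
#' @return a validated \code{BDConfig} object.
#' @export
bdConfig <- function(...) {
  new("BDConfig", ...)
}

# Boltzmann constant, kcal/mol/K
.kB <- 0.0019872041

#' Stokes-Einstein dilute-limit diffusion coefficient
#'
#' \eqn{D^0 = k_B T / (6 \pi \eta a)} for a sphere of radius \code{a}.
#' With radius in Angstrom, temperature in K and viscosity in mPa s, the
#' result is in A^2/ns (1 A^2/ns = 10 um^2/s).
#'
#' @param radius sphere radius, Angstrom (vectorized).
#' @param temperature K.
#' @param viscosity mPa s.
#' @return D0 in A^2/ns.
#' @export
#' @examples
#' stokesEinsteinD0(19.6, temperature = 293, viscosity = 1.0)  # ~10.95 A^2/ns
stokesEinsteinD0 <- function(radius, temperature = 298.15, viscosity = 0.891) {
  if (any(radius <= 0) || temperature <= 0 || viscosity <= 0)
    stop("radius, temperature and viscosity must be > 0")
  kB_J <- 1.380649e-23                    # J/K
  D_m2s <- kB_J * temperature / (6 * pi * viscosity * 1e-3 * radius * 1e-10)
  D_m2s * 1e11                            # m^2/s -> A^2/ns
}

#' Unit conversion between A^2/ns and um^2/s
#'
#' 1 A^2/ns = 1e-20 m^2 / 1e-9 s = 1e-11 m^2/s = 10 um^2/s.
#'
#' @param x value(s) to convert.
#' @return converted value(s).
#' @export
A2ns_to_um2s <- function(x) 10 * x
#' @rdname A2ns_to_um2s
#' @export
um2s_to_A2ns <- function(x) x / 10

.fill_D0 <- function(state, config) {
  if (length(state@D0)) state@D0 else
    stokesEinsteinD0(state@radii, config@temperature, config@viscosity)
}

#' Run a Brownian-dynamics simulation
#'
#' Propagates the system with the overdamped Ermak-McCammon update
#' \deqn{r_i^{n+1} = r_i^n + \frac{D_i^n \Delta t}{k_B T} F_i^n + R_i^n}
#' where \eqn{R_i^n} has independent Gaussian components of zero mean and
#' variance \eqn{2 D_i^n \Delta t}. Per step, in order: neighbor lists are
#' refreshed if stale, local volume fractions and effective D are evaluated
#' at the current positions (when HI is enabled), forces are evaluated at the
#' current positions, then all mobile spheres move. The divergence term for
#' position-dependent D is omitted, matching the explicit scheme the model
#' defines. Noise draws are taken for every sphere in a fixed order whether
#' or not it is frozen and independent of the HI toggle, so a given seed
#' yields the same random stream under every control setting.
#'
#' Positions are integrated unwrapped; wrapped coordinates and image counters
#' are available from the returned frames via \code{\link{minImage}} /
#' modular arithmetic. The run aborts with a diagnostic if any single-step
#' displacement exceeds a stability bound (non-finite forces or a blow-up).
#'
#' @param state a \code{\link{SystemState-class}}; its \code{D0} slot is
#'   filled from Stokes-Einstein at the configured temperature/viscosity if
#'   empty.
#' @param config a \code{\link{BDConfig-class}}; \code{config@seed} seeds the
#'   trajectory RNG.
#' @param noiseScale multiplies the random-displacement standard deviation;
#'   0 gives the deterministic drift limit (used in tests).
#' @param recordPhi record per-sphere local volume fractions at frame times.
#' @param verbose print progress (time, energy, max phi) every 10\% of steps.
#' @return a \code{\link{BDTrajectory-class}}; frame count is
#'   \code{nSteps*dt/saveInterval + 1} (frame 0 is the initial state).
#' @export
runSimulation <- function(state, config = bdConfig(), noiseScale = 1,
                          recordPhi = FALSE, verbose = FALSE) {
  validObject(config)
  validObject(state)
  if (config@boxLength != state@boxLength)
    stop("state and config disagree on boxLength")
  if (nSpheres(state) > 0 && config@hydrodynamics &&
      config@boxLength <= 2 * config@rcutMultiplier * max(state@radii))
    stop("box too small: the local-volume cutoff must fit within half the box")
  D0 <- .fill_D0(state, config)
  saveEvery <- as.integer(round(config@saveInterval / config@dt))
  nSteps <- as.integer(config@nSteps)
  if (nSteps %% saveEvery != 0)
    stop("nSteps must be a multiple of saveInterval/dt")
  tp <- .state_topology_args(state)
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(as.integer(config@seed))
  res <- cpp_run_bd(state@positions, state@radii, as.integer(state@molecule),
                    state@frozen, D0, tp$bonds, tp$bondL0, tp$angles,
                    tp$angleTheta0, state@boxLength, config@dt, nSteps,
                    saveEvery, .kB * config@temperature, config@kStretch,
                    config@kBend, config@kRepulse, config@repulsion,
                    config@hydrodynamics, config@rcutMultiplier,
                    config@includeSelf, config@phiMax, config@skin,
                    noiseScale, recordPhi, 1e-8, isTRUE(verbose))
  cfg <- .config_as_list(config)
  cfg$maxPhiSeen <- res$maxPhi
  if (config@hydrodynamics && res$maxPhi > config@phiMax)
    message(sprintf(
      "local volume fraction reached %.3f and was clamped at %.2f for the Tokuyama rescaling",
      res$maxPhi, config@phiMax))
  en <- res$energies
  colnames(en) <- c("stretch", "bend", "repulsion")
  new("BDTrajectory", times = as.numeric(res$times), frames = res$frames,
      molecule = state@molecule, proteinId = state@proteinId,
      radii = state@radii, config = cfg, energies = en,
      phi = if (!is.null(res$phiFrames)) res$phiFrames else matrix(numeric(), 0, 0))
}

.config_as_list <- function(config) {
  nm <- slotNames(config)
  out <- lapply(nm, function(s) slot(config, s))
  names(out) <- nm
  out
}

#' Advance the system by a single BD step
#'
#' One Ermak-McCammon update of the state (same scheme as
#' \code{\link{runSimulation}}); mainly useful for stepwise inspection and
#' for checking the deterministic drift limit with \code{noiseScale = 0}.
#'
#' @inheritParams runSimulation
#' @return the updated \code{\link{SystemState-class}} (positions unwrapped).
#' @export
bdStep <- function(state, config = bdConfig(), noiseScale = 1) {
  cfg <- config
  cfg@nSteps <- 1
  cfg@saveInterval <- cfg@dt
  traj <- runSimulation(state, cfg, noiseScale = noiseScale)
  state@positions <- frames(traj)[2, , , drop = TRUE]
  if (nSpheres(state) == 1L) state@positions <- matrix(state@positions, 1, 3)
  state@D0 <- .fill_D0(state, config)
  state
}

#' Freeze all molecules except the chosen tracers
#'
#' Marks every sphere outside the tracer molecules as frozen: frozen spheres
#' still exert forces and contribute to local volume fractions but do not
#' move. Used for the immobile-crowder control.
#'
#' @param state a \code{\link{SystemState-class}}.
#' @param tracerIds protein identifiers or molecule indices to keep mobile.
#' @return the state with updated frozen flags.
#' @export
freezeCrowders <- function(state, tracerIds) {
  if (is.character(tracerIds)) {
    unknown <- setdiff(tracerIds, unique(state@proteinId))
    if (length(unknown)) stop("unknown protein id: ", paste(unknown, collapse = ", "))
    keep <- state@proteinId %in% tracerIds
  } else {
    unknown <- setdiff(tracerIds, unique(state@molecule))
    if (length(unknown)) stop("unknown molecule index: ", paste(unknown, collapse = ", "))
    keep <- state@molecule %in% tracerIds
  }
  state@frozen <- !keep
  state
}
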