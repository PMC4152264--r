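#' @useDynLib crowdbd, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
#' @importFrom stats kmeans lm coef rnorm runif uniroot fft sd ks.test
#' @importFrom utils read.table write.table head
NULL

#' Coarse-grained protein model
#'
#' A protein represented by 1--5 spheres obtained from k-means clustering of
#' its C-alpha coordinates (or built synthetically). Sphere centers are in a
#' reference (local) frame; bonds connect every unordered sphere pair with
#' equilibrium length equal to the reference distance, and angles cover every
#' vertex-distinct triple with equilibrium value taken from the reference
#' geometry.
#'
#' @slot proteinId single identifier string.
#' @slot centers numeric matrix (n x 3), sphere centers, Angstrom.
#' @slot radii numeric vector of sphere radii, Angstrom.
#' @slot bonds integer matrix (m x 2) of 1-based sphere indices, one row per
#'   unordered pair.
#' @slot bondLengths equilibrium bond lengths, Angstrom.
#' @slot angles integer matrix (q x 3); columns are (i, vertex, k).
#' @slot angleValues equilibrium angles, radians.
#' @slot molecularWeight kDa.
#' @slot copyNumber copies of this protein in the box.
#' @slot tracer logical; marks the tracer species (e.g. the single GFP copy).
#'
#' @exportClass CGProtein
setClass("CGProtein",
  representation(
    proteinId = "character",
    centers = "matrix",
    radii = "numeric",
    bonds = "matrix",
    bondLengths = "numeric",
    angles = "matrix",
    angleValues = "numeric",
    molecularWeight = "numeric",
    copyNumber = "integer",
    tracer = "logical"
  ),
  prototype(copyNumber = 1L, tracer = FALSE, molecularWeight = NA_real_)
)

setValidity("CGProtein", function(object) {
  n <- nrow(object@centers)
  msg <- character()
  if (length(object@proteinId) != 1L) msg <- c(msg, "proteinId must be a single string")
  if (ncol(object@centers) != 3L) msg <- c(msg, "centers must be n x 3")
  if (n < 1L || n > 5L) msg <- c(msg, "sphere count must be in 1..5")
  if (length(object@radii) != n) msg <- c(msg, "radii length must match centers")
  if (any(object@radii <= 0)) msg <- c(msg, "all radii must be > 0")
  if (nrow(object@bonds) != n * (n - 1L) / 2L)
    msg <- c(msg, "bonds must list every unordered sphere pair exactly once")
  if (nrow(object@bonds) > 0L) {
    key <- paste(pmin(object@bonds[, 1], object@bonds[, 2]),
                 pmax(object@bonds[, 1], object@bonds[, 2]))
    if (anyDuplicated(key)) msg <- c(msg, "duplicate bond")
    d <- sqrt(rowSums((object@centers[object@bonds[, 1], , drop = FALSE] -
                       object@centers[object@bonds[, 2], , drop = FALSE])^2))
    if (any(abs(d - object@bondLengths) > 1e-6 * pmax(1, d)))
      msg <- c(msg, "equilibrium bond lengths must equal reference distances")
  }
  if (length(object@bondLengths) != nrow(object@bonds))
    msg <- c(msg, "bondLengths length must match bonds")
  if (length(object@angleValues) != nrow(object@angles))
    msg <- c(msg, "angleValues length must match angles")
  if (length(object@copyNumber) != 1L || object@copyNumber < 1L)
    msg <- c(msg, "copyNumber must be a positive integer")
  if (length(msg)) msg else TRUE
})

#' Periodic simulation box state
#'
#' Positions are stored unwrapped (continuous across boundary crossings);
#' wrapped coordinates in [0, L) and integer image counters are derived by
#' \code{\link{wrappedPositions}} and \code{\link{imageCounts}}.
#'
#' @slot boxLength cubic box edge, Angstrom.
#' @slot positions numeric matrix (N x 3), unwrapped sphere centers, Angstrom.
#' @slot radii sphere radii, Angstrom.
#' @slot molecule integer molecule index per sphere (1-based).
#' @slot proteinId protein identifier per sphere.
#' @slot D0 per-sphere dilute-limit diffusion coefficient, A^2/ns (may be
#'   empty; then filled from Stokes-Einstein at simulation time).
#' @slot frozen logical per sphere; frozen spheres exert forces and occupy
#'   volume but do not move.
#' @slot bonds,bondLengths,angles,angleValues global bonded topology over all
#'   spheres (1-based indices into the position matrix).
#'
#' @exportClass SystemState
setClass("SystemState",
  representation(
    boxLength = "numeric",
    positions = "matrix",
    radii = "numeric",
    molecule = "integer",
    proteinId = "character",
    D0 = "numeric",
    frozen = "logical",
    bonds = "matrix",
    bondLengths = "numeric",
    angles = "matrix",
    angleValues = "numeric"
  ),
  prototype(D0 = numeric())
)

setValidity("SystemState", function(object) {
  N <- nrow(object@positions)
  msg <- character()
  if (length(object@boxLength) != 1L || object@boxLength <= 0)
    msg <- c(msg, "boxLength must be a single positive number")
  if (ncol(object@positions) != 3L) msg <- c(msg, "positions must be N x 3")
  if (length(object@radii) != N) msg <- c(msg, "radii length must be N")
  if (N > 0 && any(object@radii <= 0)) msg <- c(msg, "radii must be > 0")
  if (length(object@molecule) != N) msg <- c(msg, "molecule length must be N")
  if (length(object@frozen) != N) msg <- c(msg, "frozen length must be N")
  if (!(length(object@D0) %in% c(0L, N))) msg <- c(msg, "D0 must be empty or length N")
  if (nrow(object@bonds) > 0 && max(object@bonds) > N) msg <- c(msg, "bond index out of range")
  if (nrow(object@angles) > 0 && max(object@angles) > N) msg <- c(msg, "angle index out of range")
  if (length(msg)) msg else TRUE
})

#' Simulation configuration
#'
#' Physical constants, force-field parameters, mean-field hydrodynamics
#' settings and run control for \code{\link{runSimulation}}. Harmonic terms
#' use the convention E = k x^2 (no 1/2 prefactor), so the default constants
#' (0.06, 0.006, 0.1) are tied to that convention.
#'
#' @slot boxLength box edge, Angstrom (default 406).
#' @slot dt time step, ns (default 0.01).
#' @slot nSteps number of BD steps.
#' @slot saveInterval trajectory save interval, ns; must be an integer
#'   multiple of \code{dt} (default 10; use 1 or less for displacement
#'   autocorrelation analyses).
#' @slot temperature K (default 298.15).
#' @slot viscosity solvent viscosity, mPa s (default 0.891, water at 25 C).
#' @slot seed RNG seed for the trajectory.
#' @slot hydrodynamics enable mean-field HI rescaling of D.
#' @slot repulsion enable inter-protein harmonic repulsion.
#' @slot kStretch kcal/mol/A^2 (default 0.06).
#' @slot kBend kcal/mol/rad^2 (default 0.006).
#' @slot kRepulse kcal/mol/A^2 (default 0.1).
#' @slot rcutMultiplier local-volume cutoff as a multiple of the sphere
#'   radius (default 4).
#' @slot includeSelf include the sphere's own volume in its local volume
#'   fraction (default TRUE, following the printed local-fraction definition).
#' @slot phiMax clamp on the local volume fraction (default 0.63, near random
#'   close packing; the Tokuyama function diverges at phi = 8/9).
#' @slot skin Verlet-list skin, Angstrom (default 10).
#'
#' @exportClass BDConfig
setClass("BDConfig",
  representation(
    boxLength = "numeric", dt = "numeric", nSteps = "numeric",
    saveInterval = "numeric", temperature = "numeric", viscosity = "numeric",
    seed = "numeric", hydrodynamics = "logical", repulsion = "logical",
    kStretch = "numeric", kBend = "numeric", kRepulse = "numeric",
    rcutMultiplier = "numeric", includeSelf = "logical", phiMax = "numeric",
    skin = "numeric"
  ),
  prototype(
    boxLength = 406, dt = 0.01, nSteps = 1000, saveInterval = 10,
    temperature = 298.15, viscosity = 0.891, seed = 1,
    hydrodynamics = TRUE, repulsion = TRUE,
    kStretch = 0.06, kBend = 0.006, kRepulse = 0.1,
    rcutMultiplier = 4, includeSelf = TRUE, phiMax = 0.63, skin = 10
  )
)

setValidity("BDConfig", function(object) {
  msg <- character()
  if (object@dt <= 0) msg <- c(msg, "dt must be > 0")
  k <- object@saveInterval / object@dt
  if (abs(k - round(k)) > 1e-9) msg <- c(msg, "saveInterval must be an integer multiple of dt")
  if (object@nSteps < 0) msg <- c(msg, "nSteps must be >= 0")
  if (object@boxLength <= 0) msg <- c(msg, "boxLength must be > 0")
  if (object@temperature <= 0 || object@viscosity <= 0)
    msg <- c(msg, "temperature and viscosity must be > 0")
  if (any(c(object@kStretch, object@kBend, object@kRepulse) < 0))
    msg <- c(msg, "force constants must be >= 0")
  if (object@rcutMultiplier <= 1) msg <- c(msg, "rcutMultiplier must be > 1")
  if (object@phiMax <= 0 || object@phiMax >= 1) msg <- c(msg, "phiMax must be in (0, 1)")
  if (object@skin <= 0) msg <- c(msg, "skin must be > 0")
  if (length(msg)) msg else TRUE
})

#' Brownian-dynamics trajectory
#'
#' Frames of unwrapped sphere positions at a fixed save interval, plus the
#' configuration echo needed to interpret them.
#'
#' @slot times frame times, ns.
#' @slot frames numeric array (frames x spheres x 3), unwrapped, Angstrom.
#' @slot molecule molecule index per sphere.
#' @slot proteinId protein id per sphere.
#' @slot radii sphere radii, Angstrom.
#' @slot config list echo of the \code{BDConfig} used.
#' @slot energies matrix (frames x 3): stretch, bend, repulsion energies,
#'   kcal/mol.
#' @slot phi matrix of per-sphere local volume fractions at frame times (only
#'   when recorded), else a 0 x 0 matrix.
#'
#' @exportClass BDTrajectory
setClass("BDTrajectory",
  representation(
    times = "numeric", frames = "array", molecule = "integer",
    proteinId = "character", radii = "numeric", config = "list",
    energies = "matrix", phi = "matrix"
  ),
  prototype(phi = matrix(numeric(), 0, 0))
)

setValidity("BDTrajectory", function(object) {
  d <- dim(object@frames)
  msg <- character()
  if (length(d) != 3L || d[3] != 3L) msg <- c(msg, "frames must be T x N x 3")
  if (length(object@times) != d[1]) msg <- c(msg, "times length must match frames")
  if (length(object@radii) != d[2]) msg <- c(msg, "radii length must match frames")
  if (length(object@times) > 1) {
    dtv <- diff(object@times)
    if (max(abs(dtv - dtv[1])) > 1e-9 * max(1, dtv[1]))
      msg <- c(msg, "frame spacing must be uniform")
  }
  if (length(msg)) msg else TRUE
})
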