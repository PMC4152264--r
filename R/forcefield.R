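#' Minimum-image displacement
#'
#' Maps each displacement component into \code{[-L/2, L/2)} (the lower edge
#' is closed, the upper open).
#'
#' @param d numeric vector or matrix of displacement components, Angstrom.
#' @param boxLength box edge, Angstrom.
#' @return object of the same shape as \code{d}.
#' @export
#' @examples
#' minImage(c(0, 6, -5), 10)
minImage <- function(d, boxLength) {
  if (boxLength <= 0) stop("boxLength must be > 0")
  d - boxLength * floor(d / boxLength + 0.5)
}

.state_topology_args <- function(state) {
  list(
    bonds = matrix(as.integer(state@bonds - 1L), ncol = 2),
    bondL0 = state@bondLengths,
    angles = matrix(as.integer(state@angles - 1L), ncol = 3),
    angleTheta0 = state@angleValues
  )
}

.energy_forces <- function(state, config, doStretch, doBend, doRep) {
  tp <- .state_topology_args(state)
  res <- cpp_energy_forces(state@positions, state@radii,
                           as.integer(state@molecule), tp$bonds, tp$bondL0,
                           tp$angles, tp$angleTheta0, state@boxLength,
                           config@kStretch, config@kBend, config@kRepulse,
                           doStretch, doBend, doRep, 1e-8)
  list(energies = c(stretch = res$E_stretch, bend = res$E_bend,
                    repulsion = res$E_repulsion),
       forces = res$forces)
}

#' Stretching energy and forces
#'
#' Harmonic stretching over every intra-protein bond,
#' \eqn{E_s = \sum_b k_s (l_b - l_b^0)^2} (no 1/2 prefactor), with analytic
#' gradient. Zero at the reference geometry.
#'
#' @param state a \code{\link{SystemState-class}}.
#' @param config a \code{\link{BDConfig-class}} supplying \code{kStretch}.
#' @return list with \code{energies} (named vector, kcal/mol) and
#'   \code{forces} (N x 3, kcal/mol/A).
#' @export
stretchForces <- function(state, config = bdConfig()) {
  .energy_forces(state, config, TRUE, FALSE, FALSE)
}

#' Bending energy and forces
#'
#' Harmonic bending over every vertex-distinct angle triple,
#' \eqn{E_b = \sum_a g (\theta_a - \theta_a^0)^2}. Near-collinear angles are
#' handled by clamping \eqn{\sin\theta} at 1e-8 in the gradient.
#'
#' @inheritParams stretchForces
#' @return as \code{\link{stretchForces}}.
#' @export
bendForces <- function(state, config = bdConfig()) {
  .energy_forces(state, config, FALSE, TRUE, FALSE)
}

#' Inter-protein repulsion energy and forces
#'
#' Harmonic overlap penalty between spheres of different proteins:
#' \eqn{E_r = \sum k_r (\sigma - r)^2} for minimum-image distance
#' \eqn{r < \sigma} (sum of radii), zero otherwise. Intra-protein pairs are
#' excluded regardless of distance.
#'
#' @inheritParams stretchForces
#' @return as \code{\link{stretchForces}}.
#' @export
repulsionForces <- function(state, config = bdConfig()) {
  .energy_forces(state, config, FALSE, FALSE, TRUE)
}

#' Total energy and forces
#'
#' Sum of the stretching, bending and repulsion contributions, honoring the
#' \code{repulsion} toggle in the configuration (the bonded terms can be
#' silenced by zeroing their force constants).
#'
#' @inheritParams stretchForces
#' @return list with per-term \code{energies} (kcal/mol), total \code{forces}
#'   (N x 3, kcal/mol/A) and \code{net} (the force sum over all spheres,
#'   which vanishes by translation invariance).
#' @export
totalForces <- function(state, config = bdConfig()) {
  res <- .energy_forces(state, config, config@kStretch > 0, config@kBend > 0,
                        config@repulsion)
  res$net <- colSums(res$forces)
  res
}
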