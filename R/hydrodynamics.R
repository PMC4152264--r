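#' Intersection volume of a sphere with a cutoff ball
#'
#' Exact volume of a sphere of radius \code{a} whose center lies at distance
#' \code{d} from the center of a ball of radius \code{R}: the full sphere
#' volume when it lies entirely inside (\code{d <= R - a}), zero when
#' entirely outside (\code{d >= R + a}), and the spherical-lens closed form
#' in between. Continuous in \code{d} at both regime boundaries.
#'
#' @param d center-center distance, Angstrom (vectorized).
#' @param R cutoff ball radius, Angstrom.
#' @param a sphere radius, Angstrom.
#' @return intersection volume, Angstrom^3.
#' @export
sphereOverlapVolume <- function(d, R, a) {
  if (any(d < 0) || R <= 0 || a <= 0) stop("d must be >= 0 and R, a > 0")
  vapply(d, cpp_sphere_ball_overlap, numeric(1), R = R, a = a)
}

#' Local volume fraction of every sphere
#'
#' For sphere i, the fraction of the cutoff ball of radius
#' \code{rcutMultiplier * a_i} occupied by sphere volume: the sphere's own
#' volume (when \code{includeSelf}) plus the exact intersection volumes of
#' all neighbors (full volume for those completely inside, the lens overlap
#' for those partially inside), divided by the ball volume, using
#' minimum-image neighbor distances, clamped to \code{[0, phiMax]}. An
#' isolated sphere with self-inclusion has \eqn{\phi = 1/64} at the default
#' cutoff multiplier of 4.
#'
#' @param state a \code{\link{SystemState-class}}.
#' @param config a \code{\link{BDConfig-class}} supplying
#'   \code{rcutMultiplier}, \code{includeSelf} and \code{phiMax}.
#' @return numeric vector of per-sphere volume fractions.
#' @export
localVolumeFraction <- function(state, config = bdConfig()) {
  if (config@rcutMultiplier * max(state@radii) + max(state@radii) >
      state@boxLength / 2)
    warning("cutoff ball reaches beyond half the box; a neighbor could contribute via more than one periodic image")
  cpp_local_phi(state@positions, state@radii, state@boxLength,
                config@rcutMultiplier, config@includeSelf, config@phiMax)
}

#' Tokuyama mean-field hydrodynamic function H(phi)
#'
#' Short-time hard-sphere suspension correction
#' \deqn{H(\phi) = \frac{2 b^2}{1 - b} - \frac{c}{1 + 2c}
#'   - \frac{b c (2 + c)}{(1 + c)(1 - b + c)}}
#' with \eqn{b = \sqrt{9\phi/8}} and \eqn{c = 11\phi/16}. H(0) = 0 and H is
#' strictly increasing; it diverges as \eqn{\phi \to 8/9}, which is why the
#' local volume fraction is clamped upstream.
#'
#' @param phi volume fraction(s) in \code{[0, phiMax]}.
#' @param phiMax admissible upper bound (default 0.63).
#' @return H values, dimensionless.
#' @export
#' @examples
#' tokuyamaH(c(0, 1/64, 0.3))
tokuyamaH <- function(phi, phiMax = 0.63) {
  if (any(!is.finite(phi)) || any(phi < 0) || any(phi > phiMax + 1e-12))
    stop("phi must lie in [0, ", phiMax, "]")
  as.numeric(cpp_tokuyama_H(phi))
}

#' Effective per-sphere diffusion coefficients
#'
#' Mean-field hydrodynamic rescaling of the dilute-limit diffusion
#' coefficient: \eqn{D_i = D_i^0 / (1 + H(\phi_i))} when hydrodynamics are
#' enabled, \eqn{D_i = D_i^0} otherwise (the free-draining control).
#'
#' @param state a \code{\link{SystemState-class}}; if its \code{D0} slot is
#'   empty, dilute-limit values are computed from Stokes-Einstein at the
#'   configuration's temperature and viscosity.
#' @param config a \code{\link{BDConfig-class}}.
#' @return numeric vector of per-sphere D, A^2/ns, each in \code{(0, D0]}.
#' @export
effectiveDiffusion <- function(state, config = bdConfig()) {
  D0 <- if (length(state@D0)) state@D0 else
    stokesEinsteinD0(state@radii, config@temperature, config@viscosity)
  if (!config@hydrodynamics) return(D0)
  phi <- localVolumeFraction(state, config)
  D0 / (1 + tokuyamaH(phi, config@phiMax))
}
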