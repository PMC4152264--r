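# Shared fixtures and independent oracles for the test suite.

# one-sphere state in a large box (free or HI-isolated sphere scenarios)
singleSphereState <- function(radius = 24.7, L = 1000) {
  new("SystemState", boxLength = L,
      positions = matrix(L / 2, 1, 3), radii = radius,
      molecule = 1L, proteinId = "tracer", D0 = numeric(), frozen = FALSE,
      bonds = matrix(integer(), 0, 2), bondLengths = numeric(),
      angles = matrix(integer(), 0, 3), angleValues = numeric())
}

# small crowded box of synthetic proteins (deterministic); minL keeps the
# box large enough for the hydrodynamic cutoff (L > 8 max radius)
smallCrowdedBox <- function(nProt = 10, copies = 3L, target_occ = 0.2,
                            seed = 42, nmax = 5L, minL = 250) {
  protos <- lapply(seq_len(nProt), function(i)
    makeSyntheticProtein(1L + (i - 1L) %% nmax, seed = 500 + i,
                         proteinId = sprintf("p%02d", i),
                         copyNumber = copies))
  vol <- sum(vapply(protos, function(p)
    unionVolume(p@centers, p@radii) * p@copyNumber, numeric(1)))
  L <- max((vol / target_occ)^(1 / 3), minL)
  assembleBox(protos, boxLength = L, seed = seed, maxAttempts = 5000)
}

# independent R implementation of the local volume fraction (brute force,
# O(N^2), own lens formula) -- oracle for the engine and cpp paths
phiOracle <- function(pos, radii, L, rcutMult = 4, includeSelf = TRUE,
                      phiMax = 0.63) {
  lens <- function(d, R, a) {
    if (d >= R + a) return(0)
    if (d + a <= R) return(4 / 3 * pi * a^3)
    if (d + R <= a) return(4 / 3 * pi * R^3)
    pi * (R + a - d)^2 *
      (d^2 + 2 * d * a - 3 * a^2 + 2 * d * R + 6 * a * R - 3 * R^2) / (12 * d)
  }
  N <- nrow(pos)
  phi <- numeric(N)
  for (i in seq_len(N)) {
    Rc <- rcutMult * radii[i]
    v <- if (includeSelf) 4 / 3 * pi * radii[i]^3 else 0
    for (j in seq_len(N)) {
      if (j == i) next
      d <- pos[i, ] - pos[j, ]
      d <- d - L * floor(d / L + 0.5)
      v <- v + lens(sqrt(sum(d^2)), Rc, radii[j])
    }
    phi[i] <- min(v / (4 / 3 * pi * Rc^3), phiMax)
  }
  phi
}

# independent repulsion energy (brute force, R)
repEnergyOracle <- function(pos, radii, mol, L, kr) {
  E <- 0
  N <- nrow(pos)
  for (i in seq_len(N - 1)) {
    for (j in (i + 1):N) {
      if (mol[i] == mol[j]) next
      d <- pos[i, ] - pos[j, ]
      d <- d - L * floor(d / L + 0.5)
      r <- sqrt(sum(d^2))
      s <- radii[i] + radii[j]
      if (r < s) E <- E + kr * (s - r)^2
    }
  }
  E
}

# central finite-difference force from an energy closure
fdForces <- function(posmat, energyFun, h = 1e-5) {
  F <- matrix(0, nrow(posmat), 3)
  for (i in seq_len(nrow(posmat))) {
    for (c in 1:3) {
      pp <- posmat; pp[i, c] <- pp[i, c] + h
      pm <- posmat; pm[i, c] <- pm[i, c] - h
      F[i, c] <- -(energyFun(pp) - energyFun(pm)) / (2 * h)
    }
  }
  F
}

# free Brownian trajectory generated directly from rnorm (independent of the
# engine) -- oracle for the analysis estimators
freeBDSeries <- function(n, D, dt, dim = 3) {
  steps <- matrix(rnorm(n * dim, sd = sqrt(2 * D * dt)), n, dim)
  x <- apply(steps, 2, cumsum)
  x <- rbind(0, x)
  attr(x, "times") <- (0:n) * dt
  x
}
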