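test_that("Stokes-Einstein D0 has the right values and scaling", {
  # a = 19.6 A, T = 293 K, eta = 1 mPa s: hand unit conversion gives
  # kB*T/(6 pi eta a) = 1.095e-10 m^2/s = 10.95 A^2/ns = 109.5 um^2/s
  D <- stokesEinsteinD0(19.6, temperature = 293, viscosity = 1.0)
  expect_equal(D, 10.95, tolerance = 2e-3)
  expect_equal(A2ns_to_um2s(D), 109.5, tolerance = 0.2)
  # doubling the radius halves D0
  expect_equal(stokesEinsteinD0(10), 2 * stokesEinsteinD0(20), tolerance = 1e-12)
  # dimensional-analysis oracle at a = 1 A, T = 300 K, eta = 0.891:
  # 1.380649e-23*300/(6*pi*0.891e-3*1e-10) m^2/s * 1e11 (A^2/ns per m^2/s)
  want <- 1.380649e-23 * 300 / (6 * pi * 0.891e-3 * 1e-10) * 1e11
  expect_equal(stokesEinsteinD0(1, 300, 0.891), want, tolerance = 1e-12)
  expect_error(stokesEinsteinD0(-1), "must be > 0")
})

test_that("unit conversion round-trips and matches its definition", {
  # 1 A^2/ns = 1e-20 m^2 / 1e-9 s = 1e-11 m^2/s = 10 um^2/s
  expect_equal(A2ns_to_um2s(1), 10)
  expect_equal(um2s_to_A2ns(A2ns_to_um2s(3.7)), 3.7, tolerance = 1e-15)
  expect_equal(A2ns_to_um2s(um2s_to_A2ns(87)), 87, tolerance = 1e-15)
})

test_that("degenerate steps leave the state unchanged", {
  st <- singleSphereState()
  st@D0 <- 0  # D = 0: no drift, no noise
  cfg <- bdConfig(boxLength = 1000, nSteps = 10, saveInterval = 0.01,
                  hydrodynamics = FALSE, repulsion = FALSE, seed = 1)
  tr <- runSimulation(st, cfg)
  expect_equal(frames(tr)[11, , ], frames(tr)[1, , ], tolerance = 1e-15)
  # zero steps: initial frame only
  cfg0 <- bdConfig(boxLength = 1000, nSteps = 0, saveInterval = 0.01)
  tr0 <- runSimulation(singleSphereState(), cfg0)
  expect_identical(dim(frames(tr0))[1], 1L)
})

test_that("noiseless runs reproduce the deterministic drift limit", {
  # constant force from a stretched bond; with noiseScale = 0 the step is
  # exactly D dt F / kBT
  p <- makeSyntheticProtein(2, seed = 5)
  st <- assembleBox(list(p), boxLength = 800, seed = 1)
  st@positions[2, ] <- st@positions[1, ] +
    (st@positions[2, ] - st@positions[1, ]) * 1.2  # stretch by 20%
  cfg <- bdConfig(boxLength = 800, dt = 0.01, nSteps = 1, saveInterval = 0.01,
                  hydrodynamics = FALSE, seed = 3)
  st@D0 <- stokesEinsteinD0(st@radii, cfg@temperature, cfg@viscosity)
  F <- totalForces(st, cfg)$forces
  tr <- runSimulation(st, cfg, noiseScale = 0)
  drift <- frames(tr)[2, , ] - frames(tr)[1, , ]
  kBT <- 0.0019872041 * cfg@temperature
  expect_equal(drift, F * st@D0 * cfg@dt / kBT, tolerance = 1e-12)
})

test_that("free-sphere displacement variance matches 2 D dt per component", {
  st <- singleSphereState(radius = 24.7)
  n <- 1e4
  cfg <- bdConfig(boxLength = 1000, dt = 0.01, nSteps = n, saveInterval = 0.01,
                  hydrodynamics = FALSE, repulsion = FALSE, seed = 101)
  D0 <- stokesEinsteinD0(24.7, cfg@temperature, cfg@viscosity)
  tr <- runSimulation(st, cfg)
  com <- comTrajectory(tr, 1L)
  inc <- apply(com, 2, diff)
  v <- mean(inc^2)
  K <- length(inc)
  se <- sqrt(2 / K) * 2 * D0 * cfg@dt  # SE of a variance estimate
  expect_lt(abs(v - 2 * D0 * cfg@dt), 5 * se)
  # increments pass a normality check
  g <- gaussianityCheck(inc)
  expect_true(all(abs(g$kurtosis) < 0.2))
})

test_that("fixed seeds reproduce trajectories bit for bit", {
  st <- smallCrowdedBox(nProt = 5, copies = 2L, target_occ = 0.2, seed = 3)
  cfg <- bdConfig(boxLength = boxLength(st), nSteps = 300, dt = 0.01,
                  saveInterval = 0.5, seed = 77)
  t1 <- runSimulation(st, cfg)
  t2 <- runSimulation(st, cfg)
  expect_identical(frames(t1), frames(t2))
  # a different seed decorrelates
  cfg@seed <- 78
  t3 <- runSimulation(st, cfg)
  expect_false(isTRUE(all.equal(frames(t1), frames(t3))))
})

test_that("the noise stream is independent of the HI toggle", {
  # with HI on vs off the random displacements differ only through the
  # factor sqrt(D_eff/D0) per sphere; for a single isolated sphere phi is
  # constant so the ratio of increments must be exactly that factor
  st <- singleSphereState(radius = 18)
  cfgOn <- bdConfig(boxLength = 1000, nSteps = 50, dt = 0.01,
                    saveInterval = 0.01, hydrodynamics = TRUE,
                    repulsion = FALSE, seed = 9)
  cfgOff <- cfgOn; cfgOff@hydrodynamics <- FALSE
  trOn <- runSimulation(st, cfgOn)
  trOff <- runSimulation(st, cfgOff)
  incOn <- apply(comTrajectory(trOn, 1L), 2, diff)
  incOff <- apply(comTrajectory(trOff, 1L), 2, diff)
  fac <- sqrt(1 / (1 + tokuyamaH(1 / 64)))
  expect_equal(incOn, incOff * fac, tolerance = 1e-12)
})

test_that("trajectory frames are uniformly spaced, continuous and unwrapped", {
  st <- smallCrowdedBox(nProt = 4, copies = 2L, target_occ = 0.15, seed = 8)
  cfg <- bdConfig(boxLength = boxLength(st), nSteps = 1000, dt = 0.01,
                  saveInterval = 1, seed = 12)
  tr <- runSimulation(st, cfg)
  expect_identical(dim(frames(tr))[1], 11L)  # nSteps*dt/saveInterval + 1
  expect_equal(diff(frameTimes(tr)), rep(1, 10), tolerance = 1e-12)
  # continuity: no frame-to-frame COM jump near the box length
  for (m in unique(molecules(tr))) {
    com <- comTrajectory(tr, m)
    step <- sqrt(rowSums(apply(com, 2, diff)^2))
    expect_true(all(step < boxLength(st) / 4))
  }
})

test_that("frozen crowders exert forces but do not move", {
  st <- smallCrowdedBox(nProt = 4, copies = 3L, target_occ = 0.25, seed = 44)
  tracerMol <- 1L
  stF <- freezeCrowders(st, tracerMol)
  expect_identical(sum(!frozenSpheres(stF)), sum(molecules(st) == tracerMol))
  cfg <- bdConfig(boxLength = boxLength(st), nSteps = 500, dt = 0.01,
                  saveInterval = 1, seed = 2)
  tr <- runSimulation(stF, cfg)
  moved <- apply(frames(tr), 2, function(x) max(abs(x[nrow(x), ] - x[1, ])))
  expect_true(all(moved[frozenSpheres(stF)] == 0))
  expect_true(all(moved[!frozenSpheres(stF)] > 0))
  # frozen spheres still contribute to phi: a frozen neighbor inside the
  # tracer's cutoff raises phi above the isolated 1/64
  stP <- new("SystemState", boxLength = 600,
             positions = rbind(c(300, 300, 300), c(330, 300, 300)),
             radii = c(15, 15), molecule = 1:2, proteinId = c("t", "o"),
             D0 = numeric(), frozen = c(FALSE, TRUE),
             bonds = matrix(integer(), 0, 2), bondLengths = numeric(),
             angles = matrix(integer(), 0, 3), angleValues = numeric())
  trP <- runSimulation(stP, bdConfig(boxLength = 600, nSteps = 0,
                                     saveInterval = 0.01, seed = 2),
                       recordPhi = TRUE)
  expect_equal(trP@phi[1, 1], 2 / 64, tolerance = 1e-9)
  # freezing nothing is a no-op
  st0 <- freezeCrowders(st, unique(molecules(st)))
  expect_false(any(frozenSpheres(st0)))
  expect_error(freezeCrowders(st, "nosuch"), "unknown")
})

test_that("a caged tracer's MSD saturates below the cage size", {
  # tracer at the center of a sealed 3x3x3 grid of frozen obstacles
  # (spacing 22 A, radii 10 A): every exit channel is narrower than the
  # tracer, so its MSD must plateau far below the free 6 D t growth
  grid <- as.matrix(expand.grid(x = c(-22, 0, 22), y = c(-22, 0, 22),
                                z = c(-22, 0, 22)))
  grid <- grid[rowSums(abs(grid)) > 0, ]
  ctr <- rbind(c(0, 0, 0), grid) + 100
  nO <- nrow(grid)
  st <- new("SystemState", boxLength = 200, positions = ctr,
            radii = c(8, rep(10, nO)),
            molecule = seq_len(nO + 1L),
            proteinId = c("t", sprintf("o%02d", seq_len(nO))),
            D0 = numeric(), frozen = c(FALSE, rep(TRUE, nO)),
            bonds = matrix(integer(), 0, 2), bondLengths = numeric(),
            angles = matrix(integer(), 0, 3), angleValues = numeric())
  cfg <- bdConfig(boxLength = 200, nSteps = 2e4, dt = 0.01, saveInterval = 1,
                  hydrodynamics = FALSE, repulsion = TRUE, kRepulse = 1,
                  seed = 5)
  tr <- suppressWarnings(runSimulation(st, cfg))  # small-skin warning expected
  com <- comTrajectory(tr, 1L)
  msd <- msdMultiOrigin(com)
  # cage bound: the center cannot wander more than ~the gap to contact in
  # any direction, MSD plateaus around (few A)^2 while free diffusion would
  # reach 6*D0*100 ~ 8000 A^2
  expect_lt(max(msd$msd), 3 * 14^2)
  D0 <- stokesEinsteinD0(8)
  expect_lt(max(msd$msd), 6 * D0 * max(msd$lag) / 5)
})

test_that("instability is caught and reported with a diagnostic", {
  # two heavily overlapping foreign spheres with a huge force constant
  st <- new("SystemState", boxLength = 200,
            positions = rbind(c(100, 100, 100), c(100.5, 100, 100)),
            radii = c(20, 20), molecule = 1:2, proteinId = c("a", "b"),
            D0 = numeric(), frozen = c(FALSE, FALSE),
            bonds = matrix(integer(), 0, 2), bondLengths = numeric(),
            angles = matrix(integer(), 0, 3), angleValues = numeric())
  cfg <- bdConfig(boxLength = 200, nSteps = 100, dt = 0.01,
                  saveInterval = 0.01, hydrodynamics = FALSE,
                  kRepulse = 1e5, seed = 1)
  expect_error(suppressWarnings(runSimulation(st, cfg)), "unstable")
})

test_that("config validation rejects inconsistent settings", {
  expect_error(bdConfig(dt = -0.01), "dt")
  expect_error(bdConfig(saveInterval = 0.015, dt = 0.01), "multiple")
  expect_error(bdConfig(rcutMultiplier = 0.5), "rcutMultiplier")
  expect_error(bdConfig(phiMax = 1.2), "phiMax")
  # box must accommodate the local-volume cutoff
  st <- singleSphereState(radius = 30, L = 200)
  cfg <- bdConfig(boxLength = 200, nSteps = 10, saveInterval = 0.01)
  expect_error(runSimulation(st, cfg), "box too small")
})

test_that("YAML config and trajectory CSV round-trip", {
  cfg <- bdConfig(nSteps = 100, seed = 42, hydrodynamics = FALSE,
                  kRepulse = 0.3)
  f <- tempfile(fileext = ".yaml")
  writeBDConfig(cfg, f)
  cfg2 <- readBDConfig(f)
  expect_equal(cfg2@kRepulse, 0.3)
  expect_false(cfg2@hydrodynamics)
  expect_equal(cfg2@nSteps, 100)
  st <- smallCrowdedBox(nProt = 3, copies = 1L, target_occ = 0.1, seed = 2)
  cfg3 <- bdConfig(boxLength = boxLength(st), nSteps = 100, dt = 0.01,
                   saveInterval = 0.5, seed = 7)
  tr <- runSimulation(st, cfg3)
  csv <- tempfile(fileext = ".csv")
  writeTrajectoryCSV(tr, csv)
  tr2 <- readTrajectoryCSV(csv)
  expect_equal(frames(tr2), frames(tr), tolerance = 1e-12)
  expect_equal(frameTimes(tr2), frameTimes(tr))
  expect_identical(molecules(tr2), molecules(tr))
})

test_that("bdStep advances the state by one Ermak-McCammon update", {
  p <- makeSyntheticProtein(2, seed = 21)
  st <- assembleBox(list(p), boxLength = 600, seed = 1)
  st@positions[2, ] <- st@positions[2, ] + c(2, 0, 0)  # off equilibrium
  cfg <- bdConfig(boxLength = 600, dt = 0.01, saveInterval = 0.01,
                  hydrodynamics = FALSE, seed = 6)
  st@D0 <- stokesEinsteinD0(st@radii, cfg@temperature, cfg@viscosity)
  F <- totalForces(st, cfg)$forces
  out <- bdStep(st, cfg, noiseScale = 0)
  expect_s4_class(out, "SystemState")
  kBT <- 0.0019872041 * cfg@temperature
  expect_equal(out@positions - st@positions,
               F * st@D0 * cfg@dt / kBT, tolerance = 1e-8)
})
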