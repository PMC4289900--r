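test_that("cable assembly converts specific to absolute quantities", {
  # uniform cylinder: axial conductance between adjacent equal segments
  # equals the closed form for the midpoint-to-midpoint span
  L <- 99; d <- 2; ra <- 70
  m <- chainMorph(L, diam_um = d, spacing_um = 11)
  mod <- buildModel(m, uniformProfile(ra = ra))
  sg <- segmentTable(mod)
  segs <- which(sg$section == 1L)
  lseg <- sg$length_um[segs[1]]
  # R = ra * lseg / (pi r^2), halves from two identical segments, in Ohm
  Rspan <- ra * lseg / (pi * (d / 2 * 1e-4)^2) * 1e-4
  gexp <- 1e9 / Rspan
  expect_equal(mod@g_axial_nS[segs[2]], gexp, tolerance = 1e-9)

  # doubling the membrane area doubles capacitance and leak conductance
  m1 <- singleCompModel(rm = 10, radius = 20)
  m2 <- singleCompModel(rm = 10, radius = 20 * sqrt(2))
  expect_equal(m2@cap_pF, 2 * m1@cap_pF, tolerance = 1e-9)
  expect_equal(m2@g_leak_nS, 2 * m1@g_leak_nS, tolerance = 1e-9)

  # zero-diameter segment is a structural error
  grid <- compartmentalize(smallTree(1.5))
  mech <- assignMechanisms(grid)
  grid@segments$diam_um[5] <- 0
  expect_error(buildCableModel(grid, mech), "zero-diameter")
})

test_that("DC steady state matches closed forms and balances charge", {
  # single compartment: 10 pA through 100 MOhm -> +1 mV
  mod <- singleCompModel()
  v <- steadyState(mod, c("1" = 10))
  expect_equal(v, -64, tolerance = 1e-6)
  expect_equal(steadyState(mod), -65)

  # two-compartment network vs explicit 2x2 matrix inversion
  m <- chainMorph(30, diam_um = 2, spacing_um = 10)
  mod2 <- buildModel(m, uniformProfile())
  n <- nSegments(mod2)
  gax <- mod2@g_axial_nS
  A <- diag(mod2@g_leak_nS)
  for (i in 2:n) {
    p <- mod2@parent[i]
    A[i, p] <- A[i, p] - gax[i]
    A[p, i] <- A[p, i] - gax[i]
    A[i, i] <- A[i, i] + gax[i]
    A[p, p] <- A[p, p] + gax[i]
  }
  inj <- numeric(n); inj[n] <- 20
  vexp <- solve(A, mod2@g_leak_nS * -65 + inj)
  expect_equal(steadyState(mod2, stats::setNames(20, n)), vexp,
               tolerance = 1e-6)

  # charge balance on a branched HCN model
  tree <- smallTree(2)
  modh <- buildModel(tree, dist = hcnDistribution())
  vh <- steadyState(modh, c("1" = -20))
  act <- hcnActivation(vh, modh@kinetics)
  res <- modh@g_leak_nS * (modh@e_leak - vh) +
    modh@gh_nS * act$m_inf * (modh@e_h - vh)
  res[1] <- res[1] - 20
  for (i in 2:length(vh)) {
    p <- modh@parent[i]
    flow <- modh@g_axial_nS[i] * (vh[p] - vh[i])
    res[i] <- res[i] + flow
    res[p] <- res[p] - flow
  }
  expect_lt(max(abs(res)), 1e-3) # < 1 pA by a wide margin
})

test_that("holding balance makes -65 mV an exact rest for HCN models", {
  tree <- smallTree(2)
  modh <- buildModel(tree, dist = hcnDistribution())
  expect_equal(steadyState(modh), rep(-65, nSegments(modh)), tolerance = 1e-9)
  # without holding the model drifts depolarized
  free <- buildModel(tree, dist = hcnDistribution(), hold_mV = NULL)
  expect_gt(max(steadyState(free)), -60)
})

test_that("RC charging follows the closed form within 0.5 percent", {
  mod <- singleCompModel() # R = 100 MOhm, tau = 10 ms
  dt <- 0.025
  nst <- round(60 / dt)
  tr <- runSimulation(mod, rep(10, nst + 1), 1L, 1L, dt_ms = dt)
  t <- tr$time
  vexp <- -65 + 10 * 100 * 1e-3 * (1 - exp(-t / 10))
  for (tt in c(10, 50)) { # t = tau and t = 5 tau
    i <- which.min(abs(t - tt))
    expect_equal(unname(tr$v[i, 1]) - (-65), vexp[i] - (-65),
                 tolerance = 5e-3)
  }
  # zero stimulus: flat at rest
  flat <- runSimulation(mod, rep(0, 1001), 1L, 1L, dt_ms = 0.1)
  expect_equal(range(flat$v), c(-65, -65))
})

test_that("passive responses are linear and reciprocal", {
  tree <- smallTree(2)
  mod <- buildModel(tree)
  sg <- segmentTable(mod)
  a <- trunkSite(mod, 150)
  b <- trunkSite(mod, 300)
  stim <- chirpStimulus(20, 25, 1, 0.1)
  r1 <- runSimulation(mod, as.numeric(stim), a, c(a, b), dt_ms = 0.1)
  r3 <- runSimulation(mod, 3 * as.numeric(stim), a, c(a, b), dt_ms = 0.1)
  expect_equal(3 * (r1$v[, 1] + 65), r3$v[, 1] + 65, tolerance = 1e-9)
  # reciprocity: inject at a record at b == inject at b record at a
  r_ab <- runSimulation(mod, as.numeric(stim), a, b, dt_ms = 0.1)
  r_ba <- runSimulation(mod, as.numeric(stim), b, a, dt_ms = 0.1)
  expect_equal(r_ab$v[, 1], r_ba$v[, 1], tolerance = 1e-9)
})

test_that("chirp response of a passive chain matches the admittance oracle", {
  m <- chainMorph(60, diam_um = 2, spacing_um = 20) # 3 compartments + soma
  mod <- buildModel(m, uniformProfile())
  tip <- nSegments(mod)
  prof <- localImpedance(mod, tip, testProtocol())
  f <- frequencies(prof)
  sel <- seq(1, length(f), by = 4)
  zo <- oracleImpedance(mod, f[sel], tip)
  zm <- impedanceValues(prof)[sel]
  expect_lt(max(Mod(zm - zo) / Mod(zo)), 0.01)
})

test_that("halving dt leaves recorded traces unchanged to < 0.2 percent", {
  tree <- smallTree(2)
  mod <- buildModel(tree, dist = hcnDistribution())
  site <- trunkSite(mod, 300)
  for (dt in c(0.05, 0.025)) {
    chirp <- chirpStimulus(50, 25, 2, dt)
    tr <- runSimulation(mod, as.numeric(chirp), site, site, dt_ms = dt)
    if (dt == 0.05) coarse <- tr else fine <- tr
  }
  vc <- coarse$v[, 1]
  vf <- fine$v[seq(1, nrow(fine$v), by = 2), 1]
  span <- diff(range(vf))
  expect_lt(max(abs(vc - vf)) / span, 0.002)
})

test_that("refining the spatial grid changes steady states by < 0.5 percent", {
  tree <- smallTree(2)
  m1 <- buildModel(tree, dist = hcnDistribution(), d_lambda = 0.1)
  m2 <- buildModel(tree, dist = hcnDistribution(), d_lambda = 0.05)
  for (s in c(0, 150, 300)) {
    s1 <- trunkSite(m1, s); s2 <- trunkSite(m2, s)
    v1 <- steadyState(m1, stats::setNames(-30, s1))[s1]
    v2 <- steadyState(m2, stats::setNames(-30, s2))[s2]
    expect_lt(abs(v1 - v2) / abs(v2 + 65), 0.005)
  }
})

test_that("invalid sites and malformed stimuli are rejected", {
  mod <- singleCompModel()
  expect_error(runSimulation(mod, rep(0, 11), 5L, 1L), "out of range")
  expect_error(runSimulation(mod, rep(0, 11), 1L, 7L), "out of range")
  expect_error(steadyState(mod, c("9" = 1)), "out of range")
})
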