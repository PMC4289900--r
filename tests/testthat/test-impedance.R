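test_that("chirp waveform sweeps 0-25 Hz linearly", {
  w <- chirpStimulus(50, 25, 25, 0.025)
  expect_equal(w[1], 0)
  expect_equal(max(abs(w)), 50, tolerance = 1e-4)
  # zero crossings: integral of the instantaneous frequency gives
  # f_end * T / 2 cycles = 312.5, i.e. about 625 crossings over 25 s
  crossings <- sum(diff(sign(w[w != 0])) != 0)
  expect_equal(crossings, 625, tolerance = 0.005)
  # instantaneous frequency at T/2 is f_end/2: count crossings in a 1 s
  # window around the middle (~12.5 cycles -> ~25 crossings)
  t <- seq(0, 25, by = 0.025e-3 * 1000) / 1000 # not used; keep grid implicit
  mid <- w[round(length(w) * 0.48):round(length(w) * 0.52)]
  cr <- sum(diff(sign(mid[mid != 0])) != 0)
  expect_equal(cr / (0.04 * 25), 2 * 12.5, tolerance = 0.05)
})

test_that("chirp-derived RC impedance matches the closed forms", {
  mod <- singleCompModel() # R = 100 MOhm, tau = 10 ms
  prof <- localImpedance(mod, 1L, simProtocol())
  f <- frequencies(prof)
  Z <- impedanceValues(prof)
  Ztrue <- 100 / (1 + 1i * 2 * pi * f * 0.01)
  expect_lt(max(Mod(Z - Ztrue) / Mod(Ztrue)), 0.01)
  # cutoff frequency 1/(2 pi tau) = 15.92 Hz: |Z| = 0.707 R, phase -45 deg
  ic <- which.min(abs(f - 15.9155))
  expect_equal(Mod(Z)[ic], 70.7, tolerance = 0.01)
  expect_equal(Arg(Z)[ic] * 180 / pi, -45, tolerance = 0.02)
  # DC consistency: |Z(0.5)| ~ pulse-measured R_in
  rin <- measureInputResistance(mod, 1L)
  expect_equal(Mod(Z)[1], rin, tolerance = 0.05)
})

test_that("impedance computation guards its preconditions", {
  dt <- 0.1
  t <- seq(0, 2000, by = dt) / 1000
  pure <- sin(2 * pi * 5 * t) # single tone: no excitation elsewhere
  resp <- 0.5 * pure
  expect_error(computeImpedance(pure, resp, dt), "insufficient excitation")
  expect_error(computeImpedance(pure, resp[-1], dt), "length")
})

test_that("resonance measures recover constructed profile features", {
  f <- seq(0.5, 25, by = 0.1)
  # band-pass magnitude with an analytic peak at 7 Hz
  mag <- 40 + 20 * exp(-((f - 7)^2) / 18)
  ph <- rep(-0.1, length(f))
  Z <- complex(modulus = mag, argument = ph)
  prof <- new("ImpedanceProfile", freq = f, Z = Z, kind = "local",
              site_um = 0)
  meas <- resonanceMeasures(prof)
  expect_equal(meas$f_R, 7, tolerance = 0.05)
  expect_equal(meas$z_max, 60, tolerance = 0.01)
  expect_equal(meas$Q, 60 / mag[1], tolerance = 0.01)
  expect_equal(meas$Phi_L, 0) # phase everywhere negative

  # strictly low-pass: band-edge peak, Q = 1, no inductive area
  lp <- complex(modulus = 100 / sqrt(1 + (f / 5)^2), argument = -atan(f / 5))
  lpp <- new("ImpedanceProfile", freq = f, Z = lp, kind = "local",
             site_um = 0)
  ml <- resonanceMeasures(lpp)
  expect_equal(ml$f_R, 0.5)
  expect_equal(ml$Q, 1)
  expect_equal(ml$Phi_L, 0)

  # constructed positive-phase region integrates by trapezoid
  ph2 <- pmax(0.2 - 0.05 * abs(f - 10), 0)
  Z2 <- complex(modulus = rep(50, length(f)), argument = ph2)
  p2 <- new("ImpedanceProfile", freq = f, Z = Z2, kind = "local", site_um = 0)
  expect_equal(resonanceMeasures(p2)$Phi_L, pracma::trapz(f, ph2))
})

test_that("local and transfer impedance share the expected structure", {
  tree <- smallTree(2)
  mod <- buildModel(tree)
  prot <- testProtocol()
  # coincident sites: local and transfer profiles identical
  pl <- localImpedance(mod, 1L, prot)
  pt <- transferImpedance(mod, 1L, prot)
  expect_equal(impedanceValues(pl), impedanceValues(pt), tolerance = 1e-12)

  # attenuation: transfer DC magnitude below local at both ends
  site <- trunkSite(mod, 300)
  pls <- localImpedance(mod, site, prot)
  pts <- transferImpedance(mod, site, prot)
  expect_lt(Mod(impedanceValues(pts))[1], Mod(impedanceValues(pls))[1])
  pl0 <- localImpedance(mod, 1L, prot)
  expect_lt(Mod(impedanceValues(pts))[1], Mod(impedanceValues(pl0))[1])

  # passive reciprocity: site -> soma equals soma -> site
  rev <- transferBothWays(mod, site, prot)
  expect_lt(max(Mod(rev$fwd - rev$bwd) / Mod(rev$fwd)), 0.005)
})

test_that("input resistance is the V-I slope and respects linearity", {
  mod <- singleCompModel()
  r1 <- measureInputResistance(mod, 1L)
  expect_equal(r1, 100, tolerance = 5e-3)
  # amplitude-set independence on a linear system
  r2 <- measureInputResistance(mod, 1L, seq(-25, 25, 5))
  expect_equal(r2, r1, tolerance = 1e-6)
  # analytic value R = rm/area recovered within 0.5 percent
  expect_equal(r1, 100, tolerance = 5e-3)
  expect_error(measureInputResistance(mod, 1L, c(-10, 20)), "symmetric")
})

test_that("chirp normalization preserves somatic response amplitude", {
  expect_equal(normalizeChirpAmplitude(50, 50), 50)
  expect_equal(normalizeChirpAmplitude(50, 100), 25)
  expect_error(normalizeChirpAmplitude(-1, 50), "positive|TRUE")

  # somatic peak-to-peak voltage comparable across a short atrophy series
  series <- generatePruneSeries(smallTree(3), step_mm = 1, floor_mm = 1)
  prot <- testProtocol()
  ptp <- numeric(3)
  base_rin <- NULL
  for (i in 1:3) {
    mod <- buildModel(seriesMembers(series)[[i]], dist = hcnDistribution())
    rin <- measureInputResistance(mod, 1L, prot$rin_amps_pA,
                                  settle_ms = prot$settle_ms)
    if (is.null(base_rin)) base_rin <- rin
    amp <- normalizeChirpAmplitude(base_rin, rin)
    stim <- c(as.numeric(chirpStimulus(amp, 25, prot$chirp_dur_s,
                                       prot$dt_ms)))
    tr <- runSimulation(mod, stim, 1L, 1L, dt_ms = prot$dt_ms)
    ptp[i] <- diff(range(tr$v[, 1]))
  }
  expect_lt(max(ptp) / min(ptp), 1.10)
})

test_that("maps are complete and equal standalone recomputation", {
  tree <- smallTree(2)
  mod <- buildModel(tree)
  prot <- testProtocol()
  map <- mapOverLocations(mod, c(0, 150), prot)
  ids <- c("Rin", "fR", "Zloc_max", "Q", "PhiL",
           "fTR", "ZTR_max", "Q_TR", "PhiL_TR")
  expect_setequal(unique(map$measurement), ids)
  expect_equal(nrow(map), 2 * 9)
  # per-site recomputation
  seg <- trunkSite(mod, 150)
  rin <- measureInputResistance(mod, seg, prot$rin_amps_pA,
                                pulse_ms = prot$rin_pulse_ms,
                                settle_ms = prot$settle_ms,
                                dt_ms = prot$dt_ms)
  expect_equal(map$value[map$site_um == 150 & map$measurement == "Rin"],
               rin, tolerance = 1e-9)
  loc <- resonanceMeasures(localImpedance(mod, seg, prot))
  expect_equal(map$value[map$site_um == 150 & map$measurement == "fR"],
               loc$f_R, tolerance = 1e-9)

  # series mapping: one value per member, explicit gaps, base-site check
  series <- generatePruneSeries(smallTree(3), step_mm = 1, floor_mm = 1)
  lf <- mapOverSeries(series, 150, "Rin", protocol = prot)
  expect_equal(nrow(lf), 3)
  expect_true(all(is.finite(lf$value)))
  expect_true(all(diff(lf$value) > 0)) # R_in rises as length falls
  expect_error(mapOverSeries(series, 600, "Rin", protocol = prot),
               "cannot be resolved")
  expect_error(mapOverSeries(series, 150, "bogus"), "unknown measurement")
})
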