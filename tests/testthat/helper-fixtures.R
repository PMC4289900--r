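# Fixture builders shared across the suite. All morphologies are generated
# in code; nothing is read from disk except temporary files the tests write
# themselves.

# A minimal 3-node SWC file: soma plus two chained apical nodes.
writeTinySWC <- function(path = tempfile(fileext = ".swc")) {
  writeLines(c(
    "# tiny fixture",
    "1 1 0 0 0 10 -1",
    "2 4 0 50 0 1 1",
    "3 4 0 100 0 1 2"
  ), path)
  path
}

# Single-compartment (soma-only) model: R = rm/area, tau = rm*cm.
# radius 28.20948 um gives an area of 1e4 um^2, so rm = 10 kOhm cm^2 yields
# R = 100 MOhm and tau = 10 ms.
singleCompModel <- function(rm = 10, radius = 28.20948, dist = NULL,
                            kinetics = hcnKinetics()) {
  nd <- data.frame(id = 1L, type = 1L, x = 0, y = 0, z = 0,
                   radius = radius, parent = -1L)
  m <- neuronMorphology(nd)
  buildModel(m, passiveProfile(rm_som = rm, rm_end = rm), dist, kinetics)
}

# Soma plus an unbranched apical cable of given length/diameter, with
# spatially constant passive properties (so closed forms apply).
chainMorph <- function(length_um = 300, diam_um = 2, spacing_um = 10,
                       soma_radius = 10) {
  n <- round(length_um / spacing_um)
  nd <- data.frame(
    id = 1:(n + 1L),
    type = c(1L, rep(4L, n)),
    x = 0, y = c(0, seq_len(n) * spacing_um), z = 0,
    radius = c(soma_radius, rep(diam_um / 2, n)),
    parent = c(-1L, 1:n)
  )
  neuronMorphology(nd)
}

uniformProfile <- function(rm = 20, ra = 70, cm = 1) {
  passiveProfile(rm_som = rm, rm_end = rm, ra_som = ra, ra_end = ra, cm = cm)
}

# Small stylized trees for pipeline-level tests.
smallTree <- function(target_mm = 3, seed = 7) {
  generateStylizedCA1(synthParams(target_mm = target_mm, seed = seed))
}

# Reduced-cost protocol for tests on small models: 4 s chirp (0.25 Hz grid).
testProtocol <- function(...) {
  simProtocol(chirp_dur_s = 4, settle_ms = 100, tail_ms = 400,
              rin_amps_pA = seq(-25, 25, 12.5), ...)
}

# Transfer impedance measured in both directions between a site and the soma
# (reciprocity check for passive trees).
transferBothWays <- function(model, site, prot = testProtocol()) {
  fwd <- transferImpedance(model, site, prot)
  dt <- prot$dt_ms
  chirp <- chirpStimulus(prot$chirp_amp_pA, prot$chirp_fend_hz,
                         prot$chirp_dur_s, dt)
  nset <- round(prot$settle_ms / dt)
  ntail <- round(prot$tail_ms / dt)
  stim <- c(rep(0, nset), as.numeric(chirp), rep(0, ntail))
  tr <- runSimulation(model, stim, 1L, site, dt_ms = dt,
                      v_init = prot$v_init)
  win <- (nset + 1L):(length(stim) - 1L)
  bwd <- computeImpedance(stim[win], tr$v[win, 1], dt, kind = "transfer")
  list(fwd = impedanceValues(fwd), bwd = impedanceValues(bwd))
}
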