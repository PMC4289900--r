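#' @include AllClasses.R cable.R
NULL

#' Simulation and measurement protocol settings
#'
#' Bundles the stimulation/recording parameters used by the map-level
#' functions. The default is a reduced-cost protocol (0.1 ms steps, 10 s
#' chirp sweeping 0-25 Hz, giving a 0.1 Hz transform grid); `full = TRUE`
#' selects the full-resolution protocol (25 us steps, 25 s chirp).
#'
#' @param full use the full-resolution protocol.
#' @param dt_ms integration step (ms).
#' @param chirp_amp_pA chirp amplitude (pA).
#' @param chirp_fend_hz final swept frequency (Hz).
#' @param chirp_dur_s chirp duration (s).
#' @param settle_ms initial interval discarded before any measurement.
#' @param tail_ms zero-stimulus interval appended after the chirp and
#'   included in the transform window, so the response decay is captured and
#'   the transform ratio is free of truncation leakage.
#' @param rin_amps_pA current-pulse amplitudes for the V-I protocol (pA).
#' @param rin_pulse_ms pulse duration (ms).
#' @param v_init initial/holding potential (mV).
#' @return a list of protocol settings.
#' @export
simProtocol <- function(full = FALSE,
                        dt_ms = if (full) 0.025 else 0.1,
                        chirp_amp_pA = 50, chirp_fend_hz = 25,
                        chirp_dur_s = if (full) 25 else 10,
                        settle_ms = 200, tail_ms = 500,
                        rin_amps_pA = seq(-50, 50, 10),
                        rin_pulse_ms = 300,
                        v_init = -65) {
  list(dt_ms = dt_ms, chirp_amp_pA = chirp_amp_pA,
       chirp_fend_hz = chirp_fend_hz, chirp_dur_s = chirp_dur_s,
       settle_ms = settle_ms, tail_ms = tail_ms,
       rin_amps_pA = rin_amps_pA,
       rin_pulse_ms = rin_pulse_ms, v_init = v_init)
}

#' Chirp (ZAP) current waveform
#'
#' Constant-amplitude sinusoid whose instantaneous frequency increases
#' linearly from 0 to `f_end` over `duration_s`:
#' I(t) = A sin(pi (f_end/duration) t^2). The value is 0 at t = 0 and the
#' instantaneous frequency at t = duration/2 is f_end/2.
#'
#' @param amplitude_pA amplitude (pA, default 50).
#' @param f_end_hz final frequency (Hz, default 25).
#' @param duration_s sweep duration (s, default 25).
#' @param dt_ms sample interval (ms).
#' @return numeric waveform (pA) of length duration/dt + 1, with attributes
#'   `dt_ms` and `duration_s`.
#' @export
chirpStimulus <- function(amplitude_pA = 50, f_end_hz = 25, duration_s = 25,
                          dt_ms = 0.025) {
  stopifnot(duration_s > 0, dt_ms > 0)
  t <- seq(0, duration_s, by = dt_ms / 1000)
  w <- amplitude_pA * sin(pi * (f_end_hz / duration_s) * t^2)
  attr(w, "dt_ms") <- dt_ms
  attr(w, "duration_s") <- duration_s
  w
}

#' Chirp amplitude normalization across morphologies
#'
#' Scales the chirp amplitude inversely with the somatic input resistance so
#' that the somatic peak-to-peak voltage response stays comparable across
#' pruned morphologies: amplitude = base_amplitude * base_rin / model_rin.
#'
#' @param base_rin_Mohm somatic input resistance of the reference (base) model.
#' @param model_rin_Mohm somatic input resistance of the model under study.
#' @param base_amplitude_pA reference amplitude (default 50 pA).
#' @return scaled amplitude in pA.
#' @export
normalizeChirpAmplitude <- function(base_rin_Mohm, model_rin_Mohm,
                                    base_amplitude_pA = 50) {
  stopifnot(base_rin_Mohm > 0, model_rin_Mohm > 0)
  base_amplitude_pA * base_rin_Mohm / model_rin_Mohm
}

#' Input resistance from the slope of the V-I relation
#'
#' Injects depolarizing and hyperpolarizing current pulses at `site`, reads
#' the local steady-state deflection as the mean of the final 10 ms of each
#' pulse, and returns the least-squares slope of the V-I plot in megaohms.
#'
#' @param model a [CableModel-class].
#' @param site segment index of injection/recording.
#' @param amplitudes_pA pulse amplitudes, symmetric about 0 (default -50..50
#'   pA in 10 pA steps; a reduced -25..25 pA range in 5 pA steps limits
#'   voltage excursions in high-impedance models).
#' @param pulse_ms pulse duration (default 300 ms).
#' @param settle_ms discarded settling interval before the pulse.
#' @param dt_ms integration step.
#' @param v_init holding potential (mV).
#' @return input resistance in megaohms.
#' @export
measureInputResistance <- function(model, site, amplitudes_pA = seq(-50, 50, 10),
                                   pulse_ms = 300, settle_ms = 200,
                                   dt_ms = 0.1, v_init = -65) {
  if (max(abs(amplitudes_pA + rev(amplitudes_pA))) > 1e-9) {
    stop("amplitudes must be symmetric about 0")
  }
  nset <- round(settle_ms / dt_ms)
  npul <- round(pulse_ms / dt_ms)
  ntot <- nset + npul
  nread <- max(2L, round(10 / dt_ms))
  dv <- vapply(amplitudes_pA, function(a) {
    if (a == 0) return(0)
    stim <- c(rep(0, nset), rep(a, npul + 1L))
    tr <- runSimulation(model, stim, site, site, dt_ms = dt_ms,
                        v_init = v_init)
    v <- tr$v[, 1]
    # baseline strictly before any pulse current enters the integration
    mean(v[(ntot - nread + 1L):(ntot + 1L)]) - v[max(nset, 1L)]
  }, numeric(1))
  ord <- order(amplitudes_pA)
  if (any(diff(dv[ord]) < -1e-6)) {
    stop("measurement error: non-monotone V-I relation")
  }
  # slope in mV/pA = GOhm; report MOhm
  slope <- stats::coef(stats::lm(dv ~ amplitudes_pA))[["amplitudes_pA"]]
  slope * 1000
}

#' Impedance profile from stimulus and response traces
#'
#' Z(f) = V(f)/I(f) on the discrete Fourier grid, restricted to the analysis
#' band: magnitude sqrt(Re^2 + Im^2), phase atan2(Im, Re). Both traces are
#' demeaned before transforming. An optional boxcar smoothing over a fixed
#' 0.25 Hz window can be enabled.
#'
#' @param stim_pA stimulus samples (pA).
#' @param v_mV response samples (mV), same time base.
#' @param dt_ms sample interval (ms).
#' @param band analysis band in Hz (default c(0.5, 25); the chirp starts at
#'   0 Hz where the transform ratio is ill-conditioned).
#' @param kind "local" or "transfer".
#' @param site_um radial distance of the injection site (annotation only).
#' @param smooth apply 0.25 Hz boxcar smoothing to Z (default FALSE).
#' @return an [ImpedanceProfile-class] (impedance in megaohms).
#' @export
computeImpedance <- function(stim_pA, v_mV, dt_ms, band = c(0.5, 25),
                             kind = "local", site_um = NA_real_,
                             smooth = FALSE) {
  n <- length(stim_pA)
  stopifnot(length(v_mV) == n)
  f <- (seq_len(n) - 1) / (n * dt_ms * 1e-3)
  Iw <- stats::fft(stim_pA - mean(stim_pA))
  Vw <- stats::fft(v_mV - mean(v_mV))
  keep <- which(f >= band[1] - 1e-9 & f <= band[2] + 1e-9)
  if (length(keep) < 3) stop("band too narrow for the transform grid")
  mag_I <- Mod(Iw[keep])
  if (min(mag_I) < 1e-4 * max(mag_I)) {
    stop("measurement error: insufficient excitation within the band")
  }
  Z <- Vw[keep] / Iw[keep] * 1000 # mV/pA -> MOhm
  fr <- f[keep]
  if (smooth) {
    w <- max(1L, round(0.25 / (fr[2] - fr[1])))
    if (w > 1L) {
      kern <- rep(1 / w, w)
      Z <- complex(
        real = stats::filter(Re(Z), kern, sides = 2),
        imaginary = stats::filter(Im(Z), kern, sides = 2)
      )
      ok <- !is.na(Re(Z))
      Z <- Z[ok]
      fr <- fr[ok]
    }
  }
  new("ImpedanceProfile", freq = fr, Z = Z, kind = kind, site_um = site_um)
}

# Run a chirp at `site`, recording at the site and at the soma; returns the
# local and transfer impedance profiles from one simulation.
.impedancePair <- function(model, site, protocol = simProtocol(),
                           amplitude_pA = protocol$chirp_amp_pA,
                           smooth = FALSE) {
  dt <- protocol$dt_ms
  chirp <- chirpStimulus(amplitude_pA, protocol$chirp_fend_hz,
                         protocol$chirp_dur_s, dt)
  nset <- round(protocol$settle_ms / dt)
  ntail <- round((protocol$tail_ms %||% 500) / dt)
  stim <- c(rep(0, nset), as.numeric(chirp), rep(0, ntail))
  soma <- 1L
  rec <- unique(c(site, soma))
  tr <- runSimulation(model, stim, site, rec, dt_ms = dt,
                      v_init = protocol$v_init)
  # window = chirp plus decay tail (the settle interval is discarded)
  win <- (nset + 1L):(length(stim) - 1L)
  sg <- model@grid@segments
  x_um <- sg$radial_um[site]
  vloc <- tr$v[win, as.character(site)]
  vsom <- tr$v[win, as.character(soma)]
  list(
    local = computeImpedance(stim[win], vloc, dt, kind = "local",
                             site_um = x_um, smooth = smooth),
    transfer = computeImpedance(stim[win], vsom, dt, kind = "transfer",
                                site_um = x_um, smooth = smooth)
  )
}

#' Local impedance profile at a site
#'
#' Chirp current injected at `site` with the voltage response recorded at the
#' same location.
#'
#' @param model a [CableModel-class].
#' @param site segment index of the injection.
#' @param protocol settings from [simProtocol()].
#' @param amplitude_pA chirp amplitude (after any normalization).
#' @param smooth passed to [computeImpedance()].
#' @return an [ImpedanceProfile-class].
#' @export
localImpedance <- function(model, site, protocol = simProtocol(),
                           amplitude_pA = protocol$chirp_amp_pA,
                           smooth = FALSE) {
  .impedancePair(model, site, protocol, amplitude_pA, smooth)$local
}

#' Transfer impedance profile from a site to the soma
#'
#' Chirp current injected at `site` with the voltage response recorded at the
#' soma; the profile is attributed to the injection site's distance.
#'
#' @inheritParams localImpedance
#' @return an [ImpedanceProfile-class].
#' @export
transferImpedance <- function(model, site, protocol = simProtocol(),
                              amplitude_pA = protocol$chirp_amp_pA,
                              smooth = FALSE) {
  .impedancePair(model, site, protocol, amplitude_pA, smooth)$transfer
}

#' Resonance measures of an impedance profile
#'
#' f_R is the frequency at which |Z| peaks, refined by a least-squares
#' parabola fitted over a +/- 1 Hz window around the grid argmax (ties and
#' band-edge peaks resolve to the lower band edge); the windowed fit averages
#' out transform-grid ripple that a three-point refinement would follow.
#' z_max = |Z(f_R)|, Q = |Z(f_R)| / |Z(0.5 Hz)|, and Phi_L is the area under
#' the inductive (positive) part of the phase profile (rad Hz, trapezoid
#' rule).
#'
#' @param profile an [ImpedanceProfile-class] covering 0.5-25 Hz.
#' @return list with `f_R` (Hz), `z_max` (MOhm), `Q`, `Phi_L` (rad Hz).
#' @export
resonanceMeasures <- function(profile) {
  stopifnot(is(profile, "ImpedanceProfile"))
  f <- profile@freq
  mag <- Mod(profile@Z)
  ph <- Arg(profile@Z)
  i <- which.max(mag)
  f_R <- f[i]
  z_max <- mag[i]
  if (i > 1L && i < length(mag)) {
    win <- which(abs(f - f[i]) <= 1 + 1e-9)
    if (length(win) >= 5L) {
      fitc <- stats::coef(stats::lm(mag[win] ~ f[win] + I(f[win]^2)))
      a <- fitc[[3]]; b <- fitc[[2]]
      if (is.finite(a) && a < 0) {
        vertex <- -b / (2 * a)
        vertex <- max(min(vertex, max(f[win])), min(f[win]))
        f_R <- vertex
        z_max <- fitc[[1]] + b * vertex + a * vertex^2
      }
    } else {
      y1 <- mag[i - 1]; y2 <- mag[i]; y3 <- mag[i + 1]
      den <- y1 - 2 * y2 + y3
      delta <- if (abs(den) > 0) 0.5 * (y1 - y3) / den else 0
      delta <- max(min(delta, 0.5), -0.5)
      df <- f[2] - f[1]
      f_R <- f[i] + delta * df
      z_max <- y2 - 0.25 * (y1 - y3) * delta
    }
  }
  z05 <- stats::approx(f, mag, xout = max(0.5, f[1]), rule = 2)$y
  Phi_L <- pracma::trapz(f, pmax(ph, 0))
  list(f_R = f_R, z_max = z_max, Q = max(z_max / z05, 1), Phi_L = Phi_L)
}

#' Measurement map over somatoapical locations
#'
#' Computes the full measurement battery at each requested trunk location:
#' input resistance and the local/transfer impedance measures (resonance
#' frequency, peak amplitude, resonance strength, total inductive phase).
#'
#' @param model a [CableModel-class].
#' @param sites_um radial distances of the injection sites along the trunk
#'   (default soma, 150, 300 um).
#' @param protocol settings from [simProtocol()].
#' @param chirp_amp_pA chirp amplitude (after any normalization).
#' @param rin_amps_pA V-I amplitudes.
#' @param coord "radial" or "path" site lookup.
#' @return data.frame with columns `site_um` (requested), `seg`,
#'   `site_radial_um`, `site_path_um`, `measurement`, `value`; measurements
#'   are Rin, fR, Zloc_max, Q, PhiL (local) and fTR, ZTR_max, Q_TR, PhiL_TR
#'   (transfer).
#' @export
mapOverLocations <- function(model, sites_um = c(0, 150, 300),
                             protocol = simProtocol(),
                             chirp_amp_pA = protocol$chirp_amp_pA,
                             rin_amps_pA = protocol$rin_amps_pA,
                             coord = "radial") {
  sg <- model@grid@segments
  rows <- list()
  for (s in sites_um) {
    seg <- trunkSite(model, s, coord)
    rin <- measureInputResistance(model, seg, rin_amps_pA,
                                  pulse_ms = protocol$rin_pulse_ms,
                                  settle_ms = protocol$settle_ms,
                                  dt_ms = protocol$dt_ms,
                                  v_init = protocol$v_init)
    pair <- .impedancePair(model, seg, protocol, chirp_amp_pA)
    loc <- resonanceMeasures(pair$local)
    tr <- resonanceMeasures(pair$transfer)
    vals <- c(Rin = rin,
              fR = loc$f_R, Zloc_max = loc$z_max, Q = loc$Q, PhiL = loc$Phi_L,
              fTR = tr$f_R, ZTR_max = tr$z_max, Q_TR = tr$Q,
              PhiL_TR = tr$Phi_L)
    rows[[length(rows) + 1L]] <- data.frame(
      site_um = s, seg = seg,
      site_radial_um = sg$radial_um[seg], site_path_um = sg$path_um[seg],
      measurement = names(vals), value = unname(vals)
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Measurement as a function of total dendritic length
#'
#' Evaluates one measurement at a fixed trunk site in every member of an
#' atrophy series. Members in which the site cannot be resolved yield an
#' explicit NA gap.
#'
#' @param series a [PruneSeries-class].
#' @param site_um radial distance of the site (um).
#' @param measurement one of the nine measurement ids (see
#'   [mapOverLocations()]).
#' @param profile,dist,kinetics biophysics applied identically to every member.
#' @param protocol settings from [simProtocol()].
#' @param normalize_chirp scale the chirp by each member's somatic input
#'   resistance relative to the base member (used with HCN models).
#' @param d_lambda discretization fraction.
#' @return data.frame with `length_mm` and `value`.
#' @export
mapOverSeries <- function(series, site_um, measurement,
                          profile = passiveProfile(), dist = NULL,
                          kinetics = hcnKinetics(),
                          protocol = simProtocol(),
                          normalize_chirp = !is.null(dist),
                          d_lambda = 0.1) {
  stopifnot(is(series, "PruneSeries"))
  ids <- c("Rin", "fR", "Zloc_max", "Q", "PhiL",
           "fTR", "ZTR_max", "Q_TR", "PhiL_TR")
  if (!measurement %in% ids) {
    stop("unknown measurement '", measurement, "'")
  }
  base_rin <- NULL
  vals <- numeric(length(series@members))
  for (i in seq_along(series@members)) {
    model <- buildModel(series@members[[i]], profile, dist, kinetics,
                        d_lambda)
    seg <- trunkSite(model, site_um, "radial")
    sgr <- model@grid@segments$radial_um[seg]
    if (i == 1L && abs(sgr - site_um) > 50) {
      stop("configuration error: site ", site_um,
           " um cannot be resolved on the base morphology")
    }
    if (abs(sgr - site_um) > 50) {
      vals[i] <- NA_real_
      next
    }
    amp <- protocol$chirp_amp_pA
    if (normalize_chirp) {
      rin_som <- measureInputResistance(model, 1L, protocol$rin_amps_pA,
                                        pulse_ms = protocol$rin_pulse_ms,
                                        settle_ms = protocol$settle_ms,
                                        dt_ms = protocol$dt_ms,
                                        v_init = protocol$v_init)
      if (is.null(base_rin)) base_rin <- rin_som
      amp <- normalizeChirpAmplitude(base_rin, rin_som, protocol$chirp_amp_pA)
    }
    if (measurement == "Rin") {
      vals[i] <- measureInputResistance(model, seg, protocol$rin_amps_pA,
                                        pulse_ms = protocol$rin_pulse_ms,
                                        settle_ms = protocol$settle_ms,
                                        dt_ms = protocol$dt_ms,
                                        v_init = protocol$v_init)
    } else {
      pair <- .impedancePair(model, seg, protocol, amp)
      side <- if (measurement %in% c("fR", "Zloc_max", "Q", "PhiL")) {
        resonanceMeasures(pair$local)
      } else {
        resonanceMeasures(pair$transfer)
      }
      vals[i] <- switch(measurement,
        fR = , fTR = side$f_R,
        Zloc_max = , ZTR_max = side$z_max,
        Q = , Q_TR = side$Q,
        PhiL = , PhiL_TR = side$Phi_L
      )
    }
  }
  data.frame(length_mm = series@achieved_mm, value = vals)
}

#' @describeIn frequencies frequency grid accessor.
#' @export
setMethod("frequencies", "ImpedanceProfile", function(x) x@freq)

#' @describeIn impedanceValues complex impedance accessor.
#' @export
setMethod("impedanceValues", "ImpedanceProfile", function(x) x@Z)

setMethod("show", "ImpedanceProfile", function(object) {
  m <- resonanceMeasures(object)
  cat(sprintf("ImpedanceProfile (%s): %.1f-%.1f Hz, f_R = %.2f Hz, |Z|max = %.1f MOhm, Q = %.2f\n",
              object@kind, min(object@freq), max(object@freq),
              m$f_R, m$z_max, m$Q))
})
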