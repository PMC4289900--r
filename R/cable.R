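#' @include AllClasses.R biophysics.R
#' @useDynLib resonmap, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Assemble a cable model from a grid and a mechanism table
#'
#' Converts specific membrane quantities into absolute per-segment values
#' (pF, nS) using frustum areas, and derives the axial coupling conductance
#' between neighboring segment midpoints from the series resistance of the
#' two half-segments (each using its own local axial resistivity, length and
#' diameter).
#'
#' When `hold_mV` is given (default -65) and the model carries HCN
#' conductance, the leak reversal of each segment is offset so that the
#' uniform holding potential is an exact DC steady state: the battery absorbs
#' the standing h current, the way a holding current clamps the baseline in
#' the corresponding experiments. Measurements then probe the model at the
#' stated potential rather than at a depolarized drifted rest.
#'
#' @param grid a [CompartmentGrid-class].
#' @param mech mechanism table from [assignMechanisms()].
#' @param kinetics an [HcnKinetics-class] (used when any gh > 0; harmless
#'   otherwise).
#' @param hold_mV holding potential balanced by the leak battery (NULL to
#'   leave the leak reversal at its nominal value and let the model find its
#'   own rest).
#' @return a [CableModel-class].
#' @export
buildCableModel <- function(grid, mech, kinetics = hcnKinetics(),
                            hold_mV = -65) {
  stopifnot(is(grid, "CompartmentGrid"))
  sg <- grid@segments
  if (nrow(sg) != nrow(mech) || any(sg$seg != mech$seg)) {
    stop("grid and mechanism table are inconsistent")
  }
  if (any(sg$diam_um <= 0)) {
    stop("structural error: zero-diameter segment in grid")
  }
  area_cm2 <- sg$area_um2 * 1e-8
  cap_pF <- mech$cm_uf_cm2 * area_cm2 * 1e6
  g_leak <- area_cm2 / (mech$rm_kohm_cm2 * 1e3) * 1e9
  gh <- mech$gh_uS_cm2 * 1e-6 * area_cm2 * 1e9

  # half-segment axial resistance in Ohm
  halfR <- mech$ra_ohm_cm * (sg$length_um / 2) /
    (pi * (sg$diam_um / 2)^2) * 1e4
  parent <- sg$parent_seg
  g_axial <- numeric(nrow(sg))
  nz <- which(parent > 0L)
  g_axial[nz] <- 1e9 / (halfR[nz] + halfR[parent[nz]])

  if (sum(parent == 0L) != 1L || any(parent >= sg$seg)) {
    stop("structural error: disconnected grid")
  }

  e_leak <- rep(attr(mech, "e_pas") %||% -65, nrow(sg))
  if (!is.null(hold_mV) && any(gh > 0)) {
    m_hold <- hcnActivation(hold_mV, kinetics)$m_inf
    e_leak <- hold_mV - gh * m_hold * (kinetics@e_h - hold_mV) / g_leak
  }

  obj <- new("CableModel",
    grid = grid, mech = mech,
    parent = as.integer(parent),
    cap_pF = cap_pF, g_leak_nS = g_leak, gh_nS = gh,
    g_axial_nS = g_axial,
    e_leak = e_leak,
    e_h = kinetics@e_h,
    kinetics = kinetics
  )
  validObject(obj)
  obj
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build a full model from a morphology in one call
#'
#' Convenience wrapper: discretize with the d-lambda rule, assign mechanisms,
#' assemble the cable system.
#'
#' @param morph a [NeuronMorphology-class].
#' @param profile a [PassiveProfile-class].
#' @param dist an [HcnDistribution-class] or NULL for a passive model.
#' @param kinetics an [HcnKinetics-class].
#' @param d_lambda discretization fraction (default 0.1).
#' @param hold_mV holding potential passed to [buildCableModel()].
#' @return a [CableModel-class].
#' @export
buildModel <- function(morph, profile = passiveProfile(), dist = NULL,
                       kinetics = hcnKinetics(), d_lambda = 0.1,
                       hold_mV = -65) {
  grid <- compartmentalize(morph, profile, d_lambda)
  mech <- assignMechanisms(grid, profile, dist)
  attr(mech, "e_pas") <- profile@e_pas
  buildCableModel(grid, mech, kinetics, hold_mV)
}

#' DC steady state of a cable model
#'
#' Solves the nonlinear DC system (leak plus HCN at its voltage-dependent
#' steady-state activation) by damped fixed-point iteration on the gating
#' variable with an exact sparse linear solve for the voltages at each
#' iterate. Converges when the net current into every segment is below
#' `tol_pA`.
#'
#' @param model a [CableModel-class].
#' @param injections named numeric vector of DC currents in pA; names are
#'   segment indices (or a plain vector of length nSegments).
#' @param tol_pA residual tolerance (default 1e-3 pA).
#' @param max_iter iteration cap.
#' @return numeric vector of steady-state membrane potentials (mV).
#' @export
steadyState <- function(model, injections = NULL, tol_pA = 1e-3,
                        max_iter = 200) {
  n <- length(model@parent)
  I <- numeric(n)
  if (!is.null(injections)) {
    if (is.null(names(injections)) && length(injections) == n) {
      I <- as.numeric(injections)
    } else {
      idx <- as.integer(names(injections))
      if (any(is.na(idx)) || any(idx < 1L) || any(idx > n)) {
        stop("injection site out of range")
      }
      I[idx] <- I[idx] + as.numeric(injections)
    }
  }
  parent <- model@parent
  nz <- which(parent > 0L)
  ii <- c(seq_len(n), nz, parent[nz])
  jj <- c(seq_len(n), parent[nz], nz)
  gax <- model@g_axial_nS
  kin <- model@kinetics
  has_h <- any(model@gh_nS > 0)

  v <- rep(-65, n)
  damp <- 1
  for (iter in seq_len(max_iter)) {
    m <- if (has_h) hcnActivation(v, kin)$m_inf else numeric(n)
    gm <- model@g_leak_nS + model@gh_nS * m
    diagv <- gm
    diagv[nz] <- diagv[nz] + gax[nz]
    addp <- tapply(gax[nz], parent[nz], sum)
    diagv[as.integer(names(addp))] <- diagv[as.integer(names(addp))] + addp
    A <- Matrix::sparseMatrix(
      i = ii, j = jj,
      x = c(diagv, -gax[nz], -gax[nz]), dims = c(n, n)
    )
    b <- model@g_leak_nS * model@e_leak + model@gh_nS * m * model@e_h + I
    v_new <- as.numeric(Matrix::solve(A, b))
    v <- v + damp * (v_new - v)
    # residual: net current into each segment
    m <- if (has_h) hcnActivation(v, kin)$m_inf else numeric(n)
    res <- model@g_leak_nS * (model@e_leak - v) +
      model@gh_nS * m * (model@e_h - v) + I
    res[nz] <- res[nz] + gax[nz] * (v[parent[nz]] - v[nz])
    flow <- tapply(gax[nz] * (v[nz] - v[parent[nz]]), parent[nz], sum)
    res[as.integer(names(flow))] <- res[as.integer(names(flow))] + flow
    if (max(abs(res)) < tol_pA) return(v)
    if (iter > 50) damp <- 0.5
  }
  stop("numerical error: steady state did not converge in ", max_iter,
       " iterations (max residual ", signif(max(abs(res)), 3), " pA)")
}

#' Integrate a cable model under current injection
#'
#' Advances the membrane potential with an implicit scheme (trapezoid rule by
#' default, backward Euler as fallback) solving the branched-tree linear
#' system exactly per step by ordered elimination; the HCN gate is updated by
#' the locally exact exponential rule. The initial state is `v_init`
#' everywhere with gates at their steady-state activation for `v_init`.
#'
#' @param model a [CableModel-class].
#' @param stim either a numeric waveform (single injection site) or a matrix
#'   with one column per site; sampled at step boundaries, so a waveform of
#'   length N simulates N-1 steps.
#' @param stim_sites integer segment indices of the injection site(s).
#' @param record_sites integer segment indices to record.
#' @param dt_ms time step (ms; default 0.1; the full-resolution protocol uses
#'   0.025).
#' @param v_init initial membrane potential (mV, default -65).
#' @param method "cn" (trapezoid, second order) or "euler" (backward Euler).
#' @return list with `time` (ms) and `v` (matrix, one column per record site).
#' @export
runSimulation <- function(model, stim, stim_sites, record_sites,
                          dt_ms = 0.1, v_init = -65, method = c("cn", "euler")) {
  method <- match.arg(method)
  n <- length(model@parent)
  if (is.vector(stim)) stim <- matrix(stim, ncol = 1)
  stopifnot(length(stim_sites) == ncol(stim))
  if (any(stim_sites < 1L | stim_sites > n) ||
      any(record_sites < 1L | record_sites > n)) {
    stop("stimulus/record site out of range")
  }
  nsteps <- nrow(stim) - 1L
  kin <- model@kinetics
  qfac <- kin@q10^((kin@t_ref - kin@t_sim) / 10)
  vmat <- .simulate_cable_cpp(
    parent = model@parent - 1L,
    cap_pF = model@cap_pF,
    g_leak = model@g_leak_nS,
    e_leak = model@e_leak,
    gh_max = model@gh_nS,
    e_h = model@e_h,
    g_axial = model@g_axial_nS,
    v_half = kin@v_half, k_slope = kin@k,
    tau_peak = kin@tau_peak, tau_vmid = kin@tau_vmid,
    tau_width = kin@tau_width, q_factor = qfac,
    dt = dt_ms, nsteps = nsteps, v_init = v_init,
    stim_sites = as.integer(stim_sites) - 1L,
    stim = stim,
    record_sites = as.integer(record_sites) - 1L,
    theta = if (method == "cn") 0.5 else 1.0
  )
  colnames(vmat) <- as.character(record_sites)
  list(time = seq(0, by = dt_ms, length.out = nsteps + 1L), v = vmat,
       dt_ms = dt_ms)
}

#' Locate the trunk segment nearest a somatoapical coordinate
#'
#' @param model a [CableModel-class] (or [CompartmentGrid-class]).
#' @param distance_um target distance from the soma (um).
#' @param coord "radial" (default, straight-line) or "path" (arc length).
#' @return integer segment index (1 = soma when `distance_um` is closest to 0).
#' @export
trunkSite <- function(model, distance_um, coord = c("radial", "path")) {
  coord <- match.arg(coord)
  sg <- if (is(model, "CableModel")) model@grid@segments else model@segments
  cand <- which(sg$is_trunk | sg$section == 0L)
  d <- if (coord == "radial") sg$radial_um[cand] else sg$path_um[cand]
  cand[which.min(abs(d - distance_um))]
}

setMethod("show", "CableModel", function(object) {
  cat("CableModel:", length(object@parent), "segments;",
      if (any(object@gh_nS > 0)) "HCN-endowed" else "passive", "\n")
})
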