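#' @include AllClasses.R
NULL

#' Passive-property profile constructor
#'
#' Defaults reproduce a CA1 pyramidal model whose somatoapical membrane and
#' axial resistivities fall sigmoidally with radial distance: Rm from 55 to
#' 20 kOhm cm^2 and Ra from 70 to 30 Ohm cm, with midpoint 250 um and slope
#' 50 um, Cm = 1 uF/cm^2, resting leak reversal -65 mV.
#'
#' @param rm_som,rm_end membrane resistivity at soma / distal asymptote (kOhm cm^2).
#' @param ra_som,ra_end axial resistivity at soma / distal asymptote (Ohm cm).
#' @param half_um,slope_um sigmoid midpoint and slope (um).
#' @param cm specific membrane capacitance (uF/cm^2).
#' @param e_pas leak reversal (mV).
#' @return a [PassiveProfile-class].
#' @export
passiveProfile <- function(rm_som = 55, rm_end = 20, ra_som = 70, ra_end = 30,
                           half_um = 250, slope_um = 50, cm = 1, e_pas = -65) {
  obj <- new("PassiveProfile",
    rm_som = rm_som, rm_end = rm_end, ra_som = ra_som, ra_end = ra_end,
    half_um = half_um, slope_um = slope_um, cm = cm, e_pas = e_pas
  )
  validObject(obj)
  obj
}

#' HCN conductance gradient constructor
#'
#' Defaults place a 25-fold sigmoidal rise over a 50 uS/cm^2 somatic density,
#' with midpoint 350 um and slope 15 um, i.e.
#' gh(x) = 50 (1 + 25 / (1 + exp(-(x - 350)/15))) uS/cm^2.
#'
#' @param g_base somatic density (uS/cm^2).
#' @param fold distal fold increase.
#' @param half_um,slope_um sigmoid midpoint and slope (um).
#' @return an [HcnDistribution-class].
#' @export
hcnDistribution <- function(g_base = 50, fold = 25, half_um = 350, slope_um = 15) {
  obj <- new("HcnDistribution",
    g_base = g_base, fold = fold, half_um = half_um, slope_um = slope_um
  )
  validObject(obj)
  obj
}

#' HCN gating kinetics constructor
#'
#' Single first-order hyperpolarization-activated gate with half-activation
#' at -82 mV (slope 9 mV), a bell-shaped time constant peaking at 60 ms near
#' -75 mV at the 27 degree reference temperature, Q10 = 4.5 and reversal
#' -30 mV; simulations default to 34 degrees, so tau is scaled by
#' q10^((t_ref - t_sim)/10) ~= 0.349 (peak ~21 ms, within the range reported
#' for CA1 dendritic h currents at physiological temperature).
#'
#' @param v_half,k activation midpoint and inverse slope (mV).
#' @param tau_peak,tau_vmid,tau_width bell-shaped tau parameters (ms, mV, mV).
#' @param e_h reversal potential (mV).
#' @param q10 temperature sensitivity.
#' @param t_ref,t_sim reference and simulation temperatures (degrees C).
#' @return an [HcnKinetics-class].
#' @export
hcnKinetics <- function(v_half = -82, k = 9, tau_peak = 60, tau_vmid = -75,
                        tau_width = 20, e_h = -30, q10 = 4.5,
                        t_ref = 27, t_sim = 34) {
  obj <- new("HcnKinetics",
    v_half = v_half, k = k, tau_peak = tau_peak, tau_vmid = tau_vmid,
    tau_width = tau_width, e_h = e_h, q10 = q10, t_ref = t_ref, t_sim = t_sim
  )
  validObject(obj)
  obj
}

#' Evaluate the membrane resistivity profile
#'
#' Rm(x) = rm_som + (rm_end - rm_som) / (1 + exp((half - x)/slope)).
#'
#' @param x_um radial distance from the soma (um, >= 0).
#' @param profile a [PassiveProfile-class].
#' @return kOhm cm^2.
#' @export
membraneResistivity <- function(x_um, profile = passiveProfile()) {
  stopifnot(all(x_um >= 0))
  profile@rm_som + (profile@rm_end - profile@rm_som) /
    (1 + exp((profile@half_um - x_um) / profile@slope_um))
}

#' Evaluate the axial resistivity profile
#'
#' Ra(x) = ra_som + (ra_end - ra_som) / (1 + exp((half - x)/slope)).
#'
#' @inheritParams membraneResistivity
#' @return Ohm cm.
#' @export
axialResistivity <- function(x_um, profile = passiveProfile()) {
  stopifnot(all(x_um >= 0))
  profile@ra_som + (profile@ra_end - profile@ra_som) /
    (1 + exp((profile@half_um - x_um) / profile@slope_um))
}

#' Evaluate the HCN maximal-conductance gradient
#'
#' gh(x) = g_base (1 + fold / (1 + exp(-(x - half)/slope))).
#'
#' @param x_um radial distance from the soma (um, >= 0).
#' @param dist an [HcnDistribution-class].
#' @return uS/cm^2.
#' @export
hcnDensity <- function(x_um, dist = hcnDistribution()) {
  stopifnot(all(x_um >= 0))
  dist@g_base * (1 + dist@fold /
    (1 + exp(-(x_um - dist@half_um) / dist@slope_um)))
}

#' HCN gate steady state and time constant
#'
#' @param v membrane potential (mV).
#' @param kin an [HcnKinetics-class].
#' @return list with `m_inf` (fraction, decreasing in v) and `tau` (ms, at
#'   the simulation temperature).
#' @export
hcnActivation <- function(v, kin = hcnKinetics()) {
  m_inf <- 1 / (1 + exp((v - kin@v_half) / kin@k))
  qfac <- kin@q10^((kin@t_ref - kin@t_sim) / 10)
  u <- (v - kin@tau_vmid) / kin@tau_width
  tau <- qfac * 2 * kin@tau_peak / (exp(u) + exp(-u))
  list(m_inf = m_inf, tau = tau)
}

#' Assign membrane mechanisms to a compartment grid
#'
#' Apical segments (type 4) take the profile values at their midpoint radial
#' distance; somatic and basal segments take the somatic (x = 0) values, as
#' do axonal segments if present. With `dist = NULL` the model is passive
#' (gh = 0 everywhere).
#'
#' @param grid a [CompartmentGrid-class].
#' @param profile a [PassiveProfile-class].
#' @param dist an [HcnDistribution-class], or NULL for a passive model.
#' @return data.frame with one row per segment: `seg`, `rm_kohm_cm2`,
#'   `ra_ohm_cm`, `cm_uf_cm2`, `gh_uS_cm2`.
#' @export
assignMechanisms <- function(grid, profile = passiveProfile(), dist = NULL) {
  stopifnot(is(grid, "CompartmentGrid"))
  sg <- grid@segments
  xeff <- ifelse(sg$type == 4L, sg$radial_um, 0)
  gh <- if (is.null(dist)) {
    rep(0, nrow(sg))
  } else {
    hcnDensity(xeff, dist)
  }
  data.frame(
    seg = sg$seg,
    rm_kohm_cm2 = membraneResistivity(xeff, profile),
    ra_ohm_cm = axialResistivity(xeff, profile),
    cm_uf_cm2 = rep(profile@cm, nrow(sg)),
    gh_uS_cm2 = gh
  )
}

#' Dump evaluated biophysical profiles along the trunk
#'
#' @param grid a [CompartmentGrid-class].
#' @param profile a [PassiveProfile-class].
#' @param dist an [HcnDistribution-class] or NULL.
#' @param path optional CSV output path.
#' @return data.frame of trunk segment midpoints with evaluated Rm, Ra, gh.
#' @export
profileDump <- function(grid, profile = passiveProfile(), dist = NULL,
                        path = NULL) {
  mech <- assignMechanisms(grid, profile, dist)
  sg <- grid@segments
  keep <- sg$is_trunk | sg$section == 0L
  out <- cbind(sg[keep, c("seg", "path_um", "radial_um", "diam_um")],
               mech[keep, c("rm_kohm_cm2", "ra_ohm_cm", "gh_uS_cm2")])
  out <- out[order(out$path_um), ]
  rownames(out) <- NULL
  if (!is.null(path)) {
    utils::write.csv(out, path, row.names = FALSE)
    return(invisible(out))
  }
  out
}
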