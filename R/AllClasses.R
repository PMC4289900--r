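#' @import methods
NULL

#' Neuronal morphology with SWC semantics
#'
#' A rooted tree of 3D points with radii. Nodes follow SWC conventions:
#' type 1 = soma, 3 = basal dendrite, 4 = apical dendrite (type 2, axon, is
#' carried but excluded from dendritic measures). The constructor
#' [neuronMorphology()] derives per-node path/radial distances and the
#' decomposition into unbranched sections, so objects are always internally
#' consistent.
#'
#' @slot nodes data.frame with columns `id`, `type`, `x`, `y`, `z`, `radius`,
#'   `parent`, plus derived `path_um` and `radial_um`.
#' @slot sections data.frame with one row per unbranched section: `section`,
#'   `parent_section` (0 for soma-attached), `length_um`, `type`, `is_trunk`,
#'   `is_terminal`, `mid_radial_um`.
#' @slot sectionNodes list of integer node-id vectors, one per section,
#'   ordered proximal to distal (excluding the anchor node).
#' @slot somaCentroid numeric length-3, radius-weighted centroid of soma nodes
#'   (micrometres); the origin for radial distances.
#' @slot labels optional per-node subtree tags ("soma", "trunk", "oblique",
#'   "basal", ...); when present, trunk identification uses the tags instead
#'   of the max-radial-tip heuristic. Tags survive pruning but not SWC
#'   round-trips (the format has no field for them).
#' @slot breakIds node ids at which sections end even without branching;
#'   pruning populates this with the base tree's branch points so that the
#'   surviving sections (and hence the d-lambda segments) of a pruned member
#'   are identical to the base tree's, enabling same-location comparisons.
#' @exportClass NeuronMorphology
setClass("NeuronMorphology",
  representation(
    nodes = "data.frame",
    sections = "data.frame",
    sectionNodes = "list",
    somaCentroid = "numeric",
    labels = "character",
    breakIds = "integer"
  )
)

setValidity("NeuronMorphology", function(object) {
  nd <- object@nodes
  msgs <- character()
  req <- c("id", "type", "x", "y", "z", "radius", "parent")
  if (!all(req %in% names(nd))) {
    return(paste("nodes must have columns", paste(req, collapse = ", ")))
  }
  if (nrow(nd) == 0L) msgs <- c(msgs, "morphology has no nodes")
  if (any(nd$radius <= 0)) msgs <- c(msgs, "all radii must be strictly positive")
  if (anyDuplicated(nd$id)) msgs <- c(msgs, "node ids must be unique")
  roots <- which(nd$parent == -1L)
  if (length(roots) != 1L) msgs <- c(msgs, "exactly one root node required")
  nonroot <- nd$parent != -1L
  if (!all(nd$parent[nonroot] %in% nd$id)) {
    msgs <- c(msgs, "every non-root parent id must resolve to a node")
  }
  # parent precedes child in file order (topological order)
  pos <- match(nd$parent[nonroot], nd$id)
  if (any(pos >= which(nonroot))) {
    msgs <- c(msgs, "parents must precede children")
  }
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' Compartmental discretization of a morphology
#'
#' Produced by [compartmentalize()] using the d-lambda rule: every section is
#' split into the smallest odd number of equal-length segments shorter than
#' `d_lambda` times the 100 Hz space constant of that section. Segment 1 is
#' always the soma compartment.
#'
#' @slot segments data.frame with one row per segment: `seg`, `section`
#'   (0 for soma), `parent_seg` (0 for soma), `type`, `is_trunk`, `path_um`,
#'   `radial_um` (midpoint distances), `diam_um`, `length_um`, `area_um2`.
#' @slot d_lambda numeric fraction of lambda_100 used as the length bound.
#' @slot morphology the source [NeuronMorphology-class].
#' @exportClass CompartmentGrid
setClass("CompartmentGrid",
  representation(
    segments = "data.frame",
    d_lambda = "numeric",
    morphology = "NeuronMorphology"
  )
)

setValidity("CompartmentGrid", function(object) {
  sg <- object@segments
  msgs <- character()
  if (any(sg$area_um2 <= 0)) msgs <- c(msgs, "segment areas must be positive")
  if (any(sg$diam_um <= 0)) msgs <- c(msgs, "segment diameters must be positive")
  counts <- table(sg$section[sg$section > 0])
  if (length(counts) && any(counts %% 2L == 0L)) {
    msgs <- c(msgs, "per-section segment counts must be odd")
  }
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' Sigmoidal passive-property profiles along the somatoapical axis
#'
#' Specific membrane resistivity and axial resistivity vary with radial
#' distance x from the soma as
#' R(x) = R_som + (R_end - R_som) / (1 + exp((half - x)/slope)).
#' Basal and somatic compartments take the somatic (x = 0) values.
#'
#' @slot rm_som,rm_end membrane resistivity at soma / distal asymptote (kOhm cm^2).
#' @slot ra_som,ra_end axial resistivity at soma / distal asymptote (Ohm cm).
#' @slot half_um,slope_um sigmoid midpoint and slope (micrometres).
#' @slot cm specific capacitance (uF/cm^2).
#' @slot e_pas leak reversal potential (mV).
#' @exportClass PassiveProfile
setClass("PassiveProfile",
  representation(
    rm_som = "numeric", rm_end = "numeric",
    ra_som = "numeric", ra_end = "numeric",
    half_um = "numeric", slope_um = "numeric",
    cm = "numeric", e_pas = "numeric"
  )
)

setValidity("PassiveProfile", function(object) {
  if (any(c(object@rm_som, object@rm_end, object@ra_som, object@ra_end,
            object@cm) <= 0)) {
    return("resistivities and capacitance must be positive")
  }
  if (object@slope_um <= 0) return("slope_um must be positive")
  TRUE
})

#' Sigmoidal HCN maximal-conductance gradient
#'
#' gh(x) = g_base * (1 + fold / (1 + exp(-(x - half)/slope))) in uS/cm^2 as a
#' function of radial distance x; basal and somatic compartments take the
#' x = 0 value.
#'
#' @slot g_base somatic density (uS/cm^2).
#' @slot fold distal fold increase over `g_base` (dimensionless).
#' @slot half_um,slope_um sigmoid midpoint and slope (micrometres).
#' @exportClass HcnDistribution
setClass("HcnDistribution",
  representation(
    g_base = "numeric", fold = "numeric",
    half_um = "numeric", slope_um = "numeric"
  )
)

setValidity("HcnDistribution", function(object) {
  if (object@g_base < 0 || object@fold < 0) {
    return("g_base and fold must be non-negative")
  }
  if (object@slope_um <= 0) return("slope_um must be positive")
  TRUE
})

#' HCN (h) channel gating kinetics
#'
#' Single first-order hyperpolarization-activated gate:
#' m_inf(V) = 1/(1 + exp((V - v_half)/k)) with k > 0 (so m_inf decreases with
#' depolarization), and a bell-shaped voltage-dependent time constant
#' tau(V) = 2 * tau_peak / (exp((V - tau_vmid)/tau_width) +
#' exp(-(V - tau_vmid)/tau_width)) defined at the reference temperature and
#' scaled by q10^((t_ref - t_sim)/10) at the simulation temperature.
#'
#' @slot v_half half-activation voltage (mV).
#' @slot k inverse slope of the activation curve (mV, > 0).
#' @slot tau_peak peak time constant at `t_ref` (ms).
#' @slot tau_vmid voltage of the tau peak (mV).
#' @slot tau_width width of the tau bell (mV).
#' @slot e_h reversal potential of the mixed cationic current (mV).
#' @slot q10 temperature sensitivity factor.
#' @slot t_ref,t_sim reference and simulation temperatures (degrees C).
#' @exportClass HcnKinetics
setClass("HcnKinetics",
  representation(
    v_half = "numeric", k = "numeric",
    tau_peak = "numeric", tau_vmid = "numeric", tau_width = "numeric",
    e_h = "numeric", q10 = "numeric", t_ref = "numeric", t_sim = "numeric"
  )
)

setValidity("HcnKinetics", function(object) {
  if (object@k <= 0) return("k must be positive")
  if (object@q10 <= 0) return("q10 must be positive")
  if (object@tau_peak <= 0 || object@tau_width <= 0) {
    return("tau parameters must be positive")
  }
  TRUE
})

#' Cable model: discretized segments with attached mechanisms
#'
#' Built by [buildCableModel()]. Internal units are pA, mV, nS, pF, ms, so
#' that I = C dV/dt and I = g (V - E) hold without conversion factors.
#'
#' @slot grid the [CompartmentGrid-class].
#' @slot mech per-segment mechanism table (`seg`, `rm_kohm_cm2`, `ra_ohm_cm`,
#'   `cm_uf_cm2`, `gh_uS_cm2`) from [assignMechanisms()].
#' @slot parent integer parent segment (0 for the root/soma segment).
#' @slot cap_pF,g_leak_nS,gh_nS per-segment absolute capacitance and conductances.
#' @slot g_axial_nS coupling conductance between each segment's midpoint and
#'   its parent's midpoint (0 for the root).
#' @slot e_leak per-segment leak reversal (mV); when the model is held at a
#'   fixed potential the DC holding current is absorbed into this battery.
#' @slot e_h HCN reversal potential (mV).
#' @slot kinetics the [HcnKinetics-class] used for the h current.
#' @exportClass CableModel
setClass("CableModel",
  representation(
    grid = "CompartmentGrid",
    mech = "data.frame",
    parent = "integer",
    cap_pF = "numeric",
    g_leak_nS = "numeric",
    gh_nS = "numeric",
    g_axial_nS = "numeric",
    e_leak = "numeric",
    e_h = "numeric",
    kinetics = "HcnKinetics"
  )
)

setValidity("CableModel", function(object) {
  n <- length(object@parent)
  msgs <- character()
  if (any(lengths(list(object@cap_pF, object@g_leak_nS, object@gh_nS,
                       object@g_axial_nS, object@e_leak)) != n)) {
    msgs <- c(msgs, "per-segment vectors must have equal length")
  }
  if (any(object@cap_pF <= 0)) msgs <- c(msgs, "capacitances must be positive")
  if (any(object@g_leak_nS < 0) || any(object@gh_nS < 0) ||
      any(object@g_axial_nS < 0)) {
    msgs <- c(msgs, "conductances must be non-negative")
  }
  if (n > 1 && any(object@g_axial_nS[-1] <= 0)) {
    msgs <- c(msgs, "non-root segments must couple to their parent")
  }
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' Complex impedance over a frequency band
#'
#' @slot freq strictly increasing frequency grid (Hz).
#' @slot Z complex impedance (megaohms).
#' @slot kind "local" (record at the injection site) or "transfer" (record at
#'   the soma).
#' @slot site_um radial distance of the injection site (micrometres).
#' @exportClass ImpedanceProfile
setClass("ImpedanceProfile",
  representation(
    freq = "numeric",
    Z = "complex",
    kind = "character",
    site_um = "numeric"
  )
)

setValidity("ImpedanceProfile", function(object) {
  if (length(object@freq) != length(object@Z)) {
    return("freq and Z must have equal length")
  }
  if (is.unsorted(object@freq, strictly = TRUE)) {
    return("frequency grid must be strictly increasing")
  }
  if (!object@kind %in% c("local", "transfer")) {
    return("kind must be 'local' or 'transfer'")
  }
  TRUE
})

#' Atrophy series produced by uniform pruning
#'
#' Ordered morphologies of decreasing total dendritic length; each member is
#' a subtree of the previous one (chained pruning), so any surviving segment
#' keeps its base-tree geometry.
#'
#' @slot members list of [NeuronMorphology-class] objects, base first.
#' @slot target_mm,achieved_mm target and achieved total dendritic lengths (mm).
#' @slot provenance list (one element per member) with `removed_sections`,
#'   `removed_nodes` and the per-stratum removal ledger.
#' @exportClass PruneSeries
setClass("PruneSeries",
  representation(
    members = "list",
    target_mm = "numeric",
    achieved_mm = "numeric",
    provenance = "list"
  )
)

setValidity("PruneSeries", function(object) {
  n <- length(object@members)
  if (length(object@target_mm) != n || length(object@achieved_mm) != n) {
    return("targets/achieved lengths must match member count")
  }
  if (n > 1 && any(diff(object@achieved_mm) > 1e-9)) {
    return("achieved lengths must be non-increasing")
  }
  TRUE
})

#' Spatial influence field of a localized channel cluster
#'
#' For a measurement M (input resistance or resonance frequency) the
#' unnormalized influence factor at trunk location x is
#' IF(x) = |M_org(x) - M_new(x)| / M_org(x), where M_new is measured with the
#' cluster inserted; Lambda(x) = IF(x)/max IF is its max-normalized form.
#'
#' @slot table data.frame with columns `x_um` (trunk path distance), `m_org`,
#'   `m_new`, `IF`, `Lambda`.
#' @slot measurement "Rin" or "fR".
#' @slot background "passive" or "gradient".
#' @slot cluster list with `path_um` (cluster location), `total_nS`, `seg`.
#' @slot degenerate TRUE when max IF = 0 (Lambda undefined, reported as 0).
#' @exportClass InfluenceField
setClass("InfluenceField",
  representation(
    table = "data.frame",
    measurement = "character",
    background = "character",
    cluster = "list",
    degenerate = "logical"
  )
)

#' Full study result
#'
#' @slot maps data.frame of all nine measurements on the (member x site)
#'   grid: `length_mm`, `site_um`, `background`, `measurement`, `value`.
#' @slot constriction data.frame of distal/proximal ratios per member.
#' @slot influence data.frame of influence-field AUC values per member.
#' @slot provenance list: config echo, seed, achieved lengths.
#' @exportClass StudyResult
setClass("StudyResult",
  representation(
    maps = "data.frame",
    constriction = "data.frame",
    influence = "data.frame",
    provenance = "list"
  )
)
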