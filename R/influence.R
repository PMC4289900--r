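#' @include AllClasses.R impedance.R
NULL

#' Insert a localized HCN-conductance cluster
#'
#' Adds a total conductance to the segment nearest `path_um` along the apical
#' trunk. The addition is normalized by the host segment's surface area (the
#' specific density added is `total_nS / area`), so the same cluster on a
#' segment of twice the area contributes half the density. The input model is
#' not modified.
#'
#' @param model a [CableModel-class].
#' @param path_um cluster location as path distance from the soma along the
#'   trunk (um). The default used by [influenceField()] is the midpoint of
#'   the trunk path.
#' @param total_nS total cluster conductance (nS).
#' @return a new [CableModel-class] with the cluster inserted; the chosen
#'   segment index is in attribute `cluster_seg`.
#' @export
insertCluster <- function(model, path_um, total_nS) {
  stopifnot(is(model, "CableModel"))
  sg <- model@grid@segments
  trunk <- which(sg$is_trunk)
  if (!length(trunk)) stop("configuration error: model has no apical trunk")
  if (path_um > max(sg$path_um[trunk] + sg$length_um[trunk] / 2) ||
      path_um < 0) {
    stop("configuration error: cluster location beyond the trunk extent")
  }
  seg <- trunk[which.min(abs(sg$path_um[trunk] - path_um))]
  out <- model
  out@gh_nS[seg] <- out@gh_nS[seg] + total_nS
  out@mech$gh_uS_cm2[seg] <- out@mech$gh_uS_cm2[seg] +
    total_nS / (sg$area_um2[seg] * 1e-8) * 1e-3 # nS/cm^2 -> uS/cm^2
  attr(out, "cluster_seg") <- seg
  out
}

#' Physiologically scaled default cluster conductance
#'
#' Total conductance equal to the gradient's density at its sigmoid midpoint
#' (675 uS/cm^2 with defaults) times the host segment's area.
#'
#' @param model a [CableModel-class].
#' @param path_um cluster location (um path distance).
#' @param dist an [HcnDistribution-class] supplying the reference density.
#' @return total conductance in nS.
#' @export
defaultClusterConductance <- function(model, path_um,
                                      dist = hcnDistribution()) {
  sg <- model@grid@segments
  trunk <- which(sg$is_trunk)
  seg <- trunk[which.min(abs(sg$path_um[trunk] - path_um))]
  gh <- hcnDensity(dist@half_um, dist) # uS/cm^2 at the midpoint
  gh * 1e-6 * (sg$area_um2[seg] * 1e-8) * 1e9 # -> nS
}

# Measurement of Rin or fR at a set of segments.
.measureAt <- function(model, segs, measurement, protocol, rin_amps) {
  vapply(segs, function(seg) {
    if (measurement == "Rin") {
      measureInputResistance(model, seg, rin_amps,
                             pulse_ms = protocol$rin_pulse_ms,
                             settle_ms = protocol$settle_ms,
                             dt_ms = protocol$dt_ms, v_init = protocol$v_init)
    } else {
      prof <- localImpedance(model, seg, protocol)
      resonanceMeasures(prof)$f_R
    }
  }, numeric(1))
}

#' Influence field of an HCN cluster on a measurement
#'
#' Measures `measurement` (input resistance or local resonance frequency) at
#' trunk locations with and without a conductance cluster and forms the
#' unnormalized influence factor IF(x) = |M_org(x) - M_new(x)| / M_org(x)
#' and its max-normalized version Lambda(x) = IF(x)/max IF. Works on a
#' passive background (gh = 0 apart from the cluster) or on the gradient
#' background (cluster appended to the existing distribution).
#'
#' @param model a [CableModel-class] (passive or HCN-endowed; this defines
#'   the background).
#' @param measurement "Rin" or "fR".
#' @param cluster_path_um cluster location (default: trunk path midpoint).
#' @param total_nS total cluster conductance (default 100 nS, large enough
#'   to reshape both measurements visibly on a full-size tree; see
#'   [defaultClusterConductance()] for an area-scaled alternative).
#' @param sites segment indices of measurement locations (default: every
#'   trunk segment midpoint, soma included). The cluster's host segment is
#'   always added so the field peak is resolvable.
#' @param protocol settings from [simProtocol()].
#' @param rin_amps_pA V-I amplitudes for Rin (default reduced range).
#' @return an [InfluenceField-class]. When max IF = 0 the field is flagged
#'   degenerate and Lambda is reported as 0.
#' @export
influenceField <- function(model, measurement = c("Rin", "fR"),
                           cluster_path_um = NULL, total_nS = 100,
                           sites = NULL, protocol = simProtocol(),
                           rin_amps_pA = seq(-25, 25, 12.5)) {
  measurement <- match.arg(measurement)
  sg <- model@grid@segments
  trunk <- which(sg$is_trunk)
  if (is.null(cluster_path_um)) {
    cluster_path_um <- max(sg$path_um[trunk]) / 2
  }
  if (is.null(sites)) sites <- c(1L, trunk)
  background <- if (any(model@gh_nS > 0)) "gradient" else "passive"

  new_model <- insertCluster(model, cluster_path_um, total_nS)
  sites <- sort(unique(c(as.integer(sites), attr(new_model, "cluster_seg"))))
  m_org <- .measureAt(model, sites, measurement, protocol, rin_amps_pA)
  m_new <- .measureAt(new_model, sites, measurement, protocol, rin_amps_pA)

  ok <- m_org != 0
  if (!all(ok)) {
    warning(sum(!ok), " site(s) with zero reference measurement excluded")
    sites <- sites[ok]; m_org <- m_org[ok]; m_new <- m_new[ok]
  }
  IF <- abs(m_org - m_new) / m_org
  mx <- max(IF)
  degenerate <- mx <= 0
  Lambda <- if (degenerate) rep(0, length(IF)) else IF / mx

  tab <- data.frame(
    x_um = sg$path_um[sites], seg = sites,
    m_org = m_org, m_new = m_new, IF = IF, Lambda = Lambda
  )
  tab <- tab[order(tab$x_um), ]
  rownames(tab) <- NULL
  new("InfluenceField",
    table = tab, measurement = measurement, background = background,
    cluster = list(path_um = cluster_path_um, total_nS = total_nS,
                   seg = attr(new_model, "cluster_seg")),
    degenerate = degenerate
  )
}

#' Area under an influence field
#'
#' Trapezoid integrals of the normalized (Lambda) and unnormalized (IF)
#' influence factors over the trunk path coordinate.
#'
#' @param field an [InfluenceField-class].
#' @return list with `auc_norm` and `auc_unnorm` (um).
#' @export
influenceAUC <- function(field) {
  stopifnot(is(field, "InfluenceField"))
  tab <- field@table
  if (nrow(tab) < 2) stop("need at least 2 grid points")
  list(
    auc_norm = pracma::trapz(tab$x_um, tab$Lambda),
    auc_unnorm = pracma::trapz(tab$x_um, tab$IF)
  )
}

#' Influence field across the entire dendritic arbor
#'
#' Computes the unnormalized influence factor of a trunk cluster at every
#' dendritic segment (trunk, obliques and basal tree), for rendering
#' arbor-wide influence maps.
#'
#' @inheritParams influenceField
#' @param max_segments optional cap: when the arbor has more segments, an
#'   evenly spaced subset is measured.
#' @return data.frame with `seg`, `section`, `type`, `path_um`, `radial_um`,
#'   `m_org`, `m_new`, `IF`.
#' @export
arborInfluenceMap <- function(model, measurement = c("Rin", "fR"),
                              cluster_path_um = NULL, total_nS = 100,
                              protocol = simProtocol(),
                              rin_amps_pA = seq(-25, 25, 12.5),
                              max_segments = Inf) {
  measurement <- match.arg(measurement)
  sg <- model@grid@segments
  trunk <- which(sg$is_trunk)
  if (is.null(cluster_path_um)) {
    cluster_path_um <- max(sg$path_um[trunk]) / 2
  }
  sites <- which(sg$type %in% c(1L, 3L, 4L))
  if (length(sites) > max_segments) {
    sites <- sites[round(seq(1, length(sites), length.out = max_segments))]
  }
  new_model <- insertCluster(model, cluster_path_um, total_nS)
  m_org <- .measureAt(model, sites, measurement, protocol, rin_amps_pA)
  m_new <- .measureAt(new_model, sites, measurement, protocol, rin_amps_pA)
  IF <- ifelse(m_org != 0, abs(m_org - m_new) / m_org, NA_real_)
  data.frame(
    seg = sites, section = sg$section[sites], type = sg$type[sites],
    path_um = sg$path_um[sites], radial_um = sg$radial_um[sites],
    m_org = m_org, m_new = m_new, IF = IF
  )
}

#' @describeIn fieldTable influence table accessor.
#' @export
setMethod("fieldTable", "InfluenceField", function(x) x@table)

setMethod("show", "InfluenceField", function(object) {
  auc <- influenceAUC(object)
  cat(sprintf("InfluenceField (%s on %s background): cluster at %.0f um, auc_norm = %.1f um%s\n",
              object@measurement, object@background,
              object@cluster$path_um, auc$auc_norm,
              if (object@degenerate) " [degenerate]" else ""))
})
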