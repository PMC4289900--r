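#' @include AllClasses.R impedance.R influence.R prune.R synthetic.R
NULL

#' Build a study configuration
#'
#' Assembles and validates the configuration consumed by [runStudy()]. The
#' defaults describe the reduced-cost version of the full design: a stylized
#' 17.5 mm morphology, a chained atrophy series in ~1 mm decrements down to
#' 1 mm, passive and HCN-gradient backgrounds, and the three canonical trunk
#' sites (soma, ~150 um, ~300 um radial distance).
#'
#' @param morphology either a `SynthParams` list from [synthParams()] or a
#'   path to an SWC file.
#' @param step_mm,floor_mm,stratum_um atrophy series settings.
#' @param members indices of series members to measure (default: five members
#'   evenly spread from base to floor).
#' @param backgrounds subset of c("passive", "gradient").
#' @param profile,dist,kinetics biophysics.
#' @param sites_um measurement sites (radial um).
#' @param protocol settings from [simProtocol()].
#' @param influence NULL, or a list with `measurements` (subset of
#'   c("Rin","fR")), `backgrounds`, `members` (indices), `n_sites`.
#' @param outdir optional output directory for CSV/JSON artifacts.
#' @param seed RNG seed (synthetic morphology generation).
#' @return a list of class `StudyConfig`.
#' @export
studyConfig <- function(morphology = synthParams(),
                        step_mm = 1, floor_mm = 1, stratum_um = 50,
                        members = NULL,
                        backgrounds = c("passive", "gradient"),
                        profile = passiveProfile(),
                        dist = hcnDistribution(),
                        kinetics = hcnKinetics(),
                        sites_um = c(0, 150, 300),
                        protocol = simProtocol(),
                        influence = NULL,
                        outdir = NULL, seed = 1L) {
  backgrounds <- match.arg(backgrounds, several.ok = TRUE)
  if (is.character(morphology) && !file.exists(morphology)) {
    stop("configuration error: SWC file not found: ", morphology)
  }
  structure(
    list(morphology = morphology, step_mm = step_mm, floor_mm = floor_mm,
         stratum_um = stratum_um, members = members,
         backgrounds = backgrounds, profile = profile, dist = dist,
         kinetics = kinetics, sites_um = sites_um, protocol = protocol,
         influence = influence, outdir = outdir, seed = as.integer(seed)),
    class = "StudyConfig"
  )
}

#' Load a study configuration from YAML or JSON
#'
#' Scalar fields override the [studyConfig()] defaults; nested sections
#' `synth`, `profile`, `dist`, `kinetics`, `protocol` and `influence` are
#' passed to the corresponding constructors.
#'
#' @param path a .yaml/.yml or .json file.
#' @return a `StudyConfig` list.
#' @export
loadStudyConfig <- function(path) {
  if (!file.exists(path)) stop("configuration error: file not found: ", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  args <- list()
  if (!is.null(raw$swc)) args$morphology <- raw$swc
  if (!is.null(raw$synth)) args$morphology <- do.call(synthParams, raw$synth)
  if (!is.null(raw$profile)) args$profile <- do.call(passiveProfile, raw$profile)
  if (!is.null(raw$dist)) args$dist <- do.call(hcnDistribution, raw$dist)
  if (!is.null(raw$kinetics)) args$kinetics <- do.call(hcnKinetics, raw$kinetics)
  if (!is.null(raw$protocol)) args$protocol <- do.call(simProtocol, raw$protocol)
  for (f in c("step_mm", "floor_mm", "stratum_um", "members", "backgrounds",
              "sites_um", "influence", "outdir", "seed")) {
    if (!is.null(raw[[f]])) args[[f]] <- raw[[f]]
  }
  do.call(studyConfig, args)
}

#' Ratio of a measurement between a distal and a proximal site
#'
#' Convenience metric for the constriction of a functional map: the ratio
#' M(distal)/M(proximal) drawn from a [mapOverLocations()] table. Values
#' converging to 1 along an atrophy series indicate a flattening map.
#'
#' @param map data.frame from [mapOverLocations()].
#' @param measurement measurement id (e.g. "fR" or "Rin").
#' @param proximal_um,distal_um requested site coordinates present in `map`.
#' @return the dimensionless ratio, or NA when a site is missing.
#' @export
constrictionRatio <- function(map, measurement, proximal_um = 0,
                              distal_um = 300) {
  rows <- map$measurement == measurement
  mp <- map$value[rows & map$site_um == proximal_um]
  md <- map$value[rows & map$site_um == distal_um]
  if (!length(mp) || !length(md)) return(NA_real_)
  md[1] / mp[1]
}

.configDigest <- function(config) {
  config$outdir <- NULL # exclude volatile output location
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(jsonlite::serializeJSON(config, digits = 10), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full atrophy study
#'
#' Executes the complete pipeline: morphology acquisition (stylized generator
#' or SWC file), chained atrophy series, model construction on the requested
#' backgrounds, the nine-measurement map at every (member, site) pair with
#' chirp-amplitude normalization on HCN models, distal/proximal constriction
#' ratios per member, and (optionally) influence-field AUC tables. Outputs
#' are deterministic for a fixed config and seed.
#'
#' @param config a `StudyConfig` from [studyConfig()] or [loadStudyConfig()].
#' @return a [StudyResult-class].
#' @export
runStudy <- function(config = studyConfig()) {
  stopifnot(inherits(config, "StudyConfig"))
  morph <- if (is.character(config$morphology)) {
    readSWC(config$morphology)
  } else {
    p <- config$morphology
    p$seed <- config$seed
    generateStylizedCA1(p)
  }
  series <- generatePruneSeries(morph, config$step_mm, config$floor_mm,
                                config$stratum_um)
  nmem <- length(series@members)
  members <- config$members %||% unique(round(seq(1, nmem, length.out = min(5, nmem))))
  prot <- config$protocol

  maps <- list()
  constr <- list()
  for (bg in config$backgrounds) {
    dist <- if (bg == "gradient") config$dist else NULL
    base_rin <- NULL
    for (i in members) {
      model <- buildModel(series@members[[i]], config$profile, dist,
                          config$kinetics)
      amp <- prot$chirp_amp_pA
      if (bg == "gradient") {
        rin_som <- measureInputResistance(
          model, 1L, prot$rin_amps_pA, pulse_ms = prot$rin_pulse_ms,
          settle_ms = prot$settle_ms, dt_ms = prot$dt_ms,
          v_init = prot$v_init)
        if (is.null(base_rin)) base_rin <- rin_som
        amp <- normalizeChirpAmplitude(base_rin, rin_som, prot$chirp_amp_pA)
      }
      map <- mapOverLocations(model, config$sites_um, prot, chirp_amp_pA = amp)
      map$length_mm <- series@achieved_mm[i]
      map$member <- i
      map$background <- bg
      maps[[length(maps) + 1L]] <- map
      pu <- min(config$sites_um)
      du <- max(config$sites_um)
      for (m in unique(map$measurement)) {
        constr[[length(constr) + 1L]] <- data.frame(
          member = i, length_mm = series@achieved_mm[i], background = bg,
          measurement = m,
          ratio = constrictionRatio(map, m, pu, du)
        )
      }
    }
  }
  maps <- do.call(rbind, maps)
  constr <- do.call(rbind, constr)

  infl <- data.frame()
  if (!is.null(config$influence)) {
    sp <- config$influence
    imem <- sp$members %||% c(members[1], members[length(members)])
    ibg <- sp$backgrounds %||% config$backgrounds
    imeas <- sp$measurements %||% "Rin"
    nsites <- sp$n_sites %||% 8L
    rows <- list()
    for (bg in ibg) {
      dist <- if (bg == "gradient") config$dist else NULL
      for (i in imem) {
        model <- buildModel(series@members[[i]], config$profile, dist,
                            config$kinetics)
        sg <- model@grid@segments
        trunk <- which(sg$is_trunk)
        sites <- c(1L, trunk[round(seq(1, length(trunk),
                                       length.out = nsites - 1L))])
        for (m in imeas) {
          fld <- influenceField(model, m, sites = sites, protocol = prot)
          auc <- influenceAUC(fld)
          rows[[length(rows) + 1L]] <- data.frame(
            member = i, length_mm = series@achieved_mm[i], background = bg,
            measurement = m, auc_norm = auc$auc_norm,
            auc_unnorm = auc$auc_unnorm,
            degenerate = fld@degenerate
          )
        }
      }
    }
    infl <- do.call(rbind, rows)
  }

  result <- new("StudyResult",
    maps = maps, constriction = constr, influence = infl,
    provenance = list(
      config_md5 = .configDigest(config),
      seed = config$seed,
      achieved_mm = series@achieved_mm,
      members_measured = members,
      n_members = nmem,
      package_version = as.character(utils::packageVersion("resonmap"))
    )
  )
  if (!is.null(config$outdir)) writeStudyResult(result, config$outdir)
  result
}

#' Write study outputs as CSV tables and a JSON summary
#'
#' Files are written to a temporary name and renamed into place so partial
#' outputs never overwrite complete ones.
#'
#' @param result a [StudyResult-class].
#' @param dir output directory (created if missing).
#' @return invisibly, the paths written.
#' @export
writeStudyResult <- function(result, dir) {
  stopifnot(is(result, "StudyResult"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  .atomicWrite <- function(obj, path, writer) {
    tmp <- paste0(path, ".tmp")
    writer(obj, tmp)
    file.rename(tmp, path)
    path
  }
  paths <- c(
    .atomicWrite(result@maps, file.path(dir, "maps.csv"),
                 function(o, p) utils::write.csv(o, p, row.names = FALSE)),
    .atomicWrite(result@constriction, file.path(dir, "constriction.csv"),
                 function(o, p) utils::write.csv(o, p, row.names = FALSE))
  )
  if (nrow(result@influence)) {
    paths <- c(paths,
      .atomicWrite(result@influence, file.path(dir, "influence.csv"),
                   function(o, p) utils::write.csv(o, p, row.names = FALSE)))
  }
  paths <- c(paths,
    .atomicWrite(result@provenance, file.path(dir, "summary.json"),
                 function(o, p) jsonlite::write_json(o, p, auto_unbox = TRUE,
                                                     digits = NA)))
  invisible(paths)
}

setMethod("show", "StudyResult", function(object) {
  cat("StudyResult:", length(unique(object@maps$member)), "members x",
      length(unique(object@maps$site_um)), "sites x",
      length(unique(object@maps$measurement)), "measurements;",
      "backgrounds:", paste(unique(object@maps$background), collapse = ", "),
      "\n")
})
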