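#' @include AllClasses.R morphology.R
NULL

# Run expr with a fixed RNG seed, restoring the caller's RNG state.
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Parameters for the stylized CA1 generator
#'
#' @param target_mm target total dendritic length (mm, default 17.5).
#' @param trunk_um apical trunk length; the trunk is embedded as a straight
#'   path so its radial and path extents coincide (um, default 450).
#' @param trunk_diam_um start/end trunk diameter (um, default 4 tapering to 1).
#' @param oblique_mean_um,oblique_sd_um oblique length distribution (um).
#' @param oblique_diam_um oblique diameter (um).
#' @param basal_fraction fraction of the non-trunk length budget assigned to
#'   the basal tree (default 0.3).
#' @param basal_diam_um basal diameter (um).
#' @param spacing_um node spacing along straight pieces (um).
#' @param seed RNG seed; the same seed reproduces the tree node-for-node.
#' @return a list of class `SynthParams`.
#' @export
synthParams <- function(target_mm = 17.5, trunk_um = 450,
                        trunk_diam_um = c(4, 1),
                        oblique_mean_um = 120, oblique_sd_um = 30,
                        oblique_diam_um = 0.8,
                        basal_fraction = 0.3, basal_diam_um = 1,
                        spacing_um = 10, seed = 1L) {
  if (target_mm * 1000 < trunk_um) {
    stop("configuration error: target length shorter than the trunk")
  }
  if (any(c(target_mm, trunk_um, oblique_mean_um, basal_diam_um,
            oblique_diam_um, spacing_um) <= 0)) {
    stop("configuration error: lengths must be positive")
  }
  structure(
    list(target_mm = target_mm, trunk_um = trunk_um,
         trunk_diam_um = trunk_diam_um,
         oblique_mean_um = oblique_mean_um, oblique_sd_um = oblique_sd_um,
         oblique_diam_um = oblique_diam_um,
         basal_fraction = basal_fraction, basal_diam_um = basal_diam_um,
         spacing_um = spacing_um, seed = as.integer(seed)),
    class = "SynthParams"
  )
}

# Unit vector perpendicular to u; horizontal (zero y-component) whenever u is
# not vertical, so branching never steepens a descending direction.
.perp <- function(u) {
  if (abs(u[2]) > 0.99) return(c(1, 0, 0))
  w <- c(-u[3], 0, u[1])
  w / sqrt(sum(w^2))
}

.rotateToward <- function(u, w, angle_deg) {
  a <- angle_deg * pi / 180
  v <- u * cos(a) + w * sin(a)
  v / sqrt(sum(v^2))
}

#' Generate a stylized CA1-pyramidal-like morphology
#'
#' Builds a soma (single node, radius 10 um), a straight apical trunk of
#' `trunk_um` with linearly tapering diameter, oblique branches attached
#' along the trunk (unbranched when short, recursively bifurcating so that no
#' unbranched run exceeds ~120 um), and a basal binary tree at the soma. The
#' non-trunk length budget is split between obliques and basal tree by
#' `basal_fraction`, and piece lengths are scaled so the total dendritic
#' length equals `target_mm` exactly (well within the 2 percent contract).
#' Fully reproducible for a fixed seed.
#'
#' @param params a `SynthParams` list from [synthParams()], or nothing to use
#'   the defaults (17.5 mm, 450 um trunk).
#' @return a [NeuronMorphology-class].
#' @export
generateStylizedCA1 <- function(params = synthParams()) {
  stopifnot(inherits(params, "SynthParams"))
  p <- params
  .withSeed(p$seed, .generateCA1(p))
}

.generateCA1 <- function(p) {
  spacing <- p$spacing_um
  nodes <- list()
  labels <- character()
  nid <- 0L
  addNode <- function(type, pos, radius, parent, label) {
    nid <<- nid + 1L
    nodes[[nid]] <<- c(nid, type, pos, radius, parent)
    labels[[nid]] <<- label
    nid
  }
  soma <- addNode(1L, c(0, 0, 0), 10, -1L, "soma")

  # straight piece of given length; returns last node id
  piece <- function(type, start_pos, dir, len, r_start, r_end, parent, label) {
    k <- floor(len / spacing)
    ss <- seq_len(k) * spacing
    if (k == 0L || len - k * spacing > 1e-6) ss <- c(ss, len)
    last <- parent
    for (s in ss) {
      r <- r_start + (r_end - r_start) * s / len
      last <- addNode(type, start_pos + dir * s, r, last, label)
    }
    last
  }

  # recursively branching subtree of total length len along dir
  subtree <- function(type, start_pos, dir, len, radius, parent, label,
                      run_max = 120, stem = 100) {
    if (len <= run_max) {
      piece(type, start_pos, dir, len, radius, radius, parent, label)
      return(invisible(NULL))
    }
    s <- min(stem, len / 3)
    last <- piece(type, start_pos, dir, s, radius, radius, parent, label)
    tip <- start_pos + dir * s
    w <- .perp(dir)
    ang <- stats::runif(1, 20, 35)
    rem <- (len - s) / 2
    subtree(type, tip, .rotateToward(dir, w, ang), rem, radius, last, label,
            run_max, stem)
    subtree(type, tip, .rotateToward(dir, w, -ang), rem, radius, last, label,
            run_max, stem)
  }

  # apical trunk: straight along +y, tapering diameter
  r0 <- p$trunk_diam_um[1] / 2
  r1 <- p$trunk_diam_um[2] / 2
  ntr <- round(p$trunk_um / spacing)
  trunk_ids <- integer(ntr)
  last <- soma
  for (i in seq_len(ntr)) {
    y <- p$trunk_um * i / ntr
    r <- r0 + (r1 - r0) * i / ntr
    last <- addNode(4L, c(0, y, 0), r, last, "trunk")
    trunk_ids[i] <- last
  }

  budget <- p$target_mm * 1000 - p$trunk_um
  basal_total <- p$basal_fraction * budget
  obl_total <- budget - basal_total
  if (obl_total < 40) { # too small for obliques; fold into basal tree
    basal_total <- budget
    obl_total <- 0
  }

  if (obl_total > 0) {
    count <- max(1L, round(obl_total / p$oblique_mean_um))
    lens <- stats::rnorm(count, p$oblique_mean_um, p$oblique_sd_um)
    lens <- pmin(pmax(lens, 60), 180)
    lens <- lens * (obl_total / sum(lens))
    # obliques attach along the whole trunk and run near-horizontally, so
    # each one stays roughly within the radial stratum of its attachment
    attach_y <- stats::runif(count, 60, p$trunk_um - 20)
    for (i in seq_len(count)) {
      j <- which.min(abs(p$trunk_um * seq_len(ntr) / ntr - attach_y[i]))
      anchor <- trunk_ids[j]
      apos <- c(0, p$trunk_um * j / ntr, 0)
      az <- stats::runif(1, 0, 2 * pi)
      cy <- stats::runif(1, -0.15, 0.05)
      ch <- sqrt(1 - cy^2)
      dir <- c(ch * cos(az), cy, ch * sin(az))
      subtree(4L, apos, dir, lens[i], p$oblique_diam_um / 2, anchor,
              "oblique")
    }
  }

  if (basal_total > 0) {
    half <- basal_total / 2
    for (sgn in c(-1, 1)) {
      dir <- c(sgn * sin(pi / 9), -cos(pi / 9), 0)
      subtree(3L, c(0, 0, 0), dir, half, p$basal_diam_um / 2, soma, "basal",
              run_max = 120, stem = 80)
    }
  }

  m <- do.call(rbind, nodes)
  nd <- data.frame(
    id = as.integer(m[, 1]), type = as.integer(m[, 2]),
    x = m[, 3], y = m[, 4], z = m[, 5], radius = m[, 6],
    parent = as.integer(m[, 7])
  )
  neuronMorphology(nd, labels)
}
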