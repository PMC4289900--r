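#' @include AllClasses.R AllGenerics.R
NULL

.euclid <- function(a, b) sqrt(sum((a - b)^2))

# Euclidean length of the edge ending at each non-root node (NA for root).
.edgeLengths <- function(nodes) {
  idx <- match(nodes$parent, nodes$id)
  dx <- nodes$x - nodes$x[idx]
  dy <- nodes$y - nodes$y[idx]
  dz <- nodes$z - nodes$z[idx]
  sqrt(dx^2 + dy^2 + dz^2)
}

#' Construct a NeuronMorphology from an SWC-style node table
#'
#' Validates SWC semantics (single root, parents precede children, positive
#' radii), computes per-node path and radial distances from the soma
#' centroid, and decomposes the tree into maximal unbranched sections.
#'
#' @param nodes data.frame with columns `id`, `type`, `x`, `y`, `z`, `radius`,
#'   `parent` (parent = -1 for the root). Coordinates and radii in
#'   micrometres.
#' @param labels optional character vector of per-node subtree tags (same
#'   order as `nodes`); nodes tagged "trunk" define the apical trunk.
#' @param break_at optional node ids at which sections must end even without
#'   a branch point (used by pruning to keep section boundaries stable).
#' @return a [NeuronMorphology-class] object.
#' @details The soma may comprise 1-3 type-1 nodes; the radius-weighted
#'   centroid of type-1 nodes is the origin for radial distances, and soma
#'   nodes carry path distance 0. Without labels, the apical trunk is
#'   identified as the section path from the soma to the type-4 tip at
#'   maximal radial distance.
#' @export
neuronMorphology <- function(nodes, labels = character(),
                             break_at = integer()) {
  nodes <- as.data.frame(nodes)[, c("id", "type", "x", "y", "z", "radius", "parent")]
  nodes$id <- as.integer(nodes$id)
  nodes$type <- as.integer(nodes$type)
  nodes$parent <- as.integer(nodes$parent)
  if (nrow(nodes) == 0L) stop("morphology has no nodes")

  soma <- nodes$type == 1L
  if (!any(soma)) stop("morphology must contain at least one soma (type 1) node")
  w <- nodes$radius[soma]
  centroid <- c(
    sum(nodes$x[soma] * w), sum(nodes$y[soma] * w), sum(nodes$z[soma] * w)
  ) / sum(w)

  # distances: path walks edges from the soma, radial is straight-line
  el <- .edgeLengths(nodes)
  pidx <- match(nodes$parent, nodes$id)
  path <- numeric(nrow(nodes))
  for (i in seq_len(nrow(nodes))) {
    if (soma[i]) {
      path[i] <- 0
    } else if (nodes$parent[i] == -1L) {
      path[i] <- 0
    } else {
      path[i] <- path[pidx[i]] + el[i]
    }
  }
  nodes$path_um <- path
  nodes$radial_um <- sqrt((nodes$x - centroid[1])^2 +
                          (nodes$y - centroid[2])^2 +
                          (nodes$z - centroid[3])^2)

  if (length(labels) && length(labels) != nrow(nodes)) {
    stop("labels must match the number of nodes")
  }
  break_at <- as.integer(intersect(break_at, nodes$id))
  sec <- .buildSections(nodes, labels, break_at)
  obj <- new("NeuronMorphology",
    nodes = nodes,
    sections = sec$table,
    sectionNodes = sec$nodes,
    somaCentroid = centroid,
    labels = labels,
    breakIds = break_at
  )
  validObject(obj)
  obj
}

# Decompose into maximal unbranched runs of non-soma nodes. Sections start at
# nodes whose parent is a soma node or a branch point. The section's length
# includes the edge from its anchor (parent) node.
.buildSections <- function(nodes, labels = character(),
                           break_at = integer()) {
  n <- nrow(nodes)
  id2row <- seq_len(n)
  names(id2row) <- nodes$id
  kids <- vector("list", n)
  for (i in seq_len(n)) {
    p <- nodes$parent[i]
    if (p != -1L) {
      pr <- id2row[[as.character(p)]]
      kids[[pr]] <- c(kids[[pr]], i)
    }
  }
  nkids <- lengths(kids)
  soma <- nodes$type == 1L

  pr <- match(nodes$parent, nodes$id)
  isBreak <- nodes$id %in% break_at
  isStart <- !soma & (nodes$parent == -1L | soma[pr] | nkids[pr] >= 2L |
                        isBreak[pr])
  starts <- which(isStart)

  secNodes <- list()
  secRows <- list()
  for (s in starts) {
    chain <- s
    cur <- s
    while (nkids[cur] == 1L && !isBreak[cur]) {
      nxt <- kids[[cur]][1]
      if (soma[nxt]) break
      chain <- c(chain, nxt)
      cur <- nxt
    }
    secNodes[[length(secNodes) + 1L]] <- nodes$id[chain]
    secRows[[length(secRows) + 1L]] <- chain
  }

  el <- .edgeLengths(nodes)
  nsec <- length(secNodes)
  node2sec <- integer(n) # 0 = soma / unassigned
  for (k in seq_len(nsec)) node2sec[secRows[[k]]] <- k

  tab <- data.frame(
    section = seq_len(nsec),
    parent_section = integer(nsec),
    type = integer(nsec),
    length_um = numeric(nsec),
    is_trunk = logical(nsec),
    is_terminal = logical(nsec),
    mid_radial_um = numeric(nsec)
  )
  for (k in seq_len(nsec)) {
    rows <- secRows[[k]]
    anchor <- pr[rows[1]]
    tab$parent_section[k] <- if (is.na(anchor) || soma[anchor]) 0L else node2sec[anchor]
    tab$type[k] <- nodes$type[rows[1]]
    tab$length_um[k] <- sum(el[rows])
    tab$is_terminal[k] <- nkids[rows[length(rows)]] == 0L
    # radial distance of the arc midpoint
    cum <- cumsum(el[rows])
    half <- tab$length_um[k] / 2
    j <- which(cum >= half)[1]
    tab$mid_radial_um[k] <- nodes$radial_um[rows[j]]
  }

  # apical trunk: explicit labels when present, otherwise the section path
  # from the soma to the max-radial type-4 node
  if (length(labels)) {
    for (k in seq_len(nsec)) {
      tab$is_trunk[k] <- all(labels[secRows[[k]]] == "trunk")
    }
  } else {
    ap <- which(nodes$type == 4L)
    if (length(ap)) {
      tip <- ap[which.max(nodes$radial_um[ap])]
      k <- node2sec[tip]
      while (k != 0L) {
        tab$is_trunk[k] <- TRUE
        k <- tab$parent_section[k]
      }
    }
  }
  list(table = tab, nodes = secNodes)
}

#' Read an SWC morphology file
#'
#' Parses the standard 7-column whitespace-delimited SWC dialect with `#`
#' comment lines and returns a validated [NeuronMorphology-class].
#'
#' @param path path to an SWC file.
#' @return a [NeuronMorphology-class].
#' @export
readSWC <- function(path) {
  if (!file.exists(path)) stop("SWC file not found: ", path)
  raw <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", raw)
  lines <- raw[keep]
  lineno <- which(keep)
  if (!length(lines)) stop("SWC file contains no data lines: ", path)
  fields <- strsplit(trimws(lines), "\\s+")
  bad <- which(lengths(fields) != 7L)
  if (length(bad)) {
    stop(sprintf("malformed SWC line %d (expected 7 fields): '%s'",
                 lineno[bad[1]], lines[bad[1]]))
  }
  m <- suppressWarnings(matrix(as.numeric(unlist(fields)), ncol = 7, byrow = TRUE))
  if (anyNA(m)) {
    bad <- which(apply(is.na(m), 1, any))[1]
    stop(sprintf("malformed SWC line %d (non-numeric field): '%s'",
                 lineno[bad], lines[bad]))
  }
  nodes <- data.frame(
    id = as.integer(m[, 1]), type = as.integer(m[, 2]),
    x = m[, 3], y = m[, 4], z = m[, 5], radius = m[, 6],
    parent = as.integer(m[, 7])
  )
  if (any(nodes$radius <= 0)) {
    stop("structural error: non-positive radius at node id ",
         nodes$id[which(nodes$radius <= 0)[1]])
  }
  orphan <- nodes$parent != -1L & !(nodes$parent %in% nodes$id)
  if (any(orphan)) {
    stop("structural error: node ", nodes$id[which(orphan)[1]],
         " references missing parent ", nodes$parent[which(orphan)[1]])
  }
  neuronMorphology(nodes)
}

#' Write a morphology as a standard SWC file
#'
#' Node ids are renumbered contiguously (1..n, preserving order) as required
#' by the SWC convention; the mapping from old to new ids is returned
#' invisibly.
#'
#' @param x a [NeuronMorphology-class].
#' @param path output file path.
#' @return invisibly, a named integer vector mapping old ids to new ids.
#' @export
writeSWC <- function(x, path) {
  stopifnot(is(x, "NeuronMorphology"))
  nd <- x@nodes
  if (nrow(nd) == 0L) stop("refusing to write an empty morphology")
  newid <- seq_len(nrow(nd))
  names(newid) <- nd$id
  newparent <- ifelse(nd$parent == -1L, -1L,
                      newid[as.character(nd$parent)])
  out <- sprintf("%d %d %.6g %.6g %.6g %.6g %d",
                 newid, nd$type, nd$x, nd$y, nd$z, nd$radius, newparent)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# SWC written by resonmap", out), con)
  invisible(newid)
}

#' @describeIn totalDendriticLength sum of dendritic edge lengths in mm.
#' @export
setMethod("totalDendriticLength", "NeuronMorphology", function(x) {
  nd <- x@nodes
  el <- .edgeLengths(nd)
  dend <- nd$type %in% c(3L, 4L) & nd$parent != -1L
  sum(el[dend], na.rm = TRUE) / 1000
})

#' Radial distance of nodes from the soma centroid
#'
#' @param x a [NeuronMorphology-class].
#' @param ids node ids (default: all nodes).
#' @return straight-line 3D distances in micrometres.
#' @export
radialDistance <- function(x, ids = NULL) {
  stopifnot(is(x, "NeuronMorphology"))
  nd <- x@nodes
  if (is.null(ids)) return(nd$radial_um)
  j <- match(ids, nd$id)
  if (anyNA(j)) stop("node id not in morphology: ", ids[which(is.na(j))[1]])
  nd$radial_um[j]
}

#' Path distance of nodes from the soma
#'
#' Arc length along the tree from the soma to each node (soma nodes are at
#' path distance 0).
#'
#' @inheritParams radialDistance
#' @return path distances in micrometres.
#' @export
pathDistance <- function(x, ids = NULL) {
  stopifnot(is(x, "NeuronMorphology"))
  nd <- x@nodes
  if (is.null(ids)) return(nd$path_um)
  j <- match(ids, nd$id)
  if (anyNA(j)) stop("node id not in morphology: ", ids[which(is.na(j))[1]])
  nd$path_um[j]
}

#' Space constant at 100 Hz
#'
#' lambda_f = 1e5 * sqrt(d / (4 pi f ra cm)) micrometres at f = 100 Hz, the
#' quantity bounding segment length in the d-lambda discretization rule.
#'
#' @param diam_um cable diameter (micrometres).
#' @param ra_ohm_cm axial resistivity (Ohm cm).
#' @param cm_uf_cm2 specific membrane capacitance (uF/cm^2).
#' @return lambda_100 in micrometres.
#' @export
spaceConstant100 <- function(diam_um, ra_ohm_cm, cm_uf_cm2 = 1) {
  if (any(diam_um <= 0) || any(ra_ohm_cm <= 0) || any(cm_uf_cm2 <= 0)) {
    stop("spaceConstant100: all arguments must be positive")
  }
  1e5 * sqrt(diam_um / (4 * pi * 100 * ra_ohm_cm * cm_uf_cm2))
}

# Interpolate position and radius at arc coordinate q along a polyline.
# pos: k x 3 matrix, r: radii, cum: cumulative arc (cum[1] = 0 at the anchor).
.interpAlong <- function(pos, r, cum, q) {
  q <- max(min(q, cum[length(cum)]), 0)
  j <- findInterval(q, cum, rightmost.closed = TRUE)
  j <- max(1L, min(j, length(cum) - 1L))
  seg <- cum[j + 1] - cum[j]
  t <- if (seg > 0) (q - cum[j]) / seg else 0
  list(
    pos = pos[j, ] * (1 - t) + pos[j + 1, ] * t,
    radius = r[j] * (1 - t) + r[j + 1] * t
  )
}

# Lateral frustum area of the piece of a polyline between arcs a and b.
.frustumArea <- function(r, cum, a, b) {
  brk <- sort(unique(c(a, b, cum[cum > a & cum < b])))
  area <- 0
  interp_r <- function(q) {
    j <- findInterval(q, cum, rightmost.closed = TRUE)
    j <- max(1L, min(j, length(cum) - 1L))
    seg <- cum[j + 1] - cum[j]
    t <- if (seg > 0) (q - cum[j]) / seg else 0
    r[j] * (1 - t) + r[j + 1] * t
  }
  for (i in seq_len(length(brk) - 1L)) {
    r1 <- interp_r(brk[i]); r2 <- interp_r(brk[i + 1])
    h <- brk[i + 1] - brk[i]
    area <- area + pi * (r1 + r2) * sqrt(h^2 + (r1 - r2)^2)
  }
  area
}

#' Discretize a morphology with the d-lambda rule
#'
#' Splits every section into the smallest odd number n of equal-length
#' segments such that section_length / n < d_lambda * lambda_100, where
#' lambda_100 is computed from the section's length-weighted mean diameter
#' and the local axial resistivity of `profile` (somatic value for basal and
#' somatic sections, the radial-distance profile value for apical sections).
#' The soma is always a single compartment (segment 1).
#'
#' @param x a [NeuronMorphology-class].
#' @param profile a [PassiveProfile-class] supplying ra and cm.
#' @param d_lambda fraction of lambda_100 bounding segment length (default 0.1).
#' @return a [CompartmentGrid-class].
#' @export
compartmentalize <- function(x, profile = passiveProfile(), d_lambda = 0.1) {
  stopifnot(is(x, "NeuronMorphology"), is(profile, "PassiveProfile"))
  if (d_lambda <= 0) stop("d_lambda must be positive")
  nd <- x@nodes
  sec <- x@sections
  secNodes <- x@sectionNodes
  id2row <- match(nd$id, nd$id) # identity; use match on demand

  soma <- nd[nd$type == 1L, , drop = FALSE]
  somaRadius <- mean(soma$radius)
  if (nrow(soma) == 1L) {
    somaArea <- 4 * pi * soma$radius^2 # sphere
  } else {
    cumS <- c(0, cumsum(.edgeLengths(soma)[-1]))
    somaArea <- .frustumArea(soma$radius, cumS, 0, max(cumS))
    if (somaArea <= 0) somaArea <- 4 * pi * somaRadius^2
  }

  segs <- list(data.frame(
    seg = 1L, section = 0L, parent_seg = 0L, type = 1L, is_trunk = FALSE,
    path_um = 0, radial_um = 0, diam_um = 2 * somaRadius,
    length_um = 2 * somaRadius, area_um2 = somaArea
  ))
  lastSegOfSection <- integer(nrow(sec))
  nextSeg <- 2L

  for (k in seq_len(nrow(sec))) {
    rows <- match(secNodes[[k]], nd$id)
    anchorRow <- match(nd$parent[rows[1]], nd$id)
    chainRows <- c(anchorRow, rows)
    pos <- as.matrix(nd[chainRows, c("x", "y", "z")])
    r <- nd$radius[chainRows]
    el <- sqrt(rowSums((pos[-1, , drop = FALSE] -
                        pos[-nrow(pos), , drop = FALSE])^2))
    cum <- c(0, cumsum(el))
    L <- cum[length(cum)]
    if (L <= 0) {
      warning("zero-length section ", k, " collapsed")
      lastSegOfSection[k] <- if (sec$parent_section[k] == 0L) 1L else
        lastSegOfSection[sec$parent_section[k]]
      next
    }
    # length-weighted mean diameter over edges
    dmean <- 2 * sum((r[-1] + r[-length(r)]) / 2 * el) / L
    xref <- if (sec$type[k] == 4L) sec$mid_radial_um[k] else 0
    ra <- axialResistivity(xref, profile)
    lam <- spaceConstant100(dmean, ra, profile@cm)
    n <- max(1L, ceiling(L / (d_lambda * lam)))
    if (L / n >= d_lambda * lam) n <- n + 1L
    if (n %% 2L == 0L) n <- n + 1L

    pathStart <- nd$path_um[chainRows[1]]
    parent <- if (sec$parent_section[k] == 0L) 1L else
      lastSegOfSection[sec$parent_section[k]]
    slen <- L / n
    rowsOut <- vector("list", n)
    for (j in seq_len(n)) {
      mid <- (j - 0.5) * slen
      ip <- .interpAlong(pos, r, cum, mid)
      rowsOut[[j]] <- data.frame(
        seg = nextSeg, section = k, parent_seg = parent,
        type = sec$type[k], is_trunk = sec$is_trunk[k],
        path_um = pathStart + mid,
        radial_um = .euclid(ip$pos, x@somaCentroid),
        diam_um = 2 * ip$radius,
        length_um = slen,
        area_um2 = .frustumArea(r, cum, (j - 1) * slen, j * slen)
      )
      parent <- nextSeg
      nextSeg <- nextSeg + 1L
    }
    lastSegOfSection[k] <- nextSeg - 1L
    segs[[length(segs) + 1L]] <- do.call(rbind, rowsOut)
  }

  grid <- new("CompartmentGrid",
    segments = do.call(rbind, segs),
    d_lambda = d_lambda,
    morphology = x
  )
  validObject(grid)
  grid
}

#' Export a morphometry report
#'
#' One row per section: id, length, path and radial distance of the section
#' midpoint, mean diameter, type and trunk/terminal flags.
#'
#' @param x a [NeuronMorphology-class].
#' @param path optional CSV output path.
#' @return the report data.frame (invisibly when `path` is given).
#' @export
morphometryReport <- function(x, path = NULL) {
  stopifnot(is(x, "NeuronMorphology"))
  nd <- x@nodes
  sec <- x@sections
  mid_path <- vapply(seq_len(nrow(sec)), function(k) {
    rows <- match(x@sectionNodes[[k]], nd$id)
    stats::median(nd$path_um[rows])
  }, numeric(1))
  out <- data.frame(
    section = sec$section, type = sec$type, length_um = sec$length_um,
    mid_path_um = mid_path, mid_radial_um = sec$mid_radial_um,
    is_trunk = sec$is_trunk, is_terminal = sec$is_terminal
  )
  if (!is.null(path)) {
    utils::write.csv(out, path, row.names = FALSE)
    return(invisible(out))
  }
  out
}

#' @describeIn nNodes number of nodes in a morphology.
#' @export
setMethod("nNodes", "NeuronMorphology", function(x) nrow(x@nodes))

#' @describeIn nNodes number of segments in a grid.
#' @export
setMethod("nSegments", "CompartmentGrid", function(x) nrow(x@segments))

#' @describeIn nNodes number of segments in a cable model.
#' @export
setMethod("nSegments", "CableModel", function(x) length(x@parent))

#' @describeIn morphNodes node table of a morphology.
#' @export
setMethod("morphNodes", "NeuronMorphology", function(x) x@nodes)

#' @describeIn sectionTable section table of a morphology.
#' @export
setMethod("sectionTable", "NeuronMorphology", function(x) x@sections)

#' @describeIn segmentTable segment table of a grid.
#' @export
setMethod("segmentTable", "CompartmentGrid", function(x) x@segments)

#' @describeIn segmentTable segment table of a cable model's grid.
#' @export
setMethod("segmentTable", "CableModel", function(x) x@grid@segments)

#' @describeIn somaCentroid soma centroid of a morphology.
#' @export
setMethod("somaCentroid", "NeuronMorphology", function(x) x@somaCentroid)

setMethod("show", "NeuronMorphology", function(object) {
  cat("NeuronMorphology:", nrow(object@nodes), "nodes,",
      nrow(object@sections), "sections,",
      sprintf("%.3f mm dendritic length\n", totalDendriticLength(object)))
})

setMethod("show", "CompartmentGrid", function(object) {
  cat("CompartmentGrid:", nrow(object@segments), "segments (d_lambda =",
      object@d_lambda, ")\n")
})
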