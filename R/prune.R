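#' @include AllClasses.R morphology.R
NULL

# Per-section attribution of dendritic edge length to radial strata.
# Returns a list (one element per section) of named vectors stratum -> um.
.sectionStrata <- function(x, stratum_um) {
  nd <- x@nodes
  el <- .edgeLengths(nd)
  pr <- match(nd$parent, nd$id)
  lapply(x@sectionNodes, function(ids) {
    rows <- match(ids, nd$id)
    mid <- (nd$radial_um[rows] + nd$radial_um[pr[rows]]) / 2
    bin <- floor(mid / stratum_um) + 1L
    tapply(el[rows], bin, sum)
  })
}

#' Prune a morphology to a target total dendritic length
#'
#' Removes whole terminal sections, never rerouting or adding nodes, so the
#' result is a strict subtree of the input (surviving nodes keep their ids,
#' positions, diameters, and therefore their path and radial distances).
#' Removal is spread across concentric radial-distance strata: at each step
#' the stratum most under-pruned relative to a uniform removal quota loses
#' its longest available terminal section (ties broken by smallest section
#' id). The apical trunk and soma are always retained.
#'
#' @param x a [NeuronMorphology-class].
#' @param target_mm target total dendritic length (mm).
#' @param stratum_um radial stratum width (um, default 50).
#' @param protected additional section ids (in `sectionTable(x)` numbering)
#'   to retain.
#' @param tol_mm achieved-length tolerance (default 0.1 mm).
#' @return a [NeuronMorphology-class] with attributes `removed_sections`,
#'   `removed_nodes` and `stratum_ledger`.
#' @export
pruneToLength <- function(x, target_mm, stratum_um = 50, protected = integer(),
                          tol_mm = 0.1) {
  stopifnot(is(x, "NeuronMorphology"))
  L0 <- totalDendriticLength(x)
  if (target_mm > L0 + 1e-9) {
    warning("target exceeds current length; returning the tree unchanged")
    out <- x
    attr(out, "removed_sections") <- integer()
    attr(out, "removed_nodes") <- integer()
    attr(out, "stratum_ledger") <- NULL
    return(out)
  }
  sec <- x@sections
  dend <- sec$type %in% c(3L, 4L)
  prot <- sec$is_trunk | seq_len(nrow(sec)) %in% protected | !dend
  protLen <- sum(sec$length_um[prot & dend]) / 1000
  if (target_mm < protLen - tol_mm) {
    stop("infeasibility error: protected sections alone exceed the target (",
         signif(protLen, 4), " mm protected)")
  }

  strata <- .sectionStrata(x, stratum_um)
  nbin <- max(c(1L, unlist(lapply(strata, function(s) as.integer(names(s))))))
  avail <- numeric(nbin)
  for (k in which(!prot)) {
    s <- strata[[k]]
    avail[as.integer(names(s))] <- avail[as.integer(names(s))] + s
  }

  R <- (L0 - target_mm) * 1000 # um to remove
  quota <- if (sum(avail) > 0) R * avail / sum(avail) else numeric(nbin)
  removed_bin <- numeric(nbin)
  removed <- 0

  children <- split(seq_len(nrow(sec)), sec$parent_section)
  childrenOf <- function(k) children[[as.character(k)]] %||% integer()
  alive <- rep(TRUE, nrow(sec))
  isTerminalAlive <- function(k) {
    kids <- childrenOf(k)
    !length(kids) || !any(alive[kids])
  }
  secbin <- pmin(pmax(floor(sec$mid_radial_um / stratum_um) + 1L, 1L), nbin)
  removed_ids <- integer()

  repeat {
    remaining <- R - removed
    if (remaining <= 50) break # within half the 0.1 mm tolerance band
    cand <- which(alive & !prot)
    cand <- cand[vapply(cand, isTerminalAlive, logical(1))]
    if (!length(cand)) break

    pick <- NA_integer_
    if (remaining <= 150) {
      # terminal-section granularity: finish with the best-fitting section
      err <- abs(sec$length_um[cand] - remaining)
      best <- cand[order(err, cand)][1]
      if (abs(sec$length_um[best] - remaining) >= remaining) break
      pick <- best
    } else {
      # pick the terminal section whose removal best serves the per-stratum
      # deficits, counting every stratum its edges pass through; removal
      # beyond a stratum's quota earns no credit
      deficit <- pmax(quota - removed_bin, 0)
      fit <- cand[sec$length_um[cand] <= remaining + stratum_um]
      pool <- if (length(fit)) fit else cand
      score <- vapply(pool, function(k) {
        s <- strata[[k]]
        sum(pmin(deficit[as.integer(names(s))], s))
      }, numeric(1))
      pick <- pool[order(-score, -sec$length_um[pool], pool)][1]
    }

    alive[pick] <- FALSE
    removed_ids <- c(removed_ids, pick)
    removed <- removed + sec$length_um[pick]
    s <- strata[[pick]]
    removed_bin[as.integer(names(s))] <- removed_bin[as.integer(names(s))] + s
  }

  dropNodes <- unlist(x@sectionNodes[removed_ids], use.names = FALSE)
  nd <- x@nodes
  keep <- !(nd$id %in% dropNodes)
  lab <- if (length(x@labels)) x@labels[keep] else character()
  # surviving sections must keep their boundaries: every current branch
  # point (and inherited break point) becomes a fixed section break
  counts <- table(nd$parent[nd$parent != -1L])
  branchIds <- as.integer(names(counts)[counts >= 2L])
  out <- neuronMorphology(
    nd[keep, c("id", "type", "x", "y", "z", "radius", "parent")], lab,
    break_at = union(x@breakIds, branchIds))
  achieved <- totalDendriticLength(out)
  if (abs(achieved - target_mm) > tol_mm) {
    warning(sprintf("achieved length %.3f mm misses target %.3f mm by > %.2f mm",
                    achieved, target_mm, tol_mm))
  }
  attr(out, "removed_sections") <- removed_ids
  attr(out, "removed_nodes") <- as.integer(dropNodes %||% integer())
  attr(out, "stratum_ledger") <- data.frame(
    stratum = seq_len(nbin),
    radial_lo_um = (seq_len(nbin) - 1) * stratum_um,
    available_um = avail,
    quota_um = quota,
    removed_um = removed_bin
  )
  out
}

#' Generate an atrophy series by chained uniform pruning
#'
#' Produces an ordered series of morphologies whose total dendritic lengths
#' decrease in approximately `step_mm` decrements from the base length down
#' to `floor_mm`; each member is pruned from the previous member (chained),
#' so every member is a subtree of all earlier members. For the default
#' 17.5 mm base with 1 mm steps and a 1 mm floor this yields 17 morphologies.
#'
#' @param x the base [NeuronMorphology-class].
#' @param step_mm approximate decrement per member (default 1 mm).
#' @param floor_mm length of the most pruned member (default 1 mm).
#' @param stratum_um radial stratum width for uniform pruning (default 50 um).
#' @return a [PruneSeries-class]; member 1 is the unpruned base.
#' @export
generatePruneSeries <- function(x, step_mm = 1, floor_mm = 1, stratum_um = 50) {
  stopifnot(is(x, "NeuronMorphology"))
  L0 <- totalDendriticLength(x)
  if (L0 <= floor_mm) stop("tree length must exceed the series floor")
  nmem <- max(2L, round((L0 - floor_mm) / step_mm) + 1L)
  targets <- seq(L0, floor_mm, length.out = nmem)

  members <- vector("list", nmem)
  prov <- vector("list", nmem)
  achieved <- numeric(nmem)
  members[[1]] <- x
  achieved[1] <- L0
  prov[[1]] <- list(removed_sections = integer(), removed_nodes = integer(),
                    stratum_ledger = NULL)
  cur <- x
  for (i in 2:nmem) {
    cur <- pruneToLength(cur, targets[i], stratum_um = stratum_um)
    members[[i]] <- cur
    achieved[i] <- totalDendriticLength(cur)
    prov[[i]] <- list(
      removed_sections = attr(cur, "removed_sections"),
      removed_nodes = attr(cur, "removed_nodes"),
      stratum_ledger = attr(cur, "stratum_ledger")
    )
  }
  obj <- new("PruneSeries",
    members = members, target_mm = targets, achieved_mm = achieved,
    provenance = prov
  )
  validObject(obj)
  obj
}

#' Write a prune series as SWC files with JSON provenance sidecars
#'
#' @param series a [PruneSeries-class].
#' @param dir output directory (created if missing).
#' @param prefix file name prefix.
#' @return invisibly, the file paths written.
#' @export
writePruneSeries <- function(series, dir, prefix = "member") {
  stopifnot(is(series, "PruneSeries"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (i in seq_along(series@members)) {
    swc <- file.path(dir, sprintf("%s_%02d.swc", prefix, i))
    writeSWC(series@members[[i]], swc)
    side <- file.path(dir, sprintf("%s_%02d.json", prefix, i))
    pv <- series@provenance[[i]]
    jsonlite::write_json(
      list(
        target_mm = series@target_mm[i],
        achieved_mm = series@achieved_mm[i],
        removed_sections = pv$removed_sections,
        removed_nodes = pv$removed_nodes,
        stratum_ledger = pv$stratum_ledger
      ),
      side, auto_unbox = TRUE, digits = NA, null = "null"
    )
    paths <- c(paths, swc, side)
  }
  invisible(paths)
}

#' @describeIn seriesMembers member list accessor.
#' @export
setMethod("seriesMembers", "PruneSeries", function(x) x@members)

#' @describeIn seriesLengths achieved lengths accessor.
#' @export
setMethod("seriesLengths", "PruneSeries", function(x) x@achieved_mm)

setMethod("show", "PruneSeries", function(object) {
  cat("PruneSeries:", length(object@members), "members;",
      sprintf("%.2f -> %.2f mm\n", object@achieved_mm[1],
              object@achieved_mm[length(object@achieved_mm)]))
})
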