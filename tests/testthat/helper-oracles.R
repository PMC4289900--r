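# Independent frequency-domain oracle: direct complex linear solve of the
# discretized cable at each frequency. Shares only the model's conductance
# vectors with the implementation under test; the time stepping, transform
# and measurement code paths are not involved.
#
# For passive models this is exact; with quasi = TRUE the HCN current is
# linearized around v0 (phenomenological inductance), which is the small-
# signal limit of the nonlinear model.
oracleImpedance <- function(model, freqs_hz, inject, record = inject,
                            quasi = any(model@gh_nS > 0), v0 = -65) {
  n <- nSegments(model)
  par <- model@parent
  gax <- model@g_axial_nS
  kin <- model@kinetics
  act <- hcnActivation(v0, kin)
  m0 <- act$m_inf
  mslope <- -m0 * (1 - m0) / kin@k
  vapply(freqs_hz, function(f) {
    w <- 2 * pi * f / 1000 # rad/ms with nS, pF units
    yh <- if (quasi) {
      model@gh_nS * m0 +
        model@gh_nS * (v0 - kin@e_h) * mslope / (1 + 1i * w * act$tau)
    } else {
      model@gh_nS * m0
    }
    diagv <- model@g_leak_nS + 1i * w * model@cap_pF + yh
    A <- matrix(0 + 0i, n, n)
    for (i in seq_len(n)[-1]) {
      p <- par[i]
      A[i, p] <- -gax[i]
      A[p, i] <- -gax[i]
      diagv[i] <- diagv[i] + gax[i]
      diagv[p] <- diagv[p] + gax[i]
    }
    diag(A) <- diagv
    b <- rep(0 + 0i, n)
    b[inject] <- 1
    solve(A, b)[record] * 1000 # mV/pA -> MOhm
  }, complex(1))
}

# Brute-force pruning oracle: greedy removal of whole terminal sections,
# choosing at every step the section that minimizes the resulting maximal
# per-stratum deviation from the uniform removal fraction. Independent of
# the package's pruning heuristic; used to bound the achievable balance.
# Returns the per-stratum removed lengths.
prunedOracleBins <- function(morph, target_mm, stratum_um = 50) {
  sec <- sectionTable(morph)
  aud <- strataOf(morph, stratum_um)
  removable <- !sec$is_trunk & sec$type %in% c(3L, 4L)
  nbin <- max(aud$bin, na.rm = TRUE)
  secBins <- lapply(seq_len(nrow(sec)), function(k) {
    rows <- aud[aud$id %in% morph@sectionNodes[[k]], ]
    tapply(rows$len, rows$bin, sum)
  })
  avail <- rep(0, nbin)
  for (k in which(removable)) {
    s <- secBins[[k]]
    avail[as.integer(names(s))] <- avail[as.integer(names(s))] + s
  }
  R <- (totalDendriticLength(morph) - target_mm) * 1000
  gf <- R / sum(avail)
  kids <- split(seq_len(nrow(sec)), sec$parent_section)
  alive <- rep(TRUE, nrow(sec))
  removedBin <- rep(0, nbin)
  removed <- 0
  ok <- avail > 0
  repeat {
    if (R - removed <= 50) break
    cand <- which(alive & removable)
    cand <- cand[vapply(cand, function(k) {
      ch <- kids[[as.character(k)]]
      is.null(ch) || !any(alive[ch])
    }, logical(1))]
    if (!length(cand)) break
    dev <- vapply(cand, function(k) {
      s <- secBins[[k]]
      rb <- removedBin
      rb[as.integer(names(s))] <- rb[as.integer(names(s))] + s
      max(abs(rb[ok] / avail[ok] - gf))
    }, numeric(1))
    k <- cand[which.min(dev)]
    s <- secBins[[k]]
    removedBin[as.integer(names(s))] <- removedBin[as.integer(names(s))] + s
    removed <- removed + sec$length_um[k]
    alive[k] <- FALSE
  }
  list(bins = removedBin, avail = avail, global_frac = gf)
}

# Brute-force per-stratum removed-length audit from removed node ids.
strataOf <- function(morph, stratum_um = 50) {
  nd <- morphNodes(morph)
  pr <- match(nd$parent, nd$id)
  el <- sqrt((nd$x - nd$x[pr])^2 + (nd$y - nd$y[pr])^2 + (nd$z - nd$z[pr])^2)
  mid <- (nd$radial_um + nd$radial_um[pr]) / 2
  dend <- nd$type %in% c(3L, 4L) & nd$parent != -1L
  data.frame(id = nd$id, len = el, bin = floor(mid / stratum_um) + 1L,
             dend = dend)
}
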