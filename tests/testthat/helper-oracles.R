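# Independent oracles and fixture builders used across the suite.

# Geodesic contour-ring oracle: shortest-path distance through the NAWM
# lattice (igraph BFS), binned into rings. Independent of the package's
# iterated-dilation implementation.
oracle_rings <- function(wmh, nawm, n_contours, width, connectivity = 6L) {
  d <- dim(wmh)
  nawm_only <- nawm & !wmh
  lab <- array(0L, d)
  if (!any(wmh)) { lab[nawm_only] <- 30L; return(lab) }
  node_mask <- wmh | nawm_only
  ids <- which(node_mask)
  node_of <- integer(prod(d)); node_of[ids] <- seq_along(ids)
  offs <- as.matrix(expand.grid(x = -1:1, y = -1:1, z = -1:1))
  if (connectivity == 6L) offs <- offs[rowSums(abs(offs)) == 1, , drop = FALSE]
  else offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  # keep one direction per neighbour pair (undirected edges)
  offs <- offs[offs[, 1] > 0 | (offs[, 1] == 0 & offs[, 2] > 0) |
                 (offs[, 1] == 0 & offs[, 2] == 0 & offs[, 3] > 0), ,
               drop = FALSE]
  co <- arrayInd(ids, d)
  edges <- list()
  for (i in seq_len(nrow(offs))) {
    nb <- sweep(co, 2, offs[i, ], "+")
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
      nb[, 3] >= 1 & nb[, 3] <= d[3]
    nbi <- nb[ok, 1] + (nb[ok, 2] - 1) * d[1] + (nb[ok, 3] - 1) * d[1] * d[2]
    tgt <- node_of[nbi]
    src <- seq_along(ids)[ok]
    keep <- tgt > 0L
    edges[[i]] <- cbind(src[keep], tgt[keep])
  }
  el <- do.call(rbind, edges)
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, length(ids) - igraph::vcount(g)))
  src_nodes <- node_of[which(wmh)]
  dm <- igraph::distances(g, v = src_nodes)
  dist <- apply(dm, 2, min)
  for (k in seq_len(n_contours)) {
    in_k <- dist > (k - 1L) * width & dist <= k * width
    sel <- ids[in_k & nawm_only[ids]]
    lab[sel] <- 10L + k
  }
  far <- ids[nawm_only[ids] & (dist > n_contours * width | is.infinite(dist))]
  lab[far] <- 30L
  lab
}

# Random blob-like mask: union of a few balls on the grid.
random_blob_mask <- function(d, n_balls, r_range = c(1.5, 4)) {
  idx <- arrayInd(seq_len(prod(d)), d)
  m <- rep(FALSE, prod(d))
  for (i in seq_len(n_balls)) {
    ctr <- runif(3, 2, d - 1)
    r <- runif(1, r_range[1], r_range[2])
    m <- m | (rowSums(sweep(idx, 2, ctr)^2) <= r^2)
  }
  array(m, d)
}

# Small compartment-truth table for hand-built voxel simulations.
flat_truth <- function(tissues, ktrans, vp = 0.005, t10 = 900, m0 = 1000,
                       md = 0.8, fa = 0.3) {
  data.frame(tissue = tissues, t10_ms = t10, m0 = m0,
             ktrans_per_min = ktrans, vp = vp, md = md, fa = fa,
             stringsAsFactors = FALSE)
}

# Numeric-quadrature Patlak oracle: tissue enhancement at given times via
# adaptive integration of the plasma curve (independent of the closed-form
# integral in the package).
quadrature_enhancement <- function(ktrans, vp, t10_ms, m0, cfg, times) {
  cum <- vapply(times, function(tt)
    stats::integrate(function(x) plasma_curve(x, cfg), 0, tt,
                     rel.tol = 1e-10, subdivisions = 2000L)$value,
    numeric(1))
  conc <- ktrans * cum + vp * plasma_curve(times, cfg)
  s0 <- spgr_signal(m0, t10_ms, cfg$tr_ms, cfg$flip_angles_deg[2])
  r1 <- 1 / t10_ms + cfg$r1_relaxivity * conc * 1e-3
  (spgr_signal(m0, 1 / r1, cfg$tr_ms, cfg$flip_angles_deg[2]) - s0) / s0
}

# Tiny deterministic cohort helper for model-level tests.
quick_cohort <- function(n = 60, seed = 1, effects = covariate_effects(), ...) {
  cfg <- cohort_config(n_patients = n, seed = seed, ...)
  generate_cohort(cfg, effects)
}
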