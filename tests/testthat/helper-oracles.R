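# Independent oracles and small fixture builders shared across the suite.
# Oracles deliberately use different formulations than the package code
# paths they check (dense assembly, parametric intersection, exhaustive
# scans).

# dense stiffness matrix from the analytic derivative of the element-loop
# force: dF(i,a)/dp(j,b) = -V [ lambda g_ia g_jb + mu (g_ja g_ib
#                               + delta_ab g_i.g_j) ]
oracle_dense_stiffness <- function(nbrs, grads, vols, lambda, mu, n_nodes) {
  K <- matrix(0, 3 * n_nodes, 3 * n_nodes)
  for (e in seq_along(nbrs)) {
    idx <- nbrs[[e]]
    G <- grads[[e]]
    V <- vols[e]
    for (ii in seq_along(idx)) {
      for (jj in seq_along(idx)) {
        gi <- G[ii, ]
        gj <- G[jj, ]
        blk <- -V * (lambda * outer(gi, gj) + mu * outer(gj, gi) +
                       mu * sum(gi * gj) * diag(3))
        ri <- 3 * (idx[ii] - 1) + 1:3
        rj <- 3 * (idx[jj] - 1) + 1:3
        K[ri, rj] <- K[ri, rj] + blk
      }
    }
  }
  K
}

# flatten an n x 3 state matrix to the (node-major) dense-K ordering
flat3 <- function(m) as.numeric(t(m))
unflat3 <- function(v) matrix(v, ncol = 3, byrow = TRUE)

# parametric segment-triangle intersection: solve P + t D = a + u e1 + v e2
# and test 0 <= t <= 1, u >= 0, v >= 0, u + v <= 1 (boundary inclusive).
oracle_seg_tri <- function(P, Q, tri, eps = 1e-12) {
  a <- tri[1:3]; b <- tri[4:6]; c <- tri[7:9]
  M <- cbind(b - a, c - a, -(Q - P))
  scale <- prod(pmax(sqrt(colSums(M^2)), 1e-300))
  if (abs(det(M)) < 1e-12 * scale) {
    # segment (near-)parallel to the triangle plane: intersection only in
    # the in-plane case, resolved conservatively by box overlap
    n <- c(M[2, 1] * M[3, 2] - M[3, 1] * M[2, 2],
           M[3, 1] * M[1, 2] - M[1, 1] * M[3, 2],
           M[1, 1] * M[2, 2] - M[2, 1] * M[1, 2])
    if (abs(sum((P - a) * n)) > eps * sqrt(sum(n^2)) * max(1, sqrt(sum((P - a)^2)))) {
      return(FALSE)
    }
    lo <- pmin(a, b, c); hi <- pmax(a, b, c)
    return(all(pmin(P, Q) <= hi & pmax(P, Q) >= lo))
  }
  x <- solve(M, P - a)
  u <- x[1]; v <- x[2]; t <- x[3]
  t >= -eps && t <= 1 + eps && u >= -eps && v >= -eps && u + v <= 1 + eps
}

oracle_any_seg_tri <- function(P, Q, tris) {
  for (t in seq_len(nrow(tris))) {
    if (oracle_seg_tri(P, Q, tris[t, ])) return(TRUE)
  }
  FALSE
}

# exhaustive severed-link scan over every stored pair and every triangle
oracle_detect <- function(scene, tris) {
  pr <- softcut::connectivityPairs(scene$tables)
  vol_hit <- vapply(seq_along(pr$elem), function(i) {
    oracle_any_seg_tri(scene$model$elems[pr$elem[i], ],
                       scene$model$nodes[pr$node[i], ], tris)
  }, logical(1))
  if (is.null(scene$tables$surf)) {
    return(list(volume = cbind(elem = pr$elem[vol_hit],
                               node = pr$node[vol_hit]),
                surface = cbind(vertex = integer(0), node = integer(0))))
  }
  sp <- local({
    t <- scene$tables$surf
    W <- t$max_row_width
    keep <- outer(t$row_lengths, seq_len(W), ">=")
    list(vertex = row(keep)[keep],
         node = as.integer(t$payload[, seq(1, 2 * W, by = 2)][keep]))
  })
  surf_hit <- vapply(seq_along(sp$vertex), function(i) {
    oracle_any_seg_tri(scene$surface$vertices[sp$vertex[i], ],
                       scene$model$nodes[sp$node[i], ], tris)
  }, logical(1))
  list(volume = cbind(elem = pr$elem[vol_hit], node = pr$node[vol_hit]),
       surface = cbind(vertex = sp$vertex[surf_hit],
                       node = sp$node[surf_hit]))
}

# exhaustive k-nearest-neighbor scan
oracle_knn <- function(points, q, k) {
  d2 <- colSums((t(points) - q)^2)
  order(d2, seq_len(nrow(points)))[seq_len(k)]
}

# regular block of nx x ny x nz grid nodes with the interior dual-grid
# elements; the smallest self-consistent volume model for dense oracles
block_model <- function(nx = 3, ny = 3, nz = 3, h = 1) {
  g <- expand.grid(z = (seq_len(nz) - 1) * h, y = (seq_len(ny) - 1) * h,
                   x = (seq_len(nx) - 1) * h, KEEP.OUT.ATTRS = FALSE)
  nodes <- cbind(g$x, g$y, g$z)
  ge <- expand.grid(z = (seq_len(nz - 1) - 0.5) * h,
                    y = (seq_len(ny - 1) - 0.5) * h,
                    x = (seq_len(nx - 1) - 0.5) * h, KEEP.OUT.ATTRS = FALSE)
  elems <- cbind(ge$x, ge$y, ge$z)
  softcut::newVolumeModel(nodes, elems, rep(h^3, nrow(elems)), h)
}

# minimal volume-only scene (no surface) around an arbitrary model
volume_scene <- function(model, k_min = 8, max_row_width = 16,
                         batch_size = 4) {
  sc <- new.env(parent = emptyenv())
  class(sc) <- "CutScene"
  sc$model <- model
  sc$params <- list(k_min = k_min, coplanar_tol = 0.05, cond_tol = 1e12,
                    dt = 1 / 60, gravity = c(0, 0, -9.81), cg_tol = 1e-6,
                    cg_max_iter = NULL, precision = "double")
  n_elems <- nrow(model$elems)
  bs <- min(batch_size, n_elems)
  W <- max_row_width
  sc$tables <- list(
    conn = softcut::createTable(n_elems, W, 4, bs, "connectivity"),
    values = softcut::createTable(n_elems, W, 8, bs, "shape_values"),
    grads = softcut::createTable(n_elems, W, 24, bs, "shape_gradients",
                                 slot_cols = 3)
  )
  nbrs <- softcut::buildInitialConnectivity(model, k_min, W)
  for (e in seq_len(n_elems)) softcut::writeRow(sc$tables$conn, e, nbrs[[e]])
  sc$support_radii <- softcut::nodeSupportRadii(model, k_min)
  for (e in seq_len(n_elems)) softcut::recomputeElementShapes(sc, e)
  sc$material <- softcut::materialParams()
  sc$fixed <- logical(nrow(model$nodes))
  sc$mass <- softcut::lumpedMass(model, sc$tables, sc$material)
  sc$cut_surface <- softcut::newCutSurface()
  for (t in sc$tables) softcut::flushTable(t)
  sc
}

# shape rows as plain lists (for the dense oracle)
scene_shape_lists <- function(scene) {
  n_elems <- nrow(scene$model$elems)
  nbrs <- lapply(seq_len(n_elems), function(e) {
    as.integer(softcut::readRow(scene$tables$conn, e))
  })
  grads <- lapply(seq_len(n_elems), function(e) {
    softcut::readRow(scene$tables$grads, e)
  })
  list(nbrs = nbrs, grads = grads)
}

# memoised expensive fixtures (shared across test files within a run)
.fixture_cache <- new.env(parent = emptyenv())
cached_fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache, inherits = FALSE)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache, inherits = FALSE)
}

# the standard small torus demo configuration used throughout the suite
small_demo_config <- function(...) {
  softcut::defaultRunConfig(
    h = 0.15, n_u = 24, n_v = 12, n_frames = 40,
    cut_start = 6L, cut_frames = 20L, batch_size = 16L, ...
  )
}

small_scene <- function() {
  cached_fixture("small_scene", function() softcut::buildScene(small_demo_config()))
}

# partition-of-unity / gradient-consistency / linear-reproduction residuals
# for every element row, computed straight off the table payloads
shape_invariant_residuals <- function(scene) {
  n_elems <- nrow(scene$model$elems)
  pou <- grad <- repro <- numeric(n_elems)
  for (e in seq_len(n_elems)) {
    nbr <- as.integer(softcut::readRow(scene$tables$conn, e))
    phi <- softcut::readRow(scene$tables$values, e)
    g <- softcut::readRow(scene$tables$grads, e)
    pou[e] <- abs(sum(phi) - 1)
    grad[e] <- max(abs(colSums(g)))
    repro[e] <- max(abs(colSums(phi * scene$model$nodes[nbr, , drop = FALSE]) -
                          scene$model$elems[e, ]))
  }
  list(pou = pou, grad = grad, repro = repro)
}
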