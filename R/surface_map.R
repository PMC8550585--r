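# Surface embedding: each render-mesh vertex carries a weight row over
# volume nodes (stored index+weight pairs in a fixed-width table).  The
# vertex-node graph reuses the element-node connectivity: a vertex maps to
# the neighbor node set of its nearest element, with weights given by the
# MLS shape values at the vertex rest position, so the surface deforms
# consistently with the volume (exact linear reproduction, translation
# equivariance).

surfacePairs <- function(surf) {
    W <- surf$max_row_width
    keep <- outer(surf$row_lengths, seq_len(W), ">=")
    idx <- surf$payload[, seq(1, 2 * W, by = 2), drop = FALSE]
    wts <- surf$payload[, seq(2, 2 * W, by = 2), drop = FALSE]
    list(
        vertex = row(keep)[keep],
        node = as.integer(idx[keep]),
        w = wts[keep]
    )
}

#' Build the vertex-to-node surface mapping
#'
#' Fills the surface-weight table: vertex v gets the node set of its
#' nearest element and MLS weights evaluated at the vertex rest position.
#' Weights sum to 1 per vertex (partition of unity).
#'
#' @param scene a `CutScene` whose connectivity and shape tables are built.
#' @param chunk vertices per distance block.
#' @return Invisibly, the per-vertex nearest-element index vector.
#' @export
buildSurfaceMapping <- function(scene, chunk = 512L) {
    verts <- scene$surface$vertices
    elems <- scene$model$elems
    nv <- nrow(verts)
    nearest <- integer(nv)
    for (lo in seq(1L, nv, by = chunk)) {
        hi <- min(lo + chunk - 1L, nv)
        blk <- verts[lo:hi, , drop = FALSE]
        d2 <- outer(rowSums(blk^2), rowSums(elems^2), "+") -
            2 * blk %*% t(elems)
        nearest[lo:hi] <- max.col(-d2, ties.method = "first")
    }
    for (v in seq_len(nv)) {
        nbr <- as.integer(readRow(scene$tables$conn, nearest[v]))
        sh <- shapeRow(verts[v, ], scene$model$nodes[nbr, , drop = FALSE],
                       scene$support_radii[nbr],
                       cond_tol = scene$params$cond_tol,
                       label = sprintf("vertex %d", v))
        writeRow(scene$tables$surf, v, cbind(nbr, sh$values))
    }
    invisible(nearest)
}

#' Current surface vertex positions
#'
#' x_v = X_v + sum_i w_i^v u_i over the vertex's mapped nodes.
#'
#' @param scene a `CutScene`.
#' @param state a `SimState` (uses `state$u`).
#' @return n_vertices x 3 matrix of deformed positions.
#' @export
updateSurfacePositions <- function(scene, state) {
    sp <- surfacePairs(scene$tables$surf)
    out <- scene$surface$vertices
    if (length(sp$vertex)) {
        for (d in 1:3) {
            disp <- rowsum(sp$w * state$u[sp$node, d], sp$vertex)
            out[as.integer(rownames(disp)), d] <-
                out[as.integer(rownames(disp)), d] + disp
        }
    }
    out
}
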