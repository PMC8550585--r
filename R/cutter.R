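# Topology changes: swept-blade surface accumulation, link severing by
# segment-triangle intersection (rest coordinates, tie-inclusive), neighbor
# re-selection under the coplanarity and visibility criteria, and dirty-row
# bookkeeping that touches only the modified rows.

#' Accumulated cut surface
#'
#' Swept-tool triangles with per-triangle frame stamps.  Used both for link
#' severing (against a frame's new triangles) and for the visibility test
#' (against the full accumulated surface).
#'
#' @return An environment of class `CutSurface`.
#' @export
newCutSurface <- function() {
    cs <- new.env(parent = emptyenv())
    cs$tris <- matrix(numeric(0), 0, 9)
    cs$frame <- integer(0)
    class(cs) <- "CutSurface"
    cs
}

#' @export
print.CutSurface <- function(x, ...) {
    cat(sprintf("CutSurface: %d triangles over %d frames\n",
                nrow(x$tris), length(unique(x$frame))))
    invisible(x)
}

#' @rdname newCutSurface
#' @param cs a `CutSurface`.
#' @param tris k x 9 matrix of triangles (three concatenated vertices).
#' @param frame frame stamp.
#' @export
addCutTriangles <- function(cs, tris, frame) {
    if (nrow(tris) > 0) {
        cs$tris <- rbind(cs$tris, tris)
        cs$frame <- c(cs$frame, rep(as.integer(frame), nrow(tris)))
    }
    invisible(cs)
}

triangleAreas <- function(tris) {
    if (nrow(tris) == 0) return(numeric(0))
    e1 <- tris[, 4:6, drop = FALSE] - tris[, 1:3, drop = FALSE]
    e2 <- tris[, 7:9, drop = FALSE] - tris[, 1:3, drop = FALSE]
    cx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
    cy <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
    cz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
    0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

#' Sweep the tool between two frames
#'
#' For each polyline segment, the quad between its position at the previous
#' and current frame, split along one diagonal into two triangles:
#' (a0, b0, b1) and (a0, b1, a1).  Degenerate triangles (area below
#' `min_area`) are dropped, so a stationary tool sweeps nothing.
#'
#' @param tool_prev,tool_next k x 3 polyline endpoint matrices (same k).
#' @param min_area area threshold for discarding degenerate sweeps
#'   (default 1e-12; scale as 1e-12 h^2 in scene code).
#' @return n x 9 matrix of swept triangles.
#' @export
sweepTool <- function(tool_prev, tool_next, min_area = 1e-12) {
    tool_prev <- as.matrix(tool_prev)
    tool_next <- as.matrix(tool_next)
    if (!all(dim(tool_prev) == dim(tool_next))) {
        stop(softcutError("tool polylines must have the same endpoint count",
                          "softcutArgumentError"))
    }
    k <- nrow(tool_prev)
    tris <- matrix(numeric(0), 0, 9)
    for (s in seq_len(k - 1)) {
        a0 <- tool_prev[s, ]; b0 <- tool_prev[s + 1, ]
        a1 <- tool_next[s, ]; b1 <- tool_next[s + 1, ]
        tris <- rbind(tris, c(a0, b0, b1), c(a0, b1, a1))
    }
    tris[triangleAreas(tris) > min_area, , drop = FALSE]
}

# segment-triangle intersection ---------------------------------------------

cross3 <- function(u, v) {
    cbind(
        u[, 2] * v[, 3] - u[, 3] * v[, 2],
        u[, 3] * v[, 1] - u[, 1] * v[, 3],
        u[, 1] * v[, 2] - u[, 2] * v[, 1]
    )
}

#' Segment-triangle intersection (tie-inclusive)
#'
#' Orientation-test formulation: a segment intersects a triangle iff its
#' endpoints do not lie strictly on the same side of the triangle plane and
#' the three segment-vs-edge orientation tests share a sign.  Ties (segment
#' touching an edge, vertex, or the plane) count as intersection —
#' conservative severing.  The fully coplanar case falls back to a
#' bounding-box overlap test.
#'
#' @param P,Q n x 3 matrices of segment start/end points.
#' @param tris m x 9 triangle matrix.
#' @return Logical vector: does segment i hit any triangle?
#' @export
segmentsHitTriangles <- function(P, Q, tris) {
    P <- matrix(P, ncol = 3)
    Q <- matrix(Q, ncol = 3)
    n <- nrow(P)
    hit <- logical(n)
    if (nrow(tris) == 0 || n == 0) return(hit)
    for (t in seq_len(nrow(tris))) {
        todo <- which(!hit)
        if (length(todo) == 0) break
        a <- tris[t, 1:3]; b <- tris[t, 4:6]; c3 <- tris[t, 7:9]
        nrm <- c(
            (b[2] - a[2]) * (c3[3] - a[3]) - (b[3] - a[3]) * (c3[2] - a[2]),
            (b[3] - a[3]) * (c3[1] - a[1]) - (b[1] - a[1]) * (c3[3] - a[3]),
            (b[1] - a[1]) * (c3[2] - a[2]) - (b[2] - a[2]) * (c3[1] - a[1])
        )
        Pi <- P[todo, , drop = FALSE]
        Qi <- Q[todo, , drop = FALSE]
        sA <- (Pi[, 1] - a[1]) * nrm[1] + (Pi[, 2] - a[2]) * nrm[2] +
            (Pi[, 3] - a[3]) * nrm[3]
        sB <- (Qi[, 1] - a[1]) * nrm[1] + (Qi[, 2] - a[2]) * nrm[2] +
            (Qi[, 3] - a[3]) * nrm[3]
        straddle <- sA * sB <= 0 & !(sA == 0 & sB == 0)
        coplanar <- sA == 0 & sB == 0
        res <- logical(length(todo))
        idx <- which(straddle)
        if (length(idx)) {
            Ps <- Pi[idx, , drop = FALSE]
            D <- Qi[idx, , drop = FALSE] - Ps
            A <- matrix(a, length(idx), 3, byrow = TRUE) - Ps
            B <- matrix(b, length(idx), 3, byrow = TRUE) - Ps
            C <- matrix(c3, length(idx), 3, byrow = TRUE) - Ps
            t1 <- rowSums(D * cross3(A, B))
            t2 <- rowSums(D * cross3(B, C))
            t3 <- rowSums(D * cross3(C, A))
            res[idx] <- (t1 >= 0 & t2 >= 0 & t3 >= 0) |
                (t1 <= 0 & t2 <= 0 & t3 <= 0)
        }
        idx <- which(coplanar)
        if (length(idx)) {
            tmin <- pmin(a, b, c3); tmax <- pmax(a, b, c3)
            Ps <- Pi[idx, , drop = FALSE]
            Qs <- Qi[idx, , drop = FALSE]
            ov <- rep(TRUE, length(idx))
            for (dmn in 1:3) {
                ov <- ov & pmin(Ps[, dmn], Qs[, dmn]) <= tmax[dmn] &
                    pmax(Ps[, dmn], Qs[, dmn]) >= tmin[dmn]
            }
            res[idx] <- ov
        }
        hit[todo[res]] <- TRUE
    }
    hit
}

# axis-aligned bounding-box prefilter: keep segments whose box overlaps the
# union box of the triangles (pruning only; the exact test decides)
segmentBoxFilter <- function(P, Q, tris) {
    if (nrow(tris) == 0) return(integer(0))
    lo <- c(min(tris[, c(1, 4, 7)]), min(tris[, c(2, 5, 8)]),
            min(tris[, c(3, 6, 9)]))
    hi <- c(max(tris[, c(1, 4, 7)]), max(tris[, c(2, 5, 8)]),
            max(tris[, c(3, 6, 9)]))
    keep <- rep(TRUE, nrow(P))
    for (d in 1:3) {
        keep <- keep & pmin(P[, d], Q[, d]) <= hi[d] &
            pmax(P[, d], Q[, d]) >= lo[d]
    }
    which(keep)
}

#' Detect element-node and vertex-node links severed by new sweep triangles
#'
#' A link is severed iff the straight segment from the element center
#' (resp. surface-vertex rest position) to the node rest position
#' intersects any of the frame's new swept triangles, boundary inclusive.
#' An AABB prefilter prunes candidates; the exact orientation test decides.
#'
#' @param scene a `CutScene`.
#' @param new_tris k x 9 matrix of this frame's sweep triangles.
#' @return List with `volume` (matrix, columns elem / node) and `surface`
#'   (matrix, columns vertex / node).
#' @export
detectCutLinks <- function(scene, new_tris) {
    empty <- list(
        volume = matrix(integer(0), 0, 2,
                        dimnames = list(NULL, c("elem", "node"))),
        surface = matrix(integer(0), 0, 2,
                         dimnames = list(NULL, c("vertex", "node")))
    )
    if (is.null(new_tris) || nrow(new_tris) == 0) return(empty)
    pr <- connectivityPairs(scene$tables)
    P <- scene$model$elems[pr$elem, , drop = FALSE]
    Q <- scene$model$nodes[pr$node, , drop = FALSE]
    cand <- segmentBoxFilter(P, Q, new_tris)
    volhit <- cand[segmentsHitTriangles(P[cand, , drop = FALSE],
                                        Q[cand, , drop = FALSE], new_tris)]
    vol <- cbind(elem = pr$elem[volhit], node = pr$node[volhit])

    if (is.null(scene$tables$surf)) {        # volume-only scene
        return(list(volume = vol, surface = empty$surface))
    }
    sp <- surfacePairs(scene$tables$surf)
    P <- scene$surface$vertices[sp$vertex, , drop = FALSE]
    Q <- scene$model$nodes[sp$node, , drop = FALSE]
    cand <- segmentBoxFilter(P, Q, new_tris)
    surfhit <- cand[segmentsHitTriangles(P[cand, , drop = FALSE],
                                         Q[cand, , drop = FALSE], new_tris)]
    surf <- cbind(vertex = sp$vertex[surfhit], node = sp$node[surfhit])
    list(volume = vol, surface = surf)
}

#' Visibility test against the accumulated cut surface
#'
#' A node is a valid neighbor of an evaluation point only if the segment
#' joining them crosses no accumulated cut triangle (ties count as
#' crossings, so nothing ever reconnects across a cut).
#'
#' @param from length-3 point (element center or vertex).
#' @param to k x 3 matrix of candidate endpoints.
#' @param cs a `CutSurface`.
#' @return Logical vector, TRUE where visible.
#' @export
visibleFrom <- function(from, to, cs) {
    to <- matrix(to, ncol = 3)
    if (nrow(cs$tris) == 0) return(rep(TRUE, nrow(to)))
    P <- matrix(from, nrow(to), 3, byrow = TRUE)
    out <- rep(TRUE, nrow(to))
    cand <- segmentBoxFilter(P, to, cs$tris)
    if (length(cand)) {
        out[cand] <- !segmentsHitTriangles(P[cand, , drop = FALSE],
                                           to[cand, , drop = FALSE], cs$tris)
    }
    out
}

#' Apply a frame's topology changes
#'
#' Severed nodes are removed from their element rows; a modified element
#' falling below `k_min` neighbors or failing the coplanarity check is
#' refilled with its nearest *visible* nodes until both conditions hold
#' (overflow error naming the element if the fixed row width cannot
#' accommodate a valid set).  Shape rows of modified elements are
#' recomputed.  Vertex mappings lose their severed nodes and are
#' renormalized; a vertex whose weights collapse (sum below 1e-9) is
#' remapped from scratch to the node set of its nearest visible element.
#' Exactly the modified rows — and no others — become dirty, and the lumped
#' mass vector is refreshed.
#'
#' @param scene a `CutScene`.
#' @param severed result of [detectCutLinks()].
#' @param frame current frame number (stamped nowhere here; kept for logs).
#' @return List with `modified_elements`, `modified_vertices`,
#'   `n_overflow` (always 0 on normal return; overflow raises).
#' @export
applyCut <- function(scene, severed, frame = NA_integer_) {
    mod_elems <- integer(0)
    mod_verts <- integer(0)
    if (nrow(severed$volume) > 0) {
        by_elem <- split(severed$volume[, "node"], severed$volume[, "elem"])
        for (en in names(by_elem)) {
            e <- as.integer(en)
            cutElementRow(scene, e, as.integer(by_elem[[en]]))
            mod_elems <- c(mod_elems, e)
        }
    }
    if (nrow(severed$surface) > 0) {
        by_vert <- split(severed$surface[, "node"], severed$surface[, "vertex"])
        for (vn in names(by_vert)) {
            v <- as.integer(vn)
            cutVertexRow(scene, v, as.integer(by_vert[[vn]]))
            mod_verts <- c(mod_verts, v)
        }
    }
    if (length(mod_elems) || length(mod_verts)) {
        scene$mass <- lumpedMass(scene$model, scene$tables, scene$material)
    }
    list(modified_elements = sort(mod_elems),
         modified_vertices = sort(mod_verts),
         n_overflow = 0L)
}

# remove severed nodes from one element row, refill under the coplanarity +
# visibility criteria, recompute its shape rows
cutElementRow <- function(scene, e, severed_nodes) {
    p <- scene$params
    row <- as.integer(readRow(scene$tables$conn, e))
    row <- setdiff(row, severed_nodes)
    center <- scene$model$elems[e, ]
    nodes <- scene$model$nodes
    needsWork <- function(r) {
        length(r) < p$k_min ||
            !coplanarityCheck(nodes[r, , drop = FALSE], p$coplanar_tol,
                              scene$model$h)
    }
    if (needsWork(row)) {
        d2 <- colSums((t(nodes) - center)^2)
        cand <- order(d2, seq_len(nrow(nodes)))
        cand <- cand[!(cand %in% row) & !(cand %in% severed_nodes)]
        # visibility is checked lazily, a chunk of candidates at a time,
        # since most cuts need only a handful of replacements
        ci <- 0L
        nextVisible <- function() {
            while (ci < length(cand)) {
                take <- cand[(ci + 1L):min(ci + 16L, length(cand))]
                vis <- visibleFrom(center, nodes[take, , drop = FALSE],
                                   scene$cut_surface)
                ci <<- ci + length(take)
                if (any(vis)) return(take[vis])
            }
            integer(0)
        }
        queue <- integer(0)
        repeat {
            if (!needsWork(row)) break
            if (length(row) >= scene$tables$conn$max_row_width) {
                overflowError(e, "connectivity", length(row) + 1L,
                              scene$tables$conn$max_row_width)
            }
            if (length(queue) == 0) queue <- nextVisible()
            if (length(queue) == 0) {
                overflowError(e, "connectivity", length(row) + 1L,
                              scene$tables$conn$max_row_width)
            }
            row <- c(row, queue[1L])
            queue <- queue[-1L]
        }
    }
    writeRow(scene$tables$conn, e, row)
    recomputeElementShapes(scene, e)
    invisible(row)
}

# remove severed nodes from one vertex mapping row; renormalize or remap
cutVertexRow <- function(scene, v, severed_nodes) {
    m <- readRow(scene$tables$surf, v)
    if (length(m) == 0) m <- matrix(numeric(0), 0, 2)
    keep <- !(m[, 1] %in% severed_nodes)
    m <- m[keep, , drop = FALSE]
    s <- if (nrow(m)) sum(m[, 2]) else 0
    if (nrow(m) >= 1 && s >= 1e-9) {
        m[, 2] <- m[, 2] / s
        writeRow(scene$tables$surf, v, m)
    } else {
        remapVertex(scene, v)
    }
    invisible(v)
}

# rebuild a vertex mapping from its nearest visible element's node set
remapVertex <- function(scene, v) {
    x <- scene$surface$vertices[v, ]
    d2 <- colSums((t(scene$model$elems) - x)^2)
    ord <- order(d2, seq_len(nrow(scene$model$elems)))
    for (e in ord[seq_len(min(64L, length(ord)))]) {
        if (!visibleFrom(x, matrix(scene$model$elems[e, ], 1, 3),
                         scene$cut_surface)) next
        nbr <- as.integer(readRow(scene$tables$conn, e))
        vis <- visibleFrom(x, scene$model$nodes[nbr, , drop = FALSE],
                           scene$cut_surface)
        nbr <- nbr[vis]
        if (length(nbr) < 4) next
        sh <- try(shapeRow(x, scene$model$nodes[nbr, , drop = FALSE],
                           scene$support_radii[nbr],
                           cond_tol = scene$params$cond_tol,
                           label = sprintf("vertex %d remap", v)),
                  silent = TRUE)
        if (inherits(sh, "try-error")) next
        writeRow(scene$tables$surf, v, cbind(nbr, sh$values))
        return(invisible(v))
    }
    stop(softcutError(
        sprintf("vertex %d: no visible element with a usable node set", v),
        "softcutRemapError"
    ))
}
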