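# Synthetic test-scene factory: torus volume model, parametric torus surface,
# initial element-node connectivity and the scripted blade trajectory.

#' Volume model constructor
#'
#' A volume model is a node cloud plus cubic integration elements: each
#' element is a quadrature cell with a center and a volume, at which strain
#' and stress are evaluated and distributed to its neighbor nodes.
#'
#' @param node_positions n x 3 matrix of node rest positions.
#' @param element_centers m x 3 matrix of element centers.
#' @param element_volume length-m vector of element volumes.
#' @param grid_spacing the generating grid spacing h.
#' @return An object of class `VolumeModel`.
#' @export
newVolumeModel <- function(node_positions, element_centers, element_volume,
                           grid_spacing) {
    node_positions <- as.matrix(node_positions)
    element_centers <- as.matrix(element_centers)
    stopifnot(
        ncol(node_positions) == 3, ncol(element_centers) == 3,
        length(element_volume) == nrow(element_centers),
        all(element_volume > 0), grid_spacing > 0,
        nrow(node_positions) > 0, nrow(element_centers) > 0
    )
    structure(
        list(
            nodes = node_positions,
            elems = element_centers,
            vol = as.numeric(element_volume),
            h = grid_spacing
        ),
        class = "VolumeModel"
    )
}

#' @export
print.VolumeModel <- function(x, ...) {
    cat(sprintf(
        "VolumeModel: %d nodes, %d cubic elements (h = %g, total volume %g)\n",
        nrow(x$nodes), nrow(x$elems), x$h, sum(x$vol)
    ))
    invisible(x)
}

#' Is a point inside the solid torus?
#'
#' Solid torus around the z axis: (sqrt(x^2 + y^2) - R)^2 + z^2 <= r^2.
#'
#' @param p n x 3 matrix of points.
#' @param R,r major and minor radii.
#' @return Logical vector.
#' @export
insideTorus <- function(p, R, r) {
    p <- matrix(p, ncol = 3)
    (sqrt(p[, 1]^2 + p[, 2]^2) - R)^2 + p[, 3]^2 <= r^2
}

# grid coordinates i*h covering [-lim, lim]
gridAxis <- function(lim, h, offset = 0) {
    i <- seq(floor((-lim - offset) / h), ceiling((lim - offset) / h))
    i * h + offset
}

#' Generate the torus volume model
#'
#' Nodes are regular-grid points of spacing `h` inside the solid torus;
#' element centers sit on the dual grid (offset h/2 in every axis), also
#' restricted to the torus, each with volume h^3.  Generation is fully
#' deterministic in (R, r, h).
#'
#' @param R major radius (tube center-line radius).
#' @param r minor radius (tube radius).
#' @param h grid spacing; requires 0 < h < r < R.
#' @return A [newVolumeModel()] object.
#' @export
generateTorusVolume <- function(R = 1, r = 0.3, h = 0.07) {
    if (!(h > 0 && h < r && r < R)) {
        stop(softcutError(
            sprintf("invalid torus geometry: need 0 < h < r < R, got h=%g r=%g R=%g", h, r, R),
            "softcutGeometryError"
        ))
    }
    lim_xy <- R + r
    grid3 <- function(offset) {
        xs <- gridAxis(lim_xy, h, offset)
        ys <- gridAxis(lim_xy, h, offset)
        zs <- gridAxis(r, h, offset)
        # x slowest, then y, then z: rows within a (x, y) column are contiguous
        g <- expand.grid(z = zs, y = ys, x = xs, KEEP.OUT.ATTRS = FALSE)
        cbind(g$x, g$y, g$z)
    }
    nodes <- grid3(0)
    nodes <- nodes[insideTorus(nodes, R, r), , drop = FALSE]
    elems <- grid3(h / 2)
    elems <- elems[insideTorus(elems, R, r), , drop = FALSE]
    if (nrow(nodes) < 8 || nrow(elems) < 1) {
        stop(softcutError(
            sprintf(
                "degenerate torus discretization: %d nodes, %d elements (need >= 8 and >= 1)",
                nrow(nodes), nrow(elems)
            ),
            "softcutGeometryError"
        ))
    }
    newVolumeModel(nodes, elems, rep(h^3, nrow(elems)), h)
}

#' Surface mesh constructor
#' @param vertices n x 3 matrix of vertex rest positions.
#' @param triangles m x 3 integer matrix of 1-based vertex indices.
#' @return Object of class `SurfaceMesh`.
#' @export
newSurfaceMesh <- function(vertices, triangles) {
    vertices <- as.matrix(vertices)
    triangles <- matrix(as.integer(as.matrix(triangles)), ncol = 3)
    stopifnot(ncol(vertices) == 3)
    if (nrow(triangles) > 0 &&
        (min(triangles) < 1 || max(triangles) > nrow(vertices))) {
        stop(softcutError("triangle index out of range", "softcutGeometryError"))
    }
    structure(list(vertices = vertices, triangles = triangles),
              class = "SurfaceMesh")
}

#' @export
print.SurfaceMesh <- function(x, ...) {
    cat(sprintf(
        "SurfaceMesh: %d vertices, %d triangles\n",
        nrow(x$vertices), nrow(x$triangles)
    ))
    invisible(x)
}

#' Generate a closed parametric torus triangulation
#'
#' `n_u` subdivisions around the major circle and `n_v` around the tube give
#' `n_u * n_v` vertices and `2 * n_u * n_v` triangles forming a closed
#' genus-1 surface (every edge shared by exactly two triangles).
#'
#' @param R,r torus radii.
#' @param n_u,n_v major/minor subdivision counts (each >= 3).
#' @return A [newSurfaceMesh()] object.
#' @export
generateTorusSurface <- function(R = 1, r = 0.3, n_u = 100, n_v = 50) {
    stopifnot(n_u >= 3, n_v >= 3)
    iu <- rep(seq_len(n_u) - 1L, each = n_v)
    iv <- rep(seq_len(n_v) - 1L, times = n_u)
    th <- 2 * pi * iu / n_u
    ph <- 2 * pi * iv / n_v
    verts <- cbind(
        (R + r * cos(ph)) * cos(th),
        (R + r * cos(ph)) * sin(th),
        r * sin(ph)
    )
    vid <- function(u, v) (u %% n_u) * n_v + (v %% n_v) + 1L
    u <- rep(seq_len(n_u) - 1L, each = n_v)
    v <- rep(seq_len(n_v) - 1L, times = n_u)
    a <- vid(u, v); b <- vid(u + 1L, v); c2 <- vid(u + 1L, v + 1L); d <- vid(u, v + 1L)
    tris <- rbind(cbind(a, b, c2), cbind(a, c2, d))
    newSurfaceMesh(verts, tris)
}

# spatial hash of points into cubic cells of size h -------------------------

makeCellIndex <- function(points, h, offset = 0) {
    key <- apply(round((points - offset) / h), 1, paste, collapse = ",")
    cells <- new.env(parent = emptyenv(), hash = TRUE)
    idx <- split(seq_len(nrow(points)), key)
    for (k in names(idx)) assign(k, idx[[k]], envir = cells)
    list(cells = cells, h = h, offset = offset)
}

cellCandidates <- function(index, center, L) {
    base <- floor((center - index$offset) / index$h + 1e-9)
    rng <- lapply(1:3, function(d) (base[d] - L):(base[d] + 1L + L))
    keys <- apply(expand.grid(rng[[1]], rng[[2]], rng[[3]]), 1, paste,
                  collapse = ",")
    out <- lapply(keys, function(k) {
        if (exists(k, envir = index$cells, inherits = FALSE)) {
            get(k, envir = index$cells, inherits = FALSE)
        } else NULL
    })
    unlist(out, use.names = FALSE)
}

#' Build the initial element-node connectivity
#'
#' Each element receives its `k_min` nearest nodes (rest-position Euclidean
#' distance), extended with next-nearest nodes whenever the selected set
#' fails the [coplanarityCheck()] spread test, up to `max_row_width`.  A set
#' that cannot be made non-coplanar within the row budget raises an overflow
#' error naming the element.
#'
#' @param model a `VolumeModel`.
#' @param k_min minimum neighbors per element (>= 4; default 8).
#' @param max_row_width fixed row capacity of the connectivity store.
#' @param coplanar_tol tolerance fraction for [coplanarityCheck()].
#' @return List of integer vectors (1-based node indices), one per element.
#' @export
buildInitialConnectivity <- function(model, k_min = 8, max_row_width = 16,
                                     coplanar_tol = 0.05) {
    stopifnot(k_min >= 4)
    nodes <- model$nodes
    h <- model$h
    index <- makeCellIndex(nodes, h)
    n_elems <- nrow(model$elems)
    out <- vector("list", n_elems)
    for (e in seq_len(n_elems)) {
        center <- model$elems[e, ]
        L <- 0L
        repeat {
            cand <- cellCandidates(index, center, L)
            enough <- length(cand) >= min(k_min + 4L, nrow(nodes))
            if (enough || length(cand) == nrow(nodes) || L >= 6L) break
            L <- L + 1L
        }
        sel <- selectNonCoplanar(nodes, cand, center, k_min, max_row_width,
                                 coplanar_tol, h, label = e)
        # the local candidate window may be too small for a valid set; widen
        while (is.null(sel) && length(cand) < nrow(nodes) && L < 8L) {
            L <- L + 2L
            cand <- cellCandidates(index, center, L)
            sel <- selectNonCoplanar(nodes, cand, center, k_min, max_row_width,
                                     coplanar_tol, h, label = e)
        }
        if (is.null(sel)) {
            overflowError(e, "connectivity",
                          needed = max_row_width + 1L, max_row_width = max_row_width)
        }
        out[[e]] <- sel
    }
    out
}

# Greedy distance-ordered selection: take the k_min nearest candidates, then
# keep appending the next-nearest until the set spans 3D.  NULL when the
# candidate pool is exhausted or the row budget is hit while still coplanar.
selectNonCoplanar <- function(nodes, cand, center, k_min, max_row_width,
                              coplanar_tol, h, label) {
    if (length(cand) < k_min) return(NULL)
    d2 <- colSums((t(nodes[cand, , drop = FALSE]) - center)^2)
    ord <- cand[order(d2, cand)]
    k <- min(k_min, length(ord))
    sel <- ord[seq_len(k)]
    repeat {
        ok <- length(sel) >= k_min &&
            coplanarityCheck(nodes[sel, , drop = FALSE], coplanar_tol, h)
        if (ok) return(as.integer(sel))
        if (length(sel) >= max_row_width || length(sel) >= length(ord)) {
            return(NULL)
        }
        sel <- ord[seq_len(length(sel) + 1L)]
    }
}

#' Per-node MLS support radii
#'
#' The support radius of node i is 1.1 times the distance to its k-th
#' nearest element center at rest; supports are never recomputed during a
#' run (total-Lagrangian, rest-configuration shape functions).
#'
#' @param model a `VolumeModel`.
#' @param k which nearest element center sets the radius (default 8).
#' @param chunk rows per distance block (memory control).
#' @return Numeric vector of radii, one per node.
#' @export
nodeSupportRadii <- function(model, k = 8, chunk = 512L) {
    nodes <- model$nodes
    elems <- model$elems
    k <- min(k, nrow(elems))
    n <- nrow(nodes)
    out <- numeric(n)
    for (lo in seq(1L, n, by = chunk)) {
        hi <- min(lo + chunk - 1L, n)
        blk <- nodes[lo:hi, , drop = FALSE]
        d2 <- outer(rowSums(blk^2), rowSums(elems^2), "+") -
            2 * blk %*% t(elems)
        out[lo:hi] <- apply(d2, 1, function(v) sqrt(max(sort(v, partial = k)[k], 0)))
    }
    1.1 * out
}

#' Tool trajectory constructor
#'
#' @param frames list of k x 3 matrices (polyline endpoints), one per frame.
#' @return Object of class `ToolTrajectory`.
#' @export
newToolTrajectory <- function(frames) {
    stopifnot(length(frames) >= 1)
    frames <- lapply(frames, function(f) {
        f <- as.matrix(f)
        stopifnot(ncol(f) == 3, nrow(f) >= 2)
        f
    })
    structure(list(frames = frames), class = "ToolTrajectory")
}

#' Default blade trajectory through the torus tube
#'
#' A two-point blade segment, parallel to z and spanning beyond the tube,
#' translates across the tube cross-section near the azimuth theta = 0: x
#' goes from R - 1.2 r to R + 1.2 r over `n_frames`, so the blade starts and
#' ends outside the solid.  The sweep plane is offset from y = 0 by
#' `plane_offset` so that it never coincides with a grid symmetry plane or
#' the surface seam (which would create degenerate tangential contacts).
#'
#' @param R,r torus radii.
#' @param n_frames number of trajectory frames (>= 2).
#' @param plane_offset y position of the sweep plane (default r/17).
#' @return A [newToolTrajectory()] object.
#' @export
defaultCutTrajectory <- function(R = 1, r = 0.3, n_frames = 60,
                                 plane_offset = r / 17) {
    stopifnot(n_frames >= 2)
    xs <- seq(R - 1.2 * r, R + 1.2 * r, length.out = n_frames)
    z <- 1.5 * r
    frames <- lapply(xs, function(x) {
        rbind(c(x, plane_offset, -z), c(x, plane_offset, z))
    })
    newToolTrajectory(frames)
}
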