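# Moving-least-squares (EFG) shape functions with a linear basis
# p(x) = (1, x, y, z) and the C^2 cubic B-spline weight.  Values and
# gradients are evaluated at rest positions only (total-Lagrangian,
# small-strain model) and stored row-aligned with the connectivity table.

#' Cubic B-spline weight of normalized distance
#'
#' w(q) = 2/3 - 4 q^2 + 4 q^3 for q <= 1/2,
#' w(q) = 4/3 - 4 q + 4 q^2 - (4/3) q^3 for 1/2 < q <= 1, else 0.
#'
#' @param q normalized distance(s) |x - x_i| / r_i.
#' @return Weight values (and, from [splineWeightDeriv()], dw/dq).
#' @export
splineWeight <- function(q) {
    w <- numeric(length(q))
    a <- q <= 0.5
    b <- q > 0.5 & q <= 1
    w[a] <- 2 / 3 - 4 * q[a]^2 + 4 * q[a]^3
    w[b] <- 4 / 3 - 4 * q[b] + 4 * q[b]^2 - (4 / 3) * q[b]^3
    w
}

#' @rdname splineWeight
#' @export
splineWeightDeriv <- function(q) {
    dw <- numeric(length(q))
    a <- q <= 0.5
    b <- q > 0.5 & q <= 1
    dw[a] <- -8 * q[a] + 12 * q[a]^2
    dw[b] <- -4 + 8 * q[b] - 4 * q[b]^2
    dw
}

#' Coplanarity (3D spread) check for a neighbor set
#'
#' TRUE iff the smallest eigenvalue of the centered covariance
#' sum (x - xbar)(x - xbar)^T / n exceeds (tolerance_fraction * h)^2, i.e.
#' the points genuinely span 3D at the scale of the grid spacing, so the
#' MLS moment matrix is invertible.
#'
#' @param points k x 3 matrix (k >= 4).
#' @param tolerance_fraction spread threshold as a fraction of h (default 0.05).
#' @param h reference length scale (grid spacing).
#' @return Logical scalar.
#' @export
coplanarityCheck <- function(points, tolerance_fraction = 0.05, h = 1) {
    points <- as.matrix(points)
    if (nrow(points) < 4) {
        stop(softcutError(
            sprintf("coplanarity check needs >= 4 points, got %d", nrow(points)),
            "softcutInsufficientPointsError"
        ))
    }
    ctr <- sweep(points, 2, colMeans(points))
    C <- crossprod(ctr) / nrow(points)
    ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
    min(ev) > (tolerance_fraction * h)^2
}

#' Evaluate MLS shape functions and gradients at a point
#'
#' Shape functions phi_i(x) = p(x)^T A(x)^{-1} w_i(x) p(x_i) with moment
#' matrix A(x) = sum_j w_j(x) p(x_j) p(x_j)^T; gradients by the standard
#' total-derivative formula, differentiating both A and the weights.  The
#' result satisfies partition of unity, zero gradient sum, and exact linear
#' reproduction whenever A is well conditioned.
#'
#' @param eval_point length-3 evaluation point.
#' @param neighbor_positions k x 3 matrix (k >= 4, non-coplanar).
#' @param support_radii per-neighbor support radius; every neighbor must lie
#'   strictly inside its support (weight > 0).
#' @param cond_tol condition-number threshold for the 4 x 4 moment matrix;
#'   beyond it a rank-deficiency error is raised rather than silently
#'   regularizing.
#' @param label identifier used in error messages (e.g. element index).
#' @return List with `values` (length k) and `gradients` (k x 3).
#' @export
mlsEvaluate <- function(eval_point, neighbor_positions, support_radii,
                        cond_tol = 1e12, label = "evaluation point") {
    X <- as.matrix(neighbor_positions)
    k <- nrow(X)
    stopifnot(k >= 4, length(support_radii) == k)
    x <- as.numeric(eval_point)
    diff <- sweep(X, 2, x)           # X_i - x
    d <- sqrt(rowSums(diff^2))
    q <- d / support_radii
    if (any(q >= 1)) {
        stop(softcutError(
            sprintf("%s: %d neighbor(s) at or beyond their support radius",
                    paste(label, collapse = ","), sum(q >= 1)),
            "softcutSupportError"
        ))
    }
    w <- splineWeight(q)
    P <- cbind(1, X)                 # k x 4 basis at the neighbors
    A <- crossprod(P, w * P)
    sv <- svd(A, nu = 0, nv = 0)$d
    kap <- if (min(sv) > 0) max(sv) / min(sv) else Inf
    if (!is.finite(kap) || kap > cond_tol) {
        rankDeficiencyError(paste(label, collapse = ","), kap)
    }
    px <- c(1, x)
    gamma <- solve(A, px)
    Pg <- drop(P %*% gamma)
    phi <- w * Pg
    # dq/dx_k = -(X_ik - x_k) / (r_i d_i); zero where d = 0 (dw/dq(0) = 0)
    dwdq <- splineWeightDeriv(q)
    inv_rd <- ifelse(d > 0, 1 / (support_radii * d), 0)
    grads <- matrix(0, k, 3)
    for (a in 1:3) {
        dw_a <- dwdq * (-diff[, a]) * inv_rd
        dA_a <- crossprod(P, dw_a * P)
        e_a <- c(0, 0, 0, 0); e_a[a + 1] <- 1
        dgamma <- solve(A, e_a - dA_a %*% gamma)
        grads[, a] <- dw_a * Pg + w * drop(P %*% dgamma)
    }
    list(values = phi, gradients = grads)
}

# Effective per-pair radii: a neighbor legitimately selected beyond its
# nominal support (boundary elements, post-cut replacements) gets its radius
# expanded so the weight stays positive; MLS consistency is unaffected.
effectiveRadii <- function(eval_point, X, radii) {
    d <- sqrt(rowSums(sweep(as.matrix(X), 2, as.numeric(eval_point))^2))
    pmax(radii, d / 0.95)
}

#' Shape row for one neighbor set (with support-radius expansion)
#'
#' Internal-friendly wrapper around [mlsEvaluate()] used wherever shape rows
#' are (re)built: applies the per-pair effective support radius before
#' evaluating.
#'
#' @inheritParams mlsEvaluate
#' @param radii nominal per-neighbor support radii.
#' @return As [mlsEvaluate()].
#' @export
shapeRow <- function(eval_point, neighbor_positions, radii,
                     cond_tol = 1e12, label = "evaluation point") {
    r_eff <- effectiveRadii(eval_point, neighbor_positions, radii)
    mlsEvaluate(eval_point, neighbor_positions, r_eff,
                cond_tol = cond_tol, label = label)
}

#' Recompute the shape rows of a single element
#'
#' Re-evaluates the MLS values and gradients of `element_index` from its
#' current connectivity row and writes exactly that row of the shape-value
#' and shape-gradient tables (marking their batches dirty).  On a
#' rank-deficiency error nothing is written.
#'
#' @param scene a `CutScene` (see [buildScene()]).
#' @param element_index which element to refresh.
#' @return Invisibly, the list from [shapeRow()].
#' @export
recomputeElementShapes <- function(scene, element_index) {
    nbr <- as.integer(readRow(scene$tables$conn, element_index))
    if (length(nbr) < 4) {
        stop(softcutError(
            sprintf("element %d has %d neighbors (< 4)", element_index, length(nbr)),
            "softcutInsufficientPointsError"
        ))
    }
    center <- scene$model$elems[element_index, ]
    sh <- shapeRow(center, scene$model$nodes[nbr, , drop = FALSE],
                   scene$support_radii[nbr],
                   cond_tol = scene$params$cond_tol,
                   label = sprintf("element %d", element_index))
    writeRow(scene$tables$values, element_index, sh$values)
    writeRow(scene$tables$grads, element_index, sh$gradients)
    invisible(sh)
}
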