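# Implicit dynamic elasticity: lumped mass, element-loop stiffness operator
# (compiled kernel), unpreconditioned matrix-free conjugate gradient, and
# the backward-Euler velocity update
#   (M - dt^2 K) dv = dt (f_elastic + f_ext),   v <- v0 + dv,
#   u <- u0 + dt v.
# K is never assembled; it exists only as the apply-operator.  M is the
# per-node lumped mass vector.

#' Material parameters for linear elasticity
#'
#' Derives the Lame constants lambda = E nu / ((1 + nu)(1 - 2 nu)) and
#' mu = E / (2 (1 + nu)).  Defaults are soft-tissue-like: E = 10 kPa,
#' nu = 0.45, rho = 1000 kg/m^3.
#'
#' @param E Young's modulus (Pa).
#' @param nu Poisson ratio in \[0, 0.5).
#' @param rho mass density (kg/m^3).
#' @return Object of class `MaterialParams`.
#' @export
materialParams <- function(E = 1e4, nu = 0.45, rho = 1000) {
    if (!(E > 0 && nu >= 0 && nu < 0.5 && rho > 0)) {
        stop(softcutError(
            "need E > 0, 0 <= nu < 0.5, rho > 0",
            "softcutArgumentError"
        ))
    }
    structure(
        list(
            E = E, nu = nu, rho = rho,
            lambda = E * nu / ((1 + nu) * (1 - 2 * nu)),
            mu = E / (2 * (1 + nu))
        ),
        class = "MaterialParams"
    )
}

#' Simulation state
#'
#' Nodal displacements and velocities plus the Dirichlet mask.  Fixed nodes
#' keep u = v = 0 at all times.
#'
#' @param n_nodes number of nodes.
#' @param fixed logical mask of Dirichlet-fixed nodes (default none).
#' @return Object of class `SimState`.
#' @export
newSimState <- function(n_nodes, fixed = logical(n_nodes)) {
    stopifnot(length(fixed) == n_nodes)
    structure(
        list(
            u = matrix(0, n_nodes, 3),
            v = matrix(0, n_nodes, 3),
            fixed = fixed
        ),
        class = "SimState"
    )
}

# active (element, slot) masks and pair extraction ---------------------------

#' Element-node pair view of the connectivity and shape tables
#'
#' Flattens the occupied slots of the connectivity table into parallel
#' vectors (element index, node index, shape value, gradient components),
#' used for vectorized mass assembly, link enumeration and oracles.
#'
#' @param tables the scene table list (conn / values / grads).
#' @return List with `elem`, `node`, `phi`, `gx`, `gy`, `gz`.
#' @export
connectivityPairs <- function(tables) {
    conn <- tables$conn
    W <- conn$max_row_width
    keep <- outer(conn$row_lengths, seq_len(W), ">=")
    gp <- tables$grads$payload
    list(
        elem = row(keep)[keep],
        node = as.integer(conn$payload[keep]),
        phi = tables$values$payload[keep],
        gx = gp[, seq(1, 3 * W, by = 3), drop = FALSE][keep],
        gy = gp[, seq(2, 3 * W, by = 3), drop = FALSE][keep],
        gz = gp[, seq(3, 3 * W, by = 3), drop = FALSE][keep]
    )
}

#' Lumped mass vector
#'
#' Each element distributes its mass rho V_I over its neighbor nodes in
#' proportion to the shape values phi_i^I.  MLS values can be (mildly)
#' negative, and a negative lumped mass would break the definiteness of
#' the implicit system, so negative values are clipped to zero and the
#' remainder renormalized per element; with all-positive values this is
#' exactly m_i = sum_I rho V_I phi_i^I, and in every case the element
#' distributes exactly rho V_I, so total mass equals rho * sum(V) to
#' roundoff.  Isolated nodes (no incident element, e.g. fully disconnected
#' by cutting) receive a floor mass of 1e-12 times the mean mass to keep
#' the system matrix definite.
#'
#' @param model a `VolumeModel`.
#' @param tables scene tables (conn / values).
#' @param material a [materialParams()] object.
#' @return Numeric vector of nodal masses (all > 0).
#' @export
lumpedMass <- function(model, tables, material) {
    pr <- connectivityPairs(tables)
    m <- numeric(nrow(model$nodes))
    w <- pmax(pr$phi, 0)
    se <- rowsum(w, pr$elem)
    scale <- numeric(nrow(model$elems))
    scale[as.integer(rownames(se))] <- se
    contrib <- material$rho * model$vol[pr$elem] * w / scale[pr$elem]
    s <- rowsum(contrib, pr$node)
    m[as.integer(rownames(s))] <- s
    floor_m <- 1e-12 * mean(m[m > 0])
    m[m <= 0] <- floor_m
    m
}

#' Matrix-free stiffness product K p
#'
#' Element loop: strain from the stored shape gradients, linear-elastic
#' stress, force density distributed back to the element's nodes.  Returns
#' K p with K symmetric negative semi-definite; components of fixed nodes
#' are projected out (input and output) to preserve symmetry on the free
#' subspace.
#'
#' @param p n_nodes x 3 matrix.
#' @param model a `VolumeModel`.
#' @param tables scene tables (conn / grads).
#' @param material a [materialParams()] object.
#' @param fixed integer vector of fixed node indices (or logical mask).
#' @return n_nodes x 3 matrix K p.
#' @export
applyStiffness <- function(p, model, tables, material, fixed = integer(0)) {
    ctx <- stiffnessContext(model, tables, material, fixed)
    ctx$apply(p)
}

#' Reusable stiffness-operator context
#'
#' Extracts the table payloads once (integer connectivity, gradient matrix)
#' so the per-iteration operator application does no conversion work; used
#' by the CG loop, which applies the operator many times per frame.
#'
#' @inheritParams applyStiffness
#' @return List with `apply` (function(p) -> K p) and the extracted arrays.
#' @export
stiffnessContext <- function(model, tables, material, fixed = integer(0)) {
    if (is.logical(fixed)) fixed <- which(fixed)
    conn <- tables$conn$payload
    storage.mode(conn) <- "integer"
    len <- tables$conn$row_lengths
    if (!identical(dim(tables$grads$payload),
                   c(nrow(conn), 3L * tables$conn$max_row_width)) ||
        tables$grads$n_rows != tables$conn$n_rows) {
        stop(softcutError("shape-gradient table is not row-aligned with the connectivity table",
                          "softcutConsistencyError"))
    }
    grads <- tables$grads$payload
    vol <- model$vol
    lambda <- material$lambda
    mu <- material$mu
    fixed <- as.integer(fixed)
    list(
        apply = function(p) {
            cpp_apply_stiffness(conn, len, grads, vol, lambda, mu, p, fixed)
        },
        conn = conn, len = len, grads = grads, vol = vol, fixed = fixed
    )
}

#' Unpreconditioned conjugate gradient
#'
#' Matrix-free CG for a symmetric positive-definite operator on the free
#' subspace.  Stops when |r|^2 <= tol^2 |b|^2 or at `max_iter` (flagged, not
#' an error).  Each iteration reduces to exactly two scalars, r'r and
#' p'Ap — the quantities a device implementation would ship back per
#' iteration to decide whether to continue.
#'
#' @param apply_A function mapping a vector/matrix to A times it.
#' @param b right-hand side (vector or matrix; solution has the same shape).
#' @param tol relative residual tolerance.
#' @param max_iter iteration cap.
#' @return List with `x`, `iterations`, `converged`, `residual` (relative).
#' @export
cgSolve <- function(apply_A, b, tol = 1e-6, max_iter = 10 * NROW(b)) {
    x <- b * 0
    bb <- sum(b * b)
    if (bb == 0) {
        return(list(x = x, iterations = 0L, converged = TRUE, residual = 0))
    }
    r <- b
    p <- r
    rr <- bb
    it <- 0L
    while (it < max_iter) {
        Ap <- apply_A(p)
        pAp <- sum(p * Ap)
        if (!is.finite(pAp) || pAp <= 0) {
            stop(softcutError(
                sprintf("CG divergence: p'Ap = %g at iteration %d", pAp, it),
                "softcutDivergenceError"
            ))
        }
        alpha <- rr / pAp
        x <- x + alpha * p
        r <- r - alpha * Ap
        rr_new <- sum(r * r)
        it <- it + 1L
        if (!is.finite(rr_new)) {
            stop(softcutError("CG divergence: non-finite residual",
                              "softcutDivergenceError"))
        }
        if (rr_new <= tol^2 * bb) {
            return(list(x = x, iterations = it, converged = TRUE,
                        residual = sqrt(rr_new / bb)))
        }
        p <- r + (rr_new / rr) * p
        rr <- rr_new
    }
    list(x = x, iterations = it, converged = FALSE,
         residual = sqrt(rr / bb))
}

#' One backward-Euler step (core form)
#'
#' Solves (M - dt^2 K) dv = dt (K u0 + f_ext) by matrix-free CG, then
#' v = v0 + dv and u = u0 + dt v.  Fixed nodes are untouched (and must
#' enter with u = v = 0).  `apply_K` is any symmetric negative
#' semi-definite operator, which keeps the step testable against
#' closed-form scalar systems.
#'
#' @param u0,v0 n x 3 matrices (or vectors) at the beginning of the step.
#' @param mass per-node lumped mass.
#' @param apply_K function p -> K p.
#' @param f_ext external nodal forces, same shape as u0.
#' @param dt time-step length.
#' @param fixed integer indices of fixed nodes (rows).
#' @param tol,max_iter CG controls.
#' @param precision `"double"` (default) or `"single"` (state rounded
#'   through IEEE single precision after the update).
#' @return List with `u`, `v`, `cg` (the [cgSolve()] result sans `x`).
#' @export
stepCore <- function(u0, v0, mass, apply_K, f_ext, dt,
                     fixed = integer(0), tol = 1e-6,
                     max_iter = 10 * NROW(u0), precision = "double") {
    if (is.logical(fixed)) fixed <- which(fixed)
    f0 <- apply_K(u0) + f_ext
    if (length(fixed)) {
        f0 <- zeroRows(f0, fixed)
    }
    apply_A <- function(x) mass * x - dt^2 * apply_K(x)
    sol <- cgSolve(apply_A, dt * f0, tol = tol, max_iter = max_iter)
    v <- v0 + sol$x
    u <- u0 + dt * v
    if (length(fixed)) {
        u <- zeroRows(u, fixed)
        v <- zeroRows(v, fixed)
    }
    if (identical(precision, "single")) {
        u <- roundState(u)
        v <- roundState(v)
    }
    list(u = u, v = v,
         cg = sol[c("iterations", "converged", "residual")])
}

zeroRows <- function(x, rows) {
    if (is.matrix(x)) x[rows, ] <- 0 else x[rows] <- 0
    x
}

roundState <- function(x) {
    d <- dim(x)
    x <- cpp_round_to_float(as.numeric(x))
    dim(x) <- d
    x
}

#' One backward-Euler step on a scene
#'
#' Scene-level wrapper around [stepCore()] using the current tables as the
#' stiffness operator and the scene's lumped mass.
#'
#' @param scene a `CutScene` from [buildScene()].
#' @param state a `SimState`.
#' @param f_ext external nodal forces (n x 3); default gravity from the
#'   scene parameters applied through the lumped mass.
#' @param dt time step (default from scene parameters).
#' @param tol,max_iter,precision see [stepCore()].
#' @return List with updated `state` and `cg` diagnostics.
#' @export
stepDynamics <- function(scene, state, f_ext = NULL, dt = scene$params$dt,
                         tol = scene$params$cg_tol,
                         max_iter = scene$params$cg_max_iter,
                         precision = scene$params$precision) {
    if (is.null(f_ext)) {
        f_ext <- outer(scene$mass, scene$params$gravity)
    }
    ctx <- stiffnessContext(scene$model, scene$tables, scene$material,
                            scene$fixed)
    if (is.null(max_iter)) max_iter <- 10L * nrow(state$u)
    res <- stepCore(state$u, state$v, scene$mass, ctx$apply, f_ext, dt,
                    fixed = which(scene$fixed), tol = tol,
                    max_iter = max_iter, precision = precision)
    state$u <- res$u
    state$v <- res$v
    list(state = state, cg = res$cg)
}

#' Elastic and kinetic energy of a state
#'
#' Elastic energy 1/2 u' (-K) u via the matrix-free operator; kinetic
#' energy 1/2 v' M v with the lumped mass.  Backward Euler with no external
#' forcing never increases their sum.
#'
#' @param u,v n x 3 state matrices.
#' @param mass lumped mass vector.
#' @param apply_K the stiffness operator.
#' @return List with `elastic`, `kinetic`, `total`.
#' @export
stateEnergy <- function(u, v, mass, apply_K) {
    el <- -0.5 * sum(u * apply_K(u))
    ki <- 0.5 * sum(mass * rowSums(v^2))
    list(elastic = el, kinetic = ki, total = el + ki)
}
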