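# Scene assembly and the main simulation loop.  A CutScene bundles the
# volume model, surface mesh, the four fixed-width tables (connectivity,
# shape values, shape gradients, surface weights), material, Dirichlet
# mask, lumped mass, the accumulated cut surface and the transfer ledger.
# Scenes are environments: cutting mutates tables in place.

#' Build a complete cutting scene from a run configuration
#'
#' Generates the torus volume and surface, selects the initial element
#' neighbor sets, evaluates all shape rows, builds the surface mapping,
#' fixes the nodes with x < -(R - r/2) (the hanging-torus demo anchor) and
#' computes the lumped mass.  The four tables are flushed once at the end
#' (the initial full upload) without ledger recording, so the ledger only
#' sees per-frame update traffic.
#'
#' @param config a [defaultRunConfig()]-shaped list.
#' @return An environment of class `CutScene`.
#' @export
buildScene <- function(config = defaultRunConfig()) {
    config <- validateConfig(config)
    sc <- new.env(parent = emptyenv())
    class(sc) <- "CutScene"
    sc$params <- config
    sc$model <- generateTorusVolume(config$R, config$r, config$h)
    sc$surface <- generateTorusSurface(config$R, config$r,
                                       config$n_u, config$n_v)
    sc$material <- materialParams(config$E, config$nu, config$rho)
    n_elems <- nrow(sc$model$elems)
    n_nodes <- nrow(sc$model$nodes)
    n_verts <- nrow(sc$surface$vertices)
    W <- config$max_row_width
    bs <- function(n) min(config$batch_size, n)
    sc$tables <- list(
        conn = createTable(n_elems, W, 4L, bs(n_elems), "connectivity"),
        values = createTable(n_elems, W, 8L, bs(n_elems), "shape_values"),
        grads = createTable(n_elems, W, 24L, bs(n_elems), "shape_gradients",
                            slot_cols = 3L),
        surf = createTable(n_verts, W, 12L, bs(n_verts), "surface_weights",
                           slot_cols = 2L)
    )
    nbrs <- buildInitialConnectivity(sc$model, config$k_min, W,
                                     config$coplanar_tol)
    for (e in seq_len(n_elems)) writeRow(sc$tables$conn, e, nbrs[[e]])
    sc$support_radii <- nodeSupportRadii(sc$model, config$k_min)
    for (e in seq_len(n_elems)) recomputeElementShapes(sc, e)
    buildSurfaceMapping(sc)
    sc$fixed <- sc$model$nodes[, 1] < -(config$R - config$r / 2)
    sc$mass <- lumpedMass(sc$model, sc$tables, sc$material)
    sc$cut_surface <- newCutSurface()
    sc$ledger <- newLedger()
    # initial upload: everything dirty, not part of per-update traffic
    for (t in sc$tables) flushTable(t)
    sc
}

#' @export
print.CutScene <- function(x, ...) {
    cat(sprintf(
        "CutScene: %d nodes, %d elements, %d surface vertices (%d fixed nodes)\n",
        nrow(x$model$nodes), nrow(x$model$elems),
        nrow(x$surface$vertices), sum(x$fixed)
    ))
    invisible(x)
}

# tool polyline at a global frame, or NULL outside the cutting window
toolAtFrame <- function(traj, frame, start_frame) {
    k <- frame - start_frame + 1L
    if (k < 1L || k > length(traj$frames)) return(NULL)
    traj$frames[[k]]
}

#' Run simulation frames
#'
#' The per-frame loop, in order: cut detection (sweep the tool from its
#' previous position and collect severed links), cut application (row
#' edits, neighbor re-selection, shape/mapping refresh), one table flush
#' per table recording the transfer ledger, deformation (backward-Euler
#' step under gravity), surface position update.
#'
#' @param scene a `CutScene`.
#' @param state a `SimState` (default: rest, with the scene's fixed mask).
#' @param n_frames how many frames to run.
#' @param traj optional `ToolTrajectory`; default from the scene config.
#' @param start_frame global frame at which the trajectory begins.
#' @param frame_hook optional `function(scene, state, frame, info)` called
#'   at the end of every frame (testing/diagnostics).
#' @param collect_obj if TRUE, keep each frame's surface positions.
#' @return List with `state`, `frame_log`, `cut_events`, `ledger`,
#'   `surface_positions` (final), `obj_frames` (if collected).
#' @export
runFrames <- function(scene, state = NULL, n_frames = scene$params$n_frames,
                      traj = NULL, start_frame = scene$params$cut_start,
                      frame_hook = NULL, collect_obj = FALSE) {
    p <- scene$params
    if (is.null(state)) {
        state <- newSimState(nrow(scene$model$nodes), scene$fixed)
    }
    if (is.null(traj) && p$cut_frames >= 2) {
        traj <- defaultCutTrajectory(p$R, p$r, p$cut_frames,
                                     plane_offset = p$cut_plane_offset)
    }
    frame_log <- vector("list", n_frames)
    cut_events <- vector("list", n_frames)
    obj_frames <- if (collect_obj) vector("list", n_frames) else NULL
    prev_tool <- NULL
    surf_pos <- scene$surface$vertices
    for (frame in seq_len(n_frames)) {
        tool <- if (is.null(traj)) NULL else
            toolAtFrame(traj, frame, start_frame)
        n_sev_vol <- 0L; n_sev_surf <- 0L; n_mod <- 0L
        if (!is.null(tool) && !is.null(prev_tool)) {
            tris <- sweepTool(prev_tool, tool,
                              min_area = 1e-12 * scene$model$h^2)
            if (nrow(tris) > 0) {
                addCutTriangles(scene$cut_surface, tris, frame)
                severed <- detectCutLinks(scene, tris)
                n_sev_vol <- nrow(severed$volume)
                n_sev_surf <- nrow(severed$surface)
                if (n_sev_vol + n_sev_surf > 0) {
                    mods <- applyCut(scene, severed, frame)
                    n_mod <- length(mods$modified_elements)
                }
            }
        }
        prev_tool <- tool
        for (t in scene$tables) {
            flushTable(t, scene$ledger, frame, batching = p$batching)
        }
        sd <- stepDynamics(scene, state)
        state <- sd$state
        surf_pos <- updateSurfacePositions(scene, state)
        frame_log[[frame]] <- data.frame(
            frame = frame,
            cg_iterations = sd$cg$iterations,
            cg_converged = sd$cg$converged,
            residual = sd$cg$residual,
            max_displacement = max(sqrt(rowSums(state$u^2)))
        )
        cut_events[[frame]] <- data.frame(
            frame = frame,
            n_severed_volume_links = n_sev_vol,
            n_severed_surface_links = n_sev_surf,
            n_modified_elements = n_mod,
            n_overflow_warnings = 0L
        )
        if (collect_obj) obj_frames[[frame]] <- surf_pos
        if (!is.null(frame_hook)) {
            frame_hook(scene, state, frame,
                       list(cg = sd$cg, n_severed_volume = n_sev_vol,
                            n_severed_surface = n_sev_surf))
        }
    }
    emptyDf <- function(x) if (is.null(x)) data.frame() else x
    list(
        state = state,
        frame_log = emptyDf(do.call(rbind, frame_log)),
        cut_events = emptyDf(do.call(rbind, cut_events)),
        ledger = scene$ledger,
        surface_positions = surf_pos,
        obj_frames = obj_frames
    )
}
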