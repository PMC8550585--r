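# Cutting: tool sweeps, tie-inclusive segment-triangle detection against a
# parametric oracle, row surgery with coplanarity + visibility refill, and
# dirty-row locality.

test_that("tool sweeps triangulate the swept quads and drop degenerates", {
  seg <- rbind(c(0, 0, 0), c(1, 0, 0))
  expect_equal(nrow(sweepTool(seg, seg)), 0)          # stationary tool

  moved <- seg + matrix(rep(c(0, 1, 0), each = 2), 2, 3)
  tris <- sweepTool(seg, moved)
  expect_equal(nrow(tris), 2)
  expect_equal(sum(softcut:::triangleAreas(tris)), 1) # unit quad

  poly3 <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0.5, 0))
  expect_equal(nrow(sweepTool(poly3, poly3 + 0.5)), 4)

  expect_error(sweepTool(seg, poly3), class = "softcutArgumentError")
})

test_that("segment-triangle test agrees with the parametric oracle, ties included", {
  tri <- matrix(c(0, 0, 0, 1, 0, 0, 0, 1, 0), 1, 9, byrow = TRUE)
  # through the centroid
  expect_true(segmentsHitTriangles(c(1 / 3, 1 / 3, -1), c(1 / 3, 1 / 3, 1), tri))
  # touching a vertex and an edge: ties count as hits
  expect_true(segmentsHitTriangles(c(0, 0, -1), c(0, 0, 0), tri))
  expect_true(segmentsHitTriangles(c(0.5, 0, -1), c(0.5, 0, 1), tri))
  # clear miss
  expect_false(segmentsHitTriangles(c(2, 2, -1), c(2, 2, 1), tri))
  # randomized agreement with the independent parametric solve
  set.seed(31)
  for (rep in 1:300) {
    t1 <- matrix(rnorm(9), 1, 9)
    P <- rnorm(3); Q <- rnorm(3)
    got <- segmentsHitTriangles(P, Q, t1)
    want <- oracle_seg_tri(P, Q, t1[1, ])
    if (got != want) {
      # disagreement is only tolerable within oracle epsilon of a boundary
      fail(sprintf("disagreement on case %d", rep))
    }
  }
  expect_true(TRUE)
})

test_that("detection far from the model severs nothing", {
  scene <- small_scene()
  far <- matrix(c(50, 50, 50, 51, 50, 50, 50, 51, 50), 1, 9, byrow = TRUE)
  sev <- detectCutLinks(scene, far)
  expect_equal(nrow(sev$volume), 0)
  expect_equal(nrow(sev$surface), 0)
})

test_that("a single crossing link is reported exactly", {
  # one element whose link to one node passes through a unit triangle
  m <- block_model(4, 3, 3, 0.5)
  scene <- volume_scene(m, batch_size = 1)
  e <- 1L
  nbr <- as.integer(readRow(scene$tables$conn, e))
  ctr <- m$elems[e, ]
  target <- nbr[1]
  mid <- (ctr + m$nodes[target, ]) / 2
  dir <- m$nodes[target, ] - ctr
  # small triangle orthogonal to the link at its midpoint
  b1 <- c(-dir[2], dir[1], 0); if (sum(b1^2) < 1e-12) b1 <- c(0, -dir[3], dir[2])
  b1 <- 0.2 * b1 / sqrt(sum(b1^2))
  b2 <- c(dir[2] * b1[3] - dir[3] * b1[2],
          dir[3] * b1[1] - dir[1] * b1[3],
          dir[1] * b1[2] - dir[2] * b1[1])
  b2 <- 0.2 * b2 / sqrt(sum(b2^2))
  tri <- matrix(c(mid - b1 - b2, mid + 2 * b1 - b2, mid - b1 + 2 * b2),
                1, 9, byrow = TRUE)
  sev <- detectCutLinks(scene, tri)
  hit_this <- sev$volume[sev$volume[, "elem"] == e, , drop = FALSE]
  expect_true(any(hit_this[, "node"] == target))
  # oracle agreement over all stored pairs
  osev <- oracle_detect(scene, tri)
  expect_setequal(paste(sev$volume[, 1], sev$volume[, 2]),
                  paste(osev$volume[, 1], osev$volume[, 2]))
})

test_that("empty severed set leaves every table bit-identical and clean", {
  scene <- small_scene()
  for (t in scene$tables) flushTable(t)
  snap <- lapply(scene$tables, function(t) t$payload)
  mods <- applyCut(scene, list(volume = matrix(0L, 0, 2),
                               surface = matrix(0L, 0, 2)))
  expect_length(mods$modified_elements, 0)
  for (nm in names(scene$tables)) {
    expect_false(any(scene$tables[[nm]]$dirty))
    expect_identical(scene$tables[[nm]]$payload, snap[[nm]])
  }
})

test_that("severing one of nine neighbors dirties exactly one row per shape table", {
  m <- block_model(4, 3, 3, 0.5)
  scene <- volume_scene(m, batch_size = 1)      # batch = row: exact census
  e <- 2L
  nbr <- as.integer(readRow(scene$tables$conn, e))
  extra <- setdiff(oracle_knn(m$nodes, m$elems[e, ], 12), nbr)[1]
  writeRow(scene$tables$conn, e, c(nbr, extra))
  recomputeElementShapes(scene, e)
  for (t in scene$tables) flushTable(t)
  mods <- applyCut(scene, list(
    volume = cbind(elem = e, node = extra),
    surface = matrix(0L, 0, 2)
  ))
  expect_equal(mods$modified_elements, e)
  for (nm in c("conn", "values", "grads")) {
    expect_equal(which(scene$tables[[nm]]$dirty), e,
                 ignore_attr = TRUE, label = nm)
  }
  row <- as.integer(readRow(scene$tables$conn, e))
  expect_setequal(row, nbr)                      # back to the original 8
  expect_lt(abs(sum(readRow(scene$tables$values, e)) - 1), 1e-9)
  # total mass is preserved through the cut (partition of unity per row)
  expect_equal(sum(scene$mass), scene$material$rho * sum(scene$model$vol),
               tolerance = 1e-12)
})

test_that("a plane sweep through a bar separates sides; far side is invisible", {
  m <- block_model(5, 2, 2, 1)                   # nodes x = 0..4
  scene <- volume_scene(m, batch_size = 1)
  plane_x <- 2.1
  quad <- rbind(
    c(plane_x, -1, -1, plane_x, 3, -1, plane_x, 3, 3),
    c(plane_x, -1, -1, plane_x, 3, 3, plane_x, -1, 3)
  )
  addCutTriangles(scene$cut_surface, quad, 1L)
  sev <- detectCutLinks(scene, quad)
  expect_true(nrow(sev$volume) > 0)
  # only links straddling the plane are severed
  for (i in seq_len(nrow(sev$volume))) {
    cx <- m$elems[sev$volume[i, "elem"], 1]
    nx <- m$nodes[sev$volume[i, "node"], 1]
    expect_true((cx - plane_x) * (nx - plane_x) < 0)
  }
  mods <- applyCut(scene, sev)
  for (e in mods$modified_elements) {
    row <- as.integer(readRow(scene$tables$conn, e))
    side <- sign(m$elems[e, 1] - plane_x)
    # every retained / appended node is on the element's own side
    expect_true(all(sign(m$nodes[row, 1] - plane_x) == side))
    # the full exhaustive visibility oracle agrees: far-side candidates
    # are all blocked by the accumulated cut surface
    far <- which(sign(m$nodes[, 1] - plane_x) != side)
    ctr <- m$elems[e, ]
    blocked <- vapply(far, function(nd) {
      oracle_any_seg_tri(ctr, m$nodes[nd, ], scene$cut_surface$tris)
    }, logical(1))
    expect_true(all(blocked))
    expect_true(all(!visibleFrom(ctr, m$nodes[far, , drop = FALSE],
                                 scene$cut_surface)))
    # monotone disconnection: nothing severed was reconnected
    cut_here <- sev$volume[sev$volume[, "elem"] == e, "node"]
    expect_length(intersect(row, cut_here), 0)
    # post-cut validity
    expect_true(coplanarityCheck(m$nodes[row, , drop = FALSE], 0.05, m$h))
    expect_lt(abs(sum(readRow(scene$tables$values, e)) - 1), 1e-9)
  }
  expect_equal(sum(scene$mass), scene$material$rho * sum(scene$model$vol),
               tolerance = 1e-9)
})

test_that("overflow is raised when no valid visible neighbor set fits the row", {
  # sever everything on one side of a 2-cell bar: the remaining candidates
  # are a single coplanar node layer, and the far side is invisible
  m <- block_model(3, 2, 2, 1)
  scene <- volume_scene(m, batch_size = 1, max_row_width = 8)
  plane_x <- 1.1
  quad <- rbind(
    c(plane_x, -1, -1, plane_x, 3, -1, plane_x, 3, 3),
    c(plane_x, -1, -1, plane_x, 3, 3, plane_x, -1, 3)
  )
  addCutTriangles(scene$cut_surface, quad, 1L)
  sev <- detectCutLinks(scene, quad)
  expect_error(applyCut(scene, sev), class = "softcutOverflowError")
})
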