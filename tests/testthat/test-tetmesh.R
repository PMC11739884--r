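tet_volumes <- seg2fem:::tet_volumes

test_that("volume filling conserves the enclosed volume and the vertices", {
  m <- ball_mesh(8, 1)
  tm <- memo("ball8_filled", fill_volume(m, 1.0))
  expect_equal(tet_mesh_volume(tm), mesh_volume(m),
               tolerance = 0.005)
  expect_true(all(tet_volumes(tm$nodes, tm$elements) > 0))
  # every original surface vertex appears among the nodes bit-identically
  expect_identical(tm$nodes[tm$surface_node_map, , drop = FALSE],
                   m$vertices)
  # no duplicated nodes
  expect_false(any(duplicated(round(tm$nodes, 9))))
})

test_that("degenerate and self-intersecting surfaces are rejected cleanly", {
  expect_error(fill_volume(crossing_tets_mesh()),
               class = "seg2fem_meshing_error")
  m <- ball_mesh(6, 1)
  holed <- tri_mesh(m$vertices, m$faces[-1, , drop = FALSE])
  err <- tryCatch(fill_volume(holed), condition = function(e) e)
  expect_s3_class(err, "seg2fem_meshing_error")
  expect_false(is.null(err$diagnostics))
})

test_that("halving the target edge at least doubles the element count", {
  box <- plate_mesh(10, 10, 1, z0 = 0)
  # closed 10 mm cube built from a voxel block
  g <- array(0L, dim = c(14, 14, 14))
  g[3:12, 3:12, 3:12] <- 1L
  cube <- extract_surface(label_volume(g, c(1, 1, 1)), 1L)
  n_coarse <- nrow(fill_volume(cube, 2.0)$elements)
  n_fine <- nrow(fill_volume(cube, 1.0)$elements)
  expect_gte(n_fine, 2 * n_coarse)
})

test_that("quadratic conversion adds exactly one midpoint per unique edge", {
  one <- tet_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
                  matrix(1:4, 1), "linear")
  q1 <- to_quadratic(one)
  expect_equal(nrow(q1$nodes), 10)
  expect_identical(q1$nodes[1:4, ], one$nodes)
  # midpoints 5-10 are exact edge midpoints in the conventional order
  ep <- list(c(1, 2), c(2, 3), c(3, 1), c(1, 4), c(2, 4), c(3, 4))
  for (e in seq_along(ep))
    expect_equal(q1$nodes[q1$elements[1, 4 + e], ],
                 colMeans(one$nodes[ep[[e]], ]), tolerance = 1e-15)

  # two tets sharing a face: brute-force unique-edge enumeration
  nodes <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1), c(1, 1, 1))
  two <- tet_mesh(nodes, rbind(c(1, 2, 3, 4), c(2, 3, 4, 5)), "linear")
  edges <- unique(t(apply(rbind(
    t(utils::combn(c(1, 2, 3, 4), 2)), t(utils::combn(c(2, 3, 4, 5), 2))),
    1, sort)))
  q2 <- to_quadratic(two)
  expect_equal(nrow(q2$nodes), nrow(nodes) + nrow(edges))
  expect_error(to_quadratic(q2), class = "seg2fem_spec_error")
})

test_that("aspect ratio is the max/min edge-length quotient", {
  reg <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
  expect_equal(aspect_ratio(reg), 1.0, tolerance = 1e-12)
  tall <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 5))
  expect_equal(aspect_ratio(tall), sqrt(26), tolerance = 1e-12)
  expect_equal(aspect_ratio(tall * 3.7), aspect_ratio(tall), tolerance = 1e-12)
  degen <- rbind(c(0, 0, 0), c(0, 0, 0), c(0, 1, 0), c(0, 0, 1))
  expect_error(aspect_ratio(degen), class = "seg2fem_degenerate_error")
})

test_that("poor-quality percentage counts elements above the threshold", {
  # 9 regular tets + 1 stretched tet (ratio 6) = 10% poor
  reg <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
  nodes <- NULL
  elems <- NULL
  for (i in 1:9) {
    nodes <- rbind(nodes, sweep(reg, 2, c(10 * i, 0, 0), "+"))
    elems <- rbind(elems, (i - 1) * 4 + 1:4)
  }
  stretched <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0),
                     c(0, 0, sqrt(36 - 1))) # max edge sqrt(36)=6, min 1
  nodes <- rbind(nodes, sweep(stretched, 2, c(100, 0, 0), "+"))
  elems <- rbind(elems, 36 + 1:4)
  tm <- tet_mesh(nodes, elems, "linear")
  expect_equal(poor_quality_fraction(tm, threshold = 5), 10.0)
  expect_equal(poor_quality_fraction(tm, threshold = 10), 0.0)
  reg_only <- tet_mesh(nodes[1:36, ], elems[1:9, , drop = FALSE], "linear")
  expect_equal(poor_quality_fraction(reg_only), 0.0)
})

test_that("structured tet block meshes the box exactly", {
  tm <- tet_block(c(2, 3, 4), 1)
  expect_equal(tet_mesh_volume(tm), 24, tolerance = 1e-12)
  expect_true(all(tet_volumes(tm$nodes, tm$elements) > 0))
})
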