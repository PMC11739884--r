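test_that("extracted ball surface is watertight with the analytic volume", {
  m <- ball_mesh(10, 1)
  d <- diagnose(m)
  expect_true(d$watertight)
  expect_true(d$manifold)
  expect_true(d$oriented)
  expect_false(d$self_intersecting)
  expect_equal(d$n_components, 1L)
  vol_mesh <- mesh_volume(m)
  expect_lt(abs(vol_mesh - 4 / 3 * pi * 10^3) / (4 / 3 * pi * 10^3), 0.05)
  # enclosed volume tracks voxel count x voxel volume, tighter as resolution
  # increases
  vox <- sum(ball_volume(10, 1)$grid)
  err1 <- abs(vol_mesh - vox) / vox
  expect_lt(err1, 0.02)
  m2 <- ball_mesh(10, 0.5)
  vox2 <- sum(ball_volume(10, 0.5)$grid) * 0.5^3
  err2 <- abs(mesh_volume(m2) - vox2) / vox2
  expect_lt(err2, err1)
})

test_that("absent labels raise an empty-body error", {
  expect_error(extract_surface(ball_volume(5), 7L),
               class = "seg2fem_empty_body_error")
})

test_that("anisotropic spacing produces stair-step z-plateaus", {
  vol <- generate_phantom(phantom_spec(n_levels = 1, jitter = 0, seed = 1,
                                       spacing_mm = c(1, 1, 3)))
  m <- extract_surface(vol, labels_present(vol)[1])
  zs <- sort(unique(m$vertices[, 3]))
  # all vertex z-values live on the half-slice lattice (multiples of 1.5 mm)
  expect_true(all(abs(zs / 1.5 - round(zs / 1.5)) < 1e-9))
  expect_lt(length(zs), 20)
})

test_that("diagnose counts boundary edges and finds self-intersections", {
  m <- ball_mesh(6, 1)
  holed <- tri_mesh(m$vertices, m$faces[-1, , drop = FALSE], m$body_id)
  d <- diagnose(holed)
  expect_false(d$watertight)
  expect_equal(d$n_boundary_edges, 3L)
  expect_true(diagnose(crossing_tets_mesh())$self_intersecting)
  expect_equal(diagnose(crossing_tets_mesh())$n_components, 2L)
})

test_that("repair closes holes and merges coincident vertices", {
  m <- ball_mesh(6, 1)
  # two coincident vertices: duplicate a vertex and point one face at the copy
  v2 <- rbind(m$vertices, m$vertices[m$faces[1, 1], ])
  f2 <- m$faces
  f2[1, 1] <- nrow(v2)
  dup <- tri_mesh(v2, f2)
  rep1 <- repair_mesh(dup)
  expect_equal(nrow(rep1$vertices), nrow(m$vertices))
  expect_true(diagnose(rep1)$watertight)

  # hole: drop one face, repair must re-close it without moving vertices
  holed <- tri_mesh(m$vertices, m$faces[-10, , drop = FALSE])
  rep2 <- repair_mesh(holed)
  d <- diagnose(rep2)
  expect_true(d$watertight)
  expect_equal(d$n_boundary_edges, 0L)
  expect_identical(rep2$vertices, m$vertices)

  # watertight input comes back unchanged up to vertex deduplication
  rep3 <- repair_mesh(m)
  expect_identical(rep3$vertices, m$vertices)
  expect_identical(rep3$faces, m$faces)
})

test_that("STL and PLY round trips preserve the geometry", {
  m <- ball_mesh(6, 1)
  stl <- tempfile(fileext = ".stl")
  ply <- tempfile(fileext = ".ply")
  on.exit(unlink(c(stl, ply)))
  write_stl(m, stl)
  back <- repair_mesh(read_stl(stl))
  expect_equal(mesh_volume(back), mesh_volume(m), tolerance = 1e-6)
  write_ply(m, ply)
  back2 <- read_ply(ply)
  expect_identical(back2$faces, m$faces)
  expect_equal(back2$vertices, m$vertices, tolerance = 1e-12)
})
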