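test_that("interface detection selects exactly the vertices under threshold", {
  a <- plate_mesh(8, 8, 1, z0 = 0)
  # plate 0.5 mm away with coincident lateral grid: every vertex in contact
  aligned <- plate_mesh(16, 16, 0.5, z0 = 0.5)
  expect_length(detect_interface_vertices(a, aligned, 0.6), nrow(a$vertices))
  # offset, coarser plate: selection equals the brute-force all-pairs oracle
  b <- plate_mesh(12, 12, 0.7, z0 = 0.5, x0 = -1, y0 = -1)
  ids <- detect_interface_vertices(a, b, 0.6)
  d <- sqrt(outer(rowSums(a$vertices^2), rowSums(b$vertices^2), "+") -
            2 * a$vertices %*% t(b$vertices))
  expect_equal(sort(ids), which(apply(d, 1, min) < 0.6))
  far <- plate_mesh(8, 8, 1, z0 = 2.0)
  expect_length(detect_interface_vertices(a, far, 0.8), 0)
})

test_that("per-level thresholds stay within the anatomical range", {
  labs <- c(4:25, ivd_label_for(4:24))
  thr <- interface_threshold_for_label(labs)
  expect_true(all(thr >= 0.6 & thr <= 0.8))
  expect_lt(interface_threshold_for_label(5), interface_threshold_for_label(20))
})

test_that("Laplacian smoothing follows the umbrella update exactly", {
  m <- ball_mesh(6, 1)
  expect_identical(laplacian_smooth(m, iters = 0), m)
  # single selected vertex with weight 1 lands on its neighbour centroid
  sel <- 10L
  nb <- setdiff(unique(as.vector(m$faces[rowSums(m$faces == sel) > 0, ])), sel)
  out <- laplacian_smooth(m, subset = sel, iters = 1, weight = 1)
  expect_equal(out$vertices[sel, ], colMeans(m$vertices[nb, ]), tolerance = 1e-12)
  expect_identical(out$vertices[-sel, ], m$vertices[-sel, ])
  # closed surface shrinks under full Laplacian smoothing
  expect_lt(mesh_volume(laplacian_smooth(m, iters = 10, weight = 0.5)),
            mesh_volume(m))
})

test_that("Taubin smoothing preserves volume better than pure Laplacian", {
  m <- ball_mesh(8, 1)
  expect_identical(taubin_smooth(m, lambda = 0, mu = 0, iters = 5), m)
  v0 <- mesh_volume(m)
  dv_taubin <- abs(mesh_volume(taubin_smooth(m, 0.5, -0.53, 10)) - v0) / v0
  dv_laplace <- abs(mesh_volume(laplacian_smooth(m, iters = 10, weight = 0.5)) - v0) / v0
  expect_lt(dv_taubin, dv_laplace)
  # flat plate: interior vertices stay in the plane
  p <- plate_mesh(6, 6, 1, z0 = 2)
  sm <- taubin_smooth(p, 0.5, -0.53, 5)
  expect_true(all(abs(sm$vertices[, 3] - 2) < 1e-12))
})

test_that("dilation displaces along normals and compensates shrinkage", {
  # genuinely round sphere: project the voxel-ball triangulation onto r = 10
  m <- ball_mesh(10, 0.5)
  ctr <- colMeans(m$vertices)
  rel <- sweep(m$vertices, 2, ctr)
  m$vertices <- sweep(10 * rel / sqrt(rowSums(rel^2)), 2, ctr, "+")
  expect_identical(dilate_mesh(m, 0), m)
  v0 <- mesh_volume(m)
  v_dilated <- mesh_volume(dilate_mesh(m, 1))
  expect_lt(abs(v_dilated - v0 * 1.1^3) / (v0 * 1.1^3), 0.02)
  # shrink by Laplacian, then calibrated dilation restores volume within 1%
  shrunk <- laplacian_smooth(m, iters = 5, weight = 0.5)
  off <- seg2fem:::calibrate_dilation(shrunk, v0)
  expect_lte(off, 0.5)
  expect_lt(abs(mesh_volume(dilate_mesh(shrunk, off)) - v0) / v0, 0.011)
})

test_that("selective vertebra smoothing moves positions only", {
  vol <- phantom_subject(1)
  labs <- labels_present(vol)
  vert <- extract_surface(vol, 11L)
  ivds <- lapply(c(1011L, 1112L), function(l) repair_mesh(extract_surface(vol, l)))
  sm <- smooth_vertebra(vert, ivds, smoothing_params())
  expect_equal(nrow(sm$mesh$vertices), nrow(repair_mesh(vert)$vertices))
  expect_identical(sm$mesh$faces, repair_mesh(vert)$faces)
  expect_gt(length(sm$interface$superior), 0)
  expect_gt(length(sm$interface$inferior), 0)
  expect_length(intersect(sm$interface$superior, sm$interface$inferior), 0)
  # selected vertices face the discs; unselected endplate-region-free vertices
  # lie farther away from both discs than the threshold at smoothing entry
  base <- repair_mesh(vert)
  dmin <- pmin(seg2fem:::.nn_nearest(base$vertices, ivds[[1]]$vertices)$distance,
               seg2fem:::.nn_nearest(base$vertices, ivds[[2]]$vertices)$distance)
  sel <- sort(union(sm$interface$superior, sm$interface$inferior))
  thr <- interface_threshold_for_label(11L)
  expect_true(all(dmin[sel] < thr))
  expect_true(all(dmin[-sel] >= thr))
  # no adjacent discs: empty interface, result equals repair + Taubin
  sm0 <- smooth_vertebra(vert, list(), smoothing_params())
  expect_length(sm0$interface$superior, 0)
  ref <- taubin_smooth(repair_mesh(vert), 0.5, -0.53, 10)
  expect_identical(sm0$mesh$vertices, ref$vertices)
})

test_that("adaptive disc smoothing snaps interface vertices bitwise", {
  vol <- phantom_subject(1)
  ivd <- extract_surface(vol, 1011L)
  raw_discs <- lapply(c(1011L, 1112L), function(l)
    repair_mesh(extract_surface(vol, l)))
  v10 <- smooth_vertebra(extract_surface(vol, 10L), raw_discs[1],
                         smoothing_params())$mesh
  v11 <- smooth_vertebra(extract_surface(vol, 11L), raw_discs,
                         smoothing_params())$mesh
  sm <- smooth_ivd_adaptive(ivd, v10, v11, smoothing_params())
  corr <- sm$interface$correspondence
  expect_gt(nrow(corr), 0)
  key <- function(m) paste(sprintf("%.17g", m[, 1]), sprintf("%.17g", m[, 2]),
                           sprintf("%.17g", m[, 3]))
  vert_keys <- c(key(v10$vertices), key(v11$vertices))
  snapped_keys <- key(sm$mesh$vertices[corr$vertex, , drop = FALSE])
  expect_true(all(snapped_keys %in% vert_keys)) # bitwise shared nodes
  # each snapped vertex carries the coordinates of its recorded target
  sup <- corr[corr$side == "superior", ]
  top_is_v10 <- mean(v10$vertices[, 3]) > mean(v11$vertices[, 3])
  tgt <- if (top_is_v10) v10 else v11
  expect_identical(sm$mesh$vertices[sup$vertex, , drop = FALSE],
                   tgt$vertices[sup$target, , drop = FALSE])
  # volume drift of the full smoothing stays moderate
  expect_lt(abs(mesh_volume(sm$mesh) - mesh_volume(ivd)) / mesh_volume(ivd), 0.1)
})

test_that("snapping picks the geometrically nearest vertebra vertex", {
  # toy: fine disc grid 0.5 mm below a coarser vertebra grid
  ivd <- plate_mesh(10, 10, 0.5, z0 = 0)
  vert <- plate_mesh(5, 5, 1.0, z0 = 0.5)
  # brute-force all-pairs distance oracle
  d <- sqrt(outer(rowSums(ivd$vertices^2), rowSums(vert$vertices^2), "+") -
            2 * ivd$vertices %*% t(vert$vertices))
  ids <- detect_interface_vertices(ivd, vert, 0.6)
  expect_equal(sort(ids), which(apply(d, 1, min) < 0.6))
  # with a threshold above the diagonal gap every disc vertex is in contact
  ids_all <- detect_interface_vertices(ivd, vert, 0.9)
  expect_length(ids_all, nrow(ivd$vertices))
  # each disc vertex maps to its geometrically nearest vertebra node
  nn <- seg2fem:::.nn_nearest(ivd$vertices, vert$vertices)
  brute <- apply(d, 1, which.min)
  expect_equal(nn$index, as.integer(brute))
  expect_equal(nn$distance, apply(d, 1, min), tolerance = 1e-12)
})

test_that("discs beyond the threshold keep their preprocessed shape", {
  vol <- phantom_subject(2)
  ivd <- extract_surface(vol, 1011L)
  far_vert <- extract_surface(vol, 10L)
  far_vert$vertices[, 3] <- far_vert$vertices[, 3] + 50
  sm <- smooth_ivd_adaptive(ivd, far_vert, NULL, smoothing_params())
  expect_equal(nrow(sm$interface$correspondence), 0)
  expect_length(sm$interface$superior, 0)
})
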