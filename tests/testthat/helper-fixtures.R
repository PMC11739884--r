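# shared fixtures, memoized so expensive objects build once per test run
.fix <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fix[[key]])) .fix[[key]] <- force(expr)
  .fix[[key]]
}

# voxelized ball of radius r (mm) at isotropic spacing s
ball_volume <- function(r = 10, s = 1, margin = 3) {
  n <- ceiling((2 * r + 2 * margin * s) / s)
  xs <- ((1:n) - 0.5) * s - n * s / 2
  g <- array(0L, dim = c(n, n, n))
  for (k in seq_len(n))
    g[, , k] <- (outer(xs^2, xs^2, "+") + xs[k]^2 <= r^2) * 1L
  label_volume(g, c(s, s, s))
}

ball_mesh <- function(r = 10, s = 1) {
  memo(sprintf("ball_%g_%g", r, s), extract_surface(ball_volume(r, s), 1L))
}

# rectangular triangulated plate grid in the z = z0 plane
plate_mesh <- function(nx = 10, ny = 10, dx = 1, z0 = 0, x0 = 0, y0 = 0) {
  xs <- x0 + (0:nx) * dx
  ys <- y0 + (0:ny) * dx
  v <- as.matrix(expand.grid(xs, ys))
  v <- cbind(v, z0)
  id <- function(i, j) i + (nx + 1) * (j - 1)
  f <- list()
  for (j in seq_len(ny)) for (i in seq_len(nx)) {
    f[[length(f) + 1]] <- rbind(c(id(i, j), id(i + 1, j), id(i + 1, j + 1)),
                                c(id(i, j), id(i + 1, j + 1), id(i, j + 1)))
  }
  tri_mesh(v, do.call(rbind, f))
}

# a small defect-free phantom subject and its processed artifacts
phantom_subject <- function(seed = 1) {
  memo(sprintf("phantom_%d", seed),
       generate_phantom(phantom_spec(seed = seed)))
}

phantom_artifacts <- function(seed = 1) {
  memo(sprintf("artifacts_%d", seed), {
    rep <- run_subject(phantom_subject(seed),
                       pipeline_config(stop_after = "quality"))
    list(reports = rep, artifacts = attr(rep, "artifacts"))
  })
}

# two interpenetrating tetrahedra in one mesh (self-intersecting fixture)
crossing_tets_mesh <- function() {
  tet_faces <- rbind(c(1, 3, 2), c(1, 2, 4), c(2, 3, 4), c(1, 4, 3))
  v1 <- rbind(c(0, 0, 0), c(2, 0, 0), c(0, 2, 0), c(0, 0, 2))
  v2 <- sweep(v1, 2, c(0.5, 0.3, 0.4), "+")
  tri_mesh(rbind(v1, v2), rbind(tet_faces, tet_faces + 4L))
}
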