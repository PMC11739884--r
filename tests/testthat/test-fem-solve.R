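node_dofs <- seg2fem:::node_dofs

test_that("assembled operator is symmetric with a 6-dim rigid null space", {
  tm <- tet_mesh(rbind(c(1, 1, 1), c(1, -1, -1), c(-1, -1, 1), c(-1, 1, -1)),
                 matrix(1:4, 1), "linear")
  K <- as.matrix(assemble_stiffness(tm, material(100, 0.3)))
  expect_lt(max(abs(K - t(K))), 1e-12)
  ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  expect_equal(sum(abs(ev) < 1e-8 * max(ev)), 6)
  # linearity in E
  K2 <- as.matrix(assemble_stiffness(tm, material(200, 0.3)))
  expect_equal(K2, 2 * K, tolerance = 1e-12)
  # rigid-body modes are annihilated (translations and small rotations)
  x <- tm$nodes
  modes <- cbind(
    as.vector(t(cbind(1, 0, 0))[, rep(1, 4)]),
    as.vector(t(cbind(0, 1, 0))[, rep(1, 4)]),
    as.vector(t(cbind(0, 0, 1))[, rep(1, 4)]),
    as.vector(t(cbind(-x[, 2], x[, 1], 0))),
    as.vector(t(cbind(0, -x[, 3], x[, 2]))),
    as.vector(t(cbind(x[, 3], 0, -x[, 1]))))
  expect_lt(max(abs(K %*% modes)) / max(abs(K)), 1e-9)
  # quadratic element too
  Kq <- as.matrix(assemble_stiffness(to_quadratic(tm), material(100, 0.3)))
  expect_lt(max(abs(Kq - t(Kq))), 1e-10)
  evq <- eigen(Kq, symmetric = TRUE, only.values = TRUE)$values
  expect_equal(sum(abs(evq) < 1e-8 * max(evq)), 6)
})

test_that("inverted elements are reported by name", {
  bad <- tet_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
                  matrix(c(2, 1, 3, 4), 1), "linear")
  expect_error(assemble_stiffness(bad, material(1, 0.3)), "element 1")
})

test_that("kinematic coupling reduces symmetrically and maps rigidly", {
  tm <- to_quadratic(tet_block(c(2, 2, 4), 1))
  top <- which(abs(tm$nodes[, 3] - 4) < 1e-9)
  ref <- reference_node(tm, top)
  coup <- apply_kinematic_coupling(tm, top, ref)
  K <- assemble_stiffness(tm, material(100, 0.3))
  Kr <- as.matrix(Matrix::t(coup$T) %*% K %*% coup$T)
  expect_lt(max(abs(Kr - t(Kr))) / max(abs(Kr)), 1e-9)
  # prescribed pure rotation theta about z: u = theta x r for coupled nodes
  theta <- 1e-3
  ured <- numeric(ncol(coup$T))
  ured[coup$ref_cols] <- c(0, 0, 0, 0, 0, theta)
  u <- matrix(as.vector(coup$T %*% ured), ncol = 3, byrow = TRUE)
  r <- sweep(tm$nodes[top, , drop = FALSE], 2, tm$nodes[ref, ])
  expect_equal(u[top, ], cbind(-theta * r[, 2], theta * r[, 1], 0),
               tolerance = 1e-12)
  expect_true(all(u[-top, ] == 0))
})

test_that("zero load produces zero displacement", {
  tm <- to_quadratic(tet_block(c(2, 2, 4), 1))
  bot <- which(abs(tm$nodes[, 3]) < 1e-9)
  res <- solve_linear_elastic(tm, material(500, 0.3),
                              fixed_dofs = node_dofs(bot))
  expect_true(res$converged)
  expect_equal(max(abs(res$u)), 0)
})

test_that("patch test: linear fields are reproduced to machine accuracy", {
  A <- matrix(c(1e-3, 2e-4, -1e-4, 3e-4, -2e-3, 5e-4,
                2e-4, 1e-4, 1.5e-3), 3, 3)
  for (quad in c(FALSE, TRUE)) {
    tm <- tet_block(c(2, 2, 2), 1)
    if (quad) tm <- to_quadratic(tm)
    u_exact <- tm$nodes %*% t(A)
    onb <- apply(tm$nodes, 1, function(p) any(abs(p) < 1e-9 | abs(p - 2) < 1e-9))
    fixed_nodes <- which(onb)
    res <- solve_linear_elastic(
      tm, material(1000, 0.3),
      fixed_dofs = node_dofs(fixed_nodes),
      fixed_values = as.vector(t(u_exact[fixed_nodes, ])))
    u <- matrix(res$u, ncol = 3, byrow = TRUE)
    expect_lt(max(abs(u - u_exact)) / max(abs(u_exact)), 1e-8)
    stress <- seg2fem:::.tet_element_stress(tm$nodes, tm$elements, res$u,
                                            1000, 0.3)
    expect_lt(max(apply(stress, 2, function(s) diff(range(s)))) /
                max(abs(stress)), 1e-8)
  }
})

test_that("bar fixture matches F*L/(E*A) within 1%", {
  E <- 2000; L <- 20; F <- 100
  tm <- to_quadratic(tet_block(c(4, 4, L), 1))
  bot <- which(abs(tm$nodes[, 3]) < 1e-9)
  top <- which(abs(tm$nodes[, 3] - L) < 1e-9)
  coup <- apply_kinematic_coupling(tm, top, reference_node(tm, top))
  res <- solve_linear_elastic(tm, material(E, 0), fixed_dofs = node_dofs(bot),
                              coupling = coup,
                              ref_load = c(0, 0, F, 0, 0, 0))
  expect_true(res$converged)
  expect_equal(res$ref_motion[3], F * L / (E * 16), tolerance = 0.01)
})

test_that("beam fixture matches M*L/(E*I) within 5% and converges with mesh", {
  E <- 2000; L <- 40; M <- 500; I <- 4 * 4^3 / 12
  exact <- M * L / (E * I)
  tip_err <- function(h, quad) {
    tm <- tet_block(c(4, 4, L), h)
    if (quad) tm <- to_quadratic(tm)
    bot <- which(abs(tm$nodes[, 3]) < 1e-9)
    top <- which(abs(tm$nodes[, 3] - L) < 1e-9)
    coup <- apply_kinematic_coupling(tm, top, reference_node(tm, top))
    res <- solve_linear_elastic(tm, material(E, 0), fixed_dofs = node_dofs(bot),
                                coupling = coup,
                                ref_load = c(0, 0, 0, M, 0, 0))
    abs(res$ref_motion[4] - exact) / exact
  }
  expect_lt(tip_err(1, TRUE), 0.05)
  # linear elements cannot represent the quadratic bending field: their
  # error is visible and decreases monotonically under uniform refinement
  errs_lin <- vapply(c(4, 2, 1), tip_err, numeric(1), quad = FALSE)
  expect_gt(errs_lin[1], 0.05)
  expect_true(all(diff(errs_lin) < 0))
})

test_that("equilibrium: reactions balance the applied moment", {
  art <- phantom_artifacts(1)$artifacts
  a <- art[["1011"]] # disc: small enough to solve quickly
  mdl <- build_model(a$tet, a$interface, default_materials()$ivd)
  res <- solve_static(mdl)
  expect_true(res$converged)
  # restrained nodes carry zero displacement
  expect_true(all(res$displacements[mdl$bc$set, ] == 0))
  # net force balance: a pure moment has zero resultant, so the restrained
  # reactions must also sum to zero
  x <- mdl$mesh$nodes
  R <- matrix(res$reactions, ncol = 3, byrow = TRUE)
  Rb <- R[mdl$bc$set, , drop = FALSE]
  mom_scale <- sqrt(sum(mdl$load$moment^2))
  expect_lt(max(abs(colSums(Rb))) / (mom_scale / 10), 1e-8)
  # reaction moment at the restrained set balances the applied 7.5 N·m
  rel <- sweep(x[mdl$bc$set, , drop = FALSE], 2, x[mdl$coupling$ref, ])
  m_react <- c(sum(rel[, 2] * Rb[, 3] - rel[, 3] * Rb[, 2]),
               sum(rel[, 3] * Rb[, 1] - rel[, 1] * Rb[, 3]),
               sum(rel[, 1] * Rb[, 2] - rel[, 2] * Rb[, 1]))
  expect_equal(m_react, -mdl$load$moment, tolerance = 1e-8)
  expect_equal(sqrt(sum(m_react^2)) / 1e3, 7.5, tolerance = 1e-8)
  # rigid coupling to first order: every coupled node obeys the small-
  # rotation rigid map u = u_ref + theta x r to solver precision
  u <- res$displacements
  set <- mdl$coupling$set
  rm6 <- res$ref_node_motion
  r <- sweep(x[set, , drop = FALSE], 2, x[mdl$coupling$ref, ])
  u_rigid <- cbind(rm6[1] + rm6[5] * r[, 3] - rm6[6] * r[, 2],
                   rm6[2] + rm6[6] * r[, 1] - rm6[4] * r[, 3],
                   rm6[3] + rm6[4] * r[, 2] - rm6[5] * r[, 1])
  diam <- max(dist(x[set, , drop = FALSE]))
  expect_lt(max(abs(u[set, , drop = FALSE] - u_rigid)) / diam, 1e-8)
})

test_that("singular systems report non-convergence instead of crashing", {
  # no boundary conditions at all: pure rigid-body-singular system
  tm <- tet_block(c(2, 2, 2), 1)
  res <- solve_linear_elastic(tm, material(100, 0.3), fixed_dofs = integer(0),
                              loads = rep(0.1, 3 * nrow(tm$nodes)))
  expect_false(res$converged)
})

test_that("von Mises matches its closed forms", {
  expect_equal(von_mises(c(120, 0, 0, 0, 0, 0)), 120)
  expect_equal(von_mises(c(0, 0, 0, 35, 0, 0)), sqrt(3) * 35)
  expect_equal(von_mises(diag(3) * -77), 0)
  s <- matrix(c(10, 5, 1, 5, 20, 2, 1, 2, 30), 3, 3)
  expect_equal(von_mises(s),
               sqrt(0.5 * ((10 - 20)^2 + (20 - 30)^2 + (30 - 10)^2) +
                    3 * (5^2 + 2^2 + 1^2)))
})
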