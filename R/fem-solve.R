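#' Assemble the global stiffness operator
#'
#' Standard isoparametric small-strain elasticity assembly: linear
#' tetrahedra integrated exactly (constant strain), quadratic tetrahedra
#' with the 4-point interior quadrature rule. The operator is symmetric
#' positive semi-definite with the 6-dimensional rigid-body null space
#' before constraints; an inverted element raises an assembly error naming
#' the element.
#'
#' @param tm a [tet_mesh()].
#' @param material a [material()].
#' @return Sparse symmetric `dgCMatrix` of dimension `3 * n_nodes`.
#' @export
assemble_stiffness <- function(tm, material) {
  tr <- .assemble_tet_stiffness(tm$nodes, tm$elements,
                                material$youngs_modulus,
                                material$poisson_ratio)
  n <- 3L * nrow(tm$nodes)
  Matrix::sparseMatrix(i = tr$i, j = tr$j, x = tr$x, dims = c(n, n))
}

# dof ids (1-based into the 3N displacement vector) of a node set
node_dofs <- function(nodes, dofs = 1:3) {
  as.vector(t(outer(3L * (as.integer(nodes) - 1L), dofs, "+")))
}

#' Kinematic-coupling transformation
#'
#' Builds the sparse transformation `T` eliminating the coupled node
#' degrees of freedom through the small-rotation rigid map
#' `u_i = u_ref + theta x (x_i - x_ref)`. Reduced unknowns are the
#' translations of all uncoupled nodes followed by the reference's 6
#' generalized DoF (3 translations, 3 rotations). The reduced operator
#' `t(T) K T` stays symmetric, and loads on coupled nodes transfer
#' statically equivalent forces and moments to the reference.
#'
#' @param tm a [tet_mesh()].
#' @param coupled_set node ids rigidly tied to the reference.
#' @param ref reference node id (member of the mesh).
#' @return List with the sparse matrix `T`, the reduced-system column
#'   bookkeeping (`free_nodes`, `ref_cols` = the 6 reference columns).
#' @export
apply_kinematic_coupling <- function(tm, coupled_set, ref) {
  nn <- nrow(tm$nodes)
  coupled_set <- sort(unique(c(as.integer(coupled_set), as.integer(ref))))
  free_nodes <- setdiff(seq_len(nn), coupled_set)
  ncol_red <- 3L * length(free_nodes) + 6L
  ref_cols <- 3L * length(free_nodes) + 1:6
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  # identity on free nodes
  if (length(free_nodes)) {
    ii <- node_dofs(free_nodes)
    jj <- seq_len(3L * length(free_nodes))
    xx <- rep(1, 3L * length(free_nodes))
  }
  # coupled nodes: u = u_ref + theta x r
  r <- sweep(tm$nodes[coupled_set, , drop = FALSE], 2,
             tm$nodes[ref, ])
  for (k in seq_along(coupled_set)) {
    nd <- coupled_set[k]
    rows <- 3L * (nd - 1L) + 1:3
    # translation part
    ii <- c(ii, rows)
    jj <- c(jj, ref_cols[1:3])
    xx <- c(xx, rep(1, 3))
    # rotation part: [theta x r] coefficient matrix
    rx <- r[k, 1]; ry <- r[k, 2]; rz <- r[k, 3]
    cm <- rbind(c(0, rz, -ry), c(-rz, 0, rx), c(ry, -rx, 0))
    nzi <- which(cm != 0, arr.ind = TRUE)
    ii <- c(ii, rows[nzi[, 1]])
    jj <- c(jj, ref_cols[3 + nzi[, 2]])
    xx <- c(xx, cm[nzi])
  }
  T_ <- Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                             dims = c(3L * nn, ncol_red))
  list(T = T_, free_nodes = free_nodes, ref_cols = ref_cols,
       coupled_set = coupled_set, ref = as.integer(ref))
}

#' Von Mises equivalent stress
#'
#' @param stress a symmetric 3 x 3 stress tensor, or a length-6 vector
#'   (sxx, syy, szz, sxy, syz, szx), or a matrix with 6 such columns.
#' @return Scalar (or vector) equivalent stress.
#' @export
von_mises <- function(stress) {
  if (is.matrix(stress) && all(dim(stress) == c(3, 3)))
    stress <- c(stress[1, 1], stress[2, 2], stress[3, 3],
                stress[1, 2], stress[2, 3], stress[3, 1])
  s <- if (is.matrix(stress)) stress else matrix(stress, nrow = 1)
  sqrt(0.5 * ((s[, 1] - s[, 2])^2 + (s[, 2] - s[, 3])^2 + (s[, 3] - s[, 1])^2) +
       3 * (s[, 4]^2 + s[, 5]^2 + s[, 6]^2))
}

# shared linear solve with singularity detection
solve_spd <- function(K, f) {
  u <- tryCatch({
    ch <- Matrix::Cholesky(Matrix::forceSymmetric(K), LDL = FALSE,
                           perm = TRUE, super = TRUE)
    as.vector(Matrix::solve(ch, f))
  }, error = function(e) NULL, warning = function(w) NULL)
  if (is.null(u) || any(!is.finite(u))) return(NULL)
  # guard against semi-definite systems that slipped through Cholesky
  res <- sqrt(sum((as.vector(K %*% u) - f)^2)) /
    max(sqrt(sum(f^2)), 1e-30)
  if (res > 1e-6) return(NULL)
  u
}

#' General static linear-elastic solve
#'
#' Lower-level entry used by [solve_static()] and by verification fixtures:
#' arbitrary prescribed displacements, nodal loads and optionally one
#' kinematic coupling with a generalized load on the reference node.
#'
#' @param tm a [tet_mesh()].
#' @param material a [material()].
#' @param fixed_dofs integer dof ids (1-based into the 3N vector) with
#'   prescribed values `fixed_values` (default 0).
#' @param fixed_values numeric, recycled to `length(fixed_dofs)`.
#' @param loads numeric length-3N nodal load vector (or NULL).
#' @param coupling result of [apply_kinematic_coupling()] (or NULL).
#' @param ref_load length-6 generalized force/moment on the coupling
#'   reference (N, N·mm).
#' @return List with `u` (3N displacements), `converged`, `ref_motion`
#'   (6-vector or NULL), `reactions` (3N vector `K u - f`).
#' @export
solve_linear_elastic <- function(tm, material, fixed_dofs = integer(0),
                                 fixed_values = 0, loads = NULL,
                                 coupling = NULL, ref_load = rep(0, 6)) {
  n <- 3L * nrow(tm$nodes)
  K <- assemble_stiffness(tm, material)
  f <- if (is.null(loads)) numeric(n) else as.numeric(loads)
  fixed_dofs <- as.integer(fixed_dofs)
  fixed_values <- rep_len(as.numeric(fixed_values), length(fixed_dofs))

  if (!is.null(coupling)) {
    if (length(intersect(node_dofs(coupling$coupled_set), fixed_dofs)))
      stop_seg2fem("coupled set intersects restrained dofs",
                   "seg2fem_constraint_error")
    T_ <- coupling$T
    Kr <- Matrix::t(T_) %*% K %*% T_
    fr <- as.vector(Matrix::t(T_) %*% f)
    fr[coupling$ref_cols] <- fr[coupling$ref_cols] + ref_load
    # map fixed dofs into reduced numbering (they are all free-node dofs)
    red_index <- integer(n)
    red_index[node_dofs(coupling$free_nodes)] <-
      seq_len(3L * length(coupling$free_nodes))
    fixed_red <- red_index[fixed_dofs]
    keep <- setdiff(seq_len(ncol(T_)), fixed_red)
    ub <- numeric(ncol(T_))
    ub[fixed_red] <- fixed_values
    rhs <- fr[keep] - as.vector(Kr[keep, fixed_red, drop = FALSE] %*%
                                  fixed_values)
    usol <- solve_spd(Kr[keep, keep], rhs)
    if (is.null(usol))
      return(list(u = NULL, converged = FALSE, ref_motion = NULL,
                  reactions = NULL))
    ured <- ub
    ured[keep] <- usol
    u <- as.vector(T_ %*% ured)
    ref_motion <- ured[coupling$ref_cols]
  } else {
    keep <- setdiff(seq_len(n), fixed_dofs)
    ub <- numeric(n)
    ub[fixed_dofs] <- fixed_values
    rhs <- f[keep] - as.vector(K[keep, fixed_dofs, drop = FALSE] %*%
                                 fixed_values)
    usol <- solve_spd(K[keep, keep], rhs)
    if (is.null(usol))
      return(list(u = NULL, converged = FALSE, ref_motion = NULL,
                  reactions = NULL))
    u <- ub
    u[keep] <- usol
    ref_motion <- NULL
  }
  reactions <- as.vector(K %*% u) - f
  list(u = u, converged = TRUE, ref_motion = ref_motion,
       reactions = reactions)
}

#' Solve a standalone body model statically
#'
#' Sparse symmetric solve of the reduced system (kinematic coupling
#' eliminated by DoF transformation, inferior set fully restrained,
#' flexion moment on the reference's rotational DoF). On a singular or
#' ill-conditioned system the result carries `converged = FALSE` instead of
#' raising, mirroring how failed solver runs are accounted for in cohort
#' statistics.
#'
#' @param model an [build_model()] result.
#' @return An object of class `fe_result`: nodal `displacements` (n x 3,
#'   mm), `element_von_mises` (MPa), `element_stress` (e x 6),
#'   `ref_node_motion` (3 translations mm + 3 rotations rad), `reactions`,
#'   `converged`.
#' @export
solve_static <- function(model) {
  tm <- model$mesh
  coup <- apply_kinematic_coupling(tm, model$coupling$set, model$coupling$ref)
  fixed <- node_dofs(model$bc$set, model$bc$dofs)
  res <- solve_linear_elastic(tm, model$material, fixed_dofs = fixed,
                              loads = NULL, coupling = coup,
                              ref_load = c(0, 0, 0, model$load$moment))
  if (!res$converged) {
    return(structure(list(displacements = NULL, element_von_mises = NULL,
                          element_stress = NULL, ref_node_motion = NULL,
                          reactions = NULL, converged = FALSE),
                     class = "fe_result"))
  }
  stress <- .tet_element_stress(tm$nodes, tm$elements, res$u,
                                model$material$youngs_modulus,
                                model$material$poisson_ratio)
  structure(list(displacements = matrix(res$u, ncol = 3, byrow = TRUE),
                 element_von_mises = von_mises(stress),
                 element_stress = stress,
                 ref_node_motion = res$ref_motion,
                 reactions = res$reactions, converged = TRUE),
            class = "fe_result")
}

#' @export
#' @method print fe_result
print.fe_result <- function(x, ...) {
  if (!x$converged) {
    cat("fe_result: NOT converged\n")
  } else {
    cat(sprintf("fe_result: max |u| %.4g mm, max von Mises %.4g MPa\n",
                max(sqrt(rowSums(x$displacements^2))),
                max(x$element_von_mises)))
  }
  invisible(x)
}

#' Export a solved model as VTU and a JSON summary
#'
#' @param model an [build_model()] result.
#' @param result the matching [solve_static()] result.
#' @param vtu_path,json_path output paths (NULL to skip either).
#' @return Invisibly, the summary list.
#' @export
export_results <- function(model, result, vtu_path = NULL, json_path = NULL) {
  summary <- list(body = model$body_name, converged = result$converged)
  if (result$converged) {
    summary$max_von_mises_mpa <- max(result$element_von_mises)
    summary$mean_von_mises_mpa <- mean(result$element_von_mises)
    summary$ref_node_motion <- result$ref_node_motion
    if (!is.null(vtu_path))
      write_vtu(model$mesh, vtu_path,
                point_data = list(displacement = result$displacements),
                cell_data = list(von_mises = result$element_von_mises))
  }
  if (!is.null(json_path))
    jsonlite::write_json(summary, json_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  invisible(summary)
}
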