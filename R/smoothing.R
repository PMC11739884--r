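#' Smoothing parameters
#'
#' Parameters of the two anatomically constrained smoothing protocols. The
#' interface threshold is the vertex-to-vertex contact distance; anatomical
#' use ranges 0.6-0.8 mm depending on the spinal level (a wider range is
#' permitted, e.g. for toy fixtures). Taubin factors follow the classic
#' pass-band choice (`lambda = 0.5`, `mu = -0.53`); `dilation_offset_mm = NULL`
#' requests per-body calibration of the disc dilation step so that the
#' preprocessed volume matches the raw enclosed volume within 1%, bounded by
#' 0.5 mm.
#'
#' @param interface_threshold_mm contact distance threshold (mm), > 0.
#' @param laplace_iters,laplace_weight Laplacian iteration count and step
#'   factor in (0, 1\].
#' @param taubin_lambda,taubin_mu,taubin_iters Taubin shrink (> 0) and
#'   inflate (< 0, `|mu| > lambda`) factors and iteration count.
#' @param dilation_offset_mm non-negative dilation offset (mm), or NULL for
#'   volume-calibrated.
#' @return An object of class `smoothing_params`.
#' @export
smoothing_params <- function(interface_threshold_mm = 0.8, laplace_iters = 10L,
                             laplace_weight = 0.5, taubin_lambda = 0.5,
                             taubin_mu = -0.53, taubin_iters = 10L,
                             dilation_offset_mm = NULL) {
  if (interface_threshold_mm <= 0)
    stop_seg2fem("interface threshold must be > 0", "seg2fem_spec_error")
  if (laplace_weight <= 0 || laplace_weight > 1)
    stop_seg2fem("laplace_weight must lie in (0, 1]", "seg2fem_spec_error")
  if (!(taubin_mu < 0 && taubin_lambda > 0))
    stop_seg2fem("need taubin_mu < 0 < taubin_lambda", "seg2fem_spec_error")
  if (abs(taubin_mu) <= taubin_lambda)
    stop_seg2fem("need |taubin_mu| > taubin_lambda", "seg2fem_spec_error")
  if (!is.null(dilation_offset_mm) && dilation_offset_mm < 0)
    stop_seg2fem("dilation offset must be >= 0", "seg2fem_spec_error")
  structure(list(interface_threshold_mm = interface_threshold_mm,
                 laplace_iters = as.integer(laplace_iters),
                 laplace_weight = laplace_weight,
                 taubin_lambda = taubin_lambda, taubin_mu = taubin_mu,
                 taubin_iters = as.integer(taubin_iters),
                 dilation_offset_mm = dilation_offset_mm),
            class = "smoothing_params")
}

#' Per-level interface distance thresholds
#'
#' Default threshold table: 0.6 mm for cervical-range vertebra labels (4-7)
#' and their discs, 0.8 mm otherwise — smaller cervical anatomy warrants the
#' tighter bound.
#'
#' @param label vertebra or IVD label id.
#' @return Threshold in mm.
#' @export
interface_threshold_for_label <- function(label) {
  upper <- ifelse(is_ivd_label(label), label %/% 100L, label)
  ifelse(upper <= 7, 0.6, 0.8)
}

#' Interface map of a body
#'
#' Records the interface vertex index sets of a body's mesh (superior and
#' inferior contact surfaces) and, for adaptively smoothed discs, the
#' correspondence of each snapped interface vertex to the adjacent vertebra
#' vertex whose coordinates it received (bitwise equal).
#'
#' @param body_id label id of the body.
#' @param superior,inferior disjoint integer index sets into the body mesh.
#' @param correspondence data frame with columns `vertex` (index into the
#'   body mesh), `side` (`"superior"`/`"inferior"`) and `target` (index into
#'   the adjacent vertebra mesh); empty for vertebrae.
#' @return An object of class `interface_map`.
#' @export
interface_map <- function(body_id, superior = integer(0), inferior = integer(0),
                          correspondence = NULL) {
  superior <- sort(unique(as.integer(superior)))
  inferior <- sort(unique(as.integer(inferior)))
  if (length(intersect(superior, inferior)))
    stop_seg2fem("superior and inferior interface sets must be disjoint",
                 "seg2fem_spec_error")
  if (is.null(correspondence))
    correspondence <- data.frame(vertex = integer(0), side = character(0),
                                 target = integer(0))
  structure(list(body_id = body_id, superior = superior, inferior = inferior,
                 correspondence = correspondence),
            class = "interface_map")
}

#' Detect interface vertices between two meshes
#'
#' Returns exactly the vertices of `mesh_a` whose nearest-vertex distance to
#' `mesh_b` is strictly below the threshold. Distances are vertex-to-vertex,
#' matching the definition of the snapping step.
#'
#' @param mesh_a,mesh_b [tri_mesh()] objects.
#' @param threshold_mm contact distance threshold (> 0).
#' @return Integer vertex indices into `mesh_a` (possibly empty).
#' @export
detect_interface_vertices <- function(mesh_a, mesh_b, threshold_mm) {
  stopifnot(threshold_mm > 0, nrow(mesh_a$vertices) > 0,
            nrow(mesh_b$vertices) > 0)
  nn <- .nn_nearest(mesh_a$vertices, mesh_b$vertices)
  which(nn$distance < threshold_mm)
}

# 1-ring adjacency as a sparse 0/1 matrix plus vertex degrees
mesh_adjacency <- function(mesh) {
  f <- mesh$faces
  nv <- nrow(mesh$vertices)
  i <- c(f[, 1], f[, 2], f[, 2], f[, 3], f[, 3], f[, 1])
  j <- c(f[, 2], f[, 1], f[, 3], f[, 2], f[, 1], f[, 3])
  a <- Matrix::sparseMatrix(i = i, j = j, x = 1, dims = c(nv, nv))
  a@x[] <- 1 # collapse duplicate edge entries to 0/1
  list(A = a, deg = Matrix::rowSums(a))
}

# one umbrella step p <- p + w * (mean(neighbours) - p) on `subset` rows
umbrella_step <- function(v, adj, subset, w) {
  nb_mean <- as.matrix(adj$A[subset, , drop = FALSE] %*% v)
  deg <- adj$deg[subset]
  ok <- deg > 0
  nb_mean[ok, ] <- nb_mean[ok, , drop = FALSE] / deg[ok]
  nb_mean[!ok, ] <- v[subset[!ok], , drop = FALSE] # isolated: stay
  v[subset, ] <- v[subset, , drop = FALSE] +
    w * (nb_mean - v[subset, , drop = FALSE])
  v
}

#' Laplacian (umbrella) smoothing of a vertex subset
#'
#' Per iteration every selected vertex moves toward the centroid of its
#' 1-ring neighbours by the step factor `weight`; unselected vertices never
#' move. Shrinks closed meshes — the motivation for the disc dilation step.
#'
#' @param mesh a [tri_mesh()].
#' @param subset integer vertex indices to smooth, or NULL for all vertices.
#' @param iters iteration count (>= 0; 0 is the identity).
#' @param weight step factor in (0, 1\].
#' @return The smoothed [tri_mesh()] (same connectivity).
#' @export
laplacian_smooth <- function(mesh, subset = NULL, iters = 10L, weight = 0.5) {
  stopifnot(iters >= 0)
  if (iters == 0) return(mesh)
  adj <- mesh_adjacency(mesh)
  subset <- if (is.null(subset)) seq_len(nrow(mesh$vertices)) else
    sort(unique(as.integer(subset)))
  if (!length(subset)) return(mesh)
  if (any(adj$deg[subset] == 0))
    warning("isolated vertices in smoothing subset are left unmoved")
  v <- mesh$vertices
  for (it in seq_len(iters)) v <- umbrella_step(v, adj, subset, weight)
  out <- mesh
  out$vertices <- v
  out
}

#' Taubin smoothing
#'
#' Alternates umbrella steps with a positive (shrink) factor `lambda` and a
#' negative (inflate) factor `mu`, suppressing the volume loss of pure
#' Laplacian smoothing while removing high-frequency surface noise.
#'
#' @param mesh a [tri_mesh()].
#' @param lambda,mu step factors of the alternating passes.
#' @param iters number of lambda/mu iteration pairs.
#' @param subset vertex indices to smooth, or NULL for the whole mesh.
#' @return The smoothed [tri_mesh()] (same connectivity).
#' @export
taubin_smooth <- function(mesh, lambda = 0.5, mu = -0.53, iters = 10L,
                          subset = NULL) {
  stopifnot(iters >= 0)
  if (iters == 0 || (lambda == 0 && mu == 0)) return(mesh)
  adj <- mesh_adjacency(mesh)
  subset <- if (is.null(subset)) seq_len(nrow(mesh$vertices)) else
    sort(unique(as.integer(subset)))
  if (!length(subset)) return(mesh)
  v <- mesh$vertices
  for (it in seq_len(iters)) {
    v <- umbrella_step(v, adj, subset, lambda)
    v <- umbrella_step(v, adj, subset, mu)
  }
  out <- mesh
  out$vertices <- v
  out
}

#' Dilate a mesh along vertex normals
#'
#' Displaces every vertex along its area-weighted vertex normal by
#' `offset_mm`, compensating the volume loss of Laplacian smoothing.
#'
#' @param mesh a watertight, outward-oriented [tri_mesh()].
#' @param offset_mm non-negative offset (mm).
#' @return The dilated [tri_mesh()].
#' @export
dilate_mesh <- function(mesh, offset_mm) {
  stopifnot(offset_mm >= 0)
  if (offset_mm == 0) return(mesh)
  out <- mesh
  out$vertices <- mesh$vertices + offset_mm * vertex_normals(mesh)
  out
}

# offset (bounded by max_offset) whose dilation brings the mesh volume to
# `target` within rel_tol; bisection on the monotone volume-offset relation
calibrate_dilation <- function(mesh, target, max_offset = 0.5, rel_tol = 0.01) {
  volume_at <- function(o) mesh_volume(dilate_mesh(mesh, o))
  if (volume_at(0) >= target * (1 - rel_tol)) return(0)
  if (volume_at(max_offset) <= target) return(max_offset)
  lo <- 0
  hi <- max_offset
  for (i in 1:30) {
    mid <- (lo + hi) / 2
    vm <- volume_at(mid)
    if (abs(vm - target) <= rel_tol * target) return(mid)
    if (vm < target) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# split interface ids of mesh against a list of neighbour meshes into
# superior/inferior sets by the neighbour centroid along `axis`
split_interfaces <- function(mesh, neighbours, thresholds, axis = c(0, 0, 1)) {
  ctr <- mean(mesh$vertices %*% axis)
  sup <- integer(0)
  inf <- integer(0)
  for (i in seq_along(neighbours)) {
    nb <- neighbours[[i]]
    if (is.null(nb)) next
    ids <- detect_interface_vertices(mesh, nb, thresholds[[i]])
    if (mean(nb$vertices %*% axis) >= ctr) sup <- union(sup, ids)
    else inf <- union(inf, ids)
  }
  # a vertex claimed by both sides is kept on the nearer one
  both <- intersect(sup, inf)
  if (length(both)) {
    for (vtx in both) {
      d <- vapply(neighbours, function(nb) {
        if (is.null(nb)) return(Inf)
        min(sqrt(colSums((t(nb$vertices) - mesh$vertices[vtx, ])^2)))
      }, numeric(1))
      nearer <- which.min(d)
      if (mean(neighbours[[nearer]]$vertices %*% axis) >= ctr)
        inf <- setdiff(inf, vtx)
      else sup <- setdiff(sup, vtx)
    }
  }
  list(superior = sort(sup), inferior = sort(inf))
}

#' Selective, edge-preserving vertebra smoothing
#'
#' Pipeline: repair, detect interface vertex sets against each adjacent disc
#' mesh, Laplacian-smooth only those interface subsets (the anatomical
#' contact surfaces), reinsert, then Taubin-smooth the whole mesh. Vertex
#' and face counts never change; only positions move. Regions not facing a
#' disc keep their (stair-stepped) geometry apart from the gentle Taubin
#' pass.
#'
#' @param mesh raw vertebra [tri_mesh()].
#' @param adjacent_ivds list of 0-2 adjacent disc meshes (end vertebrae
#'   have one; NULL entries allowed).
#' @param params a [smoothing_params()].
#' @param axis stacking axis used to classify interfaces as
#'   superior/inferior.
#' @return `list(mesh = <smoothed tri_mesh>, interface = <interface_map>)`.
#' @export
smooth_vertebra <- function(mesh, adjacent_ivds = list(),
                            params = smoothing_params(), axis = c(0, 0, 1)) {
  mesh <- repair_mesh(mesh)
  adjacent_ivds <- Filter(Negate(is.null), adjacent_ivds)
  thr <- rep(list(params$interface_threshold_mm), length(adjacent_ivds))
  sets <- split_interfaces(mesh, adjacent_ivds, thr, axis)
  sel <- union(sets$superior, sets$inferior)
  if (length(sel))
    mesh <- laplacian_smooth(mesh, sel, params$laplace_iters,
                             params$laplace_weight)
  mesh <- taubin_smooth(mesh, params$taubin_lambda, params$taubin_mu,
                        params$taubin_iters)
  list(mesh = mesh,
       interface = interface_map(mesh$body_id, sets$superior, sets$inferior))
}

# vertex ids within `rings` edge hops of `seed` ids
ring_neighbourhood <- function(adj, seed, rings) {
  sel <- seed
  for (r in seq_len(rings)) {
    nb <- which(Matrix::colSums(adj$A[sel, , drop = FALSE]) > 0)
    sel <- union(sel, nb)
  }
  sel
}

#' Adaptive disc smoothing with shared-node snapping
#'
#' Pipeline: preprocess (Taubin, Laplacian, repair, volume-compensating
#' dilation), detect interface vertices against the already-smoothed
#' adjacent vertebrae, replace each interface vertex coordinate with the
#' coordinates of the nearest vertebra vertex (bitwise), then Taubin-smooth
#' the border ring around the contact patches with all snapped vertices
#' frozen, and repair. Disc vertices snapped onto the same vertebra vertex
#' are merged. The result shares node coordinates with the vertebra meshes
#' exactly, which is what later allows conforming volume meshes without
#' contact formulations.
#'
#' @param ivd raw disc [tri_mesh()].
#' @param vert_above,vert_below smoothed adjacent vertebra meshes (outputs
#'   of [smooth_vertebra()]); either may be NULL.
#' @param params a [smoothing_params()].
#' @param axis stacking axis.
#' @return `list(mesh = <tri_mesh>, interface = <interface_map>)` with the
#'   correspondence table filled for every snapped vertex.
#' @export
smooth_ivd_adaptive <- function(ivd, vert_above = NULL, vert_below = NULL,
                                params = smoothing_params(), axis = c(0, 0, 1)) {
  raw_volume <- abs(mesh_volume(ivd))
  m <- taubin_smooth(ivd, params$taubin_lambda, params$taubin_mu,
                     params$taubin_iters)
  m <- laplacian_smooth(m, NULL, params$laplace_iters, params$laplace_weight)
  m <- repair_mesh(m)
  off <- params$dilation_offset_mm %||%
    calibrate_dilation(m, raw_volume, max_offset = 0.5, rel_tol = 0.01)
  m <- dilate_mesh(m, off)

  neighbours <- list(vert_above, vert_below)
  thr <- rep(list(params$interface_threshold_mm), 2L)
  sets <- split_interfaces(m, neighbours, thr, axis)

  v <- m$vertices
  corr <- data.frame(vertex = integer(0), side = character(0),
                     target = integer(0))
  snap_to <- function(ids, target_mesh, side) {
    if (!length(ids) || is.null(target_mesh)) return(invisible(NULL))
    nn <- .nn_nearest(v[ids, , drop = FALSE], target_mesh$vertices)
    v[ids, ] <<- target_mesh$vertices[nn$index, , drop = FALSE]
    corr <<- rbind(corr, data.frame(vertex = ids, side = side,
                                    target = nn$index))
    invisible(NULL)
  }
  above_is_sup <- is.null(vert_below) ||
    (!is.null(vert_above) &&
     mean(vert_above$vertices %*% axis) >= mean(m$vertices %*% axis))
  snap_to(sets$superior, if (above_is_sup) vert_above else vert_below, "superior")
  snap_to(sets$inferior, if (above_is_sup) vert_below else vert_above, "inferior")
  m$vertices <- v
  snapped <- sort(c(sets$superior, sets$inferior))

  if (length(snapped)) {
    # merge disc vertices that snapped onto the same vertebra vertex
    dd <- merge_duplicate_vertices(m$vertices, m$faces, tol = 1e-9)
    m <- tri_mesh(dd$vertices, dd$faces, ivd$body_id)
    remap <- dd$map
    snapped <- sort(unique(remap[snapped]))
    sets$superior <- sort(unique(remap[sets$superior]))
    sets$inferior <- sort(unique(remap[sets$inferior]))
    corr$vertex <- remap[corr$vertex]
    corr <- corr[!duplicated(corr$vertex), , drop = FALSE]

    adj <- mesh_adjacency(m)
    border <- setdiff(ring_neighbourhood(adj, snapped, 2L), snapped)
    if (length(border))
      m <- taubin_smooth(m, params$taubin_lambda, params$taubin_mu,
                         params$taubin_iters, subset = border)
    # tight tolerance: already deduplicated, must not renumber snapped ids
    m <- repair_mesh(m, merge_tol = 1e-9)
  } else {
    m$body_id <- ivd$body_id
  }

  rep <- diagnose(m)
  if (rep$self_intersecting)
    stop_seg2fem("adaptive smoothing produced self-intersecting faces",
                 "seg2fem_smoothing_error", diagnostics = rep,
                 category = "self_intersecting_faces")
  list(mesh = m,
       interface = interface_map(ivd$body_id, sets$superior, sets$inferior,
                                 correspondence = corr))
}

# merge vertices coincident on a `tol` grid; returns vertices, faces
# (degenerate/duplicate faces dropped) and the old->new index map
merge_duplicate_vertices <- function(v, f, tol = 1e-9) {
  key <- paste(round(v[, 1] / tol), round(v[, 2] / tol), round(v[, 3] / tol))
  first <- match(key, key)
  keep <- which(first == seq_along(first))
  map <- match(first, keep)
  v <- v[keep, , drop = FALSE]
  f <- matrix(map[f], ncol = 3)
  ok <- f[, 1] != f[, 2] & f[, 2] != f[, 3] & f[, 1] != f[, 3]
  f <- f[ok, , drop = FALSE]
  fk <- apply(f, 1, function(r) paste(sort(r), collapse = "_"))
  f <- f[!duplicated(fk), , drop = FALSE]
  list(vertices = v, faces = f, map = map)
}
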