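#' Tetrahedral volume mesh
#'
#' @param nodes n x 3 numeric node coordinates (mm).
#' @param elements e x 4 (linear) or e x 10 (quadratic) matrix of 1-based
#'   node indices; corner nodes first, edge midpoints 5-10 in the order
#'   (1-2, 2-3, 3-1, 1-4, 2-4, 3-4).
#' @param order `"linear"` or `"quadratic"`.
#' @param surface_node_map integer vector mapping surface vertex index to
#'   volume node index (injective; mapped coordinates equal the surface
#'   vertex coordinates).
#' @param surface the boundary [tri_mesh()] the volume was filled from.
#' @return An object of class `tet_mesh`.
#' @export
tet_mesh <- function(nodes, elements, order = c("linear", "quadratic"),
                     surface_node_map = NULL, surface = NULL) {
  order <- match.arg(order)
  nodes <- as_matrix3(nodes, "nodes")
  elements <- as.matrix(elements)
  storage.mode(elements) <- "integer"
  want <- if (order == "linear") 4L else 10L
  if (ncol(elements) != want)
    stop_seg2fem(sprintf("%s elements must have %d nodes", order, want),
                 "seg2fem_format_error")
  if (nrow(elements) && (min(elements) < 1L || max(elements) > nrow(nodes)))
    stop_seg2fem("element indices out of range", "seg2fem_format_error")
  structure(list(nodes = nodes, elements = elements, order = order,
                 surface_node_map = surface_node_map, surface = surface),
            class = "tet_mesh")
}

#' @export
#' @method print tet_mesh
print.tet_mesh <- function(x, ...) {
  cat(sprintf("tet_mesh: %d nodes, %d %s tetrahedra\n", nrow(x$nodes),
              nrow(x$elements), x$order))
  invisible(x)
}

# signed volumes of the corner tets
tet_volumes <- function(nodes, elements) {
  a <- nodes[elements[, 1], , drop = FALSE]
  b <- nodes[elements[, 2], , drop = FALSE] - a
  c_ <- nodes[elements[, 3], , drop = FALSE] - a
  d <- nodes[elements[, 4], , drop = FALSE] - a
  (b[, 1] * (c_[, 2] * d[, 3] - c_[, 3] * d[, 2]) -
   b[, 2] * (c_[, 1] * d[, 3] - c_[, 3] * d[, 1]) +
   b[, 3] * (c_[, 1] * d[, 2] - c_[, 2] * d[, 1])) / 6
}

#' Total element volume of a tet mesh
#' @param tm a [tet_mesh()].
#' @export
tet_mesh_volume <- function(tm) sum(tet_volumes(tm$nodes, tm$elements))

# locate the python interpreter carrying scipy (cached per session)
the <- new.env(parent = emptyenv())
find_python <- function() {
  if (!is.null(the$python)) return(the$python)
  for (cand in c(Sys.getenv("SEG2FEM_PYTHON", ""), "python", "python3")) {
    if (!nzchar(cand)) next
    exe <- Sys.which(cand)
    if (!nzchar(exe)) next
    ok <- tryCatch(system2(exe, c("-c", "\"import scipy.spatial\""),
                           stdout = FALSE, stderr = FALSE) == 0,
                   error = function(e) FALSE, warning = function(w) FALSE)
    if (isTRUE(ok)) {
      the$python <- exe
      return(exe)
    }
  }
  NULL
}

# unconstrained 3D Delaunay of a point set (0-based -> 1-based simplices)
delaunay_tets <- function(points) {
  exe <- find_python()
  if (is.null(exe))
    stop_seg2fem("no python interpreter with scipy found for the Delaunay kernel",
                 "seg2fem_meshing_error")
  script <- system.file("python", "delaunay_tets.py", package = "seg2fem")
  fin <- tempfile(fileext = ".f64")
  fout <- tempfile(fileext = ".i32")
  on.exit(unlink(c(fin, fout)))
  writeBin(as.vector(t(points)), fin, size = 8)
  status <- system2(exe, c(shQuote(script), shQuote(fin), shQuote(fout)),
                    stdout = FALSE, stderr = FALSE)
  if (status != 0 || !file.exists(fout))
    stop_seg2fem("Delaunay kernel failed", "seg2fem_meshing_error")
  raw <- readBin(fout, "integer", n = file.size(fout) / 4L, size = 4L)
  matrix(raw, ncol = 4, byrow = TRUE) + 1L
}

# split every surface edge longer than max_len at its exact midpoint
# (planar splits: the geometry and the enclosed volume are unchanged)
split_long_edges <- function(mesh, max_len) {
  v <- mesh$vertices
  f <- mesh$faces
  repeat {
    nv <- nrow(v)
    ek <- cbind(edge_key(f[, 1], f[, 2], nv), edge_key(f[, 2], f[, 3], nv),
                edge_key(f[, 3], f[, 1], nv))
    len <- cbind(sqrt(rowSums((v[f[, 1], ] - v[f[, 2], ])^2)),
                 sqrt(rowSums((v[f[, 2], ] - v[f[, 3], ])^2)),
                 sqrt(rowSums((v[f[, 3], ] - v[f[, 1], ])^2)))
    long_keys <- unique(as.vector(ek[len > max_len]))
    if (!length(long_keys)) break
    lo <- long_keys %/% (nv + 1)
    hi <- long_keys %% (nv + 1)
    mids <- (v[lo, , drop = FALSE] + v[hi, , drop = FALSE]) / 2
    mid_id <- nv + seq_along(long_keys)
    v <- rbind(v, mids)
    midx <- matrix(match(ek, long_keys), ncol = 3) # NA when edge not split
    newf <- vector("list", nrow(f))
    for (i in seq_len(nrow(f))) {
      a <- f[i, 1]; b <- f[i, 2]; c_ <- f[i, 3]
      s <- midx[i, ]
      if (all(is.na(s))) {
        newf[[i]] <- c(a, b, c_)
        next
      }
      mab <- if (!is.na(s[1])) mid_id[s[1]] else NA
      mbc <- if (!is.na(s[2])) mid_id[s[2]] else NA
      mca <- if (!is.na(s[3])) mid_id[s[3]] else NA
      n_split <- sum(!is.na(c(mab, mbc, mca)))
      newf[[i]] <-
        if (n_split == 3L) {
          c(a, mab, mca, mab, b, mbc, mca, mbc, c_, mab, mbc, mca)
        } else if (n_split == 2L) {
          if (is.na(mca)) c(mab, b, mbc, a, mab, mbc, a, mbc, c_)
          else if (is.na(mbc)) c(a, mab, mca, mab, b, mca, mca, b, c_)
          else c(a, b, mbc, a, mbc, mca, mca, mbc, c_)
        } else {
          if (!is.na(mab)) c(a, mab, c_, mab, b, c_)
          else if (!is.na(mbc)) c(a, b, mbc, a, mbc, c_)
          else c(a, b, mca, mca, b, c_)
        }
    }
    f <- matrix(unlist(newf), ncol = 3, byrow = TRUE)
  }
  tri_mesh(v, f, mesh$body_id)
}

#' Fill a closed surface mesh with tetrahedra
#'
#' Constrained tetrahedralization retaining every input surface vertex at
#' its exact coordinates: the boundary triangulation is first uniformly
#' refined by exact midpoint edge splits (geometry unchanged) down to the
#' target edge length, interior points are seeded on a body-centred-cubic
#' lattice at the target spacing (with a small deterministic jitter that
#' breaks Delaunay degeneracies), the combined point set is Delaunay
#' tetrahedralized, and tetrahedra whose centroid lies outside the surface
#' (generalized winding number < 1/2) are discarded. All returned elements
#' are positively oriented.
#'
#' @param mesh a watertight, manifold, non-self-intersecting [tri_mesh()].
#' @param target_edge_mm global seed size (mm), default 1.
#' @param min_size_mm minimum element size (mm); interior points closer than
#'   `0.7 * target_edge_mm` to the boundary (but never closer than
#'   `min_size_mm`) are not seeded.
#' @return A linear [tet_mesh()] whose first nodes are the original surface
#'   vertices (`surface_node_map` is the identity on them).
#' @export
fill_volume <- function(mesh, target_edge_mm = 1.0, min_size_mm = 0.1) {
  d <- diagnose(mesh)
  if (!d$watertight || !d$manifold || d$self_intersecting)
    stop_seg2fem("surface is not a watertight, manifold, non-self-intersecting mesh",
                 "seg2fem_meshing_error", diagnostics = d)
  n_orig <- nrow(mesh$vertices)
  surf <- split_long_edges(mesh, 1.5 * target_edge_mm)
  sv <- surf$vertices
  h <- target_edge_mm

  lo <- apply(sv, 2, min)
  hi <- apply(sv, 2, max)
  axes <- lapply(1:3, function(d_) {
    if (hi[d_] - lo[d_] < h) return(mean(c(lo[d_], hi[d_])))
    seq(lo[d_] + h / 2, hi[d_], by = h)
  })
  cubic <- as.matrix(expand.grid(axes[[1]], axes[[2]], axes[[3]]))
  bcc <- sweep(cubic, 2, c(h / 2, h / 2, h / 2), "+")
  cand <- rbind(cubic, bcc)
  keep <- cand[, 1] <= hi[1] & cand[, 2] <= hi[2] & cand[, 3] <= hi[3]
  cand <- cand[keep, , drop = FALSE]
  colnames(cand) <- NULL

  if (nrow(cand)) {
    nn <- .nn_nearest(cand, sv)
    clearance <- max(0.7 * h, min_size_mm)
    cand <- cand[nn$distance > clearance, , drop = FALSE]
  }
  if (nrow(cand)) {
    wn <- .winding_number(cand, sv, surf$faces)
    cand <- cand[wn > 0.5, , drop = FALSE]
  }
  if (nrow(cand)) {
    jit <- with_local_seed(1L, matrix(runif(3 * nrow(cand), -1, 1),
                                      ncol = 3))
    cand <- cand + 0.05 * h * jit
  }

  pts <- rbind(sv, cand)
  simp <- delaunay_tets(pts)
  vols <- tet_volumes(pts, simp)
  flip <- vols < 0
  if (any(flip)) simp[flip, 2:3] <- simp[flip, 3:2, drop = FALSE]
  vols <- abs(vols)
  simp <- simp[vols > 1e-9, , drop = FALSE]

  # tets built purely from interior seed points are inside by construction;
  # only tets touching the boundary need the winding-number test
  n_sv <- nrow(sv)
  touches <- simp[, 1] <= n_sv | simp[, 2] <= n_sv | simp[, 3] <= n_sv |
    simp[, 4] <= n_sv
  keep_tet <- !touches
  if (any(touches)) {
    ts <- which(touches)
    centroids <- (pts[simp[ts, 1], ] + pts[simp[ts, 2], ] +
                  pts[simp[ts, 3], ] + pts[simp[ts, 4], ]) / 4
    wn <- .winding_number(centroids, sv, surf$faces)
    keep_tet[ts] <- wn > 0.5
  }
  simp <- simp[keep_tet, , drop = FALSE]
  if (!nrow(simp))
    stop_seg2fem("no interior tetrahedra survived filtering",
                 "seg2fem_meshing_error")

  used <- sort(unique(as.vector(simp)))
  n_surf <- nrow(sv)
  if (!all(seq_len(n_surf) %in% used))
    stop_seg2fem("surface vertices lost during tetrahedralization",
                 "seg2fem_meshing_error")
  remap <- integer(nrow(pts))
  remap[used] <- seq_along(used)
  tet_mesh(pts[used, , drop = FALSE], matrix(remap[simp], ncol = 4),
           order = "linear", surface_node_map = seq_len(n_orig),
           surface = surf)
}

#' Convert a linear tet mesh to quadratic (10-node) elements
#'
#' Each unique edge of the tetrahedral complex receives exactly one midpoint
#' node; elements are extended to the 10-node layout (corners, then edge
#' midpoints in the order 1-2, 2-3, 3-1, 1-4, 2-4, 3-4). Corner node
#' coordinates are unchanged.
#'
#' @param tm a linear [tet_mesh()].
#' @return A quadratic [tet_mesh()].
#' @export
to_quadratic <- function(tm) {
  if (tm$order != "linear")
    stop_seg2fem("mesh is already quadratic", "seg2fem_spec_error")
  el <- tm$elements
  nv <- nrow(tm$nodes)
  epairs <- list(c(1, 2), c(2, 3), c(3, 1), c(1, 4), c(2, 4), c(3, 4))
  keys <- sapply(epairs, function(p) edge_key(el[, p[1]], el[, p[2]], nv))
  keys <- matrix(keys, nrow = nrow(el))
  uk <- unique(as.vector(keys))
  a <- uk %/% (nv + 1)
  b <- uk %% (nv + 1)
  mids <- (tm$nodes[a, , drop = FALSE] + tm$nodes[b, , drop = FALSE]) / 2
  mid_ids <- nv + seq_along(uk)
  midcol <- matrix(mid_ids[match(as.vector(keys), uk)], nrow = nrow(el))
  tet_mesh(rbind(tm$nodes, mids), cbind(el, midcol), order = "quadratic",
           surface_node_map = tm$surface_node_map, surface = tm$surface)
}

#' Aspect ratio of one tetrahedron
#'
#' The mesh-quality metric used throughout the cohort statistics: the ratio
#' of the longest to the shortest of the six edge lengths (1 for a regular
#' tetrahedron; > 5 marks a poor element).
#'
#' @param corner_coords 4 x 3 matrix of corner coordinates.
#' @return Aspect ratio >= 1.
#' @export
aspect_ratio <- function(corner_coords) {
  p <- as_matrix3(corner_coords, "corners")
  if (nrow(p) != 4) stop_seg2fem("need 4 corner points", "seg2fem_spec_error")
  pairs <- utils::combn(4, 2)
  len <- sqrt(rowSums((p[pairs[1, ], , drop = FALSE] -
                       p[pairs[2, ], , drop = FALSE])^2))
  if (any(len == 0))
    stop_seg2fem("degenerate element: zero-length edge", "seg2fem_degenerate_error")
  max(len) / min(len)
}

#' Aspect ratios of all elements
#'
#' Computed on corner nodes; for quadratic elements with exact edge
#' midpoints this coincides with the full-edge definition.
#'
#' @param tm a [tet_mesh()].
#' @return Numeric vector of per-element aspect ratios.
#' @export
aspect_ratios <- function(tm) {
  el <- tm$elements[, 1:4, drop = FALSE]
  v <- tm$nodes
  pairs <- list(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
  len <- sapply(pairs, function(p)
    sqrt(rowSums((v[el[, p[1]], , drop = FALSE] -
                  v[el[, p[2]], , drop = FALSE])^2)))
  len <- matrix(len, nrow = nrow(el))
  if (any(len == 0))
    stop_seg2fem("degenerate element: zero-length edge", "seg2fem_degenerate_error")
  apply(len, 1, max) / apply(len, 1, min)
}

#' Percentage of poor-quality elements
#'
#' Share (in percent) of elements whose aspect ratio exceeds the threshold;
#' the poor-element criterion is a ratio > 5, and meshes are conventionally
#' aimed at less than 10% poor elements.
#'
#' @param tm a non-empty [tet_mesh()].
#' @param threshold aspect-ratio cutoff, default 5.
#' @return Percentage in \[0, 100\].
#' @export
poor_quality_fraction <- function(tm, threshold = 5) {
  if (nrow(tm$elements) == 0)
    stop_seg2fem("empty mesh", "seg2fem_spec_error")
  ar <- aspect_ratios(tm)
  100 * sum(ar > threshold) / length(ar)
}

#' Structured tetrahedral block (test fixture)
#'
#' A box `[0, L1] x [0, L2] x [0, L3]` meshed by splitting each cube of an
#' `edge_mm` grid into six tetrahedra. Used for solver verification
#' fixtures (bars, beams, patches).
#'
#' @param lengths_mm box edge lengths (3-vector, mm).
#' @param edge_mm grid spacing (mm).
#' @return A linear [tet_mesh()] (no surface attached).
#' @export
tet_block <- function(lengths_mm, edge_mm = 1) {
  n <- pmax(round(lengths_mm / edge_mm), 1L)
  xs <- lapply(1:3, function(d) seq(0, lengths_mm[d], length.out = n[d] + 1))
  nodes <- as.matrix(expand.grid(xs[[1]], xs[[2]], xs[[3]]))
  colnames(nodes) <- NULL
  nid <- function(i, j, k) i + (n[1] + 1) * ((j - 1) + (n[2] + 1) * (k - 1))
  tets6 <- rbind(c(1, 6, 2, 7), c(1, 2, 3, 7), c(1, 3, 4, 7),
                 c(1, 4, 8, 7), c(1, 8, 5, 7), c(1, 5, 6, 7))
  el <- vector("list", prod(n))
  idx <- 0L
  for (k in seq_len(n[3])) for (j in seq_len(n[2])) for (i in seq_len(n[1])) {
    corn <- c(nid(i, j, k), nid(i + 1, j, k), nid(i + 1, j + 1, k),
              nid(i, j + 1, k), nid(i, j, k + 1), nid(i + 1, j, k + 1),
              nid(i + 1, j + 1, k + 1), nid(i, j + 1, k + 1))
    idx <- idx + 1L
    el[[idx]] <- matrix(corn[tets6], ncol = 4)
  }
  el <- do.call(rbind, el)
  vols <- tet_volumes(nodes, el)
  flip <- vols < 0
  if (any(flip)) el[flip, 2:3] <- el[flip, 3:2, drop = FALSE]
  tet_mesh(nodes, el, order = "linear")
}

#' Export a tet mesh (with optional results) as ASCII VTU
#'
#' @param tm a [tet_mesh()].
#' @param path output path.
#' @param point_data named list of per-node vectors/matrices.
#' @param cell_data named list of per-element vectors.
#' @return `path`, invisibly.
#' @export
write_vtu <- function(tm, path, point_data = list(), cell_data = list()) {
  nn <- nrow(tm$nodes)
  ne <- nrow(tm$elements)
  npe <- ncol(tm$elements)
  vtk_type <- if (npe == 4) 10L else 24L # tetra / quadratic tetra
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w('<?xml version="1.0"?>')
  w('<VTKFile type="UnstructuredGrid" version="0.1" byte_order="LittleEndian">')
  w('  <UnstructuredGrid>')
  w('    <Piece NumberOfPoints="%d" NumberOfCells="%d">', nn, ne)
  w('      <Points>')
  w('        <DataArray type="Float64" NumberOfComponents="3" format="ascii">')
  writeLines(sprintf("%.10g %.10g %.10g", tm$nodes[, 1], tm$nodes[, 2],
                     tm$nodes[, 3]), con)
  w('        </DataArray>')
  w('      </Points>')
  w('      <Cells>')
  w('        <DataArray type="Int32" Name="connectivity" format="ascii">')
  writeLines(apply(tm$elements - 1L, 1, paste, collapse = " "), con)
  w('        </DataArray>')
  w('        <DataArray type="Int32" Name="offsets" format="ascii">')
  writeLines(as.character(seq_len(ne) * npe), con)
  w('        </DataArray>')
  w('        <DataArray type="UInt8" Name="types" format="ascii">')
  writeLines(as.character(rep(vtk_type, ne)), con)
  w('        </DataArray>')
  w('      </Cells>')
  if (length(point_data)) {
    w('      <PointData>')
    for (nm in names(point_data)) {
      val <- point_data[[nm]]
      ncomp <- if (is.matrix(val)) ncol(val) else 1L
      w('        <DataArray type="Float64" Name="%s" NumberOfComponents="%d" format="ascii">',
        nm, ncomp)
      if (is.matrix(val))
        writeLines(apply(val, 1, function(r) paste(sprintf("%.10g", r),
                                                   collapse = " ")), con)
      else writeLines(sprintf("%.10g", val), con)
      w('        </DataArray>')
    }
    w('      </PointData>')
  }
  if (length(cell_data)) {
    w('      <CellData>')
    for (nm in names(cell_data)) {
      w('        <DataArray type="Float64" Name="%s" format="ascii">', nm)
      writeLines(sprintf("%.10g", cell_data[[nm]]), con)
      w('        </DataArray>')
    }
    w('      </CellData>')
  }
  w('    </Piece>')
  w('  </UnstructuredGrid>')
  w('</VTKFile>')
  invisible(path)
}
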