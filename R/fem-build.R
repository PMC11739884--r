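#' Linear elastic isotropic material
#'
#' @param youngs_modulus Young's modulus in MPa (> 0). With model space in
#'   mm and forces in N, stresses come out in MPa.
#' @param poisson_ratio Poisson's ratio in \[0, 0.5); 0 is admitted for
#'   closed-form verification fixtures.
#' @return An object of class `fem_material`.
#' @export
material <- function(youngs_modulus, poisson_ratio) {
  if (youngs_modulus <= 0)
    stop_seg2fem("youngs_modulus must be > 0", "seg2fem_spec_error")
  if (poisson_ratio < 0 || poisson_ratio >= 0.5)
    stop_seg2fem("poisson_ratio must lie in [0, 0.5)", "seg2fem_spec_error")
  structure(list(youngs_modulus = youngs_modulus,
                 poisson_ratio = poisson_ratio),
            class = "fem_material")
}

#' Default material table (configurable placeholders, not ground truth)
#'
#' Literature-informed defaults: stiff cortical-scale bone for vertebrae
#' (E = 10000 MPa, nu = 0.3) and a soft isotropic disc
#' (E = 10 MPa, nu = 0.45).
#' @return Named list with entries `vertebra` and `ivd`.
#' @export
default_materials <- function() {
  list(vertebra = material(10000, 0.3), ivd = material(10, 0.45))
}

#' Match interface surface vertices to volume nodes by rounded coordinates
#'
#' Volume meshing renumbers nodes; the interface node sets are therefore
#' recovered by comparing coordinates rounded to `decimals` digits (default
#' micrometre precision). Every interface vertex must find exactly one
#' volume node, otherwise the vertex-retention contract of the mesher was
#' broken and a mapping error naming the vertex is raised.
#'
#' @param surface the [tri_mesh()] the volume was filled from.
#' @param vertex_ids interface vertex indices into `surface`.
#' @param tm the [tet_mesh()].
#' @param decimals rounding precision in digits (default 3).
#' @return Integer set of volume node ids (same order as `vertex_ids`).
#' @export
map_surface_to_volume_nodes <- function(surface, vertex_ids, tm, decimals = 3) {
  if (!length(vertex_ids)) return(integer(0))
  rkey <- function(m) paste(round(m[, 1], decimals), round(m[, 2], decimals),
                            round(m[, 3], decimals))
  node_keys <- rkey(tm$nodes)
  want <- rkey(surface$vertices[vertex_ids, , drop = FALSE])
  hit <- match(want, node_keys)
  if (anyNA(hit))
    stop_seg2fem(sprintf("no volume node matches surface vertex %d at %d decimals",
                         vertex_ids[which(is.na(hit))[1]], decimals),
                 "seg2fem_mapping_error")
  hit
}

#' Reference node of a node set
#'
#' The member of `nset` closest (Euclidean) to the centroid of the set's
#' coordinates; ties broken toward the lowest node id.
#'
#' @param tm a [tet_mesh()].
#' @param nset non-empty integer set of node ids.
#' @return A single node id.
#' @export
reference_node <- function(tm, nset) {
  nset <- sort(unique(as.integer(nset)))
  if (!length(nset)) stop_seg2fem("empty node set", "seg2fem_spec_error")
  p <- tm$nodes[nset, , drop = FALSE]
  ctr <- colMeans(p)
  d2 <- rowSums(sweep(p, 2, ctr)^2)
  nset[which.min(d2)] # which.min returns the first (lowest id) minimum
}

#' Assemble a simulation-ready FE model
#'
#' Populates the standalone-body load case: a kinematic coupling tying the
#' superior interface node set rigidly to its reference node, the inferior
#' node set restrained in all degrees of freedom (every node of the set is
#' fully fixed, which also restrains the surface's rigid rotations), and a
#' flexion moment applied at the superior reference node. Model space is
#' mm, so the moment is stored in N·mm.
#'
#' @param tm a [tet_mesh()] (typically quadratic).
#' @param iface the body's [interface_map()] (indices into `tm$surface`).
#' @param material a [material()].
#' @param moment_nm flexion moment magnitude in N·m (default 7.5).
#' @param flexion_axis unit vector of the moment axis (default the world
#'   x axis, orthogonal to the stacking direction and the
#'   anterior-posterior axis).
#' @param body_name name used for set naming in the `.inp` export.
#' @param decimals coordinate-rounding precision for node matching.
#' @return An object of class `fe_model`.
#' @export
build_model <- function(tm, iface, material, moment_nm = 7.5,
                        flexion_axis = c(1, 0, 0), body_name = NULL,
                        decimals = 3) {
  if (is.null(tm$surface))
    stop_seg2fem("tet mesh carries no boundary surface", "seg2fem_spec_error")
  if (!length(iface$superior) || !length(iface$inferior))
    stop_seg2fem("zero-measure interface: superior and inferior sets must be non-empty",
                 "seg2fem_model_error")
  nset_sup <- sort(map_surface_to_volume_nodes(tm$surface, iface$superior, tm,
                                               decimals))
  nset_inf <- sort(map_surface_to_volume_nodes(tm$surface, iface$inferior, tm,
                                               decimals))
  if (length(intersect(nset_sup, nset_inf)))
    stop_seg2fem("superior and inferior node sets overlap", "seg2fem_model_error")
  flexion_axis <- flexion_axis / sqrt(sum(flexion_axis^2))
  body_name <- body_name %||%
    (if (!is.null(tm$surface$body_id)) label_name(tm$surface$body_id) else "BODY")
  structure(list(mesh = tm,
                 nset_superior = nset_sup, nset_inferior = nset_inf,
                 ref_superior = reference_node(tm, nset_sup),
                 ref_inferior = reference_node(tm, nset_inf),
                 coupling = list(ref = reference_node(tm, nset_sup),
                                 set = nset_sup),
                 bc = list(set = nset_inf, dofs = 1:3),
                 load = list(node = reference_node(tm, nset_sup),
                             moment = moment_nm * 1e3 * flexion_axis),
                 material = material, analysis = "static",
                 body_name = toupper(body_name)),
            class = "fe_model")
}

#' @export
#' @method print fe_model
print.fe_model <- function(x, ...) {
  cat(sprintf("fe_model %s: %d nodes, %d %s elements\n", x$body_name,
              nrow(x$mesh$nodes), nrow(x$mesh$elements), x$mesh$order))
  cat(sprintf("  nset sup/inf: %d / %d nodes; moment %.3g N·mm about (%.2g, %.2g, %.2g)\n",
              length(x$nset_superior), length(x$nset_inferior),
              sqrt(sum(x$load$moment^2)), x$load$moment[1] , x$load$moment[2],
              x$load$moment[3]))
  invisible(x)
}

# keyword-format data lines: at most 16 entries per line
inp_wrap16 <- function(ids) {
  chunks <- split(ids, ceiling(seq_along(ids) / 16))
  vapply(chunks, function(ch) paste(ch, collapse = ", "), character(1))
}

#' Write / read an FE model in the ABAQUS/CalculiX `.inp` keyword dialect
#'
#' Emits node and element blocks (C3D4 or C3D10), named node sets (body
#' name + `_SUP` / `_INF` / `_REF_SUP` / `_REF_INF`), the kinematic coupling
#' block, the elastic material, and a static step with the boundary block
#' (all translations of the inferior set) and the concentrated moment load
#' (rotational components 4-6 at the superior reference node). Data lines
#' follow the 16-entries-per-line continuation rule. `read_inp()` inverts
#' `write_inp()`; unknown keywords raise a parse error with the line number.
#'
#' @param model an [build_model()] result.
#' @param path file path.
#' @return `path` invisibly (writer); an `fe_model` (reader; the boundary
#'   surface is not part of the format and comes back NULL).
#' @export
write_inp <- function(model, path) {
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  m <- model$mesh
  nm <- model$body_name
  etype <- if (m$order == "quadratic") "C3D10" else "C3D4"
  w("*HEADING")
  w("seg2fem model %s", nm)
  w("*NODE")
  writeLines(sprintf("%d, %.10e, %.10e, %.10e", seq_len(nrow(m$nodes)),
                     m$nodes[, 1], m$nodes[, 2], m$nodes[, 3]), con)
  w("*ELEMENT, TYPE=%s, ELSET=%s_ALL", etype, nm)
  writeLines(vapply(seq_len(nrow(m$elements)), function(e)
    paste(c(e, m$elements[e, ]), collapse = ", "), character(1)), con)
  w("*NSET, NSET=%s_SUP", nm)
  writeLines(inp_wrap16(model$nset_superior), con)
  w("*NSET, NSET=%s_INF", nm)
  writeLines(inp_wrap16(model$nset_inferior), con)
  w("*NSET, NSET=%s_REF_SUP", nm)
  w("%d", model$ref_superior)
  w("*NSET, NSET=%s_REF_INF", nm)
  w("%d", model$ref_inferior)
  w("*COUPLING, CONSTRAINT NAME=%s_COUP, REF NODE=%d, SURFACE=%s_SUP",
    nm, model$coupling$ref, nm)
  w("*KINEMATIC")
  w("*MATERIAL, NAME=%s_MAT", nm)
  w("*ELASTIC")
  w("%.10e, %.10e", model$material$youngs_modulus, model$material$poisson_ratio)
  w("*SOLID SECTION, ELSET=%s_ALL, MATERIAL=%s_MAT", nm, nm)
  w("*STEP")
  w("*STATIC")
  w("*BOUNDARY")
  w("%s_INF, %d, %d", nm, min(model$bc$dofs), max(model$bc$dofs))
  w("*CLOAD")
  for (d in 1:3)
    if (model$load$moment[d] != 0)
      w("%d, %d, %.10e", model$load$node, 3L + d, model$load$moment[d])
  w("*END STEP")
  invisible(path)
}

#' @rdname write_inp
#' @export
read_inp <- function(path) {
  lines <- readLines(path)
  nodes <- NULL; elems <- NULL; etype <- NULL
  nsets <- list(); cur <- NULL
  mat_vals <- c(NA_real_, NA_real_)
  coupling_ref <- NA_integer_; coupling_surf <- NULL
  bc_set <- NULL; bc_dofs <- NULL
  cload <- list()
  mode <- ""
  node_buf <- list(); elem_buf <- list()
  for (li in seq_along(lines)) {
    line <- trimws(lines[li])
    if (!nzchar(line) || startsWith(line, "**")) next
    if (startsWith(line, "*")) {
      kw <- toupper(sub(",.*$", "", line))
      mode <- ""
      if (kw == "*HEADING") mode <- "heading"
      else if (kw == "*NODE") mode <- "node"
      else if (kw == "*ELEMENT") {
        mode <- "element"
        etype <- sub(".*TYPE=([^, ]+).*", "\\1", toupper(line))
      } else if (kw == "*NSET") {
        cur <- sub(".*NSET=([^, ]+).*", "\\1", toupper(line))
        nsets[[cur]] <- integer(0)
        mode <- "nset"
      } else if (kw == "*COUPLING") {
        coupling_ref <- as.integer(sub(".*REF NODE=([0-9]+).*", "\\1",
                                       toupper(line)))
        coupling_surf <- sub(".*SURFACE=([^, ]+).*", "\\1", toupper(line))
      } else if (kw == "*KINEMATIC" || kw == "*MATERIAL" ||
                 kw == "*SOLID SECTION" || kw == "*STEP" || kw == "*STATIC" ||
                 kw == "*END STEP") {
        # structural keywords without data we need to capture
      } else if (kw == "*ELASTIC") mode <- "elastic"
      else if (kw == "*BOUNDARY") mode <- "boundary"
      else if (kw == "*CLOAD") mode <- "cload"
      else stop_seg2fem(sprintf("unknown keyword at line %d: %s", li, line),
                        "seg2fem_parse_error")
      next
    }
    parts <- trimws(strsplit(line, ",")[[1]])
    if (mode == "node") {
      node_buf[[length(node_buf) + 1L]] <- as.numeric(parts)
    } else if (mode == "element") {
      elem_buf[[length(elem_buf) + 1L]] <- as.integer(parts)
    } else if (mode == "nset") {
      nsets[[cur]] <- c(nsets[[cur]], as.integer(parts))
    } else if (mode == "elastic") {
      mat_vals <- as.numeric(parts[1:2])
    } else if (mode == "boundary") {
      bc_set <- parts[1]
      bc_dofs <- as.integer(parts[2]):as.integer(parts[3])
    } else if (mode == "cload") {
      cload[[length(cload) + 1L]] <- as.numeric(parts)
    } else if (mode != "heading") {
      stop_seg2fem(sprintf("unexpected data at line %d", li),
                   "seg2fem_parse_error")
    }
  }
  nodes_m <- do.call(rbind, node_buf)
  nodes <- nodes_m[order(nodes_m[, 1]), 2:4, drop = FALSE]
  elems_m <- do.call(rbind, elem_buf)
  elems <- elems_m[order(elems_m[, 1]), -1, drop = FALSE]
  order_ <- if (identical(etype, "C3D10")) "quadratic" else "linear"
  nm <- sub("_SUP$", "", coupling_surf)
  moment <- c(0, 0, 0)
  load_node <- NA_integer_
  for (cl in cload) {
    load_node <- as.integer(cl[1])
    moment[as.integer(cl[2]) - 3L] <- cl[3]
  }
  tm <- tet_mesh(nodes, elems, order = order_)
  structure(list(mesh = tm,
                 nset_superior = sort(nsets[[paste0(nm, "_SUP")]]),
                 nset_inferior = sort(nsets[[paste0(nm, "_INF")]]),
                 ref_superior = nsets[[paste0(nm, "_REF_SUP")]][1],
                 ref_inferior = nsets[[paste0(nm, "_REF_INF")]][1],
                 coupling = list(ref = coupling_ref,
                                 set = sort(nsets[[paste0(nm, "_SUP")]])),
                 bc = list(set = sort(nsets[[paste0(nm, "_INF")]]),
                           dofs = bc_dofs),
                 load = list(node = load_node, moment = moment),
                 material = material(mat_vals[1], mat_vals[2]),
                 analysis = "static", body_name = nm),
            class = "fe_model")
}
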