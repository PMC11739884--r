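#' Pipeline configuration
#'
#' @param min_voxels small-component removal threshold (linked voxels).
#' @param min_body_voxels bodies below this voxel count are classified as
#'   `small_segmentation_volume` failures.
#' @param connectivity voxel connectivity for component analysis (26 or 6).
#' @param smoothing a [smoothing_params()]; its interface threshold is
#'   overridden per body by `threshold_fun` when non-NULL.
#' @param threshold_fun function(label) returning the per-level contact
#'   threshold in mm; default [interface_threshold_for_label()].
#' @param target_edge_mm,min_size_mm volume meshing seed sizes (mm).
#' @param quadratic generate 10-node elements?
#' @param materials named list with `vertebra` and `ivd` [material()]s.
#' @param moment_nm,flexion_axis load case of the standalone models.
#' @param axis stacking axis of the volume (superior direction).
#' @param stop_after last stage to execute: `"quality"` (mesh + quality
#'   statistics), `"model"` (+ node sets and `.inp`-ready models) or
#'   `"solve"` (+ static solve).
#' @param outdir optional directory for per-body artifacts (smoothed STL,
#'   `.inp`, VTU, report JSON).
#' @return A config list (class `pipeline_config`).
#' @export
pipeline_config <- function(min_voxels = 4L, min_body_voxels = 200L,
                            connectivity = 26L,
                            smoothing = smoothing_params(),
                            threshold_fun = interface_threshold_for_label,
                            target_edge_mm = 1.0, min_size_mm = 0.1,
                            quadratic = TRUE,
                            materials = default_materials(),
                            moment_nm = 7.5, flexion_axis = c(1, 0, 0),
                            axis = c(0, 0, 1),
                            stop_after = c("solve", "model", "quality"),
                            outdir = NULL) {
  stop_after <- match.arg(stop_after)
  structure(list(min_voxels = min_voxels, min_body_voxels = min_body_voxels,
                 connectivity = connectivity, smoothing = smoothing,
                 threshold_fun = threshold_fun,
                 target_edge_mm = target_edge_mm, min_size_mm = min_size_mm,
                 quadratic = quadratic, materials = materials,
                 moment_nm = moment_nm, flexion_axis = flexion_axis,
                 axis = axis, stop_after = stop_after, outdir = outdir),
            class = "pipeline_config")
}

#' Classify a body failure into the cohort failure categories
#'
#' Deterministic priority order:
#' `disconnected_volumes > small_segmentation_volume > hole >
#' non_manifold_edges > self_intersecting_faces > mapping_error >
#' non_convergence`.
#'
#' @param report a [diagnose()] report or NULL.
#' @param stage stage identifier (informational).
#' @param component_count voxel connected-component count of the body.
#' @param voxel_count body voxel count.
#' @param min_body_voxels small-body threshold.
#' @param cavity does the voxel mask contain an enclosed cavity?
#' @return A failure category string.
#' @export
classify_failure <- function(report = NULL, stage = "unknown",
                             component_count = 1L, voxel_count = Inf,
                             min_body_voxels = 200L, cavity = FALSE) {
  if (component_count > 1L) return("disconnected_volumes")
  if (voxel_count < min_body_voxels) return("small_segmentation_volume")
  if (cavity) return("hole")
  if (!is.null(report)) {
    if (report$n_boundary_edges > 0L || report$n_components > 1L) return("hole")
    if (report$n_nonmanifold_edges > 0L) return("non_manifold_edges")
    if (report$self_intersecting) return("self_intersecting_faces")
  }
  if (identical(stage, "node_sets")) return("mapping_error")
  if (identical(stage, "solve")) return("non_convergence")
  "non_convergence"
}

body_report <- function(body_id, status = "ok", failure_category = "none",
                        n_nodes = NA_integer_, n_elements = NA_integer_,
                        poor_fraction_pct = NA_real_, stage_durations = list()) {
  structure(list(body_id = body_id, status = status,
                 failure_category = failure_category,
                 n_nodes = n_nodes, n_elements = n_elements,
                 poor_fraction_pct = poor_fraction_pct,
                 stage_durations = stage_durations),
            class = "body_report")
}

#' @export
#' @method print body_report
print.body_report <- function(x, ...) {
  cat(sprintf("body %s [%s]%s: %s nodes, %s elements, poor %.3g%%\n",
              x$body_id, label_name(x$body_id),
              if (x$status == "ok") "" else paste0(" FAILED (", x$failure_category, ")"),
              x$n_nodes, x$n_elements, x$poor_fraction_pct))
  invisible(x)
}

# failure category carried by a seg2fem condition, if any
condition_category <- function(e, default) {
  cat <- e$category
  if (!is.null(cat)) return(cat)
  rep <- e$diagnostics
  if (!is.null(rep)) return(classify_failure(rep))
  default
}

#' Run the full pipeline on one subject volume
#'
#' Executes, per labeled body: mask cleanup, surface extraction and repair,
#' smoothing (all vertebrae selectively first, then discs adaptively
#' against the smoothed vertebrae), constrained tetrahedral filling,
#' quadratic conversion, quality statistics and — depending on
#' `stop_after` — node-set construction, model assembly and the static
#' solve. A failure at any stage records its category and the run continues
#' with the remaining bodies.
#'
#' @param volume a [label_volume()] with at least one labeled body.
#' @param config a [pipeline_config()].
#' @return List of `body_report` objects (one per body), with the processed
#'   meshes/models attached as attribute `artifacts`.
#' @export
run_subject <- function(volume, config = pipeline_config()) {
  labs <- labels_present(volume)
  if (!length(labs))
    stop_seg2fem("volume contains no labeled body", "seg2fem_subject_error")
  volume <- remove_small_components(volume, config$min_voxels,
                                    config$connectivity)
  verts <- sort(labs[is_vertebra_label(labs)])
  ivds <- sort(labs[is_ivd_label(labs)])
  reports <- list()
  artifacts <- list()
  timing <- function(expr) {
    t0 <- proc.time()[["elapsed"]]
    val <- force(expr)
    list(val = val, dt = proc.time()[["elapsed"]] - t0)
  }

  # voxel-level screening + raw surfaces for all bodies
  raw <- list()
  screened <- list()
  for (lab in c(verts, ivds)) {
    key <- as.character(lab)
    vx <- sum(volume$grid == lab)
    ncomp <- if (vx > 0) count_components(volume, lab, config$connectivity) else 0L
    cavity <- vx > 0 && has_enclosed_cavity(volume, lab)
    if (vx == 0 || ncomp != 1L || vx < config$min_body_voxels || cavity) {
      cat_ <- classify_failure(component_count = max(ncomp, 1L),
                               voxel_count = vx,
                               min_body_voxels = config$min_body_voxels,
                               cavity = cavity)
      screened[[key]] <- cat_
      next
    }
    res <- tryCatch({
      m <- extract_surface(volume, lab)
      repair_mesh(m)
    }, seg2fem_error = function(e) e)
    if (inherits(res, "error")) {
      screened[[key]] <- condition_category(res, "hole")
    } else {
      d <- diagnose(res)
      if (d$n_components > 1L) {
        screened[[key]] <- "hole"
      } else if (d$self_intersecting) {
        screened[[key]] <- "self_intersecting_faces"
      } else {
        raw[[key]] <- res
      }
    }
  }

  smoothing_for <- function(lab) {
    sp <- config$smoothing
    if (!is.null(config$threshold_fun))
      sp$interface_threshold_mm <- config$threshold_fun(lab)
    sp
  }
  adjacent_ivd_labels <- function(v) ivds[ivds %/% 100L == v | ivds %% 100L == v]
  smoothed_verts <- list()
  smoothed <- list()
  ifaces <- list()

  # vertebrae first (selective smoothing)
  for (lab in verts) {
    key <- as.character(lab)
    if (!is.null(screened[[key]]) || is.null(raw[[key]])) next
    res <- tryCatch({
      adj <- Filter(Negate(is.null), raw[as.character(adjacent_ivd_labels(lab))])
      timing(smooth_vertebra(raw[[key]], adj, smoothing_for(lab), config$axis))
    }, seg2fem_error = function(e) e)
    if (inherits(res, "error")) {
      screened[[key]] <- condition_category(res, "non_manifold_edges")
    } else {
      smoothed_verts[[key]] <- res$val$mesh
      smoothed[[key]] <- res$val$mesh
      ifaces[[key]] <- res$val$interface
      attr(smoothed[[key]], "t_smooth") <- res$dt
    }
  }

  # discs second (adaptive smoothing against smoothed vertebrae)
  for (lab in ivds) {
    key <- as.character(lab)
    if (!is.null(screened[[key]]) || is.null(raw[[key]])) next
    pair <- ivd_pair(lab)
    proj <- function(l) {
      m <- smoothed_verts[[as.character(l)]]
      if (is.null(m)) return(-Inf)
      mean(m$vertices %*% config$axis)
    }
    above <- if (proj(pair[1]) >= proj(pair[2])) pair[1] else pair[2]
    below <- setdiff(pair, above)
    res <- tryCatch({
      timing(smooth_ivd_adaptive(raw[[key]],
                                 smoothed_verts[[as.character(above)]],
                                 smoothed_verts[[as.character(below)]],
                                 smoothing_for(lab), config$axis))
    }, seg2fem_error = function(e) e)
    if (inherits(res, "error")) {
      screened[[key]] <- condition_category(res, "self_intersecting_faces")
    } else {
      smoothed[[key]] <- res$val$mesh
      ifaces[[key]] <- res$val$interface
      attr(smoothed[[key]], "t_smooth") <- res$dt
    }
  }

  # meshing, model building, solving
  for (lab in c(verts, ivds)) {
    key <- as.character(lab)
    if (!is.null(screened[[key]])) {
      reports[[key]] <- body_report(lab, status = "failed",
                                    failure_category = screened[[key]])
      next
    }
    mesh <- smoothed[[key]]
    durations <- list(smooth = attr(mesh, "t_smooth") %||% NA_real_)
    step <- tryCatch({
      tmr <- timing({
        tm <- fill_volume(mesh, config$target_edge_mm, config$min_size_mm)
        if (config$quadratic) tm <- to_quadratic(tm)
        tm
      })
      durations$mesh <- tmr$dt
      tm <- tmr$val
      poor <- poor_quality_fraction(tm)
      rep_ <- body_report(lab, status = "ok",
                          n_nodes = nrow(tm$nodes),
                          n_elements = nrow(tm$elements),
                          poor_fraction_pct = poor,
                          stage_durations = durations)
      art <- list(mesh = mesh, tet = tm, interface = ifaces[[key]])
      if (config$stop_after %in% c("model", "solve")) {
        iface <- ifaces[[key]]
        if (length(iface$superior) && length(iface$inferior)) {
          mat <- if (is_ivd_label(lab)) config$materials$ivd
                 else config$materials$vertebra
          mdl <- timing(build_model(tm, iface, mat, config$moment_nm,
                                    config$flexion_axis))
          rep_$stage_durations$model <- mdl$dt
          art$model <- mdl$val
          if (config$stop_after == "solve") {
            sol <- timing(solve_static(mdl$val))
            rep_$stage_durations$solve <- sol$dt
            art$result <- sol$val
            if (!sol$val$converged) {
              rep_$status <- "failed"
              rep_$failure_category <- "non_convergence"
            }
          }
        }
      }
      list(report = rep_, art = art)
    }, seg2fem_error = function(e) e)
    if (inherits(step, "error")) {
      cat_ <- if (inherits(step, "seg2fem_mapping_error")) "mapping_error"
              else condition_category(step, "self_intersecting_faces")
      reports[[key]] <- body_report(lab, status = "failed",
                                    failure_category = cat_,
                                    stage_durations = durations)
    } else {
      reports[[key]] <- step$report
      artifacts[[key]] <- step$art
    }
  }

  if (!is.null(config$outdir)) write_subject_outputs(artifacts, config$outdir)
  out <- reports[as.character(c(verts, ivds))]
  attr(out, "artifacts") <- artifacts
  out
}

write_subject_outputs <- function(artifacts, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  for (key in names(artifacts)) {
    art <- artifacts[[key]]
    nm <- label_name(as.integer(key))
    write_stl(art$mesh, file.path(outdir, paste0(nm, "_smoothed.stl")))
    if (!is.null(art$model))
      write_inp(art$model, file.path(outdir, paste0(nm, ".inp")))
    if (!is.null(art$result) && art$result$converged)
      export_results(art$model, art$result,
                     vtu_path = file.path(outdir, paste0(nm, ".vtu")),
                     json_path = file.path(outdir, paste0(nm, "_summary.json")))
  }
  invisible(NULL)
}

#' Aggregate body reports into cohort statistics
#'
#' Label-wise mean poor-quality fractions over successfully meshed models
#' (failed models are excluded from the means), failure tallies by
#' category, and the overall share of successful models under the 5% and
#' 10% poor-element marks.
#'
#' @param reports list of `body_report`s, e.g. concatenated over subjects.
#' @return An object of class `cohort_summary`: data frame `per_label`
#'   (label, n_ok, n_failed, mean_poor_pct), `failure_tally`, `share_under_5pct`,
#'   `share_under_10pct`, counts.
#' @export
summarize_cohort <- function(reports) {
  if (!length(reports)) stop_seg2fem("no reports", "seg2fem_spec_error")
  df <- data.frame(
    label = vapply(reports, function(r) as.integer(r$body_id), integer(1)),
    status = vapply(reports, function(r) r$status, character(1)),
    category = vapply(reports, function(r) r$failure_category, character(1)),
    poor = vapply(reports, function(r) as.numeric(r$poor_fraction_pct),
                  numeric(1)))
  ok <- df[df$status == "ok", , drop = FALSE]
  labs <- sort(unique(df$label))
  per_label <- data.frame(
    label = labs,
    name = label_name(labs),
    n_ok = vapply(labs, function(l) sum(ok$label == l), integer(1)),
    n_failed = vapply(labs, function(l)
      sum(df$label == l & df$status == "failed"), integer(1)),
    mean_poor_pct = vapply(labs, function(l) {
      v <- ok$poor[ok$label == l]
      if (length(v)) mean(v) else NA_real_
    }, numeric(1)))
  cats <- c("small_segmentation_volume", "disconnected_volumes", "hole",
            "non_manifold_edges", "self_intersecting_faces", "mapping_error",
            "non_convergence")
  tally <- vapply(cats, function(cc) sum(df$category == cc), integer(1))
  structure(list(per_label = per_label,
                 failure_tally = tally,
                 n_attempted = nrow(df), n_ok = nrow(ok),
                 n_failed = nrow(df) - nrow(ok),
                 share_under_5pct = if (nrow(ok)) 100 * mean(ok$poor < 5) else NA_real_,
                 share_under_10pct = if (nrow(ok)) 100 * mean(ok$poor < 10) else NA_real_),
            class = "cohort_summary")
}

#' @export
#' @method print cohort_summary
print.cohort_summary <- function(x, ...) {
  cat(sprintf("cohort: %d attempted, %d ok, %d failed\n", x$n_attempted,
              x$n_ok, x$n_failed))
  cat(sprintf("  models with < 5%% poor elements: %.1f%%; < 10%%: %.1f%%\n",
              x$share_under_5pct, x$share_under_10pct))
  print(x$per_label, row.names = FALSE)
  if (any(x$failure_tally > 0)) {
    cat("  failures:\n")
    for (nm in names(x$failure_tally))
      if (x$failure_tally[[nm]] > 0)
        cat(sprintf("    %s: %d\n", nm, x$failure_tally[[nm]]))
  }
  invisible(x)
}

#' Write a cohort summary as JSON and CSV
#'
#' @param summary a [summarize_cohort()] result.
#' @param json_path,csv_path output paths (NULL to skip).
#' @return Invisibly, `summary`.
#' @export
write_cohort_summary <- function(summary, json_path = NULL, csv_path = NULL) {
  if (!is.null(csv_path))
    utils::write.csv(summary$per_label, csv_path, row.names = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(
      list(per_label = summary$per_label,
           failure_tally = as.list(summary$failure_tally),
           n_attempted = summary$n_attempted, n_ok = summary$n_ok,
           n_failed = summary$n_failed,
           share_under_5pct = summary$share_under_5pct,
           share_under_10pct = summary$share_under_10pct),
      json_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}
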