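#' Specification of a synthetic vertebra/disc phantom
#'
#' Describes a stack of `n_levels` vertebral bodies with intervertebral
#' discs between consecutive bodies, voxelized at an MRI-like anisotropic
#' resolution (1 x 1 mm in-plane, thicker slices). Vertebral bodies are
#' superellipse-cylinders with a mild waist and an optional posterior lobe
#' standing in for the posterior processes; discs are flatter blobs with a
#' mild bulge. `jitter` randomly perturbs per-body shape scale and center
#' (relative amplitude), so distinct seeds yield distinct subjects.
#'
#' @param n_levels number of vertebrae (>= 1); `n_levels - 1` discs are
#'   generated between them.
#' @param body_radius_mm lateral semi-axis of the vertebral body (mm).
#' @param body_height_mm vertebral body height (mm).
#' @param disc_height_mm disc height (mm); must hold at least one slice.
#' @param spacing_mm voxel spacing (in-plane, in-plane, slice) in mm.
#' @param jitter relative shape perturbation amplitude in \[0, 0.3\].
#' @param seed integer RNG seed; identical spec + seed is bit-reproducible.
#' @param base_label label of the topmost vertebra (vertebra labels must
#'   stay within 4..25).
#' @param posterior_lobe add the posterior lobe to vertebrae?
#' @param defects list of `list(body = <label>, kind = <defect kind>)`
#'   entries applied by [generate_phantom()] via [inject_defect()].
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(n_levels = 3L, body_radius_mm = 8, body_height_mm = 12,
                         disc_height_mm = 4.5, spacing_mm = c(1, 1, 3),
                         jitter = 0.1, seed = 1L, base_label = 10L,
                         posterior_lobe = TRUE, defects = list()) {
  if (n_levels < 1)
    stop_seg2fem("n_levels must be >= 1", "seg2fem_spec_error")
  if (body_radius_mm <= 0 || body_height_mm <= 0 || disc_height_mm <= 0)
    stop_seg2fem("phantom dimensions must be positive", "seg2fem_spec_error")
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) != 3 || any(spacing_mm <= 0))
    stop_seg2fem("spacing_mm must be 3 positive numbers", "seg2fem_spec_error")
  if (jitter < 0 || jitter > 0.3)
    stop_seg2fem("jitter must lie in [0, 0.3]", "seg2fem_spec_error")
  if (base_label < 4 || base_label + n_levels - 1 > 25)
    stop_seg2fem("vertebra labels must lie in 4..25", "seg2fem_spec_error")
  # a body thinner than one slice would vanish / merge neighbours
  if (body_height_mm * (1 - jitter) < spacing_mm[3] ||
      (n_levels > 1 && disc_height_mm * (1 - jitter) < spacing_mm[3]))
    stop_seg2fem("bodies thinner than one slice would overlap at the requested heights",
                 "seg2fem_spec_error")
  structure(list(n_levels = as.integer(n_levels),
                 body_radius_mm = body_radius_mm,
                 body_height_mm = body_height_mm,
                 disc_height_mm = disc_height_mm,
                 spacing_mm = spacing_mm, jitter = jitter,
                 seed = as.integer(seed), base_label = as.integer(base_label),
                 posterior_lobe = isTRUE(posterior_lobe), defects = defects),
            class = "phantom_spec")
}

# superellipse membership |x/a|^p + |y/b|^p <= 1 for a grid of points
superellipse_mask <- function(xs, ys, cx, cy, a, b, p) {
  u <- abs(outer(xs - cx, rep(1, length(ys))) / a)^p
  v <- abs(outer(rep(1, length(xs)), ys - cy) / b)^p
  u + v <= 1
}

#' Generate a synthetic labeled vertebra/disc stack
#'
#' Voxelizes the phantom described by `spec` into a [label_volume()]. Bodies
#' are stacked along z with vertebrae and discs in direct voxel contact, so
#' extracted surfaces of adjacent bodies coincide at their interface, as in
#' segmentation masks of real spines. With a thick slice spacing the surface
#' carries the characteristic stair-step artifact.
#'
#' @param spec a [phantom_spec()].
#' @return A [label_volume()] with the spec attached as attribute `spec`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  n <- spec$n_levels
  sp <- spec$spacing_mm
  a0 <- spec$body_radius_mm
  b0 <- 0.8 * a0

  n_bodies <- 2L * n - 1L
  with_local_seed(spec$seed, {
    jit <- matrix(runif(6L * n_bodies, -1, 1), ncol = 6L)
  })
  j <- spec$jitter

  # per-body: label, kind, semi-axes, height, center offset
  bodies <- vector("list", n_bodies)
  z0 <- 2 * sp[3]
  for (i in seq_len(n_bodies)) {
    vert <- i %% 2L == 1L
    lvl <- (i + 1L) %/% 2L
    label <- if (vert) spec$base_label + lvl - 1L
             else ivd_label_for(spec$base_label + lvl - 1L)
    h0 <- if (vert) spec$body_height_mm else spec$disc_height_mm
    sc <- 1 + j * jit[i, 1:2] * 0.8
    h <- h0 * (1 + j * jit[i, 3] * 0.5)
    ctr <- j * a0 * 0.5 * jit[i, 4:5]
    bodies[[i]] <- list(label = label, vert = vert,
                        a = a0 * sc[1] * if (vert) 1 else 1.05,
                        b = b0 * sc[2] * if (vert) 1 else 1.05,
                        h = h, cx = ctr[1], cy = ctr[2], z0 = z0)
    z0 <- z0 + h
  }
  z_top <- z0

  half_x <- a0 * 1.5 + 2 * sp[1]
  half_y_pos <- b0 * 1.5 + 2 * sp[2]
  half_y_neg <- b0 * 2.6 + 2 * sp[2] # room for the posterior lobe
  nx <- ceiling(2 * half_x / sp[1])
  ny <- ceiling((half_y_pos + half_y_neg) / sp[2])
  nz <- ceiling((z_top + 2 * sp[3]) / sp[3])
  grid <- array(0L, dim = c(nx, ny, nz))

  # voxel centers in world mm (center the stack laterally)
  xs <- (seq_len(nx) - 0.5) * sp[1] - half_x
  ys <- (seq_len(ny) - 0.5) * sp[2] - half_y_neg
  zs <- (seq_len(nz) - 0.5) * sp[3]

  for (bd in bodies) {
    ks <- which(zs >= bd$z0 & zs < bd$z0 + bd$h)
    for (k in ks) {
      t <- (zs[k] - bd$z0) / bd$h
      prof <- if (bd$vert) 1 - 0.12 * sin(pi * t)^2 else 1 + 0.08 * sin(pi * t)^2
      m <- superellipse_mask(xs, ys, bd$cx, bd$cy, bd$a * prof, bd$b * prof, 2.5)
      if (bd$vert && spec$posterior_lobe) {
        la <- 0.5 * bd$a * prof
        lb <- 0.55 * bd$b * prof
        m <- m | superellipse_mask(xs, ys, bd$cx, bd$cy - bd$b * prof - 0.45 * lb,
                                   la, lb, 2)
      }
      sl <- grid[, , k]
      sl[m & sl == 0L] <- bd$label
      grid[, , k] <- sl
    }
  }

  origin <- c(-half_x, -half_y_neg, 0) + sp / 2
  affine <- diag(c(sp, 1))
  affine[1:3, 4] <- origin
  labs <- vapply(bodies, function(b) b$label, integer(1))
  vol <- label_volume(grid, sp, affine = affine,
                      label_names = setNames(label_name(labs), labs))
  for (d in spec$defects)
    vol <- inject_defect(vol, d$body, d$kind)
  attr(vol, "spec") <- spec
  vol
}

#' Inject a segmentation defect into a label volume
#'
#' Adds one of the defect kinds observed in real segmentation masks:
#' \describe{
#'   \item{`small_component`}{an extra 3-voxel island carrying the body's
#'     label, disjoint from the main blob (a partial-volume artifact;
#'     removed again by [remove_small_components()]).}
#'   \item{`disconnected_volume`}{removes one full slice of the body so the
#'     label splits into two components, each larger than 4 voxels.}
#'   \item{`internal_hole`}{carves a small fully enclosed background cavity
#'     inside the body.}
#' }
#' All other labels are untouched.
#'
#' @param vol a [label_volume()].
#' @param body label id of the body to corrupt.
#' @param kind one of `"small_component"`, `"disconnected_volume"`,
#'   `"internal_hole"`.
#' @return The corrupted [label_volume()].
#' @export
inject_defect <- function(vol, body,
                          kind = c("small_component", "disconnected_volume",
                                   "internal_hole")) {
  kind <- match.arg(kind)
  mask <- vol$grid == body
  if (!any(mask))
    stop_seg2fem(sprintf("label %d not present", body), "seg2fem_spec_error")
  idx <- which(mask, arr.ind = TRUE)
  dm <- dim(vol$grid)
  grid <- vol$grid

  if (kind == "small_component") {
    # 3-voxel island along x, at least 2 voxels clear of every body voxel
    mid <- round(colMeans(idx))
    xmax <- max(idx[, 1])
    x0 <- xmax + 3L
    if (x0 + 2L > dm[1])
      stop_seg2fem("no room for island defect", "seg2fem_spec_error")
    ks <- c(x0, x0 + 1L, x0 + 2L)
    if (any(grid[cbind(ks, mid[2], mid[3])] != 0L))
      stop_seg2fem("island site not background", "seg2fem_spec_error")
    grid[cbind(ks, mid[2], mid[3])] <- as.integer(body)
  } else if (kind == "disconnected_volume") {
    kk <- sort(unique(idx[, 3]))
    if (length(kk) < 3)
      stop_seg2fem("body too thin to disconnect", "seg2fem_spec_error")
    kcut <- kk[ceiling(length(kk) / 2)]
    sl <- grid[, , kcut]
    sl[sl == body] <- 0L
    grid[, , kcut] <- sl
  } else { # internal_hole
    # carve a 7-voxel cross around a deep-interior voxel near the centroid
    ctr <- round(colMeans(idx))
    deep <- function(p) {
      if (any(p < 3L) || any(p > dm - 2L)) return(FALSE)
      all(vol$grid[(p[1] - 2):(p[1] + 2), (p[2] - 2):(p[2] + 2),
                   max(p[3] - 1, 1):min(p[3] + 1, dm[3])] == body)
    }
    cand <- idx[order(rowSums(sweep(idx, 2, ctr)^2)), , drop = FALSE]
    hit <- NULL
    for (r in seq_len(min(nrow(cand), 5000L))) {
      if (deep(cand[r, ])) { hit <- cand[r, ]; break }
    }
    if (is.null(hit))
      stop_seg2fem("no interior voxel deep enough for a cavity",
                   "seg2fem_spec_error")
    off <- rbind(c(0, 0, 0), c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0))
    grid[sweep(off, 2, hit, "+")] <- 0L
  }
  out <- vol
  out$grid <- grid
  out
}

#' Phantom specs for a synthetic cohort
#'
#' Builds one [phantom_spec()] per subject with consecutive seeds and
#' alternating base labels, emulating a multi-patient dataset at desk scale.
#'
#' @param n_subjects number of subjects.
#' @param seeds integer seeds, one per subject.
#' @param n_levels,jitter,... forwarded to [phantom_spec()].
#' @return List of `phantom_spec` objects.
#' @export
phantom_cohort_specs <- function(n_subjects = 30L, seeds = seq_len(n_subjects),
                                 n_levels = 3L, jitter = 0.1, ...) {
  stopifnot(length(seeds) == n_subjects)
  lapply(seq_len(n_subjects), function(i) {
    phantom_spec(n_levels = n_levels, jitter = jitter, seed = seeds[i],
                 base_label = 10L + (i %% 2L), ...)
  })
}
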