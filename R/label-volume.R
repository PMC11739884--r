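#' Labeled voxel volume
#'
#' A 3D integer label grid with voxel spacing and a voxel-to-world affine.
#' Label 0 is background. By the segmentation convention used throughout the
#' package, vertebra labels lie in 4..25 and an intervertebral disc (IVD)
#' between vertebrae `v` and `v + 1` carries the label `100 * v + (v + 1)`
#' (e.g. 1011 for the disc between vertebrae 10 and 11); the label-name
#' sidecar spells these as `"vert_10"` and `"ivd_10_11"`.
#'
#' @param grid 3D integer array of label ids (0 = background).
#' @param spacing_mm numeric length-3 voxel spacing in mm (in-plane,
#'   in-plane, slice); slice spacing may exceed in-plane spacing.
#' @param affine 4x4 voxel-to-world transform applied to 0-based voxel
#'   indices. Defaults to `diag(spacing)` with the origin at half a voxel, so
#'   voxel centers sit at `(index - 1/2) * spacing`.
#' @param label_names optional named character vector mapping label ids
#'   (names) to body names.
#' @return An object of class `label_volume`.
#' @export
label_volume <- function(grid, spacing_mm, affine = NULL, label_names = NULL) {
  if (length(dim(grid)) != 3L)
    stop_seg2fem("grid must be a 3D array", "seg2fem_format_error")
  if (any(grid != round(grid)) || any(grid < 0))
    stop_seg2fem("grid values must be non-negative integers",
                 "seg2fem_format_error")
  storage.mode(grid) <- "integer"
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) != 3L || any(!is.finite(spacing_mm)) ||
      any(spacing_mm <= 0))
    stop_seg2fem("spacing_mm must be 3 strictly positive numbers",
                 "seg2fem_spec_error")
  if (is.null(affine)) {
    affine <- diag(c(spacing_mm, 1))
    affine[1:3, 4] <- spacing_mm / 2
  }
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L)))
    stop_seg2fem("affine must be a 4x4 matrix", "seg2fem_format_error")
  cn <- sqrt(colSums(affine[1:3, 1:3]^2))
  if (any(abs(cn - spacing_mm) > 1e-6 * pmax(spacing_mm, 1)))
    stop_seg2fem("affine linear part inconsistent with spacing",
                 "seg2fem_format_error")
  structure(list(grid = grid, spacing_mm = spacing_mm, affine = affine,
                 label_names = label_names),
            class = "label_volume")
}

#' @export
#' @method print label_volume
print.label_volume <- function(x, ...) {
  d <- dim(x$grid)
  labs <- setdiff(sort(unique(as.vector(x$grid))), 0L)
  cat(sprintf("label_volume: %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm\n",
              d[1], d[2], d[3], x$spacing_mm[1], x$spacing_mm[2], x$spacing_mm[3]))
  cat(sprintf("  %d labels: %s\n", length(labs),
              paste(utils::head(labs, 12), collapse = " ")))
  invisible(x)
}

#' Labels present in a volume
#' @param vol a [label_volume()].
#' @return Sorted integer vector of nonzero labels.
#' @export
labels_present <- function(vol) {
  setdiff(sort(unique(as.vector(vol$grid))), 0L)
}

#' Label conventions for vertebrae and IVDs
#'
#' `is_vertebra_label()` tests for the vertebra range 4..25; `ivd_label_for()`
#' builds the disc label for the pair (`v`, `v + 1`); `ivd_pair()` decodes a
#' disc label into the adjacent vertebra pair.
#' @param label integer label id(s).
#' @param upper upper vertebra label of the pair.
#' @export
is_vertebra_label <- function(label) label >= 4L & label <= 25L

#' @rdname is_vertebra_label
#' @export
is_ivd_label <- function(label) label >= 100L

#' @rdname is_vertebra_label
#' @export
ivd_label_for <- function(upper) as.integer(100L * upper + upper + 1L)

#' @rdname is_vertebra_label
#' @export
ivd_pair <- function(label) c(label %/% 100L, label %% 100L)

#' Human-readable body name for a label
#' @param label integer label id.
#' @export
label_name <- function(label) {
  ifelse(is_ivd_label(label),
         sprintf("ivd_%d_%d", label %/% 100L, label %% 100L),
         sprintf("vert_%d", label))
}

# world coordinates of 0-based voxel indices (n x 3)
voxel_to_world <- function(vol, idx0) {
  idx0 <- as_matrix3(idx0, "voxel indices")
  t(vol$affine[1:3, 1:3] %*% t(idx0) + vol$affine[1:3, 4])
}

#' Read a label volume from a NIfTI file
#'
#' Reads a 3D integer-valued NIfTI image, recovering the label grid, the
#' voxel spacing and the voxel-to-world affine. A `<path>.labels.json`
#' sidecar, if present, is read into the label-name table.
#'
#' @param path path to a `.nii` / `.nii.gz` file.
#' @return A [label_volume()].
#' @export
read_label_volume <- function(path) {
  if (!file.exists(path))
    stop_seg2fem(sprintf("file not found: %s", path), "seg2fem_format_error")
  img <- RNifti::readNifti(path)
  if (length(dim(img)) == 4L && dim(img)[4] == 1L) dim(img) <- dim(img)[1:3]
  if (length(dim(img)) != 3L)
    stop_seg2fem("expected a 3D NIfTI volume", "seg2fem_format_error")
  arr <- array(as.vector(img), dim = dim(img)) # strip image attributes
  if (any(arr != round(arr)))
    stop_seg2fem("NIfTI data is not integer-valued", "seg2fem_format_error")
  aff <- matrix(as.vector(RNifti::xform(img)), 4, 4)
  spacing <- sqrt(colSums(aff[1:3, 1:3]^2))
  label_names <- NULL
  sidecar <- paste0(path, ".labels.json")
  if (file.exists(sidecar)) {
    ln <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    label_names <- setNames(as.character(unlist(ln)), names(ln))
  }
  label_volume(arr, spacing, affine = aff, label_names = label_names)
}

#' Write a label volume to a NIfTI file
#'
#' Writes the grid as integer NIfTI with the affine in the sform, plus a
#' `<path>.labels.json` sidecar mapping label integers to body names.
#'
#' @param vol a [label_volume()].
#' @param path output path (`.nii.gz` recommended).
#' @return `path`, invisibly.
#' @export
write_label_volume <- function(vol, path) {
  arr <- vol$grid
  attr(arr, "pixdim") <- vol$spacing_mm
  img <- RNifti::asNifti(arr, datatype = "int32")
  img <- RNifti::`sform<-`(img, structure(vol$affine, code = 2L))
  img <- RNifti::`qform<-`(img, structure(vol$affine, code = 2L))
  RNifti::writeNifti(img, path)
  labs <- labels_present(vol)
  nm <- vol$label_names %||% setNames(label_name(labs), labs)
  jsonlite::write_json(as.list(nm), paste0(path, ".labels.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

# component labeling of one label's mask; returns integer array with
# attribute n_components
label_components <- function(vol, label, connectivity = 26L) {
  mask <- vol$grid == label
  .cc_label_mask(as.vector(mask), dim(vol$grid), as.integer(connectivity))
}

#' Count connected components of a label
#'
#' @param vol a [label_volume()].
#' @param label label id (> 0).
#' @param connectivity 26 (default) or 6.
#' @return Number of connected components; 0 if the label is absent.
#' @export
count_components <- function(vol, label, connectivity = 26L) {
  if (label <= 0) stop_seg2fem("label must be > 0", "seg2fem_spec_error")
  attr(label_components(vol, label, connectivity), "n_components")
}

#' Remove small connected components from every label
#'
#' Connected components with fewer than `min_voxels` voxels are set to
#' background; larger components are untouched. Mirrors the mask-editing
#' rule of removing partial-volume segmentations below a linked-voxel
#' threshold. The operation is idempotent.
#'
#' @param vol a [label_volume()].
#' @param min_voxels components with voxel count `< min_voxels` are removed
#'   (components of exactly `min_voxels` voxels are kept). Default 4.
#' @param connectivity 26 (default) or 6.
#' @return A cleaned [label_volume()].
#' @export
remove_small_components <- function(vol, min_voxels = 4L, connectivity = 26L) {
  if (min_voxels < 1) stop_seg2fem("min_voxels must be >= 1", "seg2fem_spec_error")
  grid <- vol$grid
  for (lab in labels_present(vol)) {
    cc <- label_components(vol, lab, connectivity)
    ncomp <- attr(cc, "n_components")
    if (ncomp <= 1L) next
    sizes <- tabulate(cc[cc > 0L], nbins = ncomp)
    drop <- which(sizes < min_voxels)
    if (length(drop)) grid[cc %in% drop] <- 0L
  }
  out <- vol
  out$grid <- grid
  out
}

#' Merge endplate labels into an IVD label
#'
#' Relabels every voxel carrying one of `endplate_labels` to `ivd_label`, so
#' that endplates and disc form a single body for surface extraction. The
#' total foreground voxel count is unchanged.
#'
#' @param vol a [label_volume()].
#' @param endplate_labels integer vector of endplate label ids (may be empty).
#' @param ivd_label target disc label (> 0).
#' @return The merged [label_volume()].
#' @export
merge_ivd_endplates <- function(vol, endplate_labels, ivd_label) {
  if (ivd_label == 0)
    stop_seg2fem("cannot merge into background (ivd_label = 0)",
                 "seg2fem_spec_error")
  if (length(endplate_labels) == 0) return(vol)
  out <- vol
  out$grid[out$grid %in% as.integer(endplate_labels)] <- as.integer(ivd_label)
  out
}

#' Detect an enclosed cavity in a label's voxel mask
#'
#' A cavity is a background component (6-connectivity) that does not touch
#' the grid border and whose voxels are enclosed by the body. Cavities turn
#' into internal surface shells at extraction and are treated as hole
#' defects by the pipeline.
#'
#' @param vol a [label_volume()].
#' @param label label id.
#' @return TRUE if an enclosed background cavity adjacent to the label exists.
#' @export
has_enclosed_cavity <- function(vol, label) {
  mask <- vol$grid == label
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0) return(FALSE)
  lo <- pmax(apply(idx, 2, min) - 1L, 1L)
  hi <- pmin(apply(idx, 2, max) + 1L, dim(vol$grid))
  sub <- mask[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  bg <- .cc_label_mask(as.vector(!sub), dim(sub), 6L)
  dim(bg) <- dim(sub)
  ncomp <- attr(bg, "n_components")
  if (ncomp <= 1L) return(FALSE)
  border <- unique(c(bg[1, , ], bg[dim(bg)[1], , ], bg[, 1, ], bg[, dim(bg)[2], ],
                     bg[, , 1], bg[, , dim(bg)[3]]))
  any(setdiff(seq_len(ncomp), border) > 0L)
}
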