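test_that("NIfTI round trip preserves grid, spacing and label names", {
  vol <- generate_phantom(phantom_spec(n_levels = 2, seed = 4,
                                       spacing_mm = c(1, 1, 3)))
  path <- tempfile(fileext = ".nii.gz")
  on.exit(unlink(c(path, paste0(path, ".labels.json"))))
  write_label_volume(vol, path)
  back <- read_label_volume(path)
  expect_identical(back$grid, vol$grid)
  expect_equal(back$spacing_mm, vol$spacing_mm, tolerance = 1e-6)
  expect_true(all(c("vert_10", "vert_11") %in% back$label_names))
})

test_that("non-integer NIfTI data raises a format error", {
  img <- array(runif(4 * 4 * 4), dim = c(4, 4, 4))
  path <- tempfile(fileext = ".nii.gz")
  on.exit(unlink(path))
  RNifti::writeNifti(RNifti::asNifti(img), path)
  expect_error(read_label_volume(path), class = "seg2fem_format_error")
})

test_that("small-component removal follows the linked-voxel threshold", {
  g <- array(0L, dim = c(30, 10, 10))
  g[1:10, 2:6, 2:6] <- 1L           # 250-voxel component
  g[15:17, 3, 3] <- 1L              # 3-voxel component
  g[20:23, 3, 3] <- 1L              # exactly 4 voxels
  g[25:29, 3:4, 3] <- 1L            # 10 voxels
  vol <- label_volume(g, c(1, 1, 1))
  out <- remove_small_components(vol, min_voxels = 4)
  expect_equal(sum(out$grid), 250 + 4 + 10) # 3-voxel blob removed, 4 kept
  # idempotent
  expect_identical(remove_small_components(out, 4)$grid, out$grid)
  # foreground never increases
  expect_lte(sum(out$grid > 0), sum(vol$grid > 0))
  # all-background volume passes through
  empty <- label_volume(array(0L, c(4, 4, 4)), c(1, 1, 1))
  expect_identical(remove_small_components(empty)$grid, empty$grid)
})

test_that("endplate labels merge into the disc label conservatively", {
  g <- array(0L, dim = c(20, 10, 10))
  g[1:10, 1:10, 1:9] <- 1011L  # disc: 900 voxels
  g[1:10, 1:10, 10] <- 3L      # endplate: 100 voxels
  vol <- label_volume(g, c(1, 1, 1))
  merged <- merge_ivd_endplates(vol, 3L, 1011L)
  expect_equal(sum(merged$grid == 1011L), 1000)
  expect_equal(sum(merged$grid > 0), sum(vol$grid > 0))
  # merged voxel set is the union of the input voxel sets
  expect_identical(merged$grid == 1011L, vol$grid == 1011L | vol$grid == 3L)
  # empty endplate set is the identity
  expect_identical(merge_ivd_endplates(vol, integer(0), 1011L)$grid, vol$grid)
  expect_error(merge_ivd_endplates(vol, 3L, 0L), class = "seg2fem_spec_error")
})

test_that("component counting respects the connectivity convention", {
  vol <- phantom_subject(1)
  expect_equal(count_components(vol, labels_present(vol)[1]), 1L)
  expect_equal(count_components(vol, 999L), 0L)
  # checkerboard of single voxels: one component under 26-connectivity,
  # many under 6-connectivity
  n <- 6
  g <- array(0L, dim = c(n, n, n))
  idx <- which(((slice.index(g, 1) + slice.index(g, 2) + slice.index(g, 3)) %% 2) == 0)
  g[idx] <- 1L
  vol2 <- label_volume(g, c(1, 1, 1))
  expect_equal(count_components(vol2, 1L, connectivity = 26), 1L)
  expect_gt(count_components(vol2, 1L, connectivity = 6), 1L)
})
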