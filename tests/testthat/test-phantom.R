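test_that("phantom generation is deterministic and seed-sensitive", {
  spec <- phantom_spec(seed = 11, jitter = 0.1)
  v1 <- generate_phantom(spec)
  v2 <- generate_phantom(spec)
  expect_identical(v1$grid, v2$grid)
  v3 <- generate_phantom(phantom_spec(seed = 12, jitter = 0.1))
  expect_false(identical(v1$grid, v3$grid))
})

test_that("phantom labels follow the vertebra/disc conventions", {
  vol <- phantom_subject(1)
  labs <- labels_present(vol)
  verts <- labs[is_vertebra_label(labs)]
  ivds <- labs[is_ivd_label(labs)]
  expect_length(verts, 3)
  expect_length(ivds, 2)
  expect_true(all(verts >= 4 & verts <= 25))
  # each disc label encodes the adjacent vertebra pair
  for (iv in ivds) {
    pair <- ivd_pair(iv)
    expect_true(all(pair %in% verts))
    expect_equal(pair[2], pair[1] + 1)
  }
  # every defect-free body is one 26-connected component
  for (lab in labs) expect_equal(count_components(vol, lab), 1L)
})

test_that("degenerate single-level spec yields exactly one body", {
  vol <- generate_phantom(phantom_spec(n_levels = 1, seed = 5))
  expect_length(labels_present(vol), 1)
})

test_that("invalid specs are rejected", {
  expect_error(phantom_spec(n_levels = 0), class = "seg2fem_spec_error")
  expect_error(phantom_spec(body_radius_mm = -1), class = "seg2fem_spec_error")
  expect_error(phantom_spec(jitter = 0.5), class = "seg2fem_spec_error")
  # a body thinner than one slice cannot be stacked without overlap
  expect_error(phantom_spec(disc_height_mm = 1, spacing_mm = c(1, 1, 3)),
               class = "seg2fem_spec_error")
})

test_that("voxel count matches the analytic body volume at jitter 0", {
  spec <- phantom_spec(n_levels = 1, body_radius_mm = 15, body_height_mm = 25,
                       spacing_mm = c(1, 1, 1), jitter = 0,
                       posterior_lobe = FALSE, seed = 1)
  vol <- generate_phantom(spec)
  # closed form: superellipse (p = 2.5) cross-section a(z) x b(z) with the
  # waist profile used by the generator, integrated over slice planes
  a <- 15; b <- 0.8 * 15; p <- 2.5
  area_unit <- 4 * gamma(1 + 1 / p)^2 / gamma(1 + 2 / p) # area of |x|^p+|y|^p<=1
  zs <- seq(0.5, 24.5, by = 1) / 25
  slice_areas <- vapply(zs, function(t) {
    prof <- 1 - 0.12 * sin(pi * t)^2
    (a * prof) * (b * prof) * area_unit
  }, numeric(1))
  analytic <- sum(slice_areas) # spacing 1 mm
  expect_lt(abs(sum(vol$grid > 0) - analytic) / analytic, 0.05)
})

test_that("thick slices imprint the stated z-extent", {
  spec <- phantom_spec(n_levels = 1, body_height_mm = 12,
                       spacing_mm = c(1, 1, 3), jitter = 0, seed = 1)
  vol <- generate_phantom(spec)
  m <- extract_surface(vol, labels_present(vol)[1])
  zext <- diff(range(m$vertices[, 3]))
  n_slices <- length(unique(which(vol$grid > 0, arr.ind = TRUE)[, 3]))
  expect_lte(abs(zext - n_slices * 3), 3)
})

test_that("defect injection produces detectable artifacts and round-trips", {
  vol <- phantom_subject(1)
  lab <- labels_present(vol)[1]

  d1 <- inject_defect(vol, lab, "small_component")
  cc <- seg2fem:::label_components(d1, lab)
  sizes <- tabulate(cc[cc > 0], attr(cc, "n_components"))
  expect_equal(attr(cc, "n_components"), 2L)
  expect_true(3 %in% sizes)
  # all other labels untouched
  for (other in setdiff(labels_present(vol), lab))
    expect_identical(d1$grid == other, vol$grid == other)
  # cleanup removes the island exactly
  expect_identical(remove_small_components(d1)$grid, vol$grid)

  d2 <- inject_defect(vol, lab, "disconnected_volume")
  cc2 <- seg2fem:::label_components(d2, lab)
  expect_equal(attr(cc2, "n_components"), 2L)
  expect_true(all(tabulate(cc2[cc2 > 0], 2) > 4))

  d3 <- inject_defect(vol, lab, "internal_hole")
  expect_true(has_enclosed_cavity(d3, lab))
  expect_false(has_enclosed_cavity(vol, lab))

  expect_error(inject_defect(vol, 999L, "internal_hole"),
               class = "seg2fem_spec_error")
})

test_that("cohort specs alternate levels and carry distinct seeds", {
  specs <- phantom_cohort_specs(6, seeds = 1:6)
  expect_length(specs, 6)
  expect_equal(vapply(specs, function(s) s$seed, integer(1)), 1:6)
  expect_gt(length(unique(vapply(specs, function(s) s$base_label, integer(1)))), 1)
})
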