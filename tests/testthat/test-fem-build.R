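test_that("material domain is validated", {
  expect_error(material(-1, 0.3), class = "seg2fem_spec_error")
  expect_error(material(100, 0.5), class = "seg2fem_spec_error")
  m <- default_materials()
  expect_equal(m$vertebra$youngs_modulus, 10000)
  expect_equal(m$ivd$poisson_ratio, 0.45)
})

test_that("rounded-coordinate matching is total and perturbation-stable", {
  m <- ball_mesh(6, 1)
  tm <- memo("ball6_filled", fill_volume(m, 1.0))
  ids <- seq_len(nrow(m$vertices))
  hit <- map_surface_to_volume_nodes(m, ids, tm, decimals = 3)
  expect_length(hit, length(ids))
  expect_false(any(duplicated(hit))) # bijection onto its image
  expect_equal(tm$nodes[hit, ], m$vertices, tolerance = 1e-12)
  # identity mesh: volume nodes contain the vertices verbatim
  expect_identical(hit, seq_len(length(ids)))
  # sub-micrometre perturbation does not change the mapping at 3 decimals
  surf2 <- m
  surf2$vertices <- m$vertices + 1e-6 * 0.4
  expect_identical(map_surface_to_volume_nodes(surf2, ids, tm, 3), hit)
  # unmatched vertex raises a mapping error naming the culprit
  surf3 <- m
  surf3$vertices[5, ] <- surf3$vertices[5, ] + 0.123
  expect_error(map_surface_to_volume_nodes(surf3, ids, tm, 3),
               "vertex 5", class = "seg2fem_mapping_error")
})

test_that("reference node is the set member nearest the set centroid", {
  grid <- as.matrix(expand.grid(1:3, 1:3, 0))
  tm <- tet_mesh(rbind(grid, c(2, 2, 5)),
                 matrix(c(1, 2, 4, 10), 1), "linear")
  expect_equal(reference_node(tm, 1:9), 5L) # centre of the 3x3 grid
  # two-node set: tie broken toward the lower node id
  expect_equal(reference_node(tm, c(7L, 3L)), 3L)
  # random 50-node set against the exhaustive oracle
  set.seed(42)
  pts <- matrix(runif(150), ncol = 3)
  tm2 <- tet_mesh(pts, matrix(c(1, 2, 3, 4), 1), "linear")
  nset <- sample(50, 50)
  ctr <- colMeans(pts)
  brute <- which.min(rowSums(sweep(pts, 2, ctr)^2))
  expect_equal(reference_node(tm2, nset), as.integer(brute))
  expect_error(reference_node(tm2, integer(0)), class = "seg2fem_spec_error")
})

test_that("model assembly wires sets, coupling, restraint and moment", {
  art <- phantom_artifacts(1)$artifacts
  a <- art[["11"]]
  mdl <- build_model(a$tet, a$interface, default_materials()$vertebra)
  expect_equal(sqrt(sum(mdl$load$moment^2)), 7500) # 7.5 N·m in N·mm
  expect_identical(mdl$coupling$set, mdl$nset_superior)
  expect_identical(mdl$bc$set, mdl$nset_inferior)
  expect_identical(mdl$bc$dofs, 1:3) # every inferior node fully fixed
  expect_length(intersect(mdl$nset_superior, mdl$nset_inferior), 0)
  expect_true(mdl$ref_superior %in% mdl$nset_superior)
  expect_match(mdl$body_name, "VERT_11")
  # identical sets violate disjointness
  bad <- a$interface
  bad$inferior <- bad$superior
  expect_error(build_model(a$tet, bad, default_materials()$vertebra),
               class = "seg2fem_model_error")
  empty <- interface_map(11L, superior = integer(0), inferior = integer(0))
  expect_error(build_model(a$tet, empty, default_materials()$vertebra),
               class = "seg2fem_model_error")
})

test_that("inp write/read round trip is structurally exact", {
  art <- phantom_artifacts(1)$artifacts
  mdl <- build_model(art[["11"]]$tet, art[["11"]]$interface,
                     default_materials()$vertebra)
  f <- tempfile(fileext = ".inp")
  on.exit(unlink(f))
  write_inp(mdl, f)
  back <- read_inp(f)
  expect_equal(back$mesh$nodes, mdl$mesh$nodes, tolerance = 1e-9)
  expect_identical(back$mesh$elements, mdl$mesh$elements)
  expect_identical(back$nset_superior, mdl$nset_superior)
  expect_identical(back$nset_inferior, mdl$nset_inferior)
  expect_equal(back$ref_superior, mdl$ref_superior)
  expect_equal(back$load$moment, mdl$load$moment, tolerance = 1e-12)
  expect_equal(back$material$youngs_modulus, mdl$material$youngs_modulus)
  expect_identical(back$body_name, mdl$body_name)
  lines <- readLines(f)
  expect_match(lines[grep("^\\*ELEMENT", lines)], "TYPE=C3D10")
  expect_true(any(grepl("NSET=VERT_11_SUP", lines)))
})

test_that("single-tet quadratic model obeys the dialect line rules", {
  one <- to_quadratic(tet_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0),
                                     c(0, 0, 1)), matrix(1:4, 1), "linear"))
  one$surface <- tri_mesh(one$nodes[1:4, ], rbind(c(1, 3, 2), c(1, 2, 4),
                                                  c(2, 3, 4), c(1, 4, 3)))
  iface <- interface_map("toy", superior = c(1L, 2L), inferior = c(3L, 4L))
  mdl <- build_model(one, iface, material(100, 0.3), body_name = "TOY")
  f <- tempfile(fileext = ".inp")
  on.exit(unlink(f))
  write_inp(mdl, f)
  lines <- readLines(f)
  # element data line: id + 10 node ids = 11 entries (within the 16 cap)
  el_line <- lines[grep("^\\*ELEMENT", lines) + 1]
  expect_length(strsplit(el_line, ",")[[1]], 11)
  # no data line anywhere exceeds 16 comma-separated entries
  data_lines <- lines[!grepl("^\\*", lines)]
  expect_true(all(lengths(strsplit(data_lines, ",")) <= 16))
  back <- read_inp(f)
  expect_identical(back$mesh$elements, mdl$mesh$elements)
  # unknown keywords are rejected with a line number
  writeLines(c(lines, "*FREQUENCY"), f)
  expect_error(read_inp(f), "line", class = "seg2fem_parse_error")
})
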