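test_that("meshes round-trip through legacy VTK", {
  bm <- box_mesh(0.04, 0.03, 0.05, 0.015, end_electrodes = TRUE)
  path <- withr::local_tempfile(fileext = ".vtk")
  write_vtk(bm, path, cell_data = list(kv = bm$elem_vol),
            point_data = list(V = bm$nodes[, 3]))
  back <- read_vtk_mesh(path, region_labels = sort(unique(bm$region)))
  expect_equal(back$nodes, bm$nodes, tolerance = 1e-10)
  expect_equal(sum(back$elem_vol), sum(bm$elem_vol), tolerance = 1e-10)
  expect_identical(nrow(back$elems), nrow(bm$elems))
  expect_identical(back$region, bm$region)
})

test_that("imported meshes accept electrode disks and solve", {
  bm <- box_mesh(0.03, 0.03, 0.09, 0.01, end_electrodes = TRUE)
  path <- withr::local_tempfile(fileext = ".vtk")
  write_vtk(bm, path)
  disks <- data.frame(label = c("A", "B"),
                      cx = 0.015, cy = 0.015, cz = c(0.09, 0),
                      nx = 0, ny = 0, nz = c(1, -1),
                      radius = 0.05)
  back <- read_vtk_mesh(path, region_labels = "soft_tissue",
                        patch_disks = disks)
  sol <- solve_injection(assemble_system(back, spec = solve_spec()),
                         "A", "B")
  Z <- Re(sol$patch_V[["electrode_A"]]) / 1e-3
  expect_equal(Z, 0.09 / (0.18233 * 0.03 * 0.03), tolerance = 1e-6)
})

test_that("ASCII STL surfaces are read with area and enclosed volume", {
  path <- withr::local_tempfile(fileext = ".stl")
  ## unit-ish tetrahedron, outward-oriented
  writeLines(c(
    "solid tet",
    "facet normal 0 0 -1", "outer loop",
    "vertex 0 0 0", "vertex 0 1 0", "vertex 1 0 0",
    "endloop", "endfacet",
    "facet normal 0 -1 0", "outer loop",
    "vertex 0 0 0", "vertex 1 0 0", "vertex 0 0 1",
    "endloop", "endfacet",
    "facet normal -1 0 0", "outer loop",
    "vertex 0 0 0", "vertex 0 0 1", "vertex 0 1 0",
    "endloop", "endfacet",
    "facet normal 1 1 1", "outer loop",
    "vertex 1 0 0", "vertex 0 1 0", "vertex 0 0 1",
    "endloop", "endfacet",
    "endsolid tet"), path)
  stl <- read_stl(path)
  expect_identical(nrow(stl$vertices), 4L)
  expect_identical(nrow(stl$faces), 4L)
  expect_equal(stl$volume, 1 / 6, tolerance = 1e-12)
  expect_equal(stl$area, 1.5 + sqrt(3) / 2, tolerance = 1e-12)
})

test_that("sweep tables embed metadata and the configuration hash", {
  sw <- structure(list(kind = "fluid_volume",
                       points = data.frame(volume = c(0, 1e-4),
                                           Z = c(12, 11.5)),
                       meta = list(side = "right", frequency = 1e4)),
                  class = "sweep_result")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_sweep_table(sw, path, config = default_config())
  tab <- utils::read.table(path, header = TRUE, sep = "\t")
  expect_identical(names(tab),
                   c("volume", "Z", "side", "frequency", "config_hash"))
  expect_identical(unique(tab$config_hash),
                   config_hash(default_config()))
  ## identical writes are bit-identical
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_sweep_table(sw, path2, config = default_config())
  expect_identical(readLines(path), readLines(path2))
})
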