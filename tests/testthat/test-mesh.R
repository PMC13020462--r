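test_that("meshing is deterministic and produces valid tetrahedra", {
  m1 <- mesh_coarser()
  m2 <- generate_mesh(geom_right(), "coarser")
  expect_identical(m1$nodes, m2$nodes)
  expect_identical(m1$elems, m2$elems)
  expect_identical(m1$region, m2$region)
  expect_identical(m1$face_patch, m2$face_patch)
  expect_true(all(m1$elem_vol > 0))
})

test_that("region volumes partition the mesh volume exactly", {
  m <- mesh_coarser()
  v <- region_volumes(m)
  expect_lt(abs(sum(v) - sum(m$elem_vol)) / sum(m$elem_vol), 1e-12)
  expect_identical(unname(v["fluid"]), 0)  # no fluid carved
  expect_error(region_volume(m, "bladder"), "unknown region")
  expect_equal(region_volume(m, c("lung_left", "lung_right")),
               unname(v["lung_left"] + v["lung_right"]))
})

test_that("refinement levels span the expected element-count range", {
  counts <- c(coarser = nrow(mesh_coarser()$elems),
              coarse = nrow(generate_mesh(geom_right(), "coarse")$elems),
              normal = nrow(mesh_normal()$elems),
              fine = nrow(generate_mesh(geom_right(), "fine")$elems))
  expect_gt(counts["normal"], 5e4)
  expect_lt(counts["normal"], 5e5)
  expect_true(all(diff(counts) > 0))  # monotone refinement
})

test_that("mesh volumes agree with the analytic solids", {
  m <- mesh_normal()
  g <- geom_right()
  v <- region_volumes(m)
  ## torso: inscribed polygonal cross-section slightly under pi*a*b*h
  expect_lt(abs(sum(v) - pi * g$torso$a * g$torso$b * g$torso$h) /
              (pi * g$torso$a * g$torso$b * g$torso$h), 0.02)
  ## heart ellipsoid: 4/3 pi abc
  expect_lt(abs(v["heart"] - ellipsoid_volume(g$heart$semi)) /
              ellipsoid_volume(g$heart$semi), 0.02)
  ## inflated lungs: 4.84 L target
  lungs <- v["lung_left"] + v["lung_right"]
  expect_lt(abs(lungs - 4.84e-3) / 4.84e-3, 0.02)
})

test_that("electrode patches are resolved, connected and disjoint", {
  m <- mesh_coarser()
  nominal <- pi * (0.01 / 2)^2
  all_nodes <- list()
  for (lb in c("A", "B", "C", "D")) {
    p <- paste0("electrode_", lb)
    ids <- patch_face_ids(m, p)
    expect_gt(length(ids), 0)
    expect_lt(abs(patch_area(m, p) - nominal) / nominal, 0.20)
    expect_true(patch_connected(m, p))
    all_nodes[[lb]] <- patch_nodes(m, p)
  }
  ## patches never intersect each other or the airway walls
  for (i in 1:3) for (j in (i + 1):4)
    expect_length(intersect(all_nodes[[i]], all_nodes[[j]]), 0)
  aw <- unique(as.vector(m$faces[m$face_patch == "airway_wall", ]))
  expect_length(intersect(unlist(all_nodes), aw), 0)
})

test_that("box meshes are exact partitions with exact patch areas", {
  bm <- bar_mesh()
  expect_equal(sum(bm$elem_vol), 0.05 * 0.04 * 0.2, tolerance = 1e-12)
  expect_equal(patch_area(bm, "electrode_A"), 0.05 * 0.04,
               tolerance = 1e-12)
  expect_equal(patch_area(bm, "electrode_B"), 0.05 * 0.04,
               tolerance = 1e-12)
})

test_that("locate_elements finds containing elements consistently", {
  m <- mesh_coarser()
  set.seed(3)
  pts <- cbind(runif(150, -0.1, 0.1), runif(150, -0.07, 0.07),
               runif(150, 0.05, 0.45))
  eid <- locate_elements(m, pts)
  inside <- !is.na(eid)
  expect_gt(mean(inside), 0.9)
  ## each located point really lies in its element
  for (n in which(inside)[1:25]) {
    tet <- m$elems[eid[n], ]
    p1 <- m$nodes[tet[1], ]
    A <- t(m$nodes[tet[2:4], , drop = FALSE]) - p1
    lam <- solve(A, pts[n, ] - p1)
    expect_true(all(lam > -1e-8) && sum(lam) < 1 + 1e-8)
  }
  ## points far outside return NA
  expect_true(all(is.na(locate_elements(m, cbind(0.5, 0.5, 1.0)))))
})
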