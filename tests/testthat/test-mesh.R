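test_that("swept tube matches closed-form cylinder area and volume", {
  m <- build_tube(path_straight(100), 5, mesh_edge_target = 0.5)
  expect_true(is_watertight(m))
  lateral <- sum(face_areas(m)[m$labels == "lateral"])
  expect_lt(abs(lateral / (pi * 5 * 100) - 1), 0.01)
  expect_lt(abs(mesh_volume(m) / (pi * 2.5^2 * 100) - 1), 0.02)
})

test_that("swept-tube volume tracks the analytic value for arc centrelines", {
  m <- build_tube(path_arc(90, 0.03), 5, mesh_edge_target = 0.5)
  expect_true(is_watertight(m))
  expect_lt(abs(mesh_volume(m) / (pi * 2.5^2 * 90) - 1), 0.02)
})

test_that("self-intersecting sweeps are rejected at the curvature*radius bound", {
  # kappa * R = 0.05 * 15 = 0.75: accepted
  expect_s3_class(build_tube(path_arc(60, 0.05), 30, mesh_edge_target = 1),
                  "tri_mesh")
  # kappa * R = 0.07 * 15 = 1.05: rejected with a diagnostic
  expect_error(build_tube(path_arc(40, 0.07), 30, mesh_edge_target = 1),
               "self-intersecting")
})

test_that("point containment distinguishes lumen interior from exterior", {
  m <- build_tube(path_straight(50), 6, mesh_edge_target = 1)
  inside <- points_in_mesh(m, rbind(c(25, 0, 0), c(25, 2.5, 0),
                                    c(25, 4, 0), c(-5, 0, 0)))
  expect_identical(inside, c(TRUE, TRUE, FALSE, FALSE))
})

test_that("binary STL round trip preserves vertices to float precision", {
  m <- build_tube(path_straight(8), 3, mesh_edge_target = 1)
  tf <- withr::local_tempfile(fileext = ".stl")
  write_stl(m, tf)
  m2 <- read_stl(tf)
  expect_true(is_watertight(m2))
  expect_lt(max(abs(sort(as.vector(m2$vertices)) - sort(as.vector(m$vertices)))),
            1e-6)
})

test_that("ASCII PLY round trip is exact and label sidecars reattach", {
  m <- shared_avf()$mesh
  tf <- withr::local_tempfile(fileext = ".ply")
  write_ply(m, tf)
  m2 <- read_ply(tf)
  expect_identical(m2$faces, m$faces)
  expect_identical(m2$vertices, m$vertices)
  lf <- withr::local_tempfile(fileext = ".csv")
  write_face_labels(m, lf)
  m3 <- read_face_labels(m2, lf)
  expect_identical(m3$labels, m$labels)
})

test_that("malformed mesh files raise parse errors rather than loading silently", {
  tf <- withr::local_tempfile(fileext = ".ply")
  writeLines(c("ply", "format ascii 1.0", "element vertex 5"), tf)
  expect_error(read_ply(tf), "end_header")
  tf2 <- withr::local_tempfile(fileext = ".stl")
  m <- build_tube(path_straight(8), 3, mesh_edge_target = 1.5)
  write_stl(m, tf2)
  raw <- readBin(tf2, "raw", file.size(tf2))
  writeBin(raw[1:(length(raw) - 40)], tf2)
  expect_error(read_stl(tf2), "truncated")
})
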