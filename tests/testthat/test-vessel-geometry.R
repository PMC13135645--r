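test_that("centreline of an analytic cylinder lies on its axis", {
  m <- build_tube(path_straight(100), 5, mesh_edge_target = 0.5)
  cl <- extract_centreline(m, rbind(c(3, 0, 0), c(97, 0, 0)))
  off_axis <- sqrt(cl$points[, 2]^2 + cl$points[, 3]^2)
  expect_lt(max(off_axis), 0.05)
})

test_that("centreline of a torus tube follows the generating arc", {
  arc <- path_arc(90, 0.03)
  m <- build_tube(arc, 5, mesh_edge_target = 0.5)
  s1 <- centreline_at(centreline(arc), 5)$point
  s2 <- centreline_at(centreline(arc), 85)$point
  cl <- extract_centreline(m, rbind(s1, s2))
  centre <- c(0, 1 / 0.03, 0)
  radial_err <- abs(sqrt(rowSums(sweep(cl$points, 2, centre)^2)) - 1 / 0.03)
  expect_lt(max(radial_err), 0.05)  # 2% of tube radius
  # recovered curvature = 1/R within 2% away from endpoints
  mid <- cl$s > 10 & cl$s < max(cl$s) - 10
  expect_lt(abs(mean(cl$curvature[mid]) / 0.03 - 1), 0.02)
})

test_that("swapping the seeds reverses the polyline", {
  m <- build_tube(path_straight(60), 5, mesh_edge_target = 1)
  a <- extract_centreline(m, rbind(c(3, 0, 0), c(57, 0, 0)))
  b <- extract_centreline(m, rbind(c(57, 0, 0), c(3, 0, 0)))
  expect_equal(min(b$s), 0)
  n <- min(nrow(a$points), nrow(b$points))
  fwd <- a$points[seq_len(n), 1]
  rev_ <- b$points[rev(seq_len(nrow(b$points)))[seq_len(n)], 1]
  expect_lt(max(abs(sort(fwd) - sort(rev_))), 1.5)
  expect_lt(max(abs(b$points[, 2:3])), 0.05)
})

test_that("seeds outside the lumen are rejected", {
  m <- build_tube(path_straight(60), 5, mesh_edge_target = 1)
  expect_error(extract_centreline(m, rbind(c(30, 10, 0), c(57, 0, 0))),
               "outside the lumen")
})

test_that("curvature estimation: zero, circle, and noise robustness", {
  # straight line
  pts <- path_straight(80, step = 1)
  expect_lt(max(discrete_curvature(pts)), 1e-6)
  # planar arc of radius 33.33 mm -> kappa = 0.030 within 2% off-endpoints
  arc <- path_arc(80, 1 / 33.33, step = 1)
  k <- discrete_curvature(arc, smoothing_window = 10)
  inner <- seq(8, length(k) - 8)
  expect_lt(max(abs(k[inner] * 33.33 - 1)), 0.02)
  # Gaussian point noise sigma = 0.1 mm, window 10 mm: mean within 10%
  set.seed(42)
  noisy <- arc + matrix(rnorm(length(arc), 0, 0.1), nrow(arc), 3)
  kn <- discrete_curvature(noisy, smoothing_window = 10)
  expect_lt(abs(mean(kn[inner]) * 33.33 - 1), 0.10)
  # degenerate input
  expect_error(discrete_curvature(arc[c(1, 1, 2, 3, 4), ]), "degenerate")
})

test_that("curvature is invariant under rigid motion", {
  set.seed(7)
  arc <- path_arc(60, 0.02, step = 1)
  k0 <- discrete_curvature(arc)
  th <- 0.7
  Rz <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  Rx <- matrix(c(1, 0, 0, 0, cos(1.1), sin(1.1), 0, -sin(1.1), cos(1.1)), 3, 3)
  moved <- arc %*% (Rz %*% Rx) + matrix(c(5, -3, 11), nrow(arc), 3, byrow = TRUE)
  expect_lt(max(abs(discrete_curvature(moved) - k0)), 1e-6)
})

test_that("equivalent diameter recovers circular and elliptic sections", {
  m <- build_tube(path_straight(60), 5, mesh_edge_target = 0.5)
  cl <- centreline(path_straight(60, step = 1))
  expect_lt(abs(station_diameter(m, cl, 30) - 5), 0.05)
  # elliptic cylinder, semi-axes 3 and 2 mm: D = 2 sqrt(ab)
  me <- build_tube(path_straight(60), 6, mesh_edge_target = 0.5)
  me$vertices[, 3] <- me$vertices[, 3] * (2 / 3)
  expect_lt(abs(station_diameter(me, cl, 30) / (2 * sqrt(3 * 2)) - 1), 0.01)
  # a station beyond the cap is an error; an open cut is flagged missing
  expect_error(station_diameter(m, cl, 70), "outside")
})

test_that("stations inside the anastomosis patch are flagged missing", {
  model <- shared_avf()
  cl_full <- centreline(avfflow:::avf_limb_paths(model$params, step = 1)$draining_vein,
                        "draining_vein")
  d_at_junction <- station_diameter(model$mesh, cl_full, 1)
  expect_true(is.na(d_at_junction))
  d_outside <- station_diameter(model$mesh, cl_full, 30)
  expect_false(is.na(d_outside))
})

test_that("1 cm partitioning bins faces contiguously with a flagged partial tail", {
  m <- build_tube(path_straight(100), 5, mesh_edge_target = 0.7)
  cl <- list(feeding_artery = centreline(path_straight(100, step = 1),
                                         "feeding_artery"))
  seg <- partition_segments(cl, m)
  expect_equal(nrow(seg), 10L)
  expect_false(any(seg$is_partial))
  expect_true(all(seg$s_end - seg$s_start == 10))
  # 104 mm -> 10 full + one 4 mm partial
  m2 <- build_tube(path_straight(104), 5, mesh_edge_target = 0.7)
  cl2 <- list(feeding_artery = centreline(path_straight(104, step = 1),
                                          "feeding_artery"))
  seg2 <- partition_segments(cl2, m2)
  expect_equal(nrow(seg2), 11L)
  expect_identical(seg2$is_partial, c(rep(FALSE, 10), TRUE))
  expect_equal(seg2$s_end[11] - seg2$s_start[11], 4)
})

test_that("segments cover every non-anastomosis face exactly once", {
  model <- shared_avf()
  cls <- model$centrelines
  seg <- partition_segments(cls, model$mesh)
  fs <- attr(seg, "face_segment")
  anas <- model$mesh$labels == "anastomosis"
  expect_true(all(!is.na(fs)))
  counts <- tabulate(fs, nbins = nrow(seg))
  expect_equal(sum(counts), nrow(model$mesh$faces))
  expect_identical(which(seg$is_anastomosis),
                   unique(fs[anas]))
  # anastomosis faces never land in a distance-indexed segment
  expect_true(all(!seg$is_anastomosis[fs[!anas]]))
})

test_that("anastomosis angle recovers constructed straight-tube junctions", {
  for (theta in c(60, 90)) {
    th <- theta * pi / 180
    feed <- centreline(path_straight(30, direction = c(-1, 0, 0)), "feeding_artery")
    vein <- centreline(path_straight(30, direction = c(cos(th), sin(th), 0)),
                       "draining_vein")
    expect_lt(abs(anastomosis_angle(feed, vein) - theta), 1)
  }
  short <- centreline(path_straight(30, step = 4), "feeding_artery")
  vein <- centreline(path_straight(30), "draining_vein")
  expect_error(anastomosis_angle(short, vein, fit_window = 5), "larger fit_window")
})

test_that("windowed anatomy summary matches constructed profiles", {
  model <- shared_avf()
  an <- avf_anatomy(model$mesh)
  tr <- model$truth
  expect_lt(abs(an$summary$feeding_artery_diameter /
                  tr$feeding_artery_diameter - 1), 0.02)
  expect_lt(abs(an$summary$draining_vein_diameter /
                  tr$draining_vein_diameter - 1), 0.02)
  expect_lt(abs(an$summary$vein_minus_artery_diameter -
                  tr$vein_minus_artery_diameter), 0.1)
  expect_lt(abs(an$summary$anastomosis_angle - tr$anastomosis_angle), 3)
})

test_that("a tapered limb averages to the midpoint diameter over a truncated window", {
  taper <- function(s) 6 - 2 * s / 60
  m <- build_tube(path_straight(60), function(s) taper(s), mesh_edge_target = 0.5)
  cl <- centreline(path_straight(60, step = 1), "feeding_artery")
  stations <- seq(0, 60, by = 1)
  d <- station_diameter(m, cl, stations)
  expect_lt(abs(mean(d, na.rm = TRUE) - 5), 0.1)
  # straight limb: curvature summary at the noise floor
  expect_lt(mean(cl$curvature), 1e-6)
})
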