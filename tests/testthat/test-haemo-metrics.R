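times64 <- seq(0, 1, length.out = 65)[1:64]

test_that("TAWSS: constant, rectified-sinusoid, and quadrature-refined fields", {
  patch <- flat_patch_mesh(6, 10)
  s_const <- uniform_direction_series(patch, times64, 1, rep(2, 64))
  expect_equal(unique(tawss(s_const)), 2)
  # |A sin| averages to 2A/pi
  s_sin <- uniform_direction_series(patch, times64, 1, 3 * sin(2 * pi * times64))
  expect_lt(abs(mean(tawss(s_sin)) - 6 / pi), 2e-3)
  # halving the time step changes the quadrature by < 0.2%
  t128 <- seq(0, 1, length.out = 129)[1:128]
  wf <- waveform_preset("pulsatile", 600, n_samples = 128)
  ws <- womersley_wall_shear(2.5, wf)
  mag_fine <- abs(ws$tau)
  s_fine <- uniform_direction_series(patch, t128, 1, ws$tau)
  s_half <- uniform_direction_series(patch, t128[seq(1, 128, 2)], 1,
                                     ws$tau[seq(1, 128, 2)])
  for (f in list(tawss, osi)) {
    v1 <- f(s_fine)[1]
    v2 <- f(s_half)[1]
    expect_lt(abs(v2 - v1) / abs(v1 + 1e-12), 0.002)
  }
})

test_that("time samples with a gap beyond a quarter period are rejected", {
  patch <- flat_patch_mesh(2, 5)
  tt <- c(0, 0.05, 0.1, 0.6)
  s <- uniform_direction_series(patch, tt, 1, rep(1, 4))
  expect_error(tawss(s), "quarter period")
})

test_that("OSI spans 0 for unidirectional to 0.5 for zero-mean oscillation", {
  patch <- flat_patch_mesh(4, 10)
  s_uni <- uniform_direction_series(patch, times64, 1, 1 + 0.5 * sin(2 * pi * times64))
  expect_equal(unique(osi(s_uni)), 0)
  s_osc <- uniform_direction_series(patch, times64, 1, sin(2 * pi * times64))
  expect_equal(unique(osi(s_osc)), 0.5)
  # B + A sin with B = 1, A = 2 against numeric quadrature
  s_mix <- uniform_direction_series(patch, times64, 1, 1 + 2 * sin(2 * pi * times64))
  denom <- stats::integrate(function(t) abs(1 + 2 * sin(2 * pi * t)), 0, 1,
                            subdivisions = 2000, rel.tol = 1e-10)$value
  expect_equal(unique(osi(s_mix)), 0.5 * (1 - 1 / denom), tolerance = 1e-3)
})

test_that("transverse WSS vanishes for fixed directions and integrates |sin| for swinging ones", {
  patch <- flat_patch_mesh(4, 10)
  s_uni <- uniform_direction_series(patch, times64, 1, 1 + 0.5 * sin(2 * pi * times64))
  expect_equal(unique(transwss(s_uni)), 0)
  # unit shear swinging uniformly across +-90 deg about its mean direction
  th <- -pi / 2 + pi * times64
  nf <- nrow(patch$faces)
  arr <- array(0, dim = c(nf, 3, 64))
  for (j in 1:64) arr[, , j] <- matrix(c(cos(th[j]), sin(th[j]), 0),
                                       nf, 3, byrow = TRUE)
  s_rot <- surface_field_series(patch, times64, 1, arr)
  expect_equal(unique(transwss(s_rot)), 2 / pi, tolerance = 2e-3)
  # pure oscillation: no mean direction -> missing, not zero
  s_osc <- uniform_direction_series(patch, times64, 1, sin(2 * pi * times64))
  expect_message(v <- transwss(s_osc), "no mean shear direction")
  expect_true(all(is.na(v)))
})

test_that("WSSG recovers imposed linear fields on flat and curved surfaces", {
  patch <- flat_patch_mesh(10, 10)
  g0 <- wssg(tawss_map = rep(1.7, nrow(patch$faces)), mesh = patch)
  expect_lt(mean(is.na(g0)), 0.05)  # only corner faces lack a neighbourhood
  expect_equal(max(g0, na.rm = TRUE), 0)
  cen <- face_centroids(patch)
  g <- wssg(tawss_map = 0.2 * cen[, 1], mesh = patch)
  expect_lt(max(abs(g - 0.2) / 0.2, na.rm = TRUE), 0.05)
  # axially linear field on a cylinder
  cyl <- build_tube(path_straight(60), 5, mesh_edge_target = 0.7, caps = FALSE)
  cenc <- face_centroids(cyl)
  gc <- wssg(tawss_map = 0.1 * cenc[, 1], mesh = cyl)
  interior <- cenc[, 1] > 5 & cenc[, 1] < 55
  expect_lt(max(abs(gc[interior] - 0.1) / 0.1), 0.05)
})

test_that("LNH is zero for Poiseuille flow and closed-form for axial swirl", {
  set.seed(8)
  r <- runif(200, 0.1, 2); phi <- runif(200, 0, 2 * pi); z <- runif(200, 0, 10)
  pts <- cbind(r * cos(phi), r * sin(phi), z)
  e_phi <- cbind(-sin(phi), cos(phi), 0)
  e_z <- matrix(c(0, 0, 1), 200, 3, byrow = TRUE)
  # Poiseuille: axial velocity, azimuthal vorticity -> orthogonal
  v_pois <- e_z * (1 - (r / 2.5)^2)
  w_pois <- e_phi * r
  snap <- volume_snapshot(pts, v_pois, w_pois)
  expect_lt(max(abs(lnh(snap))), 1e-12)
  # rigid swirl + axial stream: LNH = W / sqrt(W^2 + Gamma^2 r^2)
  W <- 0.8; G <- 0.5
  v_swirl <- W * e_z + G * r * e_phi
  w_swirl <- 2 * G * e_z
  snap2 <- volume_snapshot(pts, v_swirl, w_swirl)
  expect_equal(lnh(snap2), W / sqrt(W^2 + G^2 * r^2), tolerance = 1e-12)
  # stagnant points are missing
  v0 <- v_swirl; v0[1:5, ] <- 0
  expect_true(all(is.na(lnh(volume_snapshot(pts, v0, w_swirl))[1:5])))
})

test_that("metric maps obey their ranges and scale linearly in the traction", {
  set.seed(9)
  patch <- flat_patch_mesh(5, 10)
  nf <- nrow(patch$faces)
  tt <- seq(0, 1, length.out = 33)[1:32]
  for (rep in 1:5) {
    arr <- array(0, dim = c(nf, 3, 32))
    base <- matrix(rnorm(nf * 2), nf, 2)
    for (j in 1:32) {
      amp <- rnorm(2)
      arr[, 1:2, j] <- cbind(base[, 1] + amp[1], base[, 2] + amp[2])
    }
    s1 <- surface_field_series(patch, tt, 1, arr)
    o <- osi(s1)
    expect_true(all(o >= 0 & o <= 0.5, na.rm = TRUE))
    expect_true(all(tawss(s1) >= 0))
    tv <- suppressMessages(transwss(s1))
    expect_true(all(tv >= 0, na.rm = TRUE))
    s3 <- surface_field_series(patch, tt, 1, 3 * arr)
    expect_equal(tawss(s3), 3 * tawss(s1), tolerance = 1e-12)
    expect_equal(suppressMessages(transwss(s3)), 3 * tv, tolerance = 1e-12)
    expect_equal(osi(s3), o, tolerance = 1e-12)
  }
})

test_that("non-tangent tractions are rejected by the field container", {
  patch <- flat_patch_mesh(2, 5)
  arr <- array(0, dim = c(nrow(patch$faces), 3, 3))
  arr[, 3, ] <- 1   # normal to the patch
  expect_error(surface_field_series(patch, c(0, 0.3, 0.6), 1, arr),
               "not tangent")
})

test_that("segment aggregation is an area-weighted partition mean", {
  m <- build_tube(path_straight(100), 5, mesh_edge_target = 0.7)
  cl <- list(feeding_artery = centreline(path_straight(100, step = 1),
                                         "feeding_artery"))
  seg <- partition_segments(cl, m)
  cen <- face_centroids(m)
  # uniform field: every segment mean equals the field value
  maps_u <- list(tawss = rep(1.3, nrow(cen)), mesh = m)
  agg_u <- segment_aggregate(maps_u, seg)
  expect_equal(agg_u$value, rep(1.3, nrow(agg_u)))
  # step field: 2 Pa on the first 50 mm, 1 Pa beyond
  maps_s <- list(tawss = ifelse(cen[, 1] < 50, 2, 1), mesh = m)
  agg_s <- segment_aggregate(maps_s, seg)
  expect_lt(max(abs(agg_s$value[1:5] - 2)), 0.05)
  expect_lt(max(abs(agg_s$value[6:10] - 1)), 0.05)
  # conservation: area-weighted mean of segment means = global mean
  ar <- face_areas(m)
  fs <- attr(seg, "face_segment")
  global <- sum(maps_s$tawss * ar) / sum(ar)
  seg_area <- vapply(seg$faces, function(f) sum(ar[f]), 0)
  expect_equal(sum(agg_s$value * seg_area) / sum(seg_area), global,
               tolerance = 1e-12)
  # all-missing segment propagates NA with a warning
  maps_na <- list(tawss = rep(NA_real_, nrow(cen)), mesh = m)
  w <- capture_warnings(agg_na <- segment_aggregate(maps_na, seg))
  expect_true(any(grepl("all faces missing", w)))
  expect_true(all(is.na(agg_na$value)))
})
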