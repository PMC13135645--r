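test_that("design validation enforces the physical parameter ranges", {
  expect_error(avf_design(feeding_artery_diameter = -1), "diameters")
  expect_error(avf_design(anastomosis_angle = 0), "anastomosis_angle")
  expect_error(avf_design(anastomosis_angle = 180), "anastomosis_angle")
  expect_error(avf_design(artery_length = 10), ">= 20 mm")
  expect_error(avf_design(artery_curvature = -0.01), "curvature")
  # planar arc wrapping onto itself is rejected unless torsion is allowed
  expect_error(avf_design(vein_curvature = 0.08, vein_torsion = 0),
               "self-intersects")
  d <- avf_design(vein_curvature = 0.08)
  expect_gt(d$vein_torsion, 0)
  # ostium wider than the available artery chord
  expect_error(avf_design(feeding_artery_diameter = 3,
                          draining_vein_diameter = 8, ostium_diameter = 8),
               "chord")
})

test_that("built junction mesh is watertight with all four face labels", {
  model <- shared_avf()
  m <- model$mesh
  expect_true(is_watertight(m))
  expect_setequal(unique(m$labels),
                  c("feeding_artery", "distal_artery", "draining_vein",
                    "anastomosis"))
  expect_gt(mesh_volume(m), 0)
  # ground-truth centrelines run from the patch boundary outward
  for (cl in model$centrelines) {
    expect_s3_class(cl, "centreline")
    expect_true(all(diff(cl$s) > 0))
    expect_true(all(points_in_mesh(m, cl$points[c(1, nrow(cl$points) %/% 2), ])))
  }
})

test_that("designed angle is realised by the ground-truth tangents at the junction", {
  set.seed(3)
  d <- avf_design(anastomosis_angle = 60, artery_curvature = 0,
                  vein_curvature = 0, artery_length = 40, vein_length = 40,
                  distal_length = 25, mesh_edge_target = 1)
  model <- build_end_to_side_avf(d)
  ang <- anastomosis_angle(model$centrelines$feeding_artery,
                           model$centrelines$draining_vein)
  expect_lt(abs(ang - 60), 0.5)
})

test_that("mirrored parameters produce the reflected geometry", {
  set.seed(4)
  d <- avf_design(artery_length = 40, vein_length = 40, distal_length = 25,
                  mesh_edge_target = 1)
  m1 <- build_end_to_side_avf(d)
  m2 <- build_end_to_side_avf(d, mirror = TRUE)
  # truth centrelines are exact reflections through z = 0
  p1 <- m1$centrelines$draining_vein$points
  p2 <- m2$centrelines$draining_vein$points
  n <- min(nrow(p1), nrow(p2))
  expect_lt(max(abs(p1[1:n, 1:2] - p2[1:n, 1:2])), 1e-6)
  expect_lt(max(abs(p1[1:n, 3] + p2[1:n, 3])), 1e-6)
  # mirrored mesh vertices lie on the reflected implicit surface
  paths <- avfflow:::avf_limb_paths(d, step = 1)
  nfeed <- nrow(paths$feeding_artery)
  artery_poly <- rbind(paths$feeding_artery[rev(seq_len(nfeed)), ],
                       paths$distal_artery[-1, , drop = FALSE])
  s_feed <- avfflow:::polyline_arclength(paths$feeding_artery)
  s_dist <- avfflow:::polyline_arclength(paths$distal_artery)
  artery_rad <- avfflow:::avf_artery_radius(d, c(-rev(s_feed), s_dist[-1]))
  vein_rad <- avfflow:::avf_vein_radius(
    d, avfflow:::polyline_arclength(paths$draining_vein))
  v <- m2$mesh$vertices
  v[, 3] <- -v[, 3]
  sdf <- pmin(avfflow:::cpp_capsule_dist(v, artery_poly, artery_rad),
              avfflow:::cpp_capsule_dist(v, paths$draining_vein, vein_rad))
  # tolerance ~ grid spacing / 3: interpolated vertices near the weld crease
  expect_lt(max(abs(sdf)), 0.35)
})

test_that("cohort generation is reproducible and converges to its specification", {
  spec <- cohort_spec(n_per_group = 50, seed = 11)
  expect_identical(generate_cohort(spec), generate_cohort(spec))
  # law of large numbers: group means/SDs near spec at n = 5000 (3 SE)
  big <- cohort_spec(n_per_group = 5000, seed = 12)
  tab <- generate_cohort(big)
  for (grp in c("High", "Low")) {
    sel <- tab$latent_group == grp
    for (v in c("fa_diameter_mm", "dv_diameter_mm", "anastomosis_angle_deg")) {
      mu <- big$group_means[[grp]][[v]]
      sd0 <- big$group_sds[[grp]][[v]]
      se <- sd0 / sqrt(5000)
      expect_lt(abs(mean(tab[[v]][sel]) - mu), 3 * se + 0.02 * sd0)
      expect_lt(abs(sd(tab[[v]][sel]) - sd0), 3 * se / sqrt(2) + 0.03 * sd0)
    }
  }
})

test_that("impossible truncated-normal draws fail after bounded rejection", {
  spec <- cohort_spec(n_per_group = 5, seed = 1,
                      group_means = list(High = c(fa_diameter_mm = -50),
                                         Low = c(fa_diameter_mm = 5)),
                      group_sds = list(High = c(fa_diameter_mm = 0.1),
                                       Low = c(fa_diameter_mm = 1)))
  expect_error(generate_cohort(spec), "no admissible draw")
})

test_that("generated cohorts reproduce the fixture schema", {
  tab <- generate_cohort(cohort_spec(n_per_group = 5, seed = 2))
  fixture <- load_avf_cohort()
  expect_identical(names(tab)[seq_along(names(fixture))], names(fixture))
  expect_true(all(tab$outflow_category ==
                    ifelse(tab$venous_outflow_ml_min >= 1000, "High", "Low")))
})
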