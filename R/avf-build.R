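#' Design parameters of a synthetic end-to-side AVF
#'
#' Validated parameter record for the synthetic fistula builder. Lengths and
#' diameters in mm, curvature in 1/mm, anastomosis angle in degrees (angle
#' between the feeding-artery flow direction and the vein takeoff direction).
#'
#' Limbs leave the junction with a straight takeoff segment before constant
#' curvature begins, so the designed angle is well-defined at the junction.
#' When a limb's curvature and usable length would make a planar arc wrap
#' onto itself (`curvature * length >= pi`), the limb is given a helical path
#' of the same constant curvature (torsion defaulting to the curvature),
#' which represents tortuosity without self-intersection; torsion can also be
#' set explicitly.
#'
#' Veins larger than the artery are joined through a tapered (spatulated)
#' ostium: the vein diameter ramps from `ostium_diameter` at the junction to
#' its nominal value over the takeoff length. By default the ostium is
#' `min(draining_vein_diameter, 1.5 * feeding_artery_diameter)`; requesting an
#' ostium wider than 1.5 times the artery diameter (about the half
#' circumference, the largest chord a side opening can offer) is rejected as
#' geometrically impossible.
#'
#' @param feeding_artery_diameter,draining_vein_diameter,distal_artery_diameter
#'   lumen diameters (mm), > 0.
#' @param artery_curvature,vein_curvature constant limb curvature (1/mm, >= 0).
#' @param anastomosis_angle junction angle (degrees), in (0, 180).
#' @param artery_length,vein_length,distal_length limb lengths from the
#'   junction (mm), >= 20.
#' @param mesh_edge_target target surface resolution (mm).
#' @param takeoff straight takeoff length at the junction (mm).
#' @param artery_torsion,vein_torsion limb torsion (1/mm); `NULL` selects 0
#'   for limbs whose arc stays short of a half turn and `curvature` otherwise.
#' @param ostium_diameter anastomotic ostium diameter (mm) or `NULL` for the
#'   default taper rule.
#' @return an object of class `avf_design`.
#' @export
avf_design <- function(feeding_artery_diameter = 5,
                       draining_vein_diameter = 7,
                       distal_artery_diameter = feeding_artery_diameter,
                       artery_curvature = 0.02,
                       vein_curvature = 0.03,
                       anastomosis_angle = 60,
                       artery_length = 120,
                       vein_length = 120,
                       distal_length = 70,
                       mesh_edge_target = 0.5,
                       takeoff = 20,
                       artery_torsion = NULL,
                       vein_torsion = NULL,
                       ostium_diameter = NULL) {
  d <- list(feeding_artery_diameter = feeding_artery_diameter,
            draining_vein_diameter = draining_vein_diameter,
            distal_artery_diameter = distal_artery_diameter,
            artery_curvature = artery_curvature,
            vein_curvature = vein_curvature,
            anastomosis_angle = anastomosis_angle,
            artery_length = artery_length,
            vein_length = vein_length,
            distal_length = distal_length,
            mesh_edge_target = mesh_edge_target,
            takeoff = takeoff,
            artery_torsion = artery_torsion,
            vein_torsion = vein_torsion,
            ostium_diameter = ostium_diameter)
  dia <- c(feeding_artery_diameter, draining_vein_diameter, distal_artery_diameter)
  if (any(!is.finite(dia)) || any(dia <= 0)) stop("all diameters must be > 0")
  if (!(anastomosis_angle > 0 && anastomosis_angle < 180))
    stop("anastomosis_angle must be in (0, 180) degrees")
  if (artery_curvature < 0 || vein_curvature < 0) stop("curvature must be >= 0")
  if (min(artery_length, vein_length, distal_length) < 20)
    stop("limb lengths must be >= 20 mm")
  if (mesh_edge_target <= 0 || takeoff < 0) stop("invalid mesh_edge_target/takeoff")
  pick_torsion <- function(torsion, kappa, usable) {
    if (!is.null(torsion)) return(torsion)
    if (kappa * usable < pi * 0.95) 0 else kappa
  }
  d$artery_torsion <- pick_torsion(artery_torsion, artery_curvature,
                                   max(artery_length, distal_length) - takeoff)
  d$vein_torsion <- pick_torsion(vein_torsion, vein_curvature,
                                 vein_length - takeoff)
  if (d$artery_torsion == 0 && artery_curvature * (max(artery_length, distal_length) - takeoff) >= pi)
    stop("artery curvature * length >= pi: planar arc self-intersects (set artery_torsion)")
  if (d$vein_torsion == 0 && vein_curvature * (vein_length - takeoff) >= pi)
    stop("vein curvature * length >= pi: planar arc self-intersects (set vein_torsion)")
  chord_max <- 1.5 * feeding_artery_diameter
  if (is.null(ostium_diameter)) {
    d$ostium_diameter <- min(draining_vein_diameter, chord_max)
  } else {
    if (ostium_diameter > chord_max)
      stop(sprintf("vein ostium (%.1f mm) wider than the local artery chord (%.1f mm): junction rejected",
                   ostium_diameter, chord_max))
    d$ostium_diameter <- ostium_diameter
  }
  structure(d, class = "avf_design")
}

#' @export
print.avf_design <- function(x, ...) {
  cat(sprintf("AVF design: artery D %.2f/%.2f mm (k=%.3f/mm), vein D %.2f mm (k=%.3f/mm), angle %.1f deg\n",
              x$feeding_artery_diameter, x$distal_artery_diameter,
              x$artery_curvature, x$draining_vein_diameter, x$vein_curvature,
              x$anastomosis_angle))
  invisible(x)
}

# analytic limb axes from the junction (at the origin) outward
avf_limb_paths <- function(params, step = 1) {
  th <- params$anastomosis_angle * pi / 180
  u_vein <- c(cos(th), sin(th), 0)
  n_vein <- c(0, 0, 1)
  list(
    feeding_artery = path_takeoff_helix(params$artery_length,
                                        params$artery_curvature,
                                        params$artery_torsion,
                                        params$takeoff,
                                        direction = c(-1, 0, 0),
                                        normal = c(0, 0, 1), step = step),
    distal_artery = path_takeoff_helix(params$distal_length,
                                       params$artery_curvature,
                                       params$artery_torsion,
                                       params$takeoff,
                                       direction = c(1, 0, 0),
                                       normal = c(0, 0, 1), step = step),
    draining_vein = path_takeoff_helix(params$vein_length,
                                       params$vein_curvature,
                                       params$vein_torsion,
                                       params$takeoff,
                                       direction = u_vein,
                                       normal = n_vein, step = step))
}

# vein radius profile implementing the tapered ostium
avf_vein_radius <- function(params, s) {
  r0 <- params$ostium_diameter / 2
  r1 <- params$draining_vein_diameter / 2
  tk <- max(params$takeoff, 1e-9)
  ifelse(s >= tk, r1, r0 + (r1 - r0) * s / tk)
}

# artery radius profile: feeding -> distal taper across the takeoff region
avf_artery_radius <- function(params, s_signed) {
  rf <- params$feeding_artery_diameter / 2
  rd <- params$distal_artery_diameter / 2
  tk <- max(params$takeoff, 1e-9)
  t <- pmin(1, pmax(0, (s_signed + tk) / (2 * tk)))
  rf + (rd - rf) * t
}

#' Build a synthetic end-to-side AVF lumen mesh
#'
#' Constructs the through-running artery (feeding and distal limbs) and the
#' draining vein joined at the requested anastomosis angle as the union of
#' two swept capsules, polygonised with marching tetrahedra on a regular
#' grid (spacing `mesh_edge_target`), which yields a single watertight,
#' outward-oriented junction mesh. Faces are labelled `feeding_artery`,
#' `distal_artery`, `draining_vein`, or `anastomosis` (faces within one vein
#' diameter of the artery-vein weld seam).
#'
#' @param params an [avf_design()].
#' @param mirror reflect the geometry through the artery-vein plane (z -> -z).
#' @return list of class `avf_model`: `mesh` (labelled [tri_mesh()]),
#'   `centrelines` (ground-truth [centreline()]s per limb, s = 0 at the
#'   anastomosis patch boundary), `truth` (designed parameters plus the
#'   analytic windowed summary the measurement pipeline should recover) and
#'   `params`.
#' @export
build_end_to_side_avf <- function(params, mirror = FALSE) {
  stopifnot(inherits(params, "avf_design"))
  h <- params$mesh_edge_target
  paths <- avf_limb_paths(params, step = min(1, 4 * h))
  if (mirror) paths <- lapply(paths, function(p) { p[, 3] <- -p[, 3]; p })
  # artery as one polyline: feeding reversed + distal
  nfeed <- nrow(paths$feeding_artery)
  artery_poly <- rbind(paths$feeding_artery[rev(seq_len(nfeed)), ],
                       paths$distal_artery[-1, , drop = FALSE])
  s_feed <- polyline_arclength(paths$feeding_artery)
  s_dist <- polyline_arclength(paths$distal_artery)
  artery_signed <- c(-rev(s_feed), s_dist[-1])
  artery_rad <- avf_artery_radius(params, artery_signed)
  vein_rad <- avf_vein_radius(params, polyline_arclength(paths$draining_vein))
  polys <- list(artery_poly, paths$draining_vein)
  radii <- list(artery_rad, vein_rad)
  allpts <- do.call(rbind, polys)
  rmax <- max(unlist(radii))
  lo <- apply(allpts, 2, min) - rmax - 4 * h
  hi <- apply(allpts, 2, max) + rmax + 4 * h
  dims <- as.integer(ceiling((hi - lo) / h) + 1L)
  vals <- cpp_union_sdf_grid(polys, radii, lo, h, dims)
  mt <- cpp_marching_tets(vals, dims, lo, h)
  mesh <- tri_mesh(mt$vertices, mt$faces)
  # limb labels by nearest capsule; weld seam -> anastomosis patch
  cen <- face_centroids(mesh)
  d_art <- cpp_capsule_dist(cen, artery_poly, artery_rad)
  d_vei <- cpp_capsule_dist(cen, paths$draining_vein, vein_rad)
  vessel <- ifelse(d_art <= d_vei, 1L, 2L)
  seam <- seam_points(mesh, vessel)
  labels <- character(nrow(cen))
  d_feed <- cpp_capsule_dist(cen, paths$feeding_artery,
                             rep(0, nrow(paths$feeding_artery)))
  d_distal <- cpp_capsule_dist(cen, paths$distal_artery,
                               rep(0, nrow(paths$distal_artery)))
  labels[vessel == 1L] <- ifelse(d_feed[vessel == 1L] <= d_distal[vessel == 1L],
                                 "feeding_artery", "distal_artery")
  labels[vessel == 2L] <- "draining_vein"
  if (nrow(seam)) {
    dpatch <- params$draining_vein_diameter
    near_seam <- patch_near_seam(cen, seam, dpatch)
    labels[near_seam] <- "anastomosis"
  }
  mesh$labels <- labels
  # ground-truth centrelines trimmed at the measured patch boundary
  cls <- list()
  truth_sum <- list()
  for (nm in names(paths)) {
    cl_full <- centreline(paths[[nm]], limb_label = nm)
    s0 <- patch_boundary_s(mesh, cl_full)
    cls[[nm]] <- trim_centreline(cl_full, s0)
    truth_sum[[nm]] <- list(s0 = s0)
  }
  truth <- avf_truth_summary(params, paths, truth_sum, mirror)
  structure(list(mesh = mesh, centrelines = cls, truth = truth, params = params),
            class = "avf_model")
}

#' @export
print.avf_model <- function(x, ...) {
  print(x$params)
  print(x$mesh)
  invisible(x)
}

# midpoints of mesh edges shared by faces assigned to different vessels
seam_points <- function(mesh, vessel) {
  f <- mesh$faces
  e <- rbind(f[, c(1L, 2L)], f[, c(2L, 3L)], f[, c(3L, 1L)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]), sep = "_")
  face_id <- rep(seq_len(nrow(f)), 3L)
  ord <- order(key)
  key_s <- key[ord]; fid_s <- face_id[ord]
  first <- !duplicated(key_s)
  i1 <- which(first)
  # watertight: each key appears exactly twice
  fa <- fid_s[i1]; fb <- fid_s[i1 + 1L]
  mixed <- vessel[fa] != vessel[fb]
  if (!any(mixed)) return(matrix(numeric(0), 0, 3))
  ekeys <- key_s[i1][mixed]
  vs <- matrix(as.integer(unlist(strsplit(ekeys, "_", fixed = TRUE))),
               ncol = 2, byrow = TRUE)
  (mesh$vertices[vs[, 1], , drop = FALSE] + mesh$vertices[vs[, 2], , drop = FALSE]) / 2
}

patch_near_seam <- function(points, seam, dist) {
  out <- logical(nrow(points))
  chunk <- 4000L
  for (i0 in seq(1L, nrow(points), by = chunk)) {
    i1 <- min(i0 + chunk - 1L, nrow(points))
    d2 <- outer(rowSums(points[i0:i1, , drop = FALSE]^2), rowSums(seam^2), "+") -
      2 * points[i0:i1, , drop = FALSE] %*% t(seam)
    out[i0:i1] <- sqrt(pmax(apply(d2, 1, min), 0)) < dist
  }
  out
}

# first arclength along a limb axis at which the cross-section cut is closed
# and touches no anastomosis-labelled face (two consecutive clean stations)
patch_boundary_s <- function(mesh, cl, step = 0.5, max_s = 40) {
  clean_run <- 0
  s_first <- NA_real_
  for (s in seq(0, min(max_s, max(cl$s)), by = step)) {
    at <- centreline_at(cl, s)
    loop <- pick_loop(plane_cut(mesh, at$point, at$tangent), at$point)
    clean <- !is.null(loop) && loop$closed &&
      !any(mesh$labels[loop$faces] == "anastomosis")
    if (clean) {
      if (clean_run == 0) s_first <- s
      clean_run <- clean_run + 1
      if (clean_run >= 2) return(s_first)
    } else {
      clean_run <- 0
    }
  }
  stop("could not locate the anastomosis patch boundary along a limb")
}

# analytic summary over the measurement windows, used as round-trip truth
avf_truth_summary <- function(params, paths, limb_info, mirror) {
  ds <- 1
  window_for <- function(nm) if (nm == "distal_artery") 50 else 100
  out <- list(anastomosis_angle = params$anastomosis_angle)
  for (nm in names(paths)) {
    s0 <- limb_info[[nm]]$s0
    L <- polyline_arclength(paths[[nm]])
    L <- L[length(L)]
    stations <- seq(s0, min(s0 + window_for(nm), L), by = ds)
    dia <- if (nm == "draining_vein") 2 * avf_vein_radius(params, stations)
           else 2 * avf_artery_radius(params,
                    if (nm == "feeding_artery") -stations else stations)
    kap_true <- ifelse(stations >= params$takeoff,
                       if (nm == "draining_vein") params$vein_curvature
                       else params$artery_curvature, 0)
    out[[paste0(nm, "_diameter")]] <- mean(dia)
    out[[paste0(nm, "_curvature")]] <- mean(kap_true)
    out[[paste0(nm, "_s0")]] <- s0
  }
  out$vein_minus_artery_diameter <-
    out$draining_vein_diameter - out$feeding_artery_diameter
  out$mirrored <- mirror
  out
}
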