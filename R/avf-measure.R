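#' Extract all limb centrelines from a labelled AVF mesh
#'
#' For each limb label present (`feeding_artery`, `distal_artery`,
#' `draining_vein`), picks an interior seed near the limb's far end (midpoint
#' of an inward ray through the lumen from a far lateral face) and marches
#' cross-section centroids towards the anastomosis patch, stopping at its
#' boundary. Returned centrelines are oriented with s = 0 at the patch
#' boundary, increasing away from the junction.
#'
#' @param mesh a labelled, watertight [tri_mesh()] with an `"anastomosis"`
#'   patch label.
#' @param spacing marching step (mm).
#' @param smoothing_window curvature smoothing window (mm).
#' @return named list of [centreline()] objects.
#' @export
avf_centrelines <- function(mesh, spacing = 1, smoothing_window = 10) {
  if (is.null(mesh$labels)) stop("mesh must carry limb labels")
  limbs <- intersect(c("feeding_artery", "distal_artery", "draining_vein"),
                     unique(mesh$labels))
  if (!length(limbs)) stop("no limb labels found on mesh")
  if (!any(mesh$labels == "anastomosis"))
    stop("mesh has no labelled anastomosis patch")
  cen <- face_centroids(mesh)
  nrm <- face_normals(mesh)
  patch_ctr <- colMeans(cen[mesh$labels == "anastomosis", , drop = FALSE])
  junction_seed <- interior_point_near(mesh, patch_ctr)
  out <- list()
  for (nm in limbs) {
    sel <- which(mesh$labels == nm)
    d <- sqrt(rowSums(sweep(cen[sel, , drop = FALSE], 2, patch_ctr)^2))
    axis_est <- sweep(cen[sel, , drop = FALSE], 2, patch_ctr)
    axis_est <- axis_est / pmax(sqrt(rowSums(axis_est^2)), 1e-12)
    lateral <- abs(rowSums(axis_est * nrm[sel, , drop = FALSE])) < 0.5
    cand <- sel[lateral][order(d[lateral], decreasing = TRUE)]
    if (!length(cand)) cand <- sel[order(d, decreasing = TRUE)]
    seed <- NULL
    for (fi in cand[seq_len(min(10L, length(cand)))]) {
      seed <- try(interior_ray_midpoint(mesh, cen[fi, ], -nrm[fi, ]), silent = TRUE)
      if (!inherits(seed, "try-error") && !is.null(seed)) break
      seed <- NULL
    }
    if (is.null(seed)) stop("could not place an interior seed in limb ", nm)
    cl <- extract_centreline(mesh, rbind(seed, junction_seed),
                             spacing = spacing, limb_label = nm,
                             smoothing_window = smoothing_window)
    out[[nm]] <- reverse_centreline(cl)
  }
  out
}

# midpoint of the chord a ray cuts through the lumen starting just inside
# the surface at `p` in direction `dir`
interior_ray_midpoint <- function(mesh, p, dir) {
  fv <- face_vertex_array(mesh)
  start <- p + 1e-6 * dir
  hits <- ray_mesh_hits(start, dir, fv)
  if (is.null(hits) || !length(hits)) return(NULL)
  t_exit <- min(hits)
  mid <- start + dir * t_exit / 2
  if (!points_in_mesh(mesh, rbind(mid))) return(NULL)
  mid
}

# an interior point near `p`: p itself if inside, else the midpoint of an
# inward ray from the nearest face
interior_point_near <- function(mesh, p) {
  if (points_in_mesh(mesh, rbind(p))) return(p)
  cen <- face_centroids(mesh)
  nrm <- face_normals(mesh)
  ord <- order(rowSums(sweep(cen, 2, p)^2))
  for (fi in ord[seq_len(min(10L, length(ord)))]) {
    mid <- interior_ray_midpoint(mesh, cen[fi, ], -nrm[fi, ])
    if (!is.null(mid)) return(mid)
  }
  stop("could not find an interior point near the anastomosis patch")
}

#' Full anatomical characterisation of a labelled AVF mesh
#'
#' Convenience wrapper: extracts limb centrelines ([avf_centrelines()]),
#' partitions the surface into 1 cm segments ([partition_segments()]) and
#' computes the windowed anatomical summary ([summarise_anatomy()]).
#'
#' @inheritParams avf_centrelines
#' @param segment_length segment length (mm).
#' @param fit_window anastomosis-angle line-fit window (mm).
#' @return list with `centrelines`, `segments`, `summary`.
#' @export
avf_anatomy <- function(mesh, spacing = 1, smoothing_window = 10,
                        segment_length = 10, fit_window = 5) {
  cls <- avf_centrelines(mesh, spacing, smoothing_window)
  seg <- partition_segments(cls, mesh, segment_length)
  summ <- summarise_anatomy(mesh, cls, fit_window)
  list(centrelines = cls, segments = seg, summary = summ)
}

#' Design set spanning the packaged cohort's anatomical ranges
#'
#' Twelve [avf_design()]s whose diameters, curvatures and anastomosis angles
#' are taken from rows of the packaged 17-fistula table (curvature read as
#' 1/mm for synthesis), so that synthetic-geometry validation sweeps the
#' observed anatomical ranges. Distal artery diameter is set to 85% of the
#' feeding artery.
#'
#' @param mesh_edge_target surface resolution passed to every design (mm).
#' @return named list of `avf_design` objects.
#' @export
avf_cohort_designs <- function(mesh_edge_target = 0.5) {
  tab <- load_avf_cohort()
  rows <- c("#71", "#69", "#60", "#40", "#77", "#65", "#87", "#57", "#34",
            "#45", "#44", "#72")
  tab <- tab[match(rows, tab$patient_id), ]
  out <- lapply(seq_len(nrow(tab)), function(i)
    avf_design(feeding_artery_diameter = tab$fa_diameter_mm[i],
               draining_vein_diameter = tab$dv_diameter_mm[i],
               distal_artery_diameter = 0.85 * tab$fa_diameter_mm[i],
               artery_curvature = tab$fa_curvature[i],
               vein_curvature = tab$dv_curvature[i],
               anastomosis_angle = tab$anastomosis_angle_deg[i],
               mesh_edge_target = mesh_edge_target))
  names(out) <- rows
  out
}

#' Geometry round-trip study over a set of designs
#'
#' For each design: build the synthetic AVF, run the full measurement
#' pipeline ([avf_anatomy()]) on the mesh alone, and compare the recovered
#' windowed summary against the builder's analytic truth.
#'
#' @param designs list of [avf_design()]s (default [avf_cohort_designs()]).
#' @param verbose print per-design progress.
#' @return `data.frame` with per-design relative diameter and curvature
#'   errors and the absolute angle error (degrees).
#' @export
avf_roundtrip_study <- function(designs = avf_cohort_designs(), verbose = FALSE) {
  rows <- lapply(seq_along(designs), function(i) {
    model <- build_end_to_side_avf(designs[[i]])
    an <- avf_anatomy(model$mesh)
    tr <- model$truth
    sm <- an$summary
    if (verbose)
      message(sprintf("design %d/%d done", i, length(designs)))
    data.frame(
      design = names(designs)[i] %||% as.character(i),
      fa_diameter_rel = sm$feeding_artery_diameter / tr$feeding_artery_diameter - 1,
      dv_diameter_rel = sm$draining_vein_diameter / tr$draining_vein_diameter - 1,
      da_diameter_rel = sm$distal_artery_diameter / tr$distal_artery_diameter - 1,
      fa_curvature_rel = sm$feeding_artery_curvature / tr$feeding_artery_curvature - 1,
      dv_curvature_rel = sm$draining_vein_curvature / tr$draining_vein_curvature - 1,
      angle_err_deg = sm$anastomosis_angle - tr$anastomosis_angle,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
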