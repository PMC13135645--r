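#' Pipeline configuration
#'
#' A validated, losslessly JSON-serialisable record of everything a pipeline
#' run needs: stage toggles, geometry parameters (or a mesh path), waveform
#' preset, fluid properties, windows, ROC variable list, seed and output
#' directory.
#'
#' @param stages subset of `c("synth", "geometry", "metrics", "stats")`.
#' @param geometry list of [avf_design()] arguments, used by the synth stage.
#' @param mesh_path labelled mesh (PLY + labels CSV) for the geometry stage;
#'   defaults to the synth stage output.
#' @param fields_path field-series container for the metrics stage; defaults
#'   to the synth stage output.
#' @param cohort_path cohort CSV for the stats stage; `NULL` uses the
#'   packaged 17-fistula table.
#' @param waveform preset name (see [waveform_preset()]).
#' @param mean_flow cycle-mean inflow, ml/min.
#' @param viscosity,density blood properties (Pa s, kg/m^3).
#' @param segment_length segment length, mm.
#' @param smoothing_window,fit_window geometry windows, mm.
#' @param roc_variables predictor columns for the ROC stage.
#' @param seed integer seed.
#' @param out_dir output directory.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(stages = c("synth", "geometry", "metrics", "stats"),
                            geometry = list(),
                            mesh_path = NULL,
                            fields_path = NULL,
                            cohort_path = NULL,
                            waveform = "pulsatile",
                            mean_flow = 600,
                            viscosity = 3.5e-3,
                            density = 1050,
                            segment_length = 10,
                            smoothing_window = 10,
                            fit_window = 5,
                            roc_variables = c("fa_curvature", "fa_diameter_mm",
                                              "dv_diameter_mm"),
                            seed = 1L,
                            out_dir = "avf_run") {
  stages <- match.arg(stages, c("synth", "geometry", "metrics", "stats"),
                      several.ok = TRUE)
  for (p in c(mesh_path, fields_path, cohort_path))
    if (!is.null(p) && !file.exists(p))
      stop("configured path does not exist: ", p)
  if (viscosity <= 0 || density <= 0) stop("fluid properties must be > 0")
  if (segment_length <= 0 || smoothing_window <= 0 || fit_window <= 0)
    stop("windows must be > 0")
  # validate geometry arguments eagerly
  do.call(avf_design, geometry)
  structure(list(stages = stages, geometry = geometry, mesh_path = mesh_path,
                 fields_path = fields_path, cohort_path = cohort_path,
                 waveform = waveform, mean_flow = mean_flow,
                 viscosity = viscosity, density = density,
                 segment_length = segment_length,
                 smoothing_window = smoothing_window, fit_window = fit_window,
                 roc_variables = roc_variables, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path JSON file.
#' @export
write_pipeline_config <- function(config, path) {
  x <- unclass(config)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$geometry <- as.list(x$geometry)
  do.call(pipeline_config, x)
}

#' Write / read a wall-shear field-series container
#'
#' A directory holding the mesh (`mesh.ply`), face labels
#' (`labels.csv`, if any), one CSV of face tractions per sample time
#' (`traction_<k>.csv`: `face_index,tx,ty,tz`, Pa) and a JSON manifest with
#' the times, period and units. Reading verifies the manifest against the
#' files present and fails on truncation rather than loading silently.
#'
#' @param series a [surface_field_series()].
#' @param dir container directory (created if needed).
#' @return `read_field_series()` returns a [surface_field_series()].
#' @export
write_field_series <- function(series, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_ply(series$mesh, file.path(dir, "mesh.ply"))
  if (!is.null(series$mesh$labels))
    write_face_labels(series$mesh, file.path(dir, "labels.csv"))
  nt <- length(series$times)
  files <- sprintf("traction_%03d.csv", seq_len(nt) - 1L)
  for (j in seq_len(nt)) {
    tw <- traction_slab(series, j)
    utils::write.csv(data.frame(face_index = seq_len(nrow(tw)),
                                tx = tw[, 1], ty = tw[, 2], tz = tw[, 3]),
                     file.path(dir, files[j]), row.names = FALSE, quote = FALSE)
  }
  jsonlite::write_json(list(times_s = series$times, period_s = series$period,
                            units = "Pa", n_faces = dim(series$traction)[1],
                            traction_files = files, mesh_file = "mesh.ply"),
                       file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_field_series
#' @export
read_field_series <- function(dir) {
  man_path <- file.path(dir, "manifest.json")
  if (!file.exists(man_path)) stop("field container has no manifest.json: ", dir)
  man <- jsonlite::read_json(man_path, simplifyVector = TRUE)
  mesh <- read_ply(file.path(dir, man$mesh_file))
  lab <- file.path(dir, "labels.csv")
  if (file.exists(lab)) mesh <- read_face_labels(mesh, lab)
  nt <- length(man$times_s)
  if (length(man$traction_files) != nt)
    stop("truncated field container: manifest lists ", nt,
         " times but ", length(man$traction_files), " traction files")
  arr <- array(0, dim = c(man$n_faces, 3, nt))
  for (j in seq_len(nt)) {
    fp <- file.path(dir, man$traction_files[j])
    if (!file.exists(fp)) stop("truncated field container: missing ", fp)
    tw <- utils::read.csv(fp)
    if (nrow(tw) != man$n_faces)
      stop(sprintf("truncated field container: %s has %d rows, expected %d",
                   man$traction_files[j], nrow(tw), man$n_faces))
    arr[tw$face_index, , j] <- as.matrix(tw[c("tx", "ty", "tz")])
  }
  surface_field_series(mesh, man$times_s, man$period_s, arr)
}

write_centrelines_csv <- function(centrelines, path) {
  rows <- lapply(centrelines, function(cl)
    data.frame(limb = cl$limb_label, s_mm = cl$s,
               x = cl$points[, 1], y = cl$points[, 2], z = cl$points[, 3],
               kappa_per_mm = cl$curvature))
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

write_segments_csv <- function(segments, path) {
  utils::write.csv(segments[c("limb", "seg_index", "s_start", "s_end",
                              "is_anastomosis", "is_partial")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

summary_as_row <- function(summary) {
  data.frame(fa_diameter_mm = summary$feeding_artery_diameter,
             fa_curvature = summary$feeding_artery_curvature,
             dv_diameter_mm = summary$draining_vein_diameter,
             dv_curvature = summary$draining_vein_curvature,
             da_diameter_mm = summary$distal_artery_diameter,
             da_curvature = summary$distal_artery_curvature,
             anastomosis_angle_deg = summary$anastomosis_angle,
             vein_minus_artery_diameter_mm = summary$vein_minus_artery_diameter)
}

#' Run the AVF analysis pipeline
#'
#' Executes the toggled stages in order — `synth` (build the synthetic AVF
#' mesh, waveform and wall-shear field container), `geometry` (centrelines,
#' segments, anatomical summary), `metrics` (wall-shear metric maps and
#' per-segment means), `stats` (group summaries, comparisons and ROC on the
#' cohort table) — writing every product plus a run manifest with checksums
#' into `config$out_dir`. Given an identical configuration and seed the
#' output files are byte-identical. A stage failure records partial
#' completion in the manifest and re-raises the error.
#'
#' @param config a [pipeline_config()].
#' @return the run manifest (list), invisibly written as
#'   `manifest.json`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  manifest <- list(package_version = as.character(utils::packageVersion("avfflow")),
                   seed = config$seed, config = unclass(config),
                   started = format(Sys.time(), tz = "UTC"),
                   stages_completed = character(0), outputs = list())
  mesh <- NULL
  series <- NULL
  finish_stage <- function(stage) {
    manifest$stages_completed <<- c(manifest$stages_completed, stage)
  }
  record <- function(paths) {
    for (p in paths)
      manifest$outputs[[basename(p)]] <<- unname(tools::md5sum(p))
  }
  run_stage <- function(stage, fun) {
    tryCatch(fun(), error = function(e) {
      manifest$failed_stage <- stage
      manifest$error <- conditionMessage(e)
      write_manifest(manifest, out)
      stop(sprintf("pipeline stage '%s' failed: %s", stage,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  if ("synth" %in% config$stages) run_stage("synth", function() {
    design <- do.call(avf_design, config$geometry)
    model <- build_end_to_side_avf(design)
    mesh <<- model$mesh
    mp <- file.path(out, "avf_mesh.ply")
    write_ply(model$mesh, mp)
    write_stl(model$mesh, file.path(out, "avf_mesh.stl"))
    lp <- file.path(out, "avf_mesh_labels.csv")
    write_face_labels(model$mesh, lp)
    cp <- file.path(out, "truth_centrelines.csv")
    write_centrelines_csv(model$centrelines, cp)
    wf <- waveform_preset(config$waveform, config$mean_flow, n_samples = 32)
    shear <- womersley_wall_shear(design$feeding_artery_diameter / 2, wf,
                                  config$viscosity, config$density)
    tube <- build_tube(path_straight(100), design$feeding_artery_diameter,
                       mesh_edge_target = 1)
    fs <- axial_traction_series(tube, shear,
                                faces = which(tube$labels == "lateral"))
    fd <- file.path(out, "fields")
    write_field_series(fs, fd)
    series <<- fs
    jsonlite::write_json(list(preset = config$waveform,
                              mean_flow_ml_min = config$mean_flow,
                              period_s = wf$period,
                              times_s = wf$sample_times,
                              flow_ml_min = waveform_flow(wf),
                              wall_shear_pa = shear$tau),
                         file.path(out, "waveform.json"),
                         auto_unbox = TRUE, digits = NA)
    record(c(mp, file.path(out, "avf_mesh.stl"), lp, cp,
             file.path(out, "waveform.json"),
             file.path(fd, list.files(fd))))
    finish_stage("synth")
  })
  if ("geometry" %in% config$stages) run_stage("geometry", function() {
    if (!is.null(config$mesh_path)) {
      mesh <<- read_ply(config$mesh_path)
      lab <- sub("\\.ply$", "_labels.csv", config$mesh_path)
      if (file.exists(lab)) mesh <<- read_face_labels(mesh, lab)
    }
    if (is.null(mesh)) stop("geometry stage needs a mesh (run synth or set mesh_path)")
    an <- avf_anatomy(mesh, smoothing_window = config$smoothing_window,
                      segment_length = config$segment_length,
                      fit_window = config$fit_window)
    p1 <- file.path(out, "centrelines.csv")
    write_centrelines_csv(an$centrelines, p1)
    p2 <- file.path(out, "segments.csv")
    write_segments_csv(an$segments, p2)
    p3 <- file.path(out, "anatomy_summary.csv")
    utils::write.csv(summary_as_row(an$summary), p3, row.names = FALSE,
                     quote = FALSE)
    record(c(p1, p2, p3))
    finish_stage("geometry")
  })
  if ("metrics" %in% config$stages) run_stage("metrics", function() {
    if (!is.null(config$fields_path)) series <<- read_field_series(config$fields_path)
    if (is.null(series)) stop("metrics stage needs a field container (run synth or set fields_path)")
    maps <- metric_maps(series)
    p1 <- file.path(out, "metric_maps.csv")
    utils::write.csv(data.frame(face_index = seq_along(maps$tawss),
                                tawss_pa = maps$tawss, osi = maps$osi,
                                transwss_pa = maps$transwss,
                                wssg_pa_mm = maps$wssg),
                     p1, row.names = FALSE, quote = FALSE)
    cl <- list(feeding_artery = centreline(path_straight(100), "feeding_artery"))
    seg <- partition_segments(cl, series$mesh, config$segment_length)
    agg <- segment_aggregate(maps, seg)
    p2 <- file.path(out, "segment_means.csv")
    utils::write.csv(agg, p2, row.names = FALSE, quote = FALSE)
    record(c(p1, p2))
    finish_stage("metrics")
  })
  if ("stats" %in% config$stages) run_stage("stats", function() {
    cohort <- if (is.null(config$cohort_path)) load_avf_cohort()
              else utils::read.csv(config$cohort_path, check.names = FALSE,
                                   stringsAsFactors = FALSE)
    paths <- character(0)
    for (grp in c("outcome", "outflow_category", "fistula_type")) {
      gs <- group_summary(cohort, grp)
      p <- file.path(out, sprintf("group_summary_%s.csv", grp))
      utils::write.csv(gs, p, row.names = FALSE, quote = FALSE)
      cgp <- file.path(out, sprintf("comparisons_%s.csv", grp))
      utils::write.csv(compare_groups(cohort, grp), cgp,
                       row.names = FALSE, quote = FALSE)
      paths <- c(paths, p, cgp)
    }
    labels <- cohort$outflow_category
    rocs <- lapply(config$roc_variables, function(v)
      mw_auc(cohort[[v]], labels, variable = v))
    rocs$angle <- mw_auc(cohort$anastomosis_angle_deg, labels,
                         variable = "anastomosis_angle_deg")
    comb <- combined_auc(cohort, config$roc_variables, labels)
    roc_tab <- do.call(rbind, lapply(c(rocs, list(comb)), function(r)
      data.frame(variable = r$variable, orientation = r$orientation,
                 auc = r$auc, n_pos = r$n_pos, n_neg = r$n_neg,
                 ties = r$n_tied_pairs)))
    p1 <- file.path(out, "roc_auc.csv")
    utils::write.csv(roc_tab, p1, row.names = FALSE, quote = FALSE)
    curves <- do.call(rbind, lapply(c(rocs, list(comb)), function(r)
      cbind(variable = r$variable, r$curve)))
    p2 <- file.path(out, "roc_curves.csv")
    utils::write.csv(curves, p2, row.names = FALSE, quote = FALSE)
    record(c(paths, p1, p2))
    finish_stage("stats")
  })
  manifest$finished <- format(Sys.time(), tz = "UTC")
  write_manifest(manifest, out)
  invisible(manifest)
}

write_manifest <- function(manifest, out) {
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
}

#' Round-trip the package's file formats
#'
#' Writes and re-reads a mesh (binary STL and ASCII PLY), a wall-shear field
#' container, and a cohort CSV, reporting the reconstruction error of each:
#' tables must round-trip exactly, meshes within float tolerance.
#'
#' @param mesh a [tri_mesh()].
#' @param series a [surface_field_series()].
#' @param cohort a cohort `data.frame`.
#' @param dir scratch directory.
#' @return list with per-format maximum absolute differences and equality
#'   flags.
#' @export
roundtrip_formats <- function(mesh, series, cohort, dir = tempfile("avf_rt_")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_stl(mesh, file.path(dir, "m.stl"))
  m_stl <- read_stl(file.path(dir, "m.stl"))
  stl_err <- max(abs(sort(as.vector(m_stl$vertices)) -
                       sort(as.vector(mesh$vertices))))
  write_ply(mesh, file.path(dir, "m.ply"))
  m_ply <- read_ply(file.path(dir, "m.ply"))
  ply_err <- max(abs(m_ply$vertices - mesh$vertices))
  write_field_series(series, file.path(dir, "fields"))
  s2 <- read_field_series(file.path(dir, "fields"))
  field_err <- max(abs(s2$traction - series$traction))
  utils::write.csv(cohort, file.path(dir, "cohort.csv"), row.names = FALSE)
  c2 <- utils::read.csv(file.path(dir, "cohort.csv"), check.names = FALSE,
                        stringsAsFactors = FALSE)
  list(stl_max_vertex_diff = stl_err,
       ply_max_vertex_diff = ply_err,
       field_max_traction_diff = field_err,
       cohort_identical = isTRUE(all.equal(cohort, c2, check.attributes = FALSE)))
}
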