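#' Time-resolved wall-shear traction field on a surface mesh
#'
#' Per-face wall-shear vectors (Pa) sampled at times covering one cardiac
#' cycle. Tractions must be tangent to the surface: faces with
#' `|tau . n| / |tau| >= 1e-3` are rejected.
#'
#' @param mesh a [tri_mesh()].
#' @param times sample times (s) in `[0, period)`, strictly increasing,
#'   starting at 0.
#' @param period cycle duration (s).
#' @param traction numeric array `faces x 3 x times` of wall-shear vectors
#'   (Pa).
#' @return object of class `surface_field_series`.
#' @export
surface_field_series <- function(mesh, times, period, traction) {
  stopifnot(inherits(mesh, "tri_mesh"))
  if (period <= 0) stop("period must be > 0")
  if (times[1] != 0 || any(diff(times) <= 0) || times[length(times)] >= period)
    stop("times must start at 0, increase strictly and stay below the period")
  traction <- as.array(traction)
  if (length(dim(traction)) != 3 || dim(traction)[2] != 3)
    stop("traction must be a faces x 3 x times array")
  if (dim(traction)[1] != nrow(mesh$faces))
    stop("traction face count does not match mesh")
  if (dim(traction)[3] != length(times))
    stop("traction time count does not match times")
  nrm <- face_normals(mesh)
  for (j in seq_along(times)) {
    tw <- traction[, , j, drop = TRUE]
    if (is.null(dim(tw))) tw <- matrix(tw, ncol = 3)
    mag <- sqrt(rowSums(tw^2))
    dotn <- abs(rowSums(tw * nrm))
    bad <- mag > 0 & dotn / pmax(mag, 1e-300) >= 1e-3
    if (any(bad))
      stop(sprintf("traction not tangent to surface on %d face(s) at t = %g",
                   sum(bad), times[j]))
  }
  structure(list(mesh = mesh, times = times, period = period,
                 traction = traction),
            class = "surface_field_series")
}

#' @export
print.surface_field_series <- function(x, ...) {
  cat(sprintf("surface_field_series: %d faces, %d times over %.2f s\n",
              dim(x$traction)[1], length(x$times), x$period))
  invisible(x)
}

#' Volumetric velocity/vorticity snapshot
#'
#' Sample points with velocity and vorticity at a single instant (typically
#' peak systole), as needed for localised normalised helicity.
#'
#' @param points k x 3 matrix of sample points (mm).
#' @param velocity k x 3 matrix (m/s).
#' @param vorticity k x 3 matrix (1/s).
#' @param time_label label of the instant (e.g. `"peak_systole"`).
#' @return object of class `volume_snapshot`.
#' @export
volume_snapshot <- function(points, velocity, vorticity,
                            time_label = "peak_systole") {
  points <- as.matrix(points); velocity <- as.matrix(velocity)
  vorticity <- as.matrix(vorticity)
  if (!all(nrow(points) == c(nrow(velocity), nrow(vorticity))))
    stop("points, velocity and vorticity must have matching row counts")
  if (any(!is.finite(velocity)) || any(!is.finite(vorticity)))
    stop("velocity/vorticity must be finite")
  structure(list(points = points, velocity = velocity, vorticity = vorticity,
                 time_label = time_label),
            class = "volume_snapshot")
}
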