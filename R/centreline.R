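#' Arclength-parameterised vessel centreline
#'
#' Ordered polyline with cumulative arclength, unit tangents and pointwise
#' curvature. Curvature is estimated by local quadratic (Savitzky-Golay type)
#' fits of the coordinates against arclength over a sliding window, which
#' realises the usual kappa = |r' x r''| / |r'|^3 on a smoothed curve;
#' endpoint windows are one-sided.
#'
#' @param points ordered n x 3 matrix of points (mm), n >= 2.
#' @param limb_label one of `"feeding_artery"`, `"distal_artery"`,
#'   `"draining_vein"`, or any informative label.
#' @param smoothing_window window width (mm) for tangent/curvature fits.
#' @return an object of class `centreline` with fields `points`, `s`,
#'   `tangent`, `curvature`, `limb_label`, `smoothing_window`.
#' @export
centreline <- function(points, limb_label = "vessel", smoothing_window = 10) {
  points <- as.matrix(points)
  if (nrow(points) < 2) stop("centreline needs at least 2 points")
  seg <- sqrt(rowSums(diff(points)^2))
  if (any(seg < 1e-12)) stop("degenerate (repeated) centreline points")
  s <- c(0, cumsum(seg))
  obj <- structure(list(points = points, s = s, tangent = NULL,
                        curvature = NULL, limb_label = limb_label,
                        smoothing_window = smoothing_window),
                   class = "centreline")
  fit <- local_quadratic_derivatives(points, s, smoothing_window)
  tg <- fit$d1 / sqrt(rowSums(fit$d1^2))
  obj$tangent <- tg
  obj$curvature <- curvature_from_derivatives(fit$d1, fit$d2)
  obj
}

#' @export
print.centreline <- function(x, ...) {
  cat(sprintf("centreline [%s]: %d points, length %.1f mm, mean curvature %.4f /mm\n",
              x$limb_label, nrow(x$points), max(x$s), mean(x$curvature)))
  invisible(x)
}

# Local quadratic least-squares fit of each coordinate against arclength in a
# window of width w centred (where possible) on each point. Returns first and
# second derivative estimates at every point.
local_quadratic_derivatives <- function(points, s, w) {
  n <- nrow(points)
  d1 <- matrix(0, n, 3)
  d2 <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    sel <- which(abs(s - s[i]) <= w / 2)
    if (length(sel) < 5) {
      # one-sided / short-curve fallback: widen to 5 nearest points
      sel <- order(abs(s - s[i]))[seq_len(min(5L, n))]
    }
    ds <- s[sel] - s[i]
    if (length(unique(round(ds, 9))) < 3) stop("degenerate centreline window")
    X <- cbind(1, ds, ds^2)
    beta <- tryCatch(solve(crossprod(X), crossprod(X, points[sel, , drop = FALSE])),
                     error = function(e) stop("degenerate centreline window"))
    d1[i, ] <- beta[2, ]
    d2[i, ] <- 2 * beta[3, ]
  }
  list(d1 = d1, d2 = d2)
}

curvature_from_derivatives <- function(d1, d2) {
  cr <- cross3(d1, d2)
  sqrt(rowSums(cr^2)) / pmax(rowSums(d1^2)^1.5, 1e-300)
}

#' Pointwise curvature of a centreline
#'
#' Curvature kappa (1/mm) per point from local quadratic fits over the given
#' smoothing window; see [centreline()] for the estimator.
#'
#' @param x a [centreline()] or an n x 3 point matrix (n >= 5).
#' @param smoothing_window window width in mm.
#' @return numeric vector of kappa >= 0 (1/mm).
#' @export
discrete_curvature <- function(x, smoothing_window = 10) {
  if (inherits(x, "centreline")) {
    pts <- x$points; s <- x$s
  } else {
    pts <- as.matrix(x)
    seg <- sqrt(rowSums(diff(pts)^2))
    if (any(seg < 1e-12)) stop("degenerate (repeated) centreline points")
    s <- c(0, cumsum(seg))
  }
  if (nrow(pts) < 5) stop("need at least 5 points for curvature estimation")
  fit <- local_quadratic_derivatives(pts, s, smoothing_window)
  curvature_from_derivatives(fit$d1, fit$d2)
}

#' Interpolate a centreline at an arclength station
#'
#' Linear interpolation of the point and (renormalised) tangent at
#' arclength `s` (mm, clamped to the centreline range).
#'
#' @param cl a [centreline()].
#' @param s arclength (mm).
#' @return list with `point` and unit `tangent`.
#' @export
centreline_at <- function(cl, s) {
  s <- max(min(s, max(cl$s)), 0)
  p <- vapply(1:3, function(d) stats::approx(cl$s, cl$points[, d], xout = s)$y, 0)
  tg <- vapply(1:3, function(d) stats::approx(cl$s, cl$tangent[, d], xout = s)$y, 0)
  list(point = p, tangent = tg / sqrt(sum(tg^2)))
}

# reverse orientation, re-zeroing arclength
reverse_centreline <- function(cl) {
  centreline(cl$points[rev(seq_len(nrow(cl$points))), , drop = FALSE],
             cl$limb_label, cl$smoothing_window)
}

# trim a centreline to s in [s0, s1], re-zeroing arclength at s0
trim_centreline <- function(cl, s0, s1 = Inf) {
  keep <- cl$s >= s0 - 1e-9 & cl$s <= s1 + 1e-9
  pts <- cl$points[keep, , drop = FALSE]
  if (cl$s[keep][1] > s0 + 1e-9 || !any(keep))
    pts <- rbind(centreline_at(cl, s0)$point, pts)
  centreline(pts, cl$limb_label, cl$smoothing_window)
}

#' Extract a centreline from a tubular lumen mesh
#'
#' Cross-section centroid marching: starting at a seed point inside the
#' lumen, the mesh is cut with a plane normal to the current direction, the
#' area centroid of the intersection polygon containing the current point
#' becomes the next centreline point, and the direction is updated from the
#' marching history. Marching stops at an open cross-section (end cap), when
#' the cut reaches faces labelled `stop_label` (the anastomosis patch), or at
#' the second seed.
#'
#' @param mesh a watertight [tri_mesh()].
#' @param seeds 2 x 3 matrix: two points inside the lumen; marching proceeds
#'   from the first towards the second.
#' @param spacing marching step and output resampling interval (mm, <= 1).
#' @param stop_label face label at which to stop (default `"anastomosis"`).
#' @param limb_label label for the returned [centreline()].
#' @param smoothing_window curvature smoothing window (mm).
#' @param max_length safety bound on extracted length (mm).
#' @return a [centreline()]; attribute `"stopped_at"` records the stop
#'   reason (`"cap"`, `"label"`, `"seed"`, or `"max_length"`).
#' @export
extract_centreline <- function(mesh, seeds, spacing = 1,
                               stop_label = "anastomosis",
                               limb_label = "vessel",
                               smoothing_window = 10,
                               max_length = 400) {
  seeds <- rbind(seeds)
  if (nrow(seeds) != 2) stop("seeds must be two interior points")
  inside <- points_in_mesh(mesh, seeds)
  if (!all(inside))
    stop("seed(s) outside the lumen: ", paste(which(!inside), collapse = ", "))
  d0 <- seeds[2, ] - seeds[1, ]
  d0 <- d0 / sqrt(sum(d0^2))
  # pass 1: rough march to learn the local tangent at the first seed; its
  # initial chord direction can be far from the tangent on curved limbs
  rough <- march_centroids(mesh, seeds[1, ], d0, seeds[2, ], spacing,
                           stop_label, max_length)
  if (!is.null(rough$pts) && nrow(rough$pts) >= 3) {
    k <- min(6L, nrow(rough$pts))
    d0 <- rough$pts[k, ] - rough$pts[1, ]
    d0 <- d0 / sqrt(sum(d0^2))
  }
  res <- march_centroids(mesh, seeds[1, ], d0, seeds[2, ], spacing,
                         stop_label, max_length)
  pts <- res$pts
  stopped <- res$stopped
  if (is.null(pts) || nrow(pts) < 2)
    stop("centreline extraction failed: fewer than 2 cross-sections found")
  out <- centreline(resample_polyline(pts, min(spacing, 1)),
                    limb_label, smoothing_window)
  attr(out, "stopped_at") <- stopped
  out
}

march_centroids <- function(mesh, start, dirn, target, spacing,
                            stop_label, max_length) {
  p <- start
  pts <- NULL
  stopped <- "max_length"
  n_max <- ceiling(max_length / spacing)
  for (step in seq_len(n_max)) {
    hit_label <- FALSE
    centro <- p
    open_cut <- FALSE
    for (it in 1:2) {
      cut <- plane_cut(mesh, centro, dirn)
      loop <- pick_loop(cut, centro)
      if (is.null(loop)) { open_cut <- TRUE; break }
      if (!loop$closed) { open_cut <- TRUE; break }
      if (!is.null(mesh$labels) && any(mesh$labels[loop$faces] == stop_label)) {
        hit_label <- TRUE
        break
      }
      centro <- polygon_centroid3(loop$points, dirn)
    }
    if (open_cut) { stopped <- "cap"; break }
    if (hit_label) { stopped <- "label"; break }
    pts <- rbind(pts, centro)
    if (step > 1) {
      d_new <- pts[nrow(pts), ] - pts[nrow(pts) - 1, ]
      d_new <- d_new / sqrt(sum(d_new^2))
      dirn <- 0.5 * dirn + 0.5 * d_new
      dirn <- dirn / sqrt(sum(dirn^2))
    }
    if (sum((centro - target) * dirn) > -spacing &&
        sqrt(sum((centro - target)^2)) < 2 * spacing) {
      stopped <- "seed"
      break
    }
    p <- centro + spacing * dirn
  }
  list(pts = pts, stopped = stopped)
}
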