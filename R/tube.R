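#' Parametric centreline paths
#'
#' Helpers for building analytic vessel axes: straight lines, planar circular
#' arcs of constant curvature, and arcs preceded by a straight takeoff. All
#' return an ordered n x 3 matrix of points (mm) sampled at `step` mm.
#'
#' @param length total path length (mm).
#' @param origin 3-vector start point (mm).
#' @param direction unit 3-vector initial tangent.
#' @param curvature constant curvature kappa (1/mm, >= 0).
#' @param normal unit 3-vector in-plane normal: the arc bends towards it.
#' @param takeoff straight length (mm) before the arc begins.
#' @param step sampling interval (mm).
#' @return n x 3 matrix of points.
#' @export
path_straight <- function(length, origin = c(0, 0, 0), direction = c(1, 0, 0),
                          step = 1) {
  direction <- direction / sqrt(sum(direction^2))
  s <- seq(0, length, by = step)
  if (s[length(s)] < length) s <- c(s, length)
  outer(s, direction) + matrix(origin, length(s), 3, byrow = TRUE)
}

#' @rdname path_straight
#' @export
path_arc <- function(length, curvature, origin = c(0, 0, 0),
                     direction = c(1, 0, 0), normal = c(0, 1, 0), step = 1) {
  if (curvature < 0) stop("curvature must be >= 0")
  if (curvature * length >= pi) stop("curvature * length must be < pi (self-intersecting arc)")
  direction <- direction / sqrt(sum(direction^2))
  normal <- normal - sum(normal * direction) * direction
  nn <- sqrt(sum(normal^2))
  if (nn < 1e-12) stop("normal must not be parallel to direction")
  normal <- normal / nn
  s <- seq(0, length, by = step)
  if (s[length(s)] < length) s <- c(s, length)
  if (curvature == 0) return(outer(s, direction) + matrix(origin, length(s), 3, byrow = TRUE))
  R <- 1 / curvature
  # circle centre at origin + R * normal
  th <- s / R
  pts <- outer(sin(th) * R, direction) + outer((1 - cos(th)) * R, normal)
  pts + matrix(origin, length(s), 3, byrow = TRUE)
}

#' @rdname path_straight
#' @export
path_takeoff_arc <- function(length, curvature, takeoff = 15,
                             origin = c(0, 0, 0), direction = c(1, 0, 0),
                             normal = c(0, 1, 0), step = 1) {
  takeoff <- min(takeoff, length)
  p1 <- path_straight(takeoff, origin, direction, step)
  if (length - takeoff < step / 2 || curvature == 0) {
    if (length > takeoff) {
      p2 <- path_straight(length - takeoff, p1[nrow(p1), ], direction, step)
      return(rbind(p1, p2[-1, , drop = FALSE]))
    }
    return(p1)
  }
  p2 <- path_arc(length - takeoff, curvature, p1[nrow(p1), ], direction, normal, step)
  rbind(p1, p2[-1, , drop = FALSE])
}

#' @rdname path_straight
#' @param torsion constant torsion tau (1/mm); 0 gives a planar arc. A
#'   helical path keeps constant curvature without ever self-intersecting,
#'   which a planar arc does once `curvature * length >= pi`.
#' @export
path_helix <- function(length, curvature, torsion = 0, origin = c(0, 0, 0),
                       direction = c(1, 0, 0), normal = c(0, 1, 0), step = 1) {
  if (curvature < 0) stop("curvature must be >= 0")
  if (curvature == 0 || abs(torsion) < 1e-12)
    return(path_arc(length, curvature, origin, direction, normal, step))
  direction <- direction / sqrt(sum(direction^2))
  normal <- normal - sum(normal * direction) * direction
  nn <- sqrt(sum(normal^2))
  if (nn < 1e-12) stop("normal must not be parallel to direction")
  normal <- normal / nn
  binorm <- c(direction[2] * normal[3] - direction[3] * normal[2],
              direction[3] * normal[1] - direction[1] * normal[3],
              direction[1] * normal[2] - direction[2] * normal[1])
  k2 <- curvature^2 + torsion^2
  a <- curvature / k2
  b <- torsion / k2
  cc <- 1 / sqrt(k2)
  e1 <- -normal
  e2 <- (a * direction + b * binorm) / cc
  e3 <- (b * direction - a * binorm) / cc
  s <- seq(0, length, by = step)
  if (s[length(s)] < length) s <- c(s, length)
  ph <- s / cc
  pts <- outer(a * (cos(ph) - 1), e1) + outer(a * sin(ph), e2) + outer(b * ph, e3)
  pts + matrix(origin, length(s), 3, byrow = TRUE)
}

#' @rdname path_straight
#' @export
path_takeoff_helix <- function(length, curvature, torsion = 0, takeoff = 15,
                               origin = c(0, 0, 0), direction = c(1, 0, 0),
                               normal = c(0, 1, 0), step = 1) {
  takeoff <- min(takeoff, length)
  p1 <- path_straight(takeoff, origin, direction, step)
  if (length - takeoff < step / 2 || curvature == 0) {
    if (length > takeoff + step / 2) {
      p2 <- path_straight(length - takeoff, p1[nrow(p1), ], direction, step)
      return(rbind(p1, p2[-1, , drop = FALSE]))
    }
    return(p1)
  }
  p2 <- path_helix(length - takeoff, curvature, torsion, p1[nrow(p1), ],
                   direction, normal, step)
  rbind(p1, p2[-1, , drop = FALSE])
}

polyline_arclength <- function(points) {
  c(0, cumsum(sqrt(rowSums(diff(points)^2))))
}

# three-point (circumcircle) curvature of a polyline, one value per point
polyline_curvature3 <- function(points) {
  n <- nrow(points)
  k <- numeric(n)
  if (n >= 3) {
    a <- points[1:(n - 2), , drop = FALSE]
    b <- points[2:(n - 1), , drop = FALSE]
    c_ <- points[3:n, , drop = FALSE]
    u <- b - a; v <- c_ - b; w <- c_ - a
    cr <- cross3(u, v)
    denom <- sqrt(rowSums(u^2) * rowSums(v^2) * rowSums(w^2))
    kk <- ifelse(denom > 0, 2 * sqrt(rowSums(cr^2)) / denom, 0)
    k[2:(n - 1)] <- kk
    k[1] <- k[2]; k[n] <- k[n - 1]
  }
  k
}

# resample a polyline at (approximately) uniform arclength spacing
resample_polyline <- function(points, spacing) {
  s <- polyline_arclength(points)
  L <- s[length(s)]
  ns <- max(2L, ceiling(L / spacing) + 1L)
  si <- seq(0, L, length.out = ns)
  apply(points, 2, function(x) stats::approx(s, x, xout = si)$y)
}

# rotation-minimising (parallel transport) frames along a polyline; returns
# list(t, u, v) of n x 3 matrices with t tangent, (u, v) spanning the normal
# plane continuously.
transport_frames <- function(points) {
  n <- nrow(points)
  tg <- matrix(0, n, 3)
  tg[1, ] <- points[2, ] - points[1, ]
  tg[n, ] <- points[n, ] - points[n - 1, ]
  if (n > 2) tg[2:(n - 1), ] <- points[3:n, , drop = FALSE] - points[1:(n - 2), , drop = FALSE]
  tg <- tg / sqrt(rowSums(tg^2))
  u <- matrix(0, n, 3)
  seed <- c(0, 0, 1)
  if (abs(sum(seed * tg[1, ])) > 0.9) seed <- c(0, 1, 0)
  u[1, ] <- seed - sum(seed * tg[1, ]) * tg[1, ]
  u[1, ] <- u[1, ] / sqrt(sum(u[1, ]^2))
  for (i in 2:n) {
    # rotate u by the minimal rotation taking t[i-1] to t[i]
    t0 <- tg[i - 1, ]; t1 <- tg[i, ]
    axis <- c(t0[2] * t1[3] - t0[3] * t1[2],
              t0[3] * t1[1] - t0[1] * t1[3],
              t0[1] * t1[2] - t0[2] * t1[1])
    sa <- sqrt(sum(axis^2)); ca <- sum(t0 * t1)
    if (sa < 1e-14) {
      u[i, ] <- u[i - 1, ]
    } else {
      axis <- axis / sa
      uu <- u[i - 1, ]
      u[i, ] <- uu * ca + c(axis[2] * uu[3] - axis[3] * uu[2],
                            axis[3] * uu[1] - axis[1] * uu[3],
                            axis[1] * uu[2] - axis[2] * uu[1]) * sa +
        axis * sum(axis * uu) * (1 - ca)
    }
    u[i, ] <- u[i, ] - sum(u[i, ] * tg[i, ]) * tg[i, ]
    u[i, ] <- u[i, ] / sqrt(sum(u[i, ]^2))
  }
  v <- cross3(tg, u)
  list(t = tg, u = u, v = v)
}

#' Sweep a circular tube along a centreline
#'
#' Builds a watertight, outward-oriented triangle mesh whose cross-section at
#' every station is a circle of the requested diameter centred on the
#' centreline, using rotation-minimising frames. End caps are triangle fans.
#' The sweep is rejected when `curvature * radius >= 1` anywhere, since the
#' inner wall would self-intersect.
#'
#' @param centreline n x 3 matrix of centreline points (mm), n >= 2.
#' @param diameter diameter profile: a positive scalar, a vector with one
#'   value per resampled station, or a function of arclength s (mm) returning
#'   diameter (mm).
#' @param mesh_edge_target target edge length of the surface triangulation
#'   (mm); controls both circumferential and axial resolution.
#' @param caps close the tube ends with planar fans (default `TRUE`).
#' @return a labelled [tri_mesh()] (`"lateral"`, `"cap_start"`, `"cap_end"`).
#' @export
build_tube <- function(centreline, diameter, mesh_edge_target = 0.5, caps = TRUE) {
  centreline <- as.matrix(centreline)
  if (nrow(centreline) < 2) stop("centreline needs at least 2 points")
  pts <- resample_polyline(centreline, mesh_edge_target)
  s <- polyline_arclength(pts)
  d <- if (is.function(diameter)) diameter(s)
       else if (length(diameter) == 1L) rep(diameter, nrow(pts))
       else stats::approx(seq(0, 1, length.out = length(diameter)),
                          diameter, xout = s / max(s))$y
  if (any(d <= 0)) stop("diameter profile must be positive everywhere")
  kap <- polyline_curvature3(pts)
  kr <- max(kap * d / 2)
  if (kr >= 1)
    stop(sprintf("self-intersecting sweep: curvature * radius = %.2f >= 1", kr))
  nc <- max(16L, ceiling(pi * max(d) / mesh_edge_target))
  fr <- transport_frames(pts)
  th <- (seq_len(nc) - 1L) / nc * 2 * pi
  ns <- nrow(pts)
  verts <- matrix(0, ns * nc, 3)
  for (i in seq_len(ns)) {
    ring <- pts[rep(i, nc), ] + (d[i] / 2) * (outer(cos(th), fr$u[i, ]) + outer(sin(th), fr$v[i, ]))
    verts[(i - 1L) * nc + seq_len(nc), ] <- ring
  }
  idx <- function(i, j) (i - 1L) * nc + ((j - 1L) %% nc) + 1L
  f <- vector("list", ns - 1L)
  for (i in seq_len(ns - 1L)) {
    j <- seq_len(nc)
    f[[i]] <- rbind(cbind(idx(i, j), idx(i + 1L, j), idx(i + 1L, j + 1L)),
                    cbind(idx(i, j), idx(i + 1L, j + 1L), idx(i, j + 1L)))
  }
  faces <- do.call(rbind, f)
  labels <- rep("lateral", nrow(faces))
  if (caps) {
    c1 <- nrow(verts) + 1L
    c2 <- nrow(verts) + 2L
    verts <- rbind(verts, pts[1, ], pts[ns, ])
    j <- seq_len(nc)
    cap1 <- cbind(c1, idx(1L, j), idx(1L, j + 1L))
    cap2 <- cbind(c2, idx(ns, j + 1L), idx(ns, j))
    faces <- rbind(faces, cap1, cap2)
    labels <- c(labels, rep("cap_start", nc), rep("cap_end", nc))
  }
  m <- tri_mesh(verts, faces, labels)
  if (caps && mesh_volume(m) < 0) m$faces <- m$faces[, c(1L, 3L, 2L)]
  m
}
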