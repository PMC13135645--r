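#' Intersect a triangle mesh with a plane
#'
#' Returns the intersection polylines (loops), each a sequence of points where
#' the plane crosses mesh edges, together with the indices of the faces
#' traversed and whether the loop closes on itself. Used for cross-section
#' diameters and centroid marching.
#'
#' @param mesh a [tri_mesh()].
#' @param point a point on the plane (mm).
#' @param normal plane normal (need not be unit).
#' @return list of loops; each loop is `list(points, faces, closed)`.
#' @export
plane_cut <- function(mesh, point, normal) {
  normal <- normal / sqrt(sum(normal^2))
  dv <- as.vector((mesh$vertices %*% normal) - sum(point * normal))
  dv[abs(dv) < 1e-12] <- 1e-12
  f <- mesh$faces
  sg <- dv > 0
  s1 <- sg[f[, 1L]]; s2 <- sg[f[, 2L]]; s3 <- sg[f[, 3L]]
  crossing <- which((s1 != s2) | (s2 != s3))
  if (!length(crossing)) return(list())
  # for each crossing face, its two crossed edges (as sorted vertex pairs)
  edge_of <- function(a, b) {
    lo <- pmin(a, b); hi <- pmax(a, b)
    paste(lo, hi, sep = "_")
  }
  fa <- f[crossing, 1L]; fb <- f[crossing, 2L]; fc <- f[crossing, 3L]
  e_ab <- sg[fa] != sg[fb]
  e_bc <- sg[fb] != sg[fc]
  e_ca <- sg[fc] != sg[fa]
  keys <- rbind(ifelse(e_ab, edge_of(fa, fb), NA),
                ifelse(e_bc, edge_of(fb, fc), NA),
                ifelse(e_ca, edge_of(fc, fa), NA))
  face_edges <- apply(keys, 2, function(k) k[!is.na(k)], simplify = FALSE)
  # unique crossed edges and their intersection points
  all_keys <- unlist(face_edges, use.names = FALSE)
  ukeys <- unique(all_keys)
  usplit <- strsplit(ukeys, "_", fixed = TRUE)
  ua <- as.integer(vapply(usplit, `[`, "", 1L))
  ub <- as.integer(vapply(usplit, `[`, "", 2L))
  t <- dv[ua] / (dv[ua] - dv[ub])
  ipts <- mesh$vertices[ua, , drop = FALSE] * (1 - t) +
    mesh$vertices[ub, , drop = FALSE] * t
  # adjacency: which crossing faces touch each crossed edge
  edge_faces <- split(rep(seq_along(face_edges), lengths(face_edges)),
                      match(all_keys, ukeys))
  # walk loops: local face index -> its two edge ids
  face_eids <- lapply(face_edges, function(k) match(k, ukeys))
  visited <- logical(length(crossing))
  loops <- list()
  for (start in seq_along(crossing)) {
    if (visited[start]) next
    # walk forward from `start` through shared edges
    chain_pts <- integer(0)
    chain_faces <- integer(0)
    cur <- start
    eid <- face_eids[[cur]][1]
    closed <- FALSE
    # first walk one way; if open, restart the other way
    for (pass in 1:2) {
      cur <- start
      eid <- face_eids[[cur]][pass]
      seg_pts <- integer(0)
      seg_faces <- integer(0)
      repeat {
        visited[cur] <- TRUE
        seg_faces <- c(seg_faces, cur)
        seg_pts <- c(seg_pts, eid)
        nbrs <- edge_faces[[eid]]
        nxt <- nbrs[nbrs != cur]
        if (!length(nxt)) break  # boundary edge: open end
        cur <- nxt[1]
        if (cur == start) { closed <- TRUE; break }
        if (visited[cur]) break
        fe <- face_eids[[cur]]
        eid <- fe[fe != eid][1]
        if (is.na(eid)) break
      }
      if (pass == 1) {
        chain_pts <- seg_pts
        chain_faces <- seg_faces
        if (closed) break
        # prepend the other direction (excluding the start face's dup entry)
      } else {
        chain_pts <- c(rev(seg_pts), chain_pts)
        chain_faces <- c(rev(seg_faces[-1]), chain_faces)
      }
    }
    loops[[length(loops) + 1L]] <- list(
      points = ipts[chain_pts, , drop = FALSE],
      faces = crossing[unique(chain_faces)],
      closed = closed)
  }
  loops
}

# orthonormal basis of the plane with given normal
plane_basis <- function(normal) {
  normal <- normal / sqrt(sum(normal^2))
  seed <- if (abs(normal[3]) < 0.9) c(0, 0, 1) else c(0, 1, 0)
  u <- seed - sum(seed * normal) * normal
  u <- u / sqrt(sum(u^2))
  v <- c(normal[2] * u[3] - normal[3] * u[2],
         normal[3] * u[1] - normal[1] * u[3],
         normal[1] * u[2] - normal[2] * u[1])
  list(u = u, v = v, n = normal)
}

# signed area (shoelace) of a 3-D planar polygon, in the plane of `normal`
polygon_area3 <- function(points, normal) {
  b <- plane_basis(normal)
  x <- points %*% b$u
  y <- points %*% b$v
  n <- length(x)
  j <- c(2:n, 1)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

polygon_centroid3 <- function(points, normal) {
  b <- plane_basis(normal)
  x <- as.vector(points %*% b$u)
  y <- as.vector(points %*% b$v)
  n <- length(x)
  j <- c(2:n, 1)
  cr <- x * y[j] - x[j] * y
  A <- sum(cr) / 2
  if (abs(A) < 1e-12) return(colMeans(points))
  cx <- sum((x + x[j]) * cr) / (6 * A)
  cy <- sum((y + y[j]) * cr) / (6 * A)
  off <- mean(points %*% b$n)
  cx * b$u + cy * b$v + off * b$n
}

point_in_polygon3 <- function(p, points, normal) {
  b <- plane_basis(normal)
  x <- as.vector(points %*% b$u); y <- as.vector(points %*% b$v)
  px <- sum(p * b$u); py <- sum(p * b$v)
  n <- length(x)
  j <- c(2:n, 1)
  crossings <- sum((y > py) != (y[j] > py) &
                   (px < (x[j] - x) * (py - y) / (y[j] - y) + x))
  crossings %% 2L == 1L
}

# choose the cut loop containing p (closed loops preferred), else the loop
# whose centroid is nearest p
pick_loop <- function(loops, p) {
  if (!length(loops)) return(NULL)
  closed <- vapply(loops, function(l) isTRUE(l$closed) && nrow(l$points) >= 3, TRUE)
  for (i in which(closed)) {
    nrm <- loop_normal(loops[[i]]$points)
    if (point_in_polygon3(p, loops[[i]]$points, nrm)) return(loops[[i]])
  }
  d <- vapply(loops, function(l) sum((colMeans(l$points) - p)^2), 0)
  loops[[which.min(d)]]
}

loop_normal <- function(points) {
  ctr <- colMeans(points)
  q <- sweep(points, 2, ctr)
  sv <- svd(q, nu = 0, nv = 3)
  sv$v[, 3]
}

#' Equivalent diameter at a centreline station
#'
#' Cuts the mesh with the plane normal to the centreline tangent at arclength
#' `s`, takes the closed intersection polygon containing the centreline
#' point, and reports the equivalent-circle diameter `2 * sqrt(A / pi)` from
#' the polygon area. The polygon is inscribed in the true (smooth) section,
#' so its area carries a known n-vertex discretisation deficit; the area is
#' multiplied by the regular-inscribed-polygon factor `2 pi / (n sin(2 pi /
#' n))`, which removes the leading bias for near-circular sections. Returns
#' `NA` (flagged missing) when the cut is open (plane exits an end cap) or
#' when the station lies in the labelled anastomosis patch.
#'
#' @param mesh a [tri_mesh()].
#' @param cl a [centreline()] inside the mesh.
#' @param s arclength station(s) (mm) within the centreline range.
#' @return equivalent diameter(s) in mm, `NA` where flagged missing.
#' @export
station_diameter <- function(mesh, cl, s) {
  vapply(s, function(si) {
    if (si < -1e-9 || si > max(cl$s) + 1e-9) stop("station outside centreline range")
    at <- centreline_at(cl, si)
    loops <- plane_cut(mesh, at$point, at$tangent)
    loop <- pick_loop(loops, at$point)
    if (is.null(loop) || !loop$closed || nrow(loop$points) < 3) return(NA_real_)
    if (!is.null(mesh$labels) && any(mesh$labels[loop$faces] == "anastomosis"))
      return(NA_real_)
    A <- polygon_area3(loop$points, at$tangent)
    n <- nrow(loop$points)
    A <- A * 2 * pi / (n * sin(2 * pi / n))
    2 * sqrt(A / pi)
  }, 0)
}

#' Partition a lumen surface into 1 cm centreline segments
#'
#' Per limb, arclength is binned into consecutive `[k*L, (k+1)*L)` windows
#' (default L = 10 mm) starting at the anastomosis patch boundary (s = 0 of
#' each limb centreline). Every non-anastomosis face is assigned to the bin
#' of its nearest centreline station across all limbs; faces labelled
#' `"anastomosis"` form their own segment. A trailing bin shorter than L is
#' kept and flagged partial.
#'
#' @param centrelines named list of [centreline()] objects (one per limb,
#'   s = 0 at the patch boundary).
#' @param mesh the labelled [tri_mesh()] the centrelines refer to.
#' @param segment_length segment length in mm (default 10).
#' @return a `data.frame` of class `segment_table` with columns `limb`,
#'   `seg_index`, `s_start`, `s_end`, `is_anastomosis`, `is_partial`, and a
#'   list-column `faces` of member face indices. Attribute `"face_segment"`
#'   maps each face to its row (NA for unassigned).
#' @export
partition_segments <- function(centrelines, mesh, segment_length = 10) {
  stopifnot(length(centrelines) >= 1)
  cen <- face_centroids(mesh)
  nf <- nrow(cen)
  anas <- if (!is.null(mesh$labels)) mesh$labels == "anastomosis" else rep(FALSE, nf)
  best_d <- rep(Inf, nf)
  best_limb <- rep(NA_integer_, nf)
  best_s <- rep(NA_real_, nf)
  for (li in seq_along(centrelines)) {
    cl <- centrelines[[li]]
    d <- cpp_capsule_dist(cen, cl$points, rep(0, nrow(cl$points)))
    upd <- d < best_d
    best_d[upd] <- d[upd]
    best_limb[upd] <- li
    # nearest station arclength: nearest polyline point (spacing <= 1 mm)
    nn <- apply_nearest_station(cen[upd, , drop = FALSE], cl)
    best_s[upd] <- nn
  }
  rows <- list()
  face_segment <- rep(NA_integer_, nf)
  eps <- 1e-6
  for (li in seq_along(centrelines)) {
    cl <- centrelines[[li]]
    L <- max(cl$s)
    nfull <- floor((L + eps) / segment_length)
    has_partial <- (L - nfull * segment_length) > eps
    nseg <- nfull + has_partial
    for (k in seq_len(nseg)) {
      s0 <- (k - 1) * segment_length
      s1 <- if (k <= nfull) k * segment_length else L
      part <- k > nfull
      sel <- which(!anas & best_limb == li &
                     best_s >= s0 - eps & (best_s < s1 - eps | (part & best_s <= s1 + eps) |
                                             (k == nfull & !has_partial & best_s <= s1 + eps)))
      rows[[length(rows) + 1L]] <- list(limb = cl$limb_label, seg_index = k,
                                        s_start = s0, s_end = s1,
                                        is_anastomosis = FALSE, is_partial = part,
                                        faces = sel)
      face_segment[sel] <- length(rows)
    }
  }
  if (any(anas)) {
    rows[[length(rows) + 1L]] <- list(limb = "anastomosis", seg_index = 0L,
                                      s_start = NA_real_, s_end = NA_real_,
                                      is_anastomosis = TRUE, is_partial = FALSE,
                                      faces = which(anas))
    face_segment[anas] <- length(rows)
  }
  out <- data.frame(limb = vapply(rows, `[[`, "", "limb"),
                    seg_index = vapply(rows, `[[`, 0L, "seg_index"),
                    s_start = vapply(rows, `[[`, 0, "s_start"),
                    s_end = vapply(rows, `[[`, 0, "s_end"),
                    is_anastomosis = vapply(rows, `[[`, TRUE, "is_anastomosis"),
                    is_partial = vapply(rows, `[[`, TRUE, "is_partial"),
                    stringsAsFactors = FALSE)
  out$faces <- lapply(rows, `[[`, "faces")
  attr(out, "face_segment") <- face_segment
  class(out) <- c("segment_table", class(out))
  out
}

apply_nearest_station <- function(points, cl) {
  if (!nrow(points)) return(numeric(0))
  # nearest vertex of the (<= 1 mm spaced) centreline polyline
  idx <- vapply(seq_len(nrow(points)), function(i) {
    which.min(colSums((t(cl$points) - points[i, ])^2))
  }, 0L)
  cl$s[idx]
}

#' Anastomosis angle between feeding artery and draining vein
#'
#' Fits a straight line (total least squares) to each centreline over a
#' window adjacent to the junction: the feeding-artery line is directed
#' downstream (towards the junction), the vein line away from it. Reports
#' the angle between the two directions in degrees, in (0, 180); larger
#' values mean a more obtuse junction.
#'
#' @param feeding feeding-artery [centreline()], s = 0 at the junction side.
#' @param vein draining-vein [centreline()], s = 0 at the junction side.
#' @param fit_window window length (mm) used for the line fits.
#' @return angle in degrees.
#' @export
anastomosis_angle <- function(feeding, vein, fit_window = 5) {
  dir_down <- -fit_line_direction(feeding, fit_window)  # towards junction
  dir_away <- fit_line_direction(vein, fit_window)      # away from junction
  ang <- acos(pmin(1, pmax(-1, sum(dir_down * dir_away)))) * 180 / pi
  ang
}

# unit direction of the TLS line through the first `fit_window` mm of a
# centreline, oriented along increasing arclength
fit_line_direction <- function(cl, fit_window) {
  sel <- which(cl$s <= min(cl$s) + fit_window + 1e-9)
  if (length(sel) < 3)
    stop(sprintf("only %d centreline points in a %g mm window; use a larger fit_window",
                 length(sel), fit_window))
  pts <- cl$points[sel, , drop = FALSE]
  ctr <- colMeans(pts)
  sv <- svd(sweep(pts, 2, ctr), nu = 0, nv = 1)
  d <- sv$v[, 1]
  span <- pts[length(sel), ] - pts[1, ]
  if (sum(d * span) < 0) d <- -d
  d
}

#' Windowed anatomical summary of an AVF
#'
#' Equivalent diameters are sampled every `ds` mm along each limb centreline
#' and averaged over 0-100 mm for the feeding artery and draining vein and
#' 0-50 mm for the distal artery (windows truncated to the available limb
#' length); stations with missing diameter (open cut or anastomosis patch)
#' are excluded. Curvature is averaged pointwise over the same windows.
#'
#' @param mesh labelled [tri_mesh()].
#' @param centrelines named list with elements `feeding_artery`,
#'   `draining_vein` and optionally `distal_artery` ([centreline()]s with
#'   s = 0 at the anastomosis patch boundary).
#' @param fit_window window (mm) for the anastomosis-angle line fits.
#' @param window_main averaging window (mm) for feeding artery/draining vein.
#' @param window_distal averaging window (mm) for the distal artery.
#' @param ds diameter sampling interval (mm).
#' @return an object of class `anatomical_summary`: per-limb mean diameter
#'   (mm) and curvature (1/mm), anastomosis angle (degrees), and
#'   `vein_minus_artery_diameter` (mm).
#' @export
summarise_anatomy <- function(mesh, centrelines, fit_window = 5,
                              window_main = 100, window_distal = 50, ds = 1) {
  need <- c("feeding_artery", "draining_vein")
  if (!all(need %in% names(centrelines)))
    stop("centrelines must include feeding_artery and draining_vein")
  one <- function(name, window) {
    cl <- centrelines[[name]]
    L <- max(cl$s)
    if (L < 10) stop(sprintf("limb %s shorter than 10 mm", name))
    stations <- seq(0, min(window, L), by = ds)
    dia <- station_diameter(mesh, cl, stations)
    kap <- stats::approx(cl$s, cl$curvature, xout = stations, rule = 2)$y
    c(diameter = mean(dia, na.rm = TRUE), curvature = mean(kap),
      n_missing = sum(is.na(dia)))
  }
  fa <- one("feeding_artery", window_main)
  dv <- one("draining_vein", window_main)
  da <- if ("distal_artery" %in% names(centrelines)) one("distal_artery", window_distal) else
    c(diameter = NA_real_, curvature = NA_real_, n_missing = NA_real_)
  ang <- anastomosis_angle(centrelines$feeding_artery, centrelines$draining_vein,
                           fit_window)
  structure(list(
    feeding_artery_diameter = unname(fa["diameter"]),
    feeding_artery_curvature = unname(fa["curvature"]),
    draining_vein_diameter = unname(dv["diameter"]),
    draining_vein_curvature = unname(dv["curvature"]),
    distal_artery_diameter = unname(da["diameter"]),
    distal_artery_curvature = unname(da["curvature"]),
    anastomosis_angle = ang,
    vein_minus_artery_diameter = unname(dv["diameter"] - fa["diameter"])),
    class = "anatomical_summary")
}

#' @export
print.anatomical_summary <- function(x, ...) {
  cat("AVF anatomical summary\n")
  cat(sprintf("  feeding artery: D = %.2f mm, curvature = %.4f /mm\n",
              x$feeding_artery_diameter, x$feeding_artery_curvature))
  cat(sprintf("  draining vein:  D = %.2f mm, curvature = %.4f /mm\n",
              x$draining_vein_diameter, x$draining_vein_curvature))
  if (is.finite(x$distal_artery_diameter))
    cat(sprintf("  distal artery:  D = %.2f mm, curvature = %.4f /mm\n",
                x$distal_artery_diameter, x$distal_artery_curvature))
  cat(sprintf("  anastomosis angle: %.1f deg\n", x$anastomosis_angle))
  cat(sprintf("  vein - artery diameter: %.2f mm\n", x$vein_minus_artery_diameter))
  invisible(x)
}
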