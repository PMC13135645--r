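# periodic trapezoidal weights for samples in [0, T): the last interval
# wraps to t[1] + T. Errors out when any gap exceeds T/4 (coverage too
# uneven for a cycle integral).
periodic_weights <- function(times, period) {
  dt <- diff(c(times, times[1] + period))
  if (length(times) < 3) stop("need at least 3 time samples")
  if (any(dt > period / 4))
    stop("non-uniform time coverage: a gap exceeds a quarter period")
  (dt + c(dt[length(dt)], dt[-length(dt)])) / 2
}

traction_slab <- function(series, j) {
  tw <- series$traction[, , j, drop = TRUE]
  if (is.null(dim(tw))) tw <- matrix(tw, ncol = 3)
  tw
}

# time integrals sum_j w_j tau_j (vector) and sum_j w_j |tau_j| (scalar)
traction_integrals <- function(series) {
  w <- periodic_weights(series$times, series$period)
  nf <- dim(series$traction)[1]
  vec <- matrix(0, nf, 3)
  mag <- numeric(nf)
  for (j in seq_along(series$times)) {
    tw <- traction_slab(series, j)
    vec <- vec + w[j] * tw
    mag <- mag + w[j] * sqrt(rowSums(tw^2))
  }
  list(vec = vec, mag = mag, w = w)
}

#' Wall-shear metric maps: TAWSS, OSI, transverse WSS, WSS gradient
#'
#' Time integrals use periodic trapezoidal quadrature over the cycle
#' (closing the last sample back to the first).
#'
#' * `tawss()`: time-averaged wall-shear magnitude,
#'   `(1/T) integral |tau| dt` (Pa).
#' * `osi()`: oscillatory shear index,
#'   `0.5 (1 - |integral tau dt| / integral |tau| dt)`, in `[0, 0.5]`;
#'   faces with zero cumulative shear are missing.
#' * `transwss()`: transverse wall shear,
#'   `(1/T) integral |tau . (n x p)| dt` with `p` the unit mean-shear
#'   direction; faces without a mean direction are missing (not zero), with
#'   the count reported via `message()`.
#' * `wssg()`: magnitude of the intrinsic surface gradient of the TAWSS
#'   field (Pa/mm), estimated per face by a least-squares fit over its
#'   edge-connected neighbours in the tangent plane; isolated faces are
#'   missing. `time_average = TRUE` instead averages the instantaneous
#'   gradient magnitude of `|tau|(t)` over the cycle.
#'
#' @param series a [surface_field_series()].
#' @return numeric per-face vector.
#' @export
tawss <- function(series) {
  ti <- traction_integrals(series)
  ti$mag / series$period
}

#' @rdname tawss
#' @export
osi <- function(series) {
  ti <- traction_integrals(series)
  out <- 0.5 * (1 - sqrt(rowSums(ti$vec^2)) / ti$mag)
  out[ti$mag <= 0] <- NA_real_
  pmin(pmax(out, 0), 0.5)
}

#' @rdname tawss
#' @export
transwss <- function(series) {
  ti <- traction_integrals(series)
  mean_mag <- sqrt(rowSums(ti$vec^2))
  undefined <- mean_mag <= 1e-12 * pmax(ti$mag, 1e-300) | ti$mag <= 0
  p <- ti$vec / pmax(mean_mag, 1e-300)
  nrm <- face_normals(series$mesh)
  e <- cross3(nrm, p)
  out <- numeric(dim(series$traction)[1])
  w <- ti$w
  for (j in seq_along(series$times)) {
    tw <- traction_slab(series, j)
    out <- out + w[j] * abs(rowSums(tw * e))
  }
  out <- out / series$period
  if (any(undefined)) {
    message(sprintf("transwss: %d face(s) with no mean shear direction reported missing",
                    sum(undefined)))
    out[undefined] <- NA_real_
  }
  out
}

#' @rdname tawss
#' @param tawss_map per-face TAWSS (or any scalar field) to differentiate;
#'   computed from `series` when missing.
#' @param mesh the mesh carrying the field (taken from `series` if given).
#' @param time_average average instantaneous gradients over the cycle
#'   instead of differentiating the time-averaged field.
#' @export
wssg <- function(series = NULL, tawss_map = NULL, mesh = NULL,
                 time_average = FALSE) {
  if (is.null(mesh)) mesh <- series$mesh
  if (time_average) {
    if (is.null(series)) stop("time_average requires a field series")
    w <- periodic_weights(series$times, series$period)
    out <- numeric(dim(series$traction)[1])
    for (j in seq_along(series$times)) {
      mag <- sqrt(rowSums(traction_slab(series, j)^2))
      out <- out + w[j] * surface_gradient_magnitude(mesh, mag)
    }
    return(out / series$period)
  }
  if (is.null(tawss_map)) tawss_map <- tawss(series)
  surface_gradient_magnitude(mesh, tawss_map)
}

# least-squares tangent-plane gradient of a per-face scalar field, using
# edge-connected neighbour centroids
surface_gradient_magnitude <- function(mesh, field) {
  f <- mesh$faces
  nf <- nrow(f)
  e <- rbind(f[, c(1L, 2L)], f[, c(2L, 3L)], f[, c(3L, 1L)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]), sep = "_")
  fid <- rep(seq_len(nf), 3L)
  ord <- order(key)
  ks <- key[ord]; fs <- fid[ord]
  first <- which(!duplicated(ks))
  pair_a <- fs[first]
  pair_b <- fs[first + 1L]
  ok <- first + 1L <= length(ks) & ks[first] == ks[pmin(first + 1L, length(ks))]
  pair_a <- pair_a[ok]; pair_b <- pair_b[ok]
  nbrs <- split(c(pair_b, pair_a), c(pair_a, pair_b))
  cen <- face_centroids(mesh)
  nrm <- face_normals(mesh)
  out <- rep(NA_real_, nf)
  for (i in seq_len(nf)) {
    nb <- nbrs[[as.character(i)]]
    nb <- nb[!is.na(field[nb])]
    if (is.na(field[i]) || length(nb) < 2) next
    d <- cen[nb, , drop = FALSE] - matrix(cen[i, ], length(nb), 3, byrow = TRUE)
    d <- d - outer(as.vector(d %*% nrm[i, ]), nrm[i, ])   # tangent plane
    b <- plane_basis(nrm[i, ])
    X <- cbind(d %*% b$u, d %*% b$v)
    y <- field[nb] - field[i]
    g <- tryCatch(qr.solve(X, y), error = function(e) NULL)
    if (is.null(g)) next
    out[i] <- sqrt(sum(g^2))
  }
  out
}

#' Localised normalised helicity
#'
#' `LNH = (v . omega) / (|v| |omega|)`, the cosine of the angle between
#' velocity and vorticity, in `[-1, 1]`; points where either vanishes are
#' missing.
#'
#' @param snapshot a [volume_snapshot()].
#' @return per-point values in `[-1, 1]` (NA where undefined).
#' @export
lnh <- function(snapshot) {
  stopifnot(inherits(snapshot, "volume_snapshot"))
  vmag <- sqrt(rowSums(snapshot$velocity^2))
  wmag <- sqrt(rowSums(snapshot$vorticity^2))
  out <- rowSums(snapshot$velocity * snapshot$vorticity) /
    pmax(vmag * wmag, 1e-300)
  out[vmag == 0 | wmag == 0] <- NA_real_
  pmin(pmax(out, -1), 1)
}

#' All wall-shear metric maps at once
#'
#' @param series a [surface_field_series()].
#' @param snapshot optional [volume_snapshot()] for LNH.
#' @return object of class `metric_maps`: per-face `tawss`, `osi`,
#'   `transwss`, `wssg` and (if a snapshot is given) per-point `lnh`.
#' @export
metric_maps <- function(series, snapshot = NULL) {
  tw <- tawss(series)
  structure(list(tawss = tw, osi = osi(series), transwss = transwss(series),
                 wssg = wssg(series, tawss_map = tw),
                 lnh = if (!is.null(snapshot)) lnh(snapshot),
                 mesh = series$mesh),
            class = "metric_maps")
}

#' @export
print.metric_maps <- function(x, ...) {
  for (nm in c("tawss", "osi", "transwss", "wssg"))
    cat(sprintf("  %-9s mean %.4g (missing %d)\n", nm,
                mean(x[[nm]], na.rm = TRUE), sum(is.na(x[[nm]]))))
  invisible(x)
}

#' Area-weighted per-segment means of metric maps
#'
#' @param maps a [metric_maps()] (or named list of per-face vectors plus a
#'   `mesh` entry).
#' @param segments a `segment_table` from [partition_segments()] on the same
#'   mesh.
#' @return tidy `data.frame` with columns `limb`, `seg_index`, `s_start`,
#'   `s_end`, `is_anastomosis`, `is_partial`, `metric`, `value`, `area_mm2`.
#'   Segments whose faces are all missing get `NA` with a warning.
#' @export
segment_aggregate <- function(maps, segments) {
  mesh <- maps$mesh
  if (is.null(mesh)) stop("maps must carry the mesh they refer to")
  ar <- face_areas(mesh)
  metric_names <- intersect(c("tawss", "osi", "transwss", "wssg"), names(maps))
  rows <- list()
  for (i in seq_len(nrow(segments))) {
    fidx <- segments$faces[[i]]
    for (mn in metric_names) {
      v <- maps[[mn]][fidx]
      a <- ar[fidx]
      keep <- !is.na(v)
      val <- if (length(fidx) && any(keep)) sum(v[keep] * a[keep]) / sum(a[keep])
             else NA_real_
      if (length(fidx) && !any(keep))
        warning(sprintf("segment %s/%d: all faces missing for %s",
                        segments$limb[i], segments$seg_index[i], mn))
      rows[[length(rows) + 1L]] <- data.frame(
        limb = segments$limb[i], seg_index = segments$seg_index[i],
        s_start = segments$s_start[i], s_end = segments$s_end[i],
        is_anastomosis = segments$is_anastomosis[i],
        is_partial = segments$is_partial[i],
        metric = mn, value = val,
        area_mm2 = if (length(fidx)) sum(a) else 0,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
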