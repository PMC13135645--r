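#' Triangle surface mesh
#'
#' Lightweight container for a triangulated lumen surface. Coordinates are in
#' millimetres throughout the package. Faces are 1-based vertex index triples
#' wound counter-clockwise when seen from outside (outward normals).
#'
#' @param vertices numeric matrix, n x 3, vertex coordinates (mm).
#' @param faces integer matrix, m x 3, vertex indices (1-based).
#' @param labels optional character vector of per-face labels (e.g. limb
#'   identity: `"feeding_artery"`, `"draining_vein"`, `"distal_artery"`,
#'   `"anastomosis"`, or `"lateral"` / `"cap_start"` / `"cap_end"` for simple
#'   tubes).
#' @return an object of class `tri_mesh`.
#' @export
tri_mesh <- function(vertices, faces, labels = NULL) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) stop("vertices must be an n x 3 matrix")
  if (ncol(faces) != 3L) stop("faces must be an m x 3 matrix")
  if (any(faces < 1L) || any(faces > nrow(vertices)))
    stop("face indices out of range")
  if (!is.null(labels)) {
    labels <- as.character(labels)
    if (length(labels) != nrow(faces))
      stop("labels must have one entry per face")
  }
  structure(list(vertices = vertices, faces = faces, labels = labels),
            class = "tri_mesh")
}

#' @export
print.tri_mesh <- function(x, ...) {
  cat(sprintf("tri_mesh: %d vertices, %d faces", nrow(x$vertices), nrow(x$faces)))
  if (!is.null(x$labels)) {
    tab <- table(x$labels)
    cat(sprintf(" | labels: %s",
                paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = ", ")))
  }
  cat(sprintf("\nbbox (mm): [%s] to [%s]\n",
              paste(sprintf("%.1f", apply(x$vertices, 2, min)), collapse = ", "),
              paste(sprintf("%.1f", apply(x$vertices, 2, max)), collapse = ", ")))
  invisible(x)
}

face_vertex_array <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  list(a = v[f[, 1L], , drop = FALSE],
       b = v[f[, 2L], , drop = FALSE],
       c = v[f[, 3L], , drop = FALSE])
}

cross3 <- function(u, v) {
  cbind(u[, 2L] * v[, 3L] - u[, 3L] * v[, 2L],
        u[, 3L] * v[, 1L] - u[, 1L] * v[, 3L],
        u[, 1L] * v[, 2L] - u[, 2L] * v[, 1L])
}

#' Per-face areas, normals and centroids
#'
#' @param mesh a [tri_mesh()].
#' @return `face_areas`: numeric vector of triangle areas (mm^2).
#' @export
face_areas <- function(mesh) {
  fv <- face_vertex_array(mesh)
  cr <- cross3(fv$b - fv$a, fv$c - fv$a)
  0.5 * sqrt(rowSums(cr^2))
}

#' @rdname face_areas
#' @return `face_normals`: m x 3 matrix of unit outward normals.
#' @export
face_normals <- function(mesh) {
  fv <- face_vertex_array(mesh)
  cr <- cross3(fv$b - fv$a, fv$c - fv$a)
  nrm <- sqrt(rowSums(cr^2))
  nrm[nrm == 0] <- 1
  cr / nrm
}

#' @rdname face_areas
#' @return `face_centroids`: m x 3 matrix of triangle centroids (mm).
#' @export
face_centroids <- function(mesh) {
  fv <- face_vertex_array(mesh)
  (fv$a + fv$b + fv$c) / 3
}

#' Total surface area and enclosed volume
#'
#' Volume uses the divergence theorem over the closed surface; it is only
#' meaningful for watertight, outward-oriented meshes.
#'
#' @param mesh a [tri_mesh()].
#' @return area in mm^2 / signed volume in mm^3.
#' @export
mesh_area <- function(mesh) sum(face_areas(mesh))

#' @rdname mesh_area
#' @export
mesh_volume <- function(mesh) {
  fv <- face_vertex_array(mesh)
  sum(rowSums(fv$a * cross3(fv$b, fv$c))) / 6
}

mesh_edge_keys <- function(faces) {
  e <- rbind(faces[, c(1L, 2L)], faces[, c(2L, 3L)], faces[, c(3L, 1L)])
  paste(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L]), sep = "_")
}

#' Watertightness check
#'
#' A closed manifold triangle mesh has every undirected edge shared by exactly
#' two faces.
#'
#' @param mesh a [tri_mesh()].
#' @return logical scalar.
#' @export
is_watertight <- function(mesh) {
  all(table(mesh_edge_keys(mesh$faces)) == 2L)
}

#' Test whether points lie inside a closed mesh
#'
#' Ray-parity test along +x with jittered restart on degenerate hits.
#'
#' @param mesh a watertight [tri_mesh()].
#' @param points k x 3 matrix of query points (mm).
#' @return logical vector of length k.
#' @export
points_in_mesh <- function(mesh, points) {
  points <- rbind(points)
  fv <- face_vertex_array(mesh)
  vapply(seq_len(nrow(points)), function(i) {
    p <- points[i, ]
    for (attempt in 1:5) {
      dir <- if (attempt == 1) c(1, 0, 0) else {
        d <- stats::rnorm(3); d / sqrt(sum(d^2))
      }
      hits <- ray_mesh_hits(p, dir, fv)
      if (!is.null(hits)) return(length(hits) %% 2L == 1L)
    }
    stop("point-in-mesh parity test failed (degenerate ray hits)")
  }, logical(1))
}

# Moller-Trumbore over all faces; returns hit distances t > 0 or NULL when a
# hit is too close to an edge/vertex to trust parity.
ray_mesh_hits <- function(origin, dir, fv) {
  eps <- 1e-9
  e1 <- fv$b - fv$a
  e2 <- fv$c - fv$a
  pv <- cross3(matrix(dir, nrow(e2), 3, byrow = TRUE), e2)
  det <- rowSums(e1 * pv)
  ok <- abs(det) > eps
  if (!any(ok)) return(numeric(0))
  tvec <- sweep(-fv$a, 2, origin, "+")   # origin - a
  u <- rowSums(tvec * pv) / det
  qv <- cross3(tvec, e1)
  v <- rowSums(sweep(qv, 2, dir, "*")) / det
  t <- rowSums(e2 * qv) / det
  inside <- ok & u > -eps & v > -eps & (u + v) < 1 + eps & t > eps
  near_edge <- inside & (u < eps | v < eps | (u + v) > 1 - eps)
  if (any(near_edge)) return(NULL)
  t[inside]
}

#' Write and read triangle meshes (binary STL, ASCII PLY)
#'
#' STL stores coordinates in 32-bit floats and duplicates shared vertices;
#' reading reconstructs shared vertices by exact coordinate matching. PLY is
#' written in ASCII at full double precision and preserves vertex sharing.
#' Face labels, which neither format carries, can be written to a sidecar CSV
#' (`face_index,label`) with [write_face_labels()].
#'
#' @param mesh a [tri_mesh()].
#' @param path file path.
#' @return `read_stl()` / `read_ply()` return a [tri_mesh()].
#' @export
write_stl <- function(mesh, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  header <- charToRaw(formatC("tri_mesh binary STL (mm)", width = 80, flag = "-"))
  writeBin(header[1:80], con)
  writeBin(as.integer(nrow(mesh$faces)), con, size = 4, endian = "little")
  fv <- face_vertex_array(mesh)
  nrm <- face_normals(mesh)
  block <- t(cbind(nrm, fv$a, fv$b, fv$c))  # 12 floats per face
  for (i in seq_len(nrow(mesh$faces))) {
    writeBin(as.numeric(block[, i]), con, size = 4, endian = "little")
    writeBin(as.integer(0), con, size = 2, endian = "little")
  }
  invisible(path)
}

#' @rdname write_stl
#' @export
read_stl <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  invisible(readBin(con, "raw", 80))
  nf <- readBin(con, "integer", 1, size = 4, endian = "little")
  if (!length(nf) || nf <= 0) stop("malformed STL: bad face count in ", path)
  tri <- matrix(NA_real_, nf, 9)
  for (i in seq_len(nf)) {
    rec <- readBin(con, "numeric", 12, size = 4, endian = "little")
    if (length(rec) < 12) stop(sprintf("malformed STL: truncated at face %d of %d", i, nf))
    readBin(con, "integer", 1, size = 2, endian = "little")
    tri[i, ] <- rec[4:12]
  }
  verts <- rbind(tri[, 1:3], tri[, 4:6], tri[, 7:9])
  key <- paste(verts[, 1], verts[, 2], verts[, 3], sep = "|")
  uid <- !duplicated(key)
  map <- match(key, key[uid])
  faces <- matrix(map, nf, 3)
  tri_mesh(verts[uid, , drop = FALSE], faces)
}

#' @rdname write_stl
#' @export
write_ply <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(mesh$vertices)),
               "property double x", "property double y", "property double z",
               sprintf("element face %d", nrow(mesh$faces)),
               "property list uchar int vertex_indices", "end_header"), con)
  writeLines(apply(mesh$vertices, 1, function(r) paste(sprintf("%.17g", r), collapse = " ")), con)
  writeLines(apply(mesh$faces - 1L, 1, function(r) paste(c(3L, r), collapse = " ")), con)
  invisible(path)
}

#' @rdname write_stl
#' @export
read_ply <- function(path) {
  lines <- readLines(path)
  if (!length(lines) || lines[1] != "ply") stop("malformed PLY: missing magic in ", path)
  hdr_end <- match("end_header", lines)
  if (is.na(hdr_end)) stop("malformed PLY: no end_header in ", path)
  hdr <- lines[seq_len(hdr_end)]
  nv <- as.integer(sub("element vertex ", "", grep("^element vertex ", hdr, value = TRUE)))
  nf <- as.integer(sub("element face ", "", grep("^element face ", hdr, value = TRUE)))
  if (length(nv) != 1L || length(nf) != 1L) stop("malformed PLY header in ", path)
  body <- lines[-seq_len(hdr_end)]
  if (length(body) < nv + nf) stop(sprintf("malformed PLY: expected %d body lines, found %d", nv + nf, length(body)))
  verts <- matrix(scan(text = body[seq_len(nv)], quiet = TRUE), nv, 3, byrow = TRUE)
  frows <- strsplit(body[nv + seq_len(nf)], " +")
  faces <- t(vapply(frows, function(r) as.integer(r[2:4]) + 1L, integer(3)))
  tri_mesh(verts, faces)
}

#' @rdname write_stl
#' @export
write_face_labels <- function(mesh, path) {
  if (is.null(mesh$labels)) stop("mesh carries no face labels")
  utils::write.csv(data.frame(face_index = seq_len(nrow(mesh$faces)),
                              label = mesh$labels),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_stl
#' @export
read_face_labels <- function(mesh, path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("face_index", "label") %in% names(tab)))
    stop("label sidecar must have columns face_index,label")
  if (nrow(tab) != nrow(mesh$faces)) stop("label sidecar row count does not match mesh")
  mesh$labels <- tab$label[order(tab$face_index)]
  mesh
}
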