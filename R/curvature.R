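#' Triangle mesh of a spherocylinder (rod-shaped cell body)
#'
#' Builds a closed, watertight, genus-0 triangle mesh of a cylinder of length
#' `body_length` capped by two hemispheres of the given radius, with its axis
#' along x and centered at the origin. `body_length = 0` yields a sphere.
#' Cap vertices lie exactly on spheres of the given radius, so the analytic
#' Gaussian curvature is `1/radius^2` on the caps and 0 on the cylindrical
#' body — a fixture with known ground truth for curvature estimators.
#'
#' @param body_length Length of the cylindrical section, nm (>= 0).
#' @param radius Radius, nm (> 0).
#' @param subdivisions Number of segments around the circumference (>= 3);
#'   axial resolution is matched to keep triangles near-regular.
#'
#' @return A list of class `"curved_mesh"`: `vertices` (n x 3, nm), `faces`
#'   (m x 3, 1-based indices, outward-oriented), `K = NULL`, `area = NULL`.
#' @examples
#' m <- make_spherocylinder_mesh(2000, 400, 24)
#' nrow(m$vertices) - nrow(unique_edges(m)) + nrow(m$faces) # Euler = 2
#' @export
make_spherocylinder_mesh <- function(body_length, radius, subdivisions = 32L) {
  check_scalar(body_length, "body_length", min = 0)
  check_scalar(radius, "radius", min = .Machine$double.eps)
  check_scalar(subdivisions, "subdivisions", min = 3)
  nc <- as.integer(subdivisions)
  # latitude rings per cap; spacing comparable to circumferential spacing
  n_phi <- max(3L, ceiling(nc / 4))
  phi <- seq(0, pi / 2, length.out = n_phi + 1L)[-1L] # exclude the pole
  theta <- seq(0, 2 * pi, length.out = nc + 1L)[-(nc + 1L)]
  half <- body_length / 2
  # ring axial positions and radii: left pole cap, body, right cap
  ring_x <- c(-half - radius * cos(phi), NULL)
  ring_r <- radius * sin(phi)
  if (body_length > 0) {
    circ_step <- 2 * pi * radius / nc
    n_body <- max(1L, round(body_length / circ_step))
    body_x <- seq(-half, half, length.out = n_body + 1L)[-c(1L, n_body + 1L)]
    if (length(body_x)) {
      ring_x <- c(ring_x, body_x)
      ring_r <- c(ring_r, rep(radius, length(body_x)))
    }
    # the phi = pi/2 rings of the two caps sit at -half and +half and double
    # as the body end rings
    ring_x <- c(ring_x, half + radius * cos(rev(phi)))
    ring_r <- c(ring_r, radius * sin(rev(phi)))
  } else {
    # sphere: mirror the cap rings, sharing the equator ring once
    ring_x <- c(ring_x, radius * cos(rev(phi))[-1L] )
    ring_r <- c(ring_r, radius * sin(rev(phi))[-1L])
  }
  o <- order(ring_x)
  ring_x <- ring_x[o]
  ring_r <- ring_r[o]
  n_ring <- length(ring_x)
  verts <- matrix(0, 2L + n_ring * nc, 3)
  verts[1, ] <- c(-half - radius, 0, 0) # left pole
  for (i in seq_len(n_ring)) {
    idx <- 1L + (i - 1L) * nc + seq_len(nc)
    verts[idx, ] <- cbind(ring_x[i], ring_r[i] * cos(theta),
                          ring_r[i] * sin(theta))
  }
  right_pole <- nrow(verts)
  verts[right_pole, ] <- c(half + radius, 0, 0)
  ring_idx <- function(i) 1L + (i - 1L) * nc + seq_len(nc)
  faces <- list()
  # left pole fan (outward orientation: normal pointing away from interior)
  r1 <- ring_idx(1L)
  faces[[1]] <- cbind(1L, r1, c(r1[-1L], r1[1L]))
  # ring-to-ring quads
  for (i in seq_len(n_ring - 1L)) {
    a <- ring_idx(i)
    b <- ring_idx(i + 1L)
    a2 <- c(a[-1L], a[1L])
    b2 <- c(b[-1L], b[1L])
    faces[[length(faces) + 1L]] <- cbind(a, b, b2)
    faces[[length(faces) + 1L]] <- cbind(a, b2, a2)
  }
  rl <- ring_idx(n_ring)
  faces[[length(faces) + 1L]] <- cbind(right_pole, c(rl[-1L], rl[1L]), rl)
  faces <- do.call(rbind, faces)
  mesh <- structure(list(vertices = verts, faces = faces,
                         K = NULL, area = NULL),
                    class = "curved_mesh")
  chk <- mesh_topology(mesh)
  if (!chk$closed || chk$euler != 2L) {
    stop("subdivisions too small to close the surface", call. = FALSE)
  }
  mesh
}

# Unique undirected edges of a mesh (m x 2 matrix of vertex indices).
#' @rdname make_spherocylinder_mesh
#' @param mesh A `curved_mesh`.
#' @export
unique_edges <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  e <- t(apply(e, 1, sort))
  unique(e)
}

mesh_topology <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  cnt <- table(key)
  n_e <- length(cnt)
  list(
    V = nrow(mesh$vertices), E = n_e, F = nrow(f),
    euler = nrow(mesh$vertices) - n_e + nrow(f),
    closed = all(cnt == 2L),
    manifold = all(cnt <= 2L),
    boundary_edges = names(cnt)[cnt == 1L]
  )
}

#' Load a triangle mesh from a PLY, OFF or OBJ file
#'
#' Reads an ASCII mesh file, fan-triangulates any polygonal faces, and
#' validates that the result is a manifold mesh (every edge shared by at most
#' two faces). Vertex/edge/face counts, the Euler characteristic, and whether
#' the mesh is closed are attached.
#'
#' @param path Path to a `.ply`, `.off` or `.obj` file (ASCII).
#' @return A `curved_mesh` (with `K` unset) with attribute `"topology"`.
#' @export
load_mesh <- function(path) {
  if (!file.exists(path)) stop("mesh file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  mesh <- switch(ext,
    ply = read_ply_ascii(path),
    off = read_off_ascii(path),
    obj = read_obj_ascii(path),
    stop("unsupported mesh format `.", ext, "` (need PLY/OFF/OBJ)",
         call. = FALSE)
  )
  if (any(mesh$faces < 1L) || any(mesh$faces > nrow(mesh$vertices))) {
    stop("corrupt mesh: face indices out of range", call. = FALSE)
  }
  chk <- mesh_topology(mesh)
  if (!chk$manifold) {
    stop("non-manifold mesh: an edge is shared by more than two faces",
         call. = FALSE)
  }
  attr(mesh, "topology") <- chk
  mesh
}

read_ply_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || trimws(lines[1]) != "ply") {
    stop("corrupt mesh file: missing `ply` magic line", call. = FALSE)
  }
  hdr_end <- which(trimws(lines) == "end_header")[1]
  if (is.na(hdr_end)) stop("corrupt PLY: no end_header", call. = FALSE)
  hdr <- lines[seq_len(hdr_end)]
  if (!any(grepl("^format\\s+ascii", trimws(hdr)))) {
    stop("only ASCII PLY is supported", call. = FALSE)
  }
  nv <- as.integer(sub(".*element\\s+vertex\\s+(\\d+).*", "\\1",
                       grep("element\\s+vertex", hdr, value = TRUE)[1]))
  nf <- as.integer(sub(".*element\\s+face\\s+(\\d+).*", "\\1",
                       grep("element\\s+face", hdr, value = TRUE)[1]))
  if (is.na(nv) || is.na(nf)) stop("corrupt PLY header", call. = FALSE)
  body <- lines[(hdr_end + 1L):length(lines)]
  body <- body[nzchar(trimws(body))]
  if (length(body) < nv + nf) stop("corrupt PLY: truncated body", call. = FALSE)
  vert_tok <- strsplit(trimws(body[seq_len(nv)]), "\\s+")
  verts <- t(vapply(vert_tok, function(t) as.numeric(t[1:3]), numeric(3)))
  if (any(!is.finite(verts))) stop("corrupt PLY: non-numeric vertex", call. = FALSE)
  face_tok <- strsplit(trimws(body[nv + seq_len(nf)]), "\\s+")
  faces <- triangulate_faces(lapply(face_tok, function(t) {
    k <- as.integer(t[1])
    as.integer(t[1L + seq_len(k)]) + 1L # PLY is 0-based
  }))
  structure(list(vertices = verts, faces = faces, K = NULL, area = NULL),
            class = "curved_mesh")
}

read_off_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  if (!length(lines) || trimws(lines[1]) != "OFF") {
    stop("corrupt mesh file: missing OFF magic line", call. = FALSE)
  }
  counts <- as.integer(strsplit(trimws(lines[2]), "\\s+")[[1]])
  nv <- counts[1]; nf <- counts[2]
  vert_tok <- strsplit(trimws(lines[2L + seq_len(nv)]), "\\s+")
  verts <- t(vapply(vert_tok, function(t) as.numeric(t[1:3]), numeric(3)))
  face_tok <- strsplit(trimws(lines[2L + nv + seq_len(nf)]), "\\s+")
  faces <- triangulate_faces(lapply(face_tok, function(t) {
    k <- as.integer(t[1])
    as.integer(t[1L + seq_len(k)]) + 1L # OFF is 0-based
  }))
  structure(list(vertices = verts, faces = faces, K = NULL, area = NULL),
            class = "curved_mesh")
}

read_obj_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^v\\s", lines, value = TRUE)
  fl <- grep("^f\\s", lines, value = TRUE)
  if (!length(vl) || !length(fl)) stop("corrupt OBJ file", call. = FALSE)
  verts <- t(vapply(strsplit(trimws(vl), "\\s+"),
                    function(t) as.numeric(t[2:4]), numeric(3)))
  faces <- triangulate_faces(lapply(strsplit(trimws(fl), "\\s+"), function(t) {
    as.integer(sub("/.*", "", t[-1])) # OBJ is 1-based; strip vt/vn refs
  }))
  structure(list(vertices = verts, faces = faces, K = NULL, area = NULL),
            class = "curved_mesh")
}

triangulate_faces <- function(face_list) {
  tris <- lapply(face_list, function(ix) {
    if (length(ix) < 3L || any(is.na(ix))) {
      stop("corrupt mesh: bad face record", call. = FALSE)
    }
    if (length(ix) == 3L) return(matrix(ix, 1))
    cbind(ix[1], ix[2:(length(ix) - 1L)], ix[3:length(ix)])
  })
  do.call(rbind, tris)
}

#' Write a mesh as ASCII PLY
#'
#' Per-vertex Gaussian curvature, when present, is stored in the conventional
#' `quality` vertex property.
#'
#' @param mesh A `curved_mesh`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mesh_ply <- function(mesh, path) {
  nv <- nrow(mesh$vertices)
  nf <- nrow(mesh$faces)
  has_k <- !is.null(mesh$K)
  hdr <- c("ply", "format ascii 1.0",
           paste("element vertex", nv),
           "property float x", "property float y", "property float z",
           if (has_k) "property float quality",
           paste("element face", nf),
           "property list uchar int vertex_indices",
           "end_header")
  vlines <- if (has_k) {
    paste(mesh$vertices[, 1], mesh$vertices[, 2], mesh$vertices[, 3], mesh$K)
  } else {
    paste(mesh$vertices[, 1], mesh$vertices[, 2], mesh$vertices[, 3])
  }
  flines <- paste(3, mesh$faces[, 1] - 1L, mesh$faces[, 2] - 1L,
                  mesh$faces[, 3] - 1L)
  writeLines(c(hdr, vlines, flines), path)
  invisible(path)
}

#' Discrete Gaussian curvature by angle deficit
#'
#' Estimates per-vertex Gaussian curvature as
#' `K_v = (2*pi - sum of incident triangle angles at v) / A_v`, with
#' barycentric vertex area `A_v` (one third of incident face areas) by
#' default, or the Meyer-style mixed Voronoi area. Boundary vertices use `pi`
#' in place of `2*pi`. For any closed mesh the total curvature
#' `sum(K_v * A_v)` telescopes to `2*pi*chi` (discrete Gauss-Bonnet), exactly
#' `4*pi` on genus-0 surfaces — a built-in correctness check.
#'
#' @param mesh A `curved_mesh`.
#' @param area `"barycentric"` (default) or `"mixed"` (Voronoi with obtuse
#'   handling).
#' @return The mesh with `K` (1/nm^2) and `area` (nm^2) per vertex filled in.
#'   Vertices with a zero-area star get `K = NA` and are flagged in attribute
#'   `"degenerate_vertices"`.
#' @examples
#' m <- gaussian_curvature(make_spherocylinder_mesh(0, 400, 24))
#' sum(m$K * m$area) / (4 * pi) # 1 (Gauss-Bonnet)
#' @export
gaussian_curvature <- function(mesh, area = c("barycentric", "mixed")) {
  area <- match.arg(area)
  v <- mesh$vertices
  f <- mesh$faces
  nv <- nrow(v)
  p1 <- v[f[, 1], , drop = FALSE]
  p2 <- v[f[, 2], , drop = FALSE]
  p3 <- v[f[, 3], , drop = FALSE]
  ang <- function(a, b, c) {
    u <- b - a; w <- c - a
    cosang <- rowSums(u * w) / sqrt(rowSums(u^2) * rowSums(w^2))
    acos(pmin(1, pmax(-1, cosang)))
  }
  a1 <- ang(p1, p2, p3)
  a2 <- ang(p2, p3, p1)
  a3 <- pi - a1 - a2
  cr <- cbind(
    (p2[, 2] - p1[, 2]) * (p3[, 3] - p1[, 3]) -
      (p2[, 3] - p1[, 3]) * (p3[, 2] - p1[, 2]),
    (p2[, 3] - p1[, 3]) * (p3[, 1] - p1[, 1]) -
      (p2[, 1] - p1[, 1]) * (p3[, 3] - p1[, 3]),
    (p2[, 1] - p1[, 1]) * (p3[, 2] - p1[, 2]) -
      (p2[, 2] - p1[, 2]) * (p3[, 1] - p1[, 1])
  )
  f_area <- 0.5 * sqrt(rowSums(cr^2))
  vid <- c(f[, 1], f[, 2], f[, 3])
  angles <- c(a1, a2, a3)
  angle_sum <- as.numeric(rowsum(angles, vid, reorder = TRUE))
  present <- sort(unique(vid))
  full_angle <- numeric(nv)
  full_angle[present] <- angle_sum
  if (area == "barycentric") {
    va <- numeric(nv)
    fa3 <- rep(f_area / 3, 3)
    va[present] <- as.numeric(rowsum(fa3, vid, reorder = TRUE))
  } else {
    va <- mixed_voronoi_area(v, f, cbind(a1, a2, a3), f_area)
  }
  chk <- mesh_topology(mesh)
  full_circle <- rep(2 * pi, nv)
  if (length(chk$boundary_edges)) {
    bverts <- unique(as.integer(unlist(strsplit(chk$boundary_edges, " "))))
    full_circle[bverts] <- pi
  }
  deficit <- full_circle - full_angle
  K <- ifelse(va > 0, deficit / va, NA_real_)
  mesh$K <- K
  mesh$area <- va
  attr(mesh, "topology") <- chk
  attr(mesh, "degenerate_vertices") <- which(va <= 0)
  mesh
}

# Meyer et al. mixed Voronoi vertex areas: Voronoi area within non-obtuse
# triangles, area/2 at the obtuse corner and area/4 at the others otherwise.
mixed_voronoi_area <- function(v, f, angles, f_area) {
  nv <- nrow(v)
  va <- numeric(nv)
  cot <- function(x) cos(x) / sin(x)
  e2 <- function(a, b) rowSums((v[f[, a], , drop = FALSE] -
                                  v[f[, b], , drop = FALSE])^2)
  # squared edge lengths opposite to each corner
  l1 <- e2(2, 3); l2 <- e2(3, 1); l3 <- e2(1, 2)
  obtuse <- angles > pi / 2
  any_obtuse <- rowSums(obtuse) > 0
  # Voronoi contributions for non-obtuse triangles
  vor1 <- (l2 * cot(angles[, 2]) + l3 * cot(angles[, 3])) / 8
  vor2 <- (l3 * cot(angles[, 3]) + l1 * cot(angles[, 1])) / 8
  vor3 <- (l1 * cot(angles[, 1]) + l2 * cot(angles[, 2])) / 8
  contrib <- cbind(vor1, vor2, vor3)
  for (k in 1:3) {
    co <- contrib[, k]
    co[any_obtuse] <- ifelse(obtuse[any_obtuse, k],
                             f_area[any_obtuse] / 2,
                             f_area[any_obtuse] / 4)
    contrib[, k] <- co
  }
  vid <- c(f[, 1], f[, 2], f[, 3])
  co_all <- c(contrib[, 1], contrib[, 2], contrib[, 3])
  present <- sort(unique(vid))
  va[present] <- as.numeric(rowsum(co_all, vid, reorder = TRUE))
  va
}

#' Axial profile of absolute Gaussian curvature
#'
#' Bins mesh vertices into equal-length bins along an axis direction and
#' reports the area-weighted mean |K| per bin — the mesh-side analogue of the
#' 40-bin axial S-layer profiles, quantifying how curvature concentrates at
#' the cell poles.
#'
#' @param mesh A `curved_mesh` with `K` computed.
#' @param axis Direction vector (default x axis).
#' @param n_bins Number of bins (default 40).
#' @return data.frame `bin`, `s_mid` (normalized axial position of bin
#'   center), `mean_abs_k`, `area`. Empty bins have `NA` curvature.
#' @export
curvature_profile <- function(mesh, axis = c(1, 0, 0), n_bins = 40L) {
  if (is.null(mesh$K)) stop("run gaussian_curvature() first", call. = FALSE)
  check_scalar(n_bins, "n_bins", min = 1)
  axis <- axis / sqrt(sum(axis^2))
  s <- as.numeric(mesh$vertices %*% axis)
  rng <- range(s)
  u <- (s - rng[1]) / (rng[2] - rng[1])
  bin <- pmin(floor(u * n_bins), n_bins - 1L) + 1L
  ok <- is.finite(mesh$K)
  wsum <- rowsum((abs(mesh$K) * mesh$area)[ok], bin[ok], reorder = TRUE)
  asum <- rowsum(mesh$area[ok], bin[ok], reorder = TRUE)
  out <- data.frame(bin = seq_len(n_bins),
                    s_mid = (seq_len(n_bins) - 0.5) / n_bins,
                    mean_abs_k = NA_real_, area = 0)
  present <- as.integer(rownames(wsum))
  out$mean_abs_k[present] <- wsum[, 1] / asum[, 1]
  out$area[present] <- asum[, 1]
  out
}

#' Export per-vertex curvature as CSV
#'
#' @param mesh A `curved_mesh` with `K` computed.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_curvature_csv <- function(mesh, path) {
  if (is.null(mesh$K)) stop("run gaussian_curvature() first", call. = FALSE)
  df <- data.frame(vertex = seq_len(nrow(mesh$vertices)),
                   x = mesh$vertices[, 1], y = mesh$vertices[, 2],
                   z = mesh$vertices[, 3],
                   K = mesh$K, absK = abs(mesh$K), area = mesh$area)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
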