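# Triangle-mesh data type and geometric conditioning utilities.

#' Construct a triangle surface mesh
#'
#' The basic geometric container of the package: vertex coordinates in
#' millimetres and counter-clockwise (outward-normal) triangle connectivity.
#'
#' @param vertices numeric V x 3 matrix of vertex coordinates (mm).
#' @param faces integer F x 3 matrix of 1-based vertex indices,
#'   counter-clockwise winding viewed from outside.
#' @param label free-text identifier.
#' @param side which body side the surface belongs to: `"left"`, `"right"`
#'   or `"unknown"`.
#' @param validate check invariants (index range, degenerate faces, finite
#'   coordinates).
#' @return An object of class `triangle_mesh` with elements `vertices`,
#'   `faces`, `label`, `side`.
#' @export
triangle_mesh <- function(vertices, faces, label = "", side = "unknown",
                          validate = TRUE) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  dimnames(vertices) <- NULL
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  dimnames(faces) <- NULL
  side <- match.arg(side, c("left", "right", "unknown"))
  mesh <- structure(
    list(vertices = vertices, faces = faces, label = as.character(label),
         side = side),
    class = "triangle_mesh")
  if (validate) validate_mesh(mesh)
  mesh
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat(sprintf("triangle_mesh '%s' (%s): %d vertices, %d faces\n",
              x$label, x$side, nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

validate_mesh <- function(mesh, require_nondegenerate = TRUE) {
  v <- mesh$vertices
  f <- mesh$faces
  if (ncol(v) != 3L) stop("vertices must be a V x 3 matrix")
  if (nrow(v) == 0L) stop("empty mesh: no vertices")
  if (!all(is.finite(v))) stop("vertices must be finite")
  if (nrow(f) > 0L) {
    if (ncol(f) != 3L) stop("faces must be an F x 3 matrix")
    if (min(f) < 1L || max(f) > nrow(v))
      stop("face indices out of range [1, V]")
    dup <- f[, 1] == f[, 2] | f[, 1] == f[, 3] | f[, 2] == f[, 3]
    if (any(dup)) stop("degenerate faces: repeated vertex indices")
    if (require_nondegenerate) {
      a <- face_areas(mesh)
      tol <- 1e-12 * max(1, max(abs(v)))^2
      if (any(a <= tol)) stop("degenerate faces: zero area")
    }
  }
  invisible(mesh)
}

# F x 3 matrix of per-face corner coordinates stacked: helper
face_corner <- function(mesh, k) mesh$vertices[mesh$faces[, k], , drop = FALSE]

row_cross <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

face_normals_raw <- function(mesh) {
  p1 <- face_corner(mesh, 1)
  row_cross(face_corner(mesh, 2) - p1, face_corner(mesh, 3) - p1)
}

face_areas <- function(mesh) {
  n <- face_normals_raw(mesh)
  0.5 * sqrt(rowSums(n^2))
}

#' Per-vertex outward normals (area weighted)
#'
#' @param mesh a [triangle_mesh()].
#' @return V x 3 matrix of unit normals.
#' @export
vertex_normals <- function(mesh) {
  n <- face_normals_raw(mesh)
  V <- nrow(mesh$vertices)
  acc <- matrix(0, V, 3)
  for (k in 1:3) {
    idx <- mesh$faces[, k]
    for (j in 1:3) acc[, j] <- acc[, j] + rowsum_fast(n[, j], idx, V)
  }
  len <- sqrt(rowSums(acc^2))
  len[len == 0] <- 1
  acc / len
}

rowsum_fast <- function(x, idx, n) {
  out <- numeric(n)
  s <- rowsum(x, idx)
  out[as.integer(rownames(s))] <- s[, 1]
  out
}

# undirected edge list: E x 2 (a < b) plus adjacent-face counts
mesh_edges <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  key <- (as.numeric(e[, 1]) - 1) * nrow(mesh$vertices) + as.numeric(e[, 2])
  tab <- table(key)
  ukey <- as.numeric(names(tab))
  a <- floor((ukey - 1) / nrow(mesh$vertices)) + 1
  b <- ukey - (a - 1) * nrow(mesh$vertices)
  list(edges = cbind(as.integer(a), as.integer(b)),
       n_faces = as.integer(tab))
}

edge_lengths <- function(mesh, edges = NULL) {
  if (is.null(edges)) edges <- mesh_edges(mesh)$edges
  sqrt(rowSums((mesh$vertices[edges[, 1], , drop = FALSE] -
                mesh$vertices[edges[, 2], , drop = FALSE])^2))
}

#' Mesh quality report
#'
#' Summarizes counts, boundary edges, connected components, edge-length
#' statistics and manifoldness — the properties that matter before a mesh
#' enters model building (uniform point distribution, watertightness).
#'
#' @param mesh a [triangle_mesh()].
#' @return list of class `mesh_quality_report`.
#' @export
mesh_quality <- function(mesh) {
  ed <- mesh_edges(mesh)
  len <- edge_lengths(mesh, ed$edges)
  g <- mesh_graph(mesh)
  comp <- igraph::components(g)
  structure(list(
    n_vertices = nrow(mesh$vertices),
    n_faces = nrow(mesh$faces),
    n_boundary_edges = sum(ed$n_faces == 1L),
    n_components = comp$no,
    edge_length_median_mm = stats::median(len),
    edge_length_iqr_mm = unname(diff(stats::quantile(len, c(0.25, 0.75)))),
    edge_length_range_mm = range(len),
    is_manifold = all(ed$n_faces <= 2L)
  ), class = "mesh_quality_report")
}

#' @export
print.mesh_quality_report <- function(x, ...) {
  cat(sprintf(paste0("mesh quality: V=%d F=%d, %d boundary edge(s), ",
                     "%d component(s), median edge %.3f mm, manifold: %s\n"),
              x$n_vertices, x$n_faces, x$n_boundary_edges, x$n_components,
              x$edge_length_median_mm, x$is_manifold))
  invisible(x)
}

mesh_graph <- function(mesh) {
  ed <- mesh_edges(mesh)$edges
  igraph::graph_from_edgelist(ed, directed = FALSE)
}

#' Area-weighted surface centroid
#'
#' The centre of mass of the surface: the face-area-weighted mean of face
#' centroids. Unlike the plain vertex mean it is invariant to triangulation
#' density, which matters when meshes of different resolutions are aligned
#' by their centres of mass.
#'
#' @param mesh a [triangle_mesh()].
#' @param method `"surface"` (default, area weighted) or `"vertex"` (plain
#'   vertex mean).
#' @return length-3 numeric vector (mm).
#' @export
centroid <- function(mesh, method = c("surface", "vertex")) {
  method <- match.arg(method)
  if (method == "vertex" || nrow(mesh$faces) == 0L)
    return(colMeans(mesh$vertices))
  a <- face_areas(mesh)
  tot <- sum(a)
  if (tot <= 0) stop("degenerate geometry: total surface area is zero")
  fc <- (face_corner(mesh, 1) + face_corner(mesh, 2) + face_corner(mesh, 3)) / 3
  colSums(fc * a) / tot
}

#' Translate a mesh so its centroid sits at the origin
#'
#' @inheritParams centroid
#' @return list with `mesh` (translated) and `translation` (the subtracted
#'   centroid vector, mm).
#' @export
translate_to_origin <- function(mesh, method = c("surface", "vertex")) {
  ctr <- centroid(mesh, method = match.arg(method))
  out <- mesh
  out$vertices <- sweep(mesh$vertices, 2, ctr)
  list(mesh = out, translation = ctr)
}

#' Taubin lambda/mu mesh smoothing
#'
#' Two-step low-pass filter that smooths surface noise without the volume
#' shrinkage of plain Laplacian smoothing: each iteration applies an
#' umbrella-operator step with positive factor `lambda` followed by a
#' negative ("inflate") step with factor `mu`.
#'
#' @param mesh a manifold [triangle_mesh()].
#' @param iterations number of lambda/mu passes.
#' @param lambda shrink factor in (0, 1).
#' @param mu inflate factor, negative with `abs(mu) > lambda`.
#' @return smoothed [triangle_mesh()] (same topology).
#' @export
taubin_smooth <- function(mesh, iterations = 10L, lambda = 0.5, mu = -0.53) {
  stopifnot(lambda > 0, lambda < 1, mu < 0, -mu > lambda)
  if (iterations == 0L) return(mesh)
  q <- mesh_quality(mesh)
  if (!q$is_manifold) stop("taubin_smooth requires a manifold mesh")
  ed <- mesh_edges(mesh)$edges
  V <- nrow(mesh$vertices)
  A <- Matrix::sparseMatrix(i = c(ed[, 1], ed[, 2]), j = c(ed[, 2], ed[, 1]),
                            x = 1, dims = c(V, V))
  deg <- Matrix::rowSums(A)
  deg[deg == 0] <- 1
  x <- mesh$vertices
  for (it in seq_len(iterations)) {
    d <- as.matrix(A %*% x) / deg - x
    x <- x + lambda * d
    d <- as.matrix(A %*% x) / deg - x
    x <- x + mu * d
  }
  out <- mesh
  out$vertices <- x
  out
}

#' Isotropic remeshing to a target edge length
#'
#' Produces a uniform triangulation of the input surface by iterated edge
#' splitting, collapsing, valence-equalizing flips and tangential
#' relaxation, with every vertex projected back onto the input surface.
#' Used to give every shape in a population a comparable, uniform point
#' distribution (default target 1.5 mm for hemipelvis work).
#'
#' @param mesh a manifold, connected [triangle_mesh()].
#' @param target_edge_length_mm desired edge length (mm).
#' @param iterations outer split/collapse/flip/relax iterations.
#' @param jitter fraction of the target length used as a one-off random
#'   tangential perturbation; nonzero values decorrelate the triangulations
#'   of near-identical inputs.
#' @param seed integer seed for the jitter.
#' @return remeshed [triangle_mesh()].
#' @export
isotropic_remesh <- function(mesh, target_edge_length_mm, iterations = 5L,
                             jitter = 0, seed = 1L) {
  stopifnot(target_edge_length_mm > 0)
  bbox <- apply(mesh$vertices, 2, range)
  diag_len <- sqrt(sum((bbox[2, ] - bbox[1, ])^2))
  if (target_edge_length_mm >= diag_len / 4)
    stop("target edge length too large relative to the mesh (>= diagonal/4)")
  feat <- mesh$vertices[abs(angle_defects(mesh)) > 0.45, , drop = FALSE]
  res <- .cpp_remesh(mesh$vertices, mesh$faces - 1L, target_edge_length_mm,
                     as.integer(iterations), jitter, as.integer(seed),
                     feat)
  if (nrow(res$vertices) < 4L)
    stop("remeshing collapsed the mesh below 4 vertices")
  triangle_mesh(res$vertices, res$faces + 1L, label = mesh$label,
                side = mesh$side, validate = FALSE)
}

# discrete Gaussian curvature proxy: 2*pi minus the angle sum at each
# vertex; large magnitudes mark cone-like apexes worth preserving
angle_defects <- function(mesh) {
  V <- nrow(mesh$vertices)
  total <- rep(2 * pi, V)
  for (k in 1:3) {
    a <- face_corner(mesh, k)
    b <- face_corner(mesh, k %% 3 + 1)
    c <- face_corner(mesh, (k + 1) %% 3 + 1)
    u <- b - a; w <- c - a
    cosang <- rowSums(u * w) /
      pmax(sqrt(rowSums(u^2)) * sqrt(rowSums(w^2)), 1e-300)
    ang <- acos(pmin(1, pmax(-1, cosang)))
    total <- total - rowsum_fast(ang, mesh$faces[, k], V)
  }
  total
}

#' Mirror a mesh across a sagittal (axis-aligned) plane
#'
#' Reflects coordinates across the plane `axis = offset` and reverses the
#' face winding so outward normals stay outward. The `side` flag is
#' flipped, supporting contralateral (left/right) comparisons under the
#' usual bilateral-symmetry assumption.
#'
#' @param mesh a [triangle_mesh()].
#' @param axis reflection plane normal: `"x"`, `"y"` or `"z"`.
#' @param offset_mm plane position along that axis.
#' @return mirrored [triangle_mesh()].
#' @export
mirror_sagittal <- function(mesh, axis = c("x", "y", "z"), offset_mm = 0) {
  axis <- match.arg(axis)
  j <- match(axis, c("x", "y", "z"))
  out <- mesh
  out$vertices[, j] <- 2 * offset_mm - out$vertices[, j]
  out$faces <- out$faces[, c(1, 3, 2), drop = FALSE]
  out$side <- switch(mesh$side, left = "right", right = "left", "unknown")
  out
}

#' Signed volume of a closed mesh (divergence theorem)
#'
#' @param mesh closed [triangle_mesh()] with outward winding.
#' @return volume in mm^3 (positive for outward normals).
#' @export
mesh_volume <- function(mesh) {
  p1 <- face_corner(mesh, 1)
  p2 <- face_corner(mesh, 2)
  p3 <- face_corner(mesh, 3)
  sum(rowSums(p1 * row_cross(p2, p3))) / 6
}

#' Closest points on a mesh surface
#'
#' For each query point, the nearest point on the (piecewise linear)
#' surface of `mesh`, with distance and hit-triangle index.
#'
#' @param mesh target [triangle_mesh()].
#' @param query Q x 3 matrix of points.
#' @return list with `points` (Q x 3), `dist` (mm), `face` (1-based index).
#' @export
closest_on_surface <- function(mesh, query) {
  query <- matrix(as.double(query), ncol = 3)
  .cpp_closest_point(mesh$vertices, mesh$faces - 1L, query)
}

#' Symmetric Hausdorff distance between two surfaces (vertex-sampled)
#'
#' @param mesh_a,mesh_b [triangle_mesh()] objects.
#' @return distance in mm.
#' @export
hausdorff_distance <- function(mesh_a, mesh_b) {
  dab <- closest_on_surface(mesh_b, mesh_a$vertices)$dist
  dba <- closest_on_surface(mesh_a, mesh_b$vertices)$dist
  max(max(dab), max(dba))
}
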