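# Correspondence establishment: similarity ICP + stiffness-annealed
# non-rigid ICP with data-driven template selection and mean-template
# refinement.

#' Construct a similarity transform
#'
#' Rotation (proper, det +1), uniform scale and translation: 7 degrees of
#' freedom. Applied as `x -> scale * x %*% t(rotation) + translation`.
#'
#' @param rotation 3 x 3 orthonormal matrix with determinant +1.
#' @param scale positive scalar.
#' @param translation length-3 vector (mm).
#' @return object of class `similarity_transform`.
#' @export
similarity_transform <- function(rotation = diag(3), scale = 1,
                                 translation = c(0, 0, 0)) {
  stopifnot(scale > 0)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-9)
    stop("rotation is not orthonormal")
  if (det(rotation) < 0) stop("rotation must be proper (det +1)")
  structure(list(rotation = rotation, scale = scale,
                 translation = as.numeric(translation)),
            class = "similarity_transform")
}

#' Apply a similarity transform to points
#'
#' @param transform a [similarity_transform()].
#' @param points N x 3 matrix.
#' @return transformed N x 3 matrix.
#' @export
apply_similarity <- function(transform, points) {
  sweep(transform$scale * points %*% t(transform$rotation), 2,
        -transform$translation)
}

#' Least-squares similarity alignment of paired point sets (Umeyama)
#'
#' Finds the rotation, optional uniform scale and translation minimizing
#' `sum(|s R x_i + t - y_i|^2)` over point pairs in given correspondence.
#' Reflections are never returned (det R = +1 enforced).
#'
#' @param source_points,target_points m x 3 matrices, row i of the source
#'   corresponding to row i of the target.
#' @param allow_scaling estimate a uniform scale (otherwise s = 1).
#' @return a [similarity_transform()].
#' @export
fit_similarity <- function(source_points, target_points, allow_scaling = TRUE) {
  x <- as.matrix(source_points)
  y <- as.matrix(target_points)
  m <- nrow(x)
  if (m < 3L) stop("at least 3 point pairs are required")
  stopifnot(nrow(y) == m, ncol(x) == 3L, ncol(y) == 3L)
  mx <- colMeans(x); my <- colMeans(y)
  xc <- sweep(x, 2, mx); yc <- sweep(y, 2, my)
  S <- crossprod(yc, xc) / m
  sv <- svd(S)
  d <- sign(det(sv$u %*% t(sv$v)))
  if (d == 0) stop("degenerate point configuration (rank deficient)")
  D <- diag(c(1, 1, d))
  if (sum(svd(xc)$d > 1e-12 * max(1, max(abs(xc)))) < 2L)
    stop("degenerate point configuration: source points are collinear")
  R <- sv$u %*% D %*% t(sv$v)
  if (allow_scaling) {
    var_x <- mean(rowSums(xc^2))
    s <- sum(sv$d * diag(D)) / var_x
    if (s <= 0) stop("degenerate configuration: non-positive scale")
  } else s <- 1
  t_vec <- my - s * as.numeric(R %*% mx)
  similarity_transform(rotation = R, scale = s, translation = t_vec)
}

#' Similarity-transform ICP between two meshes
#'
#' Iterates closest-point pairing (each source vertex to its nearest point
#' on the target surface) with Umeyama similarity fitting until the RMS
#' point-to-surface distance stops changing. The RMS is non-increasing
#' across iterations.
#'
#' @param source,target [triangle_mesh()] objects, roughly overlapping
#'   (e.g. after centroid alignment).
#' @param allow_scaling estimate uniform scale.
#' @param max_iterations iteration cap.
#' @param tol_mm stop when the RMS changes by less than this.
#' @param max_correspondence_distance_mm pairs farther than this are
#'   ignored (Inf keeps all).
#' @param sample_vertices number of source vertices used for pairing
#'   (deterministic stride subsample; Inf uses all). Alignment accuracy is
#'   insensitive to this once a few hundred pairs remain.
#' @param initial_transform warm-start [similarity_transform()].
#' @return list with `transform` (a [similarity_transform()]),
#'   `final_rms_mm`, `iterations` and `rms_trace` (per-iteration pairing
#'   RMS, non-increasing).
#' @export
icp_similarity <- function(source, target, allow_scaling = TRUE,
                           max_iterations = 100L, tol_mm = 1e-4,
                           max_correspondence_distance_mm = Inf,
                           sample_vertices = 1000L,
                           initial_transform = similarity_transform()) {
  x0 <- source$vertices
  n <- nrow(x0)
  if (is.finite(sample_vertices) && n > sample_vertices) {
    idx <- unique(round(seq(1, n, length.out = sample_vertices)))
    x0 <- x0[idx, , drop = FALSE]
  }
  res <- .cpp_icp_similarity(
    x0, target$vertices, target$faces - 1L, allow_scaling,
    as.integer(max_iterations), tol_mm,
    max_correspondence_distance_mm,
    initial_transform$rotation, initial_transform$scale,
    initial_transform$translation)
  if (!isTRUE(res$ok))
    stop("ICP divergence: fewer than 3 correspondences within the maximum distance")
  tr <- similarity_transform(rotation = res$rotation, scale = res$scale,
                             translation = res$translation)
  list(transform = tr, final_rms_mm = res$rms, iterations = res$iterations,
       rms_trace = res$rms_trace)
}

#' Non-rigid ICP parameters
#'
#' Controls the stiffness-annealed elastic registration: the template is
#' warped onto the target by a displacement field regularized by
#' graph-Laplacian smoothness on the template edge graph, with the
#' regularization weight lowered over a decreasing stiffness schedule.
#'
#' @param stiffness_schedule strictly decreasing positive weights.
#' @param inner_iterations closest-point/solve iterations per stiffness
#'   level (with early exit on convergence).
#' @param max_correspondence_distance_mm pairs farther than this are
#'   dropped from the data term.
#' @param normal_compatibility_min_cosine pairs whose source/target normals
#'   disagree by more than this cosine are dropped.
#' @param magnitude_penalty small Tikhonov weight on the displacement
#'   magnitude (relative to the unit data weight). Among all warps that fit
#'   the target surface equally well it selects the minimal-deformation
#'   one, suppressing the tangential drift that pure closest-point data
#'   terms leave unconstrained.
#' @param reverse_weight weight of the reverse (target-vertex to deformed
#'   template) correspondences in the data term, relative to the forward
#'   term. Bidirectional matching pulls template material into growing
#'   features and counteracts the shortening bias of nearest-point
#'   pairing; 0 disables.
#' @param convergence_tol_mm early exit when the largest displacement
#'   update falls below this.
#' @return list of class `nonrigid_params`.
#' @export
nonrigid_params <- function(stiffness_schedule = 16 * (0.15 / 16)^((0:5) / 5),
                            inner_iterations = 5L,
                            max_correspondence_distance_mm = 10,
                            normal_compatibility_min_cosine = 0.5,
                            magnitude_penalty = 0.15,
                            reverse_weight = 1,
                            convergence_tol_mm = 1e-3) {
  stopifnot(all(stiffness_schedule > 0),
            all(diff(stiffness_schedule) < 0),
            inner_iterations >= 1L,
            max_correspondence_distance_mm > 0,
            magnitude_penalty >= 0,
            reverse_weight >= 0,
            convergence_tol_mm > 0)
  structure(list(stiffness_schedule = stiffness_schedule,
                 inner_iterations = as.integer(inner_iterations),
                 max_correspondence_distance_mm = max_correspondence_distance_mm,
                 normal_compatibility_min_cosine = normal_compatibility_min_cosine,
                 magnitude_penalty = magnitude_penalty,
                 reverse_weight = reverse_weight,
                 convergence_tol_mm = convergence_tol_mm),
            class = "nonrigid_params")
}

template_laplacian <- function(mesh) {
  ed <- mesh_edges(mesh)$edges
  V <- nrow(mesh$vertices)
  A <- Matrix::sparseMatrix(i = c(ed[, 1], ed[, 2]), j = c(ed[, 2], ed[, 1]),
                            x = 1, dims = c(V, V))
  Matrix::Diagonal(x = Matrix::rowSums(A)) - A
}

#' Non-rigid ICP: warp a template mesh onto a target surface
#'
#' For each stiffness level, alternates closest-point correspondence
#' (template vertex to nearest point on the target surface, pruned by
#' distance and normal compatibility) with a sparse linear solve for the
#' displacement field `d` minimizing
#' `sum(w_i |v_i + d_i - c_i|^2) + stiffness * sum_edges |d_i - d_j|^2`.
#' The output keeps the template's vertex count and topology, which is what
#' establishes point-to-point correspondence.
#'
#' @param template [triangle_mesh()] to be deformed.
#' @param target [triangle_mesh()] to be matched; should already be
#'   similarity-aligned to the template.
#' @param params a [nonrigid_params()].
#' @param laplacian optional precomputed template graph Laplacian (reused
#'   across many registrations to the same template).
#' @param initial_displacement optional V x 3 warm-start displacement field.
#' @return list with `vertices` (warped template, V x 3), `residual_rms_mm`
#'   (over valid pairs), `displacement` (V x 3) and `n_valid` (valid pairs
#'   at the final level).
#' @export
nonrigid_icp <- function(template, target, params = nonrigid_params(),
                         laplacian = NULL, initial_displacement = NULL) {
  v0 <- template$vertices
  V <- nrow(v0)
  L <- if (is.null(laplacian)) template_laplacian(template) else laplacian
  tgt_fn <- face_normals_raw(target)
  fl <- sqrt(rowSums(tgt_fn^2)); fl[fl == 0] <- 1
  tgt_fn <- tgt_fn / fl
  d <- if (is.null(initial_displacement)) matrix(0, V, 3) else
    initial_displacement
  grid <- .cpp_grid_build(target$vertices, target$faces - 1L)
  faces0 <- template$faces - 1L
  # vertex-face incidence for fast area-weighted normals of the deformed
  # template (fixed topology)
  nF <- nrow(template$faces)
  M <- Matrix::sparseMatrix(i = as.vector(template$faces),
                            j = rep(seq_len(nF), 3), x = 1,
                            dims = c(V, nF))
  deformed_normals <- function(cur) {
    p1 <- cur[template$faces[, 1], , drop = FALSE]
    fn <- row_cross(cur[template$faces[, 2], , drop = FALSE] - p1,
                    cur[template$faces[, 3], , drop = FALSE] - p1)
    vn <- as.matrix(M %*% fn)
    len <- sqrt(rowSums(vn^2)); len[len == 0] <- 1
    vn / len
  }
  Y <- target$vertices
  nY <- nrow(Y)
  rev_norm <- params$reverse_weight / (nY / V)  # balance the two terms
  chol_fac <- NULL
  keep <- rep(TRUE, V)
  for (lev in seq_along(params$stiffness_schedule)) {
    alpha <- params$stiffness_schedule[lev]
    for (inner in seq_len(params$inner_iterations)) {
      cur <- v0 + d
      cp <- .cpp_grid_query(grid, cur)
      src_n <- deformed_normals(cur)
      ncos <- rowSums(src_n * tgt_fn[cp$face, , drop = FALSE])
      keep <- cp$dist <= params$max_correspondence_distance_mm &
        ncos >= params$normal_compatibility_min_cosine
      if (!any(keep))
        stop(sprintf("non-rigid registration failed: all correspondences invalid at stiffness level %d", lev))
      w <- as.numeric(keep)
      A <- alpha * L + Matrix::Diagonal(x = w + params$magnitude_penalty)
      rhs <- (cp$points - v0) * w
      if (params$reverse_weight > 0) {
        # reverse correspondences: each target vertex pulls its closest
        # point on the deformed template (barycentric on the hit face)
        rgrid <- .cpp_grid_build(cur, faces0)
        cq <- .cpp_grid_query(rgrid, Y)
        fi <- cq$face
        a1 <- template$faces[fi, 1]; a2 <- template$faces[fi, 2]
        a3 <- template$faces[fi, 3]
        P1 <- cur[a1, , drop = FALSE]
        e1 <- cur[a2, , drop = FALSE] - P1
        e2 <- cur[a3, , drop = FALSE] - P1
        pq <- cq$points - P1
        d11 <- rowSums(e1 * e1); d12 <- rowSums(e1 * e2); d22 <- rowSums(e2 * e2)
        r1 <- rowSums(pq * e1); r2 <- rowSums(pq * e2)
        den <- d11 * d22 - d12^2; den[den <= 0] <- 1e-12
        bw2 <- pmin(pmax((d22 * r1 - d12 * r2) / den, 0), 1)
        bw3 <- pmin(pmax((d11 * r2 - d12 * r1) / den, 0), 1)
        bw1 <- pmax(1 - bw2 - bw3, 0)
        wk <- rev_norm * as.numeric(cq$dist <= params$max_correspondence_distance_mm)
        bmat <- cbind(bw1, bw2, bw3)
        amat <- cbind(a1, a2, a3)
        m1 <- rep(1:3, each = 3); m2 <- rep(1:3, times = 3)
        iA <- as.vector(amat[, m1])
        jA <- as.vector(amat[, m2])
        xA <- as.vector(bmat[, m1] * bmat[, m2]) * rep(wk, 9)
        A <- A + Matrix::sparseMatrix(i = iA, j = jA, x = xA, dims = c(V, V))
        resid <- Y - (v0[a1, , drop = FALSE] * bw1 + v0[a2, , drop = FALSE] * bw2 +
                        v0[a3, , drop = FALSE] * bw3)
        B <- Matrix::sparseMatrix(i = rep(seq_len(nY), 3), j = as.vector(amat),
                                  x = as.vector(bmat) * wk, dims = c(nY, V))
        rhs <- rhs + as.matrix(Matrix::crossprod(B, resid))
      }
      # the reverse-term face blocks lie on the template edge/diagonal
      # pattern, so the symbolic factorization can be reused throughout
      A <- Matrix::forceSymmetric(A)
      if (is.null(chol_fac)) {
        chol_fac <- Matrix::Cholesky(A, LDL = FALSE, super = TRUE)
      } else {
        chol_fac <- Matrix::update(chol_fac, A)
      }
      d_new <- as.matrix(Matrix::solve(chol_fac, rhs))
      delta <- max(abs(d_new - d))
      d <- d_new
      if (delta < params$convergence_tol_mm) break
    }
  }
  cur <- v0 + d
  cp <- .cpp_grid_query(grid, cur)
  list(vertices = cur,
       residual_rms_mm = sqrt(mean(cp$dist[keep]^2)),
       displacement = d,
       n_valid = sum(keep))
}

# register one (already centered) shape to a template:
# similarity ICP aligning the shape to the template, then non-rigid warp of
# the template onto the aligned shape
register_to_template <- function(shape, template, params, laplacian,
                                 allow_scaling = TRUE, warm = NULL) {
  init <- if (is.null(warm)) similarity_transform() else warm$transform
  icp <- icp_similarity(shape, template, allow_scaling = allow_scaling,
                        initial_transform = init)
  aligned <- shape
  aligned$vertices <- apply_similarity(icp$transform, shape$vertices)
  nri <- nonrigid_icp(template, aligned, params, laplacian = laplacian,
                      initial_displacement = if (is.null(warm)) NULL else
                        warm$displacement)
  # remove the rigid (rotation + translation) component that the elastic
  # solve can accumulate as a smooth global drift: re-pose the warped
  # template onto the template frame so only true shape change remains
  rigid <- fit_similarity(nri$vertices, template$vertices,
                          allow_scaling = FALSE)
  verts <- apply_similarity(rigid, nri$vertices)
  list(vertices = verts, scale = icp$transform$scale,
       residual_rms_mm = nri$residual_rms_mm,
       transform = icp$transform, displacement = nri$displacement)
}

#' Select the registration template from the data
#'
#' One provisional registration of every shape produces a vertex-wise mean
#' shape; the shape whose registered version is closest (vertex RMSE) to
#' that mean is returned as the template, avoiding the bias of an arbitrary
#' template choice. Ties break to the lowest index.
#'
#' @param shapes list of centered [triangle_mesh()] objects.
#' @param provisional_template_index index of the shape used for the
#'   provisional registration (default 1, first in input order).
#' @param params a [nonrigid_params()].
#' @param registered_out environment; if supplied, the provisional
#'   registration results are stored in it (field `registered`) for reuse.
#' @return the selected template index.
#' @export
select_template <- function(shapes, provisional_template_index = 1L,
                            params = nonrigid_params(),
                            registered_out = NULL) {
  n <- length(shapes)
  if (n < 2L) stop("template selection needs at least 2 shapes")
  template <- shapes[[provisional_template_index]]
  lap <- template_laplacian(template)
  reg <- vector("list", n)
  for (i in seq_len(n)) {
    reg[[i]] <- tryCatch(
      register_to_template(shapes[[i]], template, params, lap),
      error = function(e) stop(sprintf("registration of shape %d ('%s') failed: %s",
                                       i, shapes[[i]]$label, conditionMessage(e))))
  }
  stack <- vapply(reg, function(r) r$vertices, template$vertices)
  mean_shape <- apply(stack, c(1, 2), mean)
  err <- vapply(seq_len(n), function(i) rmse(stack[, , i], mean_shape), 0)
  if (!is.null(registered_out)) registered_out$registered <- reg
  best <- which(err <= min(err) + 1e-9)
  if (provisional_template_index %in% best) return(provisional_template_index)
  best[1]
}

#' Establish dense correspondence across a shape population
#'
#' The full registration pipeline: (1) translate every shape so its surface
#' centroid is at the origin; (2) select the template by a provisional
#' registration pass; (3) run `n_outer_iterations` rounds in which every
#' shape is registered to the current template (similarity ICP, then
#' non-rigid ICP) and the vertex-wise mean of the registered shapes becomes
#' the next template; (4) divide each registered shape by its similarity
#' scale factor, restoring original size so that size variation is retained
#' for the shape model while pose is normalized.
#'
#' @param shapes list of conditioned [triangle_mesh()] objects (manifold,
#'   single component), length >= 3.
#' @param labels optional data.frame with one row per shape (e.g. columns
#'   `id`, `sex`); defaults to the mesh labels.
#' @param n_outer_iterations registration rounds with template refresh
#'   (default 3).
#' @param params a [nonrigid_params()].
#' @param template_index optional fixed template index (skips selection).
#' @param verbose print per-stage progress.
#' @return object of class `corresponded_shapes`: list with `faces`
#'   (template topology), `shapes` (n x V x 3 array, original size, template
#'   frame), `scale_factors`, `labels`, `template_history`, `residuals`,
#'   `template_index`.
#' @export
build_correspondences <- function(shapes, labels = NULL,
                                  n_outer_iterations = 3L,
                                  params = nonrigid_params(),
                                  template_index = NULL,
                                  verbose = FALSE) {
  n <- length(shapes)
  if (n < 3L) stop("need at least 3 shapes")
  if (is.null(labels))
    labels <- data.frame(id = vapply(shapes, function(m) m$label, ""),
                         sex = NA_character_)
  stopifnot(nrow(labels) == n)

  centered <- lapply(shapes, function(m) translate_to_origin(m)$mesh)

  if (is.null(template_index)) {
    if (verbose) message("selecting template (provisional registration pass)")
    # ranking shapes against a provisional mean does not need the final
    # registration precision: fewer inner iterations suffice
    sel_params <- params
    sel_params$inner_iterations <- min(params$inner_iterations, 3L)
    template_index <- select_template(centered, 1L, sel_params)
    if (verbose) message(sprintf("  template: shape %d ('%s')",
                                 template_index, shapes[[template_index]]$label))
  }
  template <- centered[[template_index]]
  lap <- template_laplacian(template)
  template_history <- list()
  residuals <- numeric(n)
  scales <- numeric(n)
  mean_res_prev <- Inf
  reg_stack <- NULL
  warm <- vector("list", n)
  for (outer in seq_len(n_outer_iterations)) {
    if (verbose) message(sprintf("registration iteration %d/%d", outer,
                                 n_outer_iterations))
    reg_stack <- array(0, c(nrow(template$vertices), 3, n))
    for (i in seq_len(n)) {
      r <- tryCatch(
        register_to_template(centered[[i]], template, params, lap,
                             warm = warm[[i]]),
        error = function(e) stop(sprintf(
          "iteration %d, shape %d ('%s'): %s", outer, i,
          shapes[[i]]$label, conditionMessage(e))))
      reg_stack[, , i] <- r$vertices
      residuals[i] <- r$residual_rms_mm
      scales[i] <- r$scale
      warm[[i]] <- r[c("transform", "displacement")]
    }
    mean_res <- mean(residuals)
    if (mean_res > mean_res_prev + 1e-9)
      warning(sprintf("mean registration residual did not decrease at iteration %d (%.4f -> %.4f mm)",
                      outer, mean_res_prev, mean_res))
    mean_res_prev <- mean_res
    mean_verts <- apply(reg_stack, c(1, 2), mean)
    template <- triangle_mesh(mean_verts, template$faces,
                              label = sprintf("mean_iter%d", outer),
                              validate = FALSE)
    template_history[[outer]] <- template
    if (verbose) message(sprintf("  mean residual %.4f mm", mean_res))
  }

  # restore original size: undo the scaling that the alignment applied.
  # The stored factor is measured on the registration product itself
  # (centroid-size ratio of the registered shape to the input shape), the
  # most direct estimate of the similarity-stage scale
  rms_size <- function(v) sqrt(mean(rowSums(sweep(v, 2, colMeans(v))^2)))
  shapes_out <- array(0, c(n, nrow(template$vertices), 3))
  for (i in seq_len(n)) {
    scales[i] <- rms_size(reg_stack[, , i]) / rms_size(centered[[i]]$vertices)
    shapes_out[i, , ] <- reg_stack[, , i] / scales[i]
  }
  dimnames(shapes_out) <- list(as.character(labels$id), NULL, c("x", "y", "z"))

  structure(list(faces = template$faces, shapes = shapes_out,
                 scale_factors = scales, labels = labels,
                 template_history = template_history,
                 residuals = residuals, template_index = template_index),
            class = "corresponded_shapes")
}

#' @export
print.corresponded_shapes <- function(x, ...) {
  cat(sprintf("corresponded_shapes: %d shapes, %d vertices, %d faces; mean residual %.3f mm\n",
              dim(x$shapes)[1], dim(x$shapes)[2], nrow(x$faces),
              mean(x$residuals)))
  invisible(x)
}

#' Save / load a corresponded shape set
#'
#' Directory layout: `topology.ply` (template mesh at the final mean),
#' `shapes.bin` (row-major float64 vertex coordinates, shape by shape),
#' `scales.csv`, `labels.csv` and a JSON manifest with dimensions and
#' shape order.
#'
#' @param x a `corresponded_shapes` object.
#' @param dir output directory (created if missing).
#' @return `invisible(dir)` / the restored object.
#' @export
save_corresponded <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- dim(x$shapes)[1]; V <- dim(x$shapes)[2]
  mean_verts <- apply(x$shapes, c(2, 3), mean)
  write_mesh(triangle_mesh(mean_verts, x$faces, label = "mean",
                           validate = FALSE),
             file.path(dir, "topology.ply"), "ply")
  con <- file(file.path(dir, "shapes.bin"), "wb")
  for (i in seq_len(n)) writeBin(as.vector(t(x$shapes[i, , ])), con)
  close(con)
  write.csv(data.frame(id = x$labels$id, scale = x$scale_factors,
                       residual_rms_mm = x$residuals),
            file.path(dir, "scales.csv"), row.names = FALSE)
  write.csv(x$labels, file.path(dir, "labels.csv"), row.names = FALSE)
  jsonlite::write_json(list(n_shapes = n, n_vertices = V,
                            ids = as.character(x$labels$id),
                            template_index = x$template_index,
                            format = "float64 row-major V x 3 per shape"),
                       file.path(dir, "manifest.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname save_corresponded
#' @export
load_corresponded <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  topo <- read_mesh(file.path(dir, "topology.ply"))
  n <- man$n_shapes; V <- man$n_vertices
  con <- file(file.path(dir, "shapes.bin"), "rb")
  raw <- readBin(con, "double", n * V * 3)
  close(con)
  shapes <- array(0, c(n, V, 3))
  for (i in seq_len(n))
    shapes[i, , ] <- matrix(raw[((i - 1) * V * 3 + 1):(i * V * 3)],
                            V, 3, byrow = TRUE)
  scales <- read.csv(file.path(dir, "scales.csv"))
  labels <- read.csv(file.path(dir, "labels.csv"))
  dimnames(shapes) <- list(as.character(labels$id), NULL, c("x", "y", "z"))
  structure(list(faces = topo$faces, shapes = shapes,
                 scale_factors = scales$scale, labels = labels,
                 template_history = list(),
                 residuals = scales$residual_rms_mm,
                 template_index = man$template_index),
            class = "corresponded_shapes")
}
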