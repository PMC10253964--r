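# PCA statistical shape model: fitting, synthesis, SD-unit scores,
# variance bookkeeping and regularized fitting to partial observations.

#' Fit a PCA statistical shape model
#'
#' Flattens each corresponded shape to a length-3V vector (x1,y1,z1,...),
#' computes the coordinate-wise mean and the eigendecomposition of the
#' sample covariance (divisor n - 1) via thin SVD. Components with
#' eigenvalue below `1e-12 * max(eigenvalue)` are dropped. Eigenvector
#' signs are fixed so the largest-magnitude loading of each component is
#' positive, making fits reproducible.
#'
#' @param corresponded a `corresponded_shapes` object (or an n x 3V matrix
#'   of flattened shapes plus `faces`).
#' @param faces template topology; taken from `corresponded` when omitted.
#' @return object of class `shape_model` with `mean` (length 3V),
#'   `components` (k x 3V orthonormal rows), `eigenvalues` (mm^2, sorted
#'   descending), `n_samples`, `faces`.
#' @export
fit_pca <- function(corresponded, faces = NULL) {
  if (inherits(corresponded, "corresponded_shapes")) {
    X <- flatten_shapes(corresponded$shapes)
    faces <- corresponded$faces
  } else {
    X <- as.matrix(corresponded)
  }
  n <- nrow(X)
  if (n < 3L) stop("need at least 3 shapes to fit a shape model")
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  sv <- La.svd(Xc, nu = 0, nv = min(n, ncol(Xc)))
  lambda <- sv$d^2 / (n - 1)
  keep <- lambda > 1e-12 * max(lambda, 1e-300) & seq_along(lambda) <= n - 1
  lambda <- lambda[keep]
  phi <- sv$vt[keep, , drop = FALSE]
  # sign convention: largest-magnitude loading positive
  if (nrow(phi) > 0) {
    flip <- vapply(seq_len(nrow(phi)), function(i) {
      j <- which.max(abs(phi[i, ]))
      sign(phi[i, j])
    }, 0)
    phi <- phi * flip
  }
  model <- structure(list(mean = mu, components = phi, eigenvalues = lambda,
                          n_samples = n, faces = faces),
                     class = "shape_model")
  assert_model_invariants(model, X)
  model
}

flatten_shapes <- function(shapes_array) {
  n <- dim(shapes_array)[1]
  V <- dim(shapes_array)[2]
  X <- matrix(0, n, 3 * V)
  for (i in seq_len(n)) X[i, ] <- as.vector(t(shapes_array[i, , ]))
  X
}

unflatten_shape <- function(x) matrix(x, ncol = 3, byrow = TRUE)

assert_model_invariants <- function(model, X = NULL) {
  k <- length(model$eigenvalues)
  if (k == 0) return(invisible(model))
  G <- tcrossprod(model$components)
  if (max(abs(G - diag(k))) > 1e-8)
    stop("shape model invariant violated: components not orthonormal")
  if (is.unsorted(rev(model$eigenvalues)))
    stop("shape model invariant violated: eigenvalues not descending")
  if (!is.null(X)) {
    total <- sum(sweep(X, 2, model$mean)^2) / (model$n_samples - 1)
    if (abs(sum(model$eigenvalues) - total) > 1e-6 * total)
      stop("shape model invariant violated: variance not conserved")
  }
  invisible(model)
}

#' @export
print.shape_model <- function(x, ...) {
  k <- length(x$eigenvalues)
  cat(sprintf("shape_model: %d training shapes, %d vertices, %d components\n",
              x$n_samples, length(x$mean) / 3, k))
  if (k > 0) {
    shares <- x$eigenvalues / sum(x$eigenvalues)
    cat(sprintf("  variance shares: %s%s\n",
                paste(sprintf("%.1f%%", 100 * head(shares, 5)), collapse = ", "),
                if (k > 5) ", ..." else ""))
  }
  invisible(x)
}

#' Synthesize a shape from component scores
#'
#' `x = mean + sum_i b_i * sqrt(lambda_i) * phi_i`: scores are in standard
#' deviation units, so `b = c(+3, 0, ...)` and `c(-3, 0, ...)` give the
#' +/-3 SD extreme meshes of the first mode (together covering 99.7% of
#' that mode's variation in a Gaussian population).
#'
#' @param model a [fit_pca()] model.
#' @param scores numeric vector of SD-unit scores (length <= k; missing
#'   trailing scores are zero).
#' @return V x 3 vertex matrix.
#' @export
synthesize <- function(model, scores = numeric(0)) {
  k <- length(model$eigenvalues)
  if (length(scores) > k)
    stop(sprintf("more scores (%d) than model components (%d)",
                 length(scores), k))
  x <- model$mean
  if (length(scores) > 0) {
    coef <- scores * sqrt(model$eigenvalues[seq_along(scores)])
    x <- x + as.vector(crossprod(model$components[seq_along(scores), , drop = FALSE], coef))
  }
  unflatten_shape(x)
}

#' Project a corresponded shape onto the model (SD-unit scores)
#'
#' `b_i = phi_i' (x - mean) / sqrt(lambda_i)`. With all components
#' retained, `synthesize(project(x))` reproduces a training shape to
#' numerical precision.
#'
#' @param model a [fit_pca()] model.
#' @param vertices V x 3 matrix in template correspondence (or length-3V
#'   vector).
#' @param k_use number of components (default all).
#' @return numeric vector of SD-unit scores.
#' @export
project <- function(model, vertices, k_use = NULL) {
  k <- length(model$eigenvalues)
  if (is.null(k_use)) k_use <- k
  if (k_use > k) stop(sprintf("k_use (%d) exceeds model components (%d)", k_use, k))
  x <- if (is.matrix(vertices)) as.vector(t(vertices)) else as.numeric(vertices)
  if (length(x) != length(model$mean))
    stop("vertex dimension does not match the model")
  if (k_use == 0) return(numeric(0))
  phi <- model$components[seq_len(k_use), , drop = FALSE]
  as.vector(phi %*% (x - model$mean)) / sqrt(model$eigenvalues[seq_len(k_use)])
}

#' Number of components needed for a variance fraction
#'
#' Smallest k whose cumulative eigenvalue share reaches `fraction` (e.g.
#' 0.90 of the total shape variation).
#'
#' @param model a [fit_pca()] model.
#' @param fraction target cumulative variance fraction in (0, 1].
#' @return integer k.
#' @export
components_for_variance <- function(model, fraction) {
  if (!is.numeric(fraction) || fraction <= 0 || fraction > 1)
    stop("fraction must be in (0, 1]")
  shares <- cumsum(model$eigenvalues) / sum(model$eigenvalues)
  which(shares >= fraction - 1e-12)[1]
}

#' Reconstruct a partially observed shape with the model
#'
#' Fits the model to an incomplete surface (e.g. a fractured bone) by
#' alternating: (a) similarity alignment of the current model instance to
#' the partial surface, (b) closest-point correspondence from model
#' vertices to the partial surface with distance/normal pruning, and (c) a
#' ridge-regularized solve for the SD-unit scores
#' (`min sum_observed |x_i(b) - c_i|^2 + beta * sum b_i^2`, a Gaussian
#' shape prior). Model vertices without a valid correspondence — the
#' missing region — are extrapolated by the model.
#'
#' @param model a [fit_pca()] model.
#' @param partial_mesh observed [triangle_mesh()] (any pose/size; an
#'   initial centroid + scale alignment is performed).
#' @param k_use number of components to fit.
#' @param beta ridge weight on SD-unit scores (default 0.1).
#' @param max_alternations pose/score alternations (default 3).
#' @param params pruning rules, a [nonrigid_params()] (only the distance
#'   and normal thresholds are used).
#' @param ground_truth optional V x 3 matrix of the true complete shape in
#'   the partial mesh's frame, for `rmse_full_mm`.
#' @return object of class `shape_reconstruction`: `vertices` (full
#'   reconstructed V x 3 in the partial mesh's frame), `scores`, `pose`
#'   (a [similarity_transform()] from model frame to the partial frame),
#'   `observed` (logical V), `per_vertex_residual_mm` (NA over the
#'   unobserved region), `rmse_observed_mm`, `rmse_full_mm` (NA without
#'   ground truth).
#' @export
reconstruct_partial <- function(model, partial_mesh, k_use = NULL,
                                beta = 0.1, max_alternations = 3L,
                                params = nonrigid_params(),
                                ground_truth = NULL) {
  if (beta < 0) stop("beta must be non-negative")
  k <- length(model$eigenvalues)
  if (is.null(k_use)) k_use <- k
  if (k_use > k) stop("k_use exceeds the number of model components")

  mean_mesh <- triangle_mesh(unflatten_shape(model$mean), model$faces,
                             validate = FALSE)
  tgt_fn <- face_normals_raw(partial_mesh)
  fl <- sqrt(rowSums(tgt_fn^2)); fl[fl == 0] <- 1
  tgt_fn <- tgt_fn / fl

  # initial pose: rigid ICP of the mean shape onto the partial surface.
  # The pose is rigid throughout: size is a shape-model mode here (the
  # dominant one in skeletal populations), so letting the pose carry a
  # scale would make the fit degenerate with the size score.
  icp0 <- icp_similarity(mean_mesh, partial_mesh, allow_scaling = FALSE,
                         max_iterations = 50)
  pose <- icp0$transform

  b <- numeric(k_use)
  sq <- sqrt(model$eigenvalues[seq_len(k_use)])
  phi <- model$components[seq_len(k_use), , drop = FALSE]  # k x 3V
  V <- length(model$mean) / 3
  inst_mesh <- mean_mesh
  observed <- rep(TRUE, V)
  mu_mat <- unflatten_shape(model$mean)
  phi_v <- array(phi, c(k_use, 3, V))

  refresh_observed <- function(y, cp) {
    inst_mesh$vertices <- y
    src_n <- vertex_normals(inst_mesh)
    ncos <- rowSums(src_n * tgt_fn[cp$face, , drop = FALSE])
    obs <- cp$dist <= params$max_correspondence_distance_mm &
      ncos >= params$normal_compatibility_min_cosine
    if (!any(obs))
      stop("reconstruction failed: no overlap between model and partial surface")
    obs
  }
  solve_scores <- function(b, pose, observed) {
    # design in the posed frame: R * (sqrt(lambda_j) phi_j)
    RtPhi <- array(0, c(k_use, 3, V))
    for (j in seq_len(k_use))
      RtPhi[j, , ] <- pose$scale * (pose$rotation %*% matrix(phi_v[j, , ], 3, V))
    Amat <- sweep(t(matrix(RtPhi, k_use, 3 * V)), 2, sq, "*")
    mu_posed <- apply_similarity(pose, mu_mat)
    obs3 <- rep(observed, each = 3)
    Ao <- Amat[obs3, , drop = FALSE]
    AtA <- crossprod(Ao) + beta * diag(k_use)
    for (inner in 1:5) {
      y <- apply_similarity(pose, synthesize(model, b))
      cp <- closest_on_surface(partial_mesh, y)
      r <- as.vector(t(cp$points - mu_posed))
      b_new <- as.vector(solve(AtA, crossprod(Ao, r[obs3])))
      done <- max(abs(b_new - b)) < 1e-4
      b <- b_new
      if (done) break
    }
    b
  }
  for (alt in seq_len(max_alternations)) {
    # (b,c) correspondence/score iterations under the current pose
    y <- apply_similarity(pose, synthesize(model, b))
    cp <- closest_on_surface(partial_mesh, y)
    observed <- refresh_observed(y, cp)
    b <- solve_scores(b, pose, observed)
    # (a) rigid pose refresh against the fitted instance's correspondences
    inst <- synthesize(model, b)
    y <- apply_similarity(pose, inst)
    cp <- closest_on_surface(partial_mesh, y)
    observed <- refresh_observed(y, cp)
    pose <- fit_similarity(inst[observed, , drop = FALSE],
                           cp$points[observed, , drop = FALSE],
                           allow_scaling = FALSE)
  }
  b <- solve_scores(b, pose, observed)
  inst <- synthesize(model, b)
  vertices <- apply_similarity(pose, inst)
  cp <- closest_on_surface(partial_mesh, vertices)
  per_vertex <- ifelse(observed, cp$dist, NA_real_)
  rmse_obs <- sqrt(mean(cp$dist[observed]^2))
  rmse_full <- NA_real_
  if (!is.null(ground_truth))
    rmse_full <- rmse(vertices, ground_truth)
  structure(list(vertices = vertices, scores = b, pose = pose,
                 observed = observed,
                 per_vertex_residual_mm = per_vertex,
                 rmse_observed_mm = rmse_obs, rmse_full_mm = rmse_full,
                 faces = model$faces),
            class = "shape_reconstruction")
}

#' @export
print.shape_reconstruction <- function(x, ...) {
  cat(sprintf("shape_reconstruction: %d/%d vertices observed, RMSE (observed) %.3f mm\n",
              sum(x$observed), length(x$observed), x$rmse_observed_mm))
  invisible(x)
}

#' Save / load a shape model
#'
#' Directory layout: `model.json` (dimensions, eigenvalues, provenance),
#' `mean.bin` and `components.bin` (float64), `topology.ply`.
#'
#' @param model a `shape_model`.
#' @param dir directory.
#' @return `invisible(dir)` / the restored model.
#' @export
save_shape_model <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(list(
    n_samples = model$n_samples,
    n_vertices = length(model$mean) / 3,
    k = length(model$eigenvalues),
    eigenvalues = model$eigenvalues,
    package_version = as.character(utils::packageVersion("ssmesh"))),
    file.path(dir, "model.json"), auto_unbox = TRUE, digits = NA)
  con <- file(file.path(dir, "mean.bin"), "wb")
  writeBin(model$mean, con); close(con)
  con <- file(file.path(dir, "components.bin"), "wb")
  writeBin(as.vector(t(model$components)), con); close(con)
  write_mesh(triangle_mesh(unflatten_shape(model$mean), model$faces,
                           label = "mean", validate = FALSE),
             file.path(dir, "topology.ply"), "ply")
  invisible(dir)
}

#' @rdname save_shape_model
#' @export
load_shape_model <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "model.json"),
                              simplifyVector = TRUE)
  p <- 3 * meta$n_vertices
  con <- file(file.path(dir, "mean.bin"), "rb")
  mu <- readBin(con, "double", p); close(con)
  con <- file(file.path(dir, "components.bin"), "rb")
  comp <- readBin(con, "double", meta$k * p); close(con)
  topo <- read_mesh(file.path(dir, "topology.ply"))
  structure(list(mean = mu,
                 components = matrix(comp, meta$k, p, byrow = TRUE),
                 eigenvalues = meta$eigenvalues,
                 n_samples = meta$n_samples, faces = topo$faces),
            class = "shape_model")
}
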