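# Shape-model quality metrics: RMSE, compactness, leave-one-out
# generalization, per-vertex deviation maps.

#' Root mean square error between corresponded point sets
#'
#' `sqrt(mean(|a_i - b_i|^2))` over per-vertex Euclidean distances (mm).
#'
#' @param points_a,points_b V x 3 matrices with corresponding rows.
#' @return RMSE in mm.
#' @export
rmse <- function(points_a, points_b) {
  if (!all(dim(points_a) == dim(points_b)))
    stop("point sets must have identical dimensions")
  sqrt(mean(rowSums((points_a - points_b)^2)))
}

#' Compactness curve of a shape model
#'
#' Cumulative fraction of the total shape variance captured by the first k
#' components, for k = 1..k_total. The curve answers how many modes are
#' needed to describe a given share of the population's variation.
#'
#' @param model a [fit_pca()] model.
#' @return data.frame with columns `k` and `cumulative_variance_fraction`.
#' @export
compactness_curve <- function(model) {
  lam <- model$eigenvalues
  data.frame(k = seq_along(lam),
             cumulative_variance_fraction = cumsum(lam) / sum(lam))
}

#' Leave-one-out generalization of the shape model
#'
#' Each shape in turn is held out; a model is fitted to the remaining n-1
#' shapes, and the held-out shape is projected and re-synthesized with k
#' components for each k in `k_values`. Reports the per-shape RMSE, the
#' per-k mean and a normal-approximation 95% CI
#' (`mean +/- 1.96 sd / sqrt(n)`). Deterministic and order-independent.
#'
#' @param corresponded a `corresponded_shapes` object.
#' @param k_values component counts to evaluate; values above n - 2 are
#'   trimmed with a warning.
#' @return object of class `loo_generalization`: data.frame `summary`
#'   (k, mean_rmse_mm, ci95_low_mm, ci95_high_mm) and matrix `per_shape`
#'   (shape x k).
#' @export
loo_generalization <- function(corresponded, k_values = NULL) {
  X <- flatten_shapes(corresponded$shapes)
  n <- nrow(X)
  if (n < 4L) stop("leave-one-out needs at least 4 shapes")
  if (is.null(k_values)) k_values <- unique(pmin(2^(0:10), n - 2))
  k_values <- sort(unique(as.integer(k_values)))
  if (any(k_values > n - 2L)) {
    warning(sprintf("k values above n - 2 = %d trimmed", n - 2L))
    k_values <- k_values[k_values <= n - 2L]
  }
  V <- ncol(X) / 3
  per_shape <- matrix(NA_real_, n, length(k_values),
                      dimnames = list(rownames(X), paste0("k", k_values)))
  for (i in seq_len(n)) {
    fit <- fit_pca(X[-i, , drop = FALSE], faces = corresponded$faces)
    kmax <- length(fit$eigenvalues)
    b_full <- project(fit, X[i, ], k_use = min(kmax, max(k_values)))
    for (j in seq_along(k_values)) {
      k <- min(k_values[j], kmax)
      recon <- synthesize(fit, b_full[seq_len(k)])
      per_shape[i, j] <- rmse(unflatten_shape(X[i, ]), recon)
    }
  }
  mean_rmse <- colMeans(per_shape)
  sdv <- apply(per_shape, 2, sd)
  summary <- data.frame(k = k_values,
                        mean_rmse_mm = mean_rmse,
                        ci95_low_mm = mean_rmse - 1.96 * sdv / sqrt(n),
                        ci95_high_mm = mean_rmse + 1.96 * sdv / sqrt(n),
                        row.names = NULL)
  structure(list(summary = summary, per_shape = per_shape, n = n),
            class = "loo_generalization")
}

#' @export
print.loo_generalization <- function(x, ...) {
  cat(sprintf("leave-one-out generalization over %d shapes:\n", x$n))
  print(x$summary, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Per-vertex deviation map between two surfaces
#'
#' In `corresponded` mode, the Euclidean distance between matching rows of
#' two corresponded vertex sets; in `nearest_surface` mode, the distance
#' from each vertex of `vertices_a` to the nearest point on a reference
#' mesh. Used for reconstruction-error heatmaps and male-versus-female
#' mean-shape deviation maps.
#'
#' @param vertices_a V x 3 matrix (or [triangle_mesh()]).
#' @param vertices_b V x 3 matrix with the same correspondence
#'   (`corresponded` mode) or a target [triangle_mesh()]
#'   (`nearest_surface` mode).
#' @param mode `"corresponded"` or `"nearest_surface"`.
#' @return object of class `deviation_map`: `per_vertex_distance_mm` plus
#'   `summary` (mean, sd, max, rmse).
#' @export
deviation_map <- function(vertices_a, vertices_b,
                          mode = c("corresponded", "nearest_surface")) {
  mode <- match.arg(mode)
  if (inherits(vertices_a, "triangle_mesh")) vertices_a <- vertices_a$vertices
  if (mode == "corresponded") {
    if (inherits(vertices_b, "triangle_mesh")) vertices_b <- vertices_b$vertices
    if (!all(dim(vertices_a) == dim(vertices_b)))
      stop("corresponded mode requires equal vertex counts")
    d <- sqrt(rowSums((vertices_a - vertices_b)^2))
  } else {
    if (!inherits(vertices_b, "triangle_mesh"))
      stop("nearest_surface mode requires a triangle_mesh reference")
    d <- closest_on_surface(vertices_b, vertices_a)$dist
  }
  structure(list(per_vertex_distance_mm = d,
                 summary = c(mean = mean(d), sd = sd(d), max = max(d),
                             rmse = sqrt(mean(d^2)))),
            class = "deviation_map")
}

#' @export
print.deviation_map <- function(x, ...) {
  s <- x$summary
  cat(sprintf("deviation_map: mean %.3f, sd %.3f, max %.3f, RMSE %.3f mm (%d vertices)\n",
              s["mean"], s["sd"], s["max"], s["rmse"],
              length(x$per_vertex_distance_mm)))
  invisible(x)
}

#' Export a deviation map as a colored-scalar PLY and CSV
#'
#' Writes the carrier mesh with the per-vertex distance as a PLY `quality`
#' property (clamped to `range_mm`, default 0-5 mm as conventionally used
#' for reconstruction heatmaps) plus a plain CSV of the raw distances.
#'
#' @param map a [deviation_map()].
#' @param mesh carrier [triangle_mesh()] (one vertex per distance).
#' @param path output PLY path; a `.csv` with the same stem is written too.
#' @param range_mm clamping range for the exported scalar.
#' @return `invisible(path)`.
#' @export
export_deviation_map <- function(map, mesh, path, range_mm = c(0, 5)) {
  d <- map$per_vertex_distance_mm
  stopifnot(length(d) == nrow(mesh$vertices))
  q <- pmin(pmax(d, range_mm[1]), range_mm[2])
  write_mesh(mesh, path, "ply", quality = q)
  write.csv(data.frame(vertex = seq_along(d), distance_mm = d),
            sub("\\.ply$", ".csv", path), row.names = FALSE)
  invisible(path)
}
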