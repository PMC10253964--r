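# PCA model fitting, synthesis, projection, truncation, partial fitting.

planted_matrix_population <- function(n, p, shares, seed = 1,
                                      total_sd = 10) {
  # direct matrix-level cohort: planted orthonormal modes in R^p
  set.seed(seed)
  k <- length(shares)
  Q <- qr.Q(qr(matrix(rnorm(p * k), p, k)))
  sds <- total_sd * sqrt(shares)
  b <- matrix(rnorm(n * k), n, k)
  mu <- rnorm(p)
  X <- sweep(b %*% (t(Q) * sds), 2, -mu)
  list(X = X, modes = Q, sds = sds, scores = b, mu = mu)
}

test_that("identical shapes give a zero-variance model with the shape as mean", {
  X <- matrix(rep(c(1, 2, 3, 4, 5, 6), each = 5), nrow = 5)
  m <- fit_pca(X)
  expect_equal(length(m$eigenvalues), 0L)
  expect_equal(m$mean, c(1, 2, 3, 4, 5, 6))
})

test_that("a single planted mode is recovered at n = 200", {
  pl <- planted_matrix_population(200, 60, shares = 1, seed = 2)
  m <- fit_pca(pl$X)
  lam_true <- pl$sds[1]^2
  expect_lt(abs(m$eigenvalues[1] - lam_true) / lam_true, 0.20)
  expect_gt(abs(sum(m$components[1, ] * pl$modes[, 1])), 0.99)
})

test_that("a 9:1 planted variance ratio is recovered within sampling bounds", {
  pl <- planted_matrix_population(200, 60, shares = c(0.9, 0.1), seed = 3)
  m <- fit_pca(pl$X)
  ratio <- m$eigenvalues[1] / m$eigenvalues[2]
  expect_gt(ratio, 6)
  expect_lt(ratio, 13)
})

test_that("model invariants hold on every fit (orthonormal, sorted, conserving)", {
  for (seed in 1:5) {
    pl <- planted_matrix_population(30, 45, shares = c(.5, .3, .2),
                                    seed = seed)
    m <- fit_pca(pl$X)
    k <- length(m$eigenvalues)
    expect_lt(max(abs(tcrossprod(m$components) - diag(k))), 1e-8)
    expect_false(is.unsorted(rev(m$eigenvalues)))
    total <- sum(sweep(pl$X, 2, m$mean)^2) / (nrow(pl$X) - 1)
    expect_lt(abs(sum(m$eigenvalues) - total) / total, 1e-6)
    expect_lte(k, nrow(pl$X) - 1)
  }
})

test_that("synthesize is linear and symmetric about the mean", {
  pl <- planted_matrix_population(40, 30, shares = c(.7, .3), seed = 4)
  m <- fit_pca(pl$X)
  expect_equal(as.vector(t(synthesize(m))), m$mean)
  xp <- synthesize(m, c(3, 0))
  xm <- synthesize(m, c(-3, 0))
  expect_equal(as.vector(t(xp + xm)), 2 * m$mean, tolerance = 1e-12)
  expect_error(synthesize(m, rep(1, length(m$eigenvalues) + 1)), "scores")
})

test_that("project/synthesize is the identity on training shapes (SD units)", {
  pl <- planted_matrix_population(25, 36, shares = c(.6, .25, .15), seed = 5)
  m <- fit_pca(pl$X)
  for (i in c(1, 7, 25)) {
    b <- project(m, pl$X[i, ])
    rec <- as.vector(t(synthesize(m, b)))
    expect_lt(sqrt(sum((rec - pl$X[i, ])^2)) / sqrt(sum(pl$X[i, ]^2)), 1e-8)
  }
  # x = mu + 2 sqrt(lambda_2) phi_2 projects to (0, 2, 0, ...)
  x <- m$mean + 2 * sqrt(m$eigenvalues[2]) * m$components[2, ]
  b <- project(m, x)
  expect_equal(b[1:3], c(0, 2, 0), tolerance = 1e-8)
  expect_equal(project(m, m$mean), rep(0, length(m$eigenvalues)),
               tolerance = 1e-10)
  expect_error(project(m, m$mean, k_use = 99), "k_use")
})

test_that("components_for_variance follows the cumulative spectrum", {
  tail_sh <- rep(0.23 / 9, 9)
  pl <- planted_matrix_population(400, 90,
                                  shares = c(0.68, 0.05, 0.04, tail_sh),
                                  seed = 6)
  m <- fit_pca(pl$X)
  expect_equal(components_for_variance(m, 1.0), length(m$eigenvalues))
  # fraction below the (recovered) first share resolves to one component
  sh1 <- m$eigenvalues[1] / sum(m$eigenvalues)
  expect_equal(components_for_variance(m, sh1 - 0.02), 1L)
  # the planted cumulative sums put 0.73 just beyond two components
  cum <- cumsum(m$eigenvalues) / sum(m$eigenvalues)
  k73 <- components_for_variance(m, 0.73)
  expect_equal(k73, which(cum >= 0.73)[1])
  expect_lte(k73, 3L)
  expect_error(components_for_variance(m, 0), "fraction")
  expect_error(components_for_variance(m, 1.2), "fraction")
})

test_that("shape models serialize and restore faithfully", {
  fx <- cohort_exact(n_per_group = 3, seed = 13)
  m <- fit_pca(fx$corresponded)
  dir <- withr::local_tempdir()
  save_shape_model(m, dir)
  back <- load_shape_model(dir)
  expect_equal(back$mean, m$mean, tolerance = 1e-12)
  expect_equal(back$components, m$components, tolerance = 1e-12)
  expect_equal(back$eigenvalues, m$eigenvalues, tolerance = 1e-9)
  expect_equal(back$faces, m$faces)
})

test_that("reconstruction of a complete shape reduces to projection", {
  fx <- cohort_exact(n_per_group = 8, seed = 17)
  m <- fit_pca(fx$corresponded)
  shape_i <- fx$corresponded$shapes[3, , ]
  full_mesh <- triangle_mesh(shape_i, fx$corresponded$faces,
                             validate = FALSE)
  rec <- reconstruct_partial(m, full_mesh, beta = 0)
  expect_gt(mean(rec$observed), 0.95)
  expect_lt(rec$rmse_observed_mm, 2)
  # shape is defined up to rigid motion: the fitted pose carries a small
  # rotational ambiguity (closest-point data barely constrain it), so the
  # geometry is compared after rigid alignment
  al <- fit_similarity(rec$vertices, shape_i, allow_scaling = FALSE)
  rel <- rmse(apply_similarity(al, rec$vertices), shape_i) /
    sqrt(mean(rowSums(shape_i^2)))
  expect_lt(rel, 0.05)
})

test_that("infinite regularization collapses to the posed mean shape", {
  fx <- cohort_exact(n_per_group = 8, seed = 17)
  m <- fit_pca(fx$corresponded)
  shape_i <- fx$corresponded$shapes[2, , ]
  full_mesh <- triangle_mesh(shape_i, fx$corresponded$faces,
                             validate = FALSE)
  rec <- reconstruct_partial(m, full_mesh, beta = 1e12)
  expect_lt(max(abs(rec$scores)), 1e-4)
  posed_mean <- apply_similarity(rec$pose, synthesize(m))
  expect_equal(rec$vertices, posed_mean, tolerance = 1e-8)
  expect_error(reconstruct_partial(m, full_mesh, beta = -1), "beta")
})

test_that("a simulated fracture is extrapolated by the model", {
  fx <- cohort_exact(n_per_group = 15, seed = 19)
  m <- fit_pca(fx$corresponded)
  k_modes <- length(fx$spec$mode_sd)
  i <- 4
  shape_i <- fx$corresponded$shapes[i, , ]
  mesh_i <- triangle_mesh(shape_i, fx$corresponded$faces, validate = FALSE)
  fr <- simulate_fracture(mesh_i, fraction_removed = 0.2,
                          region_center_seed = 2)
  rec <- reconstruct_partial(m, fr$partial,
                             k_use = min(k_modes, length(m$eigenvalues)))
  al <- fit_similarity(rec$vertices, shape_i, allow_scaling = FALSE)
  aligned <- apply_similarity(al, rec$vertices)
  dev <- sqrt(rowSums((aligned - shape_i)^2))
  rmse_removed <- sqrt(mean(dev[fr$removed_mask]^2))
  rmse_observed <- sqrt(mean(dev[!fr$removed_mask]^2))
  expect_lt(rmse_removed, 3 * rmse_observed)
  # the full-shape error stays below the population's mean inter-shape
  # distance (reconstruction is informative, not just the mean)
  X <- ssmesh:::flatten_shapes(fx$corresponded$shapes)
  others <- setdiff(1:10, i)
  pair_rms <- mean(apply(X[others, ], 1, function(r)
    sqrt(mean(rowSums((matrix(r, ncol = 3, byrow = TRUE) - shape_i)^2)))))
  expect_lt(rmse(aligned, shape_i), pair_rms)
})
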