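# RMSE, compactness, leave-one-out generalization, deviation maps.

test_that("rmse matches closed forms and behaves as a metric", {
  a <- matrix(rnorm(30), 10, 3)
  expect_equal(rmse(a, a), 0)
  expect_equal(rmse(a, sweep(a, 2, -c(3, 4, 0))), 5, tolerance = 1e-12)
  # per-point distances 1, 2, 3 -> sqrt(14/3)
  p <- rbind(c(0, 0, 0), c(10, 0, 0), c(0, 10, 0))
  q <- p + rbind(c(1, 0, 0), c(0, 2, 0), c(0, 0, 3))
  expect_equal(rmse(p, q), sqrt(14 / 3), tolerance = 1e-12)
  expect_error(rmse(a, a[1:5, ]), "dimensions")
  # metric properties over random triples
  set.seed(8)
  for (i in 1:25) {
    x <- matrix(rnorm(15), 5, 3); y <- matrix(rnorm(15), 5, 3)
    z <- matrix(rnorm(15), 5, 3)
    expect_equal(rmse(x, y), rmse(y, x))
    expect_lte(rmse(x, z), rmse(x, y) + rmse(y, z) + 1e-12)
    expect_gte(rmse(x, y), 0)
  }
})

test_that("compactness curve is monotone, ends at 1, matches truncation", {
  fx <- cohort_exact(n_per_group = 15, seed = 19)
  m <- fit_pca(fx$corresponded)
  cc <- compactness_curve(m)
  expect_equal(cc$k, seq_along(m$eigenvalues))
  expect_true(all(diff(cc$cumulative_variance_fraction) >= -1e-12))
  expect_equal(cc$cumulative_variance_fraction[nrow(cc)], 1, tolerance = 1e-9)
  for (f in c(0.5, 0.9, 0.99)) {
    k <- components_for_variance(m, f)
    expect_gte(cc$cumulative_variance_fraction[k], f - 1e-9)
    if (k > 1) expect_lt(cc$cumulative_variance_fraction[k - 1], f)
  }
  # single-mode model: curve is [(1, 1.0)]
  X1 <- outer(rnorm(10), c(1, 0, 0, 2, 0, 0))
  m1 <- fit_pca(X1)
  cc1 <- compactness_curve(m1)
  expect_equal(cc1$k, 1L)
  expect_equal(cc1$cumulative_variance_fraction, 1)
})

test_that("leave-one-out on identical shapes is exactly zero", {
  V <- 12
  shape <- matrix(rnorm(V * 3), V, 3)
  shapes <- array(0, c(5, V, 3))
  for (i in 1:5) shapes[i, , ] <- shape
  cs <- structure(list(faces = NULL, shapes = shapes,
                       scale_factors = rep(1, 5),
                       labels = data.frame(id = 1:5, sex = NA),
                       residuals = rep(0, 5), template_index = 1L),
                  class = "corresponded_shapes")
  suppressWarnings(loo <- loo_generalization(cs, k_values = c(1, 2)))
  expect_true(all(loo$summary$mean_rmse_mm == 0))
})

test_that("LOO error decreases with k and bottoms out at the noise floor", {
  fx <- cohort_exact(n_per_group = 12, seed = 23)
  k_modes <- length(fx$spec$mode_sd)
  ks <- c(1, 2, 4, 8, min(k_modes, 22))
  loo <- loo_generalization(fx$corresponded, k_values = ks)
  expect_lte(cor(loo$summary$k, loo$summary$mean_rmse_mm,
                 method = "spearman"), 0)
  expect_true(all(loo$summary$ci95_low_mm <= loo$summary$mean_rmse_mm))
  expect_true(all(loo$summary$ci95_high_mm >= loo$summary$mean_rmse_mm))
  expect_true(all(loo$summary$mean_rmse_mm >=
                    apply(loo$per_shape, 2, min) - 1e-12))
  # oversized k values are trimmed with a warning
  expect_warning(loo_generalization(fx$corresponded,
                                    k_values = c(2, 1000)), "trimmed")
})

test_that("deviation maps report exact distances and summaries", {
  a <- matrix(rnorm(60), 20, 3)
  z <- deviation_map(a, a)
  expect_true(all(z$per_vertex_distance_mm == 0))
  off <- sweep(a, 2, -c(2, 0, 0))
  d2 <- deviation_map(a, off)
  expect_true(all(abs(d2$per_vertex_distance_mm - 2) < 1e-12))
  expect_equal(unname(d2$summary["rmse"]), 2, tolerance = 1e-12)
  expect_equal(unname(d2$summary["rmse"]),
               sqrt(mean(d2$per_vertex_distance_mm^2)), tolerance = 1e-12)
  # nearest-surface mode equals point-to-surface distances
  cube <- cube_mesh(10)
  pts <- rbind(c(5, 5, 12), c(5, 5, 5))
  dm <- deviation_map(pts, cube, mode = "nearest_surface")
  expect_equal(dm$per_vertex_distance_mm, c(2, 5), tolerance = 1e-12)
  expect_error(deviation_map(pts, pts, mode = "nearest_surface"),
               "triangle_mesh")
})

test_that("group deviation concentrates where the group offset was planted", {
  fx <- cohort_exact(n_per_group = 100, seed = 29)
  cs <- fx$corresponded
  # divide out the planted per-shape size so the group contrast isolates
  # the offset field rather than random size imbalance between groups
  for (i in seq_len(dim(cs$shapes)[1]))
    cs$shapes[i, , ] <- cs$shapes[i, , ] / fx$pop$ground_truth$scales[i]
  mean_f <- group_mean_shape(cs, "F")
  mean_m <- group_mean_shape(cs, "M")
  dm <- deviation_map(mean_m$vertices, mean_f$vertices)
  d <- dm$per_vertex_distance_mm
  top <- order(d, decreasing = TRUE)[seq_len(ceiling(0.1 * length(d)))]
  expect_gte(mean(top %in% fx$spec$group_region), 0.8)
})
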