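# Similarity fitting, similarity ICP, non-rigid ICP, template selection,
# population correspondence.

test_that("fit_similarity recovers exact transforms (property over seeds)", {
  set.seed(42)
  x <- matrix(rnorm(300), 100, 3) * 20
  # identity
  tr <- fit_similarity(x, x)
  expect_equal(tr$rotation, diag(3), tolerance = 1e-12)
  expect_equal(tr$scale, 1, tolerance = 1e-12)
  expect_equal(tr$translation, c(0, 0, 0), tolerance = 1e-10)
  # pure scaling about the origin
  tr2 <- fit_similarity(x, 2 * x)
  expect_equal(tr2$scale, 2, tolerance = 1e-12)
  expect_equal(tr2$rotation, diag(3), tolerance = 1e-12)
  expect_equal(max(abs(tr2$translation)), 0, tolerance = 1e-10)
  # planted random similarity transforms, exact recovery
  for (i in 1:100) {
    R <- rotation_about(rnorm(3), runif(1, 0, pi))
    s <- runif(1, 0.5, 2)
    t_vec <- rnorm(3, sd = 50)
    y <- sweep(s * x %*% t(R), 2, -t_vec)
    tr <- fit_similarity(x, y)
    expect_lt(max(abs(tr$rotation - R)), 1e-9)
    expect_lt(abs(tr$scale - s), 1e-9)
    expect_lt(max(abs(tr$translation - t_vec)), 1e-7)
  }
})

test_that("fit_similarity rejects degenerate input", {
  line <- cbind(1:5, 2 * (1:5), 3 * (1:5))
  expect_error(fit_similarity(line, line), "collinear")
  expect_error(fit_similarity(line[1:2, ], line[1:2, ]), "at least 3")
  # reflections are never returned
  x <- matrix(rnorm(30), 10, 3)
  y <- x %*% diag(c(-1, 1, 1))
  tr <- fit_similarity(x, y)
  expect_gt(det(tr$rotation), 0)
})

test_that("similarity ICP recovers planted transforms on copies", {
  m <- translate_to_origin(make_base_mesh(500))$mesh
  set.seed(7)
  R <- rotation_about(rnorm(3), 30 * pi / 180)
  tgt <- m
  tgt$vertices <- sweep(1.1 * m$vertices %*% t(R), 2, -c(5, -3, 2))
  icp <- icp_similarity(m, tgt, tol_mm = 1e-10, max_iterations = 500)
  rec <- apply_similarity(icp$transform, m$vertices)
  diag_len <- sqrt(sum((apply(tgt$vertices, 2, max) -
                          apply(tgt$vertices, 2, min))^2))
  expect_lt(rmse(rec, tgt$vertices), 1e-6 * diag_len)
  # identical meshes converge immediately with near-zero RMS
  icp0 <- icp_similarity(m, m, tol_mm = 1e-10)
  expect_lt(icp0$final_rms_mm, 1e-9)
  expect_lte(icp0$iterations, 2L)
})

test_that("similarity ICP RMS trace is monotone non-increasing", {
  m <- translate_to_origin(make_base_mesh(500))$mesh
  set.seed(12)
  R <- rotation_about(rnorm(3), 25 * pi / 180)
  tgt <- m
  tgt$vertices <- sweep(0.9 * m$vertices %*% t(R), 2, -c(3, 8, -2))
  icp <- icp_similarity(m, tgt, tol_mm = 1e-9, max_iterations = 300)
  expect_true(all(diff(icp$rms_trace) <= 1e-9))
})

test_that("similarity ICP aligns independently remeshed copies below the edge length", {
  m <- make_base_mesh(500)
  a <- translate_to_origin(isotropic_remesh(m, 10, jitter = 0.2, seed = 1))$mesh
  b <- translate_to_origin(isotropic_remesh(m, 10, jitter = 0.2, seed = 2))$mesh
  set.seed(3)
  b$vertices <- b$vertices %*% t(rotation_about(rnorm(3), 0.2))
  icp <- icp_similarity(a, b)
  expect_lt(icp$final_rms_mm, 10)  # below the remeshed edge length
})

test_that("non-rigid ICP is exact on an identical target and recovers smooth warps", {
  m <- translate_to_origin(make_base_mesh(500))$mesh
  nr0 <- nonrigid_icp(m, m)
  expect_lt(nr0$residual_rms_mm, 1e-6)
  expect_lt(max(abs(nr0$vertices - m$vertices)), 1e-6)

  # planted smooth surface-offset warp with known per-vertex ground truth
  set.seed(4)
  vn <- vertex_normals(m)
  v <- m$vertices
  amp <- 2.5 * sin(v[, 1] / 45) + 2 * cos((v[, 2] + v[, 3]) / 50)
  tgt <- m
  tgt$vertices <- v + vn * amp
  nr <- nonrigid_icp(m, tgt)
  warp_rms <- sqrt(mean(amp^2))
  expect_lt(nr$residual_rms_mm, 0.3)
  expect_lt(rmse(nr$vertices, tgt$vertices), 0.5 * warp_rms)
})

test_that("non-rigid ICP fails loudly when no pairs survive pruning", {
  m <- translate_to_origin(make_base_mesh(500))$mesh
  far <- m
  far$vertices <- far$vertices + 500
  expect_error(nonrigid_icp(m, far), "stiffness level")
})

test_that("template selection picks the shape closest to the mean", {
  spec <- population_spec(n_per_group = 2, seed = 9, resolution = 500,
                          destroy_correspondence = FALSE,
                          rotation_max_deg = 0, translation_max_mm = 0,
                          noise_sd_mm = 0)
  base <- translate_to_origin(spec$base_mesh)$mesh
  V <- nrow(base$vertices)
  f2 <- matrix(spec$modes[, 2], V, 3, byrow = TRUE) * spec$mode_sd[2]
  mk <- function(a) {
    m <- base; m$vertices <- base$vertices + a * f2
    translate_to_origin(m)$mesh
  }
  # identical shapes: tie broken to the provisional index
  expect_equal(select_template(list(base, base, base), 2L), 2L)
  # planted scores -2, 0, +2 along one mode: the middle shape wins
  expect_equal(select_template(list(mk(-2), mk(0), mk(2)), 1L), 2L)
  # a shape built exactly at the population mean wins
  expect_equal(select_template(list(mk(-2), mk(2), mk(0), mk(1), mk(-1)), 1L),
               3L)
})

test_that("build_correspondences on identical shapes returns the template everywhere", {
  m <- translate_to_origin(make_base_mesh(500))$mesh
  cs <- build_correspondences(list(m, m, m), n_outer_iterations = 2L)
  expect_s3_class(cs, "corresponded_shapes")
  expect_equal(dim(cs$shapes), c(3L, nrow(m$vertices), 3L))
  expect_true(all(abs(cs$scale_factors - 1) < 1e-6))
  for (i in 1:3)
    expect_lt(rmse(cs$shapes[i, , ], cs$shapes[1, , ]), 1e-4)
})

test_that("correspondence recovers planted sizes and restores extents", {
  spec <- population_spec(n_per_group = 4, seed = 21, resolution = 500,
                          scale_sd = 0.07, destroy_correspondence = FALSE)
  pop <- sample_population(spec)
  cs <- build_correspondences(pop$meshes, labels = pop$labels)
  expect_gt(cor(1 / cs$scale_factors, pop$ground_truth$scales), 0.99)
  # rescaled shapes retain the input extents (bounding-box diagonal)
  diag_of <- function(v) sqrt(sum((apply(v, 2, max) - apply(v, 2, min))^2))
  for (i in seq_along(pop$meshes)) {
    d_in <- diag_of(pop$meshes[[i]]$vertices)
    d_out <- diag_of(cs$shapes[i, , ])
    expect_lt(abs(d_out - d_in) / d_in, 0.03)
  }
})

test_that("corresponded sets serialize and restore faithfully", {
  fx <- cohort_exact(n_per_group = 3, seed = 13)
  dir <- withr::local_tempdir()
  save_corresponded(fx$corresponded, dir)
  back <- load_corresponded(dir)
  expect_equal(back$shapes, fx$corresponded$shapes, tolerance = 1e-12)
  expect_equal(back$faces, fx$corresponded$faces)
  expect_equal(back$scale_factors, fx$corresponded$scale_factors,
               tolerance = 1e-12)
  expect_equal(as.character(back$labels$sex),
               as.character(fx$corresponded$labels$sex))
})
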