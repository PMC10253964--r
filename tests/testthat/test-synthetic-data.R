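# Generator ground truth: base surface, planted modes, fracture patches.

test_that("the base surface is deterministic, watertight and asymmetric", {
  a <- make_base_mesh(500)
  b <- make_base_mesh(500)
  expect_identical(a$vertices, b$vertices)
  expect_identical(a$faces, b$faces)
  q <- mesh_quality(a)
  expect_equal(q$n_boundary_edges, 0L)
  expect_equal(q$n_components, 1L)
  expect_true(q$is_manifold)
  E <- nrow(ssmesh:::mesh_edges(a)$edges)
  expect_equal(q$n_vertices - E + q$n_faces, 2L)  # Euler characteristic 2
  # hemipelvis scale: overall diameter around 200 mm
  diam <- max(dist(a$vertices[seq(1, nrow(a$vertices), by = 3), ]))
  expect_gt(diam, 150); expect_lt(diam, 280)
  # mirroring must be detectable: the mirrored surface is far from the
  # original even after re-alignment at the centroid
  mm <- translate_to_origin(mirror_sagittal(a, "x"))$mesh
  ao <- translate_to_origin(a)$mesh
  expect_gt(hausdorff_distance(ao, mm), 5)
  # labeled regions exist and are disjoint enough to localize modes
  regions <- attr(a, "regions")
  expect_named(regions, c("iliac", "acetabulum", "pubic"))
  expect_true(all(lengths(regions) >= 10))
  expect_lt(length(intersect(regions$iliac, regions$pubic)), 5)
  expect_error(make_base_mesh(100), "at least 500")
})

test_that("planted mode fields are orthonormal and region-localized", {
  spec <- population_spec(n_per_group = 2, seed = 3, resolution = 500)
  G <- crossprod(spec$modes)
  expect_lt(max(abs(G - diag(ncol(G)))), 1e-8)
  expect_equal(sum(spec$variance_shares), 1, tolerance = 1e-9)
  # group-offset energy concentrates in the generator's offset region
  f3 <- matrix(spec$modes[, spec$group_offset_mode],
               nrow(spec$base_mesh$vertices), 3, byrow = TRUE)
  energy <- rowSums(f3^2)
  expect_gte(sum(energy[spec$group_region]) / sum(energy), 0.90)
})

test_that("a degenerate spec reproduces the base mesh; seeds reproduce draws", {
  spec0 <- population_spec(n_per_group = 2, seed = 5, resolution = 500,
                           noise_sd_mm = 0, group_offset_d = 0,
                           rotation_max_deg = 0, translation_max_mm = 0)
  spec0$mode_sd[] <- 0
  spec0$scale_sd <- 0
  pop0 <- sample_population(spec0)
  for (m in pop0$meshes)
    expect_equal(m$vertices, spec0$centered_base, tolerance = 1e-9)
  # determinism: identical spec + seed give identical meshes
  spec <- population_spec(n_per_group = 3, seed = 7, resolution = 500,
                          destroy_correspondence = TRUE)
  p1 <- sample_population(spec)
  p2 <- sample_population(spec)
  for (i in seq_along(p1$meshes))
    expect_identical(p1$meshes[[i]]$vertices, p2$meshes[[i]]$vertices)
})

test_that("the size mode carries its intended variance share", {
  spec <- population_spec(n_per_group = 100, seed = 9, resolution = 500,
                          rotation_max_deg = 0, translation_max_mm = 0,
                          group_offset_d = 0)
  pop <- sample_population(spec)
  X <- t(vapply(pop$meshes, function(m) as.vector(t(m$vertices)),
                numeric(3 * nrow(spec$base_mesh$vertices))))
  Xc <- sweep(X, 2, colMeans(X))
  total_var <- sum(Xc^2) / (nrow(X) - 1)
  size_dir <- spec$modes[, 1]
  var_size <- sum((Xc %*% size_dir)^2) / (nrow(X) - 1)
  expect_lt(abs(var_size / total_var - spec$variance_shares[1]), 0.08)
})

test_that("ground truth records poses, scales and correspondence maps", {
  spec <- population_spec(n_per_group = 25, seed = 11, resolution = 500,
                          destroy_correspondence = TRUE)
  pop <- sample_population(spec)
  gt <- pop$ground_truth
  expect_equal(dim(gt$scores), c(50L, length(spec$mode_sd)))
  expect_true(all(gt$scales > 0))
  for (i in seq_along(pop$meshes)) {
    R <- gt$poses[[i]]$rotation
    expect_lt(max(abs(crossprod(R) - diag(3))), 1e-9)
    cmap <- gt$correspondence[[i]]
    expect_true(all(cmap >= 1 & cmap <= nrow(spec$base_mesh$vertices)))
    expect_equal(length(cmap), nrow(pop$meshes[[i]]$vertices))
  }
  # the offset raises the group-B mean score on the offset mode
  j <- spec$group_offset_mode
  expect_gt(mean(gt$scores[gt$labels$sex == "M", j]) -
              mean(gt$scores[gt$labels$sex == "F", j]), 0)
})

test_that("simulated fractures remove a connected patch of the stated size", {
  m <- make_base_mesh(500)
  fr <- simulate_fracture(m, fraction_removed = 0.2, region_center_seed = 3)
  V <- nrow(m$vertices)
  n_removed <- sum(fr$removed_mask)
  expect_lt(abs(n_removed - 0.2 * V) / V, 0.02)
  # partition: kept and removed are disjoint and exhaustive
  expect_equal(sort(c(which(fr$removed_mask), fr$kept_index)), seq_len(V))
  # removed patch is one connected component of the mesh graph
  g <- ssmesh:::mesh_graph(m)
  sub <- igraph::induced_subgraph(g, which(fr$removed_mask))
  expect_equal(igraph::components(sub)$no, 1L)
  # remaining surface stays connected
  q <- mesh_quality(fr$partial)
  expect_equal(q$n_components, 1L)
  expect_gt(q$n_boundary_edges, 0L)  # fracture rim is an open boundary
  expect_error(simulate_fracture(m, fraction_removed = 0.7), "fraction")
})
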