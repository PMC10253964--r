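# Shared fixtures: tiny analytic meshes and cached synthetic cohorts.

tetra_mesh <- function(scale = 1) {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)) * scale
  f <- rbind(c(1, 3, 2), c(1, 2, 4), c(1, 4, 3), c(2, 3, 4))
  triangle_mesh(v, f, label = "tetra")
}

cube_mesh <- function(edge = 10) {
  v <- as.matrix(expand.grid(c(0, edge), c(0, edge), c(0, edge)))
  colnames(v) <- NULL
  f <- rbind(
    c(1, 3, 2), c(2, 3, 4),  # z = 0 (normal -z)
    c(5, 6, 7), c(6, 8, 7),  # z = edge
    c(1, 2, 5), c(2, 6, 5),  # y = 0
    c(3, 7, 4), c(4, 7, 8),  # y = edge
    c(1, 5, 3), c(3, 5, 7),  # x = 0
    c(2, 4, 6), c(4, 8, 6))  # x = edge
  triangle_mesh(v, f, label = "cube")
}

rotation_about <- function(axis, angle_rad) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -axis[3], axis[2], axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(angle_rad) * K + (1 - cos(angle_rad)) * (K %*% K)
}

# cache expensive fixtures across test files within one run
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- force(expr)
  .fixtures[[name]]
}

# small exact-correspondence cohort (shared topology, known ground truth)
cohort_exact <- function(n_per_group = 20, seed = 5, resolution = 500,
                         ...) {
  key <- paste("exact", n_per_group, seed, resolution, sep = "_")
  fixture(key, {
    spec <- population_spec(n_per_group = n_per_group, seed = seed,
                            resolution = resolution,
                            destroy_correspondence = FALSE,
                            rotation_max_deg = 0, translation_max_mm = 0,
                            ...)
    pop <- sample_population(spec)
    # shared topology + no pose: the generated meshes ARE corresponded;
    # undo the planted per-shape scale exactly as the registration
    # contract would (sizes retained, pose normalized)
    V <- nrow(spec$base_mesh$vertices)
    shapes <- array(0, c(length(pop$meshes), V, 3))
    for (i in seq_along(pop$meshes)) shapes[i, , ] <- pop$meshes[[i]]$vertices
    dimnames(shapes) <- list(pop$labels$id, NULL, c("x", "y", "z"))
    cs <- structure(list(
      faces = spec$base_mesh$faces, shapes = shapes,
      scale_factors = 1 / pop$ground_truth$scales,
      labels = pop$labels, template_history = list(),
      residuals = rep(0, length(pop$meshes)), template_index = 1L),
      class = "corresponded_shapes")
    list(spec = spec, pop = pop, corresponded = cs)
  })
}

# the full study-scale cohort: 100 + 100 shapes, ~2,000 vertices, shared
# shape space with independent per-shape remeshing (no shared topology),
# pushed through the complete correspondence pipeline. Cached: several
# acceptance checks read from it.
registered_cohort <- function() {
  fixture("registered_cohort", {
    spec <- population_spec(n_per_group = 100, resolution = 2000,
                            destroy_correspondence = TRUE, seed = 11)
    pop <- sample_population(spec)
    cs <- build_correspondences(pop$meshes, labels = pop$labels,
                                verbose = FALSE)
    list(spec = spec, pop = pop, corresponded = cs,
         model = fit_pca(cs))
  })
}
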