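# End-to-end orchestration: condition -> correspond -> fit -> evaluate ->
# group-compare, with a resolved-config manifest and deterministic outputs.

#' Pipeline configuration
#'
#' Defaults follow standard hemipelvis SSM practice: 1.5 mm isotropic
#' remeshing, three registration iterations with mean-template refresh, a
#' 90% variance truncation and 15 reported components.
#'
#' @param input_dir directory of mesh files (STL/PLY/OBJ) with a
#'   `labels.csv` (columns `id`, `sex`, optional `file`); ignored when
#'   `run_pipeline()` is given meshes directly.
#' @param output_dir artifact directory.
#' @param remesh_edge_mm isotropic remeshing target (NULL skips
#'   conditioning, e.g. for already-uniform meshes).
#' @param smooth_iterations Taubin smoothing passes before remeshing
#'   (0 skips).
#' @param n_outer_iterations registration rounds.
#' @param nonrigid a [nonrigid_params()].
#' @param variance_fraction model truncation target.
#' @param n_pcs_report components reported/tested in the group comparison.
#' @param alpha significance level.
#' @param run_loo compute leave-one-out generalization (the most expensive
#'   evaluation step).
#' @param loo_k component grid for the LOO curve (default powers of two).
#' @param seed integer seed recorded in the manifest and used for any
#'   stochastic step.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(input_dir = NULL, output_dir = "ssmesh_out",
                            remesh_edge_mm = 1.5, smooth_iterations = 0L,
                            n_outer_iterations = 3L,
                            nonrigid = nonrigid_params(),
                            variance_fraction = 0.90, n_pcs_report = 15L,
                            alpha = 0.05, run_loo = FALSE, loo_k = NULL,
                            seed = 1L) {
  structure(list(input_dir = input_dir, output_dir = output_dir,
                 remesh_edge_mm = remesh_edge_mm,
                 smooth_iterations = as.integer(smooth_iterations),
                 n_outer_iterations = as.integer(n_outer_iterations),
                 nonrigid = nonrigid,
                 variance_fraction = variance_fraction,
                 n_pcs_report = as.integer(n_pcs_report),
                 alpha = alpha, run_loo = run_loo, loo_k = loo_k,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

read_population_dir <- function(input_dir) {
  labels_path <- file.path(input_dir, "labels.csv")
  if (!file.exists(labels_path))
    stop(sprintf("missing %s", labels_path))
  labels <- read.csv(labels_path)
  if (is.null(labels$file))
    labels$file <- paste0(labels$id, ".ply")
  meshes <- lapply(seq_len(nrow(labels)), function(i)
    read_mesh(file.path(input_dir, labels$file[i]),
              label = as.character(labels$id[i])))
  list(meshes = meshes, labels = labels[c("id", "sex")])
}

#' Run the full shape-modeling pipeline
#'
#' Conditions the meshes (optional smoothing and isotropic remeshing),
#' establishes correspondence, fits the PCA model, writes the model,
#' compactness (and optionally leave-one-out generalization), the group
#' comparison when two groups are present, the mean shape, +/-3 SD meshes
#' of the first three components, and a provenance manifest. Rerunning
#' with an identical config and seed reproduces all numeric outputs.
#'
#' @param config a [pipeline_config()].
#' @param meshes optional list of [triangle_mesh()] (bypasses
#'   `config$input_dir`).
#' @param labels data.frame with `id`, `sex` matching `meshes`.
#' @param verbose log per-stage progress.
#' @return invisibly, a list with `corresponded`, `model`, `evaluation`,
#'   `comparison` and the artifact directory.
#' @export
run_pipeline <- function(config, meshes = NULL, labels = NULL,
                         verbose = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  set.seed(config$seed)
  t0 <- proc.time()[["elapsed"]]
  timings <- list()
  log_stage <- function(stage, ...) {
    if (verbose) message(sprintf("[%s] %s", stage, sprintf(...)))
  }

  if (is.null(meshes)) {
    if (is.null(config$input_dir)) stop("no input: provide meshes or input_dir")
    pop <- read_population_dir(config$input_dir)
    meshes <- pop$meshes
    labels <- pop$labels
  }
  if (is.null(labels))
    labels <- data.frame(id = vapply(meshes, function(m) m$label, ""),
                         sex = NA_character_)
  out_dir <- config$output_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  # --- conditioning ---
  tic <- proc.time()[["elapsed"]]
  if (config$smooth_iterations > 0L)
    meshes <- lapply(meshes, taubin_smooth,
                     iterations = config$smooth_iterations)
  if (!is.null(config$remesh_edge_mm))
    meshes <- lapply(seq_along(meshes), function(i)
      isotropic_remesh(meshes[[i]], config$remesh_edge_mm,
                       seed = config$seed + i))
  timings$condition <- proc.time()[["elapsed"]] - tic
  log_stage("condition", "%d meshes conditioned (%.1f s)", length(meshes),
            timings$condition)

  # --- correspondence ---
  tic <- proc.time()[["elapsed"]]
  corresponded <- build_correspondences(
    meshes, labels = labels,
    n_outer_iterations = config$n_outer_iterations,
    params = config$nonrigid, verbose = verbose)
  timings$correspond <- proc.time()[["elapsed"]] - tic
  save_corresponded(corresponded, file.path(out_dir, "corresponded"))
  log_stage("correspond", "mean residual %.3f mm (%.1f s)",
            mean(corresponded$residuals), timings$correspond)

  # --- model ---
  tic <- proc.time()[["elapsed"]]
  model <- fit_pca(corresponded)
  timings$fit <- proc.time()[["elapsed"]] - tic
  save_shape_model(model, file.path(out_dir, "model"))
  k90 <- components_for_variance(model, config$variance_fraction)
  log_stage("fit", "%d components; %d needed for %.0f%% variance",
            length(model$eigenvalues), k90, 100 * config$variance_fraction)

  # --- evaluation ---
  tic <- proc.time()[["elapsed"]]
  comp <- compactness_curve(model)
  write.csv(comp, file.path(out_dir, "compactness.csv"), row.names = FALSE)
  loo <- NULL
  if (config$run_loo) {
    loo <- loo_generalization(corresponded, k_values = config$loo_k)
    write.csv(loo$summary, file.path(out_dir, "generalization.csv"),
              row.names = FALSE)
  }
  timings$evaluate <- proc.time()[["elapsed"]] - tic

  # --- mean and mode meshes ---
  mean_mesh <- triangle_mesh(unflatten_shape(model$mean), model$faces,
                             label = "mean", validate = FALSE)
  write_mesh(mean_mesh, file.path(out_dir, "mean_shape.ply"), "ply")
  for (pc in seq_len(min(3L, length(model$eigenvalues)))) {
    for (sd3 in c(-3, 3)) {
      b <- numeric(pc); b[pc] <- sd3
      write_mesh(triangle_mesh(synthesize(model, b), model$faces,
                               label = sprintf("PC%d_%+dSD", pc, sd3),
                               validate = FALSE),
                 file.path(out_dir, sprintf("pc%d_%s3sd.ply", pc,
                                            if (sd3 > 0) "plus" else "minus")),
                 "ply")
    }
  }

  # --- group comparison ---
  comparison <- NULL
  sexes <- unique(labels$sex[!is.na(labels$sex)])
  if (length(sexes) == 2L) {
    tic <- proc.time()[["elapsed"]]
    scores <- score_matrix(model, corresponded)
    m <- min(config$n_pcs_report, ncol(scores))
    comparison <- pc_score_ttest(scores, corresponded$labels$sex, m = m,
                                 alpha = config$alpha)
    write.csv(comparison$table, file.path(out_dir, "group_comparison.csv"),
              row.names = FALSE)
    diag_n <- normality_diagnostics(scores, m = m)
    sw <- data.frame(
      pc = vapply(diag_n$per_pc, `[[`, 0L, "pc"),
      shapiro_w = vapply(diag_n$per_pc, function(p)
        if (is.null(p$shapiro_w)) NA_real_ else p$shapiro_w, 0),
      shapiro_p = vapply(diag_n$per_pc, function(p)
        if (is.null(p$shapiro_p)) NA_real_ else p$shapiro_p, 0))
    write.csv(sw, file.path(out_dir, "normality.csv"), row.names = FALSE)
    for (g in sexes)
      write_mesh(group_mean_shape(corresponded, g),
                 file.path(out_dir, sprintf("mean_%s.ply", g)), "ply")
    timings$group <- proc.time()[["elapsed"]] - tic
    log_stage("group", "%d/%d components differ at alpha = %.3g",
              sum(comparison$table$significant), m, config$alpha)
  }

  manifest <- list(
    config = config[setdiff(names(config), "nonrigid")],
    nonrigid = unclass(config$nonrigid),
    n_shapes = length(meshes),
    n_template_vertices = dim(corresponded$shapes)[2],
    k_components = length(model$eigenvalues),
    k_for_variance_fraction = k90,
    seed = config$seed,
    package_version = as.character(utils::packageVersion("ssmesh")),
    r_version = R.version.string,
    wall_time_s = timings,
    total_wall_time_s = proc.time()[["elapsed"]] - t0)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")

  invisible(list(corresponded = corresponded, model = model,
                 compactness = comp, loo = loo, comparison = comparison,
                 output_dir = out_dir))
}
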