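# Group (e.g. male/female) comparison: mean shapes by coordinate
# averaging, per-component t-tests, normality diagnostics.

#' Group mean shape
#'
#' Vertex-wise mean of the registered, rescaled coordinates of all shapes
#' carrying the given label, on the template topology.
#'
#' @param corresponded a `corresponded_shapes` object.
#' @param group value matched against `corresponded$labels[[group_column]]`.
#' @param group_column label column (default `"sex"`).
#' @return a [triangle_mesh()].
#' @export
group_mean_shape <- function(corresponded, group, group_column = "sex") {
  lab <- corresponded$labels[[group_column]]
  if (is.null(lab)) stop(sprintf("no label column '%s'", group_column))
  idx <- which(lab == group)
  if (length(idx) == 0L) stop(sprintf("no shapes with %s == '%s'", group_column, group))
  verts <- apply(corresponded$shapes[idx, , , drop = FALSE], c(2, 3), mean)
  triangle_mesh(verts, corresponded$faces,
                label = sprintf("mean_%s", group), validate = FALSE)
}

#' Score matrix of a population under a shape model
#'
#' SD-unit component scores of every corresponded shape.
#'
#' @param model a [fit_pca()] model.
#' @param corresponded a `corresponded_shapes` object.
#' @param k_use number of components (default all).
#' @return n x k matrix, rows named by shape id.
#' @export
score_matrix <- function(model, corresponded, k_use = NULL) {
  X <- flatten_shapes(corresponded$shapes)
  if (is.null(k_use)) k_use <- length(model$eigenvalues)
  out <- t(apply(X, 1, function(x) project(model, x, k_use = k_use)))
  rownames(out) <- as.character(corresponded$labels$id)
  colnames(out) <- paste0("PC", seq_len(k_use))
  out
}

#' Per-component two-sample t-tests between groups
#'
#' Tests, for each of the first m principal components, whether the mean
#' score differs between the two groups (Welch's unequal-variance t-test by
#' default; Student's variant available). The t statistic is invariant to
#' the SD-unit scaling of the scores.
#'
#' @param scores n x k score matrix (rows = shapes), e.g. from
#'   [score_matrix()].
#' @param labels length-n group labels with exactly two levels present.
#' @param m number of leading components to test (default 15, capped at k).
#' @param alpha significance level.
#' @param variant `"welch"` or `"student"`.
#' @param adjustment multiple-testing adjustment: `"none"` (default),
#'   `"bonferroni"` or `"holm"`.
#' @return object of class `group_comparison`: data.frame `table` with
#'   per-PC means, t, df, p, adjusted p and significance flag, plus the
#'   settings.
#' @export
pc_score_ttest <- function(scores, labels, m = 15L, alpha = 0.05,
                           variant = c("welch", "student"),
                           adjustment = c("none", "bonferroni", "holm")) {
  variant <- match.arg(variant)
  adjustment <- match.arg(adjustment)
  labels <- as.character(labels)
  stopifnot(nrow(scores) == length(labels))
  groups <- sort(unique(labels[!is.na(labels)]))
  if (length(groups) != 2L)
    stop(sprintf("exactly two groups required, found %d", length(groups)))
  ga <- scores[labels == groups[1], , drop = FALSE]
  gb <- scores[labels == groups[2], , drop = FALSE]
  if (nrow(ga) < 2L || nrow(gb) < 2L)
    stop("each group needs at least 2 shapes")
  m <- min(m, ncol(scores))
  rows <- lapply(seq_len(m), function(j) {
    tt <- t.test(ga[, j], gb[, j], var.equal = (variant == "student"))
    data.frame(pc = j,
               mean_a = mean(ga[, j]), mean_b = mean(gb[, j]),
               t_statistic = unname(tt$statistic),
               df = unname(tt$parameter),
               p_value = tt$p.value)
  })
  tab <- do.call(rbind, rows)
  tab$p_adjusted <- p.adjust(tab$p_value, method = adjustment)
  tab$significant <- tab$p_adjusted < alpha
  names(tab)[names(tab) == "mean_a"] <- paste0("mean_", groups[1])
  names(tab)[names(tab) == "mean_b"] <- paste0("mean_", groups[2])
  structure(list(table = tab, groups = groups, alpha = alpha,
                 variant = variant, adjustment = adjustment),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("per-PC %s t-test, %s vs %s (alpha %.3g, adjustment %s)\n",
              x$variant, x$groups[1], x$groups[2], x$alpha, x$adjustment))
  print(x$table, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Normality diagnostics for component scores
#'
#' Histogram and Q-Q data per component (theoretical standard-normal
#' quantiles at plotting positions `(i - 0.5) / n`), plus an optional
#' Shapiro-Wilk test, as used to check the Gaussian assumption behind
#' SD-unit scores and t-tests.
#'
#' @param scores n x k score matrix.
#' @param m number of leading components (default 15, capped).
#' @param n_bins histogram bin count (default Sturges).
#' @param shapiro also run Shapiro-Wilk (n between 3 and 5000).
#' @return object of class `normality_diagnostics`: per-PC list with
#'   `histogram` (breaks, counts), `qq` (data.frame theoretical, sample),
#'   `degenerate` flag, and optional `shapiro_w`, `shapiro_p`.
#' @export
normality_diagnostics <- function(scores, m = 15L, n_bins = NULL,
                                  shapiro = TRUE) {
  n <- nrow(scores)
  if (n < 3L) stop("need at least 3 samples")
  m <- min(m, ncol(scores))
  per_pc <- lapply(seq_len(m), function(j) {
    x <- scores[, j]
    if (sd(x) == 0) {
      return(list(pc = j, degenerate = TRUE, histogram = NULL, qq = NULL))
    }
    brk <- if (is.null(n_bins)) "Sturges" else
      seq(min(x), max(x), length.out = n_bins + 1)
    h <- graphics::hist(x, breaks = brk, plot = FALSE)
    qq <- data.frame(theoretical = qnorm((seq_len(n) - 0.5) / n),
                     sample = sort(x))
    out <- list(pc = j, degenerate = FALSE,
                histogram = list(breaks = h$breaks, counts = h$counts),
                qq = qq)
    if (shapiro && n >= 3 && n <= 5000) {
      sw <- shapiro.test(x)
      out$shapiro_w <- unname(sw$statistic)
      out$shapiro_p <- sw$p.value
    }
    out
  })
  structure(list(per_pc = per_pc, n = n), class = "normality_diagnostics")
}

#' @export
print.normality_diagnostics <- function(x, ...) {
  cat(sprintf("normality diagnostics for %d PCs (n = %d)\n",
              length(x$per_pc), x$n))
  for (p in x$per_pc) {
    if (p$degenerate) {
      cat(sprintf("  PC%d: degenerate (zero variance)\n", p$pc))
    } else if (!is.null(p$shapiro_p)) {
      cat(sprintf("  PC%d: Shapiro-Wilk W = %.4f, p = %.3g\n",
                  p$pc, p$shapiro_w, p$shapiro_p))
    }
  }
  invisible(x)
}
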