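# Group mean shapes, per-component t-tests, normality diagnostics.

test_that("group mean shapes follow exact averaging identities", {
  fx <- cohort_exact(n_per_group = 10, seed = 31)
  cs <- fx$corresponded
  # single-member group equals that shape
  cs1 <- cs
  cs1$labels$sex <- c("A", rep("B", nrow(cs$labels) - 1))
  expect_equal(group_mean_shape(cs1, "A")$vertices,
               unname(cs$shapes[1, , ]))
  # the union mean is the weighted mean of the group means (exact)
  mf <- group_mean_shape(cs, "F")$vertices
  mm <- group_mean_shape(cs, "M")$vertices
  nf <- sum(cs$labels$sex == "F"); nm <- sum(cs$labels$sex == "M")
  overall <- unname(apply(cs$shapes, c(2, 3), mean))
  expect_equal((nf * mf + nm * mm) / (nf + nm), overall, tolerance = 1e-12)
  expect_error(group_mean_shape(cs, "X"), "no shapes")
  # two shapes symmetric about a reference average to the reference
  ref <- unname(cs$shapes[1, , ])
  delta <- matrix(rnorm(length(ref)), nrow(ref), 3)
  cs2 <- cs
  cs2$shapes <- cs$shapes[1:2, , , drop = FALSE]
  cs2$shapes[1, , ] <- ref + delta
  cs2$shapes[2, , ] <- ref - delta
  cs2$labels <- data.frame(id = 1:2, sex = c("Z", "Z"))
  expect_equal(group_mean_shape(cs2, "Z")$vertices, ref, tolerance = 1e-12)
})

test_that("the planted group offset is recovered from the group mean difference", {
  fx <- cohort_exact(n_per_group = 50, seed = 37)
  spec <- fx$spec
  cs <- fx$corresponded
  diff_vec <- as.vector(t(group_mean_shape(cs, "M")$vertices -
                            group_mean_shape(cs, "F")$vertices))
  f3 <- spec$modes[, spec$group_offset_mode]
  recovered <- sum(diff_vec * f3) / spec$mode_sd[spec$group_offset_mode]
  se <- 2 * sqrt(1 / 50 + 1 / 50)  # 2 sd of a difference of means (SD units)
  expect_lt(abs(recovered - spec$group_offset_d), se)
})

test_that("t-tests are exact on identical groups and detect large separations", {
  scores <- matrix(rnorm(40 * 4), 40, 4)
  labels <- rep(c("F", "M"), each = 20)
  same <- rbind(scores[1:20, ], scores[1:20, ])
  res0 <- pc_score_ttest(same, labels, m = 4)
  expect_true(all(abs(res0$table$t_statistic) < 1e-12))
  expect_true(all(res0$table$p_value > 1 - 1e-12))
  expect_false(any(res0$table$significant))
  # seeded cohort-scale separation (means 180 vs 167, sd 7) is detected
  set.seed(100)
  height <- c(rnorm(100, 180, 7), rnorm(100, 167, 7))
  res <- pc_score_ttest(cbind(height), rep(c("M", "F"), each = 100), m = 1)
  expect_lt(res$table$p_value, 0.001)
  expect_true(res$table$significant)
  expect_error(pc_score_ttest(scores, rep("F", 40)), "two groups")
})

test_that("the t statistic is invariant to score scaling and variants are labeled", {
  set.seed(41)
  scores <- matrix(rnorm(60 * 3), 60, 3)
  labels <- rep(c("F", "M"), each = 30)
  a <- pc_score_ttest(scores, labels, m = 3)
  b <- pc_score_ttest(scores * 17.3, labels, m = 3)
  expect_equal(a$table$t_statistic, b$table$t_statistic, tolerance = 1e-12)
  expect_equal(a$table$p_value, b$table$p_value, tolerance = 1e-12)
  st <- pc_score_ttest(scores, labels, m = 3, variant = "student")
  expect_equal(st$variant, "student")
  expect_equal(st$table$df[1], 58)
  hl <- pc_score_ttest(scores, labels, m = 3, adjustment = "holm")
  expect_equal(hl$table$p_adjusted, p.adjust(hl$table$p_value, "holm"))
})

test_that("normality diagnostics emit conserving histograms and ordered Q-Q data", {
  set.seed(43)
  scores <- matrix(rnorm(200 * 3), 200, 3)
  nd <- normality_diagnostics(scores, m = 3)
  for (p in nd$per_pc) {
    expect_false(p$degenerate)
    expect_equal(sum(p$histogram$counts), 200L)
    expect_false(is.unsorted(p$qq$theoretical))
    expect_false(is.unsorted(p$qq$sample))
    expect_gt(p$shapiro_p, 1e-6)
  }
  # a large standard-normal sample sits on the identity line centrally
  big <- matrix(rnorm(10000), ncol = 1)
  nb <- normality_diagnostics(big, m = 1, shapiro = FALSE)
  qq <- nb$per_pc[[1]]$qq
  central <- abs(qq$theoretical) < qnorm(0.99)
  expect_lt(max(abs(qq$sample[central] - qq$theoretical[central])), 0.1)
  # constant scores flag as degenerate
  ndc <- normality_diagnostics(cbind(rep(1, 50)), m = 1)
  expect_true(ndc$per_pc[[1]]$degenerate)
})
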