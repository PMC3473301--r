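test_that("fold metrics follow the class-count arithmetic", {
  truth <- rep(c(1L, -1L), c(5, 25))
  m <- orfclass:::fold_metrics(truth, rep(-1L, 30))
  expect_equal(unname(m["percent_correct"]), 100 * 25 / 30, tolerance = 1e-9)
  expect_equal(unname(m["sensitivity"]), 0)
  expect_equal(unname(m["specificity"]), 100)
  # percent correct is the class-weighted mix of sensitivity and specificity
  pred <- rep(c(1L, -1L, 1L, -1L), c(3, 2, 5, 20))
  m2 <- orfclass:::fold_metrics(truth, pred)
  expect_equal(unname(m2["percent_correct"]),
               unname((5 * m2["sensitivity"] + 25 * m2["specificity"]) / 30),
               tolerance = 1e-9)
})

test_that("cross-validation emits one record per fold with both classes", {
  orfs <- contrast_dataset(20, 40, seed = 30)
  rec <- run_cv(orfs, "imm", "codon", folds = 5, seed = 1)
  expect_equal(nrow(rec), 5L)
  expect_equal(rec$fold, 1:5)
  expect_true(all(rec$percent_correct >= 0 & rec$percent_correct <= 100))
  # contrast this strong is fully separable
  expect_true(all(rec$percent_correct == 100))
  rec2 <- run_cv(orfs, "cppls", "codon", folds = 5, seed = 1, A_max = 2,
                 inner_folds = 0)
  expect_true(all(rec2$percent_correct == 100))
})

test_that("score density overlap is 1 for identical and 0 for disjoint samples", {
  s <- rep(c(-2, 0, 3), 20)
  sd1 <- score_densities(c(s, s), rep(c(1L, -1L), each = 60))
  expect_equal(sd1$overlap, 1, tolerance = 1e-3)
  sd2 <- score_densities(c(rnorm(50, 50), rnorm(50, -50)),
                         rep(c(1L, -1L), each = 50))
  expect_lt(sd2$overlap, 0.01)
  # symmetric in the two classes
  x <- c(rnorm(40, 1), rnorm(40))
  l <- rep(c(1L, -1L), each = 40)
  expect_equal(score_densities(x, l)$overlap, score_densities(x, -l)$overlap,
               tolerance = 1e-12)
  expect_error(score_densities(rnorm(5), rep(1L, 5)), "both classes")
})

test_that("the arcsine square-root transform maps percentages as stated", {
  expect_equal(transform_performance(100), pi / 2)
  expect_equal(transform_performance(50), pi / 4)
  expect_equal(transform_performance(0), 0)
  expect_error(transform_performance(101), "\\[0, 100\\]")
  y <- seq(0, 100, by = 5)
  expect_true(all(diff(transform_performance(y)) > 0))
})

test_that("the transform stabilizes binomial variance", {
  set.seed(31)
  ratio <- vapply(c(0.7, 0.8, 0.9, 0.95, 0.99), function(p) {
    y <- 100 * rbinom(4000, 100, p) / 100
    c(var_y = var(y), var_z = var(transform_performance(y)))
  }, numeric(2))
  spread <- function(v) max(v) / min(v)
  expect_lt(spread(ratio["var_z", ]), spread(ratio["var_y", ]))
})

test_that("balanced mixed-effect ANOVA matches the mean-decomposition oracle", {
  cells <- simulate_performance_table(n_species = 4, seed = 32)
  a <- mixed_anova(cells)
  oracle <- balanced_ss_oracle(cells)
  expect_lt(abs(a$table$sum_sq[1] - oracle["method"]), 1e-9)
  expect_lt(abs(a$table$sum_sq[2] - oracle["representation"]), 1e-9)
  expect_lt(abs(a$table$sum_sq[3] - oracle["interaction"]), 1e-9)
  expect_lt(abs(a$table$sum_sq[4] - oracle["species"]), 1e-9)
  expect_lt(abs(a$table$sum_sq[5] - oracle["residual"]), 1e-9)
  # additivity of the decomposition
  expect_lt(abs(sum(a$table$sum_sq) - oracle["total"]), 1e-9)
  # degrees of freedom sum to cells - 1
  expect_equal(sum(a$table$df), nrow(cells) - 1)
})

test_that("ANOVA degrees of freedom and variance components behave", {
  cells <- simulate_performance_table(n_species = 12, seed = 33)
  a <- mixed_anova(cells)
  expect_equal(a$table$df, c(1, 2, 2, 11, 55))
  ms <- a$table$mean_sq
  expect_equal(a$sigma_e, sqrt(ms[5]))
  expect_equal(a$sigma_s, sqrt(max(0, (ms[4] - ms[5]) / 6)))
  # all-equal cells give zero sums of squares
  flat <- cells; flat$z <- 1
  a0 <- mixed_anova(flat)
  expect_equal(a0$table$sum_sq, rep(0, 5), tolerance = 1e-12)
  # incomplete table is rejected
  expect_error(mixed_anova(cells[-1, ]), "balanced")
})

test_that("Tukey adjusted p-values match the studentized-range oracle", {
  set.seed(34)
  df <- data.frame(g = factor(rep(c("a", "b", "c"), each = 8)),
                   y = rnorm(24) + rep(c(0, 0.5, 1), each = 8))
  fit <- stats::aov(y ~ g, df)
  s <- summary(fit)[[1]]
  mine <- tukey_hsd(tapply(df$y, df$g, mean), s["Residuals", "Mean Sq"],
                    s["Residuals", "Df"], 8)
  ref <- stats::TukeyHSD(fit)$g
  key <- paste(mine$group_b, mine$group_a, sep = "-")
  expect_lt(max(abs(mine$p_adj - ref[key, "p adj"])), 1e-6)
  # identical means are never significant
  same <- tukey_hsd(c(a = 1, b = 1), 0.5, 10, 5)
  expect_gt(same$p_adj, 0.999)
  # range-based adjustment is conservative relative to a plain t test
  pt2 <- 2 * stats::pt(abs(diff(tapply(df$y, df$g, mean))[1]) /
                         sqrt(2 * s["Residuals", "Mean Sq"] / 8),
                       s["Residuals", "Df"], lower.tail = FALSE)
  expect_gte(mine$p_adj[mine$group_a == "a" & mine$group_b == "b"], pt2)
  expect_error(tukey_hsd(c(a = 1, b = 2), 0.5, 0, 5), "df_residual")
})

test_that("variance F-test inverts under sample swap and detects 4x variance", {
  set.seed(35)
  a <- rnorm(100, 0, 2)
  b <- rnorm(100, 0, 1)
  f1 <- variance_f_test(a, b)
  f2 <- variance_f_test(b, a)
  expect_equal(f1$F, 1 / f2$F, tolerance = 1e-12)
  # the two-sided p is evaluated on opposite F tails; equal up to the
  # floating-point error of the distribution function
  expect_equal(f1$p_value, f2$p_value, tolerance = 1e-4)
  expect_lt(f1$p_value, 0.01)
  expect_equal(variance_f_test(a, a)$F, 1)
  expect_error(variance_f_test(a, rep(1, 5)), "zero variance")
})

test_that("planted fixed effects are detected by the mixed model", {
  cells <- simulate_performance_table(
    n_species = 12, method_effect = 0.1,
    representation_effects = c(0.05, 0, -0.05),
    interaction_effect = 0.05, seed = 36
  )
  a <- mixed_anova(cells)
  p <- a$table$p_value
  expect_lt(p[1], 0.01)  # method
  expect_lt(p[2], 0.01)  # representation
  # a null table yields calibrated (non-tiny) p-values most of the time
  null_cells <- simulate_performance_table(
    n_species = 12, method_effect = 0, representation_effects = c(0, 0, 0),
    interaction_effect = 0, seed = 37
  )
  expect_gt(mixed_anova(null_cells)$table$p_value[1], 0.001)
})

test_that("fold records aggregate into transformed balanced cells", {
  rec <- expand.grid(method = c("imm", "cppls"),
                     representation = c("codon", "protein", "dna"),
                     species = c("s1", "s2"), fold = 1:3,
                     stringsAsFactors = FALSE)
  rec$percent_correct <- 90 + as.integer(factor(rec$method)) * 2 + rec$fold
  cells <- performance_cells(rec)
  expect_equal(nrow(cells), 12L)
  one <- rec[rec$method == "imm" & rec$representation == "codon" &
               rec$species == "s1", "percent_correct"]
  expect_equal(cells$z[cells$method == "imm" & cells$representation == "codon" &
                         cells$species == "s1"],
               transform_performance(mean(one)))
})
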