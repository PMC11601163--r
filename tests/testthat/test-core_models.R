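test_that("fit_marker solves the exact-line case", {
  spec <- model_spec(form = "simple", predictors = "sucs")
  fit <- fit_marker(y = c(1, 2, 3), X = matrix(c(-1, 0, 1), 3, 1),
                    samples = rep("s", 3), spec)
  expect_equal(unname(fit$intercepts), 2, tolerance = 1e-12)
  expect_equal(unname(fit$slopes[1, ]), 1, tolerance = 1e-12)
  expect_equal(fit$residuals, rep(0, 3), tolerance = 1e-12)
  expect_equal(fit$r_squared, 1)
})

test_that("all three forms match the normal-equations oracle", {
  set.seed(21)
  n <- 60
  samples <- rep(c("s1", "s2"), each = n / 2)
  X <- matrix(rnorm(n * 2), n, 2, dimnames = list(NULL, c("x1", "x2")))
  y <- 1 + 0.5 * X[, 1] - 0.3 * X[, 2] +
    ifelse(samples == "s2", 0.8, 0) + rnorm(n, sd = 0.3)

  solve_ne <- function(D, y) solve(t(D) %*% D, t(D) %*% y)

  # simple: [1, X]
  f1 <- fit_marker(y, X, samples, model_spec(form = "simple",
                                             predictors = "sucs"))
  b1 <- solve_ne(cbind(1, X), y)
  expect_equal(unname(c(f1$intercepts, f1$slopes[1, ])), as.vector(b1),
               tolerance = 1e-10)

  # offset: [indicators, X], no global intercept (cell-means coding)
  f2 <- fit_marker(y, X, samples, model_spec(form = "offset",
                                             predictors = "sucs"))
  D <- cbind(samples == "s1", samples == "s2", X)
  b2 <- solve_ne(D, y)
  expect_equal(unname(c(f2$intercepts, f2$slopes[1, ])), as.vector(b2),
               tolerance = 1e-10)
  expect_equal(f2$slopes["s1", ], f2$slopes["s2", ])  # shared slope
  expect_equal(f2$residuals, as.vector(y - D %*% b2), tolerance = 1e-10)

  # interaction == concatenation of independent per-sample simple fits
  f3 <- fit_marker(y, X, samples, model_spec(form = "interaction",
                                             predictors = "sucs"))
  for (s in c("s1", "s2")) {
    idx <- samples == s
    bs <- solve_ne(cbind(1, X[idx, ]), y[idx])
    expect_equal(unname(c(f3$intercepts[s], f3$slopes[s, ])), as.vector(bs),
                 tolerance = 1e-10)
  }

  # fitted + residual reproduces the input; residuals sum to 0 per stratum
  for (f in list(f1, f2, f3)) {
    expect_equal(f$fitted + f$residuals, y, tolerance = 1e-8)
    expect_lt(abs(sum(f$residuals)), 1e-6 * n)
  }
  for (s in c("s1", "s2"))
    expect_lt(abs(sum(f3$residuals[samples == s])), 1e-6 * n)

  # nested-model R^2 ordering
  expect_gte(f3$r_squared, f2$r_squared - 1e-12)
  expect_gte(f2$r_squared, f1$r_squared - 1e-12)
})

test_that("fit_marker error contracts: singular design, small strata", {
  set.seed(22)
  n <- 30
  x <- rnorm(n)
  X <- cbind(x1 = x, x2 = 2 * x)  # collinear
  expect_error(fit_marker(rnorm(n), X, rep("s", n),
                          model_spec(form = "simple", predictors = "sucs")),
               "collinear")
  X2 <- cbind(x1 = rnorm(n), x2 = rnorm(n))
  samples <- c(rep("big", n - 2), "tiny", "tiny")
  expect_error(fit_marker(rnorm(n), X2, samples,
                          model_spec(form = "interaction",
                                     predictors = "sucs")),
               "tiny")
  expect_error(fit_marker(rnorm(5), X2, rep("s", n),
                          model_spec(form = "simple", predictors = "sucs")),
               "agree in length")
})

test_that("correct_marker implements intercept + residual, both offsets", {
  set.seed(23)
  n <- 80
  samples <- rep(c("a", "b"), each = n / 2)
  X <- matrix(rnorm(n), n, 1, dimnames = list(NULL, "x"))
  y <- 2 + 1.5 * X[, 1] + ifelse(samples == "b", 1, 0) + rnorm(n, 0.2)

  spec <- model_spec(form = "interaction", predictors = "sucs",
                     keep_offset = TRUE)
  fit <- fit_marker(y, X, samples, spec)
  ystar <- correct_marker(fit, spec)
  # independent subtraction oracle: y - slope(j) * x
  oracle <- y - fit$slopes[samples, "x"] * X[, 1]
  expect_equal(ystar, unname(oracle), tolerance = 1e-10)

  # keep_offset = FALSE replaces O(j) by the unweighted intercept mean
  spec0 <- model_spec(form = "interaction", predictors = "sucs",
                      keep_offset = FALSE)
  ystar0 <- correct_marker(fit, spec0)
  expect_equal(ystar0, mean(fit$intercepts) + fit$residuals,
               tolerance = 1e-12)
  expect_equal(as.vector(tapply(ystar0, samples, mean)),
               rep(mean(fit$intercepts), 2), tolerance = 1e-10)

  # perfectly linear data collapse to the intercept
  ylin <- 1 + 2 * X[, 1]
  slin <- model_spec(form = "simple", predictors = "sucs")
  flin <- fit_marker(ylin, X, samples, slin)
  expect_equal(correct_marker(flin, slin), rep(1, n), tolerance = 1e-8)

  # uncorrelated-by-construction predictor: y* == y
  xo <- matrix(residuals(lm(rnorm(n) ~ y)), n, 1)  # orthogonal to y
  fo <- fit_marker(y, xo, rep("s", n), slin)
  expect_equal(correct_marker(fo, slin), y, tolerance = 1e-8)
})

test_that("run_rucova corrects configured markers and passes others through", {
  tab <- asinh_transform(make_confounded_table())
  panel <- demo_panel()
  spec <- model_spec(form = "interaction", predictors = "pcs")
  res <- run_rucova(tab, panel, spec)

  expect_s3_class(res, "corrected_table")
  expect_named(res$fit_register, c("m1", "m2", "m3"))
  # non-corrected channels bitwise unchanged (incl. surrogate sources)
  passthrough <- setdiff(tab$channel_names, panel$markers_to_correct)
  expect_identical(res$table$values[, passthrough],
                   tab$values[, passthrough])
  # the confounded markers lose most of their variance to the fit
  expect_gt(res$fit_register$m1$r_squared, 0.5)
  # m3 had no latent dependence; little variance removed
  expect_lt(res$fit_register$m3$r_squared, 0.2)

  # residual orthogonality within each least-squares stratum
  X <- res$pca$scores
  for (m in panel$markers_to_correct)
    for (s in unique(tab$sample_labels)) {
      idx <- tab$sample_labels == s
      expect_lt(max(abs(cor(res$table$values[idx, m], X[idx, ]))), 1e-8)
    }

  # idempotence: a second pass finds nothing left to remove
  res2 <- run_rucova(res$table, panel, spec)
  for (m in panel$markers_to_correct)
    expect_lt(max(abs(res2$fit_register[[m]]$slopes)), 1e-8)
  expect_equal(res2$table$values, res$table$values, tolerance = 1e-8)
})

test_that("run_rucova guards preconditions", {
  tab <- make_confounded_table()
  panel <- demo_panel()
  expect_error(run_rucova(tab, panel), "asinh")
  atab <- asinh_transform(tab)
  p_missing <- demo_panel(markers = c("m1", "nope"))
  expect_error(run_rucova(atab, p_missing), "nope")
  expect_error(run_rucova(atab, panel,
                          model_spec(predictors = "pcs", n_pcs = 9)),
               "n_pcs")
  expect_error(model_spec(n_pcs = 0), "n_pcs")
})

test_that("fit register exports tidily", {
  tab <- asinh_transform(make_confounded_table(n_per_sample = 60))
  res <- run_rucova(tab, demo_panel(),
                    model_spec(form = "offset", predictors = "sucs"))
  reg <- fit_register_table(res)
  expect_identical(names(reg), c("marker", "sample", "term", "estimate"))
  # 3 markers x 3 samples x (intercept + 4 SUCs)
  expect_identical(nrow(reg), 3L * 3L * 5L)
  expect_true(all(is.finite(reg$estimate)))
})
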