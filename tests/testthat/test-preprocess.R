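test_that("asinh_transform matches the closed-form oracle and guards state", {
  tab <- make_raw_table(n = 20, seed = 11)
  out <- asinh_transform(tab, cofactor = 5)
  expect_identical(out$transform_state, "asinh")
  # closed form: asinh(x) = log(x + sqrt(x^2 + 1))
  x <- tab$values / 5
  expect_equal(out$values, log(x + sqrt(x^2 + 1)),
               ignore_attr = FALSE, tolerance = 1e-12)
  expect_equal(asinh_transform(tab, 7)$values[tab$values == 0],
               rep(0, sum(tab$values == 0)))
  expect_error(asinh_transform(out), "raw")
  expect_error(asinh_transform(tab, cofactor = -1), "positive")
})

test_that("zscore normalizes globally and per sample (n-1 denominator)", {
  tab <- asinh_transform(make_raw_table(n = 60, seed = 12))
  z <- zscore(tab)
  expect_identical(z$transform_state, "asinh_zscored")
  expect_lt(max(abs(colMeans(z$values))), 1e-12)
  expect_equal(unname(apply(z$values, 2, sd)),
               rep(1, ncol(z$values)), tolerance = 1e-12)

  # (1,2,3) -> (-1,0,1) with sd denominator n-1
  one <- event_table(matrix(c(1, 2, 3), 3, 1, dimnames = list(NULL, "a")),
                     sample_labels = "s", transform_state = "asinh")
  expect_equal(as.vector(zscore(one)$values), c(-1, 0, 1))

  # per-sample z-scores are shift-invariant: two constant-shifted copies
  base <- matrix(rnorm(30), 10, 3, dimnames = list(NULL, c("a", "b", "c")))
  shifted <- event_table(rbind(base, base + 5),
                         sample_labels = rep(c("s1", "s2"), each = 10),
                         transform_state = "asinh")
  zz <- zscore(shifted, per_sample = TRUE)
  expect_equal(zz$values[1:10, ], zz$values[11:20, ], tolerance = 1e-12)

  # degenerate channel named in the error
  cc <- event_table(cbind(a = rnorm(10), flat = rep(1, 10)),
                    sample_labels = "s", transform_state = "asinh")
  expect_error(zscore(cc), "flat")
})

test_that("minmax maps to [0,1] and agrees with the affine oracle", {
  expect_equal(minmax(c(2, 4, 6)), c(0, 0.5, 1))
  set.seed(13)
  v <- rnorm(100)
  out <- minmax(v)
  expect_equal(range(out), c(0, 1))
  expect_equal(out, (v - min(v)) / diff(range(v)), tolerance = 1e-12)
  expect_error(minmax(rep(3, 5)), "constant")
})

test_that("compute_mean_dna standardizes each iridium channel first", {
  tab <- asinh_transform(make_raw_table(n = 50, seed = 14))
  panel <- demo_panel()
  got <- compute_mean_dna(tab, panel)
  # oracle: independent per-channel z-score then average
  z1 <- as.vector(scale(tab$values[, "Ir191"]))
  z2 <- as.vector(scale(tab$values[, "Ir193"]))
  expect_equal(got, (z1 + z2) / 2, tolerance = 1e-12)

  # identical channels: mean equals either standardized channel
  dup <- tab
  dup$values[, "Ir193"] <- dup$values[, "Ir191"]
  expect_equal(compute_mean_dna(dup, panel), z1, tolerance = 1e-12)

  p1 <- demo_panel(); p1$dna_channels <- "Ir191"
  expect_equal(compute_mean_dna(tab, p1), z1, tolerance = 1e-12)

  p_missing <- demo_panel(); p_missing$dna_channels <- c("Ir191", "Ir999")
  expect_error(compute_mean_dna(tab, p_missing), "Ir999")
  expect_error(compute_mean_dna(make_raw_table(), panel), "asinh")
})

test_that("compute_mean_bc takes the top-k barcode mean per cell", {
  tab <- asinh_transform(make_raw_table(n = 30, seed = 15))
  panel <- demo_panel()  # 3 barcode channels, n_top = 2
  got <- compute_mean_bc(tab, panel)
  bc <- tab$values[, c("Pd104", "Pd105", "Pd106")]
  oracle <- apply(bc, 1, function(v) mean(sort(v, decreasing = TRUE)[1:2]))
  expect_equal(got, oracle, tolerance = 1e-12)

  # hand case: (1, 5, 3), top 2 -> 4
  hand <- tab; hand$values[1, c("Pd104", "Pd105", "Pd106")] <- c(1, 5, 3)
  expect_equal(compute_mean_bc(hand, panel)[1], 4)

  # n_top = all channels -> plain row mean
  pall <- demo_panel(); pall$n_top_barcodes <- 3L
  expect_equal(compute_mean_bc(tab, pall), rowMeans(bc), tolerance = 1e-12)

  # permutation invariance over barcode channel order
  pperm <- demo_panel(); pperm$barcode_channels <- c("Pd106", "Pd104", "Pd105")
  expect_equal(compute_mean_bc(tab, pperm), got, tolerance = 1e-12)
})

test_that("assemble_sucs builds the roster in panel order with centering", {
  tab <- asinh_transform(make_raw_table(n = 80, seed = 16))
  panel <- demo_panel()
  s_none <- assemble_sucs(tab, panel, centering = "none")
  expect_identical(colnames(s_none),
                   c("mean_DNA", "mean_BC", "panAkt", "totalERK"))

  s_glob <- assemble_sucs(tab, panel, centering = "global")
  expect_lt(max(abs(colMeans(s_glob))), 1e-9)
  # two-path equivalence: manual grand-mean subtraction == global centering
  expect_equal(unclass(s_glob), sweep(unclass(s_none), 2, colMeans(s_none)),
               ignore_attr = TRUE, tolerance = 1e-12)
  # centering preserves column variances
  expect_equal(apply(s_glob, 2, var), apply(s_none, 2, var),
               tolerance = 1e-12)

  s_per <- assemble_sucs(tab, panel, centering = "per_sample")
  for (s in unique(tab$sample_labels))
    expect_lt(max(abs(colMeans(s_per[tab$sample_labels == s, ]))), 1e-9)

  p_empty <- demo_panel()
  p_empty$dna_channels <- character()
  p_empty$barcode_channels <- character()
  p_empty$antibody_suc_markers <- character()
  expect_error(assemble_sucs(tab, p_empty, "none"), "empty SUC roster")
})

test_that("pca_sucs matches an eigendecomposition oracle", {
  set.seed(17)
  tab <- asinh_transform(make_confounded_table(n_per_sample = 100))
  sucs <- assemble_sucs(tab, demo_panel(), centering = "global")
  res <- pca_sucs(sucs)

  # oracle: eigen of the correlation matrix of the raw SUC columns
  z <- scale(unclass(sucs))
  eig <- eigen(cov(z), symmetric = TRUE)
  expect_equal(res$var_explained, 100 * eig$values / sum(eig$values),
               tolerance = 1e-8)
  expect_equal(abs(res$loadings), abs(eig$vectors), ignore_attr = TRUE,
               tolerance = 1e-8)

  # contract invariants
  expect_equal(crossprod(res$loadings), diag(4), ignore_attr = TRUE,
               tolerance = 1e-8)
  expect_equal(sum(res$var_explained), 100, tolerance = 1e-6)
  expect_true(all(diff(res$var_explained) <= 1e-9))
  # reconstruction: scores %*% t(loadings) gives back the z-scored input
  expect_equal(res$scores %*% t(res$loadings),
               z - rep(colMeans(z), each = nrow(z)),
               ignore_attr = TRUE, tolerance = 1e-8)
  # sign convention: largest-magnitude entry of each loading positive
  for (k in 1:4)
    expect_gt(res$loadings[which.max(abs(res$loadings[, k])), k], 0)
})

test_that("pca_sucs flags rank deficiency and degenerate inputs", {
  set.seed(18)
  x <- rnorm(100)
  m <- cbind(a = x, b = 2 * x + 3)  # perfectly correlated pair
  expect_warning(res <- pca_sucs(m), "rank-deficient")
  expect_equal(res$var_explained, c(100, 0), tolerance = 1e-8)
  expect_error(pca_sucs(matrix(x, ncol = 1)), "at least 2")
})
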