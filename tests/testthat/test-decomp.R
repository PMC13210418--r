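test_that("log-normalized features follow the defining examples", {
  mk <- function(counts) pcdrad:::new_binned_counts(
    array(counts, c(2, 2, 2)), 1, 7.5, c(20, 60), is_noisy = TRUE)
  n0 <- c(1000, 1000)
  f <- to_features(mk(1000), n0)
  expect_true(all(f$f == 0))                       # n = n0 -> f = 0
  f <- to_features(mk(1000 * exp(-2)), n0)
  expect_equal(as.numeric(f$f), rep(2, 8), tolerance = 1e-12)
  f <- to_features(mk(0), n0)                      # clamp at 0.5 counts
  expect_equal(f$f[1, 1, 1], -log(0.5 / 1000), tolerance = 1e-12)
  expect_equal(f$f[1, 1, 1], 7.601, tolerance = 1e-3)
  expect_error(to_features(mk(10), c(1000, 0)), "positive")
  expect_error(to_features(mk(10), c(1000, 10, 10)), "length")
})

test_that("calibration grid is a uniform lattice with zero-feature origin", {
  g <- make_calibration_grid(3, sp_h, drf_h, thr4_h, al_range = c(0, 10),
                             pmma_range = c(0, 120),
                             mu_al = mu_al_h, mu_pmma = mu_pmma_h)
  expect_equal(sort(unique(g$thickness[, 1])), c(0, 5, 10))
  expect_equal(sort(unique(g$thickness[, 2])), c(0, 60, 120))
  expect_equal(as.numeric(g$features[1, ]), rep(0, 4))  # (0, 0) node
  # features strictly increase along each material axis, in every bin
  for (k in 1:4) {
    al_axis <- g$features[g$thickness[, 2] == 0, k]
    pm_axis <- g$features[g$thickness[, 1] == 0, k]
    expect_true(all(diff(al_axis) > 0))
    expect_true(all(diff(pm_axis) > 0))
  }
  expect_error(make_calibration_grid(1, sp_h, drf_h, thr4_h))
  expect_error(make_calibration_grid(3, sp_h, drf_h, thr4_h,
                                     al_range = c(5, 5)), "non-empty")
})

test_that("poly2 interpolates exact degree-2 data and matches normal equations", {
  set.seed(42)
  X <- matrix(runif(64 * 3), 64, 3)
  D <- pcdrad:::poly_design(X, 2)
  beta <- cbind(rnorm(ncol(D)), rnorm(ncol(D)))
  Y <- D %*% beta
  g <- fake_grid(X, Y)
  fit <- decomp_fit(g, "poly2")
  expect_lt(max(abs(predict(fit, X) - Y)) / max(abs(Y)), 1e-8)
  # independent normal-equations oracle on a well-conditioned problem
  ne <- solve(crossprod(D), crossprod(D, Y))
  expect_equal(unname(fit$coefs), unname(ne), tolerance = 1e-6)
})

test_that("poly2 rejects under-determined designs", {
  # 6 thresholds -> 28 quadratic terms, but a 3x3 grid has only 9 nodes
  g6 <- make_calibration_grid(3, sp_h, drf_h, default_thresholds(6),
                              mu_al = mu_al_h, mu_pmma = mu_pmma_h)
  expect_error(decomp_fit(g6, "poly2"), "under-determined")
  expect_error(decomp_fit(grid8_h, "poly2", degree = 5), "degree")
})

test_that("near-singular over-determined polynomial designs fall back to min-norm LS", {
  g6 <- make_calibration_grid(8, sp_h, drf_h, default_thresholds(6),
                              mu_al = mu_al_h, mu_pmma = mu_pmma_h)
  expect_warning(fit <- decomp_fit(g6, "poly2"), "rank-deficient")
  res <- predict(fit, g6$features) - g6$thickness
  expect_lt(sqrt(mean(res^2)), 0.5)  # still a sensible fit on the nodes
})

test_that("MLP has the stated capacity, determinism, and parameter counts", {
  # exact linear map is recovered well within 1% of the target range
  set.seed(1)
  X <- as.matrix(expand.grid(seq(0, 1, length = 8), seq(0, 1, length = 8)))
  Y <- cbind(2 * X[, 1] + 0.5 * X[, 2], 10 * X[, 2] - X[, 1])
  g <- fake_grid(X, Y)
  fit <- decomp_fit(g, "mlp", width = 64, epochs = 8000, seed = 3)
  Xv <- as.matrix(expand.grid(seq(0.05, 0.95, length = 7),
                              seq(0.05, 0.95, length = 7)))
  Yv <- cbind(2 * Xv[, 1] + 0.5 * Xv[, 2], 10 * Xv[, 2] - Xv[, 1])
  rmse <- sqrt(colMeans((predict(fit, Xv) - Yv)^2))
  expect_lt(rmse[1], 0.01 * diff(range(Y[, 1])))
  expect_lt(rmse[2], 0.01 * diff(range(Y[, 2])))
  # identical seed and config -> identical predictions
  fit2 <- decomp_fit(g, "mlp", width = 64, epochs = 8000, seed = 3)
  expect_identical(predict(fit, Xv), predict(fit2, Xv))
  # closed-form trainable-parameter counts
  expect_equal(mlp_param_count(4, 128, 2), 17410)
  expect_equal(mlp_param_count(4, 256, 2), 67586)
  expect_equal(mlp_param_count(4, 256, 2) / mlp_param_count(4, 128, 2),
               3.88, tolerance = 0.01)
})

test_that("SVR prediction equals the explicit dual-form expansion", {
  fit <- decomp_fit(grid8_h, "svr")
  X <- grid8_h$features[c(3, 17, 40), ]
  pred <- predict(fit, X)
  # independent oracle: evaluate sum_i (alpha_i - alpha_i*) K(x_i, x) + b
  Xs <- scale(X, fit$x_center, fit$x_scale)
  for (m in 1:2) {
    sv <- fit$svms[[m]]
    manual <- sapply(seq_len(nrow(Xs)), function(i) {
      k <- exp(-fit$hyper$gamma *
                 colSums((t(sv$SV) - as.numeric(Xs[i, ]))^2))
      sum(sv$coefs * k) - sv$rho
    })
    mm <- manual * (fit$y_max[m] - fit$y_min[m]) + fit$y_min[m]
    expect_equal(as.numeric(pred[, m]), mm, tolerance = 1e-10)
  }
})

test_that("SVR training error shrinks with calibration density", {
  g3 <- make_calibration_grid(3, sp_h, drf_h, thr4_h,
                              mu_al = mu_al_h, mu_pmma = mu_pmma_h)
  f3 <- decomp_fit(g3, "svr")
  f8 <- decomp_fit(grid8_h, "svr")
  rmse <- function(fit, g) sqrt(mean((predict(fit, g$features) -
                                        g$thickness)^2))
  expect_lte(rmse(f8, grid8_h), rmse(f3, g3))
  # epsilon-insensitive fit: training residuals near the epsilon tube
  # (scaled-target units) for a smooth toy problem
  set.seed(2)
  X <- matrix(seq(0, 1, length = 40), 40, 2)
  X[, 2] <- X[, 2]^2
  Y <- cbind(X[, 1] * 3, 1 + X[, 2])
  fit <- decomp_fit(fake_grid(X, Y), "svr")
  sc <- abs(predict(fit, X) - Y) / rep(fit$y_max - fit$y_min, each = 40)
  expect_lt(max(sc), 0.05)
})

test_that("decomposition is pixelwise and shape-preserving", {
  fit <- decomp_fit(grid8_h, "poly2")
  f <- slab_features(4.1, 83)
  fi <- structure(list(f = array(rep(f, each = 12), c(3, 4, 4)), pitch = 1,
                       thresholds = thr4_h, exposure_mas = 7.5),
                  class = "feature_image")
  maps <- decompose(fit, fi)
  expect_s3_class(maps, "thickness_maps")
  expect_equal(dim(maps$al), c(3, 4))
  expect_equal(diff(range(maps$al)), 0)  # constant in -> constant out
  # permuting pixels permutes predictions identically (no spatial context)
  X <- grid8_h$features[1:10, ]
  p <- sample(10)
  expect_identical(predict(fit, X)[p, ], predict(fit, X[p, ]))
  expect_error(predict(fit, X[, 1:3]), "dimension")
})

test_that("all three models invert noise-free calibration-range features", {
  fits <- list(poly2 = decomp_fit(grid8_h, "poly2"),
               svr = decomp_fit(grid8_h, "svr"))
  f_mid <- slab_features(5.2, 70)
  for (fit in fits) {
    p <- predict(fit, f_mid)
    expect_equal(p[1], 5.2, tolerance = 0.5)
    expect_equal(p[2], 70, tolerance = 5)
  }
})
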