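#' Fit a material-decomposition model
#'
#' Fits the mapping from log-normalized spectral features to basis-material
#' thicknesses (Al, PMMA) on a noise-free calibration grid. Three model
#' classes are supported:
#'
#' * `"poly2"` -- full second-degree polynomial (intercept, linear, square
#'   and cross terms) fit per material by ordinary least squares; a
#'   third-degree basis is available via `degree = 3` but is off by default.
#'   Under-determined designs (fewer grid nodes than polynomial terms) and
#'   rank deficiency raise an error rather than being silently regularized.
#' * `"mlp"` -- fully-connected network (default two hidden layers of 128
#'   ReLU units, linear output), dropout 0.01 and L2 weight decay, trained
#'   full-batch with Adam on a smooth-L1 loss. Inputs are standardized and
#'   targets min-max scaled to `[0, 1]` per material; training is
#'   deterministic given `seed`.
#' * `"svr"` -- one epsilon-insensitive RBF support vector regression per
#'   material (`C = 100`, `epsilon = 0.010`, `gamma = "scale"`) on
#'   standardized features and `[0, 1]`-scaled targets.
#'
#' @param grid a [make_calibration_grid()] object.
#' @param method `"poly2"`, `"mlp"` or `"svr"`.
#' @param degree polynomial degree (2 or 3), `"poly2"` only.
#' @param width,layers hidden width and depth, `"mlp"` only.
#' @param dropout,l2,lr,epochs,seed MLP training hyperparameters.
#' @param cost,epsilon,gamma SVR hyperparameters (`gamma = "scale"` maps to
#'   `1 / (Nb * var(features))` on the standardized features).
#' @return an object of classes `decomp_<method>` and `decomp_model`, with
#'   [predict()][predict.decomp_model], [coef()], [print()], [summary()]
#'   and [residuals()] methods.
#' @export
decomp_fit <- function(grid, method = c("poly2", "mlp", "svr"),
                       degree = 2,
                       width = 128, layers = 2, dropout = 0.01, l2 = 1e-4,
                       lr = 1e-3, epochs = 10000, seed = 1,
                       cost = 100, epsilon = 0.010, gamma = "scale") {
  stopifnot(inherits(grid, "calibration_grid"))
  method <- match.arg(method)
  X <- grid$features
  Y <- grid$thickness
  obj <- switch(method,
    poly2 = fit_poly_core(X, Y, degree),
    mlp = fit_mlp_core(X, Y, width = width, layers = layers,
                       dropout = dropout, l2 = l2, lr = lr,
                       epochs = epochs, seed = seed),
    svr = fit_svr_core(X, Y, cost = cost, epsilon = epsilon, gamma = gamma))
  obj$method <- method
  obj$n_features <- ncol(X)
  obj$grid_G <- grid$G
  obj$ranges <- list(al = grid$al_range, pmma = grid$pmma_range)
  obj$thresholds <- grid$thresholds
  class(obj) <- c(paste0("decomp_", method), "decomp_model")
  obj$train_pred <- predict(obj, X)
  obj
}

#' @rdname decomp_fit
#' @param ... passed on to [decomp_fit()].
#' @export
fit_poly2 <- function(grid, ...) decomp_fit(grid, "poly2", ...)

#' @rdname decomp_fit
#' @export
fit_mlp <- function(grid, ...) decomp_fit(grid, "mlp", ...)

#' @rdname decomp_fit
#' @export
fit_svr <- function(grid, ...) decomp_fit(grid, "svr", ...)

# polynomial design matrix: intercept, linear, and all monomials of total
# degree up to `degree`
poly_design <- function(X, degree) {
  n_b <- ncol(X)
  cols <- list(`(Intercept)` = rep(1, nrow(X)))
  for (i in seq_len(n_b)) cols[[paste0("f", i)]] <- X[, i]
  for (i in seq_len(n_b)) for (j in i:n_b)
    cols[[paste0("f", i, ":f", j)]] <- X[, i] * X[, j]
  if (degree >= 3) {
    for (i in seq_len(n_b)) for (j in i:n_b) for (k in j:n_b)
      cols[[paste0("f", i, ":f", j, ":f", k)]] <- X[, i] * X[, j] * X[, k]
  }
  do.call(cbind, cols)
}

fit_poly_core <- function(X, Y, degree) {
  if (!(degree %in% c(2, 3))) stop("polynomial degree must be 2 or 3")
  D <- poly_design(X, degree)
  if (nrow(D) < ncol(D))
    stop(sprintf(
      "under-determined polynomial fit: %d terms but only %d calibration nodes",
      ncol(D), nrow(D)))
  # spectral features are strongly correlated across bins (they live near a
  # two-dimensional manifold), so the monomial design is severely
  # ill-conditioned; column equilibration plus SVD-truncated minimum-norm
  # least squares keeps the fit well-defined at any threshold count, with a
  # diagnostic when directions are dropped
  cs <- apply(abs(D), 2, max)
  sv <- svd(sweep(D, 2, cs, `/`))
  keep <- sv$d > 1e-10 * sv$d[1]
  if (!all(keep))
    warning(sprintf(
      "polynomial design numerically rank-deficient (rank %d of %d terms); using minimum-norm least squares",
      sum(keep), ncol(D)))
  coefs <- (sv$v[, keep, drop = FALSE] %*%
              (crossprod(sv$u[, keep, drop = FALSE], Y) / sv$d[keep])) / cs
  rownames(coefs) <- colnames(D)
  list(coefs = coefs, degree = degree, rank = sum(keep))
}

fit_mlp_core <- function(X, Y, width, layers, dropout, l2, lr, epochs, seed) {
  x_center <- colMeans(X)
  x_scale <- apply(X, 2, stats::sd)
  if (any(x_scale == 0)) stop("degenerate calibration grid: constant feature")
  Xs <- scale(X, x_center, x_scale)
  y_min <- apply(Y, 2, min); y_max <- apply(Y, 2, max)
  Ys <- scale(Y, y_min, y_max - y_min)
  fit <- mlp_train(Xs, Ys, widths = rep(width, layers), dropout = dropout,
                   l2 = l2, lr = lr, epochs = epochs, seed = seed)
  list(net = fit$net, loss_trace = fit$loss_trace,
       x_center = x_center, x_scale = x_scale,
       y_min = y_min, y_max = y_max,
       hyper = list(width = width, layers = layers, dropout = dropout,
                    l2 = l2, lr = lr, epochs = epochs, seed = seed),
       n_params = mlp_param_count(ncol(X), width, layers, ncol(Y)))
}

fit_svr_core <- function(X, Y, cost, epsilon, gamma) {
  x_center <- colMeans(X)
  x_scale <- apply(X, 2, stats::sd)
  if (any(x_scale == 0)) stop("degenerate calibration grid: constant feature")
  Xs <- scale(X, x_center, x_scale)
  y_min <- apply(Y, 2, min); y_max <- apply(Y, 2, max)
  if (is.character(gamma) && gamma == "scale")
    gamma <- 1 / (ncol(Xs) * stats::var(as.numeric(Xs)))
  fits <- lapply(1:2, function(m) {
    ys <- (Y[, m] - y_min[m]) / (y_max[m] - y_min[m])
    e1071::svm(x = Xs, y = ys, type = "eps-regression", kernel = "radial",
               cost = cost, epsilon = epsilon, gamma = gamma, scale = FALSE)
  })
  list(svms = fits, x_center = x_center, x_scale = x_scale,
       y_min = y_min, y_max = y_max,
       hyper = list(cost = cost, epsilon = epsilon, gamma = gamma))
}

#' Predict basis-material thicknesses
#'
#' Applies a fitted decomposition model per pixel. Negative predictions are
#' not clipped, so bias stays measurable with its sign.
#'
#' @param object a `decomp_model`.
#' @param newdata an `n x Nb` feature matrix or a `feature_image`.
#' @param ... unused.
#' @return for a matrix input, an `n x 2` matrix with columns `al`, `pmma`
#'   (mm); for a `feature_image`, a `thickness_maps` at the image pitch.
#' @export
predict.decomp_model <- function(object, newdata, ...) {
  is_image <- inherits(newdata, "feature_image")
  X <- if (is_image) as_feature_matrix(newdata) else as.matrix(newdata)
  if (ncol(X) != object$n_features)
    stop("feature dimension does not match the fitted model")
  out <- predict_core(object, X)
  colnames(out) <- c("al", "pmma")
  if (is_image) {
    d <- dim(newdata$f)
    new_thickness_maps_signed(matrix(out[, 1], d[1], d[2]),
                              matrix(out[, 2], d[1], d[2]), newdata$pitch)
  } else out
}

# thickness_maps constructor that tolerates negative estimates
new_thickness_maps_signed <- function(al, pmma, pitch) {
  structure(list(al = al, pmma = pmma, pitch = pitch),
            class = "thickness_maps")
}

predict_core <- function(object, X) UseMethod("predict_core")

#' @export
predict_core.decomp_poly2 <- function(object, X) {
  poly_design(X, object$degree) %*% object$coefs
}

#' @export
predict_core.decomp_mlp <- function(object, X) {
  Xs <- scale(X, object$x_center, object$x_scale)
  Ys <- mlp_predict(object$net, Xs)
  sweep(sweep(Ys, 2, object$y_max - object$y_min, `*`), 2, object$y_min, `+`)
}

#' @export
predict_core.decomp_svr <- function(object, X) {
  Xs <- scale(X, object$x_center, object$x_scale)
  Ys <- matrix(0, nrow(Xs), 2)
  for (m in 1:2)
    Ys[, m] <- as.numeric(stats::predict(object$svms[[m]], Xs))
  sweep(sweep(Ys, 2, object$y_max - object$y_min, `*`), 2, object$y_min, `+`)
}

#' Decompose a feature image into thickness maps
#'
#' @param model a fitted `decomp_model`.
#' @param features a `feature_image`.
#' @return a `thickness_maps` at the image (macro) pitch.
#' @export
decompose <- function(model, features) {
  stopifnot(inherits(model, "decomp_model"),
            inherits(features, "feature_image"))
  predict(model, features)
}

#' @export
print.decomp_model <- function(x, ...) {
  cat(sprintf("<decomp_model> method = %s, %d features, trained on %dx%d grid\n",
              x$method, x$n_features, x$grid_G, x$grid_G))
  cat(sprintf("  ranges: Al [%g, %g] mm, PMMA [%g, %g] mm\n",
              x$ranges$al[1], x$ranges$al[2], x$ranges$pmma[1],
              x$ranges$pmma[2]))
  invisible(x)
}

#' @export
coef.decomp_poly2 <- function(object, ...) object$coefs

#' @export
summary.decomp_model <- function(object, ...) {
  cat(sprintf("Material decomposition model (%s)\n", object$method))
  print(object)
  if (!is.null(object$train_pred)) {
    cat("  (training predictions cached; see residuals())\n")
  }
  invisible(object)
}

#' Training residuals of a decomposition fit
#'
#' Residuals (prediction minus truth, mm) on the calibration nodes the
#' model was trained on.
#'
#' @param object a `decomp_model` fitted by [decomp_fit()].
#' @param grid the calibration grid it was trained on.
#' @param ... unused.
#' @return an `n x 2` matrix of residuals.
#' @export
residuals.decomp_model <- function(object, grid, ...) {
  stopifnot(inherits(grid, "calibration_grid"))
  predict(object, grid$features) - grid$thickness
}
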