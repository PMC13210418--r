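#' Log-normalized spectral features
#'
#' Converts a noisy macro-pixel count stack into the per-pixel feature
#' vector `f_k = -log(n_k / n_{k,0})`, where `n_{k,0}` are the matching
#' open-beam counts. Zero (or tiny) counts are clamped to `clamp` before
#' the log so features stay finite at ultra-low dose.
#'
#' @param noisy a `binned_counts` stack (macro pitch).
#' @param open_beam open-beam reference: either a numeric vector of
#'   per-macro-pixel expected counts per bin, or a `binned_counts` with
#'   matching shape. All open-beam counts must be positive.
#' @param clamp lower clamp applied to measured counts (default 0.5).
#' @return an object of class `feature_image`: field `f` is an
#'   ny x nx x Nb array.
#' @export
to_features <- function(noisy, open_beam, clamp = 0.5) {
  stopifnot(inherits(noisy, "binned_counts"))
  d <- dim(noisy$counts)
  if (inherits(open_beam, "binned_counts")) {
    if (!identical(dim(open_beam$counts), d))
      stop("open-beam stack shape does not match")
    n0 <- open_beam$counts
  } else {
    if (length(open_beam) != d[3])
      stop("open-beam vector length does not match the number of bins")
    n0 <- aperm(array(open_beam, c(d[3], d[1], d[2])), c(2, 3, 1))
  }
  if (any(n0 <= 0)) stop("open-beam counts must be positive in every bin")
  f <- -log(pmax(noisy$counts, clamp) / n0)
  structure(list(f = f, pitch = noisy$pitch, thresholds = noisy$thresholds,
                 exposure_mas = noisy$exposure_mas),
            class = "feature_image")
}

# flatten a feature image into an n_pixels x Nb matrix (column-major order)
as_feature_matrix <- function(fi) {
  stopifnot(inherits(fi, "feature_image"))
  d <- dim(fi$f)
  matrix(fi$f, d[1] * d[2], d[3])
}

# noise-free bin counts for a uniform slab (single representative pixel)
slab_bin_counts <- function(spectrum, drf, thresholds, x_al, x_pmma,
                            mu_al, mu_pmma) {
  B <- bin_response(drf, thresholds)
  I <- spectrum$fluence *
    exp(-mu_at(mu_al, spectrum$energies) * x_al -
          mu_at(mu_pmma, spectrum$energies) * x_pmma)
  as.numeric(crossprod(B, I))
}

#' Noise-free calibration grid
#'
#' Uniform G x G lattice (endpoints included) over the Al and PMMA
#' thickness ranges; for each node the log-normalized feature vector is
#' computed from noise-free expected counts of a uniform slab (a single
#' representative pixel; the unit-sum sharing kernel leaves uniform regions
#' unchanged, and the exposure cancels out of the features).
#'
#' @param G grid size per material axis (>= 2).
#' @param spectrum,drf,thresholds forward-model components.
#' @param al_range,pmma_range thickness ranges in mm, `c(min, max)`.
#' @param mu_al,mu_pmma optional pre-loaded attenuation tables.
#' @return an object of class `calibration_grid`: `thickness` (G^2 x 2,
#'   columns al/pmma, mm) and `features` (G^2 x Nb).
#' @export
make_calibration_grid <- function(G, spectrum, drf, thresholds,
                                  al_range = c(0, 10),
                                  pmma_range = c(0, 120),
                                  mu_al = load_attenuation("al"),
                                  mu_pmma = load_attenuation("pmma")) {
  stopifnot(G >= 2)
  if (diff(al_range) <= 0 || diff(pmma_range) <= 0)
    stop("thickness ranges must be non-empty")
  check_thresholds(thresholds, drf$detected_kev)
  al <- seq(al_range[1], al_range[2], length.out = G)
  pm <- seq(pmma_range[1], pmma_range[2], length.out = G)
  th <- as.matrix(expand.grid(al = al, pmma = pm))
  n0 <- slab_bin_counts(spectrum, drf, thresholds, 0, 0, mu_al, mu_pmma)
  feats <- t(vapply(seq_len(nrow(th)), function(i) {
    n <- slab_bin_counts(spectrum, drf, thresholds, th[i, 1], th[i, 2],
                         mu_al, mu_pmma)
    -log(n / n0)
  }, numeric(length(thresholds))))
  structure(list(thickness = th, features = feats, G = G,
                 al_range = al_range, pmma_range = pmma_range,
                 thresholds = thresholds),
            class = "calibration_grid")
}

#' Export a calibration grid as CSV
#' @param grid a `calibration_grid`.
#' @param path output file.
#' @export
export_calibration_grid <- function(grid, path) {
  df <- data.frame(x_al = grid$thickness[, 1], x_pmma = grid$thickness[, 2])
  f <- as.data.frame(grid$features)
  names(f) <- paste0("f_", seq_len(ncol(f)))
  utils::write.csv(cbind(df, f), path, row.names = FALSE)
  invisible(path)
}

#' Dense validation lattice over the calibration ranges
#'
#' `n x n` uniform lattice over the same ranges as `grid`, with any node
#' whose (Al, PMMA) pair coincides with a calibration training node removed.
#'
#' @param grid a `calibration_grid`.
#' @param spectrum,drf forward-model components (thresholds are taken from
#'   the grid).
#' @param n lattice size per axis.
#' @param mu_al,mu_pmma optional pre-loaded attenuation tables.
#' @return a `calibration_grid`-shaped object restricted to the
#'   non-training nodes.
#' @export
validation_lattice <- function(grid, spectrum, drf, n = 25,
                               mu_al = load_attenuation("al"),
                               mu_pmma = load_attenuation("pmma")) {
  val <- make_calibration_grid(n, spectrum, drf, grid$thresholds,
                               al_range = grid$al_range,
                               pmma_range = grid$pmma_range,
                               mu_al = mu_al, mu_pmma = mu_pmma)
  key <- function(m) paste(signif(m[, 1], 12), signif(m[, 2], 12))
  keep <- !(key(val$thickness) %in% key(grid$thickness))
  val$thickness <- val$thickness[keep, , drop = FALSE]
  val$features <- val$features[keep, , drop = FALSE]
  val
}

#' @export
print.feature_image <- function(x, ...) {
  d <- dim(x$f)
  cat(sprintf("<feature_image> %d x %d px at %.3g mm, %d features\n",
              d[1], d[2], x$pitch, d[3]))
  invisible(x)
}

#' @export
print.calibration_grid <- function(x, ...) {
  cat(sprintf("<calibration_grid> %d x %d nodes, Al [%g, %g] mm, PMMA [%g, %g] mm, %d features\n",
              x$G, x$G, x$al_range[1], x$al_range[2], x$pmma_range[1],
              x$pmma_range[2], ncol(x$features)))
  invisible(x)
}
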