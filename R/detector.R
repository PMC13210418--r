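#' CdTe photon-counting detector configuration
#'
#' Physical parameters of the parametric detector response model. The
#' deposited-energy distribution for a monoenergetic incident beam is
#' modelled as a photopeak plus a low-energy charge-sharing tail (fraction
#' set by the geometric probability that an isotropic Gaussian charge cloud,
#' centered uniformly in the pixel, loses charge across a pixel border),
#' optional Cd/Te fluorescence-escape lines, and Gaussian spectral
#' broadening from electronic noise and Fano statistics,
#' `sigma(E)^2 = sigma_el^2 + F * w * E` (keV^2).
#'
#' @param cdte_thickness_mm sensor thickness (mm).
#' @param pixel_pitch_mm native pixel pitch (mm).
#' @param charge_cloud_sigma_mm Gaussian charge-cloud standard deviation (mm).
#' @param electronic_noise_kev electronic noise sigma (keV).
#' @param fano_factor Fano factor (dimensionless).
#' @param pair_creation_kev electron-hole pair creation energy (keV).
#' @param escape_model_on include Cd/Te K-fluorescence escape lines.
#' @param escape_fraction_cd,escape_fraction_te escape-line weight above the
#'   respective K-edge.
#' @param rebin_factor micro- to macro-pixel summation factor.
#' @return a `detector_config` list; `incident_kev` is fixed at the
#'   15--174 keV 1 keV grid, `detected_kev` at 1--174 keV.
#' @export
detector_config <- function(cdte_thickness_mm = 1.0, pixel_pitch_mm = 0.1,
                            charge_cloud_sigma_mm = 0.025,
                            electronic_noise_kev = 2.0, fano_factor = 0.089,
                            pair_creation_kev = 4.43e-3,
                            escape_model_on = TRUE,
                            escape_fraction_cd = 0.05,
                            escape_fraction_te = 0.05,
                            rebin_factor = 10L) {
  stopifnot(cdte_thickness_mm > 0, pixel_pitch_mm > 0,
            charge_cloud_sigma_mm > 0, electronic_noise_kev > 0,
            fano_factor > 0, pair_creation_kev > 0,
            escape_fraction_cd >= 0, escape_fraction_te >= 0,
            rebin_factor >= 1)
  structure(
    list(cdte_thickness_mm = cdte_thickness_mm,
         pixel_pitch_mm = pixel_pitch_mm,
         charge_cloud_sigma_mm = charge_cloud_sigma_mm,
         electronic_noise_kev = electronic_noise_kev,
         fano_factor = fano_factor, pair_creation_kev = pair_creation_kev,
         escape_model_on = escape_model_on,
         escape_fraction_cd = escape_fraction_cd,
         escape_fraction_te = escape_fraction_te,
         rebin_factor = as.integer(rebin_factor),
         incident_kev = 15:174, detected_kev = 1:174),
    class = "detector_config")
}

# Cd/Te K-shell constants (keV)
K_EDGE_CD <- 26.711
K_EDGE_TE <- 31.814
K_ALPHA_CD <- 23.17
K_ALPHA_TE <- 27.47

# antiderivative of the standard normal CDF
.intPhi <- function(x) x * stats::pnorm(x) + stats::dnorm(x)

# mean over a cloud center uniform in [0, p] of Phi((c - u) / sigma)
.avgPhi <- function(c, p, sigma) {
  sigma / p * (.intPhi(c / sigma) - .intPhi((c - p) / sigma))
}

# 1D probability that the charge collected in the central pixel, for a cloud
# centered uniformly in it
.retained_1d <- function(sigma, p) .avgPhi(p, p, sigma) - .avgPhi(0, p, sigma)

#' Charge-sharing fraction
#'
#' Expected fraction of a 2D Gaussian charge cloud (sd `sigma`), centered
#' uniformly at random in a `pitch`-sized square pixel, that is collected
#' outside that pixel.
#'
#' @param config a [detector_config()].
#' @return scalar in (0, 1).
#' @export
sharing_fraction <- function(config) {
  1 - .retained_1d(config$charge_cloud_sigma_mm, config$pixel_pitch_mm)^2
}

#' 3x3 charge-sharing kernel
#'
#' Integrates an isotropic 2D Gaussian charge cloud (sd
#' `charge_cloud_sigma_mm`), centered uniformly over the central pixel, over
#' each pixel area of the 3x3 neighborhood, then normalizes to unit sum. The
#' kernel is separable and 4-fold symmetric; as sigma tends to 0 it tends to
#' the identity.
#'
#' @param config a [detector_config()].
#' @return 3x3 numeric matrix with non-negative entries summing to 1.
#' @export
sharing_kernel <- function(config) {
  sigma <- config$charge_cloud_sigma_mm
  p <- config$pixel_pitch_mm
  if (sigma <= 0) stop("charge_cloud_sigma_mm must be positive")
  # mass landing in 1D neighbor k (offset k * p) for k = -1, 0, 1
  w1 <- vapply(-1:1, function(k) {
    .avgPhi((k + 1) * p, p, sigma) - .avgPhi(k * p, p, sigma)
  }, numeric(1))
  k <- outer(w1, w1)
  k / sum(k)
}

#' Build the detector response function matrix
#'
#' Rows index incident energy (15--174 keV), columns detected energy
#' (1--174 keV). For incident energy E the row carries total mass
#' `1 - exp(-mu_CdTe(E) d)` (interaction probability), split into a
#' photopeak at E, a charge-sharing tail uniform over (0, E], and (when
#' `escape_model_on`) Cd/Te fluorescence escape lines at E minus the K-alpha
#' energies; the deposited spectrum is then convolved with a mass-conserving
#' Gaussian of energy-dependent width.
#'
#' @param config a [detector_config()].
#' @param mu_cdte optional pre-loaded CdTe attenuation table.
#' @return an object of class `drf_matrix` with fields `R`, `incident_kev`,
#'   `detected_kev`, `config`.
#' @export
build_drf <- function(config = detector_config(),
                      mu_cdte = load_attenuation("cdte")) {
  stopifnot(inherits(config, "detector_config"))
  inc <- config$incident_kev
  det <- config$detected_kev
  eff <- 1 - exp(-mu_at(mu_cdte, inc) * config$cdte_thickness_mm)
  s <- sharing_fraction(config)

  # energy-dependent Gaussian broadening, applied per deposited energy
  sig <- sqrt(config$electronic_noise_kev^2 +
                config$fano_factor * config$pair_creation_kev * det)
  G <- vapply(seq_along(det), function(j) {
    w <- stats::dnorm(det, mean = det[j], sd = sig[j])
    w / sum(w)
  }, numeric(length(det)))
  G <- t(G)  # G[source, out]

  R <- matrix(0, length(inc), length(det))
  for (i in seq_along(inc)) {
    E <- inc[i]
    dep <- numeric(length(det))
    peak <- 1 - s
    if (config$escape_model_on) {
      for (esc in list(c(K_EDGE_CD, K_ALPHA_CD, config$escape_fraction_cd),
                       c(K_EDGE_TE, K_ALPHA_TE, config$escape_fraction_te))) {
        if (E > esc[1] && esc[3] > 0) {
          e_line <- round(E - esc[2])
          if (e_line >= 1) {
            frac <- (1 - s) * esc[3]
            dep[e_line] <- dep[e_line] + frac
            peak <- peak - frac
          }
        }
      }
    }
    dep[E] <- dep[E] + peak
    tail_bins <- which(det <= E)
    dep[tail_bins] <- dep[tail_bins] + s / length(tail_bins)
    R[i, ] <- eff[i] * (dep %*% G)
  }
  structure(list(R = R, incident_kev = inc, detected_kev = det,
                 config = config),
            class = "drf_matrix")
}

#' Export a DRF matrix as CSV
#' @param drf a `drf_matrix`.
#' @param path output file.
#' @export
export_drf <- function(drf, path) {
  m <- drf$R
  dimnames(m) <- list(incident_keV = drf$incident_kev,
                      detected_keV = drf$detected_kev)
  utils::write.csv(m, path)
  invisible(path)
}

#' Default threshold placement
#'
#' `M` comparator thresholds equally spaced over the 20--100 keV span:
#' `T_k = 20 + (k - 1) * 80 / M` keV. Bin k covers `[T_k, T_{k+1})`; the
#' last bin is open above.
#'
#' @param M number of thresholds (2--6).
#' @return increasing numeric vector of length `M` (keV).
#' @export
default_thresholds <- function(M) {
  if (!(M %in% 2:6)) stop("number of thresholds must be in 2..6")
  20 + 80 * (seq_len(M) - 1) / M
}

check_thresholds <- function(thresholds, detected_kev) {
  stopifnot(length(thresholds) >= 2, length(thresholds) <= 6,
            all(diff(thresholds) > 0),
            min(thresholds) >= min(detected_kev),
            max(thresholds) <= max(detected_kev))
  invisible(thresholds)
}

# per-incident-energy expected response summed into threshold bins:
# B[i, k] = sum_j R[i, j] * 1(T_k <= E_j < T_{k+1})
bin_response <- function(drf, thresholds) {
  check_thresholds(thresholds, drf$detected_kev)
  M <- length(thresholds)
  edges <- c(thresholds, Inf)
  B <- vapply(seq_len(M), function(k) {
    sel <- drf$detected_kev >= edges[k] & drf$detected_kev < edges[k + 1]
    rowSums(drf$R[, sel, drop = FALSE])
  }, numeric(length(drf$incident_kev)))
  B
}

new_binned_counts <- function(counts, pitch, exposure_mas, thresholds,
                              is_noisy = FALSE, seed = NA_integer_) {
  structure(list(counts = counts, pitch = pitch, exposure_mas = exposure_mas,
                 thresholds = thresholds, is_noisy = is_noisy, seed = seed),
            class = "binned_counts")
}

#' Expected (noise-free) energy-bin counts
#'
#' Forward-projects thickness maps through the Beer--Lambert model and the
#' detector response: for each micro-pixel the transmitted spectrum is
#' multiplied into the DRF and summed into threshold bins. The per-bin
#' expectation is computed once per unique (Al, PMMA) thickness pair and
#' broadcast to all pixels sharing it.
#'
#' @param maps a `thickness_maps` at the native (micro) pitch.
#' @param spectrum an [load_spectrum()] object on the DRF incident grid;
#'   fluence is per native (micro) pixel.
#' @param drf a [build_drf()] matrix.
#' @param thresholds increasing threshold energies in keV.
#' @param exposure_mas exposure in mAs.
#' @param mu_al,mu_pmma optional pre-loaded attenuation tables.
#' @return a `binned_counts` object: `counts` is an ny x nx x M array of
#'   expected counts per micro-pixel.
#' @export
expected_bin_counts <- function(maps, spectrum, drf, thresholds, exposure_mas,
                                mu_al = load_attenuation("al"),
                                mu_pmma = load_attenuation("pmma")) {
  stopifnot(inherits(maps, "thickness_maps"), inherits(drf, "drf_matrix"))
  if (!identical(as.numeric(spectrum$energies),
                 as.numeric(drf$incident_kev)))
    stop("spectrum and DRF energy grids do not match")
  B <- bin_response(drf, thresholds)
  fl_micro <- spectrum$fluence * (exposure_mas / spectrum$reference_mas)
  att_al <- mu_at(mu_al, spectrum$energies)
  att_pm <- mu_at(mu_pmma, spectrum$energies)
  key <- paste(maps$al, maps$pmma, sep = "/")
  uk <- which(!duplicated(key))
  per_pair <- vapply(uk, function(idx) {
    I <- fl_micro * exp(-att_al * maps$al[idx] - att_pm * maps$pmma[idx])
    as.numeric(crossprod(B, I))
  }, numeric(ncol(B)))  # M x n_unique
  idx <- match(key, key[uk])
  n <- dim(maps$al)
  counts <- array(t(per_pair)[idx, ], dim = c(n[1], n[2], ncol(B)))
  new_binned_counts(counts, maps$pitch, exposure_mas, thresholds)
}

#' Open-beam expected counts per energy bin
#'
#' Noise-free expected counts with no object in the beam, the reference
#' `n_{k,0}` used by [to_features()].
#'
#' @param spectrum,drf,thresholds forward-model components.
#' @param exposure_mas exposure in mAs.
#' @param macro if `TRUE` (default), counts per macro-pixel; otherwise per
#'   native pixel.
#' @return numeric vector of length `length(thresholds)`.
#' @export
open_beam_counts <- function(spectrum, drf, thresholds, exposure_mas,
                             macro = TRUE) {
  B <- bin_response(drf, thresholds)
  fl_micro <- spectrum$fluence * (exposure_mas / spectrum$reference_mas)
  n <- as.numeric(crossprod(B, fl_micro))
  if (macro) n * drf$config$rebin_factor^2 else n
}

# 3x3 convolution with symmetric (reflect) boundary padding
conv3x3_reflect <- function(m, k) {
  n1 <- nrow(m); n2 <- ncol(m)
  ri <- c(1, seq_len(n1), n1)
  ci <- c(1, seq_len(n2), n2)
  p <- m[ri, ci]
  out <- matrix(0, n1, n2)
  for (dr in -1:1) for (dc in -1:1) {
    out <- out + k[dr + 2, dc + 2] *
      p[seq_len(n1) + 1 + dr, seq_len(n2) + 1 + dc]
  }
  out
}

#' Apply the spatial charge-sharing convolution
#'
#' Convolves each energy-bin image of a noise-free count stack with the 3x3
#' sharing kernel (reflect padding). Charge sharing acts on the mean
#' response, so noisy stacks are rejected.
#'
#' @param image a noise-free `binned_counts` at native pitch.
#' @param kernel a [sharing_kernel()] matrix.
#' @return the convolved `binned_counts`.
#' @export
apply_sharing <- function(image, kernel) {
  stopifnot(inherits(image, "binned_counts"))
  if (image$is_noisy)
    stop("charge sharing applies to expected (noise-free) counts only")
  stopifnot(all(dim(kernel) == c(3, 3)),
            abs(sum(kernel) - 1) < 1e-12)
  for (k in seq_len(dim(image$counts)[3]))
    image$counts[, , k] <- conv3x3_reflect(image$counts[, , k], kernel)
  image
}

#' Poisson-sample a count stack
#'
#' Independent Poisson draws per pixel and energy bin with mean equal to
#' the expected counts. Deterministic given `seed`; the caller's RNG state
#' is left untouched.
#'
#' @param image a noise-free `binned_counts`.
#' @param seed integer seed.
#' @return an integer-valued noisy `binned_counts`.
#' @export
sample_poisson <- function(image, seed) {
  stopifnot(inherits(image, "binned_counts"))
  if (any(image$counts < 0)) stop("negative means")
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  image$counts <- array(stats::rpois(length(image$counts), image$counts),
                        dim = dim(image$counts))
  image$is_noisy <- TRUE
  image$seed <- as.integer(seed)
  image
}

block_sum <- function(m, f) {
  g1 <- rep(seq_len(nrow(m) / f), each = f)
  g2 <- rep(seq_len(ncol(m) / f), each = f)
  t(rowsum(t(rowsum(m, g1)), g2))
}

#' Rebin a count stack to macro-pixels
#'
#' Non-overlapping `factor` x `factor` block summation; total counts are
#' conserved exactly and Poisson statistics are preserved (sums of
#' independent Poissons).
#'
#' @param image a `binned_counts`.
#' @param factor block size; image dimensions must be divisible by it.
#' @return the rebinned `binned_counts` with pitch multiplied by `factor`.
#' @export
rebin_counts <- function(image, factor = 10L) {
  stopifnot(inherits(image, "binned_counts"))
  d <- dim(image$counts)
  if (d[1] %% factor != 0 || d[2] %% factor != 0)
    stop("image dimensions are not divisible by the rebin factor")
  out <- array(0, c(d[1] / factor, d[2] / factor, d[3]))
  for (k in seq_len(d[3])) out[, , k] <- block_sum(image$counts[, , k], factor)
  image$counts <- out
  image$pitch <- image$pitch * factor
  image
}

#' Simulate one acquisition end to end
#'
#' Convenience chain used throughout: expected counts at native pitch,
#' charge-sharing convolution of the means, Poisson sampling, and rebinning
#' to macro-pixels.
#'
#' @param bundle a `phantom_bundle`.
#' @param spectrum,drf,thresholds forward-model components.
#' @param exposure_mas exposure in mAs.
#' @param seed Poisson seed; `NULL` keeps the noise-free means.
#' @param kernel optional pre-computed sharing kernel.
#' @param mu_al,mu_pmma optional pre-loaded attenuation tables.
#' @return a macro-pitch `binned_counts`.
#' @export
simulate_acquisition <- function(bundle, spectrum, drf, thresholds,
                                 exposure_mas, seed = NULL,
                                 kernel = sharing_kernel(drf$config),
                                 mu_al = load_attenuation("al"),
                                 mu_pmma = load_attenuation("pmma")) {
  img <- expected_bin_counts(bundle$maps, spectrum, drf, thresholds,
                             exposure_mas, mu_al = mu_al, mu_pmma = mu_pmma)
  img <- apply_sharing(img, kernel)
  if (!is.null(seed)) img <- sample_poisson(img, seed)
  rebin_counts(img, drf$config$rebin_factor)
}

#' @export
print.drf_matrix <- function(x, ...) {
  cat(sprintf("<drf_matrix> %d incident x %d detected energies (keV)\n",
              length(x$incident_kev), length(x$detected_kev)))
  cat(sprintf("  row sums (detection efficiency) in [%.3f, %.3f]\n",
              min(rowSums(x$R)), max(rowSums(x$R))))
  invisible(x)
}

#' @export
print.binned_counts <- function(x, ...) {
  d <- dim(x$counts)
  cat(sprintf("<binned_counts> %d x %d px at %.3g mm, %d bins, %s, %.3g mAs\n",
              d[1], d[2], x$pitch, d[3],
              if (x$is_noisy) sprintf("noisy (seed %d)", x$seed) else "noise-free",
              x$exposure_mas))
  invisible(x)
}
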