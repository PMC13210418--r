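#' Unit-sum disk matched-filter template
#'
#' Binary disk of radius `radius_mm` at pitch `pitch_mm`, normalized to unit
#' sum, so the filter response equals the local mean inside the disk.
#'
#' @param radius_mm disk radius in mm.
#' @param pitch_mm pixel pitch of the image it will be applied to (mm).
#' @return a `disk_template` with the pixel offset set `Omega` and uniform
#'   weights `1 / |Omega|`.
#' @export
disk_template <- function(radius_mm, pitch_mm = 1) {
  w <- ceiling(radius_mm / pitch_mm)
  off <- expand.grid(dy = -w:w, dx = -w:w)
  keep <- sqrt(off$dy^2 + off$dx^2) * pitch_mm <= radius_mm
  off <- off[keep, ]
  structure(list(offsets = off, radius_mm = radius_mm, pitch_mm = pitch_mm,
                 n = nrow(off), half_width = w),
            class = "disk_template")
}

#' Matched-filter response map
#'
#' Response at pixel p is the mean of `map` over the disk centered at p
#' (unit-sum template). A border band of the template half-width is marked
#' invalid (`NA`).
#'
#' @param map 2D numeric matrix (e.g. one decomposed material map).
#' @param template a [disk_template()].
#' @return matrix of responses, `NA` in the invalid border band.
#' @export
matched_filter <- function(map, template) {
  stopifnot(is.matrix(map), inherits(template, "disk_template"))
  w <- template$half_width
  n1 <- nrow(map); n2 <- ncol(map)
  if (2 * w + 1 > min(n1, n2)) stop("template larger than image")
  pad <- matrix(NA_real_, n1 + 2 * w, n2 + 2 * w)
  pad[w + seq_len(n1), w + seq_len(n2)] <- map
  acc <- matrix(0, n1, n2)
  for (i in seq_len(template$n)) {
    acc <- acc + pad[w + seq_len(n1) + template$offsets$dy[i],
                     w + seq_len(n2) + template$offsets$dx[i]]
  }
  acc / template$n
}

#' True-positive decision variable
#'
#' Maximum matched-filter response within an acceptance region around the
#' known target location.
#'
#' @param response a [matched_filter()] map.
#' @param center_xy_mm target center `c(x, y)` in mm.
#' @param acceptance_radius_mm acceptance-region radius in mm.
#' @param pitch_mm pixel pitch of the response map.
#' @return scalar score.
#' @export
tp_score <- function(response, center_xy_mm, acceptance_radius_mm,
                     pitch_mm = 1) {
  m <- disk_mask(dim(response), pitch_mm, center_xy_mm[1], center_xy_mm[2],
                 max(acceptance_radius_mm, pitch_mm / 2))
  vals <- response[m]
  vals <- vals[is.finite(vals)]
  if (length(vals) == 0) stop("acceptance region has no valid pixels")
  max(vals)
}

#' False-positive decision variables
#'
#' Strict 8-neighborhood local maxima of the response inside each search
#' mask whose value exceeds the `percentile` quantile of the in-mask
#' response values; scores are pooled over all masks. A constant response
#' yields no marks.
#'
#' @param response a [matched_filter()] map.
#' @param masks list of logical matrices (search regions), same shape as
#'   `response`.
#' @param percentile quantile threshold in (0, 1), default 0.95.
#' @return numeric vector of pooled scores (possibly empty).
#' @export
fp_scores <- function(response, masks, percentile = 0.95) {
  if (!is.list(masks)) masks <- list(masks)
  if (length(masks) == 0 || any(!vapply(masks, any, logical(1))))
    stop("empty search mask")
  n1 <- nrow(response); n2 <- ncol(response)
  pad <- matrix(-Inf, n1 + 2, n2 + 2)
  pad[1 + seq_len(n1), 1 + seq_len(n2)] <- ifelse(is.na(response), -Inf,
                                                  response)
  is_max <- matrix(TRUE, n1, n2)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    is_max <- is_max & (pad[1 + seq_len(n1), 1 + seq_len(n2)] >
                          pad[1 + seq_len(n1) + dr, 1 + seq_len(n2) + dc])
  }
  out <- numeric(0)
  for (m in masks) {
    vals <- response[m]
    vals <- vals[is.finite(vals)]
    if (length(vals) == 0) next
    thr <- stats::quantile(vals, percentile, names = FALSE)
    sel <- m & is_max & !is.na(response) & response > thr
    out <- c(out, response[sel])
  }
  out
}

#' Nonparametric EFROC area
#'
#' Exponential free-response ROC area
#' `A_FE = (1/I) sum_i exp(-(1/N) sum_j H(y_j - x_i))` with `H(z) = 1` for
#' `z > 0`, `1/2` for `z = 0`, `0` for `z < 0`; `x_i` are true-positive
#' scores, `y_j` pooled false-positive scores, and `N` the number of
#' signal-absent images. With no false positives, `A_FE = 1`.
#'
#' @param tp true-positive scores (length I >= 1).
#' @param fp false-positive scores (length J >= 0).
#' @param n_absent number of signal-absent images N (>= 1).
#' @return list with `a_fe`, `I`, `J`, `N`.
#' @export
efroc_area <- function(tp, fp, n_absent) {
  stopifnot(length(tp) >= 1, n_absent >= 1,
            all(is.finite(tp)), all(is.finite(fp)))
  if (length(fp) == 0) {
    a <- 1
  } else {
    H <- outer(fp, tp, function(y, x) (sign(y - x) + 1) / 2)
    a <- mean(exp(-colSums(H) / n_absent))
  }
  list(a_fe = a, I = length(tp), J = length(fp), N = n_absent)
}

#' Hanley--McNeil standard error of an AUC
#'
#' `sigma = sqrt([A(1-A) + (Nt-1)(Q1-A^2) + (Nf-1)(Q2-A^2)] / (Nt Nf))`
#' with `Q1 = A / (2 - A)` and `Q2 = 2 A^2 / (1 + A)`.
#'
#' @param auc area under the curve in `[0, 1]`.
#' @param nt,nf numbers of positive and negative scores (>= 1).
#' @return standard error (>= 0).
#' @export
hanley_mcneil_sigma <- function(auc, nt, nf) {
  if (auc < 0 || auc > 1) stop("auc must lie in [0, 1]")
  stopifnot(nt >= 1, nf >= 1)
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  v <- (auc * (1 - auc) + (nt - 1) * (q1 - auc^2) +
          (nf - 1) * (q2 - auc^2)) / (nt * nf)
  sqrt(max(v, 0))
}

# rectangle + exclusion-disk mask at macro pitch
rect_mask <- function(dim_px, pitch, x_range, y_range) {
  x <- (seq_len(dim_px[2]) - 0.5) * pitch
  y <- (seq_len(dim_px[1]) - 0.5) * pitch
  outer(y >= y_range[1] & y <= y_range[2], x >= x_range[1] & x <= x_range[2],
        `&`)
}

#' False-positive search masks for an LCD phantom
#'
#' Two macro-pitch search regions matching the detectability protocol:
#' (i) a uniform-background rectangle in the left half of the field,
#' excluding the (removed) signal disk location and its surroundings, and
#' (ii) a rectangle containing the thick non-target inserts in the right
#' half.
#'
#' @param bundle an LCD `phantom_bundle`.
#' @param macro_pitch_mm analysis pixel pitch (mm).
#' @param exclusion_mm radius around the signal-disk location excluded from
#'   the background mask.
#' @return list of two logical matrices.
#' @export
lcd_fp_masks <- function(bundle, macro_pitch_mm = 1, exclusion_mm = 6) {
  stopifnot(bundle$kind %in% c("al_lcd", "pmma_lcd"))
  n <- round(bundle$size_mm / macro_pitch_mm)
  bg <- rect_mask(c(n, n), macro_pitch_mm, c(5, 45), c(5, 95))
  # exclude the signal-disk layout position (fixed at (25, 50) mm)
  bg <- bg & !disk_mask(c(n, n), macro_pitch_mm, 25, 50, exclusion_mm)
  nt <- rect_mask(c(n, n), macro_pitch_mm, c(55, 95), c(25, 75))
  list(background = bg, non_target = nt)
}

#' Run one EFROC detectability task
#'
#' Simulates `R` paired signal-present / signal-absent acquisitions of an
#' LCD phantom (each pair shares its Poisson seed, so differences are
#' signal-driven), decomposes them with one or more fitted models, scores
#' the target-material map with the unit-sum disk matched filter, and
#' returns the nonparametric EFROC area with its Hanley--McNeil standard
#' error.
#'
#' @param task `"al_lcd"` or `"pmma_lcd"`.
#' @param models a fitted `decomp_model` or a named list of them (sharing
#'   the simulated realizations).
#' @param spectrum,drf,thresholds forward-model components.
#' @param dose_mas exposure in mAs.
#' @param R number of paired realizations.
#' @param seed_base Poisson seeds are `seed_base + 0:(R-1)`.
#' @param acceptance_radius_mm TP acceptance-region radius (default 2x the
#'   signal radius).
#' @param fp_percentile threshold quantile for FP candidate marks.
#' @param mu_al,mu_pmma optional pre-loaded attenuation tables.
#' @return an `efroc_result` (fields `a_fe`, `sigma`, `tp`, `fp`, `I`, `J`,
#'   `N`, `task`, `dose_mas`), or a named list of them when `models` is a
#'   list.
#' @export
run_efroc_task <- function(task, models, spectrum, drf, thresholds, dose_mas,
                           R = 10, seed_base = 0,
                           acceptance_radius_mm = NULL,
                           fp_percentile = 0.95,
                           mu_al = load_attenuation("al"),
                           mu_pmma = load_attenuation("pmma")) {
  single <- inherits(models, "decomp_model")
  if (single) models <- list(model = models)
  stopifnot(all(vapply(models, inherits, logical(1), "decomp_model")),
            R >= 1)
  present <- build_lcd_phantom(task)
  absent <- remove_insert(present, present$signal_insert)
  sig <- present$inserts[1, ]
  target <- sig$material
  if (is.null(acceptance_radius_mm)) acceptance_radius_mm <- 2 * sig$radius_mm
  macro_pitch <- present$maps$pitch * drf$config$rebin_factor
  tmpl <- disk_template(sig$radius_mm, macro_pitch)
  masks <- lcd_fp_masks(present, macro_pitch)
  kernel <- sharing_kernel(drf$config)
  n0 <- open_beam_counts(spectrum, drf, thresholds, dose_mas)

  mean_p <- rebinned_mean(present, spectrum, drf, thresholds, dose_mas,
                          kernel, mu_al, mu_pmma)
  mean_a <- rebinned_mean(absent, spectrum, drf, thresholds, dose_mas,
                          kernel, mu_al, mu_pmma)
  tp <- lapply(models, function(m) numeric(R))
  fp <- lapply(models, function(m) numeric(0))
  for (r in seq_len(R)) {
    seed <- seed_base + r - 1
    noisy_p <- rebin_counts(sample_poisson(mean_p, seed),
                            drf$config$rebin_factor)
    noisy_a <- rebin_counts(sample_poisson(mean_a, seed),
                            drf$config$rebin_factor)
    feat_p <- to_features(noisy_p, n0)
    feat_a <- to_features(noisy_a, n0)
    for (nm in names(models)) {
      map_p <- decompose(models[[nm]], feat_p)
      map_a <- decompose(models[[nm]], feat_a)
      img_p <- if (target == "al") map_p$al else map_p$pmma
      img_a <- if (target == "al") map_a$al else map_a$pmma
      tp[[nm]][r] <- tp_score(matched_filter(img_p, tmpl),
                              c(sig$center_x_mm, sig$center_y_mm),
                              acceptance_radius_mm, macro_pitch)
      fp[[nm]] <- c(fp[[nm]],
                    fp_scores(matched_filter(img_a, tmpl), masks,
                              fp_percentile))
    }
  }
  out <- lapply(names(models), function(nm) {
    ar <- efroc_area(tp[[nm]], fp[[nm]], n_absent = R)
    structure(
      list(a_fe = ar$a_fe,
           sigma = hanley_mcneil_sigma(ar$a_fe, ar$I, max(ar$J, 1)),
           tp = tp[[nm]], fp = fp[[nm]], I = ar$I, J = ar$J, N = ar$N,
           task = task, dose_mas = dose_mas, model = nm,
           acceptance_radius_mm = acceptance_radius_mm,
           fp_percentile = fp_percentile, seed_base = seed_base),
      class = "efroc_result")
  })
  names(out) <- names(models)
  if (single) out[[1]] else out
}

# noise-free mean stack at native pitch with sharing applied
rebinned_mean <- function(bundle, spectrum, drf, thresholds, dose_mas,
                          kernel, mu_al, mu_pmma) {
  img <- expected_bin_counts(bundle$maps, spectrum, drf, thresholds,
                             dose_mas, mu_al = mu_al, mu_pmma = mu_pmma)
  apply_sharing(img, kernel)
}

#' @export
print.efroc_result <- function(x, ...) {
  cat(sprintf("<efroc_result> %s, %s, %.3g mAs: A_FE = %.4f (sigma %.4f), I = %d, J = %d\n",
              x$task, x$model, x$dose_mas, x$a_fe, x$sigma, x$I, x$J))
  invisible(x)
}
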