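#' ROI mean over an insert
#'
#' Mean of the selected material's thickness map over pixels whose centers
#' lie within the insert disk shrunk by `margin_mm` (the boundary band is
#' excluded to avoid partial-volume contamination).
#'
#' @param maps a `thickness_maps` (typically at macro pitch).
#' @param insert one row of an insert registry (see [insert_spec()]).
#' @param margin_mm boundary margin excluded from the ROI (default 2 mm).
#' @param material `"al"`, `"pmma"`, or `NULL` to use the insert's own
#'   material.
#' @return scalar mean thickness in mm.
#' @export
roi_mean <- function(maps, insert, margin_mm = 2, material = NULL) {
  stopifnot(inherits(maps, "thickness_maps"))
  r <- insert$radius_mm - margin_mm
  if (r <= 0) stop("margin leaves an empty ROI")
  m <- disk_mask(dim(maps$al), maps$pitch, insert$center_x_mm,
                 insert$center_y_mm, r)
  if (!any(m)) stop("empty ROI")
  mat <- if (is.null(material)) insert$material else material
  mean(if (mat == "al") maps$al[m] else maps$pmma[m])
}

#' Bias of repeated thickness estimates
#'
#' Signed systematic error `mean(t_hat) - t_true` over noise realizations.
#'
#' @param t_hat per-realization ROI-mean estimates (mm), length N >= 1.
#' @param t_true ground-truth thickness (mm).
#' @return bias in mm.
#' @export
thickness_bias <- function(t_hat, t_true) {
  stopifnot(length(t_hat) >= 1)
  mean(t_hat - t_true)
}

#' Root mean square error of repeated thickness estimates
#'
#' `sqrt(mean((t_hat - t_true)^2))`; combines systematic error and
#' realization-to-realization variability.
#'
#' @inheritParams thickness_bias
#' @return RMSE in mm.
#' @export
thickness_rmse <- function(t_hat, t_true) {
  stopifnot(length(t_hat) >= 1)
  sqrt(mean((t_hat - t_true)^2))
}

#' Per-insert accuracy table
#'
#' Summarizes decomposed maps from several noise realizations into one row
#' per insert: truth, bias, RMSE and the standard deviation of the ROI
#' means.
#'
#' @param maps_list list of decomposed `thickness_maps`, one per noise
#'   realization.
#' @param bundle the `phantom_bundle` that was imaged (supplies the insert
#'   registry and background).
#' @param margin_mm ROI boundary margin in mm.
#' @return data frame with columns `insert`, `material`, `t_true_mm`,
#'   `bias_mm`, `rmse_mm`, `std_mm`, `n_realizations`.
#' @export
insert_accuracy <- function(maps_list, bundle, margin_mm = 2) {
  stopifnot(inherits(bundle, "phantom_bundle"), length(maps_list) >= 1)
  ins <- bundle$inserts
  rows <- lapply(seq_len(nrow(ins)), function(i) {
    t_true <- bundle$background[[ins$material[i]]] + ins$delta_mm[i]
    t_hat <- vapply(maps_list, roi_mean, numeric(1), insert = ins[i, ],
                    margin_mm = margin_mm)
    data.frame(insert = i, material = ins$material[i], t_true_mm = t_true,
               bias_mm = thickness_bias(t_hat, t_true),
               rmse_mm = thickness_rmse(t_hat, t_true),
               std_mm = if (length(t_hat) > 1) stats::sd(t_hat) else 0,
               n_realizations = length(t_hat))
  })
  do.call(rbind, rows)
}
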