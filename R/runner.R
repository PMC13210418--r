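#' Experiment configuration
#'
#' Validated configuration for the accuracy and detectability sweeps. The
#' defaults reproduce the study conditions: three dose levels (1e5, 2.3e6,
#' 1e7 open-beam photons per native pixel), calibration grids 3x3 / 5x5 /
#' 8x8, threshold counts 2 / 4 / 6, all three decomposition models, five
#' noise realizations for the accuracy metrics and ten paired realizations
#' for EFROC.
#'
#' @param dose_photons open-beam photons per native pixel per dose level.
#' @param grid_sizes calibration grid sizes (subset of \{3, 5, 8\}).
#' @param threshold_counts numbers of energy thresholds (subset of 2..6).
#' @param models decomposition methods to evaluate.
#' @param n_seeds noise realizations per accuracy condition.
#' @param efroc_r paired realizations per EFROC condition.
#' @param seed_base first Poisson seed.
#' @param grid_sweep_m threshold count held fixed during the grid sweep.
#' @param efroc_grid,efroc_m calibration grid size and threshold count held
#'   fixed for EFROC.
#' @param roi_margin_mm ROI boundary margin.
#' @param mlp_epochs,mlp_seed MLP training controls.
#' @param detector detector configuration override.
#' @param out_dir if non-`NULL`, sweep tables are also written there as CSV.
#' @return an `experiment_config` list.
#' @export
experiment_config <- function(dose_photons = c(1e5, 2.3e6, 1e7),
                              grid_sizes = c(3, 5, 8),
                              threshold_counts = c(2, 4, 6),
                              models = c("poly2", "mlp", "svr"),
                              n_seeds = 5, efroc_r = 10, seed_base = 0,
                              grid_sweep_m = 2, efroc_grid = 8, efroc_m = 4,
                              roi_margin_mm = 2,
                              mlp_epochs = 10000, mlp_seed = 1,
                              detector = detector_config(),
                              out_dir = NULL) {
  stopifnot(all(dose_photons > 0),
            all(grid_sizes %in% c(3, 5, 8)),
            all(threshold_counts %in% 2:6),
            all(models %in% c("poly2", "mlp", "svr")),
            n_seeds >= 1, efroc_r >= 1,
            grid_sweep_m %in% 2:6, efroc_m %in% 2:6,
            efroc_grid >= 2, roi_margin_mm >= 0,
            inherits(detector, "detector_config"))
  cfg <- list(dose_photons = dose_photons, grid_sizes = grid_sizes,
              threshold_counts = threshold_counts, models = models,
              n_seeds = n_seeds, efroc_r = efroc_r, seed_base = seed_base,
              grid_sweep_m = grid_sweep_m, efroc_grid = efroc_grid,
              efroc_m = efroc_m, roi_margin_mm = roi_margin_mm,
              mlp_epochs = mlp_epochs, mlp_seed = mlp_seed,
              detector = detector, out_dir = out_dir)
  cfg$hash <- config_hash(cfg)
  structure(cfg, class = "experiment_config")
}

config_hash <- function(cfg) {
  s <- paste(deparse(cfg[setdiff(names(cfg), c("out_dir", "hash"))]),
             collapse = "")
  sprintf("%08x", sum(utf8ToInt(s) * (seq_along(utf8ToInt(s)) %% 251 + 1)) %%
            .Machine$integer.max)
}

fit_all_models <- function(grid, cfg) {
  out <- list()
  for (m in cfg$models) {
    out[[m]] <- switch(m,
      poly2 = decomp_fit(grid, "poly2"),
      mlp = decomp_fit(grid, "mlp", epochs = cfg$mlp_epochs,
                       seed = cfg$mlp_seed),
      svr = decomp_fit(grid, "svr"))
  }
  out
}

provenance_cols <- function(df, cfg) {
  df$config_hash <- cfg$hash
  df$seed_base <- cfg$seed_base
  df$version <- as.character(utils::packageVersion("pcdrad"))
  df
}

#' Per-insert accuracy sweeps
#'
#' Runs the two quantitative sweeps on the quantitative phantom:
#' (i) calibration-grid sweep -- every (model, dose, grid size) combination
#' at a fixed threshold count (`grid_sweep_m`); (ii) threshold sweep --
#' every (model, threshold count) at the highest dose and the densest grid.
#' All models see identical noisy realizations per condition. Deterministic
#' for a fixed configuration.
#'
#' @param cfg an [experiment_config()].
#' @return data frame of per-insert bias/RMSE rows with sweep coordinates
#'   (`sweep`, `model`, `dose_mas`, `grid`, `m_thresholds`) and provenance
#'   columns; written to `grid_sweep.csv` / `threshold_sweep.csv` under
#'   `out_dir` when configured.
#' @export
run_accuracy_sweep <- function(cfg = experiment_config()) {
  stopifnot(inherits(cfg, "experiment_config"))
  mu_al <- load_attenuation("al"); mu_pmma <- load_attenuation("pmma")
  spectrum <- load_spectrum()
  drf <- build_drf(cfg$detector)
  kernel <- sharing_kernel(cfg$detector)
  phantom <- build_quant_phantom(cfg$detector$pixel_pitch_mm)
  doses <- photons_to_mas(cfg$dose_photons)
  seeds <- cfg$seed_base + seq_len(cfg$n_seeds) - 1

  sweep_rows <- function(sweep_name, m_thr, grids, doses_use) {
    thresholds <- default_thresholds(m_thr)
    models_by_grid <- lapply(grids, function(G) {
      grid <- make_calibration_grid(G, spectrum, drf, thresholds,
                                    mu_al = mu_al, mu_pmma = mu_pmma)
      fit_all_models(grid, cfg)
    })
    names(models_by_grid) <- as.character(grids)
    n0 <- NULL
    mean_img <- expected_bin_counts(phantom$maps, spectrum, drf, thresholds,
                                    1, mu_al = mu_al, mu_pmma = mu_pmma)
    mean_img <- apply_sharing(mean_img, kernel)
    rows <- list()
    for (dose in doses_use) {
      scaled <- mean_img
      scaled$counts <- scaled$counts * dose
      scaled$exposure_mas <- dose
      n0 <- open_beam_counts(spectrum, drf, thresholds, dose)
      feats <- lapply(seeds, function(s) {
        noisy <- rebin_counts(sample_poisson(scaled, s),
                              cfg$detector$rebin_factor)
        to_features(noisy, n0)
      })
      for (G in as.character(grids)) for (m in cfg$models) {
        maps_list <- lapply(feats, decompose,
                            model = models_by_grid[[G]][[m]])
        acc <- insert_accuracy(maps_list, phantom,
                               margin_mm = cfg$roi_margin_mm)
        acc$sweep <- sweep_name; acc$model <- m
        acc$dose_mas <- dose; acc$grid <- as.integer(G)
        acc$m_thresholds <- m_thr
        rows[[length(rows) + 1]] <- acc
      }
    }
    do.call(rbind, rows)
  }

  grid_sweep <- sweep_rows("grid", cfg$grid_sweep_m, cfg$grid_sizes, doses)
  thr_sweep <- do.call(rbind, lapply(cfg$threshold_counts, function(m_thr)
    sweep_rows("threshold", m_thr, max(cfg$grid_sizes), max(doses))))
  out <- provenance_cols(rbind(grid_sweep, thr_sweep), cfg)
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(out[out$sweep == "grid", ],
                     file.path(cfg$out_dir, "grid_sweep.csv"),
                     row.names = FALSE)
    utils::write.csv(out[out$sweep == "threshold", ],
                     file.path(cfg$out_dir, "threshold_sweep.csv"),
                     row.names = FALSE)
  }
  out
}

#' EFROC detectability sweep
#'
#' Runs [run_efroc_task()] for both LCD tasks, every model, and every dose
#' level, at the fixed EFROC calibration grid and threshold count.
#'
#' @param cfg an [experiment_config()].
#' @return data frame with one row per (task, model, dose).
#' @export
run_efroc_sweep <- function(cfg = experiment_config()) {
  stopifnot(inherits(cfg, "experiment_config"))
  mu_al <- load_attenuation("al"); mu_pmma <- load_attenuation("pmma")
  spectrum <- load_spectrum()
  drf <- build_drf(cfg$detector)
  thresholds <- default_thresholds(cfg$efroc_m)
  grid <- make_calibration_grid(cfg$efroc_grid, spectrum, drf, thresholds,
                                mu_al = mu_al, mu_pmma = mu_pmma)
  models <- fit_all_models(grid, cfg)
  doses <- photons_to_mas(cfg$dose_photons)
  rows <- list()
  for (task in c("al_lcd", "pmma_lcd")) for (dose in doses) {
    res <- run_efroc_task(task, models, spectrum, drf, thresholds, dose,
                          R = cfg$efroc_r, seed_base = cfg$seed_base,
                          mu_al = mu_al, mu_pmma = mu_pmma)
    for (nm in names(res)) {
      r <- res[[nm]]
      rows[[length(rows) + 1]] <- data.frame(
        task = task, model = nm, dose_mas = dose, a_fe = r$a_fe,
        sigma = r$sigma, I = r$I, J = r$J, N = r$N,
        acceptance_radius_mm = r$acceptance_radius_mm,
        fp_percentile = r$fp_percentile, seed_base = r$seed_base)
    }
  }
  out <- provenance_cols(do.call(rbind, rows), cfg)
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(out, file.path(cfg$out_dir, "efroc_sweep.csv"),
                     row.names = FALSE)
  }
  out
}

#' MLP architecture sensitivity study
#'
#' Trains networks with `layers` hidden layers and `widths` neurons per
#' layer on the noise-free calibration grid and reports validation RMSE per
#' material on a dense lattice over the calibration ranges (training nodes
#' excluded), averaged over `n_seeds` initialization seeds, together with
#' trainable-parameter counts.
#'
#' @param cfg an [experiment_config()].
#' @param layers hidden-layer depths to evaluate.
#' @param widths hidden-layer widths to evaluate.
#' @param n_seeds initialization seeds per architecture.
#' @param val_n validation lattice size per axis.
#' @return data frame with one row per (layers, width).
#' @export
run_mlp_architecture_study <- function(cfg = experiment_config(),
                                       layers = 1:3,
                                       widths = c(32, 64, 128, 256),
                                       n_seeds = 3, val_n = 25) {
  stopifnot(inherits(cfg, "experiment_config"), n_seeds >= 1)
  mu_al <- load_attenuation("al"); mu_pmma <- load_attenuation("pmma")
  spectrum <- load_spectrum()
  drf <- build_drf(cfg$detector)
  thresholds <- default_thresholds(cfg$efroc_m)
  grid <- make_calibration_grid(cfg$efroc_grid, spectrum, drf, thresholds,
                                mu_al = mu_al, mu_pmma = mu_pmma)
  val <- validation_lattice(grid, spectrum, drf, n = val_n,
                            mu_al = mu_al, mu_pmma = mu_pmma)
  rows <- list()
  for (L in layers) for (w in widths) {
    rmse <- vapply(seq_len(n_seeds), function(s) {
      fit <- decomp_fit(grid, "mlp", width = w, layers = L,
                        epochs = cfg$mlp_epochs, seed = cfg$mlp_seed + s - 1)
      pred <- predict(fit, val$features)
      c(al = sqrt(mean((pred[, 1] - val$thickness[, 1])^2)),
        pmma = sqrt(mean((pred[, 2] - val$thickness[, 2])^2)))
    }, numeric(2))
    rows[[length(rows) + 1]] <- data.frame(
      layers = L, width = w,
      n_params = mlp_param_count(ncol(grid$features), w, L),
      rmse_al_mean = mean(rmse["al", ]), rmse_al_std = stats::sd(rmse["al", ]),
      rmse_pmma_mean = mean(rmse["pmma", ]),
      rmse_pmma_std = stats::sd(rmse["pmma", ]),
      rmse_mean = mean(colMeans(rmse)), n_seeds = n_seeds)
  }
  out <- provenance_cols(do.call(rbind, rows), cfg)
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(out, file.path(cfg$out_dir, "mlp_architecture.csv"),
                     row.names = FALSE)
  }
  out
}

#' @export
print.experiment_config <- function(x, ...) {
  cat("<experiment_config>\n")
  cat(sprintf("  doses: %s photons/macro-pixel (%s mAs)\n",
              paste(format(x$dose_photons, scientific = TRUE), collapse = ", "),
              paste(signif(photons_to_mas(x$dose_photons), 3), collapse = ", ")))
  cat(sprintf("  grids: %s | thresholds: %s | models: %s\n",
              paste(x$grid_sizes, collapse = ","),
              paste(x$threshold_counts, collapse = ","),
              paste(x$models, collapse = ",")))
  cat(sprintf("  %d accuracy seeds, %d EFROC pairs, seed base %d, hash %s\n",
              x$n_seeds, x$efroc_r, x$seed_base, x$hash))
  invisible(x)
}
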