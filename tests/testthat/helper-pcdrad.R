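# Shared fixtures, built once per test run. Everything is generated in code;
# the only files read are the package's bundled spectrum/attenuation tables.

sp_h <- load_spectrum()
mu_al_h <- load_attenuation("al")
mu_pmma_h <- load_attenuation("pmma")
mu_cdte_h <- load_attenuation("cdte")
cfg_h <- detector_config()
drf_h <- build_drf(cfg_h, mu_cdte = mu_cdte_h)
thr4_h <- default_thresholds(4)
grid8_h <- make_calibration_grid(8, sp_h, drf_h, thr4_h,
                                 mu_al = mu_al_h, mu_pmma = mu_pmma_h)

# noise-free background feature vector of the LucAl slab (4.1 mm Al + 83 mm
# PMMA) for the default M = 4 thresholds
slab_features <- function(x_al, x_pmma, thresholds = thr4_h) {
  n <- pcdrad:::slab_bin_counts(sp_h, drf_h, thresholds, x_al, x_pmma,
                                mu_al_h, mu_pmma_h)
  n0 <- pcdrad:::slab_bin_counts(sp_h, drf_h, thresholds, 0, 0,
                                 mu_al_h, mu_pmma_h)
  matrix(-log(n / n0), 1)
}

# tiny synthetic calibration-grid object for regression-model contract tests
fake_grid <- function(features, thickness) {
  structure(list(thickness = thickness, features = features,
                 G = as.integer(sqrt(nrow(features))),
                 al_range = range(thickness[, 1]),
                 pmma_range = range(thickness[, 2]),
                 thresholds = seq_len(ncol(features))),
            class = "calibration_grid")
}

# uniform-slab bundle helper used by detector tests
uniform_bundle <- function(size_mm = 10, pitch = 0.1, al = 4.1, pmma = 83) {
  n <- round(size_mm / pitch)
  ins <- insert_spec(size_mm / 2, size_mm / 2, 1, "al", 0)[0, ]
  structure(
    list(maps = structure(list(al = matrix(al, n, n),
                               pmma = matrix(pmma, n, n), pitch = pitch),
                          class = "thickness_maps"),
         inserts = ins, kind = "uniform", signal_insert = NA_integer_,
         background = c(al = al, pmma = pmma), size_mm = size_mm),
    class = "phantom_bundle")
}
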