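test_that("DRF rows peak at the photopeak and carry the interaction probability", {
  i <- which(drf_h$incident_kev == 60)
  row <- drf_h$R[i, ]
  expect_equal(drf_h$detected_kev[which.max(row)], 60)
  eff <- 1 - exp(-mu_at(mu_cdte_h, 60) * cfg_h$cdte_thickness_mm)
  expect_equal(sum(row), eff, tolerance = 1e-6)
  # rows never peak above the incident energy
  peaks <- drf_h$detected_kev[apply(drf_h$R, 1, which.max)]
  expect_true(all(peaks <= drf_h$incident_kev))
  expect_true(all(drf_h$R >= 0))
  expect_true(all(rowSums(drf_h$R) <= 2))
})

test_that("DRF degenerates to a scaled diagonal without sharing or noise", {
  cfg0 <- detector_config(charge_cloud_sigma_mm = 1e-6,
                          electronic_noise_kev = 1e-6,
                          fano_factor = 1e-9, pair_creation_kev = 1e-9,
                          escape_model_on = FALSE)
  d0 <- build_drf(cfg0, mu_cdte = mu_cdte_h)
  eff <- 1 - exp(-mu_at(mu_cdte_h, d0$incident_kev) * 1.0)
  for (i in c(1, 60, 140)) {
    row <- d0$R[i, ]
    expect_equal(row[d0$incident_kev[i]], eff[i], tolerance = 1e-4)
    expect_lt(sum(row) - row[d0$incident_kev[i]], 1e-4)
  }
})

test_that("sharing kernel matches a quadrature oracle and its limits", {
  k <- sharing_kernel(cfg_h)
  expect_equal(sum(k), 1, tolerance = 1e-12)
  expect_equal(k, k[3:1, ], tolerance = 1e-12)  # 4-fold symmetry
  expect_equal(k, t(k), tolerance = 1e-12)
  # quadrature oracle: average Gaussian mass in each pixel over cloud centers
  p <- cfg_h$pixel_pitch_mm; s <- cfg_h$charge_cloud_sigma_mm
  u <- (seq_len(2000) - 0.5) * p / 2000
  mass_1d <- function(kk) mean(pnorm(((kk + 1) * p - u) / s) -
                                 pnorm((kk * p - u) / s))
  oracle <- outer(vapply(-1:1, mass_1d, 0), vapply(-1:1, mass_1d, 0))
  oracle <- oracle / sum(oracle)
  expect_equal(k[2, 2], oracle[2, 2], tolerance = 1e-6)
  expect_equal(as.numeric(k), as.numeric(oracle), tolerance = 1e-6)
  # vanishing cloud: identity kernel
  k0 <- sharing_kernel(detector_config(charge_cloud_sigma_mm = 1e-9))
  expect_equal(k0[2, 2], 1, tolerance = 1e-6)
})

test_that("threshold placement and binning partition the counted range", {
  expect_equal(default_thresholds(2), c(20, 60))
  expect_equal(default_thresholds(4), c(20, 40, 60, 80))
  expect_error(default_thresholds(1))
  expect_error(default_thresholds(7))
  B <- pcdrad:::bin_response(drf_h, thr4_h)
  # no counts are lost between bins: bins tile [T1, infinity)
  above_t1 <- rowSums(drf_h$R[, drf_h$detected_kev >= 20])
  expect_equal(rowSums(B), above_t1, tolerance = 1e-12)
})

test_that("expected counts are uniform open-beam and monotone in thickness", {
  b0 <- uniform_bundle(2, 0.1, al = 0, pmma = 0)
  img0 <- expected_bin_counts(b0$maps, sp_h, drf_h, thr4_h, 7.5,
                              mu_al = mu_al_h, mu_pmma = mu_pmma_h)
  for (k in 1:4) expect_equal(diff(range(img0$counts[, , k])), 0)
  count_at <- function(pm) {
    b <- uniform_bundle(1, 0.1, al = 4.1, pmma = pm)
    expected_bin_counts(b$maps, sp_h, drf_h, thr4_h, 7.5,
                        mu_al = mu_al_h, mu_pmma = mu_pmma_h)$counts[1, 1, ]
  }
  thick <- sapply(c(60, 80, 100), count_at)  # 4 bins x 3 thicknesses
  expect_true(all(diff(t(thick)) < 0))       # every bin strictly decreases
  bad_sp <- sp_h; bad_sp$energies <- bad_sp$energies + 1
  expect_error(expected_bin_counts(b0$maps, bad_sp, drf_h, thr4_h, 7.5),
               "grids")
})

test_that("charge-sharing convolution conserves interior counts", {
  k <- sharing_kernel(cfg_h)
  b <- uniform_bundle(3, 0.1)
  img <- expected_bin_counts(b$maps, sp_h, drf_h, thr4_h, 1,
                             mu_al = mu_al_h, mu_pmma = mu_pmma_h)
  sh <- apply_sharing(img, k)
  expect_equal(sh$counts, img$counts, tolerance = 1e-12)  # uniform unchanged
  # single impulse spreads exactly like the kernel
  imp <- img
  imp$counts <- array(0, dim(img$counts))
  imp$counts[15, 15, 1] <- 1
  sh2 <- apply_sharing(imp, k)
  expect_equal(sh2$counts[14:16, 14:16, 1], k, tolerance = 1e-12)
  expect_equal(sum(sh2$counts), 1, tolerance = 1e-9)
  # noisy stacks are rejected: sharing acts on the mean response
  noisy <- sample_poisson(img, 1)
  expect_error(apply_sharing(noisy, k), "noise-free")
})

test_that("Poisson sampling is unbiased, reproducible, and leaves RNG alone", {
  b <- uniform_bundle(32, 0.1, al = 0, pmma = 0)
  img <- expected_bin_counts(b$maps, sp_h, drf_h, thr4_h, 7.5,
                             mu_al = mu_al_h, mu_pmma = mu_pmma_h)
  img$counts <- array(100, dim(img$counts))  # controlled mean
  n1 <- sample_poisson(img, 7)
  n2 <- sample_poisson(img, 7)
  expect_identical(n1$counts, n2$counts)
  expect_true(all(n1$counts == round(n1$counts)))
  # sample mean of >= 1e5 draws within +-0.5 of the mean (5 sigma of SEM)
  expect_lt(abs(mean(n1$counts[, , 1]) - 100), 0.5)
  # zero mean always yields zero counts
  img$counts[] <- 0
  expect_true(all(sample_poisson(img, 3)$counts == 0))
  # caller RNG state is preserved
  set.seed(123); before <- .Random.seed
  invisible(sample_poisson(img, 5))
  expect_identical(.Random.seed, before)
})

test_that("rebinning sums blocks and conserves totals exactly", {
  img <- pcdrad:::new_binned_counts(array(1, c(20, 30, 2)), 0.1, 1,
                                    c(20, 60))
  rb <- rebin_counts(img, 10)
  expect_equal(dim(rb$counts), c(2, 3, 2))
  expect_true(all(rb$counts == 100))
  expect_equal(rb$pitch, 1)
  img$counts <- array(rpois(20 * 30 * 2, 50), c(20, 30, 2))
  rb <- rebin_counts(img, 10)
  expect_equal(sum(rb$counts), sum(img$counts))
  expect_error(rebin_counts(img, 7), "divisible")
})

test_that("rebinned counts remain Poisson end to end", {
  # variance ~= mean across realizations x pixels for the full chain
  b <- uniform_bundle(20, 0.1)
  img <- expected_bin_counts(b$maps, sp_h, drf_h, thr4_h, 0.075,
                             mu_al = mu_al_h, mu_pmma = mu_pmma_h)
  img <- apply_sharing(img, sharing_kernel(cfg_h))
  stacks <- lapply(0:4, function(s)
    rebin_counts(sample_poisson(img, s), 10)$counts[, , 2])
  x <- unlist(stacks)
  expect_equal(var(x), mean(x), tolerance = 0.1)
})
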