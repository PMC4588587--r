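make_dip <- function(offs, center = 0, width = 0.08, depth = 0.85) {
  1 - depth * exp(-((offs - center) / width)^2)
}

test_that("symmetric dips are centered exactly and shifts are recovered", {
  offs <- wassr_offsets()
  w0 <- wassr_spectrum(offs, make_dip(offs))
  expect_equal(as.numeric(max_symmetry_center(w0)), 0, tolerance = 1e-3)

  w1 <- wassr_spectrum(offs, make_dip(offs, center = 0.12))
  expect_equal(as.numeric(max_symmetry_center(w1)), 0.12,
               tolerance = 1e-3)

  w2 <- wassr_spectrum(offs, make_dip(offs, center = -0.2))
  expect_equal(as.numeric(max_symmetry_center(w2)), -0.2,
               tolerance = 1e-3)
})

test_that("noisy center matches the brute-force grid-search oracle", {
  offs <- wassr_offsets()
  set.seed(31)
  for (center in c(0.07, -0.15, 0.22)) {
    sig <- make_dip(offs, center) + rnorm(length(offs), sd = 0.005)
    w <- wassr_spectrum(offs, sig)
    est <- as.numeric(max_symmetry_center(w))
    ora <- oracle_symmetry_center(w, grid = 5e-4)
    expect_lt(abs(est - ora), 0.002)
  }
})

test_that("degenerate WASSR inputs are flagged", {
  offs <- wassr_offsets()
  expect_error(max_symmetry_center(
    wassr_spectrum(offs, rep(0.9, length(offs)))), "flat")
  expect_error(wassr_spectrum(offs[1:5], rep(1, 5)), ">= 7")
  # a dip pushed to the search edge carries the boundary flag
  w <- wassr_spectrum(offs, make_dip(offs, center = 0.3))
  est <- max_symmetry_center(w)
  expect_true(isTRUE(attr(est, "boundary")) || abs(est - 0.3) < 0.02)
})

test_that("field_map recovers uniform and smooth shift fields", {
  offs <- wassr_offsets()
  n <- 8
  sys <- build_system(NULL, "tissue")

  # uniform imposed 0.1 ppm shift
  base <- simulate_wassr_voxel(sys, 0.1)
  vols <- array(rep(base$signal, each = n * n), dim = c(n, n, length(offs)))
  fm <- field_map(offset_stack(vols, offs))
  expect_true(all(fm$mask))
  expect_lt(max(abs(fm$delta0_ppm - 0.1)), 0.002)

  # smooth polynomial field at SNR 50
  set.seed(41)
  truth <- b0_polynomial_field(n, c(0.02, 0.08, -0.06, 0, 0.04, 0))
  vols <- array(0, dim = c(n, n, length(offs)))
  for (i in 1:n) for (j in 1:n) {
    vols[i, j, ] <- simulate_wassr_voxel(sys, truth[i, j],
                                         noise_sd = 0.02)$signal
  }
  fm2 <- field_map(offset_stack(vols, offs))
  err <- abs(fm2$delta0_ppm - truth)[fm2$mask]
  expect_gt(mean(err <= 0.01), 0.9)

  # masked-out voxels carry the NA sentinel
  mask <- matrix(FALSE, n, n); mask[1:2, ] <- TRUE
  fm3 <- field_map(offset_stack(vols, offs), mask = mask)
  expect_true(all(is.na(fm3$delta0_ppm[!mask])))
  expect_error(field_map(offset_stack(vols, offs),
                         mask = matrix(TRUE, 2, 2)), "mismatch")
})

test_that("B0 correction inverts an imposed shift", {
  offs <- seq(-2, 2, by = 0.1)
  truth <- make_dip(offs, 0, width = 0.5)
  shifted <- make_dip(offs, 0.1, width = 0.5)
  z <- zspectrum(offs, shifted, s0 = 1, normalized = TRUE)

  expect_identical(apply_b0_correction(z, 0), z)
  zc <- apply_b0_correction(z, 0.1)
  interior <- abs(offs) <= 1.8
  expect_lt(max(abs(zc$signal[interior] - truth[interior])), 1e-3)
  expect_error(apply_b0_correction(z, 3), "half the sampled range")
})

test_that("B0 correction restores band asymmetry of a shifted tissue spectrum", {
  # in tissue the broad MT background slopes steeply through the Eu
  # band, so an uncorrected 0.2 ppm shift biases the asymmetry; this
  # is the regime the per-voxel correction targets
  sys <- build_system(agent_preset("Eu-HPDO3A", 4.5), "tissue")
  pulse <- pulse_preset("eu_invivo")
  offs <- c(-20:-16, 16:20)
  d0 <- 0.2

  z_true <- simulate_zspectrum(sys, pulse, acquisition_protocol(offs))
  truth <- auc_contrast(z_true, eu_band())

  zs <- simulate_zspectrum(sys, pulse, acquisition_protocol(offs - d0))
  z_meas <- zspectrum(offs, zs$signal[match(offs - d0, zs$offsets_ppm)],
                      s0 = 1, normalized = TRUE)
  before <- auc_contrast(z_meas, eu_band())
  after <- auc_contrast(apply_b0_correction(z_meas, d0), eu_band())
  expect_lt(abs(after - truth), abs(before - truth))
  expect_lt(abs(after - truth), 0.01)
})
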