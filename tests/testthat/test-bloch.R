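test_that("zero saturation power leaves the spectrum at unity", {
  sys <- build_system(agent_preset("Eu-HPDO3A", 4), "solution")
  z <- simulate_zspectrum(sys, saturation_pulse(0, 1.5),
                          acquisition_protocol(seq(-110, 110, by = 5)))
  expect_true(all(abs(z$signal - 1) < 1e-9))
})

test_that("strong long on-resonance saturation annihilates water signal", {
  w <- build_system(NULL, "solution")
  z <- simulate_zspectrum(w, saturation_pulse(10, 10),
                          acquisition_protocol(0))
  expect_lt(abs(z$signal), 0.01)
})

test_that("propagator matches independent solutions for the Eu solution spectrum", {
  skip_if_not_installed("deSolve")
  sys <- build_system(agent_preset("Eu-HPDO3A", 4), "solution")
  offs <- seq(-110, 110, by = 5)
  z <- simulate_zspectrum(sys, pulse_preset("eu_solution"),
                          acquisition_protocol(offs))
  # independently assembled eigendecomposition solution, every offset
  eig <- vapply(offs, function(o) oracle_bm_eigen(sys, 15, 1.5, o),
                numeric(1))
  expect_lt(max(abs(z$signal - eig)), 0.01)
  # fine-step time integration at representative offsets
  sub <- c(-60, -20, 20, 60)
  ora <- vapply(sub, function(o) oracle_bm_signal(sys, 15, 1.5, o),
                numeric(1))
  expect_lt(max(abs(z$signal[match(sub, z$offsets_ppm)] - ora)), 0.01)
})

test_that("propagator matches the integration oracle on random systems", {
  skip_if_not_installed("deSolve")
  set.seed(101)
  offs <- c(-60, -18, 10, 45, 90)
  for (i in 1:10) {
    sys <- random_system()
    z <- simulate_zspectrum(sys, saturation_pulse(12, 0.3),
                            acquisition_protocol(offs))
    ora <- vapply(offs, function(o) oracle_bm_signal(sys, 12, 0.3, o),
                  numeric(1))
    expect_lt(max(abs(z$signal - ora)), 0.01)
  }
})

test_that("semisolid pool dynamics match the integration oracle", {
  skip_if_not_installed("deSolve")
  sys <- build_system(agent_preset("Yb-HPDO3A", 9.5), "tissue")
  offs <- c(-97, -20, 30, 97)
  z <- simulate_zspectrum(sys, pulse_preset("yb_invivo"),
                          acquisition_protocol(offs))
  ora <- vapply(offs, function(o) oracle_bm_signal(sys, 56, 0.6, o),
                numeric(1))
  expect_lt(max(abs(z$signal - ora)), 0.01)
})

test_that("long-pulse simulation converges to the analytic two-pool steady state", {
  sys <- build_system(agent_preset("Eu-HPDO3A", 4), "solution")
  for (off in c(18, 5, 60)) {
    ss <- analytic_two_pool_steady_state(sys, pulse_preset("eu_solution"),
                                         off)
    zl <- simulate_zspectrum(sys, saturation_pulse(15, 30),
                             acquisition_protocol(off))
    expect_lt(abs(zl$signal - ss), 0.02)
  }
})

test_that("analytic steady state degenerates correctly", {
  # fraction 0 -> pure direct saturation; k = 0 -> water-only value
  base <- build_system(NULL, "solution")
  f0 <- spin_system(base$water,
                    list(cest_pool("s", 0, 18, 5000, 1, 0.01)))
  k0 <- spin_system(base$water,
                    list(cest_pool("s", 3.6e-5, 18, 0, 1, 0.01)))
  p <- pulse_preset("eu_solution")
  w_only <- analytic_two_pool_steady_state(
    spin_system(base$water), p, 18)
  expect_equal(analytic_two_pool_steady_state(f0, p, 18), w_only,
               tolerance = 1e-9)
  expect_equal(analytic_two_pool_steady_state(k0, p, 18), w_only,
               tolerance = 1e-9)
  # more than two pools rejected
  yb <- build_system(agent_preset("Yb-HPDO3A", 4), "solution")
  expect_error(analytic_two_pool_steady_state(yb, p, 97), "two pools")
})

test_that("simulated spectra are normalized and physically bounded", {
  set.seed(7)
  offs <- seq(-110, 110, by = 10)
  for (i in 1:5) {
    sys <- random_system()
    z <- simulate_zspectrum(sys, saturation_pulse(runif(1, 2, 25), 1),
                            acquisition_protocol(offs))
    # off-resonance: [0, 1] up to solver tolerance; on-resonance values
    # may transiently undershoot zero (coherent nutation) but stay
    # bounded by |M0|
    off_res <- abs(offs) >= 5
    expect_true(all(z$signal[off_res] > -1e-6))
    expect_true(all(z$signal < 1 + 1e-6))
    expect_true(all(abs(z$signal) <= 1 + 1e-6))
  }
})

test_that("agent-free systems have zero asymmetry", {
  offs <- seq(-110, 110, by = 5)
  for (env in c("solution", "tissue")) {
    sys <- build_system(NULL, env)
    z <- simulate_zspectrum(sys, pulse_preset("eu_solution"),
                            acquisition_protocol(offs))
    asym <- mtr_asymmetry(z, offs[offs > 0])
    expect_lt(max(abs(asym)), 1e-4)
  }
})

test_that("site asymmetry is non-decreasing in concentration", {
  asyms <- vapply(seq(0, 10, by = 2), function(conc) {
    sys <- build_system(agent_preset("Eu-HPDO3A", conc), "solution")
    z <- simulate_zspectrum(sys, pulse_preset("eu_solution"),
                            acquisition_protocol(c(-18, 18)))
    mtr_asymmetry(z, 18)
  }, numeric(1))
  expect_true(all(diff(asyms) >= -1e-9))
})

test_that("tissue MT attenuates the Eu channel far more than the Yb channel", {
  contrast <- function(agent, conc, pulse, band) {
    vapply(c("solution", "tissue"), function(env) {
      sys <- build_system(agent_preset(agent, conc), env)
      offs <- c(-rev(band$member_offsets_ppm), band$member_offsets_ppm)
      z <- simulate_zspectrum(sys, pulse, acquisition_protocol(offs))
      auc_contrast(z, band)
    }, numeric(1))
  }
  eu <- contrast("Eu-HPDO3A", 6.8, pulse_preset("eu_invivo"), eu_band())
  yb <- contrast("Yb-HPDO3A", 9.5, pulse_preset("yb_invivo"), yb_band())
  # attenuation is a reduction in both channels...
  expect_lt(eu["tissue"], eu["solution"])
  expect_lt(yb["tissue"], yb["solution"])
  # ...but the surviving fraction is much smaller at 18 ppm than 97 ppm
  expect_lt(eu["tissue"] / eu["solution"], yb["tissue"] / yb["solution"])
})
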