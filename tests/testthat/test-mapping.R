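# build a small stack with a prescribed uniform band asymmetry (%)
uniform_band_stack <- function(n = 6, band = eu_band(), asym_pct = 2,
                               s0 = 2) {
  m <- band$member_offsets_ppm
  offs <- c(-300, 0, -rev(m), m)
  vols <- array(0, dim = c(n, n, length(offs)))
  for (k in seq_along(offs)) {
    o <- offs[k]
    v <- if (abs(o) >= 100) s0 else if (o == 0) 0.05 * s0 else
      if (o < 0) 0.9 * s0 else (0.9 - asym_pct / 100) * s0
    vols[, , k] <- v
  }
  offset_stack(vols, offs)
}

test_that("uniform band asymmetry produces a uniform map", {
  st <- uniform_band_stack(asym_pct = 2)
  cm <- compute_channel_map(st, eu_band())
  expect_equal(unname(cm$values_pct), matrix(2, 6, 6), tolerance = 1e-9)
  expect_equal(cm$channel, "Eu18")
})

test_that("a zero field map leaves the channel map unchanged", {
  st <- uniform_band_stack(asym_pct = 3)
  fm <- structure(list(delta0_ppm = matrix(0, 6, 6),
                       mask = matrix(TRUE, 6, 6)),
                  class = "field_map")
  plain <- compute_channel_map(st, eu_band())
  corr <- compute_channel_map(st, eu_band(), fieldmap = fm)
  expect_equal(corr$values_pct, plain$values_pct)
})

test_that("the map is invariant under global intensity scaling", {
  st <- uniform_band_stack(asym_pct = 2.5)
  st2 <- offset_stack(st$volumes * 37.5, st$offsets_ppm)
  m1 <- compute_channel_map(st, eu_band())
  m2 <- compute_channel_map(st2, eu_band())
  expect_equal(m1$values_pct, m2$values_pct, tolerance = 1e-12)
})

test_that("missing band volumes are reported", {
  st <- uniform_band_stack()
  keep <- st$offsets_ppm != 17
  st2 <- offset_stack(st$volumes[, , keep], st$offsets_ppm[keep])
  expect_error(compute_channel_map(st2, eu_band()), "17")
  st3 <- offset_stack(st$volumes[, , abs(st$offsets_ppm) < 100],
                      st$offsets_ppm[abs(st$offsets_ppm) < 100])
  expect_error(compute_channel_map(st3, eu_band()), "reference")
})

test_that("ROI comparison reduces to the Welch formula on tiny ROIs", {
  vals <- matrix(NA_real_, 3, 3)
  vals[1, ] <- c(3.1, 2.9, 3.3)   # labeled
  vals[3, ] <- c(1.2, 0.8, 1.0)   # control
  cm <- structure(list(values_pct = vals, channel = "Eu18",
                       mask = !is.na(vals)), class = "contrast_map")
  lab <- matrix(FALSE, 3, 3); lab[1, ] <- TRUE
  ctl <- matrix(FALSE, 3, 3); ctl[3, ] <- TRUE
  rs <- roi_compare(cm, lab, ctl)

  a <- vals[1, ]; b <- vals[3, ]
  expect_equal(rs$mean_diff_pct, mean(a) - mean(b))
  expect_equal(rs$sem_pct, sqrt(var(a) / 3 + var(b) / 3))
  expect_equal(rs$p_value, t.test(a, b)$p.value)
  expect_equal(unname(rs$n_voxels), c(3, 3))
})

test_that("degenerate-variance ROIs are handled", {
  vals <- matrix(1, 4, 4); vals[3:4, ] <- 3
  cm <- structure(list(values_pct = vals, channel = "Eu18",
                       mask = matrix(TRUE, 4, 4)),
                  class = "contrast_map")
  lab <- matrix(FALSE, 4, 4); lab[3:4, ] <- TRUE
  ctl <- !lab
  rs <- roi_compare(cm, lab, ctl)
  expect_equal(rs$mean_diff_pct, 2.0)
  expect_equal(rs$p_value, 0)
  expect_error(roi_compare(cm, lab, lab), "disjoint")
  expect_error(roi_compare(cm, lab, matrix(FALSE, 4, 4)), "empty")
})

test_that("null ROIs from one noise distribution rarely reach significance", {
  set.seed(71)
  hits <- 0
  for (i in 1:100) {
    vals <- matrix(rnorm(100), 10, 10)
    cm <- structure(list(values_pct = vals, channel = "Eu18",
                         mask = matrix(TRUE, 10, 10)),
                    class = "contrast_map")
    lab <- matrix(FALSE, 10, 10); lab[1:5, ] <- TRUE
    if (roi_compare(cm, lab, !lab)$p_value < 0.05) hits <- hits + 1
  }
  expect_lte(hits, 10)
})

test_that("overlay counts supra-threshold voxels and respects thresholds", {
  zero <- structure(list(values_pct = matrix(0, 5, 5), channel = "Eu18",
                         mask = matrix(TRUE, 5, 5)),
                    class = "contrast_map")
  t2w <- matrix(0.5, 5, 5)
  sc <- threshold_overlay(list(zero), t2w, 1)
  expect_equal(unname(sc$counts), 0L)
  # background preserved where nothing is hot
  expect_equal(dim(sc$rgb), c(5, 5, 3))

  one <- zero
  one$values_pct[2, 3] <- 5
  sc1 <- threshold_overlay(list(one), t2w, 1, palette = "blue")
  expect_equal(unname(sc1$counts), 1L)
  # the hot voxel is blue-dominant
  expect_gt(sc1$rgb[2, 3, 3], sc1$rgb[2, 3, 1])

  expect_error(threshold_overlay(list(one), t2w, -1), ">= 0")

  tmp <- file.path(tempdir(), "ov.png")
  sc2 <- threshold_overlay(list(one), t2w, 1, file = tmp)
  expect_true(file.exists(tmp))
  unlink(tmp)
})

test_that("T2w lesion masking follows the 1-SD hyperintensity rule", {
  set.seed(81)
  img <- matrix(1, 8, 8)
  img[1:4, ] <- 1 + 0.02 * matrix(rnorm(32, sd = 1), 4, 8)
  img[6:8, 2:4] <- 2
  ref <- matrix(FALSE, 8, 8); ref[1:4, ] <- TRUE
  m <- lesion_mask_from_t2w(img, ref)
  expect_true(all(m[6:8, 2:4]))
  # voxels at exactly the reference mean are never flagged
  expect_false(any(m[5, ]))
  # a higher threshold excludes the reference noise entirely
  m4 <- lesion_mask_from_t2w(img, ref, n_sd = 4)
  expect_false(any(m4[1:4, ]))
  expect_true(all(m4[6:8, 2:4]))
})
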