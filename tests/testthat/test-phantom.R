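test_that("mixture planner reproduces the co-implantation arithmetic", {
  plan <- mixture_plan()
  expect_equal(unname(plan$cells_per_uL), c(160000, 40000))
  expect_equal(plan$ec_reduction_pct, 80)
  expect_equal(unname(plan$voxel_mM), c(4.5152, 1.577), tolerance = 1e-3)

  nsc_only <- mixture_plan(c(1, 0))
  expect_equal(unname(nsc_only$voxel_mM["yb"]), 0)
  expect_error(mixture_plan(c(0, 0)), "not both zero")
  expect_error(mixture_plan(cell_volume_fraction = 0), "0, 1")
  expect_equal(unname(unlabeled_plan()$voxel_mM), c(0, 0))
})

test_that("tube phantoms lay out compartments without overlap", {
  spec <- tube_phantom(list(c(4, 0), c(0, 4), c(4, 4)))
  expect_equal(sort(unique(as.vector(spec$label_map))), 0:4)
  expect_equal(nrow(spec$compartments), 4)   # agar + 3 tubes
  expect_equal(spec$compartments$eu_mM, c(0, 4, 0, 4))
  expect_equal(spec$compartments$yb_mM, c(0, 0, 4, 4))

  empty <- tube_phantom(list())
  expect_equal(sort(unique(as.vector(empty$label_map))), 0:1)

  expect_error(tube_phantom(list(c(1, 0), c(0, 1)), tube_radius = 30),
               "overlap")
  expect_error(tube_phantom(list(c(-1, 0))), ">= 0")
})

test_that("lesion phantoms conserve agent amounts across patterns", {
  plan <- mixture_plan()
  hom <- lesion_phantom(plan, "homogeneous", seed = 5)
  imp <- hom$masks$implant
  eu_map <- matrix(0, 64, 64)
  for (i in seq_len(nrow(hom$compartments))) {
    eu_map[hom$label_map == hom$compartments$label[i]] <-
      hom$compartments$eu_mM[i]
  }
  expect_true(all(eu_map[imp] == plan$voxel_mM["eu"]))

  pat <- lesion_phantom(plan, "patched", seed = 5)
  for (agent in c("eu_mM", "yb_mM")) {
    conc <- matrix(0, 64, 64)
    for (i in seq_len(nrow(pat$compartments))) {
      conc[pat$label_map == pat$compartments$label[i]] <-
        pat$compartments[[agent]][i]
    }
    target <- plan$voxel_mM[[sub("_mM", "", agent)]]
    expect_equal(mean(conc[imp]), target, tolerance = 1e-9)
    # patched pattern is genuinely heterogeneous
    expect_gt(stats::sd(conc[imp]), 0)
  }

  ctrl <- lesion_phantom(unlabeled_plan(), "homogeneous", seed = 5)
  expect_true(all(ctrl$compartments$eu_mM == 0))
  expect_true(all(ctrl$compartments$yb_mM == 0))
})

test_that("phantom construction is deterministic under the seed", {
  a <- lesion_phantom(mixture_plan(), "patched", seed = 9)
  b <- lesion_phantom(mixture_plan(), "patched", seed = 9)
  expect_identical(a, b)
  c <- lesion_phantom(mixture_plan(), "patched", seed = 10)
  expect_false(identical(a$label_map, c$label_map))
})

test_that("phantom_spec enforces its invariants", {
  lab <- matrix(1L, 4, 4)
  comp <- paracest:::compartment_row(1, "x")
  expect_error(phantom_spec(lab, comp), "seed")
  expect_error(phantom_spec(lab, comp, b0_field = matrix(1, 4, 4),
                            seed = 1), "0.3")
  comp_bad <- comp; comp_bad$eu_mM <- -1
  expect_error(phantom_spec(lab, comp_bad, seed = 1), ">= 0")
  lab2 <- lab; lab2[1, 1] <- 7L
  expect_error(phantom_spec(lab2, comp, seed = 1), "missing")
})

test_that("simulated studies are deterministic and blank phantoms are silent", {
  spec <- tube_phantom(list(c(4, 0)), n = 24, tube_radius = 5,
                       noise_sigma = 0.01)
  s1 <- simulate_study(spec, seed = 2)
  s2 <- simulate_study(spec, seed = 2)
  expect_identical(s1$eu_stack$volumes, s2$eu_stack$volumes)
  expect_identical(s1$wassr_stack$volumes, s2$wassr_stack$volumes)
  s3 <- simulate_study(spec, seed = 3)
  expect_false(identical(s1$eu_stack$volumes, s3$eu_stack$volumes))

  blank <- tube_phantom(list(), n = 24, noise_sigma = 0)
  sb <- simulate_study(blank, seed = 1)
  inside <- blank$label_map > 0
  for (m in list(compute_channel_map(sb$eu_stack, eu_band(),
                                     mask = inside),
                 compute_channel_map(sb$yb_stack, yb_band(),
                                     mask = inside))) {
    expect_lt(max(abs(m$values_pct[inside])), 1e-6)
  }
})

test_that("pipeline recovers the asymmetry simulated for a tube compartment", {
  spec <- tube_phantom(list(c(4, 0)), n = 24, tube_radius = 5,
                       noise_sigma = 0)
  study <- simulate_study(spec, seed = 2)
  cm <- compute_channel_map(study$eu_stack, eu_band(),
                            mask = spec$label_map > 0)
  tube_val <- mean(cm$values_pct[study$truth$masks$tube1])

  # direct-spectrum oracle for the same compartment
  sys <- build_system(agent_preset("Eu-HPDO3A", 4), "solution",
                      overrides = list(water_T1 = 3, water_T2 = 1.5))
  z <- simulate_zspectrum(sys, pulse_preset("eu_invivo"),
                          acquisition_protocol(c(-20:-16, 16:20)))
  direct <- auc_contrast(z, eu_band())
  expect_lt(abs(tube_val - direct) / direct, 0.1)
})

test_that("T2w rendering darkens agent-bearing voxels monotonically", {
  plan <- mixture_plan()
  labeled <- lesion_phantom(plan, "homogeneous", seed = 4)
  ctrl <- lesion_phantom(unlabeled_plan(), "homogeneous", seed = 4)
  imp <- labeled$masks$implant

  img_l <- t2w_render(labeled)
  img_c <- t2w_render(ctrl)
  expect_true(all(img_l[imp] < img_c[imp]))
  # identical where no agent differs
  expect_equal(img_l[!imp], img_c[!imp])
  # stronger relaxivity -> darker implant
  img_l2 <- t2w_render(labeled, r2_agent = 2)
  expect_true(all(img_l2[imp] < img_l[imp]))
  expect_error(t2w_render(labeled, r2_agent = -1), "negative")

  # agent-free phantom renders baseline tissue contrast only
  expect_equal(t2w_render(ctrl), img_c)
  # lesion cavity is hyperintense relative to healthy tissue
  expect_gt(mean(img_c[ctrl$masks$lesion]),
            mean(img_c[ctrl$masks$brain & !ctrl$masks$lesion]))
})
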