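test_that("phantom masks satisfy the tissue-nesting invariants", {
  m <- make_phantom_masks(c(32, 32, 16), 3)
  expect_equal(sum(m$gm & m$wm), 0)
  expect_true(all(m$wb[m$gm]))
  expect_true(all(m$wb[m$wm]))
  expect_gt(sum(m$gm), sum(m$wm))
  # deterministic
  expect_identical(m, make_phantom_masks(c(32, 32, 16), 3))
  # brain volume = voxel count x voxel volume
  expect_equal(brain_volume_from_masks(m), sum(m$wb) * 27 / 1000)
  expect_error(make_phantom_masks(c(4, 32, 16), 3), "grid_dims")
})

test_that("EtCO2 trace steps at the gas switch with exact per-breath maxima", {
  p <- ground_truth_params(etco2_baseline = 40, etco2_step = 10, seed = 1)
  tr <- simulate_etco2_trace(p, duration = 600, sample_rate = 10,
                             breath_period = 4, gas_switch_time = 240,
                             start_time = 0, noise_sd = 0)
  et <- extract_etco2(tr)
  pre <- et$etco2[et$breath_time < 230]
  post <- et$etco2[et$breath_time > 280]
  expect_true(all(abs(pre - 40) < 1e-6))
  expect_true(all(abs(post - 50) < 1e-6))
  # transition completes within 30 s of the switch
  trans <- et$etco2[et$breath_time >= 240 + 30]
  expect_true(all(abs(trans - 50) < 1e-6))

  # zero step: constant end-tidal values
  p0 <- ground_truth_params(etco2_step = 0, seed = 1)
  tr0 <- simulate_etco2_trace(p0, duration = 400, start_time = 0,
                              gas_switch_time = 240)
  et0 <- extract_etco2(tr0)
  expect_true(all(abs(et0$etco2 - 40) < 1e-6))

  # seeded determinism
  trn1 <- simulate_etco2_trace(p, duration = 400, start_time = 0,
                               gas_switch_time = 240, noise_sd = 0.5)
  trn2 <- simulate_etco2_trace(p, duration = 400, start_time = 0,
                               gas_switch_time = 240, noise_sd = 0.5)
  expect_identical(trn1$co2, trn2$co2)

  expect_error(simulate_etco2_trace(p, duration = 100, start_time = 0,
                                    gas_switch_time = 240), "gas switch")
})

test_that("dual-echo generator obeys its construction rules", {
  masks <- make_phantom_masks(small_grid)
  tl <- acquisition_timeline()

  # labeling efficiency scales the hypercapnic difference signal by
  # exactly its value (compare two noiseless series voxel-wise)
  p1 <- ground_truth_params(noise_sd_asl = 0, noise_sd_bold = 0, seed = 3)
  p9 <- ground_truth_params(noise_sd_asl = 0, noise_sd_bold = 0, seed = 3,
                            labeling_efficiency_hc = 0.9)
  d1 <- simulate_dual_echo(p1, masks, tl)
  d9 <- simulate_dual_echo(p9, masks, tl)
  # label volumes in the hypercapnic plateau: M0 - dM vs M0 - 0.9 dM
  lab_hc <- which(volume_parity(tl) == "label" & volume_times(tl) >= 360)
  vox <- which(masks$gm)[1]
  ai <- arrayInd(vox, dim(masks$gm))
  m0 <- d1$echo1[ai[1], ai[2], ai[3], 1]  # control volume = M0
  dm1 <- m0 - d1$echo1[ai[1], ai[2], ai[3], lab_hc[1]]
  dm9 <- m0 - d9$echo1[ai[1], ai[2], ai[3], lab_hc[1]]
  expect_equal(dm9 / dm1, 0.9, tolerance = 1e-10)

  # drift: noiseless control time course strictly increasing
  pd <- ground_truth_params(noise_sd_asl = 0, noise_sd_bold = 0,
                            drift_slope = 0.05, seed = 3)
  dd <- simulate_dual_echo(pd, masks, tl)
  ctrl <- which(volume_parity(tl) == "control")
  tc <- dd$echo1[ai[1], ai[2], ai[3], ctrl]
  expect_true(all(diff(tc) > 0))

  # grid mismatch rejected
  bad <- make_phantom_masks(c(8, 8, 8))
  expect_error(roi_time_course(surround_subtract(d1$echo1), bad$wb), "grid")
})

test_that("PC pair flux matches the direct summation oracle", {
  p <- ground_truth_params(basal_flux_sss = 300, pc_cvr_true = 6.15,
                           etco2_step = 10, seed = 5)
  pc <- simulate_pc_pair(p)
  # direct summation over the true vessel voxels
  flux_ra <- sum(pc$ra$velocity[pc$ra$vessel_mask]) * pc$ra$voxel_area * 60
  expect_equal(flux_ra, 300, tolerance = 1e-8)
  flux_hc <- sum(pc$hc$velocity[pc$hc$vessel_mask]) * pc$hc$voxel_area * 60
  expect_equal(flux_hc, 300 * (1 + 6.15 * 10 / 100), tolerance = 1e-8)

  # parabolic profile: ROI mean velocity ~ half the peak (discretized)
  v <- pc$ra$velocity[pc$ra$vessel_mask]
  expect_equal(mean(v) / max(v), 0.5, tolerance = 0.1)

  # zero reactivity: HC flux = RA flux
  p0 <- ground_truth_params(basal_flux_sss = 300, pc_cvr_true = 0, seed = 5)
  pc0 <- simulate_pc_pair(p0)
  expect_equal(sum(pc0$hc$velocity[pc0$hc$vessel_mask]),
               sum(pc0$ra$velocity[pc0$ra$vessel_mask]), tolerance = 1e-8)

  # flux incompatible with the velocity-encoding cap rejected
  phuge <- ground_truth_params(basal_flux_sss = 1e5, seed = 5)
  expect_error(simulate_pc_pair(phuge), "venc")
})

test_that("cohort generator reproduces the group design", {
  co <- make_cohort(n_young = 32, n_old = 17, seed = 9)
  expect_equal(nrow(co$truth), 49)
  expect_equal(sum(co$truth$group == "young"), 32)
  expect_equal(length(co$params), 49)
  expect_true(all(c("sex", "site", "pc_cvr_true", "basal_cbf") %in%
                    names(co$truth)))

  # same seed: identical cohort
  co2 <- make_cohort(n_young = 32, n_old = 17, seed = 9)
  expect_identical(co$truth, co2$truth)

  # zero between-subject sd: identical params within group
  eff0 <- cohort_effects()
  eff0$young_sd <- 0
  eff0$old_sd <- 0
  cz <- make_cohort(4, 4, effects = eff0, seed = 1)
  young <- cz$truth[cz$truth$group == "young", ]
  expect_true(all(young$pc_cvr_true == young$pc_cvr_true[1]))

  effneg <- cohort_effects()
  effneg$young_sd[1] <- -1
  expect_error(make_cohort(4, 4, effects = effneg), "sd")
  expect_error(make_cohort(1, 4), "2 subjects")
})
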