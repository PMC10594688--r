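# Resampling and mutual-information affine registration. Registration
# tests use a reduced sample count: recovery tolerances are still met and
# each run stays in the tens of seconds.

fast_cfg <- registration_config(n_samples = 8000)

test_that("resampling through the identity reproduces the input", {
  ph <- exact_phantom()
  ident <- affine_transform()
  out <- resample(ph$insp, ident, ph$insp)
  expect_equal(out$data, ph$insp$data, tolerance = 1e-12)
  # nearest is exactly idempotent under the identity
  out_nn <- resample(ph$insp, ident, ph$insp, interpolation = "nearest")
  expect_identical(out_nn$data, ph$insp$data)
  m <- resample(ph$insp_mask, ident, ph$insp)
  expect_identical(m$data, ph$insp_mask$data)
})

test_that("masks stay binary under arbitrary transforms", {
  ph <- exact_phantom()
  t <- affine_transform(diag(3) * 1.07, c(3.3, -2.1, 0.7),
                        c(48, 48, 38))
  m <- resample(ph$insp_mask, t, ph$insp)
  expect_true(all(m$data %in% c(TRUE, FALSE)))
  expect_true(is.logical(m$data))
})

test_that("a one-voxel translation moves a delta image exactly one voxel", {
  a <- array(-1000, c(12, 12, 12))
  a[6, 6, 6] <- 500
  v <- ct_volume(a)
  t <- affine_transform(translation = c(1, 0, 0))  # 1 mm = 1 voxel
  out <- resample(v, t, v, interpolation = "nearest")
  expect_equal(which(out$data == 500),
               which(array(seq_len(12^3), c(12, 12, 12)) ==
                       7 + 5 * 12 + 5 * 144))
  expect_equal(out$data[7, 6, 6], 500)
  expect_equal(sum(out$data == 500), 1)
})

test_that("self-registration returns a transform near the identity", {
  ph <- make_paired_phantom(phantom_spec(seed = 11))
  tr <- register_affine(ph$insp, ph$insp, ph$insp_mask, ph$insp_mask,
                        fast_cfg)
  # within 0.1 voxel (0.25 mm) mean displacement over the mask
  expect_lt(airtrap:::mean_displacement(tr, ph$insp_mask), 0.25)
  expect_gte(attr(tr, "mi_final"), attr(tr, "mi_initial"))
})

test_that("a known voxel translation is recovered within half a voxel", {
  sp <- phantom_spec(seed = 21)
  sp$motion <- affine_transform(translation = c(4, -3, 2) * sp$spacing)
  ph <- make_paired_phantom(sp)
  tr <- register_affine(ph$insp, ph$exp, ph$insp_mask, ph$exp_mask,
                        fast_cfg)
  expect_lt(max(abs(tr$matrix - diag(3))), 0.02)
  expect_true(all(abs(tr$translation - c(4, -3, 2) * sp$spacing) <
                    0.5 * sp$spacing))
})

test_that("a known uniform scaling is recovered within 2%", {
  # expiratory phantom scaled by 1.15 toward inspiration
  sp <- phantom_spec(seed = 22)
  sp$motion <- exhale_motion(sp, scale = 1 / 1.15, shift = c(0, 0, 0))
  ph <- make_paired_phantom(sp)
  tr <- register_affine(ph$insp, ph$exp, ph$insp_mask, ph$exp_mask)
  expect_lt(max(abs(tr$matrix - diag(3) * 1.15)), 0.02 * 1.15)
})

test_that("final mutual information does not fall below the initial value", {
  sp <- phantom_spec(seed = 23)
  sp$motion <- exhale_motion(sp)
  ph <- make_paired_phantom(sp)
  tr <- register_affine(ph$insp, ph$exp, ph$insp_mask, ph$exp_mask,
                        fast_cfg)
  expect_gte(attr(tr, "mi_final"), attr(tr, "mi_initial"))
})

test_that("build_paired_study aligns a known-motion pair", {
  sp <- phantom_spec(seed = 24)
  sp$motion <- exhale_motion(sp)
  ph <- make_paired_phantom(sp)
  ps <- build_paired_study(ph$insp, ph$insp_mask, ph$exp, ph$exp_mask,
                           fast_cfg)
  expect_true(check_geometry(ps$exp_in_insp, ph$insp))
  expect_gte(dice(ps$joint_mask$data, ph$insp_mask$data), 0.95)
  # voxel-wise agreement: median |exp-in-insp - (insp + class delta)|
  # cannot be checked directly, but the registered expiratory HU inside
  # the joint mask must match the phantom's inspiratory-frame expiratory
  # field; with identity motion they are equal, with known motion the
  # registered error stays within interpolation + noise scale
  ideal <- ph$insp$data + 150  # normal tissue dominates (75%)
  err <- abs(ps$exp_in_insp$data - ideal)[ps$joint_mask$data]
  expect_lt(median(err), 35)   # most voxels are normal-class
})

test_that("identity-motion pairs register to near-identity alignment", {
  ph <- make_paired_phantom(phantom_spec(seed = 25))
  ps <- build_paired_study(ph$insp, ph$insp_mask, ph$exp, ph$exp_mask,
                           fast_cfg)
  expect_gte(dice(ps$joint_mask$data, ph$insp_mask$data), 0.99)
  expect_lt(airtrap:::mean_displacement(ps$transform, ph$insp_mask), 1.0)
})

test_that("direction = exp_frame swaps the fixed and moving roles", {
  ph <- exact_phantom()
  cfg <- registration_config(direction = "exp_frame")
  ps <- build_paired_study(ph$insp, ph$insp_mask, ph$exp, ph$exp_mask,
                           cfg, transform = affine_transform())
  expect_true(!is.null(ps$insp_in_exp))
  expect_true(check_geometry(ps$insp_in_exp, ph$exp))
  pf <- airtrap:::paired_fields(ps)
  expect_identical(pf$exp, ph$exp$data)
})
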