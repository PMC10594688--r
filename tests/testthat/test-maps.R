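# Voxel-wise PRM and ATI maps.

test_that("PRM assigns the four threshold combinations correctly", {
  insp <- array(c(-970, -900, -900, -970), c(4, 1, 1))
  exp <- array(c(-900, -900, -700, -700), c(4, 1, 1))
  ps <- tiny_paired_study(insp, exp)
  res <- prm_classify(ps)
  cls <- res$map$data[, 1, 1]
  expect_equal(unname(cls),
               unname(c(airtrap:::PRM_LEGEND["emph"],
                        airtrap:::PRM_LEGEND["fsad"],
                        airtrap:::PRM_LEGEND["normal"],
                        airtrap:::PRM_LEGEND["unclassified"])))
  expect_equal(sum(res$fractions), 1)
})

test_that("threshold-equal voxels follow the >= convention", {
  ps <- tiny_paired_study(array(-950, c(2, 1, 1)), array(-856, c(2, 1, 1)))
  res <- prm_classify(ps)
  expect_true(all(res$map$data == airtrap:::PRM_LEGEND["normal"]))
})

test_that("noise-free phantom PRM fractions are exact", {
  ph <- exact_phantom()
  ps <- build_paired_study(ph$insp, ph$insp_mask, ph$exp, ph$exp_mask,
                           transform = affine_transform())
  res <- prm_classify(ps)
  expect_equal(unname(res$fractions[c("emph", "fsad", "normal",
                                      "unclassified")]),
               unname(c(ph$truth$prm["emph"], ph$truth$prm["fsad"],
                        ph$truth$prm["normal"],
                        ph$truth$prm["unclassified"])))
})

test_that("PRM matches a brute-force voxel loop on noisy data", {
  withr::local_seed(31)
  ph <- make_paired_phantom(phantom_spec(shape = c(24, 24, 16),
                                         noise_sd = 30, seed = 31))
  ps <- build_paired_study(ph$insp, ph$insp_mask, ph$exp, ph$exp_mask,
                           transform = affine_transform())
  res <- prm_classify(ps)
  pf <- airtrap:::paired_fields(ps)
  bf <- brute_force_prm(pf$insp, pf$exp, pf$joint)
  expect_equal(unname(res$fractions), unname(bf))
})

test_that("lowering the expiratory threshold never raises Emph + Fsad", {
  withr::local_seed(32)
  ph <- make_paired_phantom(phantom_spec(shape = c(24, 24, 16),
                                         noise_sd = 25, seed = 32))
  ps <- build_paired_study(ph$insp, ph$insp_mask, ph$exp, ph$exp_mask,
                           transform = affine_transform())
  thr <- seq(-900, -800, by = 20)
  at_total <- vapply(thr, function(t) {
    fr <- prm_classify(ps, prm_thresholds(at_exp = t))$fractions
    fr[["emph"]] + fr[["fsad"]]
  }, 0)
  expect_true(all(diff(at_total) >= 0))
})

test_that("ATI applies the signed 60 HU rise rule in the eligible band", {
  insp <- array(c(-900, -900, -960, -700), c(4, 1, 1))
  exp <- array(c(-860, -800, -950, -600), c(4, 1, 1))
  ps <- tiny_paired_study(insp, exp)
  res <- ati_map(ps)
  # voxel 1: rise 40 -> trapped; voxel 2: rise 100 -> not; voxel 3:
  # excluded (emphysema); voxel 4: outside the band
  expect_equal(res$ati, 0.5)
  expect_equal(res$emph, 0.25)
  expect_equal(res$map$data[, 1, 1],
               unname(c(airtrap:::ATI_LEGEND["air_trapping"],
                        airtrap:::ATI_LEGEND["eligible_no_at"],
                        airtrap:::ATI_LEGEND["emph"],
                        airtrap:::ATI_LEGEND["other"])))
  # paradoxical density drops count as trapped (signed difference)
  ps2 <- tiny_paired_study(array(-900, c(2, 1, 1)),
                           array(-950, c(2, 1, 1)))
  expect_equal(ati_map(ps2)$ati, 1)
})

test_that("planted trapped fraction of the eligible band is recovered", {
  ph <- exact_phantom()
  ps <- build_paired_study(ph$insp, ph$insp_mask, ph$exp, ph$exp_mask,
                           transform = affine_transform())
  res <- ati_map(ps)
  # eligible = normal + fsad; trapped = fsad (rise 20 < 60)
  expect_equal(res$ati, ph$truth$ati)
  expect_equal(res$ati, 0.20 / 0.95, tolerance = 1e-3)
})

test_that("ATI matches a brute-force voxel loop on noisy data", {
  ph <- make_paired_phantom(phantom_spec(shape = c(24, 24, 16),
                                         noise_sd = 30, seed = 33))
  ps <- build_paired_study(ph$insp, ph$insp_mask, ph$exp, ph$exp_mask,
                           transform = affine_transform())
  pf <- airtrap:::paired_fields(ps)
  expect_equal(ati_map(ps)$ati, brute_force_ati(pf$insp, pf$exp, pf$joint))
})

test_that("ati is invariant to small shared HU shifts inside the band", {
  # interior-band phantom: means 10+ HU away from every threshold edge
  cl <- phantom_classes(c("normal", "fsad"), c(0.7, 0.3),
                        c(-890, -905), c(150, 20))
  ph <- exact_phantom(classes = cl)
  base <- ati_map(build_paired_study(
    ph$insp, ph$insp_mask, ph$exp, ph$exp_mask,
    transform = affine_transform()))$ati
  for (shift in c(-5, 5)) {
    insp2 <- ct_volume(ph$insp$data + shift, ph$insp$spacing)
    exp2 <- ct_volume(ph$exp$data + shift, ph$exp$spacing)
    ps2 <- build_paired_study(insp2, lung_mask(ph$insp_mask$data, insp2),
                              exp2, lung_mask(ph$exp_mask$data, exp2),
                              transform = affine_transform())
    expect_equal(ati_map(ps2)$ati, base)
  }
})

test_that("overlays render class colours and validate slice bounds", {
  ph <- exact_phantom(shape = c(24, 24, 16))
  ps <- build_paired_study(ph$insp, ph$insp_mask, ph$exp, ph$exp_mask,
                           transform = affine_transform())
  res <- prm_classify(ps)
  expect_error(render_overlay(ps, res$map, 3, 99), "range")

  # an all-normal synthetic map shows exactly one overlay colour
  lab <- array(0L, dim(ph$insp$data))
  lab[ph$insp_mask$data] <- airtrap:::PRM_LEGEND[["normal"]]
  m <- label_map(lab, ph$insp, airtrap:::PRM_LEGEND)
  pal <- c(emph = "#FF0000", fsad = "#FFFF00", normal = "#00FF00",
           unclassified = "#0000FF")
  rgb <- render_overlay(ps, m, 3, 8, palette = pal, alpha = 1)
  in_map <- t(lab[, , 8])[rev(seq_len(24)), ] > 0
  greens <- rgb[, , 2][in_map] == 1 & rgb[, , 1][in_map] == 0
  expect_true(all(greens))
  f <- withr::local_tempfile(fileext = ".png")
  render_overlay(ps, m, 3, 8, palette = pal, path = f)
  expect_true(file.exists(f) && file.size(f) > 0)
})

test_that("a planted trapped sphere appears at the right overlay location", {
  a <- array(-890, c(32, 32, 32))
  ctr <- c(16, 16, 16)
  idx <- arrayInd(seq_len(32^3), c(32, 32, 32))
  sph <- sqrt(rowSums(sweep(idx, 2, ctr)^2)) <= 5
  exp <- array(-740, c(32, 32, 32))     # normal rise everywhere
  exp[sph] <- -880                      # trapped sphere: rise 10
  ps <- tiny_paired_study(a, exp)
  res <- ati_map(ps)
  rgb <- render_overlay(ps, res$map, 3, 16,
                        palette = c(air_trapping = "#FF0000",
                                    eligible_no_at = "#00FF0000",
                                    emph = "#0000FF",
                                    other = "#00000000"))
  red <- rgb[, , 1] > 0.5 & rgb[, , 2] < 0.4
  cm <- colMeans(which(red, arr.ind = TRUE))
  # display flips rows; centre must map to the sphere centre within 1 px
  expect_lt(abs(cm[["col"]] - 16), 1)
  expect_lt(abs((33 - cm[["row"]]) - 16), 1)
})
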