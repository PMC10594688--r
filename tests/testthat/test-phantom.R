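# Phantom generator, truth oracle, cohort simulator.

test_that("phantom generation is deterministic given the seed", {
  a <- make_paired_phantom(phantom_spec(shape = c(24, 24, 16), seed = 4))
  b <- make_paired_phantom(phantom_spec(shape = c(24, 24, 16), seed = 4))
  expect_identical(a$insp$data, b$insp$data)
  expect_identical(a$exp$data, b$exp$data)
  c <- make_paired_phantom(phantom_spec(shape = c(24, 24, 16), seed = 5))
  expect_false(identical(a$insp$data, c$insp$data))
})

test_that("planted class fractions are exact voxel counts", {
  ph <- exact_phantom()
  tr <- ph$truth
  expect_equal(sum(tr$class_counts), sum(ph$insp_mask$data))
  expect_equal(unname(tr$fractions),
               unname(tr$class_counts / sum(tr$class_counts)))
  expect_lt(max(abs(tr$prm[c("emph", "fsad", "normal")] -
                      c(0.05, 0.20, 0.75))), 1 / sum(tr$class_counts))
  expect_equal(tr$ati, tr$prm[["fsad"]] /
                 (tr$prm[["fsad"]] + tr$prm[["normal"]]))
})

test_that("zero-noise normal-only phantom yields the design E/I exactly", {
  ph <- exact_phantom(classes = phantom_classes("normal", 1, -880, 150))
  expect_equal(ph$truth$ei_ratio, -730 / -880)
  expect_equal(mla(ph$exp, ph$exp_mask) / mla(ph$insp, ph$insp_mask),
               ph$truth$ei_ratio, tolerance = 1e-12)
})

test_that("class HU assignments respect their defining bands", {
  cl <- phantom_classes()
  normal <- cl[cl$name == "normal", ]
  fsad <- cl[cl$name == "fsad", ]
  emph <- cl[cl$name == "emph", ]
  expect_true(normal$insp_mean > -950 && normal$insp_mean < -856)
  expect_true(fsad$insp_mean > -950 && fsad$insp_mean < -856)
  expect_lt(fsad$exp_delta, 60)
  expect_gte(normal$exp_delta, 140)
  expect_lt(emph$insp_mean, -950)
  expect_lt(emph$insp_mean + emph$exp_delta, -856)
  expect_equal(sum(cl$fraction), 1)
})

test_that("known motion changes the expiratory frame as prescribed", {
  sp <- phantom_spec(seed = 6)
  sp$motion <- exhale_motion(sp, scale = 0.88)
  ph <- make_paired_phantom(sp)
  # expiratory lung volume should be ~0.88^3 of inspiratory
  expect_equal(lung_volume(ph$exp_mask) / lung_volume(ph$insp_mask),
               0.88^3, tolerance = 0.02)
  expect_equal(ph$truth$vdr, 100 * (1 - lung_volume(ph$exp_mask) /
                                      lung_volume(ph$insp_mask)))
})

test_that("cohort simulation is deterministic and respects domains", {
  co <- simulate_cohort(cohort_spec(seed = 12))
  co2 <- simulate_cohort(cohort_spec(seed = 12))
  expect_identical(co, co2)
  expect_equal(nrow(co), 73)
  expect_equal(sum(co$group == "case"), 46)
  for (v in c("prm_fsad", "prm_emph", "laa_exp_856", "ati"))
    expect_true(all(co[[v]] >= 0 & co[[v]] <= 1))
  expect_true(all(co$smoking[co$group == "control"] == 0))
  expect_false(any(duplicated(co$subject_id)))
})

test_that("uncorrelated equal-mean groups give near-zero mean correlation", {
  spec0 <- cohort_spec(
    mean_case = c(laa_exp_856 = 0.25, fev1_fvc = 85),
    mean_control = c(laa_exp_856 = 0.25, fev1_fvc = 85),
    sd_case = c(laa_exp_856 = 0.08, fev1_fvc = 10),
    sd_control = c(laa_exp_856 = 0.08, fev1_fvc = 10),
    correlation = diag(2), smoking_rate_case = 0)
  rs <- vapply(1:1000, function(s) {
    spec0$seed <- s
    co <- simulate_cohort(spec0)
    cor(co$laa_exp_856, co$fev1_fvc)
  }, 0)
  expect_lt(abs(mean(rs)), 0.01)
})

test_that("simulator moments converge to the prescribed ones at large n", {
  spec <- cohort_spec(
    n_case = 10000, n_control = 2,
    mean_case = c(ati = 0.35, fev1_fvc = 80),
    mean_control = c(ati = 0.24, fev1_fvc = 88),
    sd_case = c(ati = 0.1, fev1_fvc = 11),
    sd_control = c(ati = 0.05, fev1_fvc = 12),
    correlation = matrix(c(1, -0.6, -0.6, 1), 2), seed = 99)
  co <- simulate_cohort(spec)
  cs <- co[co$group == "case", ]
  expect_equal(mean(cs$ati), 0.35, tolerance = 0.005)
  expect_equal(sd(cs$fev1_fvc), 11, tolerance = 0.3)
  expect_equal(cor(cs$ati, cs$fev1_fvc), -0.6, tolerance = 0.03)
})

test_that("invalid cohort specifications are rejected", {
  expect_error(cohort_spec(correlation = matrix(c(1, 2, 2, 1), 2),
                           mean_case = c(a = 1, b = 2),
                           mean_control = c(a = 1, b = 2),
                           sd_case = c(a = 1, b = 1),
                           sd_control = c(a = 1, b = 1)),
               "positive semi-definite")
  expect_error(phantom_classes(fraction = c(0.5, 0.4, 0.2)), "sum to 1")
})
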