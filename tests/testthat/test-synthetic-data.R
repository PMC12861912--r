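test_that("phantom generation is reproducible and validates geometry", {
  spec <- phantom_spec(shape = c(16, 16), center = c(8, 8), axes = c(4, 4),
                       truth = compartment_params(0.7, 0.1, 0.2, S0 = 100),
                       sigma = 2)
  a <- generate_phantom(spec, seed = 3)
  b <- generate_phantom(spec, seed = 3)
  expect_identical(a$stack, b$stack)
  expect_gt(sum(a$roi_mask), 0)
  expect_error(phantom_spec(shape = c(10, 10), center = c(9, 5), axes = c(4, 4),
                            truth = compartment_params(1, 0, 0)),
               class = "rsilung_invalid_argument")
})

test_that("noiseless phantoms round-trip through the fitting chain", {
  spec <- phantom_spec(shape = c(16, 16), center = c(8, 8), axes = c(4, 4),
                       truth = compartment_params(0.7, 0.1, 0.2, S0 = 100))
  ph <- generate_phantom(spec)
  maps <- fit_parameter_maps(ph$stack, ph$schedule)
  lesion <- ph$roi_mask
  expect_true(all(abs(maps$f1$values[lesion] - 0.7) < 1e-7))
  expect_true(all(abs(maps$f2$values[lesion] - 0.1) < 1e-7))
  # background is free water
  expect_true(all(abs(maps$f3$values[!lesion] - 1) < 1e-7))
})

test_that("a linear f1 ramp is recovered with the correct ROI mean", {
  spec <- phantom_spec(shape = c(41, 21), center = c(21, 11), axes = c(18, 8),
                       truth = compartment_params(0.6, 0.2, 0.2, S0 = 100),
                       truth_end = compartment_params(0.9, 0.05, 0.05, S0 = 100))
  ph <- generate_phantom(spec)
  maps <- fit_parameter_maps(ph$stack, ph$schedule, mask = ph$roi_mask)
  sm <- summarize_roi(maps, ph$roi_mask)
  # the ellipse is symmetric about mid-ramp, so the mean sits at 0.75
  expect_equal(sm$f1, 0.75, tolerance = 0.01)
})

test_that("cohort generation produces the requested groups, reproducibly", {
  cohort <- generate_cohort(30, 67, seed = 1)
  expect_equal(nrow(cohort), 97)
  expect_equal(sum(cohort$subtype == "SCC"), 30)
  expect_equal(sum(cohort$subtype == "AC"), 67)
  expect_identical(cohort, generate_cohort(30, 67, seed = 1))
  expect_error(generate_cohort(1, 67), class = "rsilung_invalid_argument")
})

test_that("every generated record satisfies the patient invariants", {
  for (seed in 1:100) {
    co <- generate_cohort(4, 4, seed = seed)
    expect_true(all(co$subtype %in% c("SCC", "AC")))
    expect_true(all(co$diameter > 0))
    expect_true(all(co$suvmax > 0))
    expect_true(all(co$adc > 0))
    expect_true(all(co$f1 >= 0 & co$f1 <= 1))
    expect_true(all(co$f2 >= 0 & co$f3 >= 0))
    expect_true(all(abs(co$f1 + co$f2 + co$f3 - 1) < 1e-12))
  }
})

test_that("group means of f1 converge to the published group means", {
  co <- generate_cohort(10000, 10000, seed = 2)
  expect_lt(abs(mean(co$f1[co$subtype == "SCC"]) - 0.6711), 0.005)
  expect_lt(abs(mean(co$f1[co$subtype == "AC"]) - 0.8627), 0.004)
  # moment matching holds for the sds too
  expect_lt(abs(sd(co$f1[co$subtype == "SCC"]) - 0.1727), 0.005)
  expect_lt(abs(sd(co$adc[co$subtype == "AC"]) - 0.25e-3), 0.01e-3)
})

test_that("sample medians track the generators' closed-form medians", {
  co <- generate_cohort(20000, 20000, seed = 3)
  spec <- default_cohort_spec()
  for (g in c("SCC", "AC")) {
    s <- spec[[g]]
    sub <- co[co$subtype == g, ]
    # log-normal medians are the published medians by construction
    expect_lt(abs(median(sub$diameter) / s$diameter$median - 1), 0.02)
    expect_lt(abs(median(sub$suvmax) / s$suvmax$median - 1), 0.02)
    # truncated normal medians from the closed-form quantile
    tn_f1 <- rsilung:::tnorm_match(s$f1$mean, s$f1$sd, 0, 1)
    expect_lt(abs(median(sub$f1) / rsilung:::tnorm_median(tn_f1) - 1), 0.02)
    tn_adc <- rsilung:::tnorm_match(s$adc$mean, s$adc$sd, 0, Inf)
    expect_lt(abs(median(sub$adc) / rsilung:::tnorm_median(tn_adc) - 1), 0.02)
    expect_lt(abs(median(sub$age) / s$age$mean - 1), 0.02)
  }
  # group ordering of the hindered/free fractions matches the source data
  expect_gt(median(co$f2[co$subtype == "SCC"]), median(co$f2[co$subtype == "AC"]))
  expect_gt(median(co$f3[co$subtype == "SCC"]), median(co$f3[co$subtype == "AC"]))
})

test_that("image mode agrees exactly with ground truth when noise-free", {
  co_img <- generate_cohort(3, 3, seed = 9, mode = "image", snr = Inf)
  co_sum <- generate_cohort(3, 3, seed = 9, mode = "summary")
  # the fraction draws are identical; image mode re-derives them by fitting
  expect_equal(co_img$f1, co_sum$f1, tolerance = 1e-8)
  expect_equal(co_img$f2, co_sum$f2, tolerance = 1e-8)
  expect_equal(co_img$f3, co_sum$f3, tolerance = 1e-8)
  # image-mode ADC comes from the signal, not the ADC generator
  expect_false(isTRUE(all.equal(co_img$adc, co_sum$adc)))
  expect_true(all(co_img$adc > 1e-3 & co_img$adc < 3e-3))
})

test_that("phantom-backed cohorts are deterministic and drop no one at sigma 0", {
  truths <- list(compartment_params(0.7, 0.1, 0.2, S0 = 100),
                 compartment_params(0.9, 0.05, 0.05, S0 = 100),
                 compartment_params(0.6, 0.2, 0.2, S0 = 100),
                 compartment_params(0.85, 0.1, 0.05, S0 = 100))
  specs <- lapply(truths, function(tr)
    phantom_spec(shape = c(9, 9), center = c(5, 5), axes = c(3, 3), truth = tr))
  groups <- c("SCC", "SCC", "AC", "AC")
  a <- cohort_from_phantoms(specs, groups, seed = 4)
  b <- cohort_from_phantoms(specs, groups, seed = 4)
  expect_identical(a, b)
  expect_equal(nrow(a), 4)
  expect_equal(a$f1, vapply(truths, function(tr) tr$f[1], numeric(1)),
               tolerance = 1e-8)
})

test_that("fitted group difference in f1 is detected from noisy phantoms", {
  set.seed(21)
  reject <- replicate(60, {
    co <- generate_cohort(20, 20, mode = "image", snr = 50)
    welch_t_samples(co$f1[co$subtype == "SCC"], co$f1[co$subtype == "AC"])$p < 0.05
  })
  expect_gte(mean(reject), 0.95)
})
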