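perfect_dilutions <- function(intercept = 37, slope = -3.3219, reps = 3,
                              target = NULL) {
  d <- expand.grid(copies = 10^(1:7), rep = seq_len(reps))
  d$cq <- intercept + slope * log10(d$copies)
  if (!is.null(target)) d$target <- target
  d
}

test_that("standard-curve fitting recovers slope, efficiency and QC", {
  cv <- suppressWarnings(fit_standard_curve(perfect_dilutions()))
  expect_equal(cv$slope, -3.3219, tolerance = 1e-10)
  expect_equal(cv$efficiency, 1, tolerance = 1e-4)
  expect_equal(cv$r_squared, 1)
  expect_true(cv$qc_pass)

  cv36 <- suppressWarnings(fit_standard_curve(perfect_dilutions(slope = -3.6)))
  expect_equal(cv36$efficiency, 10^(1 / 3.6) - 1, tolerance = 1e-10)
  expect_false(cv36$qc_pass)

  # noisy series recovers the planted slope
  set.seed(20)
  d <- perfect_dilutions(reps = 9)
  d$cq <- d$cq + rnorm(nrow(d), 0, 0.1)
  expect_lt(abs(fit_standard_curve(d)$slope + 3.3219), 0.05)

  expect_error(fit_standard_curve(data.frame(copies = c(10, 100), cq = c(3, 2))),
               "3 distinct")
  up <- data.frame(copies = 10^(1:4), cq = 1:4)
  expect_error(fit_standard_curve(up), "negative")
})

test_that("sample quantification inverts the curve with a t-interval", {
  cv <- suppressWarnings(fit_standard_curve(perfect_dilutions()))
  # single-copy inversion sits past the Cq-35 cutoff, so lift it explicitly
  expect_equal(quantify_sample(37, cv, cq_cutoff = Inf)$copies, 1,
               tolerance = 1e-9)
  expect_equal(quantify_sample(30.3562, cv)$copies, 100, tolerance = 1e-3)
  q0 <- quantify_sample(rep(30.3562, 3), cv)
  expect_equal(q0$ci_low, q0$copies)
  expect_equal(q0$ci_high, q0$copies)

  q <- quantify_sample(c(24.9, 25.1, 25.0), cv)
  expect_true(q$ci_low < q$copies && q$copies < q$ci_high)
  expect_error(quantify_sample(numeric(0), cv), "at least one")

  # all replicates at/above the cutoff -> below_detection bound
  bd <- quantify_sample(c(36, NA, 38), cv, cq_cutoff = 35)
  expect_true(bd$below_detection)
  expect_equal(bd$ci_low, 0)
})

test_that("calibration round trip is exact without noise", {
  cv <- suppressWarnings(fit_standard_curve(perfect_dilutions()))
  for (copies in c(1, 7, 100, 5e4, 1e7)) {
    cq <- 37 - 3.3219 * log10(copies)
    expect_equal(quantify_sample(cq, cv, cq_cutoff = Inf)$copies, copies,
                 tolerance = 1e-9)
  }
})

test_that("efficiency is invariant to scaling all copies", {
  d1 <- perfect_dilutions()
  d2 <- d1
  d2$copies <- d2$copies * 50
  cv1 <- suppressWarnings(fit_standard_curve(d1))
  cv2 <- suppressWarnings(fit_standard_curve(d2))
  expect_equal(cv1$slope, cv2$slope)
  expect_equal(cv1$efficiency, cv2$efficiency)
  expect_false(isTRUE(all.equal(cv1$intercept_cq, cv2$intercept_cq)))
})

test_that("ratios propagate CIs and flag detection bounds", {
  cv <- suppressWarnings(fit_standard_curve(perfect_dilutions()))
  qa <- quantify_sample(c(25.0, 25.1, 24.9), cv, sample_id = "s1")
  r11 <- ratio_with_ci(qa, qa, cv, cv)
  expect_equal(r11$ratio, 1)
  expect_true(r11$ci_low <= 1 && 1 <= r11$ci_high)

  qb <- quantify_sample(c(28.2, 28.4, 28.3), cv, sample_id = "s1")
  r <- ratio_with_ci(qa, qb, cv, cv)
  expect_equal(r$ratio, qa$copies / qb$copies)
  expect_true(r$ci_low < r$ratio && r$ratio < r$ci_high)

  bd <- quantify_sample(c(37, 38, NA), cv, sample_id = "s1", cq_cutoff = 35)
  rb <- ratio_with_ci(bd, qb, cv, cv)
  expect_true(rb$below_detection) # numerator bound: ratio is an upper limit
  expect_equal(rb$ci_low, 0)
  rd <- ratio_with_ci(qb, bd, cv, cv)
  expect_true(rd$below_detection && is.na(rd$ratio)) # denominator undefined
})

test_that("NGS ratio normalises by genome length with a bootstrap CI", {
  expect_equal(ngs_ratio(240, 180, 24000, 18000, bootstrap_reps = 0)$ratio, 1)
  expect_equal(ngs_ratio(200, 100, 24000, 18000, bootstrap_reps = 0)$ratio, 1.5)
  r <- ngs_ratio(20000, 1000, 24347, 18113, bootstrap_reps = 2000, seed = 2)
  expect_true(r$ci_low < r$ratio && r$ratio < r$ci_high)
  expect_error(ngs_ratio(0, 0, 100, 100), "no reads")
  z <- ngs_ratio(100, 0, 100, 100, bootstrap_reps = 0)
  expect_true(z$below_detection || is.infinite(z$ratio))
})

test_that("quantify_samples processes a long table per sample x target", {
  sim <- simulate_qpcr_dataset(n_samples = 4, sigma_cq = 0.05, seed = 33)
  curves <- fit_standard_curves(sim$dilutions)
  expect_named(curves, c("F_cox1", "M_nad1", "nuclear_atpa"))
  q <- quantify_samples(sim$samples, curves)
  expect_equal(nrow(q), 4 * 2 * 3) # samples x tissues x targets
  truth <- sim$truth$samples
  m <- merge(q[q$target == "nuclear_atpa", ], truth, by = c("sample_id", "tissue"))
  expect_true(all(abs(log10(m$copies / sim$truth$ndna_copies)) < 0.1))
  expect_error(quantify_samples(sim$samples,
                                curves[c("F_cox1", "M_nad1")]),
               "no standard curve")
})
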