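test_that("labeling efficiency follows the dye/protein absorbance ratio", {
  # 0.70/70000 = 10 uM dye; (0.3437 - 0.12*0.70)/25974 ~ 10 uM protein
  expect_equal(
    suppressWarnings(
      labeling_efficiency(0.70, 0.3437, 70000, 25974, 0.12)),
    1.0, tolerance = 1e-3)
  expect_equal(labeling_efficiency(0, 0.5, 70000, 25974, 0.12), 0)
  # zero correction factor reduces to the simple concentration ratio
  expect_equal(labeling_efficiency(0.35, 0.5, 70000, 25974, 0),
               (0.35 / 70000) / (0.5 / 25974))
  expect_error(labeling_efficiency(0.7, 0.05, 70000, 25974, 0.12),
               class = "plusend_degenerate_input")
  expect_warning(labeling_efficiency(0.9, 0.3437, 70000, 25974, 0.12),
                 "clipping")
})

test_that("step pmf matches the expanded binomial, conditional and not", {
  full <- predict_step_pmf(2, 1)
  expect_equal(full$prob[full$k == 2], 1)
  expect_true(all(full$prob[full$k != 2] == 0))

  un <- predict_step_pmf(2, 0.7, conditional_on_visible = FALSE)
  expect_equal(un$prob, c(0.09, 0.42, 0.49), tolerance = 1e-12)

  cond <- predict_step_pmf(2, 0.7)
  expect_equal(cond$prob, c(0.42, 0.49) / 0.91, tolerance = 1e-12)

  mono <- predict_step_pmf(1, 0.55)
  expect_equal(mono$prob, 1)
  expect_equal(predict_step_pmf(1, 0.55, FALSE)$prob, c(0.45, 0.55))

  expect_error(predict_step_pmf(5, 0.5), class = "plusend_domain_error")
  expect_error(predict_step_pmf(2, 0), class = "plusend_domain_error")
})

test_that("pmf normalisation and mean hold across the (n, p) grid", {
  for (n in 1:4) {
    for (p in c(0.3, 0.5, 0.7, 1.0)) {
      un <- predict_step_pmf(n, p, conditional_on_visible = FALSE)
      expect_equal(sum(un$prob), 1, tolerance = 1e-12)
      expect_equal(sum(un$k * un$prob), n * p, tolerance = 1e-12)
      cond <- predict_step_pmf(n, p)
      expect_true(all(cond$k >= 1))
      expect_equal(sum(cond$prob), 1, tolerance = 1e-12)
    }
  }
})

test_that("noise-free staircases are counted exactly with exact times", {
  tr <- staircase_trace(c(2, 1, 0))
  res <- detect_steps(tr)
  expect_equal(res$n_steps, 2L)
  expect_equal(res$step_times[[1]], c(10, 20))

  flat <- staircase_trace(1, dwell_frames = 30)
  expect_equal(detect_steps(flat)$n_steps, 0L)
})

test_that("step counting is accurate on noisy simulated dimer traces", {
  sim <- simulate_bleach_traces(2, 0.7, 300, noise_sd = 0.15, seed = 3)
  res <- detect_steps(sim$traces)
  joined <- dplyr::left_join(sim$truth, res, by = "molecule_id")
  expect_gt(mean(joined$n_steps == joined$true_step_count), 0.9)
})

test_that("step histograms pool the 4+ tail and drop zero-step traces", {
  h <- step_histogram(c(1, 1, 2, 3, 4, 5, 6, 0))
  expect_equal(h$count, c(2L, 1L, 1L, 3L))
  expect_equal(sum(h$count), 7L)
  expect_error(step_histogram(integer()),
               class = "plusend_insufficient_data")
})

test_that("an exact dimer histogram is called with zero distance", {
  counts <- round(1000 * c(0.42, 0.49) / 0.91)
  oi <- infer_oligomer(c(rep(1L, counts[1]), rep(2L, counts[2])), 0.7)
  expect_equal(oi$best_n, 2)
  expect_lt(oi$candidates$distance[oi$candidates$n == 2], 1e-5)
  expect_false(oi$small_sample)
})

test_that("small samples are flagged but still processed", {
  oi <- infer_oligomer(c(1L, 2L, 2L, 1L, 2L), 0.7)
  expect_true(oi$small_sample)
  expect_true(oi$best_n %in% 1:4)
})

test_that("inference degrades at low labeling efficiency", {
  margin <- function(p, seed) {
    sim <- simulate_bleach_traces(2, p, 300, duration = 10,
                                  frame_interval = 1, seed = seed)
    oi <- infer_oligomer(step_histogram(sim$truth$true_step_count), p)
    d <- sort(oi$candidates$distance)
    d[2] - d[1]
  }
  m_hi <- vapply(1:20, function(s) margin(0.70, 500 + s), numeric(1))
  m_lo <- vapply(1:20, function(s) margin(0.55, 700 + s), numeric(1))
  expect_gt(mean(m_hi), mean(m_lo))
})

test_that("the full simulate-detect-infer pipeline recovers n in {1, 2}", {
  for (n_true in 1:2) {
    hits <- vapply(1:20, function(s) {
      sim <- simulate_bleach_traces(n_true, 0.7, 120, noise_sd = 0.15,
                                    seed = 2000 + 40 * n_true + s)
      res <- detect_steps(sim$traces)
      infer_oligomer(step_histogram(res), 0.7)$best_n == n_true
    }, logical(1))
    expect_gte(mean(hits), 0.9)
  }
})
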