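test_that("a perfect line gives slope 0.1 um/s and rate 37", {
  tr <- tibble::tibble(filament_id = "f1", time = seq(0, 20, 5),
                       length = seq(0, 2, 0.5))
  est <- elongation_rates(tr, actin_conc = 1)
  expect_equal(est$slope, 0.1)
  expect_equal(est$rate, 37.0)
  expect_equal(est$fit_r2, 1)
  expect_equal(est$n_points, 5L)
})

test_that("rate conversion is linear and divides by concentration", {
  tr <- linear_track(0.05)
  est1 <- elongation_rates(tr, actin_conc = 1)
  est2 <- elongation_rates(dplyr::mutate(tr, length = 2 * length),
                           actin_conc = 1)
  expect_equal(est2$slope, 2 * est1$slope)
  expect_equal(est2$rate, 2 * est1$rate)
  est_half <- elongation_rates(tr, actin_conc = 0.5)
  expect_equal(est_half$rate, 2 * est1$rate)
  expect_equal(est1$rate, est1$slope * 370)
})

test_that("noise-free simulated free ends recover the 10.2 default rate", {
  cfg <- sim_config(length_noise_sd = 0)
  sim <- simulate_filaments(cfg, 20, seed = 1)
  est <- elongation_rates(sim$tracks, actin_conc = cfg$actin_conc)
  expect_true(all(abs(est$rate - 10.2) < 0.01))
  expect_true(all(est$fit_r2 > 1 - 1e-9))
})

test_that("flat tracks give rate 0 and short tracks are rejected", {
  tr <- tibble::tibble(filament_id = "f1", time = seq(0, 20, 5),
                       length = rep(1, 5))
  est <- elongation_rates(tr)
  expect_equal(est$slope, 0)
  expect_equal(est$rate, 0)
  short <- tibble::tibble(filament_id = "f2", time = c(0, 5, 10),
                          length = c(0, 1, 2))
  expect_error(elongation_rates(short), "f2",
               class = "plusend_insufficient_data")
  expect_error(elongation_rates(tr, actin_conc = 0),
               class = "plusend_domain_error")
})

test_that("three stalled increments become one 15-s pause", {
  tr <- stalled_track(n_stalled = 3)
  p <- detect_pauses(tr)
  expect_equal(nrow(p), 1)
  expect_equal(p$duration, 15)
  expect_equal(p$n_frames, 3L)
  expect_false(p$truncated_by_movie_end)
  expect_equal(p$duration, min_resolvable_pause(5, 3))
})

test_that("linear tracks have no pauses and short stalls are ignored", {
  expect_equal(nrow(detect_pauses(linear_track(0.1))), 0)
  expect_equal(nrow(detect_pauses(stalled_track(n_stalled = 2))), 0)
})

test_that("stalls reaching the final frame are flagged as truncated", {
  tr <- stalled_track(n_stalled = 4, n_after = 0)
  p <- detect_pauses(tr)
  expect_equal(nrow(p), 1)
  expect_true(p$truncated_by_movie_end)
})

test_that("separated stalled runs are distinct pauses and never overlap", {
  grow <- c(0.5, 0.5, 0, 0, 0, 0.5, 0, 0, 0, 0.5, 0.5)
  tr <- tibble::tibble(filament_id = "f1",
                       time = seq(0, by = 5, length.out = length(grow) + 1),
                       length = cumsum(c(0, grow)))
  p <- detect_pauses(tr)
  expect_equal(nrow(p), 2)
  expect_true(all(p$duration >= 15))
  expect_true(p$end[1] <= p$start[2])
})

test_that("pause detection is independent of row order", {
  cfg <- sim_config(length_noise_sd = 0.02,
                    transition_rates = c("free->iqgap1_paused" = 0.005))
  sim <- simulate_filaments(cfg, 10, seed = 9)
  shuffled <- sim$tracks[sample.int(nrow(sim$tracks)), ]
  expect_equal(detect_pauses(sim$tracks), detect_pauses(shuffled))
})

test_that("minimum resolvable pause is the frame interval times the rule", {
  expect_equal(min_resolvable_pause(5, 3), 15)
  expect_equal(min_resolvable_pause(1, 2), 2)
  expect_equal(min_resolvable_pause(3.2, 3), 9.6)
})

test_that("nucleation counts filaments present and grown at the query time", {
  t0 <- linear_track(0.1, id = "a")
  counts <- count_nucleation(dplyr::bind_rows(
    t0, linear_track(0.1, id = "b"), linear_track(0.1, id = "c")), 50)
  expect_equal(counts$n_filaments, 3L)

  appear <- function(t_start, id) {
    tibble::tibble(filament_id = id, fov_id = "FOV-1",
                   time = seq(t_start, 400, 5),
                   length = 0.05 * (seq(t_start, 400, 5) - t_start))
  }
  tracks <- dplyr::bind_rows(appear(50, "a"), appear(150, "b"),
                             appear(250, "c"))
  expect_equal(count_nucleation(tracks, 200)$n_filaments, 2L)
})

test_that("growth-phase rates beat whole-track rates under pausing", {
  cfg <- sim_config(length_noise_sd = 0.02,
                    transition_rates = c("free->iqgap1_paused" = 0.004))
  sim <- simulate_filaments(cfg, 120, seed = 21)
  whole <- elongation_rates(sim$tracks, actin_conc = 1)
  growth <- elongation_rates(sim$tracks, actin_conc = 1,
                             exclude_pauses = TRUE)
  expect_lt(mean(whole$rate), mean(growth$rate, na.rm = TRUE))
  expect_lt(mean(whole$rate), 10.2)  # pauses drag the mean rate down
})
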