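test_that("sim_config validates fields and names the offender", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(frame_interval = 0), "frame_interval",
               class = "plusend_config_error")
  expect_error(sim_config(movie_duration = 10), "movie_duration",
               class = "plusend_config_error")
  expect_error(sim_config(state_growth_rates = c(free = -1)),
               "state_growth_rates", class = "plusend_config_error")
  expect_error(sim_config(state_growth_rates = c(cp_capped = 5)),
               "non-growing", class = "plusend_config_error")
  expect_error(sim_config(transition_rates = c("free->nowhere" = 1)),
               "unknown state", class = "plusend_config_error")
  expect_error(sim_config(transition_rates = c(0.1)),
               class = "plusend_config_error")
})

test_that("identical config and seed give bit-identical filament output", {
  cfg <- sim_config(transition_rates = c("free->iqgap1_paused" = 0.005))
  a <- simulate_filaments(cfg, 10, seed = 42)
  b <- simulate_filaments(cfg, 10, seed = 42)
  expect_identical(a$tracks, b$tracks)
  expect_identical(a$events, b$events)
})

test_that("zero noise and zero transitions give exactly linear tracks", {
  cfg <- sim_config(length_noise_sd = 0)
  sim <- simulate_filaments(cfg, 5, seed = 1)
  v <- 10.2 * 1 / 370
  for (id in unique(sim$tracks$filament_id)) {
    tr <- sim$tracks[sim$tracks$filament_id == id, ]
    slopes <- diff(tr$length) / diff(tr$time)
    expect_equal(slopes, rep(v, length(slopes)), tolerance = 1e-12)
  }
})

test_that("zero growth rates give flat tracks at the initial length", {
  cfg <- sim_config(length_noise_sd = 0,
                    state_growth_rates = c(free = 0))
  sim <- simulate_filaments(cfg, 4, seed = 2)
  expect_true(all(sim$tracks$length == 0))
})

test_that("ground-truth events tile each filament's lifetime", {
  cfg <- sim_config(length_noise_sd = 0.05,
                    transition_rates = c("free->iqgap1_paused" = 0.01,
                                         "free->cp_capped" = 0.002))
  sim <- simulate_filaments(cfg, 30, seed = 3)
  ev <- dplyr::arrange(sim$events, filament_id, start)
  for (id in unique(ev$filament_id)) {
    e <- ev[ev$filament_id == id, ]
    expect_true(all(e$end > e$start))
    expect_equal(e$start[-1], e$end[-nrow(e)])
    expect_equal(e$end[nrow(e)], cfg$movie_duration)
  }
})

test_that("ground-truth pause durations match the configured Gaussian", {
  cfg <- sim_config(length_noise_sd = 0,
                    transition_rates = c("free->iqgap1_paused" = 0.004))
  sim <- simulate_filaments(cfg, 500, seed = 11)
  tp <- true_pauses(sim$events, cfg$movie_duration)
  expect_gt(nrow(tp), 300)
  expect_lt(abs(mean(tp$duration) - 20.6), 0.5)
  expect_lt(abs(sd(tp$duration) - 5), 0.7)
})

test_that("fully labeled dimers always show two true steps", {
  sim <- simulate_bleach_traces(2, p_label = 1, n_molecules = 50, seed = 1)
  expect_true(all(sim$truth$true_step_count == 2L))
  expect_equal(nrow(sim$truth), 50)
})

test_that("noise-free trace plateaus are exact multiples of the unit step", {
  sim <- simulate_bleach_traces(2, p_label = 1, n_molecules = 10,
                                bleach_rate = 0.1, noise_sd = 0,
                                seed = 2)
  expect_true(all(abs(sim$traces$intensity -
                        round(sim$traces$intensity)) < 1e-12))
  last <- dplyr::slice_tail(dplyr::group_by(sim$traces, molecule_id), n = 1)
  expect_true(all(last$intensity <= 2))
})

test_that("visible-step counts follow the conditional binomial law", {
  grid <- expand.grid(n = 1:4, p = c(0.3, 0.5, 0.7, 1.0))
  for (i in seq_len(nrow(grid))) {
    n <- grid$n[i]
    p <- grid$p[i]
    sim <- simulate_bleach_traces(n, p, n_molecules = 4000,
                                  duration = 10, frame_interval = 1,
                                  seed = 100 + i)
    k <- sim$truth$true_step_count
    expect_true(all(k >= 1))
    expected <- predict_step_pmf(n, p)
    for (j in seq_len(nrow(expected))) {
      expect_lt(abs(mean(k == expected$k[j]) - expected$prob[j]), 0.03)
    }
  }
})

test_that("dimer visible-step split at 70% label is 46.2/53.8", {
  sim <- simulate_bleach_traces(2, 0.7, n_molecules = 10000,
                                duration = 10, frame_interval = 1,
                                seed = 5)
  k <- sim$truth$true_step_count
  expect_lt(abs(mean(k == 1) - 0.42 / 0.91), 0.02)
  expect_lt(abs(mean(k == 2) - 0.49 / 0.91), 0.02)
})

test_that("p_label outside (0, 1] is rejected", {
  expect_error(simulate_bleach_traces(2, 0, 10),
               class = "plusend_domain_error")
  expect_error(simulate_bleach_traces(2, 1.2, 10),
               class = "plusend_domain_error")
  expect_error(simulate_bleach_traces(5, 0.5, 10),
               class = "plusend_domain_error")
})

test_that("dwell sampling matches the exponential law and censors", {
  dw <- simulate_dwells(c(x = 100), movie_duration = 10000,
                        n_molecules = 5000, seed = 1)
  d <- dw$release_time - dw$bind_time
  expect_lt(abs(mean(d[!dw$censored]) - 100), 5)

  dw2 <- simulate_dwells(c(x = 100), movie_duration = 0.01,
                         n_molecules = 100, seed = 2)
  expect_true(all(dw2$censored))

  # competing exponentials: hazard adds
  dw3 <- simulate_dwells(c(x = 100), displacement_hazard = 0.05,
                         movie_duration = 10000, n_molecules = 5000,
                         seed = 3)
  d3 <- dw3$release_time[!dw3$censored] - dw3$bind_time[!dw3$censored]
  expect_lt(abs(mean(d3) - 1 / 0.06) / (1 / 0.06), 0.05)

  expect_error(simulate_dwells(c(x = -1), movie_duration = 10,
                               n_molecules = 5),
               class = "plusend_domain_error")
  expect_error(simulate_dwells(c(100), movie_duration = 10,
                               n_molecules = 5),
               class = "plusend_domain_error")
})

test_that("spot simulation respects extent and the coloc fraction limits", {
  sp <- simulate_spots(density = 0.02, coloc_fraction = 1, jitter_sd = 0,
                       fov_extent = c(50, 50), seed = 1)
  a <- sp[sp$channel == "A", ]
  b <- sp[sp$channel == "B", ]
  expect_equal(nrow(a), nrow(b))
  expect_equal(sort(a$x), sort(b$x))
  expect_equal(sort(a$y), sort(b$y))
  expect_true(all(sp$x >= 0 & sp$x <= 50 & sp$y >= 0 & sp$y <= 50))

  sp0 <- simulate_spots(density = 0.02, coloc_fraction = 0, seed = 2)
  expect_true(all(is.na(sp0$partner_of)))
})

test_that("bundle fields are right-skewed only for partial bundling", {
  none <- simulate_bundle_field(20000, 0, seed = 1)
  some <- simulate_bundle_field(20000, 0.2, bundle_multiplier = 4, seed = 1)
  all_b <- simulate_bundle_field(20000, 1, seed = 1)
  s_none <- intensity_skewness(none)
  s_some <- intensity_skewness(some)
  s_all <- intensity_skewness(all_b)
  expect_lt(abs(s_none), 0.1)
  expect_lt(abs(s_all), 0.1)
  expect_gt(s_some, s_none + 0.5)
})
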