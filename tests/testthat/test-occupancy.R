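mk_dwells <- function(dwell, censored = rep(FALSE, length(dwell)),
                      species = "x") {
  tibble::tibble(molecule_id = sprintf("m%d", seq_along(dwell)),
                 species = species, bind_time = 0, release_time = dwell,
                 censored = censored)
}

test_that("identical dwells give a single step from 1 to 0", {
  sc <- survival_curve(mk_dwells(rep(10, 4)))
  expect_equal(sc$surv[sc$time == 0], 1)
  expect_equal(sc$surv[sc$time == 10], 0)
  expect_true(all(diff(sc$surv) <= 0))
})

test_that("the exponential median lands at mean * log(2)", {
  dw <- simulate_dwells(c(x = 30), movie_duration = 10000,
                        n_molecules = 5000, seed = 1)
  sc <- survival_curve(dw)
  s_med <- sc$surv[max(which(sc$time <= 30 * log(2)))]
  expect_lt(abs(s_med - 0.5), 0.02)
})

test_that("drop-mode survival equals a brute-force counter", {
  set.seed(7)
  for (rep in 1:5) {
    d <- round(rexp(40, 0.1), 1) + 0.1
    sc <- survival_curve(mk_dwells(d), censoring = "drop")
    expect_equal(sc$surv, brute_survival(d, sc$time))
    expect_true(all(diff(sc$surv) <= 0))
  }
})

test_that("Kaplan-Meier reduces exactly to the empirical curve uncensored", {
  set.seed(8)
  d <- round(rexp(60, 0.05), 1) + 0.1
  km <- survival_curve(mk_dwells(d), censoring = "kaplan_meier")
  emp <- survival_curve(mk_dwells(d), censoring = "drop")
  expect_equal(km$time, emp$time)
  expect_equal(km$surv, emp$surv, tolerance = 1e-12)
})

test_that("censored molecules hold the KM curve above the drop curve", {
  d <- c(5, 10, 15, 20, 40, 40, 40)
  cen <- c(rep(FALSE, 4), rep(TRUE, 3))
  km <- survival_curve(mk_dwells(d, cen), censoring = "kaplan_meier")
  dr <- survival_curve(mk_dwells(d, cen), censoring = "drop")
  expect_gte(km$surv[km$time == 20], dr$surv[dr$time == 20])
  expect_error(survival_curve(mk_dwells(c(5, 6), c(TRUE, TRUE))),
               class = "plusend_insufficient_data")
})

test_that("dwell summaries report per-species statistics and censoring", {
  s <- dwell_summary(mk_dwells(125))
  expect_equal(s$max, 125)
  expect_equal(s$mean, s$median)
  s2 <- dwell_summary(dplyr::bind_rows(
    mk_dwells(c(10, 20, 30), species = "a"),
    mk_dwells(c(5, 50), c(FALSE, TRUE), species = "b")))
  expect_equal(s2$n[s2$species == "a"], 3L)
  expect_equal(s2$n_censored[s2$species == "b"], 1L)
  expect_equal(s2$max[s2$species == "b"], 5)
})

test_that("a displacement hazard shrinks the longest dwells", {
  wins <- vapply(1:100, function(s) {
    base <- simulate_dwells(c(x = 100), movie_duration = 1e5,
                            n_molecules = 50, seed = 3000 + s)
    disp <- simulate_dwells(c(x = 100), displacement_hazard = 0.05,
                            movie_duration = 1e5, n_molecules = 50,
                            seed = 9000 + s)
    max(base$release_time - base$bind_time) >
      max(disp$release_time - disp$bind_time)
  }, logical(1))
  expect_gte(mean(wins), 0.95)
})

test_that("identical spot sets colocalize at 100 percent", {
  a <- tibble::tibble(x = runif(50, 0, 40), y = runif(50, 0, 40))
  res <- colocalize(a, a, match_radius = 0.4)
  expect_equal(res$percent, 100)
  expect_equal(res$n_matched, 50L)
})

test_that("matching is one-to-one and complete at infinite radius", {
  set.seed(12)
  a <- tibble::tibble(x = runif(30, 0, 10), y = runif(30, 0, 10))
  b <- tibble::tibble(x = runif(30, 0, 10), y = runif(30, 0, 10))
  res <- colocalize(a, b, match_radius = 1e6)
  expect_equal(res$n_matched, 30L)
  expect_lte(colocalize(a, b[1:7, ], match_radius = 1e6)$n_matched, 7L)
})

test_that("independent sparse fields match only at chance level", {
  sp <- simulate_spots(density = 0.05, coloc_fraction = 0, seed = 13)
  res <- colocalize(sp, fov_extent = c(80, 80))
  expect_lt(res$percent, 6)  # background regime, a few percent
  expect_lt(abs(res$percent_corrected), 4)
})

test_that("the chance-corrected estimator recovers a known mixture", {
  sp <- simulate_spots(density = 0.05, coloc_fraction = 0.5,
                       jitter_sd = 0.05, n_fov = 4, seed = 14)
  res <- colocalize(sp, fov_extent = c(80, 80))
  expect_lt(abs(mean(res$percent_corrected) - 50), 3)
})

test_that("an empty reference channel is flagged, not an error", {
  b <- tibble::tibble(x = 1:3, y = 1:3)
  res <- colocalize(b[0, ], b)
  expect_true(res$undefined)
  expect_true(is.na(res$percent))
})
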