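# Hand-built posterior object for the degenerate-draw checks.
fake_fit <- function(r, k, B_final, catch_final) {
  draws <- tibble::tibble(r = r, k = k, q = 1e-3, sigma_obs = 0.05,
                          sigma_proc = 0, msy = r * k / 4, fmsy = r / 2,
                          bmsy = k / 2)
  structure(list(draws = draws,
                 biomass = matrix(B_final, length(r), 2),
                 years = c(2000L, 2001L), catch = c(catch_final, 0),
                 cpue = c(1, 1), ess = length(r), n_draws = length(r),
                 meta = list()),
            class = "bsm_fit")
}

test_that("the Schaefer recurrence has its equilibria and matches hand iteration", {
  # at carrying capacity with no catch, biomass stays put
  expect_equal(as.numeric(simulate_schaefer(0.3, 500, rep(0, 10), B0 = 500)),
               rep(500, 11))
  # fishing exactly MSY from Bmsy holds the stock at k/2
  r <- 0.2; k <- 1000
  expect_equal(as.numeric(simulate_schaefer(r, k, rep(r * k / 4, 15),
                                            B0 = k / 2)),
               rep(k / 2, 16), tolerance = 1e-12)
  # against the independent hand-iterated recurrence
  expect_equal(as.numeric(simulate_schaefer(0.2, 1000, rep(50, 12), B0 = 900)),
               oracle_schaefer(0.2, 1000, rep(50, 12), 900),
               tolerance = 1e-12)
  # catches an order of magnitude above production hit the floor
  tr <- simulate_schaefer(0.1, 100, rep(90, 5), B0 = 50)
  expect_true(attr(tr, "hit_floor"))
})

test_that("fitting recovers a known stock history and keeps MSY identities", {
  gs <- gen_schaefer_series(r = 0.25, k = 1000, q = 0.001, sigma_obs = 0.1,
                            years = 1985:2024, seed = 71)
  fit <- suppressWarnings(
    fit_bsm(gs$data, bk_priors = tibble::tibble(year = 1985, lo = 0.75,
                                                hi = 1.0),
            n_draws = 6000, n_stages = 5, min_ess = 300, seed = 72))
  td <- tidy(fit)
  expect_true(td$lci[td$term == "r"] <= 0.25 &&
                td$uci[td$term == "r"] >= 0.25)
  expect_true(td$lci[td$term == "k"] <= 1000 &&
                td$uci[td$term == "k"] >= 1000)
  # reference-point identities hold draw by draw
  expect_equal(fit$draws$msy, fit$draws$r * fit$draws$k / 4)
  expect_equal(fit$draws$bmsy, fit$draws$k / 2)
  expect_equal(fit$draws$fmsy, fit$draws$r / 2)
  # trajectories have the full year axis
  expect_equal(ncol(fit$biomass), length(fit$years) + 1)
  g <- glance(fit)
  expect_equal(g$n_years, 40)
  expect_gt(g$ess, 0)
})

test_that("a zero-noise series with matched priors reproduces the trajectory", {
  gs <- gen_schaefer_series(r = 0.25, k = 1000, q = 0.001, sigma_proc = 0,
                            sigma_obs = 0, years = 1995:2024, seed = 5)
  fit <- suppressWarnings(
    fit_bsm(gs$data, r_prior = c(0.2, 0.3),
            bk_priors = tibble::tibble(year = 1995, lo = 0.9, hi = 1.0),
            n_draws = 6000, n_stages = 5, min_ess = 200, seed = 6))
  med_traj <- apply(fit$biomass, 2, median)
  expect_equal(med_traj, gs$truth$B, tolerance = 0.05)
})

test_that("priors excluding the truth pile up at the boundary with a warning", {
  gs <- gen_schaefer_series(r = 0.35, k = 1000, q = 0.001, sigma_obs = 0.05,
                            years = 1985:2024, seed = 13)
  expect_warning(
    fit_bsm(gs$data, r_prior = c(0.02, 0.08),
            bk_priors = tibble::tibble(year = 1985, lo = 0.75, hi = 1.0),
            n_draws = 4000, n_stages = 4, min_ess = 1e9, seed = 14),
    "boundary|effective sample size")
})

test_that("CPUE gaps are skipped in the likelihood, not imputed", {
  gs <- gen_schaefer_series(r = 0.25, k = 1000, q = 0.001, sigma_obs = 0.1,
                            years = 1985:2024, seed = 41)
  gappy <- gs$data
  gappy$cpue[c(5:9, 20:24)] <- NA
  fit <- suppressWarnings(
    fit_bsm(gappy, bk_priors = tibble::tibble(year = 1985, lo = 0.75, hi = 1),
            n_draws = 5000, n_stages = 5, min_ess = 200, seed = 42))
  td <- tidy(fit)
  expect_true(td$lci[td$term == "r"] <= 0.25 &&
                td$uci[td$term == "r"] >= 0.25)
  expect_equal(glance(fit)$n_obs_cpue, 30)
})

test_that("reference points and Kobe quadrants follow their definitions", {
  # single draw at B = 1.5 Bmsy fished at F = 0.5 Fmsy: green quadrant
  r <- 0.2; k <- 1000
  B <- 1.5 * k / 2
  C <- 0.5 * (r / 2) * B
  f1 <- fake_fit(r, k, B, C)
  kp <- kobe_probabilities(f1, year = f1$years[1])
  expect_equal(kp$green, 1)
  expect_equal(kp$green + kp$yellow + kp$orange + kp$red, 1)
  rp <- reference_points(f1)
  expect_equal(rp$b_bmsy[1], 1.5)
  expect_equal(rp$f_fmsy[1], 0.5)

  # draw exactly at Bmsy: relative biomass is one
  f2 <- fake_fit(r, k, k / 2, r * k / 8)
  expect_equal(reference_points(f2)$b_bmsy[1], 1)

  # a cloud symmetric around (1, 1) with independent axes puts about a
  # quarter of the draws in each quadrant
  set.seed(8)
  n <- 4000
  kk <- rep(1000, n)
  C <- 50
  Bs <- (kk / 2) * exp(rnorm(n, 0, 0.2))          # B/Bmsy symmetric about 1
  rr <- 2 * C / (Bs * exp(rnorm(n, 0, 0.2)))      # F/Fmsy symmetric about 1
  f3 <- fake_fit(rr, kk, Bs, C)
  kp3 <- kobe_probabilities(f3, year = f3$years[1])
  expect_equal(kp3$green + kp3$yellow + kp3$orange + kp3$red, 1)
  expect_true(all(abs(c(kp3$green, kp3$yellow, kp3$orange, kp3$red) - 0.25)
                  < 0.05))
})

test_that("input validation rejects malformed series", {
  good <- gen_schaefer_series(seed = 1)$data
  bk <- tibble::tibble(year = good$year[1], lo = 0.5, hi = 0.9)
  expect_error(fit_bsm(good[1:5, ], bk_priors = bk), "at least 10")
  allzero <- dplyr::mutate(good, catch = 0)
  expect_error(fit_bsm(allzero, bk_priors = bk), "all-zero")
  expect_error(fit_bsm(good, bk_priors = tibble::tibble(year = 1800,
                                                        lo = 0.5, hi = 0.9)),
               "anchor year")
  expect_error(fit_bsm(good, bk_priors = tibble::tibble(year = good$year[1],
                                                        lo = 0.9, hi = 0.5)),
               "invalid")
})
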