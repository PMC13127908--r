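test_that("swept-area standardization turns counts into densities", {
  hauls <- tibble::tibble(haul_id = "H1", year = 2020, stratum = "shelf",
                          distance_km = 2.5, wingspread_km = 0.02)
  lengths <- tibble::tibble(haul_id = "H1", length_cm = 30, count = 10)
  areas <- tibble::tibble(stratum = "shelf", area_km2 = 1000)
  d <- standardize_survey_lf(hauls, lengths, areas)
  expect_equal(d$density, 10 / 0.05)  # 200 ind/km2

  # equal densities in both strata: the weighted mean is that density for
  # any area split
  hauls2 <- tibble::tibble(haul_id = c("A", "B"), year = 2020,
                           stratum = c("shelf", "slope"),
                           distance_km = 2.5, wingspread_km = 0.02)
  lengths2 <- tibble::tibble(haul_id = c("A", "B"), length_cm = 30,
                             count = c(10, 10))
  for (split in list(c(100, 900), c(500, 500), c(999, 1))) {
    areas2 <- tibble::tibble(stratum = c("shelf", "slope"), area_km2 = split)
    expect_equal(standardize_survey_lf(hauls2, lengths2, areas2)$density, 200)
  }
  expect_error(standardize_survey_lf(
    dplyr::mutate(hauls, distance_km = 0), lengths, areas), "swept")
  expect_error(standardize_survey_lf(
    hauls, lengths, tibble::tibble(stratum = "slope", area_km2 = 1)),
    "without an area")
})

test_that("stratified estimates recover a known density field", {
  field <- tidyr::expand_grid(stratum = c("shallow", "deep"),
                              length_cm = seq(21, 45, 3)) |>
    dplyr::mutate(density = ifelse(stratum == "shallow", 120, 40) *
                    exp(-(length_cm - 30)^2 / 100))
  areas <- tibble::tibble(stratum = c("shallow", "deep"),
                          area_km2 = c(800, 2200))
  errs <- vapply(1:200, function(s) {
    g <- gen_survey_hauls(field, areas, n_hauls = 8, swept_km2 = 0.06,
                          seed = s)
    est <- standardize_survey_lf(g$hauls, g$lengths, areas)
    tot_est <- sum(est$density)
    tot_true <- sum(g$truth$density)
    tot_est - tot_true
  }, numeric(1))
  # unbiased: mean error within 2 standard errors of zero
  expect_lt(abs(mean(errs)), 2 * stats::sd(errs) / sqrt(length(errs)))
})

test_that("length binning and 6-year periods follow the survey convention", {
  d <- tidyr::expand_grid(year = 2002:2024, length_cm = c(20, 22, 31)) |>
    dplyr::mutate(density = 1)
  lf <- aggregate_lf(d)
  expect_setequal(unique(lf$period),
                  c("2002-2007", "2008-2013", "2014-2019", "2020-2024"))
  expect_setequal(unique(lf$bin), c(18, 21, 30))

  single <- aggregate_lf(dplyr::filter(d, year == 2010))
  expect_equal(unique(single$period), "2010-2010")

  # binning conserves total density within a year
  one <- dplyr::filter(d, year == 2002)
  expect_equal(sum(aggregate_lf(one)$density), sum(one$density))
  expect_error(aggregate_lf(d, bin_width = 0), "positive")
  expect_error(aggregate_lf(dplyr::filter(d, year %in% c(2002, 2010))),
               "contiguous")
})

test_that("the equilibrium LF model is monotone beyond full selection", {
  L <- seq(1.5, 58.5, 3)
  for (fk in c(0, 0.8, 2.5)) {
    p <- rajastat:::lbb_expected_lf(L, linf = 60, lc = 24, mk = 1.5, fk = fk)
    N <- p / rajastat:::lbb_selectivity(L, 24, 10 / 24)
    above <- L > 30  # comfortably past Lc
    expect_true(all(diff(N[above]) <= 1e-12))
  }
})

test_that("relative biomass declines with fishing and is 1 unexploited", {
  bb <- vapply(c(0, 0.5, 1, 2, 4), function(fk)
    rajastat:::lbb_bb0(60, 24, 1.5, fk), numeric(1))
  expect_equal(bb[1], 1, tolerance = 1e-9)
  expect_true(all(diff(bb) < 0))
  # mean catch length shrinks as fishing pressure rises
  lm_ <- vapply(c(0, 1, 3), function(fk)
    rajastat:::lbb_lmean(60, 24, 1.5, fk), numeric(1))
  expect_true(all(diff(lm_) < 0))
  expect_true(all(lm_ > 24 & lm_ < 60))
})

test_that("reference lengths follow their closed forms", {
  ref <- derived_reference_lengths(60, 1.5, 1)
  expect_equal(ref$lopt, 40)
  expect_equal(ref$lcopt, 60 * 5 / (2 * 4.5), tolerance = 1e-12)
  # unexploited limit: Lcopt sits strictly below Lopt
  ref0 <- derived_reference_lengths(60, 1.5, 0)
  expect_equal(ref0$lcopt, 60 * 2 / 4.5)
  expect_lt(ref0$lcopt, ref0$lopt)
})

test_that("noise-free length frequencies are recovered within 10%", {
  g <- gen_length_frequencies(linf = 60, mk = 1.5, fk = 1.5, lc = 24,
                              n_fish = Inf, seed = 1)
  fit <- fit_lbb(g$lf, n_eff = 10000, seed = 1)
  est <- fit$estimates[fit$estimates$period == "pooled", ]
  expect_equal(est$linf, 60, tolerance = 0.1)
  expect_equal(est$lc, 24, tolerance = 0.1)
  expect_equal(est$mk, 1.5, tolerance = 0.1)
  expect_equal(est$fk, 1.5, tolerance = 0.1)
  expect_equal(est$fm, 1.0, tolerance = 0.1)
})

test_that("the unexploited scenario yields F/M near 0 and B/B0 near 1", {
  g0 <- gen_length_frequencies(linf = 60, mk = 1.5, fk = 0, lc = 24,
                               n_fish = Inf, seed = 2)
  fit0 <- fit_lbb(g0$lf, n_eff = 10000, seed = 2)
  est <- fit0$estimates[fit0$estimates$period == "pooled", ]
  expect_lt(est$fm, 0.1)
  expect_gt(est$bb0, 0.9)
})

test_that("estimates are invariant to rescaling the length frequencies", {
  g <- gen_length_frequencies(n_fish = Inf, seed = 3)
  lf2 <- g$lf
  lf2$count <- lf2$count * 2
  attr(lf2, "bin_width") <- attr(g$lf, "bin_width")
  f1 <- fit_lbb(g$lf, n_eff = 2000, seed = 3)
  f2 <- fit_lbb(lf2, n_eff = 2000, seed = 3)
  expect_equal(f1$estimates$linf, f2$estimates$linf, tolerance = 1e-8)
  expect_equal(f1$estimates$fk, f2$estimates$fk, tolerance = 1e-8)
})

test_that("multinomial survey noise leaves parameters recoverable", {
  res <- purrr::map_dfr(1:10, function(s) {
    g <- gen_length_frequencies(linf = 60, mk = 1.5, fk = 1.5, lc = 24,
                                n_fish = 500, seed = s)
    fit <- fit_lbb(g$lf, seed = s)
    fit$estimates[fit$estimates$period == "pooled",
                  c("linf", "mk", "fk", "lc")]
  })
  expect_lt(abs(median(res$linf) / 60 - 1), 0.05)
  expect_lt(abs(median(res$mk) / 1.5 - 1), 0.25)
  expect_lt(abs(median(res$fk) / 1.5 - 1), 0.25)
})

test_that("degenerate length frequencies are rejected", {
  lf <- tibble::tibble(period = "p1", bin = c(24, 27, 30), count = c(5, 3, 1))
  expect_error(fit_lbb(lf), "at least 5")
})
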