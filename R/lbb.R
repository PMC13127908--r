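#' Swept-area standardization of survey length frequencies
#'
#' Converts haul-level length records to per-year density at length
#' (individuals per km2). Per-haul density is count divided by the swept area
#' (distance towed x horizontal wing spread); hauls are averaged within each
#' depth stratum (zero catches count), and stratum means are combined into a
#' global mean weighted by stratum surface area.
#'
#' @param hauls Tibble with columns `haul_id`, `year`, `stratum`,
#'   `distance_km`, `wingspread_km`.
#' @param lengths Long tibble with columns `haul_id`, `length_cm`, `count`.
#' @param stratum_areas Tibble with columns `stratum`, `area_km2`; every
#'   sampled stratum must have an area.
#' @return Tibble with columns `year`, `length_cm`, `density` (ind/km2,
#'   area-weighted over strata).
#' @export
standardize_survey_lf <- function(hauls, lengths, stratum_areas) {
  assert_that(all(hauls$distance_km > 0 & hauls$wingspread_km > 0),
              "zero swept area")
  assert_that(all(hauls$stratum %in% stratum_areas$stratum),
              "stratum without an area")
  hauls <- mutate(hauls, swept = .data$distance_km * .data$wingspread_km)
  n_hauls <- hauls |> count(.data$year, .data$stratum, name = "n_hauls")
  # per stratum-year mean density at length: sum over hauls of count/swept,
  # divided by the number of hauls (so hauls without that length count as 0)
  dens <- lengths |>
    left_join(select(hauls, "haul_id", "year", "stratum", "swept"),
              by = "haul_id") |>
    group_by(.data$year, .data$stratum, .data$length_cm) |>
    summarise(total = sum(.data$count / .data$swept), .groups = "drop") |>
    left_join(n_hauls, by = c("year", "stratum")) |>
    mutate(mean_density = .data$total / .data$n_hauls)
  areas <- mutate(stratum_areas, w = .data$area_km2 / sum(.data$area_km2))
  # area-weighted global mean; strata sampled in the year but lacking a
  # length class contribute zero, which the grouped sum realises implicitly
  dens |>
    left_join(select(areas, "stratum", "w"), by = "stratum") |>
    group_by(.data$year, .data$length_cm) |>
    summarise(density = sum(.data$mean_density * .data$w), .groups = "drop") |>
    arrange(.data$year, .data$length_cm)
}

# Period labels for contiguous years cut into blocks of `period_length`,
# the final block keeping the remainder (possibly short).
make_periods <- function(years, period_length) {
  y0 <- min(years)
  idx <- (years - y0) %/% period_length
  last <- max(idx)
  starts <- y0 + idx * period_length
  ends <- pmin(starts + period_length - 1, max(years))
  sprintf("%d-%d", starts, ends)
}

#' Aggregate densities at length into a binned multi-year matrix
#'
#' Pools per-year density-at-length into fixed-width length bins (default
#' 3 cm, lower edges at multiples of the width from 0) and multi-year periods
#' (default 6 years, the final period absorbing the remainder of the series
#' and therefore possibly shorter). Within a period the yearly densities are
#' averaged, so units stay ind/km2.
#'
#' @param density Tibble with columns `year`, `length_cm`, `density` (from
#'   [standardize_survey_lf()]).
#' @param bin_width Length-class width in cm (> 0; default 3).
#' @param period_length Period length in years (default 6).
#' @return Tibble with columns `period`, `bin` (lower edge, cm), `density`;
#'   attribute `bin_width`.
#' @export
#' @examples
#' d <- tibble::tibble(year = 2002:2024, length_cm = 30, density = 1)
#' unique(aggregate_lf(d)$period)
aggregate_lf <- function(density, bin_width = 3, period_length = 6) {
  assert_that(bin_width > 0, "bin_width must be positive")
  yrs <- sort(unique(density$year))
  assert_that(all(diff(yrs) == 1) || length(yrs) == 1, "years must be contiguous")
  binned <- density |>
    mutate(period = make_periods(.data$year, period_length),
           bin = floor(.data$length_cm / bin_width) * bin_width)
  yrs_per_period <- binned |>
    distinct(.data$period, .data$year) |>
    count(.data$period, name = "n_years")
  out <- binned |>
    group_by(.data$period, .data$bin) |>
    summarise(density = sum(.data$density), .groups = "drop") |>
    left_join(yrs_per_period, by = "period") |>
    mutate(density = .data$density / .data$n_years) |>
    select("period", "bin", "density") |>
    arrange(.data$period, .data$bin)
  structure(out, bin_width = bin_width)
}

# Logistic trawl selectivity; steepness tied to Lc.
lbb_selectivity <- function(L, Lc, alpha) 1 / (1 + exp(-alpha * (L - Lc)))

# Predicted relative catch-at-length over bin midpoints `L` (sorted):
# equilibrium survivorship recursion with total mortality exponent
# M/K + (F/K) S(L), times selectivity. Returns a vector proportional to the
# expected length-frequency; zero beyond Linf.
lbb_expected_lf <- function(L, linf, lc, mk, fk, alpha = 10 / lc) {
  nb <- length(L)
  S <- lbb_selectivity(L, lc, alpha)
  N <- numeric(nb)
  N[1] <- 1
  for (i in 2:nb) {
    if (linf <= L[i] || linf <= L[i - 1]) {
      N[i] <- 0
    } else {
      N[i] <- N[i - 1] * ((linf - L[i]) / (linf - L[i - 1]))^(mk + fk * S[i])
    }
  }
  p <- N * S
  if (sum(p) > 0) p / sum(p) else p
}

# Relative exploited biomass B/B0 by numerical cohort integration: fine
# length grid to Linf, survivorship under M/K (+ F/K S above Lc) from the
# continuous mortality-per-growth ODE, isometric weight L^b.
lbb_bb0 <- function(linf, lc, mk, fk, alpha = 10 / lc, b_exp = 3,
                    n_grid = 200) {
  L <- seq(0, linf * (1 - 1e-3), length.out = n_grid)
  dL <- L[2] - L[1]
  S <- lbb_selectivity(L, lc, alpha)
  haz_u <- mk / (linf - L)
  haz_e <- (mk + fk * S) / (linf - L)
  N_u <- exp(-cumsum(haz_u) * dL)
  N_e <- exp(-cumsum(haz_e) * dL)
  w <- L^b_exp / (linf - L)  # residence time per length increment
  sum(N_e * w) / sum(N_u * w)
}

# Predicted mean length in the catch (selectivity-weighted survivors).
lbb_lmean <- function(linf, lc, mk, fk, alpha = 10 / lc, n_grid = 200) {
  L <- seq(0, linf * (1 - 1e-3), length.out = n_grid)
  dL <- L[2] - L[1]
  S <- lbb_selectivity(L, lc, alpha)
  N <- exp(-cumsum((mk + fk * S) / (linf - L)) * dL)
  catch <- N * S / (linf - L)
  sum(L * catch) / sum(catch)
}

#' Optimal and optimal-capture reference lengths
#'
#' Closed-form reference lengths from asymptotic length and the mortality
#' ratios: `Lopt = Linf * 3 / (3 + M/K)` is the length at which an
#' unexploited cohort's biomass peaks, and
#' `Lcopt = Linf * (2 + 3 F/M) / ((1 + F/M) (3 + M/K))` the length at first
#' capture that maximises catch and biomass at the given fishing pressure.
#'
#' @param linf Asymptotic length (cm).
#' @param mk Natural mortality over somatic growth rate, M/K.
#' @param fm Fishing over natural mortality, F/M.
#' @return One-row tibble with columns `lopt` and `lcopt` (cm).
#' @export
#' @examples
#' derived_reference_lengths(60, 1.5, 1)  # lopt 40, lcopt 33.33
derived_reference_lengths <- function(linf, mk, fm) {
  tibble(lopt = linf * 3 / (3 + mk),
         lcopt = linf * (2 + 3 * fm) / ((1 + fm) * (3 + mk)))
}

# Log posterior for one period's LF at parameter vector th = (linf, lc, mk, fk).
lbb_logpost <- function(th, L, counts, priors, alpha_mult = 10) {
  linf <- th[1]; lc <- th[2]; mk <- th[3]; fk <- th[4]
  # large finite penalty (not -Inf) so optim's finite differences stay defined
  if (linf <= max(L) || lc <= 0 || lc >= linf || mk <= 0 || fk < 0) return(-1e10)
  p <- lbb_expected_lf(L, linf, lc, mk, fk, alpha = alpha_mult / lc)
  if (any(p <= 0 & counts > 0)) return(-1e10)
  ll <- sum(counts[p > 0] * log(p[p > 0]))
  lp <- dnorm(linf, priors$linf_mean, priors$linf_sd, log = TRUE) +
    dnorm(lc, priors$lc_mean, priors$lc_sd, log = TRUE) +
    dnorm(mk, priors$mk_mean, priors$mk_sd, log = TRUE)
  ll + lp
}

# Fit one period by posterior-mode search plus dense grid integration
# around the mode. Returns medians/CIs and a weight-resampled draw set for
# derived quantities.
lbb_fit_period <- function(L, counts, priors, n_grid = 11, n_draws = 1500,
                           seed = 1) {
  start <- c(priors$linf_mean, priors$lc_mean, priors$mk_mean, 1)
  lower <- c(max(L) + 0.25, min(L) * 0.5 + 0.1, 0.3, 0)
  upper <- c(priors$linf_mean * 2, max(L), 5, 8)
  start <- pmin(pmax(start, lower + 1e-6), upper - 1e-6)
  opt <- optim(start, function(th) -lbb_logpost(th, L, counts, priors),
               method = "L-BFGS-B", lower = lower, upper = upper,
               hessian = TRUE)
  sds <- sqrt(abs(diag(tryCatch(solve(opt$hessian), error = function(e)
    diag(4) * 0.04))))
  sds <- pmax(pmin(sds, (upper - lower) / 4), c(0.2, 0.1, 0.02, 0.02))
  axes <- lapply(1:4, function(i) {
    seq(max(lower[i], opt$par[i] - 4 * sds[i]),
        min(upper[i], opt$par[i] + 4 * sds[i]), length.out = n_grid)
  })
  grid <- as.matrix(expand.grid(axes))
  lp <- apply(grid, 1, lbb_logpost, L = L, counts = counts, priors = priors)
  w <- exp(lp - max(lp))
  w[!is.finite(w) | lp <= -1e9] <- 0
  idx <- with_seed(seed, sample.int(nrow(grid), n_draws, replace = TRUE,
                                    prob = w))
  draws <- tibble(linf = grid[idx, 1], lc = grid[idx, 2],
                  mk = grid[idx, 3], fk = grid[idx, 4]) |>
    mutate(fm = .data$fk / .data$mk)
  list(mode = setNames(opt$par, c("linf", "lc", "mk", "fk")), draws = draws)
}

#' Fit the length-based Bayesian biomass (LBB) model
#'
#' Fits, per period and pooled across periods, the equilibrium length-
#' frequency model
#' \deqn{N_{L_i} = N_{L_{i-1}} \left(\frac{L_\infty - L_i}
#'   {L_\infty - L_{i-1}}\right)^{M/K + (F/K) S_{L_i}}}
#' with logistic gear selectivity
#' \eqn{S_L = 1/(1 + e^{-\alpha (L - L_c)})} (steepness tied to `Lc`,
#' \eqn{\alpha = 10/L_c}), observed length frequencies entering as
#' multinomial counts of selected survivors \eqn{N_L S_L}.
#'
#' The posterior (normal priors on `Linf`, `Lc`, `M/K`; flat on `F/K`) is
#' explored by mode search followed by dense grid integration around the
#' mode; reported values are posterior medians with 95% credible intervals.
#' By default `Linf` is first estimated from the pooled length frequency and
#' the per-period fits receive a tightened `Linf` prior around that pooled
#' estimate (`pool_linf = FALSE` keeps fully independent per-period priors).
#' Derived quantities per draw: `F/M = (F/K)/(M/K)`, relative biomass `B/B0`
#' by numerical cohort integration of exploited vs unexploited biomass, the
#' predicted mean catch length, and the reference lengths of
#' [derived_reference_lengths()].
#'
#' @param lf Tibble with columns `period`, `bin` (lower edge, cm) and a value
#'   column `density` or `count`, e.g. from [aggregate_lf()] or
#'   [gen_length_frequencies()].
#' @param priors Optional named list overriding prior settings:
#'   `linf_mean`, `linf_cv` (default max observed length / 0.95, cv 0.1),
#'   `mk_mean`, `mk_cv` (default 1.5, cv 0.15), `lc_cv` (default 0.2 around
#'   the ascending limb's 50% point).
#' @param n_eff Effective multinomial sample size used when the value column
#'   is a density rather than counts (default 1000).
#' @param pool_linf Estimate `Linf` from the pooled LF and shrink per-period
#'   `Linf` priors towards it (default `TRUE`).
#' @param seed Integer seed (grid resampling of derived quantities).
#' @return An object of class `lbb_fit` with `estimates` (tibble, one row per
#'   period plus `"pooled"`: posterior medians and 95% CIs of `linf`, `lc`,
#'   `mk`, `fk`, `fm`, `bb0`, plus `lmean`, `lopt`, `lcopt`) and `draws`
#'   (named list of per-period posterior draw tibbles).
#' @export
fit_lbb <- function(lf, priors = list(), n_eff = 1000, pool_linf = TRUE,
                    seed = 1) {
  val_col <- if ("count" %in% names(lf)) "count" else "density"
  assert_that(val_col %in% names(lf), "need a count or density column")
  bin_w <- attr(lf, "bin_width") %||% {
    bs <- sort(unique(lf$bin))
    if (length(bs) > 1) min(diff(bs)) else 3
  }
  periods <- unique(lf$period)
  # integer-valued counts are used as multinomial counts; densities (or
  # non-integer scaled frequencies) are normalized to n_eff pseudo-counts
  is_counts <- val_col == "count" &&
    all(abs(lf[[val_col]] - round(lf[[val_col]])) < 1e-9)
  per_data <- lapply(periods, function(p) {
    d <- lf[lf$period == p & lf[[val_col]] > 0, ]
    d <- d[order(d$bin), ]
    if (nrow(d) < 5) abort(paste0("degenerate length frequency in period ", p,
                                  ": need at least 5 non-empty bins"))
    v <- d[[val_col]]
    list(L = d$bin + bin_w / 2,
         counts = if (is_counts) v else v / sum(v) * n_eff)
  })
  names(per_data) <- periods
  pooled <- {
    agg <- lf |>
      group_by(.data$bin) |>
      summarise(v = sum(.data[[val_col]]), .groups = "drop") |>
      filter(.data$v > 0) |>
      arrange(.data$bin)
    list(L = agg$bin + bin_w / 2,
         counts = if (is_counts) agg$v else agg$v / sum(agg$v) * n_eff)
  }
  default_priors <- function(L, counts) {
    lmax <- max(L)
    asc <- which(counts >= max(counts) / 2)[1]
    lc0 <- L[max(asc, 1)]
    list(linf_mean = priors$linf_mean %||% (lmax / 0.95),
         linf_sd = (priors$linf_mean %||% (lmax / 0.95)) *
           (priors$linf_cv %||% 0.1),
         mk_mean = priors$mk_mean %||% 1.5,
         mk_sd = (priors$mk_mean %||% 1.5) * (priors$mk_cv %||% 0.15),
         lc_mean = lc0, lc_sd = lc0 * (priors$lc_cv %||% 0.2))
  }
  pooled_fit <- lbb_fit_period(pooled$L, pooled$counts,
                               default_priors(pooled$L, pooled$counts),
                               seed = seed)
  fits <- purrr::imap(per_data, function(d, p) {
    pr <- default_priors(d$L, d$counts)
    if (pool_linf) {
      pr$linf_mean <- median(pooled_fit$draws$linf)
      pr$linf_sd <- pr$linf_mean * 0.05
    }
    lbb_fit_period(d$L, d$counts, pr, seed = seed + match(p, periods))
  })
  fits <- c(fits, list(pooled = pooled_fit))
  summarise_fit <- function(f, p) {
    dr <- f$draws |>
      mutate(bb0 = purrr::pmap_dbl(list(.data$linf, .data$lc, .data$mk,
                                        .data$fk), lbb_bb0),
             lmean = purrr::pmap_dbl(list(.data$linf, .data$lc, .data$mk,
                                          .data$fk), lbb_lmean))
    med <- function(x) median(x)
    lo <- function(x) quantile(x, 0.025, names = FALSE)
    hi <- function(x) quantile(x, 0.975, names = FALSE)
    ref <- derived_reference_lengths(med(dr$linf), med(dr$mk),
                                     med(dr$fm))
    tibble(period = p,
           linf = med(dr$linf), linf_lci = lo(dr$linf), linf_uci = hi(dr$linf),
           lc = med(dr$lc), lc_lci = lo(dr$lc), lc_uci = hi(dr$lc),
           mk = med(dr$mk), mk_lci = lo(dr$mk), mk_uci = hi(dr$mk),
           fk = med(dr$fk), fk_lci = lo(dr$fk), fk_uci = hi(dr$fk),
           fm = med(dr$fm), fm_lci = lo(dr$fm), fm_uci = hi(dr$fm),
           bb0 = med(dr$bb0), bb0_lci = lo(dr$bb0), bb0_uci = hi(dr$bb0),
           lmean = med(dr$lmean), lopt = ref$lopt, lcopt = ref$lcopt)
  }
  estimates <- purrr::imap_dfr(fits, function(f, p) summarise_fit(f, p))
  structure(list(estimates = estimates,
                 draws = purrr::map(fits, "draws"),
                 modes = purrr::map(fits, "mode"),
                 meta = list(n_eff = n_eff, pool_linf = pool_linf,
                             seed = seed, backend = "mode + dense grid")),
            class = "lbb_fit")
}

#' @export
#' @rdname fit_lbb
#' @param x,object An `lbb_fit` object.
#' @param ... Unused.
print.lbb_fit <- function(x, ...) {
  cat("Length-based Bayesian biomass fit (", x$meta$backend, ")\n", sep = "")
  print(select(x$estimates, "period", "linf", "lc", "mk", "fk", "fm", "bb0",
               "lmean", "lopt", "lcopt"))
  invisible(x)
}

#' Tidy per-period LBB estimates
#'
#' @inheritParams print.lbb_fit
#' @return Long tibble: `period`, `term`, `estimate`, `lci`, `uci`.
#' @export
tidy.lbb_fit <- function(x, ...) {
  purrr::map_dfr(c("linf", "lc", "mk", "fk", "fm", "bb0"), function(term) {
    tibble(period = x$estimates$period, term = term,
           estimate = x$estimates[[term]],
           lci = x$estimates[[paste0(term, "_lci")]],
           uci = x$estimates[[paste0(term, "_uci")]])
  }) |> arrange(.data$period)
}

#' One-row summary of an LBB fit (final period)
#'
#' @inheritParams print.lbb_fit
#' @return One-row tibble: `n_periods`, final-period `fm`, `bb0`, `lmean`,
#'   `lopt`, `lcopt`.
#' @export
glance.lbb_fit <- function(x, ...) {
  est <- filter(x$estimates, .data$period != "pooled")
  fin <- est[nrow(est), ]
  tibble(n_periods = nrow(est), fm = fin$fm, bb0 = fin$bb0,
         lmean = fin$lmean, lopt = fin$lopt, lcopt = fin$lcopt)
}

#' Plot LBB stock-status trajectories
#'
#' Per-period posterior medians and 95% CIs of relative fishing pressure
#' (F/M, with the F = M reference line) and relative biomass (B/B0).
#'
#' @inheritParams print.lbb_fit
#' @return A ggplot object.
#' @export
autoplot.lbb_fit <- function(object, ...) {
  est <- filter(object$estimates, .data$period != "pooled")
  long <- dplyr::bind_rows(
    tibble(period = est$period, metric = "F/M", estimate = est$fm,
           lci = est$fm_lci, uci = est$fm_uci, ref = 1),
    tibble(period = est$period, metric = "B/B0", estimate = est$bb0,
           lci = est$bb0_lci, uci = est$bb0_uci, ref = NA_real_))
  ggplot2::ggplot(long, ggplot2::aes(.data$period, .data$estimate,
                                     group = 1)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lci, ymax = .data$uci),
                         alpha = 0.25) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::geom_hline(ggplot2::aes(yintercept = .data$ref),
                        linetype = "dashed", na.rm = TRUE) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}
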