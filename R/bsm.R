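#' Simulate a Schaefer surplus-production biomass trajectory
#'
#' Iterates the Schaefer dynamics
#' \deqn{B_{t+1} = B_t + r B_t (1 - B_t/k) - C_t}
#' optionally perturbed by multiplicative lognormal process error
#' (mean-corrected, so `sigma_proc = 0` recovers the deterministic
#' recurrence). Biomass is floored at `1e-6 * k` so infeasibly large catches
#' cannot drive the state negative; hitting the floor is recorded.
#'
#' @param r Intrinsic growth rate (1/yr).
#' @param k Carrying capacity (catch units).
#' @param catches Numeric vector of annual catches \eqn{C_t}.
#' @param B0 Initial biomass (> 0).
#' @param sigma_proc Process-error standard deviation on the log scale.
#' @param seed Optional seed (RNG state restored).
#' @return Numeric vector of length `length(catches) + 1` (biomass at the
#'   start of each year plus the final state), with attribute `hit_floor`.
#' @export
#' @examples
#' simulate_schaefer(0.2, 1000, rep(50, 5), B0 = 900)
simulate_schaefer <- function(r, k, catches, B0, sigma_proc = 0, seed = NULL) {
  assert_that(B0 > 0, "B0 must be positive")
  T <- length(catches)
  eps <- if (sigma_proc > 0) {
    with_seed(seed, rnorm(T, -sigma_proc^2 / 2, sigma_proc))
  } else rep(0, T)
  B <- numeric(T + 1)
  B[1] <- B0
  floor_b <- 1e-6 * k
  hit <- FALSE
  for (t in seq_len(T)) {
    b <- B[t] + r * B[t] * (1 - B[t] / k) - catches[t]
    if (b < floor_b) {
      b <- floor_b
      hit <- TRUE
    }
    B[t + 1] <- b * exp(eps[t])
  }
  structure(B, hit_floor = hit)
}

#' Fit the Bayesian state-space Schaefer model
#'
#' Fits the Schaefer surplus-production model to an annual catch series and a
#' (possibly gappy) CPUE index. Priors follow the usual data-poor
#' configuration:
#' * `r` log-uniform on the supplied resilience window;
#' * `k` log-uniform on `[max(C)/r_hi, 4 max(C)/r_lo]`;
#' * `q` log-uniform on a generous data-derived window;
#' * relative biomass `B/k` constrained by hard windows at anchor years
#'   (`bk_priors`); the first-year window also serves as the prior for the
#'   initial state;
#' * `sigma_proc`, `sigma_obs` half-normal with scale 0.1.
#'
#' The state-space model has multiplicative lognormal process error on the
#' Schaefer dynamics and observation model
#' `log cpue_t ~ Normal(log(q B_t), sigma_obs)`. The marginal likelihood
#' over the process-error sequence is computed by an extended Kalman filter
#' on the scalar log-biomass state (exact when `sigma_proc = 0`; a mild
#' linearization otherwise). Catchability `q` is sampled jointly with the
#' other parameters. Parameter vectors whose trajectory hits the biomass
#' floor (an infeasible catch history) or whose filtered state violates a
#' `B/k` window receive zero weight.
#'
#' Because the posterior over `(r, k)` is a narrow curved ridge inside a
#' wide prior, plain prior sampling is hopeless. The sampler therefore
#' (i) locates the posterior mode by multi-start quasi-Newton search,
#' (ii) refines a kernel-mixture (population Monte Carlo) proposal over a
#' few importance stages, each defensively mixed with 25% prior draws, and
#' (iii) computes final importance weights, reporting their effective
#' sample size (warning when below `min_ess`, or when the posterior piles
#' up against the `r` prior boundary). Posterior draws are obtained by
#' weighted resampling; their biomass trajectories are drawn with a
#' forward-filter backward-sampling pass on the linearized state space.
#'
#' @param data Tibble with columns `year`, `catch` and `cpue` (`cpue` may be
#'   `NA` in gap years); at least 10 years.
#' @param r_prior Length-2 vector, the resilience window `(lo, hi)`.
#' @param bk_priors Tibble with columns `year`, `lo`, `hi` giving hard
#'   relative-biomass windows (at least one; anchor years must be in the
#'   series).
#' @param n_draws Number of parameter draws per importance stage.
#' @param n_stages Number of kernel-mixture refinement stages.
#' @param n_resample Number of posterior draws kept after resampling.
#' @param min_ess Effective-sample-size threshold below which a warning is
#'   raised.
#' @param seed Integer seed (RNG state restored).
#' @return An object of class `bsm_fit`: a list with `draws` (tibble of
#'   `r`, `k`, `q`, `sigma_obs`, `sigma_proc`, `msy`, `fmsy`, `bmsy`),
#'   `biomass` (draws x years+1 matrix), `years`, `catch`, `cpue`, `ess`,
#'   `n_draws` and `meta`.
#' @export
fit_bsm <- function(data, r_prior = c(0.05, 0.5), bk_priors,
                    n_draws = 12000, n_stages = 5, n_resample = 3000,
                    min_ess = 1000, seed = 1) {
  assert_that(all(c("year", "catch", "cpue") %in% names(data)),
              "data needs columns year, catch, cpue")
  assert_that(nrow(data) >= 10, "need at least 10 years")
  assert_that(any(data$catch > 0), "all-zero catch series")
  assert_that(!is.unsorted(data$year, strictly = TRUE),
              "years must be strictly increasing")
  assert_that(all(bk_priors$lo > 0 & bk_priors$lo < bk_priors$hi &
                    bk_priors$hi <= 1), "invalid B/k windows")
  assert_that(all(bk_priors$year %in% c(data$year, max(data$year) + 1L)),
              "B/k anchor year outside the series")
  years <- data$year
  catches <- data$catch
  cpue <- data$cpue
  obs_idx <- which(!is.na(cpue))
  assert_that(length(obs_idx) >= 3, "need at least 3 CPUE observations")
  Tn <- length(catches)
  maxC <- max(catches)
  k_lo <- maxC / r_prior[2]
  k_hi <- 4 * maxC / r_prior[1]
  start_win <- bk_priors[bk_priors$year == years[1], , drop = FALSE]
  b0_win <- if (nrow(start_win) > 0) c(start_win$lo[1], start_win$hi[1]) else c(0.25, 1)
  win_idx <- match(bk_priors$year, c(years, max(years) + 1L))
  # generous data-derived support for log q (q ~ cpue / biomass)
  q_rng <- log(c(min(cpue, na.rm = TRUE) / (10 * k_hi),
                 10 * max(cpue, na.rm = TRUE) / (1e-3 * k_lo)))

  # parameter vector th: (log r, log k, b0 fraction, log q, sigma_proc,
  # sigma_obs)
  half_scale <- 0.1
  lb <- c(log(r_prior[1]), log(k_lo), b0_win[1], q_rng[1], 0, 1e-3)
  ub <- c(log(r_prior[2]), log(k_hi), b0_win[2], q_rng[2], Inf, Inf)
  # fully normalized prior density: needed because the proposal mixes
  # kernels with the prior, so constants do not cancel in the weights
  log_unif_const <- -sum(log(ub[1:4] - lb[1:4]))
  log_prior <- function(th) {
    ok <- rep(TRUE, nrow(th))
    for (d in 1:4) ok <- ok & th[, d] >= lb[d] & th[, d] <= ub[d]
    ok <- ok & th[, 5] >= 0 & th[, 6] >= lb[6]
    lp <- rep(-Inf, nrow(th))
    lp[ok] <- log_unif_const +
      log(2) + dnorm(th[ok, 5], 0, half_scale, log = TRUE) +
      log(2) + dnorm(th[ok, 6], 0, half_scale, log = TRUE)
    lp
  }
  sample_prior <- function(n) {
    cbind(runif(n, lb[1], ub[1]), runif(n, lb[2], ub[2]),
          runif(n, lb[3], ub[3]), runif(n, lb[4], ub[4]),
          abs(rnorm(n, 0, half_scale)),
          pmax(abs(rnorm(n, 0, half_scale)), lb[6]))
  }

  # Extended Kalman filter on x = log B, vectorized over parameter draws.
  # Returns the marginal log-likelihood; with record = TRUE also the
  # filtered/predicted moments and linearization slopes needed by the
  # backward sampler.
  ekf <- function(th, record = FALSE) {
    n <- nrow(th)
    r <- exp(th[, 1]); k <- exp(th[, 2]); logq <- th[, 4]
    sp2 <- th[, 5]^2; so2 <- th[, 6]^2
    floor_b <- 1e-6 * k
    x <- log(th[, 3] * k)  # initial state, no uncertainty
    P <- numeric(n)
    ll <- numeric(n)
    ok <- rep(TRUE, n)
    xf <- Pf <- matrix(NA_real_, n, Tn + 1)
    xp <- Pp <- aa <- matrix(NA_real_, n, Tn)
    obs_upd <- function(t_idx) {
      if (!(t_idx %in% obs_idx)) return(invisible(NULL))
      y <- log(cpue[t_idx])
      S <- P + so2
      ll <<- ll + dnorm(y, logq + x, sqrt(S), log = TRUE)
      K <- P / S
      x <<- x + K * (y - logq - x)
      P <<- (1 - K) * P
    }
    win_chk <- function(t_idx) {
      wi <- which(win_idx == t_idx)
      if (length(wi)) {
        frac <- exp(x) / k
        ok <<- ok & frac >= bk_priors$lo[wi[1]] & frac <= bk_priors$hi[wi[1]]
      }
    }
    obs_upd(1L); win_chk(1L)
    if (record) { xf[, 1] <- x; Pf[, 1] <- P }
    for (t in seq_len(Tn)) {
      B <- exp(x)
      f <- B + r * B * (1 - B / k) - catches[t]
      bad <- f < floor_b
      ok <- ok & !bad
      f[bad] <- floor_b[bad]
      a <- B * (1 + r - 2 * r * B / k) / f  # d log f / d x
      x <- log(f) - sp2 / 2
      P <- a^2 * P + sp2
      if (record) { xp[, t] <- x; Pp[, t] <- P; aa[, t] <- a }
      obs_upd(t + 1L); win_chk(t + 1L)
      if (record) { xf[, t + 1] <- x; Pf[, t + 1] <- P }
    }
    ll[!ok] <- -Inf
    if (record) list(ll = ll, xf = xf, Pf = Pf, xp = xp, Pp = Pp, aa = aa)
    else ll
  }
  # Backward simulation sampler on the linearized state space: one biomass
  # trajectory per parameter draw, conditional on all observations.
  ffbs <- function(fl, n) {
    x_draw <- matrix(NA_real_, n, Tn + 1)
    x_draw[, Tn + 1] <- rnorm(n, fl$xf[, Tn + 1], sqrt(pmax(fl$Pf[, Tn + 1], 0)))
    for (t in rev(seq_len(Tn))) {
      J <- fl$Pf[, t] * fl$aa[, t] / pmax(fl$Pp[, t], 1e-300)
      J[fl$Pp[, t] <= 0] <- 0
      m <- fl$xf[, t] + J * (x_draw[, t + 1] - fl$xp[, t])
      v <- pmax(fl$Pf[, t] - J * fl$aa[, t] * fl$Pf[, t], 0)
      x_draw[, t] <- rnorm(n, m, sqrt(v))
    }
    exp(x_draw)
  }
  # posterior-mode search (deterministic likelihood surface) for the
  # proposal's starting point
  neg_post <- function(th1) {
    if (any(th1 < lb[c(1:4, 6)]) || any(th1 > pmin(ub[c(1:4, 6)], 1e300)))
      return(1e10)
    th6 <- matrix(c(th1[1:4], 0, th1[5]), 1)
    v <- -(ekf(th6) + log_prior(th6))
    if (!is.finite(v)) 1e10 else v
  }
  ess_of <- function(logw) {
    if (all(!is.finite(logw))) return(0)
    w <- exp(logw - max(logw[is.finite(logw)]))
    w[!is.finite(w)] <- 0
    sum(w)^2 / sum(w^2)
  }

  res <- with_seed(seed, {
    mix_p <- 0.25
    min_sd <- c(0.02, 0.02, 0.01, 0.02, 0.004, 0.004)
    # (i) multi-start mode search
    best <- NULL
    for (i in seq_len(8)) {
      st <- lb[c(1:4, 6)] + runif(5) * (pmin(ub[c(1:4, 6)], c(ub[1:4], 0.5)) -
                                          lb[c(1:4, 6)])
      st[5] <- 0.1
      o <- tryCatch(optim(st, neg_post, method = "Nelder-Mead",
                          control = list(maxit = 400)),
                    error = function(e) NULL)
      if (!is.null(o) && (is.null(best) || o$value < best$value)) best <- o
    }
    if (is.null(best) || best$value >= 1e10) {
      abort("no feasible draws: priors exclude every catch-consistent trajectory")
    }
    mode6 <- c(best$par[1:4], 0.02, best$par[5])
    # (ii) kernel-mixture refinement; stage 1 kernels sit on the mode
    cent <- matrix(mode6, 1)
    S_emp <- diag(c(0.05, 0.05, 0.02, 0.05, 0.01, 0.01)^2)
    th <- NULL; logw <- NULL
    max_stages <- n_stages + 5L  # keep refining while ESS lags the target
    stage <- 0L
    repeat {
      stage <- stage + 1L
      h <- if (stage == 1) 1 else 0.35
      ch <- tryCatch(chol(S_emp * h + diag(min_sd^2)),
                     error = function(e) diag(sqrt(diag(S_emp) * h + min_sd^2)))
      n_kern <- round(n_draws * (1 - mix_p))
      pick <- sample.int(nrow(cent), n_kern, replace = TRUE)
      th <- rbind(cent[pick, , drop = FALSE] +
                    t(t(ch) %*% matrix(rnorm(6 * n_kern), 6)),
                  sample_prior(n_draws - n_kern))
      th[, 5] <- abs(th[, 5])  # reflect sigma_proc at zero
      lp <- log_prior(th)
      # mixture density: kernels + prior
      dens <- numeric(n_draws)
      ld_const <- -sum(log(diag(ch))) - 3 * log(2 * pi)
      for (j in seq_len(nrow(cent))) {
        z <- forwardsolve(t(ch), t(th) - cent[j, ])
        zr <- forwardsolve(t(ch), t(th * c(1, 1, 1, 1, -1, 1)[col(th)]) -
                             cent[j, ])  # reflection image in sigma_proc
        dens <- dens + exp(-colSums(z^2) / 2 + ld_const) +
          exp(-colSums(zr^2) / 2 + ld_const)
      }
      dens <- dens / nrow(cent)
      pr_dens <- exp(lp)
      lq <- log((1 - mix_p) * dens + mix_p * pr_dens)
      ll <- ekf(th)
      logw <- lp + ll - lq
      logw[!is.finite(lp)] <- -Inf
      if (all(!is.finite(logw))) {
        abort("no feasible draws: priors exclude every catch-consistent trajectory")
      }
      if ((stage >= n_stages && ess_of(logw) >= min_ess) ||
            stage >= max_stages) break
      w <- exp(logw - max(logw[is.finite(logw)]))
      w[!is.finite(w)] <- 0
      wn <- w / sum(w)
      n_cent <- min(500, n_draws)
      cent <- th[sample.int(n_draws, n_cent, replace = TRUE, prob = w), ,
                 drop = FALSE]
      m <- colSums(th * wn)
      d <- sweep(th, 2, m)
      S_emp <- crossprod(d * sqrt(wn), d * sqrt(wn))
    }
    ess <- ess_of(logw)
    w <- exp(logw - max(logw[is.finite(logw)]))
    w[!is.finite(w)] <- 0
    idx <- sample.int(n_draws, n_resample, replace = TRUE, prob = w)
    th_post <- th[idx, , drop = FALSE]
    fl <- ekf(th_post, record = TRUE)
    B_post <- ffbs(fl, nrow(th_post))
    list(r = exp(th_post[, 1]), k = exp(th_post[, 2]),
         q = exp(th_post[, 4]), sigma_proc = th_post[, 5],
         sigma_obs = th_post[, 6], B = B_post, ess = ess)
  })

  if (res$ess < min_ess) {
    warn(sprintf("effective sample size %.0f below %d; summaries may be unstable",
                 res$ess, min_ess))
  }
  near <- function(x, bound) mean(abs(log(x) - log(bound)) < 0.05 * diff(log(r_prior)))
  if (near(res$r, r_prior[1]) > 0.25 || near(res$r, r_prior[2]) > 0.25) {
    warn("posterior for r piles up at a prior boundary; the prior window may exclude the truth")
  }
  draws <- tibble(r = res$r, k = res$k, q = res$q,
                  sigma_obs = res$sigma_obs, sigma_proc = res$sigma_proc) |>
    mutate(msy = .data$r * .data$k / 4, fmsy = .data$r / 2, bmsy = .data$k / 2)
  structure(list(draws = draws, biomass = res$B, years = years,
                 catch = catches, cpue = cpue, ess = res$ess,
                 n_draws = n_draws,
                 meta = list(q = "sampled jointly; log-uniform prior on a data-derived window",
                             likelihood = "extended Kalman filter on log-biomass (exact at sigma_proc = 0)",
                             r_prior = r_prior, k_prior = c(k_lo, k_hi),
                             bk_priors = bk_priors, seed = seed)),
            class = "bsm_fit")
}

#' Per-year stock-status reference points from a BSM fit
#'
#' Computes, per posterior draw and year, relative biomass
#' \eqn{B_t/B_{MSY}} (with \eqn{B_{MSY} = k/2}) and relative fishing
#' mortality \eqn{F_t/F_{MSY}} (with \eqn{F_t = C_t/B_t},
#' \eqn{F_{MSY} = r/2}), and summarises them by the posterior median and 95%
#' interval.
#'
#' @param fit A `bsm_fit` object.
#' @return Tibble with columns `year`, `b_bmsy`, `b_bmsy_lci`, `b_bmsy_uci`,
#'   `f_fmsy`, `f_fmsy_lci`, `f_fmsy_uci`.
#' @export
reference_points <- function(fit) {
  T <- length(fit$years)
  Bt <- fit$biomass[, seq_len(T), drop = FALSE]
  bb <- Bt / (fit$draws$k / 2)
  ff <- sweep(1 / Bt, 2, fit$catch, `*`) / (fit$draws$r / 2)
  q <- function(m, p) apply(m, 2, quantile, p, names = FALSE)
  tibble(year = fit$years,
         b_bmsy = q(bb, 0.5), b_bmsy_lci = q(bb, 0.025), b_bmsy_uci = q(bb, 0.975),
         f_fmsy = q(ff, 0.5), f_fmsy_lci = q(ff, 0.025), f_fmsy_uci = q(ff, 0.975))
}

#' Kobe-quadrant posterior probabilities
#'
#' For a given year, the fraction of posterior draws falling in each quadrant
#' of the Kobe plot: `green` (B/Bmsy > 1, F/Fmsy <= 1, sustainably
#' exploited), `yellow` (B <= Bmsy, F <= Fmsy, recovering), `orange`
#' (B > Bmsy, F > Fmsy, overfishing of a healthy stock) and `red`
#' (B <= Bmsy, F > Fmsy, overfished and overfishing). The four probabilities
#' sum to 1.
#'
#' @param fit A `bsm_fit` object.
#' @param year Year of interest (defaults to the final year).
#' @return One-row tibble: `year`, `green`, `yellow`, `orange`, `red`.
#' @export
kobe_probabilities <- function(fit, year = max(fit$years)) {
  t_idx <- match(year, fit$years)
  assert_that(!is.na(t_idx), "year not in the fitted series")
  Bt <- fit$biomass[, t_idx]
  bb <- Bt / (fit$draws$k / 2)
  ff <- (fit$catch[t_idx] / Bt) / (fit$draws$r / 2)
  tibble(year = year,
         green = mean(bb > 1 & ff <= 1),
         yellow = mean(bb <= 1 & ff <= 1),
         orange = mean(bb > 1 & ff > 1),
         red = mean(bb <= 1 & ff > 1))
}

#' @export
#' @rdname fit_bsm
#' @param x,object A `bsm_fit` object.
#' @param ... Unused.
print.bsm_fit <- function(x, ...) {
  cat("Bayesian state-space Schaefer fit\n")
  cat(sprintf("  years: %d-%d (%d yr), posterior draws: %d, ESS: %.0f\n",
              min(x$years), max(x$years), length(x$years),
              nrow(x$draws), x$ess))
  s <- tidy(x)
  print(s, n = nrow(s))
  invisible(x)
}

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy posterior parameter summaries of a BSM fit
#'
#' @inheritParams print.bsm_fit
#' @return Tibble with one row per parameter (`r`, `k`, `q`, `msy`, `fmsy`,
#'   `bmsy`): posterior `estimate` (median), `lci`, `uci` (95% interval).
#' @export
tidy.bsm_fit <- function(x, ...) {
  purrr::map_dfr(c("r", "k", "q", "msy", "fmsy", "bmsy"), function(p) {
    v <- x$draws[[p]]
    tibble(term = p, estimate = median(v),
           lci = quantile(v, 0.025, names = FALSE),
           uci = quantile(v, 0.975, names = FALSE))
  })
}

#' One-row fit diagnostics of a BSM fit
#'
#' @inheritParams print.bsm_fit
#' @return One-row tibble: `n_years`, `n_obs_cpue`, `n_draws`, `ess`,
#'   `b_bmsy_final`, `f_fmsy_final`.
#' @export
glance.bsm_fit <- function(x, ...) {
  rp <- reference_points(x)
  tibble(n_years = length(x$years),
         n_obs_cpue = sum(!is.na(x$cpue)),
         n_draws = nrow(x$draws),
         ess = x$ess,
         b_bmsy_final = rp$b_bmsy[nrow(rp)],
         f_fmsy_final = rp$f_fmsy[nrow(rp)])
}

#' Kobe plot of a BSM fit
#'
#' Posterior-median stock trajectory in the (B/Bmsy, F/Fmsy) plane with the
#' final-year posterior cloud, on the conventional four-colour quadrant
#' background.
#'
#' @inheritParams print.bsm_fit
#' @return A ggplot object.
#' @export
autoplot.bsm_fit <- function(object, ...) {
  rp <- reference_points(object)
  t_fin <- length(object$years)
  cloud <- tibble(
    bb = object$biomass[, t_fin] / (object$draws$k / 2),
    ff = (object$catch[t_fin] / object$biomass[, t_fin]) / (object$draws$r / 2))
  lim_x <- max(2, rp$b_bmsy, cloud$bb)
  lim_y <- max(2, rp$f_fmsy, cloud$ff)
  quad <- tibble(xmin = c(0, 1, 0, 1), xmax = c(1, lim_x, 1, lim_x),
                 ymin = c(1, 1, 0, 0), ymax = c(lim_y, lim_y, 1, 1),
                 fill = c("red", "orange", "yellow", "green"))
  ggplot2::ggplot() +
    ggplot2::geom_rect(data = quad,
                       ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax,
                                    ymin = .data$ymin, ymax = .data$ymax),
                       fill = quad$fill, alpha = 0.35) +
    ggplot2::geom_point(data = cloud, ggplot2::aes(.data$bb, .data$ff),
                        alpha = 0.08, size = 0.4) +
    ggplot2::geom_path(data = rp, ggplot2::aes(.data$b_bmsy, .data$f_fmsy)) +
    ggplot2::geom_point(data = rp[nrow(rp), ],
                        ggplot2::aes(.data$b_bmsy, .data$f_fmsy), size = 2) +
    ggplot2::labs(x = expression(B/B[MSY]), y = expression(F/F[MSY])) +
    ggplot2::coord_cartesian(xlim = c(0, lim_x), ylim = c(0, lim_y),
                             expand = FALSE) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
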