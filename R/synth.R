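#' Generate a haplotype-structured COI alignment with known diversity
#'
#' Builds an alignment of `sum(haplotype_counts)` sequences from as many
#' template haplotypes as there are counts. The first haplotype is a random
#' sequence; each further haplotype differs from the first at
#' `mutations_per_haplotype` fresh sites (mutation sites are drawn without
#' replacement across haplotypes, so every pairwise distance is exactly the
#' sum of the two mutation loads). The true haplotype and nucleotide
#' diversity implied by the construction are computed from the defining
#' formulas and returned as ground truth.
#'
#' @param length Number of alignment sites.
#' @param haplotype_counts Integer vector of copies per haplotype.
#' @param mutations_per_haplotype Sites at which each non-reference haplotype
#'   differs from the reference.
#' @param seed Integer seed (RNG state restored).
#' @param path Optional path; when given, the alignment is also written as
#'   FASTA.
#' @return A list with `alignment` (a validated alignment tibble),
#'   `truth` (list: `nh`, `assignment`, `h`, `pi`) and `path` (or `NULL`).
#' @export
gen_alignment <- function(length = 591, haplotype_counts = c(26, 1, 1),
                          mutations_per_haplotype = 1, seed = 1,
                          path = NULL) {
  k <- base::length(haplotype_counts)
  assert_that(all(haplotype_counts >= 1), "haplotype counts must be positive")
  m_total <- (k - 1) * mutations_per_haplotype
  assert_that(m_total < length, "not enough sites for the requested mutations")
  out <- with_seed(seed, {
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, length, replace = TRUE)
    mut_sites <- sample.int(length, m_total)  # without replacement
    haps <- vector("list", k)
    haps[[1]] <- ref
    for (i in seq_len(k - 1)) {
      h <- ref
      sites <- mut_sites[((i - 1) * mutations_per_haplotype + 1):
                           (i * mutations_per_haplotype)]
      for (s in sites) h[s] <- sample(setdiff(bases, h[s]), 1)
      haps[[i + 1]] <- h
    }
    haps
  })
  n <- sum(haplotype_counts)
  assignment <- rep(seq_len(k), haplotype_counts)
  seqs <- vapply(out[assignment], paste, character(1), collapse = "")
  aln <- as_alignment(tibble(
    id = sprintf("synth_%03d_h%d", seq_len(n), assignment), seq = seqs))
  # truth from the defining formulas on the constructed frequencies/distances
  p <- haplotype_counts / n
  h_true <- if (n >= 2) n / (n - 1) * (1 - sum(p^2)) else 0
  dist_to_ref <- c(0, rep(mutations_per_haplotype, k - 1))
  pi_true <- 0
  if (k > 1 && n >= 2) {
    for (i in seq_len(k - 1)) {
      for (j in (i + 1):k) {
        d_ij <- if (i == 1) dist_to_ref[j] else dist_to_ref[i] + dist_to_ref[j]
        pi_true <- pi_true + 2 * p[i] * p[j] * d_ij / length
      }
    }
    pi_true <- n / (n - 1) * pi_true
  }
  if (!is.null(path)) {
    set <- Biostrings::BStringSet(setNames(aln$seq, aln$id))
    Biostrings::writeXStringSet(set, path, width = 70)
  }
  list(alignment = aln,
       truth = list(nh = k, assignment = assignment, h = h_true, pi = pi_true),
       path = path)
}

#' Generate a Schaefer catch/CPUE series with known parameters
#'
#' Simulates a biomass trajectory under the Schaefer dynamics and observes it
#' through a noisy CPUE index `cpue = q * B * lognormal(sigma_obs)`.
#' Catch rules: `"constant"` (a fixed catch, default the MSY), `"effort_ramp"`
#' (fishing mortality rising to a peak about two-thirds of the way through
#' the series, then falling — the rise-then-fall history typical of a
#' developing then managed fleet), or `"fixed_f"` (constant exploitation
#' rate).
#'
#' @param r,k,q,B0 True parameters and initial biomass (`B0` defaults to
#'   `k`).
#' @param sigma_proc,sigma_obs Log-scale process and observation error sds.
#' @param catch_rule One of `"constant"`, `"effort_ramp"`, `"fixed_f"`.
#' @param constant_catch Catch used by the constant rule (default `r*k/4`).
#' @param f_peak,f_final Exploitation rates shaping the effort ramp.
#' @param years Integer vector of calendar years.
#' @param seed Integer seed (RNG state restored).
#' @return A list with `data` (tibble: `year`, `catch`, `cpue`) and `truth`
#'   (list: parameters plus the biomass trajectory `B`, length
#'   `length(years) + 1`).
#' @export
gen_schaefer_series <- function(r = 0.25, k = 1000, q = 0.001, B0 = k,
                                sigma_proc = 0, sigma_obs = 0.1,
                                catch_rule = c("effort_ramp", "constant",
                                               "fixed_f"),
                                constant_catch = r * k / 4,
                                f_peak = 0.9 * r, f_final = 0.3 * r,
                                years = 1985:2024, seed = 1) {
  catch_rule <- match.arg(catch_rule)
  assert_that(all(c(r, k, q, B0) > 0), "parameters must be positive")
  T <- length(years)
  out <- with_seed(seed, {
    eps_p <- if (sigma_proc > 0) rnorm(T, -sigma_proc^2 / 2, sigma_proc) else
      rep(0, T)
    f_t <- switch(catch_rule,
      constant = NULL,
      fixed_f = rep(f_peak, T),
      effort_ramp = {
        t_peak <- ceiling(2 * T / 3)
        c(seq(0.1 * r, f_peak, length.out = t_peak),
          seq(f_peak, f_final, length.out = T - t_peak + 1)[-1])
      })
    B <- numeric(T + 1)
    B[1] <- B0
    catch <- numeric(T)
    floor_b <- 1e-6 * k
    for (t in seq_len(T)) {
      catch[t] <- if (catch_rule == "constant") constant_catch else f_t[t] * B[t]
      b <- B[t] + r * B[t] * (1 - B[t] / k) - catch[t]
      if (b < floor_b) {
        abort("catch rule drives biomass to the floor; scenario rejected")
      }
      B[t + 1] <- b * exp(eps_p[t])
    }
    obs <- if (sigma_obs > 0) exp(rnorm(T, -sigma_obs^2 / 2, sigma_obs)) else
      rep(1, T)
    list(B = B, catch = catch, cpue = q * B[seq_len(T)] * obs)
  })
  list(data = tibble(year = years, catch = out$catch, cpue = out$cpue),
       truth = list(r = r, k = k, q = q, B0 = B0, sigma_proc = sigma_proc,
                    sigma_obs = sigma_obs, catch_rule = catch_rule,
                    B = out$B))
}

#' Generate multinomial length frequencies from the LBB equilibrium model
#'
#' Draws, for each period, `n_fish` individual lengths from the equilibrium
#' length-frequency model of [fit_lbb()] (survivorship recursion times
#' logistic selectivity) over bins of `bin_width` cm, and returns the binned
#' counts together with the generating parameters as ground truth.
#'
#' @param linf,mk,fk,lc True parameters (`lc < linf`).
#' @param alpha Selectivity steepness (default `10 / lc`).
#' @param n_fish Individuals sampled per period (< 50 draws a warning: fits
#'   on such samples are unstable). `Inf` returns the exact expected
#'   (noise-free) frequencies scaled to 1000.
#' @param periods Character vector of period labels.
#' @param bin_width Length-class width in cm.
#' @param seed Integer seed (RNG state restored).
#' @return A list with `lf` (tibble: `period`, `bin`, `count`, attribute
#'   `bin_width`) and `truth` (the generating parameters).
#' @export
gen_length_frequencies <- function(linf = 60, mk = 1.5, fk = 1.5, lc = 24,
                                   alpha = 10 / lc, n_fish = 500,
                                   periods = c("2002-2007", "2008-2013",
                                               "2014-2019", "2020-2024"),
                                   bin_width = 3, seed = 1) {
  assert_that(lc < linf, "lc must be below linf")
  if (is.finite(n_fish) && n_fish < 50) {
    warn("n_fish < 50: length-based fits are likely unstable")
  }
  bins <- seq(0, ceiling(linf / bin_width) * bin_width - bin_width,
              by = bin_width)
  mids <- bins + bin_width / 2
  keep <- mids < linf
  p <- lbb_expected_lf(mids[keep], linf, lc, mk, fk, alpha)
  counts <- if (is.finite(n_fish)) {
    with_seed(seed, {
      purrr::map(periods, ~ as.numeric(rmultinom(1, n_fish, p)))
    })
  } else {
    rep(list(p * 1000), length(periods))
  }
  lf <- purrr::map2_dfr(periods, counts, function(pr, ct) {
    tibble(period = pr, bin = bins[keep], count = ct)
  })
  list(lf = structure(lf, bin_width = bin_width),
       truth = list(linf = linf, mk = mk, fk = fk, lc = lc, alpha = alpha,
                    fm = fk / mk, n_fish = n_fish))
}

#' Generate stratified survey hauls from a known density field
#'
#' Simulates trawl hauls in depth strata whose true density-at-length is
#' given, drawing per-haul counts as Poisson with mean density times swept
#' area. Useful for validating the swept-area standardization: the
#' area-weighted stratified estimator should recover the area-weighted true
#' density.
#'
#' @param density_field Tibble with columns `stratum`, `length_cm`,
#'   `density` (true ind/km2).
#' @param stratum_areas Tibble with columns `stratum`, `area_km2`.
#' @param n_hauls Hauls per stratum per year.
#' @param years Integer vector of survey years.
#' @param swept_km2 Mean swept area per haul (split into distance x spread).
#' @param seed Integer seed (RNG state restored).
#' @return A list with `hauls`, `lengths` (inputs for
#'   [standardize_survey_lf()]) and `truth` (the area-weighted true density
#'   per length).
#' @export
gen_survey_hauls <- function(density_field, stratum_areas, n_hauls = 10,
                             years = 2020, swept_km2 = 0.05, seed = 1) {
  strata <- unique(density_field$stratum)
  hauls <- tidyr::expand_grid(year = years, stratum = strata,
                              rep = seq_len(n_hauls)) |>
    mutate(haul_id = sprintf("H%s_%s_%02d", .data$year, .data$stratum,
                             .data$rep),
           distance_km = swept_km2 / 0.02, wingspread_km = 0.02) |>
    select("haul_id", "year", "stratum", "distance_km", "wingspread_km")
  lengths <- with_seed(seed, {
    hauls |>
      left_join(density_field, by = "stratum",
                relationship = "many-to-many") |>
      mutate(count = stats::rpois(n(), .data$density * swept_km2)) |>
      filter(.data$count > 0) |>
      select("haul_id", "length_cm", "count")
  })
  w <- stratum_areas$area_km2 / sum(stratum_areas$area_km2)
  truth <- density_field |>
    left_join(tibble(stratum = stratum_areas$stratum, w = w),
              by = "stratum") |>
    group_by(.data$length_cm) |>
    summarise(density = sum(.data$density * .data$w), .groups = "drop")
  list(hauls = hauls, lengths = lengths, truth = truth)
}

#' Generate a synthetic gridded bathymetry
#'
#' Regular lon-lat grid whose depth increases linearly with longitude from
#' `depth_range[1]` to `depth_range[2]`, so all four trawl-fishery strata
#' (50-800 m) are present in known longitude bands.
#'
#' @param lon0,lat0 Grid origin (cell-centre coordinates).
#' @param cell Cell size in degrees.
#' @param ncol,nrow Grid dimensions.
#' @param depth_range Depth at the west and east edges (m).
#' @return A bathymetry list (`lon0`, `lat0`, `cell`, `depth` matrix) usable
#'   with [lookup_depth()].
#' @export
gen_bathymetry <- function(lon0 = 2, lat0 = 39, cell = 0.01, ncol = 100,
                           nrow = 50, depth_range = c(55, 795)) {
  prof <- seq(depth_range[1], depth_range[2], length.out = ncol)
  list(lon0 = lon0, lat0 = lat0, cell = cell,
       depth = matrix(prof, nrow, ncol, byrow = TRUE))
}

#' Generate VMS pings and a fleet registry with ground-truth labels
#'
#' Simulates a trawl fleet emitting roughly 12 pings per vessel-day. For each
#' vessel-day, 1-3 depth strata are chosen as the day's fishing strategy; a
#' known fraction of pings is emitted while fishing (speed uniform in the
#' trawling band 2-3.6 kn, position inside the chosen strata's longitude
#' bands of the synthetic bathymetry), the remainder while steaming (speed
#' uniform in 5-12 kn, well clear of the band; optionally an ambiguous
#' boundary band for edge-case tests). A vessel-month registry with constant
#' horsepower accompanies the pings.
#'
#' @param n_vessels Number of vessels.
#' @param n_days Number of consecutive days from `start_date`.
#' @param start_date First day (Date or string).
#' @param bathy Bathymetry from [gen_bathymetry()].
#' @param fishing_fraction Fraction of pings emitted while fishing, in
#'   `[0, 1]`.
#' @param pings_per_day Pings per vessel-day (default 12, one every two
#'   hours).
#' @param ambiguous If `TRUE`, steaming pings are instead drawn from the
#'   boundary bands `[1.8, 2)` and `(3.6, 4]`.
#' @param hp Horsepower per vessel (recycled).
#' @param seed Integer seed (RNG state restored).
#' @return A list with `pings` (tibble: `vessel_id`, `timestamp`, `date`,
#'   `lon`, `lat`, `speed`, `depth`, `is_fishing`), `fleet` (vessel-month
#'   registry: `vessel_id`, `year`, `month`, `hp`, `time_weight`) and
#'   `truth` (per vessel-day strata sets and the expected stratum-day
#'   allocation).
#' @export
gen_vms_and_fleet <- function(n_vessels = 5, n_days = 30,
                              start_date = "2022-03-01",
                              bathy = gen_bathymetry(),
                              fishing_fraction = 0.4, pings_per_day = 12,
                              ambiguous = FALSE, hp = 300, seed = 1) {
  assert_that(fishing_fraction >= 0 && fishing_fraction <= 1,
              "fishing_fraction must be in [0, 1]")
  start_date <- as.Date(start_date)
  dates <- start_date + seq_len(n_days) - 1
  hp <- rep_len(hp, n_vessels)
  # longitude band of each stratum on the synthetic shelf profile
  prof <- bathy$depth[1, ]
  lons <- bathy$lon0 + (seq_along(prof) - 1) * bathy$cell
  strata <- levels(assign_stratum(100))
  stratum_lons <- lapply(strata, function(s) lons[which(assign_stratum(prof) == s)])
  names(stratum_lons) <- strata
  lat_rng <- bathy$lat0 + c(0, (nrow(bathy$depth) - 1) * bathy$cell)
  n_fish <- round(pings_per_day * fishing_fraction)
  out <- with_seed(seed, {
    days <- tidyr::expand_grid(vessel_id = sprintf("V%02d", seq_len(n_vessels)),
                               date = dates)
    days$k_strata <- sample(1:3, nrow(days), replace = TRUE)
    days$strata <- purrr::map(days$k_strata, ~ sort(sample(strata, .x)))
    pings <- purrr::pmap_dfr(days, function(vessel_id, date, k_strata, strata) {
      is_fishing <- c(rep(TRUE, n_fish), rep(FALSE, pings_per_day - n_fish))
      day_strata <- strata[((seq_len(n_fish) - 1) %% k_strata) + 1]
      lon <- numeric(pings_per_day)
      lon[is_fishing] <- vapply(day_strata, function(s)
        sample(stratum_lons[[s]], 1), numeric(1))
      lon[!is_fishing] <- runif(sum(!is_fishing), min(lons), max(lons))
      speed <- numeric(pings_per_day)
      speed[is_fishing] <- runif(n_fish, 2, 3.6)
      speed[!is_fishing] <- if (ambiguous) {
        ifelse(runif(pings_per_day - n_fish) < 0.5,
               runif(pings_per_day - n_fish, 1.8, 2 - 1e-9),
               runif(pings_per_day - n_fish, 3.6 + 1e-9, 4))
      } else runif(pings_per_day - n_fish, 5, 12)
      tibble(vessel_id = vessel_id,
             timestamp = as.POSIXct(date, tz = "UTC") +
               3600 * seq(0, by = 2, length.out = pings_per_day),
             date = date,
             lon = lon,
             lat = runif(pings_per_day, lat_rng[1], lat_rng[2]),
             speed = speed,
             is_fishing = is_fishing)
    })
    list(days = days, pings = pings)
  })
  pings <- mutate(out$pings, depth = lookup_depth(.data$lon, .data$lat, bathy))
  months <- unique(format(dates, "%Y-%m"))
  fleet <- tidyr::expand_grid(vessel_id = sprintf("V%02d", seq_len(n_vessels)),
                              ym = months) |>
    mutate(year = as.integer(substr(.data$ym, 1, 4)),
           month = as.integer(substr(.data$ym, 6, 7)),
           hp = hp[as.integer(substr(.data$vessel_id, 2, 3))],
           time_weight = 1) |>
    select("vessel_id", "year", "month", "hp", "time_weight")
  truth_days <- if (n_fish > 0) {
    out$days |>
      mutate(used = purrr::map(.data$strata, ~ unique(.x[((seq_len(n_fish) - 1) %%
                                                            length(.x)) + 1]))) |>
      tidyr::unnest("used") |>
      group_by(.data$vessel_id, .data$date) |>
      mutate(fraction = 1 / n()) |>
      ungroup() |>
      mutate(year = as.integer(format(.data$date, "%Y"))) |>
      group_by(.data$year, stratum = .data$used) |>
      summarise(days = sum(.data$fraction), .groups = "drop")
  } else tibble(year = integer(), stratum = character(), days = numeric())
  list(pings = pings, fleet = fleet,
       truth = list(day_strata = out$days, stratum_days = truth_days,
                    n_fishing = sum(pings$is_fishing)))
}
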