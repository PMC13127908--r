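#' Standardized fishing-effort series from a vessel-month registry
#'
#' Monthly effort is the sum over active vessels of actual engine horsepower
#' weighted by the permitted time at sea; annual effort is the sum of the
#' monthly estimates. Using actual (not nominal) horsepower and the permitted
#' time multiplier folds engine-related technological creep into the effort
#' unit; other creep components (navigation, gear efficiency) are not
#' modelled.
#'
#' @param months Tibble with columns `vessel_id`, `year`, `month`, `hp`
#'   (actual horsepower, > 0) and `time_weight` (permitted time-at-sea
#'   multiplier, >= 0).
#' @return Per-year tibble with columns `year` and `effort` (HP units).
#' @export
effort_series <- function(months) {
  assert_that(nrow(months) >= 1, "empty vessel-month registry")
  assert_that(all(months$hp > 0), "horsepower must be positive")
  assert_that(all(months$time_weight >= 0), "time_weight must be non-negative")
  months |>
    group_by(.data$year, .data$month) |>
    summarise(monthly = sum(.data$hp * .data$time_weight), .groups = "drop") |>
    group_by(.data$year) |>
    summarise(effort = sum(.data$monthly), .groups = "drop") |>
    arrange(.data$year)
}

#' Catch-per-unit-effort series
#'
#' Joins annual catch and effort by year and computes CPUE = catch / effort.
#' Years with zero effort yield `NA` CPUE (flagged, never coerced to zero).
#'
#' @param catch Tibble with columns `year`, `catch`.
#' @param effort Tibble with columns `year`, `effort` (e.g. from
#'   [effort_series()]).
#' @return Tibble with columns `year`, `catch`, `effort`, `cpue`, sorted by
#'   year.
#' @export
cpue_series <- function(catch, effort) {
  assert_that(setequal(catch$year, effort$year),
              "catch and effort year sets differ")
  left_join(catch, effort, by = "year") |>
    mutate(cpue = ifelse(.data$effort > 0, .data$catch / .data$effort,
                         NA_real_)) |>
    arrange(.data$year)
}

#' Filter VMS pings to fishing activity
#'
#' Retains pings whose instantaneous speed lies within the trawling band
#' (default 2-3.6 kn, both ends inclusive) and, when a fishing-grounds mask
#' is supplied, whose position falls inside the grounds. Order is preserved
#' and the operation is idempotent.
#'
#' @param pings Tibble with at least a `speed` column (knots); `lon`/`lat`
#'   required when a mask is used.
#' @param speed_min,speed_max Inclusive speed bounds in knots.
#' @param mask Optional fishing-grounds predicate `function(lon, lat)`
#'   returning a logical vector; `NULL` keeps all positions.
#' @return The filtered ping tibble.
#' @export
filter_vms <- function(pings, speed_min = 2.0, speed_max = 3.6, mask = NULL) {
  keep <- pings$speed >= speed_min & pings$speed <= speed_max
  if (!is.null(mask)) keep <- keep & mask(pings$lon, pings$lat)
  pings[keep, , drop = FALSE]
}

#' Assign a depth to a bathymetric stratum
#'
#' Strata are the trawl-fishery depth bands: continental shelf 50-100 m,
#' shelf break 100-200 m, upper slope 200-500 m, middle slope 500-800 m.
#' Intervals are half-open `[lo, hi)` with the last closed at 800 m, so each
#' boundary depth belongs to exactly one stratum. Depths outside 50-800 m
#' return `NA`.
#'
#' @param depth Numeric vector of depths (m, positive down).
#' @return Factor with levels `shelf`, `shelf_break`, `upper_slope`,
#'   `middle_slope`.
#' @export
assign_stratum <- function(depth) {
  cut(depth, breaks = c(50, 100, 200, 500, 800),
      labels = c("shelf", "shelf_break", "upper_slope", "middle_slope"),
      right = FALSE, include.lowest = TRUE)
}

#' Allocate fractional fishing days to depth strata
#'
#' Daily trips can exploit several depth strata (e.g. a shelf haul followed by
#' a middle-slope haul). A vessel-day whose fishing pings span k distinct
#' strata therefore contributes 1/k of a fishing day to each stratum; yearly
#' totals are aggregated per stratum. Pings whose depth falls outside the
#' 50-800 m range are dropped with a warning (their count is attached as
#' attribute `n_dropped`).
#'
#' @param pings Fishing pings (after [filter_vms()]) with columns `vessel_id`,
#'   `date` (or `timestamp`, from which the calendar date is taken) and
#'   `depth` (m).
#' @return Tibble with columns `year`, `stratum`, `days` (fractional fishing
#'   days); attribute `n_dropped` counts out-of-range pings.
#' @export
allocate_fishing_days <- function(pings) {
  if (!"date" %in% names(pings)) {
    assert_that("timestamp" %in% names(pings), "need a date or timestamp column")
    pings$date <- as.Date(pings$timestamp)
  }
  pings$stratum <- assign_stratum(pings$depth)
  n_dropped <- sum(is.na(pings$stratum))
  if (n_dropped > 0) {
    warn(paste0(n_dropped, " ping(s) outside the 50-800 m range dropped"))
    pings <- pings[!is.na(pings$stratum), , drop = FALSE]
  }
  out <- pings |>
    mutate(year = as.integer(format(.data$date, "%Y"))) |>
    distinct(.data$vessel_id, .data$date, .data$year, .data$stratum) |>
    group_by(.data$vessel_id, .data$date, .data$year) |>
    mutate(fraction = 1 / n()) |>
    ungroup() |>
    group_by(.data$year, .data$stratum) |>
    summarise(days = sum(.data$fraction), .groups = "drop") |>
    arrange(.data$year, .data$stratum)
  structure(out, n_dropped = n_dropped)
}

#' Linear trend in fishing days
#'
#' Ordinary least-squares regression of yearly fishing days on year, for one
#' stratum or for the total across strata, with the two-sided test on the
#' slope.
#'
#' @param days Tibble from [allocate_fishing_days()] (columns `year`,
#'   `stratum`, `days`).
#' @param stratum A stratum name, or `"total"` to sum across strata first.
#' @return One-row tibble: `stratum`, `slope` (days/yr), `intercept`,
#'   `r_squared`, `p_value`, `n_years`.
#' @export
stratum_trend <- function(days, stratum = "total") {
  d <- if (identical(stratum, "total")) {
    days |> group_by(.data$year) |> summarise(days = sum(.data$days), .groups = "drop")
  } else {
    days |> filter(.data$stratum == !!stratum) |> select("year", "days")
  }
  if (nrow(d) < 3) abort("need at least 3 years for a trend")
  if (stats::var(d$days) < 1e-12 * max(1, mean(d$days)^2)) {
    # constant series: no trend; lm would return numerical noise here
    return(tibble(stratum = stratum, slope = 0,
                  intercept = mean(d$days), r_squared = 0,
                  p_value = NA_real_, n_years = nrow(d)))
  }
  fit <- lm(days ~ year, data = d)
  sm <- suppressWarnings(summary(fit))
  tibble(stratum = stratum,
         slope = unname(coef(fit)["year"]),
         intercept = unname(coef(fit)["(Intercept)"]),
         r_squared = sm$r.squared,
         p_value = unname(sm$coefficients["year", "Pr(>|t|)"]),
         n_years = nrow(d))
}

#' Nearest-cell depth lookup on a gridded bathymetry
#'
#' Looks positions up in a regular lon-lat depth grid (as produced by
#' [gen_bathymetry()]): each position takes the depth of the nearest cell
#' centre. Positions outside the grid return `NA`.
#'
#' @param lon,lat Numeric position vectors.
#' @param bathy A bathymetry list with elements `lon0`, `lat0`, `cell`,
#'   `depth` (matrix, rows = lat index, cols = lon index).
#' @return Numeric vector of depths (m).
#' @export
lookup_depth <- function(lon, lat, bathy) {
  i <- round((lat - bathy$lat0) / bathy$cell) + 1L
  j <- round((lon - bathy$lon0) / bathy$cell) + 1L
  ok <- i >= 1L & i <= nrow(bathy$depth) & j >= 1L & j <= ncol(bathy$depth)
  out <- rep(NA_real_, length(lon))
  out[ok] <- bathy$depth[cbind(i[ok], j[ok])]
  out
}
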