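#' Configuration for the synthetic hourly-series generator
#'
#' Parameters controlling the seeded synthetic emulation of one or more
#' grid cells of hourly surface meteorology: a diurnal and seasonal solar
#' cycle (so convective and stable hours both occur), temperature and
#' sensible heat correlated with the solar flux, physically plausible flux,
#' wind and humidity ranges, a configurable rate of out-of-bound extremes,
#' zero-latent-heat hours (exercising the Bowen median fallback), and
#' injected missing hours.
#'
#' @param seed Integer seed governing all randomness.
#' @param n_days Number of simulated days.
#' @param grid_rows,grid_cols Grid dimensions.
#' @param cell_spacing Grid spacing, m.
#' @param solar_peak Peak clear-sky visible beam flux, W/m^2.
#' @param temp_base Annual-mean 2 m temperature, degrees C.
#' @param temp_seasonal_amp,temp_diurnal_amp Seasonal/diurnal temperature
#'   amplitudes, degrees C.
#' @param wind_sd Standard deviation of each 10 m wind component, m/s.
#' @param oob_rate Fraction of hours given one value outside the
#'   Scenario-2 physical bounds.
#' @param zero_latent_rate Fraction of hours whose latent heat flux is set
#'   to exactly zero.
#' @param missing_hours Integer positions (1-based hour indices) removed
#'   from each cell's series.
#' @param start First UTC hour of the series.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(seed = 1L, n_days = 365L, grid_rows = 1L,
                         grid_cols = 1L, cell_spacing = 3000,
                         solar_peak = 800, temp_base = 12,
                         temp_seasonal_amp = 12, temp_diurnal_amp = 6,
                         wind_sd = 2.5, oob_rate = 0.02,
                         zero_latent_rate = 0.05,
                         missing_hours = integer(0),
                         start = "2019-01-01") {
  stopifnot(n_days >= 1L, grid_rows >= 1L, grid_cols >= 1L,
            oob_rate >= 0, oob_rate <= 1,
            zero_latent_rate >= 0, zero_latent_rate <= 1)
  structure(list(seed = as.integer(seed), n_days = as.integer(n_days),
                 grid_rows = as.integer(grid_rows),
                 grid_cols = as.integer(grid_cols),
                 cell_spacing = cell_spacing, solar_peak = solar_peak,
                 temp_base = temp_base,
                 temp_seasonal_amp = temp_seasonal_amp,
                 temp_diurnal_amp = temp_diurnal_amp, wind_sd = wind_sd,
                 oob_rate = oob_rate, zero_latent_rate = zero_latent_rate,
                 missing_hours = as.integer(missing_hours), start = start),
            class = "synth_config")
}

# one cell's hourly series under the configured climate
generate_one_cell <- function(cfg, z0_cell) {
  n <- cfg$n_days * 24L
  ts <- seq(as.POSIXct(paste(cfg$start, "00:00:00"), tz = "UTC"),
            by = "hour", length.out = n)
  hod <- as.integer(format(ts, "%H", tz = "UTC"))
  doy <- as.integer(format(ts, "%j", tz = "UTC"))
  season <- cos(2 * pi * (doy - 172) / 365.25)      # 1 near solstice
  day_shape <- pmax(0, sin(pi * (hod - 6) / 12))    # 0 outside 06-18
  clearness <- clamp(stats::rbeta(n, 6, 1.5), 0.15, 1)
  vis_beam <- cfg$solar_peak * (0.65 + 0.35 * season) * day_shape * clearness
  vis_beam[vis_beam < 1] <- 0                        # true night zeros
  down_sw <- vis_beam * 1.12 + ifelse(vis_beam > 0, 25, 0)
  alb_true <- stats::runif(1, 0.14, 0.24)
  up_sw <- alb_true * down_sw * stats::runif(n, 0.95, 1.05)
  temp <- cfg$temp_base - cfg$temp_seasonal_amp * season * -1 +
    cfg$temp_diurnal_amp * sin(pi * (hod - 9) / 12) + stats::rnorm(n, 0, 1.2)
  down_lw <- 300 + 2.2 * temp + stats::rnorm(n, 0, 12)
  up_lw <- 320 + 3.0 * temp + stats::rnorm(n, 0, 8)
  latent <- pmax(0, 0.30 * down_sw + stats::rnorm(n, 5, 10))
  latent[stats::runif(n) < cfg$zero_latent_rate] <- 0
  H <- 0.32 * (down_sw - up_sw) - 22 + stats::rnorm(n, 0, 8)
  H <- clamp(H, -60, 780)
  ground <- 0.10 * (down_sw + down_lw - up_sw - up_lw) + stats::rnorm(n, 0, 5)
  u <- stats::rnorm(n, 1.2, cfg$wind_sd)
  v <- stats::rnorm(n, 0.4, cfg$wind_sd)
  speed <- sqrt(u^2 + v^2)
  u_star <- clamp(0.035 + 0.075 * speed + stats::rnorm(n, 0, 0.02), 0.01, 1.9)
  pbl <- clamp(ifelse(vis_beam > 0,
                      250 + 2800 * day_shape * clearness *
                        (0.6 + 0.4 * season) + stats::rnorm(n, 0, 80),
                      80 + 250 * stats::runif(n)), 25, 3900)
  z_im <- clamp(9000 + 1500 * season + stats::rnorm(n, 0, 400), 4000, 15000)
  rh <- clamp(70 - 1.2 * (temp - cfg$temp_base) + stats::rnorm(n, 0, 8),
              2, 100)
  pres <- 101325 + stats::rnorm(n, 0, 350)
  cloud <- clamp(100 * (1 - clearness) + stats::rnorm(n, 0, 5), 0, 100)
  precip <- ifelse(stats::runif(n) < 0.06, stats::rexp(n, 1 / 1.5), 0)
  tibble::tibble(
    timestamp = ts,
    sensible_heat = H, friction_velocity = u_star, pbl_height = pbl,
    equilibrium_geopotential_height = z_im,
    surface_roughness = rep(z0_cell, n),
    latent_heat = latent, ground_heat = ground,
    temperature_2m = temp, relative_humidity_2m = rh,
    wind_u_10m = u, wind_v_10m = v, wind_speed_10m = speed,
    downward_shortwave = down_sw, upward_shortwave = up_sw,
    downward_longwave = down_lw, upward_longwave = up_lw,
    visible_beam_downward_flux = vis_beam,
    surface_pressure = pres, total_cloud_cover = cloud,
    precip_1h = precip, fill_flag = "observed")
}

# push one value of one bounded field outside its Scenario-2 limit
inject_extremes <- function(series, rate, bounds = scenario_bounds()) {
  n <- nrow(series)
  n_inject <- round(rate * n)
  if (n_inject == 0L) return(series)
  rows <- sample.int(n, n_inject)
  fields <- sample(c("sensible_heat", "latent_heat", "friction_velocity",
                     "surface_roughness", "pbl_height"),
                   n_inject, replace = TRUE)
  for (k in seq_len(n_inject)) {
    f <- fields[k]
    hi <- if (f == "pbl_height") bounds$mixing_height_max else bounds[[f]][2]
    lo <- if (f == "pbl_height") NA_real_ else bounds[[f]][1]
    # u* and z0 are non-negative in raw forecast output; only their upper
    # bound can plausibly be exceeded
    above <- is.na(lo) || f %in% c("friction_velocity", "surface_roughness") ||
      stats::runif(1) < 0.7
    series[[f]][rows[k]] <- if (above) hi * stats::runif(1, 1.1, 1.6)
      else lo - abs(lo) * stats::runif(1, 0.1, 0.6) - 5
  }
  attr(series, "injected_rows") <- sort(rows)
  series
}

#' Generate seeded synthetic hourly surface meteorology
#'
#' Produces one hourly field set per grid cell under the configured
#' climate, deterministic for a fixed seed. Out-of-bound extremes are
#' injected at `cfg$oob_rate` (rows recorded in the `injected_rows`
#' attribute of each series) and `cfg$missing_hours` are removed.
#'
#' @param cfg A [synth_config()].
#' @return A list with `series` (list of hourly field tibbles, one per
#'   cell, named `cell_1` ...) and `grid` (a planar [grid_spec()]).
#' @export
generate_hourly_series <- function(cfg = synth_config()) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(cfg$seed)
  n_cells <- cfg$grid_rows * cfg$grid_cols
  centers <- expand.grid(
    x = (seq_len(cfg$grid_cols) - 1) * cfg$cell_spacing,
    y = (seq_len(cfg$grid_rows) - 1) * cfg$cell_spacing)
  grid <- grid_spec(centers, cfg$cell_spacing, coords = "projected")
  z0 <- stats::runif(n_cells, 0.03, 1.2)
  series <- lapply(seq_len(n_cells), function(i) {
    s <- generate_one_cell(cfg, z0[i])
    s <- inject_extremes(s, cfg$oob_rate)
    drop <- cfg$missing_hours[cfg$missing_hours <= nrow(s)]
    if (length(drop)) s <- s[-drop, ]
    s
  })
  names(series) <- paste0("cell_", seq_len(n_cells))
  list(series = series, grid = grid)
}

#' Generate paired daily prediction/observation series across sites
#'
#' Emulates matched site-day pairs of dispersion predictions and monitor
#' observations (ppb) with a tunable target correlation, site locations
#' spread across the continental-US coordinate range, station distances
#' covering all five evaluation strata, and the site covariates used in
#' the performance regression (land-use percentages, elevation, traffic,
#' mean concentration).
#'
#' @param seed Integer seed.
#' @param n_sites Number of monitoring sites (>= 5 recommended so every
#'   stratum is populated).
#' @param n_days Days per site.
#' @param agreement Target Pearson correlation between predictions and
#'   observations, in `[0, 1]`; 1 gives identical series.
#' @return A tibble of site-days with `site_id`, `date`, `predicted`,
#'   `observed`, `site_lat`, `site_lon`, `station_distance` (km),
#'   `median_aadt` and covariate columns.
#' @export
generate_paired_series <- function(seed = 1L, n_sites = 50L, n_days = 60L,
                                   agreement = 0.8) {
  stopifnot(agreement >= 0, agreement <= 1, n_sites >= 1L, n_days >= 2L)
  set.seed(seed)
  strata_lo <- c(0, 2, 10, 20, 35)
  strata_hi <- c(2, 10, 20, 35, 60)
  k <- rep_len(seq_len(5L), n_sites)
  sites <- tibble::tibble(
    site_id = sprintf("site_%03d", seq_len(n_sites)),
    site_lat = stats::runif(n_sites, 25, 48),
    site_lon = stats::runif(n_sites, -122, -70),
    station_distance = stats::runif(n_sites, strata_lo[k], strata_hi[k]),
    pct_high_density = stats::runif(n_sites, 0, 30),
    pct_low_med_density = stats::runif(n_sites, 0, 50),
    pct_forest = stats::runif(n_sites, 0, 60),
    pct_agriculture = stats::runif(n_sites, 0, 50),
    elevation_mean = stats::runif(n_sites, 0, 2000),
    elevation_sd = stats::runif(n_sites, 0, 300),
    median_aadt = stats::runif(n_sites, 500, 150000),
    mean_no2 = stats::runif(n_sites, 2, 20))
  dates <- as.Date("2019-01-01") + seq_len(n_days) - 1L
  pairs <- tidyr::crossing(sites, date = dates)
  n <- nrow(pairs)
  z_obs <- stats::rnorm(n)
  observed <- pmax(0.1, pairs$mean_no2 + 4 * z_obs)
  z_obs <- (observed - mean(observed)) / stats::sd(observed)
  z_pred <- agreement * z_obs +
    sqrt(1 - agreement^2) * stats::rnorm(n)
  predicted <- mean(observed) + stats::sd(observed) * z_pred
  if (agreement == 1) predicted <- observed
  pairs$observed <- observed
  pairs$predicted <- pmax(0, predicted)
  pairs[, c("site_id", "date", "predicted", "observed", "site_lat",
            "site_lon", "station_distance", "median_aadt",
            "pct_high_density", "pct_low_med_density", "pct_forest",
            "pct_agriculture", "elevation_mean", "elevation_sd",
            "mean_no2")]
}
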