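# construct a small, fully in-bounds hourly field set with a crude diurnal
# cycle; any column can be overridden by name
make_hours <- function(n = 24, start = "2019-06-01", ...) {
  ts <- seq(as.POSIXct(paste(start, "00:00:00"), tz = "UTC"),
            by = "hour", length.out = n)
  hod <- as.integer(format(ts, "%H", tz = "UTC"))
  day <- hod >= 6 & hod <= 18
  tb <- tibble::tibble(
    timestamp = ts,
    sensible_heat = ifelse(day, 150, -20),
    friction_velocity = 0.3,
    pbl_height = ifelse(day, 1200, 200),
    equilibrium_geopotential_height = 9000,
    surface_roughness = 0.2,
    latent_heat = ifelse(day, 120, 10),
    ground_heat = ifelse(day, 40, -5),
    temperature_2m = 20,
    relative_humidity_2m = 60,
    wind_u_10m = 1,
    wind_v_10m = 1,
    wind_speed_10m = sqrt(2),
    downward_shortwave = ifelse(day, 500, 0),
    upward_shortwave = ifelse(day, 100, 0),
    downward_longwave = 330,
    upward_longwave = 360,
    visible_beam_downward_flux = ifelse(day, 400, 0),
    surface_pressure = 101325,
    total_cloud_cover = 57,
    precip_1h = 0,
    fill_flag = "observed")
  mods <- list(...)
  for (nm in names(mods)) tb[[nm]] <- mods[[nm]]
  tb
}

# a randomized hourly series whose raw inputs AND induced derived values
# (w*, L, Bowen ratio) all lie strictly inside the physical bounds, so that
# Scenario-2 clamping is a mathematical no-op: H*Z_ic kept below the w* = 2
# level, u* below the |L| = 8888 level at the smallest |H|, latent flux
# scaled so |H/latent| stays under 10
make_inbounds_series <- function(n_days = 10, seed = 1) {
  set.seed(seed)
  n <- n_days * 24
  s <- make_hours(n)
  day <- s$visible_beam_downward_flux > 0
  s$sensible_heat <- ifelse(day, runif(n, 30, 200), runif(n, -40, -5))
  s$pbl_height <- ifelse(day, runif(n, 300, 1200), runif(n, 50, 400))
  s$friction_velocity <- runif(n, 0.1, 0.7)
  s$latent_heat <- pmin(abs(s$sensible_heat) / runif(n, 0.15, 7.5), 780)
  s$latent_heat[sample.int(n, max(1, n %/% 50))] <- 0
  s
}

# a small planar grid of cell centers with the given spacing
make_grid <- function(nx = 3, ny = 3, spacing = 3000) {
  grid_spec(expand.grid(x = (seq_len(nx) - 1) * spacing,
                        y = (seq_len(ny) - 1) * spacing),
            cell_spacing = spacing, coords = "projected")
}
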