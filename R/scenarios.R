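#' Classify each hour as convective or stable boundary layer
#'
#' HRRR carries no solar angle, so the visible beam downward solar flux is
#' the daytime proxy: it is zero at night and positive in daytime. Flux
#' strictly greater than zero classifies the hour as convective (CBL);
#' anything else, including small negative numerical noise, as stable (SBL).
#'
#' @param visible_beam_downward_flux Flux in W/m^2 (vectorized).
#' @return Character vector, `"CBL"` or `"SBL"`.
#' @examples
#' classify_boundary_layer(c(0, 350, -0.001))
#' @export
classify_boundary_layer <- function(visible_beam_downward_flux) {
  if (any(!is.finite(visible_beam_downward_flux))) {
    stop("visible beam flux must be finite", call. = FALSE)
  }
  ifelse(visible_beam_downward_flux > 0, "CBL", "SBL")
}

#' Convective velocity scale w*
#'
#' w* = (g H Z_ic / (rho c_p T_ref))^(1/3), the buoyancy velocity scale of
#' the convective boundary layer. Defined only for upward sensible heat
#' flux; for H <= 0 the AERMET missing sentinel -9 is returned.
#'
#' @param H Sensible heat flux, W/m^2.
#' @param z_ic Convective mixing height, m (>= 0).
#' @param t_ref Reference (2 m) air temperature, K (> 0).
#' @param const A [met_constants()] list.
#' @return w* in m/s, or -9 where H <= 0. Vectorized.
#' @export
convective_velocity_scale <- function(H, z_ic, t_ref,
                                      const = met_constants()) {
  if (any(!is.finite(H)) || any(!is.finite(z_ic)) || any(!is.finite(t_ref))) {
    stop("w* inputs must be finite", call. = FALSE)
  }
  if (any(z_ic < 0)) stop("z_ic must be non-negative", call. = FALSE)
  if (any(t_ref <= 0)) stop("t_ref must be positive (Kelvin)", call. = FALSE)
  ifelse(H > 0,
         (const$g * H * z_ic / (const$rho_air * const$cp_air * t_ref))^(1 / 3),
         -9)
}

#' Monin-Obukhov length L
#'
#' L = rho c_p T_ref u*^3 / (k g H), as written in the AERMOD formulation
#' convention adopted here: no leading minus sign, so L is positive for
#' daytime (H > 0) hours. This inverts the textbook micrometeorology sign
#' convention; see the package vignette. Near-neutral hours with |H| below
#' `h_epsilon` return the +8888 sentinel (the upper physical bound).
#'
#' @param H Sensible heat flux, W/m^2.
#' @param u_star Friction velocity, m/s (>= 0).
#' @param t_ref Reference temperature, K (> 0).
#' @param const A [met_constants()] list.
#' @param h_epsilon Threshold below which |H| is treated as zero, W/m^2.
#' @return L in metres. Vectorized.
#' @export
monin_obukhov_length <- function(H, u_star, t_ref, const = met_constants(),
                                 h_epsilon = 1e-6) {
  if (any(!is.finite(H)) || any(!is.finite(u_star)) || any(!is.finite(t_ref))) {
    stop("L inputs must be finite", call. = FALSE)
  }
  if (any(u_star < 0)) stop("u_star must be non-negative", call. = FALSE)
  if (any(t_ref <= 0)) stop("t_ref must be positive (Kelvin)", call. = FALSE)
  ifelse(abs(H) < h_epsilon, 8888,
         const$rho_air * const$cp_air * t_ref * u_star^3 /
           (const$von_karman * const$g * H))
}

#' Wind direction from u/v components
#'
#' WD = mod(180 + (180/pi) atan2(wind_u, wind_v), 360), the meteorological
#' "direction the wind blows from": (u=0, v=1) is a southerly (180),
#' (u=1, v=0) a westerly (270). Calm hours (both components zero) return 0
#' and are counted in a message.
#'
#' @param wind_u Eastward wind component, m/s.
#' @param wind_v Northward wind component, m/s.
#' @return Direction in degrees, in `[0, 360)`. Vectorized.
#' @export
wind_direction <- function(wind_u, wind_v) {
  calm <- wind_u == 0 & wind_v == 0
  wd <- (180 + (180 / pi) * atan2(wind_u, wind_v)) %% 360
  wd[calm] <- 0
  if (any(calm)) {
    message(sum(calm), " calm hour(s) (u = v = 0); wind direction set to 0")
  }
  wd
}

#' Surface albedo
#'
#' Set to 1 at night (SBL); in daytime (CBL) the ratio of reflected to
#' incoming shortwave, (down - up)/down, clamped to `[0, 1]` against
#' instrument noise. A CBL hour with non-positive downward shortwave is
#' degenerate and returns 1 with a warning.
#'
#' @param down_sw,up_sw Downward/upward shortwave radiation flux, W/m^2.
#' @param regime `"CBL"` or `"SBL"` per hour.
#' @return Albedo in `[0, 1]`. Vectorized.
#' @export
albedo <- function(down_sw, up_sw, regime) {
  if (any(!is.finite(down_sw)) || any(!is.finite(up_sw))) {
    stop("shortwave fluxes must be finite", call. = FALSE)
  }
  day <- regime == "CBL"
  bad_day <- day & down_sw <= 0
  if (any(bad_day)) {
    warning(sum(bad_day), " daytime hour(s) with non-positive downward ",
            "shortwave; albedo set to 1", call. = FALSE)
  }
  r <- rep(1, length(down_sw))
  ok <- day & down_sw > 0
  r[ok] <- clamp((down_sw[ok] - up_sw[ok]) / down_sw[ok], 0, 1)
  r
}

#' Bowen ratio
#'
#' |H / latent|; hours with zero latent heat flux (an infinite ratio) fall
#' back to the location's series median Bowen ratio, precomputed with
#' [bowen_median()].
#'
#' @param H Sensible heat flux, W/m^2.
#' @param latent Latent heat flux, W/m^2.
#' @param location_median Fallback median Bowen ratio for the location.
#' @return Bowen ratio, dimensionless. Vectorized.
#' @export
bowen_ratio <- function(H, latent, location_median) {
  ifelse(latent != 0, abs(H / latent), location_median)
}

#' Series median Bowen ratio for a location
#'
#' First pass of the two-pass Bowen computation: the median of |H/latent|
#' over all hours with non-zero latent heat flux.
#'
#' @param H,latent Flux series, W/m^2.
#' @return A single number (NA if no hour has non-zero latent flux).
#' @export
bowen_median <- function(H, latent) {
  ok <- latent != 0 & is.finite(H) & is.finite(latent)
  stats::median(abs(H[ok] / latent[ok]))
}

#' Cloud cover as an AERMET decile
#'
#' floor(percent / 10), so 57% becomes 5 and 100% becomes 10. Out-of-range
#' input is clamped to `[0, 100]` with a warning.
#'
#' @param percent Total cloud cover, percent.
#' @return Integer decile 0-10. Vectorized.
#' @export
cloud_cover_decile <- function(percent) {
  out_of_range <- percent < 0 | percent > 100
  if (any(out_of_range, na.rm = TRUE)) {
    warning(sum(out_of_range, na.rm = TRUE),
            " cloud cover value(s) outside [0, 100]; clamped", call. = FALSE)
  }
  as.integer(floor(clamp(percent, 0, 100) / 10))
}

#' Energy-balance sensible heat flux for convective hours
#'
#' The urban-heat-island energy balance used for daytime hours: sensible
#' heat is the residual net radiation after ground and latent heat fluxes,
#' H = (down_sw + down_lw - up_sw - up_lw) - ground - latent.
#'
#' @param down_sw,up_sw Shortwave radiation fluxes, W/m^2.
#' @param down_lw,up_lw Longwave radiation fluxes, W/m^2.
#' @param ground_heat Ground heat flux, W/m^2.
#' @param latent_heat Latent heat flux, W/m^2.
#' @return H in W/m^2. Vectorized.
#' @export
sensible_heat_cbl <- function(down_sw, up_sw, down_lw, up_lw,
                              ground_heat, latent_heat) {
  (down_sw + down_lw - up_sw - up_lw) - ground_heat - latent_heat
}

# date/hour fields from a UTC timestamp and an integer UTC offset;
# hour-ending convention: local hours 00-23 label .sfc hours 1-24
local_date_fields <- function(timestamp, tz_offset) {
  local <- timestamp + tz_offset * 3600
  list(
    year = as.integer(format(local, "%y", tz = "UTC")),
    month = as.integer(format(local, "%m", tz = "UTC")),
    day = as.integer(format(local, "%d", tz = "UTC")),
    julian_day = as.integer(format(local, "%j", tz = "UTC")),
    hour = as.integer(format(local, "%H", tz = "UTC")) + 1L
  )
}

# drop unfillable hours before building records
drop_unfillable <- function(series) {
  n <- sum(series$fill_flag == "unfillable")
  if (n > 0L) {
    message("excluding ", n, " unfillable hour(s) from surface records")
    series <- series[series$fill_flag != "unfillable", ]
  }
  series
}

#' Build Scenario-1 surface records (direct derivation)
#'
#' Derives every AERMET surface variable directly from the hourly fields:
#' H, u*, z0, mixing heights and wind pass through; w* and L come from
#' [convective_velocity_scale()] and [monin_obukhov_length()] with
#' T_ref = 2 m temperature + 273.15; the vertical potential temperature
#' gradient is the fixed -9 missing sentinel; precipitation type is fixed
#' at 11 (liquid); pressure is Pa/10; cloud cover is converted to deciles;
#' the ASOS wind adjustment flag is "NAD" and the substitution flag
#' "NoSubs".
#'
#' @param series A complete hourly field set (post [fill_missing_hours()]).
#' @param tz_offset Integer UTC offset of local standard time (e.g. -6 for
#'   CST); .sfc files are conventionally in local standard time.
#' @param const A [met_constants()] list.
#' @param h_epsilon Near-neutral |H| threshold passed to
#'   [monin_obukhov_length()].
#' @return A tibble of surface records, one row per hour, in .sfc column
#'   order plus a trailing `regime` column (not serialized).
#' @export
build_scenario1 <- function(series, tz_offset = 0L, const = met_constants(),
                            h_epsilon = 1e-6) {
  series <- drop_unfillable(validate_hourly_fields(series))
  dt <- local_date_fields(series$timestamp, tz_offset)
  regime <- classify_boundary_layer(series$visible_beam_downward_flux)
  t_ref <- series$temperature_2m + 273.15
  bo_med <- bowen_median(series$sensible_heat, series$latent_heat)
  tibble::tibble(
    year = dt$year, month = dt$month, day = dt$day,
    julian_day = dt$julian_day, hour = dt$hour,
    sensible_heat = series$sensible_heat,
    friction_velocity = series$friction_velocity,
    w_star = convective_velocity_scale(series$sensible_heat,
                                       series$pbl_height, t_ref, const),
    vptg_500m = -9,
    z_ic = series$pbl_height,
    z_im = series$equilibrium_geopotential_height,
    obukhov_length = monin_obukhov_length(series$sensible_heat,
                                          series$friction_velocity, t_ref,
                                          const, h_epsilon),
    surface_roughness = series$surface_roughness,
    bowen_ratio = bowen_ratio(series$sensible_heat, series$latent_heat,
                              bo_med),
    albedo = albedo(series$downward_shortwave, series$upward_shortwave,
                    regime),
    wind_speed = series$wind_speed_10m,
    wind_direction = wind_direction(series$wind_u_10m, series$wind_v_10m),
    wind_height = 10,
    temperature = t_ref,
    temperature_height = 2,
    precip_code = 11L,
    precip_amount = series$precip_1h,
    relative_humidity = series$relative_humidity_2m,
    station_pressure = series$surface_pressure / 10,
    cloud_cover = cloud_cover_decile(series$total_cloud_cover),
    adj_flag = "NAD",
    sub_flag = "NoSubs",
    regime = regime
  )
}

# clamp the raw input fields subject to Scenario-2 limits
clamp_inputs <- function(series, bounds) {
  series$sensible_heat <- clamp2(series$sensible_heat, bounds$sensible_heat)
  series$latent_heat <- clamp2(series$latent_heat, bounds$latent_heat)
  series$friction_velocity <- clamp2(series$friction_velocity,
                                     bounds$friction_velocity)
  series$surface_roughness <- clamp2(series$surface_roughness,
                                     bounds$surface_roughness)
  series$pbl_height <- pmin(series$pbl_height, bounds$mixing_height_max)
  series
}

# clamp the derived fields (w* keeps its -9 missing sentinel)
clamp_derived <- function(records, bounds) {
  records$w_star <- ifelse(records$w_star == -9, -9,
                           clamp2(records$w_star, bounds$w_star))
  records$obukhov_length <- clamp2(records$obukhov_length,
                                   bounds$obukhov_length)
  records$bowen_ratio <- clamp2(records$bowen_ratio, bounds$bowen)
  records
}

#' Build Scenario-2 surface records (physically bounded)
#'
#' Applies the physical limits of [scenario_bounds()] to the raw inputs
#' (H, latent heat, u*, z0, and the Z_ic cap), then recomputes w* and L
#' from the clamped values, then clamps w*, L and the Bowen ratio. When no
#' input exceeds its bounds the output is identical to [build_scenario1()].
#'
#' @inheritParams build_scenario1
#' @param bounds A [scenario_bounds()] list.
#' @return A tibble of surface records as in [build_scenario1()].
#' @export
build_scenario2 <- function(series, tz_offset = 0L,
                            bounds = scenario_bounds(),
                            const = met_constants(), h_epsilon = 1e-6) {
  series <- clamp_inputs(validate_hourly_fields(series), bounds)
  clamp_derived(build_scenario1(series, tz_offset, const, h_epsilon), bounds)
}

#' Build Scenario-3 surface records (CBL/SBL split)
#'
#' Starts from the Scenario-2 records. Hours are classified with
#' [classify_boundary_layer()]; in daytime (CBL) hours the sensible heat
#' flux is replaced by the energy-balance residual of
#' [sensible_heat_cbl()] (using the Scenario-2-clamped latent heat flux)
#' and w* and L are recomputed from it, with the same physical bounds
#' re-applied. Nighttime (SBL) hours retain their Scenario-2 values
#' unchanged.
#'
#' @inheritParams build_scenario2
#' @return A tibble of surface records as in [build_scenario1()].
#' @export
build_scenario3 <- function(series, tz_offset = 0L,
                            bounds = scenario_bounds(),
                            const = met_constants(), h_epsilon = 1e-6) {
  series <- validate_hourly_fields(series)
  records <- build_scenario2(series, tz_offset, bounds, const, h_epsilon)
  clamped <- drop_unfillable(clamp_inputs(series, bounds))
  cbl <- records$regime == "CBL"
  if (!any(cbl)) return(records)
  h_eb <- clamp2(
    sensible_heat_cbl(clamped$downward_shortwave, clamped$upward_shortwave,
                      clamped$downward_longwave, clamped$upward_longwave,
                      clamped$ground_heat, clamped$latent_heat),
    bounds$sensible_heat)
  t_ref <- clamped$temperature_2m + 273.15
  w3 <- convective_velocity_scale(h_eb, clamped$pbl_height, t_ref, const)
  l3 <- monin_obukhov_length(h_eb, clamped$friction_velocity, t_ref,
                             const, h_epsilon)
  records$sensible_heat[cbl] <- h_eb[cbl]
  records$w_star[cbl] <- ifelse(w3[cbl] == -9, -9,
                                clamp2(w3[cbl], bounds$w_star))
  records$obukhov_length[cbl] <- clamp2(l3[cbl], bounds$obukhov_length)
  records
}

#' Build surface records under a chosen scenario
#'
#' Dispatcher over [build_scenario1()], [build_scenario2()] and
#' [build_scenario3()].
#'
#' @inheritParams build_scenario2
#' @param scenario 1, 2 or 3.
#' @return A tibble of surface records.
#' @export
build_surface_records <- function(series, scenario = 3L, tz_offset = 0L,
                                  bounds = scenario_bounds(),
                                  const = met_constants(),
                                  h_epsilon = 1e-6) {
  switch(as.character(scenario),
    "1" = build_scenario1(series, tz_offset, const, h_epsilon),
    "2" = build_scenario2(series, tz_offset, bounds, const, h_epsilon),
    "3" = build_scenario3(series, tz_offset, bounds, const, h_epsilon),
    stop("scenario must be 1, 2 or 3", call. = FALSE))
}
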