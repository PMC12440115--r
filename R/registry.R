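#' HRRR variable registry
#'
#' Maps the package's internal hourly field names to the verbatim GRIB2
#' inventory description strings under which each variable appears in HRRR
#' surface (wrfsfc) files. The same registry keys both a production GRIB2
#' extraction and the plain-text fixture format read by
#' [read_hourly_table()], so fixtures and real archives share one mapping.
#'
#' @return A named character vector: names are internal field names, values
#'   the HRRR description strings.
#' @examples
#' hrrr_variable_registry()[["sensible_heat"]]
#' @export
hrrr_variable_registry <- function() {
  c(
    sensible_heat = "SFC=Ground or water surface; Sensible heat net flux [W/(m^2)]",
    friction_velocity = "SFC=Ground or water surface; Frictional velocity [m/s]",
    pbl_height = "SFC=Ground or water surface; Planetary boundary layer height [m]",
    equilibrium_geopotential_height = "EHLT=Equilibrium level; Geopotential height [gpm]",
    surface_roughness = "SFC=Ground or water surface; Surface roughness [m]",
    latent_heat = "SFC=Ground or water surface; Latent heat net flux [W/(m^2)]",
    ground_heat = "SFC=Ground or water surface; Ground heat flux [W/(m^2)]",
    temperature_2m = "2[m] HTGL=Specified height level above ground; Temperature [C]",
    relative_humidity_2m = "2[m] HTGL=Specified height level above ground; Relative humidity [%]",
    wind_u_10m = "10[m] HTGL=Specified height level above ground; u-component of wind [m/s]",
    wind_v_10m = "10[m] HTGL=Specified height level above ground; v-component of wind [m/s]",
    wind_speed_10m = "10[m] HTGL=Specified height level above ground; Wind speed [m/s]",
    downward_shortwave = "SFC=Ground or water surface; Downward short-wave radiation flux [W/m^2]",
    upward_shortwave = "SFC=Ground or water surface; Upward short-wave radiation flux [W/m^2]",
    downward_longwave = "SFC=Ground or water surface; Downward long-wave radiation flux [W/m^2]",
    upward_longwave = "SFC=Ground or water surface; Upward long-wave radiation flux [W/m^2]",
    visible_beam_downward_flux = "SFC=Ground or water surface; Visible Beam Downward Solar Flux [W/m^2]",
    surface_pressure = "SFC=Ground or water surface; Pressure [Pa]",
    total_cloud_cover = "EATM=Entire Atmosphere; Total cloud cover [%]",
    precip_1h = "SFC=Ground or water surface; 01 hr Total precipitation [kg/(m^2)]"
  )
}

# all columns of an hourly field set, in canonical order
hourly_field_names <- function() {
  c("timestamp", names(hrrr_variable_registry()), "fill_flag")
}

#' Read an hourly fixture table into an hourly field set
#'
#' Reads a column-per-variable CSV whose columns are named either by the
#' internal field names or by the verbatim HRRR description strings of
#' [hrrr_variable_registry()]; the `timestamp` column must be an ISO-8601
#' UTC date-hour.
#'
#' @param path CSV file path.
#' @return A tibble with the canonical hourly field columns, sorted by
#'   timestamp, `fill_flag` set to `"observed"` where absent.
#' @export
read_hourly_table <- function(path) {
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  reg <- hrrr_variable_registry()
  nm <- names(raw)
  hit <- match(nm, unname(reg))
  nm[!is.na(hit)] <- names(reg)[hit[!is.na(hit)]]
  names(raw) <- nm
  if (!"timestamp" %in% nm) {
    stop("fixture table lacks a 'timestamp' column", call. = FALSE)
  }
  raw$timestamp <- as.POSIXct(raw$timestamp, tz = "UTC",
                              tryFormats = c("%Y-%m-%dT%H:%M:%OS",
                                             "%Y-%m-%d %H:%M:%OS",
                                             "%Y/%m/%d %H:%M:%OS"))
  if (!"fill_flag" %in% names(raw)) raw$fill_flag <- "observed"
  missing_fields <- setdiff(hourly_field_names(), names(raw))
  if (length(missing_fields)) {
    stop("fixture table lacks required variable(s): ",
         paste(sprintf("%s (\"%s\")", missing_fields,
                       reg[missing_fields]), collapse = "; "),
         call. = FALSE)
  }
  out <- tibble::as_tibble(raw)[, hourly_field_names()]
  dplyr::arrange(out, .data$timestamp)
}

#' Write an hourly field set as a fixture table
#'
#' Inverse of [read_hourly_table()]; columns are written under the internal
#' field names.
#'
#' @param series An hourly field set tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_hourly_table <- function(series, path) {
  out <- as.data.frame(series[, hourly_field_names()])
  out$timestamp <- format(out$timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# validate the invariants of an hourly field set; returns series invisibly
validate_hourly_fields <- function(series) {
  missing_fields <- setdiff(hourly_field_names(), names(series))
  if (length(missing_fields)) {
    reg <- hrrr_variable_registry()
    known <- intersect(missing_fields, names(reg))
    stop("hourly series lacks required field(s): ",
         paste(missing_fields, collapse = ", "),
         if (length(known)) paste0(" [HRRR: ",
           paste(reg[known], collapse = "; "), "]"),
         call. = FALSE)
  }
  obs <- series$fill_flag != "unfillable"
  rng <- function(x, lo, hi) all(x[obs] >= lo & x[obs] <= hi, na.rm = TRUE)
  if (!rng(series$relative_humidity_2m, 0, 100)) {
    stop("relative_humidity_2m outside [0, 100]", call. = FALSE)
  }
  if (!rng(series$total_cloud_cover, 0, 100)) {
    stop("total_cloud_cover outside [0, 100]", call. = FALSE)
  }
  if (!all(series$wind_speed_10m[obs] >= 0, na.rm = TRUE)) {
    stop("wind_speed_10m must be non-negative", call. = FALSE)
  }
  dt <- diff(as.numeric(series$timestamp))
  if (any(dt <= 0)) stop("timestamps must be strictly increasing", call. = FALSE)
  invisible(series)
}
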