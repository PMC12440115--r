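#' Construct a .sfc file header
#'
#' AERMET surface files open with a single header line carrying the site
#' coordinates, the upper-air / surface / on-site station identifiers and a
#' version tag. Identifiers default to "00000" when unknown.
#'
#' @param latitude Degrees, positive north.
#' @param longitude Degrees, positive east.
#' @param ua_id,sf_id,os_id Station identifier strings.
#' @param version_tag Version string written after `VERSION:`.
#' @return A list of class `sfc_header`.
#' @export
sfc_header <- function(latitude = 0, longitude = 0, ua_id = "00000",
                       sf_id = "00000", os_id = "00000",
                       version_tag = "19191") {
  if (abs(latitude) > 90 || abs(longitude) > 180) {
    stop("header coordinates out of range", call. = FALSE)
  }
  structure(list(latitude = latitude, longitude = longitude,
                 ua_id = as.character(ua_id), sf_id = as.character(sf_id),
                 os_id = as.character(os_id),
                 version_tag = as.character(version_tag)),
            class = "sfc_header")
}

# the 27 serialized .sfc columns, in file order
sfc_columns <- function() {
  c("year", "month", "day", "julian_day", "hour", "sensible_heat",
    "friction_velocity", "w_star", "vptg_500m", "z_ic", "z_im",
    "obukhov_length", "surface_roughness", "bowen_ratio", "albedo",
    "wind_speed", "wind_direction", "wind_height", "temperature",
    "temperature_height", "precip_code", "precip_amount",
    "relative_humidity", "station_pressure", "cloud_cover",
    "adj_flag", "sub_flag")
}

# sprintf format per serialized numeric column (decimal precision dialect)
sfc_formats <- function() {
  c(year = "%2d", month = "%2d", day = "%2d", julian_day = "%3d",
    hour = "%2d", sensible_heat = "%7.1f", friction_velocity = "%8.4f",
    w_star = "%8.4f", vptg_500m = "%6.1f", z_ic = "%8.1f", z_im = "%8.1f",
    obukhov_length = "%9.1f", surface_roughness = "%8.4f",
    bowen_ratio = "%7.2f", albedo = "%6.2f", wind_speed = "%8.2f",
    wind_direction = "%4.0f", wind_height = "%6.1f", temperature = "%7.1f",
    temperature_height = "%6.1f", precip_code = "%3d",
    precip_amount = "%8.2f", relative_humidity = "%6.1f",
    station_pressure = "%9.1f", cloud_cover = "%3d",
    adj_flag = "%s", sub_flag = "%s")
}

#' Write surface records to a .sfc file
#'
#' One header line, then one whitespace-delimited line per hour with the 27
#' fields in AERMET order, each numeric field at a fixed decimal precision
#' (H and L to 0.1, u*, w* and z0 to 0.0001, Bowen ratio and albedo to
#' 0.01, wind speed to 0.01 with direction to whole degrees, temperature
#' and pressure to 0.1). Free-format whitespace delimiting is the dialect
#' AERMOD's free-format reader accepts.
#'
#' @param records A surface-record tibble from one of the scenario
#'   builders, chronologically ordered with no duplicate date-hours.
#' @param path Output file path.
#' @param header A [sfc_header()].
#' @return `path`, invisibly.
#' @export
write_sfc <- function(records, path, header = sfc_header()) {
  stopifnot(inherits(header, "sfc_header"))
  missing_cols <- setdiff(sfc_columns(), names(records))
  if (length(missing_cols)) {
    stop("records lack .sfc column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  key <- records$year * 1e5 + records$julian_day * 100 + records$hour
  if (anyDuplicated(key)) stop("duplicate date-hours in records",
                               call. = FALSE)
  if (is.unsorted(key)) stop("records must be chronologically ordered",
                             call. = FALSE)
  hdr <- sprintf("%9.3f%s %10.3f%s  UA_ID: %s  SF_ID: %s  OS_ID: %s  VERSION: %s",
                 abs(header$latitude), if (header$latitude < 0) "S" else "N",
                 abs(header$longitude), if (header$longitude < 0) "W" else "E",
                 header$ua_id, header$sf_id, header$os_id,
                 header$version_tag)
  fmts <- sfc_formats()
  cols <- sfc_columns()
  fields <- mapply(function(col, fmt) {
    x <- records[[col]]
    if (grepl("d$", fmt)) x <- as.integer(round(x))
    if (col == "wind_direction") x <- round(x) %% 360
    sprintf(fmt, x)
  }, cols, fmts[cols], SIMPLIFY = FALSE)
  lines <- do.call(paste, fields)
  writeLines(c(hdr, lines), path)
  invisible(path)
}

#' Read a .sfc file
#'
#' Inverse of [write_sfc()] on files it wrote; tolerant of arbitrary
#' whitespace between fields. Lines with the wrong field count raise an
#' error naming the line; hour values outside 1-24 and cloud deciles
#' outside 0-10 are validation errors.
#'
#' @param path Path to a .sfc file.
#' @return A list with elements `header` (a [sfc_header()]) and `records`
#'   (a tibble with the 27 .sfc columns).
#' @export
read_sfc <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 1L) stop("empty .sfc file", call. = FALSE)
  m <- regmatches(lines[1],
    regexec(paste0("^\\s*([0-9.]+)([NS])\\s+([0-9.-]+)([EW])",
                   "\\s+UA_ID:\\s*(\\S+)\\s+SF_ID:\\s*(\\S+)",
                   "\\s+OS_ID:\\s*(\\S+)\\s+VERSION:\\s*(\\S+)"),
            lines[1]))[[1]]
  if (length(m) != 9L) stop("malformed .sfc header: ", lines[1],
                            call. = FALSE)
  header <- sfc_header(
    latitude = as.numeric(m[2]) * if (m[3] == "S") -1 else 1,
    longitude = abs(as.numeric(m[4])) * if (m[5] == "W") -1 else 1,
    ua_id = m[6], sf_id = m[7], os_id = m[8], version_tag = m[9])
  body <- lines[-1]
  body <- body[nzchar(trimws(body))]
  toks <- strsplit(trimws(body), "\\s+")
  nf <- vapply(toks, length, integer(1))
  if (any(nf != 27L)) {
    bad <- which(nf != 27L)[1]
    stop("line ", bad + 1L, ": expected 27 fields, found ", nf[bad],
         call. = FALSE)
  }
  cols <- sfc_columns()
  mat <- do.call(rbind, toks)
  records <- tibble::as_tibble(as.data.frame(mat, stringsAsFactors = FALSE))
  names(records) <- cols
  int_cols <- c("year", "month", "day", "julian_day", "hour", "precip_code",
                "cloud_cover")
  num_cols <- setdiff(cols, c(int_cols, "adj_flag", "sub_flag"))
  for (cc in num_cols) {
    v <- suppressWarnings(as.numeric(records[[cc]]))
    if (anyNA(v)) stop("non-numeric value in column ", cc, call. = FALSE)
    records[[cc]] <- v
  }
  for (cc in int_cols) {
    v <- suppressWarnings(as.integer(records[[cc]]))
    if (anyNA(v)) stop("non-integer value in column ", cc, call. = FALSE)
    records[[cc]] <- v
  }
  if (any(records$hour < 1L | records$hour > 24L)) {
    stop("hour values outside 1-24", call. = FALSE)
  }
  if (any(records$cloud_cover < 0L | records$cloud_cover > 10L)) {
    stop("cloud cover deciles outside 0-10", call. = FALSE)
  }
  if (any(records$wind_direction < 0 | records$wind_direction >= 360)) {
    stop("wind direction outside [0, 360)", call. = FALSE)
  }
  list(header = header, records = records)
}
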