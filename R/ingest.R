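#' Describe a forecast grid
#'
#' @param centers A data frame of cell-center coordinates: columns `lat`,
#'   `lon` (degrees) when `coords = "latlon"`, or `x`, `y` (metres) when
#'   `coords = "projected"`.
#' @param cell_spacing Grid spacing in metres (3000 for HRRR).
#' @param coords Coordinate system of the centers.
#' @return A list of class `grid_spec`.
#' @export
grid_spec <- function(centers, cell_spacing = 3000,
                      coords = c("projected", "latlon")) {
  coords <- match.arg(coords)
  centers <- tibble::as_tibble(centers)
  need <- if (coords == "latlon") c("lat", "lon") else c("x", "y")
  if (!all(need %in% names(centers))) {
    stop("grid centers need columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(centers) == 0L) stop("grid has no cell centers", call. = FALSE)
  if (!is.numeric(cell_spacing) || cell_spacing <= 0) {
    stop("cell_spacing must be positive", call. = FALSE)
  }
  structure(list(centers = centers, cell_spacing = cell_spacing,
                 coords = coords), class = "grid_spec")
}

#' Find the grid cell nearest a site
#'
#' Returns the cell whose center minimizes distance to the site:
#' great-circle (haversine) distance for lat/lon grids, Euclidean for
#' projected grids. For a regular 3,000 m grid the distance can never
#' exceed the half-diagonal, 3000/sqrt(2) = 2,121 m.
#'
#' @param site Numeric length-2: `c(lat, lon)` or `c(x, y)` matching the
#'   grid's coordinate system.
#' @param grid A [grid_spec()].
#' @return A list with `index` (row into `grid$centers`), `distance_m`, and
#'   `center` (the matched center coordinates).
#' @export
select_grid_cell <- function(site, grid) {
  stopifnot(inherits(grid, "grid_spec"))
  if (length(site) != 2L || !all(is.finite(site))) {
    stop("site must be two finite coordinates", call. = FALSE)
  }
  ctr <- grid$centers
  if (grid$coords == "latlon") {
    # distHaversine takes (lon, lat)
    d <- geosphere::distHaversine(cbind(ctr$lon, ctr$lat),
                                  c(site[2], site[1]))
    c1 <- ctr$lat; c2 <- ctr$lon; s1 <- site[1]; s2 <- site[2]
  } else {
    d <- sqrt((ctr$x - site[1])^2 + (ctr$y - site[2])^2)
    c1 <- ctr$x; c2 <- ctr$y; s1 <- site[1]; s2 <- site[2]
  }
  pad <- if (grid$coords == "latlon") grid$cell_spacing / 111000 else
    grid$cell_spacing
  if (s1 < min(c1) - pad || s1 > max(c1) + pad ||
      s2 < min(c2) - pad || s2 > max(c2) + pad) {
    warning("site lies more than one cell spacing outside the grid ",
            "bounding box; returning nearest cell anyway", call. = FALSE)
  }
  i <- which.min(d)
  list(index = i, distance_m = d[i], center = ctr[i, , drop = FALSE])
}

#' Merge one-hour-forecast precipitation into an analysis series
#'
#' Analysis-hour (f00) files carry all surface variables but zero
#' precipitation; the one-hour forecast (f01) carries the forecast rainfall.
#' This replaces the `precip_1h` column of the f00 series with the f01
#' values matched by timestamp, leaving every other field untouched.
#'
#' @param f00_series Hourly field set from f00 files.
#' @param f01_precip A data frame with columns `timestamp` and `precip_1h`.
#' @return The merged hourly field set.
#' @export
merge_precip <- function(f00_series, f01_precip) {
  f01 <- tibble::as_tibble(f01_precip)
  if (!all(c("timestamp", "precip_1h") %in% names(f01))) {
    stop("f01_precip needs columns timestamp and precip_1h", call. = FALSE)
  }
  f01 <- dplyr::arrange(f01, .data$timestamp)
  missing_ts <- setdiff(as.character(f00_series$timestamp),
                        as.character(f01$timestamp))
  extra_ts <- setdiff(as.character(f01$timestamp),
                      as.character(f00_series$timestamp))
  if (length(missing_ts) || length(extra_ts)) {
    stop("f00/f01 timestamp mismatch; offending hours: ",
         paste(c(missing_ts, extra_ts), collapse = ", "), call. = FALSE)
  }
  idx <- match(as.character(f00_series$timestamp), as.character(f01$timestamp))
  out <- f00_series
  out$precip_1h <- f01$precip_1h[idx]
  out
}

#' Fill missing hours from the most recent earlier hour
#'
#' Expands the series onto a complete hourly grid between its first and
#' last timestamps. Each missing hour is filled by copying the nearest
#' earlier *observed* hour, walking back at most `max_backtrack` hours;
#' hours that cannot be filled are retained with `fill_flag = "unfillable"`
#' and all data fields `NA` (they are dropped before .sfc serialization).
#'
#' @param series Hourly field set, sorted by timestamp, possibly with gaps.
#' @param max_backtrack Maximum hours to walk back for a donor (default 6).
#' @return A complete hourly field set with `fill_flag` set to `"observed"`,
#'   `"filled_prior_hour"`, or `"unfillable"`.
#' @export
fill_missing_hours <- function(series, max_backtrack = 6L) {
  stopifnot(nrow(series) >= 1L, max_backtrack >= 1L)
  ts <- series$timestamp
  if (is.unsorted(as.numeric(ts), strictly = TRUE)) {
    stop("series must be sorted by timestamp without duplicates",
         call. = FALSE)
  }
  full <- seq(min(ts), max(ts), by = "hour")
  if (length(full) == nrow(series)) return(series)   # no gaps: identity
  idx <- match(as.numeric(full), as.numeric(ts))
  out <- series[ifelse(is.na(idx), 1L, idx), ]
  out$timestamp <- full
  data_cols <- setdiff(names(out), c("timestamp", "fill_flag"))
  for (i in which(is.na(idx))) {
    donor <- NA_integer_
    for (back in seq_len(max_backtrack)) {
      j <- i - back
      if (j >= 1L && !is.na(idx[j])) { donor <- j; break }
    }
    if (is.na(donor)) {
      out[i, data_cols] <- NA
      out$fill_flag[i] <- "unfillable"
    } else {
      out[i, data_cols] <- out[donor, data_cols]
      out$fill_flag[i] <- "filled_prior_hour"
    }
  }
  n_unfillable <- sum(out$fill_flag == "unfillable")
  if (n_unfillable > 0L) {
    message(n_unfillable, " hour(s) unfillable within ", max_backtrack,
            "-hour backtrack; flagged for exclusion from .sfc output")
  }
  out
}
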