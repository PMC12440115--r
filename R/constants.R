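#' Physical constants used in surface-layer derivations
#'
#' Returns the constants entering the convective velocity scale and
#' Monin-Obukhov length formulas. Defaults are the values used throughout
#' dispersion-model meteorology preprocessing: dry-air density at 273 K and
#' 101.325 kPa, and the specific heat of air at constant pressure in SI
#' units, J/(kg K).
#'
#' @param g Acceleration due to gravity, m/s^2.
#' @param rho_air Dry air density, kg/m^3.
#' @param cp_air Specific heat of air at constant pressure, J/(kg K).
#' @param von_karman von Karman constant, dimensionless.
#' @return A named list of class `met_constants`.
#' @examples
#' met_constants()
#' @export
met_constants <- function(g = 9.8, rho_air = 1.293, cp_air = 1004,
                          von_karman = 0.4) {
  const <- list(g = g, rho_air = rho_air, cp_air = cp_air,
                von_karman = von_karman)
  bad <- names(const)[!vapply(const, function(x)
    is.numeric(x) && length(x) == 1L && is.finite(x) && x > 0, logical(1))]
  if (length(bad)) {
    stop("met_constants must be single positive finite numbers; bad: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(const, class = "met_constants")
}

#' Physical bounds applied to surface variables (Scenarios 2 and 3)
#'
#' Upper and lower limits clamped onto raw and derived surface variables to
#' prevent implausible values reaching the dispersion model. Each bound is a
#' length-2 numeric `c(lower, upper)`; `mixing_height_max` is an upper cap
#' only.
#'
#' @param sensible_heat Bounds on sensible heat flux H, W/m^2.
#' @param latent_heat Bounds on latent heat flux, W/m^2.
#' @param friction_velocity Bounds on u*, m/s.
#' @param surface_roughness Bounds on z0, m.
#' @param mixing_height_max Cap on convective mixing height Z_ic, m.
#' @param w_star Bounds on the convective velocity scale w*, m/s.
#' @param obukhov_length Bounds on the Monin-Obukhov length L, m.
#' @param bowen Bounds on the Bowen ratio, dimensionless.
#' @return A named list of class `scenario_bounds`.
#' @examples
#' scenario_bounds()
#' @export
scenario_bounds <- function(sensible_heat = c(-64, 800),
                            latent_heat = c(-100, 800),
                            friction_velocity = c(0, 2),
                            surface_roughness = c(0, 2),
                            mixing_height_max = 4000,
                            w_star = c(0, 2),
                            obukhov_length = c(-8888, 8888),
                            bowen = c(-10, 10)) {
  b <- list(sensible_heat = sensible_heat, latent_heat = latent_heat,
            friction_velocity = friction_velocity,
            surface_roughness = surface_roughness,
            mixing_height_max = mixing_height_max,
            w_star = w_star, obukhov_length = obukhov_length,
            bowen = bowen)
  pairs <- b[setdiff(names(b), "mixing_height_max")]
  ok <- vapply(pairs, function(x)
    is.numeric(x) && length(x) == 2L && all(is.finite(x)) && x[1] < x[2],
    logical(1))
  if (!all(ok)) {
    stop("scenario_bounds entries must be c(lower, upper) with lower < upper; ",
         "bad: ", paste(names(pairs)[!ok], collapse = ", "), call. = FALSE)
  }
  if (!is.numeric(b$mixing_height_max) || length(b$mixing_height_max) != 1L ||
      !is.finite(b$mixing_height_max) || b$mixing_height_max <= 0) {
    stop("mixing_height_max must be a single positive number", call. = FALSE)
  }
  structure(b, class = "scenario_bounds")
}

# clamp a numeric vector into [lo, hi]; NA passes through
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

clamp2 <- function(x, bound) clamp(x, bound[1], bound[2])

#' Read a plain-text key/value configuration file
#'
#' Parses lines of the form `key = value` (comments start with `#`) and
#' returns overrides suitable for [met_constants()] and [scenario_bounds()].
#' Bound keys take two comma-separated numbers, e.g.
#' `sensible_heat = -64, 800`.
#'
#' @param path Path to the configuration file.
#' @return A list with elements `constants`, `bounds`, and `options`
#'   (anything else, e.g. `tz_offset`, `max_backtrack`, `h_epsilon`).
#' @export
read_met_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- lines[vapply(kv, length, integer(1)) != 2L]
  if (length(bad)) {
    stop("unparseable config line(s): ", paste(bad, collapse = "; "),
         call. = FALSE)
  }
  keys <- trimws(vapply(kv, `[[`, character(1), 1L))
  vals <- lapply(kv, function(x) {
    v <- suppressWarnings(as.numeric(trimws(strsplit(x[[2]], ",")[[1]])))
    if (anyNA(v)) stop("non-numeric config value in: ", trimws(x[[2]]),
                       call. = FALSE)
    v
  })
  names(vals) <- keys
  const_keys <- c("g", "rho_air", "cp_air", "von_karman")
  bound_keys <- setdiff(names(formals(scenario_bounds)), character(0))
  list(constants = vals[intersect(keys, const_keys)],
       bounds = vals[intersect(keys, bound_keys)],
       options = vals[setdiff(keys, c(const_keys, bound_keys))])
}
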