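#' Convert NO2 concentrations from ug/m^3 to ppb
#'
#' Multiplies by 0.53, the NO2 conversion factor at 25 degrees C and 1 atm
#' (molar volume 24.465 L/mol over the NO2 molar mass 46.006 g/mol).
#'
#' @param values Concentrations in ug/m^3.
#' @param factor Conversion factor; default 0.53.
#' @return Concentrations in ppb.
#' @examples
#' ugm3_to_ppb(10)
#' @export
ugm3_to_ppb <- function(values, factor = 0.53) {
  if (any(!is.finite(values))) stop("values must be finite", call. = FALSE)
  values * factor
}

#' Aggregate hourly values to daily means
#'
#' @param timestamps POSIXct hourly timestamps.
#' @param values Hourly values; `NA` hours are dropped.
#' @return A tibble with `date`, `value` (mean of available hours) and
#'   `n_hours` (count of contributing hours).
#' @export
daily_average <- function(timestamps, values) {
  keep <- !is.na(values)
  tb <- tibble::tibble(date = as.Date(timestamps[keep], tz = "UTC"),
                       value = values[keep])
  dplyr::summarise(dplyr::group_by(tb, .data$date),
                   n_hours = dplyr::n(),
                   value = mean(.data$value), .groups = "drop")[,
                     c("date", "value", "n_hours")]
}

#' Simple linear regression of observations on predictions
#'
#' Ordinary least squares of y (measured) on x (predicted); the coefficient
#' of determination equals the squared Pearson correlation.
#'
#' @param pred Predicted values (x).
#' @param obs Observed values (y).
#' @return A list with `n`, `slope`, `intercept`, `r_squared`.
#' @export
simple_linreg <- function(pred, obs) {
  ok <- is.finite(pred) & is.finite(obs)
  pred <- pred[ok]; obs <- obs[ok]
  if (length(pred) < 3L) stop("need at least 3 paired values", call. = FALSE)
  if (stats::var(pred) == 0) stop("zero variance in predictions",
                                  call. = FALSE)
  fit <- stats::lm(obs ~ pred)
  # R^2 of a simple regression is the squared Pearson correlation; this
  # form also avoids summary.lm's perfect-fit warning on exact data
  r2 <- if (stats::sd(obs) == 0) 0 else stats::cor(pred, obs)^2
  list(n = length(pred),
       slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = r2)
}

#' Willmott's index of agreement
#'
#' d = 1 - sum((P - O)^2) / sum((|P - mean(O)| + |O - mean(O)|)^2), the
#' original Willmott (1981) d-statistic, bounded in `[0, 1]` with 1 only
#' for perfect agreement. If both series are identical constants the
#' denominator vanishes and agreement is perfect by definition (d = 1).
#'
#' @param obs Observed series.
#' @param pred Predicted series.
#' @return A single number in `[0, 1]`.
#' @export
index_of_agreement <- function(obs, pred) {
  ok <- is.finite(obs) & is.finite(pred)
  obs <- obs[ok]; pred <- pred[ok]
  if (length(obs) < 2L) stop("need at least 2 paired values", call. = FALSE)
  o_bar <- mean(obs)
  denom <- sum((abs(pred - o_bar) + abs(obs - o_bar))^2)
  if (denom == 0) return(1)
  1 - sum((pred - obs)^2) / denom
}

#' Relative difference in index of agreement, percent
#'
#' 100 * (ioa_hrrr - ioa_obs) / ioa_hrrr: positive when the gridded-forecast
#' meteorology outperforms the observational meteorology, negative when the
#' opposite holds.
#'
#' @param ioa_hrrr IOA obtained with forecast-derived meteorology (> 0).
#' @param ioa_obs IOA obtained with observational meteorology.
#' @return Percent difference. Vectorized.
#' @export
relative_ioa_difference <- function(ioa_hrrr, ioa_obs) {
  if (any(ioa_hrrr <= 0)) stop("ioa_hrrr must be positive", call. = FALSE)
  100 * (ioa_hrrr - ioa_obs) / ioa_hrrr
}

# distance strata between monitor and nearest weather station, km
distance_bin_labels <- function() {
  c("<2km", "2-10km", "10-20km", "20-35km", ">=35km")
}

#' Assign distances to the monitor-to-station strata
#'
#' Half-open bins `[0,2)`, `[2,10)`, `[10,20)`, `[20,35)`, `[35,Inf)` km;
#' every non-negative distance falls in exactly one bin.
#'
#' @param distance_km Distances in km.
#' @return A factor with the five stratum labels.
#' @export
distance_stratum <- function(distance_km) {
  cut(distance_km, breaks = c(0, 2, 10, 20, 35, Inf), right = FALSE,
      labels = distance_bin_labels(), include.lowest = TRUE)
}

#' Evaluate paired prediction/observation series by distance stratum
#'
#' Splits site-day pairs by the distance between each monitoring site and
#' its nearest weather station and computes, per stratum, the pooled
#' regression of observed on predicted values and the index of agreement.
#'
#' @param pairs A tibble with columns `predicted`, `observed` and
#'   `station_distance` (km); typically from [generate_paired_series()] or
#'   a CSV of matched site-days.
#' @return A tibble with one row per stratum: `stratum`, `n`, `slope`,
#'   `intercept`, `r_squared`, `ioa` (statistics `NA` for strata with
#'   fewer than 3 pairs).
#' @export
stratify_by_distance <- function(pairs) {
  need <- c("predicted", "observed", "station_distance")
  if (!all(need %in% names(pairs))) {
    stop("pairs needs columns ", paste(need, collapse = ", "), call. = FALSE)
  }
  pairs$stratum <- distance_stratum(pairs$station_distance)
  out <- lapply(distance_bin_labels(), function(lab) {
    sub <- pairs[!is.na(pairs$stratum) & pairs$stratum == lab, ]
    if (nrow(sub) >= 3L && stats::var(sub$predicted) > 0) {
      fit <- simple_linreg(sub$predicted, sub$observed)
      tibble::tibble(stratum = lab, n = fit$n, slope = fit$slope,
                     intercept = fit$intercept, r_squared = fit$r_squared,
                     ioa = index_of_agreement(sub$observed, sub$predicted))
    } else {
      tibble::tibble(stratum = lab, n = nrow(sub), slope = NA_real_,
                     intercept = NA_real_, r_squared = NA_real_,
                     ioa = NA_real_)
    }
  })
  dplyr::bind_rows(out)
}

#' Regress a site-level statistic on site covariates
#'
#' Multivariate OLS of a per-site performance statistic (e.g. IOA or the
#' relative IOA difference) on site covariates such as land-use
#' percentages, location, elevation, traffic and mean concentration.
#' Coefficients are flagged significant at p < 0.05 (no multiplicity
#' correction, matching the flag-only reporting convention).
#'
#' @param sites A tibble with one row per site containing `response` and
#'   the covariate columns.
#' @param response Name of the response column.
#' @param covariates Character vector of covariate column names.
#' @return A tibble with `term`, `estimate`, `std_error`, `t_value`,
#'   `p_value`, `significant`.
#' @export
site_covariate_regression <- function(sites, response, covariates) {
  stopifnot(all(c(response, covariates) %in% names(sites)))
  if (nrow(sites) <= length(covariates) + 1L) {
    stop("need more sites than covariates", call. = FALSE)
  }
  x <- as.data.frame(sites[, covariates, drop = FALSE])
  degenerate <- names(x)[vapply(x, function(v) stats::var(v) == 0,
                                logical(1))]
  if (length(degenerate)) {
    stop("zero-variance covariate(s): ",
         paste(degenerate, collapse = ", "), call. = FALSE)
  }
  if (length(covariates) > 1L) {
    cm <- abs(stats::cor(x))
    diag(cm) <- 0
    if (any(cm > 0.9999)) {
      idx <- which(cm == max(cm), arr.ind = TRUE)[1, ]
      stop("collinear covariates: ", covariates[idx[1]], " and ",
           covariates[idx[2]], call. = FALSE)
    }
  }
  dat <- cbind(.response = sites[[response]], x)
  fit <- stats::lm(.response ~ ., data = dat)
  sm <- summary(fit)$coefficients
  tibble::tibble(term = rownames(sm),
                 estimate = unname(sm[, "Estimate"]),
                 std_error = unname(sm[, "Std. Error"]),
                 t_value = unname(sm[, "t value"]),
                 p_value = unname(sm[, "Pr(>|t|)"]),
                 significant = unname(sm[, "Pr(>|t|)"]) < 0.05)
}
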