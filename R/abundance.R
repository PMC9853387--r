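#' Convert gated event counts to cell concentration
#'
#' The volumetric conversion of the automated protocol: gated events per uL,
#' times the stain dilution factor (2 for the 1:1 mix), times 1,000 to reach
#' cells/mL. E.g. 16,500 gated events in 66 uL at dilution 2 give
#' 5e5 cells/mL.
#'
#' @param gated_events Number of events inside the population gate.
#' @param volume Analyzed volume of diluted sample, uL (> 0).
#' @param dilution Dilution factor (>= 1).
#' @return Concentration, cells/mL.
#' @examples
#' events_to_concentration(16500, 66, 2)  # 5e5
#' @export
events_to_concentration <- function(gated_events, volume, dilution = 2) {
  if (any(volume <= 0)) abort("Analyzed volume must be positive.")
  if (any(dilution < 1)) abort("Dilution factor must be >= 1.")
  if (any(gated_events < 0)) abort("Event counts must be >= 0.")
  gated_events / volume * dilution * 1000
}

#' Per-sample abundance table
#'
#' Applies [events_to_concentration()] over a tibble of per-sample gated
#' event counts, as produced by the pipeline.
#'
#' @param samples Tibble with columns `sample_id`, `timestamp`,
#'   `gated_events`, `analyzed_volume`, `dilution_factor`.
#' @return The input with `events_per_ul` and `concentration` added.
#' @export
abundance_table <- function(samples) {
  dplyr::mutate(samples,
    events_per_ul = .data$gated_events / .data$analyzed_volume,
    concentration = events_to_concentration(
      .data$gated_events, .data$analyzed_volume, .data$dilution_factor
    )
  )
}

#' Day/night abundance contrast
#'
#' Classifies samples as daylight or night by local-time window (default
#' 06:00-21:00, early-June western-Mediterranean daylight) and contrasts the
#' two groups: medians, their difference, the percent difference relative to
#' the day median, and a two-sample t-test (Welch by default; the
#' pooled-variance Student variant by `var_equal = TRUE`).
#'
#' @param series Tibble with `timestamp` and `concentration` columns.
#' @param day_window Hours `c(start, end)`: daylight is
#'   `start <= hour < end`.
#' @param var_equal Use the pooled-variance Student t-test.
#' @param tz Time zone for the local-hour classification (default UTC).
#' @return One-row tibble: `median_day`, `median_night`, `difference`,
#'   `percent`, `t_statistic`, `p_value`, `n_day`, `n_night`.
#' @export
day_night_compare <- function(series, day_window = c(6, 21),
                              var_equal = FALSE, tz = "UTC") {
  hour <- as.numeric(format(series$timestamp, "%H", tz = tz)) +
    as.numeric(format(series$timestamp, "%M", tz = tz)) / 60
  is_day <- hour >= day_window[1] & hour < day_window[2]
  day <- series$concentration[is_day]
  night <- series$concentration[!is_day]
  if (length(day) < 2 || length(night) < 2) {
    abort("Need >= 2 samples in each of the day and night windows.")
  }
  tt <- t.test(day, night, var.equal = var_equal)
  md <- median(day); mn <- median(night)
  tibble::tibble(
    median_day = md, median_night = mn, difference = md - mn,
    percent = 100 * (md - mn) / md,
    t_statistic = unname(tt$statistic), p_value = tt$p.value,
    n_day = length(day), n_night = length(night)
  )
}

#' Net growth rate from an abundance time series
#'
#' Ordinary least squares of `ln(concentration)` on time in days since the
#' first sample. The slope is the net exponential growth rate mu (per day);
#' `doubling_time = ln(2) / mu` is defined only for mu > 0.
#'
#' @param series Tibble with `timestamp` (or numeric `t_days`) and
#'   `concentration` columns; >= 3 samples, all concentrations > 0.
#' @return A `growth_fit` object; see [tidy()] and [glance()] methods.
#' @export
growth_rate <- function(series) {
  conc <- series$concentration
  if (length(conc) < 3) abort("Need >= 3 samples for a growth fit.")
  if (any(conc <= 0)) {
    abort("All concentrations must be > 0 (log undefined).")
  }
  t_days <- if ("t_days" %in% names(series)) {
    series$t_days
  } else {
    as.numeric(difftime(series$timestamp, min(series$timestamp),
                        units = "days"))
  }
  fit <- lm(log(conc) ~ t_days)
  mu <- unname(coef(fit)[2])
  se <- suppressWarnings(summary(fit))$coefficients[2, 2]
  # slopes at floating-point noise level count as zero growth
  positive <- mu > 1e-12
  structure(
    list(mu = mu, intercept = unname(coef(fit)[1]), slope_se = se,
         doubling_time = if (positive) log(2) / mu else NA_real_,
         n = length(conc), lm_fit = fit),
    class = "growth_fit"
  )
}

#' @export
print.growth_fit <- function(x, ...) {
  cat(sprintf(
    "Net growth rate: mu = %.4f +/- %.4f d^-1 (n = %d)\n", x$mu, x$slope_se,
    x$n
  ))
  if (!is.na(x$doubling_time)) {
    cat(sprintf("Doubling time: %.2f days\n", x$doubling_time))
  } else {
    cat("Doubling time: undefined (mu <= 0)\n")
  }
  invisible(x)
}

#' Tidy a growth fit
#'
#' @param x A `growth_fit`.
#' @param ... Unused.
#' @return `tidy()`: one row per coefficient with estimate and standard
#'   error; `glance()`: one-row model summary with `mu`, `slope_se`,
#'   `doubling_time`, `r_squared`, `n`.
#' @export
tidy.growth_fit <- function(x, ...) {
  s <- suppressWarnings(summary(x$lm_fit))$coefficients
  tibble::tibble(
    term = c("intercept", "mu"),
    estimate = c(x$intercept, x$mu),
    std_error = s[, 2],
    statistic = s[, 3],
    p_value = s[, 4]
  )
}

#' @rdname tidy.growth_fit
#' @export
glance.growth_fit <- function(x, ...) {
  tibble::tibble(
    mu = x$mu, slope_se = x$slope_se, doubling_time = x$doubling_time,
    r_squared = suppressWarnings(summary(x$lm_fit))$r.squared, n = x$n
  )
}
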