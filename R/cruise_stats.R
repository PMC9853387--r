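#' Read a thermosalinograph stream
#'
#' CSV with ISO-8601 `timestamp`, `temperature_C`, `salinity_psu`,
#' `conductivity` columns (the continuous underway surface-water record).
#'
#' @param path CSV file.
#' @return Tibble with parsed `POSIXct` timestamps (UTC).
#' @export
read_env_csv <- function(path) {
  df <- tibble::as_tibble(utils::read.csv(path, check.names = FALSE))
  df$timestamp <- as.POSIXct(df$timestamp, format = "%Y-%m-%dT%H:%M:%S",
                             tz = "UTC")
  if (any(is.na(df$timestamp))) abort("Unparseable env timestamps.")
  if (is.unsorted(df$timestamp, strictly = TRUE)) {
    abort("Env timestamps must be strictly increasing.")
  }
  df
}

#' Match samples to the nearest environmental record
#'
#' Nearest-in-time matching (no interpolation); a tie between two records
#' takes the earlier one. Samples whose nearest record is farther than
#' `tolerance` keep `NA` environmental fields (with a warning). Reusing one
#' env record for several samples is allowed. Matching is idempotent and
#' independent of the sample row order.
#'
#' @param samples Tibble with a `timestamp` column (any per-sample table).
#' @param env Tibble from [read_env_csv()] (time-sorted).
#' @param tolerance Maximum allowed gap in seconds (default 450 s, half the
#'   15-min sampling cadence).
#' @return `samples` with the env columns and `match_gap` (seconds) added.
#' @export
align_env <- function(samples, env, tolerance = 450) {
  if (!nrow(env)) abort("Empty environmental table.")
  st <- as.numeric(samples$timestamp)
  et <- as.numeric(env$timestamp)
  pos <- findInterval(st, et)
  lo <- pmax(pos, 1L)
  hi <- pmin(pos + 1L, length(et))
  gap_lo <- abs(st - et[lo])
  gap_hi <- abs(st - et[hi])
  take_lo <- gap_lo <= gap_hi  # tie -> earlier record
  idx <- ifelse(take_lo, lo, hi)
  gap <- pmin(gap_lo, gap_hi)
  too_far <- gap > tolerance
  if (any(too_far)) {
    warn(sprintf("%d sample(s) beyond the %ds env matching tolerance.",
                 sum(too_far), tolerance))
  }
  env_cols <- setdiff(names(env), "timestamp")
  out <- samples
  for (cn in env_cols) {
    v <- env[[cn]][idx]
    v[too_far] <- NA
    out[[cn]] <- v
  }
  out$match_gap <- gap
  out
}

#' Pearson correlation with t-distribution p-value
#'
#' @param x,y Finite, non-constant numeric vectors, `n >= 3`.
#' @return One-row tibble: `r`, `p_value`, `n`.
#' @export
pearson <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) abort("Need >= 3 complete pairs.")
  if (sd(x) == 0 || sd(y) == 0) {
    abort("Correlation undefined for a constant vector.",
          class = "cytocruise_constant_error")
  }
  ct <- cor.test(x, y, method = "pearson")
  tibble::tibble(r = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}

#' Paired-method comparison by simple least squares
#'
#' Regresses the candidate method on the reference method (y on x) and
#' reports slope, intercept, R-squared and the two-sided p-value for
#' slope != 0 — the standard check that two enumeration protocols agree.
#'
#' @param x Reference-method values.
#' @param y Candidate-method values.
#' @return One-row tibble: `slope`, `intercept`, `r_squared`, `p_slope`, `n`.
#' @export
ols_compare <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) abort("Need >= 3 complete pairs.")
  if (sd(x) == 0) abort("Reference values are constant.",
                        class = "cytocruise_constant_error")
  fit <- lm(y ~ x)
  s <- suppressWarnings(summary(fit))
  tibble::tibble(
    slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
    r_squared = s$r.squared, p_slope = s$coefficients[2, 4], n = length(x)
  )
}

#' Correlations of a cruise series against its environmental covariates
#'
#' Convenience sweep of [pearson()] for one response column against each
#' environmental column present, on raw values by default (log by flag).
#'
#' @param series A cruise series tibble (see [analyze_campaign()]).
#' @param response Column name to correlate (default `concentration`).
#' @param covariates Environmental columns.
#' @param log_response Correlate `log(response)` instead.
#' @return Tibble: `covariate`, `r`, `p_value`, `n`.
#' @export
env_correlations <- function(series, response = "concentration",
                             covariates = c("temperature_C", "salinity_psu",
                                            "conductivity"),
                             log_response = FALSE) {
  y <- series[[response]]
  if (log_response) y <- log(y)
  purrr::map_dfr(intersect(covariates, names(series)), function(cv) {
    dplyr::bind_cols(tibble::tibble(covariate = cv),
                     pearson(series[[cv]], y))
  })
}
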