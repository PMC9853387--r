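#' Synthetic cytometry populations
#'
#' Describes the event clouds the generator draws: each population has a
#' log10-Gaussian intensity per channel (standard for flow data, where
#' stained-cell fluorescence is approximately log-normal). `fraction` is the
#' proportion of stainable cells for the cell populations; for the `NOISE`
#' row it is instead the rate of sub-threshold background events per expected
#' stainable event.
#'
#' The defaults emulate a SYBR-Green-stained marine surface community: LNA
#' (low-nucleic-acid) bacteria at FL1 log10-mean 2.8, HNA at 3.4 (shared sd
#' 0.15, separable but overlapping), photosynthetic prokaryotes distinguished
#' by red autofluorescence (FL3 log10-mean 3.5 versus <= 2.5 for the rest),
#' and dim instrument/background noise well below the stained populations
#' (FL1 log10-mean 1.8). Fractions default to LNA 0.55, HNA 0.40, PHOTO 0.05
#' with a 0.1 noise rate. These are fixture defaults, not measurements.
#'
#' @param name Population label (`LNA`, `HNA`, `PHOTO`, `NOISE`, or custom).
#' @param fraction Proportion of stainable cells (or noise rate, see above).
#' @param mean,sd Named numeric vectors of per-channel log10 mean / sd.
#' @return A one-row tibble (or, for `default_populations()`, one row per
#'   population) with list-columns `mean` and `sd`.
#' @examples
#' default_populations()
#' @export
population_spec <- function(name, fraction, mean, sd) {
  if (any(sd <= 0)) abort("Channel log10 sds must be positive.")
  if (!identical(sort(names(mean)), sort(names(sd)))) {
    abort("mean and sd must be named by the same channels.")
  }
  sd_ordered <- sd[names(mean)]
  tibble::tibble(
    name = name, fraction = fraction,
    mean = list(mean), sd = list(sd_ordered)
  )
}

#' @rdname population_spec
#' @export
default_populations <- function() {
  chan <- function(fsc, ssc, fl1, fl3) {
    c(`FSC-H` = fsc, `SSC-H` = ssc, `FL1-H` = fl1, `FL3-H` = fl3)
  }
  dplyr::bind_rows(
    population_spec("LNA", 0.55, chan(2.2, 2.0, 2.8, 2.0),
                    chan(0.15, 0.15, 0.15, 0.15)),
    population_spec("HNA", 0.40, chan(2.6, 2.3, 3.4, 2.3),
                    chan(0.15, 0.15, 0.15, 0.15)),
    population_spec("PHOTO", 0.05, chan(2.5, 2.2, 3.0, 3.5),
                    chan(0.15, 0.15, 0.15, 0.15)),
    population_spec("NOISE", 0.10, chan(1.8, 1.7, 1.8, 1.6),
                    chan(0.25, 0.25, 0.25, 0.25))
  )
}

#' FL1 trigger threshold of the emulated instrument
#'
#' The generator's populations live on a fixed intensity scale on which the
#' background noise cloud (FL1 log10-mean 1.8) and the dimmest stained cells
#' (LNA, log10-mean 2.8) are separated by an acquisition trigger at
#' 10^2.35 ~= 224 arbitrary units. Analyses of synthetic campaigns should
#' threshold there; real OC-300/Accuri data use the template value 800.
#'
#' @return Threshold intensity in arbitrary units.
#' @export
synthetic_fl1_threshold <- function() 10^2.35

validate_populations <- function(populations) {
  cells <- dplyr::filter(populations, .data$name != "NOISE")
  if (nrow(cells) == 0) abort("At least one non-NOISE population is required.")
  if (abs(sum(cells$fraction) - 1) > 1e-9) {
    abort("Fractions of non-NOISE populations must sum to 1.")
  }
  invisible(populations)
}

#' Draw events from one synthetic population
#'
#' Each channel intensity is `10^N(mean, sd)` on log10 scale, independent
#' across channels; deterministic for a fixed seed.
#'
#' @param spec A one-row population tibble (see [population_spec()]).
#' @param n Number of events (>= 0).
#' @param seed Optional integer seed.
#' @return A [cyto_frame] of `n` events.
#' @export
sample_population <- function(spec, n, seed = NULL) {
  stopifnot(nrow(spec) == 1, n >= 0)
  if (!is.null(seed)) set.seed(seed)
  mu <- spec$mean[[1]]
  sdv <- spec$sd[[1]]
  cols <- purrr::imap(as.list(mu), function(m, ch) {
    10^rnorm(n, m, sdv[[ch]])
  })
  new_cyto_frame(tibble::as_tibble(cols))
}

#' Simulate one automated cytometer acquisition
#'
#' The number of stainable events follows the counting statistics of a
#' volumetric cytometer: `Poisson(lambda)` with
#' `lambda = concentration * volume / (1000 * dilution)` (concentration in
#' cells/mL, analyzed volume in uL of diluted sample). At the instrument
#' defaults (66 uL, 1:1 stain dilution) a concentration of 5e5 cells/mL
#' yields lambda = 16,500 expected events. Events are split multinomially
#' across the cell populations, and sub-threshold NOISE events are added at
#' the configured rate. The realized per-population counts are returned as
#' ground truth for recovery tests.
#'
#' @param concentration True cell concentration, cells/mL (>= 0).
#' @param populations Population table, see [default_populations()].
#' @param volume Analyzed volume of diluted sample, uL.
#' @param dilution Dilution factor (2 for the 1:1 stain mix).
#' @param seed Optional integer seed.
#' @param acquisition_time Optional `POSIXct` stamped onto the frame.
#' @param flow_rate,run_duration Acquisition metadata stored on the frame
#'   (defaults: 66 uL/min for 60 s, so `volume` should equal
#'   `flow_rate * run_duration / 60` when both are given).
#' @return A list with `frame` (the [cyto_frame], rows shuffled) and `truth`
#'   (tibble of population, n_events) plus the input concentration as
#'   attribute `concentration`.
#' @export
simulate_sample <- function(concentration, populations = default_populations(),
                            volume = 66, dilution = 2, seed = NULL,
                            acquisition_time = NULL,
                            flow_rate = 66, run_duration = 60) {
  stopifnot(concentration >= 0, volume > 0, dilution >= 1)
  validate_populations(populations)
  if (!is.null(seed)) set.seed(seed)

  lambda <- concentration * volume / (1000 * dilution)
  n_cells <- rpois(1, lambda)
  cells <- dplyr::filter(populations, .data$name != "NOISE")
  counts <- if (n_cells > 0) {
    as.vector(stats::rmultinom(1, n_cells, cells$fraction))
  } else {
    rep(0L, nrow(cells))
  }
  noise <- dplyr::filter(populations, .data$name == "NOISE")
  n_noise <- if (nrow(noise)) rpois(1, lambda * noise$fraction[[1]]) else 0L

  spec_rows <- dplyr::bind_rows(cells, noise)
  spec_counts <- c(counts, if (nrow(noise)) n_noise)
  parts <- purrr::map2(seq_len(nrow(spec_rows)), spec_counts, function(i, k) {
    tibble::as_tibble(sample_population(spec_rows[i, ], k))
  })
  events <- dplyr::bind_rows(parts)
  if (nrow(events)) events <- events[sample.int(nrow(events)), ]

  frame <- new_cyto_frame(events,
    acquisition_time = acquisition_time,
    run_duration = run_duration, flow_rate = flow_rate
  )
  truth <- tibble::tibble(population = spec_rows$name, n_events = spec_counts)
  attr(truth, "concentration") <- concentration
  list(frame = frame, truth = truth)
}

#' Describe a synthetic cruise campaign
#'
#' A scenario fixes the sampling clock (>= 15-min cadence, the machine's
#' minimum between samples; tubes rotate in succession so one sample is taken
#' per tick), the station segments with their base concentrations and
#' environmental levels, and the processes modulating true concentration:
#' an exponential net-growth trend, a diel sinusoid with its minimum at
#' midnight and maximum at noon (`1 + A * sin(2*pi*(hour - 6)/24)`),
#' multiplicative log-normal sample-to-sample noise, and a tunable coupling
#' between log-abundance and conductivity.
#'
#' Defaults correspond to an oligotrophic early-summer Mediterranean surface
#' community: base 5e5 cells/mL, 5% diel amplitude, net growth 0.04 per day,
#' 3% sampling noise, abundance-conductivity correlation 0.6.
#'
#' @param start_time,end_time Campaign span (`POSIXct` or parseable strings,
#'   UTC).
#' @param cadence Minutes between samples (>= 15).
#' @param n_tubes Sampling tubes rotating in succession (1-11).
#' @param segments Tibble of station segments: `label`, `start`, `end`,
#'   `base_concentration` (cells/mL), `temperature` (degC), `salinity` (psu),
#'   `conductivity` (instrument units). Default: one segment spanning the
#'   campaign at the levels above.
#' @param diel_amplitude Fractional diel amplitude in `[0, 1)`.
#' @param growth_rate Net exponential growth rate, per day.
#' @param env_coupling Target Pearson correlation between log-abundance and
#'   conductivity (0 disables coupling).
#' @param noise_cv Fractional sd of multiplicative sample-to-sample noise.
#' @param populations Population table for every sample.
#' @param seed Integer seed governing the whole campaign.
#' @return A list of class `cruise_scenario`.
#' @export
cruise_scenario <- function(start_time = "2021-06-03 00:00:00",
                            end_time = "2021-06-04 00:00:00",
                            cadence = 15, n_tubes = 3, segments = NULL,
                            diel_amplitude = 0.05, growth_rate = 0.04,
                            env_coupling = 0.6, noise_cv = 0.03,
                            populations = default_populations(),
                            seed = 1L) {
  start_time <- as.POSIXct(start_time, tz = "UTC")
  end_time <- as.POSIXct(end_time, tz = "UTC")
  stopifnot(end_time > start_time)
  if (cadence < 15) abort("cadence must be >= 15 min (machine minimum).")
  if (diel_amplitude < 0 || diel_amplitude >= 1) {
    abort("diel_amplitude must be in [0, 1).")
  }
  if (noise_cv < 0) abort("noise_cv must be >= 0.")
  if (n_tubes < 1 || n_tubes > 11) abort("n_tubes must be in 1..11.")
  if (is.null(segments)) {
    segments <- tibble::tibble(
      label = "D", start = start_time, end = end_time,
      base_concentration = 5e5, temperature = 20, salinity = 38,
      conductivity = 55
    )
  }
  validate_populations(populations)
  structure(
    list(start_time = start_time, end_time = end_time, cadence = cadence,
         n_tubes = n_tubes, segments = segments,
         diel_amplitude = diel_amplitude, growth_rate = growth_rate,
         env_coupling = env_coupling, noise_cv = noise_cv,
         populations = populations, seed = as.integer(seed)),
    class = "cruise_scenario"
  )
}

#' True concentrations along a scenario's sampling clock
#'
#' Evaluates, without writing any files, the per-sample ground truth a
#' scenario implies: sampling timestamps (one per cadence tick, tubes
#' rotating), the segment each falls in, and the true concentration
#' `base * exp(growth_rate * t_days) * (1 + A*sin(2*pi*(hour - 6)/24)) *
#' lognormal(0, noise_cv)`.
#'
#' @param scenario A [cruise_scenario()].
#' @return Tibble: `sample_id`, `timestamp`, `tube_id`, `station_label`,
#'   `true_concentration`, `conductivity`, `temperature`, `salinity`.
#' @export
cruise_truth <- function(scenario) {
  sc <- scenario
  set.seed(sc$seed)
  total_min <- as.numeric(difftime(sc$end_time, sc$start_time, units = "mins"))
  n <- floor(total_min / sc$cadence)
  if (n < 1) abort("Scenario spans fewer than one cadence tick.")
  ts <- sc$start_time + (seq_len(n) - 1) * sc$cadence * 60
  tube <- ((seq_len(n) - 1) %% sc$n_tubes) + 1L

  seg_idx <- vapply(ts, function(t) {
    i <- which(sc$segments$start <= t & t < sc$segments$end)
    if (!length(i)) i <- which.min(abs(as.numeric(sc$segments$start) - as.numeric(t)))
    i[1]
  }, integer(1))
  seg <- sc$segments[seg_idx, ]

  t_days <- as.numeric(difftime(ts, sc$start_time, units = "days"))
  hour <- as.numeric(format(ts, "%H", tz = "UTC")) +
    as.numeric(format(ts, "%M", tz = "UTC")) / 60
  diel <- 1 + sc$diel_amplitude * sin(2 * pi * (hour - 6) / 24)
  sdlog <- sqrt(log1p(sc$noise_cv^2))
  noise <- rlnorm(n, -sdlog^2 / 2, sdlog)  # mean-one multiplicative noise
  conc <- seg$base_concentration * exp(sc$growth_rate * t_days) * diel * noise

  # conductivity = segment level + log-abundance anomaly + noise scaled so
  # that cor(log conc, conductivity) hits env_coupling in expectation
  x <- log(conc)
  anom <- x - mean(x)
  r <- sc$env_coupling
  cond <- if (abs(r) > 0 && sd(x) > 0) {
    s <- sd(x) * sqrt(1 / r^2 - 1)
    seg$conductivity + sign(r) * anom + rnorm(n, 0, s)
  } else {
    seg$conductivity + rnorm(n, 0, 0.05)
  }

  tibble::tibble(
    sample_id = paste0(format(ts, "%Y-%m-%d_%H-%M-%S", tz = "UTC"),
                       sprintf("_tube%d.fcs", tube)),
    timestamp = ts, tube_id = tube, station_label = seg$label,
    true_concentration = conc, conductivity = cond,
    temperature = seg$temperature + rnorm(n, 0, 0.05),
    salinity = seg$salinity + rnorm(n, 0, 0.02)
  )
}

#' Generate a full synthetic cruise on disk
#'
#' Writes the same artifacts an OC-300 campaign produces: one time-signature
#' run folder per sample holding a `tube<k>.fcs` cytogram, a
#' thermosalinograph CSV at 1-min cadence (`timestamp, temperature_C,
#' salinity_psu, conductivity`), and a ground-truth CSV (`truth.csv`:
#' per-sample true concentration, population fractions, realized counts).
#' Byte-identical for a fixed scenario seed.
#'
#' @param scenario A [cruise_scenario()].
#' @param out_root Output directory (created if missing).
#' @return Invisibly, a list with `run_root`, `env_csv`, `truth_csv`, and the
#'   `truth` and `env` tibbles.
#' @export
simulate_cruise <- function(scenario, out_root) {
  sc <- scenario
  truth <- cruise_truth(sc)
  dir.create(out_root, recursive = TRUE, showWarnings = FALSE)
  run_root <- file.path(out_root, "runs")
  dir.create(run_root, showWarnings = FALSE)
  if (!dir.exists(run_root)) abort(sprintf("Cannot create %s", run_root))

  cells <- dplyr::filter(sc$populations, .data$name != "NOISE")
  seeds <- sample.int(.Machine$integer.max, nrow(truth))
  realized <- purrr::map(seq_len(nrow(truth)), function(i) {
    sim <- simulate_sample(
      truth$true_concentration[i], populations = sc$populations,
      volume = 66, dilution = 2, seed = seeds[i],
      acquisition_time = truth$timestamp[i]
    )
    folder <- file.path(run_root, format(truth$timestamp[i],
                                         "%Y-%m-%d_%H-%M-%S", tz = "UTC"))
    dir.create(folder, showWarnings = FALSE)
    write_fcs(sim$frame, file.path(folder,
                                   sprintf("tube%d.fcs", truth$tube_id[i])))
    stats::setNames(sim$truth$n_events, sim$truth$population)
  })
  counts <- dplyr::bind_rows(purrr::map(realized, ~ tibble::as_tibble(as.list(.x))))
  names(counts) <- paste0("n_", names(counts))
  truth_out <- dplyr::bind_cols(truth, counts)
  for (p in cells$name) {
    truth_out[[paste0("frac_", p)]] <- cells$fraction[cells$name == p]
  }

  # thermosalinograph stream at 1-min cadence, interpolating the per-sample
  # coupled conductivity between sampling instants
  minutes <- seq(sc$start_time, sc$end_time, by = 60)
  interp <- function(y) {
    stats::approx(as.numeric(truth$timestamp), y, as.numeric(minutes),
                  rule = 2)$y
  }
  env <- tibble::tibble(
    timestamp = minutes,
    temperature_C = interp(truth$temperature) + rnorm(length(minutes), 0, 0.01),
    salinity_psu = interp(truth$salinity) + rnorm(length(minutes), 0, 0.005),
    conductivity = interp(truth$conductivity) + rnorm(length(minutes), 0, 0.005)
  )

  env_csv <- file.path(out_root, "env.csv")
  truth_csv <- file.path(out_root, "truth.csv")
  write_timestamped_csv(env, env_csv)
  write_timestamped_csv(truth_out, truth_csv)
  invisible(list(run_root = run_root, env_csv = env_csv, truth_csv = truth_csv,
                 truth = truth_out, env = env))
}

write_timestamped_csv <- function(df, path) {
  df$timestamp <- format(df$timestamp, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
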