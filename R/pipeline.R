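#' Analyze a collated campaign end to end
#'
#' Runs the whole pipeline over a run-folder tree: collate the runs, read
#' each cytogram, apply the FL1 acquisition threshold, asinh-transform,
#' optionally gate, normalize the whole set to the global maximum green
#' fluorescence, subsample every cytogram to the common minimum, then
#' estimate per-sample abundance, mean/median relative size (and biomass
#' when a bead calibration is supplied), binned fingerprints with Hill
#' diversity, and SOM population structure (HNA/LNA/PHOTO counts and the
#' HNA/LNA ratio). When an environmental stream is given, each sample is
#' matched to its nearest record.
#'
#' @param run_root Directory of time-signature run folders.
#' @param env Optional environmental tibble ([read_env_csv()]) or CSV path.
#' @param config An [analysis_config()]; `fl1_threshold` must sit on the
#'   intensity scale of the data (800 for Accuri acquisitions,
#'   [synthetic_fl1_threshold()] for synthetic campaigns).
#' @param gate Optional [gate_spec()] applied after the transform (must be
#'   defined in transformed units).
#' @param som_pool_max Events pooled across samples for SOM training.
#' @param env_tolerance Seconds; see [align_env()].
#' @return A `cruise_analysis` list: `series` (per-sample tibble keyed by
#'   `sample_id`), `diversity` (long Hill-number table), `populations`,
#'   `fingerprints`, `som`, `metaclusters`, and a run `manifest`.
#' @export
analyze_campaign <- function(run_root, env = NULL,
                             config = analysis_config(), gate = NULL,
                             som_pool_max = 20000, env_tolerance = 450) {
  started <- Sys.time()
  set.seed(config$seed)
  volume <- config$flow_rate * config$run_duration / 60
  records <- collate_runs(run_root, dilution_factor = config$dilution_factor,
                          analyzed_volume = volume)
  if (!nrow(records)) abort(sprintf("No collatable runs under %s", run_root))
  if (!is.null(gate) && !isTRUE(gate$transformed)) {
    abort("The pipeline gate must be defined in transformed units.")
  }

  frames <- purrr::map(records$source_path, read_fcs)
  n_raw <- vapply(frames, nrow, integer(1))
  frames <- purrr::map(frames, apply_threshold,
                       threshold = config$fl1_threshold)
  n_thr <- vapply(frames, nrow, integer(1))
  frames <- purrr::map(frames, transform_asinh,
                       cofactor = config$transform_cofactor)
  if (!is.null(gate)) frames <- purrr::map(frames, apply_gate, gate = gate)
  n_gated <- vapply(frames, nrow, integer(1))
  if (any(n_gated == 0)) {
    abort(sprintf("Sample(s) with zero gated events: %s",
                  paste(records$sample_id[n_gated == 0], collapse = ", ")))
  }

  # per-sample summaries on gated events (FSC back on the raw scale)
  fsc_raw <- purrr::map(frames, function(f) {
    sinh(f[["FSC-H"]]) * config$transform_cofactor
  })
  norm <- normalize_to_max(frames)
  n_sub <- if (identical(config$subsample_size, "auto-min")) {
    min_cell_count(norm$frames)
  } else {
    config$subsample_size
  }
  seeds <- sample.int(.Machine$integer.max, length(frames))
  sub <- purrr::map2(norm$frames, seeds, function(f, s) {
    subsample_events(f, n_sub, seed = s)
  })

  fps <- purrr::map2(sub, records$sample_id, function(f, id) {
    bin_events(f, grid_size = config$grid_size, sample_id = id, clamp = TRUE)
  })
  diversity <- purrr::map_dfr(fps, hill_diversity)

  # SOM on events pooled evenly across samples. Clustering and population
  # labelling run on the transformed (unnormalized) scale, where the
  # FL3 separation of photosynthetic cells has a fixed magnitude; the
  # subsampled normalized frames are rescaled back by the global divisor.
  unnorm <- purrr::map(sub, function(f) {
    rescale_channels(f, names(f), 1 / norm$scale)
  })
  per_sample <- max(1L, ceiling(som_pool_max / length(unnorm)))
  pool_seeds <- sample.int(.Machine$integer.max, length(unnorm))
  pooled <- dplyr::bind_rows(purrr::map2(unnorm, pool_seeds, function(f, s) {
    tibble::as_tibble(subsample_events(f, min(nrow(f), per_sample), seed = s))
  }))
  pooled <- new_cyto_frame(pooled)
  som <- train_som(pooled, grid = config$som_grid, seed = config$seed)
  map <- metacluster(som, k = config$n_metaclusters)
  map <- label_populations(map, som, pooled)
  populations <- purrr::map2_dfr(unnorm, records$sample_id, function(f, id) {
    dplyr::bind_cols(tibble::tibble(sample_id = id),
                     population_counts(map, som, f))
  })

  series <- dplyr::mutate(records,
    gated_events = n_gated,
    mean_fsc = vapply(fsc_raw, mean, numeric(1)),
    median_fsc = vapply(fsc_raw, median, numeric(1))
  )
  series <- abundance_table(series)
  if (!is.null(config$bead_fsc)) {
    series <- size_biomass_table(
      series, bead_fsc = config$bead_fsc,
      bead_diameter = config$bead_diameter, gamma = config$fsc_size_exponent,
      coefficient = config$biomass_coefficient,
      exponent = config$biomass_exponent
    )
  }
  d2 <- dplyr::filter(diversity, .data$q == 2)
  series$D2 <- d2$D[match(series$sample_id, d2$sample_id)]
  series <- dplyr::left_join(series, populations, by = "sample_id")

  if (!is.null(env)) {
    if (is.character(env)) env <- read_env_csv(env)
    series <- align_env(series, env, tolerance = env_tolerance)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("cytocruise")),
    config = unclass(config), run_root = run_root,
    seed = config$seed, subsample_size = n_sub,
    normalization_scale = norm$scale,
    stage_counts = tibble::tibble(
      sample_id = records$sample_id, n_raw = n_raw, n_threshold = n_thr,
      n_gated = n_gated, n_subsampled = n_sub
    ),
    started = format(started, "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  )
  structure(
    list(series = series, diversity = diversity, populations = populations,
         fingerprints = fps, som = som, metaclusters = map,
         manifest = manifest),
    class = "cruise_analysis"
  )
}

#' @export
print.cruise_analysis <- function(x, ...) {
  cat(sprintf(
    "<cruise_analysis> %d samples | %d events/sample after subsampling\n",
    nrow(x$series), x$manifest$subsample_size
  ))
  print(dplyr::select(x$series, dplyr::any_of(c(
    "sample_id", "timestamp", "concentration", "D2", "hna_lna_ratio"
  ))))
  invisible(x)
}

#' Tidy / summarize a campaign analysis
#'
#' `tidy()` returns the per-sample series; `glance()` a one-row campaign
#' summary (sample count, events per sample, concentration and diversity
#' ranges).
#'
#' @param x A `cruise_analysis`.
#' @param ... Unused.
#' @export
tidy.cruise_analysis <- function(x, ...) tibble::as_tibble(x$series)

#' @rdname tidy.cruise_analysis
#' @export
glance.cruise_analysis <- function(x, ...) {
  tibble::tibble(
    n_samples = nrow(x$series),
    events_per_sample = x$manifest$subsample_size,
    concentration_min = min(x$series$concentration),
    concentration_max = max(x$series$concentration),
    d2_min = min(x$series$D2), d2_max = max(x$series$D2)
  )
}

#' Write campaign outputs as CSV/JSON
#'
#' Emits `series.csv`, `diversity.csv`, `populations.csv`,
#' `fingerprints.csv` (sparse triplets), `som.json` and `manifest.json`
#' under `dir`.
#'
#' @param analysis A `cruise_analysis`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_campaign <- function(analysis, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  series <- analysis$series
  series$timestamp <- format(series$timestamp, "%Y-%m-%dT%H:%M:%S",
                             tz = "UTC")
  utils::write.csv(series, file.path(dir, "series.csv"), row.names = FALSE)
  utils::write.csv(analysis$diversity, file.path(dir, "diversity.csv"),
                   row.names = FALSE)
  utils::write.csv(analysis$populations, file.path(dir, "populations.csv"),
                   row.names = FALSE)
  write_fingerprints(analysis$fingerprints, file.path(dir, "fingerprints.csv"))
  write_som(analysis$som, file.path(dir, "som.json"))
  manifest <- analysis$manifest
  manifest$stage_counts <- as.list(manifest$stage_counts)
  manifest$config$som_grid <- as.list(manifest$config$som_grid)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Sampling gain of automated over station sampling
#'
#' How many times more surface samples the automated sampler yields than a
#' station plan (366 automated vs 4 station casts gives 91.5, i.e. "more
#' than 90 times" as many).
#'
#' @param n_automated,n_station Sample counts (> 0).
#' @return The ratio.
#' @export
sampling_gain <- function(n_automated, n_station) {
  if (any(n_station <= 0)) abort("Station sample count must be positive.")
  n_automated / n_station
}
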