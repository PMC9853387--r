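#' Analysis configuration
#'
#' One structured object holding every tunable constant of the pipeline.
#' Defaults reproduce the OC-300/Accuri acquisition described in the package
#' vignette: 1-min runs at 66 uL/min fast speed, 1:1 stain dilution, FL1
#' trigger threshold 800, asinh transform with cofactor 1, 128 x 128 bin
#' fingerprints, a 10 x 10 self-organizing map (100 clusters) merged into 10
#' metaclusters, 0.5-um calibration beads, and the carbon conversion
#' biomass = 0.2 * V^0.72 pgC per cell.
#'
#' @param fl1_threshold Acquisition trigger on green fluorescence (FL1),
#'   instrument arbitrary units. Events below it are discarded.
#' @param transform_cofactor Cofactor `c` of the asinh(x / c) transform.
#' @param subsample_size Events kept per sample after subsampling; `"auto-min"`
#'   resolves to the minimum event count across the analyzed set.
#' @param grid_size Fingerprint bins per axis.
#' @param som_grid Integer `c(rows, cols)` of the SOM; rows * cols clusters.
#' @param n_metaclusters Metaclusters cut from the SOM code-vector dendrogram.
#' @param dilution_factor Stain dilution (2 = 1:1 mix with stain solution).
#' @param flow_rate uL/min through the cytometer.
#' @param run_duration Acquisition seconds per sample.
#' @param bead_diameter Calibration bead diameter, um.
#' @param bead_fsc Mean forward scatter of the calibration beads,
#'   instrument units (must be supplied for absolute size estimates).
#' @param fsc_size_exponent Exponent gamma of the single-point power-law size
#'   calibration d = bead_diameter * (FSC / bead_FSC)^(1/gamma).
#' @param biomass_coefficient,biomass_exponent Carbon conversion
#'   `pgC = coefficient * V^exponent` with V in um^3.
#' @param day_window Local-time hours `c(start, end)` classifying daylight
#'   samples; default 06:00-21:00.
#' @param seed Integer seed for every stochastic stage.
#' @return A list of class `cyto_config`.
#' @export
analysis_config <- function(fl1_threshold = 800,
                            transform_cofactor = 1,
                            subsample_size = "auto-min",
                            grid_size = 128,
                            som_grid = c(10, 10),
                            n_metaclusters = 10,
                            dilution_factor = 2,
                            flow_rate = 66,
                            run_duration = 60,
                            bead_diameter = 0.5,
                            bead_fsc = NULL,
                            fsc_size_exponent = 2,
                            biomass_coefficient = 0.2,
                            biomass_exponent = 0.72,
                            day_window = c(6, 21),
                            seed = 1L) {
  cfg <- list(
    fl1_threshold = fl1_threshold, transform_cofactor = transform_cofactor,
    subsample_size = subsample_size, grid_size = grid_size,
    som_grid = as.integer(som_grid), n_metaclusters = n_metaclusters,
    dilution_factor = dilution_factor, flow_rate = flow_rate,
    run_duration = run_duration, bead_diameter = bead_diameter,
    bead_fsc = bead_fsc, fsc_size_exponent = fsc_size_exponent,
    biomass_coefficient = biomass_coefficient,
    biomass_exponent = biomass_exponent, day_window = day_window,
    seed = as.integer(seed)
  )
  stopifnot(
    cfg$transform_cofactor > 0, cfg$grid_size >= 2,
    cfg$dilution_factor >= 1, cfg$flow_rate > 0, cfg$run_duration > 0,
    cfg$bead_diameter > 0, cfg$fsc_size_exponent > 0,
    length(cfg$som_grid) == 2, all(cfg$som_grid >= 1),
    cfg$n_metaclusters >= 1
  )
  class(cfg) <- "cyto_config"
  cfg
}

#' Read / write an analysis configuration as YAML
#'
#' Key names match the arguments of [analysis_config()]; unknown keys error.
#'
#' @param path YAML file.
#' @return `read_config()` returns a `cyto_config`; `write_config()` returns
#'   `path` invisibly.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  unknown <- setdiff(names(raw), names(formals(analysis_config)))
  if (length(unknown)) {
    abort(sprintf("Unknown config key(s): %s", paste(unknown, collapse = ", ")))
  }
  do.call(analysis_config, raw)
}

#' @rdname read_config
#' @param config A `cyto_config`.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
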