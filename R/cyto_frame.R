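#' Event matrix (cytogram) container
#'
#' A `cyto_frame` is a tibble with one row per detected particle (event) and
#' one column per detector channel, carrying acquisition metadata as
#' attributes. It is the unit every event-level operation in the package
#' consumes and returns, so cytograms chain naturally through the pipe.
#'
#' Channel intensities are instrument arbitrary units, non-negative and
#' finite. Conventional channel names follow the Accuri layout: `FSC-H`,
#' `SSC-H` (forward/side scatter), `FL1-H` (green fluorescence, the SYBR
#' Green nucleic-acid signal) and `FL3-H` (red fluorescence,
#' photosynthetic-pigment autofluorescence); `-A` area variants are allowed.
#'
#' @param events A data frame of per-event channel intensities.
#' @param acquisition_time Optional `POSIXct` acquisition timestamp.
#' @param run_duration Optional run duration in seconds (> 0).
#' @param flow_rate Optional sample flow rate in uL/min (> 0).
#' @param source_path Optional path of the file the events came from.
#'
#' @return A `cyto_frame` (tibble subclass).
#' @examples
#' cf <- cyto_frame(data.frame(`FSC-H` = c(120, 340), `FL1-H` = c(900, 1500),
#'                             check.names = FALSE))
#' n_events(cf)
#' @export
cyto_frame <- function(events, acquisition_time = NULL, run_duration = NULL,
                       flow_rate = NULL, source_path = NULL) {
  events <- tibble::as_tibble(events)
  out <- new_cyto_frame(events,
    acquisition_time = acquisition_time,
    run_duration = run_duration,
    flow_rate = flow_rate,
    source_path = source_path
  )
  validate_cyto_frame(out)
  out
}

new_cyto_frame <- function(events, acquisition_time = NULL,
                           run_duration = NULL, flow_rate = NULL,
                           source_path = NULL) {
  structure(
    events,
    acquisition_time = acquisition_time,
    run_duration = run_duration,
    flow_rate = flow_rate,
    source_path = source_path,
    class = c("cyto_frame", class(tibble::tibble()))
  )
}

validate_cyto_frame <- function(x) {
  nm <- names(x)
  if (anyDuplicated(nm)) {
    abort("Channel names of a cyto_frame must be unique.")
  }
  if (ncol(x) > 0 && !all(vapply(x, is.numeric, logical(1)))) {
    abort("All channels of a cyto_frame must be numeric.")
  }
  vals <- unlist(x, use.names = FALSE)
  if (length(vals) && !all(is.finite(vals))) {
    abort("Channel intensities must be finite.")
  }
  rd <- attr(x, "run_duration")
  if (!is.null(rd) && (!is.numeric(rd) || rd <= 0)) {
    abort("run_duration must be a positive number of seconds.")
  }
  fr <- attr(x, "flow_rate")
  if (!is.null(fr) && (!is.numeric(fr) || fr <= 0)) {
    abort("flow_rate must be positive (uL/min).")
  }
  invisible(x)
}

#' @rdname cyto_frame
#' @param x A `cyto_frame`.
#' @export
n_events <- function(x) nrow(x)

#' @rdname cyto_frame
#' @export
channel_names <- function(x) names(x)

#' Rebuild a cyto_frame around a modified event table
#'
#' Keeps acquisition metadata from `template` while replacing the events;
#' used internally so filtering/transforming never drops metadata.
#'
#' @param events New event table.
#' @param template `cyto_frame` supplying the metadata attributes.
#' @keywords internal
#' @export
with_events <- function(events, template) {
  new_cyto_frame(
    tibble::as_tibble(events),
    acquisition_time = attr(template, "acquisition_time"),
    run_duration = attr(template, "run_duration"),
    flow_rate = attr(template, "flow_rate"),
    source_path = attr(template, "source_path")
  )
}

#' @export
print.cyto_frame <- function(x, ...) {
  at <- attr(x, "acquisition_time")
  cat(sprintf(
    "<cyto_frame> %d events x %d channels%s\n", nrow(x), ncol(x),
    if (is.null(at)) "" else paste0(" | acquired ", format(at, usetz = TRUE))
  ))
  NextMethod()
}

require_channels <- function(x, channels) {
  missing <- setdiff(channels, names(x))
  if (length(missing)) {
    abort(sprintf(
      "Channel(s) %s not present (available: %s).",
      paste(missing, collapse = ", "), paste(names(x), collapse = ", ")
    ), class = "cytocruise_channel_error")
  }
  invisible(x)
}

#' Analyzed sample volume of a run
#'
#' Volume of (diluted) sample pushed through the cytometer,
#' `flow_rate * run_duration / 60` in uL. The OC-300 runs 1 min at fast
#' speed (66 uL/min), so the default acquisition analyzes 66 uL.
#'
#' @param x A `cyto_frame`.
#' @param flow_rate,run_duration Overrides (uL/min, seconds) used when the
#'   file carried no acquisition keywords.
#' @return Volume in uL.
#' @export
analyzed_volume <- function(x, flow_rate = NULL, run_duration = NULL) {
  fr <- flow_rate %||% attr(x, "flow_rate")
  rd <- run_duration %||% attr(x, "run_duration")
  if (is.null(fr) || is.null(rd)) {
    abort("flow_rate and run_duration must be set (on the frame or as arguments).")
  }
  fr * rd / 60
}

`%||%` <- function(a, b) if (is.null(a)) b else a
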