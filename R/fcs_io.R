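#' Read a Flow Cytometry Standard (FCS) file
#'
#' Parses FCS 2.0 / 3.0 / 3.1 single-dataset files with list-mode data stored
#' as integers (8/16/32 bit), single-precision floats or doubles, on either
#' byte order. Channel labels come from the `$PnN` keywords (falling back to
#' `$PnS`); acquisition metadata (`$DATE`/`$BTIM`, and the `RUNDURATION` /
#' `FLOWRATE` keywords this package writes) populate the returned frame's
#' attributes when present and are left unset otherwise.
#'
#' No compensation or amplification-law decoding is applied: only linear
#' (`$PnE` = `0,0` or absent) parameters are supported, matching the
#' uncompensated SYBR-Green acquisition the pipeline targets.
#'
#' @param path Path to an FCS file.
#' @return A [cyto_frame] with one row per event.
#' @seealso [write_fcs()], [collate_runs()]
#' @export
read_fcs <- function(path) {
  if (!file.exists(path)) abort(sprintf("FCS file not found: %s", path))
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 58) {
    abort(sprintf("'%s': truncated FCS HEADER segment (%d bytes).",
                  path, length(raw)),
          class = "cytocruise_fcs_format_error")
  }
  version <- trimws(rawToChar(raw[1:6]))
  if (!version %in% c("FCS2.0", "FCS3.0", "FCS3.1")) {
    abort(sprintf("'%s': unrecognized FCS version string '%s' in HEADER.",
                  path, version),
          class = "cytocruise_fcs_format_error")
  }
  off <- function(i) {
    s <- trimws(rawToChar(raw[(10 + 8 * (i - 1) + 1):(10 + 8 * i)]))
    if (s == "") 0 else suppressWarnings(as.numeric(s))
  }
  text_beg <- off(1); text_end <- off(2)
  data_beg <- off(3); data_end <- off(4)
  if (is.na(text_beg) || is.na(text_end) || text_beg < 1 ||
      text_end + 1 > length(raw) || text_end < text_beg) {
    abort(sprintf("'%s': invalid TEXT segment offsets in HEADER.", path),
          class = "cytocruise_fcs_format_error")
  }

  kw <- parse_fcs_text(raw[(text_beg + 1):(text_end + 1)])
  getkw <- function(key, default = NULL) kw[[key]] %||% default

  if (toupper(getkw("$MODE", "L")) != "L") {
    abort(sprintf("'%s': only list-mode ($MODE L) data is supported.", path),
          class = "cytocruise_fcs_format_error")
  }
  if (as.numeric(getkw("$NEXTDATA", "0")) != 0) {
    warn(sprintf("'%s': multi-dataset file; only the first dataset is read.",
                 path))
  }

  n_par <- as.integer(getkw("$PAR", "0"))
  n_tot <- as.integer(getkw("$TOT", "0"))
  if (is.na(n_par) || n_par < 1) {
    abort(sprintf("'%s': missing/invalid $PAR keyword in TEXT segment.", path),
          class = "cytocruise_fcs_format_error")
  }

  ch <- vapply(seq_len(n_par), function(i) {
    getkw(sprintf("$P%dN", i)) %||% getkw(sprintf("$P%dS", i)) %||%
      sprintf("P%d", i)
  }, character(1))
  ch <- make.unique(ch)

  for (i in seq_len(n_par)) {
    pe <- getkw(sprintf("$P%dE", i), "0,0")
    if (!grepl("^\\s*0\\s*,\\s*0\\s*$", pe)) {
      abort(sprintf(
        "'%s': parameter %d uses log amplification ($P%dE = %s); only linear data is supported.",
        path, i, i, pe), class = "cytocruise_fcs_format_error")
    }
  }

  if (data_beg == 0 || data_end == 0) {
    data_beg <- as.numeric(getkw("$BEGINDATA", "0"))
    data_end <- as.numeric(getkw("$ENDDATA", "0"))
  }

  if (n_tot > 0) {
    dtype <- toupper(getkw("$DATATYPE", "F"))
    byteord <- gsub("\\s", "", getkw("$BYTEORD", "1,2,3,4"))
    endian <- if (byteord %in% c("1,2,3,4", "1,2", "12")) "little"
              else if (byteord %in% c("4,3,2,1", "2,1", "21")) "big"
              else abort(sprintf("'%s': unsupported $BYTEORD '%s'.", path, byteord),
                         class = "cytocruise_fcs_format_error")
    bits <- unique(vapply(seq_len(n_par),
                          function(i) as.integer(getkw(sprintf("$P%dB", i), "32")),
                          integer(1)))
    if (length(bits) != 1L) {
      abort(sprintf("'%s': mixed $PnB widths are not supported.", path),
            class = "cytocruise_fcs_format_error")
    }
    n_values <- n_tot * n_par
    bytes_needed <- n_values * bits / 8
    # FCS offsets are 0-based byte positions of the first and last data byte
    if (data_beg < 1 || data_end + 1 > length(raw) ||
        data_end - data_beg + 1 < bytes_needed) {
      abort(sprintf(
        "'%s': DATA segment truncated (need %d bytes for %d events, have %d).",
        path, bytes_needed, n_tot, max(0, data_end - data_beg + 1)),
        class = "cytocruise_fcs_format_error")
    }
    seg <- raw[(data_beg + 1):(data_beg + bytes_needed)]
    vals <- switch(dtype,
      "F" = {
        if (bits != 32) abort(sprintf("'%s': $DATATYPE F requires $PnB 32.", path),
                              class = "cytocruise_fcs_format_error")
        readBin(seg, "numeric", n = n_values, size = 4, endian = endian)
      },
      "D" = {
        if (bits != 64) abort(sprintf("'%s': $DATATYPE D requires $PnB 64.", path),
                              class = "cytocruise_fcs_format_error")
        readBin(seg, "numeric", n = n_values, size = 8, endian = endian)
      },
      "I" = {
        if (!bits %in% c(8L, 16L, 32L)) {
          abort(sprintf("'%s': integer width %d bits not supported.", path, bits),
                class = "cytocruise_fcs_format_error")
        }
        v <- readBin(seg, "integer", n = n_values, size = bits / 8,
                     signed = (bits == 32L), endian = endian)
        if (bits == 32L && any(v < 0)) v <- v + (v < 0) * 2^32
        as.numeric(v)
      },
      abort(sprintf("'%s': unsupported $DATATYPE '%s'.", path, dtype),
            class = "cytocruise_fcs_format_error")
    )
    events <- matrix(vals, ncol = n_par, byrow = TRUE)
  } else {
    events <- matrix(numeric(0), ncol = n_par)
  }
  colnames(events) <- ch

  acq <- parse_fcs_datetime(getkw("$DATE"), getkw("$BTIM"))
  rd <- suppressWarnings(as.numeric(getkw("RUNDURATION")))
  fr <- suppressWarnings(as.numeric(getkw("FLOWRATE")))
  new_cyto_frame(
    tibble::as_tibble(events),
    acquisition_time = acq,
    run_duration = if (length(rd) && !is.na(rd)) rd else NULL,
    flow_rate = if (length(fr) && !is.na(fr)) fr else NULL,
    source_path = path
  )
}

# TEXT segment: first byte is the delimiter, then alternating key/value.
parse_fcs_text <- function(bytes) {
  delim <- rawToChar(bytes[1])
  body <- rawToChar(bytes[-1])
  parts <- strsplit(body, delim, fixed = TRUE)[[1]]
  parts <- parts[seq_len(length(parts) - length(parts) %% 2)]
  if (!length(parts)) return(list())
  keys <- toupper(trimws(parts[c(TRUE, FALSE)]))
  vals <- parts[c(FALSE, TRUE)]
  stats::setNames(as.list(vals), keys)
}

parse_fcs_datetime <- function(date, btim) {
  if (is.null(date) || is.null(btim)) return(NULL)
  for (fmt in c("%d-%b-%Y %H:%M:%S", "%Y-%m-%d %H:%M:%S")) {
    t <- as.POSIXct(paste(date, btim), format = fmt, tz = "UTC")
    if (!is.na(t)) return(t)
  }
  NULL
}

#' Write a cytogram to an FCS 3.1 file
#'
#' Emits a single-dataset FCS 3.1 file, list mode, 32-bit little-endian
#' floats — the simplest widely readable dialect. [read_fcs()] inverts it up
#' to single-precision rounding. Acquisition metadata on the frame is stored
#' as `$DATE`/`$BTIM` plus the non-standard `RUNDURATION` (s) and `FLOWRATE`
#' (uL/min) keywords.
#'
#' @param frame A valid [cyto_frame] (finite, non-negative intensities,
#'   at least one channel).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fcs <- function(frame, path) {
  if (ncol(frame) == 0) {
    abort("Cannot write an FCS file with no channels.")
  }
  validate_cyto_frame(frame)
  vals <- unlist(frame, use.names = FALSE)
  if (length(vals) && any(vals < 0)) {
    abort("Channel intensities must be non-negative to write FCS.")
  }

  n_tot <- nrow(frame)
  n_par <- ncol(frame)
  rng <- vapply(frame, function(x) if (length(x)) max(x) else 0, numeric(1))
  pnr <- pmax(1024, 2^ceiling(log2(pmax(rng, 1) + 1)))

  kw <- c(
    "$BEGINANALYSIS", "0", "$ENDANALYSIS", "0",
    "$BEGINSTEXT", "0", "$ENDSTEXT", "0",
    "$BEGINDATA", "@@@@@BD@@@", "$ENDDATA", "@@@@@ED@@@",
    "$BYTEORD", "1,2,3,4", "$DATATYPE", "F", "$MODE", "L",
    "$NEXTDATA", "0",
    "$PAR", as.character(n_par), "$TOT", as.character(n_tot)
  )
  for (i in seq_len(n_par)) {
    kw <- c(kw,
      sprintf("$P%dN", i), names(frame)[i],
      sprintf("$P%dB", i), "32",
      sprintf("$P%dE", i), "0,0",
      sprintf("$P%dR", i), format(pnr[i], scientific = FALSE)
    )
  }
  at <- attr(frame, "acquisition_time")
  if (!is.null(at)) {
    kw <- c(kw, "$DATE", format(at, "%d-%b-%Y", tz = "UTC"),
            "$BTIM", format(at, "%H:%M:%S", tz = "UTC"))
  }
  if (!is.null(attr(frame, "run_duration"))) {
    kw <- c(kw, "RUNDURATION", format(attr(frame, "run_duration")))
  }
  if (!is.null(attr(frame, "flow_rate"))) {
    kw <- c(kw, "FLOWRATE", format(attr(frame, "flow_rate")))
  }

  delim <- "/"
  if (any(grepl(delim, kw, fixed = TRUE))) {
    abort("Keyword values may not contain the '/' delimiter.")
  }
  # fixed-width data offsets so TEXT length is independent of their value
  text_body <- paste0(delim, paste0(kw, delim, collapse = ""))
  header_len <- 58L
  text_beg <- header_len
  text_end <- text_beg + nchar(text_body, type = "bytes") - 1L
  data_len <- n_tot * n_par * 4
  data_beg <- if (data_len > 0) text_end + 1L else 0L
  data_end <- if (data_len > 0) data_beg + data_len - 1L else 0L
  # placeholders are 10 bytes wide, so substitution keeps every offset valid
  text_body <- sub("@@@@@BD@@@", sprintf("%010d", data_beg), text_body,
                   fixed = TRUE)
  text_body <- sub("@@@@@ED@@@", sprintf("%010d", data_end), text_body,
                   fixed = TRUE)

  hdr_off <- function(x) {
    s <- format(x, scientific = FALSE)
    if (nchar(s) > 8) "       0" else formatC(s, width = 8)
  }
  header <- paste0(
    "FCS3.1    ",
    hdr_off(text_beg), hdr_off(text_end),
    hdr_off(if (data_len > 0) data_beg else 0),
    hdr_off(if (data_len > 0) data_end else 0),
    hdr_off(0), hdr_off(0)
  )

  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(header, con, eos = NULL)
  writeChar(text_body, con, eos = NULL)
  if (n_tot > 0) {
    writeBin(as.numeric(t(as.matrix(frame))), con, size = 4,
             endian = "little")
  }
  invisible(path)
}

#' Collate OC-300 run folders into a time-ordered sample manifest
#'
#' The automated sampler drops each acquisition into a folder named with a
#' time signature (`YYYY-MM-DD_HH-MM-SS`), and file names inside repeat
#' between folders. Collation builds the unique sample id
#' `<foldername>_<filename>` (e.g. `2021-06-03_11-01-38_A04.fcs`), parses the
#' folder timestamp, and returns records sorted by timestamp then file name.
#' Folders whose name does not parse as a timestamp are skipped with a
#' warning; other layouts are rejected, not guessed.
#'
#' @param root Directory containing run folders.
#' @param dilution_factor Stain dilution applied before acquisition
#'   (default 2: the 1:1 mix of seawater with SYBR Green working solution).
#' @param analyzed_volume Volume of diluted sample analyzed per run, uL
#'   (default 66: 1 min at 66 uL/min fast speed).
#' @return A tibble with columns `sample_id`, `timestamp`, `tube_id`
#'   (parsed from file names of the form `tube<k>.fcs`, otherwise `NA`),
#'   `station_label`, `analyzed_volume`, `dilution_factor`, `source_path`.
#' @export
collate_runs <- function(root, dilution_factor = 2, analyzed_volume = 66) {
  if (!dir.exists(root)) abort(sprintf("Directory not found: %s", root))
  folders <- list.dirs(root, recursive = FALSE, full.names = TRUE)
  ts <- as.POSIXct(basename(folders), format = "%Y-%m-%d_%H-%M-%S", tz = "UTC")
  bad <- is.na(ts) |
    !grepl("^\\d{4}-\\d{2}-\\d{2}_\\d{2}-\\d{2}-\\d{2}$", basename(folders))
  if (any(bad)) {
    warn(sprintf(
      "Skipping %d folder(s) without a YYYY-MM-DD_HH-MM-SS time signature: %s",
      sum(bad), paste(basename(folders)[bad], collapse = ", ")
    ))
  }
  folders <- folders[!bad]
  ts <- ts[!bad]

  records <- purrr::map2_dfr(folders, ts, function(f, t) {
    files <- sort(list.files(f, pattern = "\\.fcs$", ignore.case = TRUE))
    if (!length(files)) return(tibble::tibble())
    tube <- suppressWarnings(as.integer(sub("^tube(\\d+)\\.fcs$", "\\1",
                                            files, ignore.case = TRUE)))
    tibble::tibble(
      sample_id = paste(basename(f), files, sep = "_"),
      timestamp = t,
      tube_id = tube,
      station_label = NA_character_,
      analyzed_volume = analyzed_volume,
      dilution_factor = dilution_factor,
      source_path = file.path(f, files)
    )
  })
  if (!nrow(records)) {
    return(tibble::tibble(
      sample_id = character(), timestamp = as.POSIXct(character(), tz = "UTC"),
      tube_id = integer(), station_label = character(),
      analyzed_volume = numeric(), dilution_factor = numeric(),
      source_path = character()
    ))
  }
  dplyr::arrange(records, .data$timestamp, .data$sample_id)
}

#' Write a collation manifest CSV
#'
#' @param records Output of [collate_runs()].
#' @param path CSV destination.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(records, path) {
  out <- dplyr::mutate(
    dplyr::select(records, "sample_id", "timestamp", "tube_id", "source_path"),
    timestamp = format(.data$timestamp, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  )
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
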