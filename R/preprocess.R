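#' Acquisition threshold on green fluorescence
#'
#' Emulates the instrument trigger: only events at or above the FL1
#' threshold are retained (the boundary is inclusive, as for a hardware
#' trigger). The Accuri template value is 800; synthetic campaigns use
#' [synthetic_fl1_threshold()].
#'
#' @param frame A [cyto_frame].
#' @param threshold FL1 intensity cutoff.
#' @param channel FL1 channel name (default `FL1-H`).
#' @return The filtered [cyto_frame], original event order preserved.
#' @export
apply_threshold <- function(frame, threshold = 800, channel = "FL1-H") {
  require_channels(frame, channel)
  with_events(frame[frame[[channel]] >= threshold, , drop = FALSE], frame)
}

#' Inverse-hyperbolic-sine transform
#'
#' Replaces every intensity x by `asinh(x / cofactor)`, the standard
#' variance-stabilizing transform for cytometry: near-linear below the
#' cofactor, logarithmic above it, defined at zero, strictly monotone.
#'
#' @param frame A [cyto_frame].
#' @param cofactor Positive cofactor (default 1, plain asinh).
#' @param channels Channels to transform (default: all).
#' @return Transformed [cyto_frame], same shape.
#' @export
transform_asinh <- function(frame, cofactor = 1, channels = NULL) {
  stopifnot(cofactor > 0)
  channels <- channels %||% names(frame)
  require_channels(frame, channels)
  out <- tibble::as_tibble(frame)
  out[channels] <- lapply(out[channels], function(x) asinh(x / cofactor))
  with_events(out, frame)
}

#' Polygon gate
#'
#' Defines a simple (non-self-intersecting) polygon in a two-channel plane.
#' Events strictly inside or on the boundary are retained. `transformed`
#' records whether the vertices are expressed in transformed units, so a
#' gate cannot silently be applied on the wrong scale.
#'
#' @param channel_x,channel_y Channel names of the gating plane.
#' @param vertices Numeric matrix or data frame of >= 3 (x, y) vertices.
#' @param name Gate label.
#' @param transformed Are vertex coordinates in transformed units?
#' @return An object of class `gate_spec`.
#' @export
gate_spec <- function(channel_x, channel_y, vertices, name = "gate",
                      transformed = TRUE) {
  v <- as.matrix(vertices)
  if (nrow(v) < 3 || ncol(v) != 2) abort("A gate needs >= 3 (x, y) vertices.")
  if (!all(is.finite(v))) abort("Gate vertices must be finite.")
  if (polygon_self_intersects(v)) {
    abort("Gate polygon must be simple (non-self-intersecting).")
  }
  structure(list(channel_x = channel_x, channel_y = channel_y,
                 vertices = unname(v), name = name, transformed = transformed),
            class = "gate_spec")
}

# segment-intersection scan over non-adjacent edges
polygon_self_intersects <- function(v) {
  n <- nrow(v)
  edges <- cbind(v, v[c(2:n, 1), ])
  cross2 <- function(ox, oy, ax, ay, bx, by) {
    (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
  }
  for (i in seq_len(n - 2)) {
    js <- (i + 2):n
    js <- js[!(i == 1 & js == n)]
    for (j in js) {
      p <- edges[i, ]; q <- edges[j, ]
      d1 <- cross2(p[1], p[2], p[3], p[4], q[1], q[2])
      d2 <- cross2(p[1], p[2], p[3], p[4], q[3], q[4])
      d3 <- cross2(q[1], q[2], q[3], q[4], p[1], p[2])
      d4 <- cross2(q[1], q[2], q[3], q[4], p[3], p[4])
      if (((d1 > 0) != (d2 > 0)) && ((d3 > 0) != (d4 > 0))) return(TRUE)
    }
  }
  FALSE
}

#' Apply a polygon gate to a cytogram
#'
#' Even-odd (ray casting) point-in-polygon test; events on an edge or vertex
#' count as inside.
#'
#' @param frame A [cyto_frame].
#' @param gate A [gate_spec()].
#' @return The gated [cyto_frame].
#' @export
apply_gate <- function(frame, gate) {
  require_channels(frame, c(gate$channel_x, gate$channel_y))
  keep <- points_in_polygon(frame[[gate$channel_x]], frame[[gate$channel_y]],
                            gate$vertices)
  with_events(frame[keep, , drop = FALSE], frame)
}

points_in_polygon <- function(px, py, v) {
  n <- nrow(v)
  inside <- rep(FALSE, length(px))
  on_edge <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- v[i, 1]; yi <- v[i, 2]; xj <- v[j, 1]; yj <- v[j, 2]
    # boundary: point collinear with and within the edge's bounding box
    cr <- (xj - xi) * (py - yi) - (yj - yi) * (px - xi)
    on_edge <- on_edge | (abs(cr) < 1e-12 &
      px >= pmin(xi, xj) - 1e-12 & px <= pmax(xi, xj) + 1e-12 &
      py >= pmin(yi, yj) - 1e-12 & py <= pmax(yi, yj) + 1e-12)
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside | on_edge
}

#' Serialize gates as JSON
#'
#' @param gates A `gate_spec` or list of them.
#' @param path JSON file.
#' @return `read_gates()` returns a list of `gate_spec`.
#' @export
write_gates <- function(gates, path) {
  if (inherits(gates, "gate_spec")) gates <- list(gates)
  payload <- purrr::map(gates, function(g) {
    list(name = g$name, channel_x = g$channel_x, channel_y = g$channel_y,
         transformed = g$transformed,
         vertices = apply(g$vertices, 1, as.numeric, simplify = FALSE))
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_gates
#' @export
read_gates <- function(path) {
  payload <- jsonlite::read_json(path)
  purrr::map(payload, function(g) {
    gate_spec(g$channel_x, g$channel_y,
              do.call(rbind, purrr::map(g$vertices, unlist)),
              name = g$name, transformed = isTRUE(g$transformed))
  })
}

#' Normalize a sample set to the maximum green fluorescence
#'
#' Divides the fingerprint channels of every cytogram by the global maximum
#' transformed FL1 across the whole set, so that the brightest FL1 event in
#' the set maps to exactly 1 and fingerprints are comparable between
#' samples. Per-sample normalization (each cytogram by its own maximum) is
#' available but breaks cross-sample comparability.
#'
#' @param frames List of transformed [cyto_frame]s.
#' @param channels Channels to rescale; default: all channels of the first
#'   frame (the FL1-derived scale applied to every fingerprint channel).
#' @param fl1_channel Channel supplying the maximum (default `FL1-H`).
#' @param per_sample If `TRUE`, normalize each frame by its own FL1 maximum.
#' @return List with `frames` (rescaled) and `scale` (the divisor; a vector
#'   when `per_sample`).
#' @export
normalize_to_max <- function(frames, channels = NULL, fl1_channel = "FL1-H",
                             per_sample = FALSE) {
  if (!length(frames)) abort("Cannot normalize an empty sample set.")
  purrr::walk(frames, require_channels, fl1_channel)
  channels <- channels %||% names(frames[[1]])
  maxima <- vapply(frames, function(f) {
    if (nrow(f)) max(f[[fl1_channel]]) else -Inf
  }, numeric(1))
  if (per_sample) {
    frames <- purrr::map2(frames, maxima, function(f, m) {
      rescale_channels(f, channels, m)
    })
    return(list(frames = frames, scale = maxima))
  }
  scale <- max(maxima)
  if (!is.finite(scale) || scale <= 0) {
    abort("Global FL1 maximum is not positive; cannot normalize.")
  }
  list(frames = purrr::map(frames, rescale_channels, channels, scale),
       scale = scale)
}

rescale_channels <- function(frame, channels, divisor) {
  out <- tibble::as_tibble(frame)
  out[channels] <- lapply(out[channels], function(x) x / divisor)
  with_events(out, frame)
}

#' Subsample events without replacement
#'
#' Uniform, seeded, without replacement — the standard evening-out step
#' before diversity comparison (each cytogram cut to the minimum event count
#' of the set, e.g. 10,303 in the cruise this pipeline models).
#'
#' @param frame A [cyto_frame].
#' @param n Events to keep (`n <= n_events(frame)`).
#' @param seed Optional integer seed.
#' @return A [cyto_frame] of exactly `n` events.
#' @export
subsample_events <- function(frame, n, seed = NULL) {
  if (n > nrow(frame)) {
    abort(sprintf(
      "Cannot subsample %d events from %s with only %d.",
      n, attr(frame, "source_path") %||% "frame", nrow(frame)),
      class = "cytocruise_size_error")
  }
  if (!is.null(seed)) set.seed(seed)
  idx <- sort(sample.int(nrow(frame), n))
  with_events(frame[idx, , drop = FALSE], frame)
}

#' Minimum event count across a sample set
#'
#' @param frames List of [cyto_frame]s.
#' @return Integer minimum of `n_events` over the set.
#' @export
min_cell_count <- function(frames) {
  if (!length(frames)) abort("Empty sample set.")
  min(vapply(frames, nrow, integer(1)))
}
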