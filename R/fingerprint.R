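#' Binned cytometric fingerprint
#'
#' Divides one or more two-channel planes of a processed cytogram
#' (transformed, normalized to [0, 1], usually subsampled) into a
#' `grid_size` x `grid_size` grid and counts events per bin. The per-bin
#' relative densities are the "phenotypes" on which Hill diversity and
#' beta diversity are computed. An event at (u, v) falls in bin
#' `(floor(u*G), floor(v*G))`, clamped to the last bin at the upper edge, so
#' every event is counted exactly once.
#'
#' Raw bin counts are used (no kernel smoothing); an optional Gaussian
#' pre-smoothing (`smooth_sd` in bins, default off) is available for
#' sensitivity analysis.
#'
#' @param frame A [cyto_frame] with values in [0, 1] on the fingerprint
#'   channels.
#' @param pairs List of channel pairs, each `c(x, y)`; default the
#'   green-vs-red stain/autofluorescence plane `FL1-H` x `FL3-H`.
#' @param grid_size Bins per axis (default 128).
#' @param sample_id Optional label carried on the fingerprint.
#' @param smooth_sd Gaussian smoothing sd in bins (0 = off).
#' @param clamp Accept values slightly above 1 (up to 10%) by counting them
#'   in the top bin. The global normalization anchors the scale on FL1, so
#'   extreme red-fluorescence tails can exceed 1 by a little; truly
#'   unnormalized data still errors.
#' @return A `cyto_fingerprint`: list of count matrices (one per pair) plus
#'   `grid_size`, `n_events`, `sample_id`.
#' @export
bin_events <- function(frame, pairs = list(c("FL1-H", "FL3-H")),
                       grid_size = 128, sample_id = NULL, smooth_sd = 0,
                       clamp = FALSE) {
  if (!is.list(pairs)) pairs <- list(pairs)
  if (nrow(frame) < 1) abort("Cannot fingerprint an empty cytogram.")
  tol <- if (clamp) 0.1 else 1e-9
  counts <- purrr::map(pairs, function(pair) {
    require_channels(frame, pair)
    u <- frame[[pair[1]]]; v <- frame[[pair[2]]]
    if (any(u < -1e-9 | u > 1 + tol | v < -1e-9 | v > 1 + tol)) {
      abort(sprintf(
        "Channel values outside [0, 1] on %s x %s: normalize before binning.",
        pair[1], pair[2]), class = "cytocruise_normalization_error")
    }
    G <- grid_size
    ix <- pmin(pmax(floor(pmin(pmax(u, 0), 1) * G), 0), G - 1)
    iy <- pmin(pmax(floor(pmin(pmax(v, 0), 1) * G), 0), G - 1)
    m <- matrix(tabulate(ix * G + iy + 1, nbins = G * G), nrow = G)
    if (smooth_sd > 0) m <- smooth_gaussian(m, smooth_sd)
    m
  })
  names(counts) <- vapply(pairs, paste, character(1), collapse = "x")
  structure(
    list(counts = counts, pairs = pairs, grid_size = grid_size,
         n_events = nrow(frame), sample_id = sample_id),
    class = "cyto_fingerprint"
  )
}

# separable truncated-Gaussian convolution with replicated edges,
# renormalized so the total event mass is preserved exactly
smooth_gaussian <- function(m, sd) {
  r <- max(1L, ceiling(3 * sd))
  k <- stats::dnorm(-r:r, sd = sd)
  k <- k / sum(k)
  pad_conv <- function(mat) {
    n <- nrow(mat)
    idx <- pmin(pmax(outer(seq_len(n), -r:r, `+`), 1), n)
    out <- matrix(0, n, ncol(mat))
    for (j in seq_along(k)) out <- out + k[j] * mat[idx[, j], , drop = FALSE]
    out
  }
  out <- t(pad_conv(t(pad_conv(m))))
  out * sum(m) / sum(out)
}

#' @export
print.cyto_fingerprint <- function(x, ...) {
  cat(sprintf(
    "<cyto_fingerprint> %s: %d pair(s), %d x %d bins, %d events\n",
    x$sample_id %||% "(unnamed)", length(x$pairs), x$grid_size, x$grid_size,
    x$n_events
  ))
  invisible(x)
}

#' Relative bin densities of a fingerprint
#'
#' Concatenates all channel pairs and renormalizes to a probability vector.
#'
#' @param fp A `cyto_fingerprint`.
#' @return Numeric vector of length `pairs * grid_size^2` summing to 1.
#' @export
fingerprint_density <- function(fp) {
  v <- unlist(purrr::map(fp$counts, as.vector), use.names = FALSE)
  v / sum(v)
}

#' Hill-number phenotypic diversity
#'
#' The Hill number of order q is the effective number of equally abundant
#' phenotypes (bins): `D_q = (sum p_i^q)^(1/(1-q))`, with the limits
#' `D_0` = number of occupied bins, `D_1 = exp(-sum p_i log p_i)` (the
#' exponential of Shannon entropy, natural log) and `D_2 = 1 / sum p_i^2`
#' (inverse Simpson). Empty bins are excluded from the sums; for multi-pair
#' fingerprints the concatenated renormalized density vector is used.
#'
#' @param fp A `cyto_fingerprint` (or a bare non-negative density vector).
#' @param q Diversity order(s), >= 0; the reported index of the underlying
#'   study is `q = 2`.
#' @return Tibble with columns `sample_id`, `q`, `D`.
#' @examples
#' hill_diversity(c(0.75, 0.25), q = 2)  # D_2 = 1.6
#' @export
hill_diversity <- function(fp, q = c(0, 1, 2)) {
  p <- if (inherits(fp, "cyto_fingerprint")) fingerprint_density(fp) else {
    if (any(fp < 0)) abort("Densities must be >= 0.")
    fp / sum(fp)
  }
  p <- p[p > 0]
  D <- vapply(q, function(qi) {
    if (qi < 0) abort("Diversity order q must be >= 0.")
    if (abs(qi - 1) < 1e-12) {
      exp(-sum(p * log(p)))
    } else {
      sum(p^qi)^(1 / (1 - qi))
    }
  }, numeric(1))
  tibble::tibble(
    sample_id = (if (inherits(fp, "cyto_fingerprint")) fp$sample_id else NULL)
      %||% NA_character_,
    q = q, D = D
  )
}

#' Beta diversity between two fingerprints
#'
#' Bray-Curtis dissimilarity `1 - sum min(p_a, p_b)` on the normalized
#' concatenated densities: 0 for identical fingerprints, 1 for disjoint
#' supports, symmetric.
#'
#' @param fp_a,fp_b `cyto_fingerprint`s over the same pairs and grid.
#' @param metric Only `"bray"` currently.
#' @return Dissimilarity in [0, 1].
#' @export
beta_diversity <- function(fp_a, fp_b, metric = "bray") {
  metric <- match.arg(metric, "bray")
  if (fp_a$grid_size != fp_b$grid_size ||
      !identical(fp_a$pairs, fp_b$pairs)) {
    abort("Fingerprints must share channel pairs and grid size.")
  }
  pa <- fingerprint_density(fp_a)
  pb <- fingerprint_density(fp_b)
  1 - sum(pmin(pa, pb))
}

#' Store fingerprints as sparse triplets
#'
#' CSV columns `sample_id, pair, ix, iy, count` (1-based bin indices, only
#' occupied bins), invertible by [read_fingerprints()].
#'
#' @param fps List of `cyto_fingerprint`s.
#' @param path CSV file.
#' @return `path` invisibly; `read_fingerprints()` returns the list.
#' @export
write_fingerprints <- function(fps, path) {
  rows <- purrr::map_dfr(fps, function(fp) {
    purrr::imap_dfr(fp$counts, function(m, pair) {
      idx <- which(m > 0, arr.ind = TRUE)
      tibble::tibble(
        sample_id = fp$sample_id %||% NA_character_, pair = pair,
        ix = idx[, 1], iy = idx[, 2], count = m[idx],
        grid_size = fp$grid_size, n_events = fp$n_events
      )
    })
  })
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_fingerprints
#' @export
read_fingerprints <- function(path) {
  rows <- tibble::as_tibble(utils::read.csv(path, check.names = FALSE))
  purrr::map(split(rows, rows$sample_id), function(s) {
    G <- s$grid_size[1]
    counts <- purrr::map(split(s, s$pair), function(pp) {
      m <- matrix(0, G, G)
      m[cbind(pp$ix, pp$iy)] <- pp$count
      m
    })
    pairs <- purrr::map(names(counts), ~ strsplit(.x, "x", fixed = TRUE)[[1]])
    structure(
      list(counts = counts, pairs = pairs, grid_size = G,
           n_events = s$n_events[1], sample_id = s$sample_id[1]),
      class = "cyto_fingerprint"
    )
  })
}
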