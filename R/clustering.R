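#' Train a self-organizing map on pooled cytometry events
#'
#' Batch Kohonen SOM: code vectors start on the plane spanned by the first
#' two principal components of the data, and each epoch reassigns every
#' event to its nearest code vector (Euclidean) and replaces each code by
#' the Gaussian-neighborhood-weighted mean of the assigned events, with the
#' neighborhood radius shrinking linearly from `max(grid)/2` to
#' `radius_final`. The batch rule with a deterministic initialization makes
#' training reproducible without any random number stream.
#'
#' The default 10 x 10 grid yields the 100 clusters used for marine
#' prokaryote cytograms, trained on the transformed fluorescence and scatter
#' channels.
#'
#' @param frame A [cyto_frame] of pooled, transformed events
#'   (`n_events >= prod(grid)`).
#' @param channels Training channels (default FL1, FL3 and both scatters).
#' @param grid Integer `c(rows, cols)`.
#' @param epochs Batch epochs (default 10).
#' @param radius_final Final neighborhood radius in grid units; small values
#'   end training with near-k-means updates.
#' @param finetune Winner-take-all refinement iterations after the
#'   neighborhood epochs; units left without events are relocated to the
#'   worst-quantized event, so capacity is fully used (0 disables).
#' @param seed Kept for interface symmetry; training is deterministic.
#' @return A `som_model`: code vectors, grid, channels, schedules, and the
#'   initial/final quantization errors.
#' @export
train_som <- function(frame, channels = c("FL1-H", "FL3-H", "FSC-H", "SSC-H"),
                      grid = c(10, 10), epochs = 10, radius_final = 0.3,
                      finetune = 10, seed = 1L) {
  require_channels(frame, channels)
  K <- prod(grid)
  X <- as.matrix(frame[, channels, drop = FALSE])
  if (nrow(X) < K) {
    abort(sprintf("Need >= %d events to train a %dx%d SOM (have %d).",
                  K, grid[1], grid[2], nrow(X)),
          class = "cytocruise_size_error")
  }
  if (ncol(X) < 2) abort("Need >= 2 channels to train a SOM.")

  # PCA-spanned linear initialization
  ctr <- colMeans(X)
  Xc <- sweep(X, 2, ctr)
  sv <- svd(Xc, nu = 0, nv = 2)
  sdev <- sv$d / sqrt(max(1, nrow(X) - 1))
  gpos <- as.matrix(expand.grid(row = seq_len(grid[1]), col = seq_len(grid[2])))
  u <- if (grid[1] > 1) (gpos[, 1] - mean(gpos[, 1])) /
    (grid[1] / 2) else rep(0, K)
  w <- if (grid[2] > 1) (gpos[, 2] - mean(gpos[, 2])) /
    (grid[2] / 2) else rep(0, K)
  dir1 <- sv$v[, 1] * max(sdev[1], 1e-12)
  dir2 <- if (ncol(sv$v) >= 2) sv$v[, 2] * max(sdev[2], 1e-12) else 0 * dir1
  codes <- matrix(ctr, K, ncol(X), byrow = TRUE) +
    2 * (outer(u, dir1) + outer(w, dir2))
  colnames(codes) <- channels

  grid_d2 <- as.matrix(dist(gpos))^2
  sigmas <- seq(max(grid) / 2, radius_final, length.out = epochs)

  qe <- function(cl) {
    sqrt(mean(rowSums((X - codes[cl, , drop = FALSE])^2)))
  }
  nearest <- function() {
    d2 <- outer(rowSums(X^2), rep(1, K)) - 2 * X %*% t(codes) +
      outer(rep(1, nrow(X)), rowSums(codes^2))
    max.col(-d2, ties.method = "first")
  }

  cl <- nearest()
  qe_initial <- qe(cl)
  for (e in seq_len(epochs)) {
    if (e > 1) cl <- nearest()
    H <- exp(-grid_d2 / (2 * sigmas[e]^2))
    n_k <- tabulate(cl, nbins = K)
    S <- matrix(0, K, ncol(X))
    present <- rowsum(X, cl)
    S[as.integer(rownames(present)), ] <- present
    num <- H %*% S
    den <- as.vector(H %*% n_k)
    upd <- den > 0  # units with no mass in reach keep their code vector
    codes[upd, ] <- num[upd, , drop = FALSE] / den[upd]
  }
  for (i in seq_len(finetune)) {
    cl <- nearest()
    n_k <- tabulate(cl, nbins = K)
    if (any(n_k == 0)) {
      # give idle units the currently worst-quantized events
      resid <- rowSums((X - codes[cl, , drop = FALSE])^2)
      for (k in which(n_k == 0)) {
        j <- which.max(resid)
        codes[k, ] <- X[j, ]
        resid[j] <- -Inf
      }
      cl <- nearest()
      n_k <- tabulate(cl, nbins = K)
    }
    S <- matrix(0, K, ncol(X))
    present <- rowsum(X, cl)
    S[as.integer(rownames(present)), ] <- present
    occ <- n_k > 0
    codes[occ, ] <- S[occ, , drop = FALSE] / n_k[occ]
  }
  cl <- nearest()
  structure(
    list(codes = codes, grid = as.integer(grid), channels = channels,
         epochs = epochs, sigmas = sigmas, radius_final = radius_final,
         seed = seed, qe_initial = qe_initial, qe_final = qe(cl)),
    class = "som_model"
  )
}

#' @export
print.som_model <- function(x, ...) {
  cat(sprintf(
    "<som_model> %dx%d grid (%d clusters) on %s | QE %.4f -> %.4f\n",
    x$grid[1], x$grid[2], prod(x$grid), paste(x$channels, collapse = ", "),
    x$qe_initial, x$qe_final
  ))
  invisible(x)
}

#' Assign events to SOM clusters
#'
#' Nearest code vector by Euclidean distance on the training channels; ties
#' break to the lowest cluster index.
#'
#' @param model A `som_model`.
#' @param frame A [cyto_frame] containing the training channels.
#' @return Integer cluster index per event (empty for an empty frame).
#' @export
assign_events <- function(model, frame) {
  require_channels(frame, model$channels)
  X <- as.matrix(frame[, model$channels, drop = FALSE])
  if (nrow(X) == 0) return(integer(0))
  K <- nrow(model$codes)
  d2 <- outer(rowSums(X^2), rep(1, K)) - 2 * X %*% t(model$codes) +
    outer(rep(1, nrow(X)), rowSums(model$codes^2))
  max.col(-d2, ties.method = "first")
}

#' Merge SOM clusters into metaclusters
#'
#' Ward-linkage agglomerative clustering (Euclidean) of the code vectors,
#' cut at `k` groups — deterministic, unlike consensus approaches.
#'
#' @param model A `som_model`.
#' @param k Number of metaclusters (1..number of clusters; default 10).
#' @return A `metacluster_map`: integer metacluster per cluster.
#' @export
metacluster <- function(model, k = 10) {
  K <- nrow(model$codes)
  if (k < 1) abort("k must be >= 1.")
  if (k > K) abort(sprintf("k (%d) exceeds the cluster count (%d).", k, K))
  assignment <- if (k == K) {
    seq_len(K)
  } else {
    hc <- hclust(dist(model$codes), method = "ward.D2")
    unname(cutree(hc, k = k))
  }
  structure(list(assignment = assignment, k = k, labels = NULL),
            class = "metacluster_map")
}

#' Label metaclusters as PHOTO / HNA / LNA populations
#'
#' Photosynthetic prokaryotes are recognized by red autofluorescence: any
#' metacluster whose event-weighted median FL3 exceeds the red threshold is
#' labelled `PHOTO`. By default the threshold is the midpoint between the
#' FL3 medians of the two most FL3-separated metaclusters, and is only
#' armed when that separation exceeds `min_fl3_gap` (so a community without
#' high-FL3 cells yields zero PHOTO metaclusters). The remaining
#' metaclusters are split into `HNA` (high nucleic acid) and `LNA` by their
#' event-weighted median FL1 relative to a split point on the pooled
#' non-PHOTO FL1 values: by default Otsu's minimum-within-class-variance
#' threshold, which lands in the valley between the two fluorescence modes
#' and keeps the recovered HNA/LNA ratio unbiased when the groups are
#' unbalanced (the plain pooled median, available via
#' `split_method = "median"`, pulls borderline metaclusters toward a 1:1
#' split). Metaclusters that received no events are `OTHER`.
#'
#' @param map A `metacluster_map`.
#' @param model The `som_model` the map was cut from.
#' @param frame Events to label (transformed, same channels as training).
#' @param fl1_channel,fl3_channel Green / red fluorescence channel names.
#' @param red_threshold Fixed FL3 threshold overriding the midpoint rule.
#' @param min_fl3_gap Minimum FL3-median separation (transformed units)
#'   required to declare any PHOTO metacluster.
#' @param split_method `"otsu"` (default) or `"median"`: how the HNA/LNA
#'   split point on pooled non-PHOTO FL1 is chosen.
#' @return The map with a `labels` tibble (`metacluster`, `n_events`,
#'   `median_fl1`, `median_fl3`, `label`) and the per-event
#'   `cluster`/`metacluster`/`label` assignment as attribute `events`.
#' @export
label_populations <- function(map, model, frame,
                              fl1_channel = "FL1-H", fl3_channel = "FL3-H",
                              red_threshold = NULL, min_fl3_gap = 1.0,
                              split_method = c("otsu", "median")) {
  split_method <- match.arg(split_method)
  require_channels(frame, c(fl1_channel, fl3_channel))
  if (!all(c(fl1_channel, fl3_channel) %in% model$channels)) {
    abort("FL1 and FL3 must be among the SOM training channels.",
          class = "cytocruise_channel_error")
  }
  cl <- assign_events(model, frame)
  meta <- map$assignment[cl]
  stats_tbl <- tibble::tibble(
    metacluster = seq_len(map$k),
    n_events = tabulate(meta, nbins = map$k)
  )
  med_by <- function(ch) {
    vapply(seq_len(map$k), function(m) {
      v <- frame[[ch]][meta == m]
      if (length(v)) median(v) else NA_real_
    }, numeric(1))
  }
  stats_tbl$median_fl1 <- med_by(fl1_channel)
  stats_tbl$median_fl3 <- med_by(fl3_channel)

  occupied <- stats_tbl$n_events > 0
  label <- rep("OTHER", map$k)
  if (any(occupied)) {
    fl3m <- stats_tbl$median_fl3[occupied]
    thr <- red_threshold
    if (is.null(thr)) {
      # largest jump in the sorted FL3 medians: a red (photosynthetic)
      # population sits far above everything else, while metaclusters of a
      # red-free community form a near-continuum of small jumps
      srt <- sort(fl3m)
      jumps <- diff(srt)
      thr <- if (length(jumps) && max(jumps) >= min_fl3_gap) {
        i <- which.max(jumps)
        (srt[i] + srt[i + 1]) / 2
      } else {
        Inf
      }
    }
    is_photo <- occupied & !is.na(stats_tbl$median_fl3) &
      stats_tbl$median_fl3 > thr
    label[is_photo] <- "PHOTO"
    nonphoto_events <- !(map$assignment[cl] %in% which(is_photo))
    fl1_all <- frame[[fl1_channel]][nonphoto_events]
    if (length(fl1_all)) {
      split_at <- if (split_method == "otsu" && length(fl1_all) > 1) {
        otsu_threshold(fl1_all)
      } else {
        median(fl1_all)
      }
      hi <- occupied & !is_photo & stats_tbl$median_fl1 > split_at
      lo <- occupied & !is_photo & stats_tbl$median_fl1 <= split_at
      label[hi] <- "HNA"
      label[lo] <- "LNA"
    }
  }
  stats_tbl$label <- label
  map$labels <- stats_tbl
  attr(map, "events") <- tibble::tibble(cluster = cl, metacluster = meta,
                                        label = label[meta])
  map
}

# Otsu's threshold: exhaustive split minimizing total within-class variance
otsu_threshold <- function(x) {
  xs <- sort(x)
  n <- length(xs)
  cs <- cumsum(xs)
  css <- cumsum(xs^2)
  k <- seq_len(n - 1)
  wss <- (css[k] - cs[k]^2 / k) +
    ((css[n] - css[k]) - (cs[n] - cs[k])^2 / (n - k))
  i <- which.min(wss)
  (xs[i] + xs[i + 1]) / 2
}

#' Population counts and HNA/LNA ratio for one sample
#'
#' @param map A labelled `metacluster_map` (see [label_populations()]).
#' @param model The `som_model`.
#' @param frame Events of one sample.
#' @return One-row tibble: `PHOTO`, `HNA`, `LNA`, `OTHER`, `hna_lna_ratio`
#'   (NA when LNA = 0).
#' @export
population_counts <- function(map, model, frame) {
  if (is.null(map$labels)) abort("Metacluster map is not labelled yet.")
  cl <- assign_events(model, frame)
  lab <- map$labels$label[map$assignment[cl]]
  n <- function(x) sum(lab == x)
  counts <- tibble::tibble(
    PHOTO = n("PHOTO"), HNA = n("HNA"), LNA = n("LNA"), OTHER = n("OTHER")
  )
  counts$hna_lna_ratio <- if (counts$LNA > 0) counts$HNA / counts$LNA else
    NA_real_
  counts
}

#' HNA/LNA community-activity ratio
#'
#' The ratio of high- to low-nucleic-acid-content prokaryotes, a common
#' proxy for the activity level of the community.
#'
#' @param hna,lna Event counts (lna > 0).
#' @return `hna / lna`.
#' @export
hna_lna_ratio <- function(hna, lna) {
  if (any(lna <= 0)) {
    abort("HNA/LNA ratio undefined: LNA count must be > 0.",
          class = "cytocruise_ratio_error")
  }
  hna / lna
}

#' Serialize / restore a SOM model as JSON
#'
#' @param model A `som_model`.
#' @param path JSON file.
#' @return `read_som()` returns the `som_model`.
#' @export
write_som <- function(model, path) {
  payload <- list(
    grid = model$grid, channels = model$channels, epochs = model$epochs,
    sigmas = model$sigmas, radius_final = model$radius_final,
    seed = model$seed, qe_initial = model$qe_initial,
    qe_final = model$qe_final,
    codes = apply(model$codes, 1, as.numeric, simplify = FALSE)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_som
#' @export
read_som <- function(path) {
  p <- jsonlite::read_json(path)
  codes <- do.call(rbind, purrr::map(p$codes, unlist))
  colnames(codes) <- unlist(p$channels)
  structure(
    list(codes = codes, grid = as.integer(unlist(p$grid)),
         channels = unlist(p$channels), epochs = p$epochs,
         sigmas = unlist(p$sigmas), radius_final = p$radius_final,
         seed = p$seed, qe_initial = p$qe_initial, qe_final = p$qe_final),
    class = "som_model"
  )
}
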