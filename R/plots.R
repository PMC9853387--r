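#' Plot a cytogram
#'
#' Two-channel scatter of a [cyto_frame], the standard diagnostic view
#' (e.g. green vs red fluorescence after the asinh transform).
#'
#' @param frame A [cyto_frame].
#' @param x,y Channel names.
#' @param alpha Point transparency.
#' @return A ggplot object.
#' @export
plot_cytogram <- function(frame, x = "FL1-H", y = "FL3-H", alpha = 0.2) {
  require_channels(frame, c(x, y))
  df <- tibble::as_tibble(frame)
  ggplot2::ggplot(df, ggplot2::aes(.data[[x]], .data[[y]])) +
    ggplot2::geom_point(alpha = alpha, size = 0.3) +
    ggplot2::labs(x = x, y = y) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Fingerprint heat map
#'
#' @param object A `cyto_fingerprint`.
#' @param pair Which channel pair to draw (index or name).
#' @param ... Unused.
#' @return A ggplot object (log1p-scaled bin counts).
#' @export
autoplot.cyto_fingerprint <- function(object, pair = 1, ...) {
  m <- object$counts[[pair]]
  pr <- object$pairs[[if (is.numeric(pair)) pair else
    match(pair, names(object$counts))]]
  df <- tidyr::expand_grid(ix = seq_len(nrow(m)), iy = seq_len(ncol(m)))
  df$count <- m[cbind(df$ix, df$iy)]
  ggplot2::ggplot(dplyr::filter(df, .data$count > 0),
                  ggplot2::aes(.data$ix, .data$iy, fill = log1p(.data$count))) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "log1p(count)") +
    ggplot2::labs(x = pr[1], y = pr[2], title = object$sample_id) +
    ggplot2::theme_minimal()
}

#' Campaign time-series plot
#'
#' Abundance (and, when present, the HNA/LNA ratio and Hill D2) over the
#' cruise timeline, faceted by variable.
#'
#' @param object A `cruise_analysis`.
#' @param variables Series columns to draw.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cruise_analysis <- function(object,
                                     variables = c("concentration", "D2",
                                                   "hna_lna_ratio"), ...) {
  df <- tidyr::pivot_longer(
    dplyr::select(object$series, "timestamp",
                  dplyr::any_of(variables)),
    -"timestamp", names_to = "variable", values_to = "value"
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$timestamp, .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::facet_wrap(~variable, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' SOM code-vector map
#'
#' Code vectors in the green-red fluorescence plane, colored by metacluster
#' label when a labelled map is supplied.
#'
#' @param object A `som_model`.
#' @param map Optional labelled `metacluster_map`.
#' @param x,y Channels to draw.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.som_model <- function(object, map = NULL, x = "FL1-H", y = "FL3-H",
                               ...) {
  df <- tibble::as_tibble(object$codes)
  if (!is.null(map)) {
    df$label <- if (!is.null(map$labels)) {
      map$labels$label[map$assignment]
    } else {
      factor(map$assignment)
    }
  }
  p <- ggplot2::ggplot(df, ggplot2::aes(.data[[x]], .data[[y]]))
  p <- if (!is.null(map)) {
    p + ggplot2::geom_point(ggplot2::aes(color = .data$label), size = 2)
  } else {
    p + ggplot2::geom_point(size = 2)
  }
  p + ggplot2::labs(x = x, y = y) + ggplot2::theme_minimal()
}
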