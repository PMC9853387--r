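# shared fixture builders; everything is generated in code at test time

random_frame <- function(n = 100, seed = 1, channels = c("FSC-H", "SSC-H",
                                                         "FL1-H", "FL3-H")) {
  set.seed(seed)
  cols <- lapply(channels, function(ch) 10^runif(n, 1, 4))
  names(cols) <- channels
  cyto_frame(tibble::as_tibble(cols))
}

# n events from k well-separated Gaussian blobs in `d` dimensions
blob_frame <- function(n = 1000, centers, sd = 0.05, seed = 1,
                       channels = NULL) {
  set.seed(seed)
  k <- nrow(centers)
  lab <- sample.int(k, n, replace = TRUE)
  x <- centers[lab, , drop = FALSE] +
    matrix(rnorm(n * ncol(centers), 0, sd), n)
  colnames(x) <- channels %||% paste0("C", seq_len(ncol(centers)))
  list(frame = cyto_frame(tibble::as_tibble(x)), labels = lab)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ground-truth labelled mixture drawn from the generator's populations
labelled_mixture <- function(n = 8000, populations = default_populations(),
                             seed = 1) {
  set.seed(seed)
  cells <- populations[populations$name != "NOISE", ]
  counts <- as.vector(stats::rmultinom(1, n, cells$fraction))
  parts <- lapply(seq_len(nrow(cells)), function(i) {
    tibble::as_tibble(sample_population(cells[i, ], counts[i],
                                        seed = seed * 1000 + i))
  })
  list(
    frame = cyto_frame(dplyr::bind_rows(parts)),
    labels = rep(cells$name, counts),
    counts = stats::setNames(counts, cells$name)
  )
}

# a tiny on-disk campaign reused by pipeline tests
make_campaign <- function(dir, hours = 2, seed = 11, ...) {
  start <- as.POSIXct("2021-06-03 00:00:00", tz = "UTC")
  sc <- cruise_scenario(start, start + hours * 3600, seed = seed, ...)
  simulate_cruise(sc, dir)
}
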