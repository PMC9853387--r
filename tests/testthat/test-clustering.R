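test_that("batch SOM training is deterministic and reduces quantization error", {
  mix <- labelled_mixture(3000, seed = 4)
  f <- transform_asinh(mix$frame)
  m1 <- train_som(f, epochs = 8)
  m2 <- train_som(f, epochs = 8)
  expect_identical(m1$codes, m2$codes)
  expect_lte(m1$qe_final, m1$qe_initial)
  expect_true(all(is.finite(m1$codes)))
  expect_equal(dim(m1$codes), c(100, 4))

  small <- transform_asinh(random_frame(50, seed = 1))
  expect_error(train_som(small), class = "cytocruise_size_error")
})

test_that("a SOM with one unit per point captures the points", {
  set.seed(19)
  pts <- tibble::tibble(A = runif(100, 0, 10), B = runif(100, 0, 10))
  f <- cyto_frame(pts)
  m <- train_som(f, channels = c("A", "B"), grid = c(10, 10), epochs = 40,
                 radius_final = 0.05)
  expect_lt(m$qe_final, 0.05 * m$qe_initial)
})

test_that("event assignment equals the brute-force nearest code vector", {
  mix <- labelled_mixture(2000, seed = 6)
  f <- transform_asinh(mix$frame)
  m <- train_som(f)
  probe <- transform_asinh(random_frame(1000, seed = 8))
  got <- assign_events(m, probe)
  X <- as.matrix(probe[, m$channels])
  oracle <- apply(X, 1, function(x) {
    which.min(colSums((t(m$codes) - x)^2))
  })
  expect_equal(got, unname(oracle))

  # an event equal to a code vector maps to that cluster
  cv <- cyto_frame(tibble::as_tibble(m$codes[37, , drop = FALSE]))
  expect_equal(assign_events(m, cv), 37L)

  expect_equal(assign_events(m, f[0, ]), integer(0))
  expect_error(assign_events(m, cyto_frame(tibble::tibble(A = 1))),
               class = "cytocruise_channel_error")
})

test_that("metaclustering is a Ward cut with the degenerate cases exact", {
  mix <- labelled_mixture(2000, seed = 9)
  m <- train_som(transform_asinh(mix$frame))
  expect_equal(metacluster(m, 100)$assignment, 1:100)
  expect_equal(metacluster(m, 1)$assignment, rep(1L, 100))
  expect_error(metacluster(m, 0), "k must be")
  expect_error(metacluster(m, 101), "exceeds")

  # two well-separated code-vector blobs split cleanly at k = 2
  codes <- rbind(matrix(rnorm(100, 0, 0.05), 50),
                 matrix(rnorm(100, 5, 0.05), 50))
  colnames(codes) <- c("A", "B")
  toy <- structure(list(codes = codes, grid = c(10L, 10L),
                        channels = c("A", "B")), class = "som_model")
  cut2 <- metacluster(toy, 2)$assignment
  expect_equal(length(unique(cut2[1:50])), 1)
  expect_equal(length(unique(cut2[51:100])), 1)
  expect_false(cut2[1] == cut2[51])
})

test_that("three separated blobs are recovered by SOM + metaclustering", {
  skip_if_not_installed("mclust")
  centers <- rbind(c(0, 0), c(1.5, 0), c(0, 1.5))
  aris <- vapply(1:20, function(s) {
    blobs <- blob_frame(1e4, centers, sd = 0.05, seed = s,
                        channels = c("A", "B"))
    m <- train_som(blobs$frame, channels = c("A", "B"))
    mc <- metacluster(m, 3)
    est <- mc$assignment[assign_events(m, blobs$frame)]
    mclust::adjustedRandIndex(est, blobs$labels)
  }, numeric(1))
  expect_true(all(aris >= 0.95))
})

test_that("population labelling recovers PHOTO, HNA and LNA from mixtures", {
  accs <- vapply(1:20, function(s) {
    mix <- labelled_mixture(6000, seed = s)
    f <- transform_asinh(mix$frame)
    m <- train_som(f)
    map <- label_populations(metacluster(m, 10), m, f)
    mean(attr(map, "events")$label == mix$labels)
  }, numeric(1))
  expect_true(all(accs >= 0.90))
  expect_gt(mean(accs), 0.95)
})

test_that("degenerate communities label without crashing", {
  # all events identical -> one occupied metacluster, no PHOTO
  f <- cyto_frame(tibble::as_tibble(matrix(1, 300, 4, dimnames = list(
    NULL, c("FSC-H", "SSC-H", "FL1-H", "FL3-H")))))
  m <- train_som(f, epochs = 3)
  map <- label_populations(metacluster(m, 10), m, f)
  occupied <- map$labels[map$labels$n_events > 0, ]
  expect_equal(nrow(occupied), 1)
  expect_false(any(map$labels$label == "PHOTO"))
  expect_true(all(map$labels$label[map$labels$n_events == 0] == "OTHER"))

  # no red population at all -> zero PHOTO metaclusters
  pops <- dplyr::bind_rows(
    population_spec("LNA", 0.6, c(`FSC-H` = 2.2, `SSC-H` = 2.0,
                                  `FL1-H` = 2.8, `FL3-H` = 2.0),
                    c(`FSC-H` = 0.15, `SSC-H` = 0.15, `FL1-H` = 0.15,
                      `FL3-H` = 0.15)),
    population_spec("HNA", 0.4, c(`FSC-H` = 2.6, `SSC-H` = 2.3,
                                  `FL1-H` = 3.4, `FL3-H` = 2.3),
                    c(`FSC-H` = 0.15, `SSC-H` = 0.15, `FL1-H` = 0.15,
                      `FL3-H` = 0.15))
  )
  mix <- labelled_mixture(4000, populations = pops, seed = 3)
  f2 <- transform_asinh(mix$frame)
  m2 <- train_som(f2)
  map2 <- label_populations(metacluster(m2, 10), m2, f2)
  expect_false(any(map2$labels$label == "PHOTO"))
  expect_setequal(unique(attr(map2, "events")$label), c("HNA", "LNA"))
})

test_that("the HNA/LNA ratio is recovered on a 2:1 mixture", {
  pops <- dplyr::bind_rows(
    population_spec("LNA", 1 / 3, c(`FSC-H` = 2.2, `SSC-H` = 2.0,
                                    `FL1-H` = 2.8, `FL3-H` = 2.0),
                    c(`FSC-H` = 0.15, `SSC-H` = 0.15, `FL1-H` = 0.15,
                      `FL3-H` = 0.15)),
    population_spec("HNA", 2 / 3, c(`FSC-H` = 2.6, `SSC-H` = 2.3,
                                    `FL1-H` = 3.4, `FL3-H` = 2.3),
                    c(`FSC-H` = 0.15, `SSC-H` = 0.15, `FL1-H` = 0.15,
                      `FL3-H` = 0.15))
  )
  mix <- labelled_mixture(9000, populations = pops, seed = 14)
  f <- transform_asinh(mix$frame)
  m <- train_som(f)
  map <- label_populations(metacluster(m, 10), m, f)
  counts <- population_counts(map, m, f)
  expect_lt(abs(counts$hna_lna_ratio - 2) / 2, 0.1)
  expect_equal(counts$PHOTO + counts$HNA + counts$LNA + counts$OTHER,
               n_events(f))  # event-count conservation

  expect_equal(hna_lna_ratio(10, 10), 1)
  expect_equal(hna_lna_ratio(0, 5), 0)
  expect_error(hna_lna_ratio(5, 0), class = "cytocruise_ratio_error")
})

test_that("SOM models serialize to JSON and back", {
  dir <- withr::local_tempdir()
  mix <- labelled_mixture(2000, seed = 2)
  m <- train_som(transform_asinh(mix$frame), epochs = 4)
  path <- file.path(dir, "som.json")
  write_som(m, path)
  back <- read_som(path)
  expect_equal(back$codes, m$codes, tolerance = 1e-12)
  expect_equal(back$grid, m$grid)
  probe <- transform_asinh(random_frame(200, seed = 3))
  expect_equal(assign_events(back, probe), assign_events(m, probe))
})
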