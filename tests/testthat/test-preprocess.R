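test_that("the FL1 threshold is inclusive and matches a brute-force filter", {
  f <- cyto_frame(tibble::tibble(`FL1-H` = c(100, 799.99, 800, 800.01, 5000)))
  kept <- apply_threshold(f, 800)
  expect_equal(kept[["FL1-H"]], c(800, 800.01, 5000))  # boundary retained

  expect_equal(n_events(apply_threshold(f, 1e6)), 0)

  g <- random_frame(500, seed = 7)
  expect_equal(apply_threshold(g, 1000)[["FL1-H"]],
               g[["FL1-H"]][g[["FL1-H"]] >= 1000])
  expect_error(apply_threshold(cyto_frame(tibble::tibble(A = 1)), 800),
               class = "cytocruise_channel_error")
})

test_that("asinh transform matches its closed form and is monotone", {
  f <- cyto_frame(tibble::tibble(`FL1-H` = c(0, 1, 10, 1000)))
  tr <- transform_asinh(f, 1)
  expect_equal(tr[["FL1-H"]][1], 0)
  expect_equal(tr[["FL1-H"]][2], log(1 + sqrt(2)), tolerance = 1e-12)
  expect_equal(tr[["FL1-H"]][2], 0.881374, tolerance = 1e-6)

  g <- random_frame(200, seed = 4)
  for (cof in c(1, 150)) {
    u <- as.matrix(g) / cof
    expect_equal(as.matrix(transform_asinh(g, cof)),
                 log(u + sqrt(u^2 + 1)), tolerance = 1e-12)
  }
  # bijective on [0, inf): sinh inverts it
  tr2 <- transform_asinh(g, 5)
  expect_equal(sinh(as.matrix(tr2)) * 5, as.matrix(g), tolerance = 1e-9)
})

test_that("polygon gating agrees with an independent point-in-polygon oracle", {
  skip_if_not_installed("mgcv")
  set.seed(12)
  f <- cyto_frame(tibble::tibble(`FL1-H` = runif(1000, -0.5, 1.5),
                                 `FL3-H` = runif(1000, -0.5, 1.5)))
  sq <- gate_spec("FL1-H", "FL3-H",
                  rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)))
  kept <- apply_gate(f, sq)
  oracle <- mgcv::in.out(
    rbind(as.matrix(sq$vertices), sq$vertices[1, ]),
    cbind(f[["FL1-H"]], f[["FL3-H"]])
  )
  expect_equal(n_events(kept), sum(oracle))
  expect_equal(kept[["FL1-H"]], f[["FL1-H"]][oracle])

  # non-convex polygon against the same oracle
  arrow <- gate_spec("FL1-H", "FL3-H",
                     rbind(c(0, 0), c(1, 0), c(0.5, 0.5), c(1, 1), c(0, 1)))
  kept2 <- apply_gate(f, arrow)
  oracle2 <- mgcv::in.out(rbind(arrow$vertices, arrow$vertices[1, ]),
                          cbind(f[["FL1-H"]], f[["FL3-H"]]))
  expect_equal(n_events(kept2), sum(oracle2))
})

test_that("gates keep boundary events and handle disjoint/full coverage", {
  f <- cyto_frame(tibble::tibble(`FL1-H` = c(0, 0.5, 1, 2),
                                 `FL3-H` = c(0, 0.5, 1, 2)))
  sq <- gate_spec("FL1-H", "FL3-H",
                  rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)))
  expect_equal(n_events(apply_gate(f, sq)), 3)  # vertex, interior, corner
  far <- gate_spec("FL1-H", "FL3-H",
                   rbind(c(10, 10), c(11, 10), c(11, 11)))
  expect_equal(n_events(apply_gate(f, far)), 0)
  big <- gate_spec("FL1-H", "FL3-H",
                   rbind(c(-1, -1), c(3, -1), c(3, 3), c(-1, 3)))
  expect_equal(n_events(apply_gate(f, big)), n_events(f))
})

test_that("self-intersecting gates are rejected and gates serialize to JSON", {
  expect_error(
    gate_spec("A", "B", rbind(c(0, 0), c(1, 1), c(1, 0), c(0, 1))),
    "simple"
  )
  dir <- withr::local_tempdir()
  g <- gate_spec("FL1-H", "FL3-H", rbind(c(0, 0), c(2, 0), c(1, 3)),
                 name = "bacteria")
  path <- file.path(dir, "gates.json")
  write_gates(g, path)
  back <- read_gates(path)[[1]]
  expect_equal(back$vertices, g$vertices)
  expect_equal(back$name, "bacteria")
  expect_true(back$transformed)
})

test_that("normalization divides by the global FL1 maximum of the set", {
  a <- cyto_frame(tibble::tibble(`FL1-H` = c(1, 5), `FL3-H` = c(2, 3)))
  b <- cyto_frame(tibble::tibble(`FL1-H` = c(4, 10), `FL3-H` = c(1, 8)))
  res <- normalize_to_max(list(a, b))
  expect_equal(res$scale, 10)
  expect_equal(max(res$frames[[1]][["FL1-H"]]), 0.5)
  expect_equal(max(vapply(res$frames, function(f) max(f[["FL1-H"]]),
                          numeric(1))), 1)
  # scale equals the max over the concatenation
  expect_equal(res$scale, max(c(a[["FL1-H"]], b[["FL1-H"]])))
  # FL3 divided by the same FL1 scale
  expect_equal(res$frames[[2]][["FL3-H"]], c(0.1, 0.8))

  per <- normalize_to_max(list(a, b), per_sample = TRUE)
  expect_equal(per$scale, c(5, 10))
  expect_equal(max(per$frames[[1]][["FL1-H"]]), 1)

  expect_error(normalize_to_max(list()), "empty")

  # ranking within each channel is preserved
  g <- random_frame(100, seed = 3)
  norm <- normalize_to_max(list(g))$frames[[1]]
  expect_equal(order(norm[["FL3-H"]]), order(g[["FL3-H"]]))
})

test_that("subsampling is uniform, seeded and exact-size", {
  f <- random_frame(50, seed = 1)
  same <- subsample_events(f, 50, seed = 2)
  expect_equal(sort(same[["FL1-H"]]), sort(f[["FL1-H"]]))

  s1 <- subsample_events(f, 10, seed = 7)
  s2 <- subsample_events(f, 10, seed = 7)
  expect_identical(as.matrix(s1), as.matrix(s2))
  expect_equal(n_events(s1), 10)

  expect_error(subsample_events(f, 51), class = "cytocruise_size_error")

  # frequency: choosing 1 of 3 over 2000 repeats is binomial(2000, 1/3)
  g <- random_frame(3, seed = 9)
  set.seed(31)
  picks <- vapply(1:2000, function(i) {
    subsample_events(g, 1)[["FL1-H"]]
  }, numeric(1))
  tab <- table(factor(picks, levels = g[["FL1-H"]]))
  expect_true(all(abs(tab - 2000 / 3) < 3 * sqrt(2000 * (1 / 3) * (2 / 3))))
})

test_that("minimum cell count scans the whole set", {
  fs <- lapply(c(3, 7, 5), function(n) random_frame(n, seed = n))
  expect_equal(min_cell_count(fs), 3)
  expect_equal(min_cell_count(fs[2]), 7)
  expect_error(min_cell_count(list()), "Empty")
})

test_that("the preprocessing chain never increases the event count", {
  f <- random_frame(2000, seed = 13)
  thr <- apply_threshold(f, 500)
  tr <- transform_asinh(thr, 1)
  g <- gate_spec("FL1-H", "FL3-H",
                 rbind(c(5, 0), c(10, 0), c(10, 10), c(5, 10)))
  gated <- apply_gate(tr, g)
  expect_lte(n_events(thr), n_events(f))
  expect_lte(n_events(gated), n_events(thr))
  sub <- subsample_events(gated, min(100, n_events(gated)), seed = 1)
  expect_lte(n_events(sub), n_events(gated))
})
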