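unit_frame <- function(u, v) {
  cyto_frame(tibble::tibble(`FL1-H` = u, `FL3-H` = v))
}

test_that("binning counts every event once and clamps the upper edge", {
  fp1 <- bin_events(unit_frame(0.3, 0.7), grid_size = 8)
  expect_equal(sum(fp1$counts[[1]]), 1)
  expect_equal(fingerprint_density(fp1)[fingerprint_density(fp1) > 0], 1)

  # events exactly at (1, 1) land in the last bin
  fp2 <- bin_events(unit_frame(c(1, 1), c(1, 1)), grid_size = 4)
  expect_equal(fp2$counts[[1]][4, 4], 2)

  expect_error(bin_events(unit_frame(1.5, 0.5)),
               class = "cytocruise_normalization_error")
  # clamp mode tolerates small overflow but not unnormalized data
  expect_equal(sum(bin_events(unit_frame(1.05, 0.5), grid_size = 4,
                              clamp = TRUE)$counts[[1]]), 1)
  expect_error(bin_events(unit_frame(5, 0.5), clamp = TRUE),
               class = "cytocruise_normalization_error")
})

test_that("uniform draws fill a coarse grid to multinomial accuracy", {
  set.seed(42)
  n <- 1e4
  fp <- bin_events(unit_frame(runif(n), runif(n)), grid_size = 4)
  p <- fingerprint_density(fp)
  expect_equal(sum(p), 1, tolerance = 1e-12)
  sigma <- sqrt((1 / 16) * (15 / 16) / n)
  expect_true(all(abs(p - 1 / 16) < 3.5 * sigma))
})

test_that("Hill numbers satisfy their closed-form identities", {
  for (k in c(1, 16, 1024)) {
    d <- hill_diversity(rep(1 / k, k), q = c(0, 1, 2))
    expect_equal(d$D, rep(k, 3), tolerance = 1e-9)
  }
  one <- hill_diversity(c(0, 1, 0), q = c(0, 1, 2))
  expect_equal(one$D, rep(1, 3))

  two <- hill_diversity(c(0.75, 0.25), q = c(1, 2))
  expect_equal(two$D[two$q == 2], 1.6, tolerance = 1e-12)
  expect_equal(two$D[two$q == 1], exp(-(0.75 * log(0.75) + 0.25 * log(0.25))),
               tolerance = 1e-12)
  expect_equal(two$D[two$q == 1], 1.754765, tolerance = 1e-6)
})

test_that("Hill numbers are weakly decreasing in q on random fingerprints", {
  set.seed(11)
  for (i in 1:100) {
    k <- sample(2:64, 1)
    p <- rgamma(k, shape = runif(1, 0.2, 2))
    d <- hill_diversity(p / sum(p), q = c(0, 0.5, 1, 1.5, 2, 3))$D
    expect_true(all(diff(d) <= 1e-9))
  }
})

test_that("diversity is invariant under bin permutation and rises with evenness", {
  set.seed(3)
  p <- rgamma(32, 1)
  p <- p / sum(p)
  d1 <- hill_diversity(p, q = 2)$D
  d2 <- hill_diversity(sample(p), q = 2)$D
  expect_equal(d1, d2, tolerance = 1e-12)

  # two-category mixture: D2 increases as the split approaches 1:1
  w <- seq(0.5, 0.95, by = 0.05)
  d2s <- vapply(w, function(wi) hill_diversity(c(wi, 1 - wi), q = 2)$D,
                numeric(1))
  expect_true(all(diff(d2s) < 0))

  # merging two bins never increases richness
  pm <- c(p[1] + p[2], p[-(1:2)])
  expect_lte(hill_diversity(pm, q = 0)$D, hill_diversity(p, q = 0)$D)
})

test_that("fingerprints computed from events feed Hill diversity correctly", {
  # 16 events placed one per bin of a 4x4 grid -> uniform fingerprint
  centers <- (seq_len(4) - 0.5) / 4
  grid <- expand.grid(u = centers, v = centers)
  fp <- bin_events(unit_frame(grid$u, grid$v), grid_size = 4)
  d <- hill_diversity(fp)
  expect_equal(d$D, rep(16, 3), tolerance = 1e-9)
  expect_equal(d$sample_id, rep(NA_character_, 3))
})

test_that("Bray-Curtis dissimilarity matches hand and vegan oracles", {
  fa <- bin_events(unit_frame(c(0.1, 0.1, 0.6), c(0.1, 0.1, 0.6)),
                   grid_size = 2)
  expect_equal(beta_diversity(fa, fa), 0)

  fb <- bin_events(unit_frame(0.9, 0.2), grid_size = 2)
  fc <- bin_events(unit_frame(c(0.1, 0.9), c(0.1, 0.2)), grid_size = 2)
  # disjoint supports
  expect_equal(beta_diversity(fa, fb), 1)
  # hand arithmetic: p_a = (2/3, 0, 0, 1/3), p_c = (1/2, 1/2, 0, 0)
  expect_equal(beta_diversity(fa, fc), 1 - 1 / 2, tolerance = 1e-12)
  expect_equal(beta_diversity(fa, fc), beta_diversity(fc, fa))

  skip_if_not_installed("vegan")
  pa <- fingerprint_density(fa)
  pc <- fingerprint_density(fc)
  expect_equal(beta_diversity(fa, fc),
               as.numeric(vegan::vegdist(rbind(pa, pc), method = "bray")),
               tolerance = 1e-12)

  mismatch <- bin_events(unit_frame(0.5, 0.5), grid_size = 4)
  expect_error(beta_diversity(fa, mismatch), "grid")
})

test_that("sparse CSV storage round-trips fingerprints", {
  dir <- withr::local_tempdir()
  set.seed(5)
  fps <- list(
    bin_events(unit_frame(runif(200), runif(200)), grid_size = 16,
               sample_id = "s1"),
    bin_events(unit_frame(runif(100), runif(100)), grid_size = 16,
               sample_id = "s2")
  )
  path <- file.path(dir, "fp.csv")
  write_fingerprints(fps, path)
  back <- read_fingerprints(path)
  expect_equal(back$s1$counts[[1]], fps[[1]]$counts[[1]])
  expect_equal(back$s2$n_events, 100)
  expect_equal(hill_diversity(back$s1, 2)$D, hill_diversity(fps[[1]], 2)$D)
})

test_that("optional Gaussian smoothing preserves total density", {
  set.seed(6)
  fp <- bin_events(unit_frame(runif(500), runif(500)), grid_size = 32,
                   smooth_sd = 1.5)
  expect_equal(sum(fp$counts[[1]]), 500, tolerance = 1e-9)
  expect_equal(sum(fingerprint_density(fp)), 1, tolerance = 1e-12)
})
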