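test_that("genome generator respects boundary AT fractions and validates input", {
  all_at <- generate_genome(200, at_fraction = 1, seed = 1)
  expect_true(all(strsplit(all_at$bases, "")[[1]] %in% c("A", "T")))
  none_at <- generate_genome(200, at_fraction = 0, seed = 1)
  expect_true(all(strsplit(none_at$bases, "")[[1]] %in% c("G", "C")))

  expect_error(generate_genome(10, at_fraction = 1.5), "probability")
  expect_error(generate_genome(10, persistence = -0.1), "probability")
  # stationarity is impossible: implied GC->AT rate above 1
  expect_error(generate_genome(10, at_fraction = 0.9, persistence = 0.1),
               "exceeds 1")
})

test_that("generators are bit-reproducible and leave the global RNG alone", {
  g1 <- generate_genome(500, seed = 3)
  g2 <- generate_genome(500, seed = 3)
  expect_identical(g1$bases, g2$bases)

  set.seed(123)
  before <- runif(1)
  set.seed(123)
  invisible(generate_genome(100, seed = 9))
  invisible(generate_bubbles(10, seed = 9))
  invisible(generate_distances(2, 0.1, 10, seed = 9))
  expect_equal(runif(1), before)

  b1 <- generate_bubbles(50, seed = 4)
  b2 <- generate_bubbles(50, seed = 4)
  expect_identical(b1, b2)
  d1 <- generate_distances(2.38, 0.3, 50, seed = 4)
  d2 <- generate_distances(2.38, 0.3, 50, seed = 4)
  expect_identical(d1, d2)
})

test_that("independent genomes recover their AT fraction within sampling error", {
  n <- 100000L
  g <- generate_genome(n, at_fraction = 0.5, seed = 21)
  frac <- attr(at_mask(g$bases), "at_fraction")
  se <- sqrt(0.5 * 0.5 / n)
  expect_lt(abs(frac - 0.5), 3 * se)
})

test_that("Markov genomes recover stationary fraction and persistence", {
  n <- 100000L
  p <- 0.6
  a <- 0.7 # P(AT -> AT)
  b <- p * (1 - a) / (1 - p)
  g <- generate_genome(n, at_fraction = p, persistence = a, seed = 31)
  bits <- as.vector(at_mask(g$bases))

  # persistence: AT -> AT transition frequency
  prev_at <- bits[-n]
  a_hat <- mean(bits[-1][prev_at])
  se_a <- sqrt(a * (1 - a) / sum(prev_at))
  expect_lt(abs(a_hat - a), 3 * se_a)

  # stationary fraction, with autocorrelation-corrected standard error
  rho <- a - b
  se_p <- sqrt(p * (1 - p) / n * (1 + rho) / (1 - rho))
  expect_lt(abs(mean(bits) - p), 3 * se_p)
})

test_that("bubble generator covers the observed support and converts lengths", {
  u <- generate_bubbles(2000, family = "uniform", min_nm = 1, max_nm = 8,
                        seed = 5)
  expect_true(all(u$length_nm >= 1 & u$length_nm <= 8))
  se <- (8 - 1) / sqrt(12 * nrow(u))
  expect_lt(abs(mean(u$length_nm) - 4.5), 3 * se)

  fx <- generate_bubbles(5, family = "fixed", mean_nm = 1.42)
  expect_true(all(fx$length_bp_rounded == 2)) # 1.42 nm = 2 bp at 0.71 nm/bp

  expect_equal(nrow(generate_bubbles(0)), 0L)

  nm <- generate_bubbles(500, family = "normal", mean_nm = 1, sd_nm = 2,
                         seed = 6)
  expect_true(all(nm$length_nm > 0)) # truncated at zero
})

test_that("distance generator recovers its parameters", {
  expect_equal(generate_distances(1.42, 0, 5)$value_nm, rep(1.42, 5))

  d <- generate_distances(2.38, 0.3, 1000, seed = 8)
  st <- glance(distance_stats(d))
  expect_lt(abs(st$mean_nm - 2.38), 3 * 0.3 / sqrt(1000))
  expect_true(all(d$value_nm > 0))

  # composition: recovered protrusion-interval mean reproduces the scale
  di <- generate_distances(1.42, 0.2, 2000, seed = 9)
  sc <- derive_scale(mean(di$value_nm), 2)
  expect_lt(abs(sc$nm_per_bp - 0.71), 3 * 0.2 / sqrt(2000) / 2)
})
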