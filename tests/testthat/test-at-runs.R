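test_that("at_mask reduces sequences to AT bits with the right fraction", {
  m <- at_mask("AATG")
  expect_equal(as.vector(m), c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(attr(m, "at_fraction"), 0.75)

  expect_equal(attr(at_mask("GGCC"), "at_fraction"), 0)
  expect_true(all(at_mask("ATATAT")))

  expect_warning(mN <- at_mask("ANT"), "ambiguous")
  expect_equal(as.vector(mN), c(TRUE, FALSE, TRUE))
  expect_equal(attr(mN, "n_ambiguous"), 1L)

  expect_error(at_mask("AXT"), "outside")
})

test_that("maximal AT runs are extracted exactly, including end runs", {
  g <- tibble::tibble(id = "x", bases = "AATGGATTA", length = 9L)
  runs <- at_runs(g)
  expect_equal(runs$start, c(0L, 5L))
  expect_equal(runs$end, c(3L, 9L))
  expect_equal(runs$length, c(3L, 4L))
  expect_true(all(runs$kind == "at_run"))

  expect_equal(nrow(at_runs(tibble::tibble(id = "y", bases = "GGCC"))), 0L)

  all_at <- at_runs(tibble::tibble(id = "z", bases = "ATATAT"))
  expect_equal(all_at$start, 0L)
  expect_equal(all_at$end, 6L)
})

test_that("run extraction matches a naive scan and runs are maximal", {
  set.seed(42)
  for (i in 1:20) {
    bases <- random_bases(sample(10:200, 1), p_at = runif(1, 0.2, 0.8))
    mask <- as.vector(at_mask(bases))
    runs <- at_runs(tibble::tibble(id = "r", bases = bases))
    ref <- naive_runs(mask)
    expect_equal(runs$start, ref$start)
    expect_equal(runs$end, ref$end)
    # maximality: flanking positions, when they exist, are non-AT
    left <- runs$start[runs$start > 0]
    right <- runs$end[runs$end < length(mask)]
    expect_false(any(mask[left]))      # position start-1 (1-based: start)
    expect_false(any(mask[right + 1])) # position end (1-based: end+1)
  }
})

test_that("coverage_curve computes pooled percentages and validates input", {
  segs <- tibble::tibble(length = c(3, 4))
  curve <- coverage_curve(segs, total_bp = 9, thresholds = c(3, 4, 5))
  expect_equal(curve$coverage_percent, 100 * c(7, 4, 0) / 9, tolerance = 1e-12)
  expect_equal(curve$covered_bp, c(7, 4, 0))

  expect_error(coverage_curve(segs, total_bp = 0, thresholds = 1), "positive")
  expect_error(coverage_curve(segs, total_bp = 9, thresholds = numeric()),
               "positive")
  expect_error(coverage_curve(segs, total_bp = 9, thresholds = c(1, -1)),
               "positive")
})

test_that("coverage curves are non-increasing and anchored at the AT fraction", {
  set.seed(7)
  for (i in 1:15) {
    g <- generate_genome(sample(50:2000, 1), at_fraction = runif(1, 0.1, 0.9))
    curve <- at_coverage(g, thresholds = 1:10)
    expect_true(all(diff(curve$coverage_percent) <= 1e-12))
    expect_true(all(curve$coverage_percent >= 0 & curve$coverage_percent <= 100))
    frac <- attr(suppressWarnings(at_mask(g$bases)), "at_fraction")
    expect_equal(curve$coverage_percent[1], 100 * frac, tolerance = 1e-12)
  }
})

test_that("Bernoulli-genome coverage matches the geometric-run closed form", {
  expect_equal(expected_at_coverage(0.5, 2), 37.5)
  expect_equal(expected_at_coverage(0.5, 3), 25)

  cases <- list(c(p = 0.5, t = 2), c(p = 0.5, t = 3), c(p = 0.3, t = 2))
  n_genomes <- 20
  len <- 20000L
  for (cs in cases) {
    covs <- vapply(seq_len(n_genomes), function(s) {
      g <- generate_genome(len, at_fraction = cs[["p"]], seed = 1000 + s)
      at_coverage(g, cs[["t"]])$coverage_percent
    }, numeric(1))
    se <- sd(covs) / sqrt(n_genomes)
    expect_lt(abs(mean(covs) - expected_at_coverage(cs[["p"]], cs[["t"]])),
              3 * se)
  }
})

test_that("multi-record genomes pool length-weighted and never bridge records", {
  g <- tibble::tibble(
    id = c("f1", "f2"),
    bases = c("AAAT", "TAGG"), # AT run would bridge the junction if glued
    length = c(4L, 4L)
  )
  runs <- at_runs(g)
  expect_equal(runs$id, c("f1", "f2"))
  expect_equal(runs$length, c(4L, 2L)) # not one 6-run across the boundary
  curve <- at_coverage(g, thresholds = c(2, 4))
  expect_equal(curve$coverage_percent, 100 * c(6, 4) / 8)
})
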