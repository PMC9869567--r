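test_that("in-phase packing produces no zigzag segment", {
  lat <- strand_lattice(2, markers_a = 0, markers_b = 0)
  expect_equal(nrow(zigzag_segments(lat)), 0L)

  # identical marker sets on both strands: fully in-phase, zero coverage
  lat2 <- strand_lattice(10, markers_a = c(0, 3, 6), markers_b = c(0, 3, 6))
  expect_equal(nrow(zigzag_segments(lat2)), 0L)
})

test_that("alternating markers with unit offset form one segment", {
  lat <- strand_lattice(5, markers_a = c(0, 2), markers_b = 1)
  segs <- zigzag_segments(lat)
  expect_equal(nrow(segs), 1L)
  expect_equal(segs$start, 0L)
  expect_equal(segs$end, 3L)
  expect_equal(segs$n_molecules, 3L)
  expect_equal(segs$strand_of_first, "a")

  # mirror phase
  latm <- strand_lattice(5, markers_a = 1, markers_b = c(0, 2))
  expect_equal(zigzag_segments(latm)$strand_of_first, "b")
})

test_that("zigzag segments end at in-phase markers and at gaps", {
  # a: 0,2  b: 1,5  -> [0,3) then an isolated marker at 5
  lat <- strand_lattice(8, markers_a = c(0, 2), markers_b = c(1, 5))
  segs <- zigzag_segments(lat)
  expect_equal(segs$start, c(0L, 5L))
  expect_equal(segs$n_molecules, c(3L, 1L))

  # both-occupied index interrupts: a: 0,2  b: 2 -> in-phase at 2
  lat2 <- strand_lattice(6, markers_a = c(0, 2), markers_b = 2)
  segs2 <- zigzag_segments(lat2)
  expect_equal(segs2$start, 0L)
  expect_equal(segs2$end, 1L)
  expect_equal(segs2$n_molecules, 1L)
})

test_that("zigzag segments are sorted, non-overlapping, and count molecules", {
  for (s in 1:5) {
    lat <- simulate_jammed_adsorption(2000, seed = 100 + s)
    segs <- zigzag_segments(lat)
    expect_true(all(diff(segs$start) > 0))
    expect_true(all(segs$end[-nrow(segs)] <= segs$start[-1]))
    expect_equal(segs$n_molecules, segs$end - segs$start)
    # every marker position inside a segment carries exactly one marker
    one <- xor(lat$marker_a, lat$marker_b)
    for (i in seq_len(min(nrow(segs), 20))) {
      expect_true(all(one[(segs$start[i] + 1):segs$end[i]]))
    }
  }
})

test_that("GC positions split zigzag segments into combined pieces", {
  segs <- tibble::tibble(start = 0L, end = 5L, n_molecules = 5L,
                         strand_of_first = "a", kind = "zigzag")
  all_at <- rep(TRUE, 5)
  unchanged <- combined_segments(segs, all_at)
  expect_equal(unchanged$start, 0L)
  expect_equal(unchanged$end, 5L)
  expect_equal(unchanged$n_molecules, 5L)
  expect_equal(unchanged$kind, "combined")

  gc_at_2 <- c(TRUE, TRUE, FALSE, TRUE, TRUE)
  split <- combined_segments(segs, gc_at_2)
  expect_equal(split$start, c(0L, 3L))
  expect_equal(split$end, c(2L, 5L))
  expect_equal(split$n_molecules, c(2L, 2L))

  expect_error(combined_segments(segs, rep(TRUE, 4), lattice_length = 5),
               "does not match")
  expect_error(combined_segments(segs, "ATTTA"), "logical")
})

test_that("replicated coverage is monotone, bounded by marginals, reproducible", {
  n <- 3000L
  mask <- suppressWarnings(at_mask(generate_genome(n, seed = 77)$bases))
  zc <- zigzag_coverage(n, replicates = 5, base_seed = 5, thresholds = 1:6,
                        mask = mask)
  s <- zc$summary
  for (cv in unique(s$curve)) {
    vals <- s$mean_coverage[s$curve == cv][order(s$threshold[s$curve == cv])]
    expect_true(all(diff(vals) <= 1e-12))
  }
  # combined <= zigzag at every threshold of every replicate,
  # and combined <= AT coverage at threshold 1
  wide <- tidyr::pivot_wider(zc$replicates, names_from = "curve",
                             values_from = "coverage")
  expect_true(all(wide$combined <= wide$zigzag + 1e-12))
  at1 <- 100 * mean(mask)
  expect_true(all(wide$combined <= at1 + 1e-12))

  zc2 <- zigzag_coverage(n, replicates = 5, base_seed = 5, thresholds = 1:6,
                         mask = mask)
  expect_identical(zc$replicates, zc2$replicates)
  expect_identical(tidy(zc), tidy(zc2))
})

test_that("threshold 1 gives the total zigzag coverage (curve anchor)", {
  zc <- zigzag_coverage(2000, replicates = 3, base_seed = 9, thresholds = 1:3)
  s <- zc$summary
  expect_gte(s$mean_coverage[s$threshold == 1],
             s$mean_coverage[s$threshold == 3])
  # a threshold beyond any segment gives zero
  zbig <- zigzag_coverage(200, replicates = 2, base_seed = 9,
                          thresholds = 10000)
  expect_equal(zbig$summary$mean_coverage, 0)
})
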