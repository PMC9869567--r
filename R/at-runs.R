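#' Reduce a sequence to its AT mask
#'
#' Collapses a nucleotide sequence to a logical vector that is `TRUE`
#' wherever the base is `A` or `T`. This is the "reduced" representation on
#' which maximal AT-run extraction operates: only the weaker two-hydrogen-bond
#' AT pairs matter for melting-bubble propensity, so the four-letter sequence
#' is reduced to a two-class one. Ambiguous `N` bases map to `FALSE` and are
#' counted in the `n_ambiguous` attribute (with a warning).
#'
#' @param bases A single sequence string over `{A,C,G,T,N}` (lowercase
#'   accepted), e.g. the `bases` column of [read_fasta()].
#'
#' @return A logical vector with attributes `at_fraction` (mean of the bits)
#'   and `n_ambiguous` (count of `N` bases).
#'
#' @examples
#' m <- at_mask("AATG")
#' attr(m, "at_fraction") # 0.75
#' @export
at_mask <- function(bases) {
  stopifnot(is.character(bases), length(bases) == 1L)
  chars <- strsplit(toupper(bases), "", fixed = TRUE)[[1]]
  bad <- !(chars %in% c("A", "C", "G", "T", "N"))
  if (any(bad)) {
    abort(paste0(
      "sequence contains bases outside {A,C,G,T,N} at position ",
      which(bad)[1], ": '", chars[which(bad)[1]], "'"
    ))
  }
  bits <- chars %in% c("A", "T")
  n_amb <- sum(chars == "N")
  if (n_amb > 0) {
    warn(paste0(n_amb, " ambiguous 'N' base(s) treated as non-AT"))
  }
  structure(bits, at_fraction = mean(bits), n_ambiguous = n_amb)
}

# Maximal runs of TRUE in a logical vector, as a 0-based half-open tibble.
runs_from_logical <- function(bits) {
  stopifnot(is.logical(bits))
  bits <- as.vector(bits) # drop at_mask attributes, rle() wants a bare vector
  if (length(bits) == 0L || !any(bits)) {
    return(tibble(start = integer(), end = integer(), length = integer()))
  }
  r <- rle(bits)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values
  tibble(
    start = as.integer(starts[keep]),
    end = as.integer(ends[keep]),
    length = as.integer(r$lengths[keep])
  )
}

#' Extract maximal AT runs
#'
#' Finds every maximal stretch of consecutive A/T positions in each genome
#' record. Runs touching either sequence end count as maximal runs; runs
#' never bridge records (multi-record inputs, e.g. restriction fragments, are
#' physically separate strands).
#'
#' @param genome A genome tibble ([read_fasta()] / [generate_genome()]), or a
#'   logical AT mask from [at_mask()].
#'
#' @return A tibble with columns `id`, `start`, `end` (0-based, half-open),
#'   `length` (bp) and `kind = "at_run"`.
#'
#' @examples
#' g <- tibble::tibble(id = "x", bases = "AATGGATTA", length = 9L)
#' at_runs(g) # runs [0,3) and [5,9)
#' @export
at_runs <- function(genome) {
  if (is.logical(genome)) {
    runs <- runs_from_logical(genome)
    return(mutate(runs, id = "mask", kind = "at_run",
                  .before = "start"))
  }
  stopifnot(is.data.frame(genome), all(c("id", "bases") %in% names(genome)))
  purrr::map2_dfr(genome$id, genome$bases, function(id, bases) {
    runs <- runs_from_logical(suppressWarnings(at_mask(bases)))
    mutate(runs, id = id, kind = "at_run", .before = "start")
  })
}

#' Coverage-versus-threshold curve for a set of segments
#'
#' For each length threshold `t`, computes the percentage of the total
#' contour length covered by segments of length at least `t`. This is the
#' core statistic of the analysis: the fraction of a strand expected to
#' dissociate when only sufficiently long qualifying segments (AT runs,
#' zigzag passages, or their combination) melt.
#'
#' Segments from multiple records are pooled length-weighted: the numerator
#' sums covered bases over all records and the denominator is the pooled
#' total length.
#'
#' @param segments A tibble with a `length` column (bp; fractional lengths
#'   allowed for measured bubbles).
#' @param total_bp Total contour length (bp) of the underlying strand(s).
#' @param thresholds Positive length thresholds (bp).
#'
#' @return A tibble with columns `threshold_bp`, `covered_bp`, `total_bp`
#'   and `coverage_percent`, one row per threshold. `coverage_percent` is
#'   non-increasing in `threshold_bp`.
#'
#' @examples
#' segs <- tibble::tibble(length = c(3, 4))
#' coverage_curve(segs, total_bp = 9, thresholds = c(3, 4)) # 77.8%, 44.4%
#' @export
coverage_curve <- function(segments, total_bp, thresholds) {
  stopifnot(is.data.frame(segments), "length" %in% names(segments))
  if (!is.numeric(total_bp) || length(total_bp) != 1L || total_bp <= 0) {
    abort("`total_bp` must be a single positive number")
  }
  if (length(thresholds) == 0L || any(thresholds <= 0)) {
    abort("`thresholds` must be positive")
  }
  lens <- segments$length
  covered <- vapply(thresholds, function(t) sum(lens[lens >= t]), numeric(1))
  tibble(
    threshold_bp = as.numeric(thresholds),
    covered_bp = covered,
    total_bp = as.numeric(total_bp),
    coverage_percent = 100 * covered / total_bp
  )
}

#' AT-run coverage curve of a genome
#'
#' Convenience wrapper: extracts maximal AT runs with [at_runs()] and
#' evaluates [coverage_curve()] against the pooled genome length.
#'
#' @inheritParams at_runs
#' @param thresholds Run-length thresholds in bp.
#'
#' @return A coverage tibble (see [coverage_curve()]).
#' @export
at_coverage <- function(genome, thresholds = 1:12) {
  stopifnot(is.data.frame(genome), "length" %in% names(genome))
  coverage_curve(at_runs(genome), sum(genome$length), thresholds)
}

#' Expected AT-run coverage under an independent-base model
#'
#' Closed form for the expected coverage percentage of maximal AT runs of
#' length at least `t` when each position is A/T independently with
#' probability `p`: the run-length distribution is geometric, and the
#' fraction of positions lying in runs of length `L` is
#' `(1 - p)^2 * L * p^L`, so coverage at threshold `t` sums to
#' `100 * p^t * (t - (t - 1) * p)`. At `p = 0.5` this gives exactly 37.5% for
#' `t = 2` and 25% for `t = 3`.
#'
#' @param p Probability that a position is A or T.
#' @param t Run-length threshold (bp).
#'
#' @return Expected coverage in percent.
#'
#' @examples
#' expected_at_coverage(0.5, 2) # 37.5
#' @export
expected_at_coverage <- function(p, t) {
  stopifnot(p >= 0, p <= 1, t >= 1)
  100 * p^t * (t - (t - 1) * p)
}
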