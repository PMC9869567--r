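#' Construct a two-strand lattice from marker positions
#'
#' A `strand_lattice` models the two single strands of one double helix as
#' two parallel arrays of binding spots. Each adsorbed dimeric molecule
#' occupies two adjacent spots on one strand and is represented by a marker
#' at its left spot. This constructor builds a lattice directly from marker
#' positions (useful for worked examples and tests); simulated lattices come
#' from [simulate_jammed_adsorption()].
#'
#' @param length Number of binding spots per strand.
#' @param markers_a,markers_b 0-based left-spot positions of the molecules on
#'   strand a and strand b. Each molecule occupies spots `m` and `m + 1`, so
#'   positions must be in `[0, length - 2]` and at least 2 apart within a
#'   strand.
#' @param seed Optional seed recorded for provenance.
#'
#' @return An object of class `strand_lattice`: a list with elements
#'   `length`, `marker_a`, `marker_b` (logical vectors) and `seed`.
#' @export
strand_lattice <- function(length, markers_a = integer(), markers_b = integer(),
                           seed = NULL) {
  length <- as.integer(length)
  stopifnot(length >= 1L)
  to_bits <- function(pos, strand) {
    pos <- as.integer(sort(pos))
    if (any(pos < 0L) || any(pos > length - 2L)) {
      abort(paste0("marker positions on strand ", strand,
                   " must lie in [0, length - 2]"))
    }
    if (any(diff(pos) < 2L)) {
      abort(paste0("molecules overlap on strand ", strand,
                   ": markers must be at least 2 apart"))
    }
    bits <- logical(length)
    bits[pos + 1L] <- TRUE
    bits
  }
  structure(
    list(
      length = length,
      marker_a = to_bits(markers_a, "a"),
      marker_b = to_bits(markers_b, "b"),
      seed = seed
    ),
    class = "strand_lattice"
  )
}

# Random sequential adsorption of dimers on one strand, run to jamming.
# Equivalent to choosing uniformly among feasible adjacent free pairs at each
# step: scanning a uniform random permutation of all bonds and placing
# whenever both spots are free yields the same jamming ensemble, because a
# bond that is infeasible once stays infeasible forever.
fill_strand <- function(n) {
  occ <- logical(n)
  marker <- logical(n)
  for (b in sample.int(n - 1L)) {
    if (!occ[b] && !occ[b + 1L]) {
      occ[b] <- TRUE
      occ[b + 1L] <- TRUE
      marker[b] <- TRUE
    }
  }
  marker
}

#' Simulate random sequential dimer adsorption to jamming
#'
#' Fills the two strands of a lattice independently with dimeric molecules by
#' random sequential adsorption: at each step a molecule adsorbs on a
#' uniformly chosen pair of adjacent free spots, irreversibly, until no
#' adjacent free pair remains on either strand (jamming). At jamming only
#' isolated single vacancies survive; their expected fraction tends to
#' `exp(-2)` (about 13.5%) for long strands.
#'
#' @param length Binding spots per strand (at least 2).
#' @param seed Optional integer seed; when given, the deposition is
#'   reproducible and the global RNG state is left untouched.
#'
#' @return A [strand_lattice()] object at jamming.
#'
#' @examples
#' lat <- simulate_jammed_adsorption(100, seed = 1)
#' is_jammed(lat)
#' @export
simulate_jammed_adsorption <- function(length, seed = NULL) {
  length <- as.integer(length)
  if (is.na(length) || length < 2L) {
    abort("`length` must be at least 2 binding spots")
  }
  run <- function() {
    list(a = fill_strand(length), b = fill_strand(length))
  }
  m <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  structure(
    list(length = length, marker_a = m$a, marker_b = m$b, seed = seed),
    class = "strand_lattice"
  )
}

#' Per-spot occupancy of a lattice
#'
#' @param lattice A [strand_lattice()].
#' @return A list with logical vectors `a` and `b`, `TRUE` where the spot is
#'   covered by a molecule.
#' @export
occupancy <- function(lattice) {
  stopifnot(inherits(lattice, "strand_lattice"))
  body <- function(marker) marker | c(FALSE, marker[-length(marker)])
  list(a = body(lattice$marker_a), b = body(lattice$marker_b))
}

#' Reduce adsorbed molecules to left-end markers
#'
#' Each two-spot molecule is reduced to a single marker at its left spot,
#' the representation on which zigzag-phase bookkeeping operates.
#'
#' @param lattice A [strand_lattice()].
#' @return A list with integer vectors `a` and `b` of 0-based marker
#'   positions, one entry per molecule.
#'
#' @examples
#' lat <- strand_lattice(4, markers_a = c(0, 2))
#' reduce_to_markers(lat) # a: 0 2
#' @export
reduce_to_markers <- function(lattice) {
  stopifnot(inherits(lattice, "strand_lattice"))
  list(
    a = which(lattice$marker_a) - 1L,
    b = which(lattice$marker_b) - 1L
  )
}

#' Molecules of a lattice as a tibble
#'
#' @param lattice A [strand_lattice()].
#' @return A tibble with columns `id`, `strand` (`"a"`/`"b"`) and
#'   `left_spot` (0-based).
#' @export
molecules <- function(lattice) {
  m <- reduce_to_markers(lattice)
  out <- bind_rows(
    tibble(strand = "a", left_spot = m$a),
    tibble(strand = "b", left_spot = m$b)
  )
  mutate(out, id = seq_len(nrow(out)), .before = "strand")
}

#' Is a lattice jammed?
#'
#' A strand is jammed when it contains no two adjacent empty spots, i.e. no
#' further dimer can adsorb.
#'
#' @param lattice A [strand_lattice()].
#' @return `TRUE` if neither strand has an adjacent free pair.
#' @export
is_jammed <- function(lattice) {
  occ <- occupancy(lattice)
  no_pair <- function(o) !any(!o[-length(o)] & !o[-1])
  no_pair(occ$a) && no_pair(occ$b)
}

#' Exact expected vacancy count at dimer-RSA jamming
#'
#' The expected number of vacant spots left by random sequential dimer
#' adsorption on a lattice of `n` spots satisfies the recursion
#' `v_n = 2 / (n - 1) * sum(v_0, ..., v_{n-2})` (the first dimer lands on a
#' uniform bond and splits the lattice into two independent sub-lattices),
#' with `v_0 = 0`, `v_1 = 1`. The vacancy fraction `v_n / n` tends to
#' `exp(-2)` as `n` grows.
#'
#' @param n Lattice length(s) in spots.
#' @return Expected vacancy count(s), same length as `n`.
#'
#' @examples
#' expected_jamming_vacancies(3) / 3 # 1/3
#' expected_jamming_vacancies(4) / 4 # 1/6
#' @export
expected_jamming_vacancies <- function(n) {
  stopifnot(all(n >= 0))
  n_max <- max(n)
  v <- numeric(n_max + 1L) # v[k + 1] = v_k
  if (n_max >= 1L) v[2L] <- 1
  if (n_max >= 2L) {
    s <- 0 # running sum v_0 + ... + v_{k-2}
    for (k in 2:n_max) {
      v[k + 1L] <- 2 * s / (k - 1)
      s <- s + v[k] # add v_{k-1}: s becomes v_0 + ... + v_{k-1}, ready for k + 1
    }
  }
  v[n + 1L]
}

#' @export
print.strand_lattice <- function(x, ...) {
  m <- reduce_to_markers(x)
  cat("<strand_lattice> ", x$length, " spots/strand, ",
      length(m$a), " + ", length(m$b), " molecules",
      if (is_jammed(x)) ", jammed" else "",
      if (!is.null(x$seed)) paste0(", seed ", x$seed) else "",
      "\n", sep = "")
  invisible(x)
}
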