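#' Generate a synthetic genome with controlled AT statistics
#'
#' Draws the AT/GC class of each position either independently
#' (Bernoulli, the default) or from a two-state first-order Markov chain,
#' then assigns the concrete base uniformly within its class (A vs T, G vs
#' C). The Markov option models the AT-run clustering that real genomes can
#' show and which an independence model misses.
#'
#' The chain is parametrised by the stationary AT fraction `p` and the AT
#' self-transition probability `persistence` (`P(AT -> AT)`). The GC-to-AT
#' rate is then `p * (1 - persistence) / (1 - p)`, which keeps `p`
#' stationary; `persistence = p` recovers the independence model (the
#' default). The default length and `at_fraction = 0.5` emulate a
#' bacteriophage-lambda-like genome (48,502 bp at ~50% AT).
#'
#' @param length Sequence length in bp.
#' @param at_fraction Stationary probability `p` that a position is A/T.
#' @param persistence `P(AT -> AT)`; `NULL` (default) means independence.
#' @param seed Optional integer seed (global RNG state untouched).
#' @param id Record identifier.
#'
#' @return A one-row genome tibble (`id`, `bases`, `length`, `n_ambiguous`),
#'   the same shape as [read_fasta()] output.
#'
#' @examples
#' g <- generate_genome(1000, seed = 1)
#' attr(at_mask(g$bases), "at_fraction")
#' @export
generate_genome <- function(length, at_fraction = 0.5, persistence = NULL,
                            seed = NULL, id = "synthetic") {
  length <- as.integer(length)
  stopifnot(length >= 1L)
  p <- at_fraction
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 || p > 1) {
    abort("`at_fraction` must be a probability in [0, 1]")
  }
  a <- if (is.null(persistence)) p else persistence
  if (!is.numeric(a) || length(a) != 1L || is.na(a) || a < 0 || a > 1) {
    abort("`persistence` must be a probability in [0, 1]")
  }
  b <- if (p >= 1) 1 else p * (1 - a) / (1 - p) # P(GC -> AT)
  if (b > 1 + 1e-12) {
    abort(paste0("`persistence` = ", a, " is too low for `at_fraction` = ",
                 p, ": implied GC->AT rate exceeds 1"))
  }
  b <- min(b, 1)
  draw <- function() {
    is_at <- logical(length)
    if (p %in% c(0, 1) || a == p) {
      is_at <- runif(length) < p
    } else {
      u <- runif(length)
      is_at[1] <- u[1] < p
      for (i in seq_len(length)[-1]) {
        is_at[i] <- u[i] < (if (is_at[i - 1]) a else b)
      }
    }
    chars <- character(length)
    n_at <- sum(is_at)
    chars[is_at] <- sample(c("A", "T"), n_at, replace = TRUE)
    chars[!is_at] <- sample(c("G", "C"), length - n_at, replace = TRUE)
    paste(chars, collapse = "")
  }
  bases <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  tibble(id = id, bases = bases, length = length, n_ambiguous = 0L)
}

#' Generate synthetic bubble-length observations
#'
#' Draws bubble contour lengths (nm) from a chosen family and converts them
#' to bp with [nm_to_bp()]. The default, uniform on 1-8 nm, emulates the
#' observed range of dissociated sectors along imaged strands.
#'
#' @param n Number of bubbles; `n = 0` gives an empty table.
#' @param family `"uniform"` (on `[min_nm, max_nm]`), `"normal"`
#'   (`mean_nm`/`sd_nm`, truncated at zero by resampling) or `"fixed"`
#'   (every bubble exactly `mean_nm`).
#' @param min_nm,max_nm Uniform support (nm).
#' @param mean_nm,sd_nm Normal parameters, or the fixed value (nm).
#' @param scale A [conversion_scale()].
#' @param seed Optional integer seed.
#'
#' @return A tibble with columns `strand_id`, `length_nm`, `length_bp`,
#'   `length_bp_rounded` and `ok`.
#'
#' @examples
#' generate_bubbles(3, family = "fixed", mean_nm = 1.42)
#' @export
generate_bubbles <- function(n, family = c("uniform", "normal", "fixed"),
                             min_nm = 1, max_nm = 8, mean_nm = 4.5,
                             sd_nm = 1.5, scale = conversion_scale(),
                             seed = NULL) {
  family <- match.arg(family)
  n <- as.integer(n)
  stopifnot(n >= 0L)
  draw <- function() {
    switch(family,
      uniform = runif(n, min_nm, max_nm),
      normal = {
        out <- rnorm(n, mean_nm, sd_nm)
        while (any(out <= 0)) {
          out[out <= 0] <- rnorm(sum(out <= 0), mean_nm, sd_nm)
        }
        out
      },
      fixed = rep(mean_nm, n)
    )
  }
  nm <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  conv <- nm_to_bp(nm, scale)
  mutate(conv, strand_id = "synthetic", .before = "length_nm")
}

#' Generate synthetic feature-distance samples
#'
#' Draws `n` positive distances from a normal distribution truncated at zero
#' (by resampling). Used to emulate measured protrusion-interval and
#' groove-pitch samples for parameter-recovery tests.
#'
#' @param mean_nm,sd_nm Distribution parameters (nm); `sd_nm = 0` gives a
#'   constant sample.
#' @param n Sample size (>= 1).
#' @param seed Optional integer seed.
#' @param context Measurement context label, e.g. `"protrusion_interval"` or
#'   `"groove_pitch"`.
#' @param substrate Substrate label (e.g. `"Au"`, `"KBr"`).
#'
#' @return A tibble with columns `value_nm`, `context`, `substrate`.
#'
#' @examples
#' d <- generate_distances(1.42, 0.2, n = 100, seed = 1)
#' glance(distance_stats(d))
#' @export
generate_distances <- function(mean_nm, sd_nm, n, seed = NULL,
                               context = "protrusion_interval",
                               substrate = NA_character_) {
  n <- as.integer(n)
  stopifnot(n >= 1L, sd_nm >= 0, mean_nm > 0)
  draw <- function() {
    if (sd_nm == 0) {
      rep(mean_nm, n)
    } else {
      out <- rnorm(n, mean_nm, sd_nm)
      while (any(out <= 0)) {
        out[out <= 0] <- rnorm(sum(out <= 0), mean_nm, sd_nm)
      }
      out
    }
  }
  vals <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  tibble(value_nm = vals, context = context, substrate = substrate)
}
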