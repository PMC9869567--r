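#' Conversion scale between nanometres and base pairs
#'
#' Imaged contour lengths are measured in nm; the lattice statistics work in
#' bp. The default scale of 0.71 nm per bp is derived from the mean interval
#' distance between bound-complex protrusions along dissociated strands,
#' which spans two neighbouring phosphate groups (see [derive_scale()]).
#'
#' @param nm_per_bp Nanometres per base pair (> 0).
#' @param note Free-text provenance note.
#'
#' @return An object of class `conversion_scale`.
#' @export
conversion_scale <- function(nm_per_bp = 0.71,
                             note = "default protrusion-interval calibration") {
  if (!is.numeric(nm_per_bp) || length(nm_per_bp) != 1L ||
      is.na(nm_per_bp) || nm_per_bp <= 0) {
    abort("`nm_per_bp` must be a single positive number")
  }
  structure(list(nm_per_bp = nm_per_bp, note = note),
            class = "conversion_scale")
}

#' @export
print.conversion_scale <- function(x, ...) {
  cat("<conversion_scale> 1 bp = ", format(x$nm_per_bp), " nm (",
      x$note, ")\n", sep = "")
  invisible(x)
}

#' Derive the nm-per-bp scale from a protrusion interval
#'
#' The mean interval between equidistant protrusions along a coated
#' single-strand section spans a fixed number of base pairs (two, matching
#' the twofold distance between neighbouring phosphate groups), so the scale
#' is simply `mean_interval_nm / features_per_interval`. With the measured
#' mean interval of 1.42 nm this gives 0.71 nm per bp.
#'
#' @param mean_interval_nm Mean protrusion interval (nm, > 0).
#' @param features_per_interval Base pairs spanned per interval (> 0;
#'   default 2).
#'
#' @return A [conversion_scale()].
#'
#' @examples
#' derive_scale(1.42, 2) # 0.71 nm/bp
#' @export
derive_scale <- function(mean_interval_nm, features_per_interval = 2) {
  if (!is.numeric(mean_interval_nm) || length(mean_interval_nm) != 1L ||
      is.na(mean_interval_nm) || mean_interval_nm <= 0) {
    abort("`mean_interval_nm` must be a single positive number")
  }
  if (!is.numeric(features_per_interval) || length(features_per_interval) != 1L ||
      is.na(features_per_interval) || features_per_interval <= 0) {
    abort("`features_per_interval` must be a single positive number")
  }
  conversion_scale(
    nm_per_bp = mean_interval_nm / features_per_interval,
    note = paste0("derived from ", format(mean_interval_nm),
                  " nm interval spanning ", format(features_per_interval),
                  " bp")
  )
}

# round half up to the nearest integer (base round() rounds half to even)
round_half_up <- function(x) floor(x + 0.5)

#' Convert measured lengths from nm to bp
#'
#' Divides each measured length by the scale's `nm_per_bp`. Both the raw
#' (fractional) and the rounded bp value are returned; rounding is half-up to
#' the nearest integer (used for histogramming, while curves use the raw
#' values). Non-positive entries are flagged per entry (`ok = FALSE`, bp
#' values `NA`) with a warning rather than aborting the whole table.
#'
#' @param lengths_nm Numeric vector of measured lengths (nm).
#' @param scale A [conversion_scale()].
#'
#' @return A tibble with columns `length_nm`, `length_bp` (raw),
#'   `length_bp_rounded` and `ok`.
#'
#' @examples
#' nm_to_bp(c(0.71, 5.68), conversion_scale(0.71))
#' @export
nm_to_bp <- function(lengths_nm, scale = conversion_scale()) {
  stopifnot(inherits(scale, "conversion_scale"), is.numeric(lengths_nm))
  ok <- !is.na(lengths_nm) & lengths_nm > 0
  if (any(!ok)) {
    warn(paste0(sum(!ok), " non-positive or missing length(s) flagged"))
  }
  raw <- ifelse(ok, lengths_nm / scale$nm_per_bp, NA_real_)
  tibble(
    length_nm = lengths_nm,
    length_bp = raw,
    length_bp_rounded = round_half_up(raw),
    ok = ok
  )
}

#' Convert lengths from bp to nm
#'
#' @param lengths_bp Numeric vector (bp).
#' @param scale A [conversion_scale()].
#' @return Numeric vector (nm).
#' @export
bp_to_nm <- function(lengths_bp, scale = conversion_scale()) {
  stopifnot(inherits(scale, "conversion_scale"))
  lengths_bp * scale$nm_per_bp
}

#' Coverage curve of observed melting bubbles
#'
#' For each bp threshold `t`, the percentage of the total imaged contour
#' length made up by bubbles of (raw, fractional) bp length at least `t`.
#' The threshold-1 bin is flagged: bubbles shorter than the visual counting
#' threshold are systematically missed, so that bin dips below the true
#' value.
#'
#' @param bubbles A tibble with a `length_bp` column (e.g. from
#'   [nm_to_bp()] or [generate_bubbles()]).
#' @param total_contour_bp Total imaged contour length (bp); must be at least
#'   the summed bubble length.
#' @param thresholds bp thresholds.
#'
#' @return A coverage tibble (see [coverage_curve()]) with an extra logical
#'   column `flagged` marking the visual-counting-threshold bin.
#'
#' @examples
#' b <- tibble::tibble(length_bp = c(3, 4))
#' bubble_coverage_curve(b, total_contour_bp = 100, thresholds = 1:5)
#' @export
bubble_coverage_curve <- function(bubbles, total_contour_bp,
                                  thresholds = 1:12) {
  stopifnot(is.data.frame(bubbles), "length_bp" %in% names(bubbles))
  lens <- bubbles$length_bp[!is.na(bubbles$length_bp)]
  if (sum(lens) > total_contour_bp) {
    abort("`total_contour_bp` is shorter than the summed bubble lengths")
  }
  curve <- coverage_curve(tibble(length = lens),
                          total_bp = total_contour_bp,
                          thresholds = thresholds)
  mutate(curve, flagged = .data$threshold_bp <= 1)
}

#' Summary statistics and histogram of feature distances
#'
#' Arithmetic mean, sample standard deviation and a fixed-bin-width histogram
#' of measured feature-to-feature distances (protrusion intervals or groove
#' pitches).
#'
#' @param values_nm Positive distance measurements (nm), as a numeric vector
#'   or a tibble with a `value_nm` column (see [generate_distances()]).
#' @param bin_width_nm Histogram bin width (nm).
#'
#' @return An object of class `distance_stats`: list with `mean`, `sd`, `n`,
#'   `bin_width_nm` and `histogram` (tibble `bin_left`, `bin_right`,
#'   `midpoint`, `count`). `tidy()` returns the histogram, `glance()` the
#'   one-row summary.
#'
#' @examples
#' glance(distance_stats(c(1.3, 1.42, 1.5)))
#' @export
distance_stats <- function(values_nm, bin_width_nm = 0.2) {
  if (is.data.frame(values_nm)) {
    stopifnot("value_nm" %in% names(values_nm))
    values_nm <- values_nm$value_nm
  }
  values_nm <- values_nm[!is.na(values_nm)]
  if (length(values_nm) < 1L) {
    abort("`values_nm` must contain at least one measurement")
  }
  if (any(values_nm <= 0)) {
    abort("distance measurements must be positive")
  }
  stopifnot(bin_width_nm > 0)
  left0 <- floor(min(values_nm) / bin_width_nm) * bin_width_nm
  breaks <- seq(left0, max(values_nm) + bin_width_nm, by = bin_width_nm)
  counts <- table(cut(values_nm, breaks = breaks, right = FALSE))
  hist <- tibble(
    bin_left = breaks[-length(breaks)],
    bin_right = breaks[-1],
    midpoint = (breaks[-length(breaks)] + breaks[-1]) / 2,
    count = as.integer(counts)
  )
  structure(
    list(
      mean = mean(values_nm),
      sd = if (length(values_nm) > 1L) sd(values_nm) else 0,
      n = length(values_nm),
      bin_width_nm = bin_width_nm,
      histogram = hist
    ),
    class = "distance_stats"
  )
}

#' @export
print.distance_stats <- function(x, ...) {
  cat("<distance_stats> n = ", x$n, ", mean = ", format(x$mean, digits = 4),
      " nm, sd = ", format(x$sd, digits = 4), " nm\n", sep = "")
  invisible(x)
}

#' @rdname distance_stats
#' @param x A `distance_stats` object.
#' @param ... Unused.
#' @method tidy distance_stats
#' @export
tidy.distance_stats <- function(x, ...) x$histogram

#' @rdname distance_stats
#' @method glance distance_stats
#' @export
glance.distance_stats <- function(x, ...) {
  tibble(mean_nm = x$mean, sd_nm = x$sd, n = x$n,
         bin_width_nm = x$bin_width_nm)
}
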