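#' Extract antiphasic (zigzag) packing segments
#'
#' After reducing molecules to left-end markers, a zigzag passage is a
#' maximal run of consecutive spot indices at which exactly one of the two
#' strands carries a marker. Within such a run the markers necessarily
#' alternate strands with unit offset (two markers on the same strand cannot
#' sit on adjacent indices because their molecules would overlap), which is
#' exactly the antiphasic bracing pattern. A passage ends where both strands
#' carry a marker at the same index (in-phase packing) or where neither does
#' (molecule bodies or vacancies) — either way the zigzag arrangement is
#' interrupted.
#'
#' The bp extent of a segment is its marker span, so `end - start` equals the
#' number of alternating molecules.
#'
#' @param lattice A [strand_lattice()].
#'
#' @return A tibble with columns `start`, `end` (0-based half-open marker
#'   span), `n_molecules` (= `end - start`), `strand_of_first` and
#'   `kind = "zigzag"`, sorted and non-overlapping.
#'
#' @examples
#' # a at 0 and 2, b at 1: three molecules bracing in alternation
#' zigzag_segments(strand_lattice(5, markers_a = c(0, 2), markers_b = 1))
#' @export
zigzag_segments <- function(lattice) {
  stopifnot(inherits(lattice, "strand_lattice"))
  one <- xor(lattice$marker_a, lattice$marker_b)
  runs <- runs_from_logical(one)
  tibble(
    start = runs$start,
    end = runs$end,
    n_molecules = runs$length,
    strand_of_first = ifelse(lattice$marker_a[runs$start + 1L], "a", "b"),
    kind = "zigzag"
  )
}

#' Split zigzag segments at GC positions
#'
#' Combines the adsorption-pattern condition with the sequence condition:
#' each zigzag segment is split at every GC (non-AT) position inside it, so
#' the resulting pieces cover only spots where an antiphasically packed
#' molecule braces a weaker AT pair. Pieces inherit the alternation property;
#' molecule counts are recomputed per piece (threshold filtering is left to
#' the caller).
#'
#' @param segments A zigzag segment tibble from [zigzag_segments()].
#' @param mask A logical AT mask (see [at_mask()]) whose length equals the
#'   lattice length.
#' @param lattice_length Length of the lattice the segments came from, used
#'   to validate the mask.
#'
#' @return A tibble like [zigzag_segments()] with `kind = "combined"`.
#'
#' @examples
#' segs <- tibble::tibble(start = 0L, end = 5L, n_molecules = 5L,
#'                        strand_of_first = "a", kind = "zigzag")
#' mask <- c(TRUE, TRUE, FALSE, TRUE, TRUE) # GC at position 2
#' combined_segments(segs, mask, lattice_length = 5)
#' @export
combined_segments <- function(segments, mask, lattice_length = length(mask)) {
  stopifnot(is.data.frame(segments),
            all(c("start", "end") %in% names(segments)))
  if (!is.logical(mask)) {
    abort("`mask` must be a logical AT mask (see at_mask())")
  }
  if (length(mask) != lattice_length) {
    abort(paste0("mask length (", length(mask),
                 ") does not match lattice length (", lattice_length, ")"))
  }
  if (nrow(segments) == 0L) {
    return(tibble(start = integer(), end = integer(),
                  n_molecules = integer(), strand_of_first = character(),
                  kind = character()))
  }
  # Segments are non-overlapping maximal runs separated by at least one
  # position, so splitting all of them at once on a position-indicator
  # vector is equivalent to splitting each segment separately.
  zpos <- logical(lattice_length)
  for (i in seq_len(nrow(segments))) {
    zpos[(segments$start[i] + 1L):segments$end[i]] <- TRUE
  }
  pieces <- runs_from_logical(zpos & mask)
  tibble(
    start = pieces$start,
    end = pieces$end,
    n_molecules = pieces$length,
    strand_of_first = NA_character_,
    kind = "combined"
  )
}

#' Replicated zigzag (and combined) coverage curves
#'
#' Runs [simulate_jammed_adsorption()] for a number of replicates and, for
#' each molecule-count threshold `m`, computes the percentage of the strand
#' length covered by zigzag segments of at least `m` alternating molecules.
#' When an AT `mask` is supplied, the combined condition (segments split at
#' GC positions, then thresholded) is evaluated alongside.
#'
#' Replicate `r` uses seed `base_seed + r - 1`, so every replicate is
#' independently reproducible and the full run is bit-identical under a fixed
#' `base_seed`.
#'
#' @param strand_length Binding spots per strand.
#' @param replicates Number of independent jammed lattices.
#' @param base_seed Master seed.
#' @param thresholds Molecule-count thresholds (the bp-extent grid: a
#'   `k`-molecule zigzag spans `k` bp).
#' @param mask Optional logical AT mask of length `strand_length`; adds the
#'   `"combined"` curve.
#'
#' @return An object of class `rsa_coverage`: a list with
#'   * `summary`: tibble (`curve`, `threshold`, `mean_coverage`, `sd`, `se`,
#'     `n_replicates`),
#'   * `replicates`: per-replicate tibble (`replicate`, `seed`, `curve`,
#'     `threshold`, `coverage`),
#'   * `config`: the call configuration.
#'
#' @examples
#' zc <- zigzag_coverage(2000, replicates = 3, base_seed = 1, thresholds = 1:4)
#' tidy(zc)
#' @export
zigzag_coverage <- function(strand_length = 48502L, replicates = 100L,
                            base_seed = 1L, thresholds = 1:12, mask = NULL) {
  strand_length <- as.integer(strand_length)
  replicates <- as.integer(replicates)
  stopifnot(strand_length >= 2L, replicates >= 1L)
  if (!is.null(mask) && length(mask) != strand_length) {
    abort("`mask` length must equal `strand_length`")
  }
  per_rep <- purrr::map_dfr(seq_len(replicates), function(r) {
    seed_r <- base_seed + r - 1L
    lat <- simulate_jammed_adsorption(strand_length, seed = seed_r)
    segs <- zigzag_segments(lat)
    cov_of <- function(segdf) {
      vapply(thresholds, function(m) {
        100 * sum(segdf$n_molecules[segdf$n_molecules >= m]) / strand_length
      }, numeric(1))
    }
    out <- tibble(
      replicate = r, seed = seed_r, curve = "zigzag",
      threshold = as.numeric(thresholds), coverage = cov_of(segs)
    )
    if (!is.null(mask)) {
      comb <- combined_segments(segs, mask, strand_length)
      out <- bind_rows(out, tibble(
        replicate = r, seed = seed_r, curve = "combined",
        threshold = as.numeric(thresholds), coverage = cov_of(comb)
      ))
    }
    out
  })
  summary <- per_rep |>
    group_by(.data$curve, .data$threshold) |>
    summarise(
      mean_coverage = mean(.data$coverage),
      sd = sd(.data$coverage),
      se = sd(.data$coverage) / sqrt(dplyr::n()),
      n_replicates = dplyr::n(),
      .groups = "drop"
    )
  structure(
    list(
      summary = summary,
      replicates = per_rep,
      config = list(
        strand_length = strand_length, replicates = replicates,
        base_seed = base_seed, thresholds = thresholds,
        has_mask = !is.null(mask)
      )
    ),
    class = "rsa_coverage"
  )
}

#' @export
print.rsa_coverage <- function(x, ...) {
  cfg <- x$config
  cat("<rsa_coverage> ", cfg$replicates, " replicates on ",
      cfg$strand_length, "-spot strands (base seed ", cfg$base_seed, ")\n",
      sep = "")
  print(x$summary, n = 20)
  invisible(x)
}

#' @rdname zigzag_coverage
#' @param x An `rsa_coverage` object.
#' @param ... Unused.
#' @method tidy rsa_coverage
#' @export
tidy.rsa_coverage <- function(x, ...) x$summary

#' @rdname zigzag_coverage
#' @method glance rsa_coverage
#' @export
glance.rsa_coverage <- function(x, ...) {
  zig3 <- dplyr::filter(x$summary, .data$curve == "zigzag",
                        .data$threshold == 3)
  tibble(
    strand_length = x$config$strand_length,
    n_replicates = x$config$replicates,
    base_seed = x$config$base_seed,
    zigzag_coverage_3 = if (nrow(zig3)) zig3$mean_coverage else NA_real_,
    zigzag_se_3 = if (nrow(zig3)) zig3$se else NA_real_
  )
}

#' @rdname zigzag_coverage
#' @param object An `rsa_coverage` object.
#' @method autoplot rsa_coverage
#' @export
autoplot.rsa_coverage <- function(object, ...) {
  ggplot2::ggplot(
    object$summary,
    ggplot2::aes(x = .data$threshold, y = .data$mean_coverage,
                 colour = .data$curve, fill = .data$curve)
  ) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$mean_coverage - .data$se,
                   ymax = .data$mean_coverage + .data$se),
      alpha = 0.25, colour = NA
    ) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "threshold (molecules ≈ bp)",
      y = "contour length coverage (%)",
      colour = NULL, fill = NULL
    ) +
    ggplot2::theme_minimal()
}
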