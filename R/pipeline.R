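#' Run the full melting-bubble coverage analysis
#'
#' Orchestrates the three coverage analyses on one threshold grid:
#'
#' * `at` — percentage of the genome covered by maximal AT runs of length
#'   at least the threshold (sequence condition);
#' * `zigzag` — replicate mean percentage covered by antiphasic packing
#'   segments of at least that many molecules, from random sequential dimer
#'   adsorption to jamming (adsorption condition);
#' * `combined` — zigzag segments split at GC positions, then thresholded
#'   (both conditions at once, the dissociation-propensity curve);
#' * `observed` — coverage by measured bubble lengths, when supplied.
#'
#' Multi-record genomes (e.g. restriction fragments) are analysed per record
#' — lattices and runs never bridge records — and pooled length-weighted.
#' Replicate `r`, record `k` uses seed
#' `base_seed + (r - 1) * n_records + k`, and a synthetic genome (when no
#' `genome` is given) uses `base_seed` itself, so a fixed `base_seed` makes
#' the whole analysis bit-reproducible.
#'
#' @param genome A genome tibble from [read_fasta()] or [generate_genome()];
#'   `NULL` generates a lambda-like synthetic genome of `strand_length` bp.
#' @param bubbles Optional bubble table with a `length_bp` column (from
#'   [nm_to_bp()] or [generate_bubbles()]).
#' @param strand_length Length of the synthetic genome when `genome` is
#'   `NULL`.
#' @param at_fraction,persistence Synthetic genome model parameters (see
#'   [generate_genome()]).
#' @param replicates Number of jammed-lattice replicates.
#' @param base_seed Master seed for genome generation and all replicates.
#' @param thresholds Shared threshold grid (bp, equal to molecule counts for
#'   the zigzag curve).
#' @param scale A [conversion_scale()] (recorded in the manifest; bubbles are
#'   assumed already converted).
#' @param total_contour_bp Denominator for the observed curve; defaults to
#'   the genome length.
#'
#' @return An object of class `melt_analysis`: list with `curves` (named
#'   list of tibbles `at`, `zigzag`, `combined`, `observed`),
#'   `bubble_histogram`, `replicates` (per-replicate coverages), `summary`
#'   (one row; also via `glance()`) and `manifest` (config echo, seeds,
#'   config hash, package version).
#'
#' @examples
#' res <- melt_bubble_analysis(strand_length = 2000, replicates = 3,
#'                             base_seed = 1, thresholds = 1:6)
#' glance(res)
#' @export
melt_bubble_analysis <- function(genome = NULL, bubbles = NULL,
                                 strand_length = 48502L, at_fraction = 0.5,
                                 persistence = NULL, replicates = 100L,
                                 base_seed = 1L, thresholds = 1:12,
                                 scale = conversion_scale(),
                                 total_contour_bp = NULL) {
  stopifnot(length(thresholds) >= 1L, all(thresholds >= 1))
  replicates <- as.integer(replicates)
  stopifnot(replicates >= 1L)
  if (is.null(genome)) {
    genome <- generate_genome(strand_length, at_fraction = at_fraction,
                              persistence = persistence, seed = base_seed,
                              id = "synthetic_lambda_like")
  }
  stopifnot(is.data.frame(genome),
            all(c("id", "bases", "length") %in% names(genome)))
  n_rec <- nrow(genome)
  total_bp <- sum(genome$length)
  masks <- purrr::map(genome$bases, function(b) suppressWarnings(at_mask(b)))

  at_curve <- at_coverage(genome, thresholds)

  # replicated adsorption simulation, per record, pooled length-weighted
  per_rep <- purrr::map_dfr(seq_len(replicates), function(r) {
    zig_cov <- numeric(length(thresholds))
    comb_cov <- numeric(length(thresholds))
    for (k in seq_len(n_rec)) {
      seed_rk <- base_seed + (r - 1L) * n_rec + k
      lat <- simulate_jammed_adsorption(genome$length[k], seed = seed_rk)
      segs <- zigzag_segments(lat)
      comb <- combined_segments(segs, masks[[k]], genome$length[k])
      zig_cov <- zig_cov + vapply(thresholds, function(m) {
        sum(segs$n_molecules[segs$n_molecules >= m])
      }, numeric(1))
      comb_cov <- comb_cov + vapply(thresholds, function(m) {
        sum(comb$n_molecules[comb$n_molecules >= m])
      }, numeric(1))
    }
    bind_rows(
      tibble(replicate = r, curve = "zigzag",
             threshold = as.numeric(thresholds),
             coverage = 100 * zig_cov / total_bp),
      tibble(replicate = r, curve = "combined",
             threshold = as.numeric(thresholds),
             coverage = 100 * comb_cov / total_bp)
    )
  })
  sim_summary <- per_rep |>
    group_by(.data$curve, .data$threshold) |>
    summarise(
      mean_coverage = mean(.data$coverage),
      sd = sd(.data$coverage),
      se = sd(.data$coverage) / sqrt(dplyr::n()),
      n_replicates = dplyr::n(),
      .groups = "drop"
    )
  zig_curve <- filter(sim_summary, .data$curve == "zigzag")
  comb_curve <- filter(sim_summary, .data$curve == "combined")

  # observed bubbles (optional)
  if (!is.null(bubbles) && nrow(bubbles) > 0) {
    denom <- if (is.null(total_contour_bp)) total_bp else total_contour_bp
    obs_curve <- bubble_coverage_curve(bubbles, denom, thresholds)
    bp_rounded <- bubbles$length_bp_rounded %||%
      round_half_up(bubbles$length_bp)
    hist <- tibble(length_bp = as.integer(names(table(bp_rounded))),
                   count = as.integer(table(bp_rounded)))
  } else {
    obs_curve <- tibble(threshold_bp = as.numeric(thresholds),
                        covered_bp = 0, total_bp = as.numeric(total_bp),
                        coverage_percent = 0,
                        flagged = as.numeric(thresholds) <= 1)[0, ]
    hist <- tibble(length_bp = integer(), count = integer())
  }

  config <- list(
    genome_ids = genome$id, total_bp = total_bp, n_records = n_rec,
    replicates = replicates, base_seed = base_seed,
    thresholds = as.numeric(thresholds), nm_per_bp = scale$nm_per_bp,
    n_bubbles = if (is.null(bubbles)) 0L else nrow(bubbles)
  )
  at_frac_obs <- sum(purrr::map_dbl(masks, sum)) / total_bp
  run_hist <- at_runs(genome) |>
    dplyr::count(.data$length, name = "count")

  pick <- function(df, t, col = "mean_coverage") {
    row <- df[df$threshold == t, ]
    if (nrow(row)) row[[col]][1] else NA_real_
  }
  summary_row <- tibble(
    total_bp = total_bp,
    at_fraction = at_frac_obs,
    at_coverage_2bp = {
      r <- at_curve[at_curve$threshold_bp == 2, ]
      if (nrow(r)) r$coverage_percent[1] else NA_real_
    },
    zigzag_coverage_3 = pick(zig_curve, 3),
    zigzag_se_3 = pick(zig_curve, 3, "se"),
    combined_coverage_3 = pick(comb_curve, 3),
    combined_se_3 = pick(comb_curve, 3, "se"),
    n_replicates = replicates,
    base_seed = base_seed
  )

  structure(
    list(
      curves = list(at = at_curve, zigzag = zig_curve,
                    combined = comb_curve, observed = obs_curve),
      bubble_histogram = hist,
      replicates = per_rep,
      summary = summary_row,
      manifest = list(
        config = config,
        config_hash = rlang::hash(config),
        seeds = list(genome = if (n_rec == 1 &&
                                  startsWith(genome$id[1], "synthetic"))
                       base_seed else NA,
                     replicates = paste0("base_seed + (r-1)*", n_rec, " + k")),
        at_run_length_histogram = run_hist,
        package_version = as.character(utils::packageVersion("bubblecov")),
        r_version = R.version.string
      )
    ),
    class = "melt_analysis"
  )
}

#' @export
print.melt_analysis <- function(x, ...) {
  cat("<melt_analysis> ", x$summary$total_bp, " bp genome, ",
      x$summary$n_replicates, " replicates (base seed ",
      x$summary$base_seed, ")\n", sep = "")
  cat("  AT coverage (runs >= 2 bp):      ",
      sprintf("%.1f%%", x$summary$at_coverage_2bp), "\n", sep = "")
  cat("  zigzag coverage (>= 3 molecules): ",
      sprintf("%.1f%% +- %.2f (se)", x$summary$zigzag_coverage_3,
              x$summary$zigzag_se_3), "\n", sep = "")
  cat("  combined coverage (>= 3):         ",
      sprintf("%.1f%% +- %.2f (se)", x$summary$combined_coverage_3,
              x$summary$combined_se_3), "\n", sep = "")
  invisible(x)
}

#' Tidy the coverage curves of a melt analysis
#'
#' @param x A `melt_analysis` object.
#' @param ... Unused.
#' @return A long tibble with columns `curve`, `threshold_bp`,
#'   `coverage_percent` and `se` (`NA` for the deterministic curves).
#' @method tidy melt_analysis
#' @export
tidy.melt_analysis <- function(x, ...) {
  bind_rows(
    tibble(curve = "at", threshold_bp = x$curves$at$threshold_bp,
           coverage_percent = x$curves$at$coverage_percent, se = NA_real_),
    tibble(curve = "zigzag", threshold_bp = x$curves$zigzag$threshold,
           coverage_percent = x$curves$zigzag$mean_coverage,
           se = x$curves$zigzag$se),
    tibble(curve = "combined", threshold_bp = x$curves$combined$threshold,
           coverage_percent = x$curves$combined$mean_coverage,
           se = x$curves$combined$se),
    if (nrow(x$curves$observed)) {
      tibble(curve = "observed", threshold_bp = x$curves$observed$threshold_bp,
             coverage_percent = x$curves$observed$coverage_percent,
             se = NA_real_)
    }
  )
}

#' @rdname tidy.melt_analysis
#' @method glance melt_analysis
#' @export
glance.melt_analysis <- function(x, ...) x$summary

#' @rdname tidy.melt_analysis
#' @param object A `melt_analysis` object.
#' @method autoplot melt_analysis
#' @export
autoplot.melt_analysis <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$threshold_bp,
                                   y = .data$coverage_percent,
                                   colour = .data$curve)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "length threshold (bp)",
                  y = "contour length coverage (%)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Write analysis results to disk
#'
#' Writes one TSV per coverage curve (`at.tsv`, `zigzag.tsv`,
#' `combined.tsv`, `observed.tsv`) and one machine-readable JSON summary
#' (`summary.json`, holding the config echo and hash, seeds, key statistics,
#' AT-run-length histogram and bubble histogram) into `dir`.
#'
#' @param result A `melt_analysis` object.
#' @param dir Output directory (created if missing).
#'
#' @return Invisibly, the paths written.
#' @export
report <- function(result, dir) {
  stopifnot(inherits(result, "melt_analysis"))
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) abort(paste0("cannot create output directory: ", dir))
  }
  if (file.access(dir, mode = 2) != 0) {
    abort(paste0("output directory is not writable: ", dir))
  }
  sim_cols <- function(df) {
    tibble(threshold = df$threshold,
           mean_coverage_percent = df$mean_coverage,
           sd = df$sd, se = df$se, n_replicates = df$n_replicates)
  }
  paths <- c(
    at = file.path(dir, "at.tsv"),
    zigzag = file.path(dir, "zigzag.tsv"),
    combined = file.path(dir, "combined.tsv"),
    observed = file.path(dir, "observed.tsv"),
    summary = file.path(dir, "summary.json")
  )
  readr::write_tsv(result$curves$at, paths[["at"]])
  readr::write_tsv(sim_cols(result$curves$zigzag), paths[["zigzag"]])
  readr::write_tsv(sim_cols(result$curves$combined), paths[["combined"]])
  readr::write_tsv(result$curves$observed, paths[["observed"]])
  jsonlite::write_json(
    list(
      config = result$manifest$config,
      config_hash = result$manifest$config_hash,
      seeds = result$manifest$seeds,
      summary = result$summary,
      at_run_length_histogram = result$manifest$at_run_length_histogram,
      bubble_histogram = result$bubble_histogram,
      package_version = result$manifest$package_version,
      r_version = result$manifest$r_version
    ),
    paths[["summary"]], auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(paths)
}
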