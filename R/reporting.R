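#' Assemble and validate a pipeline run configuration
#'
#' @param synthetic A [synthetic_config()] to generate the landscape, or
#'   `NULL` when reading rasters from disk.
#' @param dtm_path,landcover_path Raster paths (used when `synthetic` is
#'   `NULL`).
#' @param datum_offset_mlhw NAVD88 elevation of MLHW (m), applied at read.
#' @param rises Numeric vector of sea-level-rise scenarios in metres; must
#'   be non-empty.
#' @param mlw_offset Depth of MLW below MLHW (m).
#' @param n_reps Replicates per scenario.
#' @param step Elevation step of the proportion matrix (m).
#' @param bw Bandwidth specification (see [build_proportion_matrix()]).
#' @param gls_n Subsample size for the stratified GLS.
#' @param gls_correlation `"exp"` or `"none"`.
#' @param sensitivity_sizes Subsample sizes for the sensitivity analysis,
#'   or `NULL` to skip it.
#' @param sensitivity_reps Replicates per sensitivity size.
#' @param seed Root seed; all stage seeds derive from it.
#' @param out_dir Output directory, or `NULL` to skip writing files.
#' @return An object of class `run_config`.
#' @export
run_config <- function(synthetic = synthetic_config(),
                       dtm_path = NULL, landcover_path = NULL,
                       datum_offset_mlhw = 0,
                       rises = c(0, 0.2, 0.4, 1.2), mlw_offset = 0.2,
                       n_reps = 1000, step = 0.001, bw = NULL,
                       gls_n = 2000, gls_correlation = "exp",
                       sensitivity_sizes = NULL, sensitivity_reps = 500,
                       seed = 1L, out_dir = NULL) {
  if (length(rises) == 0) stop("config error: scenario list is empty", call. = FALSE)
  if (any(rises < 0)) stop("config error: rises must be >= 0", call. = FALSE)
  if (is.null(synthetic) && (is.null(dtm_path) || is.null(landcover_path))) {
    stop("config error: provide either a synthetic config or both raster paths", call. = FALSE)
  }
  if (!is.null(synthetic)) stopifnot(inherits(synthetic, "synthetic_config"))
  stopifnot(mlw_offset > 0, n_reps >= 1, step > 0, gls_n >= 2)
  gls_correlation <- match.arg(gls_correlation, c("exp", "none"))
  structure(
    list(
      synthetic = synthetic, dtm_path = dtm_path, landcover_path = landcover_path,
      datum_offset_mlhw = datum_offset_mlhw,
      rises = rises, mlw_offset = mlw_offset, n_reps = n_reps,
      step = step, bw = bw, gls_n = gls_n, gls_correlation = gls_correlation,
      sensitivity_sizes = sensitivity_sizes, sensitivity_reps = sensitivity_reps,
      seed = as.integer(seed), out_dir = out_dir
    ),
    class = "run_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file. Recognised top-level keys mirror the arguments of
#'   [run_config()]; a `synthetic:` section is passed to
#'   [synthetic_config()], and a `landscape:` section with `dtm` /
#'   `landcover` / `datum_offset_mlhw` selects raster input instead.
#' @return A validated `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  syn <- NULL
  if (!is.null(y$synthetic)) {
    syn_args <- y$synthetic
    if (!is.null(syn_args$communities)) {
      syn_args$communities <- dplyr::bind_rows(syn_args$communities)
    }
    syn <- do.call(synthetic_config, syn_args)
  } else if (is.null(y$landscape)) {
    syn <- synthetic_config()
  }
  run_config(
    synthetic = syn,
    dtm_path = y$landscape$dtm, landcover_path = y$landscape$landcover,
    datum_offset_mlhw = y$landscape$datum_offset_mlhw %||% 0,
    rises = unlist(y$rises %||% c(0, 0.2, 0.4, 1.2)),
    mlw_offset = y$mlw_offset %||% 0.2,
    n_reps = y$n_reps %||% 1000,
    step = y$step %||% 0.001,
    bw = y$bandwidth,
    gls_n = y$gls$n %||% 2000,
    gls_correlation = y$gls$correlation %||% "exp",
    sensitivity_sizes = unlist(y$sensitivity$sizes),
    sensitivity_reps = y$sensitivity$n_reps %||% 500,
    seed = y$seed %||% 1L,
    out_dir = y$out_dir
  )
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(cnd) {
    stop("pipeline stage [", name, "] failed: ", conditionMessage(cnd), call. = FALSE)
  })
}

#' Run the full analysis pipeline
#'
#' Sequences every stage of the analysis: landscape (generate or read) →
#' pixel table → stratified GLS → density profiles → proportion matrix →
#' replicate simulations per scenario → percent-change table → optional
#' subsample sensitivity → summary CSVs and a machine-readable run
#' manifest. Any stage failure aborts with a stage-tagged error.
#'
#' @param config A [run_config()].
#' @return An object of class `slr_run`: list with `grid`, `pixels`, `fit`,
#'   `profiles`, `matrix`, `summaries` (one [replicate_simulations()]
#'   result per rise), `percent_change`, `sensitivity` (or `NULL`),
#'   `manifest`. Written to `config$out_dir` when set.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  grid <- stage("landscape", {
    if (!is.null(config$synthetic)) {
      generate_landscape(config$synthetic)
    } else {
      read_landscape(config$dtm_path, config$landcover_path, config$datum_offset_mlhw)
    }
  })
  pixels <- stage("pixel_table", to_pixel_table(grid))
  fit <- stage("gls", fit_stratified_gls(
    pixels,
    correlation = config$gls_correlation,
    max_n = config$gls_n, seed = config$seed
  ))
  profiles <- stage("density_profiles", elevation_density_profiles(pixels, bw = config$bw))
  matrix <- stage("proportion_matrix", build_proportion_matrix(pixels, step = config$step, bw = config$bw))
  summaries <- stage("simulation", {
    out <- purrr::map(config$rises, function(rise) {
      replicate_simulations(
        pixels, matrix, slr_scenario(rise, config$mlw_offset),
        n_reps = config$n_reps,
        base_seed = config$seed + round(10000 * rise)
      )
    })
    names(out) <- vapply(config$rises, format, character(1))
    out
  })
  pct <- stage("percent_change", percent_change_table(summaries))
  sens <- NULL
  if (!is.null(config$sensitivity_sizes)) {
    sens <- stage("sensitivity", subsample_sensitivity(
      pixels, matrix,
      scenarios = purrr::map(config$rises, slr_scenario, mlw_offset = config$mlw_offset),
      sizes = config$sensitivity_sizes, n_reps = config$sensitivity_reps,
      base_seed = config$seed
    ))
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("slrveg")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    rises = config$rises,
    mlw_offset = config$mlw_offset,
    n_reps = config$n_reps,
    step = config$step,
    bandwidths = as.list(matrix$bandwidths),
    gls = list(n = fit$n, correlation = config$gls_correlation),
    n_pixels = nrow(pixels),
    synthetic = !is.null(config$synthetic)
  )
  result <- structure(
    list(
      grid = grid, pixels = pixels, fit = fit, profiles = profiles,
      matrix = matrix, summaries = summaries, percent_change = pct,
      sensitivity = sens, manifest = manifest
    ),
    class = "slr_run"
  )
  if (!is.null(config$out_dir)) {
    stage("write_outputs", write_summary_tables(result, config$out_dir))
  }
  result
}

#' @export
print.slr_run <- function(x, ...) {
  cat("<slr_run> ", nrow(x$pixels), " pixels; scenarios: ",
    paste(names(x$summaries), collapse = ", "), " m\n",
    sep = ""
  )
  invisible(x)
}

#' Percent change in community area across scenarios
#'
#' For each community and scenario, the percent change in pixel count
#' relative to current conditions, computed from the median final
#' total-basis proportion across replicates:
#' `100 * (median final count - initial count) / initial count`. Negative
#' values are losses; within a scenario the changes do not sum to zero
#' because pixels are lost to the absorbing open-water state.
#'
#' @param summaries A list of [replicate_simulations()] results (one per
#'   scenario), or a single one.
#' @return Tibble with `rise`, `community`, `initial`, `percent_change`
#'   (`NA` with a warning where the initial count is zero).
#' @export
percent_change_table <- function(summaries) {
  if (inherits(summaries, "replicate_summary")) summaries <- list(summaries)
  purrr::map_dfr(summaries, function(rs) {
    med <- rs$summary |>
      dplyr::filter(.data$basis == "total", .data$state != ABSORBED_LABEL)
    df <- dplyr::left_join(rs$initial, dplyr::select(med, "state", "median"), by = "state")
    if (any(df$count == 0)) {
      warning("undefined percent change for community with zero initial count")
    }
    tibble::tibble(
      rise = rs$scenario$rise,
      community = df$state,
      initial = df$count,
      percent_change = ifelse(
        df$count > 0,
        100 * (df$median * rs$n - df$count) / df$count,
        NA_real_
      )
    )
  })
}

#' Write the summary CSV bundle for a pipeline run
#'
#' Canonical text outputs: the GLS fit table, density profiles, the
#' proportion matrix, per-scenario contingency matrices (percent-of-total
#' and row-proportion forms), final proportions with replicate intervals on
#' both bases, the percent-change table, the sensitivity summary when
#' present, and the JSON run manifest. Row and column ordering is fixed so
#' identical runs produce byte-identical files.
#'
#' @param run An `slr_run` (from [run_pipeline()]), or a named list of
#'   `replicate_summary` objects.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_summary_tables <- function(run, out_dir) {
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!ok || file.access(out_dir, 2) != 0) {
    stop("I/O error: cannot write to ", out_dir, call. = FALSE)
  }
  if (!inherits(run, "slr_run")) {
    run <- structure(list(summaries = run), class = "slr_run")
  }
  for (nm in names(run$summaries)) {
    rs <- run$summaries[[nm]]
    cont <- rs$contingency_mean
    pct_total <- tibble::as_tibble(100 * cont / rs$n)
    pct_total <- dplyr::bind_cols(tibble::tibble(from = rownames(cont)), pct_total)
    readr::write_csv(pct_total, file.path(out_dir, paste0("contingency_percent_rise_", nm, ".csv")))
    rowprop <- cont / ifelse(rowSums(cont) > 0, rowSums(cont), 1)
    rowprop_df <- dplyr::bind_cols(
      tibble::tibble(from = rownames(cont)),
      tibble::as_tibble(rowprop)
    )
    readr::write_csv(rowprop_df, file.path(out_dir, paste0("contingency_rowprop_rise_", nm, ".csv")))
  }
  intervals <- purrr::map_dfr(run$summaries, tidy)
  readr::write_csv(intervals, file.path(out_dir, "proportions_intervals.csv"))
  if (!is.null(run$percent_change)) {
    readr::write_csv(run$percent_change, file.path(out_dir, "percent_change.csv"))
  }
  if (!is.null(run$fit)) {
    readr::write_csv(tidy(run$fit), file.path(out_dir, "gls_fit.csv"))
    readr::write_csv(glance(run$fit), file.path(out_dir, "gls_glance.csv"))
  }
  if (!is.null(run$profiles)) {
    readr::write_csv(tibble::as_tibble(run$profiles), file.path(out_dir, "density_profiles.csv"))
  }
  if (!is.null(run$matrix)) {
    write_proportion_matrix(run$matrix, file.path(out_dir, "proportion_matrix.csv"))
  }
  if (!is.null(run$sensitivity)) {
    readr::write_csv(run$sensitivity$summary, file.path(out_dir, "subsample_sensitivity.csv"))
  }
  if (!is.null(run$manifest)) {
    jsonlite::write_json(run$manifest, file.path(out_dir, "manifest.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
  }
  invisible(out_dir)
}
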