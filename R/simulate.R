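#' Define a sea-level-rise scenario
#'
#' @param rise Sea-level rise in metres (>= 0). The study scenarios are
#'   0 (no change), 0.2, 0.4 and 1.2 m.
#' @param mlw_offset Depth of mean lagoon water (MLW) below MLHW in metres
#'   (default 0.2); pixels whose shifted elevation falls below `-mlw_offset`
#'   enter the absorbing open-water state.
#' @return An object of class `slr_scenario`.
#' @export
#' @examples
#' slr_scenario(0.4)
slr_scenario <- function(rise = 0, mlw_offset = 0.2) {
  stopifnot(rise >= 0, mlw_offset > 0)
  structure(list(rise = rise, mlw_offset = mlw_offset), class = "slr_scenario")
}

#' @export
print.slr_scenario <- function(x, ...) {
  cat("<slr_scenario> rise ", x$rise, " m, MLW at -", x$mlw_offset, " m MLHW\n", sep = "")
  invisible(x)
}

#' Shift an elevation for a sea-level-rise scenario
#'
#' Sea-level rise lowers every pixel's elevation relative to the moving
#' MLHW datum: a pixel at 1.2 m above MLHW sits at 1.0 m above MLHW after a
#' 0.2 m rise.
#'
#' @param elevation Elevation(s) in metres above current MLHW.
#' @param scenario An [slr_scenario()].
#' @return `elevation - rise`.
#' @export
#' @examples
#' shift_elevation(1.2, slr_scenario(0.2))
shift_elevation <- function(elevation, scenario) {
  stopifnot(inherits(scenario, "slr_scenario"))
  elevation - scenario$rise
}

#' Classify pixels from the proportion matrix
#'
#' The per-pixel stochastic kernel of the model: a pixel below MLW is
#' absorbed into open water deterministically; otherwise its new community
#' is one multinomial draw from the matrix row at its (already shifted)
#' elevation. Consumes exactly one uniform variate per pixel.
#'
#' @param elevation Shifted elevations (m above the post-rise MLHW).
#' @param matrix A [build_proportion_matrix()] result.
#' @param scenario An [slr_scenario()] (only `mlw_offset` is used here).
#' @return Character vector of community codes, with `"ABSORBED"` for
#'   open-water outcomes.
#' @export
classify_pixels <- function(elevation, matrix, scenario = slr_scenario(0)) {
  stopifnot(inherits(matrix, "community_elevation_matrix"))
  if (any(!is.finite(elevation))) stop("domain error: elevation must be finite", call. = FALSE)
  n <- length(elevation)
  comms <- colnames(matrix$proportions)
  out <- rep(ABSORBED_LABEL, n)
  u <- runif(n)
  land <- elevation >= -scenario$mlw_offset
  if (any(land)) {
    idx <- lookup_index(matrix, elevation[land])
    cum <- matrix$proportions %*% upper.tri(diag(ncol(matrix$proportions)), diag = TRUE)
    draws <- rowSums(u[land] > cum[idx, , drop = FALSE]) + 1L
    draws <- pmin(draws, length(comms)) # guard rounding at the top of the CDF
    out[land] <- comms[draws]
  }
  out
}

#' Run one replicate of the community-change simulation
#'
#' Applies [shift_elevation()] then [classify_pixels()] independently to
#' every pixel, and tallies the from-community x to-state contingency
#' matrix, the absorbed count, and final community proportions on two
#' bases: the total input pixel count, and the remaining (non-absorbed)
#' land.
#'
#' Pixels already below MLW at input are excluded (they are open water
#' boundary conditions, not transitions).
#'
#' @param pixels Data frame with `elevation` and `community`.
#' @param matrix A [build_proportion_matrix()] result (always built from
#'   the current, rise-0 landscape).
#' @param scenario An [slr_scenario()].
#' @param seed Integer seed; the replicate is deterministic given it.
#' @return An object of class `simulation_result` with elements
#'   `contingency` (communities x (communities + ABSORBED) counts),
#'   `proportions` (tibble: `state`, `basis`, `proportion`), `absorbed`,
#'   `n`, `seed`, `scenario`.
#' @export
#' @examples
#' px <- sample_pixel_table(2000, synthetic_config(), seed = 11)
#' mat <- build_proportion_matrix(px, step = 0.01)
#' run_simulation(px, mat, slr_scenario(0.4), seed = 1)
run_simulation <- function(pixels, matrix, scenario = slr_scenario(0), seed = 1L) {
  stopifnot(
    is.data.frame(pixels),
    all(c("elevation", "community") %in% names(pixels)),
    inherits(matrix, "community_elevation_matrix"),
    inherits(scenario, "slr_scenario")
  )
  pixels <- pixels[pixels$elevation >= -scenario$mlw_offset, ]
  if (nrow(pixels) == 0) stop("input error: no pixels above MLW", call. = FALSE)
  comms <- colnames(matrix$proportions)
  states <- c(comms, ABSORBED_LABEL)
  from <- factor(pixels$community, levels = comms)
  if (anyNA(from)) stop("input error: pixel community absent from matrix", call. = FALSE)

  set.seed(seed)
  to <- classify_pixels(shift_elevation(pixels$elevation, scenario), matrix, scenario)
  to_f <- factor(to, levels = states)

  n <- nrow(pixels)
  k <- length(comms)
  counts <- tabulate((as.integer(from) - 1L) * (k + 1L) + as.integer(to_f), nbins = k * (k + 1L))
  contingency <- matrix(counts, nrow = k, ncol = k + 1L, byrow = TRUE,
    dimnames = list(from = comms, to = states)
  )
  to_counts <- colSums(contingency)
  absorbed <- to_counts[[ABSORBED_LABEL]]
  remaining <- n - absorbed
  proportions <- dplyr::bind_rows(
    tibble::tibble(state = states, basis = "total", proportion = as.numeric(to_counts) / n),
    tibble::tibble(
      state = comms, basis = "remaining",
      proportion = if (remaining > 0) as.numeric(to_counts[comms]) / remaining else rep(NA_real_, k)
    )
  )
  structure(
    list(
      contingency = contingency, proportions = proportions,
      absorbed = absorbed, n = n, seed = seed, scenario = scenario
    ),
    class = "simulation_result"
  )
}

#' @export
print.simulation_result <- function(x, ...) {
  cat(
    "<simulation_result> rise ", x$scenario$rise, " m: ", x$n, " pixels, ",
    x$absorbed, " absorbed (", round(100 * x$absorbed / x$n, 1), "%)\n",
    sep = ""
  )
  invisible(x)
}

#' Tidy a simulation result
#'
#' @param x A `simulation_result`.
#' @param ... Unused.
#' @return Tibble of final proportions per state and basis.
#' @method tidy simulation_result
#' @export
tidy.simulation_result <- function(x, ...) {
  dplyr::mutate(x$proportions, rise = x$scenario$rise, .before = 1)
}

#' Replicate the simulation and summarise uncertainty
#'
#' Runs `n_reps` independent replicates (replicate `r` is seeded with
#' `base_seed + r`) and reports per community and basis the median and the
#' central 95% interval (2.5th / 97.5th percentiles) of final proportions.
#'
#' @param pixels,matrix,scenario As in [run_simulation()].
#' @param n_reps Number of replicates (study default 1000).
#' @param base_seed Integer base seed.
#' @return An object of class `replicate_summary`: `summary` (tibble with
#'   `state`, `basis`, `median`, `lower`, `upper`), `replicates` (long
#'   tibble of all replicate proportions), `initial` (tibble of input
#'   counts/proportions per community), `contingency_mean` (mean
#'   contingency counts), `absorbed`, `n`, `n_reps`, `scenario`,
#'   `base_seed`.
#' @export
replicate_simulations <- function(pixels, matrix, scenario = slr_scenario(0),
                                  n_reps = 1000, base_seed = 1L) {
  stopifnot(n_reps >= 1)
  pixels <- pixels[pixels$elevation >= -scenario$mlw_offset, ]
  if (nrow(pixels) == 0) stop("input error: no pixels above MLW", call. = FALSE)
  comms <- colnames(matrix$proportions)
  runs <- purrr::map(seq_len(n_reps), function(r) {
    run_simulation(pixels, matrix, scenario, seed = base_seed + r)
  })
  reps <- purrr::map_dfr(seq_along(runs), function(r) {
    dplyr::mutate(runs[[r]]$proportions, replicate = r, .before = 1)
  })
  summary <- reps |>
    dplyr::group_by(.data$state, .data$basis) |>
    dplyr::summarise(
      median = median(.data$proportion),
      lower = quantile(.data$proportion, 0.025, names = FALSE),
      upper = quantile(.data$proportion, 0.975, names = FALSE),
      .groups = "drop"
    ) |>
    dplyr::arrange(
      factor(.data$basis, levels = c("total", "remaining")),
      factor(.data$state, levels = c(comms, ABSORBED_LABEL))
    )
  cont <- Reduce(`+`, purrr::map(runs, "contingency")) / n_reps
  init_counts <- table(factor(pixels$community, levels = comms))
  structure(
    list(
      summary = summary, replicates = reps,
      initial = tibble::tibble(
        state = comms,
        count = as.integer(init_counts),
        proportion = as.numeric(init_counts) / nrow(pixels)
      ),
      contingency_mean = cont,
      absorbed = runs[[1]]$absorbed,
      n = nrow(pixels), n_reps = n_reps,
      scenario = scenario, base_seed = base_seed
    ),
    class = "replicate_summary"
  )
}

#' @export
print.replicate_summary <- function(x, ...) {
  cat(
    "<replicate_summary> rise ", x$scenario$rise, " m, ", x$n_reps,
    " replicates of ", x$n, " pixels; absorbed fraction ",
    round(x$absorbed / x$n, 3), "\n",
    sep = ""
  )
  print(x$summary, n = Inf)
  invisible(x)
}

#' Tidy a replicate summary
#'
#' @param x A `replicate_summary`.
#' @param ... Unused.
#' @return The summary tibble with the scenario rise and the initial
#'   (observed) proportion joined in.
#' @method tidy replicate_summary
#' @export
tidy.replicate_summary <- function(x, ...) {
  x$summary |>
    dplyr::left_join(
      dplyr::select(x$initial, state = "state", initial = "proportion"),
      by = "state"
    ) |>
    dplyr::mutate(rise = x$scenario$rise, .before = 1)
}

#' Plot predicted community proportions with replicate intervals
#'
#' The model-validation picture: observed (current) proportions as points
#' against the predicted median and central 95% interval per community.
#'
#' @param object A `replicate_summary`.
#' @param basis `"remaining"` (default; absorbed pixels excluded) or
#'   `"total"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot replicate_summary
#' @export
autoplot.replicate_summary <- function(object, basis = "remaining", ...) {
  df <- tidy(object) |> dplyr::filter(.data$basis == !!basis, .data$state != ABSORBED_LABEL)
  df$state <- factor(df$state, levels = ccbic_communities())
  ggplot2::ggplot(df, ggplot2::aes(.data$state)) +
    ggplot2::geom_pointrange(
      ggplot2::aes(y = .data$median, ymin = .data$lower, ymax = .data$upper),
      colour = "firebrick"
    ) +
    ggplot2::geom_point(ggplot2::aes(y = .data$initial), shape = 16, size = 2) +
    ggplot2::labs(
      x = "Community", y = paste0("Proportion (", basis, " basis)"),
      title = paste0("Predicted community proportions, rise ", object$scenario$rise, " m"),
      subtitle = "Black: current proportion; red: median and central 95% of replicates"
    ) +
    ggplot2::theme_minimal()
}

#' Sensitivity of prediction intervals to subsample size
#'
#' Repeats the replicate simulation on random pixel subsets of decreasing
#' size to characterise how prediction-interval width grows as data shrink.
#' The proportion matrix is held fixed (it is a property of the full
#' landscape); each size draws a fresh subsample without replacement.
#' Sizes exceeding the pixel count are skipped with a warning; a size equal
#' to the pixel count uses the pixels as-is.
#'
#' @param pixels,matrix As in [run_simulation()].
#' @param scenarios List of [slr_scenario()]s.
#' @param sizes Subsample sizes (study default `c(1e6, 1e5, 1e4, 500, 250)`).
#' @param n_reps Replicates per size and scenario (study default 500).
#' @param base_seed Integer base seed.
#' @return An object of class `subsample_sensitivity`: tibble `summary`
#'   with `size`, `rise`, `state`, `basis`, `median`, `lower`, `upper`,
#'   `width`, plus the call parameters.
#' @export
subsample_sensitivity <- function(pixels, matrix,
                                  scenarios = list(slr_scenario(0)),
                                  sizes = c(1e6, 1e5, 1e4, 500, 250),
                                  n_reps = 500, base_seed = 1L) {
  stopifnot(is.data.frame(pixels), n_reps >= 1)
  if (inherits(scenarios, "slr_scenario")) scenarios <- list(scenarios)
  n <- nrow(pixels)
  usable <- sizes[sizes <= n]
  if (length(usable) < length(sizes)) {
    warning(
      "skipping subsample size(s) exceeding pixel count: ",
      paste(format(sizes[sizes > n], scientific = FALSE), collapse = ", ")
    )
  }
  out <- purrr::map_dfr(seq_along(usable), function(i) {
    size <- usable[i]
    if (size < n) {
      set.seed(base_seed + 1000L * i)
      sub <- pixels[sample.int(n, size), ]
    } else {
      sub <- pixels
    }
    purrr::map_dfr(scenarios, function(sc) {
      rs <- replicate_simulations(sub, matrix, sc, n_reps = n_reps, base_seed = base_seed)
      dplyr::mutate(rs$summary, size = size, rise = sc$rise, .before = 1)
    })
  })
  out$width <- out$upper - out$lower
  structure(
    list(summary = out, sizes = usable, n_reps = n_reps, base_seed = base_seed),
    class = "subsample_sensitivity"
  )
}

#' @export
print.subsample_sensitivity <- function(x, ...) {
  cat(
    "<subsample_sensitivity> sizes ",
    paste(format(x$sizes, scientific = FALSE), collapse = ", "),
    "; ", x$n_reps, " replicates each\n",
    sep = ""
  )
  invisible(x)
}

#' Tidy a subsample sensitivity analysis
#'
#' @param x A `subsample_sensitivity`.
#' @param ... Unused.
#' @return The long summary tibble.
#' @method tidy subsample_sensitivity
#' @export
tidy.subsample_sensitivity <- function(x, ...) x$summary

#' Plot interval width against subsample size
#'
#' @param object A `subsample_sensitivity`.
#' @param basis Proportion basis to display.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot subsample_sensitivity
#' @export
autoplot.subsample_sensitivity <- function(object, basis = "total", ...) {
  df <- dplyr::filter(object$summary, .data$basis == !!basis, .data$state != ABSORBED_LABEL)
  ggplot2::ggplot(df, ggplot2::aes(.data$size, .data$width, colour = .data$state)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::facet_wrap(~rise, labeller = ggplot2::label_both) +
    ggplot2::labs(
      x = "Subsample size (pixels)", y = "95% interval width",
      colour = "Community",
      title = "Prediction-interval width versus subsample size"
    ) +
    ggplot2::theme_minimal()
}
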