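#' Build the community-elevation proportion matrix
#'
#' The core lookup table of the transition model: at each discretised
#' elevation step `e`, the probability of each community,
#' `p(c | e) = n_c * fhat_c(e) / sum_j n_j * fhat_j(e)`, where `fhat_c` is
#' community `c`'s Gaussian kernel density estimate of elevation and `n_c`
#' its pixel count (the empirical-Bayes prior: abundant communities carry
#' proportionally more probability at a shared elevation). Steps span
#' `[min elevation - 3 max(bw), max elevation + 3 max(bw)]` snapped to the
#' step grid; steps where every density underflows are filled from the
#' nearest step with support.
#'
#' @param pixels Data frame with `elevation` and `community`.
#' @param step Elevation step size in metres (default 0.001, small enough
#'   that discretisation anomalies vanish).
#' @param bw Bandwidth specification as in [elevation_density_profiles()].
#' @return An object of class `community_elevation_matrix`: list with
#'   `steps` (elevation grid), `proportions` (steps x communities matrix),
#'   `counts`, `bandwidths`, `step`.
#' @export
#' @examples
#' px <- sample_pixel_table(1000, synthetic_config(), seed = 5)
#' mat <- build_proportion_matrix(px, step = 0.01)
#' mat
build_proportion_matrix <- function(pixels, step = 0.001, bw = NULL) {
  stopifnot(is.data.frame(pixels), all(c("elevation", "community") %in% names(pixels)))
  if (step <= 0) stop("step must be > 0", call. = FALSE)
  pixels <- pixels[is.finite(pixels$elevation), ]
  if (nrow(pixels) < 2) stop("input error: need at least 2 pixels", call. = FALSE)
  comms <- intersect(ccbic_communities(), unique(pixels$community))
  if (length(comms) == 0) comms <- sort(unique(pixels$community))
  counts <- table(factor(pixels$community, levels = comms))
  comms <- names(counts)[counts >= 2]
  if (length(comms) == 0) stop("input error: no community has >= 2 pixels", call. = FALSE)
  counts <- as.integer(counts[comms])
  bws <- resolve_bandwidths(pixels, comms, bw)

  lo <- min(pixels$elevation) - 3 * max(bws)
  hi <- max(pixels$elevation) + 3 * max(bws)
  e0 <- floor(lo / step) * step
  n_steps <- ceiling((hi - e0) / step) + 1
  steps <- e0 + (seq_len(n_steps) - 1) * step

  weighted <- vapply(seq_along(comms), function(i) {
    x <- pixels$elevation[pixels$community == comms[i]]
    counts[i] * .kde_gauss_grid(x, steps, bws[[comms[i]]])
  }, numeric(length(steps)))
  weighted <- matrix(weighted, nrow = length(steps), dimnames = list(NULL, comms))

  total <- rowSums(weighted)
  has_support <- total > 0
  prop <- weighted / ifelse(has_support, total, 1)
  if (!all(has_support)) {
    # fill underflow rows from the nearest step with support
    src <- which(has_support)
    for (j in which(!has_support)) {
      prop[j, ] <- prop[src[which.min(abs(src - j))], ]
    }
  }

  structure(
    list(
      steps = steps, proportions = prop,
      counts = setNames(counts, comms),
      bandwidths = bws, step = step
    ),
    class = "community_elevation_matrix"
  )
}

#' @export
print.community_elevation_matrix <- function(x, ...) {
  cat(
    "<community_elevation_matrix> ", length(x$steps), " steps of ", x$step,
    " m over [", format(min(x$steps), digits = 4), ", ",
    format(max(x$steps), digits = 4), "] m MLHW, ",
    ncol(x$proportions), " communities\n",
    sep = ""
  )
  invisible(x)
}

# Snap elevations to step indices: nearest step, ties toward +Inf, clamped
# to the matrix range.
lookup_index <- function(matrix, elevation) {
  if (any(is.nan(elevation))) stop("domain error: NaN elevation", call. = FALSE)
  idx <- floor((elevation - matrix$steps[1]) / matrix$step + 0.5) + 1
  pmin(pmax(idx, 1), length(matrix$steps))
}

#' Look up the community proportions at an elevation
#'
#' Snaps the elevation to the nearest step (ties toward the higher step);
#' elevations beyond the matrix range return the boundary row.
#'
#' @param matrix A [build_proportion_matrix()] result.
#' @param elevation Elevation(s) in metres above MLHW.
#' @return For a single elevation, a named vector of community proportions;
#'   for several, a matrix with one row per elevation.
#' @export
lookup_row <- function(matrix, elevation) {
  stopifnot(inherits(matrix, "community_elevation_matrix"))
  if (any(!is.finite(elevation) & !is.na(elevation)) || any(is.na(elevation))) {
    stop("domain error: elevation must be finite", call. = FALSE)
  }
  rows <- matrix$proportions[lookup_index(matrix, elevation), , drop = FALSE]
  if (length(elevation) == 1) rows[1, ] else rows
}

#' Tidy the community-elevation proportion matrix
#'
#' @param x A `community_elevation_matrix`.
#' @param ... Unused.
#' @return Long tibble with `elevation`, `community`, `proportion`.
#' @method tidy community_elevation_matrix
#' @export
tidy.community_elevation_matrix <- function(x, ...) {
  tibble::tibble(
    elevation = rep(x$steps, times = ncol(x$proportions)),
    community = rep(colnames(x$proportions), each = length(x$steps)),
    proportion = as.numeric(x$proportions)
  )
}

#' Plot the community-elevation proportion matrix
#'
#' @param object A `community_elevation_matrix`.
#' @param ... Unused.
#' @return A ggplot: stacked community proportions along the elevation axis.
#' @method autoplot community_elevation_matrix
#' @export
autoplot.community_elevation_matrix <- function(object, ...) {
  df <- tidy(object)
  df$community <- factor(df$community, levels = colnames(object$proportions))
  ggplot2::ggplot(df, ggplot2::aes(.data$elevation, .data$proportion, fill = .data$community)) +
    ggplot2::geom_area(position = "stack") +
    ggplot2::labs(
      x = "Elevation (m above MLHW)", y = "Proportion",
      fill = "Community",
      title = "Community-elevation proportion matrix"
    ) +
    ggplot2::theme_minimal()
}

#' Write the proportion matrix to CSV
#'
#' @param matrix A `community_elevation_matrix`.
#' @param path Output CSV path (steps in rows, communities in columns).
#' @return `path`, invisibly.
#' @export
write_proportion_matrix <- function(matrix, path) {
  df <- tibble::as_tibble(matrix$proportions)
  df <- dplyr::bind_cols(tibble::tibble(elevation = matrix$steps), df)
  readr::write_csv(df, path)
  invisible(path)
}
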