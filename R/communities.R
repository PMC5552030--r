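#' Canonical vegetation community codes
#'
#' The nine natural communities of the barrier-island elevation gradient, in
#' fixed hydric-to-xeric display order, plus the sentinel codes used in land
#' cover rasters.
#'
#' @return Character vector of the nine community codes.
#' @export
#' @examples
#' ccbic_communities()
ccbic_communities <- function() {
  c("SMAR", "WETS", "MANG", "PALM", "FWET", "HAMM", "PINE", "FRST", "SCRB")
}

# sentinel land-cover codes (integer raster values)
WATER_CODE <- 0L
ABSORBED_LABEL <- "ABSORBED"

#' Default community-elevation parameters
#'
#' Per-community elevation distribution parameters used by the synthetic
#' landscape generator: marginal mean and standard deviation of elevation
#' (metres above mean lagoon high water, MLHW), landscape weight
#' (proportion of land pixels), and an optional second elevation mode.
#'
#' The means and SDs follow the stratified GLS estimates for the nine
#' communities of the Cape Canaveral barrier island complex; weights follow
#' the observed landscape composition, normalised to sum to one. Salt marsh
#' (SMAR) and freshwater wetland (FWET) default to dual-peaked elevation
#' distributions — an equal-weight two-component normal mixture with modes at
#' `mean - delta` and `mean + delta` and within-mode SD
#' `sqrt(sd^2 - delta^2)`, so the marginal mean and SD are preserved. The
#' mode separations themselves are not estimated from data (field surveys
#' attribute the dual peaks to marsh zonation or perched wetlands without
#' quantifying them) and are chosen only to make the bimodality visible.
#'
#' @param bimodal Logical; if `FALSE` the second modes are disabled and all
#'   communities are single Gaussians with the marginal mean/SD.
#' @return A tibble with columns `community`, `label`, `mean`, `sd`,
#'   `weight`, `bimodal`, `delta`.
#' @export
#' @examples
#' community_defaults()
community_defaults <- function(bimodal = TRUE) {
  out <- tibble::tibble(
    community = ccbic_communities(),
    label = c(
      "Saltwater Marsh", "Wet Scrub-Shrub", "Mangrove", "Cabbage Palm",
      "Freshwater Wetland", "Hardwood Hammock", "Pine Flatwoods",
      "Upland Forest", "Oak Scrub"
    ),
    mean = c(0.14, 0.34, 0.32, 0.78, 0.77, 0.88, 1.09, 1.83, 1.96),
    sd = c(0.55, 0.87, 1.00, 1.26, 1.07, 1.40, 1.00, 1.80, 1.65),
    weight = c(15.48, 4.49, 5.60, 5.30, 14.02, 16.31, 14.38, 6.54, 17.89),
    bimodal = bimodal & c(TRUE, FALSE, FALSE, FALSE, TRUE, FALSE, FALSE, FALSE, FALSE),
    delta = c(0.45, 0, 0, 0, 0.90, 0, 0, 0, 0)
  )
  out$delta[!out$bimodal] <- 0
  out$weight <- out$weight / sum(out$weight)
  out
}

# Validate a community parameter table (communities, means, sds, weights,
# optional second mode); used by synthetic_config() and samplers.
validate_community_params <- function(params) {
  stopifnot(is.data.frame(params))
  needed <- c("community", "mean", "sd", "weight")
  missing <- setdiff(needed, names(params))
  if (length(missing) > 0) {
    stop("community parameter table lacks columns: ", paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  if (!("bimodal" %in% names(params))) params$bimodal <- FALSE
  if (!("delta" %in% names(params))) params$delta <- 0
  if (anyDuplicated(params$community)) stop("duplicated community codes", call. = FALSE)
  if (any(params$sd <= 0)) stop("community SDs must be > 0", call. = FALSE)
  if (any(params$weight < 0)) stop("community weights must be >= 0", call. = FALSE)
  if (sum(params$weight) <= 0) stop("all community weights are zero", call. = FALSE)
  if (abs(sum(params$weight) - 1) > 1e-8) {
    params$weight <- params$weight / sum(params$weight)
  }
  if (any(params$bimodal & params$delta >= params$sd)) {
    stop("mode half-separation `delta` must be < marginal `sd`", call. = FALSE)
  }
  params
}

# Per-community elevation density (exact normal / two-mode mixture),
# vectorised over e for a single community row.
community_density <- function(e, mean, sd, bimodal = FALSE, delta = 0) {
  if (!bimodal || delta <= 0) {
    return(dnorm(e, mean, sd))
  }
  s <- sqrt(sd^2 - delta^2)
  0.5 * dnorm(e, mean - delta, s) + 0.5 * dnorm(e, mean + delta, s)
}

# Matrix of elevation-conditioned posteriors p(c | e) proportional to
# weight_c * density_c(e); rows = elevations, cols = communities.
community_posterior <- function(e, params) {
  dens <- vapply(
    seq_len(nrow(params)),
    function(i) {
      params$weight[i] * community_density(
        e, params$mean[i], params$sd[i], params$bimodal[i], params$delta[i]
      )
    },
    numeric(length(e))
  )
  dens <- matrix(dens, nrow = length(e), dimnames = list(NULL, params$community))
  dens / rowSums(dens)
}
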