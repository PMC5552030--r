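#' Configuration for the synthetic landscape generator
#'
#' Describes the statistical structure of a synthetic barrier-island
#' landscape: per-community elevation distributions (see
#' [community_defaults()]), landscape composition, grid shape, and the
#' spatial texture of the terrain (smoothing, a gentle cross-shore slope and
#' low dune ridges emulating ridge/swale topography).
#'
#' @param communities Community parameter table; defaults to
#'   [community_defaults()]. Weights must be non-negative; they are
#'   normalised to sum to 1.
#' @param rows,cols Grid shape (cells).
#' @param cell_size Cell edge in metres.
#' @param smooth Moving-average smoothing length in cells for the latent
#'   terrain field; `1` disables smoothing.
#' @param trend Relative strength of the cross-shore (west-to-east) slope in
#'   the latent field (0 disables).
#' @param ridge_amp,ridge_period Relative amplitude and period (metres) of
#'   the sinusoidal dune-ridge component (amplitude 0 disables).
#' @param sea_floor_frac Proportion of cells drawn from the sub-MLW
#'   (open-water) elevation tail.
#' @param mlw_offset Depth of mean lagoon water below MLHW (m); cells below
#'   `-mlw_offset` become open water.
#' @param seed Integer seed; the generator is deterministic given the seed.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(communities = community_defaults(),
                             rows = 200, cols = 200, cell_size = 3,
                             smooth = 8, trend = 0.8,
                             ridge_amp = 0.3, ridge_period = 150,
                             sea_floor_frac = 0.1, mlw_offset = 0.2,
                             seed = 1L) {
  communities <- validate_community_params(communities)
  stopifnot(
    rows >= 1, cols >= 1, cell_size > 0, smooth >= 1,
    sea_floor_frac >= 0, sea_floor_frac < 1, mlw_offset > 0
  )
  structure(
    list(
      communities = communities, rows = as.integer(rows), cols = as.integer(cols),
      cell_size = cell_size, smooth = as.integer(smooth), trend = trend,
      ridge_amp = ridge_amp, ridge_period = ridge_period,
      sea_floor_frac = sea_floor_frac, mlw_offset = mlw_offset,
      seed = as.integer(seed)
    ),
    class = "synthetic_config"
  )
}

# circular moving-average smoothing along both axes
smooth_field <- function(m, len) {
  if (len <= 1) {
    return(m)
  }
  k <- rep(1 / len, len)
  m <- apply(m, 2, function(v) as.numeric(stats::filter(v, k, circular = TRUE)))
  t(apply(m, 1, function(v) as.numeric(stats::filter(v, k, circular = TRUE))))
}

standardize <- function(m) {
  s <- sd(as.numeric(m))
  if (s == 0) {
    return(m * 0)
  }
  (m - mean(m)) / s
}

#' Generate a synthetic barrier-island landscape
#'
#' Builds a spatially autocorrelated elevation surface and an
#' elevation-conditioned land-cover raster with the statistical structure
#' the transition model assumes. The latent terrain field (smoothed white
#' noise + cross-shore slope + dune ridges) is rank-mapped onto the target
#' marginal elevation distribution — the community-weighted mixture of
#' per-community normals plus a sub-MLW open-water tail — so the marginal
#' elevations are an exact i.i.d. sample from the target while retaining
#' spatial clumping. Each cell at or above mean lagoon water
#' (`-mlw_offset`) is then assigned a community by one draw from the
#' analytic posterior `p(c | e) proportional to weight_c * density_c(e)`;
#' cells below become open water.
#'
#' @param config A [synthetic_config()].
#' @return A [landscape_grid()] in metres above MLHW (datum offset 0).
#' @export
#' @examples
#' grid <- generate_landscape(synthetic_config(rows = 60, cols = 60, seed = 42))
#' grid
generate_landscape <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  params <- config$communities
  nr <- config$rows
  nc <- config$cols
  n <- nr * nc
  set.seed(config$seed)

  field <- standardize(smooth_field(matrix(rnorm(n), nr, nc), config$smooth))
  if (config$trend > 0) {
    ramp <- matrix(rep(seq(0, 1, length.out = nc), each = nr), nr, nc)
    field <- field + config$trend * standardize(ramp)
  }
  if (config$ridge_amp > 0) {
    xpos <- (col(field) - 0.5) * config$cell_size
    field <- field + config$ridge_amp * standardize(sin(2 * pi * xpos / config$ridge_period))
  }

  # target marginal: sea-floor tail + community normal mixture
  is_sea <- runif(n) < config$sea_floor_frac
  target <- numeric(n)
  n_sea <- sum(is_sea)
  if (n_sea > 0) target[is_sea] <- runif(n_sea, -2, -config$mlw_offset)
  n_land <- n - n_sea
  if (n_land > 0) {
    comp <- sample.int(nrow(params), n_land, replace = TRUE, prob = params$weight)
    mu <- params$mean[comp]
    sig <- params$sd[comp]
    bim <- params$bimodal[comp]
    if (any(bim)) {
      del <- params$delta[comp]
      side <- ifelse(runif(n_land) < 0.5, -1, 1)
      mu <- ifelse(bim, mu + side * del, mu)
      sig <- ifelse(bim, sqrt(sig^2 - del^2), sig)
    }
    target[!is_sea] <- rnorm(n_land, mu, sig)
  }
  elev <- numeric(n)
  elev[order(field)] <- sort(target)
  elev <- matrix(elev, nr, nc)

  # elevation-conditioned community assignment
  comm <- matrix(WATER_CODE, nr, nc)
  land <- elev >= -config$mlw_offset
  if (any(land)) {
    post <- community_posterior(elev[land], params)
    cum <- t(apply(post, 1, cumsum))
    u <- runif(sum(land))
    comm[land] <- rowSums(u > cum) + 1L
  }
  storage.mode(comm) <- "integer"

  landscape_grid(
    elevation = elev, community = comm, classes = params$community,
    cell_size = config$cell_size, datum_offset_mlhw = 0,
    georeference = list(xll = 0, yll = 0, crs = "")
  )
}

#' Sample elevations for one community
#'
#' Draws i.i.d. elevations from a community's configured (possibly
#' two-mode) normal distribution; a unit-scale fixture for the regression
#' and density modules.
#'
#' @param community Community code present in `config`.
#' @param n Number of draws (0 allowed).
#' @param config A [synthetic_config()] (only the community table is used).
#' @param seed Integer seed.
#' @return Numeric vector of `n` elevations (m above MLHW).
#' @export
#' @examples
#' sample_community_elevations("PINE", 5, synthetic_config(), seed = 1)
sample_community_elevations <- function(community, n, config = synthetic_config(),
                                        seed = 1L) {
  params <- if (inherits(config, "synthetic_config")) config$communities else validate_community_params(config)
  i <- match(community, params$community)
  if (is.na(i)) stop("unknown community: ", community, call. = FALSE)
  stopifnot(n >= 0)
  if (n == 0) {
    return(numeric(0))
  }
  set.seed(seed)
  if (params$bimodal[i] && params$delta[i] > 0) {
    s <- sqrt(params$sd[i]^2 - params$delta[i]^2)
    side <- ifelse(runif(n) < 0.5, -1, 1)
    rnorm(n, params$mean[i] + side * params$delta[i], s)
  } else {
    rnorm(n, params$mean[i], params$sd[i])
  }
}

#' Sample a mixed pixel table from the community configuration
#'
#' Draws `n` pixels with communities allocated by the configured landscape
#' weights and elevations i.i.d. from each community's distribution, with
#' uniform random coordinates (no spatial correlation). This is the
#' generating model of the iid stratified regression benchmark.
#'
#' @param n Number of pixels.
#' @param config A [synthetic_config()].
#' @param seed Integer seed.
#' @return A tibble with `x`, `y`, `elevation`, `community`.
#' @export
sample_pixel_table <- function(n, config = synthetic_config(), seed = 1L) {
  stopifnot(inherits(config, "synthetic_config"), n >= 1)
  params <- config$communities
  set.seed(seed)
  comp <- sample.int(nrow(params), n, replace = TRUE, prob = params$weight)
  mu <- params$mean[comp]
  sig <- params$sd[comp]
  bim <- params$bimodal[comp]
  del <- params$delta[comp]
  side <- ifelse(runif(n) < 0.5, -1, 1)
  mu <- ifelse(bim & del > 0, mu + side * del, mu)
  sig <- ifelse(bim & del > 0, sqrt(sig^2 - del^2), sig)
  extent <- sqrt(n) * config$cell_size
  tibble::tibble(
    x = runif(n, 0, extent),
    y = runif(n, 0, extent),
    elevation = rnorm(n, mu, sig),
    community = params$community[comp]
  )
}
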