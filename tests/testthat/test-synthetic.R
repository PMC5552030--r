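test_that("single-community configuration labels all land cells alike", {
  cfg <- one_community_config(
    mean = 1.0, sd = 0.01,
    rows = 50, cols = 50, sea_floor_frac = 0, seed = 2
  )
  grid <- generate_landscape(cfg)
  expect_true(all(grid$community == 1L))
  px <- to_pixel_table(grid)
  expect_equal(nrow(px), 2500)
  expect_lt(abs(mean(px$elevation) - 1.0), 0.005)
  expect_lt(abs(sd(px$elevation) - 0.01), 0.002)
})

test_that("degenerate configurations are rejected", {
  expect_error(
    synthetic_config(communities = dplyr::mutate(community_defaults(), weight = 0)),
    "weights"
  )
  expect_error(
    synthetic_config(communities = dplyr::mutate(community_defaults(), sd = 0)),
    "SD"
  )
})

test_that("identical seeds reproduce identical landscapes", {
  cfg <- synthetic_config(rows = 40, cols = 40, seed = 77)
  g1 <- generate_landscape(cfg)
  g2 <- generate_landscape(cfg)
  expect_identical(g1$elevation, g2$elevation)
  expect_identical(g1$community, g2$community)
  g3 <- generate_landscape(synthetic_config(rows = 40, cols = 40, seed = 78))
  expect_false(identical(g1$elevation, g3$elevation))
})

test_that("per-community landscape elevations match the assignment distribution", {
  # On land (e >= -0.2 m) communities are assigned from p(c|e), so elevations
  # within community c follow f_c truncated at -0.2 m; compare sample means
  # against the analytic truncated means by numerical integration.
  grid <- generate_landscape(synthetic_config(rows = 220, cols = 220, seed = 8))
  px <- to_pixel_table(grid)
  params <- community_defaults()
  for (i in seq_len(nrow(params))) {
    row <- params[i, ]
    e_c <- px$elevation[px$community == row$community]
    expect_gt(length(e_c), 200)
    expect_equal(
      mean(e_c),
      truncated_mean(row, -0.2),
      tolerance = 4 * sd(e_c) / sqrt(length(e_c)) + 0.01,
      label = paste("mean elevation of", row$community)
    )
  }
  # the highest community sits near its configured (barely truncated) mean
  scrb <- px$elevation[px$community == "SCRB"]
  expect_equal(mean(scrb), truncated_mean(params[params$community == "SCRB", ], -0.2),
    tolerance = 0.05
  )
})

test_that("community frequencies follow the truncation-adjusted weights", {
  grid <- generate_landscape(synthetic_config(rows = 220, cols = 220, seed = 15))
  px <- to_pixel_table(grid)
  params <- community_defaults()
  adj <- vapply(
    seq_len(nrow(params)),
    function(i) params$weight[i] * mass_above(params[i, ], -0.2),
    numeric(1)
  )
  adj <- adj / sum(adj)
  freq <- as.numeric(table(factor(px$community, levels = params$community))) / nrow(px)
  expect_equal(freq, adj, tolerance = 0.012)
})

test_that("empirical assignment matches the analytic posterior at a fixed elevation", {
  grid <- generate_landscape(synthetic_config(rows = 350, cols = 350, seed = 21))
  px <- to_pixel_table(grid)
  e_star <- 0.5
  window <- abs(px$elevation - e_star) <= 0.01
  expect_gt(sum(window), 400)
  obs <- as.numeric(
    table(factor(px$community[window], levels = community_defaults()$community))
  ) / sum(window)
  post <- community_posterior(e_star, community_defaults())[1, ]
  se <- sqrt(post * (1 - post) / sum(window))
  expect_true(all(abs(obs - post) < 4 * se + 0.012))
})

test_that("smoothing induces positive neighbour correlation, none without it", {
  neigh_cor <- function(m) stats::cor(as.numeric(m[, -1]), as.numeric(m[, -ncol(m)]))
  base <- list(rows = 100, cols = 100, trend = 0, ridge_amp = 0, seed = 31)
  smooth_grid <- generate_landscape(do.call(synthetic_config, c(base, smooth = 6)))
  rough_grid <- generate_landscape(do.call(synthetic_config, c(base, smooth = 1)))
  expect_gt(neigh_cor(smooth_grid$elevation), 0.3)
  expect_lt(abs(neigh_cor(rough_grid$elevation)), 0.03)
})

test_that("community elevation sampler honours size, seed and moments", {
  cfg <- synthetic_config()
  expect_length(sample_community_elevations("PINE", 0, cfg), 0)
  expect_error(sample_community_elevations("XXXX", 10, cfg), "unknown")
  s1 <- sample_community_elevations("HAMM", 50, cfg, seed = 4)
  s2 <- sample_community_elevations("HAMM", 50, cfg, seed = 4)
  expect_identical(s1, s2)
  # PINE: SD within 2% of 1.00 m at n = 1e5
  pine <- sample_community_elevations("PINE", 1e5, cfg, seed = 6)
  expect_equal(sd(pine), 1.00, tolerance = 0.02)
  expect_equal(mean(pine), 1.09, tolerance = 0.02)
})

test_that("dual-mode salt marsh sample shows two density peaks at the set modes", {
  cfg <- synthetic_config()
  smar <- sample_community_elevations("SMAR", 1e5, cfg, seed = 9)
  # marginal moments preserved by the mixture parameterisation
  expect_equal(mean(smar), 0.14, tolerance = 0.01)
  expect_equal(sd(smar), 0.55, tolerance = 0.01)
  prof <- elevation_density_profiles(
    tibble::tibble(elevation = smar, community = "SMAR"),
    n_grid = 400
  )
  d <- prof$density
  local_max <- which(d > dplyr::lag(d, default = 0) & d > dplyr::lead(d, default = 0))
  peaks <- prof$elevation[local_max][d[local_max] > 0.1 * max(d)]
  expect_gte(length(peaks), 2)
  expect_lt(min(abs(peaks - (0.14 - 0.45))), 0.1)
  expect_lt(min(abs(peaks - (0.14 + 0.45))), 0.1)
})

test_that("mixed pixel sampler allocates communities by weight", {
  px <- sample_pixel_table(20000, synthetic_config(), seed = 12)
  w <- community_defaults()$weight
  freq <- as.numeric(table(factor(px$community, levels = community_defaults()$community))) / nrow(px)
  expect_equal(freq, w, tolerance = 0.012)
  # per-community means are the untruncated configured means
  means <- tapply(px$elevation, px$community, mean)
  expect_equal(
    as.numeric(means[community_defaults()$community]),
    community_defaults()$mean,
    tolerance = 0.12
  )
})
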