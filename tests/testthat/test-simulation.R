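test_that("sea-level rise shifts relative elevation by exactly the rise", {
  expect_equal(shift_elevation(1.2, slr_scenario(0.2)), 1.0)
  expect_equal(shift_elevation(2.7, slr_scenario(0)), 2.7)
  expect_equal(shift_elevation(0.1, slr_scenario(1.2)), -1.1)
  expect_error(slr_scenario(-0.1))
  expect_error(slr_scenario(0.2, mlw_offset = 0))
})

test_that("pixels below mean lagoon water are absorbed deterministically", {
  px <- two_community_pixels(500, seed = 1)
  mat <- build_proportion_matrix(px, step = 0.01)
  set.seed(1)
  out <- classify_pixels(c(-0.25, -0.2000001, -0.2, 0.5), mat, slr_scenario(0.2))
  expect_identical(out[1:2], c("ABSORBED", "ABSORBED"))
  expect_false(any(out[3:4] == "ABSORBED"))
})

test_that("a degenerate one-community matrix classifies with certainty", {
  set.seed(2)
  px <- tibble::tibble(elevation = rnorm(100, 1, 0.2), community = "HAMM")
  mat <- build_proportion_matrix(px, step = 0.01)
  set.seed(3)
  expect_true(all(classify_pixels(rep(1, 50), mat) == "HAMM"))
})

test_that("classification frequencies match the matrix row", {
  px <- sample_pixel_table(5000, synthetic_config(), seed = 3)
  mat <- build_proportion_matrix(px, step = 0.005)
  e_star <- 0.8
  n_draw <- 2e4
  set.seed(11)
  draws <- classify_pixels(rep(e_star, n_draw), mat)
  p <- lookup_row(mat, e_star)
  freq <- as.numeric(table(factor(draws, levels = names(p)))) / n_draw
  se <- sqrt(p * (1 - p) / n_draw)
  expect_true(all(abs(freq - p) <= 4 * se + 1e-12))
})

test_that("one replicate reproduces an explicit per-pixel hand trace", {
  pool <- sample_pixel_table(2000, synthetic_config(), seed = 17)
  mat <- build_proportion_matrix(pool, step = 0.01)
  px <- pool[1:20, ]
  sc <- slr_scenario(0.4)
  res <- run_simulation(px, mat, sc, seed = 23)

  kept <- px[px$elevation >= -sc$mlw_offset, ]
  set.seed(23)
  u <- runif(nrow(kept))
  traced <- character(nrow(kept))
  for (i in seq_len(nrow(kept))) {
    e_new <- kept$elevation[i] - sc$rise
    if (e_new < -sc$mlw_offset) {
      traced[i] <- "ABSORBED"
    } else {
      row <- lookup_row(mat, e_new)
      traced[i] <- names(row)[which(u[i] <= cumsum(row))[1]]
    }
  }
  traced_counts <- table(
    factor(kept$community, levels = rownames(res$contingency)),
    factor(traced, levels = colnames(res$contingency))
  )
  expect_equal(unclass(res$contingency), unclass(traced_counts), ignore_attr = TRUE)
})

test_that("contingency counts are conserved and proportions normalised", {
  grid <- small_landscape(rows = 80, cols = 80, seed = 29)
  px <- to_pixel_table(grid)
  mat <- build_proportion_matrix(px, step = 0.005)
  for (rise in c(0, 0.4, 1.2)) {
    for (s in 1:3) {
      res <- run_simulation(px, mat, slr_scenario(rise), seed = 100 + s)
      expect_equal(sum(res$contingency), res$n)
      tot <- res$proportions[res$proportions$basis == "total", ]
      expect_equal(sum(tot$proportion), 1, tolerance = 1e-12)
      rem <- res$proportions[res$proportions$basis == "remaining", ]
      if (res$absorbed < res$n) expect_equal(sum(rem$proportion), 1, tolerance = 1e-12)
    }
  }
})

test_that("absorption is deterministic per scenario and monotone in rise", {
  grid <- small_landscape(rows = 80, cols = 80, seed = 31)
  px <- to_pixel_table(grid)
  mat <- build_proportion_matrix(px, step = 0.005)
  absorbed <- vapply(c(0, 0.2, 0.4, 1.2), function(rise) {
    a <- vapply(1:4, function(s) {
      run_simulation(px, mat, slr_scenario(rise), seed = s)$absorbed
    }, numeric(1))
    expect_length(unique(a), 1)
    a[1]
  }, numeric(1))
  expect_true(all(diff(absorbed) >= 0))
})

test_that("total inundation absorbs every pixel", {
  px <- two_community_pixels(200, seed = 5)
  mat <- build_proportion_matrix(px, step = 0.01)
  res <- run_simulation(px, mat, slr_scenario(50), seed = 1)
  expect_equal(res$absorbed, res$n)
  tot <- res$proportions[res$proportions$basis == "total" & res$proportions$state != "ABSORBED", ]
  expect_true(all(tot$proportion == 0))
})

test_that("replicate summaries collapse correctly for a single replicate", {
  px <- sample_pixel_table(500, synthetic_config(), seed = 41)
  mat <- build_proportion_matrix(px, step = 0.01)
  rs <- replicate_simulations(px, mat, slr_scenario(0.2), n_reps = 1, base_seed = 7)
  one <- run_simulation(px, mat, slr_scenario(0.2), seed = 8) # base_seed + 1
  merged <- dplyr::inner_join(
    rs$summary, one$proportions,
    by = c("state", "basis")
  )
  expect_equal(merged$median, merged$proportion)
  expect_equal(merged$lower, merged$upper)
})

test_that("replicate percentiles match a direct sort-based computation", {
  px <- sample_pixel_table(800, synthetic_config(), seed = 43)
  mat <- build_proportion_matrix(px, step = 0.01)
  rs <- replicate_simulations(px, mat, slr_scenario(0.4), n_reps = 40, base_seed = 19)
  vals <- rs$replicates$proportion[
    rs$replicates$state == "SMAR" & rs$replicates$basis == "total"
  ]
  sorted <- sort(vals)
  expect_equal(
    rs$summary$median[rs$summary$state == "SMAR" & rs$summary$basis == "total"],
    median(sorted)
  )
  expect_equal(
    rs$summary$lower[rs$summary$state == "SMAR" & rs$summary$basis == "total"],
    quantile(sorted, 0.025, names = FALSE)
  )
  expect_equal(
    rs$summary$upper[rs$summary$state == "SMAR" & rs$summary$basis == "total"],
    quantile(sorted, 0.975, names = FALSE)
  )
})

test_that("no-change simulation is a fixed point of the landscape proportions", {
  grid <- small_landscape(rows = 150, cols = 150, seed = 47)
  px <- to_pixel_table(grid)
  mat <- build_proportion_matrix(px, step = 0.005)
  rs <- replicate_simulations(px, mat, slr_scenario(0), n_reps = 10, base_seed = 3)
  med <- rs$summary[rs$summary$basis == "total" & rs$summary$state != "ABSORBED", ]
  init <- rs$initial$proportion[match(med$state, rs$initial$state)]
  expect_true(all(abs(med$median - init) < 0.02))
})

test_that("a full-size subsample reproduces the full-data replicate summary", {
  px <- sample_pixel_table(600, synthetic_config(), seed = 53)
  mat <- build_proportion_matrix(px, step = 0.01)
  full <- replicate_simulations(px, mat, slr_scenario(0.2), n_reps = 5, base_seed = 31)
  expect_warning(
    sens <- subsample_sensitivity(
      px, mat,
      scenarios = list(slr_scenario(0.2)),
      sizes = c(5000, 600), n_reps = 5, base_seed = 31
    ),
    "exceeding"
  )
  sub <- sens$summary[, c("state", "basis", "median", "lower", "upper")]
  expect_equal(
    as.data.frame(sub[order(sub$state, sub$basis), ]),
    as.data.frame(full$summary[order(full$summary$state, full$summary$basis), ]),
    ignore_attr = TRUE
  )
})

test_that("interval width shrinks with subsample size at the binomial rate", {
  grid <- small_landscape(rows = 130, cols = 130, seed = 59)
  px <- to_pixel_table(grid)
  mat <- build_proportion_matrix(px, step = 0.005)
  sens <- subsample_sensitivity(
    px, mat,
    scenarios = list(slr_scenario(0.4)),
    sizes = c(10000, 1000, 250), n_reps = 40, base_seed = 9
  )
  w <- sens$summary |>
    dplyr::filter(.data$basis == "total", .data$state != "ABSORBED") |>
    dplyr::group_by(.data$size) |>
    dplyr::summarise(width = mean(.data$width))
  w <- w[order(-w$size), ]
  expect_true(all(diff(w$width) >= -1e-9)) # non-increasing in size
  ratio <- w$width[w$size == 250] / w$width[w$size == 10000]
  expect_gt(ratio, sqrt(40) * 0.5)
  expect_lt(ratio, sqrt(40) * 1.5)
})
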