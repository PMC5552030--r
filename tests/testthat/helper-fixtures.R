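# Shared fixtures: small configurations and landscapes built in code.

# a single-community configuration (weight 1) with optional overrides
one_community_config <- function(mean = 1.0, sd = 0.01, ...) {
  synthetic_config(
    communities = tibble::tibble(
      community = "PINE", mean = mean, sd = sd, weight = 1,
      bimodal = FALSE, delta = 0
    ),
    ...
  )
}

# two well-separated communities of equal weight
two_community_pixels <- function(n_each = 500, seed = 1) {
  set.seed(seed)
  tibble::tibble(
    elevation = c(rnorm(n_each, 0, 0.1), rnorm(n_each, 2, 0.1)),
    community = rep(c("SMAR", "SCRB"), each = n_each)
  )
}

# a small default landscape reused across tests
small_landscape <- function(rows = 120, cols = 120, seed = 99, ...) {
  generate_landscape(synthetic_config(rows = rows, cols = cols, seed = seed, ...))
}
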