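# In-code fixtures used across the suite.

# A minimal three-study GD table: every study has 2 non-insular + 1 insular
# population with heterozygosity (and one study a second metric).
fixture_gd <- function() {
  tibble::tibble(
    study_id = rep(c("s1", "s2", "s3"), times = c(3, 3, 6)),
    taxon_group = rep(c("birds", "fish", "mammals"), times = c(3, 3, 6)),
    population_id = c("m1", "m2", "i1", "m1", "m2", "i1",
                      rep(c("m1", "m2", "i1"), 2)),
    insular = c(FALSE, FALSE, TRUE, FALSE, FALSE, TRUE,
                rep(c(FALSE, FALSE, TRUE), 2)),
    metric_type = c(rep("heterozygosity", 6),
                    rep("heterozygosity", 3), rep("allelic_richness", 3)),
    value = c(0.71, 0.69, 0.55, 0.42, 0.44, 0.40,
              0.80, 0.82, 0.60, 8.1, 7.9, 5.0)
  )
}

# Divergence records for the same studies: one FST per pair, all pair
# classes present in s3.
fixture_divergence <- function() {
  tibble::tibble(
    study_id = c("s1", "s1", "s1", "s2", "s2", "s2"),
    population_id_a = c("m1", "m1", "m2", "m1", "m1", "m2"),
    population_id_b = c("m2", "i1", "i1", "m2", "i1", "i1"),
    metric_type = "FST",
    value = c(0.02, 0.15, 0.13, 0.05, 0.22, 0.25)
  )
}

fixture_record_set <- function() {
  as_record_set(fixture_gd(), fixture_divergence())
}

# Deterministic paired points with a known linear relationship plus fixed
# residuals; taxon groups cycled over three levels.
fixture_points <- function(n = 12, intercept = 0.5, slope = 0.8, seed = 99,
                           noise = 0.1, x_range = c(1, 5)) {
  set.seed(seed)
  x <- runif(n, x_range[1], x_range[2])
  tibble::tibble(
    unit_id = sprintf("u%02d", seq_len(n)),
    study_id = sprintf("u%02d", seq_len(n)),
    taxon_group = rep(c("birds", "fish", "mammals"), length.out = n),
    side = "within",
    x = x,
    y = intercept + slope * x + rnorm(n, 0, noise)
  )
}

# Independent normal-equations oracle for OLS: solve (X'X) b = X'y directly.
normal_equations_oracle <- function(X, y) {
  drop(solve(crossprod(X), crossprod(X, y)))
}

# Independent dense grid-search oracle for the broken-stick breakpoint:
# minimize RSS of y ~ 1 + x + (x - psi)+ over a fine psi grid.
grid_search_psi <- function(x, y, n_grid = 1000) {
  grid <- seq(min(x), max(x), length.out = n_grid + 2)[2:(n_grid + 1)]
  rss <- vapply(grid, function(psi) {
    X <- cbind(1, x, pmax(x - psi, 0))
    sum(lm.fit(X, y)$residuals^2)
  }, numeric(1))
  list(psi = grid[which.min(rss)], rss = min(rss))
}
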