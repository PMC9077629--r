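test_that("standardization gives each metric mean 0 and sd 1, invertibly", {
  rs <- validate_inclusion(fixture_record_set())
  std <- standardize(rs)

  by_metric <- split(std$gd$z_value, std$gd$metric_type)
  for (z in by_metric) {
    expect_lt(abs(mean(z)), 1e-9)
    expect_lt(abs(sd(z) - 1), 1e-9)
  }
  # {1,2,3} -> {-1,0,1} with the n-1 denominator
  gd <- tibble::tibble(study_id = "s", taxon_group = "fish",
                       population_id = c("m1", "m2", "i1"),
                       insular = c(FALSE, FALSE, TRUE),
                       metric_type = "mean_alleles", value = c(1, 2, 3))
  z <- standardize(as_record_set(gd))$gd$z_value
  expect_equal(z, c(-1, 0, 1))

  # inverse transform reproduces the raw values
  const <- std$standardization[std$standardization$table == "gd", ]
  back <- std$gd |>
    dplyr::left_join(const, by = "metric_type")
  expect_equal(back$z_value * back$sd + back$mean, back$value,
               tolerance = 1e-12)
})

test_that("zero-variance metric is a named fatal error", {
  gd <- fixture_gd()
  gd$value[gd$metric_type == "allelic_richness"] <- 7
  expect_error(standardize(as_record_set(gd)), "allelic_richness")
})

test_that("within pairing averages metrics within population, then populations", {
  # study A should land at (x, y) = (0.3, 0.1): its populations carry
  # z-scores {0.2, 0.4} (non-insular) and {0.1} (insular). A balancing
  # second study makes the metric's overall mean 0 and sd 1, so raw values
  # equal to the target z-scores standardize to themselves.
  zA <- c(0.2, 0.4, 0.1)
  m <- -sum(zA) / 3
  d <- sqrt((5 - sum(zA^2) - 3 * m^2) / 2)
  zB <- c(m - d, m, m + d)
  stopifnot(abs(mean(c(zA, zB))) < 1e-12, abs(sd(c(zA, zB)) - 1) < 1e-12)
  gd <- tibble::tibble(
    study_id = rep(c("a", "b"), each = 3),
    taxon_group = rep(c("birds", "fish"), each = 3),
    population_id = rep(c("m1", "m2", "i1"), 2),
    insular = rep(c(FALSE, FALSE, TRUE), 2),
    metric_type = "nucleotide_diversity",
    value = c(zA, zB)
  )
  std <- standardize(as_record_set(gd))
  pts <- pair_within(std)
  a <- pts[pts$study_id == "a", ]
  expect_equal(a$x, 0.3, tolerance = 1e-12)
  expect_equal(a$y, 0.1, tolerance = 1e-12)
  expect_equal(a$n_non_insular, 2L)
  expect_equal(a$n_insular, 1L)

  # population-first averaging: two metrics of one population average first
  rs <- validate_inclusion(fixture_record_set())
  std <- standardize(rs)
  pop_first <- pair_within(std, average = "population_first")
  s3 <- std$gd[std$gd$study_id == "s3", ]
  m1_mean <- mean(s3$z_value[s3$population_id == "m1"])
  m2_mean <- mean(s3$z_value[s3$population_id == "m2"])
  expect_equal(pop_first$x[pop_first$study_id == "s3"],
               mean(c(m1_mean, m2_mean)))
  # flat averaging weights all cells equally instead
  flat <- pair_within(std, average = "flat")
  expect_equal(flat$x[flat$study_id == "s3"],
               mean(s3$z_value[!s3$insular]))
})

test_that("among pairing splits non/non and ins/non pairs and drops ins/ins", {
  rs <- validate_inclusion(fixture_record_set())
  std <- standardize(rs)
  pts <- pair_among(std)
  expect_equal(nrow(pts), 2L)
  d <- std$divergence
  s1 <- d[d$study_id == "s1", ]
  expect_equal(pts$x[pts$study_id == "s1"],
               s1$z_value[s1$population_id_a == "m1" &
                            s1$population_id_b == "m2"])
  expect_equal(pts$y[pts$study_id == "s1"],
               mean(s1$z_value[s1$population_id_a == "i1" |
                                 s1$population_id_b == "i1"]))

  # an ins/ins pair changes nothing except the exclusion count
  div2 <- dplyr::bind_rows(
    fixture_divergence(),
    tibble::tibble(study_id = "s1", population_id_a = "i1",
                   population_id_b = "i2", metric_type = "FST", value = 0.4)
  )
  gd2 <- dplyr::bind_rows(
    fixture_gd(),
    tibble::tibble(study_id = "s1", taxon_group = "birds",
                   population_id = "i2", insular = TRUE,
                   metric_type = "heterozygosity", value = 0.52)
  )
  std2 <- standardize(validate_inclusion(as_record_set(gd2, div2)))
  pts2 <- pair_among(std2)
  expect_equal(attr(pts2, "n_ins_ins_excluded"), 1L)
  y1 <- pts2$y[pts2$study_id == "s1"]
  d2 <- std2$divergence
  ins_non <- d2$study_id == "s1" &
    xor(grepl("^i", d2$population_id_a), grepl("^i", d2$population_id_b))
  expect_equal(y1, mean(d2$z_value[ins_non]))
})

test_that("shift to unit minimum is exact and translation-preserving", {
  pts <- tibble::tibble(x = c(-2, 0), y = c(3, 1))
  sh <- shift_to_unit_min(pts)
  expect_equal(sh$shift_constant, 3)
  expect_equal(min(c(sh$points$x, sh$points$y)), 1)
  expect_equal(sh$points$x - pts$x, rep(3, 2))
  # differences between any two coordinates preserved
  expect_equal(diff(sh$points$y), diff(pts$y))
  # already at minimum 1: identity
  sh2 <- shift_to_unit_min(sh$points)
  expect_equal(sh2$shift_constant, 0)
  expect_equal(sh2$points$x, sh$points$x)
})

test_that("standardized pairing is invariant to uniform translation of a metric", {
  rs <- fixture_record_set()
  shifted_gd <- fixture_gd()
  shifted_gd$value[shifted_gd$metric_type == "heterozygosity"] <-
    shifted_gd$value[shifted_gd$metric_type == "heterozygosity"] + 5
  suppressWarnings(rs2 <- as_record_set(shifted_gd, fixture_divergence()))
  p1 <- pair_within(standardize(validate_inclusion(rs)))
  p2 <- pair_within(standardize(validate_inclusion(rs2)))
  expect_equal(p1$x, p2$x, tolerance = 1e-12)
  expect_equal(p1$y, p2$y, tolerance = 1e-12)
})
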