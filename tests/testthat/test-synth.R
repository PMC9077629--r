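test_that("generated datasets pass validation and inclusion by construction", {
  for (reg in c("null", "proportional", "above_threshold", "below_threshold")) {
    cfg <- synth_config(n_studies = 12, regime = reg, seed = 5,
                        include_ins_ins = TRUE)
    gen <- generate_metadataset(cfg)
    expect_s3_class(gen$records, "record_set")
    v <- validate_inclusion(gen$records)
    expect_true(all(v$inclusion$within))
    expect_true(all(v$inclusion$among))
    expect_equal(nrow(gen$truth$studies), 12L)
  }
})

test_that("the generator is deterministic and study content is counter-stable", {
  cfg <- synth_config(n_studies = 8, regime = "proportional", seed = 21)
  g1 <- generate_metadataset(cfg)
  g2 <- generate_metadataset(cfg)
  expect_identical(g1$records$gd, g2$records$gd)
  expect_identical(g1$records$divergence, g2$records$divergence)

  # study content invariant to n_studies: the first 8 studies of a larger
  # run equal the 8-study run
  cfg_big <- synth_config(n_studies = 12, regime = "proportional", seed = 21)
  g3 <- generate_metadataset(cfg_big)
  first8 <- g3$records$gd[g3$records$gd$study_id %in%
                            sprintf("S%03d", 1:8), ]
  expect_equal(as.data.frame(first8), as.data.frame(g1$records$gd))

  # byte-identical CSV output under the same seed
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_records(g1$records, d1)
  write_records(g2$records, d2)
  expect_identical(readLines(file.path(d1, "gd_records.csv")),
                   readLines(file.path(d2, "gd_records.csv")))
})

test_that("noiseless null datasets sit exactly on the one-to-one line", {
  # one metric per table so the between-study baseline spread is the only
  # variance source (with zero noise, a metric reported by a single study
  # would be constant and could not be standardized)
  cfg <- synth_config(n_studies = 10, regime = "null",
                      sigma_pop = 0, sigma_study = 0, seed = 3,
                      gd_metrics = default_gd_metric_scales()[1, ],
                      n_gd_metrics = c(1L, 1L),
                      divergence_metrics = default_divergence_metric_scales()[1, ])
  gen <- generate_metadataset(cfg)
  pts <- prepare_pairs(validate_inclusion(gen$records), side = "within")
  expect_equal(pts$y, pts$x, tolerance = 1e-9)

  # and the one-to-one null model then dominates the suite
  fits <- fit_model_suite(pts, side = "within", taxon = FALSE)
  expect_lt(fits$null$rss, 1e-16)
  cmp <- compare_models(fits)
  expect_equal(cmp$table$model[1], "null")
  expect_equal(max(cmp$table$weight), cmp$table$weight[1])
})

test_that("noiseless proportional regime scales insular latents by beta", {
  cfg <- synth_config(n_studies = 10, regime = "proportional", beta = 0.5,
                      sigma_pop = 0, sigma_study = 0, seed = 3)
  gen <- generate_metadataset(cfg)
  tr <- gen$truth$studies
  expect_equal(tr$insular_center_within, 0.5 * tr$baseline_within,
               tolerance = 1e-12)
  # and the among side is elevated by 1/beta
  expect_equal(tr$insular_center_among, 2 * tr$baseline_among,
               tolerance = 1e-12)
})

test_that("threshold regimes leave studies below/above tau untouched", {
  cfg <- synth_config(n_studies = 40, regime = "above_threshold",
                      sigma_pop = 0, sigma_study = 0, seed = 9)
  gen <- generate_metadataset(cfg)
  tr <- gen$truth$studies
  tau <- gen$truth$tau
  unaffected <- tr$baseline_within <= tau
  expect_equal(tr$insular_center_within[unaffected],
               tr$baseline_within[unaffected])
  expect_true(all(tr$insular_center_within[!unaffected] <
                    tr$baseline_within[!unaffected]))

  cfg2 <- synth_config(n_studies = 40, regime = "below_threshold",
                       sigma_pop = 0, sigma_study = 0, seed = 9)
  tr2 <- generate_metadataset(cfg2)$truth$studies
  affected2 <- tr2$baseline_within < tau
  expect_equal(tr2$insular_center_within[!affected2],
               tr2$baseline_within[!affected2])
  expect_true(all(tr2$insular_center_within[affected2] <
                    tr2$baseline_within[affected2]))
})

test_that("bounded metrics stay within their legal ranges", {
  cfg <- synth_config(n_studies = 30, regime = "below_threshold",
                      sigma_pop = 0.6, sigma_study = 0.3, seed = 17)
  gd <- generate_metadataset(cfg)$records$gd
  het <- gd$value[gd$metric_type %in% c("heterozygosity",
                                        "haplotype_diversity")]
  expect_true(all(het >= 0 & het <= 1))
})

test_that("drift and island-model presets follow their closed forms", {
  expect_equal(drift_heterozygosity(0.5, 50, 0), 0.5)
  expect_equal(drift_heterozygosity(0.5, 50, 10), 0.5 * 0.99^10)
  expect_equal(drift_heterozygosity(0.5, 1e12, 1000), 0.5, tolerance = 1e-8)
  # monotone: non-increasing in t, non-decreasing in Ne
  t <- 0:50
  expect_true(all(diff(drift_heterozygosity(0.7, 100, t)) <= 0))
  Ne <- c(2, 10, 100, 1000)
  expect_true(all(diff(drift_heterozygosity(0.7, Ne, 25)) >= 0))

  expect_equal(island_fst(0), 1)
  expect_equal(island_fst(0.25), 0.5)
  nm <- seq(0, 20, by = 0.5)
  expect_true(all(diff(island_fst(nm)) < 0))

  cfgp <- synth_config_popgen(n_studies = 6, seed = 2)
  h <- cfgp$gd_metrics[cfgp$gd_metrics$metric_type == "heterozygosity", ]
  expect_true(h$location > 0 && h$location < 0.75)
})

test_that("infeasible configurations are rejected", {
  expect_error(synth_config(pops_per_study = c(2, 5)), "pops_per_study")
  expect_error(synth_config(n_insular = c(1, 7), pops_per_study = c(3, 8)),
               "non-insular")
  expect_error(synth_config(sigma_pop = -1), "sds")
  expect_error(synth_config(tau_quantile = 1.2), "tau_quantile")
})
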