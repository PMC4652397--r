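test_that("a single parent with one unit is the degenerate split", {
  cfg <- generator_config(n_parent_areas = 1, mean_units_per_parent = 1,
                          seed = 1)
  units <- generate_units(cfg)
  expect_equal(nrow(units), 1)
  expect_equal(units$area_km2, units$parent_area_km2)
})

test_that("unit areas sum to the parent area and output is seed-stable", {
  cfg <- generator_config(n_parent_areas = 50, mean_units_per_parent = 3,
                          seed = 7)
  units <- generate_units(cfg)
  by_parent <- tapply(units$area_km2, units$parent_id, sum)
  parent_area <- tapply(units$parent_area_km2, units$parent_id, max)
  expect_equal(unname(by_parent[names(parent_area)]), unname(parent_area),
               tolerance = 1e-9)

  cfg100 <- generator_config(n_parent_areas = 100, seed = 11)
  expect_identical(generate_units(cfg100), generate_units(cfg100))
})

test_that("generator configuration is validated", {
  expect_error(generator_config(geology_gsd = c(alluvial = 0.9, sedimentary = 2,
                                                volcanic = 2, metamorphic = 2,
                                                intrusive = 2, karst = 2)),
               "exceed 1")
  expect_error(generator_config(measured_fraction = 1.5), "\\[0, 1\\]")
  expect_error(generator_config(n_parent_areas = 0), "count")
  expect_error(generator_config(mean_units_per_parent = 0.5), ">= 1")
})

test_that("measurements follow each unit's log-normal law", {
  # near-degenerate spread: concentrations collapse to the geometric mean
  gm <- c(a = 100); gsd <- c(a = 1 + 1e-12)
  cfg <- generator_config(n_parent_areas = 40, mean_units_per_parent = 1,
                          geology_gm = gm, geology_gsd = gsd,
                          measured_fraction = 1,
                          measurements_per_unit_mean = 3, seed = 3)
  units <- generate_units(cfg)
  m <- generate_measurements(units, cfg)
  gm_of <- units$true_gm[match(m$unit_id, units$unit_id)]
  expect_true(all(abs(m$concentration_bq_m3 / gm_of - 1) < 1e-4))

  # Monte-Carlo check at GM = 100, GSD = 2 with ~10,000 draws
  cfg2 <- generator_config(n_parent_areas = 700, mean_units_per_parent = 1,
                           geology_gm = c(a = 100), geology_gsd = c(a = 2),
                           measured_fraction = 1,
                           measurements_per_unit_mean = 15, seed = 4)
  units2 <- generate_units(cfg2)
  m2 <- generate_measurements(units2, cfg2)
  expect_gt(nrow(m2), 9000)
  expect_lt(abs(median(m2$concentration_bq_m3) / 100 - 1), 0.05)
  log_dev <- log(m2$concentration_bq_m3) -
    log(units2$true_gm[match(m2$unit_id, units2$unit_id)])
  expect_lt(abs(sd(log_dev) / log(2) - 1), 0.05)
  expect_true(all(m2$concentration_bq_m3 > 0))
})

test_that("a zero measurement rate yields an empty measurement table", {
  cfg <- small_config(measurements_per_unit_mean = 0)
  m <- generate_measurements(generate_units(cfg), cfg)
  expect_equal(nrow(m), 0)
})

test_that("a geology class missing from the concentration map is an error", {
  cfg <- small_config()
  units <- generate_units(cfg)
  units$geology[1] <- "unobtainium"
  expect_error(generate_measurements(units, cfg), "unobtainium")
})

test_that("null generator effects give a flat lung fraction in every stratum", {
  cfg <- small_config(seed = 5, lung_effect_radon = 1, lung_effect_smoking = 1,
                      sex_effect = 1, year_trend_ratio = 1,
                      deaths_per_unit_year = 8,
                      external_fraction = 0, under20_fraction = 0)
  units <- generate_units(cfg)
  ha <- generate_health_areas(cfg)
  truth <- radon_truth(units, cfg)
  deaths <- generate_deaths(units, ha, truth, cfg)
  deaths$lung <- startsWith(deaths$cause_code, "C34")
  deaths$radon <- truth$true_class[match(deaths$unit_id, truth$unit_id)]
  strata <- split(deaths$lung, list(deaths$radon, deaths$sex))
  for (s in strata) {
    se <- sqrt(cfg$lung_base_rate * (1 - cfg$lung_base_rate) / length(s))
    expect_lt(abs(mean(s) - cfg$lung_base_rate), 3 * se)
  }
})

test_that("the radon odds ratio is recovered by stratified counting", {
  cfg <- generator_config(n_parent_areas = 300, lung_effect_radon = 2,
                          lung_effect_smoking = 1, sex_effect = 1,
                          deaths_per_unit_year = 25, external_fraction = 0,
                          under20_fraction = 0, seed = 6)
  units <- generate_units(cfg)
  ha <- generate_health_areas(cfg)
  truth <- radon_truth(units, cfg)
  deaths <- generate_deaths(units, ha, truth, cfg)
  lung <- startsWith(deaths$cause_code, "C34")
  high <- truth$true_class[match(deaths$unit_id, truth$unit_id)] == "high"
  odds <- function(p) p / (1 - p)
  or <- odds(mean(lung[high])) / odds(mean(lung[!high]))
  expect_lt(abs(or / 2 - 1), 0.10)
})

test_that("death records are identical under a fixed seed", {
  cfg <- small_config(seed = 8)
  units <- generate_units(cfg)
  ha <- generate_health_areas(cfg)
  truth <- radon_truth(units, cfg)
  expect_identical(generate_deaths(units, ha, truth, cfg),
                   generate_deaths(units, ha, truth, cfg))
  expect_error(generate_deaths(units[0, ], ha, truth, cfg), "empty")
})

test_that("the whole study is reproducible and internally consistent", {
  cfg <- small_config(seed = 9)
  s1 <- synthesize_study(cfg)
  s2 <- synthesize_study(cfg)
  expect_identical(s1, s2)
  expect_true(all(s1$measurements$unit_id %in% s1$units$unit_id))
  expect_true(all(s1$deaths$unit_id %in% s1$units$unit_id))
  expect_setequal(s1$truth$unit_id, s1$units$unit_id)
})

test_that("measured-unit p95 rises stochastically with geology GM", {
  cfg <- generator_config(n_parent_areas = 450, seed = 10)
  study <- synthesize_study(cfg)
  tr <- build_training_set(study$units, study$measurements)
  expect_gte(nrow(tr$labels), 200)
  gm <- cfg$geology_gm[study$units$geology[match(tr$labels$unit_id,
                                                 study$units$unit_id)]]
  ct <- suppressWarnings(
    cor.test(gm, tr$labels$p95, method = "spearman", alternative = "greater"))
  expect_gt(ct$estimate, 0)
  expect_lt(ct$p.value, 0.01)
})
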