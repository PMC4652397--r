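test_that("death filtering keeps adult natural deaths and flags lung cancer", {
  d <- data.frame(cause_code = c("C34", "V43", "C340", "I21"),
                  age = c(65, 40, 70, 15))
  f <- filter_deaths(d)
  expect_equal(nrow(f), 2)  # V43 external, I21 under 20
  expect_equal(f$lung, c(TRUE, TRUE))

  # counting oracle: 100 records, 10 external-cause, 5 under-20 -> 85 survive
  set.seed(50)
  d2 <- data.frame(cause_code = rep("I64", 100), age = rep(60, 100))
  d2$cause_code[1:10] <- c("T20", "U07", "V10", "W55", "X33",
                           "Y20", "V99", "T81", "X00", "Y99")
  d2$age[11:15] <- c(0, 5, 12, 19, 19)
  expect_equal(nrow(filter_deaths(d2)), 85)

  d3 <- data.frame(cause_code = c("C34", "", NA), age = c(60, 60, 60))
  expect_warning(f3 <- filter_deaths(d3), "2 record")
  expect_equal(nrow(f3), 1)
  expect_equal(attr(f3, "n_malformed"), 2)
})

test_that("the smoking split classifies strictly-above-median as higher", {
  expect_equal(unname(median_smoking_split(c(a = 0.1, b = 0.2, c = 0.3))),
               c("lower", "lower", "higher"))
  expect_true(all(median_smoking_split(rep(0.2, 5)) == "lower"))
  set.seed(51)
  prev <- setNames(runif(83, 0.05, 0.4), paste0("HA", 1:83))
  expect_equal(sum(median_smoking_split(prev) == "higher"), 41)
  expect_error(median_smoking_split(c(a = 0.1, b = NA)), "missing")
  expect_error(median_smoking_split(c(a = 0.1)), "at least 2")
})

make_stratified_fixture <- function() {
  deaths <- data.frame(
    death_id = sprintf("d%02d", 1:6),
    year = c(2000, 2000, 2001, 2001, 2001, 2002),
    sex = c("male", "female", "male", "male", "female", "female"),
    age = 60, cause_code = c("C34", "I21", "C34", "I21", "I21", "C34"),
    unit_id = c("u1", "u1", "u2", "u2", "u3", "u3"),
    health_area_id = c("h1", "h1", "h1", "h1", "h2", "h2"))
  maps <- rbind(
    data.frame(unit_id = c("u1", "u2", "u3"), threshold = 200,
               class = c("high", "high", "low")),
    data.frame(unit_id = c("u1", "u2", "u3"), threshold = 600,
               class = c("high", "low", "INELIGIBLE")))
  smoking <- c(h1 = "higher", h2 = "lower")
  list(deaths = filter_deaths(deaths), maps = maps, smoking = smoking)
}

test_that("strata are assigned per threshold and ineligible deaths excluded", {
  fx <- make_stratified_fixture()
  st <- assign_strata(fx$deaths, fx$maps, fx$smoking)
  # u2 is high at 200 but low at 600; u3 ineligible at 600 drops out
  u2 <- st[st$unit_id == "u2", ]
  expect_equal(u2$vuln_class[u2$threshold == 200], rep("high", 2))
  expect_equal(u2$vuln_class[u2$threshold == 600], rep("low", 2))
  expect_equal(unname(attr(st, "n_excluded")), c(0L, 2L))
  expect_equal(sum(st$threshold == 600), 4)
  expect_equal(unique(st$smoking_class[st$unit_id == "u3"]), "lower")

  one_unit <- fx$deaths[fx$deaths$unit_id == "u1", ]
  st1 <- assign_strata(one_unit, fx$maps, fx$smoking)
  expect_equal(unique(st1$vuln_class[st1$threshold == 200]), "high")

  bad <- fx$deaths; bad$unit_id[1] <- "nowhere"
  expect_error(assign_strata(bad, fx$maps, fx$smoking), "absent from the map")
})

test_that("stratum counts partition the filtered deaths and match a hand tally", {
  study <- synthesize_study(small_config(seed = 52))
  filtered <- filter_deaths(study$deaths)
  smoking <- median_smoking_split(study$health_areas)
  # truth-based single-threshold map so the tally is known exactly
  maps <- data.frame(unit_id = study$truth$unit_id, threshold = 200,
                     class = study$truth$true_class)
  st <- assign_strata(filtered, maps, smoking)
  expect_equal(nrow(st), nrow(filtered))  # no ineligible units here
  tally <- table(st$vuln_class)
  by_hand <- table(study$truth$true_class[match(filtered$unit_id,
                                                study$truth$unit_id)])
  expect_equal(as.integer(tally[c("high", "low")]),
               as.integer(by_hand[c("high", "low")]))
  # any further stratification still partitions the total
  expect_equal(sum(table(st$vuln_class, st$smoking_class, st$sex)), nrow(st))
})

test_that("annual ratios divide lung deaths by natural deaths per year", {
  d <- data.frame(year = c(rep(2000, 100), rep(2001, 50)),
                  lung = c(rep(TRUE, 10), rep(FALSE, 90), rep(FALSE, 50)))
  s <- annual_ratio_series(d)
  expect_equal(s$ratio, c(0.10, 0))
  s2 <- annual_ratio_series(d, years = 2000:2002)
  expect_true(is.na(s2$ratio[3]))
})

test_that("generated stratum lung fractions are recovered in the series", {
  # base rate 0.07 with a radon odds ratio that puts the high stratum at 0.10
  or <- (0.10 / 0.90) / (0.07 / 0.93)
  cfg <- generator_config(n_parent_areas = 300, lung_base_rate = 0.07,
                          lung_effect_radon = or, lung_effect_smoking = 1,
                          sex_effect = 1, deaths_per_unit_year = 10,
                          external_fraction = 0, under20_fraction = 0,
                          seed = 53)
  study <- synthesize_study(cfg)
  filtered <- filter_deaths(study$deaths)
  maps <- data.frame(unit_id = study$truth$unit_id, threshold = 200,
                     class = study$truth$true_class)
  smoking <- median_smoking_split(study$health_areas)
  st <- assign_strata(filtered, maps, smoking)
  for (cl in c("high", "low")) {
    target <- if (cl == "high") 0.10 else 0.07
    s <- annual_ratio_series(st, threshold = 200, vuln_class = cl)
    pooled <- sum(s$lung_deaths) / sum(s$natural_deaths)
    se <- sqrt(target * (1 - target) / sum(s$natural_deaths))
    expect_lt(abs(pooled - target), 2 * se)
  }
})

test_that("a null radon effect leaves the high/low curves indistinguishable", {
  cfg <- generator_config(n_parent_areas = 300, lung_effect_radon = 1,
                          deaths_per_unit_year = 10, external_fraction = 0,
                          under20_fraction = 0, seed = 55)
  study <- synthesize_study(cfg)
  filtered <- filter_deaths(study$deaths)
  maps <- data.frame(unit_id = study$truth$unit_id, threshold = 200,
                     class = study$truth$true_class)
  st <- assign_strata(filtered, maps, median_smoking_split(study$health_areas))
  hi <- annual_ratio_series(st, threshold = 200, vuln_class = "high")
  lo <- annual_ratio_series(st, threshold = 200, vuln_class = "low")
  p <- (sum(hi$lung_deaths) + sum(lo$lung_deaths)) /
    (sum(hi$natural_deaths) + sum(lo$natural_deaths))
  se <- sqrt(p * (1 - p) * (1 / hi$natural_deaths + 1 / lo$natural_deaths))
  within_band <- abs(hi$ratio - lo$ratio) < 3 * se
  expect_gte(sum(within_band), 15)
})

test_that("the local smoother reproduces polynomials exactly", {
  x <- 1998:2013
  y_lin <- 0.002 * (x - 1998) + 0.07
  expect_equal(loess_smooth(x, y_lin, span = 0.4, degree = 1), y_lin,
               tolerance = 1e-9)
  y_const <- rep(0.08, 16)
  expect_equal(loess_smooth(x, y_const, span = 0.75, degree = 2), y_const,
               tolerance = 1e-12)
  y_quad <- 0.05 + 0.003 * (x - 2005) + 2e-4 * (x - 2005)^2
  fit_global <- lm(y_quad ~ poly(x, 2, raw = TRUE))
  expect_equal(loess_smooth(x, y_quad, span = 1, degree = 2),
               unname(fitted(fit_global)), tolerance = 1e-9)
  expect_error(loess_smooth(1:3, c(1, 2, 3), span = 0.5, degree = 2),
               "at least")
})

test_that("the smoother matches a brute-force weighted-least-squares oracle", {
  set.seed(54)
  for (i in 1:50) {
    n <- sample(8:25, 1)
    x <- sort(sample(1990:2030, n))
    y <- runif(n, 0.05, 0.15)
    span <- runif(1, 0.3, 1)
    degree <- sample(1:2, 1)
    expect_equal(loess_smooth(x, y, span = span, degree = degree),
                 oracle_loess(x, y, span, degree), tolerance = 1e-9)
  }
})

test_that("ratio-of-percentages uses the printed-percentage convention", {
  # higher smoking holds 229/1000 natural and 131/500 lung deaths:
  # 22.9% and 26.2% -> 1.14 from the rounded percentages
  deaths <- data.frame(
    year = 2000, sex = "male", age = 60,
    unit_id = c(rep("s_hi", 229), rep("s_lo", 771)),
    health_area_id = c(rep("h_hi", 229), rep("h_lo", 771)),
    cause_code = "I21")
  deaths$cause_code[c(1:131, 301:669)] <- "C34"  # 131 lung in higher smoking
  # high radon stratum: 32/1000 natural, 18.5/500 lung -> use 37/1000 lung
  maps <- data.frame(unit_id = c("s_hi", "s_lo"), threshold = 500,
                     class = "low")
  filtered <- filter_deaths(deaths)
  expect_equal(sum(filtered$lung), 500)

  st <- assign_strata(filtered, maps, c(h_hi = "higher", h_lo = "lower"))
  tab <- stratum_summary_table(st)
  smoking_row <- tab[tab$stratum == "higher_smoking", ]
  expect_equal(round(smoking_row$pct_natural, 1), 22.9)
  expect_equal(round(smoking_row$pct_lung, 1), 26.2)
  expect_equal(smoking_row$ratio_of_percentages, 1.14)

  # identical percentages give a ratio of exactly 1
  maps_all_high <- data.frame(unit_id = c("s_hi", "s_lo"), threshold = 500,
                              class = "high")
  st2 <- assign_strata(filtered, maps_all_high,
                       c(h_hi = "higher", h_lo = "lower"))
  tab2 <- stratum_summary_table(st2)
  expect_equal(tab2$ratio_of_percentages[tab2$stratum == "high_radon"], 1)
})

test_that("misclassification correction moves expected counts exactly", {
  id <- misclassification_sensitivity(100, 900, 70, 930, 0, 0)
  expect_equal(id$ratio_high, 0.1)
  expect_equal(id$ratio_low, 0.07)

  res <- misclassification_sensitivity(100, 900, 70, 930,
                                       f_lung = 0.9, f_other = 0.95)
  expect_equal(res$ratio_high, 10 / 55)
  expect_equal(sum(res$counts[c("lung_high", "lung_low")]), 170)
  expect_equal(sum(res$counts), 100 + 900 + 70 + 930)

  expect_error(misclassification_sensitivity(0, 0, 10, 10, 0.5, 0.5),
               "empty high group")
  expect_error(misclassification_sensitivity(1, 1, 1, 1, 1.5, 0), "\\[0, 1\\]")
})
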