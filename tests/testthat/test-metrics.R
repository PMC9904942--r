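test_that("mean size is the count-weighted mean over cells", {
  rec <- recon_rows("wood", 1996, c("1.2", "1.2"), "escapement",
                    c(500, 520), c(1, 3))
  expect_equal(mean_size(rec)$mean_length_mm, 515)
  one <- recon_rows("wood", 1996, "1.3", "catch", 560, 7)
  expect_equal(mean_size(one)$mean_length_mm, 560)
})

test_that("bay-wide mean equals the abundance-weighted mean of river means", {
  rec <- dplyr::bind_rows(
    recon_rows("wood", 1996, "1.2", "escapement", c(500, 510), c(10, 30)),
    recon_rows("kvichak", 1996, "1.3", "escapement", c(570, 590), c(100, 60)))
  bw <- mean_size(rec, "baywide")$mean_length_mm
  riv <- vapply(c("wood", "kvichak"),
                function(r) mean_size(rec, r)$mean_length_mm, 0)
  n <- vapply(c("wood", "kvichak"),
              function(r) mean_size(rec, r)$n_fish, 0)
  expect_equal(bw, sum(riv * n) / sum(n))
})

test_that("weighted statistics equal brute-force statistics on expanded individuals", {
  set.seed(21)
  rec <- dplyr::bind_rows(
    recon_rows("wood", rep(1995:1997, each = 4),
               rep(c("1.2", "1.3", "2.2", "2.3"), 3), "escapement",
               round(rnorm(12, 540, 25)), sample(1:50, 12)),
    recon_rows("kvichak", rep(1995:1997, each = 2),
               rep(c("1.2", "1.3"), 3), "catch",
               round(rnorm(6, 530, 25)), sample(1:50, 6)))
  flat <- expand_recon(rec)

  ms <- mean_size(rec, "baywide", "brood")
  by_year <- tap(flat$length_mm, flat$brood_year, mean)
  expect_equal(ms$mean_length_mm, unname(by_year[as.character(ms$year)]))

  ltm <- long_term_age_means(rec, "baywide")
  by_age <- tap(flat$length_mm, flat$age_code, mean)
  expect_equal(ltm$mean_length_mm, unname(by_age[ltm$age_code]))

  an <- size_at_age_anomalies(rec, "baywide", "brood")
  flat$anom <- flat$length_mm - by_age[flat$age_code]
  an_flat <- tap(flat$anom, flat$brood_year, mean)
  expect_equal(an$mean_anomaly_mm, unname(an_flat[as.character(an$year)]))

  ma <- mean_ages(rec, "baywide", "brood")
  oc <- tap(flat$ocean_years, flat$brood_year, mean)
  fw <- tap(flat$fw_years, flat$brood_year, mean)
  expect_equal(ma$mean_ocean_age, unname(oc[as.character(ma$year)]))
  expect_equal(ma$mean_fw_age, unname(fw[as.character(ma$year)]))

  cv <- cv_size_at_age(rec, "1.2", "baywide", "brood")
  f12 <- flat[flat$age_code == "1.2", ]
  cv_flat <- tap(f12$length_mm, f12$brood_year, function(x) {
    sqrt(mean((x - mean(x))^2)) / mean(x)
  })
  expect_equal(cv$cv, unname(cv_flat[as.character(cv$year)]))
})

test_that("anomalies are zero when all fish sit at their age-group long-term mean", {
  rec <- recon_rows("wood", c(1995, 1996), c("1.2", "1.2"), "escapement",
                    c(510, 510), c(5, 9))
  an <- size_at_age_anomalies(rec)
  expect_equal(an$mean_anomaly_mm, c(0, 0))
  # single age group 20mm above its long-term mean in one year
  rec2 <- recon_rows("wood", c(1995, 1996), c("1.2", "1.2"), "escapement",
                     c(500, 520), c(1, 1))
  an2 <- size_at_age_anomalies(rec2)
  expect_equal(an2$mean_anomaly_mm, c(-10, 10))
})

test_that("weight-averaged anomaly over all years is zero by construction", {
  sim <- small_sim()
  for (scope in c("baywide", "wood")) {
    an <- size_at_age_anomalies(sim$recon, scope, "brood")
    expect_equal(sum(an$mean_anomaly_mm * an$n_fish) / sum(an$n_fish), 0,
                 tolerance = 1e-9)
  }
})

test_that("mean ages average freshwater and ocean years correctly", {
  rec <- recon_rows("wood", c(1995, 1994), c("1.2", "1.3"), "escapement",
                    c(510, 560), c(10, 10))
  ma <- mean_ages(rec, year_basis = "return")  # both return in 1999
  expect_equal(ma$mean_ocean_age, 2.5)
  expect_equal(ma$mean_fw_age, 1.0)
  rec2 <- recon_rows("wood", 1995, "2.2", "catch", 520, 4)
  ma2 <- mean_ages(rec2)
  expect_equal(ma2$mean_ocean_age, 2)
  expect_equal(ma2$mean_fw_age, 2)
})

test_that("CV of size-at-age uses the weighted population SD", {
  rec <- recon_rows("wood", c(1995, 1995), c("1.2", "1.2"), "escapement",
                    c(90, 110), c(1, 1))
  expect_equal(cv_size_at_age(rec, "1.2")$cv, 0.10)
  rec0 <- recon_rows("wood", 1995, "1.2", "escapement", 510, 100)
  expect_equal(cv_size_at_age(rec0, "1.2")$cv, 0)
})

test_that("length-weight fit recovers a noiseless allometry exactly", {
  len <- seq(400, 650, by = 10)
  mass <- 4e-6 * len^3.1
  fit <- fit_length_weight(len, mass)
  expect_equal(fit$a, 4e-6, tolerance = 1e-6)
  expect_equal(fit$b, 3.1, tolerance = 1e-7)
  # applying the fit to its own inputs reproduces the masses
  expect_equal(length_to_mass(len, fit), mass, tolerance = 1e-6)
})

test_that("length-weight fit recovers noisy parameters within 2 SE", {
  set.seed(31)
  n <- 1000
  len <- runif(n, 380, 680)
  mass <- 1.1e-6 * len^3.4 * exp(rnorm(n, 0, 0.08))
  fit <- fit_length_weight(len, mass)
  se_b <- summary(fit$fit)$coefficients["b", "Std. Error"]
  expect_lt(abs(fit$b - 3.4), 2 * se_b)
  expect_gt(fit$b, 2)
  expect_lt(fit$b, 4)
})

test_that("length-weight fit guards degenerate inputs", {
  expect_error(fit_length_weight(c(500, 510), c(2000, 2100)), "at least 10")
  len <- seq(400, 650, by = 10)
  fit <- fit_length_weight(len, 4e-6 * len^3.1)
  expect_error(length_to_mass(c(500, 0), fit), "positive")
})

test_that("a 3% length decline maps to about a 10% mass decline for b near 3.4", {
  len <- seq(400, 650, by = 5)
  fit <- fit_length_weight(len, 1.1e-6 * len^3.4)
  series <- tibble::tibble(year = 1:2, mean_length_mm = c(600, 600 * 0.97))
  out <- length_series_to_mass(series, fit)
  ratio <- out$mean_mass_g[2] / out$mean_mass_g[1]
  expect_equal(ratio, 0.97^fit$b, tolerance = 1e-10)
  expect_equal(1 - ratio, 0.098, tolerance = 0.01)
})

test_that("selection differential is escapement mean minus run mean", {
  rec <- dplyr::bind_rows(
    recon_rows("wood", 1996, "1.2", "escapement", 505, 60),
    recon_rows("wood", 1996, "1.2", "catch", 522.5, 40))
  sd_ <- selection_differentials(rec)
  expect_equal(sd_$run_mean_mm, 512)
  expect_equal(sd_$sel_diff_mm, -7)
  # no fishing: escapement is the whole run, differential 0
  rec0 <- recon_rows("wood", 1996, "1.2", "escapement", c(500, 520), c(1, 1))
  expect_equal(selection_differentials(rec0)$sel_diff_mm, 0)
})

test_that("size-selective harvest produces strictly negative selection differentials", {
  sim <- small_sim()  # generator default sel_slope > 0
  sd_ <- selection_differentials(sim$recon, scope = "baywide")
  expect_true(all(sd_$sel_diff_mm < 0))
})

test_that("age-group correlations handle identical, anti-correlated and noisy series", {
  yrs <- 2000:2019
  v <- sin(seq_len(20))
  rec <- dplyr::bind_rows(
    recon_rows("wood", yrs, "1.2", "escapement", 510 + 10 * v, 1),
    recon_rows("wood", yrs, "1.3", "escapement", 560 + 10 * v, 1))
  expect_equal(age_group_correlations(rec, year_basis = "brood")$average, 1)
  rec2 <- dplyr::bind_rows(
    recon_rows("wood", yrs, "1.2", "escapement", 510 + 10 * v, 1),
    recon_rows("wood", yrs, "1.3", "escapement", 560 - 10 * v, 1))
  expect_equal(age_group_correlations(rec2, year_basis = "brood")$average, -1)
  set.seed(5)
  rec3 <- dplyr::bind_rows(
    recon_rows("wood", 1971:2020, "1.2", "escapement", rnorm(50, 510, 10), 1),
    recon_rows("wood", 1971:2020, "1.3", "escapement", rnorm(50, 560, 10), 1))
  expect_lt(abs(age_group_correlations(rec3, year_basis = "brood")$average),
            2 / sqrt(50 - 3))
})
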