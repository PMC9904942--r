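# build a predictor_table directly from raw predictor columns, mirroring the
# documented structure, so model machinery can be tested on controlled designs
make_pred_table <- function(raw, response, years = NULL) {
  n <- length(response)
  if (is.null(years)) years <- seq(1961, length.out = n)
  tab <- tibble::tibble(year = years, response = response)
  for (p in names(raw)) tab[[p]] <- raw[[p]]
  tab$regime <- factor(ifelse(tab$year <= 1988, "pre", "post"),
                       levels = c("pre", "post"))
  scaling <- tibble::tibble(predictor = names(raw),
                            center = vapply(raw, mean, 0),
                            scale = vapply(raw, sd, 0))
  for (p in names(raw)) {
    z <- (tab[[p]] - mean(tab[[p]])) / sd(tab[[p]])
    tab[[paste0("z_", p)]] <- z
    tab[[paste0("z_", p, "_sq")]] <- z^2
  }
  structure(tab, class = c("predictor_table", class(tab)), scaling = scaling)
}

test_that("seasonal SST means use the right months and lags", {
  cov <- tibble::tibble(year = 2000:2002)
  for (m in 1:12) cov[[sprintf("sst_aleutians_%02d", m)]] <- as.numeric(m)
  cov$sst_aleutians_01 <- c(1, 10, 100)
  cov$sst_aleutians_02 <- c(2, 20, 200)
  cov$sst_aleutians_03 <- c(3, 30, 300)
  w <- seasonal_sst(cov, "winter", "aleutians")
  expect_equal(w$value, c(2, 20, 200))
  # summer of the previous calendar year is assigned to the return year
  for (m in 7:9) cov[[sprintf("sst_aleutians_%02d", m)]] <- c(7, 70, 700)
  s1 <- seasonal_sst(cov, "summer", "aleutians", lag = 1)
  expect_equal(s1$year, 2001:2003)
  expect_equal(s1$value, c(7, 70, 700))
  cov_gap <- cov[, setdiff(names(cov), "sst_aleutians_02")]
  expect_error(seasonal_sst(cov_gap, "winter", "aleutians"), "missing")
})

test_that("predictor assembly lags, standardizes and squares correctly", {
  cov <- simulate_covariates(1978:2010, seed = 3)
  an <- tibble::tibble(year = 1983:2008,
                       mean_anomaly_mm = rnorm(26, 0, 5))
  sel_diffs <- tibble::tibble(return_year = 1978:2008,
                              sel_diff_mm = seq(-1, -7, length.out = 31))
  pt <- build_predictors(cov, an, sel_diffs = sel_diffs)
  expect_equal(levels(pt$regime), c("pre", "post"))
  expect_equal(as.character(pt$regime[pt$year == 1985]), "pre")
  expect_equal(as.character(pt$regime[pt$year == 1995]), "post")
  # lag-4 selection differential for year 2000 is the 1996 value
  expect_equal(pt$sel_diff_lag4[pt$year == 2000],
               sel_diffs$sel_diff_mm[sel_diffs$return_year == 1996])
  expect_equal(pt$pink_lag1[pt$year == 1990],
               cov$pink_abund[cov$year == 1989])
  # quadratic columns are squares of standardized columns
  expect_equal(pt$z_pink_lag1_sq, pt$z_pink_lag1^2)
  expect_equal(mean(pt$z_sockeye_run), 0, tolerance = 1e-12)
  expect_equal(sd(pt$z_sockeye_run), 1, tolerance = 1e-12)
})

test_that("collinearity screen excludes pairs above the threshold only", {
  set.seed(11)
  n <- 60
  x1 <- rnorm(n)
  x_hi <- 0.6 * x1 + sqrt(1 - 0.36) * rnorm(n)   # r ~ 0.6
  x_lo <- 0.4 * x1 + sqrt(1 - 0.16) * rnorm(n)   # r ~ 0.4
  while (abs(cor(x1, x_hi)) <= 0.5) x_hi <- 0.6 * x1 + 0.8 * rnorm(n)
  while (abs(cor(x1, x_lo)) > 0.5) x_lo <- 0.4 * x1 + 0.92 * rnorm(n)
  pt <- make_pred_table(list(a = x1, b = x_hi, c = x_lo),
                        response = rnorm(n))
  scr <- screen_collinearity(pt, threshold = 0.5, families = list())
  pair <- paste(scr$excluded_pairs$var1, scr$excluded_pairs$var2)
  expect_true("a b" %in% pair)
  expect_false("a c" %in% pair)
  # excluded pair never co-occurs in the selected model, even when the
  # response loads on both
  y <- 3 * x1 + 3 * x_hi + rnorm(n)
  pt2 <- make_pred_table(list(a = x1, b = x_hi, c = x_lo), response = y)
  sel <- select_model(pt2, screen = screen_collinearity(pt2, families = list()),
                      regime_interactions = NULL)
  expect_false(all(c("z_a", "z_b") %in% sel$terms))
})

test_that("the collinear competitor family with lower univariate R2 is dropped", {
  found <- vapply(1:20, function(s) {
    cov <- simulate_covariates(1975:2015, seed = s)
    yrs <- 1978:2014
    resp <- simulate_anomaly_response(cov, yrs,
                                      betas = list(pink_lag1 = -0.1),
                                      sigma_year = 3, seed = s + 300)
    an <- tibble::tibble(year = resp$year, mean_anomaly_mm = resp$response)
    pt <- build_predictors(cov, an)
    scr <- screen_collinearity(pt)
    all(c("chum_lag1", "chum_lag2") %in% scr$dropped)
  }, TRUE)
  # chum tracks pink (r > 0.7) but carries no direct signal
  expect_gte(mean(found), 0.9)
})

test_that("a single perfectly predictive covariate is selected with R2 of 1", {
  set.seed(4)
  n <- 40
  x <- rnorm(n)
  y <- 5 * x + rnorm(n, 0, 1e-8)
  pt <- make_pred_table(list(a = x, b = rnorm(n)), response = y)
  sel <- select_model(pt, screen = screen_collinearity(pt, families = list()),
                      regime_interactions = NULL)
  expect_true("z_a" %in% sel$terms)
  expect_equal(sel$r_squared, 1, tolerance = 1e-9)
})

test_that("under pure noise, the intercept-only model wins at the rate AIC theory predicts", {
  # false inclusion per candidate is P(chisq_1 > 2) = 0.157, so with three
  # independent linear candidates the null model should win ~0.843^3 = 60%
  set.seed(8)
  n <- 60
  wins <- vapply(1:200, function(i) {
    pt <- make_pred_table(list(a = rnorm(n), b = rnorm(n), c = rnorm(n)),
                          response = rnorm(n))
    sel <- select_model(pt, screen = screen_collinearity(pt, families = list()),
                        quadratic = FALSE, regime_interactions = NULL)
    length(sel$terms) == 0
  }, TRUE)
  rate <- mean(wins)
  expect_gt(rate, 0.598 - 3 * sqrt(0.598 * 0.402 / 200))
  expect_lt(rate, 0.598 + 3 * sqrt(0.598 * 0.402 / 200))
})

test_that("a strong linear-plus-quadratic signal is recovered", {
  set.seed(10)
  n <- 60
  hits <- vapply(1:200, function(i) {
    x1 <- rnorm(n); x2 <- rnorm(n); x3 <- rnorm(n)
    y <- 3 * x1 + 2 * (x2 - mean(x2))^2 + rnorm(n)
    pt <- make_pred_table(list(a = x1, b = x2, c = x3), response = y)
    sel <- select_model(pt, screen = screen_collinearity(pt, families = list()),
                        regime_interactions = NULL)
    all(c("z_a", "z_b_sq") %in% sel$terms)
  }, TRUE)
  expect_gte(mean(hits), 0.90)
})

test_that("variance shares behave on orthogonal designs and sum to R2", {
  set.seed(12)
  n <- 80
  q <- qr.Q(qr(matrix(rnorm(n * 3), n)))       # orthonormal columns
  x1 <- q[, 1]; x2 <- q[, 2]; x3 <- q[, 3]
  y <- 8 * x1 + 4 * x2 + rnorm(n, 0, 0.5)
  pt <- make_pred_table(list(a = x1, b = x2, c = x3), response = y)
  sel <- select_model(pt, screen = screen_collinearity(pt, families = list()),
                      quadratic = FALSE, regime_interactions = NULL)
  shares <- partition_variance(sel)
  expect_setequal(shares$predictor[shares$share_pct > 1], c("a", "b"))
  # orthogonal predictors: shares add up to total explained variance
  expect_equal(sum(shares$share_pct) / 100, sel$r_squared, tolerance = 0.02)
  # single-predictor model: share equals R2
  y1 <- 8 * x1 + rnorm(n, 0, 0.5)
  pt1 <- make_pred_table(list(a = x1), response = y1)
  sel1 <- select_model(pt1, screen = screen_collinearity(pt1, families = list()),
                       quadratic = FALSE, regime_interactions = NULL)
  sh1 <- partition_variance(sel1)
  expect_equal(sh1$share_pct / 100, sel1$r_squared, tolerance = 1e-10)
})

test_that("partial effects reproduce slopes, curvature and edge-widening CIs", {
  set.seed(14)
  n <- 80
  x1 <- rnorm(n); x2 <- rnorm(n)
  y <- 4 * x1 - 3 * (x2 - mean(x2))^2 + 2 * (x2 - mean(x2)) + rnorm(n, 0, 0.3)
  pt <- make_pred_table(list(a = x1, b = x2), response = y)
  sel <- select_model(pt, screen = screen_collinearity(pt, families = list()),
                      regime_interactions = NULL)
  # linear-only term: straight line with the standardized coefficient as slope
  pa <- partial_effects(sel, "a", n = 50)
  slopes <- diff(pa$fit) / diff(pa$z)
  b_a <- sel$coefficients$estimate[sel$coefficients$term == "z_a"]
  expect_equal(unname(slopes), rep(b_a, 49), tolerance = 1e-6)
  # quadratic with negative curvature: concave with vertex at -b1/(2*b2)
  pb <- partial_effects(sel, "b", n = 201)
  d2 <- diff(diff(pb$fit))
  expect_true(all(d2 < 0))
  b1 <- sel$coefficients$estimate[sel$coefficients$term == "z_b"]
  b2 <- sel$coefficients$estimate[sel$coefficients$term == "z_b_sq"]
  vertex <- -b1 / (2 * b2)
  expect_equal(pb$z[which.max(pb$fit)], vertex, tolerance = 0.05)
  # pointwise CI is wider at the grid edges than at the centre
  width <- pb$upr - pb$lwr
  expect_gt(width[1], min(width))
  expect_gt(width[201], min(width))
})

test_that("refitting the selected terms reproduces coefficients and AIC, and the dAIC table is consistent", {
  sim <- small_sim()
  an <- size_at_age_anomalies(sim$recon, "baywide", "return")
  sdf <- selection_differentials(sim$recon, scope = "baywide")
  pt <- build_predictors(sim$covars, an, sel_diffs = sdf)
  sel <- select_model(pt)
  refit <- lm(as.formula(paste("response ~",
                               if (length(sel$terms)) paste(sel$terms, collapse = " + ")
                               else "1")), data = pt)
  expect_equal(sort(coef(refit)), sort(coef(sel$best)), tolerance = 1e-12)
  expect_equal(AIC(refit), sel$aic, tolerance = 1e-10)
  expect_true(all(sel$candidates$delta_aic >= 0))
  expect_equal(min(sel$candidates$delta_aic), 0)
  expect_true(all(sel$candidates$delta_aic < 2))
})
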