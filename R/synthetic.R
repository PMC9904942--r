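#' Ground-truth configuration for the synthetic generator
#'
#' Defines the demographic model the synthetic data are drawn from. Defaults
#' emulate the Bristol Bay study system: seven river systems, brood years
#' 1960--2014, the four dominant age groups (1.2, 1.3, 2.2, 2.3), annual
#' returns of a few million fish per river, covariate-driven annual
#' size-at-age (negative effects of sockeye and pink salmon abundance,
#' positive winter / negative summer SST effects, quadratic abundance terms),
#' a slow logit drift in age composition away from 2.x fish, size-selective
#' harvest, and AL sampling of a few thousand fish per river and year.
#'
#' Linear covariate effects (`betas`) are in mm per raw predictor unit
#' (millions of fish, deg C) applied to the predictor centred at its
#' simulation-span mean; `<name>_sq` entries are quadratic curvatures in mm
#' per squared centred unit.
#'
#' @param rivers character vector of river tokens.
#' @param brood_years integer `c(first, last)` brood year.
#' @param age_groups age codes simulated.
#' @param baseline_mm named mean length (mm) per age group.
#' @param river_offset_mm named per-river additive offset (mm); default
#'   spreads rivers evenly over +/-9 mm.
#' @param betas named list of covariate effects (see above).
#' @param sigma_year SD (mm) of the shared annual size-at-age deviation not
#'   explained by covariates.
#' @param sigma_within SD (mm) of individual length around the cell mean.
#' @param comp_base named baseline age-composition shares (sum to 1).
#' @param comp_drift named logit drift per age group over the full span.
#' @param harvest_rate fraction of the run taken by the fishery.
#' @param sel_l50,sel_slope logistic length selectivity of the fishery:
#'   `P(sel | L) = plogis(sel_slope * (L - sel_l50))`; slope 0 disables
#'   size selection.
#' @param mean_return mean total return per river and brood year (fish).
#' @param cv_return lognormal CV of returns across years.
#' @param samples_escapement,samples_catch AL samples taken per river and
#'   return year from each source.
#' @param lw_a,lw_b,lw_cv true length-weight allometry `W = lw_a * L^lw_b`
#'   (g, mm) and the lognormal CV of individual mass around it; masses are
#'   recorded for catch samples, as in port sampling.
#' @param seed integer seed; one global stream drives every draw.
#' @return A list of class `truth_config`.
#' @export
truth_config <- function(rivers = default_config()$rivers,
                         brood_years = c(1960L, 2014L),
                         age_groups = c("1.2", "1.3", "2.2", "2.3"),
                         baseline_mm = c("1.2" = 505, "1.3" = 565,
                                         "2.2" = 515, "2.3" = 575),
                         river_offset_mm = NULL,
                         betas = list(sockeye_run = -0.25,
                                      sockeye_run_sq = -0.010,
                                      pink_lag1 = -0.05,
                                      pink_lag1_sq = -2e-4,
                                      sst_winter_aleutians = 4,
                                      sst_summer_bering_lag1 = -5),
                         sigma_year = 6,
                         sigma_within = 35,
                         comp_base = c("1.2" = 0.35, "1.3" = 0.38,
                                       "2.2" = 0.17, "2.3" = 0.10),
                         comp_drift = c("1.2" = 0.4, "1.3" = 0.4,
                                        "2.2" = -0.2, "2.3" = -0.8),
                         harvest_rate = 0.6,
                         sel_l50 = 530,
                         sel_slope = 0.02,
                         mean_return = 3e6,
                         cv_return = 0.4,
                         samples_escapement = 1800,
                         samples_catch = 2500,
                         lw_a = 1.1e-6,
                         lw_b = 3.4,
                         lw_cv = 0.08,
                         seed = 1L) {
  if (is.null(river_offset_mm)) {
    river_offset_mm <- stats::setNames(
      if (length(rivers) > 1) seq(-9, 9, length.out = length(rivers)) else 0,
      rivers)
  }
  stopifnot(all(age_groups %in% names(baseline_mm)),
            all(age_groups %in% names(comp_base)),
            abs(sum(comp_base[age_groups]) - 1) < 1e-8,
            sigma_year >= 0, sigma_within >= 0,
            harvest_rate >= 0, harvest_rate <= 1,
            all(baseline_mm > 0))
  cfg <- list(rivers = rivers, brood_years = as.integer(brood_years),
              age_groups = age_groups, baseline_mm = baseline_mm,
              river_offset_mm = river_offset_mm, betas = betas,
              sigma_year = sigma_year, sigma_within = sigma_within,
              comp_base = comp_base, comp_drift = comp_drift,
              harvest_rate = harvest_rate, sel_l50 = sel_l50,
              sel_slope = sel_slope, mean_return = mean_return,
              cv_return = cv_return,
              samples_escapement = samples_escapement,
              samples_catch = samples_catch,
              lw_a = lw_a, lw_b = lw_b, lw_cv = lw_cv,
              seed = as.integer(seed))
  class(cfg) <- "truth_config"
  cfg
}

#' Simulate the annual covariate series
#'
#' Monthly SSTs per ocean region are an AR(1) annual anomaly (partly shared
#' across regions, so regional series are strongly correlated) on top of a
#' seasonal cycle peaking in August. Pink and chum salmon abundances share a
#' rising trend and part of their interannual noise, reproducing the strong
#' mutual correlation of the real series that makes their effects hard to
#' separate; pink salmon carry an odd/even-year alternation from their
#' two-year life cycle. The Bristol Bay sockeye run rises towards recent
#' record returns; lake temperature warms slowly.
#'
#' @param years integer vector of calendar years (>= 10 years).
#' @param seed integer seed.
#' @return A validated [covariate_table][validate_covariates] tibble.
#' @export
simulate_covariates <- function(years, seed = 1L) {
  years <- sort(as.integer(years))
  if (length(years) < 10) stop("need at least 10 years", call. = FALSE)
  set.seed(as.integer(seed))
  n <- length(years)
  t01 <- (seq_len(n) - 1) / max(n - 1, 1)

  ar1 <- function(n, phi, sd) {
    x <- numeric(n)
    x[1] <- rnorm(1, 0, sd / sqrt(1 - phi^2))
    for (i in seq_len(n)[-1]) x[i] <- phi * x[i - 1] + rnorm(1, 0, sd)
    x
  }

  common_sst <- ar1(n, 0.6, 0.35)              # basin-scale annual anomaly
  region_mean <- c(bristol_bay = 6.0, bering_sea = 5.0,
                   gulf_of_alaska = 7.5, aleutians = 6.5)
  region_amp <- c(bristol_bay = 5.0, bering_sea = 4.0,
                  gulf_of_alaska = 3.5, aleutians = 3.0)
  out <- tibble::tibble(year = years)
  for (r in sst_regions()) {
    ann <- region_mean[[r]] + 0.5 * t01 + common_sst + ar1(n, 0.4, 0.2)
    for (m in 1:12) {
      seasonal <- region_amp[[r]] * cos(2 * pi * (m - 8) / 12)
      out[[sst_col(r, m)]] <- ann + seasonal + rnorm(n, 0, 0.15)
    }
  }

  # millions; a modest late rise on top of the large interannual swings
  # Bristol Bay runs show (keeps the run series distinguishable from the
  # steadily trending pink series, as in the observed predictor set)
  run_trend <- 27 + 9 * t01^2
  out$sockeye_run <- pmax(5, run_trend + ar1(n, 0.45, 8))

  pink_trend <- 250 + 250 * t01                 # millions, N Pacific total
  saw <- ifelse(years %% 2 == 1, 40, -40)       # odd-year dominance
  shared <- ar1(n, 0.4, 25)
  out$pink_abund <- pmax(50, pink_trend + saw + shared + rnorm(n, 0, 15))
  out$chum_abund <- pmax(20, 60 + 0.45 * (pink_trend + shared) + rnorm(n, 0, 12))

  out$lake_temp <- 11.5 + 1.2 * t01 + rnorm(n, 0, 0.5)
  validate_covariates(out)
}

# Raw-unit predictor values used both by the generator (to build the true
# signal) and by the covariate model (same definitions, independent code
# path there operates on standardized copies).
raw_signal_predictors <- function(covars, years, cfg = default_config()) {
  winter <- seasonal_sst(covars, "winter", "aleutians", lag = 0)
  summer <- seasonal_sst(covars, "summer", "bering_sea", lag = 1)
  tibble::tibble(
    year = years,
    sockeye_run = covars$sockeye_run[match(years, covars$year)],
    pink_lag1 = covars$pink_abund[match(years - 1, covars$year)],
    sst_winter_aleutians = winter$value[match(years, winter$year)],
    sst_summer_bering_lag1 = summer$value[match(years, summer$year)]
  )
}

#' True covariate signal and simulated annual anomaly response
#'
#' `anomaly_signal()` evaluates the deterministic part of the ground-truth
#' size-at-age model: each named effect in `betas` is applied to its raw
#' predictor centred at the span mean (`<name>_sq` entries to the squared
#' centred predictor). `simulate_anomaly_response()` adds the annual
#' deviation `N(0, sigma_year)` — this is exactly the data level the
#' covariate model sees, so it supports direct parameter-recovery
#' experiments without simulating individual fish.
#'
#' @param covars covariate table covering `years` (and `years - 1`).
#' @param years response years.
#' @param betas named effect list, as in [truth_config()].
#' @return `anomaly_signal()`: tibble `year`, `signal` (mm, centred on 0).
#' @export
anomaly_signal <- function(covars, years, betas) {
  preds <- raw_signal_predictors(covars, years)
  sig <- numeric(length(years))
  for (nm in names(betas)) {
    base <- sub("_sq$", "", nm)
    if (!base %in% names(preds)) {
      stop("unknown predictor in betas: ", nm, call. = FALSE)
    }
    x <- preds[[base]]
    if (anyNA(x)) stop("covariates do not cover years needed for ", base,
                       call. = FALSE)
    xc <- x - mean(x)
    sig <- sig + if (grepl("_sq$", nm)) betas[[nm]] * (xc^2 - mean(xc^2))
                 else betas[[nm]] * xc
  }
  tibble::tibble(year = years, signal = sig)
}

#' @rdname anomaly_signal
#' @param sigma_year annual noise SD (mm).
#' @param seed integer seed.
#' @return `simulate_anomaly_response()`: tibble `year`, `signal`,
#'   `response`.
#' @export
simulate_anomaly_response <- function(covars, years, betas, sigma_year,
                                      seed = 1L) {
  set.seed(as.integer(seed))
  sig <- anomaly_signal(covars, years, betas)
  sig$response <- sig$signal + rnorm(nrow(sig), 0, sigma_year)
  sig
}

#' Annual-noise SD giving a target signal R-squared
#'
#' Closed-form calibration: with signal variance `v`, noise SD
#' `sqrt(v * (1 - R2) / R2)` makes the covariates explain a fraction `R2` of
#' the response variance in expectation.
#'
#' @param signal numeric vector of the deterministic annual signal (mm).
#' @param target_r2 target fraction of variance explained.
#' @return noise SD (mm).
#' @export
calibrate_sigma_year <- function(signal, target_r2 = 0.6) {
  stopifnot(target_r2 > 0, target_r2 < 1)
  sd(signal) * sqrt((1 - target_r2) / target_r2)
}

# P(captured | fishery operates) for lengths L ~ N(mu, sd) under logistic
# selectivity, by fixed-grid quadrature (deterministic, no RNG use).
expected_selectivity <- function(mu, sd, l50, slope) {
  if (slope == 0) return(1)
  if (sd == 0) return(stats::plogis(slope * (mu - l50)))
  z <- seq(-5, 5, length.out = 201)
  w <- stats::dnorm(z); w <- w / sum(w)
  sum(w * stats::plogis(slope * (mu + sd * z - l50)))
}

# sample n lengths (integer mm) from density prop. to N(mu,sd) * wfun(l)
sample_lengths <- function(n, mu, sd, wfun = NULL) {
  if (n <= 0) return(integer(0))
  if (sd == 0) return(rep(round(mu), n))
  grid <- seq(round(mu - 6 * sd), round(mu + 6 * sd))
  dens <- stats::dnorm(grid, mu, sd)
  if (!is.null(wfun)) dens <- dens * wfun(grid)
  sample(grid, n, replace = TRUE, prob = dens)
}

#' Simulate a complete study system with known truth
#'
#' Generates, from one global seed stream, (i) brood tables whose counts are
#' the simulated returns by river, brood year and age group split into catch
#' and escapement via logistic size-selective harvest, (ii) AL samples drawn
#' from the corresponding catch and escapement length distributions, (iii)
#' run summaries by return year consistent with the brood tables to the
#' fish, and (iv) a truth record holding every cell's true mean length and
#' the annual signal. Individual lengths are Normal within an age group,
#' measured to the nearest mm.
#'
#' @param truth a [truth_config()].
#' @param covars covariate table from [simulate_covariates()]; must cover
#'   return years `brood_years[1] + 3` to `brood_years[2] + 6` and one year
#'   before the first return year.
#' @return list with `al_samples`, `brood_table`, `run_summary`, `covars`,
#'   and `truth` (config plus `cell_truth` and `year_effect` tables).
#' @export
simulate_population <- function(truth, covars) {
  stopifnot(inherits(truth, "truth_config"))
  cfg <- default_config()
  ages <- parse_age_code(truth$age_groups)
  ry_min <- truth$brood_years[1] + min(ages$total_age)
  ry_max <- truth$brood_years[2] + max(ages$total_age)
  need <- seq(ry_min - 1, ry_max)
  if (!all(need %in% covars$year)) {
    stop("covariates must cover years ", ry_min - 1, "-", ry_max, call. = FALSE)
  }

  set.seed(truth$seed)
  ret_years <- seq(ry_min, ry_max)
  sig <- anomaly_signal(covars, ret_years, truth$betas)
  year_eff <- tibble::tibble(
    return_year = ret_years,
    effect = sig$signal + rnorm(length(ret_years), 0, truth$sigma_year)
  )

  broods <- seq(truth$brood_years[1], truth$brood_years[2])
  span <- max(length(broods) - 1, 1)
  districts <- cfg$river_district

  cells <- list(); k <- 0
  for (r in truth$rivers) {
    for (y in broods) {
      # annual return and age split for this river/brood year
      tot <- truth$mean_return *
        exp(rnorm(1, -0.5 * log(1 + truth$cv_return^2),
                  sqrt(log(1 + truth$cv_return^2))))
      logit <- log(truth$comp_base[truth$age_groups]) +
        truth$comp_drift[truth$age_groups] * (y - broods[1]) / span
      p <- exp(logit) / sum(exp(logit))
      for (j in seq_along(truth$age_groups)) {
        a <- truth$age_groups[j]
        ry <- y + ages$total_age[j]
        mu <- truth$baseline_mm[[a]] + truth$river_offset_mm[[r]] +
          year_eff$effect[year_eff$return_year == ry]
        n_cell <- tot * p[j]
        psel <- expected_selectivity(mu, truth$sigma_within,
                                     truth$sel_l50, truth$sel_slope)
        catch_n <- n_cell * truth$harvest_rate * psel
        k <- k + 1
        cells[[k]] <- tibble::tibble(
          river = r, brood_year = y, age_code = a, return_year = ry,
          district = districts[[r]], mu = mu,
          escapement_count = n_cell - catch_n, catch_count = catch_n)
      }
    }
  }
  cells <- dplyr::bind_rows(cells)

  # AL sampling: per river, return year and source, a fixed number of fish
  # allocated across age groups proportional to their counts (>=1 per
  # non-empty cell so every cell is coverable).
  al <- list(); k <- 0
  for (r in truth$rivers) {
    sub_r <- cells[cells$river == r, ]
    for (ry in sort(unique(sub_r$return_year))) {
      sub <- sub_r[sub_r$return_year == ry, ]
      for (src in c("escapement", "catch")) {
        cnt <- if (src == "escapement") sub$escapement_count else sub$catch_count
        tot_n <- if (src == "escapement") truth$samples_escapement else truth$samples_catch
        if (sum(cnt) <= 0) next
        n_a <- pmax(ifelse(cnt > 0, 1L, 0L), round(tot_n * cnt / sum(cnt)))
        for (j in seq_len(nrow(sub))) {
          if (n_a[j] == 0) next
          wfun <- if (truth$sel_slope == 0) NULL else {
            if (src == "catch") {
              function(l) stats::plogis(truth$sel_slope * (l - truth$sel_l50))
            } else {
              h <- truth$harvest_rate
              function(l) 1 - h * stats::plogis(truth$sel_slope * (l - truth$sel_l50))
            }
          }
          len <- sample_lengths(n_a[j], sub$mu[j], truth$sigma_within, wfun)
          k <- k + 1
          al[[k]] <- tibble::tibble(
            river = r, return_year = ry, age_code = sub$age_code[j],
            length_mm = as.numeric(len), source = src,
            district = districts[[r]])
        }
      }
    }
  }
  al <- dplyr::bind_rows(al)
  al$mass_g <- NA_real_
  is_catch <- al$source == "catch"
  al$mass_g[is_catch] <- truth$lw_a * al$length_mm[is_catch]^truth$lw_b *
    exp(rnorm(sum(is_catch), 0, truth$lw_cv))

  brood <- validate_brood_table(
    cells[, c("river", "brood_year", "age_code",
              "escapement_count", "catch_count")])
  run <- cells |>
    dplyr::group_by(.data$river, .data$return_year) |>
    dplyr::summarise(catch = sum(.data$catch_count),
                     escapement = sum(.data$escapement_count),
                     .groups = "drop") |>
    validate_run_summary()

  truth_rec <- truth
  truth_rec$cell_truth <- cells
  truth_rec$year_effect <- year_eff
  truth_rec$signal <- sig

  list(al_samples = validate_al_samples(al),
       brood_table = brood,
       run_summary = run,
       covars = covars,
       truth = truth_rec)
}

#' Parameter-recovery experiment for the covariate model
#'
#' Repeatedly generates covariates, builds the annual anomaly response from
#' a known four-term model (negative linear and quadratic effects of the
#' sockeye run and of pink salmon abundance, with annual noise calibrated
#' to a target signal R-squared), runs the full collinearity-screened
#' all-subsets AIC selection against independent zero-effect temperature
#' decoys, and records whether every generating term was selected and what
#' the back-transformed coefficients were. Abundance predictors enter on
#' comparable per-unit scales (sockeye: millions; pink: tens of millions of
#' fish), so the two competition effects carry similar leverage, as in the
#' fitted study system.
#'
#' @param n_reps number of replicates.
#' @param n_years length of the response series.
#' @param betas true effects, as in [truth_config()]; default the
#'   experiment's reference conditions.
#' @param target_r2 signal R-squared the annual noise is calibrated to.
#' @param seed integer; replicate r uses seed `seed * 1000 + r`.
#' @return tibble with one row per replicate: logical columns per true
#'   term, `all_terms` (every true term selected), recovered raw-scale
#'   `est_*` and `se_*` for the linear effects, and the realized model
#'   `r_squared`.
#' @export
recovery_experiment <- function(n_reps = 200, n_years = 58,
                                betas = list(sockeye_run = -1.5,
                                             sockeye_run_sq = -0.16,
                                             pink_lag1 = -2,
                                             pink_lag1_sq = -0.16),
                                target_r2 = 0.6, seed = 1L) {
  true_terms <- ifelse(grepl("_sq$", names(betas)),
                       paste0("z_", sub("_sq$", "", names(betas)), "_sq"),
                       paste0("z_", names(betas)))
  cands <- c("sockeye_run", "pink_lag1", "sst_winter_aleutians",
             "sst_summer_bering_lag1", "lake_temp")
  years <- seq(2020 - n_years + 1, 2020)
  purrr::map_dfr(seq_len(n_reps), function(r) {
    s <- as.integer(seed) * 1000L + r
    covars <- simulate_covariates(seq(min(years) - 3, max(years)), seed = s)
    covars$pink_abund <- covars$pink_abund / 10
    sig <- anomaly_signal(covars, years, betas)
    resp <- simulate_anomaly_response(
      covars, years, betas,
      sigma_year = calibrate_sigma_year(sig$signal, target_r2),
      seed = s + 500L)
    an <- tibble::tibble(year = resp$year, mean_anomaly_mm = resp$response)
    preds <- build_predictors(covars, an)
    scr <- screen_collinearity(preds, candidates = cands)
    sel <- select_model(preds, screen = scr, regime_interactions = NULL)
    cf <- sel$coefficients
    g <- function(tt, col) {
      if (tt %in% cf$term) cf[[col]][cf$term == tt] else NA_real_
    }
    found <- stats::setNames(as.list(true_terms %in% sel$terms),
                             paste0("found_", names(betas)))
    tibble::tibble(
      rep = r, !!!found,
      all_terms = all(true_terms %in% sel$terms),
      est_pink = g("z_pink_lag1", "raw_estimate"),
      se_pink = g("z_pink_lag1", "raw_se"),
      est_sockeye = g("z_sockeye_run", "raw_estimate"),
      se_sockeye = g("z_sockeye_run", "raw_se"),
      r_squared = sel$r_squared)
  })
}
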