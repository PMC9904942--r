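filter_scope <- function(recon, scope) {
  if (identical(scope, "baywide")) return(recon)
  out <- recon[recon$river == scope, ]
  if (nrow(out) == 0) {
    stop("no reconstructed fish for scope '", scope, "'", call. = FALSE)
  }
  out
}

year_col <- function(year_basis) {
  match.arg(year_basis, c("brood", "return"))
  if (year_basis == "brood") "brood_year" else "return_year"
}

wmean <- function(x, w) sum(x * w) / sum(w)

#' Annual mean body size of the reconstructed return
#'
#' The weighted mean length over all reconstructed fish (catch and
#' escapement) in a year, for one river or bay-wide. Because weights are the
#' reconstructed population counts, the bay-wide mean is intrinsically
#' weighted by the catch/escapement split within rivers and by the relative
#' run sizes across rivers.
#'
#' @param recon a [reconstruct()]ed population.
#' @param scope `"baywide"` or a river token.
#' @param year_basis `"brood"` (default; avoids confounding by recruitment
#'   variation) or `"return"`.
#' @return tibble `year`, `mean_length_mm`, `n_fish`.
#' @export
mean_size <- function(recon, scope = "baywide", year_basis = "brood") {
  yc <- year_col(year_basis)
  filter_scope(recon, scope) |>
    dplyr::group_by(year = .data[[yc]]) |>
    dplyr::summarise(mean_length_mm = wmean(.data$length_mm, .data$weight),
                     n_fish = sum(.data$weight), .groups = "drop") |>
    dplyr::arrange(.data$year)
}

#' Long-term mean size per age group
#'
#' The reference sizes anomalies are measured against: the weighted mean
#' length of each age group over all years, per river (river scope) or
#' across rivers (bay-wide scope).
#'
#' @inheritParams mean_size
#' @return tibble `age_code`, `mean_length_mm`, `n_fish`.
#' @export
long_term_age_means <- function(recon, scope = "baywide") {
  filter_scope(recon, scope) |>
    dplyr::group_by(.data$age_code) |>
    dplyr::summarise(mean_length_mm = wmean(.data$length_mm, .data$weight),
                     n_fish = sum(.data$weight), .groups = "drop")
}

#' Annual mean size-at-age anomaly
#'
#' Each fish's anomaly is its length minus the long-term mean length of its
#' age group (within its river for river scope; across rivers for bay-wide
#' scope). The annual mean anomaly — the weight-proportional average of the
#' individual anomalies across age groups — is in mm, so it is directly
#' comparable to changes in mean size: it isolates the size-at-age component
#' of a mean-size trend from the age-structure component.
#'
#' @inheritParams mean_size
#' @return tibble `year`, `scope`, `year_basis`, `mean_anomaly_mm`, `n_fish`.
#' @export
size_at_age_anomalies <- function(recon, scope = "baywide",
                                  year_basis = "brood") {
  yc <- year_col(year_basis)
  sub <- filter_scope(recon, scope)
  ltm <- long_term_age_means(recon, scope)
  sub$anom <- sub$length_mm -
    ltm$mean_length_mm[match(sub$age_code, ltm$age_code)]
  sub |>
    dplyr::group_by(year = .data[[yc]]) |>
    dplyr::summarise(mean_anomaly_mm = wmean(.data$anom, .data$weight),
                     n_fish = sum(.data$weight), .groups = "drop") |>
    dplyr::mutate(scope = scope, year_basis = year_basis,
                  .before = "mean_anomaly_mm") |>
    dplyr::arrange(.data$year)
}

#' Annual mean ocean and freshwater age
#'
#' @inheritParams mean_size
#' @return tibble `year`, `mean_ocean_age`, `mean_fw_age`, `n_fish`.
#' @export
mean_ages <- function(recon, scope = "baywide", year_basis = "brood") {
  yc <- year_col(year_basis)
  filter_scope(recon, scope) |>
    dplyr::group_by(year = .data[[yc]]) |>
    dplyr::summarise(mean_ocean_age = wmean(.data$ocean_years, .data$weight),
                     mean_fw_age = wmean(.data$fw_years, .data$weight),
                     n_fish = sum(.data$weight), .groups = "drop") |>
    dplyr::arrange(.data$year)
}

#' Annual coefficient of variation of size-at-age
#'
#' Weighted population CV (SD/mean, with the population rather than sample
#' SD, since weights are reconstructed counts, not samples) of length within
#' one age group per year. Rising CVs are a signature of size-dependent
#' survival acting on the age group.
#'
#' @inheritParams mean_size
#' @param age_group a single age code, e.g. `"1.3"`.
#' @return tibble `year`, `cv`, `n_fish`.
#' @export
cv_size_at_age <- function(recon, age_group, scope = "baywide",
                           year_basis = "brood") {
  yc <- year_col(year_basis)
  sub <- filter_scope(recon, scope)
  sub <- sub[sub$age_code == age_group, ]
  if (nrow(sub) == 0) stop("no fish in age group ", age_group, call. = FALSE)
  sub |>
    dplyr::group_by(year = .data[[yc]]) |>
    dplyr::summarise(
      cv = {
        m <- wmean(.data$length_mm, .data$weight)
        sqrt(wmean((.data$length_mm - m)^2, .data$weight)) / m
      },
      n_fish = sum(.data$weight), .groups = "drop") |>
    dplyr::arrange(.data$year)
}

#' Fit the length-weight allometry W = a * S^b
#'
#' Nonlinear least squares on the mass scale (residuals in grams), with
#' starting values from the log-log linear fit — the standard, convergence-
#' safe initialisation for this model. `a` is the allometric scalar
#' (g mm^-b), `b` the allometric exponent (typically 3.2-3.6 for sockeye).
#'
#' @param length_mm,mass_g paired positive measurements (n >= 10).
#' @return object of class `length_weight_fit`: list with `a`, `b`, `n`,
#'   `sigma` (residual SD, g), and the underlying `nls` fit.
#' @export
fit_length_weight <- function(length_mm, mass_g) {
  ok <- !is.na(length_mm) & !is.na(mass_g)
  length_mm <- length_mm[ok]; mass_g <- mass_g[ok]
  if (length(length_mm) < 10) {
    stop("need at least 10 complete (length, mass) pairs", call. = FALSE)
  }
  if (any(length_mm <= 0) || any(mass_g <= 0)) {
    stop("lengths and masses must be positive", call. = FALSE)
  }
  ll <- lm(log(mass_g) ~ log(length_mm))
  start <- list(a = exp(coef(ll)[[1]]), b = coef(ll)[[2]])
  fit <- tryCatch(
    nls(mass_g ~ a * length_mm^b, start = start,
        control = stats::nls.control(maxiter = 200, warnOnly = FALSE,
                                     scaleOffset = 1)),
    error = function(e) {
      stop("length-weight fit did not converge (start: a=",
           signif(start$a, 4), ", b=", signif(start$b, 4), "): ",
           conditionMessage(e), call. = FALSE)
    })
  structure(list(a = coef(fit)[["a"]], b = coef(fit)[["b"]],
                 n = length(length_mm), sigma = summary(fit)$sigma,
                 fit = fit),
            class = "length_weight_fit")
}

#' @export
print.length_weight_fit <- function(x, ...) {
  cat(sprintf("Length-weight fit: W = %.4g * S^%.4f  (n = %d, residual SD = %.1f g)\n",
              x$a, x$b, x$n, x$sigma))
  invisible(x)
}

#' Convert lengths to masses with a fitted allometry
#'
#' `length_to_mass()` converts lengths (mm) to masses (g).
#' `length_series_to_mass()` applies the conversion to the annual mean
#' length of a [mean_size()] series — a deliberate simplification (Jensen
#' bias is ignored) that matches how bay-wide mass figures are usually
#' reported.
#'
#' @param length_mm positive lengths (mm).
#' @param fit a [fit_length_weight()] object.
#' @return masses in grams.
#' @export
length_to_mass <- function(length_mm, fit) {
  stopifnot(inherits(fit, "length_weight_fit"))
  if (any(length_mm <= 0)) stop("lengths must be positive", call. = FALSE)
  fit$a * length_mm^fit$b
}

#' @rdname length_to_mass
#' @param series tibble with `year` and `mean_length_mm` columns.
#' @return `length_series_to_mass()`: the series with `mean_mass_g` added.
#' @export
length_series_to_mass <- function(series, fit) {
  series$mean_mass_g <- length_to_mass(series$mean_length_mm, fit)
  series
}

#' Fishery selection differentials
#'
#' Mean length in the escapement minus mean length in the total run
#' (escapement + catch): the mean trait value after selection minus before.
#' Negative when the fishery removes larger fish. Computed per river and
#' return year, or bay-wide.
#'
#' @inheritParams mean_size
#' @return tibble `scope`, `return_year`, `sel_diff_mm`, plus the two means.
#' @export
selection_differentials <- function(recon, scope = "river") {
  sub <- if (identical(scope, "baywide")) {
    dplyr::mutate(recon, river = "baywide")
  } else recon
  sub |>
    dplyr::group_by(.data$river, .data$return_year) |>
    dplyr::summarise(
      run_mean_mm = wmean(.data$length_mm, .data$weight),
      esc_mean_mm = {
        e <- .data$source == "escapement"
        if (any(e)) wmean(.data$length_mm[e], .data$weight[e]) else NA_real_
      },
      .groups = "drop") |>
    dplyr::mutate(sel_diff_mm = .data$esc_mean_mm - .data$run_mean_mm) |>
    dplyr::rename(scope = "river") |>
    dplyr::arrange(.data$scope, .data$return_year)
}

#' Annual mean size-at-age by age group, and their correlations
#'
#' `annual_size_at_age()` returns the annual weighted mean length per age
#' group (wide, one column per age group). `age_group_correlations()`
#' computes the pairwise Pearson correlations of these series over
#' pairwise-complete years, plus their average — high values indicate a
#' shared (environmental) driver of growth across age groups.
#'
#' @inheritParams mean_size
#' @return `age_group_correlations()`: list with `matrix` and `average`
#'   (mean off-diagonal correlation).
#' @export
age_group_correlations <- function(recon, scope = "baywide",
                                   year_basis = "return") {
  wide <- annual_size_at_age(recon, scope, year_basis)
  m <- as.matrix(wide[, -1, drop = FALSE])
  cm <- cor(m, use = "pairwise.complete.obs", method = "pearson")
  avg <- mean(cm[upper.tri(cm)])
  list(matrix = cm, average = avg)
}

#' @rdname age_group_correlations
#' @return `annual_size_at_age()`: tibble `year` then one column per age
#'   group.
#' @export
annual_size_at_age <- function(recon, scope = "baywide",
                               year_basis = "return") {
  yc <- year_col(year_basis)
  filter_scope(recon, scope) |>
    dplyr::group_by(year = .data[[yc]], .data$age_code) |>
    dplyr::summarise(m = wmean(.data$length_mm, .data$weight),
                     .groups = "drop") |>
    tidyr::pivot_wider(names_from = "age_code", values_from = "m") |>
    dplyr::arrange(.data$year)
}
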