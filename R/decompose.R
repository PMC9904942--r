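#' Mean of an annual series over a window of years
#'
#' Each year counts once (no abundance weighting): the windows being
#' compared are short and the comparison is between periods, not fish.
#' Years missing from the series are dropped with a warning.
#'
#' @param series tibble with a `year` column and one value column (the
#'   first non-year numeric column is used), e.g. from [mean_size()].
#' @param window integer vector of years.
#' @return scalar mean.
#' @export
window_mean <- function(series, window) {
  vcol <- setdiff(names(series), c("year", "scope", "year_basis", "n_fish"))[1]
  present <- intersect(window, series$year)
  if (length(present) == 0) stop("no window years present in series", call. = FALSE)
  if (length(present) < length(window)) {
    warning("window year(s) missing from series: ",
            paste(setdiff(window, present), collapse = ", "), call. = FALSE)
  }
  mean(series[[vcol]][series$year %in% present])
}

#' Decompose mean-size change into size-at-age and age-structure parts
#'
#' Total size change is the difference in mean length between a late and an
#' early window of years. The size-at-age contribution is the corresponding
#' difference in mean size-at-age anomaly (also in mm, so directly
#' comparable); the age-structure contribution is the remainder, exactly:
#' `delta_age_structure = delta_mean_size - delta_saa`.
#'
#' @param mean_size_series annual mean size, from [mean_size()].
#' @param anomaly_series annual mean anomaly, from
#'   [size_at_age_anomalies()] on the same scope and year basis.
#' @param early,late non-overlapping integer year windows.
#' @return one-row tibble of class `size_decomposition`: `early_start`,
#'   `late_start`, window ends, `delta_mean_size_mm`, `delta_saa_mm`,
#'   `delta_age_structure_mm`.
#' @export
decompose_size_change <- function(mean_size_series, anomaly_series,
                                  early, late) {
  if (length(intersect(early, late)) > 0) {
    stop("early and late windows overlap", call. = FALSE)
  }
  d_mean <- window_mean(mean_size_series, late) -
    window_mean(mean_size_series, early)
  d_saa <- window_mean(anomaly_series, late) -
    window_mean(anomaly_series, early)
  out <- tibble::tibble(
    early_start = min(early), early_end = max(early),
    late_start = min(late), late_end = max(late),
    delta_mean_size_mm = d_mean,
    delta_saa_mm = d_saa,
    delta_age_structure_mm = d_mean - d_saa)
  class(out) <- c("size_decomposition", class(out))
  out
}

#' Rolling retrospective decomposition
#'
#' Re-runs [decompose_size_change()] with the first `window` years of the
#' record as the fixed base and every subsequent rolling `window`-year
#' period as the late window, showing how the size-at-age and age-structure
#' contributions developed through time. The final row equals the single
#' early-vs-last decomposition.
#'
#' @inheritParams decompose_size_change
#' @param window window length in years (default 5).
#' @return tibble of decompositions, one row per terminal year.
#' @export
retrospective_decomposition <- function(mean_size_series, anomaly_series,
                                        window = 5L) {
  years <- sort(intersect(mean_size_series$year, anomaly_series$year))
  if (length(years) < 2 * window) {
    stop("series too short for a ", window, "-year retrospective", call. = FALSE)
  }
  base <- years[seq_len(window)]
  ends <- years[years >= years[window] + window]
  purrr::map_dfr(ends, function(e) {
    late <- seq(e - window + 1L, e)
    decompose_size_change(mean_size_series, anomaly_series, base, late)
  })
}
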