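#' @keywords internal
#' @noRd
sst_regions <- function() c("bristol_bay", "bering_sea", "gulf_of_alaska", "aleutians")

#' @keywords internal
#' @noRd
sst_col <- function(region, month) sprintf("sst_%s_%02d", region, month)

require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop(what, ": missing required column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  invisible(df)
}

fail_rows <- function(bad, what, reason) {
  if (any(bad)) {
    stop(what, ": ", reason, " in row(s) ",
         paste(utils::head(which(bad), 20), collapse = ", "),
         if (sum(bad) > 20) sprintf(" (and %d more)", sum(bad) - 20) else "",
         call. = FALSE)
  }
}

#' Validate a table of individual age-length samples
#'
#' AL samples are individual fish measured (mid-eye-to-fork length, mm) and
#' aged (scale reading) in either the commercial catch or the escapement.
#' Validation is total: a returned table contains no record violating the
#' schema; offending rows abort with their row numbers.
#'
#' @param df data frame with columns `river`, `return_year`, `age_code`,
#'   `length_mm`, `source` (`"catch"` or `"escapement"`); optional `mass_g`,
#'   `district`.
#' @param year_range optional integer `c(min, max)` admissible return years.
#' @return A validated tibble (class `al_samples`).
#' @export
validate_al_samples <- function(df, year_range = NULL) {
  require_columns(df, c("river", "return_year", "age_code", "length_mm", "source"),
                  "AL samples")
  df <- tibble::as_tibble(df)
  if (!"mass_g" %in% names(df)) df$mass_g <- NA_real_
  if (!"district" %in% names(df)) df$district <- NA_character_
  df$return_year <- as.integer(df$return_year)
  df$length_mm <- as.numeric(df$length_mm)
  if (nrow(df) == 0) {
    warning("AL sample table is empty", call. = FALSE)
    return(structure(df, class = c("al_samples", class(df))))
  }
  fail_rows(!is_valid_age_code(df$age_code), "AL samples", "unparseable age_code")
  fail_rows(!(df$source %in% c("catch", "escapement")), "AL samples",
            "source not in {catch, escapement}")
  fail_rows(is.na(df$length_mm) | df$length_mm <= 100 | df$length_mm >= 1000,
            "AL samples", "length_mm outside (100, 1000)")
  fail_rows(!is.na(df$mass_g) & df$mass_g <= 0, "AL samples", "non-positive mass_g")
  if (!is.null(year_range)) {
    fail_rows(df$return_year < year_range[1] | df$return_year > year_range[2],
              "AL samples", "return_year outside configured range")
  }
  structure(df, class = c("al_samples", setdiff(class(df), "al_samples")))
}

#' Read age-length samples from CSV
#'
#' @param path CSV file with header matching the AL sample schema.
#' @inheritParams validate_al_samples
#' @return A validated tibble of AL samples.
#' @export
read_al_samples <- function(path, year_range = NULL) {
  validate_al_samples(read_csv_strict(path), year_range = year_range)
}

#' Validate / read a brood table
#'
#' A brood table apportions the fish returning in each calendar year to the
#' brood years (parental spawning years) and age groups they came from, for
#' one or more rivers, split into fish caught by the fishery and fish that
#' escaped to spawn. Counts come from run reconstructions and may be
#' non-integer; they are only rounded at resampling time.
#'
#' @param df data frame with columns `river`, `brood_year`, `age_code`,
#'   `escapement_count`, `catch_count`.
#' @return A validated tibble (class `brood_table`) with a `total_count`
#'   column added.
#' @export
validate_brood_table <- function(df) {
  require_columns(df, c("river", "brood_year", "age_code", "escapement_count",
                        "catch_count"), "brood table")
  df <- tibble::as_tibble(df)
  df$brood_year <- as.integer(df$brood_year)
  df$escapement_count <- as.numeric(df$escapement_count)
  df$catch_count <- as.numeric(df$catch_count)
  fail_rows(!is_valid_age_code(df$age_code), "brood table", "unparseable age_code")
  fail_rows(is.na(df$escapement_count) | df$escapement_count < 0,
            "brood table", "negative or missing escapement_count")
  fail_rows(is.na(df$catch_count) | df$catch_count < 0,
            "brood table", "negative or missing catch_count")
  key <- paste(df$river, df$brood_year, df$age_code)
  if (anyDuplicated(key)) {
    stop("brood table: duplicated (river, brood_year, age_code) key(s): ",
         paste(utils::head(unique(key[duplicated(key)]), 5), collapse = "; "),
         call. = FALSE)
  }
  df$total_count <- df$escapement_count + df$catch_count
  structure(df, class = c("brood_table", setdiff(class(df), "brood_table")))
}

#' @rdname validate_brood_table
#' @param path CSV file path.
#' @export
read_brood_table <- function(path) {
  validate_brood_table(read_csv_strict(path))
}

#' Validate / read per-river annual run summaries
#'
#' @param df data frame with columns `river`, `return_year`, `catch`,
#'   `escapement`.
#' @return A validated tibble with `run = catch + escapement`.
#' @export
validate_run_summary <- function(df) {
  require_columns(df, c("river", "return_year", "catch", "escapement"),
                  "run summary")
  df <- tibble::as_tibble(df)
  df$return_year <- as.integer(df$return_year)
  fail_rows(is.na(df$catch) | df$catch < 0, "run summary", "negative catch")
  fail_rows(is.na(df$escapement) | df$escapement < 0, "run summary",
            "negative escapement")
  df$run <- df$catch + df$escapement
  df
}

#' @rdname validate_run_summary
#' @param path CSV file path.
#' @export
read_run_summary <- function(path) validate_run_summary(read_csv_strict(path))

#' Validate / read the annual covariate table
#'
#' One row per calendar year carrying the ecological and climate covariates:
#' total Bristol Bay sockeye run (`sockeye_run`, millions of fish), North
#' Pacific pink and chum salmon abundances (`pink_abund`, `chum_abund`,
#' millions), summer lake temperature (`lake_temp`, deg C), and monthly mean
#' SST columns `sst_<region>_<mm>` for the four ocean regions
#' (`bristol_bay`, `bering_sea`, `gulf_of_alaska`, `aleutians`). The year
#' span must be contiguous.
#'
#' @param df data frame as described.
#' @return A validated tibble (class `covariate_table`).
#' @export
validate_covariates <- function(df) {
  require_columns(df, c("year", "sockeye_run", "pink_abund", "chum_abund",
                        "lake_temp"), "covariates")
  sst_cols <- as.vector(outer(sst_regions(), 1:12, sst_col))
  require_columns(df, sst_cols, "covariates")
  df <- tibble::as_tibble(df)
  df$year <- as.integer(df$year)
  if (anyDuplicated(df$year)) stop("covariates: duplicated year(s)", call. = FALSE)
  df <- dplyr::arrange(df, .data$year)
  gaps <- setdiff(seq(min(df$year), max(df$year)), df$year)
  if (length(gaps)) {
    stop("covariates: missing year(s) inside the span: ",
         paste(gaps, collapse = ", "), call. = FALSE)
  }
  num_cols <- c("sockeye_run", "pink_abund", "chum_abund", "lake_temp", sst_cols)
  for (cl in num_cols) {
    if (!is.numeric(df[[cl]])) {
      stop("covariates: non-numeric value(s) in column ", cl, call. = FALSE)
    }
    fail_rows(is.na(df[[cl]]), "covariates", paste0("missing value in ", cl))
  }
  structure(df, class = c("covariate_table", setdiff(class(df), "covariate_table")))
}

#' @rdname validate_covariates
#' @param path CSV file path.
#' @export
read_covariates <- function(path) validate_covariates(read_csv_strict(path))

read_csv_strict <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  # pin types that guessing gets wrong: age codes look numeric, all-NA
  # mass columns look logical
  pinned <- c(age_code = "c", river = "c", district = "c", source = "c",
              mass_g = "d")
  hdr <- names(readr::read_csv(path, n_max = 0, show_col_types = FALSE,
                               progress = FALSE))
  spec <- do.call(readr::cols,
                  c(lapply(pinned[names(pinned) %in% hdr], identity),
                    .default = readr::col_guess()))
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                  col_types = spec)
}

#' Write a validated table to CSV
#'
#' Plain UTF-8 CSV with header, `.` decimal, one record per row; reading the
#' file back reproduces the table field-for-field.
#'
#' @param df table to write.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_table_csv <- function(df, path) {
  df <- as.data.frame(df)
  drop <- intersect(c("total_count", "run"), names(df)) # derived columns
  df <- df[, setdiff(names(df), drop), drop = FALSE]
  readr::write_csv(df, path, progress = FALSE)
  invisible(path)
}

#' Default pipeline configuration
#'
#' Returns the configuration list used throughout the pipeline: year ranges,
#' the seven river systems analysed and their fishing districts, the four SST
#' region tokens (with the lat/lon boxes they were averaged over, recorded
#' for provenance), covariate lags and the analysis window length.
#'
#' @return A named list; see `str(default_config())`.
#' @export
default_config <- function() {
  list(
    brood_years = c(1960L, 2014L),
    rivers = c("igushik", "wood", "nushagak", "kvichak", "naknek",
               "egegik", "ugashik"),
    river_district = list(
      igushik = "nushagak", wood = "nushagak", nushagak = "nushagak",
      kvichak = "naknek_kvichak", naknek = "naknek_kvichak",
      egegik = "egegik", ugashik = "ugashik"
    ),
    age_groups = c("1.2", "1.3", "2.2", "2.3"),
    sst_regions = list(
      bristol_bay    = "56.2-60N 157.5-163.1W",
      bering_sea     = "54.3-60N 165-180W",
      gulf_of_alaska = "46.7-52.4N 157.5-172.5W",
      aleutians      = "50.5-58.1N 159.4-180W"
    ),
    window_years = 5L,
    regime_split = 1988L,          # pre <= 1988 < post (1988-1989 regime shift)
    lake_temp_lag = 2L,            # freshwater rearing ~2 y before return
    collinearity_threshold = 0.5
  )
}

#' Read a YAML pipeline configuration
#'
#' Values present in the file override [default_config()]; everything else
#' keeps its default.
#'
#' @param path YAML file path.
#' @return configuration list.
#' @export
read_config <- function(path) {
  cfg <- default_config()
  user <- yaml::read_yaml(path)
  utils::modifyList(cfg, user)
}
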