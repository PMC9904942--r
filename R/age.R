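#' Parse European-notation age codes
#'
#' Sockeye ages are recorded as `"f.o"` where `f` is years spent rearing in
#' fresh water and `o` is years spent at sea. Total age adds one further year
#' for the embryo incubating in the gravel, so e.g. a 2.3 fish is 6 years old
#' in total. Accepted codes have `f` in 0--3 (0 covers river-type fish such
#' as those of the Nushagak) and `o` in 1--4.
#'
#' @param code character vector of age codes, e.g. `"1.3"`.
#' @return A tibble with one row per code: `age_code`, `fw_years`,
#'   `ocean_years`, `total_age`.
#' @examples
#' parse_age_code(c("1.2", "2.3"))
#' @export
parse_age_code <- function(code) {
  code <- as.character(code)
  ok <- is_valid_age_code(code)
  if (any(!ok)) {
    bad <- unique(code[!ok])
    stop("unparseable age code(s): ", paste(utils::head(bad, 10), collapse = ", "),
         call. = FALSE)
  }
  fw <- as.integer(sub("\\..*$", "", code))
  oc <- as.integer(sub("^.*\\.", "", code))
  tibble::tibble(
    age_code = code,
    fw_years = fw,
    ocean_years = oc,
    total_age = fw + oc + 1L
  )
}

#' @rdname parse_age_code
#' @return `is_valid_age_code()`: logical vector.
#' @export
is_valid_age_code <- function(code) {
  grepl("^[0-3]\\.[1-4]$", as.character(code))
}

#' Assign a return-year observation to its brood year
#'
#' The brood year is the calendar year a cohort's parents spawned:
#' `brood_year = return_year - total_age`. Working by brood year removes the
#' confounding of mean-size trends with recruitment variation that a
#' return-year accounting suffers from.
#'
#' @param return_year integer vector of return (calendar) years.
#' @param age age codes (character `"f.o"`) or a tibble from
#'   [parse_age_code()]; recycled against `return_year`.
#' @return integer vector of brood years.
#' @examples
#' assign_brood_year(2020, "1.3") # 2015
#' @export
assign_brood_year <- function(return_year, age) {
  if (is.character(age)) age <- parse_age_code(age)
  as.integer(return_year) - as.integer(age$total_age)
}
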