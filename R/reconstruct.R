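#' Largest-remainder integer rounding
#'
#' Rounds a nonnegative real vector to integers that sum to
#' `round(sum(x))`: floors first, then distributes the remaining units to
#' the largest fractional parts (ties to earlier elements, so the result is
#' deterministic). Used to round brood-table counts within a (river, brood
#' year) so totals are conserved.
#'
#' @param x nonnegative numeric vector.
#' @return integer-valued numeric vector, `sum == round(sum(x))`.
#' @export
largest_remainder_round <- function(x) {
  stopifnot(all(x >= 0))
  total <- round(sum(x))
  fl <- floor(x)
  rem <- total - sum(fl)
  if (rem > 0) {
    frac <- x - fl
    idx <- order(frac, decreasing = TRUE)[seq_len(rem)]
    fl[idx] <- fl[idx] + 1
  }
  fl
}

# pool lookup keys
.key <- function(...) paste(..., sep = "\r")

#' Reconstruct complete age-length populations
#'
#' Expands AL samples into the full returning population: for every (river,
#' brood year, age group) cell of the brood table, `escapement_count` fish
#' are drawn with replacement from that river's escapement AL samples of the
#' matching return year and age group, and `catch_count` fish from the
#' catch AL samples of the river's fishing district (catch samples cannot be
#' allocated to natal rivers, so district pools are used). Draws are a
#' weighted multinomial over the eligible sample pool — statistically
#' identical to resampling fish one by one, but stored as (length, weight)
#' rows instead of billions of individuals.
#'
#' When a pool is empty a fallback ladder applies: (1) the river's AL
#' samples of that return year and age pooled over source; (2) the
#' district's catch samples; (3) the cell part is dropped and recorded in
#' the coverage manifest (`attr(x, "manifest")`, also via
#' [coverage_manifest()]).
#'
#' @param al validated AL sample table.
#' @param brood validated brood table.
#' @param river_district named list/vector mapping river to district token.
#' @param seed integer seed; the reconstruction is deterministic given it.
#' @return A tibble of class `recon_pop` with columns `river`, `brood_year`,
#'   `return_year`, `age_code`, `fw_years`, `ocean_years`, `total_age`,
#'   `source` (run component: caught vs escaped), `length_mm`, `weight`.
#' @export
reconstruct <- function(al, brood,
                        river_district = default_config()$river_district,
                        seed = 1L) {
  if (!inherits(al, "al_samples")) al <- validate_al_samples(al)
  if (!inherits(brood, "brood_table")) brood <- validate_brood_table(brood)
  set.seed(as.integer(seed))

  ages <- parse_age_code(brood$age_code)
  brood$return_year <- brood$brood_year + ages$total_age
  brood$district <- unlist(river_district[brood$river], use.names = FALSE)
  if (anyNA(brood$district)) {
    stop("river(s) missing from river_district map: ",
         paste(unique(brood$river[is.na(brood$district)]), collapse = ", "),
         call. = FALSE)
  }
  al_district <- unlist(river_district[al$river], use.names = FALSE)
  al$district <- ifelse(is.na(al$district), al_district, al$district)

  # integer counts conserving (river, brood year) totals
  brood <- brood |>
    dplyr::group_by(.data$river, .data$brood_year) |>
    dplyr::mutate(esc_n = largest_remainder_round(.data$escapement_count),
                  cat_n = largest_remainder_round(.data$catch_count)) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$river, .data$brood_year, .data$age_code)

  # prebuilt sample-pool indices
  esc_pool <- split(seq_len(nrow(al)),
                    .key(al$source, al$river, al$return_year, al$age_code))
  river_pool <- split(seq_len(nrow(al)),
                      .key(al$river, al$return_year, al$age_code))
  catch_idx <- which(al$source == "catch")
  dist_pool <- split(catch_idx,
                     .key(al$district[catch_idx], al$return_year[catch_idx],
                          al$age_code[catch_idx]))

  draw <- function(pool, n) {
    w <- as.vector(rmultinom(1, n, rep(1, length(pool))))
    keep <- w > 0
    list(idx = pool[keep], weight = w[keep])
  }

  out <- vector("list", 2L * nrow(brood))
  man <- vector("list", 2L * nrow(brood))
  k <- 0
  for (i in seq_len(nrow(brood))) {
    b <- brood[i, ]
    for (part in c("escapement", "catch")) {
      n <- if (part == "escapement") b$esc_n else b$cat_n
      k <- k + 1
      if (n == 0) next
      ladder <- if (part == "escapement") {
        list(primary = esc_pool[[.key("escapement", b$river, b$return_year, b$age_code)]],
             river_pooled = river_pool[[.key(b$river, b$return_year, b$age_code)]],
             district_catch = dist_pool[[.key(b$district, b$return_year, b$age_code)]])
      } else {
        list(primary = dist_pool[[.key(b$district, b$return_year, b$age_code)]],
             river_pooled = river_pool[[.key(b$river, b$return_year, b$age_code)]])
      }
      level <- "dropped"; pool <- NULL
      for (lv in names(ladder)) {
        if (length(ladder[[lv]]) > 0) { level <- lv; pool <- ladder[[lv]]; break }
      }
      if (level != "primary") {
        man[[k]] <- tibble::tibble(
          river = b$river, brood_year = b$brood_year, age_code = b$age_code,
          part = part, requested = n, fallback = level,
          pool_size = length(pool %||% integer(0)))
      }
      if (is.null(pool)) next
      d <- draw(pool, n)
      out[[k]] <- tibble::tibble(
        river = b$river, brood_year = b$brood_year,
        return_year = b$return_year, age_code = b$age_code,
        source = part, length_mm = al$length_mm[d$idx], weight = d$weight)
    }
  }
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0) {
    res <- tibble::tibble(river = character(), brood_year = integer(),
                          return_year = integer(), age_code = character(),
                          source = character(), length_mm = numeric(),
                          weight = numeric())
  }
  aa <- parse_age_code(res$age_code)
  res$fw_years <- aa$fw_years
  res$ocean_years <- aa$ocean_years
  res$total_age <- aa$total_age
  res <- res[, c("river", "brood_year", "return_year", "age_code",
                 "fw_years", "ocean_years", "total_age", "source",
                 "length_mm", "weight")]
  manifest <- dplyr::bind_rows(man)
  if (nrow(manifest) == 0) {
    manifest <- tibble::tibble(river = character(), brood_year = integer(),
                               age_code = character(), part = character(),
                               requested = numeric(), fallback = character(),
                               pool_size = integer())
  }
  dropped <- manifest[manifest$fallback == "dropped", ]
  if (nrow(dropped) > 0) {
    warning(sprintf("%d cell part(s) dropped for lack of eligible AL samples (see coverage_manifest())",
                    nrow(dropped)), call. = FALSE)
  }
  structure(res, class = c("recon_pop", class(res)), manifest = manifest)
}

#' @rdname reconstruct
#' @param x a reconstructed population.
#' @return `coverage_manifest()`: tibble of cell parts that needed a
#'   fallback pool or were dropped.
#' @export
coverage_manifest <- function(x) {
  stopifnot(inherits(x, "recon_pop"))
  attr(x, "manifest")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
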