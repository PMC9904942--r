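# small deterministic fixtures, built in code

tiny_al <- function() {
  validate_al_samples(tibble::tibble(
    river = rep("wood", 6),
    return_year = rep(2000L, 6),
    age_code = rep(c("1.2", "1.3"), each = 3),
    length_mm = c(500, 510, 520, 560, 570, 580),
    source = rep(c("escapement", "escapement", "catch"), 2),
    district = "nushagak"
  ))
}

tiny_brood <- function() {
  validate_brood_table(tibble::tibble(
    river = "wood",
    brood_year = c(1996L, 1996L),
    age_code = c("1.2", "1.3"),
    escapement_count = c(600, 300),
    catch_count = c(400, 200)
  ))
}

# minimal reconstructed-population tibble for metric tests
recon_rows <- function(river, brood_year, age_code, source, length_mm, weight) {
  aa <- parse_age_code(age_code)
  tibble::tibble(
    river = river, brood_year = as.integer(brood_year),
    return_year = as.integer(brood_year) + aa$total_age,
    age_code = age_code, fw_years = aa$fw_years,
    ocean_years = aa$ocean_years, total_age = aa$total_age,
    source = source, length_mm = length_mm, weight = weight)
}

# one small simulated system, computed once per test run
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      tc <- truth_config(rivers = c("wood", "kvichak"),
                         brood_years = c(1984L, 2008L),
                         mean_return = 1e5,
                         samples_escapement = 250, samples_catch = 350,
                         seed = 42)
      cov <- simulate_covariates(1981:2015, seed = 42)
      sim <- simulate_population(tc, cov)
      sim$recon <- suppressWarnings(
        reconstruct(sim$al_samples, sim$brood_table, seed = 43))
      cache <<- sim
    }
    cache
  }
})

# brute-force expansion of a weighted reconstruction to individual fish
expand_recon <- function(recon) {
  recon$weight <- as.integer(round(recon$weight))
  tidyr::uncount(tibble::as_tibble(recon), weights = weight)
}

# tapply that returns a plain named vector (drops the 1-d array dim)
tap <- function(x, g, f = mean) c(tapply(x, g, f))
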