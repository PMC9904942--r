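#' Seasonal SST means from the monthly series
#'
#' Winter is January--March, summer July--September. `lag` shifts the value
#' forward: the lag-1 summer series assigns to return year `y` the Jul--Sep
#' mean of year `y - 1` (the previous summer at sea).
#'
#' @param covars validated covariate table.
#' @param season `"winter"` or `"summer"`.
#' @param region one of the four SST region tokens.
#' @param lag nonnegative integer lag in years.
#' @return tibble `year` (the year the value is assigned to), `value` (deg C).
#' @export
seasonal_sst <- function(covars, season = c("winter", "summer"),
                         region, lag = 0L) {
  season <- match.arg(season)
  region <- match.arg(region, sst_regions())
  months <- if (season == "winter") 1:3 else 7:9
  cols <- sst_col(region, months)
  missing <- setdiff(cols, names(covars))
  if (length(missing)) {
    stop("missing monthly SST column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  vals <- rowMeans(as.matrix(covars[, cols]))
  if (anyNA(vals)) {
    bad <- covars$year[is.na(vals)]
    stop("missing SST month for region ", region, " in year(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  tibble::tibble(year = covars$year + as.integer(lag), value = vals)
}

#' Assemble the covariate-model predictor table
#'
#' Builds, for each return year, the candidate predictors of the bay-wide
#' size-at-age anomaly: same-year Bristol Bay sockeye run; North Pacific
#' pink and chum abundance at lags 1 and 2 (conditions experienced at sea by
#' both ocean-2 and ocean-3 fish); winter SST around the Aleutians in the
#' return year and summer SST in the Bering Sea the previous year; summer
#' lake temperature at the configured freshwater-rearing lag; fishery
#' selection differentials at lags 4 and 5 (about one generation) and their
#' average; and the pre/post 1988--1989 climate-regime factor. Rows are
#' restricted to years where every candidate exists. Each numeric predictor
#' gets a standardized copy `z_<name>` (fitted-range mean/SD, stored in
#' `attr(, "scaling")` for back-transformation) and a quadratic column
#' `z_<name>_sq` equal to the squared standardized value (standardizing
#' before squaring decorrelates the linear and quadratic terms).
#'
#' @param covars validated covariate table.
#' @param anomalies return-year anomaly series from
#'   [size_at_age_anomalies()] (`year_basis = "return"`).
#' @param sel_diffs optional bay-wide selection differentials from
#'   [selection_differentials()] (`scope = "baywide"`); selection terms are
#'   omitted if `NULL`.
#' @param cfg configuration list, see [default_config()].
#' @return tibble of class `predictor_table`: `year`, `response`, raw
#'   predictor columns, `regime`, `z_*` and `z_*_sq` columns.
#' @export
build_predictors <- function(covars, anomalies, sel_diffs = NULL,
                             cfg = default_config()) {
  yrs <- anomalies$year
  winter <- seasonal_sst(covars, "winter", "aleutians", lag = 0)
  summer <- seasonal_sst(covars, "summer", "bering_sea", lag = 1)
  raw <- tibble::tibble(
    year = yrs,
    response = anomalies$mean_anomaly_mm,
    sockeye_run = covars$sockeye_run[match(yrs, covars$year)],
    pink_lag1 = covars$pink_abund[match(yrs - 1, covars$year)],
    pink_lag2 = covars$pink_abund[match(yrs - 2, covars$year)],
    chum_lag1 = covars$chum_abund[match(yrs - 1, covars$year)],
    chum_lag2 = covars$chum_abund[match(yrs - 2, covars$year)],
    sst_winter_aleutians = winter$value[match(yrs, winter$year)],
    sst_summer_bering_lag1 = summer$value[match(yrs, summer$year)],
    lake_temp = covars$lake_temp[match(yrs - cfg$lake_temp_lag, covars$year)]
  )
  if (!is.null(sel_diffs)) {
    sd_ <- sel_diffs$sel_diff_mm
    sy <- sel_diffs$return_year
    raw$sel_diff_lag4 <- sd_[match(yrs - 4, sy)]
    raw$sel_diff_lag5 <- sd_[match(yrs - 5, sy)]
    raw$sel_diff_lag45mean <- (raw$sel_diff_lag4 + raw$sel_diff_lag5) / 2
  }
  raw <- raw[complete.cases(raw), ]
  if (nrow(raw) < 10) stop("fewer than 10 complete predictor years", call. = FALSE)
  raw$regime <- factor(ifelse(raw$year <= cfg$regime_split, "pre", "post"),
                       levels = c("pre", "post"))
  preds <- setdiff(names(raw), c("year", "response", "regime"))
  scaling <- tibble::tibble(predictor = preds,
                            center = vapply(raw[preds], mean, 0),
                            scale = vapply(raw[preds], sd, 0))
  for (p in preds) {
    z <- (raw[[p]] - scaling$center[scaling$predictor == p]) /
      scaling$scale[scaling$predictor == p]
    raw[[paste0("z_", p)]] <- z
    raw[[paste0("z_", p, "_sq")]] <- z^2
  }
  structure(raw, class = c("predictor_table", class(raw)), scaling = scaling)
}

#' Pairwise collinearity screen
#'
#' Computes Pearson correlations between all raw candidate predictors and
#' emits the constraint list: no candidate model may contain two predictors
#' correlated above the threshold in absolute value. Competing
#' predictor families that are collinear across the board (pink vs chum
#' abundance) are resolved up front by marginal variance explained: the
#' family whose best single-predictor regression on the response has the
#' higher R-squared is kept, the other excluded from the candidate set.
#'
#' @param pred_table a [build_predictors()] table.
#' @param threshold absolute-correlation threshold (default 0.5).
#' @param families named list of competing predictor families to resolve by
#'   univariate R-squared (default pink vs chum).
#' @param candidates optional character vector restricting which predictors
#'   are screened (default: every predictor in the table); family
#'   resolution only arbitrates between families that are both in play.
#' @return list of class `collinearity_screen`: `candidates` (retained
#'   predictor names), `excluded_pairs` (tibble `var1`, `var2`, `r`),
#'   `dropped` (predictors removed in family resolution), `family_r2`.
#' @export
screen_collinearity <- function(pred_table, threshold = 0.5,
                                families = list(
                                  pink = c("pink_lag1", "pink_lag2"),
                                  chum = c("chum_lag1", "chum_lag2")),
                                candidates = NULL) {
  preds <- attr(pred_table, "scaling")$predictor
  if (!is.null(candidates)) preds <- intersect(preds, candidates)
  fam_r2 <- NULL
  dropped <- character(0)
  fam_present <- lapply(families, intersect, preds)
  fam_present <- fam_present[lengths(fam_present) > 0]
  if (length(fam_present) >= 2) {
    r2 <- vapply(fam_present, function(vars) {
      max(vapply(vars, function(v) {
        summary(lm(pred_table$response ~ pred_table[[v]]))$r.squared
      }, 0))
    }, 0)
    fam_r2 <- r2
    keep_fam <- names(which.max(r2))
    cross_cor <- abs(cor(as.matrix(pred_table[unlist(fam_present)])))
    diag(cross_cor) <- 0
    # only drop the losing family if it actually collides with the winner
    losers <- setdiff(names(fam_present), keep_fam)
    for (lf in losers) {
      if (max(cross_cor[fam_present[[lf]], fam_present[[keep_fam]]]) > threshold) {
        dropped <- c(dropped, fam_present[[lf]])
      }
    }
  }
  cands <- setdiff(preds, dropped)
  cm <- cor(as.matrix(pred_table[cands]))
  pairs <- which(upper.tri(cm) & abs(cm) > threshold, arr.ind = TRUE)
  excluded <- tibble::tibble(var1 = cands[pairs[, 1]],
                             var2 = cands[pairs[, 2]],
                             r = cm[pairs])
  structure(list(candidates = cands, excluded_pairs = excluded,
                 dropped = dropped, family_r2 = fam_r2,
                 threshold = threshold),
            class = "collinearity_screen")
}

# admissible subsets of candidate indices under pairwise exclusions
admissible_subsets <- function(n_cand, bad_pairs, max_size) {
  out <- list(integer(0))
  for (i in seq_len(n_cand)) {
    new <- lapply(out, function(s) {
      if (length(s) >= max_size) return(NULL)
      if (length(s) && any(vapply(s, function(j)
        any(bad_pairs$i == j & bad_pairs$j == i), TRUE))) return(NULL)
      c(s, i)
    })
    out <- c(out, new[!vapply(new, is.null, TRUE)])
  }
  out
}

all_subsets <- function(x) {
  out <- list(character(0))
  for (v in x) out <- c(out, lapply(out, c, v))
  out
}

#' All-subsets AIC model selection under constraints
#'
#' Exhaustively fits every admissible linear model of the response on the
#' standardized candidate predictors and ranks them by AIC. Admissibility
#' honours (i) the collinearity constraints from [screen_collinearity()] —
#' no two predictors with |r| above the threshold enter together — and (ii)
#' marginality: a quadratic term only with its linear term, a regime x SST
#' interaction only with both main effects. Ties in AIC are broken by fewer
#' terms, then by lexicographic term order, so selection is deterministic.
#'
#' @param pred_table a [build_predictors()] table.
#' @param screen a [screen_collinearity()] result (built with defaults if
#'   `NULL`).
#' @param candidates optional character vector restricting the candidate
#'   predictors (default: all retained by the screen).
#' @param quadratic logical or character vector: which candidates may carry
#'   a quadratic term (default all).
#' @param regime_interactions character vector of predictors allowed a
#'   regime interaction (default the SST predictors), or `NULL` to drop the
#'   regime factor entirely.
#' @param rank `"AIC"` (default) or `"AICc"`.
#' @param delta_keep report all models within this AIC distance of the best
#'   (default 2).
#' @return object of class `model_selection`: `best` (the refitted `lm`),
#'   `terms`, `coefficients` (tibble with raw-scale back-transforms),
#'   `aic`, `r_squared`, `candidates` (the ΔAIC table), `n_models`,
#'   `scaling`, `data`.
#' @export
select_model <- function(pred_table, screen = NULL, candidates = NULL,
                         quadratic = TRUE,
                         regime_interactions = c("sst_winter_aleutians",
                                                 "sst_summer_bering_lag1"),
                         rank = c("AIC", "AICc"), delta_keep = 2) {
  rank <- match.arg(rank)
  if (is.null(screen)) screen <- screen_collinearity(pred_table)
  cands <- candidates %||% screen$candidates
  cands <- intersect(screen$candidates, cands)
  quad_ok <- if (isTRUE(quadratic)) cands else
    if (identical(quadratic, FALSE)) character(0) else intersect(quadratic, cands)
  use_regime <- !is.null(regime_interactions) &&
    length(unique(pred_table$regime)) >= 2
  regime_interactions <- intersect(regime_interactions %||% character(0), cands)

  n <- nrow(pred_table)
  bad <- screen$excluded_pairs
  bad <- bad[bad$var1 %in% cands & bad$var2 %in% cands, ]
  bad_idx <- tibble::tibble(i = match(bad$var1, cands), j = match(bad$var2, cands))
  bad_idx <- dplyr::bind_rows(bad_idx, tibble::tibble(i = bad_idx$j, j = bad_idx$i))
  max_lin <- min(length(cands), n - 2)

  subsets <- admissible_subsets(length(cands), bad_idx, max_lin)
  aic_fun <- function(fit) {
    a <- AIC(fit)
    if (rank == "AICc") {
      k <- length(coef(fit)) + 1
      a <- a + 2 * k * (k + 1) / max(n - k - 1, 1)
    }
    a
  }

  rows <- list(); ri <- 0
  for (s in subsets) {
    lin <- cands[s]
    zlin <- paste0("z_", lin, recycle0 = TRUE)
    term_sets <- list(zlin)
    # quadratic expansions (marginality: square only with its linear term)
    qv <- intersect(lin, quad_ok)
    if (length(qv)) {
      term_sets <- unlist(lapply(all_subsets(qv), function(q) {
        list(c(zlin, paste0("z_", q, "_sq", recycle0 = TRUE)))
      }), recursive = FALSE)
    }
    # regime main effect and interactions with included SST terms
    iv <- intersect(lin, regime_interactions)
    expanded <- term_sets
    if (use_regime) {
      with_regime <- lapply(term_sets, c, "regime")
      if (length(iv)) {
        with_regime <- unlist(lapply(all_subsets(iv), function(ia) {
          lapply(with_regime, function(ts)
            c(ts, if (length(ia)) paste0("regime:z_", ia)))
        }), recursive = FALSE)
        with_regime <- unique(with_regime)
      }
      expanded <- c(term_sets, with_regime)
    }
    for (ts in expanded) {
      if (length(ts) + 2 > n) next
      f <- if (length(ts)) paste("response ~", paste(ts, collapse = " + "))
           else "response ~ 1"
      fit <- lm(as.formula(f), data = pred_table)
      ri <- ri + 1
      rows[[ri]] <- tibble::tibble(
        terms = paste(sort(ts), collapse = " + "),
        formula = f, k = length(ts), aic = aic_fun(fit),
        r_squared = summary(fit)$r.squared)
    }
  }
  tab <- dplyr::bind_rows(rows)
  tab <- tab[!duplicated(tab$terms), ]
  tab <- tab[order(tab$aic, tab$k, tab$terms), ]
  tab$delta_aic <- tab$aic - tab$aic[1]
  best_fit <- lm(as.formula(tab$formula[1]), data = pred_table)

  scaling <- attr(pred_table, "scaling")
  cf <- summary(best_fit)$coefficients
  coefs <- tibble::tibble(term = rownames(cf),
                          estimate = unname(cf[, 1]), se = unname(cf[, 2]))
  coefs$raw_estimate <- raw_scale_coef(coefs$term, coefs$estimate, scaling)
  coefs$raw_se <- raw_scale_coef(coefs$term, coefs$se, scaling)

  structure(list(
    best = best_fit,
    terms = sort(strsplit(tab$terms[1], " \\+ ")[[1]]),
    coefficients = coefs,
    aic = tab$aic[1],
    r_squared = tab$r_squared[1],
    candidates = tab[tab$delta_aic < delta_keep,
                     c("terms", "k", "aic", "delta_aic", "r_squared")],
    n_models = nrow(tab),
    rank = rank,
    screen = screen,
    scaling = scaling,
    data = pred_table), class = "model_selection")
}

# standardized-scale coefficient -> raw predictor units. Linear terms are
# slopes at the predictor mean (mm per raw unit); quadratic terms are
# curvatures (mm per squared centred unit); others pass through.
raw_scale_coef <- function(term, est, scaling) {
  out <- est
  for (i in seq_along(term)) {
    t1 <- term[i]
    if (grepl("^z_.*_sq$", t1)) {
      p <- sub("^z_(.*)_sq$", "\\1", t1)
      out[i] <- est[i] / scaling$scale[scaling$predictor == p]^2
    } else if (grepl("^z_", t1) && !grepl(":", t1)) {
      p <- sub("^z_", "", t1)
      out[i] <- est[i] / scaling$scale[scaling$predictor == p]
    }
  }
  out
}

#' @export
print.model_selection <- function(x, ...) {
  cat("All-subsets AIC selection (", x$rank, "), ", x$n_models,
      " candidate models\n", sep = "")
  cat("Best model: response ~", paste(x$terms, collapse = " + "), "\n")
  cat(sprintf("AIC = %.2f, R^2 = %.3f; %d model(s) with dAIC < 2\n",
              x$aic, x$r_squared, nrow(x$candidates)))
  print(x$coefficients, n = Inf)
  invisible(x)
}

#' Per-predictor share of explained variance
#'
#' For each predictor in the selected model, the drop in R-squared when all
#' of that predictor's terms (linear, quadratic, interactions) are removed
#' from the model and it is refitted — a deterministic leave-one-predictor-
#' out partition, reported in percent of response variance.
#'
#' @param sel a [select_model()] result.
#' @return tibble `predictor`, `share_pct`, sorted descending.
#' @export
partition_variance <- function(sel) {
  stopifnot(inherits(sel, "model_selection"))
  terms <- sel$terms
  base_preds <- unique(sub("^z_(.*?)(_sq)?$", "\\1",
                           grep("^z_", terms, value = TRUE)))
  base_preds <- unique(sub(":.*$", "", base_preds))
  groups <- stats::setNames(lapply(base_preds, function(p) {
    terms[grepl(paste0("\\bz_", p, "(_sq)?\\b"), terms)]
  }), base_preds)
  if ("regime" %in% terms) {
    groups$regime <- terms[grepl("regime", terms)]
  }
  full_r2 <- sel$r_squared
  shares <- vapply(names(groups), function(p) {
    rest <- setdiff(terms, groups[[p]])
    # marginality: dropping a main effect drops its interactions too
    if (p != "regime") rest <- rest[!grepl(paste0("z_", p, "\\b"), rest)]
    f <- if (length(rest)) paste("response ~", paste(rest, collapse = " + "))
         else "response ~ 1"
    r2 <- summary(lm(as.formula(f), data = sel$data))$r.squared
    100 * (full_r2 - r2)
  }, 0)
  tibble::tibble(predictor = names(groups), share_pct = unname(shares)) |>
    dplyr::arrange(dplyr::desc(.data$share_pct))
}

#' Partial effect of one predictor with 95% confidence band
#'
#' Predicted response over a grid of the predictor's observed range with
#' all other numeric predictors held at their mean (standardized 0) and the
#' regime factor at its reference level. Confidence limits are pointwise
#' 95% intervals from the OLS prediction variance.
#'
#' @param sel a [select_model()] result.
#' @param predictor raw predictor name, e.g. `"pink_lag1"`.
#' @param n grid size.
#' @return tibble `x` (raw units), `z`, `fit`, `lwr`, `upr` (mm).
#' @export
partial_effects <- function(sel, predictor, n = 100) {
  stopifnot(inherits(sel, "model_selection"))
  zc <- paste0("z_", predictor)
  if (!any(grepl(paste0("\\b", zc, "\\b"), sel$terms))) {
    stop(predictor, " is not in the selected model", call. = FALSE)
  }
  zr <- range(sel$data[[zc]])
  grid <- seq(zr[1], zr[2], length.out = n)
  nd <- sel$data[rep(1, n), ]
  for (p in sel$scaling$predictor) {
    nd[[paste0("z_", p)]] <- 0
    nd[[paste0("z_", p, "_sq")]] <- 0
  }
  nd$regime <- factor("pre", levels = levels(sel$data$regime))
  nd[[zc]] <- grid
  nd[[paste0(zc, "_sq")]] <- grid^2
  pr <- predict(sel$best, newdata = nd, se.fit = TRUE)
  sc <- sel$scaling
  tibble::tibble(
    x = grid * sc$scale[sc$predictor == predictor] +
      sc$center[sc$predictor == predictor],
    z = grid,
    fit = pr$fit,
    lwr = pr$fit - 1.96 * pr$se.fit,
    upr = pr$fit + 1.96 * pr$se.fit)
}
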