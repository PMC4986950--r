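# Ensemble LASSO sensitivity analysis: attribute the difference in
# predicted flame height between the structure-only (FS) and full (FSL)
# treatments to the three mechanisms (donor flammability, receiver
# ignitability, overstorey sheltering) plus exogenous and structural
# covariates. The response is FS flame height minus FSL flame height; delta
# predictors are FSL value minus FS value.

#' Assemble the predictor matrix for the sensitivity analysis
#'
#' Twelve continuous predictors per site:
#' `delta_donor_fh` (FSL - FS donor flame height, donor = maximum flame
#' height below the highest receiver stratum), `donor_fh_fs`, `mean_ic_fsl`,
#' `sum_lai_fs`, `delta_sum_lai`, `canopy_lai_fs`, `delta_canopy_lai`,
#' `wind_velocity` (km/h), `dfmc`, `slope`, `vertical_continuity` (negated
#' sum of vertical gaps between successive occupied strata, so larger means
#' more continuous), and `surface_fine_fuel` (t/ha). The response is
#' `predicted flame height under FS minus that under FSL`.
#'
#' @param predictions An [ffm_treatments()] table containing FS and FSL rows.
#' @param sites List of [ffm_site()] objects (named or ordered by site).
#' @param weather List of [ffm_weather()] records matching `sites`.
#' @return A list of class `ffm_predictor_matrix` with `x` (matrix, sites x
#'   12), `y` (response vector) and `site_id`.
#' @export
build_predictors <- function(predictions, sites, weather) {
  pr <- as.data.frame(predictions)
  fs <- pr[pr$treatment == "FS", ]
  fsl <- pr[pr$treatment == "FSL", ]
  if (!setequal(fs$site_id, fsl$site_id) || anyDuplicated(fs$site_id))
    stop_invalid("FS and FSL predictions must cover the same site set")
  fsl <- fsl[match(fs$site_id, fsl$site_id), ]
  site_ids <- vapply(sites, function(s) s$site_id, character(1))
  idx <- match(fs$site_id, site_ids)
  if (anyNA(idx)) stop_invalid("site '%s' missing from the site list",
                               fs$site_id[is.na(idx)][1])
  w <- weather[idx]
  s <- sites[idx]

  vc <- vapply(s, vertical_continuity, numeric(1))
  x <- cbind(
    delta_donor_fh = fsl$donor_fh - fs$donor_fh,
    donor_fh_fs = fs$donor_fh,
    mean_ic_fsl = fsl$mean_ic,
    sum_lai_fs = fs$sum_lai,
    delta_sum_lai = fsl$sum_lai - fs$sum_lai,
    canopy_lai_fs = fs$canopy_lai,
    delta_canopy_lai = fsl$canopy_lai - fs$canopy_lai,
    wind_velocity = vapply(w, function(z) z$wind_velocity, numeric(1)),
    dfmc = vapply(w, function(z) z$dfmc, numeric(1)),
    slope = vapply(w, function(z) z$slope, numeric(1)),
    vertical_continuity = vc,
    surface_fine_fuel = vapply(s, function(z) z$surface_fuel_load,
                               numeric(1))
  )
  rownames(x) <- fs$site_id
  if (anyNA(x)) stop_invalid("predictor matrix contains missing cells")
  y <- fs$predicted_flame_height - fsl$predicted_flame_height
  structure(list(x = x, y = y, site_id = fs$site_id),
            class = "ffm_predictor_matrix")
}

# negated sum of vertical gaps (crown base of upper minus crown top of
# lower, floored at 0) between successive occupied strata: larger values
# mean a more vertically continuous fuel column
vertical_continuity <- function(site) {
  st <- site_strata(site)
  if (length(st) < 2) return(0)
  gaps <- 0
  for (i in seq_len(length(st) - 1)) {
    gaps <- gaps + max(0, st[[i + 1]]$crown_base_centre_height -
                         st[[i]]$crown_height)
  }
  -gaps
}

#' Cross-validated LASSO fit
#'
#' Fits an L1-penalised linear model over a descending penalty path and
#' selects the penalty by random k-fold cross-validation, either at the
#' minimum estimated prediction error (`rule = "min"`) or as the most
#' parsimonious model within one standard error of it (`rule = "1se"`).
#' Coefficients for unselected predictors are exactly zero. Predictors are
#' standardised for fitting; coefficients are reported on the original
#' predictor scale.
#'
#' @param matrix An [build_predictors()] result, or a list with `x`, `y`.
#' @param k Number of cross-validation folds, >= 2.
#' @param rule `"min"` or `"1se"`.
#' @param seed Integer seed controlling the random fold allocation.
#' @param config An [ffm_config()] list (supplies the penalty path length).
#' @return Named numeric vector of coefficients on the original scale
#'   (intercept first), with attribute `"selected"` naming the non-zero
#'   predictors.
#' @export
lasso_cv_fit <- function(matrix, k = 10, rule = c("min", "1se"), seed = 1,
                         config = ffm_config()) {
  rule <- match.arg(rule)
  x <- matrix$x
  y <- matrix$y
  stopifnot(k >= 2, nrow(x) > k)
  cf0 <- setNames(numeric(ncol(x) + 1), c("(Intercept)", colnames(x)))
  if (var(y) == 0) {
    message("constant response: all coefficients are zero")
    cf0["(Intercept)"] <- y[1]
    attr(cf0, "selected") <- character(0)
    return(cf0)
  }
  n_lambda <- cfg_block(config, "sensitivity", "n_lambda")$n_lambda
  foldid <- with_seed(seed, sample(rep_len(seq_len(k), nrow(x))))
  cvfit <- glmnet::cv.glmnet(x, y, alpha = 1, nfolds = k, foldid = foldid,
                             nlambda = n_lambda, standardize = TRUE)
  s <- if (rule == "min") "lambda.min" else "lambda.1se"
  cf <- as.numeric(coef(cvfit, s = s))
  names(cf) <- c("(Intercept)", colnames(x))
  attr(cf, "selected") <- colnames(x)[cf[-1] != 0]
  cf
}

#' Ensemble LASSO sensitivity analysis
#'
#' Repeats the cross-validated LASSO fit under independent random fold
#' allocations and records, per predictor, the inclusion frequency and the
#' mean, 2.5% and 97.5% quantiles of its coefficient over the runs in which
#' it was selected. This characterises secondary predictors whose inclusion
#' depends on the random split, around the dominant predictor(s) present in
#' every run.
#'
#' @param matrix A [build_predictors()] result.
#' @param n_runs Number of ensemble members, >= 1.
#' @param k Folds per run.
#' @param rule Penalty selection rule per run (`"min"` by default).
#' @param base_seed Base integer seed; run r uses `base_seed + r`.
#' @param config An [ffm_config()] list.
#' @return An object of class `ffm_ensemble`: a list with `summary` (one
#'   row per predictor: `n_included`, `mean_coef`, `q2.5`, `q97.5`),
#'   `n_runs` and the full `coefficients` matrix (runs x predictors).
#' @export
ffm_ensemble <- function(matrix, n_runs = 1000, k = 10, rule = "min",
                         base_seed = 1, config = ffm_config()) {
  stopifnot(n_runs >= 1)
  preds <- colnames(matrix$x)
  coefs <- base::matrix(0, n_runs, length(preds),
                        dimnames = list(NULL, preds))
  for (r in seq_len(n_runs)) {
    cf <- lasso_cv_fit(matrix, k = k, rule = rule,
                       seed = (base_seed + r) %% .Machine$integer.max,
                       config = config)
    coefs[r, ] <- cf[-1]
  }
  summ <- do.call(rbind, lapply(preds, function(p) {
    sel <- coefs[, p] != 0
    vals <- coefs[sel, p]
    data.frame(predictor = p, n_included = sum(sel),
               mean_coef = if (length(vals)) mean(vals) else NA_real_,
               q2.5 = if (length(vals)) unname(quantile(vals, 0.025))
                      else NA_real_,
               q97.5 = if (length(vals)) unname(quantile(vals, 0.975))
                       else NA_real_,
               stringsAsFactors = FALSE)
  }))
  summ <- summ[order(-summ$n_included), ]
  rownames(summ) <- NULL
  structure(list(summary = summ, n_runs = n_runs, coefficients = coefs),
            class = "ffm_ensemble")
}

#' @export
print.ffm_ensemble <- function(x, ...) {
  cat(sprintf("Ensemble LASSO sensitivity analysis (%d runs)\n", x$n_runs))
  print(x$summary, digits = 3)
  invisible(x)
}

#' @export
summary.ffm_ensemble <- function(object, ...) object$summary

#' Mean coefficients of the ensemble
#' @param object An `ffm_ensemble`.
#' @param ... Unused.
#' @return Named vector of mean coefficients (NA when never included).
#' @export
coef.ffm_ensemble <- function(object, ...) {
  setNames(object$summary$mean_coef, object$summary$predictor)
}

#' Plot ensemble inclusion frequencies
#' @param x An `ffm_ensemble`.
#' @param ... Passed to [graphics::barplot()].
#' @export
plot.ffm_ensemble <- function(x, ...) {
  s <- x$summary
  op <- graphics::par(mar = c(5, 10, 2, 1))
  on.exit(graphics::par(op))
  graphics::barplot(rev(s$n_included) / x$n_runs, horiz = TRUE,
                    names.arg = rev(s$predictor), las = 1,
                    xlab = "inclusion frequency", ...)
  invisible(x)
}

# evaluate expr under a temporary RNG state seeded with `seed`
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
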