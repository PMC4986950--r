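cfg <- ffm_config()

sim_matrix <- function(n = 200, beta1 = 2, sigma = 0.1, seed = 3,
                       p = 12) {
  set.seed(seed)
  x <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, c("signal", paste0("noise", 1:(p - 1)))))
  list(x = x, y = beta1 * x[, 1] + rnorm(n, 0, sigma))
}

test_that("predictor matrix: identical treatments give a null system", {
  syn <- ffm_synthetic_sites(seed = 41, n_sites = 4, observations = FALSE)
  preds <- ffm_treatments(syn$sites, syn$weather, c("FS", "FSL"), cfg)
  # force FS rows identical to FSL rows: all deltas and the response vanish
  fsl <- preds[preds$treatment == "FSL", ]
  fs <- fsl; fs$treatment <- "FS"
  pm <- build_predictors(rbind(fs, fsl), syn$sites, syn$weather)
  expect_equal(unname(pm$x[, "delta_donor_fh"]), rep(0, 4))
  expect_equal(unname(pm$x[, "delta_sum_lai"]), rep(0, 4))
  expect_equal(unname(pm$x[, "delta_canopy_lai"]), rep(0, 4))
  expect_equal(pm$y, rep(0, 4))
  expect_equal(ncol(pm$x), 12)
  expect_false(anyNA(pm$x))
})

test_that("predictor matrix rows follow sites; deltas are hand-computable", {
  syn <- ffm_synthetic_sites(seed = 42, n_sites = 5, observations = FALSE)
  preds <- ffm_treatments(syn$sites, syn$weather, c("FS", "FSL"), cfg)
  pm <- build_predictors(preds, syn$sites, syn$weather)
  fs <- preds[preds$treatment == "FS", ]
  fsl <- preds[preds$treatment == "FSL", ]
  fsl <- fsl[match(fs$site_id, fsl$site_id), ]
  expect_equal(unname(pm$x[, "delta_donor_fh"]),
               fsl$donor_fh - fs$donor_fh)
  expect_equal(unname(pm$x[, "canopy_lai_fs"]), fs$canopy_lai)
  expect_equal(pm$y, fs$predicted_flame_height - fsl$predicted_flame_height)

  # permuting prediction rows permutes nothing but row order
  perm <- preds[sample(nrow(preds)), ]
  pm2 <- build_predictors(perm, syn$sites, syn$weather)
  expect_equal(pm2$x[pm$site_id, ], pm$x)
  expect_equal(pm2$y[match(pm$site_id, pm2$site_id)], pm$y)
})

test_that("cross-validated LASSO recovers a single strong predictor", {
  m <- sim_matrix()
  cf_min <- lasso_cv_fit(m, k = 10, rule = "min", seed = 1, config = cfg)
  cf_1se <- lasso_cv_fit(m, k = 10, rule = "1se", seed = 1, config = cfg)
  expect_true("signal" %in% attr(cf_min, "selected"))
  expect_true("signal" %in% attr(cf_1se, "selected"))
  expect_lt(abs(cf_min["signal"] - 2) / 2, 0.1)
  expect_lt(abs(cf_1se["signal"] - 2) / 2, 0.1)
  # the one-standard-error rule is never less parsimonious
  expect_lte(length(attr(cf_1se, "selected")),
             length(attr(cf_min, "selected")))
  # unselected coefficients are exactly zero
  expect_true(all(cf_min[setdiff(names(cf_min),
                                 c("(Intercept)",
                                   attr(cf_min, "selected")))] == 0))
})

test_that("a constant response yields all-zero coefficients with notice", {
  m <- sim_matrix()
  m$y <- rep(1.5, length(m$y))
  expect_message(cf <- lasso_cv_fit(m, config = cfg), "constant response")
  expect_true(all(cf[-1] == 0))
  expect_length(attr(cf, "selected"), 0)
})

test_that("the ensemble is seed-reproducible and reduces to a single fit", {
  m <- sim_matrix(n = 60)
  e1 <- ffm_ensemble(m, n_runs = 5, base_seed = 9, config = cfg)
  e2 <- ffm_ensemble(m, n_runs = 5, base_seed = 9, config = cfg)
  expect_identical(e1$coefficients, e2$coefficients)

  single <- ffm_ensemble(m, n_runs = 1, base_seed = 4, config = cfg)
  direct <- lasso_cv_fit(m, k = 10, rule = "min", seed = 5, config = cfg)
  expect_equal(unname(single$coefficients[1, ]), unname(direct[-1]))
  s <- single$summary
  expect_true(all(s$n_included %in% c(0, 1)))
})

test_that("quantiles bracket the mean; null predictors are rarely kept", {
  m <- sim_matrix(n = 150, sigma = 0.3, seed = 12)
  ens <- ffm_ensemble(m, n_runs = 30, base_seed = 2, config = cfg)
  s <- ens$summary
  kept <- s[!is.na(s$mean_coef), ]
  expect_true(all(kept$q2.5 <= kept$mean_coef + 1e-12))
  expect_true(all(kept$mean_coef <= kept$q97.5 + 1e-12))
  # the true predictor dominates; its recovered sign matches the truth
  expect_equal(s$predictor[1], "signal")
  expect_equal(s$n_included[1], 30)
  expect_gt(s$mean_coef[1], 0)

  # pure-noise response: no predictor should be included often
  set.seed(77)
  null_m <- list(x = m$x, y = rnorm(nrow(m$x)))
  null_ens <- ffm_ensemble(null_m, n_runs = 20, base_seed = 3, config = cfg)
  expect_true(all(abs(null_ens$summary$mean_coef) < 0.5, na.rm = TRUE))
})
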