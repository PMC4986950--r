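make_table <- function(pred, lower, median, upper, treatment = "FSL",
                       sites = NULL) {
  n <- length(pred)
  if (is.null(sites)) sites <- sprintf("s%02d", seq_len(n))
  preds <- data.frame(site_id = sites, treatment = treatment,
                      predicted_flame_height = pred,
                      stringsAsFactors = FALSE)
  obs <- data.frame(site_id = sites, lower = lower, median = median,
                    upper = upper, stringsAsFactors = FALSE)
  ffm_validate(preds, obs)
}

test_that("error metrics: perfect predictions and sign cancellation", {
  tab <- make_table(c(1, 2, 3), c(0.5, 1.5, 2.5), c(1, 2, 3),
                    c(1.5, 2.5, 3.5))
  em <- error_metrics(tab, "FSL")
  expect_equal(em$me, 0)
  expect_equal(em$mae, 0)
  expect_equal(em$n, 3)

  tab2 <- make_table(c(3, 1), c(0, 0), c(2, 2), c(5, 5))
  em2 <- error_metrics(tab2, "FSL")
  expect_equal(em2$me, 0)     # +1 and -1 cancel
  expect_equal(em2$mae, 1)
  expect_equal(em2$se_mae, 0)
  expect_equal(em2$se_me, sd(c(1, -1)) / sqrt(2))
  expect_error(error_metrics(tab2, "F"), "no rows")
})

test_that("PCP counts interval membership with inclusive bounds", {
  tab <- make_table(c(1, 2, 3, 10), c(0.5, 1.5, 2.5, 0), c(1, 2, 3, 1),
                    c(1.5, 2.5, 3.5, 2))
  expect_equal(pcp(tab, "FSL")$pcp, 0.75)
  # exactly on a bound counts as correct
  tab_b <- make_table(c(2, 0.5), c(1, 0.5), c(1.5, 1), c(2, 2))
  expect_equal(pcp(tab_b, "FSL")$pcp, 1)
  # 4 sites, 2 inside
  tab4 <- make_table(c(1, 5, 2, 9), c(0, 0, 0, 0), c(1, 1, 2, 2),
                     c(2, 2, 3, 3))
  expect_equal(pcp(tab4, "FSL")$pcp, 0.5)
  # the >= 1 m subset keeps only large observed flames
  expect_equal(pcp(tab4, "FSL", min_height = 1.5)$n, 2)
})

test_that("paired comparison matches the closed-form t statistic", {
  set.seed(5)
  ae_a <- runif(10, 0, 3)
  ae_b <- ae_a + rnorm(10, 0.4, 0.3)
  sites <- sprintf("s%02d", 1:10)
  tab <- rbind(
    make_table(ae_a, rep(0, 10), rep(0, 10), rep(10, 10), "A", sites),
    make_table(ae_b, rep(0, 10), rep(0, 10), rep(10, 10), "B", sites))
  # with median 0 the absolute error equals the prediction itself
  res <- paired_comparison(tab, "A", "B", metric = "ae")
  d <- ae_a - ae_b
  t_hand <- mean(d) / (sd(d) / sqrt(10))
  expect_equal(res$t, t_hand)
  expect_equal(res$df, 9)
  expect_equal(res$p, 2 * pt(-abs(t_hand), 9))
  expect_false(res$degenerate)

  # identical per-site values degenerate to t = 0, p = 1
  same <- paired_comparison(tab, "A", "A", metric = "ae")
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_true(same$degenerate)

  # constant non-zero difference: flagged, p at the machine floor
  tab_c <- rbind(
    make_table(rep(2, 5), rep(0, 5), rep(0, 5), rep(10, 5), "A",
               sprintf("s%d", 1:5)),
    make_table(rep(1, 5), rep(0, 5), rep(0, 5), rep(10, 5), "B",
               sprintf("s%d", 1:5)))
  res_c <- paired_comparison(tab_c, "A", "B", metric = "ae")
  expect_true(res_c$degenerate)
  expect_lte(res_c$p, .Machine$double.xmin)

  expect_error(paired_comparison(tab, "A", "missing"), "same site set")
})

test_that("metric invariants: MAE bounds ME, order invariance", {
  set.seed(8)
  pred <- runif(12, 0, 8)
  med <- runif(12, 0, 8)
  tab <- make_table(pred, pmax(0, med - 1), med, med + 1)
  em <- error_metrics(tab, "FSL")
  expect_gte(em$mae, abs(em$me))
  p <- pcp(tab, "FSL")$pcp
  expect_gte(p, 0); expect_lte(p, 1)
  # permuting site order changes nothing
  perm <- tab[sample(nrow(tab)), ]
  expect_equal(error_metrics(perm, "FSL"), em)
  expect_equal(pcp(perm, "FSL"), pcp(tab, "FSL"))
})

test_that("validation summary reports one row per treatment", {
  syn <- ffm_synthetic_sites(seed = 31, n_sites = 4)
  preds <- ffm_treatments(syn$sites, syn$weather)
  val <- ffm_validate(preds, syn$observations)
  s <- summary(val)
  expect_setequal(s$treatment, c("F", "FS", "FSL"))
  expect_true(all(s$mae >= abs(s$me) - 1e-12))
  expect_true(all(s$pcp >= 0 & s$pcp <= 1))
})
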