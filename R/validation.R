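# Validation against observed flame-height intervals: signed and absolute
# errors against the interval median, proportion of correct predictions
# (prediction inside the observed interval, bounds inclusive), the >= 1 m
# subset, and paired t-tests between treatments.

#' Build a validation table from predictions and observations
#'
#' Joins treatment predictions to observed flame-height intervals. The
#' signed error is measured against the interval median; correctness is
#' membership of the full interval with inclusive bounds; `large_flame`
#' flags sites whose observed median is at least `large_threshold`.
#'
#' @param predictions An `ffm_predictions` data frame (or any data frame
#'   with `site_id`, `treatment`, `predicted_flame_height`).
#' @param observations A data frame with `site_id`, `lower`, `median`,
#'   `upper` (m).
#' @param large_threshold Observed-median threshold for the large-flame
#'   subset (m).
#' @return A `data.frame` of class `ffm_validation` with per-row `error`,
#'   `abs_error`, `correct`, `large_flame`.
#' @export
ffm_validate <- function(predictions, observations, large_threshold = 1) {
  stopifnot(all(c("site_id", "treatment", "predicted_flame_height") %in%
                  names(predictions)),
            all(c("site_id", "lower", "median", "upper") %in%
                  names(observations)))
  bad <- with(observations, lower < 0 | median < lower | upper < median)
  if (any(bad))
    stop_invalid("observations: need 0 <= lower <= median <= upper (site '%s')",
                 observations$site_id[bad][1])
  tab <- merge(as.data.frame(predictions), observations, by = "site_id")
  if (!nrow(tab)) stop_invalid("no sites in common between predictions and observations")
  tab$error <- tab$predicted_flame_height - tab$median
  tab$abs_error <- abs(tab$error)
  tab$correct <- tab$predicted_flame_height >= tab$lower &
    tab$predicted_flame_height <= tab$upper
  tab$large_flame <- tab$median >= large_threshold
  structure(tab, class = c("ffm_validation", "data.frame"))
}

#' Mean error and mean absolute error for a treatment
#'
#' The mean signed error (ME, treatment bias) and mean absolute error (MAE,
#' overall accuracy) of predicted flame height against the observed interval
#' median, with the standard error of each mean.
#'
#' @param table An [ffm_validate()] table.
#' @param treatment Treatment label to summarise.
#' @return A list with `me`, `se_me`, `mae`, `se_mae`, `n`.
#' @export
error_metrics <- function(table, treatment) {
  tab <- table[table$treatment == treatment, ]
  if (!nrow(tab)) stop_invalid("no rows for treatment '%s'", treatment)
  se <- function(x) if (length(x) > 1) sd(x) / sqrt(length(x)) else NA_real_
  list(me = mean(tab$error), se_me = se(tab$error),
       mae = mean(tab$abs_error), se_mae = se(tab$abs_error),
       n = nrow(tab))
}

#' Proportion of correct predictions
#'
#' The fraction of sites whose prediction falls inside the observed
#' flame-height interval (bounds inclusive). With `min_height` set, only
#' sites whose observed median is at least that height are counted
#' (e.g. `min_height = 1` for the large-flame subset).
#'
#' @param table An [ffm_validate()] table.
#' @param treatment Treatment label.
#' @param min_height Optional observed-median filter (m).
#' @return A list with `pcp` and `n` (sites counted).
#' @export
pcp <- function(table, treatment, min_height = NULL) {
  tab <- table[table$treatment == treatment, ]
  if (!is.null(min_height)) tab <- tab[tab$median >= min_height, ]
  if (!nrow(tab)) stop_invalid("no sites left after filtering for treatment '%s'",
                               treatment)
  list(pcp = mean(tab$correct), n = nrow(tab))
}

#' Paired comparison of two treatments
#'
#' A paired t-test over sites on per-site absolute errors (`metric = "ae"`)
#' or per-site 0/1 correctness (`metric = "correct"`). When the paired
#' differences have zero variance the test degenerates: `t` is 0 (identical
#' values, p = 1) or infinite (constant non-zero difference, p reported at
#' the machine floor) and `degenerate` is flagged.
#'
#' @param table An [ffm_validate()] table.
#' @param treatment_a,treatment_b Treatments to compare (a minus b).
#' @param metric `"ae"` or `"correct"`.
#' @return A list with `t`, `df`, `p`, `mean_diff`, `degenerate`.
#' @export
paired_comparison <- function(table, treatment_a, treatment_b,
                              metric = c("ae", "correct")) {
  metric <- match.arg(metric)
  col <- if (metric == "ae") "abs_error" else "correct"
  a <- table[table$treatment == treatment_a, c("site_id", col)]
  b <- table[table$treatment == treatment_b, c("site_id", col)]
  if (!setequal(a$site_id, b$site_id) || anyDuplicated(a$site_id))
    stop_invalid("treatments '%s' and '%s' must cover the same site set",
                 treatment_a, treatment_b)
  b <- b[match(a$site_id, b$site_id), ]
  d <- as.numeric(a[[col]]) - as.numeric(b[[col]])
  n <- length(d)
  if (sd(d) == 0) {
    if (mean(d) == 0) {
      return(list(t = 0, df = n - 1, p = 1, mean_diff = 0,
                  degenerate = TRUE))
    }
    return(list(t = sign(mean(d)) * Inf, df = n - 1,
                p = .Machine$double.xmin, mean_diff = mean(d),
                degenerate = TRUE))
  }
  tt <- t.test(d)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mean_diff = mean(d), degenerate = FALSE)
}

#' Summarise validation statistics for every treatment
#'
#' @param object An [ffm_validate()] table.
#' @param large_threshold Threshold (m) for the PCP subset on large observed
#'   flames.
#' @param ... Unused.
#' @return A `data.frame`, one row per treatment, with ME, MAE (and their
#'   standard errors), PCP and large-flame PCP.
#' @export
summary.ffm_validation <- function(object, large_threshold = 1, ...) {
  out <- do.call(rbind, lapply(unique(object$treatment), function(tr) {
    em <- error_metrics(object, tr)
    p_all <- pcp(object, tr)
    big <- object[object$treatment == tr & object$large_flame, ]
    p_big <- if (nrow(big)) mean(big$correct) else NA_real_
    data.frame(treatment = tr, n = em$n, me = em$me, se_me = em$se_me,
               mae = em$mae, se_mae = em$se_mae, pcp = p_all$pcp,
               pcp1 = p_big, n1 = nrow(big), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' @export
print.ffm_validation <- function(x, ...) {
  cat(sprintf("Validation table: %d rows, %d sites, treatments %s\n",
              nrow(x), length(unique(x$site_id)),
              paste(unique(x$treatment), collapse = "/")))
  print(summary(x), digits = 3)
  invisible(x)
}
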