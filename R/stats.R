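# Condition-comparison statistics: Shapiro-Wilk normality screening and
# two-sample t-tests on per-cycle parameter values, plus the per-trial
# cycle-time report used to study adaptation across consecutive trials.

#' Shapiro-Wilk normality screen
#'
#' @param x numeric sample of per-cycle values (n >= 3).
#' @param alpha flag threshold (default 0.05): samples with `p <= alpha`
#'   are flagged as departing from normality.
#' @return List: `statistic`, `p_value`, `flagged`. A constant sample has
#'   no defined W statistic; it is returned flagged with `p_value = NA`.
#' @export
test_normality <- function(x, alpha = 0.05) {
  x <- x[!is.na(x)]
  if (length(x) < 3L) {
    gm_stop(
      "normality test needs at least 3 observations",
      "gaitmark_sample_size_error"
    )
  }
  res <- tryCatch(stats::shapiro.test(x), error = function(e) NULL)
  if (is.null(res)) { # degenerate (constant) sample
    return(list(statistic = NA_real_, p_value = NA_real_, flagged = TRUE))
  }
  list(
    statistic = unname(res$statistic),
    p_value = res$p.value,
    flagged = res$p.value <= alpha
  )
}

#' Compare a gait parameter between two conditions
#'
#' Two-sided two-sample t-test on per-cycle parameter values, preceded by a
#' Shapiro-Wilk normality screen of each group. Welch's unequal-variance
#' form is the default; `var_equal = TRUE` gives the pooled-variance test.
#' Non-normal groups are flagged, not auto-switched to a nonparametric
#' test.
#'
#' @param records_a,records_b per-cycle values: numeric vectors, or
#'   `gait_cycles` data frames together with `parameter`.
#' @param parameter column name when data frames are supplied.
#' @param alpha significance level (default 0.05).
#' @param var_equal use the pooled-variance t-test instead of Welch.
#' @return An object of class `gait_comparison`: `parameter`, `n_a`, `n_b`,
#'   `normality_p_a`, `normality_p_b`, `normality_flagged`, `t_statistic`,
#'   `df`, `p_value`, `significant`, `alpha`, `method`.
#' @export
compare_conditions <- function(records_a, records_b, parameter = NULL,
                               alpha = 0.05, var_equal = FALSE) {
  pull <- function(r) {
    if (is.data.frame(r)) {
      gm_assert(
        !is.null(parameter) && parameter %in% names(r),
        "'parameter' must name a column of the cycle tables"
      )
      v <- r[[parameter]]
    } else {
      v <- r
    }
    as.numeric(v[!is.na(v)])
  }
  a <- pull(records_a)
  b <- pull(records_b)
  if (length(a) < 2L || length(b) < 2L) {
    gm_stop(
      "each group needs at least 2 observations",
      "gaitmark_sample_size_error"
    )
  }
  na <- if (length(a) >= 3L) test_normality(a, alpha) else list(p_value = NA, flagged = NA)
  nb <- if (length(b) >= 3L) test_normality(b, alpha) else list(p_value = NA, flagged = NA)
  tt <- stats::t.test(a, b, var.equal = var_equal)
  structure(
    list(
      parameter = if (is.null(parameter)) NA_character_ else parameter,
      n_a = length(a), n_b = length(b),
      normality_p_a = na$p_value, normality_p_b = nb$p_value,
      normality_flagged = isTRUE(na$flagged) || isTRUE(nb$flagged),
      t_statistic = unname(tt$statistic), df = unname(tt$parameter),
      p_value = tt$p.value, significant = tt$p.value < alpha,
      alpha = alpha,
      method = if (var_equal) "pooled t-test" else "Welch t-test"
    ),
    class = "gait_comparison"
  )
}

#' @export
print.gait_comparison <- function(x, ...) {
  cat(sprintf(
    "<gait_comparison> %s: t = %.3f (df %.1f), p = %.4g [%s at alpha %.2f]%s\n",
    ifelse(is.na(x$parameter), "value", x$parameter),
    x$t_statistic, x$df, x$p_value,
    ifelse(x$significant, "significant", "not significant"), x$alpha,
    ifelse(x$normality_flagged, " (normality flagged)", "")
  ))
  invisible(x)
}

# deterministic ordering of trial notation: unassisted first, then motorized
# trials by number (cue speed increases with trial number), then the
# conventional walker
trial_order_key <- function(trial) {
  num <- suppressWarnings(as.numeric(sub("^m", "", trial)))
  ifelse(
    trial == "c", 0,
    ifelse(grepl("^m[0-9]+$", trial), 1000 + num,
      ifelse(trial == "w", 1e6, 1e6 + 1)
    )
  )
}

#' Per-trial cycle-time report
#'
#' One row per (trial, side) with mean gait cycle time and its variance, in
#' cue-speed order (unassisted, then motorized trials by number, then the
#' conventional walker). Used to study adaptation: cycle-time variance
#' typically declines over the first motorized-walker trials.
#'
#' @param cycles a `gait_cycles` data frame with `trial`, `side` and `gct`
#'   columns.
#' @return Data frame: `trial`, `side`, `n_cycles`, `gct_mean`,
#'   `gct_variance`. A trial missing one side yields a warning and only the
#'   available rows.
#' @export
per_trial_report <- function(cycles) {
  gm_assert(
    all(c("trial", "side", "gct") %in% names(cycles)),
    "'cycles' needs 'trial', 'side' and 'gct' columns"
  )
  gm_assert(nrow(cycles) > 0L, "no cycles to report")
  rows <- list()
  for (tr in unique(cycles$trial)) {
    sides <- unique(cycles$side[cycles$trial == tr])
    for (missing in setdiff(c("left", "right"), sides)) {
      warning(sprintf("trial '%s': no %s-side cycles, row omitted", tr, missing))
    }
    for (s in sides) {
      v <- cycles$gct[cycles$trial == tr & cycles$side == s]
      v <- v[!is.na(v)]
      rows[[paste(tr, s)]] <- data.frame(
        trial = tr, side = s, n_cycles = length(v),
        gct_mean = mean(v),
        gct_variance = if (length(v) > 1L) stats::var(v) else NA_real_
      )
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(trial_order_key(out$trial), out$trial, out$side), ]
  rownames(out) <- NULL
  out
}
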