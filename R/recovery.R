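#' Score pipeline recovery against generator ground truth
#'
#' Runs [extract_cycles()] on a synthetic trial and matches each
#' ground-truth cycle (by its starting heel-strike time) to the nearest
#' extracted cycle on the same side. Per-cycle absolute errors of the
#' temporal parameters (in sample periods) and of the spatial parameters
#' (cm) quantify how faithfully the smoothing/detection/refinement chain
#' recovers the generated gait.
#'
#' @param sim a list with `trial` and `truth`, as returned by
#'   [generate_trial()].
#' @param config an [extraction_config()].
#' @param match_tol_s maximum start-valley mismatch for a ground-truth
#'   cycle to count as recovered at all (default 0.25 s).
#' @return A data frame with one row per ground-truth cycle: `side`, `k`,
#'   `matched`, and absolute errors `gct_err`, `sw_err`, `st_err` (sample
#'   periods), `sh_err`, `sl_err` (cm). Unmatched cycles carry `NA` errors.
#' @export
evaluate_recovery <- function(sim, config = extraction_config(),
                              match_tol_s = 0.25) {
  truth <- ground_truth_parameters(sim$truth)
  detected <- extract_cycles(sim$trial, config)
  fs <- sim$trial$sampling_rate
  tm <- attr(detected, "times") # per-cycle start-valley times, by side and k
  out <- list()
  for (side in c("left", "right")) {
    tt <- truth[truth$side == side, , drop = FALSE]
    dd <- detected[detected$side == side, , drop = FALSE]
    ts <- tm[tm$side == side, , drop = FALSE]
    for (i in seq_len(nrow(tt))) {
      true_start <- sim$truth[[side]]$heel_valley_times[tt$k[i]]
      err <- list(
        gct = NA_real_, sw = NA_real_, st = NA_real_,
        sh = NA_real_, sl = NA_real_
      )
      matched <- FALSE
      if (nrow(ts) > 0L) {
        j <- which.min(abs(ts$t_start - true_start))
        if (abs(ts$t_start[j] - true_start) <= match_tol_s) {
          matched <- TRUE
          d <- dd[dd$k == ts$k[j], , drop = FALSE]
          err$gct <- abs(d$gct - tt$gct[i]) * fs
          err$sw <- abs(d$sw - tt$sw[i]) * fs
          err$st <- abs(d$st - tt$st[i]) * fs
          err$sh <- abs(d$sh - tt$sh[i])
          err$sl <- abs(d$sl - tt$sl[i])
        }
      }
      out[[paste(side, i)]] <- data.frame(
        side = side, k = tt$k[i], matched = matched,
        gct_err = err$gct, sw_err = err$sw, st_err = err$st,
        sh_err = err$sh, sl_err = err$sl
      )
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Fraction of cycles recovered within tolerance
#'
#' @param recovery output of [evaluate_recovery()] (rows from several
#'   trials may be concatenated).
#' @param time_tol_samples tolerance on GCT/SW/ST, sample periods.
#' @param space_tol_cm tolerance on SH/SL.
#' @return Proportion in `[0, 1]` of ground-truth cycles whose temporal and
#'   spatial errors are all within tolerance (step length is skipped for
#'   first-of-run cycles where it is undefined); unmatched cycles count as
#'   failures.
#' @export
recovery_rate <- function(recovery, time_tol_samples = 3, space_tol_cm = 0.5) {
  ok <- recovery$matched &
    recovery$gct_err <= time_tol_samples &
    recovery$sw_err <= time_tol_samples &
    recovery$st_err <= time_tol_samples &
    recovery$sh_err <= space_tol_cm &
    (is.na(recovery$sl_err) | recovery$sl_err <= space_tol_cm)
  ok[is.na(ok)] <- FALSE
  mean(ok)
}
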