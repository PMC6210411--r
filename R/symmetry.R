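#' Bilateral asymmetry index
#'
#' `Ia = (XL - XR) / max(XL, XR) * 100`: zero for perfect bilateral
#' symmetry, positive when the left side's value is larger, negative when
#' the right side's is, bounded by +/-100 for positive inputs. The index is
#' scale-invariant and antisymmetric under side exchange.
#'
#' @param x_left,x_right per-side values of a gait parameter (vectors are
#'   paired elementwise); both must be strictly positive — the ratio is
#'   undefined otherwise, and all gait parameters it is applied to are
#'   positive quantities.
#' @return Asymmetry index in percent.
#' @export
#' @examples
#' asymmetry_index(1.0, 0.9) # 10: left cycle time 10% longer
asymmetry_index <- function(x_left, x_right) {
  gm_assert(
    is.numeric(x_left) && is.numeric(x_right),
    "'x_left' and 'x_right' must be numeric", "gaitmark_domain_error"
  )
  if (any(!is.finite(x_left)) || any(!is.finite(x_right)) ||
    any(x_left <= 0) || any(x_right <= 0)) {
    gm_stop(
      "asymmetry index requires strictly positive side values",
      "gaitmark_domain_error"
    )
  }
  (x_left - x_right) / pmax(x_left, x_right) * 100
}

#' Asymmetry table from per-side condition summaries
#'
#' Applies [asymmetry_index()] to the per-side condition means of cycle
#' time, step height, step length and velocity. One index per condition and
#' parameter; per-cycle left/right pairing is not defined for independent
#' feet and is not attempted.
#'
#' @param left_summaries,right_summaries named lists (by condition label)
#'   of `condition_summary` objects built from each side's cycles.
#' @param parameters parameters to index (default `gct`, `sh`, `sl`,
#'   `vel`).
#' @return Data frame of class `asymmetry_table`: `condition`, `parameter`,
#'   `ia_pct` (`NA` with a warning when a side is missing).
#' @export
asymmetry_from_summaries <- function(left_summaries, right_summaries,
                                     parameters = c("gct", "sh", "sl", "vel")) {
  conds <- union(names(left_summaries), names(right_summaries))
  rows <- list()
  for (cc in conds) {
    for (p in parameters) {
      ia <- NA_real_
      l <- left_summaries[[cc]]
      r <- right_summaries[[cc]]
      if (is.null(l) || is.null(r)) {
        warning(sprintf(
          "condition '%s': missing %s side, asymmetry not computed",
          cc, if (is.null(l)) "left" else "right"
        ))
      } else {
        ml <- l$parameters$mean[l$parameters$parameter == p]
        mr <- r$parameters$mean[r$parameters$parameter == p]
        if (is.finite(ml) && is.finite(mr)) ia <- asymmetry_index(ml, mr)
      }
      rows[[paste(cc, p)]] <- data.frame(
        condition = cc, parameter = p, ia_pct = ia
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("asymmetry_table", "data.frame")
  out
}

#' Asymmetry table straight from a cycle table
#'
#' Convenience wrapper: splits `cycles` by side within each condition,
#' summarizes, and calls [asymmetry_from_summaries()]. Only straight-walking
#' cycles should be present (turn-overlapping cycles are already excluded
#' during extraction).
#'
#' @param cycles a `gait_cycles` data frame with `side` and `condition`
#'   columns.
#' @inheritParams asymmetry_from_summaries
#' @return An `asymmetry_table` data frame.
#' @export
gait_asymmetry <- function(cycles, parameters = c("gct", "sh", "sl", "vel")) {
  gm_assert(
    all(c("side", "condition") %in% names(cycles)),
    "'cycles' needs 'side' and 'condition' columns"
  )
  split_side <- function(s) {
    sub <- cycles[cycles$side == s, , drop = FALSE]
    if (nrow(sub) == 0L) {
      return(list())
    }
    summarize_conditions(sub)
  }
  asymmetry_from_summaries(split_side("left"), split_side("right"), parameters)
}
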