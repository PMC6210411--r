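#' Bundled published reference tables
#'
#' Group-level summary statistics from a six-subject study of parkinsonian
#' gait comparing unassisted walking (`c`), a conventional walker (`w`) and
#' a motorized walker delivering haptic speed cues at low/medium/high speed
#' (`ml`, `mm`, `mh`). These printed values serve as inputs for the
#' arithmetic-identity checks ([double_support_reduction()],
#' [derived_support_ratios()], [stance_identity_residuals()]); the raw
#' recordings behind them are not public, so the tables are reference data,
#' not reproduction targets.
#'
#' @return A list of data frames: `parameters` (parameter, condition, mean,
#'   sd), `ratios` (ratio, condition, value_pct), `asymmetry` (parameter,
#'   condition, ia_pct, upper_bound).
#' @export
gait_reference_tables <- function() {
  dir <- system.file("extdata", "reference", package = "gaitmark")
  read <- function(f) utils::read.csv(file.path(dir, f), comment.char = "#")
  list(
    parameters = read("group_parameter_summary.csv"),
    ratios = read("phase_ratio_summary.csv"),
    asymmetry = read("asymmetry_reference.csv")
  )
}

ratio_value <- function(ratios, ratio, condition) {
  v <- ratios$value_pct[ratios$ratio == ratio & ratios$condition == condition]
  gm_assert(
    length(v) == 1L,
    sprintf("no unique entry for ratio '%s', condition '%s'", ratio, condition)
  )
  v
}

#' Difference of a support-phase ratio between two conditions
#'
#' @param ratios a ratio table in the layout of
#'   `gait_reference_tables()$ratios` or [ratio_table()].
#' @param ratio one of `"st_gct"`, `"ids_gct"`, `"tds_gct"`, `"ids_st"`,
#'   `"tds_st"`.
#' @param cond_a,cond_b condition labels; the result is `a - b` in
#'   percentage points.
#' @export
phase_ratio_difference <- function(ratios, ratio, cond_a, cond_b) {
  ratio_value(ratios, ratio, cond_a) - ratio_value(ratios, ratio, cond_b)
}

#' Double-support reduction between two conditions
#'
#' The headline clinical quantity: how much smaller the initial and
#' terminal double-support shares of the gait cycle are in condition
#' `cond_b` than in `cond_a`, and their sum (the overall double-support
#' reduction).
#'
#' @inheritParams phase_ratio_difference
#' @return List with `ids`, `tds`, `total`, percentage points.
#' @export
double_support_reduction <- function(ratios, cond_a = "c", cond_b = "mm") {
  ids <- phase_ratio_difference(ratios, "ids_gct", cond_a, cond_b)
  tds <- phase_ratio_difference(ratios, "tds_gct", cond_a, cond_b)
  list(ids = ids, tds = tds, total = ids + tds)
}

#' Internal consistency of support ratios
#'
#' In a consistent summary, `IDS/ST = (IDS/GCT) / (ST/GCT)` and likewise
#' for TDS — the stance-based ratios are determined by the cycle-based
#' ones. This routine recomputes the stance-based ratios from the
#' cycle-based entries and reports the residual against the tabulated
#' values, per condition.
#'
#' @param ratios a ratio table (see [phase_ratio_difference()]).
#' @return Data frame: `condition`, `ratio` (`ids_st`/`tds_st`),
#'   `tabulated_pct`, `derived_pct`, `residual_pct`.
#' @export
derived_support_ratios <- function(ratios) {
  conds <- unique(ratios$condition)
  out <- list()
  for (cc in conds) {
    st <- ratio_value(ratios, "st_gct", cc)
    for (r in c("ids_st", "tds_st")) {
      num <- ratio_value(ratios, sub("_st$", "_gct", r), cc)
      tab <- ratio_value(ratios, r, cc)
      der <- 100 * num / st
      out[[paste(cc, r)]] <- data.frame(
        condition = cc, ratio = r, tabulated_pct = tab,
        derived_pct = der, residual_pct = tab - der
      )
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Stance-time identity in a parameter summary
#'
#' Stance is defined as cycle time minus swing time, so in any summary the
#' mean stance must equal mean cycle time minus mean swing up to the
#' rounding of the printed values.
#'
#' @param parameters a parameter table in the layout of
#'   `gait_reference_tables()$parameters` or [parameter_table()].
#' @return Data frame: `condition`, `gct_mean`, `sw_mean`, `st_mean`,
#'   `residual` (= `st - (gct - sw)`, seconds).
#' @export
stance_identity_residuals <- function(parameters) {
  conds <- unique(parameters$condition)
  pv <- function(p, cc) {
    v <- parameters$mean[parameters$parameter == p & parameters$condition == cc]
    gm_assert(
      length(v) == 1L,
      sprintf("no unique entry for parameter '%s', condition '%s'", p, cc)
    )
    v
  }
  out <- do.call(rbind, lapply(conds, function(cc) {
    g <- pv("gct", cc)
    s <- pv("sw", cc)
    st <- pv("st", cc)
    data.frame(
      condition = cc, gct_mean = g, sw_mean = s, st_mean = st,
      residual = st - (g - s)
    )
  }))
  rownames(out) <- NULL
  out
}
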