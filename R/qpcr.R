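# RT-qPCR comparison arm: ddCt relative quantification, primer-efficiency
# QC from dilution series, and IR* from relative quantities.

#' Relative quantity by the delta-delta-Ct method
#'
#' `ddCt = (ct_target - ct_ref_target) - (ct_calibrator - ct_ref_calibrator)`
#' and `RQ = 2^(-ddCt)`. The sign convention is the standard Livak one:
#' a template that crosses threshold one cycle *earlier* than the calibrator
#' is twice as abundant (lower Ct => higher RQ). Omitting the reference Cts
#' gives the delta-Ct-only mode, `RQ = 2^(ct_calibrator - ct_target)`, for
#' comparisons that need no reference-gene normalisation.
#'
#' @param ct_target Ct of the target sample.
#' @param ct_calibrator Ct of the calibrator sample (same primer pair).
#' @param ct_ref_target,ct_ref_calibrator reference-gene Cts for the two
#'   samples; both `NULL` for delta-Ct-only mode.
#' @return relative quantity (positive scalar); RQ = 1 means equal abundance.
#' @export
#' @examples
#' relative_quantity(22, 25, 20, 20) # ddCt = -3, RQ = 8
relative_quantity <- function(ct_target, ct_calibrator,
                              ct_ref_target = NULL, ct_ref_calibrator = NULL) {
  if (is.null(ct_ref_target) != is.null(ct_ref_calibrator)) {
    stop_config("provide both reference Cts or neither")
  }
  cts <- c(ct_target, ct_calibrator, ct_ref_target, ct_ref_calibrator)
  if (!all(is.finite(cts))) stop_data("all Ct values must be finite")
  d_target <- if (is.null(ct_ref_target)) ct_target else ct_target - ct_ref_target
  d_cal <- if (is.null(ct_ref_calibrator)) ct_calibrator else ct_calibrator - ct_ref_calibrator
  2^(-(d_target - d_cal))
}

#' Primer amplification efficiency from a log10 dilution series
#'
#' Fits Ct against log10(dilution) by least squares; the amplification
#' efficiency is `100 * (10^(-1/slope) - 1)` percent (100% = perfect
#' doubling per cycle, slope -1/log10(2) ~ -3.32). A primer pair passes QC
#' when efficiency lies in [90, 110]% and the fit's R^2 exceeds 0.985.
#'
#' @param dilution_log10 log10 of the template dilution for each reaction
#'   (e.g. 0, -1, -2, -3 for a 4-point 10-fold series; replicates repeat the
#'   value). At least 3 distinct points.
#' @param cts observed Ct values, same length.
#' @param primer_pair label carried into the result.
#' @param efficiency_range,r_squared_min QC thresholds.
#' @return list with `primer_pair`, `slope`, `efficiency_percent`,
#'   `r_squared`, `passes`.
#' @export
#' @examples
#' d <- rep(0:-3, each = 3)
#' primer_efficiency(d, 20 - d * 1 / log10(2), "metE_P1") # 100%, R^2 = 1
primer_efficiency <- function(dilution_log10, cts, primer_pair = NA_character_,
                              efficiency_range = c(90, 110),
                              r_squared_min = 0.985) {
  if (length(dilution_log10) != length(cts)) stop_data("dilution and Ct vectors differ in length")
  if (length(unique(dilution_log10)) < 3L) {
    stop_data("need >= 3 distinct dilution points to fit an efficiency")
  }
  fit <- stats::lm(cts ~ dilution_log10)
  slope <- unname(stats::coef(fit)[2])
  if (!is.finite(slope) || slope == 0) stop_data("degenerate dilution series (zero slope)")
  # R^2 by hand: summary.lm() warns on noise-free (exact) series
  r2 <- 1 - sum(stats::residuals(fit)^2) / sum((cts - mean(cts))^2)
  eff <- 100 * (10^(-1 / slope) - 1)
  list(
    primer_pair = primer_pair,
    slope = slope,
    efficiency_percent = eff,
    r_squared = r2,
    passes = eff >= efficiency_range[1] && eff <= efficiency_range[2] && r2 > r_squared_min
  )
}

#' IR* from qPCR relative quantities
#'
#' `IR* = (RQ_P3 / RQ_P1)_Met- / (RQ_P3 / RQ_P1)_Met+`. When every RQ is
#' proportional to the underlying concentration this equals
#' [induction_ratio_star()] computed from ddPCR concentrations — the
#' cross-platform comparison the alternative induction ratio exists for.
#' Terminated transcripts cannot be isolated by qPCR (no subtraction of
#' absolute concentrations is possible), which is why only IR*, not IR, has
#' a qPCR form.
#'
#' @param rq_P3_met_minus,rq_P3_met_plus relative quantities of the
#'   downstream (full-length-only) amplicon under Met- and Met+.
#' @param rq_P1_met_minus,rq_P1_met_plus relative quantities of the upstream
#'   (total-transcript) amplicon.
#' @return IR*, positive scalar.
#' @export
ir_star_from_rq <- function(rq_P3_met_minus, rq_P3_met_plus,
                            rq_P1_met_minus, rq_P1_met_plus) {
  rqs <- c(rq_P3_met_minus, rq_P3_met_plus, rq_P1_met_minus, rq_P1_met_plus)
  if (!all(is.finite(rqs)) || any(rqs <= 0)) {
    stop_data("all relative quantities must be finite and > 0")
  }
  (rq_P3_met_minus / rq_P1_met_minus) / (rq_P3_met_plus / rq_P1_met_plus)
}

#' Average replicate Ct records and compute per-sample relative quantities
#'
#' Replicate Cts are averaged arithmetically (cycle scale) before any ddCt
#' arithmetic, the standard treatment for technical triplicates.
#'
#' @param ct_df data.frame with columns `sample_id`, `primer_pair`, `ct`
#'   (replicate rows share `sample_id` and `primer_pair`).
#' @param ct_range plausible Ct band; values outside it are rejected.
#' @return data.frame `sample_id`, `primer_pair`, `ct_mean`, `n_replicates`.
#' @export
average_ct <- function(ct_df, ct_range = c(5, 40)) {
  need <- c("sample_id", "primer_pair", "ct")
  miss <- setdiff(need, names(ct_df))
  if (length(miss)) stop_data("missing Ct column(s): ", paste(miss, collapse = ", "))
  bad <- which(!is.finite(ct_df$ct) | ct_df$ct < ct_range[1] | ct_df$ct > ct_range[2])
  if (length(bad)) {
    stop_data("Ct outside plausible band [", ct_range[1], ", ", ct_range[2],
              "] at row(s) ", paste(utils::head(bad, 5), collapse = ", "))
  }
  agg <- stats::aggregate(ct ~ sample_id + primer_pair, data = ct_df,
                          FUN = function(x) c(mean = mean(x), n = length(x)))
  data.frame(
    sample_id = agg$sample_id,
    primer_pair = agg$primer_pair,
    ct_mean = agg$ct[, "mean"],
    n_replicates = as.integer(agg$ct[, "n"]),
    stringsAsFactors = FALSE
  )
}
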