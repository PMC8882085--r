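# Absolute quantification from droplet digital PCR readouts.
#
# A ddPCR reaction partitions the template into ~20,000 droplets; after
# endpoint PCR each droplet is read as positive (>= 1 template copy) or
# negative. Under random (multinomial) partitioning the per-droplet copy
# number is Poisson, so the fraction of negative droplets estimates
# exp(-lambda) and
#
#   lambda = -ln(1 - k/n),   c [copies/ul] = lambda / V_d * dilution
#
# with k positive droplets out of n and V_d the droplet volume in ul.
# This module replaces the instrument software's quantification step.

#' Construct a droplet-count record
#'
#' One row per well: the raw readout of a single ddPCR well for one
#' sample x assay combination.
#'
#' @param sample_id,assay_id identifiers (character scalars or vectors).
#' @param positives number of positive droplets (k), non-negative integer.
#' @param total total accepted droplets (n), positive integer.
#' @param dilution_factor template dilution applied before the reaction
#'   (>= 1; 1 = undiluted).
#' @param droplet_volume_nl droplet volume in nanoliters. The default 0.85 nl
#'   is typical for the QX100/QX200 generation of instruments; it is
#'   configurable because published work rarely states it.
#' @return a `data.frame` with class `ddpcr_counts`, one row per well.
#' @export
#' @examples
#' droplet_counts("s1", "metE_P1", positives = 4000, total = 20000)
droplet_counts <- function(sample_id, assay_id, positives, total,
                           dilution_factor = 1, droplet_volume_nl = 0.85) {
  df <- data.frame(
    sample_id = as.character(sample_id),
    assay_id = as.character(assay_id),
    positives = as.numeric(positives),
    total = as.numeric(total),
    dilution_factor = as.numeric(dilution_factor),
    droplet_volume_nl = as.numeric(droplet_volume_nl),
    stringsAsFactors = FALSE
  )
  validate_droplet_counts(df)
  class(df) <- c("ddpcr_counts", "data.frame")
  df
}

validate_droplet_counts <- function(df, file = NULL) {
  where <- if (is.null(file)) "" else paste0(" in '", file, "'")
  need <- c("sample_id", "assay_id", "positives", "total")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop_data("missing droplet-count column(s)", where, ": ", paste(miss, collapse = ", "))
  }
  bad <- which(!is.finite(df$positives) | !is.finite(df$total) |
                 df$positives < 0 | df$total < 1 | df$positives > df$total)
  if (length(bad)) {
    stop_data("invalid droplet counts", where, " at row(s) ",
              paste(utils::head(bad, 5), collapse = ", "),
              ": need 0 <= positives <= total, total >= 1")
  }
  if (!is.null(df$dilution_factor) && any(df$dilution_factor < 1, na.rm = TRUE)) {
    stop_data("dilution_factor must be >= 1", where)
  }
  if (!is.null(df$droplet_volume_nl) && any(df$droplet_volume_nl <= 0, na.rm = TRUE)) {
    stop_data("droplet_volume_nl must be > 0", where)
  }
  invisible(df)
}

#' Poisson concentration estimate from droplet counts
#'
#' Converts positive/total droplet counts into an absolute template
#' concentration via the digital-PCR Poisson correction
#' \eqn{\lambda = -\ln(1 - k/n)} and
#' \eqn{c = \lambda / V_d \times \mathrm{dilution}} (copies/ul, with
#' \eqn{V_d} in ul). Confidence bounds propagate the binomial uncertainty of
#' \eqn{k/n} through the same transform.
#'
#' With `ci_method = "delta"` the variance of \eqn{\hat\lambda} is
#' \eqn{p / ((1-p) n)} (delta method on \eqn{-\ln(1-p)}) and a symmetric
#' normal interval is used; `"clopper-pearson"` inverts the exact binomial
#' interval instead. For `k = 0` the point estimate is 0 and the upper bound
#' is the one-sided exact bound (so a clean well is never reported as
#' "exactly zero with no uncertainty"). For `k = n` the Poisson transform is
#' undefined (all droplets saturated): the estimate is flagged and the
#' concentration reported as `NA`, never a silent number.
#'
#' @param counts a `ddpcr_counts` data.frame (or anything with the same
#'   columns), one row per well.
#' @param confidence_level coverage of the interval, in (0, 1). Default 0.95.
#' @param ci_method `"delta"` (default) or `"clopper-pearson"`.
#' @return a `data.frame` with one row per input well: `sample_id`,
#'   `assay_id`, `lambda_per_droplet`, `copies_per_ul`, `ci_low`, `ci_high`
#'   (copies/ul), and `saturated` (logical).
#' @export
#' @examples
#' w <- droplet_counts("s1", "a1", positives = 12642, total = 20000)
#' poisson_concentration(w)
poisson_concentration <- function(counts, confidence_level = 0.95,
                                  ci_method = c("delta", "clopper-pearson")) {
  ci_method <- match.arg(ci_method)
  validate_droplet_counts(counts)
  if (!is.numeric(confidence_level) || length(confidence_level) != 1L ||
      confidence_level <= 0 || confidence_level >= 1) {
    stop_config("confidence_level must be a single number in (0, 1)")
  }
  k <- counts$positives
  n <- counts$total
  dil <- counts$dilution_factor %||% rep(1, length(k))
  vd_nl <- counts$droplet_volume_nl %||% rep(0.85, length(k))
  vd_ul <- vd_nl * 1e-3
  alpha <- 1 - confidence_level
  z <- stats::qnorm(1 - alpha / 2)

  p <- k / n
  saturated <- k == n
  lambda <- ifelse(saturated, NA_real_, -log1p(-p))

  # binomial bounds on p, then through the same -log(1-p) transform
  p_lo <- p_hi <- rep(NA_real_, length(k))
  if (ci_method == "delta") {
    sd_lam <- sqrt(p / ((1 - p) * n))
    lam_lo <- pmax(0, lambda - z * sd_lam)
    lam_hi <- lambda + z * sd_lam
  } else {
    p_lo <- stats::qbeta(alpha / 2, k, n - k + 1)
    p_hi <- stats::qbeta(1 - alpha / 2, k + 1, n - k)
    lam_lo <- -log1p(-p_lo)
    lam_hi <- -log1p(-p_hi)
  }
  # k = 0: point estimate 0, one-sided exact upper bound (> 0 by construction)
  zero <- !saturated & k == 0
  if (any(zero)) {
    lam_lo[zero] <- 0
    lam_hi[zero] <- -log1p(-(1 - alpha^(1 / n[zero])))
  }
  lam_lo[saturated] <- NA_real_
  lam_hi[saturated] <- NA_real_
  if (any(saturated)) {
    warning(sum(saturated), " saturated well(s) (all droplets positive); ",
            "concentration undefined, dilute and re-run")
  }

  scale <- dil / vd_ul
  out <- data.frame(
    sample_id = counts$sample_id,
    assay_id = counts$assay_id,
    lambda_per_droplet = lambda,
    copies_per_ul = lambda * scale,
    ci_low = lam_lo * scale,
    ci_high = lam_hi * scale,
    saturated = saturated,
    stringsAsFactors = FALSE
  )
  class(out) <- c("ddpcr_estimates", "data.frame")
  out
}

#' Pool replicate wells before quantification
#'
#' Merges replicate wells of the same sample x assay by summing positive and
#' total droplet counts and applying the Poisson transform once. Pooling raw
#' counts (rather than averaging per-well concentrations) is the sufficient-
#' statistic treatment: the combined droplets are one larger partition of the
#' same template, so the pooled estimate has the correct (narrower)
#' confidence interval.
#'
#' @param counts `ddpcr_counts` rows; all rows must share `assay_id` and
#'   `sample_id` (they are replicates of one measurement). Dilution and
#'   droplet volume must also agree.
#' @inheritParams poisson_concentration
#' @return a one-row estimate as from [poisson_concentration()].
#' @export
merge_replicates <- function(counts, confidence_level = 0.95,
                             ci_method = c("delta", "clopper-pearson")) {
  validate_droplet_counts(counts)
  if (nrow(counts) == 0L) stop_data("no wells to merge")
  if (length(unique(counts$assay_id)) != 1L) {
    stop_data("cannot merge wells with mixed assay_id: ",
              paste(unique(counts$assay_id), collapse = ", "))
  }
  if (length(unique(counts$sample_id)) != 1L) {
    stop_data("cannot merge wells with mixed sample_id: ",
              paste(unique(counts$sample_id), collapse = ", "))
  }
  dil <- counts$dilution_factor %||% rep(1, nrow(counts))
  vd <- counts$droplet_volume_nl %||% rep(0.85, nrow(counts))
  if (length(unique(dil)) != 1L || length(unique(vd)) != 1L) {
    stop_data("replicate wells disagree on dilution_factor or droplet_volume_nl")
  }
  pooled <- droplet_counts(
    sample_id = counts$sample_id[1], assay_id = counts$assay_id[1],
    positives = sum(counts$positives), total = sum(counts$total),
    dilution_factor = dil[1], droplet_volume_nl = vd[1]
  )
  poisson_concentration(pooled, confidence_level, match.arg(ci_method))
}
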