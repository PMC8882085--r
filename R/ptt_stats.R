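# PTT statistics: terminated-transcript concentration, termination fraction,
# cleavage efficiency, and the two induction ratios.
#
# Notation (concentrations in copies/ul, one gene x condition x time point):
#   P1 — amplicon upstream of the PTT site: full-length + terminated
#   P2 — amplicon flanking the RNase H cleavage site: cleavage control
#   P3 — amplicon downstream of the cut: full-length only
# so
#   FL = P3,  T = P1 - P3,  termination fraction = T / P1.
#
# Two induction ratios compare methionine starvation (Met-) against
# methionine presence (Met+):
#   IR  = (FL/T)_Met- / (FL/T)_Met+          — ddPCR-only (needs T directly)
#   IR* = (FL/(FL+T))_Met- / (FL/(FL+T))_Met+ = (P3/P1)- / (P3/P1)+
# IR* is also computable from RT-qPCR relative quantities, where terminated
# transcripts cannot be isolated; whenever termination is higher under Met+
# than Met-, IR >= IR*.

#' One sample's three amplicon concentrations
#'
#' @param gene gene/operon name.
#' @param condition `"Met_plus"` or `"Met_minus"`.
#' @param timepoint_h time since methionine removal, hours.
#' @param cleaved was the RNase H / DNA-oligomer cleavage performed?
#' @param P1,P2,P3 concentrations in copies/ul (`P2` optional, `NA` if the
#'   cleavage-control assay was not run).
#' @return a `sample_measurement` list.
#' @export
sample_measurement <- function(gene, condition = c("Met_minus", "Met_plus"),
                               timepoint_h, cleaved, P1, P3, P2 = NA_real_) {
  condition <- match.arg(condition)
  if (any(c(P1, P3) < 0, na.rm = TRUE)) stop_data("concentrations must be >= 0")
  structure(list(
    gene = as.character(gene), condition = condition,
    timepoint_h = as.numeric(timepoint_h), cleaved = isTRUE(cleaved),
    P1 = as.numeric(P1), P2 = as.numeric(P2), P3 = as.numeric(P3)
  ), class = "sample_measurement")
}

#' Full-length / terminated decomposition of one measurement
#'
#' Splits the upstream-amplicon concentration into full-length (`FL = P3`)
#' and prematurely terminated (`T = P1 - P3`) components and derives the
#' termination fraction `T / P1`. Measurement noise can push `P3` above `P1`;
#' the negative `T` is then reported as computed and flagged rather than
#' clamped, so QC can catch failing assays — ratio operations refuse flagged
#' estimates.
#'
#' @param m a [sample_measurement()], or a list with elements `P1`, `P3`.
#' @return a `ptt_estimate` list with fields `FL`, `T`, `termination_fraction`,
#'   `fl_to_t_ratio` (`NA` when `T <= 0`), `negative_T_flag`, plus the sample
#'   annotation carried through.
#' @export
#' @examples
#' m <- sample_measurement("metE", "Met_minus", 2, TRUE, P1 = 100, P3 = 25)
#' ptt_estimate(m)
ptt_estimate <- function(m) {
  P1 <- m$P1
  P3 <- m$P3
  if (!is.finite(P1) || !is.finite(P3)) stop_data("P1 and P3 must be finite")
  if (P1 <= 0) stop_data("P1 = 0: termination fraction undefined (gene ",
                         m$gene %||% "?", ")")
  T_ <- P1 - P3
  structure(list(
    gene = m$gene %||% NA_character_,
    condition = m$condition %||% NA_character_,
    timepoint_h = m$timepoint_h %||% NA_real_,
    cleaved = m$cleaved %||% NA,
    P1 = P1, P3 = P3,
    FL = P3,
    T = T_,
    termination_fraction = T_ / P1,
    fl_to_t_ratio = if (T_ > 0) P3 / T_ else NA_real_,
    negative_T_flag = T_ < 0
  ), class = "ptt_estimate")
}

#' RNase H cleavage efficiency from the P2 control amplicon
#'
#' The P2 amplicon spans the cleavage site, so cleavage destroys its
#' template: efficiency is estimated as `1 - P2(with oligomer) / P2(without)`.
#' Values are clamped to [0, 1]; when the with-oligomer concentration exceeds
#' the without-oligomer one (possible only through noise) the result is 0
#' with an `out_of_range` attribute set.
#'
#' @param p2_with_oligo,p2_without_oligo P2 concentrations, copies/ul.
#' @return efficiency in [0, 1], attribute `out_of_range` (logical).
#' @export
#' @examples
#' cleavage_efficiency(15, 500) # 0.97
cleavage_efficiency <- function(p2_with_oligo, p2_without_oligo) {
  if (!is.finite(p2_without_oligo) || p2_without_oligo <= 0) {
    stop_data("cleavage efficiency undefined: P2 without oligomer must be > 0")
  }
  if (p2_with_oligo < 0) stop_data("P2 concentrations must be >= 0")
  e <- 1 - p2_with_oligo / p2_without_oligo
  out_of_range <- e < 0
  structure(min(1, max(0, e)), out_of_range = out_of_range)
}

refuse_if_flagged <- function(est, role) {
  if (isTRUE(est$negative_T_flag)) {
    stop_data("refusing ", role, ": negative terminated-transcript estimate ",
              "(P3 > P1) for gene ", est$gene %||% "?", "; check assay QC")
  }
}

#' Riboswitch induction ratio (IR)
#'
#' `IR = (FL/T)_Met- / (FL/T)_Met+`, the fold-change of the full-length to
#' terminated balance between methionine starvation and methionine presence.
#' Requires direct access to `T`, i.e. the ddPCR arm.
#'
#' @param met_minus,met_plus [ptt_estimate()]s for the starvation (Met-) and
#'   presence (Met+) conditions.
#' @return IR, a positive scalar.
#' @export
#' @examples
#' mm <- ptt_estimate(list(P1 = 100, P3 = 80)) # Met-: mostly full-length
#' mp <- ptt_estimate(list(P1 = 100, P3 = 20)) # Met+: mostly terminated
#' induction_ratio(mm, mp) # 16
induction_ratio <- function(met_minus, met_plus) {
  refuse_if_flagged(met_minus, "IR (Met- arm)")
  refuse_if_flagged(met_plus, "IR (Met+ arm)")
  if (met_minus$T <= 0) stop_data("IR undefined: T_Met- <= 0 (no terminated transcript in Met-)")
  if (met_plus$T <= 0) stop_data("IR undefined: T_Met+ <= 0 (no terminated transcript in Met+)")
  if (met_minus$FL <= 0) stop_data("IR undefined: FL_Met- <= 0")
  if (met_plus$FL <= 0) stop_data("IR undefined: FL_Met+ <= 0")
  (met_minus$FL / met_minus$T) / (met_plus$FL / met_plus$T)
}

#' Alternative induction ratio (IR*)
#'
#' `IR* = (FL/(FL+T))_Met- / (FL/(FL+T))_Met+ = (P3/P1)_Met- / (P3/P1)_Met+`.
#' Uses only quantities measurable by both ddPCR and RT-qPCR (the fraction of
#' transcripts that are full-length), so it is the statistic on which the two
#' platforms can be compared.
#'
#' @inheritParams induction_ratio
#' @return IR*, a non-negative scalar (0, with a warning, when Met- has no
#'   full-length signal).
#' @export
induction_ratio_star <- function(met_minus, met_plus) {
  refuse_if_flagged(met_minus, "IR* (Met- arm)")
  refuse_if_flagged(met_plus, "IR* (Met+ arm)")
  if (met_minus$P1 <= 0 || met_plus$P1 <= 0) stop_data("IR* undefined: P1 must be > 0 in both conditions")
  if (met_plus$FL <= 0) stop_data("IR* undefined: FL_Met+ <= 0")
  if (met_minus$FL <= 0) {
    warning("FL_Met- = 0: IR* = 0 (no full-length signal under starvation)")
  }
  (met_minus$P3 / met_minus$P1) / (met_plus$P3 / met_plus$P1)
}

#' Percent change in IR caused by RNase H cleavage
#'
#' `100 * (IR_with - IR_without) / IR_without`. The rounded value uses
#' round-half-away-from-zero, the convention of printed comparison tables.
#'
#' @param ir_without_cleavage IR from the control (no DNA oligomer) arm; > 0.
#' @param ir_with_cleavage IR from the cleaved arm.
#' @return list with `raw` (percent) and `rounded` (integer percent).
#' @export
#' @examples
#' ir_percent_difference(17.38, 25.91)$rounded # 49
ir_percent_difference <- function(ir_without_cleavage, ir_with_cleavage) {
  if (!is.finite(ir_without_cleavage) || ir_without_cleavage <= 0) {
    stop_data("baseline (no-cleavage) IR must be > 0")
  }
  raw <- 100 * (ir_with_cleavage - ir_without_cleavage) / ir_without_cleavage
  list(raw = raw, rounded = round_half_away(raw))
}

#' Summarise the effect of RNase H cleavage on induction ratios
#'
#' Takes matched with/without-cleavage IR pairs (one per gene x time point)
#' and reports the per-pair percent differences plus their mean and maximum
#' over a gene subset — by default every gene except designated controls,
#' since the cleavage effect is defined relative to uncleaved controls and a
#' non-riboswitch control gene has no termination signal to unbias.
#'
#' @param pairs data.frame with columns `gene`, `timepoint_h`,
#'   `ir_no_cleavage`, `ir_cleavage` (one row per matched pair).
#' @param control_genes genes excluded from the mean/max (default `"gyrA"`).
#' @return list with `table` (per-pair raw and rounded percent differences,
#'   plus an `is_control` column), `mean_percent` and `max_percent` (raw, over
#'   non-control genes), and their rounded counterparts.
#' @export
summarize_cleavage_effect <- function(pairs, control_genes = "gyrA") {
  need <- c("gene", "timepoint_h", "ir_no_cleavage", "ir_cleavage")
  miss <- setdiff(need, names(pairs))
  if (length(miss)) stop_data("missing column(s): ", paste(miss, collapse = ", "))
  key <- paste(pairs$gene, pairs$timepoint_h)
  if (anyDuplicated(key)) {
    stop_data("duplicate gene x timepoint pair(s): ",
              paste(unique(key[duplicated(key)]), collapse = ", "))
  }
  orphan <- !is.finite(pairs$ir_no_cleavage) | !is.finite(pairs$ir_cleavage)
  if (any(orphan)) {
    stop_data("unmatched pair(s) (missing IR) for: ",
              paste(key[orphan], collapse = ", "))
  }
  diffs <- mapply(function(a, b) ir_percent_difference(a, b)$raw,
                  pairs$ir_no_cleavage, pairs$ir_cleavage)
  tab <- data.frame(
    gene = pairs$gene,
    timepoint_h = pairs$timepoint_h,
    ir_no_cleavage = pairs$ir_no_cleavage,
    ir_cleavage = pairs$ir_cleavage,
    difference_pct = diffs,
    difference_pct_rounded = round_half_away(diffs),
    is_control = pairs$gene %in% control_genes,
    stringsAsFactors = FALSE
  )
  keep <- !tab$is_control
  if (!any(keep)) stop_data("no non-control pairs to summarise")
  list(
    table = tab,
    mean_percent = mean(tab$difference_pct[keep]),
    max_percent = max(tab$difference_pct[keep]),
    mean_percent_rounded = round_half_away(mean(tab$difference_pct[keep])),
    max_percent_rounded = round_half_away(max(tab$difference_pct[keep]))
  )
}
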