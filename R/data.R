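# Worked-example data shipped with the package.

#' Worked-example induction-ratio table
#'
#' Induction ratios for a five-gene *Bacillus subtilis* panel (the gyrA
#' non-riboswitch control plus the SAM-riboswitch genes/operons samT, metIC,
#' metE and mtnKA) at four methionine-starvation time points, measured by
#' ddPCR with (`ir_cleavage`) and without (`ir_no_cleavage`) oligomer-
#' directed RNase H cleavage, together with the percent difference as
#' printed in the original comparison (integer, half rounded away from
#' zero). This is the table the cleavage-effect summary operations are
#' demonstrated and regression-tested on: recomputing the differences from
#' the IR pairs reproduces the printed column within rounding of the
#' unrounded source data (±2 points), and the riboswitch-gene mean is ~23%.
#'
#' @param path override the bundled CSV (rarely needed).
#' @return data.frame with columns `gene`, `timepoint_h`, `ir_no_cleavage`,
#'   `ir_cleavage`, `printed_difference_pct`.
#' @export
#' @examples
#' ir <- example_induction_ratios()
#' summarize_cleavage_effect(ir)$mean_percent # ~23
example_induction_ratios <- function(path = system.file("extdata", "sam_riboswitch_ir.csv",
                                                        package = "pttquant")) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
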