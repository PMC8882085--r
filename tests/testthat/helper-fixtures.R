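# Shared fixtures: a compact assay design, a single-gene induction profile,
# and a generic pipeline runner for simulator-driven tests.

fixture_design <- function(full_length = 1500, gene = "demo") {
  assay_design(
    gene = gene,
    amplicon_P1 = c(40, 111),          # 3'-distance 200 on the 5' fragment
    amplicon_P2 = c(290, 330),         # spans the cut at 310
    amplicon_P3 = c(full_length - 270, full_length - 199), # 3'-distance 200
    ptt_site = 300, cleavage_site = 310, full_length = full_length
  )
}

fixture_profile <- function(f_minus = 0.3, f_plus = 0.9, gene = "demo",
                            timepoint_h = 0) {
  rbind(
    data.frame(gene = gene, condition = "Met_minus", timepoint_h = timepoint_h,
               termination_fraction = f_minus, stringsAsFactors = FALSE),
    data.frame(gene = gene, condition = "Met_plus", timepoint_h = timepoint_h,
               termination_fraction = f_plus, stringsAsFactors = FALSE)
  )
}

# simulate one gene at one timepoint and return recovered IRs for both arms
recover_ir <- function(seed, design, f_minus = 0.3, f_plus = 0.9, ...) {
  cfg <- sim_config(seed = seed,
                    induction_profile = fixture_profile(f_minus, f_plus,
                                                        gene = design$gene), ...)
  pools <- list(
    Met_minus = simulate_pool(cfg, design, "Met_minus", 0),
    Met_plus = simulate_pool(cfg, design, "Met_plus", 0)
  )
  one <- function(pool, cleaved) {
    wells <- simulate_measurement(pool, design, cfg, cleaved = cleaved)
    est <- quantify_wells(wells)
    ptt_estimate(list(
      P1 = est$copies_per_ul[grepl("_P1$", est$assay_id)],
      P3 = est$copies_per_ul[grepl("_P3$", est$assay_id)]
    ))
  }
  list(
    cut = induction_ratio(one(pools$Met_minus, TRUE), one(pools$Met_plus, TRUE)),
    uncut = induction_ratio(one(pools$Met_minus, FALSE), one(pools$Met_plus, FALSE))
  )
}
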