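# Generative model of the RT / RNase H cleavage / ddPCR workflow.
#
# The chain mirrors the bench protocol:
#   transcript pool -> (optional) oligomer-directed RNase H cleavage
#                   -> random-hexamer reverse transcription
#                   -> droplet partitioning -> positive/total counts.
#
# Reverse transcription is the step that creates the 3'-distance bias.
# Hexamer priming events are homogeneous-Poisson along each molecule (rate
# rho per nt) and extension toward the 5' end survives each nucleotide with
# probability sigma. A cDNA from a priming site at position p covers an
# amplicon [a, b] iff p >= b and extension reached a, so the expected number
# of detectable cDNA copies per molecule of length l is
#
#   E[copies] = rho * sum_{p = b..l} sigma^(p - a)
#             = rho * sigma^(b - a) * (1 - sigma^(l - b + 1)) / (1 - sigma)
#
# and with fully processive RT (sigma = 1) this is rho * (l - b + 1):
# proportional to the amplicon's distance from the molecule's 3' end. Two
# amplicons at equal 3'-distances get equal coverage — the design principle
# the equal-distance P1/P3 placement exploits; an amplicon far from the 3'
# end is proportionally over-represented — the bias the cleavage removes.

#' Simulator configuration
#'
#' Defaults describe a routine bacterial riboswitch time-course experiment:
#' ~20,000 accepted droplets of 0.85 nl, near-complete oligomer-directed
#' cleavage (e = 0.97, the upper range of reported RNase H efficiencies),
#' fully processive RT (sigma = 1, the cleanest realisation of the linear
#' 3'-distance bias), and a priming density rho chosen so per-assay droplet
#' occupancies land in the quantifiable range (lambda ~ 0.1-5) at
#' 20,000-molecule pools.
#'
#' @param priming_rate_rho expected hexamer priming events per nt per
#'   molecule (> 0).
#' @param extension_survival_sigma per-nt probability that RT extension
#'   continues toward the 5' end, in [0, 1]; 1 = fully processive.
#' @param cleavage_efficiency_e probability a full-length molecule is cut at
#'   the oligomer site, in [0, 1].
#' @param n_droplets droplets per reaction.
#' @param droplet_volume_nl droplet volume, nl.
#' @param reaction_volume_ul reaction volume, ul (bookkeeping only).
#' @param total_copies transcript molecules per gene x condition x time point.
#' @param max_lambda auto-dilution threshold: template is diluted in powers
#'   of 10 until the expected mean copies per droplet is below this, as an
#'   experimenter would to avoid saturating the droplet reader.
#' @param seed master seed; every stage derives its own substream from it.
#' @param induction_profile data.frame with columns `gene`, `timepoint_h`,
#'   `condition`, `termination_fraction`; default [default_induction_profile()].
#' @return a `sim_config` list.
#' @export
sim_config <- function(priming_rate_rho = 0.005,
                       extension_survival_sigma = 1,
                       cleavage_efficiency_e = 0.97,
                       n_droplets = 20000,
                       droplet_volume_nl = 0.85,
                       reaction_volume_ul = 20,
                       total_copies = 20000,
                       max_lambda = 3,
                       seed = 1,
                       induction_profile = default_induction_profile()) {
  if (priming_rate_rho <= 0) stop_config("priming_rate_rho must be > 0")
  if (extension_survival_sigma < 0 || extension_survival_sigma > 1) {
    stop_config("extension_survival_sigma must be in [0, 1]")
  }
  if (cleavage_efficiency_e < 0 || cleavage_efficiency_e > 1) {
    stop_config("cleavage_efficiency_e must be in [0, 1]")
  }
  if (n_droplets < 1) stop_config("n_droplets must be >= 1")
  structure(list(
    priming_rate_rho = priming_rate_rho,
    extension_survival_sigma = extension_survival_sigma,
    cleavage_efficiency_e = cleavage_efficiency_e,
    n_droplets = as.integer(n_droplets),
    droplet_volume_nl = droplet_volume_nl,
    reaction_volume_ul = reaction_volume_ul,
    total_copies = as.integer(total_copies),
    max_lambda = max_lambda,
    seed = as.integer(seed),
    induction_profile = induction_profile
  ), class = "sim_config")
}

#' Default riboswitch induction profile
#'
#' Termination fractions per gene, condition and starvation time point,
#' encoding the qualitative structure of a SAM-riboswitch methionine-
#' starvation time course: under methionine (Met_plus) riboswitch-controlled
#' genes terminate ~90% of transcripts at all times; under starvation
#' (Met_minus) termination relaxes with a maximum relief (hence IR peak) at
#' 2 h for metE, metIC and samT, an early weak relief at 1 h for mtnKA, and
#' no riboswitch response at all for the gyrA control (constant 30%
#' termination-like background in both conditions, IR ~ 1).
#'
#' @return data.frame with columns `gene`, `condition`, `timepoint_h`,
#'   `termination_fraction`.
#' @export
default_induction_profile <- function() {
  tp <- c(0, 1, 2, 3)
  f_minus <- list(
    metE  = c(0.90, 0.55, 0.17, 0.25),
    metIC = c(0.90, 0.80, 0.26, 0.80),
    samT  = c(0.90, 0.65, 0.35, 0.48),
    mtnKA = c(0.90, 0.79, 0.85, 0.88),
    gyrA  = c(0.30, 0.30, 0.30, 0.30)
  )
  f_plus <- list(
    metE = rep(0.9, 4), metIC = rep(0.9, 4), samT = rep(0.9, 4),
    mtnKA = rep(0.9, 4), gyrA = rep(0.3, 4)
  )
  do.call(rbind, lapply(names(f_minus), function(g) {
    rbind(
      data.frame(gene = g, condition = "Met_minus", timepoint_h = tp,
                 termination_fraction = f_minus[[g]], stringsAsFactors = FALSE),
      data.frame(gene = g, condition = "Met_plus", timepoint_h = tp,
                 termination_fraction = f_plus[[g]], stringsAsFactors = FALSE)
    )
  }))
}

#' Demo assay-design panel matching the default profile
#'
#' One shared geometry across the five-gene panel: a 1500-nt transcript with
#' the riboswitch terminator at nt 300, the oligomer-directed cut 10 nt
#' downstream, and P1/P3 placed 200 nt from the 3' ends of the 5' cleavage
#' fragment and the full-length transcript respectively.
#'
#' @param genes panel gene names.
#' @param full_length transcript length L, nt.
#' @return named list of [assay_design()] objects.
#' @export
demo_design <- function(genes = c("gyrA", "samT", "metIC", "metE", "mtnKA"),
                        full_length = 1500) {
  designs <- lapply(genes, function(g) {
    assay_design(
      gene = g,
      amplicon_P1 = c(40, 111),
      amplicon_P2 = c(290, 330),
      amplicon_P3 = c(full_length - 270, full_length - 199),
      ptt_site = 300, cleavage_site = 310, full_length = full_length
    )
  })
  names(designs) <- genes
  designs
}

#' Simulate a transcript pool for one gene / condition / time point
#'
#' Molecule counts: `n_terminated ~ Binomial(total, f)` with `f` the
#' termination fraction from the induction profile; the rest are full-length.
#'
#' @param config [sim_config()].
#' @param design [assay_design()] for the gene.
#' @param condition,timepoint_h profile keys.
#' @return a `transcript_pool` list with species table (`species`, `start`,
#'   `end`, `count`) and the annotation.
#' @export
simulate_pool <- function(config, design, condition, timepoint_h) {
  prof <- config$induction_profile
  hit <- prof$gene == design$gene & prof$condition == condition &
    prof$timepoint_h == timepoint_h
  if (sum(hit) != 1L) {
    stop_config("induction profile has ", sum(hit), " entries for ",
                design$gene, " / ", condition, " / ", timepoint_h, " h")
  }
  f <- prof$termination_fraction[hit]
  n_term <- with_seed(
    derive_seed(config$seed, "pool", pool_index(design$gene, condition, timepoint_h)),
    stats::rbinom(1, config$total_copies, f)
  )
  structure(list(
    gene = design$gene, condition = condition, timepoint_h = timepoint_h,
    termination_fraction = f,
    n_full_length = config$total_copies - n_term,
    n_terminated = n_term,
    species = data.frame(
      species = c("full_length", "terminated"),
      start = c(1, 1),
      end = c(design$full_length, design$ptt_site),
      count = c(config$total_copies - n_term, n_term),
      stringsAsFactors = FALSE
    )
  ), class = "transcript_pool")
}

pool_index <- function(gene, condition, timepoint_h) {
  sum(utf8ToInt(paste(gene, condition, timepoint_h))) %% 9973L
}

#' Oligomer-directed RNase H cleavage of a pool
#'
#' Each full-length molecule is cut at the cleavage site with probability
#' `e`, independently, into a 5' fragment `[1, c]` and a 3' fragment
#' `[c + 1, L]`. Terminated molecules end upstream of the site and are
#' untouched. Total molecule mass is conserved: intact + 5' fragments equals
#' the original full-length count.
#'
#' @param pool a `transcript_pool`.
#' @param design the matching [assay_design()].
#' @param e cleavage efficiency in [0, 1].
#' @param seed integer seed for the binomial draw.
#' @return the pool with its species table rewritten in fragments.
#' @export
cleave_pool <- function(pool, design, e, seed) {
  if (e < 0 || e > 1) stop_config("cleavage efficiency must be in [0, 1]")
  n_fl <- pool$species$count[pool$species$species == "full_length"]
  n_cut <- if (e == 0) 0L else if (e == 1) n_fl else {
    with_seed(seed, stats::rbinom(1, n_fl, e))
  }
  L <- design$full_length
  cpos <- design$cleavage_site
  pool$species <- rbind(
    data.frame(species = "full_length", start = 1, end = L,
               count = n_fl - n_cut, stringsAsFactors = FALSE),
    data.frame(species = "fragment_5p", start = 1, end = cpos, count = n_cut,
               stringsAsFactors = FALSE),
    data.frame(species = "fragment_3p", start = cpos + 1, end = L, count = n_cut,
               stringsAsFactors = FALSE),
    pool$species[pool$species$species == "terminated", , drop = FALSE]
  )
  rownames(pool$species) <- NULL
  pool$cleaved <- TRUE
  pool
}

#' Expected detectable cDNA copies for one amplicon over a species table
#'
#' Closed-form expectation of the RT model (see the header of this file).
#' Amplicons not fully contained in a molecule contribute zero (the target
#' was cleaved away or never transcribed), never an error.
#'
#' @param species data.frame with `start`, `end`, `count` rows (molecule
#'   species as coordinate intervals on the transcript).
#' @param amplicon `c(start, end)` transcript coordinates.
#' @param rho priming rate per nt.
#' @param sigma extension survival per nt.
#' @return expected copy number (scalar).
#' @export
expected_amplicon_copies <- function(species, amplicon, rho, sigma) {
  a <- amplicon[1]; b <- amplicon[2]
  per_mol <- mapply(function(s, e2) {
    if (a < s || b > e2) return(0)  # amplicon not carried by this species
    n_sites <- e2 - b + 1           # priming positions p = b .. end
    if (sigma >= 1) {
      rho * n_sites
    } else if (sigma <= 0) {
      0                              # no extension ever reaches a (a < b <= p)
    } else {
      rho * sigma^(b - a) * (1 - sigma^n_sites) / (1 - sigma)
    }
  }, species$start, species$end)
  sum(per_mol * species$count)
}

#' Realized cDNA synthesis for the three assay amplicons
#'
#' Draws Poisson-distributed copy numbers around the closed-form
#' expectations, summed over all molecules of the pool.
#'
#' @param pool a `transcript_pool` (cleaved or not).
#' @param design [assay_design()].
#' @param rho,sigma RT model parameters.
#' @param seed integer seed.
#' @return list with `expected` and `realized`, each a named numeric vector
#'   over `P1`, `P2`, `P3`.
#' @export
reverse_transcribe <- function(pool, design, rho, sigma, seed) {
  amps <- list(P1 = design$amplicon_P1, P2 = design$amplicon_P2,
               P3 = design$amplicon_P3)
  expected <- vapply(amps, function(a) {
    expected_amplicon_copies(pool$species, a, rho, sigma)
  }, numeric(1))
  realized <- with_seed(seed, stats::rpois(length(expected), expected))
  names(realized) <- names(expected)
  list(expected = expected, realized = realized)
}

#' Partition cDNA copies into droplets
#'
#' Copies are assigned to droplets uniformly at random (multinomial); a
#' droplet is positive when it holds at least one copy. This is the step the
#' Poisson correction of [poisson_concentration()] inverts.
#'
#' @param cdna_copies integer number of template copies in the reaction.
#' @param n_droplets number of droplets.
#' @param seed integer seed.
#' @return list `positives`, `total`.
#' @export
partition_droplets <- function(cdna_copies, n_droplets, seed) {
  if (n_droplets < 1) stop_config("n_droplets must be >= 1")
  if (cdna_copies < 0) stop_config("cdna_copies must be >= 0")
  positives <- if (cdna_copies == 0) 0L else {
    with_seed(seed, length(unique(sample.int(n_droplets, cdna_copies, replace = TRUE))))
  }
  list(positives = positives, total = as.integer(n_droplets))
}

#' Simulate the full ddPCR readout for one sample
#'
#' Composes cleavage (optional), reverse transcription and droplet
#' partitioning for one gene x condition x time point, with automatic
#' power-of-10 template dilution when the expected droplet occupancy exceeds
#' `config$max_lambda` (the dilution factor is recorded in the output and
#' undone by the quantification, exactly as on the bench).
#'
#' @param pool `transcript_pool` from [simulate_pool()] — pass the *same*
#'   pool to the cleaved and uncleaved arms to compare them on identical
#'   molecules.
#' @param design [assay_design()].
#' @param config [sim_config()].
#' @param cleaved logical; run the RNase H arm?
#' @return `ddpcr_counts` rows (one per amplicon) plus attribute `truth`
#'   (expected copies, realized copies, dilution per amplicon).
#' @export
simulate_measurement <- function(pool, design, config, cleaved) {
  idx <- pool_index(design$gene, pool$condition, pool$timepoint_h) +
    if (cleaved) 1L else 0L
  worked <- if (cleaved) {
    cleave_pool(pool, design, config$cleavage_efficiency_e,
                derive_seed(config$seed, "cleave", idx))
  } else {
    pool
  }
  rt <- reverse_transcribe(worked, design, config$priming_rate_rho,
                           config$extension_survival_sigma,
                           derive_seed(config$seed, "rt", idx))
  arm <- if (cleaved) "cut" else "uncut"
  sid <- paste(design$gene, pool$condition, paste0(pool$timepoint_h, "h"), arm,
               sep = "_")
  rows <- lapply(seq_along(rt$realized), function(i) {
    amp <- names(rt$realized)[i]
    copies <- rt$realized[[i]]
    # auto-dilute in powers of 10 to keep occupancy quantifiable
    dil <- 1
    while (rt$expected[[i]] / dil / config$n_droplets > config$max_lambda) dil <- dil * 10
    loaded <- if (dil > 1) {
      with_seed(derive_seed(config$seed, "dilute", idx + 7L * i),
                stats::rbinom(1, copies, 1 / dil))
    } else copies
    part <- partition_droplets(loaded, config$n_droplets,
                               derive_seed(config$seed, "droplets", idx + 13L * i))
    droplet_counts(
      sample_id = sid, assay_id = paste(design$gene, amp, sep = "_"),
      positives = part$positives, total = part$total,
      dilution_factor = dil, droplet_volume_nl = config$droplet_volume_nl
    )
  })
  out <- do.call(rbind, rows)
  attr(out, "truth") <- list(expected = rt$expected, realized = rt$realized,
                             termination_fraction = pool$termination_fraction)
  class(out) <- c("ddpcr_counts", "data.frame")
  out
}

#' Closed-form expected measurement (no simulation)
#'
#' The analytic expectation of P1/P2/P3 concentrations (copies/ul) for a
#' termination fraction `f`, including the effect of incomplete cleavage.
#' This is the model's prediction of what the pipeline measures; ratios of
#' these values define the *analytic* IR / IR* that the stochastic pipeline
#' should recover. With `e = 1` and equal 3'-distance amplicon placement the
#' analytic IR reduces to the idealized `((1-f)/f)_Met- / ((1-f)/f)_Met+`.
#'
#' @param design [assay_design()].
#' @param f termination fraction in [0, 1].
#' @param config [sim_config()] (for rho, sigma, droplet geometry, pool size).
#' @param cleaved logical.
#' @return named vector of expected concentrations, copies/ul.
#' @export
expected_measurement <- function(design, f, config, cleaved) {
  n <- config$total_copies
  L <- design$full_length; s <- design$ptt_site; cpos <- design$cleavage_site
  e <- if (cleaved) config$cleavage_efficiency_e else 0
  species <- data.frame(
    species = c("full_length", "fragment_5p", "fragment_3p", "terminated"),
    start = c(1, 1, cpos + 1, 1),
    end = c(L, cpos, L, s),
    count = c((1 - f) * n * (1 - e), (1 - f) * n * e, (1 - f) * n * e, f * n),
    stringsAsFactors = FALSE
  )
  amps <- list(P1 = design$amplicon_P1, P2 = design$amplicon_P2,
               P3 = design$amplicon_P3)
  copies <- vapply(amps, function(a) {
    expected_amplicon_copies(species, a, config$priming_rate_rho,
                             config$extension_survival_sigma)
  }, numeric(1))
  copies / (config$n_droplets * config$droplet_volume_nl * 1e-3)
}

#' Analytic induction ratios implied by the generative model
#'
#' @param design [assay_design()].
#' @param f_met_minus,f_met_plus termination fractions of the two conditions.
#' @param config [sim_config()].
#' @param cleaved logical; include the residual-intact-molecule effect of
#'   incomplete cleavage (`e` from the config) or model the uncleaved arm.
#' @return list with `IR`, `IR_star`, and `IR_ideal` (the fraction-only
#'   idealisation `((1-f)/f)- / ((1-f)/f)+`).
#' @export
analytic_induction_ratio <- function(design, f_met_minus, f_met_plus, config,
                                     cleaved = TRUE) {
  em <- function(f) {
    v <- expected_measurement(design, f, config, cleaved)
    ptt_estimate(list(P1 = v[["P1"]], P3 = v[["P3"]]))
  }
  mm <- em(f_met_minus); mp <- em(f_met_plus)
  list(
    IR = induction_ratio(mm, mp),
    IR_star = induction_ratio_star(mm, mp),
    IR_ideal = ((1 - f_met_minus) / f_met_minus) / ((1 - f_met_plus) / f_met_plus)
  )
}

#' Simulate a complete experiment
#'
#' Runs the whole panel — every gene in `designs` x both conditions x every
#' time point of the induction profile x with/without cleavage — on shared
#' per-condition molecule pools, and returns the tables the analysis
#' pipeline consumes plus the ground truth for recovery tests.
#'
#' @param config [sim_config()].
#' @param designs named list of [assay_design()]s (default [demo_design()]).
#' @return list: `droplets` (`ddpcr_counts`, one row per well), `samples`
#'   (sample sheet: `sample_id`, `gene`, `condition`, `timepoint_h`,
#'   `cleaved`), `truth` (per-sample expected/realized copies and the
#'   generating termination fractions).
#' @export
simulate_experiment <- function(config, designs = demo_design()) {
  prof <- unique(config$induction_profile[, c("gene", "timepoint_h")])
  droplets <- list(); samples <- list(); truth <- list()
  for (i in seq_len(nrow(prof))) {
    g <- prof$gene[i]; tp <- prof$timepoint_h[i]
    if (!g %in% names(designs)) next
    design <- designs[[g]]
    for (cond in c("Met_minus", "Met_plus")) {
      pool <- simulate_pool(config, design, cond, tp)
      for (cl in c(TRUE, FALSE)) {
        wells <- simulate_measurement(pool, design, config, cleaved = cl)
        sid <- wells$sample_id[1]
        droplets[[sid]] <- wells
        samples[[sid]] <- data.frame(
          sample_id = sid, gene = g, condition = cond, timepoint_h = tp,
          cleaved = cl, stringsAsFactors = FALSE
        )
        truth[[sid]] <- attr(wells, "truth")
      }
    }
  }
  droplets <- do.call(rbind, droplets)
  rownames(droplets) <- NULL
  class(droplets) <- c("ddpcr_counts", "data.frame")
  list(
    droplets = droplets,
    samples = do.call(rbind, c(samples, list(make.row.names = FALSE))),
    truth = truth
  )
}

#' Simulate qPCR Ct values from known concentrations
#'
#' One template doubling per cycle: `Ct = a - log2(concentration) + noise`,
#' with Gaussian per-reaction noise and technical replicates, emulating the
#' comparison arm in which the same samples are measured by RT-qPCR.
#'
#' @param conc data.frame with columns `sample_id`, `primer_pair`,
#'   `concentration` (any common positive scale).
#' @param intercept_a Ct of a 1-unit concentration (machine/chemistry
#'   constant; cancels in every ddCt).
#' @param sigma_ct per-reaction Gaussian noise, cycles (default 0.1).
#' @param replicates technical replicates per reaction (default 3, the usual
#'   qPCR triplicate).
#' @param seed integer seed.
#' @return data.frame of Ct records (`sample_id`, `primer_pair`, `replicate`,
#'   `ct`).
#' @export
simulate_qpcr_ct <- function(conc, intercept_a = 30, sigma_ct = 0.1,
                             replicates = 3, seed = 1) {
  if (any(conc$concentration <= 0)) stop_config("concentrations must be > 0")
  n <- nrow(conc)
  ct0 <- intercept_a - log2(conc$concentration)
  out <- do.call(rbind, lapply(seq_len(replicates), function(r) {
    data.frame(
      sample_id = conc$sample_id,
      primer_pair = conc$primer_pair,
      replicate = r,
      ct = ct0,
      stringsAsFactors = FALSE
    )
  }))
  out$ct <- out$ct + with_seed(derive_seed(seed, "qpcr"),
                               stats::rnorm(nrow(out), 0, sigma_ct))
  out
}
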