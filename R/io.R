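# CSV readers/writers and the end-to-end analysis driver.
#
# All files are plain UTF-8 comma-separated CSV with dot decimals and a
# header row. Schemas:
#   droplet CSV : sample_id, assay_id, positives, total
#                 [, dilution_factor, droplet_volume_nl]
#   sample sheet: sample_id, gene, condition, timepoint_h, cleaved
#                 [, assay_P1, assay_P2, assay_P3]
#   Ct CSV      : sample_id, primer_pair, gene, condition, timepoint_h, ct
#                 [, replicate]
# A thin adapter also accepts a QuantaSoft-like export layout
# (Well, Sample, TargetType/Target, Positives, AcceptedDroplets).

#' Read a droplet-count CSV
#'
#' @param path CSV path.
#' @param default_droplet_volume_nl used when the file has no
#'   `droplet_volume_nl` column.
#' @return a `ddpcr_counts` data.frame.
#' @export
read_droplet_csv <- function(path, default_droplet_volume_nl = 0.85) {
  if (!file.exists(path)) stop_data("droplet file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop_data("no wells in droplet file '", path, "'")
  # QuantaSoft-like export adapter
  qs <- c(Well = "well", Sample = "sample_id", Target = "assay_id",
          Positives = "positives", AcceptedDroplets = "total")
  for (nm in names(qs)) {
    if (nm %in% names(df) && !(qs[[nm]] %in% names(df))) names(df)[names(df) == nm] <- qs[[nm]]
  }
  if (!"dilution_factor" %in% names(df)) df$dilution_factor <- 1
  if (!"droplet_volume_nl" %in% names(df)) df$droplet_volume_nl <- default_droplet_volume_nl
  validate_droplet_counts(df, file = path)
  keep <- c("sample_id", "assay_id", "positives", "total",
            "dilution_factor", "droplet_volume_nl")
  df <- df[, keep]
  class(df) <- c("ddpcr_counts", "data.frame")
  df
}

#' Write / read concentration estimates
#'
#' @param estimates `ddpcr_estimates` data.frame from
#'   [poisson_concentration()].
#' @param path CSV path.
#' @return `path` (write) or the data.frame (read).
#' @export
write_concentration_csv <- function(estimates, path) {
  utils::write.csv(estimates, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_concentration_csv
#' @export
read_concentration_csv <- function(path) {
  if (!file.exists(path)) stop_data("concentration file not found: ", path)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Read a sample sheet
#'
#' Maps each `sample_id` to its gene, condition, time point and cleavage
#' status, and (optionally) to the three assay ids; without explicit
#' `assay_P1`/`assay_P2`/`assay_P3` columns the convention
#' `<gene>_P1` / `<gene>_P2` / `<gene>_P3` is assumed.
#'
#' @param path CSV path.
#' @return data.frame.
#' @export
read_sample_sheet <- function(path) {
  if (!file.exists(path)) stop_data("sample sheet not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "gene", "condition", "timepoint_h", "cleaved")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop_data("sample sheet '", path, "' missing column(s): ",
              paste(miss, collapse = ", "))
  }
  bad <- which(!df$condition %in% c("Met_minus", "Met_plus"))
  if (length(bad)) {
    stop_data("sample sheet '", path, "': unknown condition at row(s) ",
              paste(utils::head(bad, 5), collapse = ", "))
  }
  df$cleaved <- as.logical(df$cleaved)
  for (p in c("P1", "P2", "P3")) {
    col <- paste0("assay_", p)
    if (!col %in% names(df)) df[[col]] <- paste(df$gene, p, sep = "_")
  }
  df
}

#' Read a Ct CSV for the qPCR arm
#'
#' @param path CSV path.
#' @param ct_range plausible Ct band.
#' @return data.frame of Ct records.
#' @export
read_ct_csv <- function(path, ct_range = c(5, 40)) {
  if (!file.exists(path)) stop_data("Ct file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "primer_pair", "ct")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop_data("Ct file '", path, "' missing column(s): ", paste(miss, collapse = ", "))
  }
  bad <- which(!is.finite(df$ct) | df$ct < ct_range[1] | df$ct > ct_range[2])
  if (length(bad)) {
    stop_data("Ct file '", path, "': Ct outside [", ct_range[1], ", ",
              ct_range[2], "] at row(s) ", paste(utils::head(bad, 5), collapse = ", "))
  }
  df
}

#' Quantify every sample x assay of a droplet table
#'
#' Pools replicate wells per sample x assay ([merge_replicates()]) and runs
#' the Poisson quantification once per group.
#'
#' @param droplets `ddpcr_counts` rows.
#' @param confidence_level CI level.
#' @return `ddpcr_estimates` data.frame, one row per sample x assay.
#' @export
quantify_wells <- function(droplets, confidence_level = 0.95) {
  validate_droplet_counts(droplets)
  key <- paste(droplets$sample_id, droplets$assay_id, sep = "\r")
  parts <- split(seq_len(nrow(droplets)), key)
  out <- do.call(rbind, lapply(parts, function(ix) {
    merge_replicates(droplets[ix, , drop = FALSE], confidence_level)
  }))
  rownames(out) <- NULL
  out
}

#' Run the complete PTT analysis
#'
#' From raw droplet counts and a sample sheet to per-sample PTT estimates,
#' per gene x time point induction ratios for each cleavage arm, per-sample
#' cleavage efficiencies, and the with/without-cleavage comparison summary.
#'
#' @param droplets `ddpcr_counts` (e.g. from [read_droplet_csv()] or
#'   [simulate_experiment()]).
#' @param samples sample sheet data.frame (see [read_sample_sheet()]).
#' @param control_genes genes excluded from the cleavage-effect summary.
#' @param confidence_level CI level for quantification.
#' @return list: `concentrations`, `ptt` (tidy per-sample estimates),
#'   `induction` (gene x timepoint x arm IR and IR*), `cleavage_efficiency`
#'   (per gene x condition x timepoint), `comparison` (with/without-cleavage
#'   percent differences) and `summary` (mean/max effect) when both arms are
#'   present.
#' @export
ptt_pipeline <- function(droplets, samples, control_genes = "gyrA",
                         confidence_level = 0.95) {
  conc <- quantify_wells(droplets, confidence_level)
  if (!"assay_P1" %in% names(samples)) {
    for (p in c("P1", "P2", "P3")) {
      samples[[paste0("assay_", p)]] <- paste(samples$gene, p, sep = "_")
    }
  }
  lookup <- function(sid, aid) {
    hit <- conc$sample_id == sid & conc$assay_id == aid
    if (!any(hit)) return(NA_real_)
    conc$copies_per_ul[hit][1]
  }
  ptt_rows <- lapply(seq_len(nrow(samples)), function(i) {
    s <- samples[i, ]
    P1 <- lookup(s$sample_id, s$assay_P1)
    P2 <- lookup(s$sample_id, s$assay_P2)
    P3 <- lookup(s$sample_id, s$assay_P3)
    if (!is.finite(P1) || !is.finite(P3)) {
      stop_data("missing P1/P3 quantification for gene ", s$gene, " at ",
                s$timepoint_h, " h (sample ", s$sample_id, ")")
    }
    est <- ptt_estimate(list(gene = s$gene, condition = s$condition,
                             timepoint_h = s$timepoint_h, cleaved = s$cleaved,
                             P1 = P1, P3 = P3))
    data.frame(
      sample_id = s$sample_id, gene = s$gene, condition = s$condition,
      timepoint_h = s$timepoint_h, cleaved = s$cleaved,
      P1 = P1, P2 = P2, P3 = P3, FL = est$FL, T = est$T,
      termination_fraction = est$termination_fraction,
      negative_T_flag = est$negative_T_flag,
      stringsAsFactors = FALSE
    )
  })
  ptt <- do.call(rbind, ptt_rows)

  # induction ratios: pair Met- against Met+ within gene x timepoint x arm
  combos <- unique(ptt[, c("gene", "timepoint_h", "cleaved")])
  ind <- do.call(rbind, lapply(seq_len(nrow(combos)), function(i) {
    cb <- combos[i, ]
    sel <- ptt$gene == cb$gene & ptt$timepoint_h == cb$timepoint_h &
      ptt$cleaved == cb$cleaved
    mm <- ptt[sel & ptt$condition == "Met_minus", ]
    mp <- ptt[sel & ptt$condition == "Met_plus", ]
    if (nrow(mm) != 1L || nrow(mp) != 1L) {
      stop_data("need exactly one Met_minus and one Met_plus sample for gene ",
                cb$gene, " at ", cb$timepoint_h, " h (",
                if (cb$cleaved) "cleaved" else "uncleaved", " arm)")
    }
    as_est <- function(r) ptt_estimate(list(gene = r$gene, P1 = r$P1, P3 = r$P3))
    data.frame(
      gene = cb$gene, timepoint_h = cb$timepoint_h, cleaved = cb$cleaved,
      IR = induction_ratio(as_est(mm), as_est(mp)),
      IR_star = induction_ratio_star(as_est(mm), as_est(mp)),
      stringsAsFactors = FALSE
    )
  }))

  # cleavage efficiency from P2, cut vs uncut arms of the same sample
  ceff <- NULL
  combos2 <- unique(ptt[, c("gene", "condition", "timepoint_h")])
  for (i in seq_len(nrow(combos2))) {
    cb <- combos2[i, ]
    sel <- ptt$gene == cb$gene & ptt$condition == cb$condition &
      ptt$timepoint_h == cb$timepoint_h
    w <- ptt[sel & ptt$cleaved, ]
    wo <- ptt[sel & !ptt$cleaved, ]
    if (nrow(w) == 1L && nrow(wo) == 1L &&
        is.finite(w$P2) && is.finite(wo$P2) && wo$P2 > 0) {
      ceff <- rbind(ceff, data.frame(
        gene = cb$gene, condition = cb$condition, timepoint_h = cb$timepoint_h,
        efficiency = as.numeric(cleavage_efficiency(w$P2, wo$P2)),
        stringsAsFactors = FALSE
      ))
    }
  }

  out <- list(concentrations = conc, ptt = ptt, induction = ind,
              cleavage_efficiency = ceff)

  # with/without-cleavage comparison where both arms exist
  wide_key <- unique(ind[, c("gene", "timepoint_h")])
  pairs <- do.call(rbind, lapply(seq_len(nrow(wide_key)), function(i) {
    k <- wide_key[i, ]
    a <- ind$IR[ind$gene == k$gene & ind$timepoint_h == k$timepoint_h & !ind$cleaved]
    b <- ind$IR[ind$gene == k$gene & ind$timepoint_h == k$timepoint_h & ind$cleaved]
    if (length(a) == 1L && length(b) == 1L) {
      data.frame(gene = k$gene, timepoint_h = k$timepoint_h,
                 ir_no_cleavage = a, ir_cleavage = b, stringsAsFactors = FALSE)
    }
  }))
  if (!is.null(pairs) && nrow(pairs) > 0 &&
      any(!pairs$gene %in% control_genes)) {
    eff <- summarize_cleavage_effect(pairs, control_genes)
    out$comparison <- eff$table
    out$summary <- data.frame(
      mean_percent = eff$mean_percent, max_percent = eff$max_percent,
      mean_percent_rounded = eff$mean_percent_rounded,
      max_percent_rounded = eff$max_percent_rounded
    )
  }
  out
}

#' IR* per gene and time point from a Ct table
#'
#' Averages replicate Cts, then for each gene x time point computes
#' `IR* = (RQ_P3 / RQ_P1)_Met- / (RQ_P3 / RQ_P1)_Met+` with each RQ taken
#' relative to the Met_plus sample of the same primer pair (so the
#' calibrator cancels; no reference gene is needed for a within-gene ratio
#' of ratios).
#'
#' @param ct_df Ct records: `sample_id`, `primer_pair` (`P1` or `P3`),
#'   `gene`, `condition`, `timepoint_h`, `ct`.
#' @return data.frame `gene`, `timepoint_h`, `IR_star`.
#' @export
qpcr_pipeline <- function(ct_df) {
  need <- c("gene", "condition", "timepoint_h", "primer_pair", "ct")
  miss <- setdiff(need, names(ct_df))
  if (length(miss)) stop_data("Ct table missing column(s): ", paste(miss, collapse = ", "))
  ct_df$sample_id <- ct_df$sample_id %||%
    paste(ct_df$gene, ct_df$condition, ct_df$timepoint_h, sep = "_")
  avg <- stats::aggregate(ct ~ gene + condition + timepoint_h + primer_pair,
                          data = ct_df, FUN = mean)
  key <- unique(avg[, c("gene", "timepoint_h")])
  do.call(rbind, lapply(seq_len(nrow(key)), function(i) {
    k <- key[i, ]
    pick <- function(cond, p) {
      v <- avg$ct[avg$gene == k$gene & avg$timepoint_h == k$timepoint_h &
                    avg$condition == cond & avg$primer_pair == p]
      if (length(v) != 1L) {
        stop_data("need one mean Ct for ", k$gene, " ", cond, " ", p,
                  " at ", k$timepoint_h, " h; found ", length(v))
      }
      v
    }
    rq_p3_minus <- relative_quantity(pick("Met_minus", "P3"), pick("Met_plus", "P3"))
    rq_p1_minus <- relative_quantity(pick("Met_minus", "P1"), pick("Met_plus", "P1"))
    data.frame(
      gene = k$gene, timepoint_h = k$timepoint_h,
      IR_star = ir_star_from_rq(rq_p3_minus, 1, rq_p1_minus, 1),
      stringsAsFactors = FALSE
    )
  }))
}

#' Write the tables produced by a simulated experiment
#'
#' Emits the droplet CSV, the sample sheet, and a ground-truth JSON log in
#' exactly the formats the pipeline consumes.
#'
#' @param sim result of [simulate_experiment()].
#' @param dir output directory (created if missing).
#' @return named character vector of the written paths.
#' @export
write_experiment <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    droplets = file.path(dir, "droplets.csv"),
    samples = file.path(dir, "samples.csv"),
    truth = file.path(dir, "truth.json")
  )
  utils::write.csv(sim$droplets, paths[["droplets"]], row.names = FALSE, quote = FALSE)
  utils::write.csv(sim$samples, paths[["samples"]], row.names = FALSE, quote = FALSE)
  jsonlite::write_json(sim$truth, paths[["truth"]], auto_unbox = TRUE, digits = NA)
  paths
}
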