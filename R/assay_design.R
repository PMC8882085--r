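# Per-gene amplicon geometry for the three-amplicon PTT assay.
#
# Layout along the transcript (1-based, counted from the 5' end):
#
#   5'---[P1]---ptt_site---cleavage_site---[P3]--------------3'  (length L)
#              ^ terminated transcripts end here
#                       ^ RNase H cuts here, directed by a DNA oligomer
#
# P1 sits upstream of the premature-termination site, so it amplifies both
# full-length and terminated transcripts. P2 flanks the cleavage site and
# reports cleavage efficiency. P3 sits downstream of the cut, so after
# cleavage it amplifies full-length transcripts only. P1 and P3 are placed at
# the same distance (~200 nt) from the 3' ends of, respectively, the 5'
# cleavage fragment and the full-length transcript, which equalises the
# random-hexamer cDNA coverage of the two amplicons and removes the
# 3'-distance bias from the FL/T comparison.

#' Define a three-amplicon PTT assay for one gene
#'
#' @param gene gene/operon name.
#' @param amplicon_P1,amplicon_P2,amplicon_P3 length-2 integer vectors
#'   `c(start, end)`, 1-based inclusive transcript coordinates from the 5' end.
#' @param ptt_site coordinate of the premature termination point (the 3' end
#'   of terminated transcripts).
#' @param cleavage_site coordinate of the oligomer-directed RNase H cut,
#'   downstream of `ptt_site`.
#' @param full_length transcript length L in nt.
#' @param target_3prime_distance design distance of P1/P3 from their
#'   respective 3' ends, nt (default 200).
#' @param distance_tolerance_nt allowed mismatch between the two 3'-distances
#'   (default 25 nt).
#' @return an `assay_design` list.
#' @export
#' @examples
#' assay_design("metE", c(40, 111), c(290, 330), c(1230, 1301),
#'   ptt_site = 300, cleavage_site = 310, full_length = 1500)
assay_design <- function(gene, amplicon_P1, amplicon_P2, amplicon_P3,
                         ptt_site, cleavage_site, full_length,
                         target_3prime_distance = 200,
                         distance_tolerance_nt = 25) {
  amp_ok <- function(a) is.numeric(a) && length(a) == 2L && all(is.finite(a)) &&
    a[1] >= 1 && a[1] <= a[2]
  if (!amp_ok(amplicon_P1) || !amp_ok(amplicon_P2) || !amp_ok(amplicon_P3)) {
    stop_config("amplicons must be c(start, end) with 1 <= start <= end")
  }
  if (!(ptt_site < cleavage_site && cleavage_site < full_length)) {
    stop_config("require ptt_site < cleavage_site < full_length (gene ", gene, ")")
  }
  if (amplicon_P1[2] >= ptt_site) {
    stop_config("amplicon_P1 must lie entirely 5' of ptt_site (gene ", gene, ")")
  }
  if (!(amplicon_P2[1] <= cleavage_site && cleavage_site <= amplicon_P2[2])) {
    stop_config("amplicon_P2 must span cleavage_site (gene ", gene, ")")
  }
  if (amplicon_P3[1] <= cleavage_site) {
    stop_config("amplicon_P3 must lie entirely 3' of cleavage_site (gene ", gene, ")")
  }
  if (amplicon_P3[2] > full_length) {
    stop_config("amplicon_P3 extends beyond the transcript (gene ", gene, ")")
  }
  d1 <- three_prime_distance(amplicon_P1, cleavage_site)   # on the 5' fragment
  d3 <- three_prime_distance(amplicon_P3, full_length)     # on the full-length
  if (abs(d1 - d3) > distance_tolerance_nt) {
    stop_config("P1/P3 3'-distances differ by ", abs(d1 - d3), " nt (> ",
                distance_tolerance_nt, " nt tolerance) for gene ", gene,
                "; the equal-distance design is what removes the RT bias")
  }
  structure(list(
    gene = as.character(gene),
    amplicon_P1 = as.numeric(amplicon_P1),
    amplicon_P2 = as.numeric(amplicon_P2),
    amplicon_P3 = as.numeric(amplicon_P3),
    ptt_site = as.numeric(ptt_site),
    cleavage_site = as.numeric(cleavage_site),
    full_length = as.numeric(full_length),
    target_3prime_distance = as.numeric(target_3prime_distance),
    distance_tolerance_nt = as.numeric(distance_tolerance_nt)
  ), class = "assay_design")
}

#' 3'-distance of an amplicon on a molecule
#'
#' For an amplicon spanning `[a, b]` (5'-based) on a molecule of length `len`,
#' the distance from the molecule's 3' end is `len - b + 1`. This is the
#' quantity cDNA coverage is proportional to under fully processive
#' reverse transcription.
#'
#' @param amplicon `c(start, end)`.
#' @param len molecule length, nt.
#' @return distance in nt, or `NA` if the amplicon is not contained in the
#'   molecule.
#' @export
three_prime_distance <- function(amplicon, len) {
  if (amplicon[2] > len) return(NA_real_)
  len - amplicon[2] + 1
}

#' @export
print.assay_design <- function(x, ...) {
  cat("PTT assay design for", x$gene, "\n")
  cat(sprintf("  transcript length L = %d nt; PTT site %d; cleavage site %d\n",
              as.integer(x$full_length), as.integer(x$ptt_site), as.integer(x$cleavage_site)))
  cat(sprintf("  P1 [%d, %d]  (3'-distance on 5' fragment: %d nt)\n",
              as.integer(x$amplicon_P1[1]), as.integer(x$amplicon_P1[2]),
              as.integer(three_prime_distance(x$amplicon_P1, x$cleavage_site))))
  cat(sprintf("  P2 [%d, %d]  (spans the cleavage site)\n",
              as.integer(x$amplicon_P2[1]), as.integer(x$amplicon_P2[2])))
  cat(sprintf("  P3 [%d, %d]  (3'-distance on full-length: %d nt)\n",
              as.integer(x$amplicon_P3[1]), as.integer(x$amplicon_P3[2]),
              as.integer(three_prime_distance(x$amplicon_P3, x$full_length))))
  invisible(x)
}

#' Read assay designs from a JSON config
#'
#' The config is a JSON array of objects with the exact field names of
#' [assay_design()] (amplicons as two-element arrays). See
#' `system.file("extdata", "demo_design.json", package = "pttquant")`.
#'
#' @param path JSON file path.
#' @return named list of `assay_design` objects, one per gene.
#' @export
read_assay_design <- function(path) {
  if (!file.exists(path)) stop_config("design file not found: ", path)
  raw <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  designs <- lapply(raw, function(g) {
    assay_design(
      gene = g$gene,
      amplicon_P1 = unlist(g$amplicon_P1),
      amplicon_P2 = unlist(g$amplicon_P2),
      amplicon_P3 = unlist(g$amplicon_P3),
      ptt_site = g$ptt_site,
      cleavage_site = g$cleavage_site,
      full_length = g$full_length,
      target_3prime_distance = g$target_3prime_distance %||% 200,
      distance_tolerance_nt = g$distance_tolerance_nt %||% 25
    )
  })
  names(designs) <- vapply(designs, `[[`, "", "gene")
  designs
}

#' Write assay designs to a JSON config
#'
#' @param designs a single `assay_design` or a list of them.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_assay_design <- function(designs, path) {
  if (inherits(designs, "assay_design")) designs <- list(designs)
  jsonlite::write_json(lapply(designs, unclass), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
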