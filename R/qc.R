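#' Genome quality score
#'
#' Computes the quality score (QS) of a genome bin from external
#' completeness/contamination estimates, defined as
#' `completeness - 5 * contamination`. Both inputs are percentages; the
#' score may be negative for heavily contaminated bins.
#'
#' @param completeness Estimated completeness, percent in \[0, 100\].
#' @param contamination Estimated contamination, percent in \[0, 100\].
#' @return Numeric quality score (vectorised over its inputs).
#' @examples
#' quality_score(90, 5)   # 65
#' quality_score(50, 10)  # 0
#' @export
quality_score <- function(completeness, contamination) {
  if (!is.numeric(completeness) || !is.numeric(contamination))
    stop("completeness and contamination must be numeric", call. = FALSE)
  if (any(is.na(completeness)) || any(is.na(contamination)) ||
      any(completeness < 0 | completeness > 100) ||
      any(contamination < 0 | contamination > 100))
    stop("completeness and contamination must lie in [0, 100]", call. = FALSE)
  completeness - 5 * contamination
}

#' Quality tier of a genome bin
#'
#' Assigns the MIMAG-derived quality tier: `near_complete` for bins with
#' completeness > 90% and contamination < 5%; otherwise `medium_quality`
#' for completeness >= 50% and contamination < 10%; otherwise `fail`.
#' Also reports whether the quality score exceeds 50 (`qs50`), the gate
#' used for dereplicating medium-quality bins.
#'
#' Boundary semantics are intentionally literal: the near-complete tier is
#' strict (`>90`, `<5`), the medium tier mixes an inclusive completeness
#' bound (`>=50`) with a strict contamination bound (`<10`), and the QS
#' flag is strict (`>50`).
#'
#' @param completeness,contamination Percent in \[0, 100\] (vectorised).
#' @return A data.frame with columns `tier` (factor-like character:
#'   `near_complete`, `medium_quality` or `fail`), `qs` and `qs50`.
#' @examples
#' classify_tier(95, 2)
#' classify_tier(50, 9.9)  # medium_quality, qs50 FALSE
#' @export
classify_tier <- function(completeness, contamination) {
  qs <- quality_score(completeness, contamination)
  tier <- ifelse(completeness > 90 & contamination < 5, "near_complete",
          ifelse(completeness >= 50 & contamination < 10, "medium_quality",
                 "fail"))
  data.frame(tier = tier, qs = qs, qs50 = qs > 50,
             stringsAsFactors = FALSE)
}

# Union length of half-open integer intervals [start, end)
interval_union_length <- function(start, end) {
  if (length(start) == 0L) return(0)
  if (any(start < 0) || any(end < 0))
    stop("negative coordinates in hit intervals", call. = FALSE)
  if (any(end <= start)) stop("hit with end <= start", call. = FALSE)
  o <- order(start, end)
  start <- start[o]; end <- end[o]
  total <- 0; lo <- start[1]; hi <- end[1]
  for (i in seq_along(start)[-1]) {
    if (start[i] > hi) { total <- total + (hi - lo); lo <- start[i]; hi <- end[i] }
    else hi <- max(hi, end[i])
  }
  total + (hi - lo)
}

#' rRNA gene presence from alignment hits
#'
#' A ribosomal RNA gene (5S, 16S or 23S) is called present when the total
#' non-overlapping alignment length of its hits exceeds 80% of the expected
#' model length (strictly more than 80%). Hit coordinates are 0-based,
#' half-open; overlapping hits are merged before summing.
#'
#' @param hits data.frame with columns `start`, `end` (bp, 0-based
#'   half-open) for one gene in one genome; may have zero rows.
#' @param expected_length Expected full-length gene size in bp (taken from
#'   the covariance model used for detection; supplied by the caller, not
#'   asserted by this package).
#' @param min_fraction Fraction of the expected length that must be
#'   covered; default 0.8.
#' @return Logical: is the gene present?
#' @examples
#' rna_presence(data.frame(start = c(0, 50), end = c(100, 150)), 150)
#' @export
rna_presence <- function(hits, expected_length, min_fraction = 0.8) {
  stopifnot_scalar(expected_length, "expected_length", lo = 1)
  if (is.null(hits) || nrow(hits) == 0L) return(FALSE)
  len <- interval_union_length(hits$start, hits$end)
  len > min_fraction * expected_length
}

#' MIMAG high-quality flag
#'
#' A bin qualifies as MIMAG high-quality when it is near-complete
#' (completeness > 90%, contamination < 5%), carries all three rRNA genes
#' (5S, 16S, 23S, each covering more than 80% of its expected length) and
#' encodes at least 18 tRNAs.
#'
#' @param tier Quality tier as returned by [classify_tier()].
#' @param rna_flags Named logical vector with entries `"5S"`, `"16S"`,
#'   `"23S"` (from [rna_presence()]).
#' @param trna_count Number of distinct tRNAs detected.
#' @return Logical.
#' @export
mimag_high_quality <- function(tier, rna_flags, trna_count) {
  needed <- c("5S", "16S", "23S")
  if (!all(needed %in% names(rna_flags)))
    stop("rna_flags must be named with 5S, 16S and 23S", call. = FALSE)
  identical(tier, "near_complete") &&
    all(rna_flags[needed]) &&
    trna_count >= 18
}

#' Score and tier a table of genome bins
#'
#' Convenience wrapper applying [quality_score()] and [classify_tier()] to a
#' QC table, optionally adding the MIMAG high-quality flag when rRNA hits
#' and tRNA counts are supplied.
#'
#' @param qc data.frame with columns `genome_id`, `completeness`,
#'   `contamination` (and optionally `genome_length`, `n_contigs`).
#' @param rna_hits Optional data.frame with columns `genome_id`, `gene`
#'   (5S/16S/23S), `start`, `end`, `expected_length`.
#' @param trna_counts Optional data.frame with `genome_id`, `trna_count`.
#' @return The input with `qs`, `tier`, `qs50` and (when annotation is
#'   supplied) `mimag_high_quality` columns appended.
#' @export
score_mags <- function(qc, rna_hits = NULL, trna_counts = NULL) {
  stopifnot(all(c("genome_id", "completeness", "contamination") %in% names(qc)))
  res <- cbind(qc, classify_tier(qc$completeness, qc$contamination))
  if (!is.null(rna_hits) && !is.null(trna_counts)) {
    flags <- vapply(seq_len(nrow(res)), function(i) {
      gid <- res$genome_id[i]
      rf <- vapply(c("5S", "16S", "23S"), function(g) {
        h <- rna_hits[rna_hits$genome_id == gid & rna_hits$gene == g, ,
                      drop = FALSE]
        if (nrow(h) == 0L) return(FALSE)
        rna_presence(h, expected_length = h$expected_length[1])
      }, logical(1))
      tc <- trna_counts$trna_count[match(gid, trna_counts$genome_id)]
      if (is.na(tc)) tc <- 0L
      mimag_high_quality(res$tier[i], rf, tc)
    }, logical(1))
    res$mimag_high_quality <- flags
  }
  res
}
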