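#' Depth and variation penalty scores
#'
#' Presence penalties combine missing genome coverage with read-depth
#' statistics: `depth_penalty = (100 - coverage) * log(mean_depth)` and
#' `variation_penalty = (100 - coverage) * cv`, where `cv =
#' sd_depth / mean_depth` (0 when the mean depth is 0). A genome with
#' high mean depth (or uneven depth) over a small covered fraction scores
#' high penalties and is unlikely to be genuinely present. The natural
#' logarithm is used, and the mean depth is clamped to >= 1 before the
#' log so sub-1x depths cannot produce negative penalties.
#'
#' @param coverage Percent of genome positions covered, in \[0, 100\]
#'   (vectorised).
#' @param mean_depth,sd_depth Read depth mean and standard deviation
#'   (reads per position), >= 0.
#' @return data.frame with columns `depth_penalty`, `variation_penalty`.
#' @examples
#' penalty_scores(80, 10, 5)  # (20 * log(10), 20 * 0.5)
#' @export
penalty_scores <- function(coverage, mean_depth, sd_depth) {
  if (any(coverage < 0 | coverage > 100, na.rm = TRUE))
    stop("coverage must be in [0, 100]", call. = FALSE)
  if (any(mean_depth < 0 | sd_depth < 0, na.rm = TRUE))
    stop("depth statistics must be non-negative", call. = FALSE)
  cv <- ifelse(mean_depth == 0, 0, sd_depth / mean_depth)
  missing_cov <- 100 - coverage
  data.frame(depth_penalty = missing_cov * log(pmax(mean_depth, 1)),
             variation_penalty = missing_cov * cv)
}

#' Call genome presence per sample
#'
#' A genome is called present in a sample when its coverage reaches
#' `min_coverage`% and both penalty scores fall at or below the stated
#' percentile of their distributions (taken over all genome-sample rows
#' of the current run with coverage > 0, type-7 linear interpolation).
#' Fixed numeric thresholds may be supplied instead for cross-run
#' stability.
#'
#' @param table data.frame with columns `genome_id`, `sample_id`,
#'   `coverage`, `mean_depth`, `sd_depth` and (optionally)
#'   `unique_proper_pairs`, `total_reads` for relative abundance.
#' @param min_coverage Minimum coverage percent, default 60.
#' @param percentile Penalty percentile used for thresholding, default
#'   99.
#' @param thresholds Optional list with fixed `depth` and `variation`
#'   penalty cutoffs, bypassing the percentile computation.
#' @return The input with `depth_penalty`, `variation_penalty`,
#'   `present` and (when read counts are available) `rel_abundance`
#'   columns appended; penalty thresholds attached as attribute
#'   `"thresholds"`.
#' @export
call_presence <- function(table, min_coverage = 60, percentile = 99,
                          thresholds = NULL) {
  if (is.null(table) || nrow(table) == 0L) return(table)
  pen <- penalty_scores(table$coverage, table$mean_depth, table$sd_depth)
  if (is.null(thresholds)) {
    pop <- table$coverage > 0
    thresholds <- list(
      depth = quantile(pen$depth_penalty[pop], percentile / 100,
                       type = 7, names = FALSE),
      variation = quantile(pen$variation_penalty[pop], percentile / 100,
                           type = 7, names = FALSE))
  }
  out <- cbind(table, pen)
  out$present <- out$coverage >= min_coverage &
    pen$depth_penalty <= thresholds$depth &
    pen$variation_penalty <= thresholds$variation
  if (all(c("unique_proper_pairs", "total_reads") %in% names(out)))
    out$rel_abundance <- relative_abundance(out$unique_proper_pairs,
                                            out$total_reads)
  attr(out, "thresholds") <- thresholds
  out
}

#' Relative abundance from read counts
#'
#' The relative abundance of a genome in a sample is the proportion of
#' uniquely mapped, correctly paired reads assigned to it out of the
#' sample's total read count.
#'
#' @param unique_proper_pairs,total_reads Read counts (vectorised).
#' @return Fraction in \[0, 1\].
#' @export
relative_abundance <- function(unique_proper_pairs, total_reads) {
  if (any(total_reads <= 0))
    stop("total_reads must be positive", call. = FALSE)
  if (any(unique_proper_pairs < 0 | unique_proper_pairs > total_reads))
    stop("unique_proper_pairs must lie in [0, total_reads]", call. = FALSE)
  unique_proper_pairs / total_reads
}

CONTINENTS <- c("Africa", "Asia", "Europe", "North America",
                "South America", "Oceania")

#' Per-genome geographic prevalence summary
#'
#' Summarises presence calls by geographic region: for each genome and
#' continent, the number of samples where it is present at relative
#' abundance strictly above `min_abund` (default 0.01%), plus three
#' flags per genome:
#' \describe{
#'   \item{common_in_<region>}{detected above `min_abund` in strictly
#'     more than `region_frac` (default 20%) of that region's samples;}
#'   \item{global}{present in at least one sample from every one of the
#'     six continents;}
#'   \item{non_west_only}{present only in samples from outside Europe
#'     and North America.}
#' }
#'
#' @param calls Output of [call_presence()] including `rel_abundance`.
#' @param metadata data.frame with columns `sample_id`, `continent`
#'   (labels must be among the six continents).
#' @param min_abund Abundance detection floor (fraction), default 1e-4.
#' @param region_frac Fraction of a region's samples for the "common"
#'   flag, default 0.2.
#' @return List with `counts` (genome x continent detection counts),
#'   `region_sizes`, and `flags` (data.frame: genome_id,
#'   common_in_<continent>..., global, non_west_only).
#' @export
prevalence_summary <- function(calls, metadata, min_abund = 1e-4,
                               region_frac = 0.2) {
  stopifnot(all(c("sample_id", "continent") %in% names(metadata)))
  unknown <- !metadata$continent %in% CONTINENTS
  if (any(unknown))
    stop("unknown continent label for sample(s): ",
         paste(metadata$sample_id[unknown], collapse = ", "), call. = FALSE)
  missing_meta <- setdiff(unique(calls$sample_id), metadata$sample_id)
  if (length(missing_meta))
    stop("samples without continent label: ",
         paste(missing_meta, collapse = ", "), call. = FALSE)
  calls$continent <- metadata$continent[match(calls$sample_id,
                                              metadata$sample_id)]
  genomes <- sort(unique(calls$genome_id))
  region_sizes <- table(factor(metadata$continent, levels = CONTINENTS))

  det_ab <- calls$present & calls$rel_abundance > min_abund
  counts <- t(vapply(genomes, function(g) {
    sel <- calls$genome_id == g & det_ab
    as.integer(table(factor(calls$continent[sel], levels = CONTINENTS)))
  }, integer(length(CONTINENTS))))
  colnames(counts) <- CONTINENTS

  pres_counts <- t(vapply(genomes, function(g) {
    sel <- calls$genome_id == g & calls$present
    as.integer(table(factor(calls$continent[sel], levels = CONTINENTS)))
  }, integer(length(CONTINENTS))))
  colnames(pres_counts) <- CONTINENTS

  west <- c("Europe", "North America")
  flags <- data.frame(genome_id = genomes, stringsAsFactors = FALSE)
  for (ct in CONTINENTS) {
    nm <- paste0("common_in_", gsub(" ", "_", ct))
    flags[[nm]] <- counts[, ct] > region_frac * as.integer(region_sizes[ct])
  }
  flags$global <- apply(pres_counts > 0, 1, all)
  detected_any <- rowSums(pres_counts) > 0
  flags$non_west_only <- detected_any &
    rowSums(pres_counts[, west, drop = FALSE]) == 0
  list(counts = counts, region_sizes = region_sizes, flags = flags)
}
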