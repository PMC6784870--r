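#' Fragment-based average nucleotide identity
#'
#' Desk-scale ANI estimator: the query is cut into non-overlapping
#' fragments (default 1 kb); each fragment is anchored into the reference
#' by exact k-mer matches (k = 15, forward strand) and scored by ungapped
#' identity at its best candidate offset. Fragments reaching
#' `min_identity` count as aligned. Reported quantities:
#' \describe{
#'   \item{ani}{mean identity of aligned fragments, percent (NA when no
#'     fragment aligns);}
#'   \item{af_query}{aligned fragments / total fragments, percent (the
#'     "aligned query" fraction);}
#'   \item{af_ref}{union of matched reference intervals / reference
#'     length, percent;}
#'   \item{af_larger}{coverage of whichever genome is longer (`af_query`
#'     if the query is at least as long as the reference, else
#'     `af_ref`).}
#' }
#' The aligner is substitution-aware only: genomes differing by indels or
#' inversions need a gapped aligner, which is outside this package's
#' scope.
#'
#' @param query,ref Nucleotide strings.
#' @param query_id,ref_id Identifiers carried into the result.
#' @param fragment_length Fragment size in bp, default 1000. A query
#'   shorter than this is treated as a single fragment.
#' @param min_identity Identity fraction for a fragment to count as
#'   aligned, default 0.8.
#' @param anchor_k Exact-match anchor k-mer length, default 15.
#' @return One-row data.frame of class `pairwise_comparison`: `query_id`,
#'   `ref_id`, `ani`, `af_query`, `af_ref`, `af_larger`, `n_fragments`,
#'   `n_aligned`.
#' @export
fragment_ani <- function(query, ref, query_id = "query", ref_id = "ref",
                         fragment_length = 1000L, min_identity = 0.8,
                         anchor_k = 15L) {
  query <- as.character(query); ref <- as.character(ref)
  if (!nzchar(query) || !nzchar(ref)) stop("empty sequence", call. = FALSE)
  r <- fragment_ani_cpp(query, ref, as.integer(fragment_length),
                        min_identity, as.integer(anchor_k),
                        max_candidates = 64L)
  af_larger <- if (nchar(query) >= nchar(ref)) r$af_query else r$af_ref
  out <- data.frame(query_id = query_id, ref_id = ref_id,
                    ani = r$ani, af_query = r$af_query, af_ref = r$af_ref,
                    af_larger = af_larger,
                    n_fragments = r$n_fragments, n_aligned = r$n_aligned,
                    stringsAsFactors = FALSE)
  class(out) <- c("pairwise_comparison", class(out))
  out
}

#' Assign a genome to its best-matching reference
#'
#' Finds the reference with the lowest Mash distance to the query (ties
#' broken lexicographically by reference id), verifies the candidate with
#' [fragment_ani()], and reports a match only when at least
#' `min_af`% of the query aligns at `min_ani`% or better average
#' nucleotide identity (defaults: 60% aligned, 95% ANI — the species
#' assignment rule).
#'
#' @param query_sketch `genome_sketch` of the query.
#' @param reference_sketches List of reference `genome_sketch` objects.
#' @param sequences Named character vector (or function `id -> sequence`)
#'   providing the query and candidate reference sequences.
#' @param min_ani,min_af Acceptance thresholds, percent.
#' @param ... Passed to [fragment_ani()].
#' @return A list: `matched` (logical), `ref_id` (best candidate),
#'   `mash_d`, and the `comparison` row (NULL when the candidate stage
#'   failed to produce one).
#' @export
assign_to_reference <- function(query_sketch, reference_sketches, sequences,
                                min_ani = 95, min_af = 60, ...) {
  if (length(reference_sketches) == 0L)
    stop("empty reference set", call. = FALSE)
  get_seq <- if (is.function(sequences)) sequences else function(id) {
    if (!id %in% names(sequences))
      stop(sprintf("missing sequence for '%s'", id), call. = FALSE)
    sequences[[id]]
  }
  ids <- vapply(reference_sketches, function(x) x$genome_id, character(1))
  d <- vapply(reference_sketches, function(r)
    mash_distance(query_sketch, r), numeric(1))
  o <- order(d, ids)
  best <- o[1]
  cmp <- fragment_ani(get_seq(query_sketch$genome_id), get_seq(ids[best]),
                      query_id = query_sketch$genome_id,
                      ref_id = ids[best], ...)
  matched <- !is.na(cmp$ani) && cmp$af_query >= min_af && cmp$ani >= min_ani
  list(matched = matched, ref_id = ids[best], mash_d = d[best],
       comparison = cmp)
}

#' Dereplicate genomes into species-level clusters
#'
#' Greedy species-level dereplication within Mash pre-clusters. Genomes
#' are visited in descending quality-score order (ties: longer genome,
#' then id); each genome joins the best-matching existing cluster whose
#' representative it hits at `ani >= 95`% with coverage of the larger
#' genome at least `nc * 100`%, and otherwise founds a new cluster. The
#' representative of each cluster is therefore its highest-QS member
#' (cluster founders). The coverage threshold `nc` is 0.60 for
#' near-complete genomes and 0.30 for medium-quality genomes with QS
#' above 50, mirroring the two dereplication passes of catalogue
#' construction; near-complete candidates with contamination above 5% are
#' excluded before clustering.
#'
#' @param mags data.frame with columns `genome_id`, `qs`, `completeness`,
#'   `contamination`, `genome_length`.
#' @param sequences Named character vector of genome sequences.
#' @param preclusters Named integer vector (genome id -> pre-cluster), as
#'   from [precluster()]. Every genome in `mags` must appear.
#' @param tier `"near_complete"` (nc = 0.60, contamination <= 5 enforced)
#'   or `"medium_quality"` (nc = 0.30).
#' @param min_ani ANI threshold, percent; default 95 (the species
#'   boundary).
#' @param nc Coverage threshold override (fraction); default set by
#'   `tier`.
#' @param ... Passed to [fragment_ani()].
#' @return data.frame with columns `mgs_id`, `genome_id`,
#'   `representative_id`, `is_representative`, `precluster`.
#' @export
dereplicate <- function(mags, sequences, preclusters,
                        tier = c("near_complete", "medium_quality"),
                        min_ani = 95, nc = NULL, ...) {
  tier <- match.arg(tier)
  if (is.null(nc)) nc <- if (tier == "near_complete") 0.60 else 0.30
  stopifnot(all(c("genome_id", "qs") %in% names(mags)))
  if (!all(mags$genome_id %in% names(preclusters)))
    stop("every genome must belong to exactly one precluster", call. = FALSE)
  if (tier == "near_complete" && "contamination" %in% names(mags))
    mags <- mags[mags$contamination <= 5, , drop = FALSE]
  if (nrow(mags) == 0L)
    return(data.frame(mgs_id = character(0), genome_id = character(0),
                      representative_id = character(0),
                      is_representative = logical(0),
                      precluster = integer(0), stringsAsFactors = FALSE))
  glen <- if ("genome_length" %in% names(mags)) mags$genome_length
          else nchar(sequences[mags$genome_id])
  mags <- mags[order(-mags$qs, -glen, mags$genome_id), , drop = FALSE]

  rows <- list()
  mgs_counter <- 0L
  for (pc in unique(preclusters[mags$genome_id])) {
    members <- mags[preclusters[mags$genome_id] == pc, , drop = FALSE]
    reps <- character(0)      # representative id per open cluster
    assignment <- character(nrow(members))
    for (i in seq_len(nrow(members))) {
      gid <- members$genome_id[i]
      best_rep <- NA_character_; best_ani <- -Inf
      for (rep_id in reps) {
        cmp <- fragment_ani(sequences[[gid]], sequences[[rep_id]],
                            query_id = gid, ref_id = rep_id, ...)
        if (!is.na(cmp$ani) && cmp$ani >= min_ani &&
            cmp$af_larger >= nc * 100 && cmp$ani > best_ani) {
          best_rep <- rep_id; best_ani <- cmp$ani
        }
      }
      if (is.na(best_rep)) {
        reps <- c(reps, gid)
        assignment[i] <- gid
      } else assignment[i] <- best_rep
    }
    for (rep_id in reps) {
      mgs_counter <- mgs_counter + 1L
      in_cluster <- members$genome_id[assignment == rep_id]
      rows[[length(rows) + 1L]] <- data.frame(
        mgs_id = sprintf("MGS%04d", mgs_counter),
        genome_id = in_cluster,
        representative_id = rep_id,
        is_representative = in_cluster == rep_id,
        precluster = pc, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Matthews correlation coefficient of a clustering against marker-gene AAI
#'
#' Scores how well a genome clustering agrees with pairwise average
#' amino-acid identity (AAI) at a given threshold. Over all unordered
#' genome pairs: a true positive is a same-cluster pair with AAI at or
#' above the threshold; a false negative a same-cluster pair below it; a
#' false positive a cross-cluster pair at or above it; a true negative a
#' cross-cluster pair below it. MCC is computed from these counts, with
#' the 0/0 case defined as 0. Typical evaluation thresholds are 90, 95
#' and 97%.
#'
#' @param clusters Named vector: cluster label per genome id.
#' @param aai Symmetric numeric matrix of pairwise AAI (percent) with
#'   genome ids as dimnames; must cover every genome in `clusters`.
#' @param threshold AAI threshold, percent in (0, 100\].
#' @return MCC in \[-1, 1\].
#' @export
cluster_mcc <- function(clusters, aai, threshold) {
  stopifnot_scalar(threshold, "threshold", lo = .Machine$double.eps, hi = 100)
  ids <- names(clusters)
  if (is.null(ids) || !all(ids %in% rownames(aai)))
    stop("aai must be defined for all clustered genomes", call. = FALSE)
  aai <- aai[ids, ids, drop = FALSE]
  same <- outer(clusters, clusters, "==")
  hi <- aai >= threshold
  ut <- upper.tri(same)
  tp <- sum(same[ut] & hi[ut]); fn <- sum(same[ut] & !hi[ut])
  fp <- sum(!same[ut] & hi[ut]); tn <- sum(!same[ut] & !hi[ut])
  mcc_from_counts(tp, fp, fn, tn)
}

# exact double arithmetic; counts here are far below 2^53
mcc_from_counts <- function(tp, fp, fn, tn) {
  denom <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  if (denom == 0) return(0)
  (tp * tn - fp * fn) / denom
}
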