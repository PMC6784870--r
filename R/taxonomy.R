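TAX_RANKS <- c("domain", "phylum", "class", "order", "family", "genus",
               "species")

#' Construct a ranked lineage
#'
#' A lineage is a named character vector over the seven standard ranks
#' (domain to species); names may be missing (NA) from any rank downward
#' but never in the middle (a named genus implies a named family and
#' above).
#'
#' @param ... Rank names, e.g. `lineage(domain = "Bacteria", phylum =
#'   "Firmicutes")`.
#' @param validate Check the no-gap invariant (default TRUE).
#' @return Named character vector of length 7.
#' @export
lineage <- function(..., validate = TRUE) {
  given <- list(...)
  bad <- setdiff(names(given), TAX_RANKS)
  if (length(bad)) stop("unknown ranks: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  out <- setNames(rep(NA_character_, length(TAX_RANKS)), TAX_RANKS)
  out[names(given)] <- unlist(given)
  if (validate && lineage_has_gap(out))
    stop("lineage has a gap (a named rank below a missing one)",
         call. = FALSE)
  out
}

lineage_has_gap <- function(lin) {
  named <- !is.na(lin[TAX_RANKS]) & nzchar(lin[TAX_RANKS])
  if (!any(named)) return(FALSE)
  last <- max(which(named))
  !all(named[seq_len(last)])
}

# case-fold and strip the provisional "Candidatus" prefix before comparing
normalize_taxon <- function(x) {
  x <- tolower(trimws(x))
  sub("^candidatus\\s+", "", x)
}

# TRUE when every rank named in both lineages agrees (placement is a
# prefix of the candidate in the well-formed, gap-free case)
lineage_compatible <- function(placement, candidate) {
  shared <- !is.na(placement) & !is.na(candidate)
  all(normalize_taxon(placement[shared]) ==
        normalize_taxon(candidate[shared]))
}

#' Does an organism label name a cultured species?
#'
#' A subject label is taken to represent a cultured, validly named
#' species when it is a binomial (two or more words) containing none of
#' the case-insensitive tokens `uncultured`, `sp.` or `bacterium`.
#'
#' @param name Organism label(s); vectorised.
#' @return Logical vector.
#' @examples
#' is_cultured_name("Ruminococcus bromii")       # TRUE
#' is_cultured_name("Lactobacillus sp. ABC-1")   # FALSE
#' is_cultured_name("uncultured organism")       # FALSE
#' @export
is_cultured_name <- function(name) {
  vapply(name, function(n) {
    if (is.na(n) || !nzchar(trimws(n))) return(FALSE)
    words <- strsplit(trimws(n), "\\s+")[[1]]
    if (length(words) < 2L) return(FALSE)
    !any(tolower(words) %in% c("uncultured", "sp.", "bacterium"))
  }, logical(1), USE.NAMES = FALSE)
}

#' Species-level call from protein best hits
#'
#' A subject genome qualifies as a species-level match when at least 60%
#' of the query's proteins align to it with at least 80% of the sequence
#' aligned and at least 96% amino-acid identity. Among qualifying
#' subjects the one with the highest qualifying fraction wins (ties:
#' highest mean identity, then lexicographic subject name).
#'
#' @param hits data.frame with columns `protein_id`, `subject_name`,
#'   `identity` (percent), `coverage` (percent of the sequence aligned;
#'   whether this is subject- or query-side coverage is the caller's
#'   convention, see [read_protein_hits()]).
#' @param n_proteins Total number of proteins predicted for the query
#'   genome (the denominator of the fraction).
#' @param min_fraction,min_identity,min_coverage Rule thresholds;
#'   defaults 0.60, 96, 80.
#' @return NULL when no subject qualifies, else a list with `subject`,
#'   `fraction`, `mean_identity`.
#' @export
species_call <- function(hits, n_proteins, min_fraction = 0.60,
                         min_identity = 96, min_coverage = 80) {
  stopifnot_scalar(n_proteins, "n_proteins", lo = 1)
  if (is.null(hits) || nrow(hits) == 0L) return(NULL)
  q <- hits[hits$coverage >= min_coverage & hits$identity >= min_identity, ,
            drop = FALSE]
  if (nrow(q) == 0L) return(NULL)
  per_subj <- split(q, q$subject_name)
  frac <- vapply(per_subj, function(h)
    length(unique(h$protein_id)) / n_proteins, numeric(1))
  mid <- vapply(per_subj, function(h) mean(h$identity), numeric(1))
  ok <- frac >= min_fraction
  if (!any(ok)) return(NULL)
  cand <- names(per_subj)[ok]
  o <- order(-frac[ok], -mid[ok], cand)
  best <- cand[o[1]]
  list(subject = best, fraction = unname(frac[best]),
       mean_identity = unname(mid[best]))
}

#' Genus-level call from protein best hits
#'
#' A genus qualifies when at least 50% of the query's proteins hit a
#' member of it with e-value below 1e-5, identity strictly above 40% and
#' coverage strictly above 50%.
#'
#' @param hits data.frame with columns `protein_id`, `genus`, `identity`,
#'   `coverage`, `evalue`.
#' @param n_proteins Total protein count of the query genome.
#' @param min_fraction,max_evalue,min_identity,min_coverage Rule
#'   thresholds; defaults 0.50, 1e-5, 40, 50 (identity and coverage
#'   bounds are strict).
#' @return NULL or a list with `genus`, `fraction`, `mean_identity`.
#' @export
genus_call <- function(hits, n_proteins, min_fraction = 0.50,
                       max_evalue = 1e-5, min_identity = 40,
                       min_coverage = 50) {
  stopifnot_scalar(n_proteins, "n_proteins", lo = 1)
  if (is.null(hits) || nrow(hits) == 0L) return(NULL)
  q <- hits[hits$evalue < max_evalue & hits$identity > min_identity &
              hits$coverage > min_coverage, , drop = FALSE]
  q <- q[!is.na(q$genus) & nzchar(q$genus), , drop = FALSE]
  if (nrow(q) == 0L) return(NULL)
  per_genus <- split(q, q$genus)
  frac <- vapply(per_genus, function(h)
    length(unique(h$protein_id)) / n_proteins, numeric(1))
  mid <- vapply(per_genus, function(h) mean(h$identity), numeric(1))
  ok <- frac >= min_fraction
  if (!any(ok)) return(NULL)
  cand <- names(per_genus)[ok]
  o <- order(-frac[ok], -mid[ok], cand)
  best <- cand[o[1]]
  list(genus = best, fraction = unname(frac[best]),
       mean_identity = unname(mid[best]))
}

#' Resolve the final lineage of a species cluster
#'
#' Combines a phylogenetic-placement lineage with protein-hit species and
#' genus calls, and flags uncultured candidate species (UMGS):
#' \itemize{
#'   \item A cultured species-level match whose lineage is compatible
#'     with the placement (every rank named by both agrees, after
#'     case-folding and stripping "Candidatus") is adopted in full;
#'     `umgs = FALSE`.
#'   \item When the protein assignment conflicts with the placement at
#'     any shared rank, the placement is kept (protein databases can be
#'     mislabelled), `umgs = TRUE` and the record is flagged
#'     `needs_review` for manual curation.
#'   \item With no cultured species match, `umgs = TRUE`; a compatible
#'     genus call deepens the lineage to genus level.
#' }
#' Placements not classified at least to class rank are flagged
#' `unresolvable` (returned, not thrown).
#'
#' @param placement Lineage from phylogenetic placement (see
#'   [lineage()]).
#' @param protein_species NULL or list with `subject`, `lineage`
#'   (full 7-rank lineage of the matched subject).
#' @param protein_genus NULL or list with `genus`, `lineage` (lineage
#'   down to genus).
#' @param cultured_flag Is the species-level subject a cultured isolate
#'   (see [is_cultured_name()])?
#' @return List: `lineage`, `umgs`, `needs_review`, `unresolvable`.
#' @export
resolve_lineage <- function(placement, protein_species = NULL,
                            protein_genus = NULL, cultured_flag = FALSE) {
  if (is.na(placement[["class"]]))
    return(list(lineage = placement, umgs = NA, needs_review = TRUE,
                unresolvable = TRUE))
  if (!is.null(protein_species)) {
    sp_lin <- protein_species$lineage
    if (lineage_compatible(placement, sp_lin)) {
      if (cultured_flag)
        return(list(lineage = sp_lin, umgs = FALSE, needs_review = FALSE,
                    unresolvable = FALSE))
      # uncultured-labelled species match: stays a candidate species
    } else {
      return(list(lineage = placement, umgs = TRUE, needs_review = TRUE,
                  unresolvable = FALSE))
    }
  }
  final <- placement
  review <- FALSE
  if (!is.null(protein_genus)) {
    g_lin <- protein_genus$lineage
    if (lineage_compatible(placement, g_lin)) {
      take <- is.na(final) & !is.na(g_lin)
      final[take] <- g_lin[take]
      final[["species"]] <- NA_character_
    } else review <- TRUE
  }
  list(lineage = final, umgs = TRUE, needs_review = review,
       unresolvable = FALSE)
}

#' Read a tabular protein-alignment file
#'
#' Parses the common 12-column tab-separated alignment format (query,
#' subject, identity, alignment length, mismatches, gap opens, qstart,
#' qend, sstart, send, evalue, bitscore) and computes per-hit coverage
#' from a table of sequence lengths. Coverage can be computed on the
#' subject side (alignment length / subject length; the default) or the
#' query side — the wording "percent of the sequence aligned" admits
#' both, so the choice is explicit configuration.
#'
#' @param path Tab-separated file without header, 12 columns.
#' @param lengths data.frame with columns `id`, `length` covering the
#'   chosen side's sequences.
#' @param coverage_on `"subject"` (default) or `"query"`.
#' @return data.frame with `protein_id`, `subject_name`, `identity`,
#'   `coverage`, `evalue`, `bitscore`.
#' @export
read_protein_hits <- function(path, lengths,
                              coverage_on = c("subject", "query")) {
  coverage_on <- match.arg(coverage_on)
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  x <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(x) != 12L) stop("expected 12 tab-separated columns", call. = FALSE)
  names(x) <- cols
  side <- if (coverage_on == "subject") x$sseqid else x$qseqid
  len <- lengths$length[match(side, lengths$id)]
  if (anyNA(len))
    stop("missing sequence length for some hits", call. = FALSE)
  data.frame(protein_id = x$qseqid, subject_name = x$sseqid,
             identity = x$pident, coverage = 100 * x$length / len,
             evalue = x$evalue, bitscore = x$bitscore,
             stringsAsFactors = FALSE)
}
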