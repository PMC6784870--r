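# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: string-based k-mer sets, explicit pair loops,
# position counting and exhaustive subset enumeration.

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

revcomp_str <- function(x) {
  vapply(x, function(s)
    chartr("ACGT", "TGCA",
           paste(rev(strsplit(s, "")[[1]]), collapse = "")),
    character(1), USE.NAMES = FALSE)
}

# set of canonical k-mers of a sequence, by plain string manipulation
canonical_kmer_set <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  km <- substring(seq, 1:(n - k + 1), k:n)
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(km)))
  unique(pmin(km, rc))
}

exact_kmer_jaccard <- function(a, b, k = 21) {
  sa <- canonical_kmer_set(a, k)
  sb <- canonical_kmer_set(b, k)
  length(intersect(sa, sb)) / length(union(sa, sb))
}

# the bottom-s Jaccard estimate, recomputed from sketch contents
sketch_jaccard <- function(a, b) {
  merged <- sort(unique(c(a$hashes, b$hashes)))
  x <- merged[seq_len(min(a$s, length(merged)))]
  sum(x %in% a$hashes & x %in% b$hashes) / length(x)
}

# MCC by explicit enumeration of unordered pairs with if/else counting
brute_mcc <- function(clusters, aai, threshold) {
  ids <- names(clusters)
  tp <- fp <- fn <- tn <- 0
  for (i in seq_along(ids)[-length(ids)]) {
    for (j in seq(i + 1, length(ids))) {
      same <- clusters[[ids[i]]] == clusters[[ids[j]]]
      hi <- aai[ids[i], ids[j]] >= threshold
      if (same && hi) tp <- tp + 1
      else if (same && !hi) fn <- fn + 1
      else if (!same && hi) fp <- fp + 1
      else tn <- tn + 1
    }
  }
  den <- sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  if (den == 0) 0 else (tp * tn - fp * fn) / den
}

# interval-union length by counting integer positions
brute_union_len <- function(start, end) {
  pos <- unlist(mapply(function(s, e) seq(s, e - 1), start, end,
                       SIMPLIFY = FALSE))
  length(unique(pos))
}

# expected accumulation-curve value at depth x by exhaustive enumeration
# of all sample subsets of size x
enum_accum_expectation <- function(detections, x) {
  n <- nrow(detections)
  subsets <- utils::combn(n, x)
  mean(apply(subsets, 2, function(idx)
    sum(colSums(detections[idx, , drop = FALSE]) > 0)))
}

# protein-hit fixture builders shared across taxonomy tests
make_hits <- function(n_qual, n_total, subject = "Subj a",
                      identity = 99, coverage = 95) {
  data.frame(protein_id = sprintf("p%03d", seq_len(n_total)),
             subject_name = subject,
             identity = c(rep(identity, n_qual), rep(50, n_total - n_qual)),
             coverage = c(rep(coverage, n_qual), rep(95, n_total - n_qual)),
             evalue = 1e-30, stringsAsFactors = FALSE)
}

make_genus_hits <- function(n_qual, n_total, genus = "GenusA",
                            identity = 60, coverage = 80, evalue = 1e-20) {
  data.frame(protein_id = sprintf("p%03d", seq_len(n_total)),
             genus = genus,
             identity = c(rep(identity, n_qual), rep(30, n_total - n_qual)),
             coverage = c(rep(coverage, n_qual), rep(30, n_total - n_qual)),
             evalue = c(rep(evalue, n_qual), rep(1e-3, n_total - n_qual)),
             stringsAsFactors = FALSE)
}

# random mutated copy of a sequence (substitutions only), for ANI oracles
mutate_seq <- function(seq, rate) {
  bases <- c("A", "C", "G", "T")
  g <- strsplit(seq, "")[[1]]
  mut <- which(runif(length(g)) < rate)
  if (length(mut)) {
    shift <- sample.int(3, length(mut), replace = TRUE)
    g[mut] <- bases[(match(g[mut], bases) - 1L + shift) %% 4L + 1L]
  }
  paste(g, collapse = "")
}
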