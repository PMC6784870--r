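#' Bottom-s MinHash sketch of a genome
#'
#' Builds a MinHash sketch of a nucleotide sequence: every canonical k-mer
#' (lexicographic minimum of the k-mer and its reverse complement) is
#' hashed with a fixed, documented 64-bit non-cryptographic hash
#' (splitmix64, seed 42) and the `s` smallest distinct values are kept.
#' K-mers containing ambiguity codes (N) are skipped. Hash values are
#' truncated to their top 53 bits so they are exactly representable as R
#' doubles; ordering and distinctness are unaffected.
#'
#' @param sequence Nucleotide string (A/C/G/T/N, case-insensitive), or a
#'   length-1 [Biostrings::DNAStringSet] element coerced with
#'   `as.character()` by the caller.
#' @param genome_id Identifier attached to the sketch.
#' @param k K-mer length, default 21.
#' @param s Sketch size (maximum number of hashes kept), default 1000.
#' @param hash_seed Seed of the sketch hash; fixed (42) by default so that
#'   sketches are comparable across runs and machines.
#' @return An object of class `genome_sketch`: list with `genome_id`, `k`,
#'   `s` and `hashes` (sorted ascending, distinct, length <= s).
#' @examples
#' sk <- sketch(paste(sample(c("A","C","G","T"), 100, TRUE), collapse = ""),
#'              "g1")
#' length(sk$hashes) <= sk$s
#' @export
sketch <- function(sequence, genome_id = "genome", k = 21L, s = 1000L,
                   hash_seed = 42) {
  sequence <- as.character(sequence)
  if (length(sequence) != 1L || is.na(sequence))
    stop("sequence must be a single string", call. = FALSE)
  if (nchar(sequence) < k)
    stop("sequence shorter than k", call. = FALSE)
  h <- sketch_hashes_cpp(sequence, as.integer(k), as.integer(s),
                         as.numeric(hash_seed))
  structure(list(genome_id = genome_id, k = as.integer(k),
                 s = as.integer(s), hashes = h),
            class = "genome_sketch")
}

#' @export
print.genome_sketch <- function(x, ...) {
  cat(sprintf("genome_sketch '%s': k=%d, s=%d, %d hashes\n",
              x$genome_id, x$k, x$s, length(x$hashes)))
  invisible(x)
}

#' Mash distance between two sketches
#'
#' Estimates the k-mer Jaccard index from the union sketch and converts it
#' to a Mash distance. With `X` the `s` smallest values of the merged hash
#' sets `A` and `B`, the Jaccard estimate is `j = |X n A n B| / |X|` and
#' `d = min(1, -log(2j / (1 + j)) / k)`; `j = 0` maps to `d = 1`.
#'
#' @param a,b `genome_sketch` objects with matching `k` and `s`.
#' @return Distance in \[0, 1\].
#' @examples
#' # j = 0.2, k = 21  ->  -log(0.4 / 1.2) / 21 = 0.05231...
#' @export
mash_distance <- function(a, b) {
  stopifnot(inherits(a, "genome_sketch"), inherits(b, "genome_sketch"))
  if (a$k != b$k) stop("sketches have different k", call. = FALSE)
  if (a$s != b$s) stop("sketches have different sketch size", call. = FALSE)
  merged <- sort(unique(c(a$hashes, b$hashes)))
  x <- merged[seq_len(min(a$s, length(merged)))]
  j <- sum(x %in% a$hashes & x %in% b$hashes) / length(x)
  mash_from_jaccard(j, a$k)
}

# closed form d(j, k); j = 0 -> 1, capped at 1
mash_from_jaccard <- function(j, k) {
  if (j <= 0) return(1)
  min(1, -log(2 * j / (1 + j)) / k)
}

#' All-against-all Mash distance matrix
#'
#' @param sketches List of `genome_sketch` objects (names taken from their
#'   `genome_id` fields).
#' @return Symmetric numeric matrix with zero diagonal, dimnames = genome
#'   ids.
#' @export
mash_dist_matrix <- function(sketches) {
  ids <- vapply(sketches, function(x) x$genome_id, character(1))
  n <- length(sketches)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  if (n < 2) return(d)
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    d[i, j] <- d[j, i] <- mash_distance(sketches[[i]], sketches[[j]])
  }
  d
}

#' Pre-cluster genomes by hierarchical clustering of Mash distances
#'
#' Builds an agglomerative hierarchical clustering (average linkage by
#' default) from a Mash distance matrix and cuts the dendrogram at the
#' given height, yielding coarse genome groups that are subsequently
#' dereplicated at nucleotide resolution. The 0.2 default corresponds
#' roughly to >= 80% sequence identity between group members.
#'
#' @param d Symmetric distance matrix with genome ids as dimnames (as from
#'   [mash_dist_matrix()]).
#' @param cutoff Tree cut height, default 0.2.
#' @param method Linkage: `"average"` (default), `"single"` or
#'   `"complete"`.
#' @return Named integer vector: cluster id per genome. Zero-row input
#'   yields an empty vector.
#' @export
precluster <- function(d, cutoff = 0.2, method = c("average", "single",
                                                   "complete")) {
  method <- match.arg(method)
  if (is.null(d) || nrow(d) == 0L) return(setNames(integer(0), character(0)))
  if (nrow(d) == 1L) return(setNames(1L, rownames(d)))
  hc <- hclust(as.dist(d), method = method)
  cutree(hc, h = cutoff)
}

#' Serialize / read sketches as JSON
#'
#' Sketches are stored as a documented JSON object (`genome_id`, `k`, `s`,
#' `hashes`) so they can be reused across runs. Hash values are written
#' as decimal strings: they are 53-bit integers, and JSON number
#' round-tripping is not guaranteed to preserve them exactly.
#'
#' @param sketches List of `genome_sketch` objects.
#' @param path Output file.
#' @return `path` (write) or a list of sketches (read), invisibly for the
#'   writer.
#' @export
write_sketches <- function(sketches, path) {
  payload <- lapply(sketches, function(x)
    list(genome_id = x$genome_id, k = x$k, s = x$s,
         hashes = sprintf("%.0f", x$hashes)))
  jsonlite::write_json(payload, path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_sketches
#' @export
read_sketches <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(seq_len(nrow(payload)), function(i)
    structure(list(genome_id = payload$genome_id[i],
                   k = as.integer(payload$k[i]),
                   s = as.integer(payload$s[i]),
                   hashes = as.numeric(payload$hashes[[i]])),
              class = "genome_sketch"))
}
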