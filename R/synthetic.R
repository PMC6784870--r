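PHYLA_POOL <- c("Firmicutes", "Bacteroidetes", "Actinobacteria",
                "Proteobacteria")

#' Simulate a genome collection with planted species structure
#'
#' Generates `n_species` independent ancestor sequences (uniform ACGT).
#' The first strain of each species is the ancestor itself (it later
#' becomes the species representative); the remaining strains are
#' i.i.d. point-mutated copies at the stated per-site substitution
#' rate. Mutations are substitutions only (no indels), so the expected
#' nucleotide identity of a strain to the representative is exactly
#' `1 - divergence` and the planted ANI is analytic. Each species
#' receives a synthetic ranked lineage; the last
#' `n_uncultured` species are planted as uncultured (no binomial species
#' name, no cultured isolate relative at species-level identity).
#'
#' @param n_species,strains_per_species Positive counts.
#' @param divergence Per-site substitution rate in \[0, 0.5).
#' @param genome_length Genome size in bp (>= 210).
#' @param n_uncultured Number of species planted as uncultured (taken
#'   from the end of the species list), default 0.
#' @param seed RNG seed; the generator is a pure function of its
#'   parameters and the seed.
#' @return List with `sequences` (named character vector, one per
#'   genome), `truth` (data.frame: species_id, genome_id,
#'   planted_ani_to_rep, cultured) and `lineages` (data.frame:
#'   species_id, domain...species, cultured).
#' @export
simulate_genome_set <- function(n_species, strains_per_species, divergence,
                                genome_length, n_uncultured = 0, seed = 1) {
  stopifnot_scalar(n_species, "n_species", lo = 1)
  stopifnot_scalar(strains_per_species, "strains_per_species", lo = 1)
  stopifnot_scalar(genome_length, "genome_length", lo = 210)
  if (divergence < 0 || divergence >= 0.5)
    stop("divergence must lie in [0, 0.5)", call. = FALSE)
  if (n_uncultured > n_species)
    stop("n_uncultured cannot exceed n_species", call. = FALSE)
  bases <- c("A", "C", "G", "T")
  with_seed(seed, {
    seqs <- character(0)
    truth <- list()
    lineages <- list()
    for (i in seq_len(n_species)) {
      sid <- sprintf("SP%02d", i)
      anc <- sample(bases, genome_length, replace = TRUE)
      cultured <- i <= n_species - n_uncultured
      genus <- sprintf("Simulogenus%02d", i)
      lineages[[i]] <- data.frame(
        species_id = sid, domain = "Bacteria",
        phylum = PHYLA_POOL[(i - 1) %% length(PHYLA_POOL) + 1],
        class = sprintf("Simuloclassia%02d", (i - 1) %% length(PHYLA_POOL) + 1),
        order = sprintf("Simulales%02d", i),
        family = sprintf("Simulaceae%02d", i),
        genus = genus,
        species = if (cultured) paste(genus, sprintf("simulans%02d", i))
                  else NA_character_,
        cultured = cultured, stringsAsFactors = FALSE)
      for (j in seq_len(strains_per_species)) {
        gid <- sprintf("%s_G%02d", sid, j)
        g <- anc
        if (divergence > 0 && j > 1L) {
          mut <- which(runif(genome_length) < divergence)
          if (length(mut)) {
            # substitute with one of the three other bases, uniformly
            shift <- sample.int(3, length(mut), replace = TRUE)
            idx <- (match(g[mut], bases) - 1L + shift) %% 4L + 1L
            g[mut] <- bases[idx]
          }
        }
        seqs[gid] <- paste(g, collapse = "")
        truth[[length(truth) + 1L]] <- data.frame(
          species_id = sid, genome_id = gid,
          planted_ani_to_rep = if (j == 1L) 1 else 1 - divergence,
          cultured = cultured, stringsAsFactors = FALSE)
      }
    }
    list(sequences = seqs, truth = do.call(rbind, truth),
         lineages = do.call(rbind, lineages))
  })
}

#' Simulate per-genome QC estimates
#'
#' Attaches completeness/contamination estimates to a simulated genome
#' set so that every genome lands in the near-complete tier and the
#' first strain of each species carries the highest quality score (and
#' therefore becomes the cluster representative after dereplication).
#'
#' @param truth Truth table from [simulate_genome_set()].
#' @param genome_length Genome size used for the `genome_length` column.
#' @param seed RNG seed.
#' @return data.frame: genome_id, completeness, contamination,
#'   genome_length, n_contigs.
#' @export
simulate_mag_qc <- function(truth, genome_length, seed = 1) {
  with_seed(seed, {
    is_rep <- !duplicated(truth$species_id)
    n <- nrow(truth)
    completeness <- ifelse(is_rep, 99 + runif(n), 91 + 5 * runif(n))
    contamination <- ifelse(is_rep, 0.5 * runif(n), 2 * runif(n))
    data.frame(genome_id = truth$genome_id,
               completeness = round(completeness, 2),
               contamination = round(contamination, 2),
               genome_length = genome_length,
               n_contigs = 1L + rpois(n, 20),
               stringsAsFactors = FALSE)
  })
}

#' Plant per-sample presence/abundance truth
#'
#' Each genome is present in each sample independently with probability
#' `prevalence`; relative abundances of the present genomes are drawn
#' from a normalised gamma (Dirichlet) vector scaled so that per-sample
#' abundances sum to `total_fraction` (< 1, leaving headroom for
#' unmapped reads).
#'
#' @param genome_ids Character vector.
#' @param n_samples Number of samples (ids `SAMPLE01`, ...).
#' @param prevalence Per-genome per-sample presence probability, default
#'   0.5.
#' @param total_fraction Summed abundance of present genomes per sample,
#'   default 0.9.
#' @param seed RNG seed.
#' @return data.frame: genome_id, sample_id, present, true_abundance.
#' @export
simulate_presence_truth <- function(genome_ids, n_samples,
                                    prevalence = 0.5,
                                    total_fraction = 0.9, seed = 1) {
  stopifnot_scalar(n_samples, "n_samples", lo = 1)
  with_seed(seed, {
    rows <- lapply(seq_len(n_samples), function(s) {
      sample_id <- sprintf("SAMPLE%02d", s)
      present <- runif(length(genome_ids)) < prevalence
      ab <- numeric(length(genome_ids))
      if (any(present)) {
        w <- rgamma(sum(present), shape = 1)
        ab[present] <- total_fraction * w / sum(w)
      }
      data.frame(genome_id = genome_ids, sample_id = sample_id,
                 present = present, true_abundance = ab,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}

#' Simulate per-genome per-sample depth summaries
#'
#' Emulates coverage/depth summaries as they would be computed from read
#' mappings, using a window-level model (fixed-width windows, default
#' 1 kb equivalents): a present genome covers almost all windows
#' (missing fraction shrinks to zero with `dispersion`) with
#' gamma-distributed window depths of mean `depth_mean` and coefficient
#' of variation `dispersion`; an absent genome draws either a
#' near-zero-coverage profile with trace depth (70% of cases) or a
#' patchy high-depth/low-coverage profile (30%) so that both penalty
#' scores are exercised. Mean and sd of depth are computed over covered
#' windows.
#'
#' @param truth Presence truth from [simulate_presence_truth()].
#' @param depth_mean Mean read depth of present genomes, default 10.
#' @param dispersion Depth coefficient of variation, default 0.5.
#' @param n_windows Windows per genome, default 50.
#' @param total_reads Total reads per sample, default 1e6.
#' @param seed RNG seed.
#' @return data.frame: genome_id, sample_id, coverage, mean_depth,
#'   sd_depth, unique_proper_pairs, total_reads.
#' @export
simulate_depth_summaries <- function(truth, depth_mean = 10,
                                     dispersion = 0.5, n_windows = 50,
                                     total_reads = 1e6, seed = 1) {
  stopifnot_scalar(depth_mean, "depth_mean", lo = 1e-9)
  if (is.null(truth) || nrow(truth) == 0L)
    return(data.frame(genome_id = character(0), sample_id = character(0),
                      coverage = numeric(0), mean_depth = numeric(0),
                      sd_depth = numeric(0),
                      unique_proper_pairs = integer(0),
                      total_reads = integer(0), stringsAsFactors = FALSE))
  with_seed(seed, {
    n <- nrow(truth)
    coverage <- mean_depth <- sd_depth <- numeric(n)
    upp <- integer(n)
    for (i in seq_len(n)) {
      if (truth$present[i]) {
        frac_missing <- dispersion * rbeta(1, 1, 49)
        n_cov <- max(1L, round((1 - frac_missing) * n_windows))
        depths <- if (dispersion < 1e-12) rep(depth_mean, n_cov)
        else rgamma(n_cov, shape = 1 / dispersion^2,
                    rate = 1 / (depth_mean * dispersion^2))
        upp[i] <- as.integer(round(total_reads * truth$true_abundance[i]))
      } else if (runif(1) < 0.7) {
        # trace mapping: a few windows at very low depth
        n_cov <- round(runif(1, 0, 0.3) * n_windows)
        depths <- if (n_cov > 0) rexp(n_cov, rate = 1) else numeric(0)
        upp[i] <- rpois(1, total_reads * 1e-6)
      } else {
        # patchy: high depth over a small covered fraction
        n_cov <- round(runif(1, 0.2, 0.5) * n_windows)
        depths <- rgamma(n_cov, shape = 1 / 1.5^2,
                         rate = 1 / (3 * depth_mean * 1.5^2))
        upp[i] <- rpois(1, total_reads * 1e-6)
      }
      n_cov <- length(depths)
      coverage[i] <- 100 * n_cov / n_windows
      mean_depth[i] <- if (n_cov > 0) mean(depths) else 0
      sd_depth[i] <- if (n_cov > 1) sd(depths) else 0
    }
    data.frame(genome_id = truth$genome_id, sample_id = truth$sample_id,
               coverage = coverage, mean_depth = mean_depth,
               sd_depth = sd_depth, unique_proper_pairs = upp,
               total_reads = as.integer(total_reads),
               stringsAsFactors = FALSE)
  })
}

#' Simulate protein best-hit tables consistent with planted lineages
#'
#' For each genome in the species truth, emits one best hit per protein.
#' Genomes of cultured species hit a subject named with the planted
#' binomial: 75% of proteins qualify at the species rule (identity
#' >= 96%, coverage >= 80%) and the rest fall below the identity bound.
#' Genomes of planted-uncultured species hit a cultured relative in the
#' same genus at sub-species identity (60-90%), so the species rule
#' never fires while 75% of proteins qualify at the genus rule. With
#' probability `noise` a protein's qualification status is re-drawn
#' Bernoulli(0.5), so `noise = 1` drives qualifying fractions to ~0.5.
#'
#' @param truth,lineages Tables from [simulate_genome_set()].
#' @param n_proteins Proteins per genome, default 100.
#' @param noise Per-protein status-randomisation probability in
#'   \[0, 1\], default 0.
#' @param seed RNG seed.
#' @return List with `hits` (genome_id, protein_id, subject_name,
#'   identity, coverage, evalue) and `subjects` (subject_name plus its
#'   7-rank lineage).
#' @export
simulate_protein_hits <- function(truth, lineages, n_proteins = 100,
                                  noise = 0, seed = 1) {
  stopifnot_scalar(n_proteins, "n_proteins", lo = 1)
  stopifnot_scalar(noise, "noise", lo = 0, hi = 1)
  with_seed(seed, {
    subj_rows <- list(); hit_rows <- list()
    for (si in seq_len(nrow(lineages))) {
      lin <- lineages[si, ]
      subject <- if (lin$cultured) lin$species
                 else paste(lin$genus, "propinquus")
      subj_rows[[si]] <- data.frame(
        subject_name = subject, domain = lin$domain, phylum = lin$phylum,
        class = lin$class, order = lin$order, family = lin$family,
        genus = lin$genus,
        species = subject, stringsAsFactors = FALSE)
      members <- truth$genome_id[truth$species_id == lin$species_id]
      n_qual <- ceiling(0.75 * n_proteins)
      for (gid in members) {
        qual <- c(rep(TRUE, n_qual), rep(FALSE, n_proteins - n_qual))
        flip <- runif(n_proteins) < noise
        qual[flip] <- runif(sum(flip)) < 0.5
        if (lin$cultured) {
          identity <- ifelse(qual, runif(n_proteins, 97, 100),
                             runif(n_proteins, 50, 90))
          coverage <- ifelse(qual, runif(n_proteins, 85, 100),
                             runif(n_proteins, 85, 100))
          evalue <- rep(1e-30, n_proteins)
        } else {
          identity <- ifelse(qual, runif(n_proteins, 60, 90),
                             runif(n_proteins, 20, 35))
          coverage <- ifelse(qual, runif(n_proteins, 60, 100),
                             runif(n_proteins, 20, 45))
          evalue <- ifelse(qual, 1e-30, 1e-3)
        }
        hit_rows[[length(hit_rows) + 1L]] <- data.frame(
          genome_id = gid,
          protein_id = sprintf("%s_P%04d", gid, seq_len(n_proteins)),
          subject_name = subject, identity = identity,
          coverage = coverage, evalue = evalue, stringsAsFactors = FALSE)
      }
    }
    list(hits = do.call(rbind, hit_rows),
         subjects = unique(do.call(rbind, subj_rows)))
  })
}
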