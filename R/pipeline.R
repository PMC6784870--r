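#' Default pipeline configuration
#'
#' Collects every tunable threshold of the catalogue workflow with its
#' default, so that a run's manifest records the exact settings used.
#'
#' @param ... Overrides for any listed element.
#' @return Named list of parameters.
#' @export
catalogue_config <- function(...) {
  cfg <- list(
    k = 21L, sketch_size = 1000L, hash_seed = 42,
    precluster_cutoff = 0.2, linkage = "average",
    fragment_length = 1000L, min_fragment_identity = 0.8, anchor_k = 15L,
    assign_min_ani = 95, assign_min_af = 60,
    derep_min_ani = 95, nc_near_complete = 0.60, nc_medium = 0.30,
    max_contamination_near_complete = 5,
    species_min_fraction = 0.60, species_min_identity = 96,
    species_min_coverage = 80,
    genus_min_fraction = 0.50, genus_max_evalue = 1e-5,
    genus_min_identity = 40, genus_min_coverage = 50,
    presence_min_coverage = 60, presence_percentile = 99,
    min_abundance = 1e-4, region_fraction = 0.2,
    n_boot = 10, seed = 1)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config entries: ",
                        paste(bad, collapse = ", "), call. = FALSE)
  cfg[names(over)] <- over
  cfg
}

#' Write a complete synthetic input bundle
#'
#' Generates every input the catalogue workflow consumes — genomes
#' (FASTA, 80-column wrapped), QC estimates, rRNA/tRNA tables, species
#' and presence truth, depth summaries, protein hits with subject
#' lineages, placement lineages, sample metadata and a labelled tree —
#' and writes them as plain-text files with documented schemas.
#'
#' @param dir Output directory (created if needed).
#' @param n_species,strains_per_species,divergence,genome_length,
#'   n_uncultured Passed to [simulate_genome_set()].
#' @param n_samples,prevalence Passed to [simulate_presence_truth()].
#' @param depth_mean,dispersion Passed to [simulate_depth_summaries()].
#' @param n_proteins,noise Passed to [simulate_protein_hits()].
#' @param seed Root seed; each generator stage receives a derived child
#'   seed.
#' @return Invisibly, a named list of the file paths written.
#' @export
simulate_bundle <- function(dir, n_species = 10, strains_per_species = 3,
                            divergence = 0.01, genome_length = 50000,
                            n_uncultured = 2, n_samples = 30,
                            prevalence = 0.5, depth_mean = 10,
                            dispersion = 0.5, n_proteins = 100,
                            noise = 0, seed = 1) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  sim_seed <- child_seed(seed, "simulate")

  gs <- simulate_genome_set(n_species, strains_per_species, divergence,
                            genome_length, n_uncultured, seed = sim_seed)
  dna <- Biostrings::DNAStringSet(gs$sequences)
  Biostrings::writeXStringSet(dna, p("genomes.fasta"), width = 80L)

  qc <- simulate_mag_qc(gs$truth, genome_length, seed = sim_seed + 1L)
  write_tsv(qc, p("qc.tsv"))

  # every genome carries complete rRNA loci and 20 tRNAs in this bundle;
  # rRNA/tRNA attrition is not part of the planted truth being tested
  expected <- c(`5S` = 110, `16S` = 1540, `23S` = 2900)
  rna <- do.call(rbind, lapply(names(expected), function(g)
    data.frame(genome_id = qc$genome_id, gene = g, start = 0,
               end = expected[[g]], expected_length = expected[[g]],
               stringsAsFactors = FALSE)))
  write_tsv(rna, p("rna_hits.tsv"))
  write_tsv(data.frame(genome_id = qc$genome_id, trna_count = 20L),
            p("trna.tsv"))

  write_tsv(gs$truth, p("species_truth.tsv"))
  write_tsv(gs$lineages, p("lineages.tsv"))

  pt <- simulate_presence_truth(gs$truth$genome_id, n_samples,
                                prevalence = prevalence,
                                seed = sim_seed + 2L)
  write_tsv(pt, p("presence_truth.tsv"))
  depth <- simulate_depth_summaries(pt, depth_mean = depth_mean,
                                    dispersion = dispersion,
                                    n_windows = max(10L, round(genome_length / 1000)),
                                    seed = sim_seed + 3L)
  write_tsv(depth, p("depth.tsv"))

  ph <- simulate_protein_hits(gs$truth, gs$lineages,
                              n_proteins = n_proteins, noise = noise,
                              seed = sim_seed + 4L)
  write_tsv(ph$hits, p("protein_hits.tsv"))
  write_tsv(ph$subjects, p("subjects.tsv"))

  # placement lineages: cultured species placed to genus rank,
  # uncultured ones to class rank (their genus is unknown to placement)
  placement <- merge(gs$truth[, c("genome_id", "species_id")],
                     gs$lineages, by = "species_id")
  placement <- placement[order(placement$genome_id), ]
  placement$species <- NA_character_
  unc <- !placement$cultured
  placement$genus[unc] <- NA_character_
  placement$family[unc] <- NA_character_
  placement$order[unc] <- NA_character_
  write_tsv(placement[, c("genome_id", TAX_RANKS)], p("placement.tsv"))

  meta <- data.frame(sample_id = sprintf("SAMPLE%02d", seq_len(n_samples)),
                     continent = CONTINENTS[(seq_len(n_samples) - 1) %%
                                              length(CONTINENTS) + 1],
                     stringsAsFactors = FALSE)
  write_tsv(meta, p("metadata.tsv"))

  # labelled tree over the species representatives (first strain of each)
  reps <- gs$truth$genome_id[!duplicated(gs$truth$species_id)]
  tree <- with_seed(sim_seed + 5L, ape::rtree(max(2L, length(reps))))
  tree$tip.label <- if (length(reps) >= 2) reps
                    else c(reps, "placeholder")[seq_along(tree$tip.label)]
  ape::write.tree(tree, p("tree.nwk"))
  ann <- merge(data.frame(genome_id = reps, stringsAsFactors = FALSE),
               merge(gs$truth[!duplicated(gs$truth$species_id),
                              c("genome_id", "species_id", "cultured")],
                     gs$lineages[, c("species_id", "phylum")],
                     by = "species_id"), by = "genome_id")
  ann$set <- ifelse(ann$cultured, "reference", "novel")
  write_tsv(ann[, c("genome_id", "set", "phylum")], p("tip_annotation.tsv"))

  invisible(list(dir = dir, genomes = p("genomes.fasta"), qc = p("qc.tsv"),
                 rna_hits = p("rna_hits.tsv"), trna = p("trna.tsv"),
                 species_truth = p("species_truth.tsv"),
                 lineages = p("lineages.tsv"),
                 presence_truth = p("presence_truth.tsv"),
                 depth = p("depth.tsv"),
                 protein_hits = p("protein_hits.tsv"),
                 subjects = p("subjects.tsv"),
                 placement = p("placement.tsv"),
                 metadata = p("metadata.tsv"), tree = p("tree.nwk"),
                 tip_annotation = p("tip_annotation.tsv")))
}

#' Locate a bundle's input files by their conventional names
#'
#' Builds the named path list [run_catalogue()] expects from a directory
#' laid out like the output of [simulate_bundle()]. Missing optional
#' files (reference genomes, depth summaries, metadata, tree) are simply
#' omitted.
#'
#' @param dir Directory containing the bundle.
#' @return Named list of existing file paths.
#' @export
bundle_paths <- function(dir) {
  files <- c(genomes = "genomes.fasta", qc = "qc.tsv",
             rna_hits = "rna_hits.tsv", trna = "trna.tsv",
             species_truth = "species_truth.tsv", lineages = "lineages.tsv",
             presence_truth = "presence_truth.tsv", depth = "depth.tsv",
             protein_hits = "protein_hits.tsv", subjects = "subjects.tsv",
             placement = "placement.tsv", metadata = "metadata.tsv",
             tree = "tree.nwk", tip_annotation = "tip_annotation.tsv",
             reference = "reference.fasta")
  out <- list(dir = dir)
  for (nm in names(files)) {
    path <- file.path(dir, files[[nm]])
    if (file.exists(path)) out[[nm]] <- path
  }
  for (need in c("genomes", "qc"))
    if (is.null(out[[need]]))
      stop(sprintf("bundle is missing %s under %s", files[[need]], dir),
           call. = FALSE)
  out
}

read_lineage_row <- function(row) {
  lin <- setNames(rep(NA_character_, length(TAX_RANKS)), TAX_RANKS)
  for (r in TAX_RANKS) {
    v <- row[[r]]
    if (!is.null(v) && !is.na(v) && nzchar(v)) lin[r] <- v
  }
  lin
}

#' Run the full catalogue-construction workflow
#'
#' Executes the end-to-end pipeline on an input bundle (as written by
#' [simulate_bundle()], or any files following the same schemas): QC
#' scoring and tiering, MinHash sketching, optional reference
#' assignment, Mash pre-clustering, per-tier species dereplication,
#' protein-hit taxonomy with UMGS flagging, presence/abundance calling
#' with geographic prevalence, and diversity statistics. All outputs
#' are tab-separated (plus a JSON manifest recording every threshold
#' and seed), and the run is byte-identical given identical inputs and
#' configuration.
#'
#' @param bundle Named list of input paths (see [simulate_bundle()]); a
#'   `reference` FASTA entry is optional and enables the assignment
#'   stage.
#' @param out_dir Output directory.
#' @param config From [catalogue_config()].
#' @return Invisibly, a list with the principal in-memory results:
#'   `mags`, `assignment`, `clusters`, `taxonomy`, `presence`,
#'   `prevalence`, `diversity`, `curve`, `fit`, `manifest`.
#' @export
run_catalogue <- function(bundle, out_dir, config = catalogue_config()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  o <- function(f) file.path(out_dir, f)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  log_counts <- list()

  # --- QC -------------------------------------------------------------
  mags <- stage("qc", {
    qc <- read_tsv(bundle$qc)
    rna <- if (!is.null(bundle$rna_hits)) read_tsv(bundle$rna_hits)
    trna <- if (!is.null(bundle$trna)) read_tsv(bundle$trna)
    score_mags(qc, rna, trna)
  })
  write_tsv(mags, o("mags.tsv"))
  log_counts$genomes_in <- nrow(mags)

  seqs <- stage("qc", {
    dna <- Biostrings::readDNAStringSet(bundle$genomes)
    names(dna) <- sub("\\s.*$", "", names(dna))
    setNames(as.character(dna), names(dna))
  })
  if (nrow(mags) == 0L) {
    warning("empty genome set: writing an empty catalogue")
    manifest <- c(config, log_counts)
    jsonlite::write_json(manifest, o("manifest.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    return(invisible(list(mags = mags, manifest = manifest)))
  }

  # --- sketches + optional reference assignment -----------------------
  sketches <- stage("sketch", lapply(names(seqs), function(id)
    sketch(seqs[[id]], id, k = config$k, s = config$sketch_size,
           hash_seed = config$hash_seed)))
  names(sketches) <- names(seqs)

  assignment <- NULL
  unassigned <- mags
  if (!is.null(bundle$reference)) {
    assignment <- stage("assign", {
      refs <- Biostrings::readDNAStringSet(bundle$reference)
      names(refs) <- sub("\\s.*$", "", names(refs))
      ref_seqs <- setNames(as.character(refs), names(refs))
      ref_sk <- lapply(names(ref_seqs), function(id)
        sketch(ref_seqs[[id]], id, k = config$k, s = config$sketch_size,
               hash_seed = config$hash_seed))
      all_seqs <- c(seqs, ref_seqs)
      do.call(rbind, lapply(mags$genome_id, function(gid) {
        a <- assign_to_reference(sketches[[gid]], ref_sk, all_seqs,
                                 min_ani = config$assign_min_ani,
                                 min_af = config$assign_min_af,
                                 fragment_length = config$fragment_length,
                                 min_identity = config$min_fragment_identity,
                                 anchor_k = config$anchor_k)
        data.frame(genome_id = gid, matched = a$matched,
                   ref_id = a$ref_id, mash_d = a$mash_d,
                   ani = a$comparison$ani, af_query = a$comparison$af_query,
                   stringsAsFactors = FALSE)
      }))
    })
    write_tsv(assignment, o("assignment.tsv"))
    unassigned <- mags[!mags$genome_id %in%
                         assignment$genome_id[assignment$matched], ,
                       drop = FALSE]
  }
  log_counts$genomes_unassigned <- nrow(unassigned)

  # --- precluster + dereplicate per tier ------------------------------
  clusters <- stage("derep", {
    out <- list()
    for (tier in c("near_complete", "medium_quality")) {
      sub <- unassigned[unassigned$tier == tier, , drop = FALSE]
      if (tier == "medium_quality") sub <- sub[sub$qs50, , drop = FALSE]
      if (nrow(sub) == 0L) next
      d <- mash_dist_matrix(sketches[sub$genome_id])
      pc <- precluster(d, cutoff = config$precluster_cutoff,
                       method = config$linkage)
      cl <- dereplicate(sub, seqs, pc, tier = tier,
                        min_ani = config$derep_min_ani,
                        nc = if (tier == "near_complete")
                          config$nc_near_complete else config$nc_medium,
                        fragment_length = config$fragment_length,
                        min_identity = config$min_fragment_identity,
                        anchor_k = config$anchor_k)
      if (!is.null(cl) && nrow(cl)) {
        cl$tier <- tier
        cl$mgs_id <- paste0(cl$mgs_id, if (tier == "medium_quality") "m" else "")
        out[[tier]] <- cl
      }
    }
    do.call(rbind, out)
  })
  rownames(clusters) <- NULL
  write_tsv(clusters, o("mgs_clusters.tsv"))
  reps <- clusters$genome_id[clusters$is_representative]
  log_counts$mgs <- length(reps)

  # --- taxonomy -------------------------------------------------------
  taxonomy <- stage("classify", {
    hits <- read_tsv(bundle$protein_hits)
    subjects <- read_tsv(bundle$subjects)
    placement <- read_tsv(bundle$placement)
    hits$genus <- subjects$genus[match(hits$subject_name,
                                       subjects$subject_name)]
    do.call(rbind, lapply(reps, function(gid) {
      h <- hits[hits$genome_id == gid, , drop = FALSE]
      np <- max(1L, length(unique(h$protein_id)))
      sp <- species_call(h, np,
                         min_fraction = config$species_min_fraction,
                         min_identity = config$species_min_identity,
                         min_coverage = config$species_min_coverage)
      gn <- genus_call(h, np,
                       min_fraction = config$genus_min_fraction,
                       max_evalue = config$genus_max_evalue,
                       min_identity = config$genus_min_identity,
                       min_coverage = config$genus_min_coverage)
      pl_row <- placement[placement$genome_id == gid, , drop = FALSE]
      pl <- if (nrow(pl_row)) read_lineage_row(pl_row[1, ])
            else setNames(rep(NA_character_, 7), TAX_RANKS)
      sp_arg <- NULL; cultured <- FALSE
      if (!is.null(sp)) {
        srow <- subjects[subjects$subject_name == sp$subject, , drop = FALSE]
        sp_arg <- list(subject = sp$subject,
                       lineage = read_lineage_row(srow[1, ]))
        cultured <- is_cultured_name(sp$subject)
      }
      gn_arg <- NULL
      if (!is.null(gn)) {
        grow <- subjects[subjects$genus == gn$genus, , drop = FALSE]
        g_lin <- read_lineage_row(grow[1, ])
        g_lin["species"] <- NA_character_
        gn_arg <- list(genus = gn$genus, lineage = g_lin)
      }
      res <- resolve_lineage(pl, sp_arg, gn_arg, cultured)
      out <- data.frame(genome_id = gid,
                        mgs_id = clusters$mgs_id[match(gid, clusters$genome_id)],
                        stringsAsFactors = FALSE)
      for (r in TAX_RANKS) out[[r]] <- res$lineage[[r]]
      out$umgs <- res$umgs
      out$needs_review <- res$needs_review
      out$unresolvable <- res$unresolvable
      out
    }))
  })
  write_tsv(taxonomy, o("taxonomy.tsv"))
  log_counts$umgs <- sum(taxonomy$umgs, na.rm = TRUE)

  # --- presence / abundance / prevalence ------------------------------
  presence <- prevalence <- NULL
  if (!is.null(bundle$depth)) {
    presence <- stage("presence", {
      depth <- read_tsv(bundle$depth)
      depth <- depth[depth$genome_id %in% reps, , drop = FALSE]
      call_presence(depth, min_coverage = config$presence_min_coverage,
                    percentile = config$presence_percentile)
    })
    write_tsv(presence, o("presence_calls.tsv"))
    log_counts$present_pairs <- sum(presence$present)
    if (!is.null(bundle$metadata)) {
      prevalence <- stage("presence", {
        meta <- read_tsv(bundle$metadata)
        prevalence_summary(presence, meta,
                           min_abund = config$min_abundance,
                           region_frac = config$region_fraction)
      })
      write_tsv(prevalence$flags, o("prevalence_flags.tsv"))
    }
  }

  # --- diversity ------------------------------------------------------
  diversity <- curve <- fit <- NULL
  if (!is.null(bundle$tree)) {
    diversity <- stage("diversity", {
      ann <- read_tsv(bundle$tip_annotation)
      tree <- as_phylo(bundle$tree)
      baseline <- ann$genome_id[ann$set == "reference"]
      groups <- setNames(ann$phylum, ann$genome_id)
      if (length(intersect(baseline, tree$tip.label)) == 0L)
        list(pd_all = pd_total(tree), pd_baseline = NA_real_,
             increase_pct = NA_real_)
      else pd_increase(tree, baseline, groups = groups)
    })
    div_tab <- data.frame(scope = "overall", pd_all = diversity$pd_all,
                          pd_baseline = diversity$pd_baseline,
                          increase_pct = diversity$increase_pct)
    if (!is.null(diversity$by_group))
      div_tab <- rbind(div_tab,
                       data.frame(scope = diversity$by_group$group,
                                  pd_all = diversity$by_group$pd_all,
                                  pd_baseline = diversity$by_group$pd_baseline,
                                  increase_pct = diversity$by_group$increase_pct))
    write_tsv(div_tab, o("diversity.tsv"))
  }
  if (!is.null(presence) && nrow(presence)) {
    curve <- stage("diversity", {
      det <- with(presence,
                  tapply(present, list(sample_id, genome_id), any))
      det[is.na(det)] <- FALSE
      accumulation_curve(det, n_boot = config$n_boot,
                         seed = child_seed(config$seed, "diversity"))
    })
    fit <- fit_asymptotic(curve)
    write_tsv(data.frame(x = curve$x, y_mean = curve$y_mean,
                         y_sd = curve$y_sd), o("accumulation_curve.tsv"))
    write_tsv(data.frame(Asym = fit$Asym, R0 = fit$R0, lrc = fit$lrc,
                         converged = fit$converged), o("asymptotic_fit.tsv"))
  }

  manifest <- c(config, log_counts)
  jsonlite::write_json(manifest, o("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  invisible(list(mags = mags, assignment = assignment, clusters = clusters,
                 taxonomy = taxonomy, presence = presence,
                 prevalence = prevalence, diversity = diversity,
                 curve = curve, fit = fit, manifest = manifest))
}
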