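test_that("cultured-name heuristic follows the token rules", {
  expect_true(is_cultured_name("Ruminococcus bromii"))
  expect_true(is_cultured_name("Alistipes putredinis DSM 17216"))
  expect_false(is_cultured_name("Lactobacillus sp. ABC-1"))
  expect_false(is_cultured_name("uncultured organism"))
  expect_false(is_cultured_name("Firmicutes bacterium CAG:110"))
  expect_false(is_cultured_name("Clostridium"))  # single word
  expect_false(is_cultured_name(""))
  # token match, not substring: 'bacterium' must be its own word
  expect_true(is_cultured_name("Bacteroides fragilis"))
})

test_that("species call flips exactly at the 60%/96%/80% boundaries", {
  expect_false(is.null(species_call(make_hits(60, 100), 100)))
  expect_null(species_call(make_hits(59, 100), 100))
  # identity boundary is inclusive at 96
  expect_false(is.null(species_call(make_hits(60, 100, identity = 96), 100)))
  expect_null(species_call(make_hits(60, 100, identity = 95.99), 100))
  # coverage boundary inclusive at 80
  expect_false(is.null(species_call(make_hits(60, 100, coverage = 80), 100)))
  expect_null(species_call(make_hits(60, 100, coverage = 79.9), 100))
  expect_null(species_call(make_hits(0, 1)[0, ], 100))  # empty table
})

test_that("species call picks the best qualifying subject", {
  h <- rbind(make_hits(80, 100, subject = "Best match"),
             make_hits(65, 100, subject = "Good match"))
  res <- species_call(h, 100)
  expect_equal(res$subject, "Best match")
  expect_equal(res$fraction, 0.8)
})

test_that("genus call flips at the 50%/40%/50%/1e-5 boundaries", {
  expect_false(is.null(genus_call(make_genus_hits(5, 10), 10)))
  expect_null(genus_call(make_genus_hits(4, 10), 10))
  # strict bounds: identity exactly 40 and coverage exactly 50 fail
  expect_null(genus_call(make_genus_hits(10, 10, identity = 40), 10))
  expect_null(genus_call(make_genus_hits(10, 10, coverage = 50), 10))
  # e-value exactly 1e-5 fails the strict '<'
  expect_null(genus_call(make_genus_hits(10, 10, evalue = 1e-5), 10))
  expect_false(is.null(genus_call(make_genus_hits(10, 10, evalue = 9e-6), 10)))
})

test_that("species and genus calls are monotone in qualifying hits", {
  set.seed(53)
  for (i in 1:20) {
    nq <- sample(60:90, 1)
    h <- make_hits(nq, 100)
    base <- species_call(h, 100)
    expect_false(is.null(base))
    # upgrade one non-qualifying protein to qualifying
    h2 <- h; k <- which(h2$identity < 96)[1]
    h2$identity[k] <- 99; h2$coverage[k] <- 95
    after <- species_call(h2, 100)
    expect_false(is.null(after))
    expect_gte(after$fraction, base$fraction)
  }
})

test_that("lineage resolution follows the adopt/keep/incongruence rules", {
  placement <- lineage(domain = "Bacteria", phylum = "Firmicutes",
                       class = "Clostridia")
  sp_lin <- lineage(domain = "Bacteria", phylum = "Firmicutes",
                    class = "Clostridia", order = "Eubacteriales",
                    family = "Oscillospiraceae", genus = "Ruminococcus",
                    species = "Ruminococcus bromii")
  # compatible cultured species match: adopt protein lineage
  res <- resolve_lineage(placement,
                         list(subject = "Ruminococcus bromii",
                              lineage = sp_lin), NULL, cultured_flag = TRUE)
  expect_false(res$umgs)
  expect_equal(res$lineage[["species"]], "Ruminococcus bromii")
  # incongruent protein lineage: keep placement, flag review
  bad_lin <- sp_lin; bad_lin[["class"]] <- "Bacteroidia"
  res2 <- resolve_lineage(placement,
                          list(subject = "x", lineage = bad_lin), NULL,
                          cultured_flag = TRUE)
  expect_true(res2$umgs)
  expect_true(res2$needs_review)
  expect_equal(res2$lineage[["class"]], "Clostridia")
  # no species hit, compatible genus hit: lineage deepened to genus, umgs
  g_lin <- sp_lin; g_lin[["species"]] <- NA_character_
  res3 <- resolve_lineage(placement, NULL,
                          list(genus = "Ruminococcus", lineage = g_lin))
  expect_true(res3$umgs)
  expect_equal(res3$lineage[["genus"]], "Ruminococcus")
  expect_true(is.na(res3$lineage[["species"]]))
  # placement below class rank: unresolvable, not an error
  shallow <- lineage(domain = "Bacteria", phylum = "Firmicutes")
  res4 <- resolve_lineage(shallow, NULL, NULL)
  expect_true(res4$unresolvable)
})

test_that("resolved lineages never contain rank gaps", {
  placement <- lineage(domain = "Bacteria", phylum = "Firmicutes",
                       class = "Clostridia")
  full <- lineage(domain = "Bacteria", phylum = "Firmicutes",
                  class = "Clostridia", order = "O", family = "F",
                  genus = "G", species = "G s")
  g_only <- full; g_only[["species"]] <- NA_character_
  cases <- list(
    resolve_lineage(placement, list(subject = "G s", lineage = full),
                    NULL, TRUE),
    resolve_lineage(placement, NULL, list(genus = "G", lineage = g_only)),
    resolve_lineage(placement, NULL, NULL))
  for (cs in cases) expect_false(magcat:::lineage_has_gap(cs$lineage))
  expect_error(lineage(domain = "Bacteria", genus = "G"), "gap")
})

test_that("name normalization strips Candidatus and case for compatibility", {
  a <- lineage(domain = "Bacteria", phylum = "Candidatus Saccharibacteria",
               class = "X")
  b <- lineage(domain = "bacteria", phylum = "saccharibacteria",
               class = "x", order = "O", family = "F", genus = "G")
  expect_true(magcat:::lineage_compatible(a, b))
})

test_that("12-column alignment tables are parsed with configurable coverage", {
  path <- tempfile(fileext = ".tsv")
  rows <- data.frame(q = "p1", s = "subj1", pid = 97.5, len = 80,
                     mm = 2, go = 0, qs = 1, qe = 80, ss = 1, se = 80,
                     ev = 1e-40, bs = 150)
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  lens <- data.frame(id = c("p1", "subj1"), length = c(100, 90))
  sub_cov <- read_protein_hits(path, lens, coverage_on = "subject")
  expect_equal(sub_cov$coverage, 100 * 80 / 90)
  q_cov <- read_protein_hits(path, lens, coverage_on = "query")
  expect_equal(q_cov$coverage, 80)
  expect_equal(sub_cov$identity, 97.5)
})

test_that("noise-free synthetic protein tables reproduce planted status", {
  gs <- simulate_genome_set(4, 1, 0.01, 1000, n_uncultured = 2, seed = 61)
  ph <- simulate_protein_hits(gs$truth, gs$lineages, n_proteins = 100,
                              noise = 0, seed = 62)
  ph$hits$genus <- ph$subjects$genus[match(ph$hits$subject_name,
                                           ph$subjects$subject_name)]
  for (gid in gs$truth$genome_id) {
    h <- ph$hits[ph$hits$genome_id == gid, ]
    cultured <- gs$truth$cultured[gs$truth$genome_id == gid]
    sp <- species_call(h, 100)
    gn <- genus_call(h, 100)
    if (cultured) {
      expect_false(is.null(sp))
      expect_true(is_cultured_name(sp$subject))
    } else {
      expect_null(sp)         # identities planted below 96
      expect_false(is.null(gn))  # same-genus hits qualify
    }
  }
})
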