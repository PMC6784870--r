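test_that("fragment ANI recovers identity, containment and planted divergence", {
  set.seed(3)
  ref <- rand_dna(20000)
  self <- fragment_ani(ref, ref)
  expect_equal(self$ani, 100)
  expect_equal(self$af_query, 100)
  # containment: query is the first half of the reference
  half <- substr(ref, 1, 10000)
  cmp <- fragment_ani(half, ref)
  expect_equal(cmp$ani, 100)
  expect_equal(cmp$af_query, 100)
  expect_equal(cmp$af_ref, 50, tolerance = 0.02)
  expect_equal(cmp$af_larger, cmp$af_ref)  # ref is the larger genome
  # planted divergence 0.05: ANI within 3 binomial se of 95
  L <- 50000
  anc <- rand_dna(L)
  strain <- mutate_seq(anc, 0.05)
  est <- fragment_ani(strain, anc)
  se <- sqrt(0.05 * 0.95 / L)
  expect_lt(abs(est$ani / 100 - 0.95), 3 * se)
  # near-symmetry on mutation-only pairs
  est2 <- fragment_ani(anc, strain)
  expect_lt(abs(est$ani - est2$ani), 1)
  expect_error(fragment_ani("", "ACGT"), "empty")
})

test_that("a query shorter than the fragment length is a single fragment", {
  set.seed(11)
  ref <- rand_dna(5000)
  cmp <- fragment_ani(substr(ref, 100, 500), ref, fragment_length = 1000)
  expect_equal(cmp$n_fragments, 1L)
  expect_equal(cmp$af_query, 100)
})

test_that("reference assignment applies the 60% AF / 95% ANI rule", {
  set.seed(19)
  L <- 30000
  refs <- setNames(lapply(1:3, function(i) rand_dna(L)), paste0("ref", 1:3))
  ref_sk <- lapply(names(refs), function(id) sketch(refs[[id]], id))
  # identical query matches its reference
  q_same <- refs[["ref2"]]
  seqs <- c(refs, query = q_same)
  a <- assign_to_reference(sketch(q_same, "query"), ref_sk, seqs)
  expect_true(a$matched)
  expect_equal(a$ref_id, "ref2")
  # planted ANI ~99, full AF: accepted
  q99 <- mutate_seq(refs[["ref1"]], 0.01)
  a99 <- assign_to_reference(sketch(q99, "query"), ref_sk,
                             c(refs, query = q99))
  expect_true(a99$matched)
  expect_equal(a99$ref_id, "ref1")
  # planted ANI ~90: best match found but below the ANI threshold
  q90 <- mutate_seq(refs[["ref1"]], 0.10)
  a90 <- assign_to_reference(sketch(q90, "query"), ref_sk,
                             c(refs, query = q90))
  expect_false(a90$matched)
  # high-ANI but low-AF construction: 40% from the reference, 60% padding
  q40 <- paste0(substr(refs[["ref1"]], 1, 0.4 * L), rand_dna(0.6 * L))
  a40 <- assign_to_reference(sketch(q40, "query"), ref_sk,
                             c(refs, query = q40))
  expect_false(a40$matched)
  expect_lt(a40$comparison$af_query, 60)
  expect_error(assign_to_reference(sketch(q_same, "q"), list(), seqs),
               "empty reference")
})

make_qc <- function(ids, qs) {
  data.frame(genome_id = ids, qs = qs,
             completeness = pmin(100, qs + 2), contamination = 0.4,
             genome_length = NA_integer_, stringsAsFactors = FALSE)
}

test_that("dereplication collapses strains and keeps the best-QS representative", {
  set.seed(29)
  anc <- rand_dna(30000)
  seqs <- c(A = mutate_seq(anc, 0.005), B = anc, C = rand_dna(30000))
  qc <- make_qc(c("A", "B", "C"), qs = c(80, 60, 70))
  qc$genome_length <- nchar(seqs[qc$genome_id])
  pc <- setNames(c(1L, 1L, 2L), c("A", "B", "C"))
  cl <- dereplicate(qc, seqs, pc, tier = "near_complete")
  expect_equal(length(unique(cl$mgs_id)), 2L)
  ab <- cl[cl$genome_id %in% c("A", "B"), ]
  expect_equal(unique(ab$representative_id), "A")  # QS 80 beats 60
  # single MAG is its own representative
  one <- dereplicate(make_qc("X", 70), c(X = anc),
                     setNames(1L, "X"), tier = "near_complete")
  expect_true(one$is_representative)
  # two genomes at ~90% ANI stay separate (below the 95% boundary)
  far <- c(P = anc, Q = mutate_seq(anc, 0.10))
  cl2 <- dereplicate(make_qc(c("P", "Q"), c(75, 60)), far,
                     setNames(c(1L, 1L), c("P", "Q")),
                     tier = "near_complete")
  expect_equal(length(unique(cl2$mgs_id)), 2L)
})

test_that("near-complete dereplication excludes contaminated candidates", {
  set.seed(37)
  anc <- rand_dna(20000)
  qc <- make_qc(c("A", "B"), c(80, 60))
  qc$contamination <- c(6, 1)  # A exceeds the 5% gate
  seqs <- c(A = anc, B = mutate_seq(anc, 0.005))
  cl <- dereplicate(qc, seqs, setNames(c(1L, 1L), c("A", "B")),
                    tier = "near_complete")
  expect_false("A" %in% cl$genome_id)
  expect_equal(cl$representative_id, "B")
})

test_that("planted species structure is recovered as a partition", {
  gs <- simulate_genome_set(4, 3, divergence = 0.01, genome_length = 20000,
                            seed = 101)
  qc <- simulate_mag_qc(gs$truth, 20000, seed = 102)
  qc <- cbind(qc, classify_tier(qc$completeness, qc$contamination))
  sk <- lapply(names(gs$sequences), function(id) sketch(gs$sequences[[id]], id))
  pc <- precluster(mash_dist_matrix(sk))
  cl <- dereplicate(qc, gs$sequences, pc, tier = "near_complete")
  # partition: disjoint and covering
  expect_setequal(cl$genome_id, gs$truth$genome_id)
  expect_false(any(duplicated(cl$genome_id)))
  # exactly the planted species, members grouped with their own species
  expect_equal(length(unique(cl$mgs_id)), 4L)
  grouping <- gs$truth$species_id[match(cl$genome_id, gs$truth$genome_id)]
  expect_true(all(tapply(grouping, cl$mgs_id,
                         function(x) length(unique(x)) == 1)))
  # representatives of distinct clusters never satisfy the merge rule
  reps <- cl$genome_id[cl$is_representative]
  for (i in seq_along(reps)[-length(reps)]) for (j in seq(i + 1, length(reps))) {
    cmp <- fragment_ani(gs$sequences[[reps[i]]], gs$sequences[[reps[j]]])
    expect_false(!is.na(cmp$ani) && cmp$ani >= 95 && cmp$af_larger >= 60)
  }
})

test_that("cluster MCC matches the hand-built 5-genome instance and conventions", {
  # TP=4, FP=1, FN=1, TN=4 -> (16 - 1) / sqrt(5^4) = 0.6
  expect_equal(magcat:::mcc_from_counts(4, 1, 1, 4), 0.6)
  ids <- paste0("g", 1:4)
  aai <- matrix(100, 4, 4, dimnames = list(ids, ids))
  cl <- setNames(c(1, 1, 2, 2), ids)
  # perfect agreement: same-cluster pairs high, cross pairs low
  aai[1:2, 3:4] <- aai[3:4, 1:2] <- 80
  expect_equal(cluster_mcc(cl, aai, 95), 1)
  # all one cluster, all AAI above threshold: denominator 0 -> 0
  expect_equal(cluster_mcc(setNames(rep(1, 4), ids),
                           matrix(99, 4, 4, dimnames = list(ids, ids)), 95), 0)
  expect_error(cluster_mcc(cl, aai, 0), "threshold")
  expect_error(cluster_mcc(cl, aai, 101), "threshold")
})

test_that("cluster MCC equals brute-force pair enumeration on random instances", {
  set.seed(43)
  for (i in 1:60) {
    n <- sample(3:12, 1)
    ids <- paste0("g", seq_len(n))
    cl <- setNames(sample(1:3, n, replace = TRUE), ids)
    aai <- matrix(runif(n * n, 70, 100), n, n, dimnames = list(ids, ids))
    aai[lower.tri(aai)] <- t(aai)[lower.tri(aai)]
    diag(aai) <- 100
    t <- sample(c(90, 95, 97), 1)
    expect_equal(cluster_mcc(cl, aai, t), brute_mcc(cl, aai, t),
                 tolerance = 1e-12)
  }
})
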