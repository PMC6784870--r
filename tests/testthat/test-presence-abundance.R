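test_that("penalty scores follow the printed formula", {
  expect_equal(unlist(penalty_scores(100, 50, 25)),
               c(depth_penalty = 0, variation_penalty = 0))
  expect_equal(penalty_scores(80, 1, 0.5)$depth_penalty, 0)  # ln(1) = 0
  p <- penalty_scores(80, 10, 5)
  expect_equal(p$depth_penalty, 20 * log(10))
  expect_equal(p$variation_penalty, 10)
  # zero mean depth: cv defined as 0, depth clamped to 1 before the log
  p0 <- penalty_scores(40, 0, 0)
  expect_equal(unlist(p0), c(depth_penalty = 0, variation_penalty = 0))
  expect_error(penalty_scores(120, 1, 1), "coverage")
})

test_that("penalties are non-negative and weakly decreasing in coverage", {
  set.seed(71)
  for (i in 1:100) {
    cov <- sort(runif(2, 0, 100))
    md <- runif(1, 0, 50); sdd <- runif(1, 0, 30)
    lo <- penalty_scores(cov[1], md, sdd)
    hi <- penalty_scores(cov[2], md, sdd)
    expect_gte(lo$depth_penalty, 0)
    expect_gte(lo$variation_penalty, 0)
    expect_lte(hi$depth_penalty, lo$depth_penalty)
    expect_lte(hi$variation_penalty, lo$variation_penalty)
  }
})

test_that("presence requires 60% coverage regardless of penalties", {
  tab <- data.frame(genome_id = paste0("g", 1:3),
                    sample_id = "s1",
                    coverage = c(100, 50, 80),
                    mean_depth = c(10, 1, 10),
                    sd_depth = c(1, 0, 2))
  calls <- call_presence(tab)
  expect_true(calls$present[1])
  expect_false(calls$present[2])  # coverage 50 is an absolute veto
  # single perfect row: penalties 0 pass any threshold
  one <- call_presence(tab[1, ])
  expect_true(one$present)
})

test_that("percentile thresholding bounds the number of exceeding rows", {
  set.seed(73)
  n <- 500
  tab <- data.frame(genome_id = sprintf("g%03d", 1:n), sample_id = "s",
                    coverage = runif(n, 1, 100),
                    mean_depth = runif(n, 0, 50),
                    sd_depth = runif(n, 0, 40))
  calls <- call_presence(tab, percentile = 99)
  thr <- attr(calls, "thresholds")
  # type-7 99th percentile: at most ceiling(1% of n) rows exceed it
  expect_lte(sum(calls$depth_penalty > thr$depth), ceiling(0.01 * n))
  expect_lte(sum(calls$variation_penalty > thr$variation), ceiling(0.01 * n))
  # fixed thresholds bypass the percentile machinery
  fixed <- call_presence(tab, thresholds = list(depth = 1e9, variation = 1e9))
  expect_true(all(fixed$present == (fixed$coverage >= 60)))
})

test_that("relative abundance is the unique-proper-pair fraction", {
  expect_equal(relative_abundance(0, 1000), 0)
  expect_equal(relative_abundance(1000, 1000), 1)
  expect_equal(relative_abundance(25, 100000), 2.5e-4)
  expect_gt(relative_abundance(25, 100000), 1e-4)  # passes the 0.01% filter
  expect_error(relative_abundance(5, 0), "positive")
  expect_error(relative_abundance(10, 5), "unique_proper_pairs")
})

test_that("synthetic presence calls match planted truth", {
  pt <- simulate_presence_truth(sprintf("g%02d", 1:20), n_samples = 25,
                                seed = 79)
  depth <- simulate_depth_summaries(pt, seed = 80)
  calls <- call_presence(depth)
  m <- merge(calls, pt, by = c("genome_id", "sample_id"))
  expect_gte(mean(m$present.x == m$present.y), 0.99)
  # per-sample abundance sums stay below 1
  ab <- tapply(calls$rel_abundance, calls$sample_id, sum)
  expect_true(all(ab <= 1))
})

test_that("absent genomes essentially never reach 60% coverage", {
  pt <- data.frame(genome_id = sprintf("a%04d", 1:1000),
                   sample_id = "s1", present = FALSE, true_abundance = 0)
  depth <- simulate_depth_summaries(pt, seed = 81)
  expect_gte(mean(depth$coverage < 60), 0.99)
})

test_that("present genomes approach full even coverage as dispersion -> 0", {
  pt <- data.frame(genome_id = sprintf("p%02d", 1:20), sample_id = "s1",
                   present = TRUE, true_abundance = 0.01)
  depth <- simulate_depth_summaries(pt, dispersion = 0, seed = 82)
  expect_true(all(depth$coverage == 100))
  expect_true(all(depth$sd_depth == 0))
  # determinism and the empty-table contract
  d2 <- simulate_depth_summaries(pt, dispersion = 0, seed = 82)
  expect_identical(depth, d2)
  expect_equal(nrow(simulate_depth_summaries(pt[0, ], seed = 1)), 0L)
})

test_that("prevalence summary computes region counts and geography flags", {
  samples <- sprintf("s%02d", 1:12)
  conts <- rep(c("Africa", "Asia", "Europe", "North America",
                 "South America", "Oceania"), 2)
  meta <- data.frame(sample_id = samples, continent = conts)
  calls <- expand.grid(genome_id = c("gA", "gB", "gC"),
                       sample_id = samples, stringsAsFactors = FALSE)
  # gA: everywhere at high abundance; gB: only Africa (3 of 2 samples);
  # gC: only Asia + Oceania at high abundance
  calls$present <- FALSE; calls$rel_abundance <- 0
  calls$present[calls$genome_id == "gA"] <- TRUE
  calls$rel_abundance[calls$genome_id == "gA"] <- 0.01
  sel_b <- calls$genome_id == "gB" &
    calls$sample_id %in% samples[conts == "Africa"]
  calls$present[sel_b] <- TRUE
  calls$rel_abundance[sel_b] <- 0.001
  sel_c <- calls$genome_id == "gC" &
    calls$sample_id %in% samples[conts %in% c("Asia", "Oceania")]
  calls$present[sel_c] <- TRUE
  calls$rel_abundance[sel_c] <- 0.02
  ps <- prevalence_summary(calls, meta)
  flags <- ps$flags
  expect_true(flags$global[flags$genome_id == "gA"])
  expect_false(flags$global[flags$genome_id == "gB"])
  expect_true(flags$non_west_only[flags$genome_id == "gB"])
  expect_true(flags$non_west_only[flags$genome_id == "gC"])
  expect_false(flags$non_west_only[flags$genome_id == "gA"])
  # common-in-region: 2 of 2 African samples > 20%
  expect_true(flags$common_in_Africa[flags$genome_id == "gB"])
  expect_equal(ps$counts["gB", "Africa"], 2L)
  expect_equal(ps$counts["gB", "Asia"], 0L)
  # unknown continent errors and names the sample
  bad <- meta; bad$continent[3] <- "Atlantis"
  expect_error(prevalence_summary(calls, bad), "s03")
})

test_that("detection below the abundance floor is excluded from region counts", {
  meta <- data.frame(sample_id = c("s1", "s2"),
                     continent = c("Africa", "Africa"))
  calls <- data.frame(genome_id = "g", sample_id = c("s1", "s2"),
                      present = TRUE, rel_abundance = c(1e-4, 2e-4))
  ps <- prevalence_summary(calls, meta)
  # strict '>': exactly 0.01% does not count
  expect_equal(ps$counts["g", "Africa"], 1L)
})
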