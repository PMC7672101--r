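# Clustered-mutation machinery. Oracles: hand genomes with enumerable
# context pools, the closed-form law of uniform spacings, hand-built
# simulation results with hand-checkable test statistics, and a brute-force
# re-implementation of cluster chaining.

.fake_sim <- function(counts, max_d) {
  structure(list(distance_counts = counts, n_mutations = sum(counts[1, ]),
                 positions = NULL, max_d = max_d), class = "sim_result")
}

test_that("sim_config validates its arguments", {
  r <- GenomicRanges::GRanges("c1", IRanges::IRanges(1, 100))
  expect_error(sim_config(r, 10, n_sim = 0, seed = 1), "n_sim")
  expect_error(sim_config(r, 10, max_d = 1, seed = 1), "max_d")
  cf <- sim_config(r, 10, seed = 1)
  expect_s3_class(cf, "sim_config")
  expect_equal(cf$context_mode, "tri")
})

test_that("context_spectrum counts reference contexts; edges drop out", {
  g <- c(c1 = "ACGTACGTAC")
  df <- data.frame(sample_id = "s", chrom = "c1", pos = c(2, 6, 1, 10, 5),
                   ref = c("C", "C", "A", "C", "A"),
                   alt = c("T", "T", "C", "T", "G"))
  ct <- mutation_catalog(df)
  sp <- context_spectrum(ct, g, "tri")
  # pos 2 and 6 both sit in ACG; pos 5 in TAC; pos 1 and 10 are edges
  expect_equal(sp[["ACG"]], 2L)
  expect_equal(sp[["TAC"]], 1L)
  expect_equal(sum(sp), 3L)
  expect_equal(context_spectrum(ct, g, "none"), 5L)
  sp5 <- context_spectrum(ct, g, "penta")
  expect_equal(sum(sp5), 2L)                 # pos 2 now too close to the edge
  expect_equal(sp5[["GTACG"]], 1L)           # pos 5
  expect_equal(sp5[["TACGT"]], 1L)           # pos 6
})

test_that("context_site_index enumerates per-context site pools exactly", {
  g <- c(c1 = "ACGTACGTAC")
  r <- GenomicRanges::GRanges("c1", IRanges::IRanges(1, 10))
  idx <- context_site_index(r, g, "tri")
  all_pos <- sort(unlist(idx, use.names = FALSE))
  expect_equal(all_pos, 2:9)                 # interior positions only
  expect_equal(sort(idx[["ACG"]]), c(2, 6))  # ACG centered at 2 and 6
  expect_equal(idx[["TAC"]], c(5, 9))
  # restricted region restricts the pools
  r2 <- GenomicRanges::GRanges("c1", IRanges::IRanges(4, 8))
  idx2 <- context_site_index(r2, g, "tri")
  expect_equal(sort(unlist(idx2, use.names = FALSE)), 4:8)
  # "none" mode pools everything under one key
  idx0 <- context_site_index(r, g, "none")
  expect_equal(sort(idx0[["*"]]), 1:10)
})

test_that("simulated replicates reproduce the context spectrum exactly", {
  set.seed(5)
  g <- c(c1 = paste(sample(c("A", "C", "G", "T"), 20000, replace = TRUE),
                    collapse = ""))
  r <- GenomicRanges::GRanges("c1", IRanges::IRanges(1, 20000))
  idx <- context_site_index(r, g, "tri")
  picks <- names(idx)[vapply(idx, length, integer(1)) >= 50][1:4]
  spectrum <- stats::setNames(c(15L, 7L, 3L, 12L), picks)
  cf <- sim_config(r, spectrum, n_sim = 3, max_d = 100, seed = 42)
  res <- simulate_random_catalog(cf, g)
  expect_equal(res$n_mutations, sum(spectrum))
  # replicate 1 positions carry exactly the requested context histogram
  ctx <- substring(g[["c1"]], res$positions - 1, res$positions + 1)
  expect_equal(as.integer(table(ctx)[picks]), as.integer(spectrum))
  # its distance tally matches a direct computation from the positions
  dd <- diff(sort(res$positions))
  expect_equal(res$distance_counts[1, ],
               tabulate(dd[dd >= 1 & dd <= 100], nbins = 100))
  # deterministic under the seed; site_index shortcut changes nothing
  res2 <- simulate_random_catalog(cf, g, site_index = idx)
  expect_identical(res$distance_counts, res2$distance_counts)
  # unattainable context is an error
  r0 <- GenomicRanges::GRanges("c1", IRanges::IRanges(1, 3))
  cfa <- sim_config(r0, stats::setNames(1L, "CCC"), seed = 1)
  expect_error(simulate_random_catalog(cfa, c(c1 = "ATATATAT")),
               "unattainable")
  expect_error(simulate_random_catalog(sim_config(r, c(3, 4), seed = 1), g),
               "single total")
})

test_that("context-free simulation follows the uniform-spacings law", {
  L <- 1e5; n <- 50
  g <- c(c1 = strrep("A", L))
  r <- GenomicRanges::GRanges("c1", IRanges::IRanges(1, L))
  cf <- sim_config(r, n, n_sim = 400, max_d = 2000, context_mode = "none",
                   seed = 77)
  res <- simulate_random_catalog(cf, g)
  # each of the n - 1 internal spacings satisfies P(S <= d) = 1 - (1 - d/L)^n;
  # mean count of spacings <= 1000 over replicates must match
  d0 <- 1000
  expected <- (n - 1) * (1 - (1 - d0 / L)^n)
  got <- mean(rowSums(res$distance_counts[, 1:d0]))
  expect_equal(got, expected, tolerance = 1 / expected)   # +- 1 pair
})

test_that("cross-chromosome pairs never enter the distance tallies", {
  g <- c(c1 = strrep("A", 1000), c2 = strrep("A", 1000))
  r <- GenomicRanges::GRanges(c("c1", "c2"), IRanges::IRanges(1, 1000))
  cf <- sim_config(r, 200, n_sim = 5, max_d = 10000, context_mode = "none",
                   seed = 3)
  res <- simulate_random_catalog(cf, g)
  # both chromosomes are populated (offsets of 1e9 mark the second)
  expect_true(any(res$positions > 1e9) && any(res$positions < 1e9))
  # no recorded distance can exceed a chromosome length
  expect_equal(sum(res$distance_counts[, 1000:10000]), 0)
})

test_that("observed_distances equals per-chromosome brute force", {
  set.seed(9)
  df <- data.frame(sample_id = "s",
                   chrom = sample(c("c1", "c2"), 200, replace = TRUE),
                   pos = sample(1:5000, 200), ref = "C", alt = "T")
  ct <- mutation_catalog(df)
  got <- sort(observed_distances(ct, max_d = 300))
  want <- sort(unlist(lapply(c("c1", "c2"), function(ch) {
    d <- diff(sort(df$pos[df$chrom == ch]))
    d[d <= 300]
  })))
  expect_equal(got, want)
  # cross-chromosome pair exclusion: interleaved positions, huge max_d
  df2 <- data.frame(sample_id = "s", chrom = c("a", "b"), pos = c(100, 105),
                    ref = "C", alt = "T")
  expect_length(observed_distances(mutation_catalog(df2), max_d = 1e6), 0)
  # single mutation yields nothing
  expect_length(observed_distances(mutation_catalog(df2[1, ]), 100), 0)
})

test_that("cluster_scan single-sample empirical p and effect CI by hand", {
  # one window: d in 2..6
  obs <- list(rep(2L, 6))                    # window total 6
  counts <- matrix(0L, 5, 10)
  counts[, 4] <- 1:5                         # replicate window totals 1..5
  sims <- list(.fake_sim(counts, 10))
  sc <- cluster_scan(obs, sims, window = 5, step = 1, range = c(2, 6))
  expect_equal(nrow(sc), 1)
  expect_equal(sc$observed, 6)
  expect_equal(sc$simulated_mean, 3)
  expect_equal(sc$effect_size, 2)
  # empirical two-sided p: (0 + 1)/6 above, doubled
  expect_equal(sc$p, 2 * (0 + 1) / (5 + 1))
  expect_equal(sc$p_bonferroni, sc$p)
  # percentile CI of the replicate totals 1..5 (type-7 quantiles 1.1, 4.9)
  expect_equal(sc$effect_ci_low, 6 / 4.9)
  expect_equal(sc$effect_ci_high, 6 / 1.1)
})

test_that("cluster_scan marks windows with no observed pairs as NA", {
  obs <- list(c(2L, 2L))                     # only distance 2 observed
  counts <- matrix(0L, 4, 12)
  counts[, 2] <- 3L                          # simulations also only at d = 2
  sims <- list(.fake_sim(counts, 12))
  sc <- cluster_scan(obs, sims, window = 5, step = 1, range = c(2, 8))
  expect_equal(sc$d, 2:4)
  expect_false(is.na(sc$p[1]))               # window 2..6 holds the 2 pairs
  expect_true(is.na(sc$p[2]))                # 3..7: nothing observed
  expect_true(is.na(sc$p[3]))
  expect_true(is.na(sc$p_bonferroni[2]))
  # simulated mass outside the window: effect columns NA there
  expect_true(is.na(sc$effect_size[3]))
})

test_that("cluster_scan multi-sample p is the exact signed-rank by hand", {
  # three samples, one window (d = 2..6), observed - simulated differences
  # planted as (2, 3, 1): all positive, p = 2/2^3
  obs <- list(rep(2L, 4), rep(3L, 5), rep(4L, 3))
  mk <- function(total) {
    m <- matrix(0L, 6, 10); m[, 2] <- total; m
  }
  sims <- list(.fake_sim(mk(2L), 10), .fake_sim(mk(2L), 10),
               .fake_sim(mk(2L), 10))
  sc <- cluster_scan(obs, sims, window = 5, step = 1, range = c(2, 6))
  diffs <- c(4 - 2, 5 - 2, 3 - 2)
  expect_equal(sc$p, wilcoxon_signed_rank_exact(diffs))
  expect_equal(sc$p, 2 / 2^3)
  expect_equal(sc$observed, 12)
  expect_equal(sc$simulated_mean, 6)
  expect_equal(sc$effect_size, 2)
  # pairing errors
  expect_error(cluster_scan(obs[1:2], sims), "pair up")
  expect_error(cluster_scan(obs, sims, range = c(2, 50)),
               "do not cover")
})

test_that("cluster_scan window grid covers range - window + 1 starts", {
  obs <- list(sample(2:40, 30, replace = TRUE))
  counts <- matrix(1L, 3, 50)
  sc <- cluster_scan(obs, list(.fake_sim(counts, 50)), window = 5,
                     range = c(2, 46))
  expect_equal(sc$d, 2:42)
  expect_equal(nrow(sc), 41)
})

test_that("cluster_membership matches hand chains and brute force", {
  df <- data.frame(sample_id = "s", chrom = "c1",
                   pos = c(10, 20, 120, 130, 135, 500),
                   ref = "C", alt = "T")
  cm <- cluster_membership(mutation_catalog(df), max_gap = 16)
  expect_equal(nrow(cm), 2)
  expect_equal(cm$start, c(10, 120))
  expect_equal(cm$end, c(20, 135))
  expect_equal(cm$size, c(2L, 3L))
  expect_equal(cm$mean_gap, c(10, 7.5))
  # chromosomes never chain together
  df2 <- data.frame(sample_id = "s", chrom = c("a", "b"), pos = c(5, 10),
                    ref = "C", alt = "T")
  expect_equal(nrow(cluster_membership(mutation_catalog(df2), 100)), 0)
  # brute-force oracle on 1000 random positions
  set.seed(17)
  pos <- sort(sample(1:50000, 1000))
  df3 <- data.frame(sample_id = "s", chrom = "c1", pos = pos,
                    ref = "C", alt = "T")
  cm3 <- cluster_membership(mutation_catalog(df3), max_gap = 16)
  # independent chaining: split at gaps > 16, keep runs of length >= 2
  runs <- split(pos, cumsum(c(1, as.integer(diff(pos) > 16))))
  runs <- runs[vapply(runs, length, integer(1)) >= 2]
  expect_equal(nrow(cm3), length(runs))
  expect_equal(cm3$start, unname(vapply(runs, min, numeric(1))))
  expect_equal(cm3$end, unname(vapply(runs, max, numeric(1))))
  expect_equal(cm3$size, unname(vapply(runs, length, integer(1))))
})

test_that("planted clusters in the generator are recovered by chaining", {
  scene <- scene_small()
  tracks <- tracks_small()
  ctl <- make_catalog(scene, tracks,
                      mutagenesis_spec(n_samples = 1, n_sbs = 500,
                                       cluster_fraction = 0.2,
                                       cluster_max_gap = 12, seed = 31))
  planted <- ctl[ctl$xsim_cluster > 0, ]
  ids <- table(planted$xsim_cluster)
  pairs <- names(ids)[ids == 2]
  expect_gt(length(pairs), 40)               # 50 planted, few lost to context
  # every surviving planted pair spans at most the configured gap
  for (k in pairs) {
    p <- planted$pos[planted$xsim_cluster == as.integer(k)]
    expect_lte(diff(range(p)), 12)
  }
  cm <- cluster_membership(ctl, max_gap = 12)
  expect_gt(nrow(cm), 0.8 * length(pairs))
})
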