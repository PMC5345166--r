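# Generators: distributional behaviour, degenerate cases, reproducibility.

test_that("simulated totals and fractions match the diploid (2,2) model", {
  n <- 400
  sc <- sim_scenario(n, segments_single(n, 2, 2), mean_depth = 200, seed = 11)
  sim <- simulate_mip_counts(sc)
  tot <- as.vector(sim$counts$reads_A + sim$counts$reads_B)
  expect_lt(abs(mean(tot) - 200), 3 * sqrt(200 / n))
  fA <- sum(sim$counts$reads_A) / sum(tot)
  expect_lt(abs(fA - 0.5), 3 * sqrt(0.25 / sum(tot)))
})

test_that("a (4,0) state with zero mismapping yields only paralog-A reads", {
  sc <- sim_scenario(50, segments_single(50, 4, 0), mismap_rate = 0, seed = 2)
  sim <- simulate_mip_counts(sc)
  expect_true(all(sim$counts$reads_B == 0))
  expect_gt(sum(sim$counts$reads_A), 0)
})

test_that("copy-neutral exchange keeps depth flat but shifts the A-fraction", {
  n <- 300
  sc <- sim_scenario(n, segments_event(n, 2, 2, 100, 200, 3, 1),
                     mean_depth = 200, mismap_rate = 0.01, seed = 3)
  sim <- simulate_mip_counts(sc)
  tot <- as.vector(sim$counts$reads_A + sim$counts$reads_B)
  fA <- as.vector(sim$counts$reads_A) / tot
  mid <- 101:200
  flank <- c(1:100, 201:300)
  # depth invariant under copy-neutral exchange: both segments Poisson(200)
  se <- sqrt(200 / 100) * sqrt(2)
  expect_lt(abs(mean(tot[mid]) - mean(tot[flank])), 4 * se)
  # expected fractions from the mismap mixture, by direct evaluation
  f_mid <- 0.75 * (1 - 0.02) + 0.01
  f_flank <- 0.5
  expect_lt(abs(mean(fA[mid]) - f_mid), 0.02)
  expect_lt(abs(mean(fA[flank]) - f_flank), 0.02)
  expect_gt(mean(fA[mid]), mean(fA[flank]) + 0.2)
})

test_that("the empirical A-fraction converges to the mismap-adjusted truth", {
  sc <- sim_scenario(20, segments_single(20, 3, 1), mean_depth = 1e5,
                     mismap_rate = 0.01, seed = 4)
  sim <- simulate_mip_counts(sc)
  fA <- sum(sim$counts$reads_A) / sum(sim$counts$reads_A + sim$counts$reads_B)
  expect_equal(fA, 0.75 * (1 - 0.02) + 0.01, tolerance = 1e-3)
})

test_that("overdispersion inflates total-count variance as Var = mu + od*mu^2", {
  n <- 4000
  sc0 <- sim_scenario(n, segments_single(n, 2, 2), mean_depth = 200,
                      overdispersion = 0, seed = 5)
  sc1 <- sim_scenario(n, segments_single(n, 2, 2), mean_depth = 200,
                      overdispersion = 0.05, seed = 5)
  t0 <- as.vector(simulate_mip_counts(sc0)$counts$reads_A +
                    simulate_mip_counts(sc0)$counts$reads_B)
  t1 <- as.vector(simulate_mip_counts(sc1)$counts$reads_A +
                    simulate_mip_counts(sc1)$counts$reads_B)
  expect_lt(var(t0), 1.3 * 200)
  expect_gt(var(t1), 0.7 * (200 + 0.05 * 200^2))
  expect_lt(var(t1), 1.3 * (200 + 0.05 * 200^2))
})

test_that("generators are bit-reproducible given a seed", {
  sc <- sim_scenario(30, segments_single(30, 2, 2), seed = 99)
  expect_identical(simulate_mip_counts(sc), simulate_mip_counts(sc))
  ev <- evo_scenario(t_dup = 2, seq_len = 500, seed = 42)
  expect_identical(simulate_k2p_quartet(ev), simulate_k2p_quartet(ev))
  specs <- data.frame(pos = 5, ref = "A", alt = "T", paralog = "unassigned",
                      effect = "missense", freq = 0.1, dropout = 0.1)
  expect_identical(simulate_cohort_variants(50, 50, specs, seed = 7),
                   simulate_cohort_variants(50, 50, specs, seed = 7))
})

test_that("a whole-locus zero-copy scenario collapses depth with a warning", {
  sc <- sim_scenario(10, segments_single(10, 0, 0), seed = 1)
  expect_warning(sim <- simulate_mip_counts(sc), "copy number 0")
  expect_true(all(sim$counts$reads_A + sim$counts$reads_B == 0))
})

test_that("quartet with zero substitution rate gives identical sequences", {
  sc <- evo_scenario(t_dup = 3, subs_rate = 0, seq_len = 200, seed = 1)
  aln <- simulate_k2p_quartet(sc)
  expect_equal(nrow(unique(aln)), 1L)
})

test_that("equal-rate quartets show transition:transversion counts near 1:2", {
  sc <- evo_scenario(t_dup = 3, t_out = 30, subs_rate = 4e-3, kappa = 0.5,
                     seq_len = 2e5, seed = 6)
  aln <- simulate_k2p_quartet(sc)
  d <- k2p_distance(aln, c("paralogA", "orang"))
  expect_equal(d$P / d$Q, 0.5, tolerance = 0.08)
})

test_that("dating recovers a mid-branch duplication ratio of one half", {
  sc <- evo_scenario(t_dup = 3, t_cc = 6, seq_len = 3e5, seed = 8)
  aln <- simulate_k2p_quartet(sc)
  res <- date_duplication(aln, n_boot = 100, seed = 8)
  expect_equal(res$t_hat / res$t_cc, 0.5, tolerance = 0.06)
})

test_that("cohort variant generator honours carrier frequencies", {
  specs0 <- data.frame(pos = 5, ref = "A", alt = "T", paralog = "unassigned",
                       effect = "missense", freq = 0, dropout = 0)
  sim0 <- simulate_cohort_variants(100, 100, specs0, seed = 1)
  expect_true(all(sim0$genotypes == "0/0"))
  expect_equal(sim0$truth$case_count + sim0$truth$control_count, 0)

  # mean recovered carrier count over seeds ~ 2598 * 0.0038 = 9.87
  specs <- data.frame(pos = 5, ref = "A", alt = "T", paralog = "unassigned",
                      effect = "frameshift", freq = 0.0038, dropout = 0)
  counts <- vapply(1:30, function(s) {
    simulate_cohort_variants(0, 2598, specs, seed = s)$truth$control_count
  }, numeric(1))
  expect_equal(mean(counts), 2598 * 0.0038, tolerance = 0.2)

  expect_error(
    simulate_cohort_variants(10, 10, transform(specs, freq = 1.2), seed = 1),
    "frequency")
})

test_that("complete genotyping dropout is flagged as undefined", {
  specs <- data.frame(pos = 5, ref = "A", alt = "T", paralog = "unassigned",
                      effect = "missense", freq = 0.5, dropout = 1)
  sim <- simulate_cohort_variants(20, 20, specs, seed = 1)
  expect_true(all(sim$genotypes == "./."))
  expect_true(sim$truth$undefined)
  expect_equal(sim$truth$cases_genotyped, 0)
})

test_that("count matrices and truth paths survive a disk round trip", {
  sim <- simulate_mip_counts(sim_scenario(25, segments_single(25, 2, 2),
                                          seed = 3))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_mip_counts(sim$counts, f)
  back <- read_mip_counts(f)
  expect_identical(back$reads_A, sim$counts$reads_A)
  expect_identical(back$reads_B, sim$counts$reads_B)
  j <- withr::local_tempfile(fileext = ".json")
  write_truth_json(sim$truth, j)
  expect_silent(jsonlite::read_json(j))
})
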