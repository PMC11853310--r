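test_that("a fixed seed reproduces byte-identical outputs", {
  cfg <- generator_config(seed = 21, n_reads_per_sample = 50)
  a <- simulate_feature_dataset(cfg)
  b <- simulate_feature_dataset(cfg)
  expect_identical(a, b)
  pa <- simulate_modprob_dataset(cfg, coverage = 20)
  pb <- simulate_modprob_dataset(cfg, coverage = 20)
  expect_identical(pa, pb)
  ca <- simulate_cooccurring_transcripts(5, 100, 0.3, 0.2, 0.2, seed = 3)
  cb <- simulate_cooccurring_transcripts(5, 100, 0.3, 0.2, 0.2, seed = 3)
  expect_identical(ca, cb)
})

test_that("epsilon above stoichiometry is rejected", {
  expect_error(generator_config(stoichiometry = 0.1, epsilon = 0.2),
               "epsilon")
})

test_that("realized modified fraction follows Binomial(coverage, s)", {
  cfg <- generator_config(seed = 31, n_reads_per_sample = 1000,
                          stoichiometry = 0.5, epsilon = 0,
                          n_kmers = 1, n_unaffected_kmers = 0,
                          n_sites_per_kmer = 1)
  sim <- simulate_feature_dataset(cfg)
  frac <- sim$truth %>%
    filter(sample == "treated") %>%
    summarise(f = mean(modified)) %>%
    pull(f)
  bounds <- qbinom(c(0.005, 0.995), 1000, 0.5) / 1000
  expect_gte(frac, bounds[1])
  expect_lte(frac, bounds[2])
  # control is unmodified under epsilon = 0
  expect_equal(sum(sim$truth$modified[sim$truth$sample == "control"]), 0)
})

test_that("modProb class medians hit their calibration targets", {
  cfg <- generator_config(seed = 41, stoichiometry = 1)
  withr::with_seed(41, {
    unmod <- rbeta(10000, cfg$modprob_unmod[1], cfg$modprob_unmod[2])
    mod <- rbeta(10000, cfg$modprob_mod[1], cfg$modprob_mod[2])
  })
  expect_lte(median(unmod), 0.01)
  expect_lt(abs(median(mod) - 0.7), 0.05)
})

test_that("co-occurrence generator preserves marginals for any rho", {
  for (rho in c(-0.1, 0, 0.3, 0.7)) {
    sim <- simulate_cooccurring_transcripts(
      n_transcripts = 1, coverage = 5000, fA = 0.3, fB = 0.2, rho = rho,
      seed = 5)
    bounds_A <- qbinom(c(0.005, 0.995), 5000, 0.3) / 5000
    bounds_B <- qbinom(c(0.005, 0.995), 5000, 0.2) / 5000
    expect_gte(mean(sim$truth$modified_A), bounds_A[1])
    expect_lte(mean(sim$truth$modified_A), bounds_A[2])
    expect_gte(mean(sim$truth$modified_B), bounds_B[1])
    expect_lte(mean(sim$truth$modified_B), bounds_B[2])
  }
})

test_that("rho = 0 gives joint modification at the product of marginals", {
  sim <- simulate_cooccurring_transcripts(
    n_transcripts = 1, coverage = 20000, fA = 0.2, fB = 0.1, rho = 0,
    seed = 7)
  joint <- mean(sim$truth$modified_A & sim$truth$modified_B)
  expect_equal(sim$pairs$p11[1], 0.02)
  expect_lt(abs(joint - 0.02), 3 * sqrt(0.02 * 0.98 / 20000))
})

test_that("the upper Frechet bound gives comonotone co-modification", {
  sim <- simulate_cooccurring_transcripts(
    n_transcripts = 1, coverage = 5000, fA = 0.1, fB = 0.1, rho = 1,
    seed = 9)
  expect_equal(mean(sim$truth$modified_A & sim$truth$modified_B),
               mean(sim$truth$modified_A))
  expect_error(
    simulate_cooccurring_transcripts(1, 100, fA = 0.2, fB = 0.1, rho = -0.9,
                                     seed = 1),
    "Frechet")
})

test_that("pool mixing draws exact counts without replacement", {
  cfg1 <- generator_config(seed = 51, stoichiometry = 1)
  cfg0 <- generator_config(seed = 51, stoichiometry = 0)
  pm <- simulate_modprob_dataset(cfg1, n_refs = 1, coverage = 300,
                                 read_prefix = "M_")
  pu <- simulate_modprob_dataset(cfg0, n_refs = 1, coverage = 4000,
                                 sequences = pm$sequences, sites = pm$sites,
                                 read_prefix = "U_")
  mx <- mix_pools(pm$calls, pu$calls, 0.0625, 4000, seed = 1)
  ids <- attr(mx, "sampled_ids")
  expect_length(ids$modified, 250)        # 4000 x 6.25%
  expect_length(ids$unmodified, 3750)
  expect_equal(anyDuplicated(c(ids$modified, ids$unmodified)), 0L)

  all_unm <- mix_pools(pm$calls, pu$calls, 0, 100, seed = 1)
  expect_false(any(all_unm$from_modified_pool))
  all_mod <- mix_pools(pm$calls, pu$calls, 1, 100, seed = 1)
  expect_true(all(all_mod$from_modified_pool))

  expect_error(mix_pools(pm$calls, pu$calls, 1, 5000, seed = 1), "deficit")
})

test_that("a null configuration yields null-distributed KS p-values across k-mers", {
  cfg <- generator_config(seed = 61, n_reads_per_sample = 40,
                          stoichiometry = 0, epsilon = 0,
                          n_kmers = 100, n_unaffected_kmers = 100,
                          n_sites_per_kmer = 1)
  sim <- simulate_feature_dataset(cfg)
  bal <- aggregate_by_kmer(sim$records, max_reads_per_position = 40, seed = 1)
  res <- ks_select_kmers(bal, features = "SI", alpha = 0.05, D_min = 0,
                         n_min = 30)
  expect_equal(nrow(res), 200)
  # With 40 reads per sample the exact two-sample KS p-value is discrete and
  # super-uniform, so compare against an independent oracle: p-values of
  # ks.test on iid normal pairs of the same size.
  oracle <- withr::with_seed(62, {
    replicate(2000, suppressWarnings(
      ks.test(rnorm(40), rnorm(40))$p.value))
  })
  ks <- suppressWarnings(ks.test(res$p, oracle))
  expect_gt(ks$p.value, 0.01)
  # and the p-values stay conservative: P(p <= alpha) <= alpha-ish
  expect_lte(mean(res$p <= 0.05), 0.05 + 3 * sqrt(0.05 * 0.95 / 200))
})
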