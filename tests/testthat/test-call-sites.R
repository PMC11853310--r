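test_that("binarization uses a closed inequality at the threshold", {
  expect_true(binarize(0.5, 0.5))
  expect_false(binarize(0.499, 0.5))
  expect_true(all(binarize(runif(100), 0)))
  expect_error(binarize(0.5, 1.5), "tau")
})

test_that("site calling applies the coverage and frequency gates", {
  s <- call_sites(make_site_calls(coverage = 25, n_modified = 2))
  expect_equal(s$frequency, 0.08)
  expect_true(s$passed)

  s1 <- call_sites(make_site_calls(coverage = 25, n_modified = 1))
  expect_equal(s1$frequency, 0.04)
  expect_false(s1$passed)

  s2 <- call_sites(make_site_calls(coverage = 24, n_modified = 24))
  expect_false(s2$passed)   # coverage gate despite 100% frequency
})

test_that("modified counts are non-increasing in tau; tau = 0 calls everything", {
  withr::with_seed(401, {
    calls <- make_site_calls(coverage = 100, n_modified = 40,
                             p_mod = runif(40, 0.5, 1),
                             p_unmod = runif(60, 0, 0.5))
    taus <- seq(0, 1, 0.05)
    nm <- vapply(taus, function(t) call_sites(calls, tau = t)$n_modified,
                 integer(1))
    expect_true(all(diff(nm) <= 0))
    expect_equal(call_sites(calls, tau = 0)$frequency, 1)
  })
})

test_that("the Youden optimum matches an exhaustive-scan oracle exactly", {
  withr::with_seed(402, {
    grid <- seq(0, 1, by = 0.01)
    for (i in 1:20) {
      m <- rbeta(200, 4, 2); u <- rbeta(200, 0.5, 10)
      scan <- youden_threshold(m, u, grid)
      # independent brute-force oracle
      J <- vapply(grid, function(t) mean(m >= t) - mean(u >= t), numeric(1))
      expect_equal(attr(scan, "J_star"), max(J))
      expect_equal(attr(scan, "tau_star"), grid[which(J == max(J))[1]])
    }
  })
})

test_that("perfect separation yields J = 1 in the gap; identical classes give J ~ 0", {
  m <- seq(0.6, 1, length.out = 100); u <- seq(0, 0.2, length.out = 100)
  scan <- youden_threshold(m, u)
  expect_equal(attr(scan, "J_star"), 1)
  expect_gt(attr(scan, "tau_star"), 0.2)
  expect_lte(attr(scan, "tau_star"), 0.6)

  withr::with_seed(403, {
    x <- runif(2000)
    scan0 <- youden_threshold(x, x)
    expect_equal(attr(scan0, "J_star"), 0)
  })
  expect_error(youden_threshold(numeric(0), runif(5)), "empty")
})

test_that("swapping the class labels preserves the attainable Youden index", {
  withr::with_seed(404, {
    m <- rbeta(1000, 4.3, 2); u <- rbeta(1000, 0.3, 30)
    direct <- attr(youden_threshold(m, u), "J_star")
    swapped <- attr(youden_threshold(1 - u, 1 - m), "J_star")
    expect_lt(abs(direct - swapped), 0.02)
  })
})

test_that("stoichiometry is recovered on in-silico mixtures", {
  cfg1 <- generator_config(seed = 405, stoichiometry = 1)
  cfg0 <- generator_config(seed = 405, stoichiometry = 0)
  pm <- simulate_modprob_dataset(cfg1, n_refs = 2, coverage = 400,
                                 n_sites_per_ref = 4, read_prefix = "M_")
  pu <- simulate_modprob_dataset(cfg0, n_refs = 2, coverage = 400,
                                 sequences = pm$sequences, sites = pm$sites,
                                 read_prefix = "U_")
  mixes <- lapply(c(0.25, 0.5), function(t) {
    list(calls = mix_pools(pm$calls, pu$calls, t, 300, seed = 406),
         target = t, sites = pm$sites)
  })
  rec <- stoichiometry_recovery(mixes)
  at01 <- rec %>% filter(tau == 0.1)
  expect_lte(max(abs(at01$bias)), 0.02)
  # monotone in target at fixed tau
  for (t in unique(rec$tau)) {
    est <- rec %>% filter(tau == t) %>% arrange(target) %>% pull(estimate)
    expect_true(all(diff(est) >= 0))
  }
})

test_that("false positive rate arithmetic and the replicable variant", {
  fake_sites <- function(n_pass, n_total) {
    tibble(chrom = "c", pos = seq_len(n_total), strand = "+",
           coverage = 30L, n_modified = 0L, frequency = 0,
           passed = c(rep(TRUE, n_pass), rep(FALSE, n_total - n_pass)),
           tau = 0.5)
  }
  r <- evaluate_fpr(fake_sites(1, 10000))
  expect_equal(r$fpr, 1e-4)

  # replicable FPR can only shrink relative to single replicates
  rep1 <- fake_sites(5, 1000); rep2 <- fake_sites(3, 1000)
  both <- evaluate_fpr(list(rep1, rep2))
  expect_lte(both$fpr, evaluate_fpr(rep1)$fpr)
  expect_lte(both$fpr, evaluate_fpr(rep2)$fpr)
  expect_error(evaluate_fpr(fake_sites(0, 100) %>% filter(coverage > 100)),
               "testable")
})

test_that("unmodified controls produce zero FPR at tau = 0.5 across seeds", {
  for (seed in 501:505) {
    cfg <- generator_config(seed = seed, stoichiometry = 0, epsilon = 0)
    sim <- simulate_modprob_dataset(cfg, n_refs = 2, coverage = 40)
    sites <- call_sites(sim$calls, tau = 0.5)
    expect_equal(evaluate_fpr(sites)$fpr, 0)
  }
})

test_that("replicate concordance: identity, disjoint, and resampling envelope", {
  withr::with_seed(407, {
    truth_f <- runif(60, 0.05, 0.6)
    draw <- function() {
      n_mod <- rbinom(60, 100, truth_f)
      tibble(chrom = "c", pos = 1:60, strand = "+", coverage = 100L,
             n_modified = n_mod, frequency = n_mod / 100,
             passed = n_mod / 100 >= 0.05, tau = 0.5)
    }
    a <- draw()
    ident <- replicate_concordance(a, a)
    expect_equal(ident$overlap_rep1, 1)
    expect_equal(ident$spearman_rho, 1)

    b <- a %>% mutate(pos = pos + 1000L)
    expect_error(replicate_concordance(a, b), "shared")

    # envelope from an independent resampling oracle
    oracle <- replicate(200, cor(rbinom(60, 100, truth_f) / 100,
                                 rbinom(60, 100, truth_f) / 100,
                                 method = "spearman"))
    obs <- replicate_concordance(draw(), draw())$spearman_rho
    expect_gte(obs, min(oracle))
    expect_lte(obs, max(oracle))
  })
})
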