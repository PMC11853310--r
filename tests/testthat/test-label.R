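label_accuracy <- function(sim, labels) {
  tv <- labels %>%
    filter(partition == "test") %>%
    inner_join(sim$truth, by = c("read_id", "ref_id", "pos", "kmer"))
  mean((tv$label == "modified") == tv$modified)
}

test_that("ground-truth recovery on separable data reaches high accuracy", {
  cfg <- generator_config(seed = 201, n_reads_per_sample = 200,
                          stoichiometry = 0.5, epsilon = 0, delta_si = 2,
                          n_kmers = 2, n_unaffected_kmers = 1,
                          n_sites_per_kmer = 1)
  sim <- simulate_feature_dataset(cfg)
  bal <- aggregate_by_kmer(sim$records, max_reads_per_position = 200, seed = 1)
  sel <- ks_select_kmers(bal)
  labels <- label_selected_kmers(bal, sel, seed = 1)
  expect_gte(label_accuracy(sim, labels), 0.90)
})

test_that("saturated data labels nearly all treated test reads modified", {
  cfg <- generator_config(seed = 202, n_reads_per_sample = 200,
                          stoichiometry = 1, epsilon = 0, delta_si = 2,
                          n_kmers = 1, n_unaffected_kmers = 0,
                          n_sites_per_kmer = 1)
  sim <- simulate_feature_dataset(cfg)
  bal <- aggregate_by_kmer(sim$records, max_reads_per_position = 200, seed = 1)
  labels <- label_kmer_reads(bal, seed = 1)
  frac <- labels %>%
    filter(partition == "test", sample == "treated") %>%
    summarise(f = mean(label == "modified")) %>% pull(f)
  expect_gte(frac, 0.95)
})

test_that("null data selects no k-mers, so no reads get labeled", {
  cfg <- generator_config(seed = 203, n_reads_per_sample = 100,
                          stoichiometry = 0, epsilon = 0,
                          n_kmers = 3, n_unaffected_kmers = 3,
                          n_sites_per_kmer = 1)
  sim <- simulate_feature_dataset(cfg)
  bal <- aggregate_by_kmer(sim$records, max_reads_per_position = 100, seed = 1)
  sel <- ks_select_kmers(bal)
  expect_equal(sum(sel$selected), 0)
  expect_equal(nrow(label_selected_kmers(bal, sel, seed = 1)), 0)
})

test_that("stage 2 never relabels confident stage-1 reads", {
  cfg <- generator_config(seed = 204, n_reads_per_sample = 150,
                          stoichiometry = 0.5, epsilon = 0, delta_si = 1,
                          n_kmers = 1, n_unaffected_kmers = 0,
                          n_sites_per_kmer = 1)
  sim <- simulate_feature_dataset(cfg)
  bal <- aggregate_by_kmer(sim$records, max_reads_per_position = 150, seed = 1)
  labels <- label_kmer_reads(bal, seed = 1, lo = 0.3, hi = 0.7)
  confident <- labels %>%
    filter(partition == "train",
           stage1_prob <= 0.3 | stage1_prob >= 0.7)
  expect_gt(nrow(confident), 0)
  expect_equal(confident$label,
               ifelse(confident$stage1_prob >= 0.5, "modified", "unmodified"))
})

test_that("test accuracy is non-decreasing along an effect-size ladder", {
  acc <- vapply(c(0.5, 1, 2, 4), function(d) {
    cfg <- generator_config(seed = 205, n_reads_per_sample = 200,
                            stoichiometry = 0.5, epsilon = 0, delta_si = d,
                            trace_unmod = c(5, 5), trace_mod = c(5, 5),
                            mp_unmod = c(2, 2), mp_mod = c(2, 2),
                            dwell_factor = 1,
                            n_kmers = 1, n_unaffected_kmers = 0,
                            n_sites_per_kmer = 1)
    sim <- simulate_feature_dataset(cfg)
    bal <- aggregate_by_kmer(sim$records, max_reads_per_position = 200,
                             seed = 1)
    label_accuracy(sim, label_kmer_reads(bal, seed = 1))
  }, numeric(1))
  expect_true(all(diff(acc) >= 0))
  # at 4 SD separation the Bayes error is ~2%, plus surrogate-label noise
  expect_gte(acc[4], 0.90)
})

test_that("labeling a multi-k-mer input or an undersized k-mer errors", {
  withr::with_seed(206, {
    two <- bind_rows(make_rna002_records(40, "CTGACTG", "control"),
                     make_rna002_records(40, "GTCACAG", "treated"))
    expect_error(label_kmer_reads(two), "one k-mer")
    small <- bind_rows(
      make_rna002_records(10, "CTGACTG", "control"),
      make_rna002_records(10, "CTGACTG", "treated") %>%
        mutate(read_id = paste0("t_", read_id)))
    expect_error(label_kmer_reads(small), "required")
  })
})
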