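suppressPackageStartupMessages({
  library(dplyr)
  library(tibble)
})

# Write a SAM file from header + record lines; returns the path.
write_sam <- function(records, refs = c(ref1 = 1000L), path = NULL) {
  path <- path %||% tempfile(fileext = ".sam")
  header <- c("@HD\tVN:1.6",
              sprintf("@SQ\tSN:%s\tLN:%d", names(refs), refs))
  writeLines(c(header, records), path)
  path
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Minimal valid RNA002 feature table rows (all invariants satisfied).
make_rna002_records <- function(n = 10, kmer = "CTGACTG", sample = "control") {
  tr <- runif(n, 0.6, 0.95)
  rest <- matrix(runif(3 * n), ncol = 3)
  rest <- rest / rowSums(rest) * (1 - tr)
  tibble(
    read_id = sprintf("read%03d", seq_len(n)),
    ref_id = "ref1", pos = 100L, strand = "+", ref_base = "A",
    kmer = kmer, sample = sample,
    SI = rnorm(n, 100, 3), MP = runif(n, 0, 0.2),
    DT = rlnorm(n, 2, 0.3), DT10 = rlnorm(n, 2, 0.3),
    TR = tr, TA = tr, TC = rest[, 1], TG = rest[, 2], TT = rest[, 3])
}

# Synthetic RNA004-schema records: one informative feature, rest noise.
make_rna004_records <- function(kmer, n_per_sample, shift = 0, seed = 1) {
  withr::with_seed(seed, {
    feats <- setdiff(permod::feature_columns("rna004"),
                     grep("^kmer", permod::feature_columns("rna004"), value = TRUE))
    out <- tibble(
      read_id = sprintf("%s_%04d", kmer, seq_len(2 * n_per_sample)),
      ref_id = "ref1", pos = 50L, strand = "+", ref_base = "A", kmer = kmer,
      sample = rep(c("control", "treated"), each = n_per_sample))
    for (f in feats) out[[f]] <- runif(2 * n_per_sample)
    out$SI_mean_p0 <- out$SI_mean_p0 +
      ifelse(out$sample == "treated", shift, 0)
    for (kc in grep("^kmer", permod::feature_columns("rna004"), value = TRUE)) {
      out[[kc]] <- kmer
    }
    out
  })
}

# Per-read calls for one site at given coverage / modified count.
make_site_calls <- function(ref_id = "chr1", pos = 100L, coverage, n_modified,
                            p_mod = 1, p_unmod = 0) {
  tibble(
    read_id = sprintf("%s_%d_r%04d", ref_id, pos, seq_len(coverage)),
    ref_id = ref_id, pos = pos, strand = "+", base = "A",
    modProb = c(rep_len(p_mod, n_modified),
                rep_len(p_unmod, coverage - n_modified)))
}
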