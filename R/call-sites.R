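#' Binarize a per-read modification probability
#'
#' A base in a read is called modified when its modification probability is
#' greater than or equal to the threshold (closed inequality, so
#' `modProb = 0.5` at `tau = 0.5` is modified).
#'
#' @param modProb Numeric vector of probabilities in `[0, 1]`.
#' @param tau Threshold in `[0, 1]`.
#' @return Logical vector, `TRUE` = modified.
#' @export
binarize <- function(modProb, tau = 0.5) {
  if (tau < 0 || tau > 1) abort("tau must lie in [0, 1]")
  modProb >= tau
}

#' Call modified sites from per-read probability calls
#'
#' Groups calls by `(ref_id, pos, strand)`, counts overlapping reads
#' (coverage) and reads at or above the per-read probability threshold, and
#' flags a site as passed when `coverage >= min_cov` and
#' `frequency >= min_freq`. With the defaults (coverage at least 25 and 5%
#' stoichiometry) a site at exactly 25x needs a minimum of 2 modified reads.
#'
#' @param calls Tibble of per-read calls (`ref_id`, `pos`, `strand`,
#'   `modProb`), e.g. from [read_modbam()].
#' @param tau Per-read modification probability threshold.
#' @param min_cov Minimum coverage for a site to pass.
#' @param min_freq Minimum modified-read fraction for a site to pass.
#' @return A tibble ordered by `(chrom, pos)` with columns `chrom`, `pos`,
#'   `strand`, `coverage`, `n_modified`, `frequency`, `passed`, `tau`.
#'   Zero-coverage positions are absent by construction.
#' @export
call_sites <- function(calls, tau = 0.5, min_cov = 25L, min_freq = 0.05) {
  check_columns(calls, c("ref_id", "pos", "strand", "modProb"), "calls")
  calls %>%
    group_by(chrom = .data$ref_id, .data$pos, .data$strand) %>%
    summarise(coverage = n(),
              n_modified = sum(binarize(.data$modProb, tau)),
              .groups = "drop") %>%
    mutate(frequency = .data$n_modified / .data$coverage,
           passed = .data$coverage >= min_cov & .data$frequency >= min_freq,
           tau = tau) %>%
    arrange(.data$chrom, .data$pos)
}

#' Optimize the per-read threshold by the Youden index
#'
#' Scans a threshold grid, computing the true-positive rate on calls from
#' known modified bases and the false-positive rate on calls from known
#' unmodified bases, and reports the Youden index `J = TPR - FPR` with its
#' maximizer (smallest threshold on ties).
#'
#' @param modified_probs,unmodified_probs Numeric vectors of per-read
#'   modification probabilities of the two ground-truth classes.
#' @param grid Threshold grid (default 0 to 1 in steps of 0.01).
#' @return A tibble of class `permod_threshold_scan` with columns `tau`,
#'   `tpr`, `fpr`, `J`; attributes `tau_star` and `J_star` give the optimum.
#' @export
youden_threshold <- function(modified_probs, unmodified_probs,
                             grid = seq(0, 1, by = 0.01)) {
  if (length(modified_probs) == 0) abort("modified class is empty")
  if (length(unmodified_probs) == 0) abort("unmodified class is empty")
  scan <- tibble(
    tau = grid,
    tpr = vapply(grid, function(t) mean(modified_probs >= t), numeric(1)),
    fpr = vapply(grid, function(t) mean(unmodified_probs >= t), numeric(1))
  ) %>%
    mutate(J = .data$tpr - .data$fpr)
  best <- which(scan$J == max(scan$J))[1]   # smallest tau on ties
  structure(scan,
            class = c("permod_threshold_scan", class(scan)),
            tau_star = scan$tau[best], J_star = scan$J[best])
}

#' Evaluate stoichiometry recovery on read mixtures
#'
#' For mixtures of known target stoichiometry (built with [mix_pools()]),
#' estimates the per-site modified fraction at each per-read threshold and
#' reports the bias against the target.
#'
#' @param mixtures Named list of call tibbles; names are the target
#'   stoichiometries (fractions, e.g. `"0.0625"`), or a list of lists with
#'   elements `calls`, `target` and optionally `sites` (tibble of `ref_id`,
#'   `pos` restricting the evaluation to true modification sites).
#' @param tau_list Per-read thresholds to evaluate (defaults to the three
#'   reporting thresholds 0.5, 0.1, 0.01).
#' @return A tibble of class `permod_mixture_result`: `target`, `tau`,
#'   `estimate` (mean per-site frequency over all covered sites), `bias`.
#' @export
stoichiometry_recovery <- function(mixtures, tau_list = c(0.5, 0.1, 0.01)) {
  entries <- purrr::imap(mixtures, function(m, nm) {
    if (is.list(m) && !is.data.frame(m)) {
      list(calls = m$calls, target = m$target, sites = m$sites)
    } else {
      list(calls = m, target = as.numeric(nm), sites = NULL)
    }
  })
  out <- purrr::map_dfr(entries, function(e) {
    calls <- e$calls
    if (!is.null(e$sites)) {
      calls <- dplyr::semi_join(calls, e$sites, by = c("ref_id", "pos"))
    }
    purrr::map_dfr(tau_list, function(t) {
      sites <- call_sites(calls, tau = t, min_cov = 1L, min_freq = 0)
      tibble(target = e$target, tau = t,
             estimate = mean(sites$frequency),
             bias = mean(sites$frequency) - e$target)
    })
  }) %>% arrange(.data$tau, .data$target)
  structure(out, class = c("permod_mixture_result", class(out)))
}

#' False positive rate on a known-unmodified control
#'
#' On a control known to be unmodified (IVT-like), the false positive rate
#' is the fraction of testable positions (coverage at or above `min_cov`)
#' that nonetheless pass the site-calling thresholds. The replicable variant
#' counts positions passed in all replicates among positions testable in all
#' replicates.
#'
#' @param site_calls A [call_sites()] result on the control, or a list of
#'   them (one per replicate) for the replicable variant.
#' @param min_cov Coverage gate defining testable positions.
#' @return A tibble `n_testable`, `n_passed`, `fpr` (single row; for the
#'   replicable variant computed on the intersection).
#' @export
evaluate_fpr <- function(site_calls, min_cov = 25L) {
  if (is.data.frame(site_calls)) site_calls <- list(site_calls)
  testable <- purrr::map(site_calls, function(s) {
    s %>% filter(.data$coverage >= min_cov) %>%
      mutate(key = paste(.data$chrom, .data$pos, .data$strand))
  })
  shared <- Reduce(intersect, purrr::map(testable, "key"))
  if (length(shared) == 0) abort("no testable positions")
  passed_all <- Reduce(intersect, purrr::map(testable, function(s) {
    s$key[s$passed]
  }))
  tibble(n_testable = length(shared),
         n_passed = length(intersect(passed_all, shared)),
         fpr = length(intersect(passed_all, shared)) / length(shared))
}

#' Concordance of site calls between two replicates
#'
#' @param site_calls_rep1,site_calls_rep2 [call_sites()] results called with
#'   identical thresholds.
#' @param min_cov Coverage gate for the stoichiometry correlation.
#' @return A tibble with `overlap_rep1`, `overlap_rep2` (fraction of each
#'   replicate's passed sites found in the other), `n_shared_testable`, and
#'   `spearman_rho` on per-site frequencies of sites with sufficient
#'   coverage in both replicates.
#' @export
replicate_concordance <- function(site_calls_rep1, site_calls_rep2,
                                  min_cov = 25L) {
  key <- function(s) paste(s$chrom, s$pos, s$strand)
  p1 <- key(site_calls_rep1[site_calls_rep1$passed, ])
  p2 <- key(site_calls_rep2[site_calls_rep2$passed, ])
  shared <- inner_join(
    site_calls_rep1 %>% filter(.data$coverage >= min_cov) %>%
      select("chrom", "pos", "strand", f1 = "frequency"),
    site_calls_rep2 %>% filter(.data$coverage >= min_cov) %>%
      select("chrom", "pos", "strand", f2 = "frequency"),
    by = c("chrom", "pos", "strand"))
  if (nrow(shared) == 0) abort("no shared testable sites")
  tibble(
    overlap_rep1 = if (length(p1) > 0) mean(p1 %in% p2) else NA_real_,
    overlap_rep2 = if (length(p2) > 0) mean(p2 %in% p1) else NA_real_,
    n_shared_testable = nrow(shared),
    spearman_rho = suppressWarnings(
      stats::cor(shared$f1, shared$f2, method = "spearman"))
  )
}
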