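#' Number of standard deviations between observed and expected co-occurrence
#'
#' For a pair of modified sites A and B with per-site modification
#' frequencies `fA` and `fB` on the `C` reads spanning both sites, the
#' expected number of doubly modified reads under independence is
#' `Exp = fA * fB * C` and the co-occurrence statistic is
#'
#' `NSD = (Obs - Exp) / sqrt(Exp * (1 - fA * fB))`
#'
#' i.e. the number of binomial standard deviations by which the observed
#' count of doubly modified reads deviates from independence. `NSD > 0`
#' means the two sites co-occur on the same molecules more often than
#' expected.
#'
#' @param obs Observed count of reads modified at both sites.
#' @param fA,fB Per-site modification frequencies on the spanning reads.
#' @param coverage Number of reads spanning both sites (`C`).
#' @return The NSD value (numeric scalar or vector).
#' @export
nsd_statistic <- function(obs, fA, fB, coverage) {
  if (any(fA * fB >= 1)) abort("NSD undefined when fA * fB = 1")
  exp_ <- fA * fB * coverage
  (obs - exp_) / sqrt(exp_ * (1 - fA * fB))
}

#' NSD for one site pair with eligibility filtering
#'
#' Applies the pair eligibility filters (spanning coverage of at least
#' `min_cov` reads and expected doubly modified count of at least
#' `min_exp`) and computes the NSD statistic.
#'
#' @param pair A one-row data frame (or list) with `obs`, `fA`, `fB`,
#'   `coverage`.
#' @param min_cov Minimum spanning-read coverage (default 200).
#' @param min_exp Minimum expected doubly modified count (default 2).
#' @return A one-row tibble `obs`, `exp`, `fA`, `fB`, `coverage`, `nsd`,
#'   `eligible`, `reason` (`NA` when eligible; `nsd` is `NA` for ineligible
#'   pairs).
#' @export
nsd_for_pair <- function(pair, min_cov = 200L, min_exp = 2) {
  obs <- pair$obs; fA <- pair$fA; fB <- pair$fB; C <- pair$coverage
  exp_ <- fA * fB * C
  reason <- NA_character_
  if (C < min_cov) reason <- sprintf("coverage %d < %d", C, min_cov)
  else if (exp_ < min_exp) reason <- sprintf("expected %.3f < %g", exp_, min_exp)
  eligible <- is.na(reason)
  tibble(obs = obs, exp = exp_, fA = fA, fB = fB, coverage = C,
         nsd = if (eligible) nsd_statistic(obs, fA, fB, C) else NA_real_,
         eligible = eligible, reason = reason)
}

#' Scan all site pairs of each transcript for modification co-occurrence
#'
#' Restricts the calls to reads unambiguously assigned to one isoform (when
#' assignments are given), determines per-transcript modified sites, and for
#' every within-transcript site pair computes, on the reads spanning both
#' sites: the marginal frequencies `fA`, `fB`, the observed doubly modified
#' count, the independence expectation and the NSD. Pairs failing the
#' eligibility filters (spanning coverage >= `min_cov`, expected count >=
#' `min_exp`) are excluded with a reason. The eligible NSD values are then
#' compared to a seeded normal null sample of the same size and standard
#' deviation centered at 0 (Mann-Whitney), and correlated with the log10
#' genomic distance between the sites (Spearman).
#'
#' @param calls Per-read calls (`read_id`, `ref_id`, `pos`, `modProb`).
#' @param isoform_assignments Optional tibble from [read_isoform_table()];
#'   only reads with `unambiguous = TRUE` are kept, and `ref_id` is replaced
#'   by the assigned `transcript_id`.
#' @param tau Per-read modification threshold.
#' @param site_min_cov,site_min_freq Site-calling thresholds used to define
#'   the modified sites entering pair enumeration.
#' @param min_cov,min_exp Pair eligibility filters.
#' @param seed Seed for the null sample.
#' @return A list of class `permod_nsd` with `pairs` (all enumerated pairs,
#'   eligible or not), `nsd` (eligible NSD values), `null` (the mean-0 null
#'   sample), `mann_whitney_p`, `spearman_rho_distance` and `n_eligible`.
#' @export
scan_cooccurrence <- function(calls, isoform_assignments = NULL, tau = 0.5,
                              site_min_cov = 25L, site_min_freq = 0.05,
                              min_cov = 200L, min_exp = 2, seed = 1L) {
  if (!is.null(isoform_assignments)) {
    calls <- calls %>%
      inner_join(isoform_assignments %>% filter(.data$unambiguous) %>%
                   select("read_id", "transcript_id"),
                 by = "read_id") %>%
      mutate(ref_id = .data$transcript_id) %>%
      select(-"transcript_id")
  }
  sites <- call_sites(calls, tau = tau, min_cov = site_min_cov,
                      min_freq = site_min_freq) %>%
    filter(.data$passed)
  pair_rows <- split(sites$pos, sites$chrom) %>%
    purrr::keep(~ length(.x) >= 2) %>%
    purrr::imap(~ list(chrom = .y, pairs = utils::combn(sort(.x), 2)))

  pairs <- purrr::map_dfr(pair_rows, function(pr) {
    chrom <- pr$chrom; pairs <- pr$pairs
    purrr::map_dfr(seq_len(ncol(pairs)), function(j) {
      posA <- pairs[1, j]; posB <- pairs[2, j]
      tx_calls <- calls %>% filter(.data$ref_id == chrom,
                                   .data$pos %in% c(posA, posB))
      wide <- tx_calls %>%
        mutate(site = ifelse(.data$pos == posA, "A", "B"),
               mod = binarize(.data$modProb, tau)) %>%
        select("read_id", "site", "mod") %>%
        tidyr::pivot_wider(names_from = "site", values_from = "mod")
      span <- wide %>% filter(!is.na(.data$A) & !is.na(.data$B))
      C <- nrow(span)
      fA <- if (C > 0) mean(span$A) else NA_real_
      fB <- if (C > 0) mean(span$B) else NA_real_
      obs <- if (C > 0) sum(span$A & span$B) else 0L
      nsd_for_pair(list(obs = obs, fA = fA, fB = fB, coverage = C),
                   min_cov = min_cov, min_exp = min_exp) %>%
        mutate(transcript_id = chrom, posA = posA, posB = posB,
               distance = posB - posA, .before = 1)
    })
  })

  if (nrow(pairs) == 0) {
    pairs <- tibble(transcript_id = character(), posA = integer(),
                    posB = integer(), distance = integer(), obs = integer(),
                    exp = numeric(), fA = numeric(), fB = numeric(),
                    coverage = integer(), nsd = numeric(),
                    eligible = logical(), reason = character())
  }
  eligible <- pairs %>% filter(.data$eligible)
  if (nrow(eligible) == 0) {
    out <- list(pairs = pairs, nsd = numeric(0), null = numeric(0),
                mann_whitney_p = NA_real_,
                spearman_rho_distance = NA_real_, n_eligible = 0L)
    return(structure(out, class = "permod_nsd"))
  }
  null_sample <- with_seed(seed,
    stats::rnorm(nrow(eligible), mean = 0,
                 sd = max(stats::sd(eligible$nsd), .Machine$double.eps)))
  mw <- if (nrow(eligible) >= 2) {
    suppressWarnings(stats::wilcox.test(eligible$nsd, null_sample))$p.value
  } else NA_real_
  rho <- if (nrow(eligible) >= 3) {
    suppressWarnings(stats::cor(eligible$nsd, log10(eligible$distance),
                                method = "spearman"))
  } else NA_real_
  structure(list(pairs = pairs, nsd = eligible$nsd, null = null_sample,
                 mann_whitney_p = mw, spearman_rho_distance = rho,
                 n_eligible = nrow(eligible)),
            class = "permod_nsd")
}
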