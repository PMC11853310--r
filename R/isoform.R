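#' Per-isoform stoichiometry differences at shared modified sites
#'
#' For genomic sites observed on two or more isoforms, compares per-isoform
#' modification frequencies within each replicate: sites must reach a
#' per-isoform coverage of at least `min_cov` in every replicate; per
#' replicate, the mean absolute pairwise frequency difference across
#' isoforms is reported together with a two-proportion test
#' (Benjamini-Hochberg-adjusted across sites within each replicate). A site
#' is flagged `replicated` when it is significant with the same direction
#' (ordering of the two extreme isoforms) in all replicates. The Spearman
#' correlation between replicates' per-isoform frequencies is also reported.
#'
#' @param site_calls_by_isoform Tibble with one row per site x isoform x
#'   replicate: columns `chrom`, `pos`, `transcript_id`, `replicate`,
#'   `coverage`, `n_modified`.
#' @param min_cov Per-isoform coverage gate applied in every replicate.
#' @param alpha Adjusted significance level.
#' @return A list of class `permod_isoform` with `sites` (per site x
#'   replicate: `mean_abs_diff`, `p_value`, `p_adj`, `significant`,
#'   `direction`), `summary` (per site: `replicated` flag, mean of
#'   `mean_abs_diff` across replicates) and `spearman_between_replicates`.
#' @export
isoform_diff <- function(site_calls_by_isoform, min_cov = 40L, alpha = 0.05) {
  check_columns(site_calls_by_isoform,
                c("chrom", "pos", "transcript_id", "replicate",
                  "coverage", "n_modified"), "per-isoform site calls")
  x <- site_calls_by_isoform %>%
    mutate(frequency = .data$n_modified / .data$coverage,
           site = paste(.data$chrom, .data$pos))
  n_reps <- length(unique(x$replicate))
  # keep isoforms covered >= min_cov in all replicates, sites with >= 2 such
  ok_iso <- x %>%
    group_by(.data$site, .data$transcript_id) %>%
    filter(n() == n_reps, all(.data$coverage >= min_cov)) %>%
    ungroup()
  keep_sites <- ok_iso %>%
    distinct(.data$site, .data$transcript_id) %>%
    count(.data$site) %>%
    filter(.data$n >= 2) %>%
    pull(.data$site)
  y <- ok_iso %>% filter(.data$site %in% keep_sites)
  if (nrow(y) == 0) {
    return(structure(list(sites = tibble(), summary = tibble(),
                          spearman_between_replicates = NA_real_),
                     class = "permod_isoform"))
  }
  per_rep <- y %>%
    group_by(.data$site, .data$replicate) %>%
    group_modify(function(df, key) {
      pairs <- utils::combn(nrow(df), 2)
      diffs <- abs(df$frequency[pairs[1, ]] - df$frequency[pairs[2, ]])
      # test the extreme pair: isoforms with min and max frequency
      i_lo <- which.min(df$frequency); i_hi <- which.max(df$frequency)
      pt <- suppressWarnings(stats::prop.test(
        x = c(df$n_modified[i_lo], df$n_modified[i_hi]),
        n = c(df$coverage[i_lo], df$coverage[i_hi])))
      tibble(n_isoforms = nrow(df),
             mean_abs_diff = mean(diffs),
             p_value = pt$p.value,
             direction = paste(df$transcript_id[i_lo], "<",
                               df$transcript_id[i_hi]))
    }) %>%
    ungroup() %>%
    group_by(.data$replicate) %>%
    mutate(p_adj = stats::p.adjust(.data$p_value, method = "BH"),
           significant = .data$p_adj < alpha) %>%
    ungroup()
  summary <- per_rep %>%
    group_by(.data$site) %>%
    summarise(mean_abs_diff = mean(.data$mean_abs_diff),
              replicated = all(.data$significant) &&
                length(unique(.data$direction)) == 1,
              .groups = "drop")
  rho <- if (n_reps >= 2) {
    wide <- y %>%
      select("site", "transcript_id", "replicate", "frequency") %>%
      tidyr::pivot_wider(names_from = "replicate", values_from = "frequency")
    reps <- setdiff(names(wide), c("site", "transcript_id"))
    suppressWarnings(stats::cor(wide[[reps[1]]], wide[[reps[2]]],
                                method = "spearman",
                                use = "pairwise.complete.obs"))
  } else NA_real_
  structure(list(sites = per_rep, summary = summary,
                 spearman_between_replicates = rho),
            class = "permod_isoform")
}

#' Per-isoform site calls from read calls and isoform assignments
#'
#' Helper assembling the input of [isoform_diff()]: restricts calls to
#' unambiguously assigned reads and tallies coverage and modified reads per
#' genomic site per isoform.
#'
#' @param calls Per-read calls (`read_id`, `ref_id`, `pos`, `strand`,
#'   `modProb`); `ref_id` is the genomic reference.
#' @param isoform_assignments Tibble from [read_isoform_table()].
#' @param replicate Replicate label attached to the output.
#' @param tau Per-read modification threshold.
#' @return Tibble `chrom`, `pos`, `transcript_id`, `replicate`, `coverage`,
#'   `n_modified`.
#' @export
site_calls_by_isoform <- function(calls, isoform_assignments, replicate = "rep1",
                                  tau = 0.5) {
  calls %>%
    inner_join(isoform_assignments %>% filter(.data$unambiguous) %>%
                 select("read_id", "transcript_id"),
               by = "read_id") %>%
    group_by(chrom = .data$ref_id, .data$pos, .data$transcript_id) %>%
    summarise(coverage = n(),
              n_modified = sum(binarize(.data$modProb, tau)),
              .groups = "drop") %>%
    mutate(replicate = replicate)
}
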