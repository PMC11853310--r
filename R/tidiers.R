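#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a Youden threshold scan
#'
#' @param x A `permod_threshold_scan` from [youden_threshold()].
#' @param ... Unused.
#' @return The per-threshold tibble (`tau`, `tpr`, `fpr`, `J`).
#' @export
tidy.permod_threshold_scan <- function(x, ...) {
  as_tibble(x)[, c("tau", "tpr", "fpr", "J")]
}

#' @rdname tidy.permod_threshold_scan
#' @return `glance()` returns a one-row tibble `tau_star`, `J_star`, `auc`.
#' @export
glance.permod_threshold_scan <- function(x, ...) {
  scan <- as_tibble(x)
  # trapezoidal ROC area over the scanned grid
  o <- order(scan$fpr, scan$tpr)
  fpr <- c(0, scan$fpr[o], 1); tpr <- c(0, scan$tpr[o], 1)
  auc <- sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
  tibble(tau_star = attr(x, "tau_star"), J_star = attr(x, "J_star"),
         auc = auc)
}

#' Tidy an NSD co-occurrence scan
#'
#' @param x A `permod_nsd` from [scan_cooccurrence()].
#' @param ... Unused.
#' @return The pair-level tibble (one row per enumerated site pair).
#' @export
tidy.permod_nsd <- function(x, ...) as_tibble(x$pairs)

#' @rdname tidy.permod_nsd
#' @return `glance()` returns a one-row tibble with `n_eligible`,
#'   `mean_nsd`, `mann_whitney_p`, `spearman_rho_distance`.
#' @export
glance.permod_nsd <- function(x, ...) {
  tibble(n_eligible = x$n_eligible,
         mean_nsd = if (x$n_eligible > 0) mean(x$nsd) else NA_real_,
         mann_whitney_p = x$mann_whitney_p,
         spearman_rho_distance = x$spearman_rho_distance)
}

#' Tidy an exon-boundary distance analysis
#'
#' @param x A `permod_exondist` from [exon_boundary_distance()].
#' @param ... Unused.
#' @return A tibble with one row per position (`group` = observed/control,
#'   `transcript_id`, `pos`, `distance`).
#' @export
tidy.permod_exondist <- function(x, ...) {
  bind_rows(
    x$observed %>% mutate(group = "observed"),
    x$control %>% mutate(group = "control"))
}

#' @rdname tidy.permod_exondist
#' @return `glance()` returns medians, counts and the Mann-Whitney p-value.
#' @export
glance.permod_exondist <- function(x, ...) {
  tibble(n_observed = nrow(x$observed), n_control = nrow(x$control),
         median_observed = x$median_observed,
         median_control = x$median_control,
         p_value = x$p_value)
}

#' Tidy a per-isoform stoichiometry comparison
#'
#' @param x A `permod_isoform` from [isoform_diff()].
#' @param ... Unused.
#' @return The per-site x replicate tibble.
#' @export
tidy.permod_isoform <- function(x, ...) as_tibble(x$sites)

#' @rdname tidy.permod_isoform
#' @export
glance.permod_isoform <- function(x, ...) {
  tibble(n_sites = nrow(x$summary),
         n_replicated = sum(x$summary$replicated),
         spearman_between_replicates = x$spearman_between_replicates)
}
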