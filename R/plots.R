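#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_vline
#'   geom_histogram geom_density labs theme_minimal scale_x_log10
#'   geom_abline facet_wrap
#' @export
ggplot2::autoplot

#' Plot a Youden threshold scan
#'
#' Shows TPR, FPR and the Youden index J across the threshold grid with the
#' optimum marked.
#'
#' @param object A `permod_threshold_scan`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.permod_threshold_scan <- function(object, ...) {
  long <- tidy(object) %>%
    tidyr::pivot_longer(c("tpr", "fpr", "J"), names_to = "metric")
  ggplot(long, aes(x = .data$tau, y = .data$value, colour = .data$metric)) +
    geom_line() +
    geom_vline(xintercept = attr(object, "tau_star"), linetype = "dashed") +
    labs(x = "per-read modProb threshold", y = NULL,
         title = sprintf("Youden scan: tau* = %.2f, J* = %.3f",
                         attr(object, "tau_star"), attr(object, "J_star"))) +
    theme_minimal()
}

#' Plot an NSD co-occurrence distribution against its mean-0 null
#'
#' @param object A `permod_nsd` from [scan_cooccurrence()].
#' @param ... Unused.
#' @return A ggplot (density of eligible NSD values and of the matched
#'   mean-0 null sample).
#' @export
autoplot.permod_nsd <- function(object, ...) {
  df <- bind_rows(tibble(value = object$nsd, group = "observed"),
                  tibble(value = object$null, group = "null (mean 0)"))
  ggplot(df, aes(x = .data$value, fill = .data$group)) +
    geom_density(alpha = 0.4) +
    labs(x = "NSD", y = "density",
         title = sprintf("Co-occurrence NSD (n = %d pairs)",
                         object$n_eligible)) +
    theme_minimal()
}

#' Plot stoichiometry recovery across mixtures
#'
#' Estimated against target stoichiometry per threshold, with the identity
#' line.
#'
#' @param object A `permod_mixture_result` from [stoichiometry_recovery()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.permod_mixture_result <- function(object, ...) {
  ggplot(as_tibble(object),
         aes(x = .data$target, y = .data$estimate,
             colour = factor(.data$tau))) +
    geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    geom_point() + geom_line() +
    labs(x = "target stoichiometry", y = "estimated frequency",
         colour = "modProb threshold") +
    theme_minimal()
}

#' Plot exon-boundary distance distributions
#'
#' @param object A `permod_exondist` from [exon_boundary_distance()].
#' @param ... Unused.
#' @return A ggplot (log10 x axis, observed sites vs random DRACH control).
#' @export
autoplot.permod_exondist <- function(object, ...) {
  ggplot(tidy(object), aes(x = .data$distance + 1, fill = .data$group)) +
    geom_density(alpha = 0.4) +
    scale_x_log10() +
    labs(x = "distance to closest exon boundary + 1 (nt)", y = "density") +
    theme_minimal()
}
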