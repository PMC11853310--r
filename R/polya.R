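#' Compare polyA tail lengths of m6A-containing and unmodified reads
#'
#' Joins per-read modification calls with per-read polyA tail length
#' estimates, keeps reads with a tail length of at least `min_length`
#' nucleotides, bins reads into m6A-containing (at least one base at or
#' above the per-read threshold, optionally restricted to passed sites) and
#' unmodified, and compares the two tail-length distributions with a
#' two-sided Mann-Whitney test.
#'
#' Scopes: `"global"` uses every read; `"m6A_genes_only"` keeps reads of
#' genes (references) that contain at least one m6A-containing read;
#' `"per_gene_median"` aggregates each gene to one median per group before
#' testing, so each gene contributes equally.
#'
#' @param read_calls Per-read calls (`read_id`, `ref_id`, `pos`, `modProb`).
#' @param polya_records Tibble `read_id`, `polya_length` (nt), e.g. from
#'   [read_polya_table()].
#' @param tau Per-read modification threshold.
#' @param scope Analysis scope (see above).
#' @param sites Optional tibble (`ref_id`, `pos`) of passed sites; when
#'   given, only calls at these sites count toward a read's m6A status.
#' @param min_length Minimum tail length (nt) for a read to be analyzed.
#' @return A tibble of class `permod_polya`: `scope`, `n_m6A`, `n_no_m6A`,
#'   `median_m6A`, `median_no_m6A`, `p_value`. The attribute `"reads"` holds
#'   the per-read table (`read_id`, `has_m6A`, `polya_length`, `ref_id`).
#' @export
polya_compare <- function(read_calls, polya_records, tau = 0.5,
                          scope = c("global", "m6A_genes_only", "per_gene_median"),
                          sites = NULL, min_length = 10) {
  scope <- match.arg(scope)
  calls <- read_calls
  if (!is.null(sites)) {
    calls <- dplyr::semi_join(calls, sites, by = c("ref_id", "pos"))
  }
  status <- read_calls %>%
    distinct(.data$read_id, .data$ref_id) %>%
    left_join(calls %>%
                group_by(.data$read_id) %>%
                summarise(has_m6A = any(binarize(.data$modProb, tau)),
                          .groups = "drop"),
              by = "read_id") %>%
    mutate(has_m6A = !is.na(.data$has_m6A) & .data$has_m6A)
  reads <- status %>%
    inner_join(polya_records, by = "read_id") %>%
    filter(.data$polya_length >= min_length)
  if (scope == "m6A_genes_only") {
    m6a_genes <- unique(reads$ref_id[reads$has_m6A])
    reads <- reads %>% filter(.data$ref_id %in% m6a_genes)
  }
  groups <- if (scope == "per_gene_median") {
    reads %>%
      group_by(.data$ref_id, .data$has_m6A) %>%
      summarise(polya_length = stats::median(.data$polya_length),
                .groups = "drop")
  } else {
    reads
  }
  x <- groups$polya_length[groups$has_m6A]
  y <- groups$polya_length[!groups$has_m6A]
  if (length(x) == 0) abort("m6A-containing group is empty")
  if (length(y) == 0) abort("unmodified group is empty")
  out <- tibble(
    scope = scope,
    n_m6A = length(x), n_no_m6A = length(y),
    median_m6A = stats::median(x), median_no_m6A = stats::median(y),
    p_value = suppressWarnings(stats::wilcox.test(x, y))$p.value)
  attr(out, "reads") <- reads
  structure(out, class = c("permod_polya", class(out)))
}
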