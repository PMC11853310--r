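#' Column sets of the per-base feature table dialects
#'
#' The RNA002-mode table carries 9 per-base features per read: signal
#' intensity (SI), basecaller modification/error probability (MP), dwell time
#' at the position (DT) and 10 bases upstream (DT10), and the five trace
#' values (TR for the reference base, TA/TC/TG/TT per nucleotide). The
#' RNA004-mode table carries 13 features at each of positions -1, 0 and +1
#' (39 feature columns): per-position signal-intensity mean and standard
#' deviation, two dwell times, six basecaller probabilities (A, C, G, T/U,
#' stay, reference base) and the identifiers of the three most likely k-mers
#' from the basecalling model.
#'
#' @param mode `"rna002"` or `"rna004"`.
#' @return Character vector of feature column names.
#' @export
feature_columns <- function(mode = c("rna002", "rna004")) {
  mode <- match.arg(mode)
  if (mode == "rna002") {
    c("SI", "MP", "DT", "DT10", "TR", "TA", "TC", "TG", "TT")
  } else {
    per_pos <- c("SI_mean", "SI_sd", "DT0", "DT10",
                 "pA", "pC", "pG", "pT", "pN", "pRef",
                 "kmer1", "kmer2", "kmer3")
    as.vector(vapply(c("m1", "p0", "p1"),
                     function(p) paste(per_pos, p, sep = "_"),
                     character(length(per_pos))))
  }
}

id_columns <- function() {
  c("read_id", "ref_id", "pos", "strand", "ref_base", "kmer", "sample")
}

prob_feature_columns <- function(mode) {
  if (mode == "rna002") {
    c("MP", "TR", "TA", "TC", "TG", "TT")
  } else {
    grep("^p[ACGTN]|^pRef", feature_columns("rna004"), value = TRUE)
  }
}

#' Read a per-base per-read feature table
#'
#' Reads the tab-separated feature-table dialect produced by the feature
#' extraction step (and by [simulate_feature_dataset()]): one row per aligned
#' base per read, identifier columns (`read_id`, `ref_id`, `pos`, `strand`,
#' `ref_base`, `kmer`, `sample`) followed by the mode's feature columns (see
#' [feature_columns()]). Rows that violate the validity constraints
#' (probability-type features outside `[0, 1]`, negative dwell times, a k-mer
#' whose central base disagrees with `ref_base`) are rejected and reported
#' with their line numbers.
#'
#' @param path Path to a tab-separated file with a header line.
#' @param mode Feature schema, `"rna002"` (9 features) or `"rna004"`
#'   (39 features).
#' @param on_invalid `"error"` (default) raises a validation error naming
#'   the first offending line; `"reject"` drops invalid rows and reports
#'   them in the `"rejected"` attribute, keeping every valid row.
#' @return A tibble of validated records. The attribute `"rejected"` holds a
#'   tibble (`line`, `reason`) describing rejected data rows; `line` is the
#'   1-based line number in the file (header is line 1).
#' @export
read_feature_table <- function(path, mode = c("rna002", "rna004"),
                               on_invalid = c("error", "reject")) {
  mode <- match.arg(mode)
  on_invalid <- match.arg(on_invalid)
  if (!file.exists(path)) abort(sprintf("feature table not found: %s", path))
  feats <- feature_columns(mode)
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(c(id_columns(), feats), names(x))
  if (length(missing) > 0) {
    abort(sprintf("feature table %s lacks mandatory column(s): %s",
                  path, paste(missing, collapse = ", ")))
  }
  x <- x[, c(id_columns(), feats)]
  x$pos <- as.integer(x$pos)
  if (nrow(x) == 0) {
    attr(x, "rejected") <- tibble(line = integer(), reason = character())
    return(x)
  }
  bad <- validate_feature_rows(x, mode)
  rejected <- tibble(line = which(bad$any) + 1L, reason = bad$reason[bad$any])
  if (nrow(rejected) > 0 && on_invalid == "error") {
    abort(sprintf(
      "feature table %s: %d invalid row(s), first at line %d (%s)",
      path, nrow(rejected), rejected$line[1], rejected$reason[1]))
  }
  x <- x[!bad$any, , drop = FALSE]
  attr(x, "rejected") <- rejected
  x
}

validate_feature_rows <- function(x, mode) {
  reason <- rep(NA_character_, nrow(x))
  flag <- function(cond, msg) {
    cond[is.na(cond)] <- TRUE
    reason[cond & is.na(reason)] <<- msg
  }
  for (col in prob_feature_columns(mode)) {
    flag(x[[col]] < 0 | x[[col]] > 1, sprintf("%s outside [0, 1]", col))
  }
  dwell <- if (mode == "rna002") c("DT", "DT10") else
    grep("^DT", feature_columns("rna004"), value = TRUE)
  for (col in dwell) flag(x[[col]] < 0, sprintf("%s negative", col))
  flag(!x$strand %in% c("+", "-"), "strand not +/-")
  flag(nchar(x$kmer) != 7, "k-mer not 7 nt")
  central <- substr(x$kmer, 4, 4)
  flag(chartr("U", "T", central) != chartr("U", "T", x$ref_base),
       "k-mer center disagrees with ref_base")
  if (mode == "rna002") {
    # TR must equal the trace of the reference base
    base_col <- paste0("T", chartr("U", "T", x$ref_base))
    tr_ref <- vapply(seq_len(nrow(x)),
                     function(i) x[[base_col[i]]][i], numeric(1))
    flag(abs(x$TR - tr_ref) > 1e-9, "TR disagrees with trace of ref_base")
  }
  list(any = !is.na(reason), reason = reason)
}

#' Write a per-base feature table
#'
#' @param records Tibble of feature records (as returned by
#'   [read_feature_table()] or [simulate_feature_dataset()]).
#' @param path Output path (`.gz` suffix compresses).
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(records, path) {
  readr::write_tsv(records, path, progress = FALSE)
  invisible(path)
}

#' Read per-read polyA tail length estimates
#'
#' Expects a tab-separated file with columns `read_id` and `polya_length`
#' (nucleotides; tailfindr-like output).
#'
#' @param path Path to the TSV file.
#' @return A tibble with columns `read_id`, `polya_length`.
#' @export
read_polya_table <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  check_columns(x, c("read_id", "polya_length"), "polyA table")
  if (any(x$polya_length < 0, na.rm = TRUE)) {
    abort("polya_length must be >= 0")
  }
  x[, c("read_id", "polya_length")]
}

#' Read per-read isoform assignments
#'
#' Expects a tab-separated file with columns `read_id`, `transcript_id` and
#' `assignment_class` (Isoquant-like read-to-isoform assignments). Only one
#' assignment per read is allowed.
#'
#' @param path Path to the TSV file.
#' @param keep_classes Assignment classes treated as unambiguous; reads in
#'   other classes are retained in the table but flagged by downstream
#'   filters. Defaults to the unambiguous classes `unique`, `fsm` and
#'   `mono_exon_match`.
#' @return A tibble with columns `read_id`, `transcript_id`,
#'   `assignment_class` and logical `unambiguous`.
#' @export
read_isoform_table <- function(path,
                               keep_classes = c("unique", "fsm", "mono_exon_match")) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  check_columns(x, c("read_id", "transcript_id", "assignment_class"),
                "isoform table")
  if (anyDuplicated(x$read_id) > 0) {
    abort("isoform table assigns some read_id more than once")
  }
  x %>%
    select("read_id", "transcript_id", "assignment_class") %>%
    mutate(unambiguous = .data$assignment_class %in% keep_classes)
}
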