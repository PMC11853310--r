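#' Write site calls as a bedMethyl (9+2) table
#'
#' Writes per-site modification calls in the community bedMethyl dialect:
#' `chrom, start, end, mod_code, min(coverage, 1000), strand, start, end,
#' "0,0,0", coverage, frequency` with frequency as a percentage printed with
#' one decimal. Coordinates are 0-based half-open with `end = start + 1`.
#'
#' @param site_calls Tibble of site calls (from [call_sites()]) with columns
#'   `chrom`, `pos`, `strand`, `coverage`, `frequency`.
#' @param path Output path; a `.gz` suffix compresses.
#' @param mod_code Modification code column value (`"a"` = m6A).
#' @return `path`, invisibly.
#' @export
write_bedmethyl <- function(site_calls, path, mod_code = "a") {
  check_columns(site_calls, c("chrom", "pos", "strand", "coverage", "frequency"),
                "site calls")
  x <- site_calls %>% arrange(.data$chrom, .data$pos)
  out <- tibble(
    chrom = x$chrom,
    start = x$pos,
    end = x$pos + 1L,
    mod_code = mod_code,
    score = pmin(x$coverage, 1000L),
    strand = x$strand,
    thick_start = x$pos,
    thick_end = x$pos + 1L,
    rgb = "0,0,0",
    coverage = x$coverage,
    frequency = sprintf("%.1f", 100 * x$frequency)
  )
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  if (nrow(out) > 0) {
    writeLines(do.call(paste, c(as.list(out), sep = "\t")), con)
  } else {
    writeLines(character(0), con)
  }
  invisible(path)
}

#' Read a bedMethyl (9+2) table
#'
#' @param path Path to a bedMethyl file as written by [write_bedmethyl()]
#'   (plain or gzipped).
#' @return A tibble with columns `chrom`, `pos` (0-based), `strand`,
#'   `mod_code`, `coverage` and `frequency` (proportion in `[0, 1]`).
#' @export
read_bedmethyl <- function(path) {
  cols <- c("chrom", "start", "end", "mod_code", "score", "strand",
            "thick_start", "thick_end", "rgb", "coverage", "frequency")
  x <- readr::read_tsv(path, col_names = cols, show_col_types = FALSE,
                       progress = FALSE)
  if (nrow(x) > 0 && any(x$end != x$start + 1L)) {
    abort("bedMethyl rows must span exactly one base (end = start + 1)")
  }
  tibble(chrom = as.character(x$chrom), pos = as.integer(x$start),
         strand = as.character(x$strand), mod_code = as.character(x$mod_code),
         coverage = as.integer(x$coverage),
         frequency = as.numeric(x$frequency) / 100)
}
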