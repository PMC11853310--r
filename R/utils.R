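#' @noRd
`%||%` <- function(x, y) if (is.null(x)) y else x

#' Derive a deterministic sub-seed from a pipeline seed and a string key
#'
#' All stochastic steps in the package take a single pipeline-level seed;
#' per-k-mer (or per-analysis) seeds are derived from it so that results for
#' one k-mer do not depend on how many others were processed.
#'
#' @param seed Integer pipeline seed.
#' @param key Character scalar (e.g. a 7-mer).
#' @return An integer in `[0, 2^31 - 2]`.
#' @keywords internal
#' @noRd
derive_seed <- function(seed, key) {
  codes <- utf8ToInt(key)
  h <- as.numeric(seed) %% 2147483647
  for (c in codes) h <- (h * 31 + c) %% 2147483647
  as.integer(h)
}

#' Reverse-complement a DNA/RNA sequence (returned in DNA alphabet)
#' @noRd
revcomp <- function(x) {
  chartr("ACGTU", "TGCAA", vapply(x, function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE))
}

#' Complement a vector of single bases
#' @noRd
complement_base <- function(b) chartr("ACGTU", "TGCAA", b)

#' Assert that a data frame has the given columns
#' @noRd
check_columns <- function(x, cols, what = "input") {
  missing <- setdiff(cols, names(x))
  if (length(missing) > 0) {
    abort(sprintf("%s is missing required column(s): %s",
                  what, paste(missing, collapse = ", ")))
  }
  invisible(x)
}

#' Run code with a local RNG seed, restoring the RNG state afterwards
#' @noRd
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}
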