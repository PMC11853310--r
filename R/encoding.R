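#' Encode and decode per-base modification probabilities
#'
#' Modified-base alignments store per-base modification probabilities as a
#' single byte in the `ML` auxiliary tag. A byte `b` represents the
#' probability interval `[b/256, (b+1)/256)`; the point estimate on decoding
#' is the interval midpoint `(b + 0.5)/256`. The round trip is therefore
#' accurate to within 1/256.
#'
#' @param p Numeric vector of probabilities in `[0, 1]`.
#' @param byte Integer vector of encoded bytes in `[0, 255]`.
#'
#' @return `encode_modprob()` returns an integer vector of bytes in
#'   `[0, 255]`; `decode_modprob()` returns a numeric vector of
#'   probabilities in `(0, 1)`.
#'
#' @examples
#' encode_modprob(c(0, 0.5, 1))   # 0 128 255
#' decode_modprob(128)            # 0.502
#' @export
encode_modprob <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    abort("modification probabilities must lie in [0, 1]")
  }
  as.integer(pmin(floor(p * 256), 255))
}

#' @rdname encode_modprob
#' @export
decode_modprob <- function(byte) {
  if (any(is.na(byte)) || any(byte < 0 | byte > 255) || any(byte != floor(byte))) {
    abort("encoded modification probabilities must be integers in [0, 255]")
  }
  (byte + 0.5) / 256
}
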