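# Biorthogonal analysis/synthesis filter banks.
#
# The bior5.5 taps are embedded literal constants from the standard published
# B-spline biorthogonal 5.5 construction (reconstruction order 5,
# decomposition order 5), under the convention that the analysis low-pass
# filter has DC gain sqrt(2) (sum of taps = sqrt(2)).  Their correctness is
# not re-derived from B-spline theory here; it is enforced by the
# perfect-reconstruction round-trip in the test suite.

.bior55 <- list(
  dec_lo = c(0.0, 0.0,
             0.039687088347405434, 0.007948108637240322,
             -0.05446378846823691, 0.34560528195603346,
             0.7366601814282105, 0.34560528195603346,
             -0.05446378846823691, 0.007948108637240322,
             0.039687088347405434, 0.0),
  dec_hi = c(-0.013456709459118716, -0.002694966880111507,
             0.13670658466432914, -0.09350469740093886,
             -0.47680326579848425, 0.8995061097486484,
             -0.47680326579848425, -0.09350469740093886,
             0.13670658466432914, -0.002694966880111507,
             -0.013456709459118716, 0.0),
  rec_lo = c(0.013456709459118716, -0.002694966880111507,
             -0.13670658466432914, -0.09350469740093886,
             0.47680326579848425, 0.8995061097486484,
             0.47680326579848425, -0.09350469740093886,
             -0.13670658466432914, -0.002694966880111507,
             0.013456709459118716, 0.0),
  rec_hi = c(0.0, 0.0,
             0.039687088347405434, -0.007948108637240322,
             -0.05446378846823691, -0.34560528195603346,
             0.7366601814282105, -0.34560528195603346,
             -0.05446378846823691, -0.007948108637240322,
             0.039687088347405434, 0.0)
)

.haar <- list(
  dec_lo = c(1, 1) / sqrt(2),
  dec_hi = c(-1, 1) / sqrt(2),
  rec_lo = c(1, 1) / sqrt(2),
  rec_hi = c(1, -1) / sqrt(2)
)

#' Build a wavelet filter bank
#'
#' Returns the four FIR filters (analysis low/high-pass, synthesis
#' low/high-pass) of a named biorthogonal wavelet.  `"bior5.5"` — the
#' B-spline biorthogonal pair with reconstruction order 5 and decomposition
#' order 5 — is the bank used throughout the hearing-loss classification
#' pipeline; `"haar"` is provided as a short orthogonal reference bank.
#'
#' Filters follow the convention that a constant signal passed through one
#' analysis low-pass stage is multiplied by `sqrt(2)` (i.e. the low-pass taps
#' sum to `sqrt(2)`).
#'
#' @param name Wavelet identifier, one of `"bior5.5"` or `"haar"`.
#' @return An object of class `"filter_bank"`: a list with elements `name`,
#'   `dec_lo`, `dec_hi`, `rec_lo`, `rec_hi` and `length` (the common filter
#'   length, which bounds the smallest transformable image side).
#' @examples
#' fb <- wavelet_filter_bank("bior5.5")
#' sum(fb$dec_lo)  # sqrt(2)
#' @export
wavelet_filter_bank <- function(name) {
  if (!is.character(name) || length(name) != 1L || is.na(name)) {
    stop("'name' must be a single wavelet identifier string")
  }
  taps <- switch(name,
    "bior5.5" = .bior55,
    "haar"    = .haar,
    stop(sprintf("unsupported wavelet '%s'; supported: bior5.5, haar", name))
  )
  stopifnot(all(vapply(taps, function(f) all(is.finite(f)), logical(1))),
            all(lengths(taps) >= 2L))
  structure(
    c(taps, list(name = name, length = length(taps$dec_lo))),
    class = "filter_bank"
  )
}

#' @export
print.filter_bank <- function(x, ...) {
  cat(sprintf("Wavelet filter bank '%s' (filter length %d)\n", x$name, x$length))
  cat("  dec_lo:", format(x$dec_lo, digits = 4), "\n")
  cat("  dec_hi:", format(x$dec_hi, digits = 4), "\n")
  invisible(x)
}
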