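# Wavelet-entropy feature extraction: one entropy value per subband of an
# n-level decomposition, assembled into a (3n+1)-element feature vector.

#' Shannon entropy of one wavelet subband
#'
#' The default (`"energy"`) variant is the standard wavelet-entropy
#' construction: coefficient energies are normalized into a probability
#' distribution, `p_i = c_i^2 / sum_j c_j^2`, and the Shannon entropy
#' `H = -sum_i p_i log2(p_i)` (with `0 * log 0 = 0`) is returned in bits.
#' An all-zero subband returns 0 by convention.  This variant is invariant
#' to scaling of the coefficients and to their arrangement, and is bounded
#' by `log2(M)` for `M` coefficients.
#'
#' The `"histogram"` variant instead bins the raw coefficient values into
#' `bins` equal-width bins over their range and returns the entropy of the
#' bin-count distribution.  It is offered for comparison only and is not
#' used by the default pipeline.
#'
#' @param coeffs Numeric vector or matrix of subband coefficients.
#' @param variant `"energy"` (default) or `"histogram"`.
#' @param bins Number of histogram bins for the `"histogram"` variant.
#' @return Entropy in bits (non-negative scalar).
#' @examples
#' subband_entropy(c(1, 1, sqrt(2), 0))  # energies (1,1,2,0) -> 1.5 bits
#' subband_entropy(rep(3, 8))            # uniform energies -> log2(8) = 3
#' @export
subband_entropy <- function(coeffs, variant = c("energy", "histogram"),
                            bins = 256L) {
  variant <- match.arg(variant)
  c_ <- as.numeric(coeffs)
  if (length(c_) == 0L) stop("empty subband")
  if (!all(is.finite(c_))) stop("subband contains non-finite coefficients")
  if (variant == "energy") {
    e <- c_^2
    tot <- sum(e)
    if (tot == 0) return(0)
    p <- e / tot
  } else {
    rng <- range(c_)
    if (rng[1] == rng[2]) return(0)
    cnt <- tabulate(
      findInterval(c_, seq(rng[1], rng[2], length.out = bins + 1L),
                   rightmost.closed = TRUE, all.inside = TRUE),
      nbins = bins)
    p <- cnt / length(c_)
  }
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Wavelet-entropy feature vector of one image
#'
#' Decomposes the image with [wavedec2()] and computes [subband_entropy()]
#' for every subband in the canonical coarse-to-fine order, reducing the
#' image to a `3n + 1`-element feature vector — e.g. a 256 x 256 slice at
#' `n = 3` becomes 10 numbers.
#'
#' @inheritParams wavedec2
#' @inheritParams subband_entropy
#' @return Named numeric vector of length `3n + 1` (names are the subband
#'   labels), with attributes `wavelet` and `level`.
#' @examples
#' fb <- wavelet_filter_bank("bior5.5")
#' length(wavelet_entropy(matrix(rnorm(64^2), 64, 64), fb, 3))  # 10
#' @export
wavelet_entropy <- function(img, fb, n, variant = c("energy", "histogram")) {
  variant <- match.arg(variant)
  dec <- wavedec2(img, fb, n)
  v <- vapply(dec$subbands, subband_entropy, numeric(1), variant = variant)
  structure(v, wavelet = fb$name, level = dec$level)
}

#' Wavelet-entropy features for a batch of images
#'
#' @param imgs List of image matrices.
#' @inheritParams wavelet_entropy
#' @return Numeric matrix with one row per image (input order preserved,
#'   names taken from `imgs`) and `3n + 1` labeled columns, with attributes
#'   `wavelet` and `level`.
#' @examples
#' fb <- wavelet_filter_bank("haar")
#' imgs <- replicate(3, matrix(rnorm(16^2), 16, 16), simplify = FALSE)
#' dim(wavelet_entropy_batch(imgs, fb, 2))  # 3 x 7
#' @export
wavelet_entropy_batch <- function(imgs, fb, n,
                                  variant = c("energy", "histogram")) {
  variant <- match.arg(variant)
  stopifnot(is.list(imgs))
  labels <- .canonical_labels(n)
  out <- matrix(numeric(0), nrow = 0L, ncol = length(labels),
                dimnames = list(NULL, labels))
  if (length(imgs) > 0L) {
    rows <- lapply(seq_along(imgs), function(i) {
      tryCatch(wavelet_entropy(imgs[[i]], fb, n, variant = variant),
               error = function(e) {
                 stop(sprintf("image %d: %s", i, conditionMessage(e)),
                      call. = FALSE)
               })
    })
    out <- do.call(rbind, rows)
    dimnames(out) <- list(names(imgs), labels)
  }
  structure(out, wavelet = fb$name, level = as.integer(n))
}
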