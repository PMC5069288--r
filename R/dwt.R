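# n-level 2D dyadic discrete wavelet transform (analysis + synthesis).
#
# Conventions, fixed and documented because subband shapes and entropies
# depend on them:
#   * boundary handling: half-sample symmetric extension (the edge sample is
#     repeated in the mirror image);
#   * subband length per axis: floor((N + L - 1) / 2), L = filter length;
#   * coefficient grids are stored row-major with the origin at the top-left,
#     matching the raster image convention;
#   * subband labels "XY": X is the filter applied along the vertical
#     (row) axis, Y along the horizontal (column) axis; e.g. HL = high-pass
#     vertically, low-pass horizontally.

# indices of the half-sample symmetric extension of 1..N by p on both sides
.symext_idx <- function(N, p) {
  i <- seq.int(1L - p, N + p)
  m <- (i - 1L) %% (2L * N)
  ifelse(m < N, m + 1L, 2L * N - m)
}

# decimated analysis convolution as an M x N operator matrix
.analysis_op <- function(N, g) {
  L <- length(g)
  M <- (N + L - 1L) %/% 2L
  src <- .symext_idx(N, L - 1L)      # length N + 2(L-1)
  Ne <- length(src)
  G <- matrix(0, M, Ne)
  for (i in seq_len(M)) {
    j <- (L + 2L * i) - seq_len(L)   # ext positions hit by tap 1..L
    keep <- j >= 1L & j <= Ne
    G[i, j[keep]] <- g[which(keep)]
  }
  # fold the extension back onto the N source columns
  D <- matrix(0, M, N)
  for (n in unique(src)) D[, n] <- rowSums(G[, src == n, drop = FALSE])
  D
}

# synthesis (upsample + convolve + crop) as an N x M operator matrix
.synthesis_op <- function(N, M, r) {
  L <- length(r)
  S <- matrix(0, N, M)
  for (p in seq_len(N)) {
    i <- seq_len(M)
    tap <- L + p - 2L * i
    keep <- tap >= 1L & tap <= L
    S[p, i[keep]] <- r[tap[keep]]
  }
  S
}

.check_image <- function(img, fb) {
  if (!is.matrix(img) || !is.numeric(img)) {
    stop("image must be a numeric matrix")
  }
  if (!all(is.finite(img))) stop("image contains non-finite values")
  if (min(dim(img)) < fb$length) {
    stop(sprintf("image (%d x %d) is smaller than the filter length %d",
                 nrow(img), ncol(img), fb$length))
  }
  invisible(img)
}

#' Single-level 2D discrete wavelet transform
#'
#' Separable one-level dyadic analysis: the image is filtered and
#' downsampled by 2 along rows and columns with each combination of the
#' analysis low- and high-pass filters, under half-sample symmetric boundary
#' extension.  Each output subband has `floor((N + L - 1)/2)` samples per
#' axis, where `L` is the filter length.
#'
#' @param img Numeric matrix (2D grayscale image), both dimensions at least
#'   the filter length.
#' @param fb A [wavelet_filter_bank()].
#' @return A named list of four coefficient matrices `LL`, `HL`, `LH`, `HH`
#'   (all the same shape).  In the label, the first letter is the filter
#'   applied along the vertical (row) axis.
#' @examples
#' fb <- wavelet_filter_bank("haar")
#' sb <- dwt2(matrix(1, 16, 16), fb)
#' sb$LL[1, 1]      # constant c = 1 gains sqrt(2) twice -> 2
#' max(abs(sb$HH))  # high-pass annihilates constants -> 0
#' @export
dwt2 <- function(img, fb) {
  stopifnot(inherits(fb, "filter_bank"))
  .check_image(img, fb)
  Dr_lo <- .analysis_op(nrow(img), fb$dec_lo)
  Dr_hi <- .analysis_op(nrow(img), fb$dec_hi)
  Dc_lo <- .analysis_op(ncol(img), fb$dec_lo)
  Dc_hi <- .analysis_op(ncol(img), fb$dec_hi)
  lo_v <- Dr_lo %*% img   # low-pass along vertical axis
  hi_v <- Dr_hi %*% img
  list(LL = lo_v %*% t(Dc_lo),
       HL = hi_v %*% t(Dc_lo),
       LH = lo_v %*% t(Dc_hi),
       HH = hi_v %*% t(Dc_hi))
}

# canonical coarse-to-fine subband label order for an n-level decomposition
.canonical_labels <- function(n) {
  c(paste0("LL", n),
    unlist(lapply(seq(n, 1L), function(l) paste0(c("HL", "LH", "HH"), l))))
}

#' Multilevel 2D wavelet decomposition
#'
#' Recursively applies [dwt2()] to the running approximation (`LL`) band,
#' producing the `3n + 1` subbands of an `n`-level dyadic decomposition in
#' the canonical coarse-to-fine order `LLn, HLn, LHn, HHn, HL(n-1), LH(n-1),
#' HH(n-1), ..., HL1, LH1, HH1`.
#'
#' @param img Numeric matrix (2D grayscale image).
#' @param fb A [wavelet_filter_bank()].
#' @param n Decomposition depth (positive integer).  The approximation band
#'   entering every level must still be at least the filter length per axis,
#'   otherwise an over-decomposition error is raised.
#' @return An object of class `"wavelet_decomposition"`: list with `level`,
#'   `wavelet`, `subbands` (named list of coefficient matrices in canonical
#'   order) and `sizes` (per-level input dimensions, used by [waverec2()]).
#' @examples
#' fb <- wavelet_filter_bank("bior5.5")
#' dec <- wavedec2(matrix(rnorm(64^2), 64, 64), fb, 3)
#' length(dec$subbands)  # 3*3 + 1 = 10
#' @export
wavedec2 <- function(img, fb, n) {
  stopifnot(inherits(fb, "filter_bank"))
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 1 || n != round(n)) {
    stop("'n' must be a positive integer decomposition level")
  }
  n <- as.integer(n)
  .check_image(img, fb)
  approx <- img
  sizes <- vector("list", n)
  details <- vector("list", n)
  for (l in seq_len(n)) {
    if (min(dim(approx)) < fb$length) {
      stop(sprintf(paste0("cannot decompose to level %d: the level-%d ",
                          "approximation band (%d x %d) is smaller than the ",
                          "filter length %d"),
                   n, l, nrow(approx), ncol(approx), fb$length))
    }
    sizes[[l]] <- dim(approx)
    sb <- dwt2(approx, fb)
    details[[l]] <- sb[c("HL", "LH", "HH")]
    approx <- sb$LL
  }
  subbands <- c(list(approx),
                unlist(lapply(seq(n, 1L), function(l) details[[l]]),
                       recursive = FALSE))
  names(subbands) <- .canonical_labels(n)
  structure(list(level = n, wavelet = fb$name,
                 subbands = subbands, sizes = sizes),
            class = "wavelet_decomposition")
}

#' @export
print.wavelet_decomposition <- function(x, ...) {
  cat(sprintf("%d-level 2D wavelet decomposition (%s), %d subbands\n",
              x$level, x$wavelet, length(x$subbands)))
  dims <- vapply(x$subbands, function(m) paste(dim(m), collapse = "x"),
                 character(1))
  cat(" ", paste(sprintf("%s[%s]", names(dims), dims), collapse = " "), "\n")
  invisible(x)
}

#' Inverse multilevel 2D wavelet transform
#'
#' Reconstructs the image from a [wavedec2()] decomposition using the
#' synthesis bank of `fb`.  With the matched filter bank this is a perfect
#' reconstruction up to round-off in the published filter taps.
#'
#' @param dec A `"wavelet_decomposition"` object.
#' @param fb The [wavelet_filter_bank()] used for the decomposition.
#' @return The reconstructed image matrix, with the original dimensions.
#' @examples
#' fb <- wavelet_filter_bank("bior5.5")
#' x <- matrix(rnorm(32^2), 32, 32)
#' max(abs(waverec2(wavedec2(x, fb, 2), fb) - x))  # ~1e-12
#' @export
waverec2 <- function(dec, fb) {
  stopifnot(inherits(dec, "wavelet_decomposition"), inherits(fb, "filter_bank"))
  n <- dec$level
  approx <- dec$subbands[[paste0("LL", n)]]
  for (l in seq(n, 1L)) {
    HL <- dec$subbands[[paste0("HL", l)]]
    LH <- dec$subbands[[paste0("LH", l)]]
    HH <- dec$subbands[[paste0("HH", l)]]
    if (!all(dim(HL) == dim(approx)) || !all(dim(LH) == dim(approx)) ||
        !all(dim(HH) == dim(approx))) {
      stop(sprintf("inconsistent subband shapes at level %d", l))
    }
    out_dim <- dec$sizes[[l]]
    M <- dim(approx)
    Sr_lo <- .synthesis_op(out_dim[1], M[1], fb$rec_lo)
    Sr_hi <- .synthesis_op(out_dim[1], M[1], fb$rec_hi)
    Sc_lo <- .synthesis_op(out_dim[2], M[2], fb$rec_lo)
    Sc_hi <- .synthesis_op(out_dim[2], M[2], fb$rec_hi)
    approx <- Sr_lo %*% approx %*% t(Sc_lo) +
              Sr_hi %*% HL     %*% t(Sc_lo) +
              Sr_lo %*% LH     %*% t(Sc_hi) +
              Sr_hi %*% HH     %*% t(Sc_hi)
  }
  approx
}
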