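# Synthetic brain-slice phantom cohort.
#
# Emulates skull-stripped, spatially normalized, Gaussian-smoothed 2D brain
# slices whose three classes (HC, LHL, RHL) differ by (a) the energy of a
# designated spatial-frequency band of a 1/f-type stochastic texture and
# (b) a lateralized hypointense lesion for the two patient classes.  The
# band-energy effect carries most of the class signal on purpose: wavelet
# entropy is a global, location-insensitive feature, so purely mirror-image
# lesions with identical texture would be near-indistinguishable to it.

# separable Gaussian blur with half-sample symmetric borders
.gauss_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  rad <- max(1L, ceiling(3 * sigma))
  kern <- exp(-(seq(-rad, rad))^2 / (2 * sigma^2))
  kern <- kern / sum(kern)
  blur1 <- function(N) {
    src <- .symext_idx(N, rad)
    B <- matrix(0, N, N)
    for (i in seq_len(N)) {
      cols <- src[i + rad + seq(-rad, rad)]
      for (t in seq_along(cols)) B[i, cols[t]] <- B[i, cols[t]] + kern[t]
    }
    B
  }
  blur1(nrow(img)) %*% img %*% t(blur1(ncol(img)))
}

# isotropic 1/f-type random field with a multiplicative gain on one
# spatial-frequency band (cycles/pixel), unit variance inside the full grid
.texture_field <- function(nr, nc, band = c(0.06, 0.12), band_gain = 1,
                           beta = 1, f0 = 0.01) {
  fr <- c(seq(0, floor(nr / 2)), seq(-(ceiling(nr / 2) - 1), -1)) / nr
  fc <- c(seq(0, floor(nc / 2)), seq(-(ceiling(nc / 2) - 1), -1)) / nc
  f <- sqrt(outer(fr^2, fc^2, `+`))
  amp <- 1 / (f + f0)^beta
  amp[f >= band[1] & f <= band[2]] <-
    amp[f >= band[1] & f <= band[2]] * band_gain
  z <- stats::fft(matrix(stats::rnorm(nr * nc), nr, nc))
  tex <- Re(stats::fft(z * amp, inverse = TRUE)) / (nr * nc)
  (tex - mean(tex)) / stats::sd(tex)
}

#' Phantom cohort configuration
#'
#' Defaults describe a strongly separated 49-subject cohort of 256 x 256
#' slices: 20 healthy controls (HC), 15 left- (LHL) and 14 right-sided (RHL)
#' hearing-loss subjects.
#'
#' @param image_size `c(rows, cols)`, default `c(256, 256)`.
#' @param n_per_class Named counts for `HC`, `LHL`, `RHL`
#'   (default `c(HC = 20, LHL = 15, RHL = 14)`).
#' @param effect_size Relative gain of the class-specific texture band
#'   (default 0.5): the designated 0.06–0.12 cycles/pixel band is amplified
#'   by `1 + effect_size` for LHL and attenuated by `1/(1 + effect_size)`
#'   for RHL, relative to HC.  0 removes the global class signal.
#' @param lesion_contrast Relative intensity drop of the lateralized
#'   Gaussian lesion (sigma 12 px) in the left (LHL) or right (RHL)
#'   mid-temporal region of the mask (default 0.35).  0 removes the lesion.
#' @param noise_sd Gaussian pixel-noise standard deviation on the unit
#'   intensity scale (default 0.03).
#' @param smoothing_sigma Gaussian smoothing width in pixels (default 2),
#'   emulating the smoothing step of a standard preprocessing chain.
#' @param seed Integer seed fixing every random draw (default 1).
#' @return A list of class `"phantom_config"`.
#' @export
phantom_config <- function(image_size = c(256L, 256L),
                           n_per_class = c(HC = 20L, LHL = 15L, RHL = 14L),
                           effect_size = 0.5,
                           lesion_contrast = 0.35,
                           noise_sd = 0.03,
                           smoothing_sigma = 2,
                           seed = 1L) {
  stopifnot(length(image_size) == 2L, all(image_size >= 16L),
            all(n_per_class >= 0L),
            effect_size >= 0, lesion_contrast >= 0, noise_sd >= 0,
            smoothing_sigma >= 0)
  if (is.null(names(n_per_class))) names(n_per_class) <- c("HC", "LHL", "RHL")
  structure(list(image_size = as.integer(image_size),
                 n_per_class = n_per_class,
                 effect_size = effect_size,
                 lesion_contrast = lesion_contrast,
                 noise_sd = noise_sd,
                 smoothing_sigma = smoothing_sigma,
                 seed = as.integer(seed)),
            class = "phantom_config")
}

# one phantom slice; RNG state supplies the stochastic texture and noise
.phantom_slice <- function(cfg, class) {
  nr <- cfg$image_size[1]; nc <- cfg$image_size[2]
  a <- 0.4 * nr; b <- 0.4 * nc          # ellipse semi-axes = 0.8 x extents
  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  rho2 <- ((rows - (nr + 1) / 2) / a)^2 + ((cols - (nc + 1) / 2) / b)^2
  mask <- rho2 <= 1
  base <- 0.45 + 0.3 * pmax(0, 1 - rho2)
  gain <- switch(class,
                 HC  = 1,
                 LHL = 1 + cfg$effect_size,
                 RHL = 1 / (1 + cfg$effect_size),
                 stop(sprintf("unknown class '%s'", class)))
  img <- base + 0.08 * .texture_field(nr, nc, band_gain = gain)
  if (class %in% c("LHL", "RHL") && cfg$lesion_contrast > 0) {
    lr <- (nr + 1) / 2
    lc <- (nc + 1) / 2 + (if (class == "LHL") -0.5 else 0.5) * b
    if (((lr - (nr + 1) / 2) / a)^2 + ((lc - (nc + 1) / 2) / b)^2 > 1) {
      stop("internal error: lesion centre outside the brain mask")
    }
    blob <- exp(-((rows - lr)^2 + (cols - lc)^2) / (2 * 12^2))
    img <- img * (1 - cfg$lesion_contrast * blob)
  }
  img <- img + matrix(stats::rnorm(nr * nc, sd = cfg$noise_sd), nr, nc)
  img <- .gauss_blur(img, cfg$smoothing_sigma)
  img[!mask] <- 0
  pmin(pmax(img, 0), 1)
}

#' Generate a labeled phantom cohort
#'
#' Draws `sum(n_per_class)` synthetic brain slices (see [phantom_config()]
#' for what the phantom emulates and the class effects), deterministically
#' under `cfg$seed`, and shuffles the output order (also seed-determined) so
#' classes are interleaved.
#'
#' @param cfg A [phantom_config()].
#' @return List with `images` (list of matrices, names `img_001`...),
#'   `labels` (character, aligned) and `config`.
#' @examples
#' cohort <- phantom_cohort(phantom_config(image_size = c(32, 32),
#'                                         n_per_class = c(HC = 2, LHL = 1,
#'                                                         RHL = 1)))
#' table(cohort$labels)
#' @export
phantom_cohort <- function(cfg = phantom_config()) {
  stopifnot(inherits(cfg, "phantom_config"))
  total <- sum(cfg$n_per_class)
  if (total == 0L) stop("cohort is empty: all class counts are zero")
  labels <- rep(names(cfg$n_per_class), times = cfg$n_per_class)
  images <- vector("list", total)
  ord <- integer(total)
  .with_seed(cfg$seed, {
    for (i in seq_len(total)) images[[i]] <- .phantom_slice(cfg, labels[i])
    ord <- sample(total)
  })
  images <- images[ord]
  labels <- labels[ord]
  names(images) <- sprintf("img_%03d", seq_len(total))
  list(images = images, labels = labels, config = cfg)
}

#' Write / read a cohort as grayscale PNGs plus a CSV manifest
#'
#' `write_cohort()` stores each slice as an 8-bit grayscale PNG (the
#' intensity scale is the unit interval; quantization error is at most
#' 1/255) and a `manifest.csv` with columns `file,label`.  `read_cohort()`
#' reads the manifest and returns the images in manifest order.
#'
#' @param cohort List with `images` and `labels` (as from
#'   [phantom_cohort()]).
#' @param dir Target/source directory.
#' @return `write_cohort()` the directory (invisibly); `read_cohort()` a
#'   list with `images` and `labels`.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(is.list(cohort$images), length(cohort$images) > 0L)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- sprintf("%s.png", names(cohort$images) %||%
                     sprintf("img_%03d", seq_along(cohort$images)))
  for (i in seq_along(cohort$images)) {
    png::writePNG(pmin(pmax(cohort$images[[i]], 0), 1),
                  file.path(dir, files[i]))
  }
  utils::write.csv(data.frame(file = files, label = cohort$labels,
                              stringsAsFactors = FALSE),
                   file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  manifest <- file.path(dir, "manifest.csv")
  if (!file.exists(manifest)) {
    stop(sprintf("no cohort manifest at '%s'", manifest))
  }
  man <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  images <- lapply(man$file, function(f) {
    p <- file.path(dir, f)
    if (!file.exists(p)) stop(sprintf("missing cohort image '%s'", p))
    load_image(p)
  })
  names(images) <- sub("\\.png$", "", man$file)
  list(images = images, labels = man$label)
}
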