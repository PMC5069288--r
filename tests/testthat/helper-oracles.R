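# Independent reference implementations used as oracles.  These are written
# as plain loops over explicit boundary padding / convolution / decimation,
# deliberately sharing no code with the package internals.

# half-sample symmetric extension of a vector by p samples per side
oracle_symext <- function(x, p) {
  N <- length(x)
  out <- numeric(N + 2 * p)
  for (t in seq_along(out)) {
    i <- t - p                       # index into x, possibly out of range
    m <- (i - 1) %% (2 * N)
    out[t] <- if (m < N) x[m + 1] else x[2 * N - m]
  }
  out
}

# decimated analysis convolution: explicit padding + full convolution +
# downsampling, keeping floor((N + L - 1)/2) samples from phase L+1
oracle_dwt1 <- function(x, g) {
  L <- length(g)
  N <- length(x)
  ext <- oracle_symext(x, L - 1)
  full <- numeric(length(ext) + L - 1)
  for (t in seq_along(full)) {
    acc <- 0
    for (j in seq_len(L)) {
      k <- t - j + 1
      if (k >= 1 && k <= length(ext)) acc <- acc + g[j] * ext[k]
    }
    full[t] <- acc
  }
  M <- (N + L - 1) %/% 2
  full[seq(L + 1, by = 2, length.out = M)]
}

# single-level separable 2D analysis built only on oracle_dwt1
oracle_dwt2 <- function(img, fb) {
  band <- function(gv, gh) {
    tmp <- apply(img, 2, oracle_dwt1, g = gv)          # along rows (vertical)
    t(apply(tmp, 1, oracle_dwt1, g = gh))              # along columns
  }
  list(LL = band(fb$dec_lo, fb$dec_lo),
       HL = band(fb$dec_hi, fb$dec_lo),
       LH = band(fb$dec_lo, fb$dec_hi),
       HH = band(fb$dec_hi, fb$dec_hi))
}

# synthesis: upsample-by-2 + full convolution + central crop of length N
oracle_idwt1 <- function(cA, cD, r_lo, r_hi, N) {
  L <- length(r_lo)
  up <- function(c) {
    u <- numeric(2 * length(c))
    u[seq(1, by = 2, length.out = length(c))] <- c
    u
  }
  conv1 <- function(u, r) {
    full <- numeric(length(u) + L - 1)
    for (t in seq_along(full)) {
      acc <- 0
      for (j in seq_len(L)) {
        k <- t - j + 1
        if (k >= 1 && k <= length(u)) acc <- acc + r[j] * u[k]
      }
      full[t] <- acc
    }
    full
  }
  y <- conv1(up(cA), r_lo) + conv1(up(cD), r_hi)
  y[seq(L - 1, length.out = N)]
}

# direct Shannon entropy of the normalized energy distribution
oracle_entropy <- function(coeffs) {
  e <- as.numeric(coeffs)^2
  if (sum(e) == 0) return(0)
  p <- e / sum(e)
  p <- p[p > 0]
  -sum(p * log2(p))
}

# primal objective of the soft-margin linear SVM for given (w, b)
svm_primal_objective <- function(w, b, x, ysign, cost) {
  margins <- ysign * (drop(x %*% w) - b)
  0.5 * sum(w^2) + cost * sum(pmax(0, 1 - margins))
}

# dense grid search over the 2-parameter primal (1-D features)
oracle_grid_svm_1d <- function(x, ysign, cost, wlim = c(-3, 3),
                               blim = c(-3, 3), steps = 601) {
  ws <- seq(wlim[1], wlim[2], length.out = steps)
  bs <- seq(blim[1], blim[2], length.out = steps)
  best <- Inf
  xm <- matrix(x, ncol = 1)
  for (w in ws) {
    for (b in bs) {
      obj <- svm_primal_objective(w, b, xm, ysign, cost)
      if (obj < best) best <- obj
    }
  }
  best
}

# one-vs-one majority vote over all pairwise SVMs (ties: earliest class)
oracle_ovo_vote <- function(models, class_names, x) {
  votes <- setNames(numeric(length(class_names)), class_names)
  for (nm in names(models)) {
    cl <- strsplit(nm, " vs ")[[1]]
    s <- decision_score(models[[nm]], x)
    votes[if (s >= 0) cl[1] else cl[2]] <-
      votes[if (s >= 0) cl[1] else cl[2]] + 1
  }
  class_names[which.max(votes)]
}

# small well-separated Gaussian clusters for classifier tests
make_clusters <- function(centers, n_each, sd = 0.3, seed = 1) {
  set.seed(seed)
  x <- do.call(rbind, lapply(seq_len(nrow(centers)), function(i) {
    matrix(rnorm(n_each * ncol(centers), sd = sd), n_each) +
      matrix(centers[i, ], n_each, ncol(centers), byrow = TRUE)
  }))
  list(x = x, y = rep(rownames(centers), each = n_each))
}

# the aggregate reference confusion matrix of the original 49-subject
# 10 x 10-fold hearing-loss experiment, and its per-fold counts
reference_confusion <- function() {
  read_confusion(system.file("extdata", "confusion_10x10.csv",
                             package = "wedag"))
}
reference_run_folds <- function() {
  df <- utils::read.csv(system.file("extdata", "runfolds_10x10.csv",
                                    package = "wedag"))
  list(correct = as.matrix(df[, paste0("F", 1:10)]),
       total = as.matrix(df[, paste0("T", 1:10)]))
}
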