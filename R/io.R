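# File-format plumbing: PNG / NIfTI image input, feature tables and
# confusion matrices as CSV, fitted models and CV reports as JSON.

#' Load a 2D grayscale image
#'
#' Reads a PNG (8- or 16-bit) or a NIfTI volume.  For NIfTI, one sagittal
#' slice is extracted: the sagittal axis is taken as the first voxel axis of
#' the stored array and `slice` indexes it 1-based.  RGB(A) PNGs are
#' rejected unless `rgb = "luminance"`, in which case they are converted
#' with the Rec. 601 weights (0.299, 0.587, 0.114).
#'
#' @param path Path to a `.png`, `.nii` or `.nii.gz` file.
#' @param slice Sagittal slice index (1-based) — required for 3D NIfTI.
#' @param rgb `"error"` (default) or `"luminance"`: policy for color PNGs.
#' @return Numeric matrix of intensities.
#' @export
load_image <- function(path, slice = NULL, rgb = c("error", "luminance")) {
  rgb <- match.arg(rgb)
  if (!file.exists(path)) stop(sprintf("cannot read image '%s'", path))
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    img <- png::readPNG(path)
    if (length(dim(img)) == 3L) {
      if (rgb == "error") {
        stop(sprintf("'%s' is not grayscale; pass rgb = \"luminance\" to convert",
                     path))
      }
      ch <- dim(img)[3]
      img <- 0.299 * img[, , 1] + 0.587 * img[, , 2] +
        (if (ch >= 3) 0.114 * img[, , 3] else 0)
    }
    return(unclass(img))
  }
  if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    vol <- RNifti::readNifti(path)
    arr <- as.array(vol)
    if (length(dim(arr)) == 2L) return(matrix(as.numeric(arr), dim(arr)[1]))
    if (length(dim(arr)) >= 3L) {
      if (is.null(slice)) {
        stop("3D NIfTI volume: a sagittal 'slice' index (1-based) is required")
      }
      if (slice < 1L || slice > dim(arr)[1]) {
        stop(sprintf("slice %d out of range 1..%d", slice, dim(arr)[1]))
      }
      sl <- arr[slice, , ]
      return(matrix(as.numeric(sl), nrow = dim(arr)[2]))
    }
  }
  stop(sprintf("unsupported image format: '%s' (expected .png/.nii/.nii.gz)",
               path))
}

#' Write / read a wavelet-entropy feature table as CSV
#'
#' The CSV has an optional leading `label` column followed by one column per
#' subband entropy (`LL3,HL3,...`), one row per image.
#'
#' @param features Feature matrix from [wavelet_entropy_batch()].
#' @param path CSV path.
#' @param labels Optional class labels (adds the `label` column).
#' @return `write_features()` the path, invisibly; `read_features()` a list
#'   with `features` (matrix) and `labels` (or `NULL`).
#' @export
write_features <- function(features, path, labels = NULL) {
  df <- as.data.frame(unclass(features))
  if (!is.null(labels)) {
    stopifnot(length(labels) == nrow(df))
    df <- cbind(label = as.character(labels), df)
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  labels <- NULL
  if ("label" %in% names(df)) {
    labels <- df$label
    df$label <- NULL
  }
  list(features = as.matrix(df), labels = labels)
}

#' Read a confusion matrix from CSV
#'
#' Expects a square count table whose first column holds the true-class
#' names and whose header names the predicted classes.
#'
#' @param path CSV path.
#' @return A `"confusion_matrix"`.
#' @export
read_confusion <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  as_confusion_matrix(m)
}

#' Save / load a fitted DAG-SVM as JSON
#'
#' The bundle records the class order, the error penalty, the feature
#' standardization statistics, any wavelet/level feature metadata, and every
#' pairwise model's weights and bias.
#'
#' @param model A [dag_svm()] fit.
#' @param path JSON path.
#' @return `save_dag_svm()` the path, invisibly; `load_dag_svm()` a
#'   `"dag_svm"` object.
#' @export
save_dag_svm <- function(model, path) {
  stopifnot(inherits(model, "dag_svm"))
  obj <- list(
    type = "dag_svm", class_names = model$class_names, cost = model$cost,
    standardize = model$standardize,
    center = model$center, scale = model$scale,
    wavelet = model$wavelet, level = model$level,
    models = lapply(model$models, function(m) {
      list(w = m$w, b = m$b, cost = m$cost,
           pos_class = m$pos_class, neg_class = m$neg_class)
    })
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname save_dag_svm
#' @export
load_dag_svm <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$type, "dag_svm")) {
    stop(sprintf("'%s' is not a saved DAG-SVM bundle", path))
  }
  models <- lapply(obj$models, function(m) {
    structure(list(w = as.numeric(m$w), b = m$b, cost = m$cost,
                   pos_class = m$pos_class, neg_class = m$neg_class),
              class = "linear_svm")
  })
  structure(list(class_names = obj$class_names, models = models,
                 cost = obj$cost, standardize = isTRUE(obj$standardize),
                 center = if (is.null(obj$center)) NULL else
                   as.numeric(obj$center),
                 scale = if (is.null(obj$scale)) NULL else
                   as.numeric(obj$scale),
                 wavelet = obj$wavelet, level = obj$level),
            class = "dag_svm")
}

#' Export a cross-validation result as JSON and CSV tables
#'
#' Writes `report.json` (the full result), `per_run.csv` (fold-by-fold
#' correct/total counts with per-run accuracies), `confusion.csv` (the
#' aggregate confusion matrix) and `class_metrics.csv` (per-class
#' one-vs-rest metrics, percent, 2 decimals) into `dir`.
#'
#' @param cv A [cv_dag_svm()] result.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_cv_report <- function(cv, dir) {
  stopifnot(inherits(cv, "dag_svm_cv"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  runs <- nrow(cv$fold_correct)
  per_run <- data.frame(run = seq_len(runs))
  for (f in seq_len(ncol(cv$fold_correct))) {
    per_run[[paste0("F", f)]] <-
      sprintf("%d (%d)", cv$fold_correct[, f], cv$fold_total[, f])
  }
  per_run$correct <- rowSums(cv$fold_correct)
  per_run$total <- rowSums(cv$fold_total)
  per_run$accuracy <- round(cv$per_run_accuracy, 2)
  utils::write.csv(per_run, file.path(dir, "per_run.csv"), row.names = FALSE)
  cm <- as.data.frame(unclass(cv$confusion))
  utils::write.csv(cbind(class = rownames(cm), cm),
                   file.path(dir, "confusion.csv"), row.names = FALSE)
  met <- class_metrics(cv$confusion)
  met[, -1] <- round(met[, -1], 2)
  utils::write.csv(met, file.path(dir, "class_metrics.csv"),
                   row.names = FALSE)
  jsonlite::write_json(list(
    config = cv$config,
    fold_correct = cv$fold_correct, fold_total = cv$fold_total,
    per_run_accuracy = cv$per_run_accuracy,
    mean_accuracy = cv$mean_accuracy,
    confusion = list(classes = rownames(cv$confusion),
                     counts = unclass(cv$confusion)),
    class_metrics = class_metrics(cv$confusion),
    overall_accuracy = overall_accuracy(cv$confusion)
  ), file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA,
  matrix = "rowmajor")
  invisible(dir)
}
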