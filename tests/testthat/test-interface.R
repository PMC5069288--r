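test_that("PNG images load as matrices; color policy is enforced", {
  dir <- withr::local_tempdir()
  gray <- matrix(runif(32 * 40), 32, 40)
  p_gray <- file.path(dir, "gray.png")
  png::writePNG(gray, p_gray)
  got <- load_image(p_gray)
  expect_identical(dim(got), c(32L, 40L))
  expect_lte(max(abs(got - gray)), 1 / 255)
  rgbimg <- array(runif(16 * 16 * 3), c(16, 16, 3))
  p_rgb <- file.path(dir, "rgb.png")
  png::writePNG(rgbimg, p_rgb)
  expect_error(load_image(p_rgb), "not grayscale")
  lum <- load_image(p_rgb, rgb = "luminance")
  expect_identical(dim(lum), c(16L, 16L))
  want <- 0.299 * rgbimg[, , 1] + 0.587 * rgbimg[, , 2] + 0.114 * rgbimg[, , 3]
  expect_lte(max(abs(lum - want)), 3 / 255)
  expect_error(load_image(file.path(dir, "absent.png")), "cannot read")
})

test_that("NIfTI volumes yield the requested sagittal slice", {
  dir <- withr::local_tempdir()
  vol <- array(seq_len(10 * 12 * 8) / (10 * 12 * 8), c(10, 12, 8))
  p <- file.path(dir, "vol.nii.gz")
  RNifti::writeNifti(RNifti::asNifti(vol), p)
  sl <- load_image(p, slice = 4)
  expect_identical(dim(sl), c(12L, 8L))
  expect_equal(sl, vol[4, , ], ignore_attr = TRUE, tolerance = 1e-6)
  expect_error(load_image(p), "slice")
  expect_error(load_image(p, slice = 11), "out of range")
})

test_that("feature tables and models round-trip through CSV/JSON", {
  dir <- withr::local_tempdir()
  fb <- wavelet_filter_bank("bior5.5")
  cohort <- phantom_cohort(phantom_config(image_size = c(48, 48),
                                          n_per_class = c(HC = 4, LHL = 3,
                                                          RHL = 3),
                                          seed = 4))
  feats <- wavelet_entropy_batch(cohort$images, fb, 2)
  fcsv <- file.path(dir, "features.csv")
  write_features(feats, fcsv, labels = cohort$labels)
  back <- read_features(fcsv)
  expect_identical(back$labels, cohort$labels)
  expect_equal(back$features, feats, tolerance = 1e-12, ignore_attr = TRUE)
  expect_identical(colnames(back$features), colnames(feats))
  fit <- dag_svm(feats, cohort$labels, cost = 0.05)
  mjson <- file.path(dir, "model.json")
  save_dag_svm(fit, mjson)
  fit2 <- load_dag_svm(mjson)
  expect_identical(fit2$class_names, fit$class_names)
  expect_identical(predict(fit2, unclass(feats)), predict(fit, unclass(feats)))
  expect_error(load_dag_svm(fcsv))
})

test_that("the CLI pipeline runs end to end on a small cohort", {
  dir <- withr::local_tempdir()
  cohort_dir <- file.path(dir, "cohort")
  suppressMessages({
    wedag_cli(c("synth", "--out", cohort_dir, "--size", "48", "--seed", "2"))
    wedag_cli(c("extract", "--in", cohort_dir, "--level", "2",
                "--out", file.path(dir, "features.csv")))
    wedag_cli(c("train", "--features", file.path(dir, "features.csv"),
                "--out", file.path(dir, "model.json")))
    wedag_cli(c("predict", "--model", file.path(dir, "model.json"),
                "--features", file.path(dir, "features.csv"),
                "--out", file.path(dir, "pred.csv"), "--trace"))
    wedag_cli(c("cv", "--features", file.path(dir, "features.csv"),
                "--out", file.path(dir, "cv"), "--k", "7", "--runs", "2",
                "--seed", "3"))
  })
  expect_length(list.files(cohort_dir, pattern = "\\.png$"), 49)
  feats <- read_features(file.path(dir, "features.csv"))
  expect_identical(dim(feats$features), c(49L, 7L))
  pred <- utils::read.csv(file.path(dir, "pred.csv"))
  expect_identical(nrow(pred), 49L)
  expect_true(all(pred$prediction %in% c("HC", "LHL", "RHL")))
  expect_true(all(grepl("vs", pred$trace)))
  report <- jsonlite::read_json(file.path(dir, "cv", "report.json"),
                                simplifyVector = TRUE)
  expect_equal(sum(unlist(report$confusion$counts)), 2 * 49)
  expect_true(file.exists(file.path(dir, "cv", "per_run.csv")))
  expect_true(file.exists(file.path(dir, "cv", "class_metrics.csv")))
})

test_that("the metrics subcommand reproduces the reference per-class table", {
  dir <- withr::local_tempdir()
  out <- file.path(dir, "metrics.csv")
  suppressMessages(
    wedag_cli(c("metrics", "--confusion",
                system.file("extdata", "confusion_10x10.csv",
                            package = "wedag"),
                "--out", out)))
  met <- utils::read.csv(out)
  expect_identical(met$class, c("HC", "LHL", "RHL"))
  expect_equal(met$sensitivity, c(97.00, 94.00, 93.57))
  expect_equal(met$specificity, c(96.55, 97.35, 98.57))
  expect_equal(met$precision,   c(95.10, 94.00, 96.32))
  expect_equal(met$accuracy,    c(96.73, 96.33, 97.14))
  expect_equal(unique(met$overall_accuracy), 95.10)
})

test_that("bad CLI invocations fail loudly", {
  expect_error(suppressMessages(wedag_cli(c("frobnicate"))), "unknown command")
  expect_error(suppressMessages(wedag_cli(c("train", "--out", "x.json"))),
               "--features")
})
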