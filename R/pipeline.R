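#' @include ensemble.R
NULL

#' Read and write plain-text PGM images
#'
#' Minimal portable-graymap (P2, plain text) I/O used at the command-line
#' boundary; in memory every image is a plain numeric matrix in [0, 255].
#' Masks are written as 0/255 images.
#'
#' @param path file path.
#' @return \code{readPGM} returns a numeric matrix.
#' @export
readPGM <- function(path) {
  txt <- readLines(path)
  txt <- txt[!grepl("^#", txt)]
  tok <- scan(text = paste(txt, collapse = " "), what = character(),
              quiet = TRUE)
  .stopIfNot(tok[1L] == "P2", "only plain-text P2 PGM is supported")
  w <- as.integer(tok[2L]); h <- as.integer(tok[3L])
  vals <- as.numeric(tok[-(1:4)])
  .stopIfNot(length(vals) == w * h, "corrupt PGM payload")
  matrix(vals, nrow = h, ncol = w, byrow = TRUE)
}

#' @rdname readPGM
#' @param img numeric matrix in [0, 255] (rounded on write).
#' @export
writePGM <- function(img, path) {
  .assertImage(img)
  v <- round(t(img))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(img), nrow(img)), "255"), con)
  writeLines(apply(matrix(v, ncol(img), nrow(img)), 2L, paste,
                   collapse = " "), con)
  invisible(path)
}

#' Pipeline configuration
#'
#' Collects every stage's parameters with the published values as defaults.
#'
#' @param enhance an [enhanceParams()].
#' @param augment an [augmentSet()].
#' @param roiDelta,roiMinRegion,roiConnectivity dynamic-threshold and
#'   region-growing parameters.
#' @param glcmLevels descriptor quantisation levels.
#' @param bank a [modelBankConfig()].
#' @param ensembleThresholds accuracy thresholds for the stacked models
#'   (default c(90, 93, 95)).
#' @param featureSelections list of argument lists for [selectFeatures()].
#' @param kValues K-fold sweep fold counts.
#' @param testFraction held-out fraction for the split.
#' @param nPerClass phantoms per class when simulating.
#' @param augmentFirst run augmentation before segmentation (default TRUE,
#'   the published ordering); FALSE segments first (ablation).
#' @param seed global seed.
#' @return a list with class \code{mammocadPipelineConfig}.
#' @export
pipelineConfig <- function(enhance = enhanceParams(), augment = augmentSet(),
                           roiDelta = 10, roiMinRegion = 10,
                           roiConnectivity = 8L, glcmLevels = 64L,
                           bank = modelBankConfig(),
                           ensembleThresholds = c(90, 93, 95),
                           featureSelections = list(
                             list(method = "rf_importance", threshold = 0.045),
                             list(method = "univariate", k = 12L),
                             list(method = "correlation", threshold = 0.01),
                             list(method = "pca", k = 10L),
                             list(method = "wrapper", threshold = 0.01)),
                           kValues = c(3L, 4L, 5L, 7L, 10L, 12L, 15L, 18L,
                                       20L, 22L, 25L, 30L),
                           testFraction = 0.2, nPerClass = 30L,
                           augmentFirst = TRUE, seed = 1L) {
  structure(list(enhance = enhance, augment = augment, roiDelta = roiDelta,
                 roiMinRegion = roiMinRegion,
                 roiConnectivity = as.integer(roiConnectivity),
                 glcmLevels = as.integer(glcmLevels), bank = bank,
                 ensembleThresholds = ensembleThresholds,
                 featureSelections = featureSelections,
                 kValues = as.integer(kValues),
                 testFraction = testFraction,
                 nPerClass = as.integer(nPerClass),
                 augmentFirst = isTRUE(augmentFirst),
                 seed = as.integer(seed)),
            class = "mammocadPipelineConfig")
}

#' Run the full pipeline on a phantom dataset
#'
#' Executes simulate, preprocess, augment, segment, extract-features, split,
#' train, stack, select-features and the K-fold sweep in order, writing every
#' table and a JSON report into \code{outDir}. Deterministic for a fixed
#' config (including its seed).
#'
#' @param config a [pipelineConfig()].
#' @param outDir output directory (created; default a fresh temporary
#'   directory).
#' @param verbose print stage progress.
#' @return (invisibly) a list with the feature table, the bank report, the
#'   stacked-model metrics, the feature-selection summary, the K-fold sweep
#'   and the output directory.
#' @examples
#' \donttest{res <- runPipeline(pipelineConfig(nPerClass = 4L,
#'   kValues = c(3L, 4L)))}
#' @export
runPipeline <- function(config = pipelineConfig(),
                        outDir = tempfile("mammocad_run_"), verbose = TRUE) {
  stopifnot(inherits(config, "mammocadPipelineConfig"))
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (verbose) message(sprintf(...))

  say("simulate: %d phantoms/class", config$nPerClass)
  ds <- generatePhantomDataset(nPerClass = config$nPerClass,
                               seed = config$seed)

  say("preprocess: %d images", length(ds$truths))
  pre <- lapply(ds$truths, function(t)
    preprocessImage(phantomImage(t), config$enhance))
  pre <- lapply(pre, function(x) { attributes(x)[c("breastMask", "lines")] <- NULL; x })

  if (config$augmentFirst) {
    say("augment: x8")
    aug <- augmentDataset(pre, ds$labels, config$augment)
    images <- aug$images; labels <- aug$labels
  } else {
    images <- pre; labels <- ds$labels
  }

  say("segment: %d images", length(images))
  rois <- vector("list", length(images))
  ok <- logical(length(images))
  for (i in seq_along(images)) {
    r <- tryCatch(extractROI(images[[i]], delta = config$roiDelta,
                             minRegion = config$roiMinRegion,
                             connectivity = config$roiConnectivity),
                  error = function(e) e)
    if (!inherits(r, "error")) { rois[[i]] <- r; ok[i] <- TRUE }
  }
  say("segment: %d/%d succeeded", sum(ok), length(ok))

  if (!config$augmentFirst) {
    # ablation ordering: augment the segmented ROI images; the mask of an
    # augmented ROI is its non-zero support (background is exactly 0)
    say("augment (post-segmentation): x8")
    aug <- augmentDataset(lapply(rois[ok], roiImage), labels[ok],
                          config$augment)
    rois <- lapply(aug$images, function(im) {
      m <- im > 0
      sd <- which(m, arr.ind = TRUE)[1L, ]
      new("ROIResult", mask = m, seed = as.integer(sd),
          diagnostics = new("ThresholdDiagnostics", maxIntensity = max(im),
                            nearMaxIntensity = max(im), countMax = 1L,
                            countNearMax = 0L, chosenThreshold = max(im),
                            ruleFired = "MAX_SUFFICIENT"),
          roiImage = im)
    })
    labels <- aug$labels
    ok <- rep(TRUE, length(rois))
  }

  say("extract features")
  tab <- buildFeatureTable(rois[ok], labels[ok],
                           glcmLevels = config$glcmLevels)
  write.csv(tab, file.path(outDir, "features.csv"), row.names = FALSE)

  sp <- splitDataset(tab, testFraction = config$testFraction,
                     seed = config$seed)
  norm <- minmaxNormalize(sp$train)
  trainN <- norm$table
  testN <- applyNormalization(sp$test, norm$ranges)

  say("train bank: %d members", length(config$bank$members))
  bank <- trainBank(trainN, testN, config$bank)
  write.csv(bankMetrics(bank), file.path(outDir, "bank_metrics.csv"),
            row.names = FALSE)

  say("stack ensembles at thresholds %s",
      paste(config$ensembleThresholds, collapse = "/"))
  stacks <- list()
  for (th in config$ensembleThresholds) {
    spec <- tryCatch(selectByAccuracy(bank, th), error = function(e) e)
    if (inherits(spec, "error")) {
      say("  threshold %g: %s", th, conditionMessage(spec))
      next
    }
    st <- trainStacked(trainN, testN, spec, config$bank)
    stacks[[as.character(th)]] <- st$metrics
  }
  stackTab <- do.call(rbind, c(stacks, make.row.names = FALSE))
  if (!is.null(stackTab))
    write.csv(stackTab, file.path(outDir, "stacked_metrics.csv"),
              row.names = FALSE)

  bestSpec <- tryCatch(
    selectByAccuracy(bank, max(config$ensembleThresholds)),
    error = function(e) selectByAccuracy(bank, 0))

  say("feature selection: %d methods", length(config$featureSelections))
  fsRows <- list()
  for (fsArgs in config$featureSelections) {
    sel <- do.call(selectFeatures,
                   c(list(train = trainN), fsArgs,
                     list(seed = config$bank$seed)))
    trSel <- applyFeatureSelection(sel, trainN)
    teSel <- applyFeatureSelection(sel, testN)
    st <- trainStacked(trSel, teSel, bestSpec, config$bank)
    fsRows[[length(fsRows) + 1L]] <- data.frame(
      method = sel$method,
      configuration = if (!is.null(sel$threshold))
        sprintf("threshold %g", sel$threshold) else sprintf("k %d", sel$k),
      n_features = length(sel$selected),
      test_acc = st$metrics$test_acc, mcc = st$metrics$test_mcc,
      f1 = st$metrics$test_f1, auc = st$metrics$auc)
  }
  fsTab <- do.call(rbind, c(fsRows, make.row.names = FALSE))
  write.csv(fsTab, file.path(outDir, "feature_selection.csv"),
            row.names = FALSE)

  say("k-fold sweep: %d K values", length(config$kValues))
  normAll <- minmaxNormalize(tab)
  sweep <- kfoldSweep(normAll$table, "DT", config$kValues, config$bank)
  write.csv(sweep, file.path(outDir, "kfold_sweep.csv"), row.names = FALSE)

  report <- list(
    n_images = length(ds$truths),
    n_augmented = length(images),
    n_rois = sum(ok),
    bank = bankMetrics(bank),
    stacked = stackTab,
    feature_selection = fsTab,
    kfold = sweep,
    seed = config$seed)
  jsonlite::write_json(report, file.path(outDir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  files <- list.files(outDir, full.names = TRUE)
  manifest <- data.frame(file = basename(files),
                         md5 = as.character(tools::md5sum(files)))
  write.csv(manifest, file.path(outDir, "manifest.csv"), row.names = FALSE)

  invisible(list(features = tab, bank = bank, stacked = stackTab,
                 featureSelection = fsTab, kfold = sweep, outDir = outDir))
}
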