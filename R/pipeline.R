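# End-to-end drivers and configuration plumbing: synth -> extract ->
# classify, with CSV as the interchange format between extraction and
# classification and JSON for evaluation reports.

#' Default pipeline configuration
#'
#' A nested list with one section per stage; every field has the package
#' default.  \code{\link{readPipelineConfig}} merges a JSON or YAML
#' document over these defaults and rejects unknown keys.
#'
#' @return named list with sections \code{preprocess}, \code{indicators},
#'   \code{features}, \code{classify}, \code{synth}.
#' @export
pipelineConfig <- function() {
  list(
    preprocess = list(channelPolicy = "green", waveletLevel = 7L,
                      sigmas = 1:8, darkRidges = TRUE, responseFloor = 1e-3),
    indicators = list(nBins = 180L, magPercentile = 0.75,
                      angles = seq(0, 315, by = 45), minLen = 21L,
                      window = 5L),
    features = list(prominenceFrac = 0.1, angDerivTol = 0.2,
                    disDerivTol = 0.05, curPeakFloor = 0.02),
    classify = list(models = c("svm_poly", "svm_rbf", "knn", "rf"),
                    folds = 10L, seed = 1L, gridSearch = FALSE),
    synth = unclass(synthConfig()))
}

.mergeConfig <- function(defaults, user, path = "") {
  for (key in names(user)) {
    full <- if (nzchar(path)) paste0(path, ".", key) else key
    if (!key %in% names(defaults))
      stop("unknown configuration key: ", full)
    if (is.list(defaults[[key]]) && !is.list(user[[key]]))
      stop("configuration key ", full, " must be a section")
    defaults[[key]] <- if (is.list(defaults[[key]]))
      .mergeConfig(defaults[[key]], user[[key]], full)
    else user[[key]]
  }
  defaults
}

#' Read a pipeline configuration file
#'
#' Parses a JSON (\code{.json}) or YAML (\code{.yml}/\code{.yaml}) document
#' and merges it over \code{\link{pipelineConfig}}; unknown keys raise an
#' error.
#'
#' @param path configuration file path.
#' @return merged configuration list.
#' @export
readPipelineConfig <- function(path) {
  ext <- tolower(tools::file_ext(path))
  user <- switch(ext,
    json = jsonlite::fromJSON(path, simplifyVector = TRUE),
    yml = ,
    yaml = yaml::read_yaml(path),
    stop("unsupported configuration format: .", ext))
  .mergeConfig(pipelineConfig(), user)
}

#' Compute the 24 features of a single frame
#'
#' Convenience composition preprocess -> indicators -> features for one
#' image.
#'
#' @param frame as accepted by \code{\link{toGray}}.
#' @param config a \code{\link{pipelineConfig}} list.
#' @return named numeric vector of the 24 features.
#' @export
imageFeatures <- function(frame, config = pipelineConfig()) {
  pp <- do.call(preprocessFrame, c(list(frame = frame), config$preprocess))
  ind <- do.call(computeIndicators, c(list(pp = pp), config$indicators))
  do.call(extractFeatures, c(list(ind = ind), config$features))
}

#' Extract the feature table of a set of images
#'
#' Runs the full feature-extraction chain on every image and assembles the
#' feature table (columns \code{id}, \code{label}, \code{F1}..\code{F24}).
#' Per-image failures are logged as warnings and the image is skipped;
#' only zero readable inputs is an error.
#'
#' @param imagePaths character vector of image files, or a directory
#'   containing a \code{manifest.csv} written by \code{\link{genDataset}}.
#' @param labels optional character vector of class labels (recycled
#'   \code{NA} when missing); ignored when a manifest supplies them.
#' @param out optional CSV path; when given the table is also written.
#' @param config a \code{\link{pipelineConfig}} list.
#' @return the feature table data.frame.
#' @export
runExtract <- function(imagePaths, labels = NULL, out = NULL,
                       config = pipelineConfig()) {
  if (length(imagePaths) == 1L && dir.exists(imagePaths)) {
    manifest <- read.csv(file.path(imagePaths, "manifest.csv"),
                         stringsAsFactors = FALSE)
    labels <- manifest$label
    imagePaths <- file.path(imagePaths, manifest$filename)
  }
  if (!length(imagePaths)) stop("no input images")
  if (is.null(labels)) labels <- rep(NA_character_, length(imagePaths))
  rows <- vector("list", length(imagePaths))
  for (i in seq_along(imagePaths)) {
    fv <- tryCatch(
      imageFeatures(readFrame(imagePaths[i]), config),
      error = function(e) {
        warning("skipping ", imagePaths[i], ": ", conditionMessage(e),
                call. = FALSE)
        NULL
      })
    if (is.null(fv)) next
    rows[[i]] <- data.frame(id = basename(imagePaths[i]),
                            label = labels[i], t(fv),
                            stringsAsFactors = FALSE)
  }
  rows <- Filter(Negate(is.null), rows)
  if (!length(rows)) stop("no readable input images")
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  if (!is.null(out)) write.csv(tab, out, row.names = FALSE)
  tab
}

#' Cross-validated classification of a feature table
#'
#' Evaluates the requested classifier kinds on a feature table (as
#' produced by \code{\link{runExtract}}), optionally after a grid search,
#' and writes the reports.
#'
#' @param features a feature table data.frame or a CSV path; must contain
#'   a \code{label} column and the \code{F1}..\code{F24} columns.
#' @param models classifier kinds to run.
#' @param folds,seed cross-validation controls.
#' @param gridSearch when \code{TRUE}, hyperparameters are tuned with
#'   \code{\link{gridSearchCV}} first; otherwise the reference defaults of
#'   \code{\link{classifierConfig}} are used.
#' @param outDir optional directory; per-model \code{report_<kind>.json}
#'   and \code{confusion_<kind>.csv} files are written there.
#' @return named list of \code{\linkS4class{EvalReport}} objects.
#' @export
runClassify <- function(features, models = c("svm_poly", "svm_rbf",
                                             "knn", "rf"),
                        folds = 10L, seed = 1L, gridSearch = FALSE,
                        outDir = NULL) {
  if (is.character(features)) {
    nf <- utils::count.fields(features, sep = ",", quote = "\"")
    nf <- nf[!is.na(nf)]
    if (length(nf) && any(nf != nf[1]))
      stop("malformed feature CSV '", features, "': line ",
           which(nf != nf[1])[1], " has ", nf[nf != nf[1]][1],
           " fields, expected ", nf[1])
    tab <- tryCatch(read.csv(features, stringsAsFactors = FALSE),
                    error = function(e)
                      stop("malformed feature CSV '", features, "': ",
                           conditionMessage(e)))
  } else tab <- features
  if (!"label" %in% names(tab))
    stop("feature table has no 'label' column")
  missing <- setdiff(featureNames(), names(tab))
  if (length(missing))
    stop("feature table lacks columns: ", paste(missing, collapse = ", "))
  X <- as.matrix(tab[, featureNames()])
  y <- tab$label
  models <- match.arg(models, c("svm_poly", "svm_rbf", "knn", "rf"),
                      several.ok = TRUE)
  if (!is.null(outDir) && !dir.exists(outDir))
    dir.create(outDir, recursive = TRUE)
  reports <- list()
  for (kind in models) {
    config <- if (gridSearch)
      gridSearchCV(X, y, kind, folds = folds, seed = seed)
    else classifierConfig(kind)
    rep <- evaluateCV(X, y, config, folds = folds, seed = seed)
    reports[[kind]] <- rep
    if (!is.null(outDir)) {
      jsonlite::write_json(
        list(kind = kind, metrics = as.list(metrics(rep)),
             bestParams = rep@bestParams, folds = rep@folds,
             seed = rep@seed),
        file.path(outDir, paste0("report_", kind, ".json")),
        auto_unbox = TRUE, digits = NA)
      write.csv(as.data.frame(confusion(rep)),
                file.path(outDir, paste0("confusion_", kind, ".csv")),
                row.names = FALSE)
    }
  }
  reports
}

#' Run the whole pipeline: synthesize, extract, classify
#'
#' Generates the synthetic dataset, extracts the feature table and
#' evaluates the classifiers.  With fixed seeds the feature CSV and the
#' report JSONs are byte-identical across runs.
#'
#' @param dir working directory for images, feature CSV and reports.
#' @param config a \code{\link{pipelineConfig}} list.
#' @return list with elements \code{features} (data.frame) and
#'   \code{reports} (list of \code{\linkS4class{EvalReport}}).
#' @export
runPipeline <- function(dir, config = pipelineConfig()) {
  cfg <- do.call(synthConfig, config$synth)
  imgDir <- file.path(dir, "images")
  genDataset(cfg, imgDir)
  tab <- runExtract(imgDir, out = file.path(dir, "features.csv"),
                    config = config)
  reports <- runClassify(tab, models = config$classify$models,
                         folds = config$classify$folds,
                         seed = config$classify$seed,
                         gridSearch = isTRUE(config$classify$gridSearch),
                         outDir = file.path(dir, "reports"))
  list(features = tab, reports = reports)
}
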