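# End-to-end orchestration: rate search -> decimation -> segment-count
# selection -> center fit -> full-resolution thresholding -> optional
# small-neighborhood refinement.

#' Pipeline configuration
#'
#' Collects every tunable of the full segmentation flow. Defaults follow
#' the method's stated operating point: entropy-loss interval
#' `[0.01, 0.02]`, single-peak threshold `xiH = 0.015`, threshold weight
#' `beta = 0.5`.
#'
#' @param deltaMin,deltaMax feasibility interval for relative entropy loss.
#' @param stepFactor variable-step search factor in `(0, 1)`.
#' @param etaInit initial sampling rate.
#' @param S0 minimum decimated side length (pixels).
#' @param alphaRange candidate segment counts.
#' @param r fuzzy weight exponent.
#' @param tol membership convergence tolerance.
#' @param maxIter center-fit iteration cap.
#' @param beta threshold weight on the lower center.
#' @param epsilon,K,stride small-neighborhood clustering radius, neighbor
#'   count and pixel stride.
#' @param band half-width (gray levels) of the threshold band refined by
#'   clustering in hybrid mode.
#' @param mode `"hybrid"` (thresholds + clustering refinement in the
#'   threshold band), `"threshold"` (pure thresholding) or `"snc"` (pure
#'   feature-space clustering).
#' @param xiH single-peak prominence threshold.
#' @param seed integer seed for any randomized step.
#' @return A list of class `PipelineConfig`.
#' @export
osncConfig <- function(deltaMin = 0.01, deltaMax = 0.02, stepFactor = 0.5,
                       etaInit = 0.5, S0 = 32, alphaRange = 2:9, r = 2,
                       tol = 1e-5, maxIter = 300, beta = 0.5,
                       epsilon = 0.1, K = 3, stride = 2, band = 5,
                       mode = c("hybrid", "threshold", "snc"),
                       xiH = 0.015, seed = 1) {
  mode <- match.arg(mode)
  cfg <- list(deltaMin = deltaMin, deltaMax = deltaMax,
              stepFactor = stepFactor, etaInit = etaInit, S0 = S0,
              alphaRange = as.integer(alphaRange), r = r, tol = tol,
              maxIter = as.integer(maxIter), beta = beta, epsilon = epsilon,
              K = as.integer(K), stride = as.integer(stride), band = band,
              mode = mode, xiH = xiH, seed = as.integer(seed))
  stopifnot(cfg$deltaMin > 0, cfg$deltaMin < cfg$deltaMax,
            cfg$stepFactor > 0, cfg$stepFactor < 1,
            cfg$beta >= 0, cfg$beta <= 1, cfg$r > 1, cfg$epsilon > 0)
  structure(cfg, class = "PipelineConfig")
}

#' Read a pipeline configuration from YAML
#'
#' Any key accepted by [osncConfig()] may appear; missing keys keep their
#' defaults. Nested sections (`sampling:`, `fcm:`, `snc:`) are flattened.
#'
#' @param path YAML file path.
#' @return A `PipelineConfig`.
#' @export
readOSNCConfig <- function(path) {
  if (!file.exists(path)) stop("cannot read config: ", path, call. = FALSE)
  y <- yaml::read_yaml(path)
  flat <- list()
  for (nm in names(y)) {
    if (is.list(y[[nm]])) flat <- c(flat, y[[nm]]) else flat[[nm]] <- y[[nm]]
  }
  known <- names(formals(osncConfig))
  bad <- setdiff(names(flat), known)
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "), call. = FALSE)
  do.call(osncConfig, flat)
}

# Refine only the pixels whose gray value lies within `band` levels of a
# threshold: cluster their feature vectors by epsilon-chain growth and move
# each refined pixel to the threshold label most of its cluster falls in.
refineBand <- function(image, mask, J, config) {
  m <- asGrayMatrix(image)
  inBand <- Reduce(`|`, lapply(J, function(j) abs(m - j) <= config$band))
  if (sum(inBand) < 4L) return(list(mask = mask, refined = 0L))
  stack <- extractFeatures(m)
  feats <- matrix(stack@values, length(m), dim(stack@values)[3])
  bandIdx <- which(inBand)
  train <- bandIdx[seq(1L, length(bandIdx), by = config$stride)]
  model <- discoverClasses(feats[train, , drop = FALSE],
                           sncParams(config$epsilon, config$K))
  D <- classDistanceMatrix(feats[bandIdx, , drop = FALSE], model)
  cls <- max.col(-D, ties.method = "first")
  newMask <- mask
  for (i in seq_len(model@n)) {
    members <- bandIdx[cls == i]
    if (!length(members)) next
    votes <- tabulate(mask[members] + 1L)
    newMask[members] <- which.max(votes) - 1L
  }
  list(mask = newMask, refined = sum(newMask != mask))
}

#' Run the full segmentation pipeline
#'
#' Stages, in order: (1) the variable-step search picks a sampling rate
#' whose relative entropy loss lies in the configured interval, clamped so
#' the decimated short side keeps at least `S0` pixels; (2) the image is
#' decimated at that rate; (3) the fuzzy-correlation validity sweep on the
#' decimated image selects the segment count `alpha*`; (4) centers are
#' fitted at `alpha*` on the decimated image and the resulting thresholds
#' are applied to the FULL-resolution image (decimation only influences
#' parameter estimation); (5) in hybrid mode, pixels within `band` gray
#' levels of a threshold are re-labeled by small-neighborhood clustering of
#' their feature vectors. A constant (single-level) image short-circuits to
#' a single-label mask with the degeneracy flagged in the report.
#'
#' @param image a [GrayImage-class], numeric matrix, or path readable by
#'   [readGrayImage()].
#' @param config a [osncConfig()].
#' @return A list with `mask` (integer label matrix) and `report` (list:
#'   `etaO`, `samplingTrace`, `alphaStar`, `validity`, `centers`,
#'   `thresholds`, `iterations`, `converged`, `unimodal`, `degenerate`,
#'   `refinedPixels`, `timings`, `config`).
#' @examples
#' scene <- generateScene(sceneSpec(64, 64, nObjects = 1, noiseSigma = 2))
#' out <- runOSNC(sceneImage(scene), osncConfig(alphaRange = 2:4))
#' out$report$alphaStar
#' @export
runOSNC <- function(image, config = osncConfig()) {
  if (is.character(image)) image <- readGrayImage(image)
  m <- asGrayMatrix(image)
  t0 <- proc.time()[["elapsed"]]
  report <- list(config = config)
  degenerate <- length(unique(as.vector(m))) < 2L

  trace <- variableStepSearch(m, config$deltaMin, config$deltaMax,
                              config$stepFactor, config$etaInit,
                              S0 = config$S0)
  report$etaO <- trace@etaO
  report$samplingTrace <- trace
  sample <- resampleImage(m, trace@etaO)
  report$unimodal <- isUnimodal(histogramProbs(sample), config$xiH)
  t1 <- proc.time()[["elapsed"]]

  if (degenerate) {
    report$degenerate <- TRUE
    report$alphaStar <- 1L
    report$centers <- mean(m)
    report$thresholds <- numeric(0)
    report$timings <- c(sampling = t1 - t0, selection = 0, segmentation = 0)
    return(list(mask = matrix(0L, nrow(m), ncol(m)), report = report))
  }
  report$degenerate <- FALSE

  if (config$mode == "snc") {
    stack <- extractFeatures(m)
    flat <- flattenSamples(stack, config$stride)
    model <- discoverClasses(flat$features,
                             sncParams(config$epsilon, config$K,
                                       maxClasses = max(config$alphaRange)))
    mask <- segmentImage(stack, model)
    report$alphaStar <- model@n
    report$centers <- model@classMeans
    report$thresholds <- numeric(0)
    t2 <- proc.time()[["elapsed"]]
    report$timings <- c(sampling = t1 - t0, selection = 0,
                        segmentation = t2 - t1)
    return(list(mask = mask, report = report))
  }

  vr <- selectAlpha(sample, config$alphaRange, r = config$r, tol = config$tol,
                    maxIter = config$maxIter, seed = config$seed)
  report$alphaStar <- vr@alphaStar
  report$validity <- vr
  t2 <- proc.time()[["elapsed"]]

  fit <- fitCenters(sample, vr@alphaStar, r = config$r, tol = config$tol,
                    maxIter = config$maxIter, seed = config$seed)
  centers <- fit$centers@centers
  J <- computeThresholds(centers, config$beta)
  mask <- applyThresholds(m, J)
  report$centers <- centers
  report$thresholds <- J
  report$iterations <- fit$trace@iterations
  report$converged <- fit$trace@converged
  report$refinedPixels <- 0L
  if (config$mode == "hybrid" && length(J)) {
    ref <- refineBand(m, mask, J, config)
    mask <- ref$mask
    report$refinedPixels <- ref$refined
  }
  t3 <- proc.time()[["elapsed"]]
  report$timings <- c(sampling = t1 - t0, selection = t2 - t1,
                      segmentation = t3 - t2)
  list(mask = mask, report = report)
}

#' Run the pipeline over several images
#'
#' Applies [runOSNC()] with a shared configuration to each input; per-file
#' errors are collected without stopping the batch. When ground-truth
#' masks are supplied, each image's single accuracy (pixel agreement after
#' label mapping) and the batch's average accuracy are reported.
#'
#' @param images list of images or file paths.
#' @param config a [osncConfig()].
#' @param truths optional list of ground-truth label matrices (or paths),
#'   parallel to `images`.
#' @return A list with `reports` (per image), `errors` (named messages) and
#'   `summary` (list with `accuracies` and mean `M` when truths given).
#' @export
runBatch <- function(images, config = osncConfig(), truths = NULL) {
  reports <- vector("list", length(images))
  errors <- character(0)
  accs <- numeric(0)
  for (i in seq_along(images)) {
    res <- tryCatch(runOSNC(images[[i]], config), error = function(e) e)
    if (inherits(res, "error")) {
      errors[[as.character(i)]] <- conditionMessage(res)
      next
    }
    if (!is.null(truths)) {
      tr <- truths[[i]]
      if (is.character(tr)) tr <- readMask(tr)
      res$accuracy <- maskAgreement(res$mask, tr)$accuracy
      accs <- c(accs, res$accuracy)
    }
    reports[[i]] <- res
  }
  summary <- if (length(accs))
    list(accuracies = accs, M = meanAccuracy(accs)) else list()
  list(reports = reports, errors = errors, summary = summary)
}
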