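#' Feature extraction configuration
#'
#' The attribute set and window size used to build per-pixel feature
#' vectors. Available attributes:
#' \describe{
#'   \item{gray}{the pixel's own gray level.}
#'   \item{local_mean}{mean gray level over the window.}
#'   \item{local_sd}{standard deviation over the window (texture / peak-valley
#'     contrast).}
#'   \item{gradient}{Sobel gradient magnitude (edge strength).}
#' }
#' Every attribute is min-max normalized to `[0, 1]` over the image, so a
#' constant attribute maps to 0.
#'
#' @param attributes ordered character vector of attribute names.
#' @param window odd window size (>= 3) for the local statistics.
#' @return A list of class `FeatureConfig`.
#' @export
featureConfig <- function(attributes = c("gray", "local_mean", "local_sd",
                                         "gradient"),
                          window = 3) {
  known <- c("gray", "local_mean", "local_sd", "gradient")
  bad <- setdiff(attributes, known)
  if (length(bad))
    stop("unknown attribute(s): ", paste(bad, collapse = ", "), call. = FALSE)
  if (length(attributes) < 1L) stop("need at least one attribute", call. = FALSE)
  window <- as.integer(window)
  if (window < 3L || window %% 2L == 0L)
    stop("window must be odd and >= 3", call. = FALSE)
  structure(list(attributes = attributes, window = window),
            class = "FeatureConfig")
}

sobelMagnitude <- function(m) {
  p <- reflectPad(m, 1)
  M <- nrow(m); N <- ncol(m)
  sl <- function(di, dj) p[(2 + di):(1 + M + di), (2 + dj):(1 + N + dj)]
  gx <- sl(-1, 1) + 2 * sl(0, 1) + sl(1, 1) -
        sl(-1, -1) - 2 * sl(0, -1) - sl(1, -1)
  gy <- sl(1, -1) + 2 * sl(1, 0) + sl(1, 1) -
        sl(-1, -1) - 2 * sl(-1, 0) - sl(-1, 1)
  sqrt(gx^2 + gy^2)
}

minMax01 <- function(m) {
  r <- range(m)
  if (r[2] - r[1] <= 0) return(matrix(0, nrow(m), ncol(m)))
  (m - r[1]) / (r[2] - r[1])
}

#' Extract per-pixel attribute vectors
#'
#' Computes the configured attributes for every pixel (reflect padding at
#' the borders) and min-max normalizes each attribute plane to `[0, 1]`
#' over the image.
#'
#' @param image a [GrayImage-class] or numeric matrix.
#' @param config a [featureConfig()].
#' @return A [FeatureStack-class] of shape `M x N x m`.
#' @examples
#' img <- generateTexture(32, 32, seed = 1)
#' fs <- extractFeatures(img)
#' dim(featureValues(fs))
#' @export
extractFeatures <- function(image, config = featureConfig()) {
  m <- asGrayMatrix(image)
  k <- (config$window - 1L) %/% 2L
  nwin <- config$window^2
  planes <- lapply(config$attributes, function(a) {
    switch(a,
      gray = m,
      local_mean = boxSum(m, k) / nwin,
      local_sd = {
        mu <- boxSum(m, k) / nwin
        v <- boxSum(m^2, k) / nwin - mu^2
        sqrt(pmax(v, 0))
      },
      gradient = sobelMagnitude(m))
  })
  vals <- array(0, c(nrow(m), ncol(m), length(planes)))
  for (q in seq_along(planes)) vals[, , q] <- minMax01(planes[[q]])
  new("FeatureStack", values = vals, attributeNames = config$attributes)
}

#' Flatten a feature stack into a sample matrix
#'
#' Traverses the stack row-major with the given stride and returns one
#' sample per visited pixel, keeping the pixel coordinates.
#'
#' @param stack a [FeatureStack-class].
#' @param stride positive integer subsampling stride.
#' @return A list with `features` (samples x m matrix), `coords`
#'   (samples x 2 matrix of 1-based `(row, col)`).
#' @export
flattenSamples <- function(stack, stride = 1) {
  stride <- as.integer(stride)
  if (stride < 1L) stop("stride must be >= 1", call. = FALSE)
  d <- dim(stack@values)
  rows <- seq(1L, d[1], by = stride)
  cols <- seq(1L, d[2], by = stride)
  coords <- cbind(row = rep(rows, each = length(cols)),
                  col = rep(cols, times = length(rows)))
  feats <- matrix(0, nrow(coords), d[3],
                  dimnames = list(NULL, stack@attributeNames))
  for (q in seq_len(d[3]))
    feats[, q] <- matrix(stack@values[, , q], d[1], d[2])[coords]
  list(features = feats, coords = coords)
}
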