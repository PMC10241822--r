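#' @import methods
NULL

#' 8-bit grayscale image
#'
#' A matrix of integer gray levels in `[0, 255]`, row = image row. The class
#' extends `matrix` so arithmetic and subsetting behave as for plain matrices.
#'
#' @slot .Data integer-valued matrix of gray levels.
#' @export
setClass("GrayImage", contains = "matrix", validity = function(object) {
  v <- object@.Data
  if (length(v) == 0L) return("image must be non-empty")
  if (!is.numeric(v)) return("gray levels must be numeric")
  if (anyNA(v)) return("gray levels must not contain NA")
  if (any(v < 0 | v > 255)) return("gray levels must lie in [0, 255]")
  if (any(v != round(v))) return("gray levels must be integers")
  TRUE
})

#' Construct a GrayImage
#'
#' Rounds and clips a numeric matrix into an 8-bit grayscale image.
#'
#' @param x numeric matrix.
#' @return A [GrayImage-class] object.
#' @examples
#' img <- GrayImage(matrix(0:255, 16, 16))
#' dim(img)
#' @export
GrayImage <- function(x) {
  stopifnot(is.matrix(x))
  new("GrayImage", .Data = pmin(pmax(round(x), 0), 255))
}

setMethod("show", "GrayImage", function(object) {
  v <- object@.Data
  cat(sprintf("GrayImage %d x %d, gray range [%d, %d]\n",
              nrow(v), ncol(v), min(v), max(v)))
})

#' Per-pixel attribute stack
#'
#' Holds the m-attribute feature vector of every pixel, each attribute
#' min-max normalized to `[0, 1]` over the image.
#'
#' @slot values numeric array `M x N x m` in `[0, 1]`.
#' @slot attributeNames character vector of length m.
#' @export
setClass("FeatureStack",
  representation(values = "array", attributeNames = "character"),
  validity = function(object) {
    d <- dim(object@values)
    if (length(d) != 3L) return("values must be an M x N x m array")
    if (d[3] != length(object@attributeNames))
      return("attribute count must match stack depth")
    v <- object@values
    if (anyNA(v) || any(v < -1e-12 | v > 1 + 1e-12))
      return("feature values must lie in [0, 1]")
    TRUE
  })

setMethod("show", "FeatureStack", function(object) {
  d <- dim(object@values)
  cat(sprintf("FeatureStack %d x %d pixels, %d attributes: %s\n",
              d[1], d[2], d[3], paste(object@attributeNames, collapse = ", ")))
})

#' @describeIn FeatureStack-class attribute names.
#' @param x a `FeatureStack`.
#' @export
attributeNames <- function(x) x@attributeNames

#' @describeIn FeatureStack-class the `M x N x m` value array.
#' @export
featureValues <- function(x) x@values

#' Small-neighborhood cluster model
#'
#' The classes discovered by epsilon-chain growth over feature vectors,
#' with per-class attribute means, per-class attribute ranges (needed by
#' the range-normalized distance), attribute weights, and bookkeeping from
#' the training stage.
#'
#' @slot n integer class count.
#' @slot classMeans `n x m` matrix of per-class attribute means.
#' @slot classMin,classMax `n x m` per-class attribute minima / maxima.
#' @slot attributeWeights m-vector of attribute weights, summing to 1.
#' @slot classSizes integer n-vector; sums to the number of clustered samples.
#' @slot densestCount size of the largest class (c0).
#' @slot trainingWeights list with per-attribute chain weights `zeta`, the
#'   maximum `zetaP` and its attribute index `p`.
#' @export
setClass("ClusterModel",
  representation(n = "integer", classMeans = "matrix", classMin = "matrix",
                 classMax = "matrix", attributeWeights = "numeric",
                 classSizes = "integer", densestCount = "integer",
                 trainingWeights = "list"),
  validity = function(object) {
    if (object@n < 1L) return("need at least one class")
    if (nrow(object@classMeans) != object@n) return("classMeans rows != n")
    m <- ncol(object@classMeans)
    if (length(object@attributeWeights) != m)
      return("attributeWeights length != attribute count")
    if (any(object@attributeWeights < -1e-12 | object@attributeWeights > 1 + 1e-12))
      return("attribute weights must lie in [0, 1]")
    if (length(object@classSizes) != object@n) return("classSizes length != n")
    TRUE
  })

setMethod("show", "ClusterModel", function(object) {
  cat(sprintf("ClusterModel: %d classes over %d attributes\n",
              object@n, ncol(object@classMeans)))
  cat(" class sizes:", object@classSizes, "\n")
  cat(" attribute weights:", signif(object@attributeWeights, 4), "\n")
})

#' @describeIn ClusterModel-class number of discovered classes.
#' @param object a `ClusterModel`.
#' @export
nClasses <- function(object) object@n

#' @describeIn ClusterModel-class `n x m` matrix of class attribute means.
#' @export
classMeans <- function(object) object@classMeans

#' @describeIn ClusterModel-class the attribute weight vector (sums to 1).
#' @export
attributeWeights <- function(object) object@attributeWeights

#' Fuzzy membership field
#'
#' Membership of every pixel in each of n classes; per-pixel memberships
#' sum to one.
#'
#' @slot mu numeric array `M x N x n` of memberships in `[0, 1]`.
#' @export
setClass("MembershipField", representation(mu = "array"),
  validity = function(object) {
    d <- dim(object@mu)
    if (length(d) != 3L) return("mu must be an M x N x n array")
    if (anyNA(object@mu) || any(object@mu < -1e-9 | object@mu > 1 + 1e-9))
      return("memberships must lie in [0, 1]")
    s <- apply(object@mu, c(1, 2), sum)
    if (max(abs(s - 1)) > 1e-9)
      return("per-pixel membership sums must equal 1 (within 1e-9)")
    TRUE
  })

setMethod("show", "MembershipField", function(object) {
  d <- dim(object@mu)
  cat(sprintf("MembershipField %d x %d pixels, %d classes\n", d[1], d[2], d[3]))
})

#' @describeIn MembershipField-class the `M x N x n` membership array.
#' @param x a `MembershipField`.
#' @export
membership <- function(x) x@mu

#' Segmentation centers and thresholds
#'
#' The converged segmentation centers (gray levels, ascending) together
#' with the fuzzy weight index r, the threshold weight beta, and the
#' inter-center thresholds J_1..J_G (G = n - 1).
#'
#' @slot centers numeric vector of gray-level centers, sorted ascending.
#' @slot r fuzzy weight exponent (> 1).
#' @slot beta threshold weight in `[0, 1]`.
#' @slot thresholds numeric vector of n - 1 thresholds.
#' @export
setClass("CenterSet",
  representation(centers = "numeric", r = "numeric", beta = "numeric",
                 thresholds = "numeric"),
  validity = function(object) {
    if (is.unsorted(object@centers)) return("centers must be sorted ascending")
    if (length(object@thresholds) != max(length(object@centers) - 1L, 0L))
      return("threshold count must be (number of centers) - 1")
    if (object@beta < 0 || object@beta > 1) return("beta must lie in [0, 1]")
    k <- length(object@centers)
    if (k >= 2L && object@beta > 0 && object@beta < 1) {
      lo <- object@centers[-k]; hi <- object@centers[-1]
      distinct <- hi - lo > 0
      if (any(distinct & (object@thresholds <= lo | object@thresholds >= hi)))
        return("thresholds must lie strictly between adjacent distinct centers")
    }
    TRUE
  })

setMethod("show", "CenterSet", function(object) {
  cat(sprintf("CenterSet: %d centers (r = %g, beta = %g)\n",
              length(object@centers), object@r, object@beta))
  cat(" centers:   ", signif(object@centers, 5), "\n")
  if (length(object@thresholds))
    cat(" thresholds:", signif(object@thresholds, 5), "\n")
})

#' @describeIn CenterSet-class the sorted gray-level centers.
#' @param object a `CenterSet`.
#' @export
segCenters <- function(object) object@centers

#' @describeIn CenterSet-class the inter-center thresholds.
#' @export
segThresholds <- function(object) object@thresholds

#' Fit trace of the alternating center/membership optimization
#'
#' @slot objective objective value after each iteration.
#' @slot iterations number of iterations used.
#' @slot converged logical.
#' @export
setClass("FitTrace",
  representation(objective = "numeric", iterations = "integer",
                 converged = "logical"),
  validity = function(object) {
    if (any(!is.finite(object@objective))) return("objective must be finite")
    if (length(object@objective) != object@iterations)
      return("trace length must equal iteration count")
    TRUE
  })

setMethod("show", "FitTrace", function(object) {
  cat(sprintf("FitTrace: %d iterations, %sconverged, final objective %g\n",
              object@iterations, if (object@converged) "" else "NOT ",
              utils::tail(object@objective, 1)))
})

#' Sampling-rate search trace
#'
#' Records the variable-step search over resampling rates: each iterate's
#' rate, step and relative entropy loss, the first feasible rate etaF, the
#' clamped optimal rate etaO, and the full-resolution entropy S1.
#'
#' @slot iterates data.frame with columns `eta`, `t`, `delta`.
#' @slot etaF first rate whose loss fell inside the feasibility interval.
#' @slot etaO etaF clamped from below by the minimum sampled side length.
#' @slot S1 entropy (bits) of the full-resolution image.
#' @slot bounds numeric `(deltaMin, deltaMax)`.
#' @slot stepFactor the step factor k.
#' @slot S0 minimum acceptable sampled side length (pixels).
#' @slot feasible TRUE when the search found a rate inside the bounds.
#' @export
setClass("SamplingTrace",
  representation(iterates = "data.frame", etaF = "numeric", etaO = "numeric",
                 S1 = "numeric", bounds = "numeric", stepFactor = "numeric",
                 S0 = "numeric", feasible = "logical"),
  validity = function(object) {
    if (nrow(object@iterates) &&
        (any(object@iterates$eta <= 0) || any(object@iterates$eta > 1)))
      return("all visited rates must lie in (0, 1]")
    if (nrow(object@iterates) && any(object@iterates$delta < 0))
      return("relative entropy loss must be nonnegative")
    if (length(object@bounds) != 2L) return("bounds must be (deltaMin, deltaMax)")
    TRUE
  })

setMethod("show", "SamplingTrace", function(object) {
  cat(sprintf("SamplingTrace: %d iterates, etaF = %g, etaO = %g (%s)\n",
              nrow(object@iterates), object@etaF, object@etaO,
              if (object@feasible) "feasible" else "bounds not met"))
})

#' @describeIn SamplingTrace-class the clamped optimal sampling rate.
#' @param object a `SamplingTrace`.
#' @export
optimalRate <- function(object) object@etaO

#' Validity sweep report
#'
#' For each candidate segment count alpha: the fitted centers, the pairwise
#' fuzzy-correlation matrix phi, and the criterion value F = max off-diagonal
#' phi. `alphaStar` is the candidate minimizing F.
#'
#' @slot alphas integer candidates.
#' @slot F criterion value per candidate.
#' @slot phi list of per-candidate correlation matrices.
#' @slot centers list of per-candidate center vectors.
#' @slot alphaStar selected segment count.
#' @export
setClass("ValidityReport",
  representation(alphas = "integer", F = "numeric", phi = "list",
                 centers = "list", alphaStar = "integer"),
  validity = function(object) {
    k <- length(object@alphas)
    if (length(object@F) != k || length(object@phi) != k ||
        length(object@centers) != k)
      return("per-candidate fields must have one entry per alpha")
    if (!(object@alphaStar %in% object@alphas))
      return("alphaStar must be one of the candidates")
    TRUE
  })

setMethod("show", "ValidityReport", function(object) {
  cat("ValidityReport\n")
  print(data.frame(alpha = object@alphas, F = signif(object@F, 5)))
  cat(" selected alpha* =", object@alphaStar, "\n")
})

#' @describeIn ValidityReport-class the selected number of segments.
#' @param object a `ValidityReport`.
#' @export
alphaStar <- function(object) object@alphaStar

#' Synthetic scene specification
#'
#' Parameters of a simulated inspection scene: bright convex objects on a
#' uniform background, with optional crack / stain / breakage defects and
#' additive Gaussian noise. Identical spec + seed gives identical scenes.
#'
#' @slot width,height scene size in pixels (>= 16).
#' @slot backgroundLevel,objectLevel gray levels in `[0, 255]`.
#' @slot nObjects number of objects.
#' @slot objectRadius numeric `(min, max)` radius in pixels.
#' @slot defects list of `list(kind, intensityOffset, size)` entries with
#'   kind one of "crack", "stain", "breakage".
#' @slot noiseSigma additive Gaussian noise standard deviation (gray levels).
#' @slot seed integer RNG seed.
#' @export
setClass("SceneSpec",
  representation(width = "integer", height = "integer",
                 backgroundLevel = "numeric", nObjects = "integer",
                 objectRadius = "numeric", objectLevel = "numeric",
                 defects = "list", noiseSigma = "numeric", seed = "integer"),
  validity = function(object) {
    if (object@width < 16L || object@height < 16L)
      return("scene must be at least 16 x 16")
    lv <- c(object@backgroundLevel, object@objectLevel)
    if (any(lv < 0 | lv > 255)) return("gray levels must lie in [0, 255]")
    if (object@noiseSigma < 0) return("noiseSigma must be >= 0")
    if (object@nObjects < 0L) return("nObjects must be >= 0")
    if (length(object@objectRadius) != 2L || any(object@objectRadius <= 0))
      return("objectRadius must be positive (min, max)")
    for (d in object@defects) {
      if (!is.list(d) || is.null(d$kind) ||
          !d$kind %in% c("crack", "stain", "breakage"))
        return("each defect needs kind in {crack, stain, breakage}")
    }
    TRUE
  })

setMethod("show", "SceneSpec", function(object) {
  cat(sprintf(
    "SceneSpec %d x %d: background %g, %d object(s) at level %g, %d defect(s), noise sd %g, seed %d\n",
    object@width, object@height, object@backgroundLevel, object@nObjects,
    object@objectLevel, length(object@defects), object@noiseSigma, object@seed))
})

#' Labeled synthetic scene
#'
#' A generated image together with its ground-truth label mask
#' (0 = background, 1 = object, 2 = defect).
#'
#' @slot image a [GrayImage-class].
#' @slot truth integer matrix of labels in `{0, 1, 2}`.
#' @export
setClass("LabeledScene",
  representation(image = "GrayImage", truth = "matrix"),
  validity = function(object) {
    if (!identical(dim(object@image@.Data), dim(object@truth)))
      return("image and truth must have identical shape")
    if (!all(object@truth %in% 0:2)) return("truth labels must be in {0, 1, 2}")
    TRUE
  })

setMethod("show", "LabeledScene", function(object) {
  tb <- table(factor(object@truth, levels = 0:2))
  cat(sprintf("LabeledScene %d x %d: %d background, %d object, %d defect pixels\n",
              nrow(object@truth), ncol(object@truth), tb[1], tb[2], tb[3]))
})

#' @describeIn LabeledScene-class the generated image.
#' @param object a `LabeledScene`.
#' @export
sceneImage <- function(object) object@image

#' @describeIn LabeledScene-class the ground-truth label mask.
#' @export
sceneTruth <- function(object) object@truth
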