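#' Neighborhood clustering parameters
#'
#' @param epsilon chain-growth radius in normalized feature space (> 0).
#' @param K number of in-order neighbors used for the single-attribute
#'   center (>= 0).
#' @param maxClasses cap on the number of discovered classes; samples left
#'   over once the cap is reached are attached to their nearest class.
#' @return A list of class `NeighborhoodParams`.
#' @export
sncParams <- function(epsilon = 0.1, K = 3, maxClasses = 9) {
  if (epsilon <= 0) stop("epsilon must be > 0", call. = FALSE)
  K <- as.integer(K)
  if (K < 0L) stop("K must be >= 0", call. = FALSE)
  structure(list(epsilon = epsilon, K = K,
                 maxClasses = as.integer(maxClasses)),
            class = "NeighborhoodParams")
}

#' Single-attribute neighborhood center
#'
#' The mean of attribute `q` over sample `l` and its next `K` samples in
#' index order, i.e. `(1/(K+1)) * sum_{j=l}^{l+K} c_q(x_j)`.
#'
#' @param samples numeric matrix, one row per sample, one column per
#'   attribute.
#' @param l 1-based sample index.
#' @param K neighbor count; rows `l .. l+K` must exist.
#' @param q attribute (column) index.
#' @return The neighborhood attribute center.
#' @export
neighborAttributeCenter <- function(samples, l, K, q) {
  if (l < 1 || l + K > nrow(samples))
    stop("sample window [", l, ", ", l + K, "] out of range", call. = FALSE)
  mean(samples[l:(l + K), q])
}

# Grow a 1-D epsilon-chain: repeatedly absorb the nearest unabsorbed value
# within eps of the running center (the mean of absorbed values), starting
# from `center`. Returns the number absorbed.
chainGrow1d <- function(values, center, eps) {
  absorbed <- logical(length(values))
  repeat {
    d <- abs(values - center)
    d[absorbed] <- Inf
    j <- which.min(d)
    if (!is.finite(d[j]) || d[j] > eps) break
    absorbed[j] <- TRUE
    center <- mean(values[absorbed])
  }
  sum(absorbed)
}

#' Training-stage attribute weights
#'
#' For each attribute, grows an epsilon-chain in that attribute alone,
#' starting from the neighborhood attribute center of the first sample
#' ([neighborAttributeCenter()] with the configured `K`): the nearest
#' unabsorbed sample within `epsilon` of the running chain mean is absorbed
#' and the mean recomputed, until none qualifies. The chain size `s` gives
#' the attribute weight `zeta_q = s / L`; the largest weight `zeta_p`
#' identifies the most cohesive attribute `p`.
#'
#' @param samples numeric sample matrix (rows = samples, cols = attributes).
#' @param params an [sncParams()].
#' @return A list with `zeta` (per-attribute weights), `zetaP` (their
#'   maximum) and `p` (the attribute index attaining it, first on ties).
#' @export
estimateAttributeWeights <- function(samples, params = sncParams()) {
  if (nrow(samples) < 1L) stop("need at least one sample", call. = FALSE)
  L <- nrow(samples)
  K <- min(params$K, L - 1L)
  zeta <- vapply(seq_len(ncol(samples)), function(q) {
    center <- neighborAttributeCenter(samples, 1L, K, q)
    chainGrow1d(samples[, q], center, params$epsilon) / L
  }, numeric(1))
  p <- which.max(zeta)
  list(zeta = zeta, zetaP = zeta[p], p = p)
}

#' Discover classes by epsilon-chain growth
#'
#' Greedy chain clustering over full feature vectors: a class is seeded at
#' the first unassigned sample; the nearest unassigned sample within
#' `epsilon` (Euclidean distance in normalized feature space) of the
#' running class mean is absorbed and the mean recomputed, until no sample
#' qualifies; then the next class is seeded. The process is deterministic
#' given sample order. Attribute weights `b_q` are the maximum over classes
#' of the fraction of class members reachable by a single-attribute chain
#' from the class's attribute mean, renormalized to sum 1.
#'
#' @param samples numeric sample matrix (rows = samples, cols = attributes).
#' @param params an [sncParams()].
#' @return A [ClusterModel-class].
#' @examples
#' x <- rbind(matrix(0.1 + 0.01 * 1:5 / 5, 5, 1), matrix(0.9, 4, 1))
#' nClasses(discoverClasses(x, sncParams(epsilon = 0.05)))
#' @export
discoverClasses <- function(samples, params = sncParams()) {
  if (!is.matrix(samples)) samples <- as.matrix(samples)
  L <- nrow(samples)
  if (L < 1L) stop("need at least one sample", call. = FALSE)
  eps <- params$epsilon
  label <- integer(L)
  nCls <- 0L
  while (any(label == 0L)) {
    if (nCls >= params$maxClasses) break
    nCls <- nCls + 1L
    seed <- which(label == 0L)[1]
    label[seed] <- nCls
    center <- samples[seed, ]
    repeat {
      free <- which(label == 0L)
      if (length(free) == 0L) break
      d2 <- colSums((t(samples[free, , drop = FALSE]) - center)^2)
      j <- which.min(d2)
      if (d2[j] > eps^2) break
      label[free[j]] <- nCls
      inCls <- label == nCls
      center <- colMeans(samples[inCls, , drop = FALSE])
    }
  }
  if (any(label == 0L)) {
    # class cap reached: attach leftovers to their nearest class mean
    means <- do.call(rbind, lapply(seq_len(nCls), function(i)
      colMeans(samples[label == i, , drop = FALSE])))
    for (j in which(label == 0L)) {
      d2 <- rowSums((means - matrix(samples[j, ], nCls, ncol(samples),
                                    byrow = TRUE))^2)
      label[j] <- which.min(d2)
    }
  }
  m <- ncol(samples)
  classMeans <- matrix(0, nCls, m)
  classMin <- matrix(0, nCls, m)
  classMax <- matrix(0, nCls, m)
  sizes <- integer(nCls)
  bq <- numeric(m)
  for (i in seq_len(nCls)) {
    memb <- samples[label == i, , drop = FALSE]
    sizes[i] <- nrow(memb)
    classMeans[i, ] <- colMeans(memb)
    classMin[i, ] <- apply(memb, 2, min)
    classMax[i, ] <- apply(memb, 2, max)
    for (q in seq_len(m)) {
      v <- chainGrow1d(memb[, q], classMeans[i, q], eps)
      bq[q] <- max(bq[q], v / sizes[i])
    }
  }
  if (sum(bq) > 0) bq <- bq / sum(bq) else bq <- rep(1 / m, m)
  new("ClusterModel", n = nCls, classMeans = classMeans, classMin = classMin,
      classMax = classMax, attributeWeights = bq, classSizes = sizes,
      densestCount = max(sizes),
      trainingWeights = estimateAttributeWeights(samples, params))
}

# Distances from a block of samples (rows) to every class: the weighted,
# range-normalized city-block form. The per-class attribute range is taken
# over the class members together with the query sample; a zero range
# contributes nothing (a constant attribute carries no information).
classDistanceMatrix <- function(X, model) {
  if (ncol(X) != ncol(model@classMeans))
    stop("attribute count mismatch between samples and model", call. = FALSE)
  P <- nrow(X)
  D <- matrix(0, P, model@n)
  for (i in seq_len(model@n)) {
    di <- numeric(P)
    for (q in seq_len(ncol(X))) {
      rng <- pmax(model@classMax[i, q], X[, q]) -
             pmin(model@classMin[i, q], X[, q])
      num <- model@attributeWeights[q] * abs(X[, q] - model@classMeans[i, q])
      term <- ifelse(rng > 0, num / rng, 0)
      di <- di + term
    }
    D[, i] <- di
  }
  D
}

#' Distance from a sample to one class
#'
#' `d_i = sum_q b_q |c_q(x) - V_i^q| / (O_iq_max - O_iq_min)` where the
#' range of attribute `q` is taken over class `i`'s members together with
#' the query sample; a zero-range attribute contributes 0.
#'
#' @param x numeric feature vector of length m.
#' @param model a [ClusterModel-class].
#' @param i class index.
#' @return The nonnegative distance `d_i`.
#' @export
classDistance <- function(x, model, i) {
  if (i < 1 || i > model@n) stop("class index out of range", call. = FALSE)
  classDistanceMatrix(matrix(x, 1), model)[1, i]
}

#' Decision weights from class distances
#'
#' `lambda_i = (1/(n-1)) (1 - d_i / sum(d))` for `n >= 2` classes; the
#' weights sum to 1, decrease in `d_i`, and peak at the minimum-distance
#' class. A single class gets weight 1; an all-zero distance vector gives
#' uniform weights.
#'
#' @param d nonnegative, finite distance vector (length n).
#' @return Weight vector of length n summing to 1.
#' @examples
#' decisionWeights(c(1, 3))   # 0.75, 0.25
#' @export
decisionWeights <- function(d) {
  if (any(!is.finite(d)) || any(d < 0))
    stop("distances must be finite and nonnegative", call. = FALSE)
  n <- length(d)
  if (n == 1L) return(1)
  if (sum(d) == 0) return(rep(1 / n, n))
  (1 - d / sum(d)) / (n - 1)
}

#' Assign a sample to a class with decision weights
#'
#' The sample joins the class at minimum distance (lowest index on ties).
#' Decision weights follow `lambda_i = (1/(n-1)) (1 - d_i / sum(d))`, which
#' sum to 1 and decrease in `d_i`; when all distances are zero (or n = 1)
#' the weights are uniform.
#'
#' @param x numeric feature vector.
#' @param model a [ClusterModel-class].
#' @return A list with `classIndex`, `distances`, `weights`.
#' @export
assignSample <- function(x, model) {
  d <- classDistanceMatrix(matrix(x, 1), model)[1, ]
  if (any(!is.finite(d))) stop("non-finite class distances", call. = FALSE)
  list(classIndex = which.min(d), distances = d, weights = decisionWeights(d))
}

#' Segment an image with a fitted cluster model
#'
#' Assigns every pixel of the feature stack to its minimum-distance class.
#'
#' @param stack a [FeatureStack-class].
#' @param model a [ClusterModel-class].
#' @return Integer label matrix with labels in `0 .. n-1`.
#' @export
segmentImage <- function(stack, model) {
  d <- dim(stack@values)
  X <- matrix(stack@values, d[1] * d[2], d[3])
  D <- classDistanceMatrix(X, model)
  lab <- max.col(-D, ties.method = "first") - 1L
  matrix(lab, d[1], d[2])
}
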