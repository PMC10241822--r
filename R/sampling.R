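# Nearest-neighbor decimation, histogram entropy, relative entropy loss,
# and the variable-step search for the smallest acceptable sampling rate.

#' Resample an image by nearest-neighbor decimation
#'
#' Output size is `round(eta * M) x round(eta * N)` (each at least 1);
#' output pixel `(i, j)` (0-based) copies input pixel
#' `(floor(i / eta), floor(j / eta))`. No interpolation: output gray values
#' are a subset of the input's.
#'
#' @param image a [GrayImage-class] or numeric matrix.
#' @param eta sampling rate in `(0, 1]`.
#' @return A [GrayImage-class].
#' @export
resampleImage <- function(image, eta) {
  if (eta <= 0 || eta > 1) stop("eta must lie in (0, 1]", call. = FALSE)
  m <- asGrayMatrix(image)
  if (eta == 1) return(GrayImage(m))
  M1 <- max(1L, as.integer(round(eta * nrow(m))))
  N1 <- max(1L, as.integer(round(eta * ncol(m))))
  ri <- pmin(floor((seq_len(M1) - 1L) / eta) + 1L, nrow(m))
  ci <- pmin(floor((seq_len(N1) - 1L) / eta) + 1L, ncol(m))
  GrayImage(m[ri, ci, drop = FALSE])
}

#' Gray-level histogram probabilities
#'
#' `p_k` = fraction of pixels at level `k`, for all 256 levels.
#'
#' @param image a [GrayImage-class] or integer matrix.
#' @return Numeric vector of length 256 summing to 1 (index 1 = level 0).
#' @export
histogramProbs <- function(image) {
  m <- asGrayMatrix(image)
  tabulate(as.integer(m) + 1L, nbins = 256L) / length(m)
}

#' Shannon entropy of a histogram
#'
#' `S = -sum_k p_k log2 p_k` in bits, with `0 log 0 := 0`.
#'
#' @param p probability vector (e.g. from [histogramProbs()]).
#' @return Entropy in bits.
#' @export
imageEntropy <- function(p) {
  if (any(p < 0) || abs(sum(p) - 1) > 1e-9)
    stop("p must be a probability vector", call. = FALSE)
  nz <- p[p > 0]
  -sum(nz * log2(nz))
}

#' Relative entropy loss under resampling
#'
#' `delta_eta = |S_1 - S_eta| / S_1` where `S_1` is the entropy of the full
#' image and `S_eta` that of its decimation at rate `eta`. A constant image
#' (`S_1 = 0`) has loss 0 by convention.
#'
#' @param image a [GrayImage-class] or integer matrix.
#' @param eta sampling rate in `(0, 1]`.
#' @return The nonnegative relative entropy loss.
#' @export
relativeEntropyLoss <- function(image, eta) {
  S1 <- imageEntropy(histogramProbs(image))
  if (S1 == 0) return(0)
  Se <- imageEntropy(histogramProbs(resampleImage(image, eta)))
  abs(S1 - Se) / S1
}

#' Variable-step search for the smallest acceptable sampling rate
#'
#' Walks the rate `eta` with data-dependent steps until the relative
#' entropy loss first lands inside `[deltaMin, deltaMax]`: when the loss is
#' below `deltaMin` the image is oversampled and the rate shrinks by
#' `t = eta * k`; when it exceeds `deltaMax` the rate grows by
#' `t = eta * (1 - k/2)`, clamped to 1 (with the step halved on repeated
#' overshoot so the search can re-enter the interval). The first feasible
#' rate `etaF` is returned rather than the exact infimum; `etaO` is `etaF`
#' clamped from below so the decimated short side stays at least `S0`
#' pixels.
#'
#' @param image a [GrayImage-class] or integer matrix.
#' @param deltaMin,deltaMax feasibility interval for the relative entropy
#'   loss, `0 < deltaMin < deltaMax`.
#' @param k step factor in `(0, 1)`.
#' @param etaInit starting rate in `(0, 1]`.
#' @param maxIter iteration cap; if reached, the trace is marked
#'   infeasible and the last visited rate is reported.
#' @param S0 minimum acceptable decimated side length in pixels.
#' @return A [SamplingTrace-class].
#' @examples
#' tx <- generateTexture(128, 128, seed = 7)
#' tr <- variableStepSearch(tx, 0.01, 0.02)
#' optimalRate(tr)
#' @export
variableStepSearch <- function(image, deltaMin = 0.01, deltaMax = 0.02,
                               k = 0.5, etaInit = 0.5, maxIter = 50,
                               S0 = 32) {
  if (!(deltaMin > 0 && deltaMin < deltaMax))
    stop("need 0 < deltaMin < deltaMax", call. = FALSE)
  if (k <= 0 || k >= 1) stop("step factor k must lie in (0, 1)", call. = FALSE)
  if (etaInit <= 0 || etaInit > 1) stop("etaInit must lie in (0, 1]",
                                        call. = FALSE)
  m <- asGrayMatrix(image)
  S1 <- imageEntropy(histogramProbs(m))
  eta <- etaInit
  rows <- list()
  feasible <- FALSE
  overshoots <- 0L
  for (it in seq_len(maxIter)) {
    delta <- relativeEntropyLoss(m, eta)
    if (delta >= deltaMin && delta <= deltaMax) {
      rows[[it]] <- c(eta = eta, t = 0, delta = delta)
      feasible <- TRUE
      break
    }
    if (delta < deltaMin) {
      t <- eta * k
      rows[[it]] <- c(eta = eta, t = -t, delta = delta)
      eta <- eta - t
    } else {
      t <- eta * (1 - k / 2)
      if (eta + t > 1) {
        overshoots <- overshoots + 1L
        t <- min(t / 2^overshoots, 1 - eta)
      }
      rows[[it]] <- c(eta = eta, t = t, delta = delta)
      eta <- min(eta + t, 1)
    }
    if (eta <= 0) { eta <- .Machine$double.eps; break }
  }
  iter <- do.call(rbind, rows)
  iter <- as.data.frame(iter)
  etaF <- if (feasible) iter$eta[nrow(iter)] else eta
  etaO <- clampRate(etaF, S0, nrow(m), ncol(m))
  new("SamplingTrace", iterates = iter, etaF = etaF, etaO = etaO, S1 = S1,
      bounds = c(deltaMin, deltaMax), stepFactor = k, S0 = S0,
      feasible = feasible)
}

#' Clamp a sampling rate to a minimum decimated size
#'
#' `etaO = max(etaF, S0 / min(M, N))`, capped at 1: the decimated image
#' must keep at least `S0` pixels on its short side so its histogram can
#' still support peak counting.
#'
#' @param etaF candidate rate.
#' @param S0 minimum decimated side length (pixels).
#' @param M,N image dimensions.
#' @return The clamped rate in `(0, 1]`.
#' @export
clampRate <- function(etaF, S0, M, N) {
  min(max(etaF, S0 / min(M, N)), 1)
}

#' Search complexity
#'
#' `theta_x = H * (N + 1) * kSep` — optimization steps times sample-class
#' count times class-separation distances.
#'
#' @param H number of optimization steps.
#' @param Nplus1 number of sample classes.
#' @param kSep number of class-separation distances.
#' @return The operation count.
#' @export
searchComplexity <- function(H, Nplus1, kSep) {
  stopifnot(H >= 1, Nplus1 >= 1, kSep >= 1)
  H * Nplus1 * kSep
}

#' Single-peak histogram test
#'
#' Smooths the histogram with a moving average (window 5) and reports TRUE
#' when exactly one local maximum has prominence above `xiH` (a fraction of
#' total probability mass). Prominence of a peak is its height minus the
#' higher of the two valley minima separating it from taller terrain (or
#' the boundary).
#'
#' @param p probability vector over gray levels.
#' @param xiH prominence threshold as a fraction of total mass.
#' @return Logical: is the histogram unimodal at this threshold?
#' @export
isUnimodal <- function(p, xiH = 0.015) {
  if (any(p < 0) || abs(sum(p) - 1) > 1e-9)
    stop("p must be a probability vector", call. = FALSE)
  sm <- stats::filter(c(rep(0, 2), p, rep(0, 2)), rep(1 / 5, 5), sides = 2)
  sm <- as.numeric(sm)[3:(length(p) + 2)]
  n <- length(sm)
  # run-length compress so flat-topped peaks still count once
  r <- rle(sm)
  vals <- r$values
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  padded <- c(-Inf, vals, -Inf)
  isPeak <- vals > padded[seq_along(vals)] & vals > padded[seq_along(vals) + 2L]
  peaks <- as.integer(round((starts[isPeak] + ends[isPeak]) / 2))
  prominent <- 0L
  for (pk in peaks) {
    h <- sm[pk]
    leftMin <- h; i <- pk
    while (i > 1) { i <- i - 1; if (sm[i] > h) break; leftMin <- min(leftMin, sm[i]) }
    rightMin <- h; i <- pk
    while (i < n) { i <- i + 1; if (sm[i] > h) break; rightMin <- min(rightMin, sm[i]) }
    if (h - max(leftMin, rightMin) > xiH) prominent <- prominent + 1L
  }
  prominent == 1L
}
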