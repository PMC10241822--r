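# Fuzzy-correlation validity function for choosing the number of segments.
# All norms are absolute gray-level differences (the gray domain is 1-D).

#' Fuzzy deviation of a class
#'
#' `delta_c^2 = sum_ij mu_c(L_ij)^2 |L_ij - nu_c|^2` — the squared,
#' membership-weighted spread of the image around center `nu_c`.
#'
#' @param U a [MembershipField-class] or `M x N x n` membership array.
#' @param image a [GrayImage-class] or numeric matrix.
#' @param centers numeric class centers.
#' @param c class index.
#' @return The nonnegative fuzzy deviation `delta_c^2`.
#' @export
fuzzyDeviation <- function(U, image, centers, c) {
  mu <- if (is(U, "MembershipField")) U@mu else U
  m <- asGrayMatrix(image)
  sum(mu[, , c]^2 * (m - centers[c])^2)
}

#' Fuzzy relation between two classes
#'
#' `R_kl = sum_ij mu_k mu_l |L_ij - nu_k| |L_ij - nu_l|`; symmetric, and
#' `R_kk` equals the fuzzy deviation `delta_k^2`.
#'
#' @inheritParams fuzzyDeviation
#' @param k,l class indices.
#' @return The nonnegative relation value.
#' @export
fuzzyRelation <- function(U, image, centers, k, l) {
  mu <- if (is(U, "MembershipField")) U@mu else U
  m <- asGrayMatrix(image)
  sum(mu[, , k] * mu[, , l] * abs(m - centers[k]) * abs(m - centers[l]))
}

#' Fuzzy correlation between two classes
#'
#' `phi_kl = R_kl / (delta_k delta_l)` with `delta = sqrt(delta^2)`; by
#' Cauchy–Schwarz `phi_kl` lies in `[0, 1]`. A degenerate class with zero
#' deviation yields `phi = 0` with a warning rather than an error, so a
#' sweep over candidate counts can continue past collapsed fits.
#'
#' @param Rkl the fuzzy relation value.
#' @param deltaK,deltaL the (non-squared) fuzzy deviations.
#' @return The correlation in `[0, 1]`.
#' @export
fuzzyCorrelation <- function(Rkl, deltaK, deltaL) {
  if (deltaK <= 0 || deltaL <= 0) {
    warning("degenerate class with zero fuzzy deviation; correlation set to 0")
    return(0)
  }
  Rkl / (deltaK * deltaL)
}

phiMatrix <- function(U, image, centers) {
  n <- length(centers)
  delta2 <- vapply(seq_len(n), function(c)
    fuzzyDeviation(U, image, centers, c), numeric(1))
  phi <- diag(1, n)
  for (k in seq_len(n)) for (l in seq_len(n)) {
    if (l <= k) next
    R <- fuzzyRelation(U, image, centers, k, l)
    phi[k, l] <- phi[l, k] <-
      fuzzyCorrelation(R, sqrt(delta2[k]), sqrt(delta2[l]))
  }
  phi
}

#' Select the number of segments by fuzzy correlation
#'
#' For each candidate count `alpha`, fits segmentation centers with
#' [fitCenters()] and scores the partition by the maximum pairwise fuzzy
#' correlation `F_alpha = max_{k != l} phi_kl`; low correlation means the
#' classes are well separated. The selected count `alpha*` minimizes
#' `F_alpha` (smallest candidate on ties).
#'
#' @param image a [GrayImage-class] or numeric matrix.
#' @param alphaRange integer candidates, default `2:9`.
#' @param r,tol,maxIter,seed passed to [fitCenters()].
#' @return A [ValidityReport-class].
#' @examples
#' img <- GrayImage(matrix(rep(c(40, 130, 220), each = 27) +
#'                         rep_len(c(-2, 0, 2), 81), 9, 9))
#' alphaStar(selectAlpha(img, 2:4))
#' @export
selectAlpha <- function(image, alphaRange = 2:9, r = 2, tol = 1e-5,
                        maxIter = 300, seed = 1) {
  m <- asGrayMatrix(image)
  alphaRange <- as.integer(alphaRange)
  Fv <- numeric(length(alphaRange))
  phis <- vector("list", length(alphaRange))
  cents <- vector("list", length(alphaRange))
  for (a in seq_along(alphaRange)) {
    fit <- tryCatch(
      fitCenters(m, alphaRange[a], r = r, tol = tol, maxIter = maxIter,
                 seed = seed),
      error = function(e) stop("fit failed at alpha = ", alphaRange[a], ": ",
                               conditionMessage(e), call. = FALSE))
    phi <- phiMatrix(fit$membership, m, fit$centers@centers)
    offdiag <- phi[row(phi) != col(phi)]
    Fv[a] <- if (length(offdiag)) max(offdiag) else 0
    phis[[a]] <- phi
    cents[[a]] <- fit$centers@centers
  }
  new("ValidityReport", alphas = alphaRange, F = Fv, phi = phis,
      centers = cents, alphaStar = alphaRange[which.min(Fv)])
}
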