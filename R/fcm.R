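# Alternating fuzzy membership / center optimization on the gray histogram
# domain, plus threshold extraction and application.

#' Fuzzy clustering objective
#'
#' `B_f = sum_k sum_ij mu_k(L_ij)^r d_ijk^2` — the membership-weighted sum
#' of squared center distances.
#'
#' @param U a [MembershipField-class] or `M x N x n` membership array.
#' @param D an `M x N x n` array of distances `|L_ij - o_k|`.
#' @param r fuzzy weight exponent (> 1).
#' @return The scalar objective.
#' @export
fcmObjective <- function(U, D, r = 2) {
  if (r <= 1) stop("fuzzy exponent r must be > 1", call. = FALSE)
  mu <- if (is(U, "MembershipField")) U@mu else U
  if (!identical(dim(mu), dim(D)))
    stop("membership and distance arrays must have the same shape",
         call. = FALSE)
  sum(mu^r * D^2)
}

distanceField <- function(image, centers) {
  m <- asGrayMatrix(image)
  n <- length(centers)
  D <- array(0, c(nrow(m), ncol(m), n))
  for (k in seq_len(n)) D[, , k] <- abs(m - centers[k])
  D
}

#' Membership-weighted center update
#'
#' `o_k = sum_ij mu_k^r L_ij / sum_ij mu_k^r`.
#'
#' @param U a [MembershipField-class] or membership array.
#' @param image a [GrayImage-class] or numeric matrix.
#' @param r fuzzy weight exponent.
#' @param seed seed used only if a class has lost all weight and must be
#'   re-seeded at a random gray percentile.
#' @return Numeric vector of updated centers.
#' @export
updateCenters <- function(U, image, r = 2, seed = 1) {
  mu <- if (is(U, "MembershipField")) U@mu else U
  m <- asGrayMatrix(image)
  n <- dim(mu)[3]
  centers <- numeric(n)
  for (k in seq_len(n)) {
    w <- mu[, , k]^r
    tot <- sum(w)
    if (tot <= 0) {
      warning("class ", k, " lost all membership weight; re-seeding center")
      centers[k] <- withSeed(seed,
        stats::quantile(m, stats::runif(1), names = FALSE))
    } else {
      centers[k] <- sum(w * m) / tot
    }
  }
  centers
}

#' Membership update from centers
#'
#' `mu_k = d_ijk^(-2/(r-1)) / sum_k d_ijk^(-2/(r-1))`. A pixel coinciding
#' with one or more centers takes membership `1/#coincident` on those
#' centers and 0 elsewhere.
#'
#' @param image a [GrayImage-class] or numeric matrix.
#' @param centers numeric vector of gray-level centers.
#' @param r fuzzy weight exponent (> 1).
#' @return A [MembershipField-class].
#' @export
updateMembership <- function(image, centers, r = 2) {
  if (r <= 1) stop("fuzzy exponent r must be > 1", call. = FALSE)
  m <- asGrayMatrix(image)
  n <- length(centers)
  D <- distanceField(m, centers)
  ex <- -2 / (r - 1)
  W <- array(0, dim(D))
  zeroAny <- apply(D == 0, c(1, 2), any)
  pw <- D^ex                    # Inf at coincident pixels, handled below
  pw[D == 0] <- 0
  tot <- apply(pw, c(1, 2), sum)
  mu <- array(0, dim(D))
  for (k in seq_len(n)) {
    mu[, , k] <- ifelse(zeroAny, 0, pw[, , k] / tot)
  }
  if (any(zeroAny)) {
    nz <- apply(D == 0, c(1, 2), sum)
    for (k in seq_len(n)) {
      hit <- zeroAny & (D[, , k] == 0)
      mu[, , k][hit] <- 1 / nz[hit]
    }
  }
  new("MembershipField", mu = mu)
}

#' Fit segmentation centers by alternating updates
#'
#' Starting from deterministic quantile-initialized centers (the
#' `(k - 0.5)/n` gray quantiles; optionally seeded-random), alternates the
#' center update and the membership update until the largest membership
#' change falls below `tol` or `maxIter` is reached. The objective is
#' non-increasing along the iterations.
#'
#' @param image a [GrayImage-class] or numeric matrix.
#' @param n number of classes (>= 1).
#' @param r fuzzy weight exponent (> 1), default 2.
#' @param tol convergence tolerance on `max |delta mu|`.
#' @param maxIter iteration cap.
#' @param init `"quantile"` (deterministic) or `"random"`.
#' @param seed seed for `init = "random"` and degenerate re-seeding.
#' @return A list with `centers` (a [CenterSet-class] with thresholds at
#'   `beta = 0.5`), `membership` (a [MembershipField-class]) and `trace`
#'   (a [FitTrace-class]).
#' @examples
#' img <- GrayImage(matrix(c(40, 40, 200, 200), 2))
#' fit <- fitCenters(img, n = 2)
#' segCenters(fit$centers)
#' @export
fitCenters <- function(image, n, r = 2, tol = 1e-5, maxIter = 300,
                       init = c("quantile", "random"), seed = 1) {
  init <- match.arg(init)
  m <- asGrayMatrix(image)
  n <- as.integer(n)
  if (n < 1L) stop("need n >= 1 classes", call. = FALSE)
  if (length(unique(as.vector(m))) < n)
    warning("image has fewer distinct gray levels than classes; ",
            "fit may be degenerate")
  centers <- initialCenters(m, n, init, seed)
  U <- updateMembership(m, centers, r)
  obj <- numeric(0)
  converged <- FALSE
  iter <- 0L
  while (iter < maxIter) {
    iter <- iter + 1L
    centers <- updateCenters(U, m, r, seed)
    Unew <- updateMembership(m, centers, r)
    obj <- c(obj, fcmObjective(Unew, distanceField(m, centers), r))
    dmu <- max(abs(Unew@mu - U@mu))
    U <- Unew
    if (dmu < tol) { converged <- TRUE; break }
  }
  ord <- order(centers)
  centers <- centers[ord]
  U <- new("MembershipField", mu = U@mu[, , ord, drop = FALSE])
  cs <- new("CenterSet", centers = centers, r = r, beta = 0.5,
            thresholds = computeThresholds(centers, 0.5))
  list(centers = cs, membership = U,
       trace = new("FitTrace", objective = obj, iterations = iter,
                   converged = converged))
}

initialCenters <- function(m, n, init, seed) {
  if (init == "random") {
    return(sort(withSeed(seed, stats::quantile(m, stats::runif(n),
                                               names = FALSE))))
  }
  q <- stats::quantile(m, (seq_len(n) - 0.5) / n, names = FALSE)
  # coincident quantiles (heavily tied histograms) would collapse classes;
  # spread duplicates by a tiny deterministic offset
  if (anyDuplicated(q)) q <- q + (seq_len(n) - (n + 1) / 2) * 1e-3
  sort(q)
}

#' Thresholds between adjacent centers
#'
#' `J_c = beta o_c + (1 - beta) o_{c+1}` for `c = 1 .. n-1`, with
#' `beta = 0.5` the usual midpoint choice.
#'
#' @param centers sorted numeric centers (or a [CenterSet-class]).
#' @param beta weight in `[0, 1]` on the lower center.
#' @return Numeric vector of `n - 1` thresholds (empty when n < 2).
#' @export
computeThresholds <- function(centers, beta = 0.5) {
  if (is(centers, "CenterSet")) centers <- centers@centers
  if (beta < 0 || beta > 1) stop("beta must lie in [0, 1]", call. = FALSE)
  if (is.unsorted(centers)) stop("centers must be sorted", call. = FALSE)
  k <- length(centers)
  if (k < 2L) return(numeric(0))
  beta * centers[-k] + (1 - beta) * centers[-1]
}

#' Apply thresholds to an image
#'
#' Each pixel's label is the number of thresholds strictly below its gray
#' value, giving labels `0 .. G` for `G` thresholds.
#'
#' @param image a [GrayImage-class] or numeric matrix.
#' @param J sorted ascending numeric thresholds (possibly empty).
#' @return Integer label matrix.
#' @export
applyThresholds <- function(image, J) {
  m <- asGrayMatrix(image)
  if (length(J) == 0L) return(matrix(0L, nrow(m), ncol(m)))
  if (is.unsorted(J)) stop("thresholds must be sorted ascending", call. = FALSE)
  lab <- matrix(0L, nrow(m), ncol(m))
  for (j in J) lab <- lab + (m > j)
  storage.mode(lab) <- "integer"
  lab
}
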