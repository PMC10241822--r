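# Brute-force double-loop objective for small instances.
objectiveOracle <- function(mu, D, r) {
  tot <- 0
  for (k in seq_len(dim(mu)[3]))
    for (i in seq_len(dim(mu)[1]))
      for (j in seq_len(dim(mu)[2]))
        tot <- tot + mu[i, j, k]^r * D[i, j, k]^2
  tot
}

test_that("the clustering objective evaluates and matches a loop oracle", {
  expect_equal(fcmObjective(array(1, c(2, 2, 1)), array(0, c(2, 2, 1))), 0)
  expect_equal(fcmObjective(array(1, c(1, 1, 1)), array(2, c(1, 1, 1)), r = 2), 4)
  set.seed(21)
  mu <- array(runif(18), c(3, 3, 2))
  norm <- apply(mu, c(1, 2), sum)
  for (k in 1:2) mu[, , k] <- mu[, , k] / norm
  D <- array(runif(18, 0, 50), c(3, 3, 2))
  expect_equal(fcmObjective(mu, D, 2.3), objectiveOracle(mu, D, 2.3))
  expect_error(fcmObjective(mu, D, r = 1), "r must be")
})

test_that("crisp memberships give class-wise weighted means as centers", {
  img <- matrix(c(10, 20, 40), 1)
  mu <- array(0, c(1, 3, 2))
  mu[1, 1:2, 1] <- 1; mu[1, 3, 2] <- 1
  expect_equal(updateCenters(mu, img), c(15, 40))
  # single class: the global image mean
  img2 <- randomGray(3, 8)
  mu1 <- array(1, c(8, 8, 1))
  expect_equal(updateCenters(mu1, img2), mean(img2@.Data))
})

test_that("center update matches a direct weighted-mean recomputation", {
  set.seed(4)
  img <- matrix(sample(0:255, 64, replace = TRUE), 8)
  U <- updateMembership(img, c(50, 120, 210), r = 2)@mu
  got <- updateCenters(U, img, r = 2)
  for (k in 1:3)
    expect_equal(got[k], sum(U[, , k]^2 * img) / sum(U[, , k]^2))
})

test_that("membership update follows the inverse-distance power rule", {
  # pixel at a center: full membership there
  U <- updateMembership(matrix(100, 1, 1), c(100, 200), r = 2)
  expect_equal(U@mu[1, 1, ], c(1, 0))
  # equidistant: symmetric split
  U <- updateMembership(matrix(150, 1, 1), c(100, 200), r = 2)
  expect_equal(U@mu[1, 1, ], c(0.5, 0.5))
  # d = (1, 2), r = 2: mu = (0.8, 0.2)
  U <- updateMembership(matrix(101, 1, 1), c(100, 103), r = 2)
  expect_equal(U@mu[1, 1, ], c(0.8, 0.2))
  # coincident duplicate centers split the unit mass
  U <- updateMembership(matrix(100, 1, 1), c(100, 100, 200), r = 2)
  expect_equal(U@mu[1, 1, ], c(0.5, 0.5, 0))
  expect_error(updateMembership(matrix(1), c(1, 2), r = 0.5), "r must be")
})

test_that("per-pixel membership sums are one after every update", {
  set.seed(6)
  img <- matrix(sample(0:255, 100, replace = TRUE), 10)
  centers <- c(30, 90, 180)
  for (it in 1:5) {
    U <- updateMembership(img, centers, r = 2)
    sums <- apply(U@mu, c(1, 2), sum)
    expect_lt(max(abs(sums - 1)), 1e-9)
    centers <- updateCenters(U, img, r = 2)
  }
})

test_that("a two-level image converges to its exact levels", {
  img <- GrayImage(matrix(c(rep(40, 20), rep(200, 16)), 6))
  fit <- fitCenters(img, 2)
  expect_equal(segCenters(fit$centers), c(40, 200), tolerance = 1e-6)
  expect_equal(segThresholds(fit$centers), 120, tolerance = 1e-6)
  expect_true(fit$trace@converged)
})

test_that("n = 1 yields the global mean as the single center", {
  img <- randomGray(5, 8)
  fit <- fitCenters(img, 1)
  expect_equal(segCenters(fit$centers), mean(img@.Data))
  expect_length(segThresholds(fit$centers), 0)
})

test_that("the objective is non-increasing along the fit", {
  for (s in 1:10) {
    fit <- fitCenters(randomGray(s, 12), 3, tol = 1e-7)
    expect_true(all(diff(fit$trace@objective) <= 1e-9), label = paste("seed", s))
  }
})

test_that("the fit agrees with an independent fuzzy c-means reference", {
  for (s in 1:6) {
    img <- randomGray(s, 16)
    fit <- fitCenters(img, 3, tol = 1e-12, maxIter = 5000)
    expect_equal(segCenters(fit$centers), cmeansOracle(img, 3),
                 tolerance = 1e-6, label = paste("seed", s))
  }
})

test_that("thresholds are convex combinations interleaving the centers", {
  expect_equal(computeThresholds(c(100, 150), 0.5), 125)
  expect_equal(computeThresholds(c(100, 150), 1), 100)    # beta = 1 identity
  expect_equal(computeThresholds(c(10, 20, 30), 0.5), c(15, 25))
  expect_length(computeThresholds(42), 0)
  set.seed(2)
  cen <- sort(runif(5, 0, 255))
  for (beta in c(0.2, 0.5, 0.8)) {
    J <- computeThresholds(cen, beta)
    expect_true(all(J > cen[-5] & J < cen[-1]))
  }
  expect_error(computeThresholds(c(3, 1)), "sorted")
  expect_error(computeThresholds(c(1, 3), beta = 2), "beta")
})

test_that("threshold application counts thresholds strictly below each pixel", {
  expect_equal(applyThresholds(matrix(c(100, 200), 1), 125),
               matrix(c(0L, 1L), 1))
  expect_true(all(applyThresholds(randomGray(1, 8), numeric(0)) == 0L))
  # conservation: every pixel gets exactly one label
  img <- randomGray(9, 10)
  lab <- applyThresholds(img, c(60, 120, 200))
  expect_equal(length(lab), 100)
  expect_true(all(lab %in% 0:3))
  # boundary pixels: a pixel equal to a threshold stays in the lower class
  expect_equal(applyThresholds(matrix(125, 1, 1), 125), matrix(0L, 1, 1))
  expect_error(applyThresholds(img, c(5, 3)), "sorted")
})

test_that("a degenerate fit warns when levels are fewer than classes", {
  expect_warning(fitCenters(GrayImage(matrix(9, 4, 4)), 2), "distinct")
})
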