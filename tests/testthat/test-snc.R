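# Independent re-simulation of the chain-growth process, written as plain
# loops so it can serve as an oracle for discoverClasses().
chainOracle <- function(samples, eps) {
  L <- nrow(samples)
  label <- integer(L)
  cls <- 0L
  while (any(label == 0L)) {
    cls <- cls + 1L
    seed <- min(which(label == 0L))
    label[seed] <- cls
    repeat {
      members <- samples[label == cls, , drop = FALSE]
      center <- colMeans(members)
      best <- NA_integer_; bestD <- Inf
      for (j in seq_len(L)) {
        if (label[j] != 0L) next
        dj <- sqrt(sum((samples[j, ] - center)^2))
        if (dj < bestD) { bestD <- dj; best <- j }
      }
      if (!is.finite(bestD) || bestD > eps) break
      label[best] <- cls
    }
  }
  label
}

test_that("the single-attribute neighborhood center is the windowed mean", {
  s <- matrix(c(2, 4, 6), 3, 1)
  expect_equal(neighborAttributeCenter(s, 1, 2, 1), 4)
  expect_equal(neighborAttributeCenter(s, 2, 0, 1), 4)       # K = 0 identity
  const <- matrix(7, 5, 1)
  for (K in 0:4) expect_equal(neighborAttributeCenter(const, 1, K, 1), 7)
  expect_error(neighborAttributeCenter(s, 2, 2, 1), "out of range")
})

test_that("attribute chain weights reflect per-attribute cohesion", {
  # identical samples: one chain absorbs everything
  same <- matrix(0.4, 6, 2)
  w <- estimateAttributeWeights(same, sncParams(epsilon = 0.05))
  expect_equal(w$zeta, c(1, 1))
  # spread values {0, 0.5, 1}: the chain from center 0.5 only holds itself
  spread <- matrix(c(0, 0.5, 1), 3, 1)
  w <- estimateAttributeWeights(spread, sncParams(epsilon = 0.05, K = 2))
  expect_equal(w$zeta, 1 / 3)
  # constant attribute out-coheres a spread one
  set.seed(1)
  two <- cbind(rep(0.5, 20), runif(20))
  w <- estimateAttributeWeights(two, sncParams(epsilon = 0.02))
  expect_gt(w$zeta[1], w$zeta[2])
  expect_equal(w$p, 1)
  expect_equal(w$zetaP, w$zeta[1])
})

test_that("chain clustering separates tight feature clumps", {
  set.seed(5)
  x <- matrix(c(0.1 + runif(12, -0.01, 0.01), 0.9 + runif(8, -0.01, 0.01)),
              ncol = 1)
  model <- discoverClasses(x, sncParams(epsilon = 0.05))
  expect_equal(nClasses(model), 2)
  expect_equal(classMeans(model)[, 1], c(0.1, 0.9), tolerance = 0.02)
  expect_equal(sum(model@classSizes), 20L)
  expect_equal(model@densestCount, 12L)
})

test_that("identical samples collapse to a single class of full size", {
  model <- discoverClasses(matrix(0.3, 9, 3), sncParams())
  expect_equal(nClasses(model), 1)
  expect_equal(model@classSizes, 9L)
})

test_that("discovered partitions match the independent chain re-simulation", {
  for (s in 1:8) {
    set.seed(s)
    x <- matrix(runif(2 * sample(5:20, 1)), ncol = 2)
    eps <- runif(1, 0.05, 0.4)
    model <- discoverClasses(x, sncParams(epsilon = eps, maxClasses = 99))
    oracle <- chainOracle(x, eps)
    expect_equal(nClasses(model), max(oracle))
    sizes <- as.integer(table(oracle))
    expect_equal(model@classSizes, sizes)
  }
})

mkModel <- function(means, mins, maxs, b) {
  sizes <- rep(1L, nrow(means))
  new("ClusterModel", n = nrow(means), classMeans = means, classMin = mins,
      classMax = maxs, attributeWeights = b, classSizes = sizes,
      densestCount = 1L, trainingWeights = list())
}

test_that("the range-normalized distance evaluates as specified", {
  m <- mkModel(matrix(10), matrix(10), matrix(20), 1)
  expect_equal(classDistance(15, m, 1), 0.5)
  expect_equal(classDistance(10, m, 1), 0)        # at the class mean
  expect_error(classDistance(15, m, 2), "out of range")
  # query outside the class range widens the denominator
  expect_equal(classDistance(30, m, 1), 20 / 20)
})

test_that("class distance is invariant to rescaling an attribute everywhere", {
  set.seed(3)
  samples <- matrix(runif(30), ncol = 2)
  model <- discoverClasses(samples, sncParams(epsilon = 0.3))
  x <- runif(2)
  d1 <- vapply(seq_len(nClasses(model)), function(i)
    classDistance(x, model, i), numeric(1))
  # double attribute 2 across samples and the query
  s2 <- samples; s2[, 2] <- s2[, 2] * 2
  scaled <- mkModel(
    cbind(model@classMeans[, 1], model@classMeans[, 2] * 2),
    cbind(model@classMin[, 1], model@classMin[, 2] * 2),
    cbind(model@classMax[, 1], model@classMax[, 2] * 2),
    model@attributeWeights)
  x2 <- c(x[1], x[2] * 2)
  d2 <- vapply(seq_len(nClasses(model)), function(i)
    classDistance(x2, scaled, i), numeric(1))
  expect_equal(d1, d2, tolerance = 1e-12)
})

test_that("decision weights normalize, order inversely to distance, and tie-break low", {
  expect_equal(decisionWeights(c(1, 1)), c(0.5, 0.5))
  expect_equal(decisionWeights(c(1, 3)), c(0.75, 0.25))
  lam <- decisionWeights(c(1, 3, 6))
  expect_equal(sum(lam), 1)
  expect_equal(which.max(lam), 1)
  expect_equal(decisionWeights(5), 1)
  expect_equal(decisionWeights(c(0, 0, 0)), rep(1 / 3, 3))
  expect_error(decisionWeights(c(1, Inf)), "finite")
  # strictly decreasing in d_i with the rest fixed
  l1 <- decisionWeights(c(1, 2, 3))
  l2 <- decisionWeights(c(1.5, 2, 3))
  expect_lt(l2[1], l1[1])
})

test_that("assignment picks the minimum-distance class with summing weights", {
  set.seed(7)
  for (rep in 1:10) {
    samples <- matrix(runif(40), ncol = 2)
    model <- discoverClasses(samples, sncParams(epsilon = 0.2))
    x <- runif(2)
    a <- assignSample(x, model)
    d <- vapply(seq_len(nClasses(model)), function(i)
      classDistance(x, model, i), numeric(1))
    expect_equal(a$classIndex, which.min(d))       # exhaustive-min oracle
    expect_equal(sum(a$weights), 1, tolerance = 1e-9)
    expect_equal(which.max(a$weights), which.min(a$distances))
  }
})

test_that("segmentation recovers a two-region synthetic image", {
  set.seed(11)
  m <- matrix(40, 24, 24); m[, 13:24] <- 200
  img <- GrayImage(m + matrix(round(rnorm(24 * 24, 0, 2)), 24))
  # gray attribute only: spatial attributes would add a (correct but
  # truth-unlabeled) boundary class along the region edge
  stack <- extractFeatures(img, featureConfig("gray"))
  flat <- flattenSamples(stack, 2)
  model <- discoverClasses(flat$features, sncParams(epsilon = 0.25))
  mask <- segmentImage(stack, model)
  expect_identical(dim(mask), dim(img@.Data))
  truth <- matrix(0L, 24, 24); truth[, 13:24] <- 1L
  expect_gte(maskAgreement(mask, truth)$accuracy, 0.95)
})

test_that("a one-class model labels every pixel zero", {
  img <- randomGray(2, 8)
  stack <- extractFeatures(img)
  model <- discoverClasses(matrix(0.5, 4, 4), sncParams(epsilon = 10))
  expect_true(all(segmentImage(stack, model) == 0L))
})

test_that("chain discovery is deterministic in sample order", {
  set.seed(9)
  x <- matrix(runif(40), ncol = 2)
  a <- discoverClasses(x, sncParams(epsilon = 0.15))
  b <- discoverClasses(x, sncParams(epsilon = 0.15))
  expect_identical(classMeans(a), classMeans(b))
})
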