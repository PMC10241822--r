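test_that("resampling at rate 1 is the identity and never interpolates", {
  img <- randomGray(1, 12)
  expect_identical(resampleImage(img, 1)@.Data, img@.Data)
  for (eta in c(0.3, 0.5, 0.8)) {
    out <- resampleImage(img, eta)@.Data
    expect_true(all(out %in% img@.Data))
  }
  expect_error(resampleImage(img, 0), "eta")
  expect_error(resampleImage(img, 1.2), "eta")
})

test_that("decimation picks the expected source pixels", {
  m <- matrix(1:16, 4, 4)
  out <- resampleImage(GrayImage(m), 0.5)@.Data
  expect_identical(out + 0, m[c(1, 3), c(1, 3)] + 0)
  # tiny image never collapses below 1 pixel
  expect_identical(dim(resampleImage(GrayImage(matrix(7, 2, 2)), 0.2)@.Data),
                   c(1L, 1L))
})

test_that("histogram probabilities count levels and sum to one", {
  m <- matrix(c(0, 0, 1, 2, 3, 0, 5, 9, 0, 7, 8, 1, 2, 2, 4, 6), 4,
              byrow = TRUE)
  p <- histogramProbs(GrayImage(m))
  expect_equal(p[1], 4 / 16)                  # level 0
  expect_equal(sum(p), 1)
  pc <- histogramProbs(GrayImage(matrix(7, 5, 5)))
  expect_equal(pc[8], 1)
  expect_true(all(pc[-8] == 0))
  for (s in 1:3) expect_equal(sum(histogramProbs(randomGray(s))), 1)
})

test_that("entropy matches closed forms", {
  expect_equal(imageEntropy(rep(1 / 256, 256)), 8)
  expect_equal(imageEntropy(c(1, rep(0, 255))), 0)
  expect_equal(imageEntropy(c(0.5, 0.5, rep(0, 254))), 1)
  expect_error(imageEntropy(c(0.5, 0.4)), "probability")
})

test_that("relative entropy loss is zero at rate 1 and for constant images", {
  img <- randomGray(2)
  expect_equal(relativeEntropyLoss(img, 1), 0)
  expect_equal(relativeEntropyLoss(GrayImage(matrix(3, 20, 20)), 0.4), 0)
})

test_that("entropy loss matches a first-principles recomputation", {
  tx <- generateTexture(128, 128, seed = 13)
  eta <- 0.25
  got <- relativeEntropyLoss(tx, eta)
  # independent path: decimate by direct index arithmetic, count levels by
  # hand, apply the Shannon formula
  m <- tx@.Data
  ri <- pmin(floor((seq_len(round(eta * 128)) - 1) / eta) + 1, 128)
  sub <- m[ri, ri]
  ent <- function(v) {
    p <- table(v) / length(v)
    -sum(p * log2(p))
  }
  expect_equal(got, abs(ent(m) - ent(sub)) / ent(m), tolerance = 1e-12)
})

test_that("an immediately feasible start returns in one iteration", {
  tx <- generateTexture(128, 128, seed = 3)
  # find some eta whose loss is known feasible, then start the search there
  tr0 <- variableStepSearch(tx, 0.01, 0.02)
  expect_true(tr0@feasible)
  tr <- variableStepSearch(tx, 0.01, 0.02, etaInit = tr0@etaF)
  expect_equal(nrow(tr@iterates), 1)
  expect_equal(tr@etaF, tr0@etaF)
})

test_that("the returned rate respects the loss upper bound on seeded textures", {
  for (s in 1:5) {
    tx <- generateTexture(256, 256, seed = s)
    tr <- variableStepSearch(tx, 0.01, 0.02, k = 0.5, etaInit = 0.5)
    expect_true(tr@feasible)
    expect_lte(relativeEntropyLoss(tx, tr@etaF), 0.02)
    expect_gte(relativeEntropyLoss(tx, tr@etaF), 0.01)
  }
})

test_that("the search walk matches an independent re-simulation", {
  tx <- generateTexture(256, 256, seed = 4)
  k <- 0.5; lo <- 0.01; hi <- 0.02
  tr <- variableStepSearch(tx, lo, hi, k = k, etaInit = 0.5)
  eta <- 0.5
  for (it in 1:50) {
    d <- relativeEntropyLoss(tx, eta)
    if (d >= lo && d <= hi) break
    if (d < lo) eta <- eta - eta * k
    else eta <- min(eta + eta * (1 - k / 2), 1)
  }
  expect_equal(tr@etaF, eta)
  expect_equal(tr@iterates$eta[1], 0.5)
})

test_that("search iterates never leave (0, 1] and terminate within the cap", {
  for (s in 1:5) {
    tx <- generateTexture(64, 64, seed = s)
    tr <- variableStepSearch(tx, 0.001, 0.002, maxIter = 30)
    expect_lte(nrow(tr@iterates), 30)
    expect_true(all(tr@iterates$eta > 0 & tr@iterates$eta <= 1))
  }
})

test_that("rate clamping enforces the minimum decimated side", {
  expect_equal(clampRate(0.5, 32, 256, 256), 0.5)
  expect_equal(clampRate(0.05, 32, 256, 256), 0.125)
  expect_equal(clampRate(0.05, 300, 256, 256), 1)
})

test_that("the complexity count is the product of its factors", {
  expect_equal(searchComplexity(10, 5, 3), 150)
  expect_equal(searchComplexity(1, 5, 3), 15)
  expect_equal(searchComplexity(1, 1, 1), 1)
})

test_that("unimodality is judged by prominent smoothed peaks", {
  # one Gaussian-shaped histogram: unimodal
  set.seed(14)
  lv <- pmin(pmax(round(rnorm(5000, 128, 10)), 0), 255)
  p1 <- tabulate(lv + 1, 256) / 5000
  expect_true(isUnimodal(p1))
  # two well-separated equal masses: bimodal
  p2 <- numeric(256); p2[51] <- 0.5; p2[201] <- 0.5
  expect_false(isUnimodal(p2))
  # a secondary bump below the prominence threshold does not count
  p3 <- numeric(256)
  p3[121:141] <- dnorm(121:141, 131, 4)
  p3[51] <- 0.01
  p3 <- p3 / sum(p3)
  expect_true(isUnimodal(p3, xiH = 0.015))
  expect_error(isUnimodal(c(2, 3)), "probability")
})

test_that("median entropy loss does not increase with the sampling rate", {
  etas <- seq(0.05, 0.9, length.out = 10)
  med <- vapply(etas, function(e) {
    stats::median(vapply(1:20, function(s)
      relativeEntropyLoss(generateTexture(96, 96, seed = s), e), numeric(1)))
  }, numeric(1))
  ct <- suppressWarnings(stats::cor.test(etas, med, method = "spearman",
                                         alternative = "less"))
  expect_lt(ct$estimate, 0)
  expect_lt(ct$p.value, 0.05)
})
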