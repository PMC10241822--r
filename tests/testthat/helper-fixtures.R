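# Shared fixture builders. Everything is generated in code under fixed
# seeds; no binary fixtures are stored.

# An image whose pixels are drawn i.i.d. from the given gray levels with
# mild additive noise; the simplest multi-population segmentation target.
makeLevelsImage <- function(levels, seed, side = 48, noiseSd = 3) {
  set.seed(seed)
  base <- matrix(sample(levels, side * side, replace = TRUE), side)
  GrayImage(pmin(pmax(base + matrix(round(rnorm(side * side, 0, noiseSd)),
                                    side), 0), 255))
}

# A defect scene with two sizeable stains so background / object / defect
# all carry enough pixels to be recovered as three populations.
makeDefectScene <- function(seed, side = 96) {
  generateScene(sceneSpec(side, side, nObjects = 2, objectRadius = c(20, 26),
                          noiseSigma = 3,
                          defects = list(
                            list(kind = "stain", size = 500,
                                 intensityOffset = 110),
                            list(kind = "stain", size = 400,
                                 intensityOffset = 110)),
                          seed = seed))
}

randomGray <- function(seed, side = 16) {
  set.seed(seed)
  GrayImage(matrix(sample(0:255, side * side, replace = TRUE), side))
}

# Independent fuzzy c-means oracle: e1071::cmeans restarted from its own
# centers until the restarts stop moving, squeezing out its looser internal
# stopping rule. Returns sorted centers.
cmeansOracle <- function(image, n, r = 2) {
  x <- matrix(as.numeric(asMatrix(image)), ncol = 1)
  cen <- matrix(stats::quantile(x, (seq_len(n) - 0.5) / n, names = FALSE),
                ncol = 1)
  for (rep in 1:6) {
    ref <- e1071::cmeans(x, centers = cen, m = r, iter.max = 5000,
                         control = list(reltol = 1e-16))
    cen <- ref$centers
  }
  sort(as.numeric(cen))
}

asMatrix <- function(image) {
  if (methods::is(image, "GrayImage")) image@.Data else image
}
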