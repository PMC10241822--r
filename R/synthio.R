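#' Specify a synthetic inspection scene
#'
#' Builds a [SceneSpec-class] describing bright convex objects on a uniform
#' background — the typical geometry of product-on-conveyor inspection
#' imagery — with optional surface defects and additive Gaussian camera
#' noise. The three defect kinds mirror the phenotypes seen in surface
#' inspection: a `crack` is a thin (1–2 px) dark random-walk curve inside an
#' object, a `stain` is a darker filled ellipse inside an object, and a
#' `breakage` is a bite removed from the object boundary (carved back to the
#' background level).
#'
#' @param width,height scene size in pixels (at least 16).
#' @param backgroundLevel background gray level in `[0, 255]`.
#' @param nObjects number of disk-shaped objects.
#' @param objectRadius numeric `(min, max)` object radius in pixels.
#' @param objectLevel object gray level in `[0, 255]`.
#' @param defects list of defect descriptors, each a
#'   `list(kind = "crack"|"stain"|"breakage", intensityOffset = <gray levels>,
#'   size = <pixels>)`. `size` is the path length for cracks and the
#'   approximate pixel area for stains and breakages.
#' @param noiseSigma standard deviation of additive Gaussian noise.
#' @param seed integer seed; identical spec + seed yields identical scenes.
#' @return A [SceneSpec-class].
#' @examples
#' spec <- sceneSpec(64, 64, nObjects = 1,
#'                   defects = list(list(kind = "stain", size = 60)))
#' scene <- generateScene(spec)
#' table(sceneTruth(scene))
#' @export
sceneSpec <- function(width = 128, height = 128, backgroundLevel = 40,
                      nObjects = 1, objectRadius = c(15, 25),
                      objectLevel = 200, defects = list(),
                      noiseSigma = 3, seed = 1) {
  defects <- lapply(defects, function(d) {
    if (is.null(d$intensityOffset)) d$intensityOffset <- 120
    if (is.null(d$size)) d$size <- 100
    d
  })
  new("SceneSpec", width = as.integer(width), height = as.integer(height),
      backgroundLevel = backgroundLevel, nObjects = as.integer(nObjects),
      objectRadius = as.numeric(objectRadius), objectLevel = objectLevel,
      defects = defects, noiseSigma = noiseSigma, seed = as.integer(seed))
}

diskMask <- function(M, N, ci, cj, radius) {
  i <- matrix(seq_len(M), M, N)
  j <- matrix(seq_len(N), M, N, byrow = TRUE)
  (i - ci)^2 + (j - cj)^2 <= radius^2
}

# Thin dark random-walk curve restricted to `inside`; returns logical mask.
crackMask <- function(inside, ci, cj, len, thick = 2) {
  M <- nrow(inside); N <- ncol(inside)
  mask <- matrix(FALSE, M, N)
  theta <- stats::runif(1, 0, 2 * pi)
  i <- ci; j <- cj
  for (s in seq_len(len)) {
    theta <- theta + stats::rnorm(1, 0, 0.35)
    i <- i + sin(theta); j <- j + cos(theta)
    ii <- round(i); jj <- round(j)
    if (ii < 1 || ii > M || jj < 1 || jj > N || !inside[ii, jj]) {
      theta <- theta + pi / 2   # bounce back toward the object
      i <- i - sin(theta); j <- j - cos(theta)
      next
    }
    mask[ii, jj] <- TRUE
    if (thick >= 2 && ii < M && inside[ii + 1, jj]) mask[ii + 1, jj] <- TRUE
  }
  mask & inside
}

ellipseMask <- function(inside, ci, cj, area) {
  M <- nrow(inside); N <- ncol(inside)
  aspect <- stats::runif(1, 0.5, 2)
  a <- sqrt(area / pi * aspect); b <- sqrt(area / pi / aspect)
  phi <- stats::runif(1, 0, pi)
  i <- matrix(seq_len(M), M, N) - ci
  j <- matrix(seq_len(N), M, N, byrow = TRUE) - cj
  u <- cos(phi) * i + sin(phi) * j
  v <- -sin(phi) * i + cos(phi) * j
  ((u / a)^2 + (v / b)^2 <= 1) & inside
}

#' Generate a labeled synthetic scene
#'
#' Draws the scene described by a [SceneSpec-class]: objects first, then
#' defects carved into randomly chosen objects, then additive Gaussian
#' noise, with gray values clipped to `[0, 255]`. The returned truth mask
#' uses 0 = background, 1 = object, 2 = defect and is exact (computed
#' before noise). Generation is a pure function of the spec (including its
#' seed) and never perturbs the caller's RNG state.
#'
#' @param spec a [SceneSpec-class].
#' @return A [LabeledScene-class].
#' @export
generateScene <- function(spec) {
  validObject(spec)
  M <- spec@height; N <- spec@width
  withSeed(spec@seed, {
    img <- matrix(spec@backgroundLevel, M, N)
    truth <- matrix(0L, M, N)
    objects <- list()
    rmax <- spec@objectRadius[2]
    for (o in seq_len(spec@nObjects)) {
      r <- stats::runif(1, spec@objectRadius[1], spec@objectRadius[2])
      # keep the disk inside the frame when it fits; else center it
      ci <- if (M > 2 * r) stats::runif(1, r + 1, M - r) else M / 2
      cj <- if (N > 2 * r) stats::runif(1, r + 1, N - r) else N / 2
      d <- diskMask(M, N, ci, cj, r)
      img[d] <- spec@objectLevel
      truth[d] <- 1L
      objects[[o]] <- list(ci = ci, cj = cj, r = r, mask = d)
    }
    for (def in spec@defects) {
      if (length(objects) == 0L) break
      ob <- objects[[sample.int(length(objects), 1)]]
      inside <- ob$mask
      # start defects off-center so they read as surface blemishes
      ci <- ob$ci + stats::runif(1, -ob$r / 2, ob$r / 2)
      cj <- ob$cj + stats::runif(1, -ob$r / 2, ob$r / 2)
      dm <- switch(def$kind,
        crack = crackMask(inside, round(ci), round(cj), def$size),
        stain = ellipseMask(inside, ci, cj, def$size),
        breakage = {
          phi <- stats::runif(1, 0, 2 * pi)
          diskMask(M, N, ob$ci + ob$r * sin(phi), ob$cj + ob$r * cos(phi),
                   sqrt(def$size / pi)) & inside
        })
      if (def$kind == "breakage") {
        img[dm] <- spec@backgroundLevel
      } else {
        img[dm] <- pmax(spec@objectLevel - def$intensityOffset, 0)
      }
      truth[dm] <- 2L
    }
    if (spec@noiseSigma > 0)
      img <- img + matrix(stats::rnorm(M * N, 0, spec@noiseSigma), M, N)
    new("LabeledScene", image = GrayImage(img), truth = truth)
  })
}

#' Generate a smoothed-noise texture
#'
#' A seeded gray texture with a rich, roughly Gaussian histogram: white
#' noise around a mid gray, box-smoothed a few times so that neighboring
#' pixels correlate as in natural imagery. Used as a stand-in for natural
#' scenes when studying entropy loss under resampling.
#'
#' @param width,height texture size in pixels.
#' @param mean,sd gray-level mean and standard deviation of the raw noise.
#' @param passes number of 3x3 box-smoothing passes.
#' @param seed integer seed.
#' @return A [GrayImage-class].
#' @export
generateTexture <- function(width = 256, height = 256, mean = 128, sd = 60,
                            passes = 2, seed = 1) {
  withSeed(seed, {
    x <- matrix(stats::rnorm(width * height, mean, sd), height, width)
    for (p in seq_len(passes)) x <- boxSum(x, 1) / 9
    GrayImage(x)
  })
}

luminance <- c(r = 0.299, g = 0.587, b = 0.114)

toGray <- function(arr) {
  if (length(dim(arr)) == 2L) return(arr)
  ch <- dim(arr)[3]
  if (ch >= 3L) {
    luminance["r"] * arr[, , 1] + luminance["g"] * arr[, , 2] +
      luminance["b"] * arr[, , 3]
  } else {
    arr[, , 1]   # gray + alpha: drop alpha
  }
}

readPGM <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  magic <- rawToChar(raw[1:2])
  if (!magic %in% c("P2", "P5")) stop("not a PGM file: ", path, call. = FALSE)
  # collect the 3 header tokens (width, height, maxval), skipping comments
  pos <- 3L; tokens <- character(0)
  isSpace <- function(b) b %in% as.raw(c(9, 10, 13, 32))
  while (length(tokens) < 3L) {
    if (pos > length(raw)) stop("truncated PGM header: ", path, call. = FALSE)
    b <- raw[pos]
    if (b == as.raw(35L)) {                       # '#' comment to end of line
      while (pos <= length(raw) && raw[pos] != as.raw(10L)) pos <- pos + 1L
      pos <- pos + 1L
    } else if (isSpace(b)) {
      pos <- pos + 1L
    } else {
      start <- pos
      while (pos <= length(raw) && !isSpace(raw[pos]) &&
             raw[pos] != as.raw(35L)) pos <- pos + 1L
      tokens <- c(tokens, rawToChar(raw[start:(pos - 1L)]))
    }
  }
  w <- as.integer(tokens[1]); h <- as.integer(tokens[2])
  maxv <- as.integer(tokens[3])
  if (maxv > 255L) stop("only 8-bit PGM supported: ", path, call. = FALSE)
  if (magic == "P5") {
    pos <- pos + 1L                               # single whitespace after maxval
    v <- as.integer(raw[pos:(pos + w * h - 1L)])
  } else {
    v <- as.integer(strsplit(trimws(rawToChar(raw[pos:length(raw)])),
                             "[[:space:]]+")[[1]])[seq_len(w * h)]
  }
  matrix(v, nrow = h, ncol = w, byrow = TRUE)
}

writePGM <- function(m, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(sprintf("P5\n%d %d\n255\n", ncol(m), nrow(m)), con, eos = NULL)
  writeBin(as.raw(as.integer(t(m))), con)
  invisible(path)
}

imageFormat <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext, png = "png", pgm = "pgm", tif = , tiff = "tiff",
         stop("unsupported image format '", ext, "' for ", path, call. = FALSE))
}

#' Read an 8-bit grayscale image
#'
#' Reads PNG, PGM (P2/P5) or TIFF. Color inputs are converted to luminance
#' with the ITU-R BT.601 weights 0.299 R + 0.587 G + 0.114 B; an alpha
#' channel is dropped.
#'
#' @param path file path; format inferred from the extension.
#' @return A [GrayImage-class].
#' @export
readGrayImage <- function(path) {
  if (!file.exists(path)) stop("cannot read image: ", path, call. = FALSE)
  m <- switch(imageFormat(path),
    png = toGray(png::readPNG(path)) * 255,
    tiff = toGray(tiff::readTIFF(path)) * 255,
    pgm = readPGM(path))
  GrayImage(m)
}

#' Write an 8-bit grayscale image
#'
#' Writes PNG, PGM (P5) or TIFF; the write → read round trip is lossless
#' for 8-bit data.
#'
#' @param image a [GrayImage-class] or integer matrix.
#' @param path destination; format inferred from the extension.
#' @return `path`, invisibly.
#' @export
writeGrayImage <- function(image, path) {
  m <- asGrayMatrix(image)
  switch(imageFormat(path),
    png = png::writePNG(m / 255, path),
    tiff = tiff::writeTIFF(m / 255, path, bits.per.sample = 8L),
    pgm = writePGM(m, path))
  invisible(path)
}

#' Write a label mask
#'
#' Stores the integer label mask as an 8-bit gray PNG/PGM/TIFF holding the
#' raw label values, plus a JSON sidecar (`<path>.json`) mapping each label
#' to its name.
#'
#' @param mask integer matrix of labels in `[0, 255]`.
#' @param path destination image path.
#' @param labels named character vector or list, `label value -> name`;
#'   defaults to the scene semantics 0 = background, 1 = object, 2 = defect.
#' @return `path`, invisibly.
#' @export
writeMask <- function(mask, path,
                      labels = c("0" = "background", "1" = "object",
                                 "2" = "defect")) {
  writeGrayImage(GrayImage(mask), path)
  jsonlite::write_json(as.list(labels), paste0(path, ".json"),
                       auto_unbox = TRUE)
  invisible(path)
}

#' Read a label mask written by [writeMask()]
#'
#' @param path image path.
#' @return Integer matrix of labels.
#' @export
readMask <- function(path) {
  m <- readGrayImage(path)@.Data
  storage.mode(m) <- "integer"
  m
}
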