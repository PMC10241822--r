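# Recognition-accuracy metrics and mask-agreement scoring.

#' Single recognition accuracy
#'
#' `M_s = n_i / N` — the fraction of correct detections in one experiment.
#'
#' @param ni number of correct detections.
#' @param N number of testing samples (> 0).
#' @return Accuracy in `[0, 1]`.
#' @export
singleAccuracy <- function(ni, N) {
  if (N <= 0) stop("N must be positive", call. = FALSE)
  if (ni < 0 || ni > N) stop("need 0 <= ni <= N", call. = FALSE)
  ni / N
}

#' Average recognition accuracy
#'
#' `M = sum(M_s) / P` over `P` experiments.
#'
#' @param values vector of single accuracies.
#' @param P number of experiments; defaults to `length(values)`.
#' @return Mean accuracy in `[0, 1]`.
#' @export
meanAccuracy <- function(values, P = length(values)) {
  if (length(values) == 0L || P <= 0) stop("need at least one experiment",
                                           call. = FALSE)
  sum(values) / P
}

#' Score a predicted mask against ground truth
#'
#' Maps predicted labels onto truth labels by greedy majority overlap
#' (bijective: each predicted label is matched to at most one truth label,
#' largest confusion-matrix cells first), then reports pixel accuracy and
#' per-truth-class intersection-over-union under that mapping.
#'
#' @param pred integer predicted label matrix.
#' @param truth integer ground-truth label matrix of the same shape.
#' @return A list with `accuracy`, `iou` (named per truth label),
#'   `mapping` (predicted label -> truth label).
#' @examples
#' truth <- matrix(c(0, 0, 1, 1), 2)
#' pred <- matrix(c(1, 1, 0, 0), 2)   # same partition, labels swapped
#' maskAgreement(pred, truth)$accuracy
#' @export
maskAgreement <- function(pred, truth) {
  if (!identical(dim(pred), dim(truth)))
    stop("pred and truth must have identical shape", call. = FALSE)
  pl <- sort(unique(as.vector(pred)))
  tl <- sort(unique(as.vector(truth)))
  conf <- table(factor(pred, levels = pl), factor(truth, levels = tl))
  mapping <- stats::setNames(rep(NA_integer_, length(pl)), pl)
  usedT <- logical(length(tl))
  cells <- conf
  repeat {
    if (all(cells == -1)) break
    idx <- arrayInd(which.max(cells), dim(cells))
    if (cells[idx] <= 0) break
    mapping[idx[1]] <- tl[idx[2]]
    cells[idx[1], ] <- -1
    cells[, idx[2]] <- -1
    usedT[idx[2]] <- TRUE
  }
  # unmatched predicted labels keep an impossible label so they score 0
  mapped <- mapping[match(as.vector(pred), pl)]
  mapped[is.na(mapped)] <- -1L
  tv <- as.vector(truth)
  acc <- mean(mapped == tv)
  iou <- vapply(tl, function(lab) {
    inter <- sum(mapped == lab & tv == lab)
    un <- sum(mapped == lab | tv == lab)
    if (un == 0) 1 else inter / un
  }, numeric(1))
  names(iou) <- tl
  list(accuracy = acc, iou = iou, mapping = mapping)
}

#' Scene-level defect call from a mask
#'
#' A scene is called defective when any connected component of
#' defect-labeled pixels reaches `minArea` pixels (4-connectivity), a
#' simple proxy for a detector's present/absent decision.
#'
#' @param mask integer label matrix.
#' @param defectLabel label value marking defect pixels.
#' @param minArea minimum component area in pixels.
#' @return Logical defect call.
#' @export
defectCall <- function(mask, defectLabel = 2L, minArea = 20L) {
  bin <- mask == defectLabel
  if (!any(bin)) return(FALSE)
  M <- nrow(bin); N <- ncol(bin)
  lab <- matrix(0L, M, N)
  nextLab <- 0L
  idx <- which(bin)
  for (s in idx) {
    if (lab[s] != 0L) next
    nextLab <- nextLab + 1L
    queue <- s
    lab[s] <- nextLab
    size <- 1L
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      i <- (cur - 1L) %% M + 1L
      j <- (cur - 1L) %/% M + 1L
      for (nb in c(if (i > 1) cur - 1L, if (i < M) cur + 1L,
                   if (j > 1) cur - M, if (j < N) cur + M)) {
        if (bin[nb] && lab[nb] == 0L) {
          lab[nb] <- nextLab
          queue <- c(queue, nb)
          size <- size + 1L
        }
      }
    }
    if (size >= minArea) return(TRUE)
  }
  FALSE
}
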