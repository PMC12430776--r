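# Segmentation quality metrics, FLOPs accounting and runtime profiling.

#' Pixelwise segmentation metrics
#'
#' IoU, Dice, precision and recall from the confusion counts of two binary
#' masks. Conventions for degenerate masks: both empty gives 1 for every
#' rate; exactly one empty gives 0.
#'
#' @param pred_mask,truth_mask binary (0/1) matrices of identical shape.
#' @return A `metrics_report`: list(tp, fp, fn, tn, iou, dice, precision,
#'   recall).
#' @export
segmentation_metrics <- function(pred_mask, truth_mask) {
  if (!all(dim(pred_mask) == dim(truth_mask)))
    stop("mask shapes differ")
  if (!all(pred_mask %in% c(0, 1)) || !all(truth_mask %in% c(0, 1)))
    stop("masks must be binary (0/1)")
  p <- pred_mask == 1; g <- truth_mask == 1
  tp <- sum(p & g); fp <- sum(p & !g); fn <- sum(!p & g); tn <- sum(!p & !g)
  if (tp + fp + fn == 0) {
    iou <- dice <- prec <- rec <- 1
  } else {
    iou <- tp / (tp + fp + fn)
    dice <- 2 * tp / (2 * tp + fp + fn)
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- if (tp + fn > 0) tp / (tp + fn) else 0
  }
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn, iou = iou, dice = dice,
                 precision = prec, recall = rec),
            class = "metrics_report")
}

#' Extract boundary pixels of a binary mask
#'
#' A mask pixel is a boundary pixel when any of its 4-neighbours is
#' background or lies outside the image.
#'
#' @param mask binary matrix.
#' @return Two-column matrix of (row, col) coordinates.
#' @export
mask_boundary <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  m <- mask == 1
  pad <- matrix(FALSE, H + 2L, W + 2L)
  pad[2:(H + 1), 2:(W + 1)] <- m
  inner <- pad[1:H, 2:(W + 1)] & pad[3:(H + 2), 2:(W + 1)] &
    pad[2:(H + 1), 1:W] & pad[2:(H + 1), 3:(W + 2)]
  which(m & !inner, arr.ind = TRUE)
}

#' Hausdorff distance between point sets
#'
#' Directed: `max_a min_b ||a - b||_2`; symmetric: the larger of the two
#' directed distances. Distances are in pixels.
#'
#' @param A,B nonempty two-column coordinate matrices.
#' @param symmetric return the symmetric variant (default).
#' @return Distance (>= 0).
#' @export
hausdorff <- function(A, B, symmetric = TRUE) {
  A <- rbind(A); B <- rbind(B)
  if (nrow(A) == 0L || nrow(B) == 0L)
    stop("Hausdorff distance undefined for an empty point set")
  d2 <- outer(A[, 1], B[, 1], "-")^2 + outer(A[, 2], B[, 2], "-")^2
  h_ab <- sqrt(max(apply(d2, 1L, min)))
  if (!symmetric) return(h_ab)
  max(h_ab, sqrt(max(apply(d2, 2L, min))))
}

#' Hausdorff distance between mask boundaries
#'
#' @param pred_mask,truth_mask binary matrices.
#' @param symmetric symmetric variant (default).
#' @return Boundary Hausdorff distance in pixels.
#' @export
mask_hausdorff <- function(pred_mask, truth_mask, symmetric = TRUE) {
  hausdorff(mask_boundary(pred_mask), mask_boundary(truth_mask), symmetric)
}

#' Theoretical FLOPs of a convolutional layer
#'
#' `2 * Ho * Wo * Co * K^2 * Ci` multiply-add operations.
#'
#' @param Ho,Wo output height/width, @param Co output channels,
#' @param K kernel size, @param Ci input channels.
#' @return FLOP count.
#' @export
conv_flops <- function(Ho, Wo, Co, K, Ci) {
  stopifnot(Ho >= 1, Wo >= 1, Co >= 1, K >= 1, Ci >= 1)
  2 * Ho * Wo * Co * K^2 * Ci
}

#' Dense versus sparse attention cost
#'
#' @param n tokens, @param d dimension, @param k retained keys (k <= n).
#' @return list(dense, sparse, ratio) with `ratio = n / k`.
#' @export
attention_flops <- function(n, d, k) {
  stopifnot(k <= n)
  list(dense = n^2 * d, sparse = n * k * d, ratio = n / k)
}

#' Latency, throughput and energy from raw timings
#'
#' `T = mean(t_i)`, `FPS = 1 / T`, `E = P * T`. Values are
#' hardware-dependent; energy requires a user-supplied mean power draw.
#'
#' @param times per-repetition latencies in seconds.
#' @param power average power draw in watts.
#' @return A `runtime_report`: list(mean_latency, fps, energy, times).
#' @export
runtime_report <- function(times, power = 0) {
  T <- mean(times)
  structure(list(mean_latency = T, fps = 1 / T, energy = power * T,
                 times = times),
            class = "runtime_report")
}

#' Profile a callable model
#'
#' Runs one warm-up call then `reps` timed calls of `model_fn(batch)` and
#' summarizes them with [runtime_report()]. Results depend on the host
#' hardware and are labelled as such.
#'
#' @param model_fn function of one argument.
#' @param batch input passed to `model_fn`.
#' @param reps timed repetitions (>= 3).
#' @param power average power draw in watts for the energy estimate.
#' @return A `runtime_report`.
#' @export
profile_runtime <- function(model_fn, batch, reps = 5L, power = 0) {
  if (reps < 3L) stop("reps must be at least 3")
  model_fn(batch)  # warm-up
  times <- vapply(seq_len(reps), function(i) {
    t0 <- Sys.time()
    model_fn(batch)
    as.numeric(difftime(Sys.time(), t0, units = "secs"))
  }, numeric(1))
  runtime_report(times, power)
}
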