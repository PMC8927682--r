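# Confusion-matrix metrics and ranking AUC for vessel probability maps.
# Scoring is field-of-view-restricted by default (pixels outside the
# circular retinal region are excluded); pass fov = NULL to score all
# pixels, for parity with implementations that do not mask.

#' Confusion counts for a thresholded probability map
#'
#' A pixel is predicted vessel iff its probability strictly exceeds the
#' threshold (boundary pixels at exactly the threshold count as
#' background).
#'
#' @param prob probability matrix in [0, 1].
#' @param truth binary vessel annotation of the same shape.
#' @param fov binary field-of-view mask, or NULL to score every pixel.
#' @param threshold binarization threshold (default 0.5).
#' @return list with integer \code{tp}, \code{tn}, \code{fp}, \code{fn};
#'   their sum equals the number of scored pixels.
#' @export
fv_confusion <- function(prob, truth, fov = NULL, threshold = 0.5) {
  if (!identical(dim(prob), dim(truth)))
    stop("probability map and truth have different shapes")
  keep <- if (is.null(fov)) rep(TRUE, length(prob)) else {
    if (!identical(dim(fov), dim(prob)))
      stop("field-of-view mask shape mismatch")
    as.logical(fov > 0)
  }
  p <- as.numeric(prob)[keep] > threshold
  y <- as.numeric(truth)[keep] > 0.5
  list(tp = sum(p & y), tn = sum(!p & !y), fp = sum(p & !y),
       fn = sum(!p & y))
}

#' Segmentation metrics from confusion counts
#'
#' sensitivity = tp/(tp+fn), specificity = tn/(tn+fp),
#' accuracy = (tp+tn)/(tp+fn+tn+fp), F1 = 2tp/(2tp+fn+fp). A metric whose
#' denominator is zero is reported as NaN together with an
#' \code{undefined} flag naming it, never silently coerced to 0.
#'
#' @param counts list or named vector with tp, tn, fp, fn.
#' @return list with \code{sen}, \code{spe}, \code{acc}, \code{f1} and
#'   \code{undefined} (character vector of metrics with empty
#'   denominators).
#' @export
fv_metrics <- function(counts) {
  tp <- counts$tp; tn <- counts$tn; fp <- counts$fp; fn <- counts$fn
  if (any(c(tp, tn, fp, fn) < 0)) stop("negative confusion counts")
  rat <- function(num, den) if (den == 0) NaN else num / den
  out <- list(sen = rat(tp, tp + fn), spe = rat(tn, tn + fp),
              acc = rat(tp + tn, tp + tn + fp + fn),
              f1 = rat(2 * tp, 2 * tp + fn + fp))
  out$undefined <- names(out)[vapply(out[1:4], is.nan, TRUE)]
  out
}

#' Ranking AUC (Mann-Whitney statistic)
#'
#' The probability that a uniformly random vessel pixel's score exceeds a
#' random background pixel's score, counting ties as 1/2. Computed from
#' midranks, which is exactly the tie-corrected Mann-Whitney U / (n1*n0).
#'
#' @param prob probability values (matrix or vector).
#' @param truth binary labels of the same length/shape.
#' @param fov optional binary mask restricting the scored pixels.
#' @return AUC in [0, 1], or NaN (with a warning) when only one class is
#'   present inside the mask.
#' @export
fv_auc <- function(prob, truth, fov = NULL) {
  p <- as.numeric(prob)
  y <- as.numeric(truth) > 0.5
  if (length(p) != length(y)) stop("score/label length mismatch")
  if (!is.null(fov)) {
    keep <- as.numeric(fov) > 0
    p <- p[keep]; y <- y[keep]
  }
  n1 <- sum(y); n0 <- sum(!y)
  if (n1 == 0 || n0 == 0) {
    warning("AUC undefined: only one class present")
    return(NaN)
  }
  r <- rank(p)  # midranks implement the half-credit tie convention
  (sum(r[y]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Metric report for a set of predictions
#'
#' Computes per-map metrics and the micro-averaged (pooled-count) split
#' metrics for a list of probability maps.
#'
#' @param probs list of probability matrices.
#' @param truths list of matching binary annotations.
#' @param fovs list of matching field-of-view masks (or NULL).
#' @param threshold binarization threshold.
#' @return list with \code{per_map} (data.frame: one row per map) and
#'   \code{micro} (metrics on pooled counts, including pooled AUC).
#' @export
fv_metric_report <- function(probs, truths, fovs = NULL, threshold = 0.5) {
  n <- length(probs)
  if (length(truths) != n) stop("probs/truths length mismatch")
  rows <- vector("list", n)
  pooled <- c(tp = 0, tn = 0, fp = 0, fn = 0)
  all_p <- c(); all_y <- c()
  for (i in seq_len(n)) {
    fov <- if (is.null(fovs)) NULL else fovs[[i]]
    cc <- fv_confusion(probs[[i]], truths[[i]], fov, threshold)
    m <- fv_metrics(cc)
    a <- suppressWarnings(fv_auc(probs[[i]], truths[[i]], fov))
    rows[[i]] <- data.frame(map = i, tp = cc$tp, tn = cc$tn, fp = cc$fp,
                            fn = cc$fn, sen = m$sen, spe = m$spe,
                            acc = m$acc, f1 = m$f1, auc = a)
    pooled <- pooled + unlist(cc)[c("tp", "tn", "fp", "fn")]
    keep <- if (is.null(fov)) TRUE else fov > 0
    all_p <- c(all_p, probs[[i]][keep])
    all_y <- c(all_y, truths[[i]][keep])
  }
  micro <- fv_metrics(as.list(pooled))
  micro$auc <- suppressWarnings(fv_auc(all_p, all_y))
  list(per_map = do.call(rbind, rows), micro = micro)
}
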