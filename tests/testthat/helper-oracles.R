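# Independent brute-force oracles used to check the vectorised / GEMM
# implementations. These deliberately use naive double loops.

# Mask average pooling: plain double loop over spatial positions,
# normalised by the full area.
oracle_mask_avg_pool <- function(feature, mask) {
  d <- dim(feature)
  out <- numeric(d[3])
  for (c in seq_len(d[3])) {
    acc <- 0
    for (w in seq_len(d[2]))
      for (h in seq_len(d[1]))
        acc <- acc + feature[h, w, c] * mask[h, w]
    out[c] <- acc / (d[1] * d[2])
  }
  out
}

# Pixel-mean binary cross-entropy over a list of maps: scalar loop.
oracle_bce <- function(prob_maps, truths, eps = 1e-7) {
  total <- 0
  for (i in seq_along(prob_maps)) {
    p <- prob_maps[[i]]
    y <- truths[[i]]
    acc <- 0
    for (j in seq_along(p)) {
      pj <- min(max(p[j], eps), 1 - eps)
      acc <- acc - (y[j] * log(pj) + (1 - y[j]) * log(1 - pj))
    }
    total <- total + acc / length(p)
  }
  total / length(prob_maps)
}

# AUC by O(n^2) pairwise enumeration with half credit for ties.
oracle_auc <- function(scores, labels) {
  pos <- scores[labels > 0.5]
  neg <- scores[labels <= 0.5]
  wins <- 0
  for (a in pos)
    for (b in neg)
      wins <- wins + (a > b) + 0.5 * (a == b)
  wins / (length(pos) * length(neg))
}

# Per-pixel ensemble vote/fusion evaluated literally from the printed
# indicator and max/min branches.
oracle_vote_fuse <- function(triple, T = 0.5, T1 = 1) {
  votes <- sum(triple > T)
  v <- as.numeric(votes > T1)
  list(vote = v, fused = if (v == 1) max(triple) else min(triple))
}

# Brute-force patch origin enumeration: all stride positions plus a
# border-flush origin when needed.
oracle_origins <- function(n, template, stride) {
  o <- c()
  pos <- 0
  while (pos + template <= n) {
    o <- c(o, pos)
    pos <- pos + stride
  }
  if (o[length(o)] != n - template) o <- c(o, n - template)
  o
}
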