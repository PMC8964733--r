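# Independent brute-force oracles used across the suite. These are kept
# deliberately naive (double loops, exhaustive enumeration) so they share
# no code path with the package implementations they check.

# Mann-Whitney AUC by looping over every positive/negative pair
oracle_roc_auc <- function(pos, neg) {
  s <- 0
  for (p in pos) for (n in neg) {
    s <- s + if (p > n) 1 else if (p == n) 0.5 else 0
  }
  s / (length(pos) * length(neg))
}

# PR curve by explicit threshold enumeration, trapezoidal in recall,
# anchored at (0, precision of the highest threshold)
oracle_pr_auc <- function(pos, neg) {
  thr <- sort(unique(c(pos, neg)), decreasing = TRUE)
  rec <- prec <- c()
  for (t in thr) {
    tp <- sum(pos >= t); fp <- sum(neg >= t)
    if (tp + fp == 0) next
    rec <- c(rec, tp / length(pos))
    prec <- c(prec, tp / (tp + fp))
  }
  r <- c(0, rec); p <- c(prec[1], prec)
  a <- 0
  for (i in 2:length(r)) a <- a + (r[i] - r[i - 1]) * (p[i] + p[i - 1]) / 2
  a
}

# exhaustive F1 scan over observed thresholds
oracle_max_f1 <- function(pos, neg) {
  best <- -Inf
  for (t in sort(unique(c(pos, neg)))) {
    tp <- sum(pos >= t); fp <- sum(neg >= t); fn <- sum(pos < t)
    if (tp + fp == 0) next
    prec <- tp / (tp + fp); rec <- tp / (tp + fn)
    if (prec + rec == 0) next
    f1 <- 2 * prec * rec / (prec + rec)
    if (f1 > best) best <- f1
  }
  best
}

# Moran's I by the literal double sum with binary queen weights
oracle_morans_i <- function(counts, member) {
  idx <- which(member, arr.ind = TRUE)
  x <- counts[member]
  n <- length(x)
  xbar <- mean(x)
  z <- x - xbar
  num <- 0; W <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    w <- as.numeric(max(abs(idx[i, 1] - idx[j, 1]),
                        abs(idx[i, 2] - idx[j, 2])) == 1)
    num <- num + w * z[i] * z[j]
    W <- W + w
  }
  (n / W) * num / sum(z^2)
}

# maximum number of points keepable under the pairwise distance bound,
# by enumerating every subset (feasible for <= ~12 points)
oracle_max_retention <- function(lon, lat, thr_km) {
  n <- length(lon)
  d <- geosphere::distm(cbind(lon, lat),
                        fun = geosphere::distHaversine) / 1000
  best <- 0
  for (mask in 0:(2^n - 1)) {
    keep <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    if (length(keep) <= best) next
    ok <- TRUE
    if (length(keep) > 1) {
      for (a in seq_len(length(keep) - 1)) for (b in (a + 1):length(keep)) {
        if (d[keep[a], keep[b]] < thr_km) { ok <- FALSE; break }
      }
    }
    if (ok) best <- length(keep)
  }
  best
}
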