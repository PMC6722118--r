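# Independent oracles used against the package implementations.

# Exhaustive Otsu: between-class variance computed from first principles for
# every one of the n-1 cuts; lowest maximising cut wins.
oracle_otsu <- function(counts, breaks) {
  n <- length(counts)
  mids <- (breaks[-1] + breaks[-(n + 1)]) / 2
  total <- sum(counts)
  best <- -Inf
  best_k <- NA_integer_
  for (k in 1:(n - 1)) {
    n1 <- sum(counts[1:k])
    n2 <- total - n1
    if (n1 == 0 || n2 == 0) next
    m1 <- sum(counts[1:k] * mids[1:k]) / n1
    m2 <- sum(counts[(k + 1):n] * mids[(k + 1):n]) / n2
    sb <- (n1 / total) * (n2 / total) * (m1 - m2)^2
    if (sb > best + 1e-15) {
      best <- sb
      best_k <- k
    }
  }
  breaks[best_k + 1]
}

# Stack-based flood fill labeling, the slow-but-obvious reference for
# connected components.
oracle_label <- function(mask, connectivity = 8) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  nb <- if (connectivity == 8) {
    cbind(c(-1, -1, -1, 0, 0, 1, 1, 1), c(-1, 0, 1, -1, 1, -1, 0, 1))
  } else {
    cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  }
  cur <- 0L
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    if (!mask[i, j] || lab[i, j] > 0L) next
    cur <- cur + 1L
    stack <- list(c(i, j))
    lab[i, j] <- cur
    while (length(stack) > 0) {
      p <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      for (q in seq_len(nrow(nb))) {
        y <- p[1] + nb[q, 1]; x <- p[2] + nb[q, 2]
        if (y >= 1 && y <= nr && x >= 1 && x <= nc &&
            mask[y, x] && lab[y, x] == 0L) {
          lab[y, x] <- cur
          stack[[length(stack) + 1]] <- c(y, x)
        }
      }
    }
  }
  lab
}

# Label maps are equivalent if they induce the same pixel partition
# (labels in one map correspond one-to-one to labels in the other).
same_partition <- function(a, b) {
  if (!identical(a > 0, b > 0)) return(FALSE)
  fa <- a[a > 0]
  fb <- b[b > 0]
  all(tapply(fb, fa, function(v) length(unique(v))) == 1) &&
    all(tapply(fa, fb, function(v) length(unique(v))) == 1)
}

# Textbook paired t-test on a vector of differences.
oracle_paired_t <- function(d) {
  n <- length(d)
  t <- mean(d) / (sd(d) / sqrt(n))
  list(t = t, df = n - 1, p = 2 * pt(-abs(t), n - 1))
}
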