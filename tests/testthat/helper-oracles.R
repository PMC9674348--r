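# Independent brute-force oracles used across the suite. These deliberately
# re-derive results from first principles (naive loops, enumeration) and
# never call the code paths they check.

# textbook two-pass one-way ANOVA F for a single numeric vector
oracle_anova_f <- function(v, groups) {
  groups <- as.factor(groups)
  k <- nlevels(groups)
  n <- length(v)
  gm <- mean(v)
  ssb <- 0
  ssw <- 0
  for (lev in levels(groups)) {
    vi <- v[groups == lev]
    ssb <- ssb + length(vi) * (mean(vi) - gm)^2
    ssw <- ssw + sum((vi - mean(vi))^2)
  }
  (ssb / (k - 1)) / (ssw / (n - k))
}

# Benjamini-Hochberg step-up, written directly from the procedure
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  prev <- 1
  for (i in n:1) {
    val <- min(prev, p[o[i]] * n / i)
    adj[o[i]] <- val
    prev <- val
  }
  adj
}

# one-sided hypergeometric tail P(X >= x) by pmf summation
oracle_hyper_tail <- function(x, term_size, bg_size, draw_size) {
  upper <- min(term_size, draw_size)
  if (x > upper) return(0)
  sum(vapply(x:upper, function(i)
    choose(term_size, i) * choose(bg_size - term_size, draw_size - i) /
      choose(bg_size, draw_size), numeric(1)))
}

# O(n^3) agglomerative complete-linkage clustering on a point matrix;
# returns merge heights and the partition at each k
oracle_complete_linkage <- function(pts) {
  n <- nrow(pts)
  d <- as.matrix(dist(pts))
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  partitions <- list()
  partitions[[n]] <- seq_len(n)
  while (length(clusters) > 1) {
    m <- length(clusters)
    best <- c(Inf, NA, NA)
    for (i in 1:(m - 1)) for (j in (i + 1):m) {
      h <- max(d[clusters[[i]], clusters[[j]]])
      if (h < best[1]) best <- c(h, i, j)
    }
    i <- best[2]; j <- best[3]
    clusters[[i]] <- c(clusters[[i]], clusters[[j]])
    clusters[[j]] <- NULL
    heights <- c(heights, best[1])
    lab <- integer(n)
    for (ci in seq_along(clusters)) lab[clusters[[ci]]] <- ci
    partitions[[length(clusters)]] <- lab
  }
  list(heights = heights, partitions = partitions)
}

# canonical form of a partition label vector (first-appearance relabelling)
canon_partition <- function(lab) match(lab, unique(lab))

# mean silhouette width of a labelled 2-D embedding, written directly
oracle_silhouette <- function(xy, lab) {
  d <- as.matrix(dist(xy))
  n <- nrow(xy)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(lab == lab[i] & seq_len(n) != i)
    a <- mean(d[i, own])
    b <- min(vapply(setdiff(unique(lab), lab[i]),
                    function(l) mean(d[i, lab == l]), numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}
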