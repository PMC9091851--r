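# Independent brute-force oracles used to validate the dynamic programs,
# the linkage, and the label alignment against exhaustive enumeration.

# All monotone warping paths from (1,1) to (n,m), summed Euclidean cost;
# exponential enumeration, fine for lengths <= 4.
dtw_brute <- function(t1, t2) {
  n <- nrow(t1); m <- nrow(t2)
  d <- function(i, j) sqrt(sum((t1[i, ] - t2[j, ])^2))
  rec <- function(i, j) {
    if (i == 1 && j == 1) return(d(1, 1))
    best <- Inf
    if (i > 1) best <- min(best, rec(i - 1, j))
    if (j > 1) best <- min(best, rec(i, j - 1))
    if (i > 1 && j > 1) best <- min(best, rec(i - 1, j - 1))
    d(i, j) + best
  }
  rec(n, m)
}

# Memo-free recursive edit distance.
ed_brute <- function(t1, t2, eps) {
  rec <- function(i, j) {
    if (i == 0) return(j)
    if (j == 0) return(i)
    match <- all(abs(t1[i, ] - t2[j, ]) <= eps)
    min(rec(i - 1, j - 1) + (if (match) 0L else 1L),
        rec(i - 1, j) + 1L,
        rec(i, j - 1) + 1L)
  }
  rec(nrow(t1), nrow(t2))
}

# LCS count by enumerating all subsequences of the shorter sequence.
lcss_count_brute <- function(t1, t2, tx, ty, eps) {
  n <- nrow(t1); m <- nrow(t2)
  t2s <- cbind(t2[, 1] + tx, t2[, 2] + ty)
  best <- 0L
  # enumerate index subsets of t1 and test embeddability in t2s
  for (len in n:1) {
    if (len <= best) break
    combs <- utils::combn(n, len, simplify = FALSE)
    for (sub in combs) {
      j <- 1L; ok <- 0L
      for (i in sub) {
        while (j <= m && !all(abs(t1[i, ] - t2s[j, ]) <= eps)) j <- j + 1L
        if (j > m) break
        ok <- ok + 1L; j <- j + 1L
      }
      if (ok == len) { best <- len; break }
    }
  }
  best
}

lcss_brute <- function(t1, t2, eps, n_translations, translation_range = c(3, 100)) {
  gx <- seq(-translation_range[1], translation_range[1],
            length.out = 2 * n_translations + 1)
  gy <- seq(-translation_range[2], translation_range[2],
            length.out = 2 * n_translations + 1)
  best <- 0L
  for (tx in gx) for (ty in gy)
    best <- max(best, lcss_count_brute(t1, t2, tx, ty, eps))
  best / min(nrow(t1), nrow(t2))
}

# Naive O(n^3) complete-linkage agglomeration: merge heights only.
hclust_complete_brute <- function(dm) {
  n <- nrow(dm)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- Inf; bi <- 0; bj <- 0
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (j <= i) next
        h <- max(dm[clusters[[i]], clusters[[j]]])
        if (h < best) { best <- h; bi <- i; bj <- j }
      }
    }
    heights <- c(heights, best)
    clusters[[bi]] <- c(clusters[[bi]], clusters[[bj]])
    clusters[[bj]] <- NULL
  }
  heights
}

perms <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v))
    out <- c(out, lapply(perms(v[-i]), function(p) c(v[i], p)))
  out
}

# Exhaustive-permutation maximum agreement between two labelings.
align_brute <- function(la, lb) {
  K <- max(la, lb)
  tab <- table(factor(la, levels = 1:K), factor(lb, levels = 1:K))
  best <- 0
  for (p in perms(1:K))
    best <- max(best, sum(tab[cbind(1:K, p)]))
  100 * best / length(la)
}

# Random analysable trajectory of given length as a point matrix.
random_traj <- function(len) {
  pos <- sort(sample(1:4, len))
  cbind(pos = pos, value = round(stats::runif(len, 0, 60), 1))
}
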