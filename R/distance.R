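# Trajectory similarity measures on RPPs as 2-D point sequences
# (quadrant position, porosity). Missing points are dropped, not imputed;
# positions are retained, so the measures tolerate incomplete RPPs.

#' Convert an RPP trajectory to 2-D trajectory points
#'
#' Drops missing entries and keeps (quadrant index, porosity) pairs with
#' strictly increasing positions.
#'
#' @param traj Numeric length-4 vector or `rpp_trajectory`.
#' @return Matrix with columns `pos`, `value`; one row per measured point.
#' @export
trajectory_points <- function(traj) {
  v <- as.numeric(traj)
  keep <- !is.na(v)
  cbind(pos = seq_along(v)[keep], value = v[keep])
}

#' Dynamic time warping distance
#'
#' Minimal sum of Euclidean point-to-point distances over monotone warping
#' paths covering both sequences (start at the first pair, end at the last,
#' steps advance one or both sequences). Unconstrained warping; the
#' objective is the raw sum, not normalised.
#'
#' @param t1,t2 Point matrices as from [trajectory_points()] (columns pos,
#'   value), or numeric length-4 vectors with NAs.
#' @return Non-negative warping distance.
#' @export
dtw_distance <- function(t1, t2) {
  t1 <- as_points(t1); t2 <- as_points(t2)
  n <- nrow(t1); m <- nrow(t2)
  if (n == 0 || m == 0) stop("trajectories must contain at least one point")
  d <- outer(seq_len(n), seq_len(m), function(i, j)
    sqrt((t1[i, 1] - t2[j, 1])^2 + (t1[i, 2] - t2[j, 2])^2))
  acc <- matrix(Inf, n, m)
  acc[1, 1] <- d[1, 1]
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      if (i == 1 && j == 1) next
      best <- Inf
      if (i > 1) best <- min(best, acc[i - 1, j])
      if (j > 1) best <- min(best, acc[i, j - 1])
      if (i > 1 && j > 1) best <- min(best, acc[i - 1, j - 1])
      acc[i, j] <- d[i, j] + best
    }
  }
  acc[n, m]
}

as_points <- function(t) {
  if (is.matrix(t) && ncol(t) == 2) return(t)
  trajectory_points(t)
}

#' Edit distance between trajectories
#'
#' Levenshtein-style dynamic program: two points match (substitution cost
#' 0) when both coordinate differences are at most `eps`; otherwise
#' substitution, insertion and deletion each cost 1. The result is the
#' minimum number of edits for the two trajectories to be considered
#' equivalent.
#'
#' @param t1,t2 Point matrices or length-4 vectors with NAs.
#' @param eps Matching tolerance applied to both coordinates (default 5).
#' @return Non-negative integer edit count.
#' @export
edit_distance <- function(t1, t2, eps = 5) {
  if (eps < 0) stop("eps must be >= 0")
  t1 <- as_points(t1); t2 <- as_points(t2)
  n <- nrow(t1); m <- nrow(t2)
  D <- matrix(0L, n + 1L, m + 1L)
  D[, 1] <- 0:n
  D[1, ] <- 0:m
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      match <- abs(t1[i, 1] - t2[j, 1]) <= eps &&
        abs(t1[i, 2] - t2[j, 2]) <= eps
      D[i + 1, j + 1] <- min(D[i, j] + (if (match) 0L else 1L),
                             D[i, j + 1] + 1L,
                             D[i + 1, j] + 1L)
    }
  }
  as.integer(D[n + 1, m + 1])
}

#' Longest common subsequence similarity
#'
#' Counts the longest common subsequence of points (equivalent when both
#' coordinate differences are at most `eps`), maximised over a symmetric
#' grid of translations of the second trajectory in both dimensions.
#' Similarity is the count divided by the shorter length; distance is
#' 1 - similarity.
#'
#' @param t1,t2 Point matrices or length-4 vectors with NAs.
#' @param eps Matching tolerance (default 5).
#' @param n_translations Translations per dimension per sign (default 20).
#' @param translation_range Length-2 vector: maximum absolute translation in
#'   the position and value dimension. Default `c(3, 100)` spans the
#'   quadrant range and the full porosity scale.
#' @return List with `similarity` in [0, 1], `distance` = 1 - similarity,
#'   and `best_translation`.
#' @export
lcss <- function(t1, t2, eps = 5, n_translations = 20,
                 translation_range = c(3, 100)) {
  if (eps < 0) stop("eps must be >= 0")
  if (n_translations < 1) stop("n_translations must be >= 1")
  t1 <- as_points(t1); t2 <- as_points(t2)
  gx <- seq(-translation_range[1], translation_range[1],
            length.out = 2 * n_translations + 1)
  gy <- seq(-translation_range[2], translation_range[2],
            length.out = 2 * n_translations + 1)
  best <- -1L; best_tr <- c(0, 0)
  for (tx in gx) {
    for (ty in gy) {
      cnt <- lcss_count(t1, t2, tx, ty, eps)
      if (cnt > best) { best <- cnt; best_tr <- c(tx, ty) }
    }
  }
  sim <- best / min(nrow(t1), nrow(t2))
  list(similarity = sim, distance = 1 - sim, best_translation = best_tr)
}

lcss_count <- function(t1, t2, tx, ty, eps) {
  n <- nrow(t1); m <- nrow(t2)
  L <- matrix(0L, n + 1L, m + 1L)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      match <- abs(t1[i, 1] - (t2[j, 1] + tx)) <= eps &&
        abs(t1[i, 2] - (t2[j, 2] + ty)) <= eps
      L[i + 1, j + 1] <- if (match) L[i, j] + 1L
      else max(L[i, j + 1], L[i + 1, j])
    }
  }
  L[n + 1, m + 1]
}

#' Pairwise distance matrix over a set of RPPs
#'
#' Assembles the symmetric distance matrix for one similarity measure over
#' all analysable trajectories (at least two measured points). Trajectories
#' failing the rule are excluded and listed in the `rejected` attribute.
#'
#' @param rpps An `rpp_set` (see [rpp_wide()]), or a numeric matrix with 4
#'   columns and element ids as row names.
#' @param method `"dtw"`, `"ed"` or `"lcss"`.
#' @param ... Parameters passed to the measure (`eps`, `n_translations`,
#'   `translation_range`).
#' @return Symmetric matrix with zero diagonal and element ids as
#'   dimnames; attribute `rejected` lists excluded element ids.
#' @export
distance_matrix <- function(rpps, method = c("dtw", "ed", "lcss"), ...) {
  method <- match.arg(method)
  m <- rpp_matrix(rpps)
  ok <- apply(m, 1, function(v) sum(!is.na(v)) >= 2L)
  rejected <- rownames(m)[!ok]
  m <- m[ok, , drop = FALSE]
  n <- nrow(m)
  if (n < 2) stop("need at least two analysable trajectories")
  pts <- lapply(seq_len(n), function(i) trajectory_points(m[i, ]))
  D <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      D[i, j] <- D[j, i] <- switch(
        method,
        dtw = dtw_distance(pts[[i]], pts[[j]]),
        ed = edit_distance(pts[[i]], pts[[j]], ...),
        lcss = lcss(pts[[i]], pts[[j]], ...)$distance)
    }
  }
  attr(D, "rejected") <- rejected
  attr(D, "method") <- method
  D
}
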