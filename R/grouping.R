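# Grouping engines on RPP sets: restarted k-means on complete 4-point
# profiles and complete-linkage agglomerative clustering on distance
# matrices. (Group-based trajectory modelling lives in gbtm.R.)

#' Construct a grouping result
#'
#' @param method One of `kmeans`, `gbtm`, `dtw_hclust`, `ed_hclust`,
#'   `lcss_hclust`.
#' @param k Number of groups.
#' @param labels Named integer vector (element id -> group 1..k).
#' @param objective Method objective (within-cluster SS, log-likelihood, or
#'   cut height).
#' @param seed,params Run record.
#' @return A `grouping_result`.
#' @export
grouping_result <- function(method, k, labels, objective = NA_real_,
                            seed = NA_integer_, params = list()) {
  method <- match.arg(method, c("kmeans", "gbtm", "dtw_hclust",
                                "ed_hclust", "lcss_hclust"))
  labels <- stats::setNames(as.integer(labels), names(labels))
  if (is.null(names(labels))) stop("labels must be named by element id")
  if (any(labels < 1L | labels > k)) stop("labels must lie in 1..k")
  structure(list(method = method, k = as.integer(k), labels = labels,
                 objective = objective, seed = seed, params = params),
            class = "grouping_result")
}

#' @export
print.grouping_result <- function(x, ...) {
  cat(sprintf("grouping_result: %s, k = %d, n = %d, objective = %s\n",
              x$method, x$k, length(x$labels),
              format(x$objective, digits = 6)))
  print(table(group = x$labels))
  invisible(x)
}

#' K-means clustering of complete RPPs
#'
#' Lloyd iterations on the raw 4-point porosity vectors from many random
#' initialisations, keeping the labelling with minimal within-cluster sum
#' of squares. Only complete RPPs (all four points measured) are accepted.
#'
#' @param rpps An `rpp_set` or numeric matrix (rows = elements, 4 columns).
#' @param k Number of clusters.
#' @param n_restarts Random restarts (default 100).
#' @param seed Integer seed; the run is deterministic given it.
#' @return A `grouping_result` with the total within-cluster SS as
#'   objective.
#' @export
kmeans_cluster <- function(rpps, k, n_restarts = 100L, seed = 1L) {
  m <- rpp_matrix(rpps)
  if (any(is.na(m)))
    stop("k-means requires complete RPPs; route incomplete ones to the distance-based methods")
  if (nrow(m) < k) stop("fewer trajectories than clusters")
  set.seed(seed)
  fit <- NULL
  for (attempt in 1:5) {
    fit <- tryCatch(
      stats::kmeans(m, centers = k, nstart = n_restarts,
                    iter.max = 200L, algorithm = "Lloyd"),
      warning = function(w) suppressWarnings(
        stats::kmeans(m, centers = k, nstart = n_restarts,
                      iter.max = 500L, algorithm = "Lloyd")),
      error = function(e) NULL)
    if (!is.null(fit)) break
  }
  if (is.null(fit)) stop("k-means failed to produce a clustering")
  grouping_result("kmeans", k,
                  stats::setNames(fit$cluster, rownames(m)),
                  objective = fit$tot.withinss, seed = seed,
                  params = list(n_restarts = n_restarts))
}

#' Complete-linkage hierarchical clustering
#'
#' Agglomerative clustering with complete (maximum) linkage on a symmetric
#' distance matrix, as applied to the DTW/ED/LCSS distance matrices.
#'
#' @param dm Symmetric distance matrix with zero diagonal (as from
#'   [distance_matrix()]).
#' @return An `hclust` dendrogram.
#' @export
hclust_complete <- function(dm) {
  dm <- as.matrix(dm)
  if (nrow(dm) != ncol(dm) || max(abs(dm - t(dm))) > 1e-9)
    stop("distance matrix must be symmetric")
  if (any(diag(dm) != 0)) stop("distance matrix must have a zero diagonal")
  stats::hclust(stats::as.dist(dm), method = "complete")
}

#' Cut a dendrogram into k groups
#'
#' @param dendrogram An `hclust` object.
#' @param k Number of groups, between 1 and the number of leaves.
#' @param method Method tag recorded in the result (default `dtw_hclust`).
#' @return A `grouping_result`; the objective is the height of the last
#'   merge that the cut undoes.
#' @export
cut_tree <- function(dendrogram, k, method = "dtw_hclust") {
  n <- length(dendrogram$order)
  if (k < 1 || k > n) stop("k must lie in 1..n leaves")
  labels <- stats::cutree(dendrogram, k = k)
  cut_height <- if (k == 1) max(dendrogram$height) else
    dendrogram$height[n - k + 1L]
  grouping_result(method, k, labels, objective = cut_height)
}

#' Adjusted Rand index between two labelings
#'
#' Permutation-invariant chance-corrected agreement between two partitions
#' of the same elements.
#'
#' @param a,b Integer label vectors (or `grouping_result`s) over the same
#'   elements.
#' @return ARI in [-1, 1]; 1 means identical partitions.
#' @export
adjusted_rand_index <- function(a, b) {
  if (inherits(a, "grouping_result")) a <- a$labels
  if (inherits(b, "grouping_result")) b <- b$labels
  if (!is.null(names(a)) && !is.null(names(b))) {
    shared <- intersect(names(a), names(b))
    a <- a[shared]; b <- b[shared]
  }
  if (length(a) != length(b)) stop("labelings must cover the same elements")
  tab <- table(a, b)
  ch2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(ch2(tab))
  sum_a <- sum(ch2(rowSums(tab)))
  sum_b <- sum(ch2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / ch2(n)
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}
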