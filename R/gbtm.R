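# Group-based trajectory modelling: a k-component mixture of polynomial
# mean trajectories over quadrant index 1..4 with Gaussian residuals
# (shared variance), fitted by EM from many random starts.
#
# The residual model is Gaussian, not the zero-inflated Poisson of the
# criminology tools where GBTM originated: porosity is a continuous
# percentage, not an event count.

gbtm_basis <- function(degree, positions = 1:4) {
  outer(positions, 0:degree, `^`)
}

gbtm_n_par <- function(k, degree) {
  k * (degree + 1L) + (k - 1L) + 1L  # curves + mixing weights + sigma
}

# One EM run from a given hard initial assignment. Returns NULL on a
# degenerate path (empty component).
gbtm_em <- function(Y, X, k, init_labels, max_iter, tol) {
  n <- nrow(Y); d <- ncol(Y)
  XtX <- crossprod(X)
  W <- matrix(0, n, k)
  W[cbind(seq_len(n), init_labels)] <- 1
  loglik_old <- -Inf
  loglik_trace <- numeric(0)
  B <- NULL; sigma2 <- NULL; pi_g <- NULL
  for (iter in seq_len(max_iter)) {
    # M-step
    cs <- colSums(W)
    if (any(cs < 1 / n)) return(NULL)  # degenerate component
    pi_g <- cs / n
    B <- matrix(0, ncol(X), k)
    resid_ss <- 0
    M <- matrix(0, d, k)
    for (g in seq_len(k)) {
      ybar <- colSums(W[, g] * Y) / cs[g]
      B[, g] <- solve(XtX, crossprod(X, ybar))
      M[, g] <- X %*% B[, g]
    }
    R2 <- sapply(seq_len(k), function(g)
      rowSums(sweep(Y, 2, M[, g])^2))        # n x k squared residuals
    sigma2 <- sum(W * R2) / (n * d)
    sigma2 <- max(sigma2, 1e-12)
    # E-step
    logd <- -d / 2 * log(2 * pi * sigma2) - R2 / (2 * sigma2)
    logw <- sweep(logd, 2, log(pi_g), `+`)
    mx <- apply(logw, 1, max)
    lse <- mx + log(rowSums(exp(logw - mx)))
    W <- exp(logw - lse)
    loglik <- sum(lse)
    if (loglik < loglik_old - 1e-6)
      warning("EM log-likelihood decreased; numerical degeneracy")
    loglik_trace <- c(loglik_trace, loglik)
    if (is.finite(loglik_old) && abs(loglik - loglik_old) < tol) break
    loglik_old <- loglik
  }
  list(B = B, sigma = sqrt(sigma2), pi = pi_g, posterior = W,
       logLik = loglik, n_iter = iter, trace = loglik_trace,
       converged = iter < max_iter)
}

# k-means++ style seeding on the raw 4-vectors, returning hard labels.
gbtm_seed_labels <- function(Y, k) {
  n <- nrow(Y)
  centers <- matrix(NA_real_, k, ncol(Y))
  centers[1, ] <- Y[sample.int(n, 1L), ]
  d2 <- rowSums(sweep(Y, 2, centers[1, ])^2)
  if (k > 1) {
    for (g in 2:k) {
      p <- if (sum(d2) == 0) rep(1 / n, n) else d2 / sum(d2)
      centers[g, ] <- Y[sample.int(n, 1L, prob = p), ]
      d2 <- pmin(d2, rowSums(sweep(Y, 2, centers[g, ])^2))
    }
  }
  dist2 <- sapply(seq_len(k), function(g)
    rowSums(sweep(Y, 2, centers[g, ])^2))
  max.col(-matrix(dist2, n, k), ties.method = "first")
}

#' Fit a group-based trajectory model
#'
#' Fits a k-component mixture of polynomial mean trajectories over
#' quadrant index with Gaussian residuals (shared variance) by EM. Each
#' random start is seeded k-means++ style on the raw 4-vectors, warmed up
#' with a short EM burst; the best start by log-likelihood is then run to
#' convergence. AIC = -2l + 2p and BIC = -2l + p log(n) with
#' p = k(degree+1) + (k-1) + 1.
#'
#' @param rpps An `rpp_set` or complete numeric matrix (n x 4).
#' @param k Number of trajectory groups.
#' @param degree Polynomial degree (<= 3 with four points).
#' @param n_starts Random starts (default 100).
#' @param seed Integer seed.
#' @param max_iter Maximum EM iterations for the final run (default 500).
#' @param tol Convergence tolerance on the log-likelihood (default 1e-8).
#' @param warm_iter EM iterations per exploratory start (default 25).
#' @return Object of class `gbtm`: coefficients (one column per group),
#'   `sigma`, mixing `weights`, `posterior` (n x k), hard `labels`,
#'   `logLik`, `AIC`, `BIC`, and the run record.
#' @seealso [gbtm_select()], [gbtm_cve()]
#' @export
fit_gbtm <- function(rpps, k, degree = 2L, n_starts = 100L, seed = 1L,
                     max_iter = 500L, tol = 1e-8, warm_iter = 25L) {
  Y <- rpp_matrix(rpps)
  if (any(is.na(Y)))
    stop("GBTM requires complete RPPs; route incomplete ones to the distance-based methods")
  n <- nrow(Y)
  if (degree > ncol(Y) - 1L) stop("degree must be <= 3 with four points")
  if (n < k) stop("fewer trajectories than groups")
  set.seed(seed)
  X <- gbtm_basis(degree)
  best <- NULL; n_degenerate <- 0L
  for (s in seq_len(n_starts)) {
    init <- gbtm_seed_labels(Y, k)
    if (length(unique(init)) < k) { n_degenerate <- n_degenerate + 1L; next }
    run <- gbtm_em(Y, X, k, init, max_iter = warm_iter, tol = tol)
    if (is.null(run)) { n_degenerate <- n_degenerate + 1L; next }
    if (is.null(best) || run$logLik > best$logLik) {
      best <- run; best$init <- init
    }
  }
  if (is.null(best))
    stop("EM failed in all starts (degenerate components); reduce k")
  fit <- gbtm_em(Y, X, k, best$init, max_iter = max_iter, tol = tol)
  if (is.null(fit) || fit$logLik < best$logLik) fit <- best
  p <- gbtm_n_par(k, degree)
  labels <- apply(fit$posterior, 1, which.max)
  ids <- rownames(Y)
  if (is.null(ids)) ids <- sprintf("E%03d", seq_len(n))
  rownames(fit$posterior) <- ids
  structure(list(coefficients = fit$B, sigma = fit$sigma,
                 weights = fit$pi, posterior = fit$posterior,
                 labels = stats::setNames(labels, ids),
                 logLik = fit$logLik,
                 AIC = -2 * fit$logLik + 2 * p,
                 BIC = -2 * fit$logLik + p * log(n),
                 n_par = p, k = as.integer(k), degree = as.integer(degree),
                 n = n, y = Y, converged = fit$converged,
                 n_iter = fit$n_iter, n_degenerate_starts = n_degenerate,
                 seed = seed, n_starts = n_starts),
            class = "gbtm")
}

#' @export
print.gbtm <- function(x, ...) {
  cat(sprintf("GBTM: %d group%s, polynomial degree %d, n = %d\n",
              x$k, if (x$k > 1) "s" else "", x$degree, x$n))
  cat(sprintf("logLik %.3f  AIC %.3f  BIC %.3f  sigma %.3f\n",
              x$logLik, x$AIC, x$BIC, x$sigma))
  cat("group sizes:", paste(tabulate(x$labels, x$k), collapse = " "), "\n")
  invisible(x)
}

#' @export
summary.gbtm <- function(object, ...) {
  print(object)
  cat("\nmixing weights:\n")
  print(round(object$weights, 3))
  cat("\ncoefficients (rows: intercept, q, q^2, ...):\n")
  co <- object$coefficients
  dimnames(co) <- list(paste0("q^", 0:(nrow(co) - 1)),
                       paste0("group", seq_len(ncol(co))))
  print(round(co, 4))
  invisible(object)
}

#' @export
coef.gbtm <- function(object, ...) object$coefficients

#' @export
logLik.gbtm <- function(object, ...) {
  structure(object$logLik, df = object$n_par, nobs = object$n,
            class = "logLik")
}

#' Predict from a GBTM fit
#'
#' @param object A `gbtm`.
#' @param newdata Quadrant positions (default 1:4).
#' @param type `"curves"` (group mean trajectories, positions x k),
#'   `"class"` (hard labels), or `"response"` (posterior-weighted fitted
#'   trajectories per element).
#' @param ... Unused.
#' @export
predict.gbtm <- function(object, newdata = 1:4,
                         type = c("curves", "class", "response"), ...) {
  type <- match.arg(type)
  X <- gbtm_basis(object$degree, newdata)
  curves <- X %*% object$coefficients
  switch(type,
         curves = curves,
         class = object$labels,
         response = object$posterior %*% t(curves))
}

#' @export
fitted.gbtm <- function(object, ...) predict(object, type = "response")

#' @export
residuals.gbtm <- function(object, ...) object$y - fitted(object)

#' @export
simulate.gbtm <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  curves <- predict(object, type = "curves")
  out <- vector("list", nsim)
  for (s in seq_len(nsim)) {
    g <- sample.int(object$k, object$n, replace = TRUE, prob = object$weights)
    out[[s]] <- t(curves)[g, , drop = FALSE] +
      matrix(stats::rnorm(object$n * 4, 0, object$sigma), object$n, 4)
  }
  if (nsim == 1) out[[1]] else out
}

#' @export
plot.gbtm <- function(x, ...) {
  curves <- predict(x, type = "curves")
  cols <- grDevices::hcl.colors(x$k, "Dark 3")
  graphics::matplot(1:4, t(x$y), type = "l", lty = 3,
                    col = grDevices::adjustcolor(cols[x$labels], 0.4),
                    xlab = "quadrant (inner a -> outer d)",
                    ylab = "porosity (%)", xaxt = "n", ...)
  graphics::axis(1, at = 1:4, labels = letters[1:4])
  graphics::matlines(1:4, curves, lwd = 3, lty = 1, col = cols)
  invisible(x)
}

#' Leave-one-out cross-validation error of a GBTM configuration
#'
#' For each element, refits the model on the remaining elements and scores
#' the held-out trajectory as the mean squared deviation from its
#' posterior-weighted predicted curve under the refitted model. Each point
#' is predicted from membership posteriors computed on the trajectory's
#' other points only, so the score is honestly out-of-sample at both the
#' element and the point level.
#'
#' @param rpps An `rpp_set` or complete matrix.
#' @param k,degree Model configuration.
#' @param n_starts Random starts for the full-data fit whose solution
#'   warm-starts every fold's refit (default 10).
#' @param seed Integer seed.
#' @return CVE (non-negative); attribute `n_refits` records the fold count.
#' @export
gbtm_cve <- function(rpps, k, degree = 2L, n_starts = 10L, seed = 1L) {
  Y <- rpp_matrix(rpps)
  n <- nrow(Y)
  if (n < 2) stop("need at least two trajectories")
  X <- gbtm_basis(degree)
  full <- fit_gbtm(Y, k = k, degree = degree, n_starts = n_starts,
                   seed = seed, warm_iter = 15L)
  errs <- numeric(n)
  for (i in seq_len(n)) {
    init <- full$labels[-i]
    refit <- gbtm_em(Y[-i, , drop = FALSE], X, k, init,
                     max_iter = 200L, tol = 1e-6)
    if (is.null(refit)) {  # degenerate fold: fall back to fresh starts
      f <- fit_gbtm(Y[-i, , drop = FALSE], k = k, degree = degree,
                    n_starts = n_starts, seed = seed + i, warm_iter = 15L)
      refit <- list(B = f$coefficients, sigma = f$sigma, pi = f$weights)
    }
    # score each point of the held-out trajectory from posteriors that see
    # only the other three points, so added components cannot pay for
    # themselves with the very point they are asked to predict
    M <- X %*% refit$B
    pe <- vapply(seq_len(ncol(Y)), function(q) {
      r2 <- colSums((Y[i, -q] - M[-q, , drop = FALSE])^2)
      logw <- log(refit$pi) - r2 / (2 * refit$sigma^2)
      w <- exp(logw - max(logw)); w <- w / sum(w)
      (Y[i, q] - sum(M[q, ] * w))^2
    }, numeric(1))
    errs[i] <- mean(pe)
  }
  structure(mean(errs), n_refits = n)
}

#' GBTM model selection over group numbers and degrees
#'
#' Fits all combinations of group number (1..k_max) and polynomial degree,
#' tabulates AIC, BIC and (optionally) leave-one-out CVE, and repeats the
#' whole scan over several seeded runs to flag the modal best-supported
#' configuration across repetitions.
#'
#' @param rpps An `rpp_set` or complete matrix.
#' @param k_max Maximum number of groups (default 5).
#' @param degrees Polynomial degrees to scan (default 1:3).
#' @param criteria Any of `"AIC"`, `"BIC"`, `"CVE"`.
#' @param n_starts Random starts per fit (default 100).
#' @param cve_starts Random starts per CVE refit (default 10).
#' @param n_reps Seeded repetitions of the scan (default 3).
#' @param seed Integer seed.
#' @return Object of class `gbtm_selection`: `table` (one row per rep x k x
#'   degree with the criteria), `best` (best configuration per criterion
#'   per rep), `modal_k`, `modal_degree` (modal best across criteria and
#'   reps), and `fit` (refitted best modal model).
#' @export
gbtm_select <- function(rpps, k_max = 5L, degrees = 1:3,
                        criteria = c("AIC", "BIC", "CVE"),
                        n_starts = 100L, cve_starts = 10L,
                        n_reps = 3L, seed = 1L) {
  criteria <- match.arg(criteria, c("AIC", "BIC", "CVE"), several.ok = TRUE)
  Y <- rpp_matrix(rpps)
  rows <- list()
  for (rep in seq_len(n_reps)) {
    for (deg in degrees) {
      for (k in seq_len(k_max)) {
        if (nrow(Y) < k) next
        fit <- fit_gbtm(Y, k = k, degree = deg, n_starts = n_starts,
                        seed = seed + 1000L * rep + 10L * deg + k)
        row <- data.frame(rep = rep, k = k, degree = deg,
                          logLik = fit$logLik)
        if ("AIC" %in% criteria) row$AIC <- fit$AIC
        if ("BIC" %in% criteria) row$BIC <- fit$BIC
        if ("CVE" %in% criteria)
          row$CVE <- as.numeric(gbtm_cve(Y, k = k, degree = deg,
                                         n_starts = cve_starts,
                                         seed = seed + 1000L * rep + k))
        rows[[length(rows) + 1L]] <- row
      }
    }
  }
  tab <- do.call(rbind, rows)
  best <- do.call(rbind, lapply(split(tab, tab$rep), function(d) {
    do.call(rbind, lapply(criteria, function(cr) {
      i <- which.min(d[[cr]])
      data.frame(rep = d$rep[i], criterion = cr, k = d$k[i],
                 degree = d$degree[i], value = d[[cr]][i])
    }))
  }))
  rownames(best) <- NULL
  modal_k <- as.integer(names(sort(table(best$k), decreasing = TRUE))[1])
  modal_degree <- as.integer(names(sort(
    table(best$degree[best$k == modal_k]), decreasing = TRUE))[1])
  fit <- fit_gbtm(Y, k = modal_k, degree = modal_degree,
                  n_starts = n_starts, seed = seed)
  structure(list(table = tab, best = best, modal_k = modal_k,
                 modal_degree = modal_degree, criteria = criteria,
                 fit = fit, seed = seed),
            class = "gbtm_selection")
}

#' @export
print.gbtm_selection <- function(x, ...) {
  cat(sprintf("GBTM model selection (criteria: %s)\n",
              paste(x$criteria, collapse = ", ")))
  cat(sprintf("modal best-supported configuration: %d group(s), degree %d\n",
              x$modal_k, x$modal_degree))
  print(x$best)
  invisible(x)
}
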