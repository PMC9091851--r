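# Downstream of group labels: cross-method label alignment and congruence,
# skeletal-dissociation signatures, and multinomial logistic prediction of
# memberships with stepwise AIC/AICc selection.

# O(n^3) Hungarian algorithm (shortest augmenting paths with potentials)
# for the square min-cost assignment problem. Returns, for each row, the
# assigned column.
hungarian_min <- function(cost) {
  n <- nrow(cost)
  stopifnot(ncol(cost) == n)
  J0 <- n + 1L                      # virtual start column
  u <- numeric(n); v <- numeric(n + 1L)
  p <- integer(n + 1L)              # p[j]: row matched to column j (0 none)
  way <- integer(n)
  for (i in seq_len(n)) {
    p[J0] <- i
    j0 <- J0
    minv <- rep(Inf, n)
    used <- rep(FALSE, n + 1L)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]
      delta <- Inf; j1 <- 0L
      for (j in seq_len(n)) {
        if (!used[j]) {
          cur <- cost[i0, j] - u[i0] - v[j]
          if (cur < minv[j]) { minv[j] <- cur; way[j] <- j0 }
          if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
        }
      }
      for (j in seq_len(n)) {
        if (used[j]) {
          u[p[j]] <- u[p[j]] + delta
          v[j] <- v[j] - delta
        } else {
          minv[j] <- minv[j] - delta
        }
      }
      u[p[J0]] <- u[p[J0]] + delta   # virtual column is always "used"
      v[J0] <- v[J0] - delta
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == J0) break
    }
  }
  assignment <- integer(n)
  for (j in seq_len(n)) if (p[j] > 0L) assignment[p[j]] <- j
  assignment
}

#' Align the group labels of two clusterings
#'
#' Finds the one-to-one matching between the groups of two clusterings
#' that maximises the number of identically assigned elements (optimal
#' assignment on the k x k contingency table), and reports the aligned
#' agreement percentage. With unequal group numbers, unmatched groups map
#' to a null label and count as disagreement.
#'
#' @param a,b `grouping_result`s (or named label vectors) over the same
#'   element set; with partially overlapping sets the intersection is used.
#' @return List: `mapping` (for each group of `a`, the matched group of
#'   `b`, NA when matched to a padded null group), `agreement` (percent of
#'   shared elements identically grouped after alignment), `n_shared`.
#' @export
align_labels <- function(a, b) {
  la <- if (inherits(a, "grouping_result")) a$labels else a
  lb <- if (inherits(b, "grouping_result")) b$labels else b
  shared <- intersect(names(la), names(lb))
  if (length(shared) == 0) stop("the two groupings share no elements")
  la <- la[shared]; lb <- lb[shared]
  ka <- max(la); kb <- max(lb)
  K <- max(ka, kb)
  tab <- matrix(0, K, K)
  tt <- table(factor(la, levels = 1:K), factor(lb, levels = 1:K))
  tab[seq_len(nrow(tt)), seq_len(ncol(tt))] <- tt
  assignment <- hungarian_min(-tab)
  matched <- sum(tab[cbind(seq_len(K), assignment)])
  mapping <- assignment[seq_len(ka)]
  mapping[mapping > kb] <- NA_integer_
  list(mapping = mapping,
       agreement = 100 * matched / length(shared),
       n_shared = length(shared))
}

#' Cross-method congruence report
#'
#' Pairwise aligned agreement percentages between all grouping methods,
#' each method's overall congruence (the sum of its pairwise agreements
#' with every other method), and consensus tiers: the percentage of
#' elements grouped identically by all M methods, by exactly M-1, and so
#' on, computed after aligning every method's labels to a designated
#' reference method.
#'
#' @param groupings List of `grouping_result`s (>= 2) on a shared element
#'   set; list names (or the methods' own tags) label the report.
#' @param reference Index or name of the reference method for consensus
#'   alignment (default 1).
#' @return A `congruence_report`: `pairwise` (symmetric percent matrix),
#'   `overall` (named vector), `tiers` (named percent vector, "M of M"
#'   down to "1 of M"), `aligned` (element x method matrix of aligned
#'   labels), `reference`.
#' @export
congruence_report <- function(groupings, reference = 1L) {
  M <- length(groupings)
  if (M < 2) stop("need at least two groupings")
  nm <- names(groupings)
  if (is.null(nm))
    nm <- vapply(groupings, function(g) g$method, character(1))
  nm <- make.unique(nm)
  if (is.character(reference)) reference <- match(reference, nm)
  shared <- Reduce(intersect, lapply(groupings, function(g) names(g$labels)))
  if (length(shared) == 0) stop("groupings share no elements")
  pairwise <- matrix(100, M, M, dimnames = list(nm, nm))
  for (i in seq_len(M - 1)) {
    for (j in (i + 1):M) {
      al <- align_labels(groupings[[i]], groupings[[j]])
      pairwise[i, j] <- pairwise[j, i] <- al$agreement
    }
  }
  overall <- rowSums(pairwise) - 100
  # consensus tiers on labels aligned to the reference method
  ref_labels <- groupings[[reference]]$labels[shared]
  aligned <- matrix(NA_integer_, length(shared), M,
                    dimnames = list(shared, nm))
  null_label <- -1L
  for (i in seq_len(M)) {
    if (i == reference) { aligned[, i] <- groupings[[i]]$labels[shared]; next }
    al <- align_labels(groupings[[i]], groupings[[reference]])
    li <- groupings[[i]]$labels[shared]
    mapped <- al$mapping[li]
    # unmatched groups get unique negative labels: never congruent
    bad <- is.na(mapped)
    if (any(bad)) {
      mapped[bad] <- null_label - li[bad]
      null_label <- min(mapped, na.rm = TRUE) - 1L
    }
    aligned[, i] <- mapped
  }
  agree_count <- apply(aligned, 1, function(r) max(table(r)))
  tiers <- vapply(M:1, function(t) 100 * mean(agree_count == t), numeric(1))
  names(tiers) <- sprintf("%d of %d", M:1, M)
  structure(list(pairwise = pairwise, overall = overall, tiers = tiers,
                 aligned = aligned, reference = nm[reference]),
            class = "congruence_report")
}

#' @export
print.congruence_report <- function(x, ...) {
  cat("pairwise aligned agreement (%):\n")
  print(round(x$pairwise, 1))
  cat("\noverall congruence (sum of pairwise %):\n")
  print(round(x$overall, 1))
  cat(sprintf("\nconsensus tiers (reference: %s):\n", x$reference))
  print(round(x$tiers, 1))
  invisible(x)
}

#' Skeletal-dissociation signatures
#'
#' For each specimen, how its sampled bones scatter across trajectory
#' groups: "0" when all bones fall in one group, otherwise the ascending
#' hyphen-joined counts of bones per group (e.g. "1-3": two groups, one
#' bone in one and three in the other).
#'
#' @param grouping A `grouping_result` (or named label vector).
#' @param specimen_map Named character vector: element id -> specimen id.
#' @return data.frame: specimen_id, n_bones, signature, level (number of
#'   groups the specimen's bones occupy).
#' @export
dissociation <- function(grouping, specimen_map) {
  labels <- if (inherits(grouping, "grouping_result")) grouping$labels
  else grouping
  unmapped <- setdiff(names(labels), names(specimen_map))
  if (length(unmapped) > 0)
    stop("elements not mapped to a specimen: ",
         paste(utils::head(unmapped, 5), collapse = ", "))
  spec <- specimen_map[names(labels)]
  out <- lapply(split(labels, spec), function(l) {
    counts <- sort(as.integer(table(l)))
    data.frame(n_bones = length(l),
               signature = if (length(counts) == 1L) "0"
               else paste(counts, collapse = "-"),
               level = length(counts))
  })
  res <- do.call(rbind, out)
  data.frame(specimen_id = names(out), res, row.names = NULL,
             stringsAsFactors = FALSE)
}

# ---- multinomial membership prediction ------------------------------------

#' Multinomial logistic regression of group memberships
#'
#' Fits a softmax regression of clustering labels on specimen covariates
#' (age, bone type, developmental strategy, specimen), via
#' [nnet::multinom()]. Complete separation (possible in small designs
#' where, e.g., strategy perfectly splits a cohort) is caught by a
#' coefficient-magnitude check and refitted with a tiny ridge penalty, with
#' a flag raised.
#'
#' @param labels A `grouping_result` or named label vector (the response).
#' @param data data.frame of predictors; rows matched to elements by an
#'   `element_id` column or row names.
#' @param predictors Character vector of predictor column names.
#' @param maxit Maximum optimiser iterations (default 500).
#' @param ridge Ridge (weight decay) used on separation (default 1e-6).
#' @return A `multinom_fit`: the underlying fit, `AIC`, `AICc` (NA when
#'   n <= p + 1), `PM` (percent of elements whose modal predicted
#'   membership matches the actual one), `formula`, `separation`.
#' @export
multinom_fit <- function(labels, data, predictors, maxit = 500L,
                         ridge = 1e-6) {
  lv <- if (inherits(labels, "grouping_result")) labels$labels else labels
  ids <- if ("element_id" %in% names(data)) data$element_id else rownames(data)
  shared <- intersect(names(lv), ids)
  if (length(shared) < 2) stop("labels and data share too few elements")
  df <- data[match(shared, ids), , drop = FALSE]
  df$.group <- factor(lv[shared])
  if (nlevels(df$.group) < 2) stop("response has a single class")
  missing_pred <- setdiff(predictors, names(df))
  if (length(missing_pred) > 0)
    stop("predictors not in data: ", paste(missing_pred, collapse = ", "))
  fml <- stats::as.formula(paste(".group ~",
                                 if (length(predictors) == 0) "1"
                                 else paste(predictors, collapse = " + ")))
  fit <- nnet::multinom(fml, data = df, trace = FALSE, maxit = maxit)
  separation <- max(abs(stats::coef(fit))) > 15
  if (separation)
    fit <- nnet::multinom(fml, data = df, trace = FALSE, maxit = maxit,
                          decay = ridge)
  n <- nrow(df)
  p <- fit$edf
  aic <- stats::AIC(fit)
  aicc <- if (n - p - 1 > 0) aic + 2 * p * (p + 1) / (n - p - 1) else NA_real_
  pred <- stats::predict(fit, newdata = df, type = "class")
  structure(list(fit = fit, formula = fml, predictors = predictors,
                 data = df, n = n, p = p,
                 AIC = aic, AICc = aicc,
                 PM = 100 * mean(pred == df$.group),
                 separation = separation,
                 fitted_class = stats::setNames(as.integer(as.character(pred)),
                                                shared)),
            class = "multinom_fit")
}

#' @export
print.multinom_fit <- function(x, ...) {
  cat(sprintf("multinomial membership model: %s\n", deparse(x$formula)))
  cat(sprintf("n = %d, edf = %.0f, AIC = %.3f, AICc = %s, PM%% = %.1f%s\n",
              x$n, x$p, x$AIC,
              if (is.na(x$AICc)) "NA" else sprintf("%.3f", x$AICc),
              x$PM, if (x$separation) " (separation: ridge fit)" else ""))
  invisible(x)
}

#' Backward stepwise selection of membership predictors
#'
#' Starting from the full predictor set, repeatedly drops the whole
#' predictor (all levels of a categorical at once) whose removal lowers
#' the AIC the most, stopping when no drop lowers it. Reports the
#' selection path, every model visited with AIC, AICc and PM%, and the
#' AIC-best and AICc-best models.
#'
#' @param labels A `grouping_result` or named label vector.
#' @param data Predictor data.frame (see [multinom_fit()]).
#' @param predictors Character vector: the full predictor set.
#' @param ... Passed to [multinom_fit()].
#' @return A `stepwise_multinom`: `table` (model, AIC, AICc, PM%),
#'   `path` (predictor dropped at each step), `best_aic`, `best_aicc`
#'   (both `multinom_fit`s).
#' @export
stepwise_select <- function(labels, data, predictors, ...) {
  visited <- list()
  key <- function(pr) if (length(pr) == 0) "1" else paste(sort(pr), collapse = "+")
  get_fit <- function(pr) {
    k <- key(pr)
    if (is.null(visited[[k]]))
      visited[[k]] <<- multinom_fit(labels, data, pr, ...)
    visited[[k]]
  }
  current <- predictors
  path <- character(0)
  repeat {
    cur_fit <- get_fit(current)
    if (length(current) == 0) break
    drops <- vapply(current, function(pr)
      get_fit(setdiff(current, pr))$AIC, numeric(1))
    if (min(drops) < cur_fit$AIC - 1e-9) {
      dropped <- current[which.min(drops)]
      path <- c(path, dropped)
      current <- setdiff(current, dropped)
    } else break
  }
  tab <- do.call(rbind, lapply(visited, function(f)
    data.frame(model = paste(deparse(f$formula), collapse = ""),
               AIC = f$AIC, AICc = f$AICc, PM = f$PM,
               stringsAsFactors = FALSE)))
  rownames(tab) <- NULL
  aics <- vapply(visited, `[[`, numeric(1), "AIC")
  aiccs <- vapply(visited, `[[`, numeric(1), "AICc")
  structure(list(table = tab, path = path,
                 selected = current,
                 best_aic = visited[[which.min(aics)]],
                 best_aicc = if (all(is.na(aiccs))) NULL
                 else visited[[which.min(aiccs)]]),
            class = "stepwise_multinom")
}

#' @export
print.stepwise_multinom <- function(x, ...) {
  cat("backward stepwise selection (AIC)\n")
  if (length(x$path) > 0)
    cat("dropped, in order:", paste(x$path, collapse = ", "), "\n")
  cat("selected predictors:",
      if (length(x$selected) == 0) "(intercept only)"
      else paste(x$selected, collapse = " + "), "\n\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}
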