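test_that("one-group GBTM reduces to the pooled least-squares polynomial", {
  set.seed(3)
  m <- matrix(runif(80, 0, 50), 20, 4)
  fit <- fit_gbtm(m, k = 1, degree = 2, n_starts = 3, seed = 1)
  X <- rppbone:::gbtm_basis(2)
  ols <- solve(crossprod(X), crossprod(X, colMeans(m)))
  expect_equal(unname(fit$coefficients[, 1]), drop(ols), tolerance = 1e-8)
  expect_equal(unname(fit$weights), 1)
  expect_equal(unname(fit$posterior[, 1]), rep(1, 20))
})

test_that("noiseless groups are recovered exactly with hard posteriors", {
  de <- dataset_design(n_groups = 2,
                       group_mean_trajectories = list(c(40, -3, 0.5),
                                                      c(10, 2, 0)),
                       noise_sd = 0, n_elements_per_group = 10, seed = 2)
  sim <- generate_rpp_dataset(de)
  fit <- fit_gbtm(rpp_wide(sim$table), k = 2, degree = 2, n_starts = 10,
                  seed = 4)
  expect_true(all(fit$posterior %in% c(0, 1) |
                    abs(fit$posterior) < 1e-12 |
                    abs(fit$posterior - 1) < 1e-12))
  co <- fit$coefficients
  truth <- cbind(c(40, -3, 0.5), c(10, 2, 0))
  # align components to the truth by intercept before comparing
  ord <- order(-co[1, ])
  expect_equal(unname(co[, ord]), unname(truth), tolerance = 1e-6)
})

test_that("separated quadratic groups are recovered within noise", {
  de <- dataset_design(n_groups = 2,
                       group_mean_trajectories = list(c(40, -3, 0.5),
                                                      c(15, 2, -0.3)),
                       noise_sd = 2, n_elements_per_group = 30, seed = 12)
  sim <- generate_rpp_dataset(de)
  fit <- fit_gbtm(rpp_wide(sim$table), k = 2, degree = 2, n_starts = 30,
                  seed = 6)
  truth <- setNames(sim$truth$group, sim$truth$element_id)
  expect_gte(adjusted_rand_index(fit$labels, truth), 0.9)
  # residual sd of mean RPPs is noise_sd / sqrt(3 sectors)
  expect_equal(fit$sigma, 2 / sqrt(3), tolerance = 0.2)
  # AIC/BIC closed forms from the returned log-likelihood
  p <- 2 * 3 + 1 + 1
  expect_equal(fit$AIC, -2 * fit$logLik + 2 * p)
  expect_equal(fit$BIC, -2 * fit$logLik + p * log(fit$n))
})

test_that("EM log-likelihood is monotone within a run", {
  set.seed(7)
  m <- rpp_matrix(rpp_wide(generate_rpp_dataset(dataset_design(
    n_groups = 3, n_elements_per_group = 15, seed = 5))$table))
  run <- rppbone:::gbtm_em(m, rppbone:::gbtm_basis(2), 3,
                           init_labels = sample(1:3, nrow(m), TRUE),
                           max_iter = 200, tol = 1e-10)
  expect_true(all(diff(run$trace) > -1e-6))
})

test_that("model objects expose the standard S3 surface", {
  de <- dataset_design(n_groups = 2, n_elements_per_group = 10, seed = 3)
  fit <- fit_gbtm(rpp_wide(generate_rpp_dataset(de)$table), 2, 2,
                  n_starts = 10, seed = 1)
  expect_output(print(fit), "GBTM: 2 groups")
  expect_equal(dim(coef(fit)), c(3, 2))
  ll <- logLik(fit)
  expect_equal(attr(ll, "df"), fit$n_par)
  expect_equal(dim(predict(fit, type = "curves")), c(4, 2))
  expect_equal(dim(fitted(fit)), c(20, 4))
  expect_equal(unname(residuals(fit)), unname(fit$y - fitted(fit)))
  sim <- simulate(fit, seed = 2)
  expect_equal(dim(sim), c(20, 4))
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
})

test_that("CVE is near zero in the noiseless limit and counts its folds", {
  de <- dataset_design(n_groups = 2,
                       group_mean_trajectories = list(c(40, -3, 0.5),
                                                      c(10, 2, 0)),
                       noise_sd = 0, n_elements_per_group = 5, seed = 2)
  w <- rpp_wide(generate_rpp_dataset(de)$table)
  cve <- gbtm_cve(w, k = 2, degree = 2, seed = 1)
  expect_lt(as.numeric(cve), 1e-6)
  expect_equal(attr(cve, "n_refits"), 10)
})

test_that("CVE penalises overfit group numbers on homogeneous data", {
  set.seed(42)
  diffs <- replicate(10, {
    de <- dataset_design(n_groups = 1,
                         group_mean_trajectories = list(c(30, -4, 1.5)),
                         noise_sd = 2, n_elements_per_group = 25,
                         seed = sample.int(1e6, 1))
    w <- rpp_wide(generate_rpp_dataset(de)$table)
    as.numeric(gbtm_cve(w, 5, 2, seed = 1)) -
      as.numeric(gbtm_cve(w, 1, 2, seed = 1))
  })
  expect_gt(mean(diffs), 0)
})

test_that("selection restricted to one criterion reports only that column", {
  de <- dataset_design(n_groups = 2, n_elements_per_group = 8, seed = 9)
  w <- rpp_wide(generate_rpp_dataset(de)$table)
  sel <- gbtm_select(w, k_max = 2, degrees = 2, criteria = "AIC",
                     n_starts = 5, n_reps = 1, seed = 1)
  expect_true("AIC" %in% names(sel$table))
  expect_false(any(c("BIC", "CVE") %in% names(sel$table)))
})

test_that("BIC selects a single group on strong-noise homogeneous data", {
  de <- dataset_design(n_groups = 1,
                       group_mean_trajectories = list(c(30, -4, 1.5)),
                       noise_sd = 6, n_elements_per_group = 60, seed = 14)
  w <- rpp_wide(generate_rpp_dataset(de)$table)
  sel <- gbtm_select(w, k_max = 3, degrees = 2, criteria = "BIC",
                     n_starts = 10, n_reps = 1, seed = 2)
  expect_equal(sel$best$k[sel$best$criterion == "BIC"], 1)
})

test_that("group relabelling leaves congruence statistics unchanged", {
  de <- dataset_design(n_groups = 3, n_elements_per_group = 10, seed = 4)
  sim <- generate_rpp_dataset(de)
  w <- rpp_wide(sim$table)
  km <- kmeans_cluster(w, 3, n_restarts = 20, seed = 1)
  perm <- c(3L, 1L, 2L)
  km_perm <- grouping_result("kmeans", 3,
                             setNames(perm[km$labels], names(km$labels)))
  g2 <- cut_tree(hclust_complete(distance_matrix(w, "dtw")), 3)
  expect_equal(align_labels(km, g2)$agreement,
               align_labels(km_perm, g2)$agreement)
  expect_equal(adjusted_rand_index(km, g2), adjusted_rand_index(km_perm, g2))
})
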