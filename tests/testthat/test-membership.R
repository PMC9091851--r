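test_that("label alignment matches forced cases and the permutation oracle", {
  l1 <- setNames(c(1, 1, 2, 2, 3, 3, 4, 4, 1, 2), paste0("E", 1:10))
  perm <- c(4L, 3L, 1L, 2L)
  l2 <- setNames(perm[l1], names(l1))
  al <- align_labels(l1, l2)
  expect_equal(al$agreement, 100)
  expect_equal(al$mapping, perm)
  # one element moved: 90%
  l3 <- l2
  l3["E1"] <- 3L
  expect_equal(align_labels(l1, l3)$agreement, 90)
  # random labelings against exhaustive permutations
  set.seed(21)
  for (i in 1:30) {
    a <- setNames(sample(1:4, 60, TRUE), paste0("E", 1:60))
    b <- setNames(sample(1:4, 60, TRUE), paste0("E", 1:60))
    expect_equal(align_labels(a, b)$agreement, align_brute(a, b),
                 tolerance = 1e-12)
  }
  # unequal group counts: unmatched groups count as disagreement
  a <- setNames(c(1, 1, 2, 2, 3, 3), paste0("E", 1:6))
  b <- setNames(c(1, 1, 2, 2, 2, 2), paste0("E", 1:6))
  al2 <- align_labels(a, b)
  expect_equal(al2$agreement, 100 * 4 / 6, tolerance = 1e-12)
  expect_true(any(is.na(al2$mapping)))
  expect_error(align_labels(setNames(1, "X"), setNames(1, "Y")), "share")
})

test_that("congruence reports recover constructed consensus tiers", {
  ids <- paste0("E", 1:20)
  base <- setNames(rep(1:4, each = 5), ids)
  g <- function(l, m) grouping_result(m, 4, l)
  # four identical groupings up to label permutation
  gr <- list(kmeans = g(base, "kmeans"),
             gbtm = g(setNames(c(2:4, 1)[base], ids), "gbtm"),
             dtw = g(setNames(c(4, 3, 2, 1)[base], ids), "dtw_hclust"),
             ed = g(base, "ed_hclust"))
  rep0 <- congruence_report(gr)
  expect_true(all(rep0$pairwise == 100))
  expect_equal(unname(rep0$tiers["4 of 4"]), 100)
  expect_equal(unname(rep0$overall), rep(300, 4), ignore_attr = TRUE)
  # two groupings: overall equals the single pairwise value
  r2 <- congruence_report(gr[1:2])
  expect_equal(unname(r2$overall[1]), unname(r2$pairwise[1, 2]))
  # constructed tiers: 12 elements agree in all 4, 5 in exactly 3, 3 in 2
  c_lab <- base; c_lab[13:17] <- c(2, 4, 4, 1, 2); c_lab[18:20] <- c(1, 1, 2)
  d_lab <- base; d_lab[18:20] <- c(2, 2, 3)
  gr2 <- list(a = g(base, "kmeans"), b = g(base, "gbtm"),
              c = g(c_lab, "dtw_hclust"),
              d = g(d_lab, "ed_hclust"))
  tiers <- congruence_report(gr2)$tiers
  expect_equal(unname(tiers["4 of 4"]), 100 * 12 / 20)
  expect_equal(unname(tiers["3 of 4"]), 100 * 5 / 20)
  expect_equal(unname(tiers["2 of 4"]), 100 * 3 / 20)
})

test_that("dissociation signatures follow the counting rule", {
  labels <- setNames(c(1, 1, 1, 1,            # specimen A: one group
                       2, 1, 1, 1,            # specimen B: 1-3
                       1, 2, 2, 3, 3, 3),     # specimen C: 1-2-3
                     paste0("E", 1:14))
  map <- setNames(rep(c("A", "B", "C"), c(4, 4, 6)), names(labels))
  d <- dissociation(labels, map)
  d <- d[match(c("A", "B", "C"), d$specimen_id), ]
  expect_equal(d$signature, c("0", "1-3", "1-2-3"))
  expect_equal(d$level, c(1, 2, 3))
  expect_equal(d$n_bones, c(4, 4, 6))
  # counts always sum to the bone count; invariant under relabelling
  set.seed(6)
  for (i in 1:10) {
    l <- setNames(sample(1:4, 12, TRUE), paste0("E", 1:12))
    m <- setNames(rep(c("S1", "S2"), each = 6), names(l))
    dd <- dissociation(l, m)
    sums <- vapply(strsplit(dd$signature, "-"), function(s)
      if (identical(s, "0")) NA_real_ else sum(as.numeric(s)), numeric(1))
    expect_true(all(is.na(sums) | sums == dd$n_bones))
    perm <- sample(4)
    dd2 <- dissociation(setNames(perm[l], names(l)), m)
    expect_equal(dd2$signature, dd$signature)
  }
  expect_error(dissociation(labels, map[-1]), "not mapped")
})

test_that("intercept-only multinomial predicts the modal class", {
  ids <- paste0("E", 1:30)
  labels <- setNames(rep(c(1, 2, 3), c(15, 9, 6)), ids)
  dat <- data.frame(element_id = ids, age_dph = runif(30))
  fit <- multinom_fit(labels, dat, character(0))
  expect_equal(fit$PM, 100 * 15 / 30)
  # single-class response is refused
  expect_error(multinom_fit(setNames(rep(1, 30), ids), dat, "age_dph"),
               "single class")
})

test_that("AIC and AICc closed forms hold on a known two-class fit", {
  set.seed(10)
  ids <- paste0("E", 1:40)
  dat <- data.frame(element_id = ids, x = rnorm(40))
  labels <- setNames(1L + (runif(40) < plogis(dat$x)), ids)
  fit <- multinom_fit(labels, dat, "x")
  ll <- as.numeric(stats::logLik(fit$fit))
  p <- fit$p
  expect_equal(fit$AIC, 2 * p - 2 * ll, tolerance = 1e-9)
  expect_equal(fit$AICc, fit$AIC + 2 * p * (p + 1) / (40 - p - 1),
               tolerance = 1e-9)
  expect_gte(fit$AICc, fit$AIC)
})

test_that("separable predictors give PM 100 with a flagged ridge fit", {
  ids <- paste0("E", 1:24)
  strat <- rep(c("altricial", "precocial"), each = 12)
  labels <- setNames(ifelse(strat == "altricial", 1L, 2L), ids)
  dat <- data.frame(element_id = ids, dev_strategy = strat)
  fit <- multinom_fit(labels, dat, "dev_strategy")
  expect_true(fit$separation)
  expect_equal(fit$PM, 100)
})

test_that("softmax coefficients are recovered within 2 SE", {
  set.seed(31)
  n <- 200
  age <- runif(n, 0, 1)
  strat <- rbinom(n, 1, 0.5)
  b_true <- c(int = -1, age = 4, strat = 1.5)  # class 2 vs 1
  eta <- b_true[1] + b_true[2] * age + b_true[3] * strat
  y <- 1L + rbinom(n, 1, plogis(eta))
  ids <- paste0("E", 1:n)
  dat <- data.frame(element_id = ids, age = age, strat = strat)
  fit <- multinom_fit(setNames(y, ids), dat, c("age", "strat"))
  co <- drop(stats::coef(fit$fit))
  se <- drop(summary(fit$fit)$standard.errors)
  expect_true(all(abs(co - b_true) <= 2 * se))
})

test_that("backward selection drops pure-noise predictors first", {
  set.seed(17)
  n <- 150
  hits <- replicate(20, {
    age <- runif(n, 0, 1)
    strat <- factor(sample(c("altricial", "precocial"), n, TRUE))
    eta2 <- -1 + 5 * age + 2.5 * (strat == "precocial")
    eta3 <- -2 + 4 * age - 2 * (strat == "precocial")
    pr <- cbind(1, exp(eta2), exp(eta3))
    y <- apply(pr, 1, function(p) sample(1:3, 1, prob = p))
    ids <- paste0("E", 1:n)
    # categorical noise (e.g. a batch label): enough df that AIC rarely
    # retains it by chance
    dat <- data.frame(element_id = ids, age = age, strat = strat,
                      noise = factor(sample(letters[1:4], n, TRUE)))
    sel <- stepwise_select(setNames(y, ids), dat,
                           c("age", "strat", "noise"))
    length(sel$path) > 0 && sel$path[1] == "noise"
  })
  expect_gte(mean(hits), 0.9)
  # a single informative predictor survives: path length 0
  age <- runif(n, 0, 1)
  y <- 1L + rbinom(n, 1, plogis(-2 + 6 * age))
  ids <- paste0("E", 1:n)
  sel2 <- stepwise_select(setNames(y, ids),
                          data.frame(element_id = ids, age = age), "age")
  expect_length(sel2$path, 0)
  expect_equal(sel2$selected, "age")
  expect_true(all(c("model", "AIC", "AICc", "PM") %in% names(sel2$table)))
})

test_that("AIC-best model never predicts worse than the intercept-only model", {
  set.seed(23)
  for (i in 1:3) {
    n <- 80
    age <- runif(n)
    y <- 1L + rbinom(n, 1, plogis(-1 + 3 * age))
    ids <- paste0("E", 1:n)
    dat <- data.frame(element_id = ids, age = age)
    sel <- stepwise_select(setNames(y, ids), dat, "age")
    null_fit <- multinom_fit(setNames(y, ids), dat, character(0))
    expect_gte(sel$best_aic$PM, null_fit$PM)
  }
})
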