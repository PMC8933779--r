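test_that("composite T scores average observed constituents", {
  map <- defaultDomainMap()
  sc <- assignments(map)$score_id
  m <- matrix(50, length(sc), 2, dimnames = list(sc, c("p1", "p2")))
  # p1: the six memory scores take fixed values with mean 45
  mem <- assignments(map)$score_id[assignments(map)$domain == "L+LTM"]
  m[mem, "p1"] <- c(38, 42, 45, 55, 50, 40)
  # p2: symmetric pair in ST/WM
  m[c("forward_span", "backward_span"), "p2"] <- c(40, 60)
  comp <- compositeScores(ScoredCohort(m), map)
  expect_equal(comp["p1", "L+LTM"], 45)
  expect_equal(comp["p2", "ST/WM"], 50)
  expect_equal(comp["p2", "EF"], 50)
  # order invariance: permuting constituents changes nothing
  m2 <- m[sample(nrow(m)), , drop = FALSE]
  expect_equal(compositeScores(ScoredCohort(m2), map), comp)
  # missing constituents are dropped; full-missing domain is NA
  m[mem, "p2"] <- NA_real_
  comp2 <- compositeScores(ScoredCohort(m), map)
  expect_true(is.na(comp2["p2", "L+LTM"]))
  # coverage threshold turns sparse domains into NA
  m3 <- m
  m3[mem[-1], "p1"] <- NA_real_
  comp3 <- compositeScores(ScoredCohort(m3), map, min_coverage = 0.5)
  expect_true(is.na(comp3["p1", "L+LTM"]))
})

test_that("composite correlation equals a from-scratch Pearson oracle", {
  x <- c(48.2, 55.1, 39.9, 61.3, 50.0, 44.4, 58.8, 47.1)
  y <- c(51.0, 57.3, 41.2, 58.9, 48.5, 47.0, 60.2, 45.3)
  comp <- cbind(EF = x, Attention = y)
  got <- correlateComposites(comp, "EF", "Attention")
  # oracle: covariance / variance ratio and the t-distribution p-value
  n <- length(x)
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  t_hand <- r_hand * sqrt((n - 2) / (1 - r_hand^2))
  p_hand <- 2 * pt(-abs(t_hand), df = n - 2)
  expect_equal(unname(got["r"]), r_hand, tolerance = 1e-12)
  expect_equal(unname(got["p"]), p_hand, tolerance = 1e-12)
  expect_equal(unname(got["n"]), n)
  # exact linear dependence
  expect_equal(unname(correlateComposites(cbind(A = x, B = x), "A", "B")["r"]),
               1)
  # guards
  expect_error(correlateComposites(cbind(A = x, B = rep(1, n)), "A", "B"),
               "variance")
  expect_error(correlateComposites(cbind(A = x[1:2], B = y[1:2]), "A", "B"),
               "pairs")
})

test_that("null composites stay uncorrelated at scale", {
  set.seed(21)
  n <- 1000
  comp <- cbind(EF = rnorm(n), Attention = rnorm(n))
  got <- correlateComposites(comp, "EF", "Attention")
  expect_lt(abs(unname(got["r"])), 0.1)
  # sampling oracle: with true rho = 0.31 at the study's n, the estimator
  # is essentially unbiased
  set.seed(22)
  rho <- 0.31
  rbar <- mean(replicate(2000, {
    z <- matrix(rnorm(63 * 2), 63)
    z[, 2] <- rho * z[, 1] + sqrt(1 - rho^2) * z[, 2]
    cor(z[, 1], z[, 2])
  }))
  expect_equal(rbar, rho, tolerance = 0.02)
})

test_that("ANCOVA group effect matches a nested-model F oracle", {
  set.seed(13)
  n <- 40
  age <- rnorm(n, 50, 10)
  grp <- rep(c(TRUE, FALSE), each = n / 2)
  y <- 20 - 0.1 * age - 2 * grp + rnorm(n, 0, 2)
  got <- compareGroupsAncova(y, grp, age)
  # oracle: sequential F from residual sums of squares of nested fits
  rss1 <- sum(resid(lm(y ~ age))^2)
  rss2 <- sum(resid(lm(y ~ age + factor(grp)))^2)
  F_hand <- (rss1 - rss2) / (rss2 / (n - 3))
  expect_equal(unname(got["F"]), F_hand, tolerance = 1e-10)
  expect_equal(unname(got["df1"]), 1)
  expect_equal(unname(got["df2"]), n - 3)
  expect_equal(unname(got["p"]),
               pf(F_hand, 1, n - 3, lower.tail = FALSE), tolerance = 1e-10)
  # identical groups -> F ~ 0
  y2 <- c(y[grp], y[grp])
  got2 <- compareGroupsAncova(y2, rep(c(TRUE, FALSE), each = sum(grp)),
                              c(age[grp], age[grp]))
  expect_lt(unname(got2["F"]), 1e-20)
  expect_error(compareGroupsAncova(y, rep(TRUE, n), age), "two")
})

test_that("ANCOVA detects a planted 1-SD group effect with adequate power", {
  set.seed(14)
  rej <- mean(replicate(500, {
    grp <- rbinom(63, 1, 0.5)
    age <- rnorm(63, 50, 10)
    y <- rnorm(63) + 1 * grp
    compareGroupsAncova(y, grp, age)["p"] < 0.05
  }))
  expect_gte(rej, 0.8)
})

test_that("binned chi-square matches hand computation and finds effects", {
  counts <- referenceBandCounts()
  # construct groups so the 2x2 table for one score is (10,20 / 20,10)
  m <- matrix(rep(c(30, 55), c(30, 30)), 1, 60,
              dimnames = list("coding", sprintf("P%03d", 1:60)))
  cohort <- ScoredCohort(m)
  grp <- rep(c("hosp", "home", "hosp", "home"), c(10, 20, 20, 10))
  got <- binnedGroupTest(cohort, "coding", grp, bins = "combined")
  expect_equal(unname(got["statistic"]), 20 / 3, tolerance = 1e-12)
  expect_equal(unname(got["df"]), 1)
  # identical distributions -> statistic 0
  grp0 <- rep(c("a", "b"), 30)
  got0 <- binnedGroupTest(cohort, "coding", grp0)
  expect_equal(unname(got0["statistic"]), 0, tolerance = 1e-12)
  # degenerate table errors
  m1 <- matrix(55, 1, 20, dimnames = list("coding", sprintf("Q%02d", 1:20)))
  expect_error(binnedGroupTest(ScoredCohort(m1), "coding",
                               rep(c("a", "b"), 10)), "degenerate")
  expect_error(binnedGroupTest(cohort, "nope", grp), "nope")
  # power oracle: impaired fractions 0.4 vs 0.1 at n = 30 + 30; the exact
  # power of the uncorrected chi-square, enumerated over the binomial
  # outcome pair, is 0.796 -- the Monte-Carlo rate must agree with it
  exact <- 0
  for (k1 in 0:30) for (k2 in 0:30) {
    O <- matrix(c(k1, 30 - k1, k2, 30 - k2), 2)
    if (any(rowSums(O) == 0) || any(colSums(O) == 0)) next
    pch <- suppressWarnings(chisq.test(O, correct = FALSE)$p.value)
    if (!is.na(pch) && pch < 0.05)
      exact <- exact + dbinom(k1, 30, 0.4) * dbinom(k2, 30, 0.1)
  }
  expect_equal(exact, 0.796, tolerance = 1e-3)
  set.seed(15)
  rej <- mean(replicate(400, {
    bands <- c(ifelse(runif(30) < 0.4, 30, 55),
               ifelse(runif(30) < 0.1, 30, 55))
    mm <- matrix(bands, 1, 60,
                 dimnames = list("s", sprintf("R%03d", 1:60)))
    g <- rep(c("x", "y"), each = 30)
    out <- tryCatch(
      suppressWarnings(
        binnedGroupTest(ScoredCohort(mm), "s", g, bins = "impaired")),
      error = function(e) c(p = 1))
    out["p"] < 0.05
  }))
  expect_equal(rej, exact, tolerance = 0.05)
})

test_that("per-domain covariate correlations flag degenerate covariates", {
  set.seed(16)
  comp <- cbind(EF = rnorm(50, 50, 7), Attention = rnorm(50, 50, 7))
  # covariate tracking one composite
  res <- correlateCovariate(comp, comp[, "EF"] + rnorm(50, 0, 0.5))
  expect_gt(res$r[res$domain == "EF"], 0.95)
  expect_true(all(res$p >= 0 & res$p <= 1))
  # constant covariate: per-domain NA with warning, not an abort
  expect_warning(
    correlateCovariate(comp[, "EF", drop = FALSE], rep(3, 50)), "variance")
  res0 <- suppressWarnings(correlateCovariate(comp, rep(3, 50)))
  expect_true(all(is.na(res0$r)))
  # Holm column is monotone relative to raw p
  res2 <- suppressWarnings(correlateCovariate(comp, rnorm(50), holm = TRUE))
  expect_true(all(res2$p_holm >= res2$p - 1e-15))
  # named covariate lookup from a data frame
  cohort <- simulateCohort(simConfig(n_patients = 63), seed = 19)
  cc <- compositeScores(cohort)
  res3 <- correlateCovariate(cc, "CK", data = covariates(cohort))
  expect_equal(nrow(res3), 7)
  # p decreases as |r| grows at fixed n (spot check on the formula)
  r <- c(0.1, 0.3, 0.5); n <- 63
  p <- 2 * pt(-abs(r * sqrt((n - 2) / (1 - r^2))), n - 2)
  expect_true(all(diff(p) < 0))
})
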