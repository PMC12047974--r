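test_that("residualization leaves orthogonal features untouched", {
  set.seed(30)
  n <- 60
  covs <- cbind(age = rnorm(n), sex = rbinom(n, 1, 0.5), fd = runif(n))
  raw <- rnorm(n)
  fit <- lm(raw ~ covs)
  orth <- residuals(fit) + 3  # orthogonal to covariates by construction
  out <- residualize(orth, covs)
  expect_equal(out, orth, tolerance = 1e-10, ignore_attr = TRUE)

  perfect <- 2 * covs[, "age"]
  out2 <- residualize(perfect, covs)
  expect_equal(out2, rep(mean(perfect), n), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("residualization equals the closed-form hat-matrix projection", {
  set.seed(31)
  n <- 40
  covs <- cbind(rnorm(n), runif(n))
  y <- matrix(rnorm(n * 5), n)
  x <- cbind(1, covs)
  hat <- x %*% solve(crossprod(x)) %*% t(x)
  expected <- (diag(n) - hat) %*% y +
    matrix(colMeans(y), n, 5, byrow = TRUE)
  expect_equal(residualize(y, covs), expected, tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_error(residualize(y, cbind(covs, covs[, 1] * 2)), "collinear")
  covs_na <- covs; covs_na[2, 1] <- NA
  expect_error(residualize(y, covs_na), "missing")
})

test_that("the parcel-wise linear model controls the null and finds planted shifts", {
  set.seed(32)
  n <- 80; p <- 200
  grp <- rep(0:1, each = n / 2)
  covs <- cbind(age = rnorm(n))
  null_scores <- matrix(rnorm(n * p), n)
  res0 <- regional_glm(null_scores, grp, covs)
  expect_lte(mean(res0$q < .05), 0.05)

  sch <- make_parcel_scheme(p, 7, seed = 1)
  smn <- which(sch$network == "SMN")
  scores <- null_scores
  scores[grp == 1, smn] <- scores[grp == 1, smn] + 1.2
  res1 <- regional_glm(scores, grp, covs)
  hits <- which(res1$q < .05)
  expect_gt(length(hits), 0)
  expect_gte(mean(hits %in% smn), 0.8)
})

test_that("a covariate orthogonal to a balanced contrast leaves t unchanged", {
  set.seed(33)
  n <- 40
  grp <- rep(0:1, each = n / 2)
  cov_raw <- rnorm(n)
  cov_orth <- residuals(lm(cov_raw ~ grp))
  y <- matrix(rnorm(n * 10), n)
  with_cov <- regional_glm(y, grp, cbind(cov_orth))
  without <- regional_glm(y, grp, NULL)
  # same estimates; t differs only through the residual df
  t_rescaled <- with_cov$t * sqrt((n - 2) / (n - 3)) *
    sqrt(colSums(residuals(lm(y ~ grp + cov_orth))^2) /
           colSums(residuals(lm(y ~ grp))^2))
  expect_equal(t_rescaled, without$t, tolerance = 1e-8, ignore_attr = TRUE)
  expect_error(regional_glm(y, rep(1, n), NULL), "two levels")
})

test_that("Mann-Whitney exact branch reproduces the enumeration case", {
  mw <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(mw$U, 0)
  expect_equal(mw$p, 0.1)  # 2 of the 20 assignments are as extreme
  expect_match(mw$method, "exact")

  same <- mann_whitney(c(1, 2, 9), c(1, 2, 9))
  expect_equal(same$U, 9 / 2)

  degen <- mann_whitney(rep(3, 4), rep(3, 5))
  expect_true(degen$degenerate)
  expect_equal(degen$p, 1)
  expect_equal(degen$eta_sq, 0)
  expect_error(mann_whitney(numeric(0), 1), "nonempty")
})

test_that("exact enumeration agrees with wilcox.test and the normal branch", {
  set.seed(34)
  for (i in 1:5) {
    a <- rnorm(6); b <- rnorm(6)  # continuous, no ties
    mw <- mann_whitney(a, b)
    wt <- wilcox.test(a, b, exact = TRUE)
    expect_equal(mw$U, unname(wt$statistic))
    expect_equal(mw$p, wt$p.value, tolerance = 1e-12)
    approx <- mann_whitney(a, b, exact_max = 0)
    expect_lt(abs(mw$p - approx$p), 0.02)
  }
})

test_that("BH adjustment reproduces the hand-stepped example", {
  expect_equal(fdr_bh(c(0.001, 0.008, 0.039, 0.041)),
               c(0.004, 0.016, 0.041, 0.041))
  expect_equal(fdr_bh(0.03), 0.03)
  expect_equal(fdr_bh(rep(1, 5)), rep(1, 5))
  set.seed(35)
  p <- runif(50)
  q <- fdr_bh(p)
  expect_true(all(q >= p))
  ord <- sample(50)
  expect_equal(fdr_bh(p[ord]), q[ord])
  expect_error(fdr_bh(c(0.5, 1.2)), "\\[0, 1\\]")
  pna <- c(0.01, NA, 0.5)
  qna <- fdr_bh(pna)
  expect_true(is.na(qna[2]))
  expect_equal(qna[c(1, 3)], fdr_bh(c(0.01, 0.5)))
})

test_that("clinical screening drops and imputes by the stated rules", {
  cohort <- data.frame(
    group = c("HC", "HC", "HC", "ROP", "ROP", "ROP"),
    s1 = c(1, 2, 3, NA, 5, 6), s2 = c(1, NA, 3, 4, 5, 6),
    s3 = c(1, 2, NA, 4, 5, 6), s4 = c(1, 2, 3, NA, 5, 6),
    s5 = c(1, 2, 3, 4, 5, 6), s6 = c(1, 2, 3, NA, 5, 6),
    s7 = c(1, 2, 3, NA, 5, 6), s8 = c(1, 2, 3, 4, 5, 6),
    s9 = c(1, 2, 3, 4, 5, 6), s10 = c(1, 2, 3, 4, 5, 6))
  clin <- paste0("s", 1:10)
  out <- screen_and_impute_clinical(cohort, clin)
  # subject 4 has 4/10 = 40% missing -> dropped; 10-30% retained
  expect_equal(nrow(out), 5)
  expect_equal(attr(out, "n_dropped"), 1)
  expect_false(anyNA(out[, clin]))
  # group-wise median imputation: HC s2 values (1, 3) -> 2
  expect_equal(out$s2[2], 2)

  exact30 <- data.frame(group = "HC",
                        s1 = NA, s2 = NA, s3 = NA,
                        s4 = 1, s5 = 1, s6 = 1, s7 = 1, s8 = 1, s9 = 1,
                        s10 = 1)
  exact30 <- rbind(exact30, within(exact30, {s1 <- 2; s2 <- 2; s3 <- 2}))
  kept <- screen_and_impute_clinical(exact30, clin)
  expect_equal(nrow(kept), 2)  # exactly 30% missing is retained

  allmiss <- data.frame(group = c("HC", "HC"), s1 = c(NA, NA),
                        s2 = c(1, 2), s3 = c(1, 2), s4 = c(1, 2),
                        s5 = c(1, 2), s6 = c(1, 2), s7 = c(1, 2),
                        s8 = c(1, 2), s9 = c(1, 2), s10 = c(1, 2))
  expect_error(screen_and_impute_clinical(allmiss, clin),
               "entirely missing")
})

test_that("metric-clinical correlations behave under identity, ranks and null", {
  set.seed(36)
  n <- 100
  m <- cbind(a = rnorm(n), b = rnorm(n))
  clin <- data.frame(c1 = m[, "a"], c2 = exp(m[, "b"]), c3 = rnorm(n))
  out <- clinical_correlations(m, clin)
  expect_equal(out$r[out$metric == "a" & out$clinical == "c1"], 1)
  expect_equal(out$r[out$metric == "b" & out$clinical == "c2"], 1)
  null_r <- out$r[out$clinical == "c3"]
  expect_true(all(abs(null_r) < 0.3))
  expect_true(all(out$q[out$clinical == "c3"] > .05))
  const <- clinical_correlations(m, data.frame(c = rep(1, n)))
  expect_true(all(is.na(const$r)))
})

test_that("explained-variance ANOVA has correct df and type-I control", {
  ev <- c(0.2, 0.3, 0.4, 0.2, 0.3, 0.4)  # same values in both groups
  grp <- rep(c("a", "b"), each = 3)
  out <- explained_variance_anova(ev, grp)
  expect_equal(out$F, 0)

  set.seed(37)
  sizes <- c(HC = 376, ROP = 243, ROD = 212, `CHR-P` = 240)
  g4 <- rep(names(sizes), sizes)
  out4 <- explained_variance_anova(rnorm(sum(sizes)), g4)
  expect_equal(out4$df1, 3)
  expect_equal(out4$df2, 1067)

  rej <- replicate(1000, {
    e <- rnorm(40)
    explained_variance_anova(e, rep(letters[1:4], each = 10))$p < .05
  })
  expect_gte(mean(rej), 0.035)
  expect_lte(mean(rej), 0.065)
  expect_error(explained_variance_anova(1:3, c("a", "a", "b")), ">= 2 subjects")
})
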