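test_that("Wald ratio and its first-order SE", {
  wr <- wald_ratio(0.2, 0.02, 0.01)
  expect_equal(wr$ratio, 0.1)
  expect_equal(wr$se, 0.05)
  expect_equal(wald_ratio(1, 0.05, 0.01), list(ratio = 0.05, se = 0.01))
  expect_equal(wald_ratio(-0.5, 0, 0.01)$ratio, 0)
  expect_equal(wald_ratio(-0.5, 0, 0.01)$se, 0.02)
  expect_error(wald_ratio(0, 0.1, 0.01), "bx = 0")
})

test_that("IVW matches the closed-form weighted mean with dispersion", {
  h <- make_h(bx = c(1, 1), by = c(0.1, 0.3), sy = c(0.1, 0.1))
  fixed <- mr_ivw(h, model = "fixed")
  expect_equal(fixed$beta, 0.2)
  expect_equal(fixed$se, sqrt(1 / 200))
  expect_equal(fixed$q_stat, 2)
  expect_equal(fixed$q_df, 1)
  random <- mr_ivw(h, model = "random")
  expect_equal(random$beta, 0.2)
  expect_equal(random$se, sqrt(1 / 200) * sqrt(2))
  # with Q below its df the random-effects SE equals the fixed SE
  h2 <- make_h(bx = c(1, 1, 1), by = c(0.2, 0.2, 0.2), sy = rep(0.1, 3))
  expect_equal(mr_ivw(h2, "random")$se, mr_ivw(h2, "fixed")$se)
  expect_equal(mr_ivw(h2)$beta, 0.2)
})

test_that("single-SNP IVW reduces to the Wald ratio", {
  h <- make_h(bx = 1, by = 0.05, sy = 0.01)
  fit <- mr_ivw(h)
  expect_identical(fit$method, "wald")
  expect_equal(fit$beta, 0.05)
  expect_equal(fit$se, 0.01)
  expect_equal(fit$or_, exp(0.05))
})

test_that("IVW equals the weighted mean of Wald ratios on random instances", {
  set.seed(123)
  for (i in 1:100) {
    J <- sample(2:12, 1)
    bx <- rnorm(J, 0, 1); bx[abs(bx) < 0.05] <- 0.5
    by <- rnorm(J, 0, 0.5)
    sy <- runif(J, 0.01, 0.5)
    h <- make_h(bx, by, sy)
    w <- bx^2 / sy^2
    oracle <- sum(w * (by / bx)) / sum(w)
    expect_equal(mr_ivw(h, "fixed")$beta, oracle, tolerance = 1e-10)
  }
})

test_that("estimators are scale-equivariant in the outcome", {
  set.seed(5)
  J <- 8
  bx <- rnorm(J, 0.1, 0.03); by <- rnorm(J, 0.05, 0.02)
  sy <- runif(J, 0.01, 0.05)
  h1 <- make_h(bx, by, sy)
  h2 <- make_h(bx, 3 * by, 3 * sy)
  for (model in c("fixed", "random")) {
    f1 <- mr_ivw(h1, model); f2 <- mr_ivw(h2, model)
    expect_equal(f2$beta, 3 * f1$beta)
    expect_equal(f2$se, 3 * f1$se)
    expect_equal(f2$pval, f1$pval)
  }
  e1 <- mr_egger(h1); e2 <- mr_egger(h2)
  expect_equal(e2$beta, 3 * e1$beta)
  expect_equal(e2$se, 3 * e1$se)
  expect_equal(e2$egger_intercept, 3 * e1$egger_intercept)
})

test_that("Egger regression recovers slope and intercept", {
  h <- make_h(bx = c(1, 2, 3), by = c(0.3, 0.5, 0.7), sy = rep(0.1, 3))
  fit <- mr_egger(h)
  expect_equal(fit$beta, 0.2)
  expect_equal(fit$egger_intercept, 0.1)
  # an exact proportional relation has zero intercept
  h0 <- make_h(bx = c(0.5, 1, 2), by = 0.5 * c(0.5, 1, 2), sy = rep(0.1, 3))
  fit0 <- mr_egger(h0)
  expect_equal(fit0$egger_intercept, 0, tolerance = 1e-12)
  expect_equal(fit0$beta, 0.5)
  expect_error(mr_egger(make_h(bx = c(1, 2), by = c(1, 2), sy = c(1, 1))),
               "at least 3")
  expect_error(mr_egger(make_h(bx = rep(1, 4), by = rnorm(4), sy = rep(1, 4))),
               "singular")
})

test_that("Egger matches a weighted lm oracle and is orientation-fixed", {
  set.seed(11)
  for (i in 1:20) {
    J <- sample(3:10, 1)
    bx <- rnorm(J, 0.2, 0.2)
    by <- 0.4 * bx + rnorm(J, 0.02, 0.05)
    sy <- runif(J, 0.02, 0.2)
    h <- make_h(bx, by, sy)
    fit <- mr_egger(h)
    # oracle: lm on pre-oriented data with the same dispersion rule
    flip <- ifelse(bx < 0, -1, 1)
    ofit <- lm(I(by * flip) ~ I(bx * flip), weights = 1 / sy^2)
    sm <- summary(ofit)
    scale_fix <- sqrt(max(1, sm$sigma^2) / sm$sigma^2)
    expect_equal(fit$beta, unname(coef(ofit)[2]), tolerance = 1e-10)
    expect_equal(fit$egger_intercept, unname(coef(ofit)[1]), tolerance = 1e-10)
    expect_equal(fit$se, unname(sm$coefficients[2, 2]) * scale_fix,
                 tolerance = 1e-10)
    # flipping a subset of SNPs' orientation changes nothing
    k <- sample(J, ceiling(J / 2))
    bx2 <- bx; by2 <- by
    bx2[k] <- -bx2[k]; by2[k] <- -by2[k]
    fit2 <- mr_egger(make_h(bx2, by2, sy))
    expect_equal(fit2$beta, fit$beta, tolerance = 1e-12)
    expect_equal(fit2$egger_intercept, fit$egger_intercept, tolerance = 1e-12)
  }
})

test_that("median estimators interpolate the cumulative weight at 0.5", {
  # odd-count simple median
  h <- make_h(bx = c(1, 1, 1), by = c(0.1, 0.2, 0.9), sy = rep(0.1, 3))
  expect_equal(mr_simple_median(h, n_boot = 200)$beta, 0.2)
  # weighted median by interpolation: ratios 0.1/0.2/0.3, weights 1/1/2
  sy <- 1 / sqrt(c(1, 1, 2))
  h2 <- make_h(bx = c(1, 1, 1), by = c(0.1, 0.2, 0.3), sy = sy)
  expect_equal(mr_weighted_median(h2, n_boot = 200)$beta, 0.7 / 3,
               tolerance = 1e-10)
  # degenerate: all ratios equal
  h3 <- make_h(bx = c(1, 2, 4), by = 0.3 * c(1, 2, 4), sy = rep(0.01, 3),
               sx = matrix(1e-8, 3, 1))
  fit3 <- mr_simple_median(h3, n_boot = 200)
  expect_equal(fit3$beta, 0.3)
  expect_lt(fit3$se, 0.02)
  expect_lt(fit3$pval, 0.05)
  expect_error(mr_simple_median(make_h(1, 0.1, 0.1)), "at least 3")
})

test_that("median bootstrap is seed-deterministic and leaves the RNG alone", {
  set.seed(99)
  J <- 6
  h <- make_h(rnorm(J, 0.2, 0.05), rnorm(J, 0.1, 0.03), runif(J, 0.01, 0.1),
              sx = matrix(0.01, J, 1))
  set.seed(1); before <- runif(1)
  set.seed(1)
  f1 <- mr_weighted_median(h, seed = 7)
  after <- runif(1)
  expect_identical(before, after)  # caller RNG stream undisturbed
  f2 <- mr_weighted_median(h, seed = 7)
  expect_identical(f1$se, f2$se)
  f3 <- mr_weighted_median(h, seed = 8)
  expect_false(identical(f1$se, f3$se))
})

test_that("single-SNP analysis gives one Wald row per usable SNP", {
  h <- make_h(bx = c(0.5, 0, 2), by = c(0.05, 0.1, 0.2), sy = rep(0.01, 3))
  tab <- single_snp_analysis(h)
  expect_equal(nrow(tab), 2L)
  expect_equal(tab$ratio, c(0.1, 0.1))
  expect_equal(tab$se, c(0.02, 0.005))
  expect_equal(attr(tab, "excluded")$snp, "rs002")
})

test_that("leave-one-out rows equal IVW on the complementary subsets", {
  h <- make_h(bx = c(1, 2, 3), by = c(0.1, 0.25, 0.28), sy = c(0.1, 0.2, 0.1))
  loo <- leave_one_out(h)
  expect_equal(nrow(loo), 3L)
  for (j in 1:3) {
    keep <- setdiff(1:3, j)
    sub <- make_h(h$bx[keep, , drop = FALSE], h$by[keep], h$sy[keep])
    expect_equal(loo$beta[j], mr_ivw(sub)$beta)
  }
  # homogeneous ratios: every row equals the full estimate
  hh <- make_h(bx = c(1, 2, 4), by = 0.3 * c(1, 2, 4), sy = rep(0.1, 3))
  loo2 <- leave_one_out(hh)
  expect_equal(loo2$beta, rep(0.3, 3))
  # a gross outlier moves the estimate most when excluded
  J <- 10
  bx <- rep(1, J); by <- c(rep(0.1, J - 1), 2); sy <- rep(0.05, J)
  loo3 <- leave_one_out(make_h(bx, by, sy))
  full <- mr_ivw(make_h(bx, by, sy))$beta
  expect_equal(which.max(abs(loo3$beta - full)), J)
})
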