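test_that("truth summary matches the closed-form identities", {
  ts <- truth_summary(mediation_truth(alpha = 0.5, beta_m = 0.4, beta_d = 0.1))
  expect_equal(ts$total_effect, 0.3)
  expect_equal(unname(ts$indirect), 0.2)
  expect_equal(unname(ts$proportion), 2 / 3)
  ts0 <- truth_summary(mediation_truth(alpha = 0.5, beta_m = 0, beta_d = 0.1))
  expect_equal(unname(ts0$indirect), 0)
  expect_equal(unname(ts0$proportion), 0)
  ts1 <- truth_summary(mediation_truth(alpha = 0.5, beta_m = 0.4, beta_d = 0))
  expect_equal(unname(ts1$proportion), 1)
  ts_undef <- truth_summary(mediation_truth(alpha = 0.5, beta_m = 0.4,
                                            beta_d = -0.2))
  expect_true(ts_undef$proportion_undefined)
  expect_true(is.na(ts_undef$combined_proportion))
})

test_that("the same seed reproduces bit-identical tables and leaves the
           caller RNG untouched", {
  set.seed(555); before <- runif(1)
  set.seed(555)
  s1 <- simulate_mediation_sumstats(mediation_truth(J_exposure = 20,
                                                    J_mediator = 10, seed = 3))
  expect_identical(runif(1), before)
  s2 <- simulate_mediation_sumstats(mediation_truth(J_exposure = 20,
                                                    J_mediator = 10, seed = 3))
  expect_identical(as.data.frame(s1$exposure), as.data.frame(s2$exposure))
  expect_identical(as.data.frame(s1$outcome), as.data.frame(s2$outcome))
  expect_identical(as.data.frame(s1$mediators[[1]]),
                   as.data.frame(s2$mediators[[1]]))
  s3 <- simulate_mediation_sumstats(mediation_truth(J_exposure = 20,
                                                    J_mediator = 10, seed = 4))
  expect_false(identical(s3$exposure$beta, s1$exposure$beta))
})

test_that("generated tables have the declared structure", {
  truth <- mediation_truth(J_exposure = 15, J_mediator = 5,
                           alpha = c(0.5, -0.2), beta_m = c(0.4, 0.1),
                           seed = 9)
  sim <- simulate_mediation_sumstats(truth)
  J <- 15 + 2 * 5
  expect_equal(nrow(sim$exposure), J)
  expect_length(sim$mediators, 2)
  expect_equal(nrow(sim$outcome), J)
  expect_true(all(sim$exposure$effect_allele == "A"))
  expect_true(all(sim$exposure$other_allele == "G"))
  expect_equal(dim(unclass(sim$ld)), c(J, J))
  expect_equal(unname(diag(unclass(sim$ld))), rep(1, J))
  expect_identical(attr(sim$exposure, "trait_type"), "binary")
  expect_identical(attr(sim$mediators[[1]], "trait_type"), "continuous")
})

test_that("with vanishing noise every estimator recovers the truth", {
  eps <- 1e-8
  truth <- mediation_truth(J_exposure = 40, J_mediator = 20,
                           se_x = eps, se_m = eps, se_y = eps, seed = 2)
  sim <- simulate_mediation_sumstats(truth)
  ts <- truth_summary(truth)
  exp_ids <- sim$exposure$snp[1:40]
  sub <- sim$exposure[sim$exposure$snp %in% exp_ids, ]
  attributes(sub)[c("trait_name", "trait_type")] <-
    attributes(sim$exposure)[c("trait_name", "trait_type")]
  class(sub) <- class(sim$exposure)
  h <- harmonize(sub, sim$outcome)
  expect_equal(mr_ivw(h)$beta, ts$total_effect, tolerance = 1e-6)
  expect_equal(mr_simple_median(h, n_boot = 100)$beta, ts$total_effect,
               tolerance = 1e-6)
  expect_equal(mr_weighted_median(h, n_boot = 100)$beta, ts$total_effect,
               tolerance = 1e-6)
  egger <- mr_egger(h)
  expect_equal(egger$beta, ts$total_effect, tolerance = 1e-5)
  expect_equal(egger$egger_intercept, 0, tolerance = 1e-6)
  mv <- mvmr_ivw(harmonize(list(sim$mediators[[1]], sim$exposure),
                           sim$outcome))
  expect_equal(mvmr_coef(mv, "M1")$beta, truth$beta_m, tolerance = 1e-6)
  expect_equal(mvmr_coef(mv, "exposure")$beta, truth$beta_d, tolerance = 1e-6)
})

test_that("IVW covers the true total effect at realistic noise", {
  truth <- mediation_truth(J_exposure = 150, J_mediator = 20,
                           se_y = 0.01, seed = 1)
  sim <- simulate_mediation_sumstats(truth)
  sel <- select_genomewide(sim$exposure)
  fit <- mr_ivw(harmonize(sel, sim$outcome))
  expect_lt(abs(fit$beta - truth_summary(truth)$total_effect), 3.89 * fit$se)
})

test_that("directional pleiotropy on all instruments lands in the Egger
           intercept", {
  truth <- mediation_truth(J_exposure = 150, J_mediator = 5,
                           invalid_fraction = 1, pleiotropy_mean = 0.05,
                           pleiotropy_sd = 0.01, seed = 6)
  sim <- simulate_mediation_sumstats(truth)
  exp_ids <- sim$exposure$snp[1:150]
  sub <- sim$exposure[sim$exposure$snp %in% exp_ids, ]
  attributes(sub)[c("trait_name", "trait_type")] <-
    attributes(sim$exposure)[c("trait_name", "trait_type")]
  class(sub) <- class(sim$exposure)
  fit <- mr_egger(harmonize(sub, sim$outcome))
  expect_lt(abs(fit$egger_intercept - 0.05), 3.89 * fit$egger_intercept_se)
  expect_lt(fit$egger_intercept_p, 0.05)
})
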