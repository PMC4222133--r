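test_that("constant-hazard MLE recovers the closed-form occurrence/exposure rate", {
  p <- spm_params(dim = 1, a0 = -0.1, f1_0 = 100, B = 2, Q0 = 0,
                  c0 = log(0.04), theta = 0, m0 = 100, gamma0 = 4,
                  age_range = c(30, 300))
  sch <- observation_scheme(40, censor_age = 80)
  co <- simulate_cohort(p, 400, sch, seed = 51)
  fit <- spm_fit(co, p, free = "c0",
                 options = fit_options(starts = 1, hessian = FALSE))
  chat <- unname(exp(fit$params$c0))
  closed <- sum(co$surv$delta) / sum(co$surv$tau - co$surv$t0)
  expect_equal(chat, closed, tolerance = 1e-4)
})

test_that("multi-start fitting is reproducible and the optimum is a fixed point", {
  truth <- ref_model()
  sch <- biennial_scheme()
  co <- simulate_cohort(truth, 200, sch, seed = 52)
  opts <- fit_options(starts = 3, seed = 5, hessian = FALSE)
  f1 <- spm_fit(co, truth, free = c("Q0", "c0", "theta"), options = opts)
  f2 <- spm_fit(co, truth, free = c("Q0", "c0", "theta"), options = opts)
  expect_identical(f1$par_u, f2$par_u)
  expect_identical(f1$logLik, f2$logLik)
  expect_equal(nrow(f1$starts), 3L)
  expect_equal(f1$logLik, max(f1$starts$value))
  # refitting from the optimum stays at the optimum
  f3 <- spm_fit(co, f1$params, free = c("Q0", "c0", "theta"),
                options = fit_options(starts = 1, hessian = FALSE))
  expect_lt(abs(f3$logLik - f1$logLik), 1e-4)
})

test_that("likelihood-ratio test computes the chi-square comparison", {
  truth <- ref_model()
  sch <- biennial_scheme()
  co <- simulate_cohort(truth, 150, sch, seed = 53)
  null <- spm_fit(co, truth, free = c("Q0", "c0"),
                  options = fit_options(starts = 1, hessian = FALSE))
  alt <- spm_fit(co, truth, free = c("Q0", "c0", "theta"),
                 options = fit_options(starts = 1, hessian = FALSE))
  lt <- lr_test(null, alt)
  expect_equal(lt$df, 1L)
  expect_gte(lt$statistic, 0)
  expect_equal(lt$p.value,
               pchisq(lt$statistic, 1, lower.tail = FALSE))
  # an added parameter that does not move the likelihood: statistic ~ 0, p ~ 1
  alt0 <- alt
  alt0$logLik <- null$logLik
  alt0$n_free <- 3L
  lt0 <- lr_test(null, alt0, check = FALSE)
  expect_equal(lt0$statistic, 0)
  expect_equal(lt0$p.value, 1)
  expect_error(lr_test(alt, null), "not nested|more free parameters")
  # non-nested free sets are refused
  other <- spm_fit(co, truth, free = c("Q0", "theta", "B"),
                   options = fit_options(starts = 1, hessian = FALSE))
  expect_error(lr_test(other, alt), "not nested")
})

test_that("AIC follows 2k - 2logL and ranks models", {
  f <- structure(list(kind = "basic", logLik = -100, n_free = 5L,
                      data_id = c(1, 2, 3)), class = "spm_fit")
  expect_equal(spm_aic(f), 210)
  g <- f
  g$n_free <- 6L
  expect_equal(spm_aic(g) - spm_aic(f), 2)
  tab <- compare_aic(small = f, big = g)
  expect_equal(tab$model, c("small", "big"))
  expect_equal(tab$dAIC, c(0, 2))
  h <- g
  h$data_id <- c(9, 9, 9)
  expect_error(compare_aic(f, h), "different cohorts")
})

test_that("AIC prefers the generating model over an underspecified one", {
  truth <- ref_model()
  sch <- biennial_scheme()
  co <- simulate_cohort(truth, 2000, sch, seed = 54)
  full <- spm_fit(co, truth, free = c("Q0", "c0", "theta"),
                  options = fit_options(starts = 1, hessian = FALSE,
                                        h_max = 0.5))
  # drop the hazard curvature entirely (one parameter poorer, misspecified)
  no_q <- truth
  no_q$Q0 <- matrix(0, 1, 1)
  reduced <- spm_fit(co, no_q, free = c("c0", "theta"),
                     options = fit_options(starts = 1, hessian = FALSE,
                                           h_max = 0.5))
  expect_lt(spm_aic(full), spm_aic(reduced))
})

test_that("estimation error shrinks with the sample size", {
  truth <- ref_model()
  sch <- observation_scheme(seq(40, 76, by = 6), censor_age = 80)
  free <- c("Q0", "c0")
  set.seed(55)
  err <- sapply(c(250, 1000, 4000), function(n) {
    e <- replicate(20, {
      # fine simulation step so discretization bias stays below the
      # statistical error even at the largest n
      co <- simulate_cohort(truth, n, sch, dt = 0.01)
      f <- spm_fit(co, truth, free = free,
                   options = fit_options(starts = 1, hessian = FALSE,
                                         h_max = 0.5, maxit = 200))
      abs(c(f$params$Q0[1, 1] / truth$Q0[1, 1],
            exp(f$params$c0 - truth$c0)) - 1)
    })
    apply(e, 1, median)
  })
  # median absolute relative error decreasing in n, for both parameters
  expect_true(all(err[, 2] < err[, 1]))
  expect_true(all(err[, 3] < err[, 2]))
})

test_that("Wald standard errors track the sampling spread", {
  truth <- ref_model()
  sch <- observation_scheme(seq(40, 76, by = 6), censor_age = 80)
  set.seed(56)
  reps <- replicate(30, {
    co <- simulate_cohort(truth, 1000, sch)
    f <- spm_fit(co, truth, free = c("Q0", "c0"),
                 options = fit_options(starts = 1, h_max = 0.5, maxit = 200))
    c(est = unname(f$par_u["Q0"]), se = unname(f$se_u["Q0"]))
  })
  emp_sd <- sd(reps["est", ])
  mean_se <- mean(reps["se", ])
  expect_gt(mean_se / emp_sd, 0.5)
  expect_lt(mean_se / emp_sd, 2)
})
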