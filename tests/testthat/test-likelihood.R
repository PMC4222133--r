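test_that("moment derivatives match their defining equations", {
  p <- spm_params(dim = 1, a0 = -0.1, f1_0 = 100, B = 2, Q0 = 0,
                  c0 = -10, theta = 0.05, m0 = 100, gamma0 = 4,
                  age_range = c(30, 110))
  d <- moment_derivatives(p, t = 50, m = 110, gamma = 3)
  expect_equal(d$dm, -1.0)                       # a (m - f1) with Q = 0
  expect_equal(d$dgamma[1, 1], 2 * (-0.1) * 3 + 4)
  # stationary point: m = f1, gamma = B^2 / (-2a)
  d2 <- moment_derivatives(p, t = 50, m = 100, gamma = 4 / 0.2)
  expect_equal(d2$dm, 0)
  expect_equal(d2$dgamma[1, 1], 0)
  # conditioning term pulls the mean toward the norm when Q > 0
  pq <- spm_params(dim = 1, a0 = -0.1, f1_0 = 100, f0_0 = 90, B = 2,
                   Q0 = 1e-3, c0 = -10, theta = 0.05, m0 = 100,
                   gamma0 = 4, age_range = c(30, 110))
  d3 <- moment_derivatives(pq, t = 50, m = 100, gamma = 10)
  expect_equal(d3$dm, -2 * 10 * 1e-3 * 10)
})

test_that("conditional hazard adds the quadratic and trace terms", {
  p <- spm_params(dim = 1, a0 = -0.1, f1_0 = 100, f0_0 = 90, B = 2,
                  Q0 = 1e-3, c0 = log(0.01), theta = 0, m0 = 100,
                  gamma0 = 0, age_range = c(30, 110))
  expect_equal(conditional_hazard(p, 50, m = 90, gamma = 0), 0.01)
  expect_equal(conditional_hazard(p, 50, m = 100, gamma = 0), 0.11)
  expect_equal(conditional_hazard(p, 50, m = 100, gamma = 5), 0.115)
})

test_that("moment propagation matches the linear-ODE closed form and deSolve", {
  # gamma(t): dgamma/dt = 2 a gamma + B^2, gamma(0) = 0
  p <- spm_params(dim = 1, a0 = -0.1, f1_0 = 100, B = 2, Q0 = 0,
                  c0 = -700, theta = 0, m0 = 110, gamma0 = 0,
                  age_range = c(30, 110))
  st <- spmaging:::cpp_propagate_interval(spmaging:::.par_clist(p),
                                          100, 100, 0, 40, 50, 110,
                                          matrix(0, 1, 1), 0, 0.1)
  expect_equal(st$gamma[1, 1], 4 * (1 - exp(-2)) / 0.2, tolerance = 1e-8)
  expect_equal(as.numeric(st$m), 100 + 10 * exp(-1), tolerance = 1e-8)
  # independent ODE solver oracle for the nonlinear (Q > 0) equations
  pq <- ref_model()
  rhs <- function(t, y, parms) {
    d <- moment_derivatives(pq, t, y[1], y[2])
    mu <- conditional_hazard(pq, t, y[1], y[2])
    list(c(d$dm, d$dgamma[1, 1], mu))
  }
  sol <- deSolve::ode(c(120, 25, 0), c(40, 70), rhs, NULL,
                      rtol = 1e-10, atol = 1e-12)
  st2 <- spmaging:::cpp_propagate_interval(spmaging:::.par_clist(pq),
                                           pq$f1_0, pq$f0_0, 0, 40, 70, 120,
                                           matrix(25, 1, 1), 0, 0.1)
  expect_equal(as.numeric(st2$m), unname(sol[2, 2]), tolerance = 1e-7)
  expect_equal(st2$gamma[1, 1], unname(sol[2, 3]), tolerance = 1e-7)
  expect_equal(st2$H, unname(sol[2, 4]), tolerance = 1e-7)
})

test_that("individual contributions reduce to closed forms", {
  # censored, one baseline observation, constant hazard: -c (tau - t0)
  p <- spm_params(dim = 1, a0 = -0.1, f1_0 = 100, B = 2, Q0 = 0,
                  c0 = log(0.05), theta = 0, m0 = 100, gamma0 = 4,
                  age_range = c(0, 110))
  ind <- list(t0 = 40, tau = 60, delta = 0, x = NULL,
              obs = data.frame(age = 40, y1 = 103))
  expect_equal(individual_loglik(p, ind), -0.05 * 20, tolerance = 1e-10)
  # pure Brownian bridge density: a = 0, B = 1, y(0) = y(4) = 5
  pb <- spm_params(dim = 1, a0 = 0, f1_0 = 0, B = 1, Q0 = 0,
                   c0 = -700, theta = 0, m0 = 5, gamma0 = 0,
                   age_range = c(0, 110))
  indb <- list(t0 = 0, tau = 4, delta = 0, x = NULL,
               obs = data.frame(age = c(0, 4), y1 = c(5, 5)))
  expect_equal(individual_loglik(pb, indb), dnorm(5, 5, 2, log = TRUE),
               tolerance = 1e-9)
  # duplicated examination age -> degenerate predictive density
  inddup <- list(t0 = 0, tau = 4, delta = 0, x = NULL,
                 obs = data.frame(age = c(2, 2), y1 = c(5, 5)))
  expect_error(individual_loglik(pb, inddup), "increasing|degenerate")
})

test_that("cohort likelihood is an order-invariant sum", {
  sch <- biennial_scheme()
  co <- simulate_cohort(ref_model(), 60, sch, seed = 31)
  ll <- cohort_loglik(ref_model(), co)
  lli <- indiv_logliks(ref_model(), co)
  expect_equal(as.numeric(ll), sum(lli))
  one <- co[1]
  expect_equal(as.numeric(cohort_loglik(ref_model(), one)), lli[1])
  # doubling the cohort doubles the log-likelihood
  surv2 <- co$surv
  surv2$id <- surv2$id + 1000
  long2 <- co$long
  long2$id <- long2$id + 1000
  dbl <- spm_cohort(rbind(co$long, long2), rbind(co$surv, surv2))
  expect_equal(as.numeric(cohort_loglik(ref_model(), dbl)),
               2 * as.numeric(ll), tolerance = 1e-12)
  # permutation invariance
  perm <- sample(nrow(co$surv))
  cop <- spm_cohort(co$long, co$surv[perm, ], dim = 1)
  expect_equal(as.numeric(cohort_loglik(ref_model(), cop)),
               as.numeric(ll), tolerance = 1e-9)
})

test_that("marginal survival matches Gompertz and exponential closed forms", {
  p <- spm_params(dim = 1, a0 = -0.1, f1_0 = 100, B = 2, Q0 = 0,
                  c0 = -10, theta = 0.08, m0 = 100, gamma0 = 25,
                  age_range = c(30, 110))
  ages <- c(50, 70, 90, 105)
  s <- marginal_survival(p, 40, ages)
  closed <- exp(-(exp(-10) / 0.08) * (exp(0.08 * ages) - exp(0.08 * 40)))
  expect_equal(s$survival, closed, tolerance = 1e-8)
  pe <- spm_params(dim = 1, a0 = -0.1, f1_0 = 100, B = 2, Q0 = 0,
                   c0 = log(0.05), theta = 0, m0 = 100, gamma0 = 25,
                   age_range = c(30, 110))
  se <- marginal_survival(pe, 40, 60)
  expect_equal(se$survival, exp(-1), tolerance = 1e-8)
})

test_that("likelihood at the truth beats perturbed parameters", {
  sch <- biennial_scheme()
  truth <- ref_model()
  co <- simulate_cohort(truth, 1000, sch, seed = 33)
  ll0 <- as.numeric(cohort_loglik(truth, co))
  free <- c("a0", "f1_0", "f1_1", "B", "Q0", "c0", "theta")
  u0 <- spm_pack(truth, free)
  set.seed(34)
  wins <- 0L
  for (r in 1:20) {
    u <- u0 * runif(length(u0), 0.75, 1.25)
    llp <- as.numeric(cohort_loglik(spm_unpack(u, truth, free), co))
    wins <- wins + (ll0 > llp)
  }
  expect_gte(wins, 19L)
})

test_that("discrete-time likelihood agrees with its Gaussian building blocks", {
  # single transition, a = 0, step 4, B = 1 reproduces the N(5; 5, 4) density
  pb <- spm_params(dim = 1, a0 = 0, f1_0 = 0, B = 1, Q0 = 0,
                   c0 = -700, theta = 0, m0 = 5, gamma0 = 0,
                   age_range = c(0, 110))
  long <- data.frame(id = 1, age = c(0, 4), y1 = c(5, 5))
  surv <- data.frame(id = 1, t0 = 0, tau = 4, delta = 0)
  co <- spm_cohort(long, surv)
  expect_equal(discrete_time_loglik(pb, co, step = 4),
               dnorm(5, 5, 2, log = TRUE), tolerance = 1e-9)
  # zero hazard: survival factors contribute exactly nothing
  surv2 <- data.frame(id = 1, t0 = 0, tau = 12, delta = 0)
  co2 <- spm_cohort(long, surv2)
  expect_equal(discrete_time_loglik(pb, co2, step = 4),
               dnorm(5, 5, 2, log = TRUE), tolerance = 1e-12)
  # off-grid ages error without binning
  co3 <- spm_cohort(data.frame(id = 1, age = c(0, 3), y1 = c(5, 5)), surv)
  expect_error(discrete_time_loglik(pb, co3, step = 4), "bin")
})

test_that("discrete and continuous likelihoods converge as the step shrinks", {
  truth <- ref_model()
  sch <- observation_scheme(seq(40, 49.95, by = 0.05), censor_age = 50)
  co <- simulate_cohort(truth, 300, sch, seed = 35)
  lc <- as.numeric(cohort_loglik(truth, co, h_max = 0.05))
  ld <- discrete_time_loglik(truth, co, step = 0.05, bin = TRUE)
  expect_lt(abs(ld - lc) / abs(lc), 0.005)
})

test_that("measurement error switches to the filter update consistently", {
  # with sigma_me -> 0 the filtered likelihood approaches the exact-reset one
  sch <- biennial_scheme(sigma_me = 0)
  co <- simulate_cohort(ref_model(), 50, sch, seed = 36)
  l0 <- as.numeric(cohort_loglik(ref_model(), co, sigma_me = 0))
  l1 <- as.numeric(cohort_loglik(ref_model(), co, sigma_me = 1e-6))
  expect_equal(l1, l0, tolerance = 1e-4)
  # noisy observations: filtered likelihood at the truth beats the
  # exact-reset likelihood that ignores the noise
  schn <- biennial_scheme(sigma_me = 3)
  con <- simulate_cohort(ref_model(), 400, schn, seed = 37)
  ln_f <- as.numeric(cohort_loglik(ref_model(), con, sigma_me = 3))
  ln_0 <- as.numeric(cohort_loglik(ref_model(), con, sigma_me = 0))
  expect_gt(ln_f, ln_0)
})
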