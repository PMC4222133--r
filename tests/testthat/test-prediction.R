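test_that("memoryless case: conditional survival is exponential regardless of history", {
  p <- spm_params(dim = 1, a0 = -0.2, f1_0 = 100, B = 4, Q0 = 0,
                  c0 = log(0.05), theta = 0, m0 = 100, gamma0 = 25,
                  age_range = c(30, 110))
  for (ys in c(80, 100, 130)) {
    ind <- list(t0 = 40, tau = 60, delta = 0, x = NULL,
                obs = data.frame(age = c(40, 60), y1 = c(100, ys)))
    pr <- predict_individual(p, ind, at_age = 60, horizon = 80, grid_n = 21)
    expect_equal(pr$survival[1], 1)
    expect_equal(pr$survival[21], exp(-0.05 * 20), tolerance = 1e-8)
  }
})

test_that("larger deviation from the norm lowers conditional survival", {
  p <- ref_model()
  mk <- function(y) list(t0 = 40, tau = 60, delta = 0, x = NULL,
                         obs = data.frame(age = c(40, 60), y1 = c(110, y)))
  f0_60 <- 90 + 0.5 * 60
  on_norm <- predict_individual(p, mk(f0_60), 60, 90, grid_n = 31)
  deviant <- predict_individual(p, mk(f0_60 + 25), 60, 90, grid_n = 31)
  expect_true(all(deviant$survival <= on_norm$survival + 1e-12))
  expect_lt(deviant$survival[31], on_norm$survival[31])
})

test_that("prediction has the tower property over intermediate ages", {
  p <- ref_model()
  ind <- list(t0 = 40, tau = 60, delta = 0, x = NULL,
              obs = data.frame(age = c(40, 55), y1 = c(115, 108)))
  direct <- predict_individual(p, ind, 55, 95, grid_n = 41)
  # grid point 75 appears in both paths
  mid <- direct$survival[direct$age == 75]
  two_leg <- predict_individual(p, ind, 55, 75, grid_n = 21)
  expect_equal(two_leg$survival[21], mid, tolerance = 1e-8)
})

test_that("conditional survival matches restarted Monte-Carlo paths", {
  p <- ref_model()
  ys <- 112
  s <- 60
  ind <- list(t0 = 40, tau = s, delta = 0, x = NULL,
              obs = data.frame(age = c(40, s), y1 = c(115, ys)))
  horizons <- c(65, 70, 75, 80, 85)
  pr <- predict_individual(p, ind, s, 85, grid_n = 6)
  # restart the simulation from the observed state (degenerate initial law)
  p2 <- p
  p2$m0 <- ys
  p2$gamma0 <- matrix(0, 1, 1)
  set.seed(81)
  mc <- mc_survival(p2, s, horizons, n_paths = 20000)
  z <- (pr$survival[-1] - mc$survival) / mc$se
  expect_true(all(abs(z) < 3))
})

test_that("mixture predictions combine regimes by the posterior", {
  a <- class_model(90)
  b <- class_model(115)
  ind <- list(t0 = 40, tau = 60, delta = 0, x = NULL, genotype = NA,
              obs = data.frame(age = c(40, 60), y1 = c(92, 93)))
  # K = 1 equals the basic prediction
  m1 <- latent_class_model(list(a))
  pr1 <- predict_latent(m1, ind, 60, 80, grid_n = 11)
  pr1b <- predict_individual(a, ind, 60, 80, grid_n = 11)
  expect_equal(pr1$survival, pr1b$survival, tolerance = 1e-12)
  # observed genotype: degenerate posterior at that regime
  gm <- genetic_model(list(a, b), beta0 = 0)
  ind2 <- ind
  ind2$genotype <- 2L
  pr2 <- predict_latent(gm, ind2, 60, 80, grid_n = 11)
  expect_equal(pr2$survival,
               predict_individual(b, ind2, 60, 80, grid_n = 11)$survival,
               tolerance = 1e-12)
  expect_equal(attr(pr2, "posterior"), c(0, 1))
  # posterior (0.9, 0.1): mixture curve is the pointwise convex combination
  m <- latent_class_model(list(a, a), beta0 = log(9))  # equal likelihoods
  prm <- predict_latent(m, ind, 60, 80, grid_n = 11)
  pa <- predict_individual(a, ind, 60, 80, grid_n = 11)
  expect_equal(attr(prm, "posterior"), c(0.9, 0.1))
  expect_equal(prm$survival, pa$survival, tolerance = 1e-12)
  mb <- latent_class_model(list(a, b), beta0 = log(9))
  post <- attr(predict_latent(mb, ind, 60, 80, grid_n = 11), "posterior")
  prb <- predict_individual(b, ind, 60, 80, grid_n = 11)
  mixed <- predict_latent(mb, ind, 60, 80, grid_n = 11)
  expect_equal(mixed$survival,
               post[1] * pa$survival + post[2] * prb$survival,
               tolerance = 1e-12)
})

test_that("forecasting arms are paired and scenarios act as closed forms say", {
  p <- spm_params(dim = 1, a0 = -0.2, f1_0 = 100, B = 4, Q0 = 1e-4,
                  c0 = -10, theta = 0.08, m0 = 100, gamma0 = 25,
                  age_range = c(30, 120))
  ages <- seq(45, 95, by = 10)
  null_fc <- forecast_population(p, 40, ages, n_sim = 300,
                                 scenario = scenario_spec(label = "null"),
                                 seed = 82)
  expect_identical(null_fc$survival, null_fc$survival_scen)
  expect_identical(null_fc$mean_y, null_fc$mean_y_scen)
  # removing the quadratic term leaves pure Gompertz mortality
  fc <- forecast_population(p, 40, ages, n_sim = 4000,
                            scenario = scenario_spec(Q_scale = 0), seed = 83)
  gomp <- exp(-(exp(-10) / 0.08) * (exp(0.08 * ages) - exp(0.08 * 40)))
  z <- (fc$survival_scen - gomp) / fc$se_scen
  expect_true(all(abs(z) < 3))
  # scaling Q down never lowers projected survival
  half <- forecast_population(p, 40, ages, n_sim = 1000,
                              scenario = scenario_spec(Q_scale = 0.5),
                              seed = 84)
  expect_true(all(half$survival_scen >= half$survival - 1e-12))
  # reproducibility
  again <- forecast_population(p, 40, ages, n_sim = 300,
                               scenario = scenario_spec(label = "null"),
                               seed = 82)
  expect_identical(as.data.frame(null_fc), as.data.frame(again))
})

test_that("halving the baseline hazard doubles the median remaining lifetime", {
  # exponential case: median = ln 2 / c
  p <- spm_params(dim = 1, a0 = -0.2, f1_0 = 100, B = 4, Q0 = 0,
                  c0 = log(0.05), theta = 0, m0 = 100, gamma0 = 25,
                  age_range = c(30, 400))
  ages <- seq(45, 220, by = 5)
  fc <- forecast_population(p, 40, ages, n_sim = 4000,
                            scenario = scenario_spec(mu0_scale = 0.5),
                            seed = 85)
  med <- function(S) ages[which(S <= 0.5)[1]] - 40
  ratio <- med(fc$survival_scen) / med(fc$survival)
  # median MC error ~ 1/(c sqrt(n)) per arm, plus the 5-y grid resolution
  expect_gt(ratio, 1.7)
  expect_lt(ratio, 2.3)
})

test_that("scenarios that break the invariants are refused", {
  p <- ref_model()
  expect_error(scenario_spec(Q_scale = -1))
  # direct surgery producing an indefinite Q is caught by apply_scenario
  s2 <- scenario_spec(Q_scale = 1)
  p2 <- p
  p2$Q0 <- matrix(-1e-4, 1, 1)
  expect_error(apply_scenario(p2, s2), "invalid model")
})
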