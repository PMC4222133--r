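test_that("genetic likelihood reduces to its structural identities", {
  sch <- biennial_scheme()
  one <- class_model(100)
  co <- simulate_cohort(one, 80, sch, seed = 71)  # genotype all = 1
  ll1 <- as.numeric(cohort_loglik(one, co))
  # all genotyped, K = 1: log p = 0, so equals the basic likelihood
  expect_equal(genetic_loglik(genetic_model(list(one)), co), ll1,
               tolerance = 1e-12)
  # identical regimes, all genotyped: adds the multinomial log-probabilities
  m <- genetic_model(list(one, one), beta0 = log(3))
  expect_equal(genetic_loglik(m, co), ll1 + 80 * log(0.75),
               tolerance = 1e-9)
  # fully non-genotyped: coincides with the latent-class mixture likelihood
  co_ng <- co
  co_ng$surv$genotype <- NA_integer_
  truth2 <- carrier_truth()
  expect_equal(genetic_loglik(truth2, co_ng),
               mixture_loglik(truth2, co_ng), tolerance = 1e-12)
  # label outside 1..K
  co_bad <- co
  co_bad$surv$genotype[1] <- 7L
  expect_error(genetic_loglik(m, co_bad), "1..K")
})

test_that("modes of action build the declared effect structure", {
  base <- class_model(100, Q0 = 1e-4)
  # additive: heterozygote effect is the mean of the homozygote effects on
  # the unconstrained scale, i.e. Q goes (Q, Q r, Q r^2)
  d <- spmaging:::.action_design("additive", 3L)
  comps <- spmaging:::.genetic_build(base, "Q0", delta = log(2), d, 3L)
  qs <- vapply(comps, function(p) p$Q0[1, 1], numeric(1))
  expect_equal(qs[2] / qs[1], sqrt(qs[3] / qs[1]), tolerance = 1e-10)
  expect_equal(qs[3] / qs[1], 4, tolerance = 1e-10)  # (e^{log2})^2 on chol
  # dominant: categories 2 and 3 share the effect
  dd <- spmaging:::.action_design("dominant", 3L)
  cd <- spmaging:::.genetic_build(base, "Q0", delta = 0.3, dd, 3L)
  expect_equal(cd[[2]]$Q0, cd[[3]]$Q0)
  expect_false(isTRUE(all.equal(cd[[1]]$Q0, cd[[2]]$Q0)))
  # recessive: only category 3 moves
  dr <- spmaging:::.action_design("recessive", 3L)
  cr <- spmaging:::.genetic_build(base, "Q0", delta = 0.3, dr, 3L)
  expect_equal(cr[[1]]$Q0, cr[[2]]$Q0)
  expect_false(isTRUE(all.equal(cr[[2]]$Q0, cr[[3]]$Q0)))
  # shared: no effect parameters at all
  expect_equal(ncol(spmaging:::.action_design("shared", 3L)), 0L)
})

test_that("fully genotyped free-mode fit matches stratified fits", {
  truth <- carrier_truth()
  sch <- biennial_scheme()
  co <- simulate_cohort(truth, 600, sch, genotyped_fraction = 1, seed = 72)
  base <- truth$components[[1]]
  opts <- fit_options(starts = 1, hessian = FALSE, reltol = 1e-12)
  fj <- fit_genetic(co, base, component = "Q0", mode = "free", K = 2,
                    free = character(0), free_beta = TRUE, options = opts)
  # stratified: per-genotype fits of Q0 plus the multinomial count part
  lls <- 0
  for (k in 1:2) {
    sub <- co[co$surv$genotype == k]
    fk <- spm_fit(sub, truth$components[[k]], free = "Q0", options = opts)
    lls <- lls + fk$logLik
  }
  n1 <- sum(co$surv$genotype == 1)
  n2 <- sum(co$surv$genotype == 2)
  lls <- lls + n1 * log(n1 / 600) + n2 * log(n2 / 600)
  expect_equal(fj$logLik, lls, tolerance = 1e-6 * abs(lls))
})

test_that("AIC difference equals 2 dk minus the LRT statistic across modes", {
  truth <- carrier_truth(q_ratio = 1)   # no genetic effect in truth
  sch <- biennial_scheme()
  co <- simulate_cohort(truth, 300, sch, genotyped_fraction = 0.5, seed = 73)
  base <- truth$components[[1]]
  rep <- test_genetic_effect(co, base, component = "Q0",
                             modes = c("shared", "free"), K = 2,
                             free = "c0",
                             options = fit_options(starts = 1,
                                                   hessian = FALSE))
  tab <- rep$table
  lrt <- rep$lrt
  dk <- tab$k[tab$mode == "free"] - tab$k[tab$mode == "shared"]
  daic <- tab$AIC[tab$mode == "free"] - tab$AIC[tab$mode == "shared"]
  expect_equal(daic, 2 * dk - lrt$statistic[1], tolerance = 1e-10)
  expect_equal(lrt$df[1], dk)
})

test_that("an additive truth is not rejected against the free alternative", {
  # three genotype categories, multiplicative (additive-on-log) Q effect
  base <- class_model(100, Q0 = 1e-4)
  d <- spmaging:::.action_design("additive", 3L)
  comps <- spmaging:::.genetic_build(base, "Q0", delta = 0.5 * log(3), d, 3L)
  truth <- genetic_model(comps, beta0 = c(log(4), log(2)))
  sch <- biennial_scheme()
  co <- simulate_cohort(truth, 800, sch, genotyped_fraction = 0.5, seed = 74)
  opts <- fit_options(starts = 1, hessian = FALSE)
  fa <- fit_genetic(co, base, component = "Q0", mode = "additive", K = 3,
                    free = "c0", options = opts)
  ff <- fit_genetic(co, base, component = "Q0", mode = "free", K = 3,
                    free = "c0", options = opts)
  lt <- lr_test(fa, ff, check = FALSE)
  expect_lt(lt$statistic, qchisq(0.95, lt$df))
})

test_that("constraint conflicts and empty cohorts are rejected", {
  base <- class_model(100)
  expect_error(fit_genetic(spm_cohort(data.frame(id = 1, age = 40, y1 = 100),
                                      data.frame(id = 1, t0 = 40, tau = 50,
                                                 delta = 0)),
                           base, component = "Q0", free = c("Q0", "c0")),
               "cannot also")
})
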