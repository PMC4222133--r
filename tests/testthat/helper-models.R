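# Shared fixtures: a realistic single-biomarker model (systolic-pressure
# scale) and builders for mixture truths.  Everything is generated in code;
# seeds are fixed per test.

ref_model <- function(...) {
  args <- list(dim = 1, a0 = -0.2, f1_0 = 100, f1_1 = 0.5,
               f0_0 = 90, f0_1 = 0.5, B = 4, Q0 = 5e-5, q1 = 0.02,
               c0 = -10.3, theta = 0.085, m0 = 120, gamma0 = 25,
               age_range = c(40, 110))
  mod <- utils::modifyList(args, list(...))
  do.call(spm_params, mod)
}

# two-regime builder differing in the allostatic target (and matching norm
# and initial law), well separated relative to the stationary SD B/sqrt(2|a|)
class_model <- function(f1, Q0 = 1e-4) {
  spm_params(dim = 1, a0 = -0.2, f1_0 = f1, f1_1 = 0.3, f0_0 = f1,
             f0_1 = 0.3, B = 4, Q0 = Q0, c0 = -10.3, theta = 0.085,
             m0 = f1, gamma0 = 40, age_range = c(40, 110))
}

# carrier/non-carrier truth with a genotype-specific hazard curvature
carrier_truth <- function(q_ratio = 3, Q_base = 1e-4, carrier_logit = 0.85) {
  mk <- function(Q) spm_params(dim = 1, a0 = -0.2, f1_0 = 100, f1_1 = 0.3,
                               f0_0 = 92, f0_1 = 0.3, B = 4, Q0 = Q,
                               c0 = -10.3, theta = 0.085, m0 = 100,
                               gamma0 = 40, age_range = c(40, 110))
  genetic_model(list(mk(Q_base), mk(Q_base * q_ratio)), beta0 = carrier_logit)
}

biennial_scheme <- function(from = 40, to = 78, censor = 80, ...)
  observation_scheme(seq(from, to, by = 2), censor_age = censor, ...)
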