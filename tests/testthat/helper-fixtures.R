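# Shared fixtures: random admissible parameter draws and small synthetic
# curve sets, all built in code under fixed seeds.

draw_ye <- function() {
  ye_params(alpha_e = runif(1, 0.1, 0.5),
            beta_e = exp(runif(1, log(5e-5), log(1e-3))),
            gamma_e = exp(runif(1, log(1e-4), log(2e-3))))
}

draw_negexp <- function() {
  negexp_params(phi_psii_max = runif(1, 0.3, 0.8),
                k_w = exp(runif(1, log(2e-4), log(5e-3))))
}

draw_exp <- function() {
  exp_params(fv_fm = runif(1, 0.3, 0.85), I_sat = runif(1, 200, 2000))
}

draw_nrh <- function() {
  nrh_params(alpha_prime = runif(1, 0.1, 0.5),
             theta = runif(1, 0.05, 1),
             etr_max = runif(1, 50, 400))
}

# One replicate of a noiseless curve as a plain tibble.
noiseless_curve <- function(params, kind, seed = 1) {
  tr <- synthetic_truth(params, kind = kind, noise_sd = 0, n_reps = 1,
                        seed = seed)
  generate_synthetic(tr)
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(max(abs(actual - expected) / pmax(abs(expected), 1e-300)), tol)
}
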