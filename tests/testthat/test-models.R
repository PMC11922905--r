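test_that("mechanistic curve evaluates to its closed form", {
  p <- ye_params(0.3, 1e-4, 5e-4)
  expect_equal(eval_curve(p, 1000, "ETR"), 180)
  expect_equal(eval_curve(p, 0, "ETR"), 0)
  pphi <- ye_params(0.3, 1e-4, 5e-4, phi_psii_max = 0.719)
  expect_equal(eval_curve(pphi, 0, "PHI"), 0.719)
  expect_equal(eval_curve(pphi, 1000, "PHI"), 0.719 * 0.9 / 1.5)
  # declining branch beyond 1/beta_e is returned, not clipped
  expect_lt(eval_curve(p, 1.5e4, "ETR"), 0)
  expect_equal(eval_curve(p, 1e4, "ETR"), 0) # zero crossing at I = 1/beta_e
  expect_error(eval_curve(p, -5, "ETR"), class = "lrc_error_domain")
  expect_error(eval_curve(p, 100, "PHI"), class = "lrc_error_domain") # no phimax
})

test_that("mechanistic derived quantities match the closed forms", {
  d <- derive_params(ye_params(0.3, 1e-4, 5e-4))
  expect_equal(d$i_sat, (sqrt((1e-4 + 5e-4) / 1e-4) - 1) / 5e-4)
  expect_equal(d$i_sat, 2898.98, tolerance = 1e-5)
  expect_equal(d$etr_max, 252.12, tolerance = 1e-5)
  # symmetric case
  d2 <- derive_params(ye_params(0.2, 1e-3, 1e-3))
  expect_equal(d2$i_sat, (sqrt(2) - 1) / 1e-3)
  # no down-regulation: monotone curve, supremum reported
  d3 <- derive_params(ye_params(0.3, 0, 5e-4))
  expect_identical(d3$i_sat_flag, "not-finite")
  expect_false(is.finite(d3$i_sat))
  expect_equal(d3$etr_max, 0.3 / 5e-4)
})

test_that("negative exponential curve and derivations", {
  p <- negexp_params(0.7, 1 / 1600)
  expect_equal(eval_curve(p, 0, "PHI"), 0.7)
  expect_equal(eval_curve(p, 1600, "PHI"), 0.7 * exp(-1))
  expect_equal(eval_curve(p, 1600, "ETR"), 0.42 * 1600 * 0.7 * exp(-1))
  d <- derive_params(p)
  expect_equal(d$i_sat, 1600)
  expect_equal(d$etr_max, 173.05, tolerance = 1e-4)
  d2 <- derive_params(negexp_params(0.656, 1e-3))
  expect_equal(d2$i_sat, 1000)
  expect_equal(d2$etr_max, 0.42 * 1000 * 0.656 * exp(-1))
  expect_equal(d2$etr_max, 101.36, tolerance = 1e-4)
  expect_equal(derive_params(negexp_params(0.5, 1))$i_sat, 1)
})

test_that("exponential curve resolves the darkness singularity analytically", {
  p <- exp_params(0.72, 600)
  expect_equal(eval_curve(p, 0, "PHI"), 0.72) # limit of (1 - e^-x)/x -> 1
  expect_equal(eval_curve(p, 600, "PHI"), 0.72 * (1 - exp(-1)))
  # ETR asymptote
  expect_equal(eval_curve(p, 1e9, "ETR"), 0.42 * 0.72 * 600,
               tolerance = 1e-9)
  expect_equal(0.42 * 0.72 * 600, 181.44)
  d <- derive_params(p)
  expect_equal(d$etr_max, 0.42 * 0.72 * 600 * (1 - exp(-1)))
  expect_equal(d$etr_max, 114.69, tolerance = 1e-4)
  expect_identical(d$i_sat_flag, "fitted-parameter")
  # unit normalisation
  oc1 <- optical_constants(1, 1)
  expect_equal(derive_params(exp_params(1, 1), oc1)$etr_max, 1 - exp(-1))
  # definitional identity: derived ETR_max equals the ETR curve at I = I_sat
  withr::with_seed(7, {
    for (i in 1:25) {
      q <- draw_exp()
      expect_equal(derive_params(q)$etr_max,
                   eval_curve(q, q$I_sat, "ETR"))
    }
  })
})

test_that("non-rectangular hyperbola evaluates, with analytic limits", {
  p <- nrh_params(0.3, 0.5, 200)
  expect_equal(eval_curve(p, 500, "ETR"), 100)
  # Blackman limit at theta = 1
  expect_equal(eval_curve(nrh_params(0.3, 1, 200), 500, "ETR"), 150)
  expect_equal(eval_curve(nrh_params(0.3, 1, 200), 5000, "ETR"), 200)
  # darkness limit of Phi is alpha_prime / (alpha * beta)
  expect_equal(eval_curve(nrh_params(0.336, 0.9, 200), 0, "PHI"), 0.8)
  # theta = 0 falls back to the rectangular hyperbola, no 0/0
  expect_equal(eval_curve(nrh_params(0.3, 0, 200), 500, "ETR"),
               0.3 * 500 * 200 / (0.3 * 500 + 200))
  d <- derive_params(p)
  expect_identical(d$i_sat_flag, "not-defined")
  expect_true(is.na(d$i_sat))
  expect_equal(d$etr_max, 200)
  # strictly below the asymptote for all finite I
  expect_true(all(eval_curve(p, seq(0, 1e5, by = 100), "ETR") < 200))
})

test_that("ETR and Phi curve kinds are linked by ETR = alpha*beta*Phi*I", {
  oc <- optical_constants()
  ab <- oc$alpha * oc$beta
  I <- c(1e-6, 25, 137, 600, 1234, 2000, 5000)
  withr::with_seed(11, {
    for (i in 1:50) {
      ye <- draw_ye()
      ye_l <- ye_params(ye$alpha_e, ye$beta_e, ye$gamma_e,
                        phi_psii_max = min(ye$alpha_e / ab, 1))
      if (ye_l$phi_psii_max == ye$alpha_e / ab) {
        expect_rel_equal(eval_curve(ye_l, I, "ETR"),
                         ab * eval_curve(ye_l, I, "PHI") * I, 1e-12)
      }
      ne <- draw_negexp()
      expect_rel_equal(eval_curve(ne, I, "ETR"),
                       ab * eval_curve(ne, I, "PHI") * I, 1e-12)
      ex <- draw_exp()
      expect_rel_equal(eval_curve(ex, I, "ETR"),
                       ab * eval_curve(ex, I, "PHI") * I, 1e-12)
      nr <- draw_nrh()
      expect_rel_equal(eval_curve(nr, I, "ETR"),
                       ab * eval_curve(nr, I, "PHI") * I, 1e-12)
    }
  })
})

test_that("monotonicity of the response curves", {
  I <- seq(0, 2000, by = 10)
  withr::with_seed(23, {
    for (i in 1:20) {
      ye <- draw_ye()
      phi <- eval_curve(ye_params(ye$alpha_e, ye$beta_e, ye$gamma_e, 0.7),
                        I, "PHI")
      expect_true(all(diff(phi) < 0))
      expect_true(all(diff(eval_curve(draw_negexp(), I, "PHI")) < 0))
      expect_true(all(diff(eval_curve(draw_exp(), I, "PHI")) < 0))
      nr_etr <- eval_curve(draw_nrh(), I, "ETR")
      expect_true(all(diff(nr_etr) > 0))          # increasing
      expect_true(all(diff(diff(nr_etr)) < 1e-9)) # concave
    }
  })
})
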