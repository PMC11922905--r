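test_that("aggregate parameters follow from the microscopic quantities", {
  mp <- microscopic_params(sigma_ik = 2, tau = 1, xi1 = 0.5, xi2 = 0.3,
                           xi3 = 0.2, k_P = 1, k_D = 1, g_ratio = 0.5,
                           N0 = 1, phi_exciton = 0.95, S = 1)
  agg <- aggregate_from_microscopic(mp)
  expect_equal(agg$alpha_e, 0.798)
  expect_equal(agg$beta_e, 1)
  expect_equal(agg$gamma_e, 3)

  # degeneracy-free symmetry: g_ratio = 0 makes the two terms equal
  mp0 <- microscopic_params(sigma_ik = 2, tau = 1, xi1 = 0.5, xi2 = 0.3,
                            xi3 = 0.2, k_P = 1, k_D = 1, g_ratio = 0,
                            N0 = 1, S = 1)
  agg0 <- aggregate_from_microscopic(mp0)
  expect_equal(agg0$beta_e, agg0$gamma_e)

  # gamma_e - beta_e = 2 * g_ratio * u > 0, for random draws
  withr::with_seed(5, {
    for (i in 1:100) {
      g <- runif(1, 0.01, 0.99)
      m <- microscopic_params(sigma_ik = runif(1, 0.5, 5),
                              tau = runif(1, 0.1, 2),
                              xi1 = runif(1), xi2 = runif(1),
                              xi3 = runif(1, 0.01, 1),
                              k_P = runif(1, 0.1, 5),
                              k_D = runif(1, 0.1, 5), g_ratio = g,
                              N0 = runif(1, 0.5, 2), S = 1)
      a <- aggregate_from_microscopic(m)
      D <- m$xi3 + (m$xi1 * m$k_P + m$xi2 * m$k_D) * m$tau
      u <- m$sigma_ik * m$tau / D
      expect_equal(a$gamma_e - a$beta_e, 2 * g * u)
      expect_gt(a$gamma_e, a$beta_e)
      expect_gt(a$beta_e, 0)
    }
  })
  expect_error(
    aggregate_from_microscopic(
      microscopic_params(sigma_ik = 1, tau = 1, xi1 = 0, xi2 = 0, xi3 = 0,
                         k_P = 1, k_D = 1, N0 = 1, S = 1)),
    class = "lrc_error_degenerate")
})

test_that("effective cross-section declines from sigma_ik to zero", {
  expect_equal(sigma_eff(3.6e-21, 1e-4, 5e-4, 0), 3.6e-21) # dark identity
  expect_equal(sigma_eff(3.6e-21, 1e-4, 5e-4, 1800), 3.6e-21 * 0.82 / 1.9)
  expect_equal(sigma_eff(3.6e-21, 1e-4, 5e-4, 1800), 1.5537e-21,
               tolerance = 1e-4)
  expect_equal(sigma_eff(2e-21, 2e-4, 7e-4, 1 / 2e-4), 0) # numerator zero
  # strictly decreasing in I
  vals <- sigma_eff(3.6e-21, 1e-4, 5e-4, seq(0, 2000, by = 50))
  expect_true(all(diff(vals) < 0))
})

test_that("Phi from the cross-section reproduces the mechanistic Phi curve", {
  expect_equal(phi_from_sigma(0.719, 3.6e-21, 3.6e-21), 0.719)
  expect_equal(phi_from_sigma(0.719, 1.5537e-21, 3.6e-21), 0.3103,
               tolerance = 1e-3)
  I <- c(0, 25, 137, 600, 1234, 2000)
  withr::with_seed(31, {
    for (i in 1:1000) {
      b <- exp(runif(1, log(5e-5), log(1e-3)))
      g <- exp(runif(1, log(1e-4), log(2e-3)))
      phimax <- runif(1, 0.3, 0.8)
      sig <- runif(1, 1e-21, 5e-21)
      p <- ye_params(0.3, b, g, phi_psii_max = phimax)
      composed <- phi_from_sigma(phimax, sigma_eff(sig, b, g, I), sig)
      expect_rel_equal(composed, eval_curve(p, I, "PHI"), 1e-12)
    }
  })
})

test_that("excited-state fraction rises from zero and saturates", {
  expect_equal(nk_fraction(1e-4, 5e-4, 0.5, 0), 0) # darkness: no excitation
  expect_equal(nk_fraction(1e-4, 5e-4, 0.5, 1800), (0.18 / 1.9) / 0.5)
  expect_equal(nk_fraction(1e-4, 5e-4, 0.5, 1800), 0.18947, tolerance = 1e-4)
  # algebraic I -> Inf limit
  expect_equal(nk_fraction(1e-4, 5e-4, 0.5, 1e12), 0.4, tolerance = 1e-6)
  vals <- nk_fraction(1e-4, 5e-4, 0.5, seq(0, 2000, by = 50))
  expect_true(all(diff(vals) > 0))          # increasing
  expect_true(all(diff(diff(vals)) < 0))    # concave
  expect_error(nk_fraction(1e-4, 5e-4, 1, 100), class = "lrc_error_domain")
})

test_that("NPQ curve has offset, saturating rise, and N_k's shape", {
  p <- npq_params(1e-3, 5e-4, 0.05)
  expect_equal(npq_curve(p, 0), 0.05)
  expect_equal(npq_curve(p, 1800), 1.8 / 1.9 + 0.05)
  expect_equal(npq_curve(p, 1800), 0.99737, tolerance = 1e-4)
  expect_equal(npq_curve(p, 1e12), 1e-3 / 5e-4 + 0.05, tolerance = 1e-6)
  # identical saturating shape as N_k up to an affine map
  I <- seq(0, 2000, by = 100)
  nk <- nk_fraction(2e-4, 5e-4, 0.5, I)
  npq <- npq_curve(npq_params(A = 2e-4 / 0.5, b = 5e-4, NPQ0 = 0.3), I)
  expect_rel_equal(npq, nk + 0.3, 1e-12)
})

test_that("cross-section from the fitted initial slope inverts the aggregate", {
  expect_equal(sigma_ik_from_alpha_e(0.3, N0 = 1.25e17),
               0.3 * 6e-4 / (0.42 * 0.95 * 1.25e17))
  expect_equal(sigma_ik_from_alpha_e(0.3, N0 = 1.25e17), 3.609e-21,
               tolerance = 1e-3)
  # doubling N0 halves sigma_ik
  expect_equal(sigma_ik_from_alpha_e(0.3, N0 = 2.5e17),
               sigma_ik_from_alpha_e(0.3, N0 = 1.25e17) / 2)
  # round trip through the aggregate map
  mp <- microscopic_params(sigma_ik = 3.6e-21, tau = 1e-3, xi1 = 0.4,
                           xi2 = 0.3, xi3 = 0.3, k_P = 100, k_D = 50,
                           g_ratio = 0.4, N0 = 1.25e17, phi_exciton = 0.95,
                           S = 6e-4)
  agg <- aggregate_from_microscopic(mp)
  expect_equal(sigma_ik_from_alpha_e(agg$alpha_e, phi_exciton = 0.95,
                                     S = 6e-4, N0 = 1.25e17),
               3.6e-21)
  expect_error(sigma_ik_from_alpha_e(0.3), class = "lrc_error_domain")
})
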