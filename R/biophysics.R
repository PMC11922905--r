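#' Microscopic pigment-level parameters
#'
#' Physical quantities of the light-harvesting pigment pool underlying the
#' mechanistic light-response model. The aggregate curve parameters are
#' algebraic combinations of these (see
#' [aggregate_from_microscopic()]).
#'
#' @param sigma_ik Eigen-absorption cross-section of a pigment molecule,
#'   m^2 (ground state i to excited state k).
#' @param tau Mean lifetime of the lowest excited state, s.
#' @param xi1,xi2,xi3 Occupation probabilities of photochemistry, heat loss,
#'   and fluorescence emission (dimensionless, >= 0).
#' @param k_P,k_D Rate constants of the photochemical reaction and of heat
#'   loss, s^-1.
#' @param g_ratio Degeneracy ratio `g_i / g_k` of the ground and excited
#'   energy levels, in \[0, 1).
#' @param N0 Total number (or amount) of light-harvesting pigment molecules
#'   in the measured leaf. The unit convention (count vs mol) is the
#'   caller's and is carried in `n0_unit`, never converted implicitly.
#' @param phi_exciton Exciton-use efficiency of PSII, in (0, 1\].
#'   Default 0.95.
#' @param S Leaf area, m^2. Default 6e-4.
#' @param R_ki Optional radiative k->i rate; recorded for completeness but
#'   used in no computation.
#' @param n0_unit Character tag recording the unit convention of `N0`.
#'
#' @return An object of class `microscopic_params`.
#' @examples
#' mp <- microscopic_params(sigma_ik = 2, tau = 1, xi1 = 0.5, xi2 = 0.3,
#'                          xi3 = 0.2, k_P = 1, k_D = 1, g_ratio = 0.5,
#'                          N0 = 1, S = 1)
#' aggregate_from_microscopic(mp)
#' @export
microscopic_params <- function(sigma_ik, tau, xi1, xi2, xi3, k_P, k_D,
                               g_ratio = 0.5, N0, phi_exciton = 0.95,
                               S = 6e-4, R_ki = NULL, n0_unit = "molecules") {
  for (nm in c("sigma_ik", "tau", "k_P", "k_D", "N0", "phi_exciton", "S")) {
    .check_scalar_pos(get(nm), nm)
  }
  for (nm in c("xi1", "xi2", "xi3")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0) {
      rlang::abort(paste0("`", nm, "` must be a single non-negative number."),
                   class = "lrc_error_domain")
    }
  }
  if (!is.numeric(g_ratio) || length(g_ratio) != 1L || !is.finite(g_ratio) ||
      g_ratio < 0 || g_ratio >= 1) {
    rlang::abort("`g_ratio` must lie in [0, 1) so that 1 - g_i/g_k > 0.",
                 class = "lrc_error_domain")
  }
  if (phi_exciton > 1) {
    rlang::abort("`phi_exciton` must lie in (0, 1].",
                 class = "lrc_error_domain")
  }
  structure(list(sigma_ik = sigma_ik, tau = tau, xi1 = xi1, xi2 = xi2,
                 xi3 = xi3, k_P = k_P, k_D = k_D, g_ratio = g_ratio,
                 N0 = N0, phi_exciton = phi_exciton, S = S, R_ki = R_ki,
                 n0_unit = n0_unit),
            class = "microscopic_params")
}

#' Aggregate curve parameters from microscopic quantities
#'
#' Collapses the pigment-level parameters into the three aggregate
#' parameters of the mechanistic ETR-I curve. With
#' `D = xi3 + (xi1 * k_P + xi2 * k_D) * tau` and
#' `u = sigma_ik * tau / D`:
#'
#' * `alpha_e = alpha * beta * N0 * sigma_ik * phi_exciton / S`
#' * `beta_e  = (1 - g_ratio) * u`
#' * `gamma_e = (1 + g_ratio) * u`
#'
#' so `gamma_e - beta_e = 2 * g_ratio * u > 0` whenever `g_ratio > 0`, and
#' `beta_e == gamma_e` in the degeneracy-free case `g_ratio = 0`.
#'
#' @param micro A [microscopic_params()] object.
#' @param consts An [optical_constants()] object.
#' @return A [ye_params()] object (ETR-side parameters; `phi_psii_max` is
#'   left unset because `alpha_e / (alpha * beta)` need not lie in (0, 1\]
#'   for arbitrary microscopic inputs).
#' @export
aggregate_from_microscopic <- function(micro, consts = optical_constants()) {
  stopifnot(inherits(micro, "microscopic_params"))
  D <- micro$xi3 + (micro$xi1 * micro$k_P + micro$xi2 * micro$k_D) * micro$tau
  if (D == 0) {
    rlang::abort(
      "Degenerate parameters: xi3 + (xi1*k_P + xi2*k_D)*tau must be > 0.",
      class = "lrc_error_degenerate")
  }
  u <- micro$sigma_ik * micro$tau / D
  alpha_e <- consts$alpha * consts$beta * micro$N0 * micro$sigma_ik *
    micro$phi_exciton / micro$S
  ye_params(alpha_e = alpha_e,
            beta_e = (1 - micro$g_ratio) * u,
            gamma_e = (1 + micro$g_ratio) * u)
}

#' Effective absorption cross-section as a function of light
#'
#' `sigma_ik' = sigma_ik * (1 - beta_e * I) / (1 + gamma_e * I)`: the
#' light-dependent effective absorption cross-section of light-harvesting
#' pigment molecules. Equals `sigma_ik` in darkness and decreases strictly
#' with `I`, crossing zero at `I = 1 / beta_e`.
#'
#' @param sigma_ik Eigen-absorption cross-section, m^2.
#' @param beta_e,gamma_e Aggregate down-regulation and saturation terms.
#' @param I Light intensities, micromol photons m^-2 s^-1, >= 0.
#' @return Numeric vector of effective cross-sections, m^2.
#' @examples
#' sigma_eff(3.6e-21, 1e-4, 5e-4, c(0, 1800))
#' @export
sigma_eff <- function(sigma_ik, beta_e, gamma_e, I) {
  .check_scalar_pos(sigma_ik, "sigma_ik")
  .check_nonneg_light(I)
  sigma_ik * (1 - beta_e * I) / (1 + gamma_e * I)
}

#' Effective quantum efficiency from the effective cross-section
#'
#' `Phi_PSII = phi_psii_max * sigma_eff_value / sigma_ik`: the effective
#' quantum efficiency is directly proportional to the effective absorption
#' cross-section. Composing this with [sigma_eff()] reproduces the
#' mechanistic Phi-I curve pointwise.
#'
#' @param phi_psii_max Maximum effective quantum efficiency.
#' @param sigma_eff_value Effective cross-section(s), m^2.
#' @param sigma_ik Eigen cross-section, m^2, > 0.
#' @return Numeric vector of Phi_PSII values.
#' @export
phi_from_sigma <- function(phi_psii_max, sigma_eff_value, sigma_ik) {
  .check_scalar_pos(sigma_ik, "sigma_ik")
  phi_psii_max * sigma_eff_value / sigma_ik
}

#' Excited-state pigment fraction as a function of light
#'
#' `N_k / N0 = (1 / (1 - g_ratio)) * beta_e * I / (1 + gamma_e * I)`: the
#' fraction of light-harvesting pigment molecules in the excited state.
#' Zero in darkness, strictly increasing and concave in `I`, saturating at
#' `beta_e / (gamma_e * (1 - g_ratio))`.
#'
#' @inheritParams sigma_eff
#' @param g_ratio Degeneracy ratio `g_i / g_k`, in \[0, 1).
#' @return Numeric vector of excited-state fractions.
#' @examples
#' nk_fraction(1e-4, 5e-4, 0.5, 1800)
#' @export
nk_fraction <- function(beta_e, gamma_e, g_ratio, I) {
  if (!is.numeric(g_ratio) || length(g_ratio) != 1L || !is.finite(g_ratio) ||
      g_ratio < 0 || g_ratio >= 1) {
    rlang::abort("`g_ratio` must lie in [0, 1).", class = "lrc_error_domain")
  }
  .check_nonneg_light(I)
  (1 / (1 - g_ratio)) * beta_e * I / (1 + gamma_e * I)
}

#' Non-photochemical quenching light-response curve
#'
#' Saturating NPQ-I curve `NPQ = A * I / (1 + b * I) + NPQ0` inherited from
#' the excited-state pigment dynamics: the amplitude and initial slope enter
#' only as the lumped product `A` (they are not separately identifiable from
#' an NPQ-I fit), `b` plays the role of the saturation term `gamma_e`, and
#' `NPQ0` is the dark-adapted offset.
#'
#' @param A Lumped amplitude, >= 0, per unit light intensity.
#' @param b Saturation term, m^2 s per micromol photons, > 0.
#' @param NPQ0 Dark-adapted NPQ offset, >= 0.
#' @param params An `npq_params` object.
#' @param I Light intensities, >= 0.
#' @return `npq_params()` returns a parameter object; `npq_curve()` the NPQ
#'   values at `I`.
#' @examples
#' npq_curve(npq_params(1e-3, 5e-4, 0.05), I = c(0, 1800))
#' @export
npq_params <- function(A, b, NPQ0) {
  if (!is.numeric(A) || length(A) != 1L || !is.finite(A) || A < 0) {
    rlang::abort("`A` must be a single non-negative number.",
                 class = "lrc_error_domain")
  }
  .check_scalar_pos(b, "b")
  if (!is.numeric(NPQ0) || length(NPQ0) != 1L || !is.finite(NPQ0) || NPQ0 < 0) {
    rlang::abort("`NPQ0` must be a single non-negative number.",
                 class = "lrc_error_domain")
  }
  .new_params(list(A = A, b = b, NPQ0 = NPQ0), "npq_params")
}

#' @rdname npq_params
#' @export
npq_curve <- function(params, I) {
  stopifnot(inherits(params, "npq_params"))
  .check_nonneg_light(I)
  params$A * I / (1 + params$b * I) + params$NPQ0
}

#' Eigen-absorption cross-section from the fitted initial slope
#'
#' Inverts `alpha_e = alpha * beta * N0 * sigma_ik * phi_exciton / S` to
#' estimate the eigen-absorption cross-section from a fitted ETR-I initial
#' slope: `sigma_ik = alpha_e * S / (alpha * beta * phi_exciton * N0)`.
#' `N0` must be supplied by the caller (typically estimated from measured
#' chlorophyll content); its unit convention determines the unit of the
#' result and is never converted implicitly.
#'
#' @param alpha_e Fitted initial slope of the ETR-I curve.
#' @param consts An [optical_constants()] object.
#' @param phi_exciton Exciton-use efficiency, default 0.95.
#' @param S Leaf area, m^2, default 6e-4.
#' @param N0 Total light-harvesting pigment molecules.
#' @return Eigen-absorption cross-section, m^2 (per the `N0` convention).
#' @examples
#' sigma_ik_from_alpha_e(0.3, N0 = 1.25e17) # ~3.6e-21 m^2
#' @export
sigma_ik_from_alpha_e <- function(alpha_e, consts = optical_constants(),
                                  phi_exciton = 0.95, S = 6e-4, N0) {
  if (missing(N0) || is.null(N0)) {
    rlang::abort("`N0` is required to convert the initial slope to a cross-section.",
                 class = "lrc_error_domain")
  }
  .check_scalar_pos(alpha_e, "alpha_e")
  .check_scalar_pos(phi_exciton, "phi_exciton")
  .check_scalar_pos(S, "S")
  .check_scalar_pos(N0, "N0")
  alpha_e * S / (consts$alpha * consts$beta * phi_exciton * N0)
}
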