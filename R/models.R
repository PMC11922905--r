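#' Light-response model parameter objects
#'
#' Constructors for the four light-response model families. Each validates
#' the physical admissibility of its parameters and returns a classed list
#' usable with [eval_curve()] and [derive_params()].
#'
#' * `ye_params()` - the mechanistic pigment-based model. ETR-I:
#'   `ETR = alpha_e * I * (1 - beta_e * I) / (1 + gamma_e * I)`; Phi-I:
#'   `Phi = phi_psii_max * (1 - beta_e * I) / (1 + gamma_e * I)`.
#'   `alpha_e` is the initial slope of the ETR-I curve
#'   (micromol electrons per micromol photons), `beta_e` the dynamic
#'   down-regulation term and `gamma_e` the saturation term (both
#'   m^2 s per micromol photons). When the two curve kinds are linked,
#'   `phi_psii_max = alpha_e / (alpha * beta)`.
#' * `negexp_params()` - negative exponential:
#'   `Phi = phi_psii_max * exp(-k_w * I)`.
#' * `exp_params()` - exponential:
#'   `Phi = fv_fm * (I_sat / I) * (1 - exp(-I / I_sat))`.
#' * `nrh_params()` - non-rectangular hyperbola for ETR with initial slope
#'   `alpha_prime`, curvature `theta` in (0, 1], and asymptote `etr_max`.
#'
#' @param alpha_e,beta_e,gamma_e Ye aggregate parameters (see above).
#' @param phi_psii_max Maximum effective quantum efficiency in (0, 1];
#'   optional for `ye_params` (required only to evaluate the Phi-I kind).
#' @param k_w Scaling constant of the negative exponential,
#'   (micromol photons m^-2 s^-1)^-1.
#' @param fv_fm Dark-adapted maximum PSII efficiency in (0, 1].
#' @param I_sat Saturation light intensity, micromol photons m^-2 s^-1.
#' @param alpha_prime Initial slope of the ETR-I curve.
#' @param theta Curvature, in (0, 1] (0 accepted as the rectangular limit).
#' @param etr_max Maximum electron transport rate,
#'   micromol electrons m^-2 s^-1.
#'
#' @return A classed list (`ye_params`, `negexp_params`, `exp_params` or
#'   `nrh_params`, all inheriting from `lrc_params`).
#' @examples
#' p <- ye_params(0.3, 1e-4, 5e-4)
#' eval_curve(p, I = 1000, kind = "ETR") # 180
#' derive_params(p)
#' @name lrc_params
NULL

.new_params <- function(fields, subclass) {
  structure(fields, class = c(subclass, "lrc_params"))
}

#' @rdname lrc_params
#' @export
ye_params <- function(alpha_e, beta_e, gamma_e, phi_psii_max = NULL) {
  .check_scalar_pos(alpha_e, "alpha_e")
  .check_scalar_pos(gamma_e, "gamma_e")
  if (!is.numeric(beta_e) || length(beta_e) != 1L || !is.finite(beta_e) ||
      beta_e < 0) {
    rlang::abort("`beta_e` must be a single non-negative number.",
                 class = "lrc_error_domain")
  }
  if (!is.null(phi_psii_max)) {
    if (!is.numeric(phi_psii_max) || length(phi_psii_max) != 1L ||
        !is.finite(phi_psii_max) || phi_psii_max <= 0 || phi_psii_max > 1) {
      rlang::abort("`phi_psii_max` must lie in (0, 1].",
                   class = "lrc_error_domain")
    }
  }
  .new_params(list(alpha_e = alpha_e, beta_e = beta_e, gamma_e = gamma_e,
                   phi_psii_max = phi_psii_max), "ye_params")
}

#' @rdname lrc_params
#' @export
negexp_params <- function(phi_psii_max, k_w) {
  if (!is.numeric(phi_psii_max) || length(phi_psii_max) != 1L ||
      !is.finite(phi_psii_max) || phi_psii_max <= 0 || phi_psii_max > 1) {
    rlang::abort("`phi_psii_max` must lie in (0, 1].",
                 class = "lrc_error_domain")
  }
  .check_scalar_pos(k_w, "k_w")
  .new_params(list(phi_psii_max = phi_psii_max, k_w = k_w), "negexp_params")
}

#' @rdname lrc_params
#' @export
exp_params <- function(fv_fm, I_sat) {
  if (!is.numeric(fv_fm) || length(fv_fm) != 1L || !is.finite(fv_fm) ||
      fv_fm <= 0 || fv_fm > 1) {
    rlang::abort("`fv_fm` must lie in (0, 1].", class = "lrc_error_domain")
  }
  .check_scalar_pos(I_sat, "I_sat")
  .new_params(list(fv_fm = fv_fm, I_sat = I_sat), "exp_params")
}

#' @rdname lrc_params
#' @export
nrh_params <- function(alpha_prime, theta, etr_max) {
  .check_scalar_pos(alpha_prime, "alpha_prime")
  .check_scalar_pos(etr_max, "etr_max")
  if (!is.numeric(theta) || length(theta) != 1L || !is.finite(theta) ||
      theta < 0 || theta > 1) {
    rlang::abort("`theta` must lie in [0, 1].", class = "lrc_error_domain")
  }
  .new_params(list(alpha_prime = alpha_prime, theta = theta,
                   etr_max = etr_max), "nrh_params")
}

#' @export
print.lrc_params <- function(x, ...) {
  cat("<", class(x)[1], ">\n", sep = "")
  vals <- unlist(Filter(Negate(is.null), unclass(x)))
  for (nm in names(vals)) cat(" ", nm, "=", format(vals[nm]), "\n")
  invisible(x)
}

# Fast internal curve evaluators ---------------------------------------------
# Closures over a plain named parameter vector; used both by eval_curve()
# and by the fitting objective (no S3 dispatch in the hot loop).

.curve_fun <- function(model, kind, consts) {
  ab <- consts$alpha * consts$beta
  switch(
    paste(model, kind, sep = "."),
    "ye.ETR" = function(p, I) p[["alpha_e"]] * I * (1 - p[["beta_e"]] * I) /
      (1 + p[["gamma_e"]] * I),
    "ye.PHI" = function(p, I) p[["phi_psii_max"]] * (1 - p[["beta_e"]] * I) /
      (1 + p[["gamma_e"]] * I),
    "negexp.PHI" = function(p, I) p[["phi_psii_max"]] * exp(-p[["k_w"]] * I),
    "negexp.ETR" = function(p, I) ab * I * p[["phi_psii_max"]] *
      exp(-p[["k_w"]] * I),
    "exp.PHI" = function(p, I) {
      out <- rep(p[["fv_fm"]], length(I))
      pos <- I > 0
      out[pos] <- p[["fv_fm"]] * (p[["I_sat"]] / I[pos]) *
        (1 - exp(-I[pos] / p[["I_sat"]]))
      out
    },
    "exp.ETR" = function(p, I) ab * p[["fv_fm"]] * p[["I_sat"]] *
      (1 - exp(-I / p[["I_sat"]])),
    "nrh.ETR" = function(p, I) {
      a <- p[["alpha_prime"]]; th <- p[["theta"]]; em <- p[["etr_max"]]
      if (th <= 0) return(a * I * em / (a * I + em))
      s <- a * I + em
      disc <- pmax(s^2 - 4 * th * a * I * em, 0)
      (s - sqrt(disc)) / (2 * th)
    },
    "nrh.PHI" = function(p, I) {
      a <- p[["alpha_prime"]]; th <- p[["theta"]]; em <- p[["etr_max"]]
      out <- rep(a / ab, length(I))
      pos <- I > 0
      if (any(pos)) {
        Ip <- I[pos]
        etr <- if (th <= 0) a * Ip * em / (a * Ip + em) else {
          s <- a * Ip + em
          (s - sqrt(pmax(s^2 - 4 * th * a * Ip * em, 0))) / (2 * th)
        }
        out[pos] <- etr / (ab * Ip)
      }
      out
    },
    "npq.NPQ" = function(p, I) p[["A"]] * I / (1 + p[["b"]] * I) + p[["NPQ0"]],
    rlang::abort(paste0("No curve defined for model '", model,
                        "' and kind '", kind, "'."),
                 class = "lrc_error_domain")
  )
}

.param_vector <- function(params) {
  unlist(Filter(Negate(is.null), unclass(params)))
}

.model_name <- function(params) {
  sub("_params$", "", class(params)[1])
}

#' Evaluate a light-response curve
#'
#' Evaluates a fitted or hypothesised model at a vector of light
#' intensities, for either response kind: electron transport rate (`"ETR"`,
#' micromol electrons m^-2 s^-1) or effective quantum efficiency (`"PHI"`).
#' Singularities at `I = 0` (the exponential model's `I` in a denominator
#' and the hyperbola's division by `I`) are resolved by their analytic
#' limits. Ye-model values beyond `I = 1 / beta_e` are negative and are
#' returned as-is: the declining branch carries the photoinhibition signal.
#'
#' @param object An `lrc_params` object ([ye_params()], [negexp_params()],
#'   [exp_params()], [nrh_params()] or [npq_params()]).
#' @param I Light intensities, micromol photons m^-2 s^-1, >= 0.
#' @param kind Response kind: `"ETR"`, `"PHI"`, or `"NPQ"` (the latter only
#'   for [npq_params()]).
#' @param consts An [optical_constants()] object.
#' @param ... Unused.
#' @return Numeric vector of responses, same length as `I`.
#' @examples
#' eval_curve(negexp_params(0.7, 1 / 1600), I = c(0, 1600), kind = "PHI")
#' @export
eval_curve <- function(object, I, kind = c("ETR", "PHI", "NPQ"),
                       consts = optical_constants(), ...) {
  UseMethod("eval_curve")
}

#' @export
eval_curve.lrc_params <- function(object, I, kind = c("ETR", "PHI", "NPQ"),
                                  consts = optical_constants(), ...) {
  kind <- match.arg(kind)
  .check_nonneg_light(I)
  model <- .model_name(object)
  if (model == "ye" && kind == "PHI" && is.null(object$phi_psii_max)) {
    rlang::abort("`phi_psii_max` must be set to evaluate the Phi-I kind.",
                 class = "lrc_error_domain")
  }
  f <- .curve_fun(model, kind, consts)
  f(.param_vector(object), I)
}

#' Closed-form derived light-response quantities
#'
#' Computes the saturation light intensity `I_sat` (the argmax of the ETR-I
#' curve) and the maximum electron transport rate `ETR_max` from fitted
#' model parameters, using each model's closed form:
#'
#' * Ye: `I_sat = (sqrt((beta_e + gamma_e) / beta_e) - 1) / gamma_e`,
#'   `ETR_max = alpha_e * ((sqrt(beta_e + gamma_e) - sqrt(beta_e)) / gamma_e)^2`.
#'   When `beta_e = 0` the curve rises monotonically: `I_sat` is flagged
#'   not-finite and `ETR_max` is the supremum `alpha_e / gamma_e`.
#' * Negative exponential: `I_sat = 1 / k_w`,
#'   `ETR_max = alpha * beta * I_sat * phi_psii_max * exp(-1)`.
#' * Exponential: `I_sat` is the fitted parameter itself;
#'   `ETR_max = alpha * beta * fv_fm * I_sat * (1 - exp(-1))`, i.e. the ETR
#'   curve evaluated at `I = I_sat`, not its asymptote.
#' * Non-rectangular hyperbola: `ETR_max` is the fitted asymptote; the ETR
#'   derivative is everywhere positive so `I_sat` is not defined by this
#'   model and is flagged.
#'
#' @inheritParams eval_curve
#' @return A tibble with one row: columns `i_sat`, `etr_max`, `i_sat_flag`,
#'   `etr_max_flag` (`NA` flag = a regular finite value).
#' @examples
#' derive_params(ye_params(0.3, 1e-4, 5e-4))
#' derive_params(nrh_params(0.3, 0.5, 200)) # I_sat flagged not-defined
#' @export
derive_params <- function(object, consts = optical_constants(), ...) {
  UseMethod("derive_params")
}

.derived_row <- function(i_sat, etr_max, i_sat_flag = NA_character_,
                         etr_max_flag = NA_character_) {
  tibble::tibble(i_sat = i_sat, etr_max = etr_max,
                 i_sat_flag = i_sat_flag, etr_max_flag = etr_max_flag)
}

#' @export
derive_params.ye_params <- function(object, consts = optical_constants(), ...) {
  a <- object$alpha_e; b <- object$beta_e; g <- object$gamma_e
  if (b == 0) {
    return(.derived_row(Inf, a / g, i_sat_flag = "not-finite",
                        etr_max_flag = "supremum"))
  }
  i_sat <- (sqrt((b + g) / b) - 1) / g
  etr_max <- a * ((sqrt(b + g) - sqrt(b)) / g)^2
  .derived_row(i_sat, etr_max)
}

#' @export
derive_params.negexp_params <- function(object, consts = optical_constants(),
                                        ...) {
  i_sat <- 1 / object$k_w
  etr_max <- consts$alpha * consts$beta * i_sat * object$phi_psii_max * exp(-1)
  .derived_row(i_sat, etr_max)
}

#' @export
derive_params.exp_params <- function(object, consts = optical_constants(), ...) {
  etr_max <- consts$alpha * consts$beta * object$fv_fm * object$I_sat *
    (1 - exp(-1))
  # ETR_max here equals the ETR curve at I = I_sat, not the asymptote
  # alpha*beta*fv_fm*I_sat that the curve approaches as I grows.
  .derived_row(object$I_sat, etr_max, i_sat_flag = "fitted-parameter",
               etr_max_flag = "value-at-I-sat")
}

#' @export
derive_params.nrh_params <- function(object, consts = optical_constants(), ...) {
  .derived_row(NA_real_, object$etr_max, i_sat_flag = "not-defined")
}

# Free-parameter counts per model and response kind.
.n_free_params <- function(model, kind) {
  switch(model,
         ye = 3L,
         negexp = 2L,
         exp = 2L,
         nrh = 3L,
         npq = 3L,
         rlang::abort(paste0("Unknown model '", model, "'."),
                      class = "lrc_error_domain"))
}

.param_names <- function(model, kind) {
  switch(paste(model, kind, sep = "."),
         "ye.ETR" = c("alpha_e", "beta_e", "gamma_e"),
         "ye.PHI" = c("phi_psii_max", "beta_e", "gamma_e"),
         "negexp.ETR" = ,
         "negexp.PHI" = c("phi_psii_max", "k_w"),
         "exp.ETR" = ,
         "exp.PHI" = c("fv_fm", "I_sat"),
         "nrh.ETR" = ,
         "nrh.PHI" = c("alpha_prime", "theta", "etr_max"),
         "npq.NPQ" = c("A", "b", "NPQ0"),
         rlang::abort(paste0("No parameterisation for model '", model,
                             "' and kind '", kind, "'."),
                      class = "lrc_error_domain"))
}

.params_from_vector <- function(model, kind, p, consts = optical_constants()) {
  switch(model,
         ye = if (kind == "ETR") {
           ye_params(p[["alpha_e"]], p[["beta_e"]], p[["gamma_e"]])
         } else {
           # Phi-I fits do not constrain alpha_e; store the linked value
           # alpha_e = alpha*beta*phi_psii_max so derived quantities remain
           # computable (the two curve kinds share this identity).
           ye_params(alpha_e = consts$alpha * consts$beta * p[["phi_psii_max"]],
                     beta_e = p[["beta_e"]],
                     gamma_e = p[["gamma_e"]],
                     phi_psii_max = p[["phi_psii_max"]])
         },
         negexp = negexp_params(p[["phi_psii_max"]], p[["k_w"]]),
         exp = exp_params(p[["fv_fm"]], p[["I_sat"]]),
         nrh = nrh_params(p[["alpha_prime"]], p[["theta"]], p[["etr_max"]]),
         npq = npq_params(p[["A"]], p[["b"]], p[["NPQ0"]]))
}
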