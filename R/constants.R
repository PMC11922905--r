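#' Optical constants for ETR computation
#'
#' The electron transport rate is computed as `ETR = alpha * beta * Phi_PSII * I`,
#' where `alpha` is the distribution coefficient of absorbed light energy
#' between PSII and PSI and `beta` is the leaf absorptance. Both are
#' assumptions of the measurement, not fitted quantities, so they are carried
#' explicitly and injected into every computation that needs them.
#'
#' @param alpha PSII/PSI light-distribution coefficient, dimensionless in
#'   (0, 1]. Default 0.5.
#' @param beta Leaf absorptance, dimensionless in (0, 1]. Default 0.84.
#'
#' @return An object of class `optical_constants`: a list with elements
#'   `alpha` and `beta`.
#' @examples
#' oc <- optical_constants()
#' oc$alpha * oc$beta # 0.42, the ETR conversion factor per unit Phi_PSII * I
#' @export
optical_constants <- function(alpha = 0.5, beta = 0.84) {
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) ||
      alpha <= 0 || alpha > 1) {
    rlang::abort("`alpha` must be a single number in (0, 1].",
                 class = "lrc_error_domain")
  }
  if (!is.numeric(beta) || length(beta) != 1L || !is.finite(beta) ||
      beta <= 0 || beta > 1) {
    rlang::abort("`beta` must be a single number in (0, 1].",
                 class = "lrc_error_domain")
  }
  structure(list(alpha = alpha, beta = beta), class = "optical_constants")
}

#' @export
print.optical_constants <- function(x, ...) {
  cat("<optical_constants> alpha =", x$alpha, ", beta =", x$beta, "\n")
  invisible(x)
}

# Internal: light intensities of the 16-step measurement protocol,
# micromol photons m^-2 s^-1.
.protocol_grid <- c(0, 25, 50, 100, 200, 300, 400, 600, 800, 1000,
                    1200, 1400, 1600, 1800, 1900, 2000)

#' The 16-step light protocol grid
#'
#' Incident light intensities (micromol photons m^-2 s^-1) of the standard
#' light-curve protocol used throughout the package: 16 steps from darkness
#' to 2000 micromol photons m^-2 s^-1.
#'
#' @return Numeric vector of length 16.
#' @export
protocol_grid <- function() .protocol_grid

# Internal input checks ------------------------------------------------------

.check_nonneg_light <- function(I, arg = "I") {
  if (!is.numeric(I) || anyNA(I) || any(I < 0)) {
    rlang::abort(paste0("`", arg, "` must be non-negative light intensities."),
                 class = "lrc_error_domain")
  }
  invisible(I)
}

.check_scalar_pos <- function(x, arg) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    rlang::abort(paste0("`", arg, "` must be a single positive number."),
                 class = "lrc_error_domain")
  }
  invisible(x)
}
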