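#' Synthetic light-curve truths
#'
#' Describes a generating model for synthetic light-curve data: a parameter
#' object, the response kind, the light grid, the replicate count, the noise
#' model and a mandatory seed. [generate_synthetic()] turns it into data.
#'
#' The default truths (one per model family) are the package's study
#' conditions: a mechanistic ETR-I truth whose noiseless curve peaks at
#' I = 1600 micromol photons m^-2 s^-1 with ETR_max about 195.5 micromol
#' electrons m^-2 s^-1 and Phi_PSIImax about 0.706 (a C3-crop-like leaf
#' with mild photoinhibition inside the measured range), and empirical-model
#' truths of matching magnitude. See `default_truth_params()`.
#'
#' @param params An `lrc_params` object (the generating truth).
#' @param kind Response kind the data record: `"ETR"`, `"PHI"` or `"NPQ"`.
#' @param noise_sd Gaussian noise standard deviation. Interpreted per
#'   `noise_type`. Default 0.02 (2 percent of the curve maximum).
#' @param noise_type `"relative"`: `noise_sd` is a fraction of the maximum
#'   absolute curve value; `"absolute"`: `noise_sd` is in response units.
#' @param grid Light intensities, default the 16-step [protocol_grid()].
#' @param n_reps Number of replicate leaves, default 5.
#' @param seed Integer seed (required); every source of randomness flows
#'   from it.
#' @return An object of class `synthetic_truth`.
#' @examples
#' tr <- synthetic_truth(default_truth_params("ye"), kind = "ETR", seed = 1)
#' curves <- generate_synthetic(tr)
#' @export
synthetic_truth <- function(params, kind = c("ETR", "PHI", "NPQ"),
                            noise_sd = 0.02,
                            noise_type = c("relative", "absolute"),
                            grid = protocol_grid(), n_reps = 5L, seed) {
  kind <- match.arg(kind)
  noise_type <- match.arg(noise_type)
  stopifnot(inherits(params, "lrc_params"))
  if (missing(seed) || is.null(seed)) {
    rlang::abort("`seed` is mandatory for synthetic data.",
                 class = "lrc_error_domain")
  }
  .check_nonneg_light(grid, "grid")
  if (length(grid) == 0L) {
    rlang::abort("`grid` must be non-empty.", class = "lrc_error_domain")
  }
  if (!is.numeric(noise_sd) || noise_sd < 0) {
    rlang::abort("`noise_sd` must be >= 0.", class = "lrc_error_domain")
  }
  structure(list(params = params, model = .model_name(params), kind = kind,
                 noise_sd = noise_sd, noise_type = noise_type,
                 grid = as.numeric(grid), n_reps = as.integer(n_reps),
                 seed = as.integer(seed)),
            class = "synthetic_truth")
}

#' @rdname synthetic_truth
#' @param model One of `"ye"`, `"negexp"`, `"exp"`, `"nrh"`, `"npq"`.
#' @export
default_truth_params <- function(model = c("ye", "negexp", "exp", "nrh",
                                           "npq")) {
  model <- match.arg(model)
  switch(model,
         ye = ye_params(alpha_e = 0.29652, beta_e = 2.5754e-4,
                        gamma_e = 2.6673e-4, phi_psii_max = 0.706),
         negexp = negexp_params(phi_psii_max = 0.7, k_w = 1 / 1600),
         exp = exp_params(fv_fm = 0.72, I_sat = 600),
         nrh = nrh_params(alpha_prime = 0.3, theta = 0.7, etr_max = 200),
         npq = npq_params(A = 1e-3, b = 5e-4, NPQ0 = 0.05))
}

# Deterministic per-replicate seed stream: a counter-based split of the
# user seed so each replicate's noise depends only on (seed, replicate).
.split_seed <- function(seed, r) {
  (as.integer(seed) %% 2147483647L + 104729L * as.integer(r)) %% 2147483647L
}

#' Generate synthetic light curves
#'
#' Evaluates the truth's model on its light grid and adds i.i.d. Gaussian
#' noise, independently seeded per replicate, producing the long
#' light-curve table used by the fitting functions. With `noise_sd = 0` all
#' replicates are identical to the noiseless curve. The truth and constants
#' are recorded in attributes, sufficient to regenerate the data
#' bit-identically.
#'
#' @param truth A [synthetic_truth()] object.
#' @param consts An [optical_constants()] object.
#' @return A tibble with columns `replicate_id`, `I`, `quantity`, `value`;
#'   attributes `truth`, `consts`, `provenance = "synthetic"`.
#' @export
generate_synthetic <- function(truth, consts = optical_constants()) {
  stopifnot(inherits(truth, "synthetic_truth"))
  f <- .curve_fun(truth$model, truth$kind, consts)
  p <- .param_vector(truth$params)
  mu <- f(p, truth$grid)
  sd_abs <- switch(truth$noise_type,
                   relative = truth$noise_sd * max(abs(mu)),
                   absolute = truth$noise_sd)
  out <- purrr::map_dfr(seq_len(truth$n_reps), function(r) {
    noise <- if (sd_abs > 0) {
      withr::with_seed(.split_seed(truth$seed, r),
                       stats::rnorm(length(mu), sd = sd_abs))
    } else {
      rep(0, length(mu))
    }
    tibble::tibble(replicate_id = sprintf("rep%d", r),
                   I = truth$grid, quantity = truth$kind,
                   value = mu + noise)
  })
  attr(out, "truth") <- truth
  attr(out, "consts") <- consts
  attr(out, "provenance") <- "synthetic"
  out
}
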