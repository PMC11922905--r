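#' Simulated-annealing schedule
#'
#' Controls the global search stage of [fit_light_curve()]: geometric
#' cooling with Metropolis acceptance. The initial temperature defaults to
#' the inter-quartile range of the SSR values of the multistart draws
#' (set `t_init` to override), and the chain stops once the temperature
#' falls below `t_init * t_min_ratio`.
#'
#' @param t_init Initial temperature in SSR units, or `NULL` for the
#'   IQR-of-starts default.
#' @param cooling Geometric cooling factor in (0, 1). Default 0.92.
#' @param n_iter Metropolis iterations per temperature level. Default 60.
#' @param t_min_ratio Stop when `T < t_init * t_min_ratio`. Default 1e-4.
#' @return An object of class `sa_schedule`.
#' @export
sa_schedule <- function(t_init = NULL, cooling = 0.92, n_iter = 60L,
                        t_min_ratio = 1e-4) {
  if (!is.null(t_init)) .check_scalar_pos(t_init, "t_init")
  if (!is.numeric(cooling) || length(cooling) != 1L || cooling <= 0 ||
      cooling >= 1) {
    rlang::abort("`cooling` must lie in (0, 1).", class = "lrc_error_domain")
  }
  if (!is.numeric(n_iter) || n_iter < 1) {
    rlang::abort("`n_iter` must be >= 1.", class = "lrc_error_domain")
  }
  .check_scalar_pos(t_min_ratio, "t_min_ratio")
  structure(list(t_init = t_init, cooling = cooling,
                 n_iter = as.integer(n_iter), t_min_ratio = t_min_ratio),
            class = "sa_schedule")
}

#' Default parameter bounds per model and response kind
#'
#' Physically admissible closed intervals spanning reported crop values
#' with an order of magnitude to spare. Used by [fit_config()] when no
#' bounds are supplied.
#'
#' @param model Model name: `"ye"`, `"negexp"`, `"exp"`, `"nrh"`, `"npq"`.
#' @param kind Response kind: `"ETR"`, `"PHI"` or `"NPQ"`.
#' @return Named list of `c(lower, upper)` per free parameter.
#' @export
default_bounds <- function(model, kind) {
  nm <- .param_names(model, kind)
  all_bounds <- list(
    alpha_e = c(1e-6, 2), alpha_prime = c(1e-6, 2),
    beta_e = c(0, 1e-2), gamma_e = c(1e-7, 1e-1),
    phi_psii_max = c(1e-6, 1), fv_fm = c(1e-6, 1),
    k_w = c(1e-6, 1e-1), I_sat = c(1, 5000),
    theta = c(1e-6, 1), etr_max = c(1e-3, 1000),
    A = c(0, 1), b = c(1e-7, 1e-1), NPQ0 = c(0, 5)
  )
  all_bounds[nm]
}

#' Fitting configuration
#'
#' Bundles everything [fit_light_curve()] needs besides the data: the model
#' and response kind, parameter bounds, the multistart/simulated-annealing
#' schedule, the local convergence tolerance and the mandatory seed.
#'
#' @param model `"ye"`, `"negexp"`, `"exp"`, `"nrh"` or `"npq"`.
#' @param kind `"ETR"`, `"PHI"` or `"NPQ"` (the `"npq"` model pairs only
#'   with `"NPQ"`, the others with `"ETR"`/`"PHI"`).
#' @param seed Integer seed (required); the fit is bit-reproducible given
#'   identical inputs and seed.
#' @param bounds Named list of `c(lower, upper)` per parameter, or `NULL`
#'   for [default_bounds()].
#' @param n_starts Number of Latin-hypercube start points. Default 20.
#' @param n_sa_chains Simulated-annealing chains launched from the best
#'   starts. Default 3.
#' @param sa An [sa_schedule()].
#' @param local_tol Relative SSR convergence tolerance of the local
#'   least-squares refinement. Default 1e-10.
#' @return An object of class `fit_config`.
#' @examples
#' cfg <- fit_config("ye", "ETR", seed = 42)
#' @export
fit_config <- function(model = c("ye", "negexp", "exp", "nrh", "npq"),
                       kind = c("ETR", "PHI", "NPQ"), seed, bounds = NULL,
                       n_starts = 20L, n_sa_chains = 3L, sa = sa_schedule(),
                       local_tol = 1e-10) {
  model <- match.arg(model)
  kind <- match.arg(kind)
  if ((model == "npq") != (kind == "NPQ")) {
    rlang::abort("The 'npq' model pairs with kind 'NPQ' and vice versa.",
                 class = "lrc_error_domain")
  }
  if (missing(seed) || is.null(seed)) {
    rlang::abort("`seed` is required.", class = "lrc_error_domain")
  }
  if (is.null(bounds)) bounds <- default_bounds(model, kind)
  nm <- .param_names(model, kind)
  if (!setequal(names(bounds), nm)) {
    rlang::abort(paste0("`bounds` must name exactly: ",
                        paste(nm, collapse = ", ")),
                 class = "lrc_error_domain")
  }
  bounds <- bounds[nm]
  for (b in bounds) {
    if (length(b) != 2L || !all(is.finite(b)) || b[1] >= b[2]) {
      rlang::abort("Each bound must be a finite ordered pair.",
                   class = "lrc_error_domain")
    }
  }
  stopifnot(inherits(sa, "sa_schedule"))
  .check_scalar_pos(local_tol, "local_tol")
  if (n_starts < 1) {
    rlang::abort("`n_starts` must be >= 1.", class = "lrc_error_domain")
  }
  structure(list(model = model, kind = kind, seed = as.integer(seed),
                 bounds = bounds, n_starts = as.integer(n_starts),
                 n_sa_chains = as.integer(max(1L, min(n_sa_chains, n_starts))),
                 sa = sa, local_tol = local_tol),
            class = "fit_config")
}

# Latin-hypercube starts scaled into the bounds; parameters whose bounds
# span more than three decades (and exclude zero) are sampled log-uniformly.
.lhs_starts <- function(n, bounds) {
  k <- length(bounds)
  u <- lhs::randomLHS(n, k)
  starts <- matrix(NA_real_, n, k, dimnames = list(NULL, names(bounds)))
  for (j in seq_len(k)) {
    lo <- bounds[[j]][1]; hi <- bounds[[j]][2]
    if (lo > 0 && hi / lo > 1e3) {
      starts[, j] <- exp(log(lo) + u[, j] * (log(hi) - log(lo)))
    } else {
      starts[, j] <- lo + u[, j] * (hi - lo)
    }
  }
  starts
}

.metropolis_sa <- function(par0, ssr_fun, bounds, sa, t_init) {
  k <- length(par0)
  lo <- vapply(bounds, `[`, numeric(1), 1L)
  hi <- vapply(bounds, `[`, numeric(1), 2L)
  rng <- hi - lo
  n_temps <- max(1L, ceiling(log(sa$t_min_ratio) / log(sa$cooling)))
  cur <- par0
  cur_ssr <- ssr_fun(cur)
  best <- cur
  best_ssr <- cur_ssr
  temp <- t_init
  for (t in seq_len(n_temps)) {
    step <- rng * 0.1 * max(sqrt(temp / t_init), 0.02)
    # draw the whole temperature level's randomness in one block
    z <- matrix(stats::rnorm(sa$n_iter * k), sa$n_iter, k)
    u <- stats::runif(sa$n_iter)
    for (i in seq_len(sa$n_iter)) {
      cand <- cur + z[i, ] * step
      out_lo <- cand < lo
      out_hi <- cand > hi
      if (any(out_lo)) cand[out_lo] <- lo[out_lo]
      if (any(out_hi)) cand[out_hi] <- hi[out_hi]
      cand_ssr <- ssr_fun(cand)
      d <- cand_ssr - cur_ssr
      if (d <= 0 || u[i] < exp(-d / temp)) {
        cur <- cand
        cur_ssr <- cand_ssr
        if (cur_ssr < best_ssr) {
          best <- cur
          best_ssr <- cur_ssr
        }
      }
    }
    temp <- temp * sa$cooling
  }
  list(par = best, ssr = best_ssr)
}

# Tie-break among candidate optima whose SSR agree to 1e-12 relative:
# smallest beta_e, then smallest gamma_e, then lexicographic.
.pick_best <- function(cands) {
  ssrs <- vapply(cands, `[[`, numeric(1), "ssr")
  best_ssr <- min(ssrs)
  tol <- 1e-12 * max(best_ssr, 1e-300)
  tied <- which(ssrs <= best_ssr + tol)
  if (length(tied) == 1L) return(cands[[tied]])
  pars <- do.call(rbind, lapply(cands[tied], `[[`, "par"))
  ord_cols <- intersect(c("beta_e", "gamma_e"), colnames(pars))
  if (length(ord_cols) == 0L) ord_cols <- colnames(pars)
  ord <- do.call(order, as.data.frame(pars[, ord_cols, drop = FALSE]))
  cands[[tied[ord[1]]]]
}

#' Fit one light-response curve
#'
#' Estimates the parameters of a light-response model from one replicate's
#' curve by bounded least squares: a global stage of multistart simulated
#' annealing with Metropolis acceptance (Latin-hypercube starts; chains
#' launched from the best starts), then local Levenberg-Marquardt
#' refinement from the annealed candidates and every raw start. Deterministic
#' given the config seed. Darkness (`I = 0`) points enter Phi fits through
#' the models' analytic limits.
#'
#' @param curve Data frame with columns `I` and `value` (and optionally
#'   `quantity`, filtered to the config's kind).
#' @param config A [fit_config()].
#' @param consts An [optical_constants()] object.
#' @return An object of class `lrc_fit`: fitted `params`, closed-form
#'   `derived` quantities, `gof` statistics, and `diagnostics`
#'   (convergence flag, function evaluations, boundary-hit flags, SSR of
#'   the best start). Non-convergence is flagged, not thrown.
#' @examples
#' tr <- synthetic_truth(default_truth_params("negexp"), kind = "PHI",
#'                       noise_sd = 0, seed = 7)
#' curves <- generate_synthetic(tr)
#' fit <- fit_light_curve(dplyr::filter(curves, replicate_id == "rep1"),
#'                        fit_config("negexp", "PHI", seed = 7))
#' tidy(fit)
#' @export
fit_light_curve <- function(curve, config, consts = optical_constants()) {
  stopifnot(inherits(config, "fit_config"))
  curve <- tibble::as_tibble(curve)
  if ("quantity" %in% names(curve)) {
    curve <- dplyr::filter(curve, .data$quantity == config$kind)
  }
  if (!all(c("I", "value") %in% names(curve))) {
    rlang::abort("`curve` needs columns `I` and `value`.",
                 class = "lrc_error_format")
  }
  I <- as.numeric(curve$I)
  y <- as.numeric(curve$value)
  .check_nonneg_light(I)
  k <- .n_free_params(config$model, config$kind)
  if (length(unique(I)) < k + 1L) {
    rlang::abort(paste0("Underdetermined fit: ", length(unique(I)),
                        " distinct light levels for a ", k,
                        "-parameter model (need at least ", k + 1L, ")."),
                 class = "lrc_error_underdetermined")
  }
  if (stats::sd(y) == 0) {
    rlang::abort("Degenerate data: the response is constant.",
                 class = "lrc_error_degenerate")
  }

  f <- .curve_fun(config$model, config$kind, consts)
  n_evals <- 0L
  ssr_fun <- function(p) {
    n_evals <<- n_evals + 1L
    r <- y - f(p, I)
    sum(r * r)
  }
  resid_fun <- function(p) {
    n_evals <<- n_evals + 1L
    y - f(p, I)
  }

  bounds <- config$bounds
  lo <- vapply(bounds, `[`, numeric(1), 1L)
  hi <- vapply(bounds, `[`, numeric(1), 2L)

  withr::local_seed(config$seed)

  starts <- .lhs_starts(config$n_starts, bounds)
  start_ssr <- apply(starts, 1L, ssr_fun)
  ord <- order(start_ssr)
  best_start_ssr <- start_ssr[ord[1]]

  t_init <- config$sa$t_init
  if (is.null(t_init)) {
    t_init <- stats::IQR(start_ssr)
    if (!is.finite(t_init) || t_init <= 0) t_init <- max(best_start_ssr, 1)
  }

  seeds_pts <- lapply(seq_len(config$n_sa_chains), function(i) {
    .metropolis_sa(starts[ord[i], ], ssr_fun, bounds, config$sa, t_init)
  })
  # Refine from every start, not only the best: a handful of Levenberg-
  # Marquardt runs are cheap next to the annealing stage, and basins missed
  # by the top-ranked starts (e.g. the monotone beta_e = 0 basin of peaked
  # data) are still reached from lower-ranked ones.
  raw_pts <- lapply(ord, function(i) {
    list(par = starts[i, ], ssr = start_ssr[i])
  })

  cands <- list()
  any_converged <- FALSE
  for (pt in c(seeds_pts, raw_pts)) {
    res <- tryCatch(
      minpack.lm::nls.lm(par = pt$par, lower = lo, upper = hi,
                         fn = resid_fun,
                         control = minpack.lm::nls.lm.control(
                           ftol = config$local_tol, ptol = 1e-12,
                           maxiter = 500)),
      error = function(e) NULL)
    if (!is.null(res)) {
      par <- pmin(pmax(res$par, lo), hi)
      names(par) <- names(bounds)
      cands <- c(cands, list(list(par = par, ssr = ssr_fun(par))))
      if (res$info %in% 1:4) any_converged <- TRUE
    }
    cands <- c(cands, list(pt))
  }

  best <- .pick_best(cands)
  par <- best$par
  boundary <- (par - lo) <= 1e-6 * (hi - lo) | (hi - par) <= 1e-6 * (hi - lo)
  names(boundary) <- names(bounds)

  params <- .params_from_vector(config$model, config$kind, par, consts)
  derived <- if (config$model == "npq") {
    .derived_row(NA_real_, NA_real_, "not-applicable", "not-applicable")
  } else {
    derive_params(params, consts)
  }
  fitted <- f(par, I)
  gof_stats <- gof(y, fitted, k = k)

  structure(
    list(model = config$model, kind = config$kind, params = params,
         derived = derived, gof = gof_stats,
         diagnostics = list(converged = any_converged, n_evals = n_evals,
                            boundary = boundary,
                            best_start_ssr = best_start_ssr,
                            ssr = best$ssr),
         data = tibble::tibble(I = I, observed = y, fitted = fitted),
         config = config, consts = consts),
    class = "lrc_fit")
}

#' @export
print.lrc_fit <- function(x, ...) {
  cat("<lrc_fit> model =", x$model, ", kind =", x$kind,
      if (!x$diagnostics$converged) "(not converged)" else "", "\n")
  print(tidy(x), n = Inf)
  cat(sprintf("SSR %.4g | R2 %.5f | MAE %.4g | AIC %.4g (n=%d, k=%d)\n",
              x$gof$ssr, x$gof$r2, x$gof$mae, x$gof$aic, x$gof$n, x$gof$k))
  invisible(x)
}

#' Fit all replicates of a light-curve data set
#'
#' Fits each replicate independently (per-replicate seeds derived
#' deterministically from the config seed) and aggregates the fitted
#' parameters, derived quantities and goodness-of-fit statistics as
#' mean +/- standard error (`sd / sqrt(n)`) across replicates. A failed
#' replicate is recorded and excluded from the aggregate; the success count
#' is reported. With a single replicate the SE is `NA`.
#'
#' @param curves Data frame with columns `replicate_id`, `I`, `value` (and
#'   optionally `quantity`).
#' @param config A [fit_config()].
#' @param consts An [optical_constants()] object.
#' @return An object of class `lrc_fit_set`: `fits` (per-replicate
#'   `lrc_fit` or error condition), `summary` (tibble with `term`, `type`,
#'   `mean`, `se`, `n`, `flag`), `n_ok`, `errors`.
#' @export
fit_replicates <- function(curves, config, consts = optical_constants()) {
  stopifnot(inherits(config, "fit_config"))
  curves <- tibble::as_tibble(curves)
  if (!"replicate_id" %in% names(curves)) {
    rlang::abort("`curves` needs a `replicate_id` column.",
                 class = "lrc_error_format")
  }
  reps <- unique(curves$replicate_id)
  fits <- vector("list", length(reps))
  names(fits) <- as.character(reps)
  for (r in seq_along(reps)) {
    sub <- dplyr::filter(curves, .data$replicate_id == reps[r])
    cfg_r <- config
    cfg_r$seed <- .split_seed(config$seed, r)
    fits[[r]] <- tryCatch(fit_light_curve(sub, cfg_r, consts),
                          error = function(e) e)
  }
  ok <- vapply(fits, inherits, logical(1), "lrc_fit")
  per_rep <- purrr::map_dfr(which(ok), function(r) {
    dplyr::mutate(tidy(fits[[r]]), replicate_id = as.character(reps[r]))
  })
  summary <- if (sum(ok) > 0L) {
    dplyr::summarise(
      dplyr::group_by(per_rep, .data$term, .data$type),
      mean = mean(.data$estimate),
      se = if (dplyr::n() > 1L) {
        stats::sd(.data$estimate) / sqrt(dplyr::n())
      } else NA_real_,
      n = dplyr::n(),
      flag = {
        fl <- .data$flag[!is.na(.data$flag)]
        if (length(fl) > 0L) fl[1] else NA_character_
      },
      .groups = "drop")
  } else {
    tibble::tibble(term = character(), type = character(), mean = numeric(),
                   se = numeric(), n = integer(), flag = character())
  }
  structure(list(fits = fits, summary = summary, per_replicate = per_rep,
                 n_ok = sum(ok),
                 errors = fits[!ok], config = config, consts = consts),
            class = "lrc_fit_set")
}

#' @export
print.lrc_fit_set <- function(x, ...) {
  cat("<lrc_fit_set> model =", x$config$model, ", kind =", x$config$kind,
      "|", x$n_ok, "of", length(x$fits), "replicates fitted\n")
  print(x$summary, n = Inf)
  invisible(x)
}

#' Numeric extremum oracle for ETR light-response curves
#'
#' Finds the maximising light intensity and maximum of an arbitrary ETR
#' curve numerically: a coarse grid scan over `[0, I_max]` followed by
#' golden-section refinement of the bracketing interval. Independent of the
#' closed-form derivations, it serves as the reference the closed forms are
#' checked against. When the maximum sits at the right boundary (a
#' monotonically increasing curve), that is reported via `boundary = TRUE`
#' and no interior maximum is claimed.
#'
#' @param f Function of `I` returning ETR, defined on `[0, I_max]`.
#' @param I_max Upper end of the search range. Default 3000.
#' @param n_grid Number of coarse grid points. Default 3001.
#' @param tol Absolute x-tolerance of the golden-section refinement.
#' @return List with `i_sat`, `etr_max`, `boundary`.
#' @examples
#' p <- ye_params(0.3, 1e-4, 5e-4)
#' numeric_extrema_oracle(function(I) eval_curve(p, I, "ETR"))
#' @export
numeric_extrema_oracle <- function(f, I_max = 3000, n_grid = 3001L,
                                   tol = 1e-6) {
  grid <- seq(0, I_max, length.out = n_grid)
  vals <- f(grid)
  idx <- which.max(vals)
  if (idx == n_grid) {
    return(list(i_sat = I_max, etr_max = vals[n_grid], boundary = TRUE))
  }
  loi <- max(1L, idx - 1L)
  hii <- min(n_grid, idx + 1L)
  opt <- stats::optimize(f, lower = grid[loi], upper = grid[hii],
                         maximum = TRUE, tol = tol)
  list(i_sat = opt$maximum, etr_max = opt$objective, boundary = FALSE)
}
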