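#' Goodness-of-fit statistics
#'
#' Computes the fit statistics used to compare models: the sum of squared
#' residuals (SSR), coefficient of determination
#' `R2 = 1 - SSR / SStot` (with `SStot` about the observed mean), mean
#' absolute error, and the Akaike information criterion in its
#' least-squares form `AIC = 2k + n * ln(SSR / n)`.
#'
#' A perfect fit (`SSR = 0`) has no finite AIC on this scale: the AIC is
#' reported as `-Inf` and flagged degenerate. Zero-variance observations
#' leave `R2` undefined (`NA`, flagged).
#'
#' @param observed,predicted Equal-length numeric response vectors.
#' @param k Parameter count charged to the model, >= 1.
#' @return An object of class `lrc_gof`: list with `n`, `k`, `ssr`, `r2`,
#'   `mae`, `aic`, and a character vector `flags`.
#' @examples
#' g <- gof(c(1, 2, 3), c(1, 2, 4), k = 2)
#' g$r2  # 0.5
#' g$aic # 4 + 3 * log(1/3)
#' @export
gof <- function(observed, predicted, k) {
  if (length(observed) != length(predicted)) {
    rlang::abort("`observed` and `predicted` must have equal length.",
                 class = "lrc_error_domain")
  }
  n <- length(observed)
  if (n < 1L) {
    rlang::abort("Need at least one observation.", class = "lrc_error_domain")
  }
  if (!is.numeric(k) || length(k) != 1L || k < 1) {
    rlang::abort("`k` must be a single count >= 1.",
                 class = "lrc_error_domain")
  }
  res <- observed - predicted
  ssr <- sum(res^2)
  mae <- mean(abs(res))
  sstot <- sum((observed - mean(observed))^2)
  flags <- character()
  r2 <- if (sstot == 0) {
    flags <- c(flags, "zero-variance-observations")
    NA_real_
  } else {
    1 - ssr / sstot
  }
  aic <- if (ssr == 0) {
    flags <- c(flags, "degenerate-zero-SSR")
    -Inf
  } else {
    2 * k + n * log(ssr / n)
  }
  structure(list(n = n, k = as.integer(k), ssr = ssr, r2 = r2, mae = mae,
                 aic = aic, flags = flags),
            class = "lrc_gof")
}

#' @export
print.lrc_gof <- function(x, ...) {
  cat(sprintf("<lrc_gof> n=%d k=%d SSR=%.6g R2=%.6g MAE=%.6g AIC=%.6g\n",
              x$n, x$k, x$ssr, x$r2, x$mae, x$aic))
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Observed (model-free) summary of replicate light curves
#'
#' Summarises the measured curves the way the fitted quantities are
#' compared against observation: the observed maximum effective quantum
#' efficiency is the mean `PHI` value in darkness (`I = 0`); the observed
#' `ETR_max` is the mean of the per-replicate ETR maxima; the observed
#' `I_sat` is the mean of the per-replicate argmax light levels over the
#' measured grid (no interpolation: maxima sit on protocol grid points).
#' All come with standard errors (`NA` for a single replicate).
#'
#' @param curves Long light-curve tibble (`replicate_id`, `I`, `quantity`,
#'   `value`).
#' @return Tibble with columns `term`, `mean`, `se`, `n`, `flag`.
#' @export
observed_summary <- function(curves) {
  curves <- tibble::as_tibble(curves)
  out <- list()
  summarise_stat <- function(x, term, flag = NA_character_) {
    tibble::tibble(term = term, mean = mean(x),
                   se = if (length(x) > 1L) stats::sd(x) / sqrt(length(x))
                        else NA_real_,
                   n = length(x), flag = flag)
  }
  phi <- dplyr::filter(curves, .data$quantity == "PHI")
  if (nrow(phi) > 0L) {
    dark <- dplyr::filter(phi, .data$I == 0)
    out$phi <- if (nrow(dark) > 0L) {
      summarise_stat(dark$value, "phi_psii_max")
    } else {
      tibble::tibble(term = "phi_psii_max", mean = NA_real_, se = NA_real_,
                     n = 0L, flag = "no-darkness-step")
    }
  }
  etr <- dplyr::filter(curves, .data$quantity == "ETR")
  if (nrow(etr) > 0L) {
    per_rep <- dplyr::summarise(
      dplyr::group_by(etr, .data$replicate_id),
      etr_max = max(.data$value),
      i_sat = .data$I[which.max(.data$value)],
      .groups = "drop")
    out$etr_max <- summarise_stat(per_rep$etr_max, "etr_max")
    out$i_sat <- summarise_stat(per_rep$i_sat, "i_sat")
  }
  dplyr::bind_rows(out)
}

# Which quantities each model reports in the comparison table, per curve
# kind, mirroring which cells the reference tables fill in. "i_sat" for the
# exponential model under the Phi kind is reported although its meaning is
# unclear (it is the fitted parameter, not an ETR-curve argmax).
.estimable <- function(model, kind) {
  if (kind == "ETR") {
    switch(model,
           ye = c("i_sat", "etr_max"),
           negexp = c("i_sat", "etr_max", "phi_psii_max"),
           exp = c("i_sat", "etr_max", "fv_fm"),
           nrh = "etr_max")
  } else {
    switch(model,
           ye = "phi_psii_max",
           negexp = "phi_psii_max",
           exp = c("i_sat", "fv_fm"),
           nrh = "etr_max")
  }
}

# Parameter counts charged to AIC under the two conventions.
.k_for <- function(model, kind, convention = c("free", "paper")) {
  convention <- match.arg(convention)
  if (convention == "free") return(.n_free_params(model, kind))
  if (kind == "ETR") {
    c(ye = 3L, negexp = 4L, exp = 4L, nrh = 3L)[[model]]
  } else {
    c(ye = 3L, negexp = 2L, exp = 2L, nrh = 5L)[[model]]
  }
}

#' Assemble the four-model comparison table
#'
#' Builds the per-quantity, per-model table of fitted means +/- SE, with
#' explicit not-estimable flags where a model cannot return a quantity
#' (the hyperbola has no finite saturation intensity; the exponential and
#' hyperbolic models cannot return the maximum effective quantum
#' efficiency), plus R2, MAE, the parameter count `k` used for AIC, and
#' AIC. The lowest-AIC model is recorded in the `best_model` attribute.
#'
#' @param fits Named list of [fit_replicates()] results (names are model
#'   names). At least one.
#' @param observed Optional [observed_summary()] tibble, added as an
#'   `observed` column.
#' @param k_convention `"free"` (free-parameter count; default) or
#'   `"paper"` (the printed-table convention: ETR 3/4/4/3, PHI 3/2/2/5).
#'   AIC is recomputed as `2k + n ln(SSR/n)` under the chosen convention
#'   from each replicate's SSR.
#' @return An object of class `lrc_comparison`: a long tibble (`term`,
#'   `model`, `mean`, `se`, `n`, `flag`) with attributes `kind`,
#'   `k_convention` and `best_model`.
#' @export
build_comparison_table <- function(fits, observed = NULL,
                                   k_convention = c("free", "paper")) {
  k_convention <- match.arg(k_convention)
  if (length(fits) < 1L) {
    rlang::abort("Need at least one fitted model.",
                 class = "lrc_error_domain")
  }
  kinds <- unique(vapply(fits, function(f) f$config$kind, character(1)))
  if (length(kinds) != 1L) {
    rlang::abort("All fits must share one response kind.",
                 class = "lrc_error_domain")
  }
  kind <- kinds
  quantities <- c("phi_psii_max", "i_sat", "fv_fm", "etr_max",
                  "r2", "mae", "k", "aic")

  rows <- purrr::imap_dfr(fits, function(fs, model) {
    est <- .estimable(model, kind)
    k_used <- .k_for(model, kind, k_convention)
    smry <- fs$summary
    stat_row <- function(term, type_terms) {
      hit <- dplyr::filter(smry, .data$term %in% type_terms)
      if (term %in% est && nrow(hit) > 0L && is.finite(hit$mean[1])) {
        tibble::tibble(term = term, model = model, mean = hit$mean[1],
                       se = hit$se[1], n = hit$n[1], flag = NA_character_)
      } else {
        tibble::tibble(term = term, model = model, mean = NA_real_,
                       se = NA_real_, n = fs$n_ok, flag = "not-estimable")
      }
    }
    # AIC under the requested convention, recomputed per replicate.
    ok_fits <- Filter(function(f) inherits(f, "lrc_fit"), fs$fits)
    aics <- vapply(ok_fits, function(f) {
      2 * k_used + f$gof$n * log(f$gof$ssr / f$gof$n)
    }, numeric(1))
    gof_row <- function(term, vals) {
      tibble::tibble(term = term, model = model, mean = mean(vals),
                     se = if (length(vals) > 1L) {
                       stats::sd(vals) / sqrt(length(vals))
                     } else NA_real_,
                     n = length(vals), flag = NA_character_)
    }
    r2s <- vapply(ok_fits, function(f) f$gof$r2, numeric(1))
    maes <- vapply(ok_fits, function(f) f$gof$mae, numeric(1))
    dplyr::bind_rows(
      stat_row("phi_psii_max", "phi_psii_max"),
      stat_row("i_sat", c("i_sat", "I_sat")),
      stat_row("fv_fm", "fv_fm"),
      stat_row("etr_max", "etr_max"),
      gof_row("r2", r2s),
      gof_row("mae", maes),
      tibble::tibble(term = "k", model = model, mean = k_used, se = NA_real_,
                     n = fs$n_ok, flag = NA_character_),
      gof_row("aic", aics)
    )
  })

  if (!is.null(observed)) {
    obs <- dplyr::mutate(observed, model = "observed")
    rows <- dplyr::bind_rows(rows, obs)
  }
  rows$term <- factor(rows$term, levels = quantities)
  rows$model <- factor(rows$model, levels = c("observed", names(fits)))
  rows <- dplyr::arrange(rows, .data$term, .data$model)
  rows$term <- as.character(rows$term)
  rows$model <- as.character(rows$model)

  aic_means <- dplyr::filter(rows, .data$term == "aic",
                             .data$model != "observed")
  best <- aic_means$model[which.min(aic_means$mean)]
  structure(tibble::new_tibble(rows, nrow = nrow(rows),
                               class = "lrc_comparison"),
            kind = kind, k_convention = k_convention, best_model = best)
}

#' Fit and compare the four light-response models
#'
#' Convenience pipeline: fits the mechanistic, negative-exponential,
#' exponential and non-rectangular-hyperbola models to the same replicate
#' curves, summarises the observations, and assembles the comparison
#' table.
#'
#' @param curves Long light-curve tibble (`replicate_id`, `I`, `quantity`,
#'   `value`).
#' @param kind `"ETR"` or `"PHI"`.
#' @param seed Integer seed used for every model's fit.
#' @param consts An [optical_constants()] object.
#' @param models Models to include. Default all four.
#' @param k_convention Passed to [build_comparison_table()].
#' @param ... Further arguments passed to [fit_config()].
#' @return An `lrc_comparison` table (see [build_comparison_table()]); the
#'   full fit sets are attached as attribute `fits`.
#' @export
compare_models <- function(curves, kind = c("ETR", "PHI"), seed,
                           consts = optical_constants(),
                           models = c("ye", "negexp", "exp", "nrh"),
                           k_convention = c("free", "paper"), ...) {
  kind <- match.arg(kind)
  fits <- purrr::map(rlang::set_names(models), function(m) {
    fit_replicates(curves, fit_config(m, kind, seed = seed, ...), consts)
  })
  obs <- observed_summary(curves)
  tab <- build_comparison_table(fits, observed = obs,
                                k_convention = k_convention)
  attr(tab, "fits") <- fits
  tab
}

#' @export
print.lrc_comparison <- function(x, ...) {
  cat("<lrc_comparison> kind =", attr(x, "kind"),
      "| k convention =", attr(x, "k_convention"),
      "| lowest AIC:", attr(x, "best_model"), "\n")
  NextMethod()
}
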