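#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a single light-curve fit
#'
#' Returns one row per free parameter, derived quantity (`i_sat`,
#' `etr_max`) and goodness-of-fit statistic, with a `type` column
#' distinguishing them and a `flag` column carrying not-finite /
#' not-defined markers.
#'
#' @param x An `lrc_fit` object.
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate`, `type`, `flag`.
#' @method tidy lrc_fit
#' @export
tidy.lrc_fit <- function(x, ...) {
  nm <- .param_names(x$model, x$kind)
  pv <- .param_vector(x$params)[nm]
  dplyr::bind_rows(
    tibble::tibble(term = nm, estimate = unname(pv), type = "parameter",
                   flag = NA_character_),
    tibble::tibble(term = c("i_sat", "etr_max"),
                   estimate = c(x$derived$i_sat, x$derived$etr_max),
                   type = "derived",
                   flag = c(x$derived$i_sat_flag, x$derived$etr_max_flag)),
    tibble::tibble(term = c("r2", "mae", "aic"),
                   estimate = c(x$gof$r2, x$gof$mae, x$gof$aic),
                   type = "gof", flag = NA_character_)
  )
}

#' Glance at a single light-curve fit
#'
#' @param x An `lrc_fit` object.
#' @param ... Unused.
#' @return A one-row tibble with `n`, `k`, `ssr`, `r2`, `mae`, `aic`,
#'   `converged`, `n_evals`.
#' @method glance lrc_fit
#' @export
glance.lrc_fit <- function(x, ...) {
  tibble::tibble(n = x$gof$n, k = x$gof$k, ssr = x$gof$ssr, r2 = x$gof$r2,
                 mae = x$gof$mae, aic = x$gof$aic,
                 converged = x$diagnostics$converged,
                 n_evals = x$diagnostics$n_evals)
}

#' Tidy a replicate fit set
#'
#' @param x An `lrc_fit_set` object.
#' @param ... Unused.
#' @return The aggregate tibble: `term`, `type`, `mean`, `se`, `n`, `flag`.
#' @method tidy lrc_fit_set
#' @export
tidy.lrc_fit_set <- function(x, ...) x$summary

#' Glance at a replicate fit set
#'
#' @param x An `lrc_fit_set` object.
#' @param ... Unused.
#' @return One-row tibble with replicate counts and mean goodness of fit.
#' @method glance lrc_fit_set
#' @export
glance.lrc_fit_set <- function(x, ...) {
  ok <- Filter(function(f) inherits(f, "lrc_fit"), x$fits)
  tibble::tibble(
    n_replicates = length(x$fits), n_ok = x$n_ok,
    mean_r2 = mean(vapply(ok, function(f) f$gof$r2, numeric(1))),
    mean_mae = mean(vapply(ok, function(f) f$gof$mae, numeric(1))),
    mean_aic = mean(vapply(ok, function(f) f$gof$aic, numeric(1))))
}

#' @method tidy lrc_gof
#' @export
tidy.lrc_gof <- function(x, ...) {
  tibble::tibble(n = x$n, k = x$k, ssr = x$ssr, r2 = x$r2, mae = x$mae,
                 aic = x$aic)
}

#' Plot a fitted light-response curve
#'
#' Observed points with the fitted curve drawn on a fine light grid.
#'
#' @param object An `lrc_fit` object.
#' @param n_curve Number of curve evaluation points. Default 200.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot lrc_fit
#' @export
autoplot.lrc_fit <- function(object, n_curve = 200L, ...) {
  grid <- seq(0, max(object$data$I), length.out = n_curve)
  f <- .curve_fun(object$model, object$kind, object$consts)
  curve_df <- tibble::tibble(I = grid,
                             value = f(.param_vector(object$params), grid))
  ylab <- switch(object$kind,
                 ETR = expression(ETR ~ (mu * mol ~ electrons ~ m^-2 ~ s^-1)),
                 PHI = expression(Phi[PSII]),
                 NPQ = "NPQ")
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$I)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$observed)) +
    ggplot2::geom_line(data = curve_df, ggplot2::aes(y = .data$value),
                       colour = "steelblue") +
    ggplot2::labs(
      x = expression(I ~ (mu * mol ~ photons ~ m^-2 ~ s^-1)), y = ylab,
      title = paste0("Fitted ", object$model, " model (", object$kind, ")")) +
    ggplot2::theme_minimal()
}

#' Plot a replicate fit set
#'
#' One panel per replicate: observed points and fitted curve.
#'
#' @param object An `lrc_fit_set` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot lrc_fit_set
#' @export
autoplot.lrc_fit_set <- function(object, ...) {
  ok <- Filter(function(f) inherits(f, "lrc_fit"), object$fits)
  pts <- purrr::imap_dfr(ok, function(f, id) {
    dplyr::mutate(f$data, replicate_id = id)
  })
  curves <- purrr::imap_dfr(ok, function(f, id) {
    grid <- seq(0, max(f$data$I), length.out = 200L)
    fn <- .curve_fun(f$model, f$kind, f$consts)
    tibble::tibble(replicate_id = id, I = grid,
                   fitted = fn(.param_vector(f$params), grid))
  })
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$I)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$observed), size = 0.8) +
    ggplot2::geom_line(data = curves, ggplot2::aes(y = .data$fitted),
                       colour = "steelblue") +
    ggplot2::facet_wrap(~replicate_id) +
    ggplot2::labs(x = expression(I ~ (mu * mol ~ photons ~ m^-2 ~ s^-1)),
                  y = object$config$kind) +
    ggplot2::theme_minimal()
}

#' Plot a model-comparison table
#'
#' Mean +/- SE of each reported quantity per model; goodness-of-fit rows
#' are shown in their own panels.
#'
#' @param object An `lrc_comparison` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot lrc_comparison
#' @export
autoplot.lrc_comparison <- function(object, ...) {
  df <- dplyr::filter(tibble::as_tibble(object), !is.na(.data$mean),
                      .data$term != "k")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$model, y = .data$mean)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$se,
                   ymax = .data$mean + .data$se), width = 0.2, na.rm = TRUE) +
    ggplot2::facet_wrap(~term, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "mean ± SE") +
    ggplot2::theme_minimal()
}

#' Plot raw light curves
#'
#' @param curves Long light-curve tibble.
#' @param quantity Which quantity to plot (default the first present).
#' @return A ggplot object.
#' @export
plot_light_curves <- function(curves, quantity = NULL) {
  curves <- tibble::as_tibble(curves)
  if (is.null(quantity)) quantity <- curves$quantity[1]
  df <- dplyr::filter(curves, .data$quantity == !!quantity)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$I, y = .data$value,
                                   colour = .data$replicate_id)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::labs(x = expression(I ~ (mu * mol ~ photons ~ m^-2 ~ s^-1)),
                  y = quantity, colour = "replicate") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
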