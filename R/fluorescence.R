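#' Fluorescence-derived photochemistry quantities
#'
#' Standard pulse-amplitude-modulation quantities computed from raw
#' fluorescence yields. Yields are treated as dimensionless positive reals;
#' no instrument-count scaling is imposed. All functions are vectorised and
#' scale-invariant: multiplying every yield by the same positive constant
#' leaves the result unchanged.
#'
#' * `phi_psii()`: effective quantum efficiency of PSII under actinic light,
#'   `(Fm' - F') / Fm'`.
#' * `fv_fm()`: maximum quantum efficiency of dark-adapted PSII,
#'   `(Fm - F0) / Fm`.
#' * `npq_from_fluorescence()`: non-photochemical quenching,
#'   `(Fm - Fm') / Fm'`.
#'
#' @param fmprime Maximal fluorescence in the light-adapted state (Fm').
#' @param fprime Steady-state fluorescence in the light (F').
#' @param f0 Minimal dark-adapted fluorescence (F0).
#' @param fm Maximal dark-adapted fluorescence (Fm).
#' @param records Optional labels naming each measurement, used in error
#'   messages to identify offending records.
#'
#' @return Numeric vector: `phi_psii` and `fv_fm` in \[0, 1\],
#'   `npq_from_fluorescence` >= 0.
#' @examples
#' phi_psii(2000, 600) # 0.7
#' fv_fm(400, 2000)    # 0.8
#' npq_from_fluorescence(2500, 1000) # 1.5
#' @name fluorescence
NULL

.bad_records <- function(bad, records, what) {
  labs <- if (is.null(records)) which(bad) else records[bad]
  rlang::abort(
    paste0("Invalid fluorescence measurement (", what, ") in record(s): ",
           paste(utils::head(labs, 10L), collapse = ", ")),
    class = "lrc_error_measurement"
  )
}

#' @rdname fluorescence
#' @export
phi_psii <- function(fmprime, fprime, records = NULL) {
  bad <- !is.finite(fmprime) | !is.finite(fprime) | fprime <= 0 | fmprime <= 0
  if (any(bad)) .bad_records(bad, records, "non-positive yield")
  bad <- fprime > fmprime
  if (any(bad)) .bad_records(bad, records, "F' > Fm'")
  (fmprime - fprime) / fmprime
}

#' @rdname fluorescence
#' @export
fv_fm <- function(f0, fm, records = NULL) {
  bad <- !is.finite(f0) | !is.finite(fm) | f0 <= 0 | fm <= 0
  if (any(bad)) .bad_records(bad, records, "non-positive yield")
  bad <- f0 > fm
  if (any(bad)) .bad_records(bad, records, "F0 > Fm")
  (fm - f0) / fm
}

#' @rdname fluorescence
#' @export
npq_from_fluorescence <- function(fm, fmprime, records = NULL) {
  bad <- !is.finite(fm) | !is.finite(fmprime) | fm <= 0 | fmprime <= 0
  if (any(bad)) .bad_records(bad, records, "non-positive yield")
  bad <- fmprime > fm
  if (any(bad)) .bad_records(bad, records, "Fm' > Fm: quenching cannot be negative")
  (fm - fmprime) / fmprime
}

#' Electron transport rate from effective quantum efficiency
#'
#' `ETR = alpha * beta * Phi_PSII * I`, in micromol electrons m^-2 s^-1.
#' Linear in both `phi` and `I`.
#'
#' @param phi Effective quantum efficiency, in \[0, 1\].
#' @param I Incident light intensity, micromol photons m^-2 s^-1, >= 0.
#' @param consts An [optical_constants()] object.
#' @return Numeric vector of ETR values.
#' @examples
#' etr_from_phi(0.5, 1000) # 210
#' @export
etr_from_phi <- function(phi, I, consts = optical_constants()) {
  if (!is.numeric(phi) || anyNA(phi) || any(phi < 0 | phi > 1)) {
    rlang::abort("`phi` must lie in [0, 1].", class = "lrc_error_domain")
  }
  .check_nonneg_light(I)
  consts$alpha * consts$beta * phi * I
}

#' Convert raw fluorescence records to light-curve quantities
#'
#' Takes a wide table of raw fluorescence yields (one row per light step,
#' columns `replicate_id`, `I`, optionally `F0`, `Fm`, and `Fprime`,
#' `Fmprime`) and returns the long light-curve table of derived quantities
#' (`PHI`, `ETR`, and `NPQ` where `Fm` is available). Rows violating the
#' measurement-ordering preconditions are dropped individually and reported
#' in the `problems` attribute, so one bad step does not void a curve.
#'
#' @param df Data frame with columns `replicate_id`, `I`, `Fprime`,
#'   `Fmprime`, and optionally `F0`, `Fm`.
#' @param consts An [optical_constants()] object.
#' @return A tibble with columns `replicate_id`, `I`, `quantity`, `value`;
#'   attribute `problems` holds a tibble of dropped rows with reasons.
#' @export
fluorescence_to_curves <- function(df, consts = optical_constants()) {
  need <- c("replicate_id", "I", "Fprime", "Fmprime")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0L) {
    rlang::abort(paste0("Missing fluorescence columns: ",
                        paste(missing_cols, collapse = ", ")),
                 class = "lrc_error_format")
  }
  df <- tibble::as_tibble(df)
  df$.row <- seq_len(nrow(df))

  reason <- rep(NA_character_, nrow(df))
  bad_yield <- !is.finite(df$Fprime) | !is.finite(df$Fmprime) |
    df$Fprime <= 0 | df$Fmprime <= 0
  reason[bad_yield] <- "non-positive fluorescence yield"
  bad_order <- !bad_yield & df$Fprime > df$Fmprime
  reason[bad_order] <- "F' > Fm'"
  bad_I <- is.na(reason) & (!is.finite(df$I) | df$I < 0)
  reason[bad_I] <- "negative or non-numeric I"

  keep <- is.na(reason)
  problems <- tibble::tibble(row = df$.row[!keep], reason = reason[!keep])
  ok <- df[keep, , drop = FALSE]

  phi <- phi_psii(ok$Fmprime, ok$Fprime)
  out <- dplyr::bind_rows(
    tibble::tibble(replicate_id = ok$replicate_id, I = ok$I,
                   quantity = "PHI", value = phi),
    tibble::tibble(replicate_id = ok$replicate_id, I = ok$I,
                   quantity = "ETR",
                   value = etr_from_phi(phi, ok$I, consts))
  )
  if ("Fm" %in% names(ok) && any(is.finite(ok$Fm))) {
    has_fm <- is.finite(ok$Fm) & ok$Fm > 0 & ok$Fmprime <= ok$Fm
    out <- dplyr::bind_rows(
      out,
      tibble::tibble(replicate_id = ok$replicate_id[has_fm],
                     I = ok$I[has_fm], quantity = "NPQ",
                     value = npq_from_fluorescence(ok$Fm[has_fm],
                                                   ok$Fmprime[has_fm]))
    )
  }
  out <- dplyr::arrange(out, .data$replicate_id, .data$quantity, .data$I)
  attr(out, "problems") <- problems
  attr(out, "consts") <- consts
  if (nrow(problems) > 0L) {
    rlang::warn(paste0(nrow(problems),
                       " fluorescence record(s) dropped; see attr(x, 'problems')."))
  }
  out
}
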