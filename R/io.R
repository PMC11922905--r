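#' Read light-curve data from CSV
#'
#' Two dialects are accepted:
#'
#' * **long** (canonical): header `replicate_id, I, quantity, value`, one
#'   row per observation, `quantity` in `ETR`, `PHI`, `NPQ`.
#' * **wide** (raw fluorescence): header `replicate_id, I, Fprime, Fmprime`
#'   with optional `F0`, `Fm`; rows are converted to `PHI`/`ETR` (and
#'   `NPQ` when `Fm` is present) via the configured optical constants.
#'
#' Malformed rows (non-numeric `I`/`value`, negative `I`, invalid
#' fluorescence ordering) are dropped individually and reported, with CSV
#' line numbers, in the `problems` attribute and a warning; a bad step
#' never voids its curve. Duplicate `(replicate_id, I, quantity)` rows are
#' an error.
#'
#' @param path CSV file path (UTF-8).
#' @param format `"auto"` (detect from header), `"long"` or `"wide"`.
#' @param consts An [optical_constants()] object (used by the wide dialect).
#' @return A long light-curve tibble (`replicate_id`, `I`, `quantity`,
#'   `value`) with attribute `problems`.
#' @export
read_light_curves <- function(path, format = c("auto", "long", "wide"),
                              consts = optical_constants()) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    rlang::abort(paste0("Input file not found: ", path),
                 class = "lrc_error_io")
  }
  if (file.size(path) == 0L) {
    rlang::abort("Empty input file.", class = "lrc_error_empty")
  }
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                        col_types = readr::cols(.default = readr::col_character()))
  if (nrow(df) == 0L) {
    rlang::abort("Input file has a header but no data rows.",
                 class = "lrc_error_empty")
  }
  if (format == "auto") {
    format <- if (all(c("quantity", "value") %in% names(df))) "long"
              else if (all(c("Fprime", "Fmprime") %in% names(df))) "wide"
              else NA_character_
    if (is.na(format)) {
      rlang::abort(
        "Unrecognised header: need long columns (replicate_id, I, quantity, value) or wide columns (replicate_id, I, Fprime, Fmprime).",
        class = "lrc_error_format")
    }
  }
  need <- if (format == "long") c("replicate_id", "I", "quantity", "value")
          else c("replicate_id", "I", "Fprime", "Fmprime")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0L) {
    rlang::abort(paste0("Missing header column(s): ",
                        paste(missing_cols, collapse = ", ")),
                 class = "lrc_error_format")
  }
  # Data line numbers in the file: header is line 1.
  df$.line <- seq_len(nrow(df)) + 1L

  num <- function(x) suppressWarnings(as.numeric(x))
  if (format == "long") {
    I <- num(df$I); v <- num(df$value)
    reason <- rep(NA_character_, nrow(df))
    reason[is.na(I) | is.na(v)] <- "non-numeric I or value"
    reason[is.na(reason) & I < 0] <- "negative I"
    reason[is.na(reason) & !df$quantity %in% c("ETR", "PHI", "NPQ")] <-
      "unknown quantity"
    keep <- is.na(reason)
    problems <- tibble::tibble(line = df$.line[!keep], reason = reason[!keep])
    out <- tibble::tibble(replicate_id = df$replicate_id[keep], I = I[keep],
                          quantity = df$quantity[keep], value = v[keep])
  } else {
    wide <- tibble::tibble(replicate_id = df$replicate_id, I = num(df$I),
                           Fprime = num(df$Fprime),
                           Fmprime = num(df$Fmprime))
    if ("F0" %in% names(df)) wide$F0 <- num(df$F0)
    if ("Fm" %in% names(df)) wide$Fm <- num(df$Fm)
    out <- withCallingHandlers(
      fluorescence_to_curves(wide, consts),
      warning = function(w) invokeRestart("muffleWarning"))
    problems <- attr(out, "problems")
    problems$line <- df$.line[problems$row]
    problems <- problems[c("line", "reason")]
  }
  dup <- duplicated(out[c("replicate_id", "I", "quantity")])
  if (any(dup)) {
    rlang::abort("Duplicate (replicate_id, I, quantity) rows.",
                 class = "lrc_error_format")
  }
  attr(out, "problems") <- problems
  if (nrow(problems) > 0L) {
    rlang::warn(paste0(nrow(problems), " malformed row(s) dropped (lines ",
                       paste(utils::head(problems$line, 10L), collapse = ", "),
                       "); see attr(x, 'problems')."))
  }
  out
}

#' Write light-curve data to CSV (long dialect)
#'
#' @param curves Long light-curve tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_light_curves <- function(curves, path) {
  readr::write_csv(tibble::as_tibble(curves)[
    c("replicate_id", "I", "quantity", "value")], path)
  invisible(path)
}

# Plain-list representations used for JSON serialisation -------------------

.flag_token <- function(flag) paste0("NA(", flag, ")")

.cell <- function(value, flag) {
  if (!is.na(flag)) .flag_token(flag) else value
}

#' Convert results to a plain serialisable list
#'
#' @param x An `lrc_fit`, `lrc_fit_set` or `lrc_comparison` object.
#' @param ... Unused.
#' @return A named list of plain vectors, suitable for JSON.
#' @export
as_result_list <- function(x, ...) UseMethod("as_result_list")

#' @export
as_result_list.lrc_fit <- function(x, ...) {
  nm <- .param_names(x$model, x$kind)
  pv <- as.list(.param_vector(x$params)[nm])
  list(model = x$model, kind = x$kind, parameters = pv,
       derived = list(i_sat = .cell(x$derived$i_sat, x$derived$i_sat_flag),
                      etr_max = .cell(x$derived$etr_max,
                                      x$derived$etr_max_flag)),
       gof = list(n = x$gof$n, k = x$gof$k, ssr = x$gof$ssr, r2 = x$gof$r2,
                  mae = x$gof$mae, aic = x$gof$aic),
       diagnostics = list(converged = x$diagnostics$converged,
                          n_evals = x$diagnostics$n_evals,
                          ssr = x$diagnostics$ssr),
       seed = x$config$seed)
}

#' @export
as_result_list.lrc_fit_set <- function(x, ...) {
  ok <- vapply(x$fits, inherits, logical(1), "lrc_fit")
  list(model = x$config$model, kind = x$config$kind, seed = x$config$seed,
       n_replicates = length(x$fits), n_ok = x$n_ok,
       summary = lapply(seq_len(nrow(x$summary)), function(i) {
         row <- x$summary[i, ]
         list(term = row$term, type = row$type,
              mean = .cell(row$mean, row$flag), se = row$se, n = row$n)
       }),
       replicates = lapply(x$fits[ok], as_result_list))
}

#' @export
as_result_list.lrc_comparison <- function(x, ...) {
  df <- tibble::as_tibble(x)
  list(kind = attr(x, "kind"), k_convention = attr(x, "k_convention"),
       best_model = attr(x, "best_model"),
       rows = lapply(seq_len(nrow(df)), function(i) {
         row <- df[i, ]
         list(term = row$term, model = row$model,
              mean = .cell(row$mean, row$flag), se = row$se, n = row$n)
       }))
}

#' Write fit results or comparison tables
#'
#' JSON output serialises the full structure losslessly (floats at full
#' precision; flagged cells as the literal token `"NA(flag-name)"`). CSV
#' output writes the tidy/tabular form: for a comparison table, a wide
#' table with fixed column order `term, observed, <models in fit order>`,
#' cells formatted `mean ± se` (flagged cells as `NA(flag)`); for fits,
#' the tidy parameter table.
#'
#' @param x An `lrc_fit`, `lrc_fit_set` or `lrc_comparison` object.
#' @param path Output path.
#' @param format `"json"` or `"csv"` (default from the file extension).
#' @return `path`, invisibly.
#' @export
write_results <- function(x, path, format = NULL) {
  if (is.null(format)) {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  format <- match.arg(format, c("json", "csv"))
  if (format == "json") {
    jsonlite::write_json(as_result_list(x), path, auto_unbox = TRUE,
                         digits = NA, null = "null", na = "string")
  } else {
    readr::write_csv(.as_csv_table(x), path)
  }
  invisible(path)
}

.as_csv_table <- function(x) UseMethod(".as_csv_table")

#' @export
.as_csv_table.lrc_fit <- function(x) tidy(x)

#' @export
.as_csv_table.lrc_fit_set <- function(x) x$summary

#' @export
.as_csv_table.lrc_comparison <- function(x) {
  df <- tibble::as_tibble(x)
  df$cell <- ifelse(!is.na(df$flag), .flag_token(df$flag),
                    ifelse(is.na(df$se),
                           formatC(df$mean, digits = 6, format = "g"),
                           paste0(formatC(df$mean, digits = 6, format = "g"),
                                  " ± ",
                                  formatC(df$se, digits = 3, format = "g"))))
  wide <- tidyr::pivot_wider(df[c("term", "model", "cell")],
                             names_from = "model", values_from = "cell")
  models <- setdiff(unique(df$model), "observed")
  cols <- c("term", intersect("observed", names(wide)), models)
  wide[cols]
}

#' Read back a JSON results file
#'
#' @param path JSON path written by [write_results()].
#' @return The deserialised list.
#' @export
read_results <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE,
                      simplifyMatrix = FALSE)
}
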