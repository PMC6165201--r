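# External-standard quantitation: proportional (through-origin) calibration
# against an alamethicin standard, content and relative-composition tables,
# and the length-dependent accuracy flag (a single 19-ish-residue standard
# only quantifies 17-20-residue peptaibols accurately).

#' Fit a proportional calibration
#'
#' Least-squares fit of concentration = response_factor x area through the
#' origin, the model implied by a single external standard.
#'
#' @param concentration known standard concentrations (same length as `area`).
#' @param area measured peak areas (> 0).
#' @return object of class `peptaibol_calibration`: list with
#'   `response_factor`, `residual_rms`, `n_points` and the fitted `lm`.
#' @examples
#' fit_calibration(c(10, 20), c(1000, 2000))   # factor 0.01
#' @export
fit_calibration <- function(concentration, area) {
  if (length(concentration) != length(area) || !length(area)) {
    stop(errorCondition("need matching, non-empty concentration and area vectors",
                        class = c("peptaibio_invalid_calibration", "error", "condition")))
  }
  if (any(!is.finite(area)) || any(area <= 0)) {
    stop(errorCondition("calibration areas must be positive",
                        class = c("peptaibio_invalid_calibration", "error", "condition")))
  }
  fit <- stats::lm(concentration ~ 0 + area)
  structure(list(response_factor = unname(stats::coef(fit)[["area"]]),
                 residual_rms = sqrt(mean(stats::residuals(fit)^2)),
                 n_points = length(area),
                 fit = fit),
            class = "peptaibol_calibration")
}

#' @export
print.peptaibol_calibration <- function(x, ...) {
  cat(sprintf("<peptaibol_calibration> response factor %.6g (conc/area), residual RMS %.4g, n = %d\n",
              x$response_factor, x$residual_rms, x$n_points))
  invisible(x)
}

#' @export
coef.peptaibol_calibration <- function(object, ...) {
  c(response_factor = object$response_factor)
}

#' @export
predict.peptaibol_calibration <- function(object, area, ...) {
  object$response_factor * area
}

#' Quantify peptaibol compounds from peak areas
#'
#' Applies the calibration response factor to each compound's area, computes
#' relative composition (area percent, normalised to 100), and flags the
#' length-dependent accuracy: with a single long external standard, only
#' 17-20-residue peptaibols are quantified with high accuracy (shorter ones
#' have structurally different response).
#'
#' @param name compound names.
#' @param area peak areas (>= 0, not all zero). `NA` areas are dropped.
#' @param seq_length residue counts per compound.
#' @param model a `peptaibol_calibration`.
#' @param rt optional retention times carried into the report.
#' @return data.frame of class `peptaibol_quant`: `name`, `rt`, `area`,
#'   `area_percent`, `content`, `accuracy_flag`, with attribute
#'   `total_content`.
#' @export
quantify_peptaibols <- function(name, area, seq_length, model, rt = NA_real_) {
  stopifnot(inherits(model, "peptaibol_calibration"))
  keep <- !is.na(area)
  name <- name[keep]; area <- area[keep]
  seq_length <- rep_len(seq_length, length(keep))[keep]
  rt <- rep_len(rt, length(keep))[keep]
  if (!length(area) || all(area == 0)) {
    stop(errorCondition("degenerate run: no non-zero areas to quantify",
                        class = c("peptaibio_degenerate_run", "error", "condition")))
  }
  content <- predict(model, area)
  out <- data.frame(
    name = name, rt = rt, area = area,
    area_percent = 100 * area / sum(area),
    content = content,
    accuracy_flag = ifelse(seq_length >= 17L & seq_length <= 20L,
                           "accurate", "low_accuracy"),
    stringsAsFactors = FALSE)
  attr(out, "total_content") <- sum(content)
  class(out) <- c("peptaibol_quant", "data.frame")
  out
}

#' @export
print.peptaibol_quant <- function(x, ...) {
  cat(sprintf("<peptaibol_quant> %d compounds, total content %.2f\n",
              nrow(x), attr(x, "total_content")))
  print.data.frame(x, digits = 4)
  invisible(x)
}

#' Read a calibration CSV (columns `concentration`, `area`)
#'
#' @param path CSV path.
#' @return a `peptaibol_calibration`.
#' @export
read_calibration_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("concentration", "area")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop(errorCondition(sprintf("calibration CSV '%s' is missing column '%s'", path, miss[1]),
                        class = c("peptaibio_format_error", "error", "condition")))
  }
  fit_calibration(df$concentration, df$area)
}

#' Write a quantitation report TSV (with a trailing total row)
#'
#' @param quant a `peptaibol_quant`.
#' @param path output path.
#' @export
write_quant_tsv <- function(quant, path) {
  df <- as.data.frame(quant)
  names(df)[names(df) == "content"] <- "content_ug_per_ml"
  total <- data.frame(name = "TOTAL", rt = NA, area = sum(df$area),
                      area_percent = 100,
                      content_ug_per_ml = attr(quant, "total_content"),
                      accuracy_flag = "", stringsAsFactors = FALSE)
  utils::write.table(rbind(df, total), path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
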