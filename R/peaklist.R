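# Observed ions: an m/z / intensity list with optional ion-kind labels
# (MNa, M2Na, b, y7, ms2) and a chromatographic retention time.

#' Construct a peak list
#'
#' @param mz numeric vector of m/z values (> 0).
#' @param intensity non-negative intensities (default 1).
#' @param kind optional per-peak labels from `{"MNa", "M2Na", "b", "y7",
#'   "ms2"}`; `NA` for unlabelled peaks.
#' @param rt retention time in minutes (scalar, `NA` allowed).
#' @return a `peak_list`: data.frame with columns `mz`, `intensity`, `kind`,
#'   sorted ascending by `mz`, with attribute `rt`.
#' @export
peak_list <- function(mz, intensity = rep(1, length(mz)), kind = NULL, rt = NA_real_) {
  mz <- as.numeric(mz)
  if (any(!is.finite(mz)) || any(mz <= 0)) {
    stop(errorCondition("peak m/z values must be positive and finite",
                        class = c("peptaibio_domain_error", "error", "condition")))
  }
  if (any(intensity < 0)) {
    stop(errorCondition("intensities must be non-negative",
                        class = c("peptaibio_domain_error", "error", "condition")))
  }
  if (is.null(kind)) kind <- rep(NA_character_, length(mz))
  known <- c("MNa", "M2Na", "b", "y7", "ms2")
  bad <- setdiff(stats::na.omit(unique(kind)), known)
  if (length(bad)) {
    stop(errorCondition(sprintf("unknown ion kind(s): %s", paste(bad, collapse = ", ")),
                        class = c("peptaibio_format_error", "error", "condition")))
  }
  df <- data.frame(mz = mz, intensity = as.numeric(intensity),
                   kind = as.character(kind), stringsAsFactors = FALSE)
  df <- df[order(df$mz), , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "rt") <- as.numeric(rt)[1]
  class(df) <- c("peak_list", "data.frame")
  df
}

#' Read a peak-list CSV
#'
#' Required column `mz`; optional `intensity`, `kind`, `rt` (UTF-8, decimal
#' point, header required).
#'
#' @param path CSV path.
#' @return a [peak_list()].
#' @export
read_peak_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"mz" %in% names(df)) {
    stop(errorCondition(sprintf("peak CSV '%s' is missing required column 'mz'", path),
                        class = c("peptaibio_format_error", "error", "condition")))
  }
  peak_list(df$mz,
            intensity = if ("intensity" %in% names(df)) df$intensity else rep(1, nrow(df)),
            kind = if ("kind" %in% names(df)) ifelse(nzchar(df$kind), df$kind, NA) else NULL,
            rt = if ("rt" %in% names(df)) df$rt[1] else NA_real_)
}

#' Write a peak-list CSV
#'
#' @param peaks a [peak_list()].
#' @param path output path.
#' @export
write_peak_csv <- function(peaks, path) {
  df <- as.data.frame(peaks)
  df$kind <- ifelse(is.na(df$kind), "", df$kind)
  df$rt <- attr(peaks, "rt")
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.peak_list <- function(x, ...) {
  cat(sprintf("<peak_list> %d peaks, rt = %s min\n", nrow(x),
              ifelse(is.na(attr(x, "rt")), "NA", format(attr(x, "rt")))))
  print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat(sprintf("  ... %d more\n", nrow(x) - 10))
  invisible(x)
}
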