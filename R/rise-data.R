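#' Construct a manometer rise dataset
#'
#' One replicate of the bench reading protocol: the times at which the
#' rising fluid column crossed successive graduations.  Times must be
#' strictly increasing and heights nondecreasing; duplicated times are
#' rejected rather than averaged.
#'
#' @param time crossing times in s.
#' @param height graduation heights in cm.
#' @param needle needle label.
#' @param replicate replicate label.
#' @return a data frame of class `rise_dataset` with columns `time` (s)
#'   and `height` (cm), carrying `needle` and `replicate` attributes.
#' @export
rise_dataset <- function(time, height, needle = "needle",
                         replicate = "M1") {
  if (length(time) != length(height)) {
    stop_domain("rise_dataset", "time and height must have equal length")
  }
  if (any(time < 0)) stop_domain("time", "must be >= 0")
  if (any(height < 0)) stop_domain("height", "must be >= 0")
  if (any(diff(time) <= 0)) {
    stop_domain("time", "must be strictly increasing within a replicate")
  }
  if (any(diff(height) < 0)) {
    stop_domain("height", "must be nondecreasing")
  }
  structure(data.frame(time = as.numeric(time), height = as.numeric(height)),
            needle = needle, replicate = replicate,
            class = c("rise_dataset", "data.frame"))
}

#' @export
print.rise_dataset <- function(x, ...) {
  cat(sprintf("Rise dataset: %s, replicate %s, %d observations (%.1f-%.1f cm)\n",
              attr(x, "needle"), attr(x, "replicate"), nrow(x),
              min(x$height), max(x$height)))
  print.data.frame(x, ...)
  invisible(x)
}

parse_decimal <- function(x, decimal_comma = FALSE) {
  if (decimal_comma) x <- gsub(",", ".", x, fixed = TRUE)
  suppressWarnings(as.numeric(x))   # NAs are reported by the caller
}

#' Read and write rise datasets as CSV
#'
#' The on-disk dialect has header `needle,replicate,height_cm,time_s`, one
#' row per graduation crossing.  European-style decimal commas in the
#' numeric columns are accepted via `decimal_comma = TRUE` (they are
#' normalised to points on read; files are always written with points).
#'
#' @param path file path.
#' @param decimal_comma if `TRUE`, treat `,` as the decimal separator in
#'   `height_cm` and `time_s`.
#' @return `read_rise_csv()`: a list of [rise_dataset()] objects, one per
#'   needle/replicate pair, in file order.  `write_rise_csv()`: `path`,
#'   invisibly.
#' @export
read_rise_csv <- function(path, decimal_comma = FALSE) {
  raw <- utils::read.csv(path, colClasses = "character",
                         strip.white = TRUE)
  need <- c("needle", "replicate", "height_cm", "time_s")
  if (!all(need %in% names(raw))) {
    stop("rise CSV must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  raw$height_cm <- parse_decimal(raw$height_cm, decimal_comma)
  raw$time_s <- parse_decimal(raw$time_s, decimal_comma)
  if (any(is.na(raw$height_cm)) || any(is.na(raw$time_s))) {
    stop("non-numeric height or time in ", path,
         " (decimal commas? set decimal_comma = TRUE)", call. = FALSE)
  }
  key <- paste(raw$needle, raw$replicate, sep = "\r")
  out <- lapply(split(raw, factor(key, levels = unique(key))), function(d) {
    rise_dataset(d$time_s, d$height_cm,
                 needle = d$needle[1], replicate = d$replicate[1])
  })
  names(out) <- vapply(out, function(d) {
    paste(attr(d, "needle"), attr(d, "replicate"))
  }, character(1))
  out
}

#' @rdname read_rise_csv
#' @param datasets a [rise_dataset()] or list of them.
#' @export
write_rise_csv <- function(datasets, path) {
  if (inherits(datasets, "rise_dataset")) datasets <- list(datasets)
  rows <- do.call(rbind, lapply(datasets, function(d) {
    data.frame(needle = attr(d, "needle"), replicate = attr(d, "replicate"),
               height_cm = d$height, time_s = d$time)
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read (resistance, time-constant) pairs from CSV
#'
#' Dialect: header `needle,R_cm_s_per_ml,tau_s`, one row per needle.
#'
#' @inheritParams read_rise_csv
#' @return a data frame with columns `needle`, `R` (cmH2O.s/ml) and
#'   `tau` (s).
#' @seealso [tau_r_regression()]
#' @export
read_tau_resistance_csv <- function(path, decimal_comma = FALSE) {
  raw <- utils::read.csv(path, colClasses = "character", strip.white = TRUE)
  need <- c("needle", "R_cm_s_per_ml", "tau_s")
  if (!all(need %in% names(raw))) {
    stop("pairs CSV must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  data.frame(needle = raw$needle,
             R = parse_decimal(raw$R_cm_s_per_ml, decimal_comma),
             tau = parse_decimal(raw$tau_s, decimal_comma))
}
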