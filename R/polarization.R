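# Electrode polarization statistics: mean DC level and the standard
# average exchange ratio (mean absolute sample-to-sample change), with
# interquartile-range outlier removal.

# accept a polarization tibble (column potential_mv) or a bare numeric vector
polarization_values <- function(series) {
  if (is.data.frame(series)) {
    if (!"potential_mv" %in% names(series)) {
      stop("polarization series needs a `potential_mv` column")
    }
    series$potential_mv
  } else if (is.numeric(series)) {
    series
  } else {
    stop("series must be a data frame or numeric vector")
  }
}

#' Standard average exchange ratio of a polarization series
#'
#' The mean absolute first difference
#' \deqn{\bar{X}_i = \frac{\sum_t |X_i(t) - X_i(t+1)|}{N - 1}}
#' of a DC polarization series, reported in microvolt per sampling
#' interval. For the 10 samples/s acquisition protocol the interval is
#' 0.1 s, recorded in attribute `interval_s`.
#'
#' @param series Polarization series: a tibble with column `potential_mv`
#'   (millivolt) or a bare numeric vector in mV. At least 2 samples.
#' @param fs Sampling rate in Hz; taken from the series attribute if
#'   absent, defaulting to 10.
#' @return Exchange ratio in microvolt, with attribute `interval_s`.
#' @examples
#' exchange_ratio(c(0, 3, 1, 1)) # (3 + 2 + 0) / 3 mV = 1666.7 uV
#' @export
exchange_ratio <- function(series, fs = NULL) {
  x <- polarization_values(series)
  if (length(x) < 2) stop("exchange ratio needs at least 2 samples")
  if (is.null(fs)) fs <- attr(series, "fs") %||% 10
  out <- mean(abs(diff(x))) * 1000
  attr(out, "interval_s") <- 1 / fs
  out
}

#' Group mean of per-series exchange ratios
#'
#' The grand statistic \eqn{\bar{X} = \sum_i \bar{X}_i / n}: the unweighted
#' mean of per-individual exchange ratios.
#'
#' @param series_list Either a list of polarization series (each passed to
#'   [exchange_ratio()]) or a numeric vector of already-computed
#'   per-series ratios in microvolt.
#' @return Group mean exchange ratio in microvolt.
#' @examples
#' group_exchange_ratio(c(667.14, 133.87, 399.55, 35.17))
#' @export
group_exchange_ratio <- function(series_list) {
  if (is.numeric(series_list) && !is.list(series_list)) {
    ratios <- series_list
  } else if (is.list(series_list) && !is.data.frame(series_list)) {
    ratios <- vapply(series_list, function(s) as.numeric(exchange_ratio(s)),
                     numeric(1))
  } else {
    ratios <- as.numeric(exchange_ratio(series_list))
  }
  if (length(ratios) < 1) stop("empty series list")
  mean(ratios)
}

#' Interquartile-range outlier filter
#'
#' Tukey fences: values outside `[Q1 - 1.5 IQR, Q3 + 1.5 IQR]` are flagged
#' as outliers, with quartiles computed by linear interpolation
#' (`stats::quantile` type 7). With fewer than 4 values the data pass
#' through unfiltered with a warning.
#'
#' @param values Numeric vector.
#' @param k Fence multiplier (default 1.5).
#' @return A list with `retained` (values inside the fences) and `outlier`
#'   (logical mask, `TRUE` for removed values).
#' @examples
#' iqr_filter(c(1, 2, 3, 4, 100))
#' @export
iqr_filter <- function(values, k = 1.5) {
  stopifnot(is.numeric(values))
  if (length(values) < 4) {
    warning("fewer than 4 values: IQR filter passes data through")
    return(list(retained = values, outlier = rep(FALSE, length(values))))
  }
  q <- stats::quantile(values, c(0.25, 0.75), names = FALSE, type = 7)
  fence <- c(q[1] - k * (q[2] - q[1]), q[2] + k * (q[2] - q[1]))
  out <- values < fence[1] | values > fence[2]
  list(retained = values[!out], outlier = out)
}

#' Mean DC polarization level
#'
#' Mean absolute DC potential of a polarization series, optionally after
#' IQR outlier removal of the sample values. The absolute-value convention
#' makes the level polarity-independent.
#'
#' @param series Polarization series (tibble with `potential_mv` or
#'   numeric vector, mV), at least 2 samples.
#' @param outlier_removal Apply [iqr_filter()] to the samples first?
#' @return Mean polarization level in mV (non-negative).
#' @examples
#' mean_polarization(c(-2, 2))
#' @export
mean_polarization <- function(series, outlier_removal = FALSE) {
  x <- polarization_values(series)
  if (length(x) < 2) stop("mean polarization needs at least 2 samples")
  if (outlier_removal) {
    x <- suppressWarnings(iqr_filter(x)$retained)
    if (length(x) == 0) stop("all samples removed as outliers")
  }
  mean(abs(x))
}
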