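#' Six-number summary of a numeric vector
#'
#' min, 25% quantile, median, mean, 75% quantile and max, with quantiles
#' computed by linear interpolation between order statistics (type 7).
#'
#' @param values non-empty numeric vector of finite values.
#' @return A [SummaryStats-class] object.
#' @examples
#' summaryStats(c(1, 2, 3, 4))
#' @export
summaryStats <- function(values) {
  values <- as.numeric(values)
  if (!length(values)) stop("cannot summarize an empty vector", call. = FALSE)
  if (any(!is.finite(values)))
    stop("values must be finite", call. = FALSE)
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  new("SummaryStats", min = min(values), q25 = q[1], median = q[2],
      mean = mean(values), q75 = q[3], max = max(values))
}

# Interval estimate from a vector of Monte-Carlo totals.
.intervalFromDraws <- function(draws, level) {
  if (level <= 0 || level >= 1)
    stop("interval level must be in (0, 1)", call. = FALSE)
  alpha <- (1 - level) / 2
  q <- stats::quantile(draws, c(alpha, 0.5, 1 - alpha), names = FALSE,
                       type = 7)
  new("IntervalEstimate", lower = q[1], median = q[2], upper = q[3],
      level = level)
}
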