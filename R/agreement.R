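# Agreement between two paired measurement series: Pearson correlation and
# Bland-Altman limits of agreement, used to validate pipeline-derived
# breath durations and beat counts against a reference.

#' Pearson product-moment correlation
#'
#' @param x,y Equal-length numeric series (n >= 3).
#' @return Correlation coefficient in `[-1, 1]`; `NA` when either series
#'   has zero variance.
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch", call. = FALSE)
  if (length(x) < 3) stop("need at least 3 pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y, method = "pearson")
}

#' Bland-Altman limits of agreement
#'
#' Differences are taken as estimate minus reference, `d = x - y`. The
#' limits of agreement are \eqn{\bar d \pm 1.96\,\mathrm{SD}(d)} (SD with
#' n-1 denominator); points exactly on a limit count as within (closed
#' interval).
#'
#' @param x Estimate series.
#' @param y Reference series, same length (n >= 3).
#' @return Object of class `agreement_result`: `pearson_r`, `mean_diff`,
#'   `sd_diff`, `loa_low`, `loa_high`, `pct_within`, `n`.
#' @export
bland_altman <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch", call. = FALSE)
  if (length(x) < 3) stop("need at least 3 pairs", call. = FALSE)
  d <- x - y
  md <- mean(d)
  sdd <- stats::sd(d)
  loa <- md + c(-1, 1) * 1.96 * sdd
  structure(
    list(pearson_r = pearson(x, y), mean_diff = md, sd_diff = sdd,
         loa_low = loa[1], loa_high = loa[2],
         pct_within = 100 * mean(d >= loa[1] & d <= loa[2]),
         n = length(x)),
    class = "agreement_result")
}

#' @export
print.agreement_result <- function(x, ...) {
  cat(sprintf("<agreement_result> n = %d | r = %s | d-bar = %.4g | SD = %.4g\n",
              x$n, ifelse(is.na(x$pearson_r), "NA",
                          sprintf("%.4f", x$pearson_r)),
              x$mean_diff, x$sd_diff))
  cat(sprintf("  95%% LoA [%.4g, %.4g]; %.1f%% of pairs within\n",
              x$loa_low, x$loa_high, x$pct_within))
  invisible(x)
}
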