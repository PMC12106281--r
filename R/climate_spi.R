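# Gamma maximum likelihood via the profile score equation: at the MLE,
# log(shape) - digamma(shape) = log(mean(x)) - mean(log(x)) and
# rate = shape / mean(x). One-dimensional and monotone, so a bracketed
# root search is unconditionally stable (general-purpose optimizers fail
# sporadically on small samples here).
gamma_mle <- function(x) {
  stopifnot(all(x > 0))
  s <- log(mean(x)) - mean(log(x))
  if (s <= 0) stop_hs("degenerate sample: zero log-dispersion")
  f <- function(a) log(a) - digamma(a) - s
  root <- uniroot(f, lower = 1e-10, upper = 1e10, tol = 1e-12)$root
  list(shape = root, rate = root / mean(x))
}

#' Trailing rolling sums of a monthly precipitation series
#'
#' @param series data frame `(year, month, mm)` with contiguous months, or
#'   a numeric vector of monthly totals.
#' @param window accumulation window in months (12 for the annual-scale
#'   index).
#' @return Data frame `(year, month, sum_mm)` aligned to the window's end
#'   month (length `n - window + 1`), or a plain vector if the input was a
#'   vector.
#' @export
#' @examples
#' rolling_sum(rep(10, 24), window = 12)   # all 120
rolling_sum <- function(series, window = 12L) {
  window <- check_count(window, "window")
  vec_in <- is.numeric(series) && is.null(dim(series))
  if (vec_in) {
    mm <- series
  } else {
    check_columns(series, c("year", "month", "mm"), "precipitation series")
    idx <- series$year * 12 + series$month
    if (any(diff(idx) != 1))
      stop_hs("months must be contiguous")
    mm <- series$mm
  }
  if (any(mm < 0, na.rm = TRUE)) stop_hs("precipitation must be >= 0")
  n <- length(mm)
  if (n < window)
    stop_hs(sprintf("series (%d months) shorter than the window (%d)",
                    n, window))
  cs <- cumsum(c(0, mm))
  sums <- cs[(window + 1):(n + 1)] - cs[1:(n - window + 1)]
  if (vec_in) return(sums)
  ends <- window:n
  data.frame(year = series$year[ends], month = series$month[ends],
             sum_mm = sums)
}

#' Standardized Precipitation Index from rolling sums
#'
#' Fits a gamma distribution by maximum likelihood to the positive rolling
#' sums, treats zero sums through a mixed distribution
#' \eqn{H(x) = q + (1 - q)\,F_{\Gamma}(x)} with \eqn{q} the zero fraction,
#' and maps each sum to standard-normal units:
#' \eqn{SPI = \Phi^{-1}(H(x))}. Negative SPI indicates drier-than-typical
#' conditions. All windows are pooled into a single fit by default (the
#' long-term single-trace presentation); pass `by_month = TRUE` to fit
#' separately per ending calendar month (requires `month` metadata).
#'
#' @param sums numeric vector of rolling sums, or the data frame from
#'   [rolling_sum()].
#' @param by_month fit separately for each ending calendar month.
#' @return An object of class `spi_series`: data frame (or vector input
#'   returned as data frame with `sum_mm`) with added column `spi`, and
#'   attribute `fit` = list(shape, rate, q) (per month when `by_month`).
#' @export
#' @examples
#' pr <- gen_precip(gen_config(seed = 1, n_years = 40))
#' s <- fit_spi(rolling_sum(pr))
#' summary(s$spi)
fit_spi <- function(sums, by_month = FALSE) {
  df <- if (is.numeric(sums) && is.null(dim(sums)))
    data.frame(sum_mm = sums) else sums
  check_columns(df, "sum_mm", "rolling sums")
  x <- df$sum_mm
  if (length(x) < 30L)
    warning("fewer than 30 rolling sums: the gamma fit will be unstable",
            call. = FALSE)
  if (var(x) == 0) stop_hs("zero variance in the rolling sums")

  fit_one <- function(xx) {
    pos <- xx[xx > 0]
    q <- 1 - length(pos) / length(xx)
    if (length(pos) < 4L)
      stop_hs("too few positive sums for a gamma fit")
    g <- gamma_mle(pos)
    list(shape = g$shape, rate = g$rate, q = q)
  }
  spi_one <- function(xx, f) {
    h <- ifelse(xx > 0,
                f$q + (1 - f$q) * pgamma(xx, shape = f$shape,
                                         rate = f$rate),
                pmax(f$q, .Machine$double.eps))
    # clip away exact 0/1 so the normal quantile stays finite
    h <- pmin(pmax(h, 1e-12), 1 - 1e-12)
    qnorm(h)
  }

  if (by_month) {
    check_columns(df, "month", "rolling sums (by_month = TRUE)")
    fits <- list()
    spi <- numeric(nrow(df))
    for (m in sort(unique(df$month))) {
      sel <- df$month == m
      f <- fit_one(x[sel])
      fits[[as.character(m)]] <- f
      spi[sel] <- spi_one(x[sel], f)
    }
    df$spi <- spi
    attr(df, "fit") <- fits
  } else {
    f <- fit_one(x)
    df$spi <- spi_one(x, f)
    attr(df, "fit") <- f
  }
  class(df) <- c("spi_series", "data.frame")
  df
}
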