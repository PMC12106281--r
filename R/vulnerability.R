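#' Sigmoid vulnerability model: percent embolism at a water potential
#'
#' The vulnerability curve relating leaf xylem percent embolism to water
#' potential \eqn{\Psi} (MPa):
#' \deqn{PE(\Psi) = 100 - \frac{100}{1 + e^{a (\Psi - b)}},}
#' where `a` (MPa\eqn{^{-1}}, negative) sets the sensitivity to declining
#' water potential (proportional to the slope at the midpoint) and `b`
#' (MPa) is the water potential at 50\% embolism (P50).
#'
#' @param psi water potential, MPa (any real value).
#' @param a steepness parameter, MPa^-1 (negative for a physical curve).
#' @param b P50, MPa.
#' @return Percent embolism in (0, 100); strictly decreasing in `psi` when
#'   `a < 0`.
#' @export
#' @examples
#' sigmoid_pe(-8.02, a = -2.23, b = -8.02)  # 50 at P50
sigmoid_pe <- function(psi, a, b) {
  100 - 100 / (1 + exp(a * (psi - b)))
}

#' Water potential at x percent embolism
#'
#' Closed-form inverse of [sigmoid_pe()]:
#' \deqn{\Psi_x = b + \log\{x / (100 - x)\} / a.}
#' `px(a, b, 50)` is `b`; `px(a, b, 12)` and `px(a, b, 88)` are the
#' conventional onset (P12) and severe-impairment (P88) thresholds.
#'
#' @param a,b sigmoid parameters, see [sigmoid_pe()].
#' @param x percent embolism, strictly between 0 and 100.
#' @return Water potential, MPa.
#' @export
#' @examples
#' px(-2.23, -8.02, 12)   # P12
px <- function(a, b, x) {
  if (any(x <= 0 | x >= 100))
    stop_hs("`x` must be strictly between 0 and 100")
  b + log(x / (100 - x)) / a
}

#' Fit the sigmoid vulnerability model to an embolism trace
#'
#' Nonlinear least squares of cumulative percent embolism on water
#' potential under the model of [sigmoid_pe()]. Starting values are
#' data-driven: `b0` is the water potential at the first crossing of 50\%
#' embolism and `a0` comes from the empirical spread between the 20\% and
#' 80\% crossings. If the first attempt fails, up to `restarts`
#' deterministically jittered re-initializations are tried before the best
#' iterate is reported as an error.
#'
#' Traces that never span below 20\% and above 80\% cumulative embolism
#' cannot pin both parameters; such fits carry
#' `poorly_constrained = TRUE`.
#'
#' For an `embolism_trace` (the empirical CDF of discrete pixel events
#' built by [cumulate()]), two estimator refinements apply. The cumulative
#' percentages are shifted to the midpoint (Hazen) plotting position
#' `cum - increment/2` before fitting: the inclusive cumulative sum
#' evaluates the CDF *after* each frame's events, which biases the fitted
#' P50 toward less negative values by about half a frame's event mass. And
#' the standard error of `b` is the quantile-estimator (delta-method)
#' value \eqn{2 / (|a| \sqrt{N})} with \eqn{N} the total embolized pixels
#' -- the sampling unit is the embolism event, and the naive nonlinear
#' least-squares SE on heavily autocorrelated cumulative points
#' understates the true replicate-to-replicate spread severalfold. Plain
#' `(psi_mpa, cum_pct)` data frames (e.g. model-evaluated curves) are
#' fitted as-is with the least-squares SEs.
#'
#' @param trace an `embolism_trace` (see [cumulate()]), or any data frame
#'   with columns `psi_mpa` and `cum_pct`.
#' @param restarts number of jittered re-initializations.
#' @return An object of class `sigmoid_fit`: list with `a`, `b`, `a_se`,
#'   `b_se`, `rss`, `n_points`, `converged`, `poorly_constrained`.
#' @export
#' @examples
#' psi <- seq(-1, -9, by = -0.25)
#' tr <- data.frame(psi_mpa = psi, cum_pct = sigmoid_pe(psi, -2.23, -8.02))
#' fit_sigmoid(tr)
fit_sigmoid <- function(trace, restarts = 5L) {
  check_columns(trace, c("psi_mpa", "cum_pct"), "trace")
  is_ecdf <- inherits(trace, "embolism_trace")
  psi <- trace$psi_mpa
  pe <- trace$cum_pct
  if (is_ecdf) {
    inc <- diff(c(0, pe))
    pe <- pe - inc / 2
  }
  ok <- is.finite(psi) & is.finite(pe)
  psi <- psi[ok]; pe <- pe[ok]
  n <- length(psi)
  if (n < 5L) stop_hs("need at least 5 points to fit a sigmoid")
  poorly <- !(min(pe) < 20 && max(pe) > 80)
  if (poorly)
    warning("trace does not span <20% and >80% embolism: ",
            "fit is poorly constrained", call. = FALSE)

  crossing <- function(level) {
    i <- which(pe >= level)[1]
    if (is.na(i)) return(min(psi))
    if (i == 1L) return(psi[1])
    # linear interpolation between the bracketing points
    w <- (level - pe[i - 1]) / (pe[i] - pe[i - 1])
    psi[i - 1] + w * (psi[i] - psi[i - 1])
  }
  b0 <- crossing(50)
  spread <- crossing(20) - crossing(80)
  a0 <- if (is.finite(spread) && spread > 1e-8)
    2 * log(0.12 / 0.88) / spread else -1

  dat <- data.frame(psi = psi, pe = pe)
  try_fit <- function(a_s, b_s) {
    tryCatch(
      minpack.lm::nlsLM(pe ~ 100 - 100 / (1 + exp(a * (psi - b))),
                        data = dat, start = list(a = a_s, b = b_s),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
  }
  fit <- try_fit(a0, b0)
  if (is.null(fit)) {
    jit <- with_seed(20240615L, matrix(runif(2L * restarts, 0.5, 1.5),
                                       ncol = 2L))
    for (r in seq_len(restarts)) {
      fit <- try_fit(a0 * jit[r, 1], b0 * jit[r, 2])
      if (!is.null(fit)) break
    }
  }
  if (is.null(fit))
    stop_hs(sprintf(
      "sigmoid fit failed to converge after %d restarts (start a=%.3g, b=%.3g)",
      restarts, a0, b0))
  cf <- coef(fit)
  if (cf[["a"]] >= 0)
    stop_hs(sprintf(
      "non-physical fit: estimated a = %.3g >= 0 (embolism must increase as water potential falls)",
      cf[["a"]]))
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) c(a = NA_real_, b = NA_real_))
  if (is_ecdf) {
    npx <- attr(trace, "total_pixels") %||% attr(trace, "n_events")
    if (!is.null(npx) && npx > 0)
      se[["b"]] <- 2 / (abs(cf[["a"]]) * sqrt(npx))
  }
  structure(list(a = unname(cf[["a"]]), b = unname(cf[["b"]]),
                 a_se = unname(se[["a"]]), b_se = unname(se[["b"]]),
                 rss = sum(resid(fit)^2), n_points = n,
                 converged = fit$convInfo$isConv %||% TRUE,
                 poorly_constrained = poorly),
            class = "sigmoid_fit")
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' @export
print.sigmoid_fit <- function(x, ...) {
  cat("<sigmoid_fit>\n")
  cat(sprintf("  a = %.4f +/- %.4f MPa^-1\n", x$a, x$a_se))
  cat(sprintf("  b (P50) = %.4f +/- %.4f MPa\n", x$b, x$b_se))
  cat(sprintf("  rss = %.4g, n = %d, converged = %s%s\n", x$rss,
              x$n_points, x$converged,
              if (x$poorly_constrained) ", POORLY CONSTRAINED" else ""))
  invisible(x)
}

#' Species-mean vulnerability curve from individual fits
#'
#' Species parameters are the arithmetic means of the individual leaves'
#' fitted parameters (matching the reporting convention of per-species
#' mean +/- SE of P50 and slope), with P12/P50/P88 evaluated from
#' [px()] at the mean parameters.
#'
#' @param fits list of `sigmoid_fit` objects (non-converged fits are
#'   dropped with a warning).
#' @param species optional species label.
#' @return An object of class `species_curve`: list with `a_mean`, `a_se`,
#'   `b_mean`, `b_se`, `p12`, `p50`, `p88`, `n_individuals`.
#' @export
species_curve <- function(fits, species = NA_character_) {
  if (inherits(fits, "sigmoid_fit")) fits <- list(fits)
  if (!length(fits)) stop_hs("no fits supplied")
  stopifnot(all(vapply(fits, inherits, TRUE, "sigmoid_fit")))
  conv <- vapply(fits, function(f) isTRUE(f$converged), TRUE)
  if (!any(conv)) stop_hs("no converged fits")
  if (!all(conv))
    warning(sum(!conv), " non-converged fit(s) dropped", call. = FALSE)
  fits <- fits[conv]
  a <- vapply(fits, `[[`, numeric(1), "a")
  b <- vapply(fits, `[[`, numeric(1), "b")
  n <- length(fits)
  se <- function(v) if (n > 1L) sd(v) / sqrt(n) else NA_real_
  am <- mean(a); bm <- mean(b)
  structure(list(species = species, a_mean = am, a_se = se(a),
                 b_mean = bm, b_se = se(b),
                 p12 = px(am, bm, 12), p50 = bm, p88 = px(am, bm, 88),
                 n_individuals = n),
            class = "species_curve")
}

#' @export
print.species_curve <- function(x, ...) {
  cat(sprintf("<species_curve> %s (n = %d)\n", x$species, x$n_individuals))
  cat(sprintf("  a = %.3f +/- %s MPa^-1, P50 = %.3f +/- %s MPa\n",
              x$a_mean, format(x$a_se, digits = 3),
              x$b_mean, format(x$b_se, digits = 3)))
  cat(sprintf("  P12 = %.3f, P88 = %.3f MPa\n", x$p12, x$p88))
  invisible(x)
}

#' Plot an embolism trace and its sigmoid fit
#'
#' @param x a `sigmoid_fit`.
#' @param trace optional trace the fit came from (points are drawn).
#' @param ... passed to [graphics::plot()].
#' @export
plot.sigmoid_fit <- function(x, trace = NULL, ...) {
  rng <- c(px(x$a, x$b, 99.5), px(x$a, x$b, 0.5))
  if (!is.null(trace)) rng <- range(c(rng, trace$psi_mpa))
  psi <- seq(rng[1], rng[2], length.out = 200)
  graphics::plot(psi, sigmoid_pe(psi, x$a, x$b), type = "l",
                 xlab = "Water potential (MPa)",
                 ylab = "Percent embolism (%)", ylim = c(0, 100), ...)
  if (!is.null(trace))
    graphics::points(trace$psi_mpa, trace$cum_pct, pch = 16,
                     col = "grey40")
  graphics::abline(v = x$b, lty = 2)
  invisible(x)
}
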