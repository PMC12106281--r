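#' Construct a pressure-volume curve object
#'
#' Pairs the bench-drying observations (fresh mass, water potential) with
#' the leaf's dry mass and a measured or extrapolated turgid mass, and
#' derives relative water content (RWC) per point.
#'
#' @param points data frame with columns `fresh_mass_g` and `psi_mpa`
#'   (water potential <= 0), ordered along drying.
#' @param dry_mass oven-dry mass, g; must be below every fresh mass.
#' @param turgid_mass fully-hydrated mass, g; `NULL` to estimate via
#'   [estimate_turgid_mass()].
#' @return An object of class `pv_curve`: the points plus `rwc`, with
#'   `dry_mass` and `turgid_mass` attributes.
#' @export
pv_curve <- function(points, dry_mass, turgid_mass = NULL) {
  check_columns(points, c("fresh_mass_g", "psi_mpa"), "PV points")
  if (any(points$psi_mpa > 0))
    stop_hs("water potential must be <= 0 everywhere")
  check_number(dry_mass, "dry_mass", lower = 0)
  if (dry_mass >= min(points$fresh_mass_g))
    stop_hs("dry_mass must be below the smallest fresh mass")
  if (is.null(turgid_mass)) turgid_mass <- estimate_turgid_mass(points)
  if (turgid_mass < max(points$fresh_mass_g))
    stop_hs("turgid_mass must be at least the largest fresh mass")
  out <- points
  out$rwc <- compute_rwc(points, dry_mass, turgid_mass)
  attr(out, "dry_mass") <- dry_mass
  attr(out, "turgid_mass") <- turgid_mass
  class(out) <- c("pv_curve", "data.frame")
  out
}

#' Estimate turgid mass from the wettest points of a drying series
#'
#' If the series contains a point at (numerically) zero water potential its
#' fresh mass is returned directly. Otherwise fresh mass is regressed on
#' water potential over the wettest points (those above `psi_cut`) and
#' extrapolated to zero; with fewer than 3 such points the maximum fresh
#' mass is used. The result is never below the maximum observed fresh
#' mass.
#'
#' @param points data frame with `fresh_mass_g` and `psi_mpa`.
#' @param psi_cut water potential above which points are considered "wet"
#'   enough for the linear extrapolation, MPa.
#' @return Estimated turgid mass, g.
#' @export
estimate_turgid_mass <- function(points, psi_cut = -1) {
  check_columns(points, c("fresh_mass_g", "psi_mpa"), "PV points")
  at_zero <- points$psi_mpa > -1e-8
  if (any(at_zero)) return(max(points$fresh_mass_g[at_zero]))
  wet <- points$psi_mpa > psi_cut
  if (sum(wet) >= 3L) {
    f <- lm(fresh_mass_g ~ psi_mpa, data = points[wet, , drop = FALSE])
    est <- unname(coef(f)[1])
  } else {
    est <- max(points$fresh_mass_g)
  }
  max(est, max(points$fresh_mass_g))
}

#' Relative water content per point
#'
#' `rwc = (fresh - dry) / (turgid - dry)`, clipped into `(0, 1]`.
#'
#' @param points data frame with `fresh_mass_g`.
#' @param dry_mass,turgid_mass leaf dry and turgid mass, g.
#' @return Numeric vector of RWC values.
#' @export
compute_rwc <- function(points, dry_mass, turgid_mass) {
  check_columns(points, "fresh_mass_g", "PV points")
  if (turgid_mass <= dry_mass)
    stop_hs("turgid_mass must exceed dry_mass")
  rwc <- (points$fresh_mass_g - dry_mass) / (turgid_mass - dry_mass)
  pmin(pmax(rwc, .Machine$double.eps), 1)
}

#' Locate the linear (post-turgor-loss) tail of a PV curve
#'
#' In the transformed presentation 1/\eqn{\Psi} against water deficit
#' \eqn{d = 1 - RWC}, points beyond turgor loss fall on a straight line
#' (the osmotic line) while points with positive turgor curve away from
#' it. The dry-end suffix is grown point by point from the three driest
#' observations; a candidate point joins the tail while the extended fit
#' keeps \eqn{r^2 \ge} `r2_min` *and* the candidate's residual from the
#' current line does not exceed `max(resid_k * RMSE, abs_tol)`. The
#' residual gate makes the rule exact on noiseless data (where the tail
#' RMSE is zero, so any point off the line is rejected) while the
#' \eqn{r^2} threshold governs noisy data.
#'
#' @param curve a [pv_curve()].
#' @param r2_min minimum r-squared of the tail fit (default 0.99).
#' @param resid_k residual-gate multiplier on the current tail RMSE.
#' @param abs_tol absolute residual floor of the gate (units of
#'   1/\eqn{\Psi}).
#' @return List with `tail_n` (points in the tail), `idx` (their row
#'   indices, wettest first), `slope`, `intercept` (of 1/\eqn{\Psi} on
#'   `d`), `tail_r2`.
#' @export
find_linear_tail <- function(curve, r2_min = 0.99, resid_k = 6,
                             abs_tol = 1e-8) {
  stopifnot(inherits(curve, "pv_curve"))
  check_number(r2_min, "r2_min", 0, 1)
  # the full-turgor point (psi ~ 0) is off-scale in 1/psi space
  usable <- which(curve$psi_mpa < -1e-9)
  n <- length(usable)
  if (n < 6L)
    stop_hs("need at least 6 points with psi < 0 to locate a linear tail")
  ord <- usable[order(curve$rwc[usable])]   # driest first
  d <- (1 - curve$rwc)[ord]
  y <- (1 / curve$psi_mpa)[ord]

  fit_stats <- function(k) {
    dd <- d[seq_len(k)]; yy <- y[seq_len(k)]
    f <- lm(yy ~ dd)
    ssr <- sum(resid(f)^2)
    sst <- sum((yy - mean(yy))^2)
    list(slope = unname(coef(f)[2]), intercept = unname(coef(f)[1]),
         r2 = if (sst > 0) 1 - ssr / sst else 1,
         rmse = sqrt(ssr / k), f = f)
  }

  k <- 3L
  st <- fit_stats(k)
  if (st$r2 < r2_min)
    stop_hs(sprintf(
      "no linear region: the 3 driest points have r^2 = %.4f < %.4f",
      st$r2, r2_min))
  while (k < n) {
    cand_res <- abs(y[k + 1L] - (st$intercept + st$slope * d[k + 1L]))
    if (cand_res > max(resid_k * st$rmse, abs_tol)) break
    st_new <- fit_stats(k + 1L)
    if (st_new$r2 < r2_min) break
    k <- k + 1L
    st <- st_new
  }
  list(tail_n = k, idx = rev(ord[seq_len(k)]), slope = st$slope,
       intercept = st$intercept, tail_r2 = st$r2)
}

#' Extract pressure-volume traits from a curve and its linear tail
#'
#' From the osmotic line \eqn{1/\Psi = c_0 + c_1 d} fitted to the
#' post-turgor-loss tail: the osmotic potential at full turgor is
#' \eqn{\pi_o = -1/c_0} (reported as a positive magnitude, the trait-table
#' convention); the turgor loss point is the water potential of the
#' wettest tail point (the breakpoint datum) or, with
#' `tlp_method = "intersection"`, the closed-form water potential at which
#' the modelled turgor pressure reaches zero. Turgor pressure at each
#' pre-breakpoint point is \eqn{\Psi - \Psi_s} with
#' \eqn{\Psi_s = -\pi_o / RWC} (apoplastic water fraction assumed zero),
#' and the bulk elastic modulus \eqn{\varepsilon = \Delta P / (\Delta V /
#' V)} is the OLS slope of turgor pressure on RWC over those points.
#'
#' @param curve a [pv_curve()].
#' @param tail result of [find_linear_tail()]; computed if `NULL`.
#' @param tlp_method `"breakpoint"` (default) or `"intersection"`.
#' @param r2_min passed to [find_linear_tail()] when `tail` is `NULL`.
#' @return An object of class `pv_traits`: list with `tlp`, `psi_osm_ft`
#'   (positive magnitude), `eps`, `tail_n`, `tail_r2`.
#' @export
#' @examples
#' p <- species_params("Euclea", -2.23, -8.02, 2.92, 12.43)
#' pv <- gen_pv_series(p, gen_config(seed = 1))
#' cv <- pv_curve(pv$points, pv$dry_mass)
#' extract_pv_traits(cv)
extract_pv_traits <- function(curve, tail = NULL,
                              tlp_method = c("breakpoint", "intersection"),
                              r2_min = 0.99) {
  stopifnot(inherits(curve, "pv_curve"))
  tlp_method <- match.arg(tlp_method)
  if (is.null(tail)) tail <- find_linear_tail(curve, r2_min = r2_min)
  if (tail$intercept >= 0)
    stop_hs("invalid osmotic intercept: the tail line must cross 1/psi < 0")
  psi_osm_ft <- -1 / tail$intercept
  wettest_tail <- tail$idx[1]
  tlp <- if (tlp_method == "breakpoint") {
    curve$psi_mpa[wettest_tail]
  } else {
    if (psi_osm_ft >= 0 && is.finite(psi_osm_ft)) {
      # eps from the pre-breakpoint points below, then closed form
      NA_real_   # placeholder, set after eps
    } else NA_real_
  }

  pre <- setdiff(seq_len(nrow(curve)), tail$idx)
  pre <- pre[curve$rwc[pre] > curve$rwc[wettest_tail]]
  if (length(pre) >= 3L) {
    psi_s <- -psi_osm_ft / curve$rwc[pre]
    turgor <- curve$psi_mpa[pre] - psi_s
    ef <- lm(turgor ~ curve$rwc[pre])
    eps <- unname(coef(ef)[2])
  } else {
    eps <- NA_real_
  }
  if (tlp_method == "intersection")
    tlp <- if (is.finite(eps) && eps > psi_osm_ft)
      closed_form_tlp(psi_osm_ft, eps) else curve$psi_mpa[wettest_tail]

  structure(list(tlp = tlp, psi_osm_ft = psi_osm_ft, eps = eps,
                 tail_n = tail$tail_n, tail_r2 = tail$tail_r2),
            class = "pv_traits")
}

#' @export
print.pv_traits <- function(x, ...) {
  cat("<pv_traits>\n")
  cat(sprintf("  TLP = %.3f MPa\n", x$tlp))
  cat(sprintf("  psi_osm (full turgor, magnitude) = %.3f MPa\n",
              x$psi_osm_ft))
  cat(sprintf("  elastic modulus = %s MPa  (tail: n = %d, r^2 = %.4f)\n",
              format(x$eps, digits = 4), x$tail_n, x$tail_r2))
  invisible(x)
}

#' Closed-form turgor loss point of the linear-elasticity model
#'
#' Analytic oracle for the generator's pressure-volume model: with osmotic
#' potential magnitude \eqn{\pi_o} and elastic modulus \eqn{\varepsilon},
#' turgor vanishes at symplastic RWC \eqn{1 - \pi_o/\varepsilon}, where
#' \deqn{TLP = -\pi_o / (1 - \pi_o / \varepsilon).}
#'
#' @param psi_osm_ft magnitude of osmotic potential at full turgor, MPa
#'   (positive).
#' @param eps bulk elastic modulus, MPa; must exceed `psi_osm_ft`.
#' @return Turgor loss point, MPa (negative).
#' @export
#' @examples
#' closed_form_tlp(2.92, 12.43)   # -3.8166
closed_form_tlp <- function(psi_osm_ft, eps) {
  check_number(psi_osm_ft, "psi_osm_ft", lower = 0)
  check_number(eps, "eps", lower = 0)
  if (psi_osm_ft <= 0 || eps <= psi_osm_ft)
    stop_hs("need eps > psi_osm_ft > 0: otherwise turgor is never lost")
  -psi_osm_ft / (1 - psi_osm_ft / eps)
}

#' Plot a pressure-volume curve in transformed coordinates
#'
#' @param x a `pv_curve`.
#' @param tail optional result of [find_linear_tail()]; the tail line is
#'   drawn if given.
#' @param ... passed to [graphics::plot()].
#' @export
plot.pv_curve <- function(x, tail = NULL, ...) {
  d <- 1 - x$rwc
  graphics::plot(d, 1 / x$psi_mpa, xlab = "Water deficit (1 - RWC)",
                 ylab = expression(1 / Psi ~ (MPa^-1)), pch = 16, ...)
  if (!is.null(tail)) {
    graphics::abline(tail$intercept, tail$slope, lty = 2)
    graphics::points(d[tail$idx], (1 / x$psi_mpa)[tail$idx], pch = 16,
                     col = "firebrick")
  }
  invisible(x)
}
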