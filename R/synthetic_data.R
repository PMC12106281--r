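#' Species parameter set for the synthetic-data generators
#'
#' Bundles the ground-truth physiological parameters from which all synthetic
#' observations are generated: the sigmoid vulnerability-curve parameters
#' (steepness `a` and P50 `b`), the pressure-volume parameters (osmotic
#' potential at full turgor and bulk elastic modulus), an apoplastic water
#' fraction, per-period distributions of individual minimum water potential,
#' and optional linear-predictor coefficients for the damage model.
#'
#' @param name species label.
#' @param a sigmoid steepness, MPa^-1; must be negative (embolism increases
#'   as water potential falls).
#' @param b water potential at 50\% embolism (P50), MPa; must be negative.
#' @param psi_osm_ft magnitude of osmotic potential at full turgor, MPa
#'   (positive).
#' @param eps bulk elastic modulus, MPa (positive). Must exceed
#'   `psi_osm_ft`, otherwise turgor is never lost and the turgor loss point
#'   is undefined.
#' @param apoplastic_fraction fraction of leaf water held outside the
#'   symplast, in `[0, 1)`. Default 0, under which the pressure-volume
#'   analysis' symplast-equals-total-water assumption is exact.
#' @param psi_min_by_period named list mapping period label to a
#'   `c(mean =, sd =)` pair (MPa) for individual minimum water potential.
#' @param damage_coefs named list mapping damage-metric name to a named
#'   coefficient vector on trait columns (see [gen_damage_survey()]).
#' @return An object of class `species_params`.
#' @export
#' @examples
#' species_params("Euclea", a = -2.23, b = -8.02,
#'                psi_osm_ft = 2.92, eps = 12.43)
species_params <- function(name, a, b, psi_osm_ft, eps,
                           apoplastic_fraction = 0,
                           psi_min_by_period = list(),
                           damage_coefs = list()) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop_hs("`name` must be a non-empty string")
  check_number(a, "a")
  if (a >= 0) stop_hs("`a` must be negative")
  check_number(b, "b")
  if (b >= 0) stop_hs("`b` must be negative")
  check_number(psi_osm_ft, "psi_osm_ft")
  if (psi_osm_ft <= 0) stop_hs("`psi_osm_ft` must be positive")
  check_number(eps, "eps")
  if (eps <= psi_osm_ft)
    stop_hs("`eps` must exceed `psi_osm_ft`: otherwise turgor pressure ",
            "never reaches zero and the turgor loss point is undefined")
  check_number(apoplastic_fraction, "apoplastic_fraction", 0, 1)
  if (apoplastic_fraction >= 1)
    stop_hs("`apoplastic_fraction` must be < 1")
  if (!is.list(psi_min_by_period))
    stop_hs("`psi_min_by_period` must be a named list")
  for (p in names(psi_min_by_period)) {
    v <- psi_min_by_period[[p]]
    if (!is.numeric(v) || length(v) != 2L || is.na(v["mean"]) ||
        is.na(v["sd"]) || v["sd"] < 0)
      stop_hs(sprintf(
        "psi_min_by_period[['%s']] must be c(mean =, sd =) with sd >= 0", p))
  }
  structure(list(name = name, a = a, b = b, psi_osm_ft = psi_osm_ft,
                 eps = eps, apoplastic_fraction = apoplastic_fraction,
                 psi_min_by_period = psi_min_by_period,
                 damage_coefs = damage_coefs),
            class = "species_params")
}

#' @export
print.species_params <- function(x, ...) {
  cat(sprintf("<species_params> %s\n", x$name))
  cat(sprintf("  vulnerability: a = %.3f MPa^-1, b (P50) = %.3f MPa\n",
              x$a, x$b))
  cat(sprintf("  pressure-volume: psi_osm_ft = %.3f MPa, eps = %.3f MPa",
              x$psi_osm_ft, x$eps))
  cat(sprintf(" (TLP = %.3f MPa)\n", closed_form_tlp(x$psi_osm_ft, x$eps)))
  if (length(x$psi_min_by_period))
    cat("  periods:", paste(names(x$psi_min_by_period), collapse = ", "),
        "\n")
  invisible(x)
}

#' Configuration for the synthetic-data generators
#'
#' @param seed integer RNG seed; identical configuration and seed give
#'   byte-identical output.
#' @param n_pixels number of embolism events per leaf (each event is a small
#'   group of pixels changing together).
#' @param frame_interval minutes between successive images.
#' @param log_interval minutes between psychrometer water-potential logs.
#' @param duration_h total bench-drying duration, hours.
#' @param n_pv_points number of (mass, water potential) points per
#'   pressure-volume series.
#' @param mass_noise_sd Gaussian noise on fresh mass, g.
#' @param psi_noise_sd Gaussian noise on measured water potential, MPa.
#' @param n_individuals individuals per species in field campaigns.
#' @param n_years years of monthly precipitation to generate.
#' @param gamma_shape,gamma_scale parameters of the gamma distribution of
#'   monthly precipitation (mm).
#' @return An object of class `gen_config`.
#' @export
gen_config <- function(seed = 1L, n_pixels = 500L, frame_interval = 5,
                       log_interval = 10, duration_h = 48,
                       n_pv_points = 15L, mass_noise_sd = 0,
                       psi_noise_sd = 0, n_individuals = 10L,
                       n_years = 40L, gamma_shape = 2, gamma_scale = 15) {
  cfg <- list(seed = check_count(seed, "seed", min = 0L),
              n_pixels = check_count(n_pixels, "n_pixels"),
              frame_interval = check_number(frame_interval,
                                            "frame_interval", lower = 0),
              log_interval = check_number(log_interval, "log_interval",
                                          lower = 0),
              duration_h = check_number(duration_h, "duration_h", lower = 0),
              n_pv_points = check_count(n_pv_points, "n_pv_points"),
              mass_noise_sd = check_number(mass_noise_sd, "mass_noise_sd",
                                           lower = 0),
              psi_noise_sd = check_number(psi_noise_sd, "psi_noise_sd",
                                          lower = 0),
              n_individuals = check_count(n_individuals, "n_individuals"),
              n_years = check_count(n_years, "n_years"),
              gamma_shape = check_number(gamma_shape, "gamma_shape",
                                         lower = 0),
              gamma_scale = check_number(gamma_scale, "gamma_scale",
                                         lower = 0))
  class(cfg) <- "gen_config"
  cfg
}

#' Simulate an optical-vulnerability drying campaign for one leaf
#'
#' Inverse model of the optical measurement. The leaf dries on the bench
#' while a camera records frames every `frame_interval` minutes and a
#' psychrometer logs stem water potential every `log_interval` minutes.
#' Each embolism event has a water-potential threshold drawn from the
#' sigmoid vulnerability model by inversion:
#' \deqn{\Psi_u = b + \log(u / (1 - u)) / a, \quad u \sim U(0, 1),}
#' so that the fraction of events embolized by water potential \eqn{\Psi}
#' follows the sigmoid exactly. The event fires in the frame whose water
#' potential is nearest its threshold.
#'
#' The drying trajectory is linear in time from `psi_start` down to
#' `psi_end` (default: the water potential at 99.9\% embolism, so the curve
#' is observed essentially to completion).
#'
#' @param params a [species_params()] object.
#' @param cfg a [gen_config()] object; `cfg$n_pixels` must be at least 10
#'   (fewer events cannot constrain a sigmoid fit).
#' @param psi_start water potential at the start of drying, MPa.
#' @param psi_end water potential at the end of drying, MPa; `NULL` for the
#'   automatic 99.9\% point.
#' @param pixels_per_event integer pixel count per event, length 1 or
#'   `n_pixels`.
#' @return A list with elements
#'   \describe{
#'     \item{events}{data frame `(frame_idx, time_min, n_pixels)`, one row
#'       per frame with at least one event}
#'     \item{psychrometer}{data frame `(time_min, psi_mpa)`}
#'     \item{truth}{list with the generating `a`, `b` and total pixels}
#'   }
#' @export
#' @examples
#' p <- species_params("Euclea", -2.23, -8.02, 2.92, 12.43)
#' camp <- gen_embolism_campaign(p, gen_config(seed = 1, n_pixels = 200))
#' head(camp$events)
gen_embolism_campaign <- function(params, cfg = gen_config(),
                                  psi_start = -0.5, psi_end = NULL,
                                  pixels_per_event = 1L) {
  stopifnot(inherits(params, "species_params"), inherits(cfg, "gen_config"))
  if (cfg$n_pixels < 10L)
    stop_hs("n_pixels must be >= 10: fewer events cannot constrain ",
            "a vulnerability curve fit")
  if (is.null(psi_end))
    psi_end <- params$b + log(0.999 / 0.001) / params$a
  check_number(psi_start, "psi_start", upper = 0)
  if (psi_end >= psi_start)
    stop_hs("psi_end must be more negative than psi_start")

  duration <- cfg$duration_h * 60
  frame_t <- seq(0, duration, by = cfg$frame_interval)
  log_t <- seq(0, duration, by = cfg$log_interval)
  slope <- (psi_end - psi_start) / duration   # MPa per minute, negative
  psi_frame <- psi_start + slope * frame_t
  psi_log <- psi_start + slope * log_t

  n <- cfg$n_pixels
  px <- rep_len(as.integer(pixels_per_event), n)
  if (any(px < 1L)) stop_hs("pixels_per_event must be >= 1")

  events <- with_seed(cfg$seed, {
    u <- runif(n)
    psi_u <- params$b + log(u / (1 - u)) / params$a
    # frame whose psi is nearest the threshold (clamped to the record)
    idx <- pmin(pmax(round((psi_u - psi_start) / (slope * cfg$frame_interval)),
                     0), length(frame_t) - 1L) + 1L
    agg <- tapply(px, idx, sum)
    data.frame(frame_idx = as.integer(names(agg)),
               time_min = frame_t[as.integer(names(agg))],
               n_pixels = as.integer(agg))
  })
  events <- events[order(events$frame_idx), , drop = FALSE]
  rownames(events) <- NULL

  list(events = events,
       psychrometer = data.frame(time_min = log_t, psi_mpa = psi_log),
       truth = list(a = params$a, b = params$b, total_pixels = sum(px),
                    psi_start = psi_start, psi_end = psi_end))
}

#' Render an event table as a synthetic grayscale image stack
#'
#' Builds a stack of frames in which each embolism event flips a disjoint
#' block of background pixels to a bright "embolized" intensity at its frame
#' index (pixels stay bright afterwards, as embolized xylem remains
#' refractive). Differencing successive frames with [diff_stack()] recovers
#' the event table exactly.
#'
#' @param events data frame `(frame_idx, n_pixels, ...)` as produced by
#'   [gen_embolism_campaign()].
#' @param frame_shape integer `c(rows, cols)`, each at least 8.
#' @param n_frames number of frames; default covers the last event.
#' @param background,intensity background and embolized pixel values in
#'   `[0, 1]`.
#' @return A 3-d array `(rows, cols, n_frames)` with attribute
#'   `frame_shape`.
#' @export
gen_image_stack <- function(events, frame_shape = c(64L, 64L),
                            n_frames = NULL, background = 0.1,
                            intensity = 0.9) {
  check_columns(events, c("frame_idx", "n_pixels"), "events")
  if (length(frame_shape) != 2L || any(frame_shape < 8L))
    stop_hs("frame_shape must be c(rows, cols) with both >= 8")
  area <- prod(frame_shape)
  total <- sum(events$n_pixels)
  if (total > area)
    stop_hs(sprintf("events need %d pixels but the frame has only %d",
                    total, area))
  if (is.null(n_frames)) n_frames <- max(events$frame_idx) + 1L
  if (nrow(events) && n_frames <= max(events$frame_idx))
    stop_hs("n_frames must exceed the last event's frame_idx")

  stack <- array(background, dim = c(frame_shape[1], frame_shape[2],
                                     n_frames))
  offset <- 0L
  if (nrow(events)) {
    ord <- order(events$frame_idx)
    for (i in ord) {
      k <- events$frame_idx[i]      # event seen in diff between k and k+1
      npx <- events$n_pixels[i]
      cells <- offset + seq_len(npx)
      offset <- offset + npx
      for (f in seq(k + 1L, n_frames)) {
        frame <- stack[, , f]
        frame[cells] <- intensity
        stack[, , f] <- frame
      }
    }
  }
  attr(stack, "frame_shape") <- frame_shape
  stack
}

#' Simulate a pressure-volume bench-drying series for one leaf
#'
#' Forward model of the classic pressure-volume experiment under the linear
#' elasticity assumption. Symplastic relative water content \eqn{R_s}
#' declines on a grid from 1; at each point
#' \deqn{\Psi_s = -\pi_o / R_s, \qquad
#'       \Psi_p = \max(0,\; \pi_o - \varepsilon (1 - R_s)), \qquad
#'       \Psi = \Psi_s + \Psi_p,}
#' where \eqn{\pi_o} is the magnitude of osmotic potential at full turgor
#' and \eqn{\varepsilon} the bulk elastic modulus. Fresh mass is
#' `dry_mass + water_max * (af + (1 - af) * R_s)` with apoplastic fraction
#' `af`. The default grid includes the exact turgor-loss point (bench
#' operators sample densely around the inflection) and spans at least three
#' points beyond it.
#'
#' @param params a [species_params()] object.
#' @param cfg a [gen_config()] object; `n_pv_points` must be >= 8.
#' @param dry_mass leaf dry mass, g.
#' @param water_max saturated water mass, g.
#' @param rwc_min symplastic relative water content at the dry end of the
#'   grid; `NULL` chooses a value giving a water potential about 1.8 times
#'   the turgor loss point.
#' @return An object of class `pv_series`: list with `points` (data frame
#'   `step, fresh_mass_g, psi_mpa`), `dry_mass`, `turgid_mass`, and `truth`
#'   (generating parameters incl. closed-form TLP).
#' @export
#' @examples
#' p <- species_params("Euclea", -2.23, -8.02, 2.92, 12.43)
#' pv <- gen_pv_series(p, gen_config(seed = 1))
#' pv$truth$tlp
gen_pv_series <- function(params, cfg = gen_config(), dry_mass = 0.2,
                          water_max = 0.3, rwc_min = NULL) {
  stopifnot(inherits(params, "species_params"), inherits(cfg, "gen_config"))
  if (cfg$n_pv_points < 8L)
    stop_hs("n_pv_points must be >= 8 for a pressure-volume analysis")
  po <- params$psi_osm_ft; eps <- params$eps
  af <- params$apoplastic_fraction
  rwc_tlp <- 1 - po / eps
  if (is.null(rwc_min)) rwc_min <- rwc_tlp / 1.8
  if (rwc_min >= rwc_tlp)
    stop_hs("rwc_min must lie beyond the turgor loss point")

  n <- cfg$n_pv_points
  n_post <- max(3L, floor(0.4 * n))      # >= 3 points past turgor loss
  n_pre <- n - n_post
  # grid includes full turgor (R = 1) and the exact turgor-loss point
  rs <- c(seq(1, rwc_tlp, length.out = n_pre),
          seq(rwc_tlp, rwc_min, length.out = n_post + 1L)[-1L])
  psi_s <- -po / rs
  psi_p <- pmax(0, po - eps * (1 - rs))
  psi <- psi_s + psi_p
  fresh <- dry_mass + water_max * (af + (1 - af) * rs)

  if (cfg$mass_noise_sd > 0 || cfg$psi_noise_sd > 0) {
    noise <- with_seed(cfg$seed, list(
      m = rnorm(length(rs), 0, cfg$mass_noise_sd),
      p = rnorm(length(rs), 0, cfg$psi_noise_sd)))
    fresh <- fresh + noise$m
    psi <- pmin(psi + noise$p, 0)
  }

  structure(list(
    points = data.frame(step = seq_along(rs), fresh_mass_g = fresh,
                        psi_mpa = psi),
    dry_mass = dry_mass,
    turgid_mass = dry_mass + water_max,
    truth = list(psi_osm_ft = po, eps = eps,
                 apoplastic_fraction = af,
                 tlp = closed_form_tlp(po, eps),
                 rwc = rs)),
    class = "pv_series")
}

#' Simulate a field water-potential campaign
#'
#' Draws per-individual midday minimum water potentials from each species'
#' per-period normal distribution, truncated just below zero (water
#' potential in living tissue is never positive; draws above -0.01 MPa are
#' set to -0.01).
#'
#' @param params_list list of [species_params()] objects.
#' @param periods character vector of period labels; default: all periods
#'   present in any species' `psi_min_by_period`.
#' @param cfg a [gen_config()] object (`n_individuals` >= 2).
#' @return Long-format data frame
#'   `(species, individual, period, psi_md_mpa)`.
#' @export
gen_field_campaign <- function(params_list, periods = NULL,
                               cfg = gen_config()) {
  if (inherits(params_list, "species_params"))
    params_list <- list(params_list)
  stopifnot(all(vapply(params_list, inherits, TRUE, "species_params")))
  if (cfg$n_individuals < 2L) stop_hs("n_individuals must be >= 2")
  if (is.null(periods))
    periods <- unique(unlist(lapply(params_list,
                                    function(p) names(p$psi_min_by_period))))
  if (!length(periods)) stop_hs("no periods defined")

  with_seed(cfg$seed, {
    rows <- list()
    for (p in params_list) for (per in periods) {
      ms <- p$psi_min_by_period[[per]]
      if (is.null(ms)) next
      psi <- rnorm(cfg$n_individuals, ms["mean"], ms["sd"])
      psi <- pmin(psi, -0.01)
      rows[[length(rows) + 1L]] <- data.frame(
        species = p$name, individual = seq_len(cfg$n_individuals),
        period = per, psi_md_mpa = psi, stringsAsFactors = FALSE)
    }
    if (!length(rows)) stop_hs("no species has data for the given periods")
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Simulate a canopy drought-damage survey
#'
#' Generative counterpart of the damage analysis model: each metric is
#' `clip(exp(linear predictor), 0, 100)` plus Gaussian observation noise
#' (the average of two observers), re-clipped to `[0, 100]`. Using the
#' exponential mean matches the Gaussian log-link GLM used to analyse the
#' survey, so coefficient recovery is well-posed.
#'
#' @param traits data frame of per-individual (or per-species) trait
#'   values; must contain every column named in `damage_coefs`.
#' @param damage_coefs named list: metric name -> named numeric vector of
#'   coefficients; the element named `"(Intercept)"` is the intercept.
#' @param noise_sd observer noise standard deviation (percentage points).
#' @param cfg a [gen_config()] object (seed).
#' @return `traits` with one added column per damage metric, each within
#'   `[0, 100]`.
#' @export
#' @examples
#' tr <- data.frame(p50 = c(-8, -5), height = c(2, 3))
#' cf <- list(foliage = c("(Intercept)" = 4, p50 = 0.05))
#' gen_damage_survey(tr, cf, noise_sd = 0, cfg = gen_config(seed = 1))
gen_damage_survey <- function(traits, damage_coefs, noise_sd = 2,
                              cfg = gen_config()) {
  stopifnot(is.data.frame(traits), is.list(damage_coefs))
  check_number(noise_sd, "noise_sd", lower = 0)
  with_seed(cfg$seed, {
    out <- traits
    for (metric in names(damage_coefs)) {
      cf <- damage_coefs[[metric]]
      preds <- setdiff(names(cf), "(Intercept)")
      unknown <- setdiff(preds, names(traits))
      if (length(unknown))
        stop_hs(sprintf(
          "damage_coefs[['%s']] names unknown trait(s) %s; available: %s",
          metric, paste(unknown, collapse = ", "),
          paste(names(traits), collapse = ", ")))
      eta <- rep(if ("(Intercept)" %in% names(cf)) cf[["(Intercept)"]] else 0,
                 nrow(traits))
      for (p in preds) eta <- eta + cf[[p]] * traits[[p]]
      mu <- pmin(pmax(exp(eta), 0), 100)
      if (noise_sd > 0) {
        # mean of two observers -> sd / sqrt(2)
        obs <- mu + rnorm(nrow(traits), 0, noise_sd / sqrt(2))
        mu <- pmin(pmax(obs, 0), 100)
      }
      out[[metric]] <- mu
    }
    out
  })
}

#' Simulate a monthly precipitation series
#'
#' Independent gamma-distributed monthly totals, optionally with a drought
#' block during which the scale parameter is multiplied by
#' `drought_factor` for 12 consecutive months.
#'
#' @param cfg a [gen_config()] object; `n_years` must be >= 3 (>= 30
#'   recommended for SPI fitting).
#' @param drought_start_year year index (1-based) at which a 12-month
#'   drought block begins in January, or `NULL` for none.
#' @param drought_factor multiplier on the gamma scale during the drought.
#' @return Data frame `(year, month, mm)`.
#' @export
gen_precip <- function(cfg = gen_config(), drought_start_year = NULL,
                       drought_factor = 0.4) {
  stopifnot(inherits(cfg, "gen_config"))
  if (cfg$n_years < 3L) stop_hs("n_years must be >= 3")
  n <- cfg$n_years * 12L
  scale <- rep(cfg$gamma_scale, n)
  if (!is.null(drought_start_year)) {
    check_count(drought_start_year, "drought_start_year")
    if (drought_start_year > cfg$n_years)
      stop_hs("drought_start_year beyond the series")
    i0 <- (drought_start_year - 1L) * 12L + 1L
    idx <- i0:min(i0 + 11L, n)
    scale[idx] <- scale[idx] * drought_factor
  }
  mm <- with_seed(cfg$seed, {
    if (cfg$gamma_scale == 0) rep(0, n)
    else rgamma(n, shape = cfg$gamma_shape, scale = 1) * scale
  })
  data.frame(year = rep(seq_len(cfg$n_years), each = 12L),
             month = rep(1:12, cfg$n_years), mm = mm)
}
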