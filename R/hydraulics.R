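#' Hydraulic safety margin
#'
#' Difference between the minimum leaf xylem water potential experienced in
#' the field and an embolism threshold of the vulnerability curve
#' (P12, P50 or P88): `psi_min - px_value`. Positive values mean the plant
#' operated above (wetter than) the threshold; negative values mean the
#' threshold was surpassed.
#'
#' @param psi_min minimum (most negative) field water potential, MPa.
#' @param px_value embolism threshold (e.g. P50 from [px()]), MPa.
#' @return Safety margin, MPa (vectorized).
#' @export
#' @examples
#' hsm(-5.33, -4.87)   # -0.46: the threshold was exceeded
hsm <- function(psi_min, px_value) {
  if (any(psi_min > 0, na.rm = TRUE) || any(px_value > 0, na.rm = TRUE))
    stop_hs("water potentials must be negative")
  psi_min - px_value
}

#' Stomatal safety margin
#'
#' Water-potential buffer between stomatal closure (proxied by the turgor
#' loss point) and an embolism threshold: `tlp - px_value`. Positive values
#' mean stomata close before the xylem embolizes.
#'
#' @param tlp turgor loss point, MPa.
#' @param px_value embolism threshold (P12/P50/P88), MPa.
#' @return Safety margin, MPa (vectorized).
#' @export
#' @examples
#' tr <- thicket_traits()
#' round(ssm(tr$tlp, tr$p50), 2)
ssm <- function(tlp, px_value) {
  if (any(tlp > 0, na.rm = TRUE) || any(px_value > 0, na.rm = TRUE))
    stop_hs("water potentials must be negative")
  tlp - px_value
}

#' Predicted percent embolism for a set of individuals
#'
#' Evaluates the species-mean vulnerability curve at each individual's
#' minimum water potential and averages across individuals. The nonlinear
#' transform is applied per individual *before* averaging; for steep
#' curves this differs measurably from evaluating the curve at the mean
#' water potential.
#'
#' @param psi_min numeric vector of per-individual minimum water
#'   potentials, MPa.
#' @param a_mean,b_mean species-mean sigmoid parameters, or a
#'   `species_curve` object passed as `a_mean`.
#' @return List with `mean` (percent), `se` (across individuals; `NA` for
#'   a single individual), `n`, and `per_individual`.
#' @export
#' @examples
#' ppe(c(-5.0, -5.3, -5.6), a_mean = -0.77, b_mean = -4.87)
ppe <- function(psi_min, a_mean, b_mean = NULL) {
  if (inherits(a_mean, "species_curve")) {
    b_mean <- a_mean$b_mean
    a_mean <- a_mean$a_mean
  }
  psi_min <- psi_min[is.finite(psi_min)]
  if (!length(psi_min)) stop_hs("no individuals with finite psi_min")
  per <- sigmoid_pe(psi_min, a_mean, b_mean)
  n <- length(per)
  list(mean = mean(per),
       se = if (n > 1L) sd(per) / sqrt(n) else NA_real_,
       n = n, per_individual = per)
}

#' Leaf mass per area
#'
#' @param dry_mass leaf (or leaf-batch) dry mass, g.
#' @param projected_area projected leaf area, m^2. For a batch, pass summed
#'   mass and summed area.
#' @return LMA, g m^-2.
#' @export
lma <- function(dry_mass, projected_area) {
  if (any(dry_mass <= 0) || any(projected_area <= 0))
    stop_hs("dry_mass and projected_area must be positive")
  dry_mass / projected_area
}

#' Huber value
#'
#' Sapwood cross-sectional area divided by the leaf area it subtends.
#' Supply either `sapwood_area` directly or a stem diameter
#' (`stem_diameter`), from which the area is computed assuming a circular
#' cross-section (\eqn{\pi d^2 / 4}). Areas must share units.
#'
#' @param sapwood_area sapwood cross-sectional area (e.g. mm^2).
#' @param leaf_area subtended leaf area (same units).
#' @param stem_diameter stem diameter under bark (same length unit as the
#'   areas' square root); overrides `sapwood_area` when given.
#' @return Unitless ratio.
#' @export
#' @examples
#' huber(leaf_area = pi, stem_diameter = 2)   # 1
huber <- function(sapwood_area = NULL, leaf_area, stem_diameter = NULL) {
  if (!is.null(stem_diameter)) {
    if (any(stem_diameter <= 0)) stop_hs("stem_diameter must be positive")
    sapwood_area <- pi * stem_diameter^2 / 4
  }
  if (is.null(sapwood_area))
    stop_hs("supply sapwood_area or stem_diameter")
  if (any(sapwood_area <= 0) || any(leaf_area <= 0))
    stop_hs("areas must be positive")
  sapwood_area / leaf_area
}

#' Species-level safety margins and predicted percent embolism
#'
#' Joins species vulnerability curves, turgor loss points and field
#' water-potential campaigns into the per-species, per-period margin table:
#' hydraulic safety margins from P12/P50/P88, stomatal safety margins from
#' P12/P50/P88, and predicted percent embolism (mean +/- SE across
#' individuals). The SSM standard error is propagated as
#' \eqn{\sqrt{SE_{TLP}^2 + SE_{P50}^2}} (a convention: within-species
#' pairing of the underlying individuals is not observed).
#'
#' @param curves data frame with columns `species`, `a_mean`, `b_mean`
#'   (and optionally `b_se`), e.g. stacked [species_curve()] results.
#' @param pv data frame with columns `species`, `tlp` (and optionally
#'   `tlp_se`).
#' @param field long data frame `(species, individual, period,
#'   psi_md_mpa)`; each individual's minimum over the period is used.
#' @return Data frame with one row per species x period:
#'   `hsm12, hsm50, hsm88, ssm12, ssm50, ssm88, ssm50_se, ppe_mean,
#'   ppe_se, n`.
#' @export
safety_margins <- function(curves, pv, field) {
  check_columns(curves, c("species", "a_mean", "b_mean"), "curves")
  check_columns(pv, c("species", "tlp"), "pv")
  check_columns(field, c("species", "individual", "period", "psi_md_mpa"),
                "field")
  rows <- list()
  for (sp in unique(field$species)) {
    cu <- curves[curves$species == sp, , drop = FALSE]
    pvs <- pv[pv$species == sp, , drop = FALSE]
    if (!nrow(cu) || !nrow(pvs)) next
    a <- cu$a_mean[1]; b <- cu$b_mean[1]
    pxs <- c(p12 = px(a, b, 12), p50 = b, p88 = px(a, b, 88))
    tlp_sp <- pvs$tlp[1]
    ssm_se <- sqrt((if ("tlp_se" %in% names(pvs))
      pvs$tlp_se[1]^2 else 0) +
      (if ("b_se" %in% names(cu)) cu$b_se[1]^2 else 0))
    for (per in unique(field$period[field$species == sp])) {
      fi <- field[field$species == sp & field$period == per, , drop = FALSE]
      psi_ind <- tapply(fi$psi_md_mpa, fi$individual, min)
      pp <- ppe(psi_ind, a, b)
      psi_min_mean <- mean(psi_ind)
      rows[[length(rows) + 1L]] <- data.frame(
        species = sp, period = per,
        psi_min = psi_min_mean,
        hsm12 = hsm(psi_min_mean, pxs["p12"]),
        hsm50 = hsm(psi_min_mean, pxs["p50"]),
        hsm88 = hsm(psi_min_mean, pxs["p88"]),
        ssm12 = ssm(tlp_sp, pxs["p12"]),
        ssm50 = ssm(tlp_sp, pxs["p50"]),
        ssm88 = ssm(tlp_sp, pxs["p88"]),
        ssm50_se = ssm_se,
        ppe_mean = pp$mean, ppe_se = pp$se, n = pp$n,
        stringsAsFactors = FALSE, row.names = NULL)
    }
  }
  if (!length(rows)) stop_hs("no species shared by curves, pv and field")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
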