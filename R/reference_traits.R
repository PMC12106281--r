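#' Reference hydraulic traits for six thicket tree species
#'
#' Species-mean trait values for six co-occurring woody evergreen species of
#' South Africa's Albany Subtropical Thicket, as measured on field-collected
#' material: turgor loss point (TLP), osmotic potential at full turgor
#' (magnitude), bulk elastic modulus, leaf P50 and the sigmoid steepness
#' parameter of the vulnerability curve, together with species-mean minimum
#' midday water potentials observed in a protracted dry period (2020) and a
#' subsequent wetter period (2022), plant height at the study site, leaf mass
#' per area and Huber value.
#'
#' These values serve two purposes: as a worked, fully-public input for the
#' safety-margin and trait-regression functions, and as realistic default
#' parameters for the synthetic-data generators (see
#' [default_species_params()]).
#'
#' @return A data frame with one row per species and columns
#'   \describe{
#'     \item{species}{genus label}
#'     \item{family}{botanical family}
#'     \item{tlp}{turgor loss point, MPa (negative)}
#'     \item{tlp_se}{standard error of TLP, MPa}
#'     \item{psi_osm}{osmotic potential at full turgor, MPa, stored as a
#'       positive magnitude}
#'     \item{eps}{bulk elastic modulus, MPa}
#'     \item{p50}{water potential at 50\% leaf xylem embolism, MPa}
#'     \item{p50_se}{standard error of P50, MPa}
#'     \item{slope_a}{sigmoid steepness parameter a, MPa^-1 (negative)}
#'     \item{psi_min_2020, psi_min_2022}{species-mean minimum midday water
#'       potential in the dry and wet periods, MPa (NA where not surveyed)}
#'     \item{height}{mean plant height at the study site, m}
#'     \item{lma}{leaf mass per area, g m^-2}
#'     \item{huber}{Huber value (sapwood area / leaf area, unitless)}
#'   }
#' @export
#' @examples
#' tr <- thicket_traits()
#' ssm(tr$tlp, tr$p50)   # stomatal safety margins from P50
thicket_traits <- function() {
  data.frame(
    species  = c("Boscia", "Searsia", "Euclea", "Pappea", "Schotia",
                 "Polygala"),
    family   = c("Capparaceae", "Anacardiaceae", "Ebenaceae", "Sapindaceae",
                 "Fabaceae", "Polygalaceae"),
    tlp      = c(-1.95, -3.69, -3.82, -2.33, -1.33, -1.67),
    tlp_se   = c(0.20, 0.11, 0.04, 0.11, 0.08, 0.12),
    psi_osm  = c(1.37, 2.17, 2.92, 1.45, 0.93, 1.02),
    eps      = c(4.61, 6.14, 12.43, 3.88, 3.87, 3.48),
    p50      = c(-6.39, -8.09, -8.02, -5.61, -4.64, -4.87),
    p50_se   = c(0.41, 0.21, 0.13, 0.34, 0.24, 0.22),
    slope_a  = c(-3.34, -10.07, -2.23, -2.93, -4.03, -0.77),
    # species-mean minimum midday water potentials per survey period
    psi_min_2020 = c(NA, -6.03, -5.84, -5.55, -3.82, -5.33),
    psi_min_2022 = c(-4.00, -4.31, -4.88, -4.77, -3.11, -3.79),
    height   = c(3.6, 2.2, 2.4, 3.7, 2.6, 1.4),
    lma      = c(346.1, 106.1, 265.9, 136.5, 218.0, 144.0),
    huber    = c(NA, 0.144, 0.136, 0.379, 0.114, 0.127),
    stringsAsFactors = FALSE
  )
}

#' Default generator parameter sets for the six reference species
#'
#' Converts [thicket_traits()] rows into a list of [species_params()]
#' objects, the parameter container consumed by the synthetic-data
#' generators. Minimum water potentials per period become the means of the
#' per-individual field distributions; the per-period standard deviation
#' defaults to 0.5 MPa (a typical between-individual spread for midday
#' water-potential campaigns).
#'
#' @param psi_min_sd between-individual standard deviation of minimum water
#'   potential within a species and period, MPa.
#' @return Named list of `species_params` objects (one per species).
#' @export
default_species_params <- function(psi_min_sd = 0.5) {
  tr <- thicket_traits()
  out <- lapply(seq_len(nrow(tr)), function(i) {
    psi_min <- list()
    if (!is.na(tr$psi_min_2020[i]))
      psi_min[["2020-dry"]] <- c(mean = tr$psi_min_2020[i], sd = psi_min_sd)
    if (!is.na(tr$psi_min_2022[i]))
      psi_min[["2022-wet"]] <- c(mean = tr$psi_min_2022[i], sd = psi_min_sd)
    species_params(
      name = tr$species[i],
      a = tr$slope_a[i], b = tr$p50[i],
      psi_osm_ft = tr$psi_osm[i], eps = tr$eps[i],
      psi_min_by_period = psi_min
    )
  })
  names(out) <- tr$species
  out
}
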