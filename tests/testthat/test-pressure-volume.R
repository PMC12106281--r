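test_that("turgid mass estimation uses the saturated point when present", {
  p <- euclea_params()
  pv <- gen_pv_series(p, gen_config(seed = 1))
  expect_equal(estimate_turgid_mass(pv$points), pv$turgid_mass)
  # without the saturated point: regression over wet points, floored at
  # the maximum observed fresh mass
  pts <- pv$points[-1, ]
  est <- estimate_turgid_mass(pts)
  expect_gte(est, max(pts$fresh_mass_g))
  expect_lt(abs(est - pv$turgid_mass) / pv$turgid_mass, 0.02)
  # < 3 wet points -> max fresh mass fallback
  dry_pts <- pts[pts$psi_mpa < -2, ]
  expect_equal(estimate_turgid_mass(dry_pts), max(dry_pts$fresh_mass_g))
})

test_that("relative water content is a clipped mass ratio", {
  pts <- data.frame(fresh_mass_g = c(0.5, 0.35, 0.2))
  rwc <- compute_rwc(pts, dry_mass = 0.2, turgid_mass = 0.5)
  expect_equal(rwc[1], 1)
  expect_equal(rwc[2], 0.5)
  expect_gt(rwc[3], 0)          # clipped to smallest positive value
  expect_error(compute_rwc(pts, 0.5, 0.4), "exceed")
})

test_that("linear tail detection finds exactly the post-turgor points", {
  p <- euclea_params()
  pv <- gen_pv_series(p, gen_config(seed = 1))
  cv <- pv_curve(pv$points, pv$dry_mass)
  tail_fit <- find_linear_tail(cv)
  # generator truth: points at or beyond the turgor-loss RWC
  rwc_tlp <- 1 - p$psi_osm_ft / p$eps
  expect_equal(tail_fit$tail_n, sum(pv$truth$rwc <= rwc_tlp + 1e-12))
  expect_equal(tail_fit$tail_r2, 1, tolerance = 1e-12)
  # data exactly on a line: every usable point joins the tail
  d <- seq(0.05, 0.6, length.out = 10)
  lin <- data.frame(fresh_mass_g = 0.2 + 0.3 * (1 - d),
                    psi_mpa = 1 / (-0.3 - 0.5 * d))
  cv2 <- pv_curve(lin, dry_mass = 0.19, turgid_mass = 0.5)
  expect_equal(find_linear_tail(cv2)$tail_n, 10L)
  # impossible threshold on noisy data errors
  pvn <- gen_pv_series(p, gen_config(seed = 2, mass_noise_sd = 0.004,
                                     psi_noise_sd = 0.08))
  cvn <- pv_curve(pvn$points, pvn$dry_mass, turgid_mass = pvn$turgid_mass)
  expect_error(find_linear_tail(cvn, r2_min = 1), "no linear region")
})

test_that("pv traits recover generator ground truth exactly (noiseless)", {
  cases <- list(euclea_params(), boscia_params(),
                species_params("Pappea", -2.93, -5.61, 1.45, 3.88))
  for (p in cases) {
    pv <- gen_pv_series(p, gen_config(seed = 1))
    tr <- extract_pv_traits(pv_curve(pv$points, pv$dry_mass))
    expect_equal(tr$tlp, pv$truth$tlp, tolerance = 1e-6)
    expect_equal(tr$psi_osm_ft, p$psi_osm_ft, tolerance = 1e-6)
    expect_equal(tr$eps, p$eps, tolerance = 1e-6)
    expect_lt(tr$tlp, -tr$psi_osm_ft)   # TLP beyond the osmotic potential
  }
})

test_that("pv trait recovery holds across random parameter draws", {
  set.seed(77)
  for (i in 1:50) {
    po <- runif(1, 0.8, 3)
    ratio <- runif(1, 1.5, 10)
    p <- species_params("r", -2, -6, po, po * ratio)
    pv <- gen_pv_series(p, gen_config(seed = i))
    tr <- extract_pv_traits(pv_curve(pv$points, pv$dry_mass))
    expect_equal(tr$tlp, closed_form_tlp(po, po * ratio),
                 tolerance = 1e-6)
    expect_equal(tr$psi_osm_ft, po, tolerance = 1e-6)
    expect_equal(tr$eps, po * ratio, tolerance = 1e-6)
  }
})

test_that("closed-form turgor loss point behaves analytically", {
  # rigid-wall limit: TLP approaches the osmotic potential
  expect_equal(closed_form_tlp(1, 1e9), -1, tolerance = 1e-6)
  expect_equal(closed_form_tlp(2.92, 12.43), -3.8166, tolerance = 1e-4)
  expect_equal(closed_form_tlp(1.45, 3.88), -2.3152, tolerance = 1e-4)
  expect_error(closed_form_tlp(3, 2), "eps")
})

test_that("trait estimates degrade monotonically with mass noise", {
  p <- euclea_params()
  rmse_at <- function(noise_sd) {
    errs <- vapply(1:40, function(s) {
      pv <- gen_pv_series(p, gen_config(seed = s, n_pv_points = 20,
                                        mass_noise_sd = noise_sd))
      tr <- tryCatch(
        extract_pv_traits(pv_curve(pv$points, pv$dry_mass,
                                   turgid_mass = pv$turgid_mass),
                          r2_min = 0.95),
        error = function(e) NULL)
      if (is.null(tr)) NA_real_ else tr$tlp - pv$truth$tlp
    }, numeric(1))
    sqrt(mean(errs^2, na.rm = TRUE))
  }
  r0 <- rmse_at(0)
  r1 <- rmse_at(0.002)
  r2 <- rmse_at(0.008)
  expect_lt(r0, r1)
  expect_lt(r1, r2)
})
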