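test_that("species_params validates physiological invariants", {
  expect_s3_class(euclea_params(), "species_params")
  expect_error(species_params("x", a = 1, b = -5, psi_osm_ft = 1, eps = 3),
               "negative")
  expect_error(species_params("x", a = -1, b = 5, psi_osm_ft = 1, eps = 3),
               "negative")
  # turgor never lost when walls are softer than the osmotic pull
  expect_error(species_params("x", a = -1, b = -5, psi_osm_ft = 3, eps = 2),
               "eps")
  expect_error(species_params("x", a = -1, b = -5, psi_osm_ft = 1, eps = 3,
                              apoplastic_fraction = 1), "< 1")
})

test_that("embolism campaign inverts the sigmoid correctly", {
  p <- euclea_params()
  # u = 0.5 -> threshold exactly at b; u = 0.12 -> closed-form inverse,
  # which must agree with the px() operation at 12%
  u <- c(0.5, 0.12)
  psi_u <- p$b + log(u / (1 - u)) / p$a
  expect_equal(psi_u[1], p$b)
  expect_equal(psi_u[2], -7.1265, tolerance = 1e-4)
  expect_equal(psi_u[2], px(p$a, p$b, 12))

  # median of the threshold distribution is b: about half the events
  # fire at water potentials less negative than b
  camp <- gen_embolism_campaign(p, gen_config(seed = 42, n_pixels = 2000))
  frame_psi <- approx(camp$psychrometer$time_min,
                      camp$psychrometer$psi_mpa,
                      xout = camp$events$time_min)$y
  frac_wet <- sum(camp$events$n_pixels[frame_psi >= p$b]) /
    sum(camp$events$n_pixels)
  expect_lt(abs(frac_wet - 0.5), 3 * sqrt(0.25 / 2000))
})

test_that("embolism campaign validates inputs and is deterministic", {
  p <- euclea_params()
  expect_error(gen_embolism_campaign(p, gen_config(n_pixels = 5)),
               ">= 10")
  c1 <- gen_embolism_campaign(p, gen_config(seed = 3, n_pixels = 100))
  c2 <- gen_embolism_campaign(p, gen_config(seed = 3, n_pixels = 100))
  expect_identical(c1, c2)
  c3 <- gen_embolism_campaign(p, gen_config(seed = 4, n_pixels = 100))
  expect_false(identical(c1$events, c3$events))
  # psychrometer trace declines monotonically at the log cadence
  expect_true(all(diff(c1$psychrometer$psi_mpa) < 0))
  expect_equal(unique(diff(c1$psychrometer$time_min)), 10)
})

test_that("image stack round-trips through diff_stack exactly", {
  ev <- data.frame(frame_idx = c(2L, 4L, 9L), n_pixels = c(5L, 5L, 5L))
  st <- gen_image_stack(ev, frame_shape = c(8L, 8L))
  dif <- diff_stack(st)
  expect_equal(dif$changed_pixels[c(2, 4, 9)], c(5L, 5L, 5L))
  expect_equal(sum(dif$changed_pixels), 15L)

  # no events -> identical frames -> all-zero differences
  st0 <- gen_image_stack(ev[0, ], frame_shape = c(8L, 8L), n_frames = 4L)
  expect_true(all(diff_stack(st0)$changed_pixels == 0L))

  # area overflow is an error
  expect_error(gen_image_stack(data.frame(frame_idx = 1L, n_pixels = 100L),
                               frame_shape = c(8L, 8L)), "pixels")
})

test_that("pv series follows the linear-elasticity model", {
  p <- euclea_params()
  pv <- gen_pv_series(p, gen_config(seed = 1))
  # full turgor: psi = 0 at R = 1
  expect_equal(pv$points$psi_mpa[1], 0)
  expect_equal(pv$points$fresh_mass_g[1], pv$turgid_mass)
  # recorded ground truth matches the analytic oracle
  expect_equal(pv$truth$tlp, closed_form_tlp(2.92, 12.43))
  expect_equal(closed_form_tlp(2.92, 12.43), -3.8166, tolerance = 1e-4)
  expect_equal(closed_form_tlp(1.37, 4.61), -1.9493, tolerance = 1e-4)
  # psi strictly decreasing along drying, all <= 0
  expect_true(all(diff(pv$points$psi_mpa) < 0))
  expect_true(all(pv$points$psi_mpa <= 0))
  expect_error(gen_pv_series(p, gen_config(n_pv_points = 6)), ">= 8")
})

test_that("field campaign draws per-period truncated normals", {
  p <- species_params("x", -1, -5, 1, 3,
                      psi_min_by_period = list(
                        dry = c(mean = -5.33, sd = 0),
                        wet = c(mean = -3.5, sd = 0.5)))
  f <- gen_field_campaign(list(p), cfg = gen_config(seed = 1,
                                                    n_individuals = 6))
  expect_setequal(unique(f$period), c("dry", "wet"))
  # sd = 0 -> every individual at the mean
  expect_true(all(f$psi_md_mpa[f$period == "dry"] == -5.33))
  expect_true(all(f$psi_md_mpa < 0))

  # CLT check at large n
  p2 <- species_params("y", -1, -5, 1, 3,
                       psi_min_by_period = list(dry = c(mean = -5.33,
                                                        sd = 0.5)))
  f2 <- gen_field_campaign(list(p2), cfg = gen_config(seed = 2,
                                                      n_individuals = 10000))
  expect_lt(abs(mean(f2$psi_md_mpa) + 5.33), 0.02)
})

test_that("damage survey matches the log-link generative model", {
  tr <- data.frame(p50 = c(-8, -6, -4), height = c(2, 3, 4))
  # zero coefficients, intercept log(50), no noise -> all metrics 50
  cf <- list(foliage = c("(Intercept)" = log(50)))
  d <- gen_damage_survey(tr, cf, noise_sd = 0, cfg = gen_config(seed = 1))
  expect_equal(d$foliage, rep(50, 3))
  # clipping at 100
  cf2 <- list(crown = c("(Intercept)" = log(140)))
  d2 <- gen_damage_survey(tr, cf2, noise_sd = 0, cfg = gen_config(seed = 1))
  expect_equal(d2$crown, rep(100, 3))
  # unknown trait errors and lists what is available
  expect_error(gen_damage_survey(tr, list(m = c(nope = 1)),
                                 cfg = gen_config()), "p50")
})

test_that("precipitation generator has gamma moments and drought blocks", {
  cfg <- gen_config(seed = 5, n_years = 100, gamma_shape = 2,
                    gamma_scale = 50)
  pr <- gen_precip(cfg)
  expect_equal(nrow(pr), 1200)
  expect_true(all(pr$mm >= 0))
  # mean k*theta = 100, CLT bound 3 * sd/sqrt(n), sd = sqrt(2)*50
  expect_lt(abs(mean(pr$mm) - 100), 3 * sqrt(2) * 50 / sqrt(1200))
  # scale 0 -> all-zero series
  pr0 <- gen_precip(gen_config(seed = 1, n_years = 3, gamma_scale = 0))
  expect_true(all(pr0$mm == 0))
  # drought block annual totals sit in the lower tail
  prd <- gen_precip(gen_config(seed = 5, n_years = 40),
                    drought_start_year = 20)
  annual <- tapply(prd$mm, prd$year, sum)
  expect_lte(rank(annual)[20], 3)
})

test_that("generators are reproducible and respect sign conventions", {
  p <- euclea_params()
  for (pair in list(
    list(gen_pv_series(p, gen_config(seed = 9, mass_noise_sd = 0.01)),
         gen_pv_series(p, gen_config(seed = 9, mass_noise_sd = 0.01))),
    list(gen_precip(gen_config(seed = 9, n_years = 5)),
         gen_precip(gen_config(seed = 9, n_years = 5))))) {
    expect_identical(pair[[1]], pair[[2]])
  }
})
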