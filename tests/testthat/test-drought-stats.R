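test_that("anova_tukey separates clearly distinct groups", {
  set.seed(1)
  vals <- c(rnorm(5, 0, 0.1), rnorm(5, 10, 0.1))
  grp <- rep(c("low", "high"), each = 5)
  r <- anova_tukey(vals, grp)
  expect_lt(r$p, 1e-6)
  expect_false(r$letters[["low"]] == r$letters[["high"]])
  expect_error(anova_tukey(rnorm(5), rep("a", 5)), "2 groups")
})

test_that("anova_tukey shares letters under the null", {
  share <- vapply(1:100, function(s) {
    set.seed(s)
    vals <- rnorm(15)
    grp <- rep(letters[1:3], each = 5)
    lt <- anova_tukey(vals, grp)$letters
    length(unique(lt)) == 1L
  }, logical(1))
  expect_gte(mean(share), 0.90)
})

test_that("anova_tukey type-I error is near nominal", {
  reject <- vapply(1:400, function(s) {
    set.seed(1000 + s)
    anova_tukey(rnorm(20), rep(letters[1:4], each = 5))$p < 0.05
  }, logical(1))
  # binomial 99% CI around 0.05 at 400 draws
  expect_lt(abs(mean(reject) - 0.05), 2.58 * sqrt(0.05 * 0.95 / 400))
})

test_that("paired_t handles identity, degenerate and powered cases", {
  x <- c(1, 2, 3, 4)
  r <- paired_t(x, x)
  expect_equal(r$t, 0)
  expect_equal(r$p, 1)
  # constant nonzero shift: zero variance of differences is undefined
  expect_error(paired_t(x + 5, x), "variance")
  expect_error(paired_t(1:2, 1:2), "3 complete pairs")
  # power close to theory for shift 10, sd 5, n = 10
  rej <- vapply(1:200, function(s) {
    set.seed(s)
    d <- rnorm(10, 10, 5)
    paired_t(d, rep(0, 10))$p < 0.05
  }, logical(1))
  expect_gt(mean(rej), 0.95)   # theoretical power ~ 0.9998
})

test_that("single-trait regression reproduces the TLP-elasticity link", {
  # exact line
  x <- 1:10
  r <- suppressWarnings(fit_lm_single(x, 2 * x))
  expect_equal(r$r2, 1)
  expect_equal(r$slope, 2)
  # reference species: TLP against log elastic modulus
  tr <- thicket_traits()
  r2 <- fit_lm_single(log(tr$eps), tr$tlp)
  expect_equal(r2$r2, 0.73, tolerance = 0.01)
  expect_lt(r2$slope, 0)
  expect_lt(abs(r2$p_value - 0.03), 0.005)
  # orthogonal noise: near-zero r2
  set.seed(5)
  r3 <- fit_lm_single(rnorm(500), rnorm(500))
  expect_lt(r3$r2, 0.03)
  expect_error(fit_lm_single(rep(1, 5), 1:5), "variance")
})

test_that("enumerate_models counts subsets deterministically", {
  ps <- paste0("t", 1:8)
  m <- enumerate_models(ps, 3)
  expect_length(m, 92)             # 8 + 28 + 56
  expect_length(enumerate_models("x", 3), 1)
  expect_length(enumerate_models(ps, 10), 2^8 - 1)
  expect_identical(m, enumerate_models(ps, 3))
  sizes <- vapply(m, length, integer(1))
  expect_true(!is.unsorted(sizes))
})

test_that("log-link GLM recovers generative coefficients", {
  set.seed(9)
  x <- runif(200, 0, 2)
  y <- exp(1 + 0.5 * x) + rnorm(200, 0, 0.2)
  f <- fit_glm_log(y, data.frame(x = x), floor_y = 0.01, ceiling_y = Inf)
  est <- f$coefficients["x", ]
  expect_lt(abs(est[1] - 0.5), 2 * est[2])
  expect_true(f$converged)
  # intercept-only comparison fit has no explanatory power
  null_like <- fit_glm_log(y, data.frame(z = rep(c(0, 1e-9), 100)),
                           floor_y = 0.01, ceiling_y = Inf)
  expect_lt(null_like$mcfadden_r2, 0.01)
  expect_lt(null_like$deviance_explained, 0.01)
  # duplicated predictors are a singular design
  expect_error(fit_glm_log(y, data.frame(x = x, x2 = x)), "singular")
})

test_that("GLM coefficient recovery is unbiased at n = 500", {
  errs <- vapply(1:60, function(s) {
    tr <- data.frame(x = runif(500, 0, 2))
    d <- gen_damage_survey(tr,
                           list(m = c("(Intercept)" = 1, x = 0.5)),
                           noise_sd = 0.3,
                           cfg = gen_config(seed = 500 + s))
    f <- fit_glm_log(d$m, tr["x"], floor_y = 0.01, ceiling_y = Inf)
    f$coefficients["x", 1] - 0.5
  }, numeric(1))
  expect_lt(abs(mean(errs)), 0.05)
})

test_that("VIF matches the linear-design definition and car's values", {
  skip_if_not_installed("car")
  set.seed(11)
  X <- data.frame(a = rnorm(50), b = rnorm(50))
  X$c <- X$a + 0.5 * X$b + rnorm(50, 0, 0.5)
  y <- exp(1 + 0.1 * X$a) + rnorm(50, 0, 0.1)
  f <- fit_glm_log(y, X, floor_y = 0.01, ceiling_y = Inf)
  # the definition is the *linear* design's inflation, so the independent
  # oracle is car's VIF of a linear model on the same design
  cv <- car::vif(lm(y ~ a + b + c, data = cbind(y = y, X)))
  expect_equal(unname(f$vif), unname(cv), tolerance = 1e-6)
})

test_that("orthogonal predictors have VIF exactly 1", {
  X <- data.frame(a = rep(c(-1, 1), 10), b = rep(c(-1, -1, 1, 1), 5))
  y <- exp(1 + 0.1 * X$a + 0.1 * X$b) + 0.01 * seq_len(20)
  f <- fit_glm_log(y, X, floor_y = 0.01, ceiling_y = Inf)
  expect_equal(unname(f$vif), c(1, 1), tolerance = 1e-12)
})

test_that("AIC ranking computes delta, weights and support sets", {
  mk <- function(aic, k = 1L, vif = 1) structure(
    list(formula = paste0("x", seq_len(k)), coefficients = NULL,
         aic = aic, mcfadden_r2 = 0.5, deviance_explained = 0.5,
         vif = rep(vif, k), n = 10L, n_clamped = 0L,
         saturated_regime = FALSE, converged = TRUE, model = NULL),
    class = "glm_fit")
  # equal AIC -> equal weights
  r <- rank_models(list(mk(10), mk(10)))
  expect_equal(r$akaike_weight, c(0.5, 0.5))
  # delta AIC = 2 -> 0.731 / 0.269
  r2 <- rank_models(list(mk(10), mk(12)))
  expect_equal(r2$akaike_weight, c(1 / (1 + exp(-1)), exp(-1) / (1 + exp(-1))),
               tolerance = 1e-12)
  expect_equal(r2$delta_aic, c(0, 2))
  expect_true(all(r2$similar_support))
  # translation invariance
  r3 <- rank_models(list(mk(110), mk(112)))
  expect_equal(r3$akaike_weight, r2$akaike_weight)
  expect_equal(r3$delta_aic, r2$delta_aic)
  expect_equal(sum(r$akaike_weight), 1, tolerance = 1e-12)
  # tie on AIC: fewer predictors ranks first
  r4 <- rank_models(list(mk(10, k = 3L), mk(10, k = 1L)))
  expect_equal(r4$k, c(1L, 3L))

  # VIF screen skips collinear leaders
  r5 <- rank_models(list(mk(10, k = 2L, vif = 50), mk(11, k = 1L)))
  best <- select_best(r5, vif_threshold = 10)
  expect_equal(attr(best, "rank"), 2L)
  expect_equal(nrow(attr(best, "excluded")), 1L)
  expect_error(select_best(rank_models(list(mk(10, k = 2L, vif = 50))), 10),
               "VIF")
})

test_that("near-duplicate predictors are excluded by the VIF screen", {
  set.seed(21)
  n <- 30
  X <- data.frame(a = rnorm(n))
  X$b <- X$a + rnorm(n, 0, 0.01)      # corr ~ 0.9999
  X$c <- rnorm(n)
  y <- exp(1 + 0.3 * X$a) + rnorm(n, 0, 0.05)
  sel <- damage_model_selection(y, X, max_k = 2)
  best_preds <- sel$best$formula
  expect_false(all(c("a", "b") %in% best_preds))
  expect_true(max(sel$best$vif) <= 10)
})

test_that("species-level damage fits are flagged saturated at n = 5", {
  set.seed(31)
  tr <- data.frame(p50 = c(-8, -7, -6, -5, -4),
                   tlp = c(-3.8, -3.1, -2.4, -1.9, -1.4),
                   h = c(2, 3, 2.5, 3.5, 1.5))
  y <- exp(4 + 0.1 * tr$p50) + rnorm(5, 0, 0.5)
  f <- fit_glm_log(y, tr)
  expect_true(f$saturated_regime)
  expect_false(fit_glm_log(y, tr[, 1, drop = FALSE])$saturated_regime)
})
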