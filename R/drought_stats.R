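#' One-way ANOVA with Tukey HSD and compact letter display
#'
#' Tests for differences in a trait between groups (species), then runs
#' all-pairs Tukey honestly-significant-difference comparisons and assigns
#' compact letters: groups sharing a letter are not significantly
#' different at level `alpha`. Letters are assigned by greedy
#' insert-and-absorb over groups ordered by mean.
#'
#' @param values numeric vector of observations.
#' @param groups factor or character vector of group labels, same length.
#' @param alpha significance level for the Tukey comparisons.
#' @return List with `f`, `p`, `tukey` (the [stats::TukeyHSD()] table) and
#'   `letters` (named character vector per group).
#' @export
#' @examples
#' set.seed(1)
#' anova_tukey(c(rnorm(5), rnorm(5, 10)), rep(c("a", "b"), each = 5))
anova_tukey <- function(values, groups, alpha = 0.05) {
  groups <- factor(groups)
  if (nlevels(groups) < 2L) stop_hs("need at least 2 groups")
  tab <- table(groups)
  if (any(tab < 2L)) stop_hs("every group needs at least 2 values")
  if (all(tapply(values, groups, var) == 0))
    stop_hs("zero within-group variance: ANOVA undefined")
  fit <- aov(values ~ groups)
  s <- summary(fit)[[1]]
  tk <- TukeyHSD(fit, conf.level = 1 - alpha)$groups
  lev <- levels(groups)[order(tapply(values, groups, mean))]

  # significant pairs from the Tukey table ("g2-g1" rownames)
  sig <- rownames(tk)[tk[, "p adj"] < alpha]
  pairs <- strsplit(sig, "-", fixed = TRUE)
  differs <- function(g1, g2) any(vapply(pairs, function(p)
    all(c(g1, g2) %in% p), TRUE))

  # greedy insert-and-absorb: grow letter groups of mutually
  # non-different levels, in order of increasing mean
  letter_sets <- list()
  for (g in lev) {
    placed <- FALSE
    for (i in seq_along(letter_sets)) {
      if (!any(vapply(letter_sets[[i]], differs, TRUE, g2 = g))) {
        letter_sets[[i]] <- c(letter_sets[[i]], g)
        placed <- TRUE
      }
    }
    if (!placed) letter_sets[[length(letter_sets) + 1L]] <- g
  }
  letters_out <- setNames(rep("", nlevels(groups)), levels(groups))
  for (i in seq_along(letter_sets))
    for (g in letter_sets[[i]])
      letters_out[g] <- paste0(letters_out[g], letters[i])
  list(f = s[["F value"]][1], p = s[["Pr(>F)"]][1], tukey = tk,
       letters = letters_out)
}

#' Paired t-test between two survey periods
#'
#' @param x,y metric values in the two periods, aligned by individual (or
#'   matched via `id_x` / `id_y`).
#' @param id_x,id_y optional individual identifiers used to pair `x` and
#'   `y`.
#' @return List with `t`, `p`, `df`, `n_pairs`, `mean_diff`.
#' @export
paired_t <- function(x, y, id_x = NULL, id_y = NULL) {
  if (!is.null(id_x) || !is.null(id_y)) {
    if (is.null(id_x) || is.null(id_y))
      stop_hs("supply both id_x and id_y, or neither")
    common <- intersect(id_x, id_y)
    x <- x[match(common, id_x)]
    y <- y[match(common, id_y)]
  }
  if (length(x) != length(y)) stop_hs("x and y must pair one-to-one")
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop_hs("need at least 3 complete pairs")
  d <- x - y
  if (sd(d) == 0) {
    if (any(d != 0))
      stop_hs("zero variance of differences: t statistic undefined")
    # identical vectors: no evidence of any shift
    return(list(t = 0, p = 1, df = length(x) - 1L, n_pairs = length(x),
                mean_diff = 0))
  }
  tt <- t.test(x, y, paired = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter), n_pairs = length(x),
       mean_diff = unname(tt$estimate))
}

#' Single-predictor linear model between species-mean traits
#'
#' Ordinary least squares of `y` on `x` with the r-squared (squared Pearson
#' correlation) and the two-sided p-value of the slope.
#'
#' @param x,y numeric vectors (typically species means), length >= 3.
#' @return List with `slope`, `intercept`, `r2`, `p_value`, `n`.
#' @export
#' @examples
#' tr <- thicket_traits()
#' fit_lm_single(log(tr$eps), tr$tlp)   # r2 ~ 0.73
fit_lm_single <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop_hs("need at least 3 finite pairs")
  if (var(x) == 0) stop_hs("zero variance in x")
  f <- lm(y ~ x)
  s <- summary(f)
  list(slope = unname(coef(f)[2]), intercept = unname(coef(f)[1]),
       r2 = s$r.squared, p_value = s$coefficients[2, 4], n = length(x))
}

#' Enumerate predictor subsets up to a maximum size
#'
#' All subsets of `predictors` of size 1 to `max_k`, in deterministic
#' order: by subset size, then lexicographically by the predictors'
#' positions in the input vector.
#'
#' @param predictors character vector of predictor names.
#' @param max_k largest subset size (default 3).
#' @return List of character vectors.
#' @export
#' @examples
#' length(enumerate_models(letters[1:8], 3))   # 8 + 28 + 56 = 92
enumerate_models <- function(predictors, max_k = 3L) {
  if (!length(predictors)) stop_hs("need at least one predictor")
  if (anyDuplicated(predictors)) stop_hs("duplicate predictor names")
  max_k <- min(check_count(max_k, "max_k"), length(predictors))
  out <- list()
  for (k in seq_len(max_k)) {
    cmb <- combn(predictors, k, simplify = FALSE)
    out <- c(out, cmb)
  }
  out
}

# VIF from the linear design: 1 / (1 - R^2) of each predictor regressed on
# the others. Single-predictor designs have VIF 1 by convention.
vif_design <- function(X) {
  X <- as.data.frame(X)
  p <- ncol(X)
  if (p == 1L) return(setNames(1, names(X)))
  vif <- numeric(p)
  for (j in seq_len(p)) {
    f <- lm(X[[j]] ~ ., data = X[, -j, drop = FALSE])
    r2 <- summary(f)$r.squared
    vif[j] <- 1 / (1 - min(r2, 1 - 1e-12))
  }
  setNames(vif, names(X))
}

#' Fit a Gaussian log-link GLM of a damage metric on traits
#'
#' The analysis model for canopy damage metrics: Gaussian family with log
#' link, so the expected damage is `exp(eta)` while errors are additive.
#' Responses are clamped into `[floor_y, ceiling_y]` before fitting (damage
#' percentages can be exactly 0 or 100, which the log link cannot
#' represent); the clamp count is recorded. Reports AIC (Gaussian
#' log-likelihood with estimated dispersion), McFadden pseudo r-squared
#' \eqn{1 - \ell_{model}/\ell_{null}}, deviance explained
#' \eqn{1 - D_{res}/D_{null}}, and per-predictor variance inflation
#' factors computed from the linear design. Fits with residual degrees of
#' freedom of 1 or less are flagged `saturated_regime`.
#'
#' @param y numeric response (damage percentage).
#' @param X data frame of predictor columns.
#' @param floor_y,ceiling_y clamp bounds applied to `y` before fitting.
#' @return An object of class `glm_fit`: list with `formula` (predictor
#'   names), `coefficients` (matrix: estimate, se), `aic`, `mcfadden_r2`,
#'   `deviance_explained`, `vif`, `n`, `n_clamped`, `saturated_regime`,
#'   `converged`, `model` (the underlying [stats::glm] object).
#' @export
#' @examples
#' set.seed(1)
#' x <- runif(50); y <- exp(1 + 0.5 * x) + rnorm(50, 0, 0.1)
#' fit_glm_log(y, data.frame(x = x))$coefficients
fit_glm_log <- function(y, X, floor_y = 0.5, ceiling_y = 99.5) {
  X <- as.data.frame(X)
  if (!nrow(X) || nrow(X) != length(y))
    stop_hs("y and X must have matching rows")
  if (!ncol(X)) stop_hs("X needs at least one predictor column")
  n <- length(y)
  k <- ncol(X)
  if (n <= k + 1L)
    stop_hs(sprintf("need n > k + 1 observations (n = %d, k = %d)", n, k))
  n_clamped <- sum(y < floor_y | y > ceiling_y)
  y <- pmin(pmax(y, floor_y), ceiling_y)

  qrx <- qr(cbind(1, as.matrix(X)))
  if (qrx$rank < k + 1L)
    stop_hs("singular design: predictors are linearly dependent")

  dat <- cbind(.y = y, X)
  fml <- as.formula(paste(".y ~", paste(names(X), collapse = " + ")))
  # non-convergence is recorded in the `converged` flag rather than
  # surfaced as a warning per enumerated subset
  muffle_conv <- function(w) {
    if (grepl("did not converge", conditionMessage(w)))
      invokeRestart("muffleWarning")
  }
  mus <- pmax(y, floor_y)
  fit <- withCallingHandlers(
    glm(fml, data = dat, family = gaussian(link = "log"), mustart = mus,
        control = list(maxit = 100)),
    warning = muffle_conv)
  null <- withCallingHandlers(
    glm(.y ~ 1, data = dat, family = gaussian(link = "log"),
        mustart = mus, control = list(maxit = 100)),
    warning = muffle_conv)
  ll <- as.numeric(logLik(fit))
  ll0 <- as.numeric(logLik(null))
  s <- summary(fit)
  structure(list(
    formula = names(X),
    coefficients = s$coefficients[, 1:2, drop = FALSE],
    aic = AIC(fit),
    mcfadden_r2 = 1 - ll / ll0,
    deviance_explained = 1 - fit$deviance / fit$null.deviance,
    vif = vif_design(X),
    n = n, n_clamped = n_clamped,
    saturated_regime = fit$df.residual <= 1L,
    converged = fit$converged,
    model = fit), class = "glm_fit")
}

#' @export
print.glm_fit <- function(x, ...) {
  cat(sprintf("<glm_fit> damage ~ %s\n", paste(x$formula, collapse = " + ")))
  cat(sprintf("  AIC = %.3f, McFadden R^2 = %.3f, deviance explained = %.3f\n",
              x$aic, x$mcfadden_r2, x$deviance_explained))
  cat(sprintf("  max VIF = %.2f, n = %d%s\n", max(x$vif), x$n,
              if (x$saturated_regime) " [saturated-regime]" else ""))
  invisible(x)
}

#' Rank a set of GLM fits by AIC
#'
#' Sorts ascending by AIC (ties broken by fewer predictors, then by input
#' order), computes \eqn{\Delta AIC_i = AIC_i - \min AIC} and Akaike
#' weights \eqn{w_i = e^{-\Delta_i / 2} / \sum_j e^{-\Delta_j / 2}}, and
#' marks the "similar support" set \eqn{\Delta AIC \le 2}.
#'
#' @param fits list of `glm_fit` objects.
#' @return An object of class `model_ranking`: data frame with one row per
#'   fit (`formula`, `k`, `aic`, `delta_aic`, `akaike_weight`,
#'   `similar_support`, `mcfadden_r2`, `deviance_explained`, `max_vif`,
#'   `saturated_regime`) with the fits (in ranked order) as attribute
#'   `"fits"`.
#' @export
rank_models <- function(fits) {
  if (inherits(fits, "glm_fit")) fits <- list(fits)
  if (!length(fits)) stop_hs("no fits to rank")
  stopifnot(all(vapply(fits, inherits, TRUE, "glm_fit")))
  aic <- vapply(fits, `[[`, numeric(1), "aic")
  k <- vapply(fits, function(f) length(f$formula), integer(1))
  ord <- order(aic, k, seq_along(fits))
  fits <- fits[ord]; aic <- aic[ord]; k <- k[ord]
  delta <- aic - aic[1]
  w <- exp(-delta / 2)
  w <- w / sum(w)
  out <- data.frame(
    formula = vapply(fits, function(f)
      paste(f$formula, collapse = " + "), character(1)),
    k = k, aic = aic, delta_aic = delta, akaike_weight = w,
    similar_support = delta <= 2,
    mcfadden_r2 = vapply(fits, `[[`, numeric(1), "mcfadden_r2"),
    deviance_explained = vapply(fits, `[[`, numeric(1),
                                "deviance_explained"),
    max_vif = vapply(fits, function(f) max(f$vif), numeric(1)),
    saturated_regime = vapply(fits, `[[`, logical(1), "saturated_regime"),
    stringsAsFactors = FALSE)
  attr(out, "fits") <- fits
  class(out) <- c("model_ranking", "data.frame")
  out
}

#' Select the best-supported model under a collinearity screen
#'
#' Returns the lowest-AIC fit in a [rank_models()] ranking whose every
#' predictor has VIF at or below `vif_threshold`; higher-ranked fits
#' failing the screen are recorded as excluded.
#'
#' @param ranking a `model_ranking`.
#' @param vif_threshold maximum tolerated variance inflation factor.
#' @return The selected `glm_fit`, with attributes `"excluded"` (data
#'   frame of skipped models and their max VIF) and `"rank"`.
#' @export
select_best <- function(ranking, vif_threshold = 10) {
  stopifnot(inherits(ranking, "model_ranking"))
  fits <- attr(ranking, "fits")
  excluded <- list()
  for (i in seq_along(fits)) {
    mv <- max(fits[[i]]$vif)
    if (mv <= vif_threshold) {
      best <- fits[[i]]
      attr(best, "excluded") <- if (length(excluded))
        do.call(rbind, excluded) else
          data.frame(formula = character(), max_vif = numeric())
      attr(best, "rank") <- i
      return(best)
    }
    excluded[[length(excluded) + 1L]] <- data.frame(
      formula = paste(fits[[i]]$formula, collapse = " + "), max_vif = mv,
      stringsAsFactors = FALSE)
  }
  stop_hs("no model passes the VIF screen; max VIFs: ",
          paste(sprintf("%s = %.1f",
                        vapply(fits, function(f)
                          paste(f$formula, collapse = "+"), character(1)),
                        vapply(fits, function(f) max(f$vif), numeric(1))),
                collapse = "; "))
}

#' Exhaustive GLM selection for one damage metric
#'
#' Convenience driver reproducing the damage-model workflow: enumerate all
#' predictor subsets up to `max_k`, fit a Gaussian log-link GLM for each,
#' rank by AIC with Akaike weights, and select the best model passing the
#' VIF screen.
#'
#' @param y damage metric (numeric).
#' @param traits data frame of candidate predictor columns.
#' @param predictors names of trait columns to consider; default: all.
#' @param max_k largest number of predictors per model.
#' @param vif_threshold collinearity exclusion threshold.
#' @return List with `ranking` (a `model_ranking`) and `best` (the
#'   selected `glm_fit`).
#' @export
damage_model_selection <- function(y, traits, predictors = names(traits),
                                   max_k = 3L, vif_threshold = 10) {
  traits <- as.data.frame(traits)
  check_columns(traits, predictors, "traits")
  subsets <- enumerate_models(predictors, max_k)
  fits <- lapply(subsets, function(ps)
    fit_glm_log(y, traits[, ps, drop = FALSE]))
  ranking <- rank_models(fits)
  list(ranking = ranking,
       best = select_best(ranking, vif_threshold))
}
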