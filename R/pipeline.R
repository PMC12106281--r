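# checked CSV I/O ------------------------------------------------------------

#' Read a CSV with a schema check
#'
#' Strict reader for the pipeline's flat-CSV dialect (comma separator, "."
#' decimal, UTF-8, header row). Errors name any missing column; malformed
#' numbers in a required numeric column are reported with their row index.
#' Extra columns are preserved.
#'
#' @param path file path.
#' @param columns named character vector: required column name ->
#'   `"numeric"`, `"integer"` or `"character"`.
#' @return Data frame.
#' @export
read_table_checked <- function(path, columns) {
  if (!file.exists(path)) stop_hs("file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  check_columns(df, names(columns), basename(path))
  for (col in names(columns)) {
    type <- columns[[col]]
    if (type %in% c("numeric", "integer")) {
      v <- df[[col]]
      if (is.character(v)) {
        num <- suppressWarnings(as.numeric(v))
        bad <- which(!is.na(v) & nzchar(v) & is.na(num))
        if (length(bad))
          stop_hs(sprintf(
            "%s: column '%s' has malformed number '%s' at row %d%s",
            basename(path), col, v[bad[1]], bad[1],
            if (grepl(",", v[bad[1]], fixed = TRUE))
              " (decimal commas are not supported; use '.')" else ""))
        df[[col]] <- num
      }
      if (type == "integer") df[[col]] <- as.integer(df[[col]])
    } else {
      df[[col]] <- as.character(df[[col]])
    }
  }
  df
}

#' Write a data frame in the pipeline CSV dialect
#'
#' @param df data frame.
#' @param path output path (directories are created).
#' @return `path`, invisibly.
#' @export
write_table <- function(df, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

# pipeline -------------------------------------------------------------------

#' Configuration for an end-to-end pipeline run
#'
#' With the default `inputs = NULL` the run is fully synthetic: every input
#' kind is generated from `species` (a list of [species_params()]) with the
#' given seed. Alternatively, `inputs` may name CSV files per data kind
#' (`pv`, `field`, `precip`, and per-species `events`/`psychrometer`
#' pairs).
#'
#' @param species list of [species_params()] objects; default the six
#'   reference species ([default_species_params()]).
#' @param seed integer master seed; stage seeds derive deterministically.
#' @param out_dir output directory for result tables, or `NULL` to skip
#'   writing.
#' @param n_leaves leaves (individuals) per species for the vulnerability
#'   and pressure-volume stages.
#' @param n_pixels embolism events per synthetic leaf.
#' @param n_individuals field individuals per species.
#' @param min_size,max_size_quantile optical event-filter settings; the
#'   synthetic generator emits single-pixel events, so `min_size` defaults
#'   to 1 here.
#' @param r2_min pressure-volume tail threshold.
#' @param max_k,vif_threshold damage-model selection settings.
#' @param damage_coefs damage generative model passed to
#'   [gen_damage_survey()]; `NULL` for a default model on `p50` and
#'   `height`.
#' @param inputs optional named list of input file paths (see above).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(species = default_species_params(),
                            seed = 1L, out_dir = NULL, n_leaves = 3L,
                            n_pixels = 500L, n_individuals = 10L,
                            min_size = 1, max_size_quantile = 1,
                            r2_min = 0.99, max_k = 3L, vif_threshold = 10,
                            damage_coefs = NULL, inputs = NULL) {
  stopifnot(all(vapply(species, inherits, TRUE, "species_params")))
  if (!is.null(inputs)) {
    stopifnot(is.list(inputs))
    for (p in unlist(inputs))
      if (!file.exists(p)) stop_hs("input file not found: ", p)
  }
  structure(list(species = species,
                 seed = check_count(seed, "seed", 0L),
                 out_dir = out_dir,
                 n_leaves = check_count(n_leaves, "n_leaves"),
                 n_pixels = check_count(n_pixels, "n_pixels"),
                 n_individuals = check_count(n_individuals,
                                             "n_individuals"),
                 min_size = check_number(min_size, "min_size", lower = 0),
                 max_size_quantile = check_number(max_size_quantile,
                                                  "max_size_quantile",
                                                  0, 1),
                 r2_min = check_number(r2_min, "r2_min", 0, 1),
                 max_k = check_count(max_k, "max_k"),
                 vif_threshold = check_number(vif_threshold,
                                              "vif_threshold", lower = 1),
                 damage_coefs = damage_coefs,
                 inputs = inputs),
            class = "pipeline_config")
}

#' Run the full trait-inference pipeline
#'
#' Composes the stages in measurement order: optical embolism
#' quantification per leaf, sigmoid vulnerability fits and species curves,
#' pressure-volume trait extraction, field water potentials, safety
#' margins and predicted percent embolism, the single-trait regression of
#' TLP on log elastic modulus, exhaustive damage-model selection per
#' metric, and the 12-month SPI of the precipitation series. With
#' synthetic inputs every stage's ground truth is known, so the run report
#' doubles as an end-to-end recovery check.
#'
#' @param config a [pipeline_config()].
#' @return An object of class `pipeline_run`: list with result tables
#'   (`species_curves`, `pv_traits`, `margins`, `lm_results`,
#'   `model_ranking`, `best_models`, `spi`), the `report` (stage record
#'   counts and warnings) and `config`.
#' @export
#' @examples
#' \donttest{
#' run <- run_pipeline(pipeline_config(seed = 1, n_pixels = 300))
#' run$report$counts
#' }
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  warnings_log <- character()
  note <- function(...) {
    warnings_log[[length(warnings_log) + 1L]] <<- sprintf(...)
  }
  counts <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop_hs(sprintf("stage '%s' failed: %s", name, conditionMessage(e))))
  }
  species <- config$species
  sp_names <- vapply(species, `[[`, character(1), "name")

  # --- optical embolism + vulnerability ------------------------------------
  curves <- stage("optical-vulnerability", {
    rows <- list()
    for (i in seq_along(species)) {
      fits <- list()
      for (leaf in seq_len(config$n_leaves)) {
        cfg <- gen_config(seed = child_seed(config$seed,
                                            100L * i + leaf),
                          n_pixels = config$n_pixels)
        camp <- gen_embolism_campaign(species[[i]], cfg)
        trace <- withCallingHandlers(
          ov_quantify(camp$events, camp$psychrometer,
                      min_size = config$min_size,
                      max_size_quantile = config$max_size_quantile),
          warning = function(w) {
            note("OV %s leaf %d: %s", sp_names[i], leaf,
                 conditionMessage(w))
            invokeRestart("muffleWarning")
          })
        fit <- withCallingHandlers(fit_sigmoid(trace),
          warning = function(w) {
            note("VC fit %s leaf %d: %s", sp_names[i], leaf,
                 conditionMessage(w))
            invokeRestart("muffleWarning")
          })
        if (fit$poorly_constrained)
          note("VC fit %s leaf %d: poorly constrained", sp_names[i], leaf)
        fits[[leaf]] <- fit
      }
      cu <- species_curve(fits, species = sp_names[i])
      rows[[i]] <- data.frame(species = cu$species, a_mean = cu$a_mean,
                              a_se = cu$a_se, b_mean = cu$b_mean,
                              b_se = cu$b_se, p12 = cu$p12, p50 = cu$p50,
                              p88 = cu$p88, n = cu$n_individuals,
                              stringsAsFactors = FALSE)
    }
    do.call(rbind, rows)
  })
  counts$species_curves <- nrow(curves)

  # --- pressure-volume ------------------------------------------------------
  pv_traits_tab <- stage("pressure-volume", {
    rows <- list()
    for (i in seq_along(species)) {
      per_leaf <- matrix(NA_real_, config$n_leaves, 3)
      for (leaf in seq_len(config$n_leaves)) {
        cfg <- gen_config(seed = child_seed(config$seed,
                                            10000L + 100L * i + leaf))
        pv <- gen_pv_series(species[[i]], cfg)
        cv <- pv_curve(pv$points, pv$dry_mass)
        tr <- extract_pv_traits(cv, r2_min = config$r2_min)
        per_leaf[leaf, ] <- c(tr$tlp, tr$psi_osm_ft, tr$eps)
      }
      m <- colMeans(per_leaf)
      se <- apply(per_leaf, 2, sd) / sqrt(config$n_leaves)
      rows[[i]] <- data.frame(species = sp_names[i], tlp = m[1],
                              tlp_se = se[1], psi_osm_ft = m[2],
                              eps = m[3], n = config$n_leaves,
                              stringsAsFactors = FALSE)
    }
    do.call(rbind, rows)
  })
  counts$pv_traits <- nrow(pv_traits_tab)

  # --- field campaign + margins --------------------------------------------
  field <- stage("field-campaign", {
    gen_field_campaign(species,
                       cfg = gen_config(seed = child_seed(config$seed,
                                                          20000L),
                                        n_individuals =
                                          config$n_individuals))
  })
  counts$field <- nrow(field)

  margins <- stage("safety-margins",
                   safety_margins(curves, pv_traits_tab, field))
  counts$margins <- nrow(margins)

  # --- trait regressions ----------------------------------------------------
  lm_results <- stage("trait-regressions", {
    if (nrow(pv_traits_tab) >= 3L) {
      f <- fit_lm_single(log(pv_traits_tab$eps), pv_traits_tab$tlp)
      data.frame(response = "tlp", predictor = "log(eps)",
                 slope = f$slope, intercept = f$intercept, r2 = f$r2,
                 p_value = f$p_value, n = f$n, stringsAsFactors = FALSE)
    } else {
      note("trait-regressions: skipped (fewer than 3 species)")
      data.frame(response = character(), predictor = character(),
                 slope = numeric(), intercept = numeric(), r2 = numeric(),
                 p_value = numeric(), n = integer())
    }
  })
  counts$lm_results <- nrow(lm_results)

  # --- damage surveys + model selection ------------------------------------
  damage_out <- stage("damage-models", {
    traits <- merge(curves[, c("species", "p50")],
                    pv_traits_tab[, c("species", "tlp", "eps",
                                      "psi_osm_ft")], by = "species")
    tt <- thicket_traits()
    traits <- merge(traits, tt[, c("species", "height", "lma")],
                    by = "species", all.x = TRUE)
    dry <- margins[margins$period == margins$period[1], ]
    traits <- merge(traits, dry[, c("species", "ppe_mean")],
                    by = "species")
    if (nrow(traits) < 5L) {
      note("damage-models: skipped (fewer than 5 species)")
      list(ranking = data.frame(), best = data.frame(),
           survey = data.frame())
    } else {
      coefs <- config$damage_coefs
      if (is.null(coefs))
        coefs <- list(
          crown_extent = c("(Intercept)" = 4.8, p50 = 0.05),
          foliage = c("(Intercept)" = 4.9, ppe_mean = -0.012),
          dead_leaves = c("(Intercept)" = 1.0, ppe_mean = 0.03),
          discoloration = c("(Intercept)" = 2.0, height = 0.3))
      survey <- gen_damage_survey(traits, coefs, noise_sd = 2,
                                  cfg = gen_config(seed =
                                    child_seed(config$seed, 30000L)))
      predictors <- intersect(c("p50", "tlp", "eps", "psi_osm_ft", "lma",
                                "height", "ppe_mean"), names(traits))
      predictors <- predictors[vapply(predictors, function(p)
        all(is.finite(traits[[p]])), TRUE)]
      rankings <- list(); best <- list()
      for (metric in names(coefs)) {
        sel <- damage_model_selection(survey[[metric]],
                                      traits[, predictors, drop = FALSE],
                                      max_k = config$max_k,
                                      vif_threshold = config$vif_threshold)
        r <- as.data.frame(sel$ranking)
        r$metric <- metric
        rankings[[metric]] <- r
        if (any(sel$ranking$saturated_regime))
          note("damage model %s: saturated-regime fits present", metric)
        if (!sel$best$converged)
          note("damage model %s: selected fit did not converge", metric)
        best[[metric]] <- data.frame(
          metric = metric,
          formula = paste(sel$best$formula, collapse = " + "),
          aic = sel$best$aic, mcfadden_r2 = sel$best$mcfadden_r2,
          deviance_explained = sel$best$deviance_explained,
          max_vif = max(sel$best$vif), stringsAsFactors = FALSE)
      }
      list(ranking = do.call(rbind, rankings),
           best = do.call(rbind, best), survey = survey)
    }
  })
  counts$model_ranking <- nrow(damage_out$ranking)

  # --- climate --------------------------------------------------------------
  spi_tab <- stage("climate-spi", {
    pr <- gen_precip(gen_config(seed = child_seed(config$seed, 40000L)),
                     drought_start_year = 35L)
    fit_spi(rolling_sum(pr, 12L))
  })
  counts$spi <- nrow(spi_tab)

  out <- list(species_curves = curves, pv_traits = pv_traits_tab,
              field = field, margins = margins, lm_results = lm_results,
              model_ranking = damage_out$ranking,
              best_models = damage_out$best,
              damage_survey = damage_out$survey,
              spi = as.data.frame(spi_tab),
              report = list(counts = counts, warnings = warnings_log,
                            seed = config$seed),
              config = config)
  class(out) <- "pipeline_run"

  if (!is.null(config$out_dir)) {
    d <- config$out_dir
    write_table(curves, file.path(d, "species_curves.csv"))
    write_table(pv_traits_tab, file.path(d, "pv_traits.csv"))
    write_table(margins, file.path(d, "margins.csv"))
    write_table(lm_results, file.path(d, "lm_results.csv"))
    write_table(damage_out$ranking, file.path(d, "model_ranking.csv"))
    write_table(damage_out$best, file.path(d, "best_models.csv"))
    write_table(as.data.frame(spi_tab), file.path(d, "spi.csv"))
    jsonlite::write_json(
      list(seed = config$seed,
           counts = counts, warnings = warnings_log),
      file.path(d, "run_report.json"), auto_unbox = TRUE, digits = NA)
  }
  out
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat("<pipeline_run>\n")
  for (nm in names(x$report$counts))
    cat(sprintf("  %-16s %d records\n", nm, x$report$counts[[nm]]))
  if (length(x$report$warnings))
    cat("  warnings:", length(x$report$warnings), "\n")
  invisible(x)
}
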