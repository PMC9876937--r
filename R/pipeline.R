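#' Assemble a resolved pipeline configuration
#'
#' Collects every tunable of the chain — simulation conditions, calibration
#' constants, extraction filters, the full model specification and the
#' confidence level — into one document with field-study defaults: the
#' lowest-30% resting filter, the 3 degree C nest-temperature outlier rule,
#' the 8-29 degree C analysis range, 1-h twilight-transition exclusion,
#' RQ 0.85, 20.37 J/ml O2, 80 l/h flow and a 95% confidence set.
#'
#' @param config optional list (or path to a YAML file) overriding defaults;
#'   nested lists are merged key-wise.
#' @param seed integer seed overriding the config's seed.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(config = list(), seed = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  def <- list(
    sim = list(),                      # simulation_config() overrides
    params = list(),                   # true_model_params() overrides
    filters = list(lowest_fraction = 0.30, t_range = c(8, 29),
                   outlier_threshold_c = 3, transition_h = 1,
                   min_samples = 6, absence_threshold = 0.25,
                   absence_min_bout_min = 30),
    model = list(
      main_terms = c("t_nest_int", "habitat", "diel", "run", "housing_half"),
      interactions = c("habitat:t_nest_int", "habitat:run"),
      random_slope = TRUE, nest_housing = TRUE),
    conf_level = 0.95,
    occupancy = "detect",              # "detect" or "truth"
    seed = 1L
  )
  cfg <- utils::modifyList(def, config)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  cfg$sim$seed <- cfg$seed
  structure(cfg, class = "pipeline_config")
}

# process one raw trace into a VO2 series + occupancy mask
process_trace <- function(trace, calib, noise_sd_vo2, filters,
                          truth_occupied = NULL) {
  corrected <- correct_baseline(trace, calib$fio2_reference)
  vo2 <- compute_vo2(corrected, calib, noise_sd_vo2 = noise_sd_vo2)
  override <- NULL
  if (!is.null(truth_occupied)) {
    override <- truth_occupied[!trace$is_zero_check]
  }
  mask <- detect_absence(vo2, filters$absence_threshold,
                         filters$absence_min_bout_min,
                         override_mask = override)
  list(vo2 = vo2, mask = mask)
}

#' Run the full analysis chain: simulate, process, extract, fit, report
#'
#' Simulates a cohort (raw traces, environment logs, metadata, ground
#' truth), processes traces to drift-corrected VO2 series with occupancy
#' masks, extracts the hourly mass-specific RMR table, fits all candidate
#' mixed models with ML, ranks them by AICc, refits the top model with REML
#' for the effect-size panel, computes the univariate group comparisons,
#' and (optionally) writes the report bundle to `out_dir`.
#'
#' @param config a [pipeline_config()] (or overrides list / YAML path).
#' @param out_dir output directory; `NULL` for in-memory only.
#' @return (invisibly) list with `records`, `audit`, `selection`,
#'   `effects`, `group_stats`, `recovery`, `cohort`, `config`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  if (!inherits(config, "pipeline_config")) config <- pipeline_config(config)
  sim_args <- config$sim
  sim_args$seed <- config$seed
  sim_cfg <- do.call(simulation_config, sim_args)
  params <- do.call(true_model_params, config$params)
  cohort <- simulate_cohort(sim_cfg, params)

  calib <- calibration_info(fio2_reference = sim_cfg$fio2_ambient,
                            flow_rate_stp = sim_cfg$flow_rate,
                            rq = params$rq,
                            barometric_pressure_kpa = sim_cfg$pressure_kpa)
  denom <- 1 - calib$fio2_reference * (1 - calib$rq)
  noise_sd_vo2 <- sim_cfg$noise_sd * calib$flow_rate_stp / denom

  vo2 <- list()
  masks <- list()
  for (key in names(cohort$traces)) {
    truth_occ <- if (config$occupancy == "truth") {
      cohort$truth$samples[[key]]$occupied
    } else NULL
    pr <- process_trace(cohort$traces[[key]], calib, noise_sd_vo2,
                        config$filters, truth_occ)
    vo2[[key]] <- pr$vo2
    masks[[key]] <- pr$mask
  }

  env_clean <- clean_tnest(cohort$env, config$filters$outlier_threshold_c)
  ex <- extract_hourly_rmr(vo2, masks, env_clean, cohort$metadata,
                           sim_cfg$lat, sim_cfg$lon,
                           lowest_fraction = config$filters$lowest_fraction,
                           t_range = config$filters$t_range,
                           min_samples = config$filters$min_samples,
                           transition_h = config$filters$transition_h)

  # time outside the box per individual (h per measurement day), from the
  # occupancy actually used downstream
  dt_h <- sim_cfg$sample_interval_s / 3600
  keys <- names(cohort$traces)
  key_id <- sub("_\\d{4}-\\d{2}-\\d{2}$", "", keys)
  time_outside <- vapply(split(keys, key_id), function(ks) {
    mean(vapply(ks, function(k) sum(!masks[[k]]) * dt_h, numeric(1)))
  }, numeric(1))
  gs <- group_stats_report(cohort$metadata, time_outside)

  mdl <- config$model
  cand <- enumerate_candidates(mdl$main_terms, mdl$interactions)
  fits <- lapply(cand, function(tm) {
    fit_lmm(ex$records, tm, method = "ML",
            random_slope = mdl$random_slope,
            nest_housing = mdl$nest_housing)
  })
  sel <- build_selection_table(fits, config$conf_level)
  top_terms <- sel$fits[[1]]$terms
  eff <- effect_sizes(ex$records, top_terms,
                      random_slope = mdl$random_slope,
                      nest_housing = mdl$nest_housing)

  recovery <- recovery_report(eff, params)

  out <- list(records = ex$records, audit = ex$audit, selection = sel,
              effects = eff, group_stats = gs, recovery = recovery,
              cohort = cohort, config = config)
  if (!is.null(out_dir)) write_report_bundle(out, out_dir)
  invisible(out)
}

# truth-vs-estimate table for the generating coefficients present in the
# top model
recovery_report <- function(eff, params) {
  cs <- eff$fit$coefficients
  truth <- c("(Intercept)" = params$intercept,
             "t_nest_int" = params$beta_t,
             "habitaturban" = params$beta_habitat,
             "habitaturban:t_nest_int" = params$beta_interaction,
             "dielnight" = params$beta_night,
             "run2" = params$run_effects[2],
             "run3" = params$run_effects[3],
             "run4" = params$run_effects[4])
  common <- intersect(rownames(cs), names(truth))
  data.frame(coefficient = common,
             truth = unname(truth[common]),
             estimate = cs[common, "estimate"],
             se = cs[common, "se"],
             covered = truth[common] >= cs[common, "ci_low"] &
               truth[common] <= cs[common, "ci_high"],
             row.names = NULL)
}

# write the report bundle: CSV tables + JSON panels + resolved config
write_report_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, f) utils::write.csv(df, file.path(out_dir, f),
                                        row.names = FALSE)
  w(bundle$records, "rmr_records.csv")
  w(bundle$selection$table, "selection_table.csv")
  w(bundle$group_stats, "group_stats.csv")
  w(bundle$recovery, "recovery.csv")
  cs <- bundle$effects$fit$coefficients
  top <- list(
    terms = bundle$effects$fit$terms,
    n = bundle$effects$fit$n,
    aicc = bundle$effects$fit$aicc,
    coefficients = data.frame(coefficient = rownames(cs),
                              cs[, c("estimate", "se", "df",
                                     "ci_low", "ci_high")],
                              row.names = NULL),
    cohens_f2 = as.list(bundle$effects$f2),
    icc = bundle$effects$icc,
    r2_marginal = bundle$effects$r2_marginal,
    r2_conditional = bundle$effects$r2_conditional,
    variable_weights = as.list(bundle$selection$variable_weights)
  )
  jsonlite::write_json(top, file.path(out_dir, "top_model.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(bundle$audit, file.path(out_dir, "audit.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  cfg <- unclass(bundle$config)
  yaml::write_yaml(cfg, file.path(out_dir, "config.yaml"))
  invisible(out_dir)
}

#' Prediction curves of the top model over the analysis temperature range
#'
#' @param eff an `effect_size_panel` from [effect_sizes()].
#' @param t_range integer temperature range (default 8-29).
#' @return data.frame of population-level predictions per habitat x diel x
#'   integer nest temperature (reference run, second housing half).
#' @export
prediction_curves <- function(eff, t_range = c(8, 29)) {
  grid <- expand.grid(t_nest_int = seq(t_range[1], t_range[2]),
                      habitat = c("forest", "urban"),
                      diel = c("day", "night"),
                      run = factor(1, levels = 1:4),
                      housing_half = "second",
                      stringsAsFactors = FALSE)
  fit <- eff$fit$fit
  grid$rmr_mass_specific <- stats::predict(fit, newdata = grid, re.form = NA)
  grid
}
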