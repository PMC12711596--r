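#' Deterministic child seed for a pipeline stage
#'
#' Hash of (master seed, stage name, replicate) kept below 2^31 so every
#' stage draws from its own reproducible stream and no stage perturbs
#' another's randomness.
#'
#' @param master integer master seed.
#' @param stage stage name (character).
#' @param rep replicate number (default 0).
#' @return integer seed.
#' @export
derive_seed <- function(master, stage, rep = 0L) {
  u <- utf8ToInt(stage)
  h <- sum(u * seq_along(u))
  as.integer((as.numeric(master) %% 2147483647 * 7919 +
                h * 104729 + as.numeric(rep) * 131071) %% 2147483647)
}

#' Workflow configuration with study defaults
#'
#' Collects every tunable of the end-to-end workflow. The defaults are the
#' study configuration: 15-km thinning grid, 10,000 pseudo-absences x 3
#' replicates at a 40% survey-effort floor, VIF threshold 5, all ten
#' algorithms, 70/30 calibration split x 3 cross-validation replicates,
#' ensemble gate TSS > 0.60, and two future scenarios per pseudo-GCM
#' ensemble of five. The synthetic landscape is 100 x 100 cells of 3 km
#' (pixel area `cell_size^2` km2).
#'
#' @param ... overrides of any default (unknown names are an error).
#' @return an object of class `run_config` (a named list).
#' @export
run_config <- function(...) {
  cfg <- list(
    extent = c(300, 300), cell_size = 3,
    n_predictors = 6,
    collinear_pairs = list(c(5, 6, 0.9)),
    smoothness = 2,
    truth_coefficients = c(env_1 = 8, env_2 = -5.2, env_3 = 4),
    truth_intercept = -3,
    bias_smoothness = 8, bias_strength = 2,
    n_presences_raw = 3000,
    n_target_species = 19, n_per_species = 200,
    thin_cell_km = 15,
    date_range = c(1970, 2024),
    pa_n = 10000, pa_replicates = 3, effort_floor = 0.40,
    relax_step = 0.05, effort_window = 3,
    vif_threshold = 5, vif_sample_cells = 10000,
    predictor_subset = NULL,
    algorithms = sdm_algorithms(),
    train_fraction = 0.70, cv_replicates = 3, tss_cutoff = 0.60,
    hyper = list(),
    scenarios = list(ssp126_2050 = c(env_1 = -0.3),
                     ssp585_2050 = c(env_1 = -1.0)),
    n_gcms = 5, gcm_noise_sd = 0.05,
    n_zones = 4, n_farms = 10,
    capacity_range_mw = c(20, 400),
    status_probs = c(1, 1, 1) / 3,
    pixel_area_km2 = NULL,
    seed = 1
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config field(s): ",
                        paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  stopifnot(cfg$train_fraction > 0, cfg$train_fraction < 1,
            cfg$pa_n >= 1, cfg$pa_replicates >= 1, cfg$cv_replicates >= 1,
            cfg$vif_threshold > 1, cfg$effort_floor >= 0,
            cfg$effort_floor <= 1, cfg$tss_cutoff >= -1, cfg$tss_cutoff <= 1)
  structure(cfg, class = c("run_config", "list"))
}

#' Run the full synthetic-landscape workflow
#'
#' Executes the whole chain on a generated landscape: predictor stack with
#' known truth -> biased presence sampling -> cleaning -> 15-km thinning ->
#' VIF screening -> envelope/median-split pseudo-absence generation with
#' effort-floor bias correction -> multi-algorithm TSS-weighted ensemble ->
#' current map -> scenario projection and change accounting -> zonal and
#' wind-farm overlays. Every stage seed derives from `config$seed` via
#' [derive_seed()], so a config reproduces bit-identical outputs.
#'
#' @param config a [run_config()].
#' @param output_dir optional directory; when given, tables (CSV), the
#'   manifest (JSON) and the current/binary maps (ASCII grid) are written.
#' @return list with `manifest` (stage-by-stage accounting), `stack`,
#'   `truth`, `occurrences`, `pa`, `fit` (the `esdm` object), `current`
#'   (list `suitability`, `binary`), `scenarios` (per scenario: projection,
#'   change map, change stats), `zonal`, `windfarms`, `overlap`.
#' @export
run_all <- function(config = run_config(), output_dir = NULL) {
  cfg <- config
  manifest <- list(config = cfg[setdiff(names(cfg), "hyper")])
  pix <- cfg$pixel_area_km2 %||% cfg$cell_size^2

  spec <- landscape_spec(cfg$extent, cfg$cell_size, cfg$n_predictors,
                         cfg$collinear_pairs, cfg$smoothness,
                         derive_seed(cfg$seed, "landscape"))
  stack <- make_stack(spec)
  truth <- make_truth(stack, cfg$truth_coefficients, cfg$truth_intercept)
  bias <- make_bias_field(truth$surface, cfg$bias_smoothness,
                          cfg$bias_strength,
                          derive_seed(cfg$seed, "bias"))
  manifest$landscape <- list(cells = length(truth$surface$values),
                             n_predictors = cfg$n_predictors)

  raw <- sample_presences(truth, bias, cfg$n_presences_raw,
                          derive_seed(cfg$seed, "presences"))
  cleaned <- clean_occurrences(raw, valid_mask = truth$surface,
                               date_range = cfg$date_range)
  thinned <- thin_occurrences(cleaned$occurrences, cfg$thin_cell_km,
                              seed = derive_seed(cfg$seed, "thin"))
  manifest$occurrences <- list(raw = nrow(raw),
                               cleaned = nrow(cleaned$occurrences),
                               thinned = nrow(thinned),
                               report = cleaned$report)

  # surrogate species share the observers (bias field) but have their own
  # habitat preferences, so survey effort tracks accessibility, not the
  # focal species' suitability
  set.seed(derive_seed(cfg$seed, "surrogates"))
  surrogate_truths <- lapply(seq_len(cfg$n_target_species), function(s) {
    cf <- stats::setNames(stats::rnorm(3, sd = 1.5),
                          sample(names(stack$layers), 3))
    make_truth(stack, cf)
  })
  tg_raw <- make_target_group(surrogate_truths, bias, cfg$n_target_species,
                              cfg$n_per_species,
                              derive_seed(cfg$seed, "target_group"))
  tg <- clean_occurrences(tg_raw, valid_mask = truth$surface,
                          date_range = cfg$date_range)$occurrences
  effort <- survey_effort(tg, truth$surface, cfg$effort_window)
  manifest$target_group <- list(records = nrow(tg),
                                max_effort = effort$max_effort)

  model_stack <- if (is.null(cfg$predictor_subset)) stack
                 else stack[cfg$predictor_subset]
  scr <- vif_screen(model_stack, cfg$vif_sample_cells, cfg$vif_threshold,
                    derive_seed(cfg$seed, "vif"))
  manifest$vif <- scr$report

  idx <- envelope_index(scr$stack, thinned)
  zones01 <- split_zones(idx, thinned)
  pa <- withCallingHandlers(
    sample_pseudo_absences(zones01, effort, thinned, cfg$pa_n,
                           cfg$effort_floor, cfg$pa_replicates,
                           cfg$relax_step,
                           derive_seed(cfg$seed, "pa")),
    warning = function(w) invokeRestart("muffleWarning"))
  manifest$pseudo_absence <- list(n_per_replicate = cfg$pa_n,
                                  replicates = cfg$pa_replicates,
                                  floor_used = attr(pa, "floor_used"),
                                  candidates = attr(pa, "n_candidates"),
                                  degraded = attr(pa, "degraded"))

  fit <- esdm(pa, stack = scr$stack, algorithms = cfg$algorithms,
              train_fraction = cfg$train_fraction,
              cv_replicates = cfg$cv_replicates,
              tss_cutoff = cfg$tss_cutoff, hyper = cfg$hyper,
              seed = derive_seed(cfg$seed, "esdm"))
  manifest$models <- list(n_runs = nrow(fit$runs),
                          n_members = length(fit$members),
                          ensemble_auc = fit$eval$auc,
                          ensemble_tss = fit$eval$tss,
                          threshold = fit$threshold)

  suit <- predict(fit, scr$stack)
  bin <- binarise(suit, fit$threshold)
  current <- list(suitability = suit, binary = bin)

  futures <- make_futures(stack, cfg$scenarios, cfg$n_gcms,
                          cfg$gcm_noise_sd,
                          derive_seed(cfg$seed, "futures"))
  scen_out <- lapply(stats::setNames(nm = names(futures)), function(sc) {
    gcms <- lapply(futures[[sc]], function(s) s[names(scr$stack$layers)])
    pr <- project_scenario(fit, gcms, threshold = fit$threshold)
    cm <- change_map(bin, pr$binary)
    list(projection = pr, change = cm, stats = change_stats(cm, pix))
  })
  manifest$scenarios <- lapply(scen_out, function(s)
    s$stats[c("loss_km2", "gain_km2", "net_km2", "net_pct")])

  zones <- make_zones(cfg$extent, cfg$n_zones,
                      derive_seed(cfg$seed, "zones"))
  zonal <- zonal_suitable(bin, zones, pix)
  farms <- make_windfarms(cfg$extent, cfg$n_farms, cfg$capacity_range_mw,
                          cfg$status_probs,
                          derive_seed(cfg$seed, "windfarms"))
  overlap <- windfarm_overlap(bin, farms, pix)
  manifest$overlay <- list(zonal = zonal, by_status = overlap$by_status)

  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(fit$runs, file.path(output_dir, "runs.csv"),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(pa), file.path(output_dir, "pa.csv"),
                     row.names = FALSE)
    utils::write.csv(zonal, file.path(output_dir, "zonal.csv"),
                     row.names = FALSE)
    utils::write.csv(overlap$by_status,
                     file.path(output_dir, "windfarm_overlap.csv"),
                     row.names = FALSE)
    write_ascii_grid(suit, file.path(output_dir, "suitability.asc"))
    write_ascii_grid(bin, file.path(output_dir, "suitability_binary.asc"))
    write_occurrences(thinned, file.path(output_dir, "occurrences.csv"))
    jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = 10, force = TRUE)
  }

  list(manifest = manifest, stack = stack, truth = truth,
       occurrences = thinned, effort = effort, pa = pa, fit = fit,
       current = current, scenarios = scen_out, zones = zones,
       zonal = zonal, windfarms = farms, overlap = overlap)
}
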