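#' Ground-truth parameter-recovery benchmark
#'
#' Runs the modelling chain on a landscape with a known logistic truth so
#' surface recovery can be scored exactly. The landscape is 100 x 100 cells
#' (1 km) with five standardised predictor fields — three informative
#' (coefficients 8, -5.2 and 4 on the logit scale, intercept -3, a strong
#' signal with realistic saturation) and two noise layers. Presences are
#' sampled under a two-block accessibility bias (west half 0.5, east half
#' 1.0); nineteen surrogate species with their own random habitat
#' preferences share the bias field and provide the survey-effort layer;
#' pseudo-absences come from the envelope low zone under the 40% effort
#' floor.
#'
#' @param seed integer master seed.
#' @param n_presences presence records (default 500).
#' @param n_pa pseudo-absences per replicate (default 2000).
#' @param algorithms ensemble members (default GLM, RF, GBM, SRE).
#' @param tss_cutoff ensemble gate (default 0.60).
#' @param cv_replicates cross-validation splits (default 1).
#' @return list with `stack`, `truth`, `presences`, `pa`, `fit` (the `esdm`
#'   object), `map` (ensemble suitability `raster_grid`), `auc` (pooled
#'   holdout ensemble AUC), `map_truth_r` (Pearson correlation between the
#'   ensemble map and the true surface over valid cells).
#' @export
recovery_benchmark <- function(seed = 1, n_presences = 500, n_pa = 2000,
                               algorithms = c("GLM", "RF", "GBM", "SRE"),
                               tss_cutoff = 0.60, cv_replicates = 1) {
  spec <- landscape_spec(extent = c(100, 100), cell_size = 1,
                         n_predictors = 5, smoothness = 2,
                         seed = derive_seed(seed, "landscape"))
  stack <- make_stack(spec)
  truth <- make_truth(stack, c(env_1 = 8, env_2 = -5.2, env_3 = 4),
                      intercept = -3)
  bv <- matrix(0.5, 100, 100); bv[, 51:100] <- 1
  bias <- raster_grid(bv)
  presences <- sample_presences(truth, bias, n_presences,
                                seed = derive_seed(seed, "presences"))
  set.seed(derive_seed(seed, "surrogates"))
  surrogates <- lapply(seq_len(19), function(s)
    make_truth(stack, stats::setNames(stats::rnorm(3, sd = 1.5),
                                      sample(names(stack$layers), 3))))
  effort <- survey_effort(
    make_target_group(surrogates, bias, 19, 100,
                      seed = derive_seed(seed, "target_group")),
    truth$surface)
  idx <- envelope_index(stack, presences)
  zones01 <- split_zones(idx, presences)
  pa <- withCallingHandlers(
    sample_pseudo_absences(zones01, effort, presences, n = n_pa,
                           replicates = 1,
                           seed = derive_seed(seed, "pa")),
    warning = function(w) invokeRestart("muffleWarning"))
  fit <- esdm(pa, stack = stack, algorithms = algorithms,
              cv_replicates = cv_replicates, tss_cutoff = tss_cutoff,
              seed = derive_seed(seed, "esdm"))
  map <- predict(fit, stack)
  r <- stats::cor(as.vector(map$values), as.vector(truth$surface$values),
                  use = "complete.obs")
  list(stack = stack, truth = truth, presences = presences, pa = pa,
       fit = fit, map = map, auc = fit$eval$auc, map_truth_r = r)
}
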