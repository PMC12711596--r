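#' Stratified train/test splits of a presence/pseudo-absence set
#'
#' Draws `cv_replicates` independent splits, each stratified by label so the
#' class ratio is preserved within one record; weights travel with the rows.
#'
#' @param data data.frame with columns `label` and `weight` (one replicate).
#' @param train_fraction fraction used for calibration (default 0.70).
#' @param cv_replicates number of independent splits (default 3).
#' @param seed integer seed.
#' @return list of `cv_replicates` lists with elements `train` and `test`
#'   (integer row indices).
#' @export
split_train_test <- function(data, train_fraction = 0.70, cv_replicates = 3,
                             seed = 1) {
  if (!all(c(0, 1) %in% data$label))
    stop("both classes required for splitting")
  lapply(seq_len(cv_replicates), function(r) {
    set.seed(derive_seed(seed, "cv_split", r))
    for (attempt in 1:10) {
      tr <- unlist(lapply(split(seq_len(nrow(data)), data$label),
                          function(ix)
                            sample(ix, round(train_fraction * length(ix)))))
      tr <- sort(unname(tr))
      te <- setdiff(seq_len(nrow(data)), tr)
      if (all(c(0, 1) %in% data$label[tr]) &&
          all(c(0, 1) %in% data$label[te]))
        return(list(train = tr, test = te))
    }
    stop("could not produce a split containing both classes")
  })
}

#' Fit a TSS-weighted ensemble species distribution model
#'
#' The package's central fitting function. For every combination of
#' pseudo-absence replicate and cross-validation split, each requested
#' algorithm is calibrated on the training fraction and evaluated (AUC and
#' TSS with threshold optimisation) on the holdout. Runs whose TSS exceeds
#' `tss_cutoff` (strictly) become ensemble members with weights proportional
#' to their TSS; the ensemble score is the weighted mean of member scores.
#' A default binarisation threshold is chosen by maximising the ensemble TSS
#' over the pooled holdout records.
#'
#' @param data a [sample_pseudo_absences()] `pa_set` (requires `stack`), or a
#'   data.frame with columns `label`, optional `weight` and `replicate_id`,
#'   and predictor columns.
#' @param stack a `predictor_stack` used to extract predictor values at
#'   `pa_set` point locations (and the feature space for [predict.esdm()]).
#' @param algorithms character vector from [sdm_algorithms()].
#' @param train_fraction calibration fraction (default 0.70).
#' @param cv_replicates cross-validation splits per pseudo-absence replicate
#'   (default 3).
#' @param tss_cutoff ensemble admission gate; members need TSS strictly
#'   greater than this (default 0.60).
#' @param hyper named list of hyperparameters passed to [fit_learner()].
#' @param seed integer master seed.
#' @return an object of class `esdm`: list with `runs` (evaluation table),
#'   `members`, `weights`, `eval` (pooled-holdout ensemble AUC/TSS),
#'   `threshold` (default binarisation threshold), `features`, `call`.
#' @seealso [predict.esdm()], [build_ensemble()], [variable_importance()]
#' @examples
#' spec <- landscape_spec(extent = c(60, 60), cell_size = 1,
#'                        n_predictors = 3, seed = 7)
#' stack <- make_stack(spec)
#' truth <- make_truth(stack, c(env_1 = 2, env_2 = -1))
#' pres <- sample_presences(truth, make_bias_field(truth$surface, seed = 2),
#'                          150, seed = 3)
#' pa <- data.frame(label = rep(c(1, 0), each = 150),
#'                  rbind(extract_stack(stack, pres$lon, pres$lat),
#'                        extract_stack(stack,
#'                                      runif(150, 0, 60),
#'                                      runif(150, 0, 60))))
#' fit <- esdm(pa, algorithms = c("GLM", "SRE"), cv_replicates = 1,
#'             tss_cutoff = 0.2, seed = 1)
#' fit
#' @export
esdm <- function(data, stack = NULL, algorithms = sdm_algorithms(),
                 train_fraction = 0.70, cv_replicates = 3,
                 tss_cutoff = 0.60, hyper = list(), seed = 1) {
  cl <- match.call()
  bad <- setdiff(algorithms, sdm_algorithms())
  if (length(bad))
    stop("unsupported algorithm(s): ", paste(bad, collapse = ", "))
  if (inherits(data, "pa_set")) {
    if (is.null(stack))
      stop("a predictor_stack is required when fitting from a pa_set")
    feats <- extract_stack(stack, data$x, data$y)
    tab <- cbind(data.frame(label = data$label, weight = data$weight,
                            replicate_id = data$replicate_id), feats)
  } else {
    tab <- as.data.frame(data)
    if (!"label" %in% names(tab)) stop("'data' needs a 'label' column")
    if (!"weight" %in% names(tab)) tab$weight <- 1
    if (!"replicate_id" %in% names(tab)) tab$replicate_id <- 1L
  }
  feature_names <- setdiff(names(tab), c("label", "weight", "replicate_id"))
  if (length(feature_names) == 0L) stop("no predictor columns")
  ok <- stats::complete.cases(tab[feature_names])
  tab <- tab[ok, , drop = FALSE]

  runs <- list(); members <- list()
  pooled_test <- list()
  run_row <- 0L
  for (pa_rep in sort(unique(tab$replicate_id))) {
    sub <- tab[tab$replicate_id == pa_rep, , drop = FALSE]
    splits <- split_train_test(sub, train_fraction, cv_replicates,
                               seed = derive_seed(seed, "pa_split", pa_rep))
    for (cv_rep in seq_len(cv_replicates)) {
      tr <- sub[splits[[cv_rep]]$train, , drop = FALSE]
      te <- sub[splits[[cv_rep]]$test, , drop = FALSE]
      for (alg in algorithms) {
        set.seed(derive_seed(seed, paste0("fit_", alg),
                             pa_rep * 100 + cv_rep))
        lr <- fit_learner(alg, tr[feature_names], tr$label,
                          weights = tr$weight, hyper = hyper)
        sc <- lr$predict(te[feature_names])
        ev <- tss_score(sc, te$label)
        run_row <- run_row + 1L
        runs[[run_row]] <- data.frame(
          algorithm = alg, pa_rep = pa_rep, cv_rep = cv_rep,
          auc = auc_score(sc, te$label), tss = ev$tss,
          sensitivity = ev$sensitivity, specificity = ev$specificity,
          threshold = ev$threshold)
        members[[run_row]] <- list(learner = lr, algorithm = alg,
                                   pa_rep = pa_rep, cv_rep = cv_rep,
                                   eval = c(list(auc = runs[[run_row]]$auc),
                                            ev))
        pooled_test[[run_row]] <- te
      }
    }
  }
  runs <- do.call(rbind, runs)
  ens <- build_ensemble(members, tss_cutoff = tss_cutoff)

  # pooled holdout evaluation of the ensemble itself: predict with the
  # retained members on the union of test sets of one cv pass
  pool <- unique(do.call(rbind, pooled_test))
  esc <- ensemble_scores(ens, pool[feature_names])
  pe <- tss_score(esc, pool$label)
  obj <- structure(list(runs = runs, members = ens$members,
                        weights = ens$weights, tss_cutoff = tss_cutoff,
                        eval = list(auc = auc_score(esc, pool$label),
                                    tss = pe$tss,
                                    sensitivity = pe$sensitivity,
                                    specificity = pe$specificity),
                        threshold = pe$threshold,
                        features = feature_names, call = cl),
                   class = "esdm")
  obj
}

#' Gate and weight fitted runs into an ensemble
#'
#' Retains the runs whose TSS is strictly greater than `tss_cutoff` and
#' assigns each a weight proportional to its TSS (weights sum to 1).
#'
#' @param runs list of fitted runs, each with `eval$tss` (as produced inside
#'   [esdm()], or minimal `list(eval = list(tss = ...))` stubs).
#' @param tss_cutoff admission gate (default 0.60, strict).
#' @return list with `members` (retained runs) and `weights`.
#' @export
build_ensemble <- function(runs, tss_cutoff = 0.60) {
  tss <- vapply(runs, function(r) r$eval$tss, numeric(1))
  keep <- which(tss > tss_cutoff)
  if (length(keep) == 0L)
    stop(sprintf("no model passed the ensemble gate (TSS > %.2f); max TSS %.3f",
                 tss_cutoff, max(tss)))
  w <- if (sum(tss[keep]) > 0) tss[keep] / sum(tss[keep])
       else rep(1 / length(keep), length(keep))  # non-positive gate edge case
  list(members = runs[keep], weights = w)
}

ensemble_scores <- function(ens, newx) {
  sc <- vapply(ens$members,
               function(m) as.numeric(m$learner$predict(newx)),
               numeric(nrow(newx)))
  if (is.null(dim(sc))) sc <- matrix(sc, nrow = 1)
  as.vector(sc %*% ens$weights)
}

#' @export
print.esdm <- function(x, ...) {
  cat("TSS-weighted ensemble species distribution model\n")
  cat(sprintf("  runs: %d (%d algorithms x %d PA x %d CV); members kept: %d (TSS > %.2f)\n",
              nrow(x$runs), length(unique(x$runs$algorithm)),
              length(unique(x$runs$pa_rep)), length(unique(x$runs$cv_rep)),
              length(x$members), x$tss_cutoff))
  cat(sprintf("  pooled holdout: AUC %.3f, TSS %.3f (threshold %.2f)\n",
              x$eval$auc, x$eval$tss, x$threshold))
  invisible(x)
}

#' @export
summary.esdm <- function(object, ...) {
  agg <- stats::aggregate(cbind(auc, tss) ~ algorithm, data = object$runs,
                          FUN = mean)
  agg <- agg[order(-agg$tss), ]
  res <- list(runs_by_algorithm = agg, weights = coef(object),
              eval = object$eval, threshold = object$threshold,
              n_runs = nrow(object$runs), n_members = length(object$members))
  class(res) <- "summary.esdm"
  res
}

#' @export
print.summary.esdm <- function(x, ...) {
  cat(sprintf("Ensemble of %d members from %d runs\n", x$n_members, x$n_runs))
  cat("\nMean holdout skill by algorithm:\n")
  print(x$runs_by_algorithm, row.names = FALSE, digits = 3)
  cat("\nMember weights (sum to 1):\n")
  print(round(x$weights, 4))
  cat(sprintf("\nPooled holdout: AUC %.3f, TSS %.3f; binarisation threshold %.2f\n",
              x$eval$auc, x$eval$tss, x$threshold))
  invisible(x)
}

#' @export
coef.esdm <- function(object, ...) {
  stats::setNames(object$weights,
                  vapply(object$members, function(m)
                    sprintf("%s_pa%d_cv%d", m$algorithm, m$pa_rep, m$cv_rep),
                    character(1)))
}

#' Predict habitat suitability from a fitted ensemble
#'
#' @param object an `esdm` fit.
#' @param newdata a `predictor_stack` (returns a suitability `raster_grid`)
#'   or a data.frame of predictor columns (returns a numeric vector).
#' @param type `"response"` for continuous suitability in `[0, 1]`,
#'   `"binary"` for presence/absence at `threshold`.
#' @param threshold binarisation threshold; defaults to the max-TSS
#'   threshold chosen on the pooled holdout at fitting time.
#' @param ... unused.
#' @return `raster_grid` or numeric vector, matching `newdata`.
#' @export
predict.esdm <- function(object, newdata, type = c("response", "binary"),
                         threshold = NULL, ...) {
  type <- match.arg(type)
  if (is.null(threshold)) threshold <- object$threshold
  ens <- list(members = object$members, weights = object$weights)
  if (inherits(newdata, "predictor_stack")) {
    missing <- setdiff(object$features, names(newdata$layers))
    if (length(missing))
      stop("stack lacks model layer(s): ", paste(missing, collapse = ", "))
    X <- as.data.frame(stack_values(newdata))[object$features]
    ok <- stats::complete.cases(X)
    sc <- rep(NA_real_, nrow(X))
    if (any(ok)) sc[ok] <- ensemble_scores(ens, X[ok, , drop = FALSE])
    if (type == "binary") sc <- ifelse(is.na(sc), NA, as.numeric(sc >= threshold))
    tpl <- newdata$layers[[1]]
    raster_grid(matrix(sc, nrow(tpl$values)), tpl$xmin, tpl$ymin,
                tpl$cellsize)
  } else {
    X <- as.data.frame(newdata)
    missing <- setdiff(object$features, names(X))
    if (length(missing))
      stop("newdata lacks model feature(s): ", paste(missing, collapse = ", "))
    sc <- ensemble_scores(ens, X[object$features])
    if (type == "binary") sc <- as.numeric(sc >= threshold)
    sc
  }
}

#' Binarise a suitability map at a threshold
#' @param map suitability `raster_grid`.
#' @param threshold cells with value `>=` threshold become 1.
#' @return 0/1 `raster_grid`.
#' @export
binarise <- function(map, threshold) {
  v <- ifelse(map$values >= threshold, 1, 0)
  v[!is.finite(map$values)] <- NA_real_
  raster_grid(v, map$xmin, map$ymin, map$cellsize)
}

#' @export
plot.esdm <- function(x, stack = NULL, ...) {
  if (!is.null(stack)) {
    m <- predict(x, stack)
    graphics::image(t(m$values), main = "Ensemble habitat suitability",
                    xlab = "", ylab = "", axes = FALSE, zlim = c(0, 1), ...)
  } else {
    w <- coef(x)
    graphics::barplot(sort(w, decreasing = TRUE), las = 2,
                      main = "Ensemble member weights", cex.names = 0.6, ...)
  }
  invisible(x)
}

#' Permutation variable importance of an ensemble
#'
#' For each feature, its values are permuted across records and the
#' importance is `1 - cor(reference predictions, permuted predictions)`,
#' averaged over `n_permutations` and normalised so the vector sums to 100.
#'
#' @param object an `esdm` fit.
#' @param data data.frame of predictor columns (e.g. training records or a
#'   sample of cells).
#' @param n_permutations permutations per feature (default 3).
#' @param seed integer seed.
#' @return named numeric vector of importances (percent, sums to 100).
#' @export
variable_importance <- function(object, data, n_permutations = 3, seed = 1) {
  if (n_permutations < 1) stop("n_permutations must be >= 1")
  X <- as.data.frame(data)[object$features]
  X <- X[stats::complete.cases(X), , drop = FALSE]
  ref <- predict(object, X)
  if (stats::sd(ref) == 0) {
    warning("constant ensemble predictions; importance undefined")
    return(stats::setNames(rep(0, length(object$features)), object$features))
  }
  imp <- numeric(length(object$features))
  names(imp) <- object$features
  for (f in object$features) {
    acc <- 0
    for (p in seq_len(n_permutations)) {
      set.seed(derive_seed(seed, paste0("vimp_", f), p))
      Xp <- X
      Xp[[f]] <- X[[f]][sample.int(nrow(X))]
      pred <- predict(object, Xp)
      r <- if (stats::sd(pred) == 0) 0 else stats::cor(ref, pred)
      acc <- acc + (1 - r)
    }
    imp[f] <- acc / n_permutations
  }
  imp[imp < 0] <- 0
  if (sum(imp) == 0) return(imp)
  100 * imp / sum(imp)
}
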