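test_that("train/test splits partition the data and preserve class balance", {
  d <- data.frame(label = rep(c(0, 1), each = 500), weight = 1)
  sp <- split_train_test(d, 0.70, cv_replicates = 3, seed = 5)
  for (s in sp) {
    expect_length(s$train, 700)
    expect_length(s$test, 300)
    expect_setequal(c(s$train, s$test), seq_len(1000))
    expect_length(intersect(s$train, s$test), 0)
    # stratified: class ratio preserved within a record
    expect_equal(sum(d$label[s$train] == 1), 350)
  }
  # independent splits, deterministic under the seed
  expect_false(identical(sp[[1]]$train, sp[[2]]$train))
  sp2 <- split_train_test(d, 0.70, cv_replicates = 3, seed = 5)
  expect_identical(sp, sp2)
  expect_error(split_train_test(data.frame(label = rep(1, 10), weight = 1)),
               "both classes")
})

test_that("every learner honours the uniform probabilistic contract", {
  d <- logistic_data(400, beta = c(2.5, -1.5), seed = 81)
  newx <- logistic_data(100, beta = c(2.5, -1.5), seed = 82)
  for (alg in sdm_algorithms()) {
    lr <- fit_learner(alg, d[c("env_1", "env_2")], d$label,
                      hyper = list(ann_maxit = 80, rf_ntree = 80,
                                   gbm_nrounds = 40))
    sc <- lr$predict(newx[c("env_1", "env_2")])
    expect_length(sc, 100)
    expect_true(all(sc >= 0 & sc <= 1), info = alg)
    # every learner must beat chance comfortably on this clean signal
    expect_gt(auc_score(sc, newx$label), 0.58)
  }
  expect_error(fit_learner("NOPE", d[2:3], d$label), "supported")
})

test_that("SRE envelope uses presence quantiles and predicts by inclusion", {
  set.seed(83)
  x <- data.frame(env_1 = runif(400), env_2 = runif(400))
  y <- rep(c(1, 0), each = 200)
  lr <- fit_learner("SRE", x, y, hyper = list(sre_quantile = 0.025))
  pres <- x[y == 1, ]
  expect_equal(lr$fit$lower[["env_1"]],
               quantile(pres$env_1, 0.025, names = FALSE))
  expect_equal(lr$fit$upper[["env_2"]],
               quantile(pres$env_2, 0.975, names = FALSE))
  # inside on all layers -> 1; any layer outside -> 0
  inside <- data.frame(env_1 = median(pres$env_1),
                       env_2 = median(pres$env_2))
  outside <- data.frame(env_1 = 99, env_2 = median(pres$env_2))
  expect_equal(lr$predict(inside), 1)
  expect_equal(lr$predict(outside), 0)
})

test_that("GLM separates linearly separable data perfectly on holdout", {
  d <- separable_data(200, seed = 84)
  lr <- suppressWarnings(fit_learner("GLM", d["env_1"], d$label))
  holdout <- separable_data(100, seed = 85)
  expect_equal(auc_score(lr$predict(holdout["env_1"]), holdout$label), 1.0)
})

test_that("ensemble gating is strict and weights are proportional to TSS", {
  stub <- function(tss) list(eval = list(tss = tss))
  # 0.8 and 0.6 at cutoff 0.5: weights 4/7, 3/7
  e <- build_ensemble(list(stub(0.8), stub(0.6)), tss_cutoff = 0.5)
  expect_equal(e$weights, c(4 / 7, 3 / 7))
  # strict gate: 0.60 is excluded at cutoff 0.60
  e2 <- build_ensemble(list(stub(0.8), stub(0.6), stub(0.5)),
                       tss_cutoff = 0.60)
  expect_length(e2$members, 1)
  expect_equal(e2$weights, 1)
  # equal TSS: equal weights
  e3 <- build_ensemble(list(stub(0.7), stub(0.7), stub(0.7)),
                       tss_cutoff = 0.5)
  expect_equal(e3$weights, rep(1 / 3, 3))
  # nothing passes: explicit error, not a fallback
  expect_error(build_ensemble(list(stub(0.2)), 0.6), "no model passed")
})

test_that("esdm produces the full run design and convex ensemble maps", {
  st <- toy_stack(3, 30, seed = 86)
  truth <- make_truth(st, c(env_1 = 3, env_2 = -2), intercept = -0.5)
  set.seed(87)
  ctr <- grid_centers(st$layers[[1]])
  lab <- rbinom(length(ctr$x), 1, as.vector(truth$surface$values))
  keep <- c(sample(which(lab == 1), 200), sample(which(lab == 0), 200))
  pa <- data.frame(x = ctr$x[keep], y = ctr$y[keep], label = lab[keep],
                   weight = 1,
                   replicate_id = rep_len(1:2, 400))
  class(pa) <- c("pa_set", "data.frame")
  fit <- esdm(pa, stack = st, algorithms = c("GLM", "SRE", "CTA"),
              train_fraction = 0.7, cv_replicates = 2, tss_cutoff = 0.1,
              seed = 88)
  # full design: algorithms x cv x pa replicates
  expect_equal(nrow(fit$runs), 3 * 2 * 2)
  expect_equal(sort(unique(fit$runs$algorithm)), c("CTA", "GLM", "SRE"))
  # weights sum to 1 and every member beats the gate strictly
  expect_equal(sum(fit$weights), 1)
  expect_true(all(vapply(fit$members, function(m) m$eval$tss, 1) > 0.1))
  # ensemble score is a convex combination of member scores
  X <- extract_stack(st, ctr$x[1:50], ctr$y[1:50])
  member_scores <- vapply(fit$members,
                          function(m) as.numeric(m$learner$predict(X)),
                          numeric(50))
  ens <- predict(fit, X)
  expect_true(all(ens <= apply(member_scores, 1, max) + 1e-12))
  expect_true(all(ens >= apply(member_scores, 1, min) - 1e-12))
  # map prediction matches the data-frame route cell by cell
  m <- predict(fit, st)
  expect_equal(as.vector(m$values)[1:50 + 3 * 30],
               predict(fit, extract_stack(st, ctr$x[1:50 + 3 * 30],
                                          ctr$y[1:50 + 3 * 30])),
               tolerance = 1e-12)
  # binary map equals thresholding the continuous map
  b <- predict(fit, st, type = "binary")
  expect_equal(b$values, ifelse(m$values >= fit$threshold, 1, 0))
  # determinism
  fit2 <- esdm(pa, stack = st, algorithms = c("GLM", "SRE", "CTA"),
               train_fraction = 0.7, cv_replicates = 2, tss_cutoff = 0.1,
               seed = 88)
  expect_identical(fit$runs, fit2$runs)
  expect_error(predict(fit, st[c("env_1", "env_2")]), "lacks model layer")
  # S3 surface
  expect_output(print(fit), "TSS-weighted ensemble")
  s <- summary(fit)
  expect_s3_class(s, "summary.esdm")
  expect_equal(sum(coef(fit)), 1)
})

test_that("permutation importance isolates informative predictors", {
  # unused layer gets (near) zero importance; single-feature model gets 100
  d <- logistic_data(600, beta = c(3), seed = 90)
  d$env_noise <- rnorm(600)
  fit1 <- esdm(d, algorithms = "GLM", cv_replicates = 1, tss_cutoff = 0,
               seed = 91)
  imp1 <- variable_importance(fit1, d[c("env_1", "env_noise")], seed = 92)
  expect_gt(imp1[["env_1"]], 90)
  # the dominant truth layer ranks first in >= 9 of 10 seeded repeats
  wins <- 0
  for (s in 1:10) {
    d2 <- logistic_data(500, beta = c(2.5, -1, 0.5), seed = 100 + s)
    f <- esdm(d2, algorithms = "GLM", cv_replicates = 1, tss_cutoff = 0,
              seed = 100 + s)
    imp <- variable_importance(f, d2[paste0("env_", 1:3)], seed = 100 + s)
    if (names(which.max(imp)) == "env_1") wins <- wins + 1
  }
  expect_gte(wins, 9)
  # constant predictions: zero vector with a warning
  dc <- data.frame(label = rep(c(0, 1), 50), env_1 = rnorm(100))
  fc <- esdm(dc, algorithms = "SRE", cv_replicates = 1, tss_cutoff = -1,
             hyper = list(sre_quantile = 0), seed = 93)
  expect_warning(
    impc <- variable_importance(fc, data.frame(env_1 = rep(0, 30))),
    "constant")
  expect_equal(unname(impc), 0)
})
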