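#' Supported ensemble member algorithms
#'
#' Ten algorithm identifiers: four regression methods (GLM, GAM, MARS, GBM),
#' four machine-learning methods (ANN, RF, MAXENT, SRE) and two
#' classification methods (CTA, FDA). All are fitted behind a uniform
#' contract: a learner maps a predictor vector to a score in `[0, 1]`.
#'
#' @return character vector of algorithm ids.
#' @export
sdm_algorithms <- function() {
  c("GLM", "GAM", "MARS", "GBM", "ANN", "RF", "MAXENT", "SRE", "CTA", "FDA")
}

#' Fit one ensemble member
#'
#' Dispatches to the underlying learner for `algorithm_id` and wraps it in a
#' uniform interface. Sample weights are honoured where the learner supports
#' them (GLM, GAM, MARS, GBM, ANN, MAXENT, CTA); RF, FDA and SRE ignore
#' them. SRE (surface range envelope) is the native envelope classifier:
#' presence is predicted iff every predictor lies within the presence
#' quantile bounds `[q, 1 - q]`.
#'
#' @param algorithm_id one of [sdm_algorithms()].
#' @param x data.frame of numeric predictors.
#' @param y 0/1 response.
#' @param weights non-negative sample weights (default all 1).
#' @param hyper named list of hyperparameters; honoured entries include
#'   `sre_quantile` (default 0.025), `rf_ntree` (200), `gbm_nrounds` (100),
#'   `ann_size` (4), `gam_k` (5).
#' @return object of class `sdm_learner` with elements `algorithm_id`,
#'   `fit`, and `predict(newx)` returning scores in `[0, 1]`.
#' @export
fit_learner <- function(algorithm_id, x, y, weights = NULL, hyper = list()) {
  if (!algorithm_id %in% sdm_algorithms())
    stop("unsupported algorithm '", algorithm_id, "'; supported: ",
         paste(sdm_algorithms(), collapse = ", "))
  x <- as.data.frame(x)
  y <- as.numeric(y)
  if (is.null(weights)) weights <- rep(1, length(y))
  fitter <- switch(algorithm_id,
    GLM = fit_glm, GAM = fit_gam, MARS = fit_mars, GBM = fit_gbm,
    ANN = fit_ann, RF = fit_rf, MAXENT = fit_maxent, SRE = fit_sre,
    CTA = fit_cta, FDA = fit_fda)
  out <- fitter(x, y, weights, hyper)
  out$algorithm_id <- algorithm_id
  class(out) <- "sdm_learner"
  out
}

#' @export
print.sdm_learner <- function(x, ...) {
  cat(sprintf("<sdm_learner> %s\n", x$algorithm_id))
  invisible(x)
}

clamp01 <- function(p) pmin(pmax(as.numeric(p), 0), 1)

fit_glm <- function(x, y, w, hyper) {
  d <- cbind(.y = y, x)
  # quasibinomial: identical fit to binomial, tolerant of fractional weights
  fit <- stats::glm(.y ~ ., data = d, family = stats::quasibinomial(),
                    weights = w)
  list(fit = fit,
       predict = function(newx)
         clamp01(stats::predict(fit, newdata = as.data.frame(newx),
                                type = "response")))
}

fit_gam <- function(x, y, w, hyper) {
  k <- hyper$gam_k %||% 5
  terms <- vapply(names(x), function(v) {
    if (length(unique(x[[v]])) > 2 * k) sprintf("s(%s, k = %d)", v, k) else v
  }, character(1))
  f <- stats::as.formula(paste(".y ~", paste(terms, collapse = " + ")))
  d <- cbind(.y = y, x)
  fit <- mgcv::gam(f, data = d, family = stats::quasibinomial(), weights = w)
  list(fit = fit,
       predict = function(newx)
         clamp01(mgcv::predict.gam(fit, newdata = as.data.frame(newx),
                                   type = "response")))
}

# piecewise-linear (hinge) spline basis at interior quantile knots, fitted
# as a weighted logistic regression
fit_mars <- function(x, y, w, hyper) {
  probs <- hyper$mars_knots %||% c(0.25, 0.5, 0.75)
  knots <- lapply(x, stats::quantile, probs = probs, names = FALSE)
  expand <- function(d) {
    d <- as.data.frame(d)
    out <- list()
    for (v in names(knots)) {
      out[[v]] <- d[[v]]
      for (i in seq_along(knots[[v]])) {
        kk <- knots[[v]][i]
        out[[paste0(v, "_h", i)]] <- pmax(d[[v]] - kk, 0)
      }
    }
    as.data.frame(out)
  }
  xb <- expand(x)
  d <- cbind(.y = y, xb)
  fit <- suppressWarnings(
    stats::glm(.y ~ ., data = d, family = stats::quasibinomial(),
               weights = w))
  list(fit = fit, knots = knots,
       predict = function(newx)
         clamp01(suppressWarnings(
           stats::predict(fit, newdata = expand(newx), type = "response"))))
}

fit_gbm <- function(x, y, w, hyper) {
  xm <- as.matrix(x)
  fit <- xgboost::xgboost(
    xm, factor(y, levels = c(0, 1)), weights = w,
    nrounds = hyper$gbm_nrounds %||% 100,
    max_depth = hyper$gbm_depth %||% 3,
    learning_rate = hyper$gbm_eta %||% 0.1,
    nthreads = 1, verbosity = 0)
  cn <- colnames(xm)
  list(fit = fit,
       predict = function(newx)
         clamp01(stats::predict(fit,
                                as.matrix(as.data.frame(newx)[, cn,
                                                              drop = FALSE]),
                                type = "response")))
}

fit_ann <- function(x, y, w, hyper) {
  xm <- scale(as.matrix(x))
  ctr <- attr(xm, "scaled:center"); scl <- attr(xm, "scaled:scale")
  scl[scl == 0] <- 1
  fit <- nnet::nnet(x = xm, y = y, weights = w,
                    size = hyper$ann_size %||% 4,
                    decay = hyper$ann_decay %||% 0.01,
                    maxit = hyper$ann_maxit %||% 200,
                    entropy = TRUE, trace = FALSE)
  cn <- colnames(as.matrix(x))
  list(fit = fit,
       predict = function(newx) {
         nm <- sweep(sweep(as.matrix(as.data.frame(newx)[, cn, drop = FALSE]),
                           2, ctr), 2, scl, "/")
         clamp01(stats::predict(fit, nm))
       })
}

fit_rf <- function(x, y, w, hyper) {
  fit <- randomForest::randomForest(x = x, y = factor(y, levels = c(0, 1)),
                                    ntree = hyper$rf_ntree %||% 200)
  cn <- names(x)
  list(fit = fit,
       predict = function(newx)
         clamp01(stats::predict(fit,
                                newdata = as.data.frame(newx)[, cn,
                                                              drop = FALSE],
                                type = "prob")[, "1"]))
}

# penalised (L1/L2) logistic regression on linear + quadratic features,
# the parametric core of a maximum-entropy presence-background model
fit_maxent <- function(x, y, w, hyper) {
  expand <- function(d) {
    d <- as.data.frame(d)
    cbind(as.matrix(d), as.matrix(d)^2)
  }
  xm <- expand(x)
  colnames(xm) <- c(names(x), paste0(names(x), "_sq"))
  fit <- glmnet::glmnet(xm, y, family = "binomial", weights = w,
                        alpha = hyper$maxent_alpha %||% 0.5,
                        lambda = hyper$maxent_lambda %||% 1e-3)
  list(fit = fit,
       predict = function(newx) {
         nm <- expand(as.data.frame(newx)[, names(x), drop = FALSE])
         clamp01(stats::predict(fit, nm, type = "response")[, 1])
       })
}

fit_sre <- function(x, y, w, hyper) {
  q <- hyper$sre_quantile %||% 0.025
  pres <- x[y == 1, , drop = FALSE]
  lower <- vapply(pres, stats::quantile, numeric(1), probs = q, names = FALSE)
  upper <- vapply(pres, stats::quantile, numeric(1), probs = 1 - q,
                  names = FALSE)
  cn <- names(x)
  list(fit = list(lower = lower, upper = upper, quantile = q),
       predict = function(newx) {
         nm <- as.data.frame(newx)[, cn, drop = FALSE]
         inside <- rep(TRUE, nrow(nm))
         for (j in seq_along(cn))
           inside <- inside & nm[[j]] >= lower[j] & nm[[j]] <= upper[j]
         as.numeric(inside)
       })
}

fit_cta <- function(x, y, w, hyper) {
  d <- cbind(.y = factor(y, levels = c(0, 1)), x)
  fit <- rpart::rpart(.y ~ ., data = d, weights = w, method = "class",
                      control = rpart::rpart.control(
                        cp = hyper$cta_cp %||% 0.005, minsplit = 10))
  list(fit = fit,
       predict = function(newx)
         clamp01(stats::predict(fit, newdata = as.data.frame(newx),
                                type = "prob")[, "1"]))
}

# discriminant analysis on a linear + quadratic basis (a flexible
# discriminant via basis expansion); posterior probability of presence
fit_fda <- function(x, y, w, hyper) {
  expand <- function(d) {
    d <- as.data.frame(d)
    out <- cbind(as.matrix(d), as.matrix(d)^2)
    colnames(out) <- c(names(d), paste0(names(d), "_sq"))
    out
  }
  xm <- expand(x)
  keep <- apply(xm, 2, function(col) stats::sd(col) > 1e-10)
  xm <- xm[, keep, drop = FALSE]
  fit <- MASS::lda(xm, grouping = factor(y, levels = c(0, 1)))
  cn <- names(x); kept <- colnames(xm)
  list(fit = fit,
       predict = function(newx) {
         nm <- expand(as.data.frame(newx)[, cn, drop = FALSE])
         clamp01(stats::predict(fit, nm[, kept, drop = FALSE])$posterior[, "1"])
       })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
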