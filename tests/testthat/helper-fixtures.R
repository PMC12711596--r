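# shared fixtures, built in code at test time

const_raster <- function(value, nr = 10, nc = nr, cellsize = 1) {
  raster_grid(matrix(value, nr, nc), cellsize = cellsize)
}

# small stack of independent standard-normal layers (unsmoothed)
toy_stack <- function(n_layers = 3, nr = 20, nc = nr, seed = 1, cellsize = 1) {
  set.seed(seed)
  layers <- lapply(seq_len(n_layers), function(i)
    raster_grid(matrix(rnorm(nr * nc), nr, nc), cellsize = cellsize))
  names(layers) <- paste0("env_", seq_len(n_layers))
  predictor_stack(layers)
}

# linearly separable toy presence/absence table
separable_data <- function(n = 100, seed = 1) {
  set.seed(seed)
  x <- c(rnorm(n / 2, -3), rnorm(n / 2, 3))
  data.frame(label = rep(c(0, 1), each = n / 2), env_1 = x,
             env_2 = rnorm(n))
}

# logistic-model table sampled directly from known coefficients
logistic_data <- function(n = 500, beta = c(2, -1, 0.5), seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * length(beta)), n)
  colnames(X) <- paste0("env_", seq_along(beta))
  y <- rbinom(n, 1, plogis(X %*% beta))
  cbind(data.frame(label = y), as.data.frame(X))
}

# brute-force pairwise AUC oracle (ties count one half)
auc_bruteforce <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}
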