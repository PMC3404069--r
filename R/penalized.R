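# Elastic-net-family fits parameterized the LARS-EN way: a fixed quadratic
# penalty lambda2 plus an L1 constraint expressed as the fraction s of the
# full model's L1 norm. Realized through the ridge data-augmentation
# identity: the elastic net at (lambda1, lambda2) equals the LASSO at
# lambda1 on X augmented with sqrt(lambda2) * I rows and zero responses.
# glmnet (alpha = 1) supplies the LASSO path on the augmented data; the
# full-model endpoint (lambda1 = 0) is the exact ridge solution, which the
# augmented design makes well-posed even when markers outnumber samples.

# standardize columns to mean 0 / sd 1; constant columns become all-zero
std_cols <- function(X) {
  mu <- colMeans(X)
  sd_ <- apply(X, 2L, stats::sd)
  sd_safe <- ifelse(sd_ < 1e-12, 1, sd_)
  Xs <- sweep(sweep(X, 2L, mu, "-"), 2L, sd_safe, "/")
  Xs[, sd_ < 1e-12] <- 0
  list(x = Xs, mu = mu, sd = sd_safe, constant = sd_ < 1e-12)
}

# LASSO path on the ridge-augmented design, plus the exact lambda1 = 0
# (full ridge) endpoint. Columns of $beta are ordered by increasing L1 norm.
enet_path <- function(X, y, lambda2) {
  p <- ncol(X)
  Xa <- rbind(X, sqrt(lambda2) * diag(p))
  ya <- c(y, rep(0, p))
  fit <- glmnet::glmnet(Xa, ya, alpha = 1, standardize = FALSE,
                        intercept = FALSE, nlambda = 100,
                        lambda.min.ratio = 1e-4)
  beta <- as.matrix(fit$beta)
  beta_full <- tryCatch(
    drop(solve(crossprod(Xa) , crossprod(Xa, ya))),
    error = function(e) beta[, ncol(beta)])
  beta <- cbind(0, beta, beta_full)          # lambda1 = Inf ... 0
  l1 <- colSums(abs(beta))
  l1 <- cummax(l1)                           # guard tiny non-monotonicities
  list(beta = beta, l1 = l1, l1_full = l1[length(l1)])
}

# coefficients at L1 norm == s * l1_full, linearly interpolated between the
# bracketing path points (the LASSO path is piecewise linear in the bound)
enet_coef_at_s <- function(path, s) {
  target <- s * path$l1_full
  l1 <- path$l1
  if (target <= 0) return(path$beta[, 1L])
  j <- which(l1 >= target)[1L]
  if (is.na(j)) return(path$beta[, ncol(path$beta)])
  if (j == 1L || l1[j] - l1[j - 1L] < 1e-15) return(path$beta[, j])
  w <- (target - l1[j - 1L]) / (l1[j] - l1[j - 1L])
  (1 - w) * path$beta[, j - 1L] + w * path$beta[, j]
}

# Cross-validated choice of the L1 fraction s, then absolute coefficients
# of the final fit at that s. Returns scores on the standardized scale.
enet_importance <- function(X, y, lambda2, params, s_min = 0, seed = NULL) {
  n <- nrow(X)
  if (n < 2L) abort_fmt("need at least 2 samples for a penalized fit")
  if (stats::sd(y) < 1e-12) return(rep(0, ncol(X)))

  s_grid <- params$s_grid
  folds <- params$cv_folds
  if (n < folds) {
    warning(sprintf("reducing cv_folds from %d to the %d available samples",
                    folds, n), call. = FALSE)
    folds <- n
  }
  prep <- function(Xtr, ytr) {
    sx <- std_cols(Xtr)
    if (params$standardize) {
      list(x = sx$x, y = (ytr - mean(ytr)) / max(stats::sd(ytr), 1e-12),
           xmu = sx$mu, xsd = sx$sd, ymu = mean(ytr),
           ysd = max(stats::sd(ytr), 1e-12))
    } else {
      list(x = sweep(Xtr, 2L, sx$mu, "-"), y = ytr - mean(ytr),
           xmu = sx$mu, xsd = rep(1, ncol(Xtr)), ymu = mean(ytr), ysd = 1)
    }
  }

  set.seed(seed %||% params$seed)
  fold_id <- sample(rep_len(seq_len(folds), n))
  sse <- matrix(0, folds, length(s_grid))
  for (f in seq_len(folds)) {
    tr <- fold_id != f
    pp <- prep(X[tr, , drop = FALSE], y[tr])
    if (stats::sd(y[tr]) < 1e-12) next
    path <- enet_path(pp$x, pp$y, lambda2)
    Xte <- sweep(sweep(X[!tr, , drop = FALSE], 2L, pp$xmu, "-"),
                 2L, pp$xsd, "/")
    for (k in seq_along(s_grid)) {
      b <- enet_coef_at_s(path, s_grid[k])
      pred <- pp$ymu + drop(Xte %*% b) * pp$ysd
      sse[f, k] <- sum((y[!tr] - pred)^2)
    }
  }
  cv_mse <- colSums(sse) / n
  # minimum CV error; ties resolved toward the larger (less restrictive) s
  best <- max(which(cv_mse <= min(cv_mse) + 1e-12))
  s_hat <- max(s_grid[best], s_min)

  pp <- prep(X, y)
  beta <- enet_coef_at_s(enet_path(pp$x, pp$y, lambda2), s_hat)
  score <- abs(beta)
  score[score < params$zero_tol] <- 0
  attr(score, "s") <- s_hat
  score
}
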