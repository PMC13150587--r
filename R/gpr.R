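# Gaussian process regression with an isotropic squared-exponential
# kernel k(x, x') = sf2 * exp(-||x - x'||^2 / (2 ell^2)) plus a noise
# term sn2.  Features and target are standardized internally; the three
# log hyperparameters (sf2, ell, sn2) are learned by minimizing the
# negative log marginal likelihood with analytic gradients (L-BFGS-B),
# from a fixed init (ell = 1 after standardization) plus seeded jittered
# restarts.  Duplicate training inputs are handled by the learned noise
# term, which keeps the kernel matrix positive definite.

sq_dist <- function(A, B = A) {
  an <- rowSums(A^2); bn <- rowSums(B^2)
  D2 <- outer(an, bn, `+`) - 2 * tcrossprod(A, B)
  D2[D2 < 0] <- 0
  D2
}

gpr_nll <- function(theta, D2, y) {
  sf2 <- exp(theta[1L]); ell2 <- exp(2 * theta[2L]); sn2 <- exp(theta[3L])
  n <- length(y)
  Kse <- sf2 * exp(-0.5 * D2 / ell2)
  K <- Kse + diag(sn2, n)
  L <- tryCatch(chol(K), error = function(e) NULL)
  if (is.null(L)) return(list(value = 1e10, grad = c(0, 0, 0)))
  alpha <- backsolve(L, forwardsolve(t(L), y))
  nll <- 0.5 * sum(y * alpha) + sum(log(diag(L))) + 0.5 * n * log(2 * pi)
  Kinv <- chol2inv(L)
  W <- tcrossprod(alpha) - Kinv         # d nll / dK = -W/2
  g <- c(-0.5 * sum(W * Kse),
         -0.5 * sum(W * (Kse * D2 / ell2)),
         -0.5 * sum(diag(W)) * sn2)
  list(value = nll, grad = g)
}

gpr_fit <- function(X, y, restarts = 5, seed = NULL) {
  X <- as.matrix(X)
  xc <- colMeans(X); xs <- apply(X, 2L, stats::sd); xs[xs == 0] <- 1
  Xs <- sweep(sweep(X, 2L, xc), 2L, xs, `/`)
  yc <- mean(y); ys <- stats::sd(y)
  degenerate <- !is.finite(ys) || ys == 0
  if (degenerate) ys <- 1
  yz <- (y - yc) / ys

  D2 <- sq_dist(Xs)
  lower <- c(-10, log(1e-2), log(1e-8))
  upper <- c(10, log(1e2), 5)
  inits <- with_seed(seed, {
    base <- c(0, 0, log(0.1))
    if (restarts > 1L)
      rbind(base, matrix(stats::rnorm(3L * (restarts - 1L), base, 0.8),
                         ncol = 3L, byrow = TRUE))
    else matrix(base, nrow = 1L)
  })
  inits <- pmin(pmax(inits, matrix(lower, nrow(inits), 3L, byrow = TRUE)),
                matrix(upper, nrow(inits), 3L, byrow = TRUE))
  best <- NULL
  for (i in seq_len(nrow(inits))) {
    o <- tryCatch(
      stats::optim(inits[i, ],
                   fn = function(th) gpr_nll(th, D2, yz)$value,
                   gr = function(th) gpr_nll(th, D2, yz)$grad,
                   method = "L-BFGS-B", lower = lower, upper = upper),
      error = function(e) NULL)
    if (!is.null(o) && (is.null(best) || o$value < best$value)) best <- o
  }
  if (is.null(best)) stop("GPR hyperparameter optimization failed",
                          call. = FALSE)
  theta <- best$par
  sf2 <- exp(theta[1L]); ell2 <- exp(2 * theta[2L]); sn2 <- exp(theta[3L])
  K <- sf2 * exp(-0.5 * D2 / ell2) + diag(sn2, length(yz))
  L <- chol(K + diag(1e-10, length(yz)))
  alpha <- backsolve(L, forwardsolve(t(L), yz))
  list(Xs = Xs, x_center = xc, x_scale = xs, y_center = yc, y_scale = ys,
       theta = theta, sf2 = sf2, ell = sqrt(ell2), sn2 = sn2,
       L = L, alpha = alpha, nll = best$value, degenerate = degenerate)
}

# Predictive mean (and sd) at new points, computed in blocks so that
# large grids never materialize a full cross-kernel matrix.
gpr_predict <- function(fit, Xnew, se = FALSE, block = 20000L) {
  Xnew <- as.matrix(Xnew)
  Zs <- sweep(sweep(Xnew, 2L, fit$x_center), 2L, fit$x_scale, `/`)
  n <- nrow(Zs)
  mu <- numeric(n)
  sd_out <- if (se) numeric(n) else NULL
  for (s in seq(1L, n, by = block)) {
    e <- min(s + block - 1L, n)
    Ks <- fit$sf2 * exp(-0.5 * sq_dist(Zs[s:e, , drop = FALSE], fit$Xs) /
                          fit$ell^2)
    mu[s:e] <- drop(Ks %*% fit$alpha)
    if (se) {
      v <- forwardsolve(t(fit$L), t(Ks))
      var_s <- pmax(fit$sf2 - colSums(v^2), 0)
      sd_out[s:e] <- sqrt(var_s) * fit$y_scale
    }
  }
  out <- mu * fit$y_scale + fit$y_center
  if (se) attr(out, "se") <- sd_out
  out
}
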