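# Exact Gaussian-process regression with the Tanimoto kernel over binary
# molecular fingerprints:
#
#   k(a, b) = amplitude * Tanimoto(a, b) + noise * 1[a == b]
#
# with a constant mean function. Hyperparameters are chosen by maximizing
# the log marginal likelihood. Fitting and prediction use a Cholesky
# factorization of the kernel matrix; a brute-force dense solve serves as
# the independent oracle in the test suite.

#' GP hyperparameters
#'
#' @param amplitude Kernel amplitude (> 0).
#' @param noise Observation noise variance (>= 0).
#' @param constant_mean Constant prior mean.
#' @return A `gp_hyperparams` list.
#' @export
gp_hyperparams <- function(amplitude = 1, noise = 0.1, constant_mean = 0) {
  stopifnot(amplitude > 0, noise >= 0)
  structure(list(amplitude = amplitude, noise = noise,
                 constant_mean = constant_mean),
            class = "gp_hyperparams")
}

# Tanimoto similarity matrix between two fingerprint lists (dense).
tanimoto_kernel_matrix <- function(fps_a, fps_b = fps_a) {
  A <- fp_matrix(fps_a)
  B <- if (identical(fps_b, fps_a)) A else fp_matrix(fps_b)
  tanimoto_cross(A, B)
}

# Log marginal likelihood of y under the Tanimoto GP. S is the precomputed
# n x n similarity matrix.
gp_log_marginal <- function(params, S, y, jitter = 1e-8) {
  n <- length(y)
  K <- params$amplitude * S + diag(params$noise + jitter, n)
  L <- tryCatch(chol(K), error = function(e) NULL)
  if (is.null(L)) return(-Inf)
  resid <- y - params$constant_mean
  alpha <- backsolve(L, forwardsolve(t(L), resid))
  -0.5 * sum(resid * alpha) - sum(log(diag(L))) - 0.5 * n * log(2 * pi)
}

#' Fit Tanimoto-GP hyperparameters
#'
#' Maximizes the log marginal likelihood over (amplitude, noise,
#' constant_mean) with L-BFGS-B on log-transformed scale parameters,
#' starting from `init`. The returned hyperparameters never have lower
#' log marginal likelihood than `init`. A singular kernel matrix is handled
#' by jitter on the diagonal and reported with a message.
#'
#' @param fingerprints List of fingerprints (training inputs).
#' @param y Numeric response vector (same length, >= 2).
#' @param init Initial [gp_hyperparams()].
#' @return Fitted `gp_hyperparams` with attribute `log_marginal`.
#' @export
gp_fit <- function(fingerprints, y, init = gp_hyperparams()) {
  stopifnot(length(fingerprints) == length(y), length(y) >= 2L)
  S <- tanimoto_kernel_matrix(fingerprints)
  obj <- function(theta) {
    p <- gp_hyperparams(exp(theta[1]), exp(theta[2]), theta[3])
    -gp_log_marginal(p, S, y)
  }
  theta0 <- c(log(init$amplitude), log(max(init$noise, 1e-6)), init$constant_mean)
  fit <- tryCatch(
    stats::optim(theta0, obj, method = "L-BFGS-B",
                 lower = c(log(1e-6), log(1e-8), -Inf),
                 upper = c(log(1e6), log(1e6), Inf)),
    error = function(e) { message("gp_fit: optimizer failed, jitter retained (",
                                  conditionMessage(e), ")"); NULL }
  )
  cand <- init
  if (!is.null(fit)) {
    fitted <- gp_hyperparams(exp(fit$par[1]), exp(fit$par[2]), fit$par[3])
    if (gp_log_marginal(fitted, S, y) >= gp_log_marginal(init, S, y)) {
      cand <- fitted
    }
  }
  attr(cand, "log_marginal") <- gp_log_marginal(cand, S, y)
  cand
}

#' Tanimoto-GP posterior prediction
#'
#' Standard exact-GP posterior with the Tanimoto kernel and constant mean.
#' A query with zero similarity to every training point reverts to the
#' prior (`mean = constant_mean`, `variance = amplitude`); in the noise-free
#' limit the posterior interpolates the training observations.
#'
#' @param params Fitted [gp_hyperparams()].
#' @param train_fps,train_y Training fingerprints and responses.
#' @param query_fps Query fingerprints.
#' @return List with `mean` and `variance` vectors (variance clipped at 0).
#' @export
gp_predict <- function(params, train_fps, train_y, query_fps) {
  stopifnot(inherits(params, "gp_hyperparams"),
            length(train_fps) == length(train_y))
  pre <- gp_precompute(params, train_fps, train_y)
  gp_predict_pre(pre, query_fps)
}

# Precomputed training-side quantities for repeated prediction (BO loop).
# `S` may be supplied when the caller maintains the similarity matrix
# incrementally.
gp_precompute <- function(params, train_fps, train_y, jitter = 1e-8,
                          Tmat = NULL, S = NULL) {
  n <- length(train_y)
  if (is.null(Tmat)) Tmat <- fp_matrix(train_fps)
  if (is.null(S)) S <- tanimoto_cross(Tmat, Tmat)
  K <- params$amplitude * S + diag(params$noise + jitter, n)
  L <- tryCatch(chol(K), error = function(e) {
    message("gp_precompute: kernel matrix singular, increasing jitter")
    chol(K + diag(1e-4, n))
  })
  alpha <- backsolve(L, forwardsolve(t(L), train_y - params$constant_mean))
  list(params = params, Tmat = Tmat, row_sums = rowSums(Tmat), L = L,
       alpha = alpha)
}

gp_predict_pre <- function(pre, query_fps) {
  Q <- fp_matrix(query_fps)
  Sq <- tanimoto_cross(Q, pre$Tmat)     # m x n
  Ks <- pre$params$amplitude * t(Sq)    # n x m
  mean <- pre$params$constant_mean + as.numeric(t(Ks) %*% pre$alpha)
  v <- forwardsolve(t(pre$L), Ks)       # n x m
  var <- pre$params$amplitude - colSums(v^2)
  list(mean = mean, variance = pmax(var, 0))
}
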