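# Bivariate linear Gaussian stationary autoregressive processes: the
# canonical continuous family for the Granger-causality discussion.  All
# second-order statistics are exact (discrete Lyapunov fixed point +
# Yule-Walker recursion); the simulator exists for cross-checks only.

#' Specification of a bivariate VAR(p) process
#'
#' `V_t = A_1 V_{t-1} + ... + A_p V_{t-p} + e_t`, `V = (X, Y)'`,
#' `e_t ~ N(0, Q)` i.i.d.  Row/column order of every matrix is `(X, Y)`.
#' Stationarity (companion-matrix spectral radius `< 1`) is enforced.
#' The configuration is unidirectional `X -> Y` exactly when every
#' `A_l[X, Y]` (the feedback of `Y` on `X`) is zero.
#'
#' @param coeffs a single 2x2 matrix or list of 2x2 matrices `A_1..A_p`.
#' @param noise_cov 2x2 symmetric positive-definite innovation covariance.
#' @param k number of lags used in measure computations.
#' @return an object of class `var_spec`.
#' @examples
#' sp <- var_spec(matrix(c(0.5, 0, 0.4, 0.5), 2, byrow = TRUE),
#'                diag(2), k = 3)
#' te_gaussian(sp)
#' @export
var_spec <- function(coeffs, noise_cov = diag(2), k = 3L) {
  if (is.matrix(coeffs)) coeffs <- list(coeffs)
  stopifnot(length(coeffs) >= 1L,
            all(vapply(coeffs, function(m) all(dim(m) == c(2L, 2L)), TRUE)))
  coeffs <- lapply(coeffs, function(m) {
    m <- unname(as.matrix(m)); storage.mode(m) <- "double"; m
  })
  noise_cov <- as.matrix(noise_cov)
  stopifnot(all(dim(noise_cov) == c(2L, 2L)))
  if (max(abs(noise_cov - t(noise_cov))) > 1e-10)
    stop("noise_cov must be symmetric")
  if (min(eigen(noise_cov, symmetric = TRUE, only.values = TRUE)$values) <= 1e-12)
    stop("noise_cov must be positive definite")
  k <- as.integer(k)
  stopifnot(k >= 1L)
  sp <- structure(list(order = length(coeffs), coeffs = coeffs,
                       noise_cov = noise_cov, k = k), class = "var_spec")
  if (spectral_radius(companion_matrix(sp)) >= 1 - 1e-10)
    stop(structure(class = c("nonstationary_spec", "error", "condition"),
                   list(message = "companion-matrix spectral radius >= 1: process is not stationary",
                        call = sys.call(-1))))
  sp
}

#' @export
print.var_spec <- function(x, ...) {
  cat(sprintf("<var_spec> VAR(%d), k = %d, spectral radius %.3f\n",
              x$order, x$k, spectral_radius(companion_matrix(x))))
  invisible(x)
}

companion_matrix <- function(spec) {
  p <- spec$order
  A <- matrix(0, 2L * p, 2L * p)
  A[1:2, ] <- do.call(cbind, spec$coeffs)
  if (p > 1L)
    A[3:(2L * p), 1:(2L * p - 2L)] <- diag(2L * p - 2L)
  A
}

spectral_radius <- function(m) max(Mod(eigen(m, only.values = TRUE)$values))

#' Stationary covariance of the VAR process
#'
#' Solves the discrete Lyapunov fixed point `S = A S A' + Q` on the
#' companion embedding (via the vectorized linear system) and returns the
#' zero-mean Gaussian law of `(X_t, Y_t)`.
#'
#' @param spec a `var_spec`.
#' @return a `gaussdist` of dimension 2.
#' @export
stationary_cov <- function(spec) {
  stopifnot(inherits(spec, "var_spec"))
  S <- companion_stationary(spec)
  gaussian_dist(c(0, 0), S[1:2, 1:2])
}

companion_stationary <- function(spec) {
  A <- companion_matrix(spec)
  d <- nrow(A)
  Q <- matrix(0, d, d)
  Q[1:2, 1:2] <- spec$noise_cov
  vecS <- solve(diag(d * d) - kronecker(A, A), as.vector(Q))
  S <- matrix(vecS, d, d)
  (S + t(S)) / 2
}

#' Autocovariance of the VAR process
#'
#' `Gamma(h) = E[V_t V_{t-h}']` for `h >= 0`: blocks of the companion
#' stationary covariance for `h < p`, Yule-Walker recursion
#' `Gamma(h) = sum_l A_l Gamma(h - l)` beyond.
#'
#' @param spec a `var_spec`.
#' @param h_max largest lag required.
#' @return list of 2x2 matrices `Gamma(0) .. Gamma(h_max)`.
#' @export
autocov <- function(spec, h_max) {
  stopifnot(inherits(spec, "var_spec"), h_max >= 0L)
  p <- spec$order
  S <- companion_stationary(spec)
  # S blocks: cov(V_{t-i}, V_{t-j}) = Gamma(j - i), so block (1, j) = Gamma(j-1)
  G <- vector("list", h_max + 1L)
  for (h in 0:min(h_max, p - 1L))
    G[[h + 1L]] <- S[1:2, (2L * h + 1L):(2L * h + 2L)]
  if (h_max >= p) {
    for (h in p:h_max) {
      acc <- matrix(0, 2L, 2L)
      for (l in seq_len(p)) {
        Gh <- if (h - l >= 0L) G[[h - l + 1L]] else t(G[[l - h + 1L]])
        acc <- acc + spec$coeffs[[l]] %*% Gh
      }
      G[[h + 1L]] <- acc
    }
  }
  G
}

# index helpers for the stacked vector (Y_t, Y_{-1..-k}, X_{-1..-k})
lagged_gaussian_names <- function(k, future = "Y") {
  other <- if (future == "Y") "X" else "Y"
  c(node_name(future, 0L), node_name(future, -(1:k)), node_name(other, -(1:k)))
}

#' Exact Gaussian law of the future value and its lagged past
#'
#' Zero-mean Gaussian over `(F_t, F-lags, O-lags)` — by default
#' `(Y_t, Y_{t-1..t-k}, X_{t-1..t-k})` — with the block-Toeplitz
#' covariance assembled from the autocovariances.  The operand of the
#' Gaussian transfer entropy and the configuration comparisons.
#'
#' @param spec a `var_spec`.
#' @param k lag count (defaults to `spec$k`).
#' @param future `"Y"` (default) or `"X"`.
#' @return a `gaussdist` of dimension `2k + 1`, with variable names in
#'   attribute `"var_names"`.
#' @export
lagged_gaussian <- function(spec, k = spec$k, future = c("Y", "X")) {
  stopifnot(inherits(spec, "var_spec"))
  future <- match.arg(future)
  k <- as.integer(k)
  G <- autocov(spec, k)
  cov_v <- function(ti, tj) {   # cov(V_{ti}, V_{tj}), ti, tj <= 0
    h <- ti - tj
    if (h >= 0L) G[[h + 1L]] else t(G[[-h + 1L]])
  }
  fut_i <- if (future == "Y") 2L else 1L
  oth_i <- 3L - fut_i
  times <- c(0L, -(1:k), -(1:k))
  comp  <- c(fut_i, rep(fut_i, k), rep(oth_i, k))
  d <- 2L * k + 1L
  S <- matrix(0, d, d)
  for (i in seq_len(d)) for (j in seq_len(d))
    S[i, j] <- cov_v(times[i], times[j])[comp[i], comp[j]]
  g <- gaussian_dist(rep(0, d), S)
  attr(g, "var_names") <- lagged_gaussian_names(k, future)
  g
}

# conditional variance of component 1 given a set of components
schur_cond_var <- function(S, given) {
  if (!length(given)) return(S[1L, 1L])
  Sgg <- S[given, given, drop = FALSE]
  Sg1 <- S[given, 1L, drop = FALSE]
  sol <- tryCatch(solve(Sgg, Sg1), error = function(e) {
    solve(Sgg + diag(1e-12, nrow(Sgg)), Sg1)
  })
  v <- S[1L, 1L] - drop(crossprod(Sg1, sol))
  if (!is.finite(v) || v <= 0)
    stop(structure(class = c("ill_conditioned", "error", "condition"),
                   list(message = "conditioning block numerically singular",
                        call = sys.call(-1))))
  v
}

#' Gaussian transfer entropy (linear Granger causality) in bits
#'
#' `TE = log2( Var(F_t | F-lags) / Var(F_t | F-lags, O-lags) ) / 2`, the
#' conditional variances taken from Schur complements of the exact lagged
#' Gaussian law.  Nonnegative, and zero iff the cross coefficients into
#' the future process are all zero (for generic noise).
#'
#' @param spec a `var_spec`.
#' @param k lag count (defaults to `spec$k`).
#' @param direction `"xy"` (X driving Y, the default) or `"yx"`.
#' @return numeric scalar `>= 0` in bits.
#' @export
te_gaussian <- function(spec, k = spec$k, direction = c("xy", "yx")) {
  stopifnot(inherits(spec, "var_spec"))
  direction <- match.arg(direction)
  g <- lagged_gaussian(spec, k, future = if (direction == "xy") "Y" else "X")
  S <- g$cov
  own <- 2:(k + 1L)
  all_past <- 2:(2L * k + 1L)
  v_own <- schur_cond_var(S, own)
  v_full <- schur_cond_var(S, all_past)
  max(0.5 * log2(v_own / v_full), 0)
}

# linear-Gaussian conditional of the future on a conditioning index set:
# mean w's + intercept 0, fixed variance v, plus the conditioning
# covariance needed to average quadratic forms
linear_conditional <- function(g, given) {
  S <- g$cov
  if (!length(given))
    return(list(w = numeric(0), v = S[1L, 1L], S_cond = matrix(0, 0L, 0L)))
  Sgg <- S[given, given, drop = FALSE]
  w <- solve(Sgg, S[given, 1L])
  list(w = w, v = schur_cond_var(S, given), S_cond = Sgg)
}

#' Divergence of a dynamical aspect between two VAR configurations (bits)
#'
#' Selects a probability distribution describing one aspect of the
#' dynamics and compares it between configurations with the Gaussian KL
#' divergence.  For conditional aspects the KL between the two
#' linear-Gaussian conditionals is averaged over configuration `a`'s
#' stationary law of the conditioning variables (closed form — no
#' integration error).  The inputs need not be natural causal effects;
#' for `aspect = "y_on_xlag"` under unidirectional `X -> Y` coupling they
#' are.
#'
#' @param spec_a,spec_b `var_spec` objects (compared with `spec_a`'s `k`).
#' @param aspect `"y_on_xlag"` (`p(Y_t | X_{t-1})`), `"y_on_ypast"`
#'   (`p(Y_t | Y_{t-1..t-k})`), or `"y_marginal"` (`p(Y_t)`).
#' @return numeric scalar `>= 0` in bits.
#' @export
config_divergence <- function(spec_a, spec_b,
                              aspect = c("y_on_xlag", "y_on_ypast",
                                         "y_marginal")) {
  stopifnot(inherits(spec_a, "var_spec"), inherits(spec_b, "var_spec"))
  aspect <- match.arg(aspect)
  k <- spec_a$k
  ga <- lagged_gaussian(spec_a, k)
  gb <- lagged_gaussian(spec_b, k)
  if (aspect == "y_marginal") {
    return(gaussian_kl(gaussian_dist(0, ga$cov[1L, 1L, drop = FALSE]),
                       gaussian_dist(0, gb$cov[1L, 1L, drop = FALSE])))
  }
  given <- if (aspect == "y_on_xlag") k + 2L else 2:(k + 1L)
  ca <- linear_conditional(ga, given)
  cb <- linear_conditional(gb, given)
  dw <- ca$w - cb$w
  mean_gap <- drop(crossprod(dw, ca$S_cond %*% dw))
  0.5 * (ca$v / cb$v - 1 + log(cb$v / ca$v) + mean_gap / cb$v) / log(2)
}

#' Simulate the VAR process
#'
#' Seeded; the initial window is drawn from the exact stationary law and
#' a burn-in is discarded.
#'
#' @param spec a `var_spec`.
#' @param n number of retained steps.
#' @param seed integer seed.
#' @param burn_in discarded initial steps (default 1000).
#' @return list with numeric vectors `x` and `y` of length `n`.
#' @export
simulate_var <- function(spec, n, seed, burn_in = 1000L) {
  stopifnot(inherits(spec, "var_spec"), n >= 1L)
  set.seed(as.integer(seed))
  p <- spec$order
  S0 <- companion_stationary(spec)
  w <- drop(t(chol(S0 + diag(1e-12, nrow(S0)))) %*% rnorm(nrow(S0)))
  total <- n + burn_in
  cQ <- t(chol(spec$noise_cov))
  eps <- cQ %*% matrix(rnorm(2L * total), 2L)
  out <- matrix(0, 2L, total + p)
  # stationary initial window (w stacks V_{t-1}, ..., V_{t-p})
  for (l in seq_len(p)) out[, p - l + 1L] <- w[(2L * l - 1L):(2L * l)]
  A <- spec$coeffs
  for (t in seq_len(total)) {
    v <- eps[, t]
    for (l in seq_len(p)) v <- v + A[[l]] %*% out[, p + t - l]
    out[, p + t] <- v
  }
  keep <- p + (burn_in + 1L):total
  list(x = out[1L, keep], y = out[2L, keep])
}

#' Plug-in Gaussian transfer entropy from sampled series (bits)
#'
#' Ordinary-least-squares residual-variance ratio: regress the future on
#' own lags, then on own plus other lags, and return
#' `log2(RSS_restricted / RSS_full) / 2`.
#'
#' @param x,y numeric vectors (estimates TE from `x` to `y`).
#' @param k lag count.
#' @return numeric scalar in bits.
#' @export
plugin_te_gaussian <- function(x, y, k) {
  n <- length(y)
  ts <- (k + 1L):n
  f <- y[ts]
  own <- sapply(1:k, function(l) y[ts - l])
  oth <- sapply(1:k, function(l) x[ts - l])
  rss <- function(X) {
    fit <- stats::lm.fit(cbind(1, X), f)
    mean(fit$residuals^2)
  }
  max(0.5 * log2(rss(own) / rss(cbind(own, oth))), 0)
}
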