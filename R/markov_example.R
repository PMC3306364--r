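# Bivariate binary stationary Markov process of order 1 with
# unidirectional coupling X -> Y.
#
#   P(X_t = X_{t-1})           = a        (self-repeat probability of X)
#   P(Y_t = X_{t-1})           = (1+c)/2  (independent of Y_{t-1})
#
# c = 0 makes Y i.i.d. uniform and independent of everything; c = 1 makes
# Y a deterministic copy of X one step back; a = 0 makes X alternate
# deterministically, the classical almost-synchronized extreme.  Because
# coupling is strictly unidirectional, the conditional distributions
# p(y_t | x_{t-1}) qualify as natural causal effects, while transfer
# entropy remains a statistic for the existence of the connection only.
#
# Everything here is computed exactly: joints are propagated through the
# transition tables in closed form, never sampled (the simulator exists
# only for empirical cross-checks).

#' Specification of the binary Markov example process
#'
#' @param a probability in `[0, 1]` that `X` repeats its previous value.
#' @param c coupling strength in `[0, 1]`; `P(Y_t = X_{t-1}) = (1 + c)/2`.
#' @param k number of past lags used when computing lagged joints and
#'   measures (positive integer).
#' @return an object of class `markov_spec`.
#' @examples
#' sp <- markov_spec(a = 0.25, c = 0.5, k = 5)
#' te_xy(sp)
#' @export
markov_spec <- function(a, c, k = 5L) {
  stopifnot(is.numeric(a), length(a) == 1L, a >= 0, a <= 1,
            is.numeric(c), length(c) == 1L, c >= 0, c <= 1)
  k <- as.integer(k)
  stopifnot(k >= 1L)
  structure(list(a = a, c = c, k = k), class = "markov_spec")
}

#' @export
print.markov_spec <- function(x, ...) {
  cat(sprintf("<markov_spec> a = %g, c = %g, k = %d\n", x$a, x$c, x$k))
  invisible(x)
}

# 2x2 transition matrices, state order c("0", "1").
# A[x_prev, x_next], B[x_prev, y_next]
markov_matrices <- function(spec) {
  a <- spec$a; c <- spec$c
  A <- matrix(c(a, 1 - a, 1 - a, a), 2L, 2L, byrow = TRUE,
              dimnames = list(c("0", "1"), c("0", "1")))
  B <- matrix(c((1 + c) / 2, (1 - c) / 2, (1 - c) / 2, (1 + c) / 2),
              2L, 2L, byrow = TRUE,
              dimnames = list(c("0", "1"), c("0", "1")))
  list(A = A, B = B)
}

#' Transition tables of the Markov example
#'
#' @param spec a `markov_spec`.
#' @return list of two `cpt` objects: `X` for `P(X_t | X_{t-1})` and `Y`
#'   for `P(Y_t | X_{t-1})` (the coupling; `Y`'s own past is irrelevant).
#' @export
markov_transition <- function(spec) {
  stopifnot(inherits(spec, "markov_spec"))
  m <- markov_matrices(spec)
  b <- c("0", "1")
  list(X = cpt("X[0]", b, "X[-1]", list(`X[-1]` = b), m$A),
       Y = cpt("Y[0]", b, "X[-1]", list(`X[-1]` = b), m$B))
}

#' Stationary one-step marginal of (X_t, Y_t)
#'
#' The fixed point of the joint transition operator.  Since `Y_t` depends
#' only on `X_{t-1}` and the `X` chain is 0/1-exchange symmetric (uniform
#' stationary law for every `a`; the period-2 chain at `a = 0` and the
#' absorbing chain at `a = 1` are handled as their unique symmetric
#' stationary mixtures), the joint has the closed form
#' `p(x, y) = 1/2 * sum_{x'} A[x', x] B[x', y]`.  The joint is uniform
#' exactly when `c = 0` or `a = 1/2`; otherwise `X_t` and `Y_t` are
#' correlated through their shared dependence on `X_{t-1}`.
#'
#' @param spec a `markov_spec`.
#' @return a `cdist` over `c("X[0]", "Y[0]")`.
#' @export
markov_stationary <- function(spec) {
  stopifnot(inherits(spec, "markov_spec"))
  m <- markov_matrices(spec)
  b <- c("0", "1")
  p <- outer(b, b, Vectorize(function(x, y)
    0.5 * sum(m$A[, x] * m$B[, y])))
  cdist(c("X[0]", "Y[0]"), list(`X[0]` = b, `Y[0]` = b), as.vector(p))
}

# Exact stationary joint over visible variables, built by vectorized
# forward propagation from the uniform law of the hidden X seed one step
# before the window.  Variable order as constructed (first fastest):
#   Y[-k], X[-k], Y[-k+1], X[-k+1], ..., Y[-1], X[-1], future
# where future is Y[0] or X[0].
markov_full_joint_vector <- function(spec, k, future = c("Y", "X")) {
  future <- match.arg(future)
  m <- markov_matrices(spec)
  A <- m$A; B <- m$B
  # first window step: joint of (y_{-k}, x_{-k}) after summing the seed
  C <- matrix(0, 2L, 2L)  # C[y, x]
  for (x0 in 1:2) C <- C + 0.5 * outer(B[x0, ], A[x0, ])
  v <- as.vector(C)       # dims (y_{-k}, x_{-k}), x slowest
  if (k >= 2L) {
    for (s in 2:k) {
      L <- length(v)
      xprev <- rep(1:2, each = L / 2L)
      blocks <- vector("list", 4L)
      i <- 0L
      for (x in 1:2) for (y in 1:2) {   # y faster than x in the new dims
        i <- i + 1L
        blocks[[i]] <- v * B[xprev, y] * A[xprev, x]
      }
      # order blocks as (y=1,x=1),(y=2,x=1),(y=1,x=2),(y=2,x=2)
      v <- c(blocks[[1L]], blocks[[2L]], blocks[[3L]], blocks[[4L]])
    }
  }
  # final emission from x_{-1} (the current slowest dim)
  L <- length(v)
  xprev <- rep(1:2, each = L / 2L)
  M <- if (future == "Y") B else A
  c(v * M[xprev, 1L], v * M[xprev, 2L])
}

#' Exact stationary lagged joint distribution
#'
#' The joint of the future value and `k` lags of both processes,
#' `(F, Y[-1..-k], X[-1..-k])` with `F = Y[0]` (default) or `X[0]`,
#' obtained by exact forward propagation of the stationary law — the
#' operand of the transfer-entropy and divergence computations.
#'
#' @param spec a `markov_spec` (its `k` is used unless overridden).
#' @param k number of lags; guarded at `k <= 12` (the table has
#'   `2^(2k+1)` entries).
#' @param future `"Y"` or `"X"`: which process's next value is included.
#' @return a `cdist` over `2k + 1` binary variables.
#' @export
markov_lagged_joint <- function(spec, k = spec$k, future = c("Y", "X")) {
  stopifnot(inherits(spec, "markov_spec"))
  future <- match.arg(future)
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1")
  if (k > 12L)
    stop(structure(class = c("resource_guard", "error", "condition"),
                   list(message = "k > 12 would allocate a table with more than 2^25 entries",
                        call = sys.call(-1))))
  v <- markov_full_joint_vector(spec, k, future)
  b <- c("0", "1")
  lag_names <- as.vector(vapply(-(k:1), function(t)
    c(node_name("Y", t), node_name("X", t)), character(2)))
  vars <- c(lag_names, node_name(future, 0L))
  cdist(vars, setNames(rep(list(b), length(vars)), vars), v)
}

# Forward filter: exact p(ypast, x_{-1}) over all 2^k y-histories.
# Rows indexed by the y-history (earliest lag fastest), columns by x_{-1}.
markov_forward_filter <- function(spec, k) {
  m <- markov_matrices(spec)
  M0 <- m$A * m$B[, 1L]   # M_y[x', x] = B[x', y] A[x', x]
  M1 <- m$A * m$B[, 2L]
  alpha <- matrix(0.5, 1L, 2L)
  for (s in seq_len(k)) {
    alpha <- rbind(alpha %*% M0, alpha %*% M1)
    # row index: h' = h + 2^(s-1) * y  (newest lag slowest)
  }
  alpha
}

#' Transfer entropy from X to Y (bits)
#'
#' `TE = H(Y_t | Y-past) - H(Y_t | Y-past, X-past)` with `k` lags of
#' past.  Because the coupling has order 1, `H(Y_t | Y-past, X-past)`
#' collapses exactly to `H(Y_t | X_{t-1})`; `H(Y_t | Y-past)` is obtained
#' by exact marginalization of the hidden `X` path (forward filtering),
#' which makes the computation fast for any `k` up to ~20.  Agrees with
#' [transfer_entropy()] applied to [markov_lagged_joint()].
#'
#' @param spec a `markov_spec`.
#' @param k number of past lags (defaults to `spec$k`).
#' @return numeric scalar `>= 0` in bits.
#' @export
te_xy <- function(spec, k = spec$k) {
  stopifnot(inherits(spec, "markov_spec"))
  m <- markov_matrices(spec)
  alpha <- markov_forward_filter(spec, k)   # p(ypast, x_{-1})
  P <- alpha %*% m$B                        # p(ypast, y_t)
  p_ypast <- rowSums(P)
  h_cond <- -sum(xlogy(P, P)) + sum(xlogy(p_ypast, p_ypast))  # H(Y_t|Ypast)
  b_row <- m$B[1L, ]
  h_full <- -sum(xlogy(b_row, b_row))       # H(Y_t | X_{t-1}), any x row
  max(h_cond - h_full, 0)
}

#' Transfer entropy from Y to X (bits)
#'
#' Computed from the mirrored lagged joint with `X_t` as the future
#' variable.  For this unidirectionally coupled family it is analytically
#' zero at every `(a, c, k)`; the function computes it numerically from
#' the exact table so that the claim is verified rather than assumed.
#'
#' @inheritParams te_xy
#' @return numeric scalar (0 up to float roundoff).
#' @export
te_yx <- function(spec, k = spec$k) {
  stopifnot(inherits(spec, "markov_spec"))
  d <- markov_lagged_joint(spec, k = k, future = "X")
  own <- node_name("X", -(1:k))
  other <- node_name("Y", -(1:k))
  transfer_entropy(d, node_name("X", 0L), own, other)
}

#' Smallest lag count at which the transfer entropy has converged
#'
#' Returns the smallest `k <= k_max` with
#' `|te_xy(k + 1) - te_xy(k)| < tol`; if none converges, returns `k_max`
#' with a warning.  One lag is enough when conditioning on the `X` past
#' (the coupling has order 1), but the term `H(Y_t | Y-past)` has no such
#' cutoff, so slow-mixing chains (small `a`) keep gaining information
#' from deeper `Y` lags.
#'
#' @param spec a `markov_spec`.
#' @param tol convergence tolerance in bits.
#' @param k_max largest lag count tried.
#' @return integer lag count.
#' @export
converged_k <- function(spec, tol = 1e-10, k_max = 10L) {
  stopifnot(inherits(spec, "markov_spec"))
  te_prev <- te_xy(spec, k = 1L)
  for (k in seq_len(k_max)) {
    te_next <- te_xy(spec, k = k + 1L)
    if (abs(te_next - te_prev) < tol) return(k)
    te_prev <- te_next
  }
  warning("transfer entropy not converged at k_max = ", k_max)
  k_max
}

#' Natural-effect divergence curve of the Markov example (bits)
#'
#' The average Jensen-Shannon divergence between the natural causal
#' effects `p(Y_t | X_{t-1} = x)` of the current configuration and those
#' of a reference configuration (default: `c = 0`, no causal
#' connection), weighted by the distribution of the natural
#' interventions `P(X_{t-1})` (uniform).  Existence is licensed by the
#' strictly unidirectional coupling.  The value is independent of `a`
#' because `p(Y_t | X_{t-1})` does not involve `a`, and increases
#' monotonically with `c`.
#'
#' @param spec a `markov_spec`.
#' @param reference_c coupling of the reference configuration.
#' @return numeric scalar in bits.
#' @export
natural_effect_curve <- function(spec, reference_c = 0) {
  stopifnot(inherits(spec, "markov_spec"))
  ref <- markov_spec(spec$a, reference_c, spec$k)
  eff_of <- function(sp) {
    d <- markov_lagged_joint(sp, k = 1L)
    xs <- c("0", "1")
    setNames(lapply(xs, function(x)
      conditional(d, node_name("Y", 0L), setNames(x, node_name("X", -1L)))), xs)
  }
  d_now <- markov_lagged_joint(spec, k = 1L)
  weights <- marginal(d_now, node_name("X", -1L))
  natural_effect_divergence(eff_of(spec), eff_of(ref), weights, metric = "jsd")
}

#' Mechanism-change divergence curve of the Markov example (bits)
#'
#' The average Jensen-Shannon divergence between `p(Y_t | Y-past)` of the
#' current configuration and of a reference configuration (default
#' `c = 0`), weighted by the current configuration's `P(Y-past)`.  These
#' conditionals are not natural causal effects between the subsystems —
#' the comparison quantifies the causal effect of changing the coupling
#' parameter itself on this aspect of the dynamics.  With `a = 1/2` the
#' `X` chain is i.i.d. uniform, so `p(Y_t | Y-past)` is uniform for every
#' `c` and the curve is identically zero.
#'
#' @inheritParams natural_effect_curve
#' @return numeric scalar in bits.
#' @export
mechanism_change_curve <- function(spec, reference_c = 0) {
  stopifnot(inherits(spec, "markov_spec"))
  ref <- markov_spec(spec$a, reference_c, spec$k)
  m <- markov_matrices(spec)
  mref <- markov_matrices(ref)
  k <- spec$k
  P_now <- markov_forward_filter(spec, k) %*% m$B     # p(ypast, y_t)
  P_ref <- markov_forward_filter(ref, k) %*% mref$B
  w_now <- rowSums(P_now)
  w_ref <- rowSums(P_ref)
  b <- c("0", "1")
  total <- 0
  for (h in seq_along(w_now)) {
    if (w_now[h] <= NC_TOL) next
    p_h <- cdist("Y[0]", list(`Y[0]` = b), P_now[h, ] / w_now[h])
    if (w_ref[h] <= NC_TOL) {
      # reference assigns no mass to this history; compare against the
      # reference's unconditional next-step law instead of dividing by 0
      q_h <- cdist("Y[0]", list(`Y[0]` = b), colSums(P_ref))
    } else {
      q_h <- cdist("Y[0]", list(`Y[0]` = b), P_ref[h, ] / w_ref[h])
    }
    total <- total + w_now[h] * jsd(p_h, q_h)
  }
  total
}

#' Simulate the Markov example process
#'
#' Reproducible given `seed`; the initial pair is drawn from the
#' stationary law and each step follows the transition tables.  Exists
#' for empirical cross-validation of the analytic results, which never
#' rely on it.
#'
#' @param spec a `markov_spec`.
#' @param n number of time steps (`>= 1`).
#' @param seed integer seed.
#' @return list with integer (0/1) vectors `x` and `y` of length `n`.
#' @export
simulate_markov <- function(spec, n, seed) {
  stopifnot(inherits(spec, "markov_spec"), n >= 1L)
  set.seed(as.integer(seed))
  init <- markov_stationary(spec)
  pick <- which(runif(1L) <= cumsum(as.vector(init$p)))[1L]
  g <- assignment_grid(init)[pick, ]
  x <- integer(n); y <- integer(n)
  x[1L] <- as.integer(g[[1L]]); y[1L] <- as.integer(g[[2L]])
  if (n >= 2L) {
    # X flips with probability 1 - a; Y copies X_{t-1} with prob (1+c)/2
    flips <- runif(n - 1L) > spec$a
    x[-1L] <- (x[1L] + cumsum(flips)) %% 2L
    copy <- runif(n - 1L) <= (1 + spec$c) / 2
    y[-1L] <- ifelse(copy, x[-n], 1L - x[-n])
  }
  list(x = x, y = y)
}

#' Plug-in transfer entropy estimate from binary sequences (bits)
#'
#' Histogram estimator: embeds the two sequences with `k` lags, counts
#' configurations and applies [transfer_entropy()] to the empirical
#' joint.  Consistent as the sample grows; used to cross-check the
#' analytic values.
#'
#' @param x,y integer (0/1) vectors of equal length (`x` the candidate
#'   driver: estimates TE from `x` to `y`).
#' @param k embedding lag count.
#' @return numeric scalar in bits.
#' @export
plugin_transfer_entropy <- function(x, y, k) {
  n <- length(y)
  stopifnot(length(x) == n, n > k + 1L)
  ts <- (k + 1L):n
  code <- y[ts]
  shift <- 1L
  for (l in 1:k) { code <- code + 2L^shift * y[ts - l]; shift <- shift + 1L }
  for (l in 1:k) { code <- code + 2L^shift * x[ts - l]; shift <- shift + 1L }
  counts <- tabulate(code + 1L, nbins = 2L^(2L * k + 1L))
  b <- c("0", "1")
  vars <- c(node_name("Y", 0L), node_name("Y", -(1:k)), node_name("X", -(1:k)))
  d <- cdist(vars, setNames(rep(list(b), length(vars)), vars),
             counts / sum(counts))
  transfer_entropy(d, node_name("Y", 0L), node_name("Y", -(1:k)),
                   node_name("X", -(1:k)))
}

#' Parameter sweep over (a, c) of all three analytic measures
#'
#' Computes, on the requested grid, the transfer entropies in both
#' directions, the natural-effect divergence curve and the
#' mechanism-change divergence curve.  Deterministic row order: `a`
#' major, then `c`.
#'
#' @param a_grid,c_grid numeric grids.
#' @param k lag count, or `"converged"` to use [converged_k()] per point.
#' @param file optional path; when given, the table is written as TSV
#'   (tab separated, '.' decimal) with header
#'   `a c k te_xy te_yx jsd_natural jsd_mechanism`.
#' @return the sweep as a data frame (invisibly when `file` is given).
#' @export
markov_sweep <- function(a_grid, c_grid, k = "converged", file = NULL) {
  rows <- list()
  for (a in a_grid) for (cc in c_grid) {
    sp <- markov_spec(a, cc, 5L)
    kk <- if (identical(k, "converged")) {
      suppressWarnings(converged_k(sp))
    } else as.integer(k)
    sp <- markov_spec(a, cc, kk)
    rows[[length(rows) + 1L]] <- data.frame(
      a = a, c = cc, k = kk,
      te_xy = te_xy(sp),
      te_yx = te_yx(sp),
      jsd_natural = natural_effect_curve(sp),
      jsd_mechanism = mechanism_change_curve(sp))
  }
  out <- do.call(rbind, rows)
  if (!is.null(file)) {
    write.table(format(out, digits = 15, scientific = FALSE, trim = TRUE),
                file, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(out))
  }
  out
}
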