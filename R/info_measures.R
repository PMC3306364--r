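# Information-theoretic quantification layer.  All measures are reported
# in bits (log base 2); the Gaussian closed form is evaluated in nats and
# divided by ln 2.  KL with an absolute-continuity failure returns +Inf
# rather than erroring, so parameter sweeps can report it; the
# Jensen-Shannon divergence is the documented remedy when supports differ.

xlogy <- function(x, y) {
  out <- numeric(length(x))
  pos <- x > 0
  out[pos] <- x[pos] * log2(y[pos])
  out
}

#' Kullback-Leibler divergence between categorical distributions (bits)
#'
#' `sum p log2(p/q)` with the convention `0 log 0 = 0`.  Nonnegative and
#' zero iff the two distributions are identical.  Returns `Inf` when some
#' outcome has `p > 0` but `q = 0` (use [jsd()] for distributions with
#' different domains).
#'
#' @param p,q `cdist` objects over the same variables and supports.
#' @return numeric scalar in bits (possibly `Inf`).
#' @export
kl_divergence <- function(p, q) {
  stopifnot(inherits(p, "cdist"), inherits(q, "cdist"))
  if (!identical(p$vars, q$vars) || !identical(p$support, q$support))
    stop("p and q must share variables and supports (consider jsd)")
  pv <- as.vector(p$p); qv <- as.vector(q$p)
  if (any(pv > 0 & qv == 0)) return(Inf)
  sum(xlogy(pv, pv)) - sum(xlogy(pv, qv))
}

align_supports <- function(p, q) {
  if (!identical(p$vars, q$vars))
    stop("p and q must be over the same variable names")
  supp <- setNames(lapply(p$vars, function(v)
    union(p$support[[v]], q$support[[v]])), p$vars)
  extend <- function(d) {
    if (identical(d$support, supp)) return(d)
    arr <- array(0, dim = lengths(supp), dimnames = supp)
    idx <- as.matrix(expand.grid(lapply(d$vars, function(v)
      match(d$support[[v]], supp[[v]])), KEEP.OUT.ATTRS = FALSE))
    arr[idx] <- as.vector(d$p)
    cdist(d$vars, supp, arr)
  }
  list(p = extend(p), q = extend(q))
}

#' Jensen-Shannon divergence (bits)
#'
#' The average of the two KL divergences to the equal-weight midpoint,
#' `JSD(p, q) = KL(p||m)/2 + KL(q||m)/2` with `m = (p + q)/2`.  Always
#' finite, symmetric, and bounded in `[0, 1]` bits, attaining 1 exactly
#' for distributions with disjoint supports.  Supports may differ: the
#' union support is taken and missing outcomes get probability zero.
#'
#' @param p,q `cdist` objects over the same variable names.
#' @return numeric scalar in `[0, 1]` bits.
#' @export
jsd <- function(p, q) {
  stopifnot(inherits(p, "cdist"), inherits(q, "cdist"))
  al <- align_supports(p, q)
  pv <- as.vector(al$p$p); qv <- as.vector(al$q$p)
  mv <- (pv + qv) / 2
  0.5 * (sum(xlogy(pv, pv)) - sum(xlogy(pv, mv))) +
    0.5 * (sum(xlogy(qv, qv)) - sum(xlogy(qv, mv)))
}

#' Mutual information between two groups of variables (bits)
#'
#' `I(X; Y) = KL( p(x, y) || p(x) p(y) )`.  Equivalently the average over
#' `x` of `KL(p(y|x) || p(y))`; the equality of the two routes is an
#' exact identity used as a cross-check in the test suite.
#'
#' @param p_xy a `cdist` whose variables are exactly `x` and `y` together.
#' @param x,y disjoint variable sets partitioning `p_xy`.
#' @return numeric scalar `>= 0` in bits.
#' @export
mutual_information <- function(p_xy, x, y) {
  stopifnot(inherits(p_xy, "cdist"))
  if (!setequal(c(x, y), p_xy$vars) || length(intersect(x, y)))
    stop("x and y must partition the variables of p_xy")
  px <- marginal(p_xy, x)
  py <- marginal(p_xy, y)
  # independent product aligned to p_xy's variable order
  prod_p <- outer(as.vector(px$p), as.vector(py$p))
  ind <- cdist(c(px$vars, py$vars), c(px$support, py$support),
               as.vector(prod_p))
  # reorder to p_xy's layout
  perm <- match(p_xy$vars, ind$vars)
  ind <- cdist(p_xy$vars, p_xy$support, aperm(ind$p, perm))
  kl_divergence(p_xy, ind)
}

# second route for the Eq.-20-style identity test: sum_x p(x) KL(p(y|x)||p(y))
mutual_information_via_conditionals <- function(p_xy, x, y) {
  py <- marginal(p_xy, y)
  pos <- positive_assignments(p_xy, x)
  total <- 0
  for (i in seq_len(nrow(pos))) {
    xv <- setNames(as.character(unlist(pos[i, x, drop = FALSE])), x)
    total <- total + pos$prob[i] * kl_divergence(conditional(p_xy, y, xv), py)
  }
  total
}

# ---------------------------------------------------------------------------
# Gaussian distributions

#' Multivariate Gaussian distribution (mean and covariance)
#'
#' @param mean numeric vector.
#' @param cov symmetric positive-definite covariance matrix (smallest
#'   eigenvalue `> 1e-12`).
#' @return an object of class `gaussdist`.
#' @export
gaussian_dist <- function(mean, cov) {
  mean <- as.numeric(mean)
  cov <- as.matrix(cov)
  d <- length(mean)
  stopifnot(nrow(cov) == d, ncol(cov) == d)
  if (max(abs(cov - t(cov))) > 1e-8) stop("covariance must be symmetric")
  ev <- eigen((cov + t(cov)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-12) stop("covariance must be positive definite")
  structure(list(mean = mean, cov = (cov + t(cov)) / 2), class = "gaussdist")
}

#' @export
print.gaussdist <- function(x, ...) {
  cat(sprintf("<gaussdist> dimension %d\n", length(x$mean)))
  invisible(x)
}

#' Kullback-Leibler divergence between two Gaussians (bits)
#'
#' Closed form in terms of means and covariances:
#' `KL = (tr(Sq^-1 Sp) + (mq - mp)' Sq^-1 (mq - mp) - d + ln(det Sq / det Sp)) / (2 ln 2)`.
#'
#' @param p,q `gaussdist` objects of equal dimension.
#' @return numeric scalar `>= 0` in bits.
#' @export
gaussian_kl <- function(p, q) {
  stopifnot(inherits(p, "gaussdist"), inherits(q, "gaussdist"))
  d <- length(p$mean)
  if (length(q$mean) != d) stop("dimension mismatch")
  cq <- chol(q$cov)
  cp <- chol(p$cov)
  iq <- chol2inv(cq)
  dm <- q$mean - p$mean
  tr <- sum(iq * p$cov)  # tr(Sq^-1 Sp) for symmetric Sp
  quad <- drop(crossprod(dm, iq %*% dm))
  logdet <- 2 * (sum(log(diag(cq))) - sum(log(diag(cp))))
  0.5 * (tr + quad - d + logdet) / log(2)
}

# ---------------------------------------------------------------------------
# Transfer entropy and configuration comparisons

#' Transfer entropy from an exact joint table (bits)
#'
#' The conditional mutual information between a process's next value and
#' the other process's past given its own past,
#' `TE = sum p(f, op, xp) log2[ p(f | op, xp) / p(f | op) ]`.
#' Zero iff the future is conditionally independent of the other past —
#' the general statistic for the Granger causality criterion.
#'
#' @param p a `cdist` over `{future} + own_past + other_past`.
#' @param future name of the future variable.
#' @param own_past,other_past variable sets (own past may be empty).
#' @return numeric scalar `>= 0` in bits.
#' @export
transfer_entropy <- function(p, future, own_past, other_past) {
  stopifnot(inherits(p, "cdist"), length(future) == 1L)
  if (!setequal(c(future, own_past, other_past), p$vars))
    stop("future, own_past, other_past must partition the variables of p")
  perm <- match(c(future, own_past, other_past), p$vars)
  arr <- aperm(p$p, perm)
  nf <- length(p$support[[future]])
  nop <- prod(lengths(p$support[own_past]))
  nxp <- prod(lengths(p$support[other_past]))
  a3 <- array(arr, dim = c(nf, nop, nxp))
  p_fop <- rowSums(a3, dims = 2L)           # nf x nop
  p_op <- colSums(p_fop)                    # nop
  p_opxp <- colSums(a3)                     # nop x nxp
  v <- as.vector(a3)
  v_fop <- rep(as.vector(p_fop), times = nxp)
  v_op <- rep(rep(p_op, each = nf), times = nxp)
  v_opxp <- rep(as.vector(p_opxp), each = nf)
  pos <- v > 0
  sum(v[pos] * (log2(v[pos]) + log2(v_op[pos]) -
                  log2(v_fop[pos]) - log2(v_opxp[pos])))
}

#' Average divergence between two families of natural causal effects (bits)
#'
#' Compares the same natural interventions across two configurations:
#' `sum_x w(x) D( effect_a(x) || effect_b(x) )`, with the weights `w`
#' normally the distribution of the natural interventions (the observed
#' marginal of the intervened variable).  A point-mass weight reduces to
#' a single-intervention comparison.  This is a pure functional: the
#' caller is responsible for having verified existence first.
#'
#' @param effect_a,effect_b named lists mapping intervention values to
#'   `cdist` objects (as returned by [causal_effect()]).
#' @param weights a `cdist` over the intervened variable; every value in
#'   its support must be a name of both maps.
#' @param metric `"jsd"` (default) or `"kl"`.
#' @return numeric scalar in bits (may be `Inf` for `"kl"`).
#' @export
natural_effect_divergence <- function(effect_a, effect_b, weights,
                                      metric = c("jsd", "kl")) {
  metric <- match.arg(metric)
  stopifnot(inherits(weights, "cdist"), length(weights$vars) == 1L)
  div <- if (metric == "jsd") jsd else kl_divergence
  vals <- weights$support[[1L]]
  missing <- setdiff(vals[as.vector(weights$p) > 0], names(effect_a))
  if (length(missing) || length(setdiff(vals[as.vector(weights$p) > 0],
                                        names(effect_b))))
    stop("both effect maps must be defined on all weight-support values")
  w <- as.vector(weights$p)
  total <- 0
  for (i in seq_along(vals)) {
    if (w[i] <= 0) next
    total <- total + w[i] * div(effect_a[[vals[i]]], effect_b[[vals[i]]])
  }
  total
}

#' Divergence induced by a change of mechanism (bits)
#'
#' Compares a chosen aspect of the dynamics (any pair of comparable
#' distributions) across two configurations that differ in a coupling
#' parameter.  The change of parameter is itself a punctual intervention
#' on the mechanism, so the divergence quantifies its causal effect on
#' that aspect — the inputs need not themselves be natural causal
#' effects.
#'
#' @param dist_a,dist_b `cdist` objects over the same variables.
#' @param metric `"jsd"` (default) or `"kl"`.
#' @return numeric scalar in bits.
#' @export
mechanism_change_divergence <- function(dist_a, dist_b,
                                        metric = c("jsd", "kl")) {
  metric <- match.arg(metric)
  if (metric == "jsd") jsd(dist_a, dist_b) else kl_divergence(dist_a, dist_b)
}
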