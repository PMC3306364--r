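test_that("transition tables realize the two-parameter mechanism", {
  # a = 1: X repeats forever
  tr <- markov_transition(markov_spec(1, 0.3))
  expect_equal(as.vector(tr$X$p[, "0"]), c(1, 0))
  expect_equal(as.vector(tr$X$p[, "1"]), c(0, 1))
  # a = 0, c = 1: X alternates, Y copies X exactly
  tr2 <- markov_transition(markov_spec(0, 1))
  expect_equal(as.vector(tr2$X$p[, "0"]), c(0, 1))
  expect_equal(as.vector(tr2$Y$p[, "0"]), c(1, 0))
  # c = 0: Y rows uniform regardless of a
  tr3 <- markov_transition(markov_spec(0.7, 0))
  expect_equal(as.vector(tr3$Y$p), rep(0.5, 4))
})

test_that("the stationary law is the fixed point of the joint transition operator", {
  for (par in list(c(0.25, 0.5), c(0.1, 0.8), c(0.5, 0.3), c(0.9, 0.9))) {
    sp <- markov_spec(par[1], par[2])
    st <- markov_stationary(sp)
    # apply one joint transition step: pi'(x,y) = sum_{x0,y0} pi(x0,y0) A[x0,x] B[x0,y]
    m <- markov_matrices(sp)
    pi0 <- st$p
    pi1 <- array(0, dim(pi0), dimnames(pi0))
    for (x in 1:2) for (y in 1:2)
      pi1[x, y] <- sum(rowSums(pi0) * m$A[, x] * m$B[, y])
    expect_equal(as.vector(pi1), as.vector(pi0), tolerance = 1e-12,
                 info = paste(par, collapse = ","))
    # 0/1 exchange symmetry: marginals uniform, flip-invariant joint
    expect_equal(as.vector(marginal(st, "X[0]")$p), c(0.5, 0.5))
    expect_equal(as.vector(marginal(st, "Y[0]")$p), c(0.5, 0.5))
    expect_equal(st$p[1, 1], st$p[2, 2], tolerance = 1e-12)
  }
  # uniform exactly when c = 0 or a = 1/2; correlated otherwise
  expect_equal(as.vector(markov_stationary(markov_spec(0.3, 0))$p), rep(0.25, 4))
  expect_equal(as.vector(markov_stationary(markov_spec(0.5, 0.8))$p), rep(0.25, 4))
  expect_equal(as.vector(markov_stationary(markov_spec(0.25, 0.5))$p),
               c(0.1875, 0.3125, 0.3125, 0.1875), tolerance = 1e-12)
  # degenerate chains: period-2 average at a = 0 stays well-defined
  expect_equal(sum(markov_stationary(markov_spec(0, 1))$p), 1)
})

test_that("the lagged joint matches hand products and marginal symmetry", {
  sp <- markov_spec(0.25, 0.5, 5)
  d1 <- markov_lagged_joint(sp, k = 1)
  # P(Y0=0, Y-1=0, X-1=0) = P(Y-1=0, X-1=0) * P(Y0=0 | X-1=0)
  #                       = 0.1875 * 0.75 (stationary pair law, then emission)
  expect_equal(prob_of(d1, c(`Y[0]` = "0", `Y[-1]` = "0", `X[-1]` = "0")),
               0.1875 * 0.75, tolerance = 1e-12)
  # every single-variable marginal is uniform by exchange symmetry
  for (v in d1$vars)
    expect_equal(as.vector(marginal(d1, v)$p), c(0.5, 0.5), tolerance = 1e-12)
  d <- markov_lagged_joint(sp, k = 4)
  expect_equal(sum(d$p), 1, tolerance = 1e-12)
  # the (X,Y) pair law inside the window equals the stationary law
  pair <- marginal(d, c("X[-2]", "Y[-2]"))
  expect_equal(as.vector(pair$p), as.vector(markov_stationary(sp)$p),
               tolerance = 1e-12)
  # c = 0: Y_t independent of the whole past
  d0 <- markov_lagged_joint(markov_spec(0.3, 0, 3), k = 3)
  past <- setdiff(d0$vars, "Y[0]")
  expect_equal(transfer_entropy(d0, "Y[0]", character(0), past), 0,
               tolerance = 1e-12)
  expect_error(markov_lagged_joint(sp, k = 13), class = "resource_guard")
})

test_that("the two transfer-entropy routes agree exactly", {
  for (par in list(c(0.25, 0.5), c(0.1, 0.8), c(0.5, 0.2), c(0.05, 1))) {
    sp <- markov_spec(par[1], par[2])
    for (k in c(1L, 3L, 5L)) {
      d <- markov_lagged_joint(sp, k = k)
      te_table <- transfer_entropy(d, "Y[0]", node_name("Y", -(1:k)),
                                   node_name("X", -(1:k)))
      expect_equal(te_xy(sp, k), te_table, tolerance = 1e-12,
                   info = sprintf("a=%g c=%g k=%d", par[1], par[2], k))
    }
  }
})

test_that("transfer entropy detects the connection and only the connection", {
  # zero iff c = 0
  expect_equal(te_xy(markov_spec(0.25, 0, 5)), 0, tolerance = 1e-12)
  expect_gt(te_xy(markov_spec(0.25, 0.05, 5)), 1e-9)
  # i.i.d. driver with perfect copy: exactly 1 bit
  expect_equal(te_xy(markov_spec(0.5, 1, 1)), 1, tolerance = 1e-12)
  # fully deterministic extreme: zero despite maximal coupling
  expect_equal(te_xy(markov_spec(0, 1, 2)), 0, tolerance = 1e-10)
  expect_equal(te_xy(markov_spec(0, 1, 5)), 0, tolerance = 1e-10)
  # reverse direction identically zero
  for (par in list(c(0.25, 0.5), c(0.1, 0.9), c(0.5, 0)))
    expect_lte(te_yx(markov_spec(par[1], par[2], 4)), 1e-10)
})

test_that("transfer entropy is nonmonotone in the coupling for slow chains", {
  # near-deterministic driver: the coupling also drives Y towards
  # determinism, so the extra uncertainty reduction shrinks again
  sp <- function(cc) markov_spec(0.001, cc, 7)
  te <- vapply(seq(0, 1, by = 0.1), function(cc) te_xy(sp(cc)), 0)
  # rises then falls: interior maximum beats the endpoint by a clear margin
  expect_gt(max(te) - te[length(te)], 1e-6)
  expect_gt(which.max(te), 1L)
  expect_lt(which.max(te), length(te))
  # fully deterministic extreme: coupling maximal yet TE vanishes
  expect_equal(te_xy(markov_spec(0, 1, 3)), 0, tolerance = 1e-10)
})

test_that("converged_k implements the convergence rule", {
  expect_equal(converged_k(markov_spec(0.3, 0)), 1L)      # TE identically 0
  expect_equal(converged_k(markov_spec(0.5, 0.7)), 1L)    # i.i.d. driver
  expect_warning(kk <- converged_k(markov_spec(0.1, 0.8)), "not converged")
  expect_equal(kk, 10L)
  # deeper lags genuinely matter for slow chains
  expect_gt(abs(te_xy(markov_spec(0.1, 0.8), 3) - te_xy(markov_spec(0.1, 0.8), 2)),
            1e-10)
})

test_that("the natural-effect divergence is a-invariant and increasing in c", {
  a_grid <- c(0.1, 0.25, 0.4, 0.5)
  c_grid <- seq(0, 1, by = 0.1)
  curves <- sapply(a_grid, function(a)
    vapply(c_grid, function(cc) natural_effect_curve(markov_spec(a, cc, 3)), 0))
  expect_lt(max(apply(curves, 1, function(r) diff(range(r)))), 1e-12)
  expect_true(all(diff(curves[, 1]) > 0))   # strictly increasing in c
  expect_equal(curves[1, 1], 0, tolerance = 1e-12)  # c = reference
  # reference at nonzero coupling: zero exactly at c = reference_c
  expect_equal(natural_effect_curve(markov_spec(0.3, 0.4, 3), reference_c = 0.4),
               0, tolerance = 1e-12)
})

test_that("the mechanism-change divergence vanishes at a = 1/2 and grows with c at small a", {
  for (cc in seq(0, 1, by = 0.2))
    expect_lte(mechanism_change_curve(markov_spec(0.5, cc, 5)), 1e-12)
  vals <- vapply(seq(0, 1, by = 0.2), function(cc)
    mechanism_change_curve(markov_spec(0.1, cc, 5)), 0)
  expect_equal(vals[1], 0, tolerance = 1e-12)
  expect_true(all(diff(vals) > 0))
})

test_that("the simulator reproduces the transition statistics", {
  # deterministic absorbing case
  sm <- simulate_markov(markov_spec(1, 1, 1), 50, seed = 5)
  expect_equal(length(unique(sm$x)), 1L)
  expect_equal(length(unique(sm$y[-1])), 1L)
  # empirical self-repeat frequency within the binomial interval
  n <- 1e5
  sp <- markov_spec(0.25, 0.5, 3)
  sm2 <- simulate_markov(sp, n, seed = 11)
  emp_a <- mean(sm2$x[-1] == sm2$x[-n])
  expect_lt(abs(emp_a - 0.25), 3 * sqrt(0.25 * 0.75 / n))
  emp_c <- mean(sm2$y[-1] == sm2$x[-n])
  expect_lt(abs(emp_c - 0.75), 3 * sqrt(0.75 * 0.25 / n))
  # reproducibility
  sm3 <- simulate_markov(sp, 1000, seed = 11)
  expect_identical(sm3$x, sm2$x[1:1000])
  # plug-in TE approaches the analytic value
  expect_lt(abs(plugin_transfer_entropy(sm2$x, sm2$y, 3) - te_xy(sp, 3)), 0.02)
})

test_that("the sweep table is deterministic with the documented layout", {
  tmp <- tempfile(fileext = ".tsv")
  sw <- markov_sweep(c(0.3, 0.5), c(0, 0.5), k = 2L, file = tmp)
  lines <- readLines(tmp)
  expect_equal(lines[1], "a\tc\tk\tte_xy\tte_yx\tjsd_natural\tjsd_mechanism")
  expect_equal(nrow(sw), 4L)
  expect_equal(sw$a, c(0.3, 0.3, 0.5, 0.5))  # a-major order
  tmp2 <- tempfile(fileext = ".tsv")
  markov_sweep(c(0.3, 0.5), c(0, 0.5), k = 2L, file = tmp2)
  expect_identical(readLines(tmp2), lines)
  # single grid point: one data row
  one <- markov_sweep(0.4, 0.6, k = 2L)
  expect_equal(nrow(one), 1L)
})
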