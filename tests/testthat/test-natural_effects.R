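test_that("existence follows the structural criteria on the catalogue graphs", {
  # unidirectional with mediator: exists (mediation allowed)
  expect_true(natural_effect_exists(chain_model(), "X", "Y")$exists)
  # common driver: fails, witness Z
  r <- natural_effect_exists(confounded_model(), "X", "Y")
  expect_false(r$exists)
  expect_equal(r$structural_reasons[[1L]]$code, "COMMON_DRIVER")
  expect_equal(r$structural_reasons[[1L]]$witness, "Z")
  # reverse connection
  g <- causal_graph(c("Y -> X"))
  m <- rand_model(g, 3)
  r2 <- natural_effect_exists(m, "X", "Y")
  expect_false(r2$exists)
  expect_equal(r2$structural_reasons[[1L]]$code, "REVERSE_CONNECTION")
})

test_that("bidirectional coupling defeats subsystem-level existence", {
  micro <- unroll(spec_bi(4L), "micro")
  # x = X-past, y = one future Y node: the Y past confounds
  r <- natural_effect_exists(micro, c("X[1]", "X[2]"), "Y[3]")
  expect_false(r$exists)
  codes <- vapply(r$structural_reasons, `[[`, "", "code")
  expect_true("COMMON_DRIVER" %in% codes)
  # x = whole X process, y = whole Y process: reverse connection
  rs <- natural_effect_exists(micro,
                              paste0("X[", 1:4, "]"), paste0("Y[", 1:4, "]"))
  expect_false(rs$exists)
  expect_true("REVERSE_CONNECTION" %in%
                vapply(rs$structural_reasons, `[[`, "", "code"))
})

test_that("structural existence implies p(y|x) = p(y|do(x)) on random models", {
  n_true <- 0L; n_false <- 0L
  for (seed in 1:80) {
    m <- generate_fixture(2L + (seed %% 3L), seed)
    nodes <- m$graph$nodes$name
    x <- nodes[1L]; y <- nodes[2L]
    r <- natural_effect_exists(m, x, y, check_numeric = TRUE)
    if (r$exists) {
      expect_lte(r$numeric_check$max_discrepancy, 1e-9)
      n_true <- n_true + 1L
    } else n_false <- n_false + 1L
  }
  # the fixture family must exercise both outcomes
  expect_gt(n_true, 10L)
  expect_gt(n_false, 10L)
})

test_that("conditional existence follows the rule-2 criterion", {
  # confounded pair becomes admissible given {Z}
  mB <- confounded_model()
  r <- conditional_natural_effect_exists(mB, "X", "Y", "Z",
                                         check_numeric = TRUE)
  expect_true(r$exists)
  expect_lte(r$numeric_check$max_discrepancy, 1e-9)
  # bidirectional process: conditioning on the target's own past suffices
  micro <- unroll(spec_bi(4L), "micro")
  m <- rand_model(micro, 17)
  r2 <- conditional_natural_effect_exists(m, c("X[1]", "X[2]"), "Y[3]",
                                          c("Y[1]", "Y[2]"),
                                          check_numeric = TRUE)
  expect_true(r2$exists)
  expect_lte(r2$numeric_check$max_discrepancy, 1e-9)
  # reverse edge still defeats it
  g <- causal_graph(c("Y -> X", "Z -> X", "Z -> Y"))
  r3 <- conditional_natural_effect_exists(rand_model(g, 5), "X", "Y", "Z")
  expect_false(r3$exists)
  expect_true("REVERSE_CONNECTION" %in%
                vapply(r3$structural_reasons, `[[`, "", "code"))
})

test_that("conditional structural existence implies the conditional identity", {
  checked <- 0L
  for (seed in 1:40) {
    m <- generate_fixture(4L, seed)
    nodes <- m$graph$nodes$name
    for (x in nodes) for (y in setdiff(nodes, x)) {
      for (z in all_subsets(setdiff(nodes, c(x, y)))) {
        if (!length(z)) next
        r <- conditional_natural_effect_exists(m, x, y, z)
        if (!r$exists) next
        rn <- conditional_natural_effect_exists(m, x, y, z,
                                                check_numeric = TRUE)
        expect_lte(rn$numeric_check$max_discrepancy, 1e-9)
        checked <- checked + 1L
      }
    }
  }
  expect_gt(checked, 50L)
})

test_that("the natural effect equals the observed joint when it exists", {
  mC <- chain_model()
  ne <- natural_effect(mC, "X", "Y")
  expect_equal(ne$p, marginal(model_joint(mC), c("X", "Y"))$p,
               tolerance = NC_TOL)
  # independent pair: product of marginals
  g <- causal_graph(character(0), nodes = c("X", "Y"))
  m <- discrete_model(g, list(X = cpt("X", BIN, prob = c(0.3, 0.7)),
                              Y = cpt("Y", BIN, prob = c(0.6, 0.4))))
  ne2 <- natural_effect(m, "X", "Y")
  expect_equal(as.vector(ne2$p), as.vector(outer(c(0.3, 0.7), c(0.6, 0.4))),
               tolerance = NC_TOL)
  # randomized family: identity whenever defined
  for (seed in 1:30) {
    mf <- generate_fixture(3L, seed)
    nodes <- mf$graph$nodes$name
    if (!natural_effect_exists(mf, nodes[1L], nodes[2L])$exists) next
    expect_equal(natural_effect(mf, nodes[1L], nodes[2L])$p,
                 marginal(model_joint(mf), nodes[1:2])$p, tolerance = 1e-9)
  }
  # failure carries the machine-readable report
  err <- tryCatch(natural_effect(confounded_model(), "X", "Y"),
                  no_natural_effect = identity)
  expect_s3_class(err, "no_natural_effect")
  expect_equal(err$report$structural_reasons[[1L]]$witness, "Z")
})

test_that("conditional natural effects recombine to the observed joint", {
  mB <- confounded_model()
  fam <- conditional_natural_effect(mB, "X", "Y", "Z")
  jB <- model_joint(mB)
  pz <- marginal(jB, "Z")
  # sum_z p(z) * p(x, y | z) = p(x, y)
  acc <- 0
  for (zv in names(fam))
    acc <- acc + prob_of(pz, c(Z = zv)) * fam[[zv]]$p
  expect_equal(acc, marginal(jB, c("X", "Y"))$p, tolerance = 1e-10)
  # each entry reconstructs the observed conditional joint
  for (zv in names(fam))
    expect_equal(fam[[zv]]$p, conditional(jB, c("X", "Y"), c(Z = zv))$p,
                 tolerance = 1e-10)
  # z independent of everything: every entry equals the unconditional effect
  g <- causal_graph(c("X -> Y"), nodes = c("X", "Y", "Z"))
  m <- rand_model(g, 8)
  fam2 <- conditional_natural_effect(m, "X", "Y", "Z")
  ne <- natural_effect(m, "X", "Y")
  for (zv in names(fam2))
    expect_equal(fam2[[zv]]$p, ne$p, tolerance = 1e-10)
})

test_that("conditional effects exist in the bidirectional Markov process even though unconditional ones do not", {
  micro <- unroll(spec_bi(3L), "micro")
  m <- rand_model(micro, 23)
  expect_false(natural_effect_exists(m, c("X[1]", "X[2]"), "Y[3]")$exists)
  fam <- conditional_natural_effect(m, c("X[1]", "X[2]"), "Y[3]",
                                    c("Y[1]", "Y[2]"))
  expect_gt(length(fam), 0L)
  j <- model_joint(m)
  for (zv in names(fam)) {
    parts <- strsplit(zv, ",")[[1L]]
    given <- setNames(parts, c("Y[1]", "Y[2]"))
    expect_equal(fam[[zv]]$p,
                 conditional(j, c("X[1]", "X[2]", "Y[3]"), given)$p,
                 tolerance = 1e-9)
  }
})

test_that("macro existence reduces to cross-edge directionality", {
  r <- macro_effect_exists(spec_uni(4L))
  expect_true(r$exists)
  expect_equal(attr(r, "direction"), c("X", "Y"))
  expect_false(macro_effect_exists(spec_bi(4L))$exists)
  none <- ts_spec(c("X", "Y"),
                  data.frame(from = c("X", "Y"), lag = 1L, to = c("X", "Y")),
                  horizon = 3L)
  expect_true(macro_effect_exists(none)$exists)
  tri <- ts_spec(c("X", "Y", "Z"),
                 data.frame(from = "X", lag = 1L, to = "Y"), horizon = 3L)
  expect_error(macro_effect_exists(tri), class = "unsupported_multivariate")
})

test_that("macro existence is consistent with the micro structural check across horizons", {
  for (h in 2:10) {
    for (make in list(spec_uni, spec_bi)) {
      sp <- make(h)
      micro <- unroll(sp, "micro")
      xs <- micro$nodes$name[micro$nodes$subsystem == "X"]
      ys <- micro$nodes$name[micro$nodes$subsystem == "Y"]
      micro_fwd <- natural_effect_exists(micro, xs, ys)$exists
      micro_rev <- natural_effect_exists(micro, ys, xs)$exists
      expect_equal(macro_effect_exists(sp)$exists, micro_fwd || micro_rev,
                   info = sprintf("horizon %d", h))
    }
  }
})
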