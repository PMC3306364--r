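# Exact probability machinery for finite-valued functional models.  Every
# distribution is an explicit table; nothing is sampled or approximated.
# All probability comparisons use the single package tolerance below.

#' Numerical tolerance used for probability identities
#'
#' Double-precision arithmetic throughout; exact identities (normalization,
#' adjustment, truncated factorization) are asserted to this tolerance.
#' @export
NC_TOL <- 1e-12

#' Explicit joint distribution over named finite-valued variables
#'
#' The carrier of every `p(.)`, `p(.|.)` and `p(.|do(.))` object.  The
#' probability table is a dense array with one dimension per variable,
#' covering the full Cartesian product of the supports.
#'
#' @param vars ordered character vector of variable names.
#' @param support named list (one entry per variable) of character vectors
#'   of values; a single unnamed vector is recycled for all variables.
#' @param p numeric array (or vector in column-major order, first variable
#'   fastest) of probabilities; must be nonnegative and sum to one.
#' @return an object of class `cdist`.
#' @examples
#' d <- cdist(c("X", "Y"), list(X = c("0", "1"), Y = c("0", "1")),
#'            c(0.4, 0.1, 0.1, 0.4))
#' marginal(d, "X")
#' @export
cdist <- function(vars, support, p) {
  stopifnot(is.character(vars), length(vars) >= 1L, !anyDuplicated(vars))
  if (!is.list(support)) support <- setNames(rep(list(as.character(support)),
                                                 length(vars)), vars)
  support <- lapply(support[vars], as.character)
  sizes <- lengths(support)
  if (length(p) != prod(sizes))
    stop("probability table does not cover the Cartesian product of supports")
  if (any(p < -NC_TOL)) stop("negative probability in table")
  p <- pmax(p, 0)
  if (abs(sum(p) - 1) > 1e-9)
    stop("probabilities must sum to 1 (got ", format(sum(p)), ")")
  arr <- array(as.numeric(p), dim = sizes, dimnames = support)
  structure(list(vars = vars, support = support, p = arr), class = "cdist")
}

#' @export
print.cdist <- function(x, ...) {
  cat(sprintf("<cdist> over {%s} (%d outcomes)\n",
              paste(x$vars, collapse = ", "), length(x$p)))
  if (length(x$p) <= 16L) {
    g <- assignment_grid(x)
    g$prob <- as.vector(x$p)
    print(g, row.names = FALSE)
  }
  invisible(x)
}

# full outcome grid in table order (first variable fastest)
assignment_grid <- function(d) {
  expand.grid(d$support, KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
}

#' Marginal of a categorical distribution
#'
#' @param dist a `cdist`.
#' @param keep variables to keep (order of the original distribution is
#'   preserved).
#' @return a `cdist` over `keep`.
#' @export
marginal <- function(dist, keep) {
  stopifnot(inherits(dist, "cdist"))
  if (length(keep) == 0L) stop("keep must name at least one variable")
  unknown <- setdiff(keep, dist$vars)
  if (length(unknown)) stop("unknown variable: ", unknown[1L])
  keep <- dist$vars[dist$vars %in% keep]
  if (identical(keep, dist$vars)) return(dist)
  m <- apply(dist$p, match(keep, dist$vars), sum)
  cdist(keep, dist$support[keep], m)
}

#' Exact conditional distribution
#'
#' Conditions `dist` on the assignment `given` and marginalizes the result
#' onto `target`.  Conditioning on an event of probability zero is an
#' error of class `zero_probability_condition` — the existence criteria
#' must distinguish "undefined" from "unequal".
#'
#' @param dist a `cdist`.
#' @param target variables of the returned distribution.
#' @param given named character vector of conditioning values.
#' @return a `cdist` over `target`.
#' @export
conditional <- function(dist, target, given) {
  stopifnot(inherits(dist, "cdist"))
  gv <- names(given)
  unknown <- setdiff(c(target, gv), dist$vars)
  if (length(unknown)) stop("unknown variable: ", unknown[1L])
  if (length(intersect(target, gv)))
    stop("target and conditioning variables must be disjoint")
  idx <- lapply(dist$vars, function(v) {
    if (v %in% gv) {
      val <- as.character(given[[v]])
      if (!val %in% dist$support[[v]])
        stop(sprintf("value '%s' outside the support of %s", val, v))
      val
    } else TRUE
  })
  sub <- do.call(`[`, c(list(dist$p), idx, list(drop = FALSE)))
  mass <- sum(sub)
  if (mass <= NC_TOL)
    stop(structure(class = c("zero_probability_condition", "error", "condition"),
                   list(message = "conditioning event has probability zero",
                        call = sys.call(-1))))
  rest <- setdiff(dist$vars, gv)
  keep <- rest[rest %in% target]
  m <- apply(sub, match(keep, dist$vars), sum) / mass
  cdist(keep, dist$support[keep], m)
}

# probability of a full or partial assignment
prob_of <- function(dist, assign) {
  m <- marginal(dist, names(assign))
  idx <- vapply(m$vars, function(v) match(as.character(assign[[v]]),
                                          m$support[[v]]), 0L)
  unname(m$p[matrix(idx, nrow = 1L)])
}

#' Total-variation distance between two distributions on the same support
#' @param p,q `cdist` objects over the same variables and supports.
#' @return numeric in `[0, 1]`.
#' @export
total_variation <- function(p, q) {
  stopifnot(identical(p$vars, q$vars), identical(p$support, q$support))
  sum(abs(as.vector(p$p) - as.vector(q$p))) / 2
}

# ---------------------------------------------------------------------------
# Conditional probability tables and functional models

#' Conditional probability table
#'
#' One factor of the joint factorized according to the causal structure:
#' a distribution over the child for every assignment of its parents.  The
#' random disturbance terms of a functional model are absorbed into the
#' stochastic rows.
#'
#' @param child child variable name.
#' @param support character vector of child values.
#' @param parents character vector of parent names (may be empty).
#' @param parent_supports named list of parent supports.
#' @param prob with no parents, a probability vector over `support`; with
#'   parents, a matrix with one row per parent assignment (rows ordered as
#'   `expand.grid(parent_supports)`, first parent fastest) and one column
#'   per child value.
#' @return an object of class `cpt`.
#' @export
cpt <- function(child, support, parents = character(0),
                parent_supports = list(), prob) {
  support <- as.character(support)
  stopifnot(length(support) >= 1L, !anyDuplicated(support))
  parent_supports <- lapply(parent_supports[parents], as.character)
  psizes <- lengths(parent_supports)
  if (length(parents) == 0L) {
    prob <- matrix(as.numeric(prob), nrow = 1L)
  } else {
    stopifnot(length(parents) == length(parent_supports))
    prob <- as.matrix(prob)
    if (nrow(prob) != prod(psizes) || ncol(prob) != length(support))
      stop("prob must have one row per parent assignment and one column per child value")
  }
  if (any(prob < -NC_TOL)) stop("negative probability in CPT")
  prob <- pmax(prob, 0)
  if (any(abs(rowSums(prob) - 1) > 1e-9))
    stop("every CPT row must sum to 1")
  arr <- array(t(prob), dim = c(length(support), psizes),
               dimnames = c(list(support), parent_supports))
  structure(list(child = child, support = support, parents = parents,
                 parent_supports = parent_supports, p = arr),
            class = "cpt")
}

#' @export
print.cpt <- function(x, ...) {
  cat(sprintf("<cpt> %s | {%s}\n", x$child,
              paste(x$parents, collapse = ", ")))
  invisible(x)
}

point_mass_cpt <- function(child, support, value) {
  support <- as.character(support)
  if (!value %in% support)
    stop(sprintf("value '%s' outside the support of %s", value, child))
  cpt(child, support, prob = as.numeric(support == value))
}

#' Discrete functional model
#'
#' An acyclic causal graph plus one conditional probability table per
#' node; the factorized joint distribution of the system.
#'
#' @param graph an acyclic `cgraph`.
#' @param cpts named list of `cpt` objects, one per graph node; each CPT's
#'   parent set must equal the node's graph parents.
#' @return an object of class `dfm`.
#' @examples
#' g <- causal_graph(c("X -> Z", "Z -> Y"))
#' m <- discrete_model(g, list(
#'   X = cpt("X", c("0", "1"), prob = c(0.5, 0.5)),
#'   Z = cpt("Z", c("0", "1"), "X", list(X = c("0", "1")),
#'           rbind(c(0.9, 0.1), c(0.1, 0.9))),
#'   Y = cpt("Y", c("0", "1"), "Z", list(Z = c("0", "1")),
#'           rbind(c(0.8, 0.2), c(0.2, 0.8)))))
#' marginal(model_joint(m), "Y")
#' @export
discrete_model <- function(graph, cpts) {
  stopifnot(inherits(graph, "cgraph"))
  if (!is_acyclic(graph)) stop("functional models require an acyclic graph")
  nm <- graph$nodes$name
  if (!setequal(names(cpts), nm))
    stop("cpts must name exactly the graph nodes")
  cpts <- cpts[nm]
  for (v in nm) {
    ct <- cpts[[v]]
    if (!inherits(ct, "cpt") || ct$child != v)
      stop("cpts[['", v, "']] must be a cpt for ", v)
    if (!setequal(ct$parents, parents(graph, v)))
      stop("CPT parents of ", v, " do not match graph parents")
  }
  # parent supports must agree with the parents' own declared supports
  for (v in nm) for (pa in cpts[[v]]$parents) {
    if (!identical(cpts[[v]]$parent_supports[[pa]], cpts[[pa]]$support))
      stop(structure(class = c("invalid_model", "error", "condition"),
                     list(message = sprintf(
                       "support of %s in CPT of %s disagrees with %s's own support",
                       pa, v, pa), call = sys.call(-1))))
  }
  structure(list(graph = graph, cpts = cpts), class = "dfm")
}

#' @export
print.dfm <- function(x, ...) {
  cat(sprintf("<dfm> %d variables: %s\n", nrow(x$graph$nodes),
              paste(x$graph$nodes$name, collapse = ", ")))
  invisible(x)
}

model_support <- function(model) {
  setNames(lapply(model$cpts, `[[`, "support"), names(model$cpts))
}

#' Exact joint distribution of a functional model
#'
#' `p(v1, ..., vn) = prod_i p(vi | parents(vi))`, evaluated as an exact
#' product over the full outcome grid — no sampling.
#'
#' @param model a `dfm`.
#' @return a `cdist` over all model variables.
#' @export
model_joint <- function(model) {
  stopifnot(inherits(model, "dfm"))
  vars <- model$graph$nodes$name
  supp <- model_support(model)
  grid <- expand.grid(supp, KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  p <- rep(1, nrow(grid))
  for (v in vars) {
    ct <- model$cpts[[v]]
    cols <- c(v, ct$parents)
    idx <- mapply(function(col, sup) match(grid[[col]], sup),
                  cols, c(list(ct$support), ct$parent_supports))
    p <- p * ct$p[as.matrix(idx)]
  }
  cdist(vars, supp, p)
}

#' Intervene on a functional model (the do-operator)
#'
#' Truncated factorization: each intervened variable becomes a parentless
#' node with a point mass at its do-value; all its incoming edges are
#' removed; every other CPT is untouched.  The joint of the returned model
#' is the postinterventional distribution.  Idempotent for the same
#' assignment, and the result composes with every other operation
#' unchanged.
#'
#' @param model a `dfm`.
#' @param do named character vector, e.g. `c(X = "1")`.
#' @return the intervened `dfm`.
#' @export
intervene <- function(model, do) {
  stopifnot(inherits(model, "dfm"), length(do) >= 1L)
  vars <- names(do)
  unknown <- setdiff(vars, model$graph$nodes$name)
  if (length(unknown)) stop("unknown variable: ", unknown[1L])
  g <- model$graph
  e <- g$edges[!(g$edges$to %in% vars), , drop = FALSE]
  g2 <- structure(list(nodes = g$nodes, edges = e, scale = g$scale),
                  class = "cgraph")
  cpts <- model$cpts
  for (v in vars)
    cpts[[v]] <- point_mass_cpt(v, cpts[[v]]$support, as.character(do[[v]]))
  discrete_model(g2, cpts)
}

#' Causal effect of interventions on a variable
#'
#' The map from each value `x` of `x_name` to the postinterventional
#' distribution `p(Y | do(x))`, computed by truncated factorization
#' (intervene, joint, marginalize).  `y_names` may be multivariate.
#'
#' @param model a `dfm`.
#' @param x_name intervened variable.
#' @param y_names target variables (not containing `x_name`).
#' @return named list: one `cdist` over `y_names` per value of `x_name`.
#' @export
causal_effect <- function(model, x_name, y_names) {
  stopifnot(inherits(model, "dfm"), length(x_name) == 1L)
  if (x_name %in% y_names) stop("x_name must not be in y_names")
  vals <- model$cpts[[x_name]]$support
  setNames(lapply(vals, function(v) {
    marginal(model_joint(intervene(model, setNames(v, x_name))), y_names)
  }), vals)
}

#' Causal effect by back-door adjustment
#'
#' Computes `p(y | do(x))` from the observational joint as
#' `sum_z p(y | x, z) p(z)`.  Valid only when `z_names` satisfies the
#' back-door criterion relative to `(x_name, y_names)`; a violating
#' adjustment set raises an error of class `invalid_adjustment_set`
#' rather than silently computing a biased quantity.  When the
#' precondition holds the result equals [causal_effect()] exactly.
#'
#' @inheritParams causal_effect
#' @param z_names adjustment set (may be empty).
#' @return named list: one `cdist` over `y_names` per value of `x_name`.
#' @export
adjusted_effect <- function(model, x_name, y_names, z_names = character(0)) {
  stopifnot(inherits(model, "dfm"))
  if (!back_door_satisfied(model$graph, x_name, y_names, z_names))
    stop(structure(class = c("invalid_adjustment_set", "error", "condition"),
                   list(message = sprintf(
                     "{%s} does not satisfy the back-door criterion for (%s; %s)",
                     paste(z_names, collapse = ", "), x_name,
                     paste(y_names, collapse = ", ")),
                     call = sys.call(-1))))
  joint <- model_joint(model)
  supp <- model_support(model)
  x_vals <- supp[[x_name]]
  y_supp <- supp[y_names]
  y_grid <- expand.grid(y_supp, KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  if (length(z_names) == 0L) {
    return(setNames(lapply(x_vals, function(xv)
      conditional(joint, y_names, setNames(xv, x_name))), x_vals))
  }
  z_grid <- expand.grid(supp[z_names], KEEP.OUT.ATTRS = FALSE,
                        stringsAsFactors = FALSE)
  pz <- marginal(joint, z_names)
  setNames(lapply(x_vals, function(xv) {
    acc <- rep(0, nrow(y_grid))
    for (i in seq_len(nrow(z_grid))) {
      zv <- setNames(as.character(unlist(z_grid[i, , drop = FALSE])), z_names)
      w <- prob_of(pz, zv)
      if (w <= NC_TOL) next
      cy <- conditional(joint, y_names, c(setNames(xv, x_name), zv))
      acc <- acc + w * as.vector(cy$p)
    }
    cdist(y_names, y_supp, acc / sum(acc))
  }), x_vals)
}

#' Mean-shift causal effect
#'
#' `E[Y | do(x)] - E[Y]` for a numeric-valued target: the expected value
#' of the postinterventional distribution minus the observed mean.
#'
#' @param model a `dfm`.
#' @param x_name intervened variable; `do_value` its forced value.
#' @param do_value character or numeric value within the support.
#' @param y_name numeric-supported target variable.
#' @return numeric scalar.
#' @export
mean_shift_effect <- function(model, x_name, do_value, y_name) {
  stopifnot(inherits(model, "dfm"))
  supp <- suppressWarnings(as.numeric(model$cpts[[y_name]]$support))
  if (anyNA(supp)) stop("support of ", y_name, " is not numeric")
  post <- marginal(model_joint(intervene(model, setNames(as.character(do_value),
                                                         x_name))), y_name)
  obs <- marginal(model_joint(model), y_name)
  sum(supp * as.vector(post$p)) - sum(supp * as.vector(obs$p))
}
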