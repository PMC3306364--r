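# Existence and construction of (conditional) natural causal effects.
#
# The observed conditional dependence of y on x can be read as a
# cause-and-effect relation only when conditioning coincides with
# intervening, p(y|x) = p(y|do(x)).  That identity is decided by the
# causal structure alone: it holds when no causal connection runs from y
# back to x and no common driver of x and y exists (mediating variables
# between x and y are allowed).  The structural criteria are
# authoritative; the optional numeric check is a diagnostic, because a
# measure-zero coincidence of the parameters can satisfy the identity
# numerically without licensing the interpretation.

new_existence_report <- function(exists, reasons = list(), numeric_check = NULL) {
  structure(list(exists = exists, structural_reasons = reasons,
                 numeric_check = numeric_check),
            class = "existence_report")
}

#' @export
print.existence_report <- function(x, ...) {
  cat(sprintf("<existence_report> exists: %s\n", x$exists))
  for (r in x$structural_reasons)
    cat(sprintf("  reason %s, witness {%s}\n", r$code,
                paste(r$witness, collapse = ", ")))
  if (!is.null(x$numeric_check))
    cat(sprintf("  max TV(p(y|x), p(y|do(x))) = %.3g\n",
                x$numeric_check$max_discrepancy))
  invisible(x)
}

# enumerate positive-probability assignments of `vars` under `dist`
positive_assignments <- function(dist, vars) {
  m <- marginal(dist, vars)
  g <- assignment_grid(m)
  g$prob <- as.vector(m$p)
  g[g$prob > NC_TOL, , drop = FALSE]
}

numeric_existence_check <- function(model, x, y, z = character(0)) {
  joint <- model_joint(model)
  cond_vars <- c(x, z)
  pos <- positive_assignments(joint, cond_vars)
  per_value <- numeric(0)
  for (i in seq_len(nrow(pos))) {
    av <- setNames(as.character(unlist(pos[i, cond_vars, drop = FALSE])),
                   cond_vars)
    obs <- conditional(joint, y, av)
    post_model <- intervene(model, av[x])
    post_joint <- model_joint(post_model)
    post <- if (length(z)) {
      conditional(post_joint, y, av[z])
    } else marginal(post_joint, y)
    per_value[paste(av, collapse = ",")] <- total_variation(obs, post)
  }
  list(max_discrepancy = if (length(per_value)) max(per_value) else 0,
       per_value = as.list(per_value))
}

#' Does a natural causal effect of x on y exist?
#'
#' Structural criterion: no directed path from `y` back to `x` and no
#' common driver of `x` and `y`.  When both hold, conditioning on `x`
#' coincides with intervening on `x`, so the observed conditional
#' distributions are postinterventional distributions of naturally
#' occurring interventions.  Mediating variables between `x` and `y` do
#' not block existence.
#'
#' @param model a `dfm` (or, structurally, just its graph wrapped in a
#'   model).
#' @param x,y disjoint sets of variable names.
#' @param check_numeric if `TRUE`, additionally compare `p(y|x = v)` with
#'   `p(y|do(x = v))` for every positive-probability `v` and report the
#'   maximum total-variation discrepancy.
#' @return an `existence_report` with fields `exists`,
#'   `structural_reasons` (codes `REVERSE_CONNECTION`, `COMMON_DRIVER`
#'   with witnesses) and optional `numeric_check`.
#' @export
natural_effect_exists <- function(model, x, y, check_numeric = FALSE) {
  graph <- if (inherits(model, "dfm")) model$graph else model
  stopifnot(inherits(graph, "cgraph"))
  check_nodes(graph, c(x, y))
  if (length(intersect(x, y))) stop("x and y must be disjoint")
  reasons <- list()
  if (has_causal_connection(graph, y, x)) {
    wit <- intersect(y, ancestors(graph, x))
    reasons <- c(reasons, list(list(code = "REVERSE_CONNECTION", witness = wit)))
  }
  cd <- common_drivers(graph, x, y)
  if (length(cd))
    reasons <- c(reasons, list(list(code = "COMMON_DRIVER", witness = cd)))
  nc <- NULL
  if (check_numeric && inherits(model, "dfm"))
    nc <- numeric_existence_check(model, x, y)
  new_existence_report(length(reasons) == 0L, reasons, nc)
}

#' Does a conditional natural causal effect of x on y given z exist?
#'
#' Structural criterion: no directed path from `y` back to `x`, and `z`
#' blocks every back-door path between `x` and `y` — conditioning on `z`
#' blocks the influence of every possible common driver.  Formally the
#' second condition is d-separation of `x` and `y` given `z` in the graph
#' with the edges leaving `x` removed (the observation/action exchange
#' rule of the do-calculus).  Note that this is weaker than the textbook
#' back-door criterion used by [adjusted_effect()]: `z` may contain
#' descendants of `x`, in particular mediators — both sides of the
#' defining identity `p(y|x,z) = p(y|do(x),z)` condition on `z`, so
#' blocking a mediated path harms nothing.  That is exactly what licenses
#' conditioning a bidirectional process on the target's own past.
#'
#' @inheritParams natural_effect_exists
#' @param z conditioning set, disjoint from `x` and `y`.
#' @return an `existence_report`; structural reason codes are
#'   `REVERSE_CONNECTION` and `BACKDOOR_VIOLATION`.
#' @export
conditional_natural_effect_exists <- function(model, x, y, z,
                                              check_numeric = FALSE) {
  graph <- if (inherits(model, "dfm")) model$graph else model
  stopifnot(inherits(graph, "cgraph"))
  check_nodes(graph, c(x, y, z))
  sets <- list(x = x, y = y, z = z)
  for (i in 1:2) for (j in (i + 1):3)
    if (length(intersect(sets[[i]], sets[[j]])))
      stop("x, y, z must be pairwise disjoint")
  reasons <- list()
  if (has_causal_connection(graph, y, x)) {
    wit <- intersect(y, ancestors(graph, x))
    reasons <- c(reasons, list(list(code = "REVERSE_CONNECTION", witness = wit)))
  }
  if (!backdoor_paths_blocked(graph, x, y, z))
    reasons <- c(reasons, list(list(code = "BACKDOOR_VIOLATION", witness = z)))
  nc <- NULL
  if (check_numeric && inherits(model, "dfm"))
    nc <- numeric_existence_check(model, x, y, z)
  new_existence_report(length(reasons) == 0L, reasons, nc)
}

no_natural_effect_error <- function(report) {
  cond <- structure(class = c("no_natural_effect", "error", "condition"),
                    list(message = paste0(
                      "no natural causal effect exists (",
                      paste(vapply(report$structural_reasons, function(r)
                        sprintf("%s: {%s}", r$code,
                                paste(r$witness, collapse = ", ")), ""),
                        collapse = "; "), ")"),
                      call = sys.call(-1)))
  cond$report <- report
  stop(cond)
}

#' The natural causal effect of x on y
#'
#' When the existence criterion holds, the natural causal effect is the
#' joint `p(x, y) = p(x) * p(y|do(x))` with the distribution of
#' interventions taken equal to the observed marginal of `x` (maintenance
#' of the natural joint distribution).  By construction it equals the
#' observed joint over `x` and `y`.
#'
#' @param model a `dfm`.
#' @param x,y disjoint sets of variable names.
#' @return a `cdist` over `c(x, y)`.  If existence fails, an error of
#'   class `no_natural_effect` is raised carrying the `existence_report`
#'   in its `report` field.
#' @export
natural_effect <- function(model, x, y) {
  stopifnot(inherits(model, "dfm"))
  er <- natural_effect_exists(model, x, y)
  if (!er$exists) no_natural_effect_error(er)
  joint <- model_joint(model)
  vars <- model$graph$nodes$name
  out_vars <- vars[vars %in% c(x, y)]
  supp <- model_support(model)[out_vars]
  grid <- expand.grid(supp, KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  px <- marginal(joint, x)
  p <- numeric(nrow(grid))
  pos <- positive_assignments(joint, x)
  for (i in seq_len(nrow(pos))) {
    xv <- setNames(as.character(unlist(pos[i, x, drop = FALSE])), x)
    post <- marginal(model_joint(intervene(model, xv)), y)
    sel <- rep(TRUE, nrow(grid))
    for (v in x) sel <- sel & grid[[v]] == xv[[v]]
    yi <- vapply(seq_len(nrow(grid)), function(r) {
      if (!sel[r]) return(NA_real_)
      idx <- vapply(post$vars, function(v)
        match(grid[[v]][r], post$support[[v]]), 0L)
      post$p[matrix(idx, nrow = 1L)]
    }, 0)
    p[sel] <- pos$prob[i] * yi[sel]
  }
  cdist(out_vars, supp, p / sum(p) * 1)
}

#' Conditional natural causal effects of x on y given z
#'
#' For each positive-probability value of `z`, the joint
#' `p(x, y | z) = p(x|z) * p(y|do(x), z)`; the returned family
#' reconstructs the observed `p(x, y | z)`.  Zero-probability `z` values
#' are omitted from the map.
#'
#' @inheritParams natural_effect
#' @param z conditioning set.
#' @return named list: for each `z` assignment (values comma-joined in
#'   `z` order) a `cdist` over `c(x, y)`, with the assignment's
#'   probability in attribute `"weight"`.
#' @export
conditional_natural_effect <- function(model, x, y, z) {
  stopifnot(inherits(model, "dfm"))
  er <- conditional_natural_effect_exists(model, x, y, z)
  if (!er$exists) no_natural_effect_error(er)
  joint <- model_joint(model)
  vars <- model$graph$nodes$name
  out_vars <- vars[vars %in% c(x, y)]
  supp <- model_support(model)[out_vars]
  grid <- expand.grid(supp, KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  pos_z <- positive_assignments(joint, z)
  out <- list()
  for (i in seq_len(nrow(pos_z))) {
    zv <- setNames(as.character(unlist(pos_z[i, z, drop = FALSE])), z)
    px_z <- conditional(joint, x, zv)
    p <- numeric(nrow(grid))
    pos_x <- positive_assignments(conditional(joint, x, zv), x)
    for (j in seq_len(nrow(pos_x))) {
      xv <- setNames(as.character(unlist(pos_x[j, x, drop = FALSE])), x)
      post <- conditional(model_joint(intervene(model, xv)), y, zv)
      sel <- rep(TRUE, nrow(grid))
      for (v in x) sel <- sel & grid[[v]] == xv[[v]]
      w <- pos_x$prob[j]
      for (r in which(sel)) {
        idx <- vapply(post$vars, function(v)
          match(grid[[v]][r], post$support[[v]]), 0L)
        p[r] <- w * post$p[matrix(idx, nrow = 1L)]
      }
    }
    d <- cdist(out_vars, supp, p / sum(p))
    attr(d, "weight") <- pos_z$prob[i]
    out[[paste(zv, collapse = ",")]] <- d
  }
  out
}

#' Existence of a subsystem-level (macroscopic) natural causal effect
#'
#' For a bivariate time-series specification, the total influence of one
#' subsystem's dynamics on the other exists as a natural causal effect iff
#' all cross-subsystem lag edges run in one direction only.  The decision
#' is evaluated on the micro unrolling (x = all nodes of the driving
#' subsystem, y = all nodes of the other), so it is consistent across
#' scales.  Bidirectional coupling defeats both orientations: each
#' subsystem's past is then both a driver and a consequence of the other.
#'
#' @param spec a `tsspec` with exactly two subsystems.
#' @return an `existence_report`; when the effect exists, attribute
#'   `"direction"` carries `c(from, to)`.
#' @export
macro_effect_exists <- function(spec) {
  stopifnot(inherits(spec, "tsspec"))
  if (length(spec$subsystems) != 2L)
    stop(structure(class = c("unsupported_multivariate", "error", "condition"),
                   list(message = "existence analysis is implemented for two subsystems",
                        call = sys.call(-1))))
  s <- spec$subsystems
  micro <- unroll(spec, "micro")
  nodes_of <- function(sub) {
    micro$nodes$name[micro$nodes$subsystem == sub]
  }
  try_dir <- function(from, to) {
    natural_effect_exists(micro, nodes_of(from), nodes_of(to))
  }
  r12 <- try_dir(s[1L], s[2L])
  if (r12$exists) {
    attr(r12, "direction") <- c(s[1L], s[2L])
    return(r12)
  }
  r21 <- try_dir(s[2L], s[1L])
  if (r21$exists) {
    attr(r21, "direction") <- c(s[2L], s[1L])
    return(r21)
  }
  r12
}
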