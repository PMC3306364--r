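#' @importFrom stats setNames rgamma runif rnorm
#' @importFrom utils write.table head
NULL

# Node-name convention: a static (macroscopic) variable is named by its
# subsystem label alone ("X"); a time-indexed variable is "X[3]".  Meso
# aggregate past nodes use the pseudo time index "past", i.e. "X[past]".

#' Canonical node name for a (subsystem, time) pair
#'
#' @param subsystem character label of the subsystem, e.g. `"X"`.
#' @param t integer time index, or `NA` for a static node.
#' @return character name, `"X"` or `"X[3]"`.
#' @export
node_name <- function(subsystem, t = NA) {
  n <- max(length(subsystem), length(t))
  subsystem <- rep_len(subsystem, n)
  t <- rep_len(t, n)
  ifelse(is.na(t), subsystem, sprintf("%s[%s]", subsystem, t))
}

parse_node_name <- function(name) {
  m <- regmatches(name, regexec("^(.*)\\[([^]]+)\\]$", name))
  sub_t <- vapply(seq_along(name), function(i) {
    if (length(m[[i]]) == 3L) c(m[[i]][2L], m[[i]][3L]) else c(name[i], NA_character_)
  }, character(2))
  data.frame(name = name, subsystem = sub_t[1L, ], t = sub_t[2L, ],
             stringsAsFactors = FALSE)
}

parse_edges <- function(edges) {
  if (is.character(edges)) {
    parts <- strsplit(edges, "->", fixed = TRUE)
    bad <- lengths(parts) != 2L
    if (any(bad)) stop("edge strings must have the form 'A -> B'")
    edges <- data.frame(from = trimws(vapply(parts, `[`, "", 1L)),
                        to   = trimws(vapply(parts, `[`, "", 2L)),
                        stringsAsFactors = FALSE)
  }
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (nrow(edges) > 0L) names(edges)[1:2] <- c("from", "to")
  else edges <- data.frame(from = character(0), to = character(0))
  edges <- edges[, c("from", "to"), drop = FALSE]
  if (any(!nzchar(edges$from)) || any(!nzchar(edges$to)))
    stop("edge strings must have the form 'A -> B'")
  edges
}

#' Construct a causal graph
#'
#' A directed graph over (possibly time-indexed) variables.  Nodes named
#' `"X"` are static; nodes named `"X[3]"` belong to subsystem `X` at time 3.
#' At the microscopic scale the graph must be acyclic and every edge must go
#' strictly forward in time (no instantaneous causality); mesoscopic and
#' macroscopic graphs may contain cycles, as happens when a bidirectionally
#' coupled microscopic process is collapsed to one node per subsystem.
#'
#' @param edges either a two-column data frame (`from`, `to`) of node names
#'   or a character vector of `"A -> B"` strings.
#' @param nodes optional character vector of node names; defaults to the
#'   nodes mentioned in `edges`.  Use it to declare isolated nodes.
#' @param scale one of `"micro"`, `"meso"`, `"macro"`.
#' @return an object of class `cgraph`.
#' @examples
#' g <- causal_graph(c("Z -> X", "Z -> Y", "X -> Y"))
#' parents(g, "Y")
#' @export
causal_graph <- function(edges = character(0), nodes = NULL, scale = "macro") {
  scale <- match.arg(scale, c("micro", "meso", "macro"))
  edges <- parse_edges(edges)
  nodes <- unique(c(nodes, edges$from, edges$to))
  if (length(nodes) == 0L) stop("graph must contain at least one node")
  info <- parse_node_name(nodes)
  if (anyDuplicated(info[, c("subsystem", "t")]))
    stop("duplicate (subsystem, time) pair among nodes")
  missing <- setdiff(c(edges$from, edges$to), nodes)
  if (length(missing)) stop("edge endpoint not among nodes: ", missing[1L])
  if (any(edges$from == edges$to)) stop("self-loops are not allowed")
  edges <- unique(edges)
  g <- structure(list(nodes = info, edges = edges, scale = scale),
                 class = "cgraph")
  if (scale == "micro") {
    tt <- suppressWarnings(as.integer(info$t))
    if (anyNA(tt)) stop("micro-scale graphs require every node to carry an integer time index")
    tf <- tt[match(edges$from, info$name)]
    tv <- tt[match(edges$to, info$name)]
    if (nrow(edges) > 0L && any(tf >= tv))
      stop("micro-scale edges must go from a strictly earlier to a later time (no instantaneous causality)")
    if (!is_acyclic(g)) stop("micro-scale graph must be acyclic")
  }
  g
}

#' @export
print.cgraph <- function(x, ...) {
  cat(sprintf("<cgraph> %s scale, %d nodes, %d edges\n",
              x$scale, nrow(x$nodes), nrow(x$edges)))
  if (nrow(x$edges)) {
    shown <- head(x$edges, 12L)
    cat(paste0("  ", shown$from, " -> ", shown$to, collapse = "\n"), "\n")
    if (nrow(x$edges) > 12L) cat("  ...\n")
  }
  invisible(x)
}

as_igraph <- function(g) {
  igraph::graph_from_data_frame(g$edges, directed = TRUE,
                                vertices = g$nodes$name)
}

is_acyclic <- function(g) {
  igraph::is_dag(as_igraph(g))
}

check_nodes <- function(g, v, arg = "variable") {
  unknown <- setdiff(v, g$nodes$name)
  if (length(unknown))
    stop(sprintf("unknown %s: %s", arg, paste(unknown, collapse = ", ")))
  invisible(v)
}

#' Parents of a variable
#'
#' @param graph a `cgraph`.
#' @param v a node name.
#' @return character vector of parent node names (sources of edges into `v`).
#' @export
parents <- function(graph, v) {
  stopifnot(inherits(graph, "cgraph"), length(v) == 1L)
  check_nodes(graph, v)
  sort(unique(graph$edges$from[graph$edges$to == v]))
}

descendants <- function(graph, v) {
  ig <- as_igraph(graph)
  out <- unique(unlist(lapply(v, function(s) {
    names(igraph::subcomponent(ig, s, mode = "out"))
  })))
  setdiff(out, v)
}

ancestors <- function(graph, v) {
  ig <- as_igraph(graph)
  out <- unique(unlist(lapply(v, function(s) {
    names(igraph::subcomponent(ig, s, mode = "in"))
  })))
  union(out, v)
}

#' Is there a causal connection from one set of variables to another?
#'
#' True iff a directed path (direction respected, direct edges count)
#' leads from some member of `src` to some member of `dst`.
#'
#' @param graph a `cgraph`.
#' @param src,dst non-empty, disjoint sets of node names.
#' @return logical scalar.
#' @export
has_causal_connection <- function(graph, src, dst) {
  stopifnot(inherits(graph, "cgraph"), length(src) > 0L, length(dst) > 0L)
  check_nodes(graph, c(src, dst))
  if (length(intersect(src, dst)))
    stop("src and dst must be disjoint")
  length(intersect(descendants(graph, src), dst)) > 0L
}

#' Common drivers (confounders) of two sets of variables
#'
#' A variable `w` outside `x` and `y` is a common driver when it has a
#' directed path to some member of `x` and a directed path to some member
#' of `y` that does not pass through `x`.  Influence on `y` mediated
#' entirely by the intervened set `x` is not confounding: intervening on
#' `x` cuts it.
#'
#' @param graph a `cgraph`.
#' @param x,y disjoint sets of node names.
#' @return character vector of common-driver node names (possibly empty).
#' @export
common_drivers <- function(graph, x, y) {
  stopifnot(inherits(graph, "cgraph"))
  check_nodes(graph, c(x, y))
  if (length(intersect(x, y))) stop("x and y must be disjoint")
  cand <- setdiff(graph$nodes$name, c(x, y))
  if (!length(cand)) return(character(0))
  to_x <- ancestors(graph, x)
  # reachability to y avoiding x: delete x, then take ancestors of y
  sub <- subgraph_without(graph, x)
  to_y_avoiding_x <- ancestors(sub, intersect(y, sub$nodes$name))
  sort(intersect(cand, intersect(to_x, to_y_avoiding_x)))
}

subgraph_without <- function(g, drop) {
  keep <- setdiff(g$nodes$name, drop)
  e <- g$edges[g$edges$from %in% keep & g$edges$to %in% keep, , drop = FALSE]
  structure(list(nodes = g$nodes[g$nodes$name %in% keep, , drop = FALSE],
                 edges = e, scale = g$scale), class = "cgraph")
}

#' d-separation in an acyclic causal graph
#'
#' Standard graphoid machinery: `x` and `y` are d-separated given `z` when
#' every path between them is blocked (chains and forks block when their
#' middle node is in `z`; colliders block unless the collider or one of its
#' descendants is in `z`).  Implemented by the ancestral moral-graph
#' construction.
#'
#' @param graph an acyclic `cgraph`.
#' @param x,y,z pairwise disjoint sets of node names (`z` may be empty).
#' @return logical scalar.
#' @export
d_separated <- function(graph, x, y, z = character(0)) {
  stopifnot(inherits(graph, "cgraph"))
  check_nodes(graph, c(x, y, z))
  if (!is_acyclic(graph))
    stop("d-separation is only defined for acyclic graphs (micro scale)")
  sets <- list(x, y, z)
  for (i in 1:2) for (j in (i + 1):3)
    if (length(intersect(sets[[i]], sets[[j]])))
      stop("x, y, z must be pairwise disjoint")
  anc <- ancestors(graph, c(x, y, z))
  sub <- subgraph_without(graph, setdiff(graph$nodes$name, anc))
  # moralize: connect parents sharing a child, drop direction
  e <- sub$edges
  moral <- e
  for (v in sub$nodes$name) {
    pa <- unique(e$from[e$to == v])
    if (length(pa) > 1L) {
      pairs <- t(utils::combn(pa, 2L))
      moral <- rbind(moral, data.frame(from = pairs[, 1L], to = pairs[, 2L],
                                       stringsAsFactors = FALSE))
    }
  }
  keep <- setdiff(sub$nodes$name, z)
  moral <- moral[moral$from %in% keep & moral$to %in% keep, , drop = FALSE]
  ug <- igraph::graph_from_data_frame(moral, directed = FALSE,
                                      vertices = keep)
  xs <- intersect(x, keep); ys <- intersect(y, keep)
  if (!length(xs) || !length(ys)) return(TRUE)
  reach <- unique(unlist(lapply(xs, function(s)
    names(igraph::subcomponent(ug, s, mode = "all")))))
  length(intersect(reach, ys)) == 0L
}

#' Back-door criterion
#'
#' `z` satisfies the back-door criterion relative to `(x, y)` when (i) no
#' member of `z` is a descendant of `x` and (ii) `z` blocks every path
#' between `x` and `y` that enters `x` through an incoming edge.  Condition
#' (ii) is checked as d-separation of `x` and `y` given `z` in the graph
#' with all edges leaving `x` removed.
#'
#' @param graph an acyclic `cgraph`.
#' @param x,y,z pairwise disjoint sets of node names.
#' @return logical scalar.
#' @export
back_door_satisfied <- function(graph, x, y, z = character(0)) {
  stopifnot(inherits(graph, "cgraph"))
  check_nodes(graph, c(x, y, z))
  if (!is_acyclic(graph))
    stop("the back-door criterion is only defined for acyclic graphs")
  if (length(intersect(z, descendants(graph, x)))) return(FALSE)
  backdoor_paths_blocked(graph, x, y, z)
}

# condition (ii) of the back-door criterion alone: z blocks every path
# between x and y in the graph with the edges leaving x removed.  This is
# also the graphical condition for exchanging observation and action,
# p(y|x,z) = p(y|do(x),z), where — unlike for the adjustment formula — z
# is allowed to contain descendants of x.
backdoor_paths_blocked <- function(graph, x, y, z = character(0)) {
  e <- graph$edges[!(graph$edges$from %in% x), , drop = FALSE]
  g_trunc <- structure(list(nodes = graph$nodes, edges = e, scale = graph$scale),
                       class = "cgraph")
  d_separated(g_trunc, x, y, z)
}

# ---------------------------------------------------------------------------
# Time-series specifications and unrolling across scales

#' Specification of a lagged bivariate (or multivariate) time-series graph
#'
#' Declares which subsystem drives which at which positive lag.  Lag-0
#' (instantaneous) edges are rejected.  Within-subsystem self-continuation
#' edges (e.g. `X` at lag 1 to `X`) must be declared explicitly; they are
#' not implied.
#'
#' @param subsystems ordered character vector of subsystem labels.
#' @param lag_edges data frame with columns `from`, `lag` (positive
#'   integer) and `to`.
#' @param horizon number of unrolled time steps (`>= max lag + 1`).
#' @return an object of class `tsspec`.
#' @examples
#' sp <- ts_spec(c("X", "Y"),
#'               data.frame(from = c("X", "Y", "X"), lag = 1L,
#'                          to   = c("X", "Y", "Y")),
#'               horizon = 4)
#' unroll(sp, "macro")
#' @export
ts_spec <- function(subsystems, lag_edges, horizon) {
  stopifnot(is.character(subsystems), length(subsystems) >= 1L,
            !anyDuplicated(subsystems))
  lag_edges <- as.data.frame(lag_edges, stringsAsFactors = FALSE)
  if (nrow(lag_edges) == 0L)
    lag_edges <- data.frame(from = character(0), lag = integer(0),
                            to = character(0))
  stopifnot(all(c("from", "lag", "to") %in% names(lag_edges)))
  lag_edges$lag <- as.integer(lag_edges$lag)
  if (any(lag_edges$lag < 1L))
    stop("all lags must be >= 1 (no instantaneous causality)")
  bad <- setdiff(c(lag_edges$from, lag_edges$to), subsystems)
  if (length(bad)) stop("lag edge references unknown subsystem: ", bad[1L])
  horizon <- as.integer(horizon)
  max_lag <- if (nrow(lag_edges)) max(lag_edges$lag) else 1L
  if (horizon < max_lag + 1L)
    stop("horizon must be at least max lag + 1")
  structure(list(subsystems = subsystems,
                 lag_edges = unique(lag_edges[, c("from", "lag", "to")]),
                 horizon = horizon),
            class = "tsspec")
}

#' @export
print.tsspec <- function(x, ...) {
  cat(sprintf("<tsspec> subsystems {%s}, horizon %d\n",
              paste(x$subsystems, collapse = ", "), x$horizon))
  if (nrow(x$lag_edges))
    cat(paste0("  ", x$lag_edges$from, " -(lag ", x$lag_edges$lag, ")-> ",
               x$lag_edges$to, collapse = "\n"), "\n")
  invisible(x)
}

#' Unroll a time-series specification at a chosen scale
#'
#' * `micro`: one node per (subsystem, t), t = 1..horizon; an edge per lag
#'   edge wherever both endpoints fall inside the horizon.  Always acyclic,
#'   all edges increase time.
#' * `meso`: the past of each subsystem before `t_now` is collapsed into a
#'   single aggregate node `"S[past]"` carrying all adjacency of the
#'   collapsed nodes; nodes from `t_now` on stay explicit.
#' * `macro`: one node per subsystem; edge `A -> B` iff any lag edge
#'   `A -> B` exists.  May be cyclic (bidirectional coupling).
#'
#' @param spec a `tsspec`.
#' @param scale `"micro"`, `"meso"` or `"macro"`.
#' @param t_now present time for the meso scale (`1 <= t_now < horizon`).
#' @return a `cgraph` at the requested scale.
#' @export
unroll <- function(spec, scale = c("micro", "meso", "macro"), t_now = NULL) {
  stopifnot(inherits(spec, "tsspec"))
  scale <- match.arg(scale)
  h <- spec$horizon
  le <- spec$lag_edges
  if (scale == "macro") {
    ed <- unique(le[, c("from", "to")])
    ed <- ed[ed$from != ed$to, , drop = FALSE]
    return(causal_graph(ed, nodes = spec$subsystems, scale = "macro"))
  }
  # micro node/edge set
  nodes <- as.vector(outer(spec$subsystems, seq_len(h), node_name))
  ed <- do.call(rbind, lapply(seq_len(nrow(le)), function(i) {
    ts <- seq_len(h - le$lag[i])
    data.frame(from = node_name(le$from[i], ts),
               to   = node_name(le$to[i], ts + le$lag[i]),
               stringsAsFactors = FALSE)
  }))
  if (is.null(ed)) ed <- data.frame(from = character(0), to = character(0))
  if (scale == "micro")
    return(causal_graph(ed, nodes = nodes, scale = "micro"))
  # meso: collapse nodes with t < t_now into one past node per subsystem
  if (is.null(t_now)) stop("meso scale requires t_now")
  t_now <- as.integer(t_now)
  if (t_now < 1L || t_now >= h) stop("t_now must satisfy 1 <= t_now < horizon")
  info <- parse_node_name(nodes)
  past_of <- setNames(node_name(info$subsystem, "past"), info$name)
  tt <- as.integer(info$t)
  collapse <- function(v) {
    t_v <- tt[match(v, info$name)]
    ifelse(t_v < t_now, past_of[v], v)
  }
  ed2 <- unique(data.frame(from = collapse(ed$from), to = collapse(ed$to),
                           stringsAsFactors = FALSE))
  ed2 <- ed2[ed2$from != ed2$to, , drop = FALSE]
  meso_nodes <- unique(c(node_name(unique(info$subsystem[tt < t_now]), "past"),
                         info$name[tt >= t_now]))
  causal_graph(ed2, nodes = meso_nodes, scale = "meso")
}
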