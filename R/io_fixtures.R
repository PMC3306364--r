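# JSON readers/writers, the seeded fixture generator, and the scriptable
# commands that surface the existence criteria and the Markov sweep.
# All tabular output is TSV ('.' decimal, no locale); reports are JSON.
# Writers emit keys in a fixed sorted order so that re-serialising a
# parsed file reproduces it byte-identically.

graph_to_list <- function(g) {
  info <- g$nodes
  list(
    edges = lapply(seq_len(nrow(g$edges)), function(i)
      list(from = g$edges$from[i], to = g$edges$to[i])),
    scale = g$scale,
    variables = lapply(seq_len(nrow(info)), function(i) {
      if (is.na(info$t[i])) return(list(subsystem = info$subsystem[i]))
      t <- suppressWarnings(as.integer(info$t[i]))
      list(subsystem = info$subsystem[i],
           t = if (is.na(t)) info$t[i] else t)
    })
  )
}

graph_from_list <- function(x) {
  nodes <- vapply(x$variables, function(v)
    node_name(v$subsystem, if (is.null(v$t)) NA else v$t), "")
  edges <- if (length(x$edges)) {
    data.frame(from = vapply(x$edges, `[[`, "", "from"),
               to = vapply(x$edges, `[[`, "", "to"),
               stringsAsFactors = FALSE)
  } else character(0)
  causal_graph(edges, nodes = nodes,
               scale = if (is.null(x$scale)) "macro" else x$scale)
}

#' Write / read a causal graph as JSON
#'
#' Keys: `variables` (list of `{subsystem, t}`; `t` absent for static
#' nodes), `edges` (list of `{from, to}` node names), `scale`.
#'
#' @param g a `cgraph`.
#' @param file path.
#' @return `read_causal_graph` returns a `cgraph`; the writer its input,
#'   invisibly.
#' @export
write_causal_graph <- function(g, file) {
  stopifnot(inherits(g, "cgraph"))
  jsonlite::write_json(graph_to_list(g), file, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(g)
}

#' @rdname write_causal_graph
#' @export
read_causal_graph <- function(file) {
  graph_from_list(jsonlite::read_json(file))
}

#' Write / read a time-series specification as JSON
#'
#' Keys: `subsystems`, `lag_edges` (list of `{from, lag, to}`), `horizon`.
#'
#' @param spec a `tsspec`.
#' @param file path.
#' @return `read_ts_spec` returns a `tsspec`; the writer its input,
#'   invisibly.
#' @export
write_ts_spec <- function(spec, file) {
  stopifnot(inherits(spec, "tsspec"))
  x <- list(
    horizon = spec$horizon,
    lag_edges = lapply(seq_len(nrow(spec$lag_edges)), function(i)
      list(from = spec$lag_edges$from[i], lag = spec$lag_edges$lag[i],
           to = spec$lag_edges$to[i])),
    subsystems = as.list(spec$subsystems)
  )
  jsonlite::write_json(x, file, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(spec)
}

#' @rdname write_ts_spec
#' @export
read_ts_spec <- function(file) {
  x <- jsonlite::read_json(file)
  le <- if (length(x$lag_edges)) {
    data.frame(from = vapply(x$lag_edges, `[[`, "", "from"),
               lag = vapply(x$lag_edges, function(e) as.integer(e$lag), 0L),
               to = vapply(x$lag_edges, `[[`, "", "to"),
               stringsAsFactors = FALSE)
  } else data.frame(from = character(0), lag = integer(0), to = character(0))
  ts_spec(unlist(x$subsystems), le, as.integer(x$horizon))
}

#' Write / read a discrete functional model as JSON
#'
#' Keys: `graph` (as in [write_causal_graph()]) and `cpts`: per variable
#' `{support, parents, rows}`, where `rows` maps each parent assignment
#' (values comma-joined in declared parent order; the empty string for a
#' parentless node) to the probability vector over the child support.
#'
#' @param model a `dfm`.
#' @param file path.
#' @return `read_discrete_model` returns a `dfm`; the writer its input,
#'   invisibly.
#' @export
write_discrete_model <- function(model, file) {
  stopifnot(inherits(model, "dfm"))
  cpts <- lapply(model$cpts, function(ct) {
    pg <- expand.grid(ct$parent_supports, KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
    keys <- if (nrow(pg)) apply(pg, 1L, paste, collapse = ",") else ""
    mat <- matrix(as.vector(ct$p), nrow = length(ct$support))
    rows <- setNames(lapply(seq_along(keys), function(i) mat[, i]), keys)
    list(parents = as.list(ct$parents),
         rows = rows[order(names(rows))],
         support = as.list(ct$support))
  })
  x <- list(cpts = cpts[order(names(cpts))],
            graph = graph_to_list(model$graph))
  jsonlite::write_json(x, file, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(model)
}

#' @rdname write_discrete_model
#' @export
read_discrete_model <- function(file) {
  x <- jsonlite::read_json(file)
  g <- graph_from_list(x$graph)
  cpts <- lapply(names(x$cpts), function(v) {
    ct <- x$cpts[[v]]
    support <- unlist(ct$support)
    parents <- as.character(unlist(ct$parents))
    if (length(parents) == 0L) {
      return(cpt(v, support, prob = as.numeric(unlist(ct$rows[[1L]]))))
    }
    psupp <- setNames(lapply(parents, function(p)
      unlist(x$cpts[[p]]$support)), parents)
    pg <- expand.grid(psupp, KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    keys <- apply(pg, 1L, paste, collapse = ",")
    prob <- t(vapply(keys, function(kk) as.numeric(unlist(ct$rows[[kk]])),
                     numeric(length(support))))
    cpt(v, support, parents, psupp, prob)
  })
  discrete_model(g, setNames(cpts, names(x$cpts)))
}

# ---------------------------------------------------------------------------
# Seeded fixtures

#' Generate a random discrete functional model fixture
#'
#' Samples a DAG topology over binary nodes (random topological order,
#' each admissible edge present with probability 1/2) and fills every CPT
#' row from a symmetric Dirichlet with concentration 1, clipping entries
#' to `>= 1e-3` and renormalizing so conditioning never hits a
#' zero-probability event.  Bit-identically regenerable from the seed.
#'
#' @param n_nodes number of nodes (2 to 5).
#' @param seed integer seed.
#' @return a `dfm` with attribute `"provenance"` = `list(n_nodes, seed)`.
#' @export
generate_fixture <- function(n_nodes, seed) {
  n_nodes <- as.integer(n_nodes)
  stopifnot(n_nodes >= 2L, n_nodes <= 5L)
  set.seed(as.integer(seed))
  labels <- c("X", "Y", "Z", "W", "U")[seq_len(n_nodes)]
  ord <- sample(labels)
  edges <- list()
  for (i in seq_len(n_nodes - 1L)) for (j in (i + 1L):n_nodes) {
    if (runif(1L) < 0.5)
      edges[[length(edges) + 1L]] <- c(ord[i], ord[j])
  }
  ed <- if (length(edges)) {
    m <- do.call(rbind, edges)
    data.frame(from = m[, 1L], to = m[, 2L], stringsAsFactors = FALSE)
  } else character(0)
  g <- causal_graph(ed, nodes = labels)
  b <- c("0", "1")
  rdir <- function(n_rows) {
    m <- matrix(rgamma(2L * n_rows, shape = 1), n_rows, 2L)
    m <- pmax(m / rowSums(m), 1e-3)
    m / rowSums(m)
  }
  cpts <- setNames(lapply(labels, function(v) {
    pa <- parents(g, v)
    if (!length(pa)) return(cpt(v, b, prob = rdir(1L)[1L, ]))
    cpt(v, b, pa, setNames(rep(list(b), length(pa)), pa), rdir(2L^length(pa)))
  }), labels)
  m <- discrete_model(g, cpts)
  attr(m, "provenance") <- list(n_nodes = n_nodes, seed = as.integer(seed))
  m
}

# ---------------------------------------------------------------------------
# Scriptable commands

report_to_list <- function(r) {
  list(exists = r$exists,
       reasons = lapply(r$structural_reasons, function(x)
         list(code = x$code, witness = as.list(x$witness))),
       max_discrepancy = if (is.null(r$numeric_check)) NULL else
         r$numeric_check$max_discrepancy)
}

#' Check the existence of a (conditional) natural causal effect
#'
#' Loads a discrete model from JSON, evaluates the existence criterion
#' (conditional when `z` is given), prints the report as JSON and returns
#' the exit status for pipeline use: 0 when the effect exists, 3 when it
#' does not.
#'
#' @param model_file path to a model JSON file (see
#'   [write_discrete_model()]).
#' @param x,y variable sets.
#' @param z optional conditioning set.
#' @param quiet suppress the JSON printout.
#' @return integer exit status, invisibly; the `existence_report` in
#'   attribute `"report"`.
#' @export
check_natural_effect <- function(model_file, x, y, z = NULL, quiet = FALSE) {
  model <- read_discrete_model(model_file)
  r <- if (is.null(z) || length(z) == 0L) {
    natural_effect_exists(model, x, y, check_numeric = TRUE)
  } else {
    conditional_natural_effect_exists(model, x, y, z, check_numeric = TRUE)
  }
  if (!quiet)
    cat(jsonlite::toJSON(report_to_list(r), auto_unbox = TRUE, digits = NA,
                         null = "null"), "\n")
  status <- if (r$exists) 0L else 3L
  attr(status, "report") <- r
  invisible(status)
}

#' Run the full Markov-example sweep with qualitative checks
#'
#' Writes the sweep TSV (see [markov_sweep()]) plus a JSON sidecar of the
#' qualitative properties of the three measures:
#' `te_zero_iff_c_zero`, `te_yx_zero`, `B_monotone`, `B_a_invariant`,
#' `C_zero_at_half` — each `TRUE`/`FALSE` as computed from the sweep.
#'
#' @param a_grid,c_grid parameter grids.
#' @param k lag count or `"converged"`.
#' @param out_tsv,out_json output paths.
#' @return the checks as a named logical list, invisibly.
#' @export
run_fig4_sweep <- function(a_grid = c(0.1, 0.25, 0.4, 0.5),
                           c_grid = seq(0, 1, by = 0.05),
                           k = "converged",
                           out_tsv = "markov_sweep.tsv",
                           out_json = "markov_sweep_checks.json") {
  sw <- markov_sweep(a_grid, c_grid, k = k, file = out_tsv)
  by_a <- split(sw, sw$a)
  mono <- function(v) all(diff(v) >= -1e-12)
  checks <- list(
    te_zero_iff_c_zero = all((sw$c == 0) == (sw$te_xy <= 1e-10)) &&
      all(sw$te_xy[sw$c > 0] > 1e-9),
    te_yx_zero = max(sw$te_yx) <= 1e-10,
    B_monotone = all(vapply(by_a, function(d)
      mono(d$jsd_natural[order(d$c)]), TRUE)),
    B_a_invariant = max(vapply(split(sw, sw$c), function(d)
      diff(range(d$jsd_natural)), 0)) < 1e-12,
    C_zero_at_half = if (any(sw$a == 0.5))
      max(sw$jsd_mechanism[sw$a == 0.5]) <= 1e-12 else NA
  )
  jsonlite::write_json(checks, out_json, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(checks)
}
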