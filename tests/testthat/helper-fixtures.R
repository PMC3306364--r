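# Shared builders and independent oracles.  Everything is generated in
# code; no stored fixtures.

BIN <- c("0", "1")

bin_support <- function(vars) setNames(rep(list(BIN), length(vars)), vars)

# three-node graphs: confounder with and without a direct arrow
graph_confounded_direct <- function() causal_graph(c("Z -> X", "Z -> Y", "X -> Y"))
graph_confounded_only   <- function() causal_graph(c("Z -> X", "Z -> Y"))
graph_chain             <- function() causal_graph(c("X -> Z", "Z -> Y"))

# X -> Z -> Y with p(X=1)=.5, p(Z=X)=.9, p(Y=Z)=.8
chain_model <- function() {
  discrete_model(graph_chain(), list(
    X = cpt("X", BIN, prob = c(0.5, 0.5)),
    Z = cpt("Z", BIN, "X", bin_support("X"), rbind(c(0.9, 0.1), c(0.1, 0.9))),
    Y = cpt("Y", BIN, "Z", bin_support("Z"), rbind(c(0.8, 0.2), c(0.2, 0.8)))))
}

# confounder-only model (no direct X -> Y arrow), randomized rows
confounded_model <- function(seed = 11) {
  set.seed(seed)
  r <- function(n) {
    m <- matrix(rgamma(2 * n, 1), n, 2)
    m <- pmax(m / rowSums(m), 1e-3)
    m / rowSums(m)
  }
  discrete_model(graph_confounded_only(), list(
    Z = cpt("Z", BIN, prob = r(1)[1, ]),
    X = cpt("X", BIN, "Z", bin_support("Z"), r(2)),
    Y = cpt("Y", BIN, "Z", bin_support("Z"), r(2))))
}

# random model with the given graph topology
rand_model <- function(graph, seed) {
  set.seed(seed)
  r <- function(n) {
    m <- matrix(rgamma(2 * n, 1), n, 2)
    m <- pmax(m / rowSums(m), 1e-3)
    m / rowSums(m)
  }
  cpts <- setNames(lapply(graph$nodes$name, function(v) {
    pa <- parents(graph, v)
    if (!length(pa)) return(cpt(v, BIN, prob = r(1)[1, ]))
    cpt(v, BIN, pa, bin_support(pa), r(2^length(pa)))
  }), graph$nodes$name)
  discrete_model(graph, cpts)
}

# random DAG on n named nodes: random order, each admissible edge w.p. 1/2
rand_dag <- function(n, seed) {
  set.seed(seed)
  labels <- c("A", "B", "C", "D", "E", "F")[seq_len(n)]
  ord <- sample(labels)
  edges <- list()
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
    if (runif(1) < 0.5) edges[[length(edges) + 1L]] <- c(ord[i], ord[j])
  ed <- if (length(edges)) {
    m <- do.call(rbind, edges)
    data.frame(from = m[, 1], to = m[, 2], stringsAsFactors = FALSE)
  } else character(0)
  causal_graph(ed, nodes = labels)
}

# ---------------------------------------------------------------------------
# Brute-force d-separation oracle: enumerate every simple path in the
# skeleton and apply the collider/chain/fork activation rules directly.

oracle_d_separated <- function(graph, x, y, z) {
  nodes <- graph$nodes$name
  dir_edge <- function(a, b) any(graph$edges$from == a & graph$edges$to == b)
  adj <- function(a, b) dir_edge(a, b) || dir_edge(b, a)
  desc_or_self <- function(v) {
    seen <- v
    repeat {
      nxt <- unique(graph$edges$to[graph$edges$from %in% seen])
      add <- setdiff(nxt, seen)
      if (!length(add)) return(seen)
      seen <- c(seen, add)
    }
  }
  path_active <- function(path) {
    if (length(path) == 2L) return(TRUE)
    for (i in 2:(length(path) - 1L)) {
      a <- path[i - 1L]; v <- path[i]; b <- path[i + 1L]
      collider <- dir_edge(a, v) && dir_edge(b, v)
      if (collider) {
        if (!any(desc_or_self(v) %in% z)) return(FALSE)
      } else {
        if (v %in% z) return(FALSE)
      }
    }
    TRUE
  }
  found_active <- FALSE
  walk <- function(path) {
    if (found_active) return()
    last <- path[length(path)]
    if (last %in% y) {
      if (path_active(path)) found_active <<- TRUE
      return()
    }
    for (nb in nodes) {
      if (nb %in% path) next
      if (!adj(last, nb)) next
      if (nb %in% x) next
      walk(c(path, nb))
    }
  }
  for (s in x) walk(s)
  !found_active
}

# independent conditional-mutual-information route via four entropies
oracle_cmi <- function(p, future, own, other) {
  H <- function(vars) {
    v <- as.vector(marginal(p, vars)$p)
    v <- v[v > 0]
    -sum(v * log2(v))
  }
  H(c(future, own)) + H(c(own, other)) - H(own) - H(c(future, own, other))
}

# symbolic truncated factorization: delete the intervened factors and
# restrict the table (independent route, no call to intervene())
oracle_truncated_joint <- function(model, do) {
  joint <- model_joint(model)
  grid <- expand.grid(joint$support, KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  p <- rep(1, nrow(grid))
  for (v in model$graph$nodes$name) {
    if (v %in% names(do)) next
    ct <- model$cpts[[v]]
    cols <- c(v, ct$parents)
    idx <- mapply(function(col, sup) match(grid[[col]], sup),
                  cols, c(list(ct$support), ct$parent_supports))
    p <- p * ct$p[as.matrix(idx)]
  }
  for (v in names(do)) p <- p * (grid[[v]] == do[[v]])
  cdist(joint$vars, joint$support, p / sum(p))
}

rand_cdist <- function(vars, seed) {
  set.seed(seed)
  n <- 2^length(vars)
  p <- rgamma(n, 1)
  cdist(vars, bin_support(vars), p / sum(p))
}

spec_uni <- function(h = 4L) {
  ts_spec(c("X", "Y"),
          data.frame(from = c("X", "Y", "X"), lag = 1L, to = c("X", "Y", "Y")),
          horizon = h)
}

spec_bi <- function(h = 4L) {
  ts_spec(c("X", "Y"),
          data.frame(from = c("X", "Y", "X", "Y"), lag = 1L,
                     to = c("X", "Y", "Y", "X")),
          horizon = h)
}

all_subsets <- function(v) {
  out <- list(character(0))
  for (s in v) out <- c(out, lapply(out, function(w) c(w, s)))
  out
}
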