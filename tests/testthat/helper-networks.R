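# Small networks and independent oracles shared across test files.

# diamond: S -in1- m -{sa,sb / at,bt}- t2 -out1- T, two parallel routes
make_diamond <- function(r_a = 1e-3, r_b = 1e-3) {
  nodes <- data.frame(
    id = c("S", "m", "a", "b", "t2", "T"),
    role = c("inlet_source", "interior", "interior", "interior",
             "interior", "outlet_sink"),
    territory = c(NA, NA, NA, NA, NA, "RMCA"),
    stringsAsFactors = FALSE)
  segs <- data.frame(
    id = c("in1", "sa", "sb", "at", "bt", "out1"),
    from = c("S", "m", "m", "a", "b", "t2"),
    to = c("m", "a", "b", "t2", "t2", "T"),
    length = 0.02,
    radius = c(1.4e-3, r_a, r_b, r_a, r_b, 1.4e-3),
    wall_thickness = 3e-4, youngs_modulus = 4e7,
    stringsAsFactors = FALSE)
  vascular_network(nodes, segs)
}

# random connected network: tree + extra cross edges, all-interior core
# with one inlet and n_out outlets hung off random core nodes
make_random_network <- function(n_core, n_extra = 3, n_out = 2, seed = 1) {
  set.seed(seed)
  core <- paste0("n", seq_len(n_core))
  from <- to <- character(0)
  for (i in 2:n_core) {                 # random spanning tree
    from <- c(from, core[sample.int(i - 1, 1)])
    to <- c(to, core[i])
  }
  for (k in seq_len(n_extra)) {
    pair <- sample(core, 2)
    if (!any((from == pair[1] & to == pair[2]) |
             (from == pair[2] & to == pair[1]))) {
      from <- c(from, pair[1]); to <- c(to, pair[2])
    }
  }
  inlet_host <- core[1]
  out_hosts <- sample(core[-1], n_out)
  nodes <- data.frame(
    id = c(core, "src", paste0("snk", seq_len(n_out))),
    role = c(rep("interior", n_core), "inlet_source",
             rep("outlet_sink", n_out)),
    territory = c(rep(NA, n_core + 1),
                  rep_len(c("RMCA", "LMCA", "RACA", "LACA"), n_out)),
    stringsAsFactors = FALSE)
  from <- c(from, "src", out_hosts)
  to <- c(to, inlet_host, paste0("snk", seq_len(n_out)))
  segs <- data.frame(
    id = paste0("e", seq_along(from)), from = from, to = to,
    length = runif(length(from), 0.01, 0.1),
    radius = runif(length(from), 5e-4, 2e-3),
    wall_thickness = 3e-4, youngs_modulus = 4e7,
    stringsAsFactors = FALSE)
  vascular_network(nodes, segs)
}

# dense brute-force Kirchhoff solve: full weighted graph Laplacian,
# Dirichlet rows replaced, prescribed flows on the RHS.  Independent of
# the package's sparse assembly path.
dense_kirchhoff <- function(net, resistances, pressures, flows = NULL,
                            thevenin = NULL) {
  ids <- sort(net$nodes$id)
  n <- length(ids)
  L <- matrix(0, n, n, dimnames = list(ids, ids))
  rhs <- setNames(numeric(n), ids)
  for (k in seq_len(nrow(net$segments))) {
    s <- net$segments[k, ]
    g <- 1 / resistances[[s$id]]
    L[s$from, s$from] <- L[s$from, s$from] + g
    L[s$to, s$to] <- L[s$to, s$to] + g
    L[s$from, s$to] <- L[s$from, s$to] - g
    L[s$to, s$from] <- L[s$to, s$from] - g
  }
  if (!is.null(flows)) rhs[names(flows)] <- flows
  if (!is.null(thevenin)) {
    for (k in seq_len(nrow(thevenin))) {
      nd <- thevenin$node[k]; g <- 1 / thevenin$resistance[k]
      L[nd, nd] <- L[nd, nd] + g
      rhs[nd] <- rhs[nd] + thevenin$pressure[k] * g
    }
  }
  for (nd in names(pressures)) {
    L[nd, ] <- 0; L[nd, nd] <- 1; rhs[nd] <- pressures[[nd]]
  }
  P <- solve(L, rhs)
  segs <- net$segments
  Q <- setNames((P[segs$from] - P[segs$to]) / resistances[segs$id],
                segs$id)
  list(pressures = P, flows = Q)
}

# exhaustive recursive simple-path enumeration over a directed edge
# list; oracle for the igraph-based DFS
brute_force_paths <- function(edges, sources, sinks) {
  out <- list()
  walk <- function(node, visited, acc) {
    if (node %in% sinks) {
      out[[length(out) + 1]] <<- acc
      return(invisible())
    }
    nxt <- edges$to[edges$from == node]
    for (v in nxt) if (!(v %in% visited))
      walk(v, c(visited, v), c(acc, v))
  }
  for (s in sources) walk(s, s, s)
  out[order(vapply(out, paste, "", collapse = "\r"))]
}

# forward-constructed flows on the diamond: x_true on the two routes
diamond_problem <- function(x_a = 2e-6, x_b = 1e-6) {
  net <- make_diamond()
  flows <- c(in1 = x_a + x_b, sa = x_a, sb = x_b, at = x_a, bt = x_b,
             out1 = x_a + x_b)
  basis <- enumerate_paths(net, flows)
  list(net = net, flows = flows, basis = basis,
       system = build_constraints(basis, flows), x_true = c(x_a, x_b))
}
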