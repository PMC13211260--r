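# Steady nodal-pressure mass balance of the cerebral resistance network:
# Poiseuille resistances, sparse conductance-matrix assembly, and signed
# segment flows.

#' Poiseuille resistance of a cylindrical segment
#'
#' `R = 8 mu l / (pi r^4)`.
#'
#' @param l segment length, m.
#' @param r lumen radius, m.
#' @param mu dynamic viscosity, Pa s.
#' @return resistance in Pa s/m^3.
#' @export
poiseuille_resistance <- function(l, r, mu) {
  if (any(l <= 0) || any(r <= 0) || any(mu <= 0))
    stop("poiseuille_resistance: all inputs must be positive")
  8 * mu * l / (pi * r^4)
}

#' Per-segment Poiseuille resistances of a network
#'
#' @param net a `vascular_network`.
#' @return named numeric vector (by segment id), Pa s/m^3.
#' @export
segment_resistances <- function(net) {
  s <- net$segments
  setNames(poiseuille_resistance(s$length, s$radius, net$blood$viscosity),
           s$id)
}

#' Boundary conditions for the 0D solve
#'
#' Each boundary node carries exactly one condition: a prescribed
#' pressure (Dirichlet, used for the autoregulated outlets), a prescribed
#' net inflow, or a Thevenin source (a pressure behind a series
#' resistance, used to fold the upstream aortic divider into the system
#' so the cerebral network and the inlet divider are solved
#' simultaneously).
#'
#' @param pressures named numeric vector of nodal pressures, Pa.
#' @param flows named numeric vector of prescribed net inflows, m^3/s.
#' @param thevenin data.frame with columns `node`, `pressure`,
#'   `resistance`.
#' @return a `network_boundary` list.
#' @export
network_boundary <- function(pressures = NULL, flows = NULL,
                             thevenin = NULL) {
  all_nodes <- c(names(pressures), names(flows),
                 if (!is.null(thevenin)) thevenin$node)
  if (anyDuplicated(all_nodes))
    stop("boundary error: node(s) with more than one condition: ",
         paste(unique(all_nodes[duplicated(all_nodes)]), collapse = ", "))
  structure(list(pressures = pressures, flows = flows, thevenin = thevenin),
            class = "network_boundary")
}

#' Assemble the sparse conductance system
#'
#' Builds the interior conductance matrix `B` (symmetric, weakly
#' diagonally dominant, off-diagonals `-G_mn`), the boundary coupling
#' matrix `Gb`, and the right-hand side `Gb Pb + Qb`.  Nodes with a
#' Dirichlet pressure are boundary nodes; all other nodes (including
#' Thevenin-coupled inlets and prescribed-flow nodes) are solved for.
#' Node ordering is fixed by sorted id for reproducibility.
#'
#' @param net a `vascular_network`.
#' @param resistances named per-segment resistances, Pa s/m^3 (default
#'   Poiseuille from geometry).
#' @param boundary a [network_boundary()].
#' @return a `conductance_system` list with fields `B`, `Gb`, `Pb`,
#'   `Qb`, `rhs`, `interior_ids`, `boundary_ids`, `net`, `conductances`.
#' @export
assemble_system <- function(net, resistances = segment_resistances(net),
                            boundary) {
  segs <- net$segments
  if (is.null(names(resistances))) names(resistances) <- segs$id
  G <- 1 / resistances[segs$id]
  if (any(!is.finite(G)) || any(G <= 0))
    stop("assemble_system: nonpositive or nonfinite segment resistance")

  node_ids <- sort(net$nodes$id)
  b_ids <- sort(names(boundary$pressures))
  has_cond <- c(b_ids, names(boundary$flows),
                if (!is.null(boundary$thevenin)) boundary$thevenin$node)
  roles <- setNames(net$nodes$role, net$nodes$id)
  miss <- setdiff(node_ids[roles[node_ids] != "interior"], has_cond)
  if (length(miss))
    stop("boundary error: boundary node(s) without a condition: ",
         paste(miss, collapse = ", "))
  int_ids <- setdiff(node_ids, b_ids)
  ni <- length(int_ids)
  iidx <- setNames(seq_len(ni), int_ids)
  bidx <- setNames(seq_along(b_ids), b_ids)

  ii <- jj <- xx <- numeric(0)       # triplets for B
  bi <- bj <- bx <- numeric(0)       # triplets for Gb
  for (k in seq_len(nrow(segs))) {
    f <- segs$from[k]; t <- segs$to[k]; g <- G[[k]]
    for (end in list(c(f, t), c(t, f))) {
      m <- end[1]; n <- end[2]
      if (!is.na(iidx[m])) {
        ii <- c(ii, iidx[[m]]); jj <- c(jj, iidx[[m]]); xx <- c(xx, g)
        if (!is.na(iidx[n])) {
          ii <- c(ii, iidx[[m]]); jj <- c(jj, iidx[[n]]); xx <- c(xx, -g)
        } else {
          bi <- c(bi, iidx[[m]]); bj <- c(bj, bidx[[n]]); bx <- c(bx, g)
        }
      }
    }
  }
  Qb <- setNames(numeric(ni), int_ids)
  if (!is.null(boundary$flows)) {
    unknown <- setdiff(names(boundary$flows), int_ids)
    if (length(unknown))
      stop("boundary error: prescribed flow on pressure node: ",
           paste(unknown, collapse = ", "))
    Qb[names(boundary$flows)] <- boundary$flows
  }
  th <- boundary$thevenin
  if (!is.null(th)) {
    for (k in seq_len(nrow(th))) {
      m <- th$node[k]
      if (is.na(iidx[m]))
        stop("boundary error: Thevenin condition on pressure node ", m)
      g <- 1 / th$resistance[k]
      ii <- c(ii, iidx[[m]]); jj <- c(jj, iidx[[m]]); xx <- c(xx, g)
      Qb[m] <- Qb[m] + th$pressure[k] * g
    }
  }
  B <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(ni, ni),
                            dimnames = list(int_ids, int_ids))
  Pb <- setNames(if (length(b_ids)) boundary$pressures[b_ids] else numeric(0),
                 b_ids)
  Gb <- Matrix::sparseMatrix(i = bi, j = bj, x = bx,
                             dims = c(ni, length(b_ids)),
                             dimnames = list(int_ids, b_ids))
  rhs <- as.numeric(Gb %*% Pb) + Qb
  structure(list(B = B, Gb = Gb, Pb = Pb, Qb = Qb,
                 rhs = setNames(rhs, int_ids),
                 interior_ids = int_ids, boundary_ids = b_ids,
                 net = net, conductances = G),
            class = "conductance_system")
}

#' Solve the conductance system for pressures and segment flows
#'
#' Solves `B P = Gb Pb + Qb` (sparse symmetric positive definite) and
#' recovers every signed segment flow `Q_ij = G_ij (P_i - P_j)` relative
#' to the reference orientation `from -> to`.
#'
#' @param system a `conductance_system`; `rhs` may optionally be
#'   overridden with a vector or multi-column matrix.
#' @param rhs optional replacement right-hand side (matrix columns are
#'   solved jointly).
#' @return a `flow_solution` list: `pressures` (all nodes, Pa), `flows`
#'   (per segment, m^3/s, signed by reference orientation),
#'   `boundary_flows` (net inflow at each Dirichlet node).
#' @export
solve_network <- function(system, rhs = NULL) {
  if (is.null(rhs)) rhs <- system$rhs
  P_int <- tryCatch(
    as.matrix(Matrix::solve(system$B, rhs)),
    error = function(e) stop("topology error: singular conductance matrix (",
                             conditionMessage(e), ")"))
  if (is.null(dim(rhs))) P_int <- P_int[, 1]
  net <- system$net
  all_ids <- c(system$interior_ids, system$boundary_ids)
  if (is.matrix(P_int)) {
    P <- rbind(P_int, matrix(rep(system$Pb, ncol(P_int)),
                             ncol = ncol(P_int),
                             dimnames = list(system$boundary_ids, NULL)))
  } else {
    P <- c(P_int, system$Pb)
  }
  segs <- net$segments
  if (is.matrix(P)) {
    Q <- (P[segs$from, , drop = FALSE] - P[segs$to, , drop = FALSE]) *
      system$conductances
    rownames(Q) <- segs$id
  } else {
    P <- P[all_ids]
    Q <- setNames((P[segs$from] - P[segs$to]) * system$conductances, segs$id)
  }
  bf <- boundary_inflows(net, Q, system$boundary_ids)
  structure(list(pressures = P, flows = Q, boundary_flows = bf,
                 net = net), class = "flow_solution")
}

# net inflow at each listed node implied by the signed segment flows
boundary_inflows <- function(net, flows, node_ids) {
  segs <- net$segments
  out <- if (is.matrix(flows)) {
    m <- matrix(0, length(node_ids), ncol(flows),
                dimnames = list(node_ids, NULL))
    for (k in seq_len(nrow(segs))) {
      if (segs$to[k] %in% node_ids)
        m[segs$to[k], ] <- m[segs$to[k], ] + flows[segs$id[k], ]
      if (segs$from[k] %in% node_ids)
        m[segs$from[k], ] <- m[segs$from[k], ] - flows[segs$id[k], ]
    }
    m
  } else {
    v <- setNames(numeric(length(node_ids)), node_ids)
    for (k in seq_len(nrow(segs))) {
      if (segs$to[k] %in% node_ids)
        v[segs$to[k]] <- v[segs$to[k]] + flows[[segs$id[k]]]
      if (segs$from[k] %in% node_ids)
        v[segs$from[k]] <- v[segs$from[k]] - flows[[segs$id[k]]]
    }
    v
  }
  out
}

#' One-call steady solve of a network
#'
#' Convenience wrapper: assemble + solve.
#'
#' @inheritParams assemble_system
#' @return a `flow_solution`.
#' @export
solve_network_flows <- function(net, resistances = segment_resistances(net),
                                boundary) {
  solve_network(assemble_system(net, resistances, boundary))
}

#' Verify interior mass conservation of a flow solution
#'
#' @param sol a `flow_solution`.
#' @return the maximum absolute net interior nodal flow divided by the
#'   mean absolute segment flow.
#' @export
conservation_residual <- function(sol) {
  net <- sol$net
  int_ids <- net$nodes$id[net$nodes$role == "interior"]
  resid <- boundary_inflows(net, sol$flows, int_ids)
  max(abs(resid)) / max(mean(abs(sol$flows)), .Machine$double.eps)
}
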