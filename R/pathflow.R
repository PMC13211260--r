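# Post-processing decomposition of a converged flow field into
# source-to-sink path flows: DFS feasible-path enumeration, constraint
# assembly, L1 + pumping-cost regularized nonnegative inversion,
# source-to-sink attribution and the multiplicative-noise robustness
# study.

#' Enumerate feasible source-to-sink paths by depth-first search
#'
#' All simple paths from every inlet source to every outlet sink that
#' traverse each segment consistently with the sign of its converged
#' quasi-steady flow.  Segments whose flow magnitude lies below
#' `zero_frac` times the network mean are admissible in both directions
#' (silent communicating arteries must not block enumeration).  Paths
#' are returned in deterministic lexicographic order of their node-id
#' sequences.
#'
#' @param net a `vascular_network`.
#' @param flows named per-segment signed flows (m^3/s, positive along
#'   the reference orientation), e.g. cycle means from a converged run.
#' @param max_paths hard cap on the number of enumerated paths; an
#'   explicit overflow error is raised beyond it.
#' @param zero_frac zero-flow threshold as a fraction of the mean
#'   absolute flow.
#' @param resistances optional per-segment resistances used for the
#'   per-path series resistance `Rp` (default Poiseuille).
#' @return a `path_basis` list: `paths` (list of node-id vectors),
#'   `segments` (list of segment-id vectors), `signs` (traversal sign
#'   per segment along each path), `sources`, `sinks`, `rp`, `net`.
#' @export
enumerate_paths <- function(net, flows, max_paths = 1e5,
                            zero_frac = 1e-4,
                            resistances = segment_resistances(net)) {
  segs <- net$segments
  flows <- flows[segs$id]
  thr <- zero_frac * mean(abs(flows))
  # directed edge list of admissible traversals
  ed <- NULL
  for (i in seq_len(nrow(segs))) {
    s <- segs[i, ]
    if (flows[[i]] >= -thr)
      ed <- rbind(ed, data.frame(from = s$from, to = s$to, seg = s$id,
                                 sign = 1))
    if (flows[[i]] <= thr)
      ed <- rbind(ed, data.frame(from = s$to, to = s$from, seg = s$id,
                                 sign = -1))
  }
  g <- igraph::graph_from_data_frame(ed, directed = TRUE,
                                     vertices = net$nodes["id"])
  sources <- sort(net$nodes$id[net$nodes$role == "inlet_source"])
  sinks <- sort(net$nodes$id[net$nodes$role == "outlet_sink"])
  paths <- list()
  for (src in sources) {
    sp <- igraph::all_simple_paths(g, from = src, to = sinks,
                                   mode = "out")
    paths <- c(paths, lapply(sp, function(p) names(p)))
  }
  paths <- paths[vapply(paths, function(p) p[length(p)] %in% sinks,
                        TRUE)]
  if (length(paths) > max_paths)
    stop("path enumeration overflow: ", length(paths), " paths exceed ",
         "max_paths = ", max_paths)
  ord <- order(vapply(paths, paste, "", collapse = "\r"))
  paths <- paths[ord]
  # map node sequences to segment traversals
  key <- paste(ed$from, ed$to, sep = "\r")
  seg_of <- setNames(ed$seg, key)
  sign_of <- setNames(ed$sign, key)
  seg_paths <- lapply(paths, function(p) {
    kk <- paste(p[-length(p)], p[-1], sep = "\r")
    unname(seg_of[kk])
  })
  sign_paths <- lapply(paths, function(p) {
    kk <- paste(p[-length(p)], p[-1], sep = "\r")
    unname(sign_of[kk])
  })
  rp <- vapply(seg_paths, function(ss) sum(resistances[ss]), 0)
  structure(list(paths = paths, segments = seg_paths, signs = sign_paths,
                 sources = sources, sinks = sinks, rp = rp, net = net,
                 flows = flows, zero_threshold = thr),
            class = "path_basis")
}

#' @export
print.path_basis <- function(x, ...) {
  cat("<path_basis> ", length(x$paths), " feasible paths, ",
      length(x$sources), " sources, ", length(x$sinks), " sinks\n",
      sep = "")
  invisible(x)
}

#' Assemble the stacked path-flow constraint system
#'
#' Segment rows (`Wline`, entries +1/-1 by traversal direction relative
#' to the reference orientation, target the signed segment flows),
#' source rows (`Wstart`, weighted by `lambda1`, target the inlet
#' inflows) and sink rows (`Wend`, weighted by `lambda2`, target the
#' outlet outflows), concatenated into `W x = b`.
#'
#' @param basis a `path_basis`.
#' @param flows named signed segment flows (defaults to the flows the
#'   basis was built from).
#' @param lambda1,lambda2 source/sink constraint weights.
#' @return a `constraint_system` list: `W`, `b`, the unweighted blocks
#'   `Wline`, `Wstart`, `Wend`, `Qline`, `Qstart`, `Qend`, and the
#'   weights.
#' @export
build_constraints <- function(basis, flows = basis$flows,
                              lambda1 = 1, lambda2 = 1) {
  net <- basis$net
  seg_ids <- net$segments$id
  m <- length(basis$paths)
  L <- length(seg_ids)
  Wline <- matrix(0, L, m, dimnames = list(seg_ids, NULL))
  for (p in seq_len(m))
    Wline[cbind(match(basis$segments[[p]], seg_ids), p)] <-
      basis$signs[[p]]
  Wstart <- matrix(0, length(basis$sources), m,
                   dimnames = list(basis$sources, NULL))
  Wend <- matrix(0, length(basis$sinks), m,
                 dimnames = list(basis$sinks, NULL))
  for (p in seq_len(m)) {
    nd <- basis$paths[[p]]
    Wstart[nd[1], p] <- 1
    Wend[nd[length(nd)], p] <- 1
  }
  Qline <- flows[seg_ids]
  inflow <- boundary_inflows(net, flows, c(basis$sources, basis$sinks))
  Qstart <- -inflow[basis$sources]   # net flow *into* the network
  Qend <- inflow[basis$sinks]
  W <- rbind(Wline, lambda1 * Wstart, lambda2 * Wend)
  b <- c(Qline, lambda1 * Qstart, lambda2 * Qend)
  structure(list(W = W, b = b, Wline = Wline, Wstart = Wstart,
                 Wend = Wend, Qline = Qline, Qstart = Qstart,
                 Qend = Qend, lambda1 = lambda1, lambda2 = lambda2),
            class = "constraint_system")
}

# Exact active-set (Lawson-Hanson style) solver for the nonnegative QP
#   min_{x>=0} 0.5||Wx-b||^2 + delta sum(x) + sigma sum(rp x^2)
# i.e. 0.5 x'Qx - c'x with Q = W'W + 2 sigma diag(rp), c = W'b - delta.
pathflow_qp <- function(W, b, delta, rp, sigma, tol = 1e-10,
                        max_iter = NULL) {
  m <- ncol(W)
  Q <- crossprod(W) + diag(2 * sigma * rp, m)
  cc <- as.numeric(crossprod(W, b)) - delta
  scale <- max(abs(cc), 1e-30)
  if (is.null(max_iter)) max_iter <- 20 * m + 100
  qsolve <- function(P) {
    A <- Q[P, P, drop = FALSE]
    tryCatch(solve(A, cc[P]),
             error = function(e)
               solve(A + diag(1e-12 * max(diag(A)), length(P)), cc[P]))
  }
  x <- numeric(m)
  P <- integer(0)
  for (it in seq_len(max_iter)) {
    w <- cc - as.numeric(Q %*% x)          # negative gradient
    free <- setdiff(seq_len(m), P)
    if (!length(free) || max(w[free]) <= tol * scale) break
    P <- sort(c(P, free[which.max(w[free])]))
    repeat {
      z <- qsolve(P)
      if (all(z > 0)) { x[] <- 0; x[P] <- z; break }
      neg <- which(z <= 0)
      alpha <- min(x[P][neg] / (x[P][neg] - z[neg]))
      x[P] <- x[P] + alpha * (z - x[P])
      keep <- x[P] > tol * max(x, 1e-30)
      x[P][!keep] <- 0
      P <- P[keep]
      if (!length(P)) { x[] <- 0; break }
    }
  }
  g <- as.numeric(Q %*% x) - cc            # gradient incl. L1 term
  kkt <- max(abs(g[x > 0]), 0, -(g[x <= 0]))
  if (kkt >= 100 * tol * scale)
    warning("pathflow solver: relative KKT residual ",
            signif(kkt / scale, 3))
  obj <- 0.5 * sum((as.numeric(W %*% x) - b)^2) + delta * sum(x) +
    sigma * sum(rp * x^2)
  list(x = x, objective = obj, kkt = kkt / scale, iterations = it)
}

#' Solve the regularized nonnegative path-flow inversion
#'
#' Minimizes `0.5 ||W x - b||^2 + delta ||x||_1 + sigma sum_p Rp x_p^2`
#' over `x >= 0` by a projected accelerated proximal-gradient method
#' run to a tight KKT residual; the solution is deterministic given the
#' inputs.  The source-to-sink attribution matrix is computed from the
#' minimizer.
#'
#' @param system a `constraint_system`.
#' @param basis the `path_basis` the system was built from.
#' @param delta L1 sparsity weight; default `1e-6 * max(|b|)`.
#' @param sigma pumping-cost weight on `sum Rp x^2`; default
#'   `1e-9 / median(Rp)`.
#' @param tol relative KKT tolerance.
#' @return a `path_solution` list: `x` (m^3/s per path), `objective`,
#'   `residual` (`||Wx - b||`), `kkt`, `theta` (source x sink
#'   attribution), `delta`, `sigma`.
#' @export
solve_pathflow <- function(system, basis, delta = NULL, sigma = NULL,
                           tol = 1e-10) {
  if (is.null(delta)) delta <- 1e-6 * max(abs(system$b))
  if (is.null(sigma)) sigma <- 1e-9 / median(basis$rp)
  if (delta < 0 || sigma < 0) stop("delta and sigma must be nonnegative")
  fit <- pathflow_qp(system$W, system$b, delta, basis$rp, sigma, tol)
  theta <- attribution(fit$x, basis)
  structure(list(x = fit$x, objective = fit$objective,
                 residual = sqrt(sum((system$W %*% fit$x - system$b)^2)),
                 kkt = fit$kkt, iterations = fit$iterations,
                 theta = theta, delta = delta, sigma = sigma),
            class = "path_solution")
}

#' Source-to-sink attribution matrix
#'
#' `theta[i, j]` is the fraction of sink `j`'s inflow contributed by
#' source `i`: the summed flow of paths from `i` to `j` divided by the
#' summed flow of all paths into `j`.  Columns of active sinks sum to 1;
#' sinks with zero total path flow are flagged `NA` (undefined), not
#' NaN-propagated.
#'
#' @param x nonnegative per-path flows (or a `path_solution`).
#' @param basis the `path_basis`.
#' @return matrix `sources x sinks` with an attribute
#'   `"active"` marking sinks with nonzero inflow.
#' @export
attribution <- function(x, basis) {
  if (inherits(x, "path_solution")) x <- x$x
  S <- length(basis$sources)
  E <- length(basis$sinks)
  num <- matrix(0, S, E, dimnames = list(basis$sources, basis$sinks))
  for (p in seq_along(x)) {
    nd <- basis$paths[[p]]
    num[nd[1], nd[length(nd)]] <- num[nd[1], nd[length(nd)]] + x[p]
  }
  tot <- colSums(num)
  active <- tot > 0
  theta <- sweep(num, 2, ifelse(active, tot, 1), "/")
  theta[, !active] <- NA_real_
  attr(theta, "active") <- active
  theta
}

#' Aggregate attribution over outflow territories
#'
#' Sums sink columns belonging to the same territory (flow-weighted) so
#' rows are the four inflow arteries and columns the six territories.
#'
#' @param sol a `path_solution`.
#' @param basis the `path_basis`.
#' @return matrix `sources x territories` of fractional contributions.
#' @export
territory_attribution <- function(sol, basis) {
  net <- basis$net
  terr <- setNames(net$nodes$territory, net$nodes$id)[basis$sinks]
  x <- sol$x
  num <- matrix(0, length(basis$sources), length(TERRITORIES),
                dimnames = list(basis$sources, TERRITORIES))
  tot <- setNames(numeric(length(TERRITORIES)), TERRITORIES)
  for (p in seq_along(x)) {
    nd <- basis$paths[[p]]
    tg <- terr[[nd[length(nd)]]]
    num[nd[1], tg] <- num[nd[1], tg] + x[p]
    tot[tg] <- tot[tg] + x[p]
  }
  sweep(num, 2, pmax(tot, .Machine$double.xmin), "/")
}

#' Robustness of the inversion to multiplicative noise
#'
#' Perturbs the constraint vector as `b' = b (1 + eta xi)` with
#' `xi ~ Uniform[-1, 1]` i.i.d. per entry, re-solves the inversion for
#' each replicate, and reports per-path distribution summaries and a
#' stability score: the fraction of replicates in which the path stays
#' active and within +-50% of its unperturbed flow.  Paths inactive in
#' the unperturbed solution score the fraction of replicates in which
#' they remain inactive.
#'
#' @param system a `constraint_system`.
#' @param basis the `path_basis`.
#' @param eta noise level (e.g. 0.05 or 0.10).
#' @param reps number of replicates.
#' @param seed integer RNG seed (results are bitwise reproducible).
#' @param delta,sigma regularization weights passed to
#'   [solve_pathflow()].
#' @return a `robustness_report` list: `eta`, `reps`, `x0` (unperturbed
#'   solution), `samples` (reps x paths matrix), `summary` (per-path
#'   quantiles), `stability` (per path, in `[0, 1]`), `failures`.
#' @export
robustness_study <- function(system, basis, eta = 0.05, reps = 500,
                             seed = 1L, delta = NULL, sigma = NULL) {
  stopifnot(reps >= 1, eta >= 0)
  sol0 <- solve_pathflow(system, basis, delta = delta, sigma = sigma)
  x0 <- sol0$x
  m <- length(x0)
  active_thr <- 1e-6 * max(x0, .Machine$double.xmin)
  set.seed(as.integer(seed))
  samples <- matrix(NA_real_, reps, m)
  failures <- 0L
  for (r in seq_len(reps)) {
    xi <- runif(length(system$b), -1, 1)
    bp <- system$b * (1 + eta * xi)
    fit <- tryCatch(
      pathflow_qp(system$W, bp, sol0$delta, basis$rp, sol0$sigma),
      error = function(e) NULL)
    if (is.null(fit)) { failures <- failures + 1L; next }
    samples[r, ] <- fit$x
  }
  ok <- !is.na(samples[, 1])
  active0 <- x0 > active_thr
  stability <- vapply(seq_len(m), function(p) {
    xs <- samples[ok, p]
    if (active0[p])
      mean(xs > active_thr & abs(xs - x0[p]) <= 0.5 * x0[p])
    else mean(xs <= active_thr)
  }, 0)
  qs <- t(apply(samples[ok, , drop = FALSE], 2, stats::quantile,
                probs = c(0.025, 0.25, 0.5, 0.75, 0.975)))
  structure(list(eta = eta, reps = reps, x0 = x0, samples = samples,
                 summary = qs, stability = stability,
                 failures = failures, seed = seed),
            class = "robustness_report")
}
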