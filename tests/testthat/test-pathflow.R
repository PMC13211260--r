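test_that("DFS enumeration: chain, diamond, and exhaustive oracle on random DAGs", {
  nodes <- data.frame(id = c("s", "m", "t"),
                      role = c("inlet_source", "interior", "outlet_sink"),
                      territory = c(NA, NA, "RMCA"))
  segs <- data.frame(id = c("a", "b"), from = c("s", "m"), to = c("m", "t"),
                     length = 0.02, radius = 1e-3, wall_thickness = 3e-4,
                     youngs_modulus = 4e7)
  chain <- vascular_network(nodes, segs)
  basis <- enumerate_paths(chain, c(a = 1e-6, b = 1e-6))
  expect_length(basis$paths, 1)
  expect_identical(basis$paths[[1]], c("s", "m", "t"))
  # per-path series resistance
  expect_equal(basis$rp, sum(segment_resistances(chain)))

  dp <- diamond_problem()
  expect_length(dp$basis$paths, 2)

  # random sparse networks vs the brute-force simple-path oracle
  for (seed in 1:6) {
    net <- make_random_network(8, n_extra = 3, n_out = 2, seed = 30 + seed)
    set.seed(seed)
    flows <- setNames(runif(nrow(net$segments), -1, 1) * 1e-6,
                      net$segments$id)
    basis <- enumerate_paths(net, flows)
    thr <- basis$zero_threshold
    ed <- NULL
    for (i in seq_len(nrow(net$segments))) {
      s <- net$segments[i, ]
      if (flows[[s$id]] >= -thr)
        ed <- rbind(ed, data.frame(from = s$from, to = s$to))
      if (flows[[s$id]] <= thr)
        ed <- rbind(ed, data.frame(from = s$to, to = s$from))
    }
    oracle <- brute_force_paths(ed, "src",
                                net$nodes$id[net$nodes$role == "outlet_sink"])
    expect_identical(basis$paths, oracle)
  }

  # overflow guard is explicit
  expect_error(enumerate_paths(dp$net, dp$flows, max_paths = 1),
               "overflow")
})

test_that("constraint stacking follows the printed block structure", {
  dp <- diamond_problem()
  sys <- dp$system
  L <- nrow(dp$net$segments)
  expect_identical(dim(sys$Wline), c(L, 2L))
  # column sums of |Wline| equal the number of segments per path
  expect_equal(unname(colSums(abs(sys$Wline))),
               lengths(dp$basis$segments))
  # unit weights: b is the unweighted concatenation
  expect_equal(unname(sys$b),
               unname(c(sys$Qline, sys$Qstart, sys$Qend)))
  # forward construction: W x_true = b exactly
  expect_lt(max(abs(sys$W %*% dp$x_true - sys$b)), 1e-18)
  # weighted stacking scales the source/sink blocks
  sys2 <- build_constraints(dp$basis, dp$flows, lambda1 = 3, lambda2 = 0.5)
  expect_equal(unname(sys2$b),
               unname(c(sys$Qline, 3 * sys$Qstart, 0.5 * sys$Qend)))
})

test_that("the regularized inversion recovers forward-constructed path flows", {
  dp <- diamond_problem()
  # zero data: zero solution
  sys0 <- dp$system; sys0$b <- 0 * sys0$b
  z <- solve_pathflow(sys0, dp$basis, delta = 1e-12, sigma = 0)
  expect_true(all(z$x == 0))

  sol <- solve_pathflow(dp$system, dp$basis,
                        delta = 1e-8 * max(abs(dp$system$b)), sigma = 0)
  expect_lt(max(abs(sol$x - dp$x_true) / dp$x_true), 1e-6)

  # 12-node DAG with a known sparse decomposition
  net <- make_random_network(9, n_extra = 3, n_out = 3, seed = 99)
  basis0 <- enumerate_paths(net, setNames(rep(1e-6, nrow(net$segments)),
                                          net$segments$id))
  # build flows from a sparse nonnegative combination of 3 paths
  m <- length(basis0$paths)
  x_true <- numeric(m)
  x_true[c(1, min(2, m), m)] <- c(2e-6, 1e-6, 0.5e-6)
  flows <- setNames(numeric(nrow(net$segments)), net$segments$id)
  for (p in seq_len(m)) if (x_true[p] > 0)
    flows[basis0$segments[[p]]] <- flows[basis0$segments[[p]]] +
      x_true[p] * basis0$signs[[p]]
  basis <- enumerate_paths(net, flows)
  # map x_true onto the (direction-filtered) new basis
  key <- vapply(basis0$paths, paste, "", collapse = ">")
  key2 <- vapply(basis$paths, paste, "", collapse = ">")
  x_map <- setNames(numeric(length(key2)), key2)
  x_map[key[x_true > 0]] <- x_true[x_true > 0]
  sys <- build_constraints(basis, flows)
  sol2 <- solve_pathflow(sys, basis, delta = 1e-8 * max(abs(sys$b)),
                         sigma = 0)
  expect_lt(max(abs(sol2$x - x_map)) / max(x_map), 1e-6)

  # independent optimality oracle: KKT conditions of the QP
  g <- as.numeric(crossprod(sys$W, sys$W %*% sol2$x - sys$b)) +
    1e-8 * max(abs(sys$b))
  scale <- max(abs(crossprod(sys$W, sys$b)))
  expect_true(all(g[sol2$x > 0] < 1e-8 * scale &
                    g[sol2$x > 0] > -1e-8 * scale))
  expect_true(all(g[sol2$x == 0] > -1e-8 * scale))
})

test_that("increasing the sparsity weight never increases the L1 norm", {
  dp <- diamond_problem(x_a = 2e-6, x_b = 1.5e-6)
  deltas <- max(abs(dp$system$b)) * 10^seq(-8, -1, by = 1)
  l1 <- vapply(deltas, function(d)
    sum(solve_pathflow(dp$system, dp$basis, delta = d, sigma = 0)$x), 0)
  expect_true(all(diff(l1) <= 1e-12 * l1[1]))
})

test_that("solver agrees with glmnet's nonnegative lasso", {
  skip_if_not_installed("glmnet")
  dp <- diamond_problem()
  W <- dp$system$W; b <- dp$system$b
  delta <- 1e-3 * max(abs(b))            # visible shrinkage
  sol <- solve_pathflow(dp$system, dp$basis, delta = delta, sigma = 0)
  n <- nrow(W)
  fit <- glmnet::glmnet(W, b, lambda = delta / n, lower.limits = 0,
                        intercept = FALSE, standardize = FALSE,
                        thresh = 1e-14)
  x_g <- as.numeric(fit$beta)
  expect_equal(sol$x, x_g, tolerance = 1e-4)
})

test_that("attribution columns are normalized and undefined sinks flagged", {
  dp <- diamond_problem()
  sol <- solve_pathflow(dp$system, dp$basis)
  th <- attribution(sol, dp$basis)
  expect_equal(unname(colSums(th)[attr(th, "active")]), 1, tolerance = 1e-9)
  # single-source network: the source owns every active sink
  expect_true(all(th[, attr(th, "active")] == 1))
  # zero-flow sink is NA, not NaN-propagated
  th0 <- attribution(numeric(2), dp$basis)
  expect_true(all(is.na(th0)))
  expect_false(any(attr(th0, "active")))
})

test_that("robustness study: determinism, eta = 0 exactness, dominant-path stability", {
  dp <- diamond_problem()
  r0 <- robustness_study(dp$system, dp$basis, eta = 0, reps = 5, seed = 3)
  expect_true(all(r0$stability == 1))
  expect_true(all(apply(r0$samples, 1, identical, r0$samples[1, ])))

  r1 <- robustness_study(dp$system, dp$basis, eta = 0.05, reps = 50, seed = 11)
  r2 <- robustness_study(dp$system, dp$basis, eta = 0.05, reps = 50, seed = 11)
  expect_identical(r1$samples, r2$samples)      # bitwise reproducible
  expect_identical(r1$stability, r2$stability)
  dominant <- which.max(r1$x0)
  expect_gte(r1$stability[dominant], 0.9)
  expect_identical(r1$failures, 0L)
})
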