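test_that("Poiseuille resistance scales as l and r^-4", {
  r0 <- poiseuille_resistance(0.01, 0.002, 0.0045)
  expect_equal(r0, 8 * 0.0045 * 0.01 / (pi * 0.002^4), tolerance = 1e-12)
  expect_equal(poiseuille_resistance(0.02, 0.002, 0.0045), 2 * r0)
  expect_equal(poiseuille_resistance(0.01, 0.001, 0.0045), 16 * r0)
  expect_error(poiseuille_resistance(0, 1e-3, 0.0045), "positive")
})

test_that("conductance assembly matches the printed definitions", {
  # 3-node path, single interior node: B is 1x1 = G12 + G23
  nodes <- data.frame(id = c("a", "m", "b"),
                      role = c("inlet_source", "interior", "outlet_sink"),
                      territory = c(NA, NA, "RMCA"))
  segs <- data.frame(id = c("s1", "s2"), from = c("a", "m"),
                     to = c("m", "b"), length = c(0.01, 0.02),
                     radius = c(1e-3, 1.5e-3), wall_thickness = 3e-4,
                     youngs_modulus = 4e7)
  net <- vascular_network(nodes, segs)
  r <- segment_resistances(net)
  sys <- assemble_system(net, r, network_boundary(
    pressures = c(a = 100, b = 0)))
  expect_equal(dim(sys$B), c(1, 1))
  expect_equal(as.numeric(sys$B[1, 1]), sum(1 / r), tolerance = 1e-14)
  expect_equal(as.numeric(sys$Gb["m", ]), unname(1 / r[c("s1", "s2")]))

  # star: hub diagonal is the sum of leaf conductances
  k <- 5
  nodes <- data.frame(
    id = c("hub", paste0("l", 1:k)),
    role = c("interior", "inlet_source", rep("outlet_sink", k - 1)),
    territory = c(NA, NA, rep_len(c("RMCA", "LMCA"), k - 1)))
  segs <- data.frame(id = paste0("e", 1:k), from = "hub",
                     to = paste0("l", 1:k),
                     length = seq(0.01, 0.05, length.out = k),
                     radius = 1e-3, wall_thickness = 3e-4,
                     youngs_modulus = 4e7)
  net <- vascular_network(nodes, segs)
  r <- segment_resistances(net)
  sys <- assemble_system(net, r, network_boundary(
    pressures = setNames(c(100, rep(0, k - 1)), paste0("l", 1:k))))
  expect_equal(as.numeric(sys$B[1, 1]), sum(1 / r), tolerance = 1e-14)

  # boundary node with no condition is rejected
  expect_error(assemble_system(net, r, network_boundary(
    pressures = c(l1 = 100))), "without a condition")
})

test_that("random networks: B equals the interior block of the dense Laplacian", {
  for (seed in 1:5) {
    net <- make_random_network(12, n_extra = 4, n_out = 3, seed = seed)
    r <- segment_resistances(net)
    bnd_nodes <- sort(net$nodes$id[net$nodes$role != "interior"])
    pb <- setNames(mmhg_to_pa(runif(length(bnd_nodes), 60, 100)), bnd_nodes)
    sys <- assemble_system(net, r, network_boundary(pressures = pb))
    # independent dense Laplacian
    ids <- sort(net$nodes$id)
    L <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
    for (k in seq_len(nrow(net$segments))) {
      s <- net$segments[k, ]
      g <- 1 / r[[s$id]]
      L[s$from, s$from] <- L[s$from, s$from] + g
      L[s$to, s$to] <- L[s$to, s$to] + g
      L[s$from, s$to] <- L[s$from, s$to] - g
      L[s$to, s$from] <- L[s$to, s$from] - g
    }
    int_ids <- sys$interior_ids
    expect_equal(as.matrix(sys$B), L[int_ids, int_ids], tolerance = 1e-14)
  }
})

test_that("network solve: zero gradient, series chain, conservation", {
  net <- make_cow_fixture("complete")
  r <- segment_resistances(net)
  bnd <- sort(net$nodes$id[net$nodes$role != "interior"])
  sol0 <- solve_network_flows(net, r, network_boundary(
    pressures = setNames(rep(mmhg_to_pa(90), length(bnd)), bnd)))
  expect_lt(max(abs(sol0$flows)), 1e-18)

  # series chain: uniform flow (P1 - P2) / sum(R)
  nodes <- data.frame(id = paste0("n", 1:4),
                      role = c("inlet_source", "interior", "interior",
                               "outlet_sink"),
                      territory = c(NA, NA, NA, "RACA"))
  segs <- data.frame(id = paste0("s", 1:3), from = paste0("n", 1:3),
                     to = paste0("n", 2:4), length = c(0.01, 0.03, 0.02),
                     radius = c(1e-3, 8e-4, 1.2e-3),
                     wall_thickness = 3e-4, youngs_modulus = 4e7)
  chain <- vascular_network(nodes, segs)
  rc <- segment_resistances(chain)
  sol <- solve_network_flows(chain, rc, network_boundary(
    pressures = c(n1 = 12000, n4 = 9000)))
  expect_equal(unname(sol$flows), rep(3000 / sum(rc), 3), tolerance = 1e-12)
  expect_lt(conservation_residual(sol), 1e-12)
})

test_that("sparse solve agrees with dense Kirchhoff on random mixed-boundary networks", {
  worst <- 0
  for (seed in 1:20) {
    n_core <- sample(8:25, 1)
    net <- make_random_network(n_core, n_extra = sample(2:6, 1),
                               n_out = sample(2:4, 1), seed = 100 + seed)
    r <- segment_resistances(net) * exp(stats::rnorm(nrow(net$segments), 0, 1))
    names(r) <- net$segments$id
    outs <- sort(net$nodes$id[net$nodes$role == "outlet_sink"])
    pb <- setNames(mmhg_to_pa(runif(length(outs), 60, 80)), outs)
    qin <- c(src = mls_to_m3s(runif(1, 2, 10)))
    sys <- assemble_system(net, r, network_boundary(pressures = pb,
                                                    flows = qin))
    sol <- solve_network(sys)
    ora <- dense_kirchhoff(net, r, pressures = pb, flows = qin)
    rel <- max(abs(sol$pressures[names(ora$pressures)] - ora$pressures)) /
      max(abs(ora$pressures))
    worst <- max(worst, rel)
  }
  expect_lt(worst, 1e-8)
})

test_that("Thevenin inlets reproduce the dense solve of the extended circuit", {
  net <- make_random_network(10, seed = 42)
  r <- segment_resistances(net)
  outs <- sort(net$nodes$id[net$nodes$role == "outlet_sink"])
  pb <- setNames(rep(mmhg_to_pa(70), length(outs)), outs)
  th <- data.frame(node = "src", pressure = mmhg_to_pa(95),
                   resistance = 6e7)
  sol <- solve_network_flows(net, r, network_boundary(
    pressures = pb, thevenin = th))
  ora <- dense_kirchhoff(net, r, pressures = pb, thevenin = th)
  expect_equal(unname(sol$pressures[names(ora$pressures)]),
               unname(ora$pressures), tolerance = 1e-10)
})

test_that("adding a parallel segment never increases the pressure drop", {
  net <- make_random_network(10, seed = 7)
  r <- segment_resistances(net)
  outs <- sort(net$nodes$id[net$nodes$role == "outlet_sink"])
  pb <- setNames(rep(mmhg_to_pa(70), length(outs)), outs)
  qin <- c(src = 5e-6)
  bnd <- network_boundary(pressures = pb, flows = qin)
  sol1 <- solve_network_flows(net, r, bnd)
  drop1 <- sol1$pressures[["src"]] - mmhg_to_pa(70)
  # duplicate an interior segment in parallel
  net2 <- net
  extra <- net$segments[3, ]
  extra$id <- "par"
  net2$segments <- rbind(net2$segments, extra)
  r2 <- segment_resistances(net2)
  sol2 <- solve_network_flows(net2, r2, bnd)
  drop2 <- sol2$pressures[["src"]] - mmhg_to_pa(70)
  expect_lte(drop2, drop1 + 1e-9 * abs(drop1))
})
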