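test_that("tube law: reference state, sign of stiffness, hand value", {
  A0 <- pi * (1.5e-3)^2
  expect_equal(tube_law(A0, A0, 4e7, 3e-4), P_REF_DEFAULT)
  expect_gt(tube_law(1.1 * A0, A0, 4e7, 3e-4), P_REF_DEFAULT)
  A <- 1.05 * A0
  expect_equal(tube_law(A, A0, 4e7, 3e-4, Pe = 500, P0 = 1e4),
               500 + 1e4 + 4 * pi * 4e7 * 3e-4 / (3 * A0) * (A - A0),
               tolerance = 1e-12)
  expect_equal(tube_area_from_pressure(tube_law(A, A0, 4e7, 3e-4),
                                       A0, 4e7, 3e-4), A)
  expect_error(tube_law(-A0, A0, 4e7, 3e-4), "nonpositive")
})

test_that("a resting tube with zero pressure gradient stays at rest", {
  st <- tube1d_state(0.03, 1e-3)
  bc <- list(type = "pressure", value = P_REF_DEFAULT)
  out <- step_segment(st, bc, bc, dt = 5e-5)
  expect_equal(out$A, st$A, tolerance = 1e-15)
  expect_equal(out$Q, st$Q, tolerance = 1e-20)
})

test_that("the explicit step is conservative and guards CFL", {
  st <- tube1d_state(0.03, 1e-3)
  st$Q <- 1e-7 * sin(seq(0, pi, length.out = st$n))     # non-trivial state
  st$A <- st$A0 * (1 + 0.02 * cos(seq(0, 2 * pi, length.out = st$n)))
  out <- step_segment(st, list(type = "pressure", value = P_REF_DEFAULT + 200),
                      list(type = "pressure", value = P_REF_DEFAULT),
                      dt = 5e-5)
  flux <- out$boundary_flux
  expect_equal(out$mass_change,
               (flux[["inflow"]] - flux[["outflow"]]) * 5e-5,
               tolerance = 1e-12)
  expect_error(step_segment(st, list(type = "pressure", value = P_REF_DEFAULT),
                            list(type = "pressure", value = P_REF_DEFAULT),
                            dt = 1e-2), "CFL")
})

test_that("the compiled network stepper matches the R reference on one tube", {
  st <- tube1d_state(0.04, 1.2e-3)
  p_in <- P_REF_DEFAULT + 300
  p_out <- P_REF_DEFAULT - 100
  dt_sub <- 0.9 * st$dx / wave_speed(st$A0[1], st$A0[1], st$Es, st$h,
                                     st$blood$density)
  n <- 200
  sr <- st
  for (i in seq_len(n))
    sr <- step_segment(sr, list(type = "pressure", value = p_in),
                       list(type = "pressure", value = p_out), dt_sub)
  st$node0 <- "a"; st$node1 <- "b"
  pbc <- cbind(a = rep(p_in, n + 1), b = rep(p_out, n + 1))
  cpp <- tube1d_run(list(s = st), pbc, dt_sub, cfl = 1)  # same dt, 1 substep
  expect_equal(cpp$n_substeps, n)
  expect_equal(cpp$A[[1]], sr$A, tolerance = 1e-12)
  expect_equal(cpp$Q[[1]], sr$Q, tolerance = 1e-10)
})

test_that("steady single tube reaches the Poiseuille limit", {
  st <- tube1d_state(0.10, 2e-3, Es = 1e9)   # nearly rigid wall
  st$node0 <- "in"; st$node1 <- "out"
  nt <- 4000; dt <- 5e-4
  pbc <- cbind(`in` = rep(P_REF_DEFAULT + 100, nt + 1),
               out = rep(P_REF_DEFAULT - 100, nt + 1))
  out <- tube1d_run(list(s = st), pbc, dt)
  q <- out$Qmid[nt, 1]
  r_num <- 200 / q
  r_th <- poiseuille_resistance(0.10, 2e-3, st$blood$viscosity)
  expect_lt(abs(r_num - r_th) / r_th, 0.01)
  # flow uniform along the tube at steady state
  expect_lt(abs(out$Qleft[nt, 1] - out$Qright[nt, 1]) / q, 1e-3)
})

test_that("grid refinement changes the converged flow by less than 0.5%", {
  run_dx <- function(dx) {
    st <- tube1d_state(0.05, 1.5e-3, Es = 1e9, dx = dx)
    st$node0 <- "in"; st$node1 <- "out"
    nt <- 3000
    pbc <- cbind(`in` = rep(P_REF_DEFAULT + 120, nt + 1),
                 out = rep(P_REF_DEFAULT, nt + 1))
    out <- tube1d_run(list(s = st), pbc, 5e-4)
    out$Qmid[nt, 1]
  }
  q1 <- run_dx(1e-3)
  q2 <- run_dx(5e-4)
  expect_lt(abs(q2 - q1) / abs(q1), 0.005)
})

test_that("junction coupling conserves mass and respects symmetry", {
  parent <- tube1d_state(0.03, 1.5e-3)
  d1 <- tube1d_state(0.03, 1e-3)
  d2 <- tube1d_state(0.03, 1e-3)
  parent$Q <- rep(2e-6, parent$n)            # incoming flow
  jc <- junction_couple(list(list(state = parent, end = 1),
                             list(state = d1, end = 0),
                             list(state = d2, end = 0)))
  q <- vapply(jc$boundary, `[[`, 0, "Q")
  expect_lt(abs(q[1] - q[2] - q[3]), 1e-12 * abs(q[1]))  # mass balance
  expect_equal(q[2], q[3], tolerance = 1e-12)            # symmetric daughters
  expect_error(junction_couple(list(list(state = parent, end = 1))),
               "at least 2")
})

test_that("a junction between identical tubes is transparent to a pulse", {
  mk <- function(l, n0, n1) {
    st <- tube1d_state(l, 2e-3)
    st$node0 <- n0; st$node1 <- n1
    st
  }
  dt <- 5e-4; nt <- 360
  tt <- seq(0, by = dt, length.out = nt + 1)
  p_in <- P_REF_DEFAULT + 400 * exp(-((tt - 0.03) / 0.008)^2)
  pbc <- cbind(inlet = p_in, outlet = rep(P_REF_DEFAULT, nt + 1))
  two <- tube1d_run(list(a = mk(0.05, "inlet", "J"),
                         b = mk(0.05, "J", "outlet")), pbc, dt)
  one <- tube1d_run(list(f = mk(0.10, "inlet", "outlet")), pbc, dt)
  inc <- max(abs(one$Qleft[, 1]))
  w <- tt[-1] < 0.055     # window: junction echo, before outlet effects
  refl <- max(abs(two$Qleft[w, 1] - one$Qleft[w, 1]))
  expect_lt(refl / inc, 0.01)
})

test_that("effective resistance: limits and quadrature accuracy", {
  A0 <- pi * (1.2e-3)^2
  n <- 40; dx <- 1e-3; mu <- 0.0045
  r_unif <- effective_resistance(rep(A0, n), dx, mu)
  expect_equal(r_unif, 8 * mu * (n * dx) / (pi * (1.2e-3)^4),
               tolerance = 1e-12)
  expect_equal(effective_resistance(rep(2 * A0, n), dx, mu), r_unif / 4,
               tolerance = 1e-12)
  # spatially varying area vs a fine-grid quadrature oracle
  l <- n * dx
  a_of <- function(x) A0 * (1 + 0.1 * sin(2 * pi * x / l))
  xc <- (seq_len(n) - 0.5) * dx
  r_coarse <- effective_resistance(a_of(xc), dx, mu)
  xf <- seq(0, l, length.out = 20001)
  r_fine <- pracma::trapz(xf, 8 * pi * mu / a_of(xf)^2)
  expect_lt(abs(r_coarse - r_fine) / r_fine, 1e-3)
  # matrix input reduces over the cycle
  Amat <- rbind(rep(A0, n), rep(2 * A0, n))
  expect_equal(effective_resistance(Amat, dx, mu, reduce = "mean"),
               (r_unif + r_unif / 4) / 2, tolerance = 1e-12)
})

test_that("resistance relaxation is the stated convex combination", {
  expect_equal(relax_resistance(2, 4, 1), 4)
  expect_equal(relax_resistance(3, 3, 0.25), 3)
  expect_equal(relax_resistance(2, 4, 0.5), 3)
  expect_error(relax_resistance(2, 4, 0), "\\(0, 1]")
  expect_error(relax_resistance(2, 4, 1.5), "\\(0, 1]")
})

test_that("cycle metric: identity, hand-computed scaling, relabeling", {
  nt <- 50; ns <- 4
  Q <- matrix(sin(seq_len(nt * ns)), nt, ns)
  A <- matrix(2 + cos(seq_len(nt * ns)), nt, ns)
  prev <- list(Q = Q, A = A)
  expect_identical(cycle_metric(prev, prev), 0)
  # uniform flow scaling by (1 + d), area unchanged:
  # each segment contributes d * max|Q| / max|Q| = d, mean = d
  d <- 0.07
  curr <- list(Q = (1 + d) * Q, A = A)
  expect_equal(cycle_metric(prev, curr), d, tolerance = 1e-12)
  # invariant under segment relabeling
  perm <- c(3, 1, 4, 2)
  expect_equal(cycle_metric(list(Q = Q[, perm], A = A[, perm]),
                            list(Q = curr$Q[, perm], A = A[, perm])),
               d, tolerance = 1e-12)
})

test_that("with rigid walls the 1D network approaches the 0D solution", {
  # Y-shaped network: one parent feeding two daughters
  mk <- function(l, r, n0, n1) {
    st <- tube1d_state(l, r, Es = 1e9)
    st$node0 <- n0; st$node1 <- n1
    st
  }
  segs <- list(p = mk(0.05, 1.5e-3, "in", "J"),
               d1 = mk(0.04, 1.0e-3, "J", "o1"),
               d2 = mk(0.04, 0.8e-3, "J", "o2"))
  nt <- 4000
  p_in <- P_REF_DEFAULT + 400
  pbc <- cbind(`in` = rep(p_in, nt + 1),
               o1 = rep(P_REF_DEFAULT, nt + 1),
               o2 = rep(P_REF_DEFAULT, nt + 1))
  out <- tube1d_run(segs, pbc, 5e-4)
  q1d <- out$Qmid[nt, ]
  # 0D oracle on the same topology
  nodes <- data.frame(id = c("in", "J", "o1", "o2"),
                      role = c("inlet_source", "interior", "outlet_sink",
                               "outlet_sink"),
                      territory = c(NA, NA, "RMCA", "RACA"))
  sg <- data.frame(id = c("p", "d1", "d2"), from = c("in", "J", "J"),
                   to = c("J", "o1", "o2"),
                   length = c(0.05, 0.04, 0.04),
                   radius = c(1.5e-3, 1.0e-3, 0.8e-3),
                   wall_thickness = 3e-4, youngs_modulus = 1e9)
  net <- vascular_network(nodes, sg)
  sol <- solve_network_flows(net, segment_resistances(net),
                             network_boundary(pressures = c(
                               `in` = p_in, o1 = P_REF_DEFAULT,
                               o2 = P_REF_DEFAULT)))
  expect_equal(unname(q1d[c("p", "d1", "d2")]),
               unname(sol$flows[c("p", "d1", "d2")]),
               tolerance = 0.01)
})
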