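# 1D compliant-tube flow: tube law, a reference single-segment MacCormack
# step in R, junction coupling by Riemann invariants, wrappers over the
# compiled network stepper, effective-resistance feedback and the
# cycle-convergence metric.

#' Reference pressure at which A = A0
#'
#' The tube law is anchored so that the reference area corresponds to a
#' typical mean cerebral arterial pressure.
#' @export
P_REF_DEFAULT <- mmhg_to_pa(85)

#' Affine tube law
#'
#' `P = Pe + P0 + K (A - A0)` with stiffness `K = 4 pi Es h / (3 A0)`.
#' The elastic coefficient is affine in the cross-sectional area; the
#' wall stiffness `Es h` sets the wave speed
#' `c = sqrt(K A / rho)`.
#'
#' @param A current area, m^2 (vectorized).
#' @param A0 reference area, m^2.
#' @param Es wall Young's modulus (effective), Pa.
#' @param h wall thickness, m.
#' @param Pe external pressure, Pa.
#' @param P0 reference pressure at `A = A0`, Pa.
#' @return pressure, Pa.
#' @export
tube_law <- function(A, A0, Es, h, Pe = 0, P0 = P_REF_DEFAULT) {
  if (any(A <= 0) || any(A0 <= 0)) stop("tube_law: nonpositive area")
  Pe + P0 + tube_stiffness(A0, Es, h) * (A - A0)
}

#' @rdname tube_law
#' @export
tube_stiffness <- function(A0, Es, h) 4 * pi * Es * h / (3 * A0)

#' @rdname tube_law
#' @param P pressure, Pa.
#' @export
tube_area_from_pressure <- function(P, A0, Es, h, Pe = 0,
                                    P0 = P_REF_DEFAULT) {
  A <- A0 + (P - Pe - P0) / tube_stiffness(A0, Es, h)
  if (any(A <= 0)) stop("tube_area_from_pressure: nonpositive area")
  A
}

#' Local wave speed of the affine tube law
#'
#' @inheritParams tube_law
#' @param rho blood density, kg/m^3.
#' @return wave speed, m/s.
#' @export
wave_speed <- function(A, A0, Es, h, rho) {
  sqrt(tube_stiffness(A0, Es, h) * A / rho)
}

#' Construct a discretized single-segment 1D state
#'
#' Cell-centred grid with at least `min_cells` cells; the per-cell
#' stiffness follows the (possibly spatially varying) reference area.
#'
#' @param length segment length, m.
#' @param radius lumen radius, m (scalar, or vector of per-cell radii).
#' @param Es,h wall properties.
#' @param dx target grid spacing, m (default 1e-3); the actual spacing
#'   divides the length exactly.
#' @param min_cells minimum number of cells per segment (default 10).
#' @param pref reference pressure (`Pe + P0`), Pa.
#' @param blood a [blood_properties()].
#' @return a `tube1d_state` list with fields `n`, `dx`, `x` (cell
#'   centres), `A`, `Q`, `A0`, `k`, `pref`, `Es`, `h`, `blood`.
#' @export
tube1d_state <- function(length, radius, Es = 4e7, h = 3e-4, dx = 1e-3,
                         min_cells = 10, pref = P_REF_DEFAULT,
                         blood = blood_properties()) {
  n <- max(min_cells, round(length / dx))
  dxs <- length / n
  A0 <- if (length(radius) == 1) rep(pi * radius^2, n) else {
    stopifnot(length(radius) == n)
    pi * radius^2
  }
  structure(list(n = n, dx = dxs, x = (seq_len(n) - 0.5) * dxs,
                 A = A0, Q = numeric(n), A0 = A0,
                 k = tube_stiffness(A0, Es, h), pref = pref,
                 Es = Es, h = h, blood = blood),
            class = "tube1d_state")
}

# ghost state (A_b, Q_b) for one end of a segment from a boundary
# condition and the outgoing Riemann invariant. end: 0 left, 1 right.
tube1d_ghost <- function(state, bc, end) {
  rho <- state$blood$density
  ci <- if (end == 0) 1 else state$n
  u_i <- state$Q[ci] / state$A[ci]
  c_i <- sqrt(state$k[ci] * state$A[ci] / rho)
  W <- if (end == 0) u_i - 2 * c_i else u_i + 2 * c_i
  u_of_A <- function(A) {
    cb <- sqrt(state$k[ci] * A / rho)
    if (end == 0) W + 2 * cb else W - 2 * cb
  }
  extrap <- function(face_A, face_Q) {
    # ghost linearly extrapolated through the boundary face
    Ag <- 2 * face_A - state$A[ci]
    if (Ag <= 0) Ag <- face_A
    list(A = Ag, Q = 2 * face_Q - state$Q[ci])
  }
  if (bc$type == "pressure") {
    Ab <- state$A0[ci] + (bc$value - state$pref) / state$k[ci]
    if (Ab <= 0) stop("boundary pressure collapses the tube")
    extrap(Ab, Ab * u_of_A(Ab))
  } else if (bc$type == "flow") {
    f <- function(A) A * u_of_A(A) - bc$value
    Ab <- uniroot(f, c(1e-3 * state$A0[ci], 10 * state$A0[ci]),
                  tol = 1e-15)$root
    extrap(Ab, bc$value)
  } else if (bc$type == "characteristic") {
    # non-reflecting: extrapolate the end cell
    list(A = state$A[ci], Q = state$Q[ci])
  } else stop("unknown boundary type: ", bc$type)
}

#' One MacCormack step of a single segment (reference implementation)
#'
#' Conservative predictor/corrector update of `(A, Q)` with the friction
#' source and the pressure gradient biased consistently with the flux
#' differences.  Boundary conditions may prescribe pressure, flow, or be
#' non-reflecting (`characteristic`).  Errors out if `dt` violates the
#' CFL condition.
#'
#' The returned object carries `mass_change` (the change of the volume
#' integral) and `boundary_flux` (the telescoped discrete boundary
#' fluxes), which satisfy `mass_change = (flux_in - flux_out) * dt`
#' exactly.
#'
#' @param state a `tube1d_state`.
#' @param inlet_bc,outlet_bc lists `list(type = "pressure"|"flow"|
#'   "characteristic", value = )`.
#' @param dt time step, s.
#' @return the advanced `tube1d_state`.
#' @export
step_segment <- function(state, inlet_bc, outlet_bc, dt) {
  if (dt <= 0) stop("dt must be positive")
  rho <- state$blood$density
  mu <- state$blood$viscosity
  n <- state$n
  lam_max <- max(abs(state$Q / state$A) +
                   sqrt(state$k * state$A / rho))
  if (dt > state$dx / lam_max)
    stop(sprintf("CFL violation: dt = %.3g exceeds %.3g for this segment",
                 dt, state$dx / lam_max))
  gl <- tube1d_ghost(state, inlet_bc, 0)
  gr <- tube1d_ghost(state, outlet_bc, 1)
  Ae <- c(gl$A, state$A, gr$A)
  Qe <- c(gl$Q, state$Q, gr$Q)
  k_of <- function(i) state$k[pmin(pmax(i - 1, 1), n)]
  A0_of <- function(i) state$A0[pmin(pmax(i - 1, 1), n)]
  idx <- seq_len(n + 2)
  Pe <- state$pref + k_of(idx) * (Ae - A0_of(idx))
  F2e <- Qe^2 / Ae
  lam <- dt / state$dx
  fr <- 8 * pi * mu / rho
  As <- Ae; Qs <- Qe
  i <- 2:(n + 1)
  As[i] <- Ae[i] - lam * (Qe[i + 1] - Qe[i])
  Qs[i] <- Qe[i] - lam * (F2e[i + 1] - F2e[i]) -
    lam * (Ae[i] / rho) * (Pe[i + 1] - Pe[i]) -
    dt * fr * Qe[i] / Ae[i]
  if (any(As <= 0)) stop("nonpositive area in predictor step")
  Ps <- state$pref + k_of(idx) * (As - A0_of(idx))
  F2s <- Qs^2 / As
  Anew <- 0.5 * (Ae[i] + As[i] - lam * (Qs[i] - Qs[i - 1]))
  Qnew <- 0.5 * (Qe[i] + Qs[i] - lam * (F2s[i] - F2s[i - 1]) -
                   lam * (As[i] / rho) * (Ps[i] - Ps[i - 1]) -
                   dt * fr * Qs[i] / As[i])
  if (any(Anew <= 0)) stop("nonpositive area in corrector step")
  out <- state
  out$A <- Anew
  out$Q <- Qnew
  out$mass_change <- sum(Anew - state$A) * state$dx
  out$boundary_flux <- c(inflow = 0.5 * (Qe[2] + Qe[1]),
                         outflow = 0.5 * (Qe[n + 2] + Qs[n + 1]))
  out
}

#' Couple segments meeting at a junction by Riemann invariants
#'
#' Enforces static-pressure continuity and mass conservation at a
#' branch point, closing each incident segment with its outgoing
#' characteristic invariant; returns the junction pressure and the
#' ghost-cell boundary state for every incident segment.
#'
#' @param states list of incidences, each `list(state = tube1d_state,
#'   end = 0 or 1)` (`end = 1` means the segment's `x = l` end meets
#'   the node).
#' @return list with `pressure` (Pa) and `boundary` (per incidence:
#'   `A`, `Q`).
#' @export
junction_couple <- function(states) {
  if (length(states) < 2) stop("junction needs at least 2 incident segments")
  rho <- states[[1]]$state$blood$density
  ends <- lapply(states, function(inc) {
    st <- inc$state
    ci <- if (inc$end == 0) 1 else st$n
    u <- st$Q[ci] / st$A[ci]
    cc <- sqrt(st$k[ci] * st$A[ci] / rho)
    list(k = st$k[ci], A0 = st$A0[ci], pref = st$pref,
         W = if (inc$end == 0) u - 2 * cc else u + 2 * cc,
         sgn = if (inc$end == 1) 1 else -1, end = inc$end,
         P = st$pref + st$k[ci] * (st$A[ci] - st$A0[ci]))
  })
  net_inflow <- function(P) {
    sum(vapply(ends, function(e) {
      Ab <- e$A0 + (P - e$pref) / e$k
      if (Ab <= 0) return(NA_real_)
      cb <- sqrt(e$k * Ab / rho)
      u <- if (e$end == 0) e$W + 2 * cb else e$W - 2 * cb
      e$sgn * Ab * u
    }, 0))
  }
  p0 <- mean(vapply(ends, `[[`, 0, "P"))
  lo <- p0 - 3e4; hi <- p0 + 3e4
  f_lo <- net_inflow(lo); f_hi <- net_inflow(hi)
  if (is.na(f_lo) || is.na(f_hi) || f_lo * f_hi > 0)
    stop("junction solve non-convergent: no bracket around ", signif(p0, 6))
  P <- uniroot(net_inflow, c(lo, hi), tol = 1e-12)$root
  boundary <- lapply(ends, function(e) {
    Ab <- e$A0 + (P - e$pref) / e$k
    cb <- sqrt(e$k * Ab / rho)
    u <- if (e$end == 0) e$W + 2 * cb else e$W - 2 * cb
    list(A = Ab, Q = Ab * u)
  })
  list(pressure = P, boundary = boundary)
}

#' Run the compiled 1D stepper over a general tube network
#'
#' Low-level driver: segments and nodes are given explicitly; node
#' pressures are prescribed per outer time step (matrix `pbc`), junction
#' nodes are solved by pressure continuity + mass conservation.  The
#' outer step is sub-cycled automatically under a CFL guard.
#'
#' @param segments list of `tube1d_state` objects, each augmented with
#'   `node0`, `node1`: the ids (character) of the nodes at its two ends.
#' @param pbc numeric matrix `(n_steps + 1) x n_pressure_nodes` of
#'   prescribed nodal pressures (Pa); column names are node ids.  Nodes
#'   not in `pbc` are treated as junctions.
#' @param dt outer time step, s.
#' @param cfl CFL safety factor.
#' @return list: `Qmid`, `Amid`, `Qleft`, `Qright` (matrices, one row
#'   per outer step, one column per segment), `reff` (time-averaged
#'   effective resistance per segment, Pa s/m^3), `A`, `Q` (final
#'   states), `n_substeps`.
#' @export
tube1d_run <- function(segments, pbc, dt, cfl = 0.9) {
  node_ids <- unique(unlist(lapply(segments, function(s)
    c(s$node0, s$node1))))
  pcols <- colnames(pbc)
  nidx <- setNames(seq_along(node_ids) - 1L, node_ids)
  seglist <- lapply(segments, function(s)
    list(A = s$A, Q = s$Q, A0 = s$A0, k = s$k, dx = s$dx, pref = s$pref,
         node0 = nidx[[s$node0]], node1 = nidx[[s$node1]]))
  inc <- lapply(node_ids, function(id) {
    m <- matrix(0L, 0, 2)
    for (si in seq_along(segments)) {
      if (segments[[si]]$node0 == id) m <- rbind(m, c(si - 1L, 0L))
      if (segments[[si]]$node1 == id) m <- rbind(m, c(si - 1L, 1L))
    }
    m
  })
  nodelist <- lapply(seq_along(node_ids), function(j) {
    id <- node_ids[j]
    if (id %in% pcols)
      list(type = 0L, pcol = match(id, pcols) - 1L, inc = inc[[j]])
    else list(type = 1L, pcol = 0L, inc = inc[[j]])
  })
  blood <- segments[[1]]$blood
  out <- tube1d_run_cpp(seglist, nodelist, as.matrix(pbc), dt,
                        blood$viscosity, blood$density, cfl)
  nm <- names(segments)
  if (!is.null(nm))
    colnames(out$Qmid) <- colnames(out$Amid) <- colnames(out$Qleft) <-
      colnames(out$Qright) <- names(out$reff) <- nm
  out
}

# build named tube1d states (with node ids) for every segment of a
# vascular network, applying any recorded stenoses to the reference area
network_tube_states <- function(net, dx = 1e-3, Es = NULL, h = NULL,
                                pref = P_REF_DEFAULT, init = NULL) {
  segs <- net$segments
  states <- lapply(seq_len(nrow(segs)), function(i) {
    s <- segs[i, ]
    es <- if (is.null(Es)) s$youngs_modulus else Es
    hh <- if (is.null(h)) s$wall_thickness else h
    st <- tube1d_state(s$length, s$radius, Es = es, h = hh, dx = dx,
                       pref = pref, blood = net$blood)
    sten <- net$stenoses[[s$id]]
    if (!is.null(sten)) {
      st$A0 <- stenotic_area_profile(st$x, s$length, st$A0, sten)
      st$k <- tube_stiffness(st$A0, es, hh)
      st$A <- st$A0
    }
    st$node0 <- s$from
    st$node1 <- s$to
    if (!is.null(init)) {
      st$A <- init$A[[i]]
      st$Q <- init$Q[[i]]
    }
    st
  })
  names(states) <- segs$id
  states
}

#' Effective resistance of a segment from its area field
#'
#' `Reff = integral of 8 pi mu / A(x)^2 dx` over the segment — the
#' pointwise Poiseuille density, so a uniform `A = pi r^2` reproduces
#' `8 mu l / (pi r^4)` exactly — evaluated by the trapezoidal rule on
#' the cell-centred grid with half-cell end corrections.  A matrix
#' input (rows = time samples) is reduced over the cycle window.
#'
#' @param A area samples: vector (one snapshot, cell centres) or matrix
#'   `time x cells`.
#' @param dx grid spacing, m.
#' @param mu viscosity, Pa s.
#' @param reduce `"mean"`, `"max"` or `"end"`: how the time-dependent
#'   integral is reduced to a per-cycle scalar.
#' @return effective resistance, Pa s/m^3.
#' @export
effective_resistance <- function(A, dx, mu, reduce = c("mean", "max", "end")) {
  reduce <- match.arg(reduce)
  one <- function(a) {
    f <- 8 * pi * mu / a^2
    n <- length(f)
    xc <- (seq_len(n) - 0.5) * dx
    pracma::trapz(xc, f) + 0.5 * dx * (f[1] + f[n])
  }
  if (is.matrix(A)) {
    r <- apply(A, 1, one)
    switch(reduce, mean = mean(r), max = max(r), end = r[length(r)])
  } else one(A)
}

#' Relax a segment resistance toward its 1D effective value
#'
#' `R_new = (1 - gamma) R_old + gamma R_eff`.
#'
#' @param r_old,r_eff old and 1D-derived resistances, Pa s/m^3.
#' @param gamma relaxation factor in `(0, 1]`.
#' @return relaxed resistance.
#' @export
relax_resistance <- function(r_old, r_eff, gamma) {
  if (any(gamma <= 0) || any(gamma > 1))
    stop("relaxation factor must lie in (0, 1]")
  (1 - gamma) * r_old + gamma * r_eff
}

#' Cycle-to-cycle convergence metric
#'
#' Mean over segments of the normalized maximum deviations of flow and
#' area between two consecutive cycles:
#' `Jn = mean_w [ max_t |Q^n - Q^(n-1)| / max_t |Q^(n-1)|
#'              + max_t |A^n - A^(n-1)| / max_t |A^(n-1)| ]`.
#' Segments whose previous-cycle flow never exceeds `1e-12` of the
#' network mean (e.g. silent communicating arteries) contribute only
#' their area term.
#'
#' @param prev,curr lists with matrices `Q` and `A` (`time x segment`)
#'   sampled on the same grid over one cycle.
#' @return the scalar metric `Jn >= 0`.
#' @export
cycle_metric <- function(prev, curr) {
  stopifnot(all(dim(prev$Q) == dim(curr$Q)),
            all(dim(prev$A) == dim(curr$A)))
  qmax_prev <- apply(abs(prev$Q), 2, max)
  amax_prev <- apply(abs(prev$A), 2, max)
  dq <- apply(abs(curr$Q - prev$Q), 2, max)
  da <- apply(abs(curr$A - prev$A), 2, max)
  q_floor <- 1e-12 * mean(qmax_prev)
  qterm <- ifelse(qmax_prev > q_floor, dq / qmax_prev, 0)
  aterm <- da / amax_prev
  mean(qterm + aterm)
}
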