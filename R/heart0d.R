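# Lumped-parameter closed-loop heart: four time-varying-elastance
# chambers with ideal diode valves, an aortic valve with Bernoulli and
# inertial losses, aortic/pulmonary/venous compliances, and the upstream
# resistance divider that feeds the four cerebral inlets.

#' Normalized double-Hill elastance waveform
#'
#' Smooth normalized ventricular activation on `[0, tau]`, maximum 1,
#' minimum 0, periodic with period `tau`.
#'
#' @param t time, s (vectorized); evaluated modulo `tau`.
#' @param tau cycle length, s.
#' @param alpha1,alpha2,n1,n2 shape parameters (ascending/descending
#'   limb positions and sharpness).
#' @return normalized elastance in `[0, 1]`.
#' @export
elastance_double_hill <- function(t, tau = 1,
                                  alpha1 = 0.303, alpha2 = 0.508,
                                  n1 = 1.32, n2 = 21.9) {
  tt <- (t %% tau) / tau
  up <- (tt / alpha1)^n1
  g <- (up / (1 + up)) * (1 / (1 + (tt / alpha2)^n2))
  # normalization constant of the product of Hill functions
  ttm <- seq(0, 1, length.out = 2001)
  upm <- (ttm / alpha1)^n1
  gm <- max((upm / (1 + upm)) / (1 + (ttm / alpha2)^n2))
  g / gm
}

#' Normalized atrial activation waveform
#'
#' A `sin^2` bump of width `width * tau` with onset at `onset * tau`
#' (late diastole), periodic, in `[0, 1]`.
#'
#' @param t time, s (vectorized).
#' @param tau cycle length, s.
#' @param onset,width activation onset and duration as fractions of the
#'   cycle.
#' @return normalized elastance in `[0, 1]`.
#' @export
elastance_atrial <- function(t, tau = 1, onset = 0.80, width = 0.17) {
  tt <- (t %% tau) / tau
  ph <- (tt - onset) %% 1
  ifelse(ph < width, sin(pi * ph / width)^2, 0)
}

#' Cardiac model parameters
#'
#' Active (`ea`) and passive (`eb`) elastances per chamber (`ra`, `rv`,
#' `la`, `lv`), dead volumes, wall viscoelasticity, aortic valve
#' coefficients, atrioventricular/pulmonary valve resistances, lumped
#' compliances and the systemic/upstream resistances.  The defaults are
#' literature-scale values producing an aortic pressure of roughly
#' 80-120 mmHg and a cardiac output near 5 L/min at a 1 s cycle.
#'
#' @param tau cardiac cycle length, s.
#' @param ... overrides for any default parameter.
#' @return a `cardiac_parameters` list (all values SI).
#' @export
cardiac_parameters <- function(tau = 1.0, ...) {
  p <- list(
    tau = tau,
    # chamber elastances, Pa/m^3 (active amplitude / passive)
    ea = c(ra = 8.0e6, rv = 7.3e7, la = 1.2e7, lv = 3.6e8),
    eb = c(ra = 6.7e6, rv = 6.7e6, la = 8.0e6, lv = 1.07e7),
    v0 = c(ra = 0, rv = 0, la = 0, lv = 0),      # dead volumes, m^3
    sv = 6.7e5,                                   # wall viscoelasticity, Pa s/m^3
    # aortic valve: viscous, Bernoulli, inertance
    rav = 2.7e6, bav = 6.7e8, lav = 6.7e4,
    # atrioventricular / pulmonary valve resistances
    rtv = 6.7e5, rmv = 6.7e5, rpv = 6.7e5,
    # lumped compliances, m^3/Pa
    cao = 1.1e-8, cpa = 4.5e-8, cvn = 5.25e-7,
    # systemic plumbing, Pa s/m^3
    rpul = 1.1e7, rvc = 1.3e6,
    # diagnostic sanity band on aortic pressure (warning only)
    pao_band = mmhg_to_pa(c(40, 200)),
    elastance = elastance_double_hill,
    elastance_atrial = elastance_atrial)
  ov <- list(...)
  p[names(ov)] <- ov
  structure(p, class = "cardiac_parameters")
}

#' Upstream resistance network feeding the cerebral inlets
#'
#' The aortic node drains through the right-arm branch, the systemic
#' (body + left arm) branch, and four inlet resistances `R_up,i` to the
#' cerebral inflow arteries RICA, LICA, RVA, LVA.
#'
#' @param rarm,rbody arm / systemic branch resistances, Pa s/m^3.
#' @param rup named vector of inlet resistances for the four inflow
#'   sources, Pa s/m^3.
#' @param venous_pressure systemic venous pressure, Pa.
#' @return an `upstream_network` list.
#' @export
upstream_network <- function(rarm = 6.0e8, rbody = 1.8e8,
                             rup = c(RICA = 6.0e7, LICA = 6.0e7,
                                     RVA = 1.0e8, LVA = 1.0e8),
                             venous_pressure = mmhg_to_pa(5)) {
  stopifnot(rarm > 0, rbody > 0, all(rup > 0))
  structure(list(rarm = rarm, rbody = rbody, rup = rup,
                 venous_pressure = venous_pressure),
            class = "upstream_network")
}

#' Chamber pressure from the elastance law
#'
#' `P = (E_A e(t) + E_B)(V - V0) + Sv dV/dt`, with the ventricular
#' waveform for `rv`/`lv` and the atrial waveform for `ra`/`la`.
#'
#' @param params a `cardiac_parameters`.
#' @param cm chamber id: `"ra"`, `"rv"`, `"la"` or `"lv"`.
#' @param v chamber volume, m^3.
#' @param dv_dt chamber volume rate, m^3/s.
#' @param t time, s.
#' @return pressure in Pa.
#' @export
chamber_pressure <- function(params, cm, v, dv_dt, t) {
  if (!cm %in% c("ra", "rv", "la", "lv")) stop("unknown chamber id: ", cm)
  e <- if (cm %in% c("rv", "lv")) params$elastance(t, params$tau)
       else params$elastance_atrial(t, params$tau)
  (params$ea[[cm]] * e + params$eb[[cm]]) * (v - params$v0[[cm]]) +
    params$sv * dv_dt
}

#' Aortic valve momentum balance
#'
#' `dQav/dt = Dav (Plv - Pao - Rav Qav - Bav Qav |Qav|) / Lav`, with the
#' ideal diode `Dav = 1` iff `Plv > Pao`.  The time stepper additionally
#' clamps `Qav` to zero while the valve is closed.
#'
#' @param params a `cardiac_parameters`.
#' @param plv,pao ventricular and aortic pressures, Pa.
#' @param qav current aortic valve flow, m^3/s.
#' @return `dQav/dt`, m^3/s^2.
#' @export
valve_rhs <- function(params, plv, pao, qav) {
  if (plv <= pao) return(0)
  (plv - pao - params$rav * qav - params$bav * qav * abs(qav)) / params$lav
}

# state vector layout for the closed loop
heart_state_names <- c("Vra", "Vrv", "Vla", "Vlv", "Qav", "Vao", "Vpa", "Vvn")

#' Initial cardiac state
#'
#' @param params a `cardiac_parameters`.
#' @return named numeric state vector (volumes in m^3, `Qav` in m^3/s).
#' @export
heart_initial_state <- function(params) {
  c(Vra = 6e-5, Vrv = 1.3e-4, Vla = 6e-5, Vlv = 1.3e-4, Qav = 0,
    Vao = params$cao * mmhg_to_pa(90),
    Vpa = params$cpa * mmhg_to_pa(15),
    Vvn = params$cvn * mmhg_to_pa(5))
}

# instantaneous pressures and valve flows implied by a state.
# dv_prev: lagged chamber volume rates for the viscoelastic term.
heart_algebra <- function(y, params, t, load, dv_prev = numeric(4)) {
  P <- c(ra = chamber_pressure(params, "ra", y[["Vra"]], dv_prev[[1]], t),
         rv = chamber_pressure(params, "rv", y[["Vrv"]], dv_prev[[2]], t),
         la = chamber_pressure(params, "la", y[["Vla"]], dv_prev[[3]], t),
         lv = chamber_pressure(params, "lv", y[["Vlv"]], dv_prev[[4]], t))
  pao <- y[["Vao"]] / params$cao
  ppa <- y[["Vpa"]] / params$cpa
  pvn <- y[["Vvn"]] / params$cvn
  qtv <- if (P[["ra"]] > P[["rv"]]) (P[["ra"]] - P[["rv"]]) / params$rtv else 0
  qpv <- if (P[["rv"]] > ppa) (P[["rv"]] - ppa) / params$rpv else 0
  qmv <- if (P[["la"]] > P[["lv"]]) (P[["la"]] - P[["lv"]]) / params$rmv else 0
  qpul <- (ppa - P[["la"]]) / params$rpul
  qvc <- (pvn - P[["ra"]]) / params$rvc
  # distal load: total drain from the aortic node, returned to the veins
  qload <- load$a + load$b * pao
  list(P = P, pao = pao, ppa = ppa, pvn = pvn,
       qtv = qtv, qpv = qpv, qmv = qmv, qpul = qpul, qvc = qvc,
       qload = qload)
}

heart_rhs <- function(y, params, t, load, dv_prev) {
  al <- heart_algebra(y, params, t, load, dv_prev)
  qav <- y[["Qav"]]
  dqav <- valve_rhs(params, al$P[["lv"]], al$pao, qav)
  c(Vra = al$qvc - al$qtv,
    Vrv = al$qtv - al$qpv,
    Vla = al$qpul - al$qmv,
    Vlv = al$qmv - qav,
    Qav = dqav,
    Vao = qav - al$qload,
    Vpa = al$qpv - al$qpul,
    Vvn = al$qload - al$qvc)
}

#' Advance the closed-loop heart one explicit RK4 step
#'
#' The cerebral + systemic load is an affine drain `Q = a + b Pao` from
#' the aortic node to the venous node, so total blood volume is a linear
#' invariant of the dynamics and is conserved to machine precision.
#' When the aortic valve closes (`Plv <= Pao`) the valve flow is clamped
#' to zero.
#'
#' @param state named state vector (see [heart_initial_state()]).
#' @param params a `cardiac_parameters`.
#' @param dt time step, s (must be positive and small enough for
#'   stability; 5e-4 s is the package default).
#' @param t current time, s.
#' @param load list with `a`, `b`: affine aortic drain, m^3/s and
#'   m^3/(s Pa).
#' @param dv_prev lagged chamber volume rates for the viscoelastic term.
#' @return list with the advanced `state`, the new `dv` rates and the
#'   algebraic observables `algebra`.
#' @export
step_heart <- function(state, params, dt, t = 0,
                       load = list(a = -mmhg_to_pa(5) / 1.1e8, b = 1 / 1.1e8),
                       dv_prev = numeric(4)) {
  if (!is.numeric(dt) || dt <= 0) stop("dt must be positive")
  k1 <- heart_rhs(state, params, t, load, dv_prev)
  k2 <- heart_rhs(state + dt / 2 * k1, params, t + dt / 2, load, dv_prev)
  k3 <- heart_rhs(state + dt / 2 * k2, params, t + dt / 2, load, dv_prev)
  k4 <- heart_rhs(state + dt * k3, params, t + dt, load, dv_prev)
  y <- state + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  al <- heart_algebra(y, params, t + dt, load, dv_prev)
  if (al$P[["lv"]] <= al$pao || y[["Qav"]] < 0) y[["Qav"]] <- 0
  if (any(y[heart_state_names[c(1:4, 6:8)]] < 0))
    stop("integration instability: negative volume; reduce dt")
  list(state = y, dv = (y[1:4] - state[1:4]) / dt, algebra = al)
}

#' Simulate the heart for whole cardiac cycles
#'
#' Runs [step_heart()] and records the aortic pressure/flow waveforms of
#' the final cycle plus cycle-to-cycle periodicity diagnostics.
#'
#' @param params a `cardiac_parameters`.
#' @param n_cycles number of cycles to run.
#' @param dt step, s.
#' @param load affine aortic drain (see [step_heart()]).
#' @param state optional initial state (continues a previous run).
#' @param dv_prev optional lagged volume rates.
#' @return list: `state`, `dv_prev`, `time` (one cycle), `pao`, `qav`,
#'   `plv` waveforms of the last cycle, `periodicity` (max relative
#'   cycle-to-cycle change of Pao per cycle), `stroke_volume`,
#'   `cardiac_output` (m^3/s), `total_volume`.
#' @export
simulate_heart <- function(params, n_cycles = 10, dt = 5e-4,
                           load = list(a = -mmhg_to_pa(5) / 1.1e8,
                                       b = 1 / 1.1e8),
                           state = heart_initial_state(params),
                           dv_prev = numeric(4)) {
  nt <- round(params$tau / dt)
  th <- seq(0, params$tau, by = dt / 2)        # half-step grid, 2 nt + 1
  ev_tab <- params$elastance(th, params$tau)
  ea_tab <- params$elastance_atrial(th, params$tau)
  out <- heart_run_cpp(unname(state[heart_state_names]), unname(dv_prev),
                       params[c("ea", "eb", "v0", "sv", "rav", "bav",
                                "lav", "rtv", "rmv", "rpv", "cao", "cpa",
                                "cvn", "rpul", "rvc")],
                       ev_tab, ea_tab, dt, nt, n_cycles, load$a, load$b)
  pc <- out$pao_cycles
  periodicity <- if (n_cycles > 1)
    vapply(2:n_cycles, function(cy)
      max(abs(pc[, cy] - pc[, cy - 1])) / max(abs(pc[, cy - 1])), 0)
  else numeric(0)
  state <- setNames(out$state, heart_state_names)
  if (min(out$pao) < params$pao_band[1] || max(out$pao) > params$pao_band[2])
    warning(sprintf(
      "aortic pressure %.0f-%.0f mmHg outside the sanity band %.0f-%.0f mmHg",
      pa_to_mmhg(min(out$pao)), pa_to_mmhg(max(out$pao)),
      pa_to_mmhg(params$pao_band[1]), pa_to_mmhg(params$pao_band[2])))
  list(state = state, dv_prev = out$dv,
       time = seq(dt, by = dt, length.out = nt),
       pao = out$pao, qav = out$qav, plv = out$plv,
       periodicity = periodicity,
       stroke_volume = sum(out$qav) * dt,
       cardiac_output = sum(out$qav) * dt / params$tau,
       total_volume = sum(state[heart_state_names[c(1:4, 6:8)]]))
}

#' Distribute aortic pressure through the upstream divider
#'
#' Given the aortic pressure and candidate cerebral inlet pressures,
#' returns the Ohmic branch flows `(Pao - P_i)/R_up,i` into each inflow
#' artery plus the arm and body branch flows draining to venous
#' pressure.
#'
#' @param pao aortic pressure, Pa.
#' @param up an `upstream_network`.
#' @param inlet_pressures named vector of cerebral inlet pressures, Pa;
#'   names must match `names(up$rup)`.
#' @return list with `inlet_flows` (named, m^3/s), `arm`, `body`.
#' @export
inlet_boundary <- function(pao, up, inlet_pressures) {
  miss <- setdiff(names(up$rup), names(inlet_pressures))
  if (length(miss)) stop("missing inlet id(s): ", paste(miss, collapse = ", "))
  q <- (pao - inlet_pressures[names(up$rup)]) / up$rup
  list(inlet_flows = q,
       arm = (pao - up$venous_pressure) / up$rarm,
       body = (pao - up$venous_pressure) / up$rbody)
}
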