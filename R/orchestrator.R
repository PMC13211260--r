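# Outer coupling loop: heart -> 0D network + autoregulation -> 1D tubes
# -> effective-resistance relaxation -> cycle-convergence test; scenario
# management, stenosis sweeps and baseline comparison.

#' Scenario configuration
#'
#' Collects the network, the model parameter sets and the numerical
#' controls of a coupled run.  Defaults follow the package's study
#' conditions: outer step 5e-4 s, 1 s cardiac cycle, 1 mm grid,
#' relaxation factor 0.5, cycle tolerance 0.01.
#'
#' @param network a `vascular_network`.
#' @param cam logical: autoregulated outlets (`TRUE`) or fixed outlet
#'   pressure (`FALSE`).
#' @param stenosis optional list `list(segment, rs_percent, ls = NULL)`.
#' @param dt outer time step, s.
#' @param tau cardiac cycle, s.
#' @param dx 1D grid spacing, m.
#' @param gamma resistance relaxation factor in `(0, 1]`.
#' @param eps_cycle cycle-convergence tolerance on the metric `Jn`.
#' @param max_cycles outer-cycle cap.
#' @param heart a [cardiac_parameters()].
#' @param upstream an [upstream_network()].
#' @param cam_params a [cam_parameters()].
#' @param q0 named baseline outlet flows (m^3/s); `NULL` calibrates
#'   them from a quasi-static autoregulation-off solve of the network.
#' @param zero_d_drive `"instantaneous"` drives the 1D boundary
#'   pressures with the full aortic waveform (the nodal field is affine
#'   in `Pao(t)`); `"cycle_mean"` holds them at the cycle-mean value.
#' @param seed integer seed recorded in the manifest (the coupled run
#'   itself is deterministic).
#' @param ... further overrides stored in the config.
#' @return a `scenario_config` list.
#' @export
scenario_config <- function(network, cam = TRUE, stenosis = NULL,
                            dt = 5e-4, tau = 1.0, dx = 1e-3,
                            gamma = 0.5, eps_cycle = 0.01,
                            max_cycles = 12,
                            heart = cardiac_parameters(tau = tau),
                            upstream = upstream_network(),
                            cam_params = cam_parameters(),
                            q0 = NULL,
                            zero_d_drive = c("instantaneous", "cycle_mean"),
                            seed = 1L, ...) {
  stopifnot(dt > 0, tau > 0, dx > 0, eps_cycle > 0,
            gamma > 0, gamma <= 1)
  zero_d_drive <- match.arg(zero_d_drive)
  structure(list(network = network, cam = cam, stenosis = stenosis,
                 dt = dt, tau = tau, dx = dx, gamma = gamma,
                 eps_cycle = eps_cycle, max_cycles = max_cycles,
                 heart = heart, upstream = upstream,
                 cam_params = cam_params, q0 = q0,
                 zero_d_drive = zero_d_drive,
                 seed = as.integer(seed), ...),
            class = "scenario_config")
}

# inlet-source nodes with their feeding segment (whose id indexes rup)
inlet_map <- function(net, upstream) {
  nodes <- net$nodes$id[net$nodes$role == "inlet_source"]
  segs <- net$segments
  df <- do.call(rbind, lapply(nodes, function(nd) {
    i <- which(segs$from == nd | segs$to == nd)
    data.frame(node = nd, segment = segs$id[i], stringsAsFactors = FALSE)
  }))
  miss <- setdiff(df$segment, names(upstream$rup))
  if (length(miss))
    stop("upstream network lacks R_up for inlet segment(s): ",
         paste(miss, collapse = ", "))
  df$rup <- upstream$rup[df$segment]
  df
}

outlet_nodes <- function(net) {
  sort(net$nodes$id[net$nodes$role == "outlet_sink"])
}

outlet_territories <- function(net) {
  setNames(net$nodes$territory, net$nodes$id)[outlet_nodes(net)]
}

# 0D boundary: Dirichlet outlet pressures + Thevenin inlets at pao
cerebral_boundary <- function(net, upstream, pao, p_out) {
  im <- inlet_map(net, upstream)
  network_boundary(
    pressures = p_out,
    thevenin = data.frame(node = im$node, pressure = pao,
                          resistance = im$rup))
}

# affine aortic drain seen by the heart: q = a + b * pao, combining the
# arm/body branches (to the upstream venous pressure) and the cerebral
# network at the current resistances and outlet pressures
equivalent_load <- function(net, upstream, resistances, p_out) {
  qc <- function(pao) {
    sol <- solve_network_flows(net, resistances,
                               cerebral_boundary(net, upstream, pao, p_out))
    im <- inlet_map(net, upstream)
    sum((pao - sol$pressures[im$node]) / im$rup)
  }
  p1 <- mmhg_to_pa(80); p2 <- mmhg_to_pa(120)
  q1 <- qc(p1); q2 <- qc(p2)
  b_cer <- (q2 - q1) / (p2 - p1)
  a_cer <- q1 - b_cer * p1
  g_sys <- 1 / upstream$rarm + 1 / upstream$rbody
  list(a = a_cer - g_sys * upstream$venous_pressure,
       b = b_cer + g_sys)
}

#' Calibrate territory baseline flows
#'
#' Runs the heart to a periodic orbit, solves the quasi-static network
#' with fixed (autoregulation-off) outlet pressures at the cycle-mean
#' aortic pressure, and assigns every outlet the mean flow of its
#' territory — the baseline flows `Q0` that the autoregulation defends.
#'
#' @param net the (complete) `vascular_network`.
#' @param config a `scenario_config`.
#' @return list: `q0` (named per outlet), `pao_mean` (Pa), `heart`
#'   (converged heart bundle for reuse).
#' @export
calibrate_q0 <- function(net, config) {
  r <- segment_resistances(net)
  outs <- outlet_nodes(net)
  p_fix <- setNames(rep(config$cam_params$p_fixed, length(outs)), outs)
  load <- equivalent_load(net, config$upstream, r, p_fix)
  hw <- heart_to_periodic(config, load)
  sol <- solve_network_flows(net, r,
                             cerebral_boundary(net, config$upstream,
                                               mean(hw$pao), p_fix))
  q_out <- sol$boundary_flows[outs]
  terr <- outlet_territories(net)
  q0 <- setNames(vapply(outs, function(o)
    mean(q_out[names(terr)[terr == terr[[o]]]]), 0), outs)
  list(q0 = q0, pao_mean = mean(hw$pao), heart = hw)
}

# run the heart until cycle-to-cycle periodicity of Pao drops below tol
heart_to_periodic <- function(config, load, state = NULL,
                              dv_prev = numeric(4), tol = 5e-3,
                              max_cycles = 30) {
  hw <- simulate_heart(config$heart, n_cycles = 5, dt = config$dt,
                       load = load,
                       state = if (is.null(state))
                         heart_initial_state(config$heart) else state,
                       dv_prev = dv_prev)
  cycles <- 5
  while (utils::tail(hw$periodicity, 1) > tol && cycles < max_cycles) {
    hw <- simulate_heart(config$heart, n_cycles = 2, dt = config$dt,
                         load = load, state = hw$state,
                         dv_prev = hw$dv_prev)
    cycles <- cycles + 2
  }
  hw$cycles <- cycles
  hw
}

#' Run the coupled multiscale model to a quasi-steady state
#'
#' Executes the outer coupling loop: per cycle the heart and the 0D
#' resistance network with autoregulated outlet pressures are solved
#' over one cardiac period (the nodal field is affine in the aortic
#' pressure at fixed outlet pressures, so the in-cycle 0D solve costs
#' two factorized solves); the nodal pressure waveforms then drive the
#' 1D compliant-tube solver in every segment; the 1D area fields update
#' the segment resistances through the relaxed effective-resistance
#' feedback; the loop stops when the cycle-to-cycle metric `Jn` falls
#' below `eps_cycle`.  Stenosed segments use the flow-dependent
#' stenosis resistance re-evaluated at the previous cycle-mean flow
#' (Picard lagging).
#'
#' @param config a `scenario_config`.
#' @param warm optional warm-start bundle from a previous run (fields
#'   `heart`, `dv_prev`, `p_out`, `q0`).
#' @return a `cowflow_run` list: cycle-mean `flows` (m^3/s, signed by
#'   reference orientation), nodal `pressures` (Pa),
#'   `territory_flows`, `jn_history`, `cam` state, `waveforms`
#'   (`time`, `pao`, `qav`, per-segment midpoint `Q` and `A`),
#'   `resistances`, `q0`, `converged`, `config`.
#' @export
run_coupled <- function(config, warm = NULL) {
  net <- config$network
  if (!is.null(config$stenosis)) {
    st <- config$stenosis
    net <- apply_stenosis_geometry(net, st$segment, st$rs_percent / 100,
                                   ls = st$ls)
  }
  r_pois <- segment_resistances(net)
  r <- r_pois
  for (sp in net$stenoses) r <- couple_stenosis(r, sp, 0, net)

  outs <- outlet_nodes(net)
  q0 <- config$q0
  if (is.null(q0) && !is.null(warm)) q0 <- warm$q0
  if (is.null(q0)) {
    cal <- calibrate_q0(net, config)
    q0 <- cal$q0
  }
  q0 <- q0[outs]

  p_out <- if (!is.null(warm) && !is.null(warm$p_out)) warm$p_out[outs]
    else setNames(rep(config$cam_params$p_fixed, length(outs)), outs)
  heart_state <- if (!is.null(warm)) warm$heart else NULL
  dv_prev <- if (!is.null(warm)) warm$dv_prev else numeric(4)

  nt <- round(config$tau / config$dt)
  jn_history <- numeric(0)
  cam_iters <- integer(0)
  prev_waves <- NULL
  init_1d <- NULL
  hw <- NULL
  sol_mean <- NULL
  cam_state <- NULL
  converged <- FALSE

  for (cyc in seq_len(config$max_cycles)) {
    load <- equivalent_load(net, config$upstream, r, p_out)
    if (is.null(heart_state)) {
      hw <- heart_to_periodic(config, load)
    } else {
      hw <- simulate_heart(config$heart, n_cycles = 1, dt = config$dt,
                           load = load, state = heart_state,
                           dv_prev = dv_prev)
    }
    heart_state <- hw$state
    dv_prev <- hw$dv_prev
    pao_mean <- mean(hw$pao)

    network_response <- function(p) {
      sol <- solve_network_flows(net, r,
                                 cerebral_boundary(net, config$upstream,
                                                   pao_mean, p))
      sol$boundary_flows[outs]
    }
    cam_state <- cam_fixed_point(config$cam_params, network_response,
                                 q0, p_init = p_out, cam = config$cam)
    p_out <- cam_state$p_outlet
    cam_iters <- c(cam_iters, cam_state$iterations)

    # nodal pressures are affine in Pao at fixed outlet pressures
    sys <- assemble_system(net, r,
                           cerebral_boundary(net, config$upstream,
                                             pao_mean, p_out))
    sol_mean <- solve_network(sys)
    sys2 <- assemble_system(net, r,
                            cerebral_boundary(net, config$upstream,
                                              pao_mean + 1000, p_out))
    sol_hi <- solve_network(sys2)
    all_nodes <- names(sol_mean$pressures)
    slope <- (sol_hi$pressures - sol_mean$pressures) / 1000
    pao_grid <- if (config$zero_d_drive == "cycle_mean")
      rep(pao_mean, nt + 1)
    else c(hw$pao[nt], hw$pao)             # periodic wrap to t = 0
    pbc <- outer(pao_grid - pao_mean, slope) +
      matrix(rep(sol_mean$pressures, each = nt + 1), nt + 1)
    colnames(pbc) <- all_nodes

    states <- network_tube_states(net, dx = config$dx, init = init_1d)
    out1d <- tube1d_run(states, pbc, config$dt)
    init_1d <- list(A = out1d$A, Q = out1d$Q)
    curr_waves <- list(Q = out1d$Qmid, A = out1d$Amid)

    if (!is.null(prev_waves)) {
      jn <- cycle_metric(prev_waves, curr_waves)
      jn_history <- c(jn_history, jn)
      if (jn < config$eps_cycle) converged <- TRUE
    }
    prev_waves <- curr_waves

    r_eff <- relax_resistance(r, out1d$reff[names(r)], config$gamma)
    for (sp in net$stenoses)
      r_eff <- couple_stenosis(r_eff, sp,
                               sol_mean$flows[[sp$segment_id]], net)
    r <- r_eff
    if (converged) break
  }
  if (!converged)
    stop("outer coupling did not converge: Jn trajectory ",
         paste(signif(jn_history, 3), collapse = ", "))

  terr <- outlet_territories(net)
  q_out <- sol_mean$boundary_flows[outs]
  territory_flows <- tapply(q_out, terr, sum)

  structure(list(
    flows = sol_mean$flows,
    pressures = sol_mean$pressures,
    boundary_flows = sol_mean$boundary_flows,
    territory_flows = territory_flows,
    jn_history = jn_history,
    cam = cam_state,
    cam_iterations = cam_iters,
    waveforms = list(time = hw$time, pao = hw$pao, qav = hw$qav,
                     Q = prev_waves$Q, A = prev_waves$A),
    resistances = r,
    q0 = q0,
    p_out = p_out,
    heart = heart_state,
    dv_prev = dv_prev,
    pao_mean = mean(hw$pao),
    cycles = length(jn_history) + 1L,
    converged = converged,
    network = net,
    config = config), class = "cowflow_run")
}

#' @export
print.cowflow_run <- function(x, ...) {
  cat("<cowflow_run> ", x$cycles, " outer cycles, final Jn = ",
      signif(utils::tail(x$jn_history, 1), 3), "\n", sep = "")
  cat("  mean Pao: ", round(pa_to_mmhg(x$pao_mean), 1), " mmHg\n", sep = "")
  tf <- m3s_to_mls(x$territory_flows)
  cat("  territory flows (mL/s): ",
      paste(names(tf), round(tf, 2), sep = "=", collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

#' Per-segment comparison against a baseline run
#'
#' Cycle-mean flow changes in percent, `100 (Q - Q_base) / |Q_base|`;
#' segments whose baseline flow is below the zero-flow threshold report
#' the absolute change instead (`delta_pct = NA`).  A reversal is
#' flagged where the sign differs and both flows exceed the threshold.
#'
#' @param result,baseline `cowflow_run` objects on the same topology
#'   modulo the variant's edited segments.
#' @param zero_frac zero-flow threshold as a fraction of the baseline
#'   mean absolute flow.
#' @return data.frame: `segment`, `q_mls`, `q_base_mls`, `delta_pct`,
#'   `delta_abs_mls`, `reversed`; territory deltas as attribute
#'   `"territories"`.
#' @export
compare_to_baseline <- function(result, baseline, zero_frac = 1e-4) {
  ids <- intersect(names(result$flows), names(baseline$flows))
  extra <- setdiff(union(names(result$flows), names(baseline$flows)), ids)
  q <- result$flows[ids]
  qb <- baseline$flows[ids]
  thr <- zero_frac * mean(abs(baseline$flows))
  small <- abs(qb) < thr
  delta_pct <- ifelse(small, NA_real_, 100 * (q - qb) / abs(qb))
  reversed <- !small & abs(q) >= thr & sign(q) != sign(qb)
  out <- data.frame(segment = ids,
                    q_mls = m3s_to_mls(q),
                    q_base_mls = m3s_to_mls(qb),
                    delta_pct = delta_pct,
                    delta_abs_mls = m3s_to_mls(q - qb),
                    reversed = reversed,
                    activated = small & abs(q) >= thr,
                    stringsAsFactors = FALSE, row.names = NULL)
  terr <- 100 * (result$territory_flows[names(baseline$territory_flows)] -
                   baseline$territory_flows) /
    abs(baseline$territory_flows)
  attr(out, "territories") <- terr
  attr(out, "edited_segments") <- extra
  out
}

#' Progressive stenosis sweep on one segment
#'
#' Runs the coupled model at each severity level (warm-starting the
#' heart, outlet pressures and baseline flows from the previous level)
#' and reports the communicating-artery responses: the first level at
#' which the ACoA flow direction flips relative to baseline, the first
#' level at which the ipsilateral PCoA activation threshold is crossed,
#' and the flow through the stenosed (ipsilateral feeding) segment per
#' level.  For segments whose baseline flow is below the zero-flow
#' threshold (a silent ACoA in a symmetric complete circle), the first
#' level at which the flow magnitude crosses the threshold is reported
#' as the direction-change level.
#'
#' @param config a `scenario_config` for the un-stenosed network.
#' @param segment segment id to narrow (e.g. `"RPCAP1"`).
#' @param levels severities in percent, strictly increasing, in
#'   `(0, 100)`.
#' @param baseline optional pre-computed baseline `cowflow_run`.
#' @param activation_frac ipsi-PCoA activation threshold as a fraction
#'   of its baseline-adjacent flow scale (default 0.2).
#' @return a `stenosis_sweep` list: `levels`, `runs`, `baseline`,
#'   `comm_flows` (per-level communicating-artery cycle means),
#'   `acoa_reversal_level`, `pcoa_activation_level`, `feeding_flow`.
#' @export
stenosis_sweep <- function(config, segment, levels = c(20, 50, 80),
                           baseline = NULL, activation_frac = 0.2) {
  stopifnot(all(levels > 0), all(levels < 100),
            !is.unsorted(levels, strictly = TRUE))
  if (is.null(baseline)) baseline <- run_coupled(config)
  side <- substr(segment, 1, 1)
  ipsi_pcoa <- paste0(side, "PCoA")
  comm <- c("ACoA", "RPCoA", "LPCoA")
  comm <- comm[comm %in% names(baseline$flows)]
  thr <- 1e-4 * mean(abs(baseline$flows))

  warm <- list(heart = baseline$heart, dv_prev = baseline$dv_prev,
               p_out = baseline$p_out, q0 = baseline$q0)
  runs <- list()
  comm_flows <- matrix(NA_real_, length(levels), length(comm),
                       dimnames = list(paste0(levels, "%"), comm))
  feeding <- numeric(length(levels))
  failures <- character(0)
  for (i in seq_along(levels)) {
    cfg <- config
    cfg$stenosis <- list(segment = segment, rs_percent = levels[i],
                         ls = config$stenosis$ls)
    run <- tryCatch(run_coupled(cfg, warm = warm),
                    error = function(e) e)
    if (inherits(run, "error")) {
      failures <- c(failures, sprintf("level %g%%: %s", levels[i],
                                      conditionMessage(run)))
      next
    }
    runs[[as.character(levels[i])]] <- run
    comm_flows[i, ] <- run$flows[comm]
    feeding[i] <- run$flows[[segment]]
    warm <- list(heart = run$heart, dv_prev = run$dv_prev,
                 p_out = run$p_out, q0 = run$q0)
  }

  flip_level <- function(seg_id) {
    qb <- baseline$flows[[seg_id]]
    for (i in seq_along(levels)) {
      q <- comm_flows[i, seg_id]
      if (is.na(q)) next
      if (abs(qb) < thr) {
        if (abs(q) >= thr) return(levels[i])
      } else if (abs(q) >= thr && sign(q) != sign(qb)) return(levels[i])
    }
    NA_real_
  }
  # ipsi-PCoA activation: |dQ| beyond a fraction of the mean baseline
  # flow magnitude of its neighbouring segments
  segs <- baseline$network$segments
  pc <- segs[segs$id == ipsi_pcoa, ]
  adj <- segs$id[(segs$from %in% c(pc$from, pc$to) |
                    segs$to %in% c(pc$from, pc$to)) & segs$id != ipsi_pcoa]
  scale_adj <- mean(abs(baseline$flows[adj]))
  act_level <- NA_real_
  for (i in seq_along(levels)) {
    dq <- abs(comm_flows[i, ipsi_pcoa] - baseline$flows[[ipsi_pcoa]])
    if (!is.na(dq) && dq > activation_frac * scale_adj) {
      act_level <- levels[i]; break
    }
  }
  structure(list(levels = levels, runs = runs, baseline = baseline,
                 comm_flows = comm_flows,
                 acoa_reversal_level = flip_level("ACoA"),
                 pcoa_activation_level = act_level,
                 ipsi_pcoa = ipsi_pcoa,
                 feeding_flow = setNames(feeding, paste0(levels, "%")),
                 failures = failures),
            class = "stenosis_sweep")
}

#' Save the key tables of a run
#'
#' Writes `flows.csv` (cycle means plus the min/max of the 1D midpoint
#' waveform per segment, mL/s), `territories.csv`, `waveforms.csv`
#' (aortic pressure and valve flow over the final cycle) and
#' `manifest.json` (scenario parameters, convergence history) to a
#' directory.
#'
#' @param result a `cowflow_run`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
save_run <- function(result, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  qw <- result$waveforms$Q
  write.csv(data.frame(segment = names(result$flows),
                       q_mean_mls = m3s_to_mls(result$flows),
                       q_min_mls = m3s_to_mls(apply(qw, 2, min)[names(result$flows)]),
                       q_max_mls = m3s_to_mls(apply(qw, 2, max)[names(result$flows)]),
                       row.names = NULL),
            file.path(dir, "flows.csv"), row.names = FALSE)
  write.csv(data.frame(time_s = result$waveforms$time,
                       pao_mmhg = pa_to_mmhg(result$waveforms$pao),
                       qav_mls = m3s_to_mls(result$waveforms$qav)),
            file.path(dir, "waveforms.csv"), row.names = FALSE)
  write.csv(data.frame(territory = names(result$territory_flows),
                       q_mls = m3s_to_mls(as.numeric(result$territory_flows)),
                       row.names = NULL),
            file.path(dir, "territories.csv"), row.names = FALSE)
  cfg <- result$config
  manifest <- list(
    package_version = as.character(utils::packageVersion("cowflow")),
    cam = cfg$cam, dt = cfg$dt, tau = cfg$tau, dx = cfg$dx,
    gamma = cfg$gamma, eps_cycle = cfg$eps_cycle, seed = cfg$seed,
    stenosis = cfg$stenosis,
    cycles = result$cycles, jn_history = result$jn_history,
    pao_mean_mmhg = pa_to_mmhg(result$pao_mean))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(dir)
}
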