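# Cerebral autoregulation (CAM) outlet boundary: per-terminal iterative
# update of arteriolar compliance and distal pressure until the
# max-norm pressure change falls below tolerance.

#' Cerebral autoregulation parameters
#'
#' Parameters of the terminal arteriolar bed shared by all outlets of a
#' territory: venous (`pv`) and intracranial (`pic`) pressures, venous
#' (`rv`) and arteriolar (`rsa`) resistances, arteriolar volume (`vsa`),
#' feedback gain (`gq`), baseline compliance (`ca0`) with upper/lower
#' spans (`dca_plus`, `dca_minus`), the convergence tolerance on outlet
#' pressure (`eps`, Pa) and the fixed outlet pressure used when
#' autoregulation is disabled (`p_fixed`).
#'
#' The defaults are per-outlet values at the scale of a terminal bed
#' carrying roughly 1 mL/s: the arteriolar drop at baseline flow is
#' about 55 mmHg and the compliance can roughly double upward
#' (vasodilation) and shrink by half (vasoconstriction).
#'
#' @param ... overrides for any default parameter.
#' @return a `cam_parameters` list (SI units).
#' @export
cam_parameters <- function(...) {
  p <- list(
    pv = mmhg_to_pa(6), pic = mmhg_to_pa(10),
    rv = 3.0e8, rsa = NULL, vsa = 1.0e-8,
    ca0 = 1.0e-10, dca_plus = 2.0e-10, dca_minus = 0.5e-10,
    gq = 5.0e-11,
    eps = 0.1, max_iter = 200, relax = 0.5,
    p_fixed = mmhg_to_pa(72))
  ov <- list(...)
  p[names(ov)] <- ov
  stopifnot(p$dca_plus > 0, p$dca_minus > 0, p$eps > 0)
  structure(p, class = "cam_parameters")
}

#' Arteriolar resistance consistent with a baseline flow
#'
#' When `params$rsa` is `NULL` the arteriolar resistance of each outlet
#' is derived from its baseline flow so that the baseline distal
#' pressure `Pv + Q0 Rv + Q0 Rsa` equals the resting outlet pressure
#' `p_fixed` — low-flow territories get proportionally higher
#' arteriolar resistance, as their smaller beds require.
#'
#' @param params a `cam_parameters`.
#' @param q0 baseline outlet flow(s), m^3/s.
#' @return arteriolar resistance(s), Pa s/m^3.
#' @export
cam_rsa <- function(params, q0) {
  if (!is.null(params$rsa)) return(rep_len(params$rsa, length(q0)))
  (params$p_fixed - params$pv - q0 * params$rv) / q0
}

#' Arteriolar compliance update
#'
#' Sigmoidal feedback on the flow deficit: for `Q < Q0` the compliance
#' rises along the `tanh` branch bounded by `+dCa+/2` (vasodilation),
#' for `Q > Q0` it falls, bounded by `-dCa-/2` (vasoconstriction).  The
#' two branches join continuously (both reduce to `Ca0` at `Q = Q0`).
#'
#' @param params a `cam_parameters`.
#' @param q current outlet flow, m^3/s (vectorized).
#' @param q0 baseline outlet flow, m^3/s (positive; vectorized).
#' @return compliance `Ca`, m^3/Pa.
#' @export
compliance_update <- function(params, q, q0) {
  stopifnot(all(q0 > 0))
  dev <- 1 - q / q0                       # positive = flow deficit
  up <- params$ca0 + 0.5 * params$dca_plus *
    tanh(2 * params$gq / params$dca_plus * dev)
  dn <- params$ca0 - 0.5 * params$dca_minus *
    tanh(2 * params$gq / params$dca_minus * (-dev))
  ifelse(dev >= 0, up, dn)
}

#' Residual of the distal-pressure equation
#'
#' Scalar residual in the candidate outlet pressure `p` with the
#' previous-iteration flow `q_prev` and current compliance `ca` frozen:
#' `((p - Pv - q Rv)/q) * (Ca0 (p - 2 Pic + Pv + q Rv)
#'  - Ca (2 p - 2 Pic - Q0 Rsa))^2 + 2 Vsa^2 - 4 Rsa Vsa^2`.
#'
#' The compliance factors are attached to the two pressure groups such
#' that the feedback is negative: an increased compliance
#' (vasodilation, responding to a flow deficit) moves the root — the
#' distal pressure — downward, which raises the outlet flow.  At
#' `Ca = Ca0` the root sits near `Pv + Q Rv + Q0 Rsa`, i.e. the venous
#' pressure plus the venous drop at the current flow plus the
#' arteriolar drop at baseline flow.
#'
#' @param p candidate outlet pressure, Pa (vectorized).
#' @param params a `cam_parameters`.
#' @param q_prev previous outlet flow, m^3/s.
#' @param ca current compliance, m^3/Pa.
#' @param q0 baseline outlet flow, m^3/s.
#' @return residual value (normalized units used by the root finder).
#' @export
cam_residual <- function(p, params, q_prev, ca, q0, rsa = cam_rsa(params, q0)) {
  g <- params$ca0 * (p - 2 * params$pic + params$pv + q_prev * params$rv) -
    ca * (2 * p - 2 * params$pic - q0 * rsa)
  ((p - params$pv - q_prev * params$rv) / q_prev) * g^2 +
    2 * params$vsa^2 - 4 * rsa * params$vsa^2
}

#' Solve the distal-pressure equation for one outlet
#'
#' Safeguarded scalar root finding on [cam_residual()]: the bracket is
#' scanned on a dense grid for the sign change nearest the initial
#' guess, then polished with [stats::uniroot()].
#'
#' @param params a `cam_parameters`.
#' @param q_prev previous outlet flow, m^3/s (positive).
#' @param ca current compliance, m^3/Pa.
#' @param q0 baseline outlet flow, m^3/s.
#' @param p_guess initial guess, Pa.
#' @param bracket search interval `(lo, hi)`, Pa; default
#'   `(Pv + q Rv, 40000)`.
#' @return the root `P_outlet,k`, Pa.
#' @export
solve_outlet_pressure <- function(params, q_prev, ca, q0,
                                  p_guess = params$p_fixed,
                                  bracket = NULL,
                                  rsa = cam_rsa(params, q0)) {
  if (q_prev <= 0) stop("cam: nonpositive outlet flow")
  if (is.null(bracket))
    bracket <- c(params$pv + q_prev * params$rv + 1e-6, 4e4)
  grid <- seq(bracket[1], bracket[2], length.out = 400)
  f <- cam_residual(grid, params, q_prev, ca, q0, rsa)
  sc <- which(diff(sign(f)) != 0)
  if (!length(sc)) {
    stop("cam root-bracket error: no sign change in [",
         signif(bracket[1], 6), ", ", signif(bracket[2], 6),
         "] Pa; residual range [", signif(min(f), 4), ", ",
         signif(max(f), 4), "]")
  }
  # The residual has up to three roots; the physical pair brackets the
  # crossing of the two compliance-weighted pressure groups, which is
  # available in closed form.  Select the sign change nearest to it
  # (p_guess breaks remaining ties).
  x1 <- -2 * params$pic + params$pv + q_prev * params$rv
  x2 <- -2 * params$pic - q0 * rsa
  denom <- 2 * ca - params$ca0
  p_centre <- if (abs(denom) > 1e-3 * params$ca0)
    (params$ca0 * x1 - ca * x2) / denom else p_guess
  if (p_centre < bracket[1] || p_centre > bracket[2]) p_centre <- p_guess
  i <- sc[which.min(abs(grid[sc] - p_centre) +
                      1e-6 * abs(grid[sc] - p_guess))]
  uniroot(cam_residual, c(grid[i], grid[i + 1]), params = params,
          q_prev = q_prev, ca = ca, q0 = q0, rsa = rsa, tol = 1e-10)$root
}

#' Iterate the autoregulation fixed point over all outlets
#'
#' Jacobi-style joint update: each iteration recomputes every outlet's
#' compliance from its previous flow, solves the distal-pressure
#' equation per outlet, under-relaxes the pressure update, and re-solves
#' the network for the new outlet flows.  Terminates when the max-norm
#' pressure change falls below `params$eps` (autoregulation enabled) or
#' immediately returns the fixed outlet pressure (disabled).
#'
#' @param params a `cam_parameters`.
#' @param network_response function mapping a named vector of outlet
#'   pressures to the named vector of outlet inflows (m^3/s); typically
#'   a closure over the 0D solve.
#' @param q0 named baseline flows per outlet, m^3/s.
#' @param p_init named initial outlet pressures, Pa.
#' @param cam logical; `FALSE` selects the fixed-pressure
#'   (autoregulation off) boundary.
#' @return a `cam_state` list: `p_outlet`, `q_outlet`, `ca`,
#'   `iterations`, `converged`, `trace` (per-iteration max pressure
#'   change, Pa).
#' @export
cam_fixed_point <- function(params, network_response, q0,
                            p_init = NULL, cam = TRUE) {
  outlets <- names(q0)
  if (is.null(p_init))
    p_init <- setNames(rep(params$p_fixed, length(outlets)), outlets)
  p <- p_init[outlets]
  if (!cam) {
    p <- setNames(rep(params$p_fixed, length(outlets)), outlets)
    q <- network_response(p)[outlets]
    return(structure(list(p_outlet = p, q_outlet = q,
                          ca = setNames(rep(params$ca0, length(outlets)),
                                        outlets),
                          iterations = 0L, converged = TRUE,
                          trace = numeric(0)),
                     class = "cam_state"))
  }
  q <- network_response(p)[outlets]
  trace <- numeric(0)
  ca <- setNames(rep(params$ca0, length(outlets)), outlets)
  rsa <- setNames(cam_rsa(params, q0), outlets)
  relax <- params$relax
  dp_prev <- Inf
  for (k in seq_len(params$max_iter)) {
    ca <- compliance_update(params, q, q0)
    # an outlet transiently starved during the iteration is treated as
    # carrying a trickle of 1% of baseline for the pressure update
    q_eff <- pmax(q, 0.01 * q0)
    p_star <- vapply(outlets, function(o)
      solve_outlet_pressure(params, q_eff[[o]], ca[[o]], q0[[o]],
                            p_guess = p[[o]], rsa = rsa[[o]]), 0)
    p_new <- p + relax * (p_star - p)
    q <- network_response(p_new)[outlets]
    dp <- max(abs(p_new - p))
    # adaptive damping: back off when the update is not contracting
    if (dp > dp_prev) relax <- max(relax / 2, 0.02)
    dp_prev <- dp
    trace <- c(trace, dp)
    p <- p_new
    if (dp < params$eps)
      return(structure(list(p_outlet = p, q_outlet = q, ca = ca,
                            iterations = k, converged = TRUE,
                            trace = trace), class = "cam_state"))
  }
  stop("cam non-convergence after ", params$max_iter,
       " iterations; |dP| trajectory tail: ",
       paste(signif(utils::tail(trace, 5), 4), collapse = ", "))
}
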