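# Young-Tsai localized stenosis model: flow-dependent effective
# resistance, the diameter-reduction severity metric, and the couplings
# into the 0D resistance matrix and the 1D reference-area profile.

#' Stenosis geometric specification
#'
#' Holds the healthy diameter `D0`, the stenotic diameter `Ds`, the
#' stenosis length `Ls`, the derived areas, and the empirical
#' turbulent/viscous coefficients `Kt = 1.52` and
#' `Kv = 32 (0.83 Ls + 1.64 Ds) A0^2 / (D0 As^2)`.
#'
#' @param segment_id affected segment id.
#' @param d0 healthy diameter, m.
#' @param ds stenotic diameter, m (`0 < Ds <= D0`).
#' @param ls stenosis length, m.
#' @return a `stenosis_spec` list.
#' @export
stenosis_spec <- function(segment_id, d0, ds, ls) {
  if (ds <= 0 || ds > d0) stop("stenotic diameter must satisfy 0 < Ds <= D0")
  if (ls <= 0) stop("stenosis length must be positive")
  a0 <- pi * d0^2 / 4
  as <- pi * ds^2 / 4
  structure(list(segment_id = segment_id, d0 = d0, ds = ds, ls = ls,
                 a0 = a0, as = as, kt = 1.52,
                 kv = 32 * (0.83 * ls + 1.64 * ds) * a0^2 / (d0 * as^2),
                 rs_percent = stenosis_degree(d0, ds)),
            class = "stenosis_spec")
}

#' Degree of stenosis
#'
#' `Rs = 100 (D0 - Ds) / D0` — percent diameter reduction relative to
#' the healthy vessel.
#'
#' @param d0 healthy diameter, m.
#' @param ds stenotic diameter, m.
#' @return severity in percent.
#' @export
stenosis_degree <- function(d0, ds) {
  if (any(ds > d0) || any(ds <= 0)) stop("need 0 < Ds <= D0")
  100 * (d0 - ds) / d0
}

#' Flow-dependent effective resistance of a stenosis
#'
#' `Reff(Q) = Kv mu / (A0 D0) + Kt rho / (2 A0^2) (A0/As - 1)^2 |Q|`:
#' a viscous term (reducing to roughly the Poiseuille drop over the
#' stenosis length when `Ds = D0`) plus an inertial contraction loss
#' proportional to `|Q|` that vanishes in the healthy limit.
#'
#' @param spec a [stenosis_spec()].
#' @param q volumetric flow, m^3/s (vectorized; sign-symmetric).
#' @param mu viscosity, Pa s.
#' @param rho density, kg/m^3.
#' @return effective resistance, Pa s/m^3.
#' @export
stenosis_resistance <- function(spec, q, mu, rho) {
  spec$kv * mu / (spec$a0 * spec$d0) +
    spec$kt * rho / (2 * spec$a0^2) * (spec$a0 / spec$as - 1)^2 * abs(q)
}

#' Substitute a stenosed segment's resistance into the 0D network
#'
#' Picard (lagged-coefficient) linearization of the `|Q|` nonlinearity:
#' the segment's resistance becomes the Poiseuille value of its
#' non-stenotic length plus the stenosis model evaluated at the
#' previous-iteration flow.
#'
#' @param resistances named per-segment resistances, Pa s/m^3.
#' @param spec a [stenosis_spec()].
#' @param q_prev previous-iteration flow through the segment, m^3/s.
#' @param net the `vascular_network` (for the segment length and blood).
#' @return updated resistance vector.
#' @export
couple_stenosis <- function(resistances, spec, q_prev, net) {
  i <- which(net$segments$id == spec$segment_id)
  if (!length(i)) stop("unknown segment id: ", spec$segment_id)
  s <- net$segments[i, ]
  mu <- net$blood$viscosity
  l_rest <- max(s$length - spec$ls, 0)
  r_rest <- if (l_rest > 0) poiseuille_resistance(l_rest, s$radius, mu) else 0
  resistances[[spec$segment_id]] <- r_rest +
    stenosis_resistance(spec, q_prev, mu, net$blood$density)
  resistances
}

#' Steady flow through a single stenosed tube by Picard iteration
#'
#' Solves `Q (R_lin + c |Q|) = dP` by lagged-coefficient iteration,
#' the same linearization used inside the outer coupling loop.
#'
#' @param spec a [stenosis_spec()].
#' @param dp driving pressure drop, Pa.
#' @param net network providing blood properties and segment geometry.
#' @param tol convergence tolerance on `|Q_k - Q_(k-1)| / Q`, default
#'   1e-10.
#' @param max_iter iteration cap.
#' @return list `q`, `iterations`, `history`.
#' @export
stenosis_picard_flow <- function(spec, dp, net, tol = 1e-10,
                                 max_iter = 100) {
  r <- segment_resistances(net)
  q <- dp / r[[spec$segment_id]]
  hist <- q
  for (k in seq_len(max_iter)) {
    r2 <- couple_stenosis(r, spec, q, net)
    q_new <- dp / r2[[spec$segment_id]]
    hist <- c(hist, q_new)
    if (abs(q_new - q) <= tol * max(abs(q_new), 1e-30))
      return(list(q = q_new, iterations = k, history = hist))
    q <- q_new
  }
  stop("stenosis Picard iteration did not converge in ", max_iter, " steps")
}

# reference-area profile over a stenosed segment: As over a centred span
# of length ls, with 2-cell cosine-smoothed shoulders.
stenotic_area_profile <- function(x, length, A0, spec) {
  half <- spec$ls / 2
  centre <- length / 2
  dxs <- if (length(x) > 1) x[2] - x[1] else length
  sh <- 2 * dxs                       # shoulder width
  d <- abs(x - centre)
  w <- ifelse(d <= half, 1,
              ifelse(d >= half + sh, 0,
                     0.5 * (1 + cos(pi * (d - half) / sh))))
  A0 + w * (spec$as - A0)
}
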