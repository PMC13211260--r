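---
title: "Methods: the cowflow multiscale cerebral circulation model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the cowflow multiscale cerebral circulation model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its science: the model
components and their assumptions, the parameters that matter, the
numerical choices, and the places where the design was genuinely open
and a decision had to be made.

# The coupled model

## Heart and upstream circulation

The systemic driver is a closed-loop lumped model: four cardiac
chambers with time-varying elastance
$P_{cm} = (E_{cm,A}\,e(t) + E_{cm,B})(V_{cm} - V_{cm,0}) + S_v \dot V_{cm}$,
ideal-diode atrioventricular and pulmonary valves, an aortic valve with
viscous, Bernoulli and inertial losses, and lumped aortic, pulmonary
and venous compliances.  The ventricular activation $e(t)$ is the
normalized double-Hill waveform (shape parameters $\alpha_1 = 0.303$,
$\alpha_2 = 0.508$, $n_1 = 1.32$, $n_2 = 21.9$); the atria use a
$\sin^2$ bump of width $0.17\,\tau$ starting at $0.80\,\tau$, giving a
late-diastolic atrial kick.  Two deliberate treatments:

* The valve diode multiplies the whole momentum balance, which freezes
  a stale positive $Q_{av}$ at closure; the stepper therefore also
  clamps $Q_{av}$ to zero whenever $P_{lv} \le P_{ao}$ — the standard
  ideal-diode treatment.
* The viscoelastic term $S_v \dot V_{cm}$ uses the previous step's
  volume rates (one-step lag), which keeps the right-hand side
  explicit; at $S_v$ of order $10^5$–$10^6$ Pa·s/m³ the lag is
  negligible at $\Delta t = 5\times10^{-4}$ s.

Every flow in the loop appears once with each sign in the volume
equations, so total blood volume is a linear invariant and RK4
conserves it to machine precision — the suite asserts $10^{-9}$
relative per cycle.

Chamber elastances, valve coefficients and compliances are
literature-scale values calibrated once so the default loop produces
an aortic pressure of roughly 65–105 mmHg (mean ≈ 87 mmHg) and a
cardiac output near 5 L/min at a 1 s cycle; they are plain entries of
`cardiac_parameters()` and are meant to be edited.  The aorta is a
single compliance node: pulse-wave propagation along the aorta is
deliberately outside the model, so the cerebral inlets see a common
aortic pressure behind their individual resistances
($R_{up}$ ≈ $6\times10^7$ Pa·s/m³ for the carotids, $10^8$ for the
vertebrals; arm and body branches $6\times10^8$ and $1.8\times10^8$).
The vertebral/carotid $R_{up}$ ratio, together with the fixture's
vessel calibres, was chosen so that at baseline the anterior and
posterior junction pressures balance — the defining property of a
healthy complete circle, in which the communicating arteries carry
almost no flow.

## 0D cerebral network

Each segment is a Poiseuille resistance $R = 8\mu l/(\pi r^4)$
($\mu = 0.0045$ Pa·s, $\rho = 1050$ kg/m³).  Interior nodes obey
Kirchhoff mass balance, giving the sparse symmetric system
$\mathbf{B}P = \mathbf{G}_b P_b + Q_b$; `assemble_system()` builds
exactly this block structure (diagonal = sum of incident conductances,
off-diagonals $-G_{mn}$ for interior neighbours, boundary couplings in
$\mathbf{G}_b$), with node ordering fixed by sorted id for
reproducibility.  The inlets are folded in as Thévenin sources (aortic
pressure behind $R_{up,i}$), so the divider and the network are solved
simultaneously rather than through an extra fixed-point loop.  Within
a cardiac cycle the outlet pressures are constant, hence the nodal
field is *affine in the aortic pressure*; the whole in-cycle 0D
solution costs two factorized solves, and cycle means equal the
solution at the mean aortic pressure.

## Autoregulated outlets

Each terminal bed iterates (a) the compliance law
$C_a = C_{a0} + \tfrac12\Delta C_a^{\pm}
\tanh[2G_q/\Delta C_a^{\pm}(1 - Q/Q_0)]$, with the vasodilation span
$\Delta C_a^+$ above and the vasoconstriction span $\Delta C_a^-$
below, branches joined continuously (and with equal slope $G_q$) at
$Q = Q_0$; and (b) a scalar distal-pressure equation whose root is the
outlet pressure
$$\frac{P - P_v - QR_v}{Q}\,
  \bigl[C_{a0}(P - 2P_{ic} + P_v + QR_v)
      - C_a(2P - 2P_{ic} - Q_0 R_{sa})\bigr]^2
  + 2V_{sa}^2 - 4R_{sa}V_{sa}^2 = 0 .$$
Two structural decisions here were genuinely open:

* **Which compliance multiplies which pressure group.**  The two
  candidate groupings agree at $C_a = C_{a0}$ but have opposite
  feedback signs.  Attaching $C_a$ to the *second* group (as above) is
  the negative-feedback choice: vasodilation ($C_a$ up, flow deficit)
  moves the root downward, lowering the distal pressure and restoring
  flow.  The alternative attaches $C_a$ to the first group and is
  numerically a positive feedback — a dilating bed would raise its own
  outlet pressure and starve itself further — so physiology selects
  the grouping.
* **Root selection.**  The residual has up to three roots; the two
  physical ones bracket the closed-form crossing of the pressure
  groups, $P_c = (C_{a0}X_1 - C_aX_2)/(2C_a - C_{a0})$, at a distance
  set by $V_{sa}$.  The solver scans a dense grid and polishes the
  sign change nearest $P_c$ with `uniroot`, which keeps the iteration
  off a spurious low-pressure branch that otherwise captures starved
  outlets.

The per-outlet baseline flow $Q_0$ is taken from the
autoregulation-off solve of the complete network and averaged within
each territory (`calibrate_q0()`), so all terminals of a territory
defend the same flow.  The arteriolar resistance is derived per outlet
as $R_{sa} = (P_{fix} - P_v - Q_0R_v)/Q_0$ — low-flow territories get
proportionally higher bed resistance — because a single shared
$R_{sa}$ cannot put every territory's baseline distal pressure at the
resting value (72 mmHg) simultaneously.  Remaining defaults:
$P_v = 6$ mmHg, $P_{ic} = 10$ mmHg, $R_v = 3\times10^8$ Pa·s/m³,
$V_{sa} = 10^{-8}$ m³, $C_{a0} = 10^{-10}$ m³/Pa,
$\Delta C_a^+ = 2\times10^{-10}$, $\Delta C_a^- = 0.5\times10^{-10}$,
$G_q = 5\times10^{-11}$ m³/Pa.  These are per-outlet, literature-scale
substitutes chosen once for a terminal bed carrying ~1 mL/s (arteriolar
drop ≈ 55 mmHg at baseline), not fitted quantities.

The outlets are updated Jacobi-style with under-relaxation starting at
0.5; the loop gain depends on territory resistance and can exceed the
contraction bound of a fixed factor, so the relaxation halves (floor
0.02) whenever an update fails to contract.  Convergence is the
max-norm change of outlet pressures below $\varepsilon = 0.1$ Pa
(distinct from the cycle tolerance 0.01 of $J_n$).  Because
autoregulation acts on a time scale of seconds, the fixed point is
computed once per cardiac cycle on cycle-mean flows, and outlet
pressures are held within the cycle.  An outlet transiently starved
during the iteration (non-positive lagged flow) is treated as carrying
1% of its baseline flow for the pressure update, which keeps severe
scenarios (near-occlusion without autoregulation) solvable.

## 1D compliant tubes

Each segment solves the cross-section-averaged equations
$\partial_t A + \partial_x Q = 0$ and
$\partial_t Q + \partial_x(Q^2/A) + (A/\rho)\partial_x P
 + 8\pi\mu Q/(\rho A) = 0$, closed by the affine tube law
$P = P_e + P_0 + K(x)\,(A - A_0(x))$ with stiffness
$K = 4\pi E_s h/(3A_0(x))$ and reference pressure $P_0 = 85$ mmHg at
$A = A_0$.  Because the law is affine in area (not the square-root
law), the wall coefficient $E_s h$ plays the role of an *effective*
stiffness: the default $E_s = 4\times10^7$ Pa, $h = 0.3$ mm gives a
wave speed $c = \sqrt{4\pi E_s h/(3\rho)} \approx 7$ m/s and an area
pulsation of ~10% over a 40 mmHg pulse — the physiologically anchored
quantities.

Numerics: MacCormack predictor/corrector on the conservative form
(compiled core), with the pressure gradient differenced with the same
forward/backward bias as the fluxes and the friction term as a local
source.  The continuity update telescopes, so interior mass balance
holds to machine precision (asserted in the suite).  Boundary and
junction closure use the Riemann invariants of the affine law,
$W_\pm = u \pm 2c$ with $c = \sqrt{KA/\rho}$: prescribed-pressure
nodes convert pressure to a boundary-face area and take the velocity
from the outgoing invariant; junction nodes enforce static-pressure
continuity plus mass conservation, solved per substep by safeguarded
Newton (static rather than total pressure; the difference is
$O(\rho u^2)$, two orders below the working pressures here).  Ghost
cells are linearly extrapolated through the boundary face so the
prescribed pressure acts at the segment end, not half a cell outside —
this is what brings the steady single-tube resistance within 1% of
Poiseuille.  The grid uses $\Delta x = 1$ mm with at least ten cells
per segment (short communicating arteries get a proportionally finer
spacing); the outer step is $\Delta t = 5\times10^{-4}$ s, and the
core sub-cycles it under a CFL guard (safety 0.9) because the wave
speed, not the outer step, sets the stable step.  Initial conditions
are $Q = 0$, $A = A_0$.

The per-cycle effective resistance is
$R^{\text{eff}} = \overline{\int_0^l 8\pi\mu/A(x,t)^2\,dx}$ —
the pointwise Poiseuille density, whose constant-area limit is exactly
$8\mu l/(\pi r^4)$ — time-averaged over the cycle window
(`reff_reduce` alternatives `max`/`end` are available in
`effective_resistance()`).  Resistances relax as
$R^{n+1} = (1-\gamma)R^n + \gamma R^{\text{eff},n}$ with
$\gamma = 0.5$.  Convergence of the outer loop uses
$$J_n = \frac{1}{\#N}\sum_{\omega\in N}
 \left[\frac{\max_t|Q^n_\omega - Q^{n-1}_\omega|}{\max_t|Q^{n-1}_\omega|}
     + \frac{\max_t|A^n_\omega - A^{n-1}_\omega|}{\max_t|A^{n-1}_\omega|}
 \right] < 0.01,$$
with waveforms sampled at each segment's midpoint.  Segments whose
previous-cycle flow never exceeds $10^{-12}$ of the network mean
(silent communicating arteries) contribute only their area term —
otherwise a healthy circle could never satisfy the criterion.  The
default run converges in about 4 outer cycles; non-convergence after
`max_cycles` (12) is an error carrying the $J_n$ trajectory.

## Stenosis

`apply_stenosis_geometry()` records $D_s = D_0(1 - R_s)$ and a
stenotic span $L_s$ (default 20% of the segment, centred, with
two-cell cosine shoulders in the 1D reference area to avoid grid
shocks).  The 0D resistance of the affected segment becomes Poiseuille
over the non-stenotic length plus the Young–Tsai term
$R^{\text{eff}}(Q) = K_v\mu/(A_0D_0) + K_t\rho/(2A_0^2)(A_0/A_s-1)^2|Q|$
evaluated at the previous cycle-mean flow (Picard lagging of the
$|Q|$ nonlinearity, consistent with the outer loop's lagged coupling).
The viscous term reduces to approximately the Poiseuille drop over
$L_s$ in the healthy limit, which is why the stenosis term replaces
only the stenotic span rather than the whole segment.  $R_s = 1$
(occlusion) is rejected — topological removal is the right model for
that, and the fetal-type variant provides it.

## Path-flow inversion

Post-processing only — it never alters the simulation.  Feasible paths
are all simple inlet-to-outlet paths whose traversal of every segment
agrees with the sign of its converged cycle-mean flow; segments with
$|Q| < 10^{-4}$ of the mean flow magnitude are admissible in both
directions, because silent communicating arteries must not block
enumeration.  Paths are ordered lexicographically by node sequence, and
enumeration beyond `max_paths` ($10^5$) is an explicit error, never a
silent truncation.  The constraint system stacks segment rows (signed
±1 incidences against signed flows), source rows and sink rows with
weights $\lambda_1 = \lambda_2 = 1$ (raise $\lambda_1$ to pin measured
inflows).  The inversion
$\min_{x\ge0}\tfrac12\|Wx-b\|^2 + \delta\|x\|_1 + \sigma\sum_pR_px_p^2$
defaults to $\delta = 10^{-6}\max|b|$ and
$\sigma = 10^{-9}/\mathrm{median}(R_p)$ — small enough to leave the
fitted flows essentially unbiased, large enough to select the sparse
trunk-branch decomposition among equal-fit candidates.  The solver is
an exact active-set method for the nonnegative quadratic program
(Lawson–Hanson structure on $Q = W^\top W + 2\sigma\,\mathrm{diag}R_p$,
$c = W^\top b - \delta$), deterministic and verified in the suite
against the KKT conditions and against an independent nonnegative
lasso.  Attribution normalizes path flows per sink; sinks with zero
total flow are flagged `NA` rather than propagating NaN.

The robustness study perturbs $b' = b(1 + \eta\xi)$,
$\xi \sim U[-1,1]$ i.i.d. per entry, re-solves per replicate, and
scores each path by the fraction of replicates in which it stays
active and within ±50% of its unperturbed flow (inactive paths score
the fraction of replicates in which they stay inactive).  The ±50%
band and the activity threshold ($10^{-6}$ of the maximum path flow)
are this package's explicit definition — the score is reported with
the replicate matrix so any other summary can be recomputed.  The
replicate stream uses R's RNG under a caller-supplied seed and is
bitwise reproducible.

# The synthetic network

`make_cow_fixture()` emulates a complete adult CoW: ICA (r = 2.0 mm,
l = 120 mm), VA (1.5 mm, 100 mm), BA (1.6 mm, 25 mm), PCA-P1 (1.1 mm,
8 mm), PCA-P2 (1.05 mm, 40 mm), PCoA (0.7 mm, 15 mm), MCA (1.4 mm,
30 mm), ACA-A1 (1.1 mm, 14 mm), ACA-A2 (1.1 mm, 25 mm), ACoA (0.7 mm,
3 mm), and per territory two terminal segments (0.6–0.7 mm, 20 mm),
~30 segments in all.  The values are literature-plausible calibres
chosen once so that (i) baseline territory flows land in clinical
ranges (MCA ≈ 2.5, ACA ≈ 1.2, PCA ≈ 1.1 mL/s per side, total ≈ 9.5
mL/s) and (ii) the trans-communicating pressure differences are nearly
zero — both well-documented properties of healthy circles.  The
fixture is exactly mirror-symmetric (asserted by homolog-name mapping);
an optional seeded log-normal `jitter` breaks the symmetry for
robustness experiments.  Variants edit exactly one segment: fetal-type
removes a PCA-P1; hypoplastic sets an ACA-A1 to 0.5 mm diameter
(threshold < 0.8 mm).

What the fixture does *not* emulate: image-derived tortuosity and
calibre variation along vessels, more than two terminals per
territory, anatomical left/right asymmetries, or distal leptomeningeal
anastomoses.  Passing tests therefore demonstrate the solvers and the
collateral mechanics of the ring — early ACoA engagement, later
ipsilateral PCoA recruitment, autoregulatory buffering — not
patient-specific prediction.

A consequence of exact symmetry worth flagging: the baseline ACoA flow
is numerically zero with an arbitrary sign, so a "direction reversal"
against baseline is undefined for it.  `stenosis_sweep()` therefore
reports, for segments whose baseline flow is below the zero-flow
threshold, the first severity level at which the flow magnitude
crosses the threshold as the direction-change level — the level at
which a silent collateral acquires a definite direction.
`compare_to_baseline()` likewise reports absolute (not percentage)
changes for such segments and flags them `activated` rather than
`reversed`.

# Problem sizes and determinism

The default study conditions are: 1 s cycles at $\Delta t =
5\times10^{-4}$ s; ~30 segments × ≥10 cells in 1D with CFL
sub-stepping; outer loop to $J_n < 0.01$ (typically 4 cycles);
autoregulation to 0.1 Pa (typically ≤ 50 iterations); 20 random
networks (≤ 60 nodes) for the 0D oracle; 50 replicates at
$\eta = 0.05$ for the robustness study.  A full baseline run takes a
few seconds on one core; the acceptance script recomputes everything
in well under a minute.  All coupled runs are deterministic —
randomness enters only through the robustness study and the random
oracle networks, both seeded.

# Known limitations

* The affine tube law makes $E_s$ an effective parameter; wave-speed
  and pulsation targets, not tensile measurements, justify its value.
* The heart's S2-level parameters and the autoregulation bed constants
  are substitute defaults at physiological scale, not fits to any
  dataset; clinical comparison would require re-identification.
* Autoregulation is quasi-steady (per-cycle); dynamic-autoregulation
  phenomena (rate-dependent responses, CO₂ reactivity) are out of
  scope.
* The path decomposition is unique only up to the regularization's
  tie-breaking on degenerate networks; the robustness study is the
  tool for judging which paths are trustworthy.
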