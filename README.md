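# cowflow

Multiscale 0D–1D simulation of the cardio-cerebrovascular circulation,
centred on the Circle of Willis (CoW) — the arterial ring that
redistributes cerebral blood flow through its communicating arteries
when anatomy varies or vessels narrow.  `cowflow` answers questions a
cerebrovascular modeller asks: how silent are the communicating
arteries in a complete, healthy circle; in what order do the anterior
(ACoA) and posterior (PCoA) communicating arteries recruit as a feeding
artery progressively narrows; how much of the perfusion deficit does
cerebral autoregulation absorb; and which inflow artery supplies which
territory.

## The model

* **Heart (0D).**  A closed-loop, four-chamber time-varying-elastance
  model.  Chamber pressure follows
  `P_cm = (E_A e(t) + E_B)(V_cm − V_0) + S_v dV_cm/dt`, the aortic
  valve is an ideal diode with viscous, Bernoulli and inertial losses
  (`dQ_av/dt = D_av (P_lv − P_ao − R_av Q_av − B_av Q_av|Q_av|)/L_av`),
  and the aortic node drains through an upstream resistance divider
  (`R_arm`, `R_body`, `R_up,i`) into the four cerebral inflow arteries
  (two internal carotid, two vertebral).
* **Cerebral network (0D).**  Every segment is a Poiseuille resistance
  `R = 8 μ l/(π r⁴)`; nodal mass balance gives the sparse symmetric
  system `B P = G_b P_b + Q_b`, solved jointly with the inlet divider
  (Thévenin coupling) and yielding every signed segment flow
  `Q_ij = G_ij (P_i − P_j)`.
* **Autoregulated outlets.**  Each terminal bed iterates an arteriolar
  compliance law `C_a = C_a0 + ½ΔC_a tanh[2G_q/ΔC_a (1 − Q/Q_0)]`
  and a distal-pressure equation until outlet pressures change by less
  than a tolerance; the feedback defends each territory's baseline
  flow `Q_0`.  Autoregulation can be disabled (fixed outlet pressure)
  for comparison.
* **1D compliant tubes.**  Cross-section-averaged mass/momentum
  equations with an affine tube law close each segment; a MacCormack
  scheme (compiled core, automatic CFL sub-stepping) propagates pulse
  waves, junctions couple by Riemann invariants, and per-cycle
  effective resistances `R_eff = ∫ 8πμ/A(x,t)² dx` feed back into the
  0D network under relaxation until the cycle-to-cycle metric `J_n`
  drops below 0.01.
* **Stenosis.**  The Young–Tsai empirical pressure drop
  `R_eff(Q) = K_v μ/(A_0 D_0) + K_t ρ/(2A_0²)(A_0/A_s − 1)² |Q|`
  with `K_t = 1.52`, `K_v = 32(0.83 L_s + 1.64 D_s) A_0²/(D_0 A_s²)`,
  Picard-lagged in `|Q|`; severity is the diameter reduction
  `R_s = 100 (D_0 − D_s)/D_0` %.
* **Path-flow inversion.**  The converged segment flows are decomposed
  into nonnegative source-to-sink path flows: DFS enumeration of
  direction-consistent simple paths, conservation constraints
  `W x = b` over segments/sources/sinks, and the convex program
  `min_{x≥0} ½‖Wx − b‖² + δ‖x‖₁ + σ Σ R_p x_p²` (sparsity plus
  Murray-style pumping cost), yielding the attribution matrix
  `θ_ij` — the fraction of sink `j` supplied by source `i` — and a
  multiplicative-noise robustness study.

No patient geometry ships with the package: `make_cow_fixture()`
generates a documented, bilaterally symmetric synthetic CoW (two ICAs,
two VAs merging into the basilar artery, paired A1/A2, MCA, P1/P2,
ACoA, paired PCoAs, and two terminal segments per territory) with
literature-plausible radii and lengths, plus the fetal-type PCA-P1 and
hypoplastic ACA-A1 variants.

## Worked example

```r
library(cowflow)

net <- make_cow_fixture("complete")
run <- run_coupled(scenario_config(net))
run
#> <cowflow_run> 4 outer cycles, final Jn = 0.00529
#>   mean Pao: 87.3 mmHg
#>   territory flows (mL/s): LACA=1.18, LMCA=2.48, LPCA=1.11, RACA=1.18, RMCA=2.48, RPCA=1.11

m3s_to_mls(run$flows[c("ACoA", "RPCoA", "LPCoA")])
#>     ACoA    RPCoA    LPCoA
#>  0.00000 -0.00281 -0.00281
```

The healthy circle carries ~9.5 mL/s of total cerebral blood flow with
territory flows in clinical ranges (MCA ≈ 2.5, ACA ≈ 1.2, PCA ≈ 1.1
mL/s per side), and the communicating arteries are essentially silent
(< 0.1% of ICA flow) — the signature of a complete CoW.

```r
basis <- enumerate_paths(net, run$flows)
sol   <- solve_pathflow(build_constraints(basis, run$flows), basis)
round(100 * territory_attribution(sol, basis), 1)
#>         RACA LACA RMCA LMCA RPCA LPCA
#> LICA_in    0 99.8  0.0  100    0    0
#> LVA_in     0  0.0  0.1    0   50   50
#> RICA_in  100  0.0 99.9    0    0    0
#> RVA_in     0  0.2  0.0    0   50   50
```

Each MCA/ACA territory is fed by its ipsilateral carotid; the PCA
territories split evenly between the vertebral arteries — the anterior
and posterior circulations are effectively decoupled at baseline.
Narrowing the right PCA-P1 changes that:

```r
sw <- stenosis_sweep(scenario_config(net), "RPCAP1", c(20, 50, 80),
                     baseline = run)
sw$acoa_reversal_level     # 20  — the ACoA acquires a direction first
sw$pcoa_activation_level   # 50  — the ipsilateral PCoA engages later
m3s_to_mls(sw$feeding_flow)
#>     20%     50%     80%
#> 1.02300 0.63560 0.07746
```

The anterior communicating artery is the earliest collateral, followed
by ipsilateral PCoA compensation, while flow through the stenosed
feeder collapses monotonically — the progressive transition from a
complete circle toward a fetal-type posterior supply.

A thin command-line interface wraps the same functions:

```sh
inst/cli/cowflow fixtures --variant complete --out net.json
inst/cli/cowflow run --network net.json --out out/
inst/cli/cowflow sweep --network net.json --segment RPCAP1 --levels 20,50,80 --out sweep/
```

## Network file format

`load_network()`/`save_network()` use a JSON schema
`{units: {length}, blood: {viscosity, density}, nodes: [...],
segments: [...]}` — nodes carry `id`, `role`
(`inlet_source`/`interior`/`outlet_sink`), a `territory` label on
outlets, and optional coordinates; segments carry `id`, `from`, `to`,
`length`, `radius`, `wall_thickness`, `youngs_modulus` (SI; `mm`/`cm`
unit headers are converted on load).  A `nodes.csv`/`segments.csv` pair
is the alternative.  A ready-made example lives at
`inst/extdata/cow_complete_synthetic.json` (synthetic geometry, not a
patient measurement).

## Limitations

The synthetic geometry is a stand-in for image-derived networks; the
aorta is lumped (no aortic wave propagation); leptomeningeal distal
collaterals are not represented; heart and autoregulation parameters
are literature-scale defaults, not patient-specific fits.  See the
methods vignette (`vignettes/cowflow-methods.Rmd`) for the full account
of the model, its numerical choices and their rationale.
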