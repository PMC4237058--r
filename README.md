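# rainstp

Analytical characterization of Tsodyks–Markram short-term synaptic
plasticity (STP), plus a conductance-based leaky integrate-and-fire (LIF)
network simulator and a characterization-guided search for STP parameters
that keep recurrent spiking networks alive.

## The science

A Tsodyks–Markram synapse tracks two state variables — utilization *u*
(facilitation, decaying with τ_F) and availability *x* (depression,
recovering with τ_D) — and transmits with effective weight
μ = A·x·u¹, where u¹ = u(1−U)+U and U is the baseline release
probability. Under a steady presynaptic rate *r* the state has the closed
form

    u* = τF·U·r / (1 + τF·U·r)
    u¹* = u*(1−U) + U
    x* = 1 / (1 + τD·u¹*·r)
    μ* = A·x*·u¹*

Differentiating μ*(r) gives a rational expression in *r* whose sign is
controlled by a downward quadratic, so every synapse switches from
facilitating (dμ/dr > 0) to depressing (dμ/dr < 0) at a single **critical
firing rate**

    r_crit = −1/τF + sqrt((1−U) / (U·τD·τF))     (τ in seconds, r in Hz)

A non-positive r_crit means the synapse is depressing at every rate. The
package exposes this characterization (`r_crit()`, `dmu_dr()`), the
fixed-point calibration of the scale constant A against a static weight
(`calibrate_A()`, so that μ(r*) = W exactly), the partition of r_crit into
brain-rhythm classes (N/δ/θ/α/β/γ, `classify_rhythm()`), the facilitating-
and depressing-everywhere volumes of (U, τD, τF)-space (`pn_volumes()`),
and rejection sampling from any rhythm class (`sample_udf_class()`).

Around the analytics sits a clock-driven simulator for sparse 80/20
excitatory/inhibitory LIF networks with conductance synapses, static or
STP-modulated per edge (`build_rain_topology()`, `simulate_network()`), the
jump-start protocol for self-sustained random asynchronous irregular
network (RAIN) activity with its terminal-window rate and ISI-CV metrics
(`run_rain_trial()`, `static_weight_sweep()`), and the guided parameter
search over WXYZ network signatures (`run_search()`).

## Worked example

```r
library(rainstp)

p <- stp_params(U = 0.1, tau_D = 0.12, tau_F = 0.15)
r_crit(p$U, p$tau_D, p$tau_F)
#> [1] 15.69401
classify_rhythm(r_crit(p$U, p$tau_D, p$tau_F))
#> [1] "B"

# the same synapse, driven through a staircase of presynaptic rates:
dual_regime_trace(p, rates = seq(1, 11, 2))$mu_steady
#> [1] 0.1001121 0.1099988 0.1272180 0.1435839 0.1571031 0.1674178
dual_regime_trace(p, rates = seq(18, 28, 2))$mu_steady
#> [1] 0.1823443 0.1822875 0.1810184 0.1788368 0.1759868 0.1726634
```

The steady efficacy climbs across 1–11 Hz (facilitating, below r_crit) and
falls across 18–28 Hz (depressing, above it) — the dual-regime behavior
the critical rate predicts. Calibration pins the operating point:

```r
p$A <- calibrate_A(0.04, p, r_star = 12)
stp_steady_state(p, 12)$mu_star
#> [1] 0.04
```

A command-line front end (`exec/rainstp`) wraps the same functions:
`rainstp rcrit -U 0.1 -D 0.12 -F 0.15` prints `15.7`; other subcommands
are `steady`, `volumes`, `demo-dual`, `rain`, `sweep` and `search`.

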