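---
title: "Models and methods: ligand gradients, migration metrics and gated statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: ligand gradients, migration metrics and gated statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gradlab)
```

`gradlab` implements the quantitative layer of growth-factor chemotaxis
experiments on adherent cells such as retinal Müller glia: how a ligand
gradient develops in the assay hardware, how cell movement is measured
against it, how receptor expression shifts are quantified by qPCR, and how
conditions are compared statistically. This vignette explains the models,
their assumptions, the tunable parameters, and the design decisions that
were genuinely open.

## 1. Transport model

Both assay platforms are reduced to the same one-dimensional problem: a
slender diffusion path connecting two well-mixed compartments. Along the
path the ligand concentration $C(x,t)$ (ng/mL) obeys the
convective–diffusion equation

$$\frac{\partial C}{\partial t} + \bar u\,\frac{\partial C}{\partial x}
  = D\,\frac{\partial^2 C}{\partial x^2},$$

with diffusivity $D$ (cm²/s) and bulk velocity $\bar u$ (m/s). The assays
are quiescent — reagents are loaded and left to transport — so
$\bar u = 0$ by default; the advective term is retained (upwind
discretisation) for perfusion scenarios.

**gLL microfluidic device** (`solve_gll()`): two 98 µL reservoirs joined
by a 1.3 cm microchannel of 192.6 µm hydraulic diameter. The reservoirs
are some 200× the channel volume (0.48 µL), so they are modelled as 0-D
well-mixed compartments coupled to the channel ends by flux continuity,
and the channel carries the full PDE. Only the hydraulic diameter of the
channel is specified by the device description; the cross-section
defaults to a square of that side ($3.71\times10^{-4}$ cm²) and is
configurable for other aspect ratios. The position origin is the source
end of the channel, $+x$ toward the sink.

**Transwell insert** (`solve_transwell()`): 100 µL (top, cell-seeded) and
600 µL (bottom, ligand-loaded) compartments separated by a 10 µm
track-etched membrane with 8 µm pores. Transport crosses the pore space
only, so fluxes use the open-pore area $\varepsilon A$ with porosity
$\varepsilon = \rho_\text{pore}\,\pi r_\text{pore}^2$ (default
$\rho_\text{pore} = 10^5$/cm², giving $\varepsilon \approx 0.050$) and the
in-pore diffusivity $D/\lambda$ with tortuosity $\lambda = 1$ for straight
track-etched pores — equivalently an effective membrane diffusivity
$D\varepsilon/\lambda$ over the full area. The compartment volumes and
membrane area (0.33 cm²) follow the 6.5 mm insert format; none of the
three is printed in assay protocols with full consistency, so all are
configurable.

**Diffusivities.** EGF uses the literature value $2.0\times10^{-6}$
cm²/s. VEGF is estimated from the Stokes–Einstein relation
$D = k_BT/(6\pi\eta r)$ with hydrodynamic radius 3.6 nm, $T = 310$ K and
$\eta = 6.9\times10^{-4}$ Pa·s (water at 37 °C), giving
$9.14\times10^{-7}$ cm²/s. When only a molecular weight is known,
`radius_from_mass()` supplies a globular-protein scaling
$r = 0.88\,\mathrm{MW}^{1/3}$ (nm, kDa) — constants configurable.

**Numerics.** Finite-volume method of lines: cell-centred second-order
central differences (default 130 cells for the channel, 30 across the
membrane), integrated by `deSolve::lsoda` with a banded Jacobian — the
state ordering (source, cells, sink) is tridiagonal. The finite-volume
flux form conserves mass identically at the semi-discrete level, so the
measured drift is integrator round-off (relative drift $\sim10^{-15}$,
asserted $<10^{-6}$ in the tests). The compartment/channel time-scale
contrast is severe (hours against a ~1 s membrane diffusion time, or a
~5×10⁴ h reservoir exchange time against a ~500 h channel time), which is
why an implicit stiff integrator rather than explicit stepping is used;
it also makes very long equilibration horizons cheap. Default tolerances
are `rtol = 1e-9` and an absolute tolerance of $10^{-12} C_0$; negative
concentrations beyond $10^{-6} C_0$ abort with advice to refine the grid.
Two boundary modes exist: `"finite"` (default; reservoirs deplete/fill)
and `"fixed"` (held concentrations), since reports of comparable
simulations do not always state which was used.

Verification is against two closed forms, both asserted in the test
suite: the early-time channel profile against the semi-infinite-medium
solution $C = C_0\,\mathrm{erfc}(x/2\sqrt{Dt})$ (within 2% where
$C/C_0 > 0.05$; measured ~0.1%), and the transwell compartment difference
against the two-compartment law
$\Delta C(t) = C_0 e^{-t/\tau}$ with
$\tau = \frac{V_tV_b}{V_t+V_b}\,\frac{T_h}{D_\text{eff}A}$ (within 5%;
measured ~0.004%). For the default transwell, $\tau \approx 1.57$ h — the
gradient is substantially gone within a working day, which is the known
limitation of transwell gradients that motivates microfluidic devices;
the gLL channel, by contrast, still evolves at 48 h.

**Steady-state detection** (`steady_state_time()`): the assay convention
calls a gradient steady when concentrations change by less than 5% over
an observation window. The window length and measurement location are
genuinely underdetermined in assay descriptions, so both are explicit
arguments; relative change is evaluated only where $C/C_0$ exceeds a
floor (default 0.01) to avoid 0/0 amplification in the still-empty far
channel. The routine makes no claim about any particular device reaching
steady state "overnight" — it reports what the simulated field does.

## 2. Migration metrics

Trajectories follow the tracking convention: frames every 30 min for 6 h
(13 positions, $n = 12$ intervals), only cells present at $t = 0$
tracked. The path length is the accumulated distance

$$PL = \sum_{i=1}^{n} \sqrt{(x_{i+1}-x_i)^2 + (y_{i+1}-y_i)^2},$$

and a cell is *motile* when its movement exceeds 20 µm (about two cell
diameters) — strictly greater than, on the path length by default. A
configuration switch (`on = "net"`) applies the threshold to net
displacement instead: per-condition summaries in which the motile-only
mean path length falls *below* 20 µm (as happens for unstimulated
controls) are only self-consistent under a net-displacement reading, so
both modes are exposed and `summarize_condition()` reports all-cell and
motile-only statistics without guessing intent. Standard deviations use
the $n-1$ denominator. Transwell data support counts only (cells on the
membrane underside), so `transwell_summary()` reports per-device count
means, SDs, and the fold change versus control — both the absolute means
and the fold are emitted.

## 3. ΔΔCT expression analysis

`fold_change()` implements the conventional ΔΔCT estimator
$2^{-\Delta\Delta CT}$ with $\Delta CT = \overline{CT}_\text{gene} -
\overline{CT}_\text{ref}$ (GAPDH reference by default), replicate CT
values averaged *before* differencing, and amplification efficiency
assumed exactly 2 — no efficiency correction, no standard curves. The
module is gene-label agnostic: it imposes no mapping between primer names
and receptor names. Two invariants worth noting: fold changes are
invariant to any global CT shift (reference normalisation), and
noise-free tables generated by `generate_ct_table()` round-trip exactly
through `expression_matrix()`.

## 4. Gated statistical comparison

`compare_groups()` reproduces the two-branch procedure: every group is
checked by Shapiro–Wilk at $\alpha = 0.05$; if all pass, one-way ANOVA
with Tukey HSD post-hoc; if any fails, Kruskal–Wallis with Dunn's
all-pairs post-hoc (mid-ranks, tie correction) under Holm step-down
correction. The per-group aggregation rule ("any failure routes the
whole comparison non-parametric") is the package's choice — one branch
is applied per dataset, and requiring all groups to pass is the
conservative reading. A zero-variance group is degenerate for
Shapiro–Wilk and routes non-parametric with a warning. Flags follow the
reporting convention: `*` for $p<0.05$, `**` for $p<0.01$. Note a
consequence of the gate: under three null-normal groups the parametric
branch fires at rate $0.95^3 \approx 0.86$, not 0.95. Dunn's test is
implemented in-package (z statistics on the Kruskal–Wallis ranks) since
no installed package provides it; ANOVA, Tukey, Kruskal–Wallis, Shapiro
and Holm all come from `stats`. The suite checks the Kruskal–Wallis
statistic against a brute-force rank oracle over all 3⁶ tie-saturated
assignments of six observations, Holm against the hand step-down rule,
and the gated pipeline's null type-I error rate (asserted within
[0.03, 0.07] at $\alpha = 0.05$ over 1000 seeded repeats).

## 5. Synthetic cohorts and calibration

No raw trajectory recordings are distributed with published summaries, so
the generator is the package's declared stand-in, and its defaults *are*
the study conditions: 15 cells per cohort, 12 steps of 30 min, starting
positions uniform in a 500 µm window (cells are seeded over the
sink-side channel region), seeded and bit-reproducible.

**Step model.** Each step displaces a cell by $(d, 0)$ plus isotropic
Gaussian noise of per-axis SD $\sigma$, so the step length is
Rice-distributed with mean
$\sigma\sqrt{\pi/2}\,L_{1/2}(-d^2/2\sigma^2)$ and second moment
$2\sigma^2 + d^2$ (evaluated with scaled Bessel functions; verified
against direct quadrature of the Rice density). Path length is the sum
of $n$ i.i.d. step lengths, giving closed-form cohort moments.

**Why heterogeneity.** A homogeneous-step cohort bounds the path-length
dispersion at $SD(PL) \le \overline{PL}\sqrt{(4/\pi-1)/n}$ — about 15% of
the mean at $n = 12$ (the Rayleigh limit). Published per-condition
summaries show 12–40%, so no constant-drift walk can realise them; this
is the usual signature of cell-to-cell variability in migratory vigour.
`calibrate_walk()` therefore solves within the Rice family when the
target is reachable (`drift_cv = 0`), and otherwise fixes the within-cell
directedness at $k_0 = d/\sigma = 1$ and adds a per-cell Gamma(mean 1)
speed scale multiplying both drift and noise, whose coefficient of
variation comes from the exact decomposition
$\mathrm{Var}(PL) = n v_w(1+cv^2) + (nm)^2cv^2$. With
`heterogeneity = FALSE` the infeasible case errors, stating the bound.
Calibration targets the *all-cell* path-length moments (not motile-only),
which sidesteps the control-condition ambiguity of §2 above. Recovery is
asserted in the tests: per-condition mean within 2% and SD within 10%
over 200 seeded cohorts of 15 cells (~1 s per condition).

**Gradient coupling.** Optionally the drift is recomputed each step from
a simulated field: drift $= d + s\cdot\max(0, -\partial C/\partial x)$
at the cell's current channel position (frame $+x$ points toward the
ligand source), with sensitivity $s$ in µm/step per (ng/mL/cm). This
produces positive mean displacement toward the source on monotone
profiles, increasing with $s$; it is a phenomenological coupling, not an
inference tool for real chemotactic sensitivity.

**CT tables and counts.** `generate_ct_table()` fixes the reference gene
at CT 18, target genes at CT 25 under control, offsets treated
conditions by $-\log_2(\text{fold})$, and adds optional Gaussian CT
noise. `generate_transwell_counts()` draws per-device counts from a
rounded, zero-truncated Gaussian. Reference calibration presets
(`gll_reference_summaries()`, `ta_reference_summaries()`,
`receptor_fold_targets()`) carry the published per-condition summaries.

**What passing tests do and do not show.** The generator reproduces
first and second moments of path length, count distributions and fold
matrices — not persistence, contact inhibition, proliferation, drift
that saturates, or heavy-tailed step lengths of real cells. Agreement of
the analysis pipeline on synthetic cohorts validates the pipeline's
arithmetic and the calibration algebra, not any biological claim.

## 6. Problem sizes and reproducibility

Defaults used throughout the shipped tests and the acceptance script,
chosen as comfortable working sizes for the models involved: 130/260
channel cells (default/refined), 30 membrane cells, 48 h gLL and 18 h
transwell horizons plus one 10× -slowest-time-constant equilibration run,
200 seeded cohorts of 15 cells per condition for recovery checks, and
1000 repeats for the null-calibration of the gated procedure. Every
stochastic routine takes an explicit seed; identical seeds give
bit-identical outputs. `reproduce()` chains generator → analysis →
statistics for the three built-in presets and writes all tables as CSV.

## 7. Known limitations

* The 1-D + compartment reduction ignores entrance effects, reservoir
  concentration gradients, and any 2-D/3-D structure; it is accurate in
  the slender-channel, well-stirred-reservoir regime the devices are
  designed for.
* Constant reservoir volumes (no evaporation, no sampling withdrawal);
  no ligand binding, uptake or degradation.
* Trajectory analysis assumes complete, evenly sampled tracks from cells
  present at $t=0$; shorter tracks are flagged, not imputed.
* The ΔΔCT estimator inherits its usual biases (efficiency exactly 2,
  reference-gene stability).
* Fold changes of small-count triplicates are ratio estimates and carry
  upward small-sample bias; the absolute means are reported alongside.
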