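---
title: "Composing lumped arterial models from bond-graph modules"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Composing lumped arterial models from bond-graph modules}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bondnet)
```

## The modelling problem

Whole-organ circulation models are too large to write down in one piece, yet
most published models are monoliths: coupling two of them means editing
equations by hand, which is slow and easily violates conservation laws.
`bondnet` addresses this for lumped-parameter vascular networks with two
ingredients:

1. **Energy-conserving modules.** Every sub-model is a bond graph: components
   (`R`, `C`, `I`, `Se`, `Sf`) exchange power through bonds carrying the
   co-variables potential `u` (pressure, J m⁻³) and flow `v` (m³ s⁻¹),
   connected at junctions where either the potential is common and flows sum
   to zero (0-junction) or the flow is common and potentials sum to zero
   (1-junction). Because every junction satisfies `Σᵢ uᵢ·vᵢ = 0`, any
   network of such modules is automatically consistent with energy
   conservation — composition cannot create or destroy energy.

2. **Annotation-driven composition.** Modules carry semantic triples
   (variable, physical property, entity term). Matching triples across two
   modules identify the coupling points, and the coupling itself is realised
   through *auxiliary port variables*: zero-defaulted extra terms in the
   junction conservation equations that become references to the partner
   module's variables when bound. Module definitions are never edited; an
   isolated module (all ports at 0) and a composed one share the same file.

## Vessel segments from three templates

A vessel segment of length `l` and radius `r` is reduced to three lumped
parameters under Poiseuille flow and a thin elastic wall:

$$R = \frac{8\nu l}{\pi r^4}, \qquad
  I = \frac{\rho l}{\pi r^2}, \qquad
  C = \frac{2 \pi r^3 l}{E h},$$

with the wall thickness given by the empirical two-exponential fit
$h = r\,(a e^{b r} + c e^{d r})$. The global constants and their defaults
are:

| parameter | meaning | default | unit |
|---|---|---|---|
| `nu`  | blood viscosity | 0.004 | J s m⁻³ |
| `rho` | blood density | 1050 | J s² m⁻⁵ |
| `E`   | Young's modulus of the wall | 0.4×10⁶ | J m⁻³ |
| `a`, `c` | wall-thickness fit amplitudes | 0.2802, 0.1324 | – |
| `b`, `d` | wall-thickness fit rates | −505.3, −11.14 | m⁻¹ |

Three templates cover every position in an open (acyclic) arterial tree:

* **intermediate** — inlet 1-junction carrying `R` and `I` in series, with
  one auxiliary *potential* port `u_x` (the upstream pressure arrives here);
  a bond to the outlet 0-junction, which carries the wall branch (a
  1-junction with the compliance `C` and an optional series viscoelastic
  resistance) and four auxiliary *flow* ports `vx1..vx4`. Four is the
  a-priori cap on how many branches any vessel may feed; it is a
  construction-time option.
* **initial** — the same core, but a flow source `Sf` (the cardiac output)
  feeds the inlet through a leading 0-junction instead of the `u_x` port.
* **terminal** — the same inlet, then the wall 0-junction, then a 1-junction
  with the terminal bed resistance and a pressure source `Se` at venous
  pressure. No flow ports.

### Why the initial segment splits its compliance

An ideal flow source in series with an inertance through a storage-free
junction is an index-2 constraint: the source would pin the inertance state,
and the algebraic subsystem becomes exactly singular (the package reports
this as `singular algebraic subsystem`, and a unit test documents it). The
inlet node of the tree must therefore be compliant. The initial template
consequently places half of its compliance (`C/2`) on the leading source
junction and half on the outlet — the same two-half-branch arrangement used
for viscoelastic walls, with the halves placed at the two segment ends —
keeping the segment's total compliance at `C` while making every composed
network a regular (index-1-free) ODE system. A consequence worth knowing:
a tree with `n` segments has `n + 1` compliance states and `n` inertance
states, one state per storage component.

### Boundary values the literature leaves open

Terminal bed resistance and venous pressure are inputs, not derivable from
segment geometry. The defaults are `venous_pressure = 0` and
`terminal_resistance = 3e8` J s m⁻⁶, sized so that a handful of beds in
parallel reproduces a systemic vascular resistance of order 1.3×10⁸ J s m⁻⁶
and arterial pressures in the physiological range on small test trees. Both
are per-segment options. Viscoelastic wall resistances default to 0 (pure
compliance): no accepted value exists for them, so enabling them is an
explicit modelling decision.

## Merging, lumping, cloning

`suggest_mappings()` joins the annotation tables of two modules: an *exact*
proposal needs the same entity term, the same property term, and exactly one
side being a port or a source. Accepting a flow mapping in
`merge_modules()` binds **both** directions at once: the upstream flow port
takes the downstream inlet flow, and the downstream potential port `u_x`
takes the upstream node pressure. Binding only one side would inject flow
without the corresponding back-pressure — a half-coupled join that breaks
the power balance at the seam — so the reciprocal binding is implied rather
than left to the user. When several exact proposals compete for one port the
merge refuses with an ambiguity error: the workflow keeps a human decision
in the loop rather than guessing.

`lump()` executes a composition plan — a tree whose leaves are modules —
depth-first left-to-right with binary merges (`n` leaves, `n−1` merges),
auto-accepting exact proposals. Merge order does not matter for the
resulting dynamics; a test verifies associativity by comparing both
bracketings of a three-segment chain against the monolithically built
network. Element ids are namespaced once, as `<module>.<element>`, however
deep the plan nests.

`clone_module()` deep-copies a module under a new prefix and rewrites entity
terms (e.g. left → right), which is how symmetric limbs are built once and
reused. Cloning preserves structure exactly, so a clone simulates
bit-identically to its original under identical inputs — the package treats
that as a testable guarantee, not an aspiration.

The shipped plan `adan_plan()` records the hierarchy used for the
86-segment open-loop arterial network: seven top-level lumped subdivisions
(heart outflow, head and neck, trunk, two arms, two legs). The full
topology and geometry of that network are an optional external input; the
shipped file documents the hierarchy with representative leaf names only.

## From network to ODE system

All five constitutive laws are linear, so the "symbolic" layer is exact
sparse linear algebra rather than a general computer-algebra system: every
junction equality, signed sum equation (with port terms), and constitutive
relation is a linear form over the algebraic variables (junction shared
variables, bond co-variables) with a right-hand side over
`(1, states, inputs)`. The square system is solved once, yielding an exact
state-space model

$$\dot x = A x + B w(t) + b_0,$$

states being the stored volume `q` of every `C` (`u = q/C`, `q̇ = v`) and
the flow `v` of every `I` (`v̇ = u/I`). Algebraic loops (R-only meshes) are
handled by the same solve. Numerical choices:

* variable ordering is lexicographic (radix sort), so generated systems are
  byte-reproducible;
* rows and columns are equilibrated before the solve — deep trees span many
  orders of magnitude in `R` (∝ r⁻⁴), which is harmless mathematically but
  fails naive condition checks; structural singularities (e.g. the index-2
  configuration above) still fail with an exact zero pivot;
* unbound ports enter as the constant 0 and are *recorded* in
  `sys$port_warnings` rather than raised: runnable isolated modules are part
  of the design.

`power_audit()` re-evaluates `Σ uᵢvᵢ` per junction along a stored
trajectory, including port power. For consistent traces the residuals are at
machine precision (~10⁻¹⁶ relative); a trace perturbed by 10 % is flagged at
~10⁻¹ — the audit is a tamper/consistency check, not a solver-accuracy
metric.

## Simulation and comparison

`simulate_ode()` integrates with deSolve's `lsoda` (stiff-capable, adaptive)
from all-zero initial states by default, storing states and every junction
and bond variable on a uniform grid (default 1 ms). Zero initial states are
arbitrary but harmless: `last_cycle()` extracts the final steady beat (e.g.
the 9–10 s window of a 10 s run), which is what gets compared. When a
window of exactly one period is passed in again, `last_cycle()` returns it
unchanged — extraction is idempotent by design.

The cardiac inflow is a periodic two-term Gaussian
$f(t) = \sum_{i=1}^{2} a_i \exp[-((t \bmod T - b_i)/c_i)^2]$. The package
defaults (`a = (4.2, 0.8)×10⁻⁴ m³ s⁻¹`, `b = (0.15, 0.30) s`,
`c = (0.08, 0.12) s`, `T = 1 s`) produce a single-peak ejection of ≈76 mL
per beat at 60 bpm. These are this package's own plausible-waveform choice —
they are **not** a fit to any published recording, and waveform files are
accepted wherever a waveform is.

Trace agreement is quantified by the normalised root-mean-square error

$$\mathrm{NRMSE} = 100 \times
  \frac{\sqrt{\tfrac1n \sum_i (\hat y_i - y_i)^2}}{y_{\max} - y_{\min}}\ \%,$$

normalised by the reference trace's max–min range (undefined, and an error,
for constant references). `compare_runs()` applies it per variable,
linearly interpolating onto the coarser grid when runs were sampled
differently.

## What the synthetic fixtures do and do not show

`toy_tree()` (five segments, fixed geometry) and `random_tree()`
(seed-reproducible trees with a child/parent radius ratio of 0.8, length =
10 r, branching ≤ 4) exist so that every claim is testable without external
data. They emulate the *structure* of an arterial tree — templated segments,
bifurcations, terminal beds — with plausible parameter magnitudes. They do
not reproduce measured anatomy: radius ratios are fixed rather than
following a branching law, lengths are tied to radii, and no measured
geometry or waveform enters. Green tests therefore demonstrate correctness
of construction, composition, conservation and integration — not agreement
with physiological recordings. The problem sizes used by the test-suite
(trees up to 30 segments, 10 s simulations at 1 ms output) keep a full run
at around a minute on one core while still exercising multi-level lumping.

## Known limitations

* Pressure–area laws are linear; no collapse, tapering or nonlinear
  compliance.
* Open trees only: anastomoses (vessel loops) would need a fourth, merging
  template, which is deliberately out of scope.
* Entity terms are opaque strings; no ontology reasoning, no inference of
  annotations from variable names.
* No differential-algebraic systems beyond index 1: configurations whose
  algebraic subsystem is singular are rejected, not index-reduced.
* No transformer/gyrator elements; purely hydraulic networks.
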