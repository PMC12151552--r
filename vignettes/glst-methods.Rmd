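---
title: "Cell-structured cubature electrostatics: model, calibration and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cell-structured cubature electrostatics: model, calibration and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glst)
```

## The problem and the decomposition

Computing Coulomb energies and forces for $N$ point charges costs $O(N^2)$
pairwise terms, which dominates the run time of molecular simulations. This
package accelerates the calculation for non-periodic (open-boundary) systems
by the classic Ewald split of the kernel,

$$\frac{1}{r} \;=\; \frac{\operatorname{erfc}(\alpha r)}{r}
  \;+\; \frac{\operatorname{erf}(\alpha r)}{r},$$

handling the smooth long-range part through per-cell *structure factors* so
an atom interacts with a whole distant cell at once. The box is tiled by
cubic cells of (at least) the direct-space cutoff. Pairs within a cell or
its 26 nearest neighbors get the full $1/r$ directly; all more distant cell
pairs are covered by the long-range kernel of one *alpha group*.

Alpha groups are concentric Chebyshev shells of cells around each target
cell with thickness doubling outward ($[2,2], [3,4], [5,8], \dots$, clipped
at the grid edge). Each group carries its own convergence parameter
$\alpha_g$, chosen by `choose_alpha()` as the smallest value with
$\operatorname{erfc}(\alpha_g d_{\min})/d_{\min} \le \varepsilon$ at the
shell's closest approach $d_{\min}$, so replacing $1/r$ by
$\operatorname{erf}(\alpha_g r)/r$ beyond the short-range region neglects a
remainder provably below the threshold. Because each shell has its own
$\alpha$, the near field keeps the plain Coulomb form (there is no single
complementary term to subtract); the decomposition is exact up to the
per-group erfc remainders. The shell distance bounds are conservative
corner-to-corner estimates: $d_{\min} = (s_{\min}-1)\,\min(\text{edge})$
and $d_{\max} = \sqrt{3}\,(s_{\max}+1)\,\max(\text{edge})$.

## The cubature

The long-range kernel is represented through the radial integral

$$\frac{\operatorname{erf}(\alpha r)}{r}
  = \frac{4\alpha\zeta}{\pi}\int_0^1 e^{-\zeta^2 s^2}
    j_0(2\alpha\zeta s r)\, ds + O(e^{-\zeta^2}),$$

with $j_0(x)=\sin(x)/x$ the spherical average of a plane wave. The finite
truncation $\zeta$ is set by $e^{-\zeta^2} \le \varepsilon/10$, leaving most
of the error budget to quadrature. Discretizing the radial integral with
the positive half of a Gauss–Legendre rule (roots $s_n$, weights $w_n$
summing to 1) and the spherical average with an antipodally symmetric
angular rule (unit vectors $\hat t_m$, weights $u_m$ summing to 1) gives
fused wave-vector nodes and weights

$$\vec k_{nm} = 2\alpha\zeta\, s_n\, \hat t_m,\qquad
  W_{nm} = \frac{4\alpha\zeta}{\pi}\, w_n\, e^{-\zeta^2 s_n^2}\, u_m ,$$

so that $\operatorname{erf}(\alpha|\vec r|)/|\vec r| \approx \sum_j W_j
\cos(\vec k_j\cdot\vec r)$. The leading constant absorbs both the
even-integrand factor (negative radial roots) and the antipodal factor
(lower hemisphere); it is pinned down by the $r\to 0$ limit
$\sum_j W_j \to 2\alpha/\sqrt{\pi}$ and verified empirically by
calibration, which removes any convention ambiguity.

Per atom, the basis functions are $C_j^a = q_a\cos(\vec k_j\cdot\vec r_a)$
and $S_j^a = q_a\sin(\vec k_j\cdot\vec r_a)$ — the sine part is stored as a
real quantity, under which the atom–cell energy is
$E_{aC} = k_e\sum_j W_j (C_j^a C_j^C + S_j^a S_j^C)$ with the per-cell sums
$C_j^C, S_j^C$ (the structure factors), and the force is
$\vec F_a = k_e \sum_j W_j \vec k_j (S_j^a C_j^C - C_j^a S_j^C)$. This is
algebraically identical to the complex-exponential convention with an
imaginary sine factor. Per-atom long-range energies count each ordered pair
once in each direction; the total halves their sum, forces are not halved,
and reported per-atom energies use half-shares throughout so they always
sum to the total and comparisons against the direct oracle are
convention-free.

### Angular rules: product grids and t-designs

An equal-weight point set that integrates all spherical harmonics through
degree $t$ (a spherical $t$-design) is the natural angular rule, and the
package can load published design tables (`load_spherical_design()`) and
generate small ones by seeded optimization
(`generate_spherical_design()`, practical up to $t \approx 9$). The
strengths the kernel actually demands, however, grow with the phase bound
$2\alpha\zeta d_{\max}$ — roughly $t \approx 100$–$200$ at tight
thresholds — far beyond what runtime optimization can certify. Calibration
therefore uses a weighted product rule (Gauss–Legendre in $\cos\theta$
crossed with an even number of equispaced azimuths):
exact through degree $t$ by construction, antipodally symmetric,
deterministic at any strength, and with about $(t+1)^2/2$ hemisphere
points — the same node economy as a symmetric design. The cubature
formulas above treat both uniformly ($u_m = 1/M_t$ recovers the
equal-weight case).

### Calibration and the error contract

`calibrate_cubature()` certifies each group's cubature empirically instead
of relying on printed node-selection rules:

1. *Radial order*: the smallest Gauss–Legendre order whose residual against
   the exact one-dimensional kernel (over 64 radii spanning
   $[d_{\min}, d_{\max}]$) is below a third of the budget, found by binary
   search (quadrature convergence is superexponential, so the residual is
   monotone for practical purposes).
2. *Angular strength*: the smallest $t$ whose fused cubature meets half the
   budget on a small probe set, again by binary search, followed by a
   denser certification probe (128 uniform radii crossed with 50 seeded
   random directions plus up to 64 rotated rule points, evaluated in
   compiled code via a radius-recurrence so no trigonometric calls appear
   in the inner loop). If certification falls short the strength grows by
   6% steps until it passes.
3. The certificate covers the *gradient* of the kernel as well (tolerance
   $\max(2\varepsilon, 10^{-11})$; the floor keeps the search away from the
   rounding floor of multi-million-node sums), because force accuracy is
   part of the method's contract, not a corollary of energy accuracy.

The certified residual is a per-pair bound. Across a system the residuals
compose like a random walk over remote pairs; measured on the 2959-atom
benchmark box, the per-atom RMSE in kcal/mol is about
$k_e\,\langle q^2\rangle \sqrt{N}$ times the certified residual. To make
the *measured* RMSE of energies and force components meet the user's
threshold $\varepsilon$ — the property the method advertises —
`compute_total()` maps $\varepsilon$ to the per-pair kernel tolerance

$$\varepsilon_{\text{kernel}} =
  \frac{\varepsilon}{k_e\,\langle q^2\rangle\,\sqrt{N}}
  \quad\text{clamped to } [5\times 10^{-13},\ \varepsilon],$$

exposed as `kernel_tolerance()` and overridable via
`config$kernel_epsilon`. The lower clamp reflects double precision: beyond
it, longer node lists stop reducing the measured error. This mapping is the
package's replacement for analytic node-count selection theory; it is
deliberately conservative (the random-walk model ignores the additional
cancellation from neutral, compact molecules, so measured errors typically
land one to three orders below the target).

Calibrations are cached for the session keyed by
$(\alpha, d_{\min}, d_{\max}, \varepsilon_{\text{kernel}})$, so sweeps and
repeated runs over one geometry pay the search once.

## Evaluation pipeline and complexity

`compute_total()` chains: grid construction → stable counting sort of atoms
by cell → alpha groups → per-group calibration → short-range pass →
long-range pass, and maps results back to the input atom order. The
long-range pass computes per-cell structure factors, then per-cell *remote*
sums over each group's shell, then per-atom energies and forces — two basis
evaluations per atom per group, never storing per-atom basis vectors (the
memory-lean choice). Remote sums use three-dimensional inclusive prefix
sums over the cell grid (Chebyshev shells are axis-aligned boxes, and open
boundaries are natural clipping), which is mathematically identical to
iterating the explicit long-range neighbor list; the package implements
both, uses the prefix-sum route in the compiled kernel, and tests their
equality. Node dimensions are chunked to bound memory (about 8 million
cell×node entries in flight).

The work is $2 N J$ atom×node products for the long-range part ($J$ = total
nodes over groups, independent of $N$ at fixed geometry and threshold) plus
the short-range pair count — hence linear scaling, which the size sweep
verifies on operation counts rather than wall-clock so the result is
hardware-independent. The cutoff trades the two terms against each other;
at desk-scale atom counts the long-range term dominates every valid grid,
so the U-shaped total-cost curve with an interior optimum only emerges at
large $N$ (the acceptance suite demonstrates it on the 1.59-million-atom
composition, counts only). All arithmetic is double precision; an opt-in
`single_precision_trig` flag rounds the trigonometric evaluations through
single precision to emulate the broader error distributions of
speed-optimized implementations.

Grids with fewer than four cells on the largest axis get no alpha groups
and fall back to exact all-pairs Coulomb for every cell pair. A
three-cells-per-axis grid does contain separation-2 cell pairs, but a
doubling-shell decomposition cannot cover them consistently with the
26-neighbor short-range convention, and at such sizes direct summation is
both exact and cheap — so smallness, not shell bookkeeping, decides.

## The synthetic benchmark systems

`build_salt_water_box()` emulates the benchmark compositions
(`table1_recipes()`: 38 to 1,588,868 atoms in 8–256 Å cubes): rigid 3-site
waters (O–H 0.9572 Å, H–O–H 104.52°, charges $-0.834/+0.417$) plus
Na$^+$/Cl$^-$ ions, placed by seeded rejection sampling with a 2.0 Å
minimum separation between molecule anchor sites (a cell hash keeps
placement linear; R's RNG is used inside the compiled sampler so
`set.seed()` governs everything). Orientations are uniform random
rotations. These boxes reproduce the charge magnitudes and spatial density
that drive electrostatic error statistics; they are *not* equilibrated
liquid structure — no hydrogen-bond network, no ion solvation shells, no
Lennard-Jones or bonded terms — so passing tests demonstrate the accuracy
and scaling of the electrostatics solver on realistic charge densities,
not fidelity of any water model. A water count per volume within 30% of
0.0334 Å$^{-3}$ is asserted for the benchmark rows.

## Parameters that matter

| parameter | units | default | role |
|---|---|---|---|
| `cutoff` | Å | user input | cell edge; splits direct vs cubature work |
| `epsilon` | kcal/mol (RMSE target) | user input | drives $\alpha_g$, $\zeta$, node counts via the tolerance mapping |
| `min_separation` | Å | 2.0 | packing distance of synthetic boxes |
| `ke` | kcal·Å/(mol·e²) | 332.0637141 | Coulomb constant, applied once at the end |
| `node_cap` | nodes | 4×10⁶ | calibration failure guard |
| `kernel_epsilon` | — | mapped | per-pair tolerance override |

Internal cubature math runs in $(e^2/\text{Å})$ units; the Coulomb constant
scales energies and forces once at the end.

## Numerical choices and degenerate inputs

* Stretched cells (`edge = box/floor(box/cutoff)`) keep the tiling exact
  and every edge at or above the cutoff; no remainder slabs.
* The counting sort is stable (ties by original index), so results are
  reproducible and the sort round-trips bit-exactly.
* Hemisphere membership uses the deterministic tie rule $z>0$, or $z=0$ and
  ($y>0$, or $y=0$ and $x>0$); product-rule azimuths are offset by half a
  step so no point lands on the tie boundary.
* Coincident atoms with nonzero charge product raise a singularity error
  naming the pair; coincident zero-charge atoms are tolerated.
* Atoms must lie in $[0, \text{box})$; there is no wrapping anywhere
  (periodic boundaries are out of scope), and boundary cells simply have
  fewer neighbors.
* `remove_net_force()` subtracts the mean force — the orthogonal projection
  onto the zero-net-force subspace — bringing the net force to machine
  precision (the cubature already leaves it at the $10^{-12}$ scale in
  double precision).
* Degenerate sweeps (one point, all-invalid cutoffs) are flagged in the
  returned table, never errors.

## Problem sizes used in the validation suite

The test suite validates against the $O(N^2)$ oracle on the 2959-atom
composition (32 Å box, 6.4 Å cutoff, thresholds $10^{-4}$ and $10^{-8}$)
and runs threshold-monotonicity comparisons on the 349-atom composition;
scaling and cutoff behavior are checked on operation counts up to the
24,684- and 1,588,868-atom compositions respectively, where counts are
exact without running the energy passes. These sizes exercise every branch
of the pipeline (1–20 cells per axis, 0–5 alpha groups) while keeping the
suite's one-CPU run time in minutes.

## Known limitations

* Open boundaries only; no periodic images, no minimum-image convention,
  no triclinic boxes.
* Energies and forces only — no virial/pressure tensor, no exclusion lists
  for bonded interactions.
* The per-pair→RMSE tolerance mapping is calibrated to neutral salt-water
  statistics; strongly correlated or highly charged systems may need a
  manual `kernel_epsilon`.
* Runtime-generated equal-weight designs are limited to small strengths;
  high-strength angular rules are weighted product grids (same accuracy
  contract, not minimal-point designs).
* Moving atoms are handled by full re-sort per call; there is no
  incremental re-binning.
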