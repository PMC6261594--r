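---
title: "Methods: from marker video to aerodynamic power in flapping membrane-wing flight"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from marker video to aerodynamic power in flapping membrane-wing flight}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`flapwing` implements a complete analysis chain for flapping membrane-wing
(bat-style) flight: multi-camera marker observations are reconstructed into
3D trajectories, turned into a moving triangulated wing surface, used to
drive a desk-scale incompressible Navier–Stokes solver with a sharp-interface
immersed boundary and dynamic-Smagorinsky LES, and post-processed into
transient force, lift coefficient, aerodynamic power and a lumped-mass
trajectory check. This vignette explains the models, the tunable parameters,
and the numerical choices, and states what the bundled synthetic data can and
cannot demonstrate.

Coordinates are x streamwise (flight direction), y lateral, z vertical up;
all quantities SI.

## The flight case the defaults describe

The default parameters describe a straight, slightly accelerating flight of a
~55 g bat: span $b = 52$ cm, maximum planform area $S = 360\ \mathrm{cm^2}$,
flap frequency $f = 7.25$ Hz (period 138 ms), plunge amplitude
$h_a = \pm 10.9$ cm, mean speed $U_\infty = 2.57$ m/s (accelerating 2.2 to
2.7 m/s over ~3 flap cycles), stroke-plane angle $\beta = 54.1^\circ$, and a
planform-area modulation of about 46% peak-to-peak. The dimensionless
descriptors follow from

$$\mathrm{Re} = \frac{\rho U_\infty c_m}{\mu}, \qquad
  \mathrm{St} = \frac{2 f h_a}{U_\infty}, \qquad
  A_R = \frac{b^2}{S}, \qquad Q = \frac{Mg}{S},
  \qquad k = \frac{\pi f c_m}{U_\infty}.$$

Two internal tensions in the source measurements are kept as printed and
surfaced rather than silently resolved: the printed mean chord (7.4 cm)
differs from $S/b$ (6.9 cm), and the printed wing loading
($12.1\ \mathrm{N/m^2}$) differs from $Mg/S$ ($15.0\ \mathrm{N/m^2}$).
`kinematic_metrics()` always evaluates the defining formulas from the data it
is given; `flight_params()` carries the printed 7.4 cm where a chord scale is
needed downstream (grid sizing). Similarly, the published chord Reynolds
number 11,680 implies an air viscosity no standard temperature reproduces;
air defaults here are 15 °C sea level ($\rho = 1.225$, $\mu = 1.789\times
10^{-5}$), giving $\mathrm{Re} \approx 1.3\times 10^4$, and the Reynolds
number is reported as convention-dependent.

## Synthetic capture: closed-form kinematics with exact ground truth

No raw kinematic recordings are bundled; `generate_wing_motion()` emulates
the capture with a motion model chosen so that *every* metric the pipeline
measures has a closed form:

* markers on two trapezoidal half-wing planforms (quasi-uniform grid with
  seeded jitter, a dedicated wingtip marker at exact mid-chord) plus a
  two-row body/tail strip, 108 markers and 52 frames at 120 fps by default,
  region-tagged (left/right × inner/outer, body, tail);
* a rigid-hinge flap rotation $\theta(t) = \theta_a \cos(2\pi f t)$ about an
  axis tilted so the tip's stroke path makes the stroke-plane angle with the
  horizontal while its *vertical* half-excursion equals $h_a$ exactly (the
  plunge amplitude is defined from tip z positions);
* a chordwise pitch rotation $\psi(t) = \psi_a \sin(2\pi f t)$
  ($\psi_a = 20^\circ$ by default — a free parameter, no measured value
  exists);
* a spanwise area scaling $1 + a\cos(2\pi f t)$ phase-locked to the flap
  (largest wing at the top of the stroke), so the wing-area peak-to-peak
  ratio is exactly $(1+a)/(1-a)$; the default $a = 0.30$ yields the ~46%
  peak-to-peak area change;
* a body advancing with linearly interpolated forward speed.

Because the span is *defined* as the maximum tip-to-tip distance during
flight, and the area scaling momentarily stretches the wing beyond its rest
length, the generator solves the rest half-span by fixed-point iteration so
the measured maximum equals `span_max`.

Two geometric consequences are worth noting. First, with zero modulation and
zero pitch the *material* (3D) wing area is exactly constant, but the
projected planform still varies with flap angle through $|n_z|$; tests assert
the former exactly and the latter against the closed-form tilt factor.
Second, the synthetic wing is a rigid-hinge caricature: it has no membrane
compliance, no camber, no joint articulation, and its area modulation is a
single harmonic. Passing recovery tests therefore demonstrates that the
*pipeline* is unbiased and noise-robust at realistic capture geometry and
noise levels — not that it would capture every degree of freedom of a real
membrane wing.

Cameras (`camera_ring_array()`, 3 rings × 7 pinhole cameras with radial
distortion on a 1.2 m tunnel cross-section) project the markers;
`project_to_cameras()` adds Gaussian pixel noise and independent occlusion
dropout. The default noise of 0.5 px is a realistic sub-pixel digitization
error, chosen once; no measured value exists.

## Multi-view reconstruction

`undistort()` inverts the radial distortion by fixed-point iteration
(tolerance $10^{-10}$ in normalized units, at most 50 iterations).
`triangulate_pair()` solves the two-view DLT linear least-squares per matched
observation, vectorized over all (frame, marker) pairs, and reports the RMS
reprojection residual; pairs with near-parallel rays (< 1°) are flagged.
`reconstruct_markers()` forms all camera pairs, discards candidates with
residual > 5 px or low parallax, and fuses the survivors by the
coordinate-wise median — the geometric median would differ only in
pathological cases and the coordinate-wise form is what the capture
literature describes.

`pca_clean()` is a deliberately simple, documented stand-in for more
elaborate published cleaning procedures: frames × (3·markers) matrix,
mean-imputed gaps, leading principal subspace capturing ≥ 99% variance,
3D residual norms flagged beyond 5× the MAD, flagged and missing entries
refilled by natural cubic splines in time. It never alters entries it does
not flag, and markers with fewer than 4 valid frames are left invalid and
reported.

## Wing surface: Delaunay control mesh and barycentric fine mesh

At the most-outstretched frame each region group (left wing, right wing,
body/tail) is projected onto its least-squares plane and triangulated by 2D
Delaunay (`deldir`); the connectivity is lifted to 3D and frozen. Control
points move on natural cubic splines (C², no overshoot-prone end
extrapolation; they interpolate the samples exactly). Each control triangle
is subdivided into $k^2$ congruent sub-triangles with one *global*
$k = \lceil \text{median edge} / \text{target edge} \rceil$ — a per-triangle
$k$ cannot keep shared edges watertight. Each fine vertex stores its
barycentric coordinates $(\alpha, \beta)$ with respect to its owning control
triangle,

$$\vec r_i = \vec r_1 + \alpha_i(\vec r_2 - \vec r_1) +
             \beta_i(\vec r_3 - \vec r_1),$$

computed once at the reference configuration and reused unchanged as the
wing moves, so interior points maintain their relative positions. At
production scale a 182-triangle control mesh with ~2 cm edges refined to the
fluid spacing (0.020 chords) yields ~36k fine elements, within 20% of the
published 42,839. Element velocity uses the second-order backward difference
over $\{t, t-\Delta t, t-2\Delta t\}$ with $\Delta t$ the *solver* step (not
the camera interval), acceleration the second difference on the same
stencil; both are exact for linear motion.

## Flow solver

A finite-volume fractional-step solver on a staggered (MAC) non-uniform
Cartesian grid:

* **Grid** (`build_grid()`): uniform spacing inside a refined box sized to
  contain the swept wing volume, geometric stretching (ratio ≤ 1.2 by
  default) to the boundaries, mirroring the production protocol of a
  $32c \times 16c \times 16c$ domain at 0.020-chord fine spacing (50
  cells/chord). The desk-scale defaults are far coarser; the full
  configuration is expressible but not a test target.
* **Advance**: explicit second-order Adams–Bashforth (Euler on the first
  step) of central-difference convection (divergence form) and conservative
  diffusion with total viscosity (molecular + eddy). Explicit diffusion was
  chosen over Crank–Nicolson for simplicity at desk-scale Reynolds numbers;
  `stable_dt()` combines the convective CFL and the explicit viscous bound.
* **Projection**: the variable-coefficient FV pressure Poisson system is
  symmetric; it is solved by a cached sparse Cholesky factorization
  (`Matrix`), an exact solve that trivially meets the residual tolerance and
  is far faster in interpreted R at desk scale than an iterative Krylov
  loop (the production-code ancestry of this method uses preconditioned
  BiCGSTAB; the algebraic system is the same). With no pressure Dirichlet
  face the one-dimensional null space is removed by pinning one cell of the
  reduced system. Post-projection divergence is machine-zero on regular
  fluid cells and is checked every step.
* **Boundary conditions**: Dirichlet free stream on the inlet and side
  walls, zero-gradient outflow on +x with a uniform flux correction
  enforcing exact global mass balance, periodic axes for verification
  problems, and an optional constant body force (used for channel flow).
  The moving reference frame is handled as a wind-tunnel view: free stream
  at the frame speed, wing kinematics advanced at the residual speed.
* **2D mode**: one periodic y cell; all y-derivatives vanish identically.
  Verification and the refinement protocol run in this mode for economy.

Verification: second-order convergence (observed order ≈ 2.0) on the 2D
Taylor–Green vortex against the closed-form decaying solution; plane
Poiseuille startup matches the parabolic profile to well under 1%; kinetic
energy decays monotonically in unforced periodic flow; a uniform stream is an
exact steady state of the tunnel.

### Dynamic Smagorinsky LES

The Germano-identity least-squares (Lilly) coefficient is computed locally at
each cell with a discrete box test filter (weights $\tfrac14,\tfrac12,
\tfrac14$ per active axis, width ratio 2), negative coefficients clipped:
$\nu_t = C\Delta^2|\bar S|$ with $\Delta$ the geometric-mean local spacing.
Uniform flow and solid-body rotation give $\nu_t = 0$ identically (gradients
and filters use linear-extrapolation ghosts on non-periodic axes so rigid
motions have zero strain everywhere). The vectorized implementation is tested
cell-wise to $10^{-10}$ against an independent loop-based oracle.

### Sharp-interface thin-surface immersed boundary

The wing is a zero-thickness surface with fluid on both sides. Velocity
nodes within one *normal-projected* grid spacing
($|n_x|\Delta x + |n_y|\Delta y + |n_z|\Delta z$) of the surface on each
side are IB nodes; each receives a linear velocity profile along the local
normal between the no-slip surface point (value = local surface velocity)
and a trilinear fluid probe beyond it. Interpolation is linear — the lowest
order consistent with the thin-surface geometry — and nodes exactly on the
surface take the surface velocity itself. IB velocities are imposed before
and after the projection; divergence is not meaningful in the IB-adjacent
cells and is excluded from the fluid-cell check. Element centroids are
located on the grid by per-axis binary search.

Surface loads sample each side separately: pressure is reconstructed at the
wall by two-point linear extrapolation along the side normal (samples at
$1.8h$ and $3.6h$) plus the moving-wall correction
$\partial p/\partial n = -\rho\,\vec a\cdot\hat n$ over the first offset;
one-point sampling was found to converge too slowly under grid refinement.
Viscous traction uses the one-sided tangential velocity difference
(first-order; shear is a minor contributor at $\mathrm{Re}\sim 10^4$).

The refinement protocol mirrors the production grid-independence study at
desk scale: a static broadside plate at $\mathrm{Re} = 25$ in 2D, three
grids with 8/12/24 cells across the plate, quasi-steady drag averaged over
the last quarter of a 2.5 s run. The drag approaches monotonically and
changes by under 15% between the two finest grids (about 9% as measured);
the published full-scale protocol reaches 1.6% at 50–100 cells/chord on
88.1M cells, far beyond desk scale, and is not a test target.

## Force, lift coefficient, power, cycle averages

$$\vec F = \int_S (\vec{\vec\tau} - p\hat n)\, dS, \qquad
  C_L = \frac{F_z}{\tfrac12 \rho U_\infty^2 S}, \qquad
  P = \int_S (p\hat n - \vec{\vec\tau})\cdot \vec v_{wing}\, dS,$$

evaluated as sums over the discrete elements and both sides of the thin
surface, with $S$ in $C_L$ the maximum observed planform area. For rigid
motion $P = -\vec F\cdot\vec v$ holds to round-off by construction, and
region breakdowns sum to the total exactly. Cycle averages are trapezoidal
time means over complete cycles; when a series carries no tip position,
cycle boundaries come from the autocorrelation-estimated period seeded by a
user-supplied nominal (e.g. the 138 ms flap period), or directly from the
nominal period when that convention is prescribed. The force/power CSV
reader tolerates common header aliases and takes an explicit column map for
first contact with an externally deposited file.

## Lumped-mass trajectory validation

`predict_trajectory()` integrates $\ddot{\vec x} = \vec F_{aero}(t)/M -
g\hat z$ with classic RK4 and linear force interpolation; weight is added
here because the surface integral is aerodynamic only, and wing inertia is
excluded (the wing velocity vanishes at stroke reversal, returning inertial
energy to the flow). Hover equilibrium is preserved to round-off, free fall
and constant-force cases match their closed forms, and the endpoint error
contracts at fourth order. `compare_trajectory()` resamples the observed
record by natural cubic splines and reports per-axis RMS and final offsets.

## Problem sizes and reproducibility

The test-suite and acceptance computations use: 108 markers × 52 frames ×
21 cameras for the kinematics chain; Taylor–Green at 16²/32² (order
measurement); a 4×16 channel for Poiseuille; 6³ periodic cells for the
subgrid-model oracle; and 108×72 / 216×144 2D grids for the plate
refinement pair. These sizes were chosen so each check isolates one property
at the coarsest resolution where the property is unambiguous. All randomness
flows from explicit integer seeds; rerunning with the same seed is
byte-identical.

## Known limitations

* The solver is desk-scale by design: interpreted R with a direct sparse
  factorization; the production-scale 88.1M-cell LES is out of reach and out
  of scope.
* The IB velocity profile and viscous traction are first-order near the
  surface; drag converges correspondingly slowly under refinement.
* The synthetic wing omits membrane compliance, camber and articulated
  joints; recovery tests validate the measurement chain, not membrane
  biomechanics.
* Pressure at outflow uses a zero-face-value convention; strongly unsteady
  wakes crossing the outlet would need a convective condition.
* The published $C_L = 3.21$ depends on a maximum-planform-area value that
  was never printed and is therefore not a reproduction target; the
  normalization identity itself is tested.
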