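---
title: "Defect kinematics in active nematic films with spatially varying activity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Defect kinematics in active nematic films with spatially varying activity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nematicdefects)
```

## The model

A thin active nematic film on a frictional substrate is described by a
velocity field $\mathbf u(\mathbf r)$ coupled to the nematic tensor order
parameter $Q_{ij} = S(\hat n_i \hat n_j - \tfrac12\delta_{ij})$.  The film
generates an active stress $\sigma^a_{ij} = \alpha\, Q_{ij}$, with
$\alpha < 0$ extensile (pushers) and $\alpha > 0$ contractile (pullers).
Neglecting passive elastic stresses and flow alignment, force balance on a
fluid element gives the screened incompressible Stokes problem
$$(\Gamma - \eta \nabla^2)\,\mathbf u
   = \nabla\cdot[\alpha(\mathbf r)\,\mathbf Q(\mathbf r)] - \nabla p,
   \qquad \nabla\cdot\mathbf u = 0,$$
with substrate friction $\Gamma$ and shear viscosity $\eta$.  Two lengths
control the physics: the dissipation length $\ell_d = \sqrt{\eta/\Gamma}$,
beyond which friction screens viscous transport, and the nematic coherence
length $\xi = \sqrt{K/g}$ of the defect core.  All field-level computations
use rescaled units (lengths in $\xi$, time in the director relaxation time
$\tau = \gamma/g$, activity rescaled by $\Gamma K/\gamma$), in which the
single dimensionless group is $\zeta = \ell_d/\xi$, exposed by
`zeta(medium_params(...))`.

The bulk ordering potential $\tfrac{g}{4}(1 - \tfrac12\mathrm{Tr}\,Q^2)^2$
is minimized by the uniform amplitude $S_0 = 2$
(`equilibrium_amplitude()`); an isolated half-integer defect is then
described by the quasi-static texture
$$Q_{xx} = \cos(\pm\phi + 2\theta_0), \qquad
  Q_{xy} = \sin(\pm\phi + 2\theta_0),$$
with $\phi = \mathrm{atan2}(y, x)$ the singular phase of a $\pm 1/2$ defect
at the origin and $\theta_0$ the slowly varying background orientation.
The texture is held quasi-static throughout: the amplitude profile inside
the core is not modelled, and fields carrying $1/r$ factors accept a
core-exclusion radius for grid sampling (quadratures need none, because the
polar area element cancels one power of $1/r$).

The $+1/2$ defect is polar, with polarization
$\mathbf e_+ = (\cos 2\theta_0, \sin 2\theta_0)$, the normalized divergence
of $\mathbf Q$ at the core.  The $-1/2$ defect is threefold symmetric;
its conventional polarization axis is
$\mathbf e_- = (\cos\tfrac{2\theta_0}{3}, \sin\tfrac{2\theta_0}{3})$.

## Activity profiles and the active force

Three parametric activity families are supported (`activity_profile()`):
uniform $\alpha_0$; a constant gradient $\alpha_0 + \alpha_g x$; and a
sharp step $\alpha_0 - \Delta\alpha\, H(x - x_v)$ describing an interface
at distance $x_v$ from the defect, with the defect on the high-activity
side.  At the jump itself the midpoint convention $H(0) = \tfrac12$ is
used so that centred differencing across the interface is symmetric.  An
active/passive interface is the special case $\Delta\alpha = \alpha_0$.

The active force splits into an interfacial and a bulk part,
$$\mathbf F = \mathbf Q\cdot\nabla\alpha + \alpha\,\nabla\cdot\mathbf Q
           = \mathbf F^I + \mathbf F^B .$$
`active_force()` returns both, either in closed form (all six
charge-profile combinations) or by centred finite differences on a
rectangle grid (`mode = "numeric"`, second-order accurate, which the test
suite verifies against the closed forms on an annulus under mesh
refinement).  For a step profile the interfacial force is a line density
concentrated on $x = x_v$; it is carried as an analytic `line_measure` and
reduced to one-dimensional quadratures wherever it is integrated — it is
never sampled on a grid.

## Green's-function kinematics

Without the incompressibility constraint the Green's function of
$(1 - \zeta^2\nabla^2)$ is the modified Bessel kernel
$K_0(r/\zeta)/(2\pi\zeta^2)$, so the defect self-propulsion velocity (the
net active flow through the core) and the core vorticity are
$$\mathbf v = \frac{1}{2\pi\zeta^2}\!\int\! d\mathbf r\,
     K_0\!\left(\frac{r}{\zeta}\right)[\mathbf F - \nabla p], \qquad
  \omega = -\frac{1}{2\pi\zeta^2}\!\int\! d\mathbf r\,
     K_0\!\left(\frac{r}{\zeta}\right)\nabla_\perp\!\cdot\mathbf F,$$
with $\omega = \partial_x u_y - \partial_y u_x$.  Numerical choices:

* Quadrature is nested polar, centred on the defect: a 256-point periodic
  midpoint rule in the angle (spectrally exact for the finite trigonometric
  content of the forces) inside an adaptive radial rule.  The kernel is
  truncated at $r_{\max} = 40\zeta$; since $K_0 \sim e^{-r/\zeta}$ the
  truncation error is below $10^{-15}$ relative.
* For the vorticity the derivative is moved onto the kernel,
  $\omega = \frac{1}{2\pi\zeta^3}\int K_1(r/\zeta)\,(\hat r\times\mathbf F)
  \, d\mathbf r$, which is regular for every supported force, handles the
  step-profile line force as a 1D integral, and makes pressure-independence
  manifest (gradients are curl-free; the suite perturbs the force with
  random polynomial gradients and checks $\omega$ is unchanged).
* Step-profile bulk terms are integrated over the half plane
  $x > x_v$ in defect-centred polar coordinates, the region
  $r > x_v/\cos\phi$, $|\phi| < \pi/2$.

Pressure is handled in three modes.  `"none"` omits it.
`"full_projection"` evaluates the transverse (divergence-free) projection:
for the uniform-$\alpha_0$ term this is done in the spectral domain, where
$\hat{\mathbf F}_0 = 2\pi\alpha_0\,\mathbf e_+/k$ and the angular average
of $(\mathbb 1 - \hat k\hat k)$ halves the result, giving the core speed
$\alpha_0\pi/(4\zeta)$; equivalently, in real space the projected force is
$\alpha_0\,\hat r(\mathbf e_+\!\cdot\hat r)/r$ with pressure
$p_0 = \alpha_0\,(\mathbf e_+\!\cdot\hat r)$, a form derived here and
included in the closed-form bulk pressure.  For the linear profile the
gradient-pressure closed forms are used; their core contribution vanishes
by parity, which is why a constant gradient never propels the defect.
`"uniform_term_only"` applies the projection only to the uniform term and
leaves the gradient/jump terms unprojected — this is the prescription
under which the interface profile functions below are defined.  For the
step profile the jump-induced pressure has no closed form and is
deliberately outside the model, so `"full_projection"` raises an
unsupported-case error there rather than silently approximating.

One consistency note on the closed-form pressure: with the bulk force as
implemented, the Poisson identity $\nabla^2 p = \nabla\cdot\mathbf F$
fixes the sign of the $xy$ term of the linear-gradient bulk pressure to
$+\alpha_g\sin(2\theta_0)\,xy/(3r)$; the package carries that sign, and
the test suite confirms the identity at second order in the grid spacing.
The additive system-size constant that formally regularizes the pressure
at infinity is dropped: only $\nabla p$ enters any physics.

### Closed forms in a constant gradient

For a $+1/2$ defect in $\alpha = \alpha_0 + \alpha_g x$ the kernel
integrals evaluate in closed form to the gradient torque
$$\omega_+ = \frac{3\pi}{4}\,\frac{\alpha_g}{\zeta}\sin(2\theta_0)
  \;=\; \frac{3\pi}{4}\,\frac{\alpha_g \ell_d}{\eta}\sin(2\theta_0)
  \ \text{(physical units)},$$
exposed as `omega_plus_gradient()`.  (A second dimensional spelling with
$1/(\Gamma\eta)$ that sometimes appears in print is dimensionally
inconsistent and is not provided.)  The torque vanishes for
$\theta_0 \in \{0, \pi/2\}$ and is maximal at $|\theta_0| = \pi/4$; its
effect is to rotate the polarization until it is parallel to the gradient,
after which the defect self-propels towards lower activity magnitude.  The
$-1/2$ defect gets neither velocity nor rotation from a constant gradient:
all its force harmonics average to zero against the kernel, which the
suite checks to $10^{-8}$.

In the friction-dominated limit ($\mathbf u \propto \mathbf F - \nabla p$
locally) the vorticity field away from the core follows the curl of the
force pointwise.  `vorticity_map_plus()` and `vorticity_map_minus()`
evaluate the tabulated $1/r$ maps whose sign structure on a circle gives
the vortex multiplets: four alternating vortices for the aligned $+1/2$
defect, eight for the $-1/2$, and a single vortex when the
$\sin(2\theta_0)$ term dominates ($|\theta_0| = \pi/4$ makes it the whole
map).  One implementation note: direct differentiation of the implemented
force gives the bulk curl term $\alpha_g\sin(2\theta_0)\,y^2/r^3$, i.e. an
angular factor $1 + \sin^2\phi$, whereas the tabulated map carries
$1 + \cos^2\phi$.  The two differ by a harmonic with zero circular
average, so the core torque, all circle-averaged quantities and every
vortex count are identical; `vorticity_map_plus()` follows the tabulated
form, while the Green's-function and disc-solver routes use the direct
derivative.  Vortex counting (`count_sign_domains()`) is defined on a
circle rather than by 2D connected components because it is then exactly
resolution-independent; the default tolerance excludes samples below
$10^{-12}\max|\omega|$.

### Interface profile functions

Near a sharp interface the kinematics factor into dimensional prefactors
and dimensionless wall-distance functions of $x_v$ in units of $\ell_d$
(all four are computed with $\zeta = 1$ internally, which is what makes
the prefactors carry the $\ell_d/\eta$ scalings):
$$\mathbf v_+ = \frac{\alpha_0\pi\ell_d}{4\eta} f_{v+}(x_v)\,\mathbf e_+,
\qquad
\omega_+ = -\frac{\Delta\alpha}{2\pi\eta}\sin(2\theta_0) f_{\omega+}(x_v),$$
$$\mathbf v_- = -\frac{\Delta\alpha\,\ell_d}{2\pi\eta} f_{v-}(x_v)\,
  \hat{\mathbf n}_-,
\qquad
\omega_- = -\frac{\Delta\alpha}{2\pi\eta}\sin(2\theta_0)
  f_{\omega-}(x_v),$$
with $\hat{\mathbf n}_- = (\cos 2\theta_0, \sin 2\theta_0)$.  Two
conventions deserve comment.  First, the $-1/2$ drift direction is
$\hat{\mathbf n}_-$, the angle-$2\theta_0$ axis, not the polarization
$\mathbf e_-$ (angle $2\theta_0/3$); re-deriving the velocity integrals
from the force components confirms this.  Second, the $-1/2$ torque
prefactor is written here with $\Delta\alpha$: every torque-generating
term of the step force carries the jump, and the uniform part exerts none,
so a spelling with $\alpha_0$ is equivalent only for an active/passive
interface ($\alpha_1 = 0$).

The reduced quadratures, derived with the $K_1$ kernel identity and the
exact radial integral $\int_a^\infty K_1 = K_0(a)$, are
$$f_{v+}(x_v) = 1 - \frac{2}{\pi^2}\left[
   \int_{-\infty}^{\infty}\! dy\, K_0(r_v)\frac{x_v}{r_v}
 + \int_{-\pi/2}^{\pi/2}\! d\phi \int_{x_v/\cos\phi}^{\infty}\! dr\,
   K_0(r)\right],$$
$$f_{\omega+}(x_v) = \int_{-\infty}^{\infty}\! dy\, K_1(r_v)
 + \int_{-\pi/2}^{\pi/2}\! d\phi\,\cos\phi\; K_0\!\left(
   \frac{x_v}{\cos\phi}\right),$$
$$f_{v-}(x_v) = \int_{-\infty}^{\infty}\! dy\, K_0(r_v)\frac{x_v}{r_v}
 - \int_{-\pi/2}^{\pi/2}\! d\phi\,\cos 2\phi
   \int_{x_v/\cos\phi}^{\infty}\! dr\, K_0(r),$$
$$f_{\omega-}(x_v) = \int_{-\infty}^{\infty}\! dy\, K_1(r_v)
   \frac{x_v^2 - y^2}{r_v^2}
 - \int_{-\pi/2}^{\pi/2}\! d\phi\,\cos 3\phi\; K_0\!\left(
   \frac{x_v}{\cos\phi}\right),$$
with $r_v = \sqrt{x_v^2 + y^2}$.  Because flattened typesetting makes
printed versions of such integrals easy to misread, the defining check in
this package is agreement with the general 2D kernel quadrature
(`core_velocity()` / `core_vorticity()` on the step profile), which does
not use the closed radial identity; the suite requires agreement to
$10^{-4}$ at $x_v \in \{0.25, 0.5, 1, 2\}$.

Their behaviour encodes the interface phenomenology: $f_{v+}$ rises
monotonically from $0$ at the wall to $1$ in the bulk — the $+1/2$ defect
slows down and stalls as it reaches the interface; $f_{\omega+} > 0$
grows towards the wall and diverges logarithmically at $x_v \to 0$ — the
torque reorients the polarization wall-normal, pointing away for
extensile ($2\theta_0 = \pi$) and into the wall for contractile
($2\theta_0 = 0$) activity; $f_{v-}$ is an interfacial effect of range
$\sim\ell_d$ that lets the otherwise non-motile $-1/2$ defect drift — for
extensile activity with the stable orientation, towards the wall;
$f_{\omega-}$ changes sign near $x_v \approx 0.5$ and diverges negatively
at the wall, so the $-1/2$ preferred orientation ($\theta_0 = 0$
extensile, $2\theta_0 = \pi$ contractile) is selected in the near-wall
region where the torque actually matters.  The $f_\omega$ functions are
tabulated down to $x_v = 10^{-3}$ and flagged divergent below; no
extrapolation to the wall is attempted.

## The disc solver

`solve_disc()` verifies the unbounded-domain predictions in a bounded
geometry: the screened Stokes problem in a disc of radius $R$ with no-slip
walls, driven by the analytic defect force.  The discretization is a
stream-function/vorticity method on a polar grid: with
$\mathbf u = \nabla\times(\psi\hat z)$ incompressibility is exact and the
pressure is eliminated; Fourier decomposition in the angle (the forcing
contains harmonics $|n| \le 4$ only) leaves, per harmonic, the coupled
radial system $(1 - \zeta^2 L_n)\omega_n = c_n$, $L_n\psi_n = -\omega_n$
with $L_n = \partial_r^2 + r^{-1}\partial_r - n^2/r^2$, discretized by
second-order finite differences and closed by the clamped wall conditions
$\psi_n(R) = \psi_n'(R) = 0$ (no condition on the wall vorticity is
needed) and regularity at the axis.  Solutions are checked for no-slip
and discrete-divergence residuals at solver tolerance, exact linearity in
$(\alpha_0, \alpha_g)$, and grid convergence of the core vorticity.

The point-defect forcing curl ($\sim 1/r$, $1/r^2$) is integrable and is
evaluated analytically on all shells, so the core-exclusion radius
`r_c` (default two radial spacings, bounded by $R > r_c$) only governs
where core values may be read; radial continuation of the analytic force
inside `r_c` is the identity.  Core values are read by circle-averaging at
2–3 radial spacings (`core_flow_values()`), which filters the harmonics
that vanish at the origin.

`radius_sweep()` reproduces the finite-size crossover of the core
vorticity: linear in $R$ (slope $\propto 1/\eta$) for $R \ll \ell_d$,
where the unscreened Stokes problem sets the only length, and saturation
at the closed-form gradient torque for $R \gg \ell_d$.  Default problem
sizes were chosen once for accuracy: 120 radial shells per unit radius
(capped at 2000), so the suite's $R = 10$ verification uses 1200 shells
and matches $3\pi/4$ to a few per cent (the residual gap being the
genuine finite-size effect — wall corrections enter through the
unscreened pressure and decay only algebraically, which is also why the
uniform-activity core speed approaches $\alpha_0\pi/4\zeta$ slowly from
below as $R$ grows).

## Defect dynamics

The local vorticity rotates the background director at rate $\omega/2$
and carries the defect polarization with it:
$\dot{\mathbf e}_\pm = -3^{q - 1/2}\,\omega_\pm\,
\mathrm{perp}(\mathbf e_\pm)$ (`polarization_rate()`), i.e.
counter-clockwise at rate $\omega$ for $q = +1/2$ and at $\omega/3$ for
$q = -1/2$ — the factor of three is geometric, because the $-1/2$
polarization angle is $2\theta_0/3$ while $\theta_0$ itself advances at
$\omega/2$ for both charges.  The two statements are mutually consistent,
and the integrators work in the angle variable $\theta_0$, which
conserves $|\mathbf e| = 1$ exactly; the vector rate is the exposed API.

`integrate_orientation()` (fixed $x_v$) and `integrate_trajectory()`
(coupled $\dot x_v = -v_x$, $\dot\theta_0 = \omega/2$) integrate the
resulting ODEs with `deSolve`, evaluating $\omega(x_v, \theta_0)$ and
$v(x_v, \theta_0)$ from pre-tabulated profile curves with cubic-spline
interpolation — a quadrature per ODE step would be wasteful, and the
interpolation error is held near $10^{-4}$ relative by the default
tables.  Trajectories terminate at a wall-distance cutoff (default
$10^{-3}\ell_d$) where the torque diverges and the minimal model loses
validity; the series is flagged truncated.  `stationary_orientations()`
classifies the roots of $\sin 2\theta_0$ analytically from the sign of
$d\omega/d\theta_0$, and the suite confirms the classification against
basins of attraction found by integration from eight initial angles.

## Study conditions, and what the tests do and do not show

All quantitative checks run in rescaled units with
$\Gamma = \eta = K = g = \gamma = 1$ (so $\zeta = 1$) and order-one
activities and gradients ($\alpha_0, \alpha_g, \Delta\alpha = \pm 1$),
the natural operating point of the theory; parameter dependence enters
only through the closed-form scalings ($1/\zeta$, $\ell_d/\eta$), which
are themselves tested across $\zeta \in \{0.5, 1, 2\}$.  Wall distances
exercise the interfacial region $x_v \in [0.25, 2]\,\ell_d$ plus the
asymptotic limits.

These conditions emulate an isolated, quasi-static defect in an
unbounded (or cleanly bounded) film.  They deliberately omit defect-defect
interactions, elastic and flow-alignment torques, nematic distortions
induced by the interface itself, defect creation/annihilation, and any
time dependence of the texture — the ingredients behind phenomena such as
wall-parallel drift or interface tunnelling observed in full simulations.
Passing tests therefore validate the kinematic theory and its numerics,
not the full many-defect phenomenology of a turbulent active film.

## Known limitations

* The step-profile pressure correction is not modelled
  (`full_projection` is refused there); interfacial kinematics follow the
  partial-projection convention in which the profile functions are
  defined.
* The disc solver supports uniform and linear profiles; a step inside the
  disc would require resolving the line force on the mesh.
* $f_{\omega\pm}$ are logarithmically divergent at the wall; values below
  the cutoff are flagged, and trajectory integration truncates rather than
  extrapolates.
* The quasi-static, uniform-amplitude texture is used everywhere,
  including inside the physical core $r < \xi$.
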