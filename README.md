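# nematicdefects

Kinematics of half-integer topological defects in two-dimensional active
nematic films with spatially varying activity.

Active nematics — microtubule–kinesin suspensions, bacterial films,
confluent cell monolayers — generate an active stress `α Q` that drives
spontaneous flow around the ±1/2 defects of the director field.  The
comet-shaped +1/2 defect is self-propelled; the threefold −1/2 defect is
not.  This package implements, for researchers in active matter and
cytoskeletal/cellular hydrodynamics, the kinematic theory of an isolated
defect when the activity `α(r)` varies in space: a constant gradient
reorients the +1/2 defect, and a sharp activity jump (an active/passive
interface) acts as a soft wall that slows, traps and sorts defects by
charge.

## The theory in brief

Force balance in a film on a substrate is a screened Stokes problem

    (Γ − η ∇²) u = ∇·(α Q) − ∇p,   ∇·u = 0,

whose Green's function (without incompressibility) is the Bessel kernel
`K0(r/ℓ_d)`, with `ℓ_d = √(η/Γ)` the dissipation length.  With the
quasi-static defect texture `Q = (cos(±φ + 2θ0), sin(±φ + 2θ0))`, the
defect velocity and core vorticity are kernel integrals of the active
force `F = Q·∇α + α ∇·Q`.  Highlights, all implemented and tested:

* **Uniform activity**: the +1/2 defect self-propels along its
  polarization `e+ = (cos 2θ0, sin 2θ0)` at speed `α0 π ℓ_d / (4η)`.
* **Constant gradient** `α = α0 + αg x`: no change to the
  self-propulsion, but a vorticity-induced torque
  `ω+ = (3π/4) (αg ℓ_d/η) sin 2θ0` rotates the +1/2 defect parallel to
  the gradient; the −1/2 defect neither moves nor turns.  In the
  friction-dominated limit the vorticity field forms 4 (for +1/2) or 8
  (for −1/2) counter-rotating vortices.
* **Sharp interface** at distance `x_v`: the kinematics factor into
  dimensionless wall-distance functions `f_v±`, `f_ω±` of `x_v/ℓ_d`.
  The +1/2 defect stalls at the wall (`f_v+ → 0`) and reorients
  wall-normal; the −1/2 defect acquires an interfacial drift and, with
  its stable orientation, is attracted to the wall — consistent with the
  accumulation of negative charge at active/passive interfaces.
* A stream-function/vorticity solver for the screened Stokes flow in a
  no-slip disc verifies the unbounded-domain results and the finite-size
  crossover (core vorticity linear in `R` below `ℓ_d`, saturating at the
  closed form above it).
* ODE integration of the polarization/position dynamics
  (`θ̇0 = ω/2`, `ẋ_v = −v_x`) with fixed-point classification.

See the vignette `vignettes/defect-kinematics.Rmd` for the full model,
conventions and numerical design.

## Worked example

```r
library(nematicdefects)

m <- medium_params()                      # Γ = η = K = g = 1, so ζ = 1
d <- defect_config(+1/2, theta0 = pi/4)

# torque on a +1/2 defect in a unit activity gradient
grad <- activity_profile("linear", alpha0 = 0, alphag = 1)
core_vorticity(d, grad, m)
#> Defect kinematics (rescaled units):
#>   omega = 2.3561945
#>   quadrature error estimate: 8.02e-10
omega_plus_gradient(1, pi/4, m)           # closed form: 3*pi/4
#> [1] 2.356194

# uniform-activity self-propulsion with the incompressible projection
core_velocity(defect_config(+1/2), activity_profile("uniform", 1), m,
              pressure_mode = "full_projection")
#> Defect kinematics (rescaled units):
#>   v     = (0.78539816, 0)  |v| = 0.78539816   # = pi/4, along e+
#>   pressure mode: full_projection

# +1/2 defect half a dissipation length from an active/passive interface,
# extensile activity
interface_kinematics(defect_config(+1/2, pi/3), x_v = 0.5,
                     alpha0 = -1, medium = m)
#> Defect kinematics (physical units):
#>   v     = (0.19658662, -0.34049802)  |v| = 0.39317325
#>   omega = 0.5951693
stationary_orientations(+1/2, 0.5, alpha0 = -1)
#> Stationary orientations (extensile, q = +0.5):
#>   2 theta0 = 0 : unstable
#>   2 theta0 = 3.141593 : stable
```

The first two numbers are the closed-form anchors `3π/4 ≈ 2.3562` and
`π/4 ≈ 0.7854`.  In the interface example the defect (half-speed, since
`f_v+(0.5) ≈ 0.5`) still drifts along its polarization while the positive
torque rotates `2θ0` towards `π` — the extensile stable orientation, with
the polarization pointing away from the wall.

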