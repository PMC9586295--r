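# gyroswim

Trajectory statistics and individual-based modelling of gyrotactic
microswimmers near walls.

Swimming microalgae accumulate beneath solid boundaries. Two effects drive
this for a bottom-heavy (gyrotactic) swimmer in still water: gravitational
reorientation toward upward swimming at rate `omega_g = -cos(theta)/(2B)`,
and cell--wall interaction, which sharply raises the probability of *sharp
turns* (brief episodes with `|omega| > pi/8` rad/s) near a wall and thereby
reshapes the swimming speed `V_s(y, phi)`, mean angular velocity
`omega(y, phi)` and rotational diffusivity `D_r(y, phi)` within ~5 cell
lengths of the boundary. `gyroswim` is for quantitative microswimmer-motility
work: it turns planar particle-tracking exports into those ensemble maps and
sharp-turn statistics, and closes the loop with the individual-based
Langevin model

    dy   = -V_s(y, phi) sin(phi) dt
    dphi = omega(y, phi) dt + sqrt(2 D_r(y, phi)) dW        (Ito)

integrated with forward Euler--Maruyama (dimensionless step `2e-4`),
specular wall reflection and periodic heading, in five coefficient variants
(wall effects only, + wall-varying `D_r`, gyrotaxis only, gyrotaxis + wall
effects, full model). Estimation machinery: 5x10-point track smoothing,
central-difference kinematics, threshold sharp-turn detection, 51 x 80
position-orientation binning with moment estimators
`omega = mean(dphi)/dt`, `D_r = var(dphi)/(2 dt)`, jointly normalized
probability density and width-normalized concentration `N(y)`, exponential
profile fitting `N = N0 exp(sigma z/H)` with Peclet number
`sigma = V_z H / D_T`, and the far-field image-dipole diagnostic.

Because the original raw tracks are not public, the package includes a
first-class synthetic-track generator (`synthetic_spec()`, `make_fields()`,
`generate_tracks()`) that emulates the documented wall-layer structure and
writes per-frame ground truth, so every estimator is validated by parameter
recovery (see `vignettes/gyroswim-methods.Rmd` for the model, the
finite-sampling responses of displacement-based estimators, and all
numerical choices).

## Worked example

The `analysis/` directory is a numbered workflow over the package API.
`analysis/01_generate_tracks.R` writes a synthetic 400-track dataset
(1000 um channel, 10 frames/s, 60 s tracks) plus a gyrotactic vertical-plane
companion; `02` runs the measurement pipeline; `03` validates it against the
ground truth:

```r
library(gyroswim)
spec <- synthetic_spec(seed = 11)                  # W = 1000 um, V_sb = 80 um/s,
out  <- generate_tracks(make_fields(spec), spec,   # D_rb = 0.025 rad^2/s, ...
                        n_tracks = 400, duration = 60)
write_tracks(out$tracks, "tracks.tsv")
res <- analyze_tracks("tracks.tsv", W = 1000)      # filter, smooth, kinematics,
                                                   # turns, fields, N(y)
```

Running the scripts prints, among other things:

```
Turns per visiting track: 1.147 near walls vs 0.107 in the bulk (ratio 10.71).
Mean turn duration: 1.57 s (flat across bins; see turns_per_bin.tsv).
Gyrotactic timescale: fitted B = 9.91 s (generated with B = 10 s).
Constant coefficients: max |N - 1| = 0.028 (uniform).
Variant III (vertical):   peak N = 1.32 at 990 um.
Variant V (vertical):   peak N = 2.61 at 990 um.
```

Read: sharp turns concentrate near the walls (the injected near-wall rate
multiplier plus wall bounces); turn duration carries no spatial signal; the
bulk drift of the vertical dataset returns the generating reorientation
timescale within 1%; a constant-coefficient channel is statistically
uniform, gyrotaxis alone gives mild accumulation below the upper wall, and
adding the wall-layer behaviour (variants IV-V) nearly doubles the peak --
the wall interaction amplifies, and the full model deepens, the
accumulation that gyrotaxis alone would produce.

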