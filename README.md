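# stereofid

Fiducial localization and registration accuracy for frame-based
stereotaxy.

In frame-based stereotactic surgery and radiosurgery, a localizer of
known geometry is attached to the stereotactic frame so that each CT
slice carries fiducial marks whose image positions encode the slice's
3D pose relative to the frame. `stereofid` models two such devices —
the V-shaped **Sturm-Pastyr (SP) localizer** (two diagonal rods A and
C and one vertical rod B, coplanar) and the **N-localizer** (two
vertical rods joined by a diagonal) — attached to a
Zamorano-Dujovny-style frame, and quantifies how accurately measured
fiducial centers register an image to the frame under bounded
measurement noise. It is intended for medical physicists and
developers of stereotactic planning software who want a reproducible,
scriptable accuracy model rather than hardware-specific vendor code.

## The method

For one SP localizer, a slice at local height *h* above the apex
creates three fiducial centers whose pairwise image distances obey
*d*<sub>AB</sub> = *d*<sub>BC</sub> = *h*·tan α and
*d*<sub>AC</sub> = 2 *h*·tan α when the slice is untilted. The classic
inverse reads a single point on the vertical rod from the outer
distance alone, *h*<sub>B</sub> = *d*<sub>AC</sub> / (2 tan α). Noise
makes the three distances linearly independent
(*d*<sub>AC</sub> ≠ *d*<sub>AB</sub> + *d*<sub>BC</sub>), and the
package's central method exploits all three to recover **one point
per rod axis** — three (x, y, z) coordinate triples per localizer
instead of one. The default formulation fits the collinear
configuration the true fiducials always lie on:

    s = d_AC^2 / sqrt(tan^2(α)·d_AC^2 + e^2),   e = d_AB − d_BC
    h_A = (s + q)/2,  h_C = (s − q)/2,  q = s·e/d_AC
    h_B = 2·h_A·h_C / (h_A + h_C)

which is exact on noise-free input at any slice tilt and smooth in the
measurements. The recovered correspondences from all localizers feed
an overdetermined least-squares fit of the 3×3 matrix **M** mapping
[u, v, 1] to [x, y, z]; N-localizer vertical rods contribute
(x, y)-only rows that never touch the z column. A seeded, vectorized
Monte Carlo engine perturbs every fiducial center with disk-uniform
noise of bounded magnitude and reports, per target point and slice
height, the root-mean-square 3D distance between targets mapped with
the unperturbed and perturbed matrices.

## Worked example

```r
library(stereofid)

frame <- build_frame("sp", aspects = c("anterior", "left", "right"))
plane <- make_plane(z0 = 62, theta = 10 * pi / 180)   # 10 deg tilt

fids <- lapply(frame$localizers, sp_forward, plane = plane)
fids$left
#> <fiducial_set> left: d_AB 44.139, d_BC 58.637, d_AC 102.775 mm

solve_three_point(fids$left, frame$localizers$left)
#> <sp_solution> left: heights (54.335, 62.000, 72.182) mm, collinearity -7.11e-15 mm

cs <- do.call(rbind, Map(function(f, g)
  correspondences(solve_three_point(f, g), f), fids, frame$localizers))
M <- fit_transform(cs)
apply_transform(M, c(0, -50))      # posterior target
#>         x         y         z
#>  1.44e-15 -49.24039  53.31759
```

The tilted slice crosses the left localizer's rods at three different
heights (54.3, 62.0, 72.2 mm), which the three-point solve recovers
exactly; the fitted matrix then maps the posterior image target
(0, −50) to its true frame position — at a 10° anteroposterior tilt
the posterior side of the slice sits 8.7 mm lower than the slice
center, as the z = 53.3 mm output shows.

A small accuracy sweep (4096 noise draws of up to 1 mm per fiducial
center, posterior target):

```r
tb <- sweep_scenarios(scenario_presets(n_iter = 2^12, names = "fig3"),
                      seed = 1)
subset(tb, target == "posterior" & z_mm %in% c(5, 55, 105, 155))
#>        mode z_mm rmse_mm   se_mm n_used
#>     classic    5   0.974 0.00563   4096
#>     classic   55   0.986 0.00554   4096
#>     classic  105   0.978 0.00564   4096
#>     classic  155   0.974 0.00551   4096
#> three_point    5   0.863 0.00535   4096
#> three_point   55   0.755 0.00495   4096
#> three_point  105   0.624 0.00431   4096
#> three_point  155   0.550 0.00380   4096
```

Nine coordinate sets (three per localizer) cut the posterior target
registration error by 11-44 % relative to the classic three-set
solve, with the advantage growing away from the apices of the V.

A thin command-line front-end wraps the same functions:

```sh
Rscript inst/scripts/stereofid.R simulate --scenarios fig3 --seed 1 --n 4096 --out out/
Rscript inst/scripts/stereofid.R fixtures --frame sp3 --z 50 --noise 1 --out fx/
Rscript inst/scripts/stereofid.R solve --fiducials fx/fiducials_z50.csv --frame sp3
```

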