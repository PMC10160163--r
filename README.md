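# cineflowr

Intra-cardiac blood-flow velocity prediction from long-axis cine cardiac MRI.

Standard SSFP cine imaging encodes no velocity, but the intensity
fluctuations inside the cardiac blood pool move with the blood. `cineflowr`
recovers the in-plane flow from those fluctuations: a deeply-supervised
residual U-Net maps a 9-frame temporal window of cine images to the dense
per-pixel blood displacement between consecutive frames, trained against
reference displacements derived from 4D-flow MRI. Predicted displacements
`D` (pixels/frame) and velocities `V` (cm/s) are related through the pixel
spacing `PS` (mm) and frame interval `dt` (s):

    D = (dt * v_x / ps_x, dt * v_y / ps_y),    v in mm/s

The training loss is the masked end-point error over the blood pool,
deeply supervised over three auxiliary decoder heads plus the final output:

    EPE = (1/M) * sum_i || D_i,pred - D_i,ref ||
    Loss = EPE(G, O) + sum_c w_c * EPE(G, P_c)

Evaluation uses EPE on velocities, mean angular error
`arccos(V_p . V_g / |V_p||V_g|)` (0-180 deg), signed relative error of mean
speed, Pearson correlation of the per-phase mean-speed curves, velocity
histograms and threshold sweeps, per chamber. A clinical module extracts the
transmitral E/A ratio from the flow in a mitral ROI (quadratic spline
between the valve hinge points through the LV cavity center) and classifies
diastolic function as normal iff `0.75 < E/A < 1.5`.

The package is aimed at researchers in cardiac MR image analysis who want a
fully testable, dependency-light reference implementation of this pipeline:
every stage — preprocessing, network, training, metrics, E/A — runs at desk
scale on synthetic cine phantoms with exactly known flow, with no patient
data required. The network forward/backward passes are implemented in plain
R on BLAS matrix products and verified against numerical gradients.

## Worked example

Generate a phantom with a biphasic diastolic inflow jet (E = 60 cm/s at 60 %
of the cycle, A = 40 cm/s at 90 %), then recover the E/A ratio from the true
flow field and evaluate a deliberately attenuated "prediction":

```r
library(cineflowr)

cfg <- phantom_config(e_peak = 60, a_peak = 40, noise_sd = 0)
ph  <- make_phantom(cfg)

ea <- ea_from_flow(ph$truth, ph$contours, ph$mask)
ea[c("e_velocity", "a_velocity", "ratio", "diastolic_class")]
#> $e_velocity
#> [1] 59.73449
#> $a_velocity
#> [1] 39.823
#> $ratio
#> [1] 1.5
#> $diastolic_class
#> [1] 0

pred <- flow_field(0.8 * ph$truth$vx, 0.8 * ph$truth$vy)
evaluate_regions(pred, ph$truth, ph$mask, vmin = 5)
#> # A tibble: 3 x 6
#>   region n_pixels   epe angle_error relative_error   pcc
#>   <chr>     <int> <dbl>       <dbl>          <dbl> <dbl>
#> 1 4CH       27360  2.78 0.000000166            -20     1
#> 2 LV        20760  2.80 0.000000192            -20     1
#> 3 LA         6600  2.66 0                      -20     1
```

The E and A velocities are recovered to about half a percent (the jet
profile is sampled just off its axis on the pixel grid, attenuating E and A
identically, so the ratio is nearly exact); the 20 %-attenuated field shows
the expected -20 % relative error, (numerically) zero angle error and an
EPE of 20 % of the gated mean reference speed. The measured ratio 1.49997
sits on the boundary of the strict `0.75 < E/A < 1.5` band, so the class
follows the measured value: normal.

Training and cross-validation run the same way at phantom scale:

```r
cohort <- make_phantom_cohort(8, seed = 31)   # slow-flow phantoms, +/-15 % speed scale
cv <- cross_validate(cohort,
                     network_config(window = 9, base_channels = 4),
                     train_config(epochs = 25, batch_size = 10, lr = 3e-3),
                     k = 2)
```

A command-line wrapper covers the same pipeline
(`inst/cli/cineflow.R simulate|evaluate|ea|visualize|train`).

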