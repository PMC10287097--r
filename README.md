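# headmotion

Markerless quantification of head motion during MRI from depth-camera
point clouds.

An infrared depth camera on the scanner's head coil sees a patch of the
participant's face at ~8 Hz. `headmotion` turns those point clouds into a
**motion trace** — a time series of rigid head poses relative to a cleaned
reference cloud — and into scalar **motion scores** suitable for use as
covariates in neuroimaging statistics. It is aimed at population-cohort
settings where motion is small (sub-millimetre breathing, drift, rare
bursts) and tracking must run unattended across hundreds of sessions.

## Method

Each frame `P_k` is registered to the reference `P_ref` by minimizing a
robust iterative-closest-point objective

    sum_{p in P_k} psi( || R_k p + t_k - nn_ref(R_k p + t_k) ||^2 ) + lambda

with Huber's criterion `psi` (bound `Z = (1 + r_b) median(res)`,
`r_b = 0.2`) realized as IRLS with a closed-form weighted Kabsch solve per
iteration. `lambda` is a soft anchor on the occiput contact point (weight
`alpha = 0.03` of the summed data weights): the back of the head rests on
the pillow and moves least, which stabilizes the otherwise weakly
constrained posterior pose. Frames are warm-started from the previous
pose, cleaned of outliers farther than 5 mm, and under-sampled 3x on the
raster grid.

Poses are compared with the **head pose difference** (HPD): the RMS
displacement, over a ball modelling the head (radius 82.5 mm), of the
relative transform `D = b a^-1` — in closed form
`sqrt(r^2/5 tr(A'A) + ||t + A c||^2)` with `A = R_D - I`. On top of it the
package provides per-sequence motion scores (mean of one-second summed
8 Hz pose differences, mm/s), the reference-free **motion trace
difference** for comparing two methods' traces, clock synchronization,
fMRI-frame averaging, respiration mutual information (Kraskov kNN
estimator over 7 motion components), and a longitudinal random-intercept
mixed model of motion against session time, BMI, age and sex.

Everything is validated end-to-end on seeded synthetic scenes — a
face-like reference with anatomical relief, breathing/drift/burst/rotation
ground-truth motion, sensor noise, occlusion, non-rigid bumps, outliers, a
256 Hz respiration channel and an fMRI-like comparison trace — generated
by the package itself.

## Worked example

```r
library(headmotion)

cfg    <- scenario_config(n_points = 1200, duration = 8, seed = 77,
                          rot_walk_disp_sd = 0.05)
ref    <- make_face_cloud(cfg)          # reference face patch
truth  <- make_truth_trace(cfg)         # known ground-truth motion
frames <- render_frames(ref, truth, cfg)

tk <- track_sequence(frames, ref, anchor = c(0, 0, -82.5))
tk$trace
#> <motion_trace> 64 samples (64 valid), 0.00-7.88 s, space 'camera'

score_session(tk$trace, sequence_table("demo", 0, 7.5), ball_model())
#>   sequence score_mm_per_s n_seconds
#> 1     demo      0.1722473         7

grid <- seq(0.5, 7, by = 0.125)
mtd(resample_trace(tk$trace,    times = grid, window = 3),
    resample_trace(truth$trace, times = grid, window = 3), ball_model())
#> [1] 0.08515213
```

The score says the simulated head moved ~0.17 mm/s on average during the
"demo" interval (breathing plus a small rotational wander); the motion
trace difference of 0.085 mm against the ground truth means the tracker
reproduced the true motion to better than a tenth of a millimetre of
within-head displacement, below the 0.1 mm sensor noise of the scene.

A thin CLI wraps the same functions
(`inst/cli/headmotion simulate|track|score|compare|sync|mi|analyze`).

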