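# gesturespeech

Analysis pipeline for **gesture–speech physics**: how rhythmic upper-limb
movement perturbs the acoustics of fluent speech. The package is written for
researchers in speech-motor control, gesture studies, and prosody who record
mono speech audio together with limb motion capture and want a tested,
reproducible route from raw signals to the paradigm's three statistical
results.

## The paradigm and the models

Participants retell stories while (a) not moving, (b) flapping the wrist, or
(c) swinging the forearm vertically at a target tempo of 80 BPM (1.33 Hz),
with an instructed *beat* — an abrupt stop at the maximum extension of the
downstroke. The braking impulse (effector mass × deceleration) is
hypothesized to load the respiratory–vocal system and surface in the voice.

The pipeline extracts two prosodic signals on a common 240-Hz grid:

* the **amplitude envelope** — modulus of the analytic (Hilbert) signal,
  smoothed with a 5-Hz (200-ms) Hann window;
* the **F0 track** — autocorrelation pitch tracking with sex-appropriate
  ranges (male 50–400 Hz, female 80–640 Hz), octave-jump suppression, and
  missingness marking unvoiced frames;

and from the motion trace (zero-phase first-order Butterworth at 30 Hz,
derivatives by central differences): **beat events** (position minima),
**deceleration onsets**, **maximum deceleration** in the 200 ms before each
beat, and a wavelet-ridge estimate of movement tempo.

Three analyses follow, each fit by established mixed-model machinery
(`lmerTest`, `mgcv`):

1. condition contrasts on trial-average acoustics,
   `y ~ condition + (1 | participant)` (+ sex for F0);
2. GAM trajectory smooths of beat-locked epochs (−400…+400 ms around
   maximum extension, 193 samples), with difference smooths of each
   movement condition against a **surrogate baseline** built by randomly
   re-pairing passive-condition speech with movement-trial beats within
   participant;
3. mixed-effects regressions of deceleration-window acoustic peaks on
   maximum deceleration — envelope slope, and the condition × deceleration
   interaction for F0 (wrist reference).

Because real recordings are not required, the package ships a
**synthetic-session generator** that injects known coupling (a Gaussian
acoustic bump at each beat with height `mass_factor × β × max_decel`,
plus condition-level offsets) and records full ground truth, giving every
stage of the pipeline an acceptance surface. See the methods vignette
(`vignettes/gesture-speech-physics.Rmd`) for the model details and all
tunable parameters.

## Worked example

Generate a small synthetic study, run the full pipeline, and inspect the
condition contrasts and the deceleration models:

```r
library(gesturespeech)

cfg <- pipeline_config(n_participants = 8, trials_per_condition = 2,
                       master_seed = 7, use_truth_contours = TRUE)
run <- run_all(cfg)
run
#> <gs_run> 8 participants, 48 trials, 1385 epochs (193 samples each)

print(run$models$condition_env)
#> Condition contrasts (env_z response), 48 trials
#>            term        b      se df   stat         p
#>     (Intercept) -0.09459 0.02659 45 -3.557 8.975e-04
#>  conditionwrist  0.05436 0.03761 45  1.445 1.553e-01
#>    conditionarm  0.20910 0.03761 45  5.561 1.395e-06

print(run$models$deceleration)
#> Deceleration effects on acoustic peaks (32 movement trials)
#> (deceleration standardized: SD = 1813.5 cm/s^2)
#> ENV model (random slope dropped):
#>         term     b      se df   stat         p
#>  (Intercept) 1.198 0.02833 30 42.270 2.697e-28
#>      decel_s 0.195 0.02879 30  6.775 1.633e-07
#> F0 model (random slope dropped):
#>                  term       b     se df    stat      p
#>           (Intercept)  0.5786 0.4343 28  1.3320 0.1936
#>          conditionarm  0.7483 0.4616 28  1.6210 0.1162
#>               decel_s  0.4638 0.4768 28  0.9726 0.3391
#>  conditionarm:decel_s -0.1700 0.4994 28 -0.3403 0.7361
```

Reading the output: the envelope sits about 0.21 z-units higher in arm
trials than in passive trials (the injected offset plus beat-locked bumps;
the smaller wrist effect is not resolvable at this toy scale), and peak
envelope in the deceleration window rises by ≈ 0.20 z per SD of maximum
deceleration. The subtler effects — the wrist contrast and the arm-only
F0 × deceleration interaction — need the study-scale design (37
participants), which is exactly what the acceptance suite runs. With
`use_truth_contours = FALSE` (the default) the same pipeline additionally
synthesizes audio and runs the full envelope/F0 extraction instead of
reading the generator's contours.

Beat-locked average trajectories are available for plotting:

```r
plot_trajectories(run$trajectory_means$pooled)
```

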