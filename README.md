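# gazepatchnet

Expertise classification from fixation image-patch sequences over
360° video, in R.

## The problem

Perceptual-cognitive expertise — here, the kind a soccer goalkeeper deploys
when scanning a build-up situation — leaves a signature in gaze behaviour:
*where* an athlete fixates and *in which order*. Hand-crafted scanpath
statistics (fixation counts, mean durations, …) capture little of that
signature. This package implements an end-to-end alternative: the stimulus
content at each fixation is encoded by a CNN, and the temporal structure of
the fixation sequence by a recurrent network, so that a whole trial is
classified as the product of a novice, an advanced or an expert observer.

The pipeline, for each trial of ~250 Hz gaze recorded over an
equirectangular 360° video (reference resolution 3,840 × 1,920 at 30 FPS):

1. **Quality filter** — a trial is kept only when its *tracking ratio*
   (fraction of validly tracked samples) is strictly above 75%.
2. **I-VT fixation detection** — per-sample angular velocity on the sphere
   (great-circle distance between consecutive valid gaze directions over
   Δt); samples slower than 50°/s are fixation samples, maximal runs of
   them form fixations; each fixation is reduced to its spatial center
   (circular mean across the u = 0/1 seam) and temporal center.
3. **Patch extraction** — the video frame at the fixation's temporal
   center is cut to a 224 × 224 × 3 patch around the spatial center,
   wrapping horizontally (sphere) and edge-replicating vertically (poles).
4. **Augmentation** — the dataset is doubled: each sequence gains one copy
   whose patches receive Gaussian blur, salt-and-pepper noise and one
   random geometric transform (rotation −180…180°, shear −15…15°, flip, or
   translation ±80 px).
5. **CNN features** — each patch is reduced to a 1,024-vector by a backbone
   truncated at its last pooling layer (GoogLeNet architecture by default;
   a fast deterministic "toy" backbone for offline testing).
6. **BiLSTM classifier** — sequence input (1,024) → BiLSTM with 500 units
   per direction emitting only the final step (output 1,000) → fully
   connected (100) → dropout 0.5 → fully connected (3) → softmax, trained
   with cross-entropy, minibatch 42, constant learning rate 4.4e-4, L2
   8.2e-4, validation every 52 iterations and patience-6 early stopping.
7. **Evaluation** — leave-one-participant-out: all sequences of one
   participant are held out per run, the rest split 70:30 (augmented
   copies join only the training side, classes balanced by undersampling);
   pooled confusion matrix, per-class recall, one-vs-rest ROC/AUC, and the
   mean of per-run accuracies.

A seeded synthetic-cohort generator (procedural 360° scenes with moving
colored discs standing in for players and ball, plus class-conditional
fixation/saccade processes) lets the entire pipeline run offline.

## Worked example

```r
library(gazepatchnet)

spec  <- fixture_spec(n_per_class = c(1, 1, 1), n_trials = 2, n_videos = 1,
                      video = list(width = 480, height = 240, fps = 30,
                                   duration_s = 2), seed = 7)
video <- generate_video(spec, video_id = 1)
trial <- generate_gaze(spec, participant_class = 2, video, seed = 5,
                       participant_id = "exp01")
trial
#> <trial_recording> participant exp01, trial 1, video 1, label 2 (expert)
#>   500 samples @ 250 Hz, tracking ratio 0.970

fix <- ivt_detect(trial, threshold_deg_s = 50)
nrow(fix)            # number of detected fixations in the 2 s trial
#> [1] 5
patch <- extract_patch(video, fix[1, ])
dim(patch)
#> [1] 224 224   3

bb  <- load_backbone("toy")      # "googlenet-pool5" for the CNN architecture
length(bb$forward(patch))
#> [1] 1024
```

`nrow(fix)` is the scanpath length that becomes the sequence length `T` of
the classifier input; the backbone turns each of the `T` patches into a
1,024-vector. Fitting and evaluating over a whole synthetic cohort:

```r
report <- run_cohort_evaluation(
  fixture_spec(), backbone = "toy",
  config = gazenet_config(hidden = 16, fc = 25),
  control = gazenet_control(minibatch = 16, validation_frequency = 20,
                            validation_patience = 10, max_epochs = 400,
                            learning_rate = 1e-3, l2 = 1e-2, shuffle = TRUE))
report   # prints mean/pooled accuracy, per-class recall, AUCs, confusion
```

The same stages are available as an on-disk, manifest-driven pipeline
(`pipeline_config()` + `run_pipeline()`, or the CLI at
`inst/scripts/gazepatchnet.R`).

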