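# p300sep

Single-trial decoding of nine-target P300 speller sessions with a
depthwise-separable 1D convolutional network, classical linear baselines,
and a complete simulation + evaluation harness.

## Who this is for

Brain-computer-interface researchers who want a self-contained, reproducible
pipeline for oddball P300 decoding — in particular for augmented-reality
(AR) presentation, where the P300 is smaller and ~50 ms later than on a
computer screen (CS) and single-trial (non-averaged) recognition is the
interesting regime. Because no public recordings exist for this protocol,
the package ships a seeded synthetic session generator with the protocol's
exact structure, so every result is recomputable from a single master seed.

## The model

Each trial flashes 9 stimuli once in random order (SOA 175 ms); the epoch
after each flash (600 ms, bandpassed 0.1–12 Hz, decimated to 200 samples x
30 channels) is scored by a classifier, and the trial's selection is

    argmax_j score(epoch_j),  j = 1..9   (ties -> lowest index).

The separable CNN scores epochs with the stack

    BatchNorm -> DepthConv1D(30 kernels, size 10, stride 6, pad 4) -> 34x30
    -> BatchNorm -> PointConv1D(4 kernels, size 1)                 -> 34x4
    -> Tanh -> Flatten(136) -> Dense(136->1) -> Sigmoid            -> p(target)

trained with Adam on class-weighted binary cross-entropy. A single-layer
separable convolution costs `C_sep = (h + n)(H1 - h + 1)` versus
`C = n h (H1 - h + 1)` for a standard convolution — a ratio of exactly
`1/n + 1/h` (0.35 at the defaults), which is why the network is cheap enough
for wearable AR hardware. Baselines: shrinkage LDA, Bayesian LDA (evidence
maximization), stepwise LDA (p-enter 0.1, p-remove 0.15, max 60 steps), and
a linear SVM (C = 1), all on the flattened 6000-dimensional epoch.

Selection performance is summarized as per-run accuracy, pooled AUC, and the
Wolpaw information transfer rate
`ITR = (log2 N + P log2 P + (1-P) log2((1-P)/(N-1))) * 60/T` bits/min with
N = 9 and T = 2.0 s per selection.

## Worked example

```r
library(p300sep)

# one AR run, high-SNR noise world, short inter-trial idle time
sch <- make_schedule(runs = 2, prep_ms = 300, lock_ms = 200, seed = 11)
prm <- sim_params("ar", noise_pink_uv = 1.5, noise_alpha_uv = 0.8,
                  noise_white_uv = 0.5, latency_jitter_ms = 10)
ses <- simulate_session(sch, prm, seed = 12)
ep  <- preprocess_session(ses)   # drop A1/A2, bandpass, epoch, decimate
ep
#> <epoch_set> 810 epochs x 200 samples x 30 channels @ 333.333 Hz (90 targets, 720 non-targets)

rep <- crossval(ep, model_factory("sepcnn",
                                  hyper = train_hyper(max_epochs = 40,
                                                      patience = 8, seed = 5)),
                folds = 5, seed = 9)
rep
#> <eval_report> 5-fold CV: accuracy 100.00%, AUC 1.000, ITR 95.10 bits/min
```

At this signal-to-noise ratio the network separates target from non-target
epochs essentially perfectly: all 90 trials decode to the cued stimulus
(100%), the pooled held-out AUC is 1.000, and a perfect nine-way selection
every 2 s corresponds to the ITR ceiling `log2(9) * 30 = 95.10` bits/min.
At the realistic default noise levels accuracies drop into the published
80% range and the ITR falls accordingly.

The same pipeline runs end to end from one seed:

```r
report <- run_pipeline(run_config(runs = 2, model = "sepcnn", seed = 1,
                                  out_dir = "artifacts"))
```

or from the shell:

```sh
Rscript inst/cli/p300sep simulate --environment ar --runs 10 --seed 1 --out session.h5
Rscript inst/cli/p300sep preprocess --in session.h5 --out epochs.h5
Rscript inst/cli/p300sep evaluate --in epochs.h5 --model sepcnn --folds 5 --out report.json
```

## Reference tables

`ref_accuracy_table()` and `ref_latency_table()` ship the published
15-participant benchmark (per-run accuracies; AR/CS P300 latencies) that
calibrates the simulator defaults and the ITR computation: the latency
means are 434.53 ms (CS) / 482.47 ms (AR), and the per-participant Wolpaw
ITR of the accuracy table at T = 2.0 s averages 58.0 bits/min.

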