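# hfpredict

Predict hot-flash (HF) onsets from ambulatory skin-conductance (SC)
recordings **before they are subjectively perceived**.

Hot flashes — the vasomotor symptoms of menopause — are physiologically
marked by a rapid rise in skin conductance (sweating) that begins seconds
before the person feels the event. A wearable that recognizes that rising
edge in real time can trigger a just-in-time cooling intervention at or
ahead of the perceived onset. `hfpredict` implements the analysis chain
needed to study this on 1 Hz SC traces, for researchers in digital health
and psychophysiology:

* **Window features** computed on trailing windows (real-time safe): the
  median-subtracted integral `msi = Σ (yᵢ − ỹ) Δt` (30 s windows), and six
  derivative features of a biexponential fit `y_c = A·exp(Bx² + Cx)` to the
  minimum-subtracted window on `x ∈ [0, 1]` (60 s windows): the grid extrema
  of `y_c′`, `y_c″` and `y_c′ × y_c″`. The second-derivative maximum
  (`d2max`) reacts earliest to the accelerating sweat response.
* **Three-class labeling** of windows by their last timestamp relative to
  each confirmed onset, with distinct train zones (Class 1 in [−30, 120) s,
  Class 2 in [120, 240), Class 0 in [−240, −30), rest excluded) and
  deployment-faithful test zones (Class 1 in [−60, 0), Class 2 in [0, 30),
  exclusion to 20 min post-onset, Class 0 elsewhere).
* **`hf_fit()`** — a univariate three-class logistic model behind a robust
  scaling chain (normality transform → median/IQR → arctan → standardize,
  all statistics frozen from training data), returning a classed object
  with `print`, `summary`, `coef` and `predict` methods and a lossless
  JSON artifact.
* **Event-level evaluation**: beyond merged-class window confusion
  (sensitivity, specificity, PPV, NPV, F1, predictivity), the prediction
  rate PR, identification rate IR and signed identification latency IL,
  where the first HF-positive window in [−60, +30] s of an onset counts and
  negative latency means identification *before* the reference onset.
* **The classical baseline** (`freedman_detect`): an SC rise ≥ 2 uS within
  30 s, with run-collapsing and a refractory period.
* **A seeded synthetic generator** of SC sessions and cohorts with
  ground-truth events, typical and atypical morphologies, spontaneous
  SCRs, night sweats, artifacts and delayed/missing participant markers —
  the test substrate standing in for cohort data that are not publicly
  deposited.

## Worked example

Simulate a two-hour session, extract the `d2max` feature, fit the model,
and evaluate against the ground-truth onsets:

```r
library(hfpredict)

session <- simulate_session(synth_config(duration_h = 2,
                                         event_rate_per_h = 2, seed = 8))
session
#> <synth_session> P01/S01: 2.0 h, 5 confirmed event(s), 0 night sweat(s), 4 marker(s)

ft  <- extract_feature_series(session$trace, "d2max")
ev  <- confirmed_events(session$true_events)
lab <- label_windows(ft$end_s, ev, label_scheme("train"))

model <- hf_fit(label ~ d2max,
                data.frame(d2max = ft$value, label = lab$label))
summary(model)
#> <hf_model> univariate multinomial logistic on 'd2max'
#>   trained on 480 windows (class counts: 0=210, 1=150, 2=120)
#>   scaler: arcsinh transform; L2 penalty 0.5; seed 10
#>   coefficients (log-odds vs class 0):
#>   (Intercept)  scaled
#> 1    -0.01872 3.40957
#> 2     0.36859 2.23079

test_lab <- label_windows(ft$end_s, ev, label_scheme("test"))
pred <- predict(model, data.frame(d2max = ft$value))
session_metrics(pred, test_lab$label, ft$end_s, ev, session_id = "demo")
#>    Sens  Spec   PPV PR IR    IL n_events
#> 1 0.633 0.863 0.456  1  1 -28.4        5
```

All five events are identified (`IR = 1`), all of them before the
reference onset (`PR = 1`), on average 28 s early (`IL = −28.4` s). (This
demo trains and tests on one session for brevity; `run_hf_pipeline()`
does the real thing with a participant-level train/test split.)

The end-to-end study analog — a 12-participant cohort, 6 held out for
testing balanced across typical and atypical SC morphology, one model per
feature, reports stratified three ways — is one call:

```r
run <- run_hf_pipeline(hf_run_config(synth = synth_config(duration_h = 2,
                                                          seed = 1)))
print(run)
```

A thin command-line front end for shell use lives at
`inst/scripts/hf-pipeline.R` (subcommands `simulate`, `preprocess`,
`label`, `features`, `train`, `predict`, `evaluate`, `run`, `sweep`).

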